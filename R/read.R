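#' Construct a sequencing read
#'
#' The unit passed through detection, splitting, and I/O. A read carries an
#' identifier, an uppercased sequence, an optional Phred+33 quality string
#' of equal length, and a provenance interval (`origin`) locating the
#' sequence inside the original input read, in 0-based half-open
#' coordinates. An unsplit input read is its own origin: `(id, 0, n)`.
#'
#' @param id Character identifier.
#' @param seq DNA sequence over `A,C,G,T,N` (case-insensitive; stored
#'   uppercased).
#' @param qual Optional quality string, `nchar(qual) == nchar(seq)`.
#' @param origin Optional list `list(parent=, start=, end=)`; defaults to
#'   the read itself spanning its full length.
#' @param lenient Map out-of-alphabet characters to `N` instead of erroring.
#' @return An object of class `pc_read`.
#' @examples
#' r <- new_read("readA", "ACGTACGT")
#' r$origin
#' @export
new_read <- function(id, seq, qual = NULL, origin = NULL, lenient = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, !is.na(id))
  seq <- clean_sequence(seq, lenient = lenient)
  if (!is.null(qual)) {
    stopifnot(is.character(qual), length(qual) == 1L)
    if (nchar(qual) != nchar(seq))
      stop("quality string length (", nchar(qual),
           ") does not match sequence length (", nchar(seq), ") for read '", id, "'")
  }
  if (is.null(origin)) {
    origin <- list(parent = id, start = 0L, end = nchar(seq))
  } else {
    stopifnot(is.list(origin), all(c("parent", "start", "end") %in% names(origin)))
    origin$start <- as.integer(origin$start); origin$end <- as.integer(origin$end)
    if (origin$end - origin$start != nchar(seq))
      stop("origin interval length does not match sequence length for read '", id, "'")
  }
  structure(list(id = id, seq = seq, qual = qual, origin = origin),
            class = "pc_read")
}

#' @export
print.pc_read <- function(x, ...) {
  n <- nchar(x$seq)
  preview <- if (n > 40) paste0(substr(x$seq, 1, 37), "...") else x$seq
  cat(sprintf("<read %s: %d b%s, origin %s:%d-%d>\n  %s\n",
              x$id, n, if (is.null(x$qual)) "" else " +qual",
              x$origin$parent, x$origin$start, x$origin$end, preview))
  invisible(x)
}

#' @export
length.pc_read <- function(x) nchar(x$seq)

#' Fragment identifier from provenance coordinates
#'
#' Names a fragment `"{parent}:{start}-{end}"` with 0-based half-open
#' coordinates in the original input read. Nested splits compose through
#' the origin interval, so coordinates always refer to the original frame
#' and suffixes never nest.
#'
#' @param parent_id Identifier of the original input read.
#' @param start,end Interval in the original read, `0 <= start < end`.
#' @return The fragment id string.
#' @examples
#' fragment_id("readA", 0, 100)  # "readA:0-100"
#' @export
fragment_id <- function(parent_id, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || end <= start)
    stop("invalid fragment interval [", start, ",", end, ")")
  paste0(parent_id, ":", start, "-", end)
}
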