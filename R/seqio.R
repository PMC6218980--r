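#' Read sequences from FASTA or FASTQ
#'
#' Streams a (possibly gzip-compressed) FASTA or FASTQ file into a list of
#' [new_read()] objects, in file order, sequences uppercased. Format is
#' taken from the file extension and falls back to peeking at the first
#' record character. Multi-line FASTA is supported. FASTQ quality strings
#' are validated against sequence lengths per record; a mismatch raises an
#' error naming the offending record.
#'
#' @param path Input file path; `.gz` handled transparently.
#' @param format `"fasta"`, `"fastq"`, or `NULL` to auto-detect.
#' @param lenient Map out-of-alphabet sequence characters to `N` instead of
#'   erroring.
#' @return List of `pc_read`s (qualities present iff FASTQ).
#' @export
read_seqs <- function(path, format = NULL, lenient = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(format)) format <- detect_format(path)
  format <- match.arg(format, c("fasta", "fastq"))
  if (format == "fasta") {
    x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("failed to parse FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
    quals <- NULL
  } else {
    diagnose_fastq(path)  # record-level structural validation up front
    x <- tryCatch(Biostrings::readBStringSet(path, format = "fastq",
                                             with.qualities = TRUE),
                  error = function(e) stop("failed to parse FASTQ '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
    quals <- as.character(S4Vectors::mcols(x)$qualities)
  }
  ids <- names(x)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    ids <- ifelse(is.na(ids) | ids == "", paste0("read", seq_along(x)), ids)
  seqs <- as.character(x)
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    q <- if (is.null(quals)) NULL else quals[[i]]
    if (!is.null(q) && nchar(q) != nchar(seqs[[i]]))
      stop("FASTQ record ", i, " ('", ids[[i]], "') in '", path,
           "': quality length ", nchar(q), " != sequence length ", nchar(seqs[[i]]))
    out[[i]] <- new_read(ids[[i]], seqs[[i]], qual = q, lenient = lenient)
  }
  out
}

# Line-level structural validation: truncated 4-line blocks and
# sequence/quality length disagreements are reported with record index
# and line number before the fast parser runs.
diagnose_fastq <- function(path) {
  con <- gzfile(path, "rt"); on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  i <- 1L; rec <- 0L
  while (i <= length(lines)) {
    rec <- rec + 1L
    if (i + 3L > length(lines))
      stop("truncated FASTQ record ", rec, " starting at line ", i,
           " of '", path, "'", call. = FALSE)
    id <- lines[i]
    if (!startsWith(id, "@"))
      stop("FASTQ record ", rec, " at line ", i, " of '", path,
           "' does not start with '@'", call. = FALSE)
    if (nchar(lines[i + 3L]) != nchar(lines[i + 1L]))
      stop("FASTQ record ", rec, " ('", sub("^@", "", id), "', line ", i,
           ") in '", path, "': quality length ", nchar(lines[i + 3L]),
           " != sequence length ", nchar(lines[i + 1L]), call. = FALSE)
    i <- i + 4L
  }
  invisible(NULL)
}

detect_format <- function(path) {
  base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
  ext <- tolower(sub(".*\\.", "", base))
  if (ext %in% c("fq", "fastq")) return("fastq")
  if (ext %in% c("fa", "fasta", "fna", "ffn", "frn")) return("fasta")
  con <- gzfile(path, "rt"); on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (length(first) == 0L) return("fasta")  # empty file: writable as empty FASTA
  if (startsWith(first, "@")) "fastq"
  else if (startsWith(first, ">")) "fasta"
  else stop("cannot detect sequence format of '", path, "'")
}

#' Write sequences to FASTA or FASTQ
#'
#' Round-trip stable with [read_seqs()] on ids, sequences and qualities.
#' Writing FASTQ from quality-less reads is an error unless `fill_quality`
#' supplies a constant Phred+33 character.
#'
#' @param reads List of `pc_read`s.
#' @param path Output path; a `.gz` suffix enables gzip compression.
#' @param format `"fasta"`, `"fastq"`, or `NULL` (FASTQ iff every read has
#'   qualities, FASTA otherwise).
#' @param fill_quality Optional single quality character used for reads
#'   without qualities when writing FASTQ.
#' @return Number of records written, invisibly.
#' @export
write_seqs <- function(reads, path, format = NULL, fill_quality = NULL) {
  stopifnot(is.list(reads))
  has_q <- vapply(reads, function(r) !is.null(r$qual), logical(1))
  if (is.null(format))
    format <- if (length(reads) > 0L && all(has_q)) "fastq" else "fasta"
  format <- match.arg(format, c("fasta", "fastq"))
  compress <- grepl("\\.gz$", path, ignore.case = TRUE)
  seqs <- vapply(reads, function(r) r$seq, character(1))
  ids <- vapply(reads, function(r) r$id, character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  if (format == "fasta") {
    Biostrings::writeXStringSet(x, path, format = "fasta", compress = compress)
  } else {
    quals <- vapply(reads, function(r) {
      if (!is.null(r$qual)) return(r$qual)
      if (is.null(fill_quality))
        stop("read '", r$id, "' has no qualities; cannot write FASTQ ",
             "(supply fill_quality to use a constant quality)")
      strrep(fill_quality, nchar(r$seq))
    }, character(1))
    Biostrings::writeXStringSet(x, path, format = "fastq", compress = compress,
                                qualities = Biostrings::BStringSet(quals))
  }
  invisible(length(reads))
}
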