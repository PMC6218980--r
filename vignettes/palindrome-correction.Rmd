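---
title: "Correcting palindromic chimeras in long reads: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting palindromic chimeras in long reads: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palinclean)
```

## The artifact and the correction model

Whole-genome amplification of minute DNA amounts occasionally lets the
polymerase fold back and continue elongation along the strand it has just
synthesised. The product is a chimera of the form `X + rc(X)` — a
sequence immediately followed by its own reverse complement — and the
event can repeat on its own product, nesting the structure: after `k`
full-length folds the molecule carries `2^k` copies of the original
fragment in alternating orientation. Sequenced as a long read, such an
artificial palindrome is pure poison for mapping and assembly, yet every
base in it is real genomic sequence. The correction is therefore purely
structural: find the fold, cut there, recurse, and never edit a base.

Detection exploits a symmetry: if `R` contains `X + rc(X)`, then `rc(R)`
contains the same block, so a local alignment of `R` against `rc(R)`
produces a strong hit covering both arms. A read without inverted
structure has no long shared block with its reverse complement, so its
best local self-vs-rc hit stays weak. Note there is no trivial
self-identity diagonal in this comparison — `R` vs `rc(R)` only aligns
well where inverted repeat structure exists, which is exactly the signal.

## Alignment layer

The aligner is an exact Smith–Waterman over the full dynamic-programming
matrix with traceback, written in C++ for speed but bit-identical to a
naive R implementation: the test suite asserts exact score equality
against an independent plain-R dynamic program on hundreds of random
pairs, and additionally against `Biostrings::pairwiseAlignment` under the
equivalent linear-gap parameterisation. Parameters, all integers, all
user-facing:

| parameter | default | meaning |
|---|---|---|
| match | +3 | score per identical column |
| mismatch | −4 | score per substituted column |
| gap | −3 | score per gap column (linear model, no open/extend split) |

`N` never matches anything, including another `N`, and `rc(N) = N`: a run
of ambiguity calls therefore cannot manufacture a palindrome hit. This is
deliberately conservative.

A hit is accepted as a detectable palindrome only if it clears five
ratios (defaults 0.01, 0.01, 0.01, 0.01 and base score 1.0 — see
`filter_thresholds()`). These five quantities are reconstructed
definitions: score over maximum attainable score (`match * n`), aligned
fraction of the read, identical fraction of aligned columns, score per
column, and score per read base. The definitions were chosen so that,
under the default values, the single operative criterion is
`score >= read_length` — the only reading under which the near-zero
values of the first four thresholds make sense while random
non-palindromic reads still pass through unflagged. With match = 3 and a
~12% per-copy error rate, two palindrome arms covering most of a read
comfortably exceed one score unit per read base, while the best chance
hit on a random read of a few hundred bases stays an order of magnitude
below it.

Tie-breaking is fully deterministic (smallest query start, then smallest
target start, then earliest end; diagonal preferred over vertical over
horizontal during traceback), so identical inputs give byte-identical
outputs on any platform. Memory is quadratic in read length — the price
of an exact full-matrix alignment — so reads beyond a configurable
maximum (default 100 kb) raise a resource error and pass through
uncorrected with a warning rather than exhausting memory.

## Split placement and recursion

The accepted hit occupies `[qs, qe)` on the read and `[ts, te)` on the
reverse complement; the second arm maps back to read coordinates as
`[n − te, n − ts)`. The cut is placed at the floor midpoint of the union
of the two arm intervals. For a perfect palindrome the union is the whole
read and the cut lands at `n/2`; for an embedded palindrome
`B + X + rc(X) + C` the arms are adjacent and the midpoint is their
junction; for a separated inverted repeat it is the spacer midpoint. The
query-interval midpoint would coincide in the dominant adjacent-arm case;
the union midpoint was preferred because it stays symmetric when chance
matches extend one arm. If the computed position degenerates to 0 or `n`,
the read is reported unsplit rather than recursing forever.

Both halves are re-processed as if they were fresh reads (depth-first,
left child first), which resolves nested palindromes; only the single
best hit is acted on per iteration because recursion finds the rest.
Fragments are re-tested down to 2 b. Two guards bound the work: fragments
shorter than `min_len` (default 50 b) are routed to a `discarded` list —
counted, never silently dropped, and the rule applies to intact
sub-minimum input reads too — and a cap of `max_iterations = 64` split
events per read stops adversarial inputs; observed real data needs at
most ~15. Every split strictly shortens both children, so termination is
guaranteed even without the cap.

The package-wide conservation invariant — emitted plus discarded
fragments, ordered by their origin intervals, reproduce the input read
byte for byte — is asserted in the tests across thousands of simulated
reads. Fragment ids are `parent:start-end` in original-read coordinates
(flat, never nested), so conservation is checkable from ids alone.

## What the simulator emulates — and what it does not

`simulate_readset()` generates templates as i.i.d. bases with a GC dial,
applies `fold()` (prefix + reverse complement of the prefix; breakpoint
defaults to full length) one or more times to a deterministic subset of
reads, then corrupts reads with per-base substitutions, single-base
insertions and deletions. Default rates 0.01 / 0.08 / 0.03 (~12% total,
indel-dominated) reflect the error profile of early PacBio-class
chemistry, whose published base-calling error range is roughly 11–38%;
they are motivated by that range, not fitted to any dataset. A monotone
coordinate map from pre-error to post-error positions projects the true
fold points so split placement can be scored exactly.

Deliberately not modelled: amplification branching and coverage bias,
chimeras joining distant genomic loci, position-dependent or
quality-correlated errors, and realistic quality strings. Passing the
recovery suite therefore demonstrates that the method finds and cuts
fold-back palindromes under heavy uniform noise; it does not certify
behaviour on biological repeat structure (true inverted repeats in a
genome are cut like artifacts — a known, inherent limitation of the
signal itself) or on error bursts.

Problem sizes in the tests and the acceptance script — 1000 mixed reads
of ~700 b mean length for conservation, 100 chimeric plus 100 plain
reads at template length 500 for recovery, 200 random pairs up to 300 b
for oracle equality — were chosen as the smallest sets at which the
binomial noise on the reported rates is clearly below the thresholds
being checked.

## Numerical and interface choices

- Coordinates are 0-based half-open everywhere: closed under splitting
  and concatenation.
- Sequences are uppercased on ingest; original case is not preserved.
  Out-of-alphabet characters are an error in strict mode, mapped to `N`
  in lenient mode (the CLI default is lenient with `--strict-alphabet`
  available).
- The detection threshold interacts with read length: a read shorter
  than ~`min_len` cannot contain two arms worth emitting, and reads of
  length < 2 are never aligned.
- FASTA/FASTQ parsing and writing are delegated to Biostrings; the
  wrapper adds format auto-detection, gzip by extension, per-record
  quality-length validation, and the fragment-naming convention.
- `--threads` exists for interface compatibility only; the computation
  is single-threaded, so output can never depend on it. Output format
  follows input format unless overridden.
- Expected behaviour at degenerate inputs: empty read sets produce empty
  outputs and all-zero statistics, not errors; an all-`N` read aligns
  nowhere (every column scores −4) and passes through intact.

## Evaluation semantics

`evaluate_correction()` treats a read as flagged iff at least one split
occurred. Detection precision is reported as `n/a` when nothing is
flagged. A true fold point counts as recovered when some predicted split
lies within a tolerance, by default 2% of the read length — a tolerance
on the *artifact's* scale (the coordinate-map projection of the fold
point under 12% indel noise is itself only defined to a few bases).
`gc_profile()` computes per-read GC excluding `N` from numerator and
denominator and normalises bin masses to sum 1; because correction only
cuts, the aggregate base-level GC of input and output is identical
whenever nothing is discarded.
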