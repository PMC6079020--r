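#' Alignment scoring parameters
#'
#' Affine-gap scoring used by every pairwise alignment in the package: a gap
#' of length k costs `gap_open + k * gap_extend`.
#'
#' @param match Match score (default +1).
#' @param mismatch Mismatch score (default -2).
#' @param gap_open Gap opening penalty, positive (default 10).
#' @param gap_extend Gap extension penalty per gap position, positive
#'   (default 1).
#' @return An `align_params` list.
#' @export
align_params <- function(match = 1, mismatch = -2, gap_open = 10, gap_extend = 1) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_params")
}

# Identity / coverage conventions, computed from the aligned strings:
#  - terminal gap columns (gap runs touching either end of either string) are
#    excluded from the identity denominator;
#  - internal gap columns count as mismatches;
#  - coverage of a sequence = its bases inside the non-terminal-gap core
#    region / its full length.
alignment_result <- function(aligned_a, aligned_b, score, len_a, len_b,
                             start_a = 1L, end_a = len_a,
                             start_b = 1L, end_b = len_b) {
  L <- nchar(aligned_a)
  if (L == 0) {
    return(structure(list(aligned_a = "", aligned_b = "", score = score,
                          identity = 0, alignment_length = 0L,
                          coverage_a = 0, coverage_b = 0,
                          start_a = 0L, end_a = 0L, start_b = 0L, end_b = 0L),
                     class = "alignment_result"))
  }
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1]]
  gap_a <- ca == "-"
  gap_b <- cb == "-"
  lead <- 0L
  while (lead < L && (run_start(gap_a, lead + 1L) || run_start(gap_b, lead + 1L))) {
    lead <- lead + 1L
  }
  trail <- 0L
  while (trail < L - lead &&
         (run_end(gap_a, L - trail) || run_end(gap_b, L - trail))) {
    trail <- trail + 1L
  }
  core <- if (lead + trail >= L) integer(0) else seq.int(lead + 1L, L - trail)
  n_core <- length(core)
  matches <- sum(ca[core] == cb[core] & !gap_a[core])
  identity <- if (n_core > 0) matches / n_core else 0
  cov_a <- sum(!gap_a[core]) / max(1L, len_a)
  cov_b <- sum(!gap_b[core]) / max(1L, len_b)
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b, score = score,
                 identity = identity, alignment_length = n_core,
                 coverage_a = cov_a, coverage_b = cov_b,
                 start_a = as.integer(start_a), end_a = as.integer(end_a),
                 start_b = as.integer(start_b), end_b = as.integer(end_b)),
            class = "alignment_result")
}

# is position p inside a gap run touching the start / end of the string?
run_start <- function(gaps, p) {
  p <= length(gaps) && all(gaps[seq_len(p)])
}

run_end <- function(gaps, p) {
  p >= 1 && all(gaps[p:length(gaps)])
}

#' Optimal global (Needleman-Wunsch) alignment with affine gaps
#'
#' End gaps are penalised. Identity is computed over non-terminal-gap columns
#' with internal gaps counted as mismatches; coverage of each sequence is its
#' span inside the terminal-gap-free core over its full length.
#'
#' @param a,b Non-empty nucleotide strings.
#' @param params [align_params()].
#' @return An `alignment_result` with `aligned_a`, `aligned_b`, `score`,
#'   `identity`, `alignment_length`, `coverage_a`, `coverage_b`.
#' @export
global_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align empty sequences")
  r <- cpp_align(a, b, "global", params$match, params$mismatch,
                 params$gap_open, params$gap_extend)
  alignment_result(r$aligned_a, r$aligned_b, r$score, nchar(a), nchar(b))
}

#' Optimal local (Smith-Waterman) alignment with affine gaps
#'
#' `alignment_length` is the number of aligned columns of the local alignment
#' (including internal gap columns). An all-negative scoring situation yields
#' an empty alignment with score 0.
#'
#' @inheritParams global_align
#' @return An `alignment_result` (plus `start_a`/`end_a`/`start_b`/`end_b`
#'   1-based coordinates of the aligned region).
#' @export
local_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align empty sequences")
  r <- cpp_align(a, b, "local", params$match, params$mismatch,
                 params$gap_open, params$gap_extend)
  alignment_result(r$aligned_a, r$aligned_b, r$score, nchar(a), nchar(b),
                   r$start_a, r$end_a, r$start_b, r$end_b)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("alignment: score=%.1f identity=%.3f len=%d cov_a=%.2f cov_b=%.2f\n",
              x$score, x$identity, x$alignment_length, x$coverage_a, x$coverage_b))
  if (nchar(x$aligned_a) <= 80) {
    cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  }
  invisible(x)
}

#' Pairwise identity between two sequences (global alignment convention)
#' @inheritParams global_align
#' @return Identity fraction in [0, 1].
#' @export
pairwise_identity <- function(a, b, params = align_params()) {
  global_align(a, b, params)$identity
}
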