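#' Create an empty per-stage QC ledger
#'
#' The ledger records, for every pipeline stage, how many reads went in, how
#' many came out and how many were discarded for each reason, so that read
#' conservation (in == out + discards) can be asserted on every run.
#'
#' @return A `qc_ledger` object.
#' @export
new_ledger <- function() {
  structure(list(stages = list()), class = "qc_ledger")
}

#' Add a stage entry to a QC ledger
#'
#' @param ledger A `qc_ledger`.
#' @param stage Stage name.
#' @param n_in Reads entering the stage.
#' @param n_out Reads leaving the stage.
#' @param discards Named integer vector of discard counts by reason.
#' @return The updated ledger. Errors if `n_in != n_out + sum(discards)`.
#' @export
ledger_add <- function(ledger, stage, n_in, n_out, discards = c()) {
  stopifnot(inherits(ledger, "qc_ledger"))
  if (any(c(n_in, n_out, discards) < 0)) stop("ledger counts must be non-negative")
  if (n_in != n_out + sum(discards)) {
    stop(sprintf("ledger conservation violated at stage '%s': %d != %d + %d",
                 stage, n_in, n_out, sum(discards)))
  }
  ledger$stages[[stage]] <- list(n_in = as.integer(n_in), n_out = as.integer(n_out),
                                 discards = discards)
  ledger
}

#' @export
print.qc_ledger <- function(x, ...) {
  cat("QC ledger\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    dsc <- if (length(s$discards)) {
      paste0(" (", paste(names(s$discards), s$discards, sep = "=", collapse = ", "), ")")
    } else ""
    cat(sprintf("  %-20s in=%d out=%d%s\n", nm, s$n_in, s$n_out, dsc))
  }
  invisible(x)
}

#' Convert a ledger to a data frame (for TSV export)
#' @param ledger A `qc_ledger`.
#' @return Data frame with columns `stage`, `n_in`, `n_out`, `n_discarded`.
#' @export
ledger_table <- function(ledger) {
  do.call(rbind, lapply(names(ledger$stages), function(nm) {
    s <- ledger$stages[[nm]]
    data.frame(stage = nm, n_in = s$n_in, n_out = s$n_out,
               n_discarded = s$n_in - s$n_out, stringsAsFactors = FALSE)
  }))
}

parse_index_pair <- function(ids) {
  m <- regmatches(ids, regexpr("[ACGTN]+\\+[ACGTN]+$", ids))
  out <- rep(NA_character_, length(ids))
  has <- grepl("[ACGTN]+\\+[ACGTN]+$", ids)
  out[has] <- regmatches(ids[has], regexpr("[ACGTN]+\\+[ACGTN]+$", ids[has]))
  out
}

#' Demultiplex read pairs by exact dual-index match
#'
#' Each read pair carries an `i7+i5` index annotation at the end of its
#' forward-read header. Pairs whose index combination exactly equals a
#' declared sample's index pair are assigned to that sample; everything else
#' (including single-base index mismatches) is discarded. No index error
#' correction is attempted.
#'
#' @param fwd,rev Read tables (see [read_fastq()]); row i of `fwd` is mated
#'   with row i of `rev`.
#' @param samples Sample metadata data frame with `sample_id`, `i7`, `i5`.
#' @return A list with `by_sample` (named list of `list(fwd=, rev=)`),
#'   `n_assigned` (named integer vector) and `n_discarded`.
#' @export
demultiplex <- function(fwd, rev, samples) {
  if (nrow(fwd) != nrow(rev)) stop("forward and reverse read tables differ in length")
  key <- paste(samples$i7, samples$i5, sep = "+")
  if (anyDuplicated(key)) stop("duplicate index pairs in metadata")
  obs <- parse_index_pair(fwd$id)
  hit <- match(obs, key)
  by_sample <- lapply(seq_along(key), function(k) {
    rows <- which(!is.na(hit) & hit == k)
    list(fwd = fwd[rows, , drop = FALSE], rev = rev[rows, , drop = FALSE])
  })
  names(by_sample) <- samples$sample_id
  n_assigned <- vapply(by_sample, function(p) nrow(p$fwd), integer(1))
  list(by_sample = by_sample, n_assigned = n_assigned,
       n_discarded = nrow(fwd) - sum(n_assigned))
}

#' Truncate reads before the first low-quality base
#'
#' Mirrors the USEARCH `fastq_truncqual` behaviour: each read is truncated
#' immediately before its first base with quality < `qmin`. A read whose
#' first base is low-quality becomes empty.
#'
#' @param reads Read table with `seq` and `qual` (Phred+33).
#' @param qmin Minimum quality; default 3.
#' @return The read table with truncated `seq`/`qual`.
#' @export
truncate_at_low_quality <- function(reads, qmin = 3) {
  stopifnot(qmin >= 0)
  if (nrow(reads) == 0) return(reads)
  tr <- cpp_truncate_at_q(reads$seq, reads$qual, as.integer(qmin))
  reads$seq <- tr$seq
  reads$qual <- tr$qual
  reads
}

#' Merge forward/reverse read pairs over their best ungapped overlap
#'
#' The reverse read is reverse-complemented, then all ungapped overlap offsets
#' are scanned. The best overlap of length >= `min_overlap` with mismatch
#' fraction <= `max_mismatch_frac` (lowest mismatch fraction, ties to the
#' longer overlap) yields the merged consensus: at overlap mismatches the
#' higher-quality base wins (quality ties keep the forward base) and the
#' consensus quality is the maximum of the two. Pairs with no acceptable
#' overlap are reported as merge failures, not errors.
#'
#' @param fwd,rev Read tables; row-mated.
#' @param min_overlap Minimum overlap length (default 16).
#' @param max_mismatch_frac Maximum mismatch fraction in the overlap
#'   (default 0.25).
#' @return A list with `merged` (read table of successfully merged reads) and
#'   `n_failed`.
#' @export
merge_read_pairs <- function(fwd, rev, min_overlap = 16, max_mismatch_frac = 0.25) {
  if (nrow(fwd) != nrow(rev)) stop("forward and reverse read tables differ in length")
  if (nrow(fwd) == 0) {
    return(list(merged = fwd[0, c("id", "seq", "qual")], n_failed = 0L))
  }
  rev_rc <- reverse_complement(rev$seq)
  rq <- reverse_string(rev$qual)
  res <- cpp_merge_pairs(fwd$seq, fwd$qual, rev_rc, rq,
                         as.integer(min_overlap), max_mismatch_frac)
  ok <- res$merged
  merged <- data.frame(id = fwd$id[ok], seq = res$seq[ok], qual = res$qual[ok],
                       stringsAsFactors = FALSE)
  list(merged = merged, n_failed = sum(!ok))
}

#' Quality-filter merged reads
#'
#' Discards reads that (i) contain any non-ACGT base, (ii) are shorter than
#' `min_len` nucleotides (strictly less than), or (iii) align locally to a
#' contaminant reference over >= `contam_min_len` columns at >=
#' `contam_min_id` identity (a tool-independent stand-in for a PhiX mapping
#' screen). Checks are applied in that order; each read gets at most one
#' discard reason.
#'
#' @param reads Read table.
#' @param min_len Minimum length (default 50).
#' @param contaminants Optional named character vector of contaminant
#'   sequences.
#' @param contam_min_len,contam_min_id Contaminant-screen thresholds
#'   (defaults 60 nt, 0.90).
#' @param params Alignment parameters for the contaminant screen.
#' @return A list with `kept` (read table), and `n_ambiguous`, `n_short`,
#'   `n_contaminant` discard counts.
#' @export
quality_filter <- function(reads, min_len = 50, contaminants = NULL,
                           contam_min_len = 60, contam_min_id = 0.90,
                           params = align_params()) {
  ambiguous <- grepl("[^ACGT]", reads$seq)
  short <- !ambiguous & nchar(reads$seq) < min_len
  contaminant <- rep(FALSE, nrow(reads))
  if (!is.null(contaminants) && length(contaminants) > 0) {
    check <- which(!ambiguous & !short)
    for (i in check) {
      for (ref in contaminants) {
        al <- local_align(reads$seq[i], ref, params)
        if (al$alignment_length >= contam_min_len && al$identity >= contam_min_id) {
          contaminant[i] <- TRUE
          break
        }
      }
    }
  }
  keep <- !ambiguous & !short & !contaminant
  list(kept = reads[keep, , drop = FALSE],
       n_ambiguous = sum(ambiguous), n_short = sum(short),
       n_contaminant = sum(contaminant))
}

#' Trim an anchored primer allowing IUPAC-aware mismatches
#'
#' The primer (which may contain IUPAC ambiguity codes; an ambiguity code
#' matches any base in its set) is matched at the 5' end of each read, or --
#' for `end = "3p"` -- its reverse complement is matched at the 3' end. If it
#' matches with at most `max_mismatches` mismatches the matched span is
#' removed; otherwise the read is reported untrimmed.
#'
#' @param reads Read table.
#' @param primer IUPAC primer string (5'->3' as synthesised).
#' @param max_mismatches Maximum mismatches (default 4).
#' @param end `"5p"` (default) or `"3p"`.
#' @return A list with `reads` (trimmed table including untrimmed reads),
#'   `trimmed` (logical vector).
#' @export
trim_primer <- function(reads, primer, max_mismatches = 4, end = c("5p", "3p")) {
  end <- match.arg(end)
  if (!nzchar(primer)) stop("empty primer")
  if (nrow(reads) == 0) return(list(reads = reads, trimmed = logical(0)))
  probe <- if (end == "5p") primer else reverse_complement(primer)
  mm <- cpp_iupac_anchor_mismatch(reads$seq, probe, end == "3p")
  trimmed <- !is.na(mm) & mm <= max_mismatches
  p <- nchar(probe)
  if (end == "5p") {
    reads$seq[trimmed] <- substring(reads$seq[trimmed], p + 1)
    reads$qual[trimmed] <- substring(reads$qual[trimmed], p + 1)
  } else {
    l <- nchar(reads$seq[trimmed])
    reads$seq[trimmed] <- substring(reads$seq[trimmed], 1, l - p)
    reads$qual[trimmed] <- substring(reads$qual[trimmed], 1, l - p)
  }
  list(reads = reads, trimmed = trimmed)
}

#' Dereplicate reads into phylotypes
#'
#' Collapses exactly identical sequences (full-length, exact string identity)
#' into phylotypes with per-sample counts, the study's finest unit of
#' analysis. Output is sorted by total count descending, ties broken by
#' sequence lexicographic order (C locale), which fixes the input order of
#' downstream greedy clustering.
#'
#' @param reads_by_sample Named list (sample_id -> character vector of
#'   sequences).
#' @return A `phylotype_set`: list with `tab` (data frame `phylotype_id`,
#'   `sequence`, `total_count`) and `counts` (phylotype x sample integer
#'   matrix).
#' @export
dereplicate <- function(reads_by_sample) {
  samples <- names(reads_by_sample)
  if (is.null(samples) || anyDuplicated(samples)) {
    stop("reads_by_sample must be a uniquely named list")
  }
  all_seq <- unlist(reads_by_sample, use.names = FALSE)
  if (length(all_seq) == 0) {
    return(empty_phylotype_set(samples))
  }
  if (any(grepl("[^ACGT]", all_seq))) stop("phylotype sequences must be unambiguous ACGT")
  sample_of <- rep(samples, vapply(reads_by_sample, length, integer(1)))
  uniq <- sort(unique(all_seq), method = "radix")
  idx <- match(all_seq, uniq)
  counts <- matrix(0L, nrow = length(uniq), ncol = length(samples),
                   dimnames = list(NULL, samples))
  tab2 <- table(factor(idx, levels = seq_along(uniq)),
                factor(sample_of, levels = samples))
  counts[] <- as.integer(tab2)
  total <- as.integer(rowSums(counts))
  ord <- order(-total, uniq, method = "radix")
  uniq <- uniq[ord]
  counts <- counts[ord, , drop = FALSE]
  total <- total[ord]
  ids <- sprintf("pt%05d", seq_along(uniq))
  rownames(counts) <- ids
  structure(list(
    tab = data.frame(phylotype_id = ids, sequence = uniq, total_count = total,
                     stringsAsFactors = FALSE),
    counts = counts
  ), class = "phylotype_set")
}

empty_phylotype_set <- function(samples) {
  structure(list(
    tab = data.frame(phylotype_id = character(0), sequence = character(0),
                     total_count = integer(0), stringsAsFactors = FALSE),
    counts = matrix(0L, nrow = 0, ncol = length(samples),
                    dimnames = list(NULL, samples))
  ), class = "phylotype_set")
}

#' @export
print.phylotype_set <- function(x, ...) {
  cat(sprintf("phylotype_set: %d phylotypes, %d samples, %d reads\n",
              nrow(x$tab), ncol(x$counts), sum(x$tab$total_count)))
  invisible(x)
}

#' Subset a phylotype set by row indices or phylotype ids
#' @param pset A `phylotype_set`.
#' @param which Integer/logical indices or character phylotype ids to keep.
#' @return The subset `phylotype_set` (sort order preserved).
#' @export
subset_phylotypes <- function(pset, which) {
  if (is.character(which)) which <- match(which, pset$tab$phylotype_id)
  structure(list(tab = pset$tab[which, , drop = FALSE],
                 counts = pset$counts[which, , drop = FALSE]),
            class = "phylotype_set")
}

#' Remove singleton phylotypes
#'
#' Drops phylotypes whose total count across all samples is exactly 1, as
#' these cannot be distinguished from sequencing error.
#'
#' @param pset A `phylotype_set`.
#' @return A list with `pset` (filtered) and `n_removed`.
#' @export
remove_singletons <- function(pset) {
  keep <- pset$tab$total_count > 1
  list(pset = subset_phylotypes(pset, keep), n_removed = sum(!keep))
}
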