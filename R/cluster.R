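#' Greedy centroid clustering of phylotypes into OTUs
#'
#' UCLUST-style greedy clustering: phylotypes are scanned in
#' abundance-descending order (ties lexicographic, as fixed by
#' [dereplicate()]); each phylotype joins the first existing centroid -- in
#' centroid-creation order -- with identity > `id_threshold` and both
#' coverages > `cov_threshold`, and otherwise founds a new centroid.
#'
#' A Hamming screen accelerates the scan for equal-length sequences: under
#' the default scoring (gap open 10, extend 1, mismatch -2) the optimal
#' global alignment of two equal-length sequences that differ by at most a
#' few percent is gapless, so the Hamming identity equals the alignment
#' identity. Full alignments are still computed for unequal lengths and for
#' identities within `hamming_slack` of the threshold, so the assignment is
#' the one the alignment criterion defines.
#'
#' @param tab Data frame with `phylotype_id`, `sequence`, `total_count`,
#'   sorted abundance-descending (ties lexicographic).
#' @param id_threshold Identity threshold; members require identity strictly
#'   greater (default 0.98).
#' @param cov_threshold Coverage threshold for both sequences, strict
#'   (default 0.80).
#' @param params [align_params()].
#' @param hamming_slack Band around the threshold inside which the Hamming
#'   screen defers to a full alignment (default 0.02).
#' @return A list of OTUs, each `list(otu_id, centroid, members, threshold)`,
#'   in centroid-creation order.
#' @export
greedy_cluster <- function(tab, id_threshold = 0.98, cov_threshold = 0.80,
                           params = align_params(), hamming_slack = 0.02) {
  n <- nrow(tab)
  if (n == 0) return(list())
  ord <- order(-tab$total_count, tab$sequence, method = "radix")
  if (!identical(ord, seq_len(n))) {
    stop("input must be sorted by abundance descending, ties lexicographic")
  }
  cent_seq <- character(0)
  cent_id <- character(0)
  members <- list()
  for (i in seq_len(n)) {
    q <- tab$sequence[i]
    assigned <- 0L
    if (length(cent_seq) > 0) {
      ham <- cpp_hamming_identity(q, cent_seq)
      for (k in seq_along(cent_seq)) {
        h <- ham[k]
        if (!is.na(h) && h > id_threshold) {
          # equal length, gapless-optimal regime: identity == h, coverage 1
          assigned <- k
          break
        }
        if (is.na(h) || h > id_threshold - hamming_slack) {
          al <- global_align(q, cent_seq[k], params)
          if (al$identity > id_threshold &&
              al$coverage_a > cov_threshold && al$coverage_b > cov_threshold) {
            assigned <- k
            break
          }
        }
      }
    }
    if (assigned > 0) {
      members[[assigned]] <- c(members[[assigned]], tab$phylotype_id[i])
    } else {
      cent_seq <- c(cent_seq, q)
      cent_id <- c(cent_id, tab$phylotype_id[i])
      members[[length(cent_seq)]] <- tab$phylotype_id[i]
    }
  }
  lapply(seq_along(cent_id), function(k) {
    list(otu_id = sprintf("otu%04d", k), centroid = cent_id[k],
         members = members[[k]], threshold = id_threshold)
  })
}

#' Furthest-neighbour (complete-linkage) clustering at an identity threshold
#'
#' Complete-linkage agglomeration on distance `1 - identity`: merging stops
#' as soon as any would-be cluster would contain a pair with identity below
#' `id_threshold`, so every final cluster carries a minimum-pairwise-identity
#' certificate. Inputs are ordered lexicographically by label before
#' agglomeration so merge order is deterministic.
#'
#' @param seqs Named character vector of sequences.
#' @param id_threshold Minimum within-cluster pairwise identity
#'   (default 0.99).
#' @param params [align_params()].
#' @return A list of character vectors of labels (clusters), ordered by their
#'   first label.
#' @export
furthest_neighbour_cluster <- function(seqs, id_threshold = 0.99,
                                       params = align_params()) {
  n <- length(seqs)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must be uniquely named")
  }
  seqs <- seqs[order(names(seqs), method = "radix")]
  if (n == 1) return(list(names(seqs)))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      id <- pairwise_identity(seqs[[i]], seqs[[j]], params)
      d[i, j] <- d[j, i] <- 1 - id
    }
  }
  hc <- hclust(as.dist(d), method = "complete")
  grp <- cutree(hc, h = 1 - id_threshold + 1e-12)
  out <- split(names(seqs), grp)
  names(out) <- NULL
  out[order(vapply(out, function(x) x[1], character(1)), method = "radix")]
}

#' Sum phylotype counts into OTU-level counts
#'
#' Every phylotype maps to exactly one OTU; OTU counts are the per-sample
#' sums of member phylotype counts, so column (sample) totals are conserved.
#'
#' @param pset A `phylotype_set` with chimeras and singletons already removed.
#' @param id_threshold,cov_threshold,params Passed to [greedy_cluster()].
#' @return A list with `otus` (see [greedy_cluster()]), `otu_counts`
#'   (OTU x sample matrix), and `otu_of` (named map phylotype_id -> otu_id).
#' @export
cluster_phylotypes_to_otus <- function(pset, id_threshold = 0.98,
                                       cov_threshold = 0.80,
                                       params = align_params()) {
  otus <- greedy_cluster(pset$tab, id_threshold, cov_threshold, params)
  if (length(otus) == 0) {
    return(list(otus = otus,
                otu_counts = matrix(0L, 0, ncol(pset$counts),
                                    dimnames = list(NULL, colnames(pset$counts))),
                otu_of = setNames(character(0), character(0))))
  }
  otu_of <- unlist(lapply(otus, function(o) setNames(rep(o$otu_id, length(o$members)),
                                                     o$members)))
  f <- factor(otu_of[pset$tab$phylotype_id],
              levels = vapply(otus, `[[`, character(1), "otu_id"))
  otu_counts <- rowsum(pset$counts, f)
  storage.mode(otu_counts) <- "integer"
  list(otus = otus, otu_counts = otu_counts, otu_of = otu_of)
}
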