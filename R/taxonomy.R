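#' Karlin-Altschul style E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with ungapped nucleotide constants for
#' +1/-2 scoring declared as defaults. Only the threshold gate matters for
#' the assignment logic; the constants are declared, not fitted.
#'
#' @param score Alignment score S.
#' @param query_len,db_len Effective query length m and database length n.
#' @param lambda,K Karlin-Altschul constants (defaults 1.28, 0.46).
#' @return The E-value (monotone decreasing in `score`, linear in both
#'   lengths).
#' @export
evalue <- function(score, query_len, db_len, lambda = 1.28, K = 0.46) {
  stopifnot(query_len > 0, db_len > 0)
  K * query_len * db_len * exp(-lambda * score)
}

#' Build a reference record table
#'
#' @param ref_id,sequence,marker,group_label Equal-length vectors; `marker`
#'   is `"ITS2"` or `"18S"`.
#' @return A data frame of reference records.
#' @export
reference_records <- function(ref_id, sequence, marker, group_label) {
  stopifnot(all(marker %in% c("ITS2", "18S")), all(nzchar(sequence)),
            all(nzchar(group_label)))
  data.frame(ref_id = ref_id, sequence = sequence, marker = marker,
             group_label = group_label, stringsAsFactors = FALSE)
}

#' Assign taxonomy to a query by best local alignment against a reference set
#'
#' BLAST-like threshold logic: the best reference is the top local-alignment
#' scorer (ties: lowest E-value, then lexicographic `ref_id`); the query is
#' assigned iff E-value < `max_evalue` AND identity > `min_identity` AND
#' alignment length (aligned columns, including gap columns) is strictly
#' greater than the marker-specific minimum (200 for ITS2, 150 for 18S).
#'
#' @param query_seq Query sequence.
#' @param db Reference data frame (see [reference_records()]).
#' @param marker `"ITS2"` (default) or `"18S"`; selects the alignment-length
#'   gate and restricts the database to that marker.
#' @param query_id Optional id recorded in the result.
#' @param max_evalue,min_identity E-value and identity gates (defaults 1e-8,
#'   0.90).
#' @param min_alen Alignment length gate; default 200 (ITS2) or 150 (18S).
#' @param params [align_params()].
#' @return A one-row data frame: `query_id`, `best_ref`, `evalue`,
#'   `identity`, `alignment_length`, `assigned`, `group_label` (or
#'   `"unassigned"`).
#' @export
assign_taxonomy <- function(query_seq, db, marker = c("ITS2", "18S"),
                            query_id = "query", max_evalue = 1e-8,
                            min_identity = 0.90, min_alen = NULL,
                            params = align_params()) {
  marker <- match.arg(marker)
  db <- db[db$marker == marker, , drop = FALSE]
  if (nrow(db) == 0) stop("empty reference database for marker ", marker)
  if (is.null(min_alen)) min_alen <- if (marker == "ITS2") 200 else 150
  db_len <- sum(nchar(db$sequence))
  res <- lapply(db$sequence, function(ref) local_align(query_seq, ref, params))
  scores <- vapply(res, `[[`, numeric(1), "score")
  evals <- evalue(scores, nchar(query_seq), db_len)
  ord <- order(-scores, evals, db$ref_id, method = "radix")
  best <- ord[1]
  al <- res[[best]]
  assigned <- evals[best] < max_evalue && al$identity > min_identity &&
    al$alignment_length > min_alen
  data.frame(query_id = query_id,
             best_ref = db$ref_id[best],
             evalue = evals[best],
             identity = al$identity,
             alignment_length = al$alignment_length,
             assigned = assigned,
             group_label = if (assigned) db$group_label[best] else "unassigned",
             stringsAsFactors = FALSE)
}

#' Assign taxonomy to many queries
#'
#' @param query_seqs Named character vector of query sequences.
#' @inheritParams assign_taxonomy
#' @return A data frame, one row per query (see [assign_taxonomy()]).
#' @export
assign_taxonomy_all <- function(query_seqs, db, marker = "ITS2", ...) {
  out <- lapply(seq_along(query_seqs), function(i) {
    assign_taxonomy(query_seqs[[i]], db, marker,
                    query_id = names(query_seqs)[i], ...)
  })
  do.call(rbind, out)
}

#' Build an in-house ITS2 reference database from long 18S-ITS2 reads
#'
#' Extracts the ITS2 interval of each long (Sanger-style) sequence between
#' user-supplied flanking motifs, clusters the extracted ITS2 sequences at
#' 99% identity with the furthest-neighbour algorithm *within each sample*,
#' and emits one representative per cluster (the longest sequence, ties by
#' lexicographic order) with its group label. Sequences lacking a flanking
#' motif are skipped with a warning.
#'
#' @param long_seqs Named character vector of 18S-ITS2 sequences.
#' @param sample_of Named character vector: sample label per sequence id.
#' @param group_of Named character vector: group label per sequence id.
#' @param flank5,flank3 Flanking motifs (exact match); the ITS2 interval is
#'   the span strictly between them. `NULL` keeps the full sequence.
#' @param id_threshold Furthest-neighbour identity level (default 0.99).
#' @param params [align_params()].
#' @return A reference data frame (see [reference_records()]), marker
#'   `"ITS2"`.
#' @export
build_reference_db <- function(long_seqs, sample_of, group_of,
                               flank5 = NULL, flank3 = NULL,
                               id_threshold = 0.99, params = align_params()) {
  if (length(long_seqs) == 0) {
    return(reference_records(character(0), character(0), character(0),
                             character(0)))
  }
  its2 <- vapply(names(long_seqs), function(id) {
    extract_its2(long_seqs[[id]], flank5, flank3)
  }, character(1))
  missing <- is.na(its2)
  if (any(missing)) {
    warning("flanking motif not found in: ",
            paste(names(long_seqs)[missing], collapse = ", "))
    its2 <- its2[!missing]
  }
  recs <- list()
  for (s in unique(sample_of[names(its2)])) {
    ids <- names(its2)[sample_of[names(its2)] == s]
    clusters <- furthest_neighbour_cluster(its2[ids], id_threshold, params)
    for (cl in clusters) {
      lens <- nchar(its2[cl])
      rep_id <- cl[order(-lens, its2[cl], method = "radix")][1]
      recs[[length(recs) + 1]] <- data.frame(
        ref_id = rep_id, sequence = unname(its2[rep_id]), marker = "ITS2",
        group_label = unname(group_of[rep_id]), stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0) {
    return(reference_records(character(0), character(0), character(0),
                             character(0)))
  }
  do.call(rbind, recs)
}

#' Extract the ITS2 interval between flanking motifs
#'
#' @param seq Sequence string.
#' @param flank5,flank3 Exact flanking motifs; `NULL` means no bound on that
#'   side.
#' @return The ITS2 substring, or `NA` if a requested motif is absent.
#' @export
extract_its2 <- function(seq, flank5 = NULL, flank3 = NULL) {
  start <- 1L
  end <- nchar(seq)
  if (!is.null(flank5)) {
    m <- regexpr(flank5, seq, fixed = TRUE)
    if (m == -1) return(NA_character_)
    start <- m + attr(m, "match.length")
  }
  if (!is.null(flank3)) {
    m <- regexpr(flank3, seq, fixed = TRUE)
    if (m == -1) return(NA_character_)
    end <- m - 1L
  }
  if (start > end) return(NA_character_)
  substr(seq, start, end)
}
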