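#' De novo two-parent chimera detection for a single phylotype
#'
#' A simplified two-segment chimera model with the de novo abundance-skew
#' logic of UCHIME-style screens: candidate parents are restricted to
#' phylotypes at least `min_skew` times more abundant than the query (PCR
#' chimeras are rarer than their templates). For every ordered parent pair
#' and every crossover position, the model identity is the fraction of query
#' positions explained by parent A up to the crossover and parent B after it
#' (per-position matches taken from global alignments of the query to each
#' parent). The query is flagged as chimeric iff the best two-parent model
#' beats the best single parent by at least `min_gain`.
#'
#' @param query_id Phylotype id of the query.
#' @param pset A `phylotype_set` containing the query and candidates.
#' @param min_skew Abundance skew: candidates need
#'   `total_count >= min_skew * query count` (default 2).
#' @param min_gain Minimum identity gain of the chimera model over the best
#'   single parent (default 0.02).
#' @param params [align_params()].
#' @param max_parents Cap on the number of (most abundant) candidate parents
#'   examined (default 40).
#' @param max_model_parents Pair models are searched among this many
#'   candidates with the highest single-parent identity (default 12); true
#'   parents of a chimera are among the best single matches by construction.
#' @param min_model_id Minimum model identity for a chimera call (default
#'   0.9): a real PCR chimera is explained almost perfectly by its two
#'   parents, whereas unrelated sequences admit weak two-segment models that
#'   would otherwise out-gain their (equally weak) best single parent.
#' @return A `chimera_verdict`: list with `query`, `is_chimera`, `parent_a`,
#'   `parent_b`, `crossover` (last query position taken from parent A),
#'   `id_model`, `id_best_single`.
#' @export
detect_chimera_denovo <- function(query_id, pset, min_skew = 2.0, min_gain = 0.02,
                                  params = align_params(), max_parents = 40,
                                  max_model_parents = 12, min_model_id = 0.9) {
  tab <- pset$tab
  qi <- match(query_id, tab$phylotype_id)
  if (is.na(qi)) stop("unknown query phylotype: ", query_id)
  qcount <- tab$total_count[qi]
  cand <- which(tab$total_count >= min_skew * qcount & seq_len(nrow(tab)) != qi)
  verdict <- function(is_chim, pa = NA_character_, pb = NA_character_,
                      cross = NA_integer_, idm = NA_real_, ids = NA_real_) {
    structure(list(query = query_id, is_chimera = is_chim, parent_a = pa,
                   parent_b = pb, crossover = cross, id_model = idm,
                   id_best_single = ids), class = "chimera_verdict")
  }
  if (length(cand) < 2) return(verdict(FALSE))
  q <- tab$sequence[qi]
  Lq <- nchar(q)
  # Hamming prescreen over the full candidate set: if some candidate already
  # explains the query to within min_gain of perfection, no two-parent model
  # can gain enough to flag.
  ham <- cpp_hamming_identity(q, tab$sequence[cand])
  if (any(!is.na(ham) & ham > 1 - min_gain)) {
    return(verdict(FALSE, ids = max(ham, na.rm = TRUE)))
  }
  if (length(cand) > max_parents) {
    cand <- cand[order(-tab$total_count[cand], tab$sequence[cand],
                       method = "radix")][seq_len(max_parents)]
  }
  qraw <- charToRaw(q)
  profiles <- lapply(cand, function(k) {
    ck <- tab$sequence[k]
    if (nchar(ck) == Lq) {
      # equal lengths: with substitution-dominated divergence the optimal
      # alignment is gapless, so the per-position profile is direct
      as.logical(charToRaw(ck) == qraw)
    } else {
      al <- global_align(q, ck, params)
      as.logical(cpp_match_profile(al$aligned_a, al$aligned_b))
    }
  })
  singles <- vapply(profiles, mean, numeric(1))
  id_best_single <- max(singles)
  model_set <- order(-singles)[seq_len(min(length(cand), max_model_parents))]
  best_model <- -Inf
  best_pair <- c(NA_integer_, NA_integer_)
  best_cross <- NA_integer_
  for (ai in model_set) {
    for (bi in model_set) {
      if (ai == bi) next
      diffcum <- cumsum(as.integer(profiles[[ai]]) - as.integer(profiles[[bi]]))
      totB <- sum(profiles[[bi]])
      # crossover k in 0..Lq: matches = totB + diffcum[k] (diffcum[0] = 0)
      scores <- c(totB, totB + diffcum)
      k <- which.max(scores) - 1L
      m <- scores[k + 1L] / Lq
      if (m > best_model + 1e-12) {
        best_model <- m
        best_pair <- c(ai, bi)
        best_cross <- k
      }
    }
  }
  is_chim <- best_model >= id_best_single + min_gain &&
    best_model > id_best_single && best_model >= min_model_id
  if (is_chim) {
    verdict(TRUE, tab$phylotype_id[cand[best_pair[1]]],
            tab$phylotype_id[cand[best_pair[2]]], best_cross,
            best_model, id_best_single)
  } else {
    verdict(FALSE, idm = if (is.finite(best_model)) best_model else NA_real_,
            ids = id_best_single)
  }
}

#' @export
print.chimera_verdict <- function(x, ...) {
  cat(sprintf("chimera_verdict %s: %s (id_model=%.3f, id_best_single=%.3f)\n",
              x$query, if (isTRUE(x$is_chimera)) "CHIMERA" else "ok",
              x$id_model, x$id_best_single))
  invisible(x)
}

#' Screen a whole phylotype set for de novo chimeras
#'
#' Runs the single-query detector over every phylotype and removes flagged
#' ones. A vectorised Hamming prescreen against the most abundant phylotypes
#' skips queries whose best single-parent identity already exceeds
#' `1 - min_gain` (such queries can never be flagged), so full alignment
#' work is spent only on divergent queries.
#'
#' @inheritParams detect_chimera_denovo
#' @param pset A `phylotype_set`.
#' @param screen_parents Number of most abundant phylotypes used in the
#'   vectorised prescreen (default 200); queries passing it are never
#'   aligned.
#' @return A list with `pset` (chimera-free), `verdicts` (list of
#'   `chimera_verdict` for flagged queries), `n_flagged`.
#' @export
screen_chimeras <- function(pset, min_skew = 2.0, min_gain = 0.02,
                            params = align_params(), max_parents = 40,
                            max_model_parents = 12, min_model_id = 0.9,
                            screen_parents = 200) {
  tab <- pset$tab
  n <- nrow(tab)
  if (n == 0) return(list(pset = pset, verdicts = list(), n_flagged = 0L))
  counts <- tab$total_count  # sorted descending by construction
  screen_idx <- seq_len(min(n, max(screen_parents, max_parents)))
  ham <- cpp_hamming_matrix(tab$sequence, tab$sequence[screen_idx])
  asc <- rev(counts)
  flagged <- logical(n)
  verdicts <- list()
  for (i in seq_len(n)) {
    thr <- min_skew * counts[i]
    n_ge <- n - findInterval(thr - 1e-9, asc)   # candidates incl. possibly self
    eligible <- screen_idx[counts[screen_idx] >= thr & screen_idx != i]
    n_cand <- n_ge - as.integer(counts[i] >= thr)
    if (n_cand < 2) next
    h <- ham[i, match(eligible, screen_idx)]
    if (length(eligible) > 0 && any(!is.na(h) & h > 1 - min_gain)) next
    v <- detect_chimera_denovo(tab$phylotype_id[i], pset, min_skew, min_gain,
                               params, max_parents, max_model_parents,
                               min_model_id)
    if (isTRUE(v$is_chimera)) {
      flagged[i] <- TRUE
      verdicts[[length(verdicts) + 1]] <- v
    }
  }
  list(pset = subset_phylotypes(pset, !flagged), verdicts = verdicts,
       n_flagged = sum(flagged))
}

#' Tabulate chimera verdicts
#' @param verdicts List of `chimera_verdict`s.
#' @return A data frame (one row per verdict).
#' @export
chimera_report <- function(verdicts) {
  if (length(verdicts) == 0) {
    return(data.frame(query = character(0), is_chimera = logical(0),
                      parent_a = character(0), parent_b = character(0),
                      crossover = integer(0), id_model = numeric(0),
                      id_best_single = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(verdicts, function(v) {
    data.frame(query = v$query, is_chimera = v$is_chimera,
               parent_a = v$parent_a, parent_b = v$parent_b,
               crossover = v$crossover, id_model = v$id_model,
               id_best_single = v$id_best_single, stringsAsFactors = FALSE)
  }))
}
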