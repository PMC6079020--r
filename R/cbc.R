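#' Detect compensatory base changes between two structures
#'
#' For every aligned column pair that is base-paired in BOTH structures (the
#' two partners of the pair must also be aligned to each other), the pair is
#' a CBC if both nucleotides differ between the two sequences while both
#' pairings remain canonical (AU/GC/GU; GU counts as canonical), and a
#' hemi-CBC if exactly one nucleotide differs with canonical pairing
#' retained.
#'
#' @param a,b `its2_structure` objects.
#' @param alignment Optional `alignment_result` of the two sequences (RNA/DNA
#'   indifferent); defaults to a fresh [global_align()].
#' @param window Optional integer vector of positions in `a` (sequence
#'   coordinates) defining the species-delimitation window; defaults to
#'   [delimitation_window()] of `a`.
#' @param params [align_params()] when the alignment is computed here.
#' @return A `cbc_report`: list with `cbc` / `hemi_cbc` (two-column matrices
#'   of positions in `a`, 5' partner first), `cbc_in_delimitation_window`
#'   (count), `same_species` (`cbc_in_delimitation_window == 0`).
#' @export
detect_cbc <- function(a, b, alignment = NULL, window = NULL,
                       params = align_params()) {
  if (is.null(alignment)) {
    alignment <- global_align(chartr("U", "T", a$sequence),
                              chartr("U", "T", b$sequence), params)
  }
  ca <- strsplit(chartr("T", "U", alignment$aligned_a), "", fixed = TRUE)[[1]]
  cb <- strsplit(chartr("T", "U", alignment$aligned_b), "", fixed = TRUE)[[1]]
  if (sum(ca != "-") != nchar(a$sequence) || sum(cb != "-") != nchar(b$sequence)) {
    stop("alignment inconsistent with sequence lengths")
  }
  # column -> position maps
  pos_a <- cumsum(ca != "-"); pos_a[ca == "-"] <- NA
  pos_b <- cumsum(cb != "-"); pos_b[cb == "-"] <- NA
  col_of_a <- match(seq_len(nchar(a$sequence)), pos_a)
  bases_a <- strsplit(a$sequence, "", fixed = TRUE)[[1]]
  bases_b <- strsplit(b$sequence, "", fixed = TRUE)[[1]]
  if (is.null(window)) window <- delimitation_window(a)
  cbc <- matrix(integer(0), ncol = 2)
  hemi <- matrix(integer(0), ncol = 2)
  pa <- a$pairs
  for (i in which(!is.na(pa) & pa > seq_along(pa))) {
    j <- pa[i]
    ci <- col_of_a[i]; cj <- col_of_a[j]
    bi <- pos_b[ci]; bj <- pos_b[cj]
    if (is.na(bi) || is.na(bj)) next
    if (is.na(b$pairs[bi]) || b$pairs[bi] != bj) next  # must be paired in b too
    na1 <- bases_a[i]; na2 <- bases_a[j]
    nb1 <- bases_b[bi]; nb2 <- bases_b[bj]
    if (!is_canonical_pair(nb1, nb2)) next
    ndiff <- (na1 != nb1) + (na2 != nb2)
    if (ndiff == 2) cbc <- rbind(cbc, c(i, j))
    if (ndiff == 1) hemi <- rbind(hemi, c(i, j))
  }
  n_win <- if (nrow(cbc) == 0) 0L else {
    sum(apply(cbc, 1, function(p) any(p %in% window)))
  }
  structure(list(cbc = cbc, hemi_cbc = hemi,
                 cbc_in_delimitation_window = as.integer(n_win),
                 same_species = n_win == 0L),
            class = "cbc_report")
}

#' @export
print.cbc_report <- function(x, ...) {
  cat(sprintf("cbc_report: %d CBC (%d in window), %d hemi-CBC -> %s\n",
              nrow(x$cbc), x$cbc_in_delimitation_window, nrow(x$hemi_cbc),
              if (x$same_species) "same species" else "different species"))
  invisible(x)
}

#' Delimit species among OTUs by apex-window CBCs
#'
#' Builds a graph with an edge between two OTUs whenever their pairwise CBC
#' report (window = the helix-III apex window around the YGGY motif) finds no
#' CBC inside the delimitation window; species are the connected components
#' (the compensatory base change correlates with the separation of
#' biological species, and same-species evidence is treated as transitive).
#' An OTU without a structure becomes its own species, with a warning.
#'
#' @param otu_ids Character vector of OTU ids.
#' @param structures Named list of `its2_structure` (may lack some ids).
#' @param apex_window Window size passed to [delimitation_window()]
#'   (default 10).
#' @param params [align_params()].
#' @return A named integer vector: species index for every OTU id (a
#'   partition).
#' @export
delimit_species <- function(otu_ids, structures, apex_window = 10,
                            params = align_params()) {
  have <- otu_ids %in% names(structures)
  if (any(!have)) {
    warning("no structure for: ", paste(otu_ids[!have], collapse = ", "),
            "; each becomes its own species")
  }
  ids <- otu_ids[have]
  g <- igraph::make_empty_graph(n = length(otu_ids), directed = FALSE)
  igraph::V(g)$name <- otu_ids
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq.int(i + 1, length(ids))) {
        a <- structures[[ids[i]]]
        b <- structures[[ids[j]]]
        rep_ab <- detect_cbc(a, b, window = delimitation_window(a, apex_window),
                             params = params)
        if (rep_ab$same_species) {
          g <- igraph::add_edges(g, c(ids[i], ids[j]))
        }
      }
    }
  }
  comp <- igraph::components(g)$membership
  setNames(as.integer(comp), otu_ids)
}
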