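#' Construct a community matrix
#'
#' Samples x taxa count matrix with sample metadata (region labels, sites,
#' coordinates). All-zero taxon columns are disallowed (a taxon must be
#' observed somewhere).
#'
#' @param counts Integer matrix, samples in rows (rownames = sample ids),
#'   taxa in columns (colnames = taxon ids).
#' @param samples Data frame with at least `sample_id` and `region`
#'   (optionally `site`, `lat`, `lon`), one row per matrix row.
#' @return A `community_matrix`.
#' @export
community_matrix <- function(counts, samples) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample rownames and taxon colnames")
  }
  if (!all(rownames(counts) %in% samples$sample_id)) {
    stop("every matrix row needs a metadata row")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  if (ncol(counts) > 0 && any(colSums(counts) == 0)) {
    stop("all-zero taxon columns are not allowed")
  }
  samples <- samples[match(rownames(counts), samples$sample_id), , drop = FALSE]
  structure(list(counts = counts, samples = samples), class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d samples x %d taxa, %d reads, regions: %s\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              paste(unique(x$samples$region), collapse = ", ")))
  invisible(x)
}

#' Region-presence table of a community matrix
#'
#' A taxon is present in a region iff its summed count over that region's
#' samples is at least `min_count`.
#'
#' @param cm A `community_matrix`.
#' @param min_count Presence threshold (default 1: any read confers
#'   presence).
#' @return A taxa x regions logical matrix.
#' @export
presence_table <- function(cm, min_count = 1) {
  regions <- unique(cm$samples$region)
  if (any(is.na(regions))) stop("unknown region label (NA) in metadata")
  if (ncol(cm$counts) == 0) {
    return(matrix(logical(0), nrow = 0, ncol = length(regions),
                  dimnames = list(NULL, regions)))
  }
  by_region <- rowsum(cm$counts, cm$samples$region)  # regions x taxa
  t(by_region[regions, , drop = FALSE] >= min_count)
}

#' Default two-pole region scheme
#'
#' Arctic pole: Svalbard, Greenland, Alaska; Antarctic pole: Antarctica.
#'
#' @param arctic,antarctic Character vectors of region labels.
#' @return A list with `arctic` and `antarctic`.
#' @export
region_scheme <- function(arctic = c("Svalbard", "Greenland", "Alaska"),
                          antarctic = "Antarctica") {
  list(arctic = arctic, antarctic = antarctic)
}

#' Classify a presence set into a biogeographic category
#'
#' The four categories are mutually exclusive and exhaustive under a
#' two-pole scheme: `endemic` -- exactly one region; `bipolar` -- at least
#' one region from each pole; `entire_arctic` -- all Arctic regions and no
#' Antarctic one; `arctic_shared` -- two or more (but not all) Arctic
#' regions, no Antarctic region.
#'
#' @param regions_present Non-empty character vector of regions.
#' @param scheme A [region_scheme()].
#' @return One of `"endemic"`, `"arctic_shared"`, `"entire_arctic"`,
#'   `"bipolar"`.
#' @export
classify_biogeo <- function(regions_present, scheme = region_scheme()) {
  regions_present <- unique(regions_present)
  if (length(regions_present) == 0) stop("empty presence set")
  known <- c(scheme$arctic, scheme$antarctic)
  if (!all(regions_present %in% known)) {
    stop("regions outside the declared scheme: ",
         paste(setdiff(regions_present, known), collapse = ", "))
  }
  has_arc <- any(regions_present %in% scheme$arctic)
  has_ant <- any(regions_present %in% scheme$antarctic)
  if (length(regions_present) == 1) return("endemic")
  if (has_arc && has_ant) return("bipolar")
  if (setequal(intersect(regions_present, scheme$arctic), scheme$arctic) &&
      !has_ant) {
    return("entire_arctic")
  }
  "arctic_shared"
}

#' Classify every taxon of a community matrix
#'
#' @param cm A `community_matrix`.
#' @param scheme A [region_scheme()].
#' @param min_count Presence threshold (default 1).
#' @return A data frame `taxon_id`, `regions_present` (comma-joined),
#'   `category`.
#' @export
classify_all_taxa <- function(cm, scheme = region_scheme(), min_count = 1) {
  pres <- presence_table(cm, min_count)
  categories <- apply(pres, 1, function(p) {
    classify_biogeo(colnames(pres)[p], scheme)
  })
  data.frame(taxon_id = colnames(cm$counts),
             regions_present = apply(pres, 1, function(p) {
               paste(colnames(pres)[p], collapse = ",")
             }),
             category = unname(categories), stringsAsFactors = FALSE)
}

#' Endemic-fraction and bipolar read-share summary
#'
#' Per region R: the endemic unique fraction is the number of taxa present
#' only in R over the number of taxa present in R; the bipolar read share is
#' the fraction of R's reads belonging to bipolar taxa. Overall values are
#' reported both as the arithmetic mean of the regional values and as pooled
#' read-weighted (or taxon-pooled) totals. Regions with zero reads are
#' reported as `NaN` and excluded from the means.
#'
#' @param cm A `community_matrix`.
#' @param classification A data frame from [classify_all_taxa()] covering
#'   every taxon of `cm` (recomputed when `NULL`).
#' @param scheme A [region_scheme()].
#' @param min_count Presence threshold used for the presence sets.
#' @return A `biogeo_summary`: list with `per_region` (data frame: region,
#'   n_taxa_present, n_endemic, endemic_unique_fraction, reads_total,
#'   reads_bipolar, bipolar_read_share, plus one reads/share column per
#'   category) and `overall` (mean-of-regions and pooled variants).
#' @export
read_share_summary <- function(cm, classification = NULL,
                               scheme = region_scheme(), min_count = 1) {
  if (is.null(classification)) classification <- classify_all_taxa(cm, scheme, min_count)
  stopifnot(all(colnames(cm$counts) %in% classification$taxon_id))
  cat_of <- setNames(classification$category, classification$taxon_id)
  pres <- presence_table(cm, min_count)
  regions <- colnames(pres)
  by_region <- rowsum(cm$counts, cm$samples$region)[regions, , drop = FALSE]
  cats <- c("endemic", "arctic_shared", "entire_arctic", "bipolar")
  taxon_cat <- cat_of[colnames(cm$counts)]
  per <- lapply(regions, function(R) {
    present <- pres[, R]
    n_present <- sum(present)
    n_endemic <- sum(present & rowSums(pres) == 1)
    reads_total <- sum(by_region[R, ])
    reads_by_cat <- vapply(cats, function(cc) {
      sum(by_region[R, taxon_cat == cc])
    }, numeric(1))
    data.frame(region = R,
               n_taxa_present = n_present,
               n_endemic = n_endemic,
               endemic_unique_fraction = if (n_present > 0) n_endemic / n_present else NaN,
               reads_total = reads_total,
               reads_bipolar = reads_by_cat[["bipolar"]],
               bipolar_read_share = if (reads_total > 0) {
                 reads_by_cat[["bipolar"]] / reads_total
               } else NaN,
               endemic_read_share = if (reads_total > 0) {
                 reads_by_cat[["endemic"]] / reads_total
               } else NaN,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  ok <- is.finite(per$bipolar_read_share)
  overall <- list(
    endemic_unique_fraction_mean = mean(per$endemic_unique_fraction[ok]),
    bipolar_read_share_mean = mean(per$bipolar_read_share[ok]),
    endemic_unique_fraction_pooled =
      sum(per$n_endemic) / max(1L, sum(per$n_taxa_present)),
    bipolar_read_share_pooled =
      sum(per$reads_bipolar) / max(1L, sum(per$reads_total))
  )
  structure(list(per_region = per, overall = overall), class = "biogeo_summary")
}

#' @export
print.biogeo_summary <- function(x, ...) {
  cat("biogeo_summary\n")
  print(x$per_region, row.names = FALSE)
  cat(sprintf("mean endemic unique fraction: %.3f | mean bipolar read share: %.3f\n",
              x$overall$endemic_unique_fraction_mean,
              x$overall$bipolar_read_share_mean))
  invisible(x)
}

#' Sample-taxon co-occurrence network
#'
#' Bipartite graph with one node per sample and one per (sub-sampled) taxon;
#' an edge links a sample to every taxon with a positive count in it, with
#' the count as edge weight. Taxa are sub-sampled uniformly without
#' replacement (all kept when fewer than `n_subsample`); node attributes
#' carry region labels.
#'
#' @param cm A `community_matrix`.
#' @param n_subsample Number of taxa to pick (default 20000).
#' @param seed RNG seed for the sub-sampling.
#' @return An igraph bipartite graph (`type` TRUE for taxon nodes).
#' @export
cooccurrence_network <- function(cm, n_subsample = 20000, seed = 1) {
  stopifnot(n_subsample >= 1)
  taxa <- colnames(cm$counts)
  if (length(taxa) > n_subsample) {
    taxa <- sort(withr_seed_sample(taxa, n_subsample, seed))
  }
  sub <- cm$counts[, taxa, drop = FALSE]
  idx <- which(sub > 0, arr.ind = TRUE)
  edges <- rbind(rownames(sub)[idx[, 1]], taxa[idx[, 2]])
  g <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(nrow(sub), name = rownames(sub), type = FALSE,
                         region = cm$samples$region) |>
    igraph::add_vertices(length(taxa), name = taxa, type = TRUE,
                         region = NA_character_)
  g <- igraph::add_edges(g, as.vector(edges), weight = sub[idx])
  g
}

# draw a fixed-seed sample without disturbing the caller's RNG state
withr_seed_sample <- function(x, n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample(x, n)
}

#' Export a bipartite network as GraphML and an edge-list TSV
#' @param g An igraph graph.
#' @param graphml_path,edges_path Output paths (either may be `NULL`).
#' @export
export_network <- function(g, graphml_path = NULL, edges_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(edges_path)) {
    el <- igraph::as_data_frame(g, what = "edges")
    write.table(el, edges_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(g)
}
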