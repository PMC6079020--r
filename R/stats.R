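#' Shannon-Wiener diversity index (natural log)
#'
#' `H = -sum(p_i * ln(p_i))` over taxa with positive counts; delegates to
#' \code{vegan::diversity}.
#'
#' @param counts Non-negative count vector with at least one positive entry.
#' @return The Shannon-Wiener index.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero count vector")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `BC = sum(|x - y|) / sum(x + y)`, in [0, 1].
#'
#' @param x,y Equal-length non-negative count vectors, not both all-zero.
#' @return The Bray-Curtis dissimilarity.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (sum(x) + sum(y) == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / sum(x + y)
}

#' Bray-Curtis distance matrix of a community matrix
#'
#' @param cm A `community_matrix` (or a plain samples x taxa matrix).
#' @return A `dist` object (from \code{vegan::vegdist}).
#' @export
bray_curtis_matrix <- function(cm) {
  m <- if (inherits(cm, "community_matrix")) cm$counts else cm
  vegan::vegdist(m, method = "bray")
}

#' UPGMA (average-linkage) dendrogram of a distance matrix
#'
#' Labels are put into lexicographic order before agglomeration so tie
#' handling is deterministic; the result is ultrametric by construction.
#'
#' @param d A `dist` or symmetric matrix with labels.
#' @return An `hclust` object (convert with [upgma_newick()] for export).
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 2) stop("need at least two samples")
  ord <- order(rownames(m), method = "radix")
  m <- m[ord, ord]
  hclust(as.dist(m), method = "average")
}

#' Newick export of a UPGMA dendrogram
#'
#' @param hc An `hclust` from [upgma()].
#' @param path Optional output path.
#' @return The Newick string, invisibly if written to `path`.
#' @export
upgma_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# seed-deterministic permutation indices, restoring the caller's RNG
perm_indices <- function(n, n_perm, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  lapply(seq_len(n_perm), function(i) sample.int(n))
}

permanova_f <- function(d2, groups) {
  n <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  a <- length(unique(groups))
  ss_among <- ss_total - ss_within
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Distance-based partition of sums of squares: total SS is the sum of all
#' squared pairwise distances over n; within-group SS analogously per group;
#' the pseudo-F is `(SS_among / (a-1)) / (SS_within / (n-a))`. The p-value
#' permutes group labels with the +1 rule
#' `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`, so p is never 0.
#'
#' @param d A `dist` or symmetric distance matrix over samples.
#' @param groups Group labels, one per sample (at least 2 groups, each
#'   non-empty).
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed (recorded in the result).
#' @param permutations Optional matrix of permutation index rows; overrides
#'   random permutations (used for exhaustive small-n tests).
#' @return A `permutation_test`: list with `statistic`, `n_permutations`,
#'   `p_value`, `seed`, `method`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1, permutations = NULL) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per sample required")
  if (length(unique(groups)) < 2) stop("need at least two groups")
  if (length(unique(groups)) >= n) {
    stop("no residual degrees of freedom: every group is a singleton")
  }
  if (is.null(permutations)) {
    stopifnot(n_perm >= 1)
    perms <- perm_indices(n, n_perm, seed)
  } else {
    perms <- lapply(seq_len(nrow(permutations)), function(i) permutations[i, ])
    n_perm <- length(perms)
  }
  d2 <- m^2
  f_obs <- permanova_f(d2, groups)
  f_perm <- vapply(perms, function(p) permanova_f(d2, groups[p]), numeric(1))
  p <- (sum(f_perm >= f_obs - 1e-12) + 1) / (n_perm + 1)
  structure(list(statistic = f_obs, n_permutations = n_perm, p_value = p,
                 seed = seed, method = "PERMANOVA (one-way, pseudo-F)"),
            class = "permutation_test")
}

#' Mantel test between two distance matrices
#'
#' Statistic: Pearson (default) or Spearman correlation of the
#' lower-triangle vectors; the null permutes rows and columns of `d2`
#' simultaneously; one-sided (greater) p with the +1 rule.
#'
#' @param d1,d2 `dist` objects or symmetric matrices with matching labels.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param permutations Optional explicit permutation matrix (rows =
#'   permutations).
#' @return A `permutation_test` list.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1,
                        method = c("pearson", "spearman"), permutations = NULL) {
  method <- match.arg(method)
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!identical(rownames(m1), rownames(m2))) stop("label mismatch between matrices")
  }
  n <- nrow(m1)
  if (n < 4) stop("need at least 4 samples")
  lt <- lower.tri(m1)
  r_obs <- cor(m1[lt], m2[lt], method = method)
  if (is.null(permutations)) {
    stopifnot(n_perm >= 1)
    perms <- perm_indices(n, n_perm, seed)
  } else {
    perms <- lapply(seq_len(nrow(permutations)), function(i) permutations[i, ])
    n_perm <- length(perms)
  }
  r_perm <- vapply(perms, function(p) {
    cor(m1[lt], m2[p, p][lt], method = method)
  }, numeric(1))
  p <- (sum(r_perm >= r_obs - 1e-12) + 1) / (n_perm + 1)
  structure(list(statistic = r_obs, n_permutations = n_perm, p_value = p,
                 seed = seed, method = paste0("Mantel (", method, ", one-sided)")),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("%s: statistic=%.4f, p=%.4g (%d permutations, seed %s)\n",
              x$method, x$statistic, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

#' Great-circle distance between two points, in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("coordinates out of range")
  }
  geosphere::distHaversine(c(lon1, lat1), c(lon2, lat2), r = 6371) # km radius
}

#' Pairwise great-circle distance matrix of sample sites
#'
#' @param samples Data frame with `sample_id`, `lat`, `lon`.
#' @return A `dist` object in kilometres, labelled by sample id.
#' @export
geo_distance_matrix <- function(samples) {
  n <- nrow(samples)
  m <- matrix(0, n, n, dimnames = list(samples$sample_id, samples$sample_id))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        m[i, j] <- m[j, i] <- haversine_km(samples$lat[i], samples$lon[i],
                                           samples$lat[j], samples$lon[j])
      }
    }
  }
  as.dist(m)
}

#' Mean inter-site great-circle distance between regions
#'
#' Region-level physical distance, defined as the mean over all cross-region
#' site pairs of their great-circle distances.
#'
#' @param samples Data frame with `sample_id`, `region`, `lat`, `lon`.
#' @return A symmetric region x region matrix (km).
#' @export
region_distance_matrix <- function(samples) {
  regions <- unique(samples$region)
  geo <- as.matrix(geo_distance_matrix(samples))
  out <- matrix(0, length(regions), length(regions),
                dimnames = list(regions, regions))
  for (a in regions) {
    for (b in regions) {
      if (a != b) {
        out[a, b] <- mean(geo[samples$region == a, samples$region == b])
      }
    }
  }
  out
}
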