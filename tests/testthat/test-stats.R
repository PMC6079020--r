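test_that("Shannon-Wiener matches closed forms and a frozen hand value", {
  expect_equal(shannon(c(10, 10, 10, 10)), log(4))
  expect_equal(shannon(7), 0)
  # -(1/6 ln 1/6 + 1/3 ln 1/3 + 1/2 ln 1/2), evaluated by hand
  expect_equal(shannon(c(1, 2, 3)), 1.011404, tolerance = 1e-6)
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(shannon(c(-1, 2)))
})

test_that("Bray-Curtis matches its definition and bounds", {
  expect_equal(bray_curtis(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 3)), 1)
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(1:3, 1:2), "length")
  set.seed(51)
  for (i in 1:10) {
    x <- rpois(6, 5); y <- rpois(6, 5)
    if (sum(x) + sum(y) == 0) next
    bc <- bray_curtis(x, y)
    expect_gte(bc, 0); expect_lte(bc, 1)
    expect_equal(bc, bray_curtis(y, x))
  }
  # matrix route agrees with the pairwise definition
  m <- rbind(a = c(2, 1, 0), b = c(1, 1, 1), c = c(0, 3, 2))
  d <- as.matrix(bray_curtis_matrix(m))
  expect_equal(d["a", "b"], bray_curtis(m["a", ], m["b", ]))
  expect_equal(d["a", "c"], bray_curtis(m["a", ], m["c", ]))
})

test_that("UPGMA reproduces hand agglomerations and is ultrametric", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  hc2 <- upgma(as.dist(d2))
  expect_equal(hc2$height, 0.4)   # single node at height 0.4 (leaves at 0.2)
  d3 <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc3 <- upgma(as.dist(d3))
  expect_equal(sort(hc3$height), c(0.2, 0.6))  # ((A,B),C)
  expect_setequal(hc3$merge[2, ], c(-3, 1))    # C joins the (A,B) cluster last
  coph <- cophenetic(hc3)
  expect_equal(as.matrix(coph)["A", "B"], 0.2)
  # ultrametric: cophenetic distances satisfy the three-point condition
  cm <- as.matrix(coph)
  labs <- rownames(cm)
  for (i in labs) for (j in labs) for (k in labs) {
    expect_lte(cm[i, j], max(cm[i, k], cm[j, k]) + 1e-12)
  }
  nwk <- upgma_newick(hc3)
  expect_match(nwk, "^\\(")
  expect_error(upgma(matrix(0, 1, 1, dimnames = list("A", "A"))), "two samples")
})

perm_f_oracle <- function(d, groups) {
  # independently coded pseudo-F for the exhaustive tests
  m <- as.matrix(d)^2
  n <- nrow(m)
  sst <- sum(m[upper.tri(m)]) / n
  ssw <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    sub <- m[i, i, drop = FALSE]
    ssw <- ssw + sum(sub[upper.tri(sub)]) / length(i)
  }
  a <- length(unique(groups))
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

test_that("PERMANOVA matches exhaustive permutation enumeration at n = 6", {
  pts <- c(0, 0.01, 0.02, 10, 10.01, 10.02)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:6), paste0("s", 1:6))
  groups <- rep(c("g1", "g2"), each = 3)
  perms <- all_permutations(6)
  res <- permanova(d, groups, permutations = perms)
  f_all <- apply(perms, 1, function(p) perm_f_oracle(d, groups[p]))
  p_expected <- (sum(f_all >= res$statistic - 1e-12) + 1) / (nrow(perms) + 1)
  expect_equal(res$p_value, p_expected)
  # 72 of 720 label permutations preserve the two tight groups
  expect_equal(p_expected, (72 + 1) / (720 + 1))
  expect_equal(res$statistic, perm_f_oracle(d, groups))
})

test_that("the PERMANOVA statistic agrees with vegan::adonis2", {
  set.seed(52)
  m <- matrix(rpois(60, 8), nrow = 6)
  groups <- rep(c("a", "b"), each = 3)
  d <- vegan::vegdist(m, "bray")
  ours <- permanova(d, groups, n_perm = 49, seed = 9)
  ref <- vegan::adonis2(d ~ g, data = data.frame(g = groups), permutations = 49)
  expect_equal(ours$statistic, ref$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA is invariant to sample order and seed-deterministic", {
  set.seed(53)
  m <- matrix(rpois(80, 6), nrow = 8)
  rownames(m) <- paste0("s", 1:8)
  groups <- rep(c("a", "b"), each = 4)
  d <- as.matrix(vegan::vegdist(m, "bray"))
  f1 <- permanova(d, groups, n_perm = 9, seed = 1)$statistic
  ord <- sample(8)
  f2 <- permanova(d[ord, ord], groups[ord], n_perm = 9, seed = 1)$statistic
  expect_equal(f1, f2)
  p1 <- permanova(d, groups, n_perm = 99, seed = 4)
  p2 <- permanova(d, groups, n_perm = 99, seed = 4)
  expect_equal(p1$p_value, p2$p_value)
  expect_equal(p1$seed, 4)
  expect_error(permanova(d, rep("a", 8)), "two groups")
})

test_that("Mantel matches its definition and exhaustive enumeration at n = 4", {
  set.seed(54)
  pts <- runif(4) * 10
  d1 <- as.matrix(dist(pts))
  dimnames(d1) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_equal(mantel_test(d1, 2 * d1, n_perm = 9, seed = 1)$statistic, 1)
  d2 <- as.matrix(dist(runif(4) * 10))
  dimnames(d2) <- dimnames(d1)
  perms <- all_permutations(4)
  res <- mantel_test(d1, d2, permutations = perms)
  lt <- lower.tri(d1)
  r_all <- apply(perms, 1, function(p) cor(d1[lt], d2[p, p][lt]))
  p_expected <- (sum(r_all >= res$statistic - 1e-12) + 1) / (nrow(perms) + 1)
  expect_equal(res$p_value, p_expected)
  # statistic invariant to a common relabeling
  ord <- c(3, 1, 4, 2)
  r2 <- mantel_test(d1[ord, ord], d2[ord, ord], n_perm = 9, seed = 1)$statistic
  expect_equal(res$statistic, r2)
  expect_error(mantel_test(d1[1:3, 1:3], d2[1:3, 1:3], 9), "4 samples")
  bad <- d2; rownames(bad) <- colnames(bad) <- paste0("x", 1:4)
  expect_error(mantel_test(d1, bad, 9), "label mismatch")
})

test_that("the Mantel statistic agrees with vegan::mantel", {
  set.seed(55)
  d1 <- dist(matrix(runif(24), 6))
  d2 <- dist(matrix(runif(24), 6))
  ours <- mantel_test(as.matrix(d1), as.matrix(d2), n_perm = 9, seed = 2)
  ref <- vegan::mantel(d1, d2, permutations = 9)
  expect_equal(ours$statistic, ref$statistic, tolerance = 1e-10)
})

test_that("great-circle distances match closed forms", {
  expect_equal(haversine_km(45, 30, 45, 30), 0)
  expect_equal(haversine_km(0, 0, 0, 180), pi * 6371, tolerance = 1e-6)
  expect_equal(haversine_km(10, 20, -30, 40), haversine_km(-30, 40, 10, 20))
  expect_error(haversine_km(91, 0, 0, 0), "out of range")
  samples <- data.frame(sample_id = c("a", "b"), region = c("r1", "r2"),
                        lat = c(0, 0), lon = c(0, 90), stringsAsFactors = FALSE)
  gd <- as.matrix(geo_distance_matrix(samples))
  expect_equal(gd["a", "b"], pi * 6371 / 2, tolerance = 1e-6)
  rd <- region_distance_matrix(samples)
  expect_equal(rd["r1", "r2"], gd["a", "b"])
})
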