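small_cfg <- function(reads_per_sample = 400, n_bipolar = 2, ...) {
  sim_config(samples_per_region = 1,
             n_endemic = c(Antarctica = 3, Svalbard = 2, Greenland = 2,
                           Alaska = 2),
             n_arctic_shared = 2, n_entire_arctic = 1, n_bipolar = n_bipolar,
             share_targets = rbind(
               Antarctica = c(endemic = 0.8, arctic_shared = 0,
                              entire_arctic = 0, bipolar = 0.2),
               Svalbard = c(endemic = 0.4, arctic_shared = 0.2,
                            entire_arctic = 0.1, bipolar = 0.3),
               Greenland = c(endemic = 0.4, arctic_shared = 0.2,
                             entire_arctic = 0.1, bipolar = 0.3),
               Alaska = c(endemic = 0.6, arctic_shared = 0,
                          entire_arctic = 0.1, bipolar = 0.3)),
             reads_per_sample = reads_per_sample, ...)
}

test_that("the template pool respects configured categories and divergences", {
  mc <- build_metacommunity(small_cfg(seed = 61))
  tpl <- mc$templates
  expect_equal(sum(tpl$category == "endemic"), 9)
  expect_equal(sum(tpl$category == "bipolar"), 2)
  # category/region consistency
  for (i in seq_len(nrow(tpl))) {
    regs <- strsplit(tpl$regions[i], ",")[[1]]
    expect_equal(classify_biogeo(regs), tpl$category[i], info = tpl$template_id[i])
  }
  # all templates share the scaffold structure with canonical pairs
  for (s in unique(tpl$sequence)) {
    expect_silent(its2_structure(s, mc$structure))
  }
  # within-OTU divergence < 2%, between-OTU > 2%
  by_otu <- split(tpl$sequence, tpl$otu_ancestor)
  for (grp in by_otu) {
    for (x in grp) for (y in grp) {
      if (x != y) expect_gt(pairwise_identity(x, y), 0.98)
    }
  }
  anc <- vapply(by_otu, `[[`, "", 1)
  if (length(anc) > 1) {
    for (i in 1:(length(anc) - 1)) for (j in (i + 1):length(anc)) {
      expect_lt(pairwise_identity(anc[[i]], anc[[j]]), 0.98)
    }
  }
})

test_that("expected read shares hit the configured targets exactly", {
  cfg <- small_cfg(seed = 62)
  mc <- build_metacommunity(cfg)
  cat_of <- mc$templates$category
  for (R in cfg$regions) {
    for (cc in colnames(cfg$share_targets)) {
      realized <- sum(mc$shares[cat_of == cc, R])
      expect_equal(realized, unname(cfg$share_targets[R, cc]),
                   tolerance = 1e-9, info = paste(R, cc))
    }
    expect_equal(sum(mc$shares[, R]), 1, tolerance = 1e-9)
  }
})

test_that("infeasible share targets are rejected", {
  cfg <- small_cfg(seed = 63, n_bipolar = 0)
  expect_error(build_metacommunity(cfg), "infeasible")
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- small_cfg(seed = 64)
  d1 <- tempfile("sim_a"); d2 <- tempfile("sim_b")
  t1 <- simulate_reads(build_metacommunity(cfg), d1)
  t2 <- simulate_reads(build_metacommunity(cfg), d2)
  expect_equal(unname(tools::md5sum(t1$fastq_fwd)), unname(tools::md5sum(t2$fastq_fwd)))
  expect_equal(unname(tools::md5sum(t1$fastq_rev)), unname(tools::md5sum(t2$fastq_rev)))
  expect_equal(t1$reads, t2$reads)
})

test_that("no read of an endemic template originates outside its region", {
  cfg <- small_cfg(seed = 65)
  tr <- simulate_reads(build_metacommunity(cfg), tempfile("sim"))
  rd <- tr$reads[!tr$reads$chimera, ]
  region_of_sample <- setNames(tr$samples$region, tr$samples$sample_id)
  for (i in seq_len(nrow(tr$templates))) {
    tpl <- tr$templates[i, ]
    regs <- strsplit(tpl$regions, ",")[[1]]
    obs <- unique(region_of_sample[rd$sample_id[rd$template_id == tpl$template_id]])
    expect_true(all(obs %in% regs), info = tpl$template_id)
  }
})

test_that("a noiseless channel reproduces the template sequences exactly", {
  cfg <- small_cfg(seed = 66, error_rate = 0, chimera_rate = 0)
  mc <- build_metacommunity(cfg)
  tr <- simulate_reads(mc, tempfile("sim"))
  expect_setequal(unique(tr$reads$insert), unique(mc$templates$sequence))
  # and the FASTQ mates reassemble into the templates through the package's
  # own merge + trim route
  fwd <- read_fastq(tr$fastq_fwd)[1:50, ]
  rev <- read_fastq(tr$fastq_rev)[1:50, ]
  mg <- merge_read_pairs(fwd, rev)
  expect_equal(mg$n_failed, 0L)
  t5 <- trim_primer(mg$merged, cfg$fwd_primer, 4, "5p")
  t3 <- trim_primer(t5$reads, cfg$rev_primer, 4, "3p")
  expect_true(all(t5$trimmed & t3$trimmed))
  expect_true(all(t3$reads$seq %in% mc$templates$sequence))
})

test_that("chimera counts fall inside the exact binomial interval", {
  cfg <- small_cfg(seed = 67, chimera_rate = 0.05,
                   reads_per_sample = 10000 %/% 12 + 1)
  tr <- simulate_reads(build_metacommunity(cfg), tempfile("sim"))
  n <- nrow(tr$reads)
  k <- sum(tr$reads$chimera)
  lo <- qbinom(0.005, n, 0.05)
  hi <- qbinom(0.995, n, 0.05)
  expect_gte(k, lo)
  expect_lte(k, hi)
})

test_that("truth summaries degenerate to template truth without noise", {
  cfg <- small_cfg(seed = 68, error_rate = 0, chimera_rate = 0)
  mc <- build_metacommunity(cfg)
  tr <- simulate_reads(mc, tempfile("sim"))
  ts <- truth_summary(tr)
  # every realized unique is a template, observed only within its configured
  # regions (multinomial dropout may shrink, never extend, a presence set)
  expect_true(all(ts$sequences %in% mc$templates$sequence))
  expect_lte(nrow(ts$classification), nrow(mc$templates))
  tpl_regions <- setNames(strsplit(mc$templates$regions, ","),
                          mc$templates$sequence)
  for (i in seq_len(nrow(ts$classification))) {
    obs <- strsplit(ts$classification$regions_present[i], ",")[[1]]
    tru <- tpl_regions[[ts$sequences[[ts$classification$taxon_id[i]]]]]
    expect_true(all(obs %in% tru), info = ts$classification$taxon_id[i])
  }
})
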