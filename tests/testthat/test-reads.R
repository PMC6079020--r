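test_that("demultiplexing assigns exact dual-index matches only", {
  md <- data.frame(sample_id = c("S1", "S2"), site = "x", region = "Svalbard",
                   lat = 78, lon = 11,
                   i7 = c("ACGTACGT", "TTTTACGT"),
                   i5 = c("GGGGCCCC", "GGGGCCCC"), stringsAsFactors = FALSE)
  reads <- data.frame(
    id = c("r1 ACGTACGT+GGGGCCCC",   # exact S1
           "r2 TTTTACGT+GGGGCCCC",   # exact S2
           "r3 ACGTACGA+GGGGCCCC",   # one index off by 1 nt -> discard
           "r4 AAAAAAAA+AAAAAAAA"),  # unknown -> discard
    seq = "ACGT", qual = "IIII", stringsAsFactors = FALSE)
  dm <- demultiplex(reads, reads, md)
  expect_equal(unname(dm$n_assigned), c(1L, 1L))
  expect_equal(dm$n_discarded, 2L)
  expect_equal(dm$by_sample$S1$fwd$id, "r1 ACGTACGT+GGGGCCCC")
})

test_that("duplicate index pairs are a configuration error", {
  md <- data.frame(sample_id = c("S1", "S2"), site = "x", region = "r",
                   lat = 0, lon = 0, i7 = "AAAA", i5 = "CCCC",
                   stringsAsFactors = FALSE)
  reads <- data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE)
  expect_error(demultiplex(reads, reads, md), "duplicate index pairs")
})

test_that("empty input demultiplexes to empty outputs", {
  md <- data.frame(sample_id = "S1", site = "x", region = "r", lat = 0,
                   lon = 0, i7 = "AAAA", i5 = "CCCC", stringsAsFactors = FALSE)
  empty <- data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE)
  dm <- demultiplex(empty, empty, md)
  expect_equal(unname(dm$n_assigned), 0L)
  expect_equal(dm$n_discarded, 0L)
})

phred <- function(q) rawToChar(as.raw(q + 33L))

test_that("quality truncation cuts before the first low-quality base", {
  reads <- data.frame(
    id = c("a", "b", "c"),
    seq = c("ACGT", "ACGT", "ACGT"),
    qual = c(phred(c(30, 30, 30, 30)),   # all high -> unchanged
             phred(c(2, 30, 30, 30)),    # first base low -> empty
             phred(c(30, 30, 2, 30))),   # cut before third base
    stringsAsFactors = FALSE)
  tr <- truncate_at_low_quality(reads, qmin = 3)
  expect_equal(tr$seq, c("ACGT", "", "AC"))
  expect_equal(nchar(tr$qual), nchar(tr$seq))
})

test_that("pair merging produces the consensus over the best ungapped overlap", {
  # 10 nt mates with a perfect 6 nt overlap -> 14 nt merged read
  amp <- "ACGTACGTGGAATT"
  fwd <- data.frame(id = "p", seq = substr(amp, 1, 10),
                    qual = strrep("I", 10), stringsAsFactors = FALSE)
  rev <- data.frame(id = "p",
                    seq = as.character(Biostrings::reverseComplement(
                      Biostrings::DNAString(substr(amp, 5, 14)))),
                    qual = strrep("I", 10), stringsAsFactors = FALSE)
  mg <- merge_read_pairs(fwd, rev, min_overlap = 6, max_mismatch_frac = 0)
  expect_equal(mg$n_failed, 0L)
  expect_equal(mg$merged$seq, amp)

  # no overlap of the required length -> merge failure, counted not thrown
  rev2 <- data.frame(id = "p", seq = "CCCCCCCCCC", qual = strrep("I", 10),
                     stringsAsFactors = FALSE)
  mg2 <- merge_read_pairs(fwd, rev2, min_overlap = 6, max_mismatch_frac = 0)
  expect_equal(mg2$n_failed, 1L)
  expect_equal(nrow(mg2$merged), 0L)
})

test_that("at overlap mismatches the higher-quality base wins, quality is max", {
  # fwd = AAGG (Q40 at the mismatch), rc(rev) = GATT (Q10): overlap "GG"/"GA"
  fwd <- data.frame(id = "p", seq = "AAGG", qual = phred(c(40, 40, 40, 40)),
                    stringsAsFactors = FALSE)
  rev_rc <- "GATT"
  rev <- data.frame(id = "p",
                    seq = as.character(Biostrings::reverseComplement(
                      Biostrings::DNAString(rev_rc))),
                    qual = phred(c(10, 10, 10, 10)), stringsAsFactors = FALSE)
  mg <- merge_read_pairs(fwd, rev, min_overlap = 2, max_mismatch_frac = 0.5)
  expect_equal(mg$merged$seq, "AAGGTT")   # fwd G beats rev A at Q40 > Q10
  expect_equal(substr(mg$merged$qual, 4, 4), phred(40))
  # flip the qualities: the reverse base must win
  fwd2 <- data.frame(id = "p", seq = "AAGG", qual = phred(c(40, 40, 40, 5)),
                     stringsAsFactors = FALSE)
  mg2 <- merge_read_pairs(fwd2, rev, min_overlap = 2, max_mismatch_frac = 0.5)
  expect_equal(mg2$merged$seq, "AAGATT")
})

test_that("merging is symmetric in content on perfect overlaps", {
  set.seed(42)
  for (i in 1:10) {
    amp <- random_dna(40)
    f <- substr(amp, 1, 25)
    r_rc <- substr(amp, 16, 40)
    rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    fwd <- data.frame(id = "p", seq = f, qual = strrep("I", 25),
                      stringsAsFactors = FALSE)
    rev <- data.frame(id = "p", seq = rc(r_rc), qual = strrep("I", 25),
                      stringsAsFactors = FALSE)
    m1 <- merge_read_pairs(fwd, rev, 10, 0)$merged$seq
    # swap roles: reverse read as forward and vice versa
    fwd2 <- data.frame(id = "p", seq = rc(r_rc), qual = strrep("I", 25),
                       stringsAsFactors = FALSE)
    rev2 <- data.frame(id = "p", seq = f, qual = strrep("I", 25),
                       stringsAsFactors = FALSE)
    m2 <- merge_read_pairs(fwd2, rev2, 10, 0)$merged$seq
    expect_equal(m1, rc(m2))
  }
})

test_that("quality filter discards ambiguous, short and contaminant reads", {
  contam <- setNames(paste(rep("ACGGT", 40), collapse = ""), "phix_like")
  reads <- data.frame(
    id = c("amb", "short49", "keep50", "contam", "clean"),
    seq = c(paste0(strrep("A", 60), "N"),
            strrep("A", 49),
            strrep("A", 50),
            substr(contam, 1, 80),
            strrep("GATTACA", 10)),
    qual = c(strrep("I", 61), strrep("I", 49), strrep("I", 50),
             strrep("I", 80), strrep("I", 70)),
    stringsAsFactors = FALSE)
  qf <- quality_filter(reads, min_len = 50, contaminants = contam)
  expect_equal(qf$n_ambiguous, 1L)
  expect_equal(qf$n_short, 1L)
  expect_equal(qf$n_contaminant, 1L)
  expect_setequal(qf$kept$id, c("keep50", "clean"))
})

test_that("planted QC violations are counted exactly", {
  # k = 3 ambiguous, m = 2 short, j = 2 contaminant among clean reads
  contam <- setNames(random_dna(200), "contaminant")
  set.seed(7)
  clean <- replicate(5, random_dna(80))
  reads <- data.frame(
    id = sprintf("r%02d", 1:12),
    seq = c(clean,
            vapply(1:3, function(i) paste0(random_dna(60), "N", random_dna(10)),
                   ""),
            random_dna(20), random_dna(49),
            substr(contam, 3, 90), substr(contam, 50, 180)),
    stringsAsFactors = FALSE)
  reads$qual <- strrep("I", nchar(reads$seq))
  qf <- quality_filter(reads, min_len = 50, contaminants = contam)
  expect_equal(c(qf$n_ambiguous, qf$n_short, qf$n_contaminant), c(3L, 2L, 2L))
  expect_equal(nrow(qf$kept), 5L)
})

test_that("primer trimming is IUPAC-aware with a mismatch budget", {
  primer <- "CCAGCASCYGCGGTAATTCC"  # S = C/G, Y = C/T
  exact <- "CCAGCACCCGCGGTAATTCC"   # S -> C, Y -> C
  reads <- data.frame(id = "r", seq = paste0(exact, "AAAATTTT"),
                      qual = strrep("I", 28), stringsAsFactors = FALSE)
  tr <- trim_primer(reads, primer, max_mismatches = 4)
  expect_true(tr$trimmed)
  expect_equal(tr$reads$seq, "AAAATTTT")

  # S matched by G as well
  reads_g <- data.frame(id = "r", seq = paste0("CCAGCAGCCGCGGTAATTCC", "AA"),
                        qual = strrep("I", 22), stringsAsFactors = FALSE)
  expect_true(trim_primer(reads_g, primer, 0)$trimmed)

  # 4 mismatches trimmed, 5 mismatches reported untrimmed
  mm4 <- paste0("GGAGCACCCGCGGTAATTGG", "AA")  # 4 diffs from resolved primer
  mm5 <- paste0("GGAGCACCCGCGGTAGTTGG", "AA")  # 5 diffs
  r4 <- data.frame(id = "r", seq = mm4, qual = strrep("I", 22),
                   stringsAsFactors = FALSE)
  r5 <- data.frame(id = "r", seq = mm5, qual = strrep("I", 22),
                   stringsAsFactors = FALSE)
  expect_true(trim_primer(r4, primer, 4)$trimmed)
  expect_false(trim_primer(r5, primer, 4)$trimmed)

  expect_error(trim_primer(r4, ""), "empty primer")
})

test_that("reverse primer is trimmed at the 3' end as its reverse complement", {
  primer <- "ACTTTCGTTCTTGATYRA"
  resolved_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("YR", "CG", primer))))
  reads <- data.frame(id = "r", seq = paste0("GGGGCCCC", resolved_rc),
                      qual = strrep("I", 8 + nchar(resolved_rc)),
                      stringsAsFactors = FALSE)
  tr <- trim_primer(reads, primer, 4, end = "3p")
  expect_true(tr$trimmed)
  expect_equal(tr$reads$seq, "GGGGCCCC")
})

test_that("dereplication counts, orders and round-trips exactly", {
  reads <- list(S1 = c("ACGT", "ACGT", "ACGT", "TTTT"),
                S2 = c("TTTT", "GGGG"))
  pset <- dereplicate(reads)
  expect_equal(pset$tab$sequence, c("ACGT", "TTTT", "GGGG"))
  expect_equal(pset$tab$total_count, c(3L, 2L, 1L))
  # same sequence in two samples -> one phylotype, two count entries
  expect_equal(unname(pset$counts[2, ]), c(1L, 1L))
  # sorted: abundance descending, ties lexicographic
  expect_true(all(diff(pset$tab$total_count) <= 0))
  # round trip: expanding counts and re-dereplicating is idempotent
  expanded <- lapply(colnames(pset$counts), function(s) {
    rep(pset$tab$sequence, pset$counts[, s])
  })
  names(expanded) <- colnames(pset$counts)
  pset2 <- dereplicate(expanded)
  expect_equal(pset2$tab, pset$tab)
  expect_equal(pset2$counts, pset$counts)
  # empty input
  expect_equal(nrow(dereplicate(list(S1 = character(0)))$tab), 0L)
})

test_that("singleton removal drops exactly the total-count-1 phylotypes", {
  pset <- dereplicate(list(S1 = c("AAAA", "AAAA", "CCCC"), S2 = c("GGGG", "CCCC")))
  sg <- remove_singletons(pset)
  expect_equal(sg$n_removed, 1L)              # GGGG
  expect_setequal(sg$pset$tab$sequence, c("AAAA", "CCCC"))  # CCCC kept: 2 > 1
  all_single <- dereplicate(list(S1 = c("AAAA", "CCCC")))
  expect_equal(nrow(remove_singletons(all_single)$pset$tab), 0L)
})

test_that("the QC ledger enforces read conservation at every stage", {
  led <- new_ledger()
  led <- ledger_add(led, "demux", 100, 90, c(index_mismatch = 10))
  expect_error(ledger_add(led, "bad", 100, 90, c(x = 5)),
               "conservation violated")
  expect_error(ledger_add(led, "neg", 10, -5, c(x = 15)), "non-negative")
  tab <- ledger_table(led)
  expect_equal(tab$n_in, tab$n_out + tab$n_discarded)
})
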