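test_that("base-pair maximisation handles degenerate and textbook cases", {
  expect_equal(fold_dotbracket("AAAA"), "....")
  expect_equal(fold_dotbracket("GGGAAACCC"), "(((...)))")
  expect_error(fold_dotbracket("ACGX"), "non-nucleotide")
  expect_error(fold_dotbracket(""), "length")
})

test_that("folding respects the minimum hairpin loop and is deterministic", {
  set.seed(31)
  for (i in 1:25) {
    s <- random_dna(sample(5:20, 1))
    db <- fold_dotbracket(s)
    expect_identical(db, fold_dotbracket(s))
    p <- dotbracket_pairs(db)
    paired <- which(!is.na(p) & p > seq_along(p))
    if (length(paired)) expect_true(all(p[paired] - paired > 3))
  }
})

test_that("dynamic-programming pair counts equal the exhaustive maximum", {
  set.seed(32)
  for (i in 1:60) {
    s <- random_dna(sample(4:12, 1))
    db <- fold_dotbracket(s)
    got <- sum(strsplit(db, "")[[1]] == "(")
    expect_equal(got, brute_max_pairs(s), info = s)
  }
})

test_that("helix annotation counts branch stems in 5' order", {
  one <- its2_structure("GGAAACC", "((...))")
  expect_length(one$helices, 1)
  two <- its2_structure("GGAAACCTTGGAAACC", "((...))..((...))")
  expect_length(two$helices, 2)
  expect_lt(max(two$helices[[1]]$five_prime), min(two$helices[[2]]$five_prime))
  # single enclosing pair closes the basal loop; the bulged branch below it
  # is one helix whose chain runs to the apical loop
  bulged <- its2_structure("GGAGGAAACCCC", "((.((...))))")
  expect_length(bulged$helices, 1)
  expect_equal(nrow(bulged$helices[[1]]$pairs), 3)
  expect_equal(bulged$helices[[1]]$apex_loop, 6:8)
})

test_that("the canonical fixture has four helices and passes all hallmarks", {
  st <- canonical_fixture()
  expect_length(st$helices, 4)
  hm <- validate_hallmarks(st)
  expect_true(hm$four_helices)
  expect_true(hm$helixII_UU)
  expect_true(hm$yggy_helixIII_5prime_apex)
  expect_true(hm$overall)
})

test_that("each single-violation mutant fails exactly its own hallmark", {
  m4 <- validate_hallmarks(mutant_no_helix4())
  expect_false(m4$four_helices)
  expect_true(m4$helixII_UU)
  expect_true(m4$yggy_helixIII_5prime_apex)

  muu <- validate_hallmarks(mutant_no_uu())
  expect_true(muu$four_helices)
  expect_false(muu$helixII_UU)
  expect_true(muu$yggy_helixIII_5prime_apex)

  my <- validate_hallmarks(mutant_no_yggy())
  expect_true(my$four_helices)
  expect_true(my$helixII_UU)
  expect_false(my$yggy_helixIII_5prime_apex)
  expect_false(my$overall)
})

test_that("YGGY matching is pyrimidine-specific and reports overlaps", {
  expect_equal(find_yggy("UGGU"), 1L)
  expect_equal(find_yggy("CGGC"), 1L)
  expect_equal(find_yggy("TGGT"), 1L)   # DNA input transcribed
  expect_length(find_yggy("AGGA"), 0)
  expect_equal(find_yggy("CGGCGGC"), c(1L, 4L))
})

test_that("CBC and hemi-CBC follow the definition on constructed pairs", {
  a <- its2_structure("GGAAACC", "((...))")
  # outer pair G-C -> A-U with both partners changed: CBC
  b <- its2_structure("AGAAACT", "((...))")
  rep_ab <- detect_cbc(a, b, window = integer(0))
  expect_equal(nrow(rep_ab$cbc), 1)
  expect_equal(rep_ab$cbc[1, ], c(1L, 7L))
  expect_equal(nrow(rep_ab$hemi_cbc), 0)
  # outer pair G-C -> G-U, one side changed: hemi-CBC
  h <- its2_structure("GGAAATC", "((...))")
  rep_ah <- detect_cbc(a, h, window = integer(0))
  expect_equal(nrow(rep_ah$cbc), 0)
  expect_equal(nrow(rep_ah$hemi_cbc), 1)
})

test_that("CBC reports equal an exhaustive paired-column scan", {
  sc <- its2_scaffold()
  set.seed(33)
  for (rep in 1:5) {
    seq_b <- sc$sequence
    sw <- sc$swappable_pairs[sample.int(nrow(sc$swappable_pairs), 3), , drop = FALSE]
    ch <- strsplit(seq_b, "")[[1]]
    map <- c(A = "G", T = "C", G = "A", C = "T")
    for (r in seq_len(nrow(sw))) {
      ch[sw[r, 1]] <- map[[ch[sw[r, 1]]]]
      ch[sw[r, 2]] <- map[[ch[sw[r, 2]]]]
    }
    # one hemi change at another pair (G-C -> G-T keeps GU wobble)
    rest <- setdiff(seq_len(nrow(sc$swappable_pairs)), sw)
    for (cand in sample(rest)) {
      i <- sc$swappable_pairs[cand, 1]; j <- sc$swappable_pairs[cand, 2]
      if (ch[i] == "G" && ch[j] == "C") { ch[j] <- "T"; break }
    }
    seq_b <- paste(ch, collapse = "")
    a <- its2_structure(sc$sequence, sc$dotbracket)
    b <- its2_structure(seq_b, sc$dotbracket)
    got <- detect_cbc(a, b)
    # independent oracle: sequences are unaligned-identical in length, so
    # scan every pair of a directly
    pa <- dotbracket_pairs(sc$dotbracket)
    ba <- strsplit(chartr("T", "U", sc$sequence), "")[[1]]
    bb <- strsplit(chartr("T", "U", seq_b), "")[[1]]
    canon <- c("AU", "UA", "GC", "CG", "GU", "UG")
    n_cbc <- 0; n_hemi <- 0
    for (i in which(!is.na(pa) & pa > seq_along(pa))) {
      j <- pa[i]
      if (!paste0(bb[i], bb[j]) %in% canon) next
      nd <- (ba[i] != bb[i]) + (ba[j] != bb[j])
      if (nd == 2) n_cbc <- n_cbc + 1
      if (nd == 1) n_hemi <- n_hemi + 1
    }
    expect_equal(nrow(got$cbc), n_cbc)
    expect_equal(nrow(got$hemi_cbc), n_hemi)
  }
})

test_that("CBC detection is symmetric", {
  sc <- its2_scaffold()
  a <- its2_structure(sc$sequence, sc$dotbracket)
  ch <- strsplit(sc$sequence, "")[[1]]
  ch[sc$cbc_site[1]] <- "G"; ch[sc$cbc_site[2]] <- "C"
  b <- its2_structure(paste(ch, collapse = ""), sc$dotbracket)
  ab <- detect_cbc(a, b)
  ba <- detect_cbc(b, a)
  expect_equal(nrow(ab$cbc), nrow(ba$cbc))
  expect_equal(ab$same_species, ba$same_species)
})

test_that("species delimitation separates apex-window CBCs only", {
  sc <- its2_scaffold()
  a <- its2_structure(sc$sequence, sc$dotbracket)
  # planted CBC inside the helix-III apex window -> different species
  ch <- strsplit(sc$sequence, "")[[1]]
  ch[sc$cbc_site[1]] <- "G"; ch[sc$cbc_site[2]] <- "C"
  b <- its2_structure(paste(ch, collapse = ""), sc$dotbracket)
  # CBC planted only in helix I -> same species
  ch2 <- strsplit(sc$sequence, "")[[1]]
  h1_pair <- sc$swappable_pairs[1, ]
  map <- c(A = "G", T = "C", G = "A", C = "T")
  ch2[h1_pair[1]] <- map[[ch2[h1_pair[1]]]]
  ch2[h1_pair[2]] <- map[[ch2[h1_pair[2]]]]
  c_ <- its2_structure(paste(ch2, collapse = ""), sc$dotbracket)

  part <- delimit_species(c("A", "B", "C"),
                          list(A = a, B = b, C = c_))
  expect_equal(part[["A"]], part[["C"]])   # same species despite helix-I CBC
  expect_false(part[["A"]] == part[["B"]]) # window CBC separates
  # identical sequences are the same species; result is a partition
  part2 <- delimit_species(c("X", "Y"), list(X = a, Y = a))
  expect_equal(part2[["X"]], part2[["Y"]])
  expect_length(part, 3)
  expect_false(any(is.na(part)))
})

test_that("an OTU without a structure becomes its own species with a warning", {
  sc <- its2_scaffold()
  a <- its2_structure(sc$sequence, sc$dotbracket)
  expect_warning(part <- delimit_species(c("A", "Z"), list(A = a)),
                 "no structure")
  expect_length(unique(part), 2)
})

test_that("Vienna round trip preserves records", {
  sc <- its2_scaffold()
  recs <- list(tpl1 = list(sequence = sc$sequence, dotbracket = sc$dotbracket))
  path <- tempfile(fileext = ".vienna")
  write_vienna(recs, path)
  expect_equal(read_vienna(path), recs)
})
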