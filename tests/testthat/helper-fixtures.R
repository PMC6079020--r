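# Canonical hallmark fixture (scaffold) and its single-violation mutants.

canonical_fixture <- function() {
  sc <- its2_scaffold()
  its2_structure(sc$sequence, sc$dotbracket)
}

# helix IV unfolded: four_helices becomes FALSE, everything else untouched
mutant_no_helix4 <- function() {
  sc <- its2_scaffold()
  p <- dotbracket_pairs(sc$dotbracket)
  ch <- strsplit(sc$dotbracket, "")[[1]]
  helix4_start <- length(ch) - 2 - (20 + 4 + 20) + 1  # t3 + helix IV block
  span <- seq.int(helix4_start, length(ch) - 2)
  ch[span] <- "."
  its2_structure(sc$sequence, paste(ch, collapse = ""))
}

# the 3' U of the helix-II internal loop mutated to C: no U-U mismatch
mutant_no_uu <- function() {
  sc <- its2_scaffold()
  seq <- strsplit(sc$sequence, "")[[1]]
  uu3 <- 2 + (24 + 4 + 24) + 2 + 10 + 1 + 10 + 4 + 10 + 1  # position of uu3
  stopifnot(seq[uu3] == "T")
  seq[uu3] <- "C"
  its2_structure(paste(seq, collapse = ""), sc$dotbracket)
}

# CGGC motif mutated to AGGA (A is not a pyrimidine): no YGGY in the window.
# The motif sits on the helix III stem, so its partners are adjusted to keep
# the pairs canonical (A-U), which does not affect the motif check.
mutant_no_yggy <- function() {
  sc <- its2_scaffold()
  seq <- strsplit(sc$sequence, "")[[1]]
  p <- dotbracket_pairs(sc$dotbracket)
  h3_start <- 2 + (24 + 4 + 24) + 2 + (10 + 1 + 10 + 4 + 10 + 1 + 10) + 2 + 1
  motif <- seq.int(h3_start + 24, h3_start + 27)  # arm positions 25..28
  stopifnot(paste(seq[motif], collapse = "") == "CGGC")
  seq[motif] <- c("A", "G", "G", "A")
  seq[p[motif[c(1, 4)]]] <- "T"
  its2_structure(paste(seq, collapse = ""), sc$dotbracket)
}
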