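#' The canonical ITS2 scaffold used by the simulator and fixtures
#'
#' A hand-designed ITS2-like sequence (DNA, 216 nt) whose declared secondary
#' structure shows the three eukaryotic hallmarks: four helices around an
#' open basal loop, a U-U mismatch (1x1 internal loop) in helix II, and a
#' YGGY motif (CGGC) on the 5' strand of helix III inside the apex window.
#' The structure is declared, not folded: base-pair maximisation does not
#' recover multibranch architectures, and supplying the structure keeps the
#' fixture exact.
#'
#' @return A list with `sequence` (DNA), `dotbracket`, `cbc_site` (the
#'   helix-III apex-window pair used for planting CBCs, 2 positions),
#'   `mutable_unpaired` (unpaired positions free to mutate; excludes the U-U
#'   mismatch), `swappable_pairs` (2-column matrix of pairs outside the
#'   helix-III apex window that may be swapped compensatorily).
#' @export
its2_scaffold <- function() {
  rc <- function(x) reverse_complement(x)
  h1 <- "GGCAGTCCGATGGTGCAGTCGAGC"      # 24
  h2a <- "GCTCCAGCTG"                   # 10
  h2b <- "CACGGATCGG"                   # 10
  h3 <- "GAGGCATCACTGCACCTGATCGACCGGCCA" # 30; CGGC at arm pos 25-28, CBC site 23
  h4 <- "CCGTTGAGGTCACCTGGTCA"          # 20
  segs <- list(
    t5 = "AA",
    h1_5 = h1, loop1 = "AATC", h1_3 = rc(h1),
    s1 = "AA",
    h2a = h2a, uu5 = "T", h2b = h2b, loop2 = "CAAT",
    h2b_rc = rc(h2b), uu3 = "T", h2a_rc = rc(h2a),
    s2 = "AA",
    h3_5 = h3, loop3 = "GAAA", h3_3 = rc(h3),
    s3 = "AA",
    h4_5 = h4, loop4 = "AAAC", h4_3 = rc(h4),
    t3 = "AA"
  )
  br <- function(seg, ch) strrep(ch, nchar(segs[[seg]]))
  db <- paste0(
    br("t5", "."),
    br("h1_5", "("), br("loop1", "."), br("h1_3", ")"),
    br("s1", "."),
    br("h2a", "("), ".", br("h2b", "("), br("loop2", "."),
    br("h2b_rc", ")"), ".", br("h2a_rc", ")"),
    br("s2", "."),
    br("h3_5", "("), br("loop3", "."), br("h3_3", ")"),
    br("s3", "."),
    br("h4_5", "("), br("loop4", "."), br("h4_3", ")"),
    br("t3", ".")
  )
  seq <- paste(unlist(segs), collapse = "")
  pairs <- dotbracket_pairs(db)
  # mutable unpaired positions: all unpaired minus the two U-U mismatch bases
  uu <- which(uu_positions(segs))
  unpaired <- setdiff(which(is.na(pairs)), uu)
  h3_start <- cum_start(segs, "h3_5")
  window_pos <- seq.int(h3_start + 20L, h3_start + 29L)  # arm pos 21..30
  pl <- cbind(which(!is.na(pairs) & pairs > seq_along(pairs)),
              pairs[!is.na(pairs) & pairs > seq_along(pairs)])
  in_window <- pl[, 1] %in% window_pos | pl[, 2] %in% window_pos
  cbc_site <- pl[pl[, 1] == h3_start + 22L, , drop = TRUE]  # arm pos 23
  list(sequence = seq, dotbracket = db,
       cbc_site = as.integer(cbc_site),
       mutable_unpaired = as.integer(unpaired),
       swappable_pairs = pl[!in_window, , drop = FALSE])
}

cum_start <- function(segs, name) {
  lens <- vapply(segs, nchar, integer(1))
  idx <- match(name, names(segs))
  as.integer(sum(lens[seq_len(idx - 1)]) + 1L)
}

uu_positions <- function(segs) {
  lens <- vapply(segs, nchar, integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  out <- rep(FALSE, sum(lens))
  out[starts[match("uu5", names(segs))]] <- TRUE
  out[starts[match("uu3", names(segs))]] <- TRUE
  out
}

#' Simulation configuration
#'
#' Defines the simulated study: 4 polar regions with 3 samples each, a
#' template pool with configured endemic / Arctic-shared / entire-Arctic /
#' bipolar composition, per-region category read-share targets in the regime
#' the survey observed (bipolar reads dominant where bipolar taxa occur,
#' endemic taxa numerous but read-poor), a heavy-tailed (log-normal)
#' within-category abundance law, MiSeq-like 150 nt paired reads over a
#' 264 nt amplicon, uniform per-base substitution error, and PCR chimera
#' formation.
#'
#' @param regions Region labels (first is the Antarctic pole by default
#'   scheme).
#' @param samples_per_region Samples (sites) per region.
#' @param n_endemic Named integer vector: endemic templates per region.
#' @param n_arctic_shared,n_entire_arctic,n_bipolar Template counts per
#'   category.
#' @param share_targets Region x category matrix of target read shares
#'   (rows sum to 1 over categories with templates present).
#' @param sigma_log Log-normal sigma of within-category abundance weights.
#' @param reads_per_sample Read pairs per sample.
#' @param error_rate Per-base substitution error rate.
#' @param chimera_rate Probability a read is a two-template PCR chimera.
#' @param read_len Read length (mates are cut from the amplicon with a
#'   2*read_len - amplicon overlap).
#' @param qual Constant Phred quality assigned to simulated bases.
#' @param fwd_primer,rev_primer PCR primers decorating the amplicon.
#' @param scheme A [region_scheme()] consistent with `regions`.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(regions = c("Antarctica", "Svalbard", "Greenland", "Alaska"),
                       samples_per_region = 3,
                       n_endemic = c(Antarctica = 14, Svalbard = 8,
                                     Greenland = 4, Alaska = 10),
                       n_arctic_shared = 4,
                       n_entire_arctic = 2,
                       n_bipolar = 4,
                       share_targets = NULL,
                       sigma_log = 1.2,
                       reads_per_sample = 20000,
                       error_rate = 0.001,
                       chimera_rate = 0.02,
                       read_len = 150,
                       qual = 35,
                       fwd_primer = "GCATCGATGAAGAACGCAGC",
                       rev_primer = "GGGATCCATATGCTTAAGTTCAGCGGGT",
                       scheme = region_scheme(),
                       seed = 1) {
  cats <- c("endemic", "arctic_shared", "entire_arctic", "bipolar")
  if (is.null(share_targets)) {
    share_targets <- rbind(
      Antarctica = c(endemic = 0.877, arctic_shared = 0.000,
                     entire_arctic = 0.000, bipolar = 0.123),
      Svalbard   = c(endemic = 0.300, arctic_shared = 0.120,
                     entire_arctic = 0.102, bipolar = 0.478),
      Greenland  = c(endemic = 0.150, arctic_shared = 0.100,
                     entire_arctic = 0.066, bipolar = 0.684),
      Alaska     = c(endemic = 0.450, arctic_shared = 0.150,
                     entire_arctic = 0.128, bipolar = 0.272)
    )
  }
  stopifnot(setequal(rownames(share_targets), regions),
            setequal(colnames(share_targets), cats),
            all(share_targets >= 0), all(rowSums(share_targets) <= 1 + 1e-9),
            error_rate >= 0, error_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            all(names(n_endemic) == regions))
  structure(list(
    regions = regions, samples_per_region = samples_per_region,
    n_endemic = n_endemic, n_arctic_shared = n_arctic_shared,
    n_entire_arctic = n_entire_arctic, n_bipolar = n_bipolar,
    share_targets = share_targets[regions, cats, drop = FALSE],
    sigma_log = sigma_log, reads_per_sample = reads_per_sample,
    error_rate = error_rate, chimera_rate = chimera_rate,
    read_len = read_len, qual = qual,
    fwd_primer = fwd_primer, rev_primer = rev_primer,
    scheme = scheme, seed = as.integer(seed)
  ), class = "sim_config")
}

region_coords <- function(region) {
  switch(region,
         Antarctica = c(-69.2, 39.6),
         Svalbard = c(78.9, 11.9),
         Greenland = c(67.1, -50.1),
         Alaska = c(63.1, -145.5),
         c(0, 0))
}

#' Sample metadata implied by a simulation configuration
#'
#' @param config A [sim_config()].
#' @return A metadata data frame (`sample_id`, `site`, `region`, `lat`,
#'   `lon`, `i7`, `i5`); index pairs are unique 8-mers.
#' @export
sim_sample_metadata <- function(config) {
  rows <- list()
  k <- 0L
  for (R in config$regions) {
    for (s in seq_len(config$samples_per_region)) {
      k <- k + 1L
      co <- region_coords(R)
      rows[[k]] <- data.frame(
        sample_id = sprintf("%s_%02d", substr(R, 1, 3), s),
        site = sprintf("%s site %d", R, s),
        region = R,
        lat = co[1] + 0.3 * (s - 2),
        lon = co[2] + 0.4 * (s - 2),
        i7 = index_seq(2L * k), i5 = index_seq(2L * k + 1L),
        stringsAsFactors = FALSE)
    }
  }
  validate_sample_metadata(do.call(rbind, rows))
}

index_seq <- function(k, width = 8) {
  digits <- integer(width)
  for (i in seq_len(width)) {
    digits[i] <- k %% 4L
    k <- k %/% 4L
  }
  paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
}

mutate_positions <- function(seq, pos, rng_bases) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_along(pos)) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[pos[i]])
    ch[pos[i]] <- alt[rng_bases[i]]
  }
  paste(ch, collapse = "")
}

swap_pair <- function(seq, i, j) {
  # compensatory swap: AT<->GC keeping canonical pairing (full CBC)
  map <- c(A = "G", T = "C", G = "A", C = "T")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[i] <- map[[ch[i]]]
  ch[j] <- map[[ch[j]]]
  paste(ch, collapse = "")
}

# CBC-site states cycle through mutually-CBC canonical pairs
cbc_state_pair <- function(state) {
  list(c("A", "T"), c("G", "C"), c("C", "G"), c("T", "A"))[[((state - 1) %% 4) + 1]]
}

#' Build a ground-truth metacommunity of ITS2 templates
#'
#' Templates descend from the scaffold through a group / species / OTU
#' hierarchy: group ancestors are strongly diverged (loop mutations plus
#' compensatory stem swaps, structure preserved), species within a group
#' differ by a planted compensatory base change at the helix-III apex-window
#' site (plus neutral divergence), OTU ancestors within a species differ by
#' >2% neutral divergence, and each template is an OTU ancestor. Every
#' template gets a biogeographic category and a consistent region set, and a
#' per-region expected read-share drawn from a renormalised log-normal
#' abundance law, so realized expected shares hit the configured targets
#' exactly.
#'
#' @param config A [sim_config()].
#' @return A `metacommunity`: list with `templates` (data frame:
#'   `template_id`, `sequence`, `group`, `species`, `otu_ancestor`,
#'   `category`, `regions`), `structure` (shared dot-bracket), `shares`
#'   (template x region expected-share matrix), `samples` (metadata),
#'   `config`.
#' @export
build_metacommunity <- function(config = sim_config()) {
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(config$seed)
  sc <- its2_scaffold()
  cats <- c(rep("endemic", sum(config$n_endemic)),
            rep("arctic_shared", config$n_arctic_shared),
            rep("entire_arctic", config$n_entire_arctic),
            rep("bipolar", config$n_bipolar))
  n_t <- length(cats)
  regions_of <- vector("list", n_t)
  k <- 0L
  for (R in config$regions) {
    for (i in seq_len(config$n_endemic[[R]])) {
      k <- k + 1L
      regions_of[[k]] <- R
    }
  }
  arc <- config$scheme$arctic
  shared_pairs <- list(arc[1:2], arc[1:2], arc[2:3], arc[c(1, 3)])
  for (i in seq_len(config$n_arctic_shared)) {
    k <- k + 1L
    regions_of[[k]] <- shared_pairs[[((i - 1) %% length(shared_pairs)) + 1]]
  }
  for (i in seq_len(config$n_entire_arctic)) {
    k <- k + 1L
    regions_of[[k]] <- arc
  }
  for (i in seq_len(config$n_bipolar)) {
    k <- k + 1L
    regions_of[[k]] <- config$regions
  }
  # group / species / OTU hierarchy big enough for the pool
  groups <- c("Chlamydomonas-snow group B", "Raphidonema group",
              "Chloromonadinia-snow group G")
  species_per_group <- 4
  otus_per_species <- 4
  n_otus <- length(groups) * species_per_group * otus_per_species
  if (n_t > 2 * n_otus) stop("template pool too large for the built-in hierarchy")
  group_anc <- lapply(seq_along(groups), function(g) {
    s <- sc$sequence
    pos <- sample(sc$mutable_unpaired, 10)
    s <- mutate_positions(s, pos, sample.int(3, 10, replace = TRUE))
    sw <- sc$swappable_pairs[sample.int(nrow(sc$swappable_pairs), 6), , drop = FALSE]
    for (r in seq_len(nrow(sw))) s <- swap_pair(s, sw[r, 1], sw[r, 2])
    s
  })
  otu_seqs <- character(n_otus)
  otu_meta <- data.frame(otu_ancestor = sprintf("anc%03d", seq_len(n_otus)),
                         group = character(n_otus), species = character(n_otus),
                         g_idx = integer(n_otus), sp_idx = integer(n_otus),
                         ot_idx = integer(n_otus), stringsAsFactors = FALSE)
  o <- 0L
  for (g in seq_along(groups)) {
    for (sp in seq_len(species_per_group)) {
      # species: planted CBC state at the apex-window site + neutral divergence
      s_sp <- group_anc[[g]]
      st_pair <- cbc_state_pair(sp)
      ch <- strsplit(s_sp, "", fixed = TRUE)[[1]]
      ch[sc$cbc_site[1]] <- st_pair[1]
      ch[sc$cbc_site[2]] <- st_pair[2]
      s_sp <- paste(ch, collapse = "")
      pos <- sample(sc$mutable_unpaired, 2)
      s_sp <- mutate_positions(s_sp, pos, sample.int(3, 2, replace = TRUE))
      for (ot in seq_len(otus_per_species)) {
        o <- o + 1L
        s_ot <- s_sp
        if (ot > 1) {
          pos <- sample(sc$mutable_unpaired, 5)
          s_ot <- mutate_positions(s_ot, pos, sample.int(3, 5, replace = TRUE))
        }
        # enforce the between-OTU divergence floor (>2%) against every
        # ancestor generated so far; CBC-site swaps alone are not enough.
        # Mutations target positions where the closest ancestor still agrees,
        # so every iteration strictly increases the distance.
        if (o > 1) {
          repeat {
            ham <- cpp_hamming_identity(s_ot, otu_seqs[seq_len(o - 1L)])
            if (all(ham < 0.977)) break
            worst <- otu_seqs[which.max(ham)]
            same <- intersect(
              sc$mutable_unpaired,
              which(strsplit(s_ot, "")[[1]] == strsplit(worst, "")[[1]]))
            if (length(same) == 0) break  # cannot happen with a 30-site pool
            pos <- sample(same, min(2L, length(same)))
            s_ot <- mutate_positions(s_ot, pos,
                                     sample.int(3, length(pos), replace = TRUE))
          }
        }
        otu_seqs[o] <- s_ot
        otu_meta$group[o] <- groups[g]
        otu_meta$species[o] <- sprintf("%s|sp%02d", groups[g], sp + (g - 1) * species_per_group)
        otu_meta$g_idx[o] <- g
        otu_meta$sp_idx[o] <- sp
        otu_meta$ot_idx[o] <- ot
      }
    }
  }
  if (anyDuplicated(otu_seqs)) stop("internal: duplicate OTU ancestor sequences")
  # interleave ancestors across groups and species so that even small pools
  # span the whole hierarchy (groups first, then species, then extra OTUs)
  ord <- order(otu_meta$ot_idx, otu_meta$sp_idx, otu_meta$g_idx)
  otu_seqs <- otu_seqs[ord]
  otu_meta <- otu_meta[ord, , drop = FALSE]
  # assign templates to OTU ancestors round-robin over a reduced ancestor set
  # so roughly a third of OTUs carry two templates (within-OTU divergence <2%)
  n_used <- min(n_otus, max(1L, ceiling(n_t / 1.5)))
  otu_of_template <- ((seq_len(n_t) - 1L) %% n_used) + 1L
  templates <- data.frame(
    template_id = sprintf("tpl%03d", seq_len(n_t)),
    sequence = otu_seqs[otu_of_template],
    group = otu_meta$group[otu_of_template],
    species = otu_meta$species[otu_of_template],
    otu_ancestor = otu_meta$otu_ancestor[otu_of_template],
    category = cats,
    regions = vapply(regions_of, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE)
  # second template on the same OTU ancestor: add <2% within-OTU divergence
  dup <- duplicated(templates$sequence)
  for (i in which(dup)) {
    repeat {
      pos <- sample(sc$mutable_unpaired, 2)
      cand <- mutate_positions(templates$sequence[i], pos,
                               sample.int(3, 2, replace = TRUE))
      if (!cand %in% templates$sequence) break
    }
    templates$sequence[i] <- cand
  }
  # expected per-region shares: renormalised log-normal within category
  shares <- matrix(0, n_t, length(config$regions),
                   dimnames = list(templates$template_id, config$regions))
  w <- matrix(rlnorm(n_t * length(config$regions), 0, config$sigma_log),
              n_t, length(config$regions))
  for (R in config$regions) {
    for (cc in colnames(config$share_targets)) {
      target <- config$share_targets[R, cc]
      members <- which(templates$category == cc &
                         vapply(regions_of, function(x) R %in% x, logical(1)))
      if (length(members) == 0) {
        if (target > 0) stop("infeasible share target: no ", cc, " templates in ", R)
        next
      }
      ww <- w[members, match(R, config$regions)]
      shares[members, R] <- target * ww / sum(ww)
    }
  }
  structure(list(templates = templates, structure = sc$dotbracket,
                 shares = shares, samples = sim_sample_metadata(config),
                 config = config),
            class = "metacommunity")
}

preserve_rng <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate paired amplicon reads from a metacommunity
#'
#' Per sample: multinomial template sampling from the region's expected
#' shares, PCR chimera formation (two distinct sampled templates spliced at
#' a uniform crossover of the amplicon), per-base substitution errors at the
#' configured rate on each mate, constant quality scores, primer decoration
#' and dual-index annotation in the read headers. Mates are the first and
#' last `read_len` bases of the amplicon.
#'
#' @param mc A `metacommunity` from [build_metacommunity()].
#' @param out_dir Directory for `reads_R1.fastq` / `reads_R2.fastq` and
#'   `metadata.tsv`; created if needed.
#' @return A `sim_truth`: list with `fastq_fwd`, `fastq_rev`, `metadata`
#'   (path), `samples`, `templates`, `reads` (data frame: `sample_id`,
#'   `template_id`, `chimera`, `insert` -- the realized error-bearing insert
#'   a perfect merger would reconstruct), `config`.
#' @export
simulate_reads <- function(mc, out_dir = tempfile("simreads")) {
  config <- mc$config
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(config$seed + 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fwd_p <- config$fwd_primer
  rev_p_rc <- reverse_complement(config$rev_primer)
  amplicons <- paste0(fwd_p, mc$templates$sequence, rev_p_rc)
  L <- unique(nchar(amplicons))
  if (length(L) != 1) stop("templates must share one amplicon length")
  rl <- config$read_len
  if (rl > L) stop("read length exceeds amplicon length")
  if (2 * rl - L < 1) stop("mates do not overlap; increase read_len")
  qual_str <- strrep(rawToChar(as.raw(33 + config$qual)), rl)
  md <- mc$samples
  all_fwd <- list(); all_rev <- list(); truth <- list()
  for (si in seq_len(nrow(md))) {
    smp <- md$sample_id[si]
    R <- md$region[si]
    probs <- mc$shares[, R]
    n <- config$reads_per_sample
    counts <- as.vector(rmultinom(1, n, probs))
    tpl_idx <- rep.int(seq_along(probs), counts)
    tpl_idx <- tpl_idx[sample.int(length(tpl_idx))]
    amp <- amplicons[tpl_idx]
    chim <- runif(n) < config$chimera_rate
    present <- which(probs > 0)
    for (i in which(chim)) {
      ab <- sample(present, 2, prob = probs[present])
      x <- sample.int(L - 1L, 1)
      amp[i] <- paste0(substr(amplicons[ab[1]], 1, x),
                       substr(amplicons[ab[2]], x + 1, L))
    }
    fwd <- substr(amp, 1, rl)
    rev_rc <- substr(amp, L - rl + 1L, L)  # reverse mate, plus strand
    nerr_f <- rbinom(n, rl, config$error_rate)
    nerr_r <- rbinom(n, rl, config$error_rate)
    for (i in which(nerr_f > 0)) {
      pos <- sample.int(rl, nerr_f[i])
      fwd[i] <- mutate_positions(fwd[i], pos, sample.int(3, nerr_f[i], replace = TRUE))
    }
    for (i in which(nerr_r > 0)) {
      pos <- sample.int(rl, nerr_r[i])
      rev_rc[i] <- mutate_positions(rev_rc[i], pos, sample.int(3, nerr_r[i], replace = TRUE))
    }
    # realized insert: forward mate wins in the overlap (equal qualities)
    merged <- paste0(fwd, substr(rev_rc, 2L * rl - L + 1L, rl))
    insert <- substr(merged, nchar(fwd_p) + 1L, L - nchar(rev_p_rc))
    ids <- sprintf("sim:%s:%06d %s+%s", smp, seq_len(n), md$i7[si], md$i5[si])
    all_fwd[[si]] <- data.frame(id = ids, seq = fwd, qual = qual_str,
                                stringsAsFactors = FALSE)
    all_rev[[si]] <- data.frame(id = ids, seq = reverse_complement(rev_rc),
                                qual = qual_str, stringsAsFactors = FALSE)
    truth[[si]] <- data.frame(
      sample_id = smp,
      template_id = ifelse(chim, NA_character_, mc$templates$template_id[tpl_idx]),
      chimera = chim, insert = insert, stringsAsFactors = FALSE)
  }
  fq1 <- file.path(out_dir, "reads_R1.fastq")
  fq2 <- file.path(out_dir, "reads_R2.fastq")
  write_fastq(do.call(rbind, all_fwd), fq1)
  write_fastq(do.call(rbind, all_rev), fq2)
  md_path <- file.path(out_dir, "metadata.tsv")
  write.table(md, md_path, sep = "\t", quote = FALSE, row.names = FALSE)
  structure(list(fastq_fwd = fq1, fastq_rev = fq2, metadata = md_path,
                 samples = md, templates = mc$templates, reads = do.call(rbind, truth),
                 structure = mc$structure, shares = mc$shares, config = config),
            class = "sim_truth")
}

#' Ground-truth biogeographic summary of a simulated read set
#'
#' What a perfect observer of the realized reads would compute with the
#' pipeline's own unit definitions: non-chimeric realized unique insert
#' sequences with at least `min_total` reads, classified by their true
#' region presence. A chimera-spliced sequence identical to a template
#' counts as that template's sequence. With zero sequencing error and zero
#' chimeras this equals the template-level configured truth.
#'
#' @param truth A `sim_truth`.
#' @param min_total Minimum total reads for a unique sequence to enter the
#'   summary (default 2, mirroring singleton removal).
#' @return A list with `summary` (a `biogeo_summary`), `classification`, and
#'   `cm` (the truth-level `community_matrix`).
#' @export
truth_summary <- function(truth, min_total = 2) {
  rd <- truth$reads
  is_template_seq <- rd$insert %in% truth$templates$sequence
  # unique sequences whose every read is a chimera splice and which match no
  # template are artefacts; everything else is a real realized sequence
  seq_chim <- tapply(rd$chimera & !is_template_seq, rd$insert, all)
  valid_seqs <- names(seq_chim)[!seq_chim]
  rd <- rd[rd$insert %in% valid_seqs & (!rd$chimera | is_template_seq), , drop = FALSE]
  tab <- table(rd$insert, factor(rd$sample_id, levels = truth$samples$sample_id))
  counts <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  keep <- rowSums(counts) >= min_total
  counts <- counts[keep, , drop = FALSE]
  seqs <- rownames(counts)
  ids <- sprintf("true%05d", seq_len(nrow(counts)))
  rownames(counts) <- ids
  cm <- community_matrix(t(counts), truth$samples)
  cls <- classify_all_taxa(cm, truth$config$scheme)
  list(summary = read_share_summary(cm, cls, truth$config$scheme),
       classification = cls, cm = cm,
       sequences = setNames(seqs, ids))
}

#' Score a pipeline run against the simulation ground truth
#'
#' @param pipeline A result of [run_pipeline()] on the simulated reads.
#' @param truth A `sim_truth`.
#' @return A list with `confusion` (truth x estimated category table over
#'   sequence-matched taxa), `share_errors` (per-region absolute errors of
#'   endemic unique fraction and bipolar read share, estimate vs realized
#'   truth), `otu_purity`, `truth_summary`, `estimate_summary`.
#' @export
evaluate_recovery <- function(pipeline, truth) {
  ts <- truth_summary(truth)
  est <- pipeline$biogeo_summary
  tru <- ts$summary
  regs <- tru$per_region$region
  if (!identical(sort(regs), sort(est$per_region$region))) {
    stop("region mismatch between pipeline output and truth")
  }
  eo <- est$per_region[match(regs, est$per_region$region), ]
  share_errors <- data.frame(
    region = regs,
    endemic_unique_fraction_error =
      abs(eo$endemic_unique_fraction - tru$per_region$endemic_unique_fraction),
    bipolar_read_share_error =
      abs(eo$bipolar_read_share - tru$per_region$bipolar_read_share),
    stringsAsFactors = FALSE)
  # category confusion over sequence-matched taxa
  truth_cat <- setNames(ts$classification$category, ts$sequences[ts$classification$taxon_id])
  est_tab <- pipeline$pset$tab
  est_cat <- setNames(pipeline$classification$category, pipeline$classification$taxon_id)
  matched <- est_tab$sequence %in% names(truth_cat)
  confusion <- table(truth = truth_cat[est_tab$sequence[matched]],
                     estimated = est_cat[est_tab$phylotype_id[matched]])
  # OTU purity: members must share one template (OTU-ancestor) origin
  rd <- truth$reads[!truth$reads$chimera, c("insert", "template_id")]
  anc_of_tpl <- setNames(truth$templates$otu_ancestor, truth$templates$template_id)
  maj <- tapply(anc_of_tpl[rd$template_id], rd$insert, function(x) {
    names(sort(table(x), decreasing = TRUE))[1]
  })
  anc_of_seq <- setNames(as.character(maj), names(maj))
  purity <- NA_real_
  if (length(pipeline$otus$otus) > 0) {
    pure <- vapply(pipeline$otus$otus, function(o) {
      seqs <- est_tab$sequence[match(o$members, est_tab$phylotype_id)]
      anc <- unique(stats::na.omit(anc_of_seq[seqs]))
      length(anc) <= 1
    }, logical(1))
    purity <- mean(pure)
  }
  list(confusion = confusion, share_errors = share_errors, otu_purity = purity,
       truth_summary = tru, estimate_summary = est)
}
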