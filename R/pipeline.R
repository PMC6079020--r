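#' Pipeline run configuration
#'
#' Collects all stage parameters (defaults as documented on each stage
#' function) plus input paths. Paths are validated before any stage runs.
#'
#' @param fastq_fwd,fastq_rev Paired FASTQ paths (index annotations in the
#'   forward headers).
#' @param metadata Sample metadata TSV path (see [read_sample_metadata()]).
#' @param fwd_primer,rev_primer Amplicon primers; the reverse primer is
#'   searched at the 3' end of the merged read as its reverse complement.
#' @param max_primer_mismatch Maximum primer mismatches (default 4).
#' @param qmin Quality truncation threshold (default 3).
#' @param min_len Minimum merged-read length (default 50).
#' @param min_overlap,max_mismatch_frac Read-merging parameters.
#' @param contaminants Optional named vector of contaminant sequences.
#' @param otu_id_threshold,cov_threshold OTU clustering gates (0.98 / 0.80).
#' @param min_skew,min_gain,max_parents Chimera-screen parameters.
#' @param reference_db Optional reference data frame
#'   (see [reference_records()]); when present, OTUs whose centroid is not
#'   assigned to any reference group are excluded.
#' @param marker `"ITS2"` or `"18S"`.
#' @param structures Optional named character vector: dot-bracket strings
#'   keyed by exact sequence (overrides built-in folding), or a path to a
#'   Vienna file whose records are matched by sequence.
#' @param apex_window Helix-III apex window size (default 10).
#' @param n_perm Permutations for PERMANOVA / Mantel (default 999).
#' @param network_subsample Taxa sub-sampled for the co-occurrence network
#'   (default 20000).
#' @param out_dir Optional artifact directory.
#' @param seed Global seed for all stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fastq_fwd, fastq_rev, metadata,
                            fwd_primer, rev_primer,
                            max_primer_mismatch = 4,
                            qmin = 3, min_len = 50,
                            min_overlap = 16, max_mismatch_frac = 0.25,
                            contaminants = NULL,
                            otu_id_threshold = 0.98, cov_threshold = 0.80,
                            min_skew = 2.0, min_gain = 0.02, max_parents = 40,
                            reference_db = NULL, marker = "ITS2",
                            structures = NULL, apex_window = 10,
                            n_perm = 999, network_subsample = 20000,
                            out_dir = NULL, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  for (f in c("fastq_fwd", "fastq_rev", "metadata")) {
    if (!is.character(cfg[[f]]) || !file.exists(cfg[[f]])) {
      stop("configuration error: missing input file for '", f, "'")
    }
  }
  if (!cfg$marker %in% c("ITS2", "18S")) stop("marker must be ITS2 or 18S")
  if (is.character(cfg$structures) && length(cfg$structures) == 1 &&
      file.exists(cfg$structures)) {
    recs <- read_vienna(cfg$structures)
    cfg$structures <- setNames(
      vapply(recs, `[[`, character(1), "dotbracket"),
      vapply(recs, `[[`, character(1), "sequence"))
  }
  invisible(cfg)
}

#' Run the full ITS2 biogeography pipeline
#'
#' Stage order: demultiplex -> quality truncation -> pair merging -> quality
#' filters -> primer trimming -> dereplication -> de novo chimera screen ->
#' singleton removal -> 98% OTU clustering -> taxonomic filtering (when a
#' reference database is supplied) -> secondary-structure hallmarks and CBC
#' species delimitation -> biogeographic classification and read-share
#' accounting -> community statistics -> co-occurrence network. Each stage
#' feeds the QC ledger; identical configuration and seed give identical
#' outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return A `pipeline_result` list with `ledger`, `pset` (analysed
#'   phylotypes), `otus`, `otu_counts`, `chimera_report`, `taxonomy`,
#'   `hallmarks`, `species`, `cm`, `classification`, `biogeo_summary`,
#'   `stats`, `network`, `summary`.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_pipeline_config(cfg)
  ledger <- new_ledger()
  md <- read_sample_metadata(cfg$metadata)
  fwd <- read_fastq(cfg$fastq_fwd)
  rev <- read_fastq(cfg$fastq_rev)

  dm <- demultiplex(fwd, rev, md)
  ledger <- ledger_add(ledger, "demultiplex", nrow(fwd), sum(dm$n_assigned),
                       c(index_mismatch = dm$n_discarded))

  merged_by_sample <- list()
  n_pairs <- sum(dm$n_assigned)
  n_merge_fail <- 0L
  n_amb <- 0L; n_short <- 0L; n_contam <- 0L
  n_primer_fail <- 0L
  seqs_by_sample <- list()
  for (s in md$sample_id) {
    pr <- dm$by_sample[[s]]
    f <- truncate_at_low_quality(pr$fwd, cfg$qmin)
    r <- truncate_at_low_quality(pr$rev, cfg$qmin)
    # pairs whose mates were truncated below the merge overlap cannot merge
    mg <- merge_read_pairs(f, r, cfg$min_overlap, cfg$max_mismatch_frac)
    n_merge_fail <- n_merge_fail + mg$n_failed
    qf <- quality_filter(mg$merged, cfg$min_len, cfg$contaminants)
    n_amb <- n_amb + qf$n_ambiguous
    n_short <- n_short + qf$n_short
    n_contam <- n_contam + qf$n_contaminant
    t5 <- trim_primer(qf$kept, cfg$fwd_primer, cfg$max_primer_mismatch, "5p")
    t3 <- trim_primer(t5$reads, cfg$rev_primer, cfg$max_primer_mismatch, "3p")
    ok <- t5$trimmed & t3$trimmed
    n_primer_fail <- n_primer_fail + sum(!ok)
    seqs_by_sample[[s]] <- t3$reads$seq[ok]
  }
  n_merged <- n_pairs - n_merge_fail
  ledger <- ledger_add(ledger, "merge", n_pairs, n_merged,
                       c(merge_failure = n_merge_fail))
  n_kept <- n_merged - n_amb - n_short - n_contam
  ledger <- ledger_add(ledger, "quality_filter", n_merged, n_kept,
                       c(ambiguous = n_amb, short = n_short,
                         contaminant = n_contam))
  n_trimmed <- n_kept - n_primer_fail
  ledger <- ledger_add(ledger, "primer_trim", n_kept, n_trimmed,
                       c(primer_not_found = n_primer_fail))

  pset <- dereplicate(seqs_by_sample)
  ledger <- ledger_add(ledger, "dereplicate", n_trimmed, sum(pset$tab$total_count))

  ch <- screen_chimeras(pset, cfg$min_skew, cfg$min_gain,
                        params = align_params(), max_parents = cfg$max_parents)
  n_chim_reads <- sum(pset$tab$total_count) - sum(ch$pset$tab$total_count)
  ledger <- ledger_add(ledger, "chimera_screen", sum(pset$tab$total_count),
                       sum(ch$pset$tab$total_count),
                       c(chimeric = n_chim_reads))
  pset <- ch$pset

  sg <- remove_singletons(pset)
  ledger <- ledger_add(ledger, "singleton_removal", sum(pset$tab$total_count),
                       sum(sg$pset$tab$total_count),
                       c(singleton = sg$n_removed))
  pset <- sg$pset

  cl <- cluster_phylotypes_to_otus(pset, cfg$otu_id_threshold, cfg$cov_threshold)

  taxonomy <- NULL
  if (!is.null(cfg$reference_db)) {
    cent_seq <- setNames(
      pset$tab$sequence[match(vapply(cl$otus, `[[`, character(1), "centroid"),
                              pset$tab$phylotype_id)],
      vapply(cl$otus, `[[`, character(1), "otu_id"))
    taxonomy <- assign_taxonomy_all(cent_seq, cfg$reference_db, cfg$marker)
    assigned_otus <- taxonomy$query_id[taxonomy$assigned]
    keep_pt <- pset$tab$phylotype_id[cl$otu_of[pset$tab$phylotype_id] %in% assigned_otus]
    n_before <- sum(pset$tab$total_count)
    keep_idx <- pset$tab$phylotype_id %in% keep_pt
    pset <- subset_phylotypes(pset, keep_idx)
    ledger <- ledger_add(ledger, "taxonomy_filter", n_before,
                         sum(pset$tab$total_count),
                         c(non_algal = n_before - sum(pset$tab$total_count)))
    cl$otus <- cl$otus[vapply(cl$otus, function(o) o$otu_id %in% assigned_otus,
                              logical(1))]
    cl$otu_counts <- cl$otu_counts[rownames(cl$otu_counts) %in% assigned_otus, ,
                                   drop = FALSE]
    cl$otu_of <- cl$otu_of[names(cl$otu_of) %in% keep_pt]
  }

  # secondary structure of OTU representatives: supplied structures first,
  # deterministic built-in folding otherwise
  structures <- list()
  hallmarks <- list()
  for (o in cl$otus) {
    seq <- pset$tab$sequence[match(o$centroid, pset$tab$phylotype_id)]
    if (is.na(seq)) next
    db <- if (!is.null(cfg$structures) && seq %in% names(cfg$structures)) {
      cfg$structures[[seq]]
    } else {
      fold_dotbracket(seq)
    }
    st <- its2_structure(seq, db, require_canonical = FALSE)
    structures[[o$otu_id]] <- st
    hm <- validate_hallmarks(st, cfg$apex_window)
    hallmarks[[o$otu_id]] <- data.frame(
      otu_id = o$otu_id, four_helices = hm$four_helices,
      helixII_UU = hm$helixII_UU,
      yggy = hm$yggy_helixIII_5prime_apex, overall = hm$overall,
      stringsAsFactors = FALSE)
  }
  hallmarks <- if (length(hallmarks)) do.call(rbind, hallmarks) else NULL

  # species delimitation per taxonomic group, among hallmark-passing OTUs
  species <- integer(0)
  if (length(structures) > 0) {
    group_of <- if (!is.null(taxonomy)) {
      setNames(taxonomy$group_label, taxonomy$query_id)
    } else {
      setNames(rep("all", length(structures)), names(structures))
    }
    passing <- hallmarks$otu_id[hallmarks$overall]
    offset <- 0L
    for (g in unique(group_of[names(structures)])) {
      ids <- intersect(names(structures)[group_of[names(structures)] == g], passing)
      if (length(ids) > 0) {
        part <- delimit_species(ids, structures, cfg$apex_window)
        species <- c(species, part + offset)
        offset <- offset + max(part)
      }
      solo <- setdiff(names(structures)[group_of[names(structures)] == g], ids)
      if (length(solo) > 0) {
        species <- c(species, setNames(offset + seq_along(solo), solo))
        offset <- offset + length(solo)
      }
    }
  }

  # biogeography at phylotype level
  counts <- t(pset$counts)
  cm <- community_matrix(counts, md)
  classification <- classify_all_taxa(cm, region_scheme_from(md))
  biogeo <- read_share_summary(cm, classification, region_scheme_from(md))

  # community statistics
  shannon_by_sample <- apply(cm$counts, 1, function(x) {
    if (sum(x) > 0) shannon(x) else NA_real_
  })
  bc <- bray_curtis_matrix(cm)
  stats <- list(shannon = shannon_by_sample)
  if (nrow(cm$counts) >= 2) {
    stats$upgma_newick <- upgma_newick(upgma(bc))
  }
  if (length(unique(md$region)) >= 2 && nrow(cm$counts) >= 4 &&
      nrow(cm$counts) > length(unique(md$region))) {
    stats$permanova <- permanova(bc, md$region, cfg$n_perm, seed = cfg$seed)
    geo <- geo_distance_matrix(md)
    stats$mantel <- mantel_test(bc, geo, cfg$n_perm, seed = cfg$seed)
  }
  network <- cooccurrence_network(cm, cfg$network_subsample, seed = cfg$seed)

  result <- structure(list(
    ledger = ledger, pset = pset, otus = cl, otu_counts = cl$otu_counts,
    chimera_report = chimera_report(ch$verdicts), taxonomy = taxonomy,
    hallmarks = hallmarks, species = species, cm = cm,
    classification = classification, biogeo_summary = biogeo,
    stats = stats, network = network,
    summary = pipeline_summary(ledger, pset, cl, biogeo, stats, cfg$seed)
  ), class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_artifacts(result, cfg)
  result
}

region_scheme_from <- function(md) {
  regs <- unique(md$region)
  ant <- intersect(regs, "Antarctica")
  if (length(ant) == 0) {
    # user-defined regions: single-pole scheme, everything "arctic"
    return(region_scheme(arctic = regs, antarctic = character(0)))
  }
  region_scheme(arctic = setdiff(regs, ant), antarctic = ant)
}

pipeline_summary <- function(ledger, pset, cl, biogeo, stats, seed) {
  list(
    seed = seed,
    ledger = ledger_table(ledger),
    n_phylotypes = nrow(pset$tab),
    n_reads_analysed = sum(pset$tab$total_count),
    n_otus = length(cl$otus),
    per_region = biogeo$per_region,
    overall = biogeo$overall,
    permanova_p = if (!is.null(stats$permanova)) stats$permanova$p_value else NA,
    mantel_p = if (!is.null(stats$mantel)) stats$mantel$p_value else NA
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$ledger)
  cat(sprintf("%d phylotypes in %d OTUs; %d reads analysed\n",
              nrow(x$pset$tab), length(x$otus$otus), sum(x$pset$tab$total_count)))
  print(x$biogeo_summary)
  invisible(x)
}

write_artifacts <- function(result, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  write.table(ledger_table(result$ledger), p("ledger.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_phylotypes(result$pset, p("phylotypes.fasta"), p("phylotype_counts.tsv"))
  if (length(result$otus$otus) > 0) {
    otu_map <- data.frame(phylotype_id = names(result$otus$otu_of),
                          otu_id = unname(result$otus$otu_of),
                          stringsAsFactors = FALSE)
    write.table(otu_map, p("otu_map.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cent <- vapply(result$otus$otus, `[[`, character(1), "centroid")
    cent_seq <- result$pset$tab$sequence[match(cent, result$pset$tab$phylotype_id)]
    ok <- !is.na(cent_seq)
    write_fasta(setNames(cent_seq[ok],
                         vapply(result$otus$otus, `[[`, character(1), "otu_id")[ok]),
                p("otu_centroids.fasta"))
  }
  write.table(result$chimera_report, p("chimera_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(result$taxonomy)) {
    write.table(result$taxonomy, p("taxonomy.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(result$hallmarks)) {
    write.table(result$hallmarks, p("hallmarks.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (length(result$species) > 0) {
    write.table(data.frame(otu_id = names(result$species),
                           species = unname(result$species)),
                p("species.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(result$classification, p("classification.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(result$biogeo_summary$per_region, p("biogeo_per_region.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$stats$upgma_newick)) {
    writeLines(result$stats$upgma_newick, p("dendrogram.nwk"))
  }
  export_network(result$network, p("network.graphml"), p("network_edges.tsv"))
  jsonlite::write_json(result$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = 10, dataframe = "rows")
  invisible(result)
}

#' Merge two phylotype sets (e.g., separate Arctic / Antarctic runs)
#'
#' Sums per-sample counts of identical sequences across runs (the
#' index-switching mitigation of running poles separately, merged before the
#' biogeography stage).
#'
#' @param a,b `phylotype_set`s with disjoint sample sets.
#' @return A combined, re-sorted `phylotype_set`.
#' @export
merge_phylotype_sets <- function(a, b) {
  if (length(intersect(colnames(a$counts), colnames(b$counts))) > 0) {
    stop("sample sets must be disjoint")
  }
  seqs <- sort(unique(c(a$tab$sequence, b$tab$sequence)), method = "radix")
  samples <- c(colnames(a$counts), colnames(b$counts))
  counts <- matrix(0L, length(seqs), length(samples),
                   dimnames = list(NULL, samples))
  counts[match(a$tab$sequence, seqs), colnames(a$counts)] <- a$counts
  counts[match(b$tab$sequence, seqs), colnames(b$counts)] <- b$counts
  total <- as.integer(rowSums(counts))
  ord <- order(-total, seqs, method = "radix")
  ids <- sprintf("pt%05d", seq_along(seqs))
  counts <- counts[ord, , drop = FALSE]
  rownames(counts) <- ids
  structure(list(
    tab = data.frame(phylotype_id = ids, sequence = seqs[ord],
                     total_count = total[ord], stringsAsFactors = FALSE),
    counts = counts
  ), class = "phylotype_set")
}
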