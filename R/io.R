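#' Read a FASTQ file into a read table
#'
#' Reads Sanger (Phred+33) FASTQ, plain or gzip-compressed, into a plain
#' data frame with one row per read. The full header line (minus the leading
#' `@`) is kept as `id`, so index annotations carried in the header survive.
#'
#' @param path Path to a `.fastq` or `.fastq.gz` file.
#' @return A data frame with columns `id`, `seq`, `qual` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a read table to FASTQ
#'
#' @param reads Data frame with columns `id`, `seq`, `qual`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Read/write FASTA
#'
#' Thin wrappers over Biostrings that return/accept named character vectors.
#'
#' @param path File path.
#' @return `read_fasta()`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @param seqs Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write phylotypes as abundance-annotated FASTA plus a per-sample TSV
#'
#' The FASTA uses USEARCH-style `;size=N` annotations; the sidecar TSV has one
#' row per (phylotype, sample) with a positive count.
#'
#' @param pset A `phylotype_set` (see [dereplicate()]).
#' @param fasta_path,tsv_path Output paths.
#' @export
write_phylotypes <- function(pset, fasta_path, tsv_path) {
  tab <- pset$tab
  seqs <- setNames(tab$sequence, sprintf("%s;size=%d", tab$phylotype_id, tab$total_count))
  write_fasta(seqs, fasta_path)
  idx <- which(pset$counts > 0, arr.ind = TRUE)
  side <- data.frame(
    phylotype_id = rownames(pset$counts)[idx[, 1]],
    sample_id = colnames(pset$counts)[idx[, 2]],
    count = pset$counts[idx],
    stringsAsFactors = FALSE
  )
  side <- side[order(side$phylotype_id, side$sample_id), ]
  write.table(side, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Read sample metadata
#'
#' Expects a TSV with header columns `sample_id`, `site`, `region`, `lat`,
#' `lon`, `i7`, `i5`. Sample ids and index pairs must be unique.
#'
#' @param path Path to the metadata TSV.
#' @return A validated data frame.
#' @export
read_sample_metadata <- function(path) {
  md <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_sample_metadata(md)
}

validate_sample_metadata <- function(md) {
  need <- c("sample_id", "site", "region", "lat", "lon", "i7", "i5")
  if (!all(need %in% names(md))) {
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  key <- paste(md$i7, md$i5, sep = "+")
  if (anyDuplicated(key)) stop("duplicate index pairs in metadata")
  if (any(md$lat < -90 | md$lat > 90)) stop("latitude out of range [-90, 90]")
  if (any(md$lon < -180 | md$lon > 180)) stop("longitude out of range [-180, 180]")
  md
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

reverse_string <- function(x) {
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

#' Read/write Vienna dot-bracket records
#'
#' A Vienna record is three lines: `>header`, sequence, dot-bracket string.
#'
#' @param path File path.
#' @return `read_vienna()`: a named list of `list(sequence=, dotbracket=)`.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3 != 0) stop("malformed Vienna file: ", path)
  out <- list()
  for (i in seq(1, length(lines), by = 3)) {
    if (!startsWith(lines[i], ">")) stop("malformed Vienna record at line ", i)
    id <- sub("^>", "", lines[i])
    out[[id]] <- list(sequence = lines[i + 1], dotbracket = lines[i + 2])
  }
  out
}

#' @param records Named list of `list(sequence=, dotbracket=)`.
#' @rdname read_vienna
#' @export
write_vienna <- function(records, path) {
  lines <- unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]]$sequence, records[[id]]$dotbracket)
  }))
  writeLines(lines, path)
  invisible(path)
}
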