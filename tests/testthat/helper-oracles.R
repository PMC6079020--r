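# Independent brute-force oracles, deliberately implemented without reusing
# any package internals.

# exhaustive affine-gap alignment score by enumerating every alignment path
# (states: M = aligned column, X = gap in b, Y = gap in a); feasible for
# sequences of length <= 6
brute_align_score <- function(a, b, type = c("global", "local"),
                              match = 1, mismatch = -2,
                              gap_open = 10, gap_extend = 1) {
  type <- match.arg(type)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  gap <- function(prev, state) {
    if (identical(prev, state)) -gap_extend else -(gap_open + gap_extend)
  }
  if (type == "global") {
    rec <- function(i, j, prev) {
      if (i > n && j > m) return(0)
      best <- -Inf
      if (i <= n && j <= m) {
        s <- if (ca[i] == cb[j]) match else mismatch
        best <- max(best, s + rec(i + 1, j + 1, "M"))
      }
      if (i <= n) best <- max(best, gap(prev, "X") + rec(i + 1, j, "X"))
      if (j <= m) best <- max(best, gap(prev, "Y") + rec(i, j + 1, "Y"))
      best
    }
    return(rec(1, 1, "start"))
  }
  # local: best scoring path over any start/end; a path may stop anywhere
  best_local <- 0
  rec <- function(i, j, prev, acc) {
    best_local <<- max(best_local, acc)
    if (i > n || j > m) return(invisible())
    s <- if (ca[i] == cb[j]) match else mismatch
    rec(i + 1, j + 1, "M", acc + s)
    rec(i + 1, j, "X", acc + gap(prev, "X"))
    rec(i, j + 1, "Y", acc + gap(prev, "Y"))
    invisible()
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      rec(i, j, "start", 0)
    }
  }
  best_local
}

# exhaustive enumeration of all nested canonical structures (min hairpin
# loop), returning the maximum number of base pairs; feasible for n <= 12
brute_max_pairs <- function(rna, min_loop = 3) {
  ch <- strsplit(chartr("T", "U", toupper(rna)), "")[[1]]
  ok <- function(x, y) {
    paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  enum <- function(pos) {
    if (length(pos) == 0) return(0)
    i <- pos[1]
    best <- enum(pos[-1])                      # i unpaired
    for (kk in seq_along(pos)) {
      k <- pos[kk]
      if (k - i > min_loop && ok(ch[i], ch[k])) {
        inside <- pos[pos > i & pos < k]
        outside <- pos[pos > k]
        best <- max(best, 1 + enum(inside) + enum(outside))
      }
    }
    best
  }
  enum(seq_along(ch))
}

# all permutations of 1..n as a matrix (rows)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1)))
  }
  unname(out)
}

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# phylotype table in the canonical dereplication order
make_ptab <- function(seqs, counts) {
  ord <- order(-counts, seqs, method = "radix")
  data.frame(phylotype_id = sprintf("pt%05d", seq_along(seqs)),
             sequence = seqs[ord], total_count = as.integer(counts[ord]),
             stringsAsFactors = FALSE)
}

make_pset <- function(seqs, counts, sample_id = "s1") {
  tab <- make_ptab(seqs, counts)
  m <- matrix(tab$total_count, ncol = 1,
              dimnames = list(tab$phylotype_id, sample_id))
  structure(list(tab = tab, counts = m), class = "phylotype_set")
}
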