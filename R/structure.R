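#' Fold a sequence into a base-pair-maximising nested secondary structure
#'
#' Deterministic dynamic-programming folding (Nussinov-style base-pair
#' maximisation) allowing AU/GC/GU pairs with a minimum hairpin loop of
#' `min_loop` unpaired bases. Traceback is deterministic: each 5' position is
#' paired with the smallest qualifying partner among optimal choices. This is
#' a reproducible built-in; externally predicted structures can be supplied
#' as Vienna files wherever a structure is consumed.
#'
#' @param sequence Nucleotide string (T is transcribed to U).
#' @param min_loop Minimum hairpin loop size (default 3).
#' @return A dot-bracket string.
#' @export
fold_dotbracket <- function(sequence, min_loop = 3) {
  rna <- to_rna(sequence)
  if (!nzchar(rna)) stop("sequence must have length >= 1")
  if (grepl("[^ACGU]", rna)) stop("non-nucleotide characters in sequence")
  cpp_fold_maxpair(rna, as.integer(min_loop))
}

to_rna <- function(x) chartr("T", "U", toupper(x))

#' Parse a dot-bracket string into a base-pair table
#'
#' @param dotbracket Balanced dot-bracket string over `(`, `)`, `.`.
#' @return Integer vector `p` with `p[i]` = partner of position i (NA if
#'   unpaired).
#' @export
dotbracket_pairs <- function(dotbracket) {
  ch <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("(", ")", "."))) stop("invalid dot-bracket characters")
  n <- length(ch)
  p <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[j] <- i
      p[i] <- j
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket")
  p
}

#' Build an ITS2 structure object
#'
#' Bundles a sequence with its (nested, balanced) dot-bracket structure,
#' validates that every base pair is canonical (AU, GC or GU), and annotates
#' helices (see [annotate_helices()]).
#'
#' @param sequence Nucleotide string (T transcribed to U internally).
#' @param dotbracket Dot-bracket string; defaults to [fold_dotbracket()] of
#'   the sequence.
#' @param require_canonical Error on non-canonical pairs (default TRUE).
#' @return An `its2_structure`: list with `sequence` (RNA), `dotbracket`,
#'   `pairs`, `helices` (see [annotate_helices()]).
#' @export
its2_structure <- function(sequence, dotbracket = NULL, require_canonical = TRUE) {
  rna <- to_rna(sequence)
  if (is.null(dotbracket)) dotbracket <- fold_dotbracket(rna)
  if (nchar(dotbracket) != nchar(rna)) stop("sequence/structure length mismatch")
  p <- dotbracket_pairs(dotbracket)
  bases <- strsplit(rna, "", fixed = TRUE)[[1]]
  paired <- which(!is.na(p) & p > seq_along(p))
  if (require_canonical) {
    for (i in paired) {
      if (!is_canonical_pair(bases[i], bases[p[i]])) {
        stop(sprintf("non-canonical pair %s-%s at (%d, %d)",
                     bases[i], bases[p[i]], i, p[i]))
      }
    }
  }
  st <- structure(list(sequence = rna, dotbracket = dotbracket, pairs = p,
                       helices = NULL), class = "its2_structure")
  annotate_helices(st)
}

is_canonical_pair <- function(x, y) {
  paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Annotate the helices of an ITS2 structure
#'
#' Helices are the branch stems emanating from the basal loop: the loop
#' closed by the outermost base pair if a single outermost pair encloses the
#' whole structure, or the open exterior loop otherwise. They are numbered
#' I..N in 5' order. Each helix is followed through its (possibly bulged)
#' unbranched stem; its pair list, 5'/3' strand intervals and apical loop are
#' recorded.
#'
#' @param st An `its2_structure`.
#' @return The structure with `helices`: a list of
#'   `list(number, pairs (2-col matrix), five_prime (positions),
#'   three_prime (positions), apex_loop (positions or NULL))`.
#' @export
annotate_helices <- function(st) {
  p <- st$pairs
  n <- length(p)
  top <- top_level_pairs(p, 1L, n)
  if (nrow(top) == 1 && top[1, 1] == 1 && top[1, 2] == n) {
    # basal loop is the loop closed by the outermost pairing
    roots <- top_level_pairs(p, 2L, n - 1L)
  } else {
    roots <- top
  }
  helices <- lapply(seq_len(nrow(roots)), function(k) {
    trace_helix(p, roots[k, 1], roots[k, 2], k)
  })
  st$helices <- helices
  st
}

# outermost pairs within [from, to]
top_level_pairs <- function(p, from, to) {
  out <- matrix(integer(0), ncol = 2)
  i <- from
  while (i <= to) {
    if (!is.na(p[i]) && p[i] > i) {
      out <- rbind(out, c(i, p[i]))
      i <- p[i] + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

trace_helix <- function(p, i, j, number) {
  pair_list <- matrix(integer(0), ncol = 2)
  apex <- NULL
  repeat {
    pair_list <- rbind(pair_list, c(i, j))
    inner <- top_level_pairs(p, i + 1L, j - 1L)
    if (nrow(inner) == 0) {
      apex <- if (j - i > 1) seq.int(i + 1L, j - 1L) else integer(0)
      break
    }
    if (nrow(inner) > 1) {
      apex <- NULL  # stem ends in an internal multibranch; no apical loop
      break
    }
    i <- inner[1, 1]
    j <- inner[1, 2]
  }
  five <- seq.int(min(pair_list[, 1]), max(pair_list[, 1]))
  three <- seq.int(min(pair_list[, 2]), max(pair_list[, 2]))
  list(number = number, pairs = pair_list, five_prime = five,
       three_prime = three, apex_loop = apex)
}

#' Find YGGY motif matches (overlapping)
#'
#' Y is a pyrimidine (C or U). All (possibly overlapping) start positions of
#' the motif are reported.
#'
#' @param sequence RNA or DNA string.
#' @return Integer vector of 1-based match start positions.
#' @export
find_yggy <- function(sequence) {
  rna <- to_rna(sequence)
  m <- gregexpr("(?=[CU]GG[CU])", rna, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Validate the eukaryotic ITS2 structural hallmarks
#'
#' Checks the three hallmarks shared by eukaryotic ITS2 structures: exactly
#' four helices around the basal loop; a U-U mismatch (an internal-loop
#' column presenting U opposite U) in helix II; and a YGGY motif on the 5'
#' strand of helix III overlapping the apex window (the 5'-strand positions
#' within `apex_window` bases of the apical loop).
#'
#' @param st An `its2_structure` with helices annotated.
#' @param apex_window Size of the helix-III apex window in 5'-strand
#'   positions (default 10).
#' @return A `hallmark_report`: list with `four_helices`, `helixII_UU`,
#'   `yggy_helixIII_5prime_apex`, `overall` (conjunction).
#' @export
validate_hallmarks <- function(st, apex_window = 10) {
  nh <- length(st$helices)
  four <- nh == 4
  uu <- if (nh >= 2) helix_has_uu_mismatch(st, st$helices[[2]]) else FALSE
  yggy <- if (nh >= 3) {
    length(yggy_in_apex_window(st, st$helices[[3]], apex_window)) > 0
  } else FALSE
  structure(list(four_helices = four, helixII_UU = uu,
                 yggy_helixIII_5prime_apex = yggy,
                 overall = four && uu && yggy),
            class = "hallmark_report")
}

#' @export
print.hallmark_report <- function(x, ...) {
  cat(sprintf("hallmarks: four_helices=%s helixII_UU=%s yggy=%s -> %s\n",
              x$four_helices, x$helixII_UU, x$yggy_helixIII_5prime_apex,
              if (x$overall) "PASS" else "FAIL"))
  invisible(x)
}

# U-U mismatch: between consecutive stem pairs, align the unpaired runs on
# the two strands column-wise (k-th of the 5' run with k-th-from-inside of
# the 3' run) and look for a U opposite a U.
helix_has_uu_mismatch <- function(st, helix) {
  bases <- strsplit(st$sequence, "", fixed = TRUE)[[1]]
  pl <- helix$pairs
  if (nrow(pl) < 2) return(FALSE)
  for (k in seq_len(nrow(pl) - 1)) {
    i1 <- pl[k, 1]; j1 <- pl[k, 2]
    i2 <- pl[k + 1, 1]; j2 <- pl[k + 1, 2]
    run5 <- if (i2 - i1 > 1) seq.int(i1 + 1L, i2 - 1L) else integer(0)
    run3 <- if (j1 - j2 > 1) seq.int(j2 + 1L, j1 - 1L) else integer(0)
    if (length(run5) == 0 || length(run3) == 0) next
    ncol_loop <- max(length(run5), length(run3))
    for (c in seq_len(ncol_loop)) {
      a <- if (c <= length(run5)) run5[c] else NA
      b <- if (c <= length(run3)) run3[length(run3) - c + 1L] else NA
      if (!is.na(a) && !is.na(b) && bases[a] == "U" && bases[b] == "U") {
        return(TRUE)
      }
    }
  }
  FALSE
}

# YGGY matches on the helix 5' strand overlapping the apex window
yggy_in_apex_window <- function(st, helix, apex_window = 10) {
  win <- helix_apex_window(helix, apex_window)
  if (length(win) == 0) return(integer(0))
  matches <- find_yggy(st$sequence)
  ok <- vapply(matches, function(m) {
    span <- seq.int(m, m + 3L)
    all(span %in% helix$five_prime) && any(span %in% win)
  }, logical(1))
  matches[ok]
}

# the 5'-strand positions of a helix within `apex_window` bases of its
# apical loop
helix_apex_window <- function(helix, apex_window = 10) {
  five <- helix$five_prime
  if (length(five) == 0) return(integer(0))
  tail(five, apex_window)
}

#' The CBC delimitation window of a structure
#'
#' The species-delimitation window is the helix-III apex window (5'-strand
#' positions within `apex_window` bases of the apical loop), extended to
#' include any YGGY match overlapping it.
#'
#' @param st An `its2_structure`.
#' @param apex_window Window size (default 10).
#' @return Integer vector of sequence positions (possibly empty).
#' @export
delimitation_window <- function(st, apex_window = 10) {
  if (length(st$helices) < 3) return(integer(0))
  h3 <- st$helices[[3]]
  win <- helix_apex_window(h3, apex_window)
  matches <- yggy_in_apex_window(st, h3, apex_window)
  sort(unique(c(win, unlist(lapply(matches, function(m) seq.int(m, m + 3L))))))
}
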