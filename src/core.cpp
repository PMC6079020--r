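#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Paired-read merging (ungapped overlap scan, higher-quality base wins)
// ---------------------------------------------------------------------------

// fwd / rev_rc are 5'->3' forward reads and reverse-complemented reverse reads;
// quals are Phred+33 strings of matching length (rev quals already reversed).
// For each candidate offset s (start of rev_rc within fwd, s >= 0) the overlap
// is o = min(lf - s, lr); candidates need o >= min_overlap and
// mismatches/o <= max_mismatch_frac.  Best candidate: lowest mismatch
// fraction, ties -> larger overlap, ties -> smaller offset.
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector fwd, CharacterVector fq,
                     CharacterVector rev_rc, CharacterVector rq,
                     int min_overlap, double max_mismatch_frac) {
  int n = fwd.size();
  CharacterVector mseq(n), mqual(n);
  LogicalVector ok(n);
  for (int r = 0; r < n; ++r) {
    const char *a = CHAR(STRING_ELT(fwd, r));
    const char *qa = CHAR(STRING_ELT(fq, r));
    const char *b = CHAR(STRING_ELT(rev_rc, r));
    const char *qb = CHAR(STRING_ELT(rq, r));
    int lf = strlen(a), lr = strlen(b);
    int best_s = -1, best_o = -1;
    double best_frac = 2.0;
    for (int s = 0; s + min_overlap <= lf; ++s) {
      int o = std::min(lf - s, lr);
      if (o < min_overlap) continue;
      int mm = 0;
      for (int k = 0; k < o; ++k) if (a[s + k] != b[k]) ++mm;
      double frac = (double)mm / o;
      if (frac > max_mismatch_frac) continue;
      if (frac < best_frac - 1e-12 ||
          (std::abs(frac - best_frac) <= 1e-12 && o > best_o)) {
        best_frac = frac; best_s = s; best_o = o;
      }
    }
    if (best_s < 0) { ok[r] = false; mseq[r] = NA_STRING; mqual[r] = NA_STRING; continue; }
    int s = best_s, o = best_o;
    int mlen = std::max(lf, s + lr);
    std::string ms(mlen, 'N'), mq(mlen, '!');
    for (int i = 0; i < s; ++i) { ms[i] = a[i]; mq[i] = qa[i]; }
    for (int k = 0; k < o; ++k) {
      char ca = a[s + k], cb = b[k], pa = qa[s + k], pb = qb[k];
      if (ca == cb) { ms[s + k] = ca; }
      else          { ms[s + k] = (pb > pa) ? cb : ca; }  // tie -> forward base
      mq[s + k] = std::max(pa, pb);
    }
    if (s + lr >= lf) {  // reverse read extends past forward
      for (int k = o; k < lr; ++k) { ms[s + k] = b[k]; mq[s + k] = qb[k]; }
    } else {             // forward read extends past reverse
      for (int i = s + o; i < lf; ++i) { ms[i] = a[i]; mq[i] = qa[i]; }
    }
    ok[r] = true;
    mseq[r] = ms; mqual[r] = mq;
  }
  return List::create(_["merged"] = ok, _["seq"] = mseq, _["qual"] = mqual);
}

// ---------------------------------------------------------------------------
// Quality truncation (truncate before first base with Q < qmin; Phred+33)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_truncate_at_q(CharacterVector seqs, CharacterVector quals, int qmin) {
  int n = seqs.size();
  CharacterVector os(n), oq(n);
  char thr = (char)(qmin + 33);
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    const char *q = CHAR(STRING_ELT(quals, r));
    int l = strlen(s), cut = l;
    for (int i = 0; i < l; ++i) if (q[i] < thr) { cut = i; break; }
    os[r] = std::string(s, s + cut);
    oq[r] = std::string(q, q + cut);
  }
  return List::create(_["seq"] = os, _["qual"] = oq);
}

// ---------------------------------------------------------------------------
// Hamming identity of one query against equal-length targets (NA otherwise)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_hamming_identity(std::string query, CharacterVector targets) {
  int n = targets.size(), lq = query.size();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    const char *t = CHAR(STRING_ELT(targets, r));
    int lt = strlen(t);
    if (lt != lq) { out[r] = NA_REAL; continue; }
    int mm = 0;
    for (int i = 0; i < lq; ++i) if (t[i] != query[i]) ++mm;
    out[r] = 1.0 - (double)mm / lq;
  }
  return out;
}

// Hamming identity of every query against every equal-length target
// (queries x targets; NA where lengths differ)
// [[Rcpp::export]]
NumericMatrix cpp_hamming_matrix(CharacterVector queries, CharacterVector targets) {
  int nq = queries.size(), nt = targets.size();
  NumericMatrix out(nq, nt);
  std::vector<const char *> ts(nt);
  std::vector<int> tl(nt);
  for (int j = 0; j < nt; ++j) {
    ts[j] = CHAR(STRING_ELT(targets, j));
    tl[j] = strlen(ts[j]);
  }
  for (int i = 0; i < nq; ++i) {
    const char *q = CHAR(STRING_ELT(queries, i));
    int lq = strlen(q);
    for (int j = 0; j < nt; ++j) {
      if (tl[j] != lq) { out(i, j) = NA_REAL; continue; }
      int mm = 0;
      for (int k = 0; k < lq; ++k) if (q[k] != ts[j][k]) ++mm;
      out(i, j) = 1.0 - (double)mm / lq;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Affine-gap pairwise alignment (global Needleman-Wunsch / local Smith-Waterman)
// ---------------------------------------------------------------------------

// A gap of length k costs gap_open + k * gap_extend.  Explicit traceback
// pointers; ties resolved match-state first, then gap-in-b, then gap-in-a.
// States: 0 = M (a[i]~b[j]), 1 = X (gap in b, consumes a), 2 = Y (gap in a).
// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, std::string type,
               double match, double mismatch, double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  bool local = (type == "local");
  const double NEG = -1e18;
  int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  std::vector<signed char> tbM((n + 1) * W, -1), tbX((n + 1) * W, -1),
      tbY((n + 1) * W, -1);
  auto at = [W](int i, int j) { return i * W + j; };
  M[at(0, 0)] = 0.0;
  tbM[at(0, 0)] = 3;  // 3 = start
  for (int i = 1; i <= n; ++i) {
    if (!local) { X[at(i, 0)] = -(gap_open + gap_extend * i); tbX[at(i, 0)] = (i == 1) ? 0 : 1; }
  }
  for (int j = 1; j <= m; ++j) {
    if (!local) { Y[at(0, j)] = -(gap_open + gap_extend * j); tbY[at(0, j)] = (j == 1) ? 0 : 2; }
  }
  double best = 0.0; int bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M state
      double pm = M[at(i - 1, j - 1)], px = X[at(i - 1, j - 1)], py = Y[at(i - 1, j - 1)];
      double d = pm; signed char t = 0;
      if (px > d) { d = px; t = 1; }
      if (py > d) { d = py; t = 2; }
      if (local && d < 0 && (i - 1 == 0 || j - 1 == 0 || true)) {
        // a local path may start fresh at any cell
        if (0.0 > d) { d = 0.0; t = 3; }
      }
      if (i == 1 && j == 1 && t == 0) { d = 0.0; t = 3; }  // from origin
      if (d <= NEG / 2) { M[at(i, j)] = NEG; }
      else { M[at(i, j)] = d + s; tbM[at(i, j)] = t; }
      if (local && M[at(i, j)] < 0) { M[at(i, j)] = NEG; tbM[at(i, j)] = -1; }
      // X state (gap in b)
      double xo = M[at(i - 1, j)] - (gap_open + gap_extend);
      double xe = X[at(i - 1, j)] - gap_extend;
      double xy = Y[at(i - 1, j)] - (gap_open + gap_extend);
      double dx = xo; signed char tx = 0;
      if (xe > dx) { dx = xe; tx = 1; }
      if (xy > dx) { dx = xy; tx = 2; }
      if (dx > NEG / 2) { X[at(i, j)] = dx; tbX[at(i, j)] = tx; }
      // Y state (gap in a)
      double yo = M[at(i, j - 1)] - (gap_open + gap_extend);
      double yx = X[at(i, j - 1)] - (gap_open + gap_extend);
      double ye = Y[at(i, j - 1)] - gap_extend;
      double dy = yo; signed char ty = 0;
      if (yx > dy) { dy = yx; ty = 1; }
      if (ye > dy) { dy = ye; ty = 2; }
      if (dy > NEG / 2) { Y[at(i, j)] = dy; tbY[at(i, j)] = ty; }
      if (local && M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }
  std::string ra, rb;
  double score;
  int i, j, state;
  if (local) {
    if (bi < 0 || best <= 0) {
      return List::create(_["aligned_a"] = "", _["aligned_b"] = "",
                          _["score"] = 0.0, _["start_a"] = 0, _["end_a"] = 0,
                          _["start_b"] = 0, _["end_b"] = 0);
    }
    score = best; i = bi; j = bj; state = 0;
    while (true) {
      if (state == 0) {
        signed char t = tbM[at(i, j)];
        ra += a[i - 1]; rb += b[j - 1];
        --i; --j;
        if (t == 3) break;
        state = t;
      } else if (state == 1) {
        signed char t = tbX[at(i, j)];
        ra += a[i - 1]; rb += '-';
        --i;
        state = (t == 1) ? 1 : ((t == 0) ? 0 : 2);
      } else {
        signed char t = tbY[at(i, j)];
        ra += '-'; rb += b[j - 1];
        --j;
        state = (t == 2) ? 2 : ((t == 0) ? 0 : 1);
      }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                        _["score"] = score,
                        _["start_a"] = i + 1, _["end_a"] = bi,
                        _["start_b"] = j + 1, _["end_b"] = bj);
  }
  // global: end at (n, m), best of the three states (prefer M, X, Y on ties)
  double em = M[at(n, m)], ex = X[at(n, m)], ey = Y[at(n, m)];
  score = em; state = 0;
  if (ex > score) { score = ex; state = 1; }
  if (ey > score) { score = ey; state = 2; }
  i = n; j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char t = tbM[at(i, j)];
      ra += a[i - 1]; rb += b[j - 1];
      --i; --j;
      if (t == 3) break;
      state = t;
    } else if (state == 1) {
      signed char t = tbX[at(i, j)];
      ra += a[i - 1]; rb += '-';
      --i;
      state = (t == 1) ? 1 : ((t == 0) ? 0 : 2);
    } else {
      signed char t = tbY[at(i, j)];
      ra += '-'; rb += b[j - 1];
      --j;
      state = (t == 2) ? 2 : ((t == 0) ? 0 : 1);
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score,
                      _["start_a"] = 1, _["end_a"] = n,
                      _["start_b"] = 1, _["end_b"] = m);
}

// ---------------------------------------------------------------------------
// Base-pair maximisation folding (nested structures, AU/GC/GU, min loop 3)
// ---------------------------------------------------------------------------

static inline bool can_pair(char x, char y) {
  return (x == 'A' && y == 'U') || (x == 'U' && y == 'A') ||
         (x == 'G' && y == 'C') || (x == 'C' && y == 'G') ||
         (x == 'G' && y == 'U') || (x == 'U' && y == 'G');
}

// [[Rcpp::export]]
std::string cpp_fold_maxpair(std::string rna, int min_loop) {
  int n = rna.size();
  std::string db(n, '.');
  if (n == 0) return db;
  std::vector<int> N(n * n, 0);
  auto at = [n](int i, int j) { return i * n + j; };
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = N[at(i + 1, j)];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(rna[i], rna[k])) continue;
        int v = 1 + N[at(i + 1, k - 1)] + (k < j ? N[at(k + 1, j)] : 0);
        if (v > best) best = v;
      }
      N[at(i, j)] = best;
    }
  }
  // traceback: prefer pairing i with the smallest qualifying partner
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    int target = N[at(i, j)];
    if (target == 0) continue;
    int chosen = -1;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(rna[i], rna[k])) continue;
      int v = 1 + N[at(i + 1, k - 1)] + (k < j ? N[at(k + 1, j)] : 0);
      if (v == target) { chosen = k; break; }
    }
    if (chosen < 0) {
      stack.push_back(std::make_pair(i + 1, j));
    } else {
      db[i] = '('; db[chosen] = ')';
      if (chosen - i >= 2) stack.push_back(std::make_pair(i + 1, chosen - 1));
      if (chosen < j) stack.push_back(std::make_pair(chosen + 1, j));
    }
  }
  return db;
}

// ---------------------------------------------------------------------------
// Anchored IUPAC primer mismatch counts
// ---------------------------------------------------------------------------

static inline int iupac_bits(char c) {
  switch (c) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 1 | 4; case 'Y': return 2 | 8; case 'S': return 2 | 4;
    case 'W': return 1 | 8; case 'K': return 4 | 8; case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8; case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8; case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default: return 0;
  }
}

// Mismatches of `probe` (IUPAC) anchored at the 5' end (or 3' end when
// at_end) of each read.  NA when the read is shorter than the probe.
// [[Rcpp::export]]
IntegerVector cpp_iupac_anchor_mismatch(CharacterVector seqs, std::string probe,
                                        bool at_end) {
  int n = seqs.size(), p = probe.size();
  std::vector<int> pb(p);
  for (int k = 0; k < p; ++k) pb[k] = iupac_bits(probe[k]);
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    int l = strlen(s);
    if (l < p) { out[r] = NA_INTEGER; continue; }
    int off = at_end ? (l - p) : 0;
    int mm = 0;
    for (int k = 0; k < p; ++k) {
      if ((pb[k] & iupac_bits(s[off + k])) == 0) ++mm;
    }
    out[r] = mm;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-query-position match profile of query vs candidate, from a global
// alignment (used by the two-parent chimera model)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector cpp_match_profile(std::string aligned_q, std::string aligned_c) {
  int L = aligned_q.size();
  std::vector<int> matches;
  for (int k = 0; k < L; ++k) {
    if (aligned_q[k] == '-') continue;
    matches.push_back(aligned_q[k] == aligned_c[k] && aligned_c[k] != '-');
  }
  LogicalVector out(matches.size());
  for (size_t i = 0; i < matches.size(); ++i) out[i] = (bool)matches[i];
  return out;
}
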