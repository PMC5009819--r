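#include <Rcpp.h>
#include <cstring>
#include <algorithm>
#include <vector>
#include <set>
#include <string>
using namespace Rcpp;

// The concatenated database text uses '\x01' as the read separator
// (lexicographically below every residue letter, never matched).

// [[Rcpp::export]]
List cpp_suffix_index(std::string text) {
  const int n = (int) text.size();
  if (n == 0) stop("empty text");
  const char* s = text.c_str();
  std::vector<int> sa(n);
  for (int i = 0; i < n; ++i) sa[i] = i;
  // comparison-based sort; suffixes are cut short by sentinels so average
  // comparison depth stays near the read length
  std::sort(sa.begin(), sa.end(), [&](int a, int b) {
    int la = n - a, lb = n - b, l = la < lb ? la : lb;
    int c = std::memcmp(s + a, s + b, (size_t) l);
    if (c != 0) return c < 0;
    return la < lb;
  });
  // Kasai's LCP: lcp[i] = LCP(suffix at rank i-1, suffix at rank i); lcp[0] = 0
  std::vector<int> rank(n), lcp(n, 0);
  for (int i = 0; i < n; ++i) rank[sa[i]] = i;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank[i] > 0) {
      int j = sa[rank[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[rank[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return List::create(_["sa"] = wrap(sa), _["lcp"] = wrap(lcp));
}

// Reads flagged contained: read t is a substring of another read s with
// (len_s > len_t) or (identical sequences and id_s < id_t). starts are 0-based.
// [[Rcpp::export]]
LogicalVector cpp_contained_reads(std::string text, IntegerVector sa,
                                  IntegerVector lcp, IntegerVector starts,
                                  IntegerVector lens) {
  const int n = (int) text.size(), nr = starts.size();
  std::vector<int> rank(n), read_of(n, -1);
  for (int i = 0; i < n; ++i) rank[sa[i]] = i;
  for (int r = 0; r < nr; ++r)
    for (int p = starts[r]; p < starts[r] + lens[r]; ++p) read_of[p] = r;
  LogicalVector out(nr);
  for (int t = 0; t < nr; ++t) {
    const int lt = lens[t];
    int r0 = rank[starts[t]];
    bool contained = false;
    // walk SA neighbourhood while common prefix >= lt
    for (int dir = -1; dir <= 1 && !contained; dir += 2) {
      int r = r0, minl = lt;
      while (true) {
        int rn = r + dir;
        if (rn < 0 || rn >= n) break;
        int step_lcp = dir < 0 ? lcp[r] : lcp[rn];
        if (step_lcp < minl) minl = step_lcp;
        if (minl < lt) break;
        r = rn;
        int q = sa[r];
        int srd = read_of[q];
        if (srd >= 0 && srd != t) {
          if (lens[srd] > lt && q + lt <= starts[srd] + lens[srd]) { contained = true; break; }
          if (lens[srd] == lt && q == starts[srd] && srd < t) { contained = true; break; }
        }
      }
    }
    out[t] = contained;
  }
  return out;
}

// Candidate right-extension links via the SA/LCP traversal: for each
// non-contained source read and each of its suffixes of length ov >= min_overlap,
// find reads (not contained, longer than ov) whose prefix equals the suffix.
// Only the maximal overlap per (source, sink) pair is kept (ov scanned
// descending). 1-based read indices in the result.
// [[Rcpp::export]]
DataFrame cpp_link_candidates(std::string text, IntegerVector sa,
                              IntegerVector lcp, IntegerVector starts,
                              IntegerVector lens, LogicalVector contained,
                              int min_overlap) {
  const int n = (int) text.size(), nr = starts.size();
  std::vector<int> rank(n);
  for (int i = 0; i < n; ++i) rank[sa[i]] = i;
  std::vector<int> start_read(n, -1);
  for (int r = 0; r < nr; ++r) start_read[starts[r]] = r;
  std::vector<int> src, snk, ovl;
  for (int i = 0; i < nr; ++i) {
    if (contained[i] || lens[i] <= min_overlap) continue;
    std::set<int> seen;
    for (int ov = lens[i] - 1; ov >= min_overlap; --ov) {
      int p = starts[i] + lens[i] - ov;
      int r0 = rank[p];
      for (int dir = -1; dir <= 1; dir += 2) {
        int r = r0, minl = ov;
        while (true) {
          int rn = r + dir;
          if (rn < 0 || rn >= n) break;
          int step_lcp = dir < 0 ? lcp[r] : lcp[rn];
          if (step_lcp < minl) minl = step_lcp;
          if (minl < ov) break;
          r = rn;
          int q = sa[r];
          int t = start_read[q];
          if (t >= 0 && t != i && !contained[t] && lens[t] > ov &&
              seen.find(t) == seen.end()) {
            seen.insert(t);
            src.push_back(i + 1);
            snk.push_back(t + 1);
            ovl.push_back(ov);
          }
        }
      }
    }
  }
  return DataFrame::create(_["src"] = wrap(src), _["sink"] = wrap(snk),
                           _["overlap"] = wrap(ovl));
}

static const int NEG = -1000000000;

// Banded affine-gap alignment of query window q (rows) vs target/contig t
// (columns). Gap of length g costs open + g*ext. Cells restricted to
// |i - j - shift| <= band (j = 0 column handled separately). If
// free_q_ends, leading/trailing unaligned query residues are free and the
// score is max over rows of the last column (glocal: target fully aligned);
// otherwise standard global NW and the score is cell (m, n).
// [[Rcpp::export]]
List cpp_banded_align(std::string q, std::string t, IntegerMatrix mat,
                      std::string alpha, int gap_open, int gap_extend,
                      int band, int shift, bool free_q_ends) {
  const int m = (int) q.size(), n = (int) t.size();
  int idx[256];
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (int i = 0; i < (int) alpha.size(); ++i)
    idx[(unsigned char) alpha[i]] = i;
  std::vector<int> qi(m), ti(n);
  for (int i = 0; i < m; ++i) {
    qi[i] = idx[(unsigned char) q[i]];
    if (qi[i] < 0) stop("residue '%c' not in scoring alphabet", q[i]);
  }
  for (int j = 0; j < n; ++j) {
    ti[j] = idx[(unsigned char) t[j]];
    if (ti[j] < 0) stop("residue '%c' not in scoring alphabet", t[j]);
  }
  const int go = gap_open + gap_extend; // cost of opening a length-1 gap
  // rolling rows: D best-any-state, E gap-in-target (vertical, consumes q),
  // F gap-in-query (horizontal, consumes t)
  std::vector<int> Dprev(n + 1, NEG), Dcur(n + 1, NEG);
  std::vector<int> Eprev(n + 1, NEG), Ecur(n + 1, NEG);
  std::vector<int> Fprev(n + 1, NEG), Fcur(n + 1, NEG);
  int best_end = NEG, best_end_i = -1, best_any = NEG;
  // row 0
  Dprev[0] = 0;
  for (int j = 1; j <= n; ++j) {
    if (std::abs(0 - j - shift) > band) break;
    Fprev[j] = j == 1 ? -(go) : Fprev[j - 1] - gap_extend;
    Dprev[j] = Fprev[j];
  }
  if (n == 0) {
    int sc = free_q_ends ? 0 : (m == 0 ? 0 : -(gap_open + m * gap_extend));
    return List::create(_["score"] = sc, _["q_end"] = 0, _["best"] = sc);
  }
  if ((free_q_ends || m == 0) && Dprev[n] > NEG / 2) {
    best_end = Dprev[n]; best_end_i = 0;
  }
  best_any = 0;
  for (int i = 1; i <= m; ++i) {
    std::fill(Dcur.begin(), Dcur.end(), NEG);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    // column 0
    if (free_q_ends) {
      Dcur[0] = 0;
    } else if (std::abs(i - 0 - shift) <= band) {
      Ecur[0] = -(gap_open + i * gap_extend);
      Dcur[0] = Ecur[0];
    }
    int jlo = i - shift - band, jhi = i - shift + band;
    if (jlo < 1) jlo = 1;
    if (jhi > n) jhi = n;
    for (int j = jlo; j <= jhi; ++j) {
      int e = NEG, f = NEG, d = NEG;
      if (Dprev[j] > NEG) e = Dprev[j] - go;
      if (Eprev[j] > NEG && Eprev[j] - gap_extend > e) e = Eprev[j] - gap_extend;
      if (Dcur[j - 1] > NEG) f = Dcur[j - 1] - go;
      if (Fcur[j - 1] > NEG && Fcur[j - 1] - gap_extend > f) f = Fcur[j - 1] - gap_extend;
      if (Dprev[j - 1] > NEG) d = Dprev[j - 1] + mat(qi[i - 1], ti[j - 1]);
      if (e > d) d = e;
      if (f > d) d = f;
      Ecur[j] = e; Fcur[j] = f; Dcur[j] = d;
      if (d > best_any) best_any = d;
    }
    if (Dcur[n] > NEG) {
      if (free_q_ends) {
        if (Dcur[n] > best_end) { best_end = Dcur[n]; best_end_i = i; }
      } else if (i == m) {
        best_end = Dcur[n]; best_end_i = i;
      }
    }
    std::swap(Dprev, Dcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
  }
  double score = best_end <= NEG / 2 ? R_NegInf : (double) best_end;
  return List::create(_["score"] = score, _["q_end"] = best_end_i,
                      _["best"] = (double) best_any);
}

// Ungapped sliding post-mapping: best qualifying placement of each read on
// each contig. A placement qualifies when the aligned residues are
// >= ceil(min_fraction * read length) and mismatches <= max_sub. Best
// placement = max aligned, then min subs, then smallest offset. Offsets are
// 0-based (read start minus contig start).
// [[Rcpp::export]]
DataFrame cpp_postmap(CharacterVector reads, CharacterVector contigs,
                      double min_fraction, int max_sub) {
  std::vector<int> rid, cid, off, aln, sub;
  std::vector<double> frac;
  const int nr = reads.size(), nc = contigs.size();
  std::vector<std::string> rs(nr), cs(nc);
  for (int i = 0; i < nr; ++i) rs[i] = as<std::string>(reads[i]);
  for (int j = 0; j < nc; ++j) cs[j] = as<std::string>(contigs[j]);
  for (int i = 0; i < nr; ++i) {
    const int lr = (int) rs[i].size();
    // epsilon guards ceil against binary-representation overshoot (0.6*35)
    int minaln = (int) std::ceil(min_fraction * lr - 1e-9);
    if (minaln < 1) minaln = 1;
    for (int j = 0; j < nc; ++j) {
      const int lc = (int) cs[j].size();
      if (lc < minaln) continue;
      int bA = -1, bS = 0, bD = 0;
      for (int d = -(lr - minaln); d <= lc - minaln; ++d) {
        int r0 = d < 0 ? -d : 0;       // first read index aligned
        int c0 = d > 0 ? d : 0;        // first contig index aligned
        int L = std::min(lr - r0, lc - c0);
        if (L < minaln) continue;
        int s = 0;
        for (int k = 0; k < L; ++k) {
          if (rs[i][r0 + k] != cs[j][c0 + k] && ++s > max_sub) break;
        }
        if (s > max_sub) continue;
        if (L > bA || (L == bA && (s < bS || (s == bS && d < bD)))) {
          bA = L; bS = s; bD = d;
        }
      }
      if (bA >= 0) {
        rid.push_back(i + 1);
        cid.push_back(j + 1);
        off.push_back(bD);
        aln.push_back(bA);
        sub.push_back(bS);
        frac.push_back((double) bA / (double) lr);
      }
    }
  }
  return DataFrame::create(_["read"] = wrap(rid), _["contig"] = wrap(cid),
                           _["offset"] = wrap(off), _["aligned"] = wrap(aln),
                           _["substitutions"] = wrap(sub),
                           _["fraction"] = wrap(frac));
}
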