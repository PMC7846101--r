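#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// DNA codes: A=0, C=1, G=2, T=3, anything else (N, IUPAC) = 4.
// Code 4 never matches positively: any column involving it scores the
// mismatch penalty.

static const int NEG_INF = INT_MIN / 4;

// [[Rcpp::export]]
IntegerVector dna_encode_cpp(std::string seq) {
  int n = seq.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    switch (seq[i]) {
    case 'A': case 'a': out[i] = 0; break;
    case 'C': case 'c': out[i] = 1; break;
    case 'G': case 'g': out[i] = 2; break;
    case 'T': case 't': out[i] = 3; break;
    default: out[i] = 4;
    }
  }
  return out;
}

// [[Rcpp::export]]
std::string dna_decode_cpp(IntegerVector codes) {
  static const char *alpha = "ACGTN";
  std::string out(codes.size(), 'N');
  for (int i = 0; i < codes.size(); ++i) {
    int c = codes[i];
    out[i] = (c < 0) ? '-' : alpha[c > 4 ? 4 : c];
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector revcomp_codes_cpp(IntegerVector codes) {
  int n = codes.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int c = codes[n - 1 - i];
    out[i] = (c < 4) ? 3 - c : 4;
  }
  return out;
}

// Banded pairwise alignment with affine gaps.
// mode: 0 = local (Smith-Waterman), 1 = global (Needleman-Wunsch),
//       2 = overlap (global with free end gaps on both sequences).
// Gap of length L costs gap_open + L * gap_extend.
// band_lo <= j - i <= band_hi restricts the DP (DP indices are prefix
// lengths). For modes 1 and 2 the caller must make the band wide enough
// to contain (0,0) and (m,n) paths; passing band_lo = -m, band_hi = n
// gives the full matrix.
// [[Rcpp::export]]
List align_band_cpp(IntegerVector q, IntegerVector s,
                    int reward, int penalty,
                    int gap_open, int gap_extend,
                    int band_lo, int band_hi, int mode) {
  int m = q.size(), n = s.size();
  if (band_lo > band_hi) stop("band_lo > band_hi");
  // clamp band to feasible diagonals
  if (band_lo < -m) band_lo = -m;
  if (band_hi > n) band_hi = n;
  int W = band_hi - band_lo + 1;
  if (W < 1) stop("empty band");

  // traceback byte per cell:
  //   bits 0-1: H source (0 stop, 1 diag, 2 E [gap in q / consume s],
  //             3 F [gap in s / consume q])
  //   bit 2: E extended from E; bit 3: F extended from F
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 0);
  std::vector<int> Hprev(W, NEG_INF), Hcur(W, NEG_INF);
  std::vector<int> Fprev(W, NEG_INF), Fcur(W, NEG_INF);

  auto lo_of = [&](int i) { return std::max(0, i + band_lo); };
  auto hi_of = [&](int i) { return std::min(n, i + band_hi); };

  int best = NEG_INF, best_i = -1, best_j = -1;

  // row 0
  {
    int lo = lo_of(0), hi = hi_of(0);
    for (int j = lo; j <= hi; ++j) {
      int idx = j - lo;
      if (j == 0) { Hprev[idx] = 0; tb[idx] = 0; }
      else if (mode == 1) {
        Hprev[idx] = -(gap_open + j * gap_extend);
        tb[idx] = 2 | 4; // chain of E
      } else {
        Hprev[idx] = 0; tb[idx] = 0;
      }
      Fprev[idx] = NEG_INF;
      if (mode == 0) {
        if (Hprev[idx] > best) { best = Hprev[idx]; best_i = 0; best_j = j; }
      }
    }
    if (mode == 2) {
      // free trailing gaps: boundary row/col maxima collected below
      for (int j = lo; j <= hi; ++j)
        if (j == n && Hprev[j - lo] > best) { best = Hprev[j - lo]; best_i = 0; best_j = n; }
    }
  }

  const int *qp = &q[0];
  const int *sp = (n > 0) ? &s[0] : (const int *)0;
  const int goe = gap_open + gap_extend;
  for (int i = 1; i <= m; ++i) {
    int lo = lo_of(i), hi = hi_of(i);
    int lop = lo_of(i - 1), hip = hi_of(i - 1);
    if (lo > hi) continue;
    int *Hc = Hcur.data();
    int *Fc = Fcur.data();
    const int *Hp = Hprev.data();
    const int *Fp = Fprev.data();
    uint8_t *tbr = &tb[(size_t)i * W];
    std::fill(Hcur.begin(), Hcur.end(), NEG_INF);
    std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
    const int qa = qp[i - 1];
    int E = NEG_INF;
    int Hleft = NEG_INF; // H(i, j-1)
    int row_best = NEG_INF, row_best_j = -1;
    for (int j = lo; j <= hi; ++j) {
      const int idx = j - lo;
      uint8_t t = 0;
      // E: gap in q, from (i, j-1)
      int Eh;
      {
        int e_open = (Hleft > NEG_INF) ? Hleft - goe : NEG_INF;
        int e_ext  = (E > NEG_INF) ? E - gap_extend : NEG_INF;
        if (e_ext > e_open) { Eh = e_ext; t |= 4; } else Eh = e_open;
      }
      E = Eh;
      // F: gap in s, from (i-1, j)
      int Fh = NEG_INF;
      if (j >= lop && j <= hip) {
        int hu = Hp[j - lop];
        int fu = Fp[j - lop];
        int f_open = (hu > NEG_INF) ? hu - goe : NEG_INF;
        int f_ext  = (fu > NEG_INF) ? fu - gap_extend : NEG_INF;
        if (f_ext > f_open) { Fh = f_ext; t |= 8; } else Fh = f_open;
      }
      Fc[idx] = Fh;
      // diag
      int D = NEG_INF;
      if (j >= 1 && j - 1 >= lop && j - 1 <= hip) {
        int hd = Hp[j - 1 - lop];
        if (hd > NEG_INF) {
          int sb = sp[j - 1];
          D = hd + ((qa == sb && qa < 4) ? reward : penalty);
        }
      }
      int H;
      uint8_t src;
      if (j == 0) {
        // first column
        if (mode == 1) { H = -(gap_open + i * gap_extend); src = 3; t |= 8; }
        else { H = 0; src = 0; }
      } else {
        H = D; src = 1;
        if (Eh > H) { H = Eh; src = 2; }
        if (Fh > H) { H = Fh; src = 3; }
        if (mode == 0 && H < 0) { H = 0; src = 0; }
        if (H <= NEG_INF) { H = NEG_INF; src = 0; }
      }
      Hc[idx] = H;
      Hleft = H;
      tbr[idx] = t | src;
      if (H > row_best) { row_best = H; row_best_j = j; }
    }
    if (mode == 0) {
      if (row_best > best) { best = row_best; best_i = i; best_j = row_best_j; }
    } else if (mode == 2) {
      if (i == m && row_best > best) { best = row_best; best_i = m; best_j = row_best_j; }
      if (hi == n) {
        int Hn = Hc[n - lo];
        if (Hn > best) { best = Hn; best_i = i; best_j = n; }
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  if (mode == 1) {
    int lo = lo_of(m);
    if (n < lo || n > hi_of(m)) stop("band excludes cell (m,n) in global mode");
    best = Hprev[n - lo];
    best_i = m; best_j = n;
  }
  if (best_i < 0) { best_i = 0; best_j = 0; best = 0; }

  // traceback
  std::vector<int> ops; // 0 diag, 1 consume q (gap in s), 2 consume s (gap in q)
  int i = best_i, j = best_j;
  int matches = 0, gaps = 0;
  int state = 0; // 0 = in H, 2 = in E, 3 = in F
  while (i > 0 || j > 0) {
    uint8_t t = tb[(size_t)i * W + (j - lo_of(i))];
    if (state == 0) {
      int src = t & 3;
      if (src == 0) break; // local/overlap start
      if (src == 1) {
        ops.push_back(0);
        if (q[i - 1] == s[j - 1] && q[i - 1] < 4) ++matches;
        --i; --j;
      } else {
        state = src; // enter E (2) or F (3) of this cell
      }
    } else if (state == 2) {
      // E(i,j): bit 2 set -> extended from E(i,j-1), else opened from H(i,j-1)
      ops.push_back(2); ++gaps;
      state = (t & 4) ? 2 : 0;
      --j;
    } else {
      // F(i,j): bit 3 set -> extended from F(i-1,j), else opened from H(i-1,j)
      ops.push_back(1); ++gaps;
      state = (t & 8) ? 3 : 0;
      --i;
    }
  }
  int q_start = i, s_start = j;
  std::reverse(ops.begin(), ops.end());

  return List::create(
    _["score"] = best,
    _["q_start"] = q_start, _["q_end"] = best_i,
    _["s_start"] = s_start, _["s_end"] = best_j,
    _["matches"] = matches,
    _["aln_length"] = (int)ops.size(),
    _["gaps"] = gaps,
    _["ops"] = IntegerVector(ops.begin(), ops.end()));
}

// Ungapped X-drop extension of an exact seed match: extends in both
// directions accumulating match/mismatch scores, stopping when the
// running score drops more than xdrop below the running best. Returns
// the best total ungapped score through the seed.
// [[Rcpp::export]]
int ungapped_extend_cpp(IntegerVector q, IntegerVector s,
                        int qpos, int spos, int k,
                        int reward, int penalty, int xdrop) {
  int m = q.size(), n = s.size();
  int base = k * reward; // the exact seed itself
  int best_right = 0, cur = 0;
  for (int i = qpos + k, j = spos + k; i < m && j < n; ++i, ++j) {
    cur += (q[i] == s[j] && q[i] < 4) ? reward : penalty;
    if (cur > best_right) best_right = cur;
    if (cur < best_right - xdrop) break;
  }
  int best_left = 0; cur = 0;
  for (int i = qpos - 1, j = spos - 1; i >= 0 && j >= 0; --i, --j) {
    cur += (q[i] == s[j] && q[i] < 4) ? reward : penalty;
    if (cur > best_left) best_left = cur;
    if (cur < best_left - xdrop) break;
  }
  return base + best_left + best_right;
}

// ---- seed index ------------------------------------------------------

struct SeedIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> map; // kmer -> (contig, pos)
};

static bool kmer_stream(const IntegerVector &seq, int k,
                        std::vector<std::pair<uint64_t,int>> &out) {
  int n = seq.size();
  if (k > n || k < 1 || k > 31) return false;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t val = 0;
  int run = 0; // valid bases in current window
  for (int i = 0; i < n; ++i) {
    int c = seq[i];
    if (c >= 4 || c < 0) { run = 0; val = 0; continue; }
    val = ((val << 2) | (uint64_t)c) & mask;
    if (++run >= k) out.push_back(std::make_pair(val, i - k + 1));
  }
  return true;
}

// [[Rcpp::export]]
SEXP build_seed_index_cpp(List subj_codes, int k) {
  SeedIndex *idx = new SeedIndex();
  idx->k = k;
  std::vector<std::pair<uint64_t,int>> kmers;
  for (int c = 0; c < subj_codes.size(); ++c) {
    IntegerVector s = subj_codes[c];
    kmers.clear();
    kmer_stream(s, k, kmers);
    for (size_t t = 0; t < kmers.size(); ++t)
      idx->map[kmers[t].first].push_back(std::make_pair(c, kmers[t].second));
  }
  XPtr<SeedIndex> p(idx, true);
  return p;
}

// 3-mer Shannon entropy (bits) of the k-window starting at each query
// position; used for dust-style seed masking.
static double window_entropy3(const IntegerVector &q, int start, int k) {
  std::unordered_map<int,int> cnt;
  int tot = 0;
  for (int i = start; i + 3 <= start + k; ++i) {
    int a = q[i], b = q[i + 1], c = q[i + 2];
    if (a > 3 || b > 3 || c > 3) continue;
    cnt[a * 16 + b * 4 + c]++;
    ++tot;
  }
  if (tot == 0) return 0.0;
  double H = 0.0;
  for (std::unordered_map<int,int>::iterator it = cnt.begin(); it != cnt.end(); ++it) {
    double p = (double)it->second / tot;
    H -= p * std::log2(p);
  }
  return H;
}

// Returns matrix with columns: query pos, contig index, subject pos (0-based).
// [[Rcpp::export]]
IntegerMatrix query_seed_index_cpp(SEXP ptr, IntegerVector q,
                                   bool dust, double dust_threshold) {
  XPtr<SeedIndex> idx(ptr);
  int k = idx->k;
  std::vector<std::pair<uint64_t,int>> kmers;
  kmer_stream(q, k, kmers);
  std::vector<int> qp, cc, sp;
  for (size_t t = 0; t < kmers.size(); ++t) {
    int qpos = kmers[t].second;
    if (dust && window_entropy3(q, qpos, k) < dust_threshold) continue;
    std::unordered_map<uint64_t, std::vector<std::pair<int,int>>>::iterator it =
      idx->map.find(kmers[t].first);
    if (it == idx->map.end()) continue;
    for (size_t u = 0; u < it->second.size(); ++u) {
      qp.push_back(qpos);
      cc.push_back(it->second[u].first);
      sp.push_back(it->second[u].second);
    }
  }
  IntegerMatrix out(qp.size(), 3);
  for (size_t t = 0; t < qp.size(); ++t) {
    out(t, 0) = qp[t]; out(t, 1) = cc[t]; out(t, 2) = sp[t];
  }
  return out;
}

// [[Rcpp::export]]
int seed_index_k_cpp(SEXP ptr) {
  XPtr<SeedIndex> idx(ptr);
  return idx->k;
}
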