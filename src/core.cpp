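#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Validate a columnar read set. Returns c(0, 0) when clean, otherwise
// c(read_index, code): 1 = bad interval structure, 2 = position out of
// [1, L], 3 = mutation outside coverage, 4 = lowq outside coverage.
// [[Rcpp::export]]
IntegerVector check_reads_cpp(List starts, List ends, List muts, List lowq,
                              int L) {
  int n = starts.size();
  for (int r = 0; r < n; ++r) {
    IntegerVector s = starts[r], e = ends[r];
    int k = s.size();
    if (e.size() != k || k == 0)
      return IntegerVector::create(r + 1, 1);
    for (int p = 0; p < k; ++p) {
      if (s[p] > e[p]) return IntegerVector::create(r + 1, 1);
      if (p > 0 && s[p] <= e[p - 1]) return IntegerVector::create(r + 1, 1);
      if (s[p] < 1 || e[p] > L) return IntegerVector::create(r + 1, 2);
    }
    IntegerVector m = muts[r];
    for (int q = 0; q < m.size(); ++q) {
      if (m[q] < 1 || m[q] > L) return IntegerVector::create(r + 1, 2);
      bool in = false;
      for (int p = 0; p < k; ++p)
        if (m[q] >= s[p] && m[q] <= e[p]) { in = true; break; }
      if (!in) return IntegerVector::create(r + 1, 3);
    }
    IntegerVector lq = lowq[r];
    for (int q = 0; q < lq.size(); ++q) {
      if (lq[q] < 1 || lq[q] > L) return IntegerVector::create(r + 1, 2);
      bool in = false;
      for (int p = 0; p < k; ++p)
        if (lq[q] >= s[p] && lq[q] <= e[p]) { in = true; break; }
      if (!in) return IntegerVector::create(r + 1, 4);
    }
  }
  return IntegerVector::create(0, 0);
}

// Remove per-read lowq positions (if use_lowq) and globally masked positions
// from coverage and mutation sets. drop_global has length L (or 0 for none).
// [[Rcpp::export]]
List filter_reads_cpp(List starts, List ends, List muts, List lowq,
                      LogicalVector drop_global, bool use_lowq) {
  int n = starts.size();
  bool has_global = drop_global.size() > 0;
  List out_s(n), out_e(n), out_m(n);
  std::vector<int> lq;
  for (int r = 0; r < n; ++r) {
    IntegerVector s = starts[r], e = ends[r], m = muts[r];
    lq.clear();
    if (use_lowq) {
      IntegerVector v = lowq[r];
      lq.assign(v.begin(), v.end());
      std::sort(lq.begin(), lq.end());
    }
    std::vector<int> ks, ke, km;
    for (int p = 0; p < s.size(); ++p) {
      int run = -1;
      for (int pos = s[p]; pos <= e[p]; ++pos) {
        bool drop = (has_global && drop_global[pos - 1]) ||
          (!lq.empty() &&
           std::binary_search(lq.begin(), lq.end(), pos));
        if (drop) {
          if (run >= 0) { ks.push_back(run); ke.push_back(pos - 1); run = -1; }
        } else if (run < 0) run = pos;
      }
      if (run >= 0) { ks.push_back(run); ke.push_back(e[p]); }
    }
    for (int q = 0; q < m.size(); ++q) {
      int pos = m[q];
      bool drop = (has_global && drop_global[pos - 1]) ||
        (!lq.empty() && std::binary_search(lq.begin(), lq.end(), pos));
      if (!drop) km.push_back(pos);
    }
    out_s[r] = IntegerVector(ks.begin(), ks.end());
    out_e[r] = IntegerVector(ke.begin(), ke.end());
    out_m[r] = IntegerVector(km.begin(), km.end());
  }
  return List::create(_["starts"] = out_s, _["ends"] = out_e,
                      _["muts"] = out_m);
}

// Pairwise contingency accumulation over all i < j with difference-array
// updates: per read the work is O(k^2 + |M|*k + |M|^2) for k covered
// intervals and M mutations, never O(covered^2). Integration to full count
// matrices happens once at the end.
//   N  : reads covering both i and j            (2-d difference array)
//   A  : reads with i mutated and j covered     (row difference arrays)
//   B  : reads with j mutated and i covered     (column difference arrays)
//   n11: reads with both mutated               (explicit, |M|^2 per read)
// Cells: n11; n10 = A - n11; n01 = B - n11; n00 = N - A - B + n11.
// Only the strict upper triangle (i < j) of the outputs is meaningful.
// [[Rcpp::export]]
List accumulate_cpp(List starts, List ends, List muts, int L) {
  IntegerMatrix D(L + 1, L + 1);   // 2-d diff for N
  IntegerMatrix A(L, L + 1);       // row diffs
  IntegerMatrix B(L + 1, L);       // column diffs
  IntegerMatrix n11(L, L);
  int n = starts.size();
  for (int r = 0; r < n; ++r) {
    IntegerVector s = starts[r], e = ends[r], m = muts[r];
    int k = s.size(), nm = m.size();
    for (int p = 0; p < k; ++p) {
      if (s[p] < 1 || e[p] > L) stop("read %d: position outside [1, %d]",
                                     r + 1, L);
      for (int q = p; q < k; ++q) {
        // rectangle [s_p, e_p] x [s_q, e_q]; for p == q only the upper
        // triangle of the square is ever read back
        D(s[p] - 1, s[q] - 1) += 1;
        D(s[p] - 1, e[q])     -= 1;
        D(e[p],     s[q] - 1) -= 1;
        D(e[p],     e[q])     += 1;
      }
    }
    for (int q = 0; q < nm; ++q) {
      int mp = m[q];
      for (int p = 0; p < k; ++p) {
        int lo = std::max((int)s[p], mp + 1);
        if (lo <= e[p]) { A(mp - 1, lo - 1) += 1; A(mp - 1, e[p]) -= 1; }
        int hi = std::min((int)e[p], mp - 1);
        if (s[p] <= hi) { B(s[p] - 1, mp - 1) += 1; B(hi, mp - 1) -= 1; }
      }
      for (int q2 = q + 1; q2 < nm; ++q2) {
        int a = std::min(mp, (int)m[q2]), b = std::max(mp, (int)m[q2]);
        if (a != b) n11(a - 1, b - 1) += 1;
      }
    }
  }
  // integrate
  IntegerMatrix N(L, L), Ao(L, L), Bo(L, L);
  for (int i = 0; i < L; ++i) {
    int acc = 0;
    for (int j = 0; j < L; ++j) { acc += A(i, j); Ao(i, j) = acc; }
  }
  for (int j = 0; j < L; ++j) {
    int acc = 0;
    for (int i = 0; i < L; ++i) { acc += B(i, j); Bo(i, j) = acc; }
  }
  for (int i = 0; i <= L; ++i)
    for (int j = 1; j <= L; ++j) D(i, j) += D(i, j - 1);
  for (int j = 0; j <= L; ++j)
    for (int i = 1; i <= L; ++i) D(i, j) += D(i - 1, j);
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) N(i, j) = D(i, j);
  return List::create(_["N"] = N, _["A"] = Ao, _["B"] = Bo, _["n11"] = n11);
}

// Per-molecule generative model: latent binary factor per block, position-
// wise modification probability prot * (b + f * d), OR-folded sequencing
// error, random-primed paired-end geometry with a mate gap when the insert
// exceeds twice the mate length. Uses R's RNG stream so runs are
// reproducible from set.seed().
// [[Rcpp::export]]
List simulate_cpp(int L, int nfrag, int insert_min, int insert_max,
                  int mate_len, NumericVector base_rate, NumericVector dinc,
                  IntegerVector block, NumericVector p_occ, double seq_error,
                  double lowq_frac, NumericVector prot,
                  int cpl_a, int cpl_b, double cpl_rho) {
  int K = p_occ.size();
  List out_s(nfrag), out_e(nfrag), out_m(nfrag), out_q(nfrag);
  std::vector<int> f(K > 0 ? K : 1);
  double p11 = 0.0;
  if (cpl_a > 0) {
    double pa = p_occ[cpl_a - 1], pb = p_occ[cpl_b - 1];
    p11 = pa * pb + cpl_rho * std::sqrt(pa * (1 - pa) * pb * (1 - pb));
  }
  for (int r = 0; r < nfrag; ++r) {
    for (int k = 0; k < K; ++k) {
      if (cpl_a > 0 && k == cpl_b - 1) {
        double pa = p_occ[cpl_a - 1], pb = p_occ[cpl_b - 1];
        double pc = f[cpl_a - 1] ? p11 / pa : (pb - p11) / (1 - pa);
        f[k] = unif_rand() < pc;
      } else {
        f[k] = unif_rand() < p_occ[k];
      }
    }
    int ins = insert_min +
      (int)std::floor(unif_rand() * (insert_max - insert_min + 1));
    if (ins > insert_max) ins = insert_max;  // guard unif_rand() == 1
    if (ins > L) ins = L;
    int nstart = L - ins + 1;
    int start = 1 + (int)std::floor(unif_rand() * nstart);
    if (start > nstart) start = nstart;
    std::vector<int> ks, ke;
    if (ins <= 2 * mate_len) {
      ks.push_back(start); ke.push_back(start + ins - 1);
    } else {
      ks.push_back(start); ke.push_back(start + mate_len - 1);
      ks.push_back(start + ins - mate_len); ke.push_back(start + ins - 1);
    }
    std::vector<int> mv, qv;
    for (size_t p = 0; p < ks.size(); ++p) {
      for (int pos = ks[p]; pos <= ke[p]; ++pos) {
        double pm = base_rate[pos - 1];
        int blk = block[pos - 1];
        if (blk > 0 && f[blk - 1]) pm += dinc[pos - 1];
        pm *= prot[pos - 1];
        double pobs = pm + seq_error - pm * seq_error;
        if (unif_rand() < pobs) mv.push_back(pos);
        if (lowq_frac > 0 && unif_rand() < lowq_frac) qv.push_back(pos);
      }
    }
    out_s[r] = IntegerVector(ks.begin(), ks.end());
    out_e[r] = IntegerVector(ke.begin(), ke.end());
    out_m[r] = IntegerVector(mv.begin(), mv.end());
    out_q[r] = IntegerVector(qv.begin(), qv.end());
  }
  return List::create(_["starts"] = out_s, _["ends"] = out_e,
                      _["muts"] = out_m, _["lowq"] = out_q);
}

// Per-position coverage depth and mutation counts (1-d difference array).
// [[Rcpp::export]]
List coverage_cpp(List starts, List ends, List muts, int L) {
  IntegerVector depth(L + 1), cnt(L);
  int n = starts.size();
  for (int r = 0; r < n; ++r) {
    IntegerVector s = starts[r], e = ends[r], m = muts[r];
    for (int p = 0; p < s.size(); ++p) {
      if (s[p] < 1 || e[p] > L) stop("read %d: position outside [1, %d]",
                                     r + 1, L);
      depth[s[p] - 1] += 1; depth[e[p]] -= 1;
    }
    for (int q = 0; q < m.size(); ++q) cnt[m[q] - 1] += 1;
  }
  IntegerVector d(L);
  int acc = 0;
  for (int i = 0; i < L; ++i) { acc += depth[i]; d[i] = acc; }
  return List::create(_["depth"] = d, _["count"] = cnt);
}
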