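// Low-level kernels: banded unit-cost alignment with traceback, canonical
// minimizer extraction, shared-unique-k-mer anchoring, longest increasing
// subsequence, pileup accumulation, reverse complement.
#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <deque>
#include <map>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

static const int INF16 = 60000;

// Affine-gap (Gotoh) global or fit alignment of query a against target b,
// restricted to the diagonal band dmin <= j - i <= dmax (i over a, j over b).
// Costs: match 0, mismatch mm, gap open go, gap extend ge (a gap of length
// L costs go + L * ge). The query is always consumed in full; fit = TRUE
// frees both ends of b (no cost for unaligned target flanks). Ops alphabet:
// M match, X mismatch, I consumes a only (insertion in a), D consumes b only.
// Affine penalties keep indels contiguous instead of scattering them across
// chance matches in the flanks -- essential for difference calling.
// [[Rcpp::export]]
List align_band_cpp(std::string a, std::string b, bool fit, int dmin, int dmax,
                    int mm = 4, int go = 3, int ge = 4) {
  const int n = (int)a.size(), m = (int)b.size();
  if (dmin > dmax) stop("alignment band is empty (dmin > dmax)");
  if (!fit && (m - n < dmin || m - n > dmax))
    stop("global alignment endpoint outside band");
  const long long W = (long long)dmax - dmin + 1;
  if ((double)(n + 1) * (double)W * 3.0 > 4.5e8)
    stop("alignment band too large; reduce input size or band width");
  // state matrices: 0 = M (diagonal), 1 = E (gap in a, consumes b -> 'D'),
  // 2 = F (gap in b, consumes a -> 'I')
  std::vector<uint16_t> Mv((size_t)(n + 1) * W, (uint16_t)INF16);
  std::vector<uint16_t> Ev((size_t)(n + 1) * W, (uint16_t)INF16);
  std::vector<uint16_t> Fv((size_t)(n + 1) * W, (uint16_t)INF16);
  auto idx = [&](int i, int j) -> size_t {
    return (size_t)i * W + (size_t)(j - i - dmin);
  };
  auto inb = [&](int i, int j) -> bool {
    int d = j - i;
    return j >= 0 && j <= m && d >= dmin && d <= dmax;
  };
  auto cap = [](long long v) -> uint16_t {
    return (uint16_t)(v >= INF16 ? INF16 : v);
  };
  for (int j = std::max(0, dmin); j <= std::min(m, dmax); ++j) {
    if (fit) {
      Mv[idx(0, j)] = 0;
    } else {
      if (j == 0) Mv[idx(0, 0)] = 0;
      else Ev[idx(0, j)] = cap((long long)go + (long long)ge * j);
    }
  }
  for (int i = 1; i <= n; ++i) {
    const int jlo = std::max(0, i + dmin), jhi = std::min(m, i + dmax);
    for (int j = jlo; j <= jhi; ++j) {
      const size_t c = idx(i, j);
      // F: gap in b (consume a only), from (i-1, j)
      if (inb(i - 1, j)) {
        const size_t u = idx(i - 1, j);
        long long open = (long long)std::min(Mv[u], Ev[u]) + go + ge;
        long long ext = (long long)Fv[u] + ge;
        Fv[c] = cap(std::min(open, ext));
      }
      // E: gap in a (consume b only), from (i, j-1)
      if (j >= 1 && inb(i, j - 1)) {
        const size_t l = idx(i, j - 1);
        long long open = (long long)std::min(Mv[l], Fv[l]) + go + ge;
        long long ext = (long long)Ev[l] + ge;
        Ev[c] = cap(std::min(open, ext));
      }
      // M: diagonal
      if (j >= 1 && inb(i - 1, j - 1)) {
        const size_t d = idx(i - 1, j - 1);
        long long prev = std::min(Mv[d], (uint16_t)std::min(Ev[d], Fv[d]));
        Mv[c] = cap(prev + (a[i - 1] == b[j - 1] ? 0 : mm));
      }
    }
  }
  int je = -1, state = 0;
  long long bestc = INF16;
  if (fit) {
    for (int j = std::max(0, n + dmin); j <= std::min(m, n + dmax); ++j) {
      const size_t c = idx(n, j);
      // trailing b is free: any end state is acceptable
      uint16_t v = std::min(Mv[c], std::min(Ev[c], Fv[c]));
      if ((long long)v < bestc) {
        bestc = v; je = j;
        state = (v == Mv[c]) ? 0 : (v == Fv[c] ? 2 : 1);
      }
    }
    if (je < 0) stop("no feasible alignment endpoint in band");
  } else {
    je = m;
    const size_t c = idx(n, m);
    bestc = std::min(Mv[c], std::min(Ev[c], Fv[c]));
    state = (bestc == Mv[c]) ? 0 : (bestc == Fv[c] ? 2 : 1);
  }
  if (bestc >= INF16)
    return List::create(_["ok"] = false, _["dist"] = R_NaInt);
  std::string ops;
  ops.reserve((size_t)(n + std::abs(m - n) + 16));
  int i = n, j = je;
  while (i > 0 || (!fit && j > 0)) {
    const size_t c = idx(i, j);
    if (state == 0) {
      if (i == 0) { // global with leading gap folded into M start: impossible
        stop("traceback failed (M at row 0)");
      }
      ops.push_back(a[i - 1] == b[j - 1] ? 'M' : 'X');
      const size_t d = idx(i - 1, j - 1);
      const int cost = (a[i - 1] == b[j - 1] ? 0 : mm);
      --i; --j;
      if ((long long)Mv[d] + cost == (long long)Mv[c]) state = 0;
      else if ((long long)Fv[d] + cost == (long long)Mv[c]) state = 2;
      else state = 1;
      if (i == 0 && (fit || j == 0)) break;
      if (i == 0 && !fit) { state = 1; continue; }
    } else if (state == 2) { // F: consume a
      ops.push_back('I');
      const size_t u = idx(i - 1, j);
      --i;
      if ((long long)Fv[u] + ge == (long long)Fv[c]) state = 2;
      else if ((long long)Mv[u] + go + ge == (long long)Fv[c]) state = 0;
      else state = 1;
      if (i == 0 && fit) break;
      if (i == 0 && !fit && j == 0) break;
      if (i == 0 && !fit) { state = 1; continue; }
    } else { // E: consume b
      ops.push_back('D');
      const size_t l = idx(i, j - 1);
      --j;
      if (j == 0 && i == 0) break;
      if ((long long)Ev[l] + ge == (long long)Ev[c]) state = 1;
      else if ((long long)Mv[l] + go + ge == (long long)Ev[c]) state = 0;
      else state = 2;
    }
    if (fit && i == 0) break;
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(
    _["ok"] = true, _["dist"] = (int)bestc, _["ops"] = ops,
    _["b_start"] = j, _["b_end"] = je);
}

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline uint64_t mixhash(uint64_t key, uint64_t mask) {
  key = (~key + (key << 21)) & mask;
  key = key ^ (key >> 24);
  key = (key + (key << 3) + (key << 8)) & mask;
  key = key ^ (key >> 14);
  key = (key + (key << 2) + (key << 4)) & mask;
  key = key ^ (key >> 28);
  key = (key + (key << 31)) & mask;
  return key;
}

// Canonical (strand-least) minimizers of seq: windows of w consecutive k-mers,
// leftmost minimal hash per window. k-mers containing non-ACGT are skipped and
// break windows. Returns 0-based positions, the canonical k-mer code (exact in
// a double for k <= 26), and whether the forward strand is the canonical one.
// [[Rcpp::export]]
DataFrame minimizers_cpp(std::string seq, int k, int w) {
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  if (w < 1) stop("w must be >= 1");
  const int L = (int)seq.size();
  std::vector<int> pos_out;
  std::vector<double> key_out;
  std::vector<int> fwd_out;
  if (L < k) {
    return DataFrame::create(_["pos"] = IntegerVector(0),
                             _["key"] = NumericVector(0),
                             _["fwd"] = LogicalVector(0));
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rc = 0;
  int valid = 0; // number of consecutive valid bases ending here
  // deque of (hash, kmer_index), increasing hash
  std::deque<std::pair<uint64_t, int> > dq;
  std::vector<uint64_t> canon(L, 0);
  std::vector<uint8_t> isfwd(L, 1);
  int last_emitted = -1;
  for (int i = 0; i < L; ++i) {
    const int c = base2bits(seq[i]);
    if (c < 0) {
      valid = 0; dq.clear();
      continue;
    }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    ++valid;
    if (valid < k) continue;
    const int ki = i - k + 1; // k-mer start
    uint64_t v; bool f;
    if (fwd <= rc) { v = fwd; f = true; } else { v = rc; f = false; }
    canon[ki] = v;
    isfwd[ki] = f ? 1 : 0;
    const uint64_t h = mixhash(v, mask);
    while (!dq.empty() && dq.back().first > h) dq.pop_back();
    dq.push_back(std::make_pair(h, ki));
    while (dq.front().second < ki - w + 1) dq.pop_front();
    if (valid >= k + w - 1) { // first full window available
      const int mp = dq.front().second;
      if (mp != last_emitted) {
        pos_out.push_back(mp);
        key_out.push_back((double)canon[mp]);
        fwd_out.push_back(isfwd[mp]);
        last_emitted = mp;
      }
    }
  }
  // short valid stretches (< k+w-1 but >= k): emit their minimum as well
  // (handled implicitly only for long stretches above; redo a cheap pass)
  if (pos_out.empty() && L >= k) {
    // sequence shorter than a full window (or no full window): pick global min
    uint64_t besth = ~0ULL; int bestp = -1;
    uint64_t f2 = 0, r2 = 0; int val2 = 0;
    for (int i = 0; i < L; ++i) {
      const int c = base2bits(seq[i]);
      if (c < 0) { val2 = 0; continue; }
      f2 = ((f2 << 2) | (uint64_t)c) & mask;
      r2 = (r2 >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      ++val2;
      if (val2 < k) continue;
      const int ki = i - k + 1;
      uint64_t v = std::min(f2, r2);
      const uint64_t h = mixhash(v, mask);
      if (h < besth) { besth = h; bestp = ki; }
    }
    if (bestp >= 0) {
      uint64_t v = canon[bestp];
      pos_out.push_back(bestp);
      key_out.push_back((double)v);
      fwd_out.push_back(isfwd[bestp]);
    }
  }
  return DataFrame::create(_["pos"] = wrap(pos_out),
                           _["key"] = wrap(key_out),
                           _["fwd"] = LogicalVector(fwd_out.begin(), fwd_out.end()));
}

// Positions of k-mers that occur exactly once in a AND exactly once in b with
// identical forward-strand content. Returned sorted by pos_a (0-based).
// [[Rcpp::export]]
DataFrame shared_unique_kmers_cpp(std::string a, std::string b, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_map<uint64_t, long long> ma, mb;
  ma.reserve(a.size() * 2); mb.reserve(b.size() * 2);
  for (int pass = 0; pass < 2; ++pass) {
    const std::string &s = pass == 0 ? a : b;
    std::unordered_map<uint64_t, long long> &mp = pass == 0 ? ma : mb;
    uint64_t v = 0; int valid = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      const int c = base2bits(s[i]);
      if (c < 0) { valid = 0; continue; }
      v = ((v << 2) | (uint64_t)c) & mask;
      if (++valid < k) continue;
      const int ki = i - k + 1;
      std::unordered_map<uint64_t, long long>::iterator it = mp.find(v);
      if (it == mp.end()) mp[v] = ki; else it->second = -1;
    }
  }
  std::vector<std::pair<int, int> > out;
  for (std::unordered_map<uint64_t, long long>::iterator it = ma.begin();
       it != ma.end(); ++it) {
    if (it->second < 0) continue;
    std::unordered_map<uint64_t, long long>::iterator jt = mb.find(it->first);
    if (jt == mb.end() || jt->second < 0) continue;
    out.push_back(std::make_pair((int)it->second, (int)jt->second));
  }
  std::sort(out.begin(), out.end());
  IntegerVector pa(out.size()), pb(out.size());
  for (size_t i = 0; i < out.size(); ++i) {
    pa[i] = out[i].first; pb[i] = out[i].second;
  }
  return DataFrame::create(_["pos_a"] = pa, _["pos_b"] = pb);
}

// 1-based indices of a longest strictly increasing subsequence of v.
// [[Rcpp::export]]
IntegerVector lis_cpp(IntegerVector v) {
  const int n = v.size();
  if (n == 0) return IntegerVector(0);
  std::vector<int> tails;      // indices into v of tail elements
  std::vector<int> parent(n, -1);
  for (int i = 0; i < n; ++i) {
    int lo = 0, hi = (int)tails.size();
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (v[tails[mid]] < v[i]) lo = mid + 1; else hi = mid;
    }
    if (lo > 0) parent[i] = tails[lo - 1];
    if (lo == (int)tails.size()) tails.push_back(i);
    else tails[lo] = i;
  }
  std::vector<int> res;
  for (int i = tails.empty() ? -1 : tails.back(); i >= 0; i = parent[i])
    res.push_back(i + 1);
  std::reverse(res.begin(), res.end());
  return wrap(res);
}

// Accumulate per-column base/deletion counts and between-column insertion
// candidates from alignments of oriented reads to a target of length tlen.
// [[Rcpp::export]]
List pileup_cpp(int tlen, IntegerVector t_start, CharacterVector ops,
                CharacterVector qseq) {
  const int nh = t_start.size();
  if (ops.size() != nh || qseq.size() != nh) stop("pileup input length mismatch");
  IntegerMatrix counts(tlen, 5); // A C G T del
  std::vector<int> jdiff(tlen + 2, 0);
  std::map<int, std::map<std::string, int> > ins;
  for (int h = 0; h < nh; ++h) {
    const std::string op = as<std::string>(ops[h]);
    const std::string q = as<std::string>(qseq[h]);
    int ti = t_start[h], qi = 0;
    std::string cur_ins;
    int ins_at = -1;
    for (size_t c = 0; c < op.size(); ++c) {
      const char o = op[c];
      if (o == 'I') {
        if (ins_at < 0) ins_at = ti;
        cur_ins.push_back(q[qi]);
        ++qi;
        continue;
      }
      if (ins_at >= 0) {
        ins[ins_at][cur_ins] += 1;
        cur_ins.clear(); ins_at = -1;
      }
      if (o == 'M' || o == 'X') {
        if (ti >= 0 && ti < tlen) {
          const int bidx = base2bits(q[qi]);
          if (bidx >= 0) counts(ti, bidx) += 1;
        }
        ++ti; ++qi;
      } else if (o == 'D') {
        if (ti >= 0 && ti < tlen) counts(ti, 4) += 1;
        ++ti;
      } else {
        stop("unknown op in pileup");
      }
    }
    if (ins_at >= 0) ins[ins_at][cur_ins] += 1;
    // junction coverage: read spans junction p (between p-1 and p) when
    // t_start < p < t_end
    const int te = ti;
    if (te - t_start[h] >= 2) {
      jdiff[t_start[h] + 1] += 1;
      jdiff[std::min(te, tlen + 1)] -= 1;
    }
  }
  IntegerVector jcov(tlen + 1);
  int acc = 0;
  for (int p = 0; p <= tlen; ++p) { acc += jdiff[p]; jcov[p] = acc; }
  std::vector<int> ipos; std::vector<std::string> istr; std::vector<int> icnt;
  for (std::map<int, std::map<std::string, int> >::iterator it = ins.begin();
       it != ins.end(); ++it) {
    for (std::map<std::string, int>::iterator jt = it->second.begin();
         jt != it->second.end(); ++jt) {
      ipos.push_back(it->first);
      istr.push_back(jt->first);
      icnt.push_back(jt->second);
    }
  }
  return List::create(_["counts"] = counts, _["jcov"] = jcov,
                      _["ins_pos"] = wrap(ipos), _["ins_str"] = wrap(istr),
                      _["ins_cnt"] = wrap(icnt));
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = s[s.size() - 1 - j], o;
      switch (c) {
        case 'A': o = 'T'; break; case 'C': o = 'G'; break;
        case 'G': o = 'C'; break; case 'T': o = 'A'; break;
        case 'a': o = 't'; break; case 'c': o = 'g'; break;
        case 'g': o = 'c'; break; case 't': o = 'a'; break;
        default: o = 'N';
      }
      r[j] = o;
    }
    out[i] = r;
  }
  if (x.hasAttribute("names")) out.names() = x.names();
  return out;
}

// counts of M, X, I, D in an ops string
// [[Rcpp::export]]
IntegerVector ops_stats_cpp(std::string ops) {
  int m = 0, x = 0, i = 0, d = 0;
  for (size_t c = 0; c < ops.size(); ++c) {
    switch (ops[c]) {
      case 'M': ++m; break; case 'X': ++x; break;
      case 'I': ++i; break; case 'D': ++d; break;
    }
  }
  IntegerVector out = IntegerVector::create(
    _["n_match"] = m, _["n_mismatch"] = x, _["n_ins"] = i, _["n_del"] = d);
  return out;
}

// maximum absolute net diagonal drift (|#I - #D| running) along an ops string
// [[Rcpp::export]]
int ops_max_drift_cpp(std::string ops) {
  int net = 0, mx = 0;
  for (size_t c = 0; c < ops.size(); ++c) {
    if (ops[c] == 'I') --net;
    else if (ops[c] == 'D') ++net;
    if (std::abs(net) > mx) mx = std::abs(net);
  }
  return mx;
}
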