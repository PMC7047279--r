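#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <cmath>
#include <map>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Deterministic, platform-independent RNG (xorshift128+ seeded by splitmix64)
// so that simulated reads are reproducible across systems independently of
// R's RNG state.
namespace {

struct Rng {
  uint64_t s0, s1;
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t a) {
    uint64_t x = a;
    s0 = splitmix(x);
    s1 = splitmix(x);
    if (!(s0 | s1)) s0 = 0x9E3779B97F4A7C15ULL;
  }
  uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

inline uint64_t mix(uint64_t h, uint64_t v) {
  h ^= v + 0x9E3779B97F4A7C15ULL + (h << 6) + (h >> 2);
  return h;
}

inline uint64_t derive_seed(uint64_t base, int sample, int gene, int amp, int hap) {
  uint64_t x = base;
  x = mix(x, (uint64_t)(sample + 1));
  x = mix(x, (uint64_t)(gene + 1));
  x = mix(x, (uint64_t)(amp + 1));
  x = mix(x, (uint64_t)(hap + 1));
  return x;
}

const char BASES[4] = {'A', 'C', 'G', 'T'};

inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

std::string revcomp(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp(out[i]);
  return out;
}

// i.i.d. substitution errors at rate p, via geometric position skipping
void add_errors(std::string &read, double p, Rng &rng) {
  if (p <= 0.0) return;
  const double log1mp = std::log1p(-p);
  long pos = -1;
  const long n = (long)read.size();
  while (true) {
    double u = rng.unif();
    if (u <= 0.0) u = 1e-300;
    pos += 1 + (long)std::floor(std::log(u) / log1mp);
    if (pos >= n) break;
    int b = base_idx(read[pos]);
    if (b >= 0) read[pos] = BASES[(b + 1 + rng.below(3)) % 4];
  }
}

// One read pair from an amplicon: R1 from the 5' end, R2 reverse-complement
// from the 3' end; read length is capped at the amplicon length.
void sim_pair(const std::string &seq, int read_len, double err, Rng &rng,
              std::string &r1, std::string &r2) {
  const int L = (int)seq.size();
  const int R = std::min(read_len, L);
  r1.assign(seq, 0, R);
  r2 = revcomp(seq.substr(L - R, R));
  add_errors(r1, err, rng);
  add_errors(r2, err, rng);
}

// Overlap-merge a pair given candidate amplicon lengths. Returns an empty
// string when no candidate length explains the pair. Where the two reads
// disagree in the overlap, R1's base is kept.
std::string merge_pair(const std::string &r1, const std::string &r2,
                       const std::vector<int> &cand_lens) {
  const int R = (int)r1.size();
  if ((int)r2.size() != R || R == 0) return std::string();
  const std::string r2c = revcomp(r2);
  int best_len = -1;
  double best_rate = 1e9;
  for (int L : cand_lens) {
    if (L < R || L > 2 * R) continue;
    const int ov = 2 * R - L;  // overlap size
    if (ov < 5) continue;
    int mm = 0;
    // r1 positions [L-R, R) vs r2c positions [0, ov)
    for (int k = 0; k < ov; ++k)
      if (r1[L - R + k] != r2c[k]) ++mm;
    double rate = (double)mm / ov;
    if (rate < best_rate - 1e-12) {
      best_rate = rate;
      best_len = L;
    }
  }
  if (best_len < 0 || best_rate > 0.2) return std::string();
  return r1 + r2c.substr(2 * R - best_len);
}

struct ClassRef {
  std::vector<std::string> sigs;         // per-allele signatures
  std::vector<std::string> distinct;     // deduplicated signatures
  std::vector<int> lens;                 // lengths of distinct sigs
};

const int PREFIX_LEN = 48;
const double ASSIGN_MAX_RATE = 0.2;

// Nearest reference class by prefix Hamming distance among classes holding a
// signature of the merged read's length. Ties across classes or distances
// beyond max_mm leave the read unassigned (-1).
int assign_class(const std::string &merged, const std::vector<ClassRef> &refs,
                 int max_mm) {
  const int L = (int)merged.size();
  const int P = std::min(PREFIX_LEN, L);
  int best = -1, best_d = 1 << 30;
  bool tie = false;
  for (size_t a = 0; a < refs.size(); ++a) {
    const ClassRef &cr = refs[a];
    int cls_d = 1 << 30;
    for (size_t k = 0; k < cr.distinct.size(); ++k) {
      if (cr.lens[k] != L) continue;
      const std::string &sig = cr.distinct[k];
      int d = 0;
      for (int p = 0; p < P && d < cls_d; ++p)
        if (merged[p] != sig[p]) ++d;
      if (d < cls_d) cls_d = d;
    }
    if (cls_d < best_d) {
      best_d = cls_d;
      best = (int)a;
      tie = false;
    } else if (cls_d == best_d && cls_d < (1 << 30) && (int)a != best) {
      tie = true;
    }
  }
  if (best < 0 || tie || best_d > max_mm) return -1;
  return best;
}

struct CallResult {
  std::vector<std::string> variants;
  std::vector<int> counts;
  int nreads;
};

// Positional variant caller for one amplicon stack: column-wise consensus,
// heterozygous columns where the minor-base fraction reaches min_minor_frac
// (with at least 2 supporting reads), then per-read phasing of the
// heterozygous columns; the top <= 2 phase patterns define the variants.
CallResult call_stack(const std::vector<std::string> &reads, double min_minor_frac) {
  CallResult res;
  res.nreads = (int)reads.size();
  if (reads.empty()) return res;

  // modal read length (non-modal lengths: merge artefacts, dropped)
  std::map<int, int> len_count;
  for (const auto &r : reads) ++len_count[(int)r.size()];
  int modal_len = 0, modal_n = 0;
  for (const auto &kv : len_count)
    if (kv.second > modal_n) { modal_n = kv.second; modal_len = kv.first; }

  std::vector<const std::string *> sub;
  sub.reserve(modal_n);
  for (const auto &r : reads)
    if ((int)r.size() == modal_len) sub.push_back(&r);

  std::vector<std::array<int, 4>> cnt(modal_len, {0, 0, 0, 0});
  for (const auto *r : sub)
    for (int p = 0; p < modal_len; ++p) {
      int b = base_idx((*r)[p]);
      if (b >= 0) ++cnt[p][b];
    }

  std::string consensus(modal_len, 'N');
  std::vector<int> het_pos;
  for (int p = 0; p < modal_len; ++p) {
    int b1 = 0, b2 = -1;
    for (int b = 1; b < 4; ++b) if (cnt[p][b] > cnt[p][b1]) b1 = b;
    for (int b = 0; b < 4; ++b) if (b != b1 && (b2 < 0 || cnt[p][b] > cnt[p][b2])) b2 = b;
    consensus[p] = BASES[b1];
    int c1 = cnt[p][b1], c2 = cnt[p][b2];
    if (c2 >= 2 && (double)c2 >= min_minor_frac * (c1 + c2)) het_pos.push_back(p);
  }

  if (het_pos.empty()) {
    res.variants.push_back(consensus);
    res.counts.push_back((int)sub.size());
    return res;
  }

  std::map<std::string, int> patterns;
  for (const auto *r : sub) {
    std::string pat(het_pos.size(), 'N');
    for (size_t k = 0; k < het_pos.size(); ++k) pat[k] = (*r)[het_pos[k]];
    ++patterns[pat];
  }
  std::vector<std::pair<std::string, int>> pv(patterns.begin(), patterns.end());
  std::sort(pv.begin(), pv.end(), [](const std::pair<std::string, int> &a,
                                     const std::pair<std::string, int> &b) {
    if (a.second != b.second) return a.second > b.second;
    return a.first < b.first;
  });

  auto build = [&](const std::string &pat) {
    std::string v = consensus;
    for (size_t k = 0; k < het_pos.size(); ++k) v[het_pos[k]] = pat[k];
    return v;
  };
  res.variants.push_back(build(pv[0].first));
  res.counts.push_back(pv[0].second);
  if (pv.size() > 1 &&
      (double)pv[1].second >= min_minor_frac * (pv[0].second + pv[1].second)) {
    res.variants.push_back(build(pv[1].first));
    res.counts.push_back(pv[1].second);
  }
  return res;
}

std::vector<ClassRef> build_refs(const List &class_sigs) {
  std::vector<ClassRef> refs(class_sigs.size());
  for (int a = 0; a < class_sigs.size(); ++a) {
    CharacterVector cv = class_sigs[a];
    ClassRef &cr = refs[a];
    cr.sigs.reserve(cv.size());
    for (int j = 0; j < cv.size(); ++j) cr.sigs.push_back(as<std::string>(cv[j]));
    std::vector<std::string> d(cr.sigs);
    std::sort(d.begin(), d.end());
    d.erase(std::unique(d.begin(), d.end()), d.end());
    cr.distinct = d;
    for (const auto &s : d) cr.lens.push_back((int)s.size());
  }
  return refs;
}

std::vector<int> candidate_lengths(const std::vector<ClassRef> &refs) {
  std::vector<int> lens;
  for (const auto &cr : refs)
    for (int L : cr.lens) lens.push_back(L);
  std::sort(lens.begin(), lens.end());
  lens.erase(std::unique(lens.begin(), lens.end()), lens.end());
  return lens;
}

}  // namespace

// [[Rcpp::export]]
List cpp_sim_pairs(std::string seq, int n_pairs, int read_len, double error_rate,
                   int seed, int sample, int gene, int amp, int hap) {
  Rng rng;
  rng.seed(derive_seed((uint64_t)(uint32_t)seed, sample, gene, amp, hap));
  CharacterVector r1(n_pairs), r2(n_pairs);
  std::string a, b;
  for (int j = 0; j < n_pairs; ++j) {
    sim_pair(seq, read_len, error_rate, rng, a, b);
    r1[j] = a;
    r2[j] = b;
  }
  return List::create(_["r1"] = r1, _["r2"] = r2);
}

// [[Rcpp::export]]
List cpp_call_sample(CharacterVector r1, CharacterVector r2, List class_sigs,
                     double min_minor_frac, int max_assign_mm) {
  std::vector<ClassRef> refs = build_refs(class_sigs);
  std::vector<int> cand_lens = candidate_lengths(refs);
  std::vector<std::vector<std::string>> stacks(refs.size());
  int unassigned = 0;
  for (int i = 0; i < r1.size(); ++i) {
    std::string merged = merge_pair(as<std::string>(r1[i]), as<std::string>(r2[i]),
                                    cand_lens);
    if (merged.empty()) { ++unassigned; continue; }
    int a = assign_class(merged, refs, max_assign_mm);
    if (a < 0) { ++unassigned; continue; }
    stacks[a].push_back(merged);
  }
  List out(refs.size());
  for (size_t a = 0; a < refs.size(); ++a) {
    CallResult cr = call_stack(stacks[a], min_minor_frac);
    out[a] = List::create(_["variants"] = wrap(cr.variants),
                          _["counts"] = wrap(cr.counts),
                          _["nreads"] = cr.nreads);
  }
  out.attr("unassigned") = unassigned;
  return out;
}

// Full cohort driver: for every sample, simulate read pairs for each gene /
// amplicon / haplotype (seed stream identical to cpp_sim_pairs), merge,
// assign to amplicon classes and call variants. Variants are returned as
// indices into a per-class dictionary to keep the result compact.
// [[Rcpp::export]]
List cpp_type_cohort(IntegerVector class_gene, IntegerVector class_amp,
                     List class_sigs, List haps, int depth, int read_len,
                     double error_rate, double min_minor_frac, int max_assign_mm,
                     int seed) {
  const int A = class_sigs.size();
  std::vector<ClassRef> refs = build_refs(class_sigs);
  std::vector<int> cand_lens = candidate_lengths(refs);

  const int G = haps.size();
  std::vector<IntegerMatrix> hapm;
  for (int g = 0; g < G; ++g) hapm.push_back(as<IntegerMatrix>(haps[g]));
  const int n = hapm.empty() ? 0 : hapm[0].nrow();
  const int n_pairs = std::max(1, depth / 2);

  std::vector<std::map<std::string, int>> dicts(A);
  std::vector<std::vector<std::string>> dict_list(A);
  std::vector<IntegerVector> v1(A), v2(A), c1(A), c2(A), nreads(A);
  for (int a = 0; a < A; ++a) {
    v1[a] = IntegerVector(n, 0);
    v2[a] = IntegerVector(n, 0);
    c1[a] = IntegerVector(n, 0);
    c2[a] = IntegerVector(n, 0);
    nreads[a] = IntegerVector(n, 0);
  }

  std::vector<std::vector<std::string>> stacks(A);
  Rng rng;
  std::string ra, rb;

  for (int i = 0; i < n; ++i) {
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    for (int a = 0; a < A; ++a) stacks[a].clear();
    for (int a = 0; a < A; ++a) {
      const int g = class_gene[a] - 1;
      for (int h = 0; h < 2; ++h) {
        const int allele = hapm[g](i, h) - 1;
        if (allele < 0 || allele >= (int)refs[a].sigs.size())
          stop("haplotype allele index out of range");
        const std::string &seq = refs[a].sigs[allele];
        rng.seed(derive_seed((uint64_t)(uint32_t)seed, i + 1, g + 1, class_amp[a], h + 1));
        for (int j = 0; j < n_pairs; ++j) {
          sim_pair(seq, read_len, error_rate, rng, ra, rb);
          std::string merged = merge_pair(ra, rb, cand_lens);
          if (merged.empty()) continue;
          int cls = assign_class(merged, refs, max_assign_mm);
          if (cls < 0) continue;
          stacks[cls].push_back(std::move(merged));
        }
      }
    }
    for (int a = 0; a < A; ++a) {
      CallResult cr = call_stack(stacks[a], min_minor_frac);
      nreads[a][i] = cr.nreads;
      for (size_t k = 0; k < cr.variants.size() && k < 2; ++k) {
        auto it = dicts[a].find(cr.variants[k]);
        int id;
        if (it == dicts[a].end()) {
          id = (int)dict_list[a].size() + 1;
          dicts[a][cr.variants[k]] = id;
          dict_list[a].push_back(cr.variants[k]);
        } else {
          id = it->second;
        }
        if (k == 0) { v1[a][i] = id; c1[a][i] = cr.counts[k]; }
        else { v2[a][i] = id; c2[a][i] = cr.counts[k]; }
      }
    }
  }

  List out(A);
  for (int a = 0; a < A; ++a) {
    out[a] = List::create(_["v1"] = v1[a], _["v2"] = v2[a], _["c1"] = c1[a],
                          _["c2"] = c2[a], _["nreads"] = nreads[a],
                          _["dict"] = wrap(dict_list[a]));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_merge_pairs(CharacterVector r1, CharacterVector r2,
                                IntegerVector cand_lens) {
  std::vector<int> lens(cand_lens.begin(), cand_lens.end());
  CharacterVector out(r1.size());
  for (int i = 0; i < r1.size(); ++i) {
    out[i] = merge_pair(as<std::string>(r1[i]), as<std::string>(r2[i]), lens);
  }
  return out;
}
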