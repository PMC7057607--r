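#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <functional>
using namespace Rcpp;

// ---- small helpers -------------------------------------------------------

static inline int hamming_str(const char* x, const char* y, int n, int stop_at) {
  // plain positional inequality count; N mismatches any non-N base and
  // matches N. Early abort once the count exceeds `stop_at` (< 0: never).
  int d = 0;
  for (int k = 0; k < n; ++k) {
    if (x[k] != y[k]) {
      ++d;
      if (stop_at >= 0 && d > stop_at) return d;
    }
  }
  return d;
}

static inline char comp_base(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static inline char mutate_base(char old) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  // uniform over the three bases different from `old` (over all four if N)
  if (old != 'A' && old != 'C' && old != 'G' && old != 'T') {
    return bases[(int)(unif_rand() * 4.0) % 4];
  }
  char pick;
  do {
    pick = bases[(int)(unif_rand() * 4.0) % 4];
  } while (pick == old);
  return pick;
}

// ---- Hamming distance ----------------------------------------------------

// [[Rcpp::export(name = ".hamming_cpp")]]
IntegerVector hamming_cpp(CharacterVector x, CharacterVector y) {
  R_xlen_t n = x.size();
  if (y.size() != n) stop("x and y must have the same length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING || y[i] == NA_STRING) { out[i] = NA_INTEGER; continue; }
    const char* xs = CHAR(x[i]);
    const char* ys = CHAR(y[i]);
    int lx = LENGTH(x[i]), ly = LENGTH(y[i]);
    if (lx != ly) stop("sequences must have equal length (element %d)", (int)(i + 1));
    out[i] = hamming_str(xs, ys, lx, -1);
  }
  return out;
}

// ---- all-vs-all approximate tag matching ---------------------------------

// A pair of equal-length strings within Hamming distance d must agree
// exactly on at least one of d+1 disjoint blocks. Tags are bucketed by
// (block index, block content) over both their canonical (a+b) and swapped
// (b+a) arrangements; bucket co-members become candidates, whose exact
// distance min(H(ci,cj), H(ci,swap_j)) is then verified.
// [[Rcpp::export(name = ".tag_matches_cpp")]]
DataFrame tag_matches_cpp(CharacterVector tags, CharacterVector swapped, int max_dist) {
  int n = tags.size();
  if (swapped.size() != n) stop("tags and swapped must be parallel");
  std::vector<std::string> canon(n), swp(n);
  int L = -1;
  for (int i = 0; i < n; ++i) {
    canon[i] = as<std::string>(tags[i]);
    swp[i] = as<std::string>(swapped[i]);
    if (L < 0) L = canon[i].size();
    if ((int)canon[i].size() != L || (int)swp[i].size() != L)
      stop("all tags must have equal length");
  }
  std::vector<int> out_i, out_j, out_d;
  if (n > 1 && L > 0 && max_dist >= 0) {
    int nb = max_dist + 1;
    if (nb > L) nb = L;
    std::unordered_map<std::string, std::vector<int>> buckets;
    buckets.reserve((size_t)n * nb * 2);
    for (int i = 0; i < n; ++i) {
      for (int f = 0; f < 2; ++f) {
        const std::string& s = (f == 0) ? canon[i] : swp[i];
        if (f == 1 && s == canon[i]) continue; // palindromic tag
        for (int b = 0; b < nb; ++b) {
          int from = (int)(((long long)b * L) / nb);
          int to = (int)(((long long)(b + 1) * L) / nb);
          std::string key(1, (char)('0' + b));
          key.append(s, from, to - from);
          buckets[key].push_back(i);
        }
      }
    }
    std::unordered_set<long long> seen;
    for (auto& kv : buckets) {
      std::vector<int>& v = kv.second;
      if (v.size() < 2) continue;
      // co-bucketed tag indices (may repeat across forms/blocks)
      for (size_t a = 0; a < v.size(); ++a) {
        for (size_t b = a + 1; b < v.size(); ++b) {
          int i = v[a], j = v[b];
          if (i == j) continue;
          int lo = i < j ? i : j, hi = i < j ? j : i;
          long long key = (long long)lo * n + hi;
          if (!seen.insert(key).second) continue;
          int d1 = hamming_str(canon[lo].c_str(), canon[hi].c_str(), L, max_dist);
          int d2 = hamming_str(canon[lo].c_str(), swp[hi].c_str(), L, max_dist);
          int d = d1 < d2 ? d1 : d2;
          if (d <= max_dist) {
            out_i.push_back(lo + 1);
            out_j.push_back(hi + 1);
            out_d.push_back(d);
          }
        }
      }
    }
  }
  return DataFrame::create(_["i"] = out_i, _["j"] = out_j, _["dist"] = out_d);
}

// minimum distance from each query tag to every other tag in the population,
// where the distance between two tags is the minimum over the a+b / b+a
// arrangements. `q_idx` gives each query's index into the population
// (1-based; 0 = not in the population) so a tag is never compared to itself.
// [[Rcpp::export(name = ".min_tag_dist_cpp")]]
IntegerVector min_tag_dist_cpp(CharacterVector q_canon, IntegerVector q_idx,
                               CharacterVector pop_canon, CharacterVector pop_swap) {
  int nq = q_canon.size(), np = pop_canon.size();
  if (q_idx.size() != nq) stop("q_idx must parallel q_canon");
  if (pop_swap.size() != np) stop("pop_swap must parallel pop_canon");
  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    const char* qs = CHAR(q_canon[q]);
    int L = LENGTH(q_canon[q]);
    int best = NA_INTEGER;
    int self = q_idx[q];
    for (int t = 0; t < np; ++t) {
      if (t + 1 == self) continue;
      if (LENGTH(pop_canon[t]) != L) stop("tags must have equal length");
      int cap = best == NA_INTEGER ? -1 : best - 1;
      int d = hamming_str(qs, CHAR(pop_canon[t]), L, cap);
      if (best == NA_INTEGER || d < best) best = d;
      if (best > 0) {
        cap = best - 1;
        d = hamming_str(qs, CHAR(pop_swap[t]), L, cap);
        if (d < best) best = d;
      }
      if (best == 0) break;
    }
    out[q] = best;
  }
  return out;
}

// ---- consensus voting ----------------------------------------------------

static inline int base_slot(char b) {
  switch (b) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    case 'N': return 4;
    case '-': return 5;
    default:  return -1;
  }
}

// Per-column majority vote over aligned rows, one consensus per group.
// Rows of a group are consecutive in `seqs`; `group_sizes` gives the run
// lengths. Bases with PHRED < qual_min are discarded before voting; a gap
// ('-') always votes. The winning symbol is emitted when unique and its
// fraction of surviving votes is >= cons_thres (a winning gap emits
// nothing: deletion); otherwise the column yields N. Columns where every
// vote was discarded yield N.
// [[Rcpp::export(name = ".consensus_batch_cpp")]]
CharacterVector consensus_batch_cpp(CharacterVector seqs, CharacterVector quals,
                                    IntegerVector group_sizes, double cons_thres,
                                    int qual_min) {
  static const char symbols[6] = {'A', 'C', 'G', 'T', 'N', '-'};
  int ng = group_sizes.size();
  CharacterVector out(ng);
  R_xlen_t row = 0;
  char qual_floor = (char)(qual_min + 33);
  for (int g = 0; g < ng; ++g) {
    int sz = group_sizes[g];
    if (sz < 1) stop("group %d is empty", g + 1);
    int L = LENGTH(seqs[row]);
    std::string cons;
    cons.reserve(L);
    for (int r = 0; r < sz; ++r) {
      if (LENGTH(seqs[row + r]) != L)
        stop("rows of group %d are not aligned to equal length", g + 1);
      if (LENGTH(quals[row + r]) != L)
        stop("quality string length mismatch in group %d", g + 1);
    }
    std::vector<const char*> ss(sz), qs(sz);
    for (int r = 0; r < sz; ++r) {
      ss[r] = CHAR(seqs[row + r]);
      qs[r] = CHAR(quals[row + r]);
    }
    for (int k = 0; k < L; ++k) {
      int counts[6] = {0, 0, 0, 0, 0, 0};
      int votes = 0;
      for (int r = 0; r < sz; ++r) {
        char b = ss[r][k];
        int slot = base_slot(b);
        if (slot < 0) stop("unexpected character '%c' in group %d", b, g + 1);
        if (slot != 5 && qs[r][k] < qual_floor) continue; // below quality
        ++counts[slot];
        ++votes;
      }
      if (votes == 0) { cons.push_back('N'); continue; }
      int best = 0;
      bool tie = false;
      for (int s = 1; s < 6; ++s) {
        if (counts[s] > counts[best]) { best = s; tie = false; }
        else if (counts[s] == counts[best] && counts[s] > 0 && s != best) tie = true;
      }
      if (tie || (double)counts[best] / (double)votes < cons_thres) {
        cons.push_back('N');
      } else if (symbols[best] != '-') {
        cons.push_back(symbols[best]);
      } // winning gap: deletion, emit nothing
    }
    out[g] = cons;
    row += sz;
  }
  if (row != seqs.size()) stop("group sizes do not sum to the number of rows");
  return out;
}

// position-wise duplex merge of two equal-length consensi: agreement keeps
// the base, any disagreement or N yields N.
// [[Rcpp::export(name = ".dcs_combine_cpp")]]
CharacterVector dcs_combine_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("a and b must have the same length");
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* as = CHAR(a[i]);
    const char* bs = CHAR(b[i]);
    int L = LENGTH(a[i]);
    if (LENGTH(b[i]) != L) stop("consensi of pair %d differ in length", (int)(i + 1));
    std::string s(L, 'N');
    for (int k = 0; k < L; ++k) {
      if (as[k] == bs[k] && as[k] != 'N') s[k] = as[k];
    }
    out[i] = s;
  }
  return out;
}

// mismatches between observed and expected sequences over the overlap of
// the two; with skip_n, positions where the observed base is N are removed
// from both numerator and denominator.
// [[Rcpp::export(name = ".count_mismatches_cpp")]]
List count_mismatches_cpp(CharacterVector obs, CharacterVector expd, bool skip_n) {
  R_xlen_t n = obs.size();
  if (expd.size() != n) stop("obs and expd must have the same length");
  IntegerVector mism(n), bases(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char* o = CHAR(obs[i]);
    const char* e = CHAR(expd[i]);
    int L = std::min(LENGTH(obs[i]), LENGTH(expd[i]));
    int m = 0, b = 0;
    for (int k = 0; k < L; ++k) {
      if (skip_n && o[k] == 'N') continue;
      ++b;
      if (o[k] != e[k]) ++m;
    }
    mism[i] = m;
    bases[i] = b;
  }
  return List::create(_["mismatches"] = mism, _["bases"] = bases);
}

// ---- PCR genealogy + sequencing simulator --------------------------------

struct SimSink {
  std::vector<std::string> seq1, seq2, err1, err2;
  std::vector<int> fam;
};

// One strand family: amplify `mol` through a binary PCR genealogy for
// `cycles` cycles and sequence each of the `n_reads` reads. Replication at
// cycle c happens with probability (1/decay)^(c-1); reads split between the
// two daughters with a fair coin; each daughter molecule receives
// Binomial(len, error_rate) fresh substitutions inherited by its
// descendants. Sequencing adds independent per-mate substitutions at the
// same rate. Uses R's RNG throughout.
static void sim_one_family(const std::string& molecule, int n_reads, int cycles,
                           double decay, double pcr_error_rate,
                           double seq_error_rate, int read_len,
                           int fam_id, SimSink& sink) {
  int len = molecule.size();
  std::string mol = molecule;
  std::vector<int> errpos;

  std::function<void(int, int)> rec = [&](int r, int cycle) {
    if (r == 0) return;
    if (cycle > cycles) {
      // sequence r reads off this leaf molecule
      std::string m1_t(mol.substr(0, read_len));
      std::string m2_t(read_len, 'N');
      for (int k = 0; k < read_len; ++k) m2_t[k] = comp_base(mol[len - 1 - k]);
      // PCR errors visible inside each mate window, read coordinates
      std::string p1, p2;
      for (size_t e = 0; e < errpos.size(); ++e) {
        int p = errpos[e];
        if (p < read_len) {
          if (!p1.empty()) p1 += ",";
          p1 += std::to_string(p) + ":pcr";
        }
        if (p >= len - read_len) {
          if (!p2.empty()) p2 += ",";
          p2 += std::to_string(len - 1 - p) + ":pcr";
        }
      }
      for (int i = 0; i < r; ++i) {
        std::string m1 = m1_t, m2 = m2_t, e1 = p1, e2 = p2;
        int k1 = (int)R::rbinom(read_len, seq_error_rate);
        for (int k = 0; k < k1; ++k) {
          int p = (int)(unif_rand() * read_len) % read_len;
          m1[p] = mutate_base(m1[p]);
          if (!e1.empty()) e1 += ",";
          e1 += std::to_string(p) + ":seq";
        }
        int k2 = (int)R::rbinom(read_len, seq_error_rate);
        for (int k = 0; k < k2; ++k) {
          int p = (int)(unif_rand() * read_len) % read_len;
          m2[p] = mutate_base(m2[p]);
          if (!e2.empty()) e2 += ",";
          e2 += std::to_string(p) + ":seq";
        }
        sink.seq1.push_back(m1);
        sink.seq2.push_back(m2);
        sink.err1.push_back(e1);
        sink.err2.push_back(e2);
        sink.fam.push_back(fam_id);
      }
      return;
    }
    double p_rep = std::pow(1.0 / decay, cycle - 1);
    if (unif_rand() < p_rep) {
      int r1 = (int)R::rbinom(r, 0.5);
      int r0 = r - r1;
      for (int d = 0; d < 2; ++d) {
        int rd = (d == 0) ? r0 : r1;
        if (rd == 0) continue;
        int k = (int)R::rbinom(len, pcr_error_rate);
        std::vector<std::pair<int, char>> undo;
        undo.reserve(k);
        for (int e = 0; e < k; ++e) {
          int p = (int)(unif_rand() * len) % len;
          undo.push_back(std::make_pair(p, mol[p]));
          mol[p] = mutate_base(mol[p]);
          errpos.push_back(p);
        }
        rec(rd, cycle + 1);
        for (int e = k - 1; e >= 0; --e) {
          mol[undo[e].first] = undo[e].second;
          errpos.pop_back();
        }
      }
    } else {
      rec(r, cycle + 1);
    }
  };
  rec(n_reads, 1);
}

// [[Rcpp::export(name = ".sim_reads_cpp")]]
List sim_reads_cpp(CharacterVector molecules, IntegerVector sizes, int cycles,
                   double decay, double pcr_error_rate, double seq_error_rate,
                   int read_len) {
  int nf = molecules.size();
  if (sizes.size() != nf) stop("molecules and sizes must be parallel");
  SimSink sink;
  R_xlen_t total = 0;
  for (int i = 0; i < nf; ++i) total += sizes[i];
  sink.seq1.reserve(total);
  sink.seq2.reserve(total);
  sink.err1.reserve(total);
  sink.err2.reserve(total);
  sink.fam.reserve(total);
  for (int i = 0; i < nf; ++i) {
    std::string mol = as<std::string>(molecules[i]);
    if ((int)mol.size() < read_len)
      stop("molecule %d is shorter than the read length", i + 1);
    sim_one_family(mol, sizes[i], cycles, decay, pcr_error_rate, seq_error_rate,
                   read_len, i + 1, sink);
  }
  return List::create(
    _["family"] = wrap(sink.fam),
    _["seq1"] = wrap(sink.seq1),
    _["seq2"] = wrap(sink.seq2),
    _["errors1"] = wrap(sink.err1),
    _["errors2"] = wrap(sink.err2));
}
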