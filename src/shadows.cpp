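#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <unordered_set>
using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// insert base b before 1-based position p, truncate back to the read length
static inline std::string ins_apply(const std::string &t, int p, char b) {
  std::string res;
  res.reserve(t.size());
  res.append(t, 0, p - 1);
  res.push_back(b);
  res.append(t, p - 1, t.size() - p); // drop the displaced terminal base
  return res;
}

// delete 1-based position p, append base b at the 3' end
static inline std::string del_apply(const std::string &t, int p, char b) {
  std::string res;
  res.reserve(t.size());
  res.append(t, 0, p - 1);
  res.append(t, p, t.size() - p);
  res.push_back(b);
  return res;
}

// Distance-1 indel neighbors in deterministic enumeration order (p ascending,
// base order A,C,G,T), deduplicated, self excluded. Attribution = first p seen
// (the minimal edit position).
static void indel_dist1(const std::string &t, bool insertion,
                        std::vector<std::pair<std::string, int> > &out,
                        std::unordered_set<std::string> &seen) {
  int L = (int)t.size();
  for (int p = 1; p <= L; ++p) {
    for (int k = 0; k < 4; ++k) {
      std::string v = insertion ? ins_apply(t, p, BASES[k]) : del_apply(t, p, BASES[k]);
      if (v == t) continue;
      if (seen.insert(v).second) out.push_back(std::make_pair(v, p));
    }
  }
}

// Distance-2 indel neighbors: second application of the generative rule to each
// distance-1 neighbor; strings already reachable at distance 1 keep their
// distance-1 attribution and are not re-added.
static void indel_dist2(const std::string &t, bool insertion,
                        const std::vector<std::pair<std::string, int> > &d1,
                        const std::unordered_set<std::string> &seen1,
                        std::vector<std::pair<std::pair<std::string, int>, int> > &out,
                        std::unordered_set<std::string> &seen2) {
  int L = (int)t.size();
  for (size_t u = 0; u < d1.size(); ++u) {
    const std::string &base = d1[u].first;
    int p1 = d1[u].second;
    for (int p = 1; p <= L; ++p) {
      for (int k = 0; k < 4; ++k) {
        std::string v = insertion ? ins_apply(base, p, BASES[k]) : del_apply(base, p, BASES[k]);
        if (v == t) continue;
        if (seen1.count(v)) continue;
        if (seen2.insert(v).second)
          out.push_back(std::make_pair(std::make_pair(v, p1), p));
      }
    }
  }
}

// [[Rcpp::export]]
CharacterVector cpp_neighbors(std::string seq, std::string error_type, int max_dist) {
  int L = (int)seq.size();
  std::vector<std::string> res;
  if (error_type == "substitution") {
    for (int i = 0; i < L; ++i) {
      char orig = seq[i];
      for (int k = 0; k < 4; ++k) {
        if (BASES[k] == orig) continue;
        seq[i] = BASES[k];
        res.push_back(seq);
      }
      seq[i] = orig;
    }
    if (max_dist >= 2) {
      for (int i = 0; i < L; ++i) {
        char oi = seq[i];
        for (int j = i + 1; j < L; ++j) {
          char oj = seq[j];
          for (int ki = 0; ki < 4; ++ki) {
            if (BASES[ki] == oi) continue;
            for (int kj = 0; kj < 4; ++kj) {
              if (BASES[kj] == oj) continue;
              seq[i] = BASES[ki];
              seq[j] = BASES[kj];
              res.push_back(seq);
            }
          }
          seq[i] = oi;
          seq[j] = oj;
        }
      }
    }
  } else {
    bool insertion = (error_type == "insertion");
    std::vector<std::pair<std::string, int> > d1;
    std::unordered_set<std::string> seen1;
    indel_dist1(seq, insertion, d1, seen1);
    for (size_t u = 0; u < d1.size(); ++u) res.push_back(d1[u].first);
    if (max_dist >= 2) {
      std::vector<std::pair<std::pair<std::string, int>, int> > d2;
      std::unordered_set<std::string> seen2;
      indel_dist2(seq, insertion, d1, seen1, d2, seen2);
      for (size_t u = 0; u < d2.size(); ++u) res.push_back(d2[u].first.first);
    }
  }
  return wrap(res);
}

// Shadow totals and position-stratified shadow counts for a set of target
// reads against a hashed read-count table. A distance-2 substitution shadow
// credits both differing positions; indel shadows credit their edit
// position(s), using the minimal-edit attribution when a string is reachable
// in more than one way.
// [[Rcpp::export]]
List cpp_shadow_profiles(CharacterVector targets, CharacterVector seqs,
                         NumericVector counts, CharacterVector excluded,
                         std::string error_type, int max_dist) {
  std::unordered_map<std::string, double> cnt;
  cnt.reserve(seqs.size() * 2);
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    cnt[as<std::string>(seqs[i])] += counts[i];
  std::unordered_set<std::string> excl;
  for (R_xlen_t i = 0; i < excluded.size(); ++i)
    excl.insert(as<std::string>(excluded[i]));

  int nt = (int)targets.size();
  int L = nt > 0 ? (int)std::string(targets[0]).size() : 0;
  NumericVector total(nt);
  NumericMatrix bypos(nt, L);

  for (int ti = 0; ti < nt; ++ti) {
    std::string t = as<std::string>(targets[ti]);
    double tot = 0.0;

    if (error_type == "substitution") {
      for (int i = 0; i < L; ++i) {
        char orig = t[i];
        for (int k = 0; k < 4; ++k) {
          if (BASES[k] == orig) continue;
          t[i] = BASES[k];
          std::unordered_map<std::string, double>::const_iterator it = cnt.find(t);
          if (it != cnt.end() && !excl.count(t)) {
            tot += it->second;
            bypos(ti, i) += it->second;
          }
        }
        t[i] = orig;
      }
      if (max_dist >= 2) {
        for (int i = 0; i < L; ++i) {
          char oi = t[i];
          for (int j = i + 1; j < L; ++j) {
            char oj = t[j];
            for (int ki = 0; ki < 4; ++ki) {
              if (BASES[ki] == oi) continue;
              t[i] = BASES[ki];
              for (int kj = 0; kj < 4; ++kj) {
                if (BASES[kj] == oj) continue;
                t[j] = BASES[kj];
                std::unordered_map<std::string, double>::const_iterator it = cnt.find(t);
                if (it != cnt.end() && !excl.count(t)) {
                  tot += it->second;
                  bypos(ti, i) += it->second;
                  bypos(ti, j) += it->second;
                }
              }
              t[j] = oj;
            }
            t[i] = oi;
          }
        }
      }
    } else {
      bool insertion = (error_type == "insertion");
      std::vector<std::pair<std::string, int> > d1;
      std::unordered_set<std::string> seen1;
      indel_dist1(t, insertion, d1, seen1);
      for (size_t u = 0; u < d1.size(); ++u) {
        std::unordered_map<std::string, double>::const_iterator it = cnt.find(d1[u].first);
        if (it != cnt.end() && !excl.count(d1[u].first)) {
          tot += it->second;
          bypos(ti, d1[u].second - 1) += it->second;
        }
      }
      if (max_dist >= 2) {
        std::vector<std::pair<std::pair<std::string, int>, int> > d2;
        std::unordered_set<std::string> seen2;
        indel_dist2(t, insertion, d1, seen1, d2, seen2);
        for (size_t u = 0; u < d2.size(); ++u) {
          const std::string &v = d2[u].first.first;
          std::unordered_map<std::string, double>::const_iterator it = cnt.find(v);
          if (it != cnt.end() && !excl.count(v)) {
            tot += it->second;
            bypos(ti, d2[u].first.second - 1) += it->second;
            bypos(ti, d2[u].second - 1) += it->second;
          }
        }
      }
    }
    total[ti] = tot;
  }
  return List::create(_["total"] = total, _["by_position"] = bypos);
}

// Per-copy substitution error injection under the independent or dependent
// (rate-doubling after the first error) model. Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
List cpp_inject_errors(CharacterVector reads, NumericVector rates, bool dependent) {
  R_xlen_t n = reads.size();
  int L = (int)rates.size();
  CharacterVector out(n);
  IntegerVector nerr(n);
  std::string buf;
  for (R_xlen_t r = 0; r < n; ++r) {
    buf = as<std::string>(reads[r]);
    int ne = 0;
    for (int i = 0; i < L; ++i) {
      double rate = rates[i];
      if (dependent && ne > 0) rate *= 2.0;
      if (unif_rand() < rate) {
        char orig = buf[i];
        int k = (int)(unif_rand() * 3.0);
        if (k > 2) k = 2;
        // pick among the 3 bases != orig
        int seenk = 0;
        for (int b = 0; b < 4; ++b) {
          if (BASES[b] == orig) continue;
          if (seenk == k) { buf[i] = BASES[b]; break; }
          ++seenk;
        }
        ++ne;
      }
    }
    nerr[r] = ne;
    out[r] = buf;
  }
  return List::create(_["reads"] = out, _["n_errors"] = nerr);
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// Hamming distance with early exit
static inline int ham_le(const char *a, const char *b, int L, int cap) {
  int d = 0;
  for (int i = 0; i < L; ++i) {
    if (a[i] != b[i]) {
      if (++d > cap) return d;
    }
  }
  return d;
}

struct SeedIndex {
  std::unordered_map<std::string, std::vector<int> > mapA, mapB;
  int lenA, lenB;
};

// Exhaustive-equivalent classification of reads against a reference by minimal
// Hamming distance over all offsets (optionally both strands, optionally
// circular). Alignments with <= max_mm mismatches are found exactly via a
// 3-piece pigeonhole seed index; any read whose best alignment exceeds max_mm
// is unmatched. Ties at the best distance (including cross-strand ties) make a
// read non-unique and drop it from the tally.
// [[Rcpp::export]]
List cpp_classify_reads(CharacterVector seqs, NumericVector counts,
                        std::string ref, int read_len, bool both_strands,
                        bool circular, int max_mm) {
  int n = (int)ref.size();
  int L = read_len;
  std::string ext = ref;
  if (circular) ext += ref.substr(0, (size_t)std::min(n, L - 1));
  int maxoff = circular ? (n - 1) : (n - L);

  SeedIndex idx;
  idx.lenA = L / 3;
  idx.lenB = L - 2 * idx.lenA;
  int extn = (int)ext.size();
  for (int p = 0; p + idx.lenA <= extn; ++p)
    idx.mapA[ext.substr(p, idx.lenA)].push_back(p);
  for (int p = 0; p + idx.lenB <= extn; ++p)
    idx.mapB[ext.substr(p, idx.lenB)].push_back(p);

  double u0 = 0, u1 = 0, u2 = 0, unmatched = 0, nonunique = 0;
  NumericVector perpos(L);

  std::vector<std::string> strands;
  for (R_xlen_t ri = 0; ri < seqs.size(); ++ri) {
    std::string fwd = as<std::string>(seqs[ri]);
    double w = counts[ri];
    strands.clear();
    strands.push_back(fwd);
    if (both_strands) strands.push_back(revcomp(fwd));

    int best = max_mm + 1;
    int nbest = 0;
    int best_off = -1, best_strand = 0;
    for (size_t si = 0; si < strands.size(); ++si) {
      const std::string &rd = strands[si];
      std::vector<int> cand;
      std::unordered_map<std::string, std::vector<int> >::const_iterator it;
      it = idx.mapA.find(rd.substr(0, idx.lenA));
      if (it != idx.mapA.end())
        for (size_t q = 0; q < it->second.size(); ++q) cand.push_back(it->second[q]);
      it = idx.mapA.find(rd.substr(idx.lenA, idx.lenA));
      if (it != idx.mapA.end())
        for (size_t q = 0; q < it->second.size(); ++q) cand.push_back(it->second[q] - idx.lenA);
      it = idx.mapB.find(rd.substr(2 * idx.lenA));
      if (it != idx.mapB.end())
        for (size_t q = 0; q < it->second.size(); ++q) cand.push_back(it->second[q] - 2 * idx.lenA);
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (size_t q = 0; q < cand.size(); ++q) {
        int off = cand[q];
        if (off < 0 || off > maxoff) continue;
        if (off + L > extn) continue;
        int d = ham_le(rd.c_str(), ext.c_str() + off, L, max_mm);
        if (d > max_mm) continue;
        if (d < best) {
          best = d;
          nbest = 1;
          best_off = off;
          best_strand = (int)si;
        } else if (d == best) {
          ++nbest;
        }
      }
    }

    if (best > max_mm) {
      unmatched += w;
    } else if (nbest > 1) {
      nonunique += w;
    } else {
      if (best == 0) u0 += w;
      else if (best == 1) u1 += w;
      else u2 += w;
      if (best > 0) {
        const std::string &rd = strands[best_strand];
        for (int i = 0; i < L; ++i) {
          if (rd[i] != ext[best_off + i]) {
            int read_pos = best_strand == 0 ? i : (L - 1 - i);
            perpos[read_pos] += w;
          }
        }
      }
    }
  }
  return List::create(_["u0"] = u0, _["u1"] = u1, _["u2"] = u2,
                      _["unmatched"] = unmatched, _["nonunique"] = nonunique,
                      _["per_position"] = perpos);
}
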