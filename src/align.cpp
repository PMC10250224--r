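#include <Rcpp.h>
#include <climits>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
using namespace Rcpp;

// Seed-and-verify scanners for the BSJ junction library and for contiguous
// linear alignment. Seeds are exact anchor/k-mer lookups; candidates are
// verified by full mismatch counting. Detection is exhaustive as long as at
// least one seed window is mismatch-free (guaranteed for <= (n_windows - 1)
// total mismatches per read under the pigeonhole principle).

typedef std::unordered_map<std::string, std::vector<int> > SeedMap;

static inline void add_seed(SeedMap &m, const std::string &key, int idx) {
  m[key].push_back(idx);
}

// [[Rcpp::export]]
DataFrame bsj_scan_cpp(CharacterVector reads, CharacterVector probes,
                       IntegerVector jpos, int min_anchor, int max_mm) {
  int np = probes.size(), nr = reads.size();
  std::vector<std::string> P(np);
  for (int i = 0; i < np; ++i) P[i] = as<std::string>(probes[i]);

  // left seed: the min_anchor bases ending at the junction;
  // right seed: the min_anchor bases starting at the junction.
  SeedMap leftMap, rightMap;
  for (int i = 0; i < np; ++i) {
    int j = jpos[i];
    if (j >= min_anchor)
      add_seed(leftMap, P[i].substr(j - min_anchor, min_anchor), i);
    if ((int)P[i].size() - j >= min_anchor)
      add_seed(rightMap, P[i].substr(j, min_anchor), i);
  }

  std::vector<int> out_read, out_probe, out_off, out_mm, out_nbest;

  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    int rl = rd.size();
    if (rl < 2 * min_anchor) continue;

    // candidate (probe, junction offset in read) -> mismatches
    std::vector<int> cand_p, cand_o, cand_mm;
    std::unordered_set<long long> seen;

    for (int o = min_anchor; o <= rl - min_anchor; ++o) {
      for (int side = 0; side < 2; ++side) {
        if (side == 1 && max_mm == 0) break;  // exact scan: left seed suffices
        const SeedMap &m = side == 0 ? leftMap : rightMap;
        std::string key = side == 0 ? rd.substr(o - min_anchor, min_anchor)
                                    : rd.substr(o, min_anchor);
        SeedMap::const_iterator it = m.find(key);
        if (it == m.end()) continue;
        for (size_t ci = 0; ci < it->second.size(); ++ci) {
          int p = it->second[ci];
          long long id = (long long)p * 1000 + o;
          if (!seen.insert(id).second) continue;
          int s = jpos[p] - o;  // read position 0 maps to probe position s
          if (s < 0 || s + rl > (int)P[p].size()) continue;
          const std::string &ps = P[p];
          int mm = 0;
          for (int b = 0; b < rl; ++b) {
            if (ps[s + b] != rd[b] && ++mm > max_mm) break;
          }
          if (mm <= max_mm) {
            cand_p.push_back(p); cand_o.push_back(o); cand_mm.push_back(mm);
          }
        }
      }
    }
    if (cand_p.empty()) continue;
    int best = cand_mm[0], bi = 0;
    for (size_t i = 1; i < cand_mm.size(); ++i)
      if (cand_mm[i] < best) { best = cand_mm[i]; bi = i; }
    // distinct probes achieving the best mismatch count
    std::unordered_set<int> best_probes;
    for (size_t i = 0; i < cand_mm.size(); ++i)
      if (cand_mm[i] == best) best_probes.insert(cand_p[i]);
    out_read.push_back(r + 1);
    out_probe.push_back(cand_p[bi] + 1);
    out_off.push_back(cand_o[bi]);
    out_mm.push_back(best);
    out_nbest.push_back((int)best_probes.size());
  }
  return DataFrame::create(_["read"] = out_read, _["probe"] = out_probe,
                           _["offset"] = out_off, _["mm"] = out_mm,
                           _["n_best"] = out_nbest);
}

// exempt: 0 = none, 1 = ref T read C, 2 = ref A read G
static inline bool is_exempt(char ref, char obs, int exempt) {
  if (exempt == 1) return ref == 'T' && obs == 'C';
  if (exempt == 2) return ref == 'A' && obs == 'G';
  return false;
}

// [[Rcpp::export]]
List linear_align_cpp(CharacterVector reads, CharacterVector refs,
                      int max_mm, int exempt, int seed_k = 20) {
  int nr = reads.size(), nf = refs.size();
  std::vector<std::string> R(nf);
  for (int i = 0; i < nf; ++i) R[i] = as<std::string>(refs[i]);

  std::unordered_map<std::string, std::vector<long long> > idx;
  for (int f = 0; f < nf; ++f) {
    int n = (int)R[f].size() - seed_k;
    for (int p = 0; p <= n; ++p)
      idx[R[f].substr(p, seed_k)].push_back(((long long)f << 32) | (unsigned)p);
  }

  std::vector<int> out_read, out_ref, out_pos, out_mm, out_conv, out_nbest;
  List out_convpos(nr);  // per input read; NULL when unaligned
  std::vector<bool> aligned(nr, false);

  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    int rl = rd.size();
    if (rl < seed_k) continue;
    std::unordered_set<long long> cands;
    for (int q = 0; q + seed_k <= rl; q += seed_k) {
      std::unordered_map<std::string, std::vector<long long> >::const_iterator it =
        idx.find(rd.substr(q, seed_k));
      if (it == idx.end()) continue;
      for (size_t i = 0; i < it->second.size(); ++i) {
        long long packed = it->second[i];
        int f = (int)(packed >> 32);
        long long pos = (packed & 0xffffffffLL) - q;
        if (pos < 0 || pos + rl > (long long)R[f].size()) continue;
        cands.insert(((long long)f << 32) | (unsigned)(int)pos);
      }
    }
    if (cands.empty()) continue;
    int best_mm = max_mm + 1, best_tot = INT_MAX, best_f = -1, best_p = -1, nbest = 0;
    std::vector<int> best_conv;
    for (std::unordered_set<long long>::const_iterator it = cands.begin();
         it != cands.end(); ++it) {
      int f = (int)(*it >> 32), p = (int)(*it & 0xffffffffLL);
      const std::string &rf = R[f];
      int mm = 0, conv = 0;
      std::vector<int> convpos;
      bool ok = true;
      for (int b = 0; b < rl; ++b) {
        char rc = rf[p + b], oc = rd[b];
        if (rc == oc) continue;
        if (is_exempt(rc, oc, exempt)) { ++conv; convpos.push_back(p + b); }
        else if (++mm > max_mm) { ok = false; break; }
      }
      if (!ok) continue;
      int tot = mm + conv;
      if (mm < best_mm || (mm == best_mm && tot < best_tot)) {
        best_mm = mm; best_tot = tot; best_f = f; best_p = p;
        best_conv = convpos; nbest = 1;
      } else if (mm == best_mm && tot == best_tot) {
        ++nbest;
      }
    }
    if (best_f < 0) continue;
    aligned[r] = true;
    out_read.push_back(r + 1);
    out_ref.push_back(best_f + 1);
    out_pos.push_back(best_p);
    out_mm.push_back(best_mm);
    out_conv.push_back((int)best_conv.size());
    out_nbest.push_back(nbest);
    out_convpos[r] = IntegerVector(best_conv.begin(), best_conv.end());
  }
  return List::create(
    _["hits"] = DataFrame::create(_["read"] = out_read, _["ref"] = out_ref,
                                  _["pos"] = out_pos, _["mm"] = out_mm,
                                  _["n_conv"] = out_conv, _["n_best"] = out_nbest),
    _["conversions"] = out_convpos);
}
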