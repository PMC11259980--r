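#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// 2-bit nucleotide code; -1 for anything that is not A/C/G/T
static inline int nt_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct SeedEntry {
  uint64_t h;
  int32_t chrom; // 1-based index into the sequence list
  int32_t pos;   // 0-based start
};

static bool entry_less(const SeedEntry& a, const SeedEntry& b) {
  if (a.h != b.h) return a.h < b.h;
  if (a.chrom != b.chrom) return a.chrom < b.chrom;
  return a.pos < b.pos;
}

// Collect rolling-hash entries for every valid k-mer start in seq.
// allowed may be empty (all starts allowed) or one bool per position.
static void collect_entries(const std::string& seq, int k, int chrom,
                            const std::vector<char>& allowed,
                            std::vector<SeedEntry>& out) {
  const int n = (int)seq.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0;
  int valid = 0; // number of consecutive valid bases ending at i
  for (int i = 0; i < n; ++i) {
    int c = nt_code(seq[i]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    ++valid;
    if (valid >= k) {
      int start = i - k + 1;
      if (allowed.empty() || allowed[start])
        out.push_back({h, chrom, start});
    }
  }
}

static std::vector<char> allowed_from_mask(int n, SEXP starts_, SEXP ends_) {
  std::vector<char> allowed;
  IntegerVector starts(starts_), ends(ends_);
  if (starts.size() == 0) return allowed; // empty => everything allowed
  allowed.assign(n, 1);
  for (int j = 0; j < starts.size(); ++j) {
    int s = std::max(0, starts[j]);
    int e = std::min(n, ends[j]);
    for (int p = s; p < e; ++p) allowed[p] = 0;
  }
  return allowed;
}

// Pairs of identical k-mers across (and within) sequences of one assembly.
// mask_starts/mask_ends: per-chromosome 0-based half-open intervals where
// seeds must not *start* (soft-mask convention). k-mers occurring more than
// max_occ times are skipped as repetitive.
// [[Rcpp::export]]
DataFrame cpp_self_seed_pairs(CharacterVector seqs, int k, int max_occ,
                              List mask_starts, List mask_ends) {
  std::vector<SeedEntry> entries;
  for (int c = 0; c < seqs.size(); ++c) {
    std::string s = as<std::string>(seqs[c]);
    std::vector<char> allowed =
      allowed_from_mask((int)s.size(), mask_starts[c], mask_ends[c]);
    collect_entries(s, k, c + 1, allowed, entries);
  }
  std::sort(entries.begin(), entries.end(), entry_less);

  std::vector<int> c1, p1, c2, p2;
  size_t i = 0, n = entries.size();
  while (i < n) {
    size_t j = i + 1;
    while (j < n && entries[j].h == entries[i].h) ++j;
    size_t g = j - i;
    if (g >= 2 && (int)g <= max_occ) {
      for (size_t a = i; a < j; ++a)
        for (size_t b = a + 1; b < j; ++b) {
          c1.push_back(entries[a].chrom); p1.push_back(entries[a].pos);
          c2.push_back(entries[b].chrom); p2.push_back(entries[b].pos);
        }
    }
    i = j;
  }
  return DataFrame::create(_["chrom1"] = c1, _["pos1"] = p1,
                           _["chrom2"] = c2, _["pos2"] = p2);
}

// Exact k-mer hits of each query against an assembly. Genome k-mers occurring
// more than max_occ times are skipped (over-represented seed filter).
// [[Rcpp::export]]
DataFrame cpp_query_seed_hits(CharacterVector queries, CharacterVector seqs,
                              int k, int max_occ) {
  std::vector<SeedEntry> index;
  std::vector<char> no_mask;
  for (int c = 0; c < seqs.size(); ++c) {
    std::string s = as<std::string>(seqs[c]);
    collect_entries(s, k, c + 1, no_mask, index);
  }
  std::sort(index.begin(), index.end(), entry_less);

  std::vector<int> qid, qpos, chrom, tpos;
  for (int q = 0; q < queries.size(); ++q) {
    std::string qs = as<std::string>(queries[q]);
    std::vector<SeedEntry> qents;
    collect_entries(qs, k, 1, no_mask, qents);
    for (const SeedEntry& e : qents) {
      SeedEntry key{e.h, 0, 0};
      auto lo = std::lower_bound(index.begin(), index.end(), key, entry_less);
      auto hi = lo;
      while (hi != index.end() && hi->h == e.h) ++hi;
      if (hi - lo == 0 || (int)(hi - lo) > max_occ) continue;
      for (auto it = lo; it != hi; ++it) {
        qid.push_back(q + 1); qpos.push_back(e.pos);
        chrom.push_back(it->chrom); tpos.push_back(it->pos);
      }
    }
  }
  return DataFrame::create(_["query"] = qid, _["qpos"] = qpos,
                           _["chrom"] = chrom, _["tpos"] = tpos);
}

// Smith-Waterman local alignment with affine gaps (gap of length g costs
// open + g * ext) and a heavy penalty for columns involving non-ACGT bases.
// Ties on score are broken by smallest a_start, then b_start, then a_end,
// then b_end; traceback prefers diagonal, then gap-in-b (consume a), then
// gap-in-a. Coordinates returned are 1-based inclusive; score 0 => empty.
// [[Rcpp::export]]
List cpp_sw_affine(std::string a, std::string b, double match, double mismatch,
                   double gap_open, double gap_ext, double n_pen) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e18;
  std::vector<double> H((n + 1) * (m + 1), 0.0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    int ca = nt_code(a[i - 1]);
    for (int j = 1; j <= m; ++j) {
      int cb = nt_code(b[j - 1]);
      double s = (ca < 0 || cb < 0) ? n_pen : (ca == cb ? match : mismatch);
      double e = std::max(H[idx(i, j - 1)] - (gap_open + gap_ext),
                          E[idx(i, j - 1)] - gap_ext);
      double f = std::max(H[idx(i - 1, j)] - (gap_open + gap_ext),
                          F[idx(i - 1, j)] - gap_ext);
      double h = H[idx(i - 1, j - 1)] + s;
      double v = std::max(0.0, std::max(h, std::max(e, f)));
      E[idx(i, j)] = e; F[idx(i, j)] = f; H[idx(i, j)] = v;
      if (v > best) best = v;
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0, _["columns"] = 0,
                        _["gapped"] = false);

  int best_as = n + 2, best_bs = m + 2, best_ae = 0, best_be = 0;
  int best_cols = 0; bool best_gapped = false;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (H[idx(i, j)] != best) continue;
      // traceback from (i, j)
      int ti = i, tj = j, cols = 0;
      bool gapped = false;
      int as = i, bs = j;
      char state = 'H';
      while (true) {
        if (state == 'H') {
          double v = H[idx(ti, tj)];
          if (v == 0.0) break;
          int ca = nt_code(a[ti - 1]), cb = nt_code(b[tj - 1]);
          double s = (ca < 0 || cb < 0) ? n_pen : (ca == cb ? match : mismatch);
          if (ti >= 1 && tj >= 1 && v == H[idx(ti - 1, tj - 1)] + s) {
            as = ti; bs = tj; --ti; --tj; ++cols;
          } else if (v == F[idx(ti, tj)]) {
            state = 'F';
          } else {
            state = 'E';
          }
        } else if (state == 'F') { // gap in b, consume a
          gapped = true; ++cols;
          double v = F[idx(ti, tj)];
          as = ti;
          if (v == H[idx(ti - 1, tj)] - (gap_open + gap_ext)) {
            --ti; state = 'H';
          } else {
            --ti; state = 'F';
          }
        } else { // E: gap in a, consume b
          gapped = true; ++cols;
          double v = E[idx(ti, tj)];
          bs = tj;
          if (v == H[idx(ti, tj - 1)] - (gap_open + gap_ext)) {
            --tj; state = 'H';
          } else {
            --tj; state = 'E';
          }
        }
      }
      if (as < best_as || (as == best_as && (bs < best_bs ||
          (bs == best_bs && (i < best_ae || (i == best_ae && j < best_be)))))) {
        best_as = as; best_bs = bs; best_ae = i; best_be = j;
        best_cols = cols; best_gapped = gapped;
      }
    }
  }
  return List::create(_["score"] = best, _["a_start"] = best_as,
                      _["a_end"] = best_ae, _["b_start"] = best_bs,
                      _["b_end"] = best_be, _["columns"] = best_cols,
                      _["gapped"] = best_gapped);
}

// Positionwise matches/mismatches of two equal-length strings; columns with
// non-ACGT bases are counted separately (excluded from identity).
// [[Rcpp::export]]
List cpp_base_compare(std::string a, std::string b) {
  int n = (int)std::min(a.size(), b.size());
  int match = 0, mismatch = 0, ambig = 0;
  for (int i = 0; i < n; ++i) {
    int ca = nt_code(a[i]), cb = nt_code(b[i]);
    if (ca < 0 || cb < 0) { ++ambig; continue; }
    if (ca == cb) ++match; else ++mismatch;
  }
  return List::create(_["matches"] = match, _["mismatches"] = mismatch,
                      _["ambiguous"] = ambig);
}
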