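#include <Rcpp.h>
#include <cstdint>
#include <cstdlib>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// 2-bit encoding; 4 = invalid (N etc.)
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

struct Seed { int q; long long g; };

struct Chain {
  int qs, qe;            // query interval [qs, qe)
  long long gs, ge;      // global reference interval [gs, ge)
  int nseeds;
  int cov;               // seed-supported query bases (extension excluded,
                         // so detection is orientation-symmetric)
  int ext;               // extension bases (score only)
  long long dend;        // diagonal at the chain's query end
};

// Seed-and-chain read mapper over a small reference: exact k-mer seeds with
// repeat filtering, same-diagonal micro-chains, indel-tolerant chain merging
// through a diagonal-bucket index, and x-drop ungapped extension of segment
// boundaries. Reports all candidate segments per read. The min_seeds /
// min_aligned filters act on seed-derived coverage only, so whether a short
// segment is reported does not depend on read orientation.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector read_ids, CharacterVector read_seqs,
                        CharacterVector ref_names, CharacterVector ref_seqs,
                        int k, int max_hits, int max_gap, int diag_tol,
                        int min_seeds, int min_aligned, int xdrop,
                        int match_score) {
  const int nref = ref_names.size();
  std::vector<long long> offset(nref + 1);
  const int SEP = k + 4;
  long long total = 0;
  for (int i = 0; i < nref; ++i) {
    offset[i] = total;
    total += LENGTH(STRING_ELT(ref_seqs, i)) + SEP;
  }
  offset[nref] = total;
  std::vector<int8_t> R(total, 4);
  for (int i = 0; i < nref; ++i) {
    const char *s = CHAR(STRING_ELT(ref_seqs, i));
    int L = LENGTH(STRING_ELT(ref_seqs, i));
    for (int j = 0; j < L; ++j) R[offset[i] + j] = (int8_t)enc(s[j]);
  }

  // CSR index over 4^k buckets of forward reference k-mer positions
  const uint32_t NB = 1u << (2 * k);
  const uint32_t mask = NB - 1;
  std::vector<uint32_t> cnt(NB + 1, 0);
  {
    uint32_t key = 0; int run = 0;
    for (long long p = 0; p < total; ++p) {
      int8_t b = R[p];
      if (b > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)b) & mask;
      if (++run >= k) cnt[key + 1]++;
    }
  }
  for (uint32_t i = 0; i < NB; ++i) cnt[i + 1] += cnt[i];
  std::vector<uint32_t> pos(cnt[NB]);
  {
    std::vector<uint32_t> fill(cnt.begin(), cnt.end() - 1);
    uint32_t key = 0; int run = 0;
    for (long long p = 0; p < total; ++p) {
      int8_t b = R[p];
      if (b > 3) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint32_t)b) & mask;
      if (++run >= k) pos[fill[key]++] = (uint32_t)(p - k + 1);
    }
  }

  std::vector<std::string> out_id;
  std::vector<int> out_qs, out_qe, out_refidx, out_strand, out_aligned;
  std::vector<long long> out_gs, out_ge;

  const int nreads = read_ids.size();
  for (int r = 0; r < nreads; ++r) {
    const char *s = CHAR(STRING_ELT(read_seqs, r));
    int L = LENGTH(STRING_ELT(read_seqs, r));
    if (L < k) continue;
    std::vector<int8_t> Q(L);
    for (int j = 0; j < L; ++j) Q[j] = (int8_t)enc(s[j]);

    std::vector<Seed> fwd, rev;
    uint32_t key = 0, rkey = 0; int run = 0;
    const int shift = 2 * (k - 1);
    for (int j = 0; j < L; ++j) {
      int8_t b = Q[j];
      if (b > 3) { run = 0; key = 0; rkey = 0; continue; }
      key = ((key << 2) | (uint32_t)b) & mask;
      rkey = (rkey >> 2) | ((uint32_t)(3 - b) << shift);
      if (++run < k) continue;
      int q = j - k + 1;
      uint32_t nf = cnt[key + 1] - cnt[key];
      uint32_t nr = cnt[rkey + 1] - cnt[rkey];
      if (nf + nr > (uint32_t)max_hits) continue;
      for (uint32_t t = cnt[key]; t < cnt[key + 1]; ++t)
        fwd.push_back({q, (long long)pos[t]});
      for (uint32_t t = cnt[rkey]; t < cnt[rkey + 1]; ++t)
        rev.push_back({q, (long long)pos[t]});
    }

    for (int strand = 0; strand < 2; ++strand) {
      std::vector<Seed> &seeds = strand == 0 ? fwd : rev;
      if (seeds.empty()) continue;
      // diagonal: g - q (forward) or g + q (reverse) is locally constant
      std::sort(seeds.begin(), seeds.end(), [&](const Seed &a, const Seed &b) {
        long long da = strand == 0 ? a.g - a.q : a.g + a.q;
        long long db = strand == 0 ? b.g - b.q : b.g + b.q;
        if (da != db) return da < db;
        return a.q < b.q;
      });
      // micro-chains: same diagonal, bounded query gaps
      std::vector<Chain> micro;
      for (size_t i = 0; i < seeds.size(); ++i) {
        long long d = strand == 0 ? seeds[i].g - seeds[i].q
                                  : seeds[i].g + seeds[i].q;
        bool extend = false;
        if (!micro.empty()) {
          Chain &c = micro.back();
          if (d == c.dend && seeds[i].q >= c.qe - k &&
              seeds[i].q - (c.qe - k) <= max_gap) extend = true;
        }
        if (extend) {
          Chain &c = micro.back();
          c.qe = seeds[i].q + k;
          if (strand == 0) c.ge = seeds[i].g + k; else c.gs = seeds[i].g;
          c.nseeds++;
        } else {
          Chain c;
          c.qs = seeds[i].q; c.qe = seeds[i].q + k;
          c.gs = seeds[i].g; c.ge = seeds[i].g + k;
          c.nseeds = 1; c.cov = k; c.ext = 0; c.dend = d;
          micro.push_back(c);
        }
      }
      for (auto &c : micro)
        c.cov = std::min(c.qe - c.qs, c.nseeds + k - 1);

      // merge micro-chains across small indels via a diagonal-bucket index
      std::sort(micro.begin(), micro.end(), [](const Chain &a, const Chain &b) {
        if (a.qs != b.qs) return a.qs < b.qs;
        return a.gs < b.gs;
      });
      const long long B = diag_tol > 0 ? diag_tol : 1;
      std::vector<Chain> chains;
      std::unordered_map<long long, std::vector<int>> bucket;
      for (size_t i = 0; i < micro.size(); ++i) {
        const Chain &m = micro[i];
        long long dstart = strand == 0 ? m.gs - m.qs : m.qs + (m.ge - k);
        // merge when the diagonal agrees and the query gap is bounded above;
        // overlapping / contained micro-chains (indel echoes in locally
        // periodic sequence) are absorbed rather than spawning duplicates
        int best = -1; int best_gap = max_gap + 1;
        for (long long bb = dstart / B - 2; bb <= dstart / B + 2; ++bb) {
          auto it = bucket.find(bb);
          if (it == bucket.end()) continue;
          for (int ci : it->second) {
            Chain &c = chains[ci];
            long long ddiag = std::llabs(dstart - c.dend);
            if (ddiag > diag_tol) continue;
            // a large diagonal shift needs solid seed support: this rejects
            // chance shared words at junctions (which mimic microhomology
            // and would otherwise drag the boundary across the junction)
            // while still bridging genuine indels
            if (ddiag > 3 && m.nseeds < 3) continue;
            int qgap = m.qs - c.qe;
            if (qgap > max_gap) continue;
            int gap = qgap < 0 ? 0 : qgap;
            if (gap < best_gap) { best_gap = gap; best = ci; }
          }
        }
        if (best >= 0) {
          Chain &c = chains[best];
          int adv = std::min(m.cov, m.qe - std::max(m.qs, c.qe));
          c.cov += adv < 0 ? 0 : adv;
          c.qs = std::min(c.qs, m.qs);
          c.gs = std::min(c.gs, m.gs);
          c.ge = std::max(c.ge, m.ge);
          c.nseeds += m.nseeds;
          if (m.qe >= c.qe) {
            c.qe = m.qe;
            long long nd = m.dend;
            if (nd / B != c.dend / B) bucket[nd / B].push_back(best);
            c.dend = nd;
          }
        } else {
          Chain c = m;
          chains.push_back(c);
          bucket[c.dend / B].push_back((int)(chains.size() - 1));
        }
      }

      for (auto &c : chains) {
        if (c.nseeds < min_seeds || c.cov < min_aligned) continue;
        // x-drop ungapped extension through substitutions
        if (strand == 0) {
          int sc = 0, bestsc = 0, bq = c.qs; long long bg = c.gs;
          int q = c.qs; long long g = c.gs;
          while (q > 0 && g > 0 && R[g - 1] <= 3) {
            sc += (Q[q - 1] == R[g - 1]) ? 1 : -2;
            --q; --g;
            if (sc > bestsc) { bestsc = sc; bq = q; bg = g; }
            if (bestsc - sc > xdrop) break;
          }
          if (bestsc > 0) { c.ext += c.qs - bq; c.qs = bq; c.gs = bg; }
          sc = 0; bestsc = 0; int bq2 = c.qe; long long bg2 = c.ge;
          q = c.qe; g = c.ge;
          while (q < L && g < total && R[g] <= 3) {
            sc += (Q[q] == R[g]) ? 1 : -2;
            ++q; ++g;
            if (sc > bestsc) { bestsc = sc; bq2 = q; bg2 = g; }
            if (bestsc - sc > xdrop) break;
          }
          if (bestsc > 0) { c.ext += bq2 - c.qe; c.qe = bq2; c.ge = bg2; }
        } else {
          // read[qs..qe) == revcomp(ref[gs..ge))
          int sc = 0, bestsc = 0, bq = c.qs; long long bg = c.ge;
          int q = c.qs; long long g = c.ge;
          while (q > 0 && g < total && R[g] <= 3) {
            sc += (Q[q - 1] == 3 - R[g]) ? 1 : -2;
            --q; ++g;
            if (sc > bestsc) { bestsc = sc; bq = q; bg = g; }
            if (bestsc - sc > xdrop) break;
          }
          if (bestsc > 0) { c.ext += c.qs - bq; c.qs = bq; c.ge = bg; }
          sc = 0; bestsc = 0; int bq2 = c.qe; long long bg2 = c.gs;
          q = c.qe; g = c.gs;
          while (q < L && g > 0 && R[g - 1] <= 3) {
            sc += (Q[q] == 3 - R[g - 1]) ? 1 : -2;
            ++q; --g;
            if (sc > bestsc) { bestsc = sc; bq2 = q; bg2 = g; }
            if (bestsc - sc > xdrop) break;
          }
          if (bestsc > 0) { c.ext += bq2 - c.qe; c.qe = bq2; c.gs = bg2; }
        }
        // locate contig; separator k-mers are never indexed, so a chain
        // cannot genuinely span two contigs
        int lo = 0, hi = nref - 1, ci = 0;
        while (lo <= hi) {
          int mid = (lo + hi) / 2;
          if (c.gs >= offset[mid] && c.gs < offset[mid + 1]) { ci = mid; break; }
          if (c.gs < offset[mid]) hi = mid - 1; else lo = mid + 1;
        }
        long long cl = offset[ci];
        long long clen = offset[ci + 1] - SEP - cl;
        long long rs = c.gs - cl, re = c.ge - cl;
        if (re > clen) re = clen;
        out_id.push_back(std::string(CHAR(STRING_ELT(read_ids, r))));
        out_qs.push_back(c.qs);
        out_qe.push_back(c.qe);
        out_refidx.push_back(ci + 1);
        out_gs.push_back(rs);
        out_ge.push_back(re);
        out_strand.push_back(strand == 0 ? 1 : -1);
        out_aligned.push_back(std::min(c.cov + c.ext, c.qe - c.qs));
      }
    }
  }

  int n = (int)out_id.size();
  CharacterVector id(n), chrom(n), strand(n);
  IntegerVector qs(n), qe(n), rs(n), re(n), ab(n);
  NumericVector score(n);
  for (int i = 0; i < n; ++i) {
    id[i] = out_id[i];
    chrom[i] = ref_names[out_refidx[i] - 1];
    qs[i] = out_qs[i]; qe[i] = out_qe[i];
    rs[i] = (int)out_gs[i]; re[i] = (int)out_ge[i];
    strand[i] = out_strand[i] > 0 ? "+" : "-";
    ab[i] = out_aligned[i];
    score[i] = (double)match_score * out_aligned[i];
  }
  return DataFrame::create(
    Named("read_id") = id, Named("query_start") = qs, Named("query_end") = qe,
    Named("chrom") = chrom, Named("ref_start") = rs, Named("ref_end") = re,
    Named("strand") = strand, Named("score") = score,
    Named("aligned_bases") = ab, Named("stringsAsFactors") = false);
}

// Optimal spanning subset of candidate alignments by dynamic programming.
// Candidates must arrive sorted by (query_start, -score, chrom, ref_start):
// with strict improvement tests the earliest candidate wins ties, making
// the output deterministic. Objective: sum of scores minus
// overlap_penalty * (query bases shared by consecutive chosen segments);
// consecutive overlap is capped at half the shorter segment; gaps are free.
// [[Rcpp::export]]
IntegerVector cpp_choose_spanning(IntegerVector qs, IntegerVector qe,
                                  NumericVector score, double overlap_penalty) {
  int n = qs.size();
  std::vector<double> dp(n);
  std::vector<int> pre(n, -1);
  for (int i = 0; i < n; ++i) {
    dp[i] = score[i];
    int len_i = qe[i] - qs[i];
    for (int j = 0; j < i; ++j) {
      if (qs[j] >= qs[i] || qe[j] >= qe[i]) continue;
      int ov = qe[j] - qs[i]; if (ov < 0) ov = 0;
      int len_j = qe[j] - qs[j];
      int shorter = len_i < len_j ? len_i : len_j;
      if (2 * ov > shorter) continue;
      double cand = dp[j] - overlap_penalty * ov + score[i];
      if (cand > dp[i]) { dp[i] = cand; pre[i] = j; }
    }
  }
  int best = 0;
  for (int i = 1; i < n; ++i) if (dp[i] > dp[best]) best = i;
  std::vector<int> path;
  for (int i = best; i >= 0; i = pre[i]) path.push_back(i + 1);
  std::reverse(path.begin(), path.end());
  return wrap(path);
}

// Greedy one-to-one matched-pair counts for read pairs. Input rows are
// candidate insertion matches (pair_id, element index in set A, element
// index in set B), pre-sorted by pair_id then decreasing overlap; returns
// the number of matched elements per pair_id run (pair_ids must be
// contiguous, 1..npairs).
// [[Rcpp::export]]
IntegerVector cpp_greedy_match_counts(IntegerVector pair_id, IntegerVector ia,
                                      IntegerVector ib, int npairs) {
  IntegerVector out(npairs, 0);
  int n = pair_id.size();
  int r = 0;
  std::vector<char> used_a, used_b;
  while (r < n) {
    int p = pair_id[r];
    int maxa = 0, maxb = 0;
    int r2 = r;
    while (r2 < n && pair_id[r2] == p) {
      if (ia[r2] > maxa) maxa = ia[r2];
      if (ib[r2] > maxb) maxb = ib[r2];
      ++r2;
    }
    used_a.assign(maxa + 1, 0);
    used_b.assign(maxb + 1, 0);
    int m = 0;
    for (int t = r; t < r2; ++t) {
      if (!used_a[ia[t]] && !used_b[ib[t]]) {
        used_a[ia[t]] = 1; used_b[ib[t]] = 1; ++m;
      }
    }
    out[p - 1] = m;
    r = r2;
  }
  return out;
}

// Nanopore-like read corruption: per-base errors at `rate`, split between
// substitutions, insertions and deletions. Uses R's RNG for reproducibility.
// [[Rcpp::export]]
CharacterVector cpp_mutate_reads(CharacterVector seqs, double rate,
                                 double sub_frac, double ins_frac,
                                 double del_frac) {
  const char BASES[4] = {'A', 'C', 'G', 'T'};
  double tot = sub_frac + ins_frac + del_frac;
  double p_sub = sub_frac / tot, p_ins = ins_frac / tot;
  int n = seqs.size();
  CharacterVector out(n);
  std::string buf;
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int L = LENGTH(STRING_ELT(seqs, i));
    buf.clear();
    buf.reserve((size_t)(L * (1 + rate) + 16));
    for (int j = 0; j < L; ++j) {
      if (unif_rand() >= rate) { buf.push_back(s[j]); continue; }
      double u = unif_rand();
      if (u < p_sub) {
        int b = enc(s[j]);
        int nb = (int)(unif_rand() * 3);
        if (nb >= 3) nb = 2;
        nb = (b <= 3) ? (b + 1 + nb) % 4 : nb;
        buf.push_back(BASES[nb]);
      } else if (u < p_sub + p_ins) {
        int nb = (int)(unif_rand() * 4); if (nb >= 4) nb = 3;
        buf.push_back(BASES[nb]);
        buf.push_back(s[j]);
      } // deletion: emit nothing
    }
    if (buf.empty()) buf.push_back(s[0]);
    out[i] = buf;
  }
  return out;
}
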