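#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Seed-and-extend local aligner with blastn-style scoring:
// match reward, mismatch penalty, and a gap of length l costing
// gap_open + gap_extend * l (BLAST convention). Exact seed words are hashed
// over the reference contigs; seed hits are clustered by diagonal and each
// cluster is resolved with a windowed affine Smith-Waterman with full
// three-state traceback, so alignment length, identities, mismatches and
// gap opens are exact. Both strands of every query are searched.

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
      default: break;
    }
  }
  return r;
}

struct Aln {
  int ref_idx = -1;
  int score = 0;
  int qstart = 0, qend = 0;     // 0-based inclusive, strand-local
  int sstart = 0, send = 0;     // 0-based inclusive on reference
  int matches = 0, mismatches = 0, gapopens = 0, alnlen = 0;
  bool minus = false;
};

// Local affine SW of query q vs reference window ref[w0..w1] (0-based,
// inclusive), full DP over the window with traceback.
static Aln window_sw(const std::string& q, const std::string& ref,
                     int w0, int w1,
                     int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)q.size();
  const int m = w1 - w0 + 1;
  const int openc = gap_open + gap_extend;  // cost of a length-1 gap
  const int NEG = -1000000000;
  const size_t W = (size_t)m + 1;

  std::vector<int> H((size_t)(n + 1) * W, 0);
  std::vector<int> E((size_t)(n + 1) * W, NEG);
  std::vector<int> F((size_t)(n + 1) * W, NEG);
  // hDir: 0 stop, 1 diag, 2 from F (vertical), 3 from E (horizontal)
  std::vector<uint8_t> hDir((size_t)(n + 1) * W, 0);
  std::vector<uint8_t> eExt((size_t)(n + 1) * W, 0); // E came from E
  std::vector<uint8_t> fExt((size_t)(n + 1) * W, 0); // F came from F
  auto at = [W](int i, int j) { return (size_t)i * W + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int eo = H[at(i, j - 1)] - openc, ee = E[at(i, j - 1)] - gap_extend;
      E[at(i, j)] = std::max(eo, ee);
      eExt[at(i, j)] = ee > eo;
      const int fo = H[at(i - 1, j)] - openc, fe = F[at(i - 1, j)] - gap_extend;
      F[at(i, j)] = std::max(fo, fe);
      fExt[at(i, j)] = fe > fo;
      const bool ok = base2bits(q[i - 1]) >= 0 &&
                      base2bits(ref[w0 + j - 1]) >= 0;
      const int sub = (ok && q[i - 1] == ref[w0 + j - 1]) ? match : mismatch;
      int h = H[at(i - 1, j - 1)] + sub;
      uint8_t dir = 1;
      if (F[at(i, j)] > h) { h = F[at(i, j)]; dir = 2; }
      if (E[at(i, j)] > h) { h = E[at(i, j)]; dir = 3; }
      if (h <= 0) { h = 0; dir = 0; }
      H[at(i, j)] = h;
      hDir[at(i, j)] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  Aln a;
  a.score = best;
  if (best <= 0) return a;
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  a.qend = bi - 1;
  a.send = w0 + bj - 1;
  for (;;) {
    if (state == 0) {
      uint8_t dir = hDir[at(i, j)];
      if (dir == 0) break;
      if (dir == 1) {
        ++a.alnlen;
        if (q[i - 1] == ref[w0 + j - 1]) ++a.matches; else ++a.mismatches;
        --i; --j;
      } else if (dir == 2) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 1) { // in E: ref base j aligned to a gap
      ++a.alnlen;
      bool ext = eExt[at(i, j)];
      --j;
      if (!ext) { ++a.gapopens; state = 0; }
    } else { // in F: query base i aligned to a gap
      ++a.alnlen;
      bool ext = fExt[at(i, j)];
      --i;
      if (!ext) { ++a.gapopens; state = 0; }
    }
  }
  a.qstart = i;
  a.sstart = w0 + j;
  return a;
}

struct SeedIndex {
  int w;
  std::unordered_map<uint32_t, std::vector<std::pair<int32_t, int32_t>>> pos;
};

static void index_reference(const std::vector<std::string>& refs, int w,
                            SeedIndex& idx) {
  idx.w = w;
  const uint32_t mask = (1u << (2 * w)) - 1;
  for (size_t r = 0; r < refs.size(); ++r) {
    const std::string& s = refs[r];
    uint32_t h = 0;
    int valid = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = base2bits(s[i]);
      if (b < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t)b) & mask;
      if (++valid >= w) {
        idx.pos[h].push_back({(int32_t)r, (int32_t)(i - w + 1)});
      }
    }
  }
}

struct Hit { int32_t ref; int32_t diag; int32_t rpos; int32_t qpos; };

// [[Rcpp::export]]
List cpp_align_reads(CharacterVector queries, CharacterVector query_ids,
                     CharacterVector refs, CharacterVector ref_names,
                     int word, int match, int mismatch,
                     int gap_open, int gap_extend,
                     int min_score, int max_alignments) {
  if (word < 4 || word > 15) stop("seed word length must be in 4..15");
  std::vector<std::string> R(refs.size());
  for (R_xlen_t i = 0; i < refs.size(); ++i) R[i] = as<std::string>(refs[i]);
  SeedIndex idx;
  index_reference(R, word, idx);
  const uint32_t mask = (1u << (2 * word)) - 1;
  const int band_merge = 32;   // diagonal slack when clustering seed hits
  const int pad = 24;          // window padding around a cluster
  const int max_clusters = std::max(4 * max_alignments, 16);

  std::vector<std::string> out_q, out_s;
  std::vector<double> out_pid;
  std::vector<int> out_len, out_mm, out_go, out_qs, out_qe, out_ss, out_se,
      out_score;

  for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
    const std::string q0 = as<std::string>(queries[qi]);
    const int qlen = (int)q0.size();
    std::vector<Aln> cand;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string q = strand ? revcomp(q0) : q0;
      std::vector<Hit> hits;
      uint32_t h = 0;
      int valid = 0;
      for (int i = 0; i < (int)q.size(); ++i) {
        int b = base2bits(q[i]);
        if (b < 0) { valid = 0; h = 0; continue; }
        h = ((h << 2) | (uint32_t)b) & mask;
        if (++valid >= word) {
          auto it = idx.pos.find(h);
          if (it == idx.pos.end()) continue;
          int qpos = i - word + 1;
          for (const auto& pr : it->second) {
            hits.push_back({pr.first, pr.second - qpos, pr.second, qpos});
          }
        }
      }
      if (hits.empty()) continue;
      std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
        if (a.ref != b.ref) return a.ref < b.ref;
        if (a.diag != b.diag) return a.diag < b.diag;
        return a.rpos < b.rpos;
      });
      struct Cluster { int ref; int d0, d1; int nhits; };
      std::vector<Cluster> clusters;
      for (const auto& hit : hits) {
        if (!clusters.empty()) {
          Cluster& c = clusters.back();
          if (c.ref == hit.ref && hit.diag - c.d1 <= band_merge) {
            c.d1 = hit.diag;
            ++c.nhits;
            continue;
          }
        }
        clusters.push_back({hit.ref, hit.diag, hit.diag, 1});
      }
      if ((int)clusters.size() > max_clusters) {
        std::nth_element(clusters.begin(), clusters.begin() + max_clusters,
                         clusters.end(),
                         [](const Cluster& a, const Cluster& b) {
                           return a.nhits > b.nhits;
                         });
        clusters.resize(max_clusters);
      }
      for (const auto& c : clusters) {
        const std::string& rs = R[c.ref];
        int w0 = std::max(0, c.d0 - pad);
        int w1 = std::min((int)rs.size() - 1, c.d1 + qlen - 1 + pad);
        if (w1 < w0) continue;
        Aln a = window_sw(q, rs, w0, w1, match, mismatch,
                          gap_open, gap_extend);
        if (a.score <= 0) continue;
        a.ref_idx = c.ref;
        a.minus = strand == 1;
        if (a.minus) { // report in original-read coordinates
          int qs = qlen - 1 - a.qend, qe = qlen - 1 - a.qstart;
          a.qstart = qs; a.qend = qe;
        }
        cand.push_back(a);
      }
    }

    // rank: score desc then reference position asc (deterministic,
    // independent of hash iteration order); drop alignments overlapping a
    // better one by >50% on the reference; cap at max_alignments
    std::sort(cand.begin(), cand.end(), [](const Aln& a, const Aln& b) {
      if (a.score != b.score) return a.score > b.score;
      if (a.ref_idx != b.ref_idx) return a.ref_idx < b.ref_idx;
      if (a.sstart != b.sstart) return a.sstart < b.sstart;
      return a.minus < b.minus;
    });
    std::vector<Aln> kept;
    for (const auto& a : cand) {
      if (a.score < min_score) continue;
      bool dup = false;
      for (const auto& k : kept) {
        if (k.ref_idx != a.ref_idx) continue;
        int ov = std::min(a.send, k.send) - std::max(a.sstart, k.sstart) + 1;
        if (ov > 0 && 2 * ov > (a.send - a.sstart + 1)) { dup = true; break; }
      }
      if (dup) continue;
      kept.push_back(a);
      if ((int)kept.size() >= max_alignments) break;
    }

    const std::string qid = as<std::string>(query_ids[qi]);
    for (const auto& a : kept) {
      out_q.push_back(qid);
      out_s.push_back(as<std::string>(ref_names[a.ref_idx]));
      out_pid.push_back(100.0 * a.matches / a.alnlen);
      out_len.push_back(a.alnlen);
      out_mm.push_back(a.mismatches);
      out_go.push_back(a.gapopens);
      out_qs.push_back(a.qstart + 1);
      out_qe.push_back(a.qend + 1);
      if (a.minus) { // reference coordinates descending on the minus strand
        out_ss.push_back(a.send + 1);
        out_se.push_back(a.sstart + 1);
      } else {
        out_ss.push_back(a.sstart + 1);
        out_se.push_back(a.send + 1);
      }
      out_score.push_back(a.score);
    }
  }

  return List::create(
      _["qseqid"] = out_q, _["sseqid"] = out_s, _["pident"] = out_pid,
      _["length"] = out_len, _["mismatch"] = out_mm, _["gapopen"] = out_go,
      _["qstart"] = out_qs, _["qend"] = out_qe, _["sstart"] = out_ss,
      _["send"] = out_se, _["score"] = out_score);
}
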