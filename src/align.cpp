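#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <string>
#include <climits>
#include <cstdint>

using namespace Rcpp;

// Exact pairwise alignment (Gotoh affine-gap DP) with a deterministic
// traceback, plus k-mer seeding utilities used to bound the DP to a
// subject window before aligning. Scoring: match/mismatch per base, a gap
// of length k scores gap_open + (k-1) * gap_extend.

static const int NEG = INT_MIN / 4;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

struct AlnResult {
  int score = 0, identities = 0, aln_length = 0;
  int qstart = 0, qend = 0, sstart = 0, send = 0;
  int mismatches = 0, gapopens = 0;
  bool empty = true;
};

// States: 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y (gap in a).
// Tie preference everywhere: M, then X (up), then Y (left).
// Scores are kept in two rolling rows (cache-friendly); only the byte
// traceback matrices span the full DP table.
static AlnResult gotoh_align(const std::string& a, const std::string& b,
                             bool local, int match, int mismatch,
                             int gap_open, int gap_extend) {
  const int n = (int) a.size(), m = (int) b.size();
  const size_t W = (size_t)(m + 1);
  if ((size_t)(n + 1) * W > 400000000UL)
    stop("alignment problem too large (%d x %d)", n, m);

  std::vector<int8_t> av(n), bv(m);
  for (int i = 0; i < n; ++i) av[i] = (int8_t) base_code(a[i]);
  for (int j = 0; j < m; ++j) bv[j] = (int8_t) base_code(b[j]);

  // traceback codes packed per cell: bits 0-1 for M (0=start,1=fromM,
  // 2=fromX,3=fromY), bits 2-3 for X (1=openM,2=extendX,3=openY),
  // bits 4-5 for Y (1=openM,2=openX,3=extendY)
  std::vector<uint8_t> tbA((n + 1) * W, 0);
  std::vector<int> Mp(W), Xp(W), Yp(W), Mc(W), Xc(W), Yc(W);

  // row 0
  Mp[0] = 0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    if (local) { Yp[j] = NEG; }
    else {
      Yp[j] = gap_open + (j - 1) * gap_extend;
      tbA[j] = (uint8_t)(((j == 1) ? 1 : 3) << 4);
    }
  }

  int best_i = 0, best_j = 0, best_score = local ? 0 : NEG;

  for (int i = 1; i <= n; ++i) {
    const int8_t ai = av[i - 1];
    Mc[0] = NEG; Yc[0] = NEG;
    if (local) { Xc[0] = NEG; }
    else {
      Xc[0] = gap_open + (i - 1) * gap_extend;
      tbA[i * W] = (uint8_t)(((i == 1) ? 1 : 2) << 2);
    }
    const size_t rowc = (size_t) i * W;
    uint8_t* tA = &tbA[rowc];
    for (int j = 1; j <= m; ++j) {
      const int s = (ai >= 0 && ai == bv[j - 1]) ? match : mismatch;
      // M from (i-1, j-1)
      int bp = Mp[j - 1]; uint8_t tb = 1;
      if (Xp[j - 1] > bp) { bp = Xp[j - 1]; tb = 2; }
      if (Yp[j - 1] > bp) { bp = Yp[j - 1]; tb = 3; }
      int mv = bp + s;
      if (local) {
        if (s > mv) { mv = s; tb = 0; }
        if (mv < 0) { mv = NEG; tb = 0; }
      }
      Mc[j] = mv;
      // X from (i-1, j)
      int xv = Mp[j] + gap_open; uint8_t xtb = 1;
      if (Xp[j] + gap_extend > xv) { xv = Xp[j] + gap_extend; xtb = 2; }
      if (Yp[j] + gap_open > xv) { xv = Yp[j] + gap_open; xtb = 3; }
      Xc[j] = xv;
      // Y from (i, j-1)
      int yv = Mc[j - 1] + gap_open; uint8_t ytb = 1;
      if (Xc[j - 1] + gap_open > yv) { yv = Xc[j - 1] + gap_open; ytb = 2; }
      if (Yc[j - 1] + gap_extend > yv) { yv = Yc[j - 1] + gap_extend; ytb = 3; }
      Yc[j] = yv;
      tA[j] = (uint8_t)(tb | (xtb << 2) | (ytb << 4));

      if (local && mv > best_score) { best_score = mv; best_i = i; best_j = j; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  AlnResult res;
  int i, j, state;
  if (local) {
    if (best_score <= 0) { res.score = 0; return res; }
    i = best_i; j = best_j; state = 0;
    res.score = best_score;
  } else {
    int bs = Mp[m]; state = 0;          // after the final swap, row n is in *p
    if (Xp[m] > bs) { bs = Xp[m]; state = 1; }
    if (Yp[m] > bs) { bs = Yp[m]; state = 2; }
    res.score = bs; i = n; j = m;
  }
  res.empty = false;
  res.qend = i; res.send = j;
  int prev_state_gap = -1;
  while (i > 0 || j > 0) {
    const size_t c = (size_t) i * W + j;
    if (state == 0) {
      // consume one diagonal step
      res.aln_length++;
      if (base_code(a[i - 1]) >= 0 && base_code(a[i - 1]) == base_code(b[j - 1]))
        res.identities++;
      else
        res.mismatches++;
      uint8_t tb = tbA[c] & 3;
      i--; j--;
      res.qstart = i + 1; res.sstart = j + 1;
      if (local && tb == 0) break;
      state = (tb == 1) ? 0 : (tb == 2 ? 1 : 2);
      if (i == 0 && j == 0) break;
      if (!local && i == 0 && j > 0) state = 2;
      if (!local && j == 0 && i > 0) state = 1;
    } else if (state == 1) {
      res.aln_length++;
      uint8_t tb = (tbA[c] >> 2) & 3;
      if (prev_state_gap != 1) res.gapopens++;
      prev_state_gap = 1;
      i--;
      state = (tb == 1) ? 0 : (tb == 2 ? 1 : 2);
      if (state != 1) prev_state_gap = -1;
      if (i == 0 && j == 0) break;
    } else {
      res.aln_length++;
      uint8_t tb = (tbA[c] >> 4) & 3;
      if (prev_state_gap != 2) res.gapopens++;
      prev_state_gap = 2;
      j--;
      state = (tb == 1) ? 0 : (tb == 3 ? 2 : 1);
      if (state != 2) prev_state_gap = -1;
      if (i == 0 && j == 0) break;
    }
  }
  if (res.qstart == 0) res.qstart = 1;
  if (res.sstart == 0) res.sstart = 1;
  return res;
}

static List aln_to_list(const AlnResult& r) {
  return List::create(
      _["score"] = r.score, _["identities"] = r.identities,
      _["aln_length"] = r.aln_length, _["mismatches"] = r.mismatches,
      _["gapopens"] = r.gapopens, _["qstart"] = r.qstart,
      _["qend"] = r.qend, _["sstart"] = r.sstart, _["send"] = r.send,
      _["empty"] = r.empty);
}

// [[Rcpp::export]]
List cpp_align_pair(std::string a, std::string b, std::string mode,
                    int match, int mismatch, int gap_open, int gap_extend) {
  bool local = (mode == "local");
  AlnResult r = gotoh_align(a, b, local, match, mismatch, gap_open, gap_extend);
  return aln_to_list(r);
}


// Banded local alignment around a fixed subject diagonal d0 (= j - i).
// Same state machine and tie rules as gotoh_align, but cells restricted to
// |j - i - d0| <= band; used after k-mer seeding where the optimum is known
// to lie near the seeded diagonal.
static AlnResult banded_local(const std::string& a, const std::string& b,
                              int d0, int band, int match, int mismatch,
                              int gap_open, int gap_extend) {
  const int n = (int) a.size(), m = (int) b.size();
  const int B = 2 * band + 1;
  std::vector<int8_t> av(n), bv(m);
  for (int i = 0; i < n; ++i) av[i] = (int8_t) base_code(a[i]);
  for (int j = 0; j < m; ++j) bv[j] = (int8_t) base_code(b[j]);
  std::vector<uint8_t> tbA((size_t)(n + 1) * B, 0);
  std::vector<int> Mp(B, NEG), Xp(B, NEG), Yp(B, NEG), Mc(B), Xc(B), Yc(B);

  int best_i = 0, best_k = 0, best_score = 0;
  for (int i = 1; i <= n; ++i) {
    const int8_t ai = av[i - 1];
    uint8_t* tA = &tbA[(size_t) i * B];
    for (int k = 0; k < B; ++k) {
      const int j = i + d0 - band + k;
      if (j < 1 || j > m) { Mc[k] = NEG; Xc[k] = NEG; Yc[k] = NEG; continue; }
      const int s = (ai >= 0 && ai == bv[j - 1]) ? match : mismatch;
      int bp = Mp[k]; uint8_t tb = 1;
      if (Xp[k] > bp) { bp = Xp[k]; tb = 2; }
      if (Yp[k] > bp) { bp = Yp[k]; tb = 3; }
      int mv = bp + s;
      if (s > mv) { mv = s; tb = 0; }
      if (mv < 0) { mv = NEG; tb = 0; }
      Mc[k] = mv;
      int xv = NEG; uint8_t xtb = 1;
      if (k + 1 < B) {
        xv = Mp[k + 1] + gap_open;
        if (Xp[k + 1] + gap_extend > xv) { xv = Xp[k + 1] + gap_extend; xtb = 2; }
        if (Yp[k + 1] + gap_open > xv) { xv = Yp[k + 1] + gap_open; xtb = 3; }
      }
      Xc[k] = xv;
      int yv = NEG; uint8_t ytb = 1;
      if (k >= 1) {
        yv = Mc[k - 1] + gap_open;
        if (Xc[k - 1] + gap_open > yv) { yv = Xc[k - 1] + gap_open; ytb = 2; }
        if (Yc[k - 1] + gap_extend > yv) { yv = Yc[k - 1] + gap_extend; ytb = 3; }
      }
      Yc[k] = yv;
      tA[k] = (uint8_t)(tb | (xtb << 2) | (ytb << 4));
      if (mv > best_score) { best_score = mv; best_i = i; best_k = k; }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  AlnResult res;
  if (best_score <= 0) { res.score = 0; return res; }
  res.empty = false; res.score = best_score;
  int i = best_i, k = best_k, state = 0;
  res.qend = i; res.send = i + d0 - band + k;
  int prev_state_gap = -1;
  while (i > 0) {
    const uint8_t code = tbA[(size_t) i * B + k];
    if (state == 0) {
      const int j = i + d0 - band + k;
      res.aln_length++;
      if (av[i - 1] >= 0 && av[i - 1] == bv[j - 1]) res.identities++;
      else res.mismatches++;
      res.qstart = i; res.sstart = j;
      const uint8_t tb = code & 3;
      i--;
      if (tb == 0) break;
      state = (tb == 1) ? 0 : (tb == 2 ? 1 : 2);
      prev_state_gap = -1;
    } else if (state == 1) {
      res.aln_length++;
      const uint8_t tb = (code >> 2) & 3;
      if (prev_state_gap != 1) res.gapopens++;
      prev_state_gap = 1;
      i--; k++;
      state = (tb == 1) ? 0 : (tb == 2 ? 1 : 2);
      if (state != 1) prev_state_gap = -1;
    } else {
      res.aln_length++;
      const uint8_t tb = (code >> 4) & 3;
      if (prev_state_gap != 2) res.gapopens++;
      prev_state_gap = 2;
      k--;
      state = (tb == 1) ? 0 : (tb == 3 ? 2 : 1);
      if (state != 2) prev_state_gap = -1;
    }
  }
  return res;
}

// ---- k-mer seeding ---------------------------------------------------------

static void kmer_codes(const std::string& s, int k, std::vector<int64_t>& out) {
  // out[i] = code of k-mer starting at i, or -1 if it spans a non-ACGT base
  const int n = (int) s.size();
  out.assign(std::max(0, n - k + 1), -1);
  int64_t code = 0, mask = ((int64_t)1 << (2 * k)) - 1;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | b) & mask;
    run++;
    if (run >= k) out[i - k + 1] = code;
  }
}

// sorted flat (k-mer code, position) table: cheap to build, binary-search
// lookups (node-based hash maps are slow under this allocator)
typedef std::vector<std::pair<int64_t, int>> KmerPosMap;

static KmerPosMap build_pos_map(const std::string& s, int k) {
  std::vector<int64_t> sk;
  kmer_codes(s, k, sk);
  KmerPosMap smap;
  smap.reserve(sk.size());
  for (int j = 0; j < (int) sk.size(); ++j)
    if (sk[j] >= 0) smap.emplace_back(sk[j], j);
  std::sort(smap.begin(), smap.end());
  return smap;
}

// Best seeded diagonal of q against s (via its prebuilt k-mer position
// table); returns window [wstart, wend) on s, or wstart = -1 when no
// shared k-mer exists.
static void best_window_map(const std::string& q, const KmerPosMap& smap,
                            int slen, int k, int margin, int& wstart,
                            int& wend, int& best_diag) {
  std::vector<int64_t> qk;
  kmer_codes(q, k, qk);
  std::vector<int> diags;
  for (int i = 0; i < (int) qk.size(); ++i) {
    if (qk[i] < 0) continue;
    auto lo = std::lower_bound(smap.begin(), smap.end(),
                               std::make_pair(qk[i], INT_MIN));
    for (auto it = lo; it != smap.end() && it->first == qk[i]; ++it)
      diags.push_back(it->second - i);
  }
  if (diags.empty()) { wstart = -1; wend = -1; best_diag = 0; return; }
  std::sort(diags.begin(), diags.end());
  int best_d = diags[0], best_c = 1, run = 1;
  for (size_t t = 1; t < diags.size(); ++t) {
    run = (diags[t] == diags[t - 1]) ? run + 1 : 1;
    if (run > best_c) { best_c = run; best_d = diags[t]; }
  }
  const int n = (int) q.size();
  wstart = std::max(0, best_d - margin);
  wend = std::min(slen, best_d + n + margin);
  best_diag = best_d;
}

static void best_window(const std::string& q, const std::string& s, int k,
                        int margin, int& wstart, int& wend, int& best_diag) {
  KmerPosMap smap = build_pos_map(s, k);
  best_window_map(q, smap, (int) s.size(), k, margin, wstart, wend,
                  best_diag);
}

// [[Rcpp::export]]
List cpp_seeded_local(std::string q, std::string s, int k, int margin,
                      int match, int mismatch, int gap_open, int gap_extend,
                      int band) {
  int wstart, wend, diag;
  best_window(q, s, k, margin, wstart, wend, diag);
  if (wstart < 0) {
    AlnResult nil;
    return aln_to_list(nil);
  }
  AlnResult r;
  if (band > 0) {
    r = banded_local(q, s, diag, band, match, mismatch, gap_open,
                     gap_extend);
  } else {
    r = gotoh_align(q, s.substr(wstart, wend - wstart), true, match,
                    mismatch, gap_open, gap_extend);
    if (!r.empty) { r.sstart += wstart; r.send += wstart; }
  }
  return aln_to_list(r);
}

// [[Rcpp::export]]
DataFrame cpp_batch_hits(CharacterVector queries, CharacterVector subjects,
                         int k, int min_score, int margin, int match,
                         int mismatch, int gap_open, int gap_extend,
                         bool both_strands, int band) {
  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::string> subj(ns);
  std::vector<KmerPosMap> smaps(ns);
  // global sorted (k-mer code, subject index) table, deduplicated
  std::vector<std::pair<int64_t, int>> kmap;
  for (int j = 0; j < ns; ++j) {
    subj[j] = as<std::string>(subjects[j]);
    smaps[j] = build_pos_map(subj[j], k);
    int64_t prev = -1;
    for (auto& kv : smaps[j]) {
      if (kv.first != prev) kmap.emplace_back(kv.first, j);
      prev = kv.first;
    }
  }
  std::sort(kmap.begin(), kmap.end());

  std::vector<int> o_q, o_s, o_score, o_ident, o_len, o_mm, o_go;
  std::vector<int> o_qs, o_qe, o_ss, o_se;
  std::vector<int> o_strand;  // 1 = plus, -1 = minus

  for (int i = 0; i < nq; ++i) {
    std::string qp = as<std::string>(queries[i]);
    for (int ori = 0; ori < (both_strands ? 2 : 1); ++ori) {
      std::string qo = (ori == 0) ? qp : revcomp(qp);
      std::vector<int64_t> qk;
      kmer_codes(qo, k, qk);
      std::vector<int> cand;
      for (int64_t code : qk) {
        if (code < 0) continue;
        auto lo = std::lower_bound(kmap.begin(), kmap.end(),
                                   std::make_pair(code, INT_MIN));
        for (auto it = lo; it != kmap.end() && it->first == code; ++it)
          cand.push_back(it->second);
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (int j : cand) {
        int wstart, wend, diag;
        best_window_map(qo, smaps[j], (int) subj[j].size(), k, margin,
                        wstart, wend, diag);
        if (wstart < 0) continue;
        AlnResult r;
        if (band > 0) {
          r = banded_local(qo, subj[j], diag, band, match, mismatch,
                           gap_open, gap_extend);
        } else {
          r = gotoh_align(qo, subj[j].substr(wstart, wend - wstart), true,
                          match, mismatch, gap_open, gap_extend);
          if (!r.empty) { r.sstart += wstart; r.send += wstart; }
        }
        if (r.empty || r.score < min_score) continue;
        // report query coordinates on the original (plus) strand
        int qs = r.qstart, qe = r.qend;
        if (ori == 1) {
          int L = (int) qp.size();
          qs = L - r.qend + 1; qe = L - r.qstart + 1;
        }
        o_q.push_back(i + 1); o_s.push_back(j + 1);
        o_score.push_back(r.score); o_ident.push_back(r.identities);
        o_len.push_back(r.aln_length); o_mm.push_back(r.mismatches);
        o_go.push_back(r.gapopens);
        o_qs.push_back(qs); o_qe.push_back(qe);
        o_ss.push_back(r.sstart); o_se.push_back(r.send);
        o_strand.push_back(ori == 0 ? 1 : -1);
      }
    }
  }
  return DataFrame::create(
      _["query_idx"] = o_q, _["subject_idx"] = o_s, _["score"] = o_score,
      _["identities"] = o_ident, _["aln_length"] = o_len,
      _["mismatches"] = o_mm, _["gapopens"] = o_go, _["qstart"] = o_qs,
      _["qend"] = o_qe, _["sstart"] = o_ss, _["send"] = o_se,
      _["strand"] = o_strand);
}

// [[Rcpp::export]]
CharacterVector cpp_build_reads(CharacterVector genome_seqs,
                                IntegerVector gidx, IntegerVector start0,
                                LogicalVector rc, int L,
                                IntegerVector err_read, IntegerVector err_pos0,
                                IntegerVector err_shift) {
  const int n = gidx.size();
  std::vector<std::string> gs(genome_seqs.size());
  for (int g = 0; g < genome_seqs.size(); ++g)
    gs[g] = as<std::string>(genome_seqs[g]);
  std::vector<std::string> reads(n);
  for (int i = 0; i < n; ++i) {
    const std::string& g = gs[gidx[i] - 1];
    std::string r = g.substr(start0[i], L);
    if (rc[i]) r = revcomp(r);
    reads[i] = r;
  }
  static const char* ACGT = "ACGT";
  for (int e = 0; e < err_read.size(); ++e) {
    std::string& r = reads[err_read[e] - 1];
    int p = err_pos0[e];
    int b = base_code(r[p]);
    if (b >= 0) r[p] = ACGT[(b + err_shift[e]) % 4];
  }
  return wrap(reads);
}

// [[Rcpp::export]]
std::string cpp_mutate_seq(std::string seq, IntegerVector pos0,
                           IntegerVector shift) {
  static const char* ACGT = "ACGT";
  for (int i = 0; i < pos0.size(); ++i) {
    int b = base_code(seq[pos0[i]]);
    if (b >= 0) seq[pos0[i]] = ACGT[(b + shift[i]) % 4];
  }
  return seq;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }
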