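#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap pairwise alignment with a fixed, documented traceback
// tie-break: diagonal > up (gap in reference, consumes query) > left
// (gap in query, consumes reference). A gap of length k costs
// gap_open + k * gap_extend. Two modes:
//   semi-global (default): end gaps on the reference free (the query is
//     aligned in full, the unaligned reference flanks cost nothing);
//   global: end gaps charged on both sequences (used for identity).
// Scores are kept in rolling float rows; traceback uses byte pointer
// matrices only.

static const float NEG = -1e18f;

// alignment operations over the core (scored) region
enum AlnOp : uint8_t { OP_MATCH = 0, OP_MISMATCH = 1, OP_INS = 2, OP_DEL = 3 };
// OP_INS: gap in reference (extra query base); OP_DEL: gap in query.

struct AlnCore {
  std::vector<uint8_t> ops; // core ops, query/ref order
  int qs, qe, rs, re;       // 1-based inclusive spans covered by the core
  double score;
};

struct DPBuf {
  std::vector<float> prevM, prevI, prevD, curM, curI, curD;
  std::vector<uint8_t> pM, pI, pD;
  void resize(size_t rows_bytes, size_t w) {
    if (pM.size() < rows_bytes) { pM.resize(rows_bytes); pI.resize(rows_bytes); pD.resize(rows_bytes); }
    if (prevM.size() < w) {
      prevM.resize(w); prevI.resize(w); prevD.resize(w);
      curM.resize(w); curI.resize(w); curD.resize(w);
    }
  }
};

static void align_core(const char* q, int n, const char* r, int m,
                       float match, float mismatch,
                       float gap_open, float gap_extend,
                       DPBuf& buf, AlnCore& out, bool global = false) {
  const size_t W = (size_t)(m + 1);
  buf.resize((size_t)(n + 1) * W, W);
  float *pM_ = buf.prevM.data(), *pI_ = buf.prevI.data(), *pD_ = buf.prevD.data();
  float *cM = buf.curM.data(), *cI = buf.curI.data(), *cD = buf.curD.data();
  uint8_t *tM = buf.pM.data(), *tI = buf.pI.data(), *tD = buf.pD.data();

  // row 0
  if (global) {
    pM_[0] = 0.0f; pI_[0] = NEG; pD_[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      pM_[j] = NEG; pI_[j] = NEG;
      pD_[j] = gap_open + j * gap_extend; tD[j] = (j == 1) ? 0 : 2;
    }
  } else {
    for (int j = 0; j <= m; ++j) { pM_[j] = 0.0f; pI_[j] = NEG; pD_[j] = NEG; }
  }
  for (int i = 1; i <= n; ++i) {
    size_t row = (size_t)i * W;
    // column 0: starting inside the query costs an opened reference gap
    cM[0] = NEG; cD[0] = NEG;
    cI[0] = gap_open + i * gap_extend; tI[row] = (i == 1) ? 0 : 1;
    const char qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      // diagonal: tie-break source M > I > D
      float best = pM_[j - 1]; uint8_t src = 0;
      if (pI_[j - 1] > best) { best = pI_[j - 1]; src = 1; }
      if (pD_[j - 1] > best) { best = pD_[j - 1]; src = 2; }
      cM[j] = best + (qi == r[j - 1] ? match : mismatch);
      tM[row + j] = src;
      // up: gap in reference, consume query base
      float io = pM_[j] + gap_open + gap_extend, ie = pI_[j] + gap_extend;
      if (io >= ie) { cI[j] = io; tI[row + j] = 0; } else { cI[j] = ie; tI[row + j] = 1; }
      // left: gap in query, consume reference base
      float dop = cM[j - 1] + gap_open + gap_extend, de = cD[j - 1] + gap_extend;
      if (dop >= de) { cD[j] = dop; tD[row + j] = 0; } else { cD[j] = de; tD[row + j] = 2; }
    }
    std::swap(buf.prevM, buf.curM); std::swap(buf.prevI, buf.curI);
    std::swap(buf.prevD, buf.curD);
    pM_ = buf.prevM.data(); pI_ = buf.prevI.data(); pD_ = buf.prevD.data();
    cM = buf.curM.data(); cI = buf.curI.data(); cD = buf.curD.data();
  }
  // prev* now holds row n
  int bi = n, bj = m; uint8_t bs = 0;
  float bscore = pM_[m];
  if (pI_[m] > bscore) { bscore = pI_[m]; bs = 1; }
  if (pD_[m] > bscore) { bscore = pD_[m]; bs = 2; }
  if (!global) {
    // query must be consumed in full: end anywhere in the last row
    for (int j = m; j >= 0; --j) {
      if (pM_[j] > bscore) { bscore = pM_[j]; bj = j; bs = 0; }
      if (pI_[j] > bscore) { bscore = pI_[j]; bj = j; bs = 1; }
      if (pD_[j] > bscore) { bscore = pD_[j]; bj = j; bs = 2; }
    }
  }

  out.ops.clear();
  int i = bi, j = bj; uint8_t s = bs;
  while (global ? (i > 0 || j > 0) : (i > 0)) {
    size_t c = (size_t)i * W + j;
    if (s == 0) {
      out.ops.push_back(q[i - 1] == r[j - 1] ? OP_MATCH : OP_MISMATCH);
      s = tM[c]; --i; --j;
    } else if (s == 1) {
      out.ops.push_back(OP_INS);
      s = tI[c]; --i;
    } else {
      out.ops.push_back(OP_DEL);
      s = tD[c]; --j;
    }
  }
  std::reverse(out.ops.begin(), out.ops.end());
  out.qs = i + 1; out.qe = bi; out.rs = j + 1; out.re = bj;
  out.score = bscore;
}

// [[Rcpp::export(name = ".cpp_align_semiglobal")]]
List cpp_align_semiglobal(std::string query, std::string ref,
                          double match, double mismatch,
                          double gap_open, double gap_extend) {
  DPBuf buf; AlnCore core;
  align_core(query.c_str(), (int)query.size(), ref.c_str(), (int)ref.size(),
             (float)match, (float)mismatch, (float)gap_open,
             (float)gap_extend, buf, core);
  // build full alignment strings including free end gaps
  std::string qa, ra;
  for (int j = 1; j < core.rs; ++j) { qa.push_back('-'); ra.push_back(ref[j - 1]); }
  for (int i = 1; i < core.qs; ++i) { qa.push_back(query[i - 1]); ra.push_back('-'); }
  int cs = (int)qa.size() + 1;
  int qi = core.qs, rj = core.rs;
  for (uint8_t op : core.ops) {
    switch (op) {
      case OP_MATCH: case OP_MISMATCH:
        qa.push_back(query[qi - 1]); ra.push_back(ref[rj - 1]); ++qi; ++rj; break;
      case OP_INS:
        qa.push_back(query[qi - 1]); ra.push_back('-'); ++qi; break;
      case OP_DEL:
        qa.push_back('-'); ra.push_back(ref[rj - 1]); ++rj; break;
    }
  }
  int ce = (int)qa.size();
  for (int i = core.qe + 1; i <= (int)query.size(); ++i) { qa.push_back(query[i - 1]); ra.push_back('-'); }
  for (int j = core.re + 1; j <= (int)ref.size(); ++j) { qa.push_back('-'); ra.push_back(ref[j - 1]); }
  return List::create(
    _["query_aln"] = qa, _["ref_aln"] = ra, _["score"] = core.score,
    _["query_start"] = core.qs, _["query_end"] = core.qe,
    _["ref_start"] = core.rs, _["ref_end"] = core.re,
    _["core_start"] = cs, _["core_end"] = ce);
}

static void count_errors(const AlnCore& core, int& nins, int& ndel, int& nsub,
                         std::vector<int>* ins_pos, std::vector<int>* del_pos,
                         std::vector<int>* sub_pos) {
  nins = ndel = nsub = 0;
  int rj = core.rs; // next reference position (1-based)
  for (uint8_t op : core.ops) {
    switch (op) {
      case OP_MATCH: ++rj; break;
      case OP_MISMATCH:
        ++nsub; if (sub_pos) sub_pos->push_back(rj); ++rj; break;
      case OP_INS:
        ++nins; if (ins_pos) ins_pos->push_back(rj - 1); break;
      case OP_DEL:
        ++ndel; if (del_pos) del_pos->push_back(rj); ++rj; break;
    }
  }
}

// Batched best-copy error profiling: align every query against every
// reference copy, keep the best score (ties: fewest total errors, then
// first copy), and return per-read error counts plus positional records.
// [[Rcpp::export(name = ".cpp_profile_errors")]]
List cpp_profile_errors(CharacterVector queries, CharacterVector refs,
                        double match, double mismatch,
                        double gap_open, double gap_extend) {
  int nq = queries.size(), nr = refs.size();
  std::vector<std::string> rs(nr);
  for (int r = 0; r < nr; ++r) rs[r] = as<std::string>(refs[r]);
  IntegerVector best_copy(nq), v_ins(nq), v_del(nq), v_sub(nq), v_span(nq);
  std::vector<int> rec_read, rec_type, rec_pos; // long-format positions
  DPBuf buf; AlnCore core, best;
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    double bsc = -1e30; int bidx = 0, berr = 0, bi_ = 0, bd_ = 0, bs_ = 0;
    for (int r = 0; r < nr; ++r) {
      align_core(q.c_str(), (int)q.size(), rs[r].c_str(), (int)rs[r].size(),
                 (float)match, (float)mismatch, (float)gap_open,
                 (float)gap_extend, buf, core);
      int ni, nd, nsu;
      count_errors(core, ni, nd, nsu, nullptr, nullptr, nullptr);
      int tot = ni + nd + nsu;
      if (core.score > bsc || (core.score == bsc && tot < berr)) {
        bsc = core.score; bidx = r; berr = tot; bi_ = ni; bd_ = nd; bs_ = nsu;
        best = core;
      }
    }
    best_copy[i] = bidx + 1; v_ins[i] = bi_; v_del[i] = bd_; v_sub[i] = bs_;
    v_span[i] = best.re - best.rs + 1; // covered reference bases
    std::vector<int> ip, dp, sp;
    int ni, nd, nsu;
    count_errors(best, ni, nd, nsu, &ip, &dp, &sp);
    for (int p : ip) { rec_read.push_back(i + 1); rec_type.push_back(1); rec_pos.push_back(p); }
    for (int p : dp) { rec_read.push_back(i + 1); rec_type.push_back(2); rec_pos.push_back(p); }
    for (int p : sp) { rec_read.push_back(i + 1); rec_type.push_back(3); rec_pos.push_back(p); }
  }
  return List::create(
    _["best_copy"] = best_copy, _["n_ins"] = v_ins, _["n_del"] = v_del,
    _["n_sub"] = v_sub, _["ref_span"] = v_span,
    _["pos_read"] = wrap(rec_read),
    _["pos_type"] = wrap(rec_type), _["pos_pos"] = wrap(rec_pos));
}

// identity = match columns / alignment columns of a global alignment,
// with end-gap runs (leading/trailing gap-only stretches) excluded
static double pair_identity(const std::string& a, const std::string& b,
                            float match, float mismatch,
                            float gap_open, float gap_extend,
                            DPBuf& buf, AlnCore& core,
                            int* matches_out = nullptr, int* cols_out = nullptr) {
  align_core(a.c_str(), (int)a.size(), b.c_str(), (int)b.size(),
             match, mismatch, gap_open, gap_extend, buf, core, true);
  int lo = 0, hi = (int)core.ops.size();
  while (lo < hi && (core.ops[lo] == OP_INS || core.ops[lo] == OP_DEL)) ++lo;
  while (hi > lo && (core.ops[hi - 1] == OP_INS || core.ops[hi - 1] == OP_DEL)) --hi;
  int matches = 0;
  for (int k = lo; k < hi; ++k) if (core.ops[k] == OP_MATCH) ++matches;
  int cols = hi - lo;
  if (matches_out) *matches_out = matches;
  if (cols_out) *cols_out = cols;
  return cols > 0 ? (double)matches / cols : 0.0;
}

// [[Rcpp::export(name = ".cpp_pair_identity")]]
List cpp_pair_identity(std::string a, std::string b, double match,
                       double mismatch, double gap_open, double gap_extend) {
  DPBuf buf; AlnCore core; int m, c;
  double id = pair_identity(a, b, (float)match, (float)mismatch,
                            (float)gap_open, (float)gap_extend,
                            buf, core, &m, &c);
  return List::create(_["matches"] = m, _["columns"] = c, _["identity"] = id);
}

// Greedy abundance-sorted centroid clustering: each sequence (already
// sorted by decreasing cluster size) joins the first centroid, in founding
// order, with identity >= threshold; otherwise it founds a new centroid.
// Returns the 1-based input index of each sequence's centroid.
// [[Rcpp::export(name = ".cpp_greedy_cluster")]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold,
                                 double match, double mismatch,
                                 double gap_open, double gap_extend) {
  int n = seqs.size();
  IntegerVector assign(n);
  std::vector<std::string> centroids;
  std::vector<int> centroid_idx;
  DPBuf buf; AlnCore core;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int hit = -1;
    for (size_t c = 0; c < centroids.size(); ++c) {
      if (centroids[c] == s) { hit = (int)c; break; }
      double id = pair_identity(s, centroids[c], (float)match,
                                (float)mismatch, (float)gap_open,
                                (float)gap_extend, buf, core);
      if (id >= threshold) { hit = (int)c; break; }
    }
    if (hit < 0) {
      centroids.push_back(s);
      centroid_idx.push_back(i + 1);
      assign[i] = i + 1;
    } else {
      assign[i] = centroid_idx[hit];
    }
  }
  return assign;
}

// Per-query-position match indicator against a reference (1 = aligned as an
// identical base in the core region), used by the chimera detector.
// [[Rcpp::export(name = ".cpp_match_vector")]]
IntegerVector cpp_match_vector(std::string query, std::string ref,
                               double match, double mismatch,
                               double gap_open, double gap_extend) {
  DPBuf buf; AlnCore core;
  align_core(query.c_str(), (int)query.size(), ref.c_str(), (int)ref.size(),
             (float)match, (float)mismatch, (float)gap_open,
             (float)gap_extend, buf, core, true);
  IntegerVector out((int)query.size());
  int qi = core.qs;
  for (uint8_t op : core.ops) {
    switch (op) {
      case OP_MATCH: out[qi - 1] = 1; ++qi; break;
      case OP_MISMATCH: case OP_INS: ++qi; break;
      case OP_DEL: break;
    }
  }
  return out;
}
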