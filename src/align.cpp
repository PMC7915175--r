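#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Base codes: A=0 C=1 G=2 T=3, anything else (N, IUPAC) = 4. Code 5 is the
// internal sentinel used to mask already-reported alignments out of a
// refinement window; it scores so badly no alignment crosses it.
// Lowercase (soft-masked) bases are scored like their uppercase forms.
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case '\1': return 5;
    default: return 4;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'a': return 't';
    case 'C': return 'G'; case 'c': return 'g';
    case 'G': return 'C'; case 'g': return 'c';
    case 'T': return 'A'; case 't': return 'a';
    case 'N': return 'N'; case 'n': return 'n';
    default:  return 'N';
  }
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
  return out;
}

// Substitution column classes
enum ColClass { COL_MATCH, COL_TS, COL_TV, COL_AMBIG };

static inline int col_class(int a, int b) {
  if (a >= 4 || b >= 4) return COL_AMBIG;
  if (a == b) return COL_MATCH;
  // transitions: A<->G (0,2), C<->T (1,3)
  if ((a + b) == 2 || (a + b) == 4) {
    if ((a == 0 && b == 2) || (a == 2 && b == 0) ||
        (a == 1 && b == 3) || (a == 3 && b == 1)) return COL_TS;
  }
  return COL_TV;
}

struct AlnResult {
  int score;
  int a_start, a_end, b_start, b_end; // 0-based half-open
  int matches, ts, tv, ambig, gapcols;
  bool ok;
};

// Smith-Waterman local alignment with affine gaps.
// A gap of length L costs gap_open + L * gap_extend (both negative), i.e. the
// first gap column pays gap_open + gap_extend.  N columns score `nscore` (0)
// and are classified as ambiguous, never as matches or substitutions.
static AlnResult sw_align(const std::string &a, const std::string &b,
                          int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  AlnResult res; res.score = 0; res.ok = false;
  res.a_start = res.a_end = res.b_start = res.b_end = 0;
  res.matches = res.ts = res.tv = res.ambig = res.gapcols = 0;
  if (n == 0 || m == 0) return res;
  const double cells = (double)(n + 1) * (double)(m + 1);
  if (cells > 6e8)
    stop("alignment problem too large (%d x %d)", n, m);

  std::vector<int> ac(n), bc(m);
  for (int i = 0; i < n; ++i) ac[i] = base_code(a[i]);
  for (int j = 0; j < m; ++j) bc[j] = base_code(b[j]);

  // Rolling score rows; full byte trace matrices for the traceback.
  // traces: tM 0=stop,1=diag-from-M,2=diag-from-Ix,3=diag-from-Iy
  //         tIx/tIy: bit set = extend (from same matrix), clear = open
  const int NEG = -1000000000;
  const size_t W = (size_t)m + 1;
  std::vector<int> Mp(W, 0), Mc(W, 0), Ixp(W, NEG), Ixc(W, NEG),
      Iyp(W, NEG), Iyc(W, NEG);
  std::vector<uint8_t> tM((size_t)(n + 1) * W, 0),
      tIx((size_t)(n + 1) * W, 0), tIy((size_t)(n + 1) * W, 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const size_t row = (size_t)i * W;
    Mc[0] = 0; Ixc[0] = NEG; Iyc[0] = NEG;
    const int aci = ac[i - 1];
    for (int j = 1; j <= m; ++j) {
      // Ix: gap in b (consume a[i-1])
      int open = Mp[j] + gap_open + gap_extend;
      int ext  = Ixp[j] + gap_extend;
      if (open >= ext) { Ixc[j] = open; }
      else             { Ixc[j] = ext; tIx[row + j] = 1; }
      // Iy: gap in a (consume b[j-1])
      open = Mc[j - 1] + gap_open + gap_extend;
      ext  = Iyc[j - 1] + gap_extend;
      if (open >= ext) { Iyc[j] = open; }
      else             { Iyc[j] = ext; tIy[row + j] = 1; }
      // M: diagonal
      int cls = col_class(aci, bc[j - 1]);
      int s = (cls == COL_MATCH) ? match : (cls == COL_AMBIG ? 0 : mismatch);
      if (aci == 5 || bc[j - 1] == 5) s = -100000; // sentinel
      int dM = Mp[j - 1], dIx = Ixp[j - 1], dIy = Iyp[j - 1];
      int from = 1, dbest = dM;
      if (dIx > dbest) { dbest = dIx; from = 2; }
      if (dIy > dbest) { dbest = dIy; from = 3; }
      int val = dbest + s;
      if (val <= 0) { Mc[j] = 0; tM[row + j] = 0; }
      else { Mc[j] = val; tM[row + j] = (uint8_t)from; }
      if (Mc[j] > best) { best = Mc[j]; bi = i; bj = j; }
    }
    std::swap(Mp, Mc); std::swap(Ixp, Ixc); std::swap(Iyp, Iyc);
  }
  res.score = best;
  if (best <= 0) return res;
  res.ok = true;
  // traceback from (bi, bj), state M
  int i = bi, j = bj, state = 0; // 0=M,1=Ix,2=Iy
  res.a_end = bi; res.b_end = bj;
  while (i > 0 && j > 0) {
    const size_t row = (size_t)i * W;
    if (state == 0) {
      uint8_t t = tM[row + j];
      if (t == 0) break;
      int cls = col_class(ac[i - 1], bc[j - 1]);
      if (cls == COL_MATCH) res.matches++;
      else if (cls == COL_TS) res.ts++;
      else if (cls == COL_TV) res.tv++;
      else res.ambig++;
      state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
      --i; --j;
    } else if (state == 1) {
      res.gapcols++;
      state = tIx[row + j] ? 1 : 0;
      --i;
    } else {
      res.gapcols++;
      state = tIy[row + j] ? 2 : 0;
      --j;
    }
  }
  res.a_start = i; res.b_start = j;
  return res;
}

// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b, int match, int mismatch,
                     int gap_open, int gap_extend) {
  AlnResult r = sw_align(a, b, match, mismatch, gap_open, gap_extend);
  return List::create(
      _["score"] = r.score, _["a_start"] = r.a_start, _["a_end"] = r.a_end,
      _["b_start"] = r.b_start, _["b_end"] = r.b_end, _["matches"] = r.matches,
      _["transitions"] = r.ts, _["transversions"] = r.tv,
      _["ambiguous_cols"] = r.ambig, _["gap_cols"] = r.gapcols,
      _["aligned_cols"] = r.matches + r.ts + r.tv + r.ambig);
}

struct Candidate { int tstart, tend, diag; };

// Ungapped X-drop extension of an exact k-mer seed at (tp, cp).
static Candidate xdrop_extend(const std::vector<int> &t, const std::vector<int> &c,
                              int tp, int cp, int k, int match, int mismatch,
                              int xdrop) {
  int score = k * match, best = score;
  int tr = tp + k, cr = cp + k, best_tr = tr;
  while (tr < (int)t.size() && cr < (int)c.size()) {
    int cls = col_class(t[tr], c[cr]);
    score += (cls == COL_MATCH) ? match : (cls == COL_AMBIG ? 0 : mismatch);
    ++tr; ++cr;
    if (score > best) { best = score; best_tr = tr; }
    if (best - score > xdrop) break;
  }
  score = best;
  int tl = tp, cl = cp, best_tl = tl;
  while (tl > 0 && cl > 0) {
    int cls = col_class(t[tl - 1], c[cl - 1]);
    score += (cls == COL_MATCH) ? match : (cls == COL_AMBIG ? 0 : mismatch);
    --tl; --cl;
    if (score > best) { best = score; best_tl = tl; }
    if (best - score > xdrop) break;
  }
  Candidate cand; cand.tstart = best_tl; cand.tend = best_tr; cand.diag = tp - cp;
  return cand;
}

struct Hit {
  int target_idx, cons_idx;
  int start, end, cons_start, cons_end;
  char strand;
  int score, matches, ts, tv, ambig, gapcols;
};

static void scan_one(const std::string &tseq, const std::vector<int> &tcode,
                     const std::string &cseq, int target_idx, int cons_idx,
                     char strand, int clen_orig, int k, int match, int mismatch,
                     int gap_open, int gap_extend, int xdrop, int min_score,
                     int min_len, std::vector<Hit> &hits) {
  const int tn = (int)tcode.size(), cn = (int)cseq.size();
  if (cn < k || tn < k) return;
  std::vector<int> ccode(cn);
  for (int j = 0; j < cn; ++j) ccode[j] = base_code(cseq[j]);

  // k-mer index of the consensus (2-bit codes; windows containing N skipped)
  std::unordered_map<uint32_t, std::vector<int> > index;
  uint32_t kmer = 0, mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  int valid = 0;
  for (int j = 0; j < cn; ++j) {
    int b = ccode[j];
    if (b == 4) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t)b) & mask;
    if (++valid >= k) index[kmer].push_back(j - k + 1);
  }
  if (index.empty()) return;

  std::vector<Candidate> cands;
  kmer = 0; valid = 0;
  for (int i = 0; i < tn; ++i) {
    int b = tcode[i];
    if (b == 4) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t)b) & mask;
    if (++valid < k) continue;
    std::unordered_map<uint32_t, std::vector<int> >::const_iterator it = index.find(kmer);
    if (it == index.end()) continue;
    int tp = i - k + 1;
    for (size_t s = 0; s < it->second.size(); ++s) {
      int cp = it->second[s];
      int diag = tp - cp;
      bool covered = false;
      for (size_t q = cands.size(); q-- > 0;) {
        const Candidate &cd = cands[q];
        if (cd.tend < tp - 2000) break; // candidates arrive in target order
        if (tp >= cd.tstart && tp + k <= cd.tend && std::abs(diag - cd.diag) <= 16) {
          covered = true; break;
        }
      }
      if (covered) continue;
      cands.push_back(xdrop_extend(tcode, ccode, tp, cp, k, match, mismatch, xdrop));
    }
  }
  if (cands.empty()) return;

  // merge candidate target intervals, then expand into refinement windows
  std::sort(cands.begin(), cands.end(),
            [](const Candidate &x, const Candidate &y) { return x.tstart < y.tstart; });
  int margin = std::min(cn, 1000);
  std::vector<std::pair<int, int> > windows;
  for (size_t q = 0; q < cands.size(); ++q) {
    int ws = std::max(0, cands[q].tstart - margin);
    int we = std::min(tn, cands[q].tend + margin);
    if (!windows.empty() && ws <= windows.back().second) {
      if (we > windows.back().second) windows.back().second = we;
    } else {
      windows.push_back(std::make_pair(ws, we));
    }
  }

  // Refinement per window: align, report, then recurse into the target
  // segments left and right of the reported region, so every copy inside a
  // window is recovered (not just the best-scoring one).
  for (size_t w = 0; w < windows.size(); ++w) {
    std::vector<std::pair<int, int> > stack;
    stack.push_back(windows[w]);
    int guard = 0;
    while (!stack.empty() && ++guard <= 256) {
      int ws = stack.back().first, we = stack.back().second;
      stack.pop_back();
      if (we - ws < min_len) continue;
      AlnResult r = sw_align(tseq.substr(ws, we - ws), cseq, match, mismatch,
                             gap_open, gap_extend);
      if (!r.ok || r.score < min_score) continue;
      int hstart = ws + r.a_start, hend = ws + r.a_end;
      if (hend - hstart >= min_len) {
        Hit h;
        h.target_idx = target_idx; h.cons_idx = cons_idx; h.strand = strand;
        h.start = hstart; h.end = hend;
        if (strand == '+') { h.cons_start = r.b_start; h.cons_end = r.b_end; }
        else { h.cons_start = clen_orig - r.b_end; h.cons_end = clen_orig - r.b_start; }
        h.score = r.score; h.matches = r.matches; h.ts = r.ts; h.tv = r.tv;
        h.ambig = r.ambig; h.gapcols = r.gapcols;
        hits.push_back(h);
      }
      stack.push_back(std::make_pair(ws, hstart));
      stack.push_back(std::make_pair(hend, we));
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_scan(CharacterVector t_ids, CharacterVector t_seqs,
                   CharacterVector c_names, CharacterVector c_seqs,
                   int k, int match, int mismatch, int gap_open, int gap_extend,
                   int xdrop, int min_score, int min_len, bool both_strands) {
  std::vector<Hit> hits;
  for (int ti = 0; ti < t_seqs.size(); ++ti) {
    std::string tseq = as<std::string>(t_seqs[ti]);
    std::vector<int> tcode(tseq.size());
    for (size_t i = 0; i < tseq.size(); ++i) tcode[i] = base_code(tseq[i]);
    for (int ci = 0; ci < c_seqs.size(); ++ci) {
      std::string cseq = as<std::string>(c_seqs[ci]);
      int clen = (int)cseq.size();
      scan_one(tseq, tcode, cseq, ti, ci, '+', clen, k, match, mismatch,
               gap_open, gap_extend, xdrop, min_score, min_len, hits);
      if (both_strands) {
        std::string rc = cpp_revcomp(cseq);
        scan_one(tseq, tcode, rc, ti, ci, '-', clen, k, match, mismatch,
                 gap_open, gap_extend, xdrop, min_score, min_len, hits);
      }
    }
  }
  const int n = (int)hits.size();
  CharacterVector seq_id(n), consensus_name(n), strand(n);
  IntegerVector start(n), end(n), cons_start(n), cons_end(n), score(n),
      matches(n), ts(n), tv(n), ambig(n), gapcols(n), aligned(n);
  for (int i = 0; i < n; ++i) {
    const Hit &h = hits[i];
    seq_id[i] = t_ids[h.target_idx];
    consensus_name[i] = c_names[h.cons_idx];
    strand[i] = std::string(1, h.strand);
    start[i] = h.start; end[i] = h.end;
    cons_start[i] = h.cons_start; cons_end[i] = h.cons_end;
    score[i] = h.score; matches[i] = h.matches; ts[i] = h.ts; tv[i] = h.tv;
    ambig[i] = h.ambig; gapcols[i] = h.gapcols;
    aligned[i] = h.matches + h.ts + h.tv + h.ambig;
  }
  return DataFrame::create(
      _["seq_id"] = seq_id, _["start"] = start, _["end"] = end,
      _["strand"] = strand, _["consensus_name"] = consensus_name,
      _["cons_start"] = cons_start, _["cons_end"] = cons_end,
      _["score"] = score, _["aligned_cols"] = aligned, _["matches"] = matches,
      _["transitions"] = ts, _["transversions"] = tv,
      _["ambiguous_cols"] = ambig, _["gap_cols"] = gapcols,
      _["stringsAsFactors"] = false);
}
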