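#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit base encoding; -1 for anything that is not ACGT
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}
static const char DEC[4] = {'A', 'C', 'G', 'T'};

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc(s[i]);
  return v;
}

static std::vector<int> revcomp(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int b = v[v.size() - 1 - i];
    r[i] = (b < 0) ? -1 : 3 - b;
  }
  return r;
}

typedef std::unordered_map<uint64_t, std::vector<int> > KmerIndex;

static KmerIndex index_kmers(const std::vector<int>& seq, int k, int max_bucket) {
  KmerIndex idx;
  if ((int)seq.size() < k) return idx;
  uint64_t word = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0; // length of current valid run
  for (size_t i = 0; i < seq.size(); ++i) {
    if (seq[i] < 0) { run = 0; word = 0; continue; }
    word = ((word << 2) | (uint64_t)seq[i]) & mask;
    if (++run >= k) {
      std::vector<int>& v = idx[word];
      if ((int)v.size() < max_bucket) v.push_back((int)(i + 1 - k));
    }
  }
  return idx;
}

struct Hit {
  int ref_start, ref_end, matches, aln_len;
  int q_start, q_end;   // aligned segment on the oriented query, half-open
  char strand;
  double identity;
};

// ungapped local comparison of query (oriented) against reference at
// diagonal d (query position 0 maps to reference position d).  The hit is
// trimmed to the best-scoring local segment (match +1, mismatch -2, maximum
// subarray), so unrelated flanks do not extend the alignment.
static Hit eval_diag(const std::vector<int>& q, const std::vector<int>& ref,
                     int d, char strand) {
  int qs = std::max(0, -d);
  int qe = std::min((int)q.size(), (int)ref.size() - d);
  Hit h; h.strand = strand;
  h.ref_start = h.ref_end = h.matches = h.aln_len = 0; h.identity = 0;
  h.q_start = h.q_end = 0;
  if (qe <= qs) return h;
  double run = 0, best = 0;
  int run_start = qs, best_s = qs, best_e = qs;
  for (int i = qs; i < qe; ++i) {
    bool match = q[i] >= 0 && q[i] == ref[i + d];
    double sc = match ? 1.0 : -2.0;
    if (run <= 0) { run = sc; run_start = i; }
    else run += sc;
    if (run > best) { best = run; best_s = run_start; best_e = i + 1; }
  }
  if (best <= 0) return h;
  int m = 0;
  for (int i = best_s; i < best_e; ++i)
    if (q[i] >= 0 && q[i] == ref[i + d]) ++m;
  h.ref_start = best_s + d; h.ref_end = best_e + d;
  h.q_start = best_s; h.q_end = best_e;
  h.matches = m; h.aln_len = best_e - best_s;
  h.identity = 100.0 * m / h.aln_len;
  return h;
}

// Seed-and-extend ungapped mapping of queries onto one reference sequence.
// Returns, per query, the best hit (max matches; ties broken by leftmost
// reference start, then by + strand), or all sufficiently good
// non-redundant hits when max_hits > 1.
// [[Rcpp::export]]
DataFrame cpp_seed_map(CharacterVector queries, std::string reference,
                       int k = 15, double min_identity = 0.0,
                       double min_frac = 0.0, int max_hits = 1,
                       int max_bucket = 2000) {
  std::vector<int> ref = encode(reference);
  KmerIndex idx = index_kmers(ref, k, max_bucket);

  std::vector<int> o_query, o_rs, o_re, o_matches, o_aln, o_qs, o_qe;
  std::vector<double> o_ident, o_frac;
  std::vector<char> o_strand;

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string qs = as<std::string>(queries[qi]);
    std::vector<int> qf = encode(qs), qr = revcomp(qf);
    int qlen = (int)qf.size();
    std::vector<Hit> cands;
    for (int ori = 0; ori < 2; ++ori) {
      const std::vector<int>& q = ori == 0 ? qf : qr;
      char strand = ori == 0 ? '+' : '-';
      if (qlen < k) continue;
      // vote diagonals by shared k-mers
      std::unordered_map<int, int> votes;
      uint64_t word = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
      int run = 0;
      for (int i = 0; i < qlen; ++i) {
        if (q[i] < 0) { run = 0; word = 0; continue; }
        word = ((word << 2) | (uint64_t)q[i]) & mask;
        if (++run >= k) {
          KmerIndex::const_iterator it = idx.find(word);
          if (it != idx.end())
            for (size_t p = 0; p < it->second.size(); ++p)
              votes[it->second[p] - (i + 1 - k)]++;
        }
      }
      for (std::unordered_map<int, int>::iterator it = votes.begin();
           it != votes.end(); ++it) {
        Hit h = eval_diag(q, ref, it->first, strand);
        if (h.aln_len == 0) continue;
        if (h.identity >= min_identity && (double)h.aln_len / qlen >= min_frac)
          cands.push_back(h);
      }
    }
    if (cands.empty()) continue;
    // order: best matches first, then leftmost, then + strand
    std::sort(cands.begin(), cands.end(), [](const Hit& a, const Hit& b) {
      if (a.matches != b.matches) return a.matches > b.matches;
      if (a.ref_start != b.ref_start) return a.ref_start < b.ref_start;
      return a.strand < b.strand;
    });
    int kept = 0;
    std::vector<std::pair<int,int> > claimed;
    for (size_t c = 0; c < cands.size() && kept < max_hits; ++c) {
      bool overlap = false;
      for (size_t j = 0; j < claimed.size(); ++j)
        if (cands[c].ref_start < claimed[j].second &&
            claimed[j].first < cands[c].ref_end) { overlap = true; break; }
      if (overlap) continue;
      claimed.push_back(std::make_pair(cands[c].ref_start, cands[c].ref_end));
      o_query.push_back(qi + 1);
      o_rs.push_back(cands[c].ref_start); o_re.push_back(cands[c].ref_end);
      o_qs.push_back(cands[c].q_start); o_qe.push_back(cands[c].q_end);
      o_matches.push_back(cands[c].matches); o_aln.push_back(cands[c].aln_len);
      o_ident.push_back(cands[c].identity);
      o_frac.push_back((double)cands[c].aln_len / qlen);
      o_strand.push_back(cands[c].strand);
      ++kept;
    }
  }
  CharacterVector strand(o_strand.size());
  for (size_t i = 0; i < o_strand.size(); ++i)
    strand[i] = std::string(1, o_strand[i]);
  return DataFrame::create(
    _["query"] = wrap(o_query), _["ref_start"] = wrap(o_rs),
    _["ref_end"] = wrap(o_re), _["q_start"] = wrap(o_qs),
    _["q_end"] = wrap(o_qe), _["strand"] = strand,
    _["matches"] = wrap(o_matches), _["aln_len"] = wrap(o_aln),
    _["identity"] = wrap(o_ident), _["aln_frac"] = wrap(o_frac),
    _["stringsAsFactors"] = false);
}

// Spaced-seed anchor finding between two genomes.  pattern is a string of
// '1'/'0'; positions with '1' participate in the masked word.  Hits sharing
// a diagonal and overlapping are merged into maximal anchors; anchor score
// is the number of matching bases over the merged span.
// [[Rcpp::export]]
DataFrame cpp_spaced_anchors(std::string a, std::string b, std::string pattern,
                             int max_bucket = 50) {
  int L = (int)pattern.size();
  std::vector<int> care;
  for (int i = 0; i < L; ++i) if (pattern[i] == '1') care.push_back(i);
  std::vector<int> A = encode(a), B = encode(b);
  int lenA = (int)A.size(), lenB = (int)B.size();

  // masked words of A
  std::unordered_map<uint64_t, std::vector<int> > idx;
  for (int i = 0; i + L <= lenA; ++i) {
    uint64_t w = 0; bool ok = true;
    for (size_t c = 0; c < care.size(); ++c) {
      int bse = A[i + care[c]];
      if (bse < 0) { ok = false; break; }
      w = (w << 2) | (uint64_t)bse;
    }
    if (!ok) continue;
    std::vector<int>& v = idx[w];
    if ((int)v.size() < max_bucket) v.push_back(i);
  }

  // raw hits: (strand, diag, apos); bpos implied by diag.  For '-' hits the
  // b position is in reverse-complement coordinates.
  struct Raw { int apos, bpos; char strand; };
  std::vector<Raw> hits;
  std::vector<int> Brc = revcomp(B);
  for (int ori = 0; ori < 2; ++ori) {
    const std::vector<int>& bb = ori == 0 ? B : Brc;
    char strand = ori == 0 ? '+' : '-';
    for (int j = 0; j + L <= lenB; ++j) {
      uint64_t w = 0; bool ok = true;
      for (size_t c = 0; c < care.size(); ++c) {
        int bse = bb[j + care[c]];
        if (bse < 0) { ok = false; break; }
        w = (w << 2) | (uint64_t)bse;
      }
      if (!ok) continue;
      std::unordered_map<uint64_t, std::vector<int> >::const_iterator it = idx.find(w);
      if (it == idx.end()) continue;
      for (size_t p = 0; p < it->second.size(); ++p) {
        Raw r; r.apos = it->second[p]; r.bpos = j; r.strand = strand;
        hits.push_back(r);
      }
    }
  }
  // merge overlapping same-diagonal hits
  std::sort(hits.begin(), hits.end(), [](const Raw& x, const Raw& y) {
    if (x.strand != y.strand) return x.strand < y.strand;
    int dx = x.apos - x.bpos, dy = y.apos - y.bpos;
    if (dx != dy) return dx < dy;
    return x.apos < y.apos;
  });
  std::vector<int> o_as, o_ae, o_bs, o_be, o_score;
  std::vector<char> o_strand;
  size_t i = 0;
  while (i < hits.size()) {
    size_t j = i;
    int a0 = hits[i].apos, a1 = hits[i].apos;
    while (j + 1 < hits.size() && hits[j + 1].strand == hits[i].strand &&
           hits[j + 1].apos - hits[j + 1].bpos == hits[i].apos - hits[i].bpos &&
           hits[j + 1].apos <= a1 + L) {
      ++j; a1 = hits[j].apos;
    }
    int b0 = hits[i].bpos;
    int as = a0, ae = a1 + L;          // half-open on A
    int span = ae - as;
    // score: matching bases over the merged span
    const std::vector<int>& bb = hits[i].strand == '+' ? B : Brc;
    int m = 0;
    for (int t = 0; t < span; ++t)
      if (A[as + t] >= 0 && A[as + t] == bb[b0 + t]) ++m;
    int bs, be;
    if (hits[i].strand == '+') { bs = b0; be = b0 + span; }
    else { bs = lenB - (b0 + span); be = lenB - b0; }
    o_as.push_back(as); o_ae.push_back(ae);
    o_bs.push_back(bs); o_be.push_back(be);
    o_score.push_back(m); o_strand.push_back(hits[i].strand);
    i = j + 1;
  }
  CharacterVector strand(o_strand.size());
  for (size_t t = 0; t < o_strand.size(); ++t)
    strand[t] = std::string(1, o_strand[t]);
  return DataFrame::create(
    _["a_start"] = wrap(o_as), _["a_end"] = wrap(o_ae),
    _["b_start"] = wrap(o_bs), _["b_end"] = wrap(o_be),
    _["strand"] = strand, _["score"] = wrap(o_score),
    _["stringsAsFactors"] = false);
}

// Best collinear chain of anchors (all of one strand) under an affine gap
// penalty: chain score = sum(anchor scores) minus, per consecutive pair,
// gap_open + gap_ext * max(gapA, gapB) + indel_ext * |gapA - gapB|.
// The |gapA - gapB| term prices diagonal drift (insertions/deletions), so
// off-diagonal repeat-copy anchors are not absorbed into collinear chains.
// Gaps > max_gap forbidden; anchors strictly ordered on both genomes
// (increasing on B for '+', decreasing for '-').
// Returns 1-based indices of the best chain in order, plus its score.
// [[Rcpp::export]]
List cpp_chain_best(IntegerVector a_start, IntegerVector a_end,
                    IntegerVector b_start, IntegerVector b_end,
                    NumericVector score, bool minus_strand,
                    double max_gap = 20000, double gap_open = 30,
                    double gap_ext = 0.01, double indel_ext = 0.5) {
  int n = a_start.size();
  if (n == 0) return List::create(_["chain"] = IntegerVector(0), _["score"] = 0.0);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int x, int y) {
    if (a_start[x] != a_start[y]) return a_start[x] < a_start[y];
    return a_end[x] < a_end[y];
  });
  std::vector<double> dp(n);
  std::vector<int> back(n, -1);
  double best = -1e18; int besti = -1;
  for (int oi = 0; oi < n; ++oi) {
    int i = ord[oi];
    dp[i] = score[i];
    for (int oj = 0; oj < oi; ++oj) {
      int j = ord[oj];
      if (a_end[j] > a_start[i]) continue;
      double ga = a_start[i] - a_end[j], gb;
      if (!minus_strand) {
        if (b_end[j] > b_start[i]) continue;
        gb = b_start[i] - b_end[j];
      } else {
        if (b_end[i] > b_start[j]) continue;
        gb = b_start[j] - b_end[i];
      }
      double gap = std::max(ga, gb);
      if (gap > max_gap) continue;
      double cand = dp[j] + score[i] -
        (gap_open + gap_ext * gap + indel_ext * std::abs(ga - gb));
      if (cand > dp[i]) { dp[i] = cand; back[i] = j; }
    }
    if (dp[i] > best) { best = dp[i]; besti = i; }
  }
  std::vector<int> chain;
  for (int c = besti; c >= 0; c = back[c]) chain.push_back(c + 1);
  std::reverse(chain.begin(), chain.end());
  return List::create(_["chain"] = wrap(chain), _["score"] = best);
}

// All-pairs read overlap detection (both orientations) with a shared-k-mer
// prefilter.  An edge is reported when the best ungapped overlap between two
// reads spans >= min_frac * min(lengths) and has identity >= min_identity (%).
// [[Rcpp::export]]
DataFrame cpp_overlap_edges(CharacterVector reads, double min_frac = 0.40,
                            double min_identity = 80.0, int k = 12,
                            int max_bucket = 2000) {
  int n = reads.size();
  std::vector<std::vector<int> > seqs(n);
  for (int i = 0; i < n; ++i) seqs[i] = encode(as<std::string>(reads[i]));

  // k-mer -> (read, pos) over forward reads
  std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > idx;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int i = 0; i < n; ++i) {
    uint64_t w = 0; int run = 0;
    for (size_t p = 0; p < seqs[i].size(); ++p) {
      if (seqs[i][p] < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)seqs[i][p]) & mask;
      if (++run >= k) {
        std::vector<std::pair<int,int> >& v = idx[w];
        if ((int)v.size() < max_bucket)
          v.push_back(std::make_pair(i, (int)(p + 1 - k)));
      }
    }
  }
  std::vector<int> o_i, o_j, o_olen;
  std::vector<double> o_ident;
  std::vector<char> o_orient;
  for (int i = 0; i < n; ++i) {
    std::vector<int> fwd = seqs[i], rc = revcomp(seqs[i]);
    // candidate (j, orient, diag) votes; j > i only
    std::map<std::tuple<int,int,int>, int> votes;
    for (int ori = 0; ori < 2; ++ori) {
      const std::vector<int>& q = ori == 0 ? fwd : rc;
      uint64_t w = 0; int run = 0;
      for (size_t p = 0; p < q.size(); ++p) {
        if (q[p] < 0) { run = 0; w = 0; continue; }
        w = ((w << 2) | (uint64_t)q[p]) & mask;
        if (++run >= k) {
          std::unordered_map<uint64_t, std::vector<std::pair<int,int> > >::const_iterator
            it = idx.find(w);
          if (it == idx.end()) continue;
          for (size_t h = 0; h < it->second.size(); ++h) {
            int j = it->second[h].first;
            if (j <= i) continue;
            int diag = it->second[h].second - (int)(p + 1 - k);
            votes[std::make_tuple(j, ori, diag)]++;
          }
        }
      }
    }
    // best overlap per neighbour j
    std::map<int, std::tuple<int,double,char> > bestj; // j -> (olen, ident, orient)
    for (std::map<std::tuple<int,int,int>, int>::iterator it = votes.begin();
         it != votes.end(); ++it) {
      int j = std::get<0>(it->first), ori = std::get<1>(it->first),
          d = std::get<2>(it->first);
      const std::vector<int>& q = ori == 0 ? fwd : rc;
      // q position p aligns to read j position p + d
      int qs = std::max(0, -d);
      int qe = std::min((int)q.size(), (int)seqs[j].size() - d);
      if (qe <= qs) continue;
      int m = 0;
      for (int p = qs; p < qe; ++p)
        if (q[p] >= 0 && q[p] == seqs[j][p + d]) ++m;
      int olen = qe - qs;
      double ident = 100.0 * m / olen;
      int minlen = std::min((int)q.size(), (int)seqs[j].size());
      if (olen < min_frac * minlen || ident < min_identity) continue;
      std::map<int, std::tuple<int,double,char> >::iterator bj = bestj.find(j);
      if (bj == bestj.end() || m > std::get<0>(bj->second) * std::get<1>(bj->second) / 100.0)
        bestj[j] = std::make_tuple(olen, ident, ori == 0 ? '+' : '-');
    }
    for (std::map<int, std::tuple<int,double,char> >::iterator it = bestj.begin();
         it != bestj.end(); ++it) {
      o_i.push_back(i + 1); o_j.push_back(it->first + 1);
      o_olen.push_back(std::get<0>(it->second));
      o_ident.push_back(std::get<1>(it->second));
      o_orient.push_back(std::get<2>(it->second));
    }
  }
  CharacterVector orient(o_orient.size());
  for (size_t t = 0; t < o_orient.size(); ++t)
    orient[t] = std::string(1, o_orient[t]);
  return DataFrame::create(
    _["from"] = wrap(o_i), _["to"] = wrap(o_j),
    _["overlap_length"] = wrap(o_olen), _["identity"] = wrap(o_ident),
    _["orient"] = orient, _["stringsAsFactors"] = false);
}
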