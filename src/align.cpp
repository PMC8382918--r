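#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// 2-bit DNA encoding; -1 for anything that is not A/C/G/T
static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
  return r;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    out[i] = revcomp_str(std::string(seqs[i]));
  }
  out.attr("names") = seqs.attr("names");
  return out;
}

// k-mer index of a target sequence: word -> start positions (0-based).
// Words containing non-ACGT characters are not indexed.
static void index_words(const std::string& t, int w,
                        std::unordered_map<uint64_t, std::vector<int> >& idx) {
  if ((int)t.size() < w) return;
  uint64_t word = 0, mask = (w >= 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  int run = 0;  // number of consecutive valid bases ending here
  for (int i = 0; i < (int)t.size(); ++i) {
    int b = base2bit(t[i]);
    if (b < 0) { run = 0; word = 0; continue; }
    word = ((word << 2) | (uint64_t)b) & mask;
    if (++run >= w) idx[word].push_back(i - w + 1);
  }
}

struct Hsp {
  int q_start, q_end, t_start, t_end;  // 0-based inclusive, strand of qseq used
  int matches, len, score;
  char strand;
};

// Ungapped x-drop extension of an exact seed [qpos, qpos+w) == [tpos, tpos+w).
// If trim, the HSP is cut back to the score-maximal endpoints; otherwise it
// spans the full extended region (terminal mismatches retained).
static Hsp extend_seed(const std::string& q, const std::string& t,
                       int qpos, int tpos, int w,
                       int match, int mismatch, int xdrop, bool trim) {
  int qlen = q.size(), tlen = t.size();
  // right extension
  int cur = 0, best = 0;
  int i = qpos + w, j = tpos + w;
  int best_i = i, ext_i = i;  // one past last included column
  while (i < qlen && j < tlen) {
    cur += (q[i] == t[j] && base2bit(q[i]) >= 0) ? match : mismatch;
    ++i; ++j;
    if (cur > best) { best = cur; best_i = i; }
    if (cur < best - xdrop) break;
    ext_i = i;
  }
  int right_end = trim ? best_i : ext_i;
  // left extension
  cur = 0; best = 0;
  i = qpos - 1; j = tpos - 1;
  int best_l = qpos, ext_l = qpos;  // first included column
  while (i >= 0 && j >= 0) {
    cur += (q[i] == t[j] && base2bit(q[i]) >= 0) ? match : mismatch;
    if (cur > best) { best = cur; best_l = i; }
    if (cur < best - xdrop) break;
    ext_l = i;
    --i; --j;
  }
  int left_start = trim ? best_l : ext_l;

  Hsp h;
  h.q_start = left_start;
  h.q_end = right_end - 1;
  h.t_start = tpos - (qpos - left_start);
  h.t_end = h.t_start + (h.q_end - h.q_start);
  h.len = h.q_end - h.q_start + 1;
  int m = 0;
  for (int p = 0; p < h.len; ++p) {
    char a = q[h.q_start + p], b = t[h.t_start + p];
    if (a == b && base2bit(a) >= 0) ++m;
  }
  h.matches = m;
  h.score = m * match + (h.len - m) * mismatch;
  h.strand = '+';
  return h;
}

// Seed-and-extend ungapped local alignment of each query (both strands)
// against one target. Returns all HSPs; filtering/selection is done in R.
// exclude_self: skip the trivial q==t main diagonal (for self-comparison).
// [[Rcpp::export(name = ".local_align_cpp")]]
DataFrame local_align_cpp(CharacterVector query_ids, CharacterVector query_seqs,
                          std::string target_seq,
                          int word_size, int match, int mismatch,
                          int xdrop, bool trim, bool exclude_self) {
  std::unordered_map<uint64_t, std::vector<int> > idx;
  index_words(target_seq, word_size, idx);

  std::vector<std::string> out_qid;
  std::vector<int> o_qs, o_qe, o_ts, o_te, o_len, o_mm, o_score;
  std::vector<std::string> o_strand;
  std::vector<double> o_pid;

  for (R_xlen_t qi = 0; qi < query_seqs.size(); ++qi) {
    std::string qfwd = std::string(query_seqs[qi]);
    std::string qid = std::string(query_ids[qi]);
    int qlen = qfwd.size();
    for (int s = 0; s < 2; ++s) {
      std::string q = (s == 0) ? qfwd : revcomp_str(qfwd);
      char strand = (s == 0) ? '+' : '-';
      if (qlen < word_size) continue;
      // per-diagonal extent already covered, to avoid redundant extensions
      std::unordered_map<long long, int> covered;
      uint64_t word = 0, mask = (word_size >= 32) ? ~0ULL
        : ((1ULL << (2 * word_size)) - 1);
      int run = 0;
      for (int qp = 0; qp < qlen; ++qp) {
        int b = base2bit(q[qp]);
        if (b < 0) { run = 0; word = 0; continue; }
        word = ((word << 2) | (uint64_t)b) & mask;
        if (++run < word_size) continue;
        int qpos = qp - word_size + 1;
        std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
          idx.find(word);
        if (it == idx.end()) continue;
        for (size_t pi = 0; pi < it->second.size(); ++pi) {
          int tpos = it->second[pi];
          long long diag = (long long)tpos - qpos;
          if (exclude_self && strand == '+' && diag == 0 &&
              qfwd == target_seq) continue;
          std::unordered_map<long long, int>::iterator cv = covered.find(diag);
          if (cv != covered.end() && qpos <= cv->second) continue;
          Hsp h = extend_seed(q, target_seq, qpos, tpos, word_size,
                              match, mismatch, xdrop, trim);
          covered[diag] = h.q_end;
          h.strand = strand;
          // map query coordinates back to the forward orientation
          int oqs = h.q_start, oqe = h.q_end;
          if (strand == '-') {
            oqs = qlen - 1 - h.q_end;
            oqe = qlen - 1 - h.q_start;
          }
          out_qid.push_back(qid);
          o_qs.push_back(oqs + 1);
          o_qe.push_back(oqe + 1);
          o_ts.push_back(h.t_start + 1);
          o_te.push_back(h.t_end + 1);
          o_len.push_back(h.len);
          o_mm.push_back(h.len - h.matches);
          o_score.push_back(h.score);
          o_strand.push_back(std::string(1, strand));
          o_pid.push_back(100.0 * h.matches / h.len);
        }
      }
    }
  }

  return DataFrame::create(
    _["query_id"] = out_qid,
    _["pct_identity"] = o_pid,
    _["aln_len"] = o_len,
    _["mismatches"] = o_mm,
    _["q_start"] = o_qs,
    _["q_end"] = o_qe,
    _["t_start"] = o_ts,
    _["t_end"] = o_te,
    _["score"] = o_score,
    _["strand"] = o_strand,
    _["stringsAsFactors"] = false);
}

// End-to-end placement of fixed-length reads on a target with at most k
// mismatches (both strands, all qualifying placements). Uses the pigeonhole
// principle: a read with <= k mismatches has at least one exact chunk among
// k+1 non-overlapping chunks, so candidate diagonals come from an exact
// chunk-index lookup and are then verified over the full read length.
// [[Rcpp::export(name = ".map_kmismatch_cpp")]]
DataFrame map_kmismatch_cpp(CharacterVector read_ids, CharacterVector read_seqs,
                            std::string target_seq, int k) {
  int tlen = target_seq.size();
  std::vector<std::string> out_rid, o_strand;
  std::vector<int> o_ts, o_te, o_mm, o_len;
  std::vector<double> o_pid;

  // chunk size from the shortest read; all reads are typically equal length
  int minlen = INT_MAX;
  for (R_xlen_t i = 0; i < read_seqs.size(); ++i)
    minlen = std::min(minlen, (int)std::string(read_seqs[i]).size());
  if (read_seqs.size() == 0 || tlen == 0) {
    return DataFrame::create(_["query_id"] = out_rid,
                             _["pct_identity"] = o_pid,
                             _["aln_len"] = o_len,
                             _["mismatches"] = o_mm,
                             _["t_start"] = o_ts, _["t_end"] = o_te,
                             _["strand"] = o_strand,
                             _["stringsAsFactors"] = false);
  }
  int chunk = minlen / (k + 1);
  bool use_index = chunk >= 6 && chunk <= 31;

  std::unordered_map<uint64_t, std::vector<int> > idx;
  if (use_index) index_words(target_seq, chunk, idx);

  for (R_xlen_t ri = 0; ri < read_seqs.size(); ++ri) {
    std::string rfwd = std::string(read_seqs[ri]);
    std::string rid = std::string(read_ids[ri]);
    int L = rfwd.size();
    if (L > tlen) continue;
    for (int s = 0; s < 2; ++s) {
      std::string r = (s == 0) ? rfwd : revcomp_str(rfwd);
      char strand = (s == 0) ? '+' : '-';
      std::vector<int> cand;
      if (use_index) {
        for (int c = 0; c + chunk <= L && c < (k + 1) * chunk; c += chunk) {
          uint64_t word = 0;
          bool ok = true;
          for (int p = 0; p < chunk; ++p) {
            int b = base2bit(r[c + p]);
            if (b < 0) { ok = false; break; }
            word = (word << 2) | (uint64_t)b;
          }
          if (!ok) continue;
          std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
            idx.find(word);
          if (it == idx.end()) continue;
          for (size_t pi = 0; pi < it->second.size(); ++pi) {
            int start = it->second[pi] - c;
            if (start >= 0 && start + L <= tlen) cand.push_back(start);
          }
        }
        std::sort(cand.begin(), cand.end());
        cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      } else {
        for (int start = 0; start + L <= tlen; ++start) cand.push_back(start);
      }
      for (size_t ci = 0; ci < cand.size(); ++ci) {
        int start = cand[ci];
        int mm = 0;
        for (int p = 0; p < L; ++p) {
          char a = r[p], b = target_seq[start + p];
          if (a != b || base2bit(a) < 0) { if (++mm > k) break; }
        }
        if (mm > k) continue;
        out_rid.push_back(rid);
        o_pid.push_back(100.0 * (L - mm) / L);
        o_len.push_back(L);
        o_mm.push_back(mm);
        o_ts.push_back(start + 1);
        o_te.push_back(start + L);
        o_strand.push_back(std::string(1, strand));
      }
    }
  }

  return DataFrame::create(
    _["query_id"] = out_rid,
    _["pct_identity"] = o_pid,
    _["aln_len"] = o_len,
    _["mismatches"] = o_mm,
    _["t_start"] = o_ts,
    _["t_end"] = o_te,
    _["strand"] = o_strand,
    _["stringsAsFactors"] = false);
}
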