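#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; 4 = N / other
static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
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

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
NumericMatrix gc_counts_cpp(CharacterVector seqs) {
  int n = seqs.size();
  NumericMatrix out(2, n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    double gc = 0, acgt = 0;
    for (char c : s) {
      int b = base_code(c);
      if (b < 4) { acgt++; if (b == 1 || b == 2) gc++; }
    }
    out(0, i) = gc; out(1, i) = acgt;
  }
  return out;
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > KmerIndex;

static void index_kmers(const std::vector<std::string>& seqs, int k,
                        KmerIndex& idx) {
  for (size_t s = 0; s < seqs.size(); ++s) {
    const std::string& seq = seqs[s];
    int L = (int)seq.size();
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0;  // valid bases accumulated
    for (int i = 0; i < L; ++i) {
      int b = base_code(seq[i]);
      if (b == 4) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) idx[key].push_back(std::make_pair((int)s, i - k + 1));
    }
  }
}

// Ungapped seed-and-extend end-to-end mapper. Reads are placed at the single
// best location whose full-length identity exceeds min_identity; ties broken
// by fewest mismatches, then lexicographically smallest contig id, then
// smallest start, then forward strand.
// [[Rcpp::export]]
DataFrame map_reads_cpp(CharacterVector read_ids, CharacterVector read_seqs,
                        CharacterVector contig_ids, CharacterVector contig_seqs,
                        double min_identity = 0.96, int seed_k = 15,
                        int seed_step = 8) {
  int nc = contig_ids.size(), nr = read_ids.size();
  std::vector<std::string> contigs(nc), cids(nc);
  for (int i = 0; i < nc; ++i) {
    contigs[i] = as<std::string>(contig_seqs[i]);
    cids[i] = as<std::string>(contig_ids[i]);
  }
  KmerIndex idx;
  index_kmers(contigs, seed_k, idx);

  std::vector<std::string> o_read, o_contig, o_strand;
  std::vector<int> o_start, o_end, o_mm;
  std::vector<double> o_ident;

  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(read_seqs[r]);
    int len = (int)fwd.size();
    if (len < seed_k) continue;
    int mm_cap = (int)std::floor(len * (1.0 - min_identity) - 1e-9);
    if (mm_cap < 0) continue;
    int best_mm = mm_cap + 1, best_c = -1, best_start = -1;
    char best_strand = '+';
    for (int strand = 0; strand < 2; ++strand) {
      std::string s = strand == 0 ? fwd : revcomp_str(fwd);
      std::unordered_set<int64_t> seen;
      for (int off = 0; off <= len - seed_k;
           off = (off == len - seed_k) ? len : std::min(off + seed_step, len - seed_k)) {
        uint64_t key = 0; bool ok = true;
        for (int j = 0; j < seed_k; ++j) {
          int b = base_code(s[off + j]);
          if (b == 4) { ok = false; break; }
          key = (key << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        KmerIndex::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        for (size_t h = 0; h < it->second.size(); ++h) {
          int ci = it->second[h].first;
          int diag = it->second[h].second - off;  // candidate start on contig
          if (diag < 0 || diag + len > (int)contigs[ci].size()) continue;
          int64_t sig = ((int64_t)ci << 33) | ((int64_t)(diag) << 1) | strand;
          if (!seen.insert(sig).second) continue;
          const std::string& ctg = contigs[ci];
          int mm = 0;
          for (int j = 0; j < len; ++j) {
            int a = base_code(s[j]), b = base_code(ctg[diag + j]);
            if (a != b || a == 4) { if (++mm > mm_cap) break; }
          }
          if (mm > mm_cap) continue;
          bool better = false;
          if (mm < best_mm) better = true;
          else if (mm == best_mm && best_c >= 0) {
            if (cids[ci] < cids[best_c]) better = true;
            else if (cids[ci] == cids[best_c]) {
              if (diag < best_start) better = true;
              else if (diag == best_start && strand == 0 && best_strand == '-')
                better = true;
            }
          }
          if (better) {
            best_mm = mm; best_c = ci; best_start = diag;
            best_strand = strand == 0 ? '+' : '-';
          }
        }
      }
    }
    if (best_c >= 0) {
      o_read.push_back(as<std::string>(read_ids[r]));
      o_contig.push_back(cids[best_c]);
      o_start.push_back(best_start);
      o_end.push_back(best_start + len);
      o_strand.push_back(std::string(1, best_strand));
      o_mm.push_back(best_mm);
      o_ident.push_back((double)(len - best_mm) / (double)len);
    }
  }
  return DataFrame::create(
    _["read_id"] = wrap(o_read), _["contig_id"] = wrap(o_contig),
    _["start"] = wrap(o_start), _["end"] = wrap(o_end),
    _["strand"] = wrap(o_strand), _["mismatches"] = wrap(o_mm),
    _["indels"] = IntegerVector(o_read.size(), 0),
    _["identity"] = wrap(o_ident), _["stringsAsFactors"] = false);
}

// For each read, the furthest-right end of any match of the query substrings
// within the first `window` bases, allowing up to `max_err` mismatches.
// [[Rcpp::export]]
IntegerVector trim_scan_cpp(CharacterVector read_seqs, CharacterVector subs,
                            int window = 50, int max_err = 1) {
  int nr = read_seqs.size(), ns = subs.size();
  std::vector<std::string> qs(ns);
  for (int i = 0; i < ns; ++i) qs[i] = as<std::string>(subs[i]);
  IntegerVector out(nr);
  for (int r = 0; r < nr; ++r) {
    std::string s = as<std::string>(read_seqs[r]);
    int len = (int)s.size(), best = 0;
    for (int q = 0; q < ns; ++q) {
      int m = (int)qs[q].size();
      int last_start = std::min(window, len) - m;
      for (int st = 0; st <= last_start; ++st) {
        int mm = 0;
        for (int j = 0; j < m; ++j) {
          int a = base_code(s[st + j]), b = base_code(qs[q][j]);
          if (a != b || a == 4) { if (++mm > max_err) break; }
        }
        if (mm <= max_err && st + m > best) best = st + m;
      }
    }
    out[r] = best;
  }
  return out;
}

// Semi-global DP: align prefixes x[0..i) against y with free leading gap in
// y and the alignment forced to end at y's last column. Returns, for each
// prefix length i, the mismatch and indel counts of the path minimising
// (mm + ind, ind). Used for junction-read circularity arms.
static void arm_dp(const std::string& x, const std::string& y,
                   std::vector<int>& mm_out, std::vector<int>& ind_out) {
  int m = (int)x.size(), n = (int)y.size();
  const int INF = 1 << 20;
  std::vector<int> mm_prev(n + 1, 0), ind_prev(n + 1, 0);
  std::vector<int> mm_cur(n + 1), ind_cur(n + 1);
  mm_out.assign(m + 1, INF); ind_out.assign(m + 1, INF);
  mm_out[0] = 0; ind_out[0] = 0;  // empty prefix "ends" at y end trivially
  for (int i = 1; i <= m; ++i) {
    mm_cur[0] = 0; ind_cur[0] = i;  // x chars consumed before y: indels
    for (int j = 1; j <= n; ++j) {
      int a = base_code(x[i - 1]), b = base_code(y[j - 1]);
      int sub = (a != b || a == 4) ? 1 : 0;
      // diagonal
      int bm = mm_prev[j - 1] + sub, bi = ind_prev[j - 1];
      // up: consume x char (indel)
      int um = mm_prev[j], ui = ind_prev[j] + 1;
      if (um + ui < bm + bi || (um + ui == bm + bi && ui < bi)) { bm = um; bi = ui; }
      // left: consume y char (indel)
      int lm = mm_cur[j - 1], li = ind_cur[j - 1] + 1;
      if (lm + li < bm + bi || (lm + li == bm + bi && li < bi)) { bm = lm; bi = li; }
      mm_cur[j] = bm; ind_cur[j] = bi;
    }
    mm_out[i] = mm_cur[n]; ind_out[i] = ind_cur[n];
    mm_prev.swap(mm_cur); ind_prev.swap(ind_cur);
  }
}

static bool has_shared_kmer(const std::string& read, const std::string& seg,
                            int k) {
  std::unordered_set<uint64_t> kms;
  uint64_t key = 0, mask = (1ULL << (2 * k)) - 1;
  int run = 0;
  for (size_t i = 0; i < seg.size(); ++i) {
    int b = base_code(seg[i]);
    if (b == 4) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++run >= k) kms.insert(key);
  }
  key = 0; run = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    int b = base_code(read[i]);
    if (b == 4) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++run >= k && kms.count(key)) return true;
  }
  return false;
}

// Junction-read support for contig circularity. A read supports circularity
// when it splits into a prefix arm aligning to the contig's 3' terminus and
// a suffix arm aligning from the 5' terminus, each arm >= min_overlap read
// bases with at most max_mm mismatches and max_ind indels (unit-cost edit
// alignment). Both read orientations are tried.
// [[Rcpp::export]]
DataFrame circ_support_cpp(CharacterVector read_seqs, std::string contig,
                           int min_overlap = 60, int max_mm = 3,
                           int max_ind = 2, int end_segment = 1000,
                           int prescreen_k = 16) {
  int L = (int)contig.size();
  int seg = std::min(end_segment, L / 2);
  std::string s_start = contig.substr(0, seg);
  std::string s_end = contig.substr(L - seg);
  std::string s_start_rc = revcomp_str(s_start);  // for prescreen only
  std::string s_end_rc = revcomp_str(s_end);
  int nr = read_seqs.size();
  std::vector<int> sup(nr, 0), split(nr, NA_INTEGER);
  std::vector<std::string> orient(nr, "");
  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(read_seqs[r]);
    int m = (int)fwd.size();
    if (m < 2 * min_overlap) continue;
    bool cand = (has_shared_kmer(fwd, s_start, prescreen_k) &&
                 has_shared_kmer(fwd, s_end, prescreen_k)) ||
                (has_shared_kmer(fwd, s_start_rc, prescreen_k) &&
                 has_shared_kmer(fwd, s_end_rc, prescreen_k));
    if (!cand) continue;
    for (int o = 0; o < 2 && !sup[r]; ++o) {
      std::string x = o == 0 ? fwd : revcomp_str(fwd);
      std::string xr(x.rbegin(), x.rend());
      std::vector<int> mm1, in1, mm2, in2;
      // arm 1 (read prefix -> contig 3' terminus): prefixes of x ending at
      // s_end's last column, free leading gap in s_end.
      arm_dp(x, s_end, mm1, in1);
      // arm 2 (read suffix -> contig 5' terminus): reverse both; prefixes
      // of the reversed read are read suffixes, and ending at reversed
      // s_start's last column pins the alignment to contig position 0.
      arm_dp(xr, std::string(s_start.rbegin(), s_start.rend()), mm2, in2);
      for (int i = min_overlap; i <= m - min_overlap && !sup[r]; ++i) {
        int j = m - i;  // suffix length
        if (mm1[i] <= max_mm && in1[i] <= max_ind &&
            mm2[j] <= max_mm && in2[j] <= max_ind) {
          sup[r] = 1; split[r] = i; orient[r] = o == 0 ? "+" : "-";
        }
      }
    }
  }
  return DataFrame::create(_["supports"] = wrap(sup), _["split"] = wrap(split),
                           _["orientation"] = wrap(orient),
                           _["stringsAsFactors"] = false);
}

// Ungapped local-homology predicate between read sets: a query is a hit if
// some target shares a seed whose diagonal extension contains a stretch of
// >= min_len aligned bases at >= min_ident identity (identity computed over
// the whole diagonal overlap). Self-pairs (same id) are ignored.
// [[Rcpp::export]]
LogicalVector share_hits_cpp(CharacterVector q_ids, CharacterVector q_seqs,
                             CharacterVector t_ids, CharacterVector t_seqs,
                             int min_len = 100, double min_ident = 0.9,
                             int seed_k = 16) {
  int nt = t_ids.size(), nq = q_ids.size();
  std::vector<std::string> targets(nt), tids(nt);
  for (int i = 0; i < nt; ++i) {
    targets[i] = as<std::string>(t_seqs[i]);
    tids[i] = as<std::string>(t_ids[i]);
  }
  KmerIndex idx;
  index_kmers(targets, seed_k, idx);
  LogicalVector out(nq, false);
  for (int r = 0; r < nq; ++r) {
    std::string qid = as<std::string>(q_ids[r]);
    std::string fwd = as<std::string>(q_seqs[r]);
    bool hit = false;
    for (int strand = 0; strand < 2 && !hit; ++strand) {
      std::string s = strand == 0 ? fwd : revcomp_str(fwd);
      int len = (int)s.size();
      std::unordered_set<int64_t> seen;
      for (int off = 0; off + seed_k <= len && !hit; off += seed_k / 2) {
        uint64_t key = 0; bool ok = true;
        for (int j = 0; j < seed_k; ++j) {
          int b = base_code(s[off + j]);
          if (b == 4) { ok = false; break; }
          key = (key << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        KmerIndex::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        for (size_t h = 0; h < it->second.size() && !hit; ++h) {
          int ti = it->second[h].first;
          if (tids[ti] == qid) continue;
          int diag = it->second[h].second - off;  // t pos - q pos
          int64_t sig = ((int64_t)ti << 24) ^ (int64_t)(diag + (1 << 20));
          sig = (sig << 1) | strand;
          if (!seen.insert(sig).second) continue;
          const std::string& t = targets[ti];
          int lo = std::max(0, -diag);
          int hi = std::min(len, (int)t.size() - diag);
          int ov = hi - lo;
          if (ov < min_len) continue;
          int match = 0;
          for (int j = lo; j < hi; ++j) {
            int a = base_code(s[j]), b = base_code(t[j + diag]);
            if (a == b && a < 4) match++;
          }
          if ((double)match >= min_ident * (double)ov) hit = true;
        }
      }
    }
    out[r] = hit;
  }
  return out;
}
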