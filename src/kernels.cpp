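#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstring>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  }
  return 'N';
}

static std::string revcomp_str(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string seq) { return revcomp_str(seq); }

// Sliding-window low-complexity scoring in the style of symmetric DUST:
// every window of length `window` is scored 10 * sum(c_t*(c_t-1)/2) / (n-1)
// over its overlapping-triplet counts c_t (triplets containing N ignored);
// windows scoring above `threshold` are masked, and overlapping masked
// windows are merged into 0-based half-open intervals.
// [[Rcpp::export]]
IntegerMatrix cpp_dust_intervals(std::string seq, int window, double threshold) {
  int n = (int) seq.size();
  std::vector<std::pair<int, int> > ivs;
  if (n >= window && window >= 3) {
    std::vector<int> tri(n, -1);
    for (int i = 0; i + 2 < n; ++i) {
      int a = base_code(seq[i]), b = base_code(seq[i + 1]), c = base_code(seq[i + 2]);
      tri[i] = (a < 0 || b < 0 || c < 0) ? -1 : ((a << 4) | (b << 2) | c);
    }
    int counts[64];
    std::memset(counts, 0, sizeof(counts));
    long sum = 0;
    int valid = 0;
    int wt = window - 2; // triplets per window
    for (int i = 0; i < wt; ++i) {
      int t = tri[i];
      if (t >= 0) { sum += counts[t]; counts[t]++; valid++; }
    }
    bool open = false;
    int ostart = 0, oend = 0;
    for (int s = 0;; ++s) {
      double score = (valid > 1) ? 10.0 * (double) sum / (double) (valid - 1) : 0.0;
      if (score > threshold) {
        int we = s + window;
        if (open && s <= oend) {
          if (we > oend) oend = we;
        } else {
          if (open) ivs.push_back(std::make_pair(ostart, oend));
          open = true; ostart = s; oend = we;
        }
      }
      if (s + window >= n) break;
      int t = tri[s];
      if (t >= 0) { counts[t]--; sum -= counts[t]; valid--; }
      t = tri[s + wt];
      if (t >= 0) { sum += counts[t]; counts[t]++; valid++; }
    }
    if (open) ivs.push_back(std::make_pair(ostart, oend));
  }
  IntegerMatrix out((int) ivs.size(), 2);
  for (size_t i = 0; i < ivs.size(); ++i) {
    out(i, 0) = ivs[i].first;
    out(i, 1) = ivs[i].second;
  }
  return out;
}

// Canonical (lexicographic min of forward/reverse-complement) k-mers of a
// sequence; k-mers containing any non-ACGT character are skipped. If
// unique_only, each distinct canonical k-mer is returned once.
// [[Rcpp::export]]
CharacterVector cpp_canonical_kmers(std::string seq, int k, bool unique_only) {
  int n = (int) seq.size();
  std::vector<std::string> out;
  if (n >= k) {
    std::unordered_set<std::string> seen;
    int last_bad = -1;
    for (int i = 0; i < n; ++i) {
      if (base_code(seq[i]) < 0) last_bad = i;
      int start = i - k + 1;
      if (start < 0 || last_bad >= start) continue;
      std::string fwd = seq.substr(start, k);
      std::string rc = revcomp_str(fwd);
      const std::string &can = (rc < fwd) ? rc : fwd;
      if (unique_only) {
        if (seen.insert(can).second) out.push_back(can);
      } else {
        out.push_back(can);
      }
    }
  }
  return wrap(out);
}

// Exact shared k-mer positions (forward strand) between each query and one
// subject. Returns, per query, an integer matrix with columns (qpos, spos),
// 0-based. Query positions are sampled every `qstride` bases.
// [[Rcpp::export]]
List cpp_multi_seed_matches(CharacterVector queries, std::string subject, int k,
                            int qstride) {
  int sn = (int) subject.size();
  std::unordered_map<std::string, std::vector<int> > idx;
  if (sn >= k) {
    idx.reserve((size_t) sn * 2);
    int last_bad = -1;
    for (int i = 0; i < sn; ++i) {
      if (base_code(subject[i]) < 0) last_bad = i;
      int start = i - k + 1;
      if (start < 0 || last_bad >= start) continue;
      idx[subject.substr(start, k)].push_back(start);
    }
  }
  List out(queries.size());
  for (int q = 0; q < queries.size(); ++q) {
    std::string qs = as<std::string>(queries[q]);
    std::vector<int> qpos, spos;
    int qn = (int) qs.size();
    for (int i = 0; i + k <= qn; i += qstride) {
      bool ok = true;
      for (int j = i; j < i + k; ++j)
        if (base_code(qs[j]) < 0) { ok = false; break; }
      if (!ok) continue;
      std::unordered_map<std::string, std::vector<int> >::iterator it =
        idx.find(qs.substr(i, k));
      if (it != idx.end()) {
        for (size_t m = 0; m < it->second.size(); ++m) {
          qpos.push_back(i);
          spos.push_back(it->second[m]);
        }
      }
    }
    IntegerMatrix mat((int) qpos.size(), 2);
    for (size_t m = 0; m < qpos.size(); ++m) {
      mat(m, 0) = qpos[m];
      mat(m, 1) = spos[m];
    }
    out[q] = mat;
  }
  return out;
}

// All maximal positive-scoring segments of a 0/1 match vector under
// match_score / -mismatch_pen scoring, found by recursive best-segment
// (Kadane) splitting. Rows: (start, end) 0-based half-open, score, n_match.
static void best_segment(const IntegerVector &m, int lo, int hi,
                         double ms, double xp, double min_keep,
                         std::vector<std::vector<double> > &acc) {
  if (hi - lo <= 0) return;
  double best = -1, cur = 0;
  int bs = -1, be = -1, cs = lo;
  for (int i = lo; i < hi; ++i) {
    double v = m[i] ? ms : -xp;
    if (cur <= 0) { cur = 0; cs = i; }
    cur += v;
    if (cur > best) { best = cur; bs = cs; be = i + 1; }
  }
  if (best < min_keep || bs < 0) return;
  // trim to match-bounded segment
  while (bs < be && !m[bs]) bs++;
  while (be > bs && !m[be - 1]) be--;
  if (be - bs <= 0) return;
  int nm = 0;
  double sc = 0;
  for (int i = bs; i < be; ++i) {
    if (m[i]) { nm++; sc += ms; } else sc -= xp;
  }
  std::vector<double> row(4);
  row[0] = bs; row[1] = be; row[2] = sc; row[3] = nm;
  acc.push_back(row);
  best_segment(m, lo, bs, ms, xp, min_keep, acc);
  best_segment(m, be, hi, ms, xp, min_keep, acc);
}

// [[Rcpp::export]]
NumericMatrix cpp_max_segments(IntegerVector match, double match_score,
                               double mismatch_pen, double min_keep) {
  std::vector<std::vector<double> > acc;
  best_segment(match, 0, (int) match.size(), match_score, mismatch_pen,
               min_keep, acc);
  NumericMatrix out((int) acc.size(), 4);
  for (size_t i = 0; i < acc.size(); ++i)
    for (int j = 0; j < 4; ++j) out((int) i, j) = acc[i][j];
  return out;
}

// k-mer vote tally per read against a canonical-k-mer -> label-index map.
// Returns votes matrix (reads x labels) and per-read total k-mer counts.
// [[Rcpp::export]]
List cpp_classify_reads(CharacterVector db_kmers, IntegerVector db_labels,
                        CharacterVector reads, int k, int n_labels) {
  std::unordered_map<std::string, int> db;
  db.reserve((size_t) db_kmers.size() * 2);
  for (int i = 0; i < db_kmers.size(); ++i)
    db[as<std::string>(db_kmers[i])] = db_labels[i];
  IntegerMatrix votes(reads.size(), n_labels);
  IntegerVector total(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    std::string rs = as<std::string>(reads[r]);
    int n = (int) rs.size();
    int last_bad = -1;
    for (int i = 0; i < n; ++i) {
      if (base_code(rs[i]) < 0) last_bad = i;
      int start = i - k + 1;
      if (start < 0 || last_bad >= start) continue;
      std::string fwd = rs.substr(start, k);
      std::string rc = revcomp_str(fwd);
      const std::string &can = (rc < fwd) ? rc : fwd;
      total[r]++;
      std::unordered_map<std::string, int>::iterator it = db.find(can);
      if (it != db.end()) votes(r, it->second - 1)++;
    }
  }
  return List::create(_["votes"] = votes, _["total"] = total);
}

// All occurrences (0-based) of pattern in subject.
// [[Rcpp::export]]
IntegerVector cpp_find_all(std::string pattern, std::string subject) {
  std::vector<int> pos;
  if (pattern.size() > 0 && pattern.size() <= subject.size()) {
    size_t p = subject.find(pattern, 0);
    while (p != std::string::npos) {
      pos.push_back((int) p);
      p = subject.find(pattern, p + 1);
    }
  }
  return wrap(pos);
}

// Second-order Markov sequence: trans is 16 x 4 (dinucleotide context ->
// next-base probabilities). Uses the R RNG for reproducibility.
// [[Rcpp::export]]
std::string cpp_markov_seq(NumericMatrix trans, int len) {
  const char *bases = "ACGT";
  std::string out(len, 'A');
  if (len <= 0) return out;
  // marginal for the first two bases: mean over contexts
  double marg[4];
  for (int j = 0; j < 4; ++j) {
    double s = 0;
    for (int i = 0; i < 16; ++i) s += trans(i, j);
    marg[j] = s / 16.0;
  }
  int prev1 = 0, prev2 = 0;
  for (int i = 0; i < len; ++i) {
    double u = unif_rand();
    double cum = 0;
    int pick = 3;
    if (i < 2) {
      for (int j = 0; j < 4; ++j) {
        cum += marg[j];
        if (u < cum) { pick = j; break; }
      }
    } else {
      int ctx = (prev2 << 2) | prev1;
      for (int j = 0; j < 4; ++j) {
        cum += trans(ctx, j);
        if (u < cum) { pick = j; break; }
      }
    }
    out[i] = bases[pick];
    prev2 = prev1;
    prev1 = pick;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Greedy exact suffix-prefix overlap assembler.
//
// Items are tracked in both orientations (twin pairs). Candidate overlaps are
// anchored by each item's prefix k-mer (k = min(31, min_overlap)): the prefix
// k-mer of a prospective successor must occur verbatim inside the
// predecessor, so scanning every item's text against the set of prefix
// k-mers enumerates every exact suffix-prefix overlap of length >= k.
// Containments (one item occurring verbatim inside another) are absorbed and
// count as overlaps of the contained item's full length. Merging is greedy:
// longest overlap first, ties broken by the (host key, guest key) pair,
// where an item's key is the lexicographically smallest constituent read id
// plus an orientation sign.
// ---------------------------------------------------------------------------

struct AsmItem {
  std::string seq;
  std::string key;
  std::vector<int> reads;
  int twin;
  bool alive;
};

struct AsmOcc {
  int host;   // item whose text contains the guest's prefix k-mer
  int guest;  // item whose prefix matches host suffix / interior
  int pos;    // position in host
  int ov;     // verified overlap length (guest prefix chars matched)
  bool containment;
};

static bool verify_occ(const std::vector<AsmItem> &items, int host, int guest,
                       int pos, int min_overlap, int &ov, bool &containment) {
  const std::string &h = items[host].seq;
  const std::string &g = items[guest].seq;
  int hn = (int) h.size(), gn = (int) g.size();
  if (pos + gn <= hn) {
    if (std::memcmp(h.data() + pos, g.data(), (size_t) gn) == 0) {
      ov = gn;
      containment = true;
      return true;
    }
    return false;
  }
  int o = hn - pos;
  if (o < min_overlap) return false;
  if (std::memcmp(h.data() + pos, g.data(), (size_t) o) == 0) {
    ov = o;
    containment = false;
    return true;
  }
  return false;
}

static void scan_host_for_keys(
    const std::vector<AsmItem> &items, int host,
    const std::unordered_map<std::string, std::vector<int> > &pmap, int k,
    int min_overlap, std::vector<AsmOcc> &occs) {
  const std::string &h = items[host].seq;
  int hn = (int) h.size();
  for (int p = 0; p + k <= hn; ++p) {
    std::unordered_map<std::string, std::vector<int> >::const_iterator it =
      pmap.find(h.substr(p, k));
    if (it == pmap.end()) continue;
    for (size_t m = 0; m < it->second.size(); ++m) {
      int g = it->second[m];
      if (g == host || g == items[host].twin) continue;
      if (!items[g].alive) continue;
      int ov; bool cont;
      if (verify_occ(items, host, g, p, min_overlap, ov, cont)) {
        AsmOcc o;
        o.host = host; o.guest = g; o.pos = p; o.ov = ov; o.containment = cont;
        occs.push_back(o);
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_greedy_assemble(CharacterVector reads, CharacterVector ids,
                         int min_overlap) {
  int n = reads.size();
  int k = std::min(31, min_overlap);
  std::vector<AsmItem> items;
  items.reserve((size_t) n * 4);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    std::string id = as<std::string>(ids[i]);
    AsmItem fwd, rc;
    fwd.seq = s; fwd.key = id + "+"; fwd.reads.push_back(i);
    fwd.twin = 2 * i + 1; fwd.alive = true;
    rc.seq = revcomp_str(s); rc.key = id + "-"; rc.reads.push_back(i);
    rc.twin = 2 * i; rc.alive = true;
    items.push_back(fwd);
    items.push_back(rc);
  }
  // prefix-kmer -> item indices having that prefix
  std::unordered_map<std::string, std::vector<int> > pmap;
  for (size_t i = 0; i < items.size(); ++i)
    if ((int) items[i].seq.size() >= k)
      pmap[items[i].seq.substr(0, (size_t) k)].push_back((int) i);
  std::vector<AsmOcc> occs;
  for (size_t i = 0; i < items.size(); ++i)
    scan_host_for_keys(items, (int) i, pmap, k, min_overlap, occs);

  for (;;) {
    int best = -1;
    for (size_t i = 0; i < occs.size(); ++i) {
      const AsmOcc &o = occs[i];
      if (!items[o.host].alive || !items[o.guest].alive) continue;
      if (o.guest == items[o.host].twin) continue;
      if (best < 0) { best = (int) i; continue; }
      const AsmOcc &b = occs[best];
      if (o.ov > b.ov ||
          (o.ov == b.ov &&
           (items[o.host].key < items[b.host].key ||
            (items[o.host].key == items[b.host].key &&
             items[o.guest].key < items[b.guest].key)))) {
        best = (int) i;
      }
    }
    if (best < 0) break;
    AsmOcc chosen = occs[best];
    int h = chosen.host, g = chosen.guest;
    int ht = items[h].twin, gt = items[g].twin;
    AsmItem m, mt;
    if (chosen.containment) {
      m.seq = items[h].seq;
    } else {
      m.seq = items[h].seq + items[g].seq.substr((size_t) chosen.ov);
    }
    mt.seq = revcomp_str(m.seq);
    m.key = std::min(items[h].key, items[g].key);
    mt.key = std::min(items[ht].key, items[gt].key);
    m.reads = items[h].reads;
    m.reads.insert(m.reads.end(), items[g].reads.begin(), items[g].reads.end());
    mt.reads = m.reads;
    items[h].alive = items[g].alive = items[ht].alive = items[gt].alive = false;
    int mi = (int) items.size(), mti = mi + 1;
    m.twin = mti; mt.twin = mi;
    m.alive = mt.alive = true;
    items.push_back(m);
    items.push_back(mt);
    if ((int) items[mi].seq.size() >= k) {
      pmap[items[mi].seq.substr(0, (size_t) k)].push_back(mi);
      pmap[items[mti].seq.substr(0, (size_t) k)].push_back(mti);
    }
    // inherit guest-side occurrences: m's prefix equals h's prefix (or the
    // containment host's), mt's prefix equals gt's prefix in the merge case
    size_t n_occ = occs.size();
    for (size_t i = 0; i < n_occ; ++i) {
      AsmOcc o = occs[i];
      if (!items[o.host].alive) continue;
      int new_guest = -1;
      if (o.guest == h) new_guest = mi;
      else if (o.guest == (chosen.containment ? ht : gt)) new_guest = mti;
      if (new_guest < 0) continue;
      int ov; bool cont;
      if (verify_occ(items, o.host, new_guest, o.pos, min_overlap, ov, cont)) {
        AsmOcc no;
        no.host = o.host; no.guest = new_guest; no.pos = o.pos;
        no.ov = ov; no.containment = cont;
        occs.push_back(no);
      }
    }
    // new items as hosts: scan their texts against all prefix keys
    scan_host_for_keys(items, mi, pmap, k, min_overlap, occs);
    scan_host_for_keys(items, mti, pmap, k, min_overlap, occs);
    // compact dead occurrences occasionally
    if (occs.size() > 500000) {
      std::vector<AsmOcc> keep;
      keep.reserve(occs.size() / 2);
      for (size_t i = 0; i < occs.size(); ++i)
        if (items[occs[i].host].alive && items[occs[i].guest].alive)
          keep.push_back(occs[i]);
      occs.swap(keep);
    }
  }

  std::vector<std::string> cseq, ckey;
  List creads;
  for (size_t i = 0; i < items.size(); ++i) {
    if (!items[i].alive) continue;
    if (items[i].key > items[items[i].twin].key) continue; // one per twin pair
    cseq.push_back(items[i].seq);
    ckey.push_back(items[i].key);
    creads.push_back(wrap(items[i].reads));
  }
  return List::create(_["seq"] = wrap(cseq), _["key"] = wrap(ckey),
                      _["reads"] = creads);
}

// Longest suffix-prefix self-overlap with length in [min_overlap, len/2],
// allowing up to max_mismatch_frac mismatches, anchored on an exact match of
// the first min(31, min_overlap) characters. Returns 0 when none.
// [[Rcpp::export]]
int cpp_self_overlap(std::string seq, int min_overlap, double max_mismatch_frac) {
  int n = (int) seq.size();
  int k = std::min(31, min_overlap);
  if (n < 2 * min_overlap || k <= 0) return 0;
  std::string anchor = seq.substr(0, (size_t) k);
  int best = 0;
  size_t p = seq.find(anchor, (size_t) ((n + 1) / 2));
  while (p != std::string::npos) {
    int L = n - (int) p;
    if (L >= min_overlap && L <= n / 2 && L > best) {
      int mism = 0;
      for (int i = 0; i < L; ++i)
        if (seq[(size_t) i] != seq[p + (size_t) i]) mism++;
      if ((double) mism / (double) L <= max_mismatch_frac) best = L;
    }
    p = seq.find(anchor, p + 1);
  }
  return best;
}
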