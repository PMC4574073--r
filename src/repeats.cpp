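// Tandem repeat detection via wraparound dynamic programming.
//
// A candidate repeat is a window [start, end) of the input sequence together
// with a period p; the window is scored by global alignment against cyclic
// concatenations of its leading p-mer (unit weights: +match, -mismatch,
// -indel).  The alignment must consume a whole number of reference units
// (>= 2).  Candidates passing the score / unit-identity / adjacent-unit-indel
// thresholds are deduplicated by overlap resolution (highest score wins among
// same-unit overlaps; different units may co-exist below 50 % overlap of the
// shorter).
//
// Two search strategies produce identical candidate definitions:
//  - exhaustive: every (start, period) pair, one DP sweep scoring all ends;
//  - seeded: candidate (start, period) pairs restricted to neighbourhoods of
//    exact lag-p match runs, for long sequences.

#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

struct Cell {
  long score;
  int m, x, ins, del;  // matches, mismatches, insertions (array), deletions (ref)
};

// Deterministic preference between equal-scoring alignments:
// maximise score, then matches, then minimise indels, then mismatches.
static inline bool better(const Cell& a, const Cell& b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.m != b.m) return a.m > b.m;
  const int ai = a.ins + a.del, bi = b.ins + b.del;
  if (ai != bi) return ai < bi;
  return a.x < b.x;
}

// Wraparound DP of array a[0..L) against cyclic repeats of unit u[0..p).
// State j = number of reference characters consumed mod p; alignments start
// and end at a unit boundary (j == 0), so the reference is u repeated w >= 0
// times.  If trace0 is non-null it receives the state-0 cell after every row
// i (i.e. the best alignment of the length-i prefix), length L + 1.
static Cell dp_states(const char* a, int L, const char* u, int p,
                      int mw, int xp, int ip, std::vector<Cell>* trace0) {
  std::vector<Cell> prev(p), cur(p);
  for (int j = 0; j < p; ++j) prev[j] = Cell{static_cast<long>(-ip) * j, 0, 0, 0, j};
  if (trace0) {
    trace0->resize(L + 1);
    (*trace0)[0] = prev[0];
  }
  for (int i = 1; i <= L; ++i) {
    const char ac = a[i - 1];
    for (int j = 0; j < p; ++j) {
      const int jp = (j == 0) ? p - 1 : j - 1;
      const char r = u[jp];
      const bool match = (ac == r) && ac != 'N' && r != 'N';
      Cell d = prev[jp];
      if (match) { d.score += mw; d.m++; } else { d.score -= xp; d.x++; }
      Cell up = prev[j];
      up.score -= ip; up.ins++;
      cur[j] = better(d, up) ? d : up;
    }
    // in-row deletion moves; two sweeps propagate wraparound chains
    // (deleting a whole extra unit is never optimal, so two passes suffice)
    for (int pass = 0; pass < 2; ++pass) {
      for (int j = 0; j < p; ++j) {
        const int jp = (j == 0) ? p - 1 : j - 1;
        Cell del = cur[jp];
        del.score -= ip; del.del++;
        if (better(del, cur[j])) cur[j] = del;
      }
    }
    if (trace0) (*trace0)[i] = cur[0];
    std::swap(prev, cur);
  }
  return prev[0];
}

// Independently written full-matrix DP used by the brute-force reference
// search.  Same alignment problem and tie-break rules as dp_states, coded as
// an explicit (L+1) x p table.
static Cell dp_matrix(const char* arr, int L, const char* unit, int p,
                      int mw, int xp, int ip, std::vector<Cell>& D) {
  // full (L+1) x p table, stored flat and reused across calls
  D.resize(static_cast<size_t>(L + 1) * p);
  for (int j = 0; j < p; ++j) D[j] = Cell{static_cast<long>(-ip) * j, 0, 0, 0, j};
  for (int i = 1; i <= L; ++i) {
    Cell* row = &D[static_cast<size_t>(i) * p];
    const Cell* prev = &D[static_cast<size_t>(i - 1) * p];
    for (int j = 0; j < p; ++j) {
      const int jp = (j + p - 1) % p;
      Cell diag = prev[jp];
      const bool match = (arr[i - 1] == unit[jp]) && arr[i - 1] != 'N' && unit[jp] != 'N';
      if (match) { diag.score += mw; diag.m += 1; } else { diag.score -= xp; diag.x += 1; }
      Cell up = prev[j];
      up.score -= ip; up.ins += 1;
      row[j] = better(diag, up) ? diag : up;
    }
    for (int sweep = 0; sweep < 2; ++sweep) {
      for (int j = 0; j < p; ++j) {
        const int jp = (j + p - 1) % p;
        Cell left = row[jp];
        left.score -= ip; left.del += 1;
        if (better(left, row[j])) row[j] = left;
      }
    }
  }
  return D[static_cast<size_t>(L) * p];
}

struct Candidate {
  int start, end, p;
  Cell c;
  std::string unit, canonical;
  double identity, indelf;
};

static std::string min_rotation(const std::string& u) {
  std::string best = u;
  const int p = static_cast<int>(u.size());
  for (int r = 1; r < p; ++r) {
    std::string rot = u.substr(r) + u.substr(0, r);
    if (rot < best) best = rot;
  }
  return best;
}

// Consensus pattern: the most frequent in-phase p-mer over the window's
// complete units; ties broken lexicographically.
static std::string consensus_unit(const std::string& s, int start, int end, int p) {
  std::map<std::string, int> counts;
  for (int t = start; t + p <= end; t += p) counts[s.substr(t, p)]++;
  std::string best;
  int bc = -1;
  for (auto& kv : counts) {
    if (kv.second > bc) { best = kv.first; bc = kv.second; }
  }
  return best;
}

struct Params {
  int min_score, max_unit;
  double min_identity, max_indelf, max_nfrac;
  int mw, xp, ip;
};

// Threshold test on a scored window; fills identity/indel fields on success.
static bool passes(const Cell& c, int L, int p, const Params& pr,
                   int n_count, double* identity, double* indelf) {
  const long ref = static_cast<long>(c.m) + c.x + c.del;
  if (ref < 2L * p) return false;      // at least two full units
  if (c.score < pr.min_score) return false;
  const double id = static_cast<double>(c.m) / static_cast<double>(ref);
  if (id < pr.min_identity - 1e-12) return false;
  const long w = ref / p;
  const double indf = static_cast<double>(c.ins + c.del) / static_cast<double>(w - 1);
  if (indf > pr.max_indelf + 1e-12) return false;
  if (static_cast<double>(n_count) > pr.max_nfrac * L + 1e-9) return false;
  *identity = id;
  *indelf = indf;
  return true;
}

static std::vector<int> n_prefix(const std::string& s) {
  std::vector<int> pre(s.size() + 1, 0);
  for (size_t i = 0; i < s.size(); ++i) pre[i + 1] = pre[i] + (s[i] == 'N');
  return pre;
}

// Evaluate one (start, p) pair: one DP sweep over [start, endmax), emitting
// every end whose window passes the thresholds.
static void scan_start(const std::string& s, const std::vector<int>& npre,
                       int start, int endmax, int p, const Params& pr,
                       std::vector<Candidate>& out) {
  const int Lmin = (pr.min_score + pr.mw - 1) / pr.mw;  // score <= mw * L
  if (endmax - start < std::max(Lmin, 2 * p)) return;
  std::vector<Cell> trace;
  dp_states(s.data() + start, endmax - start, s.data() + start, p,
            pr.mw, pr.xp, pr.ip, &trace);
  for (int L = std::max(Lmin, p); L <= endmax - start; ++L) {
    double id, indf;
    const int nn = npre[start + L] - npre[start];
    if (passes(trace[L], L, p, pr, nn, &id, &indf)) {
      Candidate cd;
      cd.start = start; cd.end = start + L; cd.p = p; cd.c = trace[L];
      cd.identity = id; cd.indelf = indf;
      out.push_back(cd);
    }
  }
}

// True if u is periodic with some exact period d < p, d | p (i.e. u is a
// repetition of a shorter unit, so period p is redundant for this locus).
static bool has_subperiod(const std::string& u) {
  const int p = static_cast<int>(u.size());
  for (int d = 1; d < p; ++d) {
    if (p % d != 0) continue;
    bool ok = true;
    for (int i = d; i < p && ok; ++i) ok = (u[i] == u[i - d]);
    if (ok) return true;
  }
  return false;
}

static void candidates_exhaustive(const std::string& s, const Params& pr,
                                  std::vector<Candidate>& out) {
  const int n = static_cast<int>(s.size());
  const std::vector<int> npre = n_prefix(s);
  for (int p = 1; p <= pr.max_unit && 2 * p <= n; ++p)
    for (int start = 0; start + 2 * p <= n; ++start)
      scan_start(s, npre, start, n, p, pr, out);
}

static void candidates_seeded(const std::string& s, const Params& pr,
                              std::vector<Candidate>& out) {
  const int n = static_cast<int>(s.size());
  const std::vector<int> npre = n_prefix(s);
  for (int p = 1; p <= pr.max_unit && 2 * p <= n; ++p) {
    const int seed_min = std::max(6, std::min(p, 12));
    // maximal runs of exact lag-p matches
    std::vector<std::pair<int, int>> runs;  // (start, length) of TRUE runs
    int i = 0;
    const int lim = n - p;
    while (i < lim) {
      if (s[i] == s[i + p] && s[i] != 'N') {
        int j = i;
        while (j < lim && s[j] == s[j + p] && s[j] != 'N') ++j;
        if (j - i >= seed_min) runs.push_back({i, j - i});
        i = j;
      } else {
        ++i;
      }
    }
    if (runs.empty()) continue;
    // merge runs into clusters when the covered extents are close
    size_t r0 = 0;
    while (r0 < runs.size()) {
      size_t r1 = r0;
      int ext_end = runs[r0].first + runs[r0].second + p;
      while (r1 + 1 < runs.size() && runs[r1 + 1].first - ext_end <= p + 20) {
        ++r1;
        ext_end = std::max(ext_end, runs[r1].first + runs[r1].second + p);
      }
      // skip clusters whose unit repeats a shorter unit: the locus is (and
      // scores at least as well as) a smaller-period repeat.  The unit is
      // read from the middle of the cluster's longest run so that point
      // mutations at run boundaries cannot fake or hide periodicity.
      size_t best_r = r0;
      for (size_t r = r0 + 1; r <= r1; ++r)
        if (runs[r].second > runs[best_r].second) best_r = r;
      int anchor = runs[best_r].first + runs[best_r].second / 2;
      if (anchor + p > n) anchor = n - p;
      const std::string u0 = s.substr(anchor, p);
      if (!has_subperiod(u0)) {
        const int dp_end = std::min(n, ext_end + p + 30);
        std::vector<char> use(n, 0);
        for (size_t r = r0; r <= r1; ++r) {
          const int lo = std::max(0, runs[r].first - p - 30);
          const int hi = std::min(runs[r].first + p, n - 2 * p);
          for (int st = lo; st <= hi; ++st) use[st] = 1;
        }
        for (int st = 0; st < n; ++st)
          if (use[st]) scan_start(s, npre, st, dp_end, p, pr, out);
      }
      r0 = r1 + 1;
    }
  }
}

static void annotate_units(const std::string& s, std::vector<Candidate>& cands) {
  for (auto& cd : cands) {
    cd.unit = consensus_unit(s, cd.start, cd.end, cd.p);
    cd.canonical = min_rotation(cd.unit);
  }
}

// Overlap resolution: greedy accept in deterministic order (score desc,
// period asc, start asc, end asc, canonical asc); reject a candidate that
// overlaps an accepted same-canonical-unit candidate at all, or an accepted
// different-unit candidate by >= 50 % of the shorter of the two.
static std::vector<Candidate> resolve(std::vector<Candidate> cands) {
  std::sort(cands.begin(), cands.end(), [](const Candidate& a, const Candidate& b) {
    if (a.c.score != b.c.score) return a.c.score > b.c.score;
    if (a.p != b.p) return a.p < b.p;
    if (a.start != b.start) return a.start < b.start;
    if (a.end != b.end) return a.end < b.end;
    return a.canonical < b.canonical;
  });
  std::vector<Candidate> acc;
  for (const auto& cd : cands) {
    bool ok = true;
    for (const auto& k : acc) {
      const int ov = std::min(cd.end, k.end) - std::max(cd.start, k.start);
      if (ov <= 0) continue;
      if (cd.canonical == k.canonical) { ok = false; break; }
      const int shorter = std::min(cd.end - cd.start, k.end - k.start);
      if (2 * ov >= shorter) { ok = false; break; }
    }
    if (ok) acc.push_back(cd);
  }
  std::sort(acc.begin(), acc.end(), [](const Candidate& a, const Candidate& b) {
    if (a.start != b.start) return a.start < b.start;
    return a.p < b.p;
  });
  return acc;
}

static DataFrame as_frame(const std::vector<Candidate>& cands) {
  const int n = static_cast<int>(cands.size());
  IntegerVector start(n), len(n), period(n), score(n), m(n), x(n), ins(n), del(n), units(n);
  NumericVector copy_number(n), identity(n), indelf(n);
  CharacterVector unit(n), canonical(n);
  for (int i = 0; i < n; ++i) {
    const Candidate& cd = cands[i];
    start[i] = cd.start;
    len[i] = cd.end - cd.start;
    period[i] = cd.p;
    score[i] = static_cast<int>(cd.c.score);
    m[i] = cd.c.m; x[i] = cd.c.x; ins[i] = cd.c.ins; del[i] = cd.c.del;
    units[i] = (cd.c.m + cd.c.x + cd.c.del) / cd.p;
    copy_number[i] = static_cast<double>(cd.end - cd.start) / cd.p;
    identity[i] = cd.identity;
    indelf[i] = cd.indelf;
    unit[i] = cd.unit;
    canonical[i] = cd.canonical;
  }
  return DataFrame::create(
      _["start"] = start, _["length"] = len, _["period"] = period,
      _["unit"] = unit, _["canonical"] = canonical, _["copy_number"] = copy_number,
      _["score"] = score, _["identity"] = identity, _["indel_fraction"] = indelf,
      _["matches"] = m, _["mismatches"] = x, _["insertions"] = ins,
      _["deletions"] = del, _["ref_units"] = units,
      _["stringsAsFactors"] = false);
}

static Params make_params(int min_score, int max_unit, double min_identity,
                          double max_indelf, double max_nfrac,
                          int mw, int xp, int ip) {
  Params pr;
  pr.min_score = min_score; pr.max_unit = max_unit;
  pr.min_identity = min_identity; pr.max_indelf = max_indelf;
  pr.max_nfrac = max_nfrac;
  pr.mw = mw; pr.xp = xp; pr.ip = ip;
  return pr;
}

// [[Rcpp::export]]
DataFrame rc_detect(std::string seq, int min_score, int max_unit_length,
                    double min_identity, double max_indel_fraction,
                    double max_n_fraction, int match_weight,
                    int mismatch_penalty, int indel_penalty,
                    std::string method) {
  const Params pr = make_params(min_score, max_unit_length, min_identity,
                                max_indel_fraction, max_n_fraction,
                                match_weight, mismatch_penalty, indel_penalty);
  const double n = static_cast<double>(seq.size());
  bool exhaustive;
  if (method == "exhaustive") {
    exhaustive = true;
  } else if (method == "seeded") {
    exhaustive = false;
  } else {
    // auto: exhaustive while the full (start, period) sweep stays cheap
    double cells = 0;
    for (int p = 1; p <= pr.max_unit && 2.0 * p <= n; ++p) cells += n * n / 2.0 * p;
    exhaustive = cells <= 6e7;
  }
  std::vector<Candidate> cands;
  if (exhaustive) candidates_exhaustive(seq, pr, cands);
  else candidates_seeded(seq, pr, cands);
  annotate_units(seq, cands);
  return as_frame(resolve(std::move(cands)));
}

// Brute-force reference search: every (start, length, period) triple is scored
// with its own full-matrix DP; no seeding, no shared sweeps.  Returns the
// threshold-passing candidates without overlap resolution.
// [[Rcpp::export]]
DataFrame rc_brute_candidates(std::string seq, int min_score, int max_unit_length,
                              double min_identity, double max_indel_fraction,
                              double max_n_fraction, int match_weight,
                              int mismatch_penalty, int indel_penalty) {
  const Params pr = make_params(min_score, max_unit_length, min_identity,
                                max_indel_fraction, max_n_fraction,
                                match_weight, mismatch_penalty, indel_penalty);
  const int n = static_cast<int>(seq.size());
  const std::vector<int> npre = n_prefix(seq);
  const int Lmin = (pr.min_score + pr.mw - 1) / pr.mw;
  std::vector<Candidate> cands;
  std::vector<Cell> buf;
  for (int p = 1; p <= pr.max_unit && 2 * p <= n; ++p) {
    for (int start = 0; start + 2 * p <= n; ++start) {
      const std::string unit = seq.substr(start, p);
      const int Lmax = n - start;
      dp_matrix(seq.data() + start, Lmax, unit.data(), p,
                pr.mw, pr.xp, pr.ip, buf);
      for (int L = std::max(Lmin, p); L <= Lmax; ++L) {
        const Cell c = buf[static_cast<size_t>(L) * p];
        double id, indf;
        const int nn = npre[start + L] - npre[start];
        if (passes(c, L, p, pr, nn, &id, &indf)) {
          Candidate cd;
          cd.start = start; cd.end = start + L; cd.p = p; cd.c = c;
          cd.identity = id; cd.indelf = indf;
          cands.push_back(cd);
        }
      }
    }
  }
  annotate_units(seq, cands);
  return as_frame(cands);
}

// Wraparound alignment of an explicit array against an explicit unit.
// [[Rcpp::export]]
IntegerVector rc_score(std::string array, std::string unit, int match_weight,
                       int mismatch_penalty, int indel_penalty) {
  const Cell c = dp_states(array.data(), static_cast<int>(array.size()),
                           unit.data(), static_cast<int>(unit.size()),
                           match_weight, mismatch_penalty, indel_penalty, nullptr);
  return IntegerVector::create(
      _["score"] = static_cast<int>(c.score), _["matches"] = c.m,
      _["mismatches"] = c.x, _["insertions"] = c.ins, _["deletions"] = c.del);
}

// [[Rcpp::export]]
CharacterVector rc_canonical(CharacterVector units) {
  CharacterVector out(units.size());
  for (R_xlen_t i = 0; i < units.size(); ++i) {
    out[i] = min_rotation(as<std::string>(units[i]));
  }
  return out;
}

// [[Rcpp::export]]
String rc_consensus(std::string seq, int start, int end, int period) {
  return consensus_unit(seq, start, end, period);
}
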