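#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Sample the successor of `cur` from its row of the transition table.
// Accumulates probabilities in row order against a single uniform draw so the
// pure-R reference path (same accumulation order, same RNG stream) produces
// identical walks under a fixed seed.
static int sample_next(const NumericMatrix &tab, int cur, int m) {
  double u = unif_rand();
  double acc = 0.0;
  for (int j = 0; j < m; ++j) {
    acc += tab(cur, j);
    if (u < acc) return j;
  }
  // guard against accumulated rounding: fall back to last positive entry
  for (int j = m - 1; j >= 0; --j)
    if (tab(cur, j) > 0.0) return j;
  return -1;
}

// Full multi-bout run of one model bee.
//
// dist    : (n+1) x (n+1) distance matrix, row/col 1 = nest
// table0  : initial transition table (rows sum to 1)
// f       : probability enhancement factor (>= 1)
// crop    : number of distinct flowers that fills the crop
// max_trans: cap on sampled transitions per bout; capped bouts do not qualify
// l_opt   : exact optimal circuit length for the crop (NA disables optimality
//           and stability bookkeeping)
//
// A bout starts at the nest and samples transitions until either `crop`
// distinct flowers have been visited (forced direct return, qualifying) or
// the nest vector is sampled (early return, non-qualifying) or the cap is
// hit. The remembered route of a bout is its trapline skeleton: the nest ->
// first-visit order -> nest circuit, net of revisit detours. A qualifying
// bout whose skeleton is no longer than the shortest skeleton experienced so
// far has each of the skeleton's directed transitions multiplied by f, with
// the affected rows renormalised (with `skeleton_memory` false, the
// comparison uses the full travelled length and reinforcement the full set
// of traversed transitions -- an exploratory variant).
// [[Rcpp::export]]
List run_bee_cpp(const NumericMatrix &dist, const NumericMatrix &table0,
                 double f, int n_bouts, int crop, int max_trans,
                 double l_opt, double opt_tol, bool keep_sequences,
                 bool skeleton_memory) {
  const int m = dist.nrow();
  NumericMatrix table = clone(table0);
  const bool have_opt = R_finite(l_opt);

  std::vector<double> lengths, route_lengths;
  std::vector<int> distinct_v, revisits_v, early_v;
  std::vector<int> qualifying_v, capped_v, optimal_v;
  List sequences(keep_sequences ? n_bouts : 0);

  double l_best = R_PosInf;
  int best_bout = NA_INTEGER, first_optimal = NA_INTEGER,
      stability_bout = NA_INTEGER;
  IntegerVector best_seq;
  std::vector<int> best_skel, best_full;
  std::vector<int> prev_seq;
  bool prev_optimal = false;
  int ident_run = 0;

  std::vector<char> edge_used(m * m);
  std::vector<char> row_touched(m);

  for (int b = 0; b < n_bouts; ++b) {
    int cur = 0, distinct = 0, revis = 0, steps = 0;
    bool capped = false, returned = false;
    double L = 0.0;
    std::vector<int> seq, fseq, skel;   // skel: flowers in first-visit order
    seq.push_back(0);
    std::vector<char> visited(m, 0);

    // sampling the nest vector ends the bout (an early return leaves the
    // crop unfilled and the bout non-qualifying); filling the crop triggers
    // a forced direct return
    while (distinct < crop) {
      if (steps >= max_trans) { capped = true; break; }
      int nxt = sample_next(table, cur, m);
      if (nxt < 0) stop("degenerate transition row: no positive probabilities");
      L += dist(cur, nxt);
      seq.push_back(nxt);
      cur = nxt;
      ++steps;
      if (nxt == 0) { returned = true; break; }
      fseq.push_back(nxt);
      if (!visited[nxt]) {
        visited[nxt] = 1;
        skel.push_back(nxt);
        ++distinct;
      } else {
        ++revis;
      }
    }
    if (cur != 0) {            // forced direct return once the crop is full
      L += dist(cur, 0);
      seq.push_back(0);
    }

    bool qualifying = !capped && distinct >= crop;

    // nest-to-nest circuit over the first-visit (trapline skeleton) order
    double circ = R_PosInf;
    if (!skel.empty()) {
      circ = dist(0, skel.front());
      for (size_t s = 0; s + 1 < skel.size(); ++s)
        circ += dist(skel[s], skel[s + 1]);
      circ += dist(skel.back(), 0);
    }

    // optimal: trapline skeleton forming a nest-to-nest circuit of the
    // oracle's optimal length (tie-robust, reversal-invariant)
    bool optimal = qualifying && have_opt && circ <= l_opt * (1.0 + opt_tol);

    double cmp_val = skeleton_memory ? circ : L;
    bool is_best = qualifying && cmp_val <= l_best;
    if (is_best) {
      if (cmp_val < l_best || best_bout == NA_INTEGER) {
        best_bout = b + 1;
        best_seq = IntegerVector(seq.begin(), seq.end());
      }
      l_best = cmp_val;
      best_skel = skel;
      best_full = seq;
    }
    if (is_best) {
      // reinforce each distinct directed transition of the remembered route
      std::fill(edge_used.begin(), edge_used.end(), 0);
      std::fill(row_touched.begin(), row_touched.end(), 0);
      if (skeleton_memory) {
        int prev = 0;
        for (size_t s = 0; s < best_skel.size(); ++s) {
          int bb = best_skel[s];
          if (!edge_used[prev * m + bb]) {
            edge_used[prev * m + bb] = 1;
            table(prev, bb) *= f;
            row_touched[prev] = 1;
          }
          prev = bb;
        }
        if (!edge_used[prev * m + 0]) {
          table(prev, 0) *= f;
          row_touched[prev] = 1;
        }
      } else {
        for (size_t s = 0; s + 1 < best_full.size(); ++s) {
          int a = best_full[s], bb = best_full[s + 1];
          if (!edge_used[a * m + bb]) {
            edge_used[a * m + bb] = 1;
            table(a, bb) *= f;
            row_touched[a] = 1;
          }
        }
      }
      for (int r = 0; r < m; ++r) {
        if (!row_touched[r]) continue;
        double s = 0.0;
        for (int j = 0; j < m; ++j) s += table(r, j);
        for (int j = 0; j < m; ++j) table(r, j) /= s;
      }
    }

    if (optimal && first_optimal == NA_INTEGER) first_optimal = b + 1;
    // stability: three consecutive identical optimal visitation orders
    // (direction kept: a trapline has a habitual direction)
    const std::vector<int> &route_id = skel;
    if (optimal) {
      bool same = prev_optimal && prev_seq.size() == route_id.size() &&
                  std::equal(route_id.begin(), route_id.end(),
                             prev_seq.begin());
      ident_run = same ? ident_run + 1 : 1;
      if (ident_run >= 3 && stability_bout == NA_INTEGER)
        stability_bout = b + 1;
    } else {
      ident_run = 0;
    }
    prev_seq = route_id;
    prev_optimal = optimal;

    lengths.push_back(L);
    route_lengths.push_back(R_finite(circ) ? circ : NA_REAL);
    distinct_v.push_back(distinct);
    revisits_v.push_back(revis);
    early_v.push_back(returned && distinct < crop);
    qualifying_v.push_back(qualifying);
    capped_v.push_back(capped);
    optimal_v.push_back(optimal);
    if (keep_sequences) {
      IntegerVector sv(seq.begin(), seq.end());
      sequences[b] = sv + 1;  // 1-based location indices for R
    }
  }

  if (best_seq.size() > 0) best_seq = best_seq + 1;

  return List::create(
      _["length"] = lengths, _["route_length"] = route_lengths,
      _["n_distinct"] = distinct_v,
      _["revisits"] = revisits_v, _["early_return"] = early_v,
      _["qualifying"] = LogicalVector(qualifying_v.begin(), qualifying_v.end()),
      _["capped"] = LogicalVector(capped_v.begin(), capped_v.end()),
      _["optimal"] = LogicalVector(optimal_v.begin(), optimal_v.end()),
      _["sequences"] = (keep_sequences ? SEXP(sequences) : R_NilValue),
      _["l_best"] = (R_finite(l_best) ? l_best : NA_REAL),
      _["best_bout"] = best_bout,
      _["best_sequence"] = (best_seq.size() > 0 ? best_seq : IntegerVector(0)),
      _["first_optimal"] = first_optimal,
      _["stability_bout"] = stability_bout, _["table"] = table);
}

// Exact shortest nest -> (all listed flowers) -> nest circuit by Held-Karp
// dynamic programming over visited-subset states.
//
// dist     : (n+1) x (n+1) distance matrix, row/col 1 = nest
// flowers  : 1-based location indices (>= 2) of the flowers to include
//
// Ties are broken deterministically: parents with equal cost (within 1e-9)
// prefer the smaller flower index, and the finished order is canonicalised to
// the lexicographically smaller of itself and its reversal (a closed circuit
// has direction-invariant length).
// [[Rcpp::export]]
List held_karp_cpp(const NumericMatrix &dist, const IntegerVector &flowers) {
  const int k = flowers.size();
  if (k < 1) stop("at least one flower is required");
  if (k > 16) stop("Held-Karp limited to 16 flowers");
  const double tol = 1e-9;
  std::vector<int> loc(k);
  for (int i = 0; i < k; ++i) loc[i] = flowers[i] - 1;

  const size_t nstate = (size_t(1) << k) * k;
  std::vector<double> dp(nstate, R_PosInf);
  std::vector<int> par(nstate, -1);

  for (int j = 0; j < k; ++j)
    dp[(size_t(1) << j) * k + j] = dist(0, loc[j]);

  for (size_t mask = 1; mask < (size_t(1) << k); ++mask) {
    for (int j = 0; j < k; ++j) {
      if (!(mask & (size_t(1) << j))) continue;
      size_t pmask = mask ^ (size_t(1) << j);
      if (pmask == 0) continue;
      double best = R_PosInf;
      for (int i = 0; i < k; ++i) {
        if (!(pmask & (size_t(1) << i))) continue;
        double c = dp[pmask * k + i] + dist(loc[i], loc[j]);
        if (c < best) best = c;
      }
      int bp = -1;
      for (int i = 0; i < k; ++i) {
        if (!(pmask & (size_t(1) << i))) continue;
        double c = dp[pmask * k + i] + dist(loc[i], loc[j]);
        if (c <= best + tol) { bp = i; break; }  // smallest index within tol
      }
      dp[mask * k + j] = best;
      par[mask * k + j] = bp;
    }
  }

  const size_t full = (size_t(1) << k) - 1;
  double best = R_PosInf;
  for (int j = 0; j < k; ++j) {
    double c = dp[full * k + j] + dist(loc[j], 0);
    if (c < best) best = c;
  }
  int endj = -1;
  for (int j = 0; j < k; ++j) {
    double c = dp[full * k + j] + dist(loc[j], 0);
    if (c <= best + tol) { endj = j; break; }
  }

  std::vector<int> order;
  size_t mask = full;
  int j = endj;
  while (j >= 0) {
    order.push_back(loc[j]);          // 0-based location index
    int pj = par[mask * k + j];
    mask ^= (size_t(1) << j);
    j = pj;
  }
  std::reverse(order.begin(), order.end());

  std::vector<int> rev(order.rbegin(), order.rend());
  if (std::lexicographical_compare(rev.begin(), rev.end(), order.begin(),
                                   order.end()))
    order = rev;

  IntegerVector ord(order.begin(), order.end());
  return List::create(_["order"] = ord + 1, _["length"] = best);
}
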