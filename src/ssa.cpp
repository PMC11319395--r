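#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation (Gillespie direct method) for a CTMC whose
// event rates have the density-dependent mass-action form
//   rate_e = coef_e * x[idx1_e]                  (first order)
//   rate_e = coef_e * x[idx1_e] * x[idx2_e]/scale (second order)
// Stops at t_max, at absorption (total rate zero), when the coordinates in
// ext_coords are jointly zero (branching-relevant extinction), or when
// stop_coord first reaches stop_level. Uses R's RNG so results are
// reproducible under set.seed().
//
// record_times (sorted, optional): state is recorded just before the chain
// first jumps past each time.
// [[Rcpp::export]]
List ssa_run_cpp(NumericVector x0, IntegerMatrix deltas, NumericVector coef,
                 IntegerVector idx1, IntegerVector idx2, double scale,
                 double t_max, int stop_coord, double stop_level,
                 IntegerVector ext_coords, NumericVector record_times,
                 double max_events) {
  int d = x0.size();
  int E = deltas.nrow();
  NumericVector x = clone(x0);
  double t = 0.0;
  bool crossed = false, extinct = false;
  double t_cross = NA_REAL;
  int n_rec = record_times.size();
  NumericMatrix rec(n_rec, d);
  int rec_ptr = 0;
  NumericVector rates(E);
  double n_events = 0.0;

  if (stop_coord > 0 && x[stop_coord - 1] >= stop_level) {
    crossed = true;
    t_cross = 0.0;
  }

  while (t < t_max && !crossed) {
    // extinction of the branching-relevant coordinates
    double s_ext = 0.0;
    for (int i = 0; i < ext_coords.size(); ++i) s_ext += x[ext_coords[i] - 1];
    if (ext_coords.size() > 0 && s_ext == 0.0) { extinct = true; break; }

    double total = 0.0;
    for (int e = 0; e < E; ++e) {
      double r = coef[e] * x[idx1[e] - 1];
      if (idx2[e] > 0) r *= x[idx2[e] - 1] / scale;
      if (r < 0) stop("negative rate encountered");
      rates[e] = r;
      total += r;
    }
    if (total <= 0.0) break;  // absorbed

    double dt = R::exp_rand() / total;
    double t_new = t + dt;
    while (rec_ptr < n_rec && record_times[rec_ptr] < t_new) {
      for (int i = 0; i < d; ++i) rec(rec_ptr, i) = x[i];
      ++rec_ptr;
    }
    if (t_new > t_max) { t = t_max; break; }
    t = t_new;

    double u = unif_rand() * total;
    int e = 0;
    double acc = rates[0];
    while (acc < u && e < E - 1) { ++e; acc += rates[e]; }
    for (int i = 0; i < d; ++i) x[i] += deltas(e, i);

    if (stop_coord > 0 && x[stop_coord - 1] >= stop_level) {
      crossed = true;
      t_cross = t;
    }
    if (++n_events > max_events) stop("event cap exceeded in ssa_run_cpp");
  }
  while (rec_ptr < n_rec) {  // absorbed/finished before remaining grid times
    for (int i = 0; i < d; ++i) rec(rec_ptr, i) = x[i];
    ++rec_ptr;
  }
  return List::create(_["t_end"] = t, _["state"] = x, _["crossed"] = crossed,
                      _["t_cross"] = t_cross, _["extinct"] = extinct,
                      _["n_events"] = n_events, _["grid_states"] = rec);
}
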