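#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Direct-method stochastic simulation of a reaction network.
//
// Propensity of reaction j at state n:
//   coeff[j] * n[rate_sp[j]] * sum(n[cat_idx[j]]) / dtot
// with the count factor dropped when rate_sp[j] < 0 and the catalyst factor
// dropped when cat_idx[j] is empty. Uses R's RNG so set.seed() gives
// reproducible event sequences.
//
// Optional stop condition: first time sum(stop_w * n) >= (stop_dir = 1) or
// <= (stop_dir = -1) stop_thresh. Optional state snapshots at sample_times
// (left-continuous: the state holding at each sample time). Optional full
// event log (time, reaction index).
// [[Rcpp::export]]
List ssa_core(IntegerVector init, IntegerMatrix stoich, NumericVector coeff,
              IntegerVector rate_sp, List cat_idx, NumericVector hill_K,
              NumericVector hill_h, double dtot, double t_max,
              NumericVector stop_w, double stop_thresh, int stop_dir,
              NumericVector sample_times, bool log_events,
              double max_events) {
  const int ns = init.size();
  const int nr = coeff.size();
  std::vector<double> n(ns);
  for (int i = 0; i < ns; ++i) n[i] = init[i];

  std::vector<std::vector<int> > cats(nr);
  for (int j = 0; j < nr; ++j) {
    IntegerVector cj = cat_idx[j];
    cats[j].assign(cj.begin(), cj.end());
  }

  const int nsamp = sample_times.size();
  NumericMatrix snapshots(nsamp, ns);
  int next_samp = 0;

  std::vector<double> ev_t;
  std::vector<int> ev_j;

  double t = 0.0;
  bool stopped = false;
  double n_events = 0.0;

  // helper lambdas
  auto stop_value = [&]() {
    double s = 0.0;
    for (int i = 0; i < ns; ++i) s += stop_w[i] * n[i];
    return s;
  };
  auto stop_hit = [&]() {
    if (stop_dir == 0) return false;
    double s = stop_value();
    return stop_dir > 0 ? (s >= stop_thresh) : (s <= stop_thresh);
  };
  auto record_until = [&](double tnew) {
    while (next_samp < nsamp && sample_times[next_samp] <= tnew) {
      for (int i = 0; i < ns; ++i) snapshots(next_samp, i) = n[i];
      ++next_samp;
    }
  };

  std::vector<double> a(nr);

  if (stop_hit()) {
    stopped = true;
  } else {
    while (t < t_max && n_events < max_events) {
      double a0 = 0.0;
      for (int j = 0; j < nr; ++j) {
        double aj = coeff[j];
        if (rate_sp[j] >= 0) aj *= n[rate_sp[j]];
        if (!cats[j].empty()) {
          double c = 0.0;
          for (size_t k = 0; k < cats[j].size(); ++k) c += n[cats[j][k]];
          double frac = c / dtot;
          if (hill_h[j] > 0.0) {
            double fh = std::pow(frac, hill_h[j]);
            aj *= fh / (std::pow(hill_K[j], hill_h[j]) + fh);
          } else {
            aj *= frac;
          }
        }
        a[j] = aj;
        a0 += aj;
      }
      if (a0 <= 0.0) { // absorbing state
        record_until(t_max);
        t = t_max;
        break;
      }
      double dt = -std::log(unif_rand()) / a0;
      double tnew = t + dt;
      if (tnew >= t_max) {
        record_until(t_max);
        t = t_max;
        break;
      }
      record_until(tnew);
      double target = unif_rand() * a0;
      double cum = 0.0;
      int jsel = nr - 1;
      for (int j = 0; j < nr; ++j) {
        cum += a[j];
        if (target <= cum) { jsel = j; break; }
      }
      for (int i = 0; i < ns; ++i) n[i] += stoich(i, jsel);
      t = tnew;
      n_events += 1.0;
      if (log_events) { ev_t.push_back(t); ev_j.push_back(jsel + 1); }
      if (stop_hit()) { stopped = true; break; }
    }
  }
  if (!stopped) record_until(t_max);

  IntegerVector final_state(ns);
  for (int i = 0; i < ns; ++i) final_state[i] = (int) n[i];

  List out = List::create(
    _["state"] = final_state,
    _["time"] = t,
    _["stopped"] = stopped,
    _["n_events"] = n_events,
    _["snapshots"] = snapshots);
  if (log_events) {
    out["event_times"] = NumericVector(ev_t.begin(), ev_t.end());
    out["event_reactions"] = IntegerVector(ev_j.begin(), ev_j.end());
  }
  return out;
}
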