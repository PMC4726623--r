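#include <Rcpp.h>
using namespace Rcpp;

// Izhikevich two-variable update, two half-ms sub-steps for v per ms.
// Spike detection happens at step entry (v >= 30 from the previous ms's
// integration): the neuron is reset and its spike is recorded for this ms.
// Spikes recorded at ms t deliver current at ms t+1 (1-ms propagation).

static inline void izh_integrate(double *v, double *u,
                                 const double *a, const double *b,
                                 const double *I, int n) {
  for (int i = 0; i < n; ++i) {
    double vi = v[i], ui = u[i];
    vi += 0.5 * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I[i]);
    vi += 0.5 * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I[i]);
    ui += a[i] * (b[i] * vi - ui);
    v[i] = vi;
    u[i] = ui;
  }
}

//' @title One-trial simulation kernel (1000 ms of network + plasticity)
//' @description Internal C++ engine. Steps the reservoir and motor pools in
//'   1-ms increments, applying the dopamine-modulated LTP-only STDP
//'   bookkeeping each ms, with weight cap + normalization + eligibility decay
//'   on 10-ms boundaries of the global clock. Noise is drawn from R's RNG
//'   (reservoir first, then motor, each ms) so runs are reproducible from
//'   set.seed().
//' @noRd
// [[Rcpp::export]]
List sim_trial_cpp(IntegerMatrix targets,   // fanout x n_res, 1-based post ids
                   NumericMatrix tweights,  // fanout x n_res
                   NumericVector a_res, NumericVector b_res,
                   NumericVector c_res, NumericVector dreset_res,
                   NumericVector a_mot, NumericVector b_mot,
                   NumericVector c_mot, NumericVector dreset_mot,
                   IntegerVector output_ids,   // 1-based reservoir indices
                   int n_agonist,
                   NumericMatrix s_in,         // n_out x n_mot plastic weights
                   NumericMatrix e_in,         // n_out x n_mot eligibility
                   NumericVector ctrace_in,    // n_out presynaptic traces
                   double dopamine,
                   NumericVector v_res_in, NumericVector u_res_in,
                   LogicalVector fired_res_in,
                   NumericVector v_mot_in, NumericVector u_mot_in,
                   LogicalVector fired_mot_in,
                   int t_start,                // global ms index of first step
                   bool reward_first_ms,
                   double noise_amp,
                   List pparams,
                   int trial_ms,
                   bool check_invariants) {
  const int n_res = v_res_in.size();
  const int n_mot = v_mot_in.size();
  const int n_out = output_ids.size();
  const int fanout = targets.nrow();

  const double da_decay    = as<double>(pparams["da_decay"]);
  const double trace_bump  = as<double>(pparams["trace_bump"]);
  const double trace_decay = as<double>(pparams["trace_decay"]);
  const double elig_decay  = as<double>(pparams["elig_decay"]);
  const double weight_cap  = as<double>(pparams["weight_cap"]);
  const double da_bump     = as<double>(pparams["da_bump"]);
  const int upd_int        = as<int>(pparams["update_interval"]);
  const bool norm_by_mean  = as<std::string>(pparams["normalize"]) == "mean";

  NumericMatrix s = clone(s_in);
  NumericMatrix e = clone(e_in);
  NumericVector ctrace = clone(ctrace_in);
  NumericVector v_res = clone(v_res_in), u_res = clone(u_res_in);
  NumericVector v_mot = clone(v_mot_in), u_mot = clone(u_mot_in);
  std::vector<int> fired_prev_res(n_res), fired_prev_mot(n_mot);
  for (int i = 0; i < n_res; ++i) fired_prev_res[i] = fired_res_in[i] ? 1 : 0;
  for (int i = 0; i < n_mot; ++i) fired_prev_mot[i] = fired_mot_in[i] ? 1 : 0;

  std::vector<double> I_res(n_res), I_mot(n_mot);
  std::vector<int> fired_now_res(n_res), fired_now_mot(n_mot);

  IntegerVector ag_raster(trial_ms), ant_raster(trial_ms);
  IntegerVector res_spikes(trial_ms);

  // invariant tracking (post-cap max, post-normalization mean deviation)
  double min_s = R_PosInf, max_s_postcap = R_NegInf, max_meandev = 0.0;
  int n_norms = 0;

  RNGScope scope;

  for (int k = 0; k < trial_ms; ++k) {
    const int t = t_start + k;  // global ms label for this step

    // --- spike detection at entry + reset ---------------------------------
    int n_res_fired = 0;
    for (int i = 0; i < n_res; ++i) {
      if (v_res[i] >= 30.0) {
        fired_now_res[i] = 1;
        v_res[i] = c_res[i];
        u_res[i] += dreset_res[i];
        ++n_res_fired;
      } else fired_now_res[i] = 0;
    }
    int ag = 0, ant = 0;
    for (int i = 0; i < n_mot; ++i) {
      if (v_mot[i] >= 30.0) {
        fired_now_mot[i] = 1;
        v_mot[i] = c_mot[i];
        u_mot[i] += dreset_mot[i];
        if (i < n_agonist) ++ag; else ++ant;
      } else fired_now_mot[i] = 0;
    }
    res_spikes[k] = n_res_fired;
    ag_raster[k] = ag;
    ant_raster[k] = ant;

    // --- input currents: noise + spikes from the previous ms --------------
    // same values as runif(n, -noise_amp, noise_amp): a + (b - a) * u
    for (int i = 0; i < n_res; ++i)
      I_res[i] = -noise_amp + 2.0 * noise_amp * unif_rand();
    for (int i = 0; i < n_mot; ++i)
      I_mot[i] = -noise_amp + 2.0 * noise_amp * unif_rand();
    for (int j = 0; j < n_res; ++j) {
      if (fired_prev_res[j]) {
        const int *tg = &targets(0, j);
        const double *tw = &tweights(0, j);
        for (int q = 0; q < fanout; ++q) I_res[tg[q] - 1] += tw[q];
      }
    }
    for (int r = 0; r < n_out; ++r) {
      if (fired_prev_res[output_ids[r] - 1]) {
        for (int m = 0; m < n_mot; ++m) I_mot[m] += s(r, m);
      }
    }

    // --- membrane integration ---------------------------------------------
    izh_integrate(v_res.begin(), u_res.begin(), a_res.begin(), b_res.begin(),
                  I_res.data(), n_res);
    izh_integrate(v_mot.begin(), u_mot.begin(), a_mot.begin(), b_mot.begin(),
                  I_mot.data(), n_mot);

    // --- plasticity bookkeeping for ms t ----------------------------------
    dopamine *= da_decay;
    for (int m = 0; m < n_mot; ++m) {
      if (fired_now_mot[m]) {
        for (int r = 0; r < n_out; ++r) e(r, m) += ctrace[r];
      }
    }
    const bool boundary = (t % upd_int) == 0;
    if (boundary) {
      double acc = 0.0;
      const int nn = n_out * n_mot;
      double *sp = s.begin();
      const double *ep = e.begin();
      for (int i = 0; i < nn; ++i) {
        double si = sp[i] + ep[i] * dopamine;
        if (si > weight_cap) si = weight_cap;
        sp[i] = si;
        acc += si;
        if (check_invariants) {
          if (si < min_s) min_s = si;
          if (si > max_s_postcap) max_s_postcap = si;
        }
      }
      const double divisor = norm_by_mean ? acc / nn : acc;
      const double inv = 1.0 / divisor;
      for (int i = 0; i < nn; ++i) sp[i] *= inv;
      if (check_invariants) {
        double mean_after = 0.0;
        for (int i = 0; i < nn; ++i) mean_after += sp[i];
        mean_after /= nn;
        double dev = std::abs(mean_after - (norm_by_mean ? 1.0 : 1.0 / nn));
        if (dev > max_meandev) max_meandev = dev;
        ++n_norms;
      }
    }
    for (int r = 0; r < n_out; ++r) {
      if (fired_now_res[output_ids[r] - 1]) ctrace[r] = trace_bump;
      ctrace[r] *= trace_decay;
    }
    if (boundary) {
      const int nn = n_out * n_mot;
      double *ep = e.begin();
      for (int i = 0; i < nn; ++i) ep[i] *= elig_decay;
    }
    if (k == 0 && reward_first_ms) dopamine += da_bump;

    // --- commit spikes for next ms's propagation --------------------------
    std::copy(fired_now_res.begin(), fired_now_res.end(), fired_prev_res.begin());
    std::copy(fired_now_mot.begin(), fired_now_mot.end(), fired_prev_mot.begin());
  }

  for (int i = 0; i < n_res; ++i)
    if (!R_finite(v_res[i]) || !R_finite(u_res[i]))
      stop("non-finite membrane state in reservoir neuron %d", i + 1);
  for (int i = 0; i < n_mot; ++i)
    if (!R_finite(v_mot[i]) || !R_finite(u_mot[i]))
      stop("non-finite membrane state in motor neuron %d", i + 1);

  LogicalVector fr(n_res), fm(n_mot);
  for (int i = 0; i < n_res; ++i) fr[i] = fired_prev_res[i] == 1;
  for (int i = 0; i < n_mot; ++i) fm[i] = fired_prev_mot[i] == 1;

  return List::create(
    _["agonist_raster"] = ag_raster,
    _["antagonist_raster"] = ant_raster,
    _["reservoir_spikes"] = res_spikes,
    _["s"] = s, _["e"] = e, _["ctrace"] = ctrace, _["dopamine"] = dopamine,
    _["v_res"] = v_res, _["u_res"] = u_res, _["fired_res"] = fr,
    _["v_mot"] = v_mot, _["u_mot"] = u_mot, _["fired_mot"] = fm,
    _["t_end"] = t_start + trial_ms - 1,
    _["invariants"] = List::create(
      _["min_s"] = min_s, _["max_s_postcap"] = max_s_postcap,
      _["max_meandev"] = max_meandev, _["n_norms"] = n_norms));
}

//' @title Time-varying single-resonance filter
//' @description Two-pole resonator whose center frequency varies per sample.
//'   y[n] = x[n] + b1[n] y[n-1] + b2[n] y[n-2], with b1 = 2 r cos(2 pi F/fs),
//'   b2 = -r^2, r = exp(-pi * bandwidth / fs).
//' @noRd
// [[Rcpp::export]]
NumericVector resonator_cpp(NumericVector x, NumericVector freq,
                            double bandwidth, double fs) {
  const int n = x.size();
  if (freq.size() != n) stop("freq must match signal length");
  NumericVector y(n);
  const double r = std::exp(-M_PI * bandwidth / fs);
  const double b2 = -r * r;
  double y1 = 0.0, y2 = 0.0;
  for (int i = 0; i < n; ++i) {
    const double b1 = 2.0 * r * std::cos(2.0 * M_PI * freq[i] / fs);
    const double yi = x[i] + b1 * y1 + b2 * y2;
    y2 = y1;
    y1 = yi;
    y[i] = yi;
  }
  return y;
}
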