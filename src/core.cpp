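#include <Rcpp.h>
using namespace Rcpp;

// The network is small and fixed-shape: 10 content input units (4 ink colors,
// 1 color-side non-color unit, 4 color words, 1 word-side non-color unit),
// a 10-unit hidden layer split into two task pools of 5 (color pool = hidden
// 0..4 fed by inputs 0..4, word pool = hidden 5..9 fed by inputs 5..9), and
// 5 output units (RED, GREEN, BLUE, YELLOW, neutral). Task-demand units are
// not part of the trainable weights: the attended pool receives a fixed +w_td
// on its net input, and every hidden unit carries the fixed inhibitory bias.

static inline double logistic(double net) { return 1.0 / (1.0 + std::exp(-net)); }

// attended: 0 = color naming (color pool), 1 = word reading (word pool)
static void forward_nets(const NumericMatrix& W1, const NumericMatrix& W2,
                         const double* x, int attended,
                         double bias, double w_td, double noise_sd,
                         double* hnet, double* hact, double* onet) {
  for (int j = 0; j < 10; ++j) {
    double s = bias;
    if ((attended == 0 && j < 5) || (attended == 1 && j >= 5)) s += w_td;
    // block structure: hidden j only sees its own pool's inputs
    int lo = (j < 5) ? 0 : 5;
    for (int i = lo; i < lo + 5; ++i) s += x[i] * W1(i, j);
    if (noise_sd > 0) s += R::rnorm(0.0, noise_sd);
    hnet[j] = s;
    hact[j] = logistic(s);
  }
  for (int k = 0; k < 5; ++k) {
    double s = 0.0;
    for (int j = 0; j < 10; ++j) s += hact[j] * W2(j, k);
    if (noise_sd > 0) s += R::rnorm(0.0, noise_sd);
    onet[k] = s;
  }
}

// Online backpropagation on the squared output error. Each training item has
// exactly one active content unit (single-dimension stimuli), passed as a
// 0-based index, with the matching attended pool and a one-hot target unit.
// Returns the trained weights and the per-pattern mean squared error trace.
// [[Rcpp::export]]
List cpp_train(NumericMatrix W1_, NumericMatrix W2_,
               IntegerVector input_idx, IntegerVector attended,
               IntegerVector target_idx,
               double lr, double noise_sd, double bias, double w_td) {
  NumericMatrix W1 = clone(W1_), W2 = clone(W2_);
  int n = input_idx.size();
  NumericVector mse(n);
  double x[10], hnet[10], hact[10], onet[5], oact[5], dout[5], dhid[10];
  for (int t = 0; t < n; ++t) {
    for (int i = 0; i < 10; ++i) x[i] = 0.0;
    x[input_idx[t]] = 1.0;
    forward_nets(W1, W2, x, attended[t], bias, w_td, noise_sd, hnet, hact, onet);
    double err2 = 0.0;
    for (int k = 0; k < 5; ++k) {
      oact[k] = logistic(onet[k]);
      double e = oact[k] - (k == target_idx[t] ? 1.0 : 0.0);
      err2 += e * e;
      dout[k] = e * oact[k] * (1.0 - oact[k]);
    }
    mse[t] = err2 / 5.0;
    for (int j = 0; j < 10; ++j) {
      double s = 0.0;
      for (int k = 0; k < 5; ++k) s += W2(j, k) * dout[k];
      dhid[j] = s * hact[j] * (1.0 - hact[j]);
    }
    for (int j = 0; j < 10; ++j)
      for (int k = 0; k < 5; ++k) W2(j, k) -= lr * hact[j] * dout[k];
    // only the single active input row has a nonzero gradient, and it lies
    // inside its own pool's block, so the pathway partition is preserved
    int i = input_idx[t], lo = (i < 5) ? 0 : 5;
    for (int j = lo; j < lo + 5; ++j) W1(i, j) -= lr * dhid[j];
  }
  return List::create(_["W1"] = W1, _["W2"] = W2, _["mse"] = mse);
}

static int accumulate(const double* act, double alpha, double sigma,
                      double threshold, int max_iter, int* iter_out,
                      double* ev) {
  double mu[5];
  for (int k = 0; k < 5; ++k) {
    double mx = -1e12;
    for (int l = 0; l < 5; ++l) if (l != k && act[l] > mx) mx = act[l];
    mu[k] = alpha * (act[k] - mx);
  }
  if (sigma == 0) {
    // deterministic limit: closed-form crossing time of the top drift
    int win = 0;
    for (int k = 1; k < 5; ++k) if (mu[k] > mu[win]) win = k;
    if (mu[win] <= 0) { *iter_out = max_iter; return -1; }
    double it = std::ceil(threshold / mu[win] - 1e-9);
    if (it > max_iter) { *iter_out = max_iter; return -1; }
    *iter_out = (int)it;
    return win;
  }
  for (int k = 0; k < 5; ++k) ev[k] = 0.0;
  for (int it = 1; it <= max_iter; ++it) {
    for (int k = 0; k < 5; ++k)
      ev[k] += R::rnorm(mu[k], sigma);
    int win = -1; double best = threshold;
    for (int k = 0; k < 5; ++k)
      if (ev[k] > best) { best = ev[k]; win = k; }
    if (win >= 0) { *iter_out = it; return win; }
  }
  *iter_out = max_iter;
  return -1;  // timeout
}

// Simulate one epoch of sequential color-naming trials.
// variant: 0 = PDP-refined (no memory), 1 = PDP-WM (time-delayed layer),
//          2 = conventional PDP (running-average dynamics interleaved with
//              evidence accumulation, blank-input settling between trials).
// X: n x 2 matrix of 0-based content-unit indices (ink unit, word unit).
// delay_store: 0 = output activations, 1 = raw output nets, 2 = combined nets.
// For the conventional variant the evidence increment is the raw activation
// gap (accumulation rate `pdp_rate`, nominally 1) rather than alpha * gap.
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix W1, NumericMatrix W2, IntegerMatrix X,
                  int variant, double noise_sd, double bias, double w_td,
                  double alpha, double sigma, double threshold, int max_iter,
                  double w_delay, int delay_store,
                  double tau, int iti_steps, double pdp_rate) {
  int n = X.nrow();
  IntegerVector resp(n), rt(n);
  double x[10], hnet[10], hact[10], onet[5], act[5], ev[5];
  double stored[5] = {0, 0, 0, 0, 0};      // time-delayed layer
  double hbar[10] = {0}, obar[5] = {0};    // running averages
  const int attended = 0;                  // test trials are color naming
  for (int t = 0; t < n; ++t) {
    for (int i = 0; i < 10; ++i) x[i] = 0.0;
    x[X(t, 0)] = 1.0;
    x[X(t, 1)] = 1.0;
    int it = 0, win = -1;
    if (variant == 2) {
      // settle on blank input during the inter-trial interval, then let the
      // running average track the stimulus while evidence accrues
      double blank[10] = {0};
      for (int s = 0; s < iti_steps; ++s) {
        forward_nets(W1, W2, blank, attended, bias, w_td, noise_sd,
                     hnet, hact, onet);
        for (int j = 0; j < 10; ++j) {
          hbar[j] = tau * hnet[j] + (1.0 - tau) * hbar[j];
          hact[j] = logistic(hbar[j]);
        }
        for (int k = 0; k < 5; ++k) {
          double so = 0.0;
          for (int j = 0; j < 10; ++j) so += hact[j] * W2(j, k);
          if (noise_sd > 0) so += R::rnorm(0.0, noise_sd);
          obar[k] = tau * so + (1.0 - tau) * obar[k];
        }
      }
      for (int k = 0; k < 5; ++k) ev[k] = 0.0;
      for (int s = 1; s <= max_iter; ++s) {
        forward_nets(W1, W2, x, attended, bias, w_td, noise_sd,
                     hnet, hact, onet);
        for (int j = 0; j < 10; ++j) {
          hbar[j] = tau * hnet[j] + (1.0 - tau) * hbar[j];
          hact[j] = logistic(hbar[j]);
        }
        for (int k = 0; k < 5; ++k) {
          double so = 0.0;
          for (int j = 0; j < 10; ++j) so += hact[j] * W2(j, k);
          if (noise_sd > 0) so += R::rnorm(0.0, noise_sd);
          obar[k] = tau * so + (1.0 - tau) * obar[k];
          act[k] = logistic(obar[k]);
        }
        for (int k = 0; k < 5; ++k) {
          double mx = -1e12;
          for (int l = 0; l < 5; ++l) if (l != k && act[l] > mx) mx = act[l];
          double mu = pdp_rate * (act[k] - mx);
          ev[k] += (sigma > 0) ? R::rnorm(mu, sigma) : mu;
        }
        double best = threshold;
        for (int k = 0; k < 5; ++k)
          if (ev[k] > best) { best = ev[k]; win = k; }
        if (win >= 0) { it = s; break; }
        it = s;
      }
      if (win < 0) it = max_iter;
    } else {
      forward_nets(W1, W2, x, attended, bias, w_td, noise_sd,
                   hnet, hact, onet);
      double comb[5];
      for (int k = 0; k < 5; ++k) {
        comb[k] = onet[k] + (variant == 1 ? w_delay * stored[k] : 0.0);
        act[k] = logistic(comb[k]);
      }
      win = accumulate(act, alpha, sigma, threshold, max_iter, &it, ev);
      if (variant == 1) {
        for (int k = 0; k < 5; ++k)
          stored[k] = (delay_store == 0) ? act[k]
                    : (delay_store == 1) ? onet[k] : comb[k];
      }
    }
    resp[t] = win;  // -1 marks a timeout (no threshold crossing)
    rt[t] = it;
  }
  return List::create(_["response"] = resp, _["rt"] = rt);
}
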