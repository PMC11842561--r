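// Core closed-loop dynamics: forward simulation of one trial (with optional
// feedback-driven plasticity accumulation) and backpropagation through time
// for the gradient-training phase. Time is discretised at dt; the feedback
// delay is an integer number of steps. All positions in cm, velocities cm/s.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Net {
  mat W, Win, Wout, F, maskW, maskF;
  vec b, bout;
  double lam;   // dt / tau (both ms)
  double hs;    // dt in seconds, used for position integration and plasticity
  int delta;    // feedback delay in steps
  int N;
};

Net unpack(const Rcpp::List& par) {
  Net n;
  n.W     = Rcpp::as<mat>(par["W"]);
  n.Win   = Rcpp::as<mat>(par["W_in"]);
  n.Wout  = Rcpp::as<mat>(par["W_out"]);
  n.F     = Rcpp::as<mat>(par["F"]);
  n.maskW = Rcpp::as<mat>(par["mask_W"]);
  n.maskF = Rcpp::as<mat>(par["mask_F"]);
  n.b     = Rcpp::as<vec>(par["b"]);
  n.bout  = Rcpp::as<vec>(par["b_out"]);
  double dt  = Rcpp::as<double>(par["dt"]);
  double tau = Rcpp::as<double>(par["tau"]);
  n.lam   = dt / tau;
  n.hs    = dt / 1000.0;
  n.delta = Rcpp::as<int>(par["delta_steps"]);
  n.N     = n.W.n_rows;
  return n;
}

inline mat rotmat(double deg) {
  double th = deg * datum::pi / 180.0;
  mat R(2, 2);
  R(0, 0) = std::cos(th); R(0, 1) = -std::sin(th);
  R(1, 0) = std::sin(th); R(1, 1) =  std::cos(th);
  return R;
}

} // namespace

// Forward simulation of a single trial.
//
// S:     3 x T stimulus (target dx, dy, hold)
// Pstar: 2 x T desired cursor position
// bump:  2 x T velocity perturbation added after readout, before rotation
// rot:   length-T rotation of the output, degrees
// stim:  length-T uniform extra input to all units
// clamp: if true, the delayed error input (dynamics and plasticity) is zero
// x0:    initial pre-activations; p0: initial cursor position
// plastic: accumulate the feedback-driven weight change (every `stride` steps)
// [[Rcpp::export]]
Rcpp::List cpp_run_trial(Rcpp::List par,
                         const arma::mat& S, const arma::mat& Pstar,
                         const arma::mat& bump, const arma::vec& rot,
                         const arma::vec& stim, bool clamp,
                         const arma::vec& x0, const arma::vec& p0,
                         bool plastic, double eta, int stride,
                         bool record_full) {
  Net net = unpack(par);
  const int T = S.n_cols;
  const int N = net.N;

  mat Y(N, T), V(2, T), U(2, T), P(2, T), E(2, T);
  mat X, Rtr;
  if (record_full) { X.set_size(N, T); Rtr.set_size(N, T); }

  vec x = x0;
  vec y = arma::max(x0, zeros<vec>(N));
  vec r = zeros<vec>(N);
  vec p = p0;
  mat dW;
  if (plastic) dW = zeros<mat>(N, N);

  const vec ones_n = ones<vec>(N);
  vec ed(2);

  for (int t = 0; t < T; ++t) {
    // delayed error eps(t - Delta), zero before the delay horizon or when clamped
    if (!clamp && t - net.delta >= 0) ed = E.col(t - net.delta);
    else ed.zeros();

    x += net.lam * (-x + net.W * y + net.Win * S.col(t) + net.F * ed +
                    net.b + stim(t) * ones_n);
    y = arma::max(x, zeros<vec>(N));
    r += y;

    vec v = net.Wout * y + net.bout;
    vec u = v + bump.col(t);
    vec ru = (rot(t) != 0.0) ? vec(rotmat(rot(t)) * u) : u;
    p += net.hs * ru;

    Y.col(t) = y;
    V.col(t) = v;
    U.col(t) = ru;
    P.col(t) = p;
    E.col(t) = Pstar.col(t) - p;
    if (record_full) { X.col(t) = x; Rtr.col(t) = r; }

    // accumulate the feedback-driven weight change on every stride-th step
    // (1-based steps stride, 2*stride, ..., T)
    if (plastic && ((t + 1) % stride == 0)) {
      dW += net.hs * eta * ((net.F * ed) * r.t());
    }
  }

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("y") = Y, Rcpp::Named("v") = V, Rcpp::Named("v_eff") = U,
    Rcpp::Named("p") = P, Rcpp::Named("epsilon") = E);
  if (record_full) { out["x"] = X; out["r"] = Rtr; }
  if (plastic) out["dW"] = dW % net.maskW;
  return out;
}

// Loss and gradient over a batch of trials, backpropagating through the
// closed loop (readout -> position -> error -> delayed feedback input).
// Each element of `trials` is a list with S, Pstar, bump, rot, x0, p0.
// Returns the error and activity terms of the loss and gradients w.r.t. all
// parameters (masks applied to W and F gradients). Regularisation terms are
// handled by the caller.
// [[Rcpp::export]]
Rcpp::List cpp_batch_grad(Rcpp::List par, Rcpp::List trials,
                          double gamma, bool feedback_on) {
  Net net = unpack(par);
  const int B = trials.size();
  const int N = net.N;

  double err_term = 0.0, act_term = 0.0;
  mat gW = zeros<mat>(N, N), gWin = zeros<mat>(N, net.Win.n_cols);
  mat gWout = zeros<mat>(2, N), gF = zeros<mat>(N, 2);
  vec gb = zeros<vec>(N), gbout = zeros<vec>(2);

  for (int bi = 0; bi < B; ++bi) {
    Rcpp::List tr = trials[bi];
    const mat S     = Rcpp::as<mat>(tr["S"]);
    const mat Pstar = Rcpp::as<mat>(tr["Pstar"]);
    const mat bump  = Rcpp::as<mat>(tr["bump"]);
    const vec rot   = Rcpp::as<vec>(tr["rot"]);
    const vec x0    = Rcpp::as<vec>(tr["x0"]);
    const vec p0    = Rcpp::as<vec>(tr["p0"]);
    const int T = S.n_cols;
    const double ce = 1.0 / (2.0 * B * T);
    const double ga = gamma / (double(N) * B * T);

    // ---- forward, storing what the backward pass needs
    mat X(N, T), Y(N, T), E(2, T), ED(2, T);
    cube Rots(2, 2, T);
    vec x = x0, y = arma::max(x0, zeros<vec>(N)), p = p0;
    vec y0 = y;
    vec ed(2);
    for (int t = 0; t < T; ++t) {
      if (feedback_on && t - net.delta >= 0) ed = E.col(t - net.delta);
      else ed.zeros();
      ED.col(t) = ed;
      x += net.lam * (-x + net.W * y + net.Win * S.col(t) + net.F * ed + net.b);
      y = arma::max(x, zeros<vec>(N));
      vec v = net.Wout * y + net.bout;
      vec u = v + bump.col(t);
      mat R = rotmat(rot(t));
      Rots.slice(t) = R;
      p += net.hs * (R * u);
      X.col(t) = x; Y.col(t) = y;
      E.col(t) = Pstar.col(t) - p;
    }
    err_term += ce * accu(E % E);
    act_term += ga * accu(Y % Y);

    // ---- backward
    mat GX(N, T, fill::zeros);
    vec gp_next = zeros<vec>(2);
    for (int t = T - 1; t >= 0; --t) {
      vec geps = (2.0 * ce) * E.col(t);
      if (feedback_on && t + net.delta < T)
        geps += net.lam * (net.F.t() * GX.col(t + net.delta));
      vec gp = gp_next - geps;
      vec gu = net.hs * (Rots.slice(t).t() * gp);
      vec gy = net.Wout.t() * gu + (2.0 * ga) * Y.col(t);
      if (t + 1 < T) gy += net.lam * (net.W.t() * GX.col(t + 1));
      vec gx = gy % conv_to<vec>::from(X.col(t) > 0);
      if (t + 1 < T) gx += (1.0 - net.lam) * GX.col(t + 1);
      GX.col(t) = gx;
      gp_next = gp;

      const vec yprev = (t == 0) ? y0 : vec(Y.col(t - 1));
      gW    += net.lam * (gx * yprev.t());
      gWin  += net.lam * (gx * S.col(t).t());
      gF    += net.lam * (gx * ED.col(t).t());
      gb    += net.lam * gx;
      gWout += gu * Y.col(t).t();
      gbout += gu;
    }
  }

  gW = gW % net.maskW;
  gF = gF % net.maskF;
  return Rcpp::List::create(
    Rcpp::Named("error_term") = err_term,
    Rcpp::Named("activity_term") = act_term,
    Rcpp::Named("gW") = gW, Rcpp::Named("gW_in") = gWin,
    Rcpp::Named("gW_out") = gWout, Rcpp::Named("gF") = gF,
    Rcpp::Named("gb") = gb, Rcpp::Named("gb_out") = gbout);
}
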