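// Continuous-time Markov chain machinery for interval-censored panel data:
// matrix exponential, panel log-likelihood over transition-count tables,
// analytic gradient (Frechet-derivative adjoint), BFGS fitting via R's
// C-level vmmin, discrete-observation simulation and the parametric
// bootstrap of absorption times.

#include <RcppArmadillo.h>
#include <R_ext/Applic.h>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double P_FLOOR = 1e-300;

// Assemble a generator from per-edge rates; diagonal = -(row sum).
static arma::mat build_generator(const arma::vec &rates,
                                 const arma::imat &edges, int ns) {
  arma::mat Q(ns, ns, arma::fill::zeros);
  for (arma::uword k = 0; k < edges.n_rows; ++k)
    Q(edges(k, 0) - 1, edges(k, 1) - 1) = rates(k);
  for (int i = 0; i < ns; ++i) Q(i, i) = -arma::accu(Q.row(i)) + Q(i, i);
  return Q;
}

// [[Rcpp::export]]
arma::mat ctmc_expm_cpp(const arma::mat &Q, double t) {
  return arma::expmat(Q * t);
}

struct LikData {
  const arma::imat *edges;   // n_edge x 2, 1-based state indices
  const arma::cube *counts;  // ns x ns x n_dt transition-count tables
  const arma::vec *dts;      // interval lengths, one per count slice
  int ns;
};

static double nll_value(const arma::vec &logr, const LikData &d) {
  arma::vec rates = arma::exp(logr);
  arma::mat Q = build_generator(rates, *d.edges, d.ns);
  double nll = 0.0;
  for (arma::uword s = 0; s < d.dts->n_elem; ++s) {
    arma::mat P;
    try {
      P = arma::expmat(Q * (*d.dts)(s));
    } catch (...) {
      return 1e12;  // pathological region of the parameter space
    }
    const arma::mat &N = d.counts->slice(s);
    for (int i = 0; i < d.ns; ++i)
      for (int j = 0; j < d.ns; ++j)
        if (N(i, j) > 0) {
          double p = P(i, j);
          if (!(p > P_FLOOR)) p = P_FLOOR;
          nll -= N(i, j) * std::log(p);
        }
  }
  if (!std::isfinite(nll)) nll = 1e12;
  return nll;
}

// Gradient of the negative log-likelihood w.r.t. log-rates.
//
// With M = dt*Q, P = expm(M) and G_ij = N_ij / P_ij, the gradient of the
// log-likelihood w.r.t. M is the adjoint Frechet derivative L(M', G),
// obtained exactly as the upper-right block of expm([[M', G], [0, M']]).
static arma::vec nll_gradient(const arma::vec &logr, const LikData &d) {
  arma::vec rates = arma::exp(logr);
  int ns = d.ns;
  arma::mat Q = build_generator(rates, *d.edges, ns);
  arma::mat gradQ(ns, ns, arma::fill::zeros);  // d loglik / d Q
  for (arma::uword s = 0; s < d.dts->n_elem; ++s) {
    double dt = (*d.dts)(s);
    arma::mat P;
    try {
      P = arma::expmat(Q * dt);
    } catch (...) {
      continue;
    }
    const arma::mat &N = d.counts->slice(s);
    arma::mat G(ns, ns, arma::fill::zeros);
    bool any = false;
    for (int i = 0; i < ns; ++i)
      for (int j = 0; j < ns; ++j)
        if (N(i, j) > 0) {
          double p = P(i, j);
          if (!(p > P_FLOOR)) continue;  // clamped cell: no information
          G(i, j) = N(i, j) / p;
          any = true;
        }
    if (!any) continue;
    // the adjoint is linear in G: rescale for conditioning of the
    // augmented exponential, then undo
    double gnorm = arma::norm(G, "fro");
    double scale = (gnorm > 1.0) ? gnorm : 1.0;
    arma::mat big(2 * ns, 2 * ns, arma::fill::zeros);
    arma::mat Mt = (Q * dt).t();
    big.submat(0, 0, ns - 1, ns - 1) = Mt;
    big.submat(ns, ns, 2 * ns - 1, 2 * ns - 1) = Mt;
    big.submat(0, ns, ns - 1, 2 * ns - 1) = G / scale;
    arma::mat E;
    try {
      E = arma::expmat(big);
    } catch (...) {
      continue;
    }
    gradQ += dt * scale * E.submat(0, ns, ns - 1, 2 * ns - 1);
  }
  arma::vec g(logr.n_elem);
  for (arma::uword k = 0; k < d.edges->n_rows; ++k) {
    int i = (*d.edges)(k, 0) - 1, j = (*d.edges)(k, 1) - 1;
    // Q_ij = r_k and Q_ii picks up -r_k; negate for the *negative* loglik.
    g(k) = -rates(k) * (gradQ(i, j) - gradQ(i, i));
  }
  return g;
}

// [[Rcpp::export]]
double panel_nll_cpp(const arma::vec &logr, const arma::cube &counts,
                     const arma::vec &dts, const arma::imat &edges, int ns) {
  LikData d{&edges, &counts, &dts, ns};
  return nll_value(logr, d);
}

// [[Rcpp::export]]
arma::vec panel_nll_grad_cpp(const arma::vec &logr, const arma::cube &counts,
                             const arma::vec &dts, const arma::imat &edges,
                             int ns) {
  LikData d{&edges, &counts, &dts, ns};
  return nll_gradient(logr, d);
}

extern "C" {
static double vm_fn(int n, double *par, void *ex) {
  LikData *d = static_cast<LikData *>(ex);
  arma::vec logr(par, n);
  return nll_value(logr, *d);
}
static void vm_gr(int n, double *par, double *gr, void *ex) {
  LikData *d = static_cast<LikData *>(ex);
  arma::vec logr(par, n);
  arma::vec g = nll_gradient(logr, *d);
  for (int k = 0; k < n; ++k) gr[k] = g(k);
}
}

static List fit_core(const arma::cube &counts, const arma::vec &dts,
                     const arma::imat &edges, int ns, arma::vec logr,
                     int maxit, double reltol) {
  LikData d{&edges, &counts, &dts, ns};
  int n = logr.n_elem;
  std::vector<double> par(logr.begin(), logr.end());
  std::vector<int> mask(n, 1);
  double fmin = 0.0;
  int fncount = 0, grcount = 0, fail = 0;
  vmmin(n, par.data(), &fmin, vm_fn, vm_gr, maxit, 0, mask.data(),
        R_NegInf, reltol, 10, &d, &fncount, &grcount, &fail);
  return List::create(_["logr"] = NumericVector(par.begin(), par.end()),
                      _["value"] = fmin, _["fncount"] = fncount,
                      _["grcount"] = grcount, _["convergence"] = fail);
}

// [[Rcpp::export]]
List fit_panel_cpp(const arma::cube &counts, const arma::vec &dts,
                   const arma::imat &edges, int ns, const arma::vec &init_logr,
                   int maxit = 300, double reltol = 1e-8) {
  return fit_core(counts, dts, edges, ns, init_logr, maxit, reltol);
}

// Simulate interval-censored observations of the chain: each participant p
// starts in init_states[p] and makes n_int[p] observed steps, step k using
// the interval length dts[dt_idx[offset_p + k]].  Returns per-dt tables of
// observed (from, to) pairs.  Uses R's RNG stream.
// [[Rcpp::export]]
arma::cube sim_panel_counts_cpp(const arma::mat &Q, const arma::vec &dts,
                                const IntegerVector &init_states,
                                const IntegerVector &dt_idx,
                                const IntegerVector &offsets, int ns) {
  arma::uword ndt = dts.n_elem;
  std::vector<arma::mat> Pcum(ndt);
  for (arma::uword s = 0; s < ndt; ++s) {
    arma::mat P = arma::expmat(Q * dts(s));
    P.elem(arma::find(P < 0)).zeros();
    Pcum[s] = arma::cumsum(P, 1);
  }
  arma::cube counts(ns, ns, ndt, arma::fill::zeros);
  int npart = init_states.size();
  for (int p = 0; p < npart; ++p) {
    int s = init_states[p] - 1;
    for (int k = offsets[p]; k < offsets[p + 1]; ++k) {
      int di = dt_idx[k] - 1;
      double u = unif_rand() * Pcum[di](s, ns - 1);
      int nxt = ns - 1;
      for (int j = 0; j < ns; ++j)
        if (u <= Pcum[di](s, j)) { nxt = j; break; }
      counts(s, nxt, di) += 1.0;
      s = nxt;
    }
  }
  return counts;
}

// Expected first-passage times to `absorbing` (1-based) from every state,
// solving (-Q_TT) tau = 1 on the transient states that can reach it.
// [[Rcpp::export]]
arma::vec absorption_times_cpp(const arma::mat &Q, int absorbing,
                               double rate_tol = 1e-12) {
  int ns = Q.n_rows;
  int a = absorbing - 1;
  // reachability of `a` over edges with rate > rate_tol
  std::vector<bool> reach(ns, false);
  reach[a] = true;
  for (int pass = 0; pass < ns; ++pass)
    for (int i = 0; i < ns; ++i)
      if (!reach[i])
        for (int j = 0; j < ns; ++j)
          if (i != j && Q(i, j) > rate_tol && reach[j]) { reach[i] = true; break; }
  std::vector<int> tr;
  for (int i = 0; i < ns; ++i)
    if (i != a && reach[i]) tr.push_back(i);
  arma::vec tau(ns);
  tau.fill(arma::datum::inf);
  tau(a) = 0.0;
  if (!tr.empty()) {
    arma::uvec idx(tr.size());
    for (size_t k = 0; k < tr.size(); ++k) idx(k) = tr[k];
    arma::mat A = -Q.submat(idx, idx);
    arma::vec ones(tr.size(), arma::fill::ones);
    arma::vec sol;
    bool ok = arma::solve(sol, A, ones, arma::solve_opts::no_approx);
    if (ok)
      for (size_t k = 0; k < tr.size(); ++k) tau(tr[k]) = sol(k);
  }
  return tau;
}

// Parametric bootstrap: simulate panels under Q_hat on the observed design,
// refit, and return absorption times to `absorbing` from `start_states`.
// [[Rcpp::export]]
List parboot_tau_cpp(const arma::vec &logr_hat, const arma::imat &edges,
                     int ns, const arma::vec &dts,
                     const IntegerVector &init_states,
                     const IntegerVector &dt_idx, const IntegerVector &offsets,
                     int n_boot, const IntegerVector &start_states,
                     int absorbing, int maxit = 300, double reltol = 1e-8) {
  arma::mat Qhat = build_generator(arma::exp(logr_hat), edges, ns);
  arma::mat tau_boot(n_boot, start_states.size());
  IntegerVector conv(n_boot);
  int n_fail = 0;
  for (int b = 0; b < n_boot; ++b) {
    if (b % 32 == 0) Rcpp::checkUserInterrupt();
    arma::cube counts =
        sim_panel_counts_cpp(Qhat, dts, init_states, dt_idx, offsets, ns);
    List fit = fit_core(counts, dts, edges, ns, logr_hat, maxit, reltol);
    conv[b] = as<int>(fit["convergence"]);
    if (conv[b] != 0) ++n_fail;
    arma::vec logr = as<arma::vec>(fit["logr"]);
    arma::mat Qb = build_generator(arma::exp(logr), edges, ns);
    arma::vec tau = absorption_times_cpp(Qb, absorbing);
    for (int k = 0; k < start_states.size(); ++k)
      tau_boot(b, k) = tau(start_states[k] - 1);
  }
  return List::create(_["tau"] = tau_boot, _["convergence"] = conv,
                      _["n_fail"] = n_fail);
}
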