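// Bayesian-regularized Levenberg-Marquardt training of the one-neuron
// tanh network  yhat = w2 * tanh(w1 * x + b1) + b2  on normalized data.
//
// Objective (evidence framework, half-sum convention):
//   F = beta * E_D + alpha * E_W,  E_D = 0.5*sum(e^2),  E_W = 0.5*sum(w^2)
// Hyperparameters re-estimated after every accepted step:
//   H = beta * J'J + alpha * I,  gamma = k - alpha * tr(H^-1)
//   alpha = gamma / (2 E_W),     beta = (N - gamma) / (2 E_D)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void neuron_eval(const vec& x, const vec& w, vec& yhat, mat& J) {
  vec t = tanh(w(0) * x + w(1));
  yhat = w(2) * t + w(3);
  vec s = 1.0 - t % t;           // sech^2
  J.col(0) = w(2) * s % x;
  J.col(1) = w(2) * s;
  J.col(2) = t;
  J.col(3).ones();
}

// [[Rcpp::export]]
Rcpp::List cpp_br_train(const arma::vec& x, const arma::vec& y,
                        const arma::vec& w0,
                        int max_iterations, double grad_tol, double obj_tol,
                        double mu0, double mu_inc, double mu_dec,
                        bool bayes) {
  const int k = 4;
  const double N = static_cast<double>(x.n_elem);
  const double mu_max = 1e10;

  vec w = w0;
  vec yhat(x.n_elem);
  mat J(x.n_elem, k);

  double alpha = bayes ? 0.01 : 0.0;
  double beta = 1.0;
  double gamma = k;
  double mu = mu0;

  neuron_eval(x, w, yhat, J);
  vec e = y - yhat;
  double ed = 0.5 * dot(e, e);
  double ew = 0.5 * dot(w, w);
  double F = beta * ed + alpha * ew;

  int iter = 0, stall = 0;
  bool converged = false;
  std::string reason = "max_iterations";
  double gnorm = NA_REAL;

  // per accepted step: F_before, F_accepted (same alpha/beta), then the
  // re-estimated alpha, beta, gamma
  std::vector<double> tr_rows;
  tr_rows.reserve(64 * 5);

  while (iter < max_iterations) {
    ++iter;
    mat JtJ = J.t() * J;
    vec grad = -beta * (J.t() * e) + alpha * w;   // gradient of F
    gnorm = norm(grad, 2);
    if (gnorm <= grad_tol) { converged = true; reason = "gradient"; break; }

    mat H = beta * JtJ + alpha * eye(k, k);

    // inner damping loop: grow mu until a step decreases F (fixed alpha, beta)
    bool accepted = false;
    double F_new = F;
    vec w_new = w, e_new = e, yhat_new = yhat;
    mat J_new = J;
    while (mu <= mu_max) {
      vec step;
      bool ok = solve(step, H + mu * eye(k, k), -grad,
                      solve_opts::no_approx);
      if (ok && step.is_finite()) {
        w_new = w + step;
        neuron_eval(x, w_new, yhat_new, J_new);
        if (yhat_new.is_finite()) {
          e_new = y - yhat_new;
          double ed_new = 0.5 * dot(e_new, e_new);
          double ew_new = 0.5 * dot(w_new, w_new);
          F_new = beta * ed_new + alpha * ew_new;
          if (std::isfinite(F_new) && F_new < F) {
            accepted = true;
            ed = ed_new; ew = ew_new;
            break;
          }
        }
      }
      mu *= mu_inc;
    }
    if (!accepted) { reason = "mu_overflow"; break; }

    double F_before = F;
    double F_accepted = F_new;    // under the alpha/beta used for the step
    w = w_new; e = e_new; yhat = yhat_new; J = J_new;
    mu = std::max(mu * mu_dec, 1e-20);

    if (bayes) {
      // evidence re-estimation at the accepted point
      mat H_acc = beta * (J.t() * J) + alpha * eye(k, k);
      mat Hinv;
      if (inv_sympd(Hinv, H_acc) || inv(Hinv, H_acc)) {
        gamma = k - alpha * trace(Hinv);
        if (gamma < 0.0) gamma = 0.0;
        if (gamma > k) gamma = k;
        alpha = gamma / (2.0 * std::max(ew, 1e-10));
        alpha = std::min(std::max(alpha, 1e-8), 1e8);
        beta = (N - gamma) / (2.0 * std::max(ed, 1e-12));
        beta = std::min(std::max(beta, 1e-8), 1e12);
      }
    }
    F = beta * ed + alpha * ew;

    tr_rows.push_back(F_before); tr_rows.push_back(F_accepted);
    tr_rows.push_back(alpha); tr_rows.push_back(beta);
    tr_rows.push_back(gamma);

    // relative objective stall over 5 consecutive accepted steps,
    // judged under the (alpha, beta) in force when the step was taken
    if (std::fabs(F_before - F_accepted) <=
        obj_tol * std::max(F_before, 1e-30)) {
      if (++stall >= 5) { converged = true; reason = "objective"; break; }
    } else {
      stall = 0;
    }
  }

  mat trace_mat(tr_rows.size() / 5, 5);
  for (uword i = 0; i < trace_mat.n_rows; ++i)
    for (uword j = 0; j < 5; ++j) trace_mat(i, j) = tr_rows[i * 5 + j];

  return Rcpp::List::create(
      Rcpp::Named("w") = Rcpp::NumericVector(w.begin(), w.end()),
      Rcpp::Named("alpha") = alpha, Rcpp::Named("beta") = beta,
      Rcpp::Named("gamma") = gamma, Rcpp::Named("ed") = ed,
      Rcpp::Named("ew") = ew, Rcpp::Named("objective") = F,
      Rcpp::Named("grad_norm") = gnorm,
      Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("reason") = reason,
      Rcpp::Named("trace") = trace_mat);
}
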