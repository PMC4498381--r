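// Multiplicative-update engine for the space-by-time tri-factorization.
// The outer restart loop, initialization and all bookkeeping stay in R;
// this routine only iterates the three block updates from a given start.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void scatter_stats(const cube& A, const ivec& labels, int K,
                          const vec& nk, mat& cm, vec& gmean,
                          double& trsw, double& trsb) {
  const uword S = A.n_slices;
  cm.zeros();
  for (uword s = 0; s < S; ++s) cm.col(labels(s) - 1) += vectorise(A.slice(s));
  gmean = sum(cm, 1) / double(S);
  cm.each_row() /= nk.t();
  trsw = 0.0;
  trsb = 0.0;
  for (uword s = 0; s < S; ++s) {
    vec d = vectorise(A.slice(s)) - cm.col(labels(s) - 1);
    trsw += dot(d, d);
  }
  for (int k = 0; k < K; ++k) {
    vec d = cm.col(k) - gmean;
    trsb += dot(d, d);
  }
}

// [[Rcpp::export]]
Rcpp::List mult_engine_cpp(const arma::cube& Mdat, arma::mat Wt, arma::mat W,
                           arma::cube A, const arma::ivec& labels, int K,
                           double gamma, double delta, int max_iter,
                           double tol, double eps, bool track) {
  const uword T = Mdat.n_rows, M = Mdat.n_cols, S = Mdat.n_slices;
  const uword P = Wt.n_cols, N = W.n_rows;
  const bool discr = (gamma > 0.0) || (delta > 0.0);
  const bool compensate = !discr; // compensated renormalization keeps sNM3F monotone

  vec nk(std::max(K, 1), fill::zeros);
  if (discr) {
    for (uword s = 0; s < S; ++s) nk(labels(s) - 1) += 1.0;
  }
  mat cm(P * N, std::max(K, 1), fill::zeros);
  vec gmean(P * N, fill::zeros);

  mat history(max_iter, 4);
  history.fill(datum::nan);
  double objective = datum::inf;
  bool converged = false;
  int iter = 0;

  while (iter < max_iter) {
    ++iter;
    // spatial-module update: W <- W * (Q'M) / (Q'Q W)
    mat NumW(N, M, fill::zeros), QtQ(N, N, fill::zeros);
    for (uword s = 0; s < S; ++s) {
      mat Q = Wt * A.slice(s);
      NumW += Q.t() * Mdat.slice(s);
      QtQ += Q.t() * Q;
    }
    W %= NumW / (QtQ * W + eps);
    // temporal-module update: Wt <- Wt * (M R') / (Wt R R')
    mat NumT(T, P, fill::zeros), RRt(P, P, fill::zeros);
    for (uword s = 0; s < S; ++s) {
      mat R = A.slice(s) * W;
      NumT += Mdat.slice(s) * R.t();
      RRt += R * R.t();
    }
    Wt %= NumT / (Wt * RRt + eps);
    // unit-sum renormalization before the coefficient update, so the
    // coefficient step re-absorbs the discarded scale within the same
    // iteration (zero-sum module -> uniform)
    rowvec ct = sum(Wt, 0);
    vec cw = sum(W, 1);
    for (uword j = 0; j < P; ++j) {
      if (ct(j) <= 0.0) Wt.col(j).fill(1.0 / double(T));
      else Wt.col(j) /= ct(j);
    }
    for (uword i = 0; i < N; ++i) {
      if (cw(i) <= 0.0) W.row(i).fill(1.0 / double(M));
      else W.row(i) /= cw(i);
    }
    if (compensate) {
      mat F = ct.t() * cw.t();
      for (uword s = 0; s < S; ++s) A.slice(s) %= F;
    }
    // coefficient update, Fisher terms included when discriminating
    mat G1 = Wt.t() * Wt, G2 = W * W.t();
    double trsw = 0.0, trsb = 0.0;
    mat cml, gm, scm;
    if (discr) {
      scatter_stats(A, labels, K, nk, cm, gmean, trsw, trsb);
      gm = reshape(gmean, P, N);
      scm = reshape(vec(sum(cm, 1)), P, N);
    }
    for (uword s = 0; s < S; ++s) {
      mat num = Wt.t() * Mdat.slice(s) * W.t();
      mat den = G1 * A.slice(s) * G2;
      if (discr) {
        int l = labels(s) - 1;
        cml = reshape(cm.col(l), P, N);
        num += (gamma + delta / nk(l)) * cml + (delta * K / double(S)) * gm;
        den += gamma * A.slice(s) + (delta / nk(l)) * gm + (delta / double(S)) * scm;
      }
      A.slice(s) %= num / (den + eps);
    }
    // objective at the end of the iteration
    double e_rec = 0.0;
    for (uword s = 0; s < S; ++s) {
      mat R0 = Mdat.slice(s) - Wt * A.slice(s) * W;
      e_rec += accu(R0 % R0);
    }
    double etot = e_rec;
    double trsw2 = datum::nan, trsb2 = datum::nan;
    if (discr) {
      scatter_stats(A, labels, K, nk, cm, gmean, trsw2, trsb2);
      etot = e_rec + gamma * trsw2 - delta * trsb2;
    }
    if (track) {
      history(iter - 1, 0) = e_rec;
      history(iter - 1, 1) = trsw2;
      history(iter - 1, 2) = trsb2;
      history(iter - 1, 3) = etot;
    }
    if (std::isfinite(objective) &&
        std::abs(objective - etot) <= tol * std::max(std::abs(objective), eps)) {
      objective = etot;
      converged = true;
      break;
    }
    objective = etot;
  }

  double e_nmf = 0.0;
  for (uword s = 0; s < S; ++s) {
    mat R0 = Mdat.slice(s) - Wt * A.slice(s) * W;
    e_nmf += accu(R0 % R0);
  }
  return Rcpp::List::create(
    Rcpp::Named("Wt") = Wt, Rcpp::Named("W") = W, Rcpp::Named("A3") = A,
    Rcpp::Named("e_nmf") = e_nmf, Rcpp::Named("objective") = objective,
    Rcpp::Named("converged") = converged, Rcpp::Named("n_iter") = iter,
    Rcpp::Named("history") = history.head_rows(iter));
}

// Coefficient-only multiplicative updates with fixed modules (projection of
// data onto a fixed module basis; pure reconstruction objective).
// [[Rcpp::export]]
Rcpp::List project_coef_cpp(const arma::cube& Mdat, const arma::mat& Wt,
                            const arma::mat& W, int max_iter, double tol,
                            double eps) {
  const uword S = Mdat.n_slices;
  const uword P = Wt.n_cols, N = W.n_rows;
  cube A(P, N, S, fill::ones);
  mat G1 = Wt.t() * Wt, G2 = W * W.t();
  cube num0(P, N, S);
  for (uword s = 0; s < S; ++s) num0.slice(s) = Wt.t() * Mdat.slice(s) * W.t();
  double prev = datum::inf;
  for (int it = 0; it < max_iter; ++it) {
    double err = 0.0;
    for (uword s = 0; s < S; ++s) {
      A.slice(s) %= num0.slice(s) / (G1 * A.slice(s) * G2 + eps);
      mat R0 = Mdat.slice(s) - Wt * A.slice(s) * W;
      err += accu(R0 % R0);
    }
    if (std::isfinite(prev) &&
        std::abs(prev - err) <= tol * std::max(std::abs(prev), eps)) break;
    prev = err;
  }
  return Rcpp::List::create(Rcpp::Named("A3") = A);
}
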