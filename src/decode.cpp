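// Pairwise linear C-SVC decoding engine.
//
// The pipeline fits on the order of 10^8 classifiers, each on ~8 training
// vectors (4 pseudo-trials per letter), so the solver is a compact SMO for
// tiny soft-margin linear SVMs rather than a general-purpose library call.
// Its solutions are checked against libsvm (via e1071) in the test suite.
//
// All pairwise work runs off one 80 x 80 Gram matrix of the pseudo-trial
// feature vectors: per classifier only an 8 x 8 kernel submatrix and a few
// Gram entries for the test decisions are touched. Within- and across-hand
// schemes share their training sets (same fold skeleton), so each trained
// model is tested on both the same-hand and the other-hand held-out fold.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Solve the dual of a binary C-SVC given a kernel matrix. y in {-1,+1}.
// Maximal-violating-pair working-set selection (libsvm's strategy) with the
// analytic two-variable update; v_t = y_t - g_t plays the role of the
// projected gradient, and the KKT gap is max_lo(v) - min_up(v).
static void smo_solve(const double* K, int n, const double* y, double C,
                      double* alpha, double* b,
                      int max_iter = 2000, double eps = 1e-3) {
  double g[16];  // g_i = sum_j alpha_j y_j K_ij ; n <= 16 always here
  for (int i = 0; i < n; ++i) { alpha[i] = 0.0; g[i] = 0.0; }
  for (int iter = 0; iter < max_iter; ++iter) {
    int i = -1, j = -1;
    double vi = -std::numeric_limits<double>::infinity();
    double vj = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const double v = y[t] - g[t];
      const bool in_lo = (y[t] > 0 && alpha[t] < C - 1e-12) ||
                         (y[t] < 0 && alpha[t] > 1e-12);
      const bool in_up = (y[t] > 0 && alpha[t] > 1e-12) ||
                         (y[t] < 0 && alpha[t] < C - 1e-12);
      if (in_lo && v > vi) { vi = v; i = t; }
      if (in_up && v < vj) { vj = v; j = t; }
    }
    if (i < 0 || j < 0 || vi - vj < eps) break;
    const double s = y[i] * y[j];
    double L, H;
    if (s < 0) {
      L = std::max(0.0, alpha[j] - alpha[i]);
      H = std::min(C, C + alpha[j] - alpha[i]);
    } else {
      L = std::max(0.0, alpha[i] + alpha[j] - C);
      H = std::min(C, alpha[i] + alpha[j]);
    }
    if (H - L < 1e-12) break;
    double eta = K[i * n + i] + K[j * n + j] - 2.0 * K[i * n + j];
    if (eta <= 1e-12) eta = 1e-12;
    // Ei - Ej = -(vi - vj)
    double aj = alpha[j] - y[j] * (vi - vj) / eta;
    aj = std::min(H, std::max(L, aj));
    const double daj = aj - alpha[j];
    if (std::fabs(daj) < 1e-14) break;
    const double dai = -s * daj;
    alpha[i] += dai;
    alpha[j] = aj;
    const double ci = dai * y[i], cj = daj * y[j];
    for (int t = 0; t < n; ++t) g[t] += ci * K[t * n + i] + cj * K[t * n + j];
  }
  // Bias from the KKT conditions: every alpha=0 / alpha=C / free point gives
  // a one-sided (or two-sided) constraint on b via v_i = y_i - g_i; take the
  // midpoint of the feasible interval (free SVs collapse it to a point).
  double up = std::numeric_limits<double>::infinity();
  double lo = -std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i) {
    const double v = y[i] - g[i];
    const bool gives_up = (y[i] > 0 && alpha[i] > 1e-9) ||
                          (y[i] < 0 && alpha[i] < C - 1e-9);
    const bool gives_lo = (y[i] > 0 && alpha[i] < C - 1e-9) ||
                          (y[i] < 0 && alpha[i] > 1e-9);
    if (gives_up) up = std::min(up, v);
    if (gives_lo) lo = std::max(lo, v);
  }
  if (std::isfinite(up) && std::isfinite(lo)) *b = 0.5 * (up + lo);
  else if (std::isfinite(up)) *b = up;
  else *b = lo;
}

// Train a linear C-SVC (rows of Xtr = samples) and return alpha, bias,
// primal weights and decision values for Xte. Thin feature-space wrapper
// around the solver, used directly by pairwise_cv_decode() and by the
// libsvm cross-check tests.
// [[Rcpp::export]]
Rcpp::List cpp_svm_linear(const arma::mat& Xtr, const arma::vec& ytr,
                          const arma::mat& Xte, double C = 1.0) {
  const int n = Xtr.n_rows;
  if (n > 16) Rcpp::stop("solver is specialized for <= 16 training samples");
  arma::mat K = Xtr * Xtr.t();
  arma::vec alpha(n);
  double b = 0.0;
  smo_solve(K.memptr(), n, ytr.memptr(), C, alpha.memptr(), &b);
  arma::vec w = Xtr.t() * (alpha % ytr);
  arma::vec dec = Xte * w + b;
  return Rcpp::List::create(Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("b") = b,
                            Rcpp::Named("w") = w,
                            Rcpp::Named("decision") = dec);
}

// All pairwise within/across accuracies from an 80 x 80 pseudo-trial Gram
// matrix (column layout: (cond-1)*5 + p, conditions 1..8 left hand, 9..16
// right hand). within / across are 2 x 28 accumulators (percent added
// in-place, caller zeroes and normalizes).
static void pairwise_from_gram(const double* G, double C,
                               bool do_within, bool do_across,
                               double* within, double* across) {
  const int N = 80;
  double K[64], alpha[8], y[8];
  int tr[8];
  for (int i = 0; i < 4; ++i) { y[i] = 1.0; y[4 + i] = -1.0; }
  int pair = 0;
  for (int a = 0; a < 8; ++a) {
    for (int bl = a + 1; bl < 8; ++bl, ++pair) {
      for (int hand = 0; hand < 2; ++hand) {
        const int ca = (hand * 8 + a) * 5, cb = (hand * 8 + bl) * 5;
        const int oa = ((1 - hand) * 8 + a) * 5, ob = ((1 - hand) * 8 + bl) * 5;
        double acc_w = 0.0, acc_x = 0.0;
        for (int p = 0; p < 5; ++p) {
          int k = 0;
          for (int q = 0; q < 5; ++q) if (q != p) tr[k++] = ca + q;
          for (int q = 0; q < 5; ++q) if (q != p) tr[k++] = cb + q;
          for (int i = 0; i < 8; ++i)
            for (int j = 0; j < 8; ++j)
              K[i * 8 + j] = G[tr[i] * N + tr[j]];
          double b = 0.0;
          smo_solve(K, 8, y, C, alpha, &b);
          // decision for test column t: sum_i alpha_i y_i G(tr_i, t) + b
          double wa = b, wb = b, xa = b, xb = b;
          for (int i = 0; i < 8; ++i) {
            const double c = alpha[i] * y[i];
            if (c == 0.0) continue;
            const double* Gi = G + (size_t)tr[i] * N;
            if (do_within) { wa += c * Gi[ca + p]; wb += c * Gi[cb + p]; }
            if (do_across) { xa += c * Gi[oa + p]; xb += c * Gi[ob + p]; }
          }
          if (do_within) acc_w += 50.0 * ((wa > 0) + (wb <= 0));
          if (do_across) acc_x += 50.0 * ((xa > 0) + (xb <= 0));
        }
        if (do_within) within[hand + 2 * pair] += acc_w / 5.0;
        // direction index = training hand (0: trained left, tested right)
        if (do_across) across[hand + 2 * pair] += acc_x / 5.0;
      }
    }
  }
}

// Pairwise decoding for one feature snapshot X (features x 80 pseudo-trial
// columns). Fivefold leave-one-pseudo-trial-out CV; within-hand tests the
// held-out same-hand fold, across-hand the other hand's fold of the same
// model. Returns within: 2 (hand) x 28 (pair) and across: 2 (direction:
// trained-left, trained-right) x 28 fold-averaged accuracies in %.
// [[Rcpp::export]]
Rcpp::List cpp_pairwise_set(const arma::mat& X, double C = 1.0,
                            bool do_within = true, bool do_across = true) {
  if (X.n_cols != 80) Rcpp::stop("X must have 80 columns (16 conditions x 5 pseudo-trials)");
  arma::mat G = X.t() * X;
  arma::mat within(2, 28), across(2, 28);
  within.fill(arma::datum::nan);
  across.fill(arma::datum::nan);
  if (do_within) within.zeros();
  if (do_across) across.zeros();
  pairwise_from_gram(G.memptr(), C, do_within, do_across,
                     within.memptr(), across.memptr());
  return Rcpp::List::create(Rcpp::Named("within") = within,
                            Rcpp::Named("across") = across);
}

// Full time-resolved pipeline for one subject.
//
// `data`: channels x samples x trials cube of preprocessed epochs;
// `cond`: 1-based condition index per trial (canonical order).
// Per iteration, trials of each condition are randomly assigned to
// `n_pseudo` disjoint bins of size floor(n_cond/n_pseudo) and averaged;
// per sample, pairwise CV decoding runs on the channel pattern.
// Uses R's RNG, so set.seed upstream gives bit-identical repeats.
//
// Returns within / across as 2 x 28 x samples cubes averaged over folds and
// iterations (hand / direction kept separate).
// [[Rcpp::export]]
Rcpp::List cpp_time_resolved(const arma::cube& data,
                             const arma::ivec& cond,
                             int n_iterations = 100, int n_pseudo = 5,
                             double C = 1.0,
                             bool do_within = true, bool do_across = true) {
  const int n_ch = data.n_rows, n_s = data.n_cols, n_tr = data.n_slices;
  if ((int)cond.n_elem != n_tr) Rcpp::stop("cond length must equal trial count");
  if (n_iterations < 1) Rcpp::stop("n_iterations must be at least 1");
  if (n_pseudo != 5) Rcpp::stop("the fivefold CV engine needs n_pseudo = 5");

  std::vector<std::vector<int>> by_cond(16);
  for (int t = 0; t < n_tr; ++t) {
    if (cond[t] < 1 || cond[t] > 16) Rcpp::stop("condition indices must be 1..16");
    by_cond[cond[t] - 1].push_back(t);
  }
  int min_n = INT_MAX;
  for (int c = 0; c < 16; ++c) min_n = std::min(min_n, (int)by_cond[c].size());
  if (min_n < 1) Rcpp::stop("all 16 conditions must be present");
  const int bin = min_n / n_pseudo;
  if (bin < 1) Rcpp::stop("not enough trials per condition for 5 pseudo-trials");

  arma::cube within(2, 28, n_s, arma::fill::zeros);
  arma::cube across(2, 28, n_s, arma::fill::zeros);
  arma::mat pseudo(n_ch, (size_t)n_s * 80);  // channel patterns, sample-major
  arma::mat Xs(n_ch, 80), G(80, 80);

  Rcpp::RNGScope scope;
  for (int it = 0; it < n_iterations; ++it) {
    // random disjoint bin assignment per condition (Fisher-Yates, R RNG)
    pseudo.zeros();
    for (int c = 0; c < 16; ++c) {
      std::vector<int> idx = by_cond[c];
      const int n = idx.size();
      for (int i = n - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(idx[i], idx[j]);
      }
      for (int p = 0; p < n_pseudo; ++p) {
        const int col0 = c * n_pseudo + p;
        for (int b = 0; b < bin; ++b) {
          const double* sl = data.slice_memptr(idx[p * bin + b]);
          for (int s = 0; s < n_s; ++s) {
            double* dst = pseudo.colptr((size_t)s * 80 + col0);
            const double* src = sl + (size_t)s * n_ch;
            for (int ch = 0; ch < n_ch; ++ch) dst[ch] += src[ch];
          }
        }
      }
    }
    pseudo /= bin;
    for (int s = 0; s < n_s; ++s) {
      Xs = pseudo.cols((size_t)s * 80, (size_t)s * 80 + 79);
      G = Xs.t() * Xs;
      pairwise_from_gram(G.memptr(), C, do_within, do_across,
                         within.slice_memptr(s), across.slice_memptr(s));
    }
    Rcpp::checkUserInterrupt();
  }
  within /= n_iterations;
  across /= n_iterations;
  if (!do_within) within.fill(arma::datum::nan);
  if (!do_across) across.fill(arma::datum::nan);
  return Rcpp::List::create(Rcpp::Named("within") = within,
                            Rcpp::Named("across") = across,
                            Rcpp::Named("n_iterations") = n_iterations,
                            Rcpp::Named("bin_size") = bin);
}
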