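// REML building blocks for study-block-diagonal mixed-model covariances.
//
// The marginal covariance is V = sigma2 * W with, per study block,
//   W = R(rho, gamma_plot) + U diag(g) U',
// where R collects the within-plot residual correlation (independent, AR(1)
// on integer year lags, or compound symmetry) plus the plot random intercept
// (both block diagonal by plot), and U holds the low-rank study-level random
// terms (study intercept/slopes: one column each; study x year: one indicator
// column per year), scaled by their variance ratios g. All solves use the
// Woodbury identity: per-plot Cholesky factors of R (a few years each) plus
// one small m x m system per study, so the cost is linear in the number of
// plot-years. Indefinite covariances at extreme parameters are reported via
// ok = FALSE rather than warnings.
//
// Block fields consumed from R: X (n x p), y (n), U (n x m, unscaled),
// map (m, 1-based index into gamma per U column), plot_start / plot_len
// (1-based run starts and lengths of the contiguous plot runs), year (n),
// plot_gamma (1-based index of the plot variance ratio in gamma, 0 if the
// model has no plot term).

#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// residual + plot-intercept correlation block for one plot run
static void fill_R(arma::mat& Rp, const int* year, int q, double rho,
                   int corr, double gplot) {
  for (int j = 0; j < q; ++j) {
    for (int i = 0; i < q; ++i) {
      double v;
      if (corr == 1) {
        v = std::pow(rho, std::abs(year[i] - year[j]));
      } else if (corr == 2) {
        v = (i == j) ? 1.0 : rho;
      } else {
        v = (i == j) ? 1.0 : 0.0;
      }
      Rp(i, j) = v + gplot;
    }
  }
}

// Per-block Woodbury pieces: on success appends to the accumulators and
// returns true. B = [X y]; returns B' W^-1 B contributions and log|W|.
static bool block_pieces(const List& blk, const arma::vec& gamma, double rho,
                         int corr, arma::mat& BtWiB, double& logdetW,
                         int p) {
  NumericMatrix Xr = blk["X"];
  NumericVector yr = blk["y"];
  NumericMatrix Ur = blk["U"];
  IntegerVector map = blk["map"];
  IntegerVector pstart = blk["plot_start"];
  IntegerVector plen = blk["plot_len"];
  IntegerVector year = blk["year"];
  int plot_gamma = as<int>(blk["plot_gamma"]);
  const int n = Xr.nrow();
  const int m = Ur.ncol();
  const arma::mat X(Xr.begin(), n, p, false, true);
  const arma::vec y(yr.begin(), n, false, true);
  const arma::mat U(Ur.begin(), n, std::max(m, 0), false, true);

  double gplot = (plot_gamma > 0) ? gamma(plot_gamma - 1) : 0.0;

  // B = [X y U_scaled]; compute L^-1 B per plot where R = L L'
  arma::mat B(n, p + 1 + m);
  B.cols(0, p - 1) = X;
  B.col(p) = y;
  for (int j = 0; j < m; ++j) {
    B.col(p + 1 + j) = std::sqrt(gamma(map[j] - 1)) * U.col(j);
  }
  double logdetR = 0.0;
  for (int b = 0; b < pstart.size(); ++b) {
    int s = pstart[b] - 1, q = plen[b];
    arma::mat Rp(q, q);
    fill_R(Rp, &year[s], q, rho, corr, gplot);
    arma::mat Lp;
    if (!arma::chol(Lp, Rp, "lower")) return false;
    for (int i = 0; i < q; ++i) logdetR += 2.0 * std::log(Lp(i, i));
    B.rows(s, s + q - 1) =
      arma::solve(arma::trimatl(Lp), B.rows(s, s + q - 1));
  }
  // Gram matrix of the half-whitened B gives B' R^-1 B
  arma::mat G = B.t() * B;
  arma::mat Q = G.submat(0, 0, p, p);           // [X y]' R^-1 [X y]
  if (m > 0) {
    arma::mat T = G.submat(p + 1, 0, p + m, p); // Us' R^-1 [X y]
    arma::mat M = G.submat(p + 1, p + 1, p + m, p + m);
    M.diag() += 1.0;                            // I + Us' R^-1 Us
    arma::mat LM;
    if (!arma::chol(LM, M, "lower")) return false;
    for (int i = 0; i < m; ++i) logdetW += 2.0 * std::log(LM(i, i));
    arma::mat S = arma::solve(arma::trimatl(LM), T);
    Q -= S.t() * S;                             // Woodbury correction
  }
  logdetW += logdetR;
  BtWiB += Q;
  return true;
}

// Accumulated REML pieces: log|W|, X'W^-1X, X'W^-1y, y'W^-1y.
// [[Rcpp::export]]
List reml_pieces_cpp(List blocks, arma::vec gamma, double rho, int corr,
                     int p) {
  double logdetW = 0.0;
  arma::mat BtWiB(p + 1, p + 1, arma::fill::zeros);
  for (R_xlen_t b = 0; b < blocks.size(); ++b) {
    if (!block_pieces(blocks[b], gamma, rho, corr, BtWiB, logdetW, p)) {
      return List::create(_["ok"] = false);
    }
  }
  return List::create(
    _["ok"] = true, _["logdetW"] = logdetW,
    _["XtWiX"] = BtWiB.submat(0, 0, p - 1, p - 1),
    _["XtWiy"] = BtWiB.submat(0, p, p - 1, p),
    _["ytWiy"] = BtWiB(p, p));
}

// Per-block W^-1 (y - X beta), needed for random-effect predictions (BLUPs).
// [[Rcpp::export]]
List reml_winv_resid_cpp(List blocks, arma::vec gamma, double rho, int corr,
                         arma::vec beta) {
  List out(blocks.size());
  for (R_xlen_t bi = 0; bi < blocks.size(); ++bi) {
    List blk = blocks[bi];
    NumericMatrix Xr = blk["X"];
    NumericVector yr = blk["y"];
    NumericMatrix Ur = blk["U"];
    IntegerVector map = blk["map"];
    IntegerVector pstart = blk["plot_start"];
    IntegerVector plen = blk["plot_len"];
    IntegerVector year = blk["year"];
    int plot_gamma = as<int>(blk["plot_gamma"]);
    const int n = Xr.nrow();
    const int m = Ur.ncol();
    const arma::mat X(Xr.begin(), n, Xr.ncol(), false, true);
    const arma::vec y(yr.begin(), n, false, true);
    const arma::mat U(Ur.begin(), n, std::max(m, 0), false, true);
    double gplot = (plot_gamma > 0) ? gamma(plot_gamma - 1) : 0.0;

    arma::mat B(n, 1 + m);
    B.col(0) = y - X * beta;
    for (int j = 0; j < m; ++j) {
      B.col(1 + j) = std::sqrt(gamma(map[j] - 1)) * U.col(j);
    }
    // full R^-1 solves per plot
    for (int b = 0; b < pstart.size(); ++b) {
      int s = pstart[b] - 1, q = plen[b];
      arma::mat Rp(q, q);
      fill_R(Rp, &year[s], q, rho, corr, gplot);
      B.rows(s, s + q - 1) =
        arma::solve(Rp, B.rows(s, s + q - 1),
                    arma::solve_opts::likely_sympd);
    }
    arma::vec rr = B.col(0);
    if (m > 0) {
      arma::mat RiUs = B.cols(1, m);
      arma::mat M = arma::eye(m, m);
      for (int j = 0; j < m; ++j) {
        M.col(j) += RiUs.t() *
          (std::sqrt(gamma(map[j] - 1)) * U.col(j));
      }
      arma::vec t = RiUs.t() * (y - X * beta);
      rr -= RiUs * arma::solve(M, t);
    }
    out[bi] = rr;
  }
  return out;
}
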