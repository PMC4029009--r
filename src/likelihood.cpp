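// Two-level Gaussian likelihood for LS-COM models.
//
// The model is evaluated from an unconstrained parameter vector theta:
// loadings/intercepts/latent means enter directly, residual variances on the
// log scale, and each free latent covariance block through the log-Cholesky
// factor (diagonal of the factor on the log scale).  Sufficient statistics
// are grouped by cluster size: within each group the pooled within scatter
// uses Sigma_W, and the per-target between vectors (between-only variables
// stacked with rater means) use V_g = Sigma_B + Sigma_W / n_g on the
// rater-mean block.

#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

static const double LOG2PI = 1.8378770664093454836;
static const double BIG = 1e12;

struct LscomModel {
  int p, p_b, p_w, qB, qW, n_theta;
  mat LB0, LW0;
  vec a0, m0, tB0, tW0;
  uvec lb_pos, lb_th, lw_pos, lw_th, a_pos, a_th, m_pos, m_th,
       tb_pos, tb_th, tw_pos, tw_th;
  std::vector<uvec> blkB_idx, blkB_th, blkW_idx, blkW_th;

  void init(const List& m) {
    p = as<int>(m["p"]); p_b = as<int>(m["p_b"]); p_w = as<int>(m["p_w"]);
    qB = as<int>(m["qB"]); qW = as<int>(m["qW"]);
    n_theta = as<int>(m["n_theta"]);
    LB0 = as<mat>(m["LB0"]);
    LW0 = as<mat>(m["LW0"]);
    a0 = as<vec>(m["a0"]); m0 = as<vec>(m["m0"]);
    tB0 = as<vec>(m["tB0"]); tW0 = as<vec>(m["tW0"]);
    lb_pos = as<uvec>(m["lb_pos"]); lb_th = as<uvec>(m["lb_th"]);
    lw_pos = as<uvec>(m["lw_pos"]); lw_th = as<uvec>(m["lw_th"]);
    a_pos = as<uvec>(m["a_pos"]); a_th = as<uvec>(m["a_th"]);
    m_pos = as<uvec>(m["m_pos"]); m_th = as<uvec>(m["m_th"]);
    tb_pos = as<uvec>(m["tb_pos"]); tb_th = as<uvec>(m["tb_th"]);
    tw_pos = as<uvec>(m["tw_pos"]); tw_th = as<uvec>(m["tw_th"]);
    List bB = m["blocks_B"], bW = m["blocks_W"];
    for (int b = 0; b < bB.size(); ++b) {
      List blk = bB[b];
      blkB_idx.push_back(as<uvec>(blk["idx"]));
      blkB_th.push_back(as<uvec>(blk["th"]));
    }
    for (int b = 0; b < bW.size(); ++b) {
      List blk = bW[b];
      blkW_idx.push_back(as<uvec>(blk["idx"]));
      blkW_th.push_back(as<uvec>(blk["th"]));
    }
  }

  // Phi from log-Cholesky block parameterization
  static void fill_phi(mat& Phi, const std::vector<uvec>& bidx,
                       const std::vector<uvec>& bth, const vec& theta) {
    for (size_t b = 0; b < bidx.size(); ++b) {
      const uvec& idx = bidx[b];
      const uvec& th = bth[b];
      int msz = idx.n_elem;
      mat L(msz, msz, arma::fill::zeros);
      int pos = 0;
      for (int c = 0; c < msz; ++c) {
        for (int r = c; r < msz; ++r) {
          double v = theta(th(pos++));
          L(r, c) = (r == c) ? std::exp(v) : v;
        }
      }
      Phi(idx, idx) = L * L.t();
    }
  }

  // implied moments; returns false on numerical failure
  bool moments(const vec& theta, vec& mu, mat& SigB, mat& SigW) const {
    mat LB = LB0;
    for (arma::uword i = 0; i < lb_pos.n_elem; ++i)
      LB(lb_pos(i)) = theta(lb_th(i));
    vec a = a0, mm = m0, tB = tB0, tW = tW0;
    for (arma::uword i = 0; i < a_pos.n_elem; ++i) a(a_pos(i)) = theta(a_th(i));
    for (arma::uword i = 0; i < m_pos.n_elem; ++i) mm(m_pos(i)) = theta(m_th(i));
    for (arma::uword i = 0; i < tb_pos.n_elem; ++i)
      tB(tb_pos(i)) = std::exp(theta(tb_th(i)));
    for (arma::uword i = 0; i < tw_pos.n_elem; ++i)
      tW(tw_pos(i)) = std::exp(theta(tw_th(i)));
    mat PhiB(qB, qB, arma::fill::zeros);
    fill_phi(PhiB, blkB_idx, blkB_th, theta);
    SigB = LB * PhiB * LB.t();
    SigB.diag() += tB;
    if (p_w > 0) {
      mat LW = LW0;
      for (arma::uword i = 0; i < lw_pos.n_elem; ++i)
        LW(lw_pos(i)) = theta(lw_th(i));
      mat PhiW(qW, qW, arma::fill::zeros);
      fill_phi(PhiW, blkW_idx, blkW_th, theta);
      SigW = LW * PhiW * LW.t();
      SigW.diag() += tW;
    } else {
      SigW.set_size(0, 0);
    }
    mu = a + LB * mm;
    return mu.is_finite() && SigB.is_finite() &&
           (p_w == 0 || SigW.is_finite());
  }
};

struct StatGroup {
  double Tg, ng, dg;
  mat SW, SB;
  vec mean;
};

static void read_stats(const List& s, std::vector<StatGroup>& groups) {
  List gl = s["groups"];
  for (int g = 0; g < gl.size(); ++g) {
    List one = gl[g];
    StatGroup sg;
    sg.Tg = as<double>(one["T"]);
    sg.ng = as<double>(one["n"]);
    sg.dg = as<double>(one["d"]);
    sg.SW = as<mat>(one["SW"]);
    sg.SB = as<mat>(one["SB"]);
    sg.mean = as<vec>(one["mean"]);
    groups.push_back(sg);
  }
}

static double neg2ll_core(const LscomModel& M,
                          const std::vector<StatGroup>& groups,
                          const vec& theta) {
  vec mu;
  mat SigB, SigW;
  if (!M.moments(theta, mu, SigB, SigW))
    return BIG + arma::dot(theta, theta);
  double ldW = 0.0;
  mat SigWinv;
  if (M.p_w > 0) {
    mat Lw;
    if (!arma::chol(Lw, SigW, "lower"))
      return BIG + arma::dot(theta, theta);
    ldW = 2.0 * arma::sum(arma::log(Lw.diag()));
    mat Li = arma::inv(arma::trimatl(Lw));
    SigWinv = Li.t() * Li;
  }
  double out = 0.0;
  for (size_t g = 0; g < groups.size(); ++g) {
    const StatGroup& sg = groups[g];
    if (M.p_w > 0 && sg.dg > 0) {
      out += sg.dg * (M.p_w * LOG2PI + ldW) + arma::accu(SigWinv % sg.SW);
    }
    // Jacobian of the (raters) -> (cluster mean, deviations) transformation
    if (M.p_w > 0 && sg.ng > 0) {
      out += sg.Tg * M.p_w * std::log(sg.ng);
    }
    mat V = SigB;
    if (M.p_w > 0 && sg.ng > 0) {
      V.submat(M.p_b, M.p_b, M.p - 1, M.p - 1) += SigW / sg.ng;
    }
    mat Lv;
    if (!arma::chol(Lv, V, "lower"))
      return BIG + arma::dot(theta, theta);
    double ldV = 2.0 * arma::sum(arma::log(Lv.diag()));
    mat Li = arma::inv(arma::trimatl(Lv));
    mat Vinv = Li.t() * Li;
    vec r = sg.mean - mu;
    out += sg.Tg * (M.p * LOG2PI + ldV) + arma::accu(Vinv % sg.SB) +
      sg.Tg * arma::dot(r, Vinv * r);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_neg2ll(const arma::vec& theta, const List& model, const List& stats) {
  LscomModel M;
  M.init(model);
  std::vector<StatGroup> groups;
  read_stats(stats, groups);
  return neg2ll_core(M, groups, theta);
}

// [[Rcpp::export]]
arma::vec cpp_neg2ll_grad(const arma::vec& theta, const List& model,
                          const List& stats, double h = 1e-6) {
  LscomModel M;
  M.init(model);
  std::vector<StatGroup> groups;
  read_stats(stats, groups);
  int n = theta.n_elem;
  vec g(n), th = theta;
  for (int i = 0; i < n; ++i) {
    double hi = h * (1.0 + std::abs(theta(i)));
    th(i) = theta(i) + hi;
    double fp = neg2ll_core(M, groups, th);
    th(i) = theta(i) - hi;
    double fm = neg2ll_core(M, groups, th);
    th(i) = theta(i);
    g(i) = (fp - fm) / (2.0 * hi);
  }
  return g;
}

// [[Rcpp::export]]
arma::mat cpp_neg2ll_hess(const arma::vec& theta, const List& model,
                          const List& stats, double h = 1e-4) {
  LscomModel M;
  M.init(model);
  std::vector<StatGroup> groups;
  read_stats(stats, groups);
  int n = theta.n_elem;
  vec hh(n);
  for (int i = 0; i < n; ++i) hh(i) = h * (1.0 + std::abs(theta(i)));
  double f0 = neg2ll_core(M, groups, theta);
  mat H(n, n);
  vec th = theta;
  for (int i = 0; i < n; ++i) {
    th(i) = theta(i) + hh(i);
    double fp = neg2ll_core(M, groups, th);
    th(i) = theta(i) - hh(i);
    double fm = neg2ll_core(M, groups, th);
    th(i) = theta(i);
    H(i, i) = (fp - 2.0 * f0 + fm) / (hh(i) * hh(i));
    for (int j = i + 1; j < n; ++j) {
      th(i) = theta(i) + hh(i); th(j) = theta(j) + hh(j);
      double fpp = neg2ll_core(M, groups, th);
      th(j) = theta(j) - hh(j);
      double fpm = neg2ll_core(M, groups, th);
      th(i) = theta(i) - hh(i); th(j) = theta(j) + hh(j);
      double fmp = neg2ll_core(M, groups, th);
      th(j) = theta(j) - hh(j);
      double fmm = neg2ll_core(M, groups, th);
      th(i) = theta(i); th(j) = theta(j);
      H(i, j) = H(j, i) = (fpp - fpm - fmp + fmm) / (4.0 * hh(i) * hh(j));
    }
  }
  return H;
}

// [[Rcpp::export]]
List cpp_implied(const arma::vec& theta, const List& model) {
  LscomModel M;
  M.init(model);
  vec mu;
  mat SigB, SigW;
  M.moments(theta, mu, SigB, SigW);
  return List::create(Named("mu") = mu, Named("Sigma_B") = SigB,
                      Named("Sigma_W") = SigW);
}
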