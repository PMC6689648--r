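// Inside-outside kernel for binary-branching weighted grammars.
//
// Mirrors the reference R implementation in R/rule-table.R: half-open spans
// over 1-based positions, per-position leaf rescaling, and per-node-type
// normalization of the branch/emit weight products (every parse of a
// length-l string has exactly l - 1 branch and l emit nodes, so the log
// factors are carried exactly).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Chart {
  // Ihat(span(i,j)) stored as cube slice indexed by (i, j): I(i, j, z)
  cube I;
  mat Bn;  // K x K^2, column index = y1 + y2*K (0-based)
  mat En;  // K x Kg
  mat leafhat;
  double Zhat;
  double logscale;
  bool ok;
};

Chart inside_chart(const vec& root_w, const vec& bc_w, const vec& ec_w,
                   const mat& branch_m, const mat& emit_w, const mat& leaf) {
  Chart ch;
  const int l = leaf.n_rows, K = root_w.n_elem;
  ch.ok = false;
  vec cs = max(leaf, 1);
  if (cs.min() <= 0) return ch;
  ch.leafhat = leaf.each_col() / cs;
  ch.Bn = branch_m.each_col() % bc_w;
  ch.En = emit_w.each_col() % ec_w;
  double cE = ch.En.max();
  if (cE <= 0) return ch;
  ch.En /= cE;
  ch.logscale = accu(log(cs)) + l * std::log(cE);
  if (l >= 2) {
    double cB = ch.Bn.max();
    if (cB <= 0) return ch;
    ch.Bn /= cB;
    ch.logscale += (l - 1) * std::log(cB);
  }
  ch.I = cube(l + 1, l + 1, K, fill::zeros);
  for (int i = 0; i < l; ++i) {
    vec v = ch.En * ch.leafhat.row(i).t();
    for (int z = 0; z < K; ++z) ch.I(i, i + 1, z) = v(z);
  }
  for (int w = 2; w <= l; ++w) {
    for (int i = 0; i + w <= l; ++i) {
      int j = i + w;
      vec u(K * K, fill::zeros);
      for (int k = i + 1; k < j; ++k) {
        for (int y2 = 0; y2 < K; ++y2) {
          double r = ch.I(k, j, y2);
          if (r == 0) continue;
          for (int y1 = 0; y1 < K; ++y1)
            u(y1 + y2 * K) += ch.I(i, k, y1) * r;
        }
      }
      vec v = ch.Bn * u;
      for (int z = 0; z < K; ++z) ch.I(i, j, z) = v(z);
    }
  }
  ch.Zhat = 0;
  for (int z = 0; z < K; ++z) ch.Zhat += root_w(z) * ch.I(0, l, z);
  ch.ok = ch.Zhat > 0;
  return ch;
}

} // namespace

// [[Rcpp::export(name = ".inside_logZ_cpp")]]
double inside_logZ_cpp(const arma::vec& root_w, const arma::vec& bc_w,
                       const arma::vec& ec_w, const arma::mat& branch_m,
                       const arma::mat& emit_w, const arma::mat& leaf) {
  Chart ch = inside_chart(root_w, bc_w, ec_w, branch_m, emit_w, leaf);
  if (!ch.ok) return R_NegInf;
  return std::log(ch.Zhat) + ch.logscale;
}

// [[Rcpp::export(name = ".inside_outside_cpp")]]
Rcpp::List inside_outside_cpp(const arma::vec& root_w, const arma::vec& bc_w,
                              const arma::vec& ec_w, const arma::mat& branch_m,
                              const arma::mat& emit_w, const arma::mat& leaf) {
  const int l = leaf.n_rows, K = root_w.n_elem, Kg = emit_w.n_cols;
  Chart ch = inside_chart(root_w, bc_w, ec_w, branch_m, emit_w, leaf);
  if (!ch.ok)
    Rcpp::stop("string has total weight zero (no parse with positive weight)");
  const double Zhat = ch.Zhat;
  cube O(l + 1, l + 1, K, fill::zeros);
  for (int z = 0; z < K; ++z) O(0, l, z) = root_w(z);
  mat branch_counts(K, K * K, fill::zeros);
  vec branch_choice(K, fill::zeros);
  for (int w = l; w >= 2; --w) {
    for (int i = 0; i + w <= l; ++i) {
      int j = i + w;
      vec oz(K);
      for (int z = 0; z < K; ++z) oz(z) = O(i, j, z);
      for (int z = 0; z < K; ++z) branch_choice(z) += oz(z) * ch.I(i, j, z);
      vec w2 = ch.Bn.t() * oz; // K^2, index y1 + y2*K
      for (int k = i + 1; k < j; ++k) {
        for (int y2 = 0; y2 < K; ++y2) {
          double r = ch.I(k, j, y2);
          for (int y1 = 0; y1 < K; ++y1) {
            double lft = ch.I(i, k, y1);
            double u = lft * r;
            if (u != 0) {
              int col = y1 + y2 * K;
              for (int z = 0; z < K; ++z)
                branch_counts(z, col) += oz(z) * u * ch.Bn(z, col);
            }
            O(i, k, y1) += w2(y1 + y2 * K) * r;
            O(k, j, y2) += w2(y1 + y2 * K) * lft;
          }
        }
      }
    }
  }
  branch_counts /= Zhat;
  branch_choice /= Zhat;
  mat emit_counts(K, Kg, fill::zeros);
  mat resp(l, Kg, fill::zeros);
  for (int i = 0; i < l; ++i) {
    for (int s = 0; s < Kg; ++s) {
      double lh = ch.leafhat(i, s);
      if (lh == 0) continue;
      for (int z = 0; z < K; ++z) {
        double m = O(i, i + 1, z) * ch.En(z, s) * lh / Zhat;
        emit_counts(z, s) += m;
        resp(i, s) += m;
      }
    }
  }
  vec root_counts(K);
  for (int z = 0; z < K; ++z) root_counts(z) = root_w(z) * ch.I(0, l, z) / Zhat;
  return Rcpp::List::create(
      Rcpp::Named("log_Z") = std::log(Zhat) + ch.logscale,
      Rcpp::Named("root_counts") = root_counts,
      Rcpp::Named("branch_choice_counts") = branch_choice,
      Rcpp::Named("branch_counts") = branch_counts,
      Rcpp::Named("emit_counts") = emit_counts,
      Rcpp::Named("resp") = resp);
}
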