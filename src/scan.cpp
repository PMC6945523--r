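#include <Rcpp.h>
using namespace Rcpp;

// Per-SNP univariable regression scans. Each column of G (dosages 0/1/2) is
// regressed on the phenotype separately; these are the building blocks for
// GWAS-style summary statistics at cohort scale, where calling lm()/glm()
// per variant is the bottleneck.

// Simple linear regression of y on each genotype column.
// Returns beta, se, pval (t-test, n-2 df), and a monomorphic flag.
// [[Rcpp::export(name = ".linear_scan_cpp")]]
List linear_scan_cpp(NumericMatrix G, NumericVector y) {
  const int n = G.nrow(), J = G.ncol();
  if (y.size() != n) stop("phenotype length does not match genotype rows");
  NumericVector beta(J), se(J), pval(J);
  LogicalVector mono(J);
  double ybar = mean(y);
  double syy = 0.0;
  for (int i = 0; i < n; ++i) syy += (y[i] - ybar) * (y[i] - ybar);
  for (int j = 0; j < J; ++j) {
    if (syy <= 0.0) {  // constant phenotype: slope 0 with undefined SE
      mono[j] = true; beta[j] = NA_REAL; se[j] = NA_REAL; pval[j] = NA_REAL;
      continue;
    }
    double gsum = 0.0, ggsum = 0.0, gysum = 0.0;
    for (int i = 0; i < n; ++i) {
      double g = G(i, j);
      gsum += g; ggsum += g * g; gysum += g * (y[i] - ybar);
    }
    double gbar = gsum / n;
    double sxx = ggsum - n * gbar * gbar;
    if (sxx <= 0.0 || n < 3) {
      mono[j] = true; beta[j] = NA_REAL; se[j] = NA_REAL; pval[j] = NA_REAL;
      continue;
    }
    double b = gysum / sxx;  // (g - gbar)'(y - ybar) = g'(y - ybar)
    double rss = 0.0;
    for (int i = 0; i < n; ++i) {
      double r = (y[i] - ybar) - b * (G(i, j) - gbar);
      rss += r * r;
    }
    double s2 = rss / (n - 2);
    double sej = std::sqrt(s2 / sxx);
    beta[j] = b; se[j] = sej; mono[j] = false;
    if (sej > 0.0) {
      pval[j] = 2.0 * R::pt(std::fabs(b / sej), n - 2, 0, 0);
    } else {  // exact fit: degenerate p-value convention
      pval[j] = (b == 0.0) ? 1.0 : 0.0;
    }
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["pval"] = pval,
                      _["flagged"] = mono);
}

// Logistic regression of binary y on intercept + each genotype column,
// fitted by Newton-Raphson. Returns the per-allele log-odds slope, its
// Wald SE and two-sided normal p. Non-converged or separated fits are
// flagged alongside monomorphic columns.
// [[Rcpp::export(name = ".logistic_scan_cpp")]]
List logistic_scan_cpp(NumericMatrix G, IntegerVector y,
                       int max_iter = 30, double tol = 1e-8) {
  const int n = G.nrow(), J = G.ncol();
  if (y.size() != n) stop("phenotype length does not match genotype rows");
  double ysum = 0.0;
  for (int i = 0; i < n; ++i) ysum += y[i];
  NumericVector beta(J), se(J), pval(J);
  LogicalVector flag(J);
  if (ysum <= 0.0 || ysum >= n) {  // constant outcome: nothing estimable
    for (int j = 0; j < J; ++j) {
      beta[j] = NA_REAL; se[j] = NA_REAL; pval[j] = NA_REAL; flag[j] = true;
    }
    return List::create(_["beta"] = beta, _["se"] = se, _["pval"] = pval,
                        _["flagged"] = flag);
  }
  double a0 = std::log(ysum / (n - ysum));  // null intercept start
  for (int j = 0; j < J; ++j) {
    // monomorphic check
    double gsum = 0.0, ggsum = 0.0;
    for (int i = 0; i < n; ++i) { gsum += G(i, j); ggsum += G(i, j) * G(i, j); }
    if (ggsum - gsum * gsum / n <= 0.0) {
      beta[j] = NA_REAL; se[j] = NA_REAL; pval[j] = NA_REAL; flag[j] = true;
      continue;
    }
    double a = a0, b = 0.0;
    bool ok = false;
    for (int it = 0; it < max_iter; ++it) {
      double u0 = 0.0, u1 = 0.0;            // score
      double h00 = 0.0, h01 = 0.0, h11 = 0.0;  // information
      for (int i = 0; i < n; ++i) {
        double g = G(i, j);
        double eta = a + b * g;
        double mu = 1.0 / (1.0 + std::exp(-eta));
        double w = mu * (1.0 - mu);
        double r = y[i] - mu;
        u0 += r; u1 += r * g;
        h00 += w; h01 += w * g; h11 += w * g * g;
      }
      double det = h00 * h11 - h01 * h01;
      if (det <= 0.0 || !std::isfinite(det)) break;
      double da = (h11 * u0 - h01 * u1) / det;
      double db = (h00 * u1 - h01 * u0) / det;
      a += da; b += db;
      if (std::fabs(da) < tol && std::fabs(db) < tol) {
        double se_b = std::sqrt(h00 / det);
        if (std::isfinite(se_b) && se_b > 0.0 && std::fabs(b) < 30.0) {
          beta[j] = b; se[j] = se_b;
          pval[j] = 2.0 * R::pnorm(std::fabs(b / se_b), 0.0, 1.0, 0, 0);
          ok = true;
        }
        break;
      }
    }
    flag[j] = !ok;
    if (!ok) { beta[j] = NA_REAL; se[j] = NA_REAL; pval[j] = NA_REAL; }
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["pval"] = pval,
                      _["flagged"] = flag);
}
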