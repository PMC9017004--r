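#include <Rcpp.h>
using namespace Rcpp;

// Genotype dosages 0/1/2 as two Bernoulli(maf) allele draws per individual.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix sim_genotypes_cpp(int n, NumericVector maf) {
  int p = maf.size();
  IntegerMatrix G(n, p);
  for (int j = 0; j < p; ++j) {
    double f = maf[j];
    IntegerMatrix::Column col = G(_, j);
    for (int i = 0; i < n; ++i) {
      col[i] = (unif_rand() < f) + (unif_rand() < f);
    }
  }
  return G;
}

// y += G %*% coef without coercing the integer matrix to double.
// [[Rcpp::export]]
NumericVector geno_score_cpp(IntegerMatrix G, NumericVector coef) {
  int n = G.nrow(), p = G.ncol();
  NumericVector y(n);
  for (int j = 0; j < p; ++j) {
    double a = coef[j];
    if (a == 0.0) continue;
    IntegerMatrix::Column col = G(_, j);
    for (int i = 0; i < n; ++i) y[i] += a * col[i];
  }
  return y;
}

// Per-SNP simple linear regression of y on each genotype column.
// Returns beta, se, eaf; p-values are computed in R.
// [[Rcpp::export]]
List gwas_linear_cpp(IntegerMatrix G, NumericVector y) {
  int n = G.nrow(), p = G.ncol();
  double ybar = mean(y);
  double syy = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = y[i] - ybar;
    syy += d * d;
  }
  NumericVector beta(p), se(p), eaf(p);
  for (int j = 0; j < p; ++j) {
    IntegerMatrix::Column col = G(_, j);
    double sg = 0.0, sgg = 0.0, sgy = 0.0;
    for (int i = 0; i < n; ++i) {
      double g = col[i];
      sg += g;
      sgg += g * g;
      sgy += g * y[i];
    }
    double sxx = sgg - sg * sg / n;
    double sxy = sgy - sg * ybar;
    double b = sxy / sxx;
    double rss = syy - b * sxy;
    if (rss < 0) rss = 0;
    beta[j] = b;
    se[j] = std::sqrt(rss / (n - 2) / sxx);
    eaf[j] = sg / (2.0 * n);
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["eaf"] = eaf);
}

// Per-SNP one-step (score-based) logistic regression for a binary outcome:
// beta = U/I with score U = sum g_c (y - ybar) and information
// I = ybar (1 - ybar) sum g_c^2 evaluated at the null fit.
// [[Rcpp::export]]
List gwas_logistic_cpp(IntegerMatrix G, IntegerVector y) {
  int n = G.nrow(), p = G.ncol();
  double sy = 0.0;
  for (int i = 0; i < n; ++i) sy += y[i];
  double ybar = sy / n;
  double v = ybar * (1.0 - ybar);
  NumericVector beta(p), se(p), eaf(p);
  for (int j = 0; j < p; ++j) {
    IntegerMatrix::Column col = G(_, j);
    double sg = 0.0, sgg = 0.0, sgy = 0.0;
    for (int i = 0; i < n; ++i) {
      double g = col[i];
      sg += g;
      sgg += g * g;
      sgy += g * y[i];
    }
    double sxx = sgg - sg * sg / n;
    double U = sgy - sg * ybar;
    double I = v * sxx;
    beta[j] = U / I;
    se[j] = 1.0 / std::sqrt(I);
    eaf[j] = sg / (2.0 * n);
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["eaf"] = eaf);
}
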