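#include <Rcpp.h>
using namespace Rcpp;

// One Gibbs sweep over regression effects with independent normal
// priors a_j ~ N(0, 1/prec[j]). Samples each effect from its full
// conditional given the current residual e (= y - fit), updating a and e
// in place. xtx holds the column sums of squares. Uses R's RNG so seeds
// set from R make chains reproducible.
// [[Rcpp::export(name = ".gibbs_effect_sweep")]]
void gibbs_effect_sweep(NumericMatrix X, NumericVector e,
                        NumericVector a, NumericVector xtx,
                        NumericVector prec, double sigma2e) {
  int n = X.nrow(), p = X.ncol();
  for (int j = 0; j < p; ++j) {
    double cj = 0.0;
    const double aj = a[j];
    for (int i = 0; i < n; ++i) cj += X(i, j) * e[i];
    cj += xtx[j] * aj;
    const double denom = xtx[j] + prec[j];
    const double mu = cj / denom;
    const double sd = std::sqrt(sigma2e / denom);
    const double anew = R::rnorm(mu, sd);
    const double diff = anew - aj;
    if (diff != 0.0) {
      for (int i = 0; i < n; ++i) e[i] -= X(i, j) * diff;
    }
    a[j] = anew;
  }
}
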