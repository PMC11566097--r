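#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Parameter layout, fixed everywhere: transitions (1->2, 1->3, 2->1, 2->3)
// x terms (intercept, age, cov), 12 values on the conditioned age scale
// eta_ij = alpha_ij + beta_ij * (age - center)/scale + gamma_ij * z.
// Ages outside [lo, hi] are clamped to the boundary before evaluation.

static inline void row_probs(const double* par, double age, double z,
                             double center, double scale,
                             double lo, double hi, double* p) {
  double a = age;
  if (a < lo) a = lo;
  if (a > hi) a = hi;
  double x = (a - center) / scale;
  double e12 = par[0] + par[1] * x + par[2] * z;
  double e13 = par[3] + par[4] * x + par[5] * z;
  double e21 = par[6] + par[7] * x + par[8] * z;
  double e23 = par[9] + par[10] * x + par[11] * z;
  // softmax with max-shift guard against overflow of exp()
  double m1 = 0.0;
  if (e12 > m1) m1 = e12;
  if (e13 > m1) m1 = e13;
  double d1 = std::exp(-m1) + std::exp(e12 - m1) + std::exp(e13 - m1);
  p[0] = std::exp(-m1) / d1;        // p11
  p[1] = std::exp(e12 - m1) / d1;   // p12
  p[2] = std::exp(e13 - m1) / d1;   // p13
  double m2 = 0.0;
  if (e21 > m2) m2 = e21;
  if (e23 > m2) m2 = e23;
  double d2 = std::exp(-m2) + std::exp(e21 - m2) + std::exp(e23 - m2);
  p[3] = std::exp(e21 - m2) / d2;   // p21
  p[4] = std::exp(-m2) / d2;        // p22
  p[5] = std::exp(e23 - m2) / d2;   // p23
}

// Monthly living-row probabilities at each requested age:
// columns p11, p12, p13, p21, p22, p23.
// [[Rcpp::export]]
NumericMatrix cpp_monthly_probs(NumericVector par, NumericVector ages,
                                double z, double center, double scale,
                                double lo, double hi) {
  int n = ages.size();
  NumericMatrix out(n, 6);
  double p[6];
  for (int i = 0; i < n; ++i) {
    row_probs(par.begin(), ages[i], z, center, scale, lo, hi, p);
    for (int k = 0; k < 6; ++k) out(i, k) = p[k];
  }
  return out;
}

// Precompute the monthly probability table over integer ages lo..hi for
// z = 0 and z = 1 (the only covariate values the data can carry).
static void build_table(const double* par, double center, double scale,
                        int lo, int hi, std::vector<double>& tab) {
  int nage = hi - lo + 1;
  tab.resize(2 * nage * 6);
  for (int zi = 0; zi < 2; ++zi)
    for (int a = 0; a < nage; ++a)
      row_probs(par, (double)(lo + a), (double)zi, center, scale,
                (double)lo, (double)hi, &tab[(zi * nage + a) * 6]);
}

static inline const double* tab_at(const std::vector<double>& tab,
                                   int nage, int lo, int hi,
                                   int age, int zi) {
  int a = age;
  if (a < lo) a = lo;
  if (a > hi) a = hi;
  return &tab[(zi * nage + (a - lo)) * 6];
}

// Interval-censored log-likelihood contribution of each transition pair.
// A living->living pair (x0 -> x1) contributes the (s0, s1) entry of the
// product of monthly matrices over ages x0..x1-1.  A death pair with death
// in month x1 contributes sum_j M(x0, x1-1)[s0, j] * p_j3(x1-1): survive in
// some living state j to the month before death, then die in that month.
// Probabilities are floored at 1e-300 before the log.
// [[Rcpp::export]]
NumericVector cpp_pair_loglik(NumericVector par,
                              IntegerVector age_start, IntegerVector age_end,
                              IntegerVector state_start, IntegerVector state_end,
                              IntegerVector z, LogicalVector is_death,
                              double center, double scale,
                              int lo, int hi) {
  int n = age_start.size();
  std::vector<double> tab;
  build_table(par.begin(), center, scale, lo, hi, tab);
  int nage = hi - lo + 1;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int x0 = age_start[i], x1 = age_end[i];
    int s0 = state_start[i], s1 = state_end[i];
    int zi = z[i] ? 1 : 0;
    bool dth = is_death[i];
    double v1 = (s0 == 1) ? 1.0 : 0.0;
    double v2 = (s0 == 2) ? 1.0 : 0.0;
    int last = dth ? (x1 - 1) : x1;
    for (int t = x0; t < last; ++t) {
      const double* p = tab_at(tab, nage, lo, hi, t, zi);
      double nv1 = v1 * p[0] + v2 * p[3];
      double nv2 = v1 * p[1] + v2 * p[4];
      v1 = nv1;
      v2 = nv2;
    }
    double prob;
    if (dth) {
      const double* p = tab_at(tab, nage, lo, hi, last, zi);
      prob = v1 * p[2] + v2 * p[5];
    } else {
      prob = (s1 == 1) ? v1 : v2;
    }
    if (prob < 1e-300) prob = 1e-300;
    out[i] = std::log(prob);
  }
  return out;
}

// State occupancy probabilities month by month from one starting state:
// row t (0-based) is the distribution over (1, 2, 3) at age start_age + t.
// [[Rcpp::export]]
NumericMatrix cpp_occupancy(NumericVector par, int start_age, int start_state,
                            double z, int max_age, double center, double scale,
                            double lo, double hi) {
  int T = max_age - start_age;
  NumericMatrix out(T + 1, 3);
  double v1 = (start_state == 1) ? 1.0 : 0.0;
  double v2 = (start_state == 2) ? 1.0 : 0.0;
  double v3 = 0.0;
  out(0, 0) = v1; out(0, 1) = v2; out(0, 2) = v3;
  double p[6];
  for (int t = 0; t < T; ++t) {
    row_probs(par.begin(), (double)(start_age + t), z, center, scale, lo, hi, p);
    double nv1 = v1 * p[0] + v2 * p[3];
    double nv2 = v1 * p[1] + v2 * p[4];
    v3 += v1 * p[2] + v2 * p[5];
    v1 = nv1;
    v2 = nv2;
    out(t + 1, 0) = v1; out(t + 1, 1) = v2; out(t + 1, 2) = v3;
  }
  return out;
}

// Conditional state expectancies (years) by trapezoidal integration of the
// occupancy curves: returns (e11, e12, e21, e22) for origins 1 and 2.
// [[Rcpp::export]]
NumericVector cpp_expectancies(NumericVector par, int start_age, double z,
                               int max_age, double center, double scale,
                               double lo, double hi) {
  NumericVector out(4);
  for (int origin = 1; origin <= 2; ++origin) {
    int T = max_age - start_age;
    double v1 = (origin == 1) ? 1.0 : 0.0;
    double v2 = (origin == 2) ? 1.0 : 0.0;
    double e1 = 0.5 * v1, e2 = 0.5 * v2;  // half-credit boundary months
    double p[6];
    for (int t = 0; t < T; ++t) {
      row_probs(par.begin(), (double)(start_age + t), z, center, scale, lo, hi, p);
      double nv1 = v1 * p[0] + v2 * p[3];
      double nv2 = v1 * p[1] + v2 * p[4];
      v1 = nv1;
      v2 = nv2;
      double w = (t == T - 1) ? 0.5 : 1.0;
      e1 += w * v1;
      e2 += w * v2;
    }
    out((origin - 1) * 2)     = e1 / 12.0;
    out((origin - 1) * 2 + 1) = e2 / 12.0;
  }
  return out;
}

// Implied (period) prevalence of depression: propagate a living-state
// distribution forward from base_age, renormalising among the living each
// month, and report the depressed share at the requested ages.
// init_state 1 starts all non-depressed, 2 all depressed.
// [[Rcpp::export]]
NumericVector cpp_prevalence(NumericVector par, double z, int base_age,
                             IntegerVector target_ages, int init_state,
                             double center, double scale,
                             double lo, double hi) {
  int n = target_ages.size();
  NumericVector out(n);
  double q1 = (init_state == 1) ? 1.0 : 0.0;
  double q2 = 1.0 - q1;
  int maxt = target_ages[n - 1];
  int j = 0;
  double p[6];
  for (int age = base_age; age <= maxt; ++age) {
    while (j < n && target_ages[j] == age) {
      out[j] = q2 / (q1 + q2);
      ++j;
    }
    if (age == maxt) break;
    row_probs(par.begin(), (double)age, z, center, scale, lo, hi, p);
    double n1 = q1 * p[0] + q2 * p[3];
    double n2 = q1 * p[1] + q2 * p[4];
    double s = n1 + n2;
    if (s > 0.0) {
      q1 = n1 / s;
      q2 = n2 / s;
    }
    // s == 0 only for degenerate kernels with no monthly survivors; the
    // living distribution is then left unchanged
  }
  return out;
}

// Simulate one latent monthly trajectory; states reported at ages
// start_age, start_age+1, ... until absorption in state 3 or max_age.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector cpp_simulate_path(NumericVector par, int start_age,
                                int start_state, double z, int max_age,
                                double center, double scale,
                                double lo, double hi) {
  int T = max_age - start_age;
  std::vector<int> path;
  path.reserve(T + 1);
  int s = start_state;
  path.push_back(s);
  double p[6];
  for (int t = 0; t < T && s != 3; ++t) {
    row_probs(par.begin(), (double)(start_age + t), z, center, scale, lo, hi, p);
    double u = unif_rand();
    const double* row = (s == 1) ? p : p + 3;
    if (u < row[0]) s = 1;
    else if (u < row[0] + row[1]) s = 2;
    else s = 3;
    path.push_back(s);
  }
  return IntegerVector(path.begin(), path.end());
}

// Monte-Carlo occupancy oracle: per path, the trapezoid-weighted months
// spent in states 1 and 2 (weight 1/2 on the first and last month of the
// window, matching the analytic integration convention).
// [[Rcpp::export]]
NumericMatrix cpp_microsim(NumericVector par, int start_age, int start_state,
                           double z, int n_paths, int max_age,
                           double center, double scale,
                           double lo, double hi) {
  int T = max_age - start_age;
  int zi = (z != 0.0) ? 1 : 0;
  std::vector<double> tab;
  build_table(par.begin(), center, scale, (int)lo, (int)hi, tab);
  int nage = (int)hi - (int)lo + 1;
  NumericMatrix out(n_paths, 2);
  for (int i = 0; i < n_paths; ++i) {
    int s = start_state;
    double occ1 = 0.5 * ((s == 1) ? 1.0 : 0.0);
    double occ2 = 0.5 * ((s == 2) ? 1.0 : 0.0);
    for (int t = 0; t < T && s != 3; ++t) {
      const double* p = tab_at(tab, nage, (int)lo, (int)hi, start_age + t, zi);
      double u = unif_rand();
      const double* row = (s == 1) ? p : p + 3;
      if (u < row[0]) s = 1;
      else if (u < row[0] + row[1]) s = 2;
      else s = 3;
      double w = (t == T - 1) ? 0.5 : 1.0;
      if (s == 1) occ1 += w;
      else if (s == 2) occ2 += w;
    }
    out(i, 0) = occ1;
    out(i, 1) = occ2;
  }
  return out;
}
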