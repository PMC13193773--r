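// Gibbs sampler core for univariate/multivariate linear and threshold
// (liability) animal models.  All randomness comes from R's RNG so that
// set.seed() in R makes every run reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// truncated-normal sampling
// ---------------------------------------------------------------------------

// Z ~ N(0,1) | Z > a.  Plain rejection for a < 0.45 (acceptance >= ~0.33),
// Robert (1995) exponential rejection otherwise; stable far in the tail.
static double rtnorm_lower_std(double a) {
  if (a < 0.45) {
    double x;
    do {
      x = R::norm_rand();
    } while (x <= a);
    return x;
  }
  double lambda = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (;;) {
    double x = a + R::exp_rand() / lambda;
    double d = x - lambda;
    if (R::unif_rand() <= std::exp(-0.5 * d * d)) return x;
  }
}

static double rtnorm_one_sided(double mean, double sd, double bound,
                               bool lower) {
  // lower = TRUE: support (bound, Inf); FALSE: support (-Inf, bound]
  double a = (bound - mean) / sd;
  double z = lower ? rtnorm_lower_std(a) : -rtnorm_lower_std(-a);
  return mean + sd * z;
}

//' @noRd
// [[Rcpp::export(name = ".cg_rtnorm")]]
NumericVector cg_rtnorm(int n, double mean, double sd, double bound,
                        bool lower) {
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = rtnorm_one_sided(mean, sd, bound, lower);
  return out;
}

// ---------------------------------------------------------------------------
// inverse Wishart
// ---------------------------------------------------------------------------

static arma::mat rinvwishart(double df, const arma::mat& S) {
  // X ~ Wishart(df, S^{-1}) via Bartlett; return X^{-1} ~ IW(df, S)
  const int p = S.n_rows;
  arma::mat Ssym = arma::symmatu(S);
  arma::mat Sinv;
  if (!arma::inv_sympd(Sinv, Ssym)) {
    Sinv = arma::inv(Ssym + 1e-10 * arma::eye(p, p));
  }
  arma::mat L = arma::chol(arma::symmatu(Sinv), "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; i++) A(i, i) = std::sqrt(R::rchisq(df - i));
  for (int i = 1; i < p; i++)
    for (int j = 0; j < i; j++) A(i, j) = R::norm_rand();
  arma::mat LA = L * A;
  arma::mat W = arma::symmatu(LA * LA.t());
  arma::mat out;
  if (!arma::inv_sympd(out, W)) out = arma::inv(W + 1e-10 * arma::eye(p, p));
  return arma::symmatu(out);
}

//' @noRd
// [[Rcpp::export(name = ".cg_rinvwishart")]]
arma::mat cg_rinvwishart(double df, const arma::mat& S) {
  if (df <= S.n_rows - 1)
    stop("inverse-Wishart degrees of freedom too small (df = %f)", df);
  return rinvwishart(df, S);
}

// ---------------------------------------------------------------------------
// model structure and state
// ---------------------------------------------------------------------------

struct MmeStr {
  int n, T, q;
  arma::mat Y;          // n x T outcomes, NA for missing
  arma::imat miss;      // n x T, 1 = missing
  arma::ivec thresh;    // T, 1 = threshold scale
  std::vector<arma::ivec> colptr;   // per trait, length p_t + 1
  std::vector<arma::ivec> colrows;  // per trait, doe indices (0-based)
  arma::ivec animal_doe;            // q, doe index or -1
  arma::ivec rowptr, colind;        // CSR of symmetric A-inverse
  arma::vec avals;
  double nu_a, nu_e;
  arma::mat Sa, Se;
};

struct GState {
  arma::mat L, E, a;           // n x T, n x T, q x T
  std::vector<arma::vec> b;    // per trait
  arma::mat G0, R0;
};

static MmeStr parse_str(const List& str) {
  MmeStr s;
  s.n = as<int>(str["n"]);
  s.T = as<int>(str["n_traits"]);
  s.q = as<int>(str["q"]);
  s.Y = as<arma::mat>(str["Y"]);
  s.miss = as<arma::imat>(str["miss"]);
  s.thresh = as<arma::ivec>(str["threshold"]);
  List cp = str["colptr"], cr = str["colrows"];
  for (int t = 0; t < s.T; t++) {
    s.colptr.push_back(as<arma::ivec>(cp[t]));
    s.colrows.push_back(as<arma::ivec>(cr[t]));
  }
  s.animal_doe = as<arma::ivec>(str["animal_doe"]);
  s.rowptr = as<arma::ivec>(str["ainv_rowptr"]);
  s.colind = as<arma::ivec>(str["ainv_colind"]);
  s.avals = as<arma::vec>(str["ainv_vals"]);
  s.nu_a = as<double>(str["nu_a"]);
  s.nu_e = as<double>(str["nu_e"]);
  s.Sa = as<arma::mat>(str["S_a"]);
  s.Se = as<arma::mat>(str["S_e"]);
  return s;
}

static GState parse_state(const List& state, const MmeStr& s) {
  GState g;
  g.L = as<arma::mat>(state["L"]);
  g.E = as<arma::mat>(state["E"]);
  g.a = as<arma::mat>(state["a"]);
  List bl = state["b"];
  for (int t = 0; t < s.T; t++) g.b.push_back(as<arma::vec>(bl[t]));
  g.G0 = as<arma::mat>(state["G0"]);
  g.R0 = as<arma::mat>(state["R0"]);
  return g;
}

static List state_to_list(const GState& g) {
  List bl(g.b.size());
  for (size_t t = 0; t < g.b.size(); t++) bl[t] = g.b[t];
  return List::create(_["L"] = g.L, _["E"] = g.E, _["a"] = g.a, _["b"] = bl,
                      _["G0"] = g.G0, _["R0"] = g.R0);
}

static arma::mat safe_inv_sympd(const arma::mat& X) {
  arma::mat out;
  if (!arma::inv_sympd(out, arma::symmatu(X)))
    out = arma::inv(arma::symmatu(X) +
                    1e-10 * arma::eye(X.n_rows, X.n_rows));
  return arma::symmatu(out);
}

// ---------------------------------------------------------------------------
// sweeps
// ---------------------------------------------------------------------------

// Liabilities: for each doe and trait, draw l | everything else.  Observed
// linear entries are data and never redrawn; observed threshold entries are
// truncated at 0 by the outcome; missing entries are drawn untruncated
// (data augmentation).
static void sweep_liab(GState& g, const MmeStr& s, const arma::mat& W) {
  const int T = s.T;
  for (int d = 0; d < s.n; d++) {
    for (int t = 0; t < T; t++) {
      bool missing = s.miss(d, t) == 1;
      bool threshold = s.thresh(t) == 1;
      if (!missing && !threshold) continue;  // linear observed: l = y fixed
      double mu = g.L(d, t) - g.E(d, t);     // x'b + a
      double adj = 0.0;
      for (int u = 0; u < T; u++)
        if (u != t) adj += W(t, u) * g.E(d, u);
      double cmean = mu - adj / W(t, t);
      double csd = std::sqrt(1.0 / W(t, t));
      double lnew;
      if (missing) {
        lnew = cmean + csd * R::norm_rand();
      } else {
        bool lower = s.Y(d, t) > 0.5;  // outcome 1: l > 0; outcome 0: l <= 0
        lnew = rtnorm_one_sided(cmean, csd, 0.0, lower);
      }
      g.E(d, t) += lnew - g.L(d, t);
      g.L(d, t) = lnew;
    }
  }
}

// Fixed effects: scalar Gibbs with flat priors, per trait, per column.
static void sweep_fixed(GState& g, const MmeStr& s, const arma::mat& W) {
  const int T = s.T;
  for (int t = 0; t < T; t++) {
    const arma::ivec& cp = s.colptr[t];
    const arma::ivec& cr = s.colrows[t];
    int p = cp.n_elem - 1;
    for (int j = 0; j < p; j++) {
      int lo = cp(j), hi = cp(j + 1);
      int nj = hi - lo;
      if (nj == 0) continue;
      double num = 0.0;
      for (int k = lo; k < hi; k++) {
        int d = cr(k);
        for (int u = 0; u < T; u++) num += W(t, u) * g.E(d, u);
      }
      double prec = nj * W(t, t);
      double bnew = g.b[t](j) + num / prec + R::norm_rand() / std::sqrt(prec);
      double delta = bnew - g.b[t](j);
      g.b[t](j) = bnew;
      for (int k = lo; k < hi; k++) g.E(cr(k), t) -= delta;
    }
  }
}

// Breeding values: scalar Gibbs in pedigree order using sparse A-inverse
// rows and the current G0 inverse.
static void sweep_animal(GState& g, const MmeStr& s, const arma::mat& W,
                         const arma::mat& Ginv) {
  const int T = s.T;
  arma::vec v(T);
  for (int i = 0; i < s.q; i++) {
    v.zeros();
    double aii = 0.0;
    for (int k = s.rowptr(i); k < s.rowptr(i + 1); k++) {
      int j = s.colind(k);
      double val = s.avals(k);
      if (j == i) aii = val;
      for (int t = 0; t < T; t++) v(t) += val * g.a(j, t);
    }
    int d = s.animal_doe(i);
    for (int t = 0; t < T; t++) {
      double gdotv = 0.0;
      for (int u = 0; u < T; u++) gdotv += Ginv(t, u) * v(u);
      double prec = aii * Ginv(t, t);
      double rhs = -(gdotv - prec * g.a(i, t));
      if (d >= 0) {
        double we = 0.0;
        for (int u = 0; u < T; u++) we += W(t, u) * g.E(d, u);
        rhs += we + W(t, t) * g.a(i, t);
        prec += W(t, t);
      }
      double anew = rhs / prec + R::norm_rand() / std::sqrt(prec);
      double delta = anew - g.a(i, t);
      g.a(i, t) = anew;
      v(t) += aii * delta;
      if (d >= 0) g.E(d, t) -= delta;
    }
  }
}

// --- non-centered (Cholesky) genetic parameterization ----------------------
// a_i = Lam * atil_i with atil ~ N(0, A (x) I_T); the state matrix g.a holds
// atil and Lam carries the scale.  Mixes well when the genetic variance is
// small, where the centered sampler sticks near zero.

// scalar Gibbs over atil in pedigree order
static void sweep_animal_nc(GState& g, const MmeStr& s, const arma::mat& W,
                            const arma::mat& Lam) {
  const int T = s.T;
  arma::vec v(T);
  // c_t' W c_t and W*c_t precomputations: c_t has entries Lam(u,t), u>=t
  arma::mat Wc(T, T);  // column t = W * c_t
  arma::vec cWc(T);
  for (int t = 0; t < T; t++) {
    for (int u = 0; u < T; u++) {
      double acc = 0.0;
      for (int w = t; w < T; w++) acc += W(u, w) * Lam(w, t);
      Wc(u, t) = acc;
    }
    double acc2 = 0.0;
    for (int u = t; u < T; u++) acc2 += Lam(u, t) * Wc(u, t);
    cWc(t) = acc2;
  }
  for (int i = 0; i < s.q; i++) {
    v.zeros();
    double aii = 0.0;
    for (int k = s.rowptr(i); k < s.rowptr(i + 1); k++) {
      int j = s.colind(k);
      double val = s.avals(k);
      if (j == i) aii = val;
      for (int t = 0; t < T; t++) v(t) += val * g.a(j, t);
    }
    int d = s.animal_doe(i);
    for (int t = 0; t < T; t++) {
      double prec = aii;
      double rhs = -(v(t) - aii * g.a(i, t));
      if (d >= 0) {
        double ce = 0.0;   // c' W E over all traits: W couples every trait
        for (int u = 0; u < T; u++) ce += Wc(u, t) * g.E(d, u);
        rhs += ce + cWc(t) * g.a(i, t);
        prec += cWc(t);
      }
      double anew = rhs / prec + R::norm_rand() / std::sqrt(prec);
      double delta = anew - g.a(i, t);
      g.a(i, t) = anew;
      v(t) += aii * delta;
      if (d >= 0)
        for (int u = t; u < T; u++) g.E(d, u) -= Lam(u, t) * delta;
    }
  }
}

// scalar Gibbs over the free elements of the genetic Cholesky factor,
// each a regression coefficient with covariate atil_{i(d), t} on trait u.
// Row u of Lam has u + 1 free elements and G_uu = sum of their squares, so
// each element gets prior variance tau2 / (u + 1): every trait's genetic
// variance then has the same prior scale tau2 regardless of trait order.
static void sweep_lambda(GState& g, const MmeStr& s, const arma::mat& W,
                         arma::mat& Lam, double tau2) {
  const int T = s.T;
  for (int t = 0; t < T; t++) {
    for (int u = t; u < T; u++) {
      double sxx = 0.0, sxe = 0.0;
      for (int i = 0; i < s.q; i++) {
        int d = s.animal_doe(i);
        if (d < 0) continue;
        double x = g.a(i, t);
        double we = 0.0;
        for (int w = 0; w < T; w++) we += W(u, w) * g.E(d, w);
        sxx += x * x;
        sxe += x * we;
      }
      double prec = W(u, u) * sxx + (u + 1) / tau2;
      double mean = (sxe + W(u, u) * Lam(u, t) * sxx) / prec;
      double lnew = mean + R::norm_rand() / std::sqrt(prec);
      double delta = lnew - Lam(u, t);
      Lam(u, t) = lnew;
      if (delta != 0.0) {
        for (int i = 0; i < s.q; i++) {
          int d = s.animal_doe(i);
          if (d >= 0) g.E(d, u) -= delta * g.a(i, t);
        }
      }
    }
  }
}

// M_{jk} = x_j' A^{-1} x_k over traits j,k for an animals-by-traits matrix
static arma::mat ainv_crossprod(const arma::mat& x, const MmeStr& s) {
  const int T = x.n_cols;
  arma::mat M(T, T, arma::fill::zeros);
  arma::vec v(T);
  for (int i = 0; i < s.q; i++) {
    v.zeros();
    for (int k = s.rowptr(i); k < s.rowptr(i + 1); k++) {
      int j = s.colind(k);
      for (int t = 0; t < T; t++) v(t) += s.avals(k) * x(j, t);
    }
    for (int t = 0; t < T; t++)
      for (int u = 0; u < T; u++) M(t, u) += x(i, t) * v(u);
  }
  return arma::symmatu(M);
}

static arma::mat genetic_crossprod(const GState& g, const MmeStr& s) {
  return ainv_crossprod(g.a, s);
}

// ASIS interweaving move for the non-centered chain: holding the
// natural-scale breeding values a = Lam * atil fixed, redraw the genetic
// covariance from its centered conditional p(G | a) ~ |G|^{-q/2}
// exp(-tr(G^{-1} M)/2) * prior, by Metropolis with an
// IW(q - T - 1, M) proposal; the likelihood and proposal terms cancel,
// so acceptance depends only on the prior and Cholesky-Jacobian ratio.
// On acceptance, atil is re-standardized; E and a are unchanged, so this
// move costs one sparse pass and reshuffles the G scale efficiently.
static double lam_prior_logjac(const arma::mat& Lam, double tau2, int T) {
  double lp = 0.0;
  for (int u = 0; u < T; u++) {
    for (int t = 0; t <= u; t++)
      lp += -0.5 * (u + 1) * Lam(u, t) * Lam(u, t) / tau2;
    // Jacobian dG = 2^T prod lam_uu^(T - u) dLam (0-based rows)
    lp -= (T - u) * std::log(std::fabs(Lam(u, u)) + 1e-300);
  }
  return lp;
}

static void asis_interweave(GState& g, const MmeStr& s, arma::mat& Lam,
                            double tau2) {
  const int T = s.T;
  double df = s.q - T - 1;
  if (df <= T - 1) return;
  // canonicalize column signs (positive diagonal) so the state space
  // matches the Cholesky proposals; prior is symmetric and a = Lam * atil
  // is unchanged under the paired sign flip
  for (int t = 0; t < T; t++) {
    if (Lam(t, t) < 0) {
      for (int u = t; u < T; u++) Lam(u, t) = -Lam(u, t);
      g.a.col(t) *= -1.0;
    }
  }
  arma::mat a_nat = g.a * Lam.t();
  arma::mat M = ainv_crossprod(a_nat, s);
  M = arma::symmatu(M) + 1e-10 * arma::eye(T, T);
  arma::mat Gprop = rinvwishart(df, M);
  arma::mat Lprop;
  if (!arma::chol(Lprop, arma::symmatu(Gprop), "lower")) return;
  double log_alpha = lam_prior_logjac(Lprop, tau2, T) -
                     lam_prior_logjac(Lam, tau2, T);
  if (std::log(R::unif_rand()) <= log_alpha) {
    Lam = Lprop;
    g.a = arma::solve(arma::trimatl(Lam), a_nat.t()).t();
  }
}

static void draw_G0(GState& g, const MmeStr& s) {
  arma::mat M = genetic_crossprod(g, s);
  g.G0 = rinvwishart(s.nu_a + s.q, s.Sa + M);
}

// Residual covariance draw on the working (unidentified) scale.  The
// chain itself is never rescaled: for threshold traits the liability
// scale is unidentified by the data, is anchored softly by a proper
// residual prior, and is mapped to the identified unit-residual scale
// only when draws are retained (see report_scales / cg_run_gibbs).
static void draw_R0(GState& g, const MmeStr& s) {
  arma::mat SS = g.E.t() * g.E;
  g.R0 = rinvwishart(s.nu_e + s.n, s.Se + SS);
}

// Residual correlation matrix for all-threshold models: unit diagonal is
// held exactly and each off-diagonal correlation is drawn by griddy Gibbs
// from its full conditional on a fine grid restricted to the positive-
// definite region, under a uniform prior over the feasible correlations.
static void draw_R0_corr(GState& g, const MmeStr& s) {
  const int T = s.T;
  for (int t = 0; t < T; t++) g.R0(t, t) = 1.0;
  if (T == 1) return;
  arma::mat SS = g.E.t() * g.E;
  const int npts = 201;
  arma::vec logp(npts), rs(npts);
  for (int i = 0; i < T; i++) {
    for (int j = i + 1; j < T; j++) {
      double maxlp = -arma::datum::inf;
      for (int k = 0; k < npts; k++) {
        double r = -0.995 + k * (1.99 / (npts - 1));
        rs(k) = r;
        arma::mat R = g.R0;
        R(i, j) = R(j, i) = r;
        double ld, sign;
        arma::log_det(ld, sign, R);
        if (sign <= 0 || !std::isfinite(ld)) {
          logp(k) = -arma::datum::inf;
          continue;
        }
        arma::mat Rinv;
        if (!arma::inv_sympd(Rinv, arma::symmatu(R))) {
          logp(k) = -arma::datum::inf;
          continue;
        }
        logp(k) = -0.5 * s.n * ld - 0.5 * arma::accu(Rinv % SS);
        if (logp(k) > maxlp) maxlp = logp(k);
      }
      double total = 0.0;
      for (int k = 0; k < npts; k++) {
        logp(k) = std::exp(logp(k) - maxlp);
        total += logp(k);
      }
      double u = R::unif_rand() * total;
      int pick = npts - 1;
      double cum = 0.0;
      for (int k = 0; k < npts; k++) {
        cum += logp(k);
        if (cum >= u) { pick = k; break; }
      }
      double rnew = rs(pick);
      g.R0(i, j) = g.R0(j, i) = rnew;
    }
  }
}

// per-trait scale factors mapping the working scale onto the identified
// liability scale (residual variance 1 for threshold traits)
static arma::vec report_scales(const GState& g, const MmeStr& s) {
  arma::vec sc(s.T, arma::fill::ones);
  for (int t = 0; t < s.T; t++)
    if (s.thresh(t) == 1) sc(t) = std::sqrt(g.R0(t, t));
  return sc;
}

// one-shot identification transform: rescale the whole state so that
// threshold-trait residual variances are exactly 1
static void identify_state(GState& g, const MmeStr& s) {
  arma::vec sc = report_scales(g, s);
  const int T = s.T;
  for (int t = 0; t < T; t++)
    for (int u = 0; u < T; u++) {
      g.R0(t, u) /= sc(t) * sc(u);
      g.G0(t, u) /= sc(t) * sc(u);
    }
  for (int t = 0; t < T; t++) {
    if (sc(t) == 1.0) continue;
    g.L.col(t) /= sc(t);
    g.E.col(t) /= sc(t);
    g.a.col(t) /= sc(t);
    g.b[t] /= sc(t);
  }
}

// ---------------------------------------------------------------------------
// exported single-step wrappers (used by unit tests)
// ---------------------------------------------------------------------------

//' @noRd
// [[Rcpp::export(name = ".cg_step_liab")]]
List cg_step_liab(const List& state, const List& str) {
  MmeStr s = parse_str(str);
  GState g = parse_state(state, s);
  arma::mat W = safe_inv_sympd(g.R0);
  sweep_liab(g, s, W);
  return state_to_list(g);
}

//' @noRd
// [[Rcpp::export(name = ".cg_step_location")]]
List cg_step_location(const List& state, const List& str, bool genetic) {
  MmeStr s = parse_str(str);
  GState g = parse_state(state, s);
  arma::mat W = safe_inv_sympd(g.R0);
  sweep_fixed(g, s, W);
  if (genetic) {
    arma::mat Ginv = safe_inv_sympd(g.G0);
    sweep_animal(g, s, W, Ginv);
  }
  return state_to_list(g);
}

//' @noRd
// [[Rcpp::export(name = ".cg_step_G0")]]
arma::mat cg_step_G0(const List& state, const List& str) {
  MmeStr s = parse_str(str);
  GState g = parse_state(state, s);
  if (s.nu_a + s.q <= s.T - 1)
    stop("genetic-variance degrees of freedom too small");
  arma::mat M = genetic_crossprod(g, s);
  arma::mat scale = s.Sa + M;
  if (!scale.is_sympd() && arma::rcond(scale) < 1e-14)
    stop("genetic scale matrix numerically degenerate");
  return rinvwishart(s.nu_a + s.q, scale);
}

//' @noRd
// [[Rcpp::export(name = ".cg_step_R0")]]
List cg_step_R0(const List& state, const List& str, bool rescale) {
  MmeStr s = parse_str(str);
  GState g = parse_state(state, s);
  draw_R0(g, s);
  if (rescale) identify_state(g, s);
  return state_to_list(g);
}

//' @noRd
// [[Rcpp::export(name = ".cg_genetic_crossprod")]]
arma::mat cg_genetic_crossprod(const List& state, const List& str) {
  MmeStr s = parse_str(str);
  GState g = parse_state(state, s);
  return genetic_crossprod(g, s);
}

// ---------------------------------------------------------------------------
// main driver
// ---------------------------------------------------------------------------

//' @noRd
// [[Rcpp::export(name = ".cg_run_gibbs")]]
List cg_run_gibbs(const List& str, const List& init, int n_iter, int burn_in,
                  int thin, bool fix_G0, bool fix_R0, bool noncentered,
                  double lambda_tau2, bool verbose) {
  MmeStr s = parse_str(str);
  GState g = parse_state(init, s);
  const int T = s.T;
  bool genetic = !(fix_G0 && arma::accu(arma::abs(g.G0)) == 0.0);
  bool all_threshold = arma::all(s.thresh == 1);

  if (genetic && !fix_G0 && !noncentered && s.nu_a + s.q <= T - 1)
    stop("genetic-variance prior too weak for %d pedigree animals", s.q);
  if (!fix_R0 && s.nu_e + s.n <= T - 1)
    stop("residual-variance prior too weak for %d record vectors", s.n);

  int n_keep = (n_iter - burn_in) / thin;
  arma::mat G0_draws(n_keep, T * T), R0_draws(n_keep, T * T);
  std::vector<arma::vec> b_sum;
  for (int t = 0; t < T; t++)
    b_sum.push_back(arma::vec(g.b[t].n_elem, arma::fill::zeros));
  arma::mat a_sum(s.q, T, arma::fill::zeros);

  arma::mat W = safe_inv_sympd(g.R0);
  arma::mat Ginv = genetic ? safe_inv_sympd(g.G0) : arma::mat(T, T);

  // non-centered path: g.a holds the standardized effects atil with prior
  // N(0, A (x) I); Lam carries the genetic scale and G0 = Lam Lam'
  arma::mat Lam(T, T, arma::fill::zeros);
  if (noncentered && genetic) {
    arma::mat G0s = arma::symmatu(g.G0) + 1e-8 * arma::eye(T, T);
    Lam = arma::chol(G0s, "lower");
  }

  int kept = 0;
  for (int it = 1; it <= n_iter; it++) {
    sweep_liab(g, s, W);
    sweep_fixed(g, s, W);
    if (genetic) {
      if (noncentered) {
        sweep_animal_nc(g, s, W, Lam);
        if (!fix_G0) {
          sweep_lambda(g, s, W, Lam, lambda_tau2);
          asis_interweave(g, s, Lam, lambda_tau2);
        }
        g.G0 = Lam * Lam.t();
      } else {
        sweep_animal(g, s, W, Ginv);
        if (!fix_G0) {
          draw_G0(g, s);
          Ginv = safe_inv_sympd(g.G0);
        }
      }
    }
    if (!fix_R0) {
      if (all_threshold) draw_R0_corr(g, s);
      else draw_R0(g, s);
      W = safe_inv_sympd(g.R0);
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      // retained draws and location means are reported on the identified
      // liability scale (unit residual variance for threshold traits)
      arma::vec sc = report_scales(g, s);
      arma::mat G0r = g.G0, R0r = g.R0;
      for (int t = 0; t < T; t++)
        for (int u = 0; u < T; u++) {
          G0r(t, u) /= sc(t) * sc(u);
          R0r(t, u) /= sc(t) * sc(u);
        }
      G0_draws.row(kept) = arma::vectorise(G0r).t();
      R0_draws.row(kept) = arma::vectorise(R0r).t();
      for (int t = 0; t < T; t++) b_sum[t] += g.b[t] / sc(t);
      if (noncentered && genetic)
        a_sum += (g.a * Lam.t()) * arma::diagmat(1.0 / sc);
      else
        a_sum += g.a * arma::diagmat(1.0 / sc);
      kept++;
    }
    if (verbose && it % 1000 == 0)
      Rcout << "iteration " << it << " / " << n_iter << "\n";
    if (it % 256 == 0) checkUserInterrupt();
  }

  List b_mean(T);
  for (int t = 0; t < T; t++) b_mean[t] = b_sum[t] / std::max(kept, 1);
  return List::create(_["G0_draws"] = G0_draws, _["R0_draws"] = R0_draws,
                      _["b_mean"] = b_mean,
                      _["a_mean"] = a_sum / std::max(kept, 1),
                      _["n_kept"] = kept, _["final_state"] = state_to_list(g));
}

// ---------------------------------------------------------------------------
// pedigree helpers
// ---------------------------------------------------------------------------

// Meuwissen & Luo (1992) indirect method.  sire/dam are 0-based indices
// into a topologically sorted pedigree; -1 marks an unknown parent.
// Uses the identity 1 + F_i = sum_j c_j^2 d_j over i and its ancestors,
// where c_j are gene-flow coefficients and d_j Mendelian-sampling variances.
//' @noRd
// [[Rcpp::export(name = ".cg_inbreeding_ml")]]
NumericVector cg_inbreeding_ml(const IntegerVector& sire,
                               const IntegerVector& dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> w(n);
  for (int i = 0; i < n; i++) {
    int si = sire[i], di = dam[i];
    if (si == -1 || di == -1) {
      F[i] = 0.0;  // no identity-by-descent loop can close
      continue;
    }
    int top = std::max(si, di);
    std::fill(w.begin(), w.begin() + top + 1, 0.0);
    w[si] += 0.5;
    w[di] += 0.5;
    double acc = 0.0;
    // decreasing index = reverse topological order, so w[j] is complete
    // before j is processed
    for (int j = top; j >= 0; j--) {
      if (w[j] == 0.0) continue;
      int sj = sire[j], dj = dam[j];
      double d_var;
      if (sj >= 0 && dj >= 0)
        d_var = 0.5 - 0.25 * (F[sj] + F[dj]);
      else if (sj >= 0)
        d_var = 0.75 - 0.25 * F[sj];
      else if (dj >= 0)
        d_var = 0.75 - 0.25 * F[dj];
      else
        d_var = 1.0;
      acc += w[j] * w[j] * d_var;
      if (sj >= 0) w[sj] += 0.5 * w[j];
      if (dj >= 0) w[dj] += 0.5 * w[j];
    }
    double d_own = 0.5 - 0.25 * (F[si] + F[di]);
    F[i] = acc + d_own - 1.0;
  }
  return F;
}
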