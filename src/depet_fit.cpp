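// Batch bounded Levenberg-Marquardt for the DEPET inverse problems.
//
// The bootstrap x seed-grid routine performs up to n_sets * n_seeds
// nonlinear least-squares fits (e.g. 10,000 x 125 = 1,250,000), which is the
// package's one hot loop; residuals and analytic Jacobians of the FDQ
// mixture model are evaluated here and only the per-set argmin solution is
// returned.
//
// Modes: 1 = single distance pair (d_r, d_a, log c) against the alpha-alpha
// FDQ set; 2 = dual pair (d_aa_r, d_aa_a, d_ab_r, d_ab_a, log c) against
// stacked alpha-alpha and alpha-beta sets sharing c; 3 = peptide length
// (d, log c), model c * FDQ(d).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct FdqPars {
  std::vector<double> ae, de, Ag, mu, sg;
  double scale;
};

static std::vector<FdqPars> unpack_models(const List& models) {
  std::vector<FdqPars> out;
  out.reserve(models.size());
  for (int i = 0; i < models.size(); ++i) {
    List m = models[i];
    FdqPars p;
    p.ae = as<std::vector<double> >(m["exp_amplitudes"]);
    p.de = as<std::vector<double> >(m["exp_length_constants"]);
    p.Ag = as<std::vector<double> >(m["gauss_amplitudes"]);
    p.mu = as<std::vector<double> >(m["gauss_means"]);
    p.sg = as<std::vector<double> >(m["gauss_sds"]);
    p.scale = as<double>(m["ksv_scale"]);
    out.push_back(p);
  }
  return out;
}

// FDQ value and derivative at d, with the >= 0 clip
static inline void fdq_eval(const FdqPars& m, double d, double& f, double& df) {
  double s = 0.0, ds = 0.0;
  for (size_t i = 0; i < m.ae.size(); ++i) {
    double e = m.ae[i] * std::exp(-d / m.de[i]);
    s += e;
    ds += -e / m.de[i];
  }
  const double inv_sqrt2pi = 0.3989422804014327;
  for (size_t j = 0; j < m.Ag.size(); ++j) {
    double z = (d - m.mu[j]) / m.sg[j];
    double g = m.Ag[j] * inv_sqrt2pi / m.sg[j] * std::exp(-0.5 * z * z);
    s += g;
    ds += -g * z / m.sg[j];
  }
  if (s > 0.0) {
    f = m.scale * s;
    df = m.scale * ds;
  } else {
    f = 0.0;
    df = 0.0;
  }
}

// residuals r (length nr) and Jacobian J (nr x np, column-major)
static void residuals(int mode, const std::vector<FdqPars>& maa,
                      const std::vector<FdqPars>& mab, const double* y, int nf,
                      const double* p, double* r, double* J) {
  int np = (mode == 1) ? 3 : (mode == 2 ? 5 : 2);
  int nr = (mode == 2) ? 2 * nf : nf;
  double c = std::exp(p[np - 1]);
  for (int x = 0; x < nf; ++x) {
    if (mode == 3) {
      double f, df;
      fdq_eval(maa[x], p[0], f, df);
      r[x] = c * f - y[x];
      J[0 * nr + x] = c * df;
      J[1 * nr + x] = c * f;  // d/d(log c)
    } else {
      double fr, dfr, fa, dfa;
      fdq_eval(maa[x], p[0], fr, dfr);
      fdq_eval(maa[x], p[1], fa, dfa);
      r[x] = c * (fr - fa) - y[x];
      J[0 * nr + x] = c * dfr;
      J[1 * nr + x] = -c * dfa;
      J[(np - 1) * nr + x] = c * (fr - fa);
      if (mode == 2) {
        double gr, dgr, ga, dga;
        fdq_eval(mab[x], p[2], gr, dgr);
        fdq_eval(mab[x], p[3], ga, dga);
        int k = nf + x;
        r[k] = c * (gr - ga) - y[x];
        J[0 * nr + k] = 0.0;
        J[1 * nr + k] = 0.0;
        J[2 * nr + k] = c * dgr;
        J[3 * nr + k] = -c * dga;
        J[4 * nr + k] = c * (gr - ga);
        J[2 * nr + x] = 0.0;
        J[3 * nr + x] = 0.0;
      }
    }
  }
}

// solve (A + lambda * diag(A)) x = b for small np; returns false if singular
static bool solve_damped(int np, const double* A, const double* b,
                         double lambda, double* x) {
  double M[25], rhs[5];
  for (int i = 0; i < np; ++i) {
    rhs[i] = b[i];
    for (int j = 0; j < np; ++j) M[i * np + j] = A[i * np + j];
    double d = A[i * np + i];
    M[i * np + i] = d + lambda * (d > 0 ? d : 1e-12);
  }
  for (int k = 0; k < np; ++k) {  // partial-pivot Gaussian elimination
    int piv = k;
    for (int i = k + 1; i < np; ++i)
      if (std::fabs(M[i * np + k]) > std::fabs(M[piv * np + k])) piv = i;
    if (std::fabs(M[piv * np + k]) < 1e-300) return false;
    if (piv != k) {
      for (int j = 0; j < np; ++j) std::swap(M[k * np + j], M[piv * np + j]);
      std::swap(rhs[k], rhs[piv]);
    }
    for (int i = k + 1; i < np; ++i) {
      double f = M[i * np + k] / M[k * np + k];
      for (int j = k; j < np; ++j) M[i * np + j] -= f * M[k * np + j];
      rhs[i] -= f * rhs[k];
    }
  }
  for (int i = np - 1; i >= 0; --i) {
    double s = rhs[i];
    for (int j = i + 1; j < np; ++j) s -= M[i * np + j] * x[j];
    x[i] = s / M[i * np + i];
  }
  return true;
}

static double sse_of(int nr, const double* r) {
  double s = 0.0;
  for (int i = 0; i < nr; ++i) s += r[i] * r[i];
  return s;
}

// one bounded LM minimization from one seed; returns final SSE, p updated
static double lm_minimize(int mode, const std::vector<FdqPars>& maa,
                          const std::vector<FdqPars>& mab, const double* y,
                          int nf, double* p, const double* lower,
                          const double* upper, int max_iter, double tol) {
  int np = (mode == 1) ? 3 : (mode == 2 ? 5 : 2);
  int nr = (mode == 2) ? 2 * nf : nf;
  std::vector<double> r(nr), J(nr * np), rtry(nr), Jtry(nr * np);
  double A[25], g[5], step[5], ptry[5];
  residuals(mode, maa, mab, y, nf, p, r.data(), J.data());
  double sse = sse_of(nr, r.data());
  double lambda = 1e-3;
  for (int it = 0; it < max_iter; ++it) {
    // normal equations
    for (int i = 0; i < np; ++i) {
      g[i] = 0.0;
      for (int k = 0; k < nr; ++k) g[i] -= J[i * nr + k] * r[k];
      for (int j = 0; j <= i; ++j) {
        double s = 0.0;
        for (int k = 0; k < nr; ++k) s += J[i * nr + k] * J[j * nr + k];
        A[i * np + j] = s;
        A[j * np + i] = s;
      }
    }
    bool improved = false;
    for (int tries = 0; tries < 30; ++tries) {
      if (!solve_damped(np, A, g, lambda, step)) {
        lambda *= 10.0;
        continue;
      }
      double maxstep = 0.0;
      for (int i = 0; i < np; ++i) {
        ptry[i] = p[i] + step[i];
        if (ptry[i] < lower[i]) ptry[i] = lower[i];
        if (ptry[i] > upper[i]) ptry[i] = upper[i];
        maxstep = std::max(maxstep, std::fabs(ptry[i] - p[i]));
      }
      residuals(mode, maa, mab, y, nf, ptry, rtry.data(), Jtry.data());
      double sse_try = sse_of(nr, rtry.data());
      if (sse_try < sse) {
        double delta = sse - sse_try;
        for (int i = 0; i < np; ++i) p[i] = ptry[i];
        r.swap(rtry);
        J.swap(Jtry);
        sse = sse_try;
        lambda = std::max(lambda / 3.0, 1e-12);
        improved = true;
        if (delta < tol * (1.0 + sse) || maxstep < 1e-12) return sse;
        break;
      }
      lambda *= 5.0;
      if (lambda > 1e12) return sse;
    }
    if (!improved) return sse;
  }
  return sse;
}

// [[Rcpp::export(name = ".depet_lm_batch")]]
NumericMatrix depet_lm_batch(NumericMatrix Y, List models_aa,
                             Nullable<List> models_ab, NumericMatrix seeds,
                             NumericVector lower, NumericVector upper,
                             int mode, int max_iter = 200,
                             double tol = 1e-10) {
  std::vector<FdqPars> maa = unpack_models(models_aa);
  std::vector<FdqPars> mab;
  if (mode == 2) {
    if (models_ab.isNull()) stop("dual mode needs an alpha-beta FDQ set");
    mab = unpack_models(models_ab.get());
    if (mab.size() != maa.size()) stop("FDQ set sizes differ");
  }
  int n_sets = Y.nrow(), nf = Y.ncol();
  int np = (mode == 1) ? 3 : (mode == 2 ? 5 : 2);
  if (seeds.ncol() != np) stop("seed grid has wrong parameter count");
  if ((int)maa.size() != nf) stop("FDQ set size must match fluorophore count");
  if (lower.size() != np || upper.size() != np) stop("bad bounds length");
  int n_seeds = seeds.nrow();
  NumericMatrix out(n_sets, np + 1);
  std::vector<double> y(nf);
  double p[5], pbest[5];
  for (int s = 0; s < n_sets; ++s) {
    for (int x = 0; x < nf; ++x) y[x] = Y(s, x);
    double best = R_PosInf;
    for (int q = 0; q < n_seeds; ++q) {
      for (int i = 0; i < np; ++i) p[i] = seeds(q, i);
      double sse = lm_minimize(mode, maa, mab, y.data(), nf, p,
                               lower.begin(), upper.begin(), max_iter, tol);
      if (sse < best) {
        best = sse;
        for (int i = 0; i < np; ++i) pbest[i] = p[i];
      }
    }
    for (int i = 0; i < np; ++i) out(s, i) = pbest[i];
    out(s, np) = best;
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
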