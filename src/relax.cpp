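#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Force-balance relaxation of one simulator time step.
//
// Within a time step the previous-step stress/strain histories are frozen,
// so the discretized Jeffreys constitutive relation
//   sigma_n = c_decay * sigma_prev + c1 * (eps_n - eps_prev)
//           + c2 * (eps_n - 2 eps_prev + eps_prev2)
// makes the edge stress affine in the current strain, sigma = C eps + h with
// C = c1 + c2. The per-vertex forces f_j = sum_i (sigma_i + lambda_i) t_hat_i
// are the exact negative gradient of the step energy
//   E(X) = sum_i l0_i (C eps_i^2 / 2 + h_i eps_i) + sum_i lambda_i l_i .
//
// A band-covered edge under sustained tension contracts without bound (the
// Jeffreys material flows at long times), so edges may collapse to zero
// length, where the edge direction loses smoothness. All lengths therefore
// enter through the regularised form
//   l~ = sqrt(l^2 + delta^2),  delta = 1e-2 * l0 :
// edges longer than a few percent of rest length are essentially untouched,
// the energy is smooth everywhere, and an almost-collapsed edge exerts a
// force fading linearly with its length, so coincident vertices sit in a
// genuine smooth equilibrium while band tension transmits through their
// other edges.
//
// The spring-mesh sphere has very soft inextensional bending modes next to
// stiff stretching modes, which makes first-order descent hopeless at tight
// force tolerances. E is therefore minimised by line-search Newton-CG:
// inexact Newton steps from conjugate-gradient solves with analytic
// Hessian-vector products (exact for this energy), falling back to the
// gradient direction on negative curvature, with Armijo backtracking.
// Convergence is declared when the maximum per-vertex force norm is < tol.
//
// edges are 1-based (as in the R mesh object).

namespace {

struct Problem {
  const NumericMatrix &E_;
  const NumericVector &l0, &lambda;
  std::vector<double> h;       // affine stress offset per edge
  double C;                    // stress stiffness c1 + c2
  int nv, ne;
  // per-edge geometry cached by eval() for Hessian-vector products
  std::vector<double> ux, uy, uz, lt, sfac, qfac;

  // Evaluates forces and the per-edge regularised strain/stress at X, and
  // returns the energy CHANGE relative to the reference lengths lt_ref.
  // The per-edge difference has the exact closed form
  //   phi(l2) - phi(l1) = (l2 - l1) [ C (l1 + l2 - 2 l0) / (2 l0) + h + lambda ],
  // which avoids the catastrophic cancellation of subtracting two large
  // energy totals when steps are tiny.
  double eval_delta(const std::vector<double> &X, const std::vector<double> &lt_ref,
                    std::vector<double> &F, NumericVector &sig,
                    NumericVector &eps) {
    std::fill(F.begin(), F.end(), 0.0);
    double dE = 0.0;
    for (int i = 0; i < ne; ++i) {
      const int a = E_(i, 0) - 1, b = E_(i, 1) - 1;
      const double x = X[3 * b] - X[3 * a];
      const double y = X[3 * b + 1] - X[3 * a + 1];
      const double z = X[3 * b + 2] - X[3 * a + 2];
      const double dl = 1e-2 * l0[i];
      const double l = std::sqrt(x * x + y * y + z * z + dl * dl);
      const double lr = std::sqrt(l0[i] * l0[i] + dl * dl);
      const double e = (l - lr) / l0[i];
      eps[i] = e;
      sig[i] = C * e + h[i];
      const double ten = sig[i] + lambda[i];
      const double l1 = lt_ref[i];
      dE += (l - l1) *
            (0.5 * C * (l1 + l - 2.0 * lr) / l0[i] + h[i] + lambda[i]);
      const double s = ten / l;
      ux[i] = x; uy[i] = y; uz[i] = z; lt[i] = l;
      sfac[i] = s;
      qfac[i] = C / (l0[i] * l * l) - ten / (l * l * l);
      F[3 * a] += s * x;  F[3 * a + 1] += s * y;  F[3 * a + 2] += s * z;
      F[3 * b] -= s * x;  F[3 * b + 1] -= s * y;  F[3 * b + 2] -= s * z;
    }
    return dE;
  }

  // w = Hessian(E) * v, using the geometry cached by the last eval()
  void hessvec(const std::vector<double> &v, std::vector<double> &w) const {
    std::fill(w.begin(), w.end(), 0.0);
    for (int i = 0; i < ne; ++i) {
      const int a = E_(i, 0) - 1, b = E_(i, 1) - 1;
      const double tx = v[3 * b] - v[3 * a];
      const double ty = v[3 * b + 1] - v[3 * a + 1];
      const double tz = v[3 * b + 2] - v[3 * a + 2];
      const double ut = ux[i] * tx + uy[i] * ty + uz[i] * tz;
      const double ax = sfac[i] * tx + qfac[i] * ut * ux[i];
      const double ay = sfac[i] * ty + qfac[i] * ut * uy[i];
      const double az = sfac[i] * tz + qfac[i] * ut * uz[i];
      w[3 * a] -= ax;  w[3 * a + 1] -= ay;  w[3 * a + 2] -= az;
      w[3 * b] += ax;  w[3 * b + 1] += ay;  w[3 * b + 2] += az;
    }
  }

  double max_force(const std::vector<double> &F) const {
    double maxf = 0.0;
    for (int j = 0; j < nv; ++j) {
      const double fn = std::sqrt(F[3 * j] * F[3 * j] +
                                  F[3 * j + 1] * F[3 * j + 1] +
                                  F[3 * j + 2] * F[3 * j + 2]);
      if (fn > maxf) maxf = fn;
    }
    return maxf;
  }
};

inline double dot(const std::vector<double> &a, const std::vector<double> &b) {
  double s = 0.0;
  for (size_t q = 0; q < a.size(); ++q) s += a[q] * b[q];
  return s;
}

}  // namespace

// [[Rcpp::export]]
List cpp_relax(NumericMatrix V, IntegerMatrix E, NumericVector l0,
               NumericVector sigma_prev, NumericVector eps_prev,
               NumericVector eps_prev2, NumericVector lambda,
               double c_decay, double c1, double c2,
               double tol, int max_iter, double cap_disp) {
  const int nv = V.nrow();
  const int ne = E.nrow();
  NumericMatrix Emat(E);
  NumericVector sig(ne), eps(ne);

  Problem pb{Emat, l0, lambda, std::vector<double>(ne), c1 + c2, nv, ne,
             std::vector<double>(ne), std::vector<double>(ne),
             std::vector<double>(ne), std::vector<double>(ne),
             std::vector<double>(ne), std::vector<double>(ne)};
  for (int i = 0; i < ne; ++i)
    pb.h[i] = c_decay * sigma_prev[i] - c1 * eps_prev[i] +
              c2 * (eps_prev2[i] - 2.0 * eps_prev[i]);

  const int n = 3 * nv;
  std::vector<double> X(n);
  for (int j = 0; j < nv; ++j)
    for (int d = 0; d < 3; ++d) X[3 * j + d] = V(j, d);

  std::vector<double> F(n), X_old(n);
  std::vector<double> p(n), r(n), z(n), Hp(n);
  std::vector<double> lt_acc(ne, 0.0);

  pb.eval_delta(X, lt_acc, F, sig, eps);
  lt_acc = pb.lt;
  double maxf = pb.max_force(F);

  int iter = 0, stalls = 0;
  const int max_cg = 2000;

  while (maxf >= tol && iter < max_iter && stalls < 5) {
    ++iter;

    // --- inexact Newton direction: CG on  H d = F  (descent for E) ---
    // r = residual, p = search direction in CG, z = accumulated solution
    std::fill(z.begin(), z.end(), 0.0);
    r = F;
    p = F;
    double rr = dot(r, r);
    const double rr0 = rr;
    const double forcing = std::min(0.1, std::sqrt(std::sqrt(rr0)));
    const double cg_tol2 = std::max(forcing * forcing * rr0, 1e-300);
    bool used_grad = true;                  // z == 0 means fall back to F
    for (int cg = 0; cg < max_cg && rr > cg_tol2; ++cg) {
      pb.hessvec(p, Hp);
      const double pHp = dot(p, Hp);
      if (pHp <= 1e-14 * dot(p, p)) {
        // negative/zero curvature: keep what we have (or the gradient)
        break;
      }
      const double alpha = rr / pHp;
      for (int q = 0; q < n; ++q) {
        z[q] += alpha * p[q];
        r[q] -= alpha * Hp[q];
      }
      used_grad = false;
      const double rr_new = dot(r, r);
      const double beta = rr_new / rr;
      rr = rr_new;
      for (int q = 0; q < n; ++q) p[q] = r[q] + beta * p[q];
    }
    std::vector<double> d = used_grad ? F : z;   // copy: eval() rewrites F
    double gd = -dot(F, d);                  // directional derivative of E
    if (gd >= 0.0) { d = F; gd = -dot(F, F); used_grad = true; }

    // cap the largest per-vertex move
    double dmax = 0.0;
    for (int j = 0; j < nv; ++j) {
      const double dn = std::sqrt(d[3 * j] * d[3 * j] +
                                  d[3 * j + 1] * d[3 * j + 1] +
                                  d[3 * j + 2] * d[3 * j + 2]);
      if (dn > dmax) dmax = dn;
    }
    double scale = 1.0;
    if (dmax > cap_disp) scale = cap_disp / dmax;
    if (used_grad && dmax > 0.0)
      scale = std::min(scale, 0.1 * cap_disp / dmax);

    // --- Armijo backtracking on the exact energy difference ---
    X_old = X;
    double t = scale;
    bool moved = false;
    for (int ls = 0; ls < 60; ++ls) {
      for (int q = 0; q < n; ++q) X[q] = X_old[q] + t * d[q];
      const double dE = pb.eval_delta(X, lt_acc, F, sig, eps);
      if (dE <= 1e-4 * t * gd) { moved = true; break; }
      t *= 0.5;
    }
    if (moved) {
      lt_acc = pb.lt;
      stalls = 0;
    } else {
      X = X_old;
      pb.eval_delta(X, lt_acc, F, sig, eps);  // restore cached geometry
      ++stalls;
    }
    maxf = pb.max_force(F);
  }

  NumericMatrix Xout(nv, 3);
  for (int j = 0; j < nv; ++j)
    for (int dd = 0; dd < 3; ++dd) Xout(j, dd) = X[3 * j + dd];
  return List::create(_["positions"] = Xout, _["sigma"] = sig, _["eps"] = eps,
                      _["iterations"] = iter, _["max_force"] = maxf,
                      _["converged"] = (maxf < tol));
}

// Per-vertex force vector for a given configuration (diagnostic / testing).
// [[Rcpp::export]]
NumericMatrix cpp_vertex_forces(NumericMatrix V, IntegerMatrix E,
                                NumericVector tension) {
  const int nv = V.nrow();
  const int ne = E.nrow();
  NumericMatrix F(nv, 3);
  for (int i = 0; i < ne; ++i) {
    const int a = E(i, 0) - 1, b = E(i, 1) - 1;
    const double ux = V(b, 0) - V(a, 0);
    const double uy = V(b, 1) - V(a, 1);
    const double uz = V(b, 2) - V(a, 2);
    const double l = std::sqrt(ux * ux + uy * uy + uz * uz);
    if (l <= 0.0) stop("zero-length edge %d", i + 1);
    const double s = tension[i] / l;
    F(a, 0) += s * ux; F(a, 1) += s * uy; F(a, 2) += s * uz;
    F(b, 0) -= s * ux; F(b, 1) -= s * uy; F(b, 2) -= s * uz;
  }
  return F;
}
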