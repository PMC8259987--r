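// Numerical kernels: explicit Euler-Maruyama stepping of the morphogen
// PDEs on the moving (mapped) rectangle, overdamped subcellular-element
// mechanics, and the 1D reduced gene-expression model integrator.
//
// The moving rectangular domain is mapped to the fixed computational unit
// rectangle (xi, eta) in [0,1]^2 with x1 = xi * L1, x2 = (eta - 1/2) * L2.
// Because the growth velocity is affine, mesh points at fixed (xi, eta) move
// exactly with the flow, so the mesh-relative advection vanishes and the
// transformed equations carry only the metric factors 1/L1^2, 1/L2^2 on the
// Laplacian and the uniform dilution term -(L1'/L1 + L2'/L2) C.

#include <Rcpp.h>
using namespace Rcpp;

static inline double relu(double x) { return x > 0 ? x : 0; }

// 5-point Laplacian in computational coordinates, cell-centered grid.
// Neumann (mirror ghost) everywhere except optional Dirichlet-0 at xi = 0.
static void comp_laplacian(const NumericMatrix& C, NumericMatrix& out,
                           double ax, double ay, bool dirichlet_left) {
  int nx = C.nrow(), ny = C.ncol();
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double c = C(i, j);
      double w = (i > 0) ? C(i - 1, j) : (dirichlet_left ? -c : c);
      double e = (i < nx - 1) ? C(i + 1, j) : c;
      double s = (j > 0) ? C(i, j - 1) : c;
      double n = (j < ny - 1) ? C(i, j + 1) : c;
      out(i, j) = ax * (w + e - 2 * c) + ay * (s + n - 2 * c);
    }
  }
}

// Upwind evaluation of V . grad(C) on the computational grid (used only when
// intracellular advection is switched off, to counter the mesh motion).
static void upwind_vgrad(const NumericMatrix& C, NumericMatrix& out,
                         double gL1, double gL2, int nx, int ny) {
  double dx = 1.0 / nx, dy = 1.0 / ny;
  for (int j = 0; j < ny; ++j) {
    double eta = (j + 0.5) * dy - 0.5;
    double c2 = gL2 * eta; // advection speed in eta (units 1/h in comp coords)
    for (int i = 0; i < nx; ++i) {
      double xi = (i + 0.5) * dx;
      double c1 = gL1 * xi;
      double dCdxi, dCdeta;
      if (c1 >= 0)
        dCdxi = (i > 0) ? (C(i, j) - C(i - 1, j)) / dx : 0.0;
      else
        dCdxi = (i < nx - 1) ? (C(i + 1, j) - C(i, j)) / dx : 0.0;
      if (c2 >= 0)
        dCdeta = (j > 0) ? (C(i, j) - C(i, j - 1)) / dy : 0.0;
      else
        dCdeta = (j < ny - 1) ? (C(i, j + 1) - C(i, j)) / dy : 0.0;
      out(i, j) = c1 * dCdxi + c2 * dCdeta;
    }
  }
}

// [[Rcpp::export]]
List morphogen_steps_cpp(NumericMatrix RAout_, NumericMatrix RAin_,
                         NumericMatrix FGFfree_, NumericMatrix FGFsig_,
                         NumericMatrix Hfield,
                         NumericVector L1s, NumericVector L2s,
                         NumericVector dL1s, NumericVector dL2s,
                         NumericVector ps, double dt,
                         List rp, List fp,
                         bool advect_intracellular,
                         bool multiplicative_noise,
                         bool noise_on) {
  NumericMatrix RAout = clone(RAout_), RAin = clone(RAin_),
                FGFfree = clone(FGFfree_), FGFsig = clone(FGFsig_);
  int nx = RAout.nrow(), ny = RAout.ncol();
  int nsub = L1s.size();
  double Dr = rp["Dr"], vr = rp["vr"], kr = rp["kr"], br = rp["beta_r"],
         kmax = rp["kmax"], k0 = rp["k0"], mu_r1 = rp["mu_r1"],
         mu_r2 = rp["mu_r2"];
  double Df = fp["Df"], vf = fp["vf"], ahf = fp["ahf"], kf = fp["kf"],
         krf = fp["krf"], df1 = fp["df1"], df2 = fp["df2"],
         mu_f1 = fp["mu_f1"], mu_f2 = fp["mu_f2"];
  NumericMatrix lap(nx, ny), adv(nx, ny);
  NumericMatrix RAout_new(nx, ny), RAin_new(nx, ny), FGFfree_new(nx, ny),
                FGFsig_new(nx, ny);
  std::vector<double> Arow(nx), drrow(nx);
  double dx = 1.0 / nx, dy = 1.0 / ny;

  for (int s = 0; s < nsub; ++s) {
    double L1 = L1s[s], L2 = L2s[s], dL1 = dL1s[s], dL2 = dL2s[s], p = ps[s];
    double gL1 = dL1 / L1, gL2 = dL2 / L2, g = gL1 + gL2;
    double ax = 1.0 / (L1 * L1 * dx * dx), ay = 1.0 / (L2 * L2 * dy * dy);
    double dA = (L1 * dx) * (L2 * dy);
    double namp = noise_on ? std::sqrt(dt / dA) : 0.0;
    for (int i = 0; i < nx; ++i) {
      double x1 = (i + 0.5) * dx * L1;
      Arow[i] = vr / (1.0 + std::pow(x1 / p, -20.0));
      drrow[i] = (x1 > p) ? kmax : k0;
    }

    // --- RAout ---
    comp_laplacian(RAout, lap, Dr * ax, Dr * ay, true);
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double rhs = lap(i, j) + Arow[i] + kr * RAin(i, j)
                   - (1.0 + br) * kr * RAout(i, j) - g * RAout(i, j);
        double eta = noise_on ? R::rnorm(0.0, 1.0) : 0.0;
        double amp = multiplicative_noise ? mu_r1 * RAout(i, j) : mu_r1;
        RAout_new(i, j) = relu(RAout(i, j) + dt * rhs + amp * namp * eta);
      }
    }
    // --- RAin ---
    if (!advect_intracellular) upwind_vgrad(RAin, adv, gL1, gL2, nx, ny);
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double rhs = kr * RAout(i, j) - kr * RAin(i, j) - drrow[i] * RAin(i, j);
        rhs += advect_intracellular ? (-g * RAin(i, j)) : adv(i, j);
        double eta = noise_on ? R::rnorm(0.0, 1.0) : 0.0;
        double amp = multiplicative_noise ? mu_r2 * RAin(i, j) : mu_r2;
        RAin_new(i, j) = relu(RAin(i, j) + dt * rhs + amp * namp * eta);
      }
    }
    // --- FGFfree ---
    comp_laplacian(FGFfree, lap, Df * ax, Df * ay, false);
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double H = Hfield(i, j);
        double Af = vf * H * H / (1.0 + ahf * H * H);
        double rhs = lap(i, j) + Af + krf * FGFsig(i, j)
                   - (df1 + kf) * FGFfree(i, j) - g * FGFfree(i, j);
        double eta = noise_on ? R::rnorm(0.0, 1.0) : 0.0;
        double amp = multiplicative_noise ? mu_f1 * FGFfree(i, j) : mu_f1;
        FGFfree_new(i, j) = relu(FGFfree(i, j) + dt * rhs + amp * namp * eta);
      }
    }
    // --- FGFsignal ---
    if (!advect_intracellular) upwind_vgrad(FGFsig, adv, gL1, gL2, nx, ny);
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double rhs = kf * FGFfree(i, j) - krf * FGFsig(i, j)
                   - df2 * FGFsig(i, j);
        rhs += advect_intracellular ? (-g * FGFsig(i, j)) : adv(i, j);
        double eta = noise_on ? R::rnorm(0.0, 1.0) : 0.0;
        double amp = multiplicative_noise ? mu_f2 * FGFsig(i, j) : mu_f2;
        FGFsig_new(i, j) = relu(FGFsig(i, j) + dt * rhs + amp * namp * eta);
      }
    }
    std::swap(RAout, RAout_new); std::swap(RAin, RAin_new);
    std::swap(FGFfree, FGFfree_new); std::swap(FGFsig, FGFsig_new);
  }
  return List::create(_["RAout"] = RAout, _["RAin"] = RAin,
                      _["FGFfree"] = FGFfree, _["FGFsignal"] = FGFsig);
}

// Overdamped subcellular-element update. nodes is (ncell*nnode) x 2 with the
// 2*Nnode = 12 nodes of cell c stored in rows c*nnode .. c*nnode+11.
// sigma holds each cell's krox20 sigmoid sigma(K) in [0,1]; the pairwise
// similarity weight is F = 1 - s_i (1 - s_j) - s_j (1 - s_i).
// [[Rcpp::export]]
NumericMatrix mechanics_step_cpp(NumericMatrix nodes_, NumericVector sigma,
                                 double L1, double L2, double dL1, double dL2,
                                 double dt, List mp,
                                 bool ce_on, bool selective) {
  NumericMatrix nodes = clone(nodes_);
  int nnode = 12;
  int ncell = nodes.nrow() / nnode;
  double k_intra = mp["k_intra"], l_out = mp["l_out"], l_in = mp["l_in"],
         l_inter = mp["l_inter"], A_rep = mp["A_rep"], rho_rep = mp["rho_rep"],
         A_att = mp["A_att"], rho_att = mp["rho_att"],
         node_cutoff = mp["node_cutoff"], pair_cutoff = mp["pair_cutoff"];
  NumericMatrix vel(nodes.nrow(), 2);

  // centroids
  std::vector<double> cx(ncell), cy(ncell);
  for (int c = 0; c < ncell; ++c) {
    double sx = 0, sy = 0;
    for (int k = 0; k < nnode; ++k) {
      sx += nodes(c * nnode + k, 0);
      sy += nodes(c * nnode + k, 1);
    }
    cx[c] = sx / nnode; cy[c] = sy / nnode;
  }

  // intra-cell springs: outer ring, inner ring, same-angle cross-layer
  static const int pa[18] = {0,1,2,3,4,5, 6,7,8,9,10,11, 0,1,2,3,4,5};
  static const int pb[18] = {1,2,3,4,5,0, 7,8,9,10,11,6, 6,7,8,9,10,11};
  for (int c = 0; c < ncell; ++c) {
    for (int e = 0; e < 18; ++e) {
      double l0 = (e < 6) ? l_out : (e < 12 ? l_in : l_inter);
      int ia = c * nnode + pa[e], ib = c * nnode + pb[e];
      double ddx = nodes(ia, 0) - nodes(ib, 0);
      double ddy = nodes(ia, 1) - nodes(ib, 1);
      double d = std::sqrt(ddx * ddx + ddy * ddy);
      if (d < 1e-12) continue;
      double f = -k_intra * (d - l0) / d; // restoring along the pair axis
      vel(ia, 0) += f * ddx; vel(ia, 1) += f * ddy;
      vel(ib, 0) -= f * ddx; vel(ib, 1) -= f * ddy;
    }
  }

  // inter-cell node forces for cell pairs with close centroids
  double pc2 = pair_cutoff * pair_cutoff, nc2 = node_cutoff * node_cutoff;
  for (int a = 0; a < ncell; ++a) {
    for (int b = a + 1; b < ncell; ++b) {
      double dcx = cx[a] - cx[b], dcy = cy[a] - cy[b];
      if (dcx * dcx + dcy * dcy > pc2) continue;
      double F = 0.5;
      if (selective) {
        double si = sigma[a], sj = sigma[b];
        F = 1.0 - si * (1.0 - sj) - sj * (1.0 - si);
      }
      double att = (2.0 * F - 1.0) * A_att;
      // inter-cell forces act between the outer (membrane) layers; the inner
      // layers sit more than the node cutoff away across any normal contact
      for (int ka = 0; ka < 6; ++ka) {
        int ia = a * nnode + ka;
        double xa = nodes(ia, 0), ya = nodes(ia, 1);
        for (int kb = 0; kb < 6; ++kb) {
          int ib = b * nnode + kb;
          double ddx = xa - nodes(ib, 0), ddy = ya - nodes(ib, 1);
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 > nc2 || d2 < 1e-24) continue;
          double d = std::sqrt(d2);
          double f = (A_rep * std::exp(-d / rho_rep)
                      - att * std::exp(-d / rho_att)) / d;
          vel(ia, 0) += f * ddx; vel(ia, 1) += f * ddy;
          vel(ib, 0) -= f * ddx; vel(ib, 1) -= f * ddy;
        }
      }
    }
  }

  // convergent-extension velocity, evaluated at the centroid, same for all
  // nodes of a cell
  if (ce_on) {
    for (int c = 0; c < ncell; ++c) {
      double vx = dL1 * cx[c] / L1, vy = dL2 * cy[c] / L2;
      for (int k = 0; k < nnode; ++k) {
        vel(c * nnode + k, 0) += vx;
        vel(c * nnode + k, 1) += vy;
      }
    }
  }

  for (int i = 0; i < nodes.nrow(); ++i) {
    nodes(i, 0) += dt * vel(i, 0);
    nodes(i, 1) += dt * vel(i, 1);
  }
  return nodes;
}

// 1D reduced gene-expression model on a fixed A-P segment: RA profile is a
// fixed input (quasi-static equilibrium), genes are local SDEs per node, FGF
// (two-morphogen variant only) diffuses explicitly with no-flux ends.
// In the one-morphogen variant krox20 is activated by ark * RAin^2 instead of
// afk * FGF^2 and the FGF equations are dropped.
// [[Rcpp::export]]
List run_1d_core_cpp(NumericVector RAin, NumericMatrix genes_,
                     LogicalVector active,
                     double dx, double dt, double t_max, double tol,
                     List gp, List fp, bool two_morphogen, double ark,
                     bool noise_on) {
  NumericMatrix genes = clone(genes_);
  int n = RAin.size();
  double vh = gp["vh"], ahh = gp["ahh"], arh = gp["arh"], bkh = gp["bkh"],
         bvh = gp["bvh"], dh = gp["dh"], vk = gp["vk"], akk = gp["akk"],
         afk = gp["afk"], bhk = gp["bhk"], dk = gp["dk"], vv = gp["vv"],
         arv = gp["arv"], biv = gp["biv"], dv = gp["dv"], vi = gp["vi"],
         bvi = gp["bvi"], di = gp["di"], mu_h = gp["mu_h"], mu_k = gp["mu_k"],
         mu_v = gp["mu_v"], mu_i = gp["mu_i"];
  double Df = fp["Df"], vf = fp["vf"], ahf = fp["ahf"], kf = fp["kf"],
         krf = fp["krf"], df1 = fp["df1"], df2 = fp["df2"];
  NumericVector Ffree(n), Fsig(n), Ffree_new(n), Fsig_new(n);
  int nstep = (int) std::ceil(t_max / dt);
  int check_every = std::max(1, (int) std::round(0.25 / dt));
  double sdt = std::sqrt(dt);
  bool converged = false;
  int step = 0;
  for (step = 0; step < nstep; ++step) {
    double maxrel = 0.0;
    // FGF diffusion (two-morphogen only)
    if (two_morphogen) {
      for (int i = 0; i < n; ++i) {
        double w = (i > 0) ? Ffree[i - 1] : Ffree[0];
        double e = (i < n - 1) ? Ffree[i + 1] : Ffree[n - 1];
        double lap = (w + e - 2 * Ffree[i]) / (dx * dx);
        double H = active[i] ? genes(i, 0) : 0.0;
        double Af = vf * H * H / (1.0 + ahf * H * H);
        Ffree_new[i] = relu(Ffree[i] + dt * (Df * lap + Af + krf * Fsig[i]
                                             - (df1 + kf) * Ffree[i]));
        Fsig_new[i] = relu(Fsig[i] + dt * (kf * Ffree[i] - krf * Fsig[i]
                                           - df2 * Fsig[i]));
      }
      for (int i = 0; i < n; ++i) {
        double ch = std::fabs(Ffree_new[i] - Ffree[i]) / dt;
        if (ch > maxrel) maxrel = ch;
        Ffree[i] = Ffree_new[i]; Fsig[i] = Fsig_new[i];
      }
    }
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      double H = genes(i, 0), K = genes(i, 1), V = genes(i, 2), I = genes(i, 3);
      double R2 = RAin[i] * RAin[i];
      double act_k = two_morphogen ? afk * Fsig[i] * Fsig[i] : ark * R2;
      double dH = vh * (ahh * H * H + arh * R2)
                / (1 + ahh * H * H + arh * R2 + bkh * K * K + bvh * V * V)
                - dh * H;
      double dK = vk * (akk * K * K + act_k)
                / (1 + akk * K * K + act_k + bhk * H * H) - dk * K;
      double dV = vv * (arv * R2) / (1 + arv * R2 + biv * I * I) - dv * V;
      double dI = vi / (1 + bvi * V * V) - di * I;
      double nh = 0, nk = 0, nv = 0, ni = 0;
      if (noise_on) {
        nh = mu_h * sdt * R::rnorm(0, 1); nk = mu_k * sdt * R::rnorm(0, 1);
        nv = mu_v * sdt * R::rnorm(0, 1); ni = mu_i * sdt * R::rnorm(0, 1);
      }
      double mx = std::max(std::max(std::fabs(dH), std::fabs(dK)),
                           std::max(std::fabs(dV), std::fabs(dI)));
      if (mx > maxrel) maxrel = mx;
      genes(i, 0) = relu(H + dt * dH + nh);
      genes(i, 1) = relu(K + dt * dK + nk);
      genes(i, 2) = relu(V + dt * dV + nv);
      genes(i, 3) = relu(I + dt * dI + ni);
    }
    if (!noise_on && (step % check_every == 0) && maxrel < tol) {
      converged = true;
      break;
    }
  }
  return List::create(_["genes"] = genes, _["FGFfree"] = Ffree,
                      _["FGFsignal"] = Fsig, _["converged"] = converged,
                      _["steps"] = step + 1);
}
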