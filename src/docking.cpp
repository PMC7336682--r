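#include <Rcpp.h>
using namespace Rcpp;

// Rotation matrix (row-major 3x3) from a quaternion (w, x, y, z).
// The quaternion is normalized here; an all-zero quaternion maps to the
// identity rotation.
static void quat_to_mat(const double q[4], double R[9]) {
  double n = std::sqrt(q[0]*q[0] + q[1]*q[1] + q[2]*q[2] + q[3]*q[3]);
  double w, x, y, z;
  if (n == 0.0) { w = 1.0; x = y = z = 0.0; }
  else { w = q[0]/n; x = q[1]/n; y = q[2]/n; z = q[3]/n; }
  R[0] = 1 - 2*(y*y + z*z); R[1] = 2*(x*y - w*z);     R[2] = 2*(x*z + w*y);
  R[3] = 2*(x*y + w*z);     R[4] = 1 - 2*(x*x + z*z); R[5] = 2*(y*z - w*x);
  R[6] = 2*(x*z - w*y);     R[7] = 2*(y*z + w*x);     R[8] = 1 - 2*(x*x + y*y);
}

// Rotate the rows listed in `moved` (0-based) about the axis through
// atoms a->b by angle theta (right-hand rule about the a->b direction).
static void rotate_about_axis(NumericMatrix& X, const IntegerVector& moved,
                              int a, int b, double theta) {
  double ux = X(b,0) - X(a,0), uy = X(b,1) - X(a,1), uz = X(b,2) - X(a,2);
  double n = std::sqrt(ux*ux + uy*uy + uz*uz);
  if (n == 0.0) return;
  ux /= n; uy /= n; uz /= n;
  double c = std::cos(theta), s = std::sin(theta), t = 1 - c;
  double R[9] = {
    t*ux*ux + c,    t*ux*uy - s*uz, t*ux*uz + s*uy,
    t*ux*uy + s*uz, t*uy*uy + c,    t*uy*uz - s*ux,
    t*ux*uz - s*uy, t*uy*uz + s*ux, t*uz*uz + c
  };
  double ox = X(a,0), oy = X(a,1), oz = X(a,2);
  for (int k = 0; k < moved.size(); ++k) {
    int i = moved[k];
    double px = X(i,0) - ox, py = X(i,1) - oy, pz = X(i,2) - oz;
    X(i,0) = R[0]*px + R[1]*py + R[2]*pz + ox;
    X(i,1) = R[3]*px + R[4]*py + R[5]*pz + oy;
    X(i,2) = R[6]*px + R[7]*py + R[8]*pz + oz;
  }
}

// Apply a docking genotype to reference coordinates.
// branches: list of list(axis = int[2] (1-based), moved = int[] (1-based)),
// ordered root-outward; torsions are applied innermost-branch-first so
// every axis is still at its reference-frame position when used.
// [[Rcpp::export(name = ".apply_pose_cpp")]]
NumericMatrix apply_pose_cpp(NumericMatrix ref, List branches,
                             NumericVector torsions, NumericVector quat,
                             NumericVector translation, int anchor) {
  NumericMatrix X = clone(ref);
  int nb = branches.size();
  for (int k = nb - 1; k >= 0; --k) {
    List br = branches[k];
    IntegerVector axis = br["axis"];
    IntegerVector moved = br["moved"];
    IntegerVector moved0 = clone(moved);
    for (int j = 0; j < moved0.size(); ++j) moved0[j] -= 1;
    rotate_about_axis(X, moved0, axis[0] - 1, axis[1] - 1, torsions[k]);
  }
  double q[4] = {quat[0], quat[1], quat[2], quat[3]};
  double R[9];
  quat_to_mat(q, R);
  int a = anchor - 1;
  double ox = X(a,0), oy = X(a,1), oz = X(a,2);
  int n = X.nrow();
  for (int i = 0; i < n; ++i) {
    double px = X(i,0) - ox, py = X(i,1) - oy, pz = X(i,2) - oz;
    X(i,0) = R[0]*px + R[1]*py + R[2]*pz + ox + translation[0];
    X(i,1) = R[3]*px + R[4]*py + R[5]*pz + oy + translation[1];
    X(i,2) = R[6]*px + R[7]*py + R[8]*pz + oz + translation[2];
  }
  return X;
}

static double trilinear_one(const NumericVector& grid, const IntegerVector& npts,
                            const NumericVector& origin, double spacing,
                            double x, double y, double z, double penalty,
                            bool& outside) {
  double gx = (x - origin[0]) / spacing;
  double gy = (y - origin[1]) / spacing;
  double gz = (z - origin[2]) / spacing;
  int nx = npts[0], ny = npts[1], nz = npts[2];
  if (gx < 0 || gy < 0 || gz < 0 || gx > nx - 1 || gy > ny - 1 || gz > nz - 1) {
    outside = true;
    return penalty;
  }
  outside = false;
  int ix = (int)std::floor(gx), iy = (int)std::floor(gy), iz = (int)std::floor(gz);
  if (ix == nx - 1) ix--;
  if (iy == ny - 1) iy--;
  if (iz == nz - 1) iz--;
  double fx = gx - ix, fy = gy - iy, fz = gz - iz;
  // grid is an R array indexed [ix, iy, iz], column-major
  #define G(i,j,k) grid[(i) + nx*((j) + (size_t)ny*(k))]
  double c00 = G(ix,iy,iz)     * (1-fx) + G(ix+1,iy,iz)     * fx;
  double c10 = G(ix,iy+1,iz)   * (1-fx) + G(ix+1,iy+1,iz)   * fx;
  double c01 = G(ix,iy,iz+1)   * (1-fx) + G(ix+1,iy,iz+1)   * fx;
  double c11 = G(ix,iy+1,iz+1) * (1-fx) + G(ix+1,iy+1,iz+1) * fx;
  #undef G
  double c0 = c00 * (1-fy) + c10 * fy;
  double c1 = c01 * (1-fy) + c11 * fy;
  return c0 * (1-fz) + c1 * fz;
}

// [[Rcpp::export(name = ".trilinear_cpp")]]
double trilinear_cpp(NumericVector grid, IntegerVector npts,
                     NumericVector origin, double spacing,
                     NumericVector point, double penalty) {
  bool outside;
  return trilinear_one(grid, npts, origin, spacing,
                       point[0], point[1], point[2], penalty, outside);
}

// Grid-based intermolecular energy plus pairwise ligand internal energy.
// type_idx: 1-based index of each atom's affinity grid in `type_grids`.
// pairs: 4-column matrix (i, j, eps, req) of 1-based internal pairs
// (>= 3 bonds apart). Internal terms: LJ 12-6 with well depth eps at
// req, plus Coulomb q_i q_j / (4 r^2) (distance-dependent dielectric 4r).
// [[Rcpp::export(name = ".score_coords_cpp")]]
List score_coords_cpp(NumericMatrix coords, IntegerVector type_idx,
                      NumericVector charges, List type_grids,
                      NumericVector elec_grid, IntegerVector npts,
                      NumericVector origin, double spacing,
                      NumericMatrix pairs, double penalty) {
  int n = coords.nrow();
  double e_inter = 0.0;
  for (int i = 0; i < n; ++i) {
    NumericVector g = type_grids[type_idx[i] - 1];
    bool outside;
    double aff = trilinear_one(g, npts, origin, spacing,
                               coords(i,0), coords(i,1), coords(i,2),
                               penalty, outside);
    if (outside) {
      e_inter += penalty;  // one penalty per offending atom
      continue;
    }
    double ele = trilinear_one(elec_grid, npts, origin, spacing,
                               coords(i,0), coords(i,1), coords(i,2),
                               penalty, outside);
    e_inter += aff + charges[i] * ele;
  }
  double e_internal = 0.0;
  int np = pairs.nrow();
  for (int k = 0; k < np; ++k) {
    int i = (int)pairs(k,0) - 1, j = (int)pairs(k,1) - 1;
    double eps = pairs(k,2), req = pairs(k,3);
    double dx = coords(i,0) - coords(j,0);
    double dy = coords(i,1) - coords(j,1);
    double dz = coords(i,2) - coords(j,2);
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 < 1e-12) r2 = 1e-12;
    double s2 = req*req / r2;
    double s6 = s2*s2*s2;
    double lj = eps * (s6*s6 - 2.0*s6);
    if (lj > penalty) lj = penalty;
    e_internal += lj + charges[i]*charges[j] / (4.0 * r2);
  }
  return List::create(Named("E_inter") = e_inter,
                      Named("E_internal") = e_internal);
}

// Accumulate receptor contributions onto grid maps.
// node coordinates: origin + spacing * (ix, iy, iz), column-major arrays.
// For each ligand atom type t: sum over receptor atoms of the 12-6 term
// with pair parameters (eps_pair, req_pair); electrostatic map: sum of
// q_rec / (4 r^2). Values capped at `cap` near clashes.
// Generalized Mie/LJ pair term normalized to a minimum of -eps at req:
//   E(r) = eps/(m-n) * (n*(req/r)^m - m*(req/r)^n),  m > n
// (m, n) = (12, 6) is the classic form; smaller exponents give wider,
// softer wells.
static inline double mie(double eps, double req, double r2,
                         double m, double n) {
  double s = req / std::sqrt(r2);
  return eps / (m - n) * (n * std::pow(s, m) - m * std::pow(s, n));
}

// [[Rcpp::export(name = ".build_maps_cpp")]]
List build_maps_cpp(NumericMatrix rec_xyz, NumericVector rec_q,
                    NumericMatrix pair_eps, NumericMatrix pair_req,
                    IntegerVector rec_type_idx, int n_lig_types,
                    IntegerVector npts, NumericVector origin,
                    double spacing, double cap, double exp_m, double exp_n) {
  int nx = npts[0], ny = npts[1], nz = npts[2];
  size_t nn = (size_t)nx * ny * nz;
  int na = rec_xyz.nrow();
  List grids(n_lig_types);
  std::vector<std::vector<double>*> gp(n_lig_types);
  for (int t = 0; t < n_lig_types; ++t)
    gp[t] = new std::vector<double>(nn, 0.0);
  std::vector<double> elec(nn, 0.0);
  for (int iz = 0; iz < nz; ++iz) {
    double z = origin[2] + spacing * iz;
    for (int iy = 0; iy < ny; ++iy) {
      double y = origin[1] + spacing * iy;
      for (int ix = 0; ix < nx; ++ix) {
        double x = origin[0] + spacing * ix;
        size_t idx = ix + (size_t)nx * (iy + (size_t)ny * iz);
        double ev = 0.0;
        for (int a = 0; a < na; ++a) {
          double dx = x - rec_xyz(a,0), dy = y - rec_xyz(a,1), dz = z - rec_xyz(a,2);
          double r2 = dx*dx + dy*dy + dz*dz;
          if (r2 < 1e-12) r2 = 1e-12;
          ev += rec_q[a] / (4.0 * r2);
          int rt = rec_type_idx[a] - 1;
          for (int t = 0; t < n_lig_types; ++t)
            (*gp[t])[idx] += mie(pair_eps(t, rt), pair_req(t, rt), r2,
                                 exp_m, exp_n);
        }
        elec[idx] = ev;
      }
    }
  }
  for (int t = 0; t < n_lig_types; ++t) {
    NumericVector g(nn);
    for (size_t k = 0; k < nn; ++k)
      g[k] = std::min((*gp[t])[k], cap);
    g.attr("dim") = IntegerVector::create(nx, ny, nz);
    grids[t] = g;
    delete gp[t];
  }
  NumericVector e(nn);
  for (size_t k = 0; k < nn; ++k) e[k] = std::min(elec[k], cap);
  e.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(Named("type_grids") = grids, Named("elec") = e);
}
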