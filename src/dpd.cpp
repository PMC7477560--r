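// DPD engine kernels: cell-list neighbour search, pair and bonded forces,
// modified velocity-Verlet integration loop, pair-distance histogramming.
// All lengths are in reduced units (cut-off r_C = 1 unless stated), the box is
// a periodic cube, and bead indices arriving from R are 1-based.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double min_image(double dx, double box) {
  return dx - box * std::nearbyint(dx / box);
}

// (1 - r/r_C)^s with fast paths for the common exponents
static inline double wpow(double wc, double s) {
  if (s == 0.5) return std::sqrt(wc);
  if (s == 1.0) return wc;
  if (s == 2.0) return wc * wc;
  return std::pow(wc, s);
}

// Candidate pairs from cell adjacency. Cells have edge >= cutoff so every pair
// closer than the cut-off lies in the same or an adjacent cell; the candidate
// set is a superset of the true pair set and is distance-filtered at force
// time. Falls back to all-pairs when the box is too small for a 3x3x3 grid.
static void build_candidate_pairs(const std::vector<double>& x,
                                  const std::vector<double>& y,
                                  const std::vector<double>& z,
                                  int n, double box, double cutoff,
                                  std::vector<int>& pi, std::vector<int>& pj) {
  pi.clear(); pj.clear();
  int nc = (int)std::floor(box / cutoff);
  if (nc < 3) {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) { pi.push_back(i); pj.push_back(j); }
    return;
  }
  double cell = box / nc;
  int ncell = nc * nc * nc;
  std::vector<int> head(ncell, -1), nxt(n, -1);
  for (int i = 0; i < n; ++i) {
    int cx = (int)(x[i] / cell), cy = (int)(y[i] / cell), cz = (int)(z[i] / cell);
    if (cx >= nc) cx = nc - 1; if (cy >= nc) cy = nc - 1; if (cz >= nc) cz = nc - 1;
    if (cx < 0) cx = 0; if (cy < 0) cy = 0; if (cz < 0) cz = 0;
    int c = (cz * nc + cy) * nc + cx;
    nxt[i] = head[c]; head[c] = i;
  }
  // half-shell offsets: same cell plus 13 of the 26 neighbours
  static const int off[14][3] = {
    {0,0,0}, {1,0,0}, {-1,1,0}, {0,1,0}, {1,1,0},
    {-1,-1,1}, {0,-1,1}, {1,-1,1}, {-1,0,1}, {0,0,1},
    {1,0,1}, {-1,1,1}, {0,1,1}, {1,1,1}
  };
  for (int cz = 0; cz < nc; ++cz)
    for (int cy = 0; cy < nc; ++cy)
      for (int cx = 0; cx < nc; ++cx) {
        int c = (cz * nc + cy) * nc + cx;
        for (int k = 0; k < 14; ++k) {
          int ox = (cx + off[k][0] + nc) % nc;
          int oy = (cy + off[k][1] + nc) % nc;
          int oz = (cz + off[k][2] + nc) % nc;
          int c2 = (oz * nc + oy) * nc + ox;
          for (int i = head[c]; i >= 0; i = nxt[i]) {
            int jstart = (c2 == c) ? nxt[i] : head[c2];
            for (int j = jstart; j >= 0; j = nxt[j]) {
              if (i < j) { pi.push_back(i); pj.push_back(j); }
              else       { pi.push_back(j); pj.push_back(i); }
            }
          }
        }
      }
}

// [[Rcpp::export]]
IntegerMatrix cpp_cell_pairs(NumericMatrix pos, double box, double cutoff,
                             bool filter) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2); }
  std::vector<int> pi, pj;
  build_candidate_pairs(x, y, z, n, box, cutoff, pi, pj);
  std::vector<int> keep;
  keep.reserve(pi.size());
  double c2 = cutoff * cutoff;
  for (size_t k = 0; k < pi.size(); ++k) {
    if (!filter) { keep.push_back((int)k); continue; }
    double dx = min_image(x[pi[k]] - x[pj[k]], box);
    double dy = min_image(y[pi[k]] - y[pj[k]], box);
    double dz = min_image(z[pi[k]] - z[pj[k]], box);
    if (dx*dx + dy*dy + dz*dz < c2) keep.push_back((int)k);
  }
  IntegerMatrix out((int)keep.size(), 2);
  for (size_t k = 0; k < keep.size(); ++k) {
    out(k,0) = pi[keep[k]] + 1;
    out(k,1) = pj[keep[k]] + 1;
  }
  return out;
}

struct BondedTerms {
  std::vector<int> bi, bj;            // bond endpoints (0-based)
  std::vector<double> ks, l0;
  std::vector<int> ai, aj, ak;        // angle i-j-k, j central
  std::vector<double> ka, th0;
};

// Harmonic bonds and angles; accumulates into fx/fy/fz, returns potential energy.
static double add_bonded_forces(const std::vector<double>& x,
                                const std::vector<double>& y,
                                const std::vector<double>& z,
                                double box, const BondedTerms& bt,
                                std::vector<double>& fx, std::vector<double>& fy,
                                std::vector<double>& fz, int* n_degenerate) {
  double energy = 0.0;
  for (size_t b = 0; b < bt.bi.size(); ++b) {
    int i = bt.bi[b], j = bt.bj[b];
    double dx = min_image(x[i] - x[j], box);
    double dy = min_image(y[i] - y[j], box);
    double dz = min_image(z[i] - z[j], box);
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    if (r < 1e-12) { if (n_degenerate) ++*n_degenerate; continue; }
    double dr = r - bt.l0[b];
    double fmag = -bt.ks[b] * dr / r;   // force on i along r_ij
    fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
    fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    energy += 0.5 * bt.ks[b] * dr * dr;
  }
  const double eps = 1e-10;
  for (size_t a = 0; a < bt.ai.size(); ++a) {
    int i = bt.ai[a], j = bt.aj[a], k = bt.ak[a];
    double ax = min_image(x[i] - x[j], box);
    double ay = min_image(y[i] - y[j], box);
    double az = min_image(z[i] - z[j], box);
    double bx = min_image(x[k] - x[j], box);
    double by = min_image(y[k] - y[j], box);
    double bz = min_image(z[k] - z[j], box);
    double la = std::sqrt(ax*ax + ay*ay + az*az);
    double lb = std::sqrt(bx*bx + by*by + bz*bz);
    if (la < 1e-12 || lb < 1e-12) { if (n_degenerate) ++*n_degenerate; continue; }
    double cth = (ax*bx + ay*by + az*bz) / (la * lb);
    if (cth > 1.0 - eps) { cth = 1.0 - eps; if (n_degenerate) ++*n_degenerate; }
    if (cth < -1.0 + eps) { cth = -1.0 + eps; if (n_degenerate) ++*n_degenerate; }
    double th = std::acos(cth);
    double sth = std::sqrt(1.0 - cth * cth);
    double coef = bt.ka[a] * (th - bt.th0[a]) / sth;
    // F_i = coef * (b_hat - cos(th) a_hat)/|a|;  F_k symmetric;  F_j = -(F_i+F_k)
    double fix = coef * (bx/lb - cth * ax/la) / la;
    double fiy = coef * (by/lb - cth * ay/la) / la;
    double fiz = coef * (bz/lb - cth * az/la) / la;
    double fkx = coef * (ax/la - cth * bx/lb) / lb;
    double fky = coef * (ay/la - cth * by/lb) / lb;
    double fkz = coef * (az/la - cth * bz/lb) / lb;
    fx[i] += fix; fy[i] += fiy; fz[i] += fiz;
    fx[k] += fkx; fy[k] += fky; fz[k] += fkz;
    fx[j] -= fix + fkx; fy[j] -= fiy + fky; fz[j] -= fiz + fkz;
    double dth = th - bt.th0[a];
    energy += 0.5 * bt.ka[a] * dth * dth;
  }
  return energy;
}

static BondedTerms unpack_bonded(IntegerVector bond_i, IntegerVector bond_j,
                                 NumericVector bond_ks, NumericVector bond_l0,
                                 IntegerVector ang_i, IntegerVector ang_j,
                                 IntegerVector ang_k, NumericVector ang_ka,
                                 NumericVector ang_th0) {
  BondedTerms bt;
  for (int b = 0; b < bond_i.size(); ++b) {
    bt.bi.push_back(bond_i[b] - 1); bt.bj.push_back(bond_j[b] - 1);
    bt.ks.push_back(bond_ks[b]);    bt.l0.push_back(bond_l0[b]);
  }
  for (int a = 0; a < ang_i.size(); ++a) {
    bt.ai.push_back(ang_i[a] - 1); bt.aj.push_back(ang_j[a] - 1);
    bt.ak.push_back(ang_k[a] - 1);
    bt.ka.push_back(ang_ka[a]);    bt.th0.push_back(ang_th0[a]);
  }
  return bt;
}

// [[Rcpp::export]]
List cpp_bonded_forces(NumericMatrix pos, double box,
                       IntegerVector bond_i, IntegerVector bond_j,
                       NumericVector bond_ks, NumericVector bond_l0,
                       IntegerVector ang_i, IntegerVector ang_j,
                       IntegerVector ang_k, NumericVector ang_ka,
                       NumericVector ang_th0) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n,0.0), fy(n,0.0), fz(n,0.0);
  for (int i = 0; i < n; ++i) { x[i]=pos(i,0); y[i]=pos(i,1); z[i]=pos(i,2); }
  BondedTerms bt = unpack_bonded(bond_i, bond_j, bond_ks, bond_l0,
                                 ang_i, ang_j, ang_k, ang_ka, ang_th0);
  int ndeg = 0;
  double e = add_bonded_forces(x, y, z, box, bt, fx, fy, fz, &ndeg);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) { F(i,0)=fx[i]; F(i,1)=fy[i]; F(i,2)=fz[i]; }
  return List::create(_["forces"] = F, _["energy"] = e,
                      _["n_degenerate"] = ndeg);
}

// Non-bonded DPD pair forces over an explicit pair list, with caller-supplied
// symmetric noise (one draw per listed pair). Pairs beyond the cut-off
// contribute zero. Used directly by tests; the integrator uses the same
// arithmetic with internally generated noise.
// [[Rcpp::export]]
List cpp_pair_forces(NumericMatrix pos, NumericMatrix vel,
                     IntegerMatrix pairs, IntegerVector type,
                     NumericMatrix amat, double sigma, double gamma_,
                     double s, double cutoff, double box, double dt,
                     NumericVector noise) {
  int n = pos.nrow(), np = pairs.nrow();
  NumericMatrix F(n, 3);
  int n_overlap = 0;
  double inv_sqrt_dt = 1.0 / std::sqrt(dt);
  for (int p = 0; p < np; ++p) {
    int i = pairs(p,0) - 1, j = pairs(p,1) - 1;
    double dx = min_image(pos(i,0) - pos(j,0), box);
    double dy = min_image(pos(i,1) - pos(j,1), box);
    double dz = min_image(pos(i,2) - pos(j,2), box);
    double r2 = dx*dx + dy*dy + dz*dz;
    if (r2 >= cutoff * cutoff) continue;
    double r = std::sqrt(r2);
    if (r < 1e-12) { ++n_overlap; continue; }
    double ex = dx / r, ey = dy / r, ez = dz / r;
    double wc = 1.0 - r / cutoff;
    double wd = wpow(wc, s);
    double wr = std::sqrt(wd);
    double vdotr = (vel(i,0)-vel(j,0))*ex + (vel(i,1)-vel(j,1))*ey +
                   (vel(i,2)-vel(j,2))*ez;
    double a = amat(type[i]-1, type[j]-1);
    double fmag = a * wc - gamma_ * wd * vdotr +
                  sigma * wr * noise[p] * inv_sqrt_dt;
    F(i,0) += fmag * ex; F(i,1) += fmag * ey; F(i,2) += fmag * ez;
    F(j,0) -= fmag * ex; F(j,1) -= fmag * ey; F(j,2) -= fmag * ez;
  }
  return List::create(_["forces"] = F, _["n_overlap"] = n_overlap);
}

// Conservative + bonded potential energy (thermostat terms carry no potential).
// The conservative pair potential is a_ij (1 - r)^2 / 2 inside the cut-off.
// [[Rcpp::export]]
double cpp_potential_energy(NumericMatrix pos, IntegerVector type,
                            NumericMatrix amat, double cutoff, double box,
                            IntegerVector bond_i, IntegerVector bond_j,
                            NumericVector bond_ks, NumericVector bond_l0,
                            IntegerVector ang_i, IntegerVector ang_j,
                            IntegerVector ang_k, NumericVector ang_ka,
                            NumericVector ang_th0) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n), fx(n,0.0), fy(n,0.0), fz(n,0.0);
  for (int i = 0; i < n; ++i) { x[i]=pos(i,0); y[i]=pos(i,1); z[i]=pos(i,2); }
  double e = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(x[i]-x[j], box);
      double dy = min_image(y[i]-y[j], box);
      double dz = min_image(z[i]-z[j], box);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (r < cutoff) {
        double w = 1.0 - r / cutoff;
        e += 0.5 * amat(type[i]-1, type[j]-1) * cutoff * w * w;
      }
    }
  BondedTerms bt = unpack_bonded(bond_i, bond_j, bond_ks, bond_l0,
                                 ang_i, ang_j, ang_k, ang_ka, ang_th0);
  e += add_bonded_forces(x, y, z, box, bt, fx, fy, fz, nullptr);
  return e;
}

// The full integration loop: modified velocity-Verlet with velocity prediction
// factor lambda, candidate cell list rebuilt every cell_refresh steps, Mersenne
// Twister noise, one symmetric draw per in-range pair per force evaluation.
// Production frames (positions, velocities, unwrapped positions) are saved
// every save_every steps after the warm-up.
// [[Rcpp::export]]
List cpp_run_dpd(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
                 IntegerVector type, NumericMatrix amat, double sigma,
                 double gamma_, double s, double cutoff, double box,
                 double dt, double lambda, int warmup, int production,
                 int save_every, int cell_refresh, int seed,
                 IntegerVector bond_i, IntegerVector bond_j,
                 NumericVector bond_ks, NumericVector bond_l0,
                 IntegerVector ang_i, IntegerVector ang_j,
                 IntegerVector ang_k, NumericVector ang_ka,
                 NumericVector ang_th0) {
  int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n), ux(n), uy(n), uz(n);
  std::vector<double> vx(n), vy(n), vz(n), fx(n), fy(n), fz(n);
  std::vector<double> pvx(n), pvy(n), pvz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i,0); y[i] = pos0(i,1); z[i] = pos0(i,2);
    ux[i] = x[i]; uy[i] = y[i]; uz[i] = z[i];
    vx[i] = vel0(i,0); vy[i] = vel0(i,1); vz[i] = vel0(i,2);
  }
  BondedTerms bt = unpack_bonded(bond_i, bond_j, bond_ks, bond_l0,
                                 ang_i, ang_j, ang_k, ang_ka, ang_th0);
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::vector<int> pi, pj;
  build_candidate_pairs(x, y, z, n, box, cutoff, pi, pj);

  // flat copies for the hot loop
  int nt = amat.nrow();
  std::vector<double> am(nt * nt);
  for (int a = 0; a < nt; ++a)
    for (int b = 0; b < nt; ++b) am[a * nt + b] = amat(a, b);
  std::vector<int> ty(n);
  for (int i = 0; i < n; ++i) ty[i] = type[i] - 1;

  long n_overlap = 0;
  int n_degenerate = 0;
  double inv_sqrt_dt = 1.0 / std::sqrt(dt);
  double c2 = cutoff * cutoff;
  double hb = 0.5 * box;
  bool thermostat = (sigma != 0.0 || gamma_ != 0.0);

  // positions stay wrapped in [0, box), so one fold gives the minimum image
  auto compute_forces = [&](bool with_noise) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    size_t np = pi.size();
    for (size_t p = 0; p < np; ++p) {
      int i = pi[p], j = pj[p];
      double dx = x[i] - x[j];
      if (dx > hb) dx -= box; else if (dx < -hb) dx += box;
      double dy = y[i] - y[j];
      if (dy > hb) dy -= box; else if (dy < -hb) dy += box;
      double r2 = dx * dx + dy * dy;
      if (r2 >= c2) continue;
      double dz = z[i] - z[j];
      if (dz > hb) dz -= box; else if (dz < -hb) dz += box;
      r2 += dz * dz;
      if (r2 >= c2) continue;
      double r = std::sqrt(r2);
      if (r < 1e-12) { ++n_overlap; continue; }
      double ex = dx/r, ey = dy/r, ez = dz/r;
      double wc = 1.0 - r / cutoff;
      double fmag = am[ty[i] * nt + ty[j]] * wc;
      if (thermostat) {
        double wd = wpow(wc, s);
        double vdotr = (pvx[i]-pvx[j])*ex + (pvy[i]-pvy[j])*ey +
                       (pvz[i]-pvz[j])*ez;
        fmag -= gamma_ * wd * vdotr;
        if (with_noise)
          fmag += sigma * std::sqrt(wd) * gauss(rng) * inv_sqrt_dt;
      }
      fx[i] += fmag*ex; fy[i] += fmag*ey; fz[i] += fmag*ez;
      fx[j] -= fmag*ex; fy[j] -= fmag*ey; fz[j] -= fmag*ez;
    }
    add_bonded_forces(x, y, z, box, bt, fx, fy, fz, &n_degenerate);
  };

  for (int i = 0; i < n; ++i) { pvx[i]=vx[i]; pvy[i]=vy[i]; pvz[i]=vz[i]; }
  compute_forces(thermostat);

  int total = warmup + production;
  int n_frames = (save_every > 0 && production > 0) ? production / save_every : 0;
  NumericVector save_pos(Dimension(n, 3, std::max(n_frames, 1)));
  NumericVector save_vel(Dimension(n, 3, std::max(n_frames, 1)));
  NumericVector save_unw(Dimension(n, 3, std::max(n_frames, 1)));
  if (n_frames == 0) {
    save_pos = NumericVector(Dimension(n, 3, 0));
    save_vel = NumericVector(Dimension(n, 3, 0));
    save_unw = NumericVector(Dimension(n, 3, 0));
  }
  int frame = 0;
  std::vector<double> ofx(n), ofy(n), ofz(n);
  std::vector<double> minv(n);
  for (int i = 0; i < n; ++i) minv[i] = 1.0 / mass[i];

  for (int step = 1; step <= total; ++step) {
    for (int i = 0; i < n; ++i) {
      double ax = fx[i] * minv[i], ay = fy[i] * minv[i], az = fz[i] * minv[i];
      double dxs = dt * vx[i] + 0.5 * dt * dt * ax;
      double dys = dt * vy[i] + 0.5 * dt * dt * ay;
      double dzs = dt * vz[i] + 0.5 * dt * dt * az;
      x[i] += dxs; y[i] += dys; z[i] += dzs;
      ux[i] += dxs; uy[i] += dys; uz[i] += dzs;
      // per-step displacements are tiny, one fold re-wraps
      if (x[i] >= box) x[i] -= box; else if (x[i] < 0) x[i] += box;
      if (y[i] >= box) y[i] -= box; else if (y[i] < 0) y[i] += box;
      if (z[i] >= box) z[i] -= box; else if (z[i] < 0) z[i] += box;
      if (x[i] >= box || x[i] < 0) x[i] -= box * std::floor(x[i] / box);
      if (y[i] >= box || y[i] < 0) y[i] -= box * std::floor(y[i] / box);
      if (z[i] >= box || z[i] < 0) z[i] -= box * std::floor(z[i] / box);
      // velocity prediction for the dissipative force
      pvx[i] = vx[i] + lambda * dt * ax;
      pvy[i] = vy[i] + lambda * dt * ay;
      pvz[i] = vz[i] + lambda * dt * az;
    }
    if (cell_refresh > 0 && step % cell_refresh == 0)
      build_candidate_pairs(x, y, z, n, box, cutoff, pi, pj);
    ofx = fx; ofy = fy; ofz = fz;
    compute_forces(thermostat);
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * dt * (ofx[i] + fx[i]) * minv[i];
      vy[i] += 0.5 * dt * (ofy[i] + fy[i]) * minv[i];
      vz[i] += 0.5 * dt * (ofz[i] + fz[i]) * minv[i];
      if (!std::isfinite(x[i]) || !std::isfinite(vx[i]))
        stop("non-finite state at step %d, bead %d", step, i + 1);
    }
    if (step > warmup && save_every > 0 && (step - warmup) % save_every == 0 &&
        frame < n_frames) {
      for (int i = 0; i < n; ++i) {
        save_pos[i + n*0 + 3*n*frame] = x[i];
        save_pos[i + n*1 + 3*n*frame] = y[i];
        save_pos[i + n*2 + 3*n*frame] = z[i];
        save_vel[i + n*0 + 3*n*frame] = vx[i];
        save_vel[i + n*1 + 3*n*frame] = vy[i];
        save_vel[i + n*2 + 3*n*frame] = vz[i];
        save_unw[i + n*0 + 3*n*frame] = ux[i];
        save_unw[i + n*1 + 3*n*frame] = uy[i];
        save_unw[i + n*2 + 3*n*frame] = uz[i];
      }
      ++frame;
    }
  }

  NumericMatrix fpos(n,3), fvel(n,3), funw(n,3), ffrc(n,3);
  for (int i = 0; i < n; ++i) {
    fpos(i,0)=x[i]; fpos(i,1)=y[i]; fpos(i,2)=z[i];
    fvel(i,0)=vx[i]; fvel(i,1)=vy[i]; fvel(i,2)=vz[i];
    funw(i,0)=ux[i]; funw(i,1)=uy[i]; funw(i,2)=uz[i];
    ffrc(i,0)=fx[i]; ffrc(i,1)=fy[i]; ffrc(i,2)=fz[i];
  }
  return List::create(
    _["positions"] = save_pos, _["velocities"] = save_vel,
    _["unwrapped"] = save_unw, _["n_frames"] = frame,
    _["final_positions"] = fpos, _["final_velocities"] = fvel,
    _["final_unwrapped"] = funw, _["final_forces"] = ffrc,
    _["n_overlap"] = (double)n_overlap, _["n_degenerate"] = n_degenerate);
}

// Minimum-image pair-distance histogram between two index selections
// (0 shared => cross-selection; identical selections => unique pairs).
// [[Rcpp::export]]
NumericVector cpp_pair_dist_hist(NumericMatrix pos, IntegerVector sel1,
                                 IntegerVector sel2, bool same, double box,
                                 double bin_width, int nbins) {
  NumericVector counts(nbins);
  double rmax = bin_width * nbins;
  double rmax2 = rmax * rmax;
  int n1 = sel1.size(), n2 = sel2.size();
  for (int a = 0; a < n1; ++a) {
    int i = sel1[a] - 1;
    int bstart = same ? a + 1 : 0;
    for (int b = bstart; b < n2; ++b) {
      int j = sel2[b] - 1;
      double dx = min_image(pos(i,0)-pos(j,0), box);
      double dy = min_image(pos(i,1)-pos(j,1), box);
      double dz = min_image(pos(i,2)-pos(j,2), box);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 >= rmax2) continue;
      int bin = (int)(std::sqrt(r2) / bin_width);
      if (bin >= 0 && bin < nbins) counts[bin] += 1.0;
    }
  }
  return counts;
}
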