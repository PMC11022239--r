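// Compiled cores: periodic contact search, Shrake-Rupley exposure fractions,
// and the coarse-grained rigid-body Metropolis Monte Carlo generator.
// All randomness comes from R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

// Minimum-image squared distance.
static inline double mi_dist2(const double* a, const double* b, double L) {
  double dx = min_image(a[0] - b[0], L);
  double dy = min_image(a[1] - b[1], L);
  double dz = min_image(a[2] - b[2], L);
  return dx * dx + dy * dy + dz * dz;
}

// ---------------------------------------------------------------------------
// Contact pairs: unordered component pairs with any-atom minimum-image
// distance strictly below the cutoff. Cell list when the box admits >= 4
// cells per axis, otherwise all-pairs; the result is identical either way.
// [[Rcpp::export]]
DataFrame cpp_contact_pairs(NumericMatrix coords, IntegerVector atom_component,
                            double box, double cutoff) {
  const int n = coords.nrow();
  const double cut2 = cutoff * cutoff;
  std::vector<double> xyz(3 * n);
  for (int i = 0; i < n; ++i) {
    xyz[3 * i] = coords(i, 0);
    xyz[3 * i + 1] = coords(i, 1);
    xyz[3 * i + 2] = coords(i, 2);
  }
  std::map<std::pair<int, int>, double> best;
  auto consider = [&](int i, int j) {
    int ci = atom_component[i], cj = atom_component[j];
    if (ci == cj) return;
    double d2 = mi_dist2(&xyz[3 * i], &xyz[3 * j], box);
    if (d2 < cut2) {
      std::pair<int, int> key = ci < cj ? std::make_pair(ci, cj)
                                        : std::make_pair(cj, ci);
      auto it = best.find(key);
      if (it == best.end() || d2 < it->second) best[key] = d2;
    }
  };

  int ncell = (int)std::floor(box / cutoff);
  if (ncell >= 4) {
    std::vector<std::vector<int>> cells(ncell * ncell * ncell);
    std::vector<int> cix(n), ciy(n), ciz(n);
    for (int i = 0; i < n; ++i) {
      double w;
      w = xyz[3 * i] - box * std::floor(xyz[3 * i] / box);
      cix[i] = std::min(ncell - 1, (int)(w / box * ncell));
      w = xyz[3 * i + 1] - box * std::floor(xyz[3 * i + 1] / box);
      ciy[i] = std::min(ncell - 1, (int)(w / box * ncell));
      w = xyz[3 * i + 2] - box * std::floor(xyz[3 * i + 2] / box);
      ciz[i] = std::min(ncell - 1, (int)(w / box * ncell));
      cells[(cix[i] * ncell + ciy[i]) * ncell + ciz[i]].push_back(i);
    }
    for (int i = 0; i < n; ++i) {
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int cx = (cix[i] + dx + ncell) % ncell;
            int cy = (ciy[i] + dy + ncell) % ncell;
            int cz = (ciz[i] + dz + ncell) % ncell;
            const std::vector<int>& cell = cells[(cx * ncell + cy) * ncell + cz];
            for (int j : cell)
              if (j > i) consider(i, j);
          }
    }
  } else {
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) consider(i, j);
  }

  const int m = (int)best.size();
  IntegerVector ci(m), cj(m);
  NumericVector d(m);
  int k = 0;
  for (auto& kv : best) {
    ci[k] = kv.first.first;
    cj[k] = kv.first.second;
    d[k] = std::sqrt(kv.second);
    ++k;
  }
  return DataFrame::create(_["i"] = ci, _["j"] = cj, _["min_dist"] = d);
}

// ---------------------------------------------------------------------------
// Shrake-Rupley exposed fraction per atom, deterministic Fibonacci-lattice
// sphere points. No periodicity: callers pass unwrapped cluster coordinates.
// [[Rcpp::export]]
NumericVector cpp_exposed_fraction(NumericMatrix coords, NumericVector radii,
                                   double probe, int n_points) {
  const int n = coords.nrow();
  NumericVector frac(n);
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = golden * k;
    px[k] = r * std::cos(phi);
    py[k] = r * std::sin(phi);
    pz[k] = z;
  }
  for (int i = 0; i < n; ++i) {
    double ri = radii[i] + probe;
    // neighbors whose inflated sphere can occlude points on atom i's sphere
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double rj = radii[j] + probe;
      double dx = coords(j, 0) - coords(i, 0);
      double dy = coords(j, 1) - coords(i, 1);
      double dz = coords(j, 2) - coords(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      double reach = ri + rj;
      if (d2 < reach * reach) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      double qx = coords(i, 0) + ri * px[k];
      double qy = coords(i, 1) + ri * py[k];
      double qz = coords(i, 2) + ri * pz[k];
      bool free_pt = true;
      for (int j : nb) {
        double rj = radii[j] + probe;
        double dx = qx - coords(j, 0);
        double dy = qy - coords(j, 1);
        double dz = qz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free_pt = false; break; }
      }
      if (free_pt) ++exposed;
    }
    frac[i] = (double)exposed / n_points;
  }
  return frac;
}

// ---------------------------------------------------------------------------
// Rigid-body Metropolis MC over components in a cubic periodic box.
// Square-well pair energy at the component level:
//   +inf (rejected move) if any inter-atom minimum-image distance < sigma;
//   else, for component pairs with any-atom distance < r_well:
//     -eps(kind_a, kind_b) (+ repulsion penalty for like-charged ion pairs
//      ZN-ZN and NO3-NO3).
struct McSystem {
  int ncomp;
  double box, sigma2, rw, rw2, penalty;
  std::vector<int> kind, start, len;   // CSR over atoms
  std::vector<double> xyz;             // 3*natoms, molecules contiguous
  std::vector<double> cx, cy, cz, ext; // per-component centroid + max extent
  NumericMatrix eps;

  double pair_energy(int a, int b, bool& hardcore) const {
    double d2c = 0.0;
    {
      double dx = min_image(cx[a] - cx[b], box);
      double dy = min_image(cy[a] - cy[b], box);
      double dz = min_image(cz[a] - cz[b], box);
      d2c = dx * dx + dy * dy + dz * dz;
    }
    double reach = rw + ext[a] + ext[b];
    if (d2c > reach * reach) return 0.0;
    bool within = false;
    for (int i = start[a]; i < start[a] + len[a]; ++i)
      for (int j = start[b]; j < start[b] + len[b]; ++j) {
        double d2 = mi_dist2(&xyz[3 * i], &xyz[3 * j], box);
        if (d2 < sigma2) { hardcore = true; return 0.0; }
        if (d2 < rw2) within = true;
      }
    if (!within) return 0.0;
    double u = -eps(kind[a], kind[b]);
    if ((kind[a] == 2 && kind[b] == 2) || (kind[a] == 3 && kind[b] == 3))
      u += penalty;
    return u;
  }

  // energy of component a against all others; hardcore set if any overlap
  double comp_energy(int a, bool& hardcore) const {
    double u = 0.0;
    for (int b = 0; b < ncomp; ++b) {
      if (b == a) continue;
      bool hc = false;
      u += pair_energy(a, b, hc);
      if (hc) { hardcore = true; return 0.0; }
    }
    return u;
  }

  double total_energy(bool& hardcore) const {
    double u = 0.0;
    for (int a = 0; a < ncomp; ++a)
      for (int b = a + 1; b < ncomp; ++b) {
        bool hc = false;
        u += pair_energy(a, b, hc);
        if (hc) { hardcore = true; return 0.0; }
      }
    return u;
  }

  void update_centroid(int a) {
    double sx = 0, sy = 0, sz = 0;
    for (int i = start[a]; i < start[a] + len[a]; ++i) {
      sx += xyz[3 * i]; sy += xyz[3 * i + 1]; sz += xyz[3 * i + 2];
    }
    cx[a] = sx / len[a]; cy[a] = sy / len[a]; cz[a] = sz / len[a];
  }

  // keep molecules contiguous; shift whole molecule when centroid leaves box
  void rewrap(int a) {
    double shx = box * std::floor(cx[a] / box);
    double shy = box * std::floor(cy[a] / box);
    double shz = box * std::floor(cz[a] / box);
    if (shx == 0 && shy == 0 && shz == 0) return;
    for (int i = start[a]; i < start[a] + len[a]; ++i) {
      xyz[3 * i] -= shx; xyz[3 * i + 1] -= shy; xyz[3 * i + 2] -= shz;
    }
    cx[a] -= shx; cy[a] -= shy; cz[a] -= shz;
  }
};

static void random_rotation(double max_angle, double R[3][3]) {
  // random axis (Gaussian direction), angle uniform in [-max_angle, max_angle]
  double ax = norm_rand(), ay = norm_rand(), az = norm_rand();
  double nrm = std::sqrt(ax * ax + ay * ay + az * az);
  if (nrm < 1e-12) { ax = 1; ay = 0; az = 0; nrm = 1; }
  ax /= nrm; ay /= nrm; az /= nrm;
  double th = (2.0 * unif_rand() - 1.0) * max_angle;
  double c = std::cos(th), s = std::sin(th), t = 1 - c;
  R[0][0] = t * ax * ax + c;      R[0][1] = t * ax * ay - s * az; R[0][2] = t * ax * az + s * ay;
  R[1][0] = t * ax * ay + s * az; R[1][1] = t * ay * ay + c;      R[1][2] = t * ay * az - s * ax;
  R[2][0] = t * ax * az - s * ay; R[2][1] = t * ay * az + s * ax; R[2][2] = t * az * az + c;
}

// [[Rcpp::export]]
List cpp_mc_run(NumericMatrix init_coords, IntegerVector comp_start,
                IntegerVector comp_len, IntegerVector comp_kind,
                double box, NumericMatrix eps, double sigma, double r_well,
                double penalty, double kT, double trans_step, double rot_step,
                int n_sweeps, int sample_every, int check_every) {
  McSystem S;
  S.ncomp = comp_start.size();
  S.box = box;
  S.sigma2 = sigma * sigma;
  S.rw = r_well;
  S.rw2 = r_well * r_well;
  S.penalty = penalty;
  S.eps = eps;
  S.kind.assign(comp_kind.begin(), comp_kind.end());
  S.start.assign(comp_start.begin(), comp_start.end());
  S.len.assign(comp_len.begin(), comp_len.end());
  const int natoms = init_coords.nrow();
  S.xyz.resize(3 * natoms);
  for (int i = 0; i < natoms; ++i) {
    S.xyz[3 * i] = init_coords(i, 0);
    S.xyz[3 * i + 1] = init_coords(i, 1);
    S.xyz[3 * i + 2] = init_coords(i, 2);
  }
  S.cx.resize(S.ncomp); S.cy.resize(S.ncomp); S.cz.resize(S.ncomp);
  S.ext.resize(S.ncomp);
  for (int a = 0; a < S.ncomp; ++a) {
    S.update_centroid(a);
    double mx = 0;
    for (int i = S.start[a]; i < S.start[a] + S.len[a]; ++i) {
      double dx = S.xyz[3 * i] - S.cx[a];
      double dy = S.xyz[3 * i + 1] - S.cy[a];
      double dz = S.xyz[3 * i + 2] - S.cz[a];
      mx = std::max(mx, std::sqrt(dx * dx + dy * dy + dz * dz));
    }
    S.ext[a] = mx;
  }
  bool hc0 = false;
  double U = S.total_energy(hc0);
  if (hc0) stop("initial configuration violates the hard core");

  List frames;
  long n_moves = 0, n_accept = 0;
  double max_drift = 0.0;
  std::vector<double> old_atoms;
  long move_counter = 0;

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int mv = 0; mv < S.ncomp; ++mv) {
      int a = std::min(S.ncomp - 1, (int)(unif_rand() * S.ncomp));
      bool hc_old = false;
      double u_old = S.comp_energy(a, hc_old);
      // save atom coords + centroid
      old_atoms.assign(S.xyz.begin() + 3 * S.start[a],
                       S.xyz.begin() + 3 * (S.start[a] + S.len[a]));
      double ocx = S.cx[a], ocy = S.cy[a], ocz = S.cz[a];

      double tx = (2 * unif_rand() - 1) * trans_step;
      double ty = (2 * unif_rand() - 1) * trans_step;
      double tz = (2 * unif_rand() - 1) * trans_step;
      if (S.len[a] > 1 && rot_step > 0) {
        double R[3][3];
        random_rotation(rot_step, R);
        for (int i = S.start[a]; i < S.start[a] + S.len[a]; ++i) {
          double dx = S.xyz[3 * i] - ocx;
          double dy = S.xyz[3 * i + 1] - ocy;
          double dz = S.xyz[3 * i + 2] - ocz;
          S.xyz[3 * i]     = ocx + R[0][0] * dx + R[0][1] * dy + R[0][2] * dz;
          S.xyz[3 * i + 1] = ocy + R[1][0] * dx + R[1][1] * dy + R[1][2] * dz;
          S.xyz[3 * i + 2] = ocz + R[2][0] * dx + R[2][1] * dy + R[2][2] * dz;
        }
      }
      for (int i = S.start[a]; i < S.start[a] + S.len[a]; ++i) {
        S.xyz[3 * i] += tx; S.xyz[3 * i + 1] += ty; S.xyz[3 * i + 2] += tz;
      }
      S.update_centroid(a);
      S.rewrap(a);

      bool hc_new = false;
      double u_new = S.comp_energy(a, hc_new);
      bool accept = false;
      if (!hc_new) {
        double dU = u_new - u_old;
        accept = (dU <= 0) || (unif_rand() < std::exp(-dU / kT));
      }
      ++n_moves;
      if (accept) {
        ++n_accept;
        U += u_new - u_old;
      } else {
        std::copy(old_atoms.begin(), old_atoms.end(),
                  S.xyz.begin() + 3 * S.start[a]);
        S.cx[a] = ocx; S.cy[a] = ocy; S.cz[a] = ocz;
      }
      ++move_counter;
      if (check_every > 0 && move_counter % check_every == 0) {
        bool hc = false;
        double Ufull = S.total_energy(hc);
        max_drift = std::max(max_drift, std::fabs(Ufull - U));
      }
    }
    if (sweep % sample_every == 0) {
      NumericMatrix snap(natoms, 3);
      for (int i = 0; i < natoms; ++i) {
        snap(i, 0) = S.xyz[3 * i] - box * std::floor(S.xyz[3 * i] / box);
        snap(i, 1) = S.xyz[3 * i + 1] - box * std::floor(S.xyz[3 * i + 1] / box);
        snap(i, 2) = S.xyz[3 * i + 2] - box * std::floor(S.xyz[3 * i + 2] / box);
      }
      frames.push_back(snap);
    }
  }
  return List::create(_["frames"] = frames, _["energy"] = U,
                      _["n_moves"] = (double)n_moves,
                      _["n_accept"] = (double)n_accept,
                      _["max_energy_drift"] = max_drift);
}

// Total square-well energy of a configuration (for tests and diagnostics).
// [[Rcpp::export]]
List cpp_total_energy(NumericMatrix coords, IntegerVector comp_start,
                      IntegerVector comp_len, IntegerVector comp_kind,
                      double box, NumericMatrix eps, double sigma,
                      double r_well, double penalty) {
  McSystem S;
  S.ncomp = comp_start.size();
  S.box = box;
  S.sigma2 = sigma * sigma;
  S.rw = r_well;
  S.rw2 = r_well * r_well;
  S.penalty = penalty;
  S.eps = eps;
  S.kind.assign(comp_kind.begin(), comp_kind.end());
  S.start.assign(comp_start.begin(), comp_start.end());
  S.len.assign(comp_len.begin(), comp_len.end());
  const int natoms = coords.nrow();
  S.xyz.resize(3 * natoms);
  for (int i = 0; i < natoms; ++i) {
    S.xyz[3 * i] = coords(i, 0);
    S.xyz[3 * i + 1] = coords(i, 1);
    S.xyz[3 * i + 2] = coords(i, 2);
  }
  S.cx.resize(S.ncomp); S.cy.resize(S.ncomp); S.cz.resize(S.ncomp);
  S.ext.resize(S.ncomp);
  for (int a = 0; a < S.ncomp; ++a) {
    S.update_centroid(a);
    double mx = 0;
    for (int i = S.start[a]; i < S.start[a] + S.len[a]; ++i) {
      double dx = S.xyz[3 * i] - S.cx[a];
      double dy = S.xyz[3 * i + 1] - S.cy[a];
      double dz = S.xyz[3 * i + 2] - S.cz[a];
      mx = std::max(mx, std::sqrt(dx * dx + dy * dy + dz * dz));
    }
    S.ext[a] = mx;
  }
  bool hc = false;
  double U = S.total_energy(hc);
  return List::create(_["energy"] = U, _["hardcore"] = hc);
}
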