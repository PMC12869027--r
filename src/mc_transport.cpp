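#include <Rcpp.h>
using namespace Rcpp;

// 2-D voxel Monte-Carlo photon transport with implicit-capture weighting,
// Henyey-Greenstein scattering and Russian roulette.
//
// Grid convention: row i = depth (z, downward), column j = lateral (x).
// Photons are launched on the top surface (z = 0) travelling downward.
// Fluence is estimated with the absorption estimator: deposited weight per
// voxel divided by (mu_a * voxel area), per launched photon.
//
// Weight accounting is exact: launched = absorbed + escaped + roulette_net,
// where roulette_net = weight killed at roulette minus weight added when a
// surviving photon is boosted to w / p_survive.

static const double W_MIN = 1e-4;     // roulette threshold
static const double P_SURVIVE = 0.1;  // roulette survival chance
static const int MAX_STEPS = 2000000; // hard safety cap per photon

// Sample cos(theta) from the Henyey-Greenstein phase function.
static inline double hg_cos(double g) {
  if (std::fabs(g) < 1e-6) return 2.0 * unif_rand() - 1.0;
  double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
  double c = (1.0 + g * g - f * f) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

// [[Rcpp::export(name = ".mc_fluence_cpp")]]
List mc_fluence_cpp(NumericMatrix mu_a, NumericMatrix mu_s, NumericMatrix g,
                    double dx_cm, NumericMatrix src_segments,
                    double half_angle_rad, int n_photons) {
  const int nz = mu_a.nrow(), nx = mu_a.ncol();
  const double zmax = nz * dx_cm, xmax = nx * dx_cm;
  NumericMatrix dep(nz, nx);
  double absorbed = 0.0, escaped = 0.0, roulette_net = 0.0;
  const int nseg = src_segments.nrow();

  // cumulative segment lengths for launch-position sampling
  std::vector<double> cum(nseg);
  double tot = 0.0;
  for (int s = 0; s < nseg; ++s) {
    tot += std::fabs(src_segments(s, 1) - src_segments(s, 0));
    cum[s] = tot;
  }

  for (int p = 0; p < n_photons; ++p) {
    // launch position: uniform over the union of surface segments
    double u = unif_rand() * tot;
    int s = 0;
    while (s < nseg - 1 && u > cum[s]) ++s;
    double off = u - (s > 0 ? cum[s - 1] : 0.0);
    double x0 = src_segments(s, 0), x1 = src_segments(s, 1);
    double x = (x1 >= x0) ? x0 + off : x0 - off;
    double z = 1e-9;
    // direction: angle from +z within +/- half_angle
    double th = (2.0 * unif_rand() - 1.0) * half_angle_rad;
    double ux = std::sin(th), uz = std::cos(th);

    double w = 1.0;
    double tau = -std::log(unif_rand());
    int steps = 0;
    while (steps++ < MAX_STEPS) {
      int i = (int)(z / dx_cm), j = (int)(x / dx_cm);
      if (i < 0 || i >= nz || j < 0 || j >= nx) { escaped += w; break; }
      double ma = mu_a(i, j), ms = mu_s(i, j), mt = ma + ms;

      // distance to the nearest voxel boundary along the direction
      double dz_b = (uz > 0) ? ((i + 1) * dx_cm - z) / uz
                  : (uz < 0) ? (i * dx_cm - z) / uz : R_PosInf;
      double dx_b = (ux > 0) ? ((j + 1) * dx_cm - x) / ux
                  : (ux < 0) ? (j * dx_cm - x) / ux : R_PosInf;
      double db = (dz_b < dx_b ? dz_b : dx_b);
      if (db < 0) db = 0;

      double d_int = (mt > 0) ? tau / mt : R_PosInf;
      if (d_int < db) {
        // interaction inside this voxel
        x += ux * d_int; z += uz * d_int;
        double dw = w * (ma / mt);
        dep(i, j) += dw; absorbed += dw; w -= dw;
        if (ms <= 0.0 || w <= 0.0) { absorbed += w; dep(i, j) += w; w = 0.0; }
        else {
          double c = hg_cos(g(i, j));
          double sgn = (unif_rand() < 0.5) ? 1.0 : -1.0;
          double sn = sgn * std::sqrt(1.0 - c * c);
          double ux2 = ux * c - uz * sn, uz2 = ux * sn + uz * c;
          ux = ux2; uz = uz2;
        }
        tau = -std::log(unif_rand());
        if (w <= 0.0) break;
        if (w < W_MIN) {
          if (unif_rand() < P_SURVIVE) {
            double w2 = w / P_SURVIVE;
            roulette_net -= (w2 - w);
            w = w2;
          } else { roulette_net += w; break; }
        }
      } else {
        // traverse to the voxel boundary, consume optical depth
        double step = db + 1e-9;
        x += ux * step; z += uz * step;
        if (mt > 0) tau -= mt * db;
        if (z < 0 || z >= zmax || x < 0 || x >= xmax) { escaped += w; break; }
      }
    }
  }

  NumericMatrix flu(nz, nx);
  double va = dx_cm * dx_cm;
  for (int i = 0; i < nz; ++i)
    for (int j = 0; j < nx; ++j)
      flu(i, j) = (mu_a(i, j) > 0) ? dep(i, j) / (mu_a(i, j) * va * n_photons) : 0.0;

  return List::create(_["fluence"] = flu,
                      _["absorbed"] = absorbed / n_photons,
                      _["escaped"] = escaped / n_photons,
                      _["roulette_net"] = roulette_net / n_photons);
}

// Connected-component labelling of a logical matrix, 8-connectivity,
// iterative flood fill. Returns an integer matrix (0 = background).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nz = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(nz, nx);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int i = 0; i < nz; ++i) {
    for (int j = 0; j < nx; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> q = stack.back(); stack.pop_back();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            int a = q.first + di, b = q.second + dj;
            if (a < 0 || a >= nz || b < 0 || b >= nx) continue;
            if (mask(a, b) && lab(a, b) == 0) {
              lab(a, b) = next;
              stack.push_back(std::make_pair(a, b));
            }
          }
        }
      }
    }
  }
  return lab;
}
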