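#include <Rcpp.h>
using namespace Rcpp;

// k-nearest-neighbour search, brute force over all pairs.
// Ties in distance are broken by lower bird index so results are
// deterministic and match an exhaustive oracle exactly.
// Returns a N x k integer matrix of 1-based neighbour indices, ordered by
// increasing distance; unused slots (k > N-1) are NA.
// [[Rcpp::export]]
IntegerMatrix knn_indices_cpp(NumericMatrix pos, int k) {
  const int n = pos.nrow();
  const int keff = std::min(k, n - 1);
  IntegerMatrix out(n, k);
  std::fill(out.begin(), out.end(), NA_INTEGER);
  if (keff < 1) return out;

  std::vector<double> bd(keff);
  std::vector<int> bi(keff);
  for (int i = 0; i < n; ++i) {
    int m = 0; // occupied slots
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = pos(j, 0) - pos(i, 0);
      const double dy = pos(j, 1) - pos(i, 1);
      const double dz = pos(j, 2) - pos(i, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (m == keff && (d2 > bd[m - 1] || (d2 == bd[m - 1] && j > bi[m - 1])))
        continue;
      // insertion sort into the best-list, keyed on (d2, index)
      int p = (m < keff) ? m : keff - 1;
      while (p > 0 && (bd[p - 1] > d2 || (bd[p - 1] == d2 && bi[p - 1] > j))) {
        bd[p] = bd[p - 1];
        bi[p] = bi[p - 1];
        --p;
      }
      bd[p] = d2;
      bi[p] = j;
      if (m < keff) ++m;
    }
    for (int s = 0; s < m; ++s) out(i, s) = bi[s] + 1;
  }
  return out;
}

// Distance from each bird to its single nearest neighbour (brute force).
// [[Rcpp::export]]
NumericVector nearest_neighbour_dist_cpp(NumericMatrix pos) {
  const int n = pos.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = pos(j, 0) - pos(i, 0);
      const double dy = pos(j, 1) - pos(i, 1);
      const double dz = pos(j, 2) - pos(i, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Social steering accelerations for every bird: separation from topological
// neighbours closer than sep_radius (linear ramp), alignment towards the mean
// heading of the k neighbours, cohesion towards their centroid, speed
// regulation towards cruise_speed along the heading, and a damped spring on
// altitude. The caller clamps the total acceleration and integrates.
// [[Rcpp::export]]
NumericMatrix flock_accel_cpp(NumericMatrix pos, NumericMatrix vel, int k,
                              double sep_radius, double w_sep, double w_ali,
                              double w_coh, double coh_sat, double w_spd,
                              double w_alt, double w_alt_damp,
                              double cruise_speed, double pref_altitude) {
  const int n = pos.nrow();
  NumericMatrix acc(n, 3);
  IntegerMatrix nn = knn_indices_cpp(pos, k);
  const int kmax = nn.ncol();

  for (int i = 0; i < n; ++i) {
    double ax = 0, ay = 0, az = 0;
    double cx = 0, cy = 0, cz = 0;   // neighbour centroid
    double fx = 0, fy = 0, fz = 0;   // mean neighbour heading
    int m = 0;
    for (int s = 0; s < kmax; ++s) {
      if (nn(i, s) == NA_INTEGER) break;
      const int j = nn(i, s) - 1;
      const double dx = pos(i, 0) - pos(j, 0);
      const double dy = pos(i, 1) - pos(j, 1);
      const double dz = pos(i, 2) - pos(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < sep_radius && d > 1e-12) {
        // inverse-distance ramp: repulsion strengthens sharply at close
        // range, so birds in denser flocks manoeuvre harder (greater
        // acceleration and path curvature), as observed empirically
        const double w = w_sep * (sep_radius / d - 1.0) / d;
        ax += w * dx;
        ay += w * dy;
        az += w * dz;
      }
      cx += pos(j, 0); cy += pos(j, 1); cz += pos(j, 2);
      const double sj = std::sqrt(vel(j, 0) * vel(j, 0) +
                                  vel(j, 1) * vel(j, 1) +
                                  vel(j, 2) * vel(j, 2));
      if (sj > 1e-12) {
        fx += vel(j, 0) / sj; fy += vel(j, 1) / sj; fz += vel(j, 2) / sj;
      }
      ++m;
    }
    const double si = std::sqrt(vel(i, 0) * vel(i, 0) +
                                vel(i, 1) * vel(i, 1) +
                                vel(i, 2) * vel(i, 2));
    const double hx = (si > 1e-12) ? vel(i, 0) / si : 1.0;
    const double hy = (si > 1e-12) ? vel(i, 1) / si : 0.0;
    const double hz = (si > 1e-12) ? vel(i, 2) / si : 0.0;
    if (m > 0) {
      // alignment: towards mean neighbour heading
      ax += w_ali * (fx / m - hx);
      ay += w_ali * (fy / m - hy);
      az += w_ali * (fz / m - hz);
      // cohesion: bounded steering towards the neighbour centroid
      // (saturates at w_coh beyond ~coh_sat metres of offset, so its
      // magnitude does not grow with flock spacing)
      const double ox = cx / m - pos(i, 0);
      const double oy = cy / m - pos(i, 1);
      const double oz = cz / m - pos(i, 2);
      const double on = std::sqrt(ox * ox + oy * oy + oz * oz);
      const double cw = w_coh / (on + coh_sat);
      ax += cw * ox;
      ay += cw * oy;
      az += cw * oz;
    }
    // speed regulation along current heading
    const double dv = w_spd * (cruise_speed - si);
    ax += dv * hx; ay += dv * hy; az += dv * hz;
    // damped altitude spring
    az += w_alt * (pref_altitude - pos(i, 2)) - w_alt_damp * vel(i, 2);
    acc(i, 0) = ax; acc(i, 1) = ay; acc(i, 2) = az;
  }
  return acc;
}
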