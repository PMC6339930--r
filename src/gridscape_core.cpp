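// Computational core: geometry queries, foraging simulation, oscillator
// integration, LAHN plasticity and the MLP decoder.  Everything that runs
// once per 10 ms timestep lives here; the R layer owns orchestration,
// analysis and plotting.  All randomness comes from R's RNG so that
// set.seed() in R makes every run bit-reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Rings {
  std::vector<arma::mat> rings; // each k x 2, closed implicitly (last->first)
};

Rings unpack_rings(const List& rlist) {
  Rings out;
  for (int i = 0; i < rlist.size(); ++i) {
    arma::mat m = as<arma::mat>(rlist[i]);
    out.rings.push_back(m);
  }
  return out;
}

// Even-odd rule over all rings: inside outer boundary and outside holes.
bool point_inside(const Rings& R, double px, double py) {
  bool inside = false;
  for (const arma::mat& ring : R.rings) {
    const arma::uword n = ring.n_rows;
    for (arma::uword i = 0, j = n - 1; i < n; j = i++) {
      const double xi = ring(i, 0), yi = ring(i, 1);
      const double xj = ring(j, 0), yj = ring(j, 1);
      if (((yi > py) != (yj > py)) &&
          (px < (xj - xi) * (py - yi) / (yj - yi) + xi))
        inside = !inside;
    }
  }
  return inside;
}

double seg_dist2(double px, double py, double x1, double y1, double x2,
                 double y2, double* nx = nullptr, double* ny = nullptr) {
  const double dx = x2 - x1, dy = y2 - y1;
  const double L2 = dx * dx + dy * dy;
  double t = 0.0;
  if (L2 > 0) t = std::max(0.0, std::min(1.0, ((px - x1) * dx + (py - y1) * dy) / L2));
  const double cx = x1 + t * dx, cy = y1 + t * dy;
  if (nx) { *nx = px - cx; *ny = py - cy; }
  return (px - cx) * (px - cx) + (py - cy) * (py - cy);
}

double wall_distance_one(const Rings& R, double px, double py) {
  double best = std::numeric_limits<double>::infinity();
  for (const arma::mat& ring : R.rings) {
    const arma::uword n = ring.n_rows;
    for (arma::uword i = 0, j = n - 1; i < n; j = i++) {
      const double d2 = seg_dist2(px, py, ring(j, 0), ring(j, 1), ring(i, 0), ring(i, 1));
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Unit normal (pointing from the wall toward the query point) of the
// nearest boundary segment; used for heading reflection on collision.
void nearest_wall_normal(const Rings& R, double px, double py, double* nx,
                         double* ny) {
  double best = std::numeric_limits<double>::infinity();
  double bx = 0, by = 1;
  for (const arma::mat& ring : R.rings) {
    const arma::uword n = ring.n_rows;
    for (arma::uword i = 0, j = n - 1; i < n; j = i++) {
      double vx, vy;
      const double d2 = seg_dist2(px, py, ring(j, 0), ring(j, 1), ring(i, 0), ring(i, 1), &vx, &vy);
      if (d2 < best) { best = d2; bx = vx; by = vy; }
    }
  }
  const double L = std::sqrt(bx * bx + by * by);
  if (L > 0) { *nx = bx / L; *ny = by / L; } else { *nx = 0; *ny = 1; }
}

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_points_in_rings(List rings, NumericVector x, NumericVector y) {
  Rings R = unpack_rings(rings);
  const int n = x.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = point_inside(R, x[i], y[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_wall_distance(List rings, NumericVector x, NumericVector y) {
  Rings R = unpack_rings(rings);
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = wall_distance_one(R, x[i], y[i]);
  return out;
}

// Curvature-constrained random foraging inside a fixed boundary.
// Heading random-walks with per-step turn bounded by rho*dt; speed equals
// the distance to the nearest wall, clamped between min_speed (so the
// border slowdown cannot become an absorbing trap) and speed_cap.  Steps
// that would cross a wall are rejected and the turn redrawn; after 10
// failed draws the heading is reflected off the wall normal.
// [[Rcpp::export]]
List cpp_simulate_path(List rings, int n_steps, double dt, double rho,
                       double speed_cap, double min_speed, double x0,
                       double y0, double theta0) {
  Rings R = unpack_rings(rings);
  NumericVector xs(n_steps + 1), ys(n_steps + 1), th(n_steps + 1), sp(n_steps + 1);
  double x = x0, y = y0, theta = theta0;
  xs[0] = x; ys[0] = y; th[0] = theta; sp[0] = 0.0;
  for (int k = 1; k <= n_steps; ++k) {
    const double d = wall_distance_one(R, x, y);
    const double sigma = std::min(std::max(d, min_speed), speed_cap);
    double tnew = theta, px = x, py = y;
    bool ok = false;
    for (int attempt = 0; attempt < 10; ++attempt) {
      const double gamma = R::runif(-1.0, 1.0);
      tnew = theta + gamma * rho * dt;
      px = x + sigma * dt * std::cos(tnew);
      py = y + sigma * dt * std::sin(tnew);
      if (point_inside(R, px, py)) { ok = true; break; }
    }
    if (!ok) {
      double nx, ny;
      nearest_wall_normal(R, x, y, &nx, &ny);
      double vx = std::cos(tnew), vy = std::sin(tnew);
      const double dot = vx * nx + vy * ny;
      vx -= 2.0 * dot * nx; vy -= 2.0 * dot * ny;
      tnew = std::atan2(vy, vx);
      px = x + sigma * dt * vx;
      py = y + sigma * dt * vy;
      if (!point_inside(R, px, py)) { px = x; py = y; } // stall in place
    }
    x = px; y = py; theta = tnew;
    xs[k] = x; ys[k] = y; th[k] = theta; sp[k] = sigma;
  }
  return List::create(_["x"] = xs, _["y"] = ys, _["theta"] = th, _["speed"] = sp);
}

// Foraging inside an axis-aligned rectangle [0, len] x [0, breadth(t)]
// whose breadth grows linearly to breadth_end over transform_time, then
// stays (the transforming-arena study).  Containment and wall distance are
// analytic here.
// [[Rcpp::export]]
List cpp_simulate_path_rect(double len, double breadth_start, double breadth_end,
                            double transform_time, int n_steps, double dt,
                            double rho, double speed_cap, double min_speed,
                            double x0, double y0, double theta0) {
  NumericVector xs(n_steps + 1), ys(n_steps + 1), th(n_steps + 1), sp(n_steps + 1),
      br(n_steps + 1);
  double x = x0, y = y0, theta = theta0;
  auto breadth_at = [&](double t) {
    if (transform_time <= 0 || t >= transform_time) return breadth_end;
    return breadth_start + (breadth_end - breadth_start) * t / transform_time;
  };
  xs[0] = x; ys[0] = y; th[0] = theta; sp[0] = 0.0; br[0] = breadth_at(0.0);
  for (int k = 1; k <= n_steps; ++k) {
    const double b = breadth_at(k * dt);
    const double d = std::min(std::min(x, len - x), std::min(y, b - y));
    const double sigma = std::min(std::max(std::max(d, 0.0), min_speed), speed_cap);
    double tnew = theta, px = x, py = y;
    bool ok = false;
    for (int attempt = 0; attempt < 10; ++attempt) {
      const double gamma = R::runif(-1.0, 1.0);
      tnew = theta + gamma * rho * dt;
      px = x + sigma * dt * std::cos(tnew);
      py = y + sigma * dt * std::sin(tnew);
      if (px > 0 && px < len && py > 0 && py < b) { ok = true; break; }
    }
    if (!ok) {
      // reflect off the offending axis-aligned wall(s)
      double vx = std::cos(tnew), vy = std::sin(tnew);
      if (px <= 0 || px >= len) vx = -vx;
      if (py <= 0 || py >= b) vy = -vy;
      tnew = std::atan2(vy, vx);
      px = x + sigma * dt * vx;
      py = y + sigma * dt * vy;
      if (!(px > 0 && px < len && py > 0 && py < b)) { px = x; py = y; }
    }
    x = px; y = py; theta = tnew;
    xs[k] = x; ys[k] = y; th[k] = theta; sp[k] = sigma; br[k] = b;
  }
  return List::create(_["x"] = xs, _["y"] = ys, _["theta"] = th, _["speed"] = sp,
                      _["breadth"] = br);
}

namespace {
// One step of the forced limit-cycle pair
//   du/dt = -v * om + u * (mu - (u^2 + v^2))
//   dv/dt =  u * om + v * (mu - (u^2 + v^2))
// with om held constant over the step.  In polar coordinates the system
// decouples exactly: dphi/dt = om (rigid rotation) and dr/dt =
// r (mu - r^2), whose solution is logistic in r^2.  Both parts are
// advanced in closed form, so the phase carries no per-step truncation
// error (an error that would otherwise accumulate into a slow drift of
// the interference lattice over a session) and the unforced radius
// relaxes to exactly sqrt(mu).
inline void polar_step(arma::vec& u, arma::vec& v, const arma::vec& om,
                       double mu, double dt) {
  const arma::uword n = u.n_elem;
  const double g = std::exp(2.0 * mu * dt);
  for (arma::uword i = 0; i < n; ++i) {
    const double r2 = u(i) * u(i) + v(i) * v(i);
    double phi = std::atan2(v(i), u(i)) + om(i) * dt;
    double r2n;
    if (mu != 0.0) {
      r2n = mu * r2 * g / (mu + r2 * (g - 1.0));
    } else {
      r2n = r2 / (1.0 + 2.0 * r2 * dt);
    }
    const double r = std::sqrt(r2n);
    u(i) = r * std::cos(phi);
    v(i) = r * std::sin(phi);
  }
}
} // namespace

// Single exposed oscillator step (shared by the R-level step_oscillators).
// [[Rcpp::export]]
List cpp_osc_step(arma::vec u, arma::vec v, arma::vec omega_inst, double mu,
                  double dt) {
  polar_step(u, v, omega_inst, mu, dt);
  return List::create(_["u"] = u, _["v"] = v);
}

// Drive the whole oscillator sheet along a trajectory.  pos is (T+1) x 2,
// heading length T+1; W is 2 x N (head-direction afferent weights).  The
// instantaneous frequency of oscillator i at step k is
//   omega + beta * s_k * thetaHD_i(k),  s_k = ||pos_k - pos_{k-1}|| / dt.
// Returns (T+1) x 2N [u | v] states.
// [[Rcpp::export]]
arma::mat cpp_osc_drive(const arma::mat& pos, const arma::vec& heading,
                        const arma::mat& W, double omega, double beta,
                        double mu, double dt, const arma::vec& u0,
                        const arma::vec& v0) {
  const arma::uword T = pos.n_rows;
  const arma::uword N = W.n_cols;
  arma::mat chi(T, 2 * N);
  arma::vec u = u0, v = v0;
  chi.row(0) = arma::join_rows(u.t(), v.t());
  for (arma::uword k = 1; k < T; ++k) {
    const double s =
        std::sqrt(std::pow(pos(k, 0) - pos(k - 1, 0), 2) +
                  std::pow(pos(k, 1) - pos(k - 1, 1), 2)) / dt;
    arma::vec psi = {std::cos(heading(k)), std::sin(heading(k))};
    arma::vec theta_hd = W.t() * psi;
    arma::vec om = omega + beta * s * theta_hd;
    polar_step(u, v, om, mu, dt);
    chi.row(k) = arma::join_rows(u.t(), v.t());
  }
  return chi;
}

// Online LAHN training over an input stream.
//   response: the lateral recurrence xi = q chi + w xi settled within the
//             sample, i.e. xi(t) = (I - w)^{-1} q chi(t) (the lateral loop
//             is much faster than the 10 ms input timestep; the settled
//             solution is also the only bounded reading of the recurrence
//             once anti-Hebbian learning grows |w| past unit spectral
//             radius)
//   dq = etaF * (xi chi' - diag(xi^2) q)   (Hebbian with Oja decay)
//   dw = -etaL * xi(t) xi(t-1)'            (anti-Hebbian), diag(w) = 0
// checkpoints: 1-based iteration indices at which to snapshot (q, w).
// dq_window: window length for the drift diagnostic (mean absolute net
// change of q per step per element over the window).
// [[Rcpp::export]]
List cpp_lahn_train(const arma::mat& chi, arma::mat q, arma::mat w,
                    double etaF, double etaL, IntegerVector checkpoints,
                    int dq_window) {
  const arma::uword T = chi.n_rows;
  const arma::uword n = q.n_rows;
  arma::mat xi_log(T, n, arma::fill::zeros);
  arma::vec xi_prev(n, arma::fill::zeros);
  std::vector<arma::mat> q_snaps, w_snaps;
  std::set<int> cps(checkpoints.begin(), checkpoints.end());
  std::vector<double> drift;
  arma::mat q_window_start = q;
  const arma::mat I = arma::eye(n, n);
  for (arma::uword t = 0; t < T; ++t) {
    arma::vec x = chi.row(t).t();
    arma::vec xi = arma::solve(I - w, q * x);
    xi_log.row(t) = xi.t();
    arma::vec xi2 = arma::square(xi);
    q += etaF * (xi * x.t() - arma::diagmat(xi2) * q);
    w += -etaL * (xi * xi_prev.t());
    w.diag().zeros();
    xi_prev = xi;
    const int it = static_cast<int>(t) + 1;
    if (cps.count(it)) { q_snaps.push_back(q); w_snaps.push_back(w); }
    if (dq_window > 0 && it % dq_window == 0) {
      drift.push_back(arma::accu(arma::abs(q - q_window_start)) /
                      (q.n_elem * dq_window));
      q_window_start = q;
    }
  }
  List qs(q_snaps.size()), ws(w_snaps.size());
  for (size_t i = 0; i < q_snaps.size(); ++i) { qs[i] = q_snaps[i]; ws[i] = w_snaps[i]; }
  return List::create(_["xi"] = xi_log, _["q"] = q, _["w"] = w,
                      _["q_checkpoints"] = qs, _["w_checkpoints"] = ws,
                      _["dq_drift"] = NumericVector(drift.begin(), drift.end()));
}

// Forward pass with frozen weights (for checkpoint replay): settled
// responses xi(t) = (I - w)^{-1} q chi(t), as in training.
// [[Rcpp::export]]
arma::mat cpp_lahn_replay(const arma::mat& chi, const arma::mat& q,
                          const arma::mat& w) {
  const arma::uword n = q.n_rows;
  const arma::mat A = arma::solve(arma::eye(n, n) - w, q); // n x m
  return chi * A.t();
}

// Per-lag sums for the autocorrelogram Pearson correlation, via 2-D FFT
// cross-correlations.  Z is the rate map with unvisited bins zeroed, V
// the visited indicator.  Returns, for every lag in [-L, L]^2 (x lag
// along rows), the overlap count M and the sums needed for the
// correlation of overlapping pixels:
//   S12 = sum Z(x) Z(x - tau),  S1 = sum Z(x) V(x - tau),
//   S2 = sum V(x) Z(x - tau),   S11 = sum Z^2(x) V(x - tau),
//   S22 = sum V(x) Z^2(x - tau)
namespace {
// smallest 5-smooth number >= n (FFT-friendly size)
arma::uword next_fast_size(arma::uword n) {
  for (arma::uword m = n;; ++m) {
    arma::uword k = m;
    while (k % 2 == 0) k /= 2;
    while (k % 3 == 0) k /= 3;
    while (k % 5 == 0) k /= 5;
    if (k == 1) return m;
  }
}
} // namespace

// [[Rcpp::export]]
List cpp_ac_sums(const arma::mat& Z, const arma::mat& V, int L) {
  const arma::uword pr = next_fast_size(Z.n_rows + L);
  const arma::uword pc = next_fast_size(Z.n_cols + L);
  auto pad = [&](const arma::mat& A) {
    arma::mat P(pr, pc, arma::fill::zeros);
    P.submat(0, 0, A.n_rows - 1, A.n_cols - 1) = A;
    return arma::cx_mat(P, arma::mat(pr, pc, arma::fill::zeros));
  };
  arma::cx_mat fZ = arma::fft2(pad(Z));
  arma::cx_mat fV = arma::fft2(pad(V));
  arma::cx_mat fZ2 = arma::fft2(pad(arma::square(Z)));
  // corr_AB(tau) = sum_x A(x + tau) B(x) = ifft( fft(A) * conj(fft(B)) )
  auto corr = [&](const arma::cx_mat& fA, const arma::cx_mat& fB) {
    arma::mat full = arma::real(arma::ifft2(fA % arma::conj(fB)));
    arma::mat out(2 * L + 1, 2 * L + 1);
    for (int i = -L; i <= L; ++i) {
      const arma::uword ri = (i >= 0) ? i : pr + i;
      for (int j = -L; j <= L; ++j) {
        const arma::uword cj = (j >= 0) ? j : pc + j;
        out(i + L, j + L) = full(ri, cj);
      }
    }
    return out;
  };
  arma::mat M = corr(fV, fV);
  arma::mat S12 = corr(fZ, fZ);
  arma::mat S1 = corr(fZ, fV);
  arma::mat S11 = corr(fZ2, fV);
  // S2(tau) = S1(-tau), S22(tau) = S11(-tau): mirror instead of extra FFTs
  arma::mat S2 = arma::flipud(arma::fliplr(S1));
  arma::mat S22 = arma::flipud(arma::fliplr(S11));
  return List::create(_["M"] = M, _["S12"] = S12, _["S1"] = S1,
                      _["S2"] = S2, _["S11"] = S11, _["S22"] = S22);
}

namespace {
inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }
} // namespace

// Single-hidden-layer perceptron, sigmoid units throughout, trained by
// plain online backpropagation on squared error.  Weights are initialised
// and samples shuffled with R's RNG.
// [[Rcpp::export]]
List cpp_mlp_train(const arma::mat& X, const arma::vec& y, int hidden,
                   double lr, int epochs, double init_scale) {
  const arma::uword N = X.n_rows, p = X.n_cols;
  arma::mat W1(p, hidden);
  arma::vec b1(hidden), W2(hidden);
  double b2;
  for (arma::uword i = 0; i < p; ++i)
    for (int j = 0; j < hidden; ++j) W1(i, j) = R::runif(-init_scale, init_scale);
  for (int j = 0; j < hidden; ++j) b1(j) = R::runif(-init_scale, init_scale);
  for (int j = 0; j < hidden; ++j) W2(j) = R::runif(-init_scale, init_scale);
  b2 = R::runif(-init_scale, init_scale);
  NumericVector mse_curve(epochs);
  std::vector<arma::uword> idx(N);
  for (arma::uword i = 0; i < N; ++i) idx[i] = i;
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with R's RNG
    for (arma::uword i = N - 1; i > 0; --i) {
      arma::uword j = static_cast<arma::uword>(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double sse = 0.0;
    for (arma::uword s = 0; s < N; ++s) {
      const arma::uword i = idx[s];
      arma::vec h = W1.t() * X.row(i).t() + b1;
      arma::vec a = 1.0 / (1.0 + arma::exp(-h));
      const double o = sigmoid(arma::dot(W2, a) + b2);
      const double err = o - y(i);
      sse += err * err;
      const double dout = err * o * (1.0 - o);
      arma::vec dh = dout * W2 % a % (1.0 - a);
      W2 -= lr * dout * a;
      b2 -= lr * dout;
      W1 -= lr * (X.row(i).t() * dh.t());
      b1 -= lr * dh;
    }
    mse_curve[ep] = sse / N;
  }
  return List::create(_["W1"] = W1, _["b1"] = b1, _["W2"] = W2, _["b2"] = b2,
                      _["mse_curve"] = mse_curve);
}

// [[Rcpp::export]]
arma::vec cpp_mlp_predict(const arma::mat& X, const arma::mat& W1,
                          const arma::vec& b1, const arma::vec& W2, double b2) {
  const arma::uword N = X.n_rows;
  arma::vec out(N);
  for (arma::uword i = 0; i < N; ++i) {
    arma::vec a = 1.0 / (1.0 + arma::exp(-(W1.t() * X.row(i).t() + b1)));
    out(i) = sigmoid(arma::dot(W2, a) + b2);
  }
  return out;
}
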