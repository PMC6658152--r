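#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// On-lattice diffusion-limited aggregation with noise reduction. Walkers
// are launched on a circle just outside the cluster, take unit 4-neighbour
// steps, stick on 4-neighbour contact with probability stick_p, and are
// discarded beyond a kill radius of 3x the cluster radius. Far from the
// cluster a walker takes a long jump in a uniform random direction whose
// length keeps it outside the launch circle (a walk-on-spheres step on an
// empty ball, so the harmonic measure is preserved to lattice accuracy).
// Uses R's RNG: deterministic under set.seed().
// [[Rcpp::export]]
IntegerMatrix dla_grow_cpp(int lattice, int particles, double stick_p) {
  if (particles < 1) stop("particles must be >= 1");
  IntegerMatrix grid(lattice, lattice);
  const int c = lattice / 2;
  grid(c, c) = 1;
  if (particles == 1) return grid;

  double rmax = 0.0;  // cluster radius
  const int dr[4] = {1, -1, 0, 0};
  const int dc[4] = {0, 0, 1, -1};

  for (int n = 1; n < particles; ++n) {
    const double rl = rmax + 5.0;           // launch radius
    const double rk = std::max(3.0 * rmax, 30.0);  // kill radius
    if (rl >= c - 2) stop("lattice too small for particle count");

    bool stuck = false;
    while (!stuck) {
      double th = 2.0 * M_PI * unif_rand();
      int xi = (int)std::lround(c + rl * std::cos(th));
      int yi = (int)std::lround(c + rl * std::sin(th));

      while (true) {
        const double dx = xi - c, dy = yi - c;
        const double d = std::sqrt(dx * dx + dy * dy);
        if (d > rk) break;  // killed: relaunch
        if (xi <= 1 || yi <= 1 || xi >= lattice - 2 || yi >= lattice - 2)
          break;            // off-grid: relaunch

        if (d > rl + 2.0) {
          // long jump of length d - rl: lands no closer than rl to the seed
          const double jump = d - rl;
          const double phi = 2.0 * M_PI * unif_rand();
          xi = (int)std::lround(xi + jump * std::cos(phi));
          yi = (int)std::lround(yi + jump * std::sin(phi));
          continue;
        }

        if (grid(xi + 1, yi) || grid(xi - 1, yi) ||
            grid(xi, yi + 1) || grid(xi, yi - 1)) {
          if (!grid(xi, yi) && unif_rand() < stick_p) {
            grid(xi, yi) = 1;
            if (d > rmax) rmax = d;
            stuck = true;
            break;
          }
          // noise reduction: contact without sticking, keep walking
        }

        int step = (int)(4.0 * unif_rand());
        if (step > 3) step = 3;
        const int xn = xi + dr[step], yn = yi + dc[step];
        if (!grid(xn, yn)) { xi = xn; yi = yn; }  // never walk onto the cluster
      }
    }
  }
  return grid;
}
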