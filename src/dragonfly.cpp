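#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Canonical dragonfly-algorithm swarm search (separation, alignment,
// cohesion, food attraction, enemy distraction) with linearly decaying
// inertia and behaviour weights and a Levy flight for neighbourless agents.
// `fn` is called once per iteration with the full swarm-position matrix and
// must return one objective value per row. Uses R's RNG, so results are
// reproducible under set.seed().
//
// [[Rcpp::export(name = ".da_core")]]
List da_core(Function fn, NumericVector lower, NumericVector upper,
             int swarm, int iters) {
  const int d = lower.size();
  NumericMatrix X(swarm, d), DX(swarm, d);
  std::vector<double> range(d), dmax(d);
  for (int j = 0; j < d; j++) {
    range[j] = upper[j] - lower[j];
    dmax[j] = range[j] / 10.0;
  }
  for (int i = 0; i < swarm; i++)
    for (int j = 0; j < d; j++) {
      X(i, j) = lower[j] + unif_rand() * range[j];
      DX(i, j) = (unif_rand() * 2.0 - 1.0) * dmax[j];
    }

  std::vector<double> food(d, 0.0), enemy(d, 0.0);
  double food_fit = R_PosInf, enemy_fit = R_NegInf;
  NumericVector trace(iters + 1);

  const double beta = 1.5;
  const double sigma = std::pow(
      (R::gammafn(1.0 + beta) * std::sin(M_PI * beta / 2.0)) /
          (R::gammafn((1.0 + beta) / 2.0) * beta * std::pow(2.0, (beta - 1.0) / 2.0)),
      1.0 / beta);

  for (int it = 1; it <= iters; it++) {
    NumericVector fit = fn(X);
    for (int i = 0; i < swarm; i++) {
      double f = fit[i];
      if (!R_finite(f)) f = 1e300;
      if (f < food_fit) {
        food_fit = f;
        for (int j = 0; j < d; j++) food[j] = X(i, j);
      }
      if (f > enemy_fit && f < 1e299) {
        enemy_fit = f;
        for (int j = 0; j < d; j++) enemy[j] = X(i, j);
      }
    }
    trace[it - 1] = food_fit;

    const double w = 0.9 - it * ((0.9 - 0.4) / iters);
    double my_c = 0.1 - it * (0.1 / (iters / 2.0));
    if (my_c < 0) my_c = 0;
    const double s_w = 2.0 * unif_rand() * my_c;
    const double a_w = 2.0 * unif_rand() * my_c;
    const double c_w = 2.0 * unif_rand() * my_c;
    const double f_w = 2.0 * unif_rand();
    const double e_w = my_c;
    std::vector<double> r(d);
    for (int j = 0; j < d; j++)
      r[j] = range[j] / 4.0 + range[j] * ((double)it / iters) * 2.0;

    NumericMatrix Xn = clone(X);
    for (int i = 0; i < swarm; i++) {
      std::vector<int> nb;
      for (int q = 0; q < swarm; q++) {
        if (q == i) continue;
        bool within = true, same = true;
        for (int j = 0; j < d; j++) {
          double dd = std::fabs(X(i, j) - X(q, j));
          if (dd > r[j]) { within = false; break; }
          if (dd != 0) same = false;
        }
        if (within && !same) nb.push_back(q);
      }
      const int nn = (int)nb.size();
      std::vector<double> S(d, 0.0), A(d, 0.0), C(d, 0.0), F(d, 0.0), E(d, 0.0);
      if (nn > 1) {
        for (int j = 0; j < d; j++) {
          double sx = 0, sdx = 0, sxx = 0;
          for (int q = 0; q < nn; q++) {
            sx += X(nb[q], j) - X(i, j);
            sdx += DX(nb[q], j);
            sxx += X(nb[q], j);
          }
          S[j] = -sx;
          A[j] = sdx / nn;
          C[j] = sxx / nn - X(i, j);
        }
      } else {
        for (int j = 0; j < d; j++) { A[j] = DX(i, j); }
      }
      bool food_near = true;
      for (int j = 0; j < d; j++)
        if (std::fabs(X(i, j) - food[j]) > r[j]) { food_near = false; break; }
      bool enemy_near = true;
      for (int j = 0; j < d; j++)
        if (std::fabs(X(i, j) - enemy[j]) > r[j]) { enemy_near = false; break; }
      if (food_near)
        for (int j = 0; j < d; j++) F[j] = food[j] - X(i, j);
      if (enemy_near)
        for (int j = 0; j < d; j++) E[j] = enemy[j] + X(i, j);

      if (!food_near) {
        if (nn > 1) {
          for (int j = 0; j < d; j++) {
            double dx = w * DX(i, j) + unif_rand() * A[j] +
                        unif_rand() * C[j] + unif_rand() * S[j];
            if (dx > dmax[j]) dx = dmax[j];
            if (dx < -dmax[j]) dx = -dmax[j];
            DX(i, j) = dx;
            Xn(i, j) = X(i, j) + dx;
          }
        } else {
          // no swarm in sight: Levy flight around the current position
          for (int j = 0; j < d; j++) {
            double r1 = norm_rand(), r2 = norm_rand();
            double levy = 0.01 * (r1 * sigma) /
                          std::pow(std::fabs(r2) + 1e-300, 1.0 / beta);
            Xn(i, j) = X(i, j) + levy * X(i, j);
            DX(i, j) = 0.0;
          }
        }
      } else {
        for (int j = 0; j < d; j++) {
          double dx = (s_w * S[j] + a_w * A[j] + c_w * C[j] + f_w * F[j] +
                       e_w * E[j]) + w * DX(i, j);
          if (dx > dmax[j]) dx = dmax[j];
          if (dx < -dmax[j]) dx = -dmax[j];
          DX(i, j) = dx;
          Xn(i, j) = X(i, j) + dx;
        }
      }
      for (int j = 0; j < d; j++) {
        if (Xn(i, j) < lower[j]) { Xn(i, j) = lower[j]; DX(i, j) = 0.0; }
        if (Xn(i, j) > upper[j]) { Xn(i, j) = upper[j]; DX(i, j) = 0.0; }
      }
    }
    X = Xn;
  }

  NumericVector fit = fn(X);
  for (int i = 0; i < swarm; i++) {
    double f = fit[i];
    if (!R_finite(f)) f = 1e300;
    if (f < food_fit) {
      food_fit = f;
      for (int j = 0; j < d; j++) food[j] = X(i, j);
    }
  }
  trace[iters] = food_fit;

  return List::create(_["par"] = NumericVector(food.begin(), food.end()),
                      _["value"] = food_fit, _["trace"] = trace);
}
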