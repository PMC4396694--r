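// BAOAB Langevin / metadynamics inner loop for analytic toy potentials.
// All replicas advance synchronously so replica-averaged restraints see a
// consistent average at every step. Uses R's RNG so runs are reproducible
// from set.seed() on the R side.
#include <Rcpp.h>
using namespace Rcpp;

static void toyGradient(const NumericVector& depths,
                        const NumericMatrix& centers,
                        const NumericVector& widths,
                        const NumericVector& wallCenter, double wallScale,
                        double wallPower, double wallHeight,
                        const double* x, int d, double* g) {
  for (int i = 0; i < d; ++i) g[i] = 0.0;
  int nw = centers.nrow();
  for (int k = 0; k < nw; ++k) {
    double d2 = 0.0;
    for (int i = 0; i < d; ++i) {
      double dx = x[i] - centers(k, i);
      d2 += dx * dx;
    }
    double w2 = widths[k] * widths[k];
    double e = depths[k] * std::exp(-d2 / (2.0 * w2));
    for (int i = 0; i < d; ++i)
      g[i] += (x[i] - centers(k, i)) * e / w2;
  }
  double r2 = 0.0;
  for (int i = 0; i < d; ++i) {
    double dx = x[i] - wallCenter[i];
    r2 += dx * dx;
  }
  double r = std::sqrt(r2);
  if (r > 1e-300 && wallHeight > 0) {
    double pref = wallHeight * wallPower *
      std::pow(r / wallScale, wallPower - 1.0) / (wallScale * r);
    for (int i = 0; i < d; ++i)
      g[i] += (x[i] - wallCenter[i]) * pref;
  }
}

// [[Rcpp::export]]
List bemeta_chunk_cpp(NumericMatrix X_, NumericMatrix V_,
                      IntegerVector cvIndex,
                      NumericVector depths, NumericMatrix centers,
                      NumericVector widths, NumericVector wallCenter,
                      double wallScale, double wallPower, double wallHeight,
                      List hillCenters, List hillTimes, NumericVector sigma,
                      double hillHeight, int hillStride,
                      double dt, double kT, double friction,
                      double stepOffset, int nSteps, int recordStride,
                      bool hasRestraint, NumericMatrix resA,
                      NumericVector resB, NumericVector resVal,
                      NumericVector resEps, double resK) {
  NumericMatrix X = clone(X_), V = clone(V_);
  int nrep = X.nrow(), d = X.ncol();
  RNGScope scope;

  std::vector<std::vector<double>> hc(nrep), ht(nrep), hh(nrep);
  for (int r = 0; r < nrep; ++r) {
    NumericVector c0 = hillCenters[r], t0 = hillTimes[r];
    hc[r].assign(c0.begin(), c0.end());
    ht[r].assign(t0.begin(), t0.end());
    hh[r].assign(c0.size(), hillHeight);
  }

  int nObs = hasRestraint ? resA.nrow() : 0;
  std::vector<double> avg(nObs), gE(nObs);

  int nrec = nSteps / recordStride + 1;
  std::vector<NumericMatrix> traj;
  for (int r = 0; r < nrep; ++r)
    traj.push_back(NumericMatrix(nrec, 2));
  std::vector<int> nrecUsed(nrep, 0);
  std::vector<double> resEseries;

  double c1 = std::exp(-friction * dt);
  double noise = std::sqrt(kT * (1.0 - c1 * c1));
  std::vector<double> grad(d);

  // force on replica r at its current position -> into F row
  NumericMatrix F(nrep, d);
  auto computeForces = [&](double tglob) {
    // restraint: average predictions over replicas, then chain rule
    if (hasRestraint) {
      for (int o = 0; o < nObs; ++o) {
        double s = 0.0;
        for (int r = 0; r < nrep; ++r) {
          double p = resB[o];
          for (int i = 0; i < d; ++i) p += resA(o, i) * X(r, i);
          s += p;
        }
        avg[o] = s / nrep;
        double dev = avg[o] - resVal[o];
        double ad = std::fabs(dev) - resEps[o];
        gE[o] = (ad > 0) ? 2.0 * resK * ad * (dev > 0 ? 1.0 : -1.0) : 0.0;
      }
    }
    for (int r = 0; r < nrep; ++r) {
      toyGradient(depths, centers, widths, wallCenter, wallScale,
                  wallPower, wallHeight, &X(r, 0), d, grad.data());
      for (int i = 0; i < d; ++i) F(r, i) = -grad[i];
      int ci = cvIndex[r];
      double s = X(r, ci);
      // bias force: -dV/ds, dV/ds = -sum w_k (s - c_k)/sigma^2 ... compute
      double dv = 0.0, s2 = sigma[r] * sigma[r];
      double cut2 = 64.0 * s2;  // hills beyond 8 sigma contribute < 1e-14 W
      for (size_t k = 0; k < hc[r].size(); ++k) {
        if (!(ht[r][k] < tglob)) break;
        double dc = s - hc[r][k];
        double dc2 = dc * dc;
        if (dc2 > cut2) continue;
        dv += hh[r][k] * std::exp(-dc2 / (2.0 * s2)) * (-dc / s2);
      }
      F(r, ci) -= dv;
      if (hasRestraint) {
        for (int i = 0; i < d; ++i) {
          double sens = 0.0;
          for (int o = 0; o < nObs; ++o) sens += gE[o] * resA(o, i);
          F(r, i) -= sens / nrep;
        }
      }
    }
  };

  computeForces(stepOffset);
  for (int step = 0; step < nSteps; ++step) {
    double tglob = stepOffset + step;
    // B
    for (int r = 0; r < nrep; ++r)
      for (int i = 0; i < d; ++i) V(r, i) += 0.5 * dt * F(r, i);
    // A
    for (int r = 0; r < nrep; ++r)
      for (int i = 0; i < d; ++i) X(r, i) += 0.5 * dt * V(r, i);
    // O
    for (int r = 0; r < nrep; ++r)
      for (int i = 0; i < d; ++i)
        V(r, i) = c1 * V(r, i) + noise * norm_rand();
    // A
    for (int r = 0; r < nrep; ++r)
      for (int i = 0; i < d; ++i) X(r, i) += 0.5 * dt * V(r, i);
    // B at new positions (hills deposited up to and incl. tglob act at
    // tglob+1; strict inequality k tau < t is preserved)
    double tnew = tglob + 1.0;
    // deposit hills at the *end* of steps aligned with the stride
    if (hillHeight > 0 &&
        ((long long)(tnew)) % hillStride == 0) {
      for (int r = 0; r < nrep; ++r) {
        hc[r].push_back(X(r, cvIndex[r]));
        ht[r].push_back(tnew);
        hh[r].push_back(hillHeight);
      }
    }
    computeForces(tnew);
    for (int r = 0; r < nrep; ++r)
      for (int i = 0; i < d; ++i) V(r, i) += 0.5 * dt * F(r, i);

    if (((long long)(tnew)) % recordStride == 0) {
      for (int r = 0; r < nrep; ++r) {
        traj[r](nrecUsed[r], 0) = tnew;
        traj[r](nrecUsed[r], 1) = X(r, cvIndex[r]);
        nrecUsed[r]++;
      }
      if (hasRestraint) {
        double E = 0.0;
        for (int o = 0; o < nObs; ++o) {
          double ad = std::fabs(avg[o] - resVal[o]) - resEps[o];
          if (ad > 0) E += resK * ad * ad;
        }
        resEseries.push_back(E);
      }
    }
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  List trajOut(nrep), hcOut(nrep), htOut(nrep), hhOut(nrep);
  for (int r = 0; r < nrep; ++r) {
    if (nrecUsed[r] > 0)
      trajOut[r] = traj[r](Range(0, nrecUsed[r] - 1), _);
    else
      trajOut[r] = NumericMatrix(0, 2);
    hcOut[r] = NumericVector(hc[r].begin(), hc[r].end());
    htOut[r] = NumericVector(ht[r].begin(), ht[r].end());
    hhOut[r] = NumericVector(hh[r].begin(), hh[r].end());
  }
  return List::create(_["X"] = X, _["V"] = V, _["traj"] = trajOut,
                      _["hillCenters"] = hcOut, _["hillTimes"] = htOut,
                      _["hillHeights"] = hhOut,
                      _["restraintEnergy"] =
                        NumericVector(resEseries.begin(), resEseries.end()));
}
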