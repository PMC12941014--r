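// Adaptive Metropolis-within-Gibbs sampler for BYM-type spatio-temporal
// count models:
//   y[cell] ~ Poisson(mu) or NegBin(mean mu, dispersion theta)
//   log mu  = offset + X beta + s_i + v_i + gamma_t + phi_t + delta_it
// with an intrinsic CAR prior on s (sum-to-zero enforced by re-centering
// into the flat-prior intercept each sweep), i.i.d. normal priors on v,
// phi, delta, an RW1 prior on gamma (gamma_0 pinned at 0), and conjugate
// gamma updates for every precision. Cells are tract-fastest; y < 0 marks
// a masked cell (no likelihood contribution). Uses R's RNG throughout so
// results are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline double cellLogLik(int y, double logmu, int family,
                                double theta) {
  double mu = std::exp(logmu);
  if (family == 0) {
    return y * logmu - mu - R::lgammafn(y + 1.0);
  }
  // NB with mean mu, variance mu + mu^2/theta
  return R::lgammafn(y + theta) - R::lgammafn(theta) -
         R::lgammafn(y + 1.0) + theta * std::log(theta / (theta + mu)) +
         y * (logmu - std::log(theta + mu));
}

struct Scale {
  std::vector<double> sd;
  std::vector<int> acc, tries;
  void init(int k, double s0) {
    sd.assign(k, s0); acc.assign(k, 0); tries.assign(k, 0);
  }
  void adapt(double step) {
    for (size_t j = 0; j < sd.size(); ++j) {
      if (tries[j] == 0) continue;
      double rate = (double)acc[j] / tries[j];
      sd[j] *= std::exp(step * (rate - 0.44));
      sd[j] = std::min(std::max(sd[j], 1e-6), 50.0);
      acc[j] = 0; tries[j] = 0;
    }
  }
  double accRate() const {
    long a = 0, t = 0;
    for (size_t j = 0; j < sd.size(); ++j) { a += acc[j]; t += tries[j]; }
    return t ? (double)a / t : NA_REAL;
  }
};

// [[Rcpp::export(name = ".st_sampler")]]
List st_sampler(IntegerVector y, NumericVector offset, NumericMatrix X,
                NumericVector priorMean, NumericVector priorPrec,
                IntegerVector nbrPtr, IntegerVector nbr, int nComp,
                int n, int T,
                bool hasS, bool hasV, bool hasG, bool hasP, bool hasD,
                int family, double tauA, double tauB,
                double ltMean, double ltPrec,
                int nBurn, int nKeep, int thin, List init) {
  const int nT = n * T, p = X.ncol();
  std::vector<double> beta = as<std::vector<double> >(init["beta"]);
  std::vector<double> s(n, 0.0), v(n, 0.0), gam(T, 0.0), phi(T, 0.0);
  std::vector<double> del(nT, 0.0);
  double tauS = init["tauS"], tauV = init["tauV"], tauG = init["tauG"],
         tauP = init["tauP"], tauD = init["tauD"];
  double logTheta = init["logTheta"];

  // fixed-effect linear predictor cache
  std::vector<double> xb(nT, 0.0);
  for (int c = 0; c < nT; ++c) {
    double a = 0.0;
    for (int j = 0; j < p; ++j) a += X(c, j) * beta[j];
    xb[c] = a;
  }
  std::vector<int> obsTract(n, 0), obsPeriod(T, 0);
  std::vector<char> obs(nT, 0);
  for (int t = 0; t < T; ++t)
    for (int i = 0; i < n; ++i) {
      int c = t * n + i;
      if (y[c] >= 0) { obs[c] = 1; obsTract[i]++; obsPeriod[t]++; }
    }

  // eta (log mu) for a cell from current state
  auto eta = [&](int i, int t) {
    int c = t * n + i;
    return offset[c] + xb[c] + s[i] + v[i] + gam[t] + phi[t] + del[c];
  };

  Scale scB, scS, scV, scG, scP, scD, scT;
  scB.init(1, 0.1); scS.init(n, 0.3); scV.init(n, 0.3);
  scG.init(T, 0.3); scP.init(T, 0.3); scD.init(nT, 0.3); scT.init(1, 0.5);

  // joint adaptive-Metropolis state for the fixed effects: proposal
  // d = betaScale * L z with L from the running empirical covariance
  double betaScale = 2.38 / std::sqrt((double)p);
  std::vector<double> cholL(p * p, 0.0), bSum(p, 0.0), bCross(p * p, 0.0);
  long bCount = 0;
  for (int j = 0; j < p; ++j) {
    double ssq = 0.0;
    for (int c = 0; c < nT; ++c) ssq += X(c, j) * X(c, j);
    double rms = std::sqrt(ssq / nT);
    cholL[j * p + j] = 0.1 / std::max(rms, 1e-8);
  }

  const int nIter = nBurn + nKeep * thin;
  NumericMatrix betaDraws(nKeep, p), tauDraws(nKeep, 5);
  NumericVector thetaDraws(nKeep), devDraws(nKeep);
  std::vector<double> rateSum(nT, 0.0), sSum(n, 0.0), vSum(n, 0.0),
      gSum(T, 0.0), pSum(T, 0.0), dSum(nT, 0.0);
  double maxAbsSumS = 0.0;
  int kept = 0;

  for (int iter = 0; iter < nIter; ++iter) {
    double theta = std::exp(logTheta);

    // ---- fixed effects: joint adaptive Metropolis ----
    {
      std::vector<double> z(p), d(p);
      for (int j = 0; j < p; ++j) z[j] = R::norm_rand();
      // d = scale * L z  (L lower-triangular)
      for (int j = 0; j < p; ++j) {
        double a = 0.0;
        for (int k = 0; k <= j; ++k) a += cholL[j * p + k] * z[k];
        d[j] = betaScale * a;
      }
      double lr = 0.0;
      std::vector<double> dxb(nT, 0.0);
      for (int c = 0; c < nT; ++c) {
        double a = 0.0;
        for (int j = 0; j < p; ++j) a += X(c, j) * d[j];
        dxb[c] = a;
        if (!obs[c]) continue;
        int i = c % n, t = c / n;
        double e = eta(i, t);
        lr += cellLogLik(y[c], e + a, family, theta) -
              cellLogLik(y[c], e, family, theta);
      }
      for (int j = 0; j < p; ++j) {
        if (priorPrec[j] <= 0.0) continue;
        double pn = beta[j] + d[j] - priorMean[j];
        double po = beta[j] - priorMean[j];
        lr += -0.5 * priorPrec[j] * (pn * pn - po * po);
      }
      bool acc = std::log(R::unif_rand()) < lr;
      if (acc) {
        for (int j = 0; j < p; ++j) beta[j] += d[j];
        for (int c = 0; c < nT; ++c) xb[c] += dxb[c];
      }
      if (iter < nBurn) {
        // Robbins-Monro on the global scale, target 0.25
        double step = 1.0 / std::sqrt(1.0 + iter / 50.0);
        betaScale *= std::exp(0.2 * step * ((acc ? 1.0 : 0.0) - 0.25));
        betaScale = std::min(std::max(betaScale, 1e-4), 10.0);
        // accumulate moments for the empirical proposal covariance
        for (int j = 0; j < p; ++j) {
          bSum[j] += beta[j];
          for (int k = 0; k <= j; ++k)
            bCross[j * p + k] += beta[j] * beta[k];
        }
        bCount++;
        if (bCount >= 200 && bCount % 50 == 0) {
          std::vector<double> S(p * p, 0.0);
          for (int j = 0; j < p; ++j)
            for (int k = 0; k <= j; ++k) {
              double c2 = bCross[j * p + k] / bCount -
                          (bSum[j] / bCount) * (bSum[k] / bCount);
              S[j * p + k] = S[k * p + j] = c2;
            }
          for (int j = 0; j < p; ++j)
            S[j * p + j] += 1e-8 + 1e-6 * S[j * p + j];
          // in-place Cholesky of S -> cholL (fall back: keep previous)
          std::vector<double> L(p * p, 0.0);
          bool ok = true;
          for (int j = 0; j < p && ok; ++j) {
            double sum = S[j * p + j];
            for (int k = 0; k < j; ++k) sum -= L[j * p + k] * L[j * p + k];
            if (sum <= 0.0) { ok = false; break; }
            L[j * p + j] = std::sqrt(sum);
            for (int r = j + 1; r < p; ++r) {
              double a = S[r * p + j];
              for (int k = 0; k < j; ++k)
                a -= L[r * p + k] * L[j * p + k];
              L[r * p + j] = a / L[j * p + j];
            }
          }
          if (ok) cholL = L;
        }
      } else {
        scB.tries[0]++;
        if (acc) scB.acc[0]++;
      }
    }

    // ---- spatial ICAR field ----
    if (hasS) {
      for (int i = 0; i < n; ++i) {
        int mi = nbrPtr[i + 1] - nbrPtr[i];
        if (mi == 0) continue;  // isolated: conditional undefined, keep 0
        double sbar = 0.0;
        for (int k = nbrPtr[i]; k < nbrPtr[i + 1]; ++k) sbar += s[nbr[k]];
        sbar /= mi;
        if (obsTract[i] == 0) {  // exact conditional draw from the prior
          s[i] = sbar + R::norm_rand() / std::sqrt(tauS * mi);
          continue;
        }
        double prop = s[i] + R::norm_rand() * scS.sd[i];
        double lr = -0.5 * tauS * mi *
                    ((prop - sbar) * (prop - sbar) -
                     (s[i] - sbar) * (s[i] - sbar));
        for (int t = 0; t < T; ++t) {
          int c = t * n + i;
          if (!obs[c]) continue;
          double e = eta(i, t);
          lr += cellLogLik(y[c], e + (prop - s[i]), family, theta) -
                cellLogLik(y[c], e, family, theta);
        }
        scS.tries[i]++;
        if (std::log(R::unif_rand()) < lr) { scS.acc[i]++; s[i] = prop; }
      }
      // re-centre; the level moves into the (flat-prior) intercept
      double ms = 0.0;
      for (int i = 0; i < n; ++i) ms += s[i];
      ms /= n;
      for (int i = 0; i < n; ++i) s[i] -= ms;
      beta[0] += ms;
      for (int c = 0; c < nT; ++c) xb[c] += ms;
      // conjugate tau_s update from the pairwise-difference quadratic form
      double q = 0.0;
      for (int i = 0; i < n; ++i)
        for (int k = nbrPtr[i]; k < nbrPtr[i + 1]; ++k) {
          double dd = s[i] - s[nbr[k]];
          q += dd * dd;
        }
      q *= 0.5;  // each undirected edge visited twice
      tauS = R::rgamma(tauA + 0.5 * (n - nComp), 1.0 / (tauB + 0.5 * q));
    }

    // ---- iid tract effects ----
    if (hasV) {
      for (int i = 0; i < n; ++i) {
        if (obsTract[i] == 0) {
          v[i] = R::norm_rand() / std::sqrt(tauV);
          continue;
        }
        double prop = v[i] + R::norm_rand() * scV.sd[i];
        double lr = -0.5 * tauV * (prop * prop - v[i] * v[i]);
        for (int t = 0; t < T; ++t) {
          int c = t * n + i;
          if (!obs[c]) continue;
          double e = eta(i, t);
          lr += cellLogLik(y[c], e + (prop - v[i]), family, theta) -
                cellLogLik(y[c], e, family, theta);
        }
        scV.tries[i]++;
        if (std::log(R::unif_rand()) < lr) { scV.acc[i]++; v[i] = prop; }
      }
      double q = 0.0;
      for (int i = 0; i < n; ++i) q += v[i] * v[i];
      tauV = R::rgamma(tauA + 0.5 * n, 1.0 / (tauB + 0.5 * q));
    }

    // ---- RW1 temporal effects (gamma_0 = 0) ----
    if (hasG) {
      for (int t = 0; t < T; ++t) {
        double prev = (t == 0) ? 0.0 : gam[t - 1];
        if (obsPeriod[t] == 0) {
          if (t < T - 1) {
            double m = 0.5 * (prev + gam[t + 1]);
            gam[t] = m + R::norm_rand() / std::sqrt(2.0 * tauG);
          } else {
            gam[t] = prev + R::norm_rand() / std::sqrt(tauG);
          }
          continue;
        }
        double prop = gam[t] + R::norm_rand() * scG.sd[t];
        double lr = -0.5 * tauG * ((prop - prev) * (prop - prev) -
                                   (gam[t] - prev) * (gam[t] - prev));
        if (t < T - 1)
          lr += -0.5 * tauG * ((gam[t + 1] - prop) * (gam[t + 1] - prop) -
                               (gam[t + 1] - gam[t]) * (gam[t + 1] - gam[t]));
        for (int i = 0; i < n; ++i) {
          int c = t * n + i;
          if (!obs[c]) continue;
          double e = eta(i, t);
          lr += cellLogLik(y[c], e + (prop - gam[t]), family, theta) -
                cellLogLik(y[c], e, family, theta);
        }
        scG.tries[t]++;
        if (std::log(R::unif_rand()) < lr) { scG.acc[t]++; gam[t] = prop; }
      }
      double q = 0.0;
      for (int t = 0; t < T; ++t) {
        double prev = (t == 0) ? 0.0 : gam[t - 1];
        q += (gam[t] - prev) * (gam[t] - prev);
      }
      tauG = R::rgamma(tauA + 0.5 * T, 1.0 / (tauB + 0.5 * q));
    }

    // ---- iid temporal effects ----
    if (hasP) {
      for (int t = 0; t < T; ++t) {
        if (obsPeriod[t] == 0) {
          phi[t] = R::norm_rand() / std::sqrt(tauP);
          continue;
        }
        double prop = phi[t] + R::norm_rand() * scP.sd[t];
        double lr = -0.5 * tauP * (prop * prop - phi[t] * phi[t]);
        for (int i = 0; i < n; ++i) {
          int c = t * n + i;
          if (!obs[c]) continue;
          double e = eta(i, t);
          lr += cellLogLik(y[c], e + (prop - phi[t]), family, theta) -
                cellLogLik(y[c], e, family, theta);
        }
        scP.tries[t]++;
        if (std::log(R::unif_rand()) < lr) { scP.acc[t]++; phi[t] = prop; }
      }
      double q = 0.0;
      for (int t = 0; t < T; ++t) q += phi[t] * phi[t];
      tauP = R::rgamma(tauA + 0.5 * T, 1.0 / (tauB + 0.5 * q));
    }

    // ---- space-time interaction ----
    if (hasD) {
      for (int c = 0; c < nT; ++c) {
        if (!obs[c]) {
          del[c] = R::norm_rand() / std::sqrt(tauD);
          continue;
        }
        int i = c % n, t = c / n;
        double prop = del[c] + R::norm_rand() * scD.sd[c];
        double e = eta(i, t);
        double lr = -0.5 * tauD * (prop * prop - del[c] * del[c]) +
                    cellLogLik(y[c], e + (prop - del[c]), family, theta) -
                    cellLogLik(y[c], e, family, theta);
        scD.tries[c]++;
        if (std::log(R::unif_rand()) < lr) { scD.acc[c]++; del[c] = prop; }
      }
      double q = 0.0;
      for (int c = 0; c < nT; ++c) q += del[c] * del[c];
      tauD = R::rgamma(tauA + 0.5 * nT, 1.0 / (tauB + 0.5 * q));
    }

    // ---- NB dispersion ----
    if (family == 1) {
      double prop = logTheta + R::norm_rand() * scT.sd[0];
      double thNew = std::exp(prop), lr = 0.0;
      for (int c = 0; c < nT; ++c) {
        if (!obs[c]) continue;
        int i = c % n, t = c / n;
        double e = eta(i, t);
        lr += cellLogLik(y[c], e, family, thNew) -
              cellLogLik(y[c], e, family, theta);
      }
      if (ltPrec > 0.0)
        lr += -0.5 * ltPrec * ((prop - ltMean) * (prop - ltMean) -
                               (logTheta - ltMean) * (logTheta - ltMean));
      scT.tries[0]++;
      if (std::log(R::unif_rand()) < lr) {
        scT.acc[0]++;
        logTheta = prop;
      }
    }

    // ---- adaptation during burn-in ----
    if (iter < nBurn && (iter + 1) % 50 == 0) {
      double step = std::min(0.25, 2.0 / std::sqrt((iter + 1.0) / 50.0));
      scB.adapt(step); scS.adapt(step); scV.adapt(step);
      scG.adapt(step); scP.adapt(step); scD.adapt(step); scT.adapt(step);
    }

    // ---- store ----
    if (iter >= nBurn && (iter - nBurn) % thin == 0) {
      double theta2 = std::exp(logTheta);
      for (int j = 0; j < p; ++j) betaDraws(kept, j) = beta[j];
      tauDraws(kept, 0) = tauS; tauDraws(kept, 1) = tauV;
      tauDraws(kept, 2) = tauG; tauDraws(kept, 3) = tauP;
      tauDraws(kept, 4) = tauD;
      thetaDraws[kept] = theta2;
      double dev = 0.0, ssum = 0.0;
      for (int i = 0; i < n; ++i) ssum += s[i];
      if (std::fabs(ssum) > maxAbsSumS) maxAbsSumS = std::fabs(ssum);
      for (int c = 0; c < nT; ++c) {
        int i = c % n, t = c / n;
        double e = eta(i, t);
        rateSum[c] += std::exp(e - offset[c]);
        if (obs[c]) dev += cellLogLik(y[c], e, family, theta2);
      }
      devDraws[kept] = -2.0 * dev;
      for (int i = 0; i < n; ++i) { sSum[i] += s[i]; vSum[i] += v[i]; }
      for (int t = 0; t < T; ++t) { gSum[t] += gam[t]; pSum[t] += phi[t]; }
      for (int c = 0; c < nT; ++c) dSum[c] += del[c];
      kept++;
    }
  }

  auto toMean = [&](std::vector<double>& xv) {
    NumericVector out(xv.size());
    for (size_t i = 0; i < xv.size(); ++i) out[i] = xv[i] / kept;
    return out;
  };
  std::vector<double> rs = rateSum;
  return List::create(
      _["beta"] = betaDraws, _["tau"] = tauDraws, _["theta"] = thetaDraws,
      _["deviance"] = devDraws,
      _["rateMean"] = toMean(rs),
      _["sMean"] = toMean(sSum), _["vMean"] = toMean(vSum),
      _["gammaMean"] = toMean(gSum), _["phiMean"] = toMean(pSum),
      _["deltaMean"] = toMean(dSum),
      _["maxAbsSumS"] = maxAbsSumS,
      _["accept"] = NumericVector::create(
          _["beta"] = scB.accRate(), _["s"] = scS.accRate(),
          _["v"] = scV.accRate(), _["gamma"] = scG.accRate(),
          _["phi"] = scP.accRate(), _["delta"] = scD.accRate(),
          _["theta"] = scT.accRate()));
}
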