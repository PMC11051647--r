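#include <Rcpp.h>
using namespace Rcpp;

// Age every adult compartment by one day: counts shift up one daily age
// class, the age-1 class empties, flies beyond the last class are dropped.
// [[Rcpp::export]]
NumericMatrix cpp_age_adults(const NumericMatrix& A) {
  const int n = A.nrow(), k = A.ncol();
  NumericMatrix out(n, k);
  for (int a = 1; a < k; ++a) {
    for (int i = 0; i < n; ++i) out(i, a) = A(i, a - 1);
  }
  return out;
}

// Age pupae by one day; pupae leaving the final compartment are returned
// separately as the day's mature (about-to-emerge) pupae.
// [[Rcpp::export]]
List cpp_age_pupae(const NumericMatrix& P) {
  const int n = P.nrow(), k = P.ncol();
  NumericMatrix out(n, k);
  NumericVector mature(n);
  for (int i = 0; i < n; ++i) mature[i] = P(i, k - 1);
  for (int a = 1; a < k; ++a) {
    for (int i = 0; i < n; ++i) out(i, a) = P(i, a - 1);
  }
  return List::create(_["pupae"] = out, _["mature"] = mature);
}

// Density-dependent natural mortality for one day. Densities are per km2 of
// habitat (cell count / cover). Survival is clamped to [0, 1].
// [[Rcpp::export]]
List cpp_mortality(const NumericMatrix& F, const NumericMatrix& M,
                   const NumericMatrix& P, const NumericVector& mature,
                   const NumericVector& cover, const NumericVector& mfac,
                   double msf, double msm, double msp, double k,
                   double s_adult, double s_pupa) {
  const int n = F.nrow(), ka = F.ncol(), kp = P.ncol();
  NumericMatrix Fo(n, ka), Mo(n, ka), Po(n, kp);
  NumericVector mato(n), surv_f(n), surv_m(n), surv_p(n);
  std::vector<double> dad(n, 0.0), dpu(n, 0.0);
  for (int a = 0; a < ka; ++a)
    for (int i = 0; i < n; ++i) dad[i] += F(i, a) + M(i, a);
  for (int a = 0; a < kp; ++a)
    for (int i = 0; i < n; ++i) dpu[i] += P(i, a);
  for (int i = 0; i < n; ++i) dpu[i] += mature[i];
  for (int i = 0; i < n; ++i) {
    const double da = dad[i] / cover[i];
    const double dp = dpu[i] / cover[i];
    const double dd_a = (1.0 - k) + k * da / s_adult;
    const double dd_p = (1.0 - k) + k * dp / s_pupa;
    double sf = 1.0 - mfac[i] * msf * dd_a;
    double sm = 1.0 - mfac[i] * msm * dd_a;
    double sp = 1.0 - mfac[i] * msp * dd_p;
    surv_f[i] = sf < 0 ? 0 : (sf > 1 ? 1 : sf);
    surv_m[i] = sm < 0 ? 0 : (sm > 1 ? 1 : sm);
    surv_p[i] = sp < 0 ? 0 : (sp > 1 ? 1 : sp);
  }
  for (int a = 0; a < ka; ++a) {
    for (int i = 0; i < n; ++i) {
      Fo(i, a) = F(i, a) * surv_f[i];
      Mo(i, a) = M(i, a) * surv_m[i];
    }
  }
  for (int a = 0; a < kp; ++a)
    for (int i = 0; i < n; ++i) Po(i, a) = P(i, a) * surv_p[i];
  for (int i = 0; i < n; ++i) mato[i] = mature[i] * surv_p[i];
  return List::create(_["F"] = Fo, _["M"] = Mo, _["P"] = Po,
                      _["mature"] = mato, _["surv_f"] = surv_f,
                      _["surv_m"] = surv_m, _["surv_p"] = surv_p);
}

// One day of lattice movement for one sex: out = A_state + p[age] * (A %*%
// A_state), where A is the (conservative) movement operator in compressed
// sparse column form and p the age-dependent evacuation probability.
// [[Rcpp::export]]
NumericMatrix cpp_move(const NumericMatrix& A_state, const IntegerVector& Ai,
                       const IntegerVector& Ap, const NumericVector& Ax,
                       const NumericVector& p) {
  const int n = A_state.nrow(), ka = A_state.ncol();
  NumericMatrix out = clone(A_state);
  for (int a = 0; a < ka; ++a) {
    const double pa = p[a];
    if (pa == 0.0) continue;
    for (int j = 0; j < n; ++j) {
      const double v = A_state(j, a);
      if (v == 0.0) continue;
      const double pv = pa * v;
      for (int idx = Ap[j]; idx < Ap[j + 1]; ++idx) {
        out(Ai[idx], a) += Ax[idx] * pv;
      }
    }
  }
  return out;
}

// Fused multi-day loop used by run_simulation() and burn_in().  Executes the
// same daily sequence as the composable step functions (aging, natural
// mortality, movement, control, larviposition, emergence) on in-place
// buffers; equivalence with the step composition is asserted by the test
// suite.  eff_by_day < 0 marks a day with no active control.
// [[Rcpp::export]]
List cpp_run_chunk(const NumericMatrix& F0, const NumericMatrix& M0,
                   const NumericMatrix& P0,
                   const NumericVector& cover, const NumericVector& mfac,
                   double msf, double msm, double msp, double k,
                   double s_adult, double s_pupa,
                   const IntegerVector& Ai, const IntegerVector& Ap,
                   const NumericVector& Ax,
                   const NumericVector& pf, const NumericVector& pm,
                   bool move,
                   const NumericVector& fec,
                   const IntegerVector& treated, const NumericVector& tdens,
                   const NumericVector& rate_f, const NumericVector& rate_m,
                   const NumericVector& eff_by_day, int ndays,
                   bool record, const IntegerVector& rec_cells,
                   int old_age, int mobile_age,
                   bool track_change, double change_floor) {
  const int n = F0.nrow(), A = F0.ncol(), PD = P0.ncol();
  const int nt = treated.size(), nrc = rec_cells.size();
  std::vector<double> f(F0.begin(), F0.end());
  std::vector<double> m(M0.begin(), M0.end());
  std::vector<double> p(P0.begin(), P0.end());
  std::vector<double> fbuf(n * A), mbuf(n * A);
  std::vector<double> mature(n), dad(n), dpu(n), L(n);
  std::vector<double> pooled_prev(n), pooled_cur(n);

  NumericVector rec_f, rec_m, rec_p, rec_larv, rec_kf, rec_km, rec_fpre,
      rec_mpre, rel_change;
  NumericMatrix fage, mage, cA, cF, cFo, cAm;
  if (record) {
    rec_f = NumericVector(ndays); rec_m = NumericVector(ndays);
    rec_p = NumericVector(ndays); rec_larv = NumericVector(ndays);
    rec_kf = NumericVector(ndays); rec_km = NumericVector(ndays);
    rec_fpre = NumericVector(ndays); rec_mpre = NumericVector(ndays);
    fage = NumericMatrix(A, ndays); mage = NumericMatrix(A, ndays);
    if (nrc) {
      cA = NumericMatrix(nrc, ndays); cF = NumericMatrix(nrc, ndays);
      cFo = NumericMatrix(nrc, ndays); cAm = NumericMatrix(nrc, ndays);
    }
  }
  if (track_change) {
    rel_change = NumericVector(ndays);
    for (int i = 0; i < n; ++i) {
      double s = 0;
      for (int a = 0; a < A; ++a) s += f[a * n + i] + m[a * n + i];
      pooled_prev[i] = s;
    }
  }

  for (int t = 0; t < ndays; ++t) {
    // (1) aging: shift every compartment up one day
    std::copy(p.begin() + (PD - 1) * n, p.begin() + PD * n, mature.begin());
    std::memmove(p.data() + n, p.data(), sizeof(double) * n * (PD - 1));
    std::fill(p.begin(), p.begin() + n, 0.0);
    std::memmove(f.data() + n, f.data(), sizeof(double) * n * (A - 1));
    std::fill(f.begin(), f.begin() + n, 0.0);
    std::memmove(m.data() + n, m.data(), sizeof(double) * n * (A - 1));
    std::fill(m.begin(), m.begin() + n, 0.0);

    // (2) density-dependent natural mortality
    std::fill(dad.begin(), dad.end(), 0.0);
    std::fill(dpu.begin(), dpu.end(), 0.0);
    for (int a = 0; a < A; ++a) {
      const double* fa = f.data() + a * n;
      const double* ma = m.data() + a * n;
      for (int i = 0; i < n; ++i) dad[i] += fa[i] + ma[i];
    }
    for (int a = 0; a < PD; ++a) {
      const double* pa = p.data() + a * n;
      for (int i = 0; i < n; ++i) dpu[i] += pa[i];
    }
    for (int i = 0; i < n; ++i) dpu[i] += mature[i];
    // reuse dad/dpu as survival factors
    for (int i = 0; i < n; ++i) {
      const double dd_a = (1.0 - k) + k * dad[i] / (cover[i] * s_adult);
      const double dd_p = (1.0 - k) + k * dpu[i] / (cover[i] * s_pupa);
      double sf = 1.0 - mfac[i] * msf * dd_a;
      double sm = 1.0 - mfac[i] * msm * dd_a;
      double sp = 1.0 - mfac[i] * msp * dd_p;
      dad[i] = sf < 0 ? 0 : sf;     // female survival
      L[i] = sm < 0 ? 0 : sm;       // male survival (temp)
      dpu[i] = sp < 0 ? 0 : sp;     // pupal survival
    }
    for (int a = 0; a < A; ++a) {
      double* fa = f.data() + a * n;
      double* ma = m.data() + a * n;
      for (int i = 0; i < n; ++i) { fa[i] *= dad[i]; ma[i] *= L[i]; }
    }
    for (int a = 0; a < PD; ++a) {
      double* pa = p.data() + a * n;
      for (int i = 0; i < n; ++i) pa[i] *= dpu[i];
    }
    for (int i = 0; i < n; ++i) mature[i] *= dpu[i];

    // (3) movement: out = x + p_age * (A x)
    if (move) {
      std::copy(f.begin(), f.end(), fbuf.begin());
      std::copy(m.begin(), m.end(), mbuf.begin());
      for (int a = 0; a < A; ++a) {
        const double pa_f = pf[a], pa_m = pm[a];
        const double* fa = f.data() + a * n;
        const double* ma = m.data() + a * n;
        double* foa = fbuf.data() + a * n;
        double* moa = mbuf.data() + a * n;
        for (int j = 0; j < n; ++j) {
          const double vf = pa_f * fa[j], vm = pa_m * ma[j];
          if (vf == 0.0 && vm == 0.0) continue;
          for (int idx = Ap[j]; idx < Ap[j + 1]; ++idx) {
            foa[Ai[idx]] += Ax[idx] * vf;
            moa[Ai[idx]] += Ax[idx] * vm;
          }
        }
      }
      f.swap(fbuf);
      m.swap(mbuf);
    }

    // (4) control mortality in treated cells
    const double eff = eff_by_day[t];
    double killed_f = 0.0, killed_m = 0.0, fpre = 0.0, mpre = 0.0;
    if (record) {
      for (size_t ii = 0; ii < f.size(); ++ii) fpre += f[ii];
      for (size_t ii = 0; ii < m.size(); ++ii) mpre += m[ii];
    }
    if (eff >= 0.0 && nt > 0) {
      for (int a = 0; a < A; ++a) {
        double* fa = f.data() + a * n;
        double* ma = m.data() + a * n;
        const double rf = rate_f[a] * eff, rm = rate_m[a] * eff;
        for (int j = 0; j < nt; ++j) {
          const int i = treated[j];
          double qf = rf * tdens[j]; if (qf > 1) qf = 1;
          double qm = rm * tdens[j]; if (qm > 1) qm = 1;
          killed_f += fa[i] * qf;
          killed_m += ma[i] * qm;
          fa[i] *= 1.0 - qf;
          ma[i] *= 1.0 - qm;
        }
      }
    }

    // (5) larviposition: the day's crop of larvae pupates immediately
    double larvae = 0.0;
    std::fill(L.begin(), L.end(), 0.0);
    for (int a = 0; a < A; ++a) {
      if (fec[a] == 0.0) continue;
      const double* fa = f.data() + a * n;
      for (int i = 0; i < n; ++i) L[i] += fec[a] * fa[i];
    }
    for (int i = 0; i < n; ++i) { p[i] = L[i]; larvae += L[i]; }

    // (6) emergence: mature pupae become age-1 adults, sex ratio 1:1
    for (int i = 0; i < n; ++i) {
      f[i] += 0.5 * mature[i];
      m[i] += 0.5 * mature[i];
    }

    if (record) {
      double fs = 0, ms_ = 0, ps = 0;
      for (int a = 0; a < A; ++a) {
        const double* fa = f.data() + a * n;
        const double* ma = m.data() + a * n;
        double cf = 0, cm = 0;
        for (int i = 0; i < n; ++i) { cf += fa[i]; cm += ma[i]; }
        fage(a, t) = cf; mage(a, t) = cm;
        fs += cf; ms_ += cm;
      }
      for (size_t ii = 0; ii < p.size(); ++ii) ps += p[ii];
      rec_f[t] = fs; rec_m[t] = ms_; rec_p[t] = ps;
      rec_larv[t] = larvae;
      rec_kf[t] = killed_f; rec_km[t] = killed_m;
      rec_fpre[t] = fpre; rec_mpre[t] = mpre;
      for (int jj = 0; jj < nrc; ++jj) {
        const int i = rec_cells[jj];
        double sa = 0, sf = 0, sfo = 0, sam = 0;
        for (int a = 0; a < A; ++a) {
          const double fv = f[a * n + i], mv = m[a * n + i];
          sa += fv + mv; sf += fv;
          if (a + 1 > old_age) sfo += fv;
          if (a + 1 >= mobile_age) sam += fv + mv;
        }
        cA(jj, t) = sa; cF(jj, t) = sf; cFo(jj, t) = sfo; cAm(jj, t) = sam;
      }
    }
    if (track_change) {
      double mx = 0.0;
      for (int i = 0; i < n; ++i) {
        double s = 0;
        for (int a = 0; a < A; ++a) s += f[a * n + i] + m[a * n + i];
        pooled_cur[i] = s;
        const double denom =
            pooled_prev[i] > change_floor ? pooled_prev[i] : change_floor;
        const double rc = std::abs(s - pooled_prev[i]) / denom;
        if (rc > mx) mx = rc;
      }
      rel_change[t] = mx;
      pooled_prev.swap(pooled_cur);
    }
  }

  NumericMatrix Fo(n, A), Mo(n, A), Po(n, PD);
  std::copy(f.begin(), f.end(), Fo.begin());
  std::copy(m.begin(), m.end(), Mo.begin());
  std::copy(p.begin(), p.end(), Po.begin());
  List out = List::create(_["F"] = Fo, _["M"] = Mo, _["P"] = Po);
  if (record) {
    out["females"] = rec_f; out["males"] = rec_m; out["pupae"] = rec_p;
    out["larvae"] = rec_larv; out["killed_f"] = rec_kf;
    out["killed_m"] = rec_km; out["fpre"] = rec_fpre;
    out["mpre"] = rec_mpre; out["fage"] = fage; out["mage"] = mage;
    if (nrc) {
      out["cell_adults"] = cA; out["cell_females"] = cF;
      out["cell_females_old"] = cFo; out["cell_adults_mobile"] = cAm;
    }
  }
  if (track_change) out["rel_change"] = rel_change;
  return out;
}
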