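// Production microsimulation engine.
//
// Implements, person by person, the identical draw protocol as the
// interpreted reference implementation in R/natural-history.R and
// R/screening.R (see the protocol comments there). Each person owns two
// counter-based Wichmann-Hill uniform streams derived from (seed, person):
// stream 1 for natural history (shared by both arms -> common random
// numbers), stream 2 for screening. All stream arithmetic uses exact
// double-precision integer operations so the two engines agree draw for
// draw.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double PS_M = 2147483647.0;

// Positive modulo via the floor identity; matches R's `%%` exactly and all
// quantities involved are integers below 2^53, so the result is exact.
static inline double pmod(double x, double y) {
  return x - std::floor(x / y) * y;
}

static inline double ps_mix(double x) { return pmod(16807.0 * x, PS_M); }

struct WHStream {
  double s1, s2, s3;
  void seed_from(double seed, double person, double stream) {
    double s = pmod(std::fabs(seed), PS_M) + 1.0;
    s = ps_mix(s);
    s = pmod(s + person, PS_M);
    if (s == 0.0) s = 1.0;
    s = ps_mix(s);
    s = pmod(s + 97.0 * stream + 1.0, PS_M);
    if (s == 0.0) s = 1.0;
    s = ps_mix(s);
    s = ps_mix(s);
    s1 = pmod(s, 30268.0) + 1.0;
    s = ps_mix(s);
    s2 = pmod(s, 30306.0) + 1.0;
    s = ps_mix(s);
    s3 = pmod(s, 30322.0) + 1.0;
  }
  double next() {
    s1 = pmod(171.0 * s1, 30269.0);
    s2 = pmod(172.0 * s2, 30307.0);
    s3 = pmod(170.0 * s3, 30323.0);
    return pmod(s1 / 30269.0 + s2 / 30307.0 + s3 / 30323.0, 1.0);
  }
};

// [[Rcpp::export]]
NumericVector cpp_uniforms(int seed, int person, int stream, int n) {
  WHStream st;
  st.seed_from(seed, person, stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = st.next();
  return out;
}

// ---------------------------------------------------------------------------

struct NHConfig {
  double rate, shape, sigma, frac_indolent, rho;
  double pmeans[6];   // progressive dwell means
  double imeans[3];   // indolent preinvasive dwell means
  double pdx[3];      // clinical-diagnosis probability per preclinical stage
  double s5[3];       // 5-year survival per cancer stage
  double max_age;
};

struct Segment {
  double onset;       // NaN if no lesion
  int fate;           // 1 progressive, 2 indolent
  double entries[6], dur[6];
  double dx_age;      // NaN if never clinically diagnosed
  int dx_stage;       // 0 if none
  double pc_death;    // NaN if cured / not diagnosed
};

static void make_segment(const NHConfig &cfg, WHStream &st, double current_age,
                         Segment &seg) {
  seg.onset = NA_REAL;
  seg.fate = 0;
  seg.dx_age = NA_REAL;
  seg.dx_stage = 0;
  seg.pc_death = NA_REAL;
  double u = st.next();
  if (cfg.rate == 0.0) return;
  double lam0 = cfg.rate * std::pow(current_age / cfg.sigma, cfg.shape);
  double onset = cfg.sigma *
    std::pow((lam0 - std::log1p(-u)) / cfg.rate, 1.0 / cfg.shape);
  if (onset >= cfg.max_age) return;
  seg.onset = onset;
  seg.fate = (st.next() < cfg.frac_indolent) ? 2 : 1;
  double vs[6];
  if (cfg.rho >= 1.0) {
    double v = st.next();
    for (int j = 0; j < 6; ++j) vs[j] = v;
  } else {
    double z0 = R::qnorm(st.next(), 0.0, 1.0, 1, 0);
    for (int j = 0; j < 6; ++j) {
      double zj = R::qnorm(st.next(), 0.0, 1.0, 1, 0);
      vs[j] = R::pnorm(std::sqrt(cfg.rho) * z0 +
                       std::sqrt(1.0 - cfg.rho) * zj, 0.0, 1.0, 1, 0);
    }
  }
  double e = onset;
  for (int j = 0; j < 6; ++j) {
    double mean = (seg.fate == 1) ? cfg.pmeans[j]
                                  : (j < 3 ? cfg.imeans[j] : R_PosInf);
    double d = -mean * std::log1p(-vs[j]);
    if (std::isnan(d)) d = R_PosInf;
    seg.dur[j] = d;
    seg.entries[j] = e;
    e += d;
  }
  if (seg.fate == 1) {
    for (int j = 3; j < 6; ++j) { // preclinical stages (0-based 3..5)
      double ud = st.next();
      double p = cfg.pdx[j - 3];
      if (ud < p) {
        seg.dx_stage = j + 1;
        seg.dx_age = seg.entries[j] + (ud / p) * seg.dur[j];
        break;
      }
    }
    double us = st.next();
    if (seg.dx_stage > 0) { // guaranteed when p(dx | stage III/IV) = 1
      double q = 1.0 - cfg.s5[seg.dx_stage - 4];
      if (q > 0.0 && us < q) seg.pc_death = seg.dx_age + (us / q) * 5.0;
    }
  }
}

static int stage_at_age(const Segment &seg, double t) {
  if (!R_FINITE(seg.onset) || ISNAN(seg.onset) || t < seg.onset) return 0;
  for (int j = 0; j < 6; ++j)
    if (t >= seg.entries[j] && t < seg.entries[j] + seg.dur[j]) return j + 1;
  return 0;
}

static double lt_inverse(const NumericVector &s, double u) {
  int n = s.size();
  int k;
  if (u >= s[1]) {
    k = 0;
  } else {
    int lo = 1, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (s[mid] > u) lo = mid; else hi = mid;
    }
    k = lo;
  }
  double drop = s[k] - s[k + 1];
  double frac = (drop > 0.0) ? (s[k] - u) / drop : 1.0;
  return k + frac;
}

struct ScreenConfig {
  std::vector<double> sched;
  double surv_interval;
  double sens[6], spec;
  double resect[5], resect_none, return_prob, surg_mort;
  int fp_rounds;
};

struct Counters {
  double n = 0, py = 0;
  double cases_clinical = 0, cases_sd1 = 0, cases_sd2 = 0, cases_sd34 = 0;
  double pc_deaths = 0, surgical_deaths = 0, other_deaths = 0;
  double screen_tests = 0, surveil_tests = 0;
  double resections[6] = {0, 0, 0, 0, 0, 0}; // LGD..preclin II, lesion-free
  double interval_5y = 0, interval_total = 0;
  double ever_screened = 0;
  List as_list() const {
    return List::create(
      _["n"] = n, _["person_years"] = py,
      _["cases_clinical"] = cases_clinical,
      _["cases_sd_I"] = cases_sd1, _["cases_sd_II"] = cases_sd2,
      _["cases_sd_III_IV"] = cases_sd34,
      _["pc_deaths"] = pc_deaths, _["surgical_deaths"] = surgical_deaths,
      _["other_deaths"] = other_deaths,
      _["screen_tests"] = screen_tests,
      _["surveillance_tests"] = surveil_tests,
      _["resections"] = NumericVector::create(
        resections[0], resections[1], resections[2], resections[3],
        resections[4], resections[5]),
      _["interval_cancers_5y"] = interval_5y,
      _["interval_cancers_total"] = interval_total,
      _["ever_screened"] = ever_screened);
  }
};

// Per-person screened outcome scratch.
struct ScreenOut {
  double screens, surveils, n_resect;
  int first_resect_stage, sd_stage;
  double sd_age, clin_dx_age, pc_death, final_death, last_neg;
  int clin_dx_stage, cause; // 0 other, 1 pc, 2 surgical
  bool surg, has_neg, interval_total, interval_5y;
};

static void run_screened(const NHConfig &cfg, const ScreenConfig &sc,
                         const Segment &nhseg, double ocd, WHStream &scr,
                         ScreenOut &o, Counters &tally) {
  o.screens = 0; o.surveils = 0; o.n_resect = 0;
  o.first_resect_stage = -1; o.sd_stage = 0;
  o.sd_age = NA_REAL; o.clin_dx_age = NA_REAL; o.clin_dx_stage = 0;
  o.pc_death = NA_REAL; o.last_neg = NA_REAL;
  o.surg = false; o.has_neg = false;
  o.interval_total = false; o.interval_5y = false;
  double surg_age = NA_REAL;
  bool exited = false;

  Segment cur = nhseg;
  size_t k = 0;
  bool surveilling = false;
  double tnext = 0;
  int consec = 0;
  const size_t nsched = sc.sched.size();

  while (true) {
    double t;
    if (!surveilling) {
      if (k >= nsched) break;
      t = sc.sched[k];
    } else t = tnext;

    if (!ISNAN(cur.dx_age) && cur.dx_age <= t && cur.dx_age < ocd) {
      o.clin_dx_age = cur.dx_age;
      o.clin_dx_stage = cur.dx_stage;
      o.pc_death = cur.pc_death;
      exited = true;
      break;
    }
    if (t >= ocd) break;
    int s = stage_at_age(cur, t);
    double u = scr.next();
    bool pos = (s == 0) ? (u < 1.0 - sc.spec) : (u < sc.sens[s - 1]);
    if (!surveilling) o.screens += 1; else o.surveils += 1;
    if (!pos) {
      if (!surveilling) {
        o.last_neg = t;
        o.has_neg = true;
        ++k;
      } else {
        if (s == 0) {
          if (++consec >= sc.fp_rounds) {
            surveilling = false;
            while (k < nsched && sc.sched[k] <= t) ++k;
          } else tnext = t + sc.surv_interval;
        } else {
          consec = 0;
          tnext = t + sc.surv_interval;
        }
      }
      continue;
    }
    if (s == 6) { // screen-detected stage III/IV: palliative care
      o.sd_age = t; o.sd_stage = 6;
      double u2 = scr.next();
      o.pc_death = t + u2 * 5.0;
      exited = true;
      break;
    }
    double pr = (s == 0) ? sc.resect_none : sc.resect[s - 1];
    double pret = (s == 0) ? 0.0 : sc.return_prob;
    double um = scr.next();
    if (um < pr) {
      o.n_resect += 1;
      tally.resections[s == 0 ? 5 : s - 1] += 1;
      if (o.first_resect_stage < 0) o.first_resect_stage = s;
      double us = scr.next();
      if (us < sc.surg_mort) {
        o.surg = true;
        surg_age = t;
        if (s == 4 || s == 5) { o.sd_age = t; o.sd_stage = s; }
        exited = true;
        break;
      }
      if (s >= 1 && s <= 3) {
        make_segment(cfg, scr, t, cur); // lesion removed; back at risk
        surveilling = false;
        consec = 0;
        while (k < nsched && sc.sched[k] <= t) ++k;
      } else if (s == 4 || s == 5) {
        o.sd_age = t; o.sd_stage = s;
        double u2 = scr.next();
        double q = 1.0 - cfg.s5[s - 4];
        if (q > 0.0 && u2 < q) o.pc_death = t + (u2 / q) * 5.0;
        exited = true;
        break;
      } else { // wrongful resection of a lesion-free person
        surveilling = false;
        consec = 0;
        while (k < nsched && sc.sched[k] <= t) ++k;
      }
    } else if (um < pr + pret) {
      surveilling = false;
      consec = 0;
      while (k < nsched && sc.sched[k] <= t) ++k;
    } else {
      surveilling = true;
      consec = 0;
      tnext = t + sc.surv_interval;
    }
  }

  if (!exited && !ISNAN(cur.dx_age) && cur.dx_age < ocd) {
    o.clin_dx_age = cur.dx_age;
    o.clin_dx_stage = cur.dx_stage;
    o.pc_death = cur.pc_death;
  }
  if (!ISNAN(o.pc_death) && o.pc_death >= ocd) o.pc_death = NA_REAL;
  if (o.surg) {
    o.final_death = surg_age;
    o.cause = 2;
  } else if (!ISNAN(o.pc_death)) {
    o.final_death = o.pc_death;
    o.cause = 1;
  } else {
    o.final_death = ocd;
    o.cause = 0;
  }
  if (!ISNAN(o.clin_dx_age) && o.has_neg) {
    o.interval_total = true;
    if (o.clin_dx_age - o.last_neg <= 5.0) o.interval_5y = true;
  }
}

// [[Rcpp::export]]
List cpp_run_cohort(int n, int seed, NumericVector lt_survival,
                    List nh_config, bool screen, List screen_config,
                    bool person_out = false) {
  NHConfig cfg;
  cfg.rate = as<double>(nh_config["onset_rate"]);
  cfg.shape = as<double>(nh_config["onset_shape"]);
  cfg.sigma = as<double>(nh_config["onset_sigma"]);
  cfg.frac_indolent = as<double>(nh_config["indolent_fraction"]);
  cfg.rho = as<double>(nh_config["rho"]);
  NumericVector pm = nh_config["progressive_stage_means"];
  for (int j = 0; j < 6; ++j) cfg.pmeans[j] = pm[j];
  NumericVector im = nh_config["indolent_stage_means"];
  for (int j = 0; j < 3; ++j) cfg.imeans[j] = im[j];
  NumericVector pd = nh_config["clinical_dx_prob"];
  for (int j = 0; j < 3; ++j) cfg.pdx[j] = pd[j];
  NumericVector s5 = nh_config["five_year_survival"];
  for (int j = 0; j < 3; ++j) cfg.s5[j] = s5[j];
  cfg.max_age = lt_survival.size() - 1.0;
  if (ISNAN(cfg.rate))
    stop("pathway_config is uncalibrated (onset_rate is NA): run "
         "calibrate_onset_scale() or use a shipped preset");

  ScreenConfig sc;
  if (screen) {
    NumericVector sa = screen_config["schedule"];
    sc.sched.assign(sa.begin(), sa.end());
    sc.surv_interval = as<double>(screen_config["surveillance_interval"]);
    NumericVector se = screen_config["sensitivity"];
    for (int j = 0; j < 6; ++j) sc.sens[j] = se[j];
    sc.spec = as<double>(screen_config["specificity"]);
    NumericVector rp = screen_config["resect_prob"];
    for (int j = 0; j < 5; ++j) sc.resect[j] = rp[j];
    sc.resect_none = as<double>(screen_config["resect_prob_none"]);
    sc.return_prob = as<double>(screen_config["return_prob"]);
    sc.surg_mort = as<double>(screen_config["surgical_mortality"]);
    sc.fp_rounds = as<int>(screen_config["fp_rounds"]);
  }

  Counters un, scr_c;
  un.n = n; scr_c.n = n;
  double lyg = 0.0;

  const int ncol = 22;
  NumericMatrix pm_out(person_out ? n : 0, person_out ? ncol : 0);

  WHStream nh, scr;
  Segment seg;
  ScreenOut so;

  for (int i = 1; i <= n; ++i) {
    nh.seed_from(seed, i, 1);
    double ocd = lt_inverse(lt_survival, nh.next());
    make_segment(cfg, nh, 0.0, seg);

    // unscreened outcomes
    bool u_case = !ISNAN(seg.dx_age) && seg.dx_age < ocd;
    double u_pc = (u_case && !ISNAN(seg.pc_death) && seg.pc_death < ocd)
      ? seg.pc_death : NA_REAL;
    double u_final = ISNAN(u_pc) ? ocd : u_pc;
    un.py += u_final;
    if (u_case) un.cases_clinical += 1;
    if (!ISNAN(u_pc)) un.pc_deaths += 1; else un.other_deaths += 1;

    double s_final = u_final;
    if (screen) {
      scr.seed_from(seed, i, 2);
      run_screened(cfg, sc, seg, ocd, scr, so, scr_c);
      s_final = so.final_death;
      scr_c.py += s_final;
      scr_c.screen_tests += so.screens;
      scr_c.surveil_tests += so.surveils;
      if (so.screens > 0) scr_c.ever_screened += 1;
      if (!ISNAN(so.clin_dx_age)) scr_c.cases_clinical += 1;
      if (so.sd_stage == 4) scr_c.cases_sd1 += 1;
      else if (so.sd_stage == 5) scr_c.cases_sd2 += 1;
      else if (so.sd_stage == 6) scr_c.cases_sd34 += 1;
      if (so.cause == 1) scr_c.pc_deaths += 1;
      else if (so.cause == 2) { scr_c.pc_deaths += 1; scr_c.surgical_deaths += 1; }
      else scr_c.other_deaths += 1;
      if (so.interval_total) scr_c.interval_total += 1;
      if (so.interval_5y) scr_c.interval_5y += 1;
      lyg += s_final - u_final;
    }

    if (person_out) {
      int r = i - 1;
      pm_out(r, 0) = ocd;
      pm_out(r, 1) = seg.onset;
      pm_out(r, 2) = ISNAN(seg.onset) ? 0 : seg.fate;
      pm_out(r, 3) = u_case ? seg.dx_age : NA_REAL;
      pm_out(r, 4) = u_case ? seg.dx_stage : NA_REAL;
      pm_out(r, 5) = u_pc;
      pm_out(r, 6) = u_final;
      pm_out(r, 7) = ISNAN(u_pc) ? 0 : 1;
      if (screen) {
        pm_out(r, 8) = so.screens;
        pm_out(r, 9) = so.surveils;
        pm_out(r, 10) = so.n_resect;
        pm_out(r, 11) = so.first_resect_stage < 0 ? NA_REAL
                                                  : so.first_resect_stage;
        pm_out(r, 12) = so.sd_stage;
        pm_out(r, 13) = so.sd_age;
        pm_out(r, 14) = so.surg ? 1 : 0;
        pm_out(r, 15) = so.clin_dx_age;
        pm_out(r, 16) = ISNAN(so.clin_dx_age) ? NA_REAL
                                              : (double)so.clin_dx_stage;
        pm_out(r, 17) = so.pc_death;
        pm_out(r, 18) = so.final_death;
        pm_out(r, 19) = so.cause;
        pm_out(r, 20) = so.last_neg;
        pm_out(r, 21) = (so.interval_total ? 1 : 0) + (so.interval_5y ? 2 : 0);
      } else {
        for (int c = 8; c < ncol; ++c) pm_out(r, c) = NA_REAL;
      }
    }
  }

  List out = List::create(
    _["unscreened"] = un.as_list(),
    _["screened"] = screen ? (SEXP)scr_c.as_list() : R_NilValue,
    _["life_years_gained"] = lyg);
  if (person_out) out["persons"] = pm_out;
  return out;
}
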