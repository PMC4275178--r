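#include <Rcpp.h>
using namespace Rcpp;

// Nucleosome state codes shared with the R side:
// 0 = U (unmodified), 1 = A (acetylated), 2 = M (methylated),
// 3 = E (active), 4 = S (silenced / Sir-bound).
//
// Reaction channels, in the canonical order used for event selection (the
// pure-R enumerator in R/sim.R must keep the same site-major, channel-minor
// order so that single steps are bit-reproducible across the two routes):
//   1 loss       X -> U  (X in {A,M,E,S}), rate k_loss; S returns one Sir
//   2 acetyl     U -> A, rate k_basal
//   3 activate   A -> E, rate k_act
//   4 deacetyl   A -> U, rate fI * k_deac * Ssum(i)
//   5 methylate  U/A -> M, rate k_txn * Esum(i)
//   6 bind       U -> S, rate fI * k_bind * (free_sir / N_sir) * Ssum(i)
//   7 unbind     S -> U, rate k_unbind; returns one Sir
//
// Ssum(i): kernel-weighted count of S neighbours within range R, plus the
// permanent virtual S nucleation site at position 0 (telomere end).
// Esum(i): kernel-weighted count of E neighbours (the distal boundary site is
// held in E and contributes like any E site, but never reacts itself).

static inline double site_ssum(const IntegerVector &state, int i, int L,
                               const NumericVector &w, double nucleation) {
  // i is 0-based lattice index; virtual S lives at 1-based position 0,
  // i.e. genomic separation (i + 1) from site i.
  int R = w.size();
  double s = 0.0;
  for (int d = 1; d <= R; ++d) {
    int lo = i - d, hi = i + d;
    if (lo >= 0 && state[lo] == 4) s += w[d - 1];
    if (lo == -1) s += nucleation * w[d - 1];  // virtual nucleation S at 0
    if (hi < L && state[hi] == 4) s += w[d - 1];
  }
  return s;
}

static inline double site_esum(const IntegerVector &state, int i, int L,
                               const NumericVector &w) {
  int R = w.size();
  double s = 0.0;
  for (int d = 1; d <= R; ++d) {
    int lo = i - d, hi = i + d;
    if (lo >= 0 && state[lo] == 3) s += w[d - 1];
    if (hi < L && state[hi] == 3) s += w[d - 1];
  }
  return s;
}

struct Pars {
  double k_basal, k_act, k_deac, k_txn, k_bind, k_unbind, k_loss;
  double fI;
  double N_sir;
  NumericVector w;
  bool pin_distal;
  double nucleation;  // silencer strength relative to an interior S site
};

static Pars read_pars(const List &pars) {
  Pars p;
  p.k_basal = as<double>(pars["k_basal_acetyl"]);
  p.k_act = as<double>(pars["k_activation"]);
  p.k_deac = as<double>(pars["k_sir_deacetyl"]);
  p.k_txn = as<double>(pars["k_txn_feedback"]);
  p.k_bind = as<double>(pars["k_sir_bind"]);
  p.k_unbind = as<double>(pars["k_sir_unbind"]);
  p.k_loss = as<double>(pars["k_mark_loss"]);
  p.fI = as<double>(pars["fI"]);
  p.N_sir = as<double>(pars["N_sir_total"]);
  p.w = as<NumericVector>(pars["kernel_weights"]);
  p.pin_distal = as<bool>(pars["pin_distal"]);
  p.nucleation = as<double>(pars["nucleation"]);
  return p;
}

// Per-site total propensity; channel resolution repeats the same arithmetic.
static inline double site_total(const IntegerVector &state, int i, int L,
                                const Pars &p, int free_sir) {
  int st = state[i];
  double a = 0.0;
  if (st != 0) a += p.k_loss;                                  // loss
  if (st == 0) a += p.k_basal;                                 // acetyl
  if (st == 1) a += p.k_act;                                   // activate
  if (st == 1) a += p.fI * p.k_deac * site_ssum(state, i, L, p.w, p.nucleation);
  if (st == 0 || st == 1) a += p.k_txn * site_esum(state, i, L, p.w);
  if (st == 0)
    a += p.fI * p.k_bind * (free_sir / p.N_sir) * site_ssum(state, i, L, p.w, p.nucleation);
  if (st == 4) a += p.k_unbind;                                // unbind
  return a;
}

// Full 7 x L propensity matrix, for cross-checking against the independent
// pure-R enumerator.
// [[Rcpp::export(name = ".cpp_propensity_matrix")]]
NumericMatrix cpp_propensity_matrix(IntegerVector state, int free_sir,
                                    List pars) {
  Pars p = read_pars(pars);
  int L = state.size();
  NumericMatrix out(7, L);
  for (int i = 0; i < L; ++i) {
    if (p.pin_distal && i == L - 1) continue;  // boundary site never reacts
    int st = state[i];
    double ss = site_ssum(state, i, L, p.w, p.nucleation);
    double es = site_esum(state, i, L, p.w);
    out(0, i) = (st != 0) ? p.k_loss : 0.0;
    out(1, i) = (st == 0) ? p.k_basal : 0.0;
    out(2, i) = (st == 1) ? p.k_act : 0.0;
    out(3, i) = (st == 1) ? p.fI * p.k_deac * ss : 0.0;
    out(4, i) = (st == 0 || st == 1) ? p.k_txn * es : 0.0;
    out(5, i) =
        (st == 0) ? p.fI * p.k_bind * (free_sir / p.N_sir) * ss : 0.0;
    out(6, i) = (st == 4) ? p.k_unbind : 0.0;
  }
  return out;
}

// Apply one channel at one site; returns the Sir-pool delta.
static inline int apply_channel(IntegerVector &state, int i, int ch) {
  int st = state[i];
  switch (ch) {
    case 0:  // loss X -> U
      state[i] = 0;
      return (st == 4) ? +1 : 0;
    case 1: state[i] = 1; return 0;          // U -> A
    case 2: state[i] = 3; return 0;          // A -> E
    case 3: state[i] = 0; return 0;          // A -> U (deacetylation)
    case 4: state[i] = 2; return 0;          // U/A -> M
    case 5: state[i] = 4; return -1;         // U -> S (binds one Sir)
    case 6: state[i] = 0; return +1;         // S -> U (releases one Sir)
  }
  return 0;
}

// Gillespie simulation with fixed-cadence recording of window occupancy.
// Stops at t_end or after max_events reactions (whichever first; set
// max_events < 0 for no event cap). Uses R's RNG: two uniforms per event,
// first for the exponential waiting time, then for reaction selection.
// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(IntegerVector state0, int free_sir0, List pars,
                  double t_end, double record_dt, int win_lo, int win_hi,
                  int max_events, bool check_conservation) {
  Pars p = read_pars(pars);
  IntegerVector state = clone(state0);
  int L = state.size();
  int free_sir = free_sir0;
  int countS = 0;
  for (int i = 0; i < L; ++i)
    if (state[i] == 4) ++countS;
  const int N_total = countS + free_sir;

  int n_rec = (int)std::floor(t_end / record_dt + 1e-9) + 1;
  NumericVector rtimes(n_rec), rocc(n_rec);
  IntegerVector rnS(n_rec), rfree(n_rec);
  int rec_i = 0;
  int wlen = win_hi - win_lo + 1;

  std::vector<double> ptot(L);
  double t = 0.0;
  long long n_events = 0;
  bool conserved = true;
  bool absorbed = false;

  RNGScope scope;

  auto record_upto = [&](double tnow) {
    while (rec_i < n_rec && rec_i * record_dt <= tnow + 1e-12) {
      int nw = 0;
      for (int i = win_lo - 1; i <= win_hi - 1; ++i)
        if (state[i] == 4) ++nw;
      rtimes[rec_i] = rec_i * record_dt;
      rocc[rec_i] = (double)nw / (double)wlen;
      rnS[rec_i] = countS;
      rfree[rec_i] = free_sir;
      ++rec_i;
    }
  };

  while (t < t_end && (max_events < 0 || n_events < max_events)) {
    // total propensity (per-site totals cached for the selection scan)
    double T = 0.0;
    int last = p.pin_distal ? L - 1 : L;
    for (int i = 0; i < last; ++i) {
      ptot[i] = site_total(state, i, L, p, free_sir);
      T += ptot[i];
    }
    if (p.pin_distal) ptot[L - 1] = 0.0;
    if (T <= 0.0) { absorbed = true; break; }

    double u1 = unif_rand();
    double dt = -std::log(u1) / T;
    double tnew = t + dt;
    // flush record points passed by this waiting interval (state holds
    // unchanged until the event fires)
    record_upto(std::min(tnew, t_end));
    if (tnew >= t_end) { t = t_end; break; }
    t = tnew;

    double target = unif_rand() * T;
    int site = -1;
    double acc = 0.0;
    for (int i = 0; i < L; ++i) {
      if (acc + ptot[i] >= target) { site = i; break; }
      acc += ptot[i];
    }
    if (site < 0) site = (p.pin_distal ? L - 2 : L - 1);  // guard fp slack

    // resolve channel within the site, canonical order
    double rem = target - acc;
    int st = state[site];
    double ss = site_ssum(state, site, L, p.w, p.nucleation);
    double es = site_esum(state, site, L, p.w);
    double ch_p[7];
    ch_p[0] = (st != 0) ? p.k_loss : 0.0;
    ch_p[1] = (st == 0) ? p.k_basal : 0.0;
    ch_p[2] = (st == 1) ? p.k_act : 0.0;
    ch_p[3] = (st == 1) ? p.fI * p.k_deac * ss : 0.0;
    ch_p[4] = (st == 0 || st == 1) ? p.k_txn * es : 0.0;
    ch_p[5] = (st == 0) ? p.fI * p.k_bind * (free_sir / p.N_sir) * ss : 0.0;
    ch_p[6] = (st == 4) ? p.k_unbind : 0.0;
    int ch = 6;
    for (int c = 0; c < 7; ++c) {
      if (rem <= ch_p[c]) { ch = c; break; }
      rem -= ch_p[c];
    }

    int was_S = (state[site] == 4) ? 1 : 0;
    int dsir = apply_channel(state, site, ch);
    free_sir += dsir;
    countS += (state[site] == 4 ? 1 : 0) - was_S;
    ++n_events;

    if (check_conservation && (countS + free_sir != N_total || free_sir < 0)) {
      conserved = false;
      break;
    }
  }
  // absorbed runs are stationary forever, so the tail can be filled in;
  // event-capped runs stop the clock at t
  record_upto(absorbed ? t_end : t);

  return List::create(
      _["times"] = rtimes[Range(0, std::max(rec_i - 1, 0))],
      _["occupancy"] = rocc[Range(0, std::max(rec_i - 1, 0))],
      _["n_S"] = rnS[Range(0, std::max(rec_i - 1, 0))],
      _["free_sir_series"] = rfree[Range(0, std::max(rec_i - 1, 0))],
      _["final_state"] = state, _["final_free_sir"] = free_sir,
      _["final_time"] = t, _["n_events"] = (double)n_events,
      _["absorbed"] = absorbed, _["conserved"] = conserved,
      _["sir_total"] = N_total);
}
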