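#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven simulation (Gillespie) of the reporter reaction
// network for one cell, with a transcription rate that is piecewise
// constant on the frame grid.
//
// Species: nascent mRNA at the locus (N), cytoplasmic mRNA (M), free
// peptide awaiting an FP partner (P), free FP (F), FP:peptide complex in
// cytoplasm (Cc) and nucleus (Cn).
//
// Reactions:
//   tx(t):        -> N            (piecewise-constant rate)
//   r_rel * N:  N -> M            (release of the nascent transcript)
//   d_m * M:    M -> 0
//   k_tl * M:     -> peptide      (binds a free FP instantly if any)
//   d_p * P:    P -> 0
//   d_p * Cc:  Cc -> F            (peptide degraded, FP released)
//   d_p * Cn:  Cn -> F
//   k_imp*Cc:  Cc -> Cn
//   k_leak*Cn: Cn -> Cc
//
// SynZip binding is irreversible and instantaneous: after every event any
// coexisting free FP and free peptide pair up into cytoplasmic complex.
// The FP pool F + Cc + Cn is conserved.

static inline void bind_all(long &P, long &F, long &Cc) {
  long n = P < F ? P : F;
  if (n > 0) { P -= n; F -= n; Cc += n; }
}

// [[Rcpp::export(name = ".ssa_reporter")]]
List ssa_reporter(NumericVector times, NumericVector tx_rate,
                  double release_rate, double mrna_decay,
                  double translation_rate, double peptide_decay,
                  long fp_pool, double import_rate, double leak_rate,
                  IntegerVector init = IntegerVector::create(0, 0, 0, -1, 0, 0)) {
  int nt = times.size();
  if (tx_rate.size() != nt) stop("tx_rate and times must align");
  for (int i = 0; i < nt; ++i)
    if (!R_finite(tx_rate[i]) || tx_rate[i] < 0) stop("non-finite or negative transcription rate");
  if (!R_finite(release_rate) || !R_finite(mrna_decay) ||
      !R_finite(translation_rate) || !R_finite(import_rate) ||
      !R_finite(leak_rate)) stop("non-finite rate parameter");
  // peptide_decay may be 0 (stable mode)
  if (peptide_decay < 0) stop("negative decay rate");

  if (init.size() != 6) stop("init must have 6 entries");
  long N = init[0], M = init[1], P = init[2];
  long F = init[3] < 0 ? fp_pool : init[3];  // -1: full free pool
  long Cc = init[4], Cn = init[5];
  if (F + Cc + Cn != fp_pool) stop("initial state violates FP conservation");
  IntegerVector oN(nt), oM(nt), oP(nt), oF(nt), oCc(nt), oCn(nt);

  RNGScope scope;
  double t = times[0];
  for (int k = 0; k < nt - 1; ++k) {
    double tend = times[k + 1];
    double ktx = tx_rate[k];
    while (t < tend) {
      double a1 = ktx;
      double a2 = release_rate * N;
      double a3 = mrna_decay * M;
      double a4 = translation_rate * M;
      double a5 = peptide_decay * P;
      double a6 = peptide_decay * Cc;
      double a7 = peptide_decay * Cn;
      double a8 = import_rate * Cc;
      double a9 = leak_rate * Cn;
      double a0 = a1 + a2 + a3 + a4 + a5 + a6 + a7 + a8 + a9;
      if (a0 <= 0) { t = tend; break; }
      double tau = exp_rand() / a0;
      if (t + tau >= tend) { t = tend; break; }  // rate change at boundary
      t += tau;
      double u = unif_rand() * a0;
      if ((u -= a1) < 0)      { N += 1; }
      else if ((u -= a2) < 0) { N -= 1; M += 1; }
      else if ((u -= a3) < 0) { M -= 1; }
      else if ((u -= a4) < 0) { P += 1; bind_all(P, F, Cc); }
      else if ((u -= a5) < 0) { P -= 1; }
      else if ((u -= a6) < 0) { Cc -= 1; F += 1; bind_all(P, F, Cc); }
      else if ((u -= a7) < 0) { Cn -= 1; F += 1; bind_all(P, F, Cc); }
      else if ((u -= a8) < 0) { Cc -= 1; Cn += 1; }
      else                    { Cn -= 1; Cc += 1; }
    }
    oN[k + 1] = N; oM[k + 1] = M; oP[k + 1] = P;
    oF[k + 1] = F; oCc[k + 1] = Cc; oCn[k + 1] = Cn;
  }
  // frame 0: initial state
  oN[0] = init[0]; oM[0] = init[1]; oP[0] = init[2];
  oF[0] = init[3] < 0 ? fp_pool : init[3]; oCc[0] = init[4]; oCn[0] = init[5];
  return List::create(_["nascent_mrna"] = oN, _["mrna"] = oM,
                      _["free_peptide"] = oP, _["fp_free"] = oF,
                      _["complex_cyt"] = oCc, _["complex_nuc"] = oCn);
}
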