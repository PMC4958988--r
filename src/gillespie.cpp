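#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven simulation of a linear birth-death process.
// Per-capita birth rate b and death rate d (1/hour) are constant; the
// process is observed at the supplied sample times (hours, ascending,
// starting at 0). Uses the R RNG stream so set.seed() in R governs
// reproducibility. Returns live count N, cumulative deaths D and
// cumulative births B at each sample time. Extinction is not an error:
// the series continues with N = 0.
// [[Rcpp::export]]
NumericMatrix gillespie_bd(double b, double d, double N0,
                           NumericVector times) {
  const int nt = times.size();
  NumericMatrix out(nt, 4);
  colnames(out) = CharacterVector::create("time", "live", "dead_cum",
                                          "births_cum");
  double t = 0.0;
  double N = N0, D = 0.0, B = 0.0;
  int i = 0;
  // emit any sample times at t = 0 before the first event
  while (i < nt && times[i] <= t) {
    out(i, 0) = times[i]; out(i, 1) = N; out(i, 2) = D; out(i, 3) = B;
    ++i;
  }
  const double tend = times[nt - 1];
  while (i < nt) {
    double rate = (b + d) * N;
    double tnext = (N > 0 && rate > 0) ? t + R::rexp(1.0 / rate)
                                       : R_PosInf;
    if (tnext > tend && i < nt) {
      // no further events inside the observation window
      for (; i < nt; ++i) {
        out(i, 0) = times[i]; out(i, 1) = N; out(i, 2) = D; out(i, 3) = B;
      }
      break;
    }
    // record sample points passed before the event fires
    while (i < nt && times[i] < tnext) {
      out(i, 0) = times[i]; out(i, 1) = N; out(i, 2) = D; out(i, 3) = B;
      ++i;
    }
    if (i >= nt) break;
    t = tnext;
    if (R::unif_rand() < b / (b + d)) { N += 1.0; B += 1.0; }
    else                              { N -= 1.0; D += 1.0; }
  }
  return out;
}
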