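#include <Rcpp.h>
using namespace Rcpp;

// Pair counts for Harrell's concordance.
// A pair (i, j) is comparable iff the member with the strictly earlier
// follow-up time had the event; pairs with equal event times are not
// comparable. Tied scores on a comparable pair count 1/2.
// [[Rcpp::export(name = ".concordance_counts")]]
List concordance_counts(NumericVector time, IntegerVector event,
                        NumericVector score) {
  const R_xlen_t n = time.size();
  double concordant = 0.0, discordant = 0.0, tied = 0.0;
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j) {
      R_xlen_t a, b; // a = earlier follow-up
      if (time[i] < time[j]) { a = i; b = j; }
      else if (time[j] < time[i]) { a = j; b = i; }
      else continue;              // equal times: never comparable
      if (event[a] != 1) continue; // earlier time must be an event
      if (score[a] > score[b]) concordant += 1.0;
      else if (score[a] < score[b]) discordant += 1.0;
      else tied += 1.0;
    }
  }
  return List::create(_["concordant"] = concordant,
                      _["discordant"] = discordant,
                      _["tied_score"] = tied,
                      _["comparable"] = concordant + discordant + tied);
}

// Paired bootstrap of the concordance difference: the same resample
// indices (0-based, B x n matrix) are applied to both score vectors.
// [[Rcpp::export(name = ".concordance_boot")]]
List concordance_boot(NumericVector time, IntegerVector event,
                      NumericVector scoreA, NumericVector scoreB,
                      IntegerMatrix idx) {
  const int B = idx.nrow();
  const int n = idx.ncol();
  NumericVector cA(B), cB(B);
  std::vector<double> t(n), sA(n), sB(n);
  std::vector<int> ev(n);
  for (int b = 0; b < B; ++b) {
    for (int k = 0; k < n; ++k) {
      const int i = idx(b, k);
      t[k] = time[i]; ev[k] = event[i]; sA[k] = scoreA[i]; sB[k] = scoreB[i];
    }
    double conA = 0.0, disA = 0.0, tieA = 0.0;
    double conB = 0.0, disB = 0.0, tieB = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        int a, c;
        if (t[i] < t[j]) { a = i; c = j; }
        else if (t[j] < t[i]) { a = j; c = i; }
        else continue;
        if (ev[a] != 1) continue;
        if (sA[a] > sA[c]) conA += 1.0;
        else if (sA[a] < sA[c]) disA += 1.0;
        else tieA += 1.0;
        if (sB[a] > sB[c]) conB += 1.0;
        else if (sB[a] < sB[c]) disB += 1.0;
        else tieB += 1.0;
      }
    }
    const double nA = conA + disA + tieA, nB = conB + disB + tieB;
    cA[b] = nA > 0 ? (conA + 0.5 * tieA) / nA : NA_REAL;
    cB[b] = nB > 0 ? (conB + 0.5 * tieB) / nB : NA_REAL;
  }
  return List::create(_["cA"] = cA, _["cB"] = cB);
}
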