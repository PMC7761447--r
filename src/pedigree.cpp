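#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo (1992) ancestor-tracing
// method. sire/dam are 1-based row indices into the (topologically ordered)
// pedigree, 0 = unknown. F_i = 0.5 * a(sire_i, dam_i) where a() is built from
// the decomposition u = L m with independent Mendelian deviations m_k whose
// variances are the d_k below.
// [[Rcpp::export]]
NumericVector cpp_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> d(n); // Mendelian sampling variance coefficient
  std::vector<double> Ls(n, 0.0), Ld(n, 0.0);
  std::vector<int> touched;
  touched.reserve(256);

  for (int i = 0; i < n; ++i) {
    int s = sire[i], dd = dam[i];
    if (s > i + 1 || dd > i + 1)
      stop("pedigree not topologically ordered at row %d", i + 1);
    double di = 1.0;
    if (s > 0) di -= 0.25 * (1.0 + F[s - 1]);
    if (dd > 0) di -= 0.25 * (1.0 + F[dd - 1]);
    d[i] = di;

    if (s == 0 || dd == 0) { F[i] = 0.0; continue; }

    // back-trace L coefficients of sire and dam over their ancestor sets
    touched.clear();
    int smax = (s > dd) ? s : dd;
    Ls[s - 1] += 1.0;  touched.push_back(s - 1);
    Ld[dd - 1] += 1.0; if (dd != s) touched.push_back(dd - 1);
    double a_sd = 0.0;
    for (int j = smax - 1; j >= 0; --j) {
      double ls = Ls[j], ld = Ld[j];
      if (ls == 0.0 && ld == 0.0) continue;
      int js = sire[j], jd = dam[j];
      if (js > 0) {
        if (Ls[js - 1] == 0.0 && Ld[js - 1] == 0.0) touched.push_back(js - 1);
        Ls[js - 1] += 0.5 * ls; Ld[js - 1] += 0.5 * ld;
      }
      if (jd > 0) {
        if (Ls[jd - 1] == 0.0 && Ld[jd - 1] == 0.0) touched.push_back(jd - 1);
        Ls[jd - 1] += 0.5 * ls; Ld[jd - 1] += 0.5 * ld;
      }
      a_sd += ls * ld * d[j];
    }
    F[i] = 0.5 * a_sd;
    for (size_t t = 0; t < touched.size(); ++t) {
      Ls[touched[t]] = 0.0; Ld[touched[t]] = 0.0;
    }
  }
  return F;
}

// Dense numerator relationship matrix by the tabular method.
// [[Rcpp::export]]
NumericMatrix cpp_tabular_A(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    if (s > i + 1 || d > i + 1)
      stop("pedigree not topologically ordered at row %d", i + 1);
    double asd = (s > 0 && d > 0) ? A(s - 1, d - 1) : 0.0;
    A(i, i) = 1.0 + 0.5 * asd;
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s > 0) a += 0.5 * A(j, s - 1);
      if (d > 0) a += 0.5 * A(j, d - 1);
      A(i, j) = a; A(j, i) = a;
    }
  }
  return A;
}
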