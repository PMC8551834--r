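#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gamete formation for a batch of offspring haplotypes.
//
// hap:        loci x (2 * n_parents) raw matrix of phased alleles; columns
//             2i-1, 2i belong to stored parent i (1-based from R).
// parentCols: for each gamete, the 1-based column of the parent's FIRST
//             haplotype in `hap`.
// posCM:      per-locus genetic position within its chromosome (cM).
// chrStart/chrEnd: 1-based first/last locus row of each chromosome.
// chrLen:     chromosome lengths in cM.
//
// Crossovers follow a Poisson process along the chromosome (Haldane, no
// interference): count ~ Poisson(L/100), positions uniform on (0, L).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
RawMatrix cpp_make_gametes(RawMatrix hap, IntegerVector parentCols,
                           NumericVector posCM, IntegerVector chrStart,
                           IntegerVector chrEnd, NumericVector chrLen) {
  const int nloci = hap.nrow();
  const int G = parentCols.size();
  const int nchr = chrStart.size();
  RawMatrix out(nloci, G);
  std::vector<double> cx;
  for (int g = 0; g < G; ++g) {
    const int c0 = parentCols[g] - 1;
    for (int ch = 0; ch < nchr; ++ch) {
      const int s = chrStart[ch] - 1, e = chrEnd[ch] - 1;
      const double L = chrLen[ch];
      int h = (unif_rand() < 0.5) ? 0 : 1;
      const int ncx = (int) R::rpois(L / 100.0);
      if (ncx == 0) {
        const int col = c0 + h;
        for (int r = s; r <= e; ++r) out(r, g) = hap(r, col);
      } else {
        cx.resize(ncx);
        for (int k = 0; k < ncx; ++k) cx[k] = unif_rand() * L;
        std::sort(cx.begin(), cx.end());
        int k = 0;
        for (int r = s; r <= e; ++r) {
          const double p = posCM[r];
          while (k < ncx && cx[k] <= p) { h = 1 - h; ++k; }
          out(r, g) = hap(r, c0 + h);
        }
      }
    }
  }
  return out;
}

// Recurrent mutation applied in place to freshly created gametes.
// rows/nAlleles: 1-based locus rows eligible for mutation and their allele
// counts. Markers (redraw = false, coded 0/1) flip alleles; QTLs
// (redraw = true, coded 1..k) are redrawn uniformly among the allele set.
// The per-gamete mutation count is Poisson(rate * length(rows)).
// [[Rcpp::export]]
void cpp_mutate_gametes(RawMatrix gam, IntegerVector rows, double rate,
                        IntegerVector nAlleles, bool redraw) {
  if (rate <= 0) return;
  const int G = gam.ncol();
  const int m = rows.size();
  if (m == 0) return;
  const double lambda = rate * m;
  for (int g = 0; g < G; ++g) {
    const int nmut = (int) R::rpois(lambda);
    for (int j = 0; j < nmut; ++j) {
      int idx = (int)(unif_rand() * m); if (idx >= m) idx = m - 1;
      const int r = rows[idx] - 1;
      if (!redraw) {
        gam(r, g) = (Rbyte)(1 - (int)gam(r, g));
      } else {
        const int k = nAlleles[idx];
        int a = 1 + (int)(unif_rand() * k); if (a > k) a = k;
        gam(r, g) = (Rbyte)a;
      }
    }
  }
}

// Pedigree inbreeding coefficients by the Meuwissen & Luo recursion.
// sire/dam are 0 for unknown parents; animals must be sorted so parents
// precede offspring (validated on the R side).
// [[Rcpp::export]]
NumericVector cpp_inbreeding(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> L(n + 1, 0.0), D(n + 1, 0.0);
  std::vector<char> inlist(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    const int s = sire[i - 1], d = dam[i - 1];
    const double Fs = s ? F[s - 1] : 0.0;
    const double Fd = d ? F[d - 1] : 0.0;
    if (s == 0 && d == 0)      D[i] = 1.0;
    else if (s == 0 || d == 0) D[i] = 0.75 - 0.25 * (s ? Fs : Fd);
    else                       D[i] = 0.5 - 0.25 * (Fs + Fd);
    if (s == 0 || d == 0) { F[i - 1] = 0.0; continue; }
    double f = -1.0;
    L[i] = 1.0; inlist[i] = 1;
    for (int j = i; j >= 1; --j) {
      if (!inlist[j]) continue;
      const double lj = L[j];
      const int js = sire[j - 1], jd = dam[j - 1];
      if (js) { L[js] += 0.5 * lj; inlist[js] = 1; }
      if (jd) { L[jd] += 0.5 * lj; inlist[jd] = 1; }
      f += lj * lj * D[j];
      L[j] = 0.0; inlist[j] = 0;
    }
    F[i - 1] = f;
  }
  return F;
}

// Dosage (count of the "1" allele) for bi-allelic loci.
// cols: 1-based first-haplotype column per individual; rows: 1-based locus
// rows to extract. Returns individuals x loci integer matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_dosage(RawMatrix hap, IntegerVector cols, IntegerVector rows) {
  const int n = cols.size(), m = rows.size();
  IntegerMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const int r = rows[j] - 1;
    for (int i = 0; i < n; ++i) {
      const int c = cols[i] - 1;
      out(i, j) = (int)hap(r, c) + (int)hap(r, c + 1);
    }
  }
  return out;
}
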