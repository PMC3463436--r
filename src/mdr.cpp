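#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Accuracy of the pooled HIGH/LOW classifier for one pair, from the 9
// case counts and 9 pairwise-complete totals. Cells are labelled HIGH
// when case:control >= T (exact integer cross-multiplication, so the tie
// rule is unambiguous); empty cells are LOW. Returns 0 and sets
// *degenerate when one class is absent after pairwise deletion.
static inline double pair_acc(const int *cs, const int *tot, int ncase,
                              int nctrl, bool balanced, bool tie_high,
                              bool *degenerate) {
  if (ncase == 0 || nctrl == 0) {
    *degenerate = true;
    return 0.0;
  }
  int hit_case = 0, hit_ctrl = 0;
  for (int c = 0; c < 9; ++c) {
    const int ca = cs[c];
    const int co = tot[c] - ca;
    bool high;
    if (ca == 0 && co == 0) {
      high = false;
    } else {
      // HIGH iff ca/co >= ncase/nctrl, cross-multiplied
      const long long lhs = (long long)ca * (long long)nctrl;
      const long long rhs = (long long)co * (long long)ncase;
      high = tie_high ? (lhs >= rhs) : (lhs > rhs);
    }
    if (high)
      hit_case += ca;
    else
      hit_ctrl += co;
  }
  if (balanced)
    return 0.5 * ((double)hit_case / ncase + (double)hit_ctrl / nctrl);
  return (double)(hit_case + hit_ctrl) / (double)(ncase + nctrl);
}

// Exhaustive scan over all C(n_snps, 2) unordered pairs. geno is
// individuals x SNPs with codes 0/1/2 and NA for missing; pheno is 0/1.
// Pair (i, j), i < j, occupies slot i*(2n-i-1)/2 + (j-i-1) in `accuracy`.
// [[Rcpp::export]]
List scan_pairs_cpp(IntegerMatrix geno, IntegerVector pheno, bool balanced,
                    bool tie_high) {
  const int n_ind = geno.nrow();
  const int n_snp = geno.ncol();
  if (n_snp < 2)
    stop("at least 2 SNPs required");
  const R_xlen_t n_pair = (R_xlen_t)n_snp * (n_snp - 1) / 2;

  NumericVector acc(n_pair);
  LogicalVector degen(n_pair);
  NumericVector best(n_snp, 0.0);
  LogicalVector has_valid(n_snp);

  std::vector<int> ph(n_ind);
  for (int r = 0; r < n_ind; ++r)
    ph[r] = pheno[r];

  R_xlen_t p = 0;
  double maxacc = 0.0;
  for (int i = 0; i < n_snp; ++i) {
    const int *gi = &geno[(R_xlen_t)i * n_ind];
    for (int j = i + 1; j < n_snp; ++j, ++p) {
      const int *gj = &geno[(R_xlen_t)j * n_ind];
      int cs[9] = {0}, tot[9] = {0};
      int ncase = 0, nctrl = 0;
      for (int r = 0; r < n_ind; ++r) {
        const int a = gi[r], b = gj[r];
        if (a == NA_INTEGER || b == NA_INTEGER)
          continue;
        const int cell = 3 * a + b;
        ++tot[cell];
        if (ph[r] == 1) {
          ++cs[cell];
          ++ncase;
        } else {
          ++nctrl;
        }
      }
      bool dg = false;
      const double a_ij =
          pair_acc(cs, tot, ncase, nctrl, balanced, tie_high, &dg);
      acc[p] = a_ij;
      degen[p] = dg;
      if (!dg) {
        if (a_ij > maxacc)
          maxacc = a_ij;
        if (a_ij > best[i] || !has_valid[i]) {
          best[i] = a_ij;
          has_valid[i] = true;
        }
        if (a_ij > best[j] || !has_valid[j]) {
          best[j] = a_ij;
          has_valid[j] = true;
        }
      }
    }
  }
  return List::create(_["accuracy"] = acc, _["degenerate"] = degen,
                      _["best_per_snp"] = best,
                      _["has_valid_pair"] = has_valid,
                      _["max_accuracy"] = maxacc);
}

// Maximum scan accuracy under each permuted label vector. perms is
// individuals x N with entries 0/1; column k holds permutation k.
// Pairwise-complete totals are computed once per pair, then only case
// cells are tallied per permutation (controls follow by subtraction).
// [[Rcpp::export]]
NumericVector null_maxima_cpp(IntegerMatrix geno, IntegerMatrix perms,
                              bool balanced, bool tie_high) {
  const int n_ind = geno.nrow();
  const int n_snp = geno.ncol();
  const int n_perm = perms.ncol();
  if (perms.nrow() != n_ind)
    stop("permutation matrix row count must equal individual count");

  // case index list per permutation
  std::vector<std::vector<int>> cases(n_perm);
  for (int k = 0; k < n_perm; ++k) {
    cases[k].reserve(n_ind / 2 + 1);
    for (int r = 0; r < n_ind; ++r)
      if (perms(r, k) == 1)
        cases[k].push_back(r);
  }

  NumericVector maxima(n_perm, 0.0);
  std::vector<int8_t> cell(n_ind);

  for (int i = 0; i < n_snp; ++i) {
    const int *gi = &geno[(R_xlen_t)i * n_ind];
    for (int j = i + 1; j < n_snp; ++j) {
      const int *gj = &geno[(R_xlen_t)j * n_ind];
      int tot[9] = {0};
      int n_obs = 0;
      for (int r = 0; r < n_ind; ++r) {
        const int a = gi[r], b = gj[r];
        if (a == NA_INTEGER || b == NA_INTEGER) {
          cell[r] = -1;
        } else {
          const int8_t c = (int8_t)(3 * a + b);
          cell[r] = c;
          ++tot[c];
          ++n_obs;
        }
      }
      for (int k = 0; k < n_perm; ++k) {
        int cs[9] = {0};
        const std::vector<int> &ck = cases[k];
        const int nk = (int)ck.size();
        for (int t = 0; t < nk; ++t) {
          const int8_t c = cell[ck[t]];
          if (c >= 0)
            ++cs[c];
        }
        const int ncase = cs[0] + cs[1] + cs[2] + cs[3] + cs[4] + cs[5] +
                          cs[6] + cs[7] + cs[8];
        const int nctrl = n_obs - ncase;
        bool dg = false;
        const double a_ij =
            pair_acc(cs, tot, ncase, nctrl, balanced, tie_high, &dg);
        if (!dg && a_ij > maxima[k])
          maxima[k] = a_ij;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return maxima;
}
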