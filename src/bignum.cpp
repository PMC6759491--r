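// Arbitrary-precision non-negative integer kernels.
//
// A big integer is an R numeric vector of "limbs" in little-endian order,
// each limb an integral double in [0, 1e9).  Doubles are used as the
// storage type so plain R vectors can hold the limbs; all arithmetic is
// done in uint64_t, which cannot overflow for the operations below:
//   addmul:  m * limb + limb + carry  <=  2^31 * 1e9 + 2e9  < 2^62
//   mul:     limb * limb + limb + carry  <  1e18 + 2e9      < 2^63
#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

static const uint64_t BASE = 1000000000ULL;

static std::vector<uint64_t> as_limbs(const NumericVector& x) {
  std::vector<uint64_t> v(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) v[i] = (uint64_t) x[i];
  return v;
}

static NumericVector from_limbs(std::vector<uint64_t>& v) {
  while (v.size() > 1 && v.back() == 0) v.pop_back();
  NumericVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = (double) v[i];
  return out;
}

// m*a + b, with 0 <= m < 2^31
NumericVector bn_addmul(NumericVector a, NumericVector b, double m) {
  if (m < 0 || m >= 2147483648.0 || m != std::floor(m))
    stop("multiplier must be an integer in [0, 2^31)");
  std::vector<uint64_t> av = as_limbs(a), bv = as_limbs(b);
  uint64_t mm = (uint64_t) m;
  size_t n = std::max(av.size(), bv.size()) + 1;
  std::vector<uint64_t> r(n, 0);
  uint64_t carry = 0;
  for (size_t i = 0; i < n; ++i) {
    uint64_t cur = carry;
    if (i < av.size()) cur += mm * av[i];
    if (i < bv.size()) cur += bv[i];
    r[i] = cur % BASE;
    carry = cur / BASE;
  }
  if (carry) r.push_back(carry);
  return from_limbs(r);
}

// a * b (schoolbook)
NumericVector bn_mul(NumericVector a, NumericVector b) {
  std::vector<uint64_t> av = as_limbs(a), bv = as_limbs(b);
  if ((av.size() == 1 && av[0] == 0) || (bv.size() == 1 && bv[0] == 0)) {
    NumericVector zero(1); return zero;
  }
  std::vector<uint64_t> r(av.size() + bv.size(), 0);
  for (size_t i = 0; i < av.size(); ++i) {
    uint64_t carry = 0;
    for (size_t j = 0; j < bv.size(); ++j) {
      uint64_t cur = r[i + j] + av[i] * bv[j] + carry;
      r[i + j] = cur % BASE;
      carry = cur / BASE;
    }
    size_t k = i + bv.size();
    while (carry) { uint64_t cur = r[k] + carry; r[k] = cur % BASE; carry = cur / BASE; ++k; }
  }
  return from_limbs(r);
}

// sign(a - b): -1, 0, or 1
int bn_cmp(NumericVector a, NumericVector b) {
  std::vector<uint64_t> av = as_limbs(a), bv = as_limbs(b);
  while (av.size() > 1 && av.back() == 0) av.pop_back();
  while (bv.size() > 1 && bv.back() == 0) bv.pop_back();
  if (av.size() != bv.size()) return av.size() < bv.size() ? -1 : 1;
  for (size_t i = av.size(); i-- > 0; ) {
    if (av[i] != bv[i]) return av[i] < bv[i] ? -1 : 1;
  }
  return 0;
}

// --- .Call interface and registration (hand-maintained) ---

RcppExport SEXP _dhcross_bn_addmul(SEXP aSEXP, SEXP bSEXP, SEXP mSEXP) {
BEGIN_RCPP
  return Rcpp::wrap(bn_addmul(Rcpp::as<NumericVector>(aSEXP),
                              Rcpp::as<NumericVector>(bSEXP),
                              Rcpp::as<double>(mSEXP)));
END_RCPP
}

RcppExport SEXP _dhcross_bn_mul(SEXP aSEXP, SEXP bSEXP) {
BEGIN_RCPP
  return Rcpp::wrap(bn_mul(Rcpp::as<NumericVector>(aSEXP),
                           Rcpp::as<NumericVector>(bSEXP)));
END_RCPP
}

RcppExport SEXP _dhcross_bn_cmp(SEXP aSEXP, SEXP bSEXP) {
BEGIN_RCPP
  return Rcpp::wrap(bn_cmp(Rcpp::as<NumericVector>(aSEXP),
                           Rcpp::as<NumericVector>(bSEXP)));
END_RCPP
}

static const R_CallMethodDef CallEntries[] = {
  {"_dhcross_bn_addmul", (DL_FUNC) &_dhcross_bn_addmul, 3},
  {"_dhcross_bn_mul",    (DL_FUNC) &_dhcross_bn_mul,    2},
  {"_dhcross_bn_cmp",    (DL_FUNC) &_dhcross_bn_cmp,    2},
  {NULL, NULL, 0}
};

RcppExport void R_init_dhcross(DllInfo *dll) {
  R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
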