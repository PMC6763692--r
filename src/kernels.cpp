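#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Gaussian elimination on a tree-structured symmetric matrix.
// parent is 1-based with 0 marking a root; parent[i] < i+1 is required
// (parent-before-child ordering), so a single reverse sweep triangularizes.
// Operation count tallies multiplications and divisions only; it depends on
// the number of nodes and roots, never on the branching pattern.
// [[Rcpp::export]]
List hines_solve_cpp(NumericVector d_, NumericVector b_, NumericVector rhs_,
                     IntegerVector parent) {
  int n = d_.size();
  if (b_.size() != n || rhs_.size() != n || parent.size() != n)
    stop("hines_solve: array lengths differ");
  NumericVector d = clone(d_), rhs = clone(rhs_);
  NumericVector b = b_;  // read-only
  double ops = 0.0;
  for (int i = n - 1; i >= 1; --i) {
    int p = parent[i] - 1;  // to 0-based; -1 == root
    if (p < 0) continue;
    if (p >= i) stop("hines_solve: parent[%d] >= %d (ordering violated)", i + 1, i + 1);
    if (d[i] == 0.0) stop("hines_solve: zero pivot at node %d", i + 1);
    double f = b[i] / d[i];             ops += 1;
    d[p]   -= f * b[i];                 ops += 1;
    rhs[p] -= f * rhs[i];               ops += 1;
  }
  NumericVector v(n);
  for (int i = 0; i < n; ++i) {
    int p = parent[i] - 1;
    if (d[i] == 0.0) stop("hines_solve: zero pivot at node %d", i + 1);
    if (p < 0) {
      v[i] = rhs[i] / d[i];             ops += 1;
    } else {
      v[i] = (rhs[i] - b[i] * v[p]) / d[i];  ops += 2;
    }
  }
  return List::create(_["v"] = v, _["ops"] = ops);
}

// x[idx] += vals with duplicate indices accumulated in order of appearance
// (R's subassignment drops duplicate contributions). idx is 1-based.
// [[Rcpp::export]]
NumericVector accum_add_cpp(int n, IntegerVector idx, NumericVector vals) {
  if (idx.size() != vals.size()) stop("accum_add: length mismatch");
  NumericVector out(n);
  for (int k = 0; k < idx.size(); ++k) {
    int i = idx[k] - 1;
    if (i < 0 || i >= n) stop("accum_add: index %d out of range", idx[k]);
    out[i] += vals[k];
  }
  return out;
}

static inline uint64_t rotl64(uint64_t x, int r) {
  return (x << r) | (x >> (64 - r));
}

// Counter-based uniform generator: Threefry-2x64-20, i.e. five 4-round
// add-xor-rotate blocks (rotation schedule 16,42,12,31,16,32,24,21) with a
// key injection after every block. The key is supplied as four 32-bit
// integers packed into two 64-bit words. Pure: the value depends only on
// (key, counter). Output maps the high 53 bits of the first output word
// onto [0, 1).
static double threefry_u01(uint64_t k0, uint64_t k1, uint64_t c) {
  const uint64_t parity = 0x1BD11BDAA9FC1A22ULL;  // Threefry key-schedule constant
  uint64_t ks[3] = { k0, k1, k0 ^ k1 ^ parity };
  static const int R[8] = {16, 42, 12, 31, 16, 32, 24, 21};
  uint64_t x0 = c, x1 = 0xB5AD4ECEDA1CE2A9ULL;    // fixed second counter word
  x0 += ks[0]; x1 += ks[1];
  for (int s = 1; s <= 5; ++s) {
    for (int r = 0; r < 4; ++r) {
      x0 += x1; x1 = rotl64(x1, R[((s - 1) * 4 + r) % 8]); x1 ^= x0;
    }
    x0 += ks[s % 3]; x1 += ks[(s + 1) % 3] + (uint64_t)s;
  }
  return (double)(x0 >> 11) * (1.0 / 9007199254740992.0); /* 2^-53 */
}

// key: 4 integers; counter: non-negative whole numbers (double, < 2^53).
// [[Rcpp::export]]
NumericVector counter_rng_cpp(IntegerVector key, NumericVector counter) {
  if (key.size() != 4) stop("counter_rng: key must have 4 integers");
  uint64_t k0 = ((uint64_t)(uint32_t)key[0] << 32) | (uint32_t)key[1];
  uint64_t k1 = ((uint64_t)(uint32_t)key[2] << 32) | (uint32_t)key[3];
  int n = counter.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double c = counter[i];
    if (!(c >= 0) || c != std::floor(c))
      stop("counter_rng: counters must be non-negative whole numbers");
    out[i] = threefry_u01(k0, k1, (uint64_t)c);
  }
  return out;
}

// FNV-1a 64-bit hash of a raw vector, hex string. Used for archive digests.
// [[Rcpp::export]]
std::string fnv1a64_cpp(RawVector bytes) {
  uint64_t h = 0xCBF29CE484222325ULL;
  for (int i = 0; i < bytes.size(); ++i) {
    h ^= (uint64_t)bytes[i];
    h *= 0x100000001B3ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
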