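#include <Rcpp.h>
using namespace Rcpp;

// The transition kernel over an inter-marker distance d is
//   a(k,l) = s_k [k==l] + (1 - s_k) m_l,   s_k = exp(-R_k d):
// the current segment survives the interval with exponential survival s_k;
// on termination the next class is drawn from the mixing proportions m
// (self re-entry allowed).  Both the forward and backward recursions then
// collapse to O(K) per marker instead of O(K^2).
//
// All marker-indexed matrices are passed K x N (classes down the rows) so
// that each marker's K values are contiguous in memory.

// Forward-backward with per-marker scaling.  'emis' and 'surv' are K x N:
// emission probabilities and interval survivals exp(-R_k d(t-1, t))
// (column content ignored where chrom_start[t] is TRUE); 'mixing' the
// stationary segment-class frequencies; 'chrom_start' TRUE at the first
// marker of each chromosome (the chain restarts from 'mixing' there).
//
// Returns the total log-likelihood, the Baum-Welch accumulators for the
// M-step (expected chain starts per class at chromosome starts, expected
// segment entries per class over internal intervals) and, on request,
// posterior probabilities (K x N) and the per-interval expected
// survival / termination probabilities per class used to re-estimate
// rates (K x N, column t = interval (t-1, t)).
// [[Rcpp::export]]
List fb_hmm(const NumericMatrix& emis, const NumericMatrix& surv,
            const NumericVector& mixing, const LogicalVector& chrom_start,
            bool want_gamma, bool want_rate_stats) {
  const int K = emis.nrow(), N = emis.ncol();
  if (surv.nrow() != K || surv.ncol() != N || mixing.size() != K ||
      chrom_start.size() != N)
    stop("inconsistent HMM input dimensions");
  const double* E = REAL(emis);
  const double* S = REAL(surv);
  const double* M = REAL(mixing);

  NumericMatrix alpha_m(K, N);
  double* A = REAL(alpha_m);
  std::vector<double> scale(N);
  double loglik = 0.0;

  // forward
  for (int t = 0; t < N; ++t) {
    const double* e = E + (R_xlen_t)t * K;
    const double* s = S + (R_xlen_t)t * K;
    double* a = A + (R_xlen_t)t * K;
    double c = 0.0;
    if (chrom_start[t]) {
      for (int k = 0; k < K; ++k) { a[k] = M[k] * e[k]; c += a[k]; }
    } else {
      const double* ap = a - K;
      double U = 0.0;  // mass terminating during the interval
      for (int k = 0; k < K; ++k) U += ap[k] * (1.0 - s[k]);
      for (int k = 0; k < K; ++k) {
        a[k] = e[k] * (s[k] * ap[k] + M[k] * U);
        c += a[k];
      }
    }
    if (!(c > 0.0) || !R_finite(c))
      stop("zero or non-finite forward probability at marker %d "
           "(all emission probabilities vanished?)", t + 1);
    double inv = 1.0 / c;
    for (int k = 0; k < K; ++k) a[k] *= inv;
    scale[t] = c;
    loglik += std::log(c);
  }

  // backward (scaled by the forward constants), posteriors, E-step sums
  NumericVector entry_sum(K), start_gamma_sum(K);
  NumericMatrix gamma_m, survive_m, term_m;
  double *G = 0, *SV = 0, *TM = 0;
  if (want_gamma) { gamma_m = NumericMatrix(K, N); G = REAL(gamma_m); }
  if (want_rate_stats) {
    survive_m = NumericMatrix(K, N); SV = REAL(survive_m);
    term_m = NumericMatrix(K, N); TM = REAL(term_m);
  }
  std::vector<double> beta(K, 1.0), beta_next(K), gcur(K);
  for (int t = N - 1; t >= 0; --t) {
    const double* a = A + (R_xlen_t)t * K;
    bool last_of_chrom = (t == N - 1) || chrom_start[t + 1];
    if (last_of_chrom) {
      std::fill(beta.begin(), beta.end(), 1.0);
    } else {
      const double* e1 = E + (R_xlen_t)(t + 1) * K;
      const double* s1 = S + (R_xlen_t)(t + 1) * K;
      double V = 0.0;
      for (int l = 0; l < K; ++l) V += M[l] * e1[l] * beta[l];
      double inv = 1.0 / scale[t + 1];
      double Z = 0.0, U = 0.0;
      for (int k = 0; k < K; ++k) {
        beta_next[k] = (s1[k] * e1[k] * beta[k] +
                        (1.0 - s1[k]) * V) * inv;
        U += a[k] * (1.0 - s1[k]);
        Z += a[k] * s1[k] * e1[k] * beta[k];
      }
      Z += U * V;
      if (Z > 0.0) {
        double invZ = 1.0 / Z;
        for (int k = 0; k < K; ++k) {
          double en = U * M[k] * e1[k] * beta[k] * invZ;
          entry_sum[k] += en;
          if (want_rate_stats) {
            SV[(R_xlen_t)(t + 1) * K + k] =
              a[k] * s1[k] * e1[k] * beta[k] * invZ;
            TM[(R_xlen_t)(t + 1) * K + k] =
              a[k] * (1.0 - s1[k]) * V * invZ;
          }
        }
      }
      beta.swap(beta_next);
    }
    bool need_gamma = want_gamma || chrom_start[t];
    if (need_gamma) {
      double g = 0.0;
      for (int k = 0; k < K; ++k) { gcur[k] = a[k] * beta[k]; g += gcur[k]; }
      double invg = 1.0 / g;
      for (int k = 0; k < K; ++k) gcur[k] *= invg;
      if (want_gamma)
        for (int k = 0; k < K; ++k) G[(R_xlen_t)t * K + k] = gcur[k];
      if (chrom_start[t])
        for (int k = 0; k < K; ++k) start_gamma_sum[k] += gcur[k];
    }
  }

  List out = List::create(_["loglik"] = loglik,
                          _["entry_sum"] = entry_sum,
                          _["start_gamma_sum"] = start_gamma_sum);
  if (want_gamma) out["gamma"] = gamma_m;
  if (want_rate_stats) {
    out["survive_w"] = survive_m;
    out["term_w"] = term_m;
  }
  return out;
}

// Viterbi decoding in log space for a single chromosome (chrom_start[0]
// must be the only start).  Ties are broken toward the lowest state index.
// [[Rcpp::export]]
IntegerVector viterbi_hmm(const NumericMatrix& emis, const NumericMatrix& surv,
                          const NumericVector& mixing,
                          const LogicalVector& chrom_start) {
  const int K = emis.nrow(), N = emis.ncol();
  for (int t = 1; t < N; ++t)
    if (chrom_start[t]) stop("viterbi_hmm decodes one chromosome at a time");
  const double* E = REAL(emis);
  const double* S = REAL(surv);
  const double* M = REAL(mixing);
  std::vector<double> delta(K), delta_new(K), w(K);
  IntegerMatrix back(K, N);
  int* B = INTEGER(back);
  IntegerVector path(N);
  const double NEG_INF = -std::numeric_limits<double>::infinity();

  for (int k = 0; k < K; ++k) {
    delta[k] = std::log(M[k]) + std::log(E[k]);
    B[k] = -1;
  }
  for (int t = 1; t < N; ++t) {
    const double* e = E + (R_xlen_t)t * K;
    const double* s = S + (R_xlen_t)t * K;
    int* b = B + (R_xlen_t)t * K;
    // w_k = delta_k + log(1 - s_k): mass handed over on termination;
    // keep the two largest so each target can exclude itself.
    double w1 = NEG_INF, w2 = NEG_INF;
    int a1 = -1, a2 = -1;
    for (int k = 0; k < K; ++k) {
      w[k] = delta[k] + std::log1p(-s[k]);
      if (w[k] > w1) { w2 = w1; a2 = a1; w1 = w[k]; a1 = k; }
      else if (w[k] > w2) { w2 = w[k]; a2 = k; }
    }
    for (int l = 0; l < K; ++l) {
      double stay = delta[l] + std::log(s[l] + (1.0 - s[l]) * M[l]);
      double wo = (a1 == l) ? w2 : w1;
      int ko = (a1 == l) ? a2 : a1;
      double sw = wo + std::log(M[l]);
      if (sw > stay || (sw == stay && ko >= 0 && ko < l)) {
        delta_new[l] = sw + std::log(e[l]);
        b[l] = ko;
      } else {
        delta_new[l] = stay + std::log(e[l]);
        b[l] = l;
      }
    }
    delta.swap(delta_new);
  }

  int best = 0;
  double bv = NEG_INF;
  for (int k = 0; k < K; ++k)
    if (delta[k] > bv) { bv = delta[k]; best = k; }
  for (int t = N - 1; t >= 0; --t) {
    path[t] = best + 1;
    int b = B[(R_xlen_t)t * K + best];
    if (b >= 0) best = b;
  }
  return path;
}
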