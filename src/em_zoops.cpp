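#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ZOOPS expectation-maximization for a symmetric motif geometry.
//
// Sequences are integer-encoded on 0..3 (A,C,G,T) with 4 = N; `seqs_f` holds
// the regions on their coding strand and `seqs_r` their reverse complements,
// so the minus strand is scanned with the same code path as the plus strand.
// `offsets` are the 0-based offsets of the modeled columns within the motif
// span (spacer/linker columns are absent: they score as background).  The
// symmetry constraint is expressed as a column pairing: after computing
// expected counts, column j is pooled with column partner[j], complementing
// bases when comp[j] is true.  Pooling the expected counts is the exact
// constrained M-step for tied columns, so the EM monotonicity guarantee is
// preserved.  The per-iteration log-likelihood (including the constant
// background term) is recorded before each M-step.
//
// [[Rcpp::export]]
List em_zoops_cpp(List seqs_f, List seqs_r, IntegerVector offsets,
                  IntegerVector partner, LogicalVector comp,
                  NumericMatrix pwm0, NumericVector bg,
                  double gamma0, double tol, int max_iter) {
  const int R = seqs_f.size();
  const int m = offsets.size();
  int span = 0;
  for (int j = 0; j < m; ++j) span = std::max(span, offsets[j] + 1);

  std::vector<std::vector<int> > F(R), V(R);
  for (int r = 0; r < R; ++r) {
    F[r] = as<std::vector<int> >(seqs_f[r]);
    V[r] = as<std::vector<int> >(seqs_r[r]);
    if ((int)F[r].size() < span) stop("region shorter than motif span");
  }

  NumericMatrix pwm = clone(pwm0);
  // project the start onto the symmetry manifold: monotonicity of the
  // constrained EM holds only for in-family states
  for (int j = 0; j < m; ++j) {
    const int pj = partner[j];
    if (pj < j) continue;
    double tot = 0.0;
    for (int b = 0; b < 4; ++b) {
      double other = comp[j] ? pwm0(3 - b, pj) : pwm0(b, pj);
      pwm(b, j) = pwm0(b, j) + other;
      tot += pwm(b, j);
    }
    for (int b = 0; b < 4; ++b) {
      pwm(b, j) = tot > 0.0 ? pwm(b, j) / tot : bg[b];
      if (pj > j) pwm(comp[j] ? 3 - b : b, pj) = pwm(b, j);
    }
  }
  double gamma = gamma0;
  NumericVector Q(R), best_z(R);
  IntegerVector best_pos(R), best_strand(R);

  // constant background log-likelihood over every base of every region
  double const_ll = 0.0;
  double lbg[5];
  for (int b = 0; b < 4; ++b) lbg[b] = std::log(bg[b]);
  lbg[4] = 0.0;  // N contributes a unit factor
  for (int r = 0; r < R; ++r)
    for (size_t i = 0; i < F[r].size(); ++i) const_ll += lbg[F[r][i]];

  std::vector<double> ll_trace;
  std::vector<double> lw(5 * m), cnt(4 * m), pooled(4 * m);
  double prev_ll = 0.0;
  bool converged = false;
  int iter;
  for (iter = 0; iter < max_iter; ++iter) {
    for (int j = 0; j < m; ++j) {
      for (int b = 0; b < 4; ++b) {
        double p = pwm(b, j);
        lw[b * m + j] = std::log(p > 1e-300 ? p : 1e-300) - std::log(bg[b]);
      }
      lw[4 * m + j] = 0.0;
    }
    std::fill(cnt.begin(), cnt.end(), 0.0);
    double ll = const_ll, Qsum = 0.0;

    for (int r = 0; r < R; ++r) {
      const std::vector<int>& f = F[r];
      const std::vector<int>& v = V[r];
      const int npos = (int)f.size() - span + 1;
      std::vector<double> sc(2 * npos);
      for (int p = 0; p < npos; ++p) {
        double s1 = 0.0, s2 = 0.0;
        for (int j = 0; j < m; ++j) {
          s1 += lw[f[p + offsets[j]] * m + j];
          s2 += lw[v[p + offsets[j]] * m + j];
        }
        sc[p] = s1;
        sc[npos + p] = s2;
      }
      double sum_lr = 0.0;
      for (int k = 0; k < 2 * npos; ++k) sum_lr += std::exp(sc[k]);
      const double prior = gamma / (2.0 * npos);
      const double Lr = (1.0 - gamma) + prior * sum_lr;
      ll += std::log(Lr);

      double q_r = 0.0, bz = -1.0;
      int bp = 0, bs = 0;
      for (int k = 0; k < 2 * npos; ++k) {
        const double z = prior * std::exp(sc[k]) / Lr;
        if (z <= 0.0) continue;
        q_r += z;
        const int strand = k / npos, p = k % npos;
        if (z > bz) { bz = z; bp = p; bs = strand; }
        const std::vector<int>& s = strand ? v : f;
        for (int j = 0; j < m; ++j) {
          const int b = s[p + offsets[j]];
          if (b < 4) cnt[b * m + j] += z;
        }
      }
      Q[r] = q_r;
      Qsum += q_r;
      best_z[r] = bz;
      best_pos[r] = bp;
      best_strand[r] = bs;
    }
    ll_trace.push_back(ll);

    // M-step with symmetry pooling
    for (int j = 0; j < m; ++j) {
      const int pj = partner[j];
      const bool cj = comp[j];
      for (int b = 0; b < 4; ++b) {
        const double other = cj ? cnt[(3 - b) * m + pj] : cnt[b * m + pj];
        pooled[b * m + j] = cnt[b * m + j] + other;
      }
    }
    for (int j = 0; j < m; ++j) {
      double tot = 0.0;
      for (int b = 0; b < 4; ++b) tot += pooled[b * m + j];
      for (int b = 0; b < 4; ++b)
        pwm(b, j) = tot > 0.0 ? pooled[b * m + j] / tot : bg[b];
    }
    // make the tie exact to the bit: partner columns get copies, not
    // separately rounded normalizations
    for (int j = 0; j < m; ++j) {
      const int pj = partner[j];
      if (pj > j) {
        for (int b = 0; b < 4; ++b)
          pwm(b, pj) = comp[j] ? pwm(3 - b, j) : pwm(b, j);
      }
    }
    gamma = Qsum / R;
    if (gamma < 1e-12) gamma = 1e-12;
    if (gamma > 1.0 - 1e-12) gamma = 1.0 - 1e-12;

    if (iter > 0 && std::fabs(ll - prev_ll) < tol * (std::fabs(ll) + 1.0)) {
      prev_ll = ll;
      converged = true;
      break;
    }
    prev_ll = ll;
  }

  return List::create(
    _["pwm"] = pwm, _["gamma"] = gamma,
    _["loglik"] = ll_trace.empty() ? NA_REAL : ll_trace.back(),
    _["loglik_trace"] = NumericVector(ll_trace.begin(), ll_trace.end()),
    _["Q"] = Q, _["best_pos"] = best_pos, _["best_strand"] = best_strand,
    _["best_z"] = best_z, _["n_iter"] = (int)ll_trace.size(),
    _["converged"] = converged, _["span"] = span);
}

// Sum of per-column log-odds over every start position of one strand.
// `weights5` is a 5 x m matrix (row 5 scores N as background, i.e. 0).
// [[Rcpp::export]]
NumericVector score_positions_cpp(IntegerVector seq, NumericMatrix weights5,
                                  IntegerVector offsets) {
  const int m = offsets.size();
  int span = 0;
  for (int j = 0; j < m; ++j) span = std::max(span, offsets[j] + 1);
  const int npos = seq.size() - span + 1;
  if (npos <= 0) return NumericVector(0);
  NumericVector out(npos);
  for (int p = 0; p < npos; ++p) {
    double s = 0.0;
    for (int j = 0; j < m; ++j) s += weights5(seq[p + offsets[j]], j);
    out[p] = s;
  }
  return out;
}
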