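#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Diploid haplotype-copying HMM (Li-Stephens style) posterior at one masked
// site, computed by exact forward-backward over ordered pairs of reference
// haplotypes. The two copied haplotypes switch independently: over an
// inter-variant gap of d bp a haplotype stays on its template with
// probability exp(-rho*d) + (1-exp(-rho*d))/H and moves to any given other
// template with probability (1-exp(-rho*d))/H. Emission at a typed site with
// unphased genotype g sums over the two phase assignments, each true allele
// equal to its template allele with probability 1-eps. A missing observation
// emits probability 1.
//
// The "stay or jump to uniform" transition makes the pair update O(H^2) per
// site via row/column sums; per-site rescaling keeps the recursion in the
// normalised regime so panels of hundreds of haplotypes over hundreds of
// sites do not underflow. Only the masked-site posterior is needed, so the
// forward pass stops there and the backward pass runs down to it — nothing
// is stored per site.

namespace {

// The pair-state matrices are symmetric throughout (uniform start,
// per-haplotype-exchangeable transitions, phase-symmetric emissions), so
// every kernel below touches only the lower triangle (i >= j, column-major)
// and weights off-diagonal entries twice in reductions.
struct Workspace {
  int H;
  std::vector<double> M, G, rs, q0;  // state mats, row sums, emission probs

  explicit Workspace(int H_) : H(H_), M(H_ * H_), G(H_ * H_),
                               rs(H_), q0(H_) {}

  void emission_probs(const int *panel_col, double eps) {
    for (int i = 0; i < H; ++i)
      q0[i] = panel_col[i] == 0 ? 1.0 - eps : eps;
  }

  // multiply state matrix by P(g | template pair) using current q0
  void apply_emission(std::vector<double> &A, int g) {
    if (g == NA_INTEGER || g < 0) return;
    for (int j = 0; j < H; ++j) {
      const double qj = q0[j];
      double *col = &A[(size_t)j * H];
      if (g == 0) {
        for (int i = j; i < H; ++i) col[i] *= q0[i] * qj;
      } else if (g == 2) {
        for (int i = j; i < H; ++i) col[i] *= (1.0 - q0[i]) * (1.0 - qj);
      } else {
        for (int i = j; i < H; ++i)
          col[i] *= q0[i] + qj - 2.0 * q0[i] * qj;  // het: phase sum
      }
    }
  }

  // A <- T A T^t with T = s*I + u*J (J all-ones); row sums = column sums
  void transition(std::vector<double> &A, double s, double u) {
    std::fill(rs.begin(), rs.end(), 0.0);
    double tot = 0.0;
    for (int j = 0; j < H; ++j) {
      const double *col = &A[(size_t)j * H];
      rs[j] += col[j];
      tot += col[j];
      for (int i = j + 1; i < H; ++i) {
        rs[i] += col[i];
        rs[j] += col[i];
        tot += 2.0 * col[i];
      }
    }
    const double s2 = s * s, su = s * u, u2t = u * u * tot;
    for (int j = 0; j < H; ++j) {
      double *col = &A[(size_t)j * H];
      const double base = su * rs[j] + u2t;
      for (int i = j; i < H; ++i)
        col[i] = s2 * col[i] + su * rs[i] + base;
    }
  }

  void rescale(std::vector<double> &A) {
    double tot = 0.0;
    for (int j = 0; j < H; ++j) {
      const double *col = &A[(size_t)j * H];
      tot += col[j];
      for (int i = j + 1; i < H; ++i) tot += 2.0 * col[i];
    }
    if (tot <= 0.0) stop("forward-backward underflow: all state weights zero");
    const double inv = 1.0 / tot;
    for (int j = 0; j < H; ++j) {
      double *col = &A[(size_t)j * H];
      for (int i = j; i < H; ++i) col[i] *= inv;
    }
  }
};

// posterior genotype distribution for one sample; panel is H x L
// column-major with precomputed column pointers, obs length L
void posterior_one(const IntegerMatrix &panel, const int *obs,
                   const double *pos, int L, int masked,
                   double rho, double eps, Workspace &w, double *out) {
  const int H = w.H;
  std::vector<double> &F = w.M, &B = w.G;

  // forward to the masked site (lower triangle only; see Workspace)
  std::fill(F.begin(), F.end(), 1.0 / ((double)H * H));
  w.emission_probs(&panel[0], eps);
  w.apply_emission(F, obs[0]);
  w.rescale(F);
  for (int t = 1; t <= masked; ++t) {
    double s = std::exp(-rho * (pos[t] - pos[t - 1]));
    w.transition(F, s, (1.0 - s) / H);
    w.emission_probs(&panel[(size_t)t * H], eps);
    w.apply_emission(F, obs[t]);
    w.rescale(F);
  }

  // backward from the last site down to the masked site
  std::fill(B.begin(), B.end(), 1.0);
  for (int t = L - 2; t >= masked; --t) {
    w.emission_probs(&panel[(size_t)(t + 1) * H], eps);
    w.apply_emission(B, obs[t + 1]);
    double s = std::exp(-rho * (pos[t + 1] - pos[t]));
    w.transition(B, s, (1.0 - s) / H);
    w.rescale(B);
  }

  // combine and map the state posterior to a genotype distribution
  w.emission_probs(&panel[(size_t)masked * H], eps);
  double p0 = 0.0, p1 = 0.0, p2 = 0.0, tot = 0.0;
  for (int j = 0; j < H; ++j) {
    const double qj = w.q0[j];
    const double *fc = &F[(size_t)j * H], *bc = &B[(size_t)j * H];
    for (int i = j; i < H; ++i) {
      const double wgt = (i == j ? 1.0 : 2.0) * fc[i] * bc[i];
      const double qi = w.q0[i];
      tot += wgt;
      p0 += wgt * qi * qj;
      p2 += wgt * (1.0 - qi) * (1.0 - qj);
      p1 += wgt * (qi + qj - 2.0 * qi * qj);
    }
  }
  if (tot <= 0.0) stop("zero posterior mass at masked site");
  out[0] = p0 / tot;
  out[1] = p1 / tot;
  out[2] = p2 / tot;
}

}  // namespace

// [[Rcpp::export(name = ".ls_posterior_one")]]
NumericVector ls_posterior_one(IntegerMatrix panel, IntegerVector obs,
                               NumericVector pos, int masked,
                               double rho, double eps) {
  const int H = panel.nrow(), L = panel.ncol();
  if (H < 2) stop("reference panel must contain at least 2 haplotypes");
  if (obs.size() != L || pos.size() != L)
    stop("obs/pos length must match panel site count");
  if (masked < 0 || masked >= L) stop("masked index out of range");
  Workspace w(H);
  NumericVector out(3);
  posterior_one(panel, INTEGER(obs), REAL(pos), L, masked, rho, eps, w,
                REAL(out));
  return out;
}

// [[Rcpp::export(name = ".ls_posterior_many")]]
NumericMatrix ls_posterior_many(IntegerMatrix panel, IntegerMatrix obs,
                                NumericVector pos, int masked,
                                double rho, double eps) {
  const int N = obs.nrow(), L = obs.ncol(), H = panel.nrow();
  if (H < 2) stop("reference panel must contain at least 2 haplotypes");
  if (L != panel.ncol()) stop("obs column count must match panel");
  if (pos.size() != L) stop("pos length must match panel site count");
  if (masked < 0 || masked >= L) stop("masked index out of range");
  Workspace w(H);
  NumericMatrix out(N, 3);
  std::vector<int> row(L);
  double p[3];
  for (int n = 0; n < N; ++n) {
    bool any_typed = false;
    for (int t = 0; t < L; ++t) {
      row[t] = obs(n, t);
      if (t != masked && row[t] != NA_INTEGER) any_typed = true;
    }
    if (!any_typed) {
      out(n, 0) = NA_REAL; out(n, 1) = NA_REAL; out(n, 2) = NA_REAL;
      continue;
    }
    posterior_one(panel, row.data(), REAL(pos), L, masked, rho, eps, w, p);
    out(n, 0) = p[0]; out(n, 1) = p[1]; out(n, 2) = p[2];
  }
  return out;
}
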