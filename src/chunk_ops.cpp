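// Chunk-fused SRM dynamics: forward pass and in-chunk BPTT adjoints.
//
// Mirrors the R reference implementation (per-step path in R/network.R and
// the R-level chunk algebra in R/network_chunked.R); array layout matches
// R's column-major [B, S, n] convention, so an R array maps onto an
// arma::cube(B, S, n) without copying. Equality of values and gradients
// with the pure-R per-step path is enforced by the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::cube as_cube(SEXP x, int B, int S, int n) {
  return arma::cube(REAL(x), B, S, n, false, true);
}

static NumericVector wrap_cube(const arma::cube& c) {
  NumericVector out(c.begin(), c.end());
  out.attr("dim") = IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return out;
}

// indices (0-based) of the B*P-row trace block belonging to episode b
static inline arma::uvec ep_rows(int b, int B, int P) {
  arma::uvec r(P);
  for (int i = 0; i < P; ++i) r[i] = b + (arma::uword)B * i;
  return r;
}

// [[Rcpp::export]]
List chunk_forward_cpp(SEXP pv, SEXP ph, SEXP oh, const arma::mat& W,
                       SEXP AE, const arma::vec& eps, const arma::vec& nu,
                       double theta, double scale, bool smooth,
                       IntegerVector dims) {
  const int B = dims[0], S = dims[1], Sh = dims[2], So = dims[3],
            P = dims[4], Q = dims[5];
  const int K = eps.n_elem;
  arma::cube pre = as_cube(pv, B, S, Q);
  bool has_ph = !Rf_isNull(ph), has_oh = !Rf_isNull(oh), plastic = !Rf_isNull(AE);
  arma::cube preh, ownh;
  if (has_ph) preh = as_cube(ph, B, Sh, Q);
  if (has_oh) ownh = as_cube(oh, B, So, P);

  // spike response: A[b, s, j] = sum_k eps[k] pre(s - k)
  arma::cube A(B, S, Q, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    for (int s = 0; s < S; ++s) {
      int idx = s - k; // 0-based source step
      if (idx >= 0) {
        A.col(s) += eps[k] * pre.col(idx);
      } else if (has_ph && Sh + idx >= 0) {
        A.col(s) += eps[k] * preh.col(Sh + idx);
      }
    }
  }

  // fixed-weight + plastic drive for all steps
  arma::mat Af(A.memptr(), (arma::uword)B * S, Q, false, true);
  arma::mat U = Af * W.t(); // [B*S, P]
  if (plastic) {
    arma::mat AEm = as<arma::mat>(AE); // [B*P, Q]
    for (int b = 0; b < B; ++b) {
      arma::uvec rb = ep_rows(b, B, P);
      arma::uvec sb(S);
      for (int s = 0; s < S; ++s) sb[s] = b + (arma::uword)B * s;
      U.rows(sb) += Af.rows(sb) * AEm.rows(rb).t();
    }
  }
  arma::cube Uc(U.memptr(), B, S, P, false, true);

  // refractory drive from the previous own chunk
  if (has_oh) {
    int Kc = std::min<int>(K, So);
    for (int m = 1; m <= Kc; ++m) {
      int smax = std::min(m, S);
      for (int s = 0; s < smax; ++s) {
        Uc.col(s) += nu[m - 1] * ownh.col(So + s - m);
      }
    }
  }

  // sequential within-chunk refractory + threshold
  arma::cube sarr(B, S, P), sg(B, S, P);
  for (int s = 0; s < S; ++s) {
    arma::mat u = Uc.col(s);
    int mm = std::min(K, s);
    for (int m = 1; m <= mm; ++m) u += nu[m - 1] * arma::mat(sarr.col(s - m));
    arma::mat x = u - theta;
    if (smooth) {
      // antiderivative of exp(-scale |x|)
      arma::mat v(B, P);
      for (arma::uword i = 0; i < x.n_elem; ++i) {
        double xi = x[i];
        v[i] = xi < 0 ? std::exp(scale * xi) / scale
                      : 2.0 / scale - std::exp(-scale * xi) / scale;
      }
      sarr.col(s) = v;
    } else {
      arma::mat v(B, P);
      for (arma::uword i = 0; i < x.n_elem; ++i) v[i] = x[i] >= 0 ? 1.0 : 0.0;
      sarr.col(s) = v;
    }
    arma::mat d(B, P);
    for (arma::uword i = 0; i < x.n_elem; ++i)
      d[i] = std::exp(-scale * std::abs(x[i]));
    sg.col(s) = d;
  }
  return List::create(_["s"] = wrap_cube(sarr), _["sg"] = wrap_cube(sg),
                      _["A"] = wrap_cube(A));
}

// [[Rcpp::export]]
List chunk_backward_cpp(SEXP gv, SEXP sgv, SEXP Av, const arma::mat& W,
                        SEXP AE, const arma::vec& eps, const arma::vec& nu,
                        IntegerVector dims) {
  const int B = dims[0], S = dims[1], Sh = dims[2], So = dims[3],
            P = dims[4], Q = dims[5];
  const int K = eps.n_elem;
  bool plastic = !Rf_isNull(AE);
  arma::cube g = as_cube(gv, B, S, P);
  arma::cube sg = as_cube(sgv, B, S, P);
  arma::cube A = as_cube(Av, B, S, Q);

  // membrane adjoints, backward in time with in-chunk refractory feedback
  arma::cube gu(B, S, P);
  for (int s = S - 1; s >= 0; --s) {
    arma::mat acc = g.col(s);
    int mm = std::min(K, S - 1 - s);
    for (int m = 1; m <= mm; ++m) acc += nu[m - 1] * arma::mat(gu.col(s + m));
    gu.col(s) = acc % arma::mat(sg.col(s));
  }

  // refractory gradient crossing the chunk start
  NumericVector d_own_hist_out = NumericVector(0);
  bool has_oh = So > 0;
  arma::cube d_oh;
  if (has_oh) {
    d_oh = arma::cube(B, So, P, arma::fill::zeros);
    int Kc = std::min<int>(K, So);
    for (int m = 1; m <= Kc; ++m) {
      int smax = std::min(m, S);
      for (int s = 0; s < smax; ++s) {
        d_oh.col(So + s - m) += nu[m - 1] * arma::mat(gu.col(s));
      }
    }
  }

  // weight / trace / spike-response adjoints
  arma::mat Gu(gu.memptr(), (arma::uword)B * S, P, false, true);
  arma::mat Af(A.memptr(), (arma::uword)B * S, Q, false, true);
  arma::mat dW = Gu.t() * Af;
  arma::mat dA = Gu * W; // [B*S, Q]
  arma::mat dAE;
  if (plastic) {
    arma::mat AEm = as<arma::mat>(AE);
    dAE.zeros((arma::uword)B * P, Q);
    for (int b = 0; b < B; ++b) {
      arma::uvec rb = ep_rows(b, B, P);
      arma::uvec sb(S);
      for (int s = 0; s < S; ++s) sb[s] = b + (arma::uword)B * s;
      arma::mat Gb = Gu.rows(sb); // [S, P]
      dAE.rows(rb) = Gb.t() * Af.rows(sb);
      dA.rows(sb) += Gb * AEm.rows(rb);
    }
  }

  // push spike-response adjoints through the epsilon taps
  arma::cube dAc(dA.memptr(), B, S, Q, false, true);
  arma::cube d_pre(B, S, Q, arma::fill::zeros);
  arma::cube d_ph;
  bool has_ph = Sh > 0;
  if (has_ph) d_ph = arma::cube(B, Sh, Q, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    for (int s = 0; s < S; ++s) {
      int idx = s - k;
      if (idx >= 0) d_pre.col(idx) += eps[k] * arma::mat(dAc.col(s));
      else if (has_ph && Sh + idx >= 0)
        d_ph.col(Sh + idx) += eps[k] * arma::mat(dAc.col(s));
    }
  }

  List out = List::create(
    _["d_pre_cur"] = wrap_cube(d_pre),
    _["d_pre_hist"] = has_ph ? (SEXP)wrap_cube(d_ph) : R_NilValue,
    _["d_own_hist"] = has_oh ? (SEXP)wrap_cube(d_oh) : R_NilValue,
    _["dW"] = wrap(dW),
    _["dAE"] = plastic ? (SEXP)wrap(dAE) : R_NilValue);
  return out;
}
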