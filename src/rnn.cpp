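// Batched forward pass and backpropagation-through-time for the recurrent
// rate network, plus the neighbor-count kernel of the correlation-dimension
// estimator. Array layout: input/target cubes are (cells, batch, time) so
// that each timestep is a contiguous slice.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// h_t = tanh([Wx x_t + Wh h_{t-1} + b]_(+)), o_t = tanh(Wo h_t + bo).
// The rectification [.]_+ of the preactivation applies only to the
// non-negative variant.

// [[Rcpp::export]]
Rcpp::List cpp_rnn_forward(const arma::mat& Wx, const arma::mat& Wh,
                           const arma::vec& b, const arma::mat& Wo,
                           const arma::vec& bo, const arma::cube& X,
                           bool nonneg) {
  const uword B = X.n_cols, T = X.n_slices;
  const uword nh = Wh.n_rows, no = Wo.n_rows;
  cube H(nh, B, T), O(no, B, T);
  mat h(nh, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat P = Wx * X.slice(t);
    P += Wh * h;
    P.each_col() += b;
    if (nonneg) P.clamp(0.0, datum::inf);
    h = tanh(P);
    H.slice(t) = h;
    mat U = Wo * h;
    U.each_col() += bo;
    O.slice(t) = tanh(U);
  }
  if (!H.is_finite() || !O.is_finite())
    Rcpp::stop("rnn forward produced non-finite activations");
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("O") = O);
}

// [[Rcpp::export]]
double cpp_rnn_loss(const arma::mat& Wx, const arma::mat& Wh,
                    const arma::vec& b, const arma::mat& Wo,
                    const arma::vec& bo, const arma::cube& X,
                    const arma::cube& Otar, bool nonneg) {
  const uword B = X.n_cols, T = X.n_slices;
  const uword nh = Wh.n_rows;
  mat h(nh, B, fill::zeros);
  double sse = 0.0;
  for (uword t = 0; t < T; ++t) {
    mat P = Wx * X.slice(t);
    P += Wh * h;
    P.each_col() += b;
    if (nonneg) P.clamp(0.0, datum::inf);
    h = tanh(P);
    mat U = Wo * h;
    U.each_col() += bo;
    sse += accu(square(tanh(U) - Otar.slice(t)));
  }
  return sse / (double)(Otar.n_rows * B * T);
}

// Mean-squared-error loss averaged over output neurons, time and trials,
// with its gradients via backpropagation through the full trial. The
// input drive, output projection and their weight gradients are computed
// as single large matrix products over all timesteps; only the recurrent
// product runs inside the time loop.
// [[Rcpp::export]]
Rcpp::List cpp_rnn_bptt(const arma::mat& Wx, const arma::mat& Wh,
                        const arma::vec& b, const arma::mat& Wo,
                        const arma::vec& bo, const arma::cube& X,
                        const arma::cube& Otar, bool nonneg) {
  const uword B = X.n_cols, T = X.n_slices;
  const uword nh = Wh.n_rows, no = Wo.n_rows;
  const uword n_in = Wx.n_cols, NT = B * T;

  // flat views over (cells, B*T)
  const mat Xf(const_cast<double*>(X.memptr()), n_in, NT, false, true);
  mat drive = Wx * Xf;             // input drive for every step at once
  drive.each_col() += b;

  mat H(nh, NT);
  mat Mask;
  if (nonneg) Mask.set_size(nh, NT);
  mat h(nh, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    mat P = drive.cols(t * B, t * B + B - 1) + Wh * h;
    if (nonneg) {
      Mask.cols(t * B, t * B + B - 1) = conv_to<mat>::from(P > 0.0);
      P.clamp(0.0, datum::inf);
    }
    h = tanh(P);
    H.cols(t * B, t * B + B - 1) = h;
  }
  mat O = Wo * H;                  // output projection, all steps at once
  O.each_col() += bo;
  O = tanh(O);
  if (!H.is_finite() || !O.is_finite())
    Rcpp::stop("rnn forward produced non-finite activations");

  const double denom = (double)(no * NT);
  const mat Of(const_cast<double*>(Otar.memptr()), no, NT, false, true);
  mat diff = O - Of;
  double loss = accu(square(diff)) / denom;
  mat dU = (2.0 / denom) * (diff % (1.0 - square(O)));
  mat gWo = dU * H.t();
  vec gbo = sum(dU, 1);
  mat dH = Wo.t() * dU;            // output contribution to every dh_t

  mat dP(nh, NT);
  mat carry(nh, B, fill::zeros);   // Wh^T dP_{t+1}
  for (uword ti = T; ti-- > 0;) {
    const uword c0 = ti * B, c1 = ti * B + B - 1;
    mat dPt = (dH.cols(c0, c1) + carry) %
      (1.0 - square(H.cols(c0, c1)));
    if (nonneg) dPt %= Mask.cols(c0, c1);
    dP.cols(c0, c1) = dPt;
    carry = Wh.t() * dPt;
  }
  mat gWx = dP * Xf.t();
  vec gb = sum(dP, 1);
  // sum_t dP_t h_{t-1}^T as one wide product (h_0 block is the zero state)
  mat gWh = dP.cols(B, NT - 1) * H.cols(0, NT - B - 1).t();
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("gWx") = gWx, Rcpp::Named("gWh") = gWh,
    Rcpp::Named("gb") = gb, Rcpp::Named("gWo") = gWo,
    Rcpp::Named("gbo") = gbo);
}

// von Mises place-cell target cube for a batch of trajectories:
// O(a, b, t) = exp((cos(z_a - y_{t,b}) - 1) / (2 sigma^2)).
// [[Rcpp::export]]
arma::cube cpp_target_cube(const arma::mat& y, const arma::vec& z,
                           double sigma) {
  const uword T = y.n_rows, B = y.n_cols, no = z.n_elem;
  cube O(no, B, T);
  const double s2 = 2.0 * sigma * sigma;
  for (uword t = 0; t < T; ++t) {
    for (uword b = 0; b < B; ++b) {
      const double yy = y(t, b);
      double* col = O.slice_colptr(t, b);
      for (uword a = 0; a < no; ++a)
        col[a] = std::exp((std::cos(z(a) - yy) - 1.0) / s2);
    }
  }
  return O;
}

// Single-precision variant of the training step: SGD is insensitive to
// fp32 rounding and the smaller operands roughly double throughput on
// one core. Gradients are returned as doubles.
// [[Rcpp::export]]
Rcpp::List cpp_rnn_bptt_f32(const arma::mat& Wx, const arma::mat& Wh,
                            const arma::vec& b, const arma::mat& Wo,
                            const arma::vec& bo, const arma::cube& X,
                            const arma::cube& Otar, bool nonneg) {
  const uword B = X.n_cols, T = X.n_slices;
  const uword nh = Wh.n_rows, no = Wo.n_rows;
  const uword n_in = Wx.n_cols, NT = B * T;

  fmat Wxf = conv_to<fmat>::from(Wx), Whf = conv_to<fmat>::from(Wh);
  fvec bf = conv_to<fvec>::from(b), bof = conv_to<fvec>::from(bo);
  fmat Wof = conv_to<fmat>::from(Wo);
  const mat Xd(const_cast<double*>(X.memptr()), n_in, NT, false, true);
  fmat Xf = conv_to<fmat>::from(Xd);
  const mat Od(const_cast<double*>(Otar.memptr()), no, NT, false, true);
  fmat Of = conv_to<fmat>::from(Od);

  fmat drive = Wxf * Xf;
  drive.each_col() += bf;
  fmat H(nh, NT);
  fmat Mask;
  if (nonneg) Mask.set_size(nh, NT);
  fmat h(nh, B, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    fmat P = drive.cols(t * B, t * B + B - 1) + Whf * h;
    if (nonneg) {
      Mask.cols(t * B, t * B + B - 1) = conv_to<fmat>::from(P > 0.0f);
      P.clamp(0.0f, fdatum::inf);
    }
    h = tanh(P);
    H.cols(t * B, t * B + B - 1) = h;
  }
  fmat O = Wof * H;
  O.each_col() += bof;
  O = tanh(O);
  if (!H.is_finite() || !O.is_finite())
    Rcpp::stop("rnn forward produced non-finite activations");

  const float denom = (float)(no * NT);
  fmat diff = O - Of;
  double loss = accu(conv_to<mat>::from(square(diff))) / denom;
  fmat dU = (2.0f / denom) * (diff % (1.0f - square(O)));
  fmat gWo = dU * H.t();
  fvec gbo = sum(dU, 1);
  fmat dH = Wof.t() * dU;

  fmat dP(nh, NT);
  fmat carry(nh, B, fill::zeros);
  for (uword ti = T; ti-- > 0;) {
    const uword c0 = ti * B, c1 = ti * B + B - 1;
    fmat dPt = (dH.cols(c0, c1) + carry) % (1.0f - square(H.cols(c0, c1)));
    if (nonneg) dPt %= Mask.cols(c0, c1);
    dP.cols(c0, c1) = dPt;
    carry = Whf.t() * dPt;
  }
  fmat gWx = dP * Xf.t();
  fvec gb = sum(dP, 1);
  fmat gWh = dP.cols(B, NT - 1) * H.cols(0, NT - B - 1).t();
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("gWx") = conv_to<mat>::from(gWx),
    Rcpp::Named("gWh") = conv_to<mat>::from(gWh),
    Rcpp::Named("gb") = conv_to<vec>::from(gb),
    Rcpp::Named("gWo") = conv_to<mat>::from(gWo),
    Rcpp::Named("gbo") = conv_to<vec>::from(gbo));
}

// Neighbor counts for the correlation-dimension estimator: for each base
// point, the number of other points within each radius. The base point
// itself is always excluded; when theiler > 0, points whose time index is
// within theiler of the base point's are excluded too (Theiler window
// against temporally correlated neighbors along a trajectory).
// [[Rcpp::export]]
arma::mat cpp_neighbor_counts(const arma::mat& P, const arma::uvec& base_idx,
                              const arma::vec& radii, const arma::vec& tindex,
                              double theiler) {
  const uword nb = base_idx.n_elem, nr = radii.n_elem, N = P.n_rows;
  const bool use_t = theiler > 0.0 && tindex.n_elem == N;
  mat counts(nb, nr, fill::zeros);
  vec r2 = square(radii);
  for (uword i = 0; i < nb; ++i) {
    rowvec bp = P.row(base_idx(i));
    const double tb = use_t ? tindex(base_idx(i)) : 0.0;
    vec d2(N);
    for (uword j = 0; j < N; ++j) {
      if (use_t && std::abs(tindex(j) - tb) < theiler) {
        d2(j) = datum::inf;
      } else {
        d2(j) = accu(square(P.row(j) - bp));
      }
    }
    d2(base_idx(i)) = datum::inf;
    for (uword k = 0; k < nr; ++k) counts(i, k) = accu(d2 <= r2(k));
  }
  return counts;
}
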