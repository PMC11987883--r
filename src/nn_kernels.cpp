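// Compute kernels for the sequence blocks of CLA-PTNet: LSTM forward /
// backward-through-time and the position-aware time-weighted self-attention
// products. Layout convention matches R arrays: a (B, t, d) array maps to an
// arma::cube with B rows, t columns, d slices (element (b, i, k) at
// b + i*B + k*B*t). No RNG lives here; dropout masks and initialization are
// drawn on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// write / read the (B, d) matrix sitting at time step i of a (B, t, d) cube
static inline void set_step(cube& C, uword i, const mat& M) {
  const uword d = C.n_slices;
  for (uword k = 0; k < d; ++k) C.slice(k).col(i) = M.col(k);
}
static inline mat get_step(const cube& C, uword i) {
  const uword B = C.n_rows, d = C.n_slices;
  mat M(B, d);
  for (uword k = 0; k < d; ++k) M.col(k) = C.slice(k).col(i);
  return M;
}

// flatten (B, t, c) cube to the (B*t, c) matrix sharing the same order
static inline mat flat_bt(const cube& x) {
  const uword B = x.n_rows, t = x.n_cols, c = x.n_slices;
  mat out(B * t, c);
  std::memcpy(out.memptr(), x.memptr(), sizeof(double) * B * t * c);
  return out;
}

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::cube& x, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::vec& b) {
  const uword B = x.n_rows, t = x.n_cols, d = Wh.n_rows;
  mat Xg = flat_bt(x) * Wx;                     // (B*t, 4d)
  mat bm = repmat(b.t(), B, 1);
  cube H(B, t, d), gi(B, t, d), gf(B, t, d), go(B, t, d), gg(B, t, d),
      tc(B, t, d), Cst(B, t, d);
  mat h(B, d, fill::zeros), cs(B, d, fill::zeros);
  for (uword i = 0; i < t; ++i) {
    mat A = Xg.rows(i * B, (i + 1) * B - 1) + h * Wh + bm;
    mat ig = sigm(A.cols(0, d - 1));
    mat fg = sigm(A.cols(d, 2 * d - 1));
    mat og = sigm(A.cols(2 * d, 3 * d - 1));
    mat g = tanh(A.cols(3 * d, 4 * d - 1));
    cs = fg % cs + ig % g;
    mat tch = tanh(cs);
    h = og % tch;
    set_step(gi, i, ig); set_step(gf, i, fg); set_step(go, i, og);
    set_step(gg, i, g); set_step(tc, i, tch); set_step(Cst, i, cs);
    set_step(H, i, h);
  }
  return Rcpp::List::create(
      Rcpp::Named("out") = H, Rcpp::Named("gi") = gi, Rcpp::Named("gf") = gf,
      Rcpp::Named("go") = go, Rcpp::Named("gg") = gg, Rcpp::Named("tc") = tc,
      Rcpp::Named("Cst") = Cst);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::cube& dH, const arma::cube& x,
                             const arma::mat& Wx, const arma::mat& Wh,
                             const arma::cube& gi, const arma::cube& gf,
                             const arma::cube& go, const arma::cube& gg,
                             const arma::cube& tc, const arma::cube& Cst,
                             const arma::cube& H) {
  const uword B = x.n_rows, t = x.n_cols, cin = x.n_slices, d = Wh.n_rows;
  mat dWh(d, 4 * d, fill::zeros);
  vec db(4 * d, fill::zeros);
  mat dXg(B * t, 4 * d);
  mat dh_next(B, d, fill::zeros), dc_next(B, d, fill::zeros);
  mat zero(B, d, fill::zeros);
  mat dA(B, 4 * d);
  for (uword ii = t; ii-- > 0;) {
    mat dh = get_step(dH, ii) + dh_next;
    mat ig = get_step(gi, ii), fg = get_step(gf, ii), og = get_step(go, ii);
    mat g = get_step(gg, ii), tch = get_step(tc, ii);
    mat c_prev = (ii > 0) ? get_step(Cst, ii - 1) : zero;
    mat h_prev = (ii > 0) ? get_step(H, ii - 1) : zero;
    mat do_ = dh % tch;
    mat dc = dc_next + dh % og % (1.0 - tch % tch);
    dc_next = dc % fg;
    dA.cols(0, d - 1) = (dc % g) % ig % (1.0 - ig);
    dA.cols(d, 2 * d - 1) = (dc % c_prev) % fg % (1.0 - fg);
    dA.cols(2 * d, 3 * d - 1) = do_ % og % (1.0 - og);
    dA.cols(3 * d, 4 * d - 1) = (dc % ig) % (1.0 - g % g);
    dWh += h_prev.t() * dA;
    db += sum(dA, 0).t();
    dh_next = dA * Wh.t();
    dXg.rows(ii * B, (ii + 1) * B - 1) = dA;
  }
  mat dWx = flat_bt(x).t() * dXg;
  mat dxm = dXg * Wx.t();                        // (B*t, cin)
  cube dx(B, t, cin);
  std::memcpy(dx.memptr(), dxm.memptr(), sizeof(double) * B * t * cin);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = db);
}

static inline mat softmax_rows_cpp(mat S) {
  vec mx = max(S, 1);
  S.each_col() -= mx;
  S = exp(S);
  S.each_col() /= sum(S, 1);
  return S;
}

// [[Rcpp::export]]
Rcpp::List ptwsa_forward_cpp(const arma::cube& H, const arma::mat& P,
                             const arma::mat& Wq, const arma::mat& Wk,
                             const arma::mat& Wv, const arma::vec& wt,
                             const double scale) {
  const uword B = H.n_rows, t = H.n_cols, d = H.n_slices;
  mat Hp = flat_bt(H);
  for (uword i = 0; i < t; ++i)
    Hp.rows(i * B, (i + 1) * B - 1).each_row() += P.row(i);
  mat Qa = Hp * Wq, Ka = Hp * Wk, Va = Hp * Wv;
  mat Kpa = Ka;
  for (uword i = 0; i < t; ++i)
    Kpa.rows(i * B, (i + 1) * B - 1) *= wt(i);
  cube O(B, t, d), Wc(t, t, B);
  mat Qb(t, d), Kpb(t, d), Vb(t, d);
  for (uword b = 0; b < B; ++b) {
    for (uword i = 0; i < t; ++i) {
      Qb.row(i) = Qa.row(b + i * B);
      Kpb.row(i) = Kpa.row(b + i * B);
      Vb.row(i) = Va.row(b + i * B);
    }
    mat W = softmax_rows_cpp(Qb * Kpb.t() / scale);
    mat Ob = W * Vb;                             // (t, d)
    for (uword k = 0; k < d; ++k) O.slice(k).row(b) = Ob.col(k).t();
    Wc.slice(b) = W;
  }
  return Rcpp::List::create(
      Rcpp::Named("out") = O, Rcpp::Named("Hp") = Hp, Rcpp::Named("Qa") = Qa,
      Rcpp::Named("Ka") = Ka, Rcpp::Named("Va") = Va, Rcpp::Named("Kpa") = Kpa,
      Rcpp::Named("Wc") = Wc);
}

// [[Rcpp::export]]
Rcpp::List ptwsa_backward_cpp(const arma::cube& dO, const arma::mat& P,
                              const arma::mat& Wq, const arma::mat& Wk,
                              const arma::mat& Wv, const arma::vec& wt,
                              const double scale, const arma::mat& Hp,
                              const arma::mat& Qa, const arma::mat& Ka,
                              const arma::mat& Va, const arma::mat& Kpa,
                              const arma::cube& Wc) {
  const uword B = dO.n_rows, t = dO.n_cols, d = dO.n_slices;
  mat dQa(B * t, d), dKpa(B * t, d), dVa(B * t, d);
  mat dOb(t, d), Qb(t, d), Kpb(t, d), Vb(t, d);
  for (uword b = 0; b < B; ++b) {
    for (uword i = 0; i < t; ++i) {
      for (uword k = 0; k < d; ++k) dOb(i, k) = dO(b, i, k);
      Qb.row(i) = Qa.row(b + i * B);
      Kpb.row(i) = Kpa.row(b + i * B);
      Vb.row(i) = Va.row(b + i * B);
    }
    const mat& W = Wc.slice(b);
    mat dWattn = dOb * Vb.t();
    mat dVb = W.t() * dOb;
    mat dS = W % (dWattn.each_col() - sum(dWattn % W, 1));
    mat dQb = dS * Kpb / scale;
    mat dKpb = dS.t() * Qb / scale;
    for (uword i = 0; i < t; ++i) {
      dQa.row(b + i * B) = dQb.row(i);
      dKpa.row(b + i * B) = dKpb.row(i);
      dVa.row(b + i * B) = dVb.row(i);
    }
  }
  mat dKa = dKpa;
  vec dwt(t);
  mat dP(t, d);
  for (uword i = 0; i < t; ++i) {
    const uword r0 = i * B, r1 = (i + 1) * B - 1;
    dKa.rows(r0, r1) *= wt(i);
    dwt(i) = accu(dKpa.rows(r0, r1) % Ka.rows(r0, r1));
  }
  mat dHp = dQa * Wq.t() + dKa * Wk.t() + dVa * Wv.t();
  for (uword i = 0; i < t; ++i)
    dP.row(i) = sum(dHp.rows(i * B, (i + 1) * B - 1), 0);
  mat gWq = Hp.t() * dQa, gWk = Hp.t() * dKa, gWv = Hp.t() * dVa;
  cube dx(B, t, d);
  std::memcpy(dx.memptr(), dHp.memptr(), sizeof(double) * B * t * d);
  return Rcpp::List::create(
      Rcpp::Named("dx") = dx, Rcpp::Named("P") = dP, Rcpp::Named("Wq") = gWq,
      Rcpp::Named("Wk") = gWk, Rcpp::Named("Wv") = gWv,
      Rcpp::Named("w_time") = dwt);
}

// 1-D convolution over (B, t, c_in) with odd kernel k and symmetric zero
// padding; W is (k, c_in, c_out). Shifted design matrices are rebuilt on
// the fly in the backward pass instead of being cached.
static mat shifted_flat(const cube& x, const int s) {
  const uword B = x.n_rows, t = x.n_cols, cin = x.n_slices;
  mat Xs(B * t, cin, fill::zeros);
  const int lo = std::max(0, -s), hi = std::min<int>(t - 1, t - 1 - s);
  for (uword ci = 0; ci < cin; ++ci) {
    for (int i = lo; i <= hi; ++i)
      Xs.col(ci).subvec(i * B, (i + 1) * B - 1) = x.slice(ci).col(i + s);
  }
  return Xs;
}

static mat w_shift(const cube& W, const uword j) {
  const uword cin = W.n_cols, cout = W.n_slices;
  mat Wj(cin, cout);
  for (uword o = 0; o < cout; ++o)
    for (uword ci = 0; ci < cin; ++ci) Wj(ci, o) = W(j, ci, o);
  return Wj;
}

// [[Rcpp::export]]
arma::cube conv1d_forward_cpp(const arma::cube& x, const arma::cube& W,
                              const arma::vec& b) {
  const uword B = x.n_rows, t = x.n_cols;
  const uword k = W.n_rows, cout = W.n_slices;
  const int pad = (k - 1) / 2;
  mat out = repmat(b.t(), B * t, 1);
  for (uword j = 0; j < k; ++j)
    out += shifted_flat(x, (int)j - pad) * w_shift(W, j);
  cube res(B, t, cout);
  std::memcpy(res.memptr(), out.memptr(), sizeof(double) * B * t * cout);
  return res;
}

// [[Rcpp::export]]
Rcpp::List conv1d_backward_cpp(const arma::cube& d_out, const arma::cube& x,
                               const arma::cube& W) {
  const uword B = x.n_rows, t = x.n_cols, cin = x.n_slices;
  const uword k = W.n_rows, cout = W.n_slices;
  const int pad = (k - 1) / 2;
  mat dOut((double*)d_out.memptr(), B * t, cout);
  cube dW(k, cin, cout, fill::zeros);
  vec db = sum(dOut, 0).t();
  cube dx(B, t, cin, fill::zeros);
  for (uword j = 0; j < k; ++j) {
    const int s = (int)j - pad;
    mat dWj = shifted_flat(x, s).t() * dOut;          // (cin, cout)
    for (uword o = 0; o < cout; ++o)
      for (uword ci = 0; ci < cin; ++ci) dW(j, ci, o) = dWj(ci, o);
    mat dXs = dOut * w_shift(W, j).t();               // (B*t, cin)
    const int lo = std::max(0, -s), hi = std::min<int>(t - 1, t - 1 - s);
    for (uword ci = 0; ci < cin; ++ci)
      for (int i = lo; i <= hi; ++i)
        dx.slice(ci).col(i + s) += dXs.col(ci).subvec(i * B, (i + 1) * B - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
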