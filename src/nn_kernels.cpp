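// Hot numerical kernels for the pair classifier: convolution via
// im2col + GEMM, non-overlapping max pooling, and batched multi-head
// self-attention, with exact backward passes.  Array layout matches the
// R side: a batch is a (B, L, C) array, i.e. an arma::cube with
// n_rows = B (sample index fastest), n_cols = L, n_slices = C.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// ---- convolution -------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_conv_fwd(const arma::cube& X, const arma::mat& W,
                        const arma::vec& b, int k, bool want_cache) {
  const int B = X.n_rows, L = X.n_cols, C = X.n_slices;
  const int Lc = L - k + 1;
  const int F = W.n_cols;
  mat Xc(B * Lc, k * C);
  for (int j = 0; j < k; ++j)
    for (int c = 0; c < C; ++c)
      Xc.col(j * C + c) = vectorise(X.slice(c).cols(j, j + Lc - 1));
  mat Ym = Xc * W;
  Ym.each_row() += b.t();
  cube Y(Ym.memptr(), B, Lc, F);  // same memory layout
  if (!want_cache) return Rcpp::List::create(Rcpp::Named("Y") = Y);
  return Rcpp::List::create(Rcpp::Named("Y") = Y,
                            Rcpp::Named("Xc") = Xc);
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bwd(const arma::cube& dY, const arma::mat& Xc,
                        const arma::mat& W, int k, int B, int L, int C,
                        bool want_dx) {
  const int Lc = dY.n_cols, F = dY.n_slices;
  mat dYm(const_cast<double*>(dY.memptr()), B * Lc, F, false, true);
  mat dW = Xc.t() * dYm;
  vec db = sum(dYm, 0).t();
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("dW") = dW,
                                      Rcpp::Named("db") = db);
  if (want_dx) {
    mat dXc = dYm * W.t();
    cube dX(B, L, C, fill::zeros);
    for (int j = 0; j < k; ++j)
      for (int c = 0; c < C; ++c) {
        mat sl(dXc.colptr(j * C + c), B, Lc, false, true);
        dX.slice(c).cols(j, j + Lc - 1) += sl;
      }
    out["dX"] = dX;
  }
  return out;
}

// ---- fused batch-norm + ReLU -------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_bn_relu_fwd(const arma::cube& Y, const arma::vec& gamma,
                           const arma::vec& beta, const arma::vec& rmean,
                           const arma::vec& rvar, bool training,
                           double momentum, double eps) {
  const int B = Y.n_rows, L = Y.n_cols, F = Y.n_slices;
  const double N = (double)B * L;
  cube out(B, L, F);
  mat Xhat(B * L, F);
  vec istd(F), new_mean = rmean, new_var = rvar;
  for (int f = 0; f < F; ++f) {
    const mat& sl = Y.slice(f);
    double mu, v;
    if (training) {
      mu = accu(sl) / N;
      v = accu(square(sl)) / N - mu * mu;
      new_mean(f) = momentum * new_mean(f) + (1 - momentum) * mu;
      new_var(f) = momentum * new_var(f) + (1 - momentum) * v;
    } else {
      mu = rmean(f);
      v = rvar(f);
    }
    double is = 1.0 / std::sqrt(v + eps);
    istd(f) = is;
    mat xh = (sl - mu) * is;
    Xhat.col(f) = vectorise(xh);
    out.slice(f) = clamp(gamma(f) * xh + beta(f), 0.0, datum::inf);
  }
  return Rcpp::List::create(Rcpp::Named("Y") = out,
                            Rcpp::Named("Xhat") = Xhat,
                            Rcpp::Named("istd") = istd,
                            Rcpp::Named("run_mean") = new_mean,
                            Rcpp::Named("run_var") = new_var);
}

// dY is the gradient at the ReLU output; act is the forward ReLU output
// (zero exactly where the unit was clipped).
// [[Rcpp::export]]
Rcpp::List cpp_bn_relu_bwd(const arma::cube& dY, const arma::mat& Xhat,
                           const arma::vec& istd, const arma::cube& act,
                           const arma::vec& gamma, bool training) {
  const int B = dY.n_rows, L = dY.n_cols, F = dY.n_slices;
  const double N = (double)B * L;
  cube dX(B, L, F);
  vec dgamma(F), dbeta(F);
  for (int f = 0; f < F; ++f) {
    mat d = dY.slice(f);
    d.elem(find(act.slice(f) <= 0)).zeros();      // ReLU gate
    vec dv = vectorise(d);
    const vec xh = Xhat.col(f);
    dgamma(f) = dot(dv, xh);
    dbeta(f) = accu(dv);
    if (training) {
      double m1 = dbeta(f) / N;
      double m2 = dgamma(f) / N;
      dX.slice(f) = reshape((dv - m1 - xh * m2) * (gamma(f) * istd(f)),
                            B, L);
    } else {
      dX.slice(f) = reshape(dv * (gamma(f) * istd(f)), B, L);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// ---- shift augmentation ------------------------------------------------

// Circularly shifts each half of each sample by an independent uniform
// offset in [-s, s]; draws come from R's RNG so runs are seed-exact.
// [[Rcpp::export]]
arma::cube cpp_shift_augment(const arma::cube& X, int s) {
  const int B = X.n_rows, L = X.n_cols, C = X.n_slices;
  const int h = L / 2;
  cube out(B, L, C);
  for (int b = 0; b < B; ++b) {
    for (int half = 0; half < 2; ++half) {
      int k = (int)std::floor(R::unif_rand() * (2 * s + 1)) - s;
      int off = half * h;
      for (int t = 0; t < h; ++t) {
        int src = ((t - k) % h + h) % h + off;
        for (int c = 0; c < C; ++c)
          out(b, t + off, c) = X(b, src, c);
      }
    }
  }
  return out;
}

// ---- max pooling -------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_pool_fwd(const arma::cube& Y, int p) {
  const int B = Y.n_rows, L = Y.n_cols, F = Y.n_slices;
  const int Tn = L / p;
  cube M(B, Tn, F);
  Rcpp::IntegerVector which(B * Tn * F);
  int* wptr = INTEGER(which);
  for (int f = 0; f < F; ++f)
    for (int t = 0; t < Tn; ++t)
      for (int b = 0; b < B; ++b) {
        double best = Y(b, t * p, f);
        int bj = 0;
        for (int j = 1; j < p; ++j) {
          double v = Y(b, t * p + j, f);
          if (v > best) { best = v; bj = j; }
        }
        M(b, t, f) = best;
        wptr[b + (size_t)B * (t + (size_t)Tn * f)] = bj;
      }
  which.attr("dim") = Rcpp::IntegerVector::create(B, Tn, F);
  return Rcpp::List::create(Rcpp::Named("Y") = M,
                            Rcpp::Named("which_j") = which,
                            Rcpp::Named("in_len") = L);
}

// [[Rcpp::export]]
arma::cube cpp_pool_bwd(const arma::cube& dM,
                        const Rcpp::IntegerVector& which_j, int p,
                        int L) {
  const int B = dM.n_rows, Tn = dM.n_cols, F = dM.n_slices;
  const int* wptr = INTEGER(which_j);
  cube dY(B, L, F, fill::zeros);
  for (int f = 0; f < F; ++f)
    for (int t = 0; t < Tn; ++t)
      for (int b = 0; b < B; ++b) {
        int j = wptr[b + (size_t)B * (t + (size_t)Tn * f)];
        dY(b, t * p + j, f) = dM(b, t, f);
      }
  return dY;
}

// ---- multi-head self-attention -----------------------------------------

static mat softmax_rows(mat Z) {
  Z.each_col() -= max(Z, 1);
  Z = exp(Z);
  Z.each_col() /= sum(Z, 1);
  return Z;
}

// A: (B, T, d).  Heads are contiguous column blocks.  Residual added.
// [[Rcpp::export]]
Rcpp::List cpp_attn_fwd(const arma::cube& A, const arma::mat& Wq,
                        const arma::mat& Wk, const arma::mat& Wv,
                        const arma::mat& Wo, int h, bool want_cache) {
  const int B = A.n_rows, T = A.n_cols, d = A.n_slices;
  const int dk = d / h;
  const double sc = 1.0 / std::sqrt((double)dk);
  cube out(B, T, d), Qc, Kc, Vc, Oc, Attn;
  if (want_cache) {
    Qc.set_size(B, T, d); Kc.set_size(B, T, d);
    Vc.set_size(B, T, d); Oc.set_size(B, T, d);
    Attn.set_size(T, T, (size_t)B * h);
  }
  for (int b = 0; b < B; ++b) {
    mat S = A.row(b);              // T x d
    mat Q = S * Wq, K = S * Wk, V = S * Wv;
    mat O(T, d);
    for (int hh = 0; hh < h; ++hh) {
      span cols(hh * dk, (hh + 1) * dk - 1);
      mat Ah = softmax_rows(Q.cols(cols) * K.cols(cols).t() * sc);
      if (want_cache) Attn.slice((size_t)b * h + hh) = Ah;
      O.cols(cols) = Ah * V.cols(cols);
    }
    out.row(b) = O * Wo + S;
    if (want_cache) {
      Qc.row(b) = Q; Kc.row(b) = K; Vc.row(b) = V; Oc.row(b) = O;
    }
  }
  if (!want_cache) return Rcpp::List::create(Rcpp::Named("out") = out);
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("Q") = Qc, Rcpp::Named("K") = Kc,
                            Rcpp::Named("V") = Vc, Rcpp::Named("O") = Oc,
                            Rcpp::Named("Attn") = Attn);
}

// [[Rcpp::export]]
Rcpp::List cpp_attn_bwd(const arma::cube& dOut, const arma::cube& A,
                        const arma::cube& Qc, const arma::cube& Kc,
                        const arma::cube& Vc, const arma::cube& Oc,
                        const arma::cube& Attn, const arma::mat& Wq,
                        const arma::mat& Wk, const arma::mat& Wv,
                        const arma::mat& Wo, int h) {
  const int B = A.n_rows, T = A.n_cols, d = A.n_slices;
  const int dk = d / h;
  const double sc = 1.0 / std::sqrt((double)dk);
  cube dA(B, T, d);
  mat dWq(d, d, fill::zeros), dWk(d, d, fill::zeros),
      dWv(d, d, fill::zeros), dWo(d, d, fill::zeros);
  for (int b = 0; b < B; ++b) {
    mat S = A.row(b);
    mat dOutb = dOut.row(b);
    mat Q = Qc.row(b), K = Kc.row(b), V = Vc.row(b), O = Oc.row(b);
    mat dS = dOutb;                 // residual path
    dWo += O.t() * dOutb;
    mat dO = dOutb * Wo.t();
    mat dQ(T, d), dK(T, d), dV(T, d);
    for (int hh = 0; hh < h; ++hh) {
      span cols(hh * dk, (hh + 1) * dk - 1);
      const mat& Ah = Attn.slice((size_t)b * h + hh);
      mat dOh = dO.cols(cols);
      mat dAh = dOh * V.cols(cols).t();
      dV.cols(cols) = Ah.t() * dOh;
      mat dZ = (dAh - repmat(sum(dAh % Ah, 1), 1, T)) % Ah;
      dQ.cols(cols) = dZ * K.cols(cols) * sc;
      dK.cols(cols) = dZ.t() * Q.cols(cols) * sc;
    }
    dWq += S.t() * dQ;
    dWk += S.t() * dK;
    dWv += S.t() * dV;
    dS += dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
    dA.row(b) = dS;
  }
  return Rcpp::List::create(Rcpp::Named("dA") = dA,
                            Rcpp::Named("dWq") = dWq,
                            Rcpp::Named("dWk") = dWk,
                            Rcpp::Named("dWv") = dWv,
                            Rcpp::Named("dWo") = dWo);
}
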