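// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Compact CNN regression engine: valid-mode convolutions (im2col + gemm),
// tanh activations, max pooling, an optional fully connected hidden layer,
// and a single linear output. One entry point computes predictions and
// (optionally) mean gradients over a mini-batch; the optimizer lives in R.

static arma::mat im2col(const arma::cube &X, int k, int &oh, int &ow) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  oh = H - k + 1; ow = W - k + 1;
  arma::mat cols(k * k * C, (size_t)oh * ow);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int row = ki + k * kj + k * k * c;
        for (int j = 0; j < ow; ++j)
          for (int i = 0; i < oh; ++i)
            cols(row, i + (size_t)oh * j) = X(i + ki, j + kj, c);
      }
  return cols;
}

static void col2im_add(arma::cube &dX, const arma::mat &dcols, int k) {
  const int H = dX.n_rows, W = dX.n_cols, C = dX.n_slices;
  const int oh = H - k + 1, ow = W - k + 1;
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < k; ++kj)
      for (int ki = 0; ki < k; ++ki) {
        const int row = ki + k * kj + k * k * c;
        for (int j = 0; j < ow; ++j)
          for (int i = 0; i < oh; ++i)
            dX(i + ki, j + kj, c) += dcols(row, i + (size_t)oh * j);
      }
}

static arma::cube maxpool(const arma::cube &X, int p, int s,
                          arma::ucube &argmax) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int oh = (H - p) / s + 1, ow = (W - p) / s + 1;
  arma::cube out(oh, ow, C);
  argmax.set_size(oh, ow, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        double best = -arma::datum::inf; arma::uword bidx = 0;
        for (int dj = 0; dj < p; ++dj)
          for (int di = 0; di < p; ++di) {
            const int y = i * s + di, x = j * s + dj;
            double v = X(y, x, c);
            if (v > best) { best = v; bidx = y + (arma::uword)H * x; }
          }
        out(i, j, c) = best;
        argmax(i, j, c) = bidx;
      }
  return out;
}

struct LayerCache {
  arma::mat cols;      // im2col of the conv input
  arma::cube pre_act;  // conv output before tanh
  arma::cube act;      // after tanh (pool input)
  arma::ucube argmax;  // pooling winners
  arma::cube pooled;   // pool output
  int in_h, in_w, in_c;
};

// [[Rcpp::export]]
List cnn_batch_cpp(List conv_W, List conv_b, int kernel, int pool,
                   int pool_stride, Nullable<NumericMatrix> fc_W_,
                   Nullable<NumericVector> fc_b_, NumericVector out_W,
                   double out_b, List X_list, NumericVector y,
                   bool want_grad) {
  const int L = conv_W.size();
  const int B = X_list.size();
  std::vector<arma::mat> Wc(L);
  std::vector<arma::vec> bc(L);
  for (int l = 0; l < L; ++l) {
    Wc[l] = as<arma::mat>(conv_W[l]);
    bc[l] = as<arma::vec>(conv_b[l]);
  }
  bool has_fc = fc_W_.isNotNull();
  arma::mat Wf; arma::vec bf;
  if (has_fc) { Wf = as<arma::mat>(fc_W_.get()); bf = as<arma::vec>(fc_b_.get()); }
  arma::vec wo = as<arma::vec>(out_W);

  std::vector<arma::mat> dWc(L);
  std::vector<arma::vec> dbc(L);
  arma::mat dWf; arma::vec dbf;
  arma::vec dwo(wo.n_elem, arma::fill::zeros);
  double dbo = 0.0;
  if (want_grad) {
    for (int l = 0; l < L; ++l) {
      dWc[l].zeros(Wc[l].n_rows, Wc[l].n_cols);
      dbc[l].zeros(bc[l].n_elem);
    }
    if (has_fc) { dWf.zeros(Wf.n_rows, Wf.n_cols); dbf.zeros(bf.n_elem); }
  }

  NumericVector preds(B);
  double loss = 0.0;
  const bool have_y = y.size() == B;

  for (int bi = 0; bi < B; ++bi) {
    NumericVector xr = X_list[bi];
    IntegerVector dims = xr.attr("dim");
    arma::cube X(xr.begin(), dims[0], dims[1], dims.size() > 2 ? dims[2] : 1);

    std::vector<LayerCache> cache(L);
    arma::cube cur = X;
    for (int l = 0; l < L; ++l) {
      LayerCache &cc = cache[l];
      cc.in_h = cur.n_rows; cc.in_w = cur.n_cols; cc.in_c = cur.n_slices;
      int oh, ow;
      cc.cols = im2col(cur, kernel, oh, ow);
      const int F = Wc[l].n_cols;
      arma::mat res = Wc[l].t() * cc.cols; // F x oh*ow
      res.each_col() += bc[l];
      cc.pre_act.set_size(oh, ow, F);
      for (int f = 0; f < F; ++f)
        cc.pre_act.slice(f) = arma::reshape(res.row(f), oh, ow);
      cc.act = arma::tanh(cc.pre_act);
      cc.pooled = maxpool(cc.act, pool, pool_stride, cc.argmax);
      cur = cc.pooled;
    }
    arma::vec flat = arma::vectorise(cur);
    arma::vec hidden, hpre;
    double pred;
    if (has_fc) {
      hpre = Wf.t() * flat + bf;
      hidden = arma::tanh(hpre);
      pred = arma::dot(wo, hidden) + out_b;
    } else {
      pred = arma::dot(wo, flat) + out_b;
    }
    preds[bi] = pred;

    if (!want_grad) continue;
    double err = have_y ? (pred - y[bi]) : 0.0;
    loss += err * err;
    double dpred = 2.0 * err / B;

    arma::vec dflat;
    if (has_fc) {
      dwo += dpred * hidden;
      dbo += dpred;
      arma::vec dh = dpred * wo;
      arma::vec dhpre = dh % (1.0 - arma::square(hidden));
      dWf += flat * dhpre.t();
      dbf += dhpre;
      dflat = Wf * dhpre;
    } else {
      dwo += dpred * flat;
      dbo += dpred;
      dflat = dpred * wo;
    }

    // back through conv blocks
    arma::cube dcur(cache[L - 1].pooled.n_rows, cache[L - 1].pooled.n_cols,
                    cache[L - 1].pooled.n_slices);
    std::memcpy(dcur.memptr(), dflat.memptr(), sizeof(double) * dflat.n_elem);
    for (int l = L - 1; l >= 0; --l) {
      LayerCache &cc = cache[l];
      // unpool
      arma::cube dact(cc.act.n_rows, cc.act.n_cols, cc.act.n_slices,
                      arma::fill::zeros);
      const int H = cc.act.n_rows;
      for (arma::uword c = 0; c < dcur.n_slices; ++c)
        for (arma::uword j = 0; j < dcur.n_cols; ++j)
          for (arma::uword i = 0; i < dcur.n_rows; ++i) {
            arma::uword idx = cc.argmax(i, j, c);
            dact(idx % H, idx / H, c) += dcur(i, j, c);
          }
      arma::cube dpre = dact % (1.0 - arma::square(cc.act));
      const int F = Wc[l].n_cols;
      const int oh = dpre.n_rows, ow = dpre.n_cols;
      arma::mat dres(F, (size_t)oh * ow);
      for (int f = 0; f < F; ++f)
        dres.row(f) = arma::vectorise(dpre.slice(f)).t();
      dWc[l] += cc.cols * dres.t();
      dbc[l] += arma::sum(dres, 1);
      if (l > 0) {
        arma::mat dcols = Wc[l] * dres;
        arma::cube dX(cc.in_h, cc.in_w, cc.in_c, arma::fill::zeros);
        col2im_add(dX, dcols, kernel);
        dcur = dX;
      }
    }
  }

  List out = List::create(_["preds"] = preds,
                          _["loss"] = have_y ? loss / B : NA_REAL);
  if (want_grad) {
    List gW(L), gb(L);
    for (int l = 0; l < L; ++l) { gW[l] = dWc[l]; gb[l] = dbc[l]; }
    out["d_conv_W"] = gW;
    out["d_conv_b"] = gb;
    if (has_fc) { out["d_fc_W"] = dWf; out["d_fc_b"] = dbf; }
    out["d_out_W"] = dwo;
    out["d_out_b"] = dbo;
  }
  return out;
}
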