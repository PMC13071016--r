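// Small convolutional backbone used by the simulator's local trainer.
// Three 3x3 conv blocks (stride-2 stem, then two stride-1 blocks), each
// ReLU + 2x2 max-pool, global average pooling, linear softmax head.
//
// Activations are stored as (Ho*Wo*N) x C matrices with position index
// p = i + j*Ho + img*Ho*Wo, so im2col gathers and pooling walk contiguous
// memory and the convolutions reduce to single dgemm calls per layer.
// Batches arrive as H x W x N cubes (grayscale); parameters as flat vectors
// per named group, conv layout [W (Cout x Cin*9, col-major), b], head
// layout [W (ncls x F, col-major), b].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct ConvParams {
  mat W;    // Cout x (Cin*9)
  vec b;    // Cout
  int cin, cout;
};

ConvParams unpack_conv(const Rcpp::NumericVector& v, int cin) {
  ConvParams p;
  p.cin = cin;
  p.cout = (int)(v.size() / (cin * 9 + 1));
  if ((int)v.size() != p.cout * (cin * 9 + 1))
    Rcpp::stop("conv parameter vector length inconsistent with channel counts");
  p.W = mat(const_cast<double*>(v.begin()), p.cout, cin * 9, true);
  p.b = vec(const_cast<double*>(v.begin()) + p.cout * cin * 9, p.cout, true);
  return p;
}

int conv_out(int h, int stride) { return (h + 2 - 3) / stride + 1; }

// Gather 3x3 patches (pad 1) from A (h*w*n x cin) into (ho*wo*n x cin*9).
mat im2col3(const mat& A, int h, int w, int n, int cin, int stride,
            int ho, int wo) {
  mat cols((size_t)ho * wo * n, cin * 9, fill::zeros);
  for (int c = 0; c < cin; ++c) {
    const double* src0 = A.colptr(c);
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        double* dst0 = cols.colptr(c * 9 + dj * 3 + di);
        for (int img = 0; img < n; ++img) {
          const double* src = src0 + (size_t)img * h * w;
          double* dst = dst0 + (size_t)img * ho * wo;
          for (int j = 0; j < wo; ++j) {
            const int jj = j * stride - 1 + dj;
            if (jj < 0 || jj >= w) continue;
            const double* scol = src + (size_t)jj * h;
            double* dcol = dst + (size_t)j * ho;
            const int i0 = (di == 0) ? 1 : 0;
            for (int i = i0; i < ho; ++i) {
              const int ii = i * stride - 1 + di;
              if (ii >= h) break;
              dcol[i] = scol[ii];
            }
          }
        }
      }
    }
  }
  return cols;
}

// Transpose of im2col3: scatter-add dcols back onto the input grid.
void col2im3(const mat& dcols, mat& dA, int h, int w, int n, int cin,
             int stride, int ho, int wo) {
  for (int c = 0; c < cin; ++c) {
    double* dst0 = dA.colptr(c);
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const double* src0 = dcols.colptr(c * 9 + dj * 3 + di);
        for (int img = 0; img < n; ++img) {
          double* dst = dst0 + (size_t)img * h * w;
          const double* src = src0 + (size_t)img * ho * wo;
          for (int j = 0; j < wo; ++j) {
            const int jj = j * stride - 1 + dj;
            if (jj < 0 || jj >= w) continue;
            double* dcol = dst + (size_t)jj * h;
            const double* scol = src + (size_t)j * ho;
            const int i0 = (di == 0) ? 1 : 0;
            for (int i = i0; i < ho; ++i) {
              const int ii = i * stride - 1 + di;
              if (ii >= h) break;
              dcol[ii] += scol[i];
            }
          }
        }
      }
    }
  }
}

// 2x2 max pool, stride 2 (floor on odd dims); argmax records the flat
// within-image position of the winner.
mat maxpool2(const mat& A, int ho, int wo, int n, umat& argmax) {
  const int hp = ho / 2, wp = wo / 2, cc = A.n_cols;
  mat P((size_t)hp * wp * n, cc);
  argmax.set_size((size_t)hp * wp * n, cc);
  for (int c = 0; c < cc; ++c) {
    const double* src0 = A.colptr(c);
    double* dst0 = P.colptr(c);
    uword* am0 = argmax.colptr(c);
    for (int img = 0; img < n; ++img) {
      const double* src = src0 + (size_t)img * ho * wo;
      double* dst = dst0 + (size_t)img * hp * wp;
      uword* am = am0 + (size_t)img * hp * wp;
      for (int j = 0; j < wp; ++j) {
        for (int i = 0; i < hp; ++i) {
          uword base = (size_t)(2 * j) * ho + 2 * i;
          double best = src[base]; uword bi = base;
          if (src[base + 1] > best) { best = src[base + 1]; bi = base + 1; }
          if (src[base + ho] > best) { best = src[base + ho]; bi = base + ho; }
          if (src[base + ho + 1] > best) { best = src[base + ho + 1]; bi = base + ho + 1; }
          dst[(size_t)j * hp + i] = best;
          am[(size_t)j * hp + i] = bi;
        }
      }
    }
  }
  return P;
}

mat maxpool2_back(const mat& dP, const umat& argmax, int ho, int wo, int n) {
  const int hp = ho / 2, wp = wo / 2, cc = dP.n_cols;
  mat dA((size_t)ho * wo * n, cc, fill::zeros);
  for (int c = 0; c < cc; ++c) {
    double* dst0 = dA.colptr(c);
    const double* src0 = dP.colptr(c);
    const uword* am0 = argmax.colptr(c);
    for (int img = 0; img < n; ++img) {
      double* dst = dst0 + (size_t)img * ho * wo;
      const double* src = src0 + (size_t)img * hp * wp;
      const uword* am = am0 + (size_t)img * hp * wp;
      for (size_t p = 0; p < (size_t)hp * wp; ++p) dst[am[p]] += src[p];
    }
  }
  return dA;
}

struct LayerCache {
  mat cols;     // im2col of the layer input
  mat act;      // post-ReLU pre-pool activations
  umat argmax;  // pooling argmax
  mat pooled;   // post-pool output (input of the next layer)
  int hin, win, ho, wo, hp, wp, stride;
};

struct Net {
  ConvParams c1, c2, c3;
  mat Wh; vec bh;
  int ncls, feat;
};

Net unpack_net(const Rcpp::List& params, int ncls) {
  Net net;
  net.ncls = ncls;
  net.c1 = unpack_conv(params["conv1"], 1);
  net.c2 = unpack_conv(params["conv2"], net.c1.cout);
  net.c3 = unpack_conv(params["conv3"], net.c2.cout);
  net.feat = net.c3.cout;
  Rcpp::NumericVector hv = params["head"];
  if ((int)hv.size() != ncls * net.feat + ncls)
    Rcpp::stop("head parameter vector length inconsistent with num_classes/feature width");
  net.Wh = mat(hv.begin(), ncls, net.feat, true);
  net.bh = vec(hv.begin() + ncls * net.feat, ncls, true);
  return net;
}

void conv_forward(const mat& A, int hin, int win, int n, const ConvParams& p,
                  int stride, LayerCache& L) {
  L.hin = hin; L.win = win; L.stride = stride;
  L.ho = conv_out(hin, stride);
  L.wo = conv_out(win, stride);
  L.hp = L.ho / 2; L.wp = L.wo / 2;
  L.cols = im2col3(A, hin, win, n, p.cin, stride, L.ho, L.wo);
  L.act = L.cols * p.W.t();
  L.act.each_row() += p.b.t();
  L.act.transform([](double v) { return v > 0.0 ? v : 0.0; });
  L.pooled = maxpool2(L.act, L.ho, L.wo, n, L.argmax);
}

// returns d(input); fills dW, db
mat conv_backward(const mat& dpooled, const ConvParams& p, int n,
                  const LayerCache& L, mat& dW, vec& db) {
  mat dact = maxpool2_back(dpooled, L.argmax, L.ho, L.wo, n);
  for (uword k = 0; k < dact.n_elem; ++k)
    if (L.act(k) <= 0.0) dact(k) = 0.0;
  dW = dact.t() * L.cols;
  db = sum(dact, 0).t();
  mat dcols = dact * p.W;
  mat dA((size_t)L.hin * L.win * n, p.cin, fill::zeros);
  col2im3(dcols, dA, L.hin, L.win, n, p.cin, L.stride, L.ho, L.wo);
  return dA;
}

// forward through the three blocks; returns features (N x F)
mat forward_blocks(const mat& X0, int h, int w, int n, const Net& net,
                   LayerCache& L1, LayerCache& L2, LayerCache& L3) {
  conv_forward(X0, h, w, n, net.c1, 2, L1);
  conv_forward(L1.pooled, L1.hp, L1.wp, n, net.c2, 1, L2);
  conv_forward(L2.pooled, L2.hp, L2.wp, n, net.c3, 1, L3);
  const size_t cell = (size_t)L3.hp * L3.wp;
  mat F(n, net.feat);
  for (int c = 0; c < net.feat; ++c) {
    const double* src = L3.pooled.colptr(c);
    for (int img = 0; img < n; ++img) {
      double s = 0.0;
      const double* blk = src + (size_t)img * cell;
      for (size_t p = 0; p < cell; ++p) s += blk[p];
      F(img, c) = s / cell;
    }
  }
  return F;
}

mat softmax_rows(mat Z) {
  Z.each_col() -= max(Z, 1);
  Z = exp(Z);
  Z.each_col() /= sum(Z, 1);
  return Z;
}

mat cube_to_flat(const cube& X) {
  // H x W x N cube -> (H*W*N) x 1 matrix, same memory order
  return mat(const_cast<double*>(X.memptr()), X.n_elem, 1, true);
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_tiny_eval(const arma::cube& X, const Rcpp::List& params, int ncls) {
  const int n = X.n_slices;
  if (n == 0) Rcpp::stop("empty batch");
  Net net = unpack_net(params, ncls);
  LayerCache L1, L2, L3;
  mat X0 = cube_to_flat(X);
  mat F = forward_blocks(X0, X.n_rows, X.n_cols, n, net, L1, L2, L3);
  mat logits = F * net.Wh.t();
  logits.each_row() += net.bh.t();
  mat probs = softmax_rows(logits);
  return Rcpp::List::create(Rcpp::Named("probs") = probs,
                            Rcpp::Named("features") = F);
}

// [[Rcpp::export]]
Rcpp::List cpp_tiny_grad(const arma::cube& X, const arma::ivec& y,
                         const Rcpp::List& params, int ncls,
                         Rcpp::Nullable<Rcpp::NumericMatrix> proto = R_NilValue,
                         Rcpp::Nullable<Rcpp::NumericVector> proto_mask = R_NilValue,
                         double proto_w = 0.0) {
  const int n = X.n_slices;
  if (n == 0) Rcpp::stop("empty batch");
  if ((int)y.n_elem != n) Rcpp::stop("label/batch length mismatch");
  Net net = unpack_net(params, ncls);
  LayerCache L1, L2, L3;
  mat X0 = cube_to_flat(X);
  mat F = forward_blocks(X0, X.n_rows, X.n_cols, n, net, L1, L2, L3);
  mat logits = F * net.Wh.t();
  logits.each_row() += net.bh.t();
  mat probs = softmax_rows(logits);

  double loss = 0.0;
  for (int i = 0; i < n; ++i) {
    if (y(i) < 0 || y(i) >= ncls) Rcpp::stop("label out of range");
    loss -= std::log(std::max(probs(i, y(i)), 1e-12));
  }
  loss /= n;

  mat dlogits = probs;
  for (int i = 0; i < n; ++i) dlogits(i, y(i)) -= 1.0;
  dlogits /= n;

  mat dWh = dlogits.t() * F;
  vec dbh = sum(dlogits, 0).t();
  mat dF = dlogits * net.Wh;

  // optional prototype-alignment penalty: w * mean_i ||F_i - P[y_i]||^2
  if (proto_w > 0.0 && proto.isNotNull()) {
    Rcpp::NumericMatrix Pm(proto);
    if (Pm.nrow() != ncls || Pm.ncol() != net.feat)
      Rcpp::stop("prototype matrix must be num_classes x feature_width");
    vec mask(ncls, fill::ones);
    if (proto_mask.isNotNull()) {
      Rcpp::NumericVector mv(proto_mask);
      if ((int)mv.size() != ncls) Rcpp::stop("proto_mask length mismatch");
      mask = vec(mv.begin(), ncls, true);
    }
    mat P(Pm.begin(), ncls, net.feat, true);
    for (int i = 0; i < n; ++i) {
      if (mask(y(i)) <= 0.0) continue;
      rowvec diff = F.row(i) - P.row(y(i));
      loss += proto_w * dot(diff, diff) / n;
      dF.row(i) += proto_w * 2.0 * diff / n;
    }
  }

  // GAP backward: spread each feature gradient uniformly over its cell
  const size_t cell = (size_t)L3.hp * L3.wp;
  mat dP3((size_t)cell * n, net.feat);
  for (int c = 0; c < net.feat; ++c) {
    double* dst = dP3.colptr(c);
    for (int img = 0; img < n; ++img) {
      const double g = dF(img, c) / cell;
      double* blk = dst + (size_t)img * cell;
      for (size_t p = 0; p < cell; ++p) blk[p] = g;
    }
  }

  mat dW3, dW2, dW1; vec db3, db2, db1;
  mat d2 = conv_backward(dP3, net.c3, n, L3, dW3, db3);
  mat d1 = conv_backward(d2, net.c2, n, L2, dW2, db2);
  conv_backward(d1, net.c1, n, L1, dW1, db1);

  auto pack = [](const mat& W, const vec& b) {
    Rcpp::NumericVector out(W.n_elem + b.n_elem);
    std::copy(W.begin(), W.end(), out.begin());
    std::copy(b.begin(), b.end(), out.begin() + W.n_elem);
    return out;
  };
  Rcpp::NumericVector ghead(net.Wh.n_elem + net.bh.n_elem);
  std::copy(dWh.begin(), dWh.end(), ghead.begin());
  std::copy(dbh.begin(), dbh.end(), ghead.begin() + dWh.n_elem);

  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("conv1") = pack(dW1, db1),
          Rcpp::Named("conv2") = pack(dW2, db2),
          Rcpp::Named("conv3") = pack(dW3, db3),
          Rcpp::Named("head") = ghead),
      Rcpp::Named("probs") = probs);
}
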