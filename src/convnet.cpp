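// Compact CPU encoder-decoder segmentation network.
//
// Feature maps are arma::cube (H, W, C), column-major; pixel p = i + j*H.
// Conv 3x3 (same padding) weights: mat (9*Cin x Cout) with row index
//   c*9 + (dj+1)*3 + (di+1) for input channel c and offset (di, dj).
// Transpose-conv 2x2 stride 2 weights: mat (Cin x 4*Cout) with column
//   index co*4 + dj*2 + di.
// The weight list layout (shared with the R side) is:
//   for each encoder block: W1, b1, W2, b2
//   bottleneck: W1, b1, W2, b2
//   for each decoder block, deepest first: upW, upb, W1, b1, W2, b2
//   head: W (Cin x 1), b (length 1)

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

static const double BCE_EPS = 1e-7;

static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat K((size_t)H * W, 9 * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& s = x.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (dj + 1) * 3 + (di + 1);
        double* dst = K.colptr(col);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          std::memcpy(dst + i0 + (size_t)j * H,
                      s.colptr(j + dj) + i0 + di,
                      sizeof(double) * (i1 - i0));
        }
      }
    }
  }
  return K;
}

static cube conv3_fwd(const cube& x, const mat& W, const vec& b, mat& K) {
  K = im2col3(x);
  mat o = K * W;  // HW x Cout
  o.each_row() += b.t();
  const int H = x.n_rows, Wd = x.n_cols, Cout = W.n_cols;
  cube out(H, Wd, Cout);
  for (int c = 0; c < Cout; ++c) {
    std::memcpy(out.slice(c).memptr(), o.colptr(c),
                sizeof(double) * (size_t)H * Wd);
  }
  return out;
}

static cube conv3_bwd(const mat& K, const mat& W, const cube& dOut,
                      mat& dW, vec& db) {
  const int H = dOut.n_rows, Wd = dOut.n_cols, Cout = W.n_cols;
  const int Cin = W.n_rows / 9;
  mat dM((size_t)H * Wd, Cout);
  for (int c = 0; c < Cout; ++c) {
    std::memcpy(dM.colptr(c), dOut.slice(c).memptr(),
                sizeof(double) * (size_t)H * Wd);
  }
  dW = K.t() * dM;
  db = sum(dM, 0).t();
  mat dK = dM * W.t();  // HW x 9Cin
  cube dX(H, Wd, Cin, fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    mat& s = dX.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (dj + 1) * 3 + (di + 1);
        const double* g = dK.colptr(col);
        const int j0 = std::max(0, -dj), j1 = std::min(Wd, Wd - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          double* dst = s.colptr(j + dj) + i0 + di;
          const double* gsrc = g + i0 + (size_t)j * H;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += gsrc[i];
        }
      }
    }
  }
  return dX;
}

static cube pool2_fwd(const cube& x, umat& idx) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int H2 = H / 2, W2 = W / 2;
  cube out(H2, W2, C);
  idx.set_size((size_t)H2 * W2, C);
  for (int c = 0; c < C; ++c) {
    const mat& s = x.slice(c);
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        const int i0 = 2 * i, j0 = 2 * j;
        double best = s(i0, j0);
        int bi = i0, bj = j0;
        if (s(i0 + 1, j0) > best) { best = s(i0 + 1, j0); bi = i0 + 1; bj = j0; }
        if (s(i0, j0 + 1) > best) { best = s(i0, j0 + 1); bi = i0; bj = j0 + 1; }
        if (s(i0 + 1, j0 + 1) > best) { best = s(i0 + 1, j0 + 1); bi = i0 + 1; bj = j0 + 1; }
        out(i, j, c) = best;
        idx(i + (size_t)j * H2, c) = bi + (size_t)bj * H;
      }
    }
  }
  return out;
}

static cube pool2_bwd(const cube& dOut, const umat& idx, int H, int W) {
  const int H2 = dOut.n_rows, W2 = dOut.n_cols, C = dOut.n_slices;
  cube dX(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& s = dX.slice(c);
    const mat& d = dOut.slice(c);
    for (int j = 0; j < W2; ++j) {
      for (int i = 0; i < H2; ++i) {
        s(idx(i + (size_t)j * H2, c)) += d(i, j);
      }
    }
  }
  return dX;
}

static cube tconv2_fwd(const cube& x, const mat& W, const vec& b) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols / 4;
  mat inM((size_t)H * Wd, Cin);
  for (int c = 0; c < Cin; ++c) {
    std::memcpy(inM.colptr(c), x.slice(c).memptr(),
                sizeof(double) * (size_t)H * Wd);
  }
  mat oM = inM * W;  // HW x 4Cout
  cube out(2 * H, 2 * Wd, Cout);
  for (int co = 0; co < Cout; ++co) {
    mat& s = out.slice(co);
    const double bb = b(co);
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        const double* o = oM.colptr(co * 4 + dj * 2 + di);
        for (int j = 0; j < Wd; ++j) {
          double* dst = s.colptr(2 * j + dj) + di;
          const double* o2 = o + (size_t)j * H;
          for (int i = 0; i < H; ++i) dst[2 * i] = o2[i] + bb;
        }
      }
    }
  }
  return out;
}

static cube tconv2_bwd(const cube& x, const cube& dOut, const mat& W,
                       mat& dW, vec& db) {
  const int H = x.n_rows, Wd = x.n_cols, Cin = x.n_slices;
  const int Cout = W.n_cols / 4;
  mat inM((size_t)H * Wd, Cin);
  for (int c = 0; c < Cin; ++c) {
    std::memcpy(inM.colptr(c), x.slice(c).memptr(),
                sizeof(double) * (size_t)H * Wd);
  }
  mat G((size_t)H * Wd, 4 * Cout);
  db.zeros(Cout);
  for (int co = 0; co < Cout; ++co) {
    const mat& d = dOut.slice(co);
    db(co) = accu(d);
    for (int dj = 0; dj < 2; ++dj) {
      for (int di = 0; di < 2; ++di) {
        double* g = G.colptr(co * 4 + dj * 2 + di);
        for (int j = 0; j < Wd; ++j) {
          const double* dsrc = d.colptr(2 * j + dj) + di;
          double* g2 = g + (size_t)j * H;
          for (int i = 0; i < H; ++i) g2[i] = dsrc[2 * i];
        }
      }
    }
  }
  dW = inM.t() * G;
  mat dM = G * W.t();  // HW x Cin
  cube dX(H, Wd, Cin);
  for (int c = 0; c < Cin; ++c) {
    std::memcpy(dX.slice(c).memptr(), dM.colptr(c),
                sizeof(double) * (size_t)H * Wd);
  }
  return dX;
}

static void relu_(cube& x) {
  x.for_each([](double& v) { if (v < 0) v = 0; });
}

static void relu_gate(cube& grad, const cube& act) {
  const size_t n = act.n_elem;
  for (size_t k = 0; k < n; ++k) {
    if (act(k) <= 0) grad(k) = 0;
  }
}

struct Net {
  int D;
  ivec ch;
  std::vector<mat> encW1, encW2, upW, decW1, decW2;
  std::vector<vec> encb1, encb2, upb, decb1, decb2;
  mat botW1, botW2, headW;
  vec botb1, botb2;
  double headb;
};

static Net parse_weights(const List& w, const Rcpp::IntegerVector& channels) {
  Net net;
  net.D = channels.size();
  net.ch = Rcpp::as<ivec>(channels);
  int k = 0;
  for (int i = 0; i < net.D; ++i) {
    net.encW1.push_back(Rcpp::as<mat>(w[k++]));
    net.encb1.push_back(Rcpp::as<vec>(w[k++]));
    net.encW2.push_back(Rcpp::as<mat>(w[k++]));
    net.encb2.push_back(Rcpp::as<vec>(w[k++]));
  }
  net.botW1 = Rcpp::as<mat>(w[k++]);
  net.botb1 = Rcpp::as<vec>(w[k++]);
  net.botW2 = Rcpp::as<mat>(w[k++]);
  net.botb2 = Rcpp::as<vec>(w[k++]);
  net.upW.resize(net.D); net.upb.resize(net.D);
  net.decW1.resize(net.D); net.decb1.resize(net.D);
  net.decW2.resize(net.D); net.decb2.resize(net.D);
  for (int i = net.D - 1; i >= 0; --i) {
    net.upW[i] = Rcpp::as<mat>(w[k++]);
    net.upb[i] = Rcpp::as<vec>(w[k++]);
    net.decW1[i] = Rcpp::as<mat>(w[k++]);
    net.decb1[i] = Rcpp::as<vec>(w[k++]);
    net.decW2[i] = Rcpp::as<mat>(w[k++]);
    net.decb2[i] = Rcpp::as<vec>(w[k++]);
  }
  net.headW = Rcpp::as<mat>(w[k++]);
  net.headb = Rcpp::as<vec>(w[k++])(0);
  return net;
}

struct FwdCache {
  std::vector<mat> Kenc1, Kenc2, Kdec1, Kdec2;
  std::vector<cube> Aenc1, Senc, poolOut, upIn, Adec1, Dec;
  std::vector<umat> poolIdx;
  mat Kbot1, Kbot2;
  cube Abot1, Bot;
  mat logits, P;
};

static void forward_img(const Net& net, const cube& x, FwdCache& cc) {
  const int D = net.D;
  cc.Kenc1.resize(D); cc.Kenc2.resize(D); cc.Kdec1.resize(D); cc.Kdec2.resize(D);
  cc.Aenc1.resize(D); cc.Senc.resize(D); cc.poolOut.resize(D);
  cc.upIn.resize(D); cc.Adec1.resize(D); cc.Dec.resize(D);
  cc.poolIdx.resize(D);
  cube cur = x;
  for (int i = 0; i < D; ++i) {
    cube a1 = conv3_fwd(cur, net.encW1[i], net.encb1[i], cc.Kenc1[i]);
    relu_(a1);
    cc.Aenc1[i] = a1;
    cube s = conv3_fwd(a1, net.encW2[i], net.encb2[i], cc.Kenc2[i]);
    relu_(s);
    cc.Senc[i] = s;
    cur = pool2_fwd(s, cc.poolIdx[i]);
    cc.poolOut[i] = cur;
  }
  cube ab = conv3_fwd(cur, net.botW1, net.botb1, cc.Kbot1);
  relu_(ab);
  cc.Abot1 = ab;
  cube bot = conv3_fwd(ab, net.botW2, net.botb2, cc.Kbot2);
  relu_(bot);
  cc.Bot = bot;
  cur = bot;
  for (int i = D - 1; i >= 0; --i) {
    cc.upIn[i] = cur;
    cube up = tconv2_fwd(cur, net.upW[i], net.upb[i]);
    cube cat = join_slices(up, cc.Senc[i]);
    cube a1 = conv3_fwd(cat, net.decW1[i], net.decb1[i], cc.Kdec1[i]);
    relu_(a1);
    cc.Adec1[i] = a1;
    cube d = conv3_fwd(a1, net.decW2[i], net.decb2[i], cc.Kdec2[i]);
    relu_(d);
    cc.Dec[i] = d;
    cur = d;
  }
  const int H = x.n_rows, W = x.n_cols;
  mat logits(H, W, fill::value(net.headb));
  for (int c = 0; c < (int)net.ch(0); ++c) {
    logits += net.headW(c, 0) * cc.Dec[0].slice(c);
  }
  cc.logits = logits;
  cc.P = 1.0 / (1.0 + exp(-logits));
}

// Backward from dLogit; adds raw (unnormalized) parameter gradients into
// `acc`, which is laid out exactly like the weight list.
static void backward_img(const Net& net, const cube& x, const FwdCache& cc,
                         const mat& dLogit, std::vector<mat>& accW,
                         std::vector<vec>& accB) {
  const int D = net.D;
  const int ch0 = net.ch(0);
  // index helpers into the flat weight layout
  auto encWi = [&](int i, int which) { return 2 * i + which; };        // W slots
  // weight-slot numbering (separate W and b accumulators, same order):
  //   W slots: enc(2 per block) | bot(2) | dec deepest-first (3 per) | head
  const int botW0 = 2 * D;
  auto decWslot = [&](int i, int which) { return 2 * D + 2 + 3 * (D - 1 - i) + which; };
  const int headWslot = 2 * D + 2 + 3 * D;

  cube dCur(dLogit.n_rows, dLogit.n_cols, ch0);
  for (int c = 0; c < ch0; ++c) {
    dCur.slice(c) = dLogit * net.headW(c, 0);
    accW[headWslot](c, 0) += accu(dLogit % cc.Dec[0].slice(c));
  }
  accB[headWslot](0) += accu(dLogit);

  std::vector<cube> dSkip(D);
  for (int i = 0; i < D; ++i) {
    relu_gate(dCur, cc.Dec[i]);
    mat dW2; vec db2;
    cube dA1 = conv3_bwd(cc.Kdec2[i], net.decW2[i], dCur, dW2, db2);
    accW[decWslot(i, 2)] += dW2; accB[decWslot(i, 2)] += db2;
    relu_gate(dA1, cc.Adec1[i]);
    mat dW1; vec db1;
    cube dCat = conv3_bwd(cc.Kdec1[i], net.decW1[i], dA1, dW1, db1);
    accW[decWslot(i, 1)] += dW1; accB[decWslot(i, 1)] += db1;
    const int chi = net.ch(i);
    cube dUp = dCat.slices(0, chi - 1);
    dSkip[i] = dCat.slices(chi, 2 * chi - 1);
    mat dUw; vec dUb;
    dCur = tconv2_bwd(cc.upIn[i], dUp, net.upW[i], dUw, dUb);
    accW[decWslot(i, 0)] += dUw; accB[decWslot(i, 0)] += dUb;
  }
  // dCur now holds the gradient at the bottleneck output
  relu_gate(dCur, cc.Bot);
  mat dWb2; vec dbb2;
  cube dAb = conv3_bwd(cc.Kbot2, net.botW2, dCur, dWb2, dbb2);
  accW[botW0 + 1] += dWb2; accB[botW0 + 1] += dbb2;
  relu_gate(dAb, cc.Abot1);
  mat dWb1; vec dbb1;
  cube dPool = conv3_bwd(cc.Kbot1, net.botW1, dAb, dWb1, dbb1);
  accW[botW0] += dWb1; accB[botW0] += dbb1;

  for (int i = D - 1; i >= 0; --i) {
    cube dS = pool2_bwd(dPool, cc.poolIdx[i],
                        cc.Senc[i].n_rows, cc.Senc[i].n_cols);
    dS += dSkip[i];
    relu_gate(dS, cc.Senc[i]);
    mat dW2; vec db2;
    cube dA1 = conv3_bwd(cc.Kenc2[i], net.encW2[i], dS, dW2, db2);
    accW[encWi(i, 1)] += dW2; accB[encWi(i, 1)] += db2;
    relu_gate(dA1, cc.Aenc1[i]);
    mat dW1; vec db1;
    dPool = conv3_bwd(cc.Kenc1[i], net.encW1[i], dA1, dW1, db1);
    accW[encWi(i, 0)] += dW1; accB[encWi(i, 0)] += db1;
  }
}

static void init_accumulators(const Net& net, std::vector<mat>& accW,
                              std::vector<vec>& accB) {
  const int D = net.D;
  accW.clear(); accB.clear();
  for (int i = 0; i < D; ++i) {
    accW.push_back(zeros<mat>(size(net.encW1[i])));
    accW.push_back(zeros<mat>(size(net.encW2[i])));
    accB.push_back(zeros<vec>(net.encb1[i].n_elem));
    accB.push_back(zeros<vec>(net.encb2[i].n_elem));
  }
  accW.push_back(zeros<mat>(size(net.botW1)));
  accW.push_back(zeros<mat>(size(net.botW2)));
  accB.push_back(zeros<vec>(net.botb1.n_elem));
  accB.push_back(zeros<vec>(net.botb2.n_elem));
  for (int i = D - 1; i >= 0; --i) {
    accW.push_back(zeros<mat>(size(net.upW[i])));
    accW.push_back(zeros<mat>(size(net.decW1[i])));
    accW.push_back(zeros<mat>(size(net.decW2[i])));
    accB.push_back(zeros<vec>(net.upb[i].n_elem));
    accB.push_back(zeros<vec>(net.decb1[i].n_elem));
    accB.push_back(zeros<vec>(net.decb2[i].n_elem));
  }
  accW.push_back(zeros<mat>(size(net.headW)));
  accB.push_back(zeros<vec>(1));
}

// Re-interleave separate W/b accumulators back into the flat list layout.
static List flatten_grads(const Net& net, const std::vector<mat>& accW,
                          const std::vector<vec>& accB) {
  const int D = net.D;
  List out(10 * D + 6);
  int k = 0, wi = 0, bi = 0;
  for (int i = 0; i < D; ++i) {
    out[k++] = accW[wi++]; out[k++] = accB[bi++];
    out[k++] = accW[wi++]; out[k++] = accB[bi++];
  }
  out[k++] = accW[wi++]; out[k++] = accB[bi++];
  out[k++] = accW[wi++]; out[k++] = accB[bi++];
  for (int i = D - 1; i >= 0; --i) {
    out[k++] = accW[wi++]; out[k++] = accB[bi++];
    out[k++] = accW[wi++]; out[k++] = accB[bi++];
    out[k++] = accW[wi++]; out[k++] = accB[bi++];
  }
  out[k++] = accW[wi++]; out[k++] = accB[bi++];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_unet_forward(List weights, NumericVector x,
                               Rcpp::IntegerVector channels) {
  Net net = parse_weights(weights, channels);
  cube xc = Rcpp::as<cube>(x);
  FwdCache cc;
  forward_img(net, xc, cc);
  return Rcpp::wrap(cc.P);
}

// Batch masked-BCE loss and parameter gradients.
// xs: list of HxWx3 arrays; ys, ms: lists of HxW matrices.
// Loss = sum_i sum(M_i * BCE(Y_i, clamp(P_i))) / sum_i sum(M_i);
// gradient wrt logits is M * (P - Y) / sum(M) (exact for unclamped BCE).
// [[Rcpp::export]]
List cpp_unet_batch_grad(List weights, List xs, List ys, List ms,
                         Rcpp::IntegerVector channels) {
  Net net = parse_weights(weights, channels);
  std::vector<mat> accW;
  std::vector<vec> accB;
  init_accumulators(net, accW, accB);
  double loss_num = 0, sumM = 0;
  const int n = xs.size();
  for (int b = 0; b < n; ++b) {
    cube xc = Rcpp::as<cube>(xs[b]);
    mat Y = Rcpp::as<mat>(ys[b]);
    mat M = Rcpp::as<mat>(ms[b]);
    FwdCache cc;
    forward_img(net, xc, cc);
    mat pc = clamp(cc.P, BCE_EPS, 1 - BCE_EPS);
    loss_num += accu(M % (-(Y % log(pc) + (1 - Y) % log(1 - pc))));
    sumM += accu(M);
    mat dLogit = M % (cc.P - Y);
    backward_img(net, xc, cc, dLogit, accW, accB);
  }
  if (sumM <= 0) Rcpp::stop("sum of loss-mask weights is zero");
  for (auto& g : accW) g /= sumM;
  for (auto& g : accB) g /= sumM;
  return List::create(Rcpp::Named("loss") = loss_num / sumM,
                      Rcpp::Named("grads") = flatten_grads(net, accW, accB),
                      Rcpp::Named("sum_m") = sumM);
}
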