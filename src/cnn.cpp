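// Minimal CPU CNN engine used by the localization and segmentation models.
// Tensors are arma::cube (H x W x C); networks are flat, topologically
// ordered graphs of primitive ops built on the R side.  Supported ops:
//   input, conv (k in {1,3}, stride 1, same padding), relu, maxpool (2x2),
//   upsample (2x2 nearest), concat (channel-wise), add.
// Training: mini-batch Adam on either sigmoid+MSE (heatmap regression) or
// softmax cross-entropy + soft-Dice (multi-class segmentation).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uword;

struct Node {
  int op;                 // 0 input, 1 conv, 2 relu, 3 maxpool, 4 upsample, 5 concat, 6 add
  std::vector<int> in;    // 0-based indices of input nodes
  int w;                  // 0-based weight index for conv, -1 otherwise
  int k;                  // conv kernel size
};

static int op_code(const std::string& s) {
  if (s == "input") return 0;
  if (s == "conv") return 1;
  if (s == "relu") return 2;
  if (s == "maxpool") return 3;
  if (s == "upsample") return 4;
  if (s == "concat") return 5;
  if (s == "add") return 6;
  stop("unknown op: " + s);
  return -1;
}

static std::vector<Node> parse_nodes(const List& nodes) {
  std::vector<Node> out(nodes.size());
  for (int i = 0; i < nodes.size(); ++i) {
    List nd = nodes[i];
    Node n;
    n.op = op_code(as<std::string>(nd["op"]));
    IntegerVector iv = nd["in"];
    for (int j = 0; j < iv.size(); ++j) n.in.push_back(iv[j] - 1);
    n.w = as<int>(nd["w"]) - 1;
    n.k = as<int>(nd["k"]);
    out[i] = n;
  }
  return out;
}

// im2col for same-padded k x k convolution; columns indexed by pixel (i + j*H).
static mat im2col(const cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
  mat out(k * k * C, (size_t)H * W, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        const int r = c * k * k + (dj + p) * k + (di + p);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i)
            out(r, (size_t)i + (size_t)j * H) = x(i + di, js, c);
        }
      }
    }
  }
  return out;
}

static cube col2im(const mat& cols, int H, int W, int C, int k) {
  const int p = (k - 1) / 2;
  cube out(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        const int r = c * k * k + (dj + p) * k + (di + p);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
          for (int i = i0; i < i1; ++i)
            out(i + di, js, c) += cols(r, (size_t)i + (size_t)j * H);
        }
      }
    }
  }
  return out;
}

static cube conv_fwd(const cube& x, const mat& W, const vec& b, int k, mat& cols_cache) {
  const int H = x.n_rows, Wd = x.n_cols;
  cols_cache = im2col(x, k);
  mat y = W * cols_cache;            // Cout x HW
  y.each_col() += b;
  cube out(H, Wd, W.n_rows);
  for (uword c = 0; c < W.n_rows; ++c)
    out.slice(c) = arma::reshape(y.row(c), H, Wd);
  return out;
}

static cube conv_bwd(const cube& dy, const mat& W, int k, const mat& cols,
                     int Hin, int Win, int Cin, mat& dW, vec& db) {
  const int H = dy.n_rows, Wd = dy.n_cols, Cout = dy.n_slices;
  mat dymat(Cout, (size_t)H * Wd);
  for (int c = 0; c < Cout; ++c)
    dymat.row(c) = arma::vectorise(dy.slice(c)).t();
  dW = dymat * cols.t();
  db = arma::sum(dymat, 1);
  mat dcols = W.t() * dymat;
  return col2im(dcols, Hin, Win, Cin, k);
}

struct Cache {
  std::vector<cube> out;        // node outputs
  std::vector<mat> cols;        // im2col caches for conv nodes
  std::vector<arma::ucube> argm; // maxpool argmax offsets (0..3)
};

static void forward(const std::vector<Node>& nds, const List& weights,
                    const cube& x, Cache& cc) {
  const int N = nds.size();
  cc.out.assign(N, cube());
  cc.cols.assign(N, mat());
  cc.argm.assign(N, arma::ucube());
  for (int i = 0; i < N; ++i) {
    const Node& n = nds[i];
    switch (n.op) {
      case 0: cc.out[i] = x; break;
      case 1: {
        List wl = weights[n.w];
        mat W = wl["W"]; vec b = wl["b"];
        cc.out[i] = conv_fwd(cc.out[n.in[0]], W, b, n.k, cc.cols[i]);
        break;
      }
      case 2: cc.out[i] = arma::clamp(cc.out[n.in[0]], 0.0, arma::datum::inf); break;
      case 3: {
        const cube& a = cc.out[n.in[0]];
        const int H = a.n_rows / 2, W = a.n_cols / 2, C = a.n_slices;
        cube o(H, W, C);
        arma::ucube am(H, W, C);
        for (int c = 0; c < C; ++c)
          for (int j = 0; j < W; ++j)
            for (int i2 = 0; i2 < H; ++i2) {
              double v00 = a(2 * i2, 2 * j, c), v10 = a(2 * i2 + 1, 2 * j, c);
              double v01 = a(2 * i2, 2 * j + 1, c), v11 = a(2 * i2 + 1, 2 * j + 1, c);
              double m = v00; unsigned k2 = 0;
              if (v10 > m) { m = v10; k2 = 1; }
              if (v01 > m) { m = v01; k2 = 2; }
              if (v11 > m) { m = v11; k2 = 3; }
              o(i2, j, c) = m; am(i2, j, c) = k2;
            }
        cc.out[i] = o; cc.argm[i] = am;
        break;
      }
      case 4: {
        const cube& a = cc.out[n.in[0]];
        const int H = a.n_rows, W = a.n_cols, C = a.n_slices;
        cube o(2 * H, 2 * W, C);
        for (int c = 0; c < C; ++c)
          for (int j = 0; j < W; ++j)
            for (int i2 = 0; i2 < H; ++i2) {
              const double v = a(i2, j, c);
              o(2 * i2, 2 * j, c) = v; o(2 * i2 + 1, 2 * j, c) = v;
              o(2 * i2, 2 * j + 1, c) = v; o(2 * i2 + 1, 2 * j + 1, c) = v;
            }
        cc.out[i] = o;
        break;
      }
      case 5: cc.out[i] = arma::join_slices(cc.out[n.in[0]], cc.out[n.in[1]]); break;
      case 6: cc.out[i] = cc.out[n.in[0]] + cc.out[n.in[1]]; break;
    }
  }
}

// Backward pass from dlogits at the last node; accumulates conv grads into gW/gb.
static void backward(const std::vector<Node>& nds, const List& weights,
                     Cache& cc, const cube& dlogits,
                     std::vector<mat>& gW, std::vector<vec>& gb) {
  const int N = nds.size();
  std::vector<cube> grad(N);
  std::vector<bool> has(N, false);
  grad[N - 1] = dlogits; has[N - 1] = true;
  for (int i = N - 1; i >= 0; --i) {
    if (!has[i]) continue;
    const Node& n = nds[i];
    const cube& g = grad[i];
    auto acc = [&](int tgt, const cube& d) {
      if (!has[tgt]) { grad[tgt] = d; has[tgt] = true; }
      else grad[tgt] += d;
    };
    switch (n.op) {
      case 0: break;
      case 1: {
        List wl = weights[n.w];
        mat W = wl["W"];
        const cube& xin = cc.out[n.in[0]];
        mat dW; vec db;
        cube dx = conv_bwd(g, W, n.k, cc.cols[i], xin.n_rows, xin.n_cols, xin.n_slices, dW, db);
        gW[n.w] += dW; gb[n.w] += db;
        acc(n.in[0], dx);
        break;
      }
      case 2: {
        cube d = g;
        const cube& y = cc.out[i];
        d.elem(arma::find(y <= 0)).zeros();
        acc(n.in[0], d);
        break;
      }
      case 3: {
        const cube& a = cc.out[n.in[0]];
        cube d(a.n_rows, a.n_cols, a.n_slices, arma::fill::zeros);
        const arma::ucube& am = cc.argm[i];
        const int H = g.n_rows, W = g.n_cols, C = g.n_slices;
        for (int c = 0; c < C; ++c)
          for (int j = 0; j < W; ++j)
            for (int i2 = 0; i2 < H; ++i2) {
              const unsigned k2 = am(i2, j, c);
              d(2 * i2 + (k2 & 1u), 2 * j + (k2 >> 1), c) = g(i2, j, c);
            }
        acc(n.in[0], d);
        break;
      }
      case 4: {
        const int H = g.n_rows / 2, W = g.n_cols / 2, C = g.n_slices;
        cube d(H, W, C);
        for (int c = 0; c < C; ++c)
          for (int j = 0; j < W; ++j)
            for (int i2 = 0; i2 < H; ++i2)
              d(i2, j, c) = g(2 * i2, 2 * j, c) + g(2 * i2 + 1, 2 * j, c) +
                            g(2 * i2, 2 * j + 1, c) + g(2 * i2 + 1, 2 * j + 1, c);
        acc(n.in[0], d);
        break;
      }
      case 5: {
        const int c1 = cc.out[n.in[0]].n_slices;
        acc(n.in[0], g.slices(0, c1 - 1));
        acc(n.in[1], g.slices(c1, g.n_slices - 1));
        break;
      }
      case 6: {
        acc(n.in[0], g);
        acc(n.in[1], g);
        break;
      }
    }
    if (i < N - 1) { grad[i].reset(); }  // free as we go
  }
}

static cube apply_sigmoid(const cube& z) { return 1.0 / (1.0 + arma::exp(-z)); }

static cube apply_softmax(const cube& z) {
  cube p = z;
  const int H = z.n_rows, W = z.n_cols, C = z.n_slices;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double m = -arma::datum::inf;
      for (int c = 0; c < C; ++c) m = std::max(m, z(i, j, c));
      double s = 0;
      for (int c = 0; c < C; ++c) { p(i, j, c) = std::exp(z(i, j, c) - m); s += p(i, j, c); }
      for (int c = 0; c < C; ++c) p(i, j, c) /= s;
    }
  return p;
}

// loss + gradient w.r.t. logits
static double loss_grad(const cube& logits, const cube& t, const std::string& loss,
                        double dice_weight, cube& dz) {
  const double Npix = (double)logits.n_rows * logits.n_cols;
  if (loss == "mse") {
    cube p = apply_sigmoid(logits);
    cube e = p - t;
    const double L = arma::accu(arma::square(e)) / (Npix * logits.n_slices);
    dz = (2.0 / (Npix * logits.n_slices)) * e % p % (1.0 - p);
    return L;
  }
  if (loss == "ce_dice") {
    cube p = apply_softmax(logits);
    const int C = p.n_slices;
    const double eps = 1e-7;
    // cross-entropy
    double L = -arma::accu(t % arma::log(p + eps)) / Npix;
    cube g = -(t / (p + eps)) / Npix;   // dL/dp, CE part
    // soft Dice per class
    if (dice_weight > 0) {
      for (int c = 0; c < C; ++c) {
        const double A = arma::accu(p.slice(c) % t.slice(c));
        const double B = arma::accu(p.slice(c)) + arma::accu(t.slice(c));
        const double d = (2 * A + eps) / (B + eps);
        L += dice_weight * (1.0 - d) / C;
        g.slice(c) += dice_weight / C *
          (-(2 * t.slice(c) * (B + eps) - (2 * A + eps)) / ((B + eps) * (B + eps)));
      }
    }
    // softmax Jacobian: dz_i = p_i (g_i - sum_j g_j p_j)
    mat gs(p.n_rows, p.n_cols, arma::fill::zeros);
    for (int c = 0; c < C; ++c) gs += g.slice(c) % p.slice(c);
    dz = p;
    for (int c = 0; c < C; ++c) dz.slice(c) = p.slice(c) % (g.slice(c) - gs);
    return L;
  }
  stop("unknown loss: " + loss);
  return 0;
}

// [[Rcpp::export]]
arma::cube cnn_forward_cpp(List nodes, List weights, arma::cube x, std::string activation) {
  std::vector<Node> nds = parse_nodes(nodes);
  Cache cc;
  forward(nds, weights, x, cc);
  cube z = cc.out.back();
  if (activation == "sigmoid") return apply_sigmoid(z);
  if (activation == "softmax") return apply_softmax(z);
  return z;
}

// [[Rcpp::export]]
double cnn_loss_cpp(List nodes, List weights, List X, List Y,
                    std::string loss, double dice_weight) {
  std::vector<Node> nds = parse_nodes(nodes);
  double tot = 0;
  Cache cc;
  cube dz;
  for (int s = 0; s < X.size(); ++s) {
    cube x = X[s], t = Y[s];
    forward(nds, weights, x, cc);
    tot += loss_grad(cc.out.back(), t, loss, dice_weight, dz);
  }
  return tot / X.size();
}

// Loss and per-weight gradients for one sample (used by gradient tests).
// [[Rcpp::export]]
List cnn_grad_cpp(List nodes, List weights, arma::cube x, arma::cube t,
                  std::string loss, double dice_weight) {
  std::vector<Node> nds = parse_nodes(nodes);
  const int nw = weights.size();
  std::vector<mat> gW(nw);
  std::vector<vec> gb(nw);
  for (int w = 0; w < nw; ++w) {
    List wl = weights[w];
    mat W = wl["W"]; vec b = wl["b"];
    gW[w].zeros(W.n_rows, W.n_cols);
    gb[w].zeros(b.n_elem);
  }
  Cache cc;
  cube dz;
  forward(nds, weights, x, cc);
  double L = loss_grad(cc.out.back(), t, loss, dice_weight, dz);
  backward(nds, weights, cc, dz, gW, gb);
  List og(nw), ob(nw);
  for (int w = 0; w < nw; ++w) { og[w] = gW[w]; ob[w] = gb[w]; }
  return List::create(_["loss"] = L, _["gW"] = og, _["gb"] = ob);
}

// Mini-batch Adam training.  `order` is an epochs x n matrix of 1-based sample
// indices (one shuffled permutation per epoch, generated under R's RNG so the
// whole run is reproducible).  Returns updated weights, Adam state and the
// per-epoch mean training loss.
// [[Rcpp::export]]
List cnn_train_cpp(List nodes, List weights, List X, List Y,
                   std::string loss, double dice_weight,
                   int batch, double lr, IntegerMatrix order,
                   Nullable<List> adam_state) {
  std::vector<Node> nds = parse_nodes(nodes);
  const int nw = weights.size(), n = X.size(), epochs = order.nrow();

  std::vector<mat> Wm(nw), mW(nw), vW(nw);
  std::vector<vec> bm(nw), mb(nw), vb(nw);
  double t_adam = 0;
  for (int w = 0; w < nw; ++w) {
    List wl = weights[w];
    Wm[w] = as<mat>(wl["W"]); bm[w] = as<vec>(wl["b"]);
    mW[w].zeros(Wm[w].n_rows, Wm[w].n_cols); vW[w].zeros(Wm[w].n_rows, Wm[w].n_cols);
    mb[w].zeros(bm[w].n_elem); vb[w].zeros(bm[w].n_elem);
  }
  if (adam_state.isNotNull()) {
    List st(adam_state);
    List sm = st["mW"], sv = st["vW"], smb = st["mb"], svb = st["vb"];
    t_adam = as<double>(st["t"]);
    for (int w = 0; w < nw; ++w) {
      mW[w] = as<mat>(sm[w]); vW[w] = as<mat>(sv[w]);
      mb[w] = as<vec>(smb[w]); vb[w] = as<vec>(svb[w]);
    }
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  // live weights list handed to forward/backward
  List wlive(nw);
  auto sync = [&]() {
    for (int w = 0; w < nw; ++w)
      wlive[w] = List::create(_["W"] = Wm[w], _["b"] = bm[w]);
  };
  sync();

  std::vector<mat> gW(nw); std::vector<vec> gb(nw);
  NumericVector hist(epochs);
  Cache cc; cube dz;

  for (int e = 0; e < epochs; ++e) {
    double etot = 0;
    int done = 0;
    while (done < n) {
      const int bs = std::min(batch, n - done);
      for (int w = 0; w < nw; ++w) {
        gW[w].zeros(Wm[w].n_rows, Wm[w].n_cols);
        gb[w].zeros(bm[w].n_elem);
      }
      for (int s = 0; s < bs; ++s) {
        const int idx = order(e, done + s) - 1;
        cube x = X[idx], t = Y[idx];
        forward(nds, wlive, x, cc);
        etot += loss_grad(cc.out.back(), t, loss, dice_weight, dz);
        backward(nds, wlive, cc, dz, gW, gb);
      }
      t_adam += 1;
      const double c1 = 1 - std::pow(b1, t_adam), c2 = 1 - std::pow(b2, t_adam);
      for (int w = 0; w < nw; ++w) {
        gW[w] /= bs; gb[w] /= bs;
        mW[w] = b1 * mW[w] + (1 - b1) * gW[w];
        vW[w] = b2 * vW[w] + (1 - b2) * arma::square(gW[w]);
        Wm[w] -= lr * (mW[w] / c1) / (arma::sqrt(vW[w] / c2) + eps);
        mb[w] = b1 * mb[w] + (1 - b1) * gb[w];
        vb[w] = b2 * vb[w] + (1 - b2) * arma::square(gb[w]);
        bm[w] -= lr * (mb[w] / c1) / (arma::sqrt(vb[w] / c2) + eps);
      }
      sync();
      done += bs;
      Rcpp::checkUserInterrupt();
    }
    hist[e] = etot / n;
  }

  List am(nw), av(nw), amb(nw), avb(nw);
  for (int w = 0; w < nw; ++w) {
    am[w] = mW[w]; av[w] = vW[w]; amb[w] = mb[w]; avb[w] = vb[w];
  }
  return List::create(
    _["weights"] = wlive,
    _["adam"] = List::create(_["mW"] = am, _["vW"] = av, _["mb"] = amb,
                             _["vb"] = avb, _["t"] = t_adam),
    _["loss"] = hist);
}

// Trilinear resampling of a 3D volume onto a new grid.  Output voxel centre
// (i,j,k) (0-based) maps to input continuous index (i*sx, j*sy, k*sz).
// [[Rcpp::export]]
arma::cube resample_trilinear_cpp(arma::cube v, int nx, int ny, int nz,
                                  double sx, double sy, double sz) {
  cube out(nx, ny, nz);
  const int X = v.n_rows, Y = v.n_cols, Z = v.n_slices;
  for (int k = 0; k < nz; ++k) {
    double fz = k * sz;
    int z0 = std::min((int)std::floor(fz), Z - 1), z1 = std::min(z0 + 1, Z - 1);
    double wz = fz - z0;
    for (int j = 0; j < ny; ++j) {
      double fy = j * sy;
      int y0 = std::min((int)std::floor(fy), Y - 1), y1 = std::min(y0 + 1, Y - 1);
      double wy = fy - y0;
      for (int i = 0; i < nx; ++i) {
        double fx = i * sx;
        int x0 = std::min((int)std::floor(fx), X - 1), x1 = std::min(x0 + 1, X - 1);
        double wx = fx - x0;
        double c00 = v(x0, y0, z0) * (1 - wx) + v(x1, y0, z0) * wx;
        double c10 = v(x0, y1, z0) * (1 - wx) + v(x1, y1, z0) * wx;
        double c01 = v(x0, y0, z1) * (1 - wx) + v(x1, y0, z1) * wx;
        double c11 = v(x0, y1, z1) * (1 - wx) + v(x1, y1, z1) * wx;
        double c0 = c00 * (1 - wy) + c10 * wy;
        double c1 = c01 * (1 - wy) + c11 * wy;
        out(i, j, k) = c0 * (1 - wz) + c1 * wz;
      }
    }
  }
  return out;
}
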