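// Minimal CNN backend for the masked-nucleus UNet: stride-2 convolutions and
// fractional-stride (transposed) convolutions via im2col + GEMM, ReLU,
// softmax with class- and spatially-weighted per-pixel cross-entropy, and
// full backpropagation. Layer shapes are derived from the weight matrices:
// a conv weight is (out_ch x k*k*in_ch), a tconv weight (in_ch x k*k*out_ch).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int K = 5, S = 2, P = 2;   // kernel, stride, padding everywhere

// im2col: x (H x W x C) -> (K*K*C) x (Ho*Wo), row = c*K*K + kv*K + ku,
// column = ho + Ho*wo. Ho = (H + 2P - K)/S + 1.
static arma::mat im2col(const arma::cube& x) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int Ho = (H + 2 * P - K) / S + 1, Wo = (W + 2 * P - K) / S + 1;
  arma::mat cols(K * K * C, Ho * Wo, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kv = 0; kv < K; ++kv)
      for (int ku = 0; ku < K; ++ku) {
        int row = c * K * K + kv * K + ku;
        for (int wo = 0; wo < Wo; ++wo) {
          int wsrc = wo * S - P + kv;
          if (wsrc < 0 || wsrc >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hsrc = ho * S - P + ku;
            if (hsrc < 0 || hsrc >= H) continue;
            cols(row, ho + Ho * wo) = x(hsrc, wsrc, c);
          }
        }
      }
  return cols;
}

// col2im (scatter-add adjoint of im2col): cols (K*K*C) x (Ho*Wo) into
// out (H x W x C), where Ho/Wo is the small grid.
static void col2im_add(const arma::mat& cols, arma::cube& out, int Ho, int Wo) {
  int H = out.n_rows, W = out.n_cols, C = out.n_slices;
  for (int c = 0; c < C; ++c)
    for (int kv = 0; kv < K; ++kv)
      for (int ku = 0; ku < K; ++ku) {
        int row = c * K * K + kv * K + ku;
        for (int wo = 0; wo < Wo; ++wo) {
          int wdst = wo * S - P + kv;
          if (wdst < 0 || wdst >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hdst = ho * S - P + ku;
            if (hdst < 0 || hdst >= H) continue;
            out(hdst, wdst, c) += cols(row, ho + Ho * wo);
          }
        }
      }
}

static arma::mat cube_to_mat(const arma::cube& x) {   // C x (H*W)
  int HW = x.n_rows * x.n_cols, C = x.n_slices;
  arma::mat m(C, HW);
  for (int c = 0; c < C; ++c)
    m.row(c) = arma::vectorise(x.slice(c)).t();
  return m;
}

static arma::cube mat_to_cube(const arma::mat& m, int H, int W) {
  arma::cube x(H, W, m.n_rows);
  for (unsigned c = 0; c < m.n_rows; ++c)
    x.slice(c) = arma::reshape(m.row(c).t(), H, W);
  return x;
}

// conv forward: y = W * im2col(x) + b; y (Ho x Wo x O)
static arma::cube conv_fwd(const arma::cube& x, const arma::mat& W,
                           const arma::vec& b) {
  int Ho = (x.n_rows + 2 * P - K) / S + 1;
  int Wo = (x.n_cols + 2 * P - K) / S + 1;
  arma::mat y = W * im2col(x);
  y.each_col() += b;
  return mat_to_cube(y, Ho, Wo);
}

// transposed conv forward: x (h x w x Ci), W (Ci x K*K*Co) -> y (2h x 2w x Co)
static arma::cube tconv_fwd(const arma::cube& x, const arma::mat& W,
                            const arma::vec& b) {
  int h = x.n_rows, w = x.n_cols, Co = W.n_cols / (K * K);
  arma::mat cols = W.t() * cube_to_mat(x);       // (K*K*Co) x (h*w)
  arma::cube y(2 * h, 2 * w, Co, arma::fill::zeros);
  col2im_add(cols, y, h, w);
  for (int c = 0; c < Co; ++c) y.slice(c) += b(c);
  return y;
}

static arma::cube relu(const arma::cube& x) { return arma::clamp(x, 0.0, arma::datum::inf); }

struct FwdState {
  std::vector<arma::cube> a_down;   // a_down[0] = input, a_down[i] post-ReLU
  std::vector<arma::cube> z_down;
  std::vector<arma::cube> t_up, u_in;  // pre-ReLU tconv outputs; tconv inputs
  arma::cube u_final;               // input to 1x1 conv
  arma::mat logits;                 // n_classes x HW
  arma::mat probs;
};

static FwdState unet_forward_state(const List& params, const arma::cube& x) {
  List dW = params["down_W"], db = params["down_b"];
  List uW = params["up_W"], ub = params["up_b"];
  arma::mat fW = params["final_W"];
  arma::vec fb = params["final_b"];
  int depth = dW.size();
  FwdState st;
  st.a_down.push_back(x);
  for (int i = 0; i < depth; ++i) {
    arma::cube z = conv_fwd(st.a_down.back(), as<arma::mat>(dW[i]),
                            as<arma::vec>(db[i]));
    st.z_down.push_back(z);
    st.a_down.push_back(relu(z));
  }
  arma::cube u = st.a_down.back();
  for (int j = 0; j < depth; ++j) {
    st.u_in.push_back(u);
    arma::cube t = tconv_fwd(u, as<arma::mat>(uW[j]), as<arma::vec>(ub[j]));
    st.t_up.push_back(t);
    arma::cube r = relu(t);
    if (j < depth - 1) {
      const arma::cube& skip = st.a_down[depth - 1 - j];
      u = arma::join_slices(r, skip);
    } else u = r;
  }
  st.u_final = u;
  arma::mat um = cube_to_mat(u);
  st.logits = fW * um;
  st.logits.each_col() += fb;
  arma::mat z = st.logits;
  z.each_row() -= arma::max(z, 0);
  arma::mat e = arma::exp(z);
  arma::rowvec s = arma::sum(e, 0);
  e.each_row() /= s;
  st.probs = e;
  return st;
}

// [[Rcpp::export]]
arma::cube unet_forward_cpp(List params, arma::cube x) {
  FwdState st = unet_forward_state(params, x);
  return mat_to_cube(st.probs, x.n_rows, x.n_cols);
}

// Weighted softmax cross-entropy loss and full parameter gradient for one
// example. y: H x W binary truth (class 1 = sheath); wmap: H x W spatial
// weights; class_weight multiplies the loss on truth pixels.
// [[Rcpp::export]]
List unet_grad_cpp(List params, arma::cube x, arma::mat y, arma::mat wmap,
                   double class_weight) {
  List dWl = params["down_W"], dbl = params["down_b"];
  List uWl = params["up_W"], ubl = params["up_b"];
  arma::mat fW = params["final_W"];
  int depth = dWl.size();
  FwdState st = unet_forward_state(params, x);
  int HW = x.n_rows * x.n_cols;

  arma::rowvec yv = arma::vectorise(y).t();
  arma::rowvec wv = arma::vectorise(wmap).t();
  arma::rowvec cw = wv % (1.0 + (class_weight - 1.0) * yv);
  arma::rowvec p_true = st.probs.row(0) % (1.0 - yv) + st.probs.row(1) % yv;
  double loss = arma::accu(cw % (-arma::log(arma::clamp(p_true, 1e-12, 1.0)))) / HW;

  // dlogits = cw * (p - onehot) / HW
  arma::mat dlog = st.probs;
  dlog.row(0) -= (1.0 - yv);
  dlog.row(1) -= yv;
  dlog.each_row() %= cw / HW;

  arma::mat um = cube_to_mat(st.u_final);
  arma::mat g_fW = dlog * um.t();
  arma::vec g_fb = arma::sum(dlog, 1);
  arma::mat dum = fW.t() * dlog;
  arma::cube du = mat_to_cube(dum, x.n_rows, x.n_cols);

  List g_uW(depth), g_ub(depth), g_dW(depth), g_db(depth);
  std::vector<arma::cube> da_skip(depth + 1);  // gradients w.r.t. a_down[i]

  for (int j = depth - 1; j >= 0; --j) {
    arma::cube dr;
    if (j < depth - 1) {
      int Co = st.t_up[j].n_slices;
      dr = du.slices(0, Co - 1);
      da_skip[depth - 1 - j] = du.slices(Co, du.n_slices - 1);
    } else dr = du;
    arma::cube dt = dr % arma::conv_to<arma::cube>::from(st.t_up[j] > 0);
    // tconv backward
    const arma::cube& xin = st.u_in[j];
    arma::mat cols_dy = im2col(dt);                       // (K*K*Co) x (h*w)
    arma::mat W = as<arma::mat>(uWl[j]);
    arma::mat dxm = W * cols_dy;                          // Ci x (h*w)
    arma::mat gW = cube_to_mat(xin) * cols_dy.t();        // Ci x K*K*Co
    arma::vec gb(dt.n_slices);
    for (unsigned c = 0; c < dt.n_slices; ++c) gb(c) = arma::accu(dt.slice(c));
    g_uW[j] = gW; g_ub[j] = gb;
    du = mat_to_cube(dxm, xin.n_rows, xin.n_cols);
  }
  // du is now the gradient w.r.t. a_down[depth]
  arma::cube da = du;
  for (int i = depth - 1; i >= 0; --i) {
    if (da_skip[i + 1].n_elem) da += da_skip[i + 1];
    arma::cube dz = da % arma::conv_to<arma::cube>::from(st.z_down[i] > 0);
    const arma::cube& xin = st.a_down[i];
    arma::mat dzm = cube_to_mat(dz);
    arma::mat cols = im2col(xin);
    arma::mat W = as<arma::mat>(dWl[i]);
    g_dW[i] = dzm * cols.t();
    arma::vec gb(dz.n_slices);
    for (unsigned c = 0; c < dz.n_slices; ++c) gb(c) = arma::accu(dz.slice(c));
    g_db[i] = gb;
    arma::mat dcols = W.t() * dzm;
    arma::cube dx(xin.n_rows, xin.n_cols, xin.n_slices, arma::fill::zeros);
    col2im_add(dcols, dx, dz.n_rows, dz.n_cols);
    da = dx;
  }

  return List::create(_["loss"] = loss,
                      _["grads"] = List::create(
                        _["down_W"] = g_dW, _["down_b"] = g_db,
                        _["up_W"] = g_uW, _["up_b"] = g_ub,
                        _["final_W"] = g_fW, _["final_b"] = g_fb));
}

// Chebyshev distance transform: distance from each pixel to the nearest
// non-zero pixel of `truth` (two-pass chamfer; exact for this metric).
// All-zero input yields nrow+ncol everywhere.
// [[Rcpp::export]]
NumericMatrix chebyshev_dt(IntegerMatrix truth) {
  int H = truth.nrow(), W = truth.ncol();
  double big = H + W;
  NumericMatrix d(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      d(r, c) = truth(r, c) ? 0.0 : big;
  auto relaxf = [&](int r, int c, int rr, int cc) {
    if (rr < 0 || rr >= H || cc < 0 || cc >= W) return;
    if (d(rr, cc) + 1.0 < d(r, c)) d(r, c) = d(rr, cc) + 1.0;
  };
  // column-major scans: relax only against already-visited neighbours
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      relaxf(r, c, r - 1, c); relaxf(r, c, r, c - 1);
      relaxf(r, c, r - 1, c - 1); relaxf(r, c, r + 1, c - 1);
    }
  for (int c = W - 1; c >= 0; --c)
    for (int r = H - 1; r >= 0; --r) {
      relaxf(r, c, r + 1, c); relaxf(r, c, r, c + 1);
      relaxf(r, c, r + 1, c + 1); relaxf(r, c, r - 1, c + 1);
    }
  return d;
}
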