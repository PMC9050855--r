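// Dense-block U-Net for voxelwise aliasing classification.
//
// One (frame, direction) volume at a time (batch size 1), channels-last
// feature matrices of shape [n_voxels x channels] with x-fastest linear
// voxel indexing. 3x3x3 convolutions are evaluated as z-slab im2col
// (27 tap-shifted contiguous row copies, zero padding) followed by one
// SGEMM per slab, bounding peak memory for large crops. Pooling is
// in-plane only (2x2x1) so the z extent is
// unconstrained. Backprop and Adam are implemented directly; all
// randomness (He init via Box-Muller, dropout) comes from one seeded
// mt19937 so identical seeds give identical weights and loss trajectories
// on one platform.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <array>
#include <functional>
#include <map>
#include <vector>

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::stop;

namespace {

struct Rng {
  std::mt19937 gen;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint32_t seed) : gen(seed) {}
  double unif() { return (static_cast<double>(gen()) + 0.5) / 4294967296.0; }
  double gauss() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }
};

struct Conv {
  fmat W;      // [taps*cin x cout]
  frowvec b;   // [cout]
  fmat gW, mW, vW;
  frowvec gb, mb, vb;
  int taps = 27, cin = 0, cout = 0;

  void init(int taps_, int cin_, int cout_, Rng& rng, bool zero_weights,
            float b0 = 0.0f, float b1 = 0.0f) {
    taps = taps_; cin = cin_; cout = cout_;
    W.set_size(taps * cin, cout);
    if (zero_weights) {
      W.zeros();
    } else {
      const float sd = std::sqrt(2.0f / static_cast<float>(taps * cin));
      for (uword j = 0; j < W.n_cols; ++j)
        for (uword i = 0; i < W.n_rows; ++i)
          W(i, j) = sd * static_cast<float>(rng.gauss());
    }
    b.set_size(cout); b.zeros();
    if (cout == 2) { b[0] = b0; b[1] = b1; }
    mW.zeros(size(W)); vW.zeros(size(W));
    mb.zeros(1, cout); vb.zeros(1, cout);
  }

  void adam(double lr, long t) {
    const float b1m = 0.9f, b2m = 0.999f, eps = 1e-8f;
    const float corr1 = 1.0f - std::pow(b1m, static_cast<float>(t));
    const float corr2 = 1.0f - std::pow(b2m, static_cast<float>(t));
    mW = b1m * mW + (1.0f - b1m) * gW;
    vW = b2m * vW + (1.0f - b2m) * square(gW);
    W -= static_cast<float>(lr) * (mW / corr1) / (sqrt(vW / corr2) + eps);
    mb = b1m * mb + (1.0f - b1m) * gb;
    vb = b2m * vb + (1.0f - b2m) * square(gb);
    b -= static_cast<float>(lr) * (mb / corr1) / (sqrt(vb / corr2) + eps);
  }
};

// Per-shape tables: level dims and 2x2 in-plane pooling child lists.
struct Plan {
  std::vector<umat> pool;           // per transition: [n_{l+1} x 4]
  std::vector<std::array<int,3>> d; // per level dims
};

typedef std::array<int,3> Dims3;

umat pool_table(int nx, int ny, int nz) {
  const int cx = nx / 2, cy = ny / 2;
  umat tab(static_cast<uword>(cx) * cy * nz, 4);
  uword v = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < cy; ++y)
      for (int x = 0; x < cx; ++x, ++v) {
        const uword base = static_cast<uword>(2 * x) +
          static_cast<uword>(nx) * (2 * y + static_cast<uword>(ny) * z);
        tab(v, 0) = base;
        tab(v, 1) = base + 1;
        tab(v, 2) = base + nx;
        tab(v, 3) = base + nx + 1;
      }
  return tab;
}

// im2col over a z-slab [za, zb) as 27 tap-shifted row-segment copies
// (x-fastest linear layout makes every (y, z) run of the volume a
// contiguous memcpy); one large SGEMM then evaluates the convolution.
// Slabs cap the im2col buffer so large crops never materialize the full
// [n x 27*cin] matrix at once.
void im2col_slab(const fmat& F, int cin, const Dims3& d, int za, int zb,
                 fmat& M) {
  const int nx = d[0], ny = d[1], nz = d[2];
  const uword slab = static_cast<uword>(zb - za) * nx * ny;
  M.zeros(slab, 27u * cin);
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        const int x0 = std::max(0, -dx), len = nx - std::abs(dx);
        const int ylo = std::max(0, -dy), yhi = ny - 1 - std::max(0, dy);
        const int zlo = std::max(za, -dz), zhi = std::min(zb - 1, nz - 1 - dz);
        for (int c = 0; c < cin; ++c) {
          float* dcol = M.colptr(static_cast<uword>(k) * cin + c);
          const float* scol = F.colptr(c);
          for (int z = zlo; z <= zhi; ++z) {
            float* drow = dcol + (static_cast<uword>(z - za) * ny) * nx;
            const float* srow = scol + (static_cast<uword>(z + dz) * ny) * nx;
            for (int y = ylo; y <= yhi; ++y)
              std::memcpy(drow + static_cast<uword>(y) * nx + x0,
                          srow + static_cast<uword>(y + dy) * nx + x0 + dx,
                          sizeof(float) * len);
          }
        }
      }
}

int slab_height(int cin, const Dims3& d) {
  const double cap = 96.0 * (1 << 20);  // bytes for one im2col buffer
  const double per_z = 4.0 * 27 * cin * d[0] * d[1];
  int h = static_cast<int>(cap / per_z);
  return std::max(1, std::min(d[2], h));
}

fmat conv_fwd(const Conv& cv, const fmat& F, const Dims3& d) {
  fmat Y(F.n_rows, cv.cout);
  Y.each_row() = cv.b;
  if (cv.taps == 1) { Y += F * cv.W; return Y; }
  const int h = slab_height(cv.cin, d);
  fmat M;
  for (int za = 0; za < d[2]; za += h) {
    const int zb = std::min(d[2], za + h);
    im2col_slab(F, cv.cin, d, za, zb, M);
    const uword r0 = static_cast<uword>(za) * d[0] * d[1];
    Y.rows(r0, r0 + M.n_rows - 1) += M * cv.W;
  }
  return Y;
}

// Accumulates parameter grads into cv.gW/gb; returns grad wrt the input.
// The im2col buffer is rebuilt per slab instead of cached from the
// forward pass, trading a cheap re-copy for bounded peak memory.
fmat conv_bwd(Conv& cv, const fmat& F, const Dims3& d, const fmat& dY) {
  cv.gb = sum(dY, 0);
  if (cv.taps == 1) {
    cv.gW = F.t() * dY;
    return dY * cv.W.t();
  }
  const int nx = d[0], ny = d[1], nz = d[2];
  cv.gW.zeros(27 * cv.cin, cv.cout);
  fmat dF(F.n_rows, cv.cin, fill::zeros);
  const int h = slab_height(cv.cin, d);
  fmat M;
  for (int za = 0; za < nz; za += h) {
    const int zb = std::min(nz, za + h);
    im2col_slab(F, cv.cin, d, za, zb, M);
    const uword r0 = static_cast<uword>(za) * nx * ny;
    const fmat dYs = dY.rows(r0, r0 + M.n_rows - 1);
    cv.gW += M.t() * dYs;
    const fmat dM = dYs * cv.W.t();
    // scatter: mirror of the im2col copies, accumulating into dF
    int k = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx, ++k) {
          const int x0 = std::max(0, -dx), len = nx - std::abs(dx);
          const int ylo = std::max(0, -dy), yhi = ny - 1 - std::max(0, dy);
          const int zlo = std::max(za, -dz);
          const int zhi = std::min(zb - 1, nz - 1 - dz);
          for (int c = 0; c < cv.cin; ++c) {
            float* dcol = dF.colptr(c);
            const float* mcol = dM.colptr(static_cast<uword>(k) * cv.cin + c);
            for (int z = zlo; z <= zhi; ++z) {
              float* drow = dcol + (static_cast<uword>(z + dz) * ny) * nx;
              const float* mrow = mcol + (static_cast<uword>(z - za) * ny) * nx;
              for (int y = ylo; y <= yhi; ++y) {
                float* dst = drow + static_cast<uword>(y + dy) * nx + x0 + dx;
                const float* src = mrow + static_cast<uword>(y) * nx + x0;
                for (int i = 0; i < len; ++i) dst[i] += src[i];
              }
            }
          }
        }
  }
  return dF;
}

fmat pool_fwd(const fmat& S, const umat& P, umat& arg) {
  const uword nc = P.n_rows, C = S.n_cols;
  fmat Y(nc, C);
  arg.set_size(nc, C);
  for (uword c = 0; c < C; ++c) {
    const float* src = S.colptr(c);
    float* dst = Y.colptr(c);
    for (uword i = 0; i < nc; ++i) {
      uword bj = P(i, 0);
      float best = src[bj];
      for (int j = 1; j < 4; ++j) {
        const uword cj = P(i, j);
        if (src[cj] > best) { best = src[cj]; bj = cj; }
      }
      dst[i] = best;
      arg(i, c) = bj;
    }
  }
  return Y;
}

fmat pool_bwd(const fmat& dY, const umat& arg, uword n_fine) {
  fmat dS(n_fine, dY.n_cols, fill::zeros);
  for (uword c = 0; c < dY.n_cols; ++c) {
    float* dst = dS.colptr(c);
    const float* src = dY.colptr(c);
    for (uword i = 0; i < dY.n_rows; ++i) dst[arg(i, c)] += src[i];
  }
  return dS;
}

fmat up_fwd(const fmat& Yc, const umat& P, uword n_fine) {
  fmat U(n_fine, Yc.n_cols);
  for (uword c = 0; c < Yc.n_cols; ++c) {
    const float* src = Yc.colptr(c);
    float* dst = U.colptr(c);
    for (uword i = 0; i < P.n_rows; ++i) {
      const float v = src[i];
      for (int j = 0; j < 4; ++j) dst[P(i, j)] = v;
    }
  }
  return U;
}

fmat up_bwd(const fmat& dU, const umat& P) {
  fmat dYc(P.n_rows, dU.n_cols, fill::zeros);
  for (uword c = 0; c < dU.n_cols; ++c) {
    float* dst = dYc.colptr(c);
    const float* src = dU.colptr(c);
    for (uword i = 0; i < P.n_rows; ++i)
      dst[i] = src[P(i, 0)] + src[P(i, 1)] + src[P(i, 2)] + src[P(i, 3)];
  }
  return dYc;
}

struct Net {
  int levels, dlayers, growth, channels;
  float dropout;
  long adam_t = 0;
  Conv stem, head;
  std::vector<std::vector<Conv>> enc_dense, dec_dense;
  std::vector<Conv> enc_comp, dec_trans, dec_comp;
  Rng rng;
  std::map<std::array<int,3>, Plan> plans;

  Net(int levels_, int dlayers_, int growth_, int channels_, float dropout_,
      uint32_t seed)
    : levels(levels_), dlayers(dlayers_), growth(growth_),
      channels(channels_), dropout(dropout_), rng(seed) {
    const int C = channels, g = growth, d = dlayers;
    stem.init(27, 1, C, rng, false);
    enc_dense.resize(levels); enc_comp.resize(levels);
    for (int l = 0; l < levels; ++l) {
      enc_dense[l].resize(d);
      for (int j = 0; j < d; ++j) enc_dense[l][j].init(27, C + j * g, g, rng, false);
      enc_comp[l].init(1, C + d * g, C, rng, false);
    }
    const int ndec = levels - 1;
    dec_dense.resize(ndec); dec_trans.resize(ndec); dec_comp.resize(ndec);
    for (int l = 0; l < ndec; ++l) {
      // 1x1 transition compresses the [upsampled, skip] concat back to C
      // channels before the dense block, keeping decoder cost at encoder
      // level (the DenseNet compression idea applied to the skip joins)
      dec_trans[l].init(1, 2 * C, C, rng, false);
      dec_dense[l].resize(d);
      for (int j = 0; j < d; ++j) dec_dense[l][j].init(27, C + j * g, g, rng, false);
      dec_comp[l].init(1, C + d * g, C, rng, false);
    }
    // zero head with a background-favoring bias: the untrained network
    // predicts no aliasing anywhere (the overwhelmingly common class)
    head.init(1, C, 2, rng, true, 2.0f, -2.0f);
  }

  const Plan& plan_for(int nx, int ny, int nz) {
    std::array<int,3> key{nx, ny, nz};
    auto it = plans.find(key);
    if (it != plans.end()) return it->second;
    const int div = 1 << (levels - 1);
    if (nx % div != 0 || ny % div != 0)
      stop("in-plane dims must be divisible by 2^(levels-1)");
    Plan p;
    int cx = nx, cy = ny;
    for (int l = 0; l < levels; ++l) {
      p.d.push_back({cx, cy, nz});
      if (l < levels - 1) {
        p.pool.push_back(pool_table(cx, cy, nz));
        cx /= 2; cy /= 2;
      }
    }
    return plans.emplace(key, std::move(p)).first->second;
  }

  void for_each_conv(const std::function<void(Conv&, const std::string&)>& f) {
    f(stem, "stem");
    for (int l = 0; l < levels; ++l) {
      for (int j = 0; j < dlayers; ++j)
        f(enc_dense[l][j], "enc" + std::to_string(l) + "_dense" + std::to_string(j));
      f(enc_comp[l], "enc" + std::to_string(l) + "_comp");
    }
    for (int l = 0; l < levels - 1; ++l) {
      f(dec_trans[l], "dec" + std::to_string(l) + "_trans");
      for (int j = 0; j < dlayers; ++j)
        f(dec_dense[l][j], "dec" + std::to_string(l) + "_dense" + std::to_string(j));
      f(dec_comp[l], "dec" + std::to_string(l) + "_comp");
    }
    f(head, "head");
  }
};

struct BlockCache {
  fmat B;                    // growing concat matrix, final width cin0 + d*g
  std::vector<fmat> mult;    // per dense layer: relu/dropout multiplier
};

// Dense block forward on `B` (modified in place); dropout only in training.
void dense_block_fwd(std::vector<Conv>& convs, const Dims3& dims,
                     BlockCache& cache, Net& net, bool training) {
  for (size_t j = 0; j < convs.size(); ++j) {
    fmat H = conv_fwd(convs[j], cache.B, dims);
    fmat mult = conv_to<fmat>::from(H > 0.0f);
    if (training && net.dropout > 0.0f) {
      const float scale = 1.0f / (1.0f - net.dropout);
      for (uword i = 0; i < mult.n_elem; ++i)
        if (mult[i] > 0.0f)
          mult[i] = (net.rng.unif() < net.dropout) ? 0.0f : scale;
    }
    H = (H % mult);  // relu and dropout in one multiplier, reused in backward
    cache.mult.push_back(std::move(mult));
    cache.B = join_rows(cache.B, H);
  }
}

// Backward through a dense block; dB on entry holds grad wrt the full
// concat matrix, on exit its leading columns hold grad wrt the block input.
void dense_block_bwd(std::vector<Conv>& convs, const Dims3& dims,
                     BlockCache& cache, fmat& dB, int cin0, int growth) {
  for (int j = static_cast<int>(convs.size()) - 1; j >= 0; --j) {
    const int c0 = cin0 + j * growth;
    fmat dH = dB.cols(c0, c0 + growth - 1) % cache.mult[j];
    const fmat Fin = cache.B.cols(0, c0 - 1);
    fmat dIn = conv_bwd(convs[j], Fin, dims, dH);
    dB.cols(0, c0 - 1) += dIn;
  }
}

fmat relu_keep(fmat& Y) {  // applies relu in place, returns 0/1 mask
  fmat m = conv_to<fmat>::from(Y > 0.0f);
  Y %= m;
  return m;
}

struct ForwardCache {
  fmat X;
  fmat A0; fmat A0_mask;
  std::vector<BlockCache> enc_blocks;
  std::vector<fmat> S, S_mask;           // compressed skip outputs + relu masks
  std::vector<umat> pool_arg;
  std::vector<BlockCache> dec_blocks;    // indexed by decoder level l (0..L-2)
  std::vector<fmat> cat_in, T_mask;      // concat input + transition relu mask
  std::vector<fmat> Yd, Yd_mask;
  fmat logits, prob;
};

void forward(Net& net, const fmat& X, const Plan& plan, bool training,
             ForwardCache& fc) {
  const int L = net.levels, C = net.channels, g = net.growth, d = net.dlayers;
  fc.X = X;
  fc.A0 = conv_fwd(net.stem, X, plan.d[0]);
  fc.A0_mask = relu_keep(fc.A0);
  fc.enc_blocks.resize(L); fc.S.resize(L); fc.S_mask.resize(L);
  fc.pool_arg.resize(L > 1 ? L - 1 : 0);
  fmat cur = fc.A0;
  for (int l = 0; l < L; ++l) {
    fc.enc_blocks[l].B = cur;
    dense_block_fwd(net.enc_dense[l], plan.d[l], fc.enc_blocks[l], net,
                    training);
    fc.S[l] = conv_fwd(net.enc_comp[l], fc.enc_blocks[l].B, plan.d[l]);
    fc.S_mask[l] = relu_keep(fc.S[l]);
    if (l < L - 1) cur = pool_fwd(fc.S[l], plan.pool[l], fc.pool_arg[l]);
  }
  fc.dec_blocks.resize(L > 1 ? L - 1 : 0);
  fc.cat_in.resize(L > 1 ? L - 1 : 0); fc.T_mask.resize(L > 1 ? L - 1 : 0);
  fc.Yd.resize(L > 1 ? L - 1 : 0); fc.Yd_mask.resize(L > 1 ? L - 1 : 0);
  fmat y = fc.S[L - 1];
  for (int l = L - 2; l >= 0; --l) {
    const uword n_fine = fc.S[l].n_rows;
    fmat U = up_fwd(y, plan.pool[l], n_fine);
    fc.cat_in[l] = join_rows(U, fc.S[l]);
    fmat T = conv_fwd(net.dec_trans[l], fc.cat_in[l], plan.d[l]);
    fc.T_mask[l] = relu_keep(T);
    fc.dec_blocks[l].B = T;
    dense_block_fwd(net.dec_dense[l], plan.d[l], fc.dec_blocks[l], net,
                    training);
    fc.Yd[l] = conv_fwd(net.dec_comp[l], fc.dec_blocks[l].B, plan.d[l]);
    fc.Yd_mask[l] = relu_keep(fc.Yd[l]);
    y = fc.Yd[l];
  }
  fc.logits = conv_fwd(net.head, y, plan.d[0]);
  // stable softmax over the two channels
  fc.prob.set_size(fc.logits.n_rows, 2);
  for (uword i = 0; i < fc.logits.n_rows; ++i) {
    const float m = std::max(fc.logits(i, 0), fc.logits(i, 1));
    const float e0 = std::exp(fc.logits(i, 0) - m);
    const float e1 = std::exp(fc.logits(i, 1) - m);
    fc.prob(i, 0) = e0 / (e0 + e1);
    fc.prob(i, 1) = e1 / (e0 + e1);
  }
  (void)C; (void)g; (void)d;
}

void backward(Net& net, const Plan& plan, ForwardCache& fc, const fmat& dZ) {
  const int L = net.levels, C = net.channels, g = net.growth;
  const fmat& y_final = (L > 1) ? fc.Yd[0] : fc.S[L - 1];
  fmat dY = conv_bwd(net.head, y_final, plan.d[0], dZ);
  std::vector<fmat> dS(L);
  for (int l = 0; l < L; ++l) dS[l].zeros(fc.S[l].n_rows, C);
  if (L == 1) {
    dS[0] += dY;
  } else {
    for (int l = 0; l <= L - 2; ++l) {
      dY %= fc.Yd_mask[l];
      fmat dD = conv_bwd(net.dec_comp[l], fc.dec_blocks[l].B, plan.d[l], dY);
      dense_block_bwd(net.dec_dense[l], plan.d[l], fc.dec_blocks[l], dD,
                      C, g);
      fmat dT = dD.cols(0, C - 1) % fc.T_mask[l];
      fmat dCat = conv_bwd(net.dec_trans[l], fc.cat_in[l], plan.d[l], dT);
      dS[l] += dCat.cols(C, 2 * C - 1);
      dY = up_bwd(dCat.cols(0, C - 1), plan.pool[l]);
    }
    dS[L - 1] += dY;
  }
  fmat dcur;
  for (int l = L - 1; l >= 0; --l) {
    if (l < L - 1) dS[l] += dcur;  // pooled-path grad from level l+1's input
    dS[l] %= fc.S_mask[l];
    fmat dB = conv_bwd(net.enc_comp[l], fc.enc_blocks[l].B, plan.d[l], dS[l]);
    dense_block_bwd(net.enc_dense[l], plan.d[l], fc.enc_blocks[l], dB,
                    C, g);
    if (l > 0) {
      dcur = pool_bwd(dB.cols(0, C - 1), fc.pool_arg[l - 1],
                      fc.S[l - 1].n_rows);
    } else {
      fmat dA0 = dB.cols(0, C - 1) % fc.A0_mask;
      conv_bwd(net.stem, fc.X, plan.d[0], dA0);
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".unet_create")]]
SEXP unet_create(int levels, int dense_layers, int growth, int channels,
                 double dropout, int seed) {
  if (levels < 1 || dense_layers < 1 || growth < 1 || channels < 1)
    stop("levels, dense_layers, growth, channels must all be >= 1");
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)");
  Rcpp::XPtr<Net> ptr(new Net(levels, dense_layers, growth, channels,
                              static_cast<float>(dropout),
                              static_cast<uint32_t>(seed)), true);
  return ptr;
}

// [[Rcpp::export(name = ".unet_n_params")]]
double unet_n_params(SEXP net_ptr) {
  Rcpp::XPtr<Net> net(net_ptr);
  double n = 0;
  net->for_each_conv([&](Conv& cv, const std::string&) {
    n += cv.W.n_elem + cv.b.n_elem;
  });
  return n;
}

static fmat as_feature(const Rcpp::NumericVector& vol) {
  fmat X(vol.size(), 1);
  for (R_xlen_t i = 0; i < vol.size(); ++i)
    X(i, 0) = static_cast<float>(vol[i]);
  return X;
}

// [[Rcpp::export(name = ".unet_forward")]]
Rcpp::List unet_forward(SEXP net_ptr, Rcpp::NumericVector vol,
                        Rcpp::IntegerVector dims) {
  Rcpp::XPtr<Net> net(net_ptr);
  const Plan& plan = net->plan_for(dims[0], dims[1], dims[2]);
  ForwardCache fc;
  forward(*net, as_feature(vol), plan, false, fc);
  const uword n = fc.prob.n_rows;
  Rcpp::NumericVector prob(n);
  Rcpp::IntegerVector lab(n);
  for (uword i = 0; i < n; ++i) {
    prob[i] = fc.prob(i, 1);
    lab[i] = fc.prob(i, 1) > fc.prob(i, 0) ? 1 : 0;
  }
  return List::create(Named("prob") = prob, Named("mask") = lab);
}

// [[Rcpp::export(name = ".unet_train_step")]]
Rcpp::List unet_train_step(SEXP net_ptr, Rcpp::NumericVector vol,
                           Rcpp::IntegerVector truth,
                           Rcpp::IntegerVector dims, double lr) {
  Rcpp::XPtr<Net> net(net_ptr);
  const Plan& plan = net->plan_for(dims[0], dims[1], dims[2]);
  ForwardCache fc;
  forward(*net, as_feature(vol), plan, true, fc);
  const uword n = fc.prob.n_rows;
  if (static_cast<uword>(truth.size()) != n) stop("truth size mismatch");

  const double eps = 1e-5;
  double ce = 0.0, psum = 0.0, tsum = 0.0, ptsum = 0.0;
  uword hard_fg = 0, hard_int = 0;
  for (uword i = 0; i < n; ++i) {
    const int t = truth[i];
    const double p1 = fc.prob(i, 1);
    ce -= std::log(std::max(t == 1 ? p1 : 1.0 - p1, 1e-12));
    psum += p1; ptsum += t == 1 ? p1 : 0.0; tsum += t;
    const bool pred = fc.prob(i, 1) > fc.prob(i, 0);
    hard_fg += pred; hard_int += (pred && t == 1);
  }
  ce /= n;
  const double N = 2.0 * ptsum + eps, D = psum + tsum + eps;
  const double dice_loss = 1.0 - N / D;
  const double hard_dice = (2.0 * hard_int + eps) / (hard_fg + tsum + eps);

  fmat dZ(n, 2);
  for (uword i = 0; i < n; ++i) {
    const int t = truth[i];
    const double p0 = fc.prob(i, 0), p1 = fc.prob(i, 1);
    // softmax cross entropy
    double dz0 = (p0 - (t == 0 ? 1.0 : 0.0)) / n;
    double dz1 = (p1 - (t == 1 ? 1.0 : 0.0)) / n;
    // soft-Dice term through the softmax
    const double gd = -((t == 1 ? 2.0 : 0.0) * D - N) / (D * D);
    dz1 += gd * p1 * p0;
    dz0 -= gd * p1 * p0;
    dZ(i, 0) = static_cast<float>(dz0);
    dZ(i, 1) = static_cast<float>(dz1);
  }
  backward(*net, plan, fc, dZ);
  ++net->adam_t;
  net->for_each_conv([&](Conv& cv, const std::string&) {
    cv.adam(lr, net->adam_t);
  });
  return List::create(Named("ce") = ce, Named("dice_loss") = dice_loss,
                      Named("loss") = ce + dice_loss,
                      Named("hard_dice") = hard_dice);
}

// [[Rcpp::export(name = ".unet_get_weights")]]
Rcpp::List unet_get_weights(SEXP net_ptr) {
  Rcpp::XPtr<Net> net(net_ptr);
  Rcpp::List out;
  net->for_each_conv([&](Conv& cv, const std::string& nm) {
    Rcpp::NumericMatrix W(cv.W.n_rows, cv.W.n_cols);
    for (uword j = 0; j < cv.W.n_cols; ++j)
      for (uword i = 0; i < cv.W.n_rows; ++i)
        W(i, j) = cv.W(i, j);
    Rcpp::NumericVector b(cv.b.n_elem);
    for (uword i = 0; i < cv.b.n_elem; ++i) b[i] = cv.b[i];
    out[nm + ".W"] = W;
    out[nm + ".b"] = b;
  });
  return out;
}

// [[Rcpp::export(name = ".unet_set_weights")]]
void unet_set_weights(SEXP net_ptr, Rcpp::List weights) {
  Rcpp::XPtr<Net> net(net_ptr);
  net->for_each_conv([&](Conv& cv, const std::string& nm) {
    Rcpp::NumericMatrix W = weights[nm + ".W"];
    Rcpp::NumericVector b = weights[nm + ".b"];
    if (static_cast<uword>(W.nrow()) != cv.W.n_rows ||
        static_cast<uword>(W.ncol()) != cv.W.n_cols ||
        static_cast<uword>(b.size()) != cv.b.n_elem)
      stop("weight shape mismatch for layer %s", nm.c_str());
    for (uword j = 0; j < cv.W.n_cols; ++j)
      for (uword i = 0; i < cv.W.n_rows; ++i)
        cv.W(i, j) = static_cast<float>(W(i, j));
    for (uword i = 0; i < cv.b.n_elem; ++i)
      cv.b[i] = static_cast<float>(b[i]);
    cv.mW.zeros(); cv.vW.zeros(); cv.mb.zeros(); cv.vb.zeros();
  });
  net->adam_t = 0;
}
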