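// Structured temporal convolutional network with BP-MLL training.
//
// Four convolutional blocks (P and F inputs, max- and average-pooled),
// each block: for every kernel size s, nFilters 1D convolutions spanning
// s time steps and all d feature columns with "same" zero padding
// (extra pad element at the sequence end for even s), activation,
// 2x1 pooling with stride 2, elementwise sum over the filters, and
// concatenation over kernel sizes. Block outputs plus gender and age
// feed a dense two-hidden-layer head. Training minimizes the mean
// BP-MLL pairwise ranking loss with Adam and validation-loss early
// stopping.
//
// Convolutions are evaluated as im2col + GEMM; weight layout per kernel
// size is a (s*d) x (2*nFilters) matrix whose first nFilters columns
// belong to the max-pooled block and the rest to the average-pooled
// block, so both blocks of one input share a single GEMM. Arithmetic is
// single precision (the R boundary stays double); tanh uses a rational
// polynomial approximation accurate to ~4e-7 that the compiler can
// vectorize.

#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::uword;

typedef float real;
typedef arma::Mat<real> rmat;
typedef arma::Cube<real> rcube;
typedef arma::Row<real> rrow;

namespace {

enum Act { TANH, RELU, IDENTITY };

Act actFromString(const std::string& s) {
  if (s == "tanh") return TANH;
  if (s == "relu") return RELU;
  if (s == "identity" || s == "linear") return IDENTITY;
  stop("unknown activation: " + s);
}

// rational tanh approximation (clamped at |x| ~ 8), max error ~4e-7
inline void fastTanh(real* x, size_t n) {
  const real lim = 7.99881172180175781f;
  for (size_t i = 0; i < n; ++i) {
    real v = x[i];
    v = v < -lim ? -lim : (v > lim ? lim : v);
    const real x2 = v * v;
    real p = -2.76076847742355e-16f;
    p = p * x2 + 2.00018790482477e-13f;
    p = p * x2 + -8.60467152213735e-11f;
    p = p * x2 + 5.12229709037114e-08f;
    p = p * x2 + 1.48572235717979e-05f;
    p = p * x2 + 6.37261928875436e-04f;
    p = p * x2 + 4.89352455891786e-03f;
    p = p * v;
    real q = 1.19825839466702e-06f;
    q = q * x2 + 1.18534705686654e-04f;
    q = q * x2 + 2.26843463243900e-03f;
    q = q * x2 + 4.89352518554385e-03f;
    x[i] = p / q;
  }
}

inline void applyAct(rmat& z, Act a) {
  if (a == TANH) fastTanh(z.memptr(), z.n_elem);
  else if (a == RELU) z = arma::clamp(z, (real)0, std::numeric_limits<real>::max());
}

// derivative expressed through the activation value
inline rmat actDeriv(const rmat& a, Act act) {
  if (act == TANH) return 1.0f - arma::square(a);
  if (act == RELU) return arma::conv_to<rmat>::from(a > (real)0);
  return rmat(a.n_rows, a.n_cols, arma::fill::ones);
}

struct NetConfig {
  arma::ivec S;          // kernel sizes
  uword nf;              // filters per block
  uword t, dP, dF;       // time steps, feature columns
  uword h1, h2, nLabels;
  Act convAct, hiddenAct, outputAct;
  double lr;
  uword batchSize, patience, maxEpochs;
  uword nS() const { return S.n_elem; }
  uword hp() const { return t / 2; }
  uword blockLen() const { return nS() * hp(); }
  uword featDim() const { return 4 * blockLen() + 2; }
};

NetConfig parseConfig(const List& cfg, uword dP, uword dF, uword t) {
  NetConfig c;
  c.S = as<arma::ivec>(cfg["kernelSizes"]);
  c.nf = as<uword>(cfg["nFilters"]);
  c.t = t; c.dP = dP; c.dF = dF;
  arma::ivec hidden = as<arma::ivec>(cfg["hidden"]);
  if (hidden.n_elem != 2) stop("exactly two hidden layers are supported");
  c.h1 = hidden[0]; c.h2 = hidden[1];
  c.nLabels = as<uword>(cfg["nLabels"]);
  c.convAct = actFromString(as<std::string>(cfg["convActivation"]));
  c.hiddenAct = actFromString(as<std::string>(cfg["hiddenActivation"]));
  c.outputAct = actFromString(as<std::string>(cfg["outputActivation"]));
  c.lr = as<double>(cfg["learningRate"]);
  c.batchSize = as<uword>(cfg["batchSize"]);
  c.patience = as<uword>(cfg["patience"]);
  c.maxEpochs = as<uword>(cfg["maxEpochs"]);
  if (c.t % 2 != 0) stop("t must be even for 2x1 pooling");
  for (uword i = 0; i < c.S.n_elem; ++i)
    if (c.S[i] < 1 || (uword)c.S[i] > c.t) stop("kernel size outside 1..t");
  return c;
}

// all weights of the network, flat-indexed for the optimizer
struct Params {
  // conv[input][sIdx]: W (s*d x 2nf), b (1 x 2nf); input 0 = P, 1 = F
  std::vector<std::vector<rmat>> W, B;
  rmat W1, W2, W3, b1, b2, b3;  // biases kept as 1-row matrices

  std::vector<rmat*> flat;
  void index() {
    flat.clear();
    for (int in = 0; in < 2; ++in)
      for (size_t k = 0; k < W[in].size(); ++k) {
        flat.push_back(&W[in][k]);
        flat.push_back(&B[in][k]);
      }
    flat.push_back(&W1); flat.push_back(&b1);
    flat.push_back(&W2); flat.push_back(&b2);
    flat.push_back(&W3); flat.push_back(&b3);
  }
};

rmat toReal(const arma::mat& m) { return arma::conv_to<rmat>::from(m); }
arma::mat toDouble(const rmat& m) {
  return arma::conv_to<arma::mat>::from(m);
}

Params paramsFromList(const List& weights, const NetConfig& c) {
  Params p;
  p.W.resize(2); p.B.resize(2);
  const char* names[2] = {"P", "F"};
  for (int in = 0; in < 2; ++in) {
    List conv = weights[names[in]];
    if ((uword)conv.size() != c.nS()) stop("weights do not match kernel set");
    for (uword k = 0; k < c.nS(); ++k) {
      List wk = conv[k];
      p.W[in].push_back(toReal(as<arma::mat>(wk["W"])));
      arma::mat b = as<arma::mat>(wk["b"]);
      p.B[in].push_back(toReal(b.n_rows == 1 ? b : b.t()));
    }
  }
  List dense = weights["dense"];
  p.W1 = toReal(as<arma::mat>(dense["W1"]));
  p.W2 = toReal(as<arma::mat>(dense["W2"]));
  p.W3 = toReal(as<arma::mat>(dense["W3"]));
  p.b1 = toReal(arma::mat(as<arma::rowvec>(dense["b1"])));
  p.b2 = toReal(arma::mat(as<arma::rowvec>(dense["b2"])));
  p.b3 = toReal(arma::mat(as<arma::rowvec>(dense["b3"])));
  p.index();
  return p;
}

List paramsToList(const Params& p) {
  const char* names[2] = {"P", "F"};
  List out;
  for (int in = 0; in < 2; ++in) {
    List conv(p.W[in].size());
    for (size_t k = 0; k < p.W[in].size(); ++k)
      conv[k] = List::create(Named("W") = toDouble(p.W[in][k]),
                             Named("b") = toDouble(p.B[in][k]));
    out[names[in]] = conv;
  }
  out["dense"] = List::create(
      Named("W1") = toDouble(p.W1), Named("b1") = toDouble(p.b1),
      Named("W2") = toDouble(p.W2), Named("b2") = toDouble(p.b2),
      Named("W3") = toDouble(p.W3), Named("b3") = toDouble(p.b3));
  return out;
}

// im2col for a batch: X (t x d x B) -> patches ((B*t) x (s*d));
// "same" padding, extra pad element at the end for even s.
void im2col(const rcube& X, uword s, rmat& patches) {
  const uword t = X.n_rows, d = X.n_cols, B = X.n_slices;
  const uword padLeft = (s - 1) / 2;
  patches.zeros(B * t, s * d);
  for (uword b = 0; b < B; ++b)
    for (uword j = 0; j < d; ++j) {
      const real* col = X.slice(b).colptr(j);
      for (uword i = 0; i < s; ++i) {
        // patch row r covers padded positions r .. r+s-1; element i maps
        // to unpadded time r + i - padLeft
        real* dst = patches.colptr(j * s + i) + b * t;
        uword rLo = (padLeft > i) ? padLeft - i : 0;
        uword rHi = std::min(t, t + padLeft - i);  // exclusive
        for (uword r = rLo; r < rHi; ++r) dst[r] = col[r + i - padLeft];
      }
    }
}

struct BlockCache {
  std::vector<rmat> A;           // [sIdx] activations (B*t x 2nf)
  std::vector<arma::umat> amax;  // [sIdx] argmax offset (B*hp x nf), 0/1
  std::vector<rmat> patches;     // [sIdx] im2col matrices, reused backward
};

// forward through both pooling blocks of one input; writes the summed
// pooled features into feat columns [base, base + 2*blockLen)
void convForward(const rcube& X, const std::vector<rmat>& W,
                 const std::vector<rmat>& B_, const NetConfig& c,
                 rmat& feat, uword base, BlockCache* cache, rmat& scratch) {
  const uword t = c.t, hp = c.hp(), nf = c.nf, nB = X.n_slices;
  for (uword k = 0; k < c.nS(); ++k) {
    const uword s = (uword)c.S[k];
    rmat& pk = cache ? cache->patches[k] : scratch;
    im2col(X, s, pk);
    rmat A = pk * W[k];
    A.each_row() += rrow(B_[k]);
    applyAct(A, c.convAct);
    arma::umat am;
    if (cache) am.set_size(nB * hp, nf);
    const uword offMax = base + k * hp;
    const uword offAvg = base + c.blockLen() + k * hp;
    for (uword b = 0; b < nB; ++b) {
      for (uword f = 0; f < 2 * nf; ++f) {
        const real* a = A.colptr(f) + b * t;
        if (f < nf) {  // max pooling
          for (uword u = 0; u < hp; ++u) {
            const bool second = a[2 * u + 1] > a[2 * u];
            feat(b, offMax + u) += second ? a[2 * u + 1] : a[2 * u];
            if (cache) am(b * hp + u, f) = second ? 1 : 0;
          }
        } else {       // average pooling
          for (uword u = 0; u < hp; ++u)
            feat(b, offAvg + u) += 0.5f * (a[2 * u] + a[2 * u + 1]);
        }
      }
    }
    if (cache) { cache->A[k] = std::move(A); cache->amax[k] = std::move(am); }
  }
}

// backward for one input's pair of blocks: accumulates dW, dB using the
// patches cached by the forward pass
void convBackward(const rcube& X, const NetConfig& c, const rmat& dFeat,
                  uword base, const BlockCache& cache, std::vector<rmat>& dW,
                  std::vector<rmat>& dB) {
  const uword t = c.t, hp = c.hp(), nf = c.nf, nB = X.n_slices;
  for (uword k = 0; k < c.nS(); ++k) {
    const uword s = (uword)c.S[k];
    const rmat& A = cache.A[k];
    const arma::umat& am = cache.amax[k];
    rmat dZ(nB * t, 2 * nf, arma::fill::zeros);
    const uword offMax = base + k * hp;
    const uword offAvg = base + c.blockLen() + k * hp;
    for (uword b = 0; b < nB; ++b)
      for (uword f = 0; f < 2 * nf; ++f) {
        real* dz = dZ.colptr(f) + b * t;
        if (f < nf) {
          for (uword u = 0; u < hp; ++u)
            dz[2 * u + am(b * hp + u, f)] = dFeat(b, offMax + u);
        } else {
          for (uword u = 0; u < hp; ++u) {
            const real g = 0.5f * dFeat(b, offAvg + u);
            dz[2 * u] = g; dz[2 * u + 1] = g;
          }
        }
      }
    dZ %= actDeriv(A, c.convAct);
    dW[k] += cache.patches[k].t() * dZ;
    dB[k] += arma::sum(dZ, 0);
  }
}

struct ForwardCache {
  rmat feat, H1, H2, C;
  BlockCache blkP, blkF;
};

void netForward(const rcube& P, const rcube& F, const rmat& extra,
                const Params& p, const NetConfig& c, ForwardCache& fc,
                bool keepCache, rmat& scratch) {
  const uword nB = P.n_slices;
  fc.feat.zeros(nB, c.featDim());
  if (keepCache) {
    fc.blkP.A.resize(c.nS()); fc.blkP.amax.resize(c.nS());
    fc.blkP.patches.resize(c.nS());
    fc.blkF.A.resize(c.nS()); fc.blkF.amax.resize(c.nS());
    fc.blkF.patches.resize(c.nS());
  }
  convForward(P, p.W[0], p.B[0], c, fc.feat, 0,
              keepCache ? &fc.blkP : nullptr, scratch);
  convForward(F, p.W[1], p.B[1], c, fc.feat, 2 * c.blockLen(),
              keepCache ? &fc.blkF : nullptr, scratch);
  fc.feat.cols(c.featDim() - 2, c.featDim() - 1) = extra;
  fc.H1 = fc.feat * p.W1; fc.H1.each_row() += rrow(p.b1);
  applyAct(fc.H1, c.hiddenAct);
  fc.H2 = fc.H1 * p.W2; fc.H2.each_row() += rrow(p.b2);
  applyAct(fc.H2, c.hiddenAct);
  fc.C = fc.H2 * p.W3; fc.C.each_row() += rrow(p.b3);
  applyAct(fc.C, c.outputAct);
}

// BP-MLL: mean over rows of (1/(|Y||Ybar|)) sum_{k in Y, l in Ybar}
// exp(-(c_k - c_l)). Rows with empty Y or Ybar are excluded (counted).
double bpmll(const rmat& C, const rmat& Y, rmat* grad, uword* nSkipped) {
  const uword n = C.n_rows, L = C.n_cols;
  if (grad) grad->zeros(n, L);
  double total = 0.0;
  uword used = 0, skipped = 0;
  std::vector<uword> pos, neg;
  for (uword i = 0; i < n; ++i) {
    pos.clear(); neg.clear();
    for (uword j = 0; j < L; ++j)
      (Y(i, j) > 0.5f ? pos : neg).push_back(j);
    if (pos.empty() || neg.empty()) { ++skipped; continue; }
    const double norm = 1.0 / (double)(pos.size() * neg.size());
    double li = 0.0;
    for (uword k : pos)
      for (uword l : neg) {
        const double e = std::exp(-(double)(C(i, k) - C(i, l)));
        li += e;
        if (grad) {
          (*grad)(i, k) -= (real)(e * norm);
          (*grad)(i, l) += (real)(e * norm);
        }
      }
    total += li * norm;
    ++used;
  }
  if (nSkipped) *nSkipped = skipped;
  if (used == 0) return NA_REAL;
  if (grad) *grad /= (real)used;
  return total / (double)used;
}


// forward + full backward on one batch; fills g in Params::index order.
// Returns the batch loss (NA when every row is degenerate).
double batchGradients(const rcube& Pb, const rcube& Fb, const rmat& Eb,
                      const rmat& Yb, const Params& p, const NetConfig& c,
                      ForwardCache& fc, rmat& scratch, std::vector<rmat>& g,
                      uword* skippedOut) {
  netForward(Pb, Fb, Eb, p, c, fc, true, scratch);
  rmat dC;
  uword skipped = 0;
  const double loss = bpmll(fc.C, Yb, &dC, &skipped);
  if (skippedOut) *skippedOut = skipped;
  if (Yb.n_rows == skipped) return NA_REAL;

  g.resize(p.flat.size());
  rmat dZ3 = dC % actDeriv(fc.C, c.outputAct);
  size_t gi = p.flat.size();
  g[--gi] = arma::sum(dZ3, 0);            // b3
  g[--gi] = fc.H2.t() * dZ3;              // W3
  rmat dH2 = dZ3 * p.W3.t();
  rmat dZ2 = dH2 % actDeriv(fc.H2, c.hiddenAct);
  g[--gi] = arma::sum(dZ2, 0);            // b2
  g[--gi] = fc.H1.t() * dZ2;              // W2
  rmat dH1 = dZ2 * p.W2.t();
  rmat dZ1 = dH1 % actDeriv(fc.H1, c.hiddenAct);
  g[--gi] = arma::sum(dZ1, 0);            // b1
  g[--gi] = fc.feat.t() * dZ1;            // W1
  rmat dFeat = dZ1 * p.W1.t();

  std::vector<std::vector<rmat>> gW(2), gB(2);
  for (int in = 0; in < 2; ++in)
    for (uword k = 0; k < c.nS(); ++k) {
      gW[in].push_back(rmat(arma::size(p.W[in][k]), arma::fill::zeros));
      gB[in].push_back(rmat(1, 2 * c.nf, arma::fill::zeros));
    }
  convBackward(Pb, c, dFeat, 0, fc.blkP, gW[0], gB[0]);
  convBackward(Fb, c, dFeat, 2 * c.blockLen(), fc.blkF, gW[1], gB[1]);
  size_t fi = 0;
  for (int in = 0; in < 2; ++in)
    for (uword k = 0; k < c.nS(); ++k) {
      g[fi++] = std::move(gW[in][k]);
      g[fi++] = std::move(gB[in][k]);
    }
  return loss;
}

rcube slices(const rcube& X, const arma::uvec& idx) {
  rcube out(X.n_rows, X.n_cols, idx.n_elem);
  for (uword i = 0; i < idx.n_elem; ++i) out.slice(i) = X.slice(idx[i]);
  return out;
}

double valLoss(const rcube& P, const rcube& F, const rmat& extra,
               const rmat& Y, const arma::uvec& idx, const Params& p,
               const NetConfig& c, uword batch, rmat& scratch) {
  ForwardCache fc;
  double total = 0.0; uword used = 0;
  for (uword start = 0; start < idx.n_elem; start += batch) {
    const uword end = std::min<uword>(start + batch, idx.n_elem) - 1;
    arma::uvec sub = idx.subvec(start, end);
    netForward(slices(P, sub), slices(F, sub), extra.rows(sub), p, c, fc,
               false, scratch);
    uword skipped = 0;
    const double l = bpmll(fc.C, Y.rows(sub), nullptr, &skipped);
    const uword m = sub.n_elem - skipped;
    if (m > 0) { total += l * m; used += m; }
  }
  return used > 0 ? total / used : NA_REAL;
}

}  // namespace

// [[Rcpp::export]]
List cpp_tcnn_init(List cfg, int dP, int dF, int t) {
  NetConfig c = parseConfig(cfg, dP, dF, t);
  Params p;
  p.W.resize(2); p.B.resize(2);
  const uword ds[2] = {c.dP, c.dF};
  for (int in = 0; in < 2; ++in)
    for (uword k = 0; k < c.nS(); ++k) {
      const uword s = (uword)c.S[k];
      const double sd = std::sqrt(1.0 / (double)(s * ds[in]));
      rmat W(s * ds[in], 2 * c.nf);
      for (uword i = 0; i < W.n_elem; ++i) W[i] = (real)(norm_rand() * sd);
      p.W[in].push_back(W);
      p.B[in].push_back(rmat(1, 2 * c.nf, arma::fill::zeros));
    }
  auto dense = [&](uword nin, uword nout) {
    const double sd = std::sqrt(1.0 / (double)nin);
    rmat W(nin, nout);
    for (uword i = 0; i < W.n_elem; ++i) W[i] = (real)(norm_rand() * sd);
    return W;
  };
  p.W1 = dense(c.featDim(), c.h1); p.b1.zeros(1, c.h1);
  p.W2 = dense(c.h1, c.h2); p.b2.zeros(1, c.h2);
  p.W3 = dense(c.h2, c.nLabels); p.b3.zeros(1, c.nLabels);
  return paramsToList(p);
}

// [[Rcpp::export]]
arma::mat cpp_tcnn_forward(arma::cube P, arma::cube F, arma::mat extra,
                           List weights, List cfg) {
  NetConfig c = parseConfig(cfg, P.n_cols, F.n_cols, P.n_rows);
  Params p = paramsFromList(weights, c);
  rcube Pr = arma::conv_to<rcube>::from(P);
  rcube Fr = arma::conv_to<rcube>::from(F);
  rmat Er = toReal(extra);
  rmat scratch;
  ForwardCache fc;
  const uword n = Pr.n_slices;
  arma::mat out(n, c.nLabels);
  const uword batch = std::max<uword>(c.batchSize, 1);
  for (uword start = 0; start < n; start += batch) {
    const uword end = std::min<uword>(start + batch, n) - 1;
    arma::uvec sub = arma::regspace<arma::uvec>(start, end);
    netForward(slices(Pr, sub), slices(Fr, sub), Er.rows(sub), p, c, fc,
               false, scratch);
    out.rows(sub) = toDouble(fc.C);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_bpmll_batch(arma::mat C, arma::mat Y) {
  rmat grad;
  uword skipped = 0;
  const double loss = bpmll(toReal(C), toReal(Y), &grad, &skipped);
  return List::create(Named("loss") = loss, Named("grad") = toDouble(grad),
                      Named("skipped") = (int)skipped);
}

// [[Rcpp::export]]
List cpp_tcnn_grad(arma::cube P, arma::cube F, arma::mat extra, arma::mat Y,
                   List weights, List cfg) {
  NetConfig c = parseConfig(cfg, P.n_cols, F.n_cols, P.n_rows);
  Params p = paramsFromList(weights, c);
  rcube Pr = arma::conv_to<rcube>::from(P);
  rcube Fr = arma::conv_to<rcube>::from(F);
  rmat scratch;
  ForwardCache fc;
  std::vector<rmat> g;
  uword skipped = 0;
  const double loss = batchGradients(Pr, Fr, toReal(extra), toReal(Y), p, c,
                                     fc, scratch, g, &skipped);
  Params gp = p;  // reuse structure to serialize gradients
  size_t fi = 0;
  for (int in = 0; in < 2; ++in)
    for (size_t k = 0; k < gp.W[in].size(); ++k) {
      gp.W[in][k] = g[fi++];
      gp.B[in][k] = g[fi++];
    }
  gp.W1 = g[fi++]; gp.b1 = g[fi++];
  gp.W2 = g[fi++]; gp.b2 = g[fi++];
  gp.W3 = g[fi++]; gp.b3 = g[fi++];
  return List::create(Named("loss") = loss,
                      Named("grad") = paramsToList(gp),
                      Named("skipped") = (int)skipped);
}

// [[Rcpp::export]]
List cpp_tcnn_train(arma::cube P, arma::cube F, arma::mat extra,
                    arma::mat Y, arma::uvec trainIdx, arma::uvec valIdx,
                    List cfg, List weights0, bool verbose) {
  NetConfig c = parseConfig(cfg, P.n_cols, F.n_cols, P.n_rows);
  trainIdx -= 1;  // R is 1-based
  valIdx -= 1;
  Params p = paramsFromList(weights0, c);
  rcube Pr = arma::conv_to<rcube>::from(P);
  rcube Fr = arma::conv_to<rcube>::from(F);
  rmat Er = toReal(extra);
  rmat Yr = toReal(Y);

  // Adam state
  std::vector<rmat> m(p.flat.size()), v(p.flat.size());
  for (size_t i = 0; i < p.flat.size(); ++i) {
    m[i].zeros(arma::size(*p.flat[i]));
    v[i].zeros(arma::size(*p.flat[i]));
  }
  const real beta1 = 0.9f, beta2 = 0.999f, eps = 1e-8f;
  double beta1t = 1.0, beta2t = 1.0;

  rmat scratch;
  ForwardCache fc;
  std::vector<double> trainLossLog, valLossLog;
  double bestVal = arma::datum::inf;
  List bestWeights = paramsToList(p);
  uword sinceBest = 0, totalSkipped = 0, bestEpoch = 0;

  // gradient buffers, same flat order as Params::index()
  std::vector<rmat> g(p.flat.size());

  std::vector<uword> order(trainIdx.begin(), trainIdx.end());
  for (uword epoch = 1; epoch <= c.maxEpochs; ++epoch) {
    // Fisher-Yates shuffle driven by the R RNG for reproducibility
    for (uword i = order.size() - 1; i > 0; --i) {
      uword j = (uword)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double epochLoss = 0.0; uword epochUsed = 0;
    for (uword start = 0; start < order.size(); start += c.batchSize) {
      const uword end = std::min<uword>(start + c.batchSize, order.size());
      arma::uvec sub(end - start);
      for (uword i = start; i < end; ++i) sub[i - start] = order[i];
      rcube Pb = slices(Pr, sub), Fb = slices(Fr, sub);
      rmat Eb = Er.rows(sub), Yb = Yr.rows(sub);
      uword skipped = 0;
      const double loss = batchGradients(Pb, Fb, Eb, Yb, p, c, fc, scratch,
                                         g, &skipped);
      totalSkipped += skipped;
      const uword usedRows = sub.n_elem - skipped;
      if (usedRows == 0) continue;
      if (!std::isfinite(loss))
        stop("training diverged (non-finite loss) at epoch %d", (int)epoch);
      epochLoss += loss * usedRows; epochUsed += usedRows;

      // Adam step
      beta1t *= beta1; beta2t *= beta2;
      const real corr =
          (real)(c.lr * std::sqrt(1.0 - beta2t) / (1.0 - beta1t));
      for (size_t i = 0; i < p.flat.size(); ++i) {
        m[i] = beta1 * m[i] + (1 - beta1) * g[i];
        v[i] = beta2 * v[i] + (1 - beta2) * arma::square(g[i]);
        *p.flat[i] -= corr * m[i] / (arma::sqrt(v[i]) + eps);
      }
    }
    const double tl = epochUsed ? epochLoss / epochUsed : NA_REAL;
    const double vl = valLoss(Pr, Fr, Er, Yr, valIdx, p, c,
                              std::max<uword>(c.batchSize, 64), scratch);
    trainLossLog.push_back(tl);
    valLossLog.push_back(vl);
    if (verbose)
      Rprintf("epoch %3d  train %.6f  val %.6f\n", (int)epoch, tl, vl);
    if (std::isfinite(vl) && vl < bestVal) {
      bestVal = vl;
      bestWeights = paramsToList(p);
      bestEpoch = epoch;
      sinceBest = 0;
    } else {
      ++sinceBest;
      if (sinceBest > c.patience) break;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
      Named("weights") = bestWeights,
      Named("trainLoss") = trainLossLog,
      Named("valLoss") = valLossLog,
      Named("bestEpoch") = (int)bestEpoch,
      Named("bestValLoss") = bestVal,
      Named("skippedAllOnes") = (int)totalSkipped);
}
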