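// Minimal dense/conv/LSTM network engine for 5-channel one-hot DNA input.
//
// Two fixed topologies are supported:
//   cnn      : conv(k1) -> relu -> maxpool -> conv(k2) -> relu -> maxpool
//              -> flatten -> batchnorm -> dense1(relu) -> dropout
//              -> dense2(relu) -> dense(1, sigmoid)
//   cnn_lstm : conv(k1) -> relu -> maxpool -> LSTM(H, final state)
//              -> batchnorm -> dense1(relu) -> dropout -> dense2(relu)
//              -> dense(1, sigmoid)
//
// Training is plain SGD with momentum; the learning rate is supplied per
// epoch by the caller (cosine-annealing schedule lives in R).  All
// randomness (shuffling, dropout masks) is drawn from R's RNG so that a
// set.seed() on the R side makes a run reproducible.
//
// Input batches are cubes with dimensions (batch, position, channel),
// matching an R array of dim c(N, L, 5).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::rowvec;
using arma::umat;
using arma::uvec;
using arma::vec;

namespace {

struct NetSpec {
  bool lstm;
  int width, C, k1, f1, pool, k2, f2, H, d1, d2;
  double dropout, bn_eps, bn_mom;
  // derived lengths
  int L1, P1, L2, P2, D;
};

NetSpec parse_spec(const List& s) {
  NetSpec sp;
  std::string arch = as<std::string>(s["arch"]);
  sp.lstm = (arch == "cnn_lstm");
  sp.width = as<int>(s["input_width"]);
  sp.C = as<int>(s["n_channels"]);
  sp.k1 = as<int>(s["conv1_kernel"]);
  sp.f1 = as<int>(s["conv1_filters"]);
  sp.pool = as<int>(s["pool_size"]);
  sp.dropout = as<double>(s["dropout"]);
  sp.bn_eps = 1e-5;
  sp.bn_mom = 0.9;
  sp.d1 = as<int>(s["dense1_units"]);
  sp.d2 = as<int>(s["dense2_units"]);
  sp.L1 = sp.width - sp.k1 + 1;
  sp.P1 = sp.L1 / sp.pool;
  if (sp.lstm) {
    sp.H = as<int>(s["lstm_units"]);
    sp.k2 = sp.f2 = sp.L2 = sp.P2 = 0;
    sp.D = sp.H;
  } else {
    sp.k2 = as<int>(s["conv2_kernel"]);
    sp.f2 = as<int>(s["conv2_filters"]);
    sp.H = 0;
    sp.L2 = sp.P1 - sp.k2 + 1;
    sp.P2 = sp.L2 / sp.pool;
    sp.D = sp.P2 * sp.f2;
  }
  if (sp.L1 < sp.pool)
    stop("input width too small for conv1 kernel and pooling");
  if (!sp.lstm && (sp.L2 < sp.pool))
    stop("pooled width too small for conv2 kernel");
  return sp;
}

struct Params {
  mat W1; rowvec b1;
  mat W2; rowvec b2;            // cnn only
  mat Wx, Wh; rowvec bl;        // lstm only
  rowvec gamma, beta, rmean, rvar;
  mat Wd1; rowvec bd1;
  mat Wd2; rowvec bd2;
  mat Wo; rowvec bo;
};

mat as_matc(SEXP x) { return as<mat>(x); }
rowvec as_rowv(SEXP x) { return as<rowvec>(x); }

Params params_from_list(const List& p, const NetSpec& sp) {
  Params q;
  q.W1 = as_matc(p["conv1_W"]); q.b1 = as_rowv(p["conv1_b"]);
  if (sp.lstm) {
    q.Wx = as_matc(p["lstm_Wx"]); q.Wh = as_matc(p["lstm_Wh"]);
    q.bl = as_rowv(p["lstm_b"]);
  } else {
    q.W2 = as_matc(p["conv2_W"]); q.b2 = as_rowv(p["conv2_b"]);
  }
  q.gamma = as_rowv(p["bn_gamma"]); q.beta = as_rowv(p["bn_beta"]);
  q.rmean = as_rowv(p["bn_mean"]);  q.rvar = as_rowv(p["bn_var"]);
  q.Wd1 = as_matc(p["dense1_W"]); q.bd1 = as_rowv(p["dense1_b"]);
  q.Wd2 = as_matc(p["dense2_W"]); q.bd2 = as_rowv(p["dense2_b"]);
  q.Wo = as_matc(p["out_W"]); q.bo = as_rowv(p["out_b"]);
  return q;
}

List params_to_list(const Params& q, const NetSpec& sp) {
  List out;
  out["conv1_W"] = wrap(q.W1); out["conv1_b"] = wrap(q.b1);
  if (sp.lstm) {
    out["lstm_Wx"] = wrap(q.Wx); out["lstm_Wh"] = wrap(q.Wh);
    out["lstm_b"] = wrap(q.bl);
  } else {
    out["conv2_W"] = wrap(q.W2); out["conv2_b"] = wrap(q.b2);
  }
  out["bn_gamma"] = wrap(q.gamma); out["bn_beta"] = wrap(q.beta);
  out["bn_mean"] = wrap(q.rmean);  out["bn_var"] = wrap(q.rvar);
  out["dense1_W"] = wrap(q.Wd1); out["dense1_b"] = wrap(q.bd1);
  out["dense2_W"] = wrap(q.Wd2); out["dense2_b"] = wrap(q.bd2);
  out["out_W"] = wrap(q.Wo); out["out_b"] = wrap(q.bo);
  return out;
}

Params zeros_like(const Params& q) {
  Params z;
  z.W1 = arma::zeros<mat>(q.W1.n_rows, q.W1.n_cols);
  z.b1 = arma::zeros<rowvec>(q.b1.n_elem);
  if (q.W2.n_elem) {
    z.W2 = arma::zeros<mat>(q.W2.n_rows, q.W2.n_cols);
    z.b2 = arma::zeros<rowvec>(q.b2.n_elem);
  }
  if (q.Wx.n_elem) {
    z.Wx = arma::zeros<mat>(q.Wx.n_rows, q.Wx.n_cols);
    z.Wh = arma::zeros<mat>(q.Wh.n_rows, q.Wh.n_cols);
    z.bl = arma::zeros<rowvec>(q.bl.n_elem);
  }
  z.gamma = arma::zeros<rowvec>(q.gamma.n_elem);
  z.beta = arma::zeros<rowvec>(q.beta.n_elem);
  z.Wd1 = arma::zeros<mat>(q.Wd1.n_rows, q.Wd1.n_cols);
  z.bd1 = arma::zeros<rowvec>(q.bd1.n_elem);
  z.Wd2 = arma::zeros<mat>(q.Wd2.n_rows, q.Wd2.n_cols);
  z.bd2 = arma::zeros<rowvec>(q.bd2.n_elem);
  z.Wo = arma::zeros<mat>(q.Wo.n_rows, q.Wo.n_cols);
  z.bo = arma::zeros<rowvec>(q.bo.n_elem);
  return z;
}

// im2col for a (B, L, C) cube with kernel k: rows indexed j*B + b,
// columns indexed c*k + i so that row r of the weight matrix corresponds
// to kernel offset i = r % k within channel c = r / k.
mat im2col(const cube& X, int k) {
  const int B = X.n_rows, L = X.n_cols, C = X.n_slices;
  const int Lout = L - k + 1;
  mat M(B * Lout, k * C);
  for (int c = 0; c < C; ++c)
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < Lout; ++j)
        M.submat(j * B, c * k + i, j * B + B - 1, c * k + i) =
            X.slice(c).col(j + i);
  return M;
}

// scatter-add the im2col gradient back onto the input cube
void col2im_add(cube& dX, const mat& dM, int k) {
  const int B = dX.n_rows, L = dX.n_cols;
  const int Lout = L - k + 1;
  for (unsigned int c = 0; c < dX.n_slices; ++c)
    for (int i = 0; i < k; ++i)
      for (int j = 0; j < Lout; ++j)
        dX.slice(c).col(j + i) +=
            dM.submat(j * B, c * k + i, j * B + B - 1, c * k + i);
}

// (B*Lout x F) matrix (rows j*B+b) -> cube (B, Lout, F)
cube stack_to_cube(const mat& A, int B, int Lout) {
  cube out(B, Lout, A.n_cols);
  for (unsigned int f = 0; f < A.n_cols; ++f)
    for (int j = 0; j < Lout; ++j)
      out.slice(f).col(j) = A.submat(j * B, f, j * B + B - 1, f);
  return out;
}

mat cube_to_stack(const cube& X) {
  const int B = X.n_rows, Lout = X.n_cols;
  mat A(B * Lout, X.n_slices);
  for (unsigned int f = 0; f < X.n_slices; ++f)
    for (int j = 0; j < Lout; ++j)
      A.submat(j * B, f, j * B + B - 1, f) = X.slice(f).col(j);
  return A;
}

// max pooling along the position dimension, stride = width = ps
void maxpool(const cube& X, int ps, cube& out, arma::ucube& idx) {
  const int B = X.n_rows, F = X.n_slices;
  const int Lp = X.n_cols / ps;
  out.set_size(B, Lp, F);
  idx.set_size(B, Lp, F);
  for (int f = 0; f < F; ++f) {
    for (int t = 0; t < Lp; ++t) {
      vec best = X.slice(f).col(t * ps);
      uvec arg(B, arma::fill::zeros);
      for (int s = 1; s < ps; ++s) {
        vec cand = X.slice(f).col(t * ps + s);
        for (int b = 0; b < B; ++b)
          if (cand(b) > best(b)) { best(b) = cand(b); arg(b) = s; }
      }
      out.slice(f).col(t) = best;
      for (int b = 0; b < B; ++b) idx(b, t, f) = t * ps + arg(b);
    }
  }
}

void maxpool_backward(const cube& dOut, const arma::ucube& idx, int Lin,
                      cube& dX) {
  const int B = dOut.n_rows, Lp = dOut.n_cols, F = dOut.n_slices;
  dX.zeros(B, Lin, F);
  for (int f = 0; f < F; ++f)
    for (int t = 0; t < Lp; ++t)
      for (int b = 0; b < B; ++b)
        dX(b, idx(b, t, f), f) += dOut(b, t, f);
}

mat sigmoid(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// slice timestep t of a (B, T, F) cube into a (B, F) matrix
mat time_slice(const cube& X, int t) {
  mat out(X.n_rows, X.n_slices);
  for (unsigned int f = 0; f < X.n_slices; ++f) out.col(f) = X.slice(f).col(t);
  return out;
}

struct LstmCache {
  std::vector<mat> X, i, f, g, o, c, tanhc, hprev;
};

// returns final hidden state
mat lstm_forward(const cube& Xs, const Params& q, int H, LstmCache* cache) {
  const int B = Xs.n_rows, T = Xs.n_cols;
  mat h(B, H, arma::fill::zeros), c(B, H, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat Xt = time_slice(Xs, t);
    mat G = Xt * q.Wx + h * q.Wh;
    G.each_row() += q.bl;
    mat gi = sigmoid(G.cols(0, H - 1));
    mat gf = sigmoid(G.cols(H, 2 * H - 1));
    mat gg = arma::tanh(G.cols(2 * H, 3 * H - 1));
    mat go = sigmoid(G.cols(3 * H, 4 * H - 1));
    mat cnew = gf % c + gi % gg;
    mat tc = arma::tanh(cnew);
    if (cache) {
      cache->X.push_back(Xt); cache->i.push_back(gi); cache->f.push_back(gf);
      cache->g.push_back(gg); cache->o.push_back(go);
      cache->hprev.push_back(h);
      cache->c.push_back(c);       // previous cell state
      cache->tanhc.push_back(tc);
    }
    c = cnew;
    h = go % tc;
  }
  return h;
}

// backward through time; fills gradients and the gradient wrt inputs
void lstm_backward(const LstmCache& cc, const Params& q, int H,
                   const mat& dh_last, Params& g, cube& dXs) {
  const int T = cc.X.size();
  const int B = dh_last.n_rows;
  mat dh = dh_last;
  mat dc(B, H, arma::fill::zeros);
  dXs.zeros(B, T, cc.X[0].n_cols);
  for (int t = T - 1; t >= 0; --t) {
    const mat& tc = cc.tanhc[t];
    mat do_ = dh % tc;
    dc += dh % cc.o[t] % (1.0 - tc % tc);
    mat di = dc % cc.g[t];
    mat dg = dc % cc.i[t];
    mat df = dc % cc.c[t];
    mat dcprev = dc % cc.f[t];
    mat dG(B, 4 * H);
    dG.cols(0, H - 1) = di % cc.i[t] % (1.0 - cc.i[t]);
    dG.cols(H, 2 * H - 1) = df % cc.f[t] % (1.0 - cc.f[t]);
    dG.cols(2 * H, 3 * H - 1) = dg % (1.0 - cc.g[t] % cc.g[t]);
    dG.cols(3 * H, 4 * H - 1) = do_ % cc.o[t] % (1.0 - cc.o[t]);
    g.Wx += cc.X[t].t() * dG;
    g.Wh += cc.hprev[t].t() * dG;
    g.bl += arma::sum(dG, 0);
    mat dXt = dG * q.Wx.t();
    for (unsigned int f = 0; f < dXs.n_slices; ++f)
      dXs.slice(f).col(t) = dXt.col(f);
    dh = dG * q.Wh.t();
    dc = dcprev;
  }
}

// Forward pass in evaluation mode (running BN stats, no dropout).
vec forward_eval(const Params& q, const NetSpec& sp, const cube& X) {
  const int B = X.n_rows;
  mat M1 = im2col(X, sp.k1);
  mat A1 = M1 * q.W1;
  A1.each_row() += q.b1;
  A1.elem(arma::find(A1 < 0)).zeros();
  cube C1 = stack_to_cube(A1, B, sp.L1);
  cube P1c; arma::ucube i1;
  maxpool(C1, sp.pool, P1c, i1);
  mat feat;
  if (sp.lstm) {
    feat = lstm_forward(P1c, q, sp.H, nullptr);
  } else {
    mat M2 = im2col(P1c, sp.k2);
    mat A2 = M2 * q.W2;
    A2.each_row() += q.b2;
    A2.elem(arma::find(A2 < 0)).zeros();
    cube C2 = stack_to_cube(A2, B, sp.L2);
    cube P2c; arma::ucube i2;
    maxpool(C2, sp.pool, P2c, i2);
    feat.set_size(B, sp.D);
    for (int f = 0; f < sp.f2; ++f)
      for (int t = 0; t < sp.P2; ++t)
        feat.col(f * sp.P2 + t) = P2c.slice(f).col(t);
  }
  rowvec istd = 1.0 / arma::sqrt(q.rvar + sp.bn_eps);
  mat z = feat;
  z.each_row() -= q.rmean;
  z.each_row() %= istd % q.gamma;
  z.each_row() += q.beta;
  mat a1 = z * q.Wd1; a1.each_row() += q.bd1;
  a1.elem(arma::find(a1 < 0)).zeros();
  mat a2 = a1 * q.Wd2; a2.each_row() += q.bd2;
  a2.elem(arma::find(a2 < 0)).zeros();
  mat logit = a2 * q.Wo; logit.each_row() += q.bo;
  return arma::vectorise(sigmoid(logit));
}

// One training batch: forward with batch statistics + dropout, backward,
// gradients into g.  Returns the mean binary cross-entropy.
double train_batch(Params& q, const NetSpec& sp, const cube& X, const vec& y,
                   Params& g) {
  const int B = X.n_rows;

  // ---- forward ----
  mat M1 = im2col(X, sp.k1);
  mat A1 = M1 * q.W1;
  A1.each_row() += q.b1;
  arma::umat R1 = (A1 > 0);
  A1.elem(arma::find(R1 == 0)).zeros();
  cube C1 = stack_to_cube(A1, B, sp.L1);
  cube P1c; arma::ucube i1;
  maxpool(C1, sp.pool, P1c, i1);

  LstmCache lc;
  mat feat, M2; arma::umat R2c; cube C2, P2c; arma::ucube i2;
  if (sp.lstm) {
    feat = lstm_forward(P1c, q, sp.H, &lc);
  } else {
    M2 = im2col(P1c, sp.k2);
    mat A2 = M2 * q.W2;
    A2.each_row() += q.b2;
    R2c = (A2 > 0);
    A2.elem(arma::find(R2c == 0)).zeros();
    C2 = stack_to_cube(A2, B, sp.L2);
    maxpool(C2, sp.pool, P2c, i2);
    feat.set_size(B, sp.D);
    for (int f = 0; f < sp.f2; ++f)
      for (int t = 0; t < sp.P2; ++t)
        feat.col(f * sp.P2 + t) = P2c.slice(f).col(t);
  }

  // batch normalization with batch statistics
  rowvec mu = arma::mean(feat, 0);
  mat cent = feat;
  cent.each_row() -= mu;
  rowvec var = arma::mean(cent % cent, 0);
  rowvec istd = 1.0 / arma::sqrt(var + sp.bn_eps);
  mat xhat = cent;
  xhat.each_row() %= istd;
  mat z = xhat;
  z.each_row() %= q.gamma;
  z.each_row() += q.beta;
  q.rmean = sp.bn_mom * q.rmean + (1.0 - sp.bn_mom) * mu;
  q.rvar = sp.bn_mom * q.rvar + (1.0 - sp.bn_mom) * var;

  mat a1 = z * q.Wd1; a1.each_row() += q.bd1;
  arma::umat Rd1 = (a1 > 0);
  a1.elem(arma::find(Rd1 == 0)).zeros();

  // inverted dropout, masks from R's RNG
  mat dmask(B, sp.d1, arma::fill::ones);
  if (sp.dropout > 0) {
    const double keep = 1.0 - sp.dropout;
    for (unsigned int j = 0; j < dmask.n_elem; ++j)
      dmask(j) = (unif_rand() < keep) ? (1.0 / keep) : 0.0;
  }
  mat a1d = a1 % dmask;

  mat a2 = a1d * q.Wd2; a2.each_row() += q.bd2;
  arma::umat Rd2 = (a2 > 0);
  a2.elem(arma::find(Rd2 == 0)).zeros();

  mat logit = a2 * q.Wo; logit.each_row() += q.bo;
  vec p = arma::vectorise(sigmoid(logit));

  vec pc = arma::clamp(p, 1e-12, 1.0 - 1e-12);
  double loss =
      arma::mean(-(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc)));

  // ---- backward ----
  mat dlogit = (p - y);          // B x 1
  dlogit /= (double)B;
  g.Wo += a2.t() * dlogit;
  g.bo += arma::sum(dlogit, 0);
  mat da2 = dlogit * q.Wo.t();
  da2.elem(arma::find(Rd2 == 0)).zeros();
  g.Wd2 += a1d.t() * da2;
  g.bd2 += arma::sum(da2, 0);
  mat da1 = (da2 * q.Wd2.t()) % dmask;
  da1.elem(arma::find(Rd1 == 0)).zeros();
  g.Wd1 += z.t() * da1;
  g.bd1 += arma::sum(da1, 0);
  mat dz = da1 * q.Wd1.t();

  g.gamma += arma::sum(dz % xhat, 0);
  g.beta += arma::sum(dz, 0);
  mat dxhat = dz;
  dxhat.each_row() %= q.gamma;
  rowvec s1 = arma::sum(dxhat, 0);
  rowvec s2 = arma::sum(dxhat % xhat, 0);
  mat dfeat = dxhat * (double)B;
  dfeat.each_row() -= s1;
  dfeat -= xhat % arma::repmat(s2, B, 1);
  dfeat.each_row() %= istd / (double)B;

  cube dP1c;
  if (sp.lstm) {
    lstm_backward(lc, q, sp.H, dfeat, g, dP1c);
  } else {
    cube dP2c(B, sp.P2, sp.f2);
    for (int f = 0; f < sp.f2; ++f)
      for (int t = 0; t < sp.P2; ++t)
        dP2c.slice(f).col(t) = dfeat.col(f * sp.P2 + t);
    cube dC2;
    maxpool_backward(dP2c, i2, sp.L2, dC2);
    mat dA2 = cube_to_stack(dC2);
    dA2.elem(arma::find(R2c == 0)).zeros();
    g.W2 += M2.t() * dA2;
    g.b2 += arma::sum(dA2, 0);
    mat dM2 = dA2 * q.W2.t();
    dP1c.zeros(B, sp.P1, sp.f1);
    col2im_add(dP1c, dM2, sp.k2);
  }

  cube dC1;
  maxpool_backward(dP1c, i1, sp.L1, dC1);
  mat dA1 = cube_to_stack(dC1);
  dA1.elem(arma::find(R1 == 0)).zeros();
  g.W1 += M1.t() * dA1;
  g.b1 += arma::sum(dA1, 0);

  return loss;
}

void sgd_update(Params& q, const Params& g, Params& v, double lr,
                double momentum, double wd) {
  // weight decay applies to weight matrices only, not biases or the
  // batch-norm scale/shift
  auto updw = [lr, momentum, wd](mat& w, const mat& gr, mat& vel) {
    if (!w.n_elem) return;
    vel = momentum * vel - lr * (gr + wd * w);
    w += vel;
  };
  auto updb = [lr, momentum](rowvec& w, const rowvec& gr, rowvec& vel) {
    if (!w.n_elem) return;
    vel = momentum * vel - lr * gr;
    w += vel;
  };
  updw(q.W1, g.W1, v.W1); updb(q.b1, g.b1, v.b1);
  updw(q.W2, g.W2, v.W2); updb(q.b2, g.b2, v.b2);
  updw(q.Wx, g.Wx, v.Wx); updw(q.Wh, g.Wh, v.Wh); updb(q.bl, g.bl, v.bl);
  updb(q.gamma, g.gamma, v.gamma); updb(q.beta, g.beta, v.beta);
  updw(q.Wd1, g.Wd1, v.Wd1); updb(q.bd1, g.bd1, v.bd1);
  updw(q.Wd2, g.Wd2, v.Wd2); updb(q.bd2, g.bd2, v.bd2);
  updw(q.Wo, g.Wo, v.Wo); updb(q.bo, g.bo, v.bo);
}

double grad_sqnorm(const Params& g) {
  double s = 0;
  auto acc = [&s](const mat& m) { if (m.n_elem) s += arma::accu(m % m); };
  auto accv = [&s](const rowvec& m) { if (m.n_elem) s += arma::accu(m % m); };
  acc(g.W1); accv(g.b1); acc(g.W2); accv(g.b2);
  acc(g.Wx); acc(g.Wh); accv(g.bl);
  accv(g.gamma); accv(g.beta);
  acc(g.Wd1); accv(g.bd1); acc(g.Wd2); accv(g.bd2);
  acc(g.Wo); accv(g.bo);
  return s;
}

void scale_grads(Params& g, double f) {
  auto sc = [f](mat& m) { if (m.n_elem) m *= f; };
  auto scv = [f](rowvec& m) { if (m.n_elem) m *= f; };
  sc(g.W1); scv(g.b1); sc(g.W2); scv(g.b2);
  sc(g.Wx); sc(g.Wh); scv(g.bl);
  scv(g.gamma); scv(g.beta);
  sc(g.Wd1); scv(g.bd1); sc(g.Wd2); scv(g.bd2);
  sc(g.Wo); scv(g.bo);
}

void zero_grads(Params& g) {
  g.W1.zeros(); g.b1.zeros();
  if (g.W2.n_elem) { g.W2.zeros(); g.b2.zeros(); }
  if (g.Wx.n_elem) { g.Wx.zeros(); g.Wh.zeros(); g.bl.zeros(); }
  g.gamma.zeros(); g.beta.zeros();
  g.Wd1.zeros(); g.bd1.zeros();
  g.Wd2.zeros(); g.bd2.zeros();
  g.Wo.zeros(); g.bo.zeros();
}

cube array_to_cube(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("input must be a 3-d array");
  cube out(d[0], d[1], d[2]);
  std::copy(x.begin(), x.end(), out.memptr());
  return out;
}

cube rows_of(const cube& X, const uvec& idx) {
  cube out(idx.n_elem, X.n_cols, X.n_slices);
  for (unsigned int c = 0; c < X.n_slices; ++c)
    out.slice(c) = X.slice(c).rows(idx);
  return out;
}

} // namespace

// [[Rcpp::export(name = ".nn_train")]]
List nn_train(List params, List spec, NumericVector x, NumericVector y,
              NumericVector lr_epochs, int batch_size, double momentum,
              double weight_decay, double clip_norm, int snapshot_every,
              bool verbose) {
  NetSpec sp = parse_spec(spec);
  cube X = array_to_cube(x);
  vec yy = as<vec>(y);
  const int N = X.n_rows;
  if ((int)yy.n_elem != N) stop("label length does not match batch size");
  Params q = params_from_list(params, sp);
  Params g = zeros_like(q), v = zeros_like(q);

  const int T = lr_epochs.size();
  std::vector<List> snapshots;
  NumericVector loss_trace(T);

  RNGScope rng;  // shuffling + dropout use R's RNG
  for (int epoch = 0; epoch < T; ++epoch) {
    double lr = lr_epochs[epoch];
    // Fisher-Yates shuffle driven by R's RNG
    uvec perm(N);
    for (int i = 0; i < N; ++i) perm(i) = i;
    for (int i = N - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm(i), perm(j));
    }
    double epoch_loss = 0.0;
    int nb = 0;
    for (int off = 0; off < N; off += batch_size) {
      int hi = std::min(off + batch_size, N) - 1;
      uvec idx = perm.subvec(off, hi);
      cube Xb = rows_of(X, idx);
      vec yb = yy(idx);
      zero_grads(g);
      epoch_loss += train_batch(q, sp, Xb, yb, g);
      if (clip_norm > 0) {
        double nrm = std::sqrt(grad_sqnorm(g));
        if (nrm > clip_norm) scale_grads(g, clip_norm / nrm);
      }
      sgd_update(q, g, v, lr, momentum, weight_decay);
      ++nb;
    }
    loss_trace[epoch] = epoch_loss / nb;
    if (verbose)
      Rcout << "epoch " << (epoch + 1) << " lr " << lr << " loss "
            << loss_trace[epoch] << "\n";
    if (snapshot_every > 0 && ((epoch + 1) % snapshot_every == 0))
      snapshots.push_back(params_to_list(q, sp));
    Rcpp::checkUserInterrupt();
  }
  List snaps(snapshots.size());
  for (size_t i = 0; i < snapshots.size(); ++i) snaps[i] = snapshots[i];
  return List::create(_["snapshots"] = snaps, _["loss"] = loss_trace,
                      _["params"] = params_to_list(q, sp));
}

// [[Rcpp::export(name = ".nn_predict")]]
NumericVector nn_predict(List params, List spec, NumericVector x) {
  NetSpec sp = parse_spec(spec);
  cube X = array_to_cube(x);
  Params q = params_from_list(params, sp);
  vec p = forward_eval(q, sp, X);
  return wrap(p);
}
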