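// Inception-style multi-embedding encoder with Siamese contrastive training.
//
// Layout conventions:
//  * a batch of B activations with C channels and spatial length L is one
//    arma::mat of shape (C, L*B), column (b*L + pos) = channels at position
//    pos of sequence b; flattening a batch is then a plain reshape.
//  * the k*m-dimensional head output stores embedding component i in rows
//    [i*m, (i+1)*m) (m fastest).
// Convolutions use 'same' zero padding so the l parallel unit outputs share
// the spatial extent and can be concatenated channel-wise; max-pooling uses
// window p with stride 1 (length L -> L-p+1).

#include <RcppArmadillo.h>
#include <random>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::umat;
using arma::uword;

namespace {

struct NetCfg {
  int N, k, m, layers, units, chan, pool;
  std::vector<int> widths; // per-unit convolution window
  std::vector<int> len;    // spatial length entering layer t
  std::vector<int> cin;    // channels entering layer t
  int F;                   // flattened feature size
};

NetCfg parse_cfg(const List& cfg) {
  NetCfg c;
  c.N = as<int>(cfg["N"]);
  c.k = as<int>(cfg["k"]);
  c.m = as<int>(cfg["m"]);
  c.layers = as<int>(cfg["num_layers"]);
  c.units = as<int>(cfg["units"]);
  c.chan = as<int>(cfg["channels"]);
  c.pool = as<int>(cfg["pool"]);
  c.widths = as<std::vector<int>>(cfg["widths"]);
  if ((int)c.widths.size() != c.units) stop("widths must have one entry per unit");
  c.len.resize(c.layers + 1);
  c.cin.resize(c.layers + 1);
  c.len[0] = c.N;
  c.cin[0] = 4;
  for (int t = 0; t < c.layers; ++t) {
    c.len[t + 1] = c.len[t] - c.pool + 1;
    c.cin[t + 1] = c.units * c.chan;
    if (c.len[t + 1] < 1) stop("pool window too large for sequence length");
  }
  c.F = c.cin[c.layers] * c.len[c.layers];
  return c;
}

struct Params {
  std::vector<std::vector<mat>> W, B; // [layer][unit]
  mat HW, HB;
};

Params parse_params(const List& params, const NetCfg& c) {
  Params p;
  List conv = params["conv"];
  if ((int)conv.size() != c.layers) stop("parameter/config layer mismatch");
  p.W.resize(c.layers);
  p.B.resize(c.layers);
  for (int t = 0; t < c.layers; ++t) {
    List lay = conv[t];
    if ((int)lay.size() != c.units) stop("parameter/config unit mismatch");
    p.W[t].resize(c.units);
    p.B[t].resize(c.units);
    for (int j = 0; j < c.units; ++j) {
      List u = lay[j];
      p.W[t][j] = as<mat>(u["W"]);
      p.B[t][j] = as<mat>(u["b"]);
      if ((int)p.W[t][j].n_rows != c.chan ||
          (int)p.W[t][j].n_cols != c.cin[t] * c.widths[j])
        stop("conv weight shape mismatch at layer %d unit %d", t + 1, j + 1);
    }
  }
  List head = params["head"];
  p.HW = as<mat>(head["W"]);
  p.HB = as<mat>(head["b"]);
  if ((int)p.HW.n_rows != c.k * c.m || (int)p.HW.n_cols != c.F)
    stop("head weight shape mismatch");
  return p;
}

List params_to_list(const Params& p, const NetCfg& c) {
  List conv(c.layers);
  for (int t = 0; t < c.layers; ++t) {
    List lay(c.units);
    for (int j = 0; j < c.units; ++j)
      lay[j] = List::create(_["W"] = p.W[t][j], _["b"] = p.B[t][j]);
    conv[t] = lay;
  }
  return List::create(_["conv"] = conv,
                      _["head"] = List::create(_["W"] = p.HW, _["b"] = p.HB));
}

Params zeros_like(const Params& p) {
  Params g = p;
  for (auto& lay : g.W) for (auto& w : lay) w.zeros();
  for (auto& lay : g.B) for (auto& b : lay) b.zeros();
  g.HW.zeros();
  g.HB.zeros();
  return g;
}

std::vector<mat*> flat_view(Params& p) {
  std::vector<mat*> v;
  for (size_t t = 0; t < p.W.size(); ++t)
    for (size_t j = 0; j < p.W[t].size(); ++j) {
      v.push_back(&p.W[t][j]);
      v.push_back(&p.B[t][j]);
    }
  v.push_back(&p.HW);
  v.push_back(&p.HB);
  return v;
}

mat onehot_batch(const arma::imat& seq, int N, int B) {
  mat A(4, (uword)N * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int i = 0; i < N; ++i)
      A(seq(i, b), (uword)b * N + i) = 1.0;
  return A;
}

// 'same' padding: output position pos gathers input positions pos-pad .. pos-pad+w-1
mat im2col(const mat& A, int C, int L, int B, int w) {
  mat Col((uword)C * w, (uword)L * B, arma::fill::zeros);
  const int pad = (w - 1) / 2;
  for (int q = 0; q < w; ++q) {
    const int off = q - pad;
    const int p0 = std::max(0, -off), p1 = std::min(L, L - off) - 1;
    if (p0 > p1) continue;
    for (int b = 0; b < B; ++b)
      Col.submat((uword)q * C, (uword)b * L + p0,
                 (uword)(q + 1) * C - 1, (uword)b * L + p1) =
        A.cols((uword)b * L + p0 + off, (uword)b * L + p1 + off);
  }
  return Col;
}

void col2im_add(mat& dA, const mat& dCol, int C, int L, int B, int w) {
  const int pad = (w - 1) / 2;
  for (int q = 0; q < w; ++q) {
    const int off = q - pad;
    const int p0 = std::max(0, -off), p1 = std::min(L, L - off) - 1;
    if (p0 > p1) continue;
    for (int b = 0; b < B; ++b)
      dA.cols((uword)b * L + p0 + off, (uword)b * L + p1 + off) +=
        dCol.submat((uword)q * C, (uword)b * L + p0,
                    (uword)(q + 1) * C - 1, (uword)b * L + p1);
  }
}

mat pool_fwd(const mat& H, int C, int L, int B, int p, umat& AM) {
  const int Lp = L - p + 1;
  mat P(C, (uword)Lp * B);
  AM.set_size(C, (uword)Lp * B);
  for (int b = 0; b < B; ++b)
    for (int pos = 0; pos < Lp; ++pos) {
      const uword oc = (uword)b * Lp + pos, ic = (uword)b * L + pos;
      for (int ch = 0; ch < C; ++ch) {
        double best = H(ch, ic);
        int bq = 0;
        for (int q = 1; q < p; ++q) {
          const double v = H(ch, ic + q);
          if (v > best) { best = v; bq = q; }
        }
        P(ch, oc) = best;
        AM(ch, oc) = bq;
      }
    }
  return P;
}

void pool_bwd(mat& dH, const mat& dP, const umat& AM, int C, int L, int B, int p) {
  const int Lp = L - p + 1;
  for (int b = 0; b < B; ++b)
    for (int pos = 0; pos < Lp; ++pos) {
      const uword oc = (uword)b * Lp + pos, ic = (uword)b * L + pos;
      for (int ch = 0; ch < C; ++ch)
        dH(ch, ic + AM(ch, oc)) += dP(ch, oc);
    }
}

struct Cache {
  std::vector<mat> A;                // input to each layer (A[0] = one-hot)
  std::vector<std::vector<mat>> Col; // per layer per unit (training only)
  std::vector<mat> Z;                // concatenated pre-activation
  std::vector<umat> AM;              // pool argmax offsets
  mat Fm, E;
};

void forward(const NetCfg& c, const Params& p, const arma::imat& seq, int B,
             Cache& ca, bool keep) {
  ca.A.assign(c.layers + 1, mat());
  ca.Z.assign(c.layers, mat());
  ca.AM.assign(c.layers, umat());
  ca.Col.assign(c.layers, std::vector<mat>());
  ca.A[0] = onehot_batch(seq, c.N, B);
  for (int t = 0; t < c.layers; ++t) {
    const int C = c.cin[t], L = c.len[t], Cout = c.units * c.chan;
    mat Z(Cout, (uword)L * B);
    if (keep) ca.Col[t].assign(c.units, mat());
    for (int j = 0; j < c.units; ++j) {
      mat Col = im2col(ca.A[t], C, L, B, c.widths[j]);
      mat Zj = p.W[t][j] * Col;
      Zj.each_col() += p.B[t][j].col(0);
      Z.rows((uword)j * c.chan, (uword)(j + 1) * c.chan - 1) = Zj;
      if (keep) ca.Col[t][j] = std::move(Col);
    }
    mat H = arma::clamp(Z, 0.0, arma::datum::inf);
    ca.A[t + 1] = pool_fwd(H, Cout, L, B, c.pool, ca.AM[t]);
    if (keep) ca.Z[t] = std::move(Z);
  }
  ca.Fm = arma::reshape(ca.A[c.layers], c.F, B);
  ca.E = p.HW * ca.Fm;
  ca.E.each_col() += p.HB.col(0);
}

void backward(const NetCfg& c, const Params& p, const Cache& ca, const mat& dE,
              int B, Params& g) {
  g.HW += dE * ca.Fm.t();
  g.HB += arma::sum(dE, 1);
  mat dP = arma::reshape(p.HW.t() * dE, c.cin[c.layers], (uword)c.len[c.layers] * B);
  for (int t = c.layers - 1; t >= 0; --t) {
    const int C = c.cin[t], L = c.len[t], Cout = c.units * c.chan;
    mat dH(Cout, (uword)L * B, arma::fill::zeros);
    pool_bwd(dH, dP, ca.AM[t], Cout, L, B, c.pool);
    dH %= arma::conv_to<mat>::from(ca.Z[t] > 0.0);
    mat dA;
    if (t > 0) dA.zeros(C, (uword)L * B);
    for (int j = 0; j < c.units; ++j) {
      mat dZj = dH.rows((uword)j * c.chan, (uword)(j + 1) * c.chan - 1);
      g.W[t][j] += dZj * ca.Col[t][j].t();
      g.B[t][j] += arma::sum(dZj, 1);
      if (t > 0) {
        mat dCol = p.W[t][j].t() * dZj;
        col2im_add(dA, dCol, C, L, B, c.widths[j]);
      }
    }
    if (t > 0) dP = std::move(dA);
  }
}

// Contrastive hinge loss L = max(0, (z - delta) * y) with z the minimum
// component-wise Euclidean distance; subgradient flows through the argmin
// component only. Returns the batch total; gradients are unscaled.
double loss_and_grad(const mat& Es, const mat& Et, const arma::vec& y, int k,
                     int m, double delta, mat& dEs, mat& dEt) {
  const int B = Es.n_cols;
  dEs.zeros(arma::size(Es));
  dEt.zeros(arma::size(Et));
  double total = 0.0;
  for (int b = 0; b < B; ++b) {
    double zmin = arma::datum::inf;
    int istar = 0;
    for (int i = 0; i < k; ++i) {
      double ss = 0.0;
      for (int j = 0; j < m; ++j) {
        const double d = Es((uword)i * m + j, b) - Et((uword)i * m + j, b);
        ss += d * d;
      }
      const double z = std::sqrt(ss);
      if (z < zmin) { zmin = z; istar = i; }
    }
    const double margin = (zmin - delta) * y(b);
    if (margin > 0.0) {
      total += margin;
      if (zmin > 0.0) {
        const double cof = y(b) / zmin;
        for (int j = 0; j < m; ++j) {
          const uword r = (uword)istar * m + j;
          const double d = Es(r, b) - Et(r, b);
          dEs(r, b) = cof * d;
          dEt(r, b) = -cof * d;
        }
      }
    }
  }
  return total;
}

// Deterministic normal generator (Box-Muller over mt19937_64) so that
// initialisation does not depend on the C++ standard library's
// std::normal_distribution implementation.
struct RNG64 {
  std::mt19937_64 g;
  bool have = false;
  double spare = 0.0;
  explicit RNG64(uint64_t s) : g(s) {}
  double unif() { return (double)(g() >> 11) / 9007199254740992.0; }
  double norm() {
    if (have) { have = false; return spare; }
    double u1 = unif();
    while (u1 <= 1e-300) u1 = unif();
    const double u2 = unif();
    const double r = std::sqrt(-2.0 * std::log(u1)), th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    have = true;
    return r * std::cos(th);
  }
  void fill_norm(mat& M, double sd) {
    for (uword i = 0; i < M.n_elem; ++i) M(i) = sd * norm();
  }
};

mat full_embed(const NetCfg& c, const Params& p, const arma::imat& seqs) {
  const int n = seqs.n_cols, chunk = 1024;
  mat E((uword)c.k * c.m, n);
  Cache ca;
  for (int s0 = 0; s0 < n; s0 += chunk) {
    const int s1 = std::min(n, s0 + chunk);
    forward(c, p, seqs.cols(s0, s1 - 1), s1 - s0, ca, false);
    E.cols(s0, s1 - 1) = ca.E;
  }
  return E;
}

} // namespace

// [[Rcpp::export]]
List lsme_init_cpp(List cfg, int seed) {
  NetCfg c = parse_cfg(cfg);
  RNG64 rng((uint64_t)(int64_t)seed * 0x9e3779b97f4a7c15ULL + 1ULL);
  Params p;
  p.W.resize(c.layers);
  p.B.resize(c.layers);
  for (int t = 0; t < c.layers; ++t) {
    p.W[t].resize(c.units);
    p.B[t].resize(c.units);
    for (int j = 0; j < c.units; ++j) {
      const int fan_in = c.cin[t] * c.widths[j];
      p.W[t][j].set_size(c.chan, fan_in);
      rng.fill_norm(p.W[t][j], std::sqrt(2.0 / fan_in)); // He init under ReLU
      p.B[t][j].zeros(c.chan, 1);
    }
  }
  p.HW.set_size((uword)c.k * c.m, c.F);
  rng.fill_norm(p.HW, std::sqrt(1.0 / c.F));
  p.HB.zeros((uword)c.k * c.m, 1);
  return params_to_list(p, c);
}

// [[Rcpp::export]]
NumericMatrix lsme_forward_cpp(List params, List cfg, IntegerMatrix seqs) {
  NetCfg c = parse_cfg(cfg);
  Params p = parse_params(params, c);
  if (seqs.nrow() != c.N) stop("sequence length does not match config N");
  arma::imat S(seqs.begin(), seqs.nrow(), seqs.ncol(), true);
  return wrap(full_embed(c, p, S));
}

// [[Rcpp::export]]
List lsme_train_cpp(List params, List cfg, IntegerMatrix S, IntegerMatrix T,
                    NumericVector y, int epochs, int batch_size, double lr,
                    int seed) {
  NetCfg c = parse_cfg(cfg);
  Params p = parse_params(params, c);
  const int n = S.ncol();
  if (T.ncol() != n || y.size() != n) stop("pair arrays disagree in length");
  if (S.nrow() != c.N || T.nrow() != c.N) stop("sequence length does not match config N");
  arma::imat Sm(S.begin(), S.nrow(), n, true), Tm(T.begin(), T.nrow(), n, true);
  arma::vec yv(y.begin(), n, true);

  // initial mean loss over the full training set (no updates)
  double init_loss = 0.0;
  {
    mat Es = full_embed(c, p, Sm), Et = full_embed(c, p, Tm);
    mat dEs, dEt;
    init_loss = loss_and_grad(Es, Et, yv, c.k, c.m, as<double>(cfg["delta"]),
                              dEs, dEt) / n;
  }

  Params g = zeros_like(p), m1 = zeros_like(p), m2 = zeros_like(p);
  std::vector<mat*> pv = flat_view(p), gv = flat_view(g), m1v = flat_view(m1),
                    m2v = flat_view(m2);
  const double delta = as<double>(cfg["delta"]);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  std::mt19937_64 shuf((uint64_t)(int64_t)seed * 0x2545f4914f6cdd1dULL + 7ULL);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  NumericVector epoch_loss(epochs);
  Cache ca;
  mat dEs, dEt;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), shuf);
    double tot = 0.0;
    for (int b0 = 0; b0 < n; b0 += batch_size) {
      const int b1i = std::min(n, b0 + batch_size), nb = b1i - b0;
      arma::imat X(c.N, 2 * nb);
      arma::vec yb(nb);
      for (int i = 0; i < nb; ++i) {
        X.col(i) = Sm.col(idx[b0 + i]);
        X.col(nb + i) = Tm.col(idx[b0 + i]);
        yb(i) = yv(idx[b0 + i]);
      }
      forward(c, p, X, 2 * nb, ca, true);
      mat Es = ca.E.cols(0, nb - 1), Et = ca.E.cols(nb, 2 * nb - 1);
      tot += loss_and_grad(Es, Et, yb, c.k, c.m, delta, dEs, dEt);
      mat dE = arma::join_rows(dEs, dEt) / nb;
      for (auto* gm : gv) gm->zeros();
      backward(c, p, ca, dE, 2 * nb, g);
      ++step;
      const double corr = lr * std::sqrt(1.0 - std::pow(b2, (double)step)) /
                          (1.0 - std::pow(b1, (double)step));
      for (size_t q = 0; q < pv.size(); ++q) {
        *m1v[q] = b1 * (*m1v[q]) + (1.0 - b1) * (*gv[q]);
        *m2v[q] = b2 * (*m2v[q]) + (1.0 - b2) * arma::square(*gv[q]);
        *pv[q] -= corr * (*m1v[q]) / (arma::sqrt(*m2v[q]) + eps);
      }
    }
    epoch_loss[ep] = tot / n;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = params_to_list(p, c),
                      _["initial_loss"] = init_loss,
                      _["epoch_loss"] = epoch_loss);
}

// [[Rcpp::export]]
NumericVector contrastive_loss_batch_cpp(NumericMatrix Es, NumericMatrix Et,
                                         NumericVector y, int k, int m,
                                         double delta) {
  mat es(Es.begin(), Es.nrow(), Es.ncol(), false);
  mat et(Et.begin(), Et.nrow(), Et.ncol(), false);
  NumericVector out(Es.ncol());
  for (int b = 0; b < Es.ncol(); ++b) {
    double zmin = arma::datum::inf;
    for (int i = 0; i < k; ++i) {
      double ss = 0.0;
      for (int j = 0; j < m; ++j) {
        const double d = es((uword)i * m + j, b) - et((uword)i * m + j, b);
        ss += d * d;
      }
      zmin = std::min(zmin, std::sqrt(ss));
    }
    out[b] = std::max(0.0, (zmin - delta) * y[b]);
  }
  return out;
}
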