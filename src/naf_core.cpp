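// Neural attenuation field core: multi-resolution hash encoding feeding a
// 4-layer ReLU MLP (width 64 by default), trained with Adam on rays of a CT
// scan by matching predicted to measured normalized intensities
// (Beer-Lambert: I/I0 = exp(-sum mu_i * delta_i) over uniform ray samples).
//
// The training loop implements metal-trace-masked sampling: rays carry a
// class label (0 = metal trace, never sampled; 1 = reliable; 2 = metal-aware,
// i.e. reliable and within d_th of the trace) and metal-aware rays contribute
// a weighted squared error with per-ray weights w_hat, scaled by lambda_m.
// Batch composition is area-balanced: counts proportional to set sizes,
// sampled uniformly without replacement, metal-aware rays excluded from the
// reliable draw.  Everything is driven by one std::mt19937_64 so a seed fixes
// the run bit-for-bit.
//
// Performance notes: encoding tables are stored features-by-rows (F x T) so
// a corner gather touches one contiguous stripe; the Adam update on the
// tables is sparse (only rows touched by the current batch are stepped, with
// bias correction from the global step counter), which is the usual
// optimizer treatment for hash-grid parameters; the MLP runs through BLAS
// gemm on batched sample matrices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const unsigned HASH_P2 = 2654435761u;
static const unsigned HASH_P3 = 805459861u;

static inline double softplus(double z) {
  return z > 0 ? z + std::log1p(std::exp(-z)) : std::log1p(std::exp(z));
}

struct NafNet {
  int dim, L, F, Tlog2, width;
  std::vector<int> res;            // per-level grid resolution
  std::vector<int> Trows;          // per-level table entries
  std::vector<bool> dense;
  std::vector<arma::mat> tab;      // F x Trows (features contiguous)
  arma::mat W1, W2, W3, W4;        // Din x w, w x w, w x w, w x 1
  arma::rowvec b1, b2, b3, b4;

  int din() const { return L * F; }

  void setup_levels(int base_res, int finest_res) {
    res.resize(L); Trows.resize(L); dense.resize(L);
    double b = (L > 1) ? std::exp((std::log((double)finest_res) -
                                   std::log((double)base_res)) / (L - 1))
                       : 1.0;
    // every level allocates the full table; levels whose grid fits use
    // direct (injective) indexing, finer levels spatial hashing
    int maxT = 1 << Tlog2;
    for (int l = 0; l < L; ++l) {
      res[l] = std::max(2, (int)std::floor(base_res * std::pow(b, l) + 0.5));
      double full = std::pow((double)res[l] + 1.0, dim);
      dense[l] = full <= (double)maxT;
      Trows[l] = maxT;
    }
  }

  void init(std::mt19937_64& rng) {
    std::uniform_real_distribution<double> utab(-1e-4, 1e-4);
    tab.resize(L);
    for (int l = 0; l < L; ++l) {
      tab[l].set_size(F, Trows[l]);
      for (arma::uword i = 0; i < tab[l].n_elem; ++i) tab[l](i) = utab(rng);
    }
    auto he = [&](arma::mat& W, int fan_in) {
      double s = std::sqrt(6.0 / fan_in);
      std::uniform_real_distribution<double> u(-s, s);
      for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = u(rng);
    };
    W1.set_size(din(), width); he(W1, din());
    W2.set_size(width, width); he(W2, width);
    W3.set_size(width, width); he(W3, width);
    W4.set_size(width, 1);     he(W4, width);
    b1.zeros(width); b2.zeros(width); b3.zeros(width);
    // start the field near water-scale attenuation (softplus(-4) ~ 0.018):
    // a zero bias would put mu at softplus(0) ~ 0.69 mm^-1, saturating
    // exp(-sum mu delta) to zero on every ray and killing all gradients
    b4.set_size(1); b4.fill(-4.0);
  }

  long param_count() const {
    long n = 0;
    for (int l = 0; l < L; ++l) n += (long)Trows[l] * F;
    n += W1.n_elem + W2.n_elem + W3.n_elem + W4.n_elem;
    n += b1.n_elem + b2.n_elem + b3.n_elem + b4.n_elem;
    return n;
  }

  inline unsigned corner_index(int l, int ix, int iy, int iz) const {
    if (dense[l]) {
      unsigned r1 = (unsigned)res[l] + 1u;
      unsigned id = (unsigned)ix + r1 * (unsigned)iy;
      if (dim == 3) id += r1 * r1 * (unsigned)iz;
      return id;
    }
    unsigned h = (unsigned)ix ^ ((unsigned)iy * HASH_P2);
    if (dim == 3) h ^= (unsigned)iz * HASH_P3;
    return h & ((1u << Tlog2) - 1u);
  }

  // encode P points (X col-major, P x dim, components in [0,1]) into
  // FeatT (Din x P); optionally cache corner ids and weights (L*C x P).
  void encode(const double* X, int P, arma::mat& FeatT,
              arma::Mat<arma::u32>* cidx, arma::mat* cwt) const {
    int C = 1 << dim;
    FeatT.zeros(din(), P);
    double* FT = FeatT.memptr();
    for (int p = 0; p < P; ++p) {
      double xa[3] = {0, 0, 0};
      for (int a = 0; a < dim; ++a) {
        double v = X[p + (size_t)a * P];
        xa[a] = v < 0 ? 0 : (v > 1 ? 1 : v);
      }
      double* fcol = FT + (size_t)p * din();
      arma::u32* icol = cidx ? cidx->colptr(p) : nullptr;
      double* wcol = cwt ? cwt->colptr(p) : nullptr;
      for (int l = 0; l < L; ++l) {
        int r = res[l];
        int i0[3] = {0, 0, 0};
        double fr[3] = {0, 0, 0};
        for (int a = 0; a < dim; ++a) {
          double pos = xa[a] * r;
          int ia = (int)pos;
          if (ia > r - 1) ia = r - 1;
          i0[a] = ia; fr[a] = pos - ia;
        }
        const double* T = tab[l].memptr();
        for (int c = 0; c < C; ++c) {
          int ix = i0[0] + (c & 1);
          int iy = i0[1] + ((c >> 1) & 1);
          int iz = (dim == 3) ? i0[2] + ((c >> 2) & 1) : 0;
          double w = ((c & 1) ? fr[0] : 1 - fr[0]) *
                     (((c >> 1) & 1) ? fr[1] : 1 - fr[1]);
          if (dim == 3) w *= ((c >> 2) & 1) ? fr[2] : 1 - fr[2];
          unsigned id = corner_index(l, ix, iy, iz);
          const double* trow = T + (size_t)id * F;
          double* fdst = fcol + l * F;
          for (int f = 0; f < F; ++f) fdst[f] += w * trow[f];
          if (icol) { icol[l * C + c] = id; wcol[l * C + c] = w; }
        }
      }
    }
  }

  // forward MLP on FeatT (Din x P); caches activations for backward
  void mlp_forward(const arma::mat& FeatT, arma::mat& A1, arma::mat& A2,
                   arma::mat& A3, arma::vec& raw) const {
    A1 = FeatT.t() * W1; A1.each_row() += b1; relu_(A1);
    A2 = A1 * W2;        A2.each_row() += b2; relu_(A2);
    A3 = A2 * W3;        A3.each_row() += b3; relu_(A3);
    raw = A3 * W4 + b4(0);
  }

  static void relu_(arma::mat& M) {
    double* m = M.memptr();
    for (arma::uword i = 0; i < M.n_elem; ++i) if (m[i] < 0) m[i] = 0;
  }

  arma::vec field(const arma::mat& Xn) const {
    arma::mat FeatT, A1, A2, A3; arma::vec raw;
    encode(Xn.memptr(), Xn.n_rows, FeatT, nullptr, nullptr);
    mlp_forward(FeatT, A1, A2, A3, raw);
    arma::vec mu = raw;
    for (arma::uword i = 0; i < mu.n_elem; ++i) mu(i) = softplus(mu(i));
    return mu;
  }
};

// zero the gradient where the activation was clipped
static inline void relu_mask(arma::mat& G, const arma::mat& A) {
  double* g = G.memptr();
  const double* a = A.memptr();
  for (arma::uword i = 0; i < G.n_elem; ++i) if (a[i] == 0) g[i] = 0;
}

struct NafGrads {
  std::vector<arma::mat> tab;                 // F x Trows, sparse usage
  std::vector<std::vector<unsigned>> touched; // unique touched rows
  std::vector<std::vector<char>> flag;
  arma::mat W1, W2, W3, W4;
  arma::rowvec b1, b2, b3, b4;
  void zeros_like(const NafNet& net) {
    tab.resize(net.L); touched.resize(net.L); flag.resize(net.L);
    for (int l = 0; l < net.L; ++l) {
      tab[l].zeros(net.F, net.Trows[l]);
      touched[l].clear();
      flag[l].assign(net.Trows[l], 0);
    }
    W1.zeros(arma::size(net.W1)); W2.zeros(arma::size(net.W2));
    W3.zeros(arma::size(net.W3)); W4.zeros(arma::size(net.W4));
    b1.zeros(net.b1.n_elem); b2.zeros(net.b2.n_elem);
    b3.zeros(net.b3.n_elem); b4.zeros(net.b4.n_elem);
  }
  // reset only what the last batch touched
  void reset(const NafNet& net) {
    for (int l = 0; l < net.L; ++l) {
      for (unsigned id : touched[l]) {
        double* col = tab[l].colptr(id);
        for (int f = 0; f < net.F; ++f) col[f] = 0.0;
        flag[l][id] = 0;
      }
      touched[l].clear();
    }
    W1.zeros(); W2.zeros(); W3.zeros(); W4.zeros();
    b1.zeros(); b2.zeros(); b3.zeros(); b4.zeros();
  }
};

struct RaySet {
  const double *ox, *oy, *oz, *dx, *dy, *dz, *tn, *tf;
  double hx, hy, hz;
  int dim;
};

// normalized sample coordinates for the listed rays, N uniform mid-point
// samples each; rays missing the volume (tf <= tn) contribute none.
static void ray_points(const RaySet& rs, const std::vector<int>& ids, int N,
                       arma::mat& Xn, std::vector<double>& delta,
                       std::vector<int>& nsamp) {
  int B = ids.size();
  delta.assign(B, 0.0); nsamp.assign(B, 0);
  int tot = 0;
  for (int k = 0; k < B; ++k)
    if (rs.tf[ids[k]] > rs.tn[ids[k]]) { nsamp[k] = N; tot += N; }
  Xn.set_size(tot, rs.dim);
  double* x0 = Xn.colptr(0);
  double* x1 = Xn.colptr(1);
  double* x2 = rs.dim == 3 ? Xn.colptr(2) : nullptr;
  int row = 0;
  for (int k = 0; k < B; ++k) {
    if (!nsamp[k]) continue;
    int i = ids[k];
    double dl = (rs.tf[i] - rs.tn[i]) / N;
    delta[k] = dl;
    for (int s = 0; s < N; ++s) {
      double t = rs.tn[i] + (s + 0.5) * dl;
      x0[row] = (rs.ox[i] + t * rs.dx[i] + rs.hx) / (2.0 * rs.hx);
      x1[row] = (rs.oy[i] + t * rs.dy[i] + rs.hy) / (2.0 * rs.hy);
      if (x2) x2[row] = (rs.oz[i] + t * rs.dz[i] + rs.hz) / (2.0 * rs.hz);
      ++row;
    }
  }
}

struct Workspace {
  arma::mat Xn, FeatT, A1, A2, A3, cwt, gFeatT;
  arma::Mat<arma::u32> cidx;
  arma::vec raw, mu, gmu, graw;
  std::vector<double> delta;
  std::vector<int> nsamp;
};

// forward + backward for one batch of rays with per-ray loss coefficients
// (1 for reliable rays, lambda_m * w_hat for metal-aware rays).
// Loss = sum_k coef_k * (Ipred_k - y_k)^2.
static double batch_fwd_bwd(NafNet& net, NafGrads& g, Workspace& ws,
                            const RaySet& rs, const std::vector<int>& ids,
                            const std::vector<double>& coef,
                            const std::vector<int>& cls,
                            const double* y, int N,
                            double& recon_sum, double& ma_sum,
                            bool want_grad) {
  int B = ids.size(), C = 1 << net.dim;
  ray_points(rs, ids, N, ws.Xn, ws.delta, ws.nsamp);
  int P = ws.Xn.n_rows;
  if (want_grad) { ws.cidx.set_size(net.L * C, P); ws.cwt.set_size(net.L * C, P); }
  net.encode(ws.Xn.memptr(), P, ws.FeatT,
             want_grad ? &ws.cidx : nullptr, want_grad ? &ws.cwt : nullptr);
  net.mlp_forward(ws.FeatT, ws.A1, ws.A2, ws.A3, ws.raw);
  ws.mu.set_size(P);
  for (int p = 0; p < P; ++p) ws.mu(p) = softplus(ws.raw(p));

  double loss = 0.0;
  ws.gmu.zeros(P);
  int row = 0;
  for (int k = 0; k < B; ++k) {
    int i = ids[k];
    double s = 0.0;
    for (int q = 0; q < ws.nsamp[k]; ++q) s += ws.mu(row + q);
    s *= ws.delta[k];
    double Ip = std::exp(-s);
    double e = Ip - y[i];
    double term = e * e;
    // a metal-aware ray belongs to the reliable set too, so it carries its
    // plain reconstruction term plus the weighted metal-aware term
    double w = (cls[k] == 2) ? 1.0 + coef[k] : 1.0;
    if (cls[k] == 2) ma_sum += coef[k] * term; else recon_sum += term;
    loss += w * term;
    if (want_grad && ws.nsamp[k]) {
      double gs = -2.0 * w * e * Ip * ws.delta[k];
      for (int q = 0; q < ws.nsamp[k]; ++q) ws.gmu(row + q) = gs;
    }
    row += ws.nsamp[k];
  }
  if (!want_grad || P == 0) return loss;

  ws.graw.set_size(P);
  for (int p = 0; p < P; ++p)
    ws.graw(p) = ws.gmu(p) / (1.0 + std::exp(-ws.raw(p)));
  g.W4 += ws.A3.t() * ws.graw;
  g.b4(0) += arma::accu(ws.graw);
  arma::mat gA3 = ws.graw * net.W4.t();
  relu_mask(gA3, ws.A3);
  g.W3 += ws.A2.t() * gA3;
  g.b3 += arma::sum(gA3, 0);
  arma::mat gA2 = gA3 * net.W3.t();
  relu_mask(gA2, ws.A2);
  g.W2 += ws.A1.t() * gA2;
  g.b2 += arma::sum(gA2, 0);
  arma::mat gA1 = gA2 * net.W2.t();
  relu_mask(gA1, ws.A1);
  g.W1 += ws.FeatT * gA1;
  g.b1 += arma::sum(gA1, 0);
  ws.gFeatT = net.W1 * gA1.t();  // Din x P

  const double* GF = ws.gFeatT.memptr();
  for (int p = 0; p < P; ++p) {
    const arma::u32* icol = ws.cidx.colptr(p);
    const double* wcol = ws.cwt.colptr(p);
    const double* gcol = GF + (size_t)p * net.din();
    for (int l = 0; l < net.L; ++l) {
      arma::mat& gt = g.tab[l];
      for (int c = 0; c < C; ++c) {
        double w = wcol[l * C + c];
        if (w == 0.0) continue;
        unsigned id = icol[l * C + c];
        double* dst = gt.colptr(id);
        const double* src = gcol + l * net.F;
        for (int f = 0; f < net.F; ++f) dst[f] += w * src[f];
        if (!g.flag[l][id]) { g.flag[l][id] = 1; g.touched[l].push_back(id); }
      }
    }
  }
  return loss;
}

struct Adam {
  // dense state for MLP weights/biases, sparse-rowwise for tables
  std::vector<arma::mat> tm, tv;      // per level, F x Trows
  std::vector<arma::mat> m, v;        // MLP params
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void setup(const NafNet& net, const std::vector<arma::mat*>& mlp) {
    tm.resize(net.L); tv.resize(net.L);
    for (int l = 0; l < net.L; ++l) {
      tm[l].zeros(net.F, net.Trows[l]);
      tv[l].zeros(net.F, net.Trows[l]);
    }
    m.resize(mlp.size()); v.resize(mlp.size());
    for (size_t i = 0; i < mlp.size(); ++i) {
      m[i].zeros(arma::size(*mlp[i]));
      v[i].zeros(arma::size(*mlp[i]));
    }
  }
  void step(NafNet& net, NafGrads& g, std::vector<arma::mat*>& mlp,
            std::vector<arma::mat*>& mlp_g, double lr) {
    ++t;
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    for (int l = 0; l < net.L; ++l) {
      arma::mat& P = net.tab[l];
      for (unsigned id : g.touched[l]) {
        double* pm = tm[l].colptr(id);
        double* pv = tv[l].colptr(id);
        double* pg = g.tab[l].colptr(id);
        double* pp = P.colptr(id);
        for (int f = 0; f < net.F; ++f) {
          pm[f] = b1 * pm[f] + (1 - b1) * pg[f];
          pv[f] = b2 * pv[f] + (1 - b2) * pg[f] * pg[f];
          pp[f] -= lr * (pm[f] / c1) / (std::sqrt(pv[f] / c2) + eps);
        }
      }
    }
    for (size_t i = 0; i < mlp.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * (*mlp_g[i]);
      v[i] = b2 * v[i] + (1 - b2) * arma::square(*mlp_g[i]);
      *mlp[i] -= lr * (m[i] / c1) / (arma::sqrt(v[i] / c2) + eps);
    }
  }
};

static NafNet net_from_config(const List& cfg) {
  NafNet net;
  net.dim = as<int>(cfg["dim"]);
  net.L = as<int>(cfg["n_levels"]);
  net.F = as<int>(cfg["features_per_level"]);
  net.Tlog2 = as<int>(cfg["hash_log2"]);
  net.width = as<int>(cfg["width"]);
  net.setup_levels(as<int>(cfg["base_resolution"]),
                   as<int>(cfg["finest_resolution"]));
  return net;
}

static List net_to_list(const NafNet& net) {
  List tabs(net.L);
  for (int l = 0; l < net.L; ++l) tabs[l] = wrap(net.tab[l]);
  return List::create(
      _["dim"] = net.dim, _["n_levels"] = net.L,
      _["features_per_level"] = net.F, _["hash_log2"] = net.Tlog2,
      _["width"] = net.width,
      _["resolutions"] = wrap(net.res),
      _["table_rows"] = wrap(net.Trows),
      _["tables"] = tabs,
      _["W1"] = wrap(net.W1), _["b1"] = wrap(net.b1),
      _["W2"] = wrap(net.W2), _["b2"] = wrap(net.b2),
      _["W3"] = wrap(net.W3), _["b3"] = wrap(net.b3),
      _["W4"] = wrap(net.W4), _["b4"] = wrap(net.b4),
      _["param_count"] = (double)net.param_count());
}

static NafNet net_from_list(const List& p) {
  NafNet net;
  net.dim = as<int>(p["dim"]);
  net.L = as<int>(p["n_levels"]);
  net.F = as<int>(p["features_per_level"]);
  net.Tlog2 = as<int>(p["hash_log2"]);
  net.width = as<int>(p["width"]);
  net.res = as<std::vector<int>>(p["resolutions"]);
  net.Trows = as<std::vector<int>>(p["table_rows"]);
  net.dense.resize(net.L);
  int maxT = 1 << net.Tlog2;
  for (int l = 0; l < net.L; ++l)
    net.dense[l] = std::pow((double)net.res[l] + 1.0, net.dim) <= (double)maxT;
  List tabs = p["tables"];
  net.tab.resize(net.L);
  for (int l = 0; l < net.L; ++l) net.tab[l] = as<arma::mat>(tabs[l]);
  net.W1 = as<arma::mat>(p["W1"]); net.W2 = as<arma::mat>(p["W2"]);
  net.W3 = as<arma::mat>(p["W3"]); net.W4 = as<arma::mat>(p["W4"]);
  net.b1 = as<arma::rowvec>(p["b1"]); net.b2 = as<arma::rowvec>(p["b2"]);
  net.b3 = as<arma::rowvec>(p["b3"]); net.b4 = as<arma::rowvec>(p["b4"]);
  return net;
}

static RaySet make_rayset(const NumericMatrix& origin, const NumericMatrix& dir,
                          const NumericVector& tnear, const NumericVector& tfar,
                          const NumericVector& half_extent, int dim) {
  RaySet rs;
  rs.ox = &origin(0, 0); rs.oy = &origin(0, 1); rs.oz = &origin(0, 2);
  rs.dx = &dir(0, 0); rs.dy = &dir(0, 1); rs.dz = &dir(0, 2);
  rs.tn = REAL(tnear); rs.tf = REAL(tfar);
  rs.hx = half_extent[0]; rs.hy = half_extent[1]; rs.hz = half_extent[2];
  rs.dim = dim;
  return rs;
}

// [[Rcpp::export]]
List cpp_naf_train(NumericMatrix origin, NumericMatrix dir,
                   NumericVector tnear, NumericVector tfar,
                   NumericVector y, IntegerVector ray_class,
                   NumericVector w_hat, NumericVector half_extent,
                   List config) {
  NafNet net = net_from_config(config);
  int N = as<int>(config["n_samples"]);
  int batch = as<int>(config["batch_rays"]);
  int epochs = as<int>(config["epochs"]);
  double lr0 = as<double>(config["lr"]);
  double lr_decay = as<double>(config["lr_decay"]);
  int decay_every = as<int>(config["decay_every"]);
  double lambda_m = as<double>(config["lambda_m"]);
  unsigned long seed = (unsigned long)as<double>(config["seed"]);
  bool verbose = as<bool>(config["verbose"]);

  std::mt19937_64 rng(seed);
  net.init(rng);
  RaySet rs = make_rayset(origin, dir, tnear, tfar, half_extent, net.dim);

  int n = y.size();
  std::vector<int> pool1, pool2;
  for (int i = 0; i < n; ++i) {
    if (ray_class[i] == 1) pool1.push_back(i);
    else if (ray_class[i] == 2) pool2.push_back(i);
  }
  long n1 = pool1.size(), n2 = pool2.size();
  if (n1 + n2 == 0) stop("no reliable rays to train on (trace covers all rays)");
  int n_m = (int)std::lround((double)batch * n2 / (double)(n1 + n2));
  if (n_m > n2) n_m = (int)n2;
  int n_r = batch - n_m;
  if (n_r > n1) stop("batch size exceeds available reliable rays");
  long steps_per_epoch = (n1 + n2 + batch - 1) / batch;

  NafGrads g; g.zeros_like(net);
  Workspace ws;
  // biases live in 1 x w matrices for the dense Adam path
  arma::mat B1(net.b1), B2(net.b2), B3(net.b3), B4(net.b4);
  arma::mat GB1(1, net.width), GB2(1, net.width), GB3(1, net.width), GB4(1, 1);
  std::vector<arma::mat*> mlp = {&net.W1, &net.W2, &net.W3, &net.W4,
                                 &B1, &B2, &B3, &B4};
  std::vector<arma::mat*> mlp_g = {&g.W1, &g.W2, &g.W3, &g.W4,
                                   &GB1, &GB2, &GB3, &GB4};
  Adam opt; opt.setup(net, mlp);

  long trace_sampled = 0, total_steps = 0;
  NumericMatrix log(epochs, 3);
  const double* py = REAL(y);
  const double* pw = REAL(w_hat);

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_recon = 0.0, ep_ma = 0.0;
    long ep_nr = 0, ep_nm = 0;
    double lr = lr0 * std::pow(lr_decay, (double)(ep / decay_every));
    for (long st = 0; st < steps_per_epoch; ++st) {
      std::vector<int> ids; ids.reserve(batch);
      std::vector<double> coef; coef.reserve(batch);
      std::vector<int> cls; cls.reserve(batch);
      for (int k = 0; k < n_r; ++k) {
        long j = k + (long)(rng() % (unsigned long)(n1 - k));
        std::swap(pool1[k], pool1[j]);
        ids.push_back(pool1[k]); coef.push_back(1.0); cls.push_back(1);
      }
      for (int k = 0; k < n_m; ++k) {
        long j = k + (long)(rng() % (unsigned long)(n2 - k));
        std::swap(pool2[k], pool2[j]);
        ids.push_back(pool2[k]);
        coef.push_back(lambda_m * pw[pool2[k]]);
        cls.push_back(2);
      }
      for (int k = 0; k < (int)ids.size(); ++k)
        if (ray_class[ids[k]] == 0) ++trace_sampled;
      g.reset(net);
      double recon = 0.0, ma = 0.0;
      batch_fwd_bwd(net, g, ws, rs, ids, coef, cls, py, N, recon, ma, true);
      if (!std::isfinite(recon) || !std::isfinite(ma))
        stop("NAF training diverged (non-finite loss) at epoch %d", ep + 1);
      GB1 = g.b1; GB2 = g.b2; GB3 = g.b3; GB4 = g.b4;
      opt.step(net, g, mlp, mlp_g, lr);
      net.b1 = B1.row(0); net.b2 = B2.row(0);
      net.b3 = B3.row(0); net.b4 = B4.row(0);
      ep_recon += recon; ep_ma += ma;
      ep_nr += n_r; ep_nm += n_m;
      ++total_steps;
    }
    log(ep, 0) = ep + 1;
    log(ep, 1) = ep_nr ? ep_recon / ep_nr : NA_REAL;
    log(ep, 2) = ep_nm ? ep_ma / ep_nm : NA_REAL;
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << "/" << epochs
                  << "  recon " << log(ep, 1)
                  << "  metal-aware " << log(ep, 2) << std::endl;
    Rcpp::checkUserInterrupt();
  }

  List out = net_to_list(net);
  out["log"] = log;
  out["trace_sampled"] = (double)trace_sampled;
  out["n_steps"] = (double)total_steps;
  out["n_reliable"] = (double)n1;
  out["n_metal_aware"] = (double)n2;
  out["batch_reliable"] = n_r;
  out["batch_metal_aware"] = n_m;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_naf_eval(List params, NumericMatrix coords) {
  NafNet net = net_from_list(params);
  if ((int)coords.ncol() != net.dim) stop("coordinate dimension mismatch");
  arma::mat X = as<arma::mat>(coords);
  arma::uword nbad = arma::accu(X < 0.0) + arma::accu(X > 1.0);
  X.clamp(0.0, 1.0);
  arma::vec mu(X.n_rows);
  const arma::uword chunk = 65536;
  for (arma::uword s = 0; s < X.n_rows; s += chunk) {
    arma::uword e = std::min(X.n_rows, s + chunk) - 1;
    mu.subvec(s, e) = net.field(X.rows(s, e));
  }
  NumericVector out = wrap(mu);
  out.attr("n_clamped") = (double)nbad;
  return out;
}

// [[Rcpp::export]]
List cpp_naf_predict(List params, NumericMatrix origin, NumericMatrix dir,
                     NumericVector tnear, NumericVector tfar,
                     int n_samples, NumericVector half_extent) {
  NafNet net = net_from_list(params);
  RaySet rs = make_rayset(origin, dir, tnear, tfar, half_extent, net.dim);
  int n = origin.nrow();
  NumericVector I(n), p(n);
  const int chunk = 2048;
  arma::mat Xn; std::vector<double> delta; std::vector<int> nsamp;
  for (int s = 0; s < n; s += chunk) {
    int e = std::min(n, s + chunk);
    std::vector<int> ids(e - s);
    for (int i = s; i < e; ++i) ids[i - s] = i;
    ray_points(rs, ids, n_samples, Xn, delta, nsamp);
    arma::vec mu = Xn.n_rows ? net.field(Xn) : arma::vec();
    int row = 0;
    for (size_t k = 0; k < ids.size(); ++k) {
      double sum = 0.0;
      for (int q = 0; q < nsamp[k]; ++q) sum += mu(row + q);
      sum *= delta[k];
      p[ids[k]] = sum;
      I[ids[k]] = std::exp(-sum);
      row += nsamp[k];
    }
  }
  return List::create(_["intensity"] = I, _["line_integral"] = p);
}

// loss and full gradient for a set of rays with per-ray coefficients;
// used by finite-difference checks, not by the training hot path.
// [[Rcpp::export]]
List cpp_naf_grad(List params, NumericMatrix origin, NumericMatrix dir,
                  NumericVector tnear, NumericVector tfar,
                  NumericVector y, NumericVector coef,
                  int n_samples, NumericVector half_extent) {
  NafNet net = net_from_list(params);
  RaySet rs = make_rayset(origin, dir, tnear, tfar, half_extent, net.dim);
  int n = origin.nrow();
  std::vector<int> ids(n); std::vector<double> cf(n); std::vector<int> cls(n, 2);
  for (int i = 0; i < n; ++i) { ids[i] = i; cf[i] = coef[i]; }
  NafGrads g; g.zeros_like(net);
  Workspace ws;
  double recon = 0.0, ma = 0.0;
  double loss = batch_fwd_bwd(net, g, ws, rs, ids, cf, cls, REAL(y),
                              n_samples, recon, ma, true);
  List tabs(net.L);
  for (int l = 0; l < net.L; ++l) tabs[l] = wrap(g.tab[l]);
  return List::create(_["loss"] = loss, _["g_tables"] = tabs,
                      _["g_W1"] = wrap(g.W1), _["g_b1"] = wrap(g.b1),
                      _["g_W2"] = wrap(g.W2), _["g_b2"] = wrap(g.b2),
                      _["g_W3"] = wrap(g.W3), _["g_b3"] = wrap(g.b3),
                      _["g_W4"] = wrap(g.W4), _["g_b4"] = wrap(g.b4));
}

// [[Rcpp::export]]
List cpp_naf_init(List config, double seed) {
  NafNet net = net_from_config(config);
  std::mt19937_64 rng((unsigned long)seed);
  net.init(rng);
  return net_to_list(net);
}
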