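// Bidirectional LSTM multiclass classifier with a (by default frozen)
// embedding layer, trained with Adam + 1/(1 + decay*t) learning-rate decay
// and sparse categorical cross-entropy.  Batched forward / BPTT over
// right-padded integer sequences (0 = padding).  The input projections
// (W * X, dW, dX) are hoisted out of the timestep recursion into single
// large GEMMs over all timesteps of a batch; only the U * h recursions run
// step by step.  All randomness comes from a private mt19937, so runs are
// reproducible given the seed.
#include <RcppArmadillo.h>
#include <random>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static mat glorot(int r, int c, std::mt19937& rng) {
  double lim = std::sqrt(6.0 / (double)(r + c));
  std::uniform_real_distribution<double> un(-lim, lim);
  mat M(r, c);
  for (uword i = 0; i < M.n_elem; ++i) M(i) = un(rng);
  return M;
}

// Parameter bundle: per direction W (4U x D), U (4U x U), b (4U);
// output layer Wo (C x 2U), bo (C).  Gate order: input, forget, cell, out.
struct Net {
  mat Wf, Uf, Wb, Ub, Wo;
  vec bf, bb, bo;
  int units, dim, n_classes;
};

static Net net_from_list(const List& w) {
  Net n;
  n.Wf = as<mat>(w["W_f"]); n.Uf = as<mat>(w["U_f"]); n.bf = as<vec>(w["b_f"]);
  n.Wb = as<mat>(w["W_b"]); n.Ub = as<mat>(w["U_b"]); n.bb = as<vec>(w["b_b"]);
  n.Wo = as<mat>(w["W_out"]); n.bo = as<vec>(w["b_out"]);
  n.units = n.Uf.n_cols; n.dim = n.Wf.n_cols; n.n_classes = n.Wo.n_rows;
  return n;
}

static List net_to_list(const Net& n) {
  return List::create(
    _["W_f"] = n.Wf, _["U_f"] = n.Uf, _["b_f"] = n.bf,
    _["W_b"] = n.Wb, _["U_b"] = n.Ub, _["b_b"] = n.bb,
    _["W_out"] = n.Wo, _["b_out"] = n.bo);
}

// [[Rcpp::export]]
List cpp_blstm_init(int dim, int units, int n_classes, int seed) {
  std::mt19937 rng((unsigned)seed);
  Net n;
  n.Wf = glorot(4 * units, dim, rng);
  n.Uf = glorot(4 * units, units, rng);
  n.bf = zeros<vec>(4 * units);
  n.bf.subvec(units, 2 * units - 1).fill(1.0);  // forget-gate bias init
  n.Wb = glorot(4 * units, dim, rng);
  n.Ub = glorot(4 * units, units, rng);
  n.bb = zeros<vec>(4 * units);
  n.bb.subvec(units, 2 * units - 1).fill(1.0);
  n.Wo = glorot(n_classes, 2 * units, rng);
  n.bo = zeros<vec>(n_classes);
  return net_to_list(n);
}

// Per-direction activation cache for BPTT.  Slabs are U x (b*T): step t
// occupies columns [t*b, (t+1)*b).
struct DirCache {
  mat gi, gf, gg, go, c_tilde, tc, hprev, cprev;
  mat h_final;
};

// Batch workspace shared by both directions: gathered inputs (post-dropout)
// and the padding mask.
struct BatchInput {
  mat X;        // D x (b*T)
  mat dropmask; // same shape, empty when no dropout
  rowvec m;     // 1 x (b*T), 1 = real token
  imat S;       // b x T (0-based embedding rows, 0 = pad)
  int b, T;
};

static void gather_inputs(const mat& emb, const imat& S, double dropout,
                          bool train, std::mt19937& rng, BatchInput& bi) {
  const int b = S.n_rows, T = S.n_cols, D = emb.n_cols;
  bi.S = S; bi.b = b; bi.T = T;
  bi.X.set_size(D, b * T);
  bi.m.set_size(b * T);
  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < b; ++j) {
      int v = S(j, t);
      bi.X.col(t * b + j) = emb.row(v).t();
      bi.m(t * b + j) = v > 0 ? 1.0 : 0.0;
    }
  }
  if (train && dropout > 0.0) {
    std::uniform_real_distribution<double> un(0.0, 1.0);
    const double keep = 1.0 - dropout;
    bi.dropmask.set_size(D, b * T);
    for (uword i = 0; i < bi.dropmask.n_elem; ++i)
      bi.dropmask(i) = un(rng) < keep ? 1.0 / keep : 0.0;
    bi.X %= bi.dropmask;
  } else {
    bi.dropmask.reset();
  }
}

// One direction over a batch.  forward_dir == true processes t = 0..T-1
// (final state after the last real token); false processes t = T-1..0.
// State carries through masked (padding) steps unchanged.
static void run_dir(const mat& W, const mat& U, const vec& b_,
                    const BatchInput& bi, bool forward_dir, int units,
                    DirCache& cache, bool keep_cache) {
  const int b = bi.b, T = bi.T;
  mat WX = W * bi.X;            // one big GEMM: 4U x (b*T)
  WX.each_col() += b_;
  mat h(units, b, fill::zeros), c(units, b, fill::zeros);
  if (keep_cache) {
    cache.gi.set_size(units, b * T); cache.gf.set_size(units, b * T);
    cache.gg.set_size(units, b * T); cache.go.set_size(units, b * T);
    cache.c_tilde.set_size(units, b * T); cache.tc.set_size(units, b * T);
    cache.hprev.set_size(units, b * T); cache.cprev.set_size(units, b * T);
  }
  for (int s = 0; s < T; ++s) {
    int t = forward_dir ? s : T - 1 - s;
    span cols(t * b, (t + 1) * b - 1);
    mat z = WX.cols(cols) + U * h;
    mat gi = sigm(z.rows(0, units - 1));
    mat gf = sigm(z.rows(units, 2 * units - 1));
    mat gg = tanh(z.rows(2 * units, 3 * units - 1));
    mat go = sigm(z.rows(3 * units, 4 * units - 1));
    mat c_tilde = gf % c + gi % gg;
    mat tc = tanh(c_tilde);
    rowvec m = bi.m.cols(cols.a, cols.b);
    rowvec im = 1.0 - m;
    if (keep_cache) {
      cache.gi.cols(cols) = gi; cache.gf.cols(cols) = gf;
      cache.gg.cols(cols) = gg; cache.go.cols(cols) = go;
      cache.c_tilde.cols(cols) = c_tilde; cache.tc.cols(cols) = tc;
      cache.hprev.cols(cols) = h; cache.cprev.cols(cols) = c;
    }
    mat hn = go % tc; hn.each_row() %= m;
    mat hc = h;       hc.each_row() %= im;
    h = hn + hc;
    c_tilde.each_row() %= m;
    c.each_row() %= im;
    c += c_tilde;
  }
  cache.h_final = h;
}

// BPTT for one direction.  dz for all steps is assembled into one slab so
// dW and dX come from single GEMMs afterwards.
static void back_dir(const mat& W, const mat& U, const DirCache& cc,
                     const BatchInput& bi, bool forward_dir,
                     const mat& dh_final, int units,
                     mat& dW, mat& dU, vec& db, mat& dz_all) {
  const int b = bi.b, T = bi.T;
  dz_all.zeros(4 * units, b * T);
  mat dh = dh_final;
  mat dc(units, b, fill::zeros);
  for (int s = T - 1; s >= 0; --s) {
    int t = forward_dir ? s : T - 1 - s;
    span cols(t * b, (t + 1) * b - 1);
    rowvec m = bi.m.cols(cols.a, cols.b);
    rowvec im = 1.0 - m;
    mat dh_a = dh; dh_a.each_row() %= m;
    mat dc_a = dc; dc_a.each_row() %= m;
    mat tc = cc.tc.cols(cols), go = cc.go.cols(cols);
    mat gi = cc.gi.cols(cols), gf = cc.gf.cols(cols), gg = cc.gg.cols(cols);
    mat dgo = dh_a % tc;
    mat dct = dc_a + dh_a % go % (1.0 - square(tc));
    mat dz(4 * units, b);
    dz.rows(0, units - 1)             = (dct % gg) % gi % (1.0 - gi);
    dz.rows(units, 2 * units - 1)     = (dct % cc.cprev.cols(cols)) % gf % (1.0 - gf);
    dz.rows(2 * units, 3 * units - 1) = (dct % gi) % (1.0 - square(gg));
    dz.rows(3 * units, 4 * units - 1) = dgo % go % (1.0 - go);
    dz_all.cols(cols) = dz;
    dU += dz * cc.hprev.cols(cols).t();
    mat dh_c = dh; dh_c.each_row() %= im;
    dh = U.t() * dz + dh_c;
    mat dc_c = dc; dc_c.each_row() %= im;
    dc = dct % gf + dc_c;
  }
  dW += dz_all * bi.X.t();   // one big GEMM
  db += sum(dz_all, 1);
}

// Forward pass to class probabilities for a gathered batch.
static mat forward_batch(const Net& n, const BatchInput& bi,
                         DirCache& cf, DirCache& cb, bool keep_cache) {
  run_dir(n.Wf, n.Uf, n.bf, bi, true, n.units, cf, keep_cache);
  run_dir(n.Wb, n.Ub, n.bb, bi, false, n.units, cb, keep_cache);
  mat H = join_cols(cf.h_final, cb.h_final);
  mat logits = n.Wo * H;
  logits.each_col() += n.bo;
  logits.each_row() -= max(logits, 0);
  mat P = exp(logits);
  P.each_row() /= sum(P, 0);
  return P;
}

// Trim a batch's columns to the longest sequence in it (padding is on the
// right, so dropping all-pad columns changes nothing).
static imat gather_batch(const IntegerMatrix& seqs, const std::vector<int>& rows) {
  int T = seqs.ncol();
  int maxlen = 1;
  for (int r : rows) {
    int len = 0;
    for (int t = 0; t < T; ++t) if (seqs(r, t) > 0) len = t + 1;
    if (len > maxlen) maxlen = len;
  }
  imat S(rows.size(), maxlen);
  for (size_t j = 0; j < rows.size(); ++j)
    for (int t = 0; t < maxlen; ++t) S(j, t) = seqs(rows[j], t);
  return S;
}

struct Adam {
  std::vector<mat> m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-7;
  long t = 0;
  void init(const std::vector<const mat*>& params) {
    for (auto p : params) { m.push_back(zeros<mat>(p->n_rows, p->n_cols));
                            v.push_back(zeros<mat>(p->n_rows, p->n_cols)); }
  }
  void step(std::vector<mat*> params, const std::vector<mat*>& grads,
            double lr, double decay) {
    ++t;
    double lr_t = lr / (1.0 + decay * (double)t);
    double c1 = 1.0 - std::pow(b1, (double)t);
    double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = b1 * m[i] + (1.0 - b1) * (*grads[i]);
      v[i] = b2 * v[i] + (1.0 - b2) * square(*grads[i]);
      *params[i] -= lr_t * (m[i] / c1) / (sqrt(v[i] / c2) + eps);
    }
  }
};

static void eval_metrics(const Net& n, const mat& emb, const IntegerMatrix& seqs,
                         const IntegerVector& y, double& loss, double& acc) {
  std::mt19937 dummy(0);
  DirCache cf, cb;
  BatchInput bi;
  int nobs = seqs.nrow();
  double L = 0; long correct = 0;
  const int chunk = 64;
  for (int start = 0; start < nobs; start += chunk) {
    int end = std::min(nobs, start + chunk);
    std::vector<int> rows;
    for (int r = start; r < end; ++r) rows.push_back(r);
    imat S = gather_batch(seqs, rows);
    gather_inputs(emb, S, 0.0, false, dummy, bi);
    mat P = forward_batch(n, bi, cf, cb, false);
    for (size_t j = 0; j < rows.size(); ++j) {
      int yj = y[rows[j]];
      double p = std::max(P(yj, j), 1e-12);
      L += -std::log(p);
      if ((int)index_max(P.col(j)) == yj) ++correct;
    }
  }
  loss = nobs ? L / nobs : NA_REAL;
  acc = nobs ? (double)correct / nobs : NA_REAL;
}

// [[Rcpp::export]]
List cpp_blstm_fit(List weights, NumericMatrix emb_in, IntegerMatrix seqs,
                   IntegerVector y, Nullable<IntegerMatrix> vseqs_,
                   Nullable<IntegerVector> vy_, int epochs, int batch_size,
                   double lr, double decay, double dropout, bool trainable,
                   int seed, double clipnorm) {
  Net n = net_from_list(weights);
  mat emb = as<mat>(emb_in);
  std::mt19937 rng((unsigned)seed + 0x9e3779b9u);
  const int nobs = seqs.nrow();
  const bool has_val = vseqs_.isNotNull();
  IntegerMatrix vseqs;
  IntegerVector vy;
  if (has_val) { vseqs = as<IntegerMatrix>(vseqs_); vy = as<IntegerVector>(vy_); }

  Adam adam;
  adam.init({&n.Wf, &n.Uf, &n.Wb, &n.Ub, &n.Wo});
  Adam adam_vec;
  mat bf_m(n.bf), bb_m(n.bb), bo_m(n.bo);
  adam_vec.init({&bf_m, &bb_m, &bo_m});
  Adam adam_emb;
  if (trainable) adam_emb.init({&emb});

  mat history(epochs, 4);  // train_loss, train_acc, val_loss, val_acc
  std::vector<int> perm(nobs);
  for (int i = 0; i < nobs; ++i) perm[i] = i;

  BatchInput bi;
  DirCache cf, cb;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double ep_loss = 0; long ep_correct = 0; long ep_seen = 0;
    for (int start = 0; start < nobs; start += batch_size) {
      int end = std::min(nobs, start + batch_size);
      std::vector<int> rows(perm.begin() + start, perm.begin() + end);
      int bsz = (int)rows.size();
      imat S = gather_batch(seqs, rows);
      gather_inputs(emb, S, dropout, true, rng, bi);
      mat P = forward_batch(n, bi, cf, cb, true);
      // loss / accuracy on the training batch (pre-update running mean)
      mat dlogits = P;
      for (int j = 0; j < bsz; ++j) {
        int yj = y[rows[j]];
        double p = std::max(P(yj, j), 1e-12);
        ep_loss += -std::log(p);
        if ((int)index_max(P.col(j)) == yj) ++ep_correct;
        dlogits(yj, j) -= 1.0;
      }
      ep_seen += bsz;
      dlogits /= (double)bsz;
      mat H = join_cols(cf.h_final, cb.h_final);
      mat dWo = dlogits * H.t();
      vec dbo = sum(dlogits, 1);
      mat dH = n.Wo.t() * dlogits;
      mat dWf(size(n.Wf), fill::zeros), dUf(size(n.Uf), fill::zeros);
      mat dWb(size(n.Wb), fill::zeros), dUb(size(n.Ub), fill::zeros);
      vec dbf(4 * n.units, fill::zeros), dbb(4 * n.units, fill::zeros);
      mat dzf, dzb;
      back_dir(n.Wf, n.Uf, cf, bi, true, dH.rows(0, n.units - 1),
               n.units, dWf, dUf, dbf, dzf);
      back_dir(n.Wb, n.Ub, cb, bi, false, dH.rows(n.units, 2 * n.units - 1),
               n.units, dWb, dUb, dbb, dzb);
      mat dEmb;
      if (trainable) {
        mat dX = n.Wf.t() * dzf + n.Wb.t() * dzb;  // two big GEMMs
        if (bi.dropmask.n_elem) dX %= bi.dropmask;
        dEmb = zeros<mat>(emb.n_rows, emb.n_cols);
        for (int t = 0; t < bi.T; ++t)
          for (int j = 0; j < bi.b; ++j) {
            int v = S(j, t);
            if (v > 0) dEmb.row(v) += dX.col(t * bi.b + j).t();
          }
      }
      if (clipnorm > 0.0) {
        // clip the global gradient norm (standard protection against
        // exploding gradients through long BPTT)
        double sq = accu(square(dWf)) + accu(square(dUf)) + accu(square(dbf)) +
                    accu(square(dWb)) + accu(square(dUb)) + accu(square(dbb)) +
                    accu(square(dWo)) + accu(square(dbo));
        if (trainable) sq += accu(square(dEmb));
        double gnorm = std::sqrt(sq);
        if (gnorm > clipnorm) {
          double sc = clipnorm / gnorm;
          dWf *= sc; dUf *= sc; dbf *= sc; dWb *= sc; dUb *= sc; dbb *= sc;
          dWo *= sc; dbo *= sc;
          if (trainable) dEmb *= sc;
        }
      }
      adam.step({&n.Wf, &n.Uf, &n.Wb, &n.Ub, &n.Wo},
                {&dWf, &dUf, &dWb, &dUb, &dWo}, lr, decay);
      mat dbf_m(dbf), dbb_m(dbb), dbo_m(dbo);
      adam_vec.step({&bf_m, &bb_m, &bo_m}, {&dbf_m, &dbb_m, &dbo_m}, lr, decay);
      n.bf = bf_m.col(0); n.bb = bb_m.col(0); n.bo = bo_m.col(0);
      if (trainable) {
        dEmb.row(0).zeros();  // padding row stays zero
        adam_emb.step({&emb}, {&dEmb}, lr, decay);
        emb.row(0).zeros();
      }
    }
    history(ep, 0) = ep_seen ? ep_loss / ep_seen : NA_REAL;
    history(ep, 1) = ep_seen ? (double)ep_correct / ep_seen : NA_REAL;
    if (has_val) {
      double vl, va;
      eval_metrics(n, emb, vseqs, vy, vl, va);
      history(ep, 2) = vl; history(ep, 3) = va;
    } else {
      history(ep, 2) = NA_REAL; history(ep, 3) = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = net_to_list(n),
                      _["embedding"] = wrap(emb),
                      _["history"] = wrap(history));
}

// [[Rcpp::export]]
NumericMatrix cpp_blstm_probs(List weights, NumericMatrix emb_in,
                              IntegerMatrix seqs) {
  Net n = net_from_list(weights);
  mat emb = as<mat>(emb_in);
  std::mt19937 dummy(0);
  DirCache cf, cb;
  BatchInput bi;
  int nobs = seqs.nrow();
  mat out(n.n_classes, nobs);
  const int chunk = 64;
  for (int start = 0; start < nobs; start += chunk) {
    int end = std::min(nobs, start + chunk);
    std::vector<int> rows;
    for (int r = start; r < end; ++r) rows.push_back(r);
    imat S = gather_batch(seqs, rows);
    gather_inputs(emb, S, 0.0, false, dummy, bi);
    mat P = forward_batch(n, bi, cf, cb, false);
    for (size_t j = 0; j < rows.size(); ++j) out.col(rows[j]) = P.col(j);
  }
  return wrap(out.t());
}
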