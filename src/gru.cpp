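// GRU Seq2Seq core: forward propagation with full state capture and
// backpropagation through time, including the decoder feedback path
// (the decoder consumes its own previous output, so gradients flow
// through the output layer back into the next step's input).
//
// Gate convention (PyTorch/cuDNN ordering r, z, n):
//   r_t = sigmoid(W_r x_t + bx_r + U_r h_{t-1} + bh_r)
//   z_t = sigmoid(W_z x_t + bx_z + U_z h_{t-1} + bh_z)
//   n_t = tanh   (W_n x_t + bx_n + r_t . (U_n h_{t-1} + bh_n))
//   h_t = (1 - z_t) . n_t + z_t . h_{t-1}
// With all parameters and inputs zero, h stays exactly zero (tanh(0) = 0),
// which the embedding relies on: encoder trajectories start at the origin.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Cell {
  mat W;   // 3N x M
  mat U;   // 3N x N
  vec bx;  // 3N
  vec bh;  // 3N
};

struct Out {
  mat Wy;  // M x N
  vec by;  // M
};

inline arma::uword cell_size(arma::uword N, arma::uword M) {
  return 3 * N * M + 3 * N * N + 6 * N;
}

Cell unpack_cell(const vec& theta, arma::uword off, arma::uword N, arma::uword M) {
  Cell c;
  c.W  = reshape(theta.subvec(off, off + 3 * N * M - 1), 3 * N, M);
  off += 3 * N * M;
  c.U  = reshape(theta.subvec(off, off + 3 * N * N - 1), 3 * N, N);
  off += 3 * N * N;
  c.bx = theta.subvec(off, off + 3 * N - 1);
  off += 3 * N;
  c.bh = theta.subvec(off, off + 3 * N - 1);
  return c;
}

Out unpack_out(const vec& theta, arma::uword off, arma::uword N, arma::uword M) {
  Out o;
  o.Wy = reshape(theta.subvec(off, off + M * N - 1), M, N);
  off += M * N;
  o.by = theta.subvec(off, off + M - 1);
  return o;
}

void pack_cell(vec& g, arma::uword off, const Cell& c) {
  arma::uword N = c.U.n_cols, M = c.W.n_cols;
  g.subvec(off, off + 3 * N * M - 1) += vectorise(c.W);
  off += 3 * N * M;
  g.subvec(off, off + 3 * N * N - 1) += vectorise(c.U);
  off += 3 * N * N;
  g.subvec(off, off + 3 * N - 1) += c.bx;
  off += 3 * N;
  g.subvec(off, off + 3 * N - 1) += c.bh;
}

inline vec sigmoid(const vec& x) { return 1.0 / (1.0 + exp(-x)); }

// One GRU step; caches gate activations for the backward pass.
struct StepCache {
  vec x, h_prev, r, z, n, k;  // k = U_n h_{t-1} + bh_n
};

vec gru_step(const Cell& c, const vec& x, const vec& h, arma::uword N,
             StepCache* cache) {
  vec ax = c.W * x + c.bx;
  vec ah = c.U * h + c.bh;
  vec r = sigmoid(ax.subvec(0, N - 1) + ah.subvec(0, N - 1));
  vec z = sigmoid(ax.subvec(N, 2 * N - 1) + ah.subvec(N, 2 * N - 1));
  vec k = ah.subvec(2 * N, 3 * N - 1);
  vec n = tanh(ax.subvec(2 * N, 3 * N - 1) + r % k);
  vec h_new = (1.0 - z) % n + z % h;
  if (cache) {
    cache->x = x; cache->h_prev = h; cache->r = r; cache->z = z;
    cache->n = n; cache->k = k;
  }
  return h_new;
}

// Backward through one GRU step. dh_new is d(loss)/d(h_t); accumulates
// parameter gradients into gc, returns dh_prev, writes d(loss)/d(x_t).
vec gru_step_back(const Cell& c, Cell& gc, const StepCache& s,
                  const vec& dh_new, arma::uword N, vec& dx) {
  vec dz = dh_new % (s.h_prev - s.n);
  vec dn = dh_new % (1.0 - s.z);
  vec dh_prev = dh_new % s.z;

  vec dan = dn % (1.0 - s.n % s.n);
  vec dr  = dan % s.k;
  vec dk  = dan % s.r;
  vec dar = dr % s.r % (1.0 - s.r);
  vec daz = dz % s.z % (1.0 - s.z);

  gc.W.rows(0, N - 1)         += dar * s.x.t();
  gc.W.rows(N, 2 * N - 1)     += daz * s.x.t();
  gc.W.rows(2 * N, 3 * N - 1) += dan * s.x.t();
  gc.U.rows(0, N - 1)         += dar * s.h_prev.t();
  gc.U.rows(N, 2 * N - 1)     += daz * s.h_prev.t();
  gc.U.rows(2 * N, 3 * N - 1) += dk * s.h_prev.t();
  gc.bx.subvec(0, N - 1)         += dar;
  gc.bx.subvec(N, 2 * N - 1)     += daz;
  gc.bx.subvec(2 * N, 3 * N - 1) += dan;
  gc.bh.subvec(0, N - 1)         += dar;
  gc.bh.subvec(N, 2 * N - 1)     += daz;
  gc.bh.subvec(2 * N, 3 * N - 1) += dk;

  dh_prev += c.U.rows(0, N - 1).t() * dar
           + c.U.rows(N, 2 * N - 1).t() * daz
           + c.U.rows(2 * N, 3 * N - 1).t() * dk;
  dx = c.W.rows(0, N - 1).t() * dar
     + c.W.rows(N, 2 * N - 1).t() * daz
     + c.W.rows(2 * N, 3 * N - 1).t() * dan;
  return dh_prev;
}

}  // namespace

// Forward pass collecting E (Te x N), D (Td x N), Yhat (Td x M).
// Decoder starts from the encoder's final state; its first input is the
// last encoder input row, thereafter its own previous output.
// [[Rcpp::export]]
Rcpp::List cpp_seq2seq_forward(const arma::vec& theta, int N_, int M_,
                               bool shared, const arma::mat& X, int Td_) {
  arma::uword N = N_, M = M_, Te = X.n_rows, Td = Td_;
  Cell enc = unpack_cell(theta, 0, N, M);
  arma::uword off = cell_size(N, M);
  Cell dec = shared ? enc : unpack_cell(theta, off, N, M);
  if (!shared) off += cell_size(N, M);
  Out out = unpack_out(theta, off, N, M);

  mat E(Te, N), D(Td, N), Yhat(Td, M);
  vec h(N, fill::zeros);
  for (arma::uword t = 0; t < Te; ++t) {
    h = gru_step(enc, X.row(t).t(), h, N, nullptr);
    E.row(t) = h.t();
  }
  vec x = X.row(Te - 1).t();
  for (arma::uword t = 0; t < Td; ++t) {
    h = gru_step(dec, x, h, N, nullptr);
    D.row(t) = h.t();
    vec y = out.Wy * h + out.by;
    Yhat.row(t) = y.t();
    x = y;
  }
  return Rcpp::List::create(Rcpp::Named("E") = E, Rcpp::Named("D") = D,
                            Rcpp::Named("Yhat") = Yhat);
}

// Loss and full gradient for one sequence pair.
// J = mean over all Td*M entries of squared error.
// [[Rcpp::export]]
Rcpp::List cpp_seq2seq_grad(const arma::vec& theta, int N_, int M_,
                            bool shared, const arma::mat& X,
                            const arma::mat& Y) {
  arma::uword N = N_, M = M_, Te = X.n_rows, Td = Y.n_rows;
  Cell enc = unpack_cell(theta, 0, N, M);
  arma::uword off_dec = cell_size(N, M);
  Cell dec = shared ? enc : unpack_cell(theta, off_dec, N, M);
  arma::uword off_out = shared ? off_dec : 2 * cell_size(N, M);
  Out out = unpack_out(theta, off_out, N, M);

  std::vector<StepCache> ec(Te), dc(Td);
  std::vector<vec> dstate(Td), yhat(Td);

  vec h(N, fill::zeros);
  for (arma::uword t = 0; t < Te; ++t)
    h = gru_step(enc, X.row(t).t(), h, N, &ec[t]);
  vec x = X.row(Te - 1).t();
  double loss = 0.0;
  for (arma::uword t = 0; t < Td; ++t) {
    h = gru_step(dec, x, h, N, &dc[t]);
    dstate[t] = h;
    yhat[t] = out.Wy * h + out.by;
    vec err = yhat[t] - Y.row(t).t();
    loss += dot(err, err);
    x = yhat[t];
  }
  double scale = 1.0 / double(Td * M);
  loss *= scale;

  // backward
  Cell genc; genc.W.zeros(3 * N, M); genc.U.zeros(3 * N, N);
  genc.bx.zeros(3 * N); genc.bh.zeros(3 * N);
  Cell gdec = genc;  // zero copies
  mat gWy(M, N, fill::zeros);
  vec gby(M, fill::zeros);

  vec dh(N, fill::zeros), dx_next(M, fill::zeros);
  for (arma::uword ti = Td; ti-- > 0;) {
    vec dy = 2.0 * scale * (yhat[ti] - Y.row(ti).t());
    if (ti + 1 < Td) dy += dx_next;  // fed into the next decoder step
    gWy += dy * dstate[ti].t();
    gby += dy;
    dh += out.Wy.t() * dy;
    vec dx;
    dh = gru_step_back(dec, shared ? genc : gdec, dc[ti], dh, N, dx);
    dx_next = dx;  // for ti = 0 this lands on x_Te (data): dropped
  }
  for (arma::uword ti = Te; ti-- > 0;) {
    vec dx;
    dh = gru_step_back(enc, genc, ec[ti], dh, N, dx);
  }

  vec grad(theta.n_elem, fill::zeros);
  pack_cell(grad, 0, genc);
  if (!shared) pack_cell(grad, cell_size(N, M), gdec);
  arma::uword o = off_out;
  grad.subvec(o, o + M * N - 1) += vectorise(gWy);
  grad.subvec(o + M * N, o + M * N + M - 1) += gby;

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grad") = grad);
}

// Single-linkage agglomerative clustering with cosine distance, computed
// as a Prim minimum-spanning-tree cut: removing the k-1 largest MST edges
// yields exactly the k-cluster single-linkage partition. O(P^2) time,
// O(P) memory, so sliding-window scans with ~15k state rows stay cheap.
// Returns 0-based labels numbered by first row occurrence.
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_single_linkage_cosine(const arma::mat& P, int k) {
  arma::uword n = P.n_rows;
  vec norms(n);
  for (arma::uword i = 0; i < n; ++i) norms(i) = norm(P.row(i), 2);

  // Prim's algorithm from vertex 0
  std::vector<double> best(n, std::numeric_limits<double>::infinity());
  std::vector<arma::uword> parent(n, 0);
  std::vector<bool> in_tree(n, false);
  arma::uword cur = 0;
  in_tree[0] = true;
  std::vector<std::pair<double, arma::uword>> edges;  // (weight, child)
  edges.reserve(n - 1);
  for (arma::uword it = 1; it < n; ++it) {
    for (arma::uword j = 0; j < n; ++j) {
      if (in_tree[j]) continue;
      double d = 1.0 - dot(P.row(cur), P.row(j)) / (norms(cur) * norms(j));
      if (d < best[j]) { best[j] = d; parent[j] = cur; }
    }
    double mn = std::numeric_limits<double>::infinity();
    arma::uword pick = 0;
    for (arma::uword j = 0; j < n; ++j)
      if (!in_tree[j] && best[j] < mn) { mn = best[j]; pick = j; }
    in_tree[pick] = true;
    edges.emplace_back(best[pick], pick);
    cur = pick;
  }

  // cut the k-1 heaviest edges: mark their child vertices as cut points
  std::vector<std::pair<double, arma::uword>> sorted(edges);
  std::stable_sort(sorted.begin(), sorted.end(),
                   [](const std::pair<double, arma::uword>& a,
                      const std::pair<double, arma::uword>& b) {
                     return a.first > b.first;
                   });
  std::vector<bool> cut(n, false);
  for (int c = 0; c < k - 1 && c < int(sorted.size()); ++c)
    cut[sorted[c].second] = true;

  // union-find over the kept edges
  std::vector<arma::uword> root(n);
  for (arma::uword i = 0; i < n; ++i) root[i] = i;
  std::function<arma::uword(arma::uword)> find = [&](arma::uword a) {
    while (root[a] != a) { root[a] = root[root[a]]; a = root[a]; }
    return a;
  };
  for (auto& e : edges) {
    if (cut[e.second]) continue;
    arma::uword a = find(e.second), b = find(parent[e.second]);
    if (a != b) root[a] = b;
  }

  Rcpp::IntegerVector lab(n);
  std::map<arma::uword, int> seen;
  for (arma::uword i = 0; i < n; ++i) {
    arma::uword r = find(i);
    auto it = seen.find(r);
    if (it == seen.end()) { int id = seen.size(); seen[r] = id; lab[i] = id; }
    else lab[i] = it->second;
  }
  return lab;
}
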