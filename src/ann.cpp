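#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Feed-forward net with two rectifier hidden layers and a softmax output.
// Weights travel as one flat vector (column-major per layer, weights then
// biases) so metaheuristics can treat the network as a plain solution vector.

struct Net {
  mat W1, W2, W3;
  rowvec b1, b2, b3;
};

static Net unflatten(const vec &w, const ivec &dims) {
  Net n;
  uword p = 0;
  uword d0 = dims(0), h1 = dims(1), h2 = dims(2), q = dims(3);
  n.W1 = reshape(w.subvec(p, p + d0 * h1 - 1), d0, h1); p += d0 * h1;
  n.b1 = w.subvec(p, p + h1 - 1).t();                   p += h1;
  n.W2 = reshape(w.subvec(p, p + h1 * h2 - 1), h1, h2); p += h1 * h2;
  n.b2 = w.subvec(p, p + h2 - 1).t();                   p += h2;
  n.W3 = reshape(w.subvec(p, p + h2 * q - 1), h2, q);   p += h2 * q;
  n.b3 = w.subvec(p, p + q - 1).t();
  return n;
}

static vec flatten(const Net &n) {
  return join_cols(join_cols(vectorise(n.W1), n.b1.t()),
         join_cols(join_cols(vectorise(n.W2), n.b2.t()),
                   join_cols(vectorise(n.W3), n.b3.t())));
}

static mat softmax_rows(mat Z) {
  Z.each_col() -= max(Z, 1);
  mat E = exp(Z);
  E.each_col() /= sum(E, 1);
  return E;
}

static mat forward(const Net &n, const mat &X, mat &A1, mat &A2) {
  A1 = X * n.W1;  A1.each_row() += n.b1;  A1 = clamp(A1, 0.0, datum::inf);
  A2 = A1 * n.W2; A2.each_row() += n.b2;  A2 = clamp(A2, 0.0, datum::inf);
  mat Z = A2 * n.W3; Z.each_row() += n.b3;
  return softmax_rows(Z);
}

static double loss_of(const Net &n, const mat &P, const mat &Y, double l2) {
  double ce = -accu(Y % log(P + 1e-12)) / (double)P.n_rows;
  double pen = accu(square(n.W1)) + accu(square(n.W2)) + accu(square(n.W3));
  return ce + l2 * pen;
}

// Lean training loop shared by the fitness kernel: same step-rejection
// scheme as cpp_ann_train but without history bookkeeping.
static void train_inplace(Net &n, const mat &X, const mat &Y, double l2,
                          int epochs, double lr0, double momentum) {
  uword nobs = X.n_rows;
  mat A1, A2;
  mat P = forward(n, X, A1, A2);
  double cur = loss_of(n, P, Y, l2);
  Net V;
  V.W1 = zeros(size(n.W1)); V.W2 = zeros(size(n.W2)); V.W3 = zeros(size(n.W3));
  V.b1 = zeros<rowvec>(n.b1.n_elem); V.b2 = zeros<rowvec>(n.b2.n_elem);
  V.b3 = zeros<rowvec>(n.b3.n_elem);
  double lr = lr0;
  for (int e = 0; e < epochs; ++e) {
    mat D = (P - Y) / (double)nobs;
    mat gW3 = A2.t() * D + 2.0 * l2 * n.W3;
    rowvec gb3 = sum(D, 0);
    mat D2 = (D * n.W3.t()) % (A2 > 0);
    mat gW2 = A1.t() * D2 + 2.0 * l2 * n.W2;
    rowvec gb2 = sum(D2, 0);
    mat D1 = (D2 * n.W2.t()) % (A1 > 0);
    mat gW1 = X.t() * D1 + 2.0 * l2 * n.W1;
    rowvec gb1 = sum(D1, 0);
    bool accepted = false;
    for (int tries = 0; tries < 12 && !accepted; ++tries) {
      Net Vc;
      Vc.W1 = momentum * V.W1 - lr * gW1; Vc.b1 = momentum * V.b1 - lr * gb1;
      Vc.W2 = momentum * V.W2 - lr * gW2; Vc.b2 = momentum * V.b2 - lr * gb2;
      Vc.W3 = momentum * V.W3 - lr * gW3; Vc.b3 = momentum * V.b3 - lr * gb3;
      Net cand = n;
      cand.W1 += Vc.W1; cand.b1 += Vc.b1;
      cand.W2 += Vc.W2; cand.b2 += Vc.b2;
      cand.W3 += Vc.W3; cand.b3 += Vc.b3;
      mat cA1, cA2;
      mat cP = forward(cand, X, cA1, cA2);
      double cl = loss_of(cand, cP, Y, l2);
      if (cl <= cur) {
        n = cand; V = Vc; P = cP; A1 = cA1; A2 = cA2; cur = cl;
        lr = std::min(lr * 1.1, 100.0 * lr0);
        accepted = true;
      } else {
        lr *= 0.5;
        V.W1.zeros(); V.W2.zeros(); V.W3.zeros();
        V.b1.zeros(); V.b2.zeros(); V.b3.zeros();
      }
    }
  }
}

// Wavelength-subset fitness: for each seeded split (train rows, validation
// rows, initial weights), standardize on the training rows, train, and
// return the mean validation MSE of softmax outputs vs one-hot targets.
// [[Rcpp::export]]
double cpp_subset_fitness(const arma::mat &X, const arma::mat &Y,
                          const Rcpp::List &splits, const arma::ivec &dims,
                          double l2, int epochs, double lr0,
                          double momentum) {
  double total = 0.0;
  int ns = splits.size();
  for (int s = 0; s < ns; ++s) {
    Rcpp::List sp = splits[s];
    uvec tr = Rcpp::as<uvec>(sp["train"]) - 1;
    uvec va = Rcpp::as<uvec>(sp["validation"]) - 1;
    vec w0 = Rcpp::as<vec>(sp["init"]);
    mat Xtr = X.rows(tr);
    rowvec mu = mean(Xtr, 0);
    rowvec sd_ = stddev(Xtr, 0, 0);
    sd_.elem(find(sd_ < 1e-12)).fill(1.0);
    Xtr.each_row() -= mu; Xtr.each_row() /= sd_;
    mat Xva = X.rows(va);
    Xva.each_row() -= mu; Xva.each_row() /= sd_;
    Net n = unflatten(w0, dims);
    train_inplace(n, Xtr, Y.rows(tr), l2, epochs, lr0, momentum);
    mat A1, A2;
    mat P = forward(n, Xva, A1, A2);
    total += accu(square(P - Y.rows(va))) / (double)P.n_elem;
  }
  return total / (double)ns;
}

// [[Rcpp::export]]
arma::mat cpp_ann_forward(const arma::vec &w, const arma::ivec &dims,
                          const arma::mat &X) {
  Net n = unflatten(w, dims);
  mat A1, A2;
  return forward(n, X, A1, A2);
}

// [[Rcpp::export]]
double cpp_ann_mse(const arma::vec &w, const arma::ivec &dims,
                   const arma::mat &X, const arma::mat &Y) {
  Net n = unflatten(w, dims);
  mat A1, A2;
  mat P = forward(n, X, A1, A2);
  return accu(square(P - Y)) / (double)P.n_elem;
}

// Full-batch gradient descent on cross-entropy + L2 with heavy-ball momentum
// and step rejection: a step that would raise the loss is discarded, the
// learning rate halved and the velocity reset, so the recorded loss sequence
// is non-increasing by construction. Deterministic: no RNG inside.
// [[Rcpp::export]]
Rcpp::List cpp_ann_train(const arma::vec &w0, const arma::ivec &dims,
                         const arma::mat &X, const arma::mat &Y,
                         double l2, int epochs, double lr0, double momentum) {
  Net n = unflatten(w0, dims);
  uword nobs = X.n_rows;
  mat A1, A2;
  mat P = forward(n, X, A1, A2);
  double cur = loss_of(n, P, Y, l2);
  std::vector<double> hist;
  hist.reserve(epochs + 1);
  hist.push_back(cur);

  Net V;  // velocity
  V.W1 = zeros(size(n.W1)); V.W2 = zeros(size(n.W2)); V.W3 = zeros(size(n.W3));
  V.b1 = zeros<rowvec>(n.b1.n_elem); V.b2 = zeros<rowvec>(n.b2.n_elem);
  V.b3 = zeros<rowvec>(n.b3.n_elem);
  double lr = lr0;

  for (int e = 0; e < epochs; ++e) {
    // backprop at current point
    mat D = (P - Y) / (double)nobs;
    mat gW3 = A2.t() * D + 2.0 * l2 * n.W3;
    rowvec gb3 = sum(D, 0);
    mat D2 = (D * n.W3.t()) % (A2 > 0);
    mat gW2 = A1.t() * D2 + 2.0 * l2 * n.W2;
    rowvec gb2 = sum(D2, 0);
    mat D1 = (D2 * n.W2.t()) % (A1 > 0);
    mat gW1 = X.t() * D1 + 2.0 * l2 * n.W1;
    rowvec gb1 = sum(D1, 0);

    bool accepted = false;
    for (int tries = 0; tries < 12 && !accepted; ++tries) {
      Net Vc;
      Vc.W1 = momentum * V.W1 - lr * gW1; Vc.b1 = momentum * V.b1 - lr * gb1;
      Vc.W2 = momentum * V.W2 - lr * gW2; Vc.b2 = momentum * V.b2 - lr * gb2;
      Vc.W3 = momentum * V.W3 - lr * gW3; Vc.b3 = momentum * V.b3 - lr * gb3;
      Net cand = n;
      cand.W1 += Vc.W1; cand.b1 += Vc.b1;
      cand.W2 += Vc.W2; cand.b2 += Vc.b2;
      cand.W3 += Vc.W3; cand.b3 += Vc.b3;
      mat cA1, cA2;
      mat cP = forward(cand, X, cA1, cA2);
      double cl = loss_of(cand, cP, Y, l2);
      if (cl <= cur) {
        n = cand; V = Vc; P = cP; A1 = cA1; A2 = cA2; cur = cl;
        lr = std::min(lr * 1.1, 100.0 * lr0);
        accepted = true;
      } else {
        lr *= 0.5;
        V.W1.zeros(); V.W2.zeros(); V.W3.zeros();
        V.b1.zeros(); V.b2.zeros(); V.b3.zeros();
      }
    }
    hist.push_back(cur);
  }
  return Rcpp::List::create(Rcpp::Named("weights") = flatten(n),
                            Rcpp::Named("loss") = hist);
}
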