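// Single-convolutional-layer sequence classifier.
//
// Architecture: conv(5-channel one-hot input, F filters, width L, valid) ->
// leaky ReLU -> non-overlapping max-pool(P) -> dropout -> dense(D) ->
// leaky ReLU -> dense(2) -> softmax, trained with cross-entropy and Adam.
// The small leak (slope 0.01 on the negative side) keeps gradient flowing
// through inactive units: with a hard ReLU the dense layer can die
// irrecoverably while the loss sits on its initial chance-level plateau.
//
// Sequences arrive as integer code matrices (1..5 = A,T,C,G,N), so the
// convolution over a one-hot input reduces to a table lookup: the response
// at offset t is bias + sum_j W[f, code[t+j], j].
//
// All randomness (init, shuffling, dropout) uses R's RNG, so results are
// reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

const double kLeak = 0.01;

struct Dims {
  int F, L, P, D;   // filters, kernel width, pool width, dense width
  int W;            // window length
  int C;            // conv output length = W - L + 1
  int M;            // pooled length = C / P (floor, remainder discarded)
  int K;            // flattened feature count = F * M
  // flat parameter offsets
  int oWc, obc, oW1, ob1, oW2, ob2, total;
  Dims(int F_, int L_, int P_, int D_, int W_)
      : F(F_), L(L_), P(P_), D(D_), W(W_) {
    C = W - L + 1;
    M = C / P;
    K = F * M;
    oWc = 0;
    obc = oWc + F * 5 * L;
    oW1 = obc + F;
    ob1 = oW1 + D * K;
    oW2 = ob1 + D;
    ob2 = oW2 + 2 * D;
    total = ob2 + 2;
  }
  inline int wc(int f, int c, int j) const { return oWc + (f * 5 + c) * L + j; }
};

// Forward pass for one sequence. Fills z (F*C), pooled (K), argmax (K),
// h (D), logits (2). `mask` (K) applies dropout when non-null.
void forward_one(const int* code, const double* th, const Dims& d,
                 std::vector<double>& z, std::vector<double>& pooled,
                 std::vector<int>& amax, std::vector<double>& h,
                 double* logits, const double* mask) {
  for (int f = 0; f < d.F; ++f) {
    const double* Wf = th + d.wc(f, 0, 0);
    const double bf = th[d.obc + f];
    double* zf = z.data() + f * d.C;
    for (int t = 0; t < d.C; ++t) {
      double s = bf;
      const int* ct = code + t;
      for (int j = 0; j < d.L; ++j) s += Wf[ct[j] * d.L + j];
      zf[t] = s;
    }
    for (int m = 0; m < d.M; ++m) {
      int t0 = m * d.P, best = t0;
      double bv = zf[t0];
      for (int t = t0 + 1; t < t0 + d.P; ++t)
        if (zf[t] > bv) { bv = zf[t]; best = t; }
      // leaky ReLU is monotone, so pooling the pre-activation max and
      // activating it equals pooling the activations; argmax kept
      double act = bv > 0 ? bv : kLeak * bv;
      amax[f * d.M + m] = best;
      pooled[f * d.M + m] = mask ? act * mask[f * d.M + m] : act;
    }
  }
  for (int dd = 0; dd < d.D; ++dd) {
    double s = th[d.ob1 + dd];
    const double* w1 = th + d.oW1 + dd * d.K;
    for (int k = 0; k < d.K; ++k) s += w1[k] * pooled[k];
    h[dd] = s > 0 ? s : kLeak * s;
  }
  for (int c = 0; c < 2; ++c) {
    double s = th[d.ob2 + c];
    const double* w2 = th + d.oW2 + c * d.D;
    for (int dd = 0; dd < d.D; ++dd) s += w2[dd] * h[dd];
    logits[c] = s;
  }
}

inline void softmax2(const double* logits, double* p) {
  double mx = std::max(logits[0], logits[1]);
  double e0 = std::exp(logits[0] - mx), e1 = std::exp(logits[1] - mx);
  p[0] = e0 / (e0 + e1);
  p[1] = e1 / (e0 + e1);
}

double accuracy_on(const IntegerMatrix& codes, const IntegerVector& y,
                   const double* th, const Dims& d) {
  int n = codes.nrow();
  std::vector<double> z(d.F * d.C), pooled(d.K), h(d.D);
  std::vector<int> amax(d.K), row(d.W);
  double logits[2], p[2];
  int ok = 0;
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < d.W; ++t) row[t] = codes(i, t) - 1;
    forward_one(row.data(), th, d, z, pooled, amax, h, logits, nullptr);
    softmax2(logits, p);
    int pred = p[1] > 0.5 ? 1 : 0;
    if (pred == y[i]) ++ok;
  }
  return n ? static_cast<double>(ok) / n : NA_REAL;
}

}  // namespace

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(IntegerMatrix codes, IntegerVector y,
                   IntegerMatrix codes_val, IntegerVector y_val,
                   int n_filters, int kernel_width, int pool_width,
                   int dense_width, double dropout, double lr,
                   int batch_size, int max_epochs, int patience,
                   int min_epochs) {
  const int n = codes.nrow(), W = codes.ncol();
  Dims d(n_filters, kernel_width, pool_width, dense_width, W);
  if (d.C < 1) stop("kernel wider than the window");
  if (d.M < 1) stop("pool width exceeds the convolution output length");

  RNGScope scope;
  std::vector<double> th(d.total);
  // He init for the conv filters (they feed a ReLU); Glorot for both dense
  // layers; biases zero
  const double s_conv = std::sqrt(2.0 / (5.0 * d.L));
  const double s_w1 = std::sqrt(2.0 / (d.K + d.D));
  const double s_w2 = std::sqrt(2.0 / (d.D + 2.0));
  for (int i = d.oWc; i < d.obc; ++i) th[i] = norm_rand() * s_conv;
  for (int i = d.oW1; i < d.ob1; ++i) th[i] = norm_rand() * s_w1;
  for (int i = d.oW2; i < d.ob2; ++i) th[i] = norm_rand() * s_w2;

  std::vector<double> grad(d.total), mAdam(d.total), vAdam(d.total);
  std::vector<double> z(d.F * d.C), pooled(d.K), h(d.D), mask(d.K);
  std::vector<int> amax(d.K);
  std::vector<std::vector<int>> rows(n, std::vector<int>(W));
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < W; ++t) rows[i][t] = codes(i, t) - 1;

  const double keep = 1.0 - dropout;
  const double b1a = 0.9, b2a = 0.999, eps = 1e-8;
  long adam_t = 0;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  std::vector<double> hist_loss, hist_val;
  std::vector<double> best_th(th);
  double best_val = -1.0;
  int best_epoch = 0, since_best = 0, epochs_run = 0;
  double dlog[2], logits[2], p[2];
  std::vector<double> du(d.D), dpool(d.K);

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // Fisher-Yates shuffle via R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double epoch_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int bend = std::min(start + batch_size, n);
      int bsz = bend - start;
      std::fill(grad.begin(), grad.end(), 0.0);
      for (int bi = start; bi < bend; ++bi) {
        int i = order[bi];
        if (keep < 1.0) {
          for (int k = 0; k < d.K; ++k)
            mask[k] = unif_rand() < keep ? 1.0 / keep : 0.0;
        }
        forward_one(rows[i].data(), th.data(), d, z, pooled, amax, h,
                    logits, keep < 1.0 ? mask.data() : nullptr);
        softmax2(logits, p);
        double py = std::max(p[y[i]], 1e-12);
        epoch_loss += -std::log(py);
        dlog[0] = p[0] - (y[i] == 0 ? 1.0 : 0.0);
        dlog[1] = p[1] - (y[i] == 1 ? 1.0 : 0.0);
        for (int c = 0; c < 2; ++c) {
          grad[d.ob2 + c] += dlog[c];
          double* g2 = grad.data() + d.oW2 + c * d.D;
          for (int dd = 0; dd < d.D; ++dd) g2[dd] += dlog[c] * h[dd];
        }
        for (int dd = 0; dd < d.D; ++dd) {
          double dh = th[d.oW2 + dd] * dlog[0] + th[d.oW2 + d.D + dd] * dlog[1];
          du[dd] = h[dd] > 0 ? dh : kLeak * dh;  // leaky gate (h, u same sign)
          grad[d.ob1 + dd] += du[dd];
          double* g1 = grad.data() + d.oW1 + dd * d.K;
          for (int k = 0; k < d.K; ++k) g1[k] += du[dd] * pooled[k];
        }
        for (int k = 0; k < d.K; ++k) {
          double s = 0.0;
          for (int dd = 0; dd < d.D; ++dd)
            if (du[dd] != 0.0) s += th[d.oW1 + dd * d.K + k] * du[dd];
          dpool[k] = (keep < 1.0 ? s * mask[k] : s);
        }
        for (int f = 0; f < d.F; ++f) {
          const double* zf = z.data() + f * d.C;
          for (int m = 0; m < d.M; ++m) {
            int t = amax[f * d.M + m];
            double dz = dpool[f * d.M + m];
            if (zf[t] <= 0) dz *= kLeak;  // leaky gate
            if (dz == 0.0) continue;
            grad[d.obc + f] += dz;
            const int* ct = rows[i].data() + t;
            double* gW = grad.data() + d.wc(f, 0, 0);
            for (int j = 0; j < d.L; ++j) gW[ct[j] * d.L + j] += dz;
          }
        }
      }
      // Adam step on the batch-mean gradient
      ++adam_t;
      double inv = 1.0 / bsz;
      double bc1 = 1.0 - std::pow(b1a, static_cast<double>(adam_t));
      double bc2 = 1.0 - std::pow(b2a, static_cast<double>(adam_t));
      for (int i = 0; i < d.total; ++i) {
        double g = grad[i] * inv;
        mAdam[i] = b1a * mAdam[i] + (1 - b1a) * g;
        vAdam[i] = b2a * vAdam[i] + (1 - b2a) * g * g;
        th[i] -= lr * (mAdam[i] / bc1) / (std::sqrt(vAdam[i] / bc2) + eps);
      }
    }
    epochs_run = epoch + 1;
    hist_loss.push_back(epoch_loss / n);
    double vacc = accuracy_on(codes_val, y_val, th.data(), d);
    hist_val.push_back(vacc);
    if (vacc > best_val + 1e-12) {
      best_val = vacc;
      best_th = th;
      best_epoch = epoch + 1;
      since_best = 0;
    } else if (++since_best >= patience && epoch + 1 >= min_epochs) {
      break;  // early stopping on validation accuracy
    }
    Rcpp::checkUserInterrupt();
  }
  th = best_th;  // restore the best-validation weights

  NumericVector Wc(th.begin() + d.oWc, th.begin() + d.obc);
  Wc.attr("dim") = IntegerVector::create(d.L, 5, d.F);
  NumericVector bc(th.begin() + d.obc, th.begin() + d.oW1);
  NumericVector W1(th.begin() + d.oW1, th.begin() + d.ob1);
  W1.attr("dim") = IntegerVector::create(d.K, d.D);
  NumericVector b1(th.begin() + d.ob1, th.begin() + d.oW2);
  NumericVector W2(th.begin() + d.oW2, th.begin() + d.ob2);
  W2.attr("dim") = IntegerVector::create(d.D, 2);
  NumericVector b2(th.begin() + d.ob2, th.begin() + d.ob2 + 2);

  return List::create(
      _["Wc"] = Wc, _["bc"] = bc, _["W1"] = W1, _["b1"] = b1,
      _["W2"] = W2, _["b2"] = b2,
      _["train_loss"] = NumericVector(hist_loss.begin(), hist_loss.end()),
      _["val_accuracy"] = NumericVector(hist_val.begin(), hist_val.end()),
      _["best_epoch"] = best_epoch, _["epochs_run"] = epochs_run,
      _["conv_len"] = d.C, _["pooled_len"] = d.M);
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
NumericMatrix cnn_predict_cpp(List weights, IntegerMatrix codes,
                              int n_filters, int kernel_width,
                              int pool_width, int dense_width) {
  const int n = codes.nrow(), W = codes.ncol();
  Dims d(n_filters, kernel_width, pool_width, dense_width, W);
  NumericVector Wc = weights["Wc"], bc = weights["bc"], W1 = weights["W1"],
                b1 = weights["b1"], W2 = weights["W2"], b2 = weights["b2"];
  std::vector<double> th(d.total);
  std::copy(Wc.begin(), Wc.end(), th.begin() + d.oWc);
  std::copy(bc.begin(), bc.end(), th.begin() + d.obc);
  std::copy(W1.begin(), W1.end(), th.begin() + d.oW1);
  std::copy(b1.begin(), b1.end(), th.begin() + d.ob1);
  std::copy(W2.begin(), W2.end(), th.begin() + d.oW2);
  std::copy(b2.begin(), b2.end(), th.begin() + d.ob2);

  std::vector<double> z(d.F * d.C), pooled(d.K), h(d.D);
  std::vector<int> amax(d.K), row(W);
  double logits[2], p[2];
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < W; ++t) row[t] = codes(i, t) - 1;
    forward_one(row.data(), th.data(), d, z, pooled, amax, h, logits,
                nullptr);
    softmax2(logits, p);
    out(i, 0) = p[0];
    out(i, 1) = p[1];
  }
  colnames(out) = CharacterVector::create("low", "expressed");
  return out;
}
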