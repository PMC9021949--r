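// Training/inference engine for the dual-branch (cross network + FGCNN)
// syndrome classifier. Layout conventions are shared with the R reference
// implementation (R/embedding.R, R/cross.R, R/fgcnn.R, R/head.R):
//   - x0 flatten: row-major over the n_f x k embedded matrix
//     (position f*k + j, 0-based)
//   - conv tensors: matrix of (B*k*H) rows x c channels,
//     row index b + B*j + B*k*o (batch fastest, field row slowest)
//   - pooled-tensor flatten before recombination: o fastest, then j, then
//     channel (R array order of an H' x k x m array)
//   - concatenated recombination rows flatten: row index fastest across
//     the stacked (sum r_i) x k matrix
// Templated on the floating type: float for mini-batch training (speed on
// one CPU), double for evaluation and finite-difference gradient checks.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

#if defined(__SSE2__)
#include <xmmintrin.h>
#define CFGCNN_HAVE_MXCSR 1
#endif

// Single-precision training drives Adam's moment estimates toward zero as
// gradients vanish; x86 subnormal arithmetic is microcoded and can slow
// elementwise updates by two orders of magnitude. Flush-to-zero /
// denormals-are-zero treats magnitudes below ~1e-38 as zero for the
// duration of a float training run (scoped, restored on exit).
struct FlushDenormalsGuard {
#ifdef CFGCNN_HAVE_MXCSR
  unsigned int saved;
  explicit FlushDenormalsGuard(bool enable) : saved(_mm_getcsr()) {
    if (enable) _mm_setcsr(saved | 0x8040u);  // FTZ | DAZ
  }
  ~FlushDenormalsGuard() { _mm_setcsr(saved); }
#else
  explicit FlushDenormalsGuard(bool) {}
#endif
};

using Rcpp::List;
using Rcpp::IntegerMatrix;
using Rcpp::IntegerVector;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::as;

template <typename T>
struct Engine {
  using Mat = arma::Mat<T>;
  using Col = arma::Col<T>;

  // configuration
  int nf = 0, k = 0, d = 0, L = 0, h = 0, pool = 2, pad = 0, ncls = 9;
  int nrounds = 0, ablation = 0;  // 0 full, 1 cross_only, 2 fgcnn_only
  double dropout = 0.0;
  std::vector<int> chans, rrows, Hs;  // Hs[i] = input height of round i
  arma::ivec offsets;                 // embedding row offset per field

  // parameters (biases kept as 1 x n row matrices)
  Mat emb, crossW, crossB;
  std::vector<Mat> Kmat, Kb, RW, Rb, FW, Fb, HW, Hb;

  // gradients (parallel shapes)
  Mat g_emb, g_crossW, g_crossB;
  std::vector<Mat> g_Kmat, g_Kb, g_RW, g_Rb, g_FW, g_Fb, g_HW, g_Hb;

  // Adam state
  struct Slot { Mat* w; Mat* g; Mat m, v; };
  std::vector<Slot> slots;

  // activations of the last forward pass
  int B = 0;
  arma::umat embrows;               // B x nf
  Mat X0;                           // B x d
  std::vector<Mat> Xl;              // L+1 of B x d
  Mat svals;                        // B x L
  std::vector<Mat> Tin, Xcol, Cact, Spool, Sflat, Rc;
  std::vector<arma::umat> Win;      // pooling winners (source offset in block)
  Mat MLPin;
  std::vector<Mat> Fact, Hact, Hmask;
  Mat P;                            // B x ncls probabilities

  void load(const List& params, const List& cfg) {
    nf = as<int>(cfg["n_f"]); k = as<int>(cfg["k"]);
    pool = as<int>(cfg["pool"]); h = as<int>(cfg["h"]);
    ncls = as<int>(cfg["n_classes"]);
    ablation = as<int>(cfg["ablation"]);
    dropout = as<double>(cfg["dropout"]);
    chans = as<std::vector<int>>(cfg["channels"]);
    rrows = as<std::vector<int>>(cfg["r"]);
    nrounds = static_cast<int>(chans.size());
    d = nf * k;
    pad = (h - 1) / 2;
    Hs.assign(nrounds + 1, 0);
    Hs[0] = nf;
    for (int i = 0; i < nrounds; ++i) {
      if (Hs[i] < pool) Rcpp::stop("round %d: input height %d < pool %d",
                                   i + 1, Hs[i], pool);
      Hs[i + 1] = Hs[i] / pool;
    }

    List pe = params["emb"];
    emb = as_mat(pe["table"]);
    offsets = as<arma::ivec>(pe["offsets"]);
    List pc = params["cross"];
    crossW = as_mat(pc["W"]);
    crossB = as_mat(pc["b"]);
    L = crossW.n_cols;

    List pf = params["fgcnn"];
    List conv = pf["conv"], recomb = pf["recomb"], mlp = pf["mlp"];
    Kmat.clear(); Kb.clear(); RW.clear(); Rb.clear();
    for (int i = 0; i < nrounds; ++i) {
      List ci = conv[i];
      NumericVector Karr = ci["K"];  // array (h, c, m), column-major
      int c_in = (i == 0) ? 1 : chans[i - 1];
      Mat km(h * c_in, chans[i]);
      for (size_t idx = 0; idx < static_cast<size_t>(Karr.size()); ++idx)
        km(idx % (h * c_in), idx / (h * c_in)) = static_cast<T>(Karr[idx]);
      Kmat.push_back(km);
      Kb.push_back(as_row(ci["b"]));
      List ri = recomb[i];
      RW.push_back(as_mat(ri["W"]));
      Rb.push_back(as_row(ri["b"]));
    }
    load_layers(mlp, FW, Fb);
    load_layers(params["head"], HW, Hb);
    alloc_grads();
  }

  Mat as_mat(SEXP x) {
    NumericMatrix m(x);
    Mat out(m.nrow(), m.ncol());
    for (int j = 0; j < m.ncol(); ++j)
      for (int i = 0; i < m.nrow(); ++i)
        out(i, j) = static_cast<T>(m(i, j));
    return out;
  }
  Mat as_row(SEXP x) {
    NumericVector v(x);
    Mat out(1, v.size());
    for (int i = 0; i < v.size(); ++i) out(0, i) = static_cast<T>(v[i]);
    return out;
  }
  void load_layers(const List& layers, std::vector<Mat>& Ws,
                   std::vector<Mat>& bs) {
    List lw = layers["W"], lb = layers["b"];
    Ws.clear(); bs.clear();
    for (int j = 0; j < lw.size(); ++j) {
      Ws.push_back(as_mat(lw[j]));
      bs.push_back(as_row(lb[j]));
    }
  }

  void alloc_grads() {
    auto zed = [](const Mat& w) { return Mat(w.n_rows, w.n_cols,
                                             arma::fill::zeros); };
    g_emb = zed(emb); g_crossW = zed(crossW); g_crossB = zed(crossB);
    auto zvec = [&](const std::vector<Mat>& src, std::vector<Mat>& dst) {
      dst.clear();
      for (const Mat& w : src) dst.push_back(zed(w));
    };
    zvec(Kmat, g_Kmat); zvec(Kb, g_Kb); zvec(RW, g_RW); zvec(Rb, g_Rb);
    zvec(FW, g_FW); zvec(Fb, g_Fb); zvec(HW, g_HW); zvec(Hb, g_Hb);

    slots.clear();
    auto reg = [&](Mat& w, Mat& g) {
      slots.push_back({&w, &g, Mat(w.n_rows, w.n_cols, arma::fill::zeros),
                       Mat(w.n_rows, w.n_cols, arma::fill::zeros)});
    };
    reg(emb, g_emb);
    if (ablation != 2) { reg(crossW, g_crossW); reg(crossB, g_crossB); }
    if (ablation != 1) {
      for (int i = 0; i < nrounds; ++i) {
        reg(Kmat[i], g_Kmat[i]); reg(Kb[i], g_Kb[i]);
        reg(RW[i], g_RW[i]); reg(Rb[i], g_Rb[i]);
      }
      for (size_t j = 0; j < FW.size(); ++j) { reg(FW[j], g_FW[j]);
                                               reg(Fb[j], g_Fb[j]); }
    }
    for (size_t j = 0; j < HW.size(); ++j) { reg(HW[j], g_HW[j]);
                                             reg(Hb[j], g_Hb[j]); }
  }

  void zero_grads() {
    for (Slot& s : slots) s.g->zeros();
  }

  // ---- forward ---------------------------------------------------------

  void forward(const IntegerMatrix& codes, const std::vector<int>& idx,
               bool training, std::mt19937_64& rng) {
    B = static_cast<int>(idx.size());
    embrows.set_size(B, nf);
    for (int f = 0; f < nf; ++f)
      for (int b = 0; b < B; ++b)
        embrows(b, f) = static_cast<arma::uword>(
            offsets[f] + codes(idx[b], f) + 1);

    Mat Fvec;  // fgcnn branch output
    if (ablation != 2) {  // cross branch active
      X0.set_size(B, d);
      for (int f = 0; f < nf; ++f)
        for (int j = 0; j < k; ++j)
          for (int b = 0; b < B; ++b)
            X0(b, f * k + j) = emb(embrows(b, f), j);
      Xl.assign(L + 1, Mat());
      svals.set_size(B, L);
      Xl[0] = X0;
      for (int l = 0; l < L; ++l) {
        Col s = Xl[l] * crossW.col(l);
        svals.col(l) = s;
        Xl[l + 1] = X0.each_col() % s;
        Xl[l + 1].each_row() += crossB.col(l).t();
        Xl[l + 1] += Xl[l];
      }
    }

    if (ablation != 1) {  // fgcnn branch active
      Tin.assign(nrounds, Mat()); Xcol.assign(nrounds, Mat());
      Cact.assign(nrounds, Mat()); Spool.assign(nrounds, Mat());
      Sflat.assign(nrounds, Mat()); Rc.assign(nrounds, Mat());
      Win.assign(nrounds, arma::umat());
      Mat T1(static_cast<arma::uword>(B) * k * nf, 1);
      for (int o = 0; o < nf; ++o)
        for (int j = 0; j < k; ++j)
          for (int b = 0; b < B; ++b)
            T1(b + static_cast<arma::uword>(B) * j +
               static_cast<arma::uword>(B) * k * o, 0) =
                emb(embrows(b, o), j);
      Tin[0] = std::move(T1);

      int sumR = 0;
      for (int i = 0; i < nrounds; ++i) sumR += rrows[i];
      MLPin.set_size(B, sumR * k);
      int roff = 0;
      const arma::uword Bk = static_cast<arma::uword>(B) * k;

      for (int i = 0; i < nrounds; ++i) {
        const int H = Hs[i], Hp = Hs[i + 1];
        const int c_in = (i == 0) ? 1 : chans[i - 1];
        const int m = chans[i];
        // im2col along the field axis, zero padded
        Mat& X = Xcol[i];
        X.zeros(Bk * H, h * c_in);
        for (int t = 0; t < h; ++t) {
          const int delta = t - pad;
          const int o_lo = std::max(0, -delta);
          const int o_hi = std::min(H - 1, H - 1 - delta);
          if (o_lo > o_hi) continue;
          for (int ci = 0; ci < c_in; ++ci) {
            X.submat(Bk * o_lo, t + h * ci, Bk * (o_hi + 1) - 1, t + h * ci) =
                Tin[i].submat(Bk * (o_lo + delta), ci,
                              Bk * (o_hi + 1 + delta) - 1, ci);
          }
        }
        Mat Z = X * Kmat[i];
        Z.each_row() += Kb[i];
        Cact[i] = arma::tanh(Z);
        // max pooling with winner bookkeeping
        Spool[i].set_size(Bk * Hp, m);
        Win[i].zeros(Bk * Hp, m);
        for (int oo = 0; oo < Hp; ++oo) {
          Mat cur = Cact[i].rows(Bk * (pool * oo),
                                 Bk * (pool * oo) + Bk - 1);
          arma::umat win(Bk, m, arma::fill::zeros);
          for (int t = 1; t < pool; ++t) {
            Mat cand = Cact[i].rows(Bk * (pool * oo + t),
                                    Bk * (pool * oo + t) + Bk - 1);
            arma::uvec better = arma::find(cand > cur);
            cur.elem(better) = cand.elem(better);
            arma::uvec tv(better.n_elem);
            tv.fill(static_cast<arma::uword>(t));
            win.elem(better) = tv;
          }
          Spool[i].rows(Bk * oo, Bk * oo + Bk - 1) = cur;
          Win[i].rows(Bk * oo, Bk * oo + Bk - 1) = win;
        }
        // per-sample flatten (o fastest, then j, then channel)
        Sflat[i].set_size(B, Hp * k * m);
        for (int mm = 0; mm < m; ++mm)
          for (int j = 0; j < k; ++j)
            for (int o = 0; o < Hp; ++o)
              std::copy(Spool[i].colptr(mm) + B * (j + k * o),
                        Spool[i].colptr(mm) + B * (j + k * o) + B,
                        Sflat[i].colptr(o + Hp * j + Hp * k * mm));
        Mat Rpre = Sflat[i] * RW[i];
        Rpre.each_row() += Rb[i];
        Rc[i] = arma::tanh(Rpre);
        // place into concatenated MLP input
        for (int j = 0; j < k; ++j)
          for (int rr = 0; rr < rrows[i]; ++rr)
            MLPin.col(roff + rr + sumR * j) = Rc[i].col(rr + rrows[i] * j);
        roff += rrows[i];
        if (i + 1 < nrounds) Tin[i + 1] = Spool[i];
      }

      Fact.assign(FW.size(), Mat());
      Mat A = MLPin;
      for (size_t j = 0; j < FW.size(); ++j) {
        A = A * FW[j];
        A.each_row() += Fb[j];
        A = arma::clamp(A, T(0), std::numeric_limits<T>::max());
        Fact[j] = A;
      }
      Fvec = A;
    }

    Mat I1;
    if (ablation == 0) I1 = arma::join_rows(Xl[L], Fvec);
    else if (ablation == 1) I1 = Xl[L];
    else I1 = Fvec;

    Hact.assign(HW.size(), Mat());
    Hmask.assign(HW.size(), Mat());
    Mat A = I1;
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    for (size_t j = 0; j < HW.size(); ++j) {
      A = A * HW[j];
      A.each_row() += Hb[j];
      if (j + 1 < HW.size()) {
        A = arma::clamp(A, T(0), std::numeric_limits<T>::max());
        if (training && dropout > 0) {
          Mat msk(A.n_rows, A.n_cols);
          const T scale = static_cast<T>(1.0 / (1.0 - dropout));
          for (arma::uword q = 0; q < msk.n_elem; ++q)
            msk(q) = (unif(rng) >= dropout) ? scale : T(0);
          A %= msk;
          Hmask[j] = std::move(msk);
        }
      }
      Hact[j] = A;
    }
    // row-wise stable softmax
    P = A;
    Col rowmax = arma::max(P, 1);
    P.each_col() -= rowmax;
    P = arma::exp(P);
    Col rs = arma::sum(P, 1);
    P.each_col() /= rs;
    // keep I1 for backward as Hact[-1] predecessor
    I1store = std::move(I1);
  }
  Mat I1store;

  double batch_loss(const IntegerVector& labels,
                    const std::vector<int>& idx) const {
    double s = 0;
    for (int b = 0; b < B; ++b) {
      double p = static_cast<double>(P(b, labels[idx[b]]));
      s += -std::log(std::max(p, 1e-15));
    }
    return s / B;
  }
  int batch_correct(const IntegerVector& labels,
                    const std::vector<int>& idx) const {
    int c = 0;
    for (int b = 0; b < B; ++b)
      if (static_cast<int>(P.row(b).index_max()) == labels[idx[b]]) ++c;
    return c;
  }

  // ---- backward --------------------------------------------------------

  void backward(const IntegerVector& labels, const std::vector<int>& idx) {
    zero_grads();
    const arma::uword Bk = static_cast<arma::uword>(B) * k;
    Mat dZ = P;
    for (int b = 0; b < B; ++b) dZ(b, labels[idx[b]]) -= T(1);
    dZ /= static_cast<T>(B);

    // head backward
    for (int j = static_cast<int>(HW.size()) - 1; j >= 0; --j) {
      const Mat& Aprev = (j == 0) ? I1store : Hact[j - 1];
      g_HW[j] += Aprev.t() * dZ;
      g_Hb[j] += arma::sum(dZ, 0);
      Mat dA = dZ * HW[j].t();
      if (j > 0) {
        if (Hmask[j - 1].n_elem > 0) dA %= Hmask[j - 1];
        dA %= arma::conv_to<Mat>::from(Hact[j - 1] > T(0));
      }
      dZ = std::move(dA);
    }
    // dZ now = gradient wrt I1
    Mat dCcross, dF;
    if (ablation == 0) {
      dCcross = dZ.cols(0, d - 1);
      dF = dZ.cols(d, dZ.n_cols - 1);
    } else if (ablation == 1) {
      dCcross = std::move(dZ);
    } else {
      dF = std::move(dZ);
    }

    Mat dX0total;
    if (ablation != 2) {
      Mat dXl = std::move(dCcross);
      Mat dX0acc(B, d, arma::fill::zeros);
      for (int l = L - 1; l >= 0; --l) {
        Col ds = arma::sum(dXl % X0, 1);
        g_crossW.col(l) += (Xl[l].t() * ds);
        g_crossB.col(l) += arma::sum(dXl, 0).t();
        dX0acc += dXl.each_col() % svals.col(l);
        dXl += ds * crossW.col(l).t();
      }
      dX0total = dX0acc + dXl;
    }

    Mat dT1;
    if (ablation != 1) {
      // fgcnn MLP backward
      Mat dA = std::move(dF);
      for (int j = static_cast<int>(FW.size()) - 1; j >= 0; --j) {
        dA %= arma::conv_to<Mat>::from(Fact[j] > T(0));
        const Mat& Aprev = (j == 0) ? MLPin : Fact[j - 1];
        g_FW[j] += Aprev.t() * dA;
        g_Fb[j] += arma::sum(dA, 0);
        dA = dA * FW[j].t();
      }
      Mat dMLPin = std::move(dA);

      int sumR = 0;
      for (int i = 0; i < nrounds; ++i) sumR += rrows[i];
      Mat dTnext;  // gradient wrt the input of round i+1 (pooled layout)
      for (int i = nrounds - 1; i >= 0; --i) {
        const int H = Hs[i], Hp = Hs[i + 1];
        const int c_in = (i == 0) ? 1 : chans[i - 1];
        const int m = chans[i];
        int roff = 0;
        for (int q = 0; q < i; ++q) roff += rrows[q];
        Mat dRc(B, rrows[i] * k);
        for (int j = 0; j < k; ++j)
          for (int rr = 0; rr < rrows[i]; ++rr)
            dRc.col(rr + rrows[i] * j) = dMLPin.col(roff + rr + sumR * j);
        Mat dRpre = dRc % (T(1) - arma::square(Rc[i]));
        g_RW[i] += Sflat[i].t() * dRpre;
        g_Rb[i] += arma::sum(dRpre, 0);
        Mat dSflat = dRpre * RW[i].t();
        // scatter back to pooled layout, add gradient from round i+1
        Mat dS(Bk * Hp, m, arma::fill::zeros);
        for (int mm = 0; mm < m; ++mm)
          for (int j = 0; j < k; ++j)
            for (int o = 0; o < Hp; ++o) {
              T* dst = dS.colptr(mm) + B * (j + k * o);
              const T* src = dSflat.colptr(o + Hp * j + Hp * k * mm);
              for (int b = 0; b < B; ++b) dst[b] += src[b];
            }
        if (i + 1 < nrounds) dS += dTnext;
        // pooling backward via winners
        Mat dC(Bk * H, m, arma::fill::zeros);
        for (int oo = 0; oo < Hp; ++oo)
          for (int t = 0; t < pool; ++t)
            dC.rows(Bk * (pool * oo + t), Bk * (pool * oo + t) + Bk - 1) +=
                dS.rows(Bk * oo, Bk * oo + Bk - 1) %
                arma::conv_to<Mat>::from(
                    Win[i].rows(Bk * oo, Bk * oo + Bk - 1) ==
                    static_cast<arma::uword>(t));
        // conv backward
        Mat dZc = dC % (T(1) - arma::square(Cact[i]));
        g_Kmat[i] += Xcol[i].t() * dZc;
        g_Kb[i] += arma::sum(dZc, 0);
        Mat dXcol = dZc * Kmat[i].t();
        Mat dTi(Bk * H, c_in, arma::fill::zeros);
        for (int t = 0; t < h; ++t) {
          const int delta = t - pad;
          const int o_lo = std::max(0, -delta);
          const int o_hi = std::min(H - 1, H - 1 - delta);
          if (o_lo > o_hi) continue;
          for (int ci = 0; ci < c_in; ++ci)
            dTi.submat(Bk * (o_lo + delta), ci,
                       Bk * (o_hi + 1 + delta) - 1, ci) +=
                dXcol.submat(Bk * o_lo, t + h * ci,
                             Bk * (o_hi + 1) - 1, t + h * ci);
        }
        dTnext = std::move(dTi);
      }
      dT1 = std::move(dTnext);
    }

    // embedding scatter-add
    for (int f = 0; f < nf; ++f)
      for (int b = 0; b < B; ++b) {
        const arma::uword row = embrows(b, f);
        for (int j = 0; j < k; ++j) {
          T g = 0;
          if (ablation != 2) g += dX0total(b, f * k + j);
          if (ablation != 1)
            g += dT1(b + static_cast<arma::uword>(B) * j +
                     static_cast<arma::uword>(B) * k * f, 0);
          g_emb(row, j) += g;
        }
      }
  }

  // ---- Adam ------------------------------------------------------------

  void adam_step(double lr, int t, double beta1 = 0.9, double beta2 = 0.999,
                 double eps = 1e-8) {
    const T b1 = static_cast<T>(beta1), b2 = static_cast<T>(beta2);
    const T corr1 = static_cast<T>(1.0 - std::pow(beta1, t));
    const T corr2 = static_cast<T>(1.0 - std::pow(beta2, t));
    const T alpha = static_cast<T>(lr);
    const T ieps = static_cast<T>(eps);
    const T ic2 = T(1) / std::sqrt(corr2);
    const T ac1 = alpha / corr1;
    for (Slot& s : slots) {
      T* w = s.w->memptr();
      const T* g = s.g->memptr();
      T* m = s.m.memptr();
      T* v = s.v.memptr();
      const arma::uword n = s.w->n_elem;
      for (arma::uword i = 0; i < n; ++i) {
        m[i] = b1 * m[i] + (T(1) - b1) * g[i];
        v[i] = b2 * v[i] + (T(1) - b2) * g[i] * g[i];
        w[i] -= ac1 * m[i] / (std::sqrt(v[i]) * ic2 + ieps);
      }
    }
  }

  // ---- serialization back to R ----------------------------------------

  NumericMatrix to_rmat(const Mat& m) const {
    NumericMatrix out(m.n_rows, m.n_cols);
    for (arma::uword j = 0; j < m.n_cols; ++j)
      for (arma::uword i = 0; i < m.n_rows; ++i)
        out(i, j) = static_cast<double>(m(i, j));
    return out;
  }
  NumericVector to_rvec(const Mat& m) const {
    NumericVector out(m.n_elem);
    for (arma::uword i = 0; i < m.n_elem; ++i)
      out[i] = static_cast<double>(m(i));
    return out;
  }
  List dump(const List& tmpl) const {
    return dump_from(tmpl, emb, crossW, crossB, Kmat, Kb, RW, Rb, FW, Fb,
                     HW, Hb);
  }
  List dump_grads(const List& tmpl) const {
    return dump_from(tmpl, g_emb, g_crossW, g_crossB, g_Kmat, g_Kb, g_RW,
                     g_Rb, g_FW, g_Fb, g_HW, g_Hb);
  }
  List dump_from(const List& tmpl, const Mat& e, const Mat& cw, const Mat& cb,
                 const std::vector<Mat>& km, const std::vector<Mat>& kb,
                 const std::vector<Mat>& rw, const std::vector<Mat>& rb,
                 const std::vector<Mat>& fw, const std::vector<Mat>& fb,
                 const std::vector<Mat>& hw, const std::vector<Mat>& hb)
      const {
    List pe = Rcpp::clone(as<List>(tmpl["emb"]));
    pe["table"] = to_rmat(e);
    List pc = Rcpp::clone(as<List>(tmpl["cross"]));
    pc["W"] = to_rmat(cw);
    pc["b"] = to_rmat(cb);
    List pf = Rcpp::clone(as<List>(tmpl["fgcnn"]));
    List conv = pf["conv"], recomb = pf["recomb"], mlp = pf["mlp"];
    for (int i = 0; i < nrounds; ++i) {
      List ci = Rcpp::clone(as<List>(conv[i]));
      NumericVector Karr = to_rvec(km[i]);
      NumericVector tdim = as<List>(conv[i])["K"];
      Karr.attr("dim") = tdim.attr("dim");
      ci["K"] = Karr;
      ci["b"] = to_rvec(kb[i]);
      conv[i] = ci;
      List ri = Rcpp::clone(as<List>(recomb[i]));
      ri["W"] = to_rmat(rw[i]);
      ri["b"] = to_rvec(rb[i]);
      recomb[i] = ri;
    }
    List lw = Rcpp::clone(as<List>(as<List>(mlp)["W"]));
    List lb = Rcpp::clone(as<List>(as<List>(mlp)["b"]));
    for (size_t j = 0; j < fw.size(); ++j) {
      lw[j] = to_rmat(fw[j]);
      lb[j] = to_rvec(fb[j]);
    }
    List mlp2 = List::create(Rcpp::Named("W") = lw, Rcpp::Named("b") = lb);
    pf["conv"] = conv; pf["recomb"] = recomb; pf["mlp"] = mlp2;
    List hw2 = List::create(), hb2 = List::create();
    List hwl = List::create(), hbl = List::create();
    for (size_t j = 0; j < hw.size(); ++j) {
      hwl.push_back(to_rmat(hw[j]));
      hbl.push_back(to_rvec(hb[j]));
    }
    List ph = List::create(Rcpp::Named("W") = hwl, Rcpp::Named("b") = hbl);
    return List::create(Rcpp::Named("emb") = pe, Rcpp::Named("cross") = pc,
                        Rcpp::Named("fgcnn") = pf, Rcpp::Named("head") = ph);
  }
};

template <typename T>
List train_impl(List params, const IntegerMatrix& codes,
                const IntegerVector& labels, const List& cfg) {
  Engine<T> eng;
  eng.load(params, cfg);
  FlushDenormalsGuard ftz(sizeof(T) == sizeof(float));
  const int epochs = as<int>(cfg["epochs"]);
  const int bs = as<int>(cfg["batch_size"]);
  const double lr = as<double>(cfg["lr"]);
  const int seed = as<int>(cfg["seed"]);
  const int n = codes.nrow();

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;

  NumericVector hist_acc(epochs), hist_loss(epochs);
  int t = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(perm.begin(), perm.end(), rng);
    double ep_loss = 0;
    int ep_correct = 0, nb = 0;
    for (int start = 0; start < n; start += bs) {
      const int stop = std::min(n, start + bs);
      std::vector<int> idx(perm.begin() + start, perm.begin() + stop);
      eng.forward(codes, idx, true, rng);
      ep_loss += eng.batch_loss(labels, idx) * idx.size();
      ep_correct += eng.batch_correct(labels, idx);
      eng.backward(labels, idx);
      if (lr > 0) eng.adam_step(lr, ++t);
      ++nb;
      if (!std::isfinite(ep_loss))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
    }
    hist_loss[ep] = ep_loss / n;
    hist_acc[ep] = static_cast<double>(ep_correct) / n;
    Rcpp::checkUserInterrupt();
  }
  return List::create(
      Rcpp::Named("params") = eng.dump(params),
      Rcpp::Named("history") = List::create(
          Rcpp::Named("accuracy") = hist_acc,
          Rcpp::Named("loss") = hist_loss));
}

// [[Rcpp::export]]
List cfgcnn_train_cpp(List params, IntegerMatrix codes, IntegerVector labels,
                      List cfg) {
  const std::string prec = as<std::string>(cfg["precision"]);
  if (prec == "double") return train_impl<double>(params, codes, labels, cfg);
  return train_impl<float>(params, codes, labels, cfg);
}

// [[Rcpp::export]]
NumericMatrix cfgcnn_forward_cpp(List params, IntegerMatrix codes, List cfg) {
  Engine<double> eng;
  eng.load(params, cfg);
  std::mt19937_64 rng(0);
  const int n = codes.nrow();
  NumericMatrix out(n, eng.ncls);
  const int chunk = 1024;
  for (int start = 0; start < n; start += chunk) {
    const int stop = std::min(n, start + chunk);
    std::vector<int> idx(stop - start);
    for (int i = 0; i < stop - start; ++i) idx[i] = start + i;
    eng.forward(codes, idx, false, rng);
    for (int b = 0; b < stop - start; ++b)
      for (int j = 0; j < eng.ncls; ++j)
        out(start + b, j) = eng.P(b, j);
  }
  return out;
}

// [[Rcpp::export]]
List cfgcnn_grad_cpp(List params, IntegerMatrix codes, IntegerVector labels,
                     List cfg) {
  Engine<double> eng;
  eng.load(params, cfg);
  std::mt19937_64 rng(0);
  std::vector<int> idx(codes.nrow());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = static_cast<int>(i);
  eng.forward(codes, idx, false, rng);
  const double loss = eng.batch_loss(labels, idx);
  eng.backward(labels, idx);
  return List::create(Rcpp::Named("loss") = loss,
                      Rcpp::Named("grads") = eng.dump_grads(params));
}
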