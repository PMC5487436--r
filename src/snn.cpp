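// Event-driven spiking ConvNet core: Gabor convolution layer of signed LIF
// neurons with linear leakage, subsampling (address remap) pooling, flatten
// relabeling, and an optional fully-connected positive-only LIF classifier.
// Semantics match the R reference neuron (lif_receive): leak first, then the
// instantaneous weight update, inclusive threshold comparison, reset to rest.
// Events are processed in input order with eager depth-first propagation;
// with zero module delays this equals the global earliest-first dispatch of
// the generic scheduler (nodes registered deepest-first).
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Leak {
  double slope_plus, slope_minus;  // membrane units per microsecond
  inline void apply(double &vm, double &tlast, double tnow) const {
    double dt = tnow - tlast;
    tlast = tnow;
    if (dt <= 0.0 || vm == 0.0) return;
    if (vm > 0.0) {
      vm -= slope_plus * dt;
      if (vm < 0.0) vm = 0.0;
    } else {
      vm += slope_minus * dt;
      if (vm > 0.0) vm = 0.0;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_run_snn(NumericVector ev_t, IntegerVector ev_x, IntegerVector ev_y,
                 NumericVector ev_sign, int width, int height, int ksize,
                 NumericMatrix kernels, double c1_th_plus, double c1_th_minus,
                 bool c1_emit_neg, double c1_slope_plus, double c1_slope_minus,
                 int pool, Nullable<NumericMatrix> fc_weights, double fc_th,
                 double fc_slope_plus, double fc_slope_minus,
                 NumericVector reset_times, bool record_flatten,
                 bool record_c1_vm) {
  const int n_ev = ev_t.size();
  const int n_fm = kernels.ncol();
  const int side_x = width - ksize + 1, side_y = height - ksize + 1;
  if (side_x < 1 || side_y < 1) stop("kernel larger than input");
  const int psx = side_x / pool, psy = side_y / pool;
  const bool has_fc = fc_weights.isNotNull();
  NumericMatrix W;
  int n_cls = 0;
  if (has_fc) {
    W = NumericMatrix(fc_weights);
    n_cls = W.nrow();
    if (W.ncol() != n_fm * psx * psy)
      stop("classifier weight matrix does not match the flatten size");
  }

  const Leak c1_leak{c1_slope_plus, c1_slope_minus};
  const Leak fc_leak{fc_slope_plus, fc_slope_minus};

  std::vector<double> vm(static_cast<size_t>(n_fm) * side_y * side_x, 0.0);
  std::vector<double> tl(vm.size(), 0.0);
  std::vector<double> fc_vm(n_cls, 0.0), fc_tl(n_cls, 0.0);

  std::vector<double> fl_t, fl_sign, fc_t;
  std::vector<int> fl_idx, fc_cls;
  long long n_c1 = 0, n_fc = 0;

  int ri = 0;
  const int n_reset = reset_times.size();

  for (int e = 0; e < n_ev; ++e) {
    const double t = ev_t[e];
    while (ri < n_reset && reset_times[ri] <= t) {
      const double tr = reset_times[ri];
      std::fill(vm.begin(), vm.end(), 0.0);
      std::fill(tl.begin(), tl.end(), tr);
      std::fill(fc_vm.begin(), fc_vm.end(), 0.0);
      std::fill(fc_tl.begin(), fc_tl.end(), tr);
      ++ri;
    }
    const int x = ev_x[e], y = ev_y[e];
    const double s = ev_sign[e];
    if (x < 0 || x >= width || y < 0 || y >= height)
      stop("event %d outside the input geometry", e + 1);
    const int xo_lo = std::max(0, x - ksize + 1), xo_hi = std::min(side_x - 1, x);
    const int yo_lo = std::max(0, y - ksize + 1), yo_hi = std::min(side_y - 1, y);
    for (int fm = 0; fm < n_fm; ++fm) {
      const double *K = &kernels(0, fm);
      double *vfm = &vm[static_cast<size_t>(fm) * side_y * side_x];
      double *tfm = &tl[static_cast<size_t>(fm) * side_y * side_x];
      for (int yo = yo_lo; yo <= yo_hi; ++yo) {
        const int dy = y - yo;
        for (int xo = xo_lo; xo <= xo_hi; ++xo) {
          const int dx = x - xo;
          const size_t j = static_cast<size_t>(yo) * side_x + xo;
          c1_leak.apply(vfm[j], tfm[j], t);
          vfm[j] += s * K[dy * ksize + dx];
          double out = 0.0;
          if (vfm[j] >= c1_th_plus) {
            out = 1.0;
            vfm[j] = 0.0;
          } else if (vfm[j] <= c1_th_minus) {
            if (c1_emit_neg) out = -1.0;
            vfm[j] = 0.0;
          }
          if (out != 0.0) {
            ++n_c1;
            const int idx = fm * psx * psy + (yo / pool) * psx + (xo / pool);
            if (record_flatten) {
              fl_t.push_back(t);
              fl_idx.push_back(idx);
              fl_sign.push_back(out);
            }
            if (has_fc) {
              for (int c = 0; c < n_cls; ++c) {
                fc_leak.apply(fc_vm[c], fc_tl[c], t);
                fc_vm[c] += out * W(c, idx);
                if (fc_vm[c] >= fc_th) {
                  fc_vm[c] = 0.0;
                  ++n_fc;
                  fc_t.push_back(t);
                  fc_cls.push_back(c);
                }
                // classifier neurons are the degenerate positive-only
                // variant: the negative threshold is a numeric sentinel
                // that is never reached in practice
              }
            }
          }
        }
      }
    }
  }

  List out = List::create(
      _["n_input"] = n_ev, _["n_c1"] = static_cast<double>(n_c1),
      _["n_fc"] = static_cast<double>(n_fc),
      _["flatten_t"] = wrap(fl_t), _["flatten_idx"] = wrap(fl_idx),
      _["flatten_sign"] = wrap(fl_sign), _["fc_t"] = wrap(fc_t),
      _["fc_class"] = wrap(fc_cls));
  if (record_c1_vm) {
    List maps(n_fm);
    for (int fm = 0; fm < n_fm; ++fm) {
      NumericMatrix m(side_y, side_x);
      for (int yo = 0; yo < side_y; ++yo)
        for (int xo = 0; xo < side_x; ++xo)
          m(yo, xo) = vm[static_cast<size_t>(fm) * side_y * side_x +
                         static_cast<size_t>(yo) * side_x + xo];
      maps[fm] = m;
    }
    out["c1_vm"] = maps;
  }
  return out;
}

// Standalone fully-connected spiking classifier pass over recorded flatten
// events (used when the front end has already been simulated).
// [[Rcpp::export]]
List cpp_run_fc(NumericVector ev_t, IntegerVector ev_idx, NumericVector ev_sign,
                NumericMatrix W, double fc_th, double fc_slope_plus,
                double fc_slope_minus, NumericVector reset_times) {
  const int n_ev = ev_t.size(), n_cls = W.nrow(), h = W.ncol();
  const Leak fc_leak{fc_slope_plus, fc_slope_minus};
  std::vector<double> vm(n_cls, 0.0), tl(n_cls, 0.0);
  std::vector<double> fc_t;
  std::vector<int> fc_cls;
  int ri = 0;
  const int n_reset = reset_times.size();
  for (int e = 0; e < n_ev; ++e) {
    const double t = ev_t[e];
    while (ri < n_reset && reset_times[ri] <= t) {
      std::fill(vm.begin(), vm.end(), 0.0);
      std::fill(tl.begin(), tl.end(), reset_times[ri]);
      ++ri;
    }
    const int idx = ev_idx[e];
    if (idx < 0 || idx >= h) stop("flatten index %d out of range", idx);
    const double s = ev_sign[e];
    for (int c = 0; c < n_cls; ++c) {
      fc_leak.apply(vm[c], tl[c], t);
      vm[c] += s * W(c, idx);
      if (vm[c] >= fc_th) {
        vm[c] = 0.0;
        fc_t.push_back(t);
        fc_cls.push_back(c);
      }
    }
  }
  return List::create(_["fc_t"] = wrap(fc_t), _["fc_class"] = wrap(fc_cls));
}
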