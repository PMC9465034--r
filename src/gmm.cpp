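// Per-pixel, per-channel adaptive Gaussian-mixture background model
// (Stauffer-Grimson style): K components per pixel-channel, matched within
// match_sigma standard deviations, exponential updates with learning rate
// alpha, unmatched observations replace the least-likely (lowest w/sigma)
// component, and the top-weight components covering cumulative weight
// bg_fraction form the background. A pixel is foreground when any channel
// fails to match a background component.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// [[Rcpp::export]]
List gmm_subtract_cpp(List frames, int K, double alpha, double match_sigma,
                      double bg_fraction, double init_var, double var_floor,
                      double low_weight) {
  int n_frames = frames.size();
  if (n_frames < 1) stop("empty frame stack");
  NumericVector f0 = frames[0];
  IntegerVector dims = f0.attr("dim");
  if (dims.size() != 3 || dims[2] != 3) stop("frames must be H x W x 3 arrays");
  const int H = dims[0], W = dims[1], HW = H * W, NC = 3;
  const long nstate = (long)HW * NC * K;

  std::vector<float> wv(nstate, 0.0f), mu(nstate, 0.0f), var(nstate, (float)init_var);
  // seed component 0 of every pixel-channel with the first frame
  for (int c = 0; c < NC; ++c)
    for (int p = 0; p < HW; ++p) {
      long b = ((long)c * HW + p) * K;
      wv[b] = 1.0f;
      mu[b] = (float)f0[p + c * HW];
    }

  List masks(n_frames);
  std::vector<int> order(K);
  for (int t = 0; t < n_frames; ++t) {
    NumericVector fr = frames[t];
    LogicalMatrix mask(H, W);
    for (int p = 0; p < HW; ++p) {
      bool fg_any = false;
      for (int c = 0; c < NC; ++c) {
        long b = ((long)c * HW + p) * K;
        double v = fr[p + c * HW];
        // sort component indices by w/sigma descending (K is tiny)
        for (int k = 0; k < K; ++k) order[k] = k;
        std::sort(order.begin(), order.end(), [&](int a, int bb) {
          double sa = wv[b + a] / std::sqrt((double)var[b + a]);
          double sb = wv[b + bb] / std::sqrt((double)var[b + bb]);
          return sa > sb;
        });
        // background set: smallest prefix with cumulative weight >= T
        int n_bg = K;
        double cum = 0.0;
        for (int k = 0; k < K; ++k) {
          cum += wv[b + order[k]];
          if (cum >= bg_fraction) { n_bg = k + 1; break; }
        }
        // first match in sorted order
        int match = -1;
        for (int k = 0; k < K; ++k) {
          int kk = order[k];
          if (wv[b + kk] <= 0.0f) continue;
          double sd = std::sqrt((double)var[b + kk]);
          if (std::fabs(v - mu[b + kk]) <= match_sigma * sd) { match = k; break; }
        }
        if (match < 0 || match >= n_bg) fg_any = true;
        if (alpha > 0.0) {
          if (match >= 0) {
            int kk = order[match];
            for (int k = 0; k < K; ++k) {
              long i = b + k;
              wv[i] = (1.0 - alpha) * wv[i] + (k == kk ? alpha : 0.0);
            }
            long i = b + kk;
            double d = v - mu[i];
            mu[i] += alpha * d;
            double nv = var[i] + alpha * (d * d - var[i]);
            var[i] = (float)std::max(nv, var_floor);
          } else {
            int kk = order[K - 1];  // least likely component replaced
            long i = b + kk;
            mu[i] = (float)v;
            var[i] = (float)init_var;
            wv[i] = (float)low_weight;
          }
          double s = 0.0;
          for (int k = 0; k < K; ++k) s += wv[b + k];
          if (s > 0) for (int k = 0; k < K; ++k) wv[b + k] = (float)(wv[b + k] / s);
        }
      }
      if (fg_any) mask[p] = true;
    }
    masks[t] = mask;
  }
  return masks;
}
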