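#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Greyscale morphological reconstruction by dilation (8-connectivity),
// fast-hybrid algorithm: one forward and one backward raster sweep,
// then FIFO-queue propagation until stable. marker <= mask elementwise
// is enforced by the R wrapper.
// [[Rcpp::export(name = ".reconstruct_dilate_cpp")]]
NumericMatrix reconstruct_dilate_cpp(NumericMatrix marker, NumericMatrix mask) {
  const int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask must have identical dimensions");
  NumericMatrix J = clone(marker);

  // neighbour offsets (dr, dc); N+ = already scanned in the column-major
  // sweep (earlier column, or same column and earlier row), N- the rest
  const int drp[4] = {-1, 0, 1, -1};
  const int dcp[4] = {-1, -1, -1, 0};
  const int drm[4] = {-1, 0, 1, 1};
  const int dcm[4] = {1, 1, 1, 0};

  // forward raster sweep
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + drp[k], cc = c + dcp[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && J(rr, cc) > v)
          v = J(rr, cc);
      }
      J(r, c) = std::min(v, mask(r, c));
    }
  }

  // backward sweep, queueing pixels that can still propagate
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c) {
    for (int r = nr - 1; r >= 0; --r) {
      double v = J(r, c);
      for (int k = 0; k < 4; ++k) {
        int rr = r + drm[k], cc = c + dcm[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc && J(rr, cc) > v)
          v = J(rr, cc);
      }
      v = std::min(v, mask(r, c));
      J(r, c) = v;
      for (int k = 0; k < 4; ++k) {
        int rr = r + drm[k], cc = c + dcm[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc &&
            J(rr, cc) < v && J(rr, cc) < mask(rr, cc)) {
          fifo.push(r + c * nr);
          break;
        }
      }
    }
  }

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int r = p % nr, c = p / nr;
    double v = J(r, c);
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr8[k], cc = c + dc8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < v && mask(rr, cc) != J(rr, cc)) {
        double nv = std::min(v, mask(rr, cc));
        if (nv > J(rr, cc)) {
          J(rr, cc) = nv;
          fifo.push(rr + cc * nr);
        }
      }
    }
  }
  return J;
}
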