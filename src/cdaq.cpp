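#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary mask.
// Labels are assigned in raster-scan order of each component's first pixel
// (column-major, matching R matrix storage read row-by-row would differ;
// here "raster" means ascending (row, col) lexicographic order), so the
// labeling is fully deterministic.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int n_off = (connectivity == 4) ? 4 : 8;
  const int off_r[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int off_c[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next_label = 0;
  std::vector<int> stack_r, stack_c;
  // scan rows outer, cols inner: first pixel of a component is the smallest
  // (row, col) pair not yet labeled
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next_label;
      lab(i, j) = next_label;
      stack_r.clear(); stack_c.clear();
      stack_r.push_back(i); stack_c.push_back(j);
      while (!stack_r.empty()) {
        int r = stack_r.back(); stack_r.pop_back();
        int c = stack_c.back(); stack_c.pop_back();
        for (int k = 0; k < n_off; ++k) {
          int rr = r + off_r[k], cc = c + off_c[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next_label;
            stack_r.push_back(rr); stack_c.push_back(cc);
          }
        }
      }
    }
  }
  return lab;
}

// Scan of all candidate CDA displacements in one pass.
// W: channel-1 intensity restricted to its mask (0 elsewhere);
// M: channel-1 mask; conf: confinement mask; ch2: channel-2 mask.
// For each displacement d = (dy, dx), a mask pixel at (r, c) lands on
// (r + dy, c + dx); pixels leaving the frame or the confinement are dropped.
// Returns per displacement: retained mask pixel count, the displaced
// intensity denominator sum(W over conf) and numerator sum(W over conf & ch2).
// Exact integer-shift arithmetic (no interpolation, no FFT).
// [[Rcpp::export(name = ".cda_scan_cpp")]]
DataFrame cda_scan_cpp(NumericMatrix W, LogicalMatrix M,
                       LogicalMatrix conf, LogicalMatrix ch2,
                       IntegerVector dy, IntegerVector dx) {
  const int nr = W.nrow(), nc = W.ncol();
  if (M.nrow() != nr || conf.nrow() != nr || ch2.nrow() != nr ||
      M.ncol() != nc || conf.ncol() != nc || ch2.ncol() != nc)
    stop("all images must share one shape");
  // sparse pixel list of the channel-1 mask
  std::vector<int> pr, pc;
  std::vector<double> pw;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (M(i, j)) { pr.push_back(i); pc.push_back(j); pw.push_back(W(i, j)); }
  const int npx = (int)pr.size(), nd = dy.size();
  IntegerVector retained(nd);
  NumericVector den(nd), num(nd);
  for (int d = 0; d < nd; ++d) {
    const int sy = dy[d], sx = dx[d];
    int ret = 0; double dsum = 0.0, nsum = 0.0;
    for (int p = 0; p < npx; ++p) {
      const int rr = pr[p] + sy, cc = pc[p] + sx;
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!conf(rr, cc)) continue;
      ++ret;
      dsum += pw[p];
      if (ch2(rr, cc)) nsum += pw[p];
    }
    retained[d] = ret; den[d] = dsum; num[d] = nsum;
  }
  return DataFrame::create(_["dy"] = dy, _["dx"] = dx,
                           _["retained"] = retained,
                           _["den"] = den, _["num"] = num);
}
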