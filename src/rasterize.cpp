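#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Software rasterizer: supersampled triangle scan conversion with a z-buffer
// (orthographic, nadir view; larger z wins). Colors are flat per triangle.
// Returns the box-downsampled RGB image, the per-pixel covered-subsample
// count (for the majority-rule mask) and, per primitive, the number of
// final-resolution mask pixels where that primitive owns at least one
// visible (z-winning) subsample.
//
// verts: n x 2 matrix, pixel coordinates at final resolution (x right,
//        y down, origin at the top-left pixel corner); vz: per-vertex height.
// tris:  m x 3 zero-based vertex indices. tri_prim: m, zero-based primitive
//        id. prim_color: nprim x 3 in [0,1].
// [[Rcpp::export]]
List rasterize_cpp(NumericMatrix verts, NumericVector vz, IntegerMatrix tris,
                   IntegerVector tri_prim, NumericMatrix prim_color,
                   int size, int ss, NumericVector bg) {
  const int S = size * ss;
  const int n_tri = tris.nrow();
  const int n_prim = prim_color.nrow();
  std::vector<double> zbuf((size_t)S * S,
                           -std::numeric_limits<double>::infinity());
  std::vector<int> owner((size_t)S * S, -1); // winning primitive per subsample
  std::vector<unsigned char> hit((size_t)S * S, 0);

  for (int t = 0; t < n_tri; ++t) {
    const int i0 = tris(t, 0), i1 = tris(t, 1), i2 = tris(t, 2);
    // subsample-grid coordinates; sample points at subpixel centers
    double x0 = verts(i0, 0) * ss, y0 = verts(i0, 1) * ss;
    double x1 = verts(i1, 0) * ss, y1 = verts(i1, 1) * ss;
    double x2 = verts(i2, 0) * ss, y2 = verts(i2, 1) * ss;
    double z0 = vz[i0], z1 = vz[i1], z2 = vz[i2];
    double minx = std::min(x0, std::min(x1, x2));
    double maxx = std::max(x0, std::max(x1, x2));
    double miny = std::min(y0, std::min(y1, y2));
    double maxy = std::max(y0, std::max(y1, y2));
    int xa = std::max(0, (int)std::floor(minx - 0.5));
    int xb = std::min(S - 1, (int)std::ceil(maxx - 0.5) + 1);
    int ya = std::max(0, (int)std::floor(miny - 0.5));
    int yb = std::min(S - 1, (int)std::ceil(maxy - 0.5) + 1);
    if (xa > xb || ya > yb) continue;
    double den = (y1 - y2) * (x0 - x2) + (x2 - x1) * (y0 - y2);
    if (std::fabs(den) < 1e-12) continue; // degenerate
    int prim = tri_prim[t];
    for (int py = ya; py <= yb; ++py) {
      double sy = py + 0.5;
      for (int px = xa; px <= xb; ++px) {
        double sx = px + 0.5;
        double w0 = ((y1 - y2) * (sx - x2) + (x2 - x1) * (sy - y2)) / den;
        double w1 = ((y2 - y0) * (sx - x2) + (x0 - x2) * (sy - y2)) / den;
        double w2 = 1.0 - w0 - w1;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        size_t idx = (size_t)py * S + px;
        double z = w0 * z0 + w1 * z1 + w2 * z2;
        hit[idx] = 1;
        if (z > zbuf[idx]) { zbuf[idx] = z; owner[idx] = prim; }
      }
    }
  }

  // coverage per final pixel + majority-rule mask
  IntegerMatrix coverage(size, size);
  const int maj = (ss * ss + 1) / 2; // majority of ss^2 subsamples
  LogicalMatrix mask(size, size);
  for (int py = 0; py < size; ++py)
    for (int px = 0; px < size; ++px) {
      int c = 0;
      for (int dy = 0; dy < ss; ++dy)
        for (int dx = 0; dx < ss; ++dx)
          c += hit[(size_t)(py * ss + dy) * S + (px * ss + dx)];
      coverage(py, px) = c;
      mask(py, px) = (c >= maj);
    }

  // per-primitive visible mask-pixel counts
  IntegerVector prim_mask_pixels(n_prim);
  for (int py = 0; py < size; ++py)
    for (int px = 0; px < size; ++px) {
      if (!mask(py, px)) continue;
      // which primitives win a subsample in this pixel
      int seen[16]; int nseen = 0;
      for (int dy = 0; dy < ss; ++dy)
        for (int dx = 0; dx < ss; ++dx) {
          int ow = owner[(size_t)(py * ss + dy) * S + (px * ss + dx)];
          if (ow < 0) continue;
          bool dup = false;
          for (int k = 0; k < nseen; ++k) if (seen[k] == ow) { dup = true; break; }
          if (!dup && nseen < 16) seen[nseen++] = ow;
        }
      for (int k = 0; k < nseen; ++k) prim_mask_pixels[seen[k]] += 1;
    }

  // downsample to the final image; non-mask pixels are exactly background
  NumericVector img(Dimension(size, size, 3));
  double bgr = bg[0], bgg = bg[1], bgb = bg[2];
  for (int py = 0; py < size; ++py)
    for (int px = 0; px < size; ++px) {
      double r, g, b;
      if (!mask(py, px)) {
        r = bgr; g = bgg; b = bgb;
      } else {
        r = g = b = 0.0;
        for (int dy = 0; dy < ss; ++dy)
          for (int dx = 0; dx < ss; ++dx) {
            int ow = owner[(size_t)(py * ss + dy) * S + (px * ss + dx)];
            if (ow < 0) { r += bgr; g += bgg; b += bgb; }
            else {
              r += prim_color(ow, 0); g += prim_color(ow, 1);
              b += prim_color(ow, 2);
            }
          }
        double inv = 1.0 / (ss * ss);
        r *= inv; g *= inv; b *= inv;
      }
      img[py + size * px] = r;
      img[py + size * px + (size_t)size * size] = g;
      img[py + size * px + 2 * (size_t)size * size] = b;
    }

  return List::create(_["image"] = img, _["coverage"] = coverage,
                      _["mask"] = mask,
                      _["prim_mask_pixels"] = prim_mask_pixels);
}

// Bilinear resize of an H x W x C array in [0,1] to out_h x out_w.
// Sample positions follow the pixel-center (align-corners = false)
// convention used by standard image libraries.
// [[Rcpp::export]]
NumericVector resize_bilinear_cpp(NumericVector img, int out_h, int out_w) {
  IntegerVector dims = img.attr("dim");
  const int H = dims[0], W = dims[1], C = dims.size() > 2 ? dims[2] : 1;
  NumericVector out(Dimension(out_h, out_w, C));
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int c = 0; c < C; ++c) {
    const double *in = &img[(size_t)c * H * W];
    double *o = &out[(size_t)c * out_h * out_w];
    for (int j = 0; j < out_w; ++j) {
      double xs = (j + 0.5) * sx - 0.5;
      int x0 = (int)std::floor(xs);
      double fx = xs - x0;
      int x0c = std::min(std::max(x0, 0), W - 1);
      int x1c = std::min(x0 + 1, W - 1);
      for (int i = 0; i < out_h; ++i) {
        double ys = (i + 0.5) * sy - 0.5;
        int y0 = (int)std::floor(ys);
        double fy = ys - y0;
        int y0c = std::min(std::max(y0, 0), H - 1);
        int y1c = std::min(y0 + 1, H - 1);
        double v00 = in[y0c + (size_t)H * x0c], v01 = in[y0c + (size_t)H * x1c];
        double v10 = in[y1c + (size_t)H * x0c], v11 = in[y1c + (size_t)H * x1c];
        o[i + (size_t)out_h * j] =
          (1 - fy) * ((1 - fx) * v00 + fx * v01) +
          fy * ((1 - fx) * v10 + fx * v11);
      }
    }
  }
  return out;
}
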