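#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Z-buffered sphere impostor rasterizer with orthographic projection.
//
// Screen coordinates are in pixel units: x grows to the right, y grows
// downwards (row-major image), z grows towards the viewer.  A pixel
// (row i, col j), both 0-based, has its centre at (j + 0.5, i + 0.5).
// Shading is a single headlight along +z: I = ambient + diffuse * nz.
// All rounding is floor(x + 0.5) so an R oracle can match byte-for-byte.

// [[Rcpp::export(name = ".render_spheres_cpp")]]
IntegerVector render_spheres_cpp(NumericVector cx, NumericVector cy,
                                 NumericVector cz, NumericVector rad,
                                 IntegerVector red, IntegerVector green,
                                 IntegerVector blue,
                                 int width, int height,
                                 IntegerVector background,
                                 double ambient, double diffuse) {
  const R_xlen_t n = cx.size();
  const R_xlen_t npx = (R_xlen_t)width * height;
  IntegerVector img(npx * 3);
  std::vector<double> zbuf(npx, -INFINITY);
  for (R_xlen_t p = 0; p < npx; ++p) {
    img[p * 3 + 0] = background[0];
    img[p * 3 + 1] = background[1];
    img[p * 3 + 2] = background[2];
  }
  for (R_xlen_t a = 0; a < n; ++a) {
    const double x = cx[a], y = cy[a], z = cz[a], r = rad[a];
    if (!(r > 0)) continue;
    int j0 = (int)std::floor(x - r - 0.5);
    int j1 = (int)std::ceil(x + r - 0.5);
    int i0 = (int)std::floor(y - r - 0.5);
    int i1 = (int)std::ceil(y + r - 0.5);
    if (j0 < 0) j0 = 0;
    if (i0 < 0) i0 = 0;
    if (j1 > width - 1) j1 = width - 1;
    if (i1 > height - 1) i1 = height - 1;
    for (int i = i0; i <= i1; ++i) {
      const double py = i + 0.5;
      for (int j = j0; j <= j1; ++j) {
        const double px = j + 0.5;
        const double dx = px - x, dy = py - y;
        const double d2 = dx * dx + dy * dy;
        if (d2 > r * r) continue;
        const double h = std::sqrt(r * r - d2);
        const double zs = z + h;  // sphere surface towards the viewer
        const R_xlen_t p = (R_xlen_t)i * width + j;
        if (zs <= zbuf[p]) continue;
        zbuf[p] = zs;
        const double nz = h / r;  // headlight: n . l = nz
        const double inten = ambient + diffuse * nz;
        int rr = (int)std::floor(red[a] * inten + 0.5);
        int gg = (int)std::floor(green[a] * inten + 0.5);
        int bb = (int)std::floor(blue[a] * inten + 0.5);
        img[p * 3 + 0] = rr > 255 ? 255 : rr;
        img[p * 3 + 1] = gg > 255 ? 255 : gg;
        img[p * 3 + 2] = bb > 255 ? 255 : bb;
      }
    }
  }
  return img;
}

// Area-weighted box-filter downscale.  `img` is interleaved RGB,
// row-major, length w*h*3.  Integer scale ratios reduce to a plain
// box average; fractional ratios weight source pixels by overlap.
// Rounding is floor(x + 0.5) ("round half up"), documented behaviour.

// [[Rcpp::export(name = ".box_downscale_cpp")]]
IntegerVector box_downscale_cpp(IntegerVector img, int sw, int sh,
                                int tw, int th) {
  IntegerVector out((R_xlen_t)tw * th * 3);
  const double fx = (double)sw / tw, fy = (double)sh / th;
  for (int ti = 0; ti < th; ++ti) {
    const double y0 = ti * fy, y1 = (ti + 1) * fy;
    const int si0 = (int)std::floor(y0);
    const int si1 = std::min((int)std::ceil(y1), sh);
    for (int tj = 0; tj < tw; ++tj) {
      const double x0 = tj * fx, x1 = (tj + 1) * fx;
      const int sj0 = (int)std::floor(x0);
      const int sj1 = std::min((int)std::ceil(x1), sw);
      double acc[3] = {0, 0, 0};
      double wsum = 0;
      for (int si = si0; si < si1; ++si) {
        const double wy = std::min((double)si + 1, y1) - std::max((double)si, y0);
        for (int sj = sj0; sj < sj1; ++sj) {
          const double wx = std::min((double)sj + 1, x1) - std::max((double)sj, x0);
          const double w = wx * wy;
          const R_xlen_t p = ((R_xlen_t)si * sw + sj) * 3;
          acc[0] += w * img[p + 0];
          acc[1] += w * img[p + 1];
          acc[2] += w * img[p + 2];
          wsum += w;
        }
      }
      const R_xlen_t q = ((R_xlen_t)ti * tw + tj) * 3;
      for (int c = 0; c < 3; ++c) {
        int v = (int)std::floor(acc[c] / wsum + 0.5);
        out[q + c] = v > 255 ? 255 : (v < 0 ? 0 : v);
      }
    }
  }
  return out;
}

// CRC-32 (IEEE 802.3, reflected polynomial 0xEDB88320) over a raw
// vector, as required by the PNG chunk format.

// [[Rcpp::export(name = ".crc32_cpp")]]
double crc32_cpp(RawVector data) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : (c >> 1);
      table[i] = c;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
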