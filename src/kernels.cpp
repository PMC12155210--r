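// Low-level numerical kernels: 3x3x3 convolution via im2col, nearest
// upsampling, slice-wise median filtering, trilinear/nearest resampling and
// connected-component labeling. Feature maps are (channels x voxels)
// matrices with voxel index running fastest along the first image axis.
#include <RcppArmadillo.h>
#include <functional>
#include <map>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int n, int stride) { // kernel 3, pad 1
  return (n - 1) / stride + 1;
}

// [[Rcpp::export]]
arma::mat cpp_im2col3(const arma::mat& x, IntegerVector dims, int stride) {
  const int C = x.n_rows;
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = out_dim(d1, stride), o2 = out_dim(d2, stride), o3 = out_dim(d3, stride);
  arma::mat cols(C * 27, (arma::uword)o1 * o2 * o3, arma::fill::zeros);
  for (int k = 0; k < o3; ++k) {
    for (int j = 0; j < o2; ++j) {
      for (int i = 0; i < o1; ++i) {
        const arma::uword col = (arma::uword)i + (arma::uword)o1 * (j + (arma::uword)o2 * k);
        int t = 0;
        for (int dk = -1; dk <= 1; ++dk) {
          const int zz = k * stride + dk;
          for (int dj = -1; dj <= 1; ++dj) {
            const int yy = j * stride + dj;
            for (int di = -1; di <= 1; ++di, ++t) {
              const int xx = i * stride + di;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= d1 || yy >= d2 || zz >= d3) continue;
              const arma::uword src = (arma::uword)xx + (arma::uword)d1 * (yy + (arma::uword)d2 * zz);
              for (int c = 0; c < C; ++c) cols(t * C + c, col) = x(c, src);
            }
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
arma::mat cpp_col2im3(const arma::mat& cols, int C, IntegerVector dims, int stride) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = out_dim(d1, stride), o2 = out_dim(d2, stride), o3 = out_dim(d3, stride);
  arma::mat x(C, (arma::uword)d1 * d2 * d3, arma::fill::zeros);
  for (int k = 0; k < o3; ++k) {
    for (int j = 0; j < o2; ++j) {
      for (int i = 0; i < o1; ++i) {
        const arma::uword col = (arma::uword)i + (arma::uword)o1 * (j + (arma::uword)o2 * k);
        int t = 0;
        for (int dk = -1; dk <= 1; ++dk) {
          const int zz = k * stride + dk;
          for (int dj = -1; dj <= 1; ++dj) {
            const int yy = j * stride + dj;
            for (int di = -1; di <= 1; ++di, ++t) {
              const int xx = i * stride + di;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= d1 || yy >= d2 || zz >= d3) continue;
              const arma::uword dst = (arma::uword)xx + (arma::uword)d1 * (yy + (arma::uword)d2 * zz);
              for (int c = 0; c < C; ++c) x(c, dst) += cols(t * C + c, col);
            }
          }
        }
      }
    }
  }
  return x;
}

// Nearest-neighbour doubling of each spatial axis.
// [[Rcpp::export]]
arma::mat cpp_upsample_nn(const arma::mat& x, IntegerVector dims) {
  const int C = x.n_rows;
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = 2 * d1, o2 = 2 * d2, o3 = 2 * d3;
  arma::mat y(C, (arma::uword)o1 * o2 * o3);
  for (int k = 0; k < o3; ++k)
    for (int j = 0; j < o2; ++j)
      for (int i = 0; i < o1; ++i) {
        const arma::uword src = (arma::uword)(i / 2) + (arma::uword)d1 * ((j / 2) + (arma::uword)d2 * (k / 2));
        const arma::uword dst = (arma::uword)i + (arma::uword)o1 * (j + (arma::uword)o2 * k);
        y.col(dst) = x.col(src);
      }
  return y;
}

// Adjoint of cpp_upsample_nn: sums gradient over each 2x2x2 block.
// [[Rcpp::export]]
arma::mat cpp_upsample_nn_bwd(const arma::mat& dy, IntegerVector dims_in) {
  const int C = dy.n_rows;
  const int d1 = dims_in[0], d2 = dims_in[1], d3 = dims_in[2];
  const int o1 = 2 * d1, o2 = 2 * d2, o3 = 2 * d3;
  arma::mat dx(C, (arma::uword)d1 * d2 * d3, arma::fill::zeros);
  for (int k = 0; k < o3; ++k)
    for (int j = 0; j < o2; ++j)
      for (int i = 0; i < o1; ++i) {
        const arma::uword dst = (arma::uword)(i / 2) + (arma::uword)d1 * ((j / 2) + (arma::uword)d2 * (k / 2));
        const arma::uword src = (arma::uword)i + (arma::uword)o1 * (j + (arma::uword)o2 * k);
        dx.col(dst) += dy.col(src);
      }
  return dx;
}

// Slice-wise 3x3 median filter with replicated borders.
// [[Rcpp::export]]
NumericVector cpp_median3x3(NumericVector vol, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  NumericVector out(vol.size());
  std::vector<double> w(9);
  for (int k = 0; k < d3; ++k) {
    const R_xlen_t off = (R_xlen_t)d1 * d2 * k;
    for (int j = 0; j < d2; ++j) {
      for (int i = 0; i < d1; ++i) {
        int t = 0;
        for (int dj = -1; dj <= 1; ++dj) {
          int jj = std::min(std::max(j + dj, 0), d2 - 1);
          for (int di = -1; di <= 1; ++di) {
            int ii = std::min(std::max(i + di, 0), d1 - 1);
            w[t++] = vol[off + ii + (R_xlen_t)d1 * jj];
          }
        }
        std::nth_element(w.begin(), w.begin() + 4, w.end());
        out[off + i + (R_xlen_t)d1 * j] = w[4];
      }
    }
  }
  return out;
}

// Resample onto a new grid sharing the input origin (voxel centres aligned at
// index 0). out voxel i centre sits at i*out_sp mm from the first input voxel
// centre. linear=false gives nearest-neighbour (for masks).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dims,
                           NumericVector in_sp, IntegerVector out_dims,
                           NumericVector out_sp, double pad, bool linear) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int o1 = out_dims[0], o2 = out_dims[1], o3 = out_dims[2];
  NumericVector out((R_xlen_t)o1 * o2 * o3);
  for (int k = 0; k < o3; ++k) {
    const double fz = k * out_sp[2] / in_sp[2];
    for (int j = 0; j < o2; ++j) {
      const double fy = j * out_sp[1] / in_sp[1];
      for (int i = 0; i < o1; ++i) {
        const double fx = i * out_sp[0] / in_sp[0];
        const R_xlen_t dst = (R_xlen_t)i + (R_xlen_t)o1 * (j + (R_xlen_t)o2 * k);
        if (!linear) {
          const int xi = (int)std::lround(fx), yi = (int)std::lround(fy), zi = (int)std::lround(fz);
          out[dst] = (xi < 0 || yi < 0 || zi < 0 || xi >= d1 || yi >= d2 || zi >= d3)
            ? pad : vol[(R_xlen_t)xi + (R_xlen_t)d1 * (yi + (R_xlen_t)d2 * zi)];
          continue;
        }
        if (fx < 0 || fy < 0 || fz < 0 || fx > d1 - 1 || fy > d2 - 1 || fz > d3 - 1) {
          out[dst] = pad;
          continue;
        }
        const int x0 = std::min((int)fx, d1 - 1), y0 = std::min((int)fy, d2 - 1), z0 = std::min((int)fz, d3 - 1);
        const int x1 = std::min(x0 + 1, d1 - 1), y1 = std::min(y0 + 1, d2 - 1), z1 = std::min(z0 + 1, d3 - 1);
        const double tx = fx - x0, ty = fy - y0, tz = fz - z0;
        double acc = 0.0;
        for (int cz = 0; cz <= 1; ++cz)
          for (int cy = 0; cy <= 1; ++cy)
            for (int cx = 0; cx <= 1; ++cx) {
              const double wgt = (cx ? tx : 1 - tx) * (cy ? ty : 1 - ty) * (cz ? tz : 1 - tz);
              if (wgt == 0.0) continue;
              const int xi = cx ? x1 : x0, yi = cy ? y1 : y0, zi = cz ? z1 : z0;
              acc += wgt * vol[(R_xlen_t)xi + (R_xlen_t)d1 * (yi + (R_xlen_t)d2 * zi)];
            }
        out[dst] = acc;
      }
    }
  }
  return out;
}

// 8-connected labeling of each z-slice; labels are unique across the whole
// volume (1..n). Zero = background.
// [[Rcpp::export]]
IntegerVector cpp_label_slices8(LogicalVector mask, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  IntegerVector lab((R_xlen_t)d1 * d2 * d3);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < d3; ++k) {
    const R_xlen_t off = (R_xlen_t)d1 * d2 * k;
    for (int j0 = 0; j0 < d2; ++j0) {
      for (int i0 = 0; i0 < d1; ++i0) {
        const R_xlen_t s = off + i0 + (R_xlen_t)d1 * j0;
        if (!mask[s] || lab[s]) continue;
        ++next;
        lab[s] = next;
        stack.clear();
        stack.push_back(s);
        while (!stack.empty()) {
          const R_xlen_t cur = stack.back(); stack.pop_back();
          const int ci = (int)((cur - off) % d1), cj = (int)((cur - off) / d1);
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (!di && !dj) continue;
              const int ii = ci + di, jj = cj + dj;
              if (ii < 0 || jj < 0 || ii >= d1 || jj >= d2) continue;
              const R_xlen_t nb = off + ii + (R_xlen_t)d1 * jj;
              if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); }
            }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Union-find grouping of per-slice component labels into 3D lesions by
// 26-connectivity (cross-slice links; in-plane links are already merged).
// Returns for each component label 1..n its lesion id (1..m, renumbered).
// [[Rcpp::export]]
IntegerVector cpp_group26(IntegerVector lab, IntegerVector dims, int nlab) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  std::vector<int> parent(nlab + 1);
  for (int i = 0; i <= nlab; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  for (int k = 0; k + 1 < d3; ++k) {
    const R_xlen_t off0 = (R_xlen_t)d1 * d2 * k, off1 = off0 + (R_xlen_t)d1 * d2;
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        const int a = lab[off0 + i + (R_xlen_t)d1 * j];
        if (!a) continue;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di, jj = j + dj;
            if (ii < 0 || jj < 0 || ii >= d1 || jj >= d2) continue;
            const int b = lab[off1 + ii + (R_xlen_t)d1 * jj];
            if (b) unite(a, b);
          }
      }
  }
  IntegerVector group(nlab);
  std::map<int, int> renum;
  for (int i = 1; i <= nlab; ++i) {
    const int r = find(i);
    auto it = renum.find(r);
    if (it == renum.end()) { renum[r] = (int)renum.size() + 1; group[i - 1] = (int)renum.size(); }
    else group[i - 1] = it->second;
  }
  return group;
}
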