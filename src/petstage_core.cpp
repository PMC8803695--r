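// Hot numerical primitives: trilinear volume sampling, fused MPR-stack
// extraction, connected-component flood fill, and the fused conv-block
// forward/backward (im2col + BLAS GEMM + ReLU + 2x2 max pool). All layer
// composition and optimiser logic lives in R.
#include <Rcpp.h>
using namespace Rcpp;

// Trilinear sampling of a 3-D array at fractional 1-based voxel
// coordinates; out-of-extent samples return `oob`, and samples at exact
// integer coordinates return the stored value exactly.
// [[Rcpp::export]]
NumericVector cppTrilinear(NumericVector arr, IntegerVector dm,
                           NumericMatrix coords, double oob) {
  const int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  const int n = coords.nrow();
  const double *a = arr.begin();
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    const double x = coords(r, 0), y = coords(r, 1), z = coords(r, 2);
    if (x < 1 || x > d1 || y < 1 || y > d2 || z < 1 || z > d3) {
      out[r] = oob;
      continue;
    }
    double x0 = std::floor(x), y0 = std::floor(y), z0 = std::floor(z);
    const double fx = x - x0, fy = y - y0, fz = z - z0;
    int i0 = (int)x0, j0 = (int)y0, k0 = (int)z0;
    int i1 = i0 + 1, j1 = j0 + 1, k1 = k0 + 1;
    i0 = std::min(std::max(i0, 1), d1);
    i1 = std::min(std::max(i1, 1), d1);
    j0 = std::min(std::max(j0, 1), d2);
    j1 = std::min(std::max(j1, 1), d2);
    k0 = std::min(std::max(k0, 1), d3);
    k1 = std::min(std::max(k1, 1), d3);
    const int s2 = d1, s3 = d1 * d2;
    const int b00 = (j0 - 1) * s2 + (k0 - 1) * s3;
    const int b10 = (j1 - 1) * s2 + (k0 - 1) * s3;
    const int b01 = (j0 - 1) * s2 + (k1 - 1) * s3;
    const int b11 = (j1 - 1) * s2 + (k1 - 1) * s3;
    const double v000 = a[i0 - 1 + b00];
    if (fx == 0 && fy == 0 && fz == 0) {
      out[r] = v000;
      continue;
    }
    const double v100 = a[i1 - 1 + b00];
    const double v010 = a[i0 - 1 + b10];
    const double v110 = a[i1 - 1 + b10];
    const double v001 = a[i0 - 1 + b01];
    const double v101 = a[i1 - 1 + b01];
    const double v011 = a[i0 - 1 + b11];
    const double v111 = a[i1 - 1 + b11];
    const double v00 = v000 * (1 - fx) + v100 * fx;
    const double v10 = v010 * (1 - fx) + v110 * fx;
    const double v01 = v001 * (1 - fx) + v101 * fx;
    const double v11 = v011 * (1 - fx) + v111 * fx;
    const double v0 = v00 * (1 - fy) + v10 * fy;
    const double v1 = v01 * (1 - fy) + v11 * fy;
    out[r] = v0 * (1 - fz) + v1 * fz;
  }
  return out;
}

// Fused MPR-stack extraction for the training path: trilinear-samples PET
// and CT at the supplied coordinates (13 planes x 64 x 64, plane-major,
// in-plane x fastest), applies the fixed display windows (PET 0..15 SUV,
// CT -300..300 HU) and writes the network input matrix (4096 x 26) with
// channel (p-1)*2 + modality. Arithmetic matches the plain extraction path
// exactly, including the integer-coordinate fast path.
// [[Rcpp::export]]
NumericMatrix cppExtractStack(NumericVector pet, NumericVector ct,
                              IntegerVector dm, NumericMatrix coords) {
  const int nS = 64 * 64;
  NumericMatrix X(nS, 26);
  NumericVector petV = cppTrilinear(pet, dm, coords, 0.0);
  NumericVector ctV = cppTrilinear(ct, dm, coords, -300.0);
  for (int p = 0; p < 13; ++p) {
    double *xp = &X(0, 2 * p);
    double *xc = &X(0, 2 * p + 1);
    const double *pv = petV.begin() + p * nS;
    const double *cv = ctV.begin() + p * nS;
    for (int r = 0; r < nS; ++r) {
      double v = pv[r];
      v = std::min(std::max(v, 0.0), 15.0) / 15.0;
      xp[r] = v;
      double w = cv[r];
      w = (std::min(std::max(w, -300.0), 300.0) + 300.0) / 600.0;
      xc[r] = w;
    }
  }
  return X;
}

// Connected component by breadth-first search over an eligibility mask.
// Returns the 1-based voxel indices (n x 3) of the component containing
// `seed` (which must be eligible).
// [[Rcpp::export]]
IntegerMatrix cppFloodFill(LogicalVector eligible, IntegerVector dm,
                           IntegerVector seed, int connectivity) {
  const int d1 = dm[0], d2 = dm[1], d3 = dm[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  const int *el = eligible.begin();
  std::vector<char> visited(n, 0);
  std::vector<int> queue;
  const int seedLin = (seed[0] - 1) + (seed[1] - 1) * d1 +
    (seed[2] - 1) * d1 * d2;
  if (!el[seedLin]) stop("seed voxel is not eligible for component growth");
  visited[seedLin] = 1;
  queue.push_back(seedLin);
  size_t head = 0;
  while (head < queue.size()) {
    const int lin = queue[head++];
    const int x = lin % d1;
    const int y = (lin / d1) % d2;
    const int z = lin / (d1 * d2);
    for (int dz = -1; dz <= 1; ++dz) {
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          const int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
          if (man == 0) continue;
          if (connectivity == 6 && man != 1) continue;
          const int nx = x + dx, ny = y + dy, nz = z + dz;
          if (nx < 0 || nx >= d1 || ny < 0 || ny >= d2 ||
              nz < 0 || nz >= d3) continue;
          const int nlin = nx + ny * d1 + nz * d1 * d2;
          if (el[nlin] && !visited[nlin]) {
            visited[nlin] = 1;
            queue.push_back(nlin);
          }
        }
      }
    }
  }
  IntegerMatrix out(queue.size(), 3);
  for (size_t i = 0; i < queue.size(); ++i) {
    const int lin = queue[i];
    out(i, 0) = lin % d1 + 1;
    out(i, 1) = (lin / d1) % d2 + 1;
    out(i, 2) = lin / (d1 * d2) + 1;
  }
  return out;
}

#define USE_FC_LEN_T
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif

// One fused conv block forward: im2col (3x3, zero pad), GEMM, bias, ReLU,
// 2x2 max pool. Returns everything the backward pass needs.
// [[Rcpp::export]]
List cppConvForward(NumericMatrix X, IntegerMatrix idx, NumericMatrix W,
                    NumericVector b, int n) {
  const int n2 = X.nrow(), C = X.ncol(), K = idx.ncol();
  const int F = W.ncol(), KC = K * C;
  NumericMatrix P(n2, KC);
  for (int k = 0; k < K; ++k) {
    const int *id = &idx(0, k);
    for (int c = 0; c < C; ++c) {
      const double *xc = &X(0, c);
      double *pc = &P(0, k * C + c);
      for (int r = 0; r < n2; ++r) {
        const int s = id[r];
        pc[r] = (s > n2) ? 0.0 : xc[s - 1];
      }
    }
  }
  NumericMatrix Z(n2, F);
  {
    const double one = 1.0, zero = 0.0;
    F77_CALL(dgemm)("N", "N", &n2, &F, &KC, &one, P.begin(), &n2,
      W.begin(), &KC, &zero, Z.begin(), &n2 FCONE FCONE);
  }
  LogicalMatrix mask(n2, F);
  for (int f = 0; f < F; ++f) {
    double *z = &Z(0, f);
    int *mk = &mask(0, f);
    const double bf = b[f];
    for (int r = 0; r < n2; ++r) {
      double v = z[r] + bf;
      if (v > 0) { z[r] = v; mk[r] = 1; } else { z[r] = 0.0; mk[r] = 0; }
    }
  }
  // 2x2 max pool
  const int m = n / 2, m2 = m * m;
  NumericMatrix M(m2, F);
  IntegerMatrix src(m2, F);
  for (int f = 0; f < F; ++f) {
    const double *h = &Z(0, f);
    for (int j = 0; j < m; ++j) {
      for (int i = 0; i < m; ++i) {
        const int r0 = 2 * i + (2 * j) * n;
        const int cand[4] = {r0, r0 + 1, r0 + n, r0 + n + 1};
        double best = h[cand[0]];
        int bi = cand[0];
        for (int t = 1; t < 4; ++t) {
          if (h[cand[t]] > best) { best = h[cand[t]]; bi = cand[t]; }
        }
        M(i + j * m, f) = best;
        src(i + j * m, f) = bi + 1;
      }
    }
  }
  return List::create(_["P"] = P, _["mask"] = mask, _["M"] = M,
    _["src"] = src);
}

// Matching backward: un-pool, ReLU mask, weight/bias gradients and (when
// requested) the gradient w.r.t. the block input.
// [[Rcpp::export]]
List cppConvBackward(NumericMatrix dA, IntegerMatrix src, LogicalMatrix mask,
                     NumericMatrix P, NumericMatrix W, IntegerMatrix idx,
                     int Cprev, bool needDX) {
  const int n2 = P.nrow(), F = dA.ncol(), KC = P.ncol();
  const int m2 = dA.nrow(), K = idx.ncol();
  NumericMatrix dZ(n2, F);
  for (int f = 0; f < F; ++f) {
    const double *da = &dA(0, f);
    const int *sc = &src(0, f);
    const int *mk = &mask(0, f);
    double *dz = &dZ(0, f);
    for (int r = 0; r < m2; ++r) {
      const int s = sc[r] - 1;
      if (mk[s]) dz[s] = da[r];
    }
  }
  NumericMatrix dW(KC, F);
  {
    const double one = 1.0, zero = 0.0;
    F77_CALL(dgemm)("T", "N", &KC, &F, &n2, &one, P.begin(), &n2,
      dZ.begin(), &n2, &zero, dW.begin(), &KC FCONE FCONE);
  }
  NumericVector db(F);
  for (int f = 0; f < F; ++f) {
    const double *dz = &dZ(0, f);
    double s = 0;
    for (int r = 0; r < n2; ++r) s += dz[r];
    db[f] = s;
  }
  if (!needDX) {
    return List::create(_["dW"] = dW, _["db"] = db);
  }
  NumericMatrix dP(n2, KC);
  {
    const double one = 1.0, zero = 0.0;
    F77_CALL(dgemm)("N", "T", &n2, &KC, &F, &one, dZ.begin(), &n2,
      W.begin(), &KC, &zero, dP.begin(), &n2 FCONE FCONE);
  }
  NumericMatrix dX(n2, Cprev);
  for (int k = 0; k < K; ++k) {
    const int *id = &idx(0, k);
    for (int c = 0; c < Cprev; ++c) {
      const double *pc = &dP(0, k * Cprev + c);
      double *xc = &dX(0, c);
      for (int r = 0; r < n2; ++r) {
        const int s = id[r];
        if (s <= n2) xc[s - 1] += pc[r];
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}
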