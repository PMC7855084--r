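#include <Rcpp.h>
using namespace Rcpp;

// Occupancy voxelisation of an implicitly defined solid (elliptic cylinder or
// triaxial ellipsoid) inside a cropped axis-aligned box of the voxel domain.
//
// Coordinates are in voxel units; the centre of voxel (i, j, k) (0-based) is
// at (i + 0.5, j + 0.5, k + 0.5). The shape is given by its body frame
// (columns of `rot` are the world directions of the body axes), its centre in
// world coordinates, and semi-extents `semi`:
//   kind 0 (cylinder):  semi = (cross-section semi-axis along e1,
//                               cross-section semi-axis along e2,
//                               half-length along e3)
//   kind 1 (ellipsoid): semi = three semi-axes along e1, e2, e3
//
// Voxels whose centre is farther than ~half a voxel diagonal from the surface
// are classified whole; the remaining boundary shell is supersampled with
// ss^3 regularly spaced points per voxel.

static inline void body_coords(const double *Rt, double dx, double dy, double dz,
                               double &px, double &py, double &pz) {
  px = Rt[0] * dx + Rt[1] * dy + Rt[2] * dz;
  py = Rt[3] * dx + Rt[4] * dy + Rt[5] * dz;
  pz = Rt[6] * dx + Rt[7] * dy + Rt[8] * dz;
}

static inline bool inside_shape(int kind, double px, double py, double pz,
                                double s1, double s2, double s3) {
  if (kind == 0) {
    if (std::abs(pz) > s3) return false;
    double q = (px / s1) * (px / s1) + (py / s2) * (py / s2);
    return q <= 1.0;
  }
  double q = (px / s1) * (px / s1) + (py / s2) * (py / s2) + (pz / s3) * (pz / s3);
  return q <= 1.0;
}

// [[Rcpp::export]]
NumericVector voxelise_cpp(int kind, NumericMatrix rot, NumericVector centre,
                           NumericVector semi, IntegerVector lo, IntegerVector hi,
                           int ss) {
  const int nx = hi[0] - lo[0], ny = hi[1] - lo[1], nz = hi[2] - lo[2];
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);

  // row-major transpose of rot, so body_coords computes R^T * d
  double Rt[9];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) Rt[3 * r + c] = rot(c, r);

  const double s1 = semi[0], s2 = semi[1], s3 = semi[2];
  const double cx = centre[0], cy = centre[1], cz = centre[2];
  const double m = 0.87; // > sqrt(3)/2, conservative half-diagonal margin

  std::vector<double> off(ss);
  for (int a = 0; a < ss; ++a) off[a] = (a + 0.5) / ss - 0.5;
  const double w = 1.0 / (static_cast<double>(ss) * ss * ss);

  const bool shrink_ok = (s1 > m && s2 > m && (kind == 1 ? s3 > m : true));

  // coarse pass: skip blocks wholly outside the dilated surface
  const int B = 4;
  const double mB = 0.5 * B * std::sqrt(3.0) + m;
  for (int kb = 0; kb < nz; kb += B) {
   for (int jb = 0; jb < ny; jb += B) {
    for (int ib = 0; ib < nx; ib += B) {
      const double xb = lo[0] + ib + 0.5 * std::min(B, nx - ib) - cx;
      const double yb = lo[1] + jb + 0.5 * std::min(B, ny - jb) - cy;
      const double zb = lo[2] + kb + 0.5 * std::min(B, nz - kb) - cz;
      double pbx, pby, pbz;
      body_coords(Rt, xb, yb, zb, pbx, pby, pbz);
      bool block_out;
      if (kind == 0) {
        block_out = std::abs(pbz) >= s3 + mB ||
                    !inside_shape(0, pbx, pby, 0.0, s1 + mB, s2 + mB, 1.0);
      } else {
        block_out = !inside_shape(1, pbx, pby, pbz, s1 + mB, s2 + mB, s3 + mB);
      }
      if (block_out) continue;

  for (int k = kb; k < std::min(kb + B, nz); ++k) {
    const double z = lo[2] + k + 0.5 - cz;
    for (int j = jb; j < std::min(jb + B, ny); ++j) {
      const double y = lo[1] + j + 0.5 - cy;
      for (int i = ib; i < std::min(ib + B, nx); ++i) {
        const R_xlen_t idx =
            i + static_cast<R_xlen_t>(nx) * (j + static_cast<R_xlen_t>(ny) * k);
        const double x = lo[0] + i + 0.5 - cx;
        double px, py, pz;
        body_coords(Rt, x, y, z, px, py, pz);

        // certainly outside?
        bool out_sure;
        if (kind == 0) {
          out_sure = std::abs(pz) >= s3 + m ||
                     !inside_shape(0, px, py, 0.0, s1 + m, s2 + m, 1.0);
        } else {
          out_sure = !inside_shape(1, px, py, pz, s1 + m, s2 + m, s3 + m);
        }
        if (out_sure) continue;

        // certainly inside?
        if (shrink_ok) {
          bool in_sure;
          if (kind == 0) {
            in_sure = std::abs(pz) <= s3 - m &&
                      inside_shape(0, px, py, 0.0, s1 - m, s2 - m, 1.0);
          } else {
            in_sure = inside_shape(1, px, py, pz, s1 - m, s2 - m, s3 - m);
          }
          if (in_sure) { out[idx] = 1.0; continue; }
        }

        // boundary shell: supersample
        int cnt = 0;
        for (int a = 0; a < ss; ++a)
          for (int b = 0; b < ss; ++b)
            for (int c = 0; c < ss; ++c) {
              double qx, qy, qz;
              body_coords(Rt, x + off[a], y + off[b], z + off[c], qx, qy, qz);
              if (inside_shape(kind, qx, qy, qz, s1, s2, s3)) ++cnt;
            }
        out[idx] = cnt * w;
      }
    }
  }
    }
   }
  }
  return out;
}
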