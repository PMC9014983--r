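// Core numerical engines: skeleton adjacency, threshold-free cluster
// enhancement, Freedman-Lane max-statistic permutation, and the voxelwise
// Sobel mediation permutation loop. Kept in C++ because every permutation
// re-runs a component labeling over the skeleton graph.

#include <RcppArmadillo.h>
#include <vector>
#include <array>
#include <unordered_map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Connected-component labeling restricted to suprathreshold voxels.
// Adjacency is CSR over skeleton columns (0-based). Returns, via csize,
// the component size each suprathreshold voxel belongs to; 0 elsewhere.
static void supra_component_sizes(const arma::vec& values, double h,
                                  const IntegerVector& indptr,
                                  const IntegerVector& indices,
                                  std::vector<int>& csize,
                                  std::vector<int>& stack_buf) {
  const int V = values.n_elem;
  const double tol = 1e-12 * (h > 0 ? h : 1.0);
  std::fill(csize.begin(), csize.end(), 0);
  std::vector<int> label(V, -1);
  int ncomp = 0;
  std::vector<int> sizes;
  for (int v = 0; v < V; ++v) {
    if (label[v] >= 0 || values[v] < h - tol) continue;
    // BFS/DFS from v
    int sz = 0;
    stack_buf.clear();
    stack_buf.push_back(v);
    label[v] = ncomp;
    while (!stack_buf.empty()) {
      int u = stack_buf.back(); stack_buf.pop_back();
      ++sz;
      for (int k = indptr[u]; k < indptr[u + 1]; ++k) {
        int w = indices[k];
        if (label[w] < 0 && values[w] >= h - tol) {
          label[w] = ncomp;
          stack_buf.push_back(w);
        }
      }
    }
    sizes.push_back(sz);
    ++ncomp;
  }
  for (int v = 0; v < V; ++v)
    if (label[v] >= 0) csize[v] = sizes[label[v]];
}

static arma::vec tfce_core(const arma::vec& values,
                           const IntegerVector& indptr,
                           const IntegerVector& indices,
                           double H, double E, int steps, double dh) {
  const int V = values.n_elem;
  arma::vec out(V, arma::fill::zeros);
  double vmax = values.max();
  if (!(vmax > 0)) return out;
  int nsteps;
  bool auto_dh = !(dh > 0);
  if (auto_dh) {
    nsteps = steps;
    dh = vmax / steps;
  } else {
    nsteps = (int) std::floor(vmax / dh + 1e-9);
    if (nsteps < 1) return out;
  }
  std::vector<int> csize(V), buf;
  buf.reserve(V);
  for (int k = 1; k <= nsteps; ++k) {
    // computing h as vmax*k/steps makes the top step hit max(values) exactly
    double h = auto_dh ? vmax * k / steps : dh * k;
    supra_component_sizes(values, h, indptr, indices, csize, buf);
    double hH = std::pow(h, H);
    for (int v = 0; v < V; ++v)
      if (csize[v] > 0)
        out[v] += std::pow((double) csize[v], E) * hH * dh;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_adjacency(IntegerMatrix coords, IntegerVector dims, int connectivity) {
  // coords: V x 3 (1-based voxel indices); returns CSR adjacency between
  // skeleton columns under 6/18/26 neighborhood, mask-restricted.
  const int V = coords.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<long long> lin(V);
  std::unordered_map<long long, int> col_of;
  col_of.reserve(V * 2);
  for (int v = 0; v < V; ++v) {
    long long l = (long long)(coords(v, 0) - 1)
                + (long long)nx * (coords(v, 1) - 1)
                + (long long)nx * ny * (coords(v, 2) - 1);
    lin[v] = l;
    col_of[l] = v;
  }
  std::vector<std::array<int, 3>> offs;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  IntegerVector indptr(V + 1);
  std::vector<int> idx;
  idx.reserve(V * offs.size() / 2);
  for (int v = 0; v < V; ++v) {
    indptr[v] = (int) idx.size();
    int x = coords(v, 0), y = coords(v, 1), z = coords(v, 2);
    for (auto& o : offs) {
      int xx = x + o[0], yy = y + o[1], zz = z + o[2];
      if (xx < 1 || xx > nx || yy < 1 || yy > ny || zz < 1 || zz > nz) continue;
      long long l = (long long)(xx - 1) + (long long)nx * (yy - 1)
                  + (long long)nx * ny * (zz - 1);
      auto it = col_of.find(l);
      if (it != col_of.end()) idx.push_back(it->second);
    }
  }
  indptr[V] = (int) idx.size();
  return List::create(_["indptr"] = indptr,
                      _["indices"] = IntegerVector(idx.begin(), idx.end()));
}

// [[Rcpp::export]]
NumericVector cpp_tfce(NumericVector values, IntegerVector indptr,
                       IntegerVector indices, double H, double E,
                       int steps, double dh) {
  arma::vec v(values.begin(), values.size(), false);
  arma::vec neg = arma::clamp(v, 0.0, arma::datum::inf);
  arma::vec out = tfce_core(neg, indptr, indices, H, E, steps, dh);
  return NumericVector(out.begin(), out.end());
}

// t-statistics of contrast c for OLS of each column of Y on X.
static arma::rowvec tmap_of(const arma::mat& Y, const arma::mat& X,
                            const arma::mat& M, const arma::vec& cvec,
                            double cXc, double df) {
  arma::mat B = M * Y;                    // p x V
  arma::rowvec cb = cvec.t() * B;         // 1 x V
  arma::mat XtY = X.t() * Y;              // p x V
  arma::rowvec rss = arma::sum(arma::square(Y), 0) - arma::sum(B % XtY, 0);
  arma::rowvec sigma2 = rss / df;
  sigma2.transform([](double s) { return s > 0 ? s : 0.0; });
  arma::rowvec se = arma::sqrt(sigma2 * cXc);
  arma::rowvec t(Y.n_cols);
  for (arma::uword v = 0; v < Y.n_cols; ++v)
    t[v] = se[v] > 0 ? cb[v] / se[v] : 0.0;
  return t;
}

// [[Rcpp::export]]
List cpp_perm_fwe(const arma::mat& Y, const arma::mat& X,
                  const arma::vec& cvec, const arma::uvec& nuisance,
                  const arma::umat& perms, double H, double E, int steps,
                  IntegerVector indptr, IntegerVector indices) {
  // Y: n x V metric stack (direction handled by the sign of cvec).
  // perms: n x nperm row indices (0-based), first column = identity.
  const arma::uword n = Y.n_rows;
  const int nperm = perms.n_cols;
  arma::mat XtXinv = arma::inv_sympd(X.t() * X);
  arma::mat M = XtXinv * X.t();
  double cXc = arma::as_scalar(cvec.t() * XtXinv * cvec);
  double df = (double) n - (double) X.n_cols;

  arma::mat fitted(n, Y.n_cols, arma::fill::zeros);
  arma::mat resid = Y;
  if (nuisance.n_elem > 0) {
    arma::mat Z = X.cols(nuisance);
    arma::mat Hz = Z * arma::inv_sympd(Z.t() * Z) * Z.t();
    fitted = Hz * Y;
    resid = Y - fitted;
  }

  NumericVector nullmax(nperm);
  arma::rowvec t_obs;
  arma::vec tfce_obs;
  for (int j = 0; j < nperm; ++j) {
    arma::mat Yp = fitted + resid.rows(perms.col(j));
    arma::rowvec t = tmap_of(Yp, X, M, cvec, cXc, df);
    arma::vec tpos = arma::clamp(t.t(), 0.0, arma::datum::inf);
    arma::vec enh = tfce_core(tpos, indptr, indices, H, E, steps, -1.0);
    if (j == 0) { t_obs = t; tfce_obs = enh; }
    nullmax[j] = enh.n_elem ? enh.max() : 0.0;
    if (j % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["t"] = NumericVector(t_obs.begin(), t_obs.end()),
                      _["tfce"] = NumericVector(tfce_obs.begin(), tfce_obs.end()),
                      _["nullmax"] = nullmax);
}

// Per-voxel Sobel z from sufficient statistics of centered, standardized
// x (exposure), y (outcome) and mediator columns of Mx.
static void sobel_maps(const arma::mat& Mx, const arma::vec& x,
                       const arma::vec& y, const arma::rowvec& Smm,
                       double Sxx, double Sxy, double Syy, double n,
                       arma::rowvec& a, arma::rowvec& sa,
                       arma::rowvec& b, arma::rowvec& sb,
                       arma::rowvec& z) {
  arma::rowvec Sxm = x.t() * Mx;
  arma::rowvec Sym = y.t() * Mx;
  const arma::uword V = Mx.n_cols;
  a.set_size(V); sa.set_size(V); b.set_size(V); sb.set_size(V); z.set_size(V);
  for (arma::uword v = 0; v < V; ++v) {
    double smm = Smm[v];
    double D = smm * Sxx - Sxm[v] * Sxm[v];
    if (smm <= 1e-12 || D <= 1e-12) {
      a[v] = sa[v] = b[v] = sb[v] = 0.0;
      z[v] = NA_REAL;
      continue;
    }
    double av = Sxm[v] / Sxx;
    double rss_a = smm - Sxm[v] * Sxm[v] / Sxx;
    if (rss_a < 0) rss_a = 0;
    double sav = std::sqrt(rss_a / ((n - 2.0) * Sxx));
    double bv = (Sxx * Sym[v] - Sxm[v] * Sxy) / D;
    double bxv = (smm * Sxy - Sxm[v] * Sym[v]) / D;
    double rss_b = Syy - bv * Sym[v] - bxv * Sxy;
    if (rss_b < 0) rss_b = 0;
    double sbv = std::sqrt(rss_b / (n - 3.0) * Sxx / D);
    double den = bv * bv * sav * sav + av * av * sbv * sbv
               + sav * sav * sbv * sbv;
    a[v] = av; sa[v] = sav; b[v] = bv; sb[v] = sbv;
    z[v] = den > 0 ? (av * bv) / std::sqrt(den) : NA_REAL;
  }
}

// [[Rcpp::export]]
List cpp_mediation_perm(const arma::mat& Mx, const arma::vec& x,
                        const arma::vec& y, const arma::umat& perms,
                        double H, double E, int steps,
                        IntegerVector indptr, IntegerVector indices,
                        int direction, int scheme) {
  // scheme 0 ("mediator"): jointly permute (x, y) rows against the mediator
  // stack -- equivalent to permuting the residualized mediator rows; breaks
  // both mediated links, preserves the x-y association (global null).
  // scheme 1 ("outcome"): Freedman-Lane on the outcome -- permute the
  // residuals of y on x and add the x-fit back; preserves both the x-y
  // association and the x-mediator (a) path, targeting the b-path null.
  const double n = (double) Mx.n_rows;
  const int nperm = perms.n_cols;
  arma::rowvec Smm = arma::sum(arma::square(Mx), 0);
  double Sxx = arma::dot(x, x), Sxy = arma::dot(x, y), Syy = arma::dot(y, y);
  arma::vec yfit = x * (Sxy / Sxx);
  arma::vec yres = y - yfit;

  NumericVector nullmax(nperm);
  arma::rowvec a, sa, b, sb, z;
  arma::rowvec a0, sa0, b0, sb0, z0;
  arma::vec tfce_obs;
  for (int j = 0; j < nperm; ++j) {
    arma::vec xp, yp;
    if (scheme == 0) {
      xp = x.rows(perms.col(j));
      yp = y.rows(perms.col(j));
    } else {
      xp = x;
      yp = yfit + yres.rows(perms.col(j));
    }
    double Sxy_p = arma::dot(xp, yp);
    double Syy_p = arma::dot(yp, yp);
    sobel_maps(Mx, xp, yp, Smm, Sxx, Sxy_p, Syy_p, n, a, sa, b, sb, z);
    arma::vec zdir(z.n_elem);
    for (arma::uword v = 0; v < z.n_elem; ++v) {
      double val = ISNAN(z[v]) ? 0.0 : direction * z[v];
      zdir[v] = val > 0 ? val : 0.0;
    }
    arma::vec enh = tfce_core(zdir, indptr, indices, H, E, steps, -1.0);
    if (j == 0) {
      a0 = a; sa0 = sa; b0 = b; sb0 = sb; z0 = z;
      tfce_obs = enh;
    }
    nullmax[j] = enh.n_elem ? enh.max() : 0.0;
    if (j % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["a"] = NumericVector(a0.begin(), a0.end()),
    _["sa"] = NumericVector(sa0.begin(), sa0.end()),
    _["b"] = NumericVector(b0.begin(), b0.end()),
    _["sb"] = NumericVector(sb0.begin(), sb0.end()),
    _["z"] = NumericVector(z0.begin(), z0.end()),
    _["tfce"] = NumericVector(tfce_obs.begin(), tfce_obs.end()),
    _["nullmax"] = nullmax);
}
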