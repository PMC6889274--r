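// Levenberg-Marquardt minimization of the per-ROI objectives used for
// sub-pixel Gaussian PSF fitting:
//   mode 0 (Poisson MLE deviance):
//       F_i = a_i * f(theta) + c_i,   chi2 = 2*sum(F - X) - 2*sum(X*ln(F/X))
//     where a_i is 1 (uncorrected) or rqe_i (RQE-corrected) and c_i is the
//     read-noise variance shift in e-^2; X already carries the same shift.
//   mode 1 (weighted least squares):
//       chi2 = sum w_i * (f(theta) - X_i)^2
// f(theta) is a 2-D Gaussian of fixed sigma, theta = (h, x0, y0, bg), on a
// square ROI with zero-based local pixel coordinates.  The Gaussian is
// either integrated over each pixel (convention 0) or sampled at pixel
// centers (convention 1); the height parameterization is shared with the
// R-side psfShape().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double SQRT1_2 = 0.7071067811865476;
static const double INV_SQRT_2PI = 0.3989422804014327;

// per-axis integrated profile and derivative wrt center
static inline void axisProfile(int n, double center, double sigma,
                               int convention,
                               double* I, double* dC) {
    if (convention == 1) {          // sampled
        for (int i = 0; i < n; ++i) {
            double d = (i - center) / sigma;
            double e = std::exp(-0.5 * d * d);
            I[i] = e;
            dC[i] = e * d / sigma;
        }
        return;
    }
    for (int i = 0; i < n; ++i) {
        double up = (i - center + 0.5) / sigma;
        double lo = (i - center - 0.5) / sigma;
        I[i] = 0.5 * (std::erf(up * SQRT1_2) - std::erf(lo * SQRT1_2));
        dC[i] = -INV_SQRT_2PI / sigma *
            (std::exp(-0.5 * up * up) - std::exp(-0.5 * lo * lo));
    }
}

// model shape and derivatives on the S x S ROI (column-major, row fastest,
// matching R matrix layout: index = row + S * col)
static void psfEval(int S, const double* th, double sigma, int convention,
                    double* shape, double* dx0, double* dy0) {
    std::vector<double> Ix(S), dIx(S), Iy(S), dIy(S);
    axisProfile(S, th[1], sigma, convention, Ix.data(), dIx.data());
    axisProfile(S, th[2], sigma, convention, Iy.data(), dIy.data());
    double norm = (convention == 0) ? 2.0 * M_PI * sigma * sigma : 1.0;
    for (int c = 0; c < S; ++c)
        for (int r = 0; r < S; ++r) {
            int k = r + S * c;
            shape[k] = norm * Ix[c] * Iy[r];
            dx0[k] = norm * dIx[c] * Iy[r];
            dy0[k] = norm * Ix[c] * dIy[r];
        }
}

// chi-square for current theta; fills F (model incl. a, c) when mode==0
static double objective(int mode, int npx, const double* th,
                        const double* shape,
                        const double* X, const double* A, const double* C,
                        const double* W) {
    double chi2 = 0.0;
    if (mode == 0) {
        for (int i = 0; i < npx; ++i) {
            double F = A[i] * (th[0] * shape[i] + th[3]) + C[i];
            if (F < 1e-9) F = 1e-9;
            chi2 += 2.0 * (F - X[i]) - 2.0 * X[i] * std::log(F / X[i]);
        }
    } else {
        for (int i = 0; i < npx; ++i) {
            double r = (th[0] * shape[i] + th[3]) - X[i];
            chi2 += W[i] * r * r;
        }
    }
    return chi2;
}

// 4x4 linear solve with partial pivoting; returns false if singular
static bool solve4(double Hm[4][4], double g[4], double* delta) {
    int idx[4] = {0, 1, 2, 3};
    for (int k = 0; k < 4; ++k) {
        int p = k;
        for (int r = k + 1; r < 4; ++r)
            if (std::fabs(Hm[idx[r]][k]) > std::fabs(Hm[idx[p]][k])) p = r;
        std::swap(idx[k], idx[p]);
        double piv = Hm[idx[k]][k];
        if (std::fabs(piv) < 1e-300) return false;
        for (int r = k + 1; r < 4; ++r) {
            double fac = Hm[idx[r]][k] / piv;
            for (int c = k; c < 4; ++c) Hm[idx[r]][c] -= fac * Hm[idx[k]][c];
            g[idx[r]] -= fac * g[idx[k]];
        }
    }
    for (int k = 3; k >= 0; --k) {
        double s = g[idx[k]];
        for (int c = k + 1; c < 4; ++c) s -= Hm[idx[k]][c] * delta[c];
        delta[k] = s / Hm[idx[k]][k];
    }
    return true;
}

// [[Rcpp::export]]
List cpp_fit_rois(NumericMatrix X, NumericMatrix A, NumericMatrix C,
                  NumericMatrix W, NumericMatrix theta0, int mode,
                  double sigma, int roiSide, int convention,
                  int maxIter, double tol, double lambda0) {
    int n = X.ncol();
    int npx = X.nrow();
    int S = roiSide;
    if (npx != S * S) stop("ROI pixel count does not match roiSide^2");
    NumericMatrix theta(4, n);
    LogicalVector converged(n);
    IntegerVector iters(n);
    NumericVector chi2out(n);
    LogicalVector boundHit(n);

    std::vector<double> shape(npx), dx0(npx), dy0(npx), trialShape(npx);

    for (int j = 0; j < n; ++j) {
        const double* Xj = &X(0, j);
        const double* Aj = &A(0, j);
        const double* Cj = &C(0, j);
        const double* Wj = &W(0, j);
        double th[4] = {theta0(0, j), theta0(1, j), theta0(2, j),
                        theta0(3, j)};
        bool hitBound = false;
        if (th[0] < 1e-3) th[0] = 1e-3;
        if (th[3] < 0.0) { th[3] = 0.0; }

        psfEval(S, th, sigma, convention, shape.data(), dx0.data(),
                dy0.data());
        double chi2 = objective(mode, npx, th, shape.data(), Xj, Aj, Cj,
                                Wj);
        double lambda = lambda0;
        int it = 0, nSmall = 0;
        bool ok = false;

        while (it < maxIter) {
            ++it;
            // gradient and Gauss-Newton Hessian
            double g[4] = {0, 0, 0, 0};
            double H[4][4] = {{0}};
            for (int i = 0; i < npx; ++i) {
                double df[4];
                df[0] = shape[i];
                df[1] = th[0] * dx0[i];
                df[2] = th[0] * dy0[i];
                df[3] = 1.0;
                double wfac, rfac;
                if (mode == 0) {
                    double F = Aj[i] * (th[0] * shape[i] + th[3]) + Cj[i];
                    if (F < 1e-9) F = 1e-9;
                    rfac = 2.0 * (1.0 - Xj[i] / F) * Aj[i];
                    wfac = 2.0 * (Xj[i] / (F * F)) * Aj[i] * Aj[i];
                } else {
                    double r = (th[0] * shape[i] + th[3]) - Xj[i];
                    rfac = 2.0 * Wj[i] * r;
                    wfac = 2.0 * Wj[i];
                }
                for (int a = 0; a < 4; ++a) {
                    g[a] += rfac * df[a];
                    for (int b = a; b < 4; ++b)
                        H[a][b] += wfac * df[a] * df[b];
                }
            }
            for (int a = 0; a < 4; ++a)
                for (int b = 0; b < a; ++b) H[a][b] = H[b][a];

            // damped step
            bool accepted = false;
            while (lambda <= 1e12) {
                double Hd[4][4], gd[4], delta[4];
                for (int a = 0; a < 4; ++a) {
                    gd[a] = -g[a];
                    for (int b = 0; b < 4; ++b) Hd[a][b] = H[a][b];
                    Hd[a][a] += lambda * (H[a][a] > 0 ? H[a][a] : 1.0);
                }
                if (!solve4(Hd, gd, delta)) { lambda *= 10.0; continue; }
                double tryTh[4] = {th[0] + delta[0], th[1] + delta[1],
                                   th[2] + delta[2], th[3] + delta[3]};
                if (tryTh[0] < 1e-3) tryTh[0] = 1e-3;
                if (tryTh[3] < 0.0) { tryTh[3] = 0.0; hitBound = true; }
                if (tryTh[1] < 0.0) tryTh[1] = 0.0;
                if (tryTh[1] > S - 1.0) tryTh[1] = S - 1.0;
                if (tryTh[2] < 0.0) tryTh[2] = 0.0;
                if (tryTh[2] > S - 1.0) tryTh[2] = S - 1.0;
                psfEval(S, tryTh, sigma, convention, trialShape.data(),
                        dx0.data(), dy0.data());
                double tryChi2 = objective(mode, npx, tryTh,
                                           trialShape.data(), Xj, Aj, Cj,
                                           Wj);
                if (tryChi2 <= chi2) {
                    double rel = (chi2 - tryChi2) /
                        std::max(std::fabs(chi2), 1.0);
                    for (int a = 0; a < 4; ++a) th[a] = tryTh[a];
                    std::copy(trialShape.begin(), trialShape.end(),
                              shape.begin());
                    // dx0/dy0 already refreshed by psfEval at tryTh
                    chi2 = tryChi2;
                    lambda = std::max(lambda / 10.0, 1e-12);
                    accepted = true;
                    nSmall = (rel < tol) ? nSmall + 1 : 0;
                    break;
                }
                lambda *= 10.0;
            }
            if (!accepted) break;          // stuck: damping exhausted
            if (nSmall >= 2) { ok = true; break; }
        }
        theta(0, j) = th[0]; theta(1, j) = th[1];
        theta(2, j) = th[2]; theta(3, j) = th[3];
        converged[j] = ok;
        iters[j] = it;
        chi2out[j] = chi2;
        boundHit[j] = hitBound;
    }
    return List::create(_["theta"] = theta, _["converged"] = converged,
                        _["iterations"] = iters, _["chi2"] = chi2out,
                        _["boundHit"] = boundHit);
}
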