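// Gradient-voting Hough circle transform.
//
// Two-stage scheme: every edge pixel (magnitude >= param1) casts votes along
// its gradient direction, both ways, at distances minRadius..maxRadius, into
// a centre accumulator at 1/dp resolution. Accumulator local maxima above
// param2, taken in descending vote order and thinned by minDist, become
// centre candidates; each candidate's radius is the mode of a 1 px histogram
// of edge-pixel distances within [minRadius, maxRadius].
//
// Matrices arrive column-major (H rows = y, W cols = x); coordinates returned
// are 0-based pixel (cx, cy, r).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_hough_circles(NumericMatrix mag, NumericMatrix gx,
                                NumericMatrix gy, double dp, double minDist,
                                double param1, double param2, int minRadius,
                                int maxRadius, int maxCircles) {
  const int H = mag.nrow(), W = mag.ncol();
  const int aH = (int)std::ceil(H / dp), aW = (int)std::ceil(W / dp);
  arma::mat acc(aH, aW, arma::fill::zeros);

  std::vector<int> ex, ey;
  ex.reserve(4096); ey.reserve(4096);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mag(i, j) < param1) continue;
      ex.push_back(j); ey.push_back(i);
      const double dxv = gx(i, j), dyv = gy(i, j);
      const double g = std::sqrt(dxv * dxv + dyv * dyv);
      if (g < 1e-12) continue;
      const double ux = dxv / g, uy = dyv / g;
      for (int sign = -1; sign <= 1; sign += 2) {
        for (int r = minRadius; r <= maxRadius; ++r) {
          const double cx = j + sign * ux * r, cy = i + sign * uy * r;
          const int ax = (int)std::floor(cx / dp + 0.5);
          const int ay = (int)std::floor(cy / dp + 0.5);
          if (ax < 0 || ax >= aW || ay < 0 || ay >= aH) break;
          acc(ay, ax) += 1.0;
        }
      }
    }
  }

  // candidate centres: 8-neighbour local maxima above the vote threshold
  struct Cand { double votes, cx, cy; };
  std::vector<Cand> cand;
  for (int ax = 0; ax < aW; ++ax) {
    for (int ay = 0; ay < aH; ++ay) {
      const double v = acc(ay, ax);
      if (v < param2) continue;
      bool peak = true;
      for (int oj = -1; oj <= 1 && peak; ++oj)
        for (int oi = -1; oi <= 1 && peak; ++oi) {
          if (!oi && !oj) continue;
          const int ni = ay + oi, nj = ax + oj;
          if (ni < 0 || ni >= aH || nj < 0 || nj >= aW) continue;
          if (acc(ni, nj) > v) peak = false;
        }
      if (peak) {
        // sub-pixel centre: vote-weighted centroid of the 3x3 neighbourhood
        double wsum = 0, xsum = 0, ysum = 0;
        for (int oj = -1; oj <= 1; ++oj)
          for (int oi = -1; oi <= 1; ++oi) {
            const int ni = ay + oi, nj = ax + oj;
            if (ni < 0 || ni >= aH || nj < 0 || nj >= aW) continue;
            wsum += acc(ni, nj);
            xsum += acc(ni, nj) * nj;
            ysum += acc(ni, nj) * ni;
          }
        cand.push_back({v, (xsum / wsum) * dp, (ysum / wsum) * dp});
      }
    }
  }
  std::stable_sort(cand.begin(), cand.end(),
                   [](const Cand& a, const Cand& b) { return a.votes > b.votes; });

  std::vector<Cand> kept;
  for (const Cand& c : cand) {
    bool ok = true;
    for (const Cand& k : kept) {
      const double ddx = c.cx - k.cx, ddy = c.cy - k.cy;
      if (std::sqrt(ddx * ddx + ddy * ddy) < minDist) { ok = false; break; }
    }
    if (ok) kept.push_back(c);
    if (maxCircles > 0 && (int)kept.size() >= maxCircles) break;
  }

  NumericMatrix out((int)kept.size(), 4);
  colnames(out) = CharacterVector::create("cx", "cy", "r", "score");
  const int nbin = maxRadius - minRadius + 1;
  for (size_t t = 0; t < kept.size(); ++t) {
    std::vector<int> hist(nbin, 0);
    for (size_t e = 0; e < ex.size(); ++e) {
      const double ddx = ex[e] - kept[t].cx, ddy = ey[e] - kept[t].cy;
      const int r = (int)std::floor(std::sqrt(ddx * ddx + ddy * ddy) + 0.5);
      if (r >= minRadius && r <= maxRadius) hist[r - minRadius]++;
    }
    int best = 0;
    for (int b = 1; b < nbin; ++b)
      if (hist[b] > hist[best]) best = b;
    // sub-pixel radius: count-weighted mean over the mode +-2 bins
    double wsum = 0, rsum = 0;
    for (int b = std::max(0, best - 2); b <= std::min(nbin - 1, best + 2);
         ++b) {
      wsum += hist[b];
      rsum += hist[b] * (minRadius + b);
    }
    double cx = kept[t].cx, cy = kept[t].cy;
    double rr = wsum > 0 ? rsum / wsum : minRadius + best;
    // refine by algebraic (Kasa) least-squares circle fit to the edge
    // pixels lying on the detected ring; two passes tighten the inliers
    for (int pass = 0; pass < 2; ++pass) {
      arma::mat A; arma::vec rhs;
      std::vector<double> ax_, ay_;
      for (size_t e = 0; e < ex.size(); ++e) {
        const double ddx = ex[e] - cx, ddy = ey[e] - cy;
        if (std::fabs(std::sqrt(ddx * ddx + ddy * ddy) - rr) <= 3.0) {
          ax_.push_back(ex[e]); ay_.push_back(ey[e]);
        }
      }
      if (ax_.size() < 6) break;
      A.set_size(ax_.size(), 3); rhs.set_size(ax_.size());
      for (size_t e = 0; e < ax_.size(); ++e) {
        A(e, 0) = 2 * ax_[e]; A(e, 1) = 2 * ay_[e]; A(e, 2) = 1.0;
        rhs(e) = ax_[e] * ax_[e] + ay_[e] * ay_[e];
      }
      arma::vec sol;
      if (!arma::solve(sol, A, rhs)) break;
      const double ncx = sol(0), ncy = sol(1);
      const double nr2 = sol(2) + ncx * ncx + ncy * ncy;
      if (nr2 <= 0) break;
      const double nr = std::sqrt(nr2);
      // accept only a local adjustment of the Hough hypothesis
      if (std::fabs(ncx - cx) > 5 || std::fabs(ncy - cy) > 5 ||
          std::fabs(nr - rr) > 5)
        break;
      cx = ncx; cy = ncy; rr = nr;
    }
    if (rr < minRadius) rr = minRadius;
    if (rr > maxRadius) rr = maxRadius;
    out(t, 0) = cx;
    out(t, 1) = cy;
    out(t, 2) = rr;
    out(t, 3) = kept[t].votes;
  }
  return out;
}
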