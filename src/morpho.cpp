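#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 8-neighbour offsets (row, col)
static const int DY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Label 8-connected components of a binary mask. Labels are assigned in
// raster-scan discovery order, so the result is deterministic and labels are
// consecutive 1..N.
// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(const IntegerMatrix& mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      if (mask(y, x) == 0 || lab(y, x) != 0) continue;
      // note: raster order here is column-major (R storage); discovery order
      // is still deterministic
      lab(y, x) = ++next;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < 8; ++k) {
          int yy = p.first + DY[k], xx = p.second + DX[k];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (mask(yy, xx) != 0 && lab(yy, xx) == 0) {
            lab(yy, xx) = next;
            q.push(std::make_pair(yy, xx));
          }
        }
      }
    }
  }
  return lab;
}

// Hysteresis fill: foreground = pixels strictly above `low` that are
// 8-connected through pixels strictly above `low` to a pixel strictly above
// `high`.
// [[Rcpp::export(name = ".hysteresis_fill")]]
IntegerMatrix hysteresis_fill(const NumericMatrix& img, double low, double high) {
  const int ny = img.nrow(), nx = img.ncol();
  IntegerMatrix out(ny, nx);
  std::queue<std::pair<int, int> > q;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      if (img(y, x) > high) {
        out(y, x) = 1;
        q.push(std::make_pair(y, x));
      }
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    for (int k = 0; k < 8; ++k) {
      int yy = p.first + DY[k], xx = p.second + DX[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      if (out(yy, xx) == 0 && img(yy, xx) > low) {
        out(yy, xx) = 1;
        q.push(std::make_pair(yy, xx));
      }
    }
  }
  return out;
}

static inline int at(const IntegerMatrix& m, int y, int x) {
  if (y < 0 || y >= m.nrow() || x < 0 || x >= m.ncol()) return 0;
  return m(y, x) != 0 ? 1 : 0;
}

// Guo-Hall thinning to a 1-pixel-wide, 8-connected skeleton. Endpoints are
// preserved, so a 1-pixel-wide line is its own skeleton.
// [[Rcpp::export(name = ".thin_guo_hall")]]
IntegerMatrix thin_guo_hall(const IntegerMatrix& mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix img(clone(mask));
  for (int i = 0; i < ny * nx; ++i) img[i] = img[i] != 0 ? 1 : 0;
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      kill.clear();
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) {
          if (img(y, x) == 0) continue;
          int p2 = at(img, y - 1, x),     p3 = at(img, y - 1, x + 1);
          int p4 = at(img, y, x + 1),     p5 = at(img, y + 1, x + 1);
          int p6 = at(img, y + 1, x),     p7 = at(img, y + 1, x - 1);
          int p8 = at(img, y, x - 1),     p9 = at(img, y - 1, x - 1);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int m = iter == 0 ? ((p6 | p7 | (!p9)) & p8)
                            : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && m == 0)
            kill.push_back(std::make_pair(y, x));
        }
      }
      for (size_t i = 0; i < kill.size(); ++i)
        img(kill[i].first, kill[i].second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return img;
}

// Longest geodesic path length along a skeleton, in pixel units: 1 per axial
// step, sqrt(2) per diagonal step. Exact all-pairs shortest-path maximum
// (Dijkstra from every skeleton pixel), restricted to one connected
// component; a single-pixel skeleton has length 0.
// [[Rcpp::export(name = ".geodesic_diameter")]]
double geodesic_diameter(const IntegerMatrix& skel) {
  const int ny = skel.nrow(), nx = skel.ncol();
  std::vector<int> ids(ny * nx, -1);
  std::vector<int> ys, xs;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      if (skel(y, x) != 0) {
        ids[x * ny + y] = (int)ys.size();
        ys.push_back(y);
        xs.push_back(x);
      }
  const int n = (int)ys.size();
  if (n <= 1) return 0.0;
  const double SQ2 = std::sqrt(2.0);
  // adjacency lists
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 8; ++k) {
      int yy = ys[i] + DY[k], xx = xs[i] + DX[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      int j = ids[xx * ny + yy];
      if (j >= 0) adj[i].push_back(std::make_pair(j, (DY[k] && DX[k]) ? SQ2 : 1.0));
    }
  }
  double best = 0.0;
  std::vector<double> dist(n);
  typedef std::pair<double, int> QN;
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::priority_queue<QN, std::vector<QN>, std::greater<QN> > pq;
    dist[s] = 0.0;
    pq.push(std::make_pair(0.0, s));
    while (!pq.empty()) {
      QN top = pq.top();
      pq.pop();
      int u = top.second;
      if (top.first > dist[u]) continue;
      for (size_t e = 0; e < adj[u].size(); ++e) {
        int v = adj[u][e].first;
        double nd = dist[u] + adj[u][e].second;
        if (nd < dist[v]) {
          dist[v] = nd;
          pq.push(std::make_pair(nd, v));
        }
      }
    }
    for (int v = 0; v < n; ++v)
      if (R_finite(dist[v]) && dist[v] > best) best = dist[v];
  }
  return best;
}

// Watershed splitting of a binary mask on its (negated) Euclidean distance
// transform. Seeds are the regional maxima of the h-maxima transform of the
// distance map (peaks of prominence > h), thinned so that accepted peaks are
// at least min_dist apart; flooding pops the highest distance first, ties
// broken by raster order, restricted to the mask. Deterministic.
// [[Rcpp::export(name = ".ws_split")]]
IntegerMatrix ws_split(const NumericMatrix& dist, const IntegerMatrix& mask,
                       double h, int min_dist) {
  const int ny = dist.nrow(), nx = dist.ncol();
  const double eps = 1e-9;

  // morphological reconstruction of (dist - h) under dist by iterated
  // forward/backward raster passes
  NumericMatrix R(ny, nx);
  for (int i = 0; i < ny * nx; ++i)
    R[i] = mask[i] ? dist[i] - h : R_NegInf;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      const int y0 = pass == 0 ? 0 : ny - 1, dy = pass == 0 ? 1 : -1;
      const int x0 = pass == 0 ? 0 : nx - 1, dx = pass == 0 ? 1 : -1;
      for (int x = x0; x >= 0 && x < nx; x += dx) {
        for (int y = y0; y >= 0 && y < ny; y += dy) {
          if (!mask(y, x)) continue;
          double best = R(y, x);
          for (int k = 0; k < 8; ++k) {
            int yy = y + DY[k], xx = x + DX[k];
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            if (mask(yy, xx) && R(yy, xx) > best) best = R(yy, xx);
          }
          if (best > dist(y, x)) best = dist(y, x);
          if (best > R(y, x) + eps) {
            R(y, x) = best;
            changed = true;
          }
        }
      }
    }
  }

  // regional maxima of R: plateaus with no strictly higher neighbour
  IntegerMatrix plat(ny, nx);   // plateau labels (0 = none)
  int n_plat = 0;
  std::queue<std::pair<int, int> > q;
  std::vector<char> is_max;
  is_max.push_back(0);          // index 0 unused
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      if (!mask(y, x) || plat(y, x) != 0) continue;
      // flood the equal-value plateau containing (y, x)
      ++n_plat;
      is_max.push_back(1);
      const double v = R(y, x);
      plat(y, x) = n_plat;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < 8; ++k) {
          int yy = p.first + DY[k], xx = p.second + DX[k];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (!mask(yy, xx)) continue;
          if (R(yy, xx) > v + eps) is_max[n_plat] = 0;
          else if (std::fabs(R(yy, xx) - v) <= eps && plat(yy, xx) == 0) {
            plat(yy, xx) = n_plat;
            q.push(std::make_pair(yy, xx));
          }
        }
      }
    }
  }

  // one peak pixel per maximal plateau: highest dist, then raster order
  struct Peak { int y, x, id; double d; };
  std::vector<Peak> peaks;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      int pl = plat(y, x);
      if (pl == 0 || !is_max[pl]) continue;
      bool found = false;
      for (size_t i = 0; i < peaks.size(); ++i)
        if (peaks[i].id == pl) {
          found = true;
          if (dist(y, x) > peaks[i].d + eps) {
            peaks[i].y = y; peaks[i].x = x; peaks[i].d = dist(y, x);
          }
          break;
        }
      if (!found) {
        Peak pk; pk.y = y; pk.x = x; pk.id = pl; pk.d = dist(y, x);
        peaks.push_back(pk);
      }
    }

  // greedy min-distance thinning, strongest peak first
  std::vector<size_t> order(peaks.size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](size_t a, size_t b) {
    if (peaks[a].d != peaks[b].d) return peaks[a].d > peaks[b].d;
    if (peaks[a].x != peaks[b].x) return peaks[a].x < peaks[b].x;
    return peaks[a].y < peaks[b].y;
  });
  std::vector<Peak> kept;
  std::vector<int> seed_of(peaks.size());
  for (size_t oi = 0; oi < order.size(); ++oi) {
    const Peak& p = peaks[order[oi]];
    int assign = -1;
    for (size_t j = 0; j < kept.size(); ++j) {
      double dy = kept[j].y - p.y, dx = kept[j].x - p.x;
      if (std::sqrt(dy * dy + dx * dx) < (double)min_dist) {
        assign = (int)j + 1;
        break;
      }
    }
    if (assign < 0) {
      kept.push_back(p);
      assign = (int)kept.size();
    }
    seed_of[order[oi]] = assign;
  }

  // priority flood on the distance map from the seed plateaus
  IntegerMatrix lab(ny, nx);
  typedef std::pair<double, int> QN;  // (dist, -linear index) max-heap
  std::priority_queue<QN> pq;
  for (size_t i = 0; i < peaks.size(); ++i) {
    // label every pixel of each maximal plateau with its seed id
    int pl = peaks[i].id;
    int sd = seed_of[i];
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        if (plat(y, x) == pl && lab(y, x) == 0) {
          lab(y, x) = sd;
          pq.push(std::make_pair(dist(y, x), -(x * ny + y)));
        }
  }
  while (!pq.empty()) {
    QN top = pq.top();
    pq.pop();
    int idx = -top.second;
    int y = idx % ny, x = idx / ny;
    int l = lab(y, x);
    for (int k = 0; k < 8; ++k) {
      int yy = y + DY[k], xx = x + DX[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      if (mask(yy, xx) && lab(yy, xx) == 0) {
        lab(yy, xx) = l;
        pq.push(std::make_pair(dist(yy, xx), -(xx * ny + yy)));
      }
    }
  }
  return lab;
}
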