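// Core geometry and clustering loops.
//
// Conventions shared with the R layer:
//   * point indices are 0-based here; R wrappers shift to 1-based,
//   * cluster labels: -1 = noise, 0..k-1 = clusters in discovery order,
//   * distances in km on a sphere of radius 6371.0 km,
//   * timestamps are numeric seconds (UTC epoch).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <deque>
#include <vector>

using namespace Rcpp;

static const double EARTH_RADIUS_KM = 6371.0;
static const double RAD_PER_DEG = M_PI / 180.0;
// km per degree of latitude implied by the fixed earth radius
static const double KM_PER_DEG = EARTH_RADIUS_KM * RAD_PER_DEG;
// degree-length constant used by the local equirectangular projection
static const double KM_PER_DEG_PROJ = 111.195;

inline double haversine_rad(double la1, double lo1, double la2, double lo2) {
  double sdlat = std::sin((la2 - la1) / 2.0);
  double sdlon = std::sin((lo2 - lo1) / 2.0);
  double a = sdlat * sdlat + std::cos(la1) * std::cos(la2) * sdlon * sdlon;
  if (a < 0.0) a = 0.0;
  double s = std::sqrt(a);
  if (s > 1.0) s = 1.0;
  return 2.0 * EARTH_RADIUS_KM * std::asin(s);
}

// [[Rcpp::export]]
NumericVector cpp_haversine_km(NumericVector lat1, NumericVector lon1,
                               NumericVector lat2, NumericVector lon2) {
  R_xlen_t n = std::max(lat1.size(), lat2.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double a1 = lat1[i % lat1.size()] * RAD_PER_DEG;
    double o1 = lon1[i % lon1.size()] * RAD_PER_DEG;
    double a2 = lat2[i % lat2.size()] * RAD_PER_DEG;
    double o2 = lon2[i % lon2.size()] * RAD_PER_DEG;
    out[i] = haversine_rad(a1, o1, a2, o2);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Quadtree (PR quadtree on lon/lat degrees; x = lon, y = lat)
// ---------------------------------------------------------------------------

struct QNode {
  double x0, y0, x1, y1;
  int child0;  // -1 = leaf, else nodes child0..child0+3
  int depth;
  std::vector<int> pts;
  QNode(double a, double b, double c, double d, int dep)
      : x0(a), y0(b), x1(c), y1(d), child0(-1), depth(dep) {}
};

class QuadTree {
 public:
  std::vector<QNode> nodes;
  std::vector<double> lon, lat;    // degrees
  std::vector<double> lonr, latr;  // radians
  int capacity, max_depth;
  int n_points;

  QuadTree(const NumericVector& plat, const NumericVector& plon,
           int cap = 16, int maxd = 24)
      : capacity(cap), max_depth(maxd), n_points(0) {
    int n = plat.size();
    lon.resize(n); lat.resize(n); lonr.resize(n); latr.resize(n);
    double x0 = R_PosInf, x1 = R_NegInf, y0 = R_PosInf, y1 = R_NegInf;
    for (int i = 0; i < n; ++i) {
      lat[i] = plat[i]; lon[i] = plon[i];
      latr[i] = plat[i] * RAD_PER_DEG; lonr[i] = plon[i] * RAD_PER_DEG;
      x0 = std::min(x0, lon[i]); x1 = std::max(x1, lon[i]);
      y0 = std::min(y0, lat[i]); y1 = std::max(y1, lat[i]);
    }
    if (n == 0) { x0 = y0 = -1.0; x1 = y1 = 1.0; }
    // expand so boundary points are strictly inside
    const double pad = 1e-9;
    nodes.push_back(QNode(x0 - pad, y0 - pad, x1 + pad, y1 + pad, 0));
    for (int i = 0; i < n; ++i) insert(i);
  }

  void insert(int i) {
    int node = 0;
    for (;;) {
      QNode& nd = nodes[node];
      if (nd.child0 < 0) {
        if ((int)nd.pts.size() < capacity || nd.depth >= max_depth) {
          nd.pts.push_back(i);
          ++n_points;
          return;
        }
        subdivide(node);
        // fall through: nd invalidated, reload below
      }
      node = nodes[node].child0 + quadrant(node, i);
    }
  }

  int quadrant(int node, int i) const {
    const QNode& nd = nodes[node];
    double mx = 0.5 * (nd.x0 + nd.x1), my = 0.5 * (nd.y0 + nd.y1);
    return (lon[i] >= mx ? 1 : 0) + (lat[i] >= my ? 2 : 0);
  }

  void subdivide(int node) {
    double x0 = nodes[node].x0, y0 = nodes[node].y0;
    double x1 = nodes[node].x1, y1 = nodes[node].y1;
    double mx = 0.5 * (x0 + x1), my = 0.5 * (y0 + y1);
    int dep = nodes[node].depth + 1;
    int c0 = (int)nodes.size();
    nodes.push_back(QNode(x0, y0, mx, my, dep));
    nodes.push_back(QNode(mx, y0, x1, my, dep));
    nodes.push_back(QNode(x0, my, mx, y1, dep));
    nodes.push_back(QNode(mx, my, x1, y1, dep));
    nodes[node].child0 = c0;
    std::vector<int> moved;
    moved.swap(nodes[node].pts);
    for (size_t j = 0; j < moved.size(); ++j) {
      int tgt = nodes[node].child0 + quadrant(node, moved[j]);
      nodes[tgt].pts.push_back(moved[j]);
    }
  }

  int depth() const {
    int d = 0;
    for (size_t i = 0; i < nodes.size(); ++i)
      d = std::max(d, nodes[i].depth);
    return d;
  }

  // all points inside leaves that intersect box; inspected counts every
  // point examined in those leaves (the pruning-stage candidates)
  void query_box(double qx0, double qy0, double qx1, double qy1,
                 std::vector<int>& out, double& inspected) const {
    std::vector<int> stack;
    stack.push_back(0);
    while (!stack.empty()) {
      int node = stack.back();
      stack.pop_back();
      const QNode& nd = nodes[node];
      if (nd.x1 < qx0 || nd.x0 > qx1 || nd.y1 < qy0 || nd.y0 > qy1) continue;
      if (nd.child0 >= 0) {
        stack.push_back(nd.child0);
        stack.push_back(nd.child0 + 1);
        stack.push_back(nd.child0 + 2);
        stack.push_back(nd.child0 + 3);
      } else {
        for (size_t j = 0; j < nd.pts.size(); ++j) {
          int i = nd.pts[j];
          inspected += 1.0;
          if (lon[i] >= qx0 && lon[i] <= qx1 && lat[i] >= qy0 && lat[i] <= qy1)
            out.push_back(i);
        }
      }
    }
  }

  // exact eps-ball query: conservative spherical-cap bounding box, then
  // exact haversine filter (inclusive boundary)
  void query_radius(double clat, double clon, double eps_km,
                    std::vector<int>& out, double& inspected) const {
    out.clear();
    double r = eps_km / EARTH_RADIUS_KM;  // angular radius
    double dlat = r / RAD_PER_DEG + 1e-9;
    double y0 = clat - dlat, y1 = clat + dlat;
    double x0, x1;
    if (std::fabs(clat) + dlat >= 89.0) {
      x0 = -180.0 - 1e-9; x1 = 180.0 + 1e-9;
    } else {
      double s = std::sin(r) / std::cos(clat * RAD_PER_DEG);
      if (s > 1.0) s = 1.0;
      double dlon = std::asin(s) / RAD_PER_DEG + 1e-9;
      x0 = clon - dlon; x1 = clon + dlon;
    }
    std::vector<int> cand;
    query_box(x0, y0, x1, y1, cand, inspected);
    double clatr = clat * RAD_PER_DEG, clonr = clon * RAD_PER_DEG;
    for (size_t j = 0; j < cand.size(); ++j) {
      int i = cand[j];
      if (haversine_rad(clatr, clonr, latr[i], lonr[i]) <= eps_km)
        out.push_back(i);
    }
  }
};

// [[Rcpp::export]]
SEXP cpp_quadtree_build(NumericVector lat, NumericVector lon,
                        int capacity = 16, int max_depth = 24) {
  XPtr<QuadTree> xp(new QuadTree(lat, lon, capacity, max_depth), true);
  return xp;
}

// [[Rcpp::export]]
List cpp_quadtree_query(SEXP tree, double lat, double lon, double eps_km) {
  XPtr<QuadTree> xp(tree);
  std::vector<int> out;
  double inspected = 0.0;
  xp->query_radius(lat, lon, eps_km, out, inspected);
  std::sort(out.begin(), out.end());
  return List::create(_["ids"] = wrap(out), _["inspected"] = inspected);
}

// [[Rcpp::export]]
List cpp_quadtree_stats(SEXP tree) {
  XPtr<QuadTree> xp(tree);
  return List::create(_["n_points"] = xp->n_points,
                      _["depth"] = xp->depth(),
                      _["n_nodes"] = (int)xp->nodes.size(),
                      _["node_capacity"] = xp->capacity,
                      _["max_depth"] = xp->max_depth);
}

// ---------------------------------------------------------------------------
// Convex hull: Graham scan, strictly convex, CCW from lowest-(y, x) point
// ---------------------------------------------------------------------------

static inline double cross3(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

// returns 0-based positions into (x, y) of hull vertices, CCW from the
// lowest-y (then lowest-x) vertex; exact duplicate coordinates dropped
// (lowest position kept); inputs with <= 2 distinct points returned as-is
static std::vector<int> graham_hull(const std::vector<double>& x,
                                    const std::vector<double>& y) {
  int n = (int)x.size();
  std::vector<int> idx;
  for (int i = 0; i < n; ++i) idx.push_back(i);
  // dedupe exact coordinates, keep lowest index
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    if (y[a] != y[b]) return y[a] < y[b];
    return a < b;
  });
  std::vector<int> uniq;
  for (size_t j = 0; j < idx.size(); ++j) {
    if (j == 0 || x[idx[j]] != x[idx[j - 1]] || y[idx[j]] != y[idx[j - 1]])
      uniq.push_back(idx[j]);
  }
  int m = (int)uniq.size();
  if (m <= 2) {
    // order by (y, x) for determinism
    std::sort(uniq.begin(), uniq.end(), [&](int a, int b) {
      if (y[a] != y[b]) return y[a] < y[b];
      return x[a] < x[b];
    });
    return uniq;
  }
  // pivot: lowest y, then lowest x
  int piv = uniq[0];
  for (int j = 1; j < m; ++j) {
    int i = uniq[j];
    if (y[i] < y[piv] || (y[i] == y[piv] && x[i] < x[piv])) piv = i;
  }
  std::vector<int> rest;
  for (int j = 0; j < m; ++j)
    if (uniq[j] != piv) rest.push_back(uniq[j]);
  double px = x[piv], py = y[piv];
  std::sort(rest.begin(), rest.end(), [&](int a, int b) {
    double c = cross3(px, py, x[a], y[a], x[b], y[b]);
    if (c != 0.0) return c > 0.0;
    double da = (x[a] - px) * (x[a] - px) + (y[a] - py) * (y[a] - py);
    double db = (x[b] - px) * (x[b] - px) + (y[b] - py) * (y[b] - py);
    return da < db;  // collinear with pivot: nearer first
  });
  std::vector<int> st;
  st.push_back(piv);
  for (size_t j = 0; j < rest.size(); ++j) {
    int c = rest[j];
    while (st.size() >= 2) {
      int b = st[st.size() - 1], a = st[st.size() - 2];
      if (cross3(x[a], y[a], x[b], y[b], x[c], y[c]) <= 0.0)
        st.pop_back();  // non-left turn: drop (strict convexity)
      else
        break;
    }
    st.push_back(c);
  }
  return st;
}

// [[Rcpp::export]]
IntegerVector cpp_convex_hull(NumericVector x, NumericVector y) {
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  std::vector<int> h = graham_hull(xv, yv);
  return wrap(h);
}

// ---------------------------------------------------------------------------
// Clustering engines
// ---------------------------------------------------------------------------

struct NeighborEngine {
  const std::vector<double>& lat;   // degrees
  const std::vector<double>& lon;
  const std::vector<double>& latr;  // radians
  const std::vector<double>& lonr;
  QuadTree* tree;  // NULL = brute force
  double eps_km;
  double inspected;
  double n_queries;

  NeighborEngine(const std::vector<double>& la, const std::vector<double>& lo,
                 const std::vector<double>& lar, const std::vector<double>& lor,
                 QuadTree* qt, double eps)
      : lat(la), lon(lo), latr(lar), lonr(lor), tree(qt), eps_km(eps),
        inspected(0.0), n_queries(0.0) {}

  void query(int p, std::vector<int>& out) {
    n_queries += 1.0;
    if (tree) {
      tree->query_radius(lat[p], lon[p], eps_km, out, inspected);
    } else {
      out.clear();
      int n = (int)lat.size();
      for (int i = 0; i < n; ++i) {
        inspected += 1.0;
        if (haversine_rad(latr[p], lonr[p], latr[i], lonr[i]) <= eps_km)
          out.push_back(i);
      }
    }
  }
};

// maximal run of N (time-sorted) containing p whose consecutive gaps are
// <= max_interval; walks the global (t, id)-sorted order with a membership
// mask so gaps are measured between consecutive members of N only
static void temporal_run(int p, const std::vector<int>& N,
                         const std::vector<double>& t,
                         const std::vector<int>& order_t,
                         const std::vector<int>& rank_t,
                         double max_interval,
                         std::vector<char>& member,  // scratch, all 0
                         std::vector<int>& run) {
  run.clear();
  for (size_t j = 0; j < N.size(); ++j) member[N[j]] = 1;
  int n = (int)order_t.size();
  std::vector<int> left;
  double t_prev = t[p];
  for (int pos = rank_t[p] - 1; pos >= 0; --pos) {
    int i = order_t[pos];
    if (!member[i]) continue;
    if (t_prev - t[i] > max_interval) break;
    left.push_back(i);
    t_prev = t[i];
  }
  for (size_t j = left.size(); j > 0; --j) run.push_back(left[j - 1]);
  run.push_back(p);
  t_prev = t[p];
  for (int pos = rank_t[p] + 1; pos < n; ++pos) {
    int i = order_t[pos];
    if (!member[i]) continue;
    if (t[i] - t_prev > max_interval) break;
    run.push_back(i);
    t_prev = t[i];
  }
  for (size_t j = 0; j < N.size(); ++j) member[N[j]] = 0;
}

// hull vertices (as point ids) of a point set, computed in the local
// equirectangular projection about the set's centroid
static void hull_frontier(const std::vector<int>& pts,
                          const std::vector<double>& lat,
                          const std::vector<double>& lon,
                          std::vector<int>& frontier) {
  frontier.clear();
  size_t m = pts.size();
  if (m <= 3) {
    frontier = pts;
    return;
  }
  double lat0 = 0.0, lon0 = 0.0;
  for (size_t j = 0; j < m; ++j) { lat0 += lat[pts[j]]; lon0 += lon[pts[j]]; }
  lat0 /= m; lon0 /= m;
  double cl = std::cos(lat0 * RAD_PER_DEG);
  std::vector<double> x(m), y(m);
  for (size_t j = 0; j < m; ++j) {
    x[j] = (lon[pts[j]] - lon0) * cl * KM_PER_DEG_PROJ;
    y[j] = (lat[pts[j]] - lat0) * KM_PER_DEG_PROJ;
  }
  std::vector<int> h = graham_hull(x, y);
  for (size_t j = 0; j < h.size(); ++j) frontier.push_back(pts[h[j]]);
}

// [[Rcpp::export]]
List cpp_tdbscan(NumericVector lat_, NumericVector lon_, NumericVector t_,
                 IntegerVector scan_order,  // 0-based visiting order
                 double eps_km, double min_stay_s, double max_interval_s,
                 bool use_quadtree, bool use_hull,
                 int node_capacity = 16, int qt_max_depth = 24) {
  int n = lat_.size();
  std::vector<double> lat(lat_.begin(), lat_.end());
  std::vector<double> lon(lon_.begin(), lon_.end());
  std::vector<double> t(t_.begin(), t_.end());
  std::vector<double> latr(n), lonr(n);
  for (int i = 0; i < n; ++i) {
    latr[i] = lat[i] * RAD_PER_DEG;
    lonr[i] = lon[i] * RAD_PER_DEG;
  }

  // global (t, id) time order
  std::vector<int> order_t(n), rank_t(n);
  for (int i = 0; i < n; ++i) order_t[i] = i;
  std::sort(order_t.begin(), order_t.end(), [&](int a, int b) {
    if (t[a] != t[b]) return t[a] < t[b];
    return a < b;
  });
  for (int pos = 0; pos < n; ++pos) rank_t[order_t[pos]] = pos;

  QuadTree* qt = NULL;
  if (use_quadtree && n > 0)
    qt = new QuadTree(lat_, lon_, node_capacity, qt_max_depth);
  NeighborEngine eng(lat, lon, latr, lonr, qt, eps_km);

  std::vector<int> labels(n, -1);
  std::vector<char> visited(n, 0), is_core(n, 0), member(n, 0);
  int k = 0;
  std::vector<int> N, run, newly, frontier;

  for (int oi = 0; oi < (int)scan_order.size(); ++oi) {
    int p = scan_order[oi];
    // skip points already claimed by a cluster even if never queried:
    // hull-guided expansion deliberately leaves interior points
    // unvisited, and they must not found new clusters
    if (visited[p] || labels[p] != -1) continue;
    visited[p] = 1;
    eng.query(p, N);
    temporal_run(p, N, t, order_t, rank_t, max_interval_s, member, run);
    if (t[run.back()] - t[run.front()] < min_stay_s) continue;  // not core
    is_core[p] = 1;
    int cid = k++;
    std::deque<int> queue;
    // assign the seed's temporal neighborhood, enqueue its frontier
    newly.clear();
    for (size_t j = 0; j < run.size(); ++j) {
      int i = run[j];
      if (labels[i] == -1) { labels[i] = cid; newly.push_back(i); }
    }
    if (use_hull) hull_frontier(newly, lat, lon, frontier);
    else frontier = newly;
    for (size_t j = 0; j < frontier.size(); ++j)
      if (!visited[frontier[j]]) queue.push_back(frontier[j]);
    while (!queue.empty()) {
      int q = queue.front();
      queue.pop_front();
      if (visited[q]) continue;
      visited[q] = 1;
      eng.query(q, N);
      temporal_run(q, N, t, order_t, rank_t, max_interval_s, member, run);
      if (t[run.back()] - t[run.front()] < min_stay_s) continue;
      is_core[q] = 1;
      newly.clear();
      for (size_t j = 0; j < run.size(); ++j) {
        int i = run[j];
        if (labels[i] == -1) { labels[i] = cid; newly.push_back(i); }
      }
      if (use_hull) hull_frontier(newly, lat, lon, frontier);
      else frontier = newly;
      for (size_t j = 0; j < frontier.size(); ++j)
        if (!visited[frontier[j]]) queue.push_back(frontier[j]);
    }
  }
  if (qt) delete qt;

  return List::create(_["labels"] = wrap(labels),
                      _["is_core"] = LogicalVector(is_core.begin(), is_core.end()),
                      _["n_clusters"] = k,
                      _["n_queries"] = eng.n_queries,
                      _["n_inspected"] = eng.inspected);
}

// [[Rcpp::export]]
List cpp_dbscan(NumericVector lat_, NumericVector lon_,
                double eps_km, int min_pts,
                bool use_quadtree = true,
                int node_capacity = 16, int qt_max_depth = 24) {
  int n = lat_.size();
  std::vector<double> lat(lat_.begin(), lat_.end());
  std::vector<double> lon(lon_.begin(), lon_.end());
  std::vector<double> latr(n), lonr(n);
  for (int i = 0; i < n; ++i) {
    latr[i] = lat[i] * RAD_PER_DEG;
    lonr[i] = lon[i] * RAD_PER_DEG;
  }
  QuadTree* qt = NULL;
  if (use_quadtree && n > 0)
    qt = new QuadTree(lat_, lon_, node_capacity, qt_max_depth);
  NeighborEngine eng(lat, lon, latr, lonr, qt, eps_km);

  std::vector<int> labels(n, -1);
  std::vector<char> visited(n, 0), is_core(n, 0);
  int k = 0;
  std::vector<int> N;
  for (int p = 0; p < n; ++p) {
    if (visited[p]) continue;
    visited[p] = 1;
    eng.query(p, N);
    if ((int)N.size() < min_pts) continue;
    is_core[p] = 1;
    int cid = k++;
    labels[p] = cid;
    std::deque<int> queue;
    for (size_t j = 0; j < N.size(); ++j) {
      int i = N[j];
      if (labels[i] == -1) labels[i] = cid;
      if (!visited[i]) queue.push_back(i);
    }
    while (!queue.empty()) {
      int q = queue.front();
      queue.pop_front();
      if (visited[q]) continue;
      visited[q] = 1;
      eng.query(q, N);
      if ((int)N.size() < min_pts) continue;
      is_core[q] = 1;
      for (size_t j = 0; j < N.size(); ++j) {
        int i = N[j];
        if (labels[i] == -1) labels[i] = cid;
        if (!visited[i]) queue.push_back(i);
      }
    }
  }
  if (qt) delete qt;
  return List::create(_["labels"] = wrap(labels),
                      _["is_core"] = LogicalVector(is_core.begin(), is_core.end()),
                      _["n_clusters"] = k,
                      _["n_queries"] = eng.n_queries,
                      _["n_inspected"] = eng.inspected);
}
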