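// Maximally stable extremal region detection for 8-bit grayscale images.
//
// Dark extremal regions only (pillar tips are darker than the background):
// pixels are added in order of increasing grey level to an incremental
// union-find; components of the component tree whose area history is stable
// across +/- delta grey levels are emitted as candidates, together with the
// centroid and the eccentricity of the moment-equivalent ellipse. The larger
// component keeps its identity on a merge, so a region's history follows the
// standard "larger region continues" convention. 8-connectivity throughout,
// matching the connectivity used elsewhere in the pipeline.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <unordered_map>
using namespace Rcpp;

// [[Rcpp::export(name = ".label_cpp")]]
IntegerMatrix label_cpp(LogicalMatrix mask, int conn) {
  // Connected-component labeling, conn = 4 or 8; labels 1..k, background 0.
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (conn == 8) ? 8 : 4;
  int next_label = 0;
  std::vector<int> stack;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next_label;
      stack.clear();
      stack.push_back(i + j * h);
      lab(i, j) = next_label;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % h, pc = p / h;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + dr8[k], qc = pc + dc8[k];
          if (qr < 0 || qr >= h || qc < 0 || qc >= w) continue;
          if (!mask(qr, qc) || lab(qr, qc) != 0) continue;
          lab(qr, qc) = next_label;
          stack.push_back(qr + qc * h);
        }
      }
    }
  return lab;
}

namespace {

struct Stats {
  double area, sr, sc, srr, scc, src;
};

struct Snap {
  int level;
  double area, sr, sc, srr, scc, src;
};

int find_root(std::vector<int>& parent, int x) {
  int r = x;
  while (parent[r] != r) r = parent[r];
  while (parent[x] != r) { int nxt = parent[x]; parent[x] = r; x = nxt; }
  return r;
}

void ellipse_from(const Snap& s, double& cr, double& cc, double& ecc) {
  double n = s.area;
  cr = s.sr / n;
  cc = s.sc / n;
  double mrr = s.srr / n - cr * cr;
  double mcc = s.scc / n - cc * cc;
  double mrc = s.src / n - cr * cc;
  double tr = mrr + mcc;
  double det = std::sqrt((mrr - mcc) * (mrr - mcc) + 4.0 * mrc * mrc);
  double l1 = (tr + det) / 2.0, l2 = (tr - det) / 2.0;
  ecc = (l1 <= 0) ? 0.0 : std::sqrt(std::max(0.0, 1.0 - l2 / l1));
}

} // namespace

// [[Rcpp::export(name = ".mser_detect_cpp")]]
NumericMatrix mser_detect_cpp(IntegerMatrix img, int delta, int min_area,
                              int max_area, double max_variation) {
  const int h = img.nrow(), w = img.ncol(), n = h * w;
  std::vector<int> parent(n, -1);
  std::vector<Stats> stats(n);
  std::vector<bool> visited(n, false);

  // bucket pixels by grey level
  std::vector<std::vector<int>> buckets(256);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      int v = img(i, j);
      if (v < 0) v = 0;
      if (v > 255) v = 255;
      buckets[v].push_back(i + j * h);
    }

  std::unordered_map<int, std::vector<Snap>> tracked;
  std::vector<std::array<double, 6>> out; // level, area, cr, cc, ecc, q

  auto finalize = [&](const std::vector<Snap>& hist) {
    int m = (int)hist.size();
    if (m < 2 * delta + 1) return;
    std::vector<double> q(m, R_PosInf);
    for (int i = delta; i < m - delta; ++i)
      q[i] = (hist[i + delta].area - hist[i - delta].area) / hist[i].area;
    for (int i = delta; i < m - delta; ++i) {
      bool first_of_plateau = (i == delta) || (q[i] < q[i - 1]);
      bool not_rising_next = (i == m - delta - 1) || (q[i] <= q[i + 1]);
      if (!(first_of_plateau && not_rising_next)) continue;
      if (q[i] > max_variation) continue;
      double a = hist[i].area;
      if (a < min_area || a > max_area) continue;
      double cr, cc, ecc;
      ellipse_from(hist[i], cr, cc, ecc);
      out.push_back({(double)hist[i].level, a, cr + 1.0, cc + 1.0, ecc, q[i]});
    }
  };

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  for (int g = 0; g < 256; ++g) {
    for (int p : buckets[g]) {
      int pr = p % h, pc = p / h;
      parent[p] = p;
      stats[p] = {1.0, (double)pr, (double)pc,
                  (double)pr * pr, (double)pc * pc, (double)pr * pc};
      visited[p] = true;
      for (int k = 0; k < 8; ++k) {
        int qr = pr + dr[k], qc = pc + dc[k];
        if (qr < 0 || qr >= h || qc < 0 || qc >= w) continue;
        int qp = qr + qc * h;
        if (!visited[qp]) continue;
        int ra = find_root(parent, p), rb = find_root(parent, qp);
        if (ra == rb) continue;
        int win = (stats[ra].area >= stats[rb].area) ? ra : rb;
        int lose = (win == ra) ? rb : ra;
        parent[lose] = win;
        stats[win].area += stats[lose].area;
        stats[win].sr += stats[lose].sr;
        stats[win].sc += stats[lose].sc;
        stats[win].srr += stats[lose].srr;
        stats[win].scc += stats[lose].scc;
        stats[win].src += stats[lose].src;
        auto it = tracked.find(lose);
        if (it != tracked.end()) {
          finalize(it->second);
          tracked.erase(it);
        }
        if (stats[win].area >= min_area && tracked.find(win) == tracked.end())
          tracked.emplace(win, std::vector<Snap>());
      }
      if (stats[find_root(parent, p)].area >= min_area) {
        int r = find_root(parent, p);
        if (tracked.find(r) == tracked.end())
          tracked.emplace(r, std::vector<Snap>());
      }
    }
    for (auto& kv : tracked) {
      const Stats& s = stats[kv.first];
      kv.second.push_back({g, s.area, s.sr, s.sc, s.srr, s.scc, s.src});
    }
  }
  for (auto& kv : tracked) finalize(kv.second);

  NumericMatrix res(out.size(), 6);
  for (size_t i = 0; i < out.size(); ++i)
    for (int j = 0; j < 6; ++j) res(i, j) = out[i][j];
  colnames(res) = CharacterVector::create("level", "area", "row", "col",
                                          "eccentricity", "variation");
  return res;
}
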