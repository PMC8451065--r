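#include <Rcpp.h>
#include <queue>
#include <tuple>
using namespace Rcpp;

// Seeded watershed by priority flooding: pixels are absorbed into the basin
// of the neighbouring labelled pixel with the lowest elevation first.
// `seeds` holds positive integer labels (0 = unlabelled). 4-connectivity;
// ties broken by insertion order, so the result is deterministic.
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerMatrix watershed_flood(NumericMatrix topo, IntegerMatrix seeds) {
  int nr = topo.nrow(), nc = topo.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc)
    stop("topography and seed image must have the same dimensions");
  IntegerMatrix labels = clone(seeds);
  typedef std::tuple<double, long, int, int> entry; // elev, order, idx, label
  std::priority_queue<entry, std::vector<entry>, std::greater<entry> > pq;
  long counter = 0;
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};

  for (int j = 0; j < nc; j++)
    for (int i = 0; i < nr; i++)
      if (labels(i, j) > 0)
        for (int k = 0; k < 4; k++) {
          int ni = i + di[k], nj = j + dj[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (labels(ni, nj) == 0)
            pq.push(entry(topo(ni, nj), counter++, ni + nj * nr, labels(i, j)));
        }

  while (!pq.empty()) {
    entry e = pq.top();
    pq.pop();
    int idx = std::get<2>(e), lab = std::get<3>(e);
    int i = idx % nr, j = idx / nr;
    if (labels(i, j) != 0) continue;
    labels(i, j) = lab;
    for (int k = 0; k < 4; k++) {
      int ni = i + di[k], nj = j + dj[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (labels(ni, nj) == 0)
        pq.push(entry(topo(ni, nj), counter++, ni + nj * nr, lab));
    }
  }
  return labels;
}
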