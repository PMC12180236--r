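#include <Rcpp.h>
#include <map>
#include <set>
#include <utility>
using namespace Rcpp;

// Count loops exhibiting each unordered motif pair. a_sets/b_sets hold the
// integer motif codes annotated on each loop's two anchors; a loop
// contributes at most once per pair.
// [[Rcpp::export]]
List count_motif_pairs(List a_sets, List b_sets) {
  std::map<std::pair<int, int>, int> counts;
  int n = a_sets.size();
  for (int i = 0; i < n; ++i) {
    IntegerVector a = a_sets[i];
    IntegerVector b = b_sets[i];
    if (a.size() == 0 || b.size() == 0) continue;
    std::set<std::pair<int, int> > seen;
    for (int x : a)
      for (int y : b)
        seen.insert(std::make_pair(std::min(x, y), std::max(x, y)));
    for (std::set<std::pair<int, int> >::iterator it = seen.begin();
         it != seen.end(); ++it)
      counts[*it]++;
  }
  int m = counts.size();
  IntegerVector pa(m), pb(m), ct(m);
  int k = 0;
  for (std::map<std::pair<int, int>, int>::iterator it = counts.begin();
       it != counts.end(); ++it, ++k) {
    pa[k] = it->first.first;
    pb[k] = it->first.second;
    ct[k] = it->second;
  }
  return List::create(_["motif_a"] = pa, _["motif_b"] = pb, _["count"] = ct);
}

// Count, for a fixed list of unordered pairs (pa[k] <= pb[k]), how many
// loops exhibit each pair. Used per bootstrap simulation.
// [[Rcpp::export]]
IntegerVector count_given_pairs(List a_sets, List b_sets,
                                IntegerVector pa, IntegerVector pb) {
  std::map<std::pair<int, int>, int> index;
  for (int k = 0; k < pa.size(); ++k)
    index[std::make_pair(pa[k], pb[k])] = k;
  IntegerVector out(pa.size());
  int n = a_sets.size();
  for (int i = 0; i < n; ++i) {
    IntegerVector a = a_sets[i];
    IntegerVector b = b_sets[i];
    if (a.size() == 0 || b.size() == 0) continue;
    std::set<std::pair<int, int> > seen;
    for (int x : a)
      for (int y : b)
        seen.insert(std::make_pair(std::min(x, y), std::max(x, y)));
    for (std::set<std::pair<int, int> >::iterator it = seen.begin();
         it != seen.end(); ++it) {
      std::map<std::pair<int, int>, int>::iterator f = index.find(*it);
      if (f != index.end()) out[f->second]++;
    }
  }
  return out;
}
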