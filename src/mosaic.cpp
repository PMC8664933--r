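#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Mosaic haplotypes are run-length encodings of founder-haplotype ancestry:
// 'end' holds segment end positions (cM, last == chromosome length), 'id'
// the founder haplotype each segment descends from. These two kernels are
// the inner loops of every pedigree/population simulation.

// Splice two parental mosaics at sorted crossover positions, starting from
// haplotype `first` (1 or 2). Returns the recombinant mosaic with adjacent
// equal ids merged.
// [[Rcpp::export(name = ".cpp_splice")]]
List cpp_splice(NumericVector end1, IntegerVector id1,
                NumericVector end2, IntegerVector id2,
                NumericVector cuts, int first, double len) {
  int ncuts = cuts.size();
  std::vector<double> out_end;
  std::vector<int> out_id;
  out_end.reserve(end1.size() + end2.size() + ncuts);
  out_id.reserve(end1.size() + end2.size() + ncuts);
  double a = 0.0;
  for (int c = 0; c <= ncuts; ++c) {
    double b = (c < ncuts) ? cuts[c] : len;
    if (b > a) {
      bool use1 = ((c % 2 == 0) == (first == 1));
      const NumericVector& e = use1 ? end1 : end2;
      const IntegerVector& id = use1 ? id1 : id2;
      int ja = std::upper_bound(e.begin(), e.end(), a) - e.begin();
      int jb = std::lower_bound(e.begin(), e.end(), b) - e.begin();
      for (int j = ja; j <= jb; ++j) {
        double ee = (j == jb) ? b : e[j];
        // NOTE: adjacent equal ids are NOT merged -- every boundary records
        // one crossover in the lineage's history, which the IBD segment
        // extractor needs to delimit path-recombination segments
        out_end.push_back(ee);
        out_id.push_back(id[j]);
      }
    }
    a = b;
  }
  return List::create(Named("end") = wrap(out_end),
                      Named("id") = wrap(out_id));
}

// One full gamete: splices every chromosome of a parent's two mosaic
// haplotypes. All randomness is drawn in R and passed in: `ncx` crossover
// counts per chromosome, `first` starting haplotype per chromosome (1/2),
// `cuts` the concatenated crossover positions (grouped by chromosome, not
// necessarily sorted within a chromosome).
// [[Rcpp::export(name = ".cpp_gamete")]]
List cpp_gamete(List h1, List h2, NumericVector len,
                IntegerVector ncx, IntegerVector first, NumericVector cuts) {
  int nchr = len.size();
  List out(nchr);
  int off = 0;
  for (int c = 0; c < nchr; ++c) {
    List m1 = h1[c], m2 = h2[c];
    if (ncx[c] == 0) {
      out[c] = (first[c] == 1) ? m1 : m2;
    } else {
      NumericVector cc(cuts.begin() + off, cuts.begin() + off + ncx[c]);
      std::sort(cc.begin(), cc.end());
      out[c] = cpp_splice(m1["end"], m1["id"], m2["end"], m2["id"],
                          cc, first[c], len[c]);
    }
    off += ncx[c];
  }
  return out;
}

// Path-recombination-delimited IBD segments between two mosaics: intervals
// where founder ids match, split additionally at breakpoints present in
// exactly one of the two mosaics. A breakpoint below the common ancestor is
// a recombination on one lineage's path (present in one mosaic only) and
// ends the segment; breakpoints above the common ancestor were inherited
// through it by both lineages (bit-identical positions in both mosaics) and
// do not. This matches the segment definition behind the expected-footprint
// theory, which counts every path recombination as a segment end.
// [[Rcpp::export(name = ".cpp_ibd")]]
NumericMatrix cpp_ibd(NumericVector endA, IntegerVector idA,
                      NumericVector endB, IntegerVector idB) {
  int nA = endA.size(), nB = endB.size();
  std::vector<double> st, en;
  int i = 0, j = 0;
  double pos = 0.0, cur = -1.0;
  while (i < nA && j < nB) {
    double e = std::min(endA[i], endB[j]);
    bool eq = (idA[i] == idB[j]);
    if (eq && cur < 0) cur = pos;
    if (!eq && cur >= 0) {
      if (pos > cur) { st.push_back(cur); en.push_back(pos); }
      cur = -1.0;
    }
    bool advA = (endA[i] <= e), advB = (endB[j] <= e);
    if (eq && cur >= 0 && (advA != advB) &&
        e < std::min(endA[nA - 1], endB[nB - 1])) {
      // single-sided boundary inside a shared run: split here
      if (e > cur) { st.push_back(cur); en.push_back(e); }
      cur = e;
    }
    pos = e;
    if (advA) ++i;
    if (advB) ++j;
  }
  if (cur >= 0 && pos > cur) { st.push_back(cur); en.push_back(pos); }
  NumericMatrix out(st.size(), 2);
  for (size_t r = 0; r < st.size(); ++r) {
    out(r, 0) = st[r];
    out(r, 1) = en[r];
  }
  colnames(out) = CharacterVector::create("start", "end");
  return out;
}

// Maximal intervals where two mosaics carry the same founder haplotype id
// (autozygosity when the mosaics are one individual's homologues, IBD when
// they sit in different individuals; equal-id runs are merged across
// boundaries, matching what a homozygosity/identity caller sees). Returns a
// 2-column matrix (start, end) in cM, or a 0-row matrix.
// [[Rcpp::export(name = ".cpp_shared")]]
NumericMatrix cpp_shared(NumericVector endA, IntegerVector idA,
                         NumericVector endB, IntegerVector idB) {
  int nA = endA.size(), nB = endB.size();
  std::vector<double> st, en;
  int i = 0, j = 0;
  double pos = 0.0, cur = -1.0;
  while (i < nA && j < nB) {
    double e = std::min(endA[i], endB[j]);
    if (idA[i] == idB[j]) {
      if (cur < 0) cur = pos;
    } else if (cur >= 0) {
      st.push_back(cur); en.push_back(pos);
      cur = -1.0;
    }
    pos = e;
    if (endA[i] <= e) ++i;
    if (endB[j] <= e) ++j;
  }
  if (cur >= 0) { st.push_back(cur); en.push_back(pos); }
  NumericMatrix out(st.size(), 2);
  for (size_t r = 0; r < st.size(); ++r) {
    out(r, 0) = st[r];
    out(r, 1) = en[r];
  }
  colnames(out) = CharacterVector::create("start", "end");
  return out;
}
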