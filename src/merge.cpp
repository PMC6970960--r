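#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// 3' quality-trim cut points: for each read, the kept length after cutting at
// the first position where the mean Phred score over a `window`-base window
// (shrinking at the tail) drops below `threshold`. Qualities are Phred+33.
// [[Rcpp::export]]
IntegerVector trim_cut_cpp(CharacterVector qual, int window, double threshold) {
  int n = qual.size();
  IntegerVector keep(n);
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(qual, i));
    int L = std::strlen(q);
    int cut = L;
    for (int p = 0; p < L; ++p) {
      int w = std::min(window, L - p);
      double s = 0;
      for (int j = 0; j < w; ++j) s += q[p + j] - 33;
      if (s / w < threshold) {
        // cut at the first sub-threshold base inside the trigger window
        int j = 0;
        while (j < w && q[p + j] - 33 >= threshold) ++j;
        cut = p + j;
        break;
      }
    }
    keep[i] = cut;
  }
  return keep;
}

// Merge read pairs by their overlap. r2rc/q2rc are the reverse-complemented
// mate 2 sequences with reversed quality strings. For every placement of r2rc
// relative to r1 with an overlap of at least `min_overlap` bases the mismatch
// density (mismatches / overlap length, N matching anything) is computed; the
// placement with the lowest density wins, ties going to the longest overlap
// and then to the larger offset (the standard "innie" orientation). The merge
// fails when the best density exceeds `max_density`.
//
// Consensus: agreeing bases keep the higher of the two quality scores;
// disagreeing positions take the base with the higher score and a quality of
// |q1 - q2| floored at 2; an N defers to the other base.
//
// status: 0 = merged, 1 = no_overlap, 2 = too_divergent.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector r1, CharacterVector q1,
                     CharacterVector r2rc, CharacterVector q2rc,
                     int min_overlap, double max_density) {
  int n = r1.size();
  CharacterVector mseq(n), mqual(n);
  IntegerVector overlap(n), mism(n), status(n);
  std::string out, outq;
  for (int i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(r1, i));
    const char *qa = CHAR(STRING_ELT(q1, i));
    const char *b = CHAR(STRING_ELT(r2rc, i));
    const char *qb = CHAR(STRING_ELT(q2rc, i));
    int L1 = std::strlen(a), L2 = std::strlen(b);
    if (std::min(L1, L2) < min_overlap || L1 == 0 || L2 == 0) {
      status[i] = 1; mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      overlap[i] = 0; mism[i] = 0;
      continue;
    }
    int best_o = 0, best_v = -1, best_m = 0;
    double best_d = 2.0;
    // offset o: start of r2rc relative to r1 (can be negative = "outie")
    for (int o = -(L2 - min_overlap); o <= L1 - min_overlap; ++o) {
      int s = std::max(0, o);            // overlap start in r1 coords
      int e = std::min(L1, o + L2);      // overlap end (exclusive)
      int v = e - s;
      if (v < min_overlap) continue;
      int m = 0;
      for (int p = s; p < e; ++p) {
        char ca = a[p], cb = b[p - o];
        if (ca != 'N' && cb != 'N' && ca != cb) ++m;
      }
      double d = (double)m / v;
      if (d < best_d - 1e-12 ||
          (std::abs(d - best_d) <= 1e-12 &&
           (v > best_v || (v == best_v && o > best_o)))) {
        best_d = d; best_o = o; best_v = v; best_m = m;
      }
    }
    if (best_v < 0) {
      status[i] = 1; mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      overlap[i] = 0; mism[i] = 0;
      continue;
    }
    if (best_d > max_density) {
      // indistinguishable from random placement => no credible overlap
      status[i] = best_d > 0.5 ? 1 : 2;
      mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      overlap[i] = best_v; mism[i] = best_m;
      continue;
    }
    int o = best_o;
    int from = 0;                              // merged region start (r1 coords)
    int to;                                    // merged region end (exclusive)
    if (o >= 0) to = std::max(L1, o + L2);     // innie / contained
    else        to = std::min(L1, o + L2);     // outie: overlap region only
    out.clear(); outq.clear();
    out.reserve(to - from); outq.reserve(to - from);
    for (int p = from; p < to; ++p) {
      bool inA = p >= 0 && p < L1;
      bool inB = (p - o) >= 0 && (p - o) < L2;
      if (inA && inB) {
        char ca = a[p], cb = b[p - o];
        int sa = qa[p] - 33, sb = qb[p - o] - 33;
        if (ca == cb) { out.push_back(ca); outq.push_back((char)(std::max(sa, sb) + 33)); }
        else if (ca == 'N') { out.push_back(cb); outq.push_back((char)(sb + 33)); }
        else if (cb == 'N') { out.push_back(ca); outq.push_back((char)(sa + 33)); }
        else {
          out.push_back(sa >= sb ? ca : cb);
          outq.push_back((char)(std::max(2, std::abs(sa - sb)) + 33));
        }
      } else if (inA) { out.push_back(a[p]); outq.push_back(qa[p]); }
      else { out.push_back(b[p - o]); outq.push_back(qb[p - o]); }
    }
    status[i] = 0;
    mseq[i] = out; mqual[i] = outq;
    overlap[i] = best_v; mism[i] = best_m;
  }
  return List::create(_["seq"] = mseq, _["qual"] = mqual,
                      _["overlap"] = overlap, _["mismatches"] = mism,
                      _["status"] = status);
}
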