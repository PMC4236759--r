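#include <Rcpp.h>
using namespace Rcpp;

// Minimum-penalty global alignment of a miRNA (codes A=0,C=1,G=2,U/T=3,
// 5'->3') against a transcript window taken antiparallel (the window is
// consumed 3'->5' so miRNA position 1 pairs with the window's 3' end).
// Penalties:
//   paircost(m, t)  substitution/wobble/match cost, BEFORE seed doubling
//   indel           per-base gap cost, BEFORE seed doubling
//   seed doubling: a consumed miRNA position i in [seed_start, seed_end]
//   doubles pair and miRNA-gap costs; an unpaired target base inserted
//   between miRNA positions i and i+1 is doubled iff i+1 lies in the seed.
// The DP carries the exact number of gaps used (layer g), so alignments are
// restricted to at most `max_indels` unpaired bases in total.
static double layered_score(const int *mir, int L,
                            const int *tgt_rev, int W,
                            const NumericMatrix &paircost,
                            double indel, double mult,
                            int seed_start, int seed_end,
                            int max_indels, double prune_above) {
  if (abs(W - L) > max_indels) return R_PosInf;
  const double INF = R_PosInf;
  const int G = max_indels;
  // prev[g][j]: best penalty aligning miRNA[1..i] vs window[1..j] with g gaps
  std::vector<std::vector<double>> prev(G + 1, std::vector<double>(W + 1, INF)),
      cur(G + 1, std::vector<double>(W + 1, INF));
  double ins0 = indel * ((1 >= seed_start && 1 <= seed_end) ? mult : 1.0);
  for (int j = 0; j <= std::min(W, G); ++j) prev[j][j] = j * ins0;
  for (int i = 1; i <= L; ++i) {
    bool seed_i = (i >= seed_start && i <= seed_end);
    bool seed_next = (i + 1 >= seed_start && i + 1 <= seed_end);
    double del_cost = indel * (seed_i ? mult : 1.0);
    double ins_cost = indel * (seed_next ? mult : 1.0);
    double rowmin = INF;
    for (int g = 0; g <= G; ++g) {
      std::fill(cur[g].begin(), cur[g].end(), INF);
      int jlo = std::max(0, i - g), jhi = std::min(W, i + g);
      for (int j = jlo; j <= jhi; ++j) {
        double best = INF;
        if (j >= 1 && prev[g][j - 1] < INF) {
          best = prev[g][j - 1] +
                 paircost(mir[i - 1], tgt_rev[j - 1]) * (seed_i ? mult : 1.0);
        }
        if (g >= 1) {
          if (prev[g - 1][j] < INF) {
            double v = prev[g - 1][j] + del_cost;
            if (v < best) best = v;
          }
          if (j >= 1 && cur[g - 1][j - 1] < INF) {
            double v = cur[g - 1][j - 1] + ins_cost;
            if (v < best) best = v;
          }
        }
        cur[g][j] = best;
        if (best < rowmin) rowmin = best;
      }
    }
    if (rowmin > prune_above) return R_PosInf;  // penalties only grow
    std::swap(prev, cur);
  }
  double best = INF;
  for (int g = 0; g <= G; ++g) best = std::min(best, prev[g][W]);
  return best;
}

// Scan one transcript with one miRNA: for every window start (0-based) try
// all window widths L-max_indels..L+max_indels and keep the best (minimum)
// penalty. Scores above `prune_above` are reported as Inf.
// Returns a matrix with columns: start (1-based), width, score.
// [[Rcpp::export]]
NumericMatrix cpp_scan_transcript(IntegerVector mirna, IntegerVector transcript,
                                  NumericMatrix paircost, double indel,
                                  double mult, int seed_start, int seed_end,
                                  int max_indels, double prune_above) {
  int L = mirna.size(), T = transcript.size();
  std::vector<int> mir(mirna.begin(), mirna.end());
  int wmin = std::max(1, L - max_indels), wmax = L + max_indels;
  int nstart = T - wmin + 1;
  if (nstart < 1) return NumericMatrix(0, 3);
  NumericMatrix out(nstart, 3);
  std::vector<int> rev(wmax);
  // try window widths nearest the miRNA length first, so score ties resolve
  // to the alignment with the fewest unpaired bases
  std::vector<int> widths;
  widths.push_back(L);
  for (int d = 1; d <= max_indels; ++d) {
    if (L - d >= wmin) widths.push_back(L - d);
    widths.push_back(L + d);
  }
  for (int s = 0; s < nstart; ++s) {
    double best = R_PosInf;
    int bestw = wmin;
    for (int W : widths) {
      if (s + W > T) continue;
      for (int j = 0; j < W; ++j) rev[j] = transcript[s + W - 1 - j];
      double sc = layered_score(mir.data(), L, rev.data(), W, paircost, indel,
                                mult, seed_start, seed_end, max_indels,
                                prune_above);
      if (sc < best) { best = sc; bestw = W; }
    }
    out(s, 0) = s + 1;
    out(s, 1) = bestw;
    out(s, 2) = best;
  }
  return out;
}
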