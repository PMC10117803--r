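#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh). Residues arrive as 0-based indices into
// the substitution matrix; a gap of length k costs gap_open + k * gap_extend.
//
// Traceback tie-breaking is fixed: diagonal, then up (query residue vs gap),
// then left (target residue vs gap); the best cell is the first maximum in
// row-major scan order. This makes the returned alignment deterministic.

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector t, IntegerMatrix mat,
                  int gap_open, int gap_extend) {
  const int n = q.size(), m = t.size();
  const int gap1 = gap_open + gap_extend;  // cost of a length-1 gap
  const int NEG = INT_MIN / 4;

  // H, E (gap in query, left moves), F (gap in target, up moves)
  IntegerMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  // direction taken at H(i,j): 0 stop, 1 diag, 2 up(F), 3 left(E)
  IntegerMatrix dirH(n + 1, m + 1);
  // 1 if E/F extended a previous gap rather than opening from H
  IntegerMatrix extE(n + 1, m + 1), extF(n + 1, m + 1);

  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int eOpen = H(i, j - 1) - gap1, eExt = E(i, j - 1) - gap_extend;
      E(i, j) = eOpen >= eExt ? eOpen : eExt;
      extE(i, j) = eOpen >= eExt ? 0 : 1;
      int fOpen = H(i - 1, j) - gap1, fExt = F(i - 1, j) - gap_extend;
      F(i, j) = fOpen >= fExt ? fOpen : fExt;
      extF(i, j) = fOpen >= fExt ? 0 : 1;

      int diag = H(i - 1, j - 1) + mat(q[i - 1], t[j - 1]);
      int h = 0, d = 0;
      if (diag >= h && diag > 0) { h = diag; d = 1; }
      if (F(i, j) > h) { h = F(i, j); d = 2; }
      if (E(i, j) > h) { h = E(i, j); d = 3; }
      H(i, j) = h; dirH(i, j) = d;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback from (bi, bj); state 0 = H, 2 = F, 3 = E
  std::vector<int> qp, tp;  // 1-based positions, NA_INTEGER for gap
  int i = bi, j = bj, state = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      int d = dirH(i, j);
      if (d == 0) break;
      if (d == 1) { qp.push_back(i); tp.push_back(j); --i; --j; }
      else state = d;
    } else if (state == 2) {  // up: query residue vs gap
      qp.push_back(i); tp.push_back(NA_INTEGER);
      state = extF(i, j) ? 2 : 0;
      --i;
    } else {                  // left: gap vs target residue
      qp.push_back(NA_INTEGER); tp.push_back(j);
      state = extE(i, j) ? 3 : 0;
      --j;
    }
  }
  std::reverse(qp.begin(), qp.end());
  std::reverse(tp.begin(), tp.end());

  return List::create(_["score"] = best,
                      _["query_pos"] = wrap(qp),
                      _["target_pos"] = wrap(tp));
}

// Score-only scan of one query against many targets (linear memory).
// [[Rcpp::export]]
IntegerVector sw_score_many_cpp(IntegerVector q, List targets,
                                IntegerMatrix mat, int gap_open,
                                int gap_extend) {
  const int n = q.size(), nt = targets.size();
  const int gap1 = gap_open + gap_extend;
  const int NEG = INT_MIN / 4;
  IntegerVector out(nt);

  for (int k = 0; k < nt; ++k) {
    IntegerVector t = targets[k];
    const int m = t.size();
    std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Fcol(m + 1, NEG);
    int best = 0;
    for (int i = 1; i <= n; ++i) {
      int Ecur = NEG;
      Hcur[0] = 0;
      const int qi = q[i - 1];
      for (int j = 1; j <= m; ++j) {
        int eOpen = Hcur[j - 1] - gap1, eExt = Ecur - gap_extend;
        Ecur = eOpen >= eExt ? eOpen : eExt;
        int fOpen = Hprev[j] - gap1, fExt = Fcol[j] - gap_extend;
        Fcol[j] = fOpen >= fExt ? fOpen : fExt;
        int h = Hprev[j - 1] + mat(qi, t[j - 1]);
        if (h < 0) h = 0;
        if (Fcol[j] > h) h = Fcol[j];
        if (Ecur > h) h = Ecur;
        Hcur[j] = h;
        if (h > best) best = h;
      }
      std::swap(Hprev, Hcur);
    }
    out[k] = best;
  }
  return out;
}
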