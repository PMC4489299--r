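#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Local Viterbi over a simplified single-hit profile HMM with per-node
// match (M), insert (I) and delete (D) states.  Scores are log2-odds
// against a uniform residue background; insert emissions equal the
// background and therefore contribute 0 bits, so only match emissions
// and transitions carry score.  The alignment may enter at any match
// node / sequence position and leave from any match node at no cost
// (free local ends on both sequence and model).
//
// match_lo : K x 20 matrix, log2-odds match emission scores per node.
// trans    : K x 7 matrix, log2 transition probabilities out of node j
//            in column order MM, MI, MD, IM, II, DM, DD (MM/MD/IM/DM
//            lead into node j+1; MI/II/DD stay within node j's block).
// seq      : residue codes 1..20; 0 = wildcard (uniform emission,
//            0 bits); negative = masked (no state may emit it).
//
// Tie-breaking is deterministic: predecessor candidates are examined in
// the order M, I, D, fresh-start, and only a strictly greater score
// displaces the incumbent; the best end cell is the first encountered
// scanning sequence positions then nodes in increasing order.
//
// Returns list(score, path) where path is an n x 3 integer matrix of
// (state, seq_pos, node) rows in alignment order; state 1=M, 2=I, 3=D.
// Delete rows carry seq_pos of the last emitted residue (0 if none).

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".viterbi_local_cpp")]]
List viterbi_local_cpp(NumericMatrix match_lo, NumericMatrix trans,
                       IntegerVector seq) {
  const int K = match_lo.nrow();
  const int L = seq.size();
  if (K < 1) stop("profile has no match nodes");
  if (L < 1) stop("empty sequence");

  // DP matrices, (L+1) x (K+1); row 0 / col 0 are boundary.
  std::vector<double> M((L + 1) * (K + 1), NEG_INF);
  std::vector<double> I((L + 1) * (K + 1), NEG_INF);
  std::vector<double> D((L + 1) * (K + 1), NEG_INF);
  // Traceback codes: 0 none, 1 from M, 2 from I, 3 from D, 4 fresh start.
  std::vector<uint8_t> bM((L + 1) * (K + 1), 0);
  std::vector<uint8_t> bI((L + 1) * (K + 1), 0);
  std::vector<uint8_t> bD((L + 1) * (K + 1), 0);

  const int stride = K + 1;
  #define IDX(i, j) ((i) * stride + (j))

  double best = NEG_INF;
  int best_i = -1, best_j = -1;

  for (int i = 1; i <= L; ++i) {
    const int code = seq[i - 1];
    const bool masked = code < 0;
    for (int j = 1; j <= K; ++j) {
      // --- Match ---
      if (!masked) {
        double emit = (code == 0) ? 0.0 : match_lo(j - 1, code - 1);
        double sc = NEG_INF; uint8_t from = 0;
        if (j >= 2) {
          double c = M[IDX(i - 1, j - 1)] + trans(j - 2, 0);
          if (c > sc) { sc = c; from = 1; }
          c = I[IDX(i - 1, j - 1)] + trans(j - 2, 3);
          if (c > sc) { sc = c; from = 2; }
          c = D[IDX(i - 1, j - 1)] + trans(j - 2, 5);
          if (c > sc) { sc = c; from = 3; }
        }
        if (0.0 > sc) { sc = 0.0; from = 4; }  // free local entry
        M[IDX(i, j)] = sc + emit;
        bM[IDX(i, j)] = from;
        if (M[IDX(i, j)] > best) {
          best = M[IDX(i, j)]; best_i = i; best_j = j;
        }
      }
      // --- Insert (emits residue i against background: 0 bits) ---
      if (!masked) {
        double sc = NEG_INF; uint8_t from = 0;
        double c = M[IDX(i - 1, j)] + trans(j - 1, 1);
        if (c > sc) { sc = c; from = 1; }
        c = I[IDX(i - 1, j)] + trans(j - 1, 4);
        if (c > sc) { sc = c; from = 2; }
        I[IDX(i, j)] = sc;
        bI[IDX(i, j)] = from;
      }
      // --- Delete (consumes node j, no residue) ---
      {
        double sc = NEG_INF; uint8_t from = 0;
        if (j >= 2) {
          double c = M[IDX(i, j - 1)] + trans(j - 2, 2);
          if (c > sc) { sc = c; from = 1; }
          c = D[IDX(i, j - 1)] + trans(j - 2, 6);
          if (c > sc) { sc = c; from = 3; }
        }
        D[IDX(i, j)] = sc;
        bD[IDX(i, j)] = from;
      }
    }
  }

  if (best_i < 0 || best <= NEG_INF / 2) {
    return List::create(_["score"] = R_NegInf,
                        _["path"] = IntegerMatrix(0, 3));
  }

  // Traceback from the best match cell.
  std::vector<int> st, pi, pj;
  int i = best_i, j = best_j, state = 1;  // 1=M, 2=I, 3=D
  while (true) {
    st.push_back(state); pi.push_back(i); pj.push_back(j);
    uint8_t from;
    if (state == 1) from = bM[IDX(i, j)];
    else if (state == 2) from = bI[IDX(i, j)];
    else from = bD[IDX(i, j)];
    if (state == 1) {
      if (from == 4 || from == 0) break;
      --i; --j; state = from;
    } else if (state == 2) {
      if (from == 0) break;
      --i; state = from;
    } else {
      if (from == 0) break;
      --j; state = from;
    }
  }

  const int n = (int)st.size();
  IntegerMatrix path(n, 3);
  for (int r = 0; r < n; ++r) {
    path(r, 0) = st[n - 1 - r];
    path(r, 1) = pi[n - 1 - r];
    path(r, 2) = pj[n - 1 - r];
  }
  // Delete rows do not consume a residue: report position of last
  // emitted residue before them (0 if none yet).
  int last_emit = 0;
  for (int r = 0; r < n; ++r) {
    if (path(r, 0) == 3) path(r, 1) = last_emit;
    else last_emit = path(r, 1);
  }
  colnames(path) = CharacterVector::create("state", "seq_pos", "node");
  return List::create(_["score"] = best, _["path"] = path);
}
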