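#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>

using namespace Rcpp;

// Affine-gap alignment engine shared by the glocal and overlap modes.
//
// Maximisation DP over three states (Gotoh):
//   M[i][j]  q[i] aligned to t[j]
//   X[i][j]  gap in the query, t[j] consumed   ("left" move)
//   Y[i][j]  gap in the target, q[i] consumed  ("up" move)
// A gap run of length k costs gap_open + k * gap_extend.
//
// Free borders select the mode:
//   glocal  (global in query, local in target): start states at (0, j),
//           final score = max over j of row n  -> best target window.
//   overlap (dovetail, query precedes target): start states at (i, 0)
//           (query prefix skipped free), final = max over j of row n
//           (target suffix skipped free); the covered region is a suffix
//           of the query aligned to a prefix of the target.
//
// Traceback ties prefer diagonal (M), then up (Y), then left (X).

static const int NEG = INT_MIN / 4;

static inline int max4(int a, int b, int c, int d, int &arg) {
  // preference order on ties: a (M) > b (Y) > c (X) > d (start)
  int best = a; arg = 0;
  if (b > best) { best = b; arg = 1; }
  if (c > best) { best = c; arg = 2; }
  if (d > best) { best = d; arg = 3; }
  return best;
}

// [[Rcpp::export]]
List align_engine_cpp(std::string q, std::string t,
                      int match, int mismatch, int gap_open, int gap_extend,
                      bool free_q_prefix, bool free_t_prefix) {
  const int n = (int) q.size();
  const int m = (int) t.size();
  if (n == 0 || m == 0) stop("empty sequence");

  const size_t W = (size_t)(m + 1);
  std::vector<int> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  // predecessor state: 0=M, 1=Y, 2=X, 3=start
  std::vector<unsigned char> pM((n + 1) * W, 3), pX((n + 1) * W, 3), pY((n + 1) * W, 3);

  const int go = gap_open, ge = gap_extend;

  // start(i, j): 0 where an alignment may begin
  #define START(i, j) ( ((i) == 0 && (j) == 0) || \
                        (free_t_prefix && (i) == 0) || \
                        (free_q_prefix && (j) == 0) ? 0 : NEG )

  for (int i = 1; i <= n; ++i) {
    const size_t r = (size_t) i * W, rp = (size_t)(i - 1) * W;
    const char qc = q[i - 1];
    for (int j = 0; j <= m; ++j) {
      int arg;
      if (j >= 1) {
        const int s = (qc == t[j - 1]) ? match : mismatch;
        int v = max4(M[rp + j - 1], Y[rp + j - 1], X[rp + j - 1],
                     START(i - 1, j - 1), arg);
        if (v > NEG / 2) { M[r + j] = v + s; pM[r + j] = (unsigned char) arg; }
        // X consumes t[j], gap in query
        int sx = START(i, j - 1);
        int vx = max4(M[r + j - 1] + go + ge, Y[r + j - 1] + go + ge,
                      X[r + j - 1] + ge,
                      (sx == 0 ? go + ge : NEG), arg);
        if (vx > NEG / 2) { X[r + j] = vx; pX[r + j] = (unsigned char) arg; }
      }
      // Y consumes q[i], gap in target
      int sy = START(i - 1, j);
      int vy = max4(M[rp + j] + go + ge, Y[rp + j] + ge,
                    X[rp + j] + go + ge,
                    (sy == 0 ? go + ge : NEG), arg);
      if (vy > NEG / 2) { Y[r + j] = vy; pY[r + j] = (unsigned char) arg; }
    }
  }

  // final: whole query consumed, best column of row n; ties prefer a
  // diagonal (M) ending over a gap (Y) ending, then the leftmost column
  const size_t rn = (size_t) n * W;
  int best = NEG, bj = -1; unsigned char bstate = 0;
  for (int j = 0; j <= m; ++j) {
    if (M[rn + j] > best) { best = M[rn + j]; bj = j; bstate = 0; }
    if (Y[rn + j] > best) { best = Y[rn + j]; bj = j; bstate = 1; }
  }
  if (bstate == 1) {  // an equal-scoring M ending wins over Y
    for (int j = 0; j <= m; ++j)
      if (M[rn + j] == best) { bj = j; bstate = 0; break; }
  }
  if (bj < 0) stop("alignment failed");

  // traceback
  std::string qa, ta;
  int i = n, j = bj; unsigned char st = bstate;
  while (true) {
    unsigned char pred;
    if (st == 0) {        // M
      pred = pM[(size_t) i * W + j];
      qa.push_back(q[i - 1]); ta.push_back(t[j - 1]);
      --i; --j;
    } else if (st == 1) { // Y: q consumed, gap in target
      pred = pY[(size_t) i * W + j];
      qa.push_back(q[i - 1]); ta.push_back('-');
      --i;
    } else {              // X: t consumed, gap in query
      pred = pX[(size_t) i * W + j];
      qa.push_back('-'); ta.push_back(t[j - 1]);
      --j;
    }
    if (pred == 3) break;
    st = pred;
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());

  return List::create(_["score"] = best,
                      _["q_aln"] = qa, _["t_aln"] = ta,
                      _["q_start"] = i, _["t_start"] = j, _["t_end"] = bj);
}
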