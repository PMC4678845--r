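#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// One banded glocal DP pass (global in the read, local in the reference,
// linear gap penalty) over the diagonals d0-band..d0+band. Fills `S`
// (row-major (m+1) x (2*band+1)) and returns the best final-row score,
// with the leftmost reference end column on ties (via *kbest).
static int band_pass(const std::string &read, const std::string &ref,
                     int d0, int band, int match, int mismatch, int gap,
                     std::vector<int> &S, int *kbest) {
  const int m = (int)read.size(), n = (int)ref.size();
  const int W = 2 * band + 1;
  std::fill(S.begin(), S.end(), NEG);
  auto idx = [&](int i, int k) { return (size_t)i * W + k; };
  for (int k = 0; k < W; ++k) {
    int j = d0 + k - band;
    if (j >= 0 && j <= n) S[idx(0, k)] = 0;  // free reference prefix
  }
  for (int i = 1; i <= m; ++i) {
    for (int k = 0; k < W; ++k) {
      int j = i + d0 + k - band;
      if (j < 1 || j > n) continue;
      int diag = S[idx(i - 1, k)];                         // (i-1, j-1)
      int up   = (k + 1 < W) ? S[idx(i - 1, k + 1)] : NEG; // (i-1, j)
      int left = (k - 1 >= 0) ? S[idx(i, k - 1)] : NEG;    // (i, j-1)
      int sub = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      int best = NEG;
      if (diag > NEG) best = diag + sub;
      if (up > NEG && up + gap > best) best = up + gap;
      if (left > NEG && left + gap > best) best = left + gap;
      S[idx(i, k)] = best;
    }
  }
  int best = NEG; *kbest = -1;
  for (int k = 0; k < W; ++k) {
    int j = m + d0 + k - band;
    if (j < 1 || j > n) continue;
    if (S[idx(m, k)] > best) { best = S[idx(m, k)]; *kbest = k; }
  }
  return best;
}

// Banded bisulfite-aware alignment. Inputs are already three-letter
// collapsed (C->T on both sides). Seeding: each candidate reference offset
// is scored by its best ungapped segment (Kadane along the diagonal); bands
// of half-width `band` are placed over the top seed diagonals (up to
// `max_seeds`, each at least `band` away from the previous picks) and the
// best-scoring pass wins, leftmost reference offset on ties.
//
// [[Rcpp::export(name = ".align_banded_cpp")]]
List align_banded_cpp(std::string read, std::string ref,
                      int band, int match, int mismatch, int gap,
                      int max_seeds = 4) {
  const int m = (int)read.size();
  const int n = (int)ref.size();
  if (m == 0) stop("empty read");
  if (m > n) stop("read longer than reference");

  const int nd = n - m + 1;
  std::vector<int> seed(nd);
  for (int d = 0; d < nd; ++d) {
    int run = 0, s = 0;
    for (int i = 0; i < m; ++i) {
      run += (read[i] == ref[d + i]) ? match : mismatch;
      if (run < 0) run = 0;
      if (run > s) s = run;
    }
    seed[d] = s;
  }
  std::vector<bool> taken(nd, false);
  std::vector<int> seeds;
  for (int k = 0; k < max_seeds; ++k) {
    int best = NEG, db = -1;
    for (int d = 0; d < nd; ++d)
      if (!taken[d] && seed[d] > best) { best = seed[d]; db = d; }
    if (db < 0) break;
    seeds.push_back(db);
    for (int d = std::max(0, db - band); d < std::min(nd, db + band + 1); ++d)
      taken[d] = true;
  }

  const int W = 2 * band + 1;
  std::vector<int> S((size_t)(m + 1) * W), Sbest;
  int best = NEG, kbest = -1, d0 = 0;
  for (int d : seeds) {
    int kb;
    int sc = band_pass(read, ref, d, band, match, mismatch, gap, S, &kb);
    int jend = m + d + kb - band;
    int jend_best = (kbest >= 0) ? m + d0 + kbest - band : INT_MAX;
    if (sc > best || (sc == best && jend < jend_best)) {
      best = sc; kbest = kb; d0 = d; Sbest = S;
    }
  }
  if (kbest < 0) stop("band produced no valid alignment");

  // traceback (prefer diagonal, then up, then left)
  auto idx = [&](int i, int k) { return (size_t)i * W + k; };
  std::vector<int> rp, qp;
  int nmatch = 0;
  int i = m, k = kbest;
  while (i > 0) {
    int j = i + d0 + k - band;
    int sub = (read[i - 1] == ref[j - 1]) ? match : mismatch;
    int diag = Sbest[idx(i - 1, k)];
    int up   = (k + 1 < W) ? Sbest[idx(i - 1, k + 1)] : NEG;
    int left = (k - 1 >= 0) ? Sbest[idx(i, k - 1)] : NEG;
    int cur = Sbest[idx(i, k)];
    if (diag > NEG && cur == diag + sub) {
      rp.push_back(j - 1); qp.push_back(i - 1);
      if (sub == match) ++nmatch;
      --i;                       // diagonal move, k unchanged
    } else if (up > NEG && cur == up + gap) {
      --i; ++k;                  // gap in reference (read insertion)
    } else if (left > NEG && cur == left + gap) {
      --k;                       // gap in read (reference deletion)
    } else {
      stop("traceback failed");  // should not happen
    }
  }
  std::reverse(rp.begin(), rp.end());
  std::reverse(qp.begin(), qp.end());
  int offset = rp.empty() ? d0 : rp.front();
  return List::create(_["score"] = best,
                      _["offset"] = offset,
                      _["ref_pos"] = wrap(rp),
                      _["read_pos"] = wrap(qp),
                      _["n_match"] = nmatch);
}
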