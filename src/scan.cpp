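#include <Rcpp.h>
using namespace Rcpp;

// Score every length-L window of an integer-encoded sequence (1=A,2=C,3=G,4=T,
// 0=N) against a quantized PWM and return windows at or above a threshold.
// Windows containing any N are skipped. Positions are 1-based window starts.
// A suffix-sum bound on the best attainable remaining score prunes windows
// early, which matters at stringent thresholds.
// [[Rcpp::export]]
List scan_quantized(IntegerVector seq, IntegerMatrix q, int threshold) {
  const int n = seq.size();
  const int L = q.nrow();
  std::vector<int> flat(static_cast<size_t>(L) * 4);
  std::vector<int> suf(L + 1, 0);
  for (int i = 0; i < L; ++i)
    for (int b = 0; b < 4; ++b)
      flat[static_cast<size_t>(i) * 4 + b] = q(i, b);
  for (int i = L - 1; i >= 0; --i) {
    int mx = flat[static_cast<size_t>(i) * 4];
    for (int b = 1; b < 4; ++b)
      mx = std::max(mx, flat[static_cast<size_t>(i) * 4 + b]);
    suf[i] = suf[i + 1] + mx;
  }
  const int* s = INTEGER(seq);
  std::vector<int> pos, score;
  for (int p = 0; p + L <= n; ++p) {
    int sc = 0;
    bool ok = true;
    for (int i = 0; i < L; ++i) {
      const int b = s[p + i];
      if (b < 1 || b > 4) {  // N: no window through this base can match
        p += i;              // loop increment moves past it
        ok = false;
        break;
      }
      sc += flat[static_cast<size_t>(i) * 4 + b - 1];
      if (sc + suf[i + 1] < threshold) { ok = false; break; }
    }
    if (ok && sc >= threshold) { pos.push_back(p + 1); score.push_back(sc); }
  }
  return List::create(_["pos"] = wrap(pos), _["score"] = wrap(score));
}
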