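#include <Rcpp.h>
using namespace Rcpp;

// Greedy left-to-right detection of non-wear intervals in one block of
// minute epochs. An interval is a run of >= min_window epochs that starts
// and ends on a zero-count epoch, contains no epoch at or above
// allowance_threshold, and at most allowance_count interior epochs with
// counts strictly between 0 and allowance_threshold. From each candidate
// start the longest admissible extension is taken; accepted intervals are
// skipped, a failed start advances by one epoch (a later zero can open a
// longer window by skipping an early interruption).
//
// [[Rcpp::export]]
List nonwear_scan_cpp(IntegerVector counts,
                      IntegerVector block_start, // 0-based, ascending
                      int min_window,
                      int allowance_count,
                      int allowance_threshold) {
  const int n = counts.size();
  const int nb = block_start.size();
  LogicalVector worn(n, true);
  std::vector<int> iv_block, iv_start, iv_end;

  for (int b = 0; b < nb; ++b) {
    const int s = block_start[b];
    const int e = (b + 1 < nb) ? block_start[b + 1] : n;
    int i = s;
    while (i < e) {
      if (counts[i] != 0) { ++i; continue; }
      int j = i, last_zero = i, interruptions = 0;
      while (j < e) {
        const int c = counts[j];
        if (c == 0) { last_zero = j; ++j; }
        else if (c < allowance_threshold) {
          if (interruptions < allowance_count) { ++interruptions; ++j; }
          else break;
        } else break;
      }
      const int len = last_zero - i + 1;
      if (len >= min_window) {
        iv_block.push_back(b + 1);
        iv_start.push_back(i);
        iv_end.push_back(last_zero + 1);
        for (int k = i; k <= last_zero; ++k) worn[k] = false;
        i = last_zero + 1;
      } else {
        ++i;
      }
    }
  }

  return List::create(
    _["worn"] = worn,
    _["block"] = wrap(iv_block),
    _["start"] = wrap(iv_start), // 0-based absolute, converted in R
    _["end"] = wrap(iv_end));    // exclusive
}
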