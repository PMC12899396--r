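# Independent oracles for the non-wear rule, used to cross-check the
# package's greedy scanner.
#
# Both oracles work from the window definition: a window [i, j] is
# admissible iff counts[i] == 0, counts[j] == 0, it contains no epoch at or
# above the threshold, at most `allow` epochs in (0, threshold), and spans
# at least `m` minutes. Selection is greedy left-to-right: among admissible
# windows starting at or after the cursor, take the one with the smallest
# start (longest on ties), then move the cursor past it.

# O(n^2) oracle: admissibility checked per window via prefix sums of
# breaker and interruption indicators. For short sequences only.
oracle_nonwear_brute <- function(counts, m = 90L, allow = 2L, thr = 100L) {
  n <- length(counts)
  breaker <- cumsum(counts >= thr)
  interrupt <- cumsum(counts > 0 & counts < thr)
  zero_pos <- which(counts == 0L)
  cand_start <- integer(0); cand_end <- integer(0)
  for (i in zero_pos) {
    js <- zero_pos[zero_pos >= i + m - 1L]
    if (!length(js)) next
    ok <- (breaker[js] - breaker[i]) == 0L &
      (interrupt[js] - interrupt[i]) <= allow
    js <- js[ok]
    if (length(js)) {
      cand_start <- c(cand_start, i)
      cand_end <- c(cand_end, max(js) + 1L) # longest from this start
    }
  }
  greedy_select(cand_start, cand_end)
}

# O(n) oracle: enumerate candidate windows combinatorially. Breakers
# (counts >= thr) split the sequence into regions; within a region a
# window contains a set of consecutive interruption epochs of size 0..allow
# and is trimmed to the zero epochs between the flanking interruptions.
oracle_nonwear_enum <- function(counts, m = 90L, allow = 2L, thr = 100L) {
  n <- length(counts)
  is_breaker <- counts >= thr
  r <- rle(is_breaker)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand_start <- integer(0); cand_end <- integer(0)
  for (k in which(!r$values)) {
    rs <- starts[k]; re <- ends[k]
    seg <- counts[rs:re]
    z <- which(seg == 0L) + rs - 1L
    if (!length(z)) next
    I <- which(seg > 0L) + rs - 1L
    nI <- length(I)
    for (lo in seq_len(nI + 1L)) {
      for (t in 0:allow) {
        hi <- lo + t - 1L
        if (hi > nI) next
        left_excl <- if (lo == 1L) rs - 1L else I[lo - 1L]
        right_excl <- if (hi + 1L > nI) re + 1L else I[hi + 1L]
        i1 <- findInterval(left_excl, z) + 1L    # first zero > left_excl
        i2 <- findInterval(right_excl - 1L, z)   # last zero < right_excl
        if (i1 > i2) next
        s <- z[i1]; e <- z[i2]
        if (e - s + 1L >= m) {
          cand_start <- c(cand_start, s)
          cand_end <- c(cand_end, e + 1L)
        }
      }
    }
  }
  greedy_select(cand_start, cand_end)
}

greedy_select <- function(start, end) {
  if (!length(start)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  }
  o <- order(start, -end)
  start <- start[o]; end <- end[o]
  sel_s <- integer(0); sel_e <- integer(0)
  cursor <- 0L
  for (i in seq_along(start)) {
    if (start[i] >= cursor) {
      sel_s <- c(sel_s, start[i])
      sel_e <- c(sel_e, end[i])
      cursor <- end[i]
    }
  }
  data.frame(start = sel_s, end = sel_e, length = sel_e - sel_s)
}

# structured random count sequences that exercise the rule's boundaries:
# long zero runs, sub-threshold interruptions, breakers
random_count_sequence <- function(max_len = 2000L) {
  target <- sample.int(max_len, 1L)
  out <- integer(0)
  while (length(out) < target) {
    kind <- sample(c("zeros", "low", "high"), 1L,
                   prob = c(0.45, 0.3, 0.25))
    len <- switch(kind,
                  zeros = rgeom(1L, 1 / 60) + 1L,
                  low = rgeom(1L, 1 / 2) + 1L,
                  high = rgeom(1L, 1 / 25) + 1L)
    vals <- switch(kind,
                   zeros = integer(len),
                   low = sample(1:99, len, replace = TRUE),
                   high = sample(100:4000, len, replace = TRUE))
    out <- c(out, vals)
  }
  out[seq_len(target)]
}
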