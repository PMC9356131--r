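# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the simplest possible formulations, separate from
# the package's code paths.

# Count crop seasons by direct prominent-peak counting on a daily EVI2
# series: a day is a season peak if it is a local maximum within the
# mapping year whose topographic prominence exceeds min_amplitude; peaks
# closer than merge_days keep only the highest.
oracle_intensity <- function(evi2, grid, min_amplitude = 0.15,
                             merge_days = 45) {
  n <- length(evi2)
  peaks <- c()
  for (i in 2:(n - 1)) {
    if (grid[i] < 1 || grid[i] > 365) next
    if (!(evi2[i] > evi2[i - 1])) next            # strict rise into i
    j <- i
    while (j < n && evi2[j + 1] == evi2[i]) j <- j + 1
    if (j == n || evi2[j + 1] >= evi2[i]) next    # must fall after plateau
    # prominence by direct scan
    left <- evi2[1:i]; right <- evi2[i:n]
    hl <- which(left > evi2[i])
    lmin <- if (length(hl)) min(left[max(hl):i]) else min(left)
    hr <- which(right > evi2[i])
    rmin <- if (length(hr)) min(right[1:min(hr)]) else min(right)
    if (evi2[i] - max(lmin, rmin) > min_amplitude) peaks <- c(peaks, i)
  }
  if (!length(peaks)) return(0L)
  # merge close peaks, highest first
  peaks <- peaks[order(evi2[peaks], decreasing = TRUE)]
  kept <- c()
  for (p in peaks)
    if (!length(kept) || all(abs(grid[kept] - grid[p]) >= merge_days))
      kept <- c(kept, p)
  min(length(kept), 3L)
}

# Accuracy statistics computed cell-by-cell with explicit loops.
oracle_accuracy <- function(m) {
  K <- nrow(m); N <- sum(m)
  diag_sum <- 0
  for (i in 1:K) diag_sum <- diag_sum + m[i, i]
  oa <- diag_sum / N
  rs <- numeric(K); cs <- numeric(K)
  for (i in 1:K) for (j in 1:K) {
    rs[i] <- rs[i] + m[i, j]
    cs[j] <- cs[j] + m[i, j]
  }
  pa <- numeric(K); ua <- numeric(K); f1 <- numeric(K)
  for (i in 1:K) {
    pa[i] <- m[i, i] / rs[i]
    ua[i] <- m[i, i] / cs[i]
    f1[i] <- 2 * pa[i] * ua[i] / (pa[i] + ua[i])
  }
  pe <- 0
  for (i in 1:K) pe <- pe + rs[i] * cs[i]
  pe <- pe / N^2
  list(oa = oa, pa = pa, ua = ua, f1 = f1, kappa = (oa - pe) / (1 - pe))
}

# A pattern map cycling through the full code vocabulary.
all_codes_map <- function(n) {
  codes <- phenocrop::pattern_code_table()$code
  matrix(rep_len(codes, n * n), n, n)
}
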