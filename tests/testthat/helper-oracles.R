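# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force LZ76 exhaustive-history parser: at each step find the longest
# prefix-reproducible extension, then close the phrase one symbol beyond it.
# Direct transcription of the production-parsing definition; O(n^3) but only
# used on short strings.
lz76_brute <- function(s) {
  n <- length(s)
  if (n == 0) return(0L)
  c <- 0L
  i <- 1L
  while (i <= n) {
    k <- 0L
    # longest l such that s[i:(i+l-1)] occurs starting at some j < i within
    # the history extended by the copied symbols (substring search allowed
    # to run into the phrase itself)
    repeat {
      if (i + k > n) break
      pat <- s[i:(i + k)]
      found <- FALSE
      if (i > 1) {
        for (j in 1:(i - 1)) {
          if (j + k <= n && all(s[j:(j + k)] == pat)) { found <- TRUE; break }
        }
      }
      if (!found) break
      k <- k + 1L
    }
    c <- c + 1L
    i <- i + k + 1L
  }
  c
}

# Closed-form Welch statistics
welch_oracle <- function(x, y, conf = 0.95) {
  nx <- length(x); ny <- length(y)
  vx <- var(x) / nx; vy <- var(y) / ny
  se <- sqrt(vx + vy)
  t <- (mean(x) - mean(y)) / se
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  tc <- qt(1 - (1 - conf) / 2, df)
  list(t = t, df = df, p = 2 * pt(-abs(t), df),
       ci = (mean(x) - mean(y)) + c(-1, 1) * tc * se)
}

# Textbook BH step-up, written as the literal definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    q[ord[i]] <- prev
  }
  pmin(q, 1)
}

# AUC by exhaustive pairwise comparison (ties count 1/2)
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Coarse grid-search ML for the two-component exponential mixture
biexp_grid_oracle <- function(x) {
  qs <- quantile(x[x > 0], probs = seq(0.02, 0.98, length.out = 25))
  best <- -Inf
  for (w in seq(0.05, 0.95, by = 0.05)) for (m1 in qs) for (m2 in qs) {
    if (m2 <= m1) next
    ll <- sum(log(w / m1 * exp(-x / m1) + (1 - w) / m2 * exp(-x / m2)))
    if (ll > best) best <- ll
  }
  best
}

# A minimal five-epoch recording whose samples encode their epoch index,
# for order/trim bookkeeping tests
marker_recording <- function(fs = 100, group = "HC") {
  ep <- 60 * fs
  x <- matrix(rep(1:5, each = ep) + seq_len(5 * ep) * 1e-9, nrow = 1)
  starts <- seq(1L, by = ep, length.out = 5)
  structure(list(samples = x, fs = fs, labels = "ch1", subject = "marker",
                 group = group, age = 40, sex = "female",
                 epochs = cbind(start = starts, end = starts + ep - 1L)),
            class = "recording")
}

# sample indices of the original time grid surviving the MDD harmonization
# (reorder 1-3-5-2-4, 10.6-s end trims) and the 1-s per-segment envelope trim
env_sample_index <- function(fs) {
  ep <- 60 * fs
  order_idx <- c(1, 3, 5, 2, 4)
  full <- unlist(lapply(order_idx, function(k) ((k - 1) * ep + 1):(k * ep)))
  full <- full[(10.6 * fs + 1):(length(full) - 10.6 * fs)]
  seg_len <- c(60 - 10.6, 60, 60, 60, 60 - 10.6) * fs
  ends <- cumsum(seg_len)
  starts <- c(1, ends[-5] + 1)
  keep <- unlist(lapply(1:5, function(s) (starts[s] + fs):(ends[s] - fs)))
  full[keep]
}
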