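# Independent brute-force oracles, written as straight-line loops with no
# vectorization tricks.  They share nothing with the package internals
# except the detrending front end (and signal::butter coefficients), so an
# agreement check is a genuine dual-route comparison.

chi3_median <- function(sigma) sigma * sqrt(qchisq(0.5, df = 3))

# naive truncate-and-renormalize Gaussian moving average
naive_smooth <- function(x, window, sigma) {
  half <- (window - 1) / 2
  w <- dnorm(seq(-half, half), sd = sigma)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    wi <- w[(lo - i + half + 1):(hi - i + half + 1)]
    out[i] <- sum(wi * x[lo:hi]) / sum(wi)
  }
  out
}

# naive zero-phase Butterworth low pass: odd-reflection padding plus a
# direct-form-I recursion warm-started at the steady state for the first
# padded sample (H(1) = sum(b)/sum(a))
naive_lowpass <- function(x, cutoff_hz, fs, order = 4) {
  flt <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  b <- flt$b; a <- flt$a
  p <- length(a) - 1
  padlen <- 3 * max(length(b), length(a))
  n <- length(x)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  h1 <- sum(b) / sum(a)
  run <- function(u) {
    m <- length(u)
    xprev <- rep(u[1], p)
    yprev <- rep(u[1] * h1, p)
    y <- numeric(m)
    for (i in seq_len(m)) {
      acc <- b[1] * u[i]
      for (k in seq_len(p)) acc <- acc + b[k + 1] * xprev[k] - a[k + 1] * yprev[k]
      y[i] <- acc / a[1]
      xprev <- c(u[i], xprev[-p])
      yprev <- c(y[i], yprev[-p])
    }
    y
  }
  y <- run(ext)
  y <- rev(run(rev(y)))
  y[(padlen + 1):(padlen + n)]
}

# brute-force staged classifier: consumes a raw trace, redoes everything
# after detrending with plain loops (binarize, gaps, gap filter, heuristic,
# minimum duration), returns a bout data frame
oracle_detect <- function(trace, cfg) {
  fs <- trace_fs(trace)
  d <- detrend(trace, cfg$cutoff_hz, cfg$filter_order)
  n <- nrow(d)
  mag <- numeric(n)
  for (i in seq_len(n)) mag[i] <- sqrt(d$ax[i]^2 + d$ay[i]^2 + d$az[i]^2)

  lab <- integer(n)
  for (i in seq_len(n)) lab[i] <- if (mag[i] > cfg$activity_threshold_g) 1L else 0L

  window <- round(cfg$kernel_window_s * fs)
  if (window %% 2 == 0) window <- window + 1
  sigma <- window / cfg$kernel_sigma_divisor
  lik <- naive_smooth(lab, window, sigma)
  smag <- naive_smooth(mag, window, sigma)

  # maximal runs of 0s as half-open 0-based [start, end)
  gaps <- list()
  i <- 1
  while (i <= n) {
    if (lab[i] == 0L) {
      j <- i
      while (j <= n && lab[j] == 0L) j <- j + 1
      gaps[[length(gaps) + 1]] <- c(i - 1L, j - 1L)
      i <- j
    } else i <- i + 1
  }

  min_gap <- max(1, round(cfg$min_gap_frames * fs / 100))
  retained <- list()
  for (g in gaps) {
    boundary <- g[1] == 0L || g[2] == n
    cnt <- 0L
    for (k in (g[1] + 1):g[2]) if (lik[k] < cfg$likelihood_threshold) cnt <- cnt + 1L
    if (boundary || cnt >= min_gap) retained[[length(retained) + 1]] <- g
  }

  acts <- list()
  cur <- 0L
  for (g in retained) {
    if (g[1] > cur) acts[[length(acts) + 1]] <- c(cur, g[1])
    cur <- g[2]
  }
  if (cur < n) acts[[length(acts) + 1]] <- c(cur, n)

  out <- data.frame(start_frame = integer(0), end_frame = integer(0),
                    kind = character(0))
  for (a_ in acts) {
    above <- 0L
    for (k in (a_[1] + 1):a_[2]) if (smag[k] > cfg$heuristic_threshold_g) above <- above + 1L
    frac <- above / (a_[2] - a_[1])
    kind <- if (frac < cfg$heuristic_fraction) "walking" else "rejected_transition"
    if (kind == "walking" && (a_[2] - a_[1]) / fs < cfg$min_bout_seconds) {
      kind <- "rejected_short"
    }
    out <- rbind(out, data.frame(start_frame = a_[1], end_frame = a_[2],
                                 kind = kind))
  }
  out
}

# textbook metric formulas, independent of classification_metrics()
naive_metrics <- function(tp, tn, fp, fn) {
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  npv <- div(tn, tn + fn)
  acc <- (tp + tn) / (tp + tn + fp + fn)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  c(sensitivity = sens, specificity = spec, precision = prec, npv = npv,
    accuracy = acc, f1 = f1)
}
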