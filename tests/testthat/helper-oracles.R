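# Independent brute-force reference implementations used as oracles.
# These deliberately mirror the documented rules sample by sample and stay
# free of the package's optimized code paths.

# moving median (symmetric shrinking odd windows at edges) followed by a
# moving mean (windows clipped to the signal)
naive_filter <- function(x, median_radius = 10, mean_radius = 5) {
  n <- length(x)
  med <- vapply(seq_len(n), function(i) {
    k <- min(median_radius, i - 1, n - i)
    stats::median(x[(i - k):(i + k)])
  }, numeric(1))
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - mean_radius)
    hi <- min(n, i + mean_radius)
    mean(med[lo:hi])
  }, numeric(1))
}

# maximum over all pre-stimulus windows at slow pacing, window by window
naive_noise <- function(filtered, time, stim_times, window_s = 0.2,
                        guard_s = 0.016) {
  vals <- vapply(stim_times, function(t0) {
    sel <- time >= t0 - window_s - guard_s & time < t0 - guard_s
    if (any(sel)) max(filtered[sel]) else -Inf
  }, numeric(1))
  max(vals[is.finite(vals)])
}

# exhaustive nearest-feature Euclidean distance with anisotropic spacing
brute_force_edt <- function(mask, voxel_size) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(array(Inf, d))
  gx <- (seq_len(d[1]) - 1) * voxel_size[1]
  gy <- (seq_len(d[2]) - 1) * voxel_size[2]
  gz <- (seq_len(d[3]) - 1) * voxel_size[3]
  out <- array(Inf, d)
  for (i in seq_len(nrow(idx))) {
    cx <- gx[idx[i, 1]]; cy <- gy[idx[i, 2]]; cz <- gz[idx[i, 3]]
    dd <- sqrt(outer(outer((gx - cx)^2, (gy - cy)^2, "+"), (gz - cz)^2, "+"))
    out <- pmin(out, dd)
  }
  out
}

# histogram mode (256 bins, ties to the lower bin) + 2 SD, written directly
naive_mode_2sd <- function(vals, n_bins = 256L) {
  breaks <- seq(min(vals), max(vals), length.out = n_bins + 1L)
  counts <- integer(n_bins)
  bin <- findInterval(vals, breaks, all.inside = TRUE)
  for (b in bin) counts[b] <- counts[b] + 1L
  k <- which(counts == max(counts))[1]
  (breaks[k] + breaks[k + 1]) / 2 + 2 * stats::sd(vals)
}

# closed-form Welch statistic
naive_welch <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df,
       p = 2 * stats::pt(-abs(t), df))
}

# step-down Holm adjustment written out longhand
naive_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 0
  for (i in seq_len(n)) {
    running <- max(running, (n - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}
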