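# Matrix-level harmonic fitting internals. The exported tibble interfaces in
# harmonics.R delegate here; the pipeline calls these directly for speed.

# OLS fit of the 8-term harmonic design; returns coef (8), rmse, n.
harm_fit_mat <- function(t, y, rmse_denom = "n") {
  n <- length(t)
  if (n < 8 || length(unique(t)) < 8) {
    abort(sprintf("insufficient data for harmonic fit: %d observations (%d distinct times), need >= 8",
                  n, length(unique(t))),
          class = "birdhab_insufficient_data")
  }
  X <- harmonic_design(t)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < 8L) {
    abort("rank-deficient harmonic design matrix (collinear observation times)",
          class = "birdhab_degenerate_fit")
  }
  denom <- if (rmse_denom == "n") n else max(n - 8L, 1L)
  list(coef = unname(fit$coefficients),
       rmse = sqrt(sum(fit$residuals^2) / denom), n = n)
}

# Multi-band break scan on a shared time axis. tt: sorted times; Y: matrix
# [time, band]. Returns numeric break times.
detect_breaks_mat <- function(tt, Y, window = 3, threshold_multiplier = 3,
                              min_stable = 12, min_span = 2 * DAYS_PER_YEAR) {
  if (min_stable < 8) stop_config("min_stable must be >= 8")
  n <- length(tt); nb <- ncol(Y)
  need_major <- floor(nb / 2) + 1L
  breaks <- numeric(0)
  start <- 1L
  repeat {
    # the running fit must span enough time to pin down the annual
    # harmonics, otherwise residuals beyond the fit window are dominated by
    # extrapolation error rather than real spectral change
    fit_end <- max(start + min_stable - 1L,
                   sum(tt < tt[start] + min_span))
    if (fit_end - start + 1L < min_stable || fit_end + 1L > n) break
    idx_fit <- start:fit_end
    scan <- (fit_end + 1L):n
    Xfit <- harmonic_design(tt[idx_fit])
    Xscan <- harmonic_design(tt[scan])
    exceed <- matrix(FALSE, length(scan), nb)
    for (j in seq_len(nb)) {
      fit <- stats::lm.fit(Xfit, Y[idx_fit, j])
      if (fit$rank < 8L) next
      rmse <- sqrt(mean(fit$residuals^2))
      pred <- as.vector(Xscan %*% fit$coefficients)
      exceed[, j] <- abs(Y[scan, j] - pred) >
        threshold_multiplier * max(rmse, 1e-12)
    }
    flagged <- rowSums(exceed) >= need_major
    run <- rle(flagged)
    ends <- cumsum(run$lengths)
    hit <- which(run$values & run$lengths >= window)
    if (!length(hit)) break
    first <- ends[hit[1]] - run$lengths[hit[1]] + 1L
    brk_idx <- scan[first]
    breaks <- c(breaks, tt[brk_idx])
    start <- brk_idx
  }
  breaks
}

# Break-delimited per-band segment fits. Returns list(edges, coef array
# [segment, band, 8], rmse [segment, band], n_obs, inherited).
fit_segments_mat <- function(tt, Y, window = 3, threshold_multiplier = 3,
                             min_stable = 12, t_range = NULL,
                             min_span = 2 * DAYS_PER_YEAR) {
  t_range <- t_range %||% c(min(tt), max(tt) + 1e-9)
  breaks <- detect_breaks_mat(tt, Y, window, threshold_multiplier, min_stable,
                              min_span)
  edges <- c(t_range[1], breaks, t_range[2])
  ns <- length(edges) - 1L; nb <- ncol(Y)
  coefs <- array(NA_real_, c(ns, nb, 8))
  rmse <- matrix(NA_real_, ns, nb)
  n_obs <- matrix(0L, ns, nb)
  inherited <- matrix(FALSE, ns, nb)
  for (s in seq_len(ns)) {
    keep <- which(tt >= edges[s] & tt < edges[s + 1])
    for (j in seq_len(nb)) {
      ok <- length(keep) >= 8 && length(unique(tt[keep])) >= 8
      if (ok) {
        f <- harm_fit_mat(tt[keep], Y[keep, j])
        coefs[s, j, ] <- f$coef
        rmse[s, j] <- f$rmse
        n_obs[s, j] <- f$n
      } else if (s > 1L) {
        coefs[s, j, ] <- coefs[s - 1L, j, ]
        rmse[s, j] <- rmse[s - 1L, j]
        n_obs[s, j] <- length(keep)
        inherited[s, j] <- TRUE
      } else {
        abort("first segment has too few observations to fit",
              class = "birdhab_insufficient_data")
      }
    }
  }
  list(edges = edges, coefs = coefs, rmse = rmse, n_obs = n_obs,
       inherited = inherited)
}

# 54-entry feature rows (one per query year) from a fit_segments_mat result.
features_from_segments <- function(segs, years, year0) {
  t_q <- year_mid_t(years, year0)
  seg_idx <- findInterval(t_q, segs$edges, rightmost.closed = FALSE)
  if (any(seg_idx < 1 | seg_idx > dim(segs$coefs)[1])) {
    abort("query year outside fitted segment coverage",
          class = "birdhab_coverage_error")
  }
  nb <- dim(segs$coefs)[2]
  out <- matrix(NA_real_, length(years), 8 * nb + nb)
  for (i in seq_along(years)) {
    s <- seg_idx[i]
    out[i, seq_len(8 * nb)] <- as.vector(t(segs$coefs[s, , ]))
    out[i, 8 * nb + seq_len(nb)] <- segs$rmse[s, ]
  }
  colnames(out) <- feature_names(nb)
  out
}

feature_names <- function(nb = 6) {
  c(as.vector(vapply(seq_len(nb),
                     function(b) paste0("b", b, "_", coef_names()),
                     character(8))),
    paste0("rmse_b", seq_len(nb)))
}
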