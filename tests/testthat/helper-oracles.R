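# Independent oracles used across tests. These never call the package's own
# optimization or accounting paths.

# Pairwise Mann-Whitney AUC by explicit enumeration of all (presence,
# background) pairs.
auc_pairs_oracle <- function(pres, bg) {
  cmp <- outer(pres, bg, function(p, b) (p > b) + 0.5 * (p == b))
  mean(cmp)
}

# Independent convex solver for the penalized Maxent objective: split
# lambda = a - b with a, b >= 0 so the L1 penalty becomes linear, then
# L-BFGS-B. Returns the Gibbs distribution over the background rows.
maxent_gibbs_oracle <- function(P, B, beta_j) {
  pbar <- colMeans(P)
  p <- ncol(P)
  fn <- function(ab) {
    lam <- ab[1:p] - ab[p + 1:p]
    eta <- as.vector(B %*% lam)
    -sum(pbar * lam) + log(sum(exp(eta))) + sum(beta_j * (ab[1:p] + ab[p + 1:p]))
  }
  gr <- function(ab) {
    lam <- ab[1:p] - ab[p + 1:p]
    eta <- as.vector(B %*% lam)
    w <- exp(eta - max(eta)); w <- w / sum(w)
    g <- as.vector(crossprod(B, w)) - pbar
    c(g + beta_j, -g + beta_j)
  }
  o <- stats::optim(rep(0, 2 * p), fn, gr, method = "L-BFGS-B",
                    lower = 0, control = list(maxit = 2000, factr = 10))
  lam <- o$par[1:p] - o$par[p + 1:p]
  eta <- as.vector(B %*% lam)
  exp(eta - max(eta)) / sum(exp(eta - max(eta)))
}

kl_div <- function(p, q) sum(ifelse(p > 0, p * log(p / q), 0))

# Exhaustive sensitivity-equals-specificity threshold search over observed
# scores (independent re-implementation of the selection rule).
threshold_oracle <- function(pres, bg) {
  grid <- sort(unique(c(pres, bg)))
  fnr <- vapply(grid, function(c) mean(pres < c), numeric(1))
  fpr <- vapply(grid, function(c) mean(bg >= c), numeric(1))
  d <- abs(fnr - fpr)
  best <- which(d == min(d))
  sens <- 1 - fnr
  grid[best[which.max(sens[best])]]
}

# Brute-force habitat accumulation inside a rectangular buffer: loop over
# every pixel, compute its centre, test point-in-rectangle.
route_habitat_oracle <- function(pixels_year, route, rows, cols) {
  tot <- 0
  for (i in seq_len(nrow(pixels_year))) {
    cx <- (pixels_year$col[i] - 0.5) * 30
    cy <- (pixels_year$row[i] - 0.5) * 30
    if (cx >= route$xmin && cx <= route$xmax &&
        cy >= route$ymin && cy <= route$ymax && pixels_year$habitat[i]) {
      tot <- tot + 0.09
    }
  }
  tot
}

# Normal-equations harmonic OLS solve (independent of lm/qr path).
harmonic_oracle_coef <- function(t, y) {
  T_ <- 365.25
  w <- 2 * pi * t / T_
  X <- cbind(1, t, cos(w), sin(w), cos(2 * w), sin(2 * w), cos(3 * w),
             sin(3 * w))
  solve(crossprod(X), crossprod(X, y))[, 1]
}

harmonic_truth_eval <- function(coef, t) {
  T_ <- 365.25
  w <- 2 * pi * t / T_
  coef[1] + coef[2] * t + coef[3] * cos(w) + coef[4] * sin(w) +
    coef[5] * cos(2 * w) + coef[6] * sin(2 * w) +
    coef[7] * cos(3 * w) + coef[8] * sin(3 * w)
}
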