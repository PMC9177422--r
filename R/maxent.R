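#' Expand raw SDM features into linear, quadratic and product terms
#'
#' Features are min-max scaled to `[0, 1]` using training extrema (values
#' outside the training range are clamped when the scaling is applied to new
#' data), then expanded into the linear terms, their squares, and all
#' pairwise products: `p + p + p(p-1)/2` derived features. Zero-variance
#' features are retained as constant 0 and their weights locked at zero
#' during fitting.
#'
#' @param x Tibble or matrix of raw numeric features (rows = locations).
#' @param scaling Optional scaling object from a previous call (fit mode when
#'   `NULL`, apply mode otherwise).
#' @return Numeric matrix of expanded features with attribute `"scaling"`
#'   (list of per-feature `min`, `max`).
#' @export
#' @examples
#' ef <- expand_features(tibble::tibble(a = 1:5, b = (1:5)^2))
#' ncol(ef)  # 2 + 2 + 1
expand_features <- function(x, scaling = NULL) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (is.null(scaling)) {
    if (nrow(X) < 2) stop_config("need >= 2 locations to fit feature scaling")
    scaling <- list(min = apply(X, 2, min), max = apply(X, 2, max),
                    names = colnames(X))
  }
  rng <- scaling$max - scaling$min
  S <- sweep(X, 2, scaling$min)
  S <- sweep(S, 2, ifelse(rng > 0, rng, 1), "/")
  S[, rng == 0] <- 0
  S[S < 0] <- 0; S[S > 1] <- 1
  p <- ncol(S)
  nm <- colnames(S) %||% paste0("f", seq_len(p))
  quad <- S^2
  colnames(quad) <- paste0(nm, "^2")
  if (p >= 2) {
    pairs <- utils::combn(p, 2)
    prod_mat <- S[, pairs[1, ], drop = FALSE] * S[, pairs[2, ], drop = FALSE]
    colnames(prod_mat) <- paste0(nm[pairs[1, ]], ":", nm[pairs[2, ]])
  } else {
    prod_mat <- matrix(numeric(0), nrow(S), 0)
  }
  out <- cbind(S, quad, prod_mat)
  attr(out, "scaling") <- scaling
  out
}

#' Fit a presence-only maximum-entropy (Maxent) species distribution model
#'
#' Minimizes the L1-regularized presence-only objective
#' `-mean_presence(lambda . f(x)) + log sum_background exp(lambda . f(x)) +
#' sum_j beta_j |lambda_j|` with per-feature penalty
#' `beta_j = beta * s_j / sqrt(m)` (`s_j` = presence-sample standard
#' deviation of feature `j`, `m` = number of presences), the standard Maxent
#' regularization family. The objective is convex; it is solved by proximal
#' gradient descent (FISTA with backtracking and adaptive restart). The
#' fitted Gibbs distribution over the background, its log-normalizer and its
#' entropy are stored for prediction.
#'
#' @param presences,background Tibbles/matrices of raw features at presence
#'   and background locations (same columns).
#' @param beta Regularization multiplier (> 0).
#' @param expand Expand features with [expand_features()] (default TRUE);
#'   set FALSE to fit on the supplied features as-is (no scaling).
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum proximal-gradient iterations.
#' @param min_presences Minimum presences required (default 10).
#' @param add_samples_to_background Include the presence records in the
#'   background (the Maxent 3.4 convention). This keeps the presence feature
#'   means inside the background's support, so the penalized objective is
#'   always bounded below. Default TRUE.
#' @return A `maxent_model`: weights `lambda`, `beta`, per-feature penalties,
#'   scaling, `log_z`, entropy `h`, number of background points, objective
#'   trace metadata and the output-transform tag (`"cloglog"`).
#' @export
maxent_fit <- function(presences, background, beta = 1, expand = TRUE,
                       tol = 1e-8, max_iter = 10000, min_presences = 10,
                       add_samples_to_background = TRUE) {
  if (beta <= 0) stop_config("beta must be > 0")
  P_raw <- as.matrix(presences); B_raw <- as.matrix(background)
  if (nrow(P_raw) < min_presences) {
    stop_validation("need >= %d presences, got %d", min_presences, nrow(P_raw))
  }
  if (expand) {
    all_feats <- expand_features(rbind(P_raw, B_raw))
    scaling <- attr(all_feats, "scaling")
    P <- all_feats[seq_len(nrow(P_raw)), , drop = FALSE]
    B <- all_feats[-seq_len(nrow(P_raw)), , drop = FALSE]
  } else {
    scaling <- NULL
    P <- P_raw; B <- B_raw
  }
  if (add_samples_to_background) B <- rbind(B, P)
  m <- nrow(P); n <- nrow(B)
  s_j <- apply(P, 2, stats::sd)
  # features constant across ALL training data carry no information: locked.
  s_all <- apply(rbind(P, B), 2, stats::sd)
  locked <- s_all == 0 | !is.finite(s_all)
  # floor the presence-sample sd at 5% of the pooled sd so that features
  # with (near-)constant presence values keep a positive penalty and the
  # objective stays coercive in separable directions
  s_j <- pmax(s_j, 0.05 * s_all)
  beta_j <- beta * s_j / sqrt(m)
  pbar <- colMeans(P)

  obj <- function(lam, pen = TRUE) {
    eta <- as.vector(B %*% lam)
    val <- -sum(pbar * lam) + logsumexp(eta)
    if (pen) val <- val + sum(beta_j * abs(lam))
    val
  }
  grad_f <- function(lam) {
    eta <- as.vector(B %*% lam)
    w <- exp(eta - logsumexp(eta))
    as.vector(crossprod(B, w)) - pbar
  }
  prox <- function(z, step) {
    out <- sign(z) * pmax(abs(z) - step * beta_j, 0)
    out[locked] <- 0
    out
  }

  p <- ncol(P)
  f_smooth <- function(lam) {
    eta <- as.vector(B %*% lam)
    -sum(pbar * lam) + logsumexp(eta)
  }
  # monotone FISTA with backtracking and momentum restart
  lam <- numeric(p); y <- lam; tk <- 1; L <- 1
  F_cur <- obj(lam)
  converged <- FALSE; iters <- 0L
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L; iters <- it
    g <- grad_f(y)
    fy <- f_smooth(y)
    repeat {
      z <- prox(y - g / L, 1 / L)
      d <- z - y
      if (f_smooth(z) <= fy + sum(g * d) + L / 2 * sum(d^2) + 1e-14) break
      if (L > 1e14) break
      L <- L * 2
    }
    F_z <- obj(z)
    if (F_z > F_cur + 1e-15 && any(y != lam)) {
      # momentum overshoot: restart from the last accepted iterate; the
      # plain proximal step from lam cannot increase the objective
      y <- lam; tk <- 1
      next
    }
    rel <- abs(F_cur - F_z) / (abs(F_cur) + 1e-10)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- z + (tk - 1) / tk_new * (z - lam)
    tk <- tk_new
    lam <- z
    F_cur <- F_z
    if (rel < tol && it > 1) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(sprintf(
      "Maxent optimizer did not converge in %d iterations (final gradient norm %.3e)",
      max_iter, sqrt(sum(grad_f(lam)^2))), class = "birdhab_convergence_error")
  }

  eta <- as.vector(B %*% lam)
  log_z <- logsumexp(eta)
  pr <- exp(eta - log_z)
  h <- -sum(ifelse(pr > 0, pr * log(pr), 0))
  structure(list(
    lambda = stats::setNames(lam, colnames(P)),
    beta = beta, beta_j = beta_j, locked = locked, scaling = scaling,
    expand = expand, log_z = log_z, h = h, n_background = n,
    n_presences = m, objective = obj(lam), iterations = iters,
    transform = "cloglog"
  ), class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> beta = %.2f, %d features (%d active), %d presences / %d background\n",
    x$beta, length(x$lambda), sum(x$lambda != 0), x$n_presences,
    x$n_background))
  cat(sprintf("  entropy H = %.4f, logZ = %.4f, transform = %s\n",
              x$h, x$log_z, x$transform))
  invisible(x)
}

#' Predict habitat suitability from a fitted Maxent model
#'
#' Raw output is the Gibbs density relative to the background normalizer,
#' `p(x) = exp(lambda . f(x)) / Z`; the default cloglog output is
#' `1 - exp(-exp(H) * p(x))`, which maps the background-mean raw score to
#' `1 - exp(-1)`.
#'
#' @param object A `maxent_model`.
#' @param newdata Raw feature tibble/matrix (same columns the model was fit
#'   on); expanded and clamped with the model's stored scaling.
#' @param type `"cloglog"` (default) or `"raw"`.
#' @param ... Unused.
#' @return Numeric vector of suitability scores.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("cloglog", "raw"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  F_mat <- if (object$expand) expand_features(X, object$scaling) else X
  eta <- as.vector(F_mat %*% object$lambda)
  raw <- exp(eta - object$log_z)
  if (type == "raw") raw else 1 - exp(-exp(object$h) * raw)
}

#' Sample uniform background (pseudo-absence) locations
#'
#' @param candidates Tibble of candidate pixels (e.g. all pixels of a
#'   landscape, with `row`/`col` or `x`/`y` columns).
#' @param n Sample size (default 10,000, the model-building convention).
#' @param seed Integer seed.
#' @return Tibble of `n` rows sampled uniformly without replacement, with
#'   attribute `"n_background"` recording `n`.
#' @export
sample_background <- function(candidates, n = 10000, seed = 1L) {
  if (n > nrow(candidates)) {
    stop_validation("background sample n = %d exceeds %d candidate pixels",
                    n, nrow(candidates))
  }
  withr::with_seed(seed, idx <- sample.int(nrow(candidates), n))
  out <- candidates[idx, , drop = FALSE]
  attr(out, "n_background") <- n
  out
}

#' Tune the Maxent regularization multiplier over a grid
#'
#' Fits one model per candidate beta and selects the value with the highest
#' training AUC (presence scores vs background scores); ties break toward
#' the larger (more regularized) beta. Failed fits are recorded and skipped.
#'
#' @inheritParams maxent_fit
#' @param grid Candidate beta values (default `seq(0.1, 2, by = 0.1)`).
#' @param ... Passed to [maxent_fit()].
#' @return List with `beta` (selected), `model`, and `results` (tibble of
#'   `beta`, `train_auc`, `error`).
#' @export
tune_beta <- function(presences, background, grid = seq(0.1, 2, by = 0.1),
                      ...) {
  fits <- purrr::map(grid, function(b) {
    tryCatch(maxent_fit(presences, background, beta = b, ...),
             error = function(e) e)
  })
  res <- purrr::map2_dfr(grid, fits, function(b, f) {
    if (inherits(f, "error")) {
      tibble::tibble(beta = b, train_auc = NA_real_,
                     error = conditionMessage(f))
    } else {
      tibble::tibble(
        beta = b,
        train_auc = auc(predict(f, presences), predict(f, background)),
        error = NA_character_
      )
    }
  })
  ok <- which(!is.na(res$train_auc))
  if (!length(ok)) stop_validation("all beta-grid fits failed")
  best <- ok[order(res$train_auc[ok], res$beta[ok],
                   decreasing = TRUE)][1]
  list(beta = res$beta[best], model = fits[[best]], results = res)
}

#' Area under the ROC curve by rank statistic
#'
#' Equals the Mann-Whitney probability that a presence score exceeds a
#' background score, counting ties as one half.
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.9, 0.4), c(0.6, 0.1))  # 0.75
auc <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores)) {
    stop_validation("both score sets must be non-empty")
  }
  m <- length(presence_scores); n <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Spatially blocked train/test split
#'
#' Square blocks of edge `block_edge` tile the extent of the points; whole
#' blocks are randomly assigned to the test set until the test share of
#' points is as close as possible to `1 - train_fraction`, so nearby points
#' never straddle the split.
#'
#' @param points Tibble with `x`, `y` (planar metres).
#' @param block_edge Block edge length (m). The conventional "15 km^2"
#'   blocking is ambiguous between a 15 km edge and a 15 km^2 area
#'   (edge about 3.87 km); pass whichever edge is wanted.
#' @param train_fraction Target training share (default 0.8).
#' @param seed Integer seed.
#' @return `points` with added `block_id` and `fold` (`"train"`/`"test"`)
#'   columns.
#' @export
spatial_block_split <- function(points, block_edge, train_fraction = 0.8,
                                seed = 1L) {
  if (block_edge <= 0) stop_config("block_edge must be > 0")
  bx <- floor((points$x - min(points$x)) / block_edge)
  by <- floor((points$y - min(points$y)) / block_edge)
  block_id <- paste0(bx, "_", by)
  blocks <- unique(block_id)
  if (length(blocks) < 2) {
    stop_validation("all points fall in a single block; cannot hold out")
  }
  target <- 1 - train_fraction
  withr::with_seed(seed, perm <- sample(blocks))
  counts <- table(block_id)[perm]
  share <- cumsum(as.numeric(counts)) / nrow(points)
  k <- which.min(abs(c(0, share) - target)) - 1L
  test_blocks <- if (k > 0) perm[seq_len(k)] else character(0)
  dplyr::mutate(points, block_id = block_id,
                fold = ifelse(block_id %in% test_blocks, "test", "train"))
}
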