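#' Robust principal component analysis for outlier-resistant monitoring
#'
#' Fits a robust PCA model in three stages. (1) The data are reduced to the
#' affine subspace they span via singular value decomposition. (2)
#' Stahel-Donoho outlyingness is computed over a set of projection
#' directions through pairs of observations (all pairwise-difference
#' directions when `N <= 25`, plus `n_directions` seeded random pair
#' directions), and the `h` least outlying observations are kept, with
#' `h = max(floor(alpha * N), floor((N + k + 1) / 2))`. (3) The covariance
#' of the kept observations defines the initial k-dimensional subspace; the
#' scores in that subspace are refined with a reweighted
#' minimum-covariance-determinant (MCD) estimate, whose eigenvectors rotate
#' the loadings and whose eigenvalues become the robust component variances.
#'
#' When `k` is not given it is chosen as the smallest number of components
#' whose cumulative explained variance (on the trimmed covariance spectrum)
#' reaches `variance_target`.
#'
#' All randomness (direction sampling, MCD restarts) derives from `seed`;
#' the global RNG state is left untouched.
#'
#' @param x Complete numeric matrix, `N` lots by `p` features, typically the
#'   output of [prepare_feature_matrix()]. `N >= 4`.
#' @param k Number of components; `NULL` for variance-driven selection.
#' @param variance_target Cumulative explained-variance target in (0, 1]
#'   used when `k` is `NULL` (default 0.80).
#' @param alpha Coverage fraction in (0.5, 1]: the fraction of observations
#'   the estimator is tuned to cover (default 0.75; lower is more robust,
#'   higher more efficient).
#' @param quantile Quantile for the default outlier cutoffs (default 0.975).
#' @param n_directions Number of seeded random pair directions for the
#'   outlyingness stage (default 250).
#' @param seed Integer seed for all stochastic steps (default 1).
#' @return An object of class `robpca`: list with `center` (p-vector),
#'   `loadings` (orthonormal p x k), `eigenvalues` (descending), `k`,
#'   `alpha`, `h`, `quantile`, `explained_variance_fraction`,
#'   `cum_variance`, `best_subset` (row indices of the MCD h-subset),
#'   `outlyingness`, `sd` / `od` (distances of the training lots),
#'   `cutoffs`, `flag` (per-lot quadrant), `n`, `p`, `seed`.
#' @references Hubert, M., Rousseeuw, P. J., Vanden Branden, K. (2005)
#'   ROBPCA: a new approach to robust principal component analysis.
#'   Technometrics 47(1), 64-79.
#' @examples
#' set.seed(42)
#' x <- matrix(rnorm(50 * 6), 50, 6)
#' x[1:3, ] <- x[1:3, ] + 8   # three abnormal lots
#' fit <- robpca(x, k = 2, seed = 7)
#' print(fit)
#' table(fit$flag)
#' @export
robpca <- function(x, k = NULL, variance_target = 0.80, alpha = 0.75,
                   quantile = 0.975, n_directions = 250L, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  p <- ncol(x)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (anyNA(x)) stop("x must be complete; impute upstream", call. = FALSE)
  if (alpha <= 0.5 || alpha > 1) stop("alpha must be in (0.5, 1]",
                                      call. = FALSE)
  # stage 1: reduce to the affine subspace spanned by the data
  m0 <- colMeans(x)
  xc <- sweep(x, 2L, m0)
  sv <- svd(xc)
  tol <- max(n, p) * sv$d[1L] * .Machine$double.eps
  r <- sum(sv$d > tol)
  if (r < 1L) stop("data matrix has rank 0", call. = FALSE)
  V <- sv$v[, seq_len(r), drop = FALSE]
  z <- xc %*% V                       # n x r, exact representation
  if (!is.null(k) && k > r) {
    stop("k = ", k, " exceeds the data rank ", r, call. = FALSE)
  }

  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)

  # stage 2: Stahel-Donoho outlyingness along pair directions
  outl <- sd_outlyingness(z, n_directions)

  h0 <- floor(alpha * n)
  kmax <- min(r, h0 - 1L)
  if (kmax < 1L) stop("alpha * N too small for any component", call. = FALSE)
  ord <- order(outl)
  H0 <- ord[seq_len(h0)]
  eg0 <- eigen(stats::cov(z[H0, , drop = FALSE]), symmetric = TRUE)
  ev0 <- pmax(eg0$values, 0)
  cum0 <- cumsum(ev0) / sum(ev0)
  if (is.null(k)) {
    k <- which(cum0 >= variance_target)[1L]
    if (is.na(k)) k <- length(ev0)
    k <- min(k, kmax)
  }
  h <- max(h0, floor((n + k + 1) / 2))
  if (h > n) h <- n
  if (h < k + 1L) stop("alpha * N < k + 1: too few covered observations",
                       call. = FALSE)
  H <- ord[seq_len(h)]
  eg <- eigen(stats::cov(z[H, , drop = FALSE]), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  mu1 <- colMeans(z[H, , drop = FALSE])
  Ek <- eg$vectors[, seq_len(k), drop = FALSE]
  cumvar <- cumsum(ev) / sum(ev)

  # orthogonal-distance reweighting: points close to the preliminary
  # subspace (OD below its Wilson-Hilferty cutoff) refine the subspace,
  # restoring efficiency on clean data without readmitting leverage points
  zc <- sweep(z, 2L, mu1)
  resid0 <- zc - (zc %*% Ek) %*% t(Ek)
  od0 <- sqrt(rowSums(resid0^2))
  if (any(od0 > 1e-10 * max(1, sqrt(sum(ev))))) {
    u <- od0^(2 / 3)
    od_cut0 <- (stats::median(u) + stats::mad(u) *
                  stats::qnorm(quantile))^(3 / 2)
    wod <- od0 <= od_cut0
    if (sum(wod) > k + 1L) {
      mu1 <- colMeans(z[wod, , drop = FALSE])
      eg <- eigen(stats::cov(z[wod, , drop = FALSE]), symmetric = TRUE)
      ev <- pmax(eg$values, 0)
      Ek <- eg$vectors[, seq_len(k), drop = FALSE]
      cumvar <- cumsum(ev) / sum(ev)
    }
  }

  # stage 3: reweighted MCD refinement in the k-dimensional score space
  scores0 <- sweep(z, 2L, mu1) %*% Ek
  mcd <- mcd_fit(scores0, h, quantile = quantile)
  egk <- eigen(mcd$cov, symmetric = TRUE)
  lam <- pmax(egk$values, .Machine$double.eps)
  R <- egk$vectors
  loadings <- V %*% Ek %*% R
  center <- as.numeric(m0 + V %*% (mu1 + Ek %*% mcd$center))

  fit <- structure(list(
    center = stats::setNames(center, colnames(x)),
    loadings = loadings, eigenvalues = lam, k = k, alpha = alpha, h = h,
    quantile = quantile,
    explained_variance_fraction = cumvar[k], cum_variance = cumvar,
    best_subset = sort(mcd$best_subset), outlyingness = outl,
    n = n, p = p, seed = as.integer(seed),
    feature_names = colnames(x), lot_ids = rownames(x)), class = "robpca")
  d <- distances(fit, x)
  fit$sd <- d$sd
  fit$od <- d$od
  fit$cutoffs <- cutoffs(fit, quantile = quantile)
  fit$flag <- classify_quadrant(d$sd, d$od, fit$cutoffs)
  fit
}

# Evaluate fn under a private RNG stream; returns a restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

# Stahel-Donoho outlyingness over directions through pairs of points:
# all pairs when n <= 25, plus n_random seeded pair directions.
sd_outlyingness <- function(z, n_random) {
  n <- nrow(z)
  dirs <- list()
  if (n <= 25L) {
    prs <- utils::combn(n, 2L)
    for (j in seq_len(ncol(prs))) {
      dirs[[length(dirs) + 1L]] <- z[prs[1L, j], ] - z[prs[2L, j], ]
    }
  }
  if (n_random > 0L) {
    i1 <- sample.int(n, n_random, replace = TRUE)
    i2 <- sample.int(n, n_random, replace = TRUE)
    keep <- i1 != i2
    for (j in which(keep)) {
      dirs[[length(dirs) + 1L]] <- z[i1[j], ] - z[i2[j], ]
    }
  }
  outl <- numeric(n)
  for (v in dirs) {
    nv <- sqrt(sum(v^2))
    if (nv < .Machine$double.eps) next
    pr <- as.numeric(z %*% (v / nv))
    s <- stats::mad(pr)
    if (s < .Machine$double.eps) next
    o <- abs(pr - stats::median(pr)) / s
    outl <- pmax(outl, o)
  }
  outl
}

# Minimum covariance determinant in low dimension. Exhaustive over all
# h-subsets when feasible, otherwise seeded C-step search (FAST-MCD style).
# Returns the reweighted center/cov (consistency-corrected) and the raw
# best h-subset.
mcd_fit <- function(y, h, quantile = 0.975, n_starts = 500L,
                    exhaustive_limit = 20000) {
  y <- as.matrix(y)
  n <- nrow(y)
  k <- ncol(y)
  if (h >= n) {
    ctr <- colMeans(y)
    cv <- stats::cov(y)
    return(list(center = ctr, cov = cv, best_subset = seq_len(n)))
  }
  det_of <- function(idx) {
    cv <- stats::cov(y[idx, , drop = FALSE])
    determinant(cv, logarithm = TRUE)$modulus[1L]
  }
  cstep <- function(idx) {
    repeat {
      ctr <- colMeans(y[idx, , drop = FALSE])
      cv <- stats::cov(y[idx, , drop = FALSE])
      if (!all(is.finite(cv)) || rcond_sym(cv) < 1e-12) {
        cv <- cv + diag(1e-10 * max(diag(cv), 1), k)
      }
      d2 <- stats::mahalanobis(y, ctr, cv, tol = 1e-20)
      new_idx <- order(d2)[seq_len(h)]
      if (setequal(new_idx, idx)) return(sort(new_idx))
      idx <- new_idx
    }
  }
  if (choose(n, h) <= exhaustive_limit) {
    subsets <- utils::combn(n, h)
    lds <- apply(subsets, 2L, det_of)
    best <- subsets[, which.min(lds)]
  } else {
    best <- NULL
    best_ld <- Inf
    for (s in seq_len(n_starts)) {
      idx0 <- sample.int(n, k + 1L)
      ctr <- colMeans(y[idx0, , drop = FALSE])
      cv <- stats::cov(y[idx0, , drop = FALSE])
      if (!all(is.finite(cv)) || rcond_sym(cv) < 1e-12) {
        cv <- cv + diag(1e-8 * max(diag(cv), 1), k)
      }
      d2 <- stats::mahalanobis(y, ctr, cv, tol = 1e-20)
      idx <- cstep(order(d2)[seq_len(h)])
      ld <- det_of(idx)
      if (ld < best_ld) {
        best_ld <- ld
        best <- idx
      }
    }
  }
  ctr_raw <- colMeans(y[best, , drop = FALSE])
  cov_raw <- stats::cov(y[best, , drop = FALSE])
  # consistency factor for h/n trimming under the normal model
  cf <- (h / n) / stats::pchisq(stats::qchisq(h / n, k), k + 2L)
  cov_raw <- cov_raw * cf
  # one reweighting step at the chi-squared cutoff
  d2 <- stats::mahalanobis(y, ctr_raw, cov_raw, tol = 1e-20)
  w <- d2 <= stats::qchisq(quantile, k)
  if (sum(w) > k) {
    ctr <- colMeans(y[w, , drop = FALSE])
    cv <- stats::cov(y[w, , drop = FALSE])
    dn <- mean(w)
    cf2 <- dn / stats::pchisq(stats::qchisq(dn, k), k + 2L)
    cv <- cv * cf2
  } else {
    ctr <- ctr_raw
    cv <- cov_raw
  }
  list(center = ctr, cov = cv, best_subset = best)
}

rcond_sym <- function(m) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Score and orthogonal distances under a robust PCA model
#'
#' The score distance `SD_i = sqrt(sum_k t_ik^2 / lambda_k)` is the
#' Mahalanobis-type distance of an observation's scores within the model
#' subspace; the orthogonal distance `OD_i = ||x_i - mu - P t_i||` is its
#' Euclidean distance to that subspace.
#'
#' @param model A fitted [robpca()] model.
#' @param x Numeric matrix with `p` columns (defaults to asking the model
#'   for its training distances via `model$sd` / `model$od`).
#' @return A list with numeric vectors `sd`, `od` and the score matrix
#'   `scores` (N x k).
#' @export
distances <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$p) {
    stop("x has ", ncol(x), " columns; model expects ", model$p,
         call. = FALSE)
  }
  xc <- sweep(x, 2L, model$center)
  t_sc <- xc %*% model$loadings
  sd_i <- sqrt(rowSums(sweep(t_sc^2, 2L, model$eigenvalues, "/")))
  resid <- xc - t_sc %*% t(model$loadings)
  od_i <- sqrt(rowSums(resid^2))
  list(sd = sd_i, od = od_i, scores = t_sc)
}

#' Outlier cutoffs for the score / orthogonal distance map
#'
#' The score-distance cutoff is `sqrt(qchisq(quantile, k))` (squared score
#' distances of regular observations are approximately chi-squared with `k`
#' degrees of freedom). The orthogonal-distance cutoff uses the
#' Wilson-Hilferty approximation: `OD^(2/3)` is treated as Gaussian with
#' robustly estimated center and scale (median and MAD), giving
#' `od_cut = (center + scale * z_quantile)^(3/2)`. When the model spans the
#' full data rank all orthogonal distances are numerically zero and the OD
#' cutoff is returned as `NA` (OD classification suppressed).
#'
#' @param model A fitted [robpca()] model.
#' @param quantile Cutoff quantile (default 0.975).
#' @param od Orthogonal distances used for the Wilson-Hilferty fit; defaults
#'   to the model's training distances.
#' @return Named numeric vector `c(sd_cut, od_cut)`.
#' @export
cutoffs <- function(model, quantile = 0.975, od = model$od) {
  sd_cut <- sqrt(stats::qchisq(quantile, df = model$k))
  scale_ref <- sqrt(mean(model$eigenvalues))
  if (all(od < 1e-10 * max(scale_ref, 1))) {
    od_cut <- NA_real_
  } else {
    u <- od^(2 / 3)
    ctr <- stats::median(u)
    scl <- stats::mad(u)
    if (scl == 0) scl <- stats::sd(u)
    od_cut <- (ctr + scl * stats::qnorm(quantile))^(3 / 2)
  }
  c(sd_cut = sd_cut, od_cut = od_cut)
}

#' Classify lots into outlier-map quadrants
#'
#' Strict inequalities flag an outlier: `regular` when both distances are at
#' or below their cutoffs, `score_outlier` when only the score distance
#' exceeds, `orthogonal_outlier` when only the orthogonal distance exceeds,
#' `both` when both do. An `NA` orthogonal cutoff suppresses OD
#' classification.
#'
#' @param sd,od Numeric distance vectors.
#' @param cuts Named vector `c(sd_cut, od_cut)` from [cutoffs()].
#' @return Factor with levels `regular`, `score_outlier`,
#'   `orthogonal_outlier`, `both`.
#' @export
classify_quadrant <- function(sd, od, cuts) {
  sd_out <- sd > cuts[["sd_cut"]]
  od_out <- if (is.na(cuts[["od_cut"]])) rep(FALSE, length(od)) else
    od > cuts[["od_cut"]]
  lab <- ifelse(sd_out & od_out, "both",
         ifelse(sd_out, "score_outlier",
         ifelse(od_out, "orthogonal_outlier", "regular")))
  factor(lab, levels = c("regular", "score_outlier", "orthogonal_outlier",
                         "both"))
}

#' Build the outlier map for a campaign
#'
#' @param model A fitted [robpca()] model.
#' @param x Feature matrix (defaults to reusing the training distances).
#' @param quantile Cutoff quantile (default 0.975, both lines).
#' @return A data frame of class `outlier_map` with `lot_id`, `sd`, `od`,
#'   `quadrant`, and the cutoffs in attributes `cutoffs` and `quantile`.
#' @export
outlier_map <- function(model, x = NULL, quantile = 0.975) {
  if (is.null(x)) {
    sd_i <- model$sd
    od_i <- model$od
    lots <- model$lot_ids %||% paste0("lot", seq_along(sd_i))
  } else {
    d <- distances(model, x)
    sd_i <- d$sd
    od_i <- d$od
    lots <- rownames(x) %||% paste0("lot", seq_along(sd_i))
  }
  cuts <- cutoffs(model, quantile = quantile, od = od_i)
  out <- data.frame(lot_id = lots, sd = sd_i, od = od_i,
                    quadrant = classify_quadrant(sd_i, od_i, cuts),
                    stringsAsFactors = FALSE)
  attr(out, "cutoffs") <- cuts
  attr(out, "quantile") <- quantile
  class(out) <- c("outlier_map", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-variable contributions to the score distance
#'
#' Decomposes each lot's squared score distance additively over variables:
#' `c_ij = (x_ij - mu_j) * sum_k P_jk t_ik / lambda_k`, so that
#' `sum_j c_ij = SD_i^2` exactly. Variables with large contributions point
#' to the root cause of a score outlier.
#'
#' @param model A fitted [robpca()] model.
#' @param x Numeric matrix (or single row) of lots to decompose.
#' @return Matrix of contributions (lots x variables) with attribute
#'   `sd2 = rowSums`.
#' @export
score_contributions <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L,
                                   dimnames = list(NULL,
                                                   model$feature_names)) else
    as.matrix(x)
  xc <- sweep(x, 2L, model$center)
  t_sc <- xc %*% model$loadings
  w <- t_sc %*% diag(1 / model$eigenvalues,
                     nrow = model$k) %*% t(model$loadings)
  contrib <- xc * w
  colnames(contrib) <- model$feature_names
  attr(contrib, "sd2") <- rowSums(contrib)
  contrib
}

#' @export
print.robpca <- function(x, ...) {
  cat(sprintf(paste0("<robpca> N = %d lots, p = %d features, k = %d ",
                     "components (%.1f%% of trimmed variance)\n"),
              x$n, x$p, x$k, 100 * x$explained_variance_fraction))
  cat(sprintf("  alpha = %.2f (h = %d), cutoff quantile = %.3f\n",
              x$alpha, x$h, x$quantile))
  cat(sprintf("  cutoffs: SD %.3f, OD %s\n", x$cutoffs[["sd_cut"]],
              if (is.na(x$cutoffs[["od_cut"]])) "n/a (full-rank model)" else
                sprintf("%.3f", x$cutoffs[["od_cut"]])))
  tab <- table(x$flag)
  cat("  lots:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.robpca <- function(object, ...) {
  structure(list(fit = object), class = "summary.robpca")
}

#' @export
print.summary.robpca <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nEigenvalues (robust component variances):\n")
  print(signif(f$eigenvalues, 4))
  cat("\nCumulative explained variance (trimmed spectrum):\n")
  print(round(utils::head(f$cum_variance, f$k + 2L), 4))
  out <- order(f$sd, decreasing = TRUE)[seq_len(min(5L, f$n))]
  cat("\nLargest score distances (lot index: SD):\n")
  cat(paste(sprintf("  %d: %.2f%s", out, f$sd[out],
                    ifelse(f$flag[out] != "regular", " *", "")),
            collapse = "\n"), "\n")
  invisible(x)
}

#' Predict method: distances and scores for new lots
#'
#' @param object A fitted [robpca()] model.
#' @param newdata Numeric matrix with `p` columns.
#' @param ... Unused.
#' @return Data frame with `sd`, `od`, `quadrant` and scores `t1..tk`.
#' @export
predict.robpca <- function(object, newdata, ...) {
  d <- distances(object, newdata)
  q <- classify_quadrant(d$sd, d$od, object$cutoffs)
  out <- data.frame(sd = d$sd, od = d$od, quadrant = q)
  sc <- d$scores
  colnames(sc) <- paste0("t", seq_len(ncol(sc)))
  cbind(out, sc)
}

#' Plot the score/orthogonal distance outlier map
#'
#' @param x A fitted [robpca()] model.
#' @param labels Optional lot labels for flagged lots.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.robpca <- function(x, labels = NULL, ...) {
  cuts <- x$cutoffs
  graphics::plot(x$sd, x$od, xlab = "Score distance",
                 ylab = "Orthogonal distance",
                 main = sprintf("Outlier map (k = %d, %.1f%% quantile)",
                                x$k, 100 * x$quantile), ...)
  graphics::abline(v = cuts[["sd_cut"]], lty = 2)
  if (!is.na(cuts[["od_cut"]])) graphics::abline(h = cuts[["od_cut"]],
                                                 lty = 2)
  flagged <- which(x$flag != "regular")
  if (length(flagged)) {
    lb <- if (is.null(labels)) flagged else labels[flagged]
    graphics::text(x$sd[flagged], x$od[flagged], lb, pos = 3, cex = 0.8)
  }
  invisible(x)
}

#' Classical PCA diagnostics: Hotelling T-squared and normalized DModX
#'
#' The non-robust counterpart used for comparison: classical PCA (mean
#' centering, SVD), Hotelling `T2_i = sum_k t_ik^2 / lambda_k` with the 95\%
#' F-distribution limit `k (N-1)(N+1) / (N (N-k)) * F_{0.95; k, N-k}`, and
#' the normalized distance-to-model `DModX_i` (the residual standard
#' deviation of lot `i` divided by the pooled residual standard deviation)
#' with its 95\% F-based limit. Because classical eigenvalues are inflated
#' by the very outliers one is looking for, gross lots can mask themselves
#' here -- which is the motivation for the robust fit.
#'
#' @param x Complete, column-scaled numeric matrix (N x p).
#' @param k Number of components, `k < min(N - 1, p)`.
#' @param limit_quantile Control-limit quantile (default 0.95).
#' @return An object of class `cpca_diagnostics`: data frame with `t2`,
#'   `dmodx`, flags, plus attributes `t2_limit`, `t2_median`, `dmodx_limit`,
#'   `k`.
#' @export
fit_cpca_diagnostics <- function(x, k, limit_quantile = 0.95) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (k >= min(n - 1L, p)) {
    stop("k must be smaller than min(N - 1, p)", call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  lam <- pc$sdev[seq_len(k)]^2
  t_sc <- pc$x[, seq_len(k), drop = FALSE]
  t2 <- rowSums(sweep(t_sc^2, 2L, lam, "/"))
  t2_limit <- k * (n - 1) * (n + 1) / (n * (n - k)) *
    stats::qf(limit_quantile, k, n - k)
  resid <- sweep(x, 2L, pc$center) -
    t_sc %*% t(pc$rotation[, seq_len(k), drop = FALSE])
  rss_i <- rowSums(resid^2)
  s0 <- sqrt(sum(rss_i) / ((n - k - 1) * (p - k)))
  degenerate <- s0 < 1e-8 * sqrt(mean(x^2) + 1)  # data lie in the subspace
  dmodx <- if (!degenerate) sqrt(rss_i / (p - k)) / s0 else rep(0, n)
  dmodx_limit <- sqrt(stats::qf(limit_quantile, p - k, (n - k - 1) * (p - k)))
  out <- data.frame(t2 = t2, dmodx = dmodx,
                    t2_outlier = t2 > t2_limit,
                    dmodx_outlier = !degenerate & dmodx > dmodx_limit)
  rownames(out) <- rownames(x)
  attr(out, "t2_limit") <- t2_limit
  attr(out, "t2_median") <- stats::median(t2)
  attr(out, "dmodx_limit") <- dmodx_limit
  attr(out, "k") <- k
  class(out) <- c("cpca_diagnostics", "data.frame")
  out
}
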