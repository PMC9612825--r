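#' SIMPLS partial least squares regression (single response)
#'
#' Fits PLSR by the SIMPLS deflation algorithm: X is autoscaled (centered,
#' unit variance), y centered; components are extracted so that successive
#' score vectors are orthogonal, and the loadings basis is deflated from the
#' cross-product vector. Zero-variance columns are dropped with a warning.
#'
#' @param X numeric matrix (conditions x predictors), e.g. a flux table with
#'   one column per reaction.
#' @param y numeric response vector (e.g. insulin-secretion fold-changes).
#' @param n_components number of latent components.
#' @return object of class `bg_plsr`: weights `R`, scores `T`, loadings `P`,
#'   y-loadings `q`, standardized coefficients `coef_std`, raw-scale
#'   coefficients `coef_raw` + `intercept`, scaling (`x_center`, `x_scale`,
#'   `y_center`), per-component explained y-variance, `fitted`, `r2`, `vip`.
#' @export
simpls_fit <- function(X, y, n_components = 3) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n_components <- as.integer(n_components)
  n <- nrow(X); p_all <- ncol(X)
  if (n < 2) stop("need at least 2 rows")
  if (n_components > min(n - 1, p_all))
    stop("n_components must be <= min(rows - 1, columns)")
  cn <- colnames(X) %||% paste0("x", seq_len(p_all))
  colnames(X) <- cn
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  keep <- scl > 0
  if (!all(keep))
    warning(sum(!keep), " zero-variance column(s) dropped: ",
            paste(utils::head(cn[!keep], 5), collapse = ", "))
  Xk <- X[, keep, drop = FALSE]
  p <- ncol(Xk)
  if (n_components > p) stop("n_components exceeds usable columns")
  X0 <- scale(Xk, center = ctr[keep], scale = scl[keep])
  ybar <- mean(y)
  y0 <- y - ybar

  S <- crossprod(X0, y0)
  R <- TT <- P <- V <- NULL
  q <- numeric(n_components)
  for (a in seq_len(n_components)) {
    r <- S
    t <- X0 %*% r
    normt <- sqrt(sum(t^2))
    if (normt < 1e-12 * max(1, sqrt(sum(X0^2))))
      stop("rank deficiency: no usable component ", a)
    t <- t / normt; r <- r / normt
    pa <- crossprod(X0, t)
    q[a] <- sum(y0 * t)
    v <- pa
    if (!is.null(V)) v <- v - V %*% crossprod(V, pa)
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R <- cbind(R, r); TT <- cbind(TT, t); P <- cbind(P, pa); V <- cbind(V, v)
  }
  coef_std <- R %*% q[seq_len(n_components)]
  fitted <- as.numeric(X0 %*% coef_std) + ybar
  r2 <- 1 - sum((y - fitted)^2) / sum((y - ybar)^2)
  # back to raw flux units
  coef_raw <- setNames(rep(0, p_all), cn)
  coef_raw[keep] <- coef_std / scl[keep]
  intercept <- ybar - sum(coef_raw[keep] * ctr[keep])
  ssy <- q^2  # scores are unit norm, so q_a^2 is the y-variance captured
  vip <- setNames(rep(NA_real_, p_all), cn)
  wnorm <- sweep(R, 2, sqrt(colSums(R^2)), "/")
  vip[keep] <- sqrt(p * as.numeric(wnorm^2 %*% ssy) / sum(ssy))
  rownames(coef_std) <- cn[keep]
  structure(list(n_components = n_components, R = R, scores = TT,
                 loadings = P, q = q, coef_std = coef_std,
                 coef_raw = coef_raw, intercept = intercept,
                 x_center = ctr, x_scale = scl, keep = keep,
                 y_center = ybar, ssy = ssy, fitted = fitted, r2 = r2,
                 vip = vip, columns = cn),
            class = "bg_plsr")
}

#' @export
print.bg_plsr <- function(x, ...) {
  cat("<bg_plsr> ", x$n_components, " components, ", sum(x$keep), "/",
      length(x$keep), " predictors, R2 = ", round(x$r2, 4), "\n", sep = "")
  invisible(x)
}

#' @export
predict.bg_plsr <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1,
                                         dimnames = list(NULL, names(newdata)))
       else as.matrix(newdata)
  if (ncol(X) != length(object$columns))
    stop("flux vector length ", ncol(X), " does not match the fitted table (",
         length(object$columns), " columns)")
  as.numeric(X %*% object$coef_raw) + object$intercept
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a SSY_a (w_ja/||w_a||)^2 / sum_a SSY_a)` where
#' `SSY_a` is the y-variance captured by component a. Columns with VIP above
#' 1 are conventionally called influential; the squared VIPs average to 1
#' over the fitted columns.
#'
#' @param fit a `bg_plsr`.
#' @return named numeric vector (dropped zero-variance columns are `NA`).
#' @export
vip_scores <- function(fit) fit$vip

#' Leave-one-out cross-validated Q2Y
#'
#' `Q2Y = 1 - PRESS / TSS` where `PRESS` sums squared leave-one-out
#' prediction errors (the fold model is refit with scaling re-estimated on
#' the retained rows) and `TSS` sums squared deviations of each held-out
#' observation from the mean of the retained responses.
#'
#' @inheritParams simpls_fit
#' @return scalar Q2Y (at most 1; can be negative).
#' @export
q2y_loo <- function(X, y, n_components = 3) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 rows for leave-one-out")
  if (n < n_components + 2)
    stop("need at least n_components + 2 rows for leave-one-out refits")
  press <- tss <- 0
  for (i in seq_len(n)) {
    f <- suppressWarnings(simpls_fit(X[-i, , drop = FALSE], y[-i], n_components))
    press <- press + (y[i] - predict(f, X[i, , drop = FALSE]))^2
    tss <- tss + (y[i] - mean(y[-i]))^2
  }
  1 - press / tss
}

#' Predict insulin secretion from a flux vector
#'
#' Applies a fitted PLSR model (or the arithmetic-mean prediction of an
#' ensemble of models, one per fitted kinetic parameter set) to a vector of
#' time-averaged reaction fluxes.
#'
#' @param fit a `bg_plsr` or a list of them (ensemble).
#' @param fluxes numeric vector/matrix in the fitted column order.
#' @return predicted insulin fold-change(s).
#' @export
predict_insulin <- function(fit, fluxes) {
  if (inherits(fit, "bg_plsr")) return(predict(fit, fluxes))
  preds <- vapply(fit, function(f) predict(f, fluxes), numeric(
    if (is.null(dim(fluxes))) 1L else nrow(fluxes)))
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

#' Per-minute flux table for a single time course
#'
#' Average flux of every reaction over each 1-minute interval `[m-1, m]` of
#' the trajectory, the input rows of the time-resolved PLSR.
#'
#' @param traj a `bg_trajectory` whose grid covers `0..duration` at 1-minute
#'   spacing.
#' @param duration minutes (rows of the result).
#' @return matrix (minute x reaction).
#' @export
per_minute_fluxes <- function(traj, duration) {
  out <- t(vapply(seq_len(duration), function(m)
    time_averaged_fluxes(traj, c(m - 1, m)), numeric(ncol(traj$flux))))
  rownames(out) <- seq_len(duration)
  out
}

#' Time-resolved PLSR within one stimulation time course
#'
#' Correlates per-minute reaction fluxes with insulin secreted per minute,
#' assuming the total insulin fold-change accrues linearly over the course:
#' the response at minute `m` is `1 + (FC_total - 1) * m / T`.
#'
#' @param flux_by_minute matrix (minute x reaction), e.g. from
#'   [per_minute_fluxes()].
#' @param fc_total total insulin-secretion fold-change over the course.
#' @param duration course length T in minutes (rows used).
#' @param n_components requested components; reduced with a warning when the
#'   course is too short.
#' @return list with `fit` (a `bg_plsr`), `response`, `duration`.
#' @export
timecourse_plsr <- function(flux_by_minute, fc_total, duration,
                            n_components = 3) {
  X <- as.matrix(flux_by_minute)[seq_len(duration), , drop = FALSE]
  y <- 1 + (fc_total - 1) * seq_len(duration) / duration
  max_comp <- duration - 1
  if (n_components > max_comp) {
    warning("course of ", duration, " minutes supports at most ", max_comp,
            " components; reducing")
    n_components <- max_comp
  }
  fit <- simpls_fit(X, y, n_components)
  list(fit = fit, response = y, duration = duration)
}
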