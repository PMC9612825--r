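# extended Fourier Amplitude Sensitivity Test (eFAST), Saltelli-style.
# Each factor in turn is driven by a high "search-curve" frequency while the
# complementary factors move at low frequencies; variance at the driver
# frequency (and harmonics) gives the first-order index, variance below the
# complementary band gives the total-order index.

#' Raw eFAST indices for a deterministic function on the unit hypercube
#'
#' @param fn function taking a numeric matrix (rows = evaluation points,
#'   columns = factors, entries in `[0, 1]`) and returning a numeric matrix
#'   of outputs (rows matching input rows) or a vector (single output).
#' @param n_factors number of factors.
#' @param samples points per search curve (must be at least `4 * M^2 + 1`).
#' @param M interference factor (harmonics summed for the first-order index).
#' @param resamples number of random-phase resample curves.
#' @param seed integer seed for the random phases.
#' @return list with matrices `first` and `total` (factor x output).
#' @export
efast_indices <- function(fn, n_factors, samples = 257, M = 4, resamples = 1,
                          seed = 1) {
  if (samples < 4 * M^2 + 1)
    stop("eFAST needs at least 4*M^2+1 = ", 4 * M^2 + 1,
         " samples per curve for interference factor M = ", M)
  set.seed(seed)
  omega_max <- floor((samples - 1) / (2 * M))  # driver frequency
  omega_comp_max <- max(1, floor(omega_max / (2 * M)))
  s <- pi * (2 * seq_len(samples) - samples - 1) / samples

  first <- total <- NULL
  for (i in seq_len(n_factors)) {
    omega <- rep(0, n_factors)
    omega[i] <- omega_max
    if (n_factors > 1) {
      others <- setdiff(seq_len(n_factors), i)
      omega[others] <- 1 + (seq_along(others) - 1) %% omega_comp_max
    }
    Si_sum <- STi_sum <- NULL
    for (r in seq_len(resamples)) {
      phi <- runif(n_factors, 0, 2 * pi)
      X <- vapply(seq_len(n_factors), function(l)
        0.5 + asin(sin(omega[l] * s + phi[l])) / pi, numeric(samples))
      Y <- fn(X)
      if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
      n_out <- ncol(Y)
      if (is.null(first)) {
        first <- matrix(NA_real_, n_factors, n_out)
        total <- matrix(NA_real_, n_factors, n_out)
        colnames(first) <- colnames(total) <- colnames(Y)
      }
      if (is.null(Si_sum)) Si_sum <- STi_sum <- numeric(n_out)
      # Fourier amplitudes on the closed curve
      wmax <- floor((samples - 1) / 2)
      co <- vapply(seq_len(wmax), function(w) cos(w * s), numeric(samples))
      si <- vapply(seq_len(wmax), function(w) sin(w * s), numeric(samples))
      for (k in seq_len(n_out)) {
        y <- Y[, k]
        A <- colMeans(y * co); B <- colMeans(y * si)
        lam <- 2 * (A^2 + B^2)
        V <- sum(lam)
        Vi <- sum(lam[omega_max * seq_len(M)], na.rm = TRUE)
        Vci <- sum(lam[seq_len(floor(omega_max / 2))])
        Si_sum[k] <- Si_sum[k] + if (V > 0) Vi / V else 0
        STi_sum[k] <- STi_sum[k] + if (V > 0) 1 - Vci / V else 0
      }
    }
    first[i, ] <- Si_sum / resamples
    total[i, ] <- STi_sum / resamples
  }
  list(first = first, total = total)
}

#' eFAST global sensitivity of model outputs to kinetic parameters
#'
#' Varies each chosen parameter over `range_decades` orders of magnitude above
#' and below its current value (log-uniform search curves) and computes
#' total-order (and first-order) sensitivity indices of each output. A
#' parameter is selected as influential when its maximal total-order index
#' across outputs exceeds `threshold`.
#'
#' @param model a `bg_model`.
#' @param params a `bg_params`; baseline values.
#' @param outputs function `function(bg_params) -> named numeric vector` of
#'   model observables (e.g. metabolite fold-changes under the training
#'   protocols; see [training_observables()]).
#' @param parameters names of the parameters to vary (default: the model's
#'   free Vmax parameters).
#' @param range_decades half-range in decades (2 = two orders of magnitude
#'   above and below baseline).
#' @param threshold selection cut on the maximal total-order index.
#' @param samples,M,resamples,seed eFAST sampling configuration (see
#'   [efast_indices()]).
#' @return object of class `bg_sensitivity`: list with `indices` (total-order,
#'   parameter x output), `first_order`, `selection` (influential parameter
#'   names), `threshold`.
#' @export
efast_sensitivity <- function(model, params = model$params, outputs,
                              parameters = vmax_names(model),
                              range_decades = 2, threshold = 0.85,
                              samples = 65, M = 4, resamples = 1, seed = 1) {
  base <- params$values[parameters]
  if (any(base <= 0)) stop("eFAST log-range needs positive baseline values")
  fn <- function(X) {
    out <- NULL
    for (r in seq_len(nrow(X))) {
      vals <- base * 10^((X[r, ] - 0.5) * 2 * range_decades)
      p <- params
      p$values[parameters] <- vals
      p$lower[parameters] <- -Inf; p$upper[parameters] <- Inf
      y <- outputs(p)
      if (is.null(out)) out <- matrix(NA_real_, nrow(X), length(y),
                                      dimnames = list(NULL, names(y)))
      out[r, ] <- y
    }
    out
  }
  res <- efast_indices(fn, length(parameters), samples = samples, M = M,
                       resamples = resamples, seed = seed)
  rownames(res$first) <- rownames(res$total) <- parameters
  sel <- parameters[apply(res$total, 1, max, na.rm = TRUE) > threshold]
  structure(list(indices = res$total, first_order = res$first,
                 selection = sel, threshold = threshold),
            class = "bg_sensitivity")
}

#' @export
print.bg_sensitivity <- function(x, ...) {
  cat("<bg_sensitivity> ", nrow(x$indices), " parameters x ",
      ncol(x$indices), " outputs; ", length(x$selection),
      " influential (max total-order index > ", x$threshold, ")\n", sep = "")
  invisible(x)
}
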