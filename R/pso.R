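#' Particle swarm minimization
#'
#' Global-best particle swarm optimizer with inertia and
#' cognitive/social acceleration, used to minimize the weighted
#' sum-of-squared-residuals objective during model fitting. Positions are
#' searched in the (possibly log-transformed) box `[lower, upper]`; particles
#' that leave the box are reflected onto the boundary with their velocity
#' component zeroed. Objective failures (non-finite values) are penalized with
#' a large finite value so the swarm continues.
#'
#' @param fn objective `function(x) -> scalar` (minimized).
#' @param lower,upper numeric bounds.
#' @param swarm_size number of particles.
#' @param iterations number of update steps.
#' @param inertia inertia weight; a length-2 vector gives a linear schedule
#'   from the first to the second value over the iterations (the default
#'   0.9 -> 0.4 is the standard time-varying-inertia variant, which converges
#'   much better in curved valleys at fixed iteration budgets).
#' @param cognitive,social acceleration coefficients.
#' @param log_space optimize on log10 scale (bounds must be positive).
#' @param init optional starting point included as one initial particle (the
#'   fitting workflow seeds the swarm with the nominal parameter estimate).
#' @param rescatter_after iterations of global-best stagnation after which
#'   the worse half of the swarm is re-seeded tightly around the best point
#'   (partial restart; set to `Inf` to disable).
#' @param seed integer seed.
#' @param trace keep the best-so-far objective value per iteration.
#' @return list with `par`, `value`, `trace` (best-so-far values), `evals`.
#' @export
pso_minimize <- function(fn, lower, upper, swarm_size = 50, iterations = 2000,
                         inertia = c(0.9, 0.4), cognitive = 1.49,
                         social = 1.49, log_space = TRUE, init = NULL,
                         rescatter_after = 40, seed = 1, trace = TRUE) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  if (log_space && any(lower <= 0)) stop("log-space search needs positive bounds")
  d <- length(lower)
  tf <- if (log_space) log10 else identity
  itf <- if (log_space) function(x) 10^x else identity
  lo <- tf(lower); hi <- tf(upper)
  set.seed(seed)
  X <- matrix(runif(swarm_size * d, rep(lo, each = swarm_size),
                    rep(hi, each = swarm_size)), swarm_size, d)
  if (!is.null(init)) X[1, ] <- pmin(pmax(tf(init), lo), hi)
  V <- matrix(runif(swarm_size * d, -1, 1), swarm_size, d) *
    matrix(rep((hi - lo) / 10, each = swarm_size), swarm_size, d)
  evalx <- function(x) {
    v <- tryCatch(fn(itf(x)), error = function(e) Inf)
    if (!is.finite(v)) 1e12 else v
  }
  P <- X
  pbest <- apply(X, 1, evalx)
  g <- which.min(pbest)
  gx <- X[g, ]; gv <- pbest[g]
  tr <- if (trace) numeric(iterations) else NULL
  evals <- swarm_size
  stall <- 0L
  w_sched <- if (length(inertia) == 2)
    seq(inertia[1], inertia[2], length.out = iterations) else
    rep(inertia[1], iterations)
  for (it in seq_len(iterations)) {
    r1 <- matrix(runif(swarm_size * d), swarm_size, d)
    r2 <- matrix(runif(swarm_size * d), swarm_size, d)
    V <- w_sched[it] * V + cognitive * r1 * (P - X) +
      social * r2 * matrix(gx, swarm_size, d, byrow = TRUE) - social * r2 * X
    X <- X + V
    for (j in seq_len(d)) {
      lowh <- X[, j] < lo[j]; high <- X[, j] > hi[j]
      X[lowh, j] <- lo[j]; X[high, j] <- hi[j]
      V[lowh | high, j] <- 0
    }
    val <- apply(X, 1, evalx)
    evals <- evals + swarm_size
    imp <- val < pbest
    P[imp, ] <- X[imp, , drop = FALSE]
    pbest[imp] <- val[imp]
    g <- which.min(pbest)
    if (pbest[g] < gv * (1 - 1e-10)) {
      gv <- pbest[g]; gx <- P[g, ]; stall <- 0L
    } else stall <- stall + 1L
    if (trace) tr[it] <- gv
    # stagnation rescatter: when the global best has not moved for a while,
    # re-seed the worse half of the swarm tightly around it to exploit the
    # local valley (partial-restart PSO variant)
    if (stall >= rescatter_after && it < iterations - 10) {
      worst <- order(pbest, decreasing = TRUE)[seq_len(swarm_size %/% 2)]
      for (i in worst) {
        X[i, ] <- pmin(pmax(gx + rnorm(d, 0, (hi - lo) / 40), lo), hi)
        V[i, ] <- rnorm(d, 0, (hi - lo) / 80)
        P[i, ] <- X[i, ]
        pbest[i] <- evalx(X[i, ])
        evals <- evals + 1
      }
      stall <- 0L
    }
  }
  list(par = itf(gx), value = gv, trace = tr, evals = evals)
}
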