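# Exact integer/rational linear algebra for conserved-moiety analysis.
# Stoichiometric entries are small integers, so doubles hold every
# intermediate exactly (fraction-free elimination keeps them integral).

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { t <- b; b <- a %% b; a <- t }
  a
}
gcd_vec <- function(v) Reduce(gcd2, abs(v[v != 0]), accumulate = FALSE)

# fraction-free Gaussian elimination to row echelon form; returns the echelon
# matrix (integer entries) and the pivot column of each nonzero row
ff_echelon <- function(A) {
  A <- round(A)
  m <- nrow(A); n <- ncol(A)
  piv_cols <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    sel <- which(abs(A[row:m, col]) > 0.5) + row - 1L
    if (!length(sel)) next
    # smallest nonzero pivot keeps entries small
    p <- sel[which.min(abs(A[sel, col]))]
    if (p != row) A[c(row, p), ] <- A[c(p, row), ]
    for (r in seq_len(m)) {
      if (r == row || abs(A[r, col]) < 0.5) next
      A[r, ] <- A[row, col] * A[r, ] - A[r, col] * A[row, ]
      g <- gcd_vec(A[r, ])
      if (!is.null(g) && length(g) && g > 1.5) A[r, ] <- A[r, ] / g
    }
    piv_cols <- c(piv_cols, col)
    row <- row + 1L
  }
  list(E = A, piv = piv_cols)
}

# exact null-space basis of an integer matrix, columns normalized to smallest
# integers with positive leading coefficient
rational_nullspace <- function(A) {
  A <- as.matrix(A)
  n <- ncol(A)
  ech <- ff_echelon(A)
  E <- ech$E; piv <- ech$piv
  free <- setdiff(seq_len(n), piv)
  if (!length(free))
    return(matrix(0, nrow = n, ncol = 0))
  basis <- matrix(0, nrow = n, ncol = length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    num <- rep(0, n); den <- rep(1, n)
    num[f] <- 1
    for (i in rev(seq_along(piv))) {
      p <- piv[i]
      # s = sum_{j > p} E[i, j] * x_j   as an exact fraction
      sn <- 0; sd <- 1
      for (j in seq_len(n)[-seq_len(p)]) {
        if (abs(E[i, j]) < 0.5 || num[j] == 0) next
        tn <- E[i, j] * num[j]; td <- den[j]
        sn <- sn * td + tn * sd
        sd <- sd * td
        g <- gcd2(sn, sd); if (g > 1.5) { sn <- sn / g; sd <- sd / g }
      }
      if (sn != 0) {
        num[p] <- -sn; den[p] <- sd * E[i, p]
        g <- gcd2(num[p], den[p]); if (g > 1.5) { num[p] <- num[p] / g; den[p] <- den[p] / g }
        if (den[p] < 0) { num[p] <- -num[p]; den[p] <- -den[p] }
      }
    }
    # clear denominators, reduce to smallest integers
    L <- Reduce(function(a, b) a / gcd2(a, b) * b, den[num != 0], accumulate = FALSE)
    x <- num * (L / den)
    g <- gcd_vec(x)
    if (!is.null(g) && length(g) && g > 0.5) x <- x / g
    lead <- x[which(x != 0)[1]]
    if (lead < 0) x <- -x
    basis[, k] <- x
  }
  basis
}

#' Conserved moieties of a network
#'
#' Computes an integer-normalized basis of the left null space of the
#' stoichiometric matrix by exact (fraction-free rational) elimination. Each
#' basis vector is a conservation relation: the amount-weighted total
#' `sum_i coef_i * volume_i * C_i` is constant along every trajectory.
#'
#' @param model a `bg_model`.
#' @return list of relations, each with `coefficients` (named integer vector
#'   over the members), `members`, and `total` (the amount-weighted conserved
#'   value in mM at the model's initial concentrations; `NA` if initials are
#'   unset). Empty list if `S` has full row rank.
#' @examples
#' m <- build_network(betacell_definition())
#' rel <- conserved_moieties(m)
#' sapply(rel, function(r) paste(r$members, collapse = "+"))
#' @export
conserved_moieties <- function(model) {
  B <- rational_nullspace(t(model$S))
  dyn <- rownames(model$S)
  vols <- compartment_volumes(model)[model$species$compartment[match(dyn, model$species$id)]]
  init <- model$species$initial[match(dyn, model$species$id)]
  out <- vector("list", ncol(B))
  for (k in seq_len(ncol(B))) {
    coef <- B[, k]
    members <- dyn[coef != 0]
    total <- if (all(!is.na(init[coef != 0])))
      sum(coef * vols * init, na.rm = TRUE) else NA_real_
    out[[k]] <- list(coefficients = setNames(coef[coef != 0], members),
                     members = members, total = total)
  }
  out
}

compartment_volumes <- function(model) {
  setNames(model$compartments$relative_volume, model$compartments$id)
}

#' Amount-weighted conserved totals along a trajectory
#'
#' @param model a `bg_model`.
#' @param traj a `bg_trajectory` from [simulate()].
#' @param relations output of [conserved_moieties()] (recomputed if missing).
#' @return matrix (time x relation) of totals.
#' @export
conservation_totals <- function(model, traj, relations = conserved_moieties(model)) {
  dyn <- rownames(model$S)
  vols <- compartment_volumes(model)[model$species$compartment[match(dyn, model$species$id)]]
  W <- vapply(relations, function(r) {
    w <- setNames(rep(0, length(dyn)), dyn)
    w[r$members] <- r$coefficients
    w * vols
  }, numeric(length(dyn)))
  totals <- traj$conc[, dyn, drop = FALSE] %*% W
  colnames(totals) <- vapply(relations, function(r)
    paste(r$members, collapse = "+"), character(1))
  totals
}

#' Structural mass-balance report
#'
#' Lists the model's source/sink reactions (those touching the exchange
#' compartment, i.e. exchanging material with the extracellular protocol
#' state) and flags dynamic species lacking a producing or consuming path.
#' Reversible reactions count in both directions.
#'
#' @param model a `bg_model`.
#' @return a list of class `bg_massbalance` with `sources_sinks`, `flagged`
#'   (data.frame of species and issue) and `balanced` (TRUE when nothing is
#'   flagged).
#' @export
validate_mass_balance <- function(model) {
  ex_comp <- model$compartments$id[model$compartments$exchange]
  ex_species <- model$species$id[model$species$compartment %in% ex_comp]
  srcs <- names(Filter(function(r)
    any(c(names(r$substrates), names(r$products)) %in% ex_species),
    model$reactions))

  rev <- vapply(model$reactions, function(r)
    isTRUE(TEMPLATES[[r$template]]$rev) ||
      (r$template == "mass_action" && !is.na(r$params$vr)), logical(1))
  S <- model$S
  flagged <- data.frame(species = character(0), issue = character(0))
  for (i in seq_len(nrow(S))) {
    row <- S[i, ]
    prod <- any(row > 0) || any(row < 0 & rev)
    cons <- any(row < 0) || any(row > 0 & rev)
    if (all(row == 0))
      flagged <- rbind(flagged, data.frame(species = rownames(S)[i],
                                           issue = "orphan (no reactions)"))
    else if (!prod)
      flagged <- rbind(flagged, data.frame(species = rownames(S)[i],
                                           issue = "no producing path"))
    else if (!cons)
      flagged <- rbind(flagged, data.frame(species = rownames(S)[i],
                                           issue = "no consuming path"))
  }
  structure(list(sources_sinks = srcs, flagged = flagged,
                 balanced = nrow(flagged) == 0),
            class = "bg_massbalance")
}

#' @export
print.bg_massbalance <- function(x, ...) {
  cat("sources/sinks:", paste(x$sources_sinks, collapse = ", "), "\n")
  if (x$balanced) cat("all dynamic species have producing and consuming paths\n")
  else { cat("flagged species:\n"); print(x$flagged) }
  invisible(x)
}
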