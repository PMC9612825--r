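# shared fixtures and independent oracles

# minimal raw definition list (no builder involvement) for structural tests
toy_definition <- function(reactions, species, parameters,
                           compartments = list(
                             list(id = "c", name = "cytosol",
                                  relative_volume = 1, exchange = FALSE))) {
  list(name = "toy", compartments = compartments, species = species,
       reactions = reactions, parameters = parameters)
}

toy_species <- function(id, comp = "c", initial = 1, boundary = FALSE,
                        pathway = "other") {
  list(id = id, name = id, compartment = comp,
       initial_concentration = initial, boundary = boundary,
       pathway = pathway)
}

toy_param <- function(name, value, kind = "misc") {
  list(name = name, value = value, kind = kind)
}

# A -> B mass action, one compartment
chain_definition <- function(k = 0.3, a0 = 2, b0 = 0) {
  toy_definition(
    reactions = list(list(
      id = "r1", template = "mass_action", pathway = "other",
      substrates = list(A = 1), products = list(B = 1),
      params = list(vf = "k1", km_sub = list(), km_prod = list()))),
    species = list(toy_species("A", initial = a0), toy_species("B", initial = b0)),
    parameters = list(toy_param("k1", k, "Vmax")))
}

# reversible A <-> B (Haldane MM), closed system
rev_ab_definition <- function(vf = 2, vr = 1, kma = 0.5, kmb = 0.5,
                              a0 = 1, b0 = 1) {
  toy_definition(
    reactions = list(list(
      id = "rab", template = "reversible_uni_uni_haldane", pathway = "other",
      substrates = list(A = 1), products = list(B = 1),
      params = list(vf = "Vf_rab", vr = "Vr_rab", keq = "Keq_rab",
                    km_sub = list("Km_rab_A"), km_prod = list("Km_rab_B")))),
    species = list(toy_species("A", initial = a0), toy_species("B", initial = b0)),
    parameters = list(toy_param("Vf_rab", vf, "Vmax"),
                      toy_param("Vr_rab", vr, "Vmax"),
                      toy_param("Keq_rab", vf / vr, "Keq"),
                      toy_param("Km_rab_A", kma, "Km"),
                      toy_param("Km_rab_B", kmb, "Km")))
}

# SVD-based null space oracle (numeric, tolerance-based)
svd_left_null <- function(S, tol = 1e-9) {
  sv <- svd(t(S), nv = nrow(S))
  rk <- sum(sv$d > tol * max(sv$d, 1))
  if (rk == nrow(S)) return(matrix(0, nrow(S), 0))
  sv$v[, (rk + 1):nrow(S), drop = FALSE]
}

# do the column spans of two bases agree (projection residuals ~ 0)?
same_span <- function(A, B, tol = 1e-9) {
  if (ncol(A) != ncol(B)) return(FALSE)
  if (ncol(A) == 0) return(TRUE)
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  r1 <- max(abs(B - qa %*% crossprod(qa, B)))
  r2 <- max(abs(A - qb %*% crossprod(qb, A)))
  r1 < tol && r2 < tol
}

# NIPALS PLS1 oracle: for a single response, component-by-component deflation
# of X; coefficients on the raw scale. Independent of the SIMPLS code path.
nipals_pls1 <- function(X, y, n_components) {
  X <- as.matrix(X)
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  keep <- scl > 0
  X0 <- scale(X[, keep, drop = FALSE], ctr[keep], scl[keep])
  ybar <- mean(y); y0 <- y - ybar
  E <- X0; f <- y0
  W <- P <- NULL; q <- numeric(n_components); TT <- NULL
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f); w <- w / sqrt(sum(w^2))
    t <- E %*% w
    p <- crossprod(E, t) / sum(t^2)
    qa <- sum(f * t) / sum(t^2)
    E <- E - t %*% t(p)
    f <- f - qa * t
    W <- cbind(W, w); P <- cbind(P, p); q[a] <- qa; TT <- cbind(TT, t)
  }
  Wstar <- W %*% solve(crossprod(P, W))
  bstd <- Wstar %*% q
  b <- setNames(rep(0, ncol(X)), colnames(X))
  b[keep] <- bstd / scl[keep]
  list(coef_raw = b, intercept = ybar - sum(b[keep] * ctr[keep]))
}

# Welch two-sample t from summary statistics
welch_t <- function(m1, s1, n1, m2, s2, n2) {
  se2 <- s1^2 / n1 + s2^2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (s1^4 / (n1^2 * (n1 - 1)) + s2^4 / (n2^2 * (n2 - 1)))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# a fake trajectory object for observable-level tests
fake_traj <- function(times, conc, flux = NULL) {
  structure(list(times = times, conc = conc,
                 flux = flux %||% matrix(0, length(times), 1,
                                         dimnames = list(NULL, "r1")),
                 nclamp = 0L, failed = FALSE),
            class = "bg_trajectory")
}
`%||%` <- function(a, b) if (is.null(a)) b else a
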