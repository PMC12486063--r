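# Shared fixtures: random influence toys, planted-feasible constraint
# systems, and independent numerical oracles. Everything is generated in
# code under a caller-supplied seed.

# random two-component influence toy on a tiny grid; numerator = LET * dose
# elementwise so the additive-numerator structure holds by construction
random_influence <- function(seed, n_vox = 50, n_beam = 10, density = 0.4) {
  set.seed(seed)
  dims <- c(n_vox, 1L, 1L)
  grid <- voxel_grid(dims, spacing = c(3, 3, 3))
  nz <- matrix(stats::runif(n_vox * n_beam) < density, n_vox, n_beam)
  # keep every column nonzero
  for (j in which(colSums(nz) == 0)) nz[sample.int(n_vox, 1), j] <- TRUE
  D <- matrix(0, n_vox, n_beam)
  D[nz] <- stats::runif(sum(nz), 0.1, 1)
  LET <- matrix(stats::runif(n_vox * n_beam, 2, 10), n_vox, n_beam)
  N <- LET * D
  influence_matrix(Matrix::Matrix(D, sparse = TRUE),
                   Matrix::Matrix(N, sparse = TRUE), grid)
}

# planted-feasible toy: a positive fluence x_star strictly satisfies every
# interval (margin on both sides); references are the planted forward values
planted_toy <- function(seed, n_vox = 50, n_beam = 10, margin = 0.5,
                        n_dose = 30, n_cdl = 15, c = cdl_constant()) {
  infl <- random_influence(seed, n_vox, n_beam)
  set.seed(seed + 1000L)
  x_star <- stats::runif(n_beam, 0.5, 2)
  vox_dose <- sample.int(n_vox, n_dose)
  vox_cdl <- sample(setdiff(seq_len(n_vox), vox_dose), n_cdl)
  yd <- as.numeric(infl$dose %*% x_star)[vox_dose]
  yc <- c * as.numeric(infl$letd_numerator %*% x_star)[vox_cdl]
  cset <- constraint_set(data.frame(
    voxel = c(vox_dose, vox_cdl),
    structure = rep(c("PTV", "OAR"), c(n_dose, n_cdl)),
    space = rep(c("dose", "cdl"), c(n_dose, n_cdl)),
    lower = c(pmax(0, yd - margin), rep(0, n_cdl)),
    upper = c(yd + margin, yc + margin),
    weight = rep(c(10, 1), c(n_dose, n_cdl)),
    ref = c(yd, yc)))
  x0 <- stats::runif(n_beam, 0, 3)
  list(infl = infl, x_star = x_star, x0 = x0, cset = cset,
       sys = constraint_system(infl, cset, c = c))
}

# independent slab-projection oracle: enumerate the KKT cases of
#   min ||y - x||^2  s.t.  L <= <a, y> <= U
# (unconstrained, lower bound active, upper bound active), solving each
# equality-constrained least-squares problem with a dense KKT linear solve,
# then keep the feasible candidate with the smallest objective
project_oracle <- function(x, a, L, U, tol = 1e-9) {
  n <- length(x)
  cands <- list()
  t0 <- sum(a * x)
  if (t0 >= L - tol && t0 <= U + tol) cands[[length(cands) + 1L]] <- x
  for (b in c(L, U)) {
    K <- rbind(cbind(2 * diag(n), a), c(a, 0))
    sol <- tryCatch(solve(K, c(2 * x, b)), error = function(e) NULL)
    if (!is.null(sol)) {
      y <- sol[seq_len(n)]
      t <- sum(a * y)
      if (t >= L - tol && t <= U + tol) cands[[length(cands) + 1L]] <- y
    }
  }
  obj <- vapply(cands, function(y) sum((y - x)^2), numeric(1))
  cands[[which.min(obj)]] - x
}

# small helper: dense forward products for cross-checking sparse ops
dense_forward <- function(infl, x) as.numeric(as.matrix(infl$dose) %*% x)

# step-convention percentile by explicit counting over candidate values
percentile_oracle <- function(values, fraction) {
  cand <- sort(unique(values))
  ok <- vapply(cand, function(v) mean(values >= v) >= fraction, logical(1))
  max(cand[ok])
}

# tiny deterministic phantom + plan for pipeline-level tests (fast)
tiny_case <- function(dims = c(14, 14, 14), spacing = 3) {
  cfg <- default_config()
  cfg$phantom$dims <- as.integer(dims)
  cfg$phantom$spacing <- spacing
  cfg$phantom$target_radius <- 12
  cfg$phantom$oar_radius <- 4.5
  cfg$plan$spot_spacing_mm <- 9
  cfg$plan$layer_spacing_mm <- 9
  synthetic_case(cfg)
}
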