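#' AMS feasibility-seeking parameters
#'
#' @param lambda relaxation parameter, constrained to 0 < lambda <= 2
#' @param max_iterations iteration budget (default 200)
#' @param tol residual tolerance (Gy): the run stops early once the weighted
#'   violation residual falls below it
#' @param normalize how projection weights are normalised: `"violated"`
#'   (default) divides by the weight sum over the currently violated rows,
#'   `"all"` by the sum over every row. Both keep the simultaneous step a
#'   convex combination of relaxed row projections — hence Fejér monotone
#'   for lambda <= 2 — but "all" shrinks the effective step as the violated
#'   set thins out and converges much more slowly in the tail
#' @return an object of class `ams_params`
#' @export
ams_params <- function(lambda = 1, max_iterations = 200, tol = 1e-6,
                       normalize = c("violated", "all")) {
  if (!is.finite(lambda) || lambda <= 0 || lambda > 2)
    stop("relaxation parameter lambda must satisfy 0 < lambda <= 2")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (tol < 0) stop("tol must be >= 0")
  structure(list(lambda = lambda, max_iterations = as.integer(max_iterations),
                 tol = tol, normalize = match.arg(normalize)),
            class = "ams_params")
}

#' Superiorization parameters
#'
#' @param alpha step-size base for the bounded perturbations, 0 < alpha < 1;
#'   the perturbation step is beta = alpha^s with s incremented at every
#'   trial, so the total perturbation length is summable
#' @param eta per-iteration decay factor of the objective weights,
#'   0 < eta < 1 (after k iterations the weights carry eta^k)
#' @param n_perturb negative-gradient perturbation steps per outer iteration
#' @param decay which objective weights eta decays: "objective" (both target
#'   and OAR sums, the default) or "oar-only"
#' @return an object of class `sup_params`
#' @export
sup_params <- function(alpha = 0.99, eta = 0.99, n_perturb = 1,
                       decay = c("objective", "oar-only")) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must satisfy 0 < alpha < 1")
  if (!is.finite(eta) || eta <= 0 || eta >= 1)
    stop("eta must satisfy 0 < eta < 1")
  if (n_perturb < 1) stop("n_perturb must be >= 1")
  structure(list(alpha = alpha, eta = eta, n_perturb = as.integer(n_perturb),
                 decay = match.arg(decay)),
            class = "sup_params")
}

#' Assemble the linear constraint system for the projection solver
#'
#' Stacks one sparse row per constraint: the dose influence row for
#' dose-space (target) constraints and c times the LET_d-numerator row for
#' cDL-space (OAR) constraints, with the interval bounds, weights and
#' reference values aligned. Rows whose influence row is entirely zero
#' cannot be acted on by a projection; they are kept but flagged inactive
#' (with a warning when their interval excludes 0, i.e. they are infeasible
#' for every fluence).
#'
#' @param infl an [influence_matrix()]
#' @param cset a [constraint_set()]
#' @param c cDL scaling constant (um/keV)
#' @return an object of class `constraint_system`: list with the stacked
#'   sparse matrix `A`, bounds `L`/`U`, weights `w`, references `ref`,
#'   squared row norms `row_norm2`, and bookkeeping columns
#' @export
constraint_system <- function(infl, cset, c = cdl_constant()) {
  if (nrow(cset) == 0) stop("no constraints")
  is_dose <- cset$space == "dose"
  parts <- list()
  if (any(is_dose))
    parts$dose <- infl$dose[cset$voxel[is_dose], , drop = FALSE]
  if (any(!is_dose))
    parts$cdl <- c * infl$letd_numerator[cset$voxel[!is_dose], , drop = FALSE]
  A <- do.call(rbind, parts)
  ord <- c(which(is_dose), which(!is_dose))
  L <- cset$lower[ord]; U <- cset$upper[ord]
  w <- cset$weight[ord]; ref <- cset$ref[ord]
  rn2 <- Matrix::rowSums(A^2)
  dead <- rn2 == 0
  if (any(dead & (L > 0 | U < 0)))
    warning(sprintf(
      "%d constraint rows have an all-zero influence row and an interval excluding 0; they are unreachable and ignored by the projections",
      sum(dead & (L > 0 | U < 0))))
  structure(list(A = A, L = L, U = U, w = w, ref = ref, row_norm2 = rn2,
                 space = cset$space[ord], structure = cset$structure[ord],
                 voxel = cset$voxel[ord], c = c),
            class = "constraint_system")
}

#' @export
print.constraint_system <- function(x, ...) {
  cat(sprintf("<constraint_system> %d rows (%d dose, %d cDL) x %d beamlets\n",
              nrow(x$A), sum(x$space == "dose"), sum(x$space == "cdl"),
              ncol(x$A)))
  invisible(x)
}

#' Euclidean projection displacement onto one interval constraint
#'
#' For the slab `L <= <a, x> <= U`, returns the displacement d with x + d
#' the Euclidean projection of x onto the slab: zero when x is inside,
#' otherwise `((U - <a,x>) / ||a||^2) a` (bound above) or the symmetric
#' expression for the lower bound, landing exactly on the violated boundary.
#'
#' @param x current point
#' @param a constraint row (numeric or 1-row sparse matrix), not all zero
#' @param L,U interval bounds, L <= U
#' @return displacement vector of the same length as x
#' @export
project_interval_row <- function(x, a, L, U) {
  a <- as.numeric(a)
  n2 <- sum(a^2)
  if (n2 == 0) stop("empty constraint row: ||a|| = 0")
  if (L > U) stop("L must not exceed U")
  t <- sum(a * x)
  if (t > U) ((U - t) / n2) * a
  else if (t < L) ((L - t) / n2) * a
  else numeric(length(x))
}

# weighted violation residual and per-row displacement scalars
system_residual <- function(sys, y, normalize = TRUE) {
  viol <- pmax(y - sys$U, 0) + pmax(sys$L - y, 0)
  wn <- if (normalize) sys$w / sum(sys$w) else sys$w
  sqrt(sum(wn * viol^2))
}

#' One simultaneous AMS projection sweep
#'
#' Computes all row residuals at once and takes the relaxed, weighted
#' simultaneous step `x <- clamp+( x + lambda * sum_i w~_i d_i )`, where the
#' sum runs over violated rows, `d_i` is the interval projection
#' displacement of row i, `w~` are the normalised weights and `clamp+` is
#' the elementwise projection onto the nonnegative orthant (fluences are
#' physical). Since each `x + lambda d_i` is a relaxed slab projection and
#' the weights form a convex combination, the unclamped step is Fejér
#' monotone with respect to the feasible intersection for 0 < lambda < 2
#' under either normalisation; the orthant clamp preserves this for any
#' feasible point with x >= 0.
#'
#' @param x current fluence vector (>= 0)
#' @param sys a [constraint_system()]
#' @param lambda relaxation parameter in (0, 2]
#' @param normalize `"violated"` (default) or `"all"`, see [ams_params()]
#' @return the updated fluence vector, with attributes `residual` (weighted
#'   violation residual before the step) and `n_violated`
#' @export
ams_iteration <- function(x, sys, lambda = 1,
                          normalize = c("violated", "all")) {
  normalize <- match.arg(normalize)
  if (lambda <= 0 || lambda > 2) stop("0 < lambda <= 2 required")
  y <- as.numeric(sys$A %*% x)
  if (any(!is.finite(y))) stop("non-finite forward product in AMS iteration")
  over <- y > sys$U & sys$row_norm2 > 0
  under <- y < sys$L & sys$row_norm2 > 0
  tvec <- numeric(length(y))
  tvec[over] <- (sys$U[over] - y[over]) / sys$row_norm2[over]
  tvec[under] <- (sys$L[under] - y[under]) / sys$row_norm2[under]
  wn <- if (normalize == "all") sys$w / sum(sys$w) else {
    v <- over | under
    if (any(v)) sys$w / sum(sys$w[v]) else sys$w
  }
  step <- lambda * as.numeric(Matrix::crossprod(sys$A, wn * tvec))
  out <- pmax(0, x + step)
  attr(out, "residual") <- system_residual(sys, y)
  attr(out, "n_violated") <- sum(over | under)
  out
}

#' Run the AMS feasibility-seeking iteration to convergence or budget
#'
#' Iterates [ams_iteration()] from `x0` until the weighted violation
#' residual drops below `params$tol` or `params$max_iterations` sweeps have
#' run. A starting point that is already feasible is returned unchanged.
#'
#' @param x0 starting fluence (>= 0)
#' @param sys a [constraint_system()]
#' @param params an [ams_params()]
#' @return list with `x` (final fluence), `iterations` (sweeps performed),
#'   `residual` (final weighted residual), `converged`, and `trace` — a data
#'   frame with per-iteration `residual`, `chi2` and `n_violated`
#' @export
feasibility_seek <- function(x0, sys, params = ams_params()) {
  x <- as.numeric(x0)
  if (any(x < 0)) stop("x0 must be >= 0")
  if (length(x) != ncol(sys$A)) stop("x0 length does not match beamlets")
  res <- system_residual(sys, as.numeric(sys$A %*% x))
  rows <- vector("list", params$max_iterations + 1L)
  rows[[1]] <- data.frame(iteration = 0L, residual = res,
                          chi2 = objective_chi2(x, sys), n_violated = NA_integer_)
  k <- 0L
  while (res >= params$tol && k < params$max_iterations) {
    k <- k + 1L
    x_new <- ams_iteration(x, sys, params$lambda, params$normalize)
    if (any(!is.finite(x_new)))
      stop(sprintf("non-finite fluence at iteration %d", k))
    nv <- attr(x_new, "n_violated")
    x <- as.numeric(x_new)
    res <- system_residual(sys, as.numeric(sys$A %*% x))
    rows[[k + 1L]] <- data.frame(iteration = k, residual = res,
                                 chi2 = objective_chi2(x, sys),
                                 n_violated = nv)
  }
  list(x = x, iterations = k, residual = res,
       converged = res < params$tol,
       trace = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
}

#' Weighted least-squares objective over the constraint references
#'
#' `chi2(x) = sum_target w_i (Dref_i - D(x)_i)^2 + sum_OAR w_i (cDLref_i -
#' cDL(x)_i)^2`: the squared weighted distance of the forward-calculated
#' dose (target rows) and cDL (OAR rows) from their reference values. This
#' is the objective the superiorization perturbations reduce; it is zero
#' iff every reference is met exactly.
#'
#' @param x fluence vector
#' @param sys a [constraint_system()] carrying reference values
#' @param weights optional weight vector overriding `sys$w` (used
#'   internally for the eta-decayed weights)
#' @return scalar chi-squared value
#' @export
objective_chi2 <- function(x, sys, weights = NULL) {
  if (any(is.na(sys$ref))) stop("constraint rows lack reference values")
  w <- if (is.null(weights)) sys$w else weights
  y <- as.numeric(sys$A %*% x)
  sum(w * (sys$ref - y)^2)
}

#' Gradient of the chi-squared objective
#'
#' `grad = -2 sum_i w_i (ref_i - y_i) a_i`, assembled as one sparse
#' matrix-vector product; matches central finite differences to high
#' relative accuracy since the objective is an exact quadratic.
#'
#' @inheritParams objective_chi2
#' @return numeric gradient of length n_beamlets
#' @export
gradient_chi2 <- function(x, sys, weights = NULL) {
  if (any(is.na(sys$ref))) stop("constraint rows lack reference values")
  w <- if (is.null(weights)) sys$w else weights
  y <- as.numeric(sys$A %*% x)
  as.numeric(-2 * Matrix::crossprod(sys$A, w * (sys$ref - y)))
}

#' Superiorization of the AMS feasibility-seeking iteration
#'
#' Each outer iteration k interlaces three phases: (a) `n_perturb` bounded
#' perturbations — the normalised negative gradient of the (eta-decayed)
#' chi-squared objective is tried with step beta = alpha^s, s incremented on
#' every trial, until the objective does not increase, then the step is
#' accepted (with the nonnegativity clamp applied); (b) the objective
#' weights are multiplied by eta (so they carry eta^k cumulatively); (c) one
#' AMS sweep. Because s never resets, the total perturbation length is
#' bounded by a geometric series, which is what preserves the convergence of
#' the perturbed iterates to a feasible point (perturbation resilience).
#'
#' @param x0 starting fluence (>= 0)
#' @param sys a [constraint_system()]
#' @param ams an [ams_params()] (its `max_iterations` is the outer budget K)
#' @param sup a [sup_params()]
#' @return list as in [feasibility_seek()], plus the trace columns `beta`
#'   (last accepted perturbation step) and `weight_scale` (eta^k); `chi2` in
#'   the trace is always evaluated with the undecayed weights so runs are
#'   comparable to plain feasibility-seeking
#' @export
superiorize <- function(x0, sys, ams = ams_params(), sup = sup_params()) {
  x <- as.numeric(x0)
  if (any(x < 0)) stop("x0 must be >= 0")
  w_dec <- sys$w
  s <- 1L  # beta = alpha^s from s = 1, so sum(beta) < alpha / (1 - alpha)
  decay_rows <- if (sup$decay == "oar-only") sys$space == "cdl"
                else rep(TRUE, length(sys$w))
  res <- system_residual(sys, as.numeric(sys$A %*% x))
  rows <- vector("list", ams$max_iterations + 1L)
  rows[[1]] <- data.frame(iteration = 0L, residual = res,
                          chi2 = objective_chi2(x, sys),
                          n_violated = NA_integer_, beta = NA_real_,
                          weight_scale = 1)
  k <- 0L
  while (res >= ams$tol && k < ams$max_iterations) {
    k <- k + 1L
    beta_used <- 0
    for (p in seq_len(sup$n_perturb)) {
      g <- gradient_chi2(x, sys, weights = w_dec)
      gn <- sqrt(sum(g^2))
      if (gn > 0) {
        v <- -g / gn
        f0 <- objective_chi2(x, sys, weights = w_dec)
        for (trial in 1:60) {
          beta <- sup$alpha ^ s
          s <- s + 1L
          cand <- pmax(0, x + beta * v)
          if (objective_chi2(cand, sys, weights = w_dec) <= f0) {
            x <- cand
            beta_used <- beta
            break
          }
          if (trial == 60L) beta_used <- 0  # step vanished; keep x
        }
      }
    }
    w_dec <- ifelse(decay_rows, w_dec * sup$eta, w_dec)
    x_new <- ams_iteration(x, sys, ams$lambda, ams$normalize)
    if (any(!is.finite(x_new)))
      stop(sprintf("non-finite fluence at iteration %d", k))
    nv <- attr(x_new, "n_violated")
    x <- as.numeric(x_new)
    res <- system_residual(sys, as.numeric(sys$A %*% x))
    rows[[k + 1L]] <- data.frame(iteration = k, residual = res,
                                 chi2 = objective_chi2(x, sys),
                                 n_violated = nv, beta = beta_used,
                                 weight_scale = sup$eta ^ k)
  }
  list(x = x, iterations = k, residual = res, converged = res < ams$tol,
       trace = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]))
}
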