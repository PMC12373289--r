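# --- Optimiser implementations ---------------------------------------------
#
# Every optimiser takes the black-box surface of a modified_problem (cost /
# gradient / residuals / jacobian in search space, box bounds when parameter
# bounds are active, a seeded start sampler) plus a start vector and a named
# list of hyperparameters. Optimisers never see the truth or the data.
# Harness-level termination (success threshold, stagnation, evaluation cap)
# is enforced inside the tracked cost closures, which signal a condition
# that run_approach() catches; the loops below therefore only need their
# own local convergence criteria.

clip_box <- function(x, lower, upper) pmin(pmax(x, lower), upper)

# reflect a proposal at finite box faces, then clip for safety
reflect_box <- function(x, lower, upper) {
  over <- is.finite(upper) & x > upper
  x[over] <- 2 * upper[over] - x[over]
  under <- is.finite(lower) & x < lower
  x[under] <- 2 * lower[under] - x[under]
  clip_box(x, lower, upper)
}

# per-coordinate scale of the search box (for steps and mutations)
box_scale <- function(mp, x0) {
  w <- mp$upper - mp$lower
  ifelse(is.finite(w), w, 2 * pmax(abs(x0), 1))
}

#' Trust-region reflective least squares
#'
#' A bounded Gauss-Newton trust-region method on the residual vector:
#' steps solve the regularised normal equations with the regularisation
#' raised until the step fits the trust radius, proposals crossing a bound
#' are reflected back into the box, and the radius adapts to the ratio of
#' actual to predicted cost reduction. Only descent steps are accepted.
#'
#' @param mp A [modified_problem()].
#' @param x0 Start vector (search space).
#' @param hyper Hyperparameters: `maxit` (default 1000), `gtol`, `xtol`.
#' @return List with `par`, `value` and `status`.
#' @keywords internal
opt_trr <- function(mp, x0, hyper = list()) {
  n <- mp$n_par
  maxit <- hyper$maxit %||% 1000
  gtol <- hyper$gtol %||% 1e-12
  xtol <- hyper$xtol %||% 1e-10
  ftol <- hyper$ftol %||% 1e-12
  x <- clip_box(x0, mp$lower, mp$upper)
  r <- mp$residuals(x)
  f2 <- sum(r^2)
  scale <- box_scale(mp, x)
  dmax <- sqrt(sum(scale^2))
  Delta <- 0.1 * dmax
  status <- "maxit"
  for (it in seq_len(maxit)) {
    # one jacobian per accepted point; rejected proposals reuse it
    J <- mp$jacobian(x)
    g <- as.numeric(crossprod(J, r))
    if (sqrt(sum(g^2)) < gtol * max(1, sqrt(f2))) { status <- "gtol"; break }
    JtJ <- crossprod(J)
    accepted <- FALSE
    for (shrink in 1:40) {
      lambda <- 0
      dx <- NULL
      repeat {
        H <- JtJ + diag(lambda, n)
        dx <- tryCatch(solve(H, -g), error = function(e) NULL)
        if (!is.null(dx) && all(is.finite(dx)) &&
            (sqrt(sum(dx^2)) <= Delta || lambda > 1e14)) break
        lambda <- max(lambda * 10, 1e-12 * max(diag(JtJ), 1e-300))
      }
      if (is.null(dx) || !all(is.finite(dx))) { status <- "singular"; break }
      xn <- reflect_box(x + dx, mp$lower, mp$upper)
      # non-rectangular bounds (rate bounds): backtrack towards x until
      # the proposal is feasible -- bound probes cost no model solves
      step <- xn - x
      k <- 0
      while (!mp$feasible(x + step) && k < 30) {
        step <- step / 2
        k <- k + 1
      }
      if (k == 30) { Delta <- Delta / 4; next }
      xn <- x + step
      if (sqrt(sum(step^2)) < xtol * (sqrt(sum(x^2)) + xtol)) {
        status <- "xtol"; accepted <- FALSE; break
      }
      rn <- mp$residuals(xn)
      f2n <- sum(rn^2)
      pred <- -(sum(g * step) + 0.5 * sum(step * (JtJ %*% step)))
      rho <- if (pred > 0) (f2 - f2n) / (2 * pred) else -1
      if (f2n < f2) {
        rel_drop <- (f2 - f2n) / max(f2, 1e-300)
        x <- xn; r <- rn; f2 <- f2n
        if (rho > 0.75 && k == 0) Delta <- min(Delta * 2, 1e3 * dmax)
        accepted <- TRUE
        if (rel_drop < ftol) status <- "ftol"
        break
      }
      Delta <- min(Delta, sqrt(sum(step^2))) / 4
      if (Delta < 1e-12 * dmax) { status <- "radius"; break }
    }
    if (!accepted) {
      if (status == "maxit") status <- "stalled"
      break
    }
    if (status == "ftol") break
  }
  list(par = x, value = sqrt(f2), status = status)
}

#' @keywords internal
opt_lm <- function(mp, x0, hyper = list()) {
  x <- clip_box(x0, mp$lower, mp$upper)
  res <- tryCatch(
    minpack.lm::nls.lm(
      par = x, fn = mp$residuals, jac = mp$jacobian,
      lower = mp$lower, upper = mp$upper,
      control = minpack.lm::nls.lm.control(
        maxiter = hyper$maxit %||% 1000)),
    error = function(e) NULL)
  if (is.null(res)) return(list(par = x, value = mp$cost(x),
                                status = "failed"))
  list(par = res$par, value = sqrt(sum(res$fvec^2)), status = "converged")
}

#' @keywords internal
opt_nelder_mead <- function(mp, x0, hyper = list()) {
  res <- stats::optim(x0, mp$cost, method = "Nelder-Mead",
                      control = list(maxit = hyper$maxit %||% 1e4,
                                     reltol = hyper$reltol %||% 1e-10))
  list(par = res$par, value = res$value, status = "converged")
}

#' @keywords internal
opt_conjugate_gd <- function(mp, x0, hyper = list()) {
  res <- stats::optim(x0, mp$cost, gr = mp$gradient, method = "CG",
                      control = list(maxit = hyper$maxit %||% 2000))
  list(par = res$par, value = res$value, status = "converged")
}

#' Covariance matrix adaptation evolution strategy
#'
#' Standard (mu/mu_w, lambda) CMA-ES with cumulative step-size adaptation
#' and rank-one plus rank-mu covariance updates. The covariance is
#' initialised diagonally from the search-box widths so that badly scaled
#' parameter spaces start with sensible per-coordinate steps.
#' @keywords internal
opt_cmaes <- function(mp, x0, hyper = list()) {
  n <- mp$n_par
  lambda <- hyper$lambda %||% (4L + floor(3 * log(n)))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  scale <- box_scale(mp, x0) / 4
  sigma <- hyper$sigma0 %||% 1
  m <- x0
  C <- diag(scale^2, n)
  pc <- ps <- numeric(n)
  best_par <- m
  best_val <- Inf
  maxit <- hyper$maxit %||% 1e4

  for (it in seq_len(maxit)) {
    eC <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eC$values, 1e-30))
    B <- eC$vectors
    if (any(!is.finite(D))) break
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)
    X <- m + sigma * Y
    vals <- apply(X, 2, mp$cost)
    ord <- order(vals)
    if (vals[ord[1]] < best_val) {
      best_val <- vals[ord[1]]; best_par <- X[, ord[1]]
    }
    ysel <- Y[, ord[seq_len(mu)], drop = FALSE]
    ybar <- as.numeric(ysel %*% w)
    m <- m + sigma * ybar
    Cinvsqrt_y <- B %*% ((1 / D) * crossprod(B, ybar))
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * as.numeric(Cinvsqrt_y)
    hsig <- as.numeric(
      sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * it)) / chiN < 1.4 + 2 / (n + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ybar
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * (ysel %*% (w * t(ysel)))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    if (!is.finite(sigma) || sigma < 1e-14 || sigma > 1e8) break
  }
  list(par = best_par, value = best_val, status = "converged")
}

#' Global-best particle swarm (constriction coefficients)
#' @keywords internal
opt_pso <- function(mp, x0, hyper = list(), seed_aux = NULL) {
  n <- mp$n_par
  swarm <- hyper$swarm %||% 20L
  w <- hyper$inertia %||% 0.7298
  c1 <- hyper$c1 %||% 1.49618
  c2 <- hyper$c2 %||% 1.49618
  maxit <- hyper$maxit %||% 1e4
  refine <- hyper$refine  # optional local refinement hook (hybrids)
  refine_every <- hyper$refine_every %||% 10

  X <- t(mp$sample_starts(swarm, seed_aux %||% sample.int(2^31 - 1, 1)))
  X[, 1] <- x0
  V <- matrix(0, n, swarm)
  pvals <- apply(X, 2, mp$cost)
  P <- X
  gbi <- which.min(pvals)
  gbest <- P[, gbi]; gval <- pvals[gbi]
  scale <- box_scale(mp, x0)
  for (it in seq_len(maxit)) {
    R1 <- matrix(stats::runif(n * swarm), n, swarm)
    R2 <- matrix(stats::runif(n * swarm), n, swarm)
    V <- w * V + c1 * R1 * (P - X) + c2 * R2 * (gbest - X)
    vmax <- 0.5 * scale
    V <- pmin(pmax(V, -vmax), vmax)
    X <- X + V
    if (any(is.finite(mp$lower))) {
      X <- apply(X, 2, reflect_box, lower = mp$lower, upper = mp$upper)
    }
    vals <- apply(X, 2, mp$cost)
    better <- vals < pvals
    P[, better] <- X[, better]
    pvals[better] <- vals[better]
    gbi <- which.min(pvals)
    if (pvals[gbi] < gval) { gbest <- P[, gbi]; gval <- pvals[gbi] }
    if (!is.null(refine) && it %% refine_every == 0) {
      loc <- refine(gbest)
      if (loc$value < gval) { gbest <- loc$par; gval <- loc$value }
    }
  }
  list(par = gbest, value = gval, status = "converged")
}

#' Real-coded genetic algorithm (tournament selection, blend crossover)
#' @keywords internal
opt_ga <- function(mp, x0, hyper = list(), seed_aux = NULL) {
  n <- mp$n_par
  pop <- hyper$pop %||% 50L
  pmut <- hyper$pmut %||% (1 / n)
  alpha <- hyper$alpha %||% 0.5
  maxgen <- hyper$maxit %||% 1e4
  scale <- box_scale(mp, x0)

  X <- t(mp$sample_starts(pop, seed_aux %||% sample.int(2^31 - 1, 1)))
  X[, 1] <- x0
  vals <- apply(X, 2, mp$cost)
  best <- which.min(vals)
  bpar <- X[, best]; bval <- vals[best]
  for (gen in seq_len(maxgen)) {
    newX <- matrix(NA_real_, n, pop)
    newX[, 1] <- bpar  # elitism
    for (k in 2:pop) {
      pick <- function() {
        ij <- sample.int(pop, 2)
        ij[which.min(vals[ij])]
      }
      pa <- X[, pick()]; pb <- X[, pick()]
      lo <- pmin(pa, pb); hi <- pmax(pa, pb); d <- hi - lo
      child <- stats::runif(n, lo - alpha * d, hi + alpha * d)
      mut <- stats::runif(n) < pmut
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, 0.1 * scale[mut])
      if (any(is.finite(mp$lower))) {
        child <- reflect_box(child, mp$lower, mp$upper)
      }
      newX[, k] <- child
    }
    X <- newX
    vals <- apply(X, 2, mp$cost)
    best <- which.min(vals)
    if (vals[best] < bval) { bpar <- X[, best]; bval <- vals[best] }
  }
  list(par = bpar, value = bval, status = "converged")
}

#' Differential evolution (rand/1/bin)
#' @keywords internal
opt_de <- function(mp, x0, hyper = list(), seed_aux = NULL) {
  n <- mp$n_par
  pop <- hyper$pop %||% min(10L * n, 40L)
  Fw <- hyper$F %||% 0.5
  CR <- hyper$CR %||% 0.9
  maxgen <- hyper$maxit %||% 1e4
  X <- t(mp$sample_starts(pop, seed_aux %||% sample.int(2^31 - 1, 1)))
  X[, 1] <- x0
  vals <- apply(X, 2, mp$cost)
  for (gen in seq_len(maxgen)) {
    for (i in seq_len(pop)) {
      abc <- sample(setdiff(seq_len(pop), i), 3)
      v <- X[, abc[1]] + Fw * (X[, abc[2]] - X[, abc[3]])
      cross <- stats::runif(n) < CR
      cross[sample.int(n, 1)] <- TRUE
      u <- ifelse(cross, v, X[, i])
      if (any(is.finite(mp$lower))) {
        u <- reflect_box(u, mp$lower, mp$upper)
      }
      fu <- mp$cost(u)
      if (fu <= vals[i]) { X[, i] <- u; vals[i] <- fu }
    }
  }
  best <- which.min(vals)
  list(par = X[, best], value = vals[best], status = "converged")
}

#' Hooke-Jeeves pattern search
#' @keywords internal
opt_pattern_search <- function(mp, x0, hyper = list()) {
  n <- mp$n_par
  x <- clip_box(x0, mp$lower, mp$upper)
  f <- mp$cost(x)
  step <- (hyper$step0 %||% 0.1) * box_scale(mp, x0)
  tol <- hyper$tol %||% 1e-8
  maxit <- hyper$maxit %||% 1e5
  for (it in seq_len(maxit)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      for (s in c(1, -1)) {
        xt <- x
        xt[i] <- xt[i] + s * step[i]
        xt <- clip_box(xt, mp$lower, mp$upper)
        ft <- mp$cost(xt)
        if (ft < f) { x <- xt; f <- ft; improved <- TRUE; break }
      }
    }
    if (!improved) {
      step <- step / 2
      if (max(step / (abs(x) + 1)) < tol) break
    }
  }
  list(par = x, value = f, status = "converged")
}

#' Repeated draws from the problem's sampling region
#' @keywords internal
opt_random_search <- function(mp, x0, hyper = list(), seed_aux = NULL) {
  best_par <- x0
  best_val <- mp$cost(x0)
  batch <- hyper$batch %||% 100L
  maxit <- hyper$maxit %||% 1e4
  base <- seed_aux %||% sample.int(2^31 - 1, 1)
  for (k in seq_len(ceiling(maxit / batch))) {
    X <- mp$sample_starts(batch, (base + k) %% (2^31 - 1))
    for (j in seq_len(nrow(X))) {
      v <- mp$cost(X[j, ])
      if (v < best_val) { best_val <- v; best_par <- X[j, ] }
    }
  }
  list(par = best_par, value = best_val, status = "converged")
}

# --- Hybrid combinators -----------------------------------------------------

# "a+b": run a, then b from a's best; "a/b": run a with periodic local
# refinement by b; combinations like "a/b+b" chain both notations.
run_optimiser_id <- function(id, mp, x0, hyper = list()) {
  stages <- strsplit(id, "+", fixed = TRUE)[[1]]
  cur <- x0
  out <- NULL
  for (st in stages) {
    if (grepl("/", st, fixed = TRUE)) {
      parts <- strsplit(st, "/", fixed = TRUE)[[1]]
      inner <- parts[2]
      hy <- hyper
      hy$refine <- function(x) {
        run_base_optimiser(inner, mp, x,
                           modifyList(hyper, list(maxit = 20)))
      }
      out <- run_base_optimiser(parts[1], mp, cur, hy)
    } else {
      out <- run_base_optimiser(st, mp, cur, hyper)
    }
    cur <- out$par
  }
  out
}

run_base_optimiser <- function(id, mp, x0, hyper = list()) {
  switch(id,
    trr = opt_trr(mp, x0, hyper),
    lm = opt_lm(mp, x0, hyper),
    nelder_mead = opt_nelder_mead(mp, x0, hyper),
    conjugate_gd = opt_conjugate_gd(mp, x0, hyper),
    cmaes = opt_cmaes(mp, x0, hyper),
    pso = opt_pso(mp, x0, hyper),
    ga = opt_ga(mp, x0, hyper),
    de = opt_de(mp, x0, hyper),
    pattern_search = opt_pattern_search(mp, x0, hyper),
    random_search = opt_random_search(mp, x0, hyper),
    stop("optimiser '", id, "' is not implemented; registry entries for ",
         "it remain available for extension", call. = FALSE)
  )
}

#' Implemented optimiser identifiers
#' @return Character vector of base optimiser ids that can be run.
#' @export
implemented_optimisers <- function() {
  c("trr", "lm", "nelder_mead", "conjugate_gd", "cmaes", "pso", "ga",
    "de", "pattern_search", "random_search")
}

optimiser_id_implemented <- function(id) {
  parts <- unlist(strsplit(unlist(strsplit(id, "+", fixed = TRUE)),
                           "/", fixed = TRUE))
  all(parts %in% implemented_optimisers())
}
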