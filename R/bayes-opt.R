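# Seeded Gaussian-process Bayesian optimisation over a mixed
# (real / integer / categorical) hyperparameter box. A Latin-hypercube
# initial design, a squared-exponential GP surrogate on the unit cube, and
# expected-improvement acquisition maximised over random candidates. A
# random-search mode with the same evaluation budget is available as a
# fallback.

.paramDim <- function(space) length(space)

.decodeParams <- function(u, space) {
  out <- list()
  for (i in seq_along(space)) {
    p <- space[[i]]
    out[[p$name]] <- switch(p$type,
      real = if (isTRUE(p$log))
        exp(log(p$lower) + u[i] * (log(p$upper) - log(p$lower)))
      else p$lower + u[i] * (p$upper - p$lower),
      int = as.integer(round(p$lower + u[i] * (p$upper - p$lower))),
      cat = p$values[[1 + min(length(p$values) - 1,
                              floor(u[i] * length(p$values)))]],
      .stopf("unknown parameter type '%s'", p$type))
  }
  out
}

.gpPosterior <- function(U, y, Ucand, ell = 0.25, noise = 1e-6) {
  ym <- mean(y); ys <- stats::sd(y)
  if (!is.finite(ys) || ys < 1e-12) ys <- 1
  yz <- (y - ym) / ys
  d2 <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    pmax(outer(an, bn, "+") - 2 * A %*% t(B), 0)
  }
  K <- exp(-0.5 * d2(U, U) / ell^2) + diag(noise + 1e-8, nrow(U))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yz))
  Ks <- exp(-0.5 * d2(Ucand, U) / ell^2)
  mu <- as.vector(Ks %*% alpha)
  v <- forwardsolve(t(L), t(Ks))
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  list(mu = mu * ys + ym, sd = sqrt(s2) * ys)
}

.expectedImprovement <- function(mu, sdv, best, xi = 0.01) {
  z <- (mu - best - xi) / sdv
  (mu - best - xi) * stats::pnorm(z) + sdv * stats::dnorm(z)
}

#' Bayesian optimisation of a black-box objective
#'
#' Maximises `objective(params)` over the given space within a fixed budget
#' of `trials` evaluations. Runs inside the caller's RNG stream, so wrapping
#' the call in a seed gives a fully deterministic trajectory.
#'
#' @param objective function taking a named parameter list, returning a
#'   scalar to maximise.
#' @param space list of parameter descriptors, each
#'   `list(name, type = "real"|"int"|"cat", lower, upper, log, values)`.
#' @param trials total evaluation budget (default 100).
#' @param n0 initial Latin-hypercube design size (default `min(10, trials)`).
#' @param optimizer `"gp"` (Gaussian-process expected improvement, default)
#'   or `"random"` (pure random search with the same budget).
#' @param candidates number of random acquisition candidates per iteration.
#' @return list with `best_params`, `best_value` and a `history` data frame
#'   (one row per trial: encoded coordinates and objective value).
#' @export
bayesOptimize <- function(objective, space, trials = 100, n0 = min(10, trials),
                          optimizer = c("gp", "random"), candidates = 256) {
  optimizer <- match.arg(optimizer)
  d <- .paramDim(space)
  stopifnot(trials >= 1)
  n0 <- min(n0, trials)
  U <- if (optimizer == "random") matrix(runif(trials * d), trials, d)
       else lhs::randomLHS(n0, d)
  y <- apply(U, 1, function(u) objective(.decodeParams(u, space)))

  if (optimizer == "gp" && trials > n0) {
    for (t in seq_len(trials - n0)) {
      Uc <- matrix(runif(candidates * d), candidates, d)
      post <- .gpPosterior(U, y, Uc)
      ei <- .expectedImprovement(post$mu, post$sd, max(y))
      u <- Uc[which.max(ei), , drop = FALSE]
      U <- rbind(U, u)
      y <- c(y, objective(.decodeParams(as.vector(u), space)))
    }
  }
  best <- which.max(y)
  hist <- as.data.frame(U)
  names(hist) <- vapply(space, `[[`, character(1), "name")
  hist$value <- y
  list(best_params = .decodeParams(U[best, ], space), best_value = y[best],
       history = hist)
}
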