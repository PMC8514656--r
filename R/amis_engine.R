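# Annealed adaptive multiple importance sampling (AMIS).
#
# Samples are drawn in the unbounded transformed parameter space.  Each
# iteration draws a batch from the current proposal, then re-weights every
# sample ever drawn against the mixture of all proposals used so far
# (deterministic-mixture multiple importance sampling), so past simulations
# are recycled.  The likelihood is tempered: the summed squared error X^2 is
# divided by an annealing temperature that rises on improvement of the best
# sample and decays geometrically otherwise, which protects the adaptation
# against premature collapse into a local minimum.  The prior is uniform in
# the transformed coordinates, so importance weights need no Jacobian term.

#' AMIS run configuration
#'
#' @param n_samples_per_iter Samples drawn per iteration (default 100).
#' @param min_iterations Minimum number of iterations before the stopping
#'   rule is consulted (default 500).
#' @param ess_factor Stopping rule: terminate once the Kish effective sample
#'   size of the temperature-1 weights exceeds `ess_factor * n_dim`
#'   (default 10).
#' @param max_iterations Hard cap on iterations; runs that hit it are
#'   flagged non-converged (default 1500).
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @param initial_box_halfwidth Half-width (transformed units) of the
#'   uniform initial proposal box around the reference (default 0.05).
#' @param T_max Initial and maximal annealing temperature (default 10).
#' @return Named list of class `"amis_config"`.
#' @export
amis_config <- function(n_samples_per_iter = 100, min_iterations = 500,
                        ess_factor = 10, max_iterations = 1500, seed = 1,
                        initial_box_halfwidth = 0.05, T_max = 10) {
  cfg <- list(n_samples_per_iter = n_samples_per_iter,
              min_iterations = min_iterations, ess_factor = ess_factor,
              max_iterations = max_iterations, seed = as.integer(seed),
              initial_box_halfwidth = initial_box_halfwidth, T_max = T_max)
  num <- unlist(cfg[c("n_samples_per_iter", "min_iterations", "ess_factor",
                      "max_iterations", "initial_box_halfwidth", "T_max")])
  if (any(num <= 0)) stop("all amis_config values must be positive")
  if (cfg$max_iterations < cfg$min_iterations) {
    stop("max_iterations must be >= min_iterations")
  }
  structure(cfg, class = "amis_config")
}

#' Uniform-box initial proposal
#'
#' A small uniform distribution around the (transformed) reference point;
#' the adaptation subsequently grows, shrinks and moves the proposal toward
#' the region of posterior mass.
#'
#' @param center Transformed reference coordinates (finite numeric vector).
#' @param halfwidth Per-axis half-width in transformed units.
#' @return A proposal component (class `"proposal_component"`), kind
#'   `"uniform-box"`, with density `1/volume` inside the box and 0 outside.
#' @export
initial_proposal <- function(center, halfwidth = 0.05) {
  stopifnot(all(is.finite(center)), halfwidth > 0)
  structure(list(kind = "uniform-box", center = as.numeric(center),
                 halfwidth = halfwidth, axes = NULL, scales = NULL,
                 iteration = 0L, n_drawn = 0L),
            class = "proposal_component")
}

STUDENT_DF <- 5  # degrees of freedom of adapted proposal components

student_component <- function(center, axes, scales, iteration) {
  structure(list(kind = "student-t", center = as.numeric(center),
                 halfwidth = NULL, axes = axes, scales = as.numeric(scales),
                 iteration = as.integer(iteration), n_drawn = 0L),
            class = "proposal_component")
}

#' Draw samples from a proposal component
#'
#' Adapted components are multivariate Student-t (5 degrees of freedom)
#' along the fitted principal axes: the heavy tails keep distant regions of
#' the posterior shell reachable in high dimension, which light-tailed
#' Gaussian components systematically miss.
#'
#' @param component A `proposal_component`.
#' @param n Number of draws (>= 1).
#' @return `n_dim x n` matrix of transformed-space draws (columns).  Draws
#'   are i.i.d. from the component and reproducible under a set seed.
#' @export
draw_samples <- function(component, n) {
  stopifnot(n >= 1)
  d <- length(component$center)
  if (component$kind == "uniform-box") {
    u <- matrix(stats::runif(d * n, -component$halfwidth,
                             component$halfwidth), d, n)
    u + component$center
  } else {
    z <- matrix(stats::rnorm(d * n), d, n)
    g <- stats::rchisq(n, df = STUDENT_DF)
    radial <- rep(sqrt(STUDENT_DF / g), each = d)
    component$center + (component$axes %*% (component$scales * z)) * radial
  }
}

# Component pdf at the columns of U (n_dim x m) -> length-m vector.
component_pdf <- function(component, U) {
  if (!is.matrix(U)) U <- matrix(U, ncol = 1)
  d <- length(component$center)
  if (component$kind == "uniform-box") {
    h <- component$halfwidth
    inside <- colSums(abs(U - component$center) <= h) == d
    as.numeric(inside) / (2 * h)^d
  } else {
    nu <- STUDENT_DF
    y <- crossprod(component$axes, U - component$center)  # axes' (u - mu)
    s <- component$scales
    m <- colSums((y / s)^2)                               # Mahalanobis^2
    log_pdf <- lgamma((nu + d) / 2) - lgamma(nu / 2) -
      0.5 * d * log(nu * pi) - sum(log(s)) -
      0.5 * (nu + d) * log1p(m / nu)
    exp(log_pdf)
  }
}

#' Mixture proposal density
#'
#' The deterministic-mixture density of all proposals used so far:
#' `q(u) = sum_c n_drawn_c * pdf_c(u) / sum_c n_drawn_c`.
#'
#' @param mixture List of `proposal_component`s, each with its `n_drawn`
#'   count recorded.
#' @param u Transformed point (vector) or `n_dim x m` matrix of columns.
#' @return Density value(s), >= 0.
#' @export
mixture_density <- function(mixture, u) {
  if (!length(mixture)) stop("empty proposal mixture")
  if (!is.matrix(u)) u <- matrix(u, ncol = 1)
  n_drawn <- vapply(mixture, `[[`, numeric(1), "n_drawn")
  acc <- numeric(ncol(u))
  for (k in seq_along(mixture)) {
    acc <- acc + n_drawn[k] * component_pdf(mixture[[k]], u)
  }
  acc / sum(n_drawn)
}

#' Importance weights of a sample set under the tempered posterior
#'
#' Raw weight `exp(-X2 / T) / q` (uniform prior in transformed space),
#' normalised to sum to one.  Samples with infinite `X2` (failed
#' simulations) receive weight zero.
#'
#' @param X2 Vector of summed squared errors (>= 0 or `Inf`).
#' @param q Mixture density at each sample (> 0 for finite-X2 samples).
#' @param T Annealing temperature (>= 1).
#' @param log_prior Optional per-sample unnormalised log-prior (0 for the
#'   default prior uniform in transformed coordinates; the Jacobian term
#'   when the prior is uniform in physical units).
#' @return Normalised weight vector summing to 1.
#' @export
update_weights <- function(X2, q, T = 1, log_prior = 0) {
  lw <- annealed_log_likelihood(X2, T) + log_prior - log(q)
  lw[!is.finite(lw)] <- -Inf
  if (all(lw == -Inf)) {
    stop(sprintf(paste0("degenerate posterior: all %d raw weights are zero ",
                        "(all simulations failed or mixture density ",
                        "vanished)"), length(X2)))
  }
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Annealing temperature update
#'
#' On improvement of the best X^2, the temperature is raised by the size of
#' the improvement (capped at `T_max`), keeping exploration alive while the
#' optimum is still moving; otherwise it decays by the factor 0.8, floored
#' at 1 (the untempered posterior).
#'
#' @param T Current temperature.
#' @param improved Logical: did the best X^2 strictly decrease during the
#'   last iteration?
#' @param delta_best_X2 Improvement (old best minus new best, >= 0).
#' @param T_max Temperature cap (default 10).
#' @return New temperature in `[1, T_max]`.
#' @export
update_temperature <- function(T, improved, delta_best_X2 = 0, T_max = 10) {
  if (isTRUE(improved)) min(T_max, T + delta_best_X2) else max(1, 0.8 * T)
}

#' Fit an adapted proposal to the weighted sample set
#'
#' Weighted mean and weighted covariance over all samples (current
#' weights), eigendecomposed so that new samples are drawn along the
#' principal component axes of the weighted sample set.  Eigenvalues are
#' floored at 1e-8 (variance units) to prevent proposal collapse when the
#' weight concentrates on few samples.
#'
#' @param U `n_dim x N` matrix of transformed samples (columns).
#' @param w Normalised weights (length N).
#' @param iteration Iteration index recorded on the component.
#' @param previous Optional previous component.  With fewer than 2
#'   positively weighted samples no covariance can be fitted and the
#'   previous component is returned with its scales inflated by 1.5
#'   (capped).  Otherwise a fraction `beta` of the previous component's
#'   covariance is added to the weighted-sample covariance before the
#'   eigendecomposition.  This single regularisation covers both failure
#'   modes of the adaptation: when the tempered weights concentrate on one
#'   sample the fitted covariance vanishes and the term contracts the
#'   proposal geometrically around the dominant sample (a trust region),
#'   and once samples populate the posterior basin with comparable weights
#'   the fitted covariance dominates and the proposal re-expands to the
#'   basin width, so it cannot collapse onto the mode.
#' @param beta Fraction of the previous component's covariance blended into
#'   the fit (default 0.25).
#' @return A Student-t `proposal_component` along the fitted axes.
#' @export
fit_proposal <- function(U, w, iteration = NA_integer_, previous = NULL,
                         beta = 0.25) {
  n_pos <- sum(w > 0)
  if (n_pos < 1) stop("no positively weighted samples")
  if (n_pos < 2 && !is.null(previous)) {
    prev <- previous
    if (prev$kind == "uniform-box") {
      prev$halfwidth <- min(20, prev$halfwidth * 1.5)
    } else {
      prev$scales <- pmin(20, prev$scales * 1.5)
    }
    prev$iteration <- as.integer(iteration)
    prev$n_drawn <- 0L
    return(prev)
  }
  mu <- as.numeric(U %*% w)
  centered <- U - mu
  sigma <- tcrossprod(sweep(centered, 2, w, `*`), centered)
  if (!is.null(previous)) {
    sigma <- sigma + beta * component_covariance(previous)
  }
  sigma <- (sigma + t(sigma)) / 2
  eig <- eigen(sigma, symmetric = TRUE)
  scales <- sqrt(pmax(eig$values, 1e-8))
  student_component(mu, eig$vectors, scales, iteration)
}

# covariance matrix represented by a proposal component
component_covariance <- function(component) {
  d <- length(component$center)
  if (component$kind == "uniform-box") {
    diag(rep(component$halfwidth^2 / 3, d), nrow = d)  # variance of U(-h, h)
  } else {
    A <- component$axes
    A %*% (component$scales^2 * t(A))
  }
}

#' Kish effective sample size
#'
#' `N_eff = (sum w)^2 / sum(w^2)`; for normalised weights this is
#' `1 / sum(w^2)`, the number of equally weighted samples the set is worth.
#'
#' @param w Weight vector (>= 0).
#' @return Effective sample size (0 for an all-zero weight vector).
#' @export
effective_sample_size <- function(w) {
  s2 <- sum(w^2)
  if (s2 == 0) return(0)
  sum(w)^2 / s2
}

#' Run the annealed AMIS loop on an arbitrary error function
#'
#' Generic engine: iteration 0 draws from the uniform initial proposal at
#' `T = T_max`; every subsequent iteration updates the temperature, re-weights
#' all samples against the full proposal mixture, fits a new
#' principal-component Gaussian proposal, draws a new batch, and evaluates
#' its X^2.  The loop stops at the first iteration count
#' `>= min_iterations` whose temperature-1 Kish effective sample size
#' exceeds `ess_factor * n_dim`, or at `max_iterations` (flagged
#' non-converged).
#'
#' @param x2_fun Function mapping an `n_dim x m` matrix of transformed
#'   coordinates (columns) to a length-m vector of X^2 values (`Inf` for
#'   failed evaluations).
#' @param center Transformed-space center of the initial proposal.
#' @param config An [amis_config()].
#' @param log_prior_fun Optional function mapping the same matrix to
#'   per-sample unnormalised log-prior values; `NULL` for a prior uniform
#'   in the transformed coordinates.
#' @return Object of class `"amis_run"`: `u` (`n_dim x N` samples), `X2`,
#'   `iteration` (per-sample batch index), `weight` (normalised T=1
#'   weights), `mixture` (list of components), `trace` (data frame with
#'   `iteration`, `T`, `best_X2`, `n_eff`), `n_iterations`, `converged`,
#'   `seed`.
#' @export
amis_run <- function(x2_fun, center, config = amis_config(),
                     log_prior_fun = NULL) {
  set.seed(config$seed)
  d <- length(center)
  n_per <- config$n_samples_per_iter

  # preallocate the sample store and the pdf cache D[s, c] = pdf of
  # component c at sample s for the whole run
  n_max <- config$max_iterations * n_per
  c_max <- config$max_iterations
  U <- matrix(NA_real_, d, n_max)
  X2 <- numeric(n_max)
  lp <- numeric(n_max)
  sample_iter <- integer(n_max)
  D <- matrix(NA_real_, n_max, c_max)

  comp <- initial_proposal(center, config$initial_box_halfwidth)
  U[, 1:n_per] <- draw_samples(comp, n_per)
  comp$n_drawn <- n_per
  mixture <- list(comp)
  X2[1:n_per] <- x2_fun(U[, 1:n_per, drop = FALSE])
  if (!is.null(log_prior_fun)) {
    lp[1:n_per] <- log_prior_fun(U[, 1:n_per, drop = FALSE])
  }
  sample_iter[1:n_per] <- 0L
  D[1:n_per, 1] <- component_pdf(comp, U[, 1:n_per, drop = FALSE])
  N <- n_per

  T_cur <- config$T_max
  best <- min(X2[1:N])
  prev_best <- best

  trace_T <- c(T_cur); trace_best <- c(best); trace_neff <- c(NA_real_)
  n_iter_done <- 1L
  converged <- FALSE

  mixture_q <- function() {
    n_drawn <- vapply(mixture, `[[`, numeric(1), "n_drawn")
    as.numeric(D[1:N, seq_along(mixture), drop = FALSE] %*% n_drawn) /
      sum(n_drawn)
  }

  while (n_iter_done < config$max_iterations) {
    i <- n_iter_done  # index of the iteration about to run

    improved <- is.finite(best) && best < prev_best
    delta <- if (improved) prev_best - best else 0
    T_cur <- update_temperature(T_cur, improved, delta, config$T_max)
    prev_best <- best

    w_adapt <- update_weights(X2[1:N], mixture_q(), T_cur,
                              log_prior = lp[1:N])

    comp <- fit_proposal(U[, 1:N, drop = FALSE], w_adapt, iteration = i,
                         previous = mixture[[length(mixture)]])
    U_new <- draw_samples(comp, n_per)
    comp$n_drawn <- n_per
    mixture[[length(mixture) + 1L]] <- comp

    # extend the pdf cache: new component at old samples, all at new samples
    idx_new <- (N + 1):(N + n_per)
    D[1:N, length(mixture)] <- component_pdf(comp, U[, 1:N, drop = FALSE])
    for (k in seq_along(mixture)) {
      D[idx_new, k] <- component_pdf(mixture[[k]], U_new)
    }

    U[, idx_new] <- U_new
    X2[idx_new] <- x2_fun(U_new)
    if (!is.null(log_prior_fun)) lp[idx_new] <- log_prior_fun(U_new)
    sample_iter[idx_new] <- i
    N <- N + n_per
    best <- min(best, min(X2[idx_new]))
    n_iter_done <- n_iter_done + 1L

    w1 <- update_weights(X2[1:N], mixture_q(), T = 1, log_prior = lp[1:N])
    n_eff <- effective_sample_size(w1)
    trace_T <- c(trace_T, T_cur)
    trace_best <- c(trace_best, best)
    trace_neff <- c(trace_neff, n_eff)

    if (n_iter_done >= config$min_iterations &&
        n_eff > config$ess_factor * d) {
      converged <- TRUE
      break
    }
  }

  w1 <- update_weights(X2[1:N], mixture_q(), T = 1, log_prior = lp[1:N])
  trace <- data.frame(iteration = seq_len(n_iter_done) - 1L, T = trace_T,
                      best_X2 = trace_best, n_eff = trace_neff)

  structure(list(u = U[, 1:N, drop = FALSE], X2 = X2[1:N],
                 iteration = sample_iter[1:N], weight = w1,
                 log_prior = lp[1:N], mixture = mixture, trace = trace,
                 n_iterations = n_iter_done, converged = converged,
                 seed = config$seed),
            class = "amis_run")
}

#' @export
print.amis_run <- function(x, ...) {
  cat(sprintf(paste0("amis_run: %d samples over %d iterations, best X2 ",
                     "%.4g, N_eff %.1f, converged: %s\n"),
              length(x$X2), x$n_iterations, min(x$X2),
              effective_sample_size(x$weight), x$converged))
  invisible(x)
}

#' Estimate the posterior of cardiac tissue parameters from a measurement
#'
#' End-to-end wrapper around [amis_run()]: transforms the parameter space,
#' evaluates the forward model and the strain likelihood for every drawn
#' sample, and returns the weighted sample set (the empirical posterior at
#' temperature 1) together with the run trace.
#'
#' @param m A `measurement_set`.
#' @param space A `parameter_space` (default the 20-parameter space).
#' @param config An [amis_config()].
#' @param sds A `normalization_sds`.
#' @param backend Forward-model backend name (default `"surrogate"`).
#' @param dt Forward-model time step (s).
#' @param prior `"transformed"` (default) for a prior uniform in the
#'   unbounded sampling coordinates, or `"physical"` for a prior uniform in
#'   physical units (adds the transform Jacobian to the weights).
#' @return Object of class `"amis_result"`: everything in `amis_run` plus
#'   `theta` (data frame of physical parameter samples, one column per
#'   parameter) and the `space`, `sds` and `backend` used.
#' @export
amis_estimate <- function(m, space = default_parameter_space(),
                          config = amis_config(), sds = normalization_sds(),
                          backend = "surrogate", dt = 0.002,
                          prior = c("transformed", "physical")) {
  stopifnot(inherits(m, "measurement_set"))
  prior <- match.arg(prior)
  x2_fun <- function(U) {
    apply(U, 2, function(u) {
      theta <- from_transformed(space, u)
      mo <- forward_model(theta, m, backend = backend, dt = dt, space = space)
      compute_error_terms(mo, m, sds)$X2
    })
  }
  log_prior_fun <- if (prior == "physical") {
    function(U) transform_log_jacobian(space, U)
  }
  center <- to_transformed(space, reference_vector(space))
  run <- amis_run(x2_fun, center, config, log_prior_fun = log_prior_fun)
  theta <- as.data.frame(t(from_transformed(space, run$u)))
  names(theta) <- space$names
  run$theta <- theta
  run$space <- space
  run$sds <- sds
  run$backend <- backend
  class(run) <- c("amis_result", "amis_run")
  run
}

#' Recompute the posterior weights of a finished run from scratch
#'
#' Rebuilds the mixture density of every sample directly from the stored
#' components (no cached values) and re-evaluates the normalised weights at
#' the given temperature.  Used to verify the incrementally maintained
#' weights.
#'
#' @param run An `amis_run`.
#' @param T Annealing temperature (default 1).
#' @return Normalised weight vector.
#' @export
recompute_weights <- function(run, T = 1) {
  q <- mixture_density(run$mixture, run$u)
  update_weights(run$X2, q, T = T, log_prior = run$log_prior %||% 0)
}
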