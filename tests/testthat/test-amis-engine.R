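test_that("initial proposal is a normalized uniform box at the reference", {
  comp <- initial_proposal(center = 0.3, halfwidth = 0.05)
  expect_equal(comp$center, 0.3)
  # density inside a 1-D box of width 0.1 is 10
  expect_equal(mixture_density(list(modifyList(comp, list(n_drawn = 10L))),
                               matrix(0.31, 1, 1)), 10)
  expect_equal(mixture_density(list(modifyList(comp, list(n_drawn = 10L))),
                               matrix(0.5, 1, 1)), 0)
  expect_error(initial_proposal(c(0, Inf)), "is.finite")
})

test_that("draws are reproducible, in-support, and degenerate correctly", {
  comp <- initial_proposal(rep(0, 3), halfwidth = 0.05)
  set.seed(5); u1 <- draw_samples(comp, 100)
  set.seed(5); u2 <- draw_samples(comp, 100)
  expect_identical(u1, u2)
  expect_true(all(abs(u1) <= 0.05))
  g <- cardamis:::student_component(c(1, 2, 3), diag(3), rep(1e-12, 3), 1L)
  set.seed(8)
  expect_equal(draw_samples(g, 4), matrix(c(1, 2, 3), 3, 4), tolerance = 1e-8)
})

test_that("mixture density is the sample-count-weighted component mean", {
  d <- 2
  box <- modifyList(initial_proposal(rep(0, d), 0.5), list(n_drawn = 100L))
  g <- cardamis:::student_component(rep(0, d), diag(d), c(1, 1), 1L)
  g$n_drawn <- 300L
  u0 <- matrix(0, d, 1)
  pdf_box <- 1 / 1^d  # 1/(2*0.5)^2
  # bivariate t with nu = 5, identity scale, at its centre
  nu <- 5
  pdf_g <- exp(lgamma((nu + d) / 2) - lgamma(nu / 2) -
                 0.5 * d * log(nu * pi))
  expect_equal(mixture_density(list(box), u0), pdf_box)
  expect_equal(mixture_density(list(box, g), u0),
               (100 * pdf_box + 300 * pdf_g) / 400)
  # hand value: components with n_drawn 100 and 300, pdfs 2.0 and 0.0
  narrow <- modifyList(initial_proposal(rep(0, 1), 0.25), list(n_drawn = 100L))
  off <- modifyList(initial_proposal(rep(10, 1), 0.25), list(n_drawn = 300L))
  expect_equal(mixture_density(list(narrow, off), matrix(0, 1, 1)), 0.5)
  expect_error(mixture_density(list(), matrix(0, 1, 1)), "empty")
})

test_that("proposal component densities are normalized and tail-heavy", {
  # Monte Carlo normalization check on a 2-D component (box integration)
  comp <- cardamis:::student_component(c(0.5, -0.2), diag(2), c(0.3, 0.15),
                                       1L)
  set.seed(12)
  lim <- 12
  n_mc <- 4e5
  pts <- rbind(runif(n_mc, 0.5 - lim, 0.5 + lim),
               runif(n_mc, -0.2 - lim, -0.2 + lim))
  mass <- mean(cardamis:::component_pdf(comp, pts)) * (2 * lim)^2
  expect_equal(mass, 1, tolerance = 0.05)
  # 1-D marginal agreement with dt(): the univariate component density
  comp1 <- cardamis:::student_component(0, matrix(1), 0.3, 1L)
  x <- seq(-3, 3, by = 0.25)
  expect_equal(cardamis:::component_pdf(comp1, matrix(x, 1)),
               dt(x / 0.3, df = 5) / 0.3, tolerance = 1e-12)
  # heavier tails than the Gaussian with matching scale
  far <- matrix(c(2, 0), 2, 1)
  g_pdf <- prod(dnorm(c(2, 0) / c(0.3, 0.15))) / (0.3 * 0.15)
  expect_gt(cardamis:::component_pdf(comp, far), g_pdf)
})

test_that("importance weights follow the tempered softmax", {
  # equal X2, equal q -> uniform
  expect_equal(update_weights(rep(2, 4), rep(1, 4), T = 1), rep(0.25, 4))
  # failed simulation gets zero
  expect_equal(update_weights(c(0, Inf), c(1, 1), T = 1), c(1, 0))
  # softmax of (0, -2)
  w <- update_weights(c(0, 2), c(1, 1), T = 1)
  expect_equal(w, c(1, exp(-2)) / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.8808, 0.1192))
  # q enters inversely
  expect_equal(update_weights(c(1, 1), c(4, 1), T = 1), c(0.2, 0.8))
  # all-failed set is a hard error
  expect_error(update_weights(c(Inf, Inf), c(1, 1), T = 1), "degenerate")
})

test_that("temperature rises with improvement and decays to 1 without", {
  expect_equal(update_temperature(5, FALSE), 4)
  expect_equal(update_temperature(1, FALSE), 1)
  expect_equal(update_temperature(1.1, FALSE), 1)
  expect_equal(update_temperature(9, TRUE, delta_best_X2 = 3), 10)
  expect_equal(update_temperature(4, TRUE, delta_best_X2 = 2.5), 6.5)

  # from T_max = 10, exactly 11 non-improving steps reach the floor
  T_cur <- 10
  n_steps <- 0
  while (T_cur > 1) {
    T_cur <- update_temperature(T_cur, FALSE)
    n_steps <- n_steps + 1
  }
  expect_equal(n_steps, 11)
  expect_identical(update_temperature(T_cur, FALSE), 1)
})

test_that("proposal fitting recovers weighted principal components", {
  # two equally weighted samples at +/-1 on axis 1 of a 3-D space
  U <- rbind(c(1, -1), c(0, 0), c(0, 0))
  comp <- fit_proposal(U, c(0.5, 0.5))
  expect_equal(sort(comp$scales, decreasing = TRUE),
               c(1, 1e-4, 1e-4))
  lead <- comp$axes[, which.max(comp$scales)]
  expect_equal(abs(lead), c(1, 0, 0))
  expect_equal(comp$center, c(0, 0, 0))

  # all weight on one sample: eigenvalue floor keeps the proposal proper
  comp1 <- fit_proposal(U, c(1, 0))
  expect_equal(comp1$scales, rep(1e-4, 3))
  expect_equal(comp1$center, c(1, 0, 0))

  # zero-weight samples are inert
  U3 <- cbind(U, c(5, 5, 5))
  comp2 <- fit_proposal(U3, c(1, 0, 0))
  expect_equal(comp2$center, comp1$center)
  expect_equal(comp2$scales, comp1$scales)

  expect_error(fit_proposal(U, c(0, 0)), "no positively weighted")
  # fewer than 2 positive weights with a previous component: inflate x1.5
  prev <- cardamis:::student_component(rep(0, 3), diag(3), rep(0.2, 3), 1L)
  infl <- fit_proposal(U, c(1, 0), previous = prev)
  expect_equal(infl$scales, rep(0.3, 3))
})

test_that("Kish effective sample size matches hand values", {
  expect_equal(effective_sample_size(rep(0.25, 4)), 4)
  expect_equal(effective_sample_size(c(1, 0, 0)), 1)
  expect_equal(effective_sample_size(c(0.5, 0.3, 0.2)), 1 / 0.38)
  expect_equal(round(effective_sample_size(c(0.5, 0.3, 0.2)), 4), 2.6316)
  expect_equal(effective_sample_size(c(0, 0)), 0)
  # unnormalised weights give the same answer
  expect_equal(effective_sample_size(c(5, 3, 2)), 1 / 0.38)
})

test_that("the loop is deterministic and respects the iteration contract", {
  cfg <- amis_config(n_samples_per_iter = 25, min_iterations = 12,
                     max_iterations = 40, seed = 9)
  r1 <- amis_run(toy_x2_2d, center = c(0, 0), config = cfg)
  r2 <- amis_run(toy_x2_2d, center = c(0, 0), config = cfg)
  expect_identical(r1$u, r2$u)
  expect_identical(r1$weight, r2$weight)
  # no termination check before min_iterations even though ESS is reached
  expect_gte(r1$n_iterations, 12)
  expect_equal(length(r1$X2), r1$n_iterations * 25)
  expect_equal(sum(r1$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(r1$trace$iteration) == 1))
  # temperatures stay within [1, T_max]
  expect_true(all(r1$trace$T >= 1 & r1$trace$T <= 10))
})

test_that("weights recomputed from scratch match the maintained weights", {
  cfg <- amis_config(n_samples_per_iter = 20, min_iterations = 10,
                     max_iterations = 15, seed = 3)
  r <- amis_run(toy_x2_2d, center = c(0, 0), config = cfg)
  expect_equal(recompute_weights(r, T = 1), r$weight, tolerance = 1e-10)
})

test_that("posterior moments match dense-grid quadrature on the 2-D toy", {
  cfg <- amis_config(n_samples_per_iter = 50, min_iterations = 200,
                     max_iterations = 200, seed = 17)
  r <- amis_run(toy_x2_2d, center = c(0, 0), config = cfg)
  w <- r$weight
  mu <- as.numeric(r$u %*% w)
  sd <- sqrt(as.numeric((r$u - mu)^2 %*% w))
  oracle <- grid_posterior_moments(toy_x2_2d, lower = c(-0.5, -1.5),
                                   upper = c(2, 0.5))
  expect_equal(mu, oracle$mean, tolerance = 0.05)
  expect_equal(sd, oracle$sd, tolerance = 0.05)
})
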