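# Shared fixtures, built in code at test time.

# a small synthetic measurement set with analytically simple traces
toy_measurement <- function(n_t = 101, HR = 60, qrs_onset = 0) {
  t <- seq(0, 1, length.out = n_t)
  base <- -0.2 * sin(pi * pmin(t / 0.6, 1))^2
  strain <- cbind(LVfw = base, IVS = base * 0.9, RVapex = base * 1.1,
                  RVmid = base * 1.05, RVbase = base * 0.95)
  measurement_set(time = t, strain = strain, HR = HR, EDV = 120,
                  EF = 0.55, RVD = 40, qrs_onset = qrs_onset)
}

# reference virtual patient (exact surrogate output, so X2(truth) = 0)
reference_vp <- function(HR = 71) {
  generate_virtual_patient(reference_vector(default_parameter_space()),
                           HR = HR)
}

# quadratic toy error in 2 transformed dimensions; posterior at T=1 is
# Gaussian with mean (0.8, -0.5) and SDs (0.3, 0.2)/sqrt(2)
toy_x2_2d <- function(U) {
  ((U[1, ] - 0.8) / 0.3)^2 + ((U[2, ] + 0.5) / 0.2)^2
}

# dense-grid quadrature oracle for weighted moments of exp(-x2) posteriors
grid_posterior_moments <- function(x2_fun, lower, upper, n = 401) {
  g1 <- seq(lower[1], upper[1], length.out = n)
  g2 <- seq(lower[2], upper[2], length.out = n)
  G <- rbind(rep(g1, times = n), rep(g2, each = n))
  w <- exp(-x2_fun(G))
  w <- w / sum(w)
  mu <- as.numeric(G %*% w)
  sd <- sqrt(as.numeric((G - mu)^2 %*% w))
  list(mean = mu, sd = sd)
}
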