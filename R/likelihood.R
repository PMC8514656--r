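# Strain likelihood: dimensionless summed squared error X^2 between model
# output and measurement, and the annealed (tempered) log-likelihood.

#' Construct a measurement set
#'
#' The observation vector for one patient (or virtual patient): five
#' segmental longitudinal strain traces on a common time grid plus global
#' scalars.
#'
#' @param time Numeric time grid (s), strictly increasing.
#' @param strain `n_t x 5` matrix of ED-referenced strain fractions with
#'   columns named `LVfw`, `IVS`, `RVapex`, `RVmid`, `RVbase` (any order).
#' @param HR Heart rate (bpm, > 0).
#' @param EDV LV end-diastolic volume (mL, > 0).
#' @param EF LV ejection fraction, in (0, 1).
#' @param RVD RV basal diameter (mm, > 0).
#' @param qrs_onset QRS onset time (s) on the trace time base.
#' @return An object of class `"measurement_set"`.
#' @export
measurement_set <- function(time, strain, HR, EDV, EF, RVD, qrs_onset = 0) {
  strain <- as.matrix(strain)
  if (is.unsorted(time, strictly = TRUE)) {
    stop("measurement time grid must be strictly increasing")
  }
  missing_seg <- setdiff(SEGMENTS, colnames(strain))
  if (length(missing_seg)) {
    stop(sprintf("missing strain column(s): %s",
                 paste(missing_seg, collapse = ", ")))
  }
  if (anyDuplicated(colnames(strain))) stop("duplicated strain columns")
  if (nrow(strain) != length(time)) {
    stop("strain trace length must equal time grid length")
  }
  if (!(EF > 0 && EF < 1)) stop("EF must lie strictly inside (0, 1)")
  if (!(HR > 0 && EDV > 0 && RVD > 0)) stop("HR, EDV and RVD must be positive")
  structure(
    list(time = as.numeric(time), strain = strain[, SEGMENTS, drop = FALSE],
         HR = HR, EDV = EDV, EF = EF, RVD = RVD, qrs_onset = qrs_onset),
    class = "measurement_set"
  )
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf(paste0("measurement_set: %d samples x 5 segments, HR %.0f bpm, ",
                     "EDV %.1f mL, EF %.3f, RVD %.1f mm\n"),
              length(x$time), x$HR, x$EDV, x$EF, x$RVD))
  invisible(x)
}

#' Default likelihood normalisation standard deviations
#'
#' One SD per error family, estimated a priori from typical measurement
#' variability; all overridable.
#'
#' @param sd_strain Strain SD (fraction).
#' @param sd_strain_rate Strain-rate SD (1/s).
#' @param sd_inter Inter-segmental strain-difference SD (fraction).
#' @param sd_EF EF SD (fraction).
#' @param sd_EDV EDV SD (mL).
#' @param sd_RVD RVD SD (mm).
#' @return Named list of class `"normalization_sds"`.
#' @export
normalization_sds <- function(sd_strain = 0.02, sd_strain_rate = 0.2,
                              sd_inter = 0.02, sd_EF = 0.05,
                              sd_EDV = 20, sd_RVD = 4) {
  sds <- list(sd_strain = sd_strain, sd_strain_rate = sd_strain_rate,
              sd_inter = sd_inter, sd_EF = sd_EF, sd_EDV = sd_EDV,
              sd_RVD = sd_RVD)
  if (any(unlist(sds) <= 0)) stop("all normalisation SDs must be positive")
  structure(sds, class = "normalization_sds")
}

#' Systolic fitting window of a measurement set
#'
#' Diastolic strain is excluded from the fit (drift makes it unreliable):
#' the window runs from QRS onset until 100 ms after the peak shortening
#' (most negative strain) of the segment whose shortening phase ends last,
#' clipped to the end of the trace.
#'
#' @param m A `measurement_set`.
#' @return Numeric vector `c(t_start, t_end)` in seconds.
#' @export
systolic_window <- function(m) {
  peak_times <- rep(NA_real_, length(SEGMENTS))
  for (j in seq_along(SEGMENTS)) {
    tr <- m$strain[, SEGMENTS[j]]
    if (diff(range(tr)) == 0) {
      warning(sprintf("flat strain trace for %s: no peak, excluded from window",
                      SEGMENTS[j]))
      next
    }
    peak_times[j] <- m$time[which.min(tr)]
  }
  if (all(is.na(peak_times))) stop("no segment has a defined peak strain")
  t_end <- min(max(peak_times, na.rm = TRUE) + 0.100, max(m$time))
  c(m$qrs_onset, t_end)
}

# central-difference rate on a (possibly non-uniform) grid
central_rate <- function(x, t) {
  n <- length(x)
  r <- numeric(n)
  r[1] <- (x[2] - x[1]) / (t[2] - t[1])
  r[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  r[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  r
}

#' Error breakdown between model output and measurement
#'
#' Computes the dimensionless summed squared error: per-segment strain and
#' strain-rate terms over the systolic window, inter-segmental strain
#' differences over the three RV segment pairs, and squared normalised
#' errors in EF, EDV and RVD.  Each windowed term is the mean squared
#' residual over the in-window samples divided by its variance; `X2` is the
#' sum of all terms.
#'
#' Model strain is linearly interpolated onto the measurement grid (the
#' model cycle is treated as periodic).
#'
#' @param mo A `model_output`.
#' @param m A `measurement_set`.
#' @param sds A `normalization_sds`.
#' @return List of class `"error_breakdown"` with per-term components and
#'   total `X2` (set to `Inf` for a non-converged model output).
#' @export
compute_error_terms <- function(mo, m, sds = normalization_sds()) {
  if (!isTRUE(mo$converged)) {
    return(structure(list(e2_strain = NULL, e2_strain_rate = NULL,
                          e2_inter = NULL, e2_EF = NA_real_,
                          e2_EDV = NA_real_, e2_RVD = NA_real_, X2 = Inf),
                     class = "error_breakdown"))
  }
  win <- systolic_window(m)
  in_win <- m$time >= win[1] & m$time <= win[2]
  n_w <- sum(in_win)
  if (n_w < 2) stop("systolic window holds fewer than 2 measurement samples")

  # periodic interpolation of the model traces onto the measurement grid
  T_cycle <- 60 / mo$HR
  t_mod <- c(mo$time, T_cycle)
  interp_seg <- function(col) {
    y <- c(col, col[1])
    stats::approx(t_mod, y, xout = m$time %% T_cycle, rule = 2)$y
  }
  mod_strain <- vapply(SEGMENTS, function(s) interp_seg(mo$strain[, s]),
                       numeric(length(m$time)))

  e2_strain <- e2_rate <- stats::setNames(numeric(length(SEGMENTS)), SEGMENTS)
  for (s in SEGMENTS) {
    res <- mod_strain[, s] - m$strain[, s]
    e2_strain[s] <- mean(res[in_win]^2) / sds$sd_strain^2
    rate_res <- central_rate(mod_strain[, s], m$time) -
      central_rate(m$strain[, s], m$time)
    e2_rate[s] <- mean(rate_res[in_win]^2) / sds$sd_strain_rate^2
  }

  pairs <- list(c("RVapex", "RVmid"), c("RVmid", "RVbase"),
                c("RVapex", "RVbase"))
  e2_inter <- stats::setNames(
    numeric(3), vapply(pairs, paste, "", collapse = "-"))
  for (k in seq_along(pairs)) {
    p <- pairs[[k]]
    d_mod <- mod_strain[, p[1]] - mod_strain[, p[2]]
    d_meas <- m$strain[, p[1]] - m$strain[, p[2]]
    e2_inter[k] <- mean((d_mod - d_meas)[in_win]^2) / sds$sd_inter^2
  }

  e2_EF <- as.numeric(((mo$EF - m$EF) / sds$sd_EF)^2)
  e2_EDV <- as.numeric(((mo$EDV - m$EDV) / sds$sd_EDV)^2)
  e2_RVD <- as.numeric(((mo$RVD - m$RVD) / sds$sd_RVD)^2)

  X2 <- sum(e2_strain) + sum(e2_rate) + sum(e2_inter) + e2_EF + e2_EDV + e2_RVD
  structure(list(e2_strain = e2_strain, e2_strain_rate = e2_rate,
                 e2_inter = e2_inter, e2_EF = e2_EF, e2_EDV = e2_EDV,
                 e2_RVD = e2_RVD, X2 = X2),
            class = "error_breakdown")
}

#' Annealed (tempered) unnormalised log-likelihood
#'
#' `log p(z | theta, T) = -X2 / T`.  Temperature `T >= 1` flattens the
#' likelihood to aid global search; `T = 1` recovers the target posterior.
#'
#' @param X2 Summed squared error (>= 0, possibly `Inf`).
#' @param T Annealing temperature (>= 1).
#' @return Log-likelihood (`-Inf` for failed simulations).
#' @export
annealed_log_likelihood <- function(X2, T = 1) {
  stopifnot(all(T >= 1))
  -X2 / T
}
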