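# Derived regional RV tissue properties: contractility (max rate of active
# stress rise), activation delay (the dT parameter), compliance (inverse
# slope of the end-diastolic passive stress-strain relation) and myocardial
# work density (area of the fibre stress-strain loop).

#' Segmental contractility
#'
#' Maximum rate of active stress rise over the cycle, the tissue-level
#' analogue of dP/dt_max.  Computed as the maximum forward difference of
#' the active stress trace; 0 if the stress never rises.
#'
#' @param active_stress Active stress trace (kPa), length >= 2.
#' @param time Matching time grid (s).
#' @return Contractility (kPa/s, >= 0).
#' @export
contractility <- function(active_stress, time) {
  stopifnot(length(active_stress) >= 2, length(time) == length(active_stress))
  d <- diff(active_stress) / diff(time)
  max(0, max(d))
}

#' Segmental end-diastolic compliance
#'
#' Inverse slope of the passive fibre stress-strain relation evaluated at
#' the end-diastolic strain (taken just before first ventricular
#' activation): `1 / (sigma0 * k1 * exp(k1 * eps_ED))`.  Larger values mean
#' a more compliant (less stiff) wall.
#'
#' @param k1 Passive stiffness exponent.
#' @param eps_ED Fibre strain at the pre-activation instant.
#' @param sigma0 Passive stress scale (kPa); default the model constant.
#' @return Compliance (strain/kPa, > 0).
#' @export
compliance <- function(k1, eps_ED, sigma0 = SIGMA0_KPA) {
  1 / (sigma0 * k1 * exp(k1 * eps_ED))
}

#' Myocardial work density
#'
#' Signed shoelace area of the fibre stress-strain loop over one cycle
#' (kPa, numerically equal to kJ/m^3).  The sign convention makes
#' physiological loops - shortening under high stress, re-lengthening under
#' low stress - positive; reversing the traversal direction flips the sign.
#'
#' @param total_stress Total fibre stress trace (kPa), one cycle.
#' @param strain Matching strain trace (closed over the cycle).
#' @return Work density (kPa).
#' @export
work_density <- function(total_stress, strain) {
  n <- length(strain)
  stopifnot(length(total_stress) == n)
  if (n < 3) stop("work_density needs at least 3 points")
  j <- c(2:n, 1)
  0.5 * sum(strain * total_stress[j] - strain[j] * total_stress)
}

# strain at the last grid point before the earliest activation onset
pre_activation_index <- function(time, qrs_onset, dT_ms, T_cycle) {
  t_on <- (qrs_onset + min(dT_ms) / 1000) %% T_cycle
  idx <- which(time < t_on)
  if (!length(idx)) length(time) else max(idx)
}

#' Tissue properties of one simulated cycle
#'
#' Contractility is evaluated on the isometric active-stress capacity
#' `SfAct * a(t)` (the realised active stress in a quasi-static force
#' balance is load-determined); compliance on the passive stress-strain
#' slope at the pre-activation strain; work density on the realised
#' stress-strain loop.
#'
#' @param mo A converged `model_output`.
#' @param theta The physical parameter vector that produced it.
#' @param qrs_onset QRS onset (s).
#' @return Data frame with one row per RV segment and columns `segment`,
#'   `contractility` (kPa/s), `activation_delay` (ms), `compliance`
#'   (strain/kPa), `work_density` (kPa).
#' @export
tissue_properties <- function(mo, theta, qrs_onset = 0) {
  stopifnot(isTRUE(mo$converged))
  T_cycle <- 60 / mo$HR
  dT_all <- vapply(SEGMENTS, function(s) theta[[paste0("dT_", s)]], 0)
  i_pre <- pre_activation_index(mo$time, qrs_onset, dT_all, T_cycle)
  rows <- lapply(RV_SEGMENTS, function(seg) {
    k1 <- theta[[paste0("k1_", seg)]]
    # contractility is evaluated on the isometric active-stress capacity
    # SfAct * a(t): in the quasi-static force balance the realised active
    # stress equals load minus passive stress and so carries no intrinsic
    # contractile information
    tau <- (mo$time - qrs_onset -
              theta[[paste0("dT_", seg)]] / 1000) %% T_cycle
    iso <- theta[[paste0("SfAct_", seg)]] *
      activation_waveform(tau, dT = 0, RSD = theta[["RSD"]], HR = mo$HR)
    # compliance uses the raw (solver) strain; recover it from the
    # re-referenced trace and the reference length at ED
    eps_ref_pre <- mo$strain[i_pre, seg]
    # strain re-referencing preserved (1 + eps) ratios; the passive state at
    # the pre-activation instant is diastolic, where total = passive stress
    sig_pas <- mo$passive_stress[i_pre, seg]
    eps_raw_pre <- log(sig_pas / SIGMA0_KPA + 1) / k1
    data.frame(
      segment = seg,
      contractility = contractility(iso, mo$time),
      activation_delay = theta[[paste0("dT_", seg)]],
      compliance = compliance(k1, eps_raw_pre),
      work_density = work_density(mo$total_stress[, seg], mo$strain[, seg])
    )
  })
  do.call(rbind, rows)
}

#' Posterior distributions of RV tissue properties
#'
#' Maps every finite-X^2 sample of a posterior sample set through the
#' forward model and the tissue-property definitions, carrying the sample's
#' temperature-1 weight.  Failed simulations are skipped (zero weight).
#'
#' @param result An `amis_result`.
#' @param m The `measurement_set` the run was fitted to.
#' @param min_weight Samples with weight below this fraction of the maximum
#'   weight are skipped to save forward evaluations (default 0: keep all).
#' @param dt Forward-model time step (s).
#' @return List of class `"tissue_posterior"` with `properties` (data frame:
#'   sample index, weight, segment, the four properties) and `segments`.
#' @export
posterior_tissue_distributions <- function(result, m, min_weight = 0,
                                           dt = 0.002) {
  keep <- which(is.finite(result$X2) &
                  result$weight >= min_weight * max(result$weight))
  rows <- vector("list", length(keep))
  for (ii in seq_along(keep)) {
    i <- keep[ii]
    theta <- stats::setNames(as.numeric(result$theta[i, ]),
                             names(result$theta))
    mo <- forward_model(theta, m, backend = result$backend, dt = dt,
                        space = result$space)
    if (!isTRUE(mo$converged)) next
    tp <- tissue_properties(mo, theta, qrs_onset = m$qrs_onset)
    tp$sample <- i
    tp$weight <- result$weight[i]
    rows[[ii]] <- tp
  }
  props <- do.call(rbind, rows)
  if (is.null(props)) stop("no converged samples to map to tissue properties")
  props$weight <- props$weight / sum(props$weight[!duplicated(props$sample)])
  structure(list(properties = props, segments = RV_SEGMENTS),
            class = "tissue_posterior")
}

#' Summary table of posterior tissue properties
#'
#' @param tp A `tissue_posterior`.
#' @return Data frame with one row per segment and property: weighted mean,
#'   SD, and 2.5/50/97.5 weighted percentiles.
#' @export
tissue_property_table <- function(tp) {
  props <- c("contractility", "activation_delay", "compliance",
             "work_density")
  out <- list()
  for (seg in tp$segments) {
    sub <- tp$properties[tp$properties$segment == seg, ]
    w <- sub$weight / sum(sub$weight)
    for (p in props) {
      x <- sub[[p]]
      mu <- sum(w * x)
      sdv <- sqrt(max(0, sum(w * (x - mu)^2)))
      qs <- weighted_quantile(x, w, c(0.025, 0.5, 0.975))
      out[[length(out) + 1L]] <- data.frame(
        segment = seg, property = p, mean = mu, sd = sdv,
        p2.5 = qs[1], p50 = qs[2], p97.5 = qs[3])
    }
  }
  do.call(rbind, out)
}
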