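# Surrogate multi-segment ventricular mechanics model.
#
# The model maps the 20-parameter vector to one steady cardiac cycle of
# segmental fibre strain and stress plus global measures (EDV, EF, RVD).
# Each wall carries a prescribed load-stress waveform (diastolic baseline
# scaled by cardiac output, systolic plateau gated by the wall's own
# contractile capacity); segment strain is solved pointwise from the
# constitutive stress balance.  The parameter semantics follow their
# physiological roles: SfAct scales active stress, k1 the passive stiffness
# exponent, dT shifts mechanical activation, AmRef sets wall size, RSD
# scales systole duration and Q0 the diastolic load level.

SIGMA0_KPA <- 0.5      # passive stress scale, fixed
ACT_SLOPE <- 5         # active length-dependence slope (physiological strain)
P_DIA_KPA <- 1         # diastolic load baseline at reference cardiac output
P_SYS_KPA <- c(LVfw = 12, IVS = 12, RVfw = 4)  # systolic load plateaus
Q0_REF_LMIN <- 5.1     # reference cardiac output, L/min
RAMP_S <- 0.030            # down-ramp duration of the load waveform (s)
RAMP_UP_FRACTION <- 0.25   # up-ramp duration as a fraction of T_act
GATE_OFF_FRACTION <- 0.85  # gate closes at this fraction of T_act
C_RVD_MM_PER_CM <- 10  # RV basal diameter calibration (surrogate-only)

#' Mechanical activation waveform
#'
#' A smooth sin^2 pulse starting `dT` milliseconds after QRS onset with
#' duration `T_act = 0.4 * RSD * sqrt(60/HR)` seconds:
#' `a(t) = sin^2(pi * tau / T_act)` for `tau = t - qrs_onset - dT/1000`
#' within `[0, T_act]`, and 0 outside.  Peak value 1 at mid-activation.
#'
#' @param t Time (s), vectorised.
#' @param dT Activation delay (ms) relative to QRS onset.
#' @param RSD Relative systole duration (dimensionless, > 0).
#' @param HR Heart rate (bpm, > 0).
#' @param qrs_onset QRS onset time (s).
#' @return Activation level in \[0, 1\], same length as `t`.
#' @export
activation_waveform <- function(t, dT, RSD, HR, qrs_onset = 0) {
  stopifnot(RSD > 0, HR > 0)
  T_act <- 0.4 * RSD * sqrt(60 / HR)
  tau <- t - qrs_onset - dT / 1000
  a <- numeric(length(t))
  inside <- tau >= 0 & tau <= T_act
  a[inside] <- sin(pi * tau[inside] / T_act)^2
  a
}

#' Total fibre stress from the surrogate constitutive law
#'
#' `sigma = SfAct * a * max(0, 1 + 5*eps) + sigma0 * (exp(k1*eps) - 1)`
#' with `sigma0 = 0.5` kPa.  The active term is linear in activation and
#' carries a linear length-dependence that vanishes below `eps = -0.2`; the
#' slope is calibrated so that reference parameters yield physiological
#' systolic strain (about -0.2) and ejection fraction under the prescribed
#' wall loads; the
#' passive term is exponential in strain and zero at the reference length.
#'
#' @param eps Fibre strain (dimensionless), vectorised.
#' @param a Activation level in \[0, 1\].
#' @param SfAct Active stress scaling factor (kPa).
#' @param k1 Passive stiffness exponent (dimensionless).
#' @return Total fibre stress (kPa).
#' @export
total_fiber_stress <- function(eps, a, SfAct, k1) {
  SfAct * a * pmax(0, 1 + ACT_SLOPE * eps) + SIGMA0_KPA * (expm1(k1 * eps))
}

#' Solve the pointwise stress balance for segment strain
#'
#' Finds the strain at which [total_fiber_stress()] equals the prescribed
#' load, by bisection on \[-0.5, 1\].  The stress is non-decreasing in
#' strain on that bracket so the root is unique when it exists.
#'
#' @param load Load stress (kPa, >= 0), vectorised.
#' @param a Activation level, same length (or scalar).
#' @param SfAct,k1 Constitutive parameters, same length (or scalar).
#' @param tol Stress tolerance (kPa).
#' @return Strain values; `NA` where no root exists in the bracket (a
#'   non-physiological sample, treated by callers as a failed simulation).
#' @export
solve_segment_strain <- function(load, a, SfAct, k1, tol = 1e-9) {
  n <- max(length(load), length(a), length(SfAct), length(k1))
  load <- rep_len(load, n); a <- rep_len(a, n)
  SfAct <- rep_len(SfAct, n); k1 <- rep_len(k1, n)
  lo <- rep_len(-0.5, n); hi <- rep_len(1.0, n)
  f_lo <- total_fiber_stress(lo, a, SfAct, k1) - load
  f_hi <- total_fiber_stress(hi, a, SfAct, k1) - load
  ok <- f_lo <= 0 & f_hi >= 0
  for (it in 1:52) {
    mid <- 0.5 * (lo + hi)
    f_mid <- total_fiber_stress(mid, a, SfAct, k1) - load
    take_lo <- f_mid > 0
    hi[take_lo] <- mid[take_lo]
    lo[!take_lo] <- mid[!take_lo]
  }
  eps <- 0.5 * (lo + hi)
  resid <- abs(total_fiber_stress(eps, a, SfAct, k1) - load)
  eps[!ok | resid >= tol] <- NA_real_
  eps
}

# Smoothed 0/1 cosine step over the given ramp duration starting at x = 0.
cosine_step <- function(x, ramp) {
  y <- pmin(pmax(x / ramp, 0), 1)
  0.5 * (1 - cos(pi * y))
}

# Periodic systole gate: slow up-ramp from phase 0 (the load builds up with
# activation, as in isovolumic contraction, so the fibre is never stretched
# above its diastolic length at systole onset), fast down-ramp completing at
# gate_end (ejection ends while the fibre is still contracting).
systole_gate <- function(t, qrs_onset, T_act, T_cycle) {
  phi <- (t - qrs_onset) %% T_cycle
  ramp_up <- RAMP_UP_FRACTION * T_act
  gate_end <- GATE_OFF_FRACTION * T_act
  g <- function(x) {
    cosine_step(x, ramp_up) - cosine_step(x - (gate_end - RAMP_S), RAMP_S)
  }
  g(phi) + g(phi + T_cycle) + g(phi - T_cycle)
}

#' Simulate one steady cardiac cycle
#'
#' Builds per-wall load-stress waveforms, solves every segment's strain at
#' every time point, re-references strains to the end-diastolic instant
#' (time of maximum LV cavity volume) and derives EDV, EF (LV spherical
#' geometry) and the RV basal diameter.
#'
#' The load waveform of wall `w` is
#' `L_w(t) = B + (P_sys,w^eff - B) * s(t)` with diastolic baseline
#' `B = P_dia * Q0 / Q0_ref`, systole gate `s(t)` (cosine-ramped window of
#' duration `T_act` after QRS onset) and effective systolic plateau
#' `P_sys,w^eff = max(B, P_sys,w * min(1, mean(SfAct_w)/SfAct_ref))`: a wall
#' generates systolic load only in proportion to its contractile capacity,
#' so a fully non-contractile heart carries a constant load and flat strain.
#'
#' @param theta Named physical parameter vector (see
#'   [default_parameter_space()]); validated against `space`.
#' @param HR Heart rate (bpm) in \[30, 200\].
#' @param dt Time step (s); default 0.002.
#' @param qrs_onset QRS onset time (s) within the cycle.
#' @param space Parameter space used for validation and naming.
#' @return An object of class `"model_output"`: list with `time` (s),
#'   `strain` (n_t x 5 matrix, ED-referenced), `active_stress`,
#'   `passive_stress`, `total_stress` (kPa matrices), `EDV` (mL), `EF`
#'   (fraction), `RVD` (mm), `HR`, `t_ED` (s), `converged` (flag).
#' @export
simulate_heart <- function(theta, HR, dt = 0.002, qrs_onset = 0,
                           space = default_parameter_space()) {
  stopifnot(HR >= 30, HR <= 200)
  theta <- validate_parameters(space, theta)
  T_cycle <- 60 / HR
  n_t <- round(T_cycle / dt)
  t <- (seq_len(n_t) - 1) * dt

  RSD <- theta[["RSD"]]; Q0 <- theta[["Q0"]]
  T_act <- 0.4 * RSD * sqrt(60 / HR)
  B <- P_DIA_KPA * Q0 / Q0_REF_LMIN
  gate <- systole_gate(t, qrs_onset, T_act, T_cycle)

  sfact_ref <- 120
  seg_wall <- c(LVfw = "LVfw", IVS = "IVS",
                RVapex = "RVfw", RVmid = "RVfw", RVbase = "RVfw")
  sfact <- vapply(SEGMENTS, function(s) theta[[paste0("SfAct_", s)]], 0)
  k1 <- vapply(SEGMENTS, function(s) theta[[paste0("k1_", s)]], 0)
  dT <- vapply(SEGMENTS, function(s) theta[[paste0("dT_", s)]], 0)

  wall_mean_sfact <- vapply(WALLS, function(w) {
    mean(sfact[SEGMENTS[seg_wall == w]])
  }, 0)
  p_sys_eff <- stats::setNames(
    pmax(B, P_SYS_KPA[WALLS] * pmin(1, wall_mean_sfact[WALLS] / sfact_ref)),
    WALLS)

  strain_raw <- act <- matrix(NA_real_, n_t, length(SEGMENTS),
                              dimnames = list(NULL, SEGMENTS))
  load_mat <- matrix(NA_real_, n_t, length(SEGMENTS),
                     dimnames = list(NULL, SEGMENTS))
  for (j in seq_along(SEGMENTS)) {
    seg <- SEGMENTS[j]
    w <- seg_wall[[seg]]
    load_mat[, j] <- B + (p_sys_eff[[w]] - B) * gate
    # wrap the activation clock onto the cycle so negative/large delays work
    tau <- (t - qrs_onset - dT[j] / 1000) %% T_cycle
    act[, j] <- activation_waveform(tau, dT = 0, RSD = RSD, HR = HR,
                                    qrs_onset = 0)
  }
  # one batched bisection over all time points and segments
  eps_all <- solve_segment_strain(as.numeric(load_mat), as.numeric(act),
                                  rep(sfact, each = n_t),
                                  rep(k1, each = n_t))
  strain_raw[] <- eps_all

  converged <- !anyNA(strain_raw)
  if (!converged) {
    return(structure(list(time = t, strain = strain_raw,
                          active_stress = NULL, passive_stress = NULL,
                          total_stress = NULL, EDV = NA_real_, EF = NA_real_,
                          RVD = NA_real_, HR = HR, t_ED = NA_real_,
                          converged = FALSE),
                     class = "model_output"))
  }

  active <- sweep(act, 2, sfact, `*`) * pmax(0, 1 + ACT_SLOPE * strain_raw)
  passive <- SIGMA0_KPA * expm1(sweep(strain_raw, 2, k1, `*`))
  total <- active + passive

  # ED = instant of maximum LV cavity volume (max LVfw strain)
  i_ED <- which.max(strain_raw[, "LVfw"])
  ref_len <- 1 + strain_raw[i_ED, ]
  strain <- sweep(1 + strain_raw, 2, ref_len, `/`) - 1

  r0 <- sqrt(theta[["AmRef_LVfw"]] / (4 * pi))          # cm
  vol <- (4 / 3) * pi * r0^3 * (1 + strain[, "LVfw"])^3 # mL
  EDV <- max(vol)
  EF <- (max(vol) - min(vol)) / max(vol)
  r_rv <- sqrt(theta[["AmRef_RVfw"]] / (4 * pi))        # cm
  RVD <- as.numeric(C_RVD_MM_PER_CM * 2 * r_rv *
                      (1 + strain[i_ED, "RVbase"]))

  out <- list(time = t, strain = strain,
              active_stress = active, passive_stress = passive,
              total_stress = total,
              EDV = EDV, EF = EF, RVD = RVD, HR = HR,
              t_ED = t[i_ED], converged = is.finite(EDV) && is.finite(EF) &&
                is.finite(RVD) && EF >= 0 && EF <= 1 && EDV > 0)
  structure(out, class = "model_output")
}

#' @export
print.model_output <- function(x, ...) {
  cat(sprintf(paste0("model_output: %d time points, HR %.0f bpm, ",
                     "EDV %.1f mL, EF %.3f, RVD %.1f mm, converged: %s\n"),
              length(x$time), x$HR, x$EDV, x$EF, x$RVD, x$converged))
  invisible(x)
}

# ---- pluggable forward-model backends ---------------------------------

fm_registry <- new.env(parent = emptyenv())

#' Register or list forward-model backends
#'
#' The estimation loop calls the forward model only through
#' [forward_model()], so the surrogate can be swapped for an external
#' simulator (e.g. a compiled cardiovascular model driven through a system
#' call) by registering a function with the same contract.
#'
#' @param name Backend name.
#' @param fun Function `(theta, HR, dt, qrs_onset, space) -> model_output`.
#' @export
register_forward_backend <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = fm_registry)
  invisible(name)
}

#' @rdname register_forward_backend
#' @export
forward_backends <- function() sort(ls(fm_registry))

#' Evaluate the forward model for a measurement context
#'
#' Dispatches to the registered backend (the built-in surrogate by default),
#' using the measurement's heart rate and QRS onset.  A backend error is
#' converted into a non-converged output rather than propagating, so the
#' sampler can assign the sample zero likelihood.
#'
#' @param theta Physical parameter vector.
#' @param measurement A `measurement_set` (see [measurement_set()]).
#' @param backend Backend name; default `"surrogate"`.
#' @param dt Time step (s).
#' @param space Parameter space.
#' @return A `model_output`.
#' @export
forward_model <- function(theta, measurement, backend = "surrogate",
                          dt = 0.002, space = default_parameter_space()) {
  if (!exists(backend, envir = fm_registry, inherits = FALSE)) {
    stop(sprintf("unknown forward-model backend '%s' (registered: %s)",
                 backend, paste(forward_backends(), collapse = ", ")))
  }
  fun <- get(backend, envir = fm_registry)
  out <- tryCatch(
    fun(theta, HR = measurement$HR, dt = dt,
        qrs_onset = measurement$qrs_onset, space = space),
    error = function(e) NULL
  )
  if (is.null(out) || !inherits(out, "model_output") || !isTRUE(out$converged)) {
    if (is.null(out) || !inherits(out, "model_output")) {
      out <- structure(list(time = numeric(0), strain = NULL,
                            EDV = NA_real_, EF = NA_real_, RVD = NA_real_,
                            HR = measurement$HR, t_ED = NA_real_,
                            converged = FALSE),
                       class = "model_output")
    }
  }
  out
}
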