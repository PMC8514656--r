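# Dataset plumbing: measurement-set files, virtual-patient generation,
# posterior persistence, run reports, and the command-line front end.

STRAIN_COLS <- c("time_s", "RVapex", "RVmid", "RVbase", "LVfw", "IVS")

#' Write / read a measurement dataset directory
#'
#' Layout: `strain.csv` with columns `time_s, RVapex, RVmid, RVbase, LVfw,
#' IVS` (strain as dimensionless fraction) and `meta.yaml` with `HR_bpm`,
#' `EDV_mL`, `EF`, `RVD_mm`, `qrs_onset_s`.  The round trip is lossless to
#' better than 1e-9.
#'
#' @param m A `measurement_set`.
#' @param dir Dataset directory (created if missing).
#' @return `write_measurement_set()` returns `dir` invisibly;
#'   `read_measurement_set()` returns a validated `measurement_set`.
#' @export
write_measurement_set <- function(m, dir) {
  stopifnot(inherits(m, "measurement_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(time_s = m$time,
                   RVapex = m$strain[, "RVapex"],
                   RVmid = m$strain[, "RVmid"],
                   RVbase = m$strain[, "RVbase"],
                   LVfw = m$strain[, "LVfw"],
                   IVS = m$strain[, "IVS"])
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   file.path(dir, "strain.csv"), row.names = FALSE,
                   quote = FALSE)
  yaml::write_yaml(list(HR_bpm = m$HR, EDV_mL = m$EDV, EF = m$EF,
                        RVD_mm = m$RVD, qrs_onset_s = m$qrs_onset),
                   file.path(dir, "meta.yaml"), precision = 15)
  invisible(dir)
}

#' @rdname write_measurement_set
#' @export
read_measurement_set <- function(dir) {
  csv <- file.path(dir, "strain.csv")
  meta_path <- file.path(dir, "meta.yaml")
  if (!file.exists(csv)) stop(sprintf("missing %s", csv))
  if (!file.exists(meta_path)) stop(sprintf("missing %s", meta_path))
  df <- utils::read.csv(csv)
  missing_cols <- setdiff(STRAIN_COLS, names(df))
  if (length(missing_cols)) {
    stop(sprintf("strain.csv is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  meta <- yaml::read_yaml(meta_path)
  need <- c("HR_bpm", "EDV_mL", "EF", "RVD_mm", "qrs_onset_s")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop(sprintf("meta.yaml is missing field(s): %s",
                 paste(miss, collapse = ", ")))
  }
  measurement_set(time = df$time_s,
                  strain = as.matrix(df[, SEGMENTS]),
                  HR = meta$HR_bpm, EDV = meta$EDV_mL, EF = meta$EF,
                  RVD = meta$RVD_mm, qrs_onset = meta$qrs_onset_s)
}

#' Generate a virtual patient from known parameters
#'
#' Runs the forward model at `theta` and packages its outputs verbatim as a
#' measurement set, so the true parameter values are known exactly and
#' fitting the dataset back gives `X2(theta_true) = 0`.  Additive Gaussian
#' strain noise is available as an extension but off by default.
#'
#' @param theta Physical parameter vector.
#' @param HR Heart rate (bpm).
#' @param noise_sd Optional strain noise SD (fraction); `NULL` for none.
#' @param qrs_onset QRS onset (s).
#' @param seed Seed used when noise is drawn (recorded in provenance).
#' @param dt Forward-model time step (s).
#' @param space Parameter space.
#' @return Object of class `"virtual_patient"`: `true_theta`, `dataset`
#'   (a `measurement_set`), and `provenance`.
#' @export
generate_virtual_patient <- function(theta, HR, noise_sd = NULL,
                                     qrs_onset = 0, seed = 1L, dt = 0.002,
                                     space = default_parameter_space()) {
  theta <- validate_parameters(space, theta)
  mo <- simulate_heart(theta, HR, dt = dt, qrs_onset = qrs_onset,
                       space = space)
  if (!isTRUE(mo$converged)) {
    stop("forward simulation at the requested parameters did not converge; ",
         "choose another theta")
  }
  strain <- mo$strain
  if (!is.null(noise_sd)) {
    set.seed(seed)
    strain <- strain + matrix(stats::rnorm(length(strain), 0, noise_sd),
                              nrow(strain), ncol(strain))
  }
  dataset <- measurement_set(time = mo$time, strain = strain, HR = HR,
                             EDV = mo$EDV, EF = mo$EF, RVD = mo$RVD,
                             qrs_onset = qrs_onset)
  structure(list(true_theta = theta, dataset = dataset,
                 provenance = list(seed = seed, backend = "surrogate",
                                   dt = dt, noise_sd = noise_sd,
                                   package_version =
                                     as.character(utils::packageVersion("cardamis")))),
            class = "virtual_patient")
}

#' Canned virtual-patient parameter presets
#'
#' Three parameter vectors emulating early disease stages of an RV
#' cardiomyopathy: `healthy` (reference tissue everywhere), `early` (a
#' mildly weakened, slightly late basal RV segment), and `overt` (weakened
#' and stiffened basal and mid segments with basal activation delay and a
#' mildly enlarged RV).  Magnitudes are subclinical-to-early on purpose:
#' the resulting datasets differ from the reference heart on the scale the
#' likelihood SDs encode (X^2 of order 1e2), the regime the annealed
#' sampler is designed to resolve.
#'
#' @return Named list of physical parameter vectors.
#' @export
virtual_patient_presets <- function() {
  space <- default_parameter_space()
  base <- reference_vector(space)
  early <- base
  early[["SfAct_RVbase"]] <- 108
  early[["dT_RVbase"]] <- 8
  overt <- base
  overt[["SfAct_RVbase"]] <- 100
  overt[["SfAct_RVmid"]] <- 110
  overt[["k1_RVbase"]] <- 12
  overt[["dT_RVbase"]] <- 15
  overt[["dT_RVmid"]] <- 6
  overt[["AmRef_RVfw"]] <- 107
  list(healthy = base, early = early, overt = overt)
}

#' Sample with maximum likelihood in a posterior sample set
#'
#' @param result An `amis_result` (or any list with `X2` and `iteration`).
#' @return Index of the sample with minimal X^2; ties broken by lowest
#'   iteration, then lowest index.
#' @export
select_max_likelihood_sample <- function(result) {
  finite <- which(is.finite(result$X2))
  if (!length(finite)) stop("no sample with finite X2")
  o <- finite[order(result$X2[finite], result$iteration[finite], finite)]
  o[1]
}

#' Persist / load a posterior sample set as CSV
#'
#' Columns: the physical parameter values (one column per parameter), `X2`,
#' `iteration` and `weight_T1`.  A companion `trace.csv` stores the
#' per-iteration temperature, best X^2 and effective sample size.
#'
#' @param result An `amis_result`.
#' @param dir Output directory.
#' @return `write_sample_set()` returns `dir` invisibly;
#'   `read_sample_set()` returns a list with `samples` and `trace` data
#'   frames.
#' @export
write_sample_set <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- result$theta
  df$X2 <- result$X2
  df$iteration <- result$iteration
  df$weight_T1 <- result$weight
  utils::write.csv(df, file.path(dir, "samples.csv"), row.names = FALSE)
  utils::write.csv(result$trace, file.path(dir, "trace.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_sample_set
#' @export
read_sample_set <- function(dir) {
  list(samples = utils::read.csv(file.path(dir, "samples.csv")),
       trace = utils::read.csv(file.path(dir, "trace.csv")))
}

#' Markdown report of a finished estimation run
#'
#' @param result An `amis_result`.
#' @param path Output file; default returns the text invisibly.
#' @return Character vector of report lines.
#' @export
run_report <- function(result, path = NULL) {
  space <- result$space
  w <- result$weight
  lines <- c(
    "# Posterior estimation report", "",
    sprintf("- samples: %d over %d iterations (seed %d)",
            length(result$X2), result$n_iterations, result$seed),
    sprintf("- best X2: %.4g", min(result$X2)),
    sprintf("- effective sample size (T=1): %.1f",
            effective_sample_size(w)),
    sprintf("- converged: %s", result$converged), "",
    "| parameter | unit | mean | sd | p2.5 | p50 | p97.5 |",
    "|---|---|---|---|---|---|---|")
  for (i in seq_along(space$names)) {
    x <- result$theta[[space$names[i]]]
    mu <- sum(w * x)
    sdv <- sqrt(max(0, sum(w * (x - mu)^2)))
    qs <- weighted_quantile(x, w, c(0.025, 0.5, 0.975))
    lines <- c(lines, sprintf(
      "| %s | %s | %.4g | %.4g | %.4g | %.4g | %.4g |",
      space$names[i], space$specs[[i]]$unit, mu, sdv, qs[1], qs[2], qs[3]))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Command-line front end
#'
#' Thin dispatcher used by the `inst/cli/cardamis` script.  Subcommands:
#' `simulate` (forward model at given parameters), `virtual-patient`,
#' `fit` (posterior estimation), `metrics` (`mi` or `hdi` on persisted
#' sample sets) and `report`.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit code: 0 success, 2 usage/configuration error,
#'   1 runtime failure.
#' @export
cardamis_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cardamis <subcommand> [options]",
    "  simulate        --params <yaml> --hr <bpm> --out <dir>",
    "  virtual-patient --preset <name> --seed <int> --out <dir>",
    "  fit             --data <dir> --config <yaml> --seed <int> --out <dir>",
    "  metrics         mi|hdi --samples <dir> [--samples2 <dir>]",
    "                  --param <name> [--true <value>]",
    "  report          --run <dir> --out <file>",
    sep = "\n")
  opt <- function(flag, default = NULL) {
    i <- match(flag, argv)
    if (is.na(i) || i == length(argv)) default else argv[i + 1]
  }
  fail <- function(msg, code = 2L) {
    message(msg)
    code
  }
  if (!length(argv)) return(fail(usage))
  sub <- argv[1]
  res <- tryCatch(switch(
    sub,
    "simulate" = {
      params <- opt("--params"); hr <- as.numeric(opt("--hr", "60"))
      out <- opt("--out")
      if (is.null(params) || is.null(out)) return(fail(usage))
      theta_list <- yaml::read_yaml(params)
      space <- default_parameter_space()
      theta <- unlist(theta_list)[space$names]
      mo <- simulate_heart(theta, HR = hr, space = space)
      m <- measurement_set(mo$time, mo$strain, hr, mo$EDV, mo$EF, mo$RVD)
      write_measurement_set(m, out)
      message(sprintf("simulated: EDV %.1f mL, EF %.3f, RVD %.1f mm",
                      mo$EDV, mo$EF, mo$RVD))
      0L
    },
    "virtual-patient" = {
      preset <- opt("--preset", "healthy")
      seed <- as.integer(opt("--seed", "1"))
      out <- opt("--out")
      if (is.null(out)) return(fail(usage))
      presets <- virtual_patient_presets()
      if (!preset %in% names(presets)) {
        return(fail(sprintf("unknown preset '%s'", preset)))
      }
      vp <- generate_virtual_patient(presets[[preset]], HR = 71, seed = seed)
      write_measurement_set(vp$dataset, out)
      utils::write.csv(data.frame(parameter = names(vp$true_theta),
                                  value = as.numeric(vp$true_theta)),
                       file.path(out, "true_parameters.csv"),
                       row.names = FALSE)
      0L
    },
    "fit" = {
      data_dir <- opt("--data"); out <- opt("--out")
      seed <- as.integer(opt("--seed", "1"))
      cfg_path <- opt("--config")
      if (is.null(data_dir) || is.null(out)) return(fail(usage))
      if (!dir.exists(data_dir)) {
        return(fail(sprintf("data directory '%s' not found", data_dir)))
      }
      cfg_args <- if (!is.null(cfg_path)) yaml::read_yaml(cfg_path) else list()
      cfg <- do.call(amis_config, c(cfg_args, list(seed = seed)))
      m <- read_measurement_set(data_dir)
      result <- amis_estimate(m, config = cfg)
      write_sample_set(result, out)
      run_report(result, file.path(out, "report.md"))
      yaml::write_yaml(c(unclass(cfg), list(data = data_dir)),
                       file.path(out, "config.lock.yaml"))
      0L
    },
    "metrics" = {
      kind <- argv[2]
      s1 <- opt("--samples"); pname <- opt("--param")
      if (is.null(s1) || is.null(pname)) return(fail(usage))
      ss1 <- read_sample_set(s1)
      if (identical(kind, "mi")) {
        s2 <- opt("--samples2")
        if (is.null(s2)) return(fail(usage))
        ss2 <- read_sample_set(s2)
        mi <- mutual_information(ss1$samples[[pname]], ss2$samples[[pname]],
                                 ss1$samples$weight_T1, ss2$samples$weight_T1)
        cat(sprintf("MI %s: %.2f%%\n", pname, mi))
        0L
      } else if (identical(kind, "hdi")) {
        tv <- as.numeric(opt("--true"))
        hdi <- hdi_containing_true(ss1$samples[[pname]],
                                   ss1$samples$weight_T1, tv)
        cat(sprintf("HDI %s: %.2f%%\n", pname, hdi))
        0L
      } else fail(usage)
    },
    "report" = {
      run_dir <- opt("--run"); out <- opt("--out")
      if (is.null(run_dir) || is.null(out)) return(fail(usage))
      ss <- read_sample_set(run_dir)
      space <- default_parameter_space()
      w <- ss$samples$weight_T1
      lines <- c("# Posterior summary", "",
                 "| parameter | mean | p2.5 | p50 | p97.5 |",
                 "|---|---|---|---|---|")
      for (nm in space$names) {
        x <- ss$samples[[nm]]
        qs <- weighted_quantile(x, w, c(0.025, 0.5, 0.975))
        lines <- c(lines, sprintf("| %s | %.4g | %.4g | %.4g | %.4g |",
                                  nm, sum(w * x) / sum(w), qs[1], qs[2], qs[3]))
      }
      writeLines(lines, out)
      0L
    },
    fail(usage)
  ), error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(res))
}
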