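# Canonical segment / wall labels. Segment order fixes vector indexing
# throughout the package.
SEGMENTS <- c("LVfw", "IVS", "RVapex", "RVmid", "RVbase")
WALLS <- c("LVfw", "IVS", "RVfw")
RV_SEGMENTS <- c("RVapex", "RVmid", "RVbase")

#' Construct a single parameter specification
#'
#' A parameter spec describes one estimated model parameter: its physical
#' bounds, the distribution family used to map it to an unbounded sampling
#' coordinate, and a physiological reference (default) value.
#'
#' @param name Base parameter name (e.g. `"SfAct"`).
#' @param scope Wall/segment label the parameter applies to, or `"global"`.
#' @param unit Physical unit string (informational).
#' @param distribution `"logit-uniform"` (bounded, mapped through the logit)
#'   or `"log-uniform"` (positive, mapped through the natural log).
#' @param lower,upper Physical bounds.  `upper` may be `Inf` for log-uniform
#'   parameters.
#' @param reference Default physical value, strictly inside the bounds.
#' @param init_lower,init_upper Finite practical bounds used only to place
#'   the initial proposal for unbounded log-uniform parameters; ignored for
#'   logit-uniform parameters (where they equal `lower`/`upper`).
#'
#' @return A list of class `"parameter_spec"`.
#' @export
parameter_spec <- function(name, scope, unit, distribution, lower, upper,
                           reference, init_lower = lower, init_upper = upper) {
  distribution <- match.arg(distribution, c("logit-uniform", "log-uniform"))
  stopifnot(is.numeric(lower), is.numeric(upper), is.numeric(reference))
  if (!(lower < reference && reference < upper)) {
    stop(sprintf("parameter %s/%s: need lower < reference < upper", name, scope))
  }
  if (distribution == "log-uniform" && lower < 0) {
    stop(sprintf("parameter %s/%s: log-uniform requires lower >= 0", name, scope))
  }
  structure(
    list(name = name, scope = scope, unit = unit,
         distribution = distribution,
         lower = lower, upper = upper, reference = reference,
         init_lower = init_lower, init_upper = init_upper),
    class = "parameter_spec"
  )
}

#' Construct a parameter space from a list of specs
#'
#' @param specs List of [parameter_spec()] objects.  Full parameter names
#'   (`name_scope`, or `name` for global scope) must be unique; their order
#'   defines vector indexing.
#'
#' @return An object of class `"parameter_space"` with elements `specs`
#'   (the list) and `names` (full parameter names).
#' @export
parameter_space <- function(specs) {
  nms <- vapply(specs, function(s) {
    if (identical(s$scope, "global")) s$name else paste(s$name, s$scope, sep = "_")
  }, character(1))
  if (anyDuplicated(nms)) stop("duplicate parameter names in space")
  structure(list(specs = specs, names = nms), class = "parameter_space")
}

#' @export
length.parameter_space <- function(x) length(x$specs)

#' @export
print.parameter_space <- function(x, ...) {
  cat(sprintf("parameter_space with %d parameters\n", length(x)))
  df <- data.frame(
    name = x$names,
    unit = vapply(x$specs, `[[`, character(1), "unit"),
    distribution = vapply(x$specs, `[[`, character(1), "distribution"),
    lower = vapply(x$specs, `[[`, numeric(1), "lower"),
    upper = vapply(x$specs, `[[`, numeric(1), "upper"),
    reference = vapply(x$specs, `[[`, numeric(1), "reference")
  )
  print(df, row.names = FALSE)
  invisible(x)
}

#' Look up one spec by name and scope
#'
#' @param space A `parameter_space`.
#' @param name Base name (e.g. `"k1"`).
#' @param scope Scope label; omit for global parameters.
#' @return The matching `parameter_spec`.
#' @export
get_spec <- function(space, name, scope = "global") {
  full <- if (identical(scope, "global")) name else paste(name, scope, sep = "_")
  i <- match(full, space$names)
  if (is.na(i)) stop(sprintf("no parameter '%s' in space", full))
  space$specs[[i]]
}

#' The default 20-parameter estimation space
#'
#' Five segmental active-stress scaling factors `SfAct` (kPa, logit-uniform
#' on \[0, 1000\]), five segmental passive stiffness exponents `k1`
#' (logit-uniform on \[1, 100\]), five segmental activation delays `dT`
#' (ms, logit-uniform on \[-200, 800\]), three reference wall areas `AmRef`
#' (cm^2, log-uniform), the global relative systole duration `RSD`
#' (log-uniform) and the cardiac output `Q0` (L/min, log-uniform).
#' Log-uniform parameters are unbounded above; finite `init_lower`/
#' `init_upper` clip ranges are attached for proposal initialisation only.
#'
#' @param reference Optional named list overriding reference values, keyed by
#'   full parameter name (e.g. `list(SfAct_RVbase = 60)`).
#'
#' @return A `parameter_space` of length 20.
#' @export
default_parameter_space <- function(reference = list()) {
  specs <- list()
  ref_sfact <- 120; ref_k1 <- 10; ref_dt <- 0
  ref_amref <- c(LVfw = 80, IVS = 45, RVfw = 100)
  for (seg in SEGMENTS) {
    specs <- c(specs, list(parameter_spec(
      "SfAct", seg, "kPa", "logit-uniform", 0, 1000, ref_sfact)))
  }
  for (seg in SEGMENTS) {
    specs <- c(specs, list(parameter_spec(
      "k1", seg, "-", "logit-uniform", 1, 100, ref_k1)))
  }
  for (seg in SEGMENTS) {
    specs <- c(specs, list(parameter_spec(
      "dT", seg, "ms", "logit-uniform", -200, 800, ref_dt)))
  }
  for (w in WALLS) {
    specs <- c(specs, list(parameter_spec(
      "AmRef", w, "cm^2", "log-uniform", 0, Inf, ref_amref[[w]],
      init_lower = 5, init_upper = 400)))
  }
  specs <- c(specs, list(parameter_spec(
    "RSD", "global", "-", "log-uniform", 0, Inf, 1.0,
    init_lower = 0.2, init_upper = 5)))
  specs <- c(specs, list(parameter_spec(
    "Q0", "global", "L/min", "log-uniform", 0, Inf, 5.1,
    init_lower = 1, init_upper = 15)))
  space <- parameter_space(specs)
  if (length(reference)) {
    for (nm in names(reference)) {
      i <- match(nm, space$names)
      if (is.na(nm) || is.na(i)) stop(sprintf("unknown parameter '%s'", nm))
      space$specs[[i]]$reference <- reference[[nm]]
    }
  }
  space
}

#' Reference (default) parameter vector of a space
#'
#' @param space A `parameter_space`.
#' @return Named numeric vector of reference physical values.
#' @export
reference_vector <- function(space) {
  stats::setNames(vapply(space$specs, `[[`, numeric(1), "reference"),
                  space$names)
}

#' Validate a physical parameter vector against its space
#'
#' @param space A `parameter_space`.
#' @param values Numeric vector, length `length(space)`; if named, names must
#'   match the space order.
#' @return The vector, named, invisibly checked to lie within all bounds.
#' @export
validate_parameters <- function(space, values) {
  if (length(values) != length(space)) {
    stop(sprintf("expected %d parameter values, got %d",
                 length(space), length(values)))
  }
  if (!is.null(names(values)) && !identical(names(values), space$names)) {
    stop("parameter names do not match the space order")
  }
  lo <- vapply(space$specs, `[[`, numeric(1), "lower")
  hi <- vapply(space$specs, `[[`, numeric(1), "upper")
  bad <- which(values < lo | values > hi | !is.finite(values))
  if (length(bad)) {
    stop(sprintf("parameter(s) out of bounds: %s",
                 paste(space$names[bad], collapse = ", ")))
  }
  stats::setNames(as.numeric(values), space$names)
}

#' Map physical parameter values to unbounded sampling coordinates
#'
#' Logit-uniform parameters map through `logit((x - lower)/(upper - lower))`;
#' log-uniform parameters map through `ln(x)`.  The transform is bijective
#' between the open physical range and the real line, and round-trips with
#' [from_transformed()] to better than 1e-10 relative.
#'
#' @param space A `parameter_space`.
#' @param values Physical values (vector of length `n`, or `n x m` matrix of
#'   column vectors).
#' @return Transformed coordinates, same shape as `values`.  Values on a
#'   closed logit bound transform to `+/-Inf`, for which a warning is issued.
#' @export
to_transformed <- function(space, values) {
  f <- function(v) {
    u <- numeric(length(v))
    for (i in seq_along(space$specs)) {
      s <- space$specs[[i]]
      if (s$distribution == "logit-uniform") {
        p <- (v[i] - s$lower) / (s$upper - s$lower)
        u[i] <- log(p) - log1p(-p)
      } else {
        u[i] <- log(v[i])
      }
    }
    u
  }
  out <- if (is.matrix(values)) apply(values, 2, f) else f(values)
  if (any(!is.finite(out))) {
    warning("non-finite transform: value on or outside a closed bound")
  }
  if (is.matrix(values)) {
    dimnames(out) <- list(space$names, colnames(values))
  } else {
    names(out) <- space$names
  }
  out
}

#' Map unbounded sampling coordinates back to physical parameter values
#'
#' Total inverse of [to_transformed()]: every finite real coordinate maps
#' strictly inside the physical bounds.
#'
#' @param space A `parameter_space`.
#' @param u Transformed coordinates (vector, or `n x m` matrix of columns).
#' @return Physical values, same shape as `u`, named by parameter.
#' @export
from_transformed <- function(space, u) {
  f <- function(w) {
    v <- numeric(length(w))
    for (i in seq_along(space$specs)) {
      s <- space$specs[[i]]
      if (s$distribution == "logit-uniform") {
        v[i] <- s$lower + (s$upper - s$lower) * stats::plogis(w[i])
      } else {
        v[i] <- exp(w[i])
      }
    }
    v
  }
  out <- if (is.matrix(u)) apply(u, 2, f) else f(u)
  if (is.matrix(u)) {
    dimnames(out) <- list(space$names, colnames(u))
  } else {
    names(out) <- space$names
  }
  out
}

#' Transformed-space box used to initialise proposals
#'
#' For logit-uniform parameters this is the transform of the full physical
#' range; for unbounded log-uniform parameters the finite practical clip
#' range (`init_lower`/`init_upper`) is used instead.
#'
#' @param space A `parameter_space`.
#' @return List with numeric vectors `lower` and `upper` in transformed
#'   coordinates (finite).
#' @keywords internal
transformed_init_box <- function(space) {
  lo <- hi <- numeric(length(space))
  for (i in seq_along(space$specs)) {
    s <- space$specs[[i]]
    if (s$distribution == "logit-uniform") {
      # open interval: leave a sliver so the logit stays finite
      eps <- 1e-6 * (s$upper - s$lower)
      rng <- c(s$lower + eps, s$upper - eps)
    } else {
      rng <- c(s$init_lower, s$init_upper)
    }
    u <- to_transformed_one(s, rng)
    lo[i] <- u[1]; hi[i] <- u[2]
  }
  list(lower = lo, upper = hi)
}

to_transformed_one <- function(s, x) {
  if (s$distribution == "logit-uniform") {
    p <- (x - s$lower) / (s$upper - s$lower)
    log(p) - log1p(-p)
  } else {
    log(x)
  }
}

#' Log-Jacobian of the physical-from-transformed map
#'
#' `sum_i log |d theta_i / d u_i|` per sample: the density correction that
#' makes a prior uniform in physical units when sampling in transformed
#' coordinates.
#'
#' @param space A `parameter_space`.
#' @param U Transformed coordinates (`n x m` matrix of column samples, or a
#'   vector).
#' @return Length-m vector of log-Jacobian values.
#' @export
transform_log_jacobian <- function(space, U) {
  if (!is.matrix(U)) U <- matrix(U, ncol = 1)
  lj <- numeric(ncol(U))
  for (i in seq_along(space$specs)) {
    s <- space$specs[[i]]
    u <- U[i, ]
    if (s$distribution == "logit-uniform") {
      lj <- lj + log(s$upper - s$lower) + stats::plogis(u, log.p = TRUE) +
        stats::plogis(-u, log.p = TRUE)
    } else {
      lj <- lj + u
    }
  }
  lj
}

#' Read / write a parameter space as YAML
#'
#' The schema is a list of records `{name, scope, unit, distribution, lower,
#' upper, reference, init_lower, init_upper}`; `.inf` encodes an unbounded
#' upper limit.
#'
#' @param path YAML file path.
#' @return `read_parameter_space()` returns a `parameter_space`;
#'   `write_parameter_space()` returns `path` invisibly.
#' @export
read_parameter_space <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(r) {
    parameter_spec(r$name, r$scope, r$unit, r$distribution,
                   as.numeric(r$lower), as.numeric(r$upper),
                   as.numeric(r$reference),
                   init_lower = as.numeric(r$init_lower %||% r$lower),
                   init_upper = as.numeric(r$init_upper %||% r$upper))
  })
  parameter_space(specs)
}

#' @rdname read_parameter_space
#' @param space A `parameter_space` to serialise.
#' @export
write_parameter_space <- function(space, path) {
  recs <- lapply(space$specs, function(s) {
    s[c("name", "scope", "unit", "distribution", "lower", "upper",
        "reference", "init_lower", "init_upper")]
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
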