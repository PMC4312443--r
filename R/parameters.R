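.param_fields <- c(
  "kon_re1", "koff_re1", "kon_re2", "koff_re2", "kon_re3", "koff_re3",
  "kcat_GEF", "Km_GEF", "kcat_GAP", "Km_GAP",
  "Ki_GEF_GDI", "Ki_GAP_GDI",
  "k_stim_act", "k_gef_deact", "k_stim_decay",
  "Rho_total", "GDI_free_excess", "GEF_total", "GAP_total",
  "Effector_total", "Stimulus_0")

# pool sizes may be zero; rate constants must be strictly positive
.pool_fields <- c("Rho_total", "GDI_free_excess", "GEF_total", "GAP_total",
                  "Effector_total", "Stimulus_0")

#' Default (baseline) parameter set
#'
#' Rate constants, inhibition constants and molecular pool sizes for the
#' Rho GTPase cycle, in uM and minutes. The free-GDI excess of 0.7 uM is
#' the estimated cellular concentration of free (non-GTPase-complexed)
#' RhoGDIalpha; the inhibition constants default to 0.1 uM, the midpoint of
#' the decade grid \{0.01, 0.1, 1.0\} uM that the scan drivers explore; GEF
#' and GAP pools default to 0.3 uM, the midpoint of the \{0.1, 0.3, 0.9\} uM
#' concentration grid. The remaining kinetic constants are calibrated
#' baseline values (see the package vignette, section on parameter
#' provenance, and `tools/calibrate-defaults.R` in the source tree): GDI
#' binds GDP-Rho two decades tighter than GTP-Rho, effector binding is
#' sub-uM, and GAP turnover is slow enough that an 8-fold non-competitive
#' suppression converts a sub-600-min decay into a multi-thousand-minute
#' plateau.
#'
#' @return Object of class `rho_params`: named list of 21 numeric fields.
#'   `Ki_GEF_GDI` / `Ki_GAP_GDI` may be `Inf` (interaction absent).
#' @export
default_parameters <- function() {
  validate_parameters(list(
    kon_re1 = 10,    koff_re1 = 0.1,   # GDI + GDP-Rho,  Kd = 0.01 uM
    kon_re2 = 10,    koff_re2 = 1.0,   # GDI + GTP-Rho,  Kd = 0.1 uM
    kon_re3 = 10,    koff_re3 = 1.0,   # GTP-Rho + effector, Kd = 0.1 uM
    kcat_GEF = 100,  Km_GEF = 0.5,
    kcat_GAP = 0.3,  Km_GAP = 1.0,
    Ki_GEF_GDI = 0.1, Ki_GAP_GDI = 0.1,
    k_stim_act = 10, k_gef_deact = 0.05, k_stim_decay = 0.1,
    Rho_total = 1.0, GDI_free_excess = 0.7,
    GEF_total = 0.3, GAP_total = 0.3,
    Effector_total = 1.0, Stimulus_0 = 0.1))
}

#' Validate a parameter set
#'
#' Checks completeness (all 21 fields), strict positivity of rate constants
#' (`Ki` may be `Inf`), and non-negativity of pool sizes.
#'
#' @param params Named list or named numeric vector.
#' @return The validated parameter set with class `rho_params`.
#' @export
validate_parameters <- function(params) {
  params <- as.list(params)
  missing <- setdiff(.param_fields, names(params))
  if (length(missing)) {
    stop("configuration error: missing parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(params), .param_fields)
  if (length(extra)) {
    stop("configuration error: unknown parameter(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  params <- params[.param_fields]
  vals <- vapply(params, as.numeric, numeric(1))
  if (any(is.na(vals))) {
    stop("configuration error: non-numeric parameter value", call. = FALSE)
  }
  rate_fields <- setdiff(.param_fields, c(.pool_fields,
                                          "Ki_GEF_GDI", "Ki_GAP_GDI"))
  bad <- rate_fields[vals[rate_fields] <= 0 | !is.finite(vals[rate_fields])]
  if (length(bad)) {
    stop("invalid parameter: must be finite and > 0: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(vals[c("Ki_GEF_GDI", "Ki_GAP_GDI")] <= 0)) {
    stop("invalid parameter: Ki must be > 0 (Inf disables inhibition)",
         call. = FALSE)
  }
  if (any(vals[.pool_fields] < 0) || any(!is.finite(vals[.pool_fields]))) {
    stop("invalid parameter: pool sizes must be finite and >= 0",
         call. = FALSE)
  }
  structure(as.list(vals), class = "rho_params")
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param params A `rho_params` object.
#' @param ... Named replacements, e.g. `GAP_total = 0.9`, `Ki_GAP_GDI = 0.01`.
#' @return Modified `rho_params`.
#' @export
set_parameters <- function(params, ...) {
  over <- list(...)
  if (length(over) == 0) return(validate_parameters(params))
  if (is.null(names(over)) || any(names(over) == "")) {
    stop("configuration error: overrides must be named", call. = FALSE)
  }
  p <- as.list(params)
  p[names(over)] <- over
  validate_parameters(p)
}

#' @export
print.rho_params <- function(x, ...) {
  cat("Rho cycle parameter set (uM, min):\n")
  v <- unlist(x)
  for (i in seq_along(v)) {
    cat(sprintf("  %-16s %g\n", names(v)[i], v[i]))
  }
  invisible(x)
}

#' Read a parameter override file
#'
#' Flat `key = value` plain-text format, one assignment per line; `#` starts
#' a comment; keys are the `rho_params` field names; the value `Inf`
#' disables the corresponding GDI interaction. Unknown keys are an error
#' (they are never silently dropped).
#'
#' @param path File path.
#' @param base Parameter set to override; defaults to [default_parameters()].
#' @return Validated `rho_params`.
#' @export
read_parameter_config <- function(path, base = default_parameters()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(validate_parameters(base))
  parts <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(\\S+)$", lines))
  bad <- lines[vapply(parts, length, 0L) != 3L]
  if (length(bad)) {
    stop("configuration error: cannot parse line(s): ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  keys <- vapply(parts, `[[`, "", 2)
  vals <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  if (anyNA(vals)) {
    stop("configuration error: non-numeric value for ",
         paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop("configuration error: duplicate key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  do.call(set_parameters, c(list(base), as.list(stats::setNames(vals, keys))))
}

#' Write a parameter set to a config file
#'
#' Inverse of [read_parameter_config()]; round-trips exactly (values are
#' written with full precision).
#'
#' @param params A `rho_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_config <- function(params, path) {
  params <- validate_parameters(params)
  v <- unlist(params)
  writeLines(c("# rhocycle parameter set (uM, min)",
               sprintf("%s = %s", names(v), formatC(v, format = "g",
                                                    digits = 17))),
             path)
  invisible(path)
}
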