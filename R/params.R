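# Model constants and simulation conventions: single source of truth for
# every gain, threshold, filter width and grid convention used downstream.

.param_defaults <- list(
  # connection gains
  Gescx1      = 2,     # complex V1 -> end-stopped drive
  Gescx2      = 3,     # lateral inhibition onto end-stopped units
  Gmtcx       = 0.5,   # complex V1 -> MT
  Gmtes       = 1,     # end-stopped V1 -> MT
  Gcsmt       = 2,     # ECRF-gated V1 drive -> MT (component mode)
  Gmtmt_ex    = 0.1,   # lateral excitation between MT neighbours
  Gmtmt_inter = 1,     # same-location inter-directional inhibition
  Gmtmt3      = 1,     # long-range inter-directional inhibition
  # spatial structure
  phi         = 6L,    # long-range inhibition window radius (units)
  N           = 8L,    # direction channels
  M           = 49L,   # MT surround extent: 7 x 7 window
  O           = 4L,    # ECRF orientation channels (0, 45, 90, 135 deg)
  # thresholds
  rho_cx      = 0.13,  # complex V1 activity threshold (lateral inhibition)
  rho_es      = 0.3,   # end-stopped activity threshold before MT projection
  T_mt        = 0.001, # MT activity threshold (lateral excitation gate)
  c_r         = 0.2,   # contrast threshold of the surround switch
  # surround modulation shape
  a           = 10,    # sigmoid slope magnitude (suppression vs contrast)
  b           = 2.4,   # slope vs motion discontinuity
  k           = 2,     # saturation constant: chi is bounded by k - 1
  # dynamics
  tau_mt      = 0.01,  # MT decay rate
  tau_es      = 0.01,  # end-stopped decay rate
  dt          = 0.01,  # integration step (time units)
  tau_g       = 0.01,  # temporal filter time constant
  T_in        = 0.4,   # inhibition delay (time units) -> 40 steps
  # front-end filters
  f           = 1.1,   # Gabor spatial frequency (cyc/deg)
  sigma_x     = 0.5,   # Gabor SD across the carrier (deg)
  sigma_y     = 0.5,   # Gabor SD along the carrier (deg)
  sigma_xc    = 0.35,  # DoG centre SDs (deg)
  sigma_yc    = 0.4,
  sigma_xs    = 0.4,   # DoG surround SDs (deg)
  sigma_ys    = 0.5,
  A_c         = 1,     # DoG centre gain
  A_s         = 0.72,  # DoG surround gain
  n_fast      = 6L,    # temporal filter orders
  n_slow      = 9L,
  # conventions
  deg_per_pixel    = 0.25,  # one model unit per stimulus pixel
  ms_per_time_unit = 1000,  # 1 time unit = 1 s, so dt = 10 ms
  # switches
  apply_rho_es  = TRUE,  # rectify end-stopped output at rho_es before MT
  literal_h_on_derivative = FALSE  # saturate the derivative, not the state
)

# accepted aliases (legacy gain names bound by their printed descriptions:
# the 0.1 gain is the excitatory one, the gain 1 the inter-directional one)
.param_aliases <- c(Gmtmt1 = "Gmtmt_inter", Gmtmt2 = "Gmtmt_ex")

#' Construct the model parameter set
#'
#' Returns the full set of model constants (gains, thresholds, filter
#' widths, integration conventions) with any named overrides applied.
#' The defaults are the model's standard operating point; grid and time
#' conventions (`deg_per_pixel`, `ms_per_time_unit`) are package choices.
#'
#' @param ... named overrides of individual fields, e.g. `mt_params(k = 2)`.
#'   The aliases `Gmtmt1`/`Gmtmt2` are accepted for
#'   `Gmtmt_inter`/`Gmtmt_ex`.
#' @return an object of class `mt_params` (a validated named list).
#' @examples
#' p <- mt_params()
#' p$c_r
#' mt_params(Gcsmt = 0)$Gcsmt
#' @export
mt_params <- function(...) {
  over <- list(...)
  p <- .apply_overrides(.param_defaults, over)
  v <- validate_params(p)
  if (length(v) > 0L)
    stop("invalid parameters: ", paste(v, collapse = "; "), call. = FALSE)
  p
}

.apply_overrides <- function(base, over) {
  if (length(over) > 0L && (is.null(names(over)) || any(names(over) == "")))
    stop("all parameter overrides must be named", call. = FALSE)
  nm <- names(over)
  al <- nm %in% names(.param_aliases)
  nm[al] <- .param_aliases[nm[al]]
  unknown <- setdiff(nm, names(base))
  if (length(unknown) > 0L)
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  names(over) <- nm
  base[nm] <- over
  # keep integer-valued fields integral
  for (fld in c("phi", "N", "M", "O", "n_fast", "n_slow")) {
    if (is.numeric(base[[fld]]) && base[[fld]] == round(base[[fld]]))
      base[[fld]] <- as.integer(base[[fld]])
  }
  structure(base, class = "mt_params")
}

#' Validate a parameter set
#'
#' Total function: returns a character vector of violations (empty when all
#' invariants hold), each naming the offending field, its value, and the
#' constraint.
#'
#' @param p an `mt_params` object or a plain named list with the same fields.
#' @return character vector of violations; `character(0)` if valid.
#' @export
validate_params <- function(p) {
  bad <- character(0)
  chk <- function(cond, field, constraint) {
    if (!isTRUE(cond))
      bad <<- c(bad, sprintf("%s = %s violates: %s", field,
                             format(p[[field]]), constraint))
  }
  pos <- c("Gescx1", "Gescx2", "Gmtcx", "Gmtes", "Gmtmt_inter", "Gmtmt3",
           "Gmtmt_ex", "a", "b", "tau_mt", "tau_es", "tau_g",
           "f", "sigma_x", "sigma_y", "sigma_xc", "sigma_yc",
           "sigma_xs", "sigma_ys", "A_c", "A_s", "deg_per_pixel",
           "ms_per_time_unit")
  for (fld in pos) chk(is.numeric(p[[fld]]) && p[[fld]] > 0, fld, "> 0")
  chk(p$Gcsmt >= 0, "Gcsmt", ">= 0")  # pattern mode sets it to 0
  chk(p$N == 8L, "N", "== 8")
  chk(p$M == 49L, "M", "== 49 (7 x 7 surround window)")
  chk(p$O >= 2L, "O", ">= 2")
  chk(p$phi >= 1L, "phi", ">= 1")
  chk(p$c_r > 0 && p$c_r < 1, "c_r", "in (0, 1)")
  chk(p$k >= 1, "k", ">= 1")
  chk(p$dt > 0, "dt", "> 0")
  chk(p$rho_cx >= 0, "rho_cx", ">= 0")
  chk(p$rho_es >= 0, "rho_es", ">= 0")
  chk(p$T_mt >= 0, "T_mt", ">= 0")
  chk(p$n_fast >= 1L, "n_fast", ">= 1")
  chk(p$n_slow > p$n_fast, "n_slow", "> n_fast")
  if (is.numeric(p$T_in) && is.numeric(p$dt) && p$dt > 0) {
    steps <- p$T_in / p$dt
    chk(abs(steps - round(steps)) < 1e-9, "T_in",
        "integer multiple of dt")
  }
  bad
}

#' Load parameters from a YAML configuration file
#'
#' Reads a key-value document, rejects unknown keys, fills absent keys with
#' the defaults, and validates the result. An empty document yields the
#' default parameter set.
#'
#' @param path path to a YAML file, or a YAML string.
#' @return an `mt_params` object.
#' @seealso [write_params()] for the inverse; the shipped defaults live at
#'   `system.file("config", "default-params.yaml", package = "mtsurround")`.
#' @export
load_params <- function(path) {
  doc <- tryCatch(
    if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path),
    error = function(e) stop("config parse error: ", conditionMessage(e),
                             call. = FALSE))
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stop("config must be a key-value mapping", call. = FALSE)
  p <- .apply_overrides(.param_defaults, doc)
  v <- validate_params(p)
  if (length(v) > 0L)
    stop("config validation error: ", paste(v, collapse = "; "),
         call. = FALSE)
  p
}

#' Serialize parameters to YAML
#'
#' @param p an `mt_params` object.
#' @param path output file; if `NULL` the YAML text is returned.
#' @return `path` invisibly, or the YAML string when `path` is `NULL`.
#' @export
write_params <- function(p, path = NULL) {
  txt <- yaml::as.yaml(unclass(p), precision = 15L)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @export
print.mt_params <- function(x, ...) {
  cat("<mt_params>", length(x), "fields\n")
  cat(sprintf("  grid: %g deg/unit, dt = %g (%g ms), inhibition delay %g (%d steps)\n",
              x$deg_per_pixel, x$dt, x$dt * x$ms_per_time_unit,
              x$T_in, as.integer(round(x$T_in / x$dt))))
  cat(sprintf("  surround: c_r = %g, a = %g, b = %g, k = %g, M = %d\n",
              x$c_r, x$a, x$b, x$k, x$M))
  invisible(x)
}

#' Stable content hash of a parameter set
#'
#' Used in run manifests so that a trace can be matched to the exact
#' constants that produced it.
#' @param p an `mt_params` object.
#' @return a character scalar.
#' @keywords internal
params_hash <- function(p) {
  s <- paste(names(p), vapply(p, function(v) format(v, digits = 17),
                              character(1)), sep = "=", collapse = ";")
  # polynomial rolling hash mod a Mersenne prime; deterministic and exact
  # in doubles (intermediate values stay below 2^53)
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
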