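# Run configuration: a nested list with sections [geometry], [load],
# [fuzzy], [schedule], [run], read from YAML.  Validation is strict: keys
# not present in the default configuration are rejected.

CONFIG_VERSION <- "1"
HISTORY_SCHEMA_VERSION <- "1"

#' Default run configuration
#'
#' The complete configuration with the package defaults: coarse geometry
#' preset, the 2.1 kN study load case, the canonical rule base with the
#' default membership functions, the perfusion schedule and a 60-day locked
#' plate run.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    version = CONFIG_VERSION,
    geometry = list(
      bone_outer_radius = 13.5, cortex_thickness = 5, segment_length = 120,
      gap_width = 20, callus_axial_semiaxis = 30, callus_radial_semiaxis = 25,
      plate_offset = 0.5, plate_width = 12, plate_thickness = 5,
      screw_radius = 2.25, screw_axial_positions = c(-40, -25, 25, 40),
      target_edge_length = 4.5),
    load = list(
      load_magnitude = 2100, frontal_tilt = 10, sagittal_tilt = 10, head_offset = 20,
      pretension_force = 500, friction_coefficient = 0.3,
      penalty_normal = 1e5, penalty_tangent = 1e3, stabilization = 1e-2,
      contact_max_iter = 50L, contact_tol = 1e-3, contact_relaxation = 0.7),
    fuzzy = list(
      rules_file = NULL, n_grid = 1001L,
      neighbour_aggregation = "max",
      membership = list()),
    schedule = list(
      cortex_far = 100, fragment_end = 0, periphery = 30, medullary = 30,
      medullary_start_day = 10, avascular_band = 5),
    run = list(
      iterations = 60L, fixation = "LP", output_dir = NULL,
      snapshot_every = 0L)
  )
}

#' Validate (and complete) a configuration
#'
#' Merges a possibly partial configuration into the defaults and rejects
#' unknown keys, non-list sections and invalid enum values.
#'
#' @param config Nested configuration list.
#' @return The completed configuration.
#' @export
validate_config <- function(config) {
  def <- default_config()
  if (is.null(config)) return(def)
  if (!is.list(config)) stop("config must be a list")
  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  }
  out <- def
  for (sec in names(config)) {
    if (sec == "version") { out$version <- as.character(config$version); next }
    val <- config[[sec]]
    if (!is.list(val)) stop(sprintf("config section '%s' must be a mapping", sec))
    unknown <- setdiff(names(val), names(def[[sec]]))
    if (length(unknown)) {
      stop(sprintf("unknown key(s) in config section '%s': %s", sec,
                   paste(unknown, collapse = ", ")))
    }
    for (key in names(val)) {
      if (!is.null(val[[key]]) || key %in% c("rules_file", "output_dir")) {
        out[[sec]][[key]] <- val[[key]]
      }
    }
  }
  out$run$fixation <- match.arg(out$run$fixation, c("LP", "DCP"))
  out$fuzzy$neighbour_aggregation <-
    match.arg(out$fuzzy$neighbour_aggregation, c("max", "mean"))
  if (out$run$iterations < 0) stop("run.iterations must be >= 0")
  out$run$iterations <- as.integer(out$run$iterations)
  out$run$snapshot_every <- as.integer(out$run$snapshot_every)
  if (!is.list(out$fuzzy$membership)) stop("fuzzy.membership must be a list")
  out
}

#' Read a configuration file
#'
#' @param path YAML configuration file with any subset of the sections of
#'   [default_config()].
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Apply dotted-path overrides to a configuration
#'
#' @param config Configuration list.
#' @param overrides Character vector of `section.key=value` assignments
#'   (values parsed as YAML, so numbers and lists work).
#' @return Updated, re-validated configuration.
#' @export
apply_overrides <- function(config, overrides = character()) {
  for (ov in overrides) {
    m <- regmatches(ov, regexec("^([^=]+)=(.*)$", ov))[[1]]
    if (length(m) != 3L) stop("override must look like section.key=value: ", ov)
    path <- strsplit(m[2], ".", fixed = TRUE)[[1]]
    value <- yaml::yaml.load(m[3])
    if (length(path) == 1L) {
      config[[path]] <- value
    } else if (length(path) == 2L) {
      config[[path[1]]][[path[2]]] <- value
    } else {
      stop("override paths deeper than section.key are not supported: ", ov)
    }
  }
  validate_config(config)
}

#' Build the fuzzy controller from the `[fuzzy]` config section
#'
#' Applies membership overrides (entries of the form
#' `list(variable=, term=, a=, b=, c=, d=)`; `.inf`/`-.inf` in YAML map to
#' infinities) on top of [default_fuzzy_variables()], loads the rule base
#' and assembles the controller.
#'
#' @param fuzzy_cfg The `fuzzy` section of a validated config.
#' @return A [fuzzy_controller()].
#' @export
controller_from_config <- function(fuzzy_cfg = default_config()$fuzzy) {
  vars <- default_fuzzy_variables()
  for (ov in fuzzy_cfg$membership) {
    need <- c("variable", "term", "a", "b", "c", "d")
    if (!all(need %in% names(ov))) {
      stop("membership override needs fields: ", paste(need, collapse = ", "))
    }
    v <- ov$variable
    if (is.null(vars[[v]])) stop("membership override for unknown variable: ", v)
    vars[[v]]$terms[[ov$term]] <- trapmf(ov$a, ov$b, ov$c, ov$d)
    vars[[v]] <- fuzzy_variable(vars[[v]]$name, vars[[v]]$universe, vars[[v]]$terms)
  }
  rb <- load_rulebase(fuzzy_cfg$rules_file, variables = vars)
  fuzzy_controller(vars, rb, n_grid = fuzzy_cfg$n_grid)
}
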