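# The daily healing loop: FE solve -> strain invariants -> per-element fuzzy
# inference -> tissue state update -> material update, iterated for 60 days.
#
# The tissue state lives on the callus elements only (bone, cartilage,
# connective tissue and blood perfusion, all in percent); cortex perfusion
# is fixed bookkeeping (100% away from the gap, 0% in the avascular
# fragment-end band) that feeds the neighbour inputs of the controller.

#' Perfusion boundary schedule
#'
#' Ghost-cell perfusion sources seen by callus elements on the model
#' boundaries: the cortex away from the fracture carries intact vascularity,
#' the fragment-end cortex band is avascular, the peripheral callus surface
#' receives the extraosseous blood supply from day 1 and the medullary
#' boundary opens after a delay (revascularisation from the marrow).
#'
#' @param cortex_far Cortex perfusion away from the gap, percent (default 100).
#' @param fragment_end Cortex perfusion in the fragment-end band (default 0).
#' @param periphery Peripheral boundary perfusion, percent (default 30).
#' @param medullary Medullary boundary perfusion, percent (default 30).
#' @param medullary_start_day First day the medullary source is active
#'   (default 10).
#' @param avascular_band Axial extent (mm) of the avascular cortex band
#'   measured from each fracture face (default 5).
#' @return List of class `perfusion_schedule`.
#' @export
perfusion_schedule <- function(cortex_far = 100, fragment_end = 0,
                               periphery = 30, medullary = 30,
                               medullary_start_day = 10, avascular_band = 5) {
  vals <- c(cortex_far, fragment_end, periphery, medullary)
  if (any(vals < 0 | vals > 100)) stop("perfusion levels must lie in [0, 100]")
  if (avascular_band < 0) stop("avascular_band must be >= 0")
  structure(list(cortex_far = cortex_far, fragment_end = fragment_end,
                 periphery = periphery, medullary = medullary,
                 medullary_start_day = medullary_start_day,
                 avascular_band = avascular_band),
            class = "perfusion_schedule")
}

gap_half_width <- function(mesh) {
  if (!is.null(mesh$params)) return(mesh$params$gap_width / 2)
  fe <- mesh$node_sets$FRAGMENT_END
  if (is.null(fe) || !length(fe)) stop("mesh carries neither parameters nor fragment-end sets")
  max(abs(mesh$nodes[fe, 3]))
}

#' Initial tissue state
#'
#' Every callus element starts as 100% connective tissue (no bone, no
#' cartilage) with 0% perfusion; cortical elements carry 100% perfusion
#' except within the avascular fragment-end band, where perfusion is 0.
#'
#' @param mesh An `fh_mesh` with a callus region.
#' @param schedule A [perfusion_schedule()].
#' @return An object of class `tissue_state` with per-callus-element fields
#'   `c_bone`, `c_cartilage`, `c_connective`, `c_perfusion` (percent), the
#'   callus element ids `elements`, fixed `cortex_perfusion` bookkeeping and
#'   the current `day` (0).
#' @export
initialize_state <- function(mesh, schedule = perfusion_schedule()) {
  callus <- which(mesh$region == region_code("CALLUS"))
  if (!length(callus)) stop("mesh has an empty callus region")
  cortical <- which(mesh$region == region_code("CORTICAL"))
  g2 <- gap_half_width(mesh)
  cz <- (mesh$nodes[mesh$tets[cortical, 1], 3] + mesh$nodes[mesh$tets[cortical, 2], 3] +
         mesh$nodes[mesh$tets[cortical, 3], 3] + mesh$nodes[mesh$tets[cortical, 4], 3]) / 4
  in_band <- abs(cz) <= g2 + schedule$avascular_band
  cortex_perfusion <- ifelse(in_band, schedule$fragment_end, schedule$cortex_far)
  n <- length(callus)
  structure(list(
    elements = callus,
    c_bone = numeric(n), c_cartilage = numeric(n),
    c_connective = rep(100, n), c_perfusion = numeric(n),
    cortex_elements = cortical, cortex_perfusion = cortex_perfusion,
    day = 0L), class = "tissue_state")
}

#' Neighbour topology of the callus
#'
#' Face adjacency between callus elements plus their ghost contributions:
#' faces shared with cortical elements act as a bone source (100% bone, the
#' cortex band's perfusion), faces shared with cancellous elements mark the
#' medullary boundary, and exterior callus faces mark the periphery.  Plate
#' and screw interfaces contribute nothing.
#'
#' @param mesh An `fh_mesh`.
#' @return An object of class `neighbour_map`.
#' @export
neighbour_map <- function(mesh) {
  callus <- which(mesh$region == region_code("CALLUS"))
  if (!length(callus)) stop("mesh has an empty callus region")
  local <- integer(nrow(mesh$tets))
  local[callus] <- seq_along(callus)
  faces <- tet_faces(mesh$tets)
  fkey <- face_keys(faces, nrow(mesh$nodes))
  owner <- rep(seq_len(nrow(mesh$tets)), times = 4L)
  o <- order(fkey)
  k <- fkey[o]
  same <- which(k[-1] == k[-length(k)])
  e1 <- owner[o[same]]; e2 <- owner[o[same + 1L]]
  r1 <- mesh$region[e1]; r2 <- mesh$region[e2]
  cal <- region_code("CALLUS"); cor <- region_code("CORTICAL")
  can <- region_code("CANCELLOUS")
  cc <- which(r1 == cal & r2 == cal)
  adj_from <- c(local[e1[cc]], local[e2[cc]])
  adj_to <- c(local[e2[cc]], local[e1[cc]])
  nb_list <- split(adj_to, factor(adj_from, levels = seq_along(callus)))
  # callus-cortex ghosts (store the cortical element id for its band perfusion)
  cx1 <- which(r1 == cal & r2 == cor); cx2 <- which(r2 == cal & r1 == cor)
  ghost_from <- c(local[e1[cx1]], local[e2[cx2]])
  ghost_cort <- c(e2[cx1], e1[cx2])
  ghost_list <- split(ghost_cort, factor(ghost_from, levels = seq_along(callus)))
  md1 <- which(r1 == cal & r2 == can); md2 <- which(r2 == cal & r1 == can)
  medullary <- logical(length(callus))
  medullary[c(local[e1[md1]], local[e2[md2]])] <- TRUE
  # exterior faces
  ext_face <- which(!(fkey %in% fkey[duplicated(fkey)]))
  periphery <- logical(length(callus))
  pe <- owner[ext_face]
  periphery[local[pe[mesh$region[pe] == cal]]] <- TRUE
  structure(list(elements = callus, neighbours = nb_list,
                 ghost_cortical = ghost_list, medullary = medullary,
                 periphery = periphery),
            class = "neighbour_map")
}

#' Neighbour state seen by each callus element
#'
#' Aggregates the perfusion and bone concentration of the face-adjacent
#' callus elements together with the active ghost sources (periphery always;
#' medullary from its start day; cortex with 100% bone and the band's
#' perfusion).  The default aggregation is the maximum, which propagates
#' vascular and ossification fronts inward from the boundaries; `"mean"` is
#' available as an alternative.
#'
#' @param state A `tissue_state`.
#' @param map A [neighbour_map()].
#' @param day Simulation day (controls the medullary source).
#' @param schedule A [perfusion_schedule()].
#' @param aggregation `"max"` (default) or `"mean"`.
#' @return List with vectors `perfusion_nb` and `bone_nb` (percent), in the
#'   callus-local element order.
#' @export
neighbour_values <- function(state, map, day, schedule = perfusion_schedule(),
                             aggregation = c("max", "mean")) {
  aggregation <- match.arg(aggregation)
  n <- length(map$elements)
  cort_perf_of <- function(ids) state$cortex_perfusion[match(ids, state$cortex_elements)]
  med_on <- day >= schedule$medullary_start_day
  agg_fun <- if (aggregation == "max") function(v) if (length(v)) max(v) else 0
             else function(v) if (length(v)) mean(v) else 0
  perf <- state$c_perfusion
  bone <- state$c_bone
  perfusion_nb <- numeric(n)
  bone_nb <- numeric(n)
  for (i in seq_len(n)) {
    nb <- map$neighbours[[i]]
    gc <- map$ghost_cortical[[i]]
    pv <- perf[nb]
    bv <- bone[nb]
    if (length(gc)) {
      pv <- c(pv, cort_perf_of(gc))
      bv <- c(bv, rep(100, length(gc)))
    }
    if (map$periphery[i]) pv <- c(pv, schedule$periphery)
    if (med_on && map$medullary[i]) pv <- c(pv, schedule$medullary)
    perfusion_nb[i] <- agg_fun(pv)
    bone_nb[i] <- agg_fun(bv)
  }
  list(perfusion_nb = perfusion_nb, bone_nb = bone_nb)
}

#' Advance the tissue state by one day
#'
#' Assembles the seven controller inputs for every callus element (strain
#' invariants converted to percent, local and neighbour concentrations),
#' runs the fuzzy inference, adds the returned daily changes, clamps each of
#' perfusion/bone/cartilage to `[0, 100]`, rescales bone and cartilage
#' proportionally if their sum exceeds 100 and rebalances the connective
#' fraction so the three tissue fractions always sum to 100.
#'
#' @param state A `tissue_state`.
#' @param stimuli Strain invariants: a list with `eps_hyd` and `eps_dis`
#'   (dimensionless), either per callus element (local order) or per mesh
#'   element.
#' @param controller A [fuzzy_controller()].
#' @param map A [neighbour_map()].
#' @param schedule A [perfusion_schedule()].
#' @param aggregation Neighbour aggregation, see [neighbour_values()].
#' @return The updated `tissue_state` (day incremented).
#' @export
step_state <- function(state, stimuli, controller, map,
                       schedule = perfusion_schedule(),
                       aggregation = "max") {
  n <- length(state$elements)
  eh <- stimuli$eps_hyd
  ed <- stimuli$eps_dis
  if (length(eh) != n) { eh <- eh[state$elements]; ed <- ed[state$elements] }
  if (anyNA(eh) || anyNA(ed) || any(!is.finite(eh)) || any(!is.finite(ed))) {
    bad <- which(!is.finite(eh) | !is.finite(ed))[1]
    stop(sprintf("non-finite strain stimulus at callus element %d (mesh element %d)",
                 bad, state$elements[bad]))
  }
  day_next <- state$day + 1L
  nb <- neighbour_values(state, map, day_next, schedule, aggregation)
  X <- cbind(eps_hyd = eh * 100, eps_dis = ed * 100,
             c_perfusion = state$c_perfusion,
             c_perfusion_neighbour = nb$perfusion_nb,
             c_bone = state$c_bone, c_bone_neighbour = nb$bone_nb,
             c_cartilage = state$c_cartilage)
  d <- infer_bulk(X, controller)
  clamp <- function(x) pmin(100, pmax(0, x))
  perf <- clamp(state$c_perfusion + d[, "d_perfusion"])
  bone <- clamp(state$c_bone + d[, "d_bone"])
  cart <- clamp(state$c_cartilage + d[, "d_cartilage"])
  s <- bone + cart
  over <- s > 100
  if (any(over)) {
    bone[over] <- bone[over] * 100 / s[over]
    cart[over] <- cart[over] * 100 / s[over]
  }
  state$c_perfusion <- perf
  state$c_bone <- bone
  state$c_cartilage <- cart
  state$c_connective <- pmax(0, 100 - bone - cart)
  state$day <- day_next
  state
}

#' Run the coupled healing simulation
#'
#' Executes the full daily loop for a configuration: build the geometry,
#' initialize the state, then for each day update the callus materials from
#' the tissue mixture, solve the elastic problem, extract strain invariants,
#' run the fuzzy controller and record a per-day summary.  The run is
#' deterministic: identical configurations produce identical histories.
#'
#' @param config Configuration list, see [default_config()].  May be
#'   partially specified; missing entries take defaults.
#' @param mesh Optional prebuilt mesh (must match the configured fixation);
#'   by default the mesh is generated from the `geometry` section.
#' @return An object of class `healing_history`: list with the per-day
#'   `history` data.frame, the final `state`, the `mesh` and the `config`.
#' @export
run_healing <- function(config = default_config(), mesh = NULL) {
  cfg <- validate_config(config)
  fixation <- cfg$run$fixation
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("healing run failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.null(mesh)) {
    mesh <- stage("geometry", build_fracture_model(
      do.call(geometry_params, cfg$geometry), fixation))
  }
  load <- stage("load", do.call(load_case, cfg$load))
  schedule <- stage("schedule", do.call(perfusion_schedule, cfg$schedule))
  controller <- stage("fuzzy", controller_from_config(cfg$fuzzy))
  ctx <- stage("fe_setup", fe_context(mesh, load, fixation))
  map <- stage("neighbour_map", neighbour_map(mesh))
  state <- stage("initialize", initialize_state(mesh, schedule))
  base <- material_field(mesh)
  callus <- state$elements
  w <- tet_volumes(mesh$nodes, mesh$tets)[callus]
  wsum <- sum(w)
  iterations <- cfg$run$iterations
  rows <- vector("list", iterations)
  snap_dir <- cfg$run$output_dir
  for (day in seq_len(iterations)) {
    mats <- stage(sprintf("materials (day %d)", day), {
      mix <- mixture_properties(state$c_bone, state$c_cartilage,
                                state$c_connective)
      E <- base$E; nu <- base$nu
      E[callus] <- mix$E; nu[callus] <- mix$nu
      list(E = E, nu = nu)
    })
    sol <- stage(sprintf("fe_solve (day %d)", day), fe_solve(ctx, mats$E, mats$nu))
    inv <- stage(sprintf("invariants (day %d)", day),
                 element_strain_invariants(mesh, sol$u))
    stim <- list(eps_hyd = inv$eps_hyd[callus], eps_dis = inv$eps_dis[callus])
    state <- stage(sprintf("fuzzy_step (day %d)", day),
                   step_state(state, stim, controller, map, schedule,
                              cfg$fuzzy$neighbour_aggregation))
    ifm <- interfragmentary_movement(mesh, sol$u)
    rows[[day]] <- data.frame(
      day = day,
      mean_bone = sum(w * state$c_bone) / wsum,
      max_bone = max(state$c_bone),
      mean_cartilage = sum(w * state$c_cartilage) / wsum,
      max_cartilage = max(state$c_cartilage),
      mean_connective = sum(w * state$c_connective) / wsum,
      mean_perfusion = sum(w * state$c_perfusion) / wsum,
      min_perfusion = min(state$c_perfusion),
      mean_E = sum(w * mats$E[callus]) / wsum,
      mean_eps_dis = 100 * sum(w * stim$eps_dis) / wsum,
      max_eps_dis = 100 * max(stim$eps_dis),
      mean_eps_hyd = 100 * sum(w * stim$eps_hyd) / wsum,
      ifm = ifm,
      contact_iterations = if (is.null(sol$contact)) 0L else sol$contact$iterations)
    if (!is.null(snap_dir) && cfg$run$snapshot_every > 0 &&
        day %% cfg$run$snapshot_every == 0) {
      dir.create(snap_dir, recursive = TRUE, showWarnings = FALSE)
      eh <- rep(NA_real_, nrow(mesh$tets)); eh[callus] <- stim$eps_hyd
      ed <- rep(NA_real_, nrow(mesh$tets)); ed[callus] <- stim$eps_dis
      write_field_vtu(mesh, file.path(snap_dir, sprintf("day_%03d.vtu", day)),
                      mats$E, mats$nu, eh, ed)
    }
  }
  history <- if (iterations > 0) do.call(rbind, rows) else
    data.frame(day = integer())
  structure(list(history = history, state = state, mesh = mesh, config = cfg),
            class = "healing_history")
}

#' @export
print.healing_history <- function(x, ...) {
  h <- x$history
  cat(sprintf("healing run: %d days, fixation %s\n", nrow(h), x$config$run$fixation))
  if (nrow(h)) {
    last <- h[nrow(h), ]
    cat(sprintf("  final mean bone %.1f%%, cartilage %.1f%%, connective %.1f%%\n",
                last$mean_bone, last$mean_cartilage, last$mean_connective))
    cat(sprintf("  final mean callus modulus %.0f MPa, IFM %.3f mm\n",
                last$mean_E, last$ifm))
  }
  invisible(x)
}

#' Summary report of a healing run
#'
#' Derives the headline milestones from a per-day history: the day and
#' value of peak mean cartilage, the first day mean bone exceeds 95%, and
#' the day-1 strain and interfragmentary movement.
#'
#' @param history A `healing_history` or its `history` data.frame.
#' @return List with the `table` (CSV-ready per-day summaries) and the
#'   milestone scalars.
#' @export
summarize_healing <- function(history) {
  h <- if (inherits(history, "healing_history")) history$history else history
  if (!nrow(h)) stop("history is empty")
  peak_day <- h$day[which.max(h$mean_cartilage)]
  b95 <- h$day[h$mean_bone >= 95]
  list(table = h,
       peak_cartilage = max(h$mean_cartilage),
       peak_cartilage_day = peak_day,
       bone95_day = if (length(b95)) min(b95) else NA_integer_,
       day1_mean_eps_dis = h$mean_eps_dis[1],
       day1_ifm = h$ifm[1],
       final_mean_bone = h$mean_bone[nrow(h)])
}

#' Per-element material field for the whole mesh
#'
#' Base materials by region (cortical, cancellous, implant steel) plus the
#' tissue-mixture properties for callus elements from a tissue state (or
#' the 100%-connective initial state when `state` is `NULL`).
#'
#' @param mesh An `fh_mesh`.
#' @param state Optional `tissue_state`.
#' @param cortical_transverse Use the transverse tensile modulus
#'   (10,000 MPa) for cortical bone instead of the compressive default
#'   (16,700 MPa).
#' @return List with per-element vectors `E` (MPa) and `nu`.
#' @export
material_field <- function(mesh, state = NULL, cortical_transverse = FALSE) {
  bm <- base_materials()
  get <- function(m) bm[bm$material == m, ]
  ne <- nrow(mesh$tets)
  E <- numeric(ne); nu <- numeric(ne)
  assign_reg <- function(code, row) {
    sel <- mesh$region == region_code(code)
    E[sel] <<- row$E; nu[sel] <<- row$nu
  }
  assign_reg("CORTICAL", get(if (cortical_transverse) "cortical_transverse" else "cortical"))
  assign_reg("CANCELLOUS", get("cancellous"))
  assign_reg("PLATE", get("steel"))
  assign_reg("SCREW", get("steel"))
  sel <- mesh$region == region_code("CALLUS")
  if (any(sel)) {
    if (is.null(state)) {
      mix <- mixture_properties(0, 0, 100)
      E[sel] <- mix$E; nu[sel] <- mix$nu
    } else {
      mix <- mixture_properties(state$c_bone, state$c_cartilage, state$c_connective)
      E[state$elements] <- mix$E
      nu[state$elements] <- mix$nu
    }
  }
  list(E = E, nu = nu)
}
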