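# Small-strain linear-elastic tet4 finite elements with screw pretension and
# frictional node-to-node penalty contact (DCP), on the N-mm-MPa system.
#
# The element stiffness of an isotropic tet4 splits into a lambda part and a
# mu part that depend on geometry only; both are precomputed per element so
# that the daily material update reduces to scaling two vectors and
# refreshing the values of a constant sparsity pattern (the symbolic
# Cholesky factorization is reused across days and contact iterations).

#' Load case for the healing simulation
#'
#' Defaults reproduce the study conditions: a 2.1 kN static load applied at
#' the proximal end along a direction tilted 10 degrees in the frontal and
#' 10 degrees in the sagittal plane from the bone axis, zero displacement at
#' the distal end, and (for DCP) a 500 N pretension per distal screw with
#' Coulomb friction coefficient 0.3 at the contact interfaces.
#'
#' @param load_magnitude Resultant load in N (default 2100).
#' @param frontal_tilt,sagittal_tilt Load direction tilts in degrees about
#'   the y and x axes (defaults 10 and 10).
#' @param head_offset Medial lever arm (mm) of the load resultant: the
#'   force acts along the tilted direction through a point offset by
#'   `head_offset` towards -x from the shaft axis, emulating the femoral
#'   head; realized as an equivalent force + couple on the load face.
#' @param pretension_force Pretension per distal screw in N (DCP only).
#' @param friction_coefficient Coulomb friction coefficient (DCP only).
#' @param fixed_node_set,load_node_set Names of the node sets carrying the
#'   zero-displacement condition and the distributed load.
#' @param load_direction Optional explicit unit load direction overriding
#'   the tilt construction.
#' @param penalty_normal,penalty_tangent Contact penalty stiffnesses in
#'   N/mm per node pair.
#' @param stabilization Stiffness of the permanent stabilization spring on
#'   every contact pair (keeps separated bodies non-singular), N/mm.
#' @param contact_max_iter,contact_tol Stick/slip iteration limit and force
#'   convergence tolerance in N.
#' @param contact_relaxation Under-relaxation factor applied to the Coulomb
#'   slip correction forces (0 < value <= 1).
#' @return A validated list of class `load_case`.
#' @export
load_case <- function(load_magnitude = 2100, frontal_tilt = 10,
                      sagittal_tilt = 10, head_offset = 20,
                      pretension_force = 500,
                      friction_coefficient = 0.3,
                      fixed_node_set = "FIXED", load_node_set = "LOAD",
                      load_direction = NULL,
                      penalty_normal = 1e5, penalty_tangent = 1e3,
                      stabilization = 1e-2,
                      contact_max_iter = 50L, contact_tol = 1e-3,
                      contact_relaxation = 0.7) {
  if (load_magnitude < 0) stop("load_magnitude must be >= 0")
  if (pretension_force < 0) stop("pretension_force must be >= 0")
  if (friction_coefficient < 0) stop("friction_coefficient must be >= 0")
  structure(list(load_magnitude = load_magnitude, frontal_tilt = frontal_tilt,
                 sagittal_tilt = sagittal_tilt, head_offset = head_offset,
                 pretension_force = pretension_force,
                 friction_coefficient = friction_coefficient,
                 fixed_node_set = fixed_node_set, load_node_set = load_node_set,
                 load_direction = load_direction,
                 penalty_normal = penalty_normal,
                 penalty_tangent = penalty_tangent,
                 stabilization = stabilization,
                 contact_max_iter = as.integer(contact_max_iter),
                 contact_tol = contact_tol,
                 contact_relaxation = contact_relaxation),
            class = "load_case")
}

load_direction_vector <- function(load) {
  if (!is.null(load$load_direction)) {
    v <- load$load_direction
    return(v / sqrt(sum(v^2)))
  }
  fr <- load$frontal_tilt * pi / 180
  sg <- load$sagittal_tilt * pi / 180
  v <- c(0, 0, -1)
  v <- c(cos(fr) * v[1] + sin(fr) * v[3], v[2], -sin(fr) * v[1] + cos(fr) * v[3])
  v <- c(v[1], cos(sg) * v[2] - sin(sg) * v[3], sin(sg) * v[2] + cos(sg) * v[3])
  v / sqrt(sum(v^2))
}

# Shape-function gradients and volumes of all tets.
shape_gradients <- function(nodes, tets) {
  x1 <- nodes[tets[, 1], , drop = FALSE]
  d1 <- nodes[tets[, 2], , drop = FALSE] - x1
  d2 <- nodes[tets[, 3], , drop = FALSE] - x1
  d3 <- nodes[tets[, 4], , drop = FALSE] - x1
  a11 <- d1[, 1]; a21 <- d1[, 2]; a31 <- d1[, 3]
  a12 <- d2[, 1]; a22 <- d2[, 2]; a32 <- d2[, 3]
  a13 <- d3[, 1]; a23 <- d3[, 2]; a33 <- d3[, 3]
  det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  if (any(det <= 0)) stop("mesh contains non-positively-oriented tets")
  g2 <- cbind((a22 * a33 - a23 * a32), (a13 * a32 - a12 * a33), (a12 * a23 - a13 * a22)) / det
  g3 <- cbind((a23 * a31 - a21 * a33), (a11 * a33 - a13 * a31), (a13 * a21 - a11 * a23)) / det
  g4 <- cbind((a21 * a32 - a22 * a31), (a12 * a31 - a11 * a32), (a11 * a22 - a12 * a21)) / det
  g1 <- -(g2 + g3 + g4)
  list(G = list(g1, g2, g3, g4), vol = det / 6)
}

#' Precompute a finite-element context for repeated solves
#'
#' Assembles everything that does not depend on the material field: shape
#' gradients, the lambda/mu split of every element stiffness, the constant
#' sparsity pattern (including contact-spring slots), the Dirichlet
#' partition, the external load vector and the pretension forces.
#'
#' @param mesh An `fh_mesh`.
#' @param load A [load_case()].
#' @param fixation `"LP"` or `"DCP"`; defaults to the mesh's fixation (or
#'   LP when the mesh carries none).
#' @param dirichlet Optional data.frame with columns `node`, `comp` (1..3)
#'   and `value` prescribing displacements; by default all components of
#'   the `fixed_node_set` are fixed at zero.
#' @return An object of class `fe_context`.
#' @export
fe_context <- function(mesh, load = load_case(), fixation = NULL,
                       dirichlet = NULL) {
  stopifnot(inherits(mesh, "fh_mesh"))
  if (is.null(fixation)) fixation <- if (is.null(mesh$fixation)) "LP" else mesh$fixation
  fixation <- match.arg(fixation, c("LP", "DCP"))
  n <- nrow(mesh$nodes); ndof <- 3L * n
  tets <- mesh$tets
  ne <- nrow(tets)
  sg <- shape_gradients(mesh$nodes, tets)
  G <- sg$G; vol <- sg$vol
  GG <- vector("list", 4L)
  for (a in 1:4) {
    GG[[a]] <- vector("list", 4L)
    for (b in 1:4) GG[[a]][[b]] <- rowSums(G[[a]] * G[[b]])
  }
  Klam <- matrix(0, ne, 144L)
  Kmu <- matrix(0, ne, 144L)
  II <- matrix(0L, ne, 144L)
  JJ <- matrix(0L, ne, 144L)
  k <- 0L
  for (a in 1:4) for (i in 1:3) for (b in 1:4) for (j in 1:3) {
    k <- k + 1L
    Klam[, k] <- vol * G[[a]][, i] * G[[b]][, j]
    Kmu[, k] <- vol * (G[[a]][, j] * G[[b]][, i] + (i == j) * GG[[a]][[b]])
    II[, k] <- 3L * (tets[, a] - 1L) + i
    JJ[, k] <- 3L * (tets[, b] - 1L) + j
  }
  I_e <- as.vector(II); J_e <- as.vector(JJ)

  # contact spring slots (values set per iteration)
  pairs <- mesh$contact_pairs
  has_contact <- fixation == "DCP" && nrow(pairs) > 0L
  if (has_contact) {
    np <- nrow(pairs)
    pdof <- cbind(3L * (pairs$node_a - 1L) + 1L, 3L * (pairs$node_a - 1L) + 2L,
                  3L * (pairs$node_a - 1L) + 3L, 3L * (pairs$node_b - 1L) + 1L,
                  3L * (pairs$node_b - 1L) + 2L, 3L * (pairs$node_b - 1L) + 3L)
    Ic <- matrix(0L, np, 36L); Jc <- matrix(0L, np, 36L)
    csign <- numeric(36L); cidx <- integer(36L)
    k <- 0L
    for (p in 1:6) for (q in 1:6) {
      k <- k + 1L
      Ic[, k] <- pdof[, p]; Jc[, k] <- pdof[, q]
      csign[k] <- if ((p <= 3L) == (q <= 3L)) 1 else -1
      cidx[k] <- ((p - 1L) %% 3L) + 3L * ((q - 1L) %% 3L) + 1L  # into 3x3 C (col-major)
    }
    I_all <- c(I_e, as.vector(Ic)); J_all <- c(J_e, as.vector(Jc))
  } else {
    np <- 0L
    csign <- numeric(); cidx <- integer()
    I_all <- I_e; J_all <- J_e
  }
  n_elem_trip <- length(I_e)

  # Dirichlet partition
  if (is.null(dirichlet)) {
    fixed_nodes <- mesh$node_sets[[load$fixed_node_set]]
    if (is.null(fixed_nodes) || !length(fixed_nodes)) {
      stop("singular stiffness (insufficient constraints): node set '",
           load$fixed_node_set,
           "' is empty and no `dirichlet` table was given")
    }
    dirichlet <- data.frame(node = rep(fixed_nodes, each = 3L),
                            comp = rep(1:3, length(fixed_nodes)),
                            value = 0)
  }
  fixed_dof <- 3L * (dirichlet$node - 1L) + dirichlet$comp
  if (anyDuplicated(fixed_dof)) stop("duplicate Dirichlet entries")
  is_free <- rep(TRUE, ndof)
  is_free[fixed_dof] <- FALSE
  free_idx <- integer(ndof)
  free_idx[is_free] <- seq_len(sum(is_free))
  fixed_idx <- integer(ndof)
  fixed_idx[fixed_dof] <- seq_along(fixed_dof)
  u_fixed <- numeric(length(fixed_dof))
  u_fixed[fixed_idx[fixed_dof]] <- dirichlet$value
  nfree <- sum(is_free)

  sel_ff <- which(is_free[I_all] & is_free[J_all] & I_all <= J_all)
  sel_fc <- which(is_free[I_all] & !is_free[J_all])
  key_ff <- (as.numeric(free_idx[J_all[sel_ff]]) - 1) * nfree + free_idx[I_all[sel_ff]]
  uk_ff <- sort(unique(key_ff))
  pos_ff <- findInterval(key_ff, uk_ff)
  key_fc <- (as.numeric(fixed_idx[J_all[sel_fc]]) - 1) * nfree + free_idx[I_all[sel_fc]]
  uk_fc <- sort(unique(key_fc))
  pos_fc <- findInterval(key_fc, uk_fc)

  i_ff <- as.integer((uk_ff - 1) %% nfree + 1)
  j_ff <- as.integer((uk_ff - 1) %/% nfree + 1)
  Kff <- Matrix::sparseMatrix(i = i_ff, j = j_ff, x = seq_along(uk_ff),
                              dims = c(nfree, nfree), symmetric = TRUE)
  perm_ff <- as.integer(Kff@x)
  i_fc <- as.integer((uk_fc - 1) %% nfree + 1)
  j_fc <- as.integer((uk_fc - 1) %/% nfree + 1)
  Kfc <- Matrix::sparseMatrix(i = i_fc, j = j_fc, x = seq_along(uk_fc),
                              dims = c(nfree, length(fixed_dof)))
  perm_fc <- as.integer(Kfc@x)

  # split the ff aggregation into the daily element part and the
  # per-contact-iteration part
  elem_part_ff <- sel_ff <= n_elem_trip
  con_sel_ff <- sel_ff[!elem_part_ff] - n_elem_trip
  con_pos_ff <- pos_ff[!elem_part_ff]
  if (np > 0L) {
    con_trip <- (n_elem_trip + 1L):length(I_all)
    if (any(!is_free[I_all[con_trip]]) || any(!is_free[J_all[con_trip]])) {
      stop("contact pair nodes must not carry Dirichlet conditions")
    }
  }

  # external loads
  f_ext <- numeric(ndof)
  load_nodes <- mesh$node_sets[[load$load_node_set]]
  if (!is.null(load_nodes) && length(load_nodes) && load$load_magnitude > 0) {
    v <- load_direction_vector(load) * load$load_magnitude / length(load_nodes)
    f_ext[3L * (load_nodes - 1L) + 1L] <- f_ext[3L * (load_nodes - 1L) + 1L] + v[1]
    f_ext[3L * (load_nodes - 1L) + 2L] <- f_ext[3L * (load_nodes - 1L) + 2L] + v[2]
    f_ext[3L * (load_nodes - 1L) + 3L] <- f_ext[3L * (load_nodes - 1L) + 3L] + v[3]
    if (load$head_offset != 0) {
      # couple of the resultant acting head_offset medial (-x) of the axis:
      # M = (-d, 0, 0) x F, realized as the minimum-norm rotational force
      # field f_i = omega x r_i on the load face
      Ftot <- load_direction_vector(load) * load$load_magnitude
      M <- c(0, load$head_offset * Ftot[3], -load$head_offset * Ftot[2])
      r <- sweep(mesh$nodes[load_nodes, , drop = FALSE], 2,
                 colMeans(mesh$nodes[load_nodes, , drop = FALSE]))
      J <- diag(3) * sum(r^2) - crossprod(r)
      om <- solve(J, M)
      fi <- cbind(om[2] * r[, 3] - om[3] * r[, 2],
                  om[3] * r[, 1] - om[1] * r[, 3],
                  om[1] * r[, 2] - om[2] * r[, 1])
      for (k in 1:3) {
        f_ext[3L * (load_nodes - 1L) + k] <- f_ext[3L * (load_nodes - 1L) + k] + fi[, k]
      }
    }
  }
  if (fixation == "DCP" && load$pretension_force > 0) {
    for (s in mesh$pretension) {
      f_ext[3L * (s$upper - 1L) + 1L] <-
        f_ext[3L * (s$upper - 1L) + 1L] - load$pretension_force / length(s$upper)
      f_ext[3L * (s$lower - 1L) + 1L] <-
        f_ext[3L * (s$lower - 1L) + 1L] + load$pretension_force / length(s$lower)
    }
  }

  # orthonormal tangent basis per contact pair
  contact <- NULL
  if (has_contact) {
    nrm <- cbind(pairs$nx, pairs$ny, pairs$nz)
    ref <- matrix(rep(c(0, 0, 1), each = np), np, 3)
    swap <- abs(nrm[, 3]) > 0.9
    ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
    t1 <- cbind(nrm[, 2] * ref[, 3] - nrm[, 3] * ref[, 2],
                nrm[, 3] * ref[, 1] - nrm[, 1] * ref[, 3],
                nrm[, 1] * ref[, 2] - nrm[, 2] * ref[, 1])
    t1 <- t1 / sqrt(rowSums(t1^2))
    t2 <- cbind(nrm[, 2] * t1[, 3] - nrm[, 3] * t1[, 2],
                nrm[, 3] * t1[, 1] - nrm[, 1] * t1[, 3],
                nrm[, 1] * t1[, 2] - nrm[, 2] * t1[, 1])
    contact <- list(pairs = pairs, nrm = nrm, t1 = t1, t2 = t2,
                    dof_a = cbind(3L * (pairs$node_a - 1L) + 1L,
                                  3L * (pairs$node_a - 1L) + 2L,
                                  3L * (pairs$node_a - 1L) + 3L),
                    dof_b = cbind(3L * (pairs$node_b - 1L) + 1L,
                                  3L * (pairs$node_b - 1L) + 2L,
                                  3L * (pairs$node_b - 1L) + 3L),
                    csign = csign, cidx = cidx)
  }

  structure(list(
    mesh = mesh, load = load, fixation = fixation,
    ndof = ndof, nfree = nfree,
    Klam = Klam, Kmu = Kmu,
    n_elem_trip = n_elem_trip,
    sel_ff = sel_ff, pos_ff = pos_ff, elem_part_ff = elem_part_ff,
    con_sel_ff = con_sel_ff, con_pos_ff = con_pos_ff,
    n_uk_ff = length(uk_ff),
    sel_fc = sel_fc, pos_fc = pos_fc, n_uk_fc = length(uk_fc),
    Kff = Kff, perm_ff = perm_ff, Kfc = Kfc, perm_fc = perm_fc,
    is_free = is_free, free_idx = free_idx, fixed_dof = fixed_dof,
    u_fixed = u_fixed, f_ext = f_ext,
    contact = contact,
    cache = new.env(parent = emptyenv())
  ), class = "fe_context")
}

# Per-element Lame parameters.
lame_parameters <- function(E, nu) {
  if (any(E <= 0)) stop("Young's modulus must be positive for every element")
  if (any(nu <= 0 | nu >= 0.5)) stop("Poisson's ratio must lie in (0, 0.5)")
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)), mu = E / (2 * (1 + nu)))
}

# Aggregate a value vector over precomputed slot positions.
agg_into <- function(n_slots, vals, pos) {
  out <- numeric(n_slots)
  tab <- rowsum(vals, pos)
  out[as.integer(rownames(tab))] <- tab[, 1]
  out
}

#' Solve the elastic problem for a material field
#'
#' Runs a static solve on a prebuilt [fe_context()].  For DCP contexts with
#' contact pairs an active-set stick/slip penalty iteration is performed
#' (normal springs active in compression, tangential stick springs replaced
#' by Coulomb slip forces where the friction limit is exceeded); the loop
#' errors out if it does not converge within the configured iteration
#' budget.
#'
#' @param ctx An [fe_context()].
#' @param E,nu Per-element material vectors (MPa, unitless).
#' @return List with `u` (n x 3 nodal displacements, mm), `fint` (internal
#'   force vector), `reactions` (at fixed dofs), and `contact` diagnostics
#'   (`iterations`, `normal_force`, `slip` or `NULL`).
#' @export
fe_solve <- function(ctx, E, nu) {
  stopifnot(inherits(ctx, "fe_context"))
  ne <- nrow(ctx$Klam)
  if (length(E) != ne || length(nu) != ne) {
    stop("materials must be defined for every element")
  }
  lp <- lame_parameters(E, nu)
  Vmat <- ctx$Klam * lp$lambda + ctx$Kmu * lp$mu
  vals_e <- as.vector(Vmat)

  agg_ff <- agg_into(ctx$n_uk_ff,
                     vals_e[ctx$sel_ff[ctx$elem_part_ff] ],
                     ctx$pos_ff[ctx$elem_part_ff])
  sel_fc_elem <- ctx$sel_fc[ctx$sel_fc <= ctx$n_elem_trip]
  agg_fc <- agg_into(ctx$n_uk_fc, vals_e[sel_fc_elem],
                     ctx$pos_fc[ctx$sel_fc <= ctx$n_elem_trip])
  Kfc <- ctx$Kfc
  Kfc@x <- agg_fc[ctx$perm_fc]
  rhs_base <- ctx$f_ext[ctx$is_free] - as.numeric(Kfc %*% ctx$u_fixed)

  solve_with <- function(agg, extra_f = NULL) {
    Kff <- ctx$Kff
    Kff@x <- agg[ctx$perm_ff]
    ch <- ctx$cache$chol
    ch <- tryCatch({
      if (is.null(ch)) Matrix::Cholesky(Kff) else Matrix::update(ch, Kff)
    }, error = function(e) {
      stop("singular stiffness (insufficient constraints): ", conditionMessage(e))
    })
    ctx$cache$chol <- ch
    rhs <- rhs_base
    if (!is.null(extra_f)) rhs <- rhs + extra_f[ctx$is_free]
    uf <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
    resid <- sqrt(sum((as.numeric(Kff %*% uf) - rhs)^2))
    if (anyNA(uf) || any(!is.finite(uf)) ||
        resid > 1e-6 * max(1, sqrt(sum(rhs^2)))) {
      stop("singular stiffness (insufficient constraints): solve residual ",
           format(resid, digits = 3))
    }
    u <- numeric(ctx$ndof)
    u[ctx$is_free] <- uf
    u[ctx$fixed_dof] <- ctx$u_fixed
    u
  }

  con <- ctx$contact
  if (is.null(con)) {
    u <- solve_with(agg_ff)
    contact_info <- NULL
  } else {
    np <- nrow(con$pairs)
    kn <- ctx$load$penalty_normal
    kt <- ctx$load$penalty_tangent
    k0 <- ctx$load$stabilization
    mu_f <- ctx$load$friction_coefficient
    omega <- ctx$load$contact_relaxation  # under-relaxation of slip corrections
    # warm start from the previous solve on this context (the healing loop
    # changes materials gradually, so yesterday's contact state is close)
    ws <- ctx$cache$contact_state
    if (!is.null(ws)) {
      active <- ws$active; slip <- ws$slip; c_app <- ws$c_app
    } else {
      active <- rep(TRUE, np); slip <- rep(FALSE, np)
      c_app <- matrix(0, np, 3)   # slip correction force applied on node b
    }
    Fn <- numeric(np)
    F_old <- matrix(0, np, 3)
    dF_prev <- Inf
    r_prev <- NULL
    u <- NULL
    converged <- FALSE
    eye <- c(1, 0, 0, 0, 1, 0, 0, 0, 1)
    nn <- cbind(con$nrm[, 1] * con$nrm[, 1], con$nrm[, 2] * con$nrm[, 1],
                con$nrm[, 3] * con$nrm[, 1], con$nrm[, 1] * con$nrm[, 2],
                con$nrm[, 2] * con$nrm[, 2], con$nrm[, 3] * con$nrm[, 2],
                con$nrm[, 1] * con$nrm[, 3], con$nrm[, 2] * con$nrm[, 3],
                con$nrm[, 3] * con$nrm[, 3])
    dF <- Inf
    for (it in seq_len(ctx$load$contact_max_iter)) {
      # per-pair 3x3 spring matrix: active pairs carry the normal penalty,
      # sticking pairs additionally the tangential penalty; slipping pairs
      # get their Coulomb friction as (under-relaxed) applied forces
      Cmat <- matrix(eye * k0, np, 9L, byrow = TRUE)
      act <- which(active)
      if (length(act)) {
        Cmat[act, ] <- Cmat[act, , drop = FALSE] + kn * nn[act, , drop = FALSE]
      }
      stick <- which(active & !slip)
      if (length(stick)) {
        tang <- matrix(eye, length(stick), 9L, byrow = TRUE) - nn[stick, , drop = FALSE]
        Cmat[stick, ] <- Cmat[stick, , drop = FALSE] + kt * tang
      }
      cvals <- Cmat[, con$cidx] * matrix(con$csign, np, 36L, byrow = TRUE)
      agg <- agg_ff
      add <- rowsum(as.vector(cvals)[ctx$con_sel_ff], ctx$con_pos_ff)
      slots <- as.integer(rownames(add))
      agg[slots] <- agg[slots] + add[, 1]

      f_con <- NULL
      if (any(c_app != 0)) {
        f_con <- numeric(ctx$ndof)
        for (cix in 1:3) {
          f_con[con$dof_b[, cix]] <- f_con[con$dof_b[, cix]] + c_app[, cix]
          f_con[con$dof_a[, cix]] <- f_con[con$dof_a[, cix]] - c_app[, cix]
        }
      }
      u <- solve_with(agg, f_con)
      du <- cbind(u[con$dof_b[, 1]] - u[con$dof_a[, 1]],
                  u[con$dof_b[, 2]] - u[con$dof_a[, 2]],
                  u[con$dof_b[, 3]] - u[con$dof_a[, 3]])
      gn <- rowSums(du * con$nrm)
      ut <- du - gn * con$nrm
      ut_len <- sqrt(rowSums(ut^2))
      # an isolated pair can chatter between active and separated in a
      # period-2 cycle with sub-newton amplitude; freeze the sets late in
      # the iteration and let the force fixed point settle
      frozen <- it >= 30L
      new_active <- if (frozen) active else gn < 0
      Fn <- ifelse(new_active, pmax(0, -kn * gn), 0)
      dir <- ut / pmax(ut_len, 1e-300)
      # stick -> slip when the stick spring force exceeds the Coulomb
      # limit; slip pairs return to stick when the limit is no longer
      # demanded (their friction force exceeds kt times the tangential slide)
      new_slip <- active & !slip & new_active & (kt * ut_len > mu_f * Fn + 1e-12)
      new_slip <- new_slip | (slip & new_active & (mu_f * Fn < kt * ut_len))
      if (frozen) new_slip <- slip
      # friction force opposing the tangential slide of node b, applied
      # with Aitken dynamic relaxation on the correction residual
      c_target <- matrix(0, np, 3)
      sl <- which(new_slip)
      if (length(sl)) {
        c_target[sl, ] <- -mu_f * Fn[sl] * dir[sl, , drop = FALSE]
      }
      r_res <- c_target - c_app
      if (all(new_active == active) && all(new_slip == slip) &&
          !is.null(r_prev)) {
        dr <- r_res - r_prev
        den <- sum(dr^2)
        if (den > 0) {
          omega <- min(10, max(0.05, -omega * sum(r_prev * dr) / den))
        }
      } else {
        omega <- ctx$load$contact_relaxation
      }
      r_prev <- r_res
      c_app <- c_app + omega * r_res
      Ft_net <- ifelse(new_slip, mu_f * Fn,
                       ifelse(new_active, pmin(kt * ut_len, mu_f * Fn), 0))
      F_new <- -Fn * con$nrm - Ft_net * dir
      same_sets <- all(new_active == active) && all(new_slip == slip)
      dF <- max(abs(F_new - F_old), abs(c_target - c_app))
      if (isTRUE(getOption("callusim.contact_trace"))) {
        cat(sprintf("it %3d active %3d (flip %2d) slip %3d dF %.4g\n",
                    it, sum(new_active), sum(new_active != active),
                    sum(new_slip), dF))
      }
      active <- new_active; slip <- new_slip
      F_old <- F_new
      if (same_sets && dF < ctx$load$contact_tol) {
        converged <- TRUE
        break
      }
      dF_prev <- dF
    }
    if (!converged) {
      stop(sprintf("contact iteration did not converge within %d iterations (residual %.3g N)",
                   ctx$load$contact_max_iter, dF))
    }
    ctx$cache$contact_state <- list(active = active, slip = slip, c_app = c_app)
    contact_info <- list(iterations = it, normal_force = Fn, slip = slip)
  }

  fint <- internal_forces(ctx, Vmat, u)
  reactions <- fint[ctx$fixed_dof] - ctx$f_ext[ctx$fixed_dof]
  list(u = matrix(u, ncol = 3, byrow = TRUE), u_flat = u,
       fint = fint, reactions = reactions, contact = contact_info)
}

# Elastic internal nodal forces sum_e Ke u_e, scattered to global dofs.
internal_forces <- function(ctx, Vmat, u) {
  tets <- ctx$mesh$tets
  ne <- nrow(tets)
  Ue <- matrix(0, ne, 12L)
  IL <- matrix(0L, ne, 12L)
  m <- 0L
  for (b in 1:4) for (j in 1:3) {
    m <- m + 1L
    dofs <- 3L * (tets[, b] - 1L) + j
    Ue[, m] <- u[dofs]
    IL[, m] <- dofs
  }
  floc <- matrix(0, ne, 12L)
  for (l in 1:12) {
    cols <- (l - 1L) * 12L + (1:12)
    floc[, l] <- rowSums(Vmat[, cols, drop = FALSE] * Ue)
  }
  out <- numeric(ctx$ndof)
  tab <- rowsum(as.vector(floc), as.vector(IL))
  out[as.integer(rownames(tab))] <- tab[, 1]
  out
}

#' One-shot assembly and solve
#'
#' Convenience wrapper building a fresh [fe_context()] and solving it once.
#' For the iterated healing loop build the context once and call
#' [fe_solve()] repeatedly instead.
#'
#' @param mesh An `fh_mesh`.
#' @param materials List with per-element vectors `E` and `nu`.
#' @param load A [load_case()].
#' @param fixation `"LP"` or `"DCP"`.
#' @param dirichlet Optional prescribed-displacement table, see
#'   [fe_context()].
#' @return See [fe_solve()].
#' @export
assemble_and_solve <- function(mesh, materials, load = load_case(),
                               fixation = NULL, dirichlet = NULL) {
  ctx <- fe_context(mesh, load, fixation, dirichlet)
  fe_solve(ctx, materials$E, materials$nu)
}

#' Per-element strain invariants
#'
#' Computes the constant small-strain tensor of every tet4 element from the
#' nodal displacements, its principal strains (closed-form symmetric 3x3
#' eigenvalues, sorted descending), the hydrostatic strain
#' \eqn{\varepsilon_{hyd} = (\varepsilon_1+\varepsilon_2+\varepsilon_3)/3}
#' and the distortional strain
#' \eqn{\varepsilon_{dis} = \frac{1}{\sqrt2}\sqrt{(\varepsilon_1-\varepsilon_2)^2
#' + (\varepsilon_2-\varepsilon_3)^2 + (\varepsilon_3-\varepsilon_1)^2}}.
#'
#' @param mesh An `fh_mesh`.
#' @param u Nodal displacement matrix (n x 3) or flat vector, mm.
#' @return List with vectors `eps_hyd`, `eps_dis` and the E x 3 matrix
#'   `principal` (all dimensionless).
#' @export
element_strain_invariants <- function(mesh, u) {
  if (is.matrix(u)) u <- as.vector(t(u))
  tets <- mesh$tets
  sg <- shape_gradients(mesh$nodes, tets)
  G <- sg$G
  comp <- function(i) cbind(u[3L * (tets[, 1] - 1L) + i], u[3L * (tets[, 2] - 1L) + i],
                            u[3L * (tets[, 3] - 1L) + i], u[3L * (tets[, 4] - 1L) + i])
  U1 <- comp(1L); U2 <- comp(2L); U3 <- comp(3L)
  gi <- function(i) cbind(G[[1]][, i], G[[2]][, i], G[[3]][, i], G[[4]][, i])
  Gx <- gi(1L); Gy <- gi(2L); Gz <- gi(3L)
  exx <- rowSums(Gx * U1)
  eyy <- rowSums(Gy * U2)
  ezz <- rowSums(Gz * U3)
  exy <- 0.5 * (rowSums(Gy * U1) + rowSums(Gx * U2))
  exz <- 0.5 * (rowSums(Gz * U1) + rowSums(Gx * U3))
  eyz <- 0.5 * (rowSums(Gz * U2) + rowSums(Gy * U3))
  principal_strains_sym3(exx, eyy, ezz, exy, exz, eyz)
}

# Closed-form eigenvalues of symmetric 3x3 tensors (vectorized), plus the
# hydrostatic and distortional invariants.
principal_strains_sym3 <- function(exx, eyy, ezz, exy, exz, eyz) {
  q <- (exx + eyy + ezz) / 3
  p2 <- (exx - q)^2 + (eyy - q)^2 + (ezz - q)^2 + 2 * (exy^2 + exz^2 + eyz^2)
  p <- sqrt(p2 / 6)
  e1 <- e2 <- e3 <- q
  nz <- which(p > 0)
  if (length(nz)) {
    b11 <- (exx[nz] - q[nz]) / p[nz]; b22 <- (eyy[nz] - q[nz]) / p[nz]
    b33 <- (ezz[nz] - q[nz]) / p[nz]
    b12 <- exy[nz] / p[nz]; b13 <- exz[nz] / p[nz]; b23 <- eyz[nz] / p[nz]
    detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(1, pmax(-1, detb / 2))
    phi <- acos(r) / 3
    e1[nz] <- q[nz] + 2 * p[nz] * cos(phi)
    e3[nz] <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    e2[nz] <- 3 * q[nz] - e1[nz] - e3[nz]
  }
  eps_dis <- sqrt(((e1 - e2)^2 + (e2 - e3)^2 + (e3 - e1)^2) / 2)
  list(eps_hyd = (e1 + e2 + e3) / 3, eps_dis = eps_dis,
       principal = cbind(e1, e2, e3))
}

#' Interfragmentary movement
#'
#' Magnitude of the difference between the mean displacement vectors of the
#' proximal and distal fracture-face node sets.
#'
#' @param mesh An `fh_mesh` with `FRAGMENT_END_PROXIMAL` and
#'   `FRAGMENT_END_DISTAL` node sets.
#' @param u Nodal displacement matrix (n x 3) or flat vector, mm.
#' @return IFM in mm.
#' @export
interfragmentary_movement <- function(mesh, u) {
  if (!is.matrix(u)) u <- matrix(u, ncol = 3, byrow = TRUE)
  prox <- mesh$node_sets$FRAGMENT_END_PROXIMAL
  dist <- mesh$node_sets$FRAGMENT_END_DISTAL
  if (!length(prox) || !length(dist)) {
    stop("fragment-end node sets are empty; cannot compute IFM")
  }
  d <- colMeans(u[prox, , drop = FALSE]) - colMeans(u[dist, , drop = FALSE])
  sqrt(sum(d^2))
}
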