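# Parametric voxel geometry for the fractured, plated bone segment.
#
# The generator meshes an idealized straight diaphyseal segment (hollow
# cortical cylinder with a cancellous core) on a structured Cartesian grid:
# feature planes (fracture faces, plate faces, screw columns, segment ends)
# are inserted exactly, every interval is subdivided to the target edge
# length, and each grid cell is split into six tetrahedra sharing the cell
# diagonal so the mesh is conforming.  Curved boundaries (cortex radii,
# callus ellipsoid) are classified by a 3x3x3 sub-sample majority per cell,
# a staircase approximation whose region volumes stay accurate at coarse
# grids.  Everything is deterministic: identical parameters produce
# identical meshes.

REGION_LEVELS <- c("CORTICAL", "CANCELLOUS", "CALLUS", "PLATE", "SCREW")

region_code <- function(name) match(name, REGION_LEVELS)

#' Geometry parameters for the fracture model
#'
#' All lengths in millimetres; the bone axis is z (right-handed frame,
#' plate on the +x side), forces in newtons, moduli in MPa.
#'
#' @param bone_outer_radius Outer cortical radius.
#' @param cortex_thickness Cortical wall thickness (must be smaller than the
#'   outer radius).
#' @param segment_length Total length of the modelled segment.
#' @param gap_width Transverse fracture gap (default 20 mm).
#' @param callus_axial_semiaxis,callus_radial_semiaxis Semi-axes of the
#'   ellipsoidal callus envelope (axial along z); the radial semi-axis must
#'   exceed the bone radius and the gap must fit inside the axial extent.
#' @param plate_offset Stand-off between plate and bone surface for locked
#'   plating (ignored for DCP, where the plate sits flush).
#' @param plate_width,plate_thickness Plate cross-section (y width, x
#'   thickness).
#' @param screw_radius Screw shaft radius.
#' @param screw_axial_positions z offsets of the screws from the gap centre;
#'   negative values are distal (fixed-end) screws.
#' @param target_edge_length Target mesh edge length; 4.5 mm is the coarse
#'   desk-scale preset, 1.0 mm the medium density.
#' @return A validated list of class `geometry_params`.
#' @export
geometry_params <- function(bone_outer_radius = 13.5,
                            cortex_thickness = 5,
                            segment_length = 120,
                            gap_width = 20,
                            callus_axial_semiaxis = 30,
                            callus_radial_semiaxis = 25,
                            plate_offset = 0.5,
                            plate_width = 12,
                            plate_thickness = 5,
                            screw_radius = 2.25,
                            screw_axial_positions = c(-40, -25, 25, 40),
                            target_edge_length = 4.5) {
  p <- list(bone_outer_radius = bone_outer_radius,
            cortex_thickness = cortex_thickness,
            segment_length = segment_length,
            gap_width = gap_width,
            callus_axial_semiaxis = callus_axial_semiaxis,
            callus_radial_semiaxis = callus_radial_semiaxis,
            plate_offset = plate_offset,
            plate_width = plate_width,
            plate_thickness = plate_thickness,
            screw_radius = screw_radius,
            screw_axial_positions = sort(as.numeric(screw_axial_positions)),
            target_edge_length = target_edge_length)
  lens <- unlist(p[c("bone_outer_radius", "cortex_thickness", "segment_length",
                     "gap_width", "callus_axial_semiaxis",
                     "callus_radial_semiaxis", "plate_width",
                     "plate_thickness", "screw_radius", "target_edge_length")])
  if (anyNA(lens) || any(lens <= 0)) {
    stop("all geometry lengths must be positive")
  }
  if (p$plate_offset < 0) stop("plate_offset must be >= 0")
  if (p$cortex_thickness >= p$bone_outer_radius) {
    stop("cortex_thickness must be smaller than bone_outer_radius")
  }
  if (p$callus_radial_semiaxis <= p$bone_outer_radius) {
    stop("callus_radial_semiaxis must exceed bone_outer_radius")
  }
  if (p$gap_width >= 2 * p$callus_axial_semiaxis) {
    stop("gap_width must be smaller than twice callus_axial_semiaxis")
  }
  if (p$gap_width + 2 >= p$segment_length) {
    stop("segment_length must comfortably exceed gap_width")
  }
  if (!length(p$screw_axial_positions) ||
      any(p$screw_axial_positions < 0) == FALSE ||
      any(p$screw_axial_positions > 0) == FALSE) {
    stop("screw_axial_positions must contain screws on both fragments")
  }
  if (any(abs(p$screw_axial_positions) <= p$gap_width / 2)) {
    stop("screws must not lie inside the fracture gap")
  }
  structure(p, class = "geometry_params")
}

# Subdivide the intervals between sorted feature coordinates so that no
# edge exceeds h.
axis_breaks <- function(features, h) {
  f <- sort(unique(features))
  out <- f[1]
  for (k in seq_len(length(f) - 1L)) {
    n <- max(1L, ceiling((f[k + 1L] - f[k]) / h - 1e-9))
    out <- c(out, f[k] + (f[k + 1L] - f[k]) * seq_len(n) / n)
  }
  out
}

# Split selected grid cells of a structured grid into 6 tetrahedra each.
# cells: data.frame-ish list with integer ix, iy, iz (cell indices) and
# integer region codes.  Returns nodes/tets/region with compact numbering.
voxel_tets <- function(xp, yp, zp, ix, iy, iz, region) {
  nxp <- length(xp); nyp <- length(yp)
  nid <- function(i, j, k) i + (j - 1L) * nxp + (k - 1L) * (nxp * nyp)
  v <- list(
    nid(ix,      iy,      iz),      # v0
    nid(ix + 1L, iy,      iz),      # v1
    nid(ix + 1L, iy + 1L, iz),      # v2
    nid(ix,      iy + 1L, iz),      # v3
    nid(ix,      iy,      iz + 1L), # v4
    nid(ix + 1L, iy,      iz + 1L), # v5
    nid(ix + 1L, iy + 1L, iz + 1L), # v6
    nid(ix,      iy + 1L, iz + 1L)  # v7
  )
  pat <- list(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
              c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  tets <- do.call(rbind, lapply(pat, function(q) {
    cbind(v[[q[1]]], v[[q[2]]], v[[q[3]]], v[[q[4]]])
  }))
  reg <- rep(region, times = 6L)
  cell_of <- rep(seq_along(ix), times = 6L)
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nxp * nyp * length(zp))
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4L)
  u <- used - 1L
  i <- u %% nxp + 1L
  j <- (u %/% nxp) %% nyp + 1L
  k <- u %/% (nxp * nyp) + 1L
  nodes <- cbind(x = xp[i], y = yp[j], z = zp[k])
  list(nodes = nodes, tets = tets, region = reg, cell_of = cell_of)
}

# Signed volumes of tetrahedra (positive for the orientation convention).
tet_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

new_fh_mesh <- function(nodes, tets, region, node_sets = list(),
                        contact_pairs = empty_contact_pairs(),
                        pretension = list(), params = NULL, fixation = NULL) {
  vol <- tet_volumes(nodes, tets)
  if (any(vol <= 0)) {
    stop(sprintf("meshing failure: %d degenerate or inverted tetrahedra", sum(vol <= 0)))
  }
  m <- structure(list(nodes = nodes, tets = tets, region = as.integer(region),
                      region_levels = REGION_LEVELS, node_sets = node_sets,
                      contact_pairs = contact_pairs, pretension = pretension,
                      params = params, fixation = fixation),
                 class = "fh_mesh")
  ns <- unlist(node_sets, use.names = FALSE)
  if (length(ns) && (min(ns) < 1L || max(ns) > nrow(nodes))) {
    stop("node sets reference nodes outside the mesh")
  }
  m
}

empty_contact_pairs <- function() {
  data.frame(node_a = integer(), node_b = integer(),
             nx = numeric(), ny = numeric(), nz = numeric(),
             type = character(), screw = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.fh_mesh <- function(x, ...) {
  cat(sprintf("fh_mesh: %d nodes, %d tet4 elements\n", nrow(x$nodes), nrow(x$tets)))
  tab <- table(factor(x$region_levels[x$region], levels = x$region_levels))
  print(tab[tab > 0])
  if (nrow(x$contact_pairs)) {
    cat(sprintf("contact pairs: %d (%s)\n", nrow(x$contact_pairs),
                paste(unique(x$contact_pairs$type), collapse = ", ")))
  }
  cat("node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  invisible(x)
}

#' Unit-cube patch-test mesh
#'
#' Builds a structured tetrahedral mesh of the unit cube with face node
#' sets (`FACE_XMIN`, ..., `FACE_ZMAX`) for Dirichlet patch tests.
#'
#' @param n_divisions Number of cells per axis (>= 1); `n_divisions = 1`
#'   yields 6 tetrahedra on 8 nodes.
#' @return An `fh_mesh` with a single region.
#' @export
build_patch_mesh <- function(n_divisions = 1L) {
  stopifnot(n_divisions >= 1L)
  p <- seq(0, 1, length.out = n_divisions + 1L)
  idx <- expand.grid(ix = seq_len(n_divisions), iy = seq_len(n_divisions),
                     iz = seq_len(n_divisions))
  vt <- voxel_tets(p, p, p, idx$ix, idx$iy, idx$iz,
                   rep(region_code("CORTICAL"), nrow(idx)))
  tol <- 1e-12
  ns <- list(
    FACE_XMIN = which(abs(vt$nodes[, 1]) < tol),
    FACE_XMAX = which(abs(vt$nodes[, 1] - 1) < tol),
    FACE_YMIN = which(abs(vt$nodes[, 2]) < tol),
    FACE_YMAX = which(abs(vt$nodes[, 2] - 1) < tol),
    FACE_ZMIN = which(abs(vt$nodes[, 3]) < tol),
    FACE_ZMAX = which(abs(vt$nodes[, 3] - 1) < tol)
  )
  new_fh_mesh(vt$nodes, vt$tets, vt$region, ns)
}

# Largest face-connected component of a set of grid cells (6-neighbour
# adjacency); returns a logical mask over the input cells.
largest_cell_component <- function(ix, iy, iz, nx, ny, nz) {
  id <- ix + (iy - 1L) * nx + (iz - 1L) * (nx * ny)
  lookup <- integer(nx * ny * nz)
  lookup[id] <- seq_along(id)
  comp <- integer(length(id))
  ncomp <- 0L
  for (s in seq_along(id)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    while (length(queue)) {
      cur <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      cx <- ix[cur]; cy <- iy[cur]; cz <- iz[cur]
      for (d in 1:6) {
        nb <- switch(d,
          if (cx > 1L) id[cur] - 1L else 0L,
          if (cx < nx) id[cur] + 1L else 0L,
          if (cy > 1L) id[cur] - nx else 0L,
          if (cy < ny) id[cur] + nx else 0L,
          if (cz > 1L) id[cur] - nx * ny else 0L,
          if (cz < nz) id[cur] + nx * ny else 0L)
        if (nb > 0L && lookup[nb] != 0L) {
          t <- lookup[nb]
          if (comp[t] == 0L) {
            comp[t] <- ncomp
            queue <- c(queue, t)
          }
        }
      }
    }
  }
  best <- which.max(tabulate(comp, ncomp))
  comp == best
}

#' Build the fractured, plated bone model
#'
#' Generates the full construct: two hollow-cylinder cortical fragments with
#' cancellous cores separated by the fracture gap, an ellipsoidal callus
#' envelope filling the gap and collaring both fragment ends, and a lateral
#' plate connected through transcortical screws.  For locked plating (`LP`)
#' the plate stands off from the bone and every interface shares nodes
#' (bonded).  For dynamic compression plating (`DCP`) the plate sits flush
#' on the bone and the distal (dynamic) screws interact through
#' duplicated-node frictional contact pairs: the plate-bone interface and
#' the screw-head bearing on the plate hole are unilateral normal contacts,
#' the near-cortex shaft interface is radial contact, and only the thread
#' engagement in the far cortex stays bonded (the axial anchor).  One
#' element slice of each distal screw shaft is marked as the pretension
#' section.
#'
#' @param params A [geometry_params()] object.
#' @param fixation `"LP"` (locked plate) or `"DCP"` (dynamic compression
#'   plate).
#' @return An `fh_mesh` with regions, node sets
#'   (`LOAD`, `FIXED`, `FRAGMENT_END_{PROXIMAL,DISTAL}`, `FRAGMENT_END`,
#'   `CALLUS_PERIPHERY`, `CALLUS_MEDULLARY`, `PLATE_BONE_INTERFACE`,
#'   `PRETENSION_SECTION`), contact pairs (DCP) and pretension sections.
#' @export
build_fracture_model <- function(params = geometry_params(),
                                 fixation = c("LP", "DCP")) {
  fixation <- match.arg(fixation)
  if (!inherits(params, "geometry_params")) {
    params <- do.call(geometry_params, params)
  }
  p <- params
  h <- p$target_edge_length
  R_out <- p$bone_outer_radius
  R_in <- R_out - p$cortex_thickness
  g2 <- p$gap_width / 2
  L2 <- p$segment_length / 2
  ca <- p$callus_axial_semiaxis
  cr <- p$callus_radial_semiaxis
  w2 <- p$plate_width / 2
  r_s <- p$screw_radius
  screws <- p$screw_axial_positions
  plate_z <- c(min(screws) - 3 * r_s, max(screws) + 3 * r_s)

  y_feat <- c(-cr, -w2, -r_s, r_s, w2, cr)
  z_feat <- c(-L2, -g2, g2, L2, plate_z, as.vector(outer(screws, c(-r_s, r_s), "+")))
  z_feat <- z_feat[z_feat >= -L2 & z_feat <= L2]
  xp0 <- axis_breaks(c(-cr, cr), h)
  yp <- axis_breaks(y_feat, h)
  zp <- axis_breaks(z_feat, h)

  # pass 1: bone tangent plane under the plate footprint (+x side), using
  # the same sub-sampled majority rule as the final classification
  cx0 <- (xp0[-1] + xp0[-length(xp0)]) / 2
  wx0 <- diff(xp0)
  cy <- (yp[-1] + yp[-length(yp)]) / 2
  wy0 <- diff(yp)
  in_foot <- which(abs(cy) < w2)
  off <- c(-1, 0, 1) / 3
  tangent <- -Inf
  for (i in seq_along(cx0)) {
    if (cx0[i] <= 0) next
    for (j in in_foot) {
      n_core <- 0; n_ann <- 0
      for (ox in off) for (oy in off) {
        r2s <- (cx0[i] + ox * wx0[i])^2 + (cy[j] + oy * wy0[j])^2
        n_core <- n_core + (r2s < R_in^2)
        n_ann <- n_ann + (r2s >= R_in^2 & r2s < R_out^2)
      }
      n_out <- 9 - n_core - n_ann
      is_bone <- (n_core >= n_ann && n_core >= n_out) ||
        (n_core < n_ann && n_ann >= n_out)
      if (is_bone) { tangent <- max(tangent, xp0[i + 1L]); break }
    }
  }
  if (!is.finite(tangent)) stop("meshing failure: no bone under the plate footprint")
  pin <- tangent + if (fixation == "LP") p$plate_offset else 0
  pout <- pin + p$plate_thickness
  xp <- sort(unique(c(xp0, pin, pout)))
  if (pout > max(xp)) xp <- c(xp, pout)

  nx <- length(xp) - 1L; ny <- length(yp) - 1L; nz <- length(zp) - 1L
  cxv <- (xp[-1] + xp[-length(xp)]) / 2
  cyv <- (yp[-1] + yp[-length(yp)]) / 2
  czv <- (zp[-1] + zp[-length(zp)]) / 2
  ix <- rep(seq_len(nx), times = ny * nz)
  iy <- rep(rep(seq_len(ny), each = nx), times = nz)
  iz <- rep(seq_len(nz), each = nx * ny)
  xc <- cxv[ix]; yc <- cyv[iy]; zc <- czv[iz]

  # radial/ellipsoid membership by 3x3x3 sub-sampling of each cell: the
  # curved boundaries (cortex radii, callus ellipsoid) are voxelized by the
  # dominant sub-volume, which keeps region volumes accurate at coarse
  # grids; the axial fracture/end planes are exact grid planes.
  wxv <- diff(xp); wyv <- diff(yp); wzv <- diff(zp)
  wx <- wxv[ix]; wy <- wyv[iy]; wz <- wzv[iz]
  off <- c(-1, 0, 1) / 3
  n_core <- n_ann <- n_ell <- numeric(length(xc))
  for (ox in off) for (oy in off) for (oz in off) {
    xs <- xc + ox * wx; ys <- yc + oy * wy; zs <- zc + oz * wz
    r2s <- xs^2 + ys^2
    n_core <- n_core + (r2s < R_in^2)
    n_ann <- n_ann + (r2s >= R_in^2 & r2s < R_out^2)
    n_ell <- n_ell + ((zs / ca)^2 + r2s / cr^2 <= 1)
  }
  n_core <- n_core / 27; n_ann <- n_ann / 27; n_ell <- n_ell / 27
  n_out <- 1 - n_core - n_ann

  in_bone_z <- abs(zc) > g2 & abs(zc) < L2
  cancellous <- in_bone_z & n_core >= n_ann & n_core >= n_out
  cortical <- in_bone_z & !cancellous & n_ann >= n_out
  callus <- n_ell >= 0.5 & !cortical & !cancellous & abs(zc) < L2
  plate <- xc > pin & xc < pout & abs(yc) < w2 &
    zc > plate_z[1] & zc < plate_z[2]
  screw_of <- rep(NA_real_, length(xc))
  for (z0 in screws) {
    hit <- abs(yc) < r_s & abs(zc - z0) < r_s & xc > -R_out & xc < pout
    screw_of[hit] <- z0
  }
  screw <- !is.na(screw_of)

  region <- integer(length(xc))
  region[callus] <- region_code("CALLUS")
  region[cancellous] <- region_code("CANCELLOUS")
  region[cortical] <- region_code("CORTICAL")
  region[plate] <- region_code("PLATE")
  region[screw] <- region_code("SCREW")

  # drop callus cells not in the main face-connected callus component
  ci <- which(region == region_code("CALLUS"))
  if (!length(ci)) stop("meshing failure: empty callus region")
  keep_callus <- largest_cell_component(ix[ci], iy[ci], iz[ci], nx, ny, nz)
  region[ci[!keep_callus]] <- 0L

  keep <- which(region > 0L)
  vt <- voxel_tets(xp, yp, zp, ix[keep], iy[keep], iz[keep], region[keep])
  nodes <- vt$nodes
  tets <- vt$tets
  reg <- vt$region
  screw_tet <- rep(screw_of[keep], times = 6L)

  tol <- 1e-9
  nr2 <- nodes[, 1]^2 + nodes[, 2]^2
  nodes_of_region <- function(code) {
    sort(unique(as.vector(tets[reg == code, , drop = FALSE])))
  }
  bone_nodes <- sort(unique(c(nodes_of_region(region_code("CORTICAL")),
                              nodes_of_region(region_code("CANCELLOUS")))))
  on_face <- function(set, zval) {
    set[abs(nodes[set, 3] - zval) < tol & nr2[set] <= (R_out + tol)^2]
  }
  frag_prox <- on_face(bone_nodes, g2)
  frag_dist <- on_face(bone_nodes, -g2)

  # exterior faces of callus elements = callus periphery
  callus_tets <- which(reg == region_code("CALLUS"))
  faces <- tet_faces(tets)
  fkey <- face_keys(faces, nrow(nodes))
  dup <- fkey %in% fkey[duplicated(fkey)]
  ext <- !dup
  owner <- rep(seq_len(nrow(tets)), times = 4L)
  periph_faces <- which(ext & reg[owner] == region_code("CALLUS"))
  callus_periphery <- sort(unique(as.vector(faces[periph_faces, ])))
  callus_nodes <- nodes_of_region(region_code("CALLUS"))
  medullary <- intersect(callus_nodes, nodes_of_region(region_code("CANCELLOUS")))
  plate_bone <- intersect(nodes_of_region(region_code("PLATE")),
                          nodes_of_region(region_code("CORTICAL")))

  node_sets <- list(
    LOAD = bone_nodes[abs(nodes[bone_nodes, 3] - L2) < tol],
    FIXED = which(abs(nodes[, 3] + L2) < tol),
    FRAGMENT_END_PROXIMAL = frag_prox,
    FRAGMENT_END_DISTAL = frag_dist,
    FRAGMENT_END = sort(unique(c(frag_prox, frag_dist))),
    CALLUS_PERIPHERY = callus_periphery,
    CALLUS_MEDULLARY = sort(medullary),
    PLATE_BONE_INTERFACE = sort(plate_bone)
  )

  contact <- empty_contact_pairs()
  if (fixation == "DCP") {
    # plate-bone interface: duplicate interface nodes on the plate side
    dup_res <- duplicate_for_contact(nodes, tets, reg, plate_bone,
                                     target = reg == region_code("PLATE"))
    nodes <- dup_res$nodes; tets <- dup_res$tets
    if (length(dup_res$pairs_a)) {
      contact <- rbind(contact, data.frame(
        node_a = dup_res$pairs_a, node_b = dup_res$pairs_b,
        nx = 1, ny = 0, nz = 0, type = "plate_bone", screw = NA_real_,
        stringsAsFactors = FALSE))
    }
    # distal gliding screws: the plate hole provides head bearing only
    # (unilateral along the screw axis; the oversized hole gives radial
    # clearance), the near-cortex shaft interface is radial contact, and
    # thread engagement in the far cortex stays bonded as the anchor
    for (z0 in screws[screws < 0]) {
      s_sel <- !is.na(screw_tet) & screw_tet == z0
      s_nodes <- sort(unique(as.vector(tets[s_sel, , drop = FALSE])))
      plate_nodes <- nodes_of_region(region_code("PLATE"))
      cand_p <- intersect(s_nodes, plate_nodes)
      dup_res <- duplicate_for_contact(nodes, tets, reg, cand_p, target = s_sel)
      nodes <- dup_res$nodes; tets <- dup_res$tets
      if (length(dup_res$pairs_a)) {
        a <- dup_res$pairs_a
        # head bearing along the screw axis
        contact <- rbind(contact, data.frame(
          node_a = a, node_b = dup_res$pairs_b,
          nx = 1, ny = 0, nz = 0,
          type = "screw_plate_head", screw = z0, stringsAsFactors = FALSE))
        # shaft bearing against the plate-hole wall (radial, zero clearance)
        len <- sqrt(nodes[a, 2]^2 + (nodes[a, 3] - z0)^2)
        off_axis <- len > 1e-9
        if (any(off_axis)) {
          aa <- a[off_axis]
          # inward normal: from the hole wall (a) towards the shaft axis (b)
          nrm <- -cbind(0, nodes[aa, 2], nodes[aa, 3] - z0) / len[off_axis]
          contact <- rbind(contact, data.frame(
            node_a = aa, node_b = dup_res$pairs_b[off_axis],
            nx = 0, ny = nrm[, 2], nz = nrm[, 3],
            type = "screw_plate_shaft", screw = z0, stringsAsFactors = FALSE))
        }
      }
      s_nodes <- sort(unique(as.vector(tets[s_sel, , drop = FALSE])))
      cort_nodes <- nodes_of_region(region_code("CORTICAL"))
      cand <- intersect(s_nodes, cort_nodes)
      cand <- cand[nodes[cand, 1] > 0]
      len0 <- sqrt(nodes[cand, 2]^2 + (nodes[cand, 3] - z0)^2)
      cand <- cand[len0 > 1e-9]  # on-axis nodes stay bonded
      dup_res <- duplicate_for_contact(nodes, tets, reg, cand, target = s_sel)
      nodes <- dup_res$nodes; tets <- dup_res$tets
      if (length(dup_res$pairs_a)) {
        a <- dup_res$pairs_a
        # inward normal: from the cortical hole wall (a) to the shaft (b)
        nrm <- -cbind(0, nodes[a, 2], nodes[a, 3] - z0)
        nrm <- nrm / sqrt(rowSums(nrm^2))
        contact <- rbind(contact, data.frame(
          node_a = a, node_b = dup_res$pairs_b,
          nx = 0, ny = nrm[, 2], nz = nrm[, 3],
          type = "screw_bone", screw = z0, stringsAsFactors = FALSE))
      }
    }
  }

  # pretension section: one element slice of each distal screw shaft,
  # located mid-way through the near cortex
  x_target <- (R_in + R_out) / 2
  i_lo <- max(which(xp <= x_target))
  plane_lo <- xp[i_lo]; plane_hi <- xp[min(i_lo + 1L, length(xp))]
  pretension <- list()
  for (z0 in screws[screws < 0]) {
    s_sel <- !is.na(screw_tet) & screw_tet == z0
    s_nodes <- sort(unique(as.vector(tets[s_sel, , drop = FALSE])))
    upper <- s_nodes[abs(nodes[s_nodes, 1] - plane_hi) < tol]
    lower <- s_nodes[abs(nodes[s_nodes, 1] - plane_lo) < tol]
    if (!length(upper) || !length(lower)) {
      stop("meshing failure: empty pretension section for screw at z = ", z0)
    }
    pretension[[length(pretension) + 1L]] <-
      list(screw_z = z0, upper = upper, lower = lower)
  }
  node_sets$PRETENSION_SECTION <-
    sort(unique(unlist(lapply(pretension, function(s) c(s$upper, s$lower)))))

  new_fh_mesh(nodes, tets, reg, node_sets, contact, pretension,
              params = p, fixation = fixation)
}

# All four faces of every tet (4 stacked blocks; owning tet of row r is
# rep(seq_len(n), times = 4)[r]), nodes sorted within each face.
tet_faces <- function(tets) {
  f <- rbind(tets[, c(1, 2, 3)], tets[, c(1, 2, 4)],
             tets[, c(1, 3, 4)], tets[, c(2, 3, 4)])
  lo <- pmin(f[, 1], f[, 2], f[, 3])
  hi <- pmax(f[, 1], f[, 2], f[, 3])
  cbind(lo, f[, 1] + f[, 2] + f[, 3] - lo - hi, hi)
}

face_keys <- function(faces, n_nodes) {
  nn <- as.numeric(n_nodes) + 1
  (faces[, 1] * nn + faces[, 2]) * nn + faces[, 3]
}

# Duplicate `cand` nodes for the elements selected by `target` (logical over
# tets); original nodes stay with the other side.  Returns updated mesh
# arrays and the original/duplicate id pairs actually used.
duplicate_for_contact <- function(nodes, tets, reg, cand, target) {
  if (!length(cand)) {
    return(list(nodes = nodes, tets = tets, pairs_a = integer(), pairs_b = integer()))
  }
  used_rows <- which(target)
  sub <- tets[used_rows, , drop = FALSE]
  hit <- sub %in% cand
  if (!any(hit)) {
    return(list(nodes = nodes, tets = tets, pairs_a = integer(), pairs_b = integer()))
  }
  touched <- sort(unique(sub[hit]))
  new_ids <- nrow(nodes) + seq_along(touched)
  map <- integer(nrow(nodes))
  map[touched] <- new_ids
  sub[hit] <- map[sub[hit]]
  tets[used_rows, ] <- sub
  nodes <- rbind(nodes, nodes[touched, , drop = FALSE])
  list(nodes = nodes, tets = tets, pairs_a = touched, pairs_b = new_ids)
}
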