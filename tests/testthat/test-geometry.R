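# Parametric voxel geometry: parameter validation, patch meshes, the
# fracture construct for both fixations, and the structural invariants.

test_that("geometry parameters enforce their invariants", {
  expect_s3_class(geometry_params(), "geometry_params")
  expect_error(geometry_params(gap_width = 0), "positive")
  expect_error(geometry_params(cortex_thickness = 14), "smaller than bone_outer_radius")
  expect_error(geometry_params(callus_radial_semiaxis = 10), "exceed bone_outer_radius")
  expect_error(geometry_params(gap_width = 70), "twice callus_axial_semiaxis")
  expect_error(geometry_params(screw_axial_positions = c(25, 40)), "both fragments")
  expect_error(geometry_params(screw_axial_positions = c(-5, 25)), "inside the fracture gap")
})

test_that("patch meshes have the minimal decomposition and refine 8x", {
  m1 <- build_patch_mesh(1)
  expect_equal(nrow(m1$tets), 6L)
  expect_equal(nrow(m1$nodes), 8L)
  m2 <- build_patch_mesh(2)
  expect_equal(nrow(m2$tets), 8L * nrow(m1$tets))
  for (m in list(m1, m2, build_patch_mesh(3))) {
    expect_true(all(callusim:::tet_volumes(m$nodes, m$tets) > 0))
  }
  expect_length(m1$node_sets$FACE_ZMIN, 4L)
})

test_that("the LP construct is fully bonded, the DCP construct has contact pairs", {
  lp <- tiny_mesh("LP")
  dcp <- tiny_mesh("DCP")
  for (m in list(lp, dcp)) {
    expect_gt(sum(m$region == 3L), 0L)          # callus present
    expect_true(all(callusim:::tet_volumes(m$nodes, m$tets) > 0))
    expect_setequal(
      setdiff(c("LOAD", "FIXED", "FRAGMENT_END", "CALLUS_PERIPHERY",
                "CALLUS_MEDULLARY", "PRETENSION_SECTION"),
              names(m$node_sets)), character())
  }
  expect_equal(nrow(lp$contact_pairs), 0L)
  expect_gt(nrow(dcp$contact_pairs), 0L)
  expect_true(all(unique(dcp$contact_pairs$type) %in%
                  c("plate_bone", "screw_bone", "screw_plate_head", "screw_plate_shaft")))
  expect_true(all(c("plate_bone", "screw_plate_head") %in% dcp$contact_pairs$type))
  # duplicated contact nodes coincide geometrically
  cp <- dcp$contact_pairs
  expect_equal(dcp$nodes[cp$node_a, ], dcp$nodes[cp$node_b, ],
               ignore_attr = TRUE)
  # contact normals are unit vectors
  expect_equal(cp$nx^2 + cp$ny^2 + cp$nz^2, rep(1, nrow(cp)))
  # pretension sections exist for the distal screws only
  expect_equal(length(dcp$pretension), 2L)
  expect_true(all(vapply(dcp$pretension, function(s) s$screw_z, 0) < 0))
})

test_that("fragment-end node sets lie exactly on the fracture faces", {
  m <- tiny_mesh("LP")
  g2 <- m$params$gap_width / 2
  expect_true(all(abs(m$nodes[m$node_sets$FRAGMENT_END_PROXIMAL, 3] - g2) < 1e-9))
  expect_true(all(abs(m$nodes[m$node_sets$FRAGMENT_END_DISTAL, 3] + g2) < 1e-9))
  r <- sqrt(rowSums(m$nodes[m$node_sets$FRAGMENT_END, 1:2]^2))
  expect_true(all(r <= m$params$bone_outer_radius + 1e-6))
})

test_that("mesh generation is deterministic", {
  a <- build_fracture_model(tiny_params(), "DCP")
  b <- build_fracture_model(tiny_params(), "DCP")
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$tets, b$tets)
  expect_identical(a$region, b$region)
  expect_identical(a$node_sets, b$node_sets)
  expect_identical(a$contact_pairs, b$contact_pairs)
})

test_that("callus volume matches the analytic ellipsoid-minus-bone volume", {
  # fixture with the implant outside the callus envelope so the analytic
  # oracle applies cleanly, at the default (coarse) density
  p <- geometry_params(plate_offset = 12,
                       screw_axial_positions = c(-45, -35, 35, 45))
  m <- build_fracture_model(p, "LP")
  v <- sum(callusim:::tet_volumes(m$nodes, m$tets)[m$region == 3L])
  disc <- function(z) {
    pmin(p$bone_outer_radius,
         p$callus_radial_semiaxis * sqrt(pmax(0, 1 - (z / p$callus_axial_semiaxis)^2)))^2 * pi
  }
  v_analytic <- 4 / 3 * pi * p$callus_axial_semiaxis * p$callus_radial_semiaxis^2 -
    2 * stats::integrate(disc, p$gap_width / 2, p$callus_axial_semiaxis)$value
  expect_lt(abs(v / v_analytic - 1), 0.05)
})

test_that("the callus is a single face-connected component", {
  m <- tiny_mesh("LP")
  map <- neighbour_map(m)
  n <- length(map$elements)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    nb <- map$neighbours[[cur]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  expect_true(all(seen))
})
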