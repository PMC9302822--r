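# Shared fixtures: small meshes and cached solves so expensive geometry /
# FE setups are built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# coarse unit-test geometry (much coarser than the analysis preset)
tiny_params <- function(...) {
  geometry_params(target_edge_length = 7.5, ...)
}

tiny_mesh <- function(fixation = "LP") {
  memo(paste0("tiny_", fixation), build_fracture_model(tiny_params(), fixation))
}

tiny_config <- function(fixation = "LP", iterations = 3L) {
  cfg <- default_config()
  cfg$geometry$target_edge_length <- 7.5
  cfg$run$fixation <- fixation
  cfg$run$iterations <- as.integer(iterations)
  cfg
}

# slender cantilever: 2 x 2 x 20 mm bar, fixed at z = 0, built on the same
# voxel machinery as the generators
beam_mesh <- function(nx = 8L, nz = 80L, L = 20) {
  memo(sprintf("beam_%d_%d", nx, nz), {
    xp <- seq(0, 2, length.out = nx + 1L)
    zp <- seq(0, L, length.out = nz + 1L)
    idx <- expand.grid(ix = seq_len(nx), iy = seq_len(nx), iz = seq_len(nz))
    vt <- callusim:::voxel_tets(xp, xp, zp, idx$ix, idx$iy, idx$iz,
                                rep(1L, nrow(idx)))
    ns <- list(FIXED = which(abs(vt$nodes[, 3]) < 1e-12),
               TIP = which(abs(vt$nodes[, 3] - L) < 1e-12))
    callusim:::new_fh_mesh(vt$nodes, vt$tets, vt$region, ns)
  })
}

# element-volume-weighted mean over the callus
callus_mean <- function(mesh, x_callus) {
  w <- callusim:::tet_volumes(mesh$nodes, mesh$tets)[mesh$region == 3L]
  sum(w * x_callus) / sum(w)
}

# full-scale cached artifacts for the acceptance checks
default_mesh <- function(fixation = "LP") {
  memo(paste0("default_", fixation),
       build_fracture_model(geometry_params(), fixation))
}

default_run <- function(fixation = "LP") {
  memo(paste0("run60_", fixation), {
    cfg <- default_config()
    cfg$run$fixation <- fixation
    run_healing(cfg, mesh = default_mesh(fixation))
  })
}

# exact centroid of a trapezoid (a,b,c,d) clipped at level alpha, via exact
# piecewise-linear integration restricted to the output universe
clipped_trapezoid_centroid <- function(a, b, c, d, alpha, universe = c(-10, 10)) {
  p <- a + alpha * (b - a)
  q <- d - alpha * (d - c)
  xs <- pmin(pmax(c(a, p, q, d), universe[1]), universe[2])
  mus <- c(0, alpha, alpha, 0)
  area <- 0; mom <- 0
  for (k in 1:3) {
    x0 <- xs[k]; x1 <- xs[k + 1]
    m0 <- mus[k]; m1 <- mus[k + 1]
    area <- area + (m0 + m1) / 2 * (x1 - x0)
    mom <- mom + (x1 - x0) * (m0 * (2 * x0 + x1) + m1 * (x0 + 2 * x1)) / 6
  }
  mom / area
}

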