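# Finite-element solver: patch test, analytic beam oracle, equilibrium,
# frame invariance, strain invariants and interfragmentary movement.

test_that("a linear displacement field is reproduced to machine precision", {
  m <- build_patch_mesh(3)
  bn <- sort(unique(unlist(m$node_sets)))
  A <- matrix(c(2e-3, 5e-4, 0, 5e-4, -1e-3, 2e-4, 0, 2e-4, 1e-3), 3, 3)
  diri <- data.frame(node = rep(bn, each = 3L), comp = rep(1:3, length(bn)),
                     value = as.vector(t(m$nodes[bn, ] %*% A)))
  sol <- assemble_and_solve(m, list(E = rep(1000, nrow(m$tets)),
                                    nu = rep(0.3, nrow(m$tets))),
                            load_case(load_magnitude = 0), "LP",
                            dirichlet = diri)
  expect_lt(max(abs(sol$u - m$nodes %*% A)), 1e-12)
  inv <- element_strain_invariants(m, sol$u)
  expect_equal(inv$eps_hyd, rep(sum(diag(A)) / 3, nrow(m$tets)), tolerance = 1e-12)
  expect_lt(max(inv$eps_dis) - min(inv$eps_dis), 1e-12)
})

test_that("zero load gives zero displacement", {
  m <- tiny_mesh("LP")
  mats <- material_field(m)
  sol <- assemble_and_solve(m, mats, load_case(load_magnitude = 0), "LP")
  expect_equal(max(abs(sol$u)), 0)
  expect_equal(interfragmentary_movement(m, sol$u), 0)
})

test_that("cantilever tip deflection matches Euler-Bernoulli within 10%", {
  m <- beam_mesh()
  P <- 10; L <- 20; E <- 1000
  tip <- m$node_sets$TIP
  ctx <- fe_context(m, load_case(load_magnitude = 0), "LP")
  ctx$f_ext[3 * (tip - 1) + 1] <- P / length(tip)  # transverse x load
  sol <- fe_solve(ctx, rep(E, nrow(m$tets)), rep(0.0, nrow(m$tets)) + 1e-9)
  delta <- mean(sol$u[tip, 1])
  I <- 2 * 2^3 / 12
  expect_lt(abs(delta / (P * L^3 / (3 * E * I)) - 1), 0.1)
})

test_that("the free-dof residual vanishes and reactions balance the load", {
  m <- tiny_mesh("LP")
  mats <- material_field(m)
  ctx <- fe_context(m, load_case(), "LP")
  sol <- fe_solve(ctx, mats$E, mats$nu)
  f <- ctx$f_ext
  resid <- (sol$fint - f)[ctx$is_free]
  expect_lt(sqrt(sum(resid^2)), 1e-6 * sqrt(sum(f^2)))
  # sum of reactions at the fixed face equals minus the applied load
  R <- colSums(matrix(sol$fint - f, ncol = 3, byrow = TRUE))
  Fapp <- callusim:::load_direction_vector(ctx$load) * ctx$load$load_magnitude
  expect_equal(unname(R), unname(-Fapp), tolerance = 1e-6)
})

test_that("strain invariants are frame invariant under rigid rotation", {
  m <- beam_mesh(nx = 2L, nz = 10L)
  P <- 5
  solve_beam <- function(mesh, dirvec) {
    tip <- mesh$node_sets$TIP
    ctx <- fe_context(mesh, load_case(load_magnitude = 0), "LP")
    for (k in 1:3) {
      ctx$f_ext[3 * (tip - 1) + k] <- P * dirvec[k] / length(tip)
    }
    sol <- fe_solve(ctx, rep(500, nrow(mesh$tets)), rep(0.3, nrow(mesh$tets)))
    element_strain_invariants(mesh, sol$u)
  }
  base <- solve_beam(m, c(1, 0, 0))
  th <- 0.7; ph <- 0.3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3) %*%
    matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3, 3)
  m2 <- m
  m2$nodes <- m$nodes %*% t(R)
  rot <- solve_beam(m2, as.numeric(R %*% c(1, 0, 0)))
  expect_lt(max(abs(base$eps_hyd - rot$eps_hyd)), 1e-9)
  expect_lt(max(abs(base$eps_dis - rot$eps_dis)), 1e-9)
})

test_that("hand-evaluated strain invariants match the closed form", {
  # pure volumetric: principal (0.01, 0.01, 0.01)
  inv <- callusim:::principal_strains_sym3(0.01, 0.01, 0.01, 0, 0, 0)
  expect_equal(inv$eps_hyd, 0.01)
  expect_equal(inv$eps_dis, 0)
  # principal strains (0.01, 0, -0.01): eps_dis = sqrt(6e-4)/sqrt(2)
  inv <- callusim:::principal_strains_sym3(0.01, 0, -0.01, 0, 0, 0)
  expect_equal(inv$eps_hyd, 0, tolerance = 1e-15)
  expect_equal(inv$eps_dis, sqrt(6e-4 / 2), tolerance = 1e-12)
  expect_equal(unname(inv$principal[1, ]), c(0.01, 0, -0.01))
  # hydrostatic equals the mean of the principal strains for random tensors
  set.seed(3)
  e <- matrix(rnorm(60, sd = 1e-2), 10)
  inv <- callusim:::principal_strains_sym3(e[, 1], e[, 2], e[, 3], e[, 4], e[, 5], e[, 6])
  expect_equal(inv$eps_hyd, rowMeans(inv$principal), tolerance = 1e-12)
  # against R's eigen() as the independent oracle
  for (i in 1:10) {
    M <- matrix(c(e[i, 1], e[i, 4], e[i, 5],
                  e[i, 4], e[i, 2], e[i, 6],
                  e[i, 5], e[i, 6], e[i, 3]), 3, 3)
    expect_equal(unname(inv$principal[i, ]), eigen(M, symmetric = TRUE)$values,
                 tolerance = 1e-10)
  }
})

test_that("rigid-body motion produces zero strain and zero IFM", {
  m <- tiny_mesh("LP")
  u <- matrix(rep(c(0.3, -0.2, 0.5), each = nrow(m$nodes)), ncol = 3)
  inv <- element_strain_invariants(m, u)
  expect_lt(max(abs(inv$eps_hyd)), 1e-10)
  expect_lt(max(abs(inv$eps_dis)), 1e-10)
  expect_lt(interfragmentary_movement(m, u), 1e-12)
  expect_error(interfragmentary_movement(build_patch_mesh(1), u[1:8, ]),
               "empty")
})

test_that("stiffening the callus strictly reduces the IFM", {
  m <- tiny_mesh("LP")
  ctx <- fe_context(m, load_case(), "LP")
  mats <- material_field(m)
  ifm <- numeric(3)
  for (k in 1:3) {
    E <- mats$E
    E[m$region == 3L] <- c(3, 300, 3000)[k]
    sol <- fe_solve(ctx, E, mats$nu)
    ifm[k] <- interfragmentary_movement(m, sol$u)
  }
  expect_true(all(diff(ifm) < 0))
})

test_that("insufficient constraints raise a singular-stiffness error", {
  # the patch mesh has no FIXED set, so a solve without Dirichlet data has
  # free rigid-body modes and must refuse to run
  m <- build_patch_mesh(1)
  expect_error(
    assemble_and_solve(m, list(E = rep(100, 6), nu = rep(0.3, 6)),
                       load_case(load_magnitude = 0)),
    "singular stiffness")
})

test_that("DCP contact solves converge and soften the construct vs bonded LP", {
  dcp <- tiny_mesh("DCP")
  mats <- material_field(dcp)
  sol <- fe_solve(fe_context(dcp, load_case(), "DCP"), mats$E, mats$nu)
  expect_false(is.null(sol$contact))
  expect_lte(sol$contact$iterations, 50L)
  lp <- tiny_mesh("LP")
  matl <- material_field(lp)
  sol_lp <- fe_solve(fe_context(lp, load_case(), "LP"), matl$E, matl$nu)
  inv_d <- element_strain_invariants(dcp, sol$u)
  inv_l <- element_strain_invariants(lp, sol_lp$u)
  dis_d <- callus_mean(dcp, inv_d$eps_dis[dcp$region == 3L])
  dis_l <- callus_mean(lp, inv_l$eps_dis[lp$region == 3L])
  expect_gte(dis_d, dis_l)
})
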