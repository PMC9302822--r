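# Mamdani engine: membership evaluation, rule base loading, activation and
# centroid defuzzification against independent oracles.

test_that("trapezoidal membership evaluates plateaus, ramps and supports", {
  mf <- trapmf(0, 2, 10, 15)
  expect_equal(fuzzify(6, mf), 1)
  expect_equal(fuzzify(1, mf), 0.5)
  expect_equal(fuzzify(20, mf), 0)
  expect_equal(fuzzify(-3, mf), 0)
  expect_equal(fuzzify(12.5, mf), 0.5)
  # open shoulders and step edges
  sh <- trapmf(-Inf, -Inf, -8, -5)
  expect_equal(fuzzify(c(-100, -8, -6.5, -5, 0), sh), c(1, 1, 0.5, 0, 0))
  st <- trapmf(0, 5, 10, 10)
  expect_equal(fuzzify(c(10, 10.0001), st), c(1, 0))
  expect_error(trapmf(3, 2, 10, 15), "non-decreasing")
})

test_that("fuzzy variables reject term sets with coverage gaps", {
  expect_error(
    fuzzy_variable("x", c(0, 10), list(lo = trapmf(0, 0, 2, 3),
                                       hi = trapmf(6, 7, 10, 10))),
    "uncovered gap")
  # touching terms whose boundary point has zero membership are fine
  expect_s3_class(
    fuzzy_variable("y", c(-10, 10), list(dn = trapmf(-10, -10, -5, 0),
                                         up = trapmf(0, 5, 10, 10))),
    "fuzzy_variable")
})

test_that("the canonical rule base loads with the documented structure", {
  rb <- load_rulebase()
  expect_length(rb$rules, 19)
  procs <- table(vapply(rb$rules, `[[`, "", "process"))
  expect_equal(procs[["Angiogenesis"]], 4L)
  expect_equal(procs[["Intramembranous ossification"]], 2L)
  expect_equal(procs[["Chondrogenesis"]], 2L)
  expect_equal(procs[["Cartilage calcification"]], 4L)
  expect_equal(procs[["Endochondral ossification"]], 4L)
  expect_equal(procs[["Tissue destruction"]], 3L)
  # rule 19 has a single antecedent on distortional strain
  expect_equal(rb$rules[[19]]$antecedents$variable, "eps_dis")
  expect_equal(nrow(rb$rules[[19]]$consequents), 3L)
})

test_that("malformed rule files are rejected with informative errors", {
  tab <- utils::read.delim(system.file("extdata", "tissue_rules.tsv",
                                       package = "callusim"),
                           check.names = FALSE)
  f18 <- tempfile(fileext = ".tsv")
  utils::write.table(tab[-19, ], f18, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_rulebase(f18), "19 rules")
  fbad <- tempfile(fileext = ".tsv")
  tab2 <- tab
  tab2$C_perfusion[1] <- "very high"
  utils::write.table(tab2, fbad, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_rulebase(fbad), "very high")
})

test_that("rule activation is the min over (possibly negated) antecedents", {
  vars <- default_fuzzy_variables()
  rb <- load_rulebase()
  # destruction by distortional strain only: full activation deep in the
  # destructive band
  x <- c(eps_hyd = 0, eps_dis = 20, c_perfusion = 0,
         c_perfusion_neighbour = 0, c_bone = 0, c_bone_neighbour = 0,
         c_cartilage = 0)
  expect_equal(rule_activation(x, rb$rules[[19]], vars), 1)
  # hand-composed min for intramembranous rule 5:
  # eps_hyd -0.5% (neg low plateau -> 1), eps_dis 5% (low plateau -> 1),
  # c_perfusion 82 -> mu_high ramp (82-70)/20 = 0.6,
  # c_bone_neighbour 95 -> mu_high plateau = 1, c_cartilage 5 -> mu_low = 1
  x5 <- c(eps_hyd = -0.5, eps_dis = 5, c_perfusion = 82,
          c_perfusion_neighbour = 0, c_bone = 0, c_bone_neighbour = 95,
          c_cartilage = 5)
  expect_equal(rule_activation(x5, rb$rules[[5]], vars), 0.6)
  # negation: rule 1 requires eps_hyd Not neg. destructive; deep negative
  # hydrostatic strain kills it
  x1 <- c(eps_hyd = -9, eps_dis = 0.5, c_perfusion = 0,
          c_perfusion_neighbour = 50, c_bone = 0, c_bone_neighbour = 0,
          c_cartilage = 0)
  expect_equal(rule_activation(x1, rb$rules[[1]], vars), 0)
  # any zero antecedent forces zero activation
  x0 <- x5; x0["c_perfusion"] <- 0
  expect_equal(rule_activation(x0, rb$rules[[5]], vars), 0)
})

test_that("inference matches the qualitative single-process expectations", {
  ctl <- fuzzy_controller()
  zero <- c(eps_hyd = 0, eps_dis = 0, c_perfusion = 0,
            c_perfusion_neighbour = 0, c_bone = 0, c_bone_neighbour = 0,
            c_cartilage = 0)
  expect_equal(unname(infer(zero, ctl)), c(0, 0, 0))
  # destructive hydrostatic strain decreases everything
  xd <- zero; xd["eps_hyd"] <- 9
  out <- infer(xd, ctl)
  expect_true(all(out < 0))
  # pure angiogenesis: low local perfusion, perfused neighbours, calm strains
  xa <- zero; xa["c_perfusion_neighbour"] <- 95
  out <- infer(xa, ctl)
  expect_gt(out["d_perfusion"], 0)
  expect_equal(unname(out["d_bone"]), 0)
  expect_equal(unname(out["d_cartilage"]), 0)
})

test_that("single-rule centroids match the closed-form trapezoid oracle", {
  ctl <- fuzzy_controller()
  # full-activation destruction rule: all outputs are the centroid of the
  # 'decrease' trapezoid
  x <- c(eps_hyd = 0, eps_dis = 25, c_perfusion = 0,
         c_perfusion_neighbour = 0, c_bone = 0, c_bone_neighbour = 0,
         c_cartilage = 0)
  out <- infer(x, ctl)
  oracle <- clipped_trapezoid_centroid(-10, -10, -5, 0, 1)
  expect_lt(abs(out[["d_bone"]] - oracle), 0.01)
  # partial activation of a single angiogenesis rule: neighbour perfusion 20
  # gives "Not low" = 1 - mu_low(20) = 0.5 in rule 1, every other rule dead
  xa <- c(eps_hyd = 0, eps_dis = 0, c_perfusion = 0,
          c_perfusion_neighbour = 20, c_bone = 0, c_bone_neighbour = 0,
          c_cartilage = 0)
  out <- infer(xa, ctl)
  oracle <- clipped_trapezoid_centroid(0, 5, 10, 10, 0.5)
  expect_lt(abs(out[["d_perfusion"]] - oracle), 0.01)
})

test_that("defuzzified outputs stay inside the output universe", {
  ctl <- fuzzy_controller()
  set.seed(11)
  n <- 200L
  X <- cbind(eps_hyd = runif(n, -12, 12), eps_dis = runif(n, 0, 35),
             c_perfusion = runif(n, 0, 100),
             c_perfusion_neighbour = runif(n, 0, 100),
             c_bone = runif(n, 0, 100), c_bone_neighbour = runif(n, 0, 100),
             c_cartilage = runif(n, 0, 100))
  out <- infer_bulk(X, ctl)
  expect_true(all(out >= -10 & out <= 10))
})

test_that("outputs are continuous in the inputs (finite differences)", {
  ctl <- fuzzy_controller()
  set.seed(7)
  n <- 100L
  X <- cbind(eps_hyd = runif(n, -9, 9), eps_dis = runif(n, 0, 25),
             c_perfusion = runif(n, 1, 99),
             c_perfusion_neighbour = runif(n, 1, 99),
             c_bone = runif(n, 1, 99), c_bone_neighbour = runif(n, 1, 99),
             c_cartilage = runif(n, 1, 99))
  base <- infer_bulk(X, ctl)
  delta <- 1e-3
  for (v in colnames(X)) {
    Xp <- X
    Xp[, v] <- Xp[, v] + delta
    pert <- infer_bulk(Xp, ctl)
    # Lipschitz-type bound: output moves by O(delta); generous constant
    expect_lt(max(abs(pert - base)), 100 * delta)
  }
})

test_that("angiogenesis output is monotone in neighbour perfusion", {
  ctl <- fuzzy_controller()
  nbs <- seq(0, 100, by = 2)
  X <- cbind(eps_hyd = 0, eps_dis = 0, c_perfusion = 5,
             c_perfusion_neighbour = nbs, c_bone = 0, c_bone_neighbour = 0,
             c_cartilage = 0)
  out <- infer_bulk(X, ctl)[, "d_perfusion"]
  expect_true(all(diff(out) >= -1e-12))
})

test_that("1001-point centroids agree with a much finer discretization", {
  vars <- default_fuzzy_variables()
  rb <- load_rulebase()
  coarse <- fuzzy_controller(vars, rb, n_grid = 1001L)
  fine <- fuzzy_controller(vars, rb, n_grid = 100001L)
  set.seed(21)
  n <- 150L
  X <- cbind(eps_hyd = runif(n, -12, 12), eps_dis = runif(n, 0, 35),
             c_perfusion = runif(n, 0, 100),
             c_perfusion_neighbour = runif(n, 0, 100),
             c_bone = runif(n, 0, 100), c_bone_neighbour = runif(n, 0, 100),
             c_cartilage = runif(n, 0, 100))
  expect_lt(max(abs(infer_bulk(X, coarse) - infer_bulk(X, fine))), 0.05)
})
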