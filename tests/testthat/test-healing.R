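# Healing loop: initialization, neighbour topology, the daily state update
# and its conservation/boundedness/propagation properties.

test_that("the initial state is 100% connective tissue with the avascular band", {
  m <- tiny_mesh("LP")
  st <- initialize_state(m)
  expect_true(all(st$c_connective == 100))
  expect_true(all(st$c_bone == 0))
  expect_true(all(st$c_cartilage == 0))
  expect_true(all(st$c_perfusion == 0))
  expect_equal(st$c_bone + st$c_cartilage + st$c_connective,
               rep(100, length(st$elements)))
  # cortex perfusion: 0 within 5 mm of the fracture faces, 100 beyond
  cz <- rowMeans(matrix(m$nodes[t(m$tets[st$cortex_elements, ]), 3], ncol = 4,
                        byrow = TRUE))
  g2 <- m$params$gap_width / 2
  expect_true(all(st$cortex_perfusion[abs(cz) <= g2 + 5] == 0))
  expect_true(all(st$cortex_perfusion[abs(cz) > g2 + 5] == 100))
  expect_error(initialize_state(build_patch_mesh(1)), "empty callus")
})

test_that("neighbour values aggregate adjacent elements and active ghosts", {
  m <- tiny_mesh("LP")
  map <- neighbour_map(m)
  st <- initialize_state(m)
  nb1 <- neighbour_values(st, map, day = 1)
  # peripheral elements see at least the extraosseous supply
  expect_true(all(nb1$perfusion_nb[map$periphery] >= 30))
  # elements with a far-cortex ghost see full cortex perfusion and bone
  far <- which(lengths(map$ghost_cortical) > 0 &
               vapply(map$ghost_cortical, function(g) {
                 length(g) > 0 && any(st$cortex_perfusion[match(g, st$cortex_elements)] == 100)
               }, TRUE))
  expect_true(all(nb1$perfusion_nb[far] == 100))
  expect_true(all(nb1$bone_nb[lengths(map$ghost_cortical) > 0] == 100))
  # interior elements without ghosts start fully unsupplied
  interior <- which(!map$periphery & !map$medullary &
                    lengths(map$ghost_cortical) == 0)
  expect_true(all(nb1$perfusion_nb[interior] == 0))
  # the medullary source switches on at its scheduled day
  med <- which(map$medullary & !map$periphery &
               lengths(map$ghost_cortical) == 0)
  nb5 <- neighbour_values(st, map, day = 5)
  nb10 <- neighbour_values(st, map, day = 10)
  expect_true(all(nb5$perfusion_nb[med] == 0))
  expect_true(all(nb10$perfusion_nb[med] == 30))
})

test_that("a quiescent element is unchanged and overload destroys tissue", {
  m <- tiny_mesh("LP")
  map <- neighbour_map(m)
  ctl <- fuzzy_controller()
  st <- initialize_state(m)
  n <- length(st$elements)
  # zero strain, zero perfusion anywhere: the only active rules are
  # angiogenesis next to the boundary sources; interior elements stay put
  st0 <- step_state(st, list(eps_hyd = numeric(n), eps_dis = numeric(n)),
                    ctl, map)
  interior <- !map$periphery & !map$medullary & lengths(map$ghost_cortical) == 0
  expect_true(all(st0$c_perfusion[interior] == 0))
  expect_true(all(st0$c_bone == 0))
  expect_true(all(st0$c_connective == 100))
  # destructive distortional strain decreases everything (floor 0)
  st1 <- st
  st1$c_bone <- rep(50, n); st1$c_cartilage <- rep(30, n)
  st1$c_connective <- rep(20, n); st1$c_perfusion <- rep(60, n)
  st2 <- step_state(st1, list(eps_hyd = numeric(n),
                              eps_dis = rep(0.30, n)), ctl, map)
  expect_true(all(st2$c_bone < 50))
  expect_true(all(st2$c_cartilage < 30))
  expect_true(all(st2$c_perfusion < 60))
  expect_equal(st2$c_bone + st2$c_cartilage + st2$c_connective, rep(100, n))
  # non-finite stimuli abort with the element id
  expect_error(step_state(st, list(eps_hyd = rep(NaN, n),
                                   eps_dis = numeric(n)), ctl, map),
               "non-finite strain stimulus")
})

test_that("a sustained osteogenic signal drives bone towards 100%", {
  m <- tiny_mesh("LP")
  map <- neighbour_map(m)
  ctl <- fuzzy_controller()
  st <- initialize_state(m)
  n <- length(st$elements)
  stim <- list(eps_hyd = rep(-0.005, n), eps_dis = rep(0.005, n))
  bones <- numeric(60)
  for (d in 1:60) {
    st <- step_state(st, stim, ctl, map)
    bones[d] <- mean(st$c_bone)
  }
  expect_true(all(diff(bones) > -1e-9))
  # plateau of the chondrogenesis/calcification balance under this signal
  expect_gt(mean(st$c_bone), 75)
  expect_lt(max(st$c_connective), 1e-6)
})

test_that("tissue fractions stay conserved and bounded under adversarial strains", {
  m <- tiny_mesh("LP")
  map <- neighbour_map(m)
  ctl <- fuzzy_controller()
  st <- initialize_state(m)
  n <- length(st$elements)
  set.seed(42)
  for (d in 1:60) {
    stim <- list(eps_hyd = rnorm(n, 0, 0.05), eps_dis = abs(rnorm(n, 0, 0.08)))
    st <- step_state(st, stim, ctl, map)
    vals <- c(st$c_bone, st$c_cartilage, st$c_connective, st$c_perfusion)
    expect_true(all(vals >= 0 & vals <= 100))
    expect_lt(max(abs(st$c_bone + st$c_cartilage + st$c_connective - 100)), 1e-6)
  }
  expect_equal(st$day, 60L)
})

test_that("the perfusion front reaches the whole callus and respects distance order", {
  m <- tiny_mesh("LP")
  map <- neighbour_map(m)
  ctl <- fuzzy_controller()
  st <- initialize_state(m)
  n <- length(st$elements)
  zero <- list(eps_hyd = numeric(n), eps_dis = numeric(n))
  # graph distance from any perfusion source (ghost-bearing element = 0)
  src <- which(map$periphery | map$medullary | lengths(map$ghost_cortical) > 0)
  dist <- rep(NA_integer_, n)
  dist[src] <- 0L
  frontier <- src
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- setdiff(unique(unlist(map$neighbours[frontier])), which(!is.na(dist)))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  first_day <- rep(NA_integer_, n)
  for (day in 1:120) {
    st <- step_state(st, zero, ctl, map)
    hit <- which(is.na(first_day) & st$c_perfusion > 5)
    first_day[hit] <- day
    if (!anyNA(first_day)) break
  }
  expect_false(anyNA(first_day))          # full revascularisation in finite time
  expect_true(all(st$c_perfusion > 5))
  # arrival day is non-decreasing in graph distance from the sources
  expect_true(all(diff(tapply(first_day, dist, min)) >= 0))
  agg <- tapply(first_day, dist, mean)
  expect_true(all(diff(agg) >= 0))
})

test_that("healing runs are deterministic and zero iterations return the initial state", {
  cfg <- tiny_config(iterations = 3L)
  r1 <- run_healing(cfg)
  r2 <- run_healing(cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$state, r2$state)
  cfg0 <- tiny_config(iterations = 0L)
  r0 <- run_healing(cfg0)
  expect_equal(nrow(r0$history), 0L)
  expect_true(all(r0$state$c_connective == 100))
  expect_equal(r0$state$day, 0L)
})

test_that("summaries expose the milestone quantities", {
  r <- run_healing(tiny_config(iterations = 3L))
  s <- summarize_healing(r)
  expect_equal(nrow(s$table), 3L)
  expect_equal(s$day1_mean_eps_dis, r$history$mean_eps_dis[1])
  expect_true(is.numeric(s$peak_cartilage))
  expect_error(summarize_healing(data.frame()), "empty")
})

test_that("material fields combine base regions with the tissue mixture", {
  m <- tiny_mesh("LP")
  mats <- material_field(m)
  expect_equal(unique(mats$E[m$region == 1L]), 16700)
  expect_equal(unique(mats$E[m$region == 2L]), 155)
  expect_equal(unique(mats$E[m$region == 4L]), 193000)
  expect_equal(unique(mats$E[m$region == 3L]), 3)     # 100% connective
  st <- initialize_state(m)
  st$c_bone <- rep(100, length(st$elements))
  st$c_connective <- rep(0, length(st$elements))
  mats2 <- material_field(m, st)
  expect_equal(unique(mats2$E[m$region == 3L]), 4000)
  matsT <- material_field(m, cortical_transverse = TRUE)
  expect_equal(unique(matsT$E[m$region == 1L]), 10000)
})
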