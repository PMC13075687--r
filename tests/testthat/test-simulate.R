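test_that("synthetic worlds are deterministic and climate-structured", {
  w1 <- make_world(world_config(seed = 5))
  w2 <- make_world(world_config(seed = 5))
  expect_identical(w1$env, w2$env)
  expect_identical(w1$area, w2$area)
  # temperature decreases away from the equator row
  expect_gt(stats::cor(w1$env$temperature, -abs(w1$env$lat)), 0.8)
  expect_true(all(w1$env$npp >= 0))
  expect_equal(length(unique(w1$area)), 6L)
  # partial correlation of NPP with precipitation given temperature > 0
  wbig <- make_world(world_config(rows = 20, cols = 20, n_areas = 4, seed = 8))
  rp <- resid(lm(npp ~ temperature, wbig$env))
  rq <- resid(lm(precipitation ~ temperature, wbig$env))
  expect_gt(stats::cor(rp, rq), 0)
  # block areas are contiguous rectangles with rook adjacency
  expect_true(isSymmetric(wbig$adjacency))
})

test_that("pure-birth clades grow at the closed-form expectation", {
  w <- make_world(world_config(seed = 3))
  ns <- vapply(1:50, function(i) {
    p <- scenario_params("cradles_of_diversity", lambda0 = 0.5, mu0 = 0,
                         gamma_T = 0, m = 0, tau = 6, seed = 900 + i,
                         n_cap = 10000)
    cl <- simulate_clade(w, p, start_area = 1)
    if (isTRUE(cl$extinct)) cl$n_extant else length(cl$phy$tip.label)
  }, numeric(1))
  expected <- exp(0.5 * 6)
  se <- stats::sd(ns) / sqrt(length(ns))
  expect_lt(abs(mean(ns) - expected), 2 * se + 1e-9)
})

test_that("simulated clades are ultrametric and internally consistent", {
  w <- make_world(world_config(seed = 3))
  for (s in c("stable_persistence", "historical_legacy")) {
    cl <- simulate_clade(w, scenario_params(s, seed = 41), occupy_prob = 0.7)
    expect_false(isTRUE(cl$extinct))
    d <- tip_depths(cl$phy)
    expect_lt((max(d) - min(d)) / max(d), 1e-9)
    # replaying the event log reproduces extant count and final ranges
    rep <- replay_event_log(cl)
    expect_equal(rep$n_extant, length(cl$phy$tip.label))
    tips <- as.integer(sub("^t", "", cl$phy$tip.label))
    arr <- cl$truth$arrival
    for (li in tips[1:5]) {
      expect_setequal(rep$ranges[[li]], arr$region[arr$species == paste0("t", li)])
    }
    # PAM consistent with final ranges: per-region richness matches
    sets <- split(arr$region, arr$species)
    for (a in sort(unique(cl$area))) {
      in_region <- sum(vapply(sets, function(r) a %in% r, logical(1)))
      expect_equal(unname(cl$truth$region_richness[a]), in_region)
    }
    expect_true(all(richness_per_cell(cl$pam) >= 0))
  }
})

test_that("equilibrium richness fluctuates around K under stable persistence", {
  w <- make_world(world_config(seed = 3))
  devs <- c()
  for (i in 1:5) {
    cl <- simulate_clade(w, scenario_params("stable_persistence", seed = 600 + i),
                         occupy_prob = 0.7)
    if (isTRUE(cl$extinct)) next
    # reconstruct regional richness through time from the event log and
    # average over the second half of the run
    log <- cl$event_log
    A <- length(unique(w$area))
    N <- rep(0, A); lastt <- 0; acc <- rep(0, A); t0 <- cl$tau / 2
    for (k in seq_len(nrow(log))) {
      t <- log$time[k]
      if (t > t0) acc <- acc + N * (t - max(lastt, t0))
      ty <- log$type[k]; r <- log$region[k]
      if (ty == "extirpation") N[r] <- N[r] - 1 else N[r] <- N[r] + 1
      lastt <- t
    }
    acc <- acc + N * (cl$tau - max(lastt, t0))
    devs <- c(devs, abs(acc / (cl$tau - t0) - cl$truth$K_r) / cl$truth$K_r)
  }
  expect_gte(mean(devs < 0.25), 0.9)
})

test_that("stable persistence decouples DR from richness relative to NPP", {
  w <- make_world(world_config(seed = 3))
  ok <- 0; tot <- 0
  for (i in 1:10) {
    cl <- simulate_clade(w, scenario_params("stable_persistence", seed = 600 + i),
                         occupy_prob = 0.7)
    if (isTRUE(cl$extinct)) next
    tot <- tot + 1
    rates <- dr_statistic(cl$phy)
    arr <- cl$truth$arrival
    A <- length(unique(w$area))
    drr <- vapply(seq_len(A), function(a) {
      sp <- arr$species[arr$region == a]
      stats::median(rates$dr[rates$species %in% sp])
    }, numeric(1))
    rich <- cl$truth$region_richness
    if (abs(stats::cor(drr, rich, method = "spearman")) <
        stats::cor(w$region_env$mean_npp, rich)) ok <- ok + 1
  }
  expect_gte(ok / tot, 0.8)
})

test_that("richness tracks NPP at equilibrium and arrival time under legacy", {
  w <- make_world(world_config(seed = 3))
  cl <- simulate_clade(w, scenario_params("stable_persistence", seed = 601),
                       occupy_prob = 0.7)
  expect_gt(stats::cor(cl$truth$region_richness, w$region_env$mean_npp), 0.5)
  hl <- simulate_clade(w, scenario_params("historical_legacy", seed = 44),
                       occupy_prob = 0.7)
  # regional colonization age = oldest arrival among its species
  arr <- hl$truth$arrival
  col_age <- vapply(sort(unique(arr$region)), function(a)
    max(arr$arrival[arr$region == a]), numeric(1))
  rich <- hl$truth$region_richness[sort(unique(arr$region))]
  expect_gt(stats::cor(rich, col_age), 0.5)
})

test_that("datasets round-trip through the plain-text exporter", {
  w <- make_world(world_config(seed = 3))
  cl <- simulate_clade(w, scenario_params("stable_persistence", seed = 601),
                       occupy_prob = 0.7)
  dir <- tempfile("clade")
  export_dataset(cl, dir)
  phy2 <- read_phylogeny(file.path(dir, "tree.nwk"))
  pam2 <- read_pam(file.path(dir, "pam.csv"))
  env2 <- read_env(file.path(dir, "env.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_setequal(phy2$tip.label, cl$phy$tip.label)
  expect_equal(unname(richness_per_cell(pam2)), unname(richness_per_cell(cl$pam)))
  expect_equal(env2$npp, cl$env$npp, tolerance = 1e-9)
  expect_equal(truth$scenario, "stable_persistence")
  expect_length(truth$tip_lambda, length(cl$phy$tip.label))
})

test_that("benchmark suites are sized, filtered, and reproducible", {
  s1 <- benchmark_suite(1, seed = 2, min_tips = 50)
  expect_length(s1$clades, 4L)
  expect_equal(nrow(s1$manifest), 4L)
  expect_true(all(s1$manifest$n_tips >= 50))
  expect_setequal(s1$manifest$scenario, names(scenario_models()))
  s2 <- benchmark_suite(1, seed = 2, min_tips = 50)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(write_phylogeny(s1$clades[[1]]$phy),
                   write_phylogeny(s2$clades[[1]]$phy))
})
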