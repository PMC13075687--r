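test_that("range state space has the expected size and ordering", {
  expect_equal(build_state_space(2, 2)$n_states - 1L, 3L)
  expect_equal(build_state_space(3, 3)$n_states - 1L, 7L)
  expect_equal(build_state_space(10, 10)$n_states - 1L, 1023L)
  sp <- build_state_space(3, 2)
  expect_equal(sp$n_states - 1L, 3 + 3)
  expect_identical(sp$states[[1]], 1L)          # singletons first, bitmask order
  expect_identical(sp$states[[4]], c(1L, 2L))
  expect_identical(sp$states[[sp$null_index]], integer(0))
  expect_error(build_state_space(11), "between 1 and 10")
})

test_that("anagenetic generator implements DEC dispersal/extirpation rates", {
  sp <- build_state_space(2, 2)
  Q <- anagenetic_Q(sp, dec_params(0.1, 0.05))
  i1 <- 1; i12 <- 3; inull <- 4
  expect_equal(Q[i1, i12], 0.1)          # {1} -> {1,2} at d|R| = d
  expect_equal(Q[i1, inull], 0.05)       # {1} -> null at e
  expect_equal(Q[i12, i1], 0.05)         # {1,2} -> {2} at e per area
  expect_equal(unname(rowSums(Q)), rep(0, 4), tolerance = 1e-14)
  expect_true(all(anagenetic_Q(sp, dec_params(0, 0)) == 0))
  # survival conditioning removes only the single-area -> null transition
  Qc <- anagenetic_Q(sp, dec_params(0.1, 0.05), condition_survival = TRUE)
  expect_equal(Qc[i1, inull], 0)
  expect_equal(Qc[i12, i1], 0.05)
})

test_that("transition probabilities match closed forms and the series oracle", {
  sp <- build_state_space(2, 2)
  Q <- anagenetic_Q(sp, dec_params(0.2, 0.07))
  expect_equal(transition_probs(Q, 0), diag(4), tolerance = 1e-12)
  P <- transition_probs(Q, 1.7)
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-10)
  expect_true(all(P >= 0))
  expect_equal(P, oracle_expm(Q * 1.7), tolerance = 1e-8)
  # A = 1 scalar closed form: P({1} -> null, t) = 1 - exp(-e t)
  sp1 <- build_state_space(1, 1)
  Q1 <- anagenetic_Q(sp1, dec_params(0.3, 0.11))
  expect_equal(transition_probs(Q1, 2.5)[1, 2], 1 - exp(-0.11 * 2.5),
               tolerance = 1e-10)
  expect_error(transition_probs(Q, -1), ">= 0")
})

test_that("cladogenesis table enumerates vicariance and subset sympatry", {
  sp <- build_state_space(2, 2)
  tb1 <- cladogenesis_table(sp, 1L)
  expect_equal(nrow(tb1), 1)
  expect_equal(tb1$weight, 1)
  tb <- cladogenesis_table(sp, c(1, 2))
  expect_equal(nrow(tb), 6)
  expect_equal(tb$weight, rep(1 / 6, 6))
  sp3 <- build_state_space(3, 3)
  for (s in seq_len(sp3$n_states - 1L))
    expect_equal(sum(cladogenesis_table(sp3, s)$weight), 1, tolerance = 1e-12)
  expect_error(cladogenesis_table(sp, integer(0)), "null")
})

test_that("pruning equals exhaustive enumeration on 2- and 3-tip trees", {
  sp <- build_state_space(2, 2)
  set.seed(11)
  for (rep in 1:3) {
    d <- round(runif(1, 0.05, 0.4), 3); e <- round(runif(1, 0.02, 0.2), 3)
    pars <- dec_params(d, e)
    t1 <- round(runif(1, 0.5, 3), 3); t2 <- round(runif(1, 0.5, 3), 3)
    cherry <- suppressWarnings(read_phylogeny(sprintf("(A:%f,B:%f);", t1, t2)))
    for (sA in 1:3) for (sB in 1:3) {
      ranges <- list(A = sp$states[[sA]], B = sp$states[[sB]])
      expect_equal(dec_loglik(cherry, ranges, pars, sp),
                   oracle_cherry_loglik(t1, t2, sA, sB, d, e),
                   tolerance = 1e-8)
    }
    ta <- round(runif(1, 0.3, 2), 3); tb <- round(runif(1, 0.3, 2), 3)
    tu <- round(runif(1, 0.3, 2), 3); tc <- round(runif(1, 0.3, 3), 3)
    three <- suppressWarnings(read_phylogeny(sprintf("((A:%f,B:%f):%f,C:%f);", ta, tb, tu, tc)))
    for (sA in 1:3) for (sC in 1:3) {
      ranges <- list(A = sp$states[[sA]], B = 2L, C = sp$states[[sC]])
      expect_equal(dec_loglik(three, ranges, pars, sp),
                   oracle_three_tip(ta, tb, tu, tc, sA, 2, sC, d, e)$loglik,
                   tolerance = 1e-8)
    }
  }
})

test_that("likelihood is symmetric in children and decreases in e for disjoint tips", {
  sp <- build_state_space(2, 2)
  pars <- dec_params(0.1, 0.05)
  l1 <- dec_loglik(suppressWarnings(read_phylogeny("(A:1,B:2);")),
                   list(A = 1, B = 2), pars, sp)
  l2 <- dec_loglik(suppressWarnings(read_phylogeny("(B:2,A:1);")),
                   list(A = 1, B = 2), pars, sp)
  expect_equal(l1, l2, tolerance = 1e-12)
  phy <- read_phylogeny("((A:1,B:1):1,C:2);")
  lls <- vapply(c(0.5, 1, 2, 4), function(e)
    dec_loglik(phy, list(A = 1, B = 2, C = 2), dec_params(0.1, e), sp), numeric(1))
  expect_true(all(diff(lls) < 0))
})

test_that("ML fit sits at a local optimum and degenerate data pin e low", {
  set.seed(21)
  sp <- build_state_space(3)
  phy <- validate_phylogeny(ape::rphylo(25, 0.4, 0))
  ranges <- simulate_dec_ranges(phy, dec_params(0.15, 0.05), sp, seed = 2)
  fit <- fit_dec(phy, ranges, sp)
  # optimum beats a 5x5 grid around it, up to the optimizer's convergence
  # tolerance on the log-likelihood
  for (fd in c(0.7, 0.9, 1, 1.1, 1.4)) for (fe in c(0.7, 0.9, 1, 1.1, 1.4)) {
    if (fd == 1 && fe == 1) next
    ll <- dec_loglik(phy, ranges,
                     dec_params(fit$params$d * fd, fit$params$e * fe), sp)
    expect_lte(ll, fit$loglik + 2e-3)
  }
  # all tips in one area -> e near its lower bound
  one <- stats::setNames(rep(list(2L), length(phy$tip.label)), phy$tip.label)
  fit1 <- fit_dec(phy, one, sp)
  expect_lt(fit1$params$e, 5e-4)
})

test_that("marginal ancestral ranges match exhaustive enumeration", {
  sp <- build_state_space(2, 2)
  d <- 0.2; e <- 0.1
  phy <- read_phylogeny("((A:1,B:1):1,C:2);")
  ranges <- list(A = 1L, B = 2L, C = 2L)
  rec <- ancestral_ranges(phy, ranges, dec_params(d, e), sp)
  or <- oracle_three_tip(1, 1, 1, 2, 1, 2, 2, d, e)
  expect_equal(unname(rec$marginal["4", ]), or$root, tolerance = 1e-8)
  expect_equal(unname(rec$marginal["5", ]), or$internal, tolerance = 1e-8)
  expect_equal(unname(rowSums(rec$marginal)), rep(1, 2), tolerance = 1e-8)
  # near-zero rates: root argmax contains the area shared by all tips
  rec0 <- ancestral_ranges(phy, list(A = c(1L, 2L), B = 2L, C = 2L),
                           dec_params(1e-4, 1e-4), sp)
  expect_true(2L %in% rec0$argmax[[4]])
  # node ages measured back from the present
  expect_equal(unname(rec$node_ages[4:5]), c(2, 1))
})

test_that("range simulation is deterministic given a seed", {
  sp <- build_state_space(3)
  phy <- validate_phylogeny(ape::rphylo(12, 0.5, 0))
  r1 <- simulate_dec_ranges(phy, dec_params(0.2, 0.1), sp, seed = 5)
  r2 <- simulate_dec_ranges(phy, dec_params(0.2, 0.1), sp, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(lengths(r1) >= 1))
})
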