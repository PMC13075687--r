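test_that("path model specification validates structure", {
  m <- path_model(rbind(c("x", "m"), c("m", "y")))
  expect_setequal(m$endogenous, c("m", "y"))
  expect_setequal(m$exogenous, "x")
  expect_error(path_model(rbind(c("x", "y"), c("y", "x"))), "cyclic")
  expect_error(path_model(rbind(c("x", "x"))), "self-loop")
})

test_that("variable table assembly: log transform, z-scores, drops", {
  cells <- paste0("c", 1:40)
  set.seed(1)
  richness <- stats::setNames(c(0L, rpois(39, 20) + 1L), cells)
  env <- data.frame(cell_id = cells, temperature = rnorm(40, 20),
                    precipitation = rnorm(40, 1000, 100), npp = runif(40, 1, 5))
  ages <- stats::setNames(runif(40, 1, 10), cells)
  rates <- stats::setNames(runif(40, 0.1, 0.5), cells)
  tab <- prepare_variables(richness, env, ages, rates, min_cells = 30)
  expect_equal(attr(tab, "dropped"), 1L)
  expect_false("c1" %in% tab$cell_id)
  expect_equal(tab$lnS, log(richness[tab$cell_id]), ignore_attr = TRUE)
  for (v in c("temperature", "precipitation", "npp", "age", "dr")) {
    expect_equal(mean(tab[[v]]), 0, tolerance = 1e-8)
    expect_equal(stats::sd(tab[[v]]), 1, tolerance = 1e-8)
  }
  expect_error(prepare_variables(richness[1:20], env[1:20, ], ages[1:20],
                                 rates[1:20], min_cells = 30), "insufficient")
  env2 <- env; env2$npp <- 1
  expect_error(prepare_variables(richness, env2, ages, rates), "constant")
  # richness 1 -> lnS 0
  r3 <- richness; r3[2] <- 1L
  tab3 <- prepare_variables(r3, env, ages, rates)
  expect_equal(tab3$lnS[tab3$cell_id == "c2"], 0)
})

test_that("mediation chain is recovered and saturated models fit perfectly", {
  set.seed(1); n <- 10000
  x <- rnorm(n)
  m <- 0.8 * x + rnorm(n, 0, sqrt(1 - 0.64))
  y <- 0.5 * m + rnorm(n, 0, sqrt(0.75))
  tab <- data.frame(x = x, m = m, y = y)
  fit <- fit_path_model(path_model(rbind(c("x", "m"), c("m", "y"))), tab)
  expect_lt(abs(unname(fit$beta["m", "x"]) - 0.8), 0.05)
  expect_lt(abs(unname(fit$beta["y", "m"]) - 0.5), 0.05)
  expect_equal(fit$df, 1)
  expect_gte(fit$cfi, 0.99)

  sat <- fit_path_model(path_model(rbind(c("x", "m"), c("x", "y"), c("m", "y"))), tab)
  expect_equal(sat$T, 0, tolerance = 1e-8)
  expect_equal(sat$df, 0)
  expect_equal(sat$srmr, 0, tolerance = 1e-8)
  expect_equal(sat$cfi, 1)
  expect_equal(sat$sigma, sat$S, tolerance = 1e-10)

  # collinear parents are refused with names
  tab$x2 <- tab$x
  expect_error(fit_path_model(path_model(rbind(c("x", "y"), c("x2", "y"))), tab),
               "singular")
})

test_that("equation-wise least squares maximizes the covariance likelihood", {
  set.seed(4)
  sys <- random_sem_system(5, seed = 8)
  dat <- simulate_sem_data(sys, 2000, seed = 9)
  model <- path_model(sys$edges, vars = sys$vars)
  fit <- fit_path_model(model, dat)
  # perturbing any fitted coefficient cannot increase the likelihood
  F_of <- function(B) {
    IB <- solve(diag(length(sys$vars)) - B)
    Sigma <- IB %*% fit$psi %*% t(IB)
    as.numeric(determinant(Sigma)$modulus) +
      sum(diag(fit$S %*% solve(Sigma)))
  }
  f0 <- F_of(fit$B)
  for (k in which(fit$B != 0)) {
    for (h in c(-1e-3, 1e-3)) {
      Bp <- fit$B; Bp[k] <- Bp[k] + h
      expect_gte(F_of(Bp), f0 - 1e-10)
    }
  }
})

test_that("implied covariance matches a Monte-Carlo simulation of the fit", {
  set.seed(2)
  sys <- random_sem_system(4, seed = 3)
  dat <- simulate_sem_data(sys, 5000, seed = 5)
  model <- path_model(sys$edges, vars = sys$vars)
  fit <- fit_path_model(model, dat)
  # draw from the fitted recursive system
  nmc <- 1e6
  X <- matrix(0, nmc, 4, dimnames = list(NULL, sys$vars))
  for (j in seq_along(sys$vars)) {
    v <- sys$vars[j]
    mu <- if (any(fit$B[v, ] != 0)) X %*% fit$B[v, ] else rep(0, nmc)
    X[, j] <- mu + rnorm(nmc, 0, sqrt(fit$psi[v, v]))
  }
  expect_equal(stats::cov(X), fit$sigma, tolerance = 1e-2, ignore_attr = TRUE)
})

test_that("fit indices follow their closed forms", {
  fi <- fit_indices(20, 10, 300, 15, 101)
  expect_equal(fi$rmsea, sqrt(10 / (10 * 100)))
  fi2 <- fit_indices(10, 10, 300, 15, 101)
  expect_equal(fi2$rmsea, 0)
  expect_equal(fi2$cfi, 1)
  expect_equal(fi2$tli, 1, tolerance = 1e-12)
  fi3 <- fit_indices(20, 10, 12, 15, 101)   # baseline no worse than its df
  expect_false(fi3$defined)
})

test_that("information criteria follow their formulas", {
  ic <- information_criteria(-100, 5, 100)
  expect_equal(ic$aic, 210)
  expect_equal(ic$bic, -2 * -100 + 5 * log(100))
  # AIC differences invariant to additive logL constants
  ic2 <- information_criteria(-100 + 7, 5, 100)
  ic3 <- information_criteria(-50 + 7, 3, 100)
  ic2b <- information_criteria(-100, 5, 100)
  ic3b <- information_criteria(-50, 3, 100)
  expect_equal(ic2$aic - ic3$aic, ic2b$aic - ic3b$aic)
  expect_error(information_criteria(-1, 0, 10))
})

test_that("effect decomposition partitions paths by final mediator", {
  # hand case: T -> NPP (0.6), NPP -> lnS (0.5)
  set.seed(10)
  sys <- list()
  m <- path_model(rbind(c("temperature", "npp"), c("npp", "lnS")))
  fit <- list(beta = matrix(0, 3, 3,
                            dimnames = list(c("temperature", "npp", "lnS"),
                                            c("temperature", "npp", "lnS"))),
              model = m)
  fit$beta["npp", "temperature"] <- 0.6
  fit$beta["lnS", "npp"] <- 0.5
  ed <- effect_decomposition(fit)
  row <- ed[ed$predictor == "temperature", ]
  expect_equal(row$via_npp, 0.3)
  expect_equal(row$direct, 0)
  expect_equal(row$total, 0.3, tolerance = 1e-10)

  # full model with random betas: totals equal the matrix-inverse oracle
  fm <- full_model()
  p <- length(fm$vars)
  B <- matrix(0, p, p, dimnames = list(fm$vars, fm$vars))
  set.seed(33)
  for (i in seq_len(nrow(fm$edges)))
    B[fm$edges$to[i], fm$edges$from[i]] <- runif(1, -0.5, 0.5)
  fit2 <- list(beta = B, model = fm)
  ed2 <- effect_decomposition(fit2)
  Tot <- solve(diag(p) - B)          # total effects: (I - B)^-1
  for (i in seq_len(nrow(ed2))) {
    expect_equal(ed2$total[i], Tot["lnS", ed2$predictor[i]], tolerance = 1e-10)
    expect_equal(ed2$total[i],
                 ed2$direct[i] + ed2$via_npp[i] + ed2$via_age[i] +
                   ed2$via_dr[i] + ed2$indirect_other[i], tolerance = 1e-10)
  }
  expect_equal(ed2$indirect_other, rep(0, nrow(ed2)))  # three classes suffice
})

test_that("VIF matches closed forms and flags collinearity", {
  n <- 400
  # exactly orthogonal predictors via QR
  set.seed(12)
  Z <- qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)))
  tab <- data.frame(a = Z[, 1], b = Z[, 2], c = Z[, 3])
  expect_equal(unname(vif(tab, c("a", "b", "c"))), rep(1, 3), tolerance = 1e-8)
  # exact correlation 0.8 -> VIF = 1/(1-0.64)
  tab$d <- 0.8 * tab$a + 0.6 * tab$b
  expect_equal(unname(vif(tab, c("a", "d"))[1]), 1 / (1 - 0.64), tolerance = 1e-8)
  tab$dup <- tab$a
  expect_true(is.infinite(vif(tab, c("a", "dup"))["dup"]))
  expect_error(vif(tab, "a"), "at least 2")
})

test_that("Moran's I: checkerboard, gradient, permutation null", {
  co <- expand.grid(x = 1:2, y = 1:2)
  expect_equal(morans_i(c(1, -1, -1, 1), co, weights = "rook"), -1, tolerance = 1e-12)
  g <- expand.grid(x = 1:10, y = 1:10)
  v <- g$x + g$y
  expect_gt(morans_i(v, g, weights = "knn"), 0.5)
  set.seed(14)
  perm <- replicate(200, morans_i(sample(v), g, weights = "knn"))
  expect_equal(mean(perm), -1 / (length(v) - 1), tolerance = 0.015)
  expect_error(morans_i(rep(1, 9), expand.grid(1:3, 1:3)), "zero variance")
  W <- spatial_weights(g, "knn", k = 8)
  expect_equal(unname(rowSums(W)), rep(1, 100), tolerance = 1e-12)
})

test_that("the spatial sensitivity refit adds lat/lon as exogenous parents", {
  m <- with_spatial_covariates(full_model())
  for (y in c("npp", "age", "dr", "lnS")) {
    expect_true(any(m$edges$from == "lat" & m$edges$to == y))
    expect_true(any(m$edges$from == "lon" & m$edges$to == y))
  }
  expect_setequal(intersect(m$exogenous, c("lat", "lon")), c("lat", "lon"))
})
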