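# Synthetic gridded worlds and clades simulated under the four
# richness-generating scenarios, with full ground truth.

#' Configuration of a synthetic gridded world
#'
#' The world is a rows x cols lattice. Temperature follows a linear
#' latitudinal gradient (warmest at the central row, the "equator") plus
#' Gaussian noise; precipitation is a smoothed Gaussian random field; NPP is
#' a linear function of standardized temperature and precipitation plus
#' noise, truncated at zero. Areas (the DEC regions of the generative
#' process) are contiguous blocks on a grid, so block rows differ systematically
#' in temperature and productivity.
#'
#' @param rows,cols lattice dimensions (>= 4 each).
#' @param n_areas number of contiguous block areas (2..10), arranged on a block grid.
#' @param temp_base equator temperature (degrees C).
#' @param temp_slope cooling per row away from the equator.
#' @param temp_sd temperature noise sd.
#' @param precip_mean,precip_sd precipitation field mean and sd (mm/yr).
#' @param precip_smoothness Gaussian-kernel length scale (cells) of the
#'   precipitation field.
#' @param npp_base,alpha_T,alpha_P,npp_sd NPP intercept, coefficients on
#'   standardized temperature and precipitation (>= 0), and noise sd.
#' @param seed integer RNG seed.
#' @export
world_config <- function(rows = 18L, cols = 12L, n_areas = 6L,
                         temp_base = 25, temp_slope = 2, temp_sd = 1,
                         precip_mean = 1500, precip_sd = 400, precip_smoothness = 3,
                         npp_base = 3, alpha_T = 0.5, alpha_P = 1.5, npp_sd = 1,
                         npp_smoothness = 3, seed = 1L) {
  stopifnot(rows >= 4L, cols >= 4L, n_areas >= 2L, n_areas <= 10L,
            alpha_T >= 0, alpha_P >= 0)
  structure(as.list(environment()), class = "world_config")
}

#' Generate a synthetic world
#'
#' @param config a \code{world_config}.
#' @return object of class \code{world}: \code{env} (cell table with
#'   temperature, precipitation, npp, lat, lon), \code{coords}, \code{area}
#'   (named cell -> area label), \code{region_env} (per-area means and
#'   standardized temperature), \code{config}.
#' @export
make_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  rows <- config$rows; cols <- config$cols
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  grid <- grid[order(grid$row, grid$col), ]
  cell_id <- sprintf("c%02d_%02d", grid$row, grid$col)
  lat <- grid$row - (rows + 1) / 2          # 0 at the equator row
  temperature <- config$temp_base - config$temp_slope * abs(lat) +
    stats::rnorm(nrow(grid), 0, config$temp_sd)
  # smoothed Gaussian random fields (unit sd) for precipitation and for the
  # non-climatic component of NPP (soils, disturbance history, ...): both
  # vary at broad spatial scale, as their real counterparts do
  xy <- cbind(grid$row, grid$col)
  smooth_field <- function(scale) {
    K <- exp(-as.matrix(stats::dist(xy))^2 / (2 * scale^2))
    raw <- as.vector(K %*% stats::rnorm(nrow(grid)))
    (raw - mean(raw)) / stats::sd(raw)
  }
  precipitation <- config$precip_mean + config$precip_sd * smooth_field(config$precip_smoothness)
  zT <- (temperature - mean(temperature)) / stats::sd(temperature)
  zP <- (precipitation - mean(precipitation)) / stats::sd(precipitation)
  npp <- pmax(config$npp_base + config$alpha_T * zT + config$alpha_P * zP +
                config$npp_sd * smooth_field(config$npp_smoothness), 0)
  # contiguous blocks as areas, arranged on a block grid (gr x gc) so that
  # block rows differ in climate while colonization can spread in 2-D
  divs <- which(config$n_areas %% seq_len(config$n_areas) == 0L)
  gc_ <- max(divs[divs <= sqrt(config$n_areas)])
  gr_ <- config$n_areas %/% gc_
  brow <- pmin(ceiling(grid$row / (rows / gr_)), gr_)
  bcol <- pmin(ceiling(grid$col / (cols / gc_)), gc_)
  area <- stats::setNames(as.integer((brow - 1L) * gc_ + bcol), cell_id)
  blk <- cbind(row = rep(seq_len(gr_), each = gc_), col = rep(seq_len(gc_), gr_))
  adjacency <- (abs(outer(blk[, "row"], blk[, "row"], "-")) +
                abs(outer(blk[, "col"], blk[, "col"], "-"))) == 1L
  env <- data.frame(cell_id = cell_id, temperature = temperature,
                    precipitation = precipitation, npp = npp,
                    lat = lat, lon = grid$col, stringsAsFactors = FALSE)
  reg <- data.frame(area = sort(unique(area)))
  reg$mean_temp <- vapply(reg$area, function(a) mean(temperature[area == a]), numeric(1))
  reg$mean_npp <- vapply(reg$area, function(a) mean(npp[area == a]), numeric(1))
  reg$z_temp <- (reg$mean_temp - mean(reg$mean_temp)) / stats::sd(reg$mean_temp)
  structure(list(env = env,
                 coords = data.frame(cell_id = cell_id, lat = lat, lon = grid$col),
                 area = area, adjacency = adjacency, region_env = reg,
                 config = config),
            class = "world")
}

#' Scenario parameters for the clade simulator
#'
#' Per-scenario generative rules (diversity dependence acts on extinction
#' only):
#' \describe{
#'   \item{stable_persistence}{speciation constant (lambda0); extinction
#'     mu0 N_r / K_r with K_r = k_npp x mean regional NPP. Richness
#'     equilibrates at K_r, tracking productivity.}
#'   \item{speciation_balance}{speciation lambda0 exp(gamma_T zT_r);
#'     extinction diversity-dependent with a common K. Equilibrium richness
#'     tracks the temperature-driven speciation rate.}
#'   \item{historical_legacy}{constant lambda > mu, no diversity
#'     dependence, slow dispersal, short horizon: richness reflects time
#'     since colonization.}
#'   \item{cradles_of_diversity}{speciation lambda0 exp(gamma_T zT_r),
#'     constant mu, short horizon: richness tracks speciation rate without
#'     reaching equilibrium.}
#' }
#' Default horizons: 25/mu0 for the equilibrium scenarios; for the
#' nonequilibrium scenarios, the time for the fastest-growing region to
#' reach ~\code{n_target} species, log(n_target)/max net diversification
#' (the literal 0.5/net-diversification would leave 1-2 species).
#'
#' @param scenario one of the four scenario names.
#' @param lambda0 base speciation rate (per lineage per region per Ma).
#' @param mu0 base extinction (extirpation) rate.
#' @param k_npp equilibrium richness per unit regional NPP.
#' @param gamma_T temperature sensitivity of speciation.
#' @param m dispersal rate to each adjacent area (per lineage per Ma).
#' @param tau simulation horizon (Ma); \code{NULL} = scenario default.
#' @param n_target target clade size used to set nonequilibrium horizons.
#' @param n_cap hard cap on extant lineages (simulation stops early).
#' @param occupancy \code{"npp"}: within an occupied region, a species'
#'   probability of occupying a cell scales with the cell's NPP (local
#'   energy limits local coexistence -- the stable-persistence mechanism at
#'   cell grain); \code{"uniform"}: all cells equally likely. Defaults to
#'   \code{"npp"} for stable_persistence and \code{"uniform"} otherwise.
#' @param seed integer RNG seed.
#' @export
scenario_params <- function(scenario = c("stable_persistence", "speciation_balance",
                                         "historical_legacy", "cradles_of_diversity"),
                            lambda0 = NULL, mu0 = NULL, k_npp = 12,
                            gamma_T = NULL, m = NULL, tau = NULL,
                            n_target = 100L, n_cap = 400L,
                            occupancy = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  # dispersal is slow (0.02/Ma) in the equilibrium scenarios so that regional
  # richness equilibrates near K rather than being inflated by immigration;
  # cradles keeps fast dispersal so assemblage ages stay uninformative there
  def <- switch(scenario,
    stable_persistence  = list(lambda0 = 0.5,  mu0 = 0.5,  gamma_T = 0, m = 0.02),
    speciation_balance  = list(lambda0 = 0.5,  mu0 = 0.5,  gamma_T = 1, m = 0.02),
    historical_legacy   = list(lambda0 = 0.3,  mu0 = 0.05, gamma_T = 0, m = 0.02),
    cradles_of_diversity = list(lambda0 = 0.25, mu0 = 0.05, gamma_T = 1, m = 0.05))
  if (is.null(lambda0)) lambda0 <- def$lambda0
  if (is.null(mu0)) mu0 <- def$mu0
  if (is.null(gamma_T)) gamma_T <- def$gamma_T
  if (is.null(m)) m <- def$m
  if (is.null(occupancy))
    occupancy <- if (scenario == "stable_persistence") "npp" else "uniform"
  occupancy <- match.arg(occupancy, c("uniform", "npp"))
  stopifnot(lambda0 >= 0, mu0 >= 0, k_npp >= 0, m >= 0)
  structure(list(scenario = scenario, lambda0 = lambda0, mu0 = mu0,
                 k_npp = k_npp, gamma_T = gamma_T, m = m, tau = tau,
                 n_target = as.integer(n_target), n_cap = as.integer(n_cap),
                 occupancy = occupancy, seed = seed),
            class = "scenario_params")
}

# resolve per-region speciation rates, K, and the horizon for a world
resolve_rates <- function(world, params) {
  reg <- world$region_env
  A <- nrow(reg)
  lambda_r <- params$lambda0 * exp(params$gamma_T * reg$z_temp)
  equilibrium <- params$scenario %in% c("stable_persistence", "speciation_balance")
  K_r <- if (params$scenario == "stable_persistence") {
    params$k_npp * reg$mean_npp
  } else if (params$scenario == "speciation_balance") {
    rep(params$k_npp * mean(reg$mean_npp), A)
  } else rep(Inf, A)
  tau <- params$tau
  if (is.null(tau)) {
    tau <- if (equilibrium) 25 / params$mu0
    else log(params$n_target) / max(lambda_r - params$mu0)
  }
  list(lambda_r = lambda_r, K_r = K_r, dd = equilibrium, tau = tau, A = A)
}

#' Simulate a clade under one richness-generating scenario
#'
#' Gillespie simulation of a lineage-based birth-death-dispersal process over
#' the world's areas, starting from one lineage in one area. Events:
#' speciation of a lineage within an occupied region (the daughter starts in
#' that region only), extirpation of a lineage from a region (global
#' extinction when the range empties), and dispersal into an adjacent
#' unoccupied region. Rates follow the scenario (see
#' \code{\link{scenario_params}}).
#'
#' @param world a \code{world}.
#' @param params a \code{scenario_params}.
#' @param start_area root lineage's area (default: drawn at random, so
#'   colonization history is contingent rather than climate-aligned).
#' @param occupy_prob probability a species occupies each cell of its areas
#'   (1 = deterministic full-area occupancy).
#' @return object of class \code{simulated_clade}: \code{phy} (extant-tip
#'   ultrametric tree), \code{pam}, \code{env}, \code{area} (cell -> area),
#'   \code{truth} (scenario, per-tip lambda, true arrival table, regional
#'   richness, lambda_r, K_r), \code{event_log}, \code{tau}, \code{params};
#'   or, if the clade died or left < 2 tips, a list with
#'   \code{extinct = TRUE}.
#' @export
simulate_clade <- function(world, params, start_area = NULL, occupy_prob = 1) {
  stopifnot(inherits(world, "world"), inherits(params, "scenario_params"))
  set.seed(params$seed)
  rr <- resolve_rates(world, params)
  A <- rr$A; tau <- rr$tau
  if (is.null(start_area)) start_area <- sample.int(A, 1L)
  cap <- 4096L
  occ <- matrix(FALSE, cap, A)          # lineage x area occupancy
  alive <- logical(cap)
  parent <- integer(cap); birth <- numeric(cap); death <- rep(NA_real_, cap)
  gain_time <- matrix(NA_real_, cap, A) # most recent acquisition of each area
  n_lin <- 1L
  occ[1L, start_area] <- TRUE; alive[1L] <- TRUE
  parent[1L] <- 0L; birth[1L] <- 0; gain_time[1L, start_area] <- 0
  # event log (preallocated, doubled as needed)
  lcap <- 4096L; lev <- 0L
  ev_time <- numeric(lcap); ev_type <- character(lcap)
  ev_lineage <- integer(lcap); ev_region <- integer(lcap); ev_child <- integer(lcap)
  log_event <- function(t, type, lineage, region, child = NA_integer_) {
    if (lev == lcap) {
      lcap <<- lcap * 2L
      length(ev_time) <<- lcap; length(ev_type) <<- lcap
      length(ev_lineage) <<- lcap; length(ev_region) <<- lcap; length(ev_child) <<- lcap
    }
    lev <<- lev + 1L
    ev_time[lev] <<- t; ev_type[lev] <<- type
    ev_lineage[lev] <<- lineage; ev_region[lev] <<- region; ev_child[lev] <<- child
  }
  log_event(0, "origin", 1L, start_area)
  t <- 0
  repeat {
    idx <- which(alive)
    if (length(idx) == 0L) break
    O <- occ[idx, , drop = FALSE]
    N_r <- colSums(O)
    mu_r <- if (rr$dd) params$mu0 * N_r / rr$K_r else rep(params$mu0, A)
    # per-capita speciation: a lineage speciates at the mean lambda over its
    # range, and the daughter is born into one of its regions (prob ~ lambda)
    lam_i <- as.vector(O %*% rr$lambda_r) / rowSums(O)
    ext_r <- N_r * mu_r
    # dispersal: per extant lineage, rate m per adjacent unoccupied area
    reachable <- (O %*% world$adjacency) > 0 & !O  # adjacent & unoccupied
    disp_rate <- params$m * sum(reachable)
    total <- sum(lam_i) + sum(ext_r) + disp_rate
    if (total <= 0) break
    t <- t + stats::rexp(1L, total)
    if (t >= tau) { t <- tau; break }
    u <- stats::runif(1L, 0, total)
    if (u < sum(lam_i)) {
      # stop at the cap without applying the event, so no zero-length pendant
      if (sum(alive) >= params$n_cap) break
      j <- sample.int(length(idx), 1L, prob = lam_i)
      li <- idx[j]
      rs <- which(O[j, ])
      r <- if (length(rs) == 1L) rs else rs[sample.int(length(rs), 1L, prob = rr$lambda_r[rs])]
      if (n_lin == cap) {
        cap <- cap * 2L
        occ <- rbind(occ, matrix(FALSE, cap / 2L, A))
        gain_time <- rbind(gain_time, matrix(NA_real_, cap / 2L, A))
        length(alive) <- cap; alive[is.na(alive)] <- FALSE
        length(parent) <- cap; length(birth) <- cap
        length(death) <- cap
      }
      n_lin <- n_lin + 1L
      occ[n_lin, r] <- TRUE; alive[n_lin] <- TRUE
      parent[n_lin] <- li; birth[n_lin] <- t
      gain_time[n_lin, r] <- t
      log_event(t, "speciation", li, r, n_lin)
    } else if (u < sum(lam_i) + sum(ext_r)) {
      r <- sample.int(A, 1L, prob = ext_r)
      li <- idx[O[, r]][sample.int(N_r[r], 1L)]
      occ[li, r] <- FALSE; gain_time[li, r] <- NA_real_
      log_event(t, "extirpation", li, r)
      if (!any(occ[li, ])) { alive[li] <- FALSE; death[li] <- t }
    } else {
      pairs <- which(reachable, arr.ind = TRUE)
      pick <- pairs[sample.int(nrow(pairs), 1L), ]
      li <- idx[pick[1L]]; r <- pick[2L]
      occ[li, r] <- TRUE; gain_time[li, r] <- t
      log_event(t, "dispersal", li, r)
    }
  }
  tau_eff <- t
  log <- data.frame(time = ev_time[seq_len(lev)], type = ev_type[seq_len(lev)],
                    lineage = ev_lineage[seq_len(lev)], region = ev_region[seq_len(lev)],
                    child = ev_child[seq_len(lev)], stringsAsFactors = FALSE)
  extant <- which(alive[seq_len(n_lin)])
  if (length(extant) < 2L)
    return(list(extinct = TRUE, n_extant = length(extant), event_log = log))
  nwk <- build_reconstructed_newick(parent[seq_len(n_lin)], birth[seq_len(n_lin)],
                                    death[seq_len(n_lin)], tau_eff)
  phy <- ape::read.tree(text = nwk)
  # occupancy: cells of occupied areas (optionally thinned, but every species
  # keeps >= 1 cell per occupied area)
  cells <- names(world$area)
  tips <- paste0("t", extant)
  occm <- matrix(0L, length(cells), length(tips), dimnames = list(cells, tips))
  npp_all <- world$env$npp
  for (j in seq_along(extant)) {
    ar <- which(occ[extant[j], ])
    for (a in ar) {
      in_a <- which(world$area == a)
      p_cell <- if (params$occupancy == "npp") {
        pmin(occupy_prob * npp_all[in_a] / mean(npp_all[in_a]), 1)
      } else rep(occupy_prob, length(in_a))
      takes <- if (occupy_prob >= 1 && params$occupancy == "uniform") in_a else {
        sel <- in_a[stats::runif(length(in_a)) < p_cell]
        if (length(sel) == 0L) sample(in_a, 1L) else sel
      }
      occm[takes, j] <- 1L
    }
  }
  pm <- pam_matrix(occm, world$coords)
  arr <- do.call(rbind, lapply(extant, function(li) {
    ar <- which(occ[li, ])
    data.frame(species = paste0("t", li), region = ar,
               arrival = tau_eff - gain_time[li, ar])
  }))
  tip_lambda <- vapply(extant, function(li) mean(rr$lambda_r[occ[li, ]]), numeric(1))
  names(tip_lambda) <- tips
  structure(list(
    phy = phy, pam = pm, env = world$env, area = world$area,
    truth = list(scenario = params$scenario, tip_lambda = tip_lambda,
                 arrival = arr, lambda_r = rr$lambda_r, K_r = rr$K_r,
                 region_richness = colSums(occ[extant, , drop = FALSE])),
    event_log = log, tau = tau_eff, params = params, extinct = FALSE),
    class = "simulated_clade")
}

# reconstructed (extant-only) tree from lineage records, as a Newick string
build_reconstructed_newick <- function(parent, birth, death, tau) {
  n <- length(parent)
  kids <- vector("list", n)
  for (i in seq_len(n)) if (parent[i] > 0L)
    kids[[parent[i]]] <- c(kids[[parent[i]]], i)
  extant <- is.na(death)
  fmt <- function(x) sprintf("%.10g", x)
  build <- function(l) {
    # returns list(str=, t=) for the surviving subtree rooted on lineage l,
    # or NULL when nothing below survives; t is the time of the subtree root
    cur <- if (extant[l]) list(str = paste0("t", l), t = tau) else NULL
    ks <- kids[[l]]
    if (!is.null(ks)) {
      for (ch in rev(ks[order(birth[ks])])) {    # latest first
        s <- build(ch)
        if (is.null(s)) next
        if (is.null(cur)) cur <- s
        else {
          tk <- birth[ch]
          cur <- list(str = paste0("(", cur$str, ":", fmt(cur$t - tk), ",",
                                   s$str, ":", fmt(s$t - tk), ")"),
                      t = tk)
        }
      }
    }
    cur
  }
  r <- build(1L)
  if (is.null(r)) stop("no extant lineage", call. = FALSE)
  paste0(r$str, ";")
}

#' Replay a simulated clade's event log
#'
#' Applies the logged events from scratch and returns the final ranges and
#' extant count; used to verify internal consistency of the simulator.
#'
#' @param clade a \code{simulated_clade} (or its \code{event_log}).
#' @param A number of areas.
#' @return list: \code{ranges} (list lineage -> occupied areas),
#'   \code{extant} (lineage ids), \code{n_extant}.
#' @export
replay_event_log <- function(clade, A = NULL) {
  log <- if (is.data.frame(clade)) clade else clade$event_log
  if (is.null(A)) A <- length(unique(if (is.data.frame(clade)) log$region else clade$area))
  n <- max(log$lineage, log$child, na.rm = TRUE)
  occ <- matrix(FALSE, n, max(log$region))
  dead <- logical(n)
  for (i in seq_len(nrow(log))) {
    ty <- log$type[i]; li <- log$lineage[i]; r <- log$region[i]
    if (ty == "origin") occ[li, r] <- TRUE
    else if (ty == "speciation") occ[log$child[i], r] <- TRUE
    else if (ty == "dispersal") occ[li, r] <- TRUE
    else if (ty == "extirpation") {
      occ[li, r] <- FALSE
      if (!any(occ[li, ])) dead[li] <- TRUE
    }
  }
  extant <- which(!dead & rowSums(occ) > 0L)
  list(ranges = lapply(seq_len(n), function(i) which(occ[i, ])),
       extant = extant, n_extant = length(extant))
}

#' Export a simulated clade as plain-text files
#'
#' Writes \code{tree.nwk}, \code{pam.csv}, \code{env.csv}, \code{truth.json}
#' in the package's standard formats, re-readable by the core module.
#'
#' @param clade a \code{simulated_clade}.
#' @param dir output directory (created if needed).
#' @export
export_dataset <- function(clade, dir) {
  stopifnot(inherits(clade, "simulated_clade"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_phylogeny(clade$phy, file.path(dir, "tree.nwk"))
  write_pam(clade$pam, file.path(dir, "pam.csv"))
  write_env(clade$env, file.path(dir, "env.csv"))
  truth <- list(scenario = clade$truth$scenario,
                tip_lambda = as.list(clade$truth$tip_lambda),
                lambda_r = clade$truth$lambda_r,
                K_r = clade$truth$K_r,
                region_richness = clade$truth$region_richness,
                arrival = clade$truth$arrival,
                area = as.list(clade$area),
                tau = clade$tau)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate a benchmark suite of simulated clades
#'
#' \code{n_per_scenario} clades per scenario at the default (strong) effect
#' sizes; clades that go extinct or end below \code{min_tips} species
#' (default 50, matching the minimum clade size used in delineation) are
#' redrawn with a fresh seed. Deterministic given \code{seed}.
#'
#' @param n_per_scenario clades per scenario (>= 1).
#' @param seed master seed.
#' @param world optional shared \code{world} (default:
#'   \code{make_world(world_config(seed = seed))}).
#' @param max_tries resampling cap per clade.
#' @return list with \code{clades} (list of \code{simulated_clade}) and
#'   \code{manifest} (data.frame: id, scenario, seed, n_tips, tau).
#' @export
benchmark_suite <- function(n_per_scenario, seed = 1L, world = NULL,
                            min_tips = 50L, max_tries = 50L) {
  stopifnot(n_per_scenario >= 1L)
  if (is.null(world)) world <- make_world(world_config(seed = seed))
  scen <- names(scenario_models())
  clades <- list(); rows <- list()
  counter <- 0L
  for (s in scen) {
    for (i in seq_len(n_per_scenario)) {
      counter <- counter + 1L
      cl <- NULL
      for (try in seq_len(max_tries)) {
        sd_i <- (seed * 10000L + counter * 100L + try) %% .Machine$integer.max
        cand <- simulate_clade(world, scenario_params(s, seed = sd_i), occupy_prob = 0.7)
        if (!isTRUE(cand$extinct) && length(cand$phy$tip.label) >= min_tips) { cl <- cand; break }
      }
      if (is.null(cl)) stop("could not simulate a surviving clade for ", s, call. = FALSE)
      id <- sprintf("%s_%02d", s, i)
      clades[[id]] <- cl
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, scenario = s, seed = cl$params$seed,
        n_tips = length(cl$phy$tip.label), tau = cl$tau)
    }
  }
  list(clades = clades, manifest = do.call(rbind, rows))
}
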