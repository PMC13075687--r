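# Independent oracles used across the suite. Everything here is deliberately
# naive (series expansions, exhaustive enumeration) and shares no code with
# the package's implementation paths.

# matrix exponential by truncated power series
oracle_expm <- function(M, nterm = 80L) {
  P <- diag(nrow(M)); term <- diag(nrow(M))
  for (k in seq_len(nterm)) { term <- term %*% M / k; P <- P + term }
  P
}

# hand-built 2-area DEC generator; states 1={1}, 2={2}, 3={1,2}, 4=null
oracle_Q2 <- function(d, e) {
  rbind(c(-(d + e), 0, d, e),
        c(0, -(d + e), d, e),
        c(e, e, -2 * e, 0),
        c(0, 0, 0, 0))
}

# hand-enumerated cladogenetic outcomes for the 2-area space
oracle_outcomes <- function(s) {
  if (s < 3) return(list(list(l = s, r = s, w = 1)))
  lapply(list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2)),
         function(o) list(l = o[1], r = o[2], w = 1 / 6))
}

# exhaustive log-likelihood of a 2-tip cherry (A:t1, B:t2)
oracle_cherry_loglik <- function(t1, t2, sA, sB, d, e) {
  P1 <- oracle_expm(oracle_Q2(d, e) * t1)
  P2 <- oracle_expm(oracle_Q2(d, e) * t2)
  L <- 0
  for (s in 1:3) for (o in oracle_outcomes(s))
    L <- L + (1 / 3) * o$w * P1[o$l, sA] * P2[o$r, sB]
  log(L)
}

# exhaustive log-likelihood and node marginals of ((A:ta,B:tb):tu, C:tc)
oracle_three_tip <- function(ta, tb, tu, tc, sA, sB, sC, d, e) {
  Q <- oracle_Q2(d, e)
  PA <- oracle_expm(Q * ta); PB <- oracle_expm(Q * tb)
  PU <- oracle_expm(Q * tu); PC <- oracle_expm(Q * tc)
  tot <- 0; mR <- numeric(3); mI <- numeric(3)
  for (sR in 1:3) for (oR in oracle_outcomes(sR))
    for (sI in 1:3) for (oI in oracle_outcomes(sI)) {
      pr <- (1 / 3) * oR$w * PU[oR$l, sI] * PC[oR$r, sC] *
        oI$w * PA[oI$l, sA] * PB[oI$r, sB]
      tot <- tot + pr; mR[sR] <- mR[sR] + pr; mI[sI] <- mI[sI] + pr
    }
  list(loglik = log(tot), root = mR / tot, internal = mI / tot)
}

# tree of m well-separated subtrees (within-depth ~1, stems 100): all
# subtrees attach to the root with equal stems, so every between-group
# patristic distance is ~202 and every within-group one is <= 2
join_subtrees <- function(parts) {
  paste0("(", paste0(unlist(parts), ":100", collapse = ","), ");")
}

make_separated_tree <- function(m, tips_per = 6L, seed = 1L) {
  set.seed(seed)
  parts <- lapply(seq_len(m), function(g) {
    sub <- ape::rcoal(tips_per, tip.label = paste0("g", g, "_", seq_len(tips_per)))
    sub$edge.length <- sub$edge.length / max(ape::node.depth.edgelength(sub))
    gsub(";$", "", ape::write.tree(sub))
  })
  read_phylogeny(join_subtrees(parts))
}

# small PAM fixture: cells x species occupancy with lattice coordinates
make_pam <- function(occ, lat = NULL, lon = NULL) {
  n <- nrow(occ)
  if (is.null(lat)) lat <- seq_len(n)
  if (is.null(lon)) lon <- rep(1, n)
  pam_matrix(occ, data.frame(cell_id = rownames(occ), lat = lat, lon = lon))
}

# population-exact standardized recursive system on p variables:
# coefficients are standardized betas because every variable has unit
# population variance by construction
random_sem_system <- function(p, seed) {
  set.seed(seed)
  vars <- paste0("v", seq_len(p))
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  Sigma <- diag(p)
  psi <- rep(1, p)
  edges <- NULL
  for (j in 2:p) {
    parents <- which(stats::runif(j - 1) < 0.6)
    if (!length(parents)) next
    b <- stats::runif(length(parents), 0.15, 0.5) * sample(c(-1, 1), length(parents), TRUE)
    v <- as.numeric(t(b) %*% Sigma[parents, parents] %*% b)
    if (v > 0.8) b <- b * sqrt(0.8 / v)
    B[j, parents] <- b
    cv <- as.vector(Sigma[seq_len(j - 1), parents, drop = FALSE] %*% b)
    Sigma[j, seq_len(j - 1)] <- cv; Sigma[seq_len(j - 1), j] <- cv
    Sigma[j, j] <- 1
    psi[j] <- 1 - as.numeric(t(b) %*% Sigma[parents, parents] %*% b)
    edges <- rbind(edges, cbind(vars[parents], vars[j]))
  }
  if (is.null(edges)) return(random_sem_system(p, seed + 1000L))
  list(vars = vars, B = B, psi = psi, edges = edges, Sigma = Sigma)
}

simulate_sem_data <- function(sys, n, seed) {
  set.seed(seed)
  p <- length(sys$vars)
  X <- matrix(0, n, p, dimnames = list(NULL, sys$vars))
  for (j in seq_len(p)) {
    mu <- if (any(sys$B[j, ] != 0)) X %*% sys$B[j, ] else rep(0, n)
    X[, j] <- mu + stats::rnorm(n, 0, sqrt(sys$psi[j]))
  }
  as.data.frame(X)
}

# a reconstruction assembled by hand: arrival_time only consumes the tree,
# the argmax ranges, node ages, and tip ranges
hand_recon <- function(phy, argmax, tip_ranges) {
  nt <- length(phy$tip.label)
  depths <- ape::node.depth.edgelength(phy)
  structure(list(argmax = argmax, tip_ranges = tip_ranges,
                 node_ages = max(depths[seq_len(nt)]) - depths,
                 phy = phy),
            class = "dec_reconstruction")
}
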