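#' Geographic range state space for the DEC model
#'
#' All nonempty subsets of \code{A} areas with at most \code{mmax} areas,
#' ordered by range size then by lexicographic bitmask, with the empty
#' (null) range appended last as an absorbing state. Areas are integers
#' 1..A (evoregion labels).
#'
#' @param A number of areas (1..10; capped at 10 to keep the 2^A state space
#'   tractable, mirroring the evoregion cap).
#' @param mmax maximum range size (defaults to A, i.e., unconstrained).
#' @return object of class \code{range_state_space}: list with \code{A},
#'   \code{mmax}, \code{states} (list of sorted integer vectors; last is the
#'   null range \code{integer(0)}), \code{n_states}, \code{null_index}.
#' @export
build_state_space <- function(A, mmax = A) {
  A <- as.integer(A); mmax <- as.integer(mmax)
  if (A < 1L || A > 10L) stop("A must be between 1 and 10", call. = FALSE)
  if (mmax < 1L || mmax > A) stop("mmax must be between 1 and A", call. = FALSE)
  states <- list()
  for (m in seq_len(mmax)) {
    combs <- utils::combn(A, m, simplify = FALSE)
    # order within size by bitmask value
    masks <- vapply(combs, function(s) sum(2^(s - 1L)), numeric(1))
    states <- c(states, combs[order(masks)])
  }
  states <- c(states, list(integer(0)))
  keys <- vapply(states, paste, character(1), collapse = ",")
  structure(list(A = A, mmax = mmax, states = states,
                 n_states = length(states), null_index = length(states),
                 keys = keys), class = "range_state_space")
}

#' @export
print.range_state_space <- function(x, ...) {
  cat("DEC state space:", x$A, "areas, mmax =", x$mmax, "->",
      x$n_states - 1L, "ranges (+ null)\n")
  invisible(x)
}

# index of a range (sorted integer vector) in the state space
state_index <- function(space, range) {
  key <- paste(sort(unique(as.integer(range))), collapse = ",")
  i <- match(key, space$keys)
  if (is.na(i)) stop("range {", key, "} not in state space (check areas/mmax)", call. = FALSE)
  i
}

#' DEC parameters
#'
#' @param d dispersal (range expansion) rate, per area per Ma.
#' @param e local extinction (range contraction) rate, per area per Ma.
#' @export
dec_params <- function(d, e) {
  if (!is.finite(d) || !is.finite(e) || d < 0 || e < 0)
    stop("d and e must be finite and >= 0", call. = FALSE)
  structure(list(d = d, e = e), class = "dec_params")
}

#' Anagenetic DEC rate matrix
#'
#' Along a branch a range R expands to R + {a} (a not in R, |R|+1 <= mmax) at
#' rate d|R| (dispersal from each occupied area), and contracts to R - {a}
#' (a in R) at rate e per area; a single-area range contracts to the
#' absorbing null range (lineage-wide extirpation). Rows sum to zero; the
#' null row is zero. With \code{condition_survival = TRUE} the null
#' transition is removed (single-area ranges cannot contract), the usual
#' conditioning for lineages known to have survived to the present; this
#' mitigates the well-known downward bias of the extirpation estimate that
#' the absorbing null range induces on extant-only trees.
#'
#' @param space a \code{range_state_space}.
#' @param params a \code{dec_params}.
#' @param condition_survival drop the single-area -> null transition.
#' @return square rate matrix over the full state space (null included).
#' @export
anagenetic_Q <- function(space, params, condition_survival = FALSE) {
  n <- space$n_states
  Q <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    R <- space$states[[i]]
    if (length(R) < space$mmax) {
      for (a in setdiff(seq_len(space$A), R))
        Q[i, state_index(space, c(R, a))] <- params$d * length(R)
    }
    if (length(R) > 1L || !condition_survival) {
      for (a in R)
        Q[i, state_index(space, setdiff(R, a))] <- params$e
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probabilities exp(Qt)
#'
#' Matrix exponential of the DEC generator. For repeated use across the
#' branches of a tree, \code{dec_propagator} precomputes the
#' eigendecomposition of Q once so each branch costs only two small matrix
#' products; it falls back to \code{ape::matexpo} when Q is numerically
#' defective.
#'
#' @param Q rate matrix.
#' @param t elapsed time (Ma), >= 0.
#' @export
transition_probs <- function(Q, t) {
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  dec_propagator(Q)(t)
}

#' @rdname transition_probs
#' @export
dec_propagator <- function(Q) {
  n <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  Vinv <- NULL
  if (!is.null(eg)) {
    Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vinv) && rcond(eg$vectors) > 1e-10) use_eigen <- TRUE
  }
  if (use_eigen) {
    V <- eg$vectors; lam <- eg$values
    f <- function(t) {
      P <- Re(V %*% (exp(lam * t) * Vinv))
      P[P < 0] <- 0
      P / rowSums(P)
    }
    # matrix-free actions P(t) v and t(P(t)) v, used by the pruning passes
    attr(f, "apply") <- function(t, v) {
      out <- Re(V %*% (exp(lam * t) * (Vinv %*% v)))
      out[out < 0] <- 0
      out
    }
    attr(f, "tapply") <- function(t, v) {
      out <- Re(t(Vinv) %*% (exp(lam * t) * (t(V) %*% v)))
      out[out < 0] <- 0
      out
    }
    attr(f, "eig") <- list(V = V, lam = lam, Vinv = Vinv)
  } else {
    f <- function(t) {
      P <- ape::matexpo(Q * t)
      P[P < 0] <- 0
      P / rowSums(P)
    }
    attr(f, "apply") <- function(t, v) as.vector(f(t) %*% v)
    attr(f, "tapply") <- function(t, v) as.vector(t(f(t)) %*% v)
  }
  f
}

#' Cladogenetic range-inheritance table
#'
#' At a speciation event a range R is partitioned between the daughters. A
#' single-area range is inherited identically by both. A widespread range
#' splits either by vicariance (one daughter gets one area a, the other the
#' remainder R - {a}; both orderings) or by subset sympatry (one daughter
#' gets a single area a of R, the other the full range R; both orderings).
#' All ordered outcomes receive equal weight summing to 1.
#'
#' @param space a \code{range_state_space}.
#' @param state state index or range (integer vector).
#' @return data.frame with columns \code{left}, \code{right} (state indices)
#'   and \code{weight}.
#' @export
cladogenesis_table <- function(space, state) {
  i <- if (length(state) == 1L && is.numeric(state) && state <= space$n_states &&
           state == round(state) && !is.list(state)) as.integer(state) else state_index(space, state)
  if (i == space$null_index) stop("null range cannot speciate", call. = FALSE)
  R <- space$states[[i]]
  if (length(R) == 1L)
    return(data.frame(left = i, right = i, weight = 1))
  out <- list()
  add <- function(l, r) out[[length(out) + 1L]] <<- c(state_index(space, l), state_index(space, r))
  for (a in R) {
    rem <- setdiff(R, a)
    add(a, rem); add(rem, a)          # vicariance, both orderings
    add(a, R);   add(R, a)            # subset sympatry, both orderings
  }
  m <- unique(do.call(rbind, out))
  data.frame(left = m[, 1], right = m[, 2], weight = rep(1 / nrow(m), nrow(m)))
}

# normalize tip ranges argument to state indices, in phy tip order
tip_state_indices <- function(phy, tip_ranges, space) {
  if (is.null(names(tip_ranges))) stop("tip_ranges must be a named list", call. = FALSE)
  missing <- setdiff(phy$tip.label, names(tip_ranges))
  if (length(missing)) stop("tip_ranges missing species: ",
                            paste(utils::head(missing), collapse = ", "), call. = FALSE)
  idx <- vapply(phy$tip.label, function(l) {
    r <- tip_ranges[[l]]
    if (length(r) == 0L) stop("tip '", l, "' has an empty range", call. = FALSE)
    if (length(r) > space$mmax) stop("tip '", l, "' range exceeds mmax", call. = FALSE)
    state_index(space, r)
  }, integer(1))
  idx
}

# flattened cladogenesis table (s, left, right, w) for a state space; cached
# per (A, mmax) within the session
.clado_cache <- new.env(parent = emptyenv())
clado_flat <- function(space) {
  key <- paste(space$A, space$mmax)
  if (!is.null(.clado_cache[[key]])) return(.clado_cache[[key]])
  n <- space$n_states
  flat <- do.call(rbind, lapply(seq_len(n - 1L), function(s) {
    tb <- cladogenesis_table(space, s)
    cbind(s = s, left = tb$left, right = tb$right, w = tb$weight)
  }))
  .clado_cache[[key]] <- flat
  flat
}

# postorder scaffold of a binary tree: edges, child-edge pairs per parent,
# and "rounds" grouping parents whose children are all ready, so branch
# propagation can be batched into a few matrix products
tree_scaffold <- function(phy) {
  if (!ape::is.binary(phy)) stop("DEC requires a binary tree", call. = FALSE)
  po <- ape::reorder.phylo(phy, "postorder")
  edge <- po$edge; elen <- po$edge.length
  nt <- length(phy$tip.label); nn <- nt + phy$Nnode
  ke1 <- ke2 <- integer(nn)                 # child-edge indices per parent
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]
    if (ke1[p] == 0L) ke1[p] <- k else ke2[p] <- k
  }
  order_parents <- unique(edge[, 1])
  rnd <- integer(nn)
  for (p in order_parents)
    rnd[p] <- max(rnd[edge[ke1[p], 2]], rnd[edge[ke2[p], 2]]) + 1L
  rounds <- split(order_parents, rnd[order_parents])
  list(edge = edge, elen = elen, ke1 = ke1, ke2 = ke2,
       order_parents = order_parents, rounds = rounds,
       nt = nt, nn = nn, root = nt + 1L)
}

# batched propagation of likelihood columns along branches
prop_batch <- function(prop, ts, Dsub) {
  eig <- attr(prop, "eig")
  if (!is.null(eig)) {
    out <- Re(eig$V %*% (exp(outer(eig$lam, ts)) * (eig$Vinv %*% Dsub)))
    out[out < 0] <- 0
    out
  } else {
    for (j in seq_along(ts)) Dsub[, j] <- prop(ts[j]) %*% Dsub[, j]
    Dsub
  }
}

# shared pruning machinery over columns (one per node); returns the total
# log-likelihood and, optionally, the pieces needed for the marginal pass.
dec_prune <- function(sc, tip_idx, space, params, keep_internals = FALSE,
                      condition_survival = FALSE) {
  n <- space$n_states
  nt <- sc$nt; nn <- sc$nn
  prop <- dec_propagator(anagenetic_Q(space, params, condition_survival))
  flat <- clado_flat(space)
  fs <- flat[, "s"]; fl <- flat[, "left"]; fr <- flat[, "right"]; fw <- flat[, "w"]
  D <- matrix(0, n, nn)        # conditional likelihood at node (pre-cladogenesis)
  U <- matrix(0, n, nn)        # likelihood at the top of each node's stem
  logscale <- numeric(nn)
  D[cbind(tip_idx, seq_len(nt))] <- 1
  edge <- sc$edge; elen <- sc$elen
  for (ps in sc$rounds) {
    ke <- c(sc$ke1[ps], sc$ke2[ps])
    chs <- edge[ke, 2]
    U[, chs] <- prop_batch(prop, elen[ke], D[, chs, drop = FALSE])
    for (p in ps) {
      c1 <- edge[sc$ke1[p], 2]; c2 <- edge[sc$ke2[p], 2]
      dp <- numeric(n)
      dp[seq_len(n - 1L)] <- rowsum(fw * U[fl, c1] * U[fr, c2], fs)
      mx <- max(dp)
      if (mx <= 0) return(list(loglik = -Inf))
      D[, p] <- dp / mx
      logscale[p] <- logscale[c1] + logscale[c2] + log(mx)
    }
  }
  root <- sc$root
  pi0 <- c(rep(1 / (n - 1L), n - 1L), 0)
  loglik <- log(sum(pi0 * D[, root])) + logscale[root]
  out <- list(loglik = loglik)
  if (keep_internals) {
    out$D <- D; out$U <- U; out$prop <- prop; out$flat <- flat
    out$pi0 <- pi0; out$sc <- sc
  }
  out
}

#' DEC log-likelihood by pruning
#'
#' Felsenstein pruning over the range state space: conditional likelihoods
#' propagate along branches via exp(Qt) and combine at nodes through the
#' cladogenetic inheritance table; the root is averaged uniformly over the
#' non-null ranges.
#'
#' @param phy binary, rooted \code{phylo} object.
#' @param tip_ranges named list: species -> integer vector of occupied areas.
#' @param params a \code{dec_params}.
#' @param space a \code{range_state_space}; by default built from the areas
#'   present in \code{tip_ranges} with \code{mmax = A}.
#' @param condition_survival use the survival-conditioned generator (see
#'   \code{\link{anagenetic_Q}}).
#' @return log-likelihood (scalar).
#' @export
dec_loglik <- function(phy, tip_ranges, params, space = NULL,
                       condition_survival = FALSE) {
  if (is.null(space)) {
    A <- max(unlist(tip_ranges))
    space <- build_state_space(A)
  }
  tip_idx <- tip_state_indices(phy, tip_ranges, space)
  dec_prune(tree_scaffold(phy), tip_idx, space, params,
            condition_survival = condition_survival)$loglik
}

#' Maximum-likelihood DEC fit
#'
#' Maximizes the pruning log-likelihood over (log d, log e) with bounded
#' quasi-Newton (L-BFGS-B) from three starting points; the best optimum is
#' returned.
#'
#' @inheritParams dec_loglik
#' @param lower,upper bounds on d and e (rates per Ma).
#' @return object of class \code{dec_fit}: \code{params}, \code{loglik},
#'   \code{convergence}, \code{starts} (per-start diagnostics).
#' @export
fit_dec <- function(phy, tip_ranges, space = NULL,
                    lower = 1e-4, upper = 5, condition_survival = FALSE) {
  if (is.null(space)) space <- build_state_space(max(unlist(tip_ranges)))
  tip_idx <- tip_state_indices(phy, tip_ranges, space)
  sc <- tree_scaffold(phy)
  nll <- function(lp) {
    ll <- dec_prune(sc, tip_idx, space, dec_params(exp(lp[1]), exp(lp[2])),
                    condition_survival = condition_survival)$loglik
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- list(log(c(0.01, 0.01)), log(c(0.1, 0.05)), log(c(1, 0.5)))
  fits <- lapply(starts, function(s0)
    tryCatch(stats::optim(s0, nll, method = "L-BFGS-B",
                          lower = log(lower), upper = log(upper),
                          control = list(maxit = 100L, factr = 1e9)),
             error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("DEC optimizer failed from all starts", call. = FALSE)
  vals <- vapply(fits[ok], `[[`, numeric(1), "value")
  best <- fits[ok][[which.min(vals)]]
  if (min(vals) >= 1e10) stop("DEC optimization did not reach a finite likelihood", call. = FALSE)
  structure(list(params = dec_params(exp(best$par[1]), exp(best$par[2])),
                 loglik = -best$value,
                 convergence = best$convergence,
                 starts = lapply(fits[ok], function(f)
                   list(d = exp(f$par[1]), e = exp(f$par[2]), loglik = -f$value))),
            class = "dec_fit")
}

#' @export
print.dec_fit <- function(x, ...) {
  cat(sprintf("DEC fit: d = %.4g, e = %.4g, logL = %.4f\n",
              x$params$d, x$params$e, x$loglik))
  invisible(x)
}

#' Marginal ancestral-range reconstruction
#'
#' Standard up/down passes consistent with \code{\link{dec_loglik}}: the up
#' pass computes conditional likelihoods of the data below each node, the
#' down pass the likelihood of everything outside it; their product,
#' normalized, is the marginal posterior over ranges at each internal node
#' (state immediately before the cladogenetic event).
#'
#' @inheritParams dec_loglik
#' @return object of class \code{dec_reconstruction}: \code{marginal}
#'   (internal nodes x non-null states matrix, rows sum to 1), \code{argmax}
#'   (list: node id -> most probable range), \code{tip_ranges},
#'   \code{node_ages} (Ma before present for all nodes), \code{space},
#'   \code{loglik}.
#' @export
ancestral_ranges <- function(phy, tip_ranges, params, space = NULL,
                             condition_survival = FALSE) {
  if (is.null(space)) space <- build_state_space(max(unlist(tip_ranges)))
  tip_idx <- tip_state_indices(phy, tip_ranges, space)
  sc <- tree_scaffold(phy)
  pr <- dec_prune(sc, tip_idx, space, params, keep_internals = TRUE,
                  condition_survival = condition_survival)
  if (!is.finite(pr$loglik)) stop("zero likelihood; reconstruction undefined", call. = FALSE)
  n <- space$n_states
  nt <- sc$nt; nn <- sc$nn
  O <- matrix(0, n, nn)
  O[, sc$root] <- pr$pi0
  fl <- pr$flat
  # down pass: preorder over internal nodes (reverse of postorder parents)
  for (p in rev(sc$order_parents)) {
    ke <- c(sc$ke1[p], sc$ke2[p])
    ch <- sc$edge[ke, 2]
    for (j in 1:2) {
      cj <- ch[j]; sib <- ch[3L - j]
      M <- numeric(n)
      contrib <- O[fl[, "s"], p] * fl[, "w"] * pr$U[fl[, "right"], sib]
      acc <- rowsum(contrib, fl[, "left"])
      M[as.integer(rownames(acc))] <- acc
      Oc <- as.vector(attr(pr$prop, "tapply")(sc$elen[ke[j]], M))
      mx <- max(Oc)
      O[, cj] <- if (mx > 0) Oc / mx else Oc
    }
  }
  internal <- (nt + 1L):nn
  marg <- t(O[, internal, drop = FALSE] * pr$D[, internal, drop = FALSE])
  marg <- marg[, -space$null_index, drop = FALSE]
  marg <- marg / rowSums(marg)
  rownames(marg) <- internal
  colnames(marg) <- space$keys[-space$null_index]
  argmax <- vector("list", nn)
  for (v in internal) argmax[[v]] <- space$states[[which.max(marg[as.character(v), ])]]
  for (i in seq_len(nt)) argmax[[i]] <- space$states[[tip_idx[i]]]
  depths <- ape::node.depth.edgelength(phy)
  ages <- max(depths[seq_len(nt)]) - depths
  structure(list(marginal = marg, argmax = argmax,
                 tip_ranges = tip_ranges, node_ages = ages,
                 space = space, loglik = pr$loglik, phy = phy),
            class = "dec_reconstruction")
}

#' Simulate geographic ranges under DEC along a tree
#'
#' Forward simulation of the anagenetic (dispersal/extirpation) process and
#' cladogenetic range inheritance down a fixed phylogeny; used to test
#' parameter recovery. Because the fixed tree is the reconstructed tree of
#' extant species, every lineage demonstrably survived: contraction to the
#' null range is disallowed (a single-area lineage keeps its last area),
#' which is the usual fixed-tree conditioning and leaves the per-area
#' extirpation rate of widespread lineages untouched.
#'
#' @inheritParams dec_loglik
#' @param root_range starting range at the root (default: one random area).
#' @param seed integer RNG seed.
#' @return named list: species -> integer vector of areas.
#' @export
simulate_dec_ranges <- function(phy, params, space, root_range = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nt <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  edge <- po$edge; elen <- po$edge.length
  pre <- rev(seq_len(nrow(edge)))   # preorder over edges
  evolve_branch <- function(r, tmax) {
    t <- 0
    repeat {
      addable <- if (length(r) < space$mmax) setdiff(seq_len(space$A), r) else integer(0)
      rate_gain <- params$d * length(r) * length(addable)
      rate_loss <- if (length(r) > 1L) params$e * length(r) else 0
      total <- rate_gain + rate_loss
      if (total <= 0) return(r)
      t <- t + stats::rexp(1L, total)
      if (t >= tmax) return(r)
      if (stats::runif(1L) < rate_gain / total) {
        r <- sort(c(r, sample(addable, 1L)))
      } else {
        r <- setdiff(r, sample(r, 1L))
      }
    }
  }
  state <- vector("list", nt + phy$Nnode)
  root <- nt + 1L
  state[[root]] <- if (is.null(root_range)) sample.int(space$A, 1L) else root_range
  daughter <- vector("list", nt + phy$Nnode)
  for (k in pre) {
    parent <- edge[k, 1]; child <- edge[k, 2]
    if (is.null(daughter[[parent]])) {
      tb <- cladogenesis_table(space, state[[parent]])
      o <- tb[sample.int(nrow(tb), 1L, prob = tb$weight), ]
      daughter[[parent]] <- list(space$states[[o$left]], space$states[[o$right]],
                                 next_slot = 1L)
    }
    slot <- daughter[[parent]]$next_slot
    daughter[[parent]]$next_slot <- slot + 1L
    state[[child]] <- evolve_branch(daughter[[parent]][[slot]], elen[k])
  }
  out <- state[seq_len(nt)]
  names(out) <- phy$tip.label
  out
}
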