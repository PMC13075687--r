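#' Specify a recursive path model
#'
#' A directed acyclic graph over observed variables. Variables with incoming
#' edges are endogenous; each is regressed on its parents, which for a
#' recursive model with uncorrelated errors is the maximum-likelihood
#' solution.
#'
#' @param edges two-column matrix or data.frame (from, to) of variable names.
#' @param vars optional variable ordering (defaults to the order of first
#'   appearance).
#' @return object of class \code{path_model}.
#' @export
path_model <- function(edges, vars = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  names(edges) <- c("from", "to")
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  if (is.null(vars)) vars <- unique(c(edges$from, edges$to))
  stopifnot(all(c(edges$from, edges$to) %in% vars))
  if (any(edges$from == edges$to)) stop("self-loop in path model", call. = FALSE)
  # acyclicity check (Kahn's algorithm)
  remaining <- edges
  pool <- vars
  while (length(pool)) {
    srcs <- setdiff(pool, unique(remaining$to))
    if (!length(srcs)) stop("path model is cyclic", call. = FALSE)
    pool <- setdiff(pool, srcs)
    remaining <- remaining[!(remaining$from %in% srcs), , drop = FALSE]
  }
  endo <- unique(edges$to)
  structure(list(vars = vars, edges = edges,
                 endogenous = endo, exogenous = setdiff(vars, endo)),
            class = "path_model")
}

#' @export
print.path_model <- function(x, ...) {
  cat("Path model:", length(x$vars), "variables,", nrow(x$edges), "edges\n")
  for (i in seq_len(nrow(x$edges)))
    cat(" ", x$edges$from[i], "->", x$edges$to[i], "\n")
  invisible(x)
}

#' Assemble the per-cell variable table
#'
#' Joins per-cell richness, environment, assemblage age, and median DR;
#' drops cells with zero richness (lnS undefined) or missing age/rate;
#' natural-log transforms richness and z-scores every predictor so path
#' coefficients are comparable across edges.
#'
#' @param richness named per-cell richness (from
#'   \code{\link{richness_per_cell}}).
#' @param env environment data.frame (cell_id, temperature, precipitation,
#'   npp).
#' @param ages named per-cell assemblage age (Ma).
#' @param rates named per-cell median DR.
#' @param coords optional data.frame (cell_id, lat, lon); when given,
#'   z-scored \code{lat}/\code{lon} columns are added for the spatial
#'   sensitivity refit.
#' @param min_cells minimum retained cells (default 30).
#' @return data.frame of class \code{variable_table} with columns
#'   \code{cell_id, lnS, temperature, precipitation, npp, age, dr} (and
#'   optionally \code{lat, lon}); attribute \code{dropped} counts excluded
#'   cells.
#' @export
prepare_variables <- function(richness, env, ages, rates, coords = NULL,
                              min_cells = 30L) {
  cells <- names(richness)
  idx <- match(cells, env$cell_id)
  if (anyNA(idx)) stop("environment table missing cells", call. = FALSE)
  df <- data.frame(cell_id = cells,
                   lnS = NA_real_,
                   temperature = env$temperature[idx],
                   precipitation = env$precipitation[idx],
                   npp = env$npp[idx],
                   age = as.numeric(ages[cells]),
                   dr = as.numeric(rates[cells]),
                   stringsAsFactors = FALSE)
  keep <- richness > 0 & !is.na(df$age) & !is.na(df$dr) &
    stats::complete.cases(df[, c("temperature", "precipitation", "npp")])
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < min_cells)
    stop("insufficient cells: ", nrow(df), " retained (< ", min_cells, ")", call. = FALSE)
  df$lnS <- log(richness[keep])
  zs <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("constant predictor cannot be z-scored", call. = FALSE)
    (v - mean(v)) / s
  }
  for (v in c("temperature", "precipitation", "npp", "age", "dr")) df[[v]] <- zs(df[[v]])
  if (!is.null(coords)) {
    j <- match(df$cell_id, coords$cell_id)
    if (anyNA(j)) stop("coords missing cells", call. = FALSE)
    df$lat <- zs(coords$lat[j]); df$lon <- zs(coords$lon[j])
    attr(df, "raw_coords") <- coords[j, c("lat", "lon")]
  }
  rownames(df) <- NULL
  attr(df, "dropped") <- dropped
  class(df) <- c("variable_table", "data.frame")
  df
}

#' Fit a recursive path model
#'
#' Each endogenous variable is regressed by least squares on its parents (the
#' ML solution for recursive models with uncorrelated errors). The implied
#' covariance Sigma(theta) = (I-B)^-1 Psi (I-B)^-T is compared with the
#' sample covariance S through the normal-theory discrepancy F_ML = ln|Sigma|
#' + tr(S Sigma^-1) - ln|S| - p and T = (n-1) F_ML, from which fit indices
#' and information criteria follow. Coefficients are reported standardized
#' (beta), using model-implied standard deviations.
#'
#' @param model a \code{path_model}.
#' @param table a \code{variable_table} (or data.frame containing the model's
#'   variables).
#' @return object of class \code{path_fit}: \code{beta} (standardized
#'   coefficient matrix, \code{beta[to, from]}), \code{B} (unstandardized),
#'   \code{psi}, \code{sigma} (implied covariance), \code{S}, \code{r2},
#'   \code{loglik}, \code{T}, \code{df}, \code{cfi}, \code{tli},
#'   \code{rmsea}, \code{srmr}, \code{aic}, \code{bic}, \code{q}, \code{n},
#'   \code{residuals} (cells x endogenous), \code{model}.
#' @export
fit_path_model <- function(model, table) {
  stopifnot(inherits(model, "path_model"))
  vars <- model$vars
  miss <- setdiff(vars, names(table))
  if (length(miss)) stop("table missing variables: ", paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(as.data.frame(table)[, vars, drop = FALSE])
  n <- nrow(X); p <- length(vars)
  S <- stats::cov(X)                         # unbiased sample covariance
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  Psi <- matrix(0, p, p, dimnames = list(vars, vars))
  resid <- matrix(NA_real_, n, length(model$endogenous),
                  dimnames = list(NULL, model$endogenous))
  for (y in model$endogenous) {
    parents <- model$edges$from[model$edges$to == y]
    Xp <- X[, parents, drop = FALSE]
    qrx <- qr(cbind(1, Xp))
    if (qrx$rank < ncol(Xp) + 1L)
      stop("singular design for '", y, "': collinear parents {",
           paste(parents, collapse = ", "), "}", call. = FALSE)
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xp), X[, y])
    B[y, parents] <- fit$coefficients[parents]
    resid[, y] <- fit$residuals
    Psi[y, y] <- sum(fit$residuals^2) / (n - 1)
  }
  exo <- model$exogenous
  Psi[exo, exo] <- S[exo, exo, drop = FALSE]
  IB <- solve(diag(p) - B)
  Sigma <- IB %*% Psi %*% t(IB)
  dimnames(Sigma) <- list(vars, vars)
  sds <- sqrt(diag(Sigma))
  beta <- B * outer(1 / sds, sds)            # beta[to,from] = B * sd(from)/sd(to)
  r2 <- 1 - diag(Psi)[model$endogenous] / diag(Sigma)[model$endogenous]
  ldS <- determinant(S, logarithm = TRUE)$modulus
  ldSig <- determinant(Sigma, logarithm = TRUE)$modulus
  F_ml <- as.numeric(ldSig + sum(diag(S %*% solve(Sigma))) - ldS - p)
  T_stat <- (n - 1) * max(F_ml, 0)
  q <- nrow(model$edges) + length(model$endogenous) +
    length(exo) + choose(length(exo), 2L)
  df <- p * (p + 1) / 2 - q
  if (df < 0) stop("negative degrees of freedom: model not identified", call. = FALSE)
  loglik <- -((n - 1) / 2) * (as.numeric(ldSig) + sum(diag(S %*% solve(Sigma))) + p * log(2 * pi))
  # baseline (independence) model for incremental indices
  ldSb <- sum(log(diag(S)))
  T_b <- (n - 1) * max(ldSb - as.numeric(ldS), 0)
  df_b <- p * (p - 1) / 2
  idx <- fit_indices(T_stat, df, T_b, df_b, n)
  Dst <- stats::cov2cor(S) - Sigma / outer(sqrt(diag(S)), sqrt(diag(S)))
  srmr <- sqrt(mean(Dst[upper.tri(Dst, diag = TRUE)]^2))
  ic <- information_criteria(loglik, q, n)
  structure(list(beta = beta, B = B, psi = Psi, sigma = Sigma, S = S,
                 r2 = r2, loglik = loglik, T = T_stat, df = df,
                 cfi = idx$cfi, tli = idx$tli, rmsea = idx$rmsea, srmr = srmr,
                 aic = ic$aic, bic = ic$bic, q = q, n = n,
                 T_baseline = T_b, df_baseline = df_b,
                 residuals = resid, model = model),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("Path fit: n = %d, T = %.3f (df = %d), CFI = %.3f, RMSEA = %.3f, SRMR = %.4f\n",
              x$n, x$T, x$df, x$cfi, x$rmsea, x$srmr))
  cat(sprintf("  logL = %.2f, AIC = %.2f, BIC = %.2f\n", x$loglik, x$aic, x$bic))
  ed <- x$model$edges
  for (i in seq_len(nrow(ed)))
    cat(sprintf("  %s -> %s: beta = %+.3f\n", ed$from[i], ed$to[i], x$beta[ed$to[i], ed$from[i]]))
  invisible(x)
}

#' Goodness-of-fit indices from discrepancy statistics
#'
#' CFI = 1 - max(T-df,0)/max(T_b-df_b, T-df, 0);
#' TLI = ((T_b/df_b)-(T/df)) / ((T_b/df_b)-1);
#' RMSEA = sqrt(max(T-df,0) / (df (n-1))).
#'
#' @param T,df model discrepancy and degrees of freedom.
#' @param T_baseline,df_baseline independence-model values.
#' @param n sample size.
#' @return list with \code{cfi}, \code{tli}, \code{rmsea}, and
#'   \code{defined} (FALSE when the baseline fits no worse than its df).
#' @export
fit_indices <- function(T, df, T_baseline, df_baseline, n) {
  if (df <= 0) {
    # saturated model: perfect fit by construction
    return(list(cfi = 1, tli = 1, rmsea = 0, defined = TRUE))
  }
  defined <- T_baseline > df_baseline
  num <- max(T - df, 0)
  den <- max(T_baseline - df_baseline, T - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  rb <- T_baseline / df_baseline
  tli <- if (!defined) NA_real_ else (rb - T / df) / (rb - 1)
  rmsea <- sqrt(max(T - df, 0) / (df * (n - 1)))
  list(cfi = cfi, tli = tli, rmsea = rmsea, defined = defined)
}

#' Information criteria
#'
#' AIC = -2 logL + 2q; BIC = -2 logL + q ln(n).
#'
#' @param loglik model log-likelihood.
#' @param q number of free parameters (>= 1).
#' @param n sample size (>= 2).
#' @export
information_criteria <- function(loglik, q, n) {
  stopifnot(q >= 1, n >= 2)
  list(aic = -2 * loglik + 2 * q, bic = -2 * loglik + q * log(n))
}

# enumerate all directed paths from 'from' to 'to' in the model; returns list
# of character vectors of visited nodes (including endpoints)
enumerate_paths <- function(model, from, to) {
  out <- list()
  walk <- function(node, path) {
    if (node == to) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    nxt <- model$edges$to[model$edges$from == node]
    for (v in nxt) walk(v, c(path, v))
  }
  walk(from, from)
  out
}

#' Direct/indirect effect decomposition
#'
#' The direct effect of a predictor on the response is its standardized path
#' coefficient; each indirect effect is the product of standardized
#' coefficients along a directed path. Indirect paths are grouped by the
#' mediator whose edge enters the response (via productivity, via assemblage
#' age, via DR), so the classes partition the indirect paths and
#' direct + indirect classes = total exactly.
#'
#' @param fit a \code{path_fit}.
#' @param response response variable (default \code{"lnS"}).
#' @param mediators named classes: class label -> mediator variable.
#' @return data.frame, one row per predictor: \code{direct}, one column per
#'   indirect class, \code{indirect_other}, \code{total}.
#' @export
effect_decomposition <- function(fit, response = "lnS",
                                 mediators = c(via_npp = "npp", via_age = "age", via_dr = "dr")) {
  model <- fit$model
  if (!(response %in% model$endogenous)) stop("'", response, "' is not endogenous", call. = FALSE)
  preds <- setdiff(model$vars, response)
  classes <- names(mediators)
  res <- data.frame(predictor = preds, direct = 0)
  for (cl in classes) res[[cl]] <- 0
  res$indirect_other <- 0
  for (i in seq_along(preds)) {
    paths <- enumerate_paths(model, preds[i], response)
    for (pth in paths) {
      b <- 1
      for (k in seq_len(length(pth) - 1L)) b <- b * fit$beta[pth[k + 1L], pth[k]]
      if (length(pth) == 2L) {
        res$direct[i] <- res$direct[i] + b
      } else {
        last_mediator <- pth[length(pth) - 1L]
        cl <- classes[match(last_mediator, mediators)]
        if (is.na(cl)) res$indirect_other[i] <- res$indirect_other[i] + b
        else res[[cl]][i] <- res[[cl]][i] + b
      }
    }
  }
  res$total <- res$direct + rowSums(res[, c(classes, "indirect_other"), drop = FALSE])
  res
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j) from regressing predictor j on the other
#' predictors; values below 5 are conventionally taken as unproblematic.
#'
#' @param table data.frame of predictors.
#' @param predictors character vector (>= 2) of column names.
#' @return named numeric vector (Inf for perfectly collinear predictors).
#' @export
vif <- function(table, predictors) {
  if (length(predictors) < 2L) stop("need at least 2 predictors", call. = FALSE)
  X <- as.matrix(as.data.frame(table)[, predictors, drop = FALSE])
  out <- stats::setNames(numeric(length(predictors)), predictors)
  for (j in seq_along(predictors)) {
    y <- X[, j]; Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- stats::lm.fit(Z, y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Spatial weights for Moran's I
#'
#' @param coords two-column matrix/data.frame of coordinates.
#' @param scheme \code{"knn"} (row-standardized k-nearest-neighbour, the
#'   default) or \code{"rook"} (lattice contiguity: unit-step neighbours in
#'   exactly one coordinate).
#' @param k number of neighbours for \code{"knn"}.
#' @export
spatial_weights <- function(coords, scheme = c("knn", "rook"), k = 8L) {
  scheme <- match.arg(scheme)
  xy <- as.matrix(coords)
  n <- nrow(xy)
  W <- matrix(0, n, n)
  if (scheme == "knn") {
    D <- as.matrix(stats::dist(xy))
    diag(D) <- Inf
    k <- min(k, n - 1L)
    for (i in seq_len(n)) W[i, order(D[i, ])[seq_len(k)]] <- 1
    W <- W / rowSums(W)
  } else {
    dx <- abs(outer(xy[, 1], xy[, 1], "-"))
    dy <- abs(outer(xy[, 2], xy[, 2], "-"))
    step_x <- min(dx[dx > 0]); step_y <- min(dy[dy > 0])
    W[(abs(dx - step_x) < 1e-9 & dy < 1e-9) | (dx < 1e-9 & abs(dy - step_y) < 1e-9)] <- 1
  }
  W
}

#' Moran's I spatial autocorrelation
#'
#' I = (n / sum(w)) * sum_ij w_ij z_i z_j / sum_i z_i^2 with z the centred
#' values. Used on per-equation residuals to diagnose residual spatial
#' structure the model does not absorb.
#'
#' @param values numeric vector (>= 4, nonconstant).
#' @param coords coordinates (n x 2), ignored if \code{weights} is a matrix.
#' @param weights \code{"knn"} (default), \code{"rook"}, or an n x n weight
#'   matrix.
#' @param k neighbours for the knn scheme.
#' @export
morans_i <- function(values, coords = NULL, weights = "knn", k = 8L) {
  n <- length(values)
  if (n < 4L) stop("need at least 4 locations", call. = FALSE)
  if (stats::sd(values) == 0) stop("zero variance in values", call. = FALSE)
  W <- if (is.matrix(weights)) weights else spatial_weights(coords, weights, k = k)
  diag(W) <- 0
  z <- values - mean(values)
  (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
}

#' Add latitude/longitude as exogenous covariates
#'
#' The spatial sensitivity refit: latitude and longitude (z-scored) become
#' exogenous parents of every endogenous variable, absorbing broad-scale
#' spatial trends.
#'
#' @param model a \code{path_model}.
#' @export
with_spatial_covariates <- function(model) {
  extra <- expand.grid(from = c("lat", "lon"), to = model$endogenous,
                       stringsAsFactors = FALSE)
  path_model(rbind(model$edges, extra), vars = unique(c(model$vars, "lat", "lon")))
}

#' Read / write a path model as JSON
#'
#' The JSON layout is \code{{"vars": [...], "edges": [[from, to], ...]}}, so
#' alternative scenario edge sets can be swapped in without code changes.
#'
#' @param path JSON file.
#' @export
read_path_model <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- matrix(unlist(spec$edges), ncol = 2, byrow = !is.matrix(spec$edges))
  if (is.matrix(spec$edges)) edges <- spec$edges
  path_model(edges, vars = spec$vars)
}

#' @rdname read_path_model
#' @param model a \code{path_model}.
#' @export
write_path_model <- function(model, path) {
  stopifnot(inherits(model, "path_model"))
  jsonlite::write_json(list(vars = model$vars,
                            edges = unname(as.matrix(model$edges))),
                       path, auto_unbox = FALSE)
  invisible(path)
}
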