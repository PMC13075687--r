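# Scenario-specific path models and information-criterion model selection.

#' The full integrative path model
#'
#' Temperature and precipitation drive productivity; climate and productivity
#' drive assemblage age and DR; richness (lnS) receives direct paths from all
#' five predictors. This encodes every hypothesized causal chain at once:
#' climate can reach richness directly, via productivity, via evolutionary
#' time, or via speciation rate, and productivity can also act via time or
#' rate. 13 edges in total.
#'
#' @return a \code{path_model} over
#'   \{temperature, precipitation, npp, age, dr, lnS\}.
#' @export
full_model <- function() {
  e <- rbind(
    c("temperature", "npp"), c("precipitation", "npp"),
    c("temperature", "age"), c("precipitation", "age"), c("npp", "age"),
    c("temperature", "dr"),  c("precipitation", "dr"),  c("npp", "dr"),
    c("temperature", "lnS"), c("precipitation", "lnS"), c("npp", "lnS"),
    c("age", "lnS"), c("dr", "lnS"))
  path_model(e, vars = c("temperature", "precipitation", "npp", "age", "dr", "lnS"))
}

#' The four scenario-specific reduced models
#'
#' Each retains only the pathways predicted to dominate under one
#' richness-generating scenario:
#' \describe{
#'   \item{stable_persistence}{equilibrium richness set by energy:
#'     productivity has the direct effect on richness (climate acts only
#'     through productivity).}
#'   \item{speciation_balance}{equilibrium richness set by speciation:
#'     climate and productivity drive DR, DR drives richness.}
#'   \item{historical_legacy}{nonequilibrium, time-limited richness:
#'     climate and productivity structure assemblage age, age drives
#'     richness.}
#'   \item{cradles_of_diversity}{nonequilibrium, rate-driven richness:
#'     climate and productivity drive DR; richness reflects both DR and the
#'     time available (age), the additive linearization of richness ~ age x
#'     rate.}
#' }
#' Direct climate -> richness edges are excluded by default (they are the
#' comparatively weak pathways under every scenario); pass custom edge sets
#' to \code{\link{select_scenario}} to change that.
#'
#' @return named list of four \code{path_model}s.
#' @export
scenario_models <- function() {
  base <- rbind(c("temperature", "npp"), c("precipitation", "npp"))
  clim_dr <- rbind(c("temperature", "dr"), c("precipitation", "dr"), c("npp", "dr"))
  clim_age <- rbind(c("temperature", "age"), c("precipitation", "age"), c("npp", "age"))
  # every model spans the same six observed variables (variables outside the
  # scenario's pathways stay as free exogenous terms), so the covariance
  # likelihoods -- hence AIC/BIC -- are comparable across scenarios
  vars <- c("temperature", "precipitation", "npp", "age", "dr", "lnS")
  list(
    stable_persistence = path_model(rbind(base, c("npp", "lnS")), vars = vars),
    speciation_balance = path_model(rbind(base, clim_dr, c("dr", "lnS")), vars = vars),
    historical_legacy = path_model(rbind(base, clim_age, c("age", "lnS")), vars = vars),
    cradles_of_diversity = path_model(rbind(base, clim_dr, c("dr", "lnS"), c("age", "lnS")),
                                      vars = vars)
  )
}

#' Select the best-supported scenario for one clade
#'
#' Fits the four reduced models to the clade's variable table and ranks them
#' by AIC and by BIC; the scenario with the lowest criterion wins. Ties are
#' broken by fewer free parameters, then by the fixed name order of
#' \code{\link{scenario_models}}.
#'
#' @param table a \code{variable_table}.
#' @param models optional named list of \code{path_model}s (defaults to
#'   \code{\link{scenario_models}}).
#' @return object of class \code{scenario_support}: data.frame \code{table}
#'   (scenario, aic, bic, delta_aic, delta_bic, q), \code{winner_aic},
#'   \code{winner_bic}, \code{fits}.
#' @export
select_scenario <- function(table, models = scenario_models()) {
  fits <- list()
  for (nm in names(models)) {
    fits[[nm]] <- tryCatch(fit_path_model(models[[nm]], table),
                           error = function(e) {
                             warning("scenario '", nm, "' unfittable: ", conditionMessage(e))
                             NULL
                           })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("no scenario model could be fitted", call. = FALSE)
  tab <- data.frame(scenario = names(fits)[ok],
                    aic = vapply(fits[ok], `[[`, numeric(1), "aic"),
                    bic = vapply(fits[ok], `[[`, numeric(1), "bic"),
                    q = vapply(fits[ok], `[[`, numeric(1), "q"),
                    row.names = NULL)
  pick <- function(crit) {
    o <- order(tab[[crit]], tab$q, match(tab$scenario, names(models)))
    tab$scenario[o[1]]
  }
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab$delta_bic <- tab$bic - min(tab$bic)
  structure(list(table = tab, winner_aic = pick("aic"), winner_bic = pick("bic"),
                 fits = fits[ok]), class = "scenario_support")
}

#' @export
print.scenario_support <- function(x, ...) {
  cat("Scenario support (winner by AIC:", x$winner_aic,
      "; by BIC:", x$winner_bic, ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Tally scenario support across clades
#'
#' @param supports list of \code{scenario_support} objects (one per clade).
#' @param scenarios scenario names defining the tally order.
#' @return data.frame: scenario, n_aic, prop_aic, n_bic, prop_bic.
#' @export
tally_support <- function(supports, scenarios = names(scenario_models())) {
  if (length(supports) == 0L) stop("no clades to tally", call. = FALSE)
  wa <- vapply(supports, `[[`, character(1), "winner_aic")
  wb <- vapply(supports, `[[`, character(1), "winner_bic")
  data.frame(scenario = scenarios,
             n_aic = as.integer(table(factor(wa, levels = scenarios))),
             prop_aic = as.numeric(table(factor(wa, levels = scenarios))) / length(wa),
             n_bic = as.integer(table(factor(wb, levels = scenarios))),
             prop_bic = as.numeric(table(factor(wb, levels = scenarios))) / length(wb))
}

#' Regress per-clade effect sizes on clade traits
#'
#' Ordinary least-squares regressions relating clade-level traits (crown age,
#' thermal physiology 0/1, species diversity, geographic extent) to the
#' strengths of direct standardized effects estimated per clade, one
#' regression per (trait, effect) pair.
#'
#' @param effects data.frame, one row per clade, one column per direct
#'   effect (e.g., \code{beta_npp}, \code{beta_age}, ...).
#' @param traits data.frame, one row per clade (same order), columns are
#'   traits.
#' @return data.frame: trait, effect, slope, intercept, p_value, r2, n.
#' @export
clade_trait_effects <- function(effects, traits) {
  if (nrow(effects) != nrow(traits)) stop("effects and traits must have one row per clade", call. = FALSE)
  if (nrow(effects) < 3L) stop("need at least 3 clades", call. = FALSE)
  out <- list()
  for (tr in names(traits)) {
    x <- traits[[tr]]
    if (!is.numeric(x)) x <- as.numeric(as.factor(x)) - 1
    if (stats::sd(x) == 0) stop("constant trait '", tr, "'", call. = FALSE)
    for (ef in names(effects)) {
      y <- effects[[ef]]
      fit <- stats::lm(y ~ x)
      sm <- summary(fit)
      out[[length(out) + 1L]] <- data.frame(
        trait = tr, effect = ef,
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        p_value = sm$coefficients[2, 4],
        r2 = sm$r.squared,
        n = length(y))
    }
  }
  do.call(rbind, out)
}
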