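# Cross-species synthesis: do the per-species exposure coefficients differ
# between dietary exposure groups, and do they track diet composition?

#' Kruskal-Wallis rank test across exposure groups
#'
#' Standard tie-corrected Kruskal-Wallis H with its chi-squared
#' approximation (k - 1 degrees of freedom). For very small samples an
#' exhaustive permutation p-value over all assignments of observations to
#' the group sizes is available instead of the chi-squared tail.
#'
#' @param values Numeric vector (e.g. per-species exposure coefficients).
#' @param groups Grouping vector, at least two non-empty groups.
#' @param exact Use the exhaustive permutation null for the p-value
#'   (feasible for about n <= 10).
#' @return List `statistic` (H), `df`, `p`, `method`.
#' @export
kruskal_wallis <- function(values, groups, exact = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) == 0L)) stop("every group must be non-empty", call. = FALSE)
  kt <- stats::kruskal.test(values, groups)
  out <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
              p = kt$p.value, method = "chi-squared")
  if (exact) {
    if (length(values) > 10L) {
      stop("exact permutation reference is limited to n <= 10", call. = FALSE)
    }
    perms <- group_assignments(as.integer(table(groups)))
    h_all <- vapply(perms, function(g) {
      unname(stats::kruskal.test(values, factor(g))$statistic)
    }, numeric(1))
    out$p <- mean(h_all >= out$statistic - 1e-12)
    out$method <- "exact permutation"
  }
  out
}

# All distinct assignments of n observations to groups of the given sizes,
# each returned as an integer group-label vector of length n.
group_assignments <- function(sizes) {
  n <- sum(sizes)
  assign_rec <- function(free, sizes, label) {
    if (length(sizes) == 1L) {
      v <- stats::setNames(rep(label, length(free)), free)
      return(list(v))
    }
    out <- list()
    for (p in utils::combn(free, sizes[1], simplify = FALSE)) {
      head <- stats::setNames(rep(label, length(p)), p)
      for (r in assign_rec(setdiff(free, p), sizes[-1], label + 1L)) {
        out[[length(out) + 1L]] <- c(head, r)
      }
    }
    out
  }
  lapply(assign_rec(seq_len(n), sizes, 1L),
         function(v) unname(v[as.character(seq_len(n))]))
}

#' Inverse-variance weighted linear regression of effect sizes
#'
#' Weighted least squares of per-species coefficients on a predictor, with
#' weights `1 / se^2` (the standard reading of weighting estimates by their
#' standard errors; `1 / se` is available since that reading is also used
#' in practice). Reports the slope, intercept, adjusted R-squared and the
#' F test on (1, n - 2) degrees of freedom from the weighted sums of
#' squares — the same summary an `lm(weights = )` fit prints.
#'
#' @param x Predictor (length >= 3, not constant).
#' @param y Effect estimates.
#' @param se Standard errors of `y` (> 0).
#' @param weighting `"inverse_variance"` (default) or `"inverse_se"`.
#' @return List `slope`, `intercept`, `adj_r_squared`, `f_statistic`,
#'   `df1`, `df2`, `p`, `n`.
#' @export
weighted_linear_regression <- function(x, y, se,
                                       weighting = c("inverse_variance",
                                                     "inverse_se")) {
  weighting <- match.arg(weighting)
  if (length(x) != length(y) || length(y) != length(se)) {
    stop("x, y and se must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (any(se <= 0)) stop("standard errors must be positive", call. = FALSE)
  if (stats::var(x) == 0) stop("predictor is constant", call. = FALSE)
  w <- if (weighting == "inverse_variance") 1 / se^2 else 1 / se
  fit <- stats::lm(y ~ x, weights = w)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[["x"]]),
       intercept = unname(stats::coef(fit)[["(Intercept)"]]),
       adj_r_squared = sm$adj.r.squared,
       f_statistic = unname(sm$fstatistic[["value"]]),
       df1 = unname(sm$fstatistic[["numdf"]]),
       df2 = unname(sm$fstatistic[["dendf"]]),
       p = unname(stats::pf(sm$fstatistic[["value"]], sm$fstatistic[["numdf"]],
                            sm$fstatistic[["dendf"]], lower.tail = FALSE)),
       n = length(x))
}

#' Cross-species synthesis of exposure coefficients
#'
#' Runs the Kruskal-Wallis comparison of per-species exposure coefficients
#' across dietary exposure groups, then one weighted regression of the
#' coefficient per available predictor (life-stage diet proportions and,
#' when present, an external population trend). Species missing a predictor
#' are dropped from that regression only — the reported degrees of freedom
#' make the sample composition auditable.
#'
#' @param effects Data frame with columns `species`, `beta1_hat`, `se`,
#'   `exposure_group`, and any of `prop_breeding`, `prop_nonbreeding`,
#'   `prop_chick`, `external_trend`.
#' @param weighting Passed to [weighted_linear_regression()].
#' @return A `synthesis_result` list: `kw` (statistic, df, p),
#'   `regressions` (one entry per predictor), `n_species`.
#' @export
synthesize_species <- function(effects, weighting = "inverse_variance") {
  check_columns(effects, c("species", "beta1_hat", "se", "exposure_group"),
                "effects")
  if (all(is.na(effects$beta1_hat))) stop("all effect estimates missing", call. = FALSE)
  effects <- effects[!is.na(effects$beta1_hat), ]
  if (any(effects$se <= 0, na.rm = TRUE)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  kw <- kruskal_wallis(effects$beta1_hat, effects$exposure_group)

  predictors <- intersect(c("prop_breeding", "prop_nonbreeding", "prop_chick",
                            "external_trend"), names(effects))
  regressions <- list()
  for (p in predictors) {
    ok <- !is.na(effects[[p]])
    if (sum(ok) < 3L) next
    regressions[[p]] <- weighted_linear_regression(
      effects[[p]][ok], effects$beta1_hat[ok], effects$se[ok],
      weighting = weighting)
  }
  structure(list(kw = kw, regressions = regressions,
                 n_species = nrow(effects)),
            class = "synthesis_result")
}

#' Render a synthesis result as a markdown report
#'
#' @param result A [synthesize_species()] result.
#' @return Character vector of report lines.
#' @export
format_synthesis_report <- function(result) {
  stopifnot(inherits(result, "synthesis_result"))
  lines <- c("# Cross-species synthesis", "",
             sprintf("Species included: %d", result$n_species), "",
             "## Exposure-group comparison (Kruskal-Wallis)",
             sprintf("chi-squared = %.3g, df = %d, p = %.3g",
                     result$kw$statistic, result$kw$df, result$kw$p), "")
  if (length(result$regressions) > 0L) {
    lines <- c(lines, "## Weighted regressions of the exposure coefficient", "")
    for (nm in names(result$regressions)) {
      r <- result$regressions[[nm]]
      lines <- c(lines, sprintf(
        "- %s: slope = %.4g, adj. R^2 = %.3g, F(%d, %d) = %.3g, p = %.3g (n = %d)",
        nm, r$slope, r$adj_r_squared, r$df1, r$df2, r$f_statistic, r$p, r$n))
    }
  }
  lines
}
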