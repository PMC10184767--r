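#' Prepare a trial table for model fitting
#'
#' Coerces the treatment columns to factors with the declared level sets
#' (viscosity 1/40 cP, light/dark, intact/blocked) and the fish id to a
#' factor.
#'
#' @param table data.frame of trial kinematics (one row per trial).
#' @return the table with factor columns.
#' @export
as_trial_table <- function(table) {
  tab <- as.data.frame(table)
  need <- c("fish_id", "viscosity", "light", "lateral_line")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("trial table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(tab$viscosity %in% c(1, 40, "1", "40")))
    stop("viscosity must be 1 or 40 cP", call. = FALSE)
  tab$viscosity <- factor(as.character(tab$viscosity), levels = c("1", "40"))
  tab$light <- factor(as.character(tab$light), levels = c("light", "dark"))
  tab$lateral_line <- factor(as.character(tab$lateral_line),
                             levels = c("intact", "blocked"))
  tab$fish_id <- factor(tab$fish_id)
  if (nlevels(tab$fish_id) < 2)
    stop("at least 2 fish are required for a mixed-model fit", call. = FALSE)
  tab
}

#' Fit the per-variable linear mixed model
#'
#' REML fit of `response ~ swim_speed + factors` with a per-fish random
#' intercept, the model family used for every magnitude variable: swimming
#' speed enters as a covariate (dropped when it is itself the response),
#' the three treatments as fixed factors (by default with all two-way
#' interactions among them), the individual as a random effect, and
#' optionally a distinct residual variance per level of a grouping factor
#' (`varIdent`-style weighting). Rows with a missing response (e.g. absent
#' fin frequency) are dropped from this variable's fit only.
#'
#' @param table trial table (see [as_trial_table()]).
#' @param response response column name.
#' @param variance_groups factor name for per-level residual variances, or
#'   `NULL` for a single variance.
#' @param interactions `"two-way"` (all two-way interactions among the
#'   three treatment factors) or `"none"` (main effects only).
#' @param covariate covariate column (default `"swim_speed"`).
#' @return object of class `swimkin_fit`: the `nlme::lme` fit plus the
#'   data and formula, for downstream contrasts.
#' @export
fit_variable_model <- function(table, response,
                               variance_groups = NULL,
                               interactions = c("two-way", "none"),
                               covariate = "swim_speed") {
  interactions <- match.arg(interactions)
  tab <- as_trial_table(table)
  if (!response %in% names(tab))
    stop("no such response column: ", response, call. = FALSE)
  tab <- tab[is.finite(tab[[response]]), , drop = FALSE]
  if (nrow(tab) < 10)
    stop("fewer than 10 rows with a finite response", call. = FALSE)
  if (sd(tab[[response]]) == 0) {
    # degenerate constant response: every effect is exactly zero and so
    # are both variance components; nothing to estimate
    return(structure(list(fit = NULL, data = tab, fixed = NULL,
                          response = response, covariate = NULL,
                          variance_groups = variance_groups,
                          degenerate = TRUE,
                          intercept = tab[[response]][1]),
                     class = "swimkin_fit"))
  }
  facs <- c("viscosity", "light", "lateral_line")
  fterm <- if (interactions == "two-way")
    paste0("(", paste(facs, collapse = " + "), ")^2")
  else paste(facs, collapse = " + ")
  use_cov <- !identical(response, covariate) && covariate %in% names(tab) &&
    sd(tab[[covariate]]) > 0          # a constant covariate is no covariate
  rhs <- paste(c(if (use_cov) covariate, fterm), collapse = " + ")
  fixed <- as.formula(paste(response, "~", rhs))
  weights <- if (!is.null(variance_groups))
    nlme::varIdent(form = as.formula(paste("~ 1 |", variance_groups)))
  else NULL
  fit <- tryCatch(
    nlme::lme(fixed, random = ~ 1 | fish_id, data = tab, weights = weights,
              method = "REML", na.action = na.omit,
              control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                         returnObject = FALSE)),
    error = function(e) {
      if (!is.null(weights))
        stop("variance weights did not converge (", conditionMessage(e),
             "); consider refitting without variance_groups", call. = FALSE)
      stop(e)
    })
  vc <- as.numeric(nlme::VarCorr(fit)[, "StdDev"])
  if (vc[1] < 1e-6 * vc[2])
    warning("between-fish variance estimated at the zero boundary; ",
            "fit retained", call. = FALSE)
  structure(list(fit = fit, data = tab, fixed = fixed, response = response,
                 covariate = if (use_cov) covariate else NULL,
                 variance_groups = variance_groups),
            class = "swimkin_fit")
}

#' @export
print.swimkin_fit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<swimkin_fit> degenerate: response '", x$response,
        "' is constant at ", x$intercept, "\n", sep = "")
    return(invisible(x))
  }
  cat("<swimkin_fit> ", deparse(x$fixed), "\n", sep = "")
  print(summary(x$fit))
  invisible(x)
}

#' Fixed-effect estimates of a fitted variable model
#'
#' @param fit a `swimkin_fit`.
#' @return named numeric vector of fixed-effect coefficients (all zero,
#'   apart from the intercept, for a degenerate constant-response fit).
#' @export
fixed_effects <- function(fit) {
  stopifnot(inherits(fit, "swimkin_fit"))
  if (isTRUE(fit$degenerate))
    return(c("(Intercept)" = fit$intercept))
  nlme::fixef(fit$fit)
}

#' Summarize variance components of a fitted variable model
#'
#' @param fit a `swimkin_fit`.
#' @return list with `fish_sd`, `residual_sd`, and when the model used
#'   per-group weighting, the per-level residual sds.
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "swimkin_fit"))
  if (isTRUE(fit$degenerate))
    return(list(fish_sd = 0, residual_sd = 0))
  vc <- nlme::VarCorr(fit$fit)
  out <- list(fish_sd = as.numeric(vc["(Intercept)", "StdDev"]),
              residual_sd = fit$fit$sigma)
  if (!is.null(fit$variance_groups)) {
    vs <- coef(fit$fit$modelStruct$varStruct, unconstrained = FALSE,
               allCoef = TRUE)
    out$group_residual_sd <- fit$fit$sigma * vs
  }
  out
}

#' Estimated-marginal-means pairwise contrasts with Bonferroni correction
#'
#' Computes estimated marginal means on the full factorial reference grid
#' (covariate held at its mean, non-focal factors averaged with equal
#' weights) and the pairwise differences between levels of each requested
#' factor, with standard errors from the fitted covariance and containment
#' degrees of freedom. Raw p-values are Bonferroni-adjusted by the number
#' of comparisons performed on this variable (`p_adj = min(1, p * m)`);
#' significance is declared at adjusted p < 0.05.
#'
#' @param fit a `swimkin_fit` from [fit_variable_model()].
#' @param factors factors to contrast (default the three treatments).
#' @param n_comparisons divisor `m` for the Bonferroni correction; default
#'   the total number of contrasts returned.
#' @param by optional conditioning factor(s): contrasts are then computed
#'   within each level combination of `by`.
#' @param alpha significance level on the adjusted scale.
#' @return data.frame of class `contrast_result`: `factor`, `contrast`,
#'   `by` levels if any, `estimate`, `std_error`, `df`, `p_raw`,
#'   `p_adjusted`, `n_comparisons`, `significant`.
#' @export
emmeans_contrasts <- function(fit,
                              factors = c("viscosity", "light",
                                          "lateral_line"),
                              n_comparisons = NULL, by = NULL,
                              alpha = 0.05) {
  stopifnot(inherits(fit, "swimkin_fit"))
  if (isTRUE(fit$degenerate))
    stop("constant response: no contrasts to compute", call. = FALSE)
  cells <- table(fit$data[, unique(c(factors, by)), drop = FALSE])
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    lab <- apply(empty, 1, function(i)
      paste(mapply(function(d, k) dimnames(cells)[[d]][k],
                   seq_along(i), i), collapse = ":"))
    stop("reference grid has empty cells: ", paste(lab, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (fc in factors) {
    spec <- if (is.null(by)) as.formula(paste("~", fc))
    else as.formula(paste("~", fc, "|", paste(by, collapse = "+")))
    emm <- suppressMessages(
      emmeans::emmeans(fit$fit, spec, data = fit$data, weights = "equal"))
    pr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                          adjust = "none"))
    pr$factor <- fc
    rows[[fc]] <- pr
  }
  res <- do.call(rbind, lapply(rows, function(r) {
    out <- data.frame(factor = r$factor, contrast = as.character(r$contrast),
                      estimate = r$estimate, std_error = r$SE, df = r$df,
                      p_raw = r$p.value, stringsAsFactors = FALSE)
    bycols <- setdiff(names(r), c("factor", "contrast", "estimate", "SE",
                                  "df", "t.ratio", "p.value"))
    if (length(bycols)) out <- cbind(out, r[, bycols, drop = FALSE])
    out
  }))
  rownames(res) <- NULL
  m <- if (is.null(n_comparisons)) nrow(res) else n_comparisons
  res$p_adjusted <- pmin(1, res$p_raw * m)
  res$n_comparisons <- m
  res$significant <- res$p_adjusted < alpha
  class(res) <- c("contrast_result", "data.frame")
  res
}

#' Exact two-sided test of a 2 x K contingency table
#'
#' Conditional exact test by full enumeration of the (multivariate)
#' hypergeometric support given both margins: the two-sided p-value is the
#' total probability of all tables no more probable than the observed one.
#' For fin-state data the rows are On/Off counts and the columns
#' treatment conditions.
#'
#' @param table a 2 x K matrix of non-negative integer counts.
#' @return a list of class `htest` with the two-sided `p.value`. A table
#'   with a zero margin carries no information; then p = 1 with a warning.
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) != 2 || ncol(tab) < 2)
    stop("a 2 x K table (K >= 2) is required", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(tab) > 1e4)
    stop("table total exceeds 10^4; enumeration refused", call. = FALSE)
  p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("a margin of the table is zero; p = 1", call. = FALSE)
    1
  } else {
    cpp_fisher_2xk(as.integer(tab[1, ]), as.integer(colSums(tab)))
  }
  structure(list(
    p.value = p, method = "Exact contingency test (full enumeration)",
    data.name = deparse(substitute(table)),
    statistic = NULL, parameter = NULL), class = "htest")
}

#' Fin-state contingency tables from a trial table
#'
#' Builds On/Off x condition count tables: one 2 x 2 table per treatment
#' factor, and the full 2 x 8 table over all condition combinations.
#'
#' @param table trial table with a `fin_state` column.
#' @return named list of count matrices.
#' @export
fin_state_table <- function(table) {
  tab <- as_trial_table(table)
  if (!"fin_state" %in% names(tab))
    stop("trial table lacks fin_state", call. = FALSE)
  fs <- factor(tab$fin_state, levels = c("On", "Off"))
  out <- list(
    viscosity = table(fs, tab$viscosity),
    light = table(fs, tab$light),
    lateral_line = table(fs, tab$lateral_line))
  cond <- interaction(tab$viscosity, tab$light, tab$lateral_line, sep = "/")
  out$condition <- table(fs, cond)
  lapply(out, function(m) {
    m <- as.matrix(unclass(m)); storage.mode(m) <- "integer"; m
  })
}

#' Screen trials for outlying residuals
#'
#' Flags trials whose absolute normalized (studentized) residual under the
#' fitted variable model exceeds `threshold` and whose removal improves
#' the normality of the remaining residuals (Shapiro-Wilk W). The
#' function only flags; removal is left to the analyst and is never done
#' silently.
#'
#' @param table trial table.
#' @param response response column name.
#' @param threshold absolute studentized-residual threshold (default 3).
#' @param ... passed to [fit_variable_model()].
#' @return data.frame with one row per candidate: row index, residual,
#'   Shapiro-Wilk W with and without the trial, and `flagged`.
#' @export
screen_outliers <- function(table, response, threshold = 3, ...) {
  fit <- fit_variable_model(table, response, ...)
  r <- residuals(fit$fit, type = "normalized")
  W_full <- shapiro.test(r)$statistic
  cand <- which(abs(r) > threshold)
  if (!length(cand))
    return(data.frame(row = integer(0), residual = numeric(0),
                      W_full = numeric(0), W_drop = numeric(0),
                      flagged = logical(0)))
  out <- data.frame(row = cand, residual = r[cand], W_full = W_full,
                    W_drop = NA_real_, flagged = FALSE)
  for (i in seq_along(cand)) {
    refit <- tryCatch(
      fit_variable_model(fit$data[-cand[i], , drop = FALSE], response, ...),
      error = function(e) NULL)
    if (is.null(refit)) next
    W <- shapiro.test(residuals(refit$fit, type = "normalized"))$statistic
    out$W_drop[i] <- W
    out$flagged[i] <- W > W_full
  }
  rownames(out) <- NULL
  out
}
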