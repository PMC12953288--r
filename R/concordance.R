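#' Summarize histology vs PDFF grading discordance
#'
#' Computes the primary-endpoint summary for a graded cohort: the discordance
#' rate with an exact binomial 95% confidence interval, counts of discordant
#' pairs by magnitude and by direction (MRI over- vs under-estimation), and
#' the full 4x4 cross-tabulation of histology grades (rows) against PDFF
#' grades (columns).
#'
#' @param cohort Data.frame with \code{hist_grade} and either
#'   \code{pdff_grade} or \code{pdff_pct} (graded on the fly).
#' @return List of class \code{discordance_summary}: \code{n}, \code{rate},
#'   \code{rate_ci} (95% exact binomial), \code{by_magnitude},
#'   \code{by_direction}, \code{crosstab}.
#' @export
discordance_summary <- function(cohort) {
  if (nrow(cohort) == 0) stop("empty cohort")
  if (!"pdff_grade" %in% names(cohort)) {
    cohort$pdff_grade <- grade_pdff(cohort$pdff_pct)
  }
  dc <- assess_discordance(cohort$hist_grade, cohort$pdff_grade)
  n <- nrow(dc)
  k <- sum(dc$discordant)
  bt <- stats::binom.test(k, n)
  structure(list(
    n = n,
    rate = k / n,
    rate_ci = unname(bt$conf.int),
    by_magnitude = table(factor(dc$magnitude[dc$discordant], levels = 1:3)),
    by_direction = table(dc$direction),
    crosstab = table(hist = factor(dc$hist_grade, levels = 0:3),
                     pdff = factor(dc$pdff_grade, levels = 0:3))
  ), class = "discordance_summary")
}

#' @export
print.discordance_summary <- function(x, ...) {
  cat(sprintf("Discordance: %d/%d (%.1f%%), 95%% CI %.1f-%.1f%%\n",
              sum(x$by_magnitude), x$n, 100 * x$rate,
              100 * x$rate_ci[1], 100 * x$rate_ci[2]))
  cat("By magnitude:\n"); print(x$by_magnitude)
  cat("By direction:\n"); print(x$by_direction)
  cat("Cross-tabulation (histology rows, PDFF columns):\n"); print(x$crosstab)
  invisible(x)
}

#' Two-group comparison of a cohort variable
#'
#' Compares a variable between two groups with the independent t-test or
#' Mann-Whitney U-test for continuous variables and the chi-square or
#' Fisher's exact test for categorical ones. With \code{test = "auto"} a
#' continuous variable uses the t-test when Shapiro-Wilk normality holds in
#' both groups at the 0.05 level and the Mann-Whitney test otherwise; a
#' categorical variable uses Fisher's exact test when any expected cell count
#' is below 5 and the chi-square test otherwise.
#'
#' @param cohort Data.frame.
#' @param grouping Name of a two-level grouping column (logical or factor).
#' @param variable Name of the variable to compare.
#' @param test One of "auto", "t", "wilcoxon", "chisq", "fisher".
#' @return List: \code{test}, \code{statistic}, \code{p_value},
#'   \code{group_summary}.
#' @export
compare_groups <- function(cohort, grouping, variable,
                           test = c("auto", "t", "wilcoxon", "chisq", "fisher")) {
  test <- match.arg(test)
  g <- cohort[[grouping]]
  v <- cohort[[variable]]
  if (is.null(g) || is.null(v)) stop("grouping or variable column not found")
  g <- factor(g)
  if (nlevels(g) != 2 || any(table(g) == 0)) {
    stop("grouping must yield two nonempty groups")
  }
  continuous <- is.numeric(v)
  if (test == "auto") {
    test <- if (continuous) {
      normal <- all(tapply(v, g, function(x) {
        if (length(x) < 3 || stats::sd(x) == 0) return(FALSE)
        stats::shapiro.test(x[seq_len(min(length(x), 5000))])$p.value > 0.05
      }))
      if (normal) "t" else "wilcoxon"
    } else {
      tab <- table(g, factor(v))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) "fisher" else "chisq"
    }
  }
  res <- switch(test,
    t = {
      if (any(table(g) < 2)) stop("t-test needs at least 2 observations per group")
      stats::t.test(v ~ g)
    },
    wilcoxon = stats::wilcox.test(v ~ g, exact = FALSE),
    chisq = stats::chisq.test(table(g, factor(v))),
    fisher = stats::fisher.test(table(g, factor(v)))
  )
  summ <- if (continuous) {
    do.call(rbind, tapply(v, g, function(x) {
      data.frame(n = length(x), mean = mean(x), sd = stats::sd(x))
    }))
  } else {
    as.data.frame(table(g, factor(v)))
  }
  list(test = test,
       statistic = if (!is.null(res$statistic)) unname(res$statistic) else NA_real_,
       p_value = res$p.value,
       group_summary = summ)
}

#' Concordant vs discordant comparisons stratified by histology grade
#'
#' For each histology grade stratum, compares each requested variable between
#' concordant and discordant patients (independent t-test by default, the
#' layout of a stratified mean +/- SD comparison table).
#'
#' @param cohort Graded cohort (needs \code{discordant} and
#'   \code{hist_grade}).
#' @param variables Character vector of numeric columns to compare.
#' @param test Passed to \code{\link{compare_groups}}.
#' @return Data.frame: stratum, variable, per-group n/mean/sd, p_value. A
#'   stratum with fewer than 2 patients in either group is reported with
#'   \code{NA} p-value.
#' @export
stratified_comparison <- function(cohort,
                                  variables = c("tiny_pct", "small_pct",
                                                "large_pct", "total_pct"),
                                  test = "t") {
  stopifnot(all(c("discordant", "hist_grade") %in% names(cohort)))
  out <- list()
  for (s in sort(unique(cohort$hist_grade))) {
    sub <- cohort[cohort$hist_grade == s, , drop = FALSE]
    for (v in variables) {
      grp <- split(sub[[v]], sub$discordant)
      row <- data.frame(
        stratum = s, variable = v,
        n_concordant = length(grp[["FALSE"]]),
        mean_concordant = if (length(grp[["FALSE"]])) mean(grp[["FALSE"]]) else NA,
        sd_concordant = if (length(grp[["FALSE"]]) > 1) stats::sd(grp[["FALSE"]]) else NA,
        n_discordant = length(grp[["TRUE"]]),
        mean_discordant = if (length(grp[["TRUE"]])) mean(grp[["TRUE"]]) else NA,
        sd_discordant = if (length(grp[["TRUE"]]) > 1) stats::sd(grp[["TRUE"]]) else NA,
        p_value = NA_real_, stringsAsFactors = FALSE
      )
      if (length(grp[["FALSE"]]) >= 2 && length(grp[["TRUE"]]) >= 2) {
        row$p_value <- compare_groups(sub, "discordant", v, test = test)$p_value
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

fit_logit <- function(formula, data) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("algorithm did not converge", msg)) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)) sep <- TRUE
  list(fit = fit, separation = sep)
}

logit_table <- function(fit, z = stats::qnorm(0.975)) {
  s <- summary(fit)$coefficients
  s <- s[rownames(s) != "(Intercept)", , drop = FALSE]
  data.frame(
    predictor = rownames(s),
    odds_ratio = exp(s[, "Estimate"]),
    ci_low = exp(s[, "Estimate"] - z * s[, "Std. Error"]),
    ci_high = exp(s[, "Estimate"] + z * s[, "Std. Error"]),
    p_value = s[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Univariable logistic regression of discordance on one predictor
#'
#' Maximum-likelihood logistic fit of a binary outcome on a single predictor.
#' Odds ratios are per unit of the predictor (per percent for area variables,
#' per year for age) with Wald 95% confidence intervals
#' \code{exp(beta +/- 1.96 SE)}. Complete or quasi-complete separation is
#' flagged in the result and raised as a warning, never returned silently.
#'
#' @param cohort Data.frame.
#' @param predictor Predictor column name.
#' @param outcome Binary outcome column name (default \code{discordant}).
#' @return List of class \code{ld_logit}: \code{table} (predictor,
#'   odds_ratio, ci_low, ci_high, p_value), \code{n_used},
#'   \code{predictors_entered}, \code{predictors_excluded_collinear},
#'   \code{separation}, \code{fit}.
#' @export
univariable_logit <- function(cohort, predictor, outcome = "discordant") {
  y <- cohort[[outcome]]
  if (is.null(y) || is.null(cohort[[predictor]])) stop("column not found")
  if (length(unique(y)) < 2) stop("outcome must have both classes")
  dat <- cohort[stats::complete.cases(cohort[, c(outcome, predictor)]), ,
                drop = FALSE]
  f <- fit_logit(stats::reformulate(predictor, response = outcome), dat)
  if (f$separation) {
    warning("separation detected in univariable fit for '", predictor, "'")
  }
  structure(list(
    table = logit_table(f$fit),
    n_used = stats::nobs(f$fit),
    predictors_entered = predictor,
    predictors_excluded_collinear = character(),
    separation = f$separation,
    fit = f$fit
  ), class = "ld_logit")
}

#' Multivariable logistic model of discordance with entry and collinearity rules
#'
#' Builds the adjusted discordance model in the staged way concordance
#' studies report it: every candidate is screened univariably and enters the
#' multivariable model only when its univariable p-value is below
#' \code{alpha}; age and sex (the forced covariates) always enter. Two
#' collinearity rules are then applied to the entered set: (a) a derived sum
#' variable (such as total LD area) is removed whenever one of its components
#' also entered, and (b) of any pair of numeric predictors with absolute
#' Pearson correlation above \code{cor_limit}, the one with the larger
#' univariable p-value is dropped. Optional interaction terms (e.g.
#' \code{"fibrosis_f2_4:large_pct"}) are added to the final fit.
#'
#' @param cohort Data.frame.
#' @param candidates Character vector of candidate predictor columns.
#' @param forced Covariates always entered (default age and sex).
#' @param outcome Binary outcome column (default \code{discordant}).
#' @param alpha Univariable entry threshold.
#' @param sum_components Named list mapping a sum variable to its component
#'   columns; defaults to total LD area as the sum of the three size classes.
#' @param cor_limit Pairwise absolute-correlation screen threshold.
#' @param interactions Optional character vector of interaction terms.
#' @return An \code{ld_logit} (see \code{\link{univariable_logit}}) whose
#'   table covers all terms of the final model; \code{univariable} holds the
#'   per-candidate screening table.
#' @export
multivariable_logit <- function(cohort, candidates,
                                forced = c("age", "sex"),
                                outcome = "discordant",
                                alpha = 0.05,
                                sum_components = list(
                                  total_pct = c("tiny_pct", "small_pct", "large_pct")
                                ),
                                cor_limit = 0.9,
                                interactions = NULL) {
  y <- cohort[[outcome]]
  if (is.null(y)) stop("outcome column not found")
  if (length(unique(y)) < 2) stop("outcome must have both classes")
  candidates <- setdiff(candidates, forced)

  uni <- lapply(candidates, function(p) univariable_logit(cohort, p, outcome))
  uni_p <- vapply(uni, function(u) min(u$table$p_value), numeric(1))
  names(uni_p) <- candidates
  uni_tab <- do.call(rbind, lapply(uni, `[[`, "table"))
  uni_tab$candidate <- rep(candidates, vapply(uni, function(u) nrow(u$table), 1L))

  entered <- candidates[uni_p < alpha]
  excluded <- character()

  # rule (a): a sum variable never coexists with its own components
  for (sv in names(sum_components)) {
    if (sv %in% entered && any(sum_components[[sv]] %in% entered)) {
      entered <- setdiff(entered, sv)
      excluded <- c(excluded, sv)
    }
  }
  # rule (b): pairwise |r| screen, keep the smaller univariable p
  num <- entered[vapply(entered, function(v) is.numeric(cohort[[v]]), logical(1))]
  repeat {
    if (length(num) < 2) break
    cm <- abs(stats::cor(cohort[, num, drop = FALSE],
                         use = "pairwise.complete.obs"))
    diag(cm) <- 0
    if (max(cm) <= cor_limit) break
    pr <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    pair <- c(num[pr[1]], num[pr[2]])
    drop <- pair[which.max(uni_p[pair])]
    entered <- setdiff(entered, drop)
    num <- setdiff(num, drop)
    excluded <- c(excluded, drop)
  }

  terms <- c(forced, entered, interactions)
  cols <- unique(c(outcome, forced, entered,
                   unlist(strsplit(interactions %||% character(), ":"))))
  dat <- cohort[stats::complete.cases(cohort[, cols, drop = FALSE]), ,
                drop = FALSE]
  f <- fit_logit(stats::reformulate(terms, response = outcome), dat)
  if (f$separation) warning("separation detected in multivariable fit")

  structure(list(
    table = logit_table(f$fit),
    n_used = stats::nobs(f$fit),
    predictors_entered = entered,
    predictors_excluded_collinear = unique(excluded),
    separation = f$separation,
    univariable = uni_tab,
    univariable_p = uni_p,
    fit = f$fit
  ), class = "ld_logit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ld_logit <- function(x, ...) {
  cat(sprintf("Logistic model (n = %d)%s\n", x$n_used,
              if (x$separation) " [separation flagged]" else ""))
  tab <- x$table
  tab[, 2:5] <- lapply(tab[, 2:5], function(z) signif(z, 3))
  print(tab, row.names = FALSE)
  if (length(x$predictors_excluded_collinear)) {
    cat("Excluded (collinearity):",
        paste(x$predictors_excluded_collinear, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Correlation between two cohort variables
#'
#' Pearson's r or Spearman's rank rho with a two-sided p-value. Spearman ties
#' are handled by midranks with the asymptotic approximation.
#'
#' @param cohort Data.frame.
#' @param x,y Column names.
#' @param method "pearson" or "spearman".
#' @return List: method, coefficient, p_value, n.
#' @export
correlate <- function(cohort, x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  xv <- cohort[[x]]; yv <- cohort[[y]]
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) stop("need at least 3 paired observations")
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("zero variance in '", if (stats::sd(xv) == 0) x else y, "'")
  }
  ct <- suppressWarnings(
    stats::cor.test(xv, yv, method = method,
                    exact = if (method == "spearman") FALSE else NULL)
  )
  list(method = method, coefficient = unname(ct$estimate),
       p_value = ct$p.value, n = length(xv))
}

#' Paired Wilcoxon tests stratified by histology grade
#'
#' Within each histology-grade stratum, compares two paired measurements
#' (by default PDFF against DIA total LD area) with the Wilcoxon matched-pairs
#' signed-rank test (asymptotic p with continuity correction). Strata smaller
#' than \code{min_n} pairs are flagged as not computed; a stratum whose
#' paired differences are all zero is degenerate and reported with p = 1 by
#' convention.
#'
#' @param cohort Graded cohort with a \code{hist_grade} column.
#' @param a,b Paired measurement column names.
#' @param min_n Minimum pairs per stratum.
#' @return Data.frame: stratum, n, statistic, p_value,
#'   status (\code{ok}, \code{too_small}, \code{degenerate}).
#' @export
wilcoxon_paired_by_grade <- function(cohort, a = "pdff_pct", b = "total_pct",
                                     min_n = 5L) {
  stopifnot(all(c(a, b, "hist_grade") %in% names(cohort)))
  strata <- sort(unique(cohort$hist_grade))
  out <- lapply(strata, function(s) {
    sub <- cohort[cohort$hist_grade == s, , drop = FALSE]
    d <- sub[[a]] - sub[[b]]
    if (length(d) < min_n) {
      return(data.frame(stratum = s, n = length(d), statistic = NA_real_,
                        p_value = NA_real_, status = "too_small"))
    }
    if (all(d == 0)) {
      return(data.frame(stratum = s, n = length(d), statistic = NA_real_,
                        p_value = 1, status = "degenerate"))
    }
    wt <- stats::wilcox.test(sub[[a]], sub[[b]], paired = TRUE, exact = FALSE)
    data.frame(stratum = s, n = length(d), statistic = unname(wt$statistic),
               p_value = wt$p.value, status = "ok")
  })
  do.call(rbind, out)
}

#' Least-squares quadratic fit
#'
#' Fits \code{y = a x^2 + b x + c}, reports the coefficient of determination
#' against the mean-only model, and classifies the curvature from the sign of
#' the quadratic coefficient beyond a tolerance. Used for the size-composition
#' curves: the tiny-plus-small share of total LD area bends concave-down with
#' increasing fat content while the large share bends concave-up.
#'
#' @param x,y Numeric vectors of equal length, at least 4 points.
#' @param tol Absolute tolerance on the quadratic coefficient below which
#'   curvature is reported as \code{none}.
#' @return List of class \code{quad_fit}: coefficients (a, b, c), r_squared,
#'   concavity ("up", "down", "none").
#' @export
quad_fit <- function(x, y, tol = 1e-8) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 4) stop("need at least 4 points")
  if (stats::sd(y) == 0) {
    return(structure(list(coefficients = c(a = 0, b = 0, c = y[1]),
                          r_squared = 0, concavity = "none"),
                     class = "quad_fit"))
  }
  fit <- stats::lm(y ~ x + I(x^2))
  if (fit$rank < 3) stop("rank-deficient design (degenerate x values)")
  cf <- stats::coef(fit)
  a <- unname(cf["I(x^2)"])
  structure(list(
    coefficients = c(a = a, b = unname(cf["x"]), c = unname(cf["(Intercept)"])),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    concavity = if (a > tol) "up" else if (a < -tol) "down" else "none"
  ), class = "quad_fit")
}

#' Sample size for estimating a proportion to a given precision
#'
#' Normal-approximation sample size for estimating a prevalence with absolute
#' precision d at a two-sided significance level alpha:
#' \code{n = ceiling(z^2 p (1 - p) / d^2)}. With an anticipated prevalence of
#' 60%, d = 0.05 and alpha = 0.05 this gives 369 participants.
#'
#' @param prevalence Anticipated proportion, strictly inside (0, 1).
#' @param precision_d Absolute precision (half-width), in (0, 1).
#' @param alpha Two-sided significance level, in (0, 1).
#' @return Integer sample size.
#' @examples
#' required_sample_size(0.6, 0.05, 0.05)
#' @export
required_sample_size <- function(prevalence, precision_d, alpha = 0.05) {
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must lie strictly in (0, 1)")
  }
  if (!is.numeric(precision_d) || precision_d <= 0 || precision_d >= 1) {
    stop("precision_d must lie in (0, 1)")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2)
  as.integer(ceiling(z^2 * prevalence * (1 - prevalence) / precision_d^2))
}
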