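#' Group comparison of one outcome (one-way ANOVA plus pairwise t-tests)
#'
#' Overall one-way ANOVA F-test across groups plus two-sample t-tests for
#' every group pair (Student by default, Welch by flag), reported without
#' multiplicity correction. With the three study groups ordered
#' EM, LM/MM, SHM the pairwise p-values follow the convention
#' P1 = EM vs LM/MM, P2 = EM vs SHM, P3 = LM/MM vs SHM.
#'
#' @param data Data frame with the outcome and the grouping column.
#' @param outcome Name of the outcome column.
#' @param group Name of the grouping column (factor or character).
#' @param welch Use Welch's t-test for the pairwise comparisons.
#' @return An object of class `group_comparison`: `summary` (per-group n,
#'   mean, sd), `p_overall`, `f_statistic`, `pairwise` (data frame of pairs
#'   and p-values), and `flag` when all within-group variances are zero.
#' @export
compare_groups <- function(data, outcome, group = "group", welch = FALSE) {
  stopifnot(outcome %in% names(data), group %in% names(data))
  y <- data[[outcome]]
  g <- data[[group]]
  ok <- stats::complete.cases(y, g)
  y <- y[ok]; g <- factor(g[ok])
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need at least 2 groups with at least 2 observations each")
  smry <- data.frame(group = levels(g),
                     n = as.integer(table(g)),
                     mean = as.numeric(tapply(y, g, mean)),
                     sd = as.numeric(tapply(y, g, stats::sd)))
  if (all(smry$sd == 0)) {
    return(structure(list(summary = smry, p_overall = NA_real_,
                          f_statistic = NA_real_, pairwise = NULL,
                          flag = "zero_within_variance"),
                     class = "group_comparison"))
  }
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  pairs <- utils::combn(levels(g), 2)
  pw <- data.frame(
    pair = apply(pairs, 2, paste, collapse = " vs "),
    p = apply(pairs, 2, function(pr) {
      stats::t.test(y[g == pr[1]], y[g == pr[2]],
                    var.equal = !welch)$p.value
    })
  )
  pw$label <- paste0("P", seq_len(nrow(pw)))
  structure(list(summary = smry,
                 p_overall = an[["Pr(>F)"]][1],
                 f_statistic = an[["F value"]][1],
                 pairwise = pw, flag = NULL),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.4g\n", x$f_statistic,
              x$p_overall))
  if (!is.null(x$pairwise)) print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Chi-square test of the sex distribution across groups
#'
#' Pearson chi-square test (no continuity correction) on the sex-by-group
#' contingency table.
#'
#' @param data A data frame with `sex` and `group` columns, or a 2 x k
#'   contingency table/matrix.
#' @param sex,group Column names when `data` is a data frame.
#' @return List with `statistic` (chi-square), `df`, `p`.
#' @export
sex_distribution_test <- function(data, sex = "sex", group = "group") {
  tab <- if (is.matrix(data) || is.table(data)) as.table(data)
         else table(data[[sex]], data[[group]])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an empty margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Pearson correlation between two columns
#'
#' @param data Data frame.
#' @param x,y Column names.
#' @return List with `r`, `p` (two-sided), `n`.
#' @export
correlate <- function(data, x, y) {
  ok <- stats::complete.cases(data[[x]], data[[y]])
  xv <- data[[x]][ok]; yv <- data[[y]][ok]
  if (length(xv) < 3) stop("need at least 3 paired observations")
  ct <- stats::cor.test(xv, yv, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(xv))
}

#' Univariate screen followed by backward-eliminated multivariate OLS
#'
#' Fits one ordinary least-squares model per candidate predictor; predictors
#' with univariate p < `enter_p` enter a joint model, from which the
#' largest-p predictor is removed iteratively until every remaining
#' predictor has p < `retain_p`. Reports unstandardized and standardized
#' coefficients (`std_beta = beta * sd(x) / sd(y)`).
#'
#' @param data Data frame (complete-case analysis per model).
#' @param outcome Name of the dependent variable.
#' @param predictors Character vector of candidate predictor names.
#' @param enter_p Univariate entry threshold.
#' @param retain_p Multivariate retention threshold.
#' @param condition_limit Condition number of the scaled design above which
#'   the multivariate model is flagged as collinear.
#' @return An object of class `regression_screen`: `univariate` (one row
#'   per candidate), `final` (retained terms; zero rows when nothing
#'   enters or survives), `r_model` (multiple R of the final model), and
#'   `flags`.
#' @export
regression_screen <- function(data, outcome, predictors,
                              enter_p = 0.05, retain_p = 0.05,
                              condition_limit = 1e3) {
  stopifnot(outcome %in% names(data), all(predictors %in% names(data)))
  uni <- do.call(rbind, lapply(predictors, function(p) {
    d <- data[stats::complete.cases(data[[outcome]], data[[p]]),
              c(outcome, p)]
    fit <- stats::lm(stats::reformulate(p, outcome), data = d)
    cf <- summary(fit)$coefficients
    b <- cf[p, "Estimate"]
    data.frame(term = p,
               beta = b,
               std_beta = b * stats::sd(d[[p]]) / stats::sd(d[[outcome]]),
               p = cf[p, "Pr(>|t|)"])
  }))
  flags <- character(0)
  selected <- uni$term[uni$p < enter_p]
  if (length(selected) == 0) {
    flags <- c(flags, "no_predictor_entered")
    return(structure(list(univariate = uni,
                          final = uni[0, ], r_model = NA_real_,
                          flags = flags),
                     class = "regression_screen"))
  }
  d <- data[stats::complete.cases(data[, c(outcome, selected)]),
            c(outcome, selected)]
  if (nrow(d) < length(selected) + 2)
    stop("too few complete cases for the multivariate model")
  repeat {
    fit <- stats::lm(stats::reformulate(selected, outcome), data = d)
    cf <- summary(fit)$coefficients
    ps <- cf[selected, "Pr(>|t|)", drop = TRUE]
    if (all(ps < retain_p)) break
    drop_term <- selected[which.max(ps)]
    selected <- setdiff(selected, drop_term)
    if (length(selected) == 0) {
      flags <- c(flags, "no_predictor_retained")
      return(structure(list(univariate = uni, final = uni[0, ],
                            r_model = NA_real_, flags = flags),
                       class = "regression_screen"))
    }
  }
  X <- scale(as.matrix(d[, selected, drop = FALSE]))
  if (length(selected) > 1 && kappa(X, exact = TRUE) > condition_limit)
    flags <- c(flags, "collinear_predictors")
  cf <- summary(fit)$coefficients
  final <- data.frame(
    term = selected,
    beta = cf[selected, "Estimate"],
    std_beta = cf[selected, "Estimate"] *
      apply(d[, selected, drop = FALSE], 2, stats::sd) /
      stats::sd(d[[outcome]]),
    p = cf[selected, "Pr(>|t|)"])
  rownames(final) <- NULL
  structure(list(univariate = uni, final = final,
                 r_model = sqrt(summary(fit)$r.squared), flags = flags),
            class = "regression_screen")
}

#' @export
print.regression_screen <- function(x, ...) {
  cat("Univariate screen:\n")
  print(x$univariate, row.names = FALSE, digits = 4)
  if (nrow(x$final) > 0) {
    cat(sprintf("Final model (R = %.3f):\n", x$r_model))
    print(x$final, row.names = FALSE, digits = 4)
  } else {
    cat("Final model: empty (", paste(x$flags, collapse = ", "), ")\n")
  }
  invisible(x)
}
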