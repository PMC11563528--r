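#' Median and interquartile range
#'
#' Continuous and ordinal variables are described as median and IQR. The
#' quartiles use the standard linear-interpolation percentile rule
#' (`stats::quantile()` type 7), so `[1,2,3,4,5]` gives IQR (2, 4).
#'
#' @param values Nonempty numeric vector (NAs dropped).
#' @return List with `median`, `q25`, `q75`, `n`.
#' @export
describe_median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("`values` must be nonempty")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q25 = q[1], q75 = q[3], n = length(values))
}

#' Mann-Whitney U test with midrank ties
#'
#' Two-sided rank-sum test. The U statistic uses midranks. When the total
#' sample size is at most `exact_cap` the p-value is exact: the full
#' permutation distribution of the rank sum under the null (all label
#' assignments equally likely, ties kept as midranks) is computed by dynamic
#' programming over the rank multiset, and the two-sided p is twice the
#' smaller tail, capped at 1. Larger samples use the tie-corrected normal
#' approximation, without continuity correction by default.
#'
#' @param x,y Nonempty numeric vectors.
#' @param exact_cap Use the exact branch when `length(x) + length(y)` is at
#'   most this. Default 12.
#' @param continuity Apply a 0.5 continuity correction in the normal
#'   approximation. Default FALSE.
#' @return List with `statistic` (U for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, exact_cap = 12L, continuity = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be nonempty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])                 # rank sum of x
  u <- w - nx * (nx + 1) / 2               # U statistic for x

  if (n <= exact_cap) {
    # exact permutation distribution of the rank sum by DP over doubled
    # midranks (doubling makes all ranks integer)
    r2 <- as.integer(round(2 * r))
    smax <- sum(r2)
    # dp[[j]] counts subsets of size j by doubled rank sum (index = sum + 1)
    dp <- vector("list", nx + 1L)
    dp[[1L]] <- c(1, rep(0, smax))
    for (j in seq_len(nx)) dp[[j + 1L]] <- rep(0, smax + 1L)
    for (rv in r2) {
      for (j in rev(seq_len(nx))) {
        shifted <- c(rep(0, rv), dp[[j]][seq_len(smax + 1L - rv)])
        dp[[j + 1L]] <- dp[[j + 1L]] + shifted
      }
    }
    dist <- dp[[nx + 1L]]
    total <- sum(dist)
    w2 <- as.integer(round(2 * w))
    p_lo <- sum(dist[seq_len(w2 + 1L)]) / total          # P(W <= w)
    p_hi <- sum(dist[(w2 + 1L):(smax + 1L)]) / total     # P(W >= w)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact (permutation distribution with midranks)"
  } else {
    mu <- nx * ny / 2
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(list(statistic = u, p_value = 1,
                                 method = "degenerate (all values tied)"))
    dev <- u - mu
    if (continuity) dev <- sign(dev) * max(0, abs(dev) - 0.5)
    z <- dev / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = u, p_value = p, method = method)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value under the probability-ordering rule: the sum of
#' hypergeometric probabilities (margins fixed) of all tables no more
#' probable than the observed one. Computed via [stats::fisher.test()],
#' whose two-sided rule is exactly this. A table with a zero margin carries
#' no information; it returns p = 1 with a warning.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return List with `p_value` and the echoed `table`.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L)))
    stop("`tab` must be a 2x2 matrix")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("`tab` must contain nonnegative integer counts")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in 2x2 table; p = 1")
    return(list(p_value = 1, table = tab))
  }
  list(p_value = stats::fisher.test(tab)$p.value, table = tab)
}

#' Compare all declared variables between two groups
#'
#' Dispatches per variable type: continuous/ordinal variables are described
#' as median (IQR) and compared by [mann_whitney()]; binary variables as
#' n (%) and compared by [fisher_exact()] on the 2x2 crosstab. Display
#' values are rounded to the nearest full digit and p-values to 3 decimals,
#' while full precision is retained in the numeric columns.
#'
#' @param cohort Data frame, one row per subject.
#' @param grouping Name of a logical column splitting the cohort; both
#'   groups must be nonempty.
#' @param variables Named character vector mapping variable names to types
#'   ("continuous" or "binary"). Ordinal scores are declared "continuous".
#' @return Data frame of class `comparison_table`: one row per variable with
#'   group descriptors, test used, exact `p_value`, and display strings.
#' @export
compare_groups <- function(cohort, grouping, variables) {
  stopifnot(is.data.frame(cohort))
  if (!grouping %in% names(cohort)) stop("unknown grouping variable: ", grouping)
  g <- as.logical(cohort[[grouping]])
  if (any(is.na(g))) stop("grouping variable must be logical without NAs")
  if (!any(g) || !any(!g)) stop("both groups must be nonempty for grouping: ", grouping)

  rows <- lapply(names(variables), function(v) {
    if (!v %in% names(cohort)) stop("unknown variable: ", v)
    type <- variables[[v]]
    val <- cohort[[v]]
    if (type == "continuous") {
      x <- as.numeric(val[g]); y <- as.numeric(val[!g])
      dx <- describe_median_iqr(x); dy <- describe_median_iqr(y)
      p <- mann_whitney(x, y)$p_value
      data.frame(
        variable = v, type = type, test = "Mann-Whitney U",
        group1 = sprintf("%d (%d-%d)", round(dx$median), round(dx$q25), round(dx$q75)),
        group2 = sprintf("%d (%d-%d)", round(dy$median), round(dy$q25), round(dy$q75)),
        p_value = p, p_display = sprintf("%.3f", p),
        stringsAsFactors = FALSE)
    } else if (type == "binary") {
      b <- as.logical(val)
      if (any(is.na(b)) || (!is.logical(val) && length(unique(val)) > 2))
        stop(sprintf("variable '%s' declared binary is not two-level logical", v))
      tab <- matrix(c(sum(b[g]), sum(!b[g]), sum(b[!g]), sum(!b[!g])),
                    nrow = 2, byrow = TRUE)
      p <- fisher_exact(tab)$p_value
      data.frame(
        variable = v, type = type, test = "Fisher's exact",
        group1 = sprintf("%d (%d)", sum(b[g]), round(100 * mean(b[g]))),
        group2 = sprintf("%d (%d)", sum(b[!g]), round(100 * mean(b[!g]))),
        p_value = p, p_display = sprintf("%.3f", p),
        stringsAsFactors = FALSE)
    } else {
      stop(sprintf("unknown variable type '%s' for '%s' (use continuous or binary)",
                   type, v))
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("comparison_table", "data.frame")
  out
}

# internal: binomial glm with the declared convergence control, with
# separation / non-convergence diagnostics naming the offending variable
fit_logistic <- function(formula, data, context) {
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned_sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop(sprintf("logistic fit did not converge (%s)", context))
  if (warned_sep && length(stats::coef(fit)) > 1L) {
    co <- stats::coef(fit)[-1]
    se <- summary(fit)$coefficients[-1, "Std. Error"]
    if (any(abs(co) > 10) || any(se > 1e3)) {
      worst <- names(which.max(abs(co)))
      stop(sprintf("quasi-separation detected for variable '%s' (%s)",
                   worst, context))
    }
  }
  fit
}

#' Stepwise-forward logistic regression with odds ratios
#'
#' Multivariate logistic regression with stepwise forward variable
#' selection, as implemented by the common clinical statistics packages: at
#' each step the candidate with the smallest Rao score-test p-value enters
#' if that p-value is below `entry_p`; after each entry, any included
#' variable whose likelihood-ratio p-value exceeds `removal_p` is removed.
#' Fitting is binomial IRLS to a relative log-likelihood change below 1e-8
#' (at most 100 iterations). The final model is reported with Wald odds
#' ratios and 95% confidence intervals; candidates never selected are
#' reported with their final score-test p-value only, carrying no odds ratio.
#'
#' With `entry_p = 1` and `removal_p = 1` the procedure reduces to the
#' full-model fit on all candidates.
#'
#' @param cohort Data frame.
#' @param candidates Character vector of candidate predictor columns.
#' @param outcome Name of a logical outcome column with both classes present.
#' @param entry_p Score-test entry threshold (default 0.05).
#' @param removal_p Likelihood-ratio removal threshold (default 0.10).
#' @return An object of class `regression_result`: `selected` (data frame
#'   with coefficient, or, ci_low, ci_high, p_value per selected variable),
#'   `not_selected` (variable, score-test p), `path` (entry/removal log),
#'   `fit` (the final `glm`), and the thresholds used.
#' @export
stepwise_logistic <- function(cohort, candidates, outcome,
                              entry_p = 0.05, removal_p = 0.10) {
  stopifnot(is.data.frame(cohort), length(candidates) >= 1L)
  if (!outcome %in% names(cohort)) stop("unknown outcome variable: ", outcome)
  y <- as.logical(cohort[[outcome]])
  if (any(is.na(y)) || !any(y) || !any(!y))
    stop("outcome must be logical with both classes present")
  missing_c <- setdiff(candidates, names(cohort))
  if (length(missing_c)) stop("unknown candidate(s): ", paste(missing_c, collapse = ", "))

  dat <- cohort[, unique(c(outcome, candidates)), drop = FALSE]
  dat[[outcome]] <- y
  # logical predictors become 0/1 so coefficient names match candidate names
  for (v in candidates)
    if (is.logical(dat[[v]])) dat[[v]] <- as.numeric(dat[[v]])
  form <- function(vars) {
    rhs <- if (length(vars)) paste(vars, collapse = " + ") else "1"
    stats::as.formula(paste(outcome, "~", rhs))
  }

  selected <- character(0)
  path <- list()
  step_i <- 0L
  repeat {
    step_i <- step_i + 1L
    if (step_i > 10L * length(candidates) + 10L)
      stop("stepwise selection did not stabilize (enter/remove cycle)")
    base_fit <- fit_logistic(form(selected), dat, "base model")
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0L) break
    score_p <- vapply(pool, function(v) {
      aug <- fit_logistic(form(c(selected, v)), dat, paste("score test for", v))
      stats::anova(base_fit, aug, test = "Rao")[2, "Pr(>Chi)"]
    }, numeric(1))
    best <- names(which.min(score_p))
    if (score_p[[best]] < entry_p) {
      selected <- c(selected, best)
      path[[length(path) + 1L]] <- data.frame(
        step = step_i, action = "enter", variable = best,
        p_value = score_p[[best]], stringsAsFactors = FALSE)
    } else break

    # backward pass: drop variables whose LR p exceeds the removal threshold
    repeat {
      cur_fit <- fit_logistic(form(selected), dat, "removal check")
      lr_p <- vapply(selected, function(v) {
        red <- fit_logistic(form(setdiff(selected, v)), dat,
                            paste("LR test for", v))
        stats::anova(red, cur_fit, test = "LRT")[2, "Pr(>Chi)"]
      }, numeric(1))
      worst <- names(which.max(lr_p))
      if (lr_p[[worst]] > removal_p) {
        selected <- setdiff(selected, worst)
        path[[length(path) + 1L]] <- data.frame(
          step = step_i, action = "remove", variable = worst,
          p_value = lr_p[[worst]], stringsAsFactors = FALSE)
        if (length(selected) == 0L) break
      } else break
    }
  }

  final <- fit_logistic(form(selected), dat, "final model")
  sm <- summary(final)$coefficients
  z <- stats::qnorm(0.975)
  sel_tab <- if (length(selected)) {
    co <- sm[selected, , drop = FALSE]
    data.frame(
      variable = selected,
      coefficient = co[, "Estimate"],
      or = exp(co[, "Estimate"]),
      ci_low = exp(co[, "Estimate"] - z * co[, "Std. Error"]),
      ci_high = exp(co[, "Estimate"] + z * co[, "Std. Error"]),
      p_value = co[, "Pr(>|z|)"],
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(variable = character(0), coefficient = numeric(0),
               or = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
  }
  pool <- setdiff(candidates, selected)
  ns_tab <- if (length(pool)) {
    ns_p <- vapply(pool, function(v) {
      aug <- fit_logistic(form(c(selected, v)), dat, paste("final score test for", v))
      stats::anova(final, aug, test = "Rao")[2, "Pr(>Chi)"]
    }, numeric(1))
    data.frame(variable = pool, p_value = unname(ns_p),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(variable = character(0), p_value = numeric(0),
               stringsAsFactors = FALSE)
  }

  structure(list(
    selected = sel_tab,
    not_selected = ns_tab,
    path = if (length(path)) do.call(rbind, path) else
      data.frame(step = integer(0), action = character(0),
                 variable = character(0), p_value = numeric(0)),
    fit = final, outcome = outcome,
    entry_p = entry_p, removal_p = removal_p
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("regression_result for '%s' (entry p < %.3g, removal p > %.3g)\n",
              x$outcome, x$entry_p, x$removal_p))
  print(odds_ratio_table(x), row.names = FALSE)
  invisible(x)
}

#' Odds-ratio display table for a stepwise regression
#'
#' One row per candidate: selected variables carry OR, 95% CI bounds and
#' Wald p; variables removed (never entered) by the selection carry their
#' score-test p only, with no odds ratio.
#'
#' @param result A `regression_result` from [stepwise_logistic()].
#' @return Data frame with columns `variable`, `or`, `ci_low`, `ci_high`,
#'   `p_value`, `selected`.
#' @export
odds_ratio_table <- function(result) {
  stopifnot(inherits(result, "regression_result"))
  a <- result$selected
  b <- result$not_selected
  rbind(
    data.frame(variable = a$variable, or = a$or, ci_low = a$ci_low,
               ci_high = a$ci_high, p_value = a$p_value,
               selected = rep(TRUE, nrow(a)), stringsAsFactors = FALSE),
    data.frame(variable = b$variable, or = rep(NA_real_, nrow(b)),
               ci_low = rep(NA_real_, nrow(b)), ci_high = rep(NA_real_, nrow(b)),
               p_value = b$p_value, selected = rep(FALSE, nrow(b)),
               stringsAsFactors = FALSE)
  )
}
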