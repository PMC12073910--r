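#' Remove estimates that converged to their lower bound
#'
#' Rows flagged `at_lower_bound`, invalid, or with missing estimates are
#' removed before any age-trajectory statistic (bound-converged estimates
#' are unreliable); the exclusion log records who was removed and why.
#'
#' @param table A cohort table from [fit_cohort()].
#' @return A list with `table` (filtered) and `log` (data.frame
#'   subject_id, region, metabolite, model, parameter, reason).
#' @export
exclude_at_bound <- function(table) {
  reason <- rep(NA_character_, nrow(table))
  reason[!is.na(table$estimate) & table$at_lower_bound %in% TRUE] <-
    "at lower bound"
  reason[!(table$valid %in% TRUE)] <- "invalid or failed fit"
  reason[is.na(table$estimate)] <- "missing estimate"
  drop <- !is.na(reason)
  log <- table[drop, c("subject_id", "region", "metabolite", "model",
                       "parameter")]
  log$reason <- reason[drop]
  rownames(log) <- NULL
  list(table = table[!drop, , drop = FALSE], log = log)
}

#' Univariate age trajectory with confidence and prediction bands
#'
#' Ordinary least squares of an estimate on age; two-sided slope p-value
#' from the t distribution with n - 2 degrees of freedom; 95 % confidence
#' and prediction bands evaluated on a 100-point age grid spanning the
#' observed ages (the prediction band contains the confidence band
#' pointwise by construction).
#'
#' @param values Numeric response (one estimate per subject).
#' @param ages Ages in years.
#' @param level Band coverage level.
#' @param grid_n Number of grid points for the bands.
#' @return A list of class `trajectory`: `analyzable`, `intercept`,
#'   `slope`, `intercept_se`, `slope_se`, `slope_p`, `n`, `bands`
#'   (data.frame age, fit, conf_lo, conf_hi, pred_lo, pred_hi).
#' @export
linear_trajectory <- function(values, ages, level = 0.95, grid_n = 100) {
  ok <- is.finite(values) & is.finite(ages)
  values <- values[ok]
  ages <- ages[ok]
  if (length(values) < 3 || stats::var(ages) == 0) {
    return(structure(list(analyzable = FALSE, n = length(values)),
                     class = "trajectory"))
  }
  if (stats::var(values) == 0) {
    # exactly constant response: OLS t-statistics are 0/0; the answer is a
    # flat line with no evidence of trend
    grid <- seq(min(ages), max(ages), length.out = grid_n)
    return(structure(
      list(analyzable = TRUE, intercept = values[1], slope = 0,
           intercept_se = 0, slope_se = 0, slope_p = 1, n = length(values),
           bands = data.frame(age = grid, fit = values[1],
                              conf_lo = values[1], conf_hi = values[1],
                              pred_lo = values[1], pred_hi = values[1]),
           data = data.frame(age = ages, value = values)),
      class = "trajectory"))
  }
  fit <- stats::lm(values ~ ages)
  # noiseless synthetic input triggers summary.lm's perfect-fit warning
  sm <- suppressWarnings(summary(fit)$coefficients)
  grid <- data.frame(ages = seq(min(ages), max(ages), length.out = grid_n))
  cb <- stats::predict(fit, grid, interval = "confidence", level = level)
  pb <- stats::predict(fit, grid, interval = "prediction", level = level)
  structure(
    list(analyzable = TRUE,
         intercept = unname(sm[1, 1]), slope = unname(sm[2, 1]),
         intercept_se = unname(sm[1, 2]), slope_se = unname(sm[2, 2]),
         slope_p = unname(sm[2, 4]), n = length(values),
         bands = data.frame(age = grid$ages, fit = cb[, "fit"],
                            conf_lo = cb[, "lwr"], conf_hi = cb[, "upr"],
                            pred_lo = pb[, "lwr"], pred_hi = pb[, "upr"]),
         data = data.frame(age = ages, value = values)),
    class = "trajectory"
  )
}

#' Age regression with the fGM/fWM tissue-ratio covariate
#'
#' OLS of y on age and fGM/fWM (y ~ b0 + b1 age + b2 fGMfWM), with
#' per-coefficient two-sided p-values from the t distribution with n - 3
#' degrees of freedom. An exactly collinear design is reported as not
#' analyzable together with its condition number.
#'
#' @param values Numeric response.
#' @param ages Ages in years.
#' @param fgmfwm fGM/fWM ratio per subject.
#' @return A list: `analyzable`, `coef` (b0, age, fgmfwm), `se`, `p`,
#'   `n`, and `condition_number` when not analyzable.
#' @export
covariate_regression <- function(values, ages, fgmfwm) {
  ok <- is.finite(values) & is.finite(ages) & is.finite(fgmfwm)
  values <- values[ok]; ages <- ages[ok]; fgmfwm <- fgmfwm[ok]
  X <- cbind(1, ages, fgmfwm)
  if (length(values) < 4 || qr(X)$rank < 3) {
    return(list(analyzable = FALSE, n = length(values),
                condition_number = kappa(X)))
  }
  fit <- stats::lm(values ~ ages + fgmfwm)
  sm <- suppressWarnings(summary(fit)$coefficients)
  list(analyzable = TRUE,
       coef = stats::setNames(sm[, 1], c("b0", "age", "fgmfwm")),
       se = stats::setNames(sm[, 2], c("b0", "age", "fgmfwm")),
       p = stats::setNames(sm[, 4], c("b0", "age", "fgmfwm")),
       n = length(values))
}

#' Young/old group comparison
#'
#' Two-sample t-test between the younger (age < cutoff) and older
#' (age >= cutoff; the boundary age goes to the older group) subjects.
#' Welch's unequal-variance test by default; the pooled Student variant is
#' available via `pooled = TRUE`.
#'
#' @param values Numeric response.
#' @param ages Ages in years.
#' @param cutoff Group boundary in years (default 50).
#' @param pooled Use the pooled-variance Student test.
#' @return A list: `analyzable`, `t`, `df`, `p`, `young` and `old`
#'   summaries (n, mean, sd).
#' @export
group_ttest <- function(values, ages, cutoff = 50, pooled = FALSE) {
  ok <- is.finite(values) & is.finite(ages)
  values <- values[ok]; ages <- ages[ok]
  young <- values[ages < cutoff]
  old <- values[ages >= cutoff]
  if (length(young) < 2 || length(old) < 2) {
    return(list(analyzable = FALSE,
                young = list(n = length(young)),
                old = list(n = length(old))))
  }
  tt <- stats::t.test(young, old, var.equal = pooled)
  list(analyzable = TRUE,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       young = list(n = length(young), mean = mean(young),
                    sd = stats::sd(young)),
       old = list(n = length(old), mean = mean(old), sd = stats::sd(old)))
}

#' Bonferroni-corrected per-test threshold
#'
#' alpha / m; with the family of two regions x three metabolites (m = 6)
#' at alpha = 0.05 this is 0.00833..., and significance uses the strict
#' inequality p < threshold.
#'
#' @param alpha Family-wise level.
#' @param m Number of tests (>= 1).
#' @return The corrected per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(m) || length(m) != 1 || m < 1) {
    stop("m must be a positive count", call. = FALSE)
  }
  alpha / m
}

#' Run the full age-trajectory analysis grid
#'
#' For every (region, metabolite, model, parameter) cell of a cohort
#' table: apply the lower-bound exclusion, then the univariate age
#' regression, the fGM/fWM covariate regression, and the young/old t-test.
#' Bonferroni control is applied to the t-tests only, with m = regions x
#' metabolites per diffusion metric (6 by default).
#'
#' @param table Cohort table from [fit_cohort()].
#' @param fractions Tissue-fraction table from [cohort_fractions()] (or
#'   same schema: subject_id, region, fgm_fwm).
#' @param alpha Family-wise level for the t-test family.
#' @param m Number of tests in the Bonferroni family (default: regions x
#'   metabolites).
#' @param cutoff Young/old age boundary in years.
#' @param pooled Use the pooled Student t-test variant.
#' @return A list with `grid` (one tidy row per cell: slope, slope_se,
#'   slope_p, beta_age, beta_age_p, beta_fgmfwm, beta_fgmfwm_p, t, t_df,
#'   t_p, t_significant, n_used, n_excluded, analyzable), `threshold`,
#'   `exclusions` (the exclusion log) and `cells` (per-cell `trajectory`
#'   objects for plotting).
#' @export
run_trajectory_suite <- function(table, fractions, alpha = 0.05,
                                 m = NULL, cutoff = 50, pooled = FALSE) {
  if (is.null(m)) {
    m <- length(unique(table$region)) * length(unique(table$metabolite))
  }
  thr <- bonferroni_threshold(alpha, m)
  exc <- exclude_at_bound(table)
  tab <- exc$table
  n_input <- stats::aggregate(
    list(n_input = table$estimate),
    by = table[, c("region", "metabolite", "model", "parameter")],
    FUN = length)

  key <- interaction(tab$region, tab$metabolite, tab$model, tab$parameter,
                     drop = TRUE)
  # deterministic cell order regardless of input row order
  cells_df <- unique(tab[, c("region", "metabolite", "model", "parameter")])
  cells_df <- cells_df[order(cells_df$region, cells_df$metabolite,
                             cells_df$model, cells_df$parameter), ,
                       drop = FALSE]
  rows <- list()
  cells <- list()
  for (i in seq_len(nrow(cells_df))) {
    cd <- cells_df[i, ]
    sub <- tab[tab$region == cd$region & tab$metabolite == cd$metabolite &
                 tab$model == cd$model & tab$parameter == cd$parameter, ]
    sub <- sub[order(sub$subject_id), , drop = FALSE]
    fr <- fractions[fractions$region == cd$region, c("subject_id",
                                                     "fgm_fwm")]
    sub <- merge(sub, fr, by = "subject_id", sort = TRUE)
    lt <- linear_trajectory(sub$estimate, sub$age)
    cv <- covariate_regression(sub$estimate, sub$age, sub$fgm_fwm)
    tt <- group_ttest(sub$estimate, sub$age, cutoff = cutoff,
                      pooled = pooled)
    ni <- n_input$n_input[n_input$region == cd$region &
                            n_input$metabolite == cd$metabolite &
                            n_input$model == cd$model &
                            n_input$parameter == cd$parameter]
    lbl <- paste(cd$region, cd$metabolite, cd$model, cd$parameter,
                 sep = "/")
    cells[[lbl]] <- lt
    rows[[i]] <- data.frame(
      region = cd$region, metabolite = cd$metabolite, model = cd$model,
      parameter = cd$parameter,
      slope = if (lt$analyzable) lt$slope else NA_real_,
      slope_se = if (lt$analyzable) lt$slope_se else NA_real_,
      slope_p = if (lt$analyzable) lt$slope_p else NA_real_,
      beta_age = if (cv$analyzable) unname(cv$coef["age"]) else NA_real_,
      beta_age_p = if (cv$analyzable) unname(cv$p["age"]) else NA_real_,
      beta_fgmfwm = if (cv$analyzable) unname(cv$coef["fgmfwm"]) else
        NA_real_,
      beta_fgmfwm_p = if (cv$analyzable) unname(cv$p["fgmfwm"]) else
        NA_real_,
      t = if (tt$analyzable) tt$t else NA_real_,
      t_df = if (tt$analyzable) tt$df else NA_real_,
      t_p = if (tt$analyzable) tt$p else NA_real_,
      t_significant = if (tt$analyzable) tt$p < thr else NA,
      n_used = nrow(sub), n_excluded = ni - nrow(sub),
      analyzable = lt$analyzable, stringsAsFactors = FALSE)
  }
  list(grid = do.call(rbind, rows), threshold = thr,
       exclusions = exc$log, cells = cells)
}

#' Plot an age trajectory with confidence and prediction bands
#'
#' Scatter of estimates vs age with the OLS line, the confidence band
#' (dashed) and the prediction band (dotted).
#'
#' @param x A `trajectory` from [linear_trajectory()].
#' @param main,ylab Plot annotation.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.trajectory <- function(x, main = "age trajectory",
                            ylab = "estimate", ...) {
  if (!isTRUE(x$analyzable)) {
    stop("trajectory not analyzable; nothing to plot", call. = FALSE)
  }
  b <- x$bands
  graphics::plot(x$data$age, x$data$value, xlab = "age (years)",
                 ylab = ylab, main = main,
                 ylim = range(b$pred_lo, b$pred_hi, x$data$value), ...)
  graphics::lines(b$age, b$fit, lwd = 2)
  graphics::lines(b$age, b$conf_lo, lty = 2)
  graphics::lines(b$age, b$conf_hi, lty = 2)
  graphics::lines(b$age, b$pred_lo, lty = 3)
  graphics::lines(b$age, b$pred_hi, lty = 3)
  invisible(x)
}
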