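#' Fit specification for one signal model
#'
#' Bundles the model name, its b-range rule, parameter bounds,
#' initialization/restart policy and convergence settings. Defaults follow
#' the analysis conventions used throughout: the monoexponential
#' representation is fitted to b < 5 ms/um^2, the kurtosis representation
#' to b < 10 ms/um^2, and both stick models to all b-values; diffusivities
#' are bounded in (0, 1.0] um^2/ms (free-diffusion ceiling) and kurtosis
#' parameters in [0, 3.0]. Lower bounds are 1e-6 for diffusivities (strict
#' positivity) and 0 for kurtosis parameters.
#'
#' @param model One of "monoexp", "kurtosis", "astrosticks",
#'   "mod_astrosticks".
#' @param b_max Upper b cutoff (exclusive); `NULL` selects the model's
#'   default rule.
#' @param lower,upper Named numeric bounds per model parameter; `NULL`
#'   selects defaults.
#' @param n_restarts Number of seeded random multi-starts in addition to the
#'   deterministic initialization.
#' @param at_bound_tol Estimates closer than this to their lower bound are
#'   flagged `at_lower_bound`.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#'
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(model = c("monoexp", "kurtosis", "astrosticks",
                               "mod_astrosticks"),
                     b_max = NULL, lower = NULL, upper = NULL,
                     n_restarts = 5, at_bound_tol = 1e-4, maxiter = 200) {
  model <- match.arg(model)
  pn <- model_param_names(model)
  if (is.null(b_max)) {
    b_max <- switch(model, monoexp = 5, kurtosis = 10, Inf)
  }
  def_lower <- ifelse(pn %in% c("ADC", "Dintra"), 1e-6, 0)
  def_upper <- ifelse(pn %in% c("ADC", "Dintra"), 1.0, 3.0)
  names(def_lower) <- names(def_upper) <- pn
  if (!is.null(lower)) def_lower[names(lower)] <- lower
  if (!is.null(upper)) def_upper[names(upper)] <- upper
  structure(
    list(model = model, param_names = pn, b_max = b_max,
         lower = def_lower, upper = def_upper,
         n_restarts = as.integer(n_restarts),
         at_bound_tol = at_bound_tol, maxiter = as.integer(maxiter)),
    class = "fit_spec"
  )
}

#' Default fit specifications for all four models
#' @return Named list of `fit_spec` objects.
#' @export
default_fit_specs <- function() {
  models <- c("monoexp", "kurtosis", "astrosticks", "mod_astrosticks")
  stats::setNames(lapply(models, fit_spec), models)
}

#' Select the b-values a fit specification uses
#'
#' Returns the protocol b-values strictly below the specification's cutoff,
#' in protocol order: three values for the monoexponential rule (b < 5),
#' four for the kurtosis rule (b < 10), all six for the stick models.
#'
#' @param spec A `fit_spec`.
#' @param protocol A `dmrs_protocol`.
#' @return Numeric subset of `protocol$b_values`.
#' @export
select_brange <- function(spec, protocol) {
  b <- protocol$b_values[protocol$b_values < spec$b_max]
  if (length(b) == 0) {
    stop("b-range rule selects no b-values from this protocol",
         call. = FALSE)
  }
  b
}

# residuals for nls.lm: data minus S0 * model; invalid modified-astro-sticks
# evaluations (negative Deff on the orientation domain) get a smooth penalty
# proportional to the constraint excess so the optimizer is pushed back.
fit_residuals <- function(par, model, b, y) {
  s0 <- par[1]
  pars <- par[-1]
  if (model == "mod_astrosticks") {
    excess <- pars[2] * pars[1] * max(b) - 1
    if (excess > 0) return(rep(1e3 * (1 + excess), length(b)))
  }
  s <- model_signal(model, b, pars, warn = FALSE)
  y - s0 * as.numeric(s)
}

fit_inits <- function(model, b, y, lower, upper, n_restarts, seed) {
  # deterministic start: log-linear ADC from the two lowest-b points
  i <- order(b)[1:2]
  adc0 <- (log(y[i[1]]) - log(y[i[2]])) / (b[i[2]] - b[i[1]])
  adc0 <- min(max(adc0, 1e-3), 1.0)
  s0_0 <- y[i[1]] * exp(b[i[1]] * adc0)
  start <- switch(model,
    monoexp = c(S0 = s0_0, ADC = adc0),
    kurtosis = c(S0 = s0_0, ADC = adc0, K = 1),
    astrosticks = c(S0 = s0_0, Dintra = min(3 * adc0, 1.0)),
    mod_astrosticks = c(S0 = s0_0, Dintra = min(3 * adc0, 1.0),
                        Kintra = 0.05)
  )
  inits <- list(start)
  if (n_restarts > 0) {
    draws <- withr::with_seed(seed, {
      lapply(seq_len(n_restarts), function(j) {
        p <- lower + stats::runif(length(lower)) * (upper - lower)
        c(S0 = max(y) * stats::runif(1, 0.5, 2), p)
      })
    })
    inits <- c(inits, draws)
  }
  inits
}

#' Fit a signal model to a decay curve
#'
#' Bounded Levenberg-Marquardt least squares (via [minpack.lm::nls.lm])
#' minimizing the unweighted sum of squared residuals between measured
#' amplitudes and S0 * model(b, params) over the specification's b-range.
#' S0 is a free positive nuisance scale. A deterministic initialization
#' (log-linear ADC from the two lowest-b points, propagated between models)
#' is augmented by seeded random restarts within the bounds; the best
#' objective is kept, so the result is deterministic given data, spec and
#' seed. Parameter sets driving the modified astro-sticks effective
#' diffusivity negative anywhere on the orientation domain receive a
#' penalized objective and the returned fit is flagged invalid if the
#' solution lies in that regime.
#'
#' @param curve A `decay_curve`.
#' @param spec A `fit_spec`.
#' @param seed Integer seed for the multi-start draws.
#' @return An object of class `dmrs_fit`: point estimates, 1-sigma
#'   uncertainties from the least-squares covariance, `S0`, residuals,
#'   `converged`, per-parameter `at_lower_bound` flags and a `valid` flag.
#' @export
fit_model <- function(curve, spec, seed = 1) {
  keep <- curve$b < spec$b_max
  b <- curve$b[keep]
  y <- curve$amplitude[keep]
  npar <- length(spec$param_names) + 1L   # + S0
  if (length(b) < npar + 1L) {
    stop(sprintf("need at least %d points in the selected b-range, have %d",
                 npar + 1L, length(b)), call. = FALSE)
  }
  if (any(y <= 0)) stop("amplitudes must be positive", call. = FALSE)

  lower <- c(S0 = 1e-6, spec$lower)
  upper <- c(S0 = 10 * max(y), spec$upper)
  inits <- fit_inits(spec$model, b, y, spec$lower, spec$upper,
                     spec$n_restarts, seed)

  best <- NULL
  for (p0 in inits) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = pmin(pmax(p0, lower), upper),
        lower = lower, upper = upper,
        fn = fit_residuals, model = spec$model, b = b, y = y,
        control = minpack.lm::nls.lm.control(
          maxiter = spec$maxiter, ftol = 1e-12, ptol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) {
    stop("all optimization starts failed", call. = FALSE)
  }

  est <- best$par
  pars <- est[-1]
  converged <- best$info %in% 1:3
  valid <- TRUE
  if (spec$model == "mod_astrosticks") {
    valid <- pars[["Kintra"]] * pars[["Dintra"]] * max(b) <= 1
  }

  se <- rep(NA_real_, npar)
  names(se) <- names(est)
  if (length(b) > npar && valid) {
    J <- num_jacobian(function(p) fit_residuals(p, spec$model, b, y), est)
    s2 <- best$deviance / (length(b) - npar)
    cv <- tryCatch(solve(crossprod(J)) * s2, error = function(e) NULL)
    if (!is.null(cv)) se <- sqrt(pmax(diag(cv), 0))
  }

  at_lb <- pars < spec$lower + spec$at_bound_tol
  fitted <- est[1] * as.numeric(model_signal(spec$model, b, pars,
                                             warn = FALSE))
  structure(
    list(model = spec$model,
         estimate = pars,
         stderr = se[-1],
         S0 = unname(est[1]), S0_stderr = unname(se[1]),
         b_used = b, residuals = y - fitted, rss = best$deviance,
         converged = converged, at_lower_bound = at_lb,
         valid = valid, n_points = length(b)),
    class = "dmrs_fit"
  )
}

num_jacobian <- function(f, p, h = 1e-7) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (j in seq_along(p)) {
    hj <- h * max(1, abs(p[j]))
    pp <- pm <- p
    pp[j] <- p[j] + hj
    pm[j] <- p[j] - hj
    J[, j] <- (f(pp) - f(pm)) / (2 * hj)
  }
  J
}

#' @export
print.dmrs_fit <- function(x, ...) {
  cat(sprintf("dmrs_fit [%s]%s%s\n", x$model,
              if (x$converged) "" else " (not converged)",
              if (x$valid) "" else " (invalid region)"))
  est <- data.frame(estimate = c(x$S0, x$estimate),
                    stderr = c(x$S0_stderr, x$stderr),
                    at_lower_bound = c(NA, x$at_lower_bound))
  rownames(est) <- c("S0", names(x$estimate))
  print(est)
  invisible(x)
}

#' Fit all models to every curve in a cohort
#'
#' Runs each fit specification on each (subject, region, metabolite) decay
#' curve and returns one tidy row per model parameter. Failed or missing
#' fits produce rows with `NA` estimates and `valid = FALSE` plus a logged
#' warning, never silent omission.
#'
#' @param records List of subject records as produced by
#'   [generate_cohort()] (each with `subject_id`, `age`, `sex`, `region`,
#'   `curves`).
#' @param specs List of `fit_spec` objects (default: all four models).
#' @param seed Integer seed; per-fit seeds are derived deterministically.
#' @return A data.frame with columns subject_id, age, sex, region,
#'   metabolite, model, parameter, estimate, stderr, at_lower_bound, valid,
#'   n_points.
#' @export
fit_cohort <- function(records, specs = default_fit_specs(), seed = 1) {
  rows <- list()
  k <- 0L
  for (ri in seq_along(records)) {
    rec <- records[[ri]]
    mets <- names(rec$curves)
    for (mi in seq_along(mets)) {
      curve <- rec$curves[[mets[mi]]]
      for (si in seq_along(specs)) {
        spec <- specs[[si]]
        fit <- NULL
        if (!is.null(curve)) {
          fit <- tryCatch(
            fit_model(curve, spec, seed = derive_seed(seed, ri, mi, si)),
            error = function(e) {
              warning(sprintf("fit failed (%s/%s/%s/%s): %s",
                              rec$subject_id, rec$region, mets[mi],
                              spec$model, conditionMessage(e)),
                      call. = FALSE)
              NULL
            })
        } else {
          warning(sprintf("missing curve for %s/%s/%s", rec$subject_id,
                          rec$region, mets[mi]), call. = FALSE)
        }
        for (pn in spec$param_names) {
          k <- k + 1L
          rows[[k]] <- data.frame(
            subject_id = rec$subject_id, age = rec$age, sex = rec$sex,
            region = rec$region, metabolite = mets[mi],
            model = spec$model, parameter = pn,
            estimate = if (is.null(fit)) NA_real_ else
              unname(fit$estimate[pn]),
            stderr = if (is.null(fit)) NA_real_ else unname(fit$stderr[pn]),
            at_lower_bound = if (is.null(fit)) NA else
              unname(fit$at_lower_bound[pn]),
            valid = if (is.null(fit)) FALSE else
              (fit$valid && fit$converged),
            n_points = if (is.null(fit)) 0L else fit$n_points,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
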