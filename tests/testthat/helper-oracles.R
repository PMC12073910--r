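# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force grids, closed-form arithmetic and
# direct Monte-Carlo sampling.

# brute-force bounded grid search of the fitting objective with S0 profiled
# analytically (linear least squares in S0 for fixed model parameters)
grid_search_oracle <- function(model, b, y, lower, upper, n_grid = 200) {
  grids <- mapply(function(lo, hi) seq(lo, hi, length.out = n_grid),
                  lower, upper, SIMPLIFY = FALSE)
  pts <- do.call(expand.grid, grids)
  best <- list(rss = Inf, pars = NULL, s0 = NA)
  for (i in seq_len(nrow(pts))) {
    pars <- as.numeric(pts[i, ])
    if (model == "mod_astrosticks" && pars[2] * pars[1] * max(b) > 1) next
    m <- as.numeric(dmrsage:::model_signal(model, b, pars, warn = FALSE))
    s0 <- sum(y * m) / sum(m * m)
    rss <- sum((y - s0 * m)^2)
    if (rss < best$rss) best <- list(rss = rss, pars = pars, s0 = s0)
  }
  best
}

# hand-computed OLS via the normal equations (no lm)
ols_oracle <- function(y, x) {
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept, se = se,
       p = 2 * stats::pt(-abs(tval), n - 2))
}

# hand-computed Welch two-sample t
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  tval <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

default_protocol <- dmrs_protocol()

noiseless_curve <- function(model, pars, protocol = default_protocol,
                            metabolite = "tNAA", region = "cerebellum") {
  decay_curve(protocol$b_values,
              as.numeric(dmrsage:::model_signal(model, protocol$b_values,
                                                pars, warn = FALSE)),
              metabolite = metabolite, region = region)
}
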