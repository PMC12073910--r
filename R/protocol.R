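#' Tetrahedral diffusion-encoding directions
#'
#' The four unit vectors obtained by normalizing (-1,-1,-1), (-1,1,1),
#' (1,-1,1) and (1,1,-1): the tetrahedral scheme that maximizes achievable
#' b-value per gradient axis on a clinical scanner.
#'
#' @return A 4 x 3 numeric matrix of unit row vectors.
#' @export
tetrahedral_directions <- function() {
  d <- rbind(
    c(-1, -1, -1),
    c(-1,  1,  1),
    c( 1, -1,  1),
    c( 1,  1, -1)
  )
  d / sqrt(rowSums(d^2))
}

#' Diffusion acquisition protocol
#'
#' Container for the diffusion-weighting design: b-values, encoding
#' directions, effective gradient timings and the number of transients
#' acquired per (b, direction) condition. The defaults are the six-b-value
#' tetrahedral semi-LASER protocol used throughout this package:
#' b = 0.01, 1.012, 4.03, 9.06, 16.09, 25.1 ms/um^2, four tetrahedral
#' directions, effective gradient duration 26.4 ms, effective separation
#' 62.5 ms, and 24 transients per condition.
#'
#' @param b_values Strictly increasing non-negative b-values in ms/um^2.
#' @param directions Matrix of gradient directions (rows), each of unit norm.
#' @param delta_eff Effective gradient duration in ms.
#' @param Delta_eff Effective gradient separation in ms.
#' @param transients_per_condition Positive integer count of transients.
#'
#' @return An object of class `dmrs_protocol`.
#' @examples
#' p <- dmrs_protocol()
#' p$b_values
#' @export
dmrs_protocol <- function(b_values = c(0.01, 1.012, 4.03, 9.06, 16.09, 25.1),
                          directions = tetrahedral_directions(),
                          delta_eff = 26.4,
                          Delta_eff = 62.5,
                          transients_per_condition = 24) {
  b_values <- as.numeric(b_values)
  if (length(b_values) == 0 || any(b_values < 0)) {
    stop("b_values must be non-negative", call. = FALSE)
  }
  if (is.unsorted(b_values, strictly = TRUE)) {
    stop("b_values must be strictly increasing", call. = FALSE)
  }
  directions <- as.matrix(directions)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-8)) {
    stop("every direction must have unit Euclidean norm", call. = FALSE)
  }
  if (!is.numeric(transients_per_condition) || transients_per_condition < 1) {
    stop("transients_per_condition must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      b_values = b_values,
      directions = directions,
      delta_eff = delta_eff,
      Delta_eff = Delta_eff,
      transients_per_condition = as.integer(transients_per_condition)
    ),
    class = "dmrs_protocol"
  )
}

#' @export
print.dmrs_protocol <- function(x, ...) {
  cat("dMRS diffusion protocol\n")
  cat("  b-values (ms/um^2):", paste(x$b_values, collapse = ", "), "\n")
  cat("  directions:", nrow(x$directions), "(tetrahedral if 4)\n")
  cat("  delta_eff / Delta_eff (ms):", x$delta_eff, "/", x$Delta_eff, "\n")
  cat("  transients per condition:", x$transients_per_condition, "\n")
  invisible(x)
}

#' Direction-averaged metabolite decay curve
#'
#' One metabolite's direction-averaged, positive signal amplitude as a
#' function of b, with optional per-point uncertainties. Amplitudes are in
#' arbitrary units; normalization by the fitted scale S0 happens in the
#' fitting layer.
#'
#' @param b Numeric b-values in ms/um^2.
#' @param amplitude Positive amplitudes, same length as `b`.
#' @param sd Optional per-point uncertainties (same length, non-negative).
#' @param metabolite Metabolite label (e.g. "tNAA", "tCho", "tCr").
#' @param region Region label (e.g. "cerebellum", "PCC").
#'
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(b, amplitude, sd = NULL,
                        metabolite = NA_character_, region = NA_character_) {
  b <- as.numeric(b)
  amplitude <- as.numeric(amplitude)
  if (length(b) != length(amplitude)) {
    stop("b and amplitude must have the same length", call. = FALSE)
  }
  if (any(!is.finite(amplitude)) || any(amplitude <= 0)) {
    stop("amplitudes must be finite and positive", call. = FALSE)
  }
  if (is.null(sd)) sd <- rep(NA_real_, length(b))
  structure(
    list(b = b, amplitude = amplitude, sd = as.numeric(sd),
         metabolite = metabolite, region = region),
    class = "decay_curve"
  )
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("decay_curve: %s / %s, %d b-values\n",
              x$metabolite, x$region, length(x$b)))
  print(data.frame(b = x$b, amplitude = x$amplitude, sd = x$sd),
        row.names = FALSE)
  invisible(x)
}

# Deterministic substream seed from a master seed and integer indices.
# Plain integer arithmetic in doubles (exact below 2^53), reduced mod 2^31-1
# so the result is a valid 32-bit seed.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- (as.numeric(master) %% 2147483647) * 7919
  if (length(idx)) {
    mult <- 104729^(seq_along(idx) - 1) %% 2147483647
    h <- h + sum((as.numeric(idx) %% 65521) * mult)
  }
  as.integer(h %% 2147483647)
}
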