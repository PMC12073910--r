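default_ref_params <- function() {
  # cohort-average astro-sticks Dintra (um^2/ms) per region x metabolite,
  # used as the generator's ground-truth reference values
  list(
    cerebellum = list(tNAA = c(Dintra = 0.346),
                      tCho = c(Dintra = 0.325),
                      tCr  = c(Dintra = 0.287)),
    PCC        = list(tNAA = c(Dintra = 0.440),
                      tCho = c(Dintra = 0.407),
                      tCr  = c(Dintra = 0.440))
  )
}

default_tissue <- function() {
  # voxel tissue-fraction means/SDs and the fractional fGM/fWM decline
  # across the age range
  list(
    cerebellum = list(mean = c(fGM = 0.82, fWM = 0.12, fCSF = 0.06),
                      sd   = c(fGM = 0.05, fWM = 0.05, fCSF = 0.03),
                      ratio_decline = 0.17),
    PCC        = list(mean = c(fGM = 0.69, fWM = 0.14, fCSF = 0.17),
                      sd   = c(fGM = 0.07, fWM = 0.03, fCSF = 0.08),
                      ratio_decline = 0.04)
  )
}

default_crlb <- function() {
  # relative area noise (LCModel-CRLB-equivalent): at b ~ 0 and at b_max,
  # linearly interpolated in b between the two
  list(
    b0 = 0.03,
    bmax = list(cerebellum = c(tNAA = 0.04, tCho = 0.06, tCr = 0.04),
                PCC        = c(tNAA = 0.07, tCho = 0.10, tCr = 0.05))
  )
}

#' Synthetic cohort configuration
#'
#' Defaults reproduce the study conditions this package emulates: 25
#' subjects aged 25-80, two regions (cerebellum, PCC), three metabolites
#' (tNAA, tCho, tCr) with astro-sticks ground truth at the cohort-average
#' Dintra values, zero age slopes on the diffusion parameters (the null
#' configuration), tissue fractions centered on the reported voxel
#' compositions with an fGM/fWM decline of ~17 % (cerebellum) and ~4 %
#' (PCC) across the age range, and area-level noise interpolating the
#' reported CRLBs from ~3 % at b ~ 0 to 4-10 % at b_max.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Two-element vector of ages in years (uniform draw).
#' @param regions Character vector of region labels.
#' @param metabolites Character vector of metabolite labels.
#' @param model Ground-truth forward model name.
#' @param ref_params Nested list region -> metabolite -> named parameter
#'   vector at the reference age.
#' @param age_slopes Named numeric per-parameter absolute change per year
#'   (applied to every region/metabolite), or a nested list mirroring
#'   `ref_params`. Default 0.
#' @param ref_age Age (years) at which `ref_params` apply.
#' @param tissue Tissue-fraction settings per region (means, SDs,
#'   fractional fGM/fWM decline across the age range).
#' @param crlb Noise settings: relative SD at b ~ 0 and per
#'   region/metabolite at b_max.
#' @param protocol A `dmrs_protocol`.
#' @param seed Master seed; all substreams derive from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 25, age_range = c(25, 80),
                          regions = c("cerebellum", "PCC"),
                          metabolites = c("tNAA", "tCho", "tCr"),
                          model = "astrosticks",
                          ref_params = default_ref_params(),
                          age_slopes = NULL,
                          ref_age = mean(age_range),
                          tissue = default_tissue(),
                          crlb = default_crlb(),
                          protocol = dmrs_protocol(),
                          seed = 42) {
  stopifnot(n_subjects >= 1, length(age_range) == 2,
            age_range[1] < age_range[2])
  pn <- model_param_names(model)
  if (is.null(age_slopes)) {
    age_slopes <- stats::setNames(rep(0, length(pn)), pn)
  }
  # a slope must leave at least one age with in-bound parameters
  for (rg in regions) for (met in metabolites) {
    p <- ref_params[[rg]][[met]]
    hi <- ifelse(names(p) %in% c("ADC", "Dintra"), 1.0, 3.0)
    ok <- vapply(age_range, function(a) {
      pa <- p + age_slopes[names(p)] * (a - ref_age)
      all(pa > 0 & pa <= hi)
    }, logical(1))
    if (!any(ok)) {
      stop("age slopes push parameters out of bounds for all ages",
           call. = FALSE)
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), age_range = age_range,
         regions = regions, metabolites = metabolites, model = model,
         ref_params = ref_params, age_slopes = age_slopes,
         ref_age = ref_age, tissue = tissue, crlb = crlb,
         protocol = protocol, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

truth_at_age <- function(config, region, metabolite, age) {
  p <- config$ref_params[[region]][[metabolite]]
  sl <- config$age_slopes[names(p)]
  sl[is.na(sl)] <- 0
  pa <- p + sl * (age - config$ref_age)
  pn <- model_param_names(config$model)
  lo <- ifelse(pn %in% c("ADC", "Dintra"), 1e-6, 0)
  hi <- ifelse(pn %in% c("ADC", "Dintra"), 1.0, 3.0)
  pmin(pmax(pa, lo + 1e-9), hi)
}

crlb_at_b <- function(b, b_range, crlb_b0, crlb_bmax) {
  crlb_b0 + (b - b_range[1]) / (b_range[2] - b_range[1]) *
    (crlb_bmax - crlb_b0)
}

#' Generate one noisy direction-averaged decay curve
#'
#' Per-direction amplitude at each b is S0 * model(b) * (1 + eps) with eps
#' Gaussian of SD equal to the CRLB fraction at that b (linear
#' interpolation in b between the b ~ 0 and b_max settings), truncated so
#' amplitudes never go non-positive, then direction-averaged.
#'
#' @param model Forward model name.
#' @param pars Named ground-truth parameter vector.
#' @param protocol A `dmrs_protocol`.
#' @param crlb_b0,crlb_bmax Relative noise SD at the protocol's lowest and
#'   highest b.
#' @param s0 True scale factor.
#' @param seed Integer seed.
#' @param metabolite,region Labels attached to the curve.
#' @return A [decay_curve()].
#' @export
generate_decay <- function(model, pars, protocol, crlb_b0 = 0.03,
                           crlb_bmax = 0.05, s0 = 1, seed = 1,
                           metabolite = NA_character_,
                           region = NA_character_) {
  b <- protocol$b_values
  ndir <- nrow(protocol$directions)
  sig <- as.numeric(model_signal(model, b, pars, warn = FALSE))
  cr <- crlb_at_b(b, range(b), crlb_b0, crlb_bmax)
  withr::with_seed(seed, {
    amp <- matrix(0, length(b), ndir)
    for (j in seq_len(ndir)) {
      amp[, j] <- s0 * sig * (1 + stats::rnorm(length(b), 0, cr))
    }
    amp <- pmax(amp, .Machine$double.eps)
    mu <- rowMeans(amp)
    se <- apply(amp, 1, stats::sd) / sqrt(ndir)
    decay_curve(b, mu, se, metabolite = metabolite, region = region)
  })
}

#' Generate a synthetic cohort
#'
#' Draws ages and sexes, per-(subject, region) tissue fractions with the
#' configured age trend (applied to the fGM mean, then renormalized to sum
#' to one), and per-metabolite noisy decay curves from the ground-truth
#' model with parameters linearly displaced by age. Every random substream
#' derives deterministically from the master seed, so two runs with the
#' same config are identical.
#'
#' @param config A [cohort_config()].
#' @return A list of subject records (one per subject x region), each a
#'   list with `subject_id`, `age`, `sex`, `region`, `fGM`, `fWM`, `fCSF`,
#'   `fgm_fwm`, `curves` (named list of [decay_curve()]) and `truth`
#'   (named list of generating parameter vectors).
#' @export
generate_cohort <- function(config) {
  ages <- withr::with_seed(derive_seed(config$seed, 1), {
    stats::runif(config$n_subjects, config$age_range[1],
                 config$age_range[2])
  })
  sexes <- withr::with_seed(derive_seed(config$seed, 2), {
    sample(c("F", "M"), config$n_subjects, replace = TRUE)
  })
  bmax <- max(config$protocol$b_values)
  records <- list()
  k <- 0L
  for (i in seq_len(config$n_subjects)) {
    for (ri in seq_along(config$regions)) {
      rg <- config$regions[ri]
      tis <- config$tissue[[rg]]
      fr <- withr::with_seed(derive_seed(config$seed, 3, i, ri), {
        # linear fGM trend: +decline/2 at the youngest age, -decline/2 at
        # the oldest, so the fGM/fWM ratio declines by ~decline overall
        trend <- 1 + tis$ratio_decline *
          (0.5 - (ages[i] - config$age_range[1]) / diff(config$age_range))
        mu <- tis$mean
        mu["fGM"] <- mu["fGM"] * trend
        f <- stats::rnorm(3, mu, tis$sd)
        f <- pmin(pmax(f, 0.01), 1)
        f / sum(f)
      })
      names(fr) <- c("fGM", "fWM", "fCSF")
      curves <- list()
      truth <- list()
      for (mi in seq_along(config$metabolites)) {
        met <- config$metabolites[mi]
        pars <- truth_at_age(config, rg, met, ages[i])
        curves[[met]] <- generate_decay(
          config$model, pars, config$protocol,
          crlb_b0 = config$crlb$b0,
          crlb_bmax = config$crlb$bmax[[rg]][[met]],
          s0 = 1, seed = derive_seed(config$seed, 4, i, ri, mi),
          metabolite = met, region = rg)
        truth[[met]] <- pars
      }
      k <- k + 1L
      records[[k]] <- list(
        subject_id = sprintf("S%03d", i), age = ages[i], sex = sexes[i],
        region = rg, fGM = unname(fr["fGM"]), fWM = unname(fr["fWM"]),
        fCSF = unname(fr["fCSF"]),
        fgm_fwm = unname(fr["fGM"] / fr["fWM"]),
        curves = curves, truth = truth)
    }
  }
  records
}

#' Tissue-fraction table of a cohort
#'
#' @param records Output of [generate_cohort()].
#' @return Data.frame (subject_id, age, sex, region, fGM, fWM, fCSF,
#'   fgm_fwm).
#' @export
cohort_fractions <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(subject_id = r$subject_id, age = r$age, sex = r$sex,
               region = r$region, fGM = r$fGM, fWM = r$fWM, fCSF = r$fCSF,
               fgm_fwm = r$fgm_fwm, stringsAsFactors = FALSE)
  }))
}

#' Generate transient-level synthetic spectra for one condition set
#'
#' Each transient is a sum of Lorentzian peaks (default singlets at 2.01,
#' 3.03 and 3.22 ppm with ~4.6 Hz linewidth) attenuated by the forward
#' model at its (b, direction), plus complex Gaussian spectral noise sized
#' so the reference-peak height at the lowest b hits the target spectral
#' SNR. Per-transient random zero-order phase and frequency offsets are
#' applied, and a configured fraction of transients is amplitude-corrupted
#' (halved) to emulate motion.
#'
#' @param model Forward model name.
#' @param pars Named parameter vector, or a named list per peak label.
#' @param protocol A `dmrs_protocol`.
#' @param snr_b0 Target spectral SNR (reference peak height / spectral
#'   noise SD) at the lowest b.
#' @param linewidth Lorentzian full width at half maximum in Hz.
#' @param peaks Named ppm centers of the simulated peaks.
#' @param peak_amps Relative peak amplitudes (same names as `peaks`).
#' @param phase_sd Per-transient zero-order phase jitter SD in radians.
#' @param drift_sd Per-transient frequency offset SD in Hz.
#' @param corrupt_frac Fraction of transients amplitude-corrupted.
#' @param corrupt_scale Amplitude multiplier of corrupted transients.
#' @param n_points Complex points per spectrum.
#' @param bandwidth Spectral bandwidth in Hz.
#' @param seed Integer seed.
#' @return A [transient_set()].
#' @export
generate_transients <- function(model, pars, protocol, snr_b0 = 20,
                                linewidth = 4.6,
                                peaks = c(tNAA = 2.01, tCr = 3.03,
                                          tCho = 3.22),
                                peak_amps = c(tNAA = 1, tCr = 0.8,
                                              tCho = 0.3),
                                phase_sd = 0, drift_sd = 0,
                                corrupt_frac = 0, corrupt_scale = 0.5,
                                n_points = 2048, bandwidth = 3000,
                                seed = 1) {
  f0 <- 127.73
  center <- 4.7
  b <- protocol$b_values
  ndir <- nrow(protocol$directions)
  ntr <- protocol$transients_per_condition
  t_s <- (seq_len(n_points) - 1) / bandwidth
  decay_t <- exp(-pi * linewidth * t_s)

  par_list <- if (is.list(pars)) pars else
    stats::setNames(rep(list(pars), length(peaks)), names(peaks))
  att <- sapply(names(peaks), function(pk) {
    as.numeric(model_signal(model, b, par_list[[pk]], warn = FALSE))
  })  # [n_b x n_peaks]
  att <- matrix(att, nrow = length(b))

  base_fid <- function(ib) {
    fid <- complex(real = rep(0, n_points))
    for (j in seq_along(peaks)) {
      fhz <- (peaks[j] - center) * f0
      fid <- fid + peak_amps[j] * att[ib, j] *
        exp(2i * pi * fhz * t_s) * decay_t
    }
    fid
  }
  # noise scale from the noiseless lowest-b reference peak height
  s0spec <- spec_from_fid(base_fid(1L))
  ppm <- ppm_axis(n_points, bandwidth, f0, center)
  refwin <- abs(ppm - 2.01) <= 0.1
  sigma <- max(Mod(s0spec[refwin])) / snr_b0

  withr::with_seed(seed, {
    spectra <- array(0 + 0i, c(n_points, length(b), ndir, ntr))
    for (ib in seq_along(b)) for (id in seq_len(ndir)) {
      fid0 <- base_fid(ib)
      for (it in seq_len(ntr)) {
        fid <- fid0
        if (corrupt_frac > 0 && stats::runif(1) < corrupt_frac) {
          fid <- fid * corrupt_scale
        }
        if (drift_sd > 0) {
          fid <- fid * exp(2i * pi * stats::rnorm(1, 0, drift_sd) * t_s)
        }
        if (phase_sd > 0) {
          fid <- fid * exp(1i * stats::rnorm(1, 0, phase_sd))
        }
        s <- spec_from_fid(fid)
        if (sigma > 0 && snr_b0 < Inf) {
          s <- s + complex(real = stats::rnorm(n_points, 0, sigma),
                           imaginary = stats::rnorm(n_points, 0, sigma))
        }
        spectra[, ib, id, it] <- s
      }
    }
    transient_set(spectra, b, bandwidth = bandwidth, f0 = f0,
                  center_ppm = center, ref_ppm = 2.01)
  })
}
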