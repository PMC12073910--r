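canonical_region <- function(x) {
  lut <- c(cerebellum = "cerebellum", pcc = "PCC")
  out <- lut[tolower(trimws(x))]
  if (any(is.na(out))) {
    stop("unknown region label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

canonical_metabolite <- function(x) {
  lut <- c(tnaa = "tNAA", tcho = "tCho", tcr = "tCr")
  out <- lut[tolower(trimws(x))]
  if (any(is.na(out))) {
    stop("unknown metabolite label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

csv_header_comment <- function(seed = NA) {
  sprintf("# dmrsage v%s | b in ms/um^2, diffusivities in um^2/ms | seed=%s",
          as.character(utils::packageVersion("dmrsage")), seed)
}

#' Write a cohort of decay curves to tidy CSV
#'
#' One row per (subject, region, metabolite, b, direction-or-"avg") with
#' columns subject_id, age, sex, region, metabolite, b_value, direction,
#' amplitude, amplitude_sd. Direction-averaged curves are written with
#' direction "avg". A comment line records the package version, units and
#' seed.
#'
#' @param records Subject records as produced by [generate_cohort()].
#' @param path Output file path.
#' @param seed Seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_decay_csv <- function(records, path, seed = NA) {
  rows <- list()
  k <- 0L
  for (rec in records) {
    for (met in names(rec$curves)) {
      cv <- rec$curves[[met]]
      k <- k + 1L
      rows[[k]] <- data.frame(
        subject_id = rec$subject_id, age = rec$age, sex = rec$sex,
        region = rec$region, metabolite = met, b_value = cv$b,
        direction = "avg", amplitude = cv$amplitude,
        amplitude_sd = cv$sd, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csv_header_comment(seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read decay curves from tidy CSV
#'
#' Expects the schema written by [write_decay_csv()] (subject_id, age, sex,
#' region, metabolite, b_value, direction, amplitude, amplitude_sd); rows
#' with per-direction amplitudes (direction other than "avg") are
#' direction-averaged on load. Region and metabolite labels are folded to
#' the canonical spellings (cerebellum/PCC, tNAA/tCho/tCr). A schema
#' mismatch names the missing column; non-positive amplitudes are a
#' validation error.
#'
#' @param path CSV file path (comment lines starting with `#` ignored).
#' @return A list of subject records (subject_id, age, sex, region,
#'   `curves`), compatible with [fit_cohort()].
#' @export
read_decay_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "sex", "region", "metabolite", "b_value",
            "direction", "amplitude", "amplitude_sd")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("decay CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$amplitude)) || any(df$amplitude <= 0)) {
    stop("decay CSV contains non-positive amplitudes", call. = FALSE)
  }
  df$region <- canonical_region(df$region)
  df$metabolite <- canonical_metabolite(df$metabolite)

  records <- list()
  k <- 0L
  for (sid in unique(df$subject_id)) {
    ds <- df[df$subject_id == sid, ]
    for (rg in unique(ds$region)) {
      dr <- ds[ds$region == rg, ]
      curves <- list()
      for (met in unique(dr$metabolite)) {
        dm <- dr[dr$metabolite == met, ]
        bs <- sort(unique(dm$b_value))
        amp <- vapply(bs, function(b) mean(dm$amplitude[dm$b_value == b]),
                      numeric(1))
        sdv <- vapply(bs, function(b) {
          v <- dm[dm$b_value == b, ]
          if (nrow(v) > 1) stats::sd(v$amplitude) / sqrt(nrow(v))
          else v$amplitude_sd[1]
        }, numeric(1))
        curves[[met]] <- decay_curve(bs, amp, sdv, metabolite = met,
                                     region = rg)
      }
      nb <- lengths(lapply(curves, `[[`, "b"))
      if (length(unique(nb)) > 1) {
        warning(sprintf("subject %s/%s: unequal b coverage across %s",
                        sid, rg, paste(names(curves), collapse = ",")),
                call. = FALSE)
      }
      k <- k + 1L
      records[[k]] <- list(subject_id = as.character(sid),
                           age = dr$age[1], sex = dr$sex[1], region = rg,
                           curves = curves)
    }
  }
  records
}

#' Write / read the tidy cohort estimate table
#'
#' The table produced by [fit_cohort()], with a header comment carrying
#' units and the seed.
#' @param table Cohort table (data.frame).
#' @param path CSV path.
#' @param seed Seed recorded in the header comment.
#' @return `path` (write) or the table (read).
#' @export
write_cohort_csv <- function(table, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(csv_header_comment(seed), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read / write a run configuration as YAML
#'
#' The serializable subset of [cohort_config()] plus statistics options
#' and the master seed; reading reconstructs a `cohort_config`.
#' @param config A `cohort_config`.
#' @param path YAML file path.
#' @return `path` (write) or a `cohort_config` (read).
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$protocol <- list(
    b_values = x$protocol$b_values,
    directions = apply(x$protocol$directions, 1, identity,
                       simplify = FALSE),
    delta_eff = x$protocol$delta_eff, Delta_eff = x$protocol$Delta_eff,
    transients_per_condition = x$protocol$transients_per_condition)
  x$age_slopes <- as.list(x$age_slopes)
  # single-element named vectors would lose their names in YAML
  x$ref_params <- lapply(x$ref_params, function(r) lapply(r, as.list))
  x$tissue <- lapply(x$tissue, function(tt) {
    list(mean = as.list(tt$mean), sd = as.list(tt$sd),
         ratio_decline = tt$ratio_decline)
  })
  x$crlb$bmax <- lapply(x$crlb$bmax, as.list)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  proto <- dmrs_protocol(
    b_values = unlist(x$protocol$b_values),
    directions = do.call(rbind, x$protocol$directions),
    delta_eff = x$protocol$delta_eff, Delta_eff = x$protocol$Delta_eff,
    transients_per_condition = x$protocol$transients_per_condition)
  cohort_config(
    n_subjects = x$n_subjects, age_range = unlist(x$age_range),
    regions = unlist(x$regions), metabolites = unlist(x$metabolites),
    model = x$model,
    ref_params = lapply(x$ref_params, function(r) lapply(r, unlist)),
    age_slopes = unlist(x$age_slopes), ref_age = x$ref_age,
    tissue = lapply(x$tissue, function(tt) {
      list(mean = unlist(tt$mean), sd = unlist(tt$sd),
           ratio_decline = tt$ratio_decline)
    }),
    crlb = list(b0 = x$crlb$b0,
                bmax = lapply(x$crlb$bmax, unlist)),
    protocol = proto, seed = x$seed)
}

#' Assemble a Markdown summary of a trajectory run
#'
#' Counts of fitted cells, exclusions by reason, and the cells significant
#' at the Bonferroni-corrected threshold.
#'
#' @param suite Output of [run_trajectory_suite()].
#' @param path Output `.md` path.
#' @return `path`, invisibly.
#' @export
render_report <- function(suite, path) {
  g <- suite$grid
  lines <- c(
    "# dMRS age-trajectory report", "",
    sprintf("- cells analyzed: %d (of %d)", sum(g$analyzable), nrow(g)),
    sprintf("- estimates excluded at the lower bound or invalid: %d",
            nrow(suite$exclusions)),
    sprintf("- Bonferroni-corrected t-test threshold: %.5f",
            suite$threshold),
    sprintf("- cells significant at the corrected threshold: %d",
            sum(g$t_significant %in% TRUE)),
    ""
  )
  sig <- g[g$t_significant %in% TRUE, ]
  if (nrow(sig)) {
    lines <- c(lines, "## Significant cells", "",
               sprintf("- %s / %s / %s / %s (t p = %.4g)", sig$region,
                       sig$metabolite, sig$model, sig$parameter, sig$t_p),
               "")
  }
  if (nrow(suite$exclusions)) {
    tab <- table(suite$exclusions$reason)
    lines <- c(lines, "## Exclusions by reason", "",
               sprintf("- %s: %d", names(tab), as.integer(tab)), "")
  }
  writeLines(lines, path)
  invisible(path)
}
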