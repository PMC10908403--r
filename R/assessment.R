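#' Correlation of an index with the reference stiffness
#'
#' Pearson's product-moment and Spearman's rank correlation (average ranks
#' for ties) between per-subject index values and the reference aortic
#' Young's modulus, after dropping pairs with missing values.
#'
#' @param index_values per-subject index values (NA allowed).
#' @param e_ao per-subject reference `E_Ao` in Pa.
#' @param cohort label (`"all"`, `"young_25"`, `"elderly_75"`, ...).
#' @param index name of the index.
#' @return object of class `va_correlation`: list with `index`, `cohort`,
#'   `r_s`, `r_p`, `n`.
#' @export
correlate <- function(index_values, e_ao, cohort = "all", index = "") {
  if (length(index_values) != length(e_ao))
    stop("index values and E_Ao must have equal length")
  ok <- is.finite(index_values) & is.finite(e_ao)
  x <- index_values[ok]; y <- e_ao[ok]
  if (length(x) < 3) stop("fewer than 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance; correlation undefined")
  structure(list(index = index, cohort = cohort,
                 r_s = cor(x, y, method = "spearman"),
                 r_p = cor(x, y, method = "pearson"),
                 n = length(x)),
            class = "va_correlation")
}

#' @export
print.va_correlation <- function(x, ...) {
  cat(sprintf("<va_correlation> %s [%s]: r_s=%.3f, r_p=%.3f, n=%d\n",
              x$index, x$cohort, x$r_s, x$r_p, x$n))
  invisible(x)
}

#' Bland-Altman agreement
#'
#' Differences `d = measured - reference`; the bias is their mean and the
#' limits of agreement are `bias +/- 1.96 SD(d)`.  The SD is the population
#' (divide-by-n) standard deviation by default; set `sample_sd = TRUE` for
#' the n-1 convention.
#'
#' @param measured,reference numeric vectors of equal length (n >= 2).
#' @param sample_sd use the sample (n-1) SD instead of the population SD.
#' @return object of class `va_bland_altman`: `bias`, `loa_half_width`
#'   (`1.96 * SD`), `differences`, `means`, `n`.
#' @export
bland_altman <- function(measured, reference, sample_sd = FALSE) {
  if (length(measured) != length(reference))
    stop("measured and reference must have equal length")
  ok <- is.finite(measured) & is.finite(reference)
  d <- measured[ok] - reference[ok]
  if (length(d) < 2) stop("need at least 2 complete pairs")
  s <- if (sample_sd) sd(d) else sqrt(mean((d - mean(d))^2))
  structure(list(bias = mean(d), loa_half_width = 1.96 * s,
                 differences = d,
                 means = (measured[ok] + reference[ok]) / 2,
                 n = length(d)),
            class = "va_bland_altman")
}

#' @export
print.va_bland_altman <- function(x, ...) {
  cat(sprintf("<va_bland_altman> bias=%.4g, 1.96SD=%.4g, n=%d\n",
              x$bias, x$loa_half_width, x$n))
  invisible(x)
}

#' @export
plot.va_bland_altman <- function(x, ...) {
  plot(x$means, x$differences, xlab = "mean of methods",
       ylab = "difference (measured - reference)", ...)
  abline(h = x$bias, lty = 1)
  abline(h = x$bias + c(-1, 1) * x$loa_half_width, lty = 2)
  invisible(x)
}

#' Relative sensitivity index
#'
#' For each input parameter, the mean signed relative change of an index
#' when the parameter is perturbed by +1 SD and -1 SD from its baseline,
#' across the age-decade baseline subjects:
#' `I = mean( (V - Vbar)/Vbar * (1/v) ) * 100` with `v = +1` for the +1 SD
#' run and `v = -1` for the -1 SD run.  A symmetric response (same sign in
#' both directions) therefore cancels to 0.
#'
#' @param values_by_perturbation data frame with columns `age`, `parameter`,
#'   `direction` (+1 or -1) and `value` (the index under the perturbation).
#' @param baselines data frame with columns `age` and `value` (the index at
#'   baseline for that age).
#' @param index name of the index.
#' @return data frame of class `va_sensitivity`: one row per parameter with
#'   columns `index`, `parameter`, `I` (percent), `n_runs`.
#' @export
sensitivity_index <- function(values_by_perturbation, baselines, index = "") {
  stopifnot(all(c("age", "parameter", "direction", "value") %in%
                  names(values_by_perturbation)),
            all(c("age", "value") %in% names(baselines)))
  if (any(baselines$value == 0)) stop("baseline index value is zero")
  vb <- baselines$value[match(values_by_perturbation$age, baselines$age)]
  if (anyNA(vb)) stop("perturbation age without a matching baseline")
  contrib <- (values_by_perturbation$value - vb) / vb *
    (1 / values_by_perturbation$direction) * 100
  agg <- tapply(contrib, values_by_perturbation$parameter, mean)
  cnt <- tapply(contrib, values_by_perturbation$parameter, length)
  out <- data.frame(index = index, parameter = names(agg),
                    I = as.numeric(agg), n_runs = as.integer(cnt),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("va_sensitivity", "data.frame")
  out
}

# the six perturbed model inputs, grouped as cardiac vs vascular properties
SENSITIVITY_PARAMETERS <- data.frame(
  parameter = c("heart rate", "stroke volume", "duration of systole",
                "large artery diameter", "input PWV",
                "peripheral vascular resistance"),
  group = rep(c("cardiac", "vascular"), each = 3),
  spec_field = c("hr", "stroke_volume_scale", "systole_fraction",
                 "diameter_scale", "stiffness_scale", "pvr_scale"),
  rel_sd = c(0.10, 0.15, 0.08, 0.10, 0.15, 0.20),
  stringsAsFactors = FALSE)

#' Sensitivity analysis on synthetic baseline subjects
#'
#' Builds the baseline subject of each age decade, perturbs each of the six
#' model inputs (heart rate, stroke volume, duration of systole; large
#' artery diameter, input PWV via the stiffness scale, peripheral vascular
#' resistance) by +/- 1 SD, recomputes all indices, and aggregates the
#' relative sensitivity index per (index, parameter) with
#' [sensitivity_index()].
#'
#' @param spec a [synthetic_spec] describing the baseline subject.
#' @param ages baseline ages (default the six decades 25, 35, ..., 75).
#' @param parameters data frame like `SENSITIVITY_PARAMETERS` (columns
#'   `parameter`, `spec_field`, `rel_sd`).
#' @param config index configuration passed to [compute_panel()].
#' @return data frame of class `va_sensitivity` with one row per
#'   (index, parameter).
#' @export
run_sensitivity <- function(spec, ages = seq(25, 75, by = 10),
                            parameters = SENSITIVITY_PARAMETERS,
                            config = list()) {
  panel_for <- function(sp, age) {
    ms <- make_subject(sp, age)
    unclass(compute_panel(ms$subject, config))
  }
  base <- lapply(ages, function(a) panel_for(spec, a))
  rows <- list()
  for (k in seq_len(nrow(parameters))) {
    fld <- parameters$spec_field[k]
    for (dir in c(1, -1)) {
      sp <- spec
      sp[[fld]] <- spec[[fld]] * (1 + dir * parameters$rel_sd[k])
      for (j in seq_along(ages)) {
        pan <- panel_for(sp, ages[j])
        rows[[length(rows) + 1]] <- data.frame(
          age = ages[j], parameter = parameters$parameter[k],
          direction = dir, index = index_names(),
          value = as.numeric(pan[index_names()]),
          stringsAsFactors = FALSE)
      }
    }
  }
  pert <- do.call(rbind, rows)
  out <- lapply(index_names(), function(nm) {
    b <- data.frame(age = ages,
                    value = vapply(seq_along(ages),
                                   function(j) base[[j]][[nm]], 0))
    p <- pert[pert$index == nm, ]
    ok <- is.finite(p$value) & is.finite(b$value[match(p$age, b$age)])
    if (!all(is.finite(b$value)) || !any(ok)) return(NULL)
    sensitivity_index(p[ok, ], b, index = nm)
  })
  res <- do.call(rbind, out)
  res <- merge(res, parameters[, c("parameter", "group")], by = "parameter",
               sort = FALSE)
  res <- res[order(res$index, res$parameter), ]
  rownames(res) <- NULL
  class(res) <- c("va_sensitivity", "data.frame")
  res
}

#' Panels and correlations for a whole population
#'
#' @param population a `synthetic_population` or a list with `subjects` and
#'   `truths`.
#' @param config passed to [compute_panel()].
#' @return data frame with one row per subject: `id`, `age`, `E_Ao`,
#'   `aoPWVt` and one column per index.
#' @export
population_panels <- function(population, config = list()) {
  subs <- population$subjects
  trs <- population$truths
  rows <- lapply(seq_along(subs), function(i) {
    pan <- as.data.frame(compute_panel(subs[[i]], config))
    cbind(data.frame(id = subs[[i]]$id, age = subs[[i]]$age,
                     E_Ao = trs[[i]]$E_Ao, aoPWVt = trs[[i]]$aoPWVt,
                     stringsAsFactors = FALSE),
          pan)
  })
  do.call(rbind, rows)
}

# correlation table over cohorts, sorted by descending spearman in "all"
correlation_table <- function(panels, cohorts = TRUE) {
  mk <- function(df, label) {
    out <- lapply(index_names(), function(nm) {
      r <- tryCatch(correlate(df[[nm]], df$E_Ao, label, nm),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(index = nm, cohort = label, r_s = r$r_s, r_p = r$r_p,
                 n = r$n, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  tabs <- list(mk(panels, "all"))
  if (cohorts) {
    young <- panels[panels$age == 25, ]
    old <- panels[panels$age == 75, ]
    if (nrow(young) >= 3) tabs <- c(tabs, list(mk(young, "young_25")))
    if (nrow(old) >= 3) tabs <- c(tabs, list(mk(old, "elderly_75")))
  }
  tab <- do.call(rbind, tabs)
  all_rs <- tab$r_s[tab$cohort == "all"][match(tab$index,
                                               tab$index[tab$cohort == "all"])]
  tab <- tab[order(tab$cohort, -abs(all_rs)), ]
  rownames(tab) <- NULL
  tab
}

#' Noise-robustness experiment
#'
#' For each SNR level, adds independent white Gaussian noise to every
#' waveform of every subject, band-pass filters, recomputes all 19 index
#' panels and correlates them with the reference `E_Ao`.  The `Inf` level
#' is the clean pipeline (no noise, no filtering).
#'
#' @param population a `synthetic_population` (or compatible list).
#' @param snr_levels SNR levels in dB (default `c(Inf, 30, 20, 15)`).
#' @param seed integer seed; noise is drawn independently per signal.
#' @param config passed to [compute_panel()].
#' @return data frame with columns `snr_db`, `index`, `cohort`, `r_s`,
#'   `r_p`, `n`.
#' @export
noise_robustness <- function(population, snr_levels = c(Inf, 30, 20, 15),
                             seed = 1, config = list()) {
  out <- list()
  for (li in seq_along(snr_levels)) {
    snr <- snr_levels[li]
    pop2 <- population
    if (is.finite(snr)) {
      for (i in seq_along(pop2$subjects)) {
        pop2$subjects[[i]] <- perturb_subject(
          pop2$subjects[[i]], snr,
          seed = seed + 7919L * li + 104729L * i)
      }
    }
    panels <- population_panels(pop2, config)
    tab <- correlation_table(panels, cohorts = FALSE)
    tab$snr_db <- snr
    out[[length(out) + 1]] <- tab
  }
  res <- do.call(rbind, out)
  res[, c("snr_db", "index", "cohort", "r_s", "r_p", "n")]
}

#' Run the full vascular-aging assessment
#'
#' End-to-end pipeline on a population: compute all index panels, correlate
#' each index with the reference aortic Young's modulus (whole cohort plus
#' young/elderly subgroups when present), Bland-Altman agreement of the six
#' PWV indices against the theoretical aortic-root PWV, the sensitivity
#' analysis on baseline subjects, and optionally the noise-robustness
#' experiment.  Results are returned as a classed bundle and, when `out_dir`
#' is given, written as CSV tables (`panels.csv`, `correlations.csv`,
#' `bland_altman.csv`, `sensitivity.csv`, `noise_robustness.csv`).
#'
#' @param population a `synthetic_population`, or `NULL` to generate one
#'   from `spec`.
#' @param spec a [synthetic_spec] used when `population` is `NULL` and for
#'   the sensitivity analysis.
#' @param snr_levels SNR levels for the noise experiment; `NULL` skips it.
#' @param sensitivity run the sensitivity analysis (logical).
#' @param seed integer seed for the noise experiment.
#' @param out_dir optional output directory for CSV tables.
#' @param config passed to [compute_panel()].
#' @return object of class `va_assessment` with elements `panels`,
#'   `correlations`, `bland_altman`, `sensitivity`, `noise`.
#' @export
run_full_assessment <- function(population = NULL, spec = synthetic_spec(),
                                snr_levels = c(Inf, 30, 20, 15),
                                sensitivity = TRUE,
                                seed = spec$seed, out_dir = NULL,
                                config = list()) {
  if (is.null(population)) population <- make_population(spec)
  panels <- population_panels(population, config)
  correlations <- correlation_table(panels)

  pwv_idx <- c("aoPWV", "cfPWV", "baPWV", "cbPWV", "crPWV", "ftPWV")
  ba <- lapply(pwv_idx, function(nm)
    tryCatch(bland_altman(panels[[nm]], panels$aoPWVt),
             error = function(e) NULL))
  names(ba) <- pwv_idx
  ba_tab <- do.call(rbind, lapply(pwv_idx, function(nm) {
    b <- ba[[nm]]
    if (is.null(b)) return(NULL)
    data.frame(index = nm, bias = b$bias, loa_half_width = b$loa_half_width,
               n = b$n, stringsAsFactors = FALSE)
  }))

  sens <- if (isTRUE(sensitivity)) run_sensitivity(spec, config = config)
  else NULL
  noise <- if (!is.null(snr_levels))
    noise_robustness(population, snr_levels, seed = seed, config = config)
  else NULL

  res <- structure(list(panels = panels, correlations = correlations,
                        bland_altman = ba_tab, bland_altman_objects = ba,
                        sensitivity = sens, noise = noise,
                        spec = population$spec),
                   class = "va_assessment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, file) if (!is.null(df))
      write.csv(df, file.path(out_dir, file), row.names = FALSE, na = "")
    wr(panels, "panels.csv")
    wr(correlations, "correlations.csv")
    wr(ba_tab, "bland_altman.csv")
    wr(sens, "sensitivity.csv")
    wr(noise, "noise_robustness.csv")
  }
  res
}

#' @export
print.va_assessment <- function(x, ...) {
  cat(sprintf("<va_assessment> %d subjects\n", nrow(x$panels)))
  cat("\nTop correlations with E_Ao (all subjects):\n")
  tab <- x$correlations[x$correlations$cohort == "all", ]
  print(utils::head(tab[, c("index", "r_s", "r_p", "n")], 8), row.names = FALSE)
  if (!is.null(x$bland_altman)) {
    cat("\nBland-Altman vs theoretical aoPWV (m/s):\n")
    print(x$bland_altman, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.va_assessment <- function(object, ...) {
  cat(sprintf("Vascular-aging assessment of %d subjects (ages %.0f-%.0f yr)\n",
              nrow(object$panels), min(object$panels$age),
              max(object$panels$age)))
  cat("\nCorrelations with E_Ao:\n")
  print(object$correlations, row.names = FALSE)
  if (!is.null(object$sensitivity)) {
    cat("\nSensitivity (percent change per +1SD input change):\n")
    print(object$sensitivity, row.names = FALSE)
  }
  if (!is.null(object$noise)) {
    cat("\nNoise robustness (Spearman r_s by SNR):\n")
    wide <- stats::reshape(object$noise[, c("snr_db", "index", "r_s")],
                           idvar = "index", timevar = "snr_db",
                           direction = "wide")
    print(wide, row.names = FALSE)
  }
  invisible(object)
}
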