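#' Plate-reader trace container
#'
#' @param times_s Strictly increasing sampling times (seconds).
#' @param a340 Absorbance at 340 nm, one value per time.
#' @param well Well label.
#' @param enzyme_conc Enzyme concentration (uM).
#' @param aap,aap_conc Activating protein label and concentration (uM).
#' @param dna_conc DNA concentration (ug/ml).
#' @param is_control No-enzyme control flag.
#' @return Object of class `plate_trace`.
#' @export
plate_trace <- function(times_s, a340, well = "A1", enzyme_conc = 0,
                        aap = "none", aap_conc = 0, dna_conc = 0,
                        is_control = FALSE) {
  if (length(times_s) < 2 || length(times_s) != length(a340))
    stop_input("need >= 2 aligned (time, A340) samples")
  if (any(diff(times_s) <= 0)) stop_input("times must be strictly increasing")
  structure(list(times_s = as.numeric(times_s), a340 = as.numeric(a340),
                 well = well, enzyme_conc = enzyme_conc, aap = aap,
                 aap_conc = aap_conc, dna_conc = dna_conc,
                 is_control = is_control),
            class = "plate_trace")
}

#' @export
print.plate_trace <- function(x, ...) {
  cat(sprintf("<plate_trace %s: %d reads over %.2f h, enzyme %g uM, DNA %g ug/ml, AAP %s %g uM%s>\n",
              x$well, length(x$times_s), diff(range(x$times_s)) / 3600,
              x$enzyme_conc, x$dna_conc, x$aap, x$aap_conc,
              if (x$is_control) " [control]" else ""))
  invisible(x)
}

#' Simulate an NADH-coupled ATPase assay trace
#'
#' Absorbance model: `A340(t) = A0 - eps * l * [ADP](t) + drift * t + noise`
#' with `[ADP](t) = specific_activity * enzyme_conc * t` (one NADH oxidized
#' per ADP through the pyruvate kinase / lactate dehydrogenase couple) and
#' `A0 = eps * l * [NADH]_0`. The paired no-enzyme control carries the same
#' drift and noise level but no enzymatic NADH consumption. Errors if the
#' requested turnover would exhaust the starting NADH.
#'
#' @param truth A [kinetic_truth()] object.
#' @param duration_hr Assay duration (hours).
#' @param interval_s Sampling interval (seconds); the default assay runs 2 h
#'   at 30 s intervals (241 reads including t = 0).
#' @param seed Integer seed for the read noise.
#' @param constants An [assay_constants()] object.
#' @param well Sample well label; the control well gets a `_ctrl` suffix.
#' @return List with elements `sample` and `control`, both [plate_trace()].
#' @export
simulate_atpase_trace <- function(truth, duration_hr = 2, interval_s = 30,
                                  seed = 1L, constants = assay_constants(),
                                  well = "A1") {
  if (!inherits(truth, "kinetic_truth")) stop_input("truth must be a kinetic_truth")
  if (duration_hr <= 0 || interval_s <= 0)
    stop_input("duration and interval must be > 0")
  el <- constants$epsilon_nadh * constants$light_path
  nadh0 <- constants$nadh_start_mM * 1e-3                  # M
  adp_end <- truth$specific_activity * truth$enzyme_conc * 1e-6 * duration_hr
  if (adp_end > nadh0)
    stop_input("NADH exhausted before the end of the trace; shorten the assay")

  t_s <- seq(0, duration_hr * 3600, by = interval_s)
  t_hr <- t_s / 3600
  a0 <- el * nadh0
  adp <- truth$specific_activity * truth$enzyme_conc * 1e-6 * t_hr
  with_seed(seed, {
    noise_s <- rnorm(length(t_s), 0, truth$noise_sd)
    noise_c <- rnorm(length(t_s), 0, truth$noise_sd)
    list(sample = plate_trace(t_s, a0 - el * adp + truth$control_drift * t_hr +
                                noise_s,
                              well = well, enzyme_conc = truth$enzyme_conc,
                              aap = truth$aap, aap_conc = truth$aap_conc,
                              dna_conc = truth$dna_conc),
         control = plate_trace(t_s, a0 + truth$control_drift * t_hr + noise_c,
                               well = paste0(well, "_ctrl"),
                               enzyme_conc = 0, aap = truth$aap,
                               aap_conc = truth$aap_conc,
                               dna_conc = truth$dna_conc, is_control = TRUE))
  })
}

#' Subtract a no-enzyme control trace
#'
#' Pointwise `A340(sample) - A340(control)`, interpolating the control onto
#' the sample's time grid if the grids differ; removes baseline drift from
#' spontaneous ATP hydrolysis and UV-induced NADH decomposition. Metadata of
#' the sample is preserved.
#'
#' @param sample,control [plate_trace()] objects with overlapping time
#'   ranges.
#' @return A corrected [plate_trace()].
#' @export
subtract_control <- function(sample, control) {
  if (max(control$times_s) < min(sample$times_s) ||
      min(control$times_s) > max(sample$times_s))
    stop_input("sample and control time ranges do not overlap")
  ctrl <- if (length(control$times_s) == length(sample$times_s) &&
              all(control$times_s == sample$times_s)) {
    control$a340
  } else {
    approx(control$times_s, control$a340, xout = sample$times_s,
           rule = 2)$y
  }
  out <- sample
  out$a340 <- sample$a340 - ctrl
  out$is_control <- FALSE
  out
}

#' ADP production rate from an A340 trace
#'
#' Least-squares slope of A340 over the fit window (default: from 300 s,
#' skipping mixing/equilibration, to the end of the trace), inverted through
#' Beer-Lambert: `rate = -slope / (eps * l)`, reported in uM per hour (one
#' NADH oxidized per ADP). A significantly increasing trace yields a warning
#' and a rate floored at 0.
#'
#' @param trace A (control-subtracted) [plate_trace()].
#' @param constants An [assay_constants()] object.
#' @param window `c(t_start, t_end)` in seconds; `Inf` means end of trace.
#' @return Object of class `rate_result`: `adp_rate` (uM/hr), `slope`
#'   (absorbance/hr), `r_squared`, `fit_window`, `n`, plus
#'   `specific_activity` filled by [specific_activity()].
#' @export
adp_rate <- function(trace, constants = assay_constants(),
                     window = c(300, Inf)) {
  sel <- trace$times_s >= window[1] & trace$times_s <= window[2]
  if (sum(sel) < 10) stop_input("need >= 10 samples in the fit window")
  t_hr <- trace$times_s[sel] / 3600
  y <- trace$a340[sel]
  fit <- lm(y ~ t_hr)
  slope <- unname(coef(fit)[2])
  # noiseless synthetic traces fit exactly; summary.lm warns about that
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  rate <- -slope / (constants$epsilon_nadh * constants$light_path) * 1e6
  if (rate < 0) {
    se <- sm$coefficients[2, 2]
    if (slope > 2 * se)
      warning("A340 increases over the fit window; rate floored at 0")
    rate <- 0
  }
  structure(list(adp_rate = rate, slope = slope, r_squared = r2,
                 fit_window = c(min(trace$times_s[sel]),
                                max(trace$times_s[sel])),
                 n = sum(sel), enzyme_conc = trace$enzyme_conc,
                 specific_activity = NA_real_),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("ADP rate %.2f uM/hr (slope %.4g /hr, R2 %.4f, %d reads in [%g, %g] s)\n",
              x$adp_rate, x$slope, x$r_squared, x$n,
              x$fit_window[1], x$fit_window[2]))
  if (!is.na(x$specific_activity))
    cat(sprintf("  specific activity %.2f ATP/enzyme/hr at %g uM enzyme\n",
                x$specific_activity, x$enzyme_conc))
  invisible(x)
}

#' Specific activity: ATP turned over per enzyme per hour
#'
#' @param rate A [adp_rate()] result or a numeric ADP rate in uM/hr.
#' @param enzyme_conc Enzyme concentration (uM, > 0); taken from the trace
#'   metadata when `rate` is a `rate_result`.
#' @return For numeric input, the specific activity (hr^-1); for a
#'   `rate_result`, the object with `specific_activity` filled in.
#' @export
specific_activity <- function(rate, enzyme_conc = NULL) {
  if (inherits(rate, "rate_result")) {
    ec <- enzyme_conc %||% rate$enzyme_conc
    if (is.null(ec) || is.na(ec) || ec <= 0)
      stop_input("enzyme_conc must be > 0")
    rate$specific_activity <- rate$adp_rate / ec
    rate$enzyme_conc <- ec
    rate
  } else {
    if (is.null(enzyme_conc) || enzyme_conc <= 0)
      stop_input("enzyme_conc must be > 0")
    rate / enzyme_conc
  }
}

#' Dose-response fit of enzyme stimulation
#'
#' Fits `activity = c + a * dose / (K + dose)` by least squares (hyperbolic
#' model); the saturation dose is reported as the dose reaching 90% of the
#' plateau increment, i.e. `9 K`. The linear model (for series that do not
#' plateau at the highest tested concentration) returns the least-squares
#' slope instead. Near-constant responses return the constant as plateau
#' with saturation dose 0.
#'
#' @param dose Dose levels (>= 4 for the hyperbolic model).
#' @param response Measured specific activities, aligned with `dose`.
#' @param model `"hyperbolic"` or `"linear"`.
#' @return Object of class `dose_response`: for the hyperbolic model
#'   `baseline` (c), `amplitude` (a), `K`, `plateau` (c + a),
#'   `saturation_dose`, `fitted`, `r_squared`; for the linear model `slope`,
#'   `intercept`, `fitted`, `r_squared`.
#' @export
dose_response <- function(dose, response, model = c("hyperbolic", "linear")) {
  model <- match.arg(model)
  if (length(dose) != length(response)) stop_input("dose and response must align")
  if (model == "linear") {
    fit <- lm(response ~ dose)
    return(structure(list(model = "linear",
                          slope = unname(coef(fit)[2]),
                          intercept = unname(coef(fit)[1]),
                          fitted = fitted(fit),
                          r_squared = suppressWarnings(summary(fit))$r.squared),
                     class = "dose_response"))
  }
  if (length(unique(dose)) < 4)
    stop_input("hyperbolic model needs >= 4 dose levels")
  if (sd(response) < 1e-10 * max(abs(response), 1)) {
    return(structure(list(model = "hyperbolic", baseline = mean(response),
                          amplitude = 0, K = NA_real_,
                          plateau = mean(response), saturation_dose = 0,
                          fitted = rep(mean(response), length(dose)),
                          r_squared = 1),
                     class = "dose_response"))
  }
  start <- list(c0 = min(response), a0 = max(response) - min(response),
                K0 = max(median(dose[dose > 0]), 1e-6))
  fit <- tryCatch(
    nls(response ~ c0 + a0 * dose / (K0 + dose), start = start),
    error = function(e)
      tryCatch(minpack.lm::nlsLM(response ~ c0 + a0 * dose / (K0 + dose),
                                 start = start),
               error = function(e2)
                 stop_input("degenerate dose-response fit: ",
                            conditionMessage(e2))))
  cf <- coef(fit)
  resid <- response - fitted(fit)
  structure(list(model = "hyperbolic",
                 baseline = unname(cf["c0"]), amplitude = unname(cf["a0"]),
                 K = unname(cf["K0"]),
                 plateau = unname(cf["c0"] + cf["a0"]),
                 saturation_dose = 9 * unname(cf["K0"]),
                 fitted = as.numeric(fitted(fit)),
                 r_squared = 1 - sum(resid^2) / sum((response - mean(response))^2)),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  if (x$model == "linear") {
    cat(sprintf("Linear dose-response: slope %.4g, intercept %.4g (R2 %.4f)\n",
                x$slope, x$intercept, x$r_squared))
  } else {
    cat(sprintf("Hyperbolic dose-response: baseline %.3g, plateau %.3g, K %.3g; 90%%-saturation at %.3g (R2 %.4f)\n",
                x$baseline, x$plateau, x$K, x$saturation_dose, x$r_squared))
  }
  invisible(x)
}
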