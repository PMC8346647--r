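## DTG / DSC concordance heuristics.
##
## The pseudo-component count is rationalized by cross-reading the two
## channels: every DTG peak is one reacting stage, and heat-flow (DSC)
## events with no DTG counterpart (e.g. char conversion riding under a
## broad mass-loss shoulder) add further stages.

#' Detect prominent peaks in a rate curve
#'
#' Strict local maxima filtered by topographic prominence.
#'
## Detector-side regularization: a first-order decomposition stage at a
## slow heating rate is at least ~35 K wide (FWHM ~ 2.446 R Tp^2 / E), so
## smoothing a channel over ~15 K before looking for features cannot
## conceal a real stage but removes grid-scale noise wiggles. This smoothing
## lives inside the detectors only - the fitted data are never re-filtered.
.detector_smooth <- function(y, tt, span_K = 15, order = 2) {
  h <- stats::median(diff(tt))
  w <- round(span_K / h)
  if (w %% 2 == 0) w <- w + 1
  w <- min(w, if (length(y) %% 2 == 1) length(y) else length(y) - 1)
  if (w <= order + 1) return(y)
  savitzky_golay(y, window = w, order = order)
}

#' Strict local maxima filtered by topographic prominence and width: a
#' real decomposition stage at a slow heating rate is at least ~35 K wide
#' (the single-first-order-reaction limit), so narrow spikes riding on
#' smoothed noise are rejected by detector-side smoothing plus a minimum
#' width at half prominence.
#'
#' @param curve a [rate_curve()].
#' @param prominence_frac minimum prominence as a fraction of the curve
#'   maximum. The default keeps minor stages (fractions of a few percent
#'   appear as shallow but wide local maxima).
#' @param min_width_K minimum peak width (K) at half prominence.
#' @param smooth_span_K detector-side smoothing length, K (0 disables).
#' @param noise_mult prominence must also exceed this multiple of the
#'   curve's point-noise level, estimated robustly from second differences
#'   (signal curvature contributes orders of magnitude less than noise at
#'   realistic levels, so the floor vanishes on clean curves).
#' @return data.frame with `temperature` (K), `height`, `prominence`,
#'   `width` (K), ordered by temperature (possibly empty).
#' @export
find_dtg_peaks <- function(curve, prominence_frac = 0.02, min_width_K = 10,
                           smooth_span_K = 15, noise_mult = 6) {
  stopifnot(inherits(curve, "rate_curve"))
  empty <- data.frame(temperature = numeric(0), height = numeric(0),
                      prominence = numeric(0), width = numeric(0))
  y <- curve$rate; tt <- curve$temperature
  noise_floor <- if (length(y) > 4)
    noise_mult * stats::mad(diff(y, differences = 2)) / sqrt(6) else 0
  if (smooth_span_K > 0) y <- .detector_smooth(y, tt, smooth_span_K)
  if (max(y) - min(y) <= 0) return(empty)
  idx <- .local_maxima(y)
  if (length(idx) == 0) return(empty)
  prom <- .peak_prominence(y, idx)
  width <- vapply(seq_along(idx), function(k) {
    p <- idx[k]; lev <- y[p] - prom[k] / 2
    il <- p; while (il > 1 && y[il] > lev) il <- il - 1
    ir <- p; while (ir < length(y) && y[ir] > lev) ir <- ir + 1
    tt[ir] - tt[il]
  }, numeric(1))
  keep <- prom >= pmax(prominence_frac * max(y), noise_floor) &
    width >= min_width_K
  data.frame(temperature = tt[idx[keep]], height = y[idx[keep]],
             prominence = prom[keep], width = width[keep])
}

## Thermal events from a DSC-derivative trace.
##
## A thermal bump in heat flow shows up in its temperature derivative as a
## pair of opposite-sign lobes with a zero crossing at the bump apex.
## The detector finds significant lobes (local extrema of the detrended
## derivative), pairs consecutive opposite-sign lobes, and places one
## event at the intervening zero crossing. Lobe order gives the bump
## sign: +then- is a heat-flow maximum (exothermic), -then+ a minimum
## (endothermic). Linear baseline drift is removed up front (it only
## offsets the derivative).
.dsc_events <- function(temperature, derivative, prominence_frac = 0.1,
                        min_sep_K = 5, smooth_span_K = 15) {
  y <- derivative - stats::median(derivative)
  if (smooth_span_K > 0) y <- .detector_smooth(y, temperature, smooth_span_K)
  thr <- prominence_frac * max(abs(y))
  if (!is.finite(thr) || thr <= 0) {
    return(data.frame(temperature = numeric(0), sign = character(0)))
  }
  imax <- .local_maxima(y)
  imin <- .local_maxima(-y)
  ext <- sort(c(imax, imin))
  ext <- ext[abs(y[ext]) >= thr]
  if (length(ext) < 2)
    return(data.frame(temperature = numeric(0), sign = character(0)))
  events <- list()
  i <- 1
  while (i < length(ext)) {
    a <- ext[i]; b <- ext[i + 1]
    ## real lobes flank a >= 25 K wide thermal bump; opposite-sign lobes
    ## closer than min_sep_K are smoothed-noise wiggles
    if (sign(y[a]) != sign(y[b]) &&
        temperature[b] - temperature[a] >= min_sep_K) {
      seg <- a:b
      cross <- which(diff(sign(y[seg])) != 0)
      tc <- if (length(cross) > 0) {
        j <- seg[cross[1]]
        t1 <- temperature[j]; t2 <- temperature[j + 1]
        t1 + (t2 - t1) * abs(y[j]) / (abs(y[j]) + abs(y[j + 1]))
      } else mean(temperature[c(a, b)])
      events[[length(events) + 1]] <-
        data.frame(temperature = tc,
                   sign = if (y[a] > 0) "exo" else "endo")
      i <- i + 2
    } else i <- i + 1
  }
  if (length(events) == 0)
    return(data.frame(temperature = numeric(0), sign = character(0)))
  do.call(rbind, events)
}

#' Suggest the pseudo-component count from DTG/DSC concordance
#'
#' Detects peaks in the DTG curve and thermal events in the DSC
#' derivative independently, matches them within a temperature tolerance,
#' and suggests `n = (DTG peaks) + (unmatched significant DSC events)`:
#' each mass-loss peak is a reacting stage, and a heat event without a
#' resolved mass-loss peak marks a stage buried under a shoulder.
#'
#' @param dtg a [rate_curve()].
#' @param dsc_derivative data.frame with `temperature` (K) and
#'   `derivative` columns, as produced by [preprocess_thermogram()].
#' @param match_tol peak-to-event matching tolerance, K (default 15; the
#'   channels' paired features align within ~5-10 K).
#' @param dtg_prominence prominence threshold for [find_dtg_peaks()].
#' @param dsc_prominence lobe-significance threshold for event detection.
#' @return List with `n_components` (suggested count) and `report`
#'   (data.frame: each feature's temperature in K and C, channel, and
#'   whether it was matched across channels). Flat inputs give 0 with an
#'   empty report.
#' @export
suggest_component_count <- function(dtg, dsc_derivative, match_tol = 15,
                                    dtg_prominence = 0.02,
                                    dsc_prominence = 0.1) {
  stopifnot(inherits(dtg, "rate_curve"))
  pk <- find_dtg_peaks(dtg, dtg_prominence)
  ev <- .dsc_events(dsc_derivative$temperature, dsc_derivative$derivative,
                    dsc_prominence)
  matched_ev <- rep(FALSE, nrow(ev))
  matched_pk <- rep(FALSE, nrow(pk))
  for (j in seq_len(nrow(ev))) {
    if (nrow(pk) == 0) break
    d <- abs(pk$temperature - ev$temperature[j])
    if (min(d) <= match_tol) {
      matched_ev[j] <- TRUE
      matched_pk[which.min(d)] <- TRUE
    }
  }
  report <- rbind(
    if (nrow(pk) > 0)
      data.frame(channel = "dtg", temperature_K = pk$temperature,
                 temperature_C = kelvin_to_celsius(pk$temperature),
                 sign = NA_character_, matched = matched_pk),
    if (nrow(ev) > 0)
      data.frame(channel = "dsc", temperature_K = ev$temperature,
                 temperature_C = kelvin_to_celsius(ev$temperature),
                 sign = ev$sign, matched = matched_ev))
  if (is.null(report))
    report <- data.frame(channel = character(0), temperature_K = numeric(0),
                         temperature_C = numeric(0), sign = character(0),
                         matched = logical(0))
  list(n_components = nrow(pk) + sum(!matched_ev), report = report)
}

#' Classify a thermal event window as endo- or exothermic
#'
#' Removes a linear baseline anchored at the window edges and takes the
#' sign of the mean residual heat flow: positive means exothermic (more
#' heat released than the local trend), negative endothermic. Means
#' smaller than a noise-scaled threshold are `"ambiguous"` (the cautious
#' "possibly endothermic" verdict).
#'
#' @param dsc a [thermogram()] or data.frame with `temperature` (K) and
#'   `heat_flow` (mW, exothermic positive).
#' @param window `c(t_lo, t_hi)`, K, inside the curve's range.
#' @param noise_mult multiple of the standard error of the mean (from a
#'   first-difference noise estimate) below which the call is ambiguous.
#' @return `"endothermic"`, `"exothermic"` or `"ambiguous"`, with
#'   attributes `mean_heat_flow` and `threshold`.
#' @export
classify_thermal_event <- function(dsc, window, noise_mult = 3) {
  tt <- if (inherits(dsc, "thermogram")) dsc$temperature else dsc$temperature
  hf <- if (inherits(dsc, "thermogram")) dsc$heat_flow else dsc$heat_flow
  if (window[1] >= window[2]) .stopf("window must be ordered")
  keep <- tt >= window[1] & tt <= window[2]
  if (sum(keep) < 3) .stopf("window [%.1f, %.1f] K holds fewer than 3 points",
                            window[1], window[2])
  tw <- tt[keep]; hw <- hf[keep]
  ## linear baseline through the window edges
  base <- hw[1] + (hw[length(hw)] - hw[1]) *
    (tw - tw[1]) / (tw[length(tw)] - tw[1])
  resid <- hw - base
  m <- mean(resid)
  noise_sd <- stats::mad(diff(hw)) / sqrt(2)
  thr <- noise_mult * noise_sd / sqrt(length(hw))
  verdict <- if (abs(m) <= thr) "ambiguous" else if (m > 0) "exothermic" else "endothermic"
  structure(verdict, mean_heat_flow = m, threshold = thr)
}
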