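#' Thermal event specification
#'
#' Describes one feature of a synthetic mDSC trace. Glass transitions are
#' sigmoid steps in the reversing heat flow (magnitude = step height, width
#' = onset-to-end span of the transition region); melting, recrystallization
#' and mesophase events are Gaussian peaks in the total heat flow
#' (magnitude = peak area; endotherms negative, exotherms positive).
#'
#' @param kind One of `"glass_transition"`, `"melting"`,
#'   `"recrystallization"`, `"mesophase"`.
#' @param center Event temperature (degC); the analytic inflection point
#'   for a glass transition.
#' @param width Transition span or peak FWHM (degC, > 0).
#' @param magnitude Step height or signed peak area (non-zero; endotherms
#'   negative).
#' @return A `thermal_event` list.
#' @export
thermal_event <- function(kind = c("glass_transition", "melting",
                                   "recrystallization", "mesophase"),
                          center, width, magnitude) {
  kind <- match.arg(kind)
  stopifnot(width > 0, magnitude != 0)
  if (kind == "melting" || kind == "mesophase") {
    if (magnitude > 0)
      stop(kind, " events are endotherms: magnitude must be negative")
  }
  if (kind == "recrystallization" && magnitude < 0)
    stop("recrystallization is an exotherm: magnitude must be positive")
  structure(list(kind = kind, center = center, width = width,
                 magnitude = magnitude),
            class = "thermal_event")
}

# onset/end of a logistic step defined at 1% / 99% of the step height
logistic_scale <- function(width) width / (2 * log(99))

#' Synthesize an mDSC thermogram
#'
#' Builds a reversing heat-flow signal as a sum of logistic steps (one per
#' glass transition; the analytic inflection point of each step equals its
#' specified center) and a total heat-flow signal as the reversing signal
#' plus Gaussian peaks for melting / recrystallization / mesophase events,
#' with i.i.d. Gaussian noise added to both channels.
#'
#' @param events List of [thermal_event()] specifications.
#' @param noise_sd Noise standard deviation (signal units; default 0.002).
#' @param grid Temperature grid in degC (default -90 to 300 by 0.1, the
#'   instrument range emulated).
#' @param seed Integer seed; the trace is reproducible from it.
#' @return A `synthetic_trace` list: `temperature`, `reverse`, `total`,
#'   `ground_truth` (the event list), `seed`.
#' @export
make_thermogram <- function(events, noise_sd = 0.002,
                            grid = seq(-90, 300, by = 0.1), seed = 1L) {
  centers <- vapply(events, `[[`, numeric(1), "center")
  if (any(centers < min(grid) | centers > max(grid)))
    stop("all event centers must lie inside the temperature grid")
  reverse <- numeric(length(grid))
  peaks <- numeric(length(grid))
  for (ev in events) {
    if (ev$kind == "glass_transition") {
      s <- logistic_scale(ev$width)
      reverse <- reverse + ev$magnitude / (1 + exp(-(grid - ev$center) / s))
    } else {
      sd_pk <- ev$width / (2 * sqrt(2 * log(2)))
      peaks <- peaks + ev$magnitude *
        stats::dnorm(grid, mean = ev$center, sd = sd_pk)
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  reverse_n <- reverse + stats::rnorm(length(grid), sd = noise_sd)
  total_n <- reverse + peaks + stats::rnorm(length(grid), sd = noise_sd)
  structure(list(temperature = grid, reverse = reverse_n, total = total_n,
                 ground_truth = events, seed = seed),
            class = "synthetic_trace")
}

#' @export
print.synthetic_trace <- function(x, ...) {
  cat(sprintf("<synthetic_trace> %d points (%.1f..%.1f degC), %d event(s)\n",
              length(x$temperature), min(x$temperature), max(x$temperature),
              length(x$ground_truth)))
  invisible(x)
}

#' Extract glass transitions from a reversing heat-flow signal
#'
#' Derivative-based feature extraction: the smoothed temperature derivative
#' of the reversing signal shows one peak per glass transition. The event
#' center is taken at the derivative maximum (the inflection point), the
#' width from the derivative peak's FWHM rescaled to the onset-to-end span
#' of the underlying logistic step, and the height from the integral of the
#' derivative over the peak region.
#'
#' @param trace A `synthetic_trace` (or list with `temperature` and
#'   `reverse`).
#' @param min_height Minimum step height to report (default 0.01).
#' @param smooth_window Smoothing window in degC (default 2).
#' @return Data frame of events (`value`, `width`, `height`), sorted.
#' @export
detect_tg_events <- function(trace, min_height = 0.01, smooth_window = 2) {
  temp <- trace$temperature
  step <- stats::median(diff(temp))
  k <- max(3L, 2L * floor(smooth_window / step / 2) + 1L)
  sm <- stats::filter(trace$reverse, rep(1 / k, k), sides = 2)
  dy <- c(NA, diff(sm)) / step
  dy[is.na(dy)] <- 0
  thr <- max(min_height / 10, 3 * stats::mad(dy, na.rm = TRUE))
  above <- dy > thr
  if (!any(above)) return(data.frame(value = numeric(0),
                                     width = numeric(0),
                                     height = numeric(0)))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  n <- length(dy)
  # extend each region into the tails (down to thr/5), then merge overlaps
  spans <- lapply(which(runs$values), function(i) {
    li <- starts[i]; ri <- ends[i]
    while (li > 1 && dy[li - 1] > thr / 5) li <- li - 1
    while (ri < n && dy[ri + 1] > thr / 5) ri <- ri + 1
    c(li, ri)
  })
  merged <- list()
  for (sp in spans) {
    last <- if (length(merged) > 0) merged[[length(merged)]] else NULL
    if (!is.null(last) && sp[1] <= last[2])
      merged[[length(merged)]] <- c(last[1], max(last[2], sp[2]))
    else merged[[length(merged) + 1]] <- sp
  }
  out <- list()
  for (sp in merged) {
    idx <- sp[1]:sp[2]
    mass <- dy[idx]
    height <- sum(mass) * step
    if (height < min_height) next
    # center: mass-weighted mean (= inflection point for a symmetric step)
    center <- sum(temp[idx] * mass) / sum(mass)
    # width: span between the 1% and 99% quantiles of the step mass,
    # matching the onset-to-end definition of the transition region
    cum <- cumsum(mass) / sum(mass)
    t01 <- temp[idx][which(cum >= 0.01)[1]]
    t99 <- temp[idx][which(cum >= 0.99)[1]]
    out[[length(out) + 1]] <- data.frame(value = center,
                                         width = t99 - t01,
                                         height = height)
  }
  if (length(out) == 0) return(data.frame(value = numeric(0),
                                          width = numeric(0),
                                          height = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$value), , drop = FALSE]
}

#' Extract peak events from the total heat-flow signal
#'
#' Subtracts the reversing signal from the total signal and reports
#' contiguous regions of significant residual as peaks with their signed
#' area (trapezoidal integration): negative areas are endotherms
#' (melting / mesophase), positive areas exotherms (recrystallization).
#'
#' @param trace A `synthetic_trace`.
#' @param min_area Minimum absolute area to report (default 0.05).
#' @return Data frame with `center`, `area`, `sign` per detected peak.
#' @export
detect_thermal_peaks <- function(trace, min_area = 0.05) {
  resid <- trace$total - trace$reverse
  temp <- trace$temperature
  step <- stats::median(diff(temp))
  noise <- stats::mad(resid)
  thr <- max(5 * noise, 1e-6)
  active <- abs(resid) > thr
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- list()
  for (i in which(runs$values)) {
    idx <- starts[i]:ends[i]
    if (length(idx) < 3) next
    area <- sum((resid[idx][-1] + resid[idx][-length(idx)]) / 2) * step
    if (abs(area) < min_area) next
    ctr <- temp[idx][which.max(abs(resid[idx]))]
    out[[length(out) + 1]] <- data.frame(
      center = ctr, area = area,
      sign = if (area < 0) "endotherm" else "exotherm")
  }
  if (length(out) == 0)
    return(data.frame(center = numeric(0), area = numeric(0),
                      sign = character(0)))
  do.call(rbind, out)
}

#' Synthesize an X-ray powder diffraction pattern
#'
#' Sum of a broad amorphous halo (wide Gaussian), optional sharp Bragg
#' peaks (narrow Gaussians) and noise, over the 4.5-30 degrees 2-theta
#' range at 0.02 degree steps.
#'
#' @param halo_weight Amplitude of the amorphous halo (>= 0).
#' @param bragg_peaks Data frame or list with `two_theta` and `intensity`
#'   (peak heights); `NULL` or empty for a fully amorphous pattern.
#' @param fwhm Bragg peak FWHM in degrees (default 0.2).
#' @param noise_sd Noise standard deviation (default 0.01).
#' @param seed Integer seed.
#' @param halo_center,halo_fwhm Halo position and breadth (defaults 19 and
#'   14 degrees).
#' @return An `xrpd_pattern` list: `two_theta`, `intensity`, `ground_truth`.
#' @export
make_xrpd <- function(halo_weight = 1, bragg_peaks = NULL, fwhm = 0.2,
                      noise_sd = 0.01, seed = 1L,
                      halo_center = 19, halo_fwhm = 14) {
  stopifnot(halo_weight >= 0)
  tt <- seq(4.5, 30, by = 0.02)
  to_sd <- function(f) f / (2 * sqrt(2 * log(2)))
  y <- halo_weight * exp(-(tt - halo_center)^2 / (2 * to_sd(halo_fwhm)^2))
  if (!is.null(bragg_peaks) && length(bragg_peaks$two_theta) > 0) {
    if (any(bragg_peaks$two_theta < 4.5 | bragg_peaks$two_theta > 30))
      stop("Bragg peaks must lie inside the 4.5-30 degree range")
    if (any(bragg_peaks$intensity < 0))
      stop("peak intensities must be non-negative")
    for (i in seq_along(bragg_peaks$two_theta))
      y <- y + bragg_peaks$intensity[i] *
        exp(-(tt - bragg_peaks$two_theta[i])^2 / (2 * to_sd(fwhm)^2))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  y <- y + stats::rnorm(length(tt), sd = noise_sd)
  structure(list(two_theta = tt, intensity = y,
                 ground_truth = list(halo_weight = halo_weight,
                                     bragg_peaks = bragg_peaks,
                                     noise_sd = noise_sd)),
            class = "xrpd_pattern")
}

#' Detect residual crystallinity in a diffraction pattern
#'
#' Estimates a slowly-varying background by a running median, then flags
#' the pattern as crystalline when any contiguous excursion above the
#' background exceeds the detection limit in prominence while being
#' narrow (FWHM below `fwhm_max`) -- i.e. a sharp Bragg peak rather than
#' halo structure.
#'
#' @param pattern An `xrpd_pattern`.
#' @param prominence_min Detection limit on peak prominence (default 0.1).
#' @param fwhm_max Maximum FWHM (degrees) for a reflection to count as
#'   sharp (default 1).
#' @param bg_window Background window in degrees (default 3).
#' @return List: `crystalline` (logical) and `peaks` (data frame of
#'   detected sharp reflections).
#' @export
detect_crystallinity <- function(pattern, prominence_min = 0.1,
                                 fwhm_max = 1, bg_window = 3) {
  tt <- pattern$two_theta
  y <- pattern$intensity
  step <- stats::median(diff(tt))
  k <- max(3L, 2L * floor(bg_window / step / 2) + 1L)
  bg <- stats::runmed(y, k)
  resid <- y - bg
  noise <- stats::mad(resid)
  thr <- max(prominence_min / 2, 4 * noise)
  active <- resid > thr
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  peaks <- list()
  for (i in which(runs$values)) {
    idx <- starts[i]:ends[i]
    pk <- idx[which.max(resid[idx])]
    prom <- resid[pk]
    if (prom < prominence_min) next
    half <- prom / 2
    li <- pk; while (li > 1 && resid[li] > half) li <- li - 1
    ri <- pk; while (ri < length(resid) && resid[ri] > half) ri <- ri + 1
    fwhm <- tt[ri] - tt[li]
    if (fwhm <= fwhm_max)
      peaks[[length(peaks) + 1]] <- data.frame(two_theta = tt[pk],
                                               prominence = prom,
                                               fwhm = fwhm)
  }
  peaks <- if (length(peaks) > 0) do.call(rbind, peaks) else
    data.frame(two_theta = numeric(0), prominence = numeric(0),
               fwhm = numeric(0))
  list(crystalline = nrow(peaks) > 0, peaks = peaks)
}

#' Fox-rule mixed glass transition
#'
#' \eqn{1/T_{g,mix} = w/T_{g,drug} + (1-w)/T_{g,polymer}} with temperatures
#' in kelvin; a simple monotone interpolant between the pure-component
#' transitions used to place synthetic mixed-Tg values (not a fitted or
#' normative mixing rule).
#'
#' @param w_drug Drug mass fraction.
#' @param tg_drug_c,tg_polymer_c Pure-component Tg in degC.
#' @return Mixed Tg in degC.
#' @export
fox_tg <- function(w_drug, tg_drug_c, tg_polymer_c) {
  td <- tg_drug_c + 273.15
  tp <- tg_polymer_c + 273.15
  1 / (w_drug / td + (1 - w_drug) / tp) - 273.15
}
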