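# Dose-response calibration: the quantitative bridge between per-condition
# cytometry summaries and the stimulus/time factors f(A,t), g(A,t) of the
# spatial model. Antigen dose is mapped to a normalized stimulus
# A = dose/dose_max in [0,1]; dose dependence is interpolated with Hill
# curves and time dependence uses fixed piecewise-linear windows.

#' Normalized antigen stimulus from dose
#'
#' Maps an immunization dose in micrograms to the normalized antigen
#' stimulus \eqn{A = dose/dose_{max} \in [0, 1]} used throughout the model.
#'
#' @param dose_ug Antigen dose(s) in µg, non-negative.
#' @param dose_max Dose mapped to maximal stimulus (default 2000 µg, the
#'   largest dose on the experimental grid).
#' @return Numeric vector of stimuli in `[0, 1]`.
#' @export
#' @examples
#' stimulus_from_dose(c(0, 125, 2000))
stimulus_from_dose <- function(dose_ug, dose_max = 2000) {
  stopifnot(is.numeric(dose_ug), all(dose_ug >= 0), dose_max > 0)
  if (any(dose_ug > dose_max))
    stop("dose_ug exceeds dose_max; extend dose_max or rescale", call. = FALSE)
  dose_ug / dose_max
}

#' Time window of IL-2 secretion
#'
#' Piecewise-linear factor for the time dependence of the IL-2 secretion
#' rate: rises linearly from 0 at t = 0 to its maximum at t = 9 h, falls
#' linearly back to 0 at t = 18 h, and stays 0 afterwards.
#'
#' @param t_hours Time(s) after immunization, in hours; must be >= 0.
#' @return Factor(s) in `[0, 1]`.
#' @export
#' @examples
#' secretion_time_profile(c(0, 4.5, 9, 18, 24))
secretion_time_profile <- function(t_hours) {
  stopifnot(is.numeric(t_hours))
  if (any(t_hours < 0)) stop("t_hours must be non-negative", call. = FALSE)
  ifelse(t_hours <= 9, t_hours / 9,
         ifelse(t_hours < 18, (18 - t_hours) / 9, 0))
}

#' Time window of CD25 (IL-2R alpha) expression
#'
#' Piecewise-linear factor for the time dependence of receptor expression:
#' linear increase from 0 at t = 0 to the maximum at t = 18 h, linear
#' decrease to 0 at t = 30 h, 0 afterwards. Receptor expression lags
#' secretion: the peak at 18 h follows the secretion peak at 9 h.
#'
#' @inheritParams secretion_time_profile
#' @return Factor(s) in `[0, 1]`.
#' @export
receptor_time_profile <- function(t_hours) {
  stopifnot(is.numeric(t_hours))
  if (any(t_hours < 0)) stop("t_hours must be non-negative", call. = FALSE)
  ifelse(t_hours <= 18, t_hours / 18,
         ifelse(t_hours < 30, (30 - t_hours) / 12, 0))
}

#' Hill dose-response curve
#'
#' Four-parameter Hill curve on the normalized stimulus scale,
#' \deqn{y(A) = floor + (ceiling - floor) \frac{A^h}{A^h + A_{50}^h}.}
#' With `anchored = TRUE` the rising part is rescaled so that the ceiling is
#' attained exactly at A = 1 (useful for calibrations stated as "value at
#' the maximal dose"), i.e. the Hill term is divided by its value at A = 1.
#'
#' @param floor Response at A = 0.
#' @param ceiling Response at saturation (at A = 1 when `anchored`).
#' @param a50 Half-maximal stimulus, in (0, 1].
#' @param h Hill coefficient (steepness), > 0.
#' @param anchored Logical; rescale so the curve reaches `ceiling` at A = 1.
#' @return An object of class `hill_curve`.
#' @seealso [fit_stimulus_curve()]
#' @export
#' @examples
#' phi <- hill_curve(0, 0.75, a50 = 1/16, h = 1, anchored = TRUE)
#' predict(phi, c(0, 0.0625, 1))
hill_curve <- function(floor = 0, ceiling = 1, a50, h = 1, anchored = FALSE) {
  stopifnot(is.numeric(floor), is.numeric(ceiling), ceiling >= floor,
            a50 > 0, a50 <= 1, h > 0)
  structure(list(floor = floor, ceiling = ceiling, a50 = a50, h = h,
                 anchored = isTRUE(anchored)),
            class = "hill_curve")
}

#' @param object A `hill_curve`.
#' @param A Normalized stimulus value(s) in `[0, 1]`.
#' @param ... Unused.
#' @rdname hill_curve
#' @export
predict.hill_curve <- function(object, A, ...) {
  stopifnot(is.numeric(A), all(A >= 0))
  w <- A^object$h / (A^object$h + object$a50^object$h)
  if (object$anchored) w <- w * (1 + object$a50^object$h)
  object$floor + (object$ceiling - object$floor) * pmin(w, 1)
}

#' @exportS3Method base::print
print.hill_curve <- function(x, ...) {
  cat(sprintf("Hill curve: floor %.4g, ceiling %.4g, A50 %.4g, h %.4g%s%s\n",
              x$floor, x$ceiling, x$a50, x$h,
              if (x$anchored) " (anchored at A=1)" else "",
              if (isTRUE(attr(x, "degenerate"))) " [degenerate fit]" else ""))
  invisible(x)
}

#' Fit a Hill curve to per-dose summaries
#'
#' Least-squares fit of the four-parameter Hill curve to summary statistics
#' (percent positive or MFI) measured over a dose grid, on the normalized
#' stimulus scale. Flat input yields a degenerate constant curve (flagged);
#' input that decreases by more than noise is flagged but still fitted.
#'
#' @param A Normalized stimuli, including 0 and 1; at least 4 points.
#' @param y Summary value at each stimulus.
#' @param h_max Upper bound for the Hill coefficient in the fit.
#' @return A `hill_curve` with attributes `rss` (residual sum of squares),
#'   `degenerate` and `nonmonotone` flags.
#' @export
#' @examples
#' A <- c(0, 0.01, 0.0625, 0.25, 0.5, 1)
#' y <- predict(hill_curve(0, 80, a50 = 0.1, h = 1.5), A)
#' fit_stimulus_curve(A, y)
fit_stimulus_curve <- function(A, y, h_max = 20) {
  stopifnot(is.numeric(A), is.numeric(y), length(A) == length(y))
  if (length(A) < 4) stop("need at least 4 dose points", call. = FALSE)
  if (min(A) > 0 || max(A) < 1)
    stop("stimulus grid must include A = 0 and A = 1 anchors", call. = FALSE)
  o <- order(A); A <- A[o]; y <- y[o]

  span <- diff(range(y))
  if (span < 1e-10 * max(1, abs(mean(y)))) {
    out <- hill_curve(mean(y), mean(y) + abs(mean(y)) * 1e-12 + 1e-12,
                      a50 = 0.5, h = 1)
    out$ceiling <- out$floor  # truly flat
    attr(out, "rss") <- sum((y - mean(y))^2)
    attr(out, "degenerate") <- TRUE
    attr(out, "nonmonotone") <- FALSE
    return(out)
  }
  drops <- diff(y) < -0.1 * span
  nonmono <- any(drops)
  if (nonmono)
    warning("summaries decrease by more than noise; Hill fit may be poor",
            call. = FALSE)

  half <- y[1] + span / 2
  a50_start <- A[which.min(abs(y - half))]
  a50_start <- min(max(a50_start, 1e-3), 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ fl + (ce - fl) * A^h / (A^h + a50^h),
      start = list(fl = y[1], ce = y[length(y)], a50 = a50_start, h = 1),
      lower = c(fl = -Inf, ce = -Inf, a50 = 1e-6, h = 1e-3),
      upper = c(fl = Inf, ce = Inf, a50 = 1, h = h_max),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- coef(fit)
    rss <- sum(residuals(fit)^2)
  } else {
    # profile-likelihood fallback: grid over the nonlinear (a50, h) pair
    # with floor/ceiling solved by least squares at each grid point
    best <- NULL
    for (a50 in 10^seq(-3, 0, length.out = 40))
      for (h in c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, min(20, h_max))) {
        w <- A^h / (A^h + a50^h)
        cf <- tryCatch(coef(stats::lm(y ~ w)), error = function(e) NULL)
        if (is.null(cf) || any(!is.finite(cf))) next
        r <- sum((y - cf[1] - cf[2] * w)^2)
        if (is.null(best) || r < best$rss)
          best <- list(rss = r, fl = cf[[1]], ce = cf[[1]] + cf[[2]],
                       a50 = a50, h = h)
      }
    p <- c(fl = best$fl, ce = best$ce, a50 = best$a50, h = best$h)
    rss <- best$rss
  }
  out <- hill_curve(min(p[["fl"]], p[["ce"]]), max(p[["fl"]], p[["ce"]]),
                    a50 = p[["a50"]], h = min(p[["h"]], h_max))
  attr(out, "rss") <- rss
  attr(out, "degenerate") <- FALSE
  attr(out, "nonmonotone") <- nonmono
  out
}

#' Bundle stimulus and time factors into model profiles
#'
#' Combines the producer-fraction curve phi (IL-2), the per-population CD25
#' capacity curves gamma, and the secretion/receptor time windows into the
#' factors used by the reaction-diffusion model:
#' f(A, t) is built from phi(A) and [secretion_time_profile()];
#' g(A, t) from gamma_pop(A) and [receptor_time_profile()].
#'
#' @param il2_curve `hill_curve` for the IL-2 producer fraction vs stimulus;
#'   its value at A = 1 defines `p_max`.
#' @param cd25_th_curve,cd25_treg_curve `hill_curve`s for relative CD25
#'   capacity of Th and Treg cells vs stimulus. The Treg curve must exceed
#'   the Th curve at A = 0 (constitutive CD25 on Treg).
#' @return Object of class `stimulus_profiles`.
#' @export
build_profiles <- function(il2_curve, cd25_th_curve, cd25_treg_curve) {
  for (cv in list(il2_curve, cd25_th_curve, cd25_treg_curve))
    if (!inherits(cv, "hill_curve"))
      stop("curves must be hill_curve objects; missing population curve?",
           call. = FALSE)
  if (predict(cd25_treg_curve, 0) <= predict(cd25_th_curve, 0))
    stop("Treg CD25 capacity at A = 0 must exceed Th (constitutive CD25)",
         call. = FALSE)
  structure(list(phi = il2_curve,
                 gamma = list(Th = cd25_th_curve, Treg = cd25_treg_curve),
                 p_max = predict(il2_curve, 1)),
            class = "stimulus_profiles")
}

#' Default calibration of the stimulus profiles
#'
#' The package's reference calibration: up to 75% of Th cells become IL-2
#' producers at maximal stimulus; relative CD25 capacity rises with
#' stimulus in both populations, with Treg cells starting from ~82% of
#' their maximum already without immunization (constitutive CD25) and
#' responding at lower stimulus than Th cells, whose capacity starts near
#' zero. All curves are anchored Hill curves (value at A = 1 equals the
#' ceiling).
#'
#' @param p_max Maximal producer fraction among Th cells (default 0.75).
#' @return A `stimulus_profiles` object.
#' @export
default_profiles <- function(p_max = 0.75) {
  build_profiles(
    il2_curve = hill_curve(0, p_max, a50 = 1 / 4, h = 1, anchored = TRUE),
    cd25_th_curve = hill_curve(0.08, 1, a50 = 1 / 4, h = 1, anchored = TRUE),
    cd25_treg_curve = hill_curve(0.818, 1, a50 = 1 / 32, h = 1,
                                 anchored = TRUE))
}

#' Normalized producer weight w(A) = phi(A)/phi(1)
#' @param profiles A `stimulus_profiles` object.
#' @param A Stimulus in `[0, 1]`.
#' @return Weight(s) in `[0, 1]`, 0 at A = 0, 1 at A = 1.
#' @export
producer_weight <- function(profiles, A) {
  stopifnot(inherits(profiles, "stimulus_profiles"))
  predict(profiles$phi, A) / predict(profiles$phi, 1)
}

#' Normalized receptor factor g(A, t) for a population
#'
#' Relative IL-2 uptake capacity: gamma_pop(A) * T_rec(t), normalized by
#' the population's own gamma at A = 1 so the factor equals 1 at maximal
#' stimulus and peak receptor time (t = 18 h). The absolute capacity
#' difference between populations is carried by `IL2R_max` in
#' [model_params()]; the gamma curves carry the stimulus dependence, with
#' the Treg curve starting from a high constitutive fraction of its
#' maximum while the Th curve starts near zero.
#'
#' @inheritParams producer_weight
#' @param t_hours Time after immunization (h).
#' @param population `"Th"` or `"Treg"`.
#' @return Factor(s) in `[0, 1]`.
#' @export
receptor_factor <- function(profiles, A, t_hours, population = c("Th", "Treg")) {
  stopifnot(inherits(profiles, "stimulus_profiles"))
  population <- match.arg(population)
  g <- predict(profiles$gamma[[population]], A) /
    predict(profiles$gamma[[population]], 1)
  g * receptor_time_profile(t_hours)
}

#' Normalized secretion factor f(A, t) for the binary/graded scenarios
#'
#' In both scenarios the population-level secretion is
#' p_max * w(A) * T_sec(t) * IL2_max per Th cell on average; see
#' [assign_producers()] for how it is split between producer count (binary)
#' and per-producer rate (graded).
#'
#' @inheritParams receptor_factor
#' @return Factor(s) in `[0, 1]`.
#' @export
secretion_factor <- function(profiles, A, t_hours) {
  stopifnot(inherits(profiles, "stimulus_profiles"))
  producer_weight(profiles, A) * secretion_time_profile(t_hours)
}

#' @exportS3Method base::print
print.stimulus_profiles <- function(x, ...) {
  cat("Stimulus profiles (p_max =", format(x$p_max), ")\n")
  cat("  phi   : "); print(x$phi)
  cat("  gammaTh : "); print(x$gamma$Th)
  cat("  gammaTreg: "); print(x$gamma$Treg)
  invisible(x)
}

#' Reference p-STAT5 positive fractions versus stimulus
#'
#' Dose-response of the fraction of p-STAT5 positive cells used to
#' calibrate the activation threshold: anchored at ~11% for antigen-specific
#' Th and ~50% for Treg cells at maximal stimulus, with Treg cells
#' responding at lower stimulus than Th cells; endogenous (antigen
#' non-specific) Th cells show almost no p-STAT5 (1%), endogenous Treg
#' behave like specific Treg.
#'
#' @param A Normalized stimulus value(s).
#' @param population One of `"Th_tg"`, `"Treg_tg"`, `"Th_endo"`, `"Treg_endo"`
#'   (transgenic = antigen-specific).
#' @return Fraction(s) in `[0, 1]`.
#' @export
pstat5_reference <- function(A, population = c("Th_tg", "Treg_tg",
                                               "Th_endo", "Treg_endo")) {
  population <- match.arg(population)
  pars <- pstat5_defaults()[[population]]
  predict(hill_curve(0, pars$max, a50 = pars$a50, h = 1, anchored = TRUE), A)
}

pstat5_defaults <- function() {
  list(Th_tg = list(max = 0.11, a50 = 1 / 4),
       Treg_tg = list(max = 0.50, a50 = 1 / 16),
       Th_endo = list(max = 0.01, a50 = 1 / 4),
       Treg_endo = list(max = 0.50, a50 = 1 / 16))
}

#' Save / load stimulus profiles as JSON
#'
#' Serializes the Hill-curve parameters of a `stimulus_profiles` bundle so
#' a calibration can be re-used across sessions or pipelines.
#'
#' @param profiles A `stimulus_profiles` object.
#' @param path JSON file path.
#' @return `path` (write) or the restored `stimulus_profiles` (read).
#' @export
write_profiles_json <- function(profiles, path) {
  stopifnot(inherits(profiles, "stimulus_profiles"))
  enc <- function(cv) cv[c("floor", "ceiling", "a50", "h", "anchored")]
  jsonlite::write_json(list(phi = enc(profiles$phi),
                            gamma_th = enc(profiles$gamma$Th),
                            gamma_treg = enc(profiles$gamma$Treg)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profiles_json
#' @export
read_profiles_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(x) hill_curve(x$floor, x$ceiling, a50 = x$a50, h = x$h,
                                anchored = x$anchored)
  build_profiles(dec(raw$phi), dec(raw$gamma_th), dec(raw$gamma_treg))
}
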