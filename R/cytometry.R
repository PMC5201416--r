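# Synthetic flow-cytometry event generator. Emulates dose- and
# time-resolved single-cell marker distributions of adoptively transferred
# (antigen-specific, "tg") and endogenous ("endo") Th and Treg cells:
# bimodal log-fluorescence IL-2 whose upper-component weight (not location)
# tracks antigen dose, unimodal CD25/CD69 whose location shifts with dose,
# and p-STAT5 positivity rising with dose (Treg > Th). Fluorescence is
# modeled as mixtures of log10-normal components, the standard picture for
# log-axis cytometry histograms.

POPULATIONS <- c("Th_tg", "Treg_tg", "Th_endo", "Treg_endo")
MARKERS <- c("IL2", "CD25", "CD69", "pSTAT5", "cFos", "NFATc2")

#' Generator configuration
#'
#' Bundles the experimental design grid and the per-marker calibration of
#' the synthetic cytometry generator.
#'
#' Key default anchors of the calibration, all at the maximal dose
#' (2000 µg) and the 14 h readout: 75% IL-2 producing Th cells; 95% of Th
#' cells above the unimmunized CD25 gate (the CD25 location shift is solved
#' from that anchor in closed form); p-STAT5 maximal positive fractions
#' 11% (Th_tg), 50% (Treg_tg and Treg_endo), 1% (Th_endo). IL-2 component
#' locations are dose-independent (binary expression); CD25 locations are
#' dose-dependent (graded expression). Endogenous Th cells keep baseline
#' CD25/pSTAT5 at all doses; endogenous Treg cells have constitutively high
#' CD25 without a dose shift.
#'
#' @param dose_grid Antigen doses in µg, non-negative, strictly increasing.
#' @param time_grid Hours post immunization.
#' @param events_per_condition Events per (population, dose, time) cell.
#' @param seed Master RNG seed for [generate_dataset()].
#' @param populations,markers Subsets to generate.
#' @param p_max Maximal IL-2 producer fraction among transgenic Th cells.
#' @param cd25_gate_fraction Fraction of Th cells above the unimmunized
#'   99th-percentile CD25 gate at the maximal dose/14 h anchor condition.
#' @param cfos_rho Latent Gaussian-copula correlation coupling c-Fos level
#'   to IL-2 positivity (per-cell pairing); NFATc2 coupling is 0.
#' @param profiles `stimulus_profiles` giving the dose dependence; defaults
#'   to [default_profiles()] so generator and spatial model share one
#'   calibration.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(dose_grid = c(0, 2, 8, 31, 125, 500, 2000),
                             time_grid = c(0, 3, 6, 9, 12, 14, 18, 24),
                             events_per_condition = 1000,
                             seed = 1,
                             populations = POPULATIONS,
                             markers = MARKERS,
                             p_max = 0.75,
                             cd25_gate_fraction = 0.95,
                             cfos_rho = 0.5,
                             profiles = default_profiles(p_max)) {
  stopifnot(is.numeric(dose_grid), all(dose_grid >= 0),
            !is.unsorted(dose_grid, strictly = TRUE),
            events_per_condition >= 1,
            all(populations %in% POPULATIONS),
            all(markers %in% MARKERS),
            p_max > 0, p_max <= 1,
            cd25_gate_fraction > 0, cd25_gate_fraction < 1)
  cfg <- list(dose_grid = dose_grid, time_grid = time_grid,
              events_per_condition = as.integer(events_per_condition),
              seed = seed, populations = populations, markers = markers,
              p_max = p_max, cd25_gate_fraction = cd25_gate_fraction,
              cfos_rho = cfos_rho, profiles = profiles,
              dose_max = max(dose_grid, 2000))
  structure(cfg, class = "generator_config")
}

#' Log-normal mixture specification for one marker/condition
#'
#' @param weights Mixture weights (sum to 1, each in `[0, 1]`).
#' @param log_locations Component centers on the log10-fluorescence scale;
#'   ascending for two components.
#' @param log_scales Component spreads (log10 units), > 0.
#' @return Object of class `mixture_spec`.
#' @export
mixture_spec <- function(weights, log_locations, log_scales) {
  stopifnot(length(weights) %in% 1:2,
            length(log_locations) == length(weights),
            length(log_scales) == length(weights),
            all(log_scales > 0), all(weights >= 0), all(weights <= 1),
            abs(sum(weights) - 1) < 1e-8)
  if (length(weights) == 2 && diff(log_locations) <= 0)
    stop("two-component locations must be ascending", call. = FALSE)
  structure(list(weights = weights, log_locations = log_locations,
                 log_scales = log_scales),
            class = "mixture_spec")
}

# Secretion-assay positivity window: the surface-capture assay integrates
# secretion, so positivity plateaus over the 6-18 h expression peak and
# decays once secretion stops (zero by 24 h). Distinct from the
# instantaneous secretion-rate window secretion_time_profile().
il2_assay_window <- function(t_hours) {
  ifelse(t_hours <= 6, t_hours / 6,
         ifelse(t_hours <= 18, 1,
                ifelse(t_hours < 24, (24 - t_hours) / 6, 0)))
}

# CD25 location shift (log10 units) at the anchor condition that puts
# `frac` of the shifted component above the 99th percentile of baseline.
cd25_anchor_shift <- function(sdlog, frac) {
  sdlog * (qnorm(0.99) + qnorm(frac))
}

#' Mixture model for a marker at one condition
#'
#' Returns the log-normal mixture describing a marker's fluorescence for a
#' population at a given antigen dose and readout time. IL-2 has two
#' components with dose-independent locations and a dose-dependent upper
#' weight (binary expression); CD25 has one dominant component whose
#' location increases with dose and follows the receptor time window
#' (graded expression); CD69 distinguishes antigen-specific high expression
#' (transgenic cells) from intermediate bystander activation (endogenous
#' cells, only after immunization); p-STAT5 has a dose-dependent positive
#' fraction, larger in Treg than Th.
#'
#' @param marker One of `IL2, CD25, CD69, pSTAT5, cFos, NFATc2`.
#' @param population One of `Th_tg, Treg_tg, Th_endo, Treg_endo`.
#' @param dose_ug Antigen dose (µg), >= 0.
#' @param time_h Readout time (h), >= 0.
#' @param config A [generator_config()].
#' @return A [mixture_spec()].
#' @export
#' @examples
#' marker_model("IL2", "Th_tg", 2000, 14)
marker_model <- function(marker, population, dose_ug, time_h,
                         config = generator_config()) {
  if (!marker %in% MARKERS)
    stop("unknown marker: ", marker, call. = FALSE)
  if (!population %in% POPULATIONS)
    stop("unknown population: ", population, call. = FALSE)
  stopifnot(dose_ug >= 0, time_h >= 0)
  A <- min(dose_ug / config$dose_max, 1)
  w_dose <- producer_weight(config$profiles, A)

  switch(marker,
    IL2 = {
      wt <- if (population == "Th_tg")
        config$p_max * w_dose * il2_assay_window(time_h) else 0
      if (wt < 1e-12)
        mixture_spec(1, 1.0, 0.30)
      else
        mixture_spec(c(1 - wt, wt), c(1.0, 2.4), c(0.30, 0.30))
    },
    CD25 = {
      sdlog <- 0.25
      base <- if (population %in% c("Treg_tg", "Treg_endo")) 1.9 else 1.2
      shift_max <- switch(population,
        Th_tg = cd25_anchor_shift(sdlog, config$cd25_gate_fraction) /
          receptor_time_profile(14),
        Treg_tg = 0.6,
        Th_endo = 0,     # no upregulation in antigen-nonspecific Th
        Treg_endo = 0)   # constitutively high, no dose shift
      loc <- base + shift_max * w_dose * receptor_time_profile(time_h)
      mixture_spec(1, loc, sdlog)
    },
    CD69 = {
      tf <- pmin(time_h / 3, 1)
      if (population %in% c("Th_tg", "Treg_tg")) {
        wt <- 0.95 * tf *
          predict(hill_curve(0, 1, a50 = 1 / 50, h = 1, anchored = TRUE), A)
        if (wt < 1e-12) mixture_spec(1, 1.0, 0.25)
        else mixture_spec(c(1 - wt, wt), c(1.0, 2.6), c(0.25, 0.25))
      } else {
        wt <- if (dose_ug > 0) 0.3 * tf else 0  # bystander intermediate
        if (wt < 1e-12) mixture_spec(1, 1.0, 0.25)
        else mixture_spec(c(1 - wt, wt), c(1.0, 1.8), c(0.25, 0.25))
      }
    },
    pSTAT5 = {
      wt <- pstat5_reference(A, population)
      if (wt < 1e-12) mixture_spec(1, 1.0, 0.25)
      else mixture_spec(c(1 - wt, wt), c(1.0, 2.2), c(0.25, 0.25))
    },
    cFos = mixture_spec(1, 1.8, 0.30),
    NFATc2 = mixture_spec(1, 2.0, 0.30))
}

#' Draw fluorescence events from a mixture specification
#'
#' @param spec A [mixture_spec()].
#' @param n Number of events, >= 1.
#' @param seed Optional seed; the same seed reproduces the sample exactly.
#' @return `n` positive linear-scale fluorescence values.
#' @export
sample_events <- function(spec, n, seed = NULL) {
  if (!inherits(spec, "mixture_spec")) stop("invalid spec", call. = FALSE)
  stopifnot(n >= 1)
  with_seed(seed, {
    comp <- if (length(spec$weights) == 1) rep(1L, n)
            else 1L + (runif(n) < spec$weights[2])
    10^(rnorm(n, spec$log_locations[comp], spec$log_scales[comp]))
  })
}

#' Generate a full synthetic cytometry event table
#'
#' Full factorial table over the configured populations, doses, times and
#' markers. Markers are paired per cell through an `event` index: the IL-2
#' positivity indicator and c-Fos share a latent Gaussian copula (rank
#' correlation `cfos_rho`), NFATc2 is uncoupled, and CD25 is independent of
#' IL-2 positivity within a condition (the amount of CD25 is the same on
#' producers and non-producers).
#'
#' @param config A [generator_config()].
#' @return A `data.frame` with columns
#'   `population, dose_ug, time_h, event, marker, fi` and class
#'   `cytometry_table`; `fi` is linear-scale fluorescence.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$events_per_condition
  out <- vector("list", 0L)
  with_seed(config$seed, {
    for (pop in config$populations) for (dose in config$dose_grid)
      for (tt in config$time_grid) {
        U <- runif(n)  # latent positivity uniform shared by IL2 and c-Fos
        block <- vector("list", length(config$markers))
        names(block) <- config$markers
        for (mk in config$markers) {
          spec <- marker_model(mk, pop, dose, tt, config)
          fi <- if (mk == "IL2" && length(spec$weights) == 2) {
            pos <- U < spec$weights[2]
            comp <- 1L + pos
            10^(rnorm(n, spec$log_locations[comp], spec$log_scales[comp]))
          } else if (mk %in% c("cFos", "NFATc2")) {
            rho <- if (mk == "cFos") config$cfos_rho else 0
            z <- rho * qnorm(1 - U) + sqrt(1 - rho^2) * rnorm(n)
            10^(spec$log_locations[1] + spec$log_scales[1] * z)
          } else {
            comp <- if (length(spec$weights) == 1) rep(1L, n)
                    else 1L + (runif(n) < spec$weights[2])
            10^(rnorm(n, spec$log_locations[comp], spec$log_scales[comp]))
          }
          block[[mk]] <- data.frame(population = pop, dose_ug = dose,
                                    time_h = tt, event = seq_len(n),
                                    marker = mk, fi = fi)
        }
        out[[length(out) + 1L]] <- do.call(rbind, block)
      }
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  class(tab) <- c("cytometry_table", "data.frame")
  tab
}

#' Write / read a cytometry event table as CSV with a JSON sidecar
#'
#' @param tab A `cytometry_table`.
#' @param path Output CSV path; a `<path>.json` sidecar records the design
#'   grid and seed.
#' @param config Optional [generator_config()] recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_cytometry_csv <- function(tab, path, config = NULL) {
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  meta <- list(n_rows = nrow(tab),
               populations = unique(tab$population),
               doses = unique(tab$dose_ug), times = unique(tab$time_h),
               markers = unique(tab$marker))
  if (!is.null(config))
    meta$config <- config[c("dose_grid", "time_grid", "events_per_condition",
                            "seed", "p_max")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cytometry_csv
#' @export
read_cytometry_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("cytometry_table", "data.frame")
  tab
}

#' Default CFSE dividing fractions
#'
#' Fraction of progenitor cells that divide by 72 h, versus antigen dose:
#' ~10% background (no proliferation up to 8 µg), rising to 94% (Th) and
#' 65% (Treg) at 500 µg; log-dose interpolation in between and a mild
#' saturation above 500 µg.
#'
#' @param population `"Th"` or `"Treg"` (transgenic, antigen-specific).
#' @param dose_ug Antigen dose in µg.
#' @return Dividing fraction in `[0, 1]`.
#' @export
default_dividing_fraction <- function(population = c("Th", "Treg"), dose_ug) {
  population <- match.arg(population)
  stopifnot(dose_ug >= 0)
  top <- if (population == "Th") 0.94 else 0.65
  sat <- if (population == "Th") 0.96 else 0.70
  if (dose_ug <= 8) return(0.10)
  if (dose_ug >= 500)
    return(top + (sat - top) * min((log10(dose_ug) - log10(500)) /
                                     (log10(2000) - log10(500)), 1))
  0.10 + (top - 0.10) * (log10(dose_ug) - log10(8)) / (log10(500) - log10(8))
}

#' Generate a synthetic CFSE generation profile
#'
#' Each of `n_precursors` progenitors divides with probability
#' `dividing_fraction`; dividing progenitors are assigned a final division
#' generation i >= 1 from `generation_distribution`, and a generation-i
#' progenitor contributes 2^i observed cells, so observed counts are the
#' multinomial cohort expansion.
#'
#' @param n_precursors Number of progenitor cells, >= 1.
#' @param dividing_fraction Probability a progenitor divides, in `[0, 1]`.
#' @param generation_distribution Probabilities over generations 1..G
#'   (G <= 10), summing to 1.
#' @param seed Optional RNG seed.
#' @return Object of class `cfse_profile`: observed cell counts for
#'   generations 0..G plus the population/dose labels if supplied via
#'   attributes.
#' @export
#' @examples
#' generate_cfse_profile(1000, 0.5, c(0.5, 0.3, 0.2), seed = 1)
generate_cfse_profile <- function(n_precursors, dividing_fraction,
                                  generation_distribution, seed = NULL) {
  if (n_precursors < 1) stop("empty precursor pool", call. = FALSE)
  stopifnot(dividing_fraction >= 0, dividing_fraction <= 1,
            length(generation_distribution) >= 1,
            length(generation_distribution) <= 10,
            all(generation_distribution >= 0),
            abs(sum(generation_distribution) - 1) < 1e-8)
  with_seed(seed, {
    n_div <- rbinom(1, n_precursors, dividing_fraction)
    gens <- if (n_div > 0)
      as.vector(rmultinom(1, n_div, generation_distribution)) else
      rep(0L, length(generation_distribution))
    counts <- c(n_precursors - n_div, gens * 2^seq_along(gens))
    structure(list(generation_counts = counts),
              class = "cfse_profile")
  })
}

#' @exportS3Method base::print
print.cytometry_table <- function(x, ...) {
  cat(sprintf(
    "Synthetic cytometry table: %d events | %d population(s) x %d dose(s) x %d time(s) x %d marker(s)\n",
    nrow(x), length(unique(x$population)), length(unique(x$dose_ug)),
    length(unique(x$time_h)), length(unique(x$marker))))
  NextMethod()
}

#' @exportS3Method base::print
print.cfse_profile <- function(x, ...) {
  g <- x$generation_counts
  cat("CFSE profile (observed cells per generation 0..",
      length(g) - 1, "):\n", sep = "")
  print(setNames(g, paste0("g", seq_along(g) - 1)))
  invisible(x)
}
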