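# Statistical stage: bimodality testing of log-fluorescence with the dip
# statistic (bootstrap-calibrated p-value), Gaussian-mixture deconvolution
# by EM, per-condition expression calls (binary vs graded), quartile
# conditioning of a response marker on a second marker, and the
# cohort-corrected CFSE precursor frequency.

# cache of bootstrap null dip samples, keyed by (n, n_boot, seed)
.dip_null_cache <- new.env(parent = emptyenv())

#' Dip statistic of a sample
#'
#' Maximum distance between the empirical CDF and the closest unimodal CDF
#' (computed via the greatest-convex-minorant / least-concave-majorant
#' construction). Always at least `1/(2n)`.
#'
#' @param x Numeric sample (any scale; no transformation applied).
#' @return The dip statistic.
#' @export
#' @examples
#' dip_statistic(c(rnorm(100), rnorm(100, 8)))
dip_statistic <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 finite values", call. = FALSE)
  dip_stat_cpp(as.numeric(x))
}

#' Dip test for unimodality of log-fluorescence
#'
#' Computes the dip statistic of log10-transformed positive fluorescence
#' values and calibrates its p-value by parametric bootstrap under the
#' classical uniform null of equal sample size.
#'
#' @param values Positive fluorescence values (linear scale), >= 4 of them.
#' @param n_boot Bootstrap replicates, >= 100.
#' @param seed Optional seed for the bootstrap (null samples are cached per
#'   `(n, n_boot, seed)` so repeated tests at one sample size are cheap).
#' @return Object of class `dip_result` with fields `statistic`, `p_value`,
#'   `n_boot`, `n`.
#' @export
dip_test <- function(values, n_boot = 2000, seed = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 4) stop("need at least 4 finite values", call. = FALSE)
  if (any(values <= 0))
    stop("non-positive fluorescence: log10 undefined", call. = FALSE)
  if (n_boot < 100) stop("n_boot must be at least 100", call. = FALSE)
  n <- length(values)
  stat <- dip_statistic(log10(values))

  key <- paste(n, n_boot, seed %||% "", sep = "_")
  null_dips <- .dip_null_cache[[key]]
  if (is.null(null_dips)) {
    null_dips <- with_seed(seed,
      vapply(seq_len(n_boot), function(i) dip_stat_cpp(runif(n)), 0))
    .dip_null_cache[[key]] <- null_dips
  }
  p <- (1 + sum(null_dips >= stat)) / (n_boot + 1)
  structure(list(statistic = stat, p_value = p, n_boot = n_boot, n = n),
            class = "dip_result")
}

#' @exportS3Method base::print
print.dip_result <- function(x, ...) {
  cat(sprintf("Dip test: D = %.5f, p = %.4g (n = %d, %d bootstrap draws)\n",
              x$statistic, x$p_value, x$n, x$n_boot))
  invisible(x)
}

#' Fit a Gaussian mixture to log-fluorescence by EM
#'
#' Expectation-maximization for a 1- or 2-component Gaussian mixture on the
#' log scale, with random restarts, a variance floor against singular
#' collapse, and deterministic behaviour under a fixed seed. Components are
#' returned ordered by mean.
#'
#' @param log_values Log-transformed values; `n >= 10 * n_components`.
#' @param n_components 1 or 2.
#' @param n_restarts Random initializations (best log-likelihood kept).
#' @param tol Convergence threshold on the log-likelihood improvement.
#' @param seed Optional RNG seed.
#' @param var_floor Lower bound for component variances (log10 units^2).
#' @param max_iter Iteration cap per restart.
#' @return Object of class `mixture_fit`: `n_components`, `means`, `sds`,
#'   `weights`, `loglik`, `converged`, and `posterior` (membership
#'   probabilities of the upper component, for 2 components).
#' @export
fit_mixture_em <- function(log_values, n_components = 2, n_restarts = 20,
                           tol = 1e-8, seed = NULL, var_floor = 1e-4,
                           max_iter = 500) {
  x <- log_values[is.finite(log_values)]
  n <- length(x)
  stopifnot(n_components %in% 1:2)
  if (n < 10 * n_components)
    stop("need at least 10 values per component", call. = FALSE)
  if (diff(range(x)) < 1e-12)
    stop("all values identical: degenerate input", call. = FALSE)

  if (n_components == 1) {
    m <- mean(x); s <- max(sd(x) * sqrt((n - 1) / n), sqrt(var_floor))
    ll <- sum(dnorm(x, m, s, log = TRUE))
    return(structure(list(n_components = 1L, means = m, sds = s, weights = 1,
                          loglik = ll, converged = TRUE, posterior = NULL),
                     class = "mixture_fit"))
  }

  em_once <- function(mu, sg, w) {
    ll_old <- -Inf; converged <- FALSE
    for (it in seq_len(max_iter)) {
      d1 <- w[1] * dnorm(x, mu[1], sg[1])
      d2 <- w[2] * dnorm(x, mu[2], sg[2])
      tot <- d1 + d2
      tot[tot < 1e-300] <- 1e-300
      r2 <- d2 / tot
      ll <- sum(log(tot))
      if (is.finite(ll) && ll - ll_old < tol && it > 1) { converged <- TRUE; break }
      ll_old <- ll
      n2 <- sum(r2); n1 <- n - n2
      if (n1 < 1e-8 || n2 < 1e-8) break  # component vanished
      mu <- c(sum((1 - r2) * x) / n1, sum(r2 * x) / n2)
      v1 <- sum((1 - r2) * (x - mu[1])^2) / n1
      v2 <- sum(r2 * (x - mu[2])^2) / n2
      sg <- sqrt(pmax(c(v1, v2), var_floor))
      w <- c(n1, n2) / n
    }
    list(mu = mu, sg = sg, w = w, ll = ll_old, converged = converged, r2 = r2)
  }

  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      qs <- sort(runif(2, 0.05, 0.95))
      mu0 <- as.numeric(quantile(x, qs)) + rnorm(2, 0, 0.01 * sd(x))
      sg0 <- rep(max(sd(x) / 2, sqrt(var_floor)), 2)
      fit <- em_once(sort(mu0), sg0, c(0.5, 0.5))
      if (is.null(best) || (is.finite(fit$ll) && fit$ll > best$ll)) best <- fit
    }
    o <- order(best$mu)
    post <- if (o[1] == 1) best$r2 else 1 - best$r2
    structure(list(n_components = 2L, means = best$mu[o], sds = best$sg[o],
                   weights = best$w[o], loglik = best$ll,
                   converged = best$converged, posterior = post),
              class = "mixture_fit")
  })
}

#' @exportS3Method base::print
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture (%d comp): means %s | sds %s | weights %s | loglik %.2f%s\n",
              x$n_components,
              paste(sprintf("%.3f", x$means), collapse = "/"),
              paste(sprintf("%.3f", x$sds), collapse = "/"),
              paste(sprintf("%.3f", x$weights), collapse = "/"),
              x$loglik, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Classify a condition as binary or graded expression
#'
#' Applies the rule used for the per-condition expression analysis: a
#' two-component mixture model is used only when the dip test rejects
#' unimodality (p < alpha); then the expression call is "binary" and the
#' percent positive equals 100 x the weight of the higher-mean component.
#' Otherwise a single component is fitted, the call is "graded", and
#' percent positive is computed against a fixed gate (typically the 99th
#' percentile of the unimmunized control of the same marker/population).
#'
#' @param values Positive linear-scale fluorescence values.
#' @param alpha Significance level of the dip test (default 0.05).
#' @param gate Linear-scale gate used for percent positive in the graded
#'   case; `NA` if unavailable.
#' @param n_boot,seed Passed to [dip_test()] / [fit_mixture_em()].
#' @return Object of class `condition_summary`: `expression_call`,
#'   `percent_positive`, `mode_high`, `mode_low` (log10 scale; `mode_low`
#'   `NA` when unimodal), `mfi` (linear scale), `dip_p`.
#' @export
classify_condition <- function(values, alpha = 0.05, gate = NA,
                               n_boot = 2000, seed = NULL) {
  dt <- dip_test(values, n_boot = n_boot, seed = seed)
  lx <- log10(values[is.finite(values) & values > 0])
  if (dt$p_value < alpha) {
    fit <- fit_mixture_em(lx, 2, seed = seed)
    out <- list(expression_call = "binary",
                percent_positive = 100 * fit$weights[2],
                mode_high = fit$means[2], mode_low = fit$means[1],
                mfi = mean(values), dip_p = dt$p_value, fit = fit)
  } else {
    fit <- fit_mixture_em(lx, 1, seed = seed)
    pp <- if (is.na(gate)) NA_real_ else 100 * mean(values > gate)
    out <- list(expression_call = "graded", percent_positive = pp,
                mode_high = fit$means[1], mode_low = NA_real_,
                mfi = mean(values), dip_p = dt$p_value, fit = fit)
  }
  structure(out, class = "condition_summary")
}

#' @exportS3Method base::print
print.condition_summary <- function(x, ...) {
  cat(sprintf("%s expression | %%positive %s | mode(s) %s | MFI %.1f | dip p %.4g\n",
              x$expression_call,
              ifelse(is.na(x$percent_positive), "NA",
                     sprintf("%.1f", x$percent_positive)),
              if (is.na(x$mode_low)) sprintf("%.2f", x$mode_high)
              else sprintf("%.2f/%.2f", x$mode_low, x$mode_high),
              x$mfi, x$dip_p))
  invisible(x)
}

#' Per-condition summary of a cytometry table
#'
#' Runs [classify_condition()] on every (population, marker, dose, time)
#' group of an event table. For graded calls the gate is the 99th
#' percentile of the dose-0 condition of the same population, marker and
#' time (the unimmunized control).
#'
#' @param tab A `cytometry_table` (see [generate_dataset()]).
#' @param alpha Dip-test significance level.
#' @param n_boot Bootstrap replicates of the dip test.
#' @param seed RNG seed (bootstrap and EM restarts).
#' @param gate_quantile Quantile of the unimmunized control defining the
#'   graded-call gate.
#' @return `data.frame` with one row per condition:
#'   `population, marker, dose_ug, time_h, call, percent_positive,
#'   mode_low, mode_high, mfi, dip_p`.
#' @export
analyze_dataset <- function(tab, alpha = 0.05, n_boot = 2000, seed = 1,
                            gate_quantile = 0.99) {
  stopifnot(all(c("population", "dose_ug", "time_h", "marker", "fi")
                %in% names(tab)))
  groups <- unique(tab[c("population", "marker", "time_h")])
  res <- list()
  for (gi in seq_len(nrow(groups))) {
    pop <- groups$population[gi]; mk <- groups$marker[gi]
    tt <- groups$time_h[gi]
    sub <- tab[tab$population == pop & tab$marker == mk & tab$time_h == tt, ]
    ctrl <- sub$fi[sub$dose_ug == 0]
    gate <- if (length(ctrl) >= 10)
      as.numeric(quantile(ctrl, gate_quantile)) else NA_real_
    for (dose in sort(unique(sub$dose_ug))) {
      v <- sub$fi[sub$dose_ug == dose]
      cs <- classify_condition(v, alpha = alpha, gate = gate,
                               n_boot = n_boot,
                               seed = child_seed(seed, gi, round(dose)))
      res[[length(res) + 1L]] <- data.frame(
        population = pop, marker = mk, dose_ug = dose, time_h = tt,
        call = cs$expression_call, percent_positive = cs$percent_positive,
        mode_low = cs$mode_low, mode_high = cs$mode_high,
        mfi = cs$mfi, dip_p = cs$dip_p)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Response positivity by quartiles of a conditioning marker
#'
#' Within each condition, events are split into four equal-count quartiles
#' by the conditioning marker (ties broken by stable rank), and the
#' fraction of response-marker-positive cells (upper mixture-component
#' membership) is reported per quartile. A flat profile indicates
#' independence; an increasing profile indicates positive coupling.
#'
#' @param tab A `cytometry_table` containing both markers with paired
#'   `event` indices.
#' @param conditioning_marker,response_marker Marker names.
#' @param seed Seed for the mixture fit.
#' @return `data.frame`: `population, dose_ug, time_h, quartile,
#'   fraction_positive, n`.
#' @export
quartile_conditioning <- function(tab, conditioning_marker, response_marker,
                                  seed = 1) {
  stopifnot(all(c(conditioning_marker, response_marker) %in% tab$marker))
  conds <- unique(tab[c("population", "dose_ug", "time_h")])
  res <- list()
  for (ci in seq_len(nrow(conds))) {
    sel <- tab$population == conds$population[ci] &
      tab$dose_ug == conds$dose_ug[ci] & tab$time_h == conds$time_h[ci]
    cond_v <- tab[sel & tab$marker == conditioning_marker, ]
    resp_v <- tab[sel & tab$marker == response_marker, ]
    m <- merge(cond_v[c("event", "fi")], resp_v[c("event", "fi")],
               by = "event", suffixes = c("_cond", "_resp"))
    if (nrow(m) < 8) stop("fewer than 8 paired events in a condition",
                          call. = FALSE)
    fit <- fit_mixture_em(log10(m$fi_resp), 2, seed = seed)
    positive <- fit$posterior > 0.5
    rk <- rank(m$fi_cond, ties.method = "first")
    q <- ceiling(4 * rk / nrow(m))
    for (k in 1:4) {
      res[[length(res) + 1L]] <- data.frame(
        population = conds$population[ci], dose_ug = conds$dose_ug[ci],
        time_h = conds$time_h[ci], quartile = k,
        fraction_positive = mean(positive[q == k]), n = sum(q == k))
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Precursor frequency of dividing cells from a CFSE profile
#'
#' Cohort correction of observed generation counts: a cell observed in
#' generation i descends from `1/2^i` precursors, so precursor counts are
#' `m_i = n_i / 2^i` and the percentage of dividing progenitors is
#' `100 * sum(m_i, i >= 1) / sum(m_i, i >= 0)`.
#'
#' @param profile A `cfse_profile` (see [generate_cfse_profile()]) or a
#'   numeric vector of observed counts per generation 0..G.
#' @return Percentage (0-100) of progenitors that divided.
#' @export
#' @examples
#' precursor_frequency(c(50, 50, 100))  # 50
precursor_frequency <- function(profile) {
  counts <- if (inherits(profile, "cfse_profile"))
    profile$generation_counts else profile
  stopifnot(is.numeric(counts), all(counts >= 0))
  if (sum(counts) == 0) stop("all-zero CFSE profile", call. = FALSE)
  m <- counts / 2^(seq_along(counts) - 1)
  100 * sum(m[-1]) / sum(m)
}
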