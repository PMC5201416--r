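# Synthetic cytometry generator: marker mixture models, event sampling,
# dataset assembly, and CFSE generation profiles.

test_that("IL-2 mixture has dose-independent locations and dose-driven
          weight (binary expression)", {
  cfg <- generator_config()
  expect_equal(marker_model("IL2", "Th_tg", 0, 14, cfg)$weights, 1)
  lo <- marker_model("IL2", "Th_tg", 125, 14, cfg)
  hi <- marker_model("IL2", "Th_tg", 2000, 14, cfg)
  expect_identical(lo$log_locations, hi$log_locations)
  expect_gt(hi$weights[2], lo$weights[2])
  expect_equal(hi$weights[2], 0.75, tolerance = 1e-9)  # p_max at 2 mg, 14 h
  # weight non-decreasing along the full dose grid
  w <- vapply(cfg$dose_grid, function(d) {
    m <- marker_model("IL2", "Th_tg", d, 14, cfg)
    if (length(m$weights) == 2) m$weights[2] else 0
  }, 0)
  expect_true(all(diff(w) >= -1e-12))
  # non-producing populations stay negative
  expect_equal(marker_model("IL2", "Treg_tg", 2000, 14, cfg)$weights, 1)
  expect_equal(marker_model("IL2", "Th_endo", 2000, 14, cfg)$weights, 1)
})

test_that("CD25 location shifts with dose (graded), Treg above Th at
          baseline, endogenous populations unshifted", {
  cfg <- generator_config()
  l8 <- marker_model("CD25", "Th_tg", 8, 14, cfg)
  l2000 <- marker_model("CD25", "Th_tg", 2000, 14, cfg)
  expect_length(l2000$weights, 1)
  expect_gt(l2000$log_locations, l8$log_locations)
  expect_gt(marker_model("CD25", "Treg_tg", 0, 14, cfg)$log_locations,
            marker_model("CD25", "Th_tg", 0, 14, cfg)$log_locations)
  expect_equal(marker_model("CD25", "Th_endo", 2000, 14, cfg)$log_locations,
               marker_model("CD25", "Th_endo", 0, 14, cfg)$log_locations)
  expect_equal(marker_model("CD25", "Treg_endo", 2000, 14, cfg)$log_locations,
               marker_model("CD25", "Treg_endo", 0, 14, cfg)$log_locations)
})

test_that("p-STAT5 positive weights rise with dose and order Treg > Th", {
  cfg <- generator_config()
  wt <- function(pop, d) {
    m <- marker_model("pSTAT5", pop, d, 14, cfg)
    if (length(m$weights) == 2) m$weights[2] else 0
  }
  expect_equal(wt("Th_tg", 2000), 0.11, tolerance = 1e-9)
  expect_equal(wt("Treg_tg", 2000), 0.50, tolerance = 1e-9)
  expect_lt(wt("Th_endo", 2000), 0.02)
  for (d in c(31, 125, 500)) expect_gt(wt("Treg_tg", d), wt("Th_tg", d))
})

test_that("unknown markers and populations are configuration errors", {
  expect_error(marker_model("CD4", "Th_tg", 0, 14), "unknown marker")
  expect_error(marker_model("IL2", "NK", 0, 14), "unknown population")
})

test_that("sample_events draws from the specified log-normal mixture", {
  spec1 <- mixture_spec(1, 2.0, 0.3)
  x <- sample_events(spec1, 1e5, seed = 1)
  expect_true(all(x > 0))
  se <- 0.3 / sqrt(1e5)
  expect_lt(abs(mean(log10(x)) - 2.0), 3 * se)

  spec2 <- mixture_spec(c(0.25, 0.75), c(1.0, 3.0), c(0.3, 0.3))
  y <- sample_events(spec2, 1e5, seed = 2)
  expect_equal(mean(log10(y) > 2.0), 0.75, tolerance = 0.01)

  expect_identical(sample_events(spec2, 100, seed = 5),
                   sample_events(spec2, 100, seed = 5))
  expect_error(sample_events(list(), 10), "invalid spec")
})

test_that("generate_dataset builds the full factorial with paired events", {
  cfg <- generator_config(dose_grid = c(0, 125, 2000), time_grid = c(0, 14),
                          events_per_condition = 300,
                          populations = c("Th_tg", "Treg_tg"),
                          markers = c("IL2", "CD25", "cFos"), seed = 42)
  tab <- generate_dataset(cfg)
  expect_equal(nrow(tab), 2 * 3 * 2 * 3 * 300)
  counts <- table(tab$population, tab$marker)
  expect_true(all(counts == 3 * 2 * 300))
  expect_true(all(tab$fi > 0))
  # byte-for-byte reproducibility under the seed
  expect_identical(tab, generate_dataset(cfg))
})

test_that("IL-2 positivity and CD25 level are independent within a
          condition, while c-Fos is coupled to IL-2 positivity", {
  cfg <- generator_config(dose_grid = c(0, 2000), time_grid = 14,
                          events_per_condition = 6000,
                          populations = "Th_tg",
                          markers = c("IL2", "CD25", "cFos", "NFATc2"),
                          seed = 9)
  tab <- generate_dataset(cfg)
  cond <- tab[tab$dose_ug == 2000, ]
  grab <- function(mk) {
    sub <- cond[cond$marker == mk, ]
    sub$fi[order(sub$event)]
  }
  pos <- grab("IL2") > 10^1.7  # between the two fixed component locations
  expect_lt(abs(cor(pos, grab("CD25"))), 0.05)
  expect_gt(cor(pos, log10(grab("cFos"))), 0.15)
  expect_lt(abs(cor(pos, log10(grab("NFATc2")))), 0.05)
})

test_that("CFSE profiles follow the cohort doubling construction", {
  p0 <- generate_cfse_profile(100, 0, c(0.5, 0.5), seed = 1)
  expect_equal(p0$generation_counts, c(100, 0, 0))

  p1 <- generate_cfse_profile(100, 1, 1, seed = 1)
  expect_equal(p1$generation_counts, c(0, 200))

  expect_error(generate_cfse_profile(0, 0.5, 1), "empty precursor")

  # round trip through the cohort precursor-frequency formula
  p <- generate_cfse_profile(1e4, 0.5, c(0.3, 0.4, 0.3), seed = 3)
  expect_equal(precursor_frequency(p), 50, tolerance = 2)
})

test_that("default dividing fractions reproduce the calibration anchors", {
  expect_equal(default_dividing_fraction("Th", 0), 0.10)
  expect_equal(default_dividing_fraction("Treg", 8), 0.10)
  expect_equal(default_dividing_fraction("Th", 500), 0.94)
  expect_equal(default_dividing_fraction("Treg", 500), 0.65)
  expect_gte(default_dividing_fraction("Th", 2000),
             default_dividing_fraction("Th", 500))
})

test_that("cytometry CSV round-trips through disk", {
  cfg <- generator_config(dose_grid = c(0, 2000), time_grid = 14,
                          events_per_condition = 50, populations = "Th_tg",
                          markers = "IL2", seed = 1)
  tab <- generate_dataset(cfg)
  path <- tempfile(fileext = ".csv")
  write_cytometry_csv(tab, path, cfg)
  back <- read_cytometry_csv(path)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$fi, tab$fi, tolerance = 1e-6)
  expect_true(file.exists(paste0(path, ".json")))
  unlink(c(path, paste0(path, ".json")))
})
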