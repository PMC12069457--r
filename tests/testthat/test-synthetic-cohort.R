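# Synthetic-cohort generator: distributional correctness, determinism,
# attraction ground truth, marker separation, survival linkage.

test_that("multitype Poisson simulation obeys the Poisson law", {
  w <- spatial_window()
  expect_equal(nrow(simulate_poisson_multitype(c(A = 0, B = 0), w, seed = 1)),
               0L)
  expect_error(simulate_poisson_multitype(c(A = -1), w), "nonnegative")

  # identical seeds give identical tables
  t1 <- simulate_poisson_multitype(c(A = 1e-4, B = 2e-4), w, seed = 99)
  t2 <- simulate_poisson_multitype(c(A = 1e-4, B = 2e-4), w, seed = 99)
  expect_identical(t1, t2)

  # mean count over 200 replicates within 3 standard errors of
  # density * area = 2000 (Poisson: SE = sqrt(2000 / 200))
  set.seed(21)
  counts <- replicate(200, nrow(simulate_poisson_multitype(c(A = 0.002), w)))
  expect_lt(abs(mean(counts) - 2000), 3 * sqrt(2000 / 200))

  # coordinates uniform: mean x near width/2
  set.seed(22)
  pts <- simulate_poisson_multitype(c(A = 0.005), w)
  expect_lt(abs(mean(pts$x_um) - 500), 3 * (1000 / sqrt(12)) / sqrt(nrow(pts)))
})

test_that("replicate counts pass a chi-square goodness-of-fit against Poisson", {
  set.seed(23)
  lambda <- 30  # density 3e-5 over 1 mm^2
  counts <- replicate(300, nrow(simulate_poisson_multitype(c(A = 3e-5))))
  brk <- qpois(seq(0, 1, length.out = 9), lambda)
  bins <- cut(counts, breaks = unique(c(-1, brk, Inf)))
  expected <- diff(ppois(unique(c(-1, brk, Inf)), lambda)) * 300
  keep <- expected > 1
  chi <- sum((table(bins)[keep] - expected[keep])^2 / expected[keep])
  p <- pchisq(chi, sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("attraction lifts the cross-type nearest-neighbor CDF; independence does not", {
  w <- spatial_window()
  expect_error(simulate_attraction("P", "O", 1e-4, 2, sigma = 0, w),
               "positive")
  none <- simulate_attraction("P", "O", 2e-4, 0, sigma = 5, w, seed = 31)
  expect_false("O" %in% none$true_type)

  # clustered offspring: empirical G(20) well above the Poisson baseline
  # at the matched offspring density
  set.seed(32)
  lift <- replicate(20, {
    cells <- simulate_attraction("P", "O", 3e-4, 2, sigma = 5, w)
    cells$sample_id <- "s"
    cells$phenotype <- cells$true_type
    alpha_o <- sum(cells$true_type == "O") / window_area(w)
    g <- gcross_empirical(cells, "P", "O", radii = c(0, 10, 20), window = w,
                          correction = "raw")
    gcross_at(g, 20) - gcross_theoretical(alpha_o, 20)
  })
  expect_gt(mean(lift), 0.2)

  # independent types stay inside a Monte-Carlo envelope of the closed form
  set.seed(33)
  vals <- replicate(200, {
    cells <- simulate_poisson_multitype(c(P = 3e-4, O = 6e-4), w)
    cells$sample_id <- "s"
    cells$phenotype <- cells$true_type
    g <- gcross_empirical(cells, "P", "O", radii = c(0, 20), window = w,
                          correction = "raw")
    g$est[2]
  })
  # 99% Monte-Carlo envelope: the replicate quantile band around the
  # closed form (the raw estimator's small edge-censoring bias sits well
  # inside the replicate spread; an attraction shift of +0.2 would not)
  theo <- gcross_theoretical(6e-4, 20)
  band <- quantile(vals - theo, c(0.005, 0.995))
  expect_gt(mean(vals) - theo, band[1])
  expect_lt(mean(vals) - theo, band[2])
  expect_lt(abs(mean(vals) - theo), 3 * sd(vals) / sqrt(200) + 0.005)
})

test_that("marker intensities separate types and recovery degrades with separation", {
  cells <- data.frame(x_um = runif(50), y_um = runif(50),
                      true_type = rep(c("Tumor", "B"), 25))
  # zero noise reproduces the configured means exactly
  mm <- default_marker_model(sdlog = 0)
  out <- simulate_marker_intensities(cells, mm, seed = 41)
  expect_equal(out$SOX10, ifelse(cells$true_type == "Tumor", 50, 1))
  expect_error(
    simulate_marker_intensities(data.frame(true_type = "Martian"), mm),
    "without a signal model")

  recovery <- function(high, sdlog, seed) {
    set.seed(seed)
    cells <- simulate_poisson_multitype(default_type_intensities("III"))
    cells$sample_id <- "s"
    mm <- default_marker_model(high = high, sdlog = sdlog)
    cells <- simulate_marker_intensities(cells, mm)
    out <- classify_cells(cells,
                          thresholds = default_thresholds(high = high))
    mean(out$phenotype == cells$true_type)
  }
  # well-separated means: near-perfect recovery
  expect_gte(recovery(high = 50, sdlog = 0.25, seed = 42), 0.99)
  # recovery degrades monotonically as separation shrinks
  r <- c(recovery(50, 0.6, 43), recovery(10, 0.6, 43), recovery(3, 0.6, 43))
  expect_true(all(diff(r) < 0))
  expect_lt(r[3], 0.9)
})

test_that("survival simulation follows the configured exponential hazard", {
  expect_error(
    simulate_survival(data.frame(patient_id = "p", f = 1),
                      list(baseline = 0, coef = c(f = 1), censor_rate = 0)),
    "positive")

  # no censoring: all events; KM median near ln(2)/baseline
  feats <- data.frame(patient_id = sprintf("p%04d", 1:2000))
  cl <- simulate_survival(feats, list(baseline = 0.05, coef = NULL,
                                      censor_rate = 0), seed = 51)
  expect_true(all(cl$event == 1))
  km <- km_estimate(cl$time_months, cl$event)
  expect_lt(abs(km$median - log(2) / 0.05), 1.5)

  # binary feature with coefficient ln 2 is recovered by Cox at n = 1000
  feats2 <- data.frame(patient_id = sprintf("p%04d", 1:1000),
                       f = rep(0:1, 500))
  cl2 <- simulate_survival(feats2, list(baseline = 0.05, coef = c(f = log(2)),
                                        censor_rate = 0.01), seed = 52)
  fit <- fit_cox_univariate(cl2$time_months, cl2$event,
                            feats2$f[match(cl2$patient_id, feats2$patient_id)])
  expect_lt(abs(fit$log_hr - log(2)), 3 * fit$se_robust)

  # patient-level feature is the mean over that patient's samples
  feats3 <- data.frame(patient_id = c("a", "a", "b"), f = c(0, 1, 1))
  set.seed(53)
  cl3a <- simulate_survival(feats3, list(baseline = 0.05, coef = c(f = 2),
                                         censor_rate = 0))
  set.seed(53)
  cl3b <- simulate_survival(data.frame(patient_id = c("a", "b"),
                                       f = c(0.5, 1)),
                            list(baseline = 0.05, coef = c(f = 2),
                                 censor_rate = 0))
  expect_equal(cl3a$time_months, cl3b$time_months)
})

test_that("cohort generation reproduces the study structure deterministically", {
  cfg <- simulation_config(
    n_patients = 157, cores_per_patient = 2, stage = "III",
    type_intensities = default_type_intensities("III") * 0.05,
    marker_model = NULL, anchor_marker_rates = NULL, seed = 61)
  co <- generate_cohort(cfg)
  expect_equal(length(unique(co$cells$sample_id)), 314L)  # 157 x 2 cores
  expect_equal(nrow(co$clinical), 157L)
  expect_true(all(table(co$cells$patient_id) > 0))

  cfg2 <- simulation_config(n_patients = 5, cores_per_patient = c(2, 1, 1, 2, 1),
                            type_intensities = c(Tumor = 2e-4, B = 1e-4),
                            marker_model = NULL, anchor_marker_rates = NULL,
                            seed = 62)
  a <- generate_cohort(cfg2)
  b <- generate_cohort(cfg2)
  expect_identical(a$cells, b$cells)
  expect_identical(a$clinical, b$clinical)
  expect_equal(length(unique(a$cells$sample_id)), 7L)
})

test_that("the configured stage composition shift is detected downstream", {
  mk <- function(stage, seed) {
    cfg <- simulation_config(
      n_patients = 60, cores_per_patient = 1, stage = stage,
      type_intensities = default_type_intensities(stage) * 0.3,
      marker_model = NULL, anchor_marker_rates = NULL, seed = seed)
    generate_cohort(cfg)
  }
  iii <- mk("III", 71)
  iv <- mk("IV", 72)
  cells <- rbind(iii$cells, iv$cells)
  cells$phenotype <- cells$true_type
  props <- cell_type_proportions(
    cells, types = c("Tumor", "CTL", "B", "NK"))
  groups <- data.frame(
    sample_id = unique(cells$sample_id),
    group = substr(unique(cells$sample_id), 1, 2))
  groups$group <- ifelse(grepl("^IV", groups$sample_id), "IV", "III")
  res <- compare_cohorts(props, groups, family = "cell_types")
  beta_of <- function(ty) res$beta[res$feature == ty]
  expect_gt(beta_of("Tumor"), 0)
  expect_gt(beta_of("CTL"), 0)
  expect_lt(beta_of("B"), 0)
  expect_lt(beta_of("NK"), 0)
  expect_lt(res$q[res$feature == "Tumor"], 0.05)
})
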