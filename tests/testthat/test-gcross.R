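# G-cross estimators: closed form, estimator vs brute-force oracle,
# interpolation, AUC, neighborhood restriction.

test_that("theoretical G-cross matches the Poisson closed form", {
  expect_equal(gcross_theoretical(0.002, 0), 0)
  expect_equal(gcross_theoretical(0, c(5, 50, 500)), c(0, 0, 0))
  # alpha * pi * r^2 = log(2)  =>  G = 1/2
  expect_equal(gcross_theoretical(log(2) / (100 * pi), 10), 0.5)
  expect_equal(gcross_theoretical(0.002, 20), 1 - exp(-0.002 * pi * 400))
  expect_error(gcross_theoretical(-1, 5), "nonnegative")
  expect_error(gcross_theoretical(0.1, -5), "nonnegative")
})

test_that("a single reference-target pair gives a step at their distance", {
  cells <- data.frame(sample_id = "s1",
                      x_um = c(50, 53), y_um = c(50, 54),
                      phenotype = c("i", "j"))
  w <- spatial_window(100, 100)
  g_raw <- gcross_empirical(cells, "i", "j", radii = 0:10, window = w,
                            correction = "raw")
  expect_equal(g_raw$est, as.numeric(0:10 >= 5))  # 3-4-5 triangle
  expect_equal(g_raw$n_i, 1L)
  expect_equal(g_raw$alpha_j, 1 / 1e4)
  # border correction: the reference point is 50 um from the boundary,
  # so it stays in the reduced sample at every r <= 10
  g_bor <- gcross_empirical(cells, "i", "j", radii = 0:10, window = w,
                            correction = "border")
  expect_equal(g_bor$est[g_bor$r == 5], 1)
  expect_equal(g_bor$est, g_raw$est)

  expect_error(gcross_empirical(cells, "i", "missing", radii = 0:10,
                                window = w), "excluded")
})

test_that("coincident points are counted at every radius including zero", {
  cells <- data.frame(sample_id = "s1", x_um = c(10, 10, 40),
                      y_um = c(20, 20, 40),
                      phenotype = c("i", "j", "j"))
  g <- gcross_empirical(cells, "i", "j", radii = c(0, 1, 2),
                        window = spatial_window(100, 100), correction = "raw")
  expect_equal(g$est, c(1, 1, 1))
})

test_that("empirical estimator equals the brute-force oracle, raw and border", {
  set.seed(11)
  w <- spatial_window(500, 800)
  radii <- seq(0, 80, by = 4)
  for (rep in 1:12) {
    cells <- random_pattern(sample(20:300, 1), c("A", "Bc", "C"), w)
    for (corr in c("raw", "border")) {
      for (pair in list(c("A", "Bc"), c("Bc", "A"), c("A", "A"))) {
        got <- gcross_empirical(cells, pair[1], pair[2], radii = radii,
                                window = w, correction = corr)
        want <- oracle_gcross(cells, pair[1], pair[2], radii, w, corr)
        expect_equal(got$est, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("G-cross is a CDF in r and generally asymmetric in its arguments", {
  set.seed(12)
  w <- spatial_window()
  for (rep in 1:8) {
    cells <- random_pattern(300, c("A", "Bc"), w)
    g <- gcross_empirical(cells, "A", "Bc", window = w, correction = "raw")
    expect_true(all(g$est >= 0 & g$est <= 1))
    expect_true(all(diff(g$est) >= 0))
  }
  # asymmetric configuration: many isolated A, one B amid an A cluster
  cells <- data.frame(
    sample_id = "s1",
    x_um = c(10, 12, 14, 900, 905, 13),
    y_um = c(10, 12, 14, 900, 905, 12),
    phenotype = c("A", "A", "A", "A", "A", "Bc"))
  gij <- gcross_empirical(cells, "A", "Bc", radii = 0:50, window = w,
                          correction = "raw")
  gji <- gcross_empirical(cells, "Bc", "A", radii = 0:50, window = w,
                          correction = "raw")
  expect_false(isTRUE(all.equal(gij$est, gji$est)))
  expect_equal(gij$est, oracle_gcross(cells, "A", "Bc", 0:50, w, "raw"))
  expect_equal(gji$est, oracle_gcross(cells, "Bc", "A", 0:50, w, "raw"))
})

test_that("curve evaluation interpolates linearly within the grid", {
  curve <- structure(list(r = c(0, 10), est = c(0, 0.5), correction = "raw",
                          type_i = "i", type_j = "j", n_i = 10L, n_j = 10L,
                          alpha_j = 1e-5, window = spatial_window()),
                     class = "gcross_curve")
  expect_equal(gcross_at(curve, 5), 0.25)
  expect_equal(gcross_at(curve, 10), 0.5)
  expect_error(gcross_at(curve, 11), "outside")

  # interpolated values lie between the neighboring grid values
  set.seed(13)
  est <- cummax(runif(21))
  curve2 <- structure(list(r = seq(0, 80, by = 4), est = est,
                           correction = "raw", type_i = "i", type_j = "j",
                           n_i = 1L, n_j = 1L, alpha_j = 1e-5,
                           window = spatial_window()),
                      class = "gcross_curve")
  for (r in runif(50, 0, 80)) {
    v <- gcross_at(curve2, r)
    lo <- est[max(which(seq(0, 80, 4) <= r))]
    hi <- est[min(which(seq(0, 80, 4) >= r))]
    expect_gte(v, lo - 1e-12)
    expect_lte(v, hi + 1e-12)
  }
})

test_that("AUC is the trapezoidal integral with undefined points re-spanned", {
  base <- list(correction = "raw", type_i = "i", type_j = "j", n_i = 1L,
               n_j = 1L, alpha_j = 1e-5, window = spatial_window())
  mk <- function(r, est) structure(c(list(r = r, est = est), base),
                                   class = "gcross_curve")
  expect_equal(gcross_auc(mk(0:40, rep(1, 41))), 40)
  expect_equal(gcross_auc(mk(0:80, (0:80) / 80)), 40)  # triangle
  expect_equal(gcross_auc(mk(0:40, rep(0, 41))), 0)
  expect_equal(gcross_auc(mk(0:40, rep(1, 41)), r_max = 25), 25)
  # NA points dropped, trapezoid re-spanned across the gap
  est <- c(0, NA, 1, 1, 1)
  expect_equal(gcross_auc(mk(c(0, 1, 2, 3, 4), est)), 0.5 * 2 + 2)
  expect_error(gcross_auc(mk(c(0, 1), c(NA, NA))), "no defined|usable")
})

test_that("neighborhood restriction conditions the reference cells only", {
  set.seed(14)
  w <- spatial_window(400, 400)
  cells <- random_pattern(150, c("A", "Bc"), w)
  cells$cell_id <- seq_len(nrow(cells))
  all_mem <- data.frame(sample_id = cells$sample_id, cell_id = cells$cell_id,
                        nb = TRUE)
  g_all <- gcross_within_neighborhood(cells, all_mem, "nb", "A", "Bc",
                                      radii = 0:40, window = w,
                                      correction = "raw")
  g_global <- gcross_empirical(cells, "A", "Bc", radii = 0:40, window = w,
                               correction = "raw")
  expect_equal(g_all$est, g_global$est)

  # hand-built configuration: restricted references vs brute force
  hand <- data.frame(
    sample_id = "s1",
    x_um = c(10, 30, 200, 220, 15, 35, 210, 230),
    y_um = c(10, 30, 200, 220, 12, 28, 205, 228),
    phenotype = rep(c("A", "Bc"), each = 4))
  hand$cell_id <- 1:8
  mem <- data.frame(sample_id = "s1", cell_id = 1:8,
                    nb = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  g <- gcross_within_neighborhood(hand, mem, "nb", "A", "Bc",
                                  radii = seq(0, 60, 2), window = w,
                                  correction = "raw")
  want <- oracle_gcross(hand, "A", "Bc", seq(0, 60, 2), w, "raw",
                        ref_keep = mem$nb)
  expect_equal(g$est, want, tolerance = 1e-12)
  expect_equal(g$n_i, 2L)
  expect_equal(g$n_j, 4L)  # targets unrestricted

  none <- data.frame(sample_id = "s1", cell_id = 1:8, nb = FALSE)
  expect_error(gcross_within_neighborhood(hand, none, "nb", "A", "Bc",
                                          window = w), "excluded")
})

test_that("the feature table reports fixed radii, AUC and exclusions", {
  set.seed(15)
  w <- spatial_window()
  cells <- rbind(random_pattern(300, c("CTL", "Tumor"), w, "s1"),
                 random_pattern(100, "Tumor", w, "s2"))  # no CTL in s2
  cells$patient_id <- ifelse(cells$sample_id == "s1", "p1", "p2")
  ft <- gcross_features(cells, list(c("CTL", "Tumor")), window = w)
  expect_identical(names(ft),
                   c("sample_id", "patient_id", "CTL_Tumor_G20",
                     "CTL_Tumor_G40", "CTL_Tumor_G60", "CTL_Tumor_G80",
                     "CTL_Tumor_AUC"))
  expect_false(anyNA(ft[ft$sample_id == "s1", -(1:2)]))
  expect_true(all(is.na(ft[ft$sample_id == "s2", -(1:2)])))
  expect_length(attr(ft, "exclusions"), 1L)
  # fixed-radius values agree with a directly estimated curve
  g <- gcross_empirical(cells[cells$sample_id == "s1", ], "CTL", "Tumor",
                        radii = 0:80, window = w)
  expect_equal(ft$CTL_Tumor_G40[ft$sample_id == "s1"], gcross_at(g, 40))
  expect_equal(ft$CTL_Tumor_AUC[ft$sample_id == "s1"], gcross_auc(g))
})
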