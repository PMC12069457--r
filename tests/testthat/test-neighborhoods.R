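# Inflammatory neighborhoods: anchor gating, disc-union membership,
# proportion views.

hand_cells <- function() {
  # 6 cells with controlled inflammatory-marker positivity (threshold 5)
  data.frame(
    sample_id = "s1",
    x_um = c(0, 10, 30, 100, 100.5, 500),
    y_um = c(0, 0, 0, 100, 100, 500),
    CD74 = c(9, 1, 1, 9, 1, 1),
    MIF = c(9, 9, 1, 9, 1, 1),
    CD44 = c(1, 9, 1, 9, 1, 1),
    cell_id = 1:6
  )
}

test_that("anchor gating requires every marker of the combination", {
  cells <- hand_cells()
  thr <- c(CD74 = 5, MIF = 5, CD44 = 5)
  expect_error(anchor_cells(cells, character(0), thr), "nonempty")

  a <- anchor_cells(cells, c("CD74", "MIF"), thr)
  expect_identical(a$cell_id, c(1L, 4L))  # cell 2 is CD74-negative

  # a cell positive for a superset anchors every contained combination
  expect_true(4L %in% anchor_cells(cells, c("CD74", "CD44"), thr)$cell_id)
  expect_true(4L %in% anchor_cells(cells, c("MIF", "CD44"), thr)$cell_id)
  expect_identical(anchor_cells(cells, c("CD74", "CD44", "MIF"), thr)$cell_id,
                   4L)

  # brute-force enumeration over all cells
  want <- which(cells$CD74 >= 5 & cells$MIF >= 5)
  expect_identical(a$cell_id, as.integer(want))
})

test_that("membership is a closed-bound nearest-anchor disc union per sample", {
  cells <- data.frame(
    sample_id = "s1",
    x_um = c(0, 10, 20.1, 20, 300),
    y_um = c(0, 0, 0, 0, 300),
    M1 = c(9, 1, 1, 1, 1),
    cell_id = 1:5
  )
  spec <- list(neighborhood_spec("nb", "M1", radius = 20))
  mem <- assign_neighborhoods(cells, spec, thresholds = c(M1 = 5))
  expect_identical(mem$nb, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  # anchor is a member of its own neighborhood (distance 0);
  # 20.1 um strictly exceeds the closed bound, 20 um does not

  # membership never crosses sample boundaries
  cells2 <- cells
  cells2$sample_id <- c("a", "b", "b", "b", "b")
  mem2 <- assign_neighborhoods(cells2, spec, thresholds = c(M1 = 5))
  expect_identical(mem2$nb, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("membership equals the all-pairs oracle and is monotone in radius", {
  set.seed(81)
  w <- spatial_window(300, 300)
  cells <- random_pattern(200, "x", w)
  cells$M1 <- runif(200, 0, 10)
  cells$M2 <- runif(200, 0, 10)
  cells$cell_id <- 1:200
  thr <- c(M1 = 7, M2 = 6)

  prev <- NULL
  for (R in c(20, 40, 60, 80)) {
    specs <- list(neighborhood_spec("nb", c("M1", "M2"), radius = R))
    mem <- assign_neighborhoods(cells, specs, thresholds = thr)
    anchors <- which(cells$M1 >= 7 & cells$M2 >= 6)
    want <- vapply(1:200, function(k) {
      d <- sqrt((cells$x_um[k] - cells$x_um[anchors])^2 +
                  (cells$y_um[k] - cells$y_um[anchors])^2)
      any(d <= R)
    }, logical(1))
    expect_identical(mem$nb, want)
    if (!is.null(prev)) expect_true(all(mem$nb | !prev))  # prev subset of mem
    prev <- mem$nb
  }
})

test_that("neighborhood prevalence and nested fractions match hand counts", {
  cells <- data.frame(
    sample_id = "s1",
    x_um = c(0, 5, 10, 200),
    y_um = c(0, 0, 0, 200),
    M1 = c(9, 1, 1, 1),
    phenotype = c("CTL", "CTL", "Tumor", "B"),
    cell_id = 1:4
  )
  specs <- list(neighborhood_spec("nb", "M1", radius = 20),
                neighborhood_spec("empty", "M1", radius = 20))
  cells$M1_empty <- 0  # no anchors for the second spec
  specs[[2]]$markers <- "M1_empty"
  mem <- assign_neighborhoods(cells, specs, thresholds = c(M1 = 5, M1_empty = 5))

  # prevalence: 3 of 4 cells within 20 um of the anchor; none for "empty"
  prev <- neighborhood_proportions(cells, mem)
  expect_equal(prev$value[prev$feature == "nb"], 0.75)
  expect_equal(prev$value[prev$feature == "empty"], 0)

  # cell types within neighborhood: 2 CTL + 1 Tumor among 3 members
  ctn <- celltype_within_neighborhood(cells, mem,
                                      types = c("CTL", "Tumor", "B"))
  g <- function(nb, ty) ctn$value[ctn$neighborhood == nb & ctn$type == ty]
  expect_equal(g("nb", "CTL"), 2 / 3)
  expect_equal(g("nb", "Tumor"), 1 / 3)
  expect_equal(g("nb", "B"), 0)
  # zero-member neighborhood contributes no rows (fraction undefined)
  expect_false("empty" %in% ctn$neighborhood)

  # neighborhoods within cell type: 2 of 2 CTLs inside, 0 of 1 B
  nct <- neighborhood_within_celltype(cells, mem,
                                      types = c("CTL", "B", "NK"))
  h <- function(ty, nb) nct$value[nct$type == ty & nct$neighborhood == nb]
  expect_equal(h("CTL", "nb"), 1)
  expect_equal(h("B", "nb"), 0)
  # absent type contributes no rows
  expect_false("NK" %in% nct$type)
})

test_that("fractions over an exclusive exhaustive partition sum to one", {
  set.seed(82)
  w <- spatial_window(300, 300)
  cells <- random_pattern(150, c("Tumor", "CTL", "B", "other"), w)
  cells$M1 <- runif(150, 0, 10)
  cells$cell_id <- seq_len(nrow(cells))
  mem <- assign_neighborhoods(cells,
                              list(neighborhood_spec("nb", "M1", radius = 40)),
                              thresholds = c(M1 = 6))
  ctn <- celltype_within_neighborhood(cells, mem,
                                      types = c("Tumor", "CTL", "B", "other"))
  sums <- tapply(ctn$value, paste(ctn$sample_id, ctn$neighborhood), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_true(all(ctn$value >= 0 & ctn$value <= 1))
})
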