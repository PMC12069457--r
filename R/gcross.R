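#' Theoretical G-cross under a homogeneous Poisson target process
#'
#' The cross-type nearest-neighbor distance function `G[i,j](r)` is the
#' cumulative distribution of the distance from a typical cell of type i to
#' its nearest cell of type j. When type j follows a homogeneous Poisson
#' process with density `alpha_j` (cells per square micrometer), independent
#' of type i, the closed form is
#' `G(r) = 1 - exp(-alpha_j * pi * r^2)`.
#'
#' @param alpha_j Density of the target cell type, in points per um^2
#'   (typically count / window area). Nonnegative.
#' @param r Distance(s) in micrometers. Nonnegative.
#' @return Values in \[0, 1\], vectorized over `r` and `alpha_j`.
#' @examples
#' gcross_theoretical(0.002, c(20, 40, 60, 80))
#' gcross_theoretical(log(2) / (100 * pi), 10)  # = 0.5
#' @seealso [gcross_empirical()]
#' @export
gcross_theoretical <- function(alpha_j, r) {
  .assert(is.numeric(alpha_j) && all(is.finite(alpha_j)) && all(alpha_j >= 0),
          "alpha_j must be nonnegative")
  .assert(is.numeric(r) && all(is.finite(r)) && all(r >= 0),
          "r must be nonnegative")
  1 - exp(-alpha_j * pi * r^2)
}

.new_gcross_curve <- function(r, est, correction, type_i, type_j,
                              n_i, n_j, alpha_j, window) {
  structure(
    list(r = r, est = est, correction = correction,
         type_i = type_i, type_j = type_j,
         n_i = n_i, n_j = n_j, alpha_j = alpha_j, window = window),
    class = "gcross_curve"
  )
}

#' @export
print.gcross_curve <- function(x, ...) {
  cat(sprintf("G-cross curve  %s -> %s  (%s estimator)\n",
              x$type_i, x$type_j, x$correction))
  cat(sprintf("  n_i = %d reference cells, n_j = %d target cells, alpha_j = %.3g /um^2\n",
              x$n_i, x$n_j, x$alpha_j))
  cat(sprintf("  radius grid: %g..%g um (%d points), %d undefined\n",
              min(x$r), max(x$r), length(x$r), sum(is.na(x$est))))
  invisible(x)
}

.check_radii <- function(radii) {
  .assert(is.numeric(radii) && length(radii) >= 2L && all(is.finite(radii)),
          "radii must be a numeric grid with at least two points")
  .assert(all(radii >= 0) && !is.unsorted(radii, strictly = TRUE),
          "radii must be nonnegative and strictly increasing")
  as.numeric(radii)
}

# Shared estimator core. rx/ry: reference points; tx/ty: targets.
# self_idx: per-reference column index into the target set to exclude
# (i = j case), or NULL.
.gcross_core <- function(rx, ry, tx, ty, radii, window, correction,
                         self_idx = NULL) {
  nnd <- .cross_nn_dist(rx, ry, tx, ty, self_idx = self_idx)
  if (correction == "raw") {
    est <- vapply(radii, function(r) mean(nnd <= r), numeric(1))
  } else {
    bd <- .border_dist(rx, ry, window)
    est <- vapply(radii, function(r) {
      keep <- bd >= r
      if (!any(keep)) return(NA_real_)
      mean(nnd[keep] <= r)
    }, numeric(1))
  }
  est
}

#' Empirical G-cross nearest-neighbor distance function
#'
#' Estimates `G[i,j](r)`, the fraction of type-i cells whose nearest type-j
#' cell lies within distance r, on a radius grid. Two estimators are
#' provided: `"raw"` (no edge correction) and `"border"` (reduced-sample
#' correction: at each r the reference set is restricted to type-i cells at
#' least r from the window boundary, so nearest-neighbor distances are never
#' censored by the window; the estimate is `NA` at radii where the restricted
#' set is empty). When `type_i == type_j`, each cell's own point is excluded
#' from its nearest-neighbor search. Coincident points (distance 0) count as
#' satisfied at every radius.
#'
#' One sample (core/ROI) is one point pattern; the estimator never pools
#' cells across samples.
#'
#' @param cells Cell table with columns `x_um`, `y_um` and a cell-type
#'   column. If `sample` is `NULL` the table must contain a single sample.
#' @param type_i,type_j Reference and target cell types.
#' @param radii Strictly increasing nonnegative radius grid in micrometers
#'   (default 0..80 um in 1 um steps).
#' @param window Observation window ([spatial_window()]).
#' @param correction `"border"` (default) or `"raw"`.
#' @param sample Optional sample id selecting one sample from `cells`.
#' @param type_col Name of the cell-type column (default `"phenotype"`).
#' @return A `gcross_curve` object: radius grid, estimates, correction,
#'   point counts `n_i`/`n_j` and target density `alpha_j = n_j / area`.
#' @details A sample with zero cells of either type cannot contribute a
#'   curve and is rejected with an error; callers scanning many pairs should
#'   catch and record the exclusion (see [gcross_features()]).
#' @examples
#' cells <- data.frame(
#'   sample_id = "s1",
#'   x_um = c(50, 53), y_um = c(50, 54),
#'   phenotype = c("CTL", "Tumor")
#' )
#' g <- gcross_empirical(cells, "CTL", "Tumor", radii = 0:10,
#'                       window = spatial_window(100, 100), correction = "raw")
#' gcross_at(g, 5)  # the single i-j distance is 5 um
#' @export
gcross_empirical <- function(cells, type_i, type_j, radii = 0:80,
                             window = spatial_window(),
                             correction = c("border", "raw"),
                             sample = NULL, type_col = "phenotype") {
  correction <- match.arg(correction)
  window <- .as_window(window)
  radii <- .check_radii(radii)
  .check_cells(cells, cols = c("x_um", "y_um", type_col))
  if (!is.null(sample)) {
    .check_cells(cells, "sample_id")
    cells <- cells[cells$sample_id == sample, , drop = FALSE]
  } else if ("sample_id" %in% names(cells)) {
    .assert(length(unique(cells$sample_id)) <= 1L,
            "cells spans several samples; supply `sample`")
  }
  types <- cells[[type_col]]
  ref_idx <- which(types == type_i)
  tar_idx <- which(types == type_j)
  if (length(ref_idx) == 0L || length(tar_idx) == 0L) {
    stop(sprintf("pair (%s, %s) excluded: zero cells of %s in sample",
                 type_i, type_j,
                 if (length(ref_idx) == 0L) type_i else type_j),
         call. = FALSE)
  }
  self_idx <- if (identical(type_i, type_j)) match(ref_idx, tar_idx) else NULL
  est <- .gcross_core(cells$x_um[ref_idx], cells$y_um[ref_idx],
                      cells$x_um[tar_idx], cells$y_um[tar_idx],
                      radii, window, correction, self_idx = self_idx)
  .new_gcross_curve(radii, est, correction, type_i, type_j,
                    n_i = length(ref_idx), n_j = length(tar_idx),
                    alpha_j = length(tar_idx) / window_area(window),
                    window = window)
}

#' G-cross restricted to an inflammatory neighborhood
#'
#' Same estimator as [gcross_empirical()], but the reference set is
#' restricted to type-i cells that are members of the given neighborhood;
#' target cells remain all type-j cells in the sample. This conditions the
#' focal (reference) cell on residing in the neighborhood while measuring
#' attraction toward the full target population.
#'
#' @inheritParams gcross_empirical
#' @param membership Membership table from [assign_neighborhoods()] for the
#'   same cells (matched by `cell_id`, or by row order when `cells` carries
#'   no `cell_id` column).
#' @param neighborhood Name of the membership column to condition on.
#' @return A `gcross_curve`.
#' @export
gcross_within_neighborhood <- function(cells, membership, neighborhood,
                                       type_i, type_j, radii = 0:80,
                                       window = spatial_window(),
                                       correction = c("border", "raw"),
                                       sample = NULL,
                                       type_col = "phenotype") {
  correction <- match.arg(correction)
  window <- .as_window(window)
  radii <- .check_radii(radii)
  .assert(neighborhood %in% names(membership),
          sprintf("membership has no column '%s'", neighborhood))
  .check_cells(cells, cols = c("x_um", "y_um", type_col))
  if (!"cell_id" %in% names(cells)) cells$cell_id <- seq_len(nrow(cells))
  if (!is.null(sample)) {
    cells <- cells[cells$sample_id == sample, , drop = FALSE]
    membership <- membership[membership$sample_id == sample, , drop = FALSE]
  }
  member <- membership[[neighborhood]][match(cells$cell_id, membership$cell_id)]
  member[is.na(member)] <- FALSE
  types <- cells[[type_col]]
  ref_idx <- which(types == type_i & member)
  tar_idx <- which(types == type_j)
  if (length(ref_idx) == 0L || length(tar_idx) == 0L) {
    stop(sprintf("pair (%s, %s) in neighborhood %s excluded: empty reference or target set",
                 type_i, type_j, neighborhood), call. = FALSE)
  }
  self_idx <- if (identical(type_i, type_j)) match(ref_idx, tar_idx) else NULL
  est <- .gcross_core(cells$x_um[ref_idx], cells$y_um[ref_idx],
                      cells$x_um[tar_idx], cells$y_um[tar_idx],
                      radii, window, correction, self_idx = self_idx)
  .new_gcross_curve(radii, est, correction, type_i, type_j,
                    n_i = length(ref_idx), n_j = length(tar_idx),
                    alpha_j = length(tar_idx) / window_area(window),
                    window = window)
}

#' Evaluate a G-cross curve at a radius
#'
#' Linear interpolation between grid points; exact at grid points. Radii at
#' which a border-corrected estimate is undefined are dropped before
#' interpolating.
#'
#' @param curve A `gcross_curve`.
#' @param r Radius in micrometers, within the grid range.
#' @return Estimate in \[0, 1\] (`NA` if `r` lies beyond the last defined
#'   grid point of a border-corrected curve).
#' @export
gcross_at <- function(curve, r) {
  .assert(inherits(curve, "gcross_curve"), "curve must be a gcross_curve")
  .assert(is.numeric(r) && length(r) >= 1L && all(is.finite(r)),
          "r must be numeric")
  .assert(all(r >= min(curve$r)) && all(r <= max(curve$r)),
          "r outside the curve's radius grid")
  ok <- !is.na(curve$est)
  .assert(sum(ok) >= 1L, "curve has no defined estimates")
  if (sum(ok) == 1L) {
    return(ifelse(r == curve$r[ok], curve$est[ok], NA_real_))
  }
  stats::approx(curve$r[ok], curve$est[ok], xout = r, method = "linear",
                rule = 1)$y
}

#' Area under a G-cross curve
#'
#' Trapezoidal integral of the estimated curve over \[0, r_max\], used as a
#' scalar spatial-infiltration feature. Undefined (border-corrected) grid
#' values are dropped and the trapezoids re-spanned over the remaining
#' points.
#'
#' @param curve A `gcross_curve`.
#' @param r_max Upper integration limit, at most the grid maximum.
#' @return The integral, in micrometers (a curve identically 1 on \[0, 40\]
#'   gives 40).
#' @export
gcross_auc <- function(curve, r_max = max(curve$r)) {
  .assert(inherits(curve, "gcross_curve"), "curve must be a gcross_curve")
  .assert(is.numeric(r_max) && length(r_max) == 1L && is.finite(r_max) &&
            r_max > 0 && r_max <= max(curve$r),
          "r_max must be in (0, max(grid)]")
  keep <- !is.na(curve$est) & curve$r <= r_max
  r <- curve$r[keep]
  g <- curve$est[keep]
  # close the interval at r_max when interpolation is possible
  if (length(r) && max(r) < r_max) {
    gmax <- gcross_at(curve, r_max)
    if (!is.na(gmax)) {
      r <- c(r, r_max)
      g <- c(g, gmax)
    }
  }
  .assert(length(r) >= 2L, "empty usable grid: cannot integrate")
  sum(diff(r) * (utils::head(g, -1) + utils::tail(g, -1)) / 2)
}

#' Per-sample G-cross feature table
#'
#' For each sample and each ordered cell-type pair, estimates the G-cross
#' curve and extracts fixed-radius evaluations and the AUC up to the largest
#' radius. These are the per-image spatial features consumed by the survival
#' scan. Pairs excluded in a sample (zero cells of either type) yield `NA`
#' features for that sample; exclusions are reported via
#' `attr(, "exclusions")`.
#'
#' @param cells Phenotyped cell table (columns `sample_id`, `x_um`, `y_um`,
#'   type column, optionally `patient_id` carried through).
#' @param pairs List of length-2 character vectors `c(type_i, type_j)`.
#' @param radii Radii (um) at which the estimate is reported
#'   (default 20/40/60/80).
#' @param window,correction,type_col Passed to [gcross_empirical()]. The
#'   estimation grid is 0..max(radii) in 1 um steps.
#' @param membership,neighborhood Optional: restrict reference cells to a
#'   neighborhood via [gcross_within_neighborhood()].
#' @param auc If `TRUE` (default) add an `<i>_<j>_AUC` column
#'   (integral over 0..max(radii)).
#' @return data.frame with one row per sample: `sample_id` (and
#'   `patient_id` if present in `cells`), then `<i>_<j>_G<r>` and
#'   `<i>_<j>_AUC` columns.
#' @export
gcross_features <- function(cells, pairs, radii = c(20, 40, 60, 80),
                            window = spatial_window(),
                            correction = c("border", "raw"),
                            type_col = "phenotype",
                            membership = NULL, neighborhood = NULL,
                            auc = TRUE) {
  correction <- match.arg(correction)
  .check_cells(cells, cols = c("sample_id", "x_um", "y_um", type_col))
  .assert(is.list(pairs) && length(pairs) >= 1L &&
            all(vapply(pairs, function(p) is.character(p) && length(p) == 2L,
                       logical(1))),
          "pairs must be a list of c(type_i, type_j) character pairs")
  radii <- sort(unique(as.numeric(radii)))
  grid <- seq(0, max(radii), by = 1)
  if (!all(radii %in% grid)) grid <- sort(unique(c(grid, radii)))
  samples <- unique(cells$sample_id)
  has_patient <- "patient_id" %in% names(cells)
  exclusions <- character(0)
  sample_rows <- split(seq_len(nrow(cells)),
                       factor(cells$sample_id, levels = samples))

  rows <- lapply(samples, function(s) {
    sub <- cells[sample_rows[[s]], , drop = FALSE]
    out <- list(sample_id = s)
    if (has_patient) out$patient_id <- sub$patient_id[1L]
    for (p in pairs) {
      stem <- paste(p[1L], p[2L], sep = "_")
      vals <- rep(NA_real_, length(radii) + as.integer(auc))
      curve <- tryCatch({
        if (is.null(membership)) {
          gcross_empirical(sub, p[1L], p[2L], radii = grid, window = window,
                           correction = correction, type_col = type_col)
        } else {
          gcross_within_neighborhood(sub, membership, neighborhood,
                                     p[1L], p[2L], radii = grid,
                                     window = window, correction = correction,
                                     type_col = type_col)
        }
      }, error = function(e) {
        exclusions <<- c(exclusions, sprintf("%s: %s", s, conditionMessage(e)))
        NULL
      })
      if (!is.null(curve)) {
        vals[seq_along(radii)] <- gcross_at(curve, radii)
        if (auc) vals[length(vals)] <- tryCatch(gcross_auc(curve),
                                                error = function(e) NA_real_)
      }
      nm <- c(paste0(stem, "_G", radii), if (auc) paste0(stem, "_AUC"))
      out[nm] <- as.list(vals)
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "exclusions") <- exclusions
  res
}
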