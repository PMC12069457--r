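# Inflammatory neighborhoods: distance-based regions around cells positive
# for an inflammatory-marker combination, plus the three proportion views
# (neighborhood prevalence, cell types within a neighborhood, neighborhoods
# within a cell type).

#' Inflammatory neighborhood specification
#'
#' A neighborhood is the union of discs of radius `radius` around every
#' anchor cell, an anchor being any cell positive for all markers in the
#' combination; equivalently, a cell is a member when its nearest anchor is
#' within `radius`.
#'
#' @param name Neighborhood name (used as a column name).
#' @param markers Nonempty character vector of markers all required
#'   positive.
#' @param radius Radius in micrometers (default 40, the emphasized
#'   interaction range; typically swept over 20-80).
#' @export
neighborhood_spec <- function(name, markers, radius = 40) {
  .assert(is.character(name) && length(name) == 1L && nzchar(name),
          "name must be a nonempty string")
  .assert(is.character(markers) && length(markers) >= 1L,
          "markers combination must be nonempty")
  .assert(is.numeric(radius) && length(radius) == 1L && radius > 0,
          "radius must be positive")
  structure(list(name = name, markers = markers, radius = as.numeric(radius)),
            class = "neighborhood_spec")
}

#' The seven default inflammatory neighborhoods
#'
#' Marker combinations over CD74, CD44, MIF, iNOS, mPGES1 and NT:
#' CD74+CD44, CD74+MIF, MIF+CD44, CD74+CD44+MIF, iNOS+mPGES1,
#' iNOS+mPGES1+NT, and iNOS+NT.
#'
#' @param radius Shared radius in micrometers.
#' @return List of [neighborhood_spec()]s.
#' @export
default_neighborhood_specs <- function(radius = 40) {
  combos <- list(
    CD74_CD44     = c("CD74", "CD44"),
    CD74_MIF      = c("CD74", "MIF"),
    MIF_CD44      = c("MIF", "CD44"),
    CD74_CD44_MIF = c("CD74", "CD44", "MIF"),
    iNOS_mPGES    = c("iNOS", "mPGES1"),
    iNOS_mPGES_NT = c("iNOS", "mPGES1", "NT"),
    iNOS_NT       = c("iNOS", "NT")
  )
  mapply(neighborhood_spec, names(combos), combos,
         MoreArgs = list(radius = radius), SIMPLIFY = FALSE)
}

#' Anchor cells of a marker combination
#'
#' Cells positive (per [threshold_positive()]) for every marker of the
#' combination. A cell positive for a superset of markers anchors every
#' contained combination.
#'
#' @param cells Cell table with intensity columns.
#' @param markers Nonempty marker combination.
#' @param thresholds Named per-marker thresholds.
#' @return The subset of `cells` that anchors the combination.
#' @export
anchor_cells <- function(cells, markers, thresholds = default_thresholds()) {
  .assert(is.character(markers) && length(markers) >= 1L,
          "marker combination must be nonempty")
  missing <- setdiff(markers, names(cells))
  .assert(length(missing) == 0L,
          paste0("no intensity column for marker(s): ",
                 paste(missing, collapse = ", ")))
  no_thr <- setdiff(markers, names(thresholds))
  .assert(length(no_thr) == 0L,
          paste0("no threshold for marker(s): ", paste(no_thr, collapse = ", ")))
  keep <- rep(TRUE, nrow(cells))
  for (m in markers) keep <- keep & threshold_positive(cells[[m]], thresholds[[m]])
  cells[keep, , drop = FALSE]
}

#' Assign cells to inflammatory neighborhoods
#'
#' A cell belongs to a neighborhood when its Euclidean distance to the
#' nearest anchor of that neighborhood is at most the neighborhood radius
#' (closed bound; anchors are members of their own neighborhood at distance
#' 0). Membership is computed within each sample independently, never
#' across samples; a cell may belong to any number of neighborhoods, and a
#' neighborhood with no anchors in a sample has no members there.
#'
#' @param cells Cell table with `sample_id`, coordinates and intensity
#'   columns (a `cell_id` column is added from row order when absent).
#' @param specs List of [neighborhood_spec()]s.
#' @param thresholds Named per-marker thresholds.
#' @return Membership table: `sample_id`, `cell_id`, one logical column per
#'   neighborhood, rows aligned with `cells`.
#' @export
assign_neighborhoods <- function(cells, specs = default_neighborhood_specs(),
                                 thresholds = default_thresholds()) {
  .check_cells(cells, cols = c("sample_id", "x_um", "y_um"))
  .assert(is.list(specs) && length(specs) >= 1L &&
            all(vapply(specs, inherits, logical(1), "neighborhood_spec")),
          "specs must be a list of neighborhood_spec objects")
  if (!"cell_id" %in% names(cells)) cells$cell_id <- seq_len(nrow(cells))
  out <- data.frame(sample_id = cells$sample_id, cell_id = cells$cell_id,
                    stringsAsFactors = FALSE)
  anchor_masks <- lapply(specs, function(sp) {
    mask <- rep(TRUE, nrow(cells))
    missing <- setdiff(sp$markers, names(cells))
    .assert(length(missing) == 0L,
            paste0("neighborhood ", sp$name, ": no intensity column for ",
                   paste(missing, collapse = ", ")))
    for (m in sp$markers) {
      mask <- mask & threshold_positive(cells[[m]], thresholds[[m]])
    }
    mask
  })
  for (k in seq_along(specs)) out[[specs[[k]]$name]] <- FALSE
  for (s in unique(cells$sample_id)) {
    in_s <- which(cells$sample_id == s)
    for (k in seq_along(specs)) {
      a <- in_s[anchor_masks[[k]][in_s]]
      if (length(a) == 0L) next
      nnd <- .cross_nn_dist(cells$x_um[in_s], cells$y_um[in_s],
                            cells$x_um[a], cells$y_um[a])
      out[[specs[[k]]$name]][in_s] <- nnd <= specs[[k]]$radius
    }
  }
  out
}

#' Neighborhood prevalence per sample
#'
#' For each sample and neighborhood: member count divided by all cells in
#' the sample.
#'
#' @param cells Cell table (supplies the per-sample denominators).
#' @param membership Output of [assign_neighborhoods()].
#' @return Tidy data.frame `sample_id`, `feature` (neighborhood), `value`.
#' @export
neighborhood_proportions <- function(cells, membership) {
  .check_cells(membership, cols = c("sample_id", "cell_id"))
  nb_cols <- setdiff(names(membership), c("sample_id", "cell_id"))
  .assert(length(nb_cols) >= 1L, "membership has no neighborhood columns")
  dt <- as.data.table(membership)
  agg <- dt[, lapply(.SD, mean), by = "sample_id", .SDcols = nb_cols]
  out <- data.table::melt(agg, id.vars = "sample_id",
                          variable.name = "feature", value.name = "value",
                          variable.factor = FALSE)
  setorderv(out, c("sample_id", "feature"))
  setDF(out)
  out
}

.join_membership <- function(cells, membership) {
  if (!"cell_id" %in% names(cells)) cells$cell_id <- seq_len(nrow(cells))
  nb_cols <- setdiff(names(membership), c("sample_id", "cell_id"))
  idx <- match(cells$cell_id, membership$cell_id)
  .assert(!anyNA(idx), "membership does not cover all cells")
  for (nb in nb_cols) cells[[nb]] <- membership[[nb]][idx]
  list(cells = cells, nb_cols = nb_cols)
}

.type_indicators <- function(cells, types = NULL) {
  ind_cols <- grep("^is_", names(cells), value = TRUE)
  if (is.null(types)) {
    types <- if (length(ind_cols)) sub("^is_", "", ind_cols) else {
      .assert("phenotype" %in% names(cells),
              "cells need a phenotype column or is_* indicator columns")
      sort(unique(cells$phenotype))
    }
  }
  ind <- lapply(types, function(ty) {
    icol <- paste0("is_", ty)
    if (icol %in% names(cells)) cells[[icol]] else cells$phenotype == ty
  })
  names(ind) <- types
  ind
}

#' Cell-type composition within each neighborhood
#'
#' For each sample, neighborhood and cell type: cells of the type that are
#' members, divided by all member cells. Samples where a neighborhood has
#' no members contribute no rows for it (the fraction is undefined),
#' mirroring zero-variance exclusion downstream.
#'
#' @param cells Phenotyped cell table.
#' @param membership Output of [assign_neighborhoods()].
#' @param types Cell types to report (default: from `is_*` columns or
#'   phenotype labels).
#' @return data.frame `sample_id`, `neighborhood`, `type`,
#'   `feature` (`"<neighborhood>|<type>"`), `value`.
#' @export
celltype_within_neighborhood <- function(cells, membership, types = NULL) {
  .check_cells(cells, cols = "sample_id")
  j <- .join_membership(cells, membership)
  cells <- j$cells
  ind <- .type_indicators(cells, types)
  rows <- list()
  for (s in unique(cells$sample_id)) {
    in_s <- cells$sample_id == s
    for (nb in j$nb_cols) {
      mem <- in_s & cells[[nb]]
      n_mem <- sum(mem)
      if (n_mem == 0L) next
      for (ty in names(ind)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, neighborhood = nb, type = ty,
          feature = paste(nb, ty, sep = "|"),
          value = sum(ind[[ty]] & mem) / n_mem,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), neighborhood = character(0),
               type = character(0), feature = character(0),
               value = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Neighborhood occupancy within each cell type
#'
#' For each sample, cell type and neighborhood: cells of the type that are
#' members, divided by all cells of the type in the sample. Samples without
#' any cell of the type contribute no rows for it.
#'
#' @inheritParams celltype_within_neighborhood
#' @return data.frame `sample_id`, `type`, `neighborhood`,
#'   `feature` (`"<type>|<neighborhood>"`), `value`.
#' @export
neighborhood_within_celltype <- function(cells, membership, types = NULL) {
  .check_cells(cells, cols = "sample_id")
  j <- .join_membership(cells, membership)
  cells <- j$cells
  ind <- .type_indicators(cells, types)
  rows <- list()
  for (s in unique(cells$sample_id)) {
    in_s <- cells$sample_id == s
    for (ty in names(ind)) {
      of_type <- in_s & ind[[ty]]
      n_ty <- sum(of_type)
      if (n_ty == 0L) next
      for (nb in j$nb_cols) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, type = ty, neighborhood = nb,
          feature = paste(ty, nb, sep = "|"),
          value = sum(of_type & cells[[nb]]) / n_ty,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), type = character(0),
               neighborhood = character(0), feature = character(0),
               value = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
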