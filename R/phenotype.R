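# Cell phenotyping from marker intensities: H-score quantification,
# threshold gating, and a priority-ordered rule hierarchy producing both an
# exclusive leaf label and overlapping per-type indicator columns.

#' H-score from staining-intensity bin percentages
#'
#' Semi-quantitative staining score:
#' `H = (% of 1+ cells) * 1 + (% of 2+ cells) * 2 + (% of 3+ cells) * 3`,
#' ranging from 0 (no staining) to 300 (100% of cells at 3+ intensity).
#'
#' @param pct_1plus,pct_2plus,pct_3plus Percentages of cells staining at
#'   weak (1+), moderate (2+) and strong (3+) intensity. Each in
#'   \[0, 100\]; their sum may not exceed 100. Vectorized.
#' @return H-score(s) in \[0, 300\].
#' @examples
#' compute_hscore(0, 0, 100)   # 300, maximum staining
#' compute_hscore(0, 0, 0)     # 0, negative
#' compute_hscore(10, 20, 30)  # 140
#' @export
compute_hscore <- function(pct_1plus, pct_2plus, pct_3plus) {
  v <- cbind(pct_1plus, pct_2plus, pct_3plus)   # recycles and type-checks
  .assert(is.numeric(v) && all(is.finite(v)),
          "percentages must be finite numerics")
  .assert(all(v >= 0) && all(v <= 100),
          "percentages must lie in [0, 100]")
  tot <- rowSums(v)
  .assert(all(tot <= 100 + 1e-8),
          "intensity-bin percentages sum to more than 100")
  drop(v %*% c(1, 2, 3))
}

#' Threshold positivity of a marker intensity
#'
#' A cell is positive when its intensity reaches the threshold (closed
#' lower bound, `intensity >= threshold`).
#'
#' @param intensity Nonnegative intensity value(s).
#' @param threshold Nonnegative gating threshold.
#' @return Logical, vectorized.
#' @export
threshold_positive <- function(intensity, threshold) {
  .assert(is.numeric(intensity) && all(intensity >= 0, na.rm = TRUE),
          "intensity must be nonnegative")
  .assert(is.numeric(threshold) && all(threshold >= 0),
          "threshold must be nonnegative")
  intensity >= threshold
}

#' Phenotype gating rule
#'
#' A cell satisfies a rule when it is positive for every marker in
#' `positive` and negative for every marker in `negative`. Among satisfied
#' rules the lowest `priority` value wins the exclusive label, which lets
#' subtype rules (CTL, Th, M2) pre-empt their parent rules (T, TAM).
#'
#' @param type Phenotype label assigned by the rule.
#' @param positive,negative Character vectors of required-positive /
#'   required-negative markers (disjoint).
#' @param priority Integer; lower wins. Must be unique within a rule set.
#' @export
phenotype_rule <- function(type, positive = character(0),
                           negative = character(0), priority) {
  .assert(is.character(type) && length(type) == 1L && nzchar(type),
          "type must be a nonempty string")
  .assert(length(intersect(positive, negative)) == 0L,
          "positive and negative marker sets must be disjoint")
  .assert(is.numeric(priority) && length(priority) == 1L,
          "priority must be a single number")
  structure(list(type = type, positive = positive, negative = negative,
                 priority = as.integer(priority)),
            class = "phenotype_rule")
}

#' Default 8-type gating hierarchy
#'
#' Tumor: SOX10+ S100+; T lineage: CD3+, subdivided into CTL (CD3+ CD8+)
#' and Th (CD3+ CD4+); B: CD20+; macrophages: CD68+ (TAM) with CD163
#' marking the M2 phenotype; NK: NKp46+. Subtypes take priority over
#' parents, so a CD3+ CD8+ cell is labeled CTL, not T, while still counting
#' as T in the overlapping indicator columns. The marker choices are a
#' configurable stand-in for a study-specific antibody panel.
#'
#' @return List of [phenotype_rule()]s.
#' @export
default_phenotype_rules <- function() {
  list(
    phenotype_rule("CTL",   positive = c("CD3", "CD8"),    priority = 1),
    phenotype_rule("Th",    positive = c("CD3", "CD4"),    priority = 2),
    phenotype_rule("M2",    positive = c("CD68", "CD163"), priority = 3),
    phenotype_rule("T",     positive = "CD3",              priority = 4),
    phenotype_rule("B",     positive = "CD20",             priority = 5),
    phenotype_rule("TAM",   positive = "CD68",             priority = 6),
    phenotype_rule("NK",    positive = "NKp46",            priority = 7),
    phenotype_rule("Tumor", positive = c("SOX10", "S100"), priority = 8)
  )
}

#' Default gating thresholds
#'
#' One threshold per marker, the geometric mean of the default high and low
#' signal means (the midpoint of a log-normal two-population model).
#'
#' @param markers Marker names.
#' @param high,low Signal means the threshold separates.
#' @export
default_thresholds <- function(markers = c("SOX10", "S100", "CD3", "CD4",
                                           "CD8", "CD20", "CD68", "CD163",
                                           "NKp46", "CD74", "CD44", "MIF",
                                           "iNOS", "mPGES1", "NT"),
                               high = 50, low = 1) {
  stats::setNames(rep(sqrt(high * low), length(markers)), markers)
}

#' Classify cells by threshold gating
#'
#' Evaluates every rule on every cell. The `phenotype` column receives the
#' label of the satisfied rule with the lowest priority value, or `"other"`
#' when no rule is satisfied. One logical `is_<type>` column per rule is
#' appended, recording rule satisfaction regardless of priority, so
#' overlapping populations (every CTL is also a T cell) remain countable.
#' Deterministic and invariant to row order.
#'
#' @param cells Cell table with an intensity column for every marker any
#'   rule references.
#' @param rules List of [phenotype_rule()]s with unique priorities.
#' @param thresholds Named per-marker thresholds covering all rule markers.
#' @return `cells` with `phenotype` and `is_<type>` columns appended.
#' @export
classify_cells <- function(cells, rules = default_phenotype_rules(),
                           thresholds = default_thresholds()) {
  .assert(is.data.frame(cells), "cells must be a data.frame")
  .assert(is.list(rules) && length(rules) >= 1L &&
            all(vapply(rules, inherits, logical(1), "phenotype_rule")),
          "rules must be a list of phenotype_rule objects")
  prios <- vapply(rules, `[[`, integer(1), "priority")
  .assert(!anyDuplicated(prios), "rule priorities must be unique")
  used <- unique(unlist(lapply(rules, function(r) c(r$positive, r$negative))))
  no_thr <- setdiff(used, names(thresholds))
  .assert(length(no_thr) == 0L,
          paste0("no threshold for marker(s): ", paste(no_thr, collapse = ", ")))
  no_col <- setdiff(used, names(cells))
  .assert(length(no_col) == 0L,
          paste0("rule references unknown marker column(s): ",
                 paste(no_col, collapse = ", ")))

  n <- nrow(cells)
  pos <- lapply(used, function(m) threshold_positive(cells[[m]], thresholds[[m]]))
  names(pos) <- used

  sat <- lapply(rules, function(r) {
    ok <- rep(TRUE, n)
    for (m in r$positive) ok <- ok & pos[[m]]
    for (m in r$negative) ok <- ok & !pos[[m]]
    ok
  })
  phenotype <- rep("other", n)
  for (k in order(prios, decreasing = TRUE)) {
    phenotype[sat[[k]]] <- rules[[k]]$type
  }
  cells$phenotype <- phenotype
  for (k in seq_along(rules)) {
    cells[[paste0("is_", rules[[k]]$type)]] <- sat[[k]]
  }
  cells
}

#' Per-sample cell-type proportions
#'
#' For each sample and type: count of cells of that type divided by all
#' cells in the sample. When overlapping `is_<type>` indicator columns are
#' present (from [classify_cells()]) they define the counts, so nested
#' populations (T contains CTL and Th) are each reported against the common
#' all-cells denominator and proportions need not sum to 1. Otherwise the
#' exclusive `phenotype` label is counted.
#'
#' @param cells Phenotyped cell table with `sample_id`.
#' @param types Types to report (default: all `is_*` columns, or all
#'   observed phenotype labels).
#' @return Tidy data.frame `sample_id`, `feature` (type), `value`
#'   (proportion in \[0, 1\]).
#' @export
cell_type_proportions <- function(cells, types = NULL) {
  .check_cells(cells, cols = "sample_id")
  ind_cols <- grep("^is_", names(cells), value = TRUE)
  if (is.null(types)) {
    types <- if (length(ind_cols)) sub("^is_", "", ind_cols) else {
      .assert("phenotype" %in% names(cells),
              "cells need a phenotype column or is_* indicator columns")
      sort(unique(cells$phenotype))
    }
  }
  dt <- as.data.table(cells)
  rows <- lapply(types, function(ty) {
    icol <- paste0("is_", ty)
    if (icol %in% names(dt)) {
      agg <- dt[, list(value = mean(.SD[[1L]])), by = "sample_id",
                .SDcols = icol]
    } else {
      .assert("phenotype" %in% names(dt),
              "cells need a phenotype column or is_* indicator columns")
      agg <- dt[, list(value = mean(phenotype == ty)), by = "sample_id"]
    }
    agg[, feature := ty]
    agg
  })
  out <- rbindlist(rows)[, c("sample_id", "feature", "value"), with = FALSE]
  setorderv(out, c("sample_id", "feature"))
  setDF(out)
  out
}
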