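# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

.set_seed <- function(seed) {
  if (!is.null(seed)) {
    .assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
            "seed must be a single finite number")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Row minima of a dense matrix without apply(); max.col is C-level.
.row_mins <- function(m) {
  m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]
}

# Nearest-neighbor distances from each reference point to a target point set.
# self_idx[i], when not NA, is the column (target index) excluded for reference
# point i (used when reference points are themselves targets, i = j case).
# Chunked so the distance matrix never exceeds ~4e6 entries.
.cross_nn_dist <- function(rx, ry, tx, ty, self_idx = NULL) {
  n_ref <- length(rx)
  n_tar <- length(tx)
  if (n_ref == 0L) return(numeric(0))
  if (n_tar == 0L) return(rep(Inf, n_ref))
  out <- numeric(n_ref)
  chunk <- max(1L, as.integer(4e6 / n_tar))
  for (s in seq(1L, n_ref, by = chunk)) {
    e <- min(s + chunk - 1L, n_ref)
    d2 <- outer(rx[s:e], tx, "-")^2 + outer(ry[s:e], ty, "-")^2
    if (!is.null(self_idx)) {
      loc <- self_idx[s:e]
      hit <- which(!is.na(loc))
      if (length(hit)) d2[cbind(hit, loc[hit])] <- Inf
    }
    out[s:e] <- sqrt(.row_mins(d2))
  }
  out
}

#' Rectangular observation window
#'
#' Defines the planar region containing a cell sample. The default matches a
#' 1 x 1 mm imaging region of interest, with coordinates in micrometers and
#' the origin at the lower-left corner.
#'
#' @param width,height Window dimensions in micrometers; must be positive.
#' @return An object of class `spatial_window` with fields `width` and
#'   `height`.
#' @examples
#' w <- spatial_window()          # 1000 x 1000 um
#' window_area(w)                 # 1e6 um^2
#' @export
spatial_window <- function(width = 1000, height = 1000) {
  .assert(is.numeric(width) && length(width) == 1L && is.finite(width) && width > 0,
          "width must be a single positive number")
  .assert(is.numeric(height) && length(height) == 1L && is.finite(height) && height > 0,
          "height must be a single positive number")
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "spatial_window")
}

#' @rdname spatial_window
#' @param window A `spatial_window`.
#' @export
window_area <- function(window) {
  window <- .as_window(window)
  window$width * window$height
}

.as_window <- function(window) {
  if (inherits(window, "spatial_window")) return(window)
  if (is.numeric(window) && length(window) == 2L) {
    return(spatial_window(window[1L], window[2L]))
  }
  stop("window must be a spatial_window or a numeric (width, height) pair",
       call. = FALSE)
}

# Distance from each point to the nearest window edge.
.border_dist <- function(x, y, window) {
  pmin(x, y, window$width - x, window$height - y)
}

.check_cells <- function(cells, cols = c("sample_id", "x_um", "y_um")) {
  .assert(is.data.frame(cells), "cells must be a data.frame")
  missing <- setdiff(cols, names(cells))
  .assert(length(missing) == 0L,
          paste0("cells is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  invisible(TRUE)
}

#' @importFrom data.table := .N .SD as.data.table data.table rbindlist setDF setorderv fwrite fread
NULL
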