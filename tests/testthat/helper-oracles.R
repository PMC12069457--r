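# Independent brute-force oracles used to validate the package estimators.
# These are deliberately written as explicit loops over the defining
# formulas and share no code with the implementation.

# Nearest-neighbor distance from each reference point to a target set,
# one reference point at a time.
oracle_nn_dist <- function(rx, ry, tx, ty, self = NULL) {
  vapply(seq_along(rx), function(k) {
    d <- sqrt((rx[k] - tx)^2 + (ry[k] - ty)^2)
    if (!is.null(self) && !is.na(self[k])) d <- d[-self[k]]
    if (length(d) == 0L) Inf else min(d)
  }, numeric(1))
}

# G-cross by direct application of the definition: the fraction of
# reference points whose nearest target lies within r; for the border
# estimator the reference set at each r is restricted to points at least r
# from the window edge.
oracle_gcross <- function(cells, type_i, type_j, radii, window,
                          correction = "raw", type_col = "phenotype",
                          ref_keep = NULL) {
  ref <- which(cells[[type_col]] == type_i)
  if (!is.null(ref_keep)) ref <- intersect(ref, which(ref_keep))
  tar <- which(cells[[type_col]] == type_j)
  self <- if (type_i == type_j) match(ref, tar) else NULL
  nnd <- oracle_nn_dist(cells$x_um[ref], cells$y_um[ref],
                        cells$x_um[tar], cells$y_um[tar], self = self)
  bd <- pmin(cells$x_um[ref], cells$y_um[ref],
             window$width - cells$x_um[ref],
             window$height - cells$y_um[ref])
  vapply(radii, function(r) {
    if (correction == "raw") return(mean(nnd <= r))
    keep <- bd >= r
    if (!any(keep)) return(NA_real_)
    mean(nnd[keep] <= r)
  }, numeric(1))
}

# Benjamini-Hochberg step-up by the definition: sort p ascending, take
# p_(k) * m / k, enforce monotonicity from the largest rank down, cap at 1,
# map back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  run_min <- Inf
  for (k in m:1) {
    run_min <- min(run_min, p[ord[k]] * m / k)
    q_sorted[k] <- min(run_min, 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Random single-sample phenotyped point pattern for oracle comparisons.
random_pattern <- function(n, types, window = spatial_window(),
                           sample_id = "s1") {
  data.frame(
    sample_id = sample_id,
    x_um = runif(n, 0, window$width),
    y_um = runif(n, 0, window$height),
    phenotype = sample(types, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
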