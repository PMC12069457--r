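# Synthetic-cohort generator: marked point patterns with known spatial,
# compositional, and survival structure, shaped like a two-TMA melanoma
# study (Stage III: 157 patients x 2 cores; Stage IV: 248 patients, 393
# cores across 5 metastatic-site strata).

.CELL_TYPES <- c("B", "T", "Th", "CTL", "NK", "TAM", "M2", "Tumor")
.INFLAMMATORY_MARKERS <- c("CD74", "CD44", "MIF", "iNOS", "mPGES1", "NT")

#' Simulate a multitype homogeneous Poisson point pattern
#'
#' For each cell type, the number of cells is Poisson with mean
#' `density * window area` and coordinates are uniform in the window. This
#' is the null model under which the G-cross closed form
#' `1 - exp(-alpha_j * pi * r^2)` holds.
#'
#' @param intensities Named nonnegative vector, points per um^2 by cell type.
#' @param window Observation window ([spatial_window()]).
#' @param seed Optional integer; if supplied the RNG is seeded so identical
#'   seeds give identical tables. `NULL` (default) continues the current
#'   RNG stream (used when composing simulations under one outer seed).
#' @return data.frame with columns `x_um`, `y_um`, `true_type`.
#' @examples
#' cells <- simulate_poisson_multitype(c(Tumor = 5e-4, CTL = 2e-4), seed = 1)
#' table(cells$true_type)
#' @export
simulate_poisson_multitype <- function(intensities, window = spatial_window(),
                                       seed = NULL) {
  .assert(is.numeric(intensities) && length(intensities) >= 1L &&
            !is.null(names(intensities)) && all(nzchar(names(intensities))),
          "intensities must be a named numeric vector")
  .assert(all(is.finite(intensities)) && all(intensities >= 0),
          "densities must be nonnegative")
  window <- .as_window(window)
  .set_seed(seed)
  area <- window_area(window)
  parts <- lapply(names(intensities), function(ty) {
    n <- stats::rpois(1L, intensities[[ty]] * area)
    data.frame(x_um = stats::runif(n, 0, window$width),
               y_um = stats::runif(n, 0, window$height),
               true_type = rep(ty, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# Offspring displaced from parents by isotropic Gaussian, re-drawn
# (rejection, not clipping) until inside the window so the within-window
# process has no boundary pile-up.
.scatter_offspring <- function(px, py, counts, sigma, window) {
  n <- sum(counts)
  if (n == 0L) return(data.frame(x_um = numeric(0), y_um = numeric(0)))
  ox <- rep(px, counts)
  oy <- rep(py, counts)
  x <- ox + stats::rnorm(n, 0, sigma)
  y <- oy + stats::rnorm(n, 0, sigma)
  bad <- which(x < 0 | x > window$width | y < 0 | y > window$height)
  while (length(bad)) {
    x[bad] <- ox[bad] + stats::rnorm(length(bad), 0, sigma)
    y[bad] <- oy[bad] + stats::rnorm(length(bad), 0, sigma)
    bad <- bad[x[bad] < 0 | x[bad] > window$width |
                 y[bad] < 0 | y[bad] > window$height]
  }
  data.frame(x_um = x, y_um = y)
}

#' Simulate cross-type spatial attraction (parent-offspring clustering)
#'
#' Parents form a homogeneous Poisson pattern; each parent receives a
#' Poisson(`mean_offspring`) number of offspring of a second type, displaced
#' by an isotropic Gaussian with scale `sigma` and re-drawn until inside the
#' window. The offspring type is thereby spatially attracted to the parent
#' type, lifting `G[parent, offspring](r)` above the Poisson baseline at
#' ranges comparable to `sigma` — the ground truth against which clustering
#' detection is validated.
#'
#' @param parent_type,offspring_type Type labels for the two patterns.
#' @param parent_density Parent intensity, points per um^2.
#' @param mean_offspring Mean offspring per parent (>= 0).
#' @param sigma Gaussian displacement scale in um (> 0).
#' @param window,seed As in [simulate_poisson_multitype()].
#' @return data.frame `x_um`, `y_um`, `true_type` containing both types.
#' @export
simulate_attraction <- function(parent_type, offspring_type, parent_density,
                                mean_offspring, sigma,
                                window = spatial_window(), seed = NULL) {
  .assert(is.numeric(sigma) && length(sigma) == 1L && is.finite(sigma) &&
            sigma > 0, "sigma must be a positive displacement scale")
  .assert(is.numeric(parent_density) && parent_density >= 0,
          "parent_density must be nonnegative")
  .assert(is.numeric(mean_offspring) && mean_offspring >= 0,
          "mean_offspring must be nonnegative")
  window <- .as_window(window)
  .set_seed(seed)
  parents <- simulate_poisson_multitype(
    stats::setNames(parent_density, parent_type), window)
  counts <- stats::rpois(nrow(parents), mean_offspring)
  kids <- .scatter_offspring(parents$x_um, parents$y_um, counts, sigma, window)
  kids$true_type <- rep(offspring_type, nrow(kids))
  out <- rbind(parents, kids)
  rownames(out) <- NULL
  out
}

#' Construct a marker signal model
#'
#' Maps each cell type to per-marker mean intensities: markers in a type's
#' positive set get the `high` mean, all others the `low` mean. Intensities
#' are later drawn log-normally around these means ([simulate_marker_intensities()]),
#' reflecting the strictly positive, multiplicative noise of fluorescence
#' and ion-count data; `sdlog` controls the overlap between the positive and
#' negative populations (`high/low` is the separation).
#'
#' @param positive Named list: cell type -> character vector of markers the
#'   type expresses (may be empty for an "other" type).
#' @param markers Full marker panel (default: union of all positive sets).
#' @param high,low Mean intensity of expressed / unexpressed markers.
#' @param sdlog Log-scale noise (0 = noise-free).
#' @return A named list of per-type `list(means, sdlog)`, class
#'   `marker_model`.
#' @export
make_marker_model <- function(positive, markers = NULL, high = 50, low = 1,
                              sdlog = 0.25) {
  .assert(is.list(positive) && !is.null(names(positive)),
          "positive must be a named list of marker sets")
  .assert(high > 0 && low > 0 && sdlog >= 0,
          "high/low means must be positive, sdlog nonnegative")
  markers <- markers %||% sort(unique(unlist(positive)))
  model <- lapply(positive, function(pos) {
    bad <- setdiff(pos, markers)
    .assert(length(bad) == 0L,
            paste0("positive markers outside panel: ", paste(bad, collapse = ", ")))
    means <- stats::setNames(ifelse(markers %in% pos, high, low), markers)
    list(means = means, sdlog = sdlog)
  })
  structure(model, class = "marker_model", markers = markers)
}

#' Default phenotype-marker signal model for the 8-type taxonomy
#'
#' Tumor cells express SOX10 and S100; T-lineage cells CD3 with CD8 (CTL)
#' or CD4 (Th); B cells CD20; macrophages CD68 with CD163 marking the M2
#' phenotype; NK cells NKp46. An "other" type expresses nothing.
#'
#' @inheritParams make_marker_model
#' @export
default_marker_model <- function(high = 50, low = 1, sdlog = 0.25) {
  make_marker_model(
    positive = list(
      Tumor = c("SOX10", "S100"),
      T     = "CD3",
      CTL   = c("CD3", "CD8"),
      Th    = c("CD3", "CD4"),
      B     = "CD20",
      TAM   = "CD68",
      M2    = c("CD68", "CD163"),
      NK    = "NKp46",
      other = character(0)
    ),
    markers = c("SOX10", "S100", "CD3", "CD4", "CD8", "CD20", "CD68",
                "CD163", "NKp46"),
    high = high, low = low, sdlog = sdlog
  )
}

#' Draw per-cell marker intensities from a signal model
#'
#' Each cell's intensity for each marker is log-normal with median equal to
#' the configured mean for its true type and log-scale noise `sdlog`
#' (noise 0 reproduces the means exactly). Deterministic under a seed.
#'
#' @param cells Cell table with a `true_type` column.
#' @param marker_model A [make_marker_model()] object covering every type
#'   present in `cells`.
#' @param seed Optional integer seed.
#' @return `cells` with one intensity column per marker appended.
#' @export
simulate_marker_intensities <- function(cells, marker_model = default_marker_model(),
                                        seed = NULL) {
  .check_cells(cells, cols = "true_type")
  .assert(inherits(marker_model, "marker_model"),
          "marker_model must come from make_marker_model()")
  unknown <- setdiff(unique(cells$true_type), names(marker_model))
  .assert(length(unknown) == 0L,
          paste0("cell type(s) without a signal model: ",
                 paste(unknown, collapse = ", ")))
  .set_seed(seed)
  markers <- attr(marker_model, "markers")
  n <- nrow(cells)
  for (m in markers) cells[[m]] <- NA_real_
  for (ty in unique(cells$true_type)) {
    idx <- which(cells$true_type == ty)
    mm <- marker_model[[ty]]
    for (m in markers) {
      cells[[m]][idx] <- stats::rlnorm(length(idx),
                                       meanlog = log(mm$means[[m]]),
                                       sdlog = mm$sdlog)
    }
  }
  cells
}

#' Assign inflammatory anchor-marker intensities
#'
#' Each cell is independently positive for each inflammatory marker with the
#' configured probability; positives draw a high log-normal intensity,
#' negatives a low one. Optionally, positivity is restricted to a sub-window
#' (`block_frac` of each dimension, lower-left anchored) to create spatially
#' coherent marker-positive regions.
#'
#' @param cells Cell table with coordinates.
#' @param rates Named probability vector, one entry per inflammatory marker.
#' @param high,low,sdlog Log-normal signal parameters as in
#'   [make_marker_model()].
#' @param block_frac Optional value in (0, 1\]: positivity only occurs in
#'   the `[0, block_frac * width] x [0, block_frac * height]` sub-window.
#' @param window,seed As elsewhere.
#' @return `cells` with one intensity column per marker appended.
#' @export
simulate_anchor_markers <- function(cells, rates = default_anchor_rates("III"),
                                    high = 50, low = 1, sdlog = 0.25,
                                    block_frac = NULL,
                                    window = spatial_window(), seed = NULL) {
  .check_cells(cells, cols = c("x_um", "y_um"))
  .assert(is.numeric(rates) && !is.null(names(rates)) &&
            all(rates >= 0 & rates <= 1),
          "rates must be named probabilities in [0, 1]")
  window <- .as_window(window)
  .set_seed(seed)
  n <- nrow(cells)
  eligible <- rep(TRUE, n)
  if (!is.null(block_frac)) {
    .assert(block_frac > 0 && block_frac <= 1, "block_frac must be in (0, 1]")
    eligible <- cells$x_um <= block_frac * window$width &
      cells$y_um <= block_frac * window$height
  }
  for (m in names(rates)) {
    pos <- eligible & (stats::runif(n) < rates[[m]])
    cells[[m]] <- stats::rlnorm(n, meanlog = log(ifelse(pos, high, low)),
                                sdlog = sdlog)
  }
  cells
}

#' Default inflammatory-marker positivity rates by stage
#'
#' Per-cell positivity probabilities for the six inflammatory markers. The
#' Stage IV defaults raise CD74/CD44/MIF and lower iNOS/mPGES1/NT relative
#' to Stage III, so CD74- and MIF-defined neighborhoods expand while
#' iNOS-associated ones contract in the advanced-stage arm.
#'
#' @param stage `"III"` or `"IV"`.
#' @export
default_anchor_rates <- function(stage = c("III", "IV")) {
  stage <- match.arg(stage)
  if (stage == "III") {
    c(CD74 = 0.10, CD44 = 0.10, MIF = 0.08,
      iNOS = 0.12, mPGES1 = 0.10, NT = 0.10)
  } else {
    c(CD74 = 0.14, CD44 = 0.12, MIF = 0.13,
      iNOS = 0.06, mPGES1 = 0.05, NT = 0.06)
  }
}

#' Simulate survival outcomes linked to per-sample features
#'
#' Patient-level features are the mean of that patient's per-sample
#' features. Event times are exponential with rate
#' `baseline * exp(sum(coef * feature))`; censoring is independent
#' exponential with rate `censor_rate` (0 = no censoring). Clustering in
#' downstream models arises from patients contributing several samples with
#' correlated features, not from a frailty term.
#'
#' @param features data.frame with `patient_id` and one numeric column per
#'   named coefficient in `survival_link$coef`.
#' @param survival_link `list(baseline = rate > 0, coef = named numeric,
#'   censor_rate = rate >= 0)`.
#' @param seed Optional integer seed.
#' @return data.frame `patient_id`, `time_months`, `event`.
#' @export
simulate_survival <- function(features, survival_link, seed = NULL) {
  .assert(is.data.frame(features) && "patient_id" %in% names(features),
          "features must be a data.frame with a patient_id column")
  .assert(is.list(survival_link) && !is.null(survival_link$baseline),
          "survival_link must list baseline, coef, censor_rate")
  base <- survival_link$baseline
  .assert(is.numeric(base) && length(base) == 1L && base > 0,
          "baseline hazard must be positive")
  cens <- survival_link$censor_rate %||% 0
  .assert(cens >= 0, "censor_rate must be nonnegative")
  coef <- survival_link$coef %||% stats::setNames(numeric(0), character(0))
  missing <- setdiff(names(coef), names(features))
  .assert(length(missing) == 0L,
          paste0("features missing linked column(s): ",
                 paste(missing, collapse = ", ")))
  .set_seed(seed)
  if (length(coef)) {
    dt <- as.data.table(features)
    agg <- dt[, lapply(.SD, function(v) mean(v, na.rm = TRUE)),
              by = "patient_id",
              .SDcols = names(coef)]
    setDF(agg)
  } else {
    agg <- data.frame(patient_id = unique(features$patient_id),
                      stringsAsFactors = FALSE)
  }
  lin <- if (length(coef)) {
    as.matrix(agg[, names(coef), drop = FALSE]) %*% coef
  } else {
    rep(0, nrow(agg))
  }
  lin[!is.finite(lin)] <- 0   # patients with no defined feature contribute baseline hazard
  rate <- base * exp(drop(lin))
  n <- nrow(agg)
  t_event <- stats::rexp(n, rate)
  t_cens <- if (cens > 0) stats::rexp(n, cens) else rep(Inf, n)
  data.frame(patient_id = agg$patient_id,
             time_months = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}

#' Build a synthetic-cohort recipe
#'
#' Bundles everything [generate_cohort()] needs: window, per-type densities
#' (optionally heterogeneous across patients), cross-type attraction rules,
#' marker signal model, inflammatory-marker rates, the survival link, cohort
#' size, and the seed.
#'
#' @param n_patients Number of patients (>= 1).
#' @param cores_per_patient Integer >= 1, or an integer vector of length
#'   `n_patients` for unequal core counts.
#' @param stage Cohort label stored in outputs (e.g. `"III"`, `"IV"`).
#' @param window Observation window per core.
#' @param type_intensities Named per-type densities (points per um^2).
#' @param density_ranges Optional named list `type -> c(lo, hi)`: that
#'   type's density is drawn uniformly per patient (shared across the
#'   patient's cores), emulating between-patient infiltration heterogeneity.
#' @param attraction_rules List of
#'   `list(parent, offspring, mean_offspring, sigma)`: offspring of the
#'   given type are added around already-generated parent-type cells
#'   (on top of any background intensity for the offspring type).
#' @param marker_model Phenotype-marker signal model, or `NULL` to omit
#'   phenotype intensity columns (experiments working on true labels).
#' @param anchor_marker_rates Named inflammatory-marker positivity
#'   probabilities, or `NULL` to omit inflammatory columns.
#' @param anchor_block_frac Optional spatial blocking of anchor positivity
#'   (see [simulate_anchor_markers()]).
#' @param survival_link `list(baseline, coef, censor_rate)`; coefficient
#'   names refer to per-sample features: `prop_<type>` (proportion of
#'   `true_type`), `<i>_<j>_G<r>` (G-cross estimate at radius r between
#'   true types), or `<i>_<j>_AUC`.
#' @param site_probs Optional named probabilities of metastatic-site strata
#'   sampled per patient.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_patients,
                              cores_per_patient = 1L,
                              stage = "III",
                              window = spatial_window(),
                              type_intensities = default_type_intensities(stage),
                              density_ranges = NULL,
                              attraction_rules = list(),
                              marker_model = default_marker_model(),
                              anchor_marker_rates = default_anchor_rates(
                                if (stage %in% c("III", "IV")) stage else "III"),
                              anchor_block_frac = NULL,
                              survival_link = list(baseline = 0.03,
                                                   coef = NULL,
                                                   censor_rate = 0.01),
                              site_probs = NULL,
                              seed = 1L) {
  .assert(is.numeric(n_patients) && n_patients >= 1,
          "n_patients must be >= 1")
  n_patients <- as.integer(n_patients)
  cpp <- as.integer(cores_per_patient)
  .assert(all(cpp >= 1L) && length(cpp) %in% c(1L, n_patients),
          "cores_per_patient must be >= 1, length 1 or n_patients")
  if (length(cpp) == 1L) cpp <- rep(cpp, n_patients)
  .assert(all(type_intensities >= 0), "densities must be nonnegative")
  .assert(is.null(site_probs) ||
            (is.numeric(site_probs) && !is.null(names(site_probs)) &&
               all(site_probs >= 0) && sum(site_probs) > 0),
          "site_probs must be named nonnegative weights")
  for (rule in attraction_rules) {
    .assert(all(c("parent", "offspring", "mean_offspring", "sigma") %in%
                  names(rule)),
            "each attraction rule needs parent, offspring, mean_offspring, sigma")
    .assert(rule$sigma > 0 && rule$mean_offspring >= 0,
            "attraction rule: sigma > 0, mean_offspring >= 0 required")
  }
  structure(list(
    n_patients = n_patients, cores_per_patient = cpp, stage = stage,
    window = .as_window(window), type_intensities = type_intensities,
    density_ranges = density_ranges, attraction_rules = attraction_rules,
    marker_model = marker_model, anchor_marker_rates = anchor_marker_rates,
    anchor_block_frac = anchor_block_frac, survival_link = survival_link,
    site_probs = site_probs, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Default per-type densities by stage
#'
#' Baseline densities give roughly 1,900 cells per 1 mm^2 core, dominated by
#' tumor cells with a realistic immune infiltrate. The Stage IV arm raises
#' Tumor and CTL densities and lowers B, NK and double-negative T densities,
#' reproducing the direction of the advanced-stage compositional shift
#' (higher tumor/CTL fractions, depleted B/NK/T fractions).
#'
#' @param stage `"III"` or `"IV"`.
#' @return Named densities in points per um^2 (8 cell types + `other`).
#' @export
default_type_intensities <- function(stage = c("III", "IV")) {
  stage <- match.arg(stage)
  base <- c(Tumor = 6e-4, T = 2.5e-4, CTL = 1.5e-4, Th = 1.5e-4,
            B = 1.2e-4, NK = 8e-5, TAM = 1.5e-4, M2 = 8e-5, other = 4e-4)
  if (stage == "IV") {
    base[c("Tumor", "CTL")] <- c(9e-4, 2.2e-4)
    base[c("B", "NK", "T")] <- c(7e-5, 4.5e-5, 2.0e-4)
  }
  base
}

# Parse feature names of the survival link and evaluate them on one sample.
.eval_sample_features <- function(cells, feature_names, window,
                                  type_col = "true_type") {
  vapply(feature_names, function(f) {
    if (grepl("^prop_", f)) {
      ty <- sub("^prop_", "", f)
      return(mean(cells[[type_col]] == ty))
    }
    m <- regmatches(f, regexec("^([^_]+)_([^_]+)_(G([0-9.]+)|AUC)$", f))[[1]]
    .assert(length(m) > 0,
            sprintf("unrecognized survival-link feature '%s'", f))
    curve <- tryCatch(
      gcross_empirical(cells, m[2L], m[3L], radii = 0:80, window = window,
                       correction = "border", type_col = type_col),
      error = function(e) NULL)
    if (is.null(curve)) return(NA_real_)
    if (m[4L] == "AUC") gcross_auc(curve) else gcross_at(curve, as.numeric(m[5L]))
  }, numeric(1))
}

#' Generate a full synthetic cohort
#'
#' Produces a cell table (one block of rows per core), a clinical table (one
#' row per patient) and the ground truth, all deterministic under the
#' config seed. Cores are simulated independently: background multitype
#' Poisson cells at (optionally patient-heterogeneous) densities, offspring
#' attached around attraction-rule parents, phenotype-marker and
#' inflammatory-marker intensities drawn per cell. Survival times follow
#' the configured hazard link on per-sample features aggregated to the
#' patient by the mean.
#'
#' @param config A [simulation_config()].
#' @return `list(cells, clinical, truth)`; `cells` has columns `sample_id`,
#'   `patient_id`, `x_um`, `y_um`, `cell_id`, marker intensity columns, and
#'   `true_type`; `clinical` has `patient_id`, `time_months`, `event`,
#'   `stage`, `site`, `age`, `sex`; `truth` records true types per cell,
#'   attraction rules, per-patient densities and hazard coefficients.
#' @examples
#' cfg <- simulation_config(n_patients = 4, cores_per_patient = 2, seed = 7)
#' cohort <- generate_cohort(cfg)
#' nrow(cohort$clinical)           # 4 patients
#' length(unique(cohort$cells$sample_id))  # 8 cores
#' @export
generate_cohort <- function(config) {
  .assert(inherits(config, "simulation_config"),
          "config must come from simulation_config()")
  set.seed(config$seed)
  w <- config$window
  coef_names <- names(config$survival_link$coef %||% numeric(0))

  cores <- list()
  feat_rows <- list()
  pat_density <- list()
  sites <- character(config$n_patients)
  ages <- integer(config$n_patients)
  sexes <- character(config$n_patients)

  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("%s_P%03d", config$stage, p)
    sites[p] <- if (is.null(config$site_probs)) NA_character_ else
      sample(names(config$site_probs), 1L,
             prob = config$site_probs / sum(config$site_probs))
    ages[p] <- as.integer(round(pmin(pmax(stats::rnorm(1, 56, 12), 20), 90)))
    sexes[p] <- sample(c("M", "F"), 1L, prob = c(0.64, 0.36))

    lambda <- config$type_intensities
    if (!is.null(config$density_ranges)) {
      for (ty in names(config$density_ranges)) {
        rg <- config$density_ranges[[ty]]
        lambda[[ty]] <- stats::runif(1, rg[1L], rg[2L])
      }
    }
    pat_density[[pid]] <- lambda

    for (k in seq_len(config$cores_per_patient[p])) {
      sid <- sprintf("%s_C%d", pid, k)
      cells <- simulate_poisson_multitype(lambda, w)
      for (rule in config$attraction_rules) {
        par_idx <- which(cells$true_type == rule$parent)
        if (length(par_idx)) {
          counts <- stats::rpois(length(par_idx), rule$mean_offspring)
          kids <- .scatter_offspring(cells$x_um[par_idx], cells$y_um[par_idx],
                                     counts, rule$sigma, w)
          if (nrow(kids)) {
            kids$true_type <- rule$offspring
            cells <- rbind(cells, kids)
          }
        }
      }
      if (!is.null(config$marker_model)) {
        cells <- simulate_marker_intensities(cells, config$marker_model)
      }
      if (!is.null(config$anchor_marker_rates)) {
        cells <- simulate_anchor_markers(cells, config$anchor_marker_rates,
                                         block_frac = config$anchor_block_frac,
                                         window = w)
      }
      cells <- cbind(data.frame(sample_id = sid, patient_id = pid,
                                stringsAsFactors = FALSE),
                     cells)
      cores[[sid]] <- cells
      if (length(coef_names)) {
        fv <- .eval_sample_features(cells, coef_names, w)
        feat_rows[[sid]] <- as.data.frame(
          c(list(sample_id = sid, patient_id = pid), as.list(fv)),
          stringsAsFactors = FALSE)
      }
    }
  }

  cells <- setDF(rbindlist(cores))
  cells$cell_id <- seq_len(nrow(cells))

  features <- if (length(feat_rows)) {
    setDF(rbindlist(feat_rows))
  } else {
    data.frame(patient_id = sprintf("%s_P%03d", config$stage,
                                    seq_len(config$n_patients)),
               stringsAsFactors = FALSE)
  }

  clinical <- simulate_survival(features, config$survival_link)
  ord <- match(sprintf("%s_P%03d", config$stage, seq_len(config$n_patients)),
               clinical$patient_id)
  clinical <- clinical[ord, , drop = FALSE]
  clinical$stage <- config$stage
  clinical$site <- sites
  clinical$age <- ages
  clinical$sex <- sexes
  rownames(clinical) <- NULL

  truth <- list(
    true_type = cells$true_type,
    attraction_rules = config$attraction_rules,
    hazard_coef = config$survival_link$coef,
    baseline_hazard = config$survival_link$baseline,
    patient_densities = pat_density,
    sample_features = if (length(feat_rows)) features else NULL,
    seed = config$seed
  )
  list(cells = cells, clinical = clinical, truth = truth)
}

#' Study-scale default cohort configurations
#'
#' `"III"`: 157 patients with 2 cores each (314 cores). `"IV"`: 248
#' patients contributing 393 cores in total (145 patients with two cores,
#' 103 with one) across five metastatic-site strata (other 35%, skin 20%,
#' GI 17%, lung 16%, lymph node 12%). Densities and inflammatory-marker
#' rates are stage-shifted via [default_type_intensities()] and
#' [default_anchor_rates()].
#'
#' @param stage `"III"` or `"IV"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [simulation_config()].
#' @export
default_simulation_config <- function(stage = c("III", "IV"), seed = 1L, ...) {
  stage <- match.arg(stage)
  if (stage == "III") {
    simulation_config(n_patients = 157L, cores_per_patient = 2L,
                      stage = "III", seed = seed, ...)
  } else {
    cpp <- rep(c(2L, 1L), c(145L, 103L))   # 393 cores over 248 patients
    simulation_config(n_patients = 248L, cores_per_patient = cpp,
                      stage = "IV",
                      site_probs = c(other = 0.35, skin = 0.20, GI = 0.17,
                                     lung = 0.16, lymph_node = 0.12),
                      seed = seed, ...)
  }
}
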