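# Survival association of spatial features: Kaplan-Meier estimation,
# log-rank comparison, univariate Cox proportional hazards with
# cluster-robust (sandwich) variance for patients contributing several
# cores, and the feature-by-feature survival scan.

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with Greenwood variance and log-log confidence
#' intervals. The median is the earliest time at which the curve drops to
#' 0.5 or below (`NA` when never reached, e.g. all observations censored);
#' survival probabilities at fixed horizons are also reported.
#'
#' @param times Follow-up times (> 0), typically months.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param conf_level Confidence level (default 0.95).
#' @param horizons Times at which survival probabilities are reported
#'   (default 60 and 120 months, i.e. 5- and 10-year survival).
#' @return Object of class `km_fit`: step function vectors (`time`,
#'   `n_risk`, `n_event`, `surv`, `lower`, `upper`), `median` with CI, and
#'   `horizon_surv` (named survival probabilities).
#' @export
km_estimate <- function(times, events, conf_level = 0.95,
                        horizons = c(60, 120)) {
  .assert(is.numeric(times) && length(times) >= 1L && all(times > 0),
          "times must be positive")
  .assert(all(events %in% c(0, 1)), "events must be 0/1")
  .assert(length(times) == length(events), "times and events lengths differ")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  tab <- summary(fit)$table
  hs <- summary(fit, times = horizons, extend = TRUE)$surv
  structure(list(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    surv = fit$surv, lower = fit$lower, upper = fit$upper,
    median = unname(tab["median"]),
    median_lower = unname(tab[grep("LCL", names(tab))]),
    median_upper = unname(tab[grep("UCL", names(tab))]),
    horizon_surv = stats::setNames(hs, horizons),
    n = length(times), n_events = sum(events),
    survfit = fit
  ), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: n = %d, events = %d\n", x$n, x$n_events))
  cat(sprintf("  median survival %.1f (%.1f-%.1f)\n",
              x$median, x$median_lower, x$median_upper))
  for (h in names(x$horizon_surv)) {
    cat(sprintf("  S(%s) = %.3f\n", h, x$horizon_surv[[h]]))
  }
  invisible(x)
}

#' Log-rank test between survival curves
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group labels; at least two non-empty groups.
#' @return `list(chisq, df, p)`.
#' @export
logrank_test <- function(times, events, groups) {
  .assert(length(unique(groups)) >= 2L,
          "log-rank test needs at least two groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g,
                           data = data.frame(times = times, events = events,
                                             g = groups))
  df <- length(sd$n) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit with cluster-robust variance
#'
#' Partial-likelihood maximization with Efron handling of ties by default.
#' The robust variance is the sandwich estimator with score residuals
#' summed within clusters before the outer product, correcting for
#' within-patient correlation when patients contribute several samples;
#' with singleton clusters it reduces to the ordinary robust variance. The
#' feature enters untransformed.
#'
#' With `ties = "breslow"`, duplicating every record within its cluster
#' leaves both the log-HR and the cluster-robust SE exactly unchanged
#' (Efron's tie correction makes the invariance approximate, since
#' duplication itself creates ties).
#'
#' @param times,events As in [km_estimate()].
#' @param x Numeric feature, non-constant.
#' @param cluster Cluster ids (typically patient ids); default each
#'   observation its own cluster.
#' @param ties Tie handling, `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_fit`: `log_hr`, `se_naive`, `se_robust`,
#'   `z`, `p` (robust Wald), `n`, `n_events`, `n_clusters`, `converged`.
#' @export
fit_cox_univariate <- function(times, events, x, cluster = NULL,
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .assert(is.numeric(x) && length(x) == length(times),
          "x must be numeric, matching times")
  .assert(all(events %in% c(0, 1)), "events must be 0/1")
  .assert(stats::var(x) > 0, "feature is constant; cannot fit")
  .assert(sum(events) >= 2, "need at least 2 events")
  dd <- data.frame(times = times, events = events, x = x,
                   cl = if (is.null(cluster)) seq_along(times) else cluster)
  fit <- survival::coxph(survival::Surv(times, events) ~ x, data = dd,
                         cluster = cl, ties = ties, robust = TRUE)
  beta <- unname(stats::coef(fit))
  se_rob <- sqrt(unname(fit$var[1L, 1L]))
  se_naive <- sqrt(unname(fit$naive.var[1L, 1L]))
  z <- beta / se_rob
  structure(list(
    log_hr = beta, se_naive = se_naive, se_robust = se_rob,
    z = z, p = 2 * stats::pnorm(-abs(z)),
    n = nrow(dd), n_events = sum(dd$events),
    n_clusters = length(unique(dd$cl)),
    converged = is.finite(beta) && is.finite(se_rob),
    coxph = fit
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "Cox fit: log-HR = %.4f (robust SE %.4f, naive SE %.4f), z = %.2f, p = %.3g\n",
    x$log_hr, x$se_robust, x$se_naive, x$z, x$p))
  cat(sprintf("  n = %d (%d events) in %d clusters\n",
              x$n, x$n_events, x$n_clusters))
  invisible(x)
}

#' Scan spatial features for survival association
#'
#' Fits one univariate cluster-robust Cox model per feature column (and,
#' optionally, per stratum), linking per-sample spatial features to
#' patient survival. Samples with a missing feature value are dropped per
#' fit, not imputed; fits with a constant feature or fewer than two events
#' are skipped with a reason. Raw p-value tiers are reported by default;
#' set `adjust = TRUE` for Benjamini-Hochberg adjustment across the scan.
#'
#' @param features Per-sample feature table with `sample_id`, `patient_id`
#'   and numeric feature columns (e.g. from [gcross_features()]).
#' @param clinical Per-patient table with `patient_id`, `time_months`,
#'   `event`, and any stratum column.
#' @param feature_cols Columns to scan (default: all numeric feature
#'   columns).
#' @param cluster_col Clustering id column (default `"patient_id"`).
#' @param stratum_col Optional clinical column (e.g. metastatic site);
#'   when given, each feature is fitted separately within each stratum.
#' @param adjust Apply BH adjustment across successful fits (default
#'   `FALSE`; tiers then follow raw p-values).
#' @return data.frame: `stratum`, `feature`, `log_hr`, `se_robust`, `z`,
#'   `p`, `q` (when adjusted), `tier`, `n`, `n_events`, `n_clusters`,
#'   `skipped`, `reason`.
#' @export
spatial_survival_scan <- function(features, clinical, feature_cols = NULL,
                                  cluster_col = "patient_id",
                                  stratum_col = NULL, adjust = FALSE) {
  .assert(is.data.frame(features) &&
            all(c("sample_id", "patient_id") %in% names(features)),
          "features must have sample_id and patient_id columns")
  .assert(is.data.frame(clinical) &&
            all(c("patient_id", "time_months", "event") %in% names(clinical)),
          "clinical must have patient_id, time_months, event")
  if (is.null(feature_cols)) {
    cand <- setdiff(names(features), c("sample_id", "patient_id"))
    feature_cols <- cand[vapply(features[cand], is.numeric, logical(1))]
  }
  .assert(length(feature_cols) >= 1L, "no feature columns to scan")

  idx <- match(features$patient_id, clinical$patient_id)
  .assert(!anyNA(idx), "features reference patients absent from clinical")
  dat <- cbind(features,
               clinical[idx, setdiff(names(clinical), "patient_id"),
                        drop = FALSE])
  strata <- if (is.null(stratum_col)) list(all = rep(TRUE, nrow(dat))) else {
    .assert(stratum_col %in% names(dat),
            sprintf("clinical has no column '%s'", stratum_col))
    split(seq_len(nrow(dat)), dat[[stratum_col]]) |>
      lapply(function(i) seq_len(nrow(dat)) %in% i)
  }

  rows <- list()
  for (st in names(strata)) {
    in_st <- strata[[st]]
    for (f in feature_cols) {
      keep <- in_st & is.finite(dat[[f]]) & !is.na(dat$time_months)
      sub <- dat[keep, , drop = FALSE]
      base <- data.frame(stratum = st, feature = f,
                         log_hr = NA_real_, se_robust = NA_real_,
                         z = NA_real_, p = NA_real_, q = NA_real_,
                         tier = NA_character_,
                         n = nrow(sub), n_events = sum(sub$event),
                         n_clusters = length(unique(sub[[cluster_col]])),
                         skipped = TRUE, reason = "",
                         stringsAsFactors = FALSE)
      if (nrow(sub) < 3L || sum(sub$event) < 2L) {
        base$reason <- "fewer than 2 events"
      } else if (stats::var(sub[[f]]) == 0) {
        base$reason <- "constant feature"
      } else {
        fit <- tryCatch(
          fit_cox_univariate(sub$time_months, sub$event, sub[[f]],
                             cluster = sub[[cluster_col]]),
          error = function(e) NULL)
        if (is.null(fit) || !fit$converged) {
          base$reason <- "fit failed"
        } else {
          base$log_hr <- fit$log_hr
          base$se_robust <- fit$se_robust
          base$z <- fit$z
          base$p <- fit$p
          base$skipped <- FALSE
        }
      }
      rows[[length(rows) + 1L]] <- base
    }
  }
  out <- do.call(rbind, rows)
  ok <- !out$skipped
  if (adjust) {
    out$q[ok] <- bh_adjust(out$p[ok])
    out$tier[ok] <- significance_tier(out$q[ok])
  } else {
    out$q <- NULL
    out$tier[ok] <- significance_tier(out$p[ok])
  }
  rownames(out) <- NULL
  out
}
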