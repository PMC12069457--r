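# Compositional comparison between cohorts: beta regression on
# proportion-valued features with Benjamini-Hochberg FDR control.

#' Compress proportions away from the 0/1 boundary
#'
#' The beta likelihood is undefined at exactly 0 or 1. The standard
#' compression `y' = (y * (n - 1) + 0.5) / n` maps \[0, 1\] into (0, 1)
#' while preserving order; it is applied to all values (not only
#' boundaries) so the transformation is continuous in the data.
#'
#' @param y Proportions in \[0, 1\].
#' @param n Sample count behind the compression (default `length(y)`),
#'   must be >= 2.
#' @return Proportions in (0, 1).
#' @examples
#' boundary_adjust(c(0, 1, 0.5), n = 100)  # 0.005, 0.995, 0.5
#' @export
boundary_adjust <- function(y, n = length(y)) {
  .assert(is.numeric(y) && all(y >= 0 & y <= 1, na.rm = TRUE),
          "y must be proportions in [0, 1]")
  .assert(is.numeric(n) && length(n) == 1L && n >= 2,
          "n must be >= 2")
  (y * (n - 1) + 0.5) / n
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: the adjusted value of the i-th smallest p-value
#' is `min over k >= i of p_(k) * m / k`, capped at 1 and mapped back to
#' input order.
#'
#' @param p p-values in \[0, 1\] (NA allowed; passed through).
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  .assert(is.numeric(p) && all(p >= 0 & p <= 1, na.rm = TRUE),
          "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Significance tier from an (adjusted) p-value
#'
#' `"***"` below 0.001, `"**"` below 0.01, `"*"` below 0.05, otherwise
#' `""`.
#'
#' @param q Numeric vector of (adjusted) p-values.
#' @export
significance_tier <- function(q) {
  out <- rep("", length(q))
  out[!is.na(q) & q < 0.05] <- "*"
  out[!is.na(q) & q < 0.01] <- "**"
  out[!is.na(q) & q < 0.001] <- "***"
  out[is.na(q)] <- NA_character_
  out
}

# Negative log-likelihood and analytic gradient of the beta regression in
# mean/precision parameterization: y ~ Beta(mu*phi, (1-mu)*phi),
# mu = plogis(X beta), theta = (beta, log phi).
.betareg_nll <- function(theta, X, y) {
  k <- ncol(X)
  mu <- stats::plogis(drop(X %*% theta[seq_len(k)]))
  phi <- exp(theta[k + 1L])
  -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

.betareg_grad <- function(theta, X, y) {
  k <- ncol(X)
  eta <- drop(X %*% theta[seq_len(k)])
  mu <- stats::plogis(eta)
  phi <- exp(theta[k + 1L])
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  # d(-ll)/d beta
  gb <- -drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  # d(-ll)/d log phi
  dphi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                (1 - mu) * digamma((1 - mu) * phi) +
                mu * log(y) + (1 - mu) * log1p(-y))
  c(gb, -dphi * phi)
}

#' Beta regression with logit mean link and fixed precision
#'
#' Maximum-likelihood fit of the beta distribution reparameterized by mean
#' `mu = plogis(X beta)` and precision `phi`, with no precision covariates.
#' Optimization is quasi-Newton (BFGS) on `(beta, log phi)` with analytic
#' gradients, started from a least-squares fit of logit-transformed
#' responses; standard errors come from the inverse observed information.
#' On the logit scale, a group coefficient is the change in log-odds of the
#' mean proportion between groups.
#'
#' @param y Responses strictly inside (0, 1) (apply [boundary_adjust()]
#'   first if needed).
#' @param x A factor/character/numeric predictor vector, or a data.frame /
#'   numeric matrix of predictors; an intercept is always added. `NULL`
#'   fits the intercept-only model.
#' @return Object of class `beta_fit`: named `coefficients` (mean-model
#'   terms), their `se`, `z`, `p`, precision `phi` (with `se_logphi`),
#'   `converged`, `n`, `loglik`, `vcov`.
#' @examples
#' set.seed(1)
#' g <- rep(c("A", "B"), each = 200)
#' mu <- ifelse(g == "A", 0.3, 0.5)
#' y <- rbeta(400, mu * 20, (1 - mu) * 20)
#' fit <- fit_beta_regression(y, g)
#' fit$coefficients  # second term near logit(0.5) - logit(0.3) = 0.847
#' @export
fit_beta_regression <- function(y, x = NULL) {
  .assert(is.numeric(y) && length(y) >= 3L && all(is.finite(y)),
          "y must be a numeric vector (length >= 3)")
  .assert(all(y > 0 & y < 1),
          "y must lie strictly in (0, 1); use boundary_adjust()")
  X <- if (is.null(x)) {
    matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  } else if (is.matrix(x)) {
    cbind(`(Intercept)` = 1, x)
  } else if (is.data.frame(x)) {
    stats::model.matrix(~., data = x)
  } else {
    .assert(length(x) == length(y), "x and y lengths differ")
    if (is.numeric(x)) {
      cbind(`(Intercept)` = 1, x = x)
    } else {
      .assert(length(unique(x)) >= 2L, "predictors are collinear or constant")
      stats::model.matrix(~x, data = data.frame(x = factor(x)))
    }
  }
  .assert(nrow(X) == length(y), "x and y lengths differ")
  .assert(qr(X)$rank == ncol(X), "predictors are collinear or constant")
  k <- ncol(X)

  # starting values: least squares on logit(y); phi from moment matching
  z <- stats::qlogis(y)
  b0 <- qr.solve(X, z)
  mu0 <- stats::plogis(drop(X %*% b0))
  s2 <- stats::var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(s2, 1e-10) - 1, 1)
  theta0 <- c(b0, log(phi0))

  opt <- stats::optim(theta0, .betareg_nll, gr = .betareg_grad,
                      X = X, y = y, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12),
                      hessian = TRUE)
  grad_norm <- sqrt(sum(.betareg_grad(opt$par, X, y)^2))
  vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  converged <- opt$convergence == 0 && !is.null(vc) &&
    all(diag(vc)[seq_len(k)] > 0) && grad_norm / length(y) < 1e-4
  se <- if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else rep(NA_real_, k + 1L)
  coefs <- stats::setNames(opt$par[seq_len(k)], colnames(X))
  zstat <- coefs / se[seq_len(k)]
  structure(list(
    coefficients = coefs,
    se = stats::setNames(se[seq_len(k)], colnames(X)),
    z = zstat,
    p = 2 * stats::pnorm(-abs(zstat)),
    phi = exp(opt$par[k + 1L]),
    se_logphi = se[k + 1L],
    converged = converged,
    n = length(y),
    loglik = -opt$value,
    vcov = if (!is.null(vc)) vc[seq_len(k), seq_len(k), drop = FALSE] else NULL
  ), class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf("Beta regression (logit link), n = %d, phi = %.3f, logLik = %.2f%s\n",
              x$n, x$phi, x$loglik,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  print(data.frame(estimate = x$coefficients, se = x$se, z = x$z, p = x$p))
  invisible(x)
}

#' Compare proportion-valued features between cohorts
#'
#' Fits one beta regression per feature with cohort as the only predictor,
#' then applies Benjamini-Hochberg FDR adjustment across the feature family
#' and assigns significance tiers at q < 0.05 / 0.01 / 0.001. The reported
#' `beta` is the change in log-odds of the mean proportion in the second
#' group relative to the first. Features whose values have zero variance
#' within any cohort (the beta model is then degenerate) are excluded from
#' fitting and from the FDR family, as are non-converged fits; both appear
#' in the output flagged with a reason.
#'
#' @param features Tidy table with columns `sample_id`, `feature`, `value`
#'   (as produced by [cell_type_proportions()],
#'   [neighborhood_proportions()], and the nested-fraction views).
#' @param groups Cohort labels: a data.frame with `sample_id` and `group`
#'   columns, or a vector named by sample id. Exactly two groups after
#'   joining; the first sorted level is the reference.
#' @param family Optional family label copied into the output (one FDR
#'   family per call).
#' @return data.frame: `family`, `feature`, `group_ref`, `group_alt`,
#'   `n_ref`, `n_alt`, `beta`, `se`, `z`, `p`, `q`, `tier`, `skipped`,
#'   `reason`.
#' @export
compare_cohorts <- function(features, groups, family = NA_character_) {
  .assert(is.data.frame(features) &&
            all(c("sample_id", "feature", "value") %in% names(features)),
          "features must have columns sample_id, feature, value")
  if (is.data.frame(groups)) {
    .assert(all(c("sample_id", "group") %in% names(groups)),
            "groups data.frame needs sample_id and group columns")
    gmap <- stats::setNames(as.character(groups$group),
                            as.character(groups$sample_id))
  } else {
    .assert(!is.null(names(groups)), "groups vector must be named by sample id")
    gmap <- stats::setNames(as.character(groups), names(groups))
  }
  grp <- gmap[as.character(features$sample_id)]
  .assert(!anyNA(grp), "some samples in features have no group label")
  levels <- sort(unique(grp))
  .assert(length(levels) == 2L,
          "compare_cohorts requires exactly two cohorts")

  feats <- unique(features$feature)
  rows <- lapply(feats, function(f) {
    sel <- features$feature == f & !is.na(features$value)
    y <- features$value[sel]
    g <- factor(grp[sel], levels = levels)
    n1 <- sum(g == levels[1L])
    n2 <- sum(g == levels[2L])
    base <- data.frame(family = family, feature = f,
                       group_ref = levels[1L], group_alt = levels[2L],
                       n_ref = n1, n_alt = n2,
                       beta = NA_real_, se = NA_real_, z = NA_real_,
                       p = NA_real_, q = NA_real_, tier = NA_character_,
                       skipped = TRUE, reason = "", stringsAsFactors = FALSE)
    if (n1 < 2L || n2 < 2L) {
      base$reason <- "fewer than 2 observations in a cohort"
      return(base)
    }
    v1 <- stats::var(y[g == levels[1L]])
    v2 <- stats::var(y[g == levels[2L]])
    if (v1 == 0 || v2 == 0) {
      base$reason <- "zero variance within a cohort"
      return(base)
    }
    ya <- boundary_adjust(y, n = length(y))
    fit <- tryCatch(fit_beta_regression(ya, g), error = function(e) NULL)
    if (is.null(fit)) {
      base$reason <- "fit error"
      return(base)
    }
    if (!fit$converged) {
      base$reason <- "did not converge"
      return(base)
    }
    base$beta <- unname(fit$coefficients[2L])
    base$se <- unname(fit$se[2L])
    base$z <- unname(fit$z[2L])
    base$p <- unname(fit$p[2L])
    base$skipped <- FALSE
    base
  })
  out <- do.call(rbind, rows)
  ok <- !out$skipped
  out$q[ok] <- bh_adjust(out$p[ok])
  out$tier[ok] <- significance_tier(out$q[ok])
  rownames(out) <- NULL
  out
}
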