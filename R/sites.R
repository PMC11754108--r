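# Functional-site identification: sigmoid decomposition of stability versus
# evolutionary fitness, residual tests, and disattenuated variance explained.

sigmoid_predict <- function(score, xmid, scal) {
  -1 + stats::plogis((score - xmid) / scal)
}

#' Check domain eligibility for the sigmoid decomposition
#'
#' Two conditions: (1) the wild type sits within the top 30% of the domain's
#' fitness distribution (fewer than 30% of variants have fitness strictly
#' above the wild type, i.e. above 0 on the normalized scale); (2) the 5th
#' to 95th percentile range of the evolutionary score exceeds 10.
#'
#' @param normalized Output of [normalize_fitness()].
#' @param scores Predictor score tibble keyed by variant.
#' @param min_variants Minimum number of jointly observed variants.
#' @return A tibble with per-domain eligibility flag and reasons.
#' @export
check_eligibility <- function(normalized, scores, min_variants = 20) {
  joined <- dplyr::inner_join(normalized, scores, by = variant_keys)
  purrr::map_dfr(split(joined, joined$domain_id), function(v) {
    reasons <- character()
    if (nrow(v) < min_variants) {
      reasons <- c(reasons, sprintf("fewer than %d joint variants", min_variants))
    }
    frac_above_wt <- mean(v$f_norm > 0)
    if (!nrow(v) || frac_above_wt >= 0.30) {
      reasons <- c(reasons, "wild type below the top 30% of the fitness distribution")
    }
    rng <- diff(stats::quantile(v$score, c(0.05, 0.95), names = FALSE))
    if (!is.finite(rng) || rng <= 10) {
      reasons <- c(reasons, "evolutionary score 5-95% range not greater than 10")
    }
    tibble::tibble(
      domain_id = v$domain_id[1],
      n = nrow(v),
      frac_above_wt = frac_above_wt,
      score_range = rng,
      eligible = length(reasons) == 0,
      reasons = list(reasons)
    )
  })
}

#' Fit the stability-versus-evolutionary-fitness sigmoid for one domain
#'
#' Weighted nonlinear least squares of `f = -1 + 1 / (1 + exp(-(s - xmid) /
#' scal))`, bounded between the wild-type fitness (0) and the unfolded
#' plateau (-1). The weights `w = (max(f) - min(f) - (f + 1))^2` prioritize
#' fitting the low-stability variants. Initialization is `xmid =
#' median(score)`, `scal = (p95 - p5) / 10`, with up to `max_restarts`
#' seeded jittered restarts before reporting non-convergence.
#'
#' @param data One domain's variants: a tibble with `score`, `f_norm` and
#'   `sigma_norm` (plus variant keys, carried through).
#' @param seed Integer seed for restart jitter.
#' @param max_restarts Restarts attempted on optimizer failure.
#' @return A `sigmoid_fit`: `domain_id`, `xmid`, `scal` (> 0), `converged`,
#'   and a `data` tibble with per-variant weight, prediction and residual
#'   (`f_norm - predicted`; positive = more stable than the evolutionary
#'   score explains).
#' @export
fit_sigmoid <- function(data, seed = 1L, max_restarts = 5) {
  stopifnot(all(c("score", "f_norm", "sigma_norm") %in% names(data)))
  if (nrow(data) < 20) {
    abort_foldstab("need at least 20 variants to fit the sigmoid", "sites")
  }
  f <- data$f_norm
  s <- data$score
  w <- (max(f) - min(f) - (f + 1))^2
  obj <- function(par) sum(w * (f - sigmoid_predict(s, par[1], par[2]))^2)
  grad <- function(par) {
    mu <- stats::plogis((s - par[1]) / par[2])
    r <- f - (-1 + mu)
    dmu <- mu * (1 - mu)
    d_xmid <- sum(2 * w * r * dmu / par[2])
    d_scal <- sum(2 * w * r * dmu * (s - par[1]) / par[2]^2)
    c(d_xmid, d_scal)
  }
  q <- stats::quantile(s, c(0.05, 0.95), names = FALSE)
  init <- c(stats::median(s), max((q[2] - q[1]) / 10, 1e-3))
  withr::local_seed(seed)
  fit <- NULL
  for (attempt in seq_len(max_restarts + 1L)) {
    start <- if (attempt == 1L) {
      init
    } else {
      c(
        init[1] + stats::rnorm(1, 0, stats::sd(s)),
        init[2] * exp(stats::rnorm(1, 0, 0.5))
      )
    }
    res <- tryCatch(
      stats::optim(
        start, obj, grad,
        method = "L-BFGS-B",
        lower = c(-Inf, 1e-8),
        control = list(maxit = 500, factr = 1e2, pgtol = 1e-12)
      ),
      error = function(e) NULL
    )
    if (!is.null(res) && res$convergence == 0) {
      fit <- res
      break
    }
    if (!is.null(res) && (is.null(fit) || res$value < fit$value)) fit <- res
  }
  converged <- !is.null(fit) && fit$convergence == 0
  par <- if (is.null(fit)) init else fit$par
  out <- data
  out$weight <- w
  out$predicted <- sigmoid_predict(s, par[1], par[2])
  out$residual <- f - out$predicted
  structure(
    list(
      domain_id = if ("domain_id" %in% names(data)) data$domain_id[1] else NA,
      xmid = par[1],
      scal = par[2],
      converged = converged,
      loss = if (is.null(fit)) NA_real_ else fit$value,
      data = out
    ),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(
    "<sigmoid_fit> ", x$domain_id, ": xmid = ", signif(x$xmid, 4),
    ", scal = ", signif(x$scal, 4),
    if (x$converged) " (converged)\n" else " (NOT converged)\n",
    sep = ""
  )
  invisible(x)
}

#' Call functional mutations from sigmoid residuals
#'
#' Two-tailed z-test of each residual against the measurement error, with
#' Benjamini-Hochberg correction within the domain. A mutation is functional
#' iff `q < fdr` and its residual exceeds `residual_cut`: the variant is
#' more stable than its evolutionary fitness predicts, indicating function
#' beyond stability.
#'
#' @param fit A converged [fit_sigmoid()] result.
#' @param fdr FDR level.
#' @param residual_cut Residual magnitude threshold (normalized units).
#' @return The fit's per-variant tibble with `z`, `p`, `q` and `functional`.
#' @export
call_functional_mutations <- function(fit, fdr = 0.1, residual_cut = 0.3) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!fit$converged) {
    abort_foldstab("sigmoid fit did not converge; domain excluded", "sites")
  }
  out <- fit$data
  out$z <- out$residual / out$sigma_norm
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out$q <- bh_adjust(out$p)
  out$functional <- out$q < fdr & out$residual > residual_cut
  out
}

#' Call functional sites from per-residue weighted mean residuals
#'
#' Residuals are averaged per residue with inverse-variance weights
#' (`1 / sigma_norm^2`); a residue is a functional site iff its weighted
#' mean residual exceeds `site_cut`. Residues with fewer than
#' `min_substitutions` measured substitutions get no call.
#'
#' @param fit A converged [fit_sigmoid()] result.
#' @param site_cut Weighted-mean-residual threshold.
#' @param min_substitutions Minimum substitutions per residue for a call.
#' @return A tibble with per-residue `n`, `weighted_mean_residual`,
#'   `is_site` (NA when uncalled) and `reason`.
#' @export
call_functional_sites <- function(fit, site_cut = 0.3, min_substitutions = 3) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (!fit$converged) {
    abort_foldstab("sigmoid fit did not converge; domain excluded", "sites")
  }
  fit$data |>
    dplyr::group_by(.data$domain_id, .data$position) |>
    dplyr::summarise(
      n = dplyr::n(),
      weighted_mean_residual =
        sum(.data$residual / .data$sigma_norm^2) / sum(1 / .data$sigma_norm^2),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      is_site = dplyr::if_else(
        .data$n >= min_substitutions,
        .data$weighted_mean_residual > site_cut,
        NA
      ),
      reason = dplyr::if_else(
        .data$n >= min_substitutions,
        NA_character_,
        sprintf("only %d measured substitutions", .data$n)
      )
    )
}

#' Disattenuated variance in evolutionary fitness explained by stability
#'
#' The observed stability-score correlation is corrected for measurement
#' noise by dividing by the square root of the replicate reliability:
#' `R_xy = r_xy / sqrt(r_xx)`. Both Pearson and Spearman versions are
#' computed; the reported fraction is the squared Pearson disattenuated
#' correlation, clipped at 1 with a warning when the correction
#' overshoots.
#'
#' @param fitness Normalized fitness values.
#' @param scores Evolutionary scores for the same variants.
#' @param rep_corr Mean correlation between biological replicates
#'   (reliability), in (0, 1].
#' @return A one-row tibble: `r_xy`, `r_xx`, `R_xy`, `fraction`, and the
#'   Spearman analogues.
#' @export
variance_explained <- function(fitness, scores, rep_corr) {
  if (!is.finite(rep_corr) || rep_corr <= 0) {
    abort_foldstab("replicate reliability r_xx must be positive", "sites")
  }
  r_p <- stats::cor(fitness, scores, use = "complete.obs")
  r_s <- stats::cor(fitness, scores, use = "complete.obs", method = "spearman")
  R_p <- r_p / sqrt(rep_corr)
  R_s <- r_s / sqrt(rep_corr)
  fraction <- R_p^2
  if (fraction > 1) {
    rlang::warn("disattenuation overcorrected; fraction clipped at 1")
    fraction <- 1
  }
  tibble::tibble(
    r_xy = r_p, r_xx = rep_corr, R_xy = R_p, fraction = fraction,
    r_xy_spearman = r_s, R_xy_spearman = R_s
  )
}
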