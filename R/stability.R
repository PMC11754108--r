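# Destabilization calling, stability-class summaries, Fisher enrichments and
# clinical classifier evaluation.

#' Call destabilizing variants by one-tailed z-test with FDR control
#'
#' `z = f_norm / sigma_norm`; the one-tailed p-value is the probability of a
#' fitness this low under the null of no destabilization, and
#' Benjamini-Hochberg correction is applied over all supplied variants in
#' one batch. A variant is destabilizing iff `q < fdr_threshold` and
#' `f_norm < 0`; strongly destabilizing variants additionally have
#' `f_norm < strong_cut`.
#'
#' @param normalized A tibble with `f_norm` and `sigma_norm` (see
#'   [normalize_fitness()]).
#' @param fdr_threshold FDR level for the destabilization call.
#' @param strong_cut Normalized-fitness threshold for strong destabilization.
#' @return The input with `z`, `p`, `q` and `stability_class`
#'   (`stable`/`mild`/`strong`) columns added.
#' @export
call_destabilizing <- function(normalized, fdr_threshold = 0.1,
                               strong_cut = -0.3) {
  if (any(!is.finite(normalized$sigma_norm)) ||
    any(normalized$sigma_norm <= 0)) {
    abort_foldstab("sigma_norm must be finite and positive", "stability")
  }
  out <- normalized
  out$z <- out$f_norm / out$sigma_norm
  out$p <- stats::pnorm(out$z)
  out$q <- bh_adjust(out$p)
  destab <- out$q < fdr_threshold & out$f_norm < 0
  out$stability_class <- dplyr::case_when(
    destab & out$f_norm < strong_cut ~ "strong",
    destab ~ "mild",
    TRUE ~ "stable"
  )
  out
}

#' Summarize stability classes per clinical label
#'
#' Joins destabilization calls with clinical annotations and tabulates, for
#' each label, the count and percentage of variants per stability class.
#' Population variants are restricted to those above the allele-frequency
#' floor and reported under their own label.
#'
#' @param calls Output of [call_destabilizing()].
#' @param annotations A clinical annotation tibble (`label`,
#'   `allele_frequency` keyed by variant).
#' @param af_floor Allele-frequency floor for population variants.
#' @return A tibble with one row per (label, stability class): `n_label`,
#'   `n`, `pct` (NA when the label group is empty). Percentages per label
#'   sum to 100.
#' @export
summarize_stability_classes <- function(calls, annotations, af_floor = 1e-5) {
  ann <- annotations
  ann <- ann[ann$label != "population" |
    (!is.na(ann$allele_frequency) & ann$allele_frequency > af_floor), ]
  joined <- dplyr::inner_join(calls, ann, by = variant_keys)
  classes <- c("stable", "mild", "strong")
  labels <- unique(ann$label)
  grid <- tidyr::expand_grid(label = labels, stability_class = classes)
  counts <- joined |>
    dplyr::count(.data$label, .data$stability_class, name = "n")
  out <- dplyr::left_join(grid, counts, by = c("label", "stability_class")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$label) |>
    dplyr::mutate(
      n_label = sum(.data$n),
      pct = dplyr::if_else(
        .data$n_label > 0, 100 * .data$n / .data$n_label, NA_real_
      )
    ) |>
    dplyr::ungroup()
  out[, c("label", "n_label", "stability_class", "n", "pct")]
}

#' Two-tailed Fisher's exact test with sample odds ratio
#'
#' The odds ratio is the sample (cross-product) odds ratio with a
#' Haldane-Anscombe 0.5 correction applied to all cells only when some cell
#' is zero. The exact two-tailed p-value sums the hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one. The 95% CI is the Woolf log-OR interval.
#'
#' @param x A 2x2 matrix (or length-4 vector, filled column-wise) of
#'   non-negative integer counts.
#' @return A one-row tibble: `odds_ratio`, `log2_or`, `p`, `ci_lo`, `ci_hi`.
#' @export
fisher_or <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 4 || any(x < 0) || any(x != round(x)) || anyNA(x)) {
    abort_foldstab("fisher_or needs four non-negative integer cells", "stats")
  }
  a <- x[1]; c_ <- x[2]; b <- x[3]; d <- x[4] # column-wise fill of a 2x2
  corr <- if (any(x == 0)) 0.5 else 0
  or <- ((a + corr) * (d + corr)) / ((b + corr) * (c_ + corr))
  se_log <- sqrt(sum(1 / (x + if (any(x == 0)) 0.5 else 0)))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)

  m <- a + c_ # first-column margin
  n_ <- b + d
  k <- a + b # first-row margin
  support <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  tibble::tibble(
    odds_ratio = or, log2_or = log2(or), p = min(p, 1),
    ci_lo = ci[1], ci_hi = ci[2]
  )
}

mcc_from_counts <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (denom == 0) {
    return(NaN)
  }
  (tp * tn - fp * fn) / denom
}

#' Evaluate a stability-based classifier of clinical variants
#'
#' Label-positive variants are pathogenic; label-negative variants are
#' benign plus population variants above the allele-frequency floor. The
#' default prediction rule calls a variant pathogenic iff its stability
#' class is `strong`. When a continuous score column is supplied, a ROC
#' curve and AUC are computed as well (the MCC still uses the class rule
#' when available).
#'
#' @param calls Output of [call_destabilizing()], or any tibble keyed by
#'   variant carrying `stability_class` and/or the score column.
#' @param annotations Clinical annotations keyed by variant.
#' @param positive_rule `"strong"` (default) or `"destabilizing"` (strong or
#'   mild) as the predicted-pathogenic rule.
#' @param score_col Optional name of a numeric column in `calls` to evaluate
#'   as a continuous classifier (ROC/AUC); lower scores are treated as more
#'   pathogenic.
#' @param af_floor Allele-frequency floor for population variants.
#' @return A `classifier_eval` object: confusion counts, `mcc`, optional
#'   `auc` and `roc_points`, and the evaluated sample size.
#' @export
evaluate_classifier <- function(calls, annotations,
                                positive_rule = c("strong", "destabilizing"),
                                score_col = NULL, af_floor = 1e-5) {
  positive_rule <- match.arg(positive_rule)
  ann <- annotations
  ann <- ann[ann$label != "population" |
    (!is.na(ann$allele_frequency) & ann$allele_frequency > af_floor), ]
  joined <- dplyr::inner_join(calls, ann, by = variant_keys)
  joined <- joined[joined$label %in% c("pathogenic", "benign", "population"), ]
  if (!any(joined$label == "pathogenic") ||
    !any(joined$label %in% c("benign", "population"))) {
    abort_foldstab(
      "need at least one pathogenic and one benign-or-population variant",
      "classifier"
    )
  }
  truth <- joined$label == "pathogenic"

  mcc <- NaN
  confusion <- c(tp = NA_real_, fp = NA_real_, tn = NA_real_, fn = NA_real_)
  reason <- NULL
  if ("stability_class" %in% names(joined)) {
    pred <- if (positive_rule == "strong") {
      joined$stability_class == "strong"
    } else {
      joined$stability_class %in% c("strong", "mild")
    }
    confusion <- c(
      tp = sum(pred & truth), fp = sum(pred & !truth),
      tn = sum(!pred & !truth), fn = sum(!pred & truth)
    )
    mcc <- mcc_from_counts(
      confusion["tp"], confusion["fp"], confusion["tn"], confusion["fn"]
    )
    if (is.nan(mcc)) reason <- "degenerate confusion table (empty margin)"
  }

  auc <- NA_real_
  roc_points <- NULL
  if (!is.null(score_col)) {
    roc <- pROC::roc(
      response = truth, predictor = joined[[score_col]],
      direction = ">", levels = c(FALSE, TRUE), quiet = TRUE
    )
    auc <- as.numeric(pROC::auc(roc))
    roc_points <- tibble::tibble(
      threshold = roc$thresholds,
      sensitivity = roc$sensitivities,
      specificity = roc$specificities
    )
  }

  structure(
    list(
      positive_rule = positive_rule,
      confusion = confusion,
      mcc = mcc,
      mcc_sd = NA_real_,
      auc = auc,
      roc_points = roc_points,
      n = nrow(joined),
      reason = reason
    ),
    class = "classifier_eval"
  )
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat("<classifier_eval> n =", x$n, " MCC =", signif(x$mcc, 3))
  if (!is.na(x$auc)) cat("  AUC =", signif(x$auc, 3))
  cat("\n")
  invisible(x)
}

#' Resampling standard deviation of the MCC
#'
#' Each resample draws `f_norm* ~ Normal(f_norm, sigma_norm)` per variant,
#' re-runs the destabilization caller and recomputes the MCC; the standard
#' deviation across resamples estimates the measurement-noise uncertainty of
#' the MCC.
#'
#' @param normalized Output of [normalize_fitness()] (needs `f_norm` and
#'   `sigma_norm`).
#' @param annotations Clinical annotations keyed by variant.
#' @param n_resamples Number of resamples (>= 2).
#' @param seed Integer seed; results are deterministic under it.
#' @param ... Passed on to [call_destabilizing()] and
#'   [evaluate_classifier()] (`fdr_threshold`, `strong_cut`,
#'   `positive_rule`, `af_floor`).
#' @return A list with `mcc_sd` and the vector of resampled `mcc` values.
#' @export
resample_mcc <- function(normalized, annotations, n_resamples = 10,
                         seed = 1L, ...) {
  if (n_resamples < 2) {
    abort_foldstab("need at least 2 resamples", "classifier")
  }
  dots <- list(...)
  call_args <- dots[names(dots) %in% c("fdr_threshold", "strong_cut")]
  eval_args <- dots[names(dots) %in% c("positive_rule", "af_floor")]
  withr::local_seed(seed)
  mccs <- vapply(seq_len(n_resamples), function(i) {
    resampled <- normalized
    resampled$f_norm <- stats::rnorm(
      nrow(normalized), normalized$f_norm, normalized$sigma_norm
    )
    calls <- do.call(call_destabilizing, c(list(resampled), call_args))
    ev <- do.call(evaluate_classifier, c(list(calls, annotations), eval_args))
    ev$mcc
  }, numeric(1))
  list(mcc_sd = stats::sd(mccs), mcc = mccs)
}
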