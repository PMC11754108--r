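# Per-domain quality control, PCA ranking with retention filtering, and
# linear fitness normalization.

#' Per-domain quality-control metrics
#'
#' Four metrics per domain: the wild-type position in the fitness
#' distribution `(f_wt - p95) / (p95 - p5)` (percentiles over all variants
#' of the domain), the mean Pearson correlation between replicate growth
#' rates for missense variants, the correlation between fitness and residue
#' rSASA, and the correlation between fitness and mutant-residue
#' hydrophobicity. Coverage is the fraction of designed variants with at
#' least `min_counts` reads in at least one replicate.
#'
#' @param variants A variant tibble with `fitness`, replicate
#'   `growth_rate_*` and optional `count_*` columns.
#' @param domains A domain tibble with `wt_growth_rate` and an `rsasa`
#'   list-column of per-residue values.
#' @param hydrophobicity Named 20-value scale; defaults to a standard
#'   hydropathy scale. The choice only affects a QC correlation.
#' @param min_counts Count threshold used for coverage.
#' @return A tibble with one row per domain: the four metrics, `coverage`,
#'   `n_missense`, and a `reasons` list-column of automatic failures
#'   (degenerate fitness range, too few missense variants).
#' @export
compute_quality_metrics <- function(variants, domains,
                                    hydrophobicity = NULL,
                                    min_counts = 10) {
  hyd <- hydrophobicity %||% KYTE_DOOLITTLE
  rate_cols <- growth_rate_cols(variants)
  cnt_cols <- count_cols(variants)

  purrr::map_dfr(split(variants, variants$domain_id), function(v) {
    id <- v$domain_id[1]
    dom <- domains[domains$domain_id == id, ]
    reasons <- character()
    mis <- v[v$variant_class == "missense" & is.finite(v$fitness), ]
    if (nrow(mis) < 20) reasons <- c(reasons, "fewer than 20 missense variants")

    f_wt <- dom$wt_growth_rate[1]
    q <- stats::quantile(v$fitness, c(0.05, 0.95), na.rm = TRUE, names = FALSE)
    wt_position <- if (q[2] > q[1]) {
      (f_wt - q[2]) / (q[2] - q[1])
    } else {
      reasons <- c(reasons, "zero fitness range")
      NA_real_
    }

    rep_corr <- if (length(rate_cols) >= 2 && nrow(mis) >= 3) {
      pairs <- utils::combn(rate_cols, 2, simplify = FALSE)
      mean(vapply(
        pairs,
        function(pr) stats::cor(mis[[pr[1]]], mis[[pr[2]]]),
        numeric(1)
      ))
    } else {
      NA_real_
    }

    rsasa <- dom$rsasa[[1]]
    sasa_corr <- if (!is.null(rsasa)) {
      stats::cor(v$fitness, rsasa[v$position], use = "complete.obs")
    } else {
      NA_real_
    }
    hyd_corr <- if (nrow(mis) >= 3) {
      stats::cor(mis$fitness, hyd[mis$mut_aa], use = "complete.obs")
    } else {
      NA_real_
    }

    coverage <- if (length(cnt_cols)) {
      mean(apply(
        as.matrix(v[, cnt_cols]), 1,
        function(x) any(x >= min_counts, na.rm = TRUE)
      ))
    } else {
      NA_real_
    }

    tibble::tibble(
      domain_id = id,
      wt_position = wt_position,
      rep_corr = rep_corr,
      sasa_corr = sasa_corr,
      hyd_corr = hyd_corr,
      coverage = coverage,
      n_missense = nrow(mis),
      reasons = list(reasons)
    )
  })
}

#' Classify a domain as folded or excluded from structural features
#'
#' A domain is excluded when it lacks a hydrophobic core (fewer than 10% of
#' residues buried, rSASA < 25%) or when its mean model confidence (pLDDT)
#' is below 50, indicating disorder.
#'
#' @param domains A domain tibble with `rsasa` and `plddt` list-columns.
#' @return A tibble with per-domain `core_fraction`, `mean_plddt`,
#'   `foldedness` (`"folded"`/`"excluded"`) and `reason`.
#' @export
classify_foldedness <- function(domains) {
  purrr::map_dfr(seq_len(nrow(domains)), function(i) {
    rsasa <- domains$rsasa[[i]]
    plddt <- domains$plddt[[i]]
    if (is.null(rsasa) || is.null(plddt) || anyNA(rsasa) || anyNA(plddt)) {
      return(tibble::tibble(
        domain_id = domains$domain_id[i],
        core_fraction = NA_real_, mean_plddt = NA_real_,
        foldedness = "excluded", reason = "missing structural features"
      ))
    }
    core_fraction <- mean(rsasa < 0.25)
    mean_plddt <- mean(plddt)
    reason <- NA_character_
    if (core_fraction < 0.10) reason <- "no hydrophobic core"
    if (mean_plddt < 50) {
      reason <- if (is.na(reason)) "disordered (low pLDDT)" else paste(reason, "disordered (low pLDDT)", sep = "; ")
    }
    tibble::tibble(
      domain_id = domains$domain_id[i],
      core_fraction = core_fraction,
      mean_plddt = mean_plddt,
      foldedness = if (is.na(reason)) "folded" else "excluded",
      reason = reason
    )
  })
}

#' Rank domains by a PCA quality score and apply retention rules
#'
#' The four quality metrics are standardized (zero mean, unit variance)
#' before PCA; the first principal component is sign-oriented so that higher
#' scores track higher replicate correlation, and domains are ranked by it.
#' A domain is retained iff its rank is within `max_rank`, its replicate
#' correlation strictly exceeds `min_rep_corr`, and its coverage exceeds
#' `min_coverage`; an explicit manual exclusion list is honoured afterwards.
#'
#' @param metrics Output of [compute_quality_metrics()].
#' @param max_rank Maximum retained rank (default: no rank filter).
#' @param min_rep_corr Strict lower bound on the replicate correlation.
#' @param min_coverage Strict lower bound on coverage.
#' @param exclude Character vector of domain ids to drop regardless of rank.
#' @return `metrics` augmented with `pc1_score`, `rank`, `retained` and
#'   updated `reasons`; the PC1 variance share is attached as attribute
#'   `pc1_var_share`.
#' @export
rank_and_filter <- function(metrics, max_rank = Inf, min_rep_corr = 0.485,
                            min_coverage = 0.5, exclude = character()) {
  metric_cols <- c("wt_position", "rep_corr", "sasa_corr", "hyd_corr")
  complete <- stats::complete.cases(metrics[, metric_cols])
  if (sum(complete) < 3) {
    abort_foldstab("need at least 3 domains with complete metrics", "qc")
  }
  m <- as.matrix(metrics[complete, metric_cols])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::warn(paste0(
      "constant metric column(s) dropped from PCA: ",
      paste(metric_cols[sds == 0], collapse = ", ")
    ))
    m <- m[, sds > 0, drop = FALSE]
  }
  z <- scale(m)
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  pc1 <- pca$x[, 1]
  orient_col <- if ("rep_corr" %in% colnames(m)) "rep_corr" else colnames(m)[1]
  s <- stats::cor(pc1, z[, orient_col])
  if (is.finite(s) && s < 0) pc1 <- -pc1

  metrics$pc1_score <- NA_real_
  metrics$pc1_score[complete] <- pc1
  ord <- order(-metrics$pc1_score, metrics$domain_id, na.last = TRUE)
  rank <- integer(nrow(metrics))
  rank[ord] <- seq_len(nrow(metrics))
  rank[!complete] <- NA_integer_
  metrics$rank <- rank

  retained <- complete &
    (is.na(rank) | rank <= max_rank) &
    !is.na(metrics$rep_corr) & metrics$rep_corr > min_rep_corr &
    !is.na(metrics$coverage) & metrics$coverage > min_coverage
  reasons <- purrr::pmap(
    list(metrics$reasons, seq_len(nrow(metrics))),
    function(r, i) {
      if (complete[i] && !is.na(rank[i]) && rank[i] > max_rank) {
        r <- c(r, sprintf("rank %d exceeds cutoff %s", rank[i], format(max_rank)))
      }
      if (!is.na(metrics$rep_corr[i]) && metrics$rep_corr[i] <= min_rep_corr) {
        r <- c(r, sprintf("replicate correlation <= %.3f", min_rep_corr))
      }
      if (!is.na(metrics$coverage[i]) && metrics$coverage[i] <= min_coverage) {
        r <- c(r, "insufficient coverage")
      }
      if (metrics$domain_id[i] %in% exclude) r <- c(r, "manually excluded")
      r
    }
  )
  metrics$reasons <- reasons
  metrics$retained <- retained &
    !(metrics$domain_id %in% exclude) &
    vapply(reasons, length, integer(1)) == 0
  attr(metrics, "pc1_var_share") <- pca$sdev[1]^2 / sum(pca$sdev^2)
  metrics
}

#' Normalize fitness within each domain
#'
#' Linear scaling such that the wild type maps to 0 and the 2.5th percentile
#' of the growth rates of all missense variants plus the wild type maps to
#' -1. Percentiles use linear interpolation between order statistics.
#' Errors propagate through the same scale factor.
#'
#' @param variants A variant tibble with `fitness` and `sigma`.
#' @param domains A domain tibble with `wt_growth_rate`.
#' @param min_missense Domains with fewer missense variants are flagged
#'   (percentile unstable) but still normalized.
#' @return `variants` augmented with `f_norm`, `sigma_norm`, `scale_factor`
#'   and `offset` (the affine map applied, `f_norm = fitness * scale_factor
#'   + offset`).
#' @export
normalize_fitness <- function(variants, domains, min_missense = 40) {
  purrr::map_dfr(split(variants, variants$domain_id), function(v) {
    id <- v$domain_id[1]
    f_wt <- domains$wt_growth_rate[domains$domain_id == id]
    if (length(f_wt) != 1 || is.na(f_wt)) {
      abort_foldstab(paste0("missing wild-type growth rate for ", id), "normalize")
    }
    mis <- v$fitness[v$variant_class == "missense"]
    if (length(mis) < min_missense) {
      rlang::warn(sprintf(
        "domain %s has only %d missense variants; 2.5th percentile unstable",
        id, length(mis)
      ))
    }
    p25 <- stats::quantile(c(mis, f_wt), 0.025, names = FALSE, type = 7)
    denom <- f_wt - p25
    if (denom <= 0) {
      abort_foldstab(
        paste0("non-positive dynamic range for domain ", id),
        "normalize"
      )
    }
    v$f_norm <- (v$fitness - f_wt) / denom
    v$sigma_norm <- v$sigma / denom
    v$scale_factor <- 1 / denom
    v$offset <- -f_wt / denom
    v
  })
}
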