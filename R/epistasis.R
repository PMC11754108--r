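# Epistasis: variants whose fitness deviates from the family energy model,
# and alignment sites enriched for such deviations.

#' Call epistatic variants from energy-model residuals
#'
#' Residuals are observed minus model-predicted fitness, in raw growth-rate
#' units (h^-1) by default; `z = residual / sigma` with a two-tailed normal
#' p-value and Benjamini-Hochberg correction within the family. A variant
#' is epistatic iff `q < fdr` and `|residual| > magnitude_cut`. Units are
#' declared, never guessed: with `units = "normalized"` the residuals are
#' converted through the per-domain normalization scale factors, which must
#' then be supplied.
#'
#' @param model A converged `family_energy_model`.
#' @param encoding The family [encode_family()] result the model was fit
#'   on.
#' @param magnitude_cut Residual magnitude gate (same units as the
#'   residuals; h^-1 in raw mode).
#' @param fdr FDR level.
#' @param units `"growth_rate"` (default) or `"normalized"`.
#' @param scale_factors Named per-domain scale factors (from
#'   [normalize_fitness()]) required in normalized mode.
#' @return The encoding's variant table with `predicted`, `residual`, `z`,
#'   `p`, `q` and `is_epistatic`.
#' @export
call_epistatic <- function(model, encoding, magnitude_cut = 0.05, fdr = 0.1,
                           units = c("growth_rate", "normalized"),
                           scale_factors = NULL) {
  units <- match.arg(units)
  stopifnot(inherits(model, "family_energy_model"))
  if (!model$converged) {
    abort_foldstab("model did not converge; residuals undefined", "epistasis")
  }
  v <- encoding$variants
  v$predicted <- predict_encoding(model, encoding)$fitness
  v$residual <- v$fitness - v$predicted
  sigma <- v$sigma
  if (units == "normalized") {
    if (is.null(scale_factors)) {
      abort_foldstab(
        "normalized units requested but no per-domain scale factors supplied",
        "epistasis"
      )
    }
    sf <- unname(scale_factors[v$domain_id])
    if (anyNA(sf)) {
      abort_foldstab("missing scale factor for some domain(s)", "epistasis")
    }
    v$residual <- v$residual * sf
    sigma <- sigma * sf
  }
  v$z <- v$residual / sigma
  v$p <- 2 * stats::pnorm(-abs(v$z))
  v$q <- bh_adjust(v$p)
  v$is_epistatic <- v$q < fdr & abs(v$residual) > magnitude_cut
  v
}

#' Classify alignment columns as core, surface or changing
#'
#' A column is core when its residue is buried (rSASA < 25%) in at least
#' 75% of the homologues carrying it, surface when exposed (rSASA > 25%)
#' in at least 75%, and changing otherwise. Homologues gapped at a column
#' are excluded from its denominator.
#'
#' @param alignment A [family_alignment()].
#' @param domains Domain tibble with an `rsasa` list-column.
#' @return A tibble with per-column `n_homologues`, burial fractions,
#'   `site_class` and a low-coverage flag for columns carried by fewer
#'   than 2 homologues.
#' @export
classify_sites <- function(alignment, domains) {
  rsasa <- stats::setNames(domains$rsasa, domains$domain_id)
  purrr::map_dfr(seq_len(alignment$columns), function(cc) {
    vals <- purrr::map_dbl(names(alignment$rows), function(id) {
      pos <- match(cc, alignment$column_map[[id]])
      if (is.na(pos)) NA_real_ else rsasa[[id]][pos]
    })
    vals <- vals[!is.na(vals)]
    n <- length(vals)
    low_coverage <- n < 2
    site_class <- if (low_coverage) {
      "changing"
    } else if (mean(vals < 0.25) >= 0.75) {
      "core"
    } else if (mean(vals > 0.25) >= 0.75) {
      "surface"
    } else {
      "changing"
    }
    tibble::tibble(
      column = cc,
      n_homologues = n,
      frac_core = if (n) mean(vals < 0.25) else NA_real_,
      site_class = site_class,
      low_coverage = low_coverage
    )
  })
}

#' Per-column enrichment of epistatic variants
#'
#' For each alignment column, a 2x2 table of (epistatic vs not) by (at the
#' column vs elsewhere) is tested with the two-tailed Fisher's exact test;
#' FDR correction runs over columns. An epistatic site has `log2(OR) > 1.5`
#' and `q < 0.05`. A family-level core-versus-surface odds ratio for
#' epistatic variants is attached as attribute `core_surface`.
#'
#' @param calls Output of [call_epistatic()] (needs `column` and
#'   `is_epistatic`).
#' @param site_classes Output of [classify_sites()].
#' @param log2_or_cut,fdr Epistatic-site thresholds.
#' @return A tibble with per-column counts, odds ratio, `log2_or`, `q`,
#'   `site_class` and `is_epistatic_site`.
#' @export
site_enrichment <- function(calls, site_classes, log2_or_cut = 1.5,
                            fdr = 0.05) {
  if (!any(calls$is_epistatic)) {
    abort_foldstab("no epistatic calls in family", "epistasis")
  }
  tot_epi <- sum(calls$is_epistatic)
  tot_non <- sum(!calls$is_epistatic)
  out <- purrr::map_dfr(sort(unique(calls$column)), function(cc) {
    at <- calls$column == cc
    a <- sum(at & calls$is_epistatic)
    b <- sum(at & !calls$is_epistatic)
    fo <- fisher_or(matrix(c(a, tot_epi - a, b, tot_non - b), 2))
    tibble::tibble(
      column = cc,
      n_epistatic = a,
      n_variants = sum(at),
      odds_ratio = fo$odds_ratio,
      log2_or = fo$log2_or,
      p = fo$p
    )
  })
  out$q <- bh_adjust(out$p)
  out <- dplyr::left_join(
    out, site_classes[, c("column", "site_class")],
    by = "column"
  )
  out$is_epistatic_site <- out$log2_or > log2_or_cut & out$q < fdr

  by_class <- dplyr::left_join(
    calls, site_classes[, c("column", "site_class")],
    by = "column"
  )
  cs <- by_class[by_class$site_class %in% c("core", "surface"), ]
  attr(out, "core_surface") <- if (nrow(cs)) {
    fisher_or(matrix(
      c(
        sum(cs$is_epistatic & cs$site_class == "core"),
        sum(cs$is_epistatic & cs$site_class == "surface"),
        sum(!cs$is_epistatic & cs$site_class == "core"),
        sum(!cs$is_epistatic & cs$site_class == "surface")
      ),
      2
    ))
  } else {
    NULL
  }
  out
}
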