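# Synthetic domain families with known thermodynamics. The generator runs the
# two-state model forwards: shared per-column mutation energies, per-homologue
# wild-type baselines, Boltzmann fraction folded, and an affine map from
# fraction folded to growth rate, with replicate measurement noise.

#' Default configuration for the synthetic family generator
#'
#' All energies are in RT units (RT fixed at 1); growth rates in h^-1.
#' Wild-type sequences are drawn per column from a softmax over the negated
#' composition energies, which guarantees mostly-folded wild types, as a
#' stability selection assay requires.
#'
#' @param core_fraction Fraction of alignment columns treated as buried core;
#'   core columns receive larger-magnitude mutation energies and low rSASA.
#' @param n_replicates Number of biological replicates per variant.
#' @param noise_sigma Standard deviation of the per-variant mean-fitness noise
#'   (h^-1); replicate noise is `noise_sigma * sqrt(n_replicates)` so the
#'   replicate mean has standard deviation `noise_sigma`.
#' @param gamma0,gamma1 Affine map from fraction folded to growth rate:
#'   `rate = gamma0 + gamma1 * p_f`. `gamma1` must be positive.
#' @param dg_wt_mean Target mean wild-type folding free energy (RT units).
#' @param u_sd Per-column spread of wild-type composition energies.
#' @param temperature Softmax temperature for wild-type residue sampling;
#'   lower values concentrate wild types on low-energy residues.
#' @param d_mean_core,d_mean_surface,d_sd Mean and spread of mutation
#'   energies (ddG) at core and surface columns.
#' @param mean_count Poisson mean of per-replicate input read counts.
#' @param n_functional Number of planted functional columns (drawn from
#'   surface columns, where binding interfaces live).
#' @param functional_penalty Evolutionary-score penalty at functional columns.
#' @param score_min,score_max Range of the synthetic evolutionary score;
#'   the default range exceeds 10 so score-range eligibility holds.
#' @param score_noise Standard deviation of evolutionary-score noise.
#' @param n_synonymous Number of synonymous (wild-type re-measurement)
#'   variants per homologue.
#' @param divergence Per-homologue fraction of columns whose wild-type
#'   residue is drawn uniformly instead of from the softmax (recycled);
#'   used to plant sequence divergence for leave-one-homologue-out studies.
#' @param sigma_floor Floor on the per-variant fitness error (h^-1).
#' @return A named list of generator settings.
#' @export
family_config <- function(core_fraction = 0.3,
                          n_replicates = 3,
                          noise_sigma = 0.05,
                          gamma0 = 0.05,
                          gamma1 = 0.4,
                          dg_wt_mean = -2.5,
                          u_sd = 0.1,
                          temperature = 0.03,
                          d_mean_core = 3.5,
                          d_mean_surface = 1.5,
                          d_sd = 1.5,
                          mean_count = 100,
                          n_functional = 4,
                          functional_penalty = 6,
                          score_min = -15,
                          score_max = 0,
                          score_noise = 0.5,
                          n_synonymous = 2,
                          divergence = 0,
                          sigma_floor = 1e-4) {
  as.list(environment())
}

#' Simulate a family of homologous domains with known energetics
#'
#' Runs the two-state thermodynamic model forwards. Every single missense
#' variant of every homologue is generated; replicate growth rates are
#' `gamma0 + gamma1 * p_f + noise`, fitness is the replicate mean and sigma
#' the replicate standard error (floored). The planted parameters are
#' returned losslessly in `truth` for recovery testing, and the truth
#' invariant `dG_wt = b0 + sum_c U[c, wt(c)]` holds exactly.
#'
#' @param n_homologues Number of homologous domains (>= 2).
#' @param n_columns Number of alignment columns (>= 5); the synthetic
#'   alignment is gap-free, so columns coincide with residue positions.
#' @param config Generator settings from [family_config()].
#' @param seed Integer seed; all randomness flows from it.
#' @param family_id Family accession used in identifiers.
#' @return A `family_sim` list with `domains`, `variants`, `alignment`
#'   (a [family_alignment()]) and `truth`.
#' @export
simulate_family <- function(n_homologues = 12, n_columns = 40,
                            config = family_config(), seed = 1L,
                            family_id = "SYNFAM1") {
  stopifnot(n_homologues >= 2, n_columns >= 5)
  if (config$gamma1 <= 0) {
    abort_foldstab("gamma1 must be positive: fitness must increase with folding", "config")
  }
  if (config$noise_sigma < 0) {
    abort_foldstab("noise_sigma must be non-negative", "config")
  }
  withr::local_seed(seed)
  L <- n_columns
  n_aa <- length(AMINO_ACIDS)

  n_core <- max(1L, round(config$core_fraction * L))
  core_columns <- sort(sample.int(L, n_core))
  surface_columns <- setdiff(seq_len(L), core_columns)

  U_true <- matrix(
    stats::rnorm(L * n_aa, 0, config$u_sd), L, n_aa,
    dimnames = list(NULL, AMINO_ACIDS)
  )
  U_true <- U_true - rowMeans(U_true)

  mu <- ifelse(seq_len(L) %in% core_columns,
    config$d_mean_core, config$d_mean_surface
  )
  D_true <- matrix(
    stats::rnorm(L * n_aa, rep(mu, n_aa), config$d_sd), L, n_aa,
    dimnames = list(NULL, AMINO_ACIDS)
  )

  n_fun <- min(config$n_functional, length(surface_columns))
  functional_columns <- sort(sample(surface_columns, n_fun))

  divergence <- rep_len(config$divergence, n_homologues)
  seqs <- vapply(seq_len(n_homologues), function(h) {
    paste(vapply(seq_len(L), function(cc) {
      if (divergence[h] > 0 && stats::runif(1) < divergence[h]) {
        # an alternative plausible residue: the softmax with the consensus
        # (modal) residue excluded, so divergence changes sequence identity
        # without grossly destabilizing the homologue
        pr <- exp(-U_true[cc, ] / config$temperature)
        pr[which.max(pr)] <- 0
        sample(AMINO_ACIDS, 1L, prob = pr / sum(pr))
      } else {
        pr <- exp(-U_true[cc, ] / config$temperature)
        sample(AMINO_ACIDS, 1L, prob = pr / sum(pr))
      }
    }, character(1)), collapse = "")
  }, character(1))

  domain_ids <- sprintf("%s_h%02d", family_id, seq_len(n_homologues))
  comp_sum <- vapply(seq_len(n_homologues), function(h) {
    wt <- strsplit(seqs[h], "")[[1]]
    sum(U_true[cbind(seq_len(L), match(wt, AMINO_ACIDS))])
  }, numeric(1))
  b0 <- config$dg_wt_mean - mean(comp_sum)
  dG_wt <- stats::setNames(b0 + comp_sum, domain_ids)

  rsasa <- lapply(seq_len(n_homologues), function(h) {
    ifelse(seq_len(L) %in% core_columns,
      stats::runif(L, 0.05, 0.24), stats::runif(L, 0.30, 0.90)
    )
  })
  plddt <- lapply(seq_len(n_homologues), function(h) stats::runif(L, 75, 95))

  domains <- tibble::tibble(
    domain_id = domain_ids,
    family_id = family_id,
    sequence = seqs,
    alignment_row = seqs,
    rsasa = rsasa,
    plddt = plddt,
    wt_growth_rate = config$gamma0 + config$gamma1 * fraction_folded(dG_wt)
  )

  variants <- purrr::map_dfr(seq_len(n_homologues), function(h) {
    wt <- strsplit(seqs[h], "")[[1]]
    mis <- tidyr::expand_grid(position = seq_len(L), mut_aa = AMINO_ACIDS)
    mis$wt_aa <- wt[mis$position]
    mis <- mis[mis$mut_aa != mis$wt_aa, ]
    mis$variant_class <- "missense"
    syn_pos <- sort(sample.int(L, min(config$n_synonymous, L)))
    syn <- tibble::tibble(
      position = syn_pos, mut_aa = wt[syn_pos], wt_aa = wt[syn_pos],
      variant_class = "synonymous"
    )
    out <- dplyr::bind_rows(mis, syn)
    out$domain_id <- domain_ids[h]
    out$dG_true <- dG_wt[h] +
      ifelse(out$variant_class == "missense",
        D_true[cbind(out$position, match(out$mut_aa, AMINO_ACIDS))], 0
      )
    out[, c(
      "domain_id", "position", "wt_aa", "mut_aa", "variant_class", "dG_true"
    )]
  })

  variants <- add_measurements(variants, config)

  truth <- structure(
    list(
      family_id = family_id,
      U_true = U_true,
      D_true = D_true,
      b0 = b0,
      gamma0 = config$gamma0,
      gamma1 = config$gamma1,
      dG_wt = dG_wt,
      core_columns = core_columns,
      functional_columns = functional_columns,
      functional_penalty = config$functional_penalty,
      epistatic_set = tibble::tibble(
        domain_id = character(), position = integer(),
        wt_aa = character(), mut_aa = character(), delta = numeric()
      ),
      noise_sigma = config$noise_sigma,
      seed = seed,
      config = config
    ),
    class = "synthetic_truth"
  )

  structure(
    list(
      domains = domains,
      variants = variants,
      alignment = family_alignment(
        stats::setNames(seqs, domain_ids), family_id
      ),
      truth = truth
    ),
    class = "family_sim"
  )
}

# Replicate growth rates, mean fitness, sigma and read counts for a variant
# table carrying true dG values. Consumes the current RNG stream.
add_measurements <- function(variants, config) {
  n <- nrow(variants)
  k <- config$n_replicates
  p <- fraction_folded(variants$dG_true)
  mu <- config$gamma0 + config$gamma1 * p
  eps <- matrix(
    stats::rnorm(n * k, 0, config$noise_sigma * sqrt(k)), n, k
  )
  rates <- mu + eps
  for (r in seq_len(k)) variants[[paste0("growth_rate_", r)]] <- rates[, r]
  counts <- matrix(stats::rpois(n * k, config$mean_count), n, k)
  for (r in seq_len(k)) variants[[paste0("count_", r)]] <- counts[, r]
  variants$fitness <- rowMeans(rates)
  sds <- apply(rates, 1, stats::sd) / sqrt(k)
  variants$sigma <- pmax(sds, config$sigma_floor)
  variants
}

#' Plant epistatic deviations in a simulated family
#'
#' A subset of missense variants has its folding free energy shifted by
#' `delta_magnitude` before fitness is regenerated, recording the planted set
#' in `truth$epistatic_set`. Deviations are oriented toward the responsive
#' side of the two-state curve (destabilizing on folded backgrounds,
#' stabilizing on unfolded ones) with probability `p_destabilizing`: in a
#' saturating assay a shift deeper into either plateau produces no
#' measurable fitness change, so symmetric planting would bury part of the
#' ground truth by construction.
#'
#' @param sim A `family_sim` from [simulate_family()].
#' @param fraction Fraction of missense variants to perturb, in `[0, 1)`.
#'   The planted count is exact (`round(fraction * n)`, sampling without
#'   replacement).
#' @param delta_magnitude Energy shift magnitude (RT units).
#' @param seed Integer seed.
#' @param core_bias Sampling weight multiplier for variants at core columns
#'   (the planted structure mirrors the enrichment of epistasis in buried
#'   cores); set to 1 for uniform sampling.
#' @param p_destabilizing Probability that a planted shift points toward
#'   the responsive side of the curve (the remainder point away).
#' @param columns Optional alignment columns to restrict planting to (for
#'   hotspot-site studies); the planted count is still `round(fraction *
#'   n_missense)`, capped by the variants available there.
#' @param domain_ids Optional homologues to restrict planting to; the
#'   fraction is then relative to their missense variants (used to emulate
#'   context dependence that grows with sequence divergence).
#' @return The updated `family_sim` with regenerated measurements for the
#'   perturbed variants and the planted set recorded in `truth`.
#' @export
inject_epistasis <- function(sim, fraction, delta_magnitude = 5, seed = 1L,
                             core_bias = 2, p_destabilizing = 0.9,
                             columns = NULL, domain_ids = NULL) {
  stopifnot(inherits(sim, "family_sim"))
  if (fraction < 0 || fraction >= 1) {
    abort_foldstab("fraction must be in [0, 1)", "config")
  }
  if (fraction == 0) {
    return(sim)
  }
  withr::local_seed(seed)
  v <- sim$variants
  mis <- which(v$variant_class == "missense")
  if (!is.null(domain_ids)) mis <- mis[v$domain_id[mis] %in% domain_ids]
  n_pick <- round(fraction * length(mis))
  if (!is.null(columns)) mis <- mis[v$position[mis] %in% columns]
  n_pick <- min(n_pick, length(mis))
  w <- ifelse(v$position[mis] %in% sim$truth$core_columns, core_bias, 1)
  picked <- sample(mis, n_pick, prob = w)
  # orient the shift toward the responsive side of the two-state curve:
  # destabilize folded backgrounds, stabilize unfolded ones
  toward <- ifelse(fraction_folded(v$dG_true[picked]) >= 0.5, 1, -1)
  sign <- ifelse(stats::runif(n_pick) < p_destabilizing, toward, -toward)
  delta <- sign * delta_magnitude
  v$dG_true[picked] <- v$dG_true[picked] + delta

  regen <- add_measurements(v[picked, , drop = FALSE], sim$truth$config)
  v[picked, names(regen)] <- regen
  sim$variants <- v
  sim$truth$epistatic_set <- tibble::tibble(
    domain_id = v$domain_id[picked],
    position = v$position[picked],
    wt_aa = v$wt_aa[picked],
    mut_aa = v$mut_aa[picked],
    delta = delta
  )
  sim
}

#' Simulate evolutionary fitness scores with planted functional sites
#'
#' Scores follow the stability signal (`score = s_max + (s_min - s_max) *
#' (1 - p_f / p_f_wt)`, clipped to the score range), minus a penalty for
#' missense mutations at planted functional columns, plus Gaussian noise.
#' This is a synthetic stand-in for a protein-language-model score: it
#' reproduces the one feature downstream analysis needs (function beyond
#' stability at specific sites), not the scale of any real predictor.
#'
#' @param sim A `family_sim` from [simulate_family()].
#' @param seed Integer seed.
#' @param config Generator settings; defaults to the settings stored in the
#'   simulation truth.
#' @return A tibble of predictor scores keyed by variant.
#' @export
simulate_evolutionary_scores <- function(sim, seed = 1L,
                                         config = NULL) {
  if (!inherits(sim, "family_sim") || is.null(sim$truth)) {
    abort_foldstab("simulation truth is required to generate scores", "config")
  }
  config <- config %||% sim$truth$config
  withr::local_seed(seed)
  v <- sim$variants
  p_wt <- fraction_folded(sim$truth$dG_wt)[v$domain_id]
  p <- fraction_folded(v$dG_true)
  base <- config$score_max +
    (config$score_min - config$score_max) * (1 - p / p_wt)
  base <- pmin(pmax(base, config$score_min), config$score_max)
  penalty <- ifelse(
    v$variant_class == "missense" &
      v$position %in% sim$truth$functional_columns,
    config$functional_penalty, 0
  )
  tibble::tibble(
    domain_id = v$domain_id,
    position = v$position,
    wt_aa = v$wt_aa,
    mut_aa = v$mut_aa,
    score = base - penalty + stats::rnorm(nrow(v), 0, config$score_noise),
    predictor_name = "synthetic_evo"
  )
}

#' Default configuration for synthetic clinical labels
#'
#' @param pathogenic_rate Base rate scaling the pathogenic sampling
#'   probability (0 disables pathogenic labels).
#' @param benign_rate,population_rate,vus_rate Per-variant labelling
#'   probabilities for near-neutral (benign, population) and remaining (VUS)
#'   variants.
#' @param functional_weight Added deleteriousness for missense variants at
#'   planted functional columns.
#' @param slope,midpoint Logistic link from combined deleteriousness to the
#'   pathogenic sampling probability.
#' @param benign_max Deleteriousness ceiling for benign/population sampling.
#' @param af_range Allele-frequency range (log-uniform) for population
#'   variants.
#' @return A named list of settings.
#' @export
clinical_config <- function(pathogenic_rate = 0.08,
                            benign_rate = 0.05,
                            population_rate = 0.05,
                            vus_rate = 0.05,
                            functional_weight = 0.5,
                            slope = 8,
                            midpoint = 0.5,
                            benign_max = 0.2,
                            af_range = c(1e-6, 1e-2)) {
  as.list(environment())
}

#' Simulate clinical variant labels conditioned on planted effects
#'
#' Pathogenic labels are sampled with probability increasing in the combined
#' deleteriousness (destabilization plus the planted functional-site effect);
#' benign and population labels are sampled from near-neutral variants, the
#' latter with log-uniform allele frequencies. Labels are mutually exclusive.
#'
#' @param sim A `family_sim` from [simulate_family()].
#' @param config Settings from [clinical_config()].
#' @param seed Integer seed.
#' @return A tibble of clinical annotations (label, allele frequency) keyed
#'   by variant; `allele_frequency` is present iff the label is
#'   `"population"`.
#' @export
simulate_clinical_labels <- function(sim, config = clinical_config(),
                                     seed = 1L) {
  stopifnot(inherits(sim, "family_sim"))
  withr::local_seed(seed)
  v <- sim$variants[sim$variants$variant_class == "missense", ]
  p_wt <- fraction_folded(sim$truth$dG_wt)[v$domain_id]
  destab <- pmin(pmax(1 - fraction_folded(v$dG_true) / p_wt, 0), 1)
  functional <- as.numeric(
    v$position %in% sim$truth$functional_columns &
      sim$truth$functional_penalty > 0
  )
  del <- destab + config$functional_weight * functional

  p_path <- pmin(
    config$pathogenic_rate * 2 *
      stats::plogis(config$slope * (del - config$midpoint)),
    1
  )
  u <- stats::runif(nrow(v))
  label <- rep(NA_character_, nrow(v))
  label[u < p_path] <- "pathogenic"

  neutral <- is.na(label) & del < config$benign_max
  u2 <- stats::runif(nrow(v))
  label[neutral & u2 < config$benign_rate] <- "benign"
  label[neutral & u2 >= config$benign_rate &
    u2 < config$benign_rate + config$population_rate] <- "population"
  label[is.na(label) & stats::runif(nrow(v)) < config$vus_rate] <- "vus"

  keep <- !is.na(label)
  af <- rep(NA_real_, sum(keep))
  pop <- label[keep] == "population"
  af[pop] <- 10^stats::runif(
    sum(pop), log10(config$af_range[1]), log10(config$af_range[2])
  )
  tibble::tibble(
    domain_id = v$domain_id[keep],
    position = v$position[keep],
    wt_aa = v$wt_aa[keep],
    mut_aa = v$mut_aa[keep],
    label = label[keep],
    allele_frequency = af
  )
}

#' @export
print.family_sim <- function(x, ...) {
  cat(
    "<family_sim> ", x$truth$family_id, ": ", nrow(x$domains),
    " homologues x ", x$alignment$columns, " columns, ",
    nrow(x$variants), " variants\n",
    sep = ""
  )
  invisible(x)
}
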