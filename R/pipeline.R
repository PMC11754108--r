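# End-to-end orchestration over a simulated or loaded family: qc ->
# normalize -> stability -> sites -> energy model -> epistasis, with a
# content-hashed artifact manifest for reproducibility checks.

#' Configure a pipeline run
#'
#' Every stochastic stage receives a sub-seed derived deterministically from
#' the master seed and the stage name, so adding stages never perturbs
#' existing ones. The configuration is serialized alongside the outputs.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Master seed.
#' @param stages Character vector of stages to run, in dependency order
#'   among `"simulate"`, `"qc"`, `"normalize"`, `"stability"`, `"sites"`,
#'   `"energymodel"`, `"epistasis"`.
#' @param n_homologues,n_columns,family Simulation shape and settings
#'   (see [simulate_family()] / [family_config()]).
#' @param epistasis_fraction,epistasis_delta Planted epistasis (0 disables).
#' @param clinical Settings from [clinical_config()].
#' @param fdr_threshold,strong_cut,residual_cut,site_cut,magnitude_cut,lambda
#'   Analysis thresholds (defaults as used throughout the package).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir,
                            seed = 1L,
                            stages = c(
                              "simulate", "qc", "normalize", "stability",
                              "sites", "energymodel", "epistasis"
                            ),
                            n_homologues = 12,
                            n_columns = 40,
                            family = family_config(),
                            epistasis_fraction = 0.05,
                            epistasis_delta = 5,
                            clinical = clinical_config(),
                            fdr_threshold = 0.1,
                            strong_cut = -0.3,
                            residual_cut = 0.3,
                            site_cut = 0.3,
                            magnitude_cut = 0.05,
                            lambda = 1e-4) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Stages execute in dependency order; each writes its outputs as TSV under
#' the configured directory and registers them, with a content hash, in the
#' returned manifest. Re-running with an identical configuration reproduces
#' identical hashes for deterministic stages. Requesting `epistasis`
#' without `energymodel` skips it with an explicit dependency warning.
#'
#' @param config A [pipeline_config()].
#' @return A list with `status` (0 on success), the `manifest` tibble and
#'   the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- tibble::tibble(
    stage = character(), file = character(), hash = character()
  )
  emit <- function(stage, name, df) {
    path <- file.path(config$outdir, name)
    readr::write_tsv(
      dplyr::select(df, !dplyr::where(is.list)), path,
      progress = FALSE
    )
    manifest <<- dplyr::bind_rows(manifest, tibble::tibble(
      stage = stage, file = name,
      hash = rlang::hash(readLines(path))
    ))
  }
  stage_seed <- function(stage) derive_seed(config$seed, stage)
  res <- list()

  jsonlite::write_json(
    config[setdiff(names(config), c("family", "clinical"))],
    file.path(config$outdir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )

  if ("simulate" %in% config$stages) {
    sim <- simulate_family(
      config$n_homologues, config$n_columns,
      config = config$family, seed = stage_seed("simulate")
    )
    if (config$epistasis_fraction > 0) {
      sim <- inject_epistasis(
        sim, config$epistasis_fraction, config$epistasis_delta,
        seed = stage_seed("simulate_epistasis")
      )
    }
    res$sim <- sim
    res$scores <- simulate_evolutionary_scores(
      sim,
      seed = stage_seed("simulate_scores")
    )
    res$annotations <- simulate_clinical_labels(
      sim,
      config = config$clinical, seed = stage_seed("simulate_clinical")
    )
    emit("simulate", "variants.tsv", sim$variants)
    emit("simulate", "scores.tsv", res$scores)
    emit("simulate", "clinical.tsv", res$annotations)
    write_alignment(
      sim$alignment, file.path(config$outdir, "alignment.fasta")
    )
    manifest <- dplyr::bind_rows(manifest, tibble::tibble(
      stage = "simulate", file = "alignment.fasta",
      hash = rlang::hash(readLines(file.path(config$outdir, "alignment.fasta")))
    ))
  }
  if (is.null(res$sim)) {
    abort_foldstab("pipeline currently requires the simulate stage", "pipeline")
  }
  sim <- res$sim

  if ("qc" %in% config$stages) {
    res$metrics <- compute_quality_metrics(sim$variants, sim$domains) |>
      rank_and_filter()
    emit(
      "qc", "qc_metrics.tsv",
      dplyr::mutate(
        res$metrics,
        reasons = purrr::map_chr(.data$reasons, paste, collapse = "; ")
      )
    )
  }
  if ("normalize" %in% config$stages) {
    res$normalized <- normalize_fitness(sim$variants, sim$domains)
    emit("normalize", "normalized.tsv", res$normalized)
  }
  if ("stability" %in% config$stages) {
    if (is.null(res$normalized)) {
      rlang::warn("stability requires normalize; skipping")
    } else {
      res$calls <- call_destabilizing(
        res$normalized,
        fdr_threshold = config$fdr_threshold,
        strong_cut = config$strong_cut
      )
      emit("stability", "stability_calls.tsv", res$calls)
      if (!is.null(res$annotations)) {
        res$class_summary <- summarize_stability_classes(
          res$calls, res$annotations
        )
        emit("stability", "stability_classes.tsv", res$class_summary)
      }
    }
  }
  if ("sites" %in% config$stages) {
    if (is.null(res$normalized) || is.null(res$scores)) {
      rlang::warn("sites requires normalize and scores; skipping")
    } else {
      joined <- dplyr::inner_join(
        res$normalized, res$scores,
        by = variant_keys
      )
      fits <- joined |>
        dplyr::filter(.data$variant_class == "missense") |>
        (\(d) split(d, d$domain_id))() |>
        purrr::map(fit_sigmoid, seed = stage_seed("sites"))
      res$sigmoid_fits <- fits
      res$functional_sites <- purrr::map_dfr(
        fits, call_functional_sites,
        site_cut = config$site_cut
      )
      emit("sites", "functional_sites.tsv", res$functional_sites)
      emit(
        "sites", "sigmoid_params.tsv",
        purrr::map_dfr(fits, \(ft) tibble::tibble(
          domain_id = ft$domain_id, xmid = ft$xmid, scal = ft$scal,
          converged = ft$converged
        ))
      )
    }
  }
  if ("energymodel" %in% config$stages) {
    res$encoding <- encode_family(sim$alignment, sim$domains, sim$variants)
    res$model <- fit_energy_model(
      res$encoding,
      lambda = config$lambda, seed = stage_seed("energymodel")
    )
    model_path <- file.path(config$outdir, "energy_model.json")
    write_energy_model(res$model, model_path)
    manifest <- dplyr::bind_rows(manifest, tibble::tibble(
      stage = "energymodel", file = "energy_model.json",
      hash = rlang::hash(readLines(model_path))
    ))
    emit("energymodel", "scaled_energies.tsv", rescale_energies(res$model))
  }
  if ("epistasis" %in% config$stages) {
    if (is.null(res$model)) {
      rlang::warn("epistasis requires the energymodel stage; skipping")
    } else {
      res$epistasis <- call_epistatic(
        res$model, res$encoding,
        magnitude_cut = config$magnitude_cut,
        fdr = config$fdr_threshold
      )
      emit("epistasis", "epistasis_calls.tsv", res$epistasis)
      site_classes <- classify_sites(sim$alignment, sim$domains)
      if (any(res$epistasis$is_epistatic)) {
        res$site_enrichment <- site_enrichment(res$epistasis, site_classes)
        emit("epistasis", "site_enrichment.tsv", res$site_enrichment)
      }
    }
  }

  readr::write_tsv(manifest, file.path(config$outdir, "manifest.tsv"),
    progress = FALSE
  )
  list(status = 0L, manifest = manifest, results = res)
}
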