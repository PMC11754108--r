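# Held-out evaluation of family energy models: tenfold cross-validation and
# leave-one-homologue-out, with genetic distances of left-out homologues.

#' Tenfold cross-validation of the family energy model
#'
#' Variants are partitioned into folds uniformly at random under the seed;
#' each fold is predicted by a model trained on the remaining folds. The
#' pooled held-out Pearson r is computed on held-out predictions only, and
#' the explainable fraction divides the held-out R-squared by the
#' R-squared between the first two biological replicates.
#'
#' @param encoding A [encode_family()] result.
#' @param lambda,maxit Passed to [fit_energy_model()].
#' @param k Number of folds.
#' @param seed Integer seed; identical seeds give identical fold
#'   assignments.
#' @return A `cv_report`: per-fold held-out r, pooled r, explainable
#'   fraction, replicate R-squared, and the per-variant fold assignment
#'   with held-out predictions.
#' @export
tenfold_cv <- function(encoding, lambda = 1e-4, k = 10, seed = 1L,
                       maxit = 20000) {
  stopifnot(inherits(encoding, "family_encoding"))
  n <- nrow(encoding$variants)
  folds <- withr::with_seed(
    derive_seed(seed, "cv_folds"),
    sample(rep_len(seq_len(k), n))
  )
  pred <- rep(NA_real_, n)
  fold_ok <- logical(k)
  per_fold <- purrr::map_dfr(seq_len(k), function(fold) {
    test <- which(folds == fold)
    train <- which(folds != fold)
    model <- tryCatch(
      fit_energy_model(
        encoding,
        lambda = lambda, maxit = maxit, compute_se = FALSE,
        seed = derive_seed(seed, paste0("cv_fold_", fold)), rows = train
      ),
      error = function(e) NULL
    )
    if (is.null(model) || !model$converged) {
      return(tibble::tibble(fold = fold, n = length(test), r = NA_real_, converged = FALSE))
    }
    fp <- predict_encoding(model, encoding, test)$fitness
    pred[test] <<- fp
    fold_ok[fold] <<- TRUE
    tibble::tibble(
      fold = fold, n = length(test),
      r = stats::cor(encoding$variants$fitness[test], fp),
      converged = TRUE
    )
  })
  held <- !is.na(pred)
  pooled_r <- stats::cor(encoding$variants$fitness[held], pred[held])

  rate_cols <- growth_rate_cols(encoding$variants)
  rep_r2 <- if (length(rate_cols) >= 2) {
    stats::cor(
      encoding$variants[[rate_cols[1]]][held],
      encoding$variants[[rate_cols[2]]][held]
    )^2
  } else {
    NA_real_
  }
  explainable <- pooled_r^2 / rep_r2
  if (is.finite(explainable) && explainable > 1.05) {
    rlang::warn(sprintf(
      "explainable fraction %.3f exceeds 1.05; replicate R-squared may be underestimated",
      explainable
    ))
  }
  structure(
    list(
      per_fold = per_fold,
      pooled_r = pooled_r,
      rep_r2 = rep_r2,
      explainable_fraction = explainable,
      assignment = tibble::tibble(
        fold = folds, observed = encoding$variants$fitness, predicted = pred
      )
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(
    "<cv_report> pooled held-out r =", signif(x$pooled_r, 3),
    " explainable fraction =", signif(x$explainable_fraction, 3), "\n"
  )
  invisible(x)
}

# Pairwise genetic distances over mutually non-gap columns.
blosum62_matrix <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
}

genetic_distances <- function(alignment, left_out, training_ids) {
  B <- blosum62_matrix()
  chars <- lapply(alignment$rows, function(r) strsplit(r, "")[[1]])
  a <- chars[[left_out]]
  dists <- purrr::map_dfr(training_ids, function(id) {
    b <- chars[[id]]
    both <- a != "-" & b != "-"
    aa <- a[both]
    bb <- b[both]
    tibble::tibble(
      hamming = sum(aa != bb),
      blosum_dist = sum(
        (B[cbind(aa, aa)] + B[cbind(bb, bb)]) / 2 - B[cbind(aa, bb)]
      )
    )
  })
  c(
    mean_hamming = mean(dists$hamming),
    mean_blosum_dist = mean(dists$blosum_dist)
  )
}

#' Leave-one-homologue-out evaluation
#'
#' Each homologue is held out entirely; the model is trained on the others
#' and the left-out domain's baseline dG is predicted purely from its
#' wild-type composition through the shared U energies. Performance is the
#' Pearson r between observed and predicted fitness of the left-out
#' variants; the average Hamming and BLOSUM62-derived distances to the
#' training homologues (over mutually non-gap columns) accompany each
#' result.
#'
#' @param encoding A [encode_family()] result.
#' @param lambda,maxit Passed to [fit_energy_model()].
#' @param seed Integer seed.
#' @param min_homologues Required family size (the held-out evaluation is
#'   only meaningful for reasonably large families).
#' @return A tibble with one row per left-out homologue: `r`,
#'   `mean_hamming`, `mean_blosum_dist`, `n_unobserved_columns` and
#'   convergence flag.
#' @export
loho <- function(encoding, lambda = 1e-4, seed = 1L, maxit = 20000,
                 min_homologues = 10) {
  stopifnot(inherits(encoding, "family_encoding"))
  nh <- length(encoding$hom_ids)
  if (nh < min_homologues) {
    abort_foldstab(
      sprintf("family has %d homologues; need at least %d", nh, min_homologues),
      "loho"
    )
  }
  purrr::map_dfr(seq_len(nh), function(h) {
    id <- encoding$hom_ids[h]
    train <- which(encoding$variants$hom_idx != h)
    test <- which(encoding$variants$hom_idx == h)
    model <- tryCatch(
      fit_energy_model(
        encoding,
        lambda = lambda, maxit = maxit, compute_se = FALSE,
        seed = derive_seed(seed, paste0("loho_", id)), rows = train
      ),
      error = function(e) NULL
    )
    dist <- genetic_distances(
      encoding$alignment, id, encoding$hom_ids[-h]
    )
    if (is.null(model) || !model$converged) {
      return(tibble::tibble(
        domain_id = id, r = NA_real_,
        mean_hamming = dist["mean_hamming"],
        mean_blosum_dist = dist["mean_blosum_dist"],
        n_unobserved_columns = NA_integer_, converged = FALSE
      ))
    }
    bl <- homologue_baselines(model, encoding$alignment)
    pred <- predict_encoding(model, encoding, test)$fitness
    tibble::tibble(
      domain_id = id,
      r = stats::cor(encoding$variants$fitness[test], pred),
      mean_hamming = dist["mean_hamming"],
      mean_blosum_dist = dist["mean_blosum_dist"],
      n_unobserved_columns = bl$n_unobserved[bl$domain_id == id],
      converged = TRUE
    )
  })
}

#' Write a family energy model as self-describing text (JSON)
#'
#' All parameters are serialized at full precision; the file records the
#' family id, column count, seed and training-config hash. Reading back a
#' model reproduces its predictions bitwise.
#'
#' @param model A `family_energy_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_energy_model <- function(model, path) {
  stopifnot(inherits(model, "family_energy_model"))
  if (any(!is.finite(c(model$b0, model$gamma0, model$gamma1, model$U, model$D)))) {
    abort_foldstab("model has non-finite parameters; refusing to write", "io")
  }
  flat <- function(m, mask, se = NULL) {
    obs <- which(mask, arr.ind = TRUE)
    out <- list(
      column = unname(obs[, 1]),
      aa = AMINO_ACIDS[obs[, 2]],
      value = unname(m[obs])
    )
    if (!is.null(se)) out$se <- unname(se[obs])
    out
  }
  payload <- list(
    format = "foldstab_energy_model",
    version = model$version,
    family_id = model$family_id,
    columns = model$columns,
    seed = model$seed,
    config_hash = model$config_hash,
    b0 = model$b0,
    gamma0 = model$gamma0,
    gamma1 = model$gamma1,
    rt = model$rt,
    lambda = model$lambda,
    converged = model$converged,
    loss = model$loss,
    train_r = model$train_r,
    ddg_scale = model$ddg_scale,
    U = flat(model$U, model$U_observed),
    D = flat(model$D, model$D_observed, model$se_D),
    hom_baselines = as.list(model$hom_baselines)
  )
  writeLines(
    jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE, na = "null"),
    path
  )
  invisible(path)
}

#' Read a family energy model written by [write_energy_model()]
#'
#' @param path Path to the model file.
#' @return A `family_energy_model`; a version mismatch is an explicit
#'   error, never a silent coercion.
#' @export
read_energy_model <- function(path) {
  payload <- jsonlite::fromJSON(path)
  if (is.null(payload$format) || payload$format != "foldstab_energy_model") {
    abort_foldstab("not a foldstab energy model file", "io")
  }
  if (payload$version != 1L) {
    abort_foldstab(
      sprintf("model file version %s is not supported (expected 1)", payload$version),
      "io"
    )
  }
  L <- payload$columns
  unflat <- function(fl, with_se = FALSE) {
    m <- matrix(0, L, 20, dimnames = list(NULL, AMINO_ACIDS))
    mask <- matrix(FALSE, L, 20, dimnames = list(NULL, AMINO_ACIDS))
    idx <- cbind(fl$column, match(fl$aa, AMINO_ACIDS))
    m[idx] <- fl$value
    mask[idx] <- TRUE
    out <- list(m = m, mask = mask)
    if (with_se && !is.null(fl$se)) {
      se <- matrix(NA_real_, L, 20, dimnames = list(NULL, AMINO_ACIDS))
      se[idx] <- fl$se
      out$se <- se
    }
    out
  }
  U <- unflat(payload$U)
  D <- unflat(payload$D, with_se = TRUE)
  structure(
    list(
      version = as.integer(payload$version),
      family_id = payload$family_id,
      columns = L,
      b0 = payload$b0,
      gamma0 = payload$gamma0,
      gamma1 = payload$gamma1,
      rt = payload$rt,
      U = U$m, U_observed = U$mask,
      D = D$m, D_observed = D$mask,
      se_D = D$se,
      lambda = payload$lambda,
      seed = payload$seed,
      converged = payload$converged,
      iterations = NA_integer_,
      loss = payload$loss,
      train_r = payload$train_r,
      config_hash = payload$config_hash,
      ddg_scale = payload$ddg_scale %||% NA_real_,
      hom_baselines = unlist(payload$hom_baselines)
    ),
    class = "family_energy_model"
  )
}
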