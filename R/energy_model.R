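# Family energy models: a two-state Boltzmann thermodynamic model fitted
# jointly across homologous domains. Each variant's folding free energy is
# the sum of a family intercept, the wild-type composition energies of its
# homologue (shared per alignment column and residue) and one shared
# mutation energy (ddG) per (column, mutant) pair; fitness is an affine map
# of the Boltzmann fraction folded. Energies are in RT units (RT = 1).

#' Encode a family's variants against its alignment
#'
#' Each variant activates the wild-type identity features of its homologue
#' (one `(column, residue)` feature per non-gap column) and, for missense
#' variants, a single mutation feature `(column, mutant)` shared across
#' homologues. Gap columns contribute no features; synonymous variants carry
#' the wild-type trait only. Nonsense variants and variants failing the
#' mean-count filter are excluded from fitting.
#'
#' @param alignment A [family_alignment()] covering all domains.
#' @param domains Domain tibble (`domain_id`, `sequence`).
#' @param variants Variant tibble with `fitness`, `sigma` and optional
#'   replicate columns.
#' @param min_mean_count Variants with mean read count not exceeding this
#'   are dropped (no count columns: no filter).
#' @return A `family_encoding`: the filtered variant table with alignment
#'   columns and feature indices, the feature tables, and the
#'   homologue-by-feature indicator matrix.
#' @export
encode_family <- function(alignment, domains, variants, min_mean_count = 29) {
  stopifnot(inherits(alignment, "family_alignment"))
  hom_ids <- names(alignment$rows)
  v <- variants[variants$domain_id %in% hom_ids, ]
  if (!nrow(v)) abort_foldstab("no variants for the alignment's domains", "encode")

  cnt_cols <- count_cols(v)
  if (length(cnt_cols)) {
    mean_counts <- rowMeans(as.matrix(v[, cnt_cols]))
    v <- v[mean_counts > min_mean_count, ]
  }
  v <- v[v$variant_class != "nonsense" & is.finite(v$fitness), ]

  v$hom_idx <- match(v$domain_id, hom_ids)
  maps <- alignment$column_map[hom_ids]
  lens <- lengths(maps)
  if (any(v$position < 1 | v$position > lens[v$hom_idx])) {
    bad <- which(v$position < 1 | v$position > lens[v$hom_idx])[1]
    abort_foldstab(
      sprintf(
        "variant %s:%d does not map to a non-gap alignment column",
        v$domain_id[bad], v$position[bad]
      ),
      "encode"
    )
  }
  v$column <- vapply(
    seq_len(nrow(v)),
    function(i) maps[[v$hom_idx[i]]][v$position[i]],
    integer(1)
  )
  relabel <- v$variant_class == "missense" & v$mut_aa == v$wt_aa
  if (any(relabel)) {
    rlang::warn(sprintf(
      "%d variant(s) identical to wild type at alignment level; treated as synonymous",
      sum(relabel)
    ))
    v$variant_class[relabel] <- "synonymous"
  }

  # wild-type identity features per homologue
  hom_feats <- purrr::map_dfr(seq_along(hom_ids), function(h) {
    res <- strsplit(ungap_row(alignment$rows[h]), "")[[1]]
    tibble::tibble(
      hom_idx = h, column = maps[[h]], aa = res
    )
  })
  u_feats <- dplyr::distinct(hom_feats[, c("column", "aa")]) |>
    dplyr::arrange(.data$column, .data$aa)
  u_feats$idx <- seq_len(nrow(u_feats))

  H <- matrix(0, length(hom_ids), nrow(u_feats))
  hf <- dplyr::left_join(hom_feats, u_feats, by = c("column", "aa"))
  H[cbind(hf$hom_idx, hf$idx)] <- 1

  mis <- v$variant_class == "missense"
  d_feats <- dplyr::distinct(
    tibble::tibble(column = v$column[mis], aa = v$mut_aa[mis])
  ) |>
    dplyr::arrange(.data$column, .data$aa)
  d_feats$idx <- seq_len(nrow(d_feats))
  v$d_idx <- NA_integer_
  v$d_idx[mis] <- d_feats$idx[match(
    paste(v$column[mis], v$mut_aa[mis]),
    paste(d_feats$column, d_feats$aa)
  )]

  structure(
    list(
      family_id = alignment$family_id,
      alignment = alignment,
      hom_ids = hom_ids,
      variants = v,
      u_feats = u_feats,
      d_feats = d_feats,
      H = H,
      n_columns = alignment$columns
    ),
    class = "family_encoding"
  )
}

#' @export
print.family_encoding <- function(x, ...) {
  cat(
    "<family_encoding> ", x$family_id, ": ", length(x$hom_ids),
    " homologues, ", nrow(x$variants), " variants, ",
    nrow(x$u_feats), " composition + ", nrow(x$d_feats),
    " mutation features\n",
    sep = ""
  )
  invisible(x)
}

# Core objective/gradient machinery shared by fit and restarts.
# Per-variant variances estimated from few replicates are heavy-tailed;
# `moderation` shrinks each variance toward the family median before
# inverse-variance weighting (0 = raw weights, 1 = uniform-ish), the usual
# empirical-Bayes stabilization for deep mutational scanning errors.
energy_loss_fns <- function(enc, rows, lambda, moderation = 0.5,
                            w_extra = NULL) {
  v <- enc$variants[rows, ]
  f <- v$fitness
  s2 <- (1 - moderation) * v$sigma^2 +
    moderation * stats::median(v$sigma)^2
  w <- 1 / s2
  if (!is.null(w_extra)) w <- w * w_extra
  hom <- v$hom_idx
  didx <- v$d_idx
  mis <- which(!is.na(didx))
  dmis <- didx[mis]
  H <- enc$H
  nU <- nrow(enc$u_feats)
  nD <- nrow(enc$d_feats)
  nh <- nrow(H)

  unpack <- function(par) {
    list(
      b0 = par[1], g0 = par[2], g1 = par[3],
      thU = par[3 + seq_len(nU)], thD = par[3 + nU + seq_len(nD)]
    )
  }
  forward <- function(pp) {
    base <- as.vector(H %*% pp$thU)
    dg <- pp$b0 + base[hom]
    dg[mis] <- dg[mis] + pp$thD[dmis]
    p <- stats::plogis(-dg)
    list(dg = dg, p = p, pred = pp$g0 + pp$g1 * p)
  }
  obj <- function(par) {
    pp <- unpack(par)
    fw <- forward(pp)
    sum(w * (f - fw$pred)^2) +
      lambda * (sum(pp$thU^2) + sum(pp$thD^2))
  }
  grad <- function(par) {
    pp <- unpack(par)
    fw <- forward(pp)
    r <- f - fw$pred
    dldpred <- -2 * w * r
    dg0 <- sum(dldpred)
    dg1 <- sum(dldpred * fw$p)
    dlddg <- dldpred * pp$g1 * (-fw$p * (1 - fw$p))
    db0 <- sum(dlddg)
    ghom <- numeric(nh)
    rs <- rowsum(dlddg, hom)
    ghom[as.integer(rownames(rs))] <- rs
    gU <- as.vector(crossprod(H, ghom)) + 2 * lambda * pp$thU
    gD <- 2 * lambda * pp$thD
    if (length(mis)) {
      rsd <- rowsum(dlddg[mis], dmis)
      gD[as.integer(rownames(rsd))] <-
        gD[as.integer(rownames(rsd))] + rsd
    }
    c(db0, dg0, dg1, gU, gD)
  }
  list(
    obj = obj, grad = grad, unpack = unpack, forward = forward,
    f = f, w = w, s2 = s2, hom = hom, didx = didx, nU = nU, nD = nD
  )
}

#' Fit the family energy model
#'
#' Minimizes the error-weighted least squares between observed fitness and
#' `gamma0 + gamma1 * p_f(dG)` with an L2 penalty `lambda` on the
#' composition (U) and mutation (D) energies, by L-BFGS-B with analytic
#' gradients. Energies are randomly initialized under `seed`; `gamma1`
#' starts at the observed fitness range and is bounded positive. After
#' fitting, each alignment column covered by every homologue has its U
#' energies centred on the residues observed there, with the shift absorbed
#' into the family intercept, making the reported parameterization unique
#' without changing any prediction. Features with no data support are zeroed
#' and marked unobserved.
#'
#' @param encoding A [encode_family()] result.
#' @param lambda L2 regularization weight on U and D (0 = unregularized).
#' @param seed Integer seed for initialization.
#' @param maxit Maximum optimizer iterations.
#' @param max_restarts Seeded re-initializations attempted when the
#'   optimizer fails or `gamma1` collapses.
#' @param moderation Fraction by which each per-variant variance is shrunk
#'   toward the family median variance before inverse-variance weighting;
#'   stabilizes weights built from few-replicate error estimates.
#' @param robust_iterations Number of Huber-type reweighting passes after
#'   the initial fit (residuals beyond 3 standard errors are downweighted
#'   and the model refit, warm-started); keeps isolated epistatic outliers
#'   from distorting the shared energies. 0 disables.
#' @param compute_se Whether to compute approximate standard errors of the
#'   mutation energies from the weighted least-squares curvature
#'   (Gauss-Newton) at the optimum.
#' @param rows Optional integer subset of encoding variants to train on
#'   (used by cross-validation).
#' @return A `family_energy_model` with `b0`, `gamma0`, `gamma1`, energy
#'   matrices `U` and `D` (with observation masks), per-homologue
#'   baselines, convergence status and training correlation.
#' @export
fit_energy_model <- function(encoding, lambda = 1e-4, seed = 1L,
                             maxit = 200000, max_restarts = 5,
                             compute_se = TRUE, rows = NULL,
                             moderation = 0.5, robust_iterations = 1) {
  stopifnot(inherits(encoding, "family_encoding"))
  rows <- rows %||% seq_len(nrow(encoding$variants))
  fns <- energy_loss_fns(encoding, rows, lambda, moderation)
  nU <- fns$nU
  nD <- fns$nD
  f <- fns$f

  lower <- c(-Inf, -Inf, 1e-6, rep(-Inf, nU + nD))
  warm <- energy_warm_start(encoding, rows)
  fit <- NULL
  for (attempt in seq_len(max_restarts + 1L)) {
    init <- withr::with_seed(
      derive_seed(seed, paste0("energy_init_", attempt)),
      warm + c(
        0, 0, 0,
        stats::rnorm(nU + nD, 0, 0.1 * attempt)
      )
    )
    res <- tryCatch(
      stats::optim(
        init, fns$obj, fns$grad,
        method = "L-BFGS-B", lower = lower,
        control = list(maxit = maxit, factr = 1e7)
      ),
      error = function(e) NULL
    )
    ok <- !is.null(res) && res$convergence == 0 && res$par[3] > 1e-5
    if (ok) {
      fit <- res
      break
    }
    if (!is.null(res) && (is.null(fit) || res$value < fit$value)) fit <- res
  }
  if (is.null(fit)) {
    abort_foldstab("energy model optimization failed on all restarts", "energy")
  }

  # Huber-type reweighting: refit with large standardized residuals
  # downweighted so isolated epistatic outliers cannot distort the shared
  # additive energies they sit on.
  for (it in seq_len(robust_iterations)) {
    pp0 <- fns$unpack(fit$par)
    zres <- (fns$f - fns$forward(pp0)$pred) / sqrt(fns$s2)
    w_extra <- pmin(1, 3 / pmax(abs(zres), 1e-12))^2
    if (all(w_extra > 0.999)) break
    fns_r <- energy_loss_fns(encoding, rows, lambda, moderation, w_extra)
    res_r <- tryCatch(
      stats::optim(
        fit$par, fns_r$obj, fns_r$grad,
        method = "L-BFGS-B", lower = lower,
        control = list(maxit = maxit, factr = 1e7)
      ),
      error = function(e) NULL
    )
    if (!is.null(res_r) && res_r$par[3] > 1e-5) fit <- res_r
  }

  converged <- fit$convergence == 0 && fit$par[3] > 1e-5
  pp <- fns$unpack(fit$par)

  # zero out features with no data support
  v <- encoding$variants[rows, ]
  u_support <- sort(unique(unlist(
    lapply(unique(v$hom_idx), function(h) which(encoding$H[h, ] == 1))
  )))
  d_support <- sort(unique(v$d_idx[!is.na(v$d_idx)]))
  pp$thU[setdiff(seq_len(nU), u_support)] <- 0
  pp$thD[setdiff(seq_len(nD), d_support)] <- 0

  # gauge fix: centre U per fully covered column, absorbing shifts into b0
  col_cov <- vapply(
    seq_len(encoding$n_columns),
    function(cc) sum(vapply(
      encoding$alignment$column_map,
      function(m) cc %in% m, logical(1)
    )),
    numeric(1)
  )
  full_cols <- which(col_cov == length(encoding$hom_ids))
  for (cc in full_cols) {
    feats <- encoding$u_feats$idx[encoding$u_feats$column == cc &
      encoding$u_feats$idx %in% u_support]
    if (!length(feats)) next
    m <- mean(pp$thU[feats])
    pp$thU[feats] <- pp$thU[feats] - m
    pp$b0 <- pp$b0 + m
  }

  L <- encoding$n_columns
  U <- matrix(0, L, 20, dimnames = list(NULL, AMINO_ACIDS))
  U_observed <- matrix(FALSE, L, 20, dimnames = list(NULL, AMINO_ACIDS))
  uo <- encoding$u_feats[encoding$u_feats$idx %in% u_support, ]
  U[cbind(uo$column, match(uo$aa, AMINO_ACIDS))] <- pp$thU[uo$idx]
  U_observed[cbind(uo$column, match(uo$aa, AMINO_ACIDS))] <- TRUE
  D <- matrix(0, L, 20, dimnames = list(NULL, AMINO_ACIDS))
  D_observed <- matrix(FALSE, L, 20, dimnames = list(NULL, AMINO_ACIDS))
  do_ <- encoding$d_feats[encoding$d_feats$idx %in% d_support, ]
  D[cbind(do_$column, match(do_$aa, AMINO_ACIDS))] <- pp$thD[do_$idx]
  D_observed[cbind(do_$column, match(do_$aa, AMINO_ACIDS))] <- TRUE

  se_D <- NULL
  if (compute_se && converged) {
    se <- energy_model_se(encoding, rows, pp, lambda, moderation)
    se_D <- matrix(NA_real_, L, 20, dimnames = list(NULL, AMINO_ACIDS))
    se_D[cbind(do_$column, match(do_$aa, AMINO_ACIDS))] <-
      se$d[do_$idx]
  }

  model <- structure(
    list(
      version = 1L,
      family_id = encoding$family_id,
      columns = L,
      b0 = pp$b0,
      gamma0 = pp$g0,
      gamma1 = pp$g1,
      rt = 1,
      U = U, U_observed = U_observed,
      D = D, D_observed = D_observed,
      se_D = se_D,
      lambda = lambda,
      seed = seed,
      converged = converged,
      iterations = fit$counts[1],
      loss = fit$value,
      config_hash = rlang::hash(list(lambda, maxit, seed)),
      ddg_scale = NA_real_
    ),
    class = "family_energy_model"
  )
  pred <- predict_encoding(model, encoding, rows)
  model$train_r <- stats::cor(encoding$variants$fitness[rows], pred$fitness)
  model$hom_baselines <- stats::setNames(
    homologue_baselines(model, encoding$alignment)$dg_wt,
    encoding$hom_ids
  )
  model
}

# Data-driven warm start: invert the affine and Boltzmann maps per variant
# (with the fraction folded clipped away from the plateaus), estimate each
# homologue's baseline from its least-destabilized variants, seed U with the
# minimum-norm composition solution and D with per-feature mean excess
# energies. Starting inside the responsive region of the sigmoid avoids the
# saturation local optima that random initialization falls into when a
# homologue's baseline drifts onto a flat plateau.
energy_warm_start <- function(enc, rows) {
  v <- enc$variants[rows, ]
  nU <- nrow(enc$u_feats)
  nD <- nrow(enc$d_feats)
  nh <- nrow(enc$H)
  g0 <- stats::quantile(v$fitness, 0.01, names = FALSE)
  g1 <- max(stats::quantile(v$fitness, 0.995, names = FALSE) - g0, 1e-3)
  phat <- pmin(pmax((v$fitness - g0) / g1, 0.02), 0.98)
  dg_i <- -stats::qlogis(phat)
  bh <- rep(0, nh)
  est <- tapply(dg_i, v$hom_idx, stats::quantile, probs = 0.1, names = FALSE)
  bh[as.integer(names(est))] <- est
  b0 <- mean(bh)
  H <- enc$H
  thU <- as.vector(crossprod(
    H, solve(tcrossprod(H) + 1e-6 * diag(nh), bh - b0)
  ))
  thD <- rep(1, nD)
  mis <- which(!is.na(v$d_idx))
  excess <- dg_i[mis] - bh[v$hom_idx[mis]]
  dm <- tapply(excess, v$d_idx[mis], mean)
  thD[as.integer(names(dm))] <- dm
  c(b0, g0, g1, thU, thD)
}

# Approximate parameter standard errors from the Gauss-Newton curvature of
# the weighted least-squares objective at the optimum.
energy_model_se <- function(enc, rows, pp, lambda, moderation = 0.5) {
  v <- enc$variants[rows, ]
  w <- 1 / ((1 - moderation) * v$sigma^2 +
    moderation * stats::median(v$sigma)^2)
  hom <- v$hom_idx
  didx <- v$d_idx
  nU <- nrow(enc$u_feats)
  nD <- nrow(enc$d_feats)
  base <- as.vector(enc$H %*% pp$thU)
  dg <- pp$b0 + base[hom]
  mis <- which(!is.na(didx))
  dg[mis] <- dg[mis] + pp$thD[didx[mis]]
  p <- stats::plogis(-dg)
  a <- -pp$g1 * p * (1 - p) # dpred / ddG

  n <- nrow(v)
  # Jacobian columns: b0, g0, g1, U block, D block
  Hl <- lapply(seq_len(nrow(enc$H)), function(h) which(enc$H[h, ] == 1))
  u_j <- Hl[hom]
  J <- Matrix::sparseMatrix(
    i = c(
      seq_len(n), seq_len(n), seq_len(n),
      rep(seq_len(n), lengths(u_j)),
      mis
    ),
    j = c(
      rep(1L, n), rep(2L, n), rep(3L, n),
      3L + unlist(u_j),
      3L + nU + didx[mis]
    ),
    x = c(
      a, rep(1, n), p,
      rep(a, lengths(u_j)),
      a[mis]
    ),
    dims = c(n, 3L + nU + nD)
  )
  A <- Matrix::crossprod(J * sqrt(w)) +
    Matrix::Diagonal(
      3L + nU + nD,
      c(rep(1e-8, 3), rep(2 * lambda + 1e-8, nU + nD))
    )
  cov <- tryCatch(
    Matrix::solve(A),
    error = function(e) NULL
  )
  if (is.null(cov)) {
    return(list(d = rep(NA_real_, nD)))
  }
  dv <- Matrix::diag(cov)
  list(d = sqrt(pmax(dv[3L + nU + seq_len(nD)], 0)))
}

# Baselines (wild-type dG) for each alignment row through the model's
# composition energies; counts residues unobserved during training.
homologue_baselines <- function(model, alignment) {
  purrr::map_dfr(names(alignment$rows), function(id) {
    row <- alignment$rows[[id]]
    cols <- alignment$column_map[[id]]
    res <- strsplit(ungap_row(row), "")[[1]]
    ri <- match(res, AMINO_ACIDS)
    observed <- model$U_observed[cbind(cols, ri)]
    tibble::tibble(
      domain_id = id,
      dg_wt = model$b0 + sum(model$U[cbind(cols, ri)]),
      n_unobserved = sum(!observed)
    )
  })
}

# Predictions for (a subset of) an encoding's variants.
predict_encoding <- function(model, encoding, rows = NULL) {
  rows <- rows %||% seq_len(nrow(encoding$variants))
  v <- encoding$variants[rows, ]
  bl <- homologue_baselines(model, encoding$alignment)
  base <- stats::setNames(bl$dg_wt, bl$domain_id)
  dg <- unname(base[v$domain_id])
  mis <- !is.na(v$d_idx)
  dg[mis] <- dg[mis] +
    model$D[cbind(v$column[mis], match(v$mut_aa[mis], AMINO_ACIDS))]
  p <- stats::plogis(-dg)
  tibble::tibble(
    dg = dg, p_f = p, fitness = model$gamma0 + model$gamma1 * p
  )
}

#' Predict fitness for the variants of a family encoding
#'
#' @param object A fitted `family_energy_model`.
#' @param encoding The [encode_family()] result to predict (typically the
#'   training family; homologue baselines are recomputed from the alignment
#'   through the composition energies).
#' @param type `"fitness"` (default), `"dg"` or `"p_f"`.
#' @param ... Unused.
#' @return A numeric vector aligned with `encoding$variants`.
#' @export
predict.family_energy_model <- function(object, encoding,
                                        type = c("fitness", "dg", "p_f"),
                                        ...) {
  type <- match.arg(type)
  predict_encoding(object, encoding)[[type]]
}

#' @export
print.family_energy_model <- function(x, ...) {
  cat(
    "<family_energy_model> ", x$family_id, ": ", x$columns, " columns, ",
    sum(x$D_observed), " mutation energies; train r = ",
    signif(x$train_r, 3),
    if (x$converged) " (converged)\n" else " (NOT converged)\n",
    sep = ""
  )
  invisible(x)
}

#' Rescale mutation energies to the comparative ddG scale
#'
#' Energies are rescaled so the wild type sits at 0 and the 2.5th percentile
#' of the fitness-oriented energy distribution maps to -1; the output is
#' reported with the destabilizing-positive orientation, so a scaled ddG
#' above 0.3 marks strong predicted destabilization. The orientation
#' (physical sign flipped to fitness-like for the percentile, then back)
#' is recorded in the attributes.
#'
#' @param model A converged `family_energy_model`.
#' @return A tibble of observed mutation energies (`column`, `mut_aa`,
#'   `ddg`, `scaled_ddg`, and standard errors when available) with
#'   attributes `scale` and `orientation`.
#' @export
rescale_energies <- function(model) {
  stopifnot(inherits(model, "family_energy_model"))
  if (!model$converged) {
    abort_foldstab("model did not converge; refusing to rescale", "energy")
  }
  obs <- which(model$D_observed, arr.ind = TRUE)
  d <- model$D[obs]
  oriented <- -d # fitness-like: destabilizing mutations negative
  q <- stats::quantile(oriented, 0.025, names = FALSE)
  scale <- abs(q)
  if (!is.finite(scale) || scale == 0) {
    abort_foldstab("degenerate energy distribution; cannot rescale", "energy")
  }
  out <- tibble::tibble(
    column = obs[, 1],
    mut_aa = AMINO_ACIDS[obs[, 2]],
    ddg = d,
    scaled_ddg = d / scale
  )
  if (!is.null(model$se_D)) {
    out$se <- model$se_D[obs]
    out$scaled_se <- out$se / scale
  }
  attr(out, "scale") <- scale
  attr(out, "orientation") <- "positive = destabilizing"
  out
}

energy_scale <- function(model) {
  if (is.finite(model$ddg_scale)) {
    return(model$ddg_scale)
  }
  attr(rescale_energies(model), "scale")
}

#' Predict stability effects for an unseen aligned homologue
#'
#' The homologue's baseline dG comes from its wild-type composition through
#' the model's U energies (columns whose residue was never observed in
#' training contribute the column-centred mean, 0, with a coverage warning);
#' each variant adds its shared mutation energy. Destabilization calls use a
#' one-tailed z-test on the scaled ddG with the inference standard errors,
#' Benjamini-Hochberg corrected.
#'
#' @param model A converged `family_energy_model` (fit with
#'   `compute_se = TRUE` for calls).
#' @param alignment_row Gapped wild-type row over the model's columns.
#' @param variants Tibble with `position`, `wt_aa`, `mut_aa` (positions in
#'   the ungapped homologue sequence).
#' @param fdr FDR level for destabilization calls.
#' @param strong_cut Scaled-ddG threshold for strong destabilization.
#' @return The variants with predicted `dg`, `p_f`, `fitness`,
#'   `scaled_ddg`, `q` and logical `destabilizing` / `strong` calls;
#'   the baseline dG and unobserved-column count are attributes.
#' @export
predict_new_homologue <- function(model, alignment_row, variants,
                                  fdr = 0.1, strong_cut = 0.3) {
  stopifnot(inherits(model, "family_energy_model"))
  alignment_row <- gsub(".", "-", alignment_row, fixed = TRUE)
  if (nchar(alignment_row) != model$columns) {
    abort_foldstab(
      sprintf(
        "alignment row has %d columns; model expects %d",
        nchar(alignment_row), model$columns
      ),
      "predict"
    )
  }
  cols <- which(strsplit(alignment_row, "")[[1]] != "-")
  res <- strsplit(ungap_row(alignment_row), "")[[1]]
  ri <- match(res, AMINO_ACIDS)
  observed <- model$U_observed[cbind(cols, ri)]
  if (any(!observed)) {
    rlang::warn(sprintf(
      "%d column(s) carry wild-type residues unobserved in training; their composition energy is taken as the column mean (0)",
      sum(!observed)
    ))
  }
  baseline <- model$b0 + sum(model$U[cbind(cols, ri)])

  v <- variants
  if (any(v$position < 1 | v$position > length(res))) {
    abort_foldstab("variant position outside the aligned sequence", "predict")
  }
  if (any(v$wt_aa != res[v$position])) {
    abort_foldstab("variant wt_aa disagrees with the alignment row", "predict")
  }
  v$column <- cols[v$position]
  is_mut <- v$mut_aa != v$wt_aa
  mi <- match(v$mut_aa, AMINO_ACIDS)
  d <- ifelse(is_mut, model$D[cbind(v$column, mi)], 0)
  d_obs <- ifelse(is_mut, model$D_observed[cbind(v$column, mi)], TRUE)
  scale <- energy_scale(model)

  v$dg <- baseline + d
  v$p_f <- stats::plogis(-v$dg)
  v$fitness_pred <- model$gamma0 + model$gamma1 * v$p_f
  v$scaled_ddg <- d / scale
  v$ddg_observed <- d_obs
  if (!is.null(model$se_D)) {
    se <- ifelse(is_mut, model$se_D[cbind(v$column, mi)], NA_real_)
    z <- d / se
    p <- stats::pnorm(z, lower.tail = FALSE)
    p[!is_mut] <- 1
    v$q <- bh_adjust(p)
    v$destabilizing <- v$q < fdr & v$scaled_ddg > 0
    v$strong <- v$destabilizing & v$scaled_ddg > strong_cut
    v$destabilizing[!is_mut | is.na(v$destabilizing)] <- FALSE
    v$strong[!is_mut | is.na(v$strong)] <- FALSE
  }
  attr(v, "baseline_dg") <- baseline
  attr(v, "n_unobserved_columns") <- sum(!observed)
  v
}
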