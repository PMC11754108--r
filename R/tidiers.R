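# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    term = c("xmid", "scal"),
    estimate = c(x$xmid, x$scal)
  )
}

#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    domain_id = x$domain_id,
    xmid = x$xmid,
    scal = x$scal,
    converged = x$converged,
    loss = x$loss,
    nobs = nrow(x$data)
  )
}

#' @export
tidy.family_energy_model <- function(x, ...) {
  obs <- which(x$D_observed, arr.ind = TRUE)
  energies <- tibble::tibble(
    term = "ddg",
    column = obs[, 1],
    aa = AMINO_ACIDS[obs[, 2]],
    estimate = x$D[obs],
    std_error = if (!is.null(x$se_D)) x$se_D[obs] else NA_real_
  )
  obs_u <- which(x$U_observed, arr.ind = TRUE)
  comp <- tibble::tibble(
    term = "composition",
    column = obs_u[, 1],
    aa = AMINO_ACIDS[obs_u[, 2]],
    estimate = x$U[obs_u],
    std_error = NA_real_
  )
  dplyr::bind_rows(energies, comp)
}

#' @export
glance.family_energy_model <- function(x, ...) {
  tibble::tibble(
    family_id = x$family_id,
    b0 = x$b0,
    gamma0 = x$gamma0,
    gamma1 = x$gamma1,
    lambda = x$lambda,
    converged = x$converged,
    loss = x$loss,
    train_r = x$train_r,
    n_energies = sum(x$D_observed)
  )
}

#' @export
tidy.classifier_eval <- function(x, ...) {
  tibble::tibble(
    term = names(x$confusion),
    count = as.numeric(x$confusion)
  )
}

#' @export
glance.classifier_eval <- function(x, ...) {
  tibble::tibble(
    mcc = x$mcc, mcc_sd = x$mcc_sd, auc = x$auc, n = x$n,
    positive_rule = x$positive_rule
  )
}

#' @export
tidy.cv_report <- function(x, ...) x$per_fold

#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    pooled_r = x$pooled_r,
    rep_r2 = x$rep_r2,
    explainable_fraction = x$explainable_fraction,
    n_folds = nrow(x$per_fold)
  )
}
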