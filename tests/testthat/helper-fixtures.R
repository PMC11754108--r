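# Shared fixtures, computed once per test run. The default family matches
# the generator's study conditions (12 homologues x 40 columns); the small
# family keeps unit tests fast.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_sim <- function() {
  fixture("default_sim", simulate_family(12, 40, seed = 7))
}

default_encoding <- function() {
  fixture("default_encoding", {
    sim <- default_sim()
    encode_family(sim$alignment, sim$domains, sim$variants)
  })
}

default_model <- function() {
  fixture("default_model", fit_energy_model(default_encoding(), seed = 4))
}

small_sim <- function() {
  fixture("small_sim", simulate_family(6, 15, seed = 11))
}

small_encoding <- function() {
  fixture("small_encoding", {
    sim <- small_sim()
    encode_family(sim$alignment, sim$domains, sim$variants)
  })
}

default_normalized <- function() {
  fixture("default_normalized", {
    sim <- default_sim()
    suppressWarnings(normalize_fitness(sim$variants, sim$domains))
  })
}

default_scores <- function() {
  fixture("default_scores", simulate_evolutionary_scores(default_sim(), seed = 8))
}

# Family energy model assembled directly from generator truth, for
# calibration tests where the model must be exactly correct.
truth_model <- function(sim) {
  L <- sim$alignment$columns
  structure(
    list(
      version = 1L,
      family_id = sim$truth$family_id,
      columns = L,
      b0 = sim$truth$b0,
      gamma0 = sim$truth$gamma0,
      gamma1 = sim$truth$gamma1,
      rt = 1,
      U = sim$truth$U_true,
      U_observed = matrix(TRUE, L, 20, dimnames = list(NULL, AMINO_ACIDS)),
      D = sim$truth$D_true,
      D_observed = matrix(TRUE, L, 20, dimnames = list(NULL, AMINO_ACIDS)),
      se_D = NULL,
      lambda = 0,
      seed = NA_integer_,
      converged = TRUE,
      iterations = 0L,
      loss = NA_real_,
      train_r = NA_real_,
      config_hash = "truth",
      ddg_scale = NA_real_
    ),
    class = "family_energy_model"
  )
}

# Confusion-table fixture: calls and annotations realizing given counts.
confusion_fixture <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  cls <- c(
    rep("strong", tp + fp),
    rep("stable", tn + fn)
  )
  label <- c(
    rep("pathogenic", tp), rep("benign", fp),
    rep("benign", tn), rep("pathogenic", fn)
  )
  keys <- tibble::tibble(
    domain_id = "d1", position = seq_len(n),
    wt_aa = "A", mut_aa = "V"
  )
  list(
    calls = dplyr::bind_cols(keys, tibble::tibble(stability_class = cls)),
    annotations = dplyr::bind_cols(
      keys,
      tibble::tibble(label = label, allele_frequency = NA_real_)
    )
  )
}
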