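# Family encoding and the two-state Boltzmann energy model.

test_that("encoding activates composition and shared mutation features", {
  aln <- family_alignment(c(h1 = "ACD", h2 = "AFD"), "fam")
  doms <- tibble::tibble(domain_id = c("h1", "h2"), sequence = c("ACD", "AFD"))
  v <- tibble::tibble(
    domain_id = c("h1", "h2", "h1"),
    position = c(2L, 2L, 1L),
    wt_aa = c("C", "F", "A"),
    mut_aa = c("G", "G", "A"),
    variant_class = c("missense", "missense", "synonymous"),
    fitness = c(0.2, 0.25, 0.4),
    sigma = 0.01
  )
  enc <- encode_family(aln, doms, v)
  # distinct wild types at column 2, shared elsewhere
  expect_equal(nrow(enc$u_feats), 4)
  # the same (column, mutant) in both homologues is one shared feature
  expect_equal(enc$variants$d_idx[1], enc$variants$d_idx[2])
  # synonymous variants carry no mutation feature
  expect_true(is.na(enc$variants$d_idx[3]))
  # identical alignment rows imply identical composition features
  aln2 <- family_alignment(c(h1 = "ACD", h2 = "ACD"), "fam")
  doms2 <- tibble::tibble(domain_id = c("h1", "h2"), sequence = "ACD")
  enc2 <- encode_family(aln2, doms2, v[3, ])
  expect_equal(enc2$H[1, ], enc2$H[2, ])
  # positions outside the aligned sequence are hard errors
  expect_error(
    encode_family(aln, doms, dplyr::mutate(v, position = 9L)),
    class = "foldstab_encode"
  )
})

test_that("the mean-count filter drops low-coverage variants", {
  sim <- small_sim()
  v <- sim$variants
  v$count_1[1] <- 0L
  v$count_2[1] <- 0L
  v$count_3[1] <- 0L
  enc <- encode_family(sim$alignment, sim$domains, v)
  expect_equal(nrow(enc$variants), nrow(v) - 1)
})

test_that("a noise-free family is recovered almost exactly", {
  cfg <- family_config(noise_sigma = 0)
  sim <- simulate_family(8, 15, config = cfg, seed = 21)
  sim$variants$sigma <- 1 # uniform weights
  enc <- encode_family(sim$alignment, sim$domains, sim$variants)
  m <- fit_energy_model(enc, lambda = 0, seed = 2)
  expect_true(m$converged)
  expect_gte(m$train_r, 0.999)
  obs <- which(m$D_observed, arr.ind = TRUE)
  expect_gte(stats::cor(m$D[obs], sim$truth$D_true[obs]), 0.99)
})

test_that("rescaling the errors leaves the optimum unchanged", {
  enc <- small_encoding()
  m1 <- fit_energy_model(enc, seed = 2, compute_se = FALSE)
  enc2 <- enc
  enc2$variants$sigma <- enc$variants$sigma * 2
  m2 <- fit_energy_model(enc2, seed = 2, compute_se = FALSE)
  # weakly constrained (near-plateau) parameters can drift along flat
  # directions, but the fitted map is unchanged
  expect_equal(predict(m1, enc), predict(m2, enc2), tolerance = 5e-3)
  expect_equal(m1$train_r, m2$train_r, tolerance = 1e-4)
})

test_that("the model is gauge-invariant and the centring is prediction-preserving", {
  enc <- small_encoding()
  m <- fixture("small_model", fit_energy_model(enc, seed = 2))
  pred <- predict(m, enc)
  shifted <- m
  cc <- 3
  obs <- shifted$U_observed[cc, ]
  shifted$U[cc, obs] <- shifted$U[cc, obs] + 0.7
  shifted$b0 <- shifted$b0 - 0.7
  expect_equal(predict(shifted, enc), pred, tolerance = 1e-12)
  # reported parameterization is centred per fully covered column
  for (col in seq_len(m$columns)) {
    vals <- m$U[col, m$U_observed[col, ]]
    if (length(vals)) expect_equal(mean(vals), 0, tolerance = 1e-8)
  }
})

test_that("predictions are bounded by the affine output map", {
  enc <- small_encoding()
  m <- fixture("small_model", fit_energy_model(enc, seed = 2))
  pred <- predict(m, enc)
  expect_true(all(pred >= m$gamma0 - 1e-12))
  expect_true(all(pred <= m$gamma0 + m$gamma1 + 1e-12))
})

test_that("the near-linear regime agrees with a weighted linear model", {
  cfg <- family_config(
    noise_sigma = 0, u_sd = 0.02, temperature = 1,
    d_mean_core = 0.05, d_mean_surface = 0.02, d_sd = 0.03,
    dg_wt_mean = 0
  )
  sim <- simulate_family(6, 10, config = cfg, seed = 31)
  sim$variants$sigma <- 1
  enc <- encode_family(sim$alignment, sim$domains, sim$variants)
  m <- fit_energy_model(enc, lambda = 0, seed = 3)
  pred <- predict(m, enc)
  v <- enc$variants
  X <- data.frame(
    f = v$fitness,
    hom = factor(v$hom_idx),
    feat = factor(ifelse(is.na(v$d_idx), 0L, v$d_idx))
  )
  lmfit <- stats::lm(f ~ hom + feat, data = X)
  expect_equal(unname(stats::fitted(lmfit)), pred, tolerance = 0.01)
})

test_that("tenfold folds are seeded and the report is consistent", {
  enc <- small_encoding()
  cv1 <- suppressWarnings(tenfold_cv(enc, k = 4, seed = 9))
  cv2 <- suppressWarnings(tenfold_cv(enc, k = 4, seed = 9))
  expect_identical(cv1$assignment$fold, cv2$assignment$fold)
  expect_equal(cv1$pooled_r, cv2$pooled_r)
  expect_equal(sort(unique(cv1$assignment$fold)), 1:4)
  expect_gt(cv1$pooled_r, 0.8)
  # held-out predictions exist for every variant
  expect_false(anyNA(cv1$assignment$predicted))
})

test_that("an over-unity explainable fraction is flagged", {
  enc <- small_encoding()
  expect_warning(
    cv <- tenfold_cv(enc, k = 4, seed = 9),
    "explainable fraction"
  )
  expect_gt(cv$explainable_fraction, 1.05)
})

test_that("leave-one-homologue-out reports distances and coverage", {
  enc <- small_encoding()
  res <- loho(enc, seed = 3, min_homologues = 6)
  expect_equal(nrow(res), 6)
  expect_true(all(res$converged))
  expect_true(all(res$mean_hamming > 0))
  expect_true(all(res$mean_blosum_dist > 0))
  expect_true(all(res$r > 0.3))
  expect_error(loho(enc, min_homologues = 10), class = "foldstab_loho")
})

test_that("genetic distances of identical rows are zero", {
  aln <- family_alignment(
    c(a = "ACD-F", b = "ACD-F", c = "AW-EF"), "fam"
  )
  d_ab <- foldstab:::genetic_distances(aln, "a", "b")
  expect_equal(unname(d_ab["mean_hamming"]), 0)
  expect_equal(unname(d_ab["mean_blosum_dist"]), 0)
  d_ac <- foldstab:::genetic_distances(aln, "a", "c")
  expect_gt(d_ac["mean_hamming"], 0)
})

test_that("a duplicated homologue is predicted like its training twin", {
  sim <- default_sim()
  ids <- sim$domains$domain_id
  twin <- "SYNFAM1_dup"
  doms <- dplyr::bind_rows(
    sim$domains,
    dplyr::mutate(sim$domains[1, ], domain_id = twin)
  )
  v_twin <- sim$variants[sim$variants$domain_id == ids[1], ]
  v_twin$domain_id <- twin
  v_twin <- withr::with_seed(
    99, foldstab:::add_measurements(v_twin, sim$truth$config)
  )
  rows <- c(sim$alignment$rows, stats::setNames(sim$alignment$rows[1], twin))
  aln <- family_alignment(rows, sim$alignment$family_id)
  enc <- encode_family(aln, doms, dplyr::bind_rows(sim$variants, v_twin))
  idx <- which(enc$variants$domain_id == twin)
  full <- fit_energy_model(enc, seed = 5, compute_se = FALSE)
  r_train <- stats::cor(enc$variants$fitness[idx], predict(full, enc)[idx])
  held <- fit_energy_model(enc, seed = 5, compute_se = FALSE, rows = -idx)
  r_loho <- stats::cor(enc$variants$fitness[idx], predict(held, enc)[idx])
  expect_lt(abs(r_loho - r_train), 0.02)
  # and the twin is at zero genetic distance from its source
  d <- foldstab:::genetic_distances(aln, twin, ids[1])
  expect_equal(unname(d["mean_hamming"]), 0)
})

test_that("rescaled energies anchor the 2.5th percentile at magnitude 1", {
  enc <- small_encoding()
  m <- fixture("small_model", fit_energy_model(enc, seed = 2))
  sc <- rescale_energies(m)
  scale <- attr(sc, "scale")
  expect_equal(
    unname(stats::quantile(-sc$ddg, 0.025) / scale), -1,
    tolerance = 1e-12
  )
  expect_identical(order(sc$ddg), order(sc$scaled_ddg)) # monotone
  expect_equal(sc$scaled_ddg, sc$ddg / scale)
  expect_match(attr(sc, "orientation"), "destabilizing")
})

test_that("unseen homologues are predicted from composition and shared energies", {
  sim7 <- simulate_family(7, 15, seed = 41)
  ids <- sim7$domains$domain_id
  train_ids <- ids[1:6]
  aln_train <- family_alignment(
    sim7$alignment$rows[train_ids], sim7$alignment$family_id
  )
  enc <- encode_family(
    aln_train,
    sim7$domains[1:6, ],
    sim7$variants[sim7$variants$domain_id %in% train_ids, ]
  )
  m <- fit_energy_model(enc, seed = 6)
  held <- sim7$variants[sim7$variants$domain_id == ids[7], ]
  pred <- suppressWarnings(predict_new_homologue(
    m, sim7$alignment$rows[[ids[7]]],
    held[, c("position", "wt_aa", "mut_aa")]
  ))
  expect_gte(
    stats::cor(pred$p_f, fraction_folded(held$dG_true)), 0.9
  )
  # predicting a training homologue reproduces its fitted values exactly
  t1 <- sim7$variants[sim7$variants$domain_id == train_ids[1], ]
  pred_t1 <- predict_new_homologue(
    m, sim7$alignment$rows[[train_ids[1]]],
    t1[, c("position", "wt_aa", "mut_aa")]
  )
  enc_idx <- enc$variants$domain_id == train_ids[1]
  expect_equal(
    pred_t1$fitness_pred,
    predict(m, enc)[enc_idx][match(
      paste(t1$position, t1$mut_aa),
      paste(enc$variants$position[enc_idx], enc$variants$mut_aa[enc_idx])
    )],
    tolerance = 1e-12
  )
  # a wild-type "variant" has scaled ddG 0 and is never called
  wt_row <- tibble::tibble(
    position = 1L,
    wt_aa = substr(sim7$domains$sequence[1], 1, 1),
    mut_aa = substr(sim7$domains$sequence[1], 1, 1)
  )
  pw <- predict_new_homologue(m, sim7$alignment$rows[[train_ids[1]]], wt_row)
  expect_equal(pw$scaled_ddg, 0)
  expect_false(pw$destabilizing)
  # row-length mismatches are rejected
  expect_error(
    predict_new_homologue(m, "AC-", wt_row),
    class = "foldstab_predict"
  )
})
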