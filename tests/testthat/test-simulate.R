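# The synthetic family generator: forward-model exactness, determinism,
# planted epistasis, evolutionary scores and clinical labels.

test_that("the generator is deterministic under its seed", {
  a <- simulate_family(4, 8, seed = 5)
  b <- simulate_family(4, 8, seed = 5)
  expect_identical(a$variants, b$variants)
  expect_identical(a$domains$sequence, b$domains$sequence)
  c <- simulate_family(4, 8, seed = 6)
  expect_false(identical(a$domains$sequence, c$domains$sequence))
})

test_that("noise-free fitness equals the affine Boltzmann map exactly", {
  cfg <- family_config(noise_sigma = 0)
  sim <- simulate_family(4, 8, config = cfg, seed = 3)
  expected <- cfg$gamma0 + cfg$gamma1 * fraction_folded(sim$variants$dG_true)
  expect_equal(sim$variants$fitness, expected, tolerance = 1e-12)
  expect_true(all(sim$variants$sigma == cfg$sigma_floor))
})

test_that("a +10 RT destabilization of a -5 RT wild type unfolds the domain", {
  p <- fraction_folded(-5 + 10)
  expect_equal(p, 1 / (1 + exp(5)))
  expect_lt(p, 0.01)
})

test_that("energetic additivity holds exactly for non-epistatic variants", {
  sim <- small_sim()
  v <- sim$variants[sim$variants$variant_class == "missense", ]
  delta <- v$dG_true - sim$truth$dG_wt[v$domain_id]
  planted <- sim$truth$D_true[cbind(v$position, match(v$mut_aa, AMINO_ACIDS))]
  expect_equal(unname(delta), unname(planted), tolerance = 1e-12)
  expect_equal(
    unname(sim$truth$dG_wt),
    sim$truth$b0 + vapply(sim$domains$sequence, function(s) {
      wt <- strsplit(s, "")[[1]]
      sum(sim$truth$U_true[cbind(seq_along(wt), match(wt, AMINO_ACIDS))])
    }, numeric(1), USE.NAMES = FALSE),
    tolerance = 1e-12
  )
})

test_that("the empirical noise matches the declared model within 10%", {
  sim <- default_sim()
  v <- sim$variants
  true_f <- sim$truth$gamma0 + sim$truth$gamma1 * fraction_folded(v$dG_true)
  resid <- v$fitness - true_f
  expect_gt(length(resid), 1000)
  expect_equal(
    stats::sd(resid), sim$truth$noise_sigma,
    tolerance = 0.1
  )
  expect_lt(abs(mean(resid)), 3 * sim$truth$noise_sigma / sqrt(length(resid)))
})

test_that("generator configuration is validated", {
  expect_error(
    simulate_family(4, 8, config = family_config(gamma1 = -1)),
    class = "foldstab_config"
  )
  expect_error(
    simulate_family(4, 8, config = family_config(noise_sigma = -0.1)),
    class = "foldstab_config"
  )
})

test_that("epistasis planting has exact counts and is reversible at zero", {
  sim <- small_sim()
  expect_identical(inject_epistasis(sim, 0, seed = 1), sim)
  n_mis <- sum(sim$variants$variant_class == "missense")
  out <- inject_epistasis(sim, 0.05, 5, seed = 2)
  expect_equal(nrow(out$truth$epistatic_set), round(0.05 * n_mis))
  expect_false(any(duplicated(out$truth$epistatic_set[, 1:4])))
  expect_error(inject_epistasis(sim, 1.2, seed = 1), class = "foldstab_config")
})

test_that("a planted shift moves fitness by gamma1 times the occupancy change", {
  cfg <- family_config(noise_sigma = 0)
  sim <- simulate_family(4, 8, config = cfg, seed = 3)
  out <- inject_epistasis(sim, 0.1, 4, seed = 9)
  es <- out$truth$epistatic_set
  before <- dplyr::inner_join(
    sim$variants, es,
    by = c("domain_id", "position", "wt_aa", "mut_aa")
  )
  after <- dplyr::inner_join(
    out$variants, es,
    by = c("domain_id", "position", "wt_aa", "mut_aa")
  )
  expect_equal(
    after$fitness - before$fitness,
    cfg$gamma1 * (fraction_folded(before$dG_true + after$delta) -
      fraction_folded(before$dG_true)),
    tolerance = 1e-12
  )
})

test_that("evolutionary scores follow stability, penalized at planted sites", {
  cfg <- family_config(noise_sigma = 0, score_noise = 0)
  sim <- simulate_family(6, 15, config = cfg, seed = 13)
  sc <- simulate_evolutionary_scores(sim, seed = 1, config = cfg)
  joined <- dplyr::inner_join(
    sim$variants, sc,
    by = c("domain_id", "position", "wt_aa", "mut_aa")
  )
  # wild-type-like variants at non-functional columns sit at the ceiling
  syn <- joined[joined$variant_class == "synonymous" &
    !(joined$position %in% sim$truth$functional_columns), ]
  expect_true(all(syn$score == cfg$score_max))
  # a fully unfolded variant at a functional column: floor minus penalty
  fun <- joined[joined$position %in% sim$truth$functional_columns &
    fraction_folded(joined$dG_true) < 1e-3, ]
  if (nrow(fun)) {
    expect_equal(
      fun$score,
      rep(cfg$score_min - cfg$functional_penalty, nrow(fun))
    )
  }
  # without planted function, score tracks fitness almost perfectly
  cfg0 <- family_config(noise_sigma = 0, score_noise = 0, n_functional = 0)
  sim0 <- simulate_family(6, 15, config = cfg0, seed = 13)
  sc0 <- simulate_evolutionary_scores(sim0, seed = 1, config = cfg0)
  j0 <- dplyr::inner_join(
    sim0$variants, sc0,
    by = c("domain_id", "position", "wt_aa", "mut_aa")
  )
  # within a homologue (fixed wild-type occupancy), the unclipped score is
  # strictly monotone in fitness
  inside <- j0[j0$score > cfg0$score_min & j0$score < cfg0$score_max, ]
  per_dom <- vapply(
    split(inside, inside$domain_id),
    function(d) stats::cor(d$score, d$fitness, method = "spearman"),
    numeric(1)
  )
  expect_true(all(per_dom > 0.999))
  expect_error(
    simulate_evolutionary_scores(list(variants = 1)),
    class = "foldstab_config"
  )
})

test_that("clinical labels respect their configuration", {
  sim <- small_sim()
  none <- simulate_clinical_labels(
    sim,
    config = clinical_config(pathogenic_rate = 0), seed = 4
  )
  expect_false(any(none$label == "pathogenic"))
  a <- simulate_clinical_labels(sim, seed = 4)
  b <- simulate_clinical_labels(sim, seed = 4)
  expect_identical(a, b)
  expect_true(all(
    is.na(a$allele_frequency) == (a$label != "population")
  ))
  expect_true(all(
    a$allele_frequency[a$label == "population"] >= 1e-6 &
      a$allele_frequency[a$label == "population"] <= 1e-2
  ))
})

test_that("structural features mark planted cores and confident models", {
  sim <- small_sim()
  core <- sim$truth$core_columns
  for (i in seq_len(nrow(sim$domains))) {
    rsasa <- sim$domains$rsasa[[i]]
    expect_true(all(rsasa[core] < 0.25))
    expect_true(all(rsasa[-core] >= 0.25))
    expect_true(all(sim$domains$plddt[[i]] >= 70))
  }
})
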