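# Quality metrics, foldedness classification, PCA ranking and fitness
# normalization.

make_domain_variants <- function(fitness, wt_rate, domain_id = "d1") {
  n <- length(fitness)
  tibble::tibble(
    domain_id = domain_id,
    position = rep(seq_len(ceiling(n / 19)), each = 19)[seq_len(n)],
    wt_aa = "A",
    mut_aa = rep_len(setdiff(AMINO_ACIDS, "A"), n),
    variant_class = "missense",
    fitness = fitness,
    sigma = 0.01,
    growth_rate_1 = fitness,
    growth_rate_2 = fitness,
    count_1 = 100L
  )
}

make_domain <- function(wt_rate, n_res = 10, domain_id = "d1") {
  tibble::tibble(
    domain_id = domain_id,
    sequence = paste(rep("A", n_res), collapse = ""),
    rsasa = list(rep(0.1, n_res)),
    plddt = list(rep(80, n_res)),
    wt_growth_rate = wt_rate
  )
}

test_that("the wild-type position metric matches its defining percentiles", {
  f <- seq(0, 1, length.out = 100)
  q <- stats::quantile(f, c(0.05, 0.95), names = FALSE)
  m_at_p95 <- suppressWarnings(compute_quality_metrics(
    make_domain_variants(f), make_domain(q[2])
  ))
  expect_equal(m_at_p95$wt_position, 0)
  m_at_p5 <- suppressWarnings(compute_quality_metrics(
    make_domain_variants(f), make_domain(q[1])
  ))
  expect_equal(m_at_p5$wt_position, -1)
})

test_that("a degenerate fitness distribution fails the domain", {
  m <- suppressWarnings(compute_quality_metrics(
    make_domain_variants(rep(0.3, 50)), make_domain(0.3)
  ))
  expect_true(is.na(m$wt_position))
  expect_true("zero fitness range" %in% m$reasons[[1]])
})

test_that("foldedness uses the core-fraction and pLDDT rules", {
  doms <- tibble::tibble(
    domain_id = c("no_core", "boundary", "disordered", "missing"),
    rsasa = list(
      rep(0.5, 20),
      c(rep(0.24, 2), rep(0.5, 18)), # exactly 10% buried
      rep(0.1, 20),
      NULL
    ),
    plddt = list(rep(70, 20), rep(70, 20), rep(49.9, 20), NULL)
  )
  out <- classify_foldedness(doms)
  expect_equal(
    out$foldedness,
    c("excluded", "folded", "excluded", "excluded")
  )
  expect_equal(out$reason[4], "missing structural features")
})

test_that("PCA ranking breaks ties lexicographically and applies strict cuts", {
  metrics <- tibble::tibble(
    domain_id = c("dom_b", "dom_a", "dom_c", "dom_d"),
    wt_position = c(0.2, 0.2, -0.5, 0.1),
    rep_corr = c(0.9, 0.9, 0.2, 0.485),
    sasa_corr = c(0.5, 0.5, -0.1, 0.4),
    hyd_corr = c(0.0, 0.0, -0.4, 0.1),
    coverage = c(0.95, 0.95, 0.9, 0.9),
    n_missense = 100L,
    reasons = list(character(), character(), character(), character())
  )
  out <- rank_and_filter(metrics)
  # identical metric rows: identical pc1, tie broken by id
  expect_equal(out$pc1_score[1], out$pc1_score[2])
  expect_lt(out$rank[out$domain_id == "dom_a"], out$rank[out$domain_id == "dom_b"])
  # rep_corr exactly at the threshold is not retained (strict inequality)
  expect_false(out$retained[out$domain_id == "dom_d"])
  expect_true(out$retained[out$domain_id == "dom_a"])
  share <- attr(out, "pc1_var_share")
  expect_gt(share, 0.25)
  expect_lte(share, 1)
})

test_that("filtering is monotone in the replicate-correlation threshold", {
  sim <- default_sim()
  metrics <- compute_quality_metrics(sim$variants, sim$domains)
  loose <- rank_and_filter(metrics, min_rep_corr = 0.3)
  strict <- rank_and_filter(metrics, min_rep_corr = 0.8)
  expect_true(all(
    strict$domain_id[strict$retained] %in% loose$domain_id[loose$retained]
  ))
  excl <- rank_and_filter(metrics, exclude = metrics$domain_id[1])
  expect_false(excl$retained[1])
})

test_that("synthetic folded domains show the expected QC signatures", {
  sim <- default_sim()
  m <- compute_quality_metrics(sim$variants, sim$domains)
  # buried positions are more destabilizing: fitness rises with rSASA
  expect_true(all(m$sasa_corr > 0))
  # no hydrophobicity artefact is planted
  expect_true(all(abs(m$hyd_corr) < 0.3))
  expect_true(all(m$coverage == 1))
  expect_gt(stats::median(m$rep_corr), 0.485)
  expect_true(all(m$rep_corr > 0.2))
})

test_that("replicate correlation decreases with the noise level", {
  reps <- vapply(c(0.02, 0.08, 0.2), function(ns) {
    sim <- simulate_family(
      3, 12,
      config = family_config(noise_sigma = ns), seed = 17
    )
    m <- compute_quality_metrics(sim$variants, sim$domains)
    mean(m$rep_corr)
  }, numeric(1))
  expect_true(all(diff(reps) < 0))
})

test_that("normalization maps the wild type to 0 and the 2.5th percentile to -1", {
  # 40 missense + wt: the 2.5th percentile is exactly the 2nd order statistic
  f <- sort(stats::runif(40, 0, 0.5))
  wt <- 0.6
  v <- make_domain_variants(f, wt)
  norm <- normalize_fitness(v, make_domain(wt), min_missense = 40)
  p25 <- f[2]
  expect_identical(norm$f_norm[which(norm$fitness == p25)], -1)
  # the wild type itself maps to zero under the same affine map
  expect_identical((wt - wt) / (wt - p25), 0)
  # halfway between the anchor points maps to -1/2
  half <- (wt + p25) / 2
  expect_equal((half - wt) / (wt - p25), -0.5)
  # the map is exactly affine
  expect_equal(stats::cor(norm$fitness, norm$f_norm), 1, tolerance = 1e-12)
  expect_equal(norm$sigma_norm, norm$sigma * norm$scale_factor)
})

test_that("a non-positive dynamic range is an error", {
  f <- seq(0.5, 1, length.out = 50)
  expect_error(
    suppressWarnings(normalize_fitness(
      make_domain_variants(f, 0.1), make_domain(0.1)
    )),
    "non-positive dynamic range",
    class = "foldstab_normalize"
  )
})
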