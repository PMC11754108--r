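# Destabilization calling, class summaries, Fisher's exact test and
# classifier evaluation.

test_that("the one-tailed z-test classifies forced cases correctly", {
  norm <- tibble::tibble(
    domain_id = "d1", position = 1:3, wt_aa = "A", mut_aa = c("V", "W", "Y"),
    f_norm = c(0, -0.5, -0.1),
    sigma_norm = c(0.05, 0.05, 0.05)
  )
  calls <- call_destabilizing(norm)
  expect_equal(calls$p[1], 0.5)
  expect_equal(calls$stability_class[1], "stable")
  expect_equal(calls$z[2], -10)
  expect_equal(calls$stability_class[2], "strong")
  expect_true(calls$q[2] < 1e-10)
  expect_error(
    call_destabilizing(dplyr::mutate(norm, sigma_norm = 0)),
    class = "foldstab_stability"
  )
})

test_that("the caller is calibrated under a pure null", {
  n <- 2000
  sigma <- withr::with_seed(1, stats::runif(n, 0.03, 0.1))
  f <- withr::with_seed(2, stats::rnorm(n, 0, sigma))
  norm <- tibble::tibble(
    domain_id = "d1", position = seq_len(n), wt_aa = "A", mut_aa = "V",
    f_norm = f, sigma_norm = sigma
  )
  calls <- call_destabilizing(norm, fdr_threshold = 0.1)
  frac <- mean(calls$stability_class != "stable")
  expect_lte(frac, 0.1 + 3 * sqrt(0.1 * 0.9 / n))
})

test_that("class summaries reproduce printed proportions", {
  calls <- tibble::tibble(
    domain_id = "d1",
    position = 1:943,
    wt_aa = "A", mut_aa = "V",
    stability_class = c(
      rep("strong", 303), rep("mild", 77), rep("stable", 241), # pathogenic
      rep("strong", 50), rep("mild", 79), rep("stable", 193) # benign
    )
  )
  ann <- tibble::tibble(
    domain_id = "d1", position = 1:943, wt_aa = "A", mut_aa = "V",
    label = c(rep("pathogenic", 621), rep("benign", 322)),
    allele_frequency = NA_real_
  )
  s <- summarize_stability_classes(calls, ann)
  path <- s[s$label == "pathogenic", ]
  expect_equal(sum(path$pct[path$stability_class %in% c("mild", "strong")]),
    100 * 380 / 621,
    tolerance = 1e-12
  )
  expect_equal(round(sum(path$pct[path$stability_class != "stable"])), 61)
  expect_equal(round(path$pct[path$stability_class == "strong"]), 49)
  ben <- s[s$label == "benign", ]
  expect_equal(round(sum(ben$pct[ben$stability_class != "stable"])), 40)
  expect_equal(round(ben$pct[ben$stability_class == "strong"]), 16)
  # percentages per label sum to 100
  sums <- as.vector(tapply(s$pct, s$label, sum))
  expect_equal(sums, rep(100, length(sums)))
})

test_that("summaries handle singleton and empty label groups", {
  calls <- tibble::tibble(
    domain_id = "d1", position = 1L, wt_aa = "A", mut_aa = "V",
    stability_class = "strong"
  )
  ann <- tibble::tibble(
    domain_id = "d1", position = c(1L, 99L), wt_aa = "A", mut_aa = "V",
    label = c("pathogenic", "vus"), allele_frequency = NA_real_
  )
  s <- summarize_stability_classes(calls, ann)
  expect_equal(s$pct[s$label == "pathogenic" & s$stability_class == "strong"], 100)
  vus <- s[s$label == "vus", ]
  expect_true(all(vus$n == 0))
  expect_true(all(is.na(vus$pct)))
})

test_that("population variants respect the allele-frequency floor", {
  calls <- tibble::tibble(
    domain_id = "d1", position = 1:2, wt_aa = "A", mut_aa = "V",
    stability_class = c("stable", "stable")
  )
  ann <- tibble::tibble(
    domain_id = "d1", position = 1:2, wt_aa = "A", mut_aa = "V",
    label = "population", allele_frequency = c(1e-6, 1e-3)
  )
  s <- summarize_stability_classes(calls, ann, af_floor = 1e-5)
  expect_equal(unique(s$n_label[s$label == "population"]), 1L)
})

test_that("fisher_or matches forced examples", {
  sym <- fisher_or(matrix(c(10, 10, 10, 10), 2))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p, 1)
  diag <- fisher_or(matrix(c(5, 0, 0, 5), 2))
  expect_equal(diag$odds_ratio, 121) # Haldane-corrected cross product
  expect_equal(diag$p, 2 / 252, tolerance = 1e-12)
  expect_error(fisher_or(c(1, 2, 3, -1)), class = "foldstab_stats")
  expect_error(fisher_or(c(1, 2, 3, 0.5)), class = "foldstab_stats")
})

test_that("fisher_or p-values agree with the exact reference over a grid", {
  for (a in 0:5) {
    for (b in 0:5) {
      for (cc in 0:5) {
        for (d in 0:5) {
          ours <- fisher_or(matrix(c(a, cc, b, d), 2))$p
          ref <- stats::fisher.test(matrix(c(a, cc, b, d), 2))$p.value
          expect_equal(ours, ref, tolerance = 1e-9)
        }
      }
    }
  }
  # a few larger tables with margins up to 15
  tables <- list(c(9, 6, 2, 13), c(15, 0, 3, 12), c(7, 7, 8, 6), c(1, 14, 14, 1))
  for (x in tables) {
    expect_equal(
      fisher_or(matrix(x, 2))$p,
      stats::fisher.test(matrix(x, 2))$p.value,
      tolerance = 1e-9
    )
  }
})

test_that("MCC equals the closed-form confusion formula on random tables", {
  withr::local_seed(42)
  for (i in 1:200) {
    tp <- sample(0:30, 1); fp <- sample(0:30, 1)
    tn <- sample(0:30, 1); fn <- sample(0:30, 1)
    if (tp + fn == 0 || fp + tn == 0) next # need both label classes
    fix <- confusion_fixture(tp, fp, tn, fn)
    ev <- evaluate_classifier(fix$calls, fix$annotations)
    denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    expected <- if (denom == 0) NaN else (tp * tn - fp * fn) / denom
    expect_equal(ev$mcc, expected)
  }
})

test_that("perfect separation gives MCC 1 and label-independent predictions near 0", {
  perfect <- confusion_fixture(tp = 20, fp = 0, tn = 20, fn = 0)
  expect_equal(evaluate_classifier(perfect$calls, perfect$annotations)$mcc, 1)
  # permuted labels on a balanced set
  withr::local_seed(7)
  mccs <- replicate(50, {
    fix <- confusion_fixture(tp = 25, fp = 25, tn = 25, fn = 25)
    perm <- sample(nrow(fix$annotations))
    fix$annotations$label <- fix$annotations$label[perm]
    evaluate_classifier(fix$calls, fix$annotations)$mcc
  })
  expect_lt(abs(mean(mccs)), 0.05)
})

test_that("ROC AUC equals the Mann-Whitney normalization", {
  withr::local_seed(3)
  n <- 120
  score <- stats::rnorm(n)
  label <- sample(c("pathogenic", "benign"), n, replace = TRUE)
  keys <- tibble::tibble(
    domain_id = "d1", position = seq_len(n), wt_aa = "A", mut_aa = "V"
  )
  calls <- dplyr::bind_cols(keys, tibble::tibble(score = score))
  ann <- dplyr::bind_cols(
    keys,
    tibble::tibble(label = label, allele_frequency = NA_real_)
  )
  ev <- evaluate_classifier(calls, ann, score_col = "score")
  pos <- score[label == "pathogenic"]
  neg <- score[label == "benign"]
  # lower score = predicted pathogenic
  u <- mean(outer(pos, neg, function(p, q) (p < q) + 0.5 * (p == q)))
  expect_equal(ev$auc, u, tolerance = 1e-9)
})

test_that("MCC resampling is seeded and scales with measurement error", {
  sim <- small_sim()
  norm <- suppressWarnings(normalize_fitness(sim$variants, sim$domains))
  ann <- simulate_clinical_labels(sim, seed = 5)
  a <- resample_mcc(norm, ann, n_resamples = 5, seed = 9)
  b <- resample_mcc(norm, ann, n_resamples = 5, seed = 9)
  expect_identical(a, b)
  tiny <- dplyr::mutate(norm, sigma_norm = 1e-9)
  expect_equal(resample_mcc(tiny, ann, n_resamples = 5, seed = 9)$mcc_sd, 0)
  wide <- dplyr::mutate(norm, sigma_norm = sigma_norm * 2)
  expect_gt(
    resample_mcc(wide, ann, n_resamples = 5, seed = 9)$mcc_sd,
    a$mcc_sd
  )
  expect_error(resample_mcc(norm, ann, n_resamples = 1, seed = 1),
    class = "foldstab_classifier"
  )
})
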