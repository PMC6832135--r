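test_that("permutation preserves both marginal frequency vectors exactly", {
  rec <- generate_cohort(cohort_config(n_doctors = 5L, seed = 71))
  pairs <- extract_pairs(rec)
  mat <- build_matrix(pairs)
  withr::with_seed(1, {
    for (b in 1:200) {
      perm <- permute_pairs(pairs)
      pm <- build_matrix(perm)
      expect_identical(pm$row_totals, mat$row_totals)
      expect_identical(pm$col_totals, mat$col_totals)
    }
  })
})

test_that("two distinct instances swap with probability one half", {
  pairs <- tibble::tibble(diagnosis = c("U61", "U62"),
                          acupoint = c("LI4", "ST36"))
  n <- 400L
  swapped <- vapply(seq_len(n), function(s) {
    withr::with_seed(s, permute_pairs(pairs)$acupoint[1] == "ST36")
  }, logical(1))
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(swapped) - 0.5), 3 * se)

  mono <- tibble::tibble(diagnosis = c("U61", "U62", "U63"),
                         acupoint = rep("LI4", 3))
  withr::with_seed(1, expect_identical(permute_pairs(mono), mono))
})

test_that("the add-one p-value estimator respects its bounds", {
  rec <- generate_cohort(cohort_config(n_doctors = 4L, seed = 72))
  pairs <- extract_pairs(rec)
  res <- null_distribution(pairs, n_perm = 1L, seed = 1)
  expect_true(all(res$p_values %in% c(0.5, 1)))
  res2 <- null_distribution(pairs, n_perm = 19L, seed = 2)
  expect_true(all(res2$p_values >= 1 / 20))
  expect_true(all(res2$p_values <= 1))
  expect_true(all(res2$exceed <= 19L))
})

test_that("a saturated matrix gives all-zero weights and p = 1 everywhere", {
  # every acupoint under every diagnosis: classic idf is 0 for every term
  pairs <- tibble::as_tibble(expand.grid(
    diagnosis = c("U61", "U62", "U63"), acupoint = c("LI4", "ST36"),
    stringsAsFactors = FALSE))
  res <- null_distribution(pairs, n_perm = 50L, seed = 3)
  expect_true(all(res$observed$weights == 0))
  expect_true(all(res$p_values == 1))
  expect_equal(nrow(significant_associations(res)), 0L)
})

test_that("p-values are deterministic in the seed and pair-order invariant", {
  rec <- generate_cohort(cohort_config(n_doctors = 6L, seed = 73))
  pairs <- extract_pairs(rec)
  a <- null_distribution(pairs, n_perm = 100L, seed = 9)
  b <- null_distribution(pairs, n_perm = 100L, seed = 9)
  expect_identical(a$p_values, b$p_values)
  shuffled <- pairs[withr::with_seed(4, sample.int(nrow(pairs))), ]
  c <- null_distribution(shuffled, n_perm = 100L, seed = 9)
  expect_identical(c$p_values, a$p_values)
  d <- null_distribution(pairs, n_perm = 100L, seed = 10)
  expect_false(identical(d$p_values, a$p_values))
})

test_that("p-values agree with exhaustive enumeration on a tiny pair list", {
  # 4 instances, acupoint multiset {LI4, LI4, ST36, KI3}; small enough to
  # enumerate all 4! assignments directly with the naive tf-idf oracle
  pairs <- tibble::tibble(
    diagnosis = c("U61", "U61", "U62", "U62"),
    acupoint = c("LI4", "LI4", "ST36", "KI3")
  )
  mat <- build_matrix(pairs)
  w_obs <- oracle_tfidf(mat$counts)
  perms <- matrix(unlist(combinat_perms(4L)), ncol = 4L, byrow = TRUE)
  acus <- pairs$acupoint
  dlev <- rownames(mat$counts)
  alev <- colnames(mat$counts)
  exceed_exact <- matrix(0, nrow(w_obs), ncol(w_obs),
                         dimnames = dimnames(w_obs))
  for (r in seq_len(nrow(perms))) {
    counts <- matrix(0L, length(dlev), length(alev),
                     dimnames = list(dlev, alev))
    ap <- acus[perms[r, ]]
    for (i in 1:4) {
      counts[pairs$diagnosis[i], ap[i]] <- counts[pairs$diagnosis[i], ap[i]] + 1L
    }
    exceed_exact <- exceed_exact + (oracle_tfidf(counts) >= w_obs)
  }
  q_exact <- exceed_exact / nrow(perms)

  B <- 4000L
  res <- null_distribution(pairs, n_perm = B, seed = 5)
  q_hat <- res$exceed / B
  se <- sqrt(pmax(q_exact * (1 - q_exact), 1e-6) / B)
  expect_true(all(abs(q_hat - q_exact) <= 3 * se + 1e-9))
})

test_that("significance flagging sorts, corrects, and validates its arguments", {
  rec <- generate_cohort(cohort_config(n_doctors = 20L, seed = 74))
  pairs <- extract_pairs(rec)
  res <- null_distribution(pairs, n_perm = 400L, seed = 6)
  sig <- significant_associations(res, alpha = 0.05)
  expect_true(all(sig$p_value <= 0.05))
  expect_true(!is.unsorted(sig$p_value))

  bh <- significant_associations(res, alpha = 0.05,
                                 correction = "benjamini-hochberg")
  expect_lte(nrow(bh), nrow(sig))
  expect_true(all(bh$p_adjusted >= bh$p_value))
  expect_error(significant_associations(res, correction = "bonferroni"))
})

test_that("record-level and pooled nulls run and stay within p-value bounds", {
  rec <- generate_cohort(cohort_config(n_doctors = 6L, seed = 75))
  pairs <- extract_pairs(rec)
  r1 <- null_distribution(pairs, n_perm = 50L, seed = 7, unit = "record")
  expect_true(all(r1$p_values >= 1 / 51 & r1$p_values <= 1))
  r2 <- null_distribution(pairs, n_perm = 50L, seed = 7, pooled = TRUE)
  expect_true(all(r2$p_values > 0 & r2$p_values <= 1))
})
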