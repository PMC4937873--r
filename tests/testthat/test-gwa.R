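test_that("MAF filter is boundary-inclusive over non-missing lines", {
  G <- matrix(0L, nrow = 200, ncol = 3)
  G[1:9, 1] <- 1L    # 0.045: below threshold
  G[1:10, 2] <- 1L   # 0.050: exactly at threshold, kept ("at least")
  # column 3 monomorphic
  pan <- make_panel(G)
  kept <- maf_filter(pan, 0.05)
  expect_identical(kept, colnames(pan$genotypes)[2])
})

test_that("single-marker test handles exact fits and matches lm", {
  r <- single_marker_test(c(1, 1, 1, 2, 2, 2), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$effect, 1)
  expect_equal(r$flag, "perfect_fit")
  expect_equal(r$p_value, 0)

  withr::with_seed(5, {
    y <- rnorm(80)
    g <- rbinom(80, 1, 0.3)
    w <- rbinom(80, 1, 0.5)
  })
  got <- single_marker_test(y, g, data.frame(w = w))
  ref <- summary(lm(y ~ g + w))$coefficients["g", ]
  expect_equal(got$effect, unname(ref[1]))
  expect_equal(got$se, unname(ref[2]))
  expect_equal(got$p_value, unname(ref[4]))

  # genotype collinear with a covariate is flagged, not given a p-value
  bad <- single_marker_test(y, g, data.frame(w = g))
  expect_equal(bad$flag, "collinear")
  expect_true(is.na(bad$p_value))
})

test_that("association p-values obey the stated invariances", {
  withr::with_seed(8, {
    y <- rnorm(200)
    g <- rbinom(200, 1, 0.4)
  })
  p1 <- single_marker_test(y, g)$p_value
  p2 <- single_marker_test(3 * y + 5, g)$p_value
  expect_equal(p1, p2, tolerance = 1e-12)

  # a covariate orthogonal to both y and g leaves effect intact and the
  # t statistic unchanged up to the one-df change in the residual scale
  base <- single_marker_test(y, g)
  c_raw <- withr::with_seed(9, rnorm(200))
  c_orth <- residuals(lm(c_raw ~ y + g))
  adj <- single_marker_test(y, g, data.frame(c = c_orth))
  expect_equal(adj$effect, base$effect, tolerance = 1e-10)
  expect_equal(adj$statistic, base$statistic, tolerance = 0.01)
})

test_that("scan is calibrated under the null and finds injected signal", {
  pan <- simulate_panel(panel_config(n_lines = 200, n_variants = 3000, seed = 10))
  y <- withr::with_seed(11, tibble::tibble(line = pan$line_ids, value = rnorm(200)))
  res <- run_gwa(y, pan, sex_mode = "none")
  p <- tidy(res)$p_value
  expect_true(abs(mean(p < 0.05) - 0.05) < 0.02)
  expect_true(abs(stats::median(p) - 0.5) < 0.05)

  # injected sensitivity effect at a common variant tops the scan in the
  # majority of seeded replicates
  pan2 <- simulate_panel(panel_config(n_lines = 100, n_variants = 500, seed = 12))
  causal <- maf_filter(pan2, 0.3)[1]
  prm <- default_sim_params("dev_time")
  prm$causal_effects <- tibble::tibble(variant_id = causal, effect = 2.5,
                                       acts_on = "sensitivity")
  wins <- sum(vapply(1:20, function(i) {
    ph <- simulate_phenotypes(pan2, prm, "dev_time", seed = 3000 + i)
    sens <- sensitivity(line_means(ph))
    sc <- run_gwa(sens, pan2, sex_mode = "average")
    dplyr::arrange(tidy(sc), p_value)$variant_id[1] == causal
  }, logical(1)))
  expect_gte(wins, 11)
})

test_that("sex modes combine line means as defined", {
  pan <- simulate_panel(panel_config(n_lines = 40, n_variants = 50, seed = 13))
  sens <- tibble::tibble(
    line = rep(pan$line_ids, each = 2), sex = rep(c("F", "M"), 40),
    sensitivity = rep(withr::with_seed(14, rnorm(40)), each = 2)
  )
  # F table equals M table: difference mode has nothing to find
  res <- run_gwa(sens, pan, sex_mode = "difference")
  expect_true(all(abs(tidy(res)$effect) < 1e-12 | is.na(tidy(res)$effect)))
  expect_equal(nrow(res$top_hits), 0)

  # average mode equals scanning the common value
  avg <- run_gwa(sens, pan, sex_mode = "average")
  fem <- run_gwa(dplyr::filter(sens, sex == "F"), pan, sex_mode = "F")
  expect_equal(tidy(avg)$p_value, tidy(fem)$p_value)

  # lethal lines drop out of the scan's n
  sens2 <- dplyr::mutate(sens, sensitivity = ifelse(line %in% pan$line_ids[1:5],
                                                    NA, sensitivity))
  res2 <- run_gwa(sens2, pan, sex_mode = "average")
  expect_equal(unique(tidy(res2)$n), 35)
})

test_that("qq pairing follows uniform order statistics", {
  one <- tibble::tibble(p_value = 0.5)
  qq <- qq_data(one)
  expect_equal(qq$expected, -log10(0.5))
  expect_equal(qq$observed, -log10(0.5))

  recs <- tibble::tibble(p_value = c(0.2, 0.01, 0.2, 0.9, 0.05))
  qq2 <- qq_data(recs)
  expect_true(all(diff(qq2$observed) <= 0))
  expect_equal(qq2$expected, -log10((1:5) / 6))
})

test_that("ld r2 equals the brute-force haplotype-table computation", {
  G <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L))
  pan <- make_panel(G)
  ids <- colnames(pan$genotypes)
  expect_equal(ld_r2(pan, c(ids[1], ids[3]))$r2, 1)  # identical columns
  expect_equal(ld_r2(pan, c(ids[1], ids[2]))$r2, 0)  # D = 0 by construction

  pan2 <- simulate_panel(panel_config(n_lines = 120, n_variants = 30, seed = 17))
  ids2 <- maf_filter(pan2, 0.05)[1:2]
  got <- ld_r2(pan2, ids2)$r2
  # brute force from the 2x2 joint line-frequency (= haplotype) table
  ga <- pan2$genotypes[, ids2[1]]; gb <- pan2$genotypes[, ids2[2]]
  pAB <- mean(ga == 1 & gb == 1); pA <- mean(ga); pB <- mean(gb)
  D <- pAB - pA * pB
  expect_equal(got, D^2 / (pA * (1 - pA) * pB * (1 - pB)))

  # symmetric and bounded
  expect_equal(ld_r2(pan2, rev(ids2))$r2, got)
  expect_true(got >= 0 && got <= 1)

  mono <- make_panel(cbind(rep(0L, 4), c(0L, 1L, 0L, 1L)))
  expect_error(ld_r2(mono, colnames(mono$genotypes)[1:2]), "monomorphic")
})
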