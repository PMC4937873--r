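test_that("per-line classification matches the Welch oracle with direction", {
  ctl <- c(10, 10, 11, 10, 11)
  pb <- c(13, 14, 13, 14, 13)
  tbl <- make_pheno(list(
    slow = list(control = ctl, lead = pb),              # clearly slower: poor
    same = list(control = ctl, lead = ctl + 0.01),      # indistinguishable: good
    fast = list(control = pb, lead = ctl)               # faster on lead: good
  ))
  calls <- classify_lines(tbl, "dev_time", sex = "F")
  cls <- setNames(calls$class, calls$line)
  expect_equal(cls[["slow"]], "poor")
  expect_equal(cls[["same"]], "good")
  expect_equal(cls[["fast"]], "good")

  orc <- welch_oracle(pb, ctl)
  row <- calls[calls$line == "slow", ]
  expect_equal(row$statistic, orc$t)
  expect_equal(row$p_value, orc$p)

  # viability flips the direction: significantly lower on lead is poor
  via <- make_pheno(list(drop = list(control = c(.8, .9, .8, .9),
                                     lead = c(.2, .1, .2, .1))),
                    trait = "viability", sex = NA_character_)
  expect_equal(classify_lines(via, "viability")$class, "poor")
})

test_that("classification agrees with a brute-force t-test over random lines", {
  withr::with_seed(21, {
    ok <- vapply(1:300, function(i) {
      ctl <- rnorm(5, 10, 1)
      pb <- rnorm(5, 10 + sample(c(0, 2), 1), 1)
      tbl <- make_pheno(list(x = list(control = ctl, lead = pb)))
      got <- classify_lines(tbl, "dev_time", sex = "F")
      tt <- t.test(pb, ctl)
      want <- if (tt$p.value < 0.05 && mean(pb) > mean(ctl)) "poor" else "good"
      got$class == want
    }, logical(1))
  })
  expect_true(all(ok))
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 42), 3), 1.19e-3)
  expect_equal(signif(bonferroni_threshold(0.05, 113), 3), 4.42e-4)
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

test_that("logistic enrichment matches the 2x2 closed form and LR oracle", {
  # good/alt 20, good/ref 10, poor/alt 10, poor/ref 20 -> OR = 4
  G <- matrix(c(rep(1L, 20), rep(0L, 10), rep(1L, 10), rep(0L, 20)), ncol = 1)
  pan <- make_panel(G)
  calls <- tibble::tibble(line = pan$line_ids,
                          class = c(rep("good", 30), rep("poor", 30)))
  v <- colnames(pan$genotypes)
  rec <- logistic_enrichment(calls, pan, v)
  expect_equal(rec$estimate, log(4), tolerance = 1e-6)

  # brute-force likelihood-ratio oracle from the binomial log-likelihoods
  ll <- function(p, y) sum(y * log(p) + (1 - y) * log(1 - p))
  y <- as.integer(calls$class == "good")
  g <- G[, 1]
  ll_alt <- ll(2 / 3, y[g == 1]) + ll(1 / 3, y[g == 0])
  ll_null <- ll(mean(y), y)
  p_lr <- pchisq(2 * (ll_alt - ll_null), 1, lower.tail = FALSE)
  expect_equal(rec$p_value, p_lr, tolerance = 1e-8)

  # relabeling good <-> poor flips the sign, keeps the p-value
  calls2 <- dplyr::mutate(calls, class = ifelse(class == "good", "poor", "good"))
  rec2 <- logistic_enrichment(calls2, pan, v)
  expect_equal(rec2$estimate, -rec$estimate, tolerance = 1e-6)
  expect_equal(rec2$p_value, rec$p_value, tolerance = 1e-8)
})

test_that("degenerate genotypes and separation are flagged", {
  G <- cbind(rep(1L, 20),                        # constant: no information
             c(rep(1L, 10), rep(0L, 10)))        # perfectly separates classes
  pan <- make_panel(G)
  calls <- tibble::tibble(line = pan$line_ids,
                          class = c(rep("good", 10), rep("poor", 10)))
  rec <- logistic_enrichment(calls, pan, colnames(pan$genotypes))
  expect_equal(rec$flag, c("no_variation", "separation"))
  expect_true(is.na(rec$estimate[1]))
  expect_true(is.finite(rec$estimate[2]))  # Firth fallback gives a finite value
  expect_true(rec$estimate[2] > 0)
})

test_that("Bonferroni keeps the family-wise error in check under the null", {
  withr::with_seed(23, {
    n_fwer <- vapply(1:60, function(i) {
      G <- matrix(rbinom(40 * 25, 1, 0.4), nrow = 40)
      pan <- make_panel(G)
      calls <- tibble::tibble(line = pan$line_ids,
                              class = sample(rep(c("good", "poor"), 20)))
      rec <- suppressWarnings(
        logistic_enrichment(calls, pan, colnames(pan$genotypes))
      )
      any(rec$significant, na.rm = TRUE)
    }, logical(1))
  })
  # FWER <= alpha plus 3-sigma Monte-Carlo slack
  expect_lte(mean(n_fwer), 0.05 + 3 * sqrt(0.05 * 0.95 / 60))
})
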