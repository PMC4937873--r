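sim_one_way <- function(n_lines, reps, var_L, var_e, mu = 10, seed = 1) {
  withr::with_seed(seed, {
    lines <- sprintf("L%03d", seq_len(n_lines))
    le <- rnorm(n_lines, 0, sqrt(var_L))
    tibble::tibble(
      line = rep(lines, each = reps),
      sex = "F", treatment = "control",
      replicate = rep(seq_len(reps), n_lines),
      trait = "dev_time",
      value = mu + rep(le, each = reps) + rnorm(n_lines * reps, 0, sqrt(var_e)),
      missing = FALSE
    )
  })
}

test_that("one-way variance components are recovered and match the EMS oracle", {
  tbl <- sim_one_way(100, 10, var_L = 2, var_e = 1, seed = 42)
  fit <- fit_anova(tbl, model = "line_only", method = "reml")
  vc <- setNames(fit$varcomp$variance, fit$varcomp$term)

  # independent oracle: (MS_L - MS_E) / r and MS_E from the raw mean squares
  a <- summary(aov(value ~ factor(line), data = tbl))[[1]]
  ms_l <- a$`Mean Sq`[1]; ms_e <- a$`Mean Sq`[2]
  expect_equal(vc[["L"]], (ms_l - ms_e) / 10, tolerance = 1e-6)
  expect_equal(vc[["resid"]], ms_e, tolerance = 1e-6)

  # and the truth is recovered within Monte-Carlo tolerance
  expect_true(abs(vc[["L"]] - 2) < 3 * 2 * sqrt(2 / 99))
  expect_true(abs(vc[["resid"]] - 1) < 3 * sqrt(2 / 900))

  # EMS path agrees with REML on this balanced interior fit
  ems <- fit_anova(tbl, model = "line_only", method = "ems")
  expect_equal(ems$varcomp$variance, fit$varcomp$variance, tolerance = 1e-6)
})

test_that("full-model REML equals the expected-mean-squares solution when balanced", {
  pan <- simulate_panel(panel_config(n_lines = 60, n_variants = 0, seed = 13))
  prm <- sim_params(mu = 10, var_L = 2, var_LxS = 1, var_LxT = 1.5,
                    var_LxSxT = 0.8, var_resid = 1, reps_per_cell = 4)
  tbl <- simulate_phenotypes(pan, prm, "dev_time", seed = 14)
  reml <- fit_anova(tbl, model = "full", method = "reml")
  ems <- fit_anova(tbl, model = "full", method = "ems")
  expect_equal(reml$varcomp$variance, ems$varcomp$variance, tolerance = 1e-4)

  # the injected line-by-treatment variance is detected
  lt <- ems$random[ems$random$term == "L:T", ]
  expect_lt(lt$p_value, 0.01)
})

test_that("degenerate and incomplete inputs are rejected or dropped", {
  flat <- make_pheno(list(a = list(control = c(5, 5, 5), lead = c(5, 5, 5)),
                          b = list(control = c(7, 7, 7), lead = c(7, 7, 7))))
  expect_error(fit_anova(flat, model = "line_only"), "degenerate")

  pan <- simulate_panel(panel_config(n_lines = 20, n_variants = 0, seed = 15))
  tbl <- simulate_phenotypes(pan, default_sim_params("dev_time"), "dev_time",
                             seed = 16) %>%
    inject_lethality(c("line_001", "line_002"), "both_sexes")
  fit <- fit_anova(tbl, model = "full")
  expect_setequal(fit$dropped_lines, c("line_001", "line_002"))
  expect_equal(fit$n_lines, 18)
})

test_that("broad-sense heritability arithmetic and invariances hold", {
  expect_equal(broad_sense_h2(c(L = 0, resid = 1))$H2, 0)
  expect_equal(broad_sense_h2(c(L = 1, resid = 1))$H2, 0.5)
  expect_equal(broad_sense_h2(c(L = 3, `L:T` = 1, resid = 1))$H2, 0.8)

  # negative components enter the raw sum; clamping applies afterwards
  h <- broad_sense_h2(c(L = 1, `L:T` = -2, resid = 0.5))
  expect_equal(h$H2_unclamped, -1 / (-0.5))
  expect_equal(h$H2, 1)  # raw ratio 2 clamps to 1

  expect_error(broad_sense_h2(c(L = 1, resid = 1), model = "full"), "missing")

  # H2 invariant to scaling and shifting every observation
  tbl <- sim_one_way(40, 5, var_L = 1.5, var_e = 1, seed = 7)
  tbl2 <- dplyr::mutate(tbl, value = 3 * value + 100)
  h1 <- broad_sense_h2(fit_anova(tbl, model = "line_only", method = "ems"))
  h2 <- broad_sense_h2(fit_anova(tbl2, model = "line_only", method = "ems"))
  expect_equal(h1$H2, h2$H2, tolerance = 1e-10)
})

test_that("line means are missing-aware brute-force group averages", {
  tbl <- make_pheno(list(a = list(control = c(10, 11, 12))))
  m <- line_means(tbl)
  expect_equal(m$mean, 11)
  expect_equal(m$n, 3)

  tbl$missing[2] <- TRUE
  m2 <- line_means(tbl)
  expect_equal(m2$mean, 11)
  expect_equal(m2$n, 2)

  tbl$missing <- TRUE
  m3 <- line_means(tbl)
  expect_true(is.na(m3$mean))
  expect_equal(m3$n, 0)

  pan <- simulate_panel(panel_config(n_lines = 15, n_variants = 0, seed = 20))
  big <- simulate_phenotypes(pan, default_sim_params("dev_time"), "dev_time",
                             seed = 21)
  got <- line_means(big)
  brute <- aggregate(value ~ line + sex + treatment, data = big, FUN = mean)
  merged <- merge(got, brute, by = c("line", "sex", "treatment"))
  expect_equal(merged$mean, merged$value)
})

test_that("sensitivity is control minus lead and antisymmetric", {
  m <- tibble::tibble(line = c("a", "a", "b", "b"), trait = "dev_time",
                      treatment = c("control", "lead", "control", "lead"),
                      mean = c(10, 13, 9, 9), n = 5)
  s <- sensitivity(m)
  expect_equal(s$sensitivity[s$line == "a"], -3)  # slower on lead
  expect_equal(s$sensitivity[s$line == "b"], 0)

  # swapping treatment labels flips the sign
  m_sw <- dplyr::mutate(m, treatment = ifelse(treatment == "control", "lead", "control"))
  expect_equal(sensitivity(m_sw)$sensitivity, -s$sensitivity)

  # a missing lead cell propagates
  m$mean[2] <- NA
  expect_true(is.na(sensitivity(m)$sensitivity[1]))
})

test_that("trait correlation matches closed-form expectation", {
  mk <- function(v) tibble::tibble(line = sprintf("l%03d", seq_along(v)),
                                   sensitivity = v)
  v <- rnorm(20)
  expect_equal(trait_correlation(mk(v), mk(v))$estimate, 1)
  expect_equal(trait_correlation(mk(v), mk(-v))$estimate, -1)
  expect_error(trait_correlation(mk(v[1:2]), mk(v[1:2])), ">= 3")

  # shared line effect u with independent noise: rho = var_u / (var_u + var_e)
  withr::with_seed(31, {
    u <- rnorm(400)
    a <- mk(u + rnorm(400, 0, 0.5))
    b <- mk(u + rnorm(400, 0, 0.5))
  })
  rho <- 1 / 1.25
  got <- trait_correlation(a, b)
  expect_equal(got$n, 400)
  expect_true(abs(got$estimate - rho) < 3 * (1 - rho^2) / sqrt(400))
})
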