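#' Partition phenotypic variance with a mixed-model ANOVA
#'
#' Fits the line-panel ANOVA for one trait and estimates its random-effect
#' variance components. The full model is
#' \deqn{Y = \mu + L + S + T + L{\times}S + L{\times}T + S{\times}T +
#'       L{\times}S{\times}T + \varepsilon,}
#' with line `L` random, sex `S` and treatment `T` fixed. Viability, which is
#' not sexed, uses \eqn{Y = \mu + L + T + L \times T + \varepsilon}
#' (`model = "no_sex"`); within one treatment the model reduces to
#' \eqn{\mu + L + S + L \times S + \varepsilon} and within one treatment and
#' sex to \eqn{\mu + L + \varepsilon}.
#'
#' Two estimators are available. `"reml"` (default) uses restricted maximum
#' likelihood via \pkg{lme4}, with Type III fixed-effect F-tests and
#' Satterthwaite denominator degrees of freedom via \pkg{lmerTest}; REML
#' constrains variances to be non-negative. `"ems"` solves the expected mean
#' squares of the balanced design (method of moments) and therefore can
#' return negative component estimates; on balanced data with an interior
#' optimum the two coincide.
#'
#' Lines missing an entire cell of a required factor (e.g. lines with no
#' lead-medium observations) are dropped from the fit, and records flagged
#' `missing` are excluded.
#'
#' @param table Phenotype tibble (see [simulate_phenotypes()] for the schema).
#' @param trait Trait to analyse; defaults to the single trait present.
#' @param model `"full"`, `"no_sex"`, `"within_treatment"`, or `"line_only"`.
#' @param method `"reml"` or `"ems"`.
#' @return An object of class `"lead_varcomp"`: a list with `varcomp`
#'   (tibble: term, variance), `fixed` (tibble: term, statistic, df1, df2,
#'   p_value), plus `method`, `model`, `trait`, `n_obs`, `n_lines`,
#'   `dropped_lines`.
#' @seealso [broad_sense_h2()], [tidy.lead_varcomp()]
#' @export
fit_anova <- function(table, trait = NULL,
                      model = c("full", "no_sex", "within_treatment", "line_only"),
                      method = c("reml", "ems")) {
  model <- match.arg(model)
  method <- match.arg(method)
  traits <- unique(table$trait)
  if (is.null(trait)) {
    if (length(traits) != 1) abort("`trait` must be given when the table holds several traits")
    trait <- traits
  }
  d <- dplyr::filter(table, .data$trait == !!trait, !.data$missing, !is.na(.data$value))
  if (nrow(d) == 0) abort(sprintf("no usable records for trait '%s'", trait))

  needs_sex <- model %in% c("full", "within_treatment")
  needs_trt <- model %in% c("full", "no_sex")
  if (needs_sex && anyNA(d$sex)) abort("model requires sexed records but `sex` is NA")
  if (needs_sex && dplyr::n_distinct(d$sex) < 2) abort("model requires both sexes")
  if (needs_trt && dplyr::n_distinct(d$treatment) < 2) abort("model requires both treatments")

  # drop lines that lack an entire required cell
  cell_vars <- c(if (needs_sex) "sex", if (needs_trt) "treatment")
  dropped <- character(0)
  if (length(cell_vars) > 0) {
    full_cells <- prod(vapply(cell_vars, function(v) dplyr::n_distinct(d[[v]]), 1L))
    per_line <- d %>%
      dplyr::distinct(dplyr::across(dplyr::all_of(c("line", cell_vars)))) %>%
      dplyr::count(.data$line)
    dropped <- per_line$line[per_line$n < full_cells]
    if (length(dropped) > 0) d <- dplyr::filter(d, !.data$line %in% dropped)
  }
  if (dplyr::n_distinct(d$line) < 2) {
    abort(paste0("fewer than 2 lines with complete cells; dropped: ",
                 paste(dropped, collapse = ", ")))
  }

  # replicate structure: need within-cell variation for a residual stratum
  wcv <- d %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c("line", cell_vars)))) %>%
    dplyr::summarise(n = dplyr::n(), v = var(.data$value), .groups = "drop")
  if (!any(wcv$n >= 2)) abort("need >= 2 replicates in at least one cell")
  if (all(wcv$v[wcv$n >= 2] == 0)) {
    abort("degenerate input: zero within-cell variance everywhere (sigma2_resid = 0)")
  }

  d <- d %>% dplyr::mutate(
    line = factor(.data$line),
    sex = if (needs_sex) factor(.data$sex) else .data$sex,
    treatment = if (needs_trt) factor(.data$treatment) else .data$treatment
  )

  res <- if (method == "reml") fit_reml(d, model) else fit_ems(d, model)

  structure(
    c(res, list(method = method, model = model, trait = trait,
                n_obs = nrow(d), n_lines = dplyr::n_distinct(d$line),
                dropped_lines = dropped)),
    class = "lead_varcomp"
  )
}

vc_terms <- function(model) {
  switch(model,
    full = c("L", "L:S", "L:T", "L:S:T"),
    no_sex = c("L", "L:T"),
    within_treatment = c("L", "L:S"),
    line_only = "L"
  )
}

fit_reml <- function(d, model) {
  fml <- switch(model,
    full = value ~ treatment * sex + (1 | line) + (1 | line:sex) +
      (1 | line:treatment) + (1 | line:sex:treatment),
    no_sex = value ~ treatment + (1 | line) + (1 | line:treatment),
    within_treatment = value ~ sex + (1 | line) + (1 | line:sex),
    line_only = value ~ 1 + (1 | line)
  )
  fit <- lmerTest::lmer(fml, data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  grp_map <- c(line = "L", `line:sex` = "L:S", `line:treatment` = "L:T",
               `line:sex:treatment` = "L:S:T", Residual = "resid")
  varcomp <- tibble::tibble(
    term = unname(grp_map[vc$grp]),
    variance = vc$vcov
  )
  ord <- c(vc_terms(model), "resid")
  varcomp <- varcomp[match(ord, varcomp$term), ]

  fixed <- if (model == "line_only") {
    tibble::tibble(term = character(0), statistic = numeric(0),
                   df1 = numeric(0), df2 = numeric(0), p_value = numeric(0))
  } else {
    at <- as.data.frame(stats::anova(fit, type = 3))
    tibble::tibble(
      term = rownames(at),
      statistic = at$`F value`, df1 = at$NumDF, df2 = at$DenDF,
      p_value = at$`Pr(>F)`
    )
  }
  list(varcomp = varcomp, fixed = fixed, fit = fit)
}

# expected-mean-squares (method-of-moments) solution for the balanced design;
# unlike REML this can return negative variance estimates
fit_ems <- function(d, model) {
  cell_vars <- switch(model,
    full = c("sex", "treatment"), no_sex = "treatment",
    within_treatment = "sex", line_only = character(0)
  )
  counts <- d %>%
    dplyr::count(dplyr::across(dplyr::all_of(c("line", cell_vars)))) %>%
    dplyr::pull(.data$n)
  if (length(unique(counts)) != 1) {
    abort("method = 'ems' requires a balanced design (equal replicates per cell)")
  }
  r <- counts[1]
  s <- if ("sex" %in% cell_vars) nlevels(d$sex) else 1L
  t <- if ("treatment" %in% cell_vars) nlevels(d$treatment) else 1L

  fml <- switch(model,
    full = value ~ line * sex * treatment,
    no_sex = value ~ line * treatment,
    within_treatment = value ~ line * sex,
    line_only = value ~ line
  )
  a <- summary(aov(fml, data = d))[[1]]
  ms <- setNames(a$`Mean Sq`, trimws(rownames(a)))
  ms_e <- ms[["Residuals"]]

  est <- switch(model,
    full = {
      s2_lst <- (ms[["line:sex:treatment"]] - ms_e) / r
      s2_lt <- (ms[["line:treatment"]] - ms[["line:sex:treatment"]]) / (s * r)
      s2_ls <- (ms[["line:sex"]] - ms[["line:sex:treatment"]]) / (t * r)
      s2_l <- (ms[["line"]] - ms[["line:sex"]] - ms[["line:treatment"]] +
                 ms[["line:sex:treatment"]]) / (s * t * r)
      c(L = s2_l, `L:S` = s2_ls, `L:T` = s2_lt, `L:S:T` = s2_lst)
    },
    no_sex = {
      s2_lt <- (ms[["line:treatment"]] - ms_e) / r
      s2_l <- (ms[["line"]] - ms[["line:treatment"]]) / (t * r)
      c(L = s2_l, `L:T` = s2_lt)
    },
    within_treatment = {
      s2_ls <- (ms[["line:sex"]] - ms_e) / r
      s2_l <- (ms[["line"]] - ms[["line:sex"]]) / (s * r)
      c(L = s2_l, `L:S` = s2_ls)
    },
    line_only = c(L = (ms[["line"]] - ms_e) / r)
  )

  varcomp <- tibble::tibble(
    term = c(names(est), "resid"),
    variance = unname(c(est, ms_e))
  )

  # fixed effects tested against the matching line-interaction mean square
  fixed <- if (model == "full") {
    denom <- c(treatment = "line:treatment", sex = "line:sex",
               `sex:treatment` = "line:sex:treatment")
    purrr::map_dfr(names(denom), function(tm) {
      f <- ms[[tm]] / ms[[denom[[tm]]]]
      df1 <- a$Df[trimws(rownames(a)) == tm]
      df2 <- a$Df[trimws(rownames(a)) == denom[[tm]]]
      tibble::tibble(term = tm, statistic = f, df1 = df1, df2 = df2,
                     p_value = pf(f, df1, df2, lower.tail = FALSE))
    })
  } else if (model == "no_sex") {
    f <- ms[["treatment"]] / ms[["line:treatment"]]
    df1 <- a$Df[trimws(rownames(a)) == "treatment"]
    df2 <- a$Df[trimws(rownames(a)) == "line:treatment"]
    tibble::tibble(term = "treatment", statistic = f, df1 = df1, df2 = df2,
                   p_value = pf(f, df1, df2, lower.tail = FALSE))
  } else if (model == "within_treatment") {
    f <- ms[["sex"]] / ms[["line:sex"]]
    df1 <- a$Df[trimws(rownames(a)) == "sex"]
    df2 <- a$Df[trimws(rownames(a)) == "line:sex"]
    tibble::tibble(term = "sex", statistic = f, df1 = df1, df2 = df2,
                   p_value = pf(f, df1, df2, lower.tail = FALSE))
  } else {
    tibble::tibble(term = character(0), statistic = numeric(0),
                   df1 = numeric(0), df2 = numeric(0), p_value = numeric(0))
  }
  # Table-style F tests for the random line terms: each mean square over its
  # expected-mean-squares denominator; the line main effect needs a
  # Satterthwaite-synthesized denominator (MS_LS + MS_LT - MS_LST)
  ftest <- function(num_ms, num_df, den_ms, den_df) {
    f <- num_ms / den_ms
    tibble::tibble(statistic = f, df1 = num_df, df2 = den_df,
                   p_value = pf(f, num_df, den_df, lower.tail = FALSE))
  }
  dfs <- setNames(a$Df, trimws(rownames(a)))
  random <- switch(model,
    full = {
      den_l <- ms[["line:sex"]] + ms[["line:treatment"]] - ms[["line:sex:treatment"]]
      df_l <- den_l^2 / (ms[["line:sex"]]^2 / dfs[["line:sex"]] +
                           ms[["line:treatment"]]^2 / dfs[["line:treatment"]] +
                           ms[["line:sex:treatment"]]^2 / dfs[["line:sex:treatment"]])
      dplyr::bind_rows(
        dplyr::mutate(ftest(ms[["line"]], dfs[["line"]], den_l, df_l), term = "L"),
        dplyr::mutate(ftest(ms[["line:sex"]], dfs[["line:sex"]],
                            ms[["line:sex:treatment"]], dfs[["line:sex:treatment"]]),
                      term = "L:S"),
        dplyr::mutate(ftest(ms[["line:treatment"]], dfs[["line:treatment"]],
                            ms[["line:sex:treatment"]], dfs[["line:sex:treatment"]]),
                      term = "L:T"),
        dplyr::mutate(ftest(ms[["line:sex:treatment"]], dfs[["line:sex:treatment"]],
                            ms_e, dfs[["Residuals"]]), term = "L:S:T")
      )
    },
    no_sex = dplyr::bind_rows(
      dplyr::mutate(ftest(ms[["line"]], dfs[["line"]],
                          ms[["line:treatment"]], dfs[["line:treatment"]]), term = "L"),
      dplyr::mutate(ftest(ms[["line:treatment"]], dfs[["line:treatment"]],
                          ms_e, dfs[["Residuals"]]), term = "L:T")
    ),
    within_treatment = dplyr::bind_rows(
      dplyr::mutate(ftest(ms[["line"]], dfs[["line"]],
                          ms[["line:sex"]], dfs[["line:sex"]]), term = "L"),
      dplyr::mutate(ftest(ms[["line:sex"]], dfs[["line:sex"]],
                          ms_e, dfs[["Residuals"]]), term = "L:S")
    ),
    line_only = dplyr::mutate(ftest(ms[["line"]], dfs[["line"]],
                                    ms_e, dfs[["Residuals"]]), term = "L")
  )
  random <- dplyr::relocate(random, "term")

  list(varcomp = varcomp, fixed = fixed, random = random, fit = NULL)
}

#' @export
print.lead_varcomp <- function(x, ...) {
  cat(sprintf("<lead_varcomp> trait '%s', model '%s' (%s), %d lines, %d obs\n",
              x$trait, x$model, toupper(x$method), x$n_lines, x$n_obs))
  if (length(x$dropped_lines) > 0) {
    cat(sprintf("  dropped %d line(s) with incomplete cells\n", length(x$dropped_lines)))
  }
  print(as.data.frame(x$varcomp), row.names = FALSE)
  invisible(x)
}

#' @describeIn fit_anova Variance components as a tibble.
#' @param x A `lead_varcomp` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.lead_varcomp <- function(x, ...) x$varcomp

#' @describeIn fit_anova One-row model summary (components wide + H2).
#' @exportS3Method generics::glance
glance.lead_varcomp <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$varcomp, names_from = "term",
                             values_from = "variance",
                             names_prefix = "sigma2_")
  h2 <- broad_sense_h2(x)
  dplyr::bind_cols(wide, h2["H2"],
                   tibble::tibble(n_lines = x$n_lines, n_obs = x$n_obs))
}

#' Broad-sense heritability from variance components
#'
#' Computes \eqn{H^2 = \sigma^2_G / \sigma^2_P} where \eqn{\sigma^2_G} is
#' the sum of all line-associated (genetic) variance components of the model
#' and \eqn{\sigma^2_P = \sigma^2_G + \varepsilon}. For the full model
#' \eqn{\sigma^2_G = \sigma^2_L + \sigma^2_{L \times S} + \sigma^2_{L \times
#' T} + \sigma^2_{L \times S \times T}}; for the unsexed (viability) model
#' \eqn{\sigma^2_L + \sigma^2_{L \times T}}; within one treatment
#' \eqn{\sigma^2_L + \sigma^2_{L \times S}}. Components are used exactly as
#' estimated — negative method-of-moments estimates included — and the
#' resulting ratio is clamped to \[0, 1\] (the unclamped value is also
#' reported).
#'
#' @param x A [fit_anova()] result, or a named numeric vector of variance
#'   components with a `resid` entry (all other entries are treated as
#'   genetic), e.g. `c(L = 1.7, "L:T" = 1.9, resid = 0.9)`.
#' @param model Model whose component set is required when `x` is a named
#'   vector; inferred from the fit otherwise.
#' @return A one-row tibble: `sigma2_G`, `sigma2_P`, `H2`, `H2_unclamped`.
#' @examples
#' broad_sense_h2(c(L = 2, resid = 2))  # H2 = 0.5
#' @export
broad_sense_h2 <- function(x, model = NULL) {
  if (inherits(x, "lead_varcomp")) {
    comp <- setNames(x$varcomp$variance, x$varcomp$term)
    model <- model %||% x$model
  } else {
    comp <- x
    if (is.null(names(comp)) || !"resid" %in% names(comp)) {
      abort("named components with a 'resid' entry are required")
    }
  }
  if (!is.null(model)) {
    need <- c(vc_terms(model), "resid")
    miss <- setdiff(need, names(comp))
    if (length(miss) > 0) {
      abort(sprintf("missing required component(s) for model '%s': %s",
                    model, paste(miss, collapse = ", ")))
    }
    comp <- comp[need]
  }
  g <- sum(comp[setdiff(names(comp), "resid")])
  p <- g + comp[["resid"]]
  h2_raw <- g / p
  tibble::tibble(
    sigma2_G = g, sigma2_P = p,
    H2 = min(max(h2_raw, 0), 1), H2_unclamped = h2_raw
  )
}

#' Cell means of a phenotype table
#'
#' Arithmetic mean of non-missing observations per grouping cell, with the
#' number of contributing records; cells whose records are all missing get
#' an `NA` mean with `n = 0`.
#'
#' @param table Phenotype tibble.
#' @param by Grouping columns (always includes `trait`).
#' @return Tibble with the grouping columns, `mean`, `n`.
#' @export
line_means <- function(table, by = c("line", "sex", "treatment")) {
  by <- union(by, "trait")
  table %>%
    dplyr::mutate(value = ifelse(.data$missing, NA_real_, .data$value)) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = if (sum(!is.na(.data$value)) > 0) mean(.data$value, na.rm = TRUE) else NA_real_,
      .groups = "drop"
    ) %>%
    dplyr::relocate("mean", .before = "n")
}

#' Per-line sensitivity to lead exposure
#'
#' The sensitivity phenotype of a line (per sex where applicable) is the
#' difference of its treatment cell means, with the convention
#' `sensitivity = mean_control - mean_lead`. It is defined only when both
#' cell means exist; lines lethal on lead medium therefore propagate `NA`
#' and drop out of downstream association scans.
#'
#' @param means Cell-mean tibble from [line_means()] grouped at least by
#'   `line` and `treatment`.
#' @return Tibble with `line` (and `sex` if present), `trait`,
#'   `mean_control`, `mean_lead`, `sensitivity`.
#' @export
sensitivity <- function(means) {
  stopifnot(all(c("line", "treatment", "mean") %in% names(means)))
  keys <- intersect(c("line", "sex", "trait"), names(means))
  means %>%
    dplyr::select(dplyr::all_of(c(keys, "treatment", "mean"))) %>%
    tidyr::pivot_wider(names_from = "treatment", values_from = "mean",
                       names_prefix = "mean_") %>%
    dplyr::mutate(sensitivity = .data$mean_control - .data$mean_lead)
}

#' Correlation of two sensitivity phenotypes across lines
#'
#' Pearson correlation of per-line sensitivity values between two traits
#' (values are averaged over sex first where sexed), over the lines present
#' with non-missing sensitivity in both tables.
#'
#' @param a,b Sensitivity tibbles from [sensitivity()].
#' @return One-row tibble: `estimate` (Pearson R), `p_value` (two-sided),
#'   `n` (lines used).
#' @export
trait_correlation <- function(a, b) {
  collapse <- function(s) {
    s %>%
      dplyr::filter(!is.na(.data$sensitivity)) %>%
      dplyr::group_by(.data$line) %>%
      dplyr::summarise(sensitivity = mean(.data$sensitivity), .groups = "drop")
  }
  ab <- dplyr::inner_join(collapse(a), collapse(b), by = "line",
                          suffix = c("_a", "_b"))
  if (nrow(ab) < 3) abort("need >= 3 lines shared between the two tables")
  ct <- cor.test(ab$sensitivity_a, ab$sensitivity_b, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate), p_value = ct$p.value, n = nrow(ab))
}
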