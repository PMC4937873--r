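#' Simulate a mutant-validation assay
#'
#' Generates replicate-level observations for transposon-insertion mutant
#' lines and their co-isogenic control measured on lead and regular food,
#' for the two-way validation ANOVA. Each mutant's line-by-treatment
#' interaction effect (its true shift in lead sensitivity relative to the
#' control background) is set by `interaction`.
#'
#' @param n_mutants Number of mutant lines (named `mutant_1`, ...).
#' @param interaction Scalar or per-mutant vector: shift added to
#'   mutant-on-lead observations (0 = null).
#' @param line_effect Fixed shift of mutant lines on both foods.
#' @param treat_effect Fixed shift of all lead-food observations.
#' @param mu Grand mean (e.g. days of development time).
#' @param sd Residual standard deviation between replicates.
#' @param reps Replicates per line x treatment x sex cell.
#' @param sexes Sexes measured, default `c("F", "M")`.
#' @param seed Integer seed.
#' @return Tibble: `line` (`control` or `mutant_i`), `treatment`
#'   (`regular`/`lead`), `sex`, `replicate`, `value`.
#' @export
simulate_mutant_assay <- function(n_mutants = 1, interaction = 0,
                                  line_effect = 0, treat_effect = 3,
                                  mu = 10.7, sd = 1, reps = 5,
                                  sexes = c("F", "M"), seed = 1) {
  interaction <- rep_len(interaction, n_mutants)
  lines <- c("control", paste0("mutant_", seq_len(n_mutants)))
  with_seed(seed, {
    grid <- tidyr::expand_grid(
      line = lines, treatment = c("regular", "lead"),
      sex = sexes, replicate = seq_len(reps)
    )
    is_mut <- grid$line != "control"
    idx <- match(grid$line, paste0("mutant_", seq_len(n_mutants)))
    int_eff <- interaction[idx]
    int_eff[is.na(int_eff)] <- 0
    eta <- mu +
      ifelse(is_mut, line_effect, 0) +
      ifelse(grid$treatment == "lead", treat_effect, 0) +
      ifelse(grid$treatment == "lead", int_eff, 0)
    grid$value <- eta + rnorm(nrow(grid), 0, sd)
    grid
  })
}

#' Two-way mutant-validation ANOVA
#'
#' Tests whether a mutant line's response to lead differs from its
#' co-isogenic control with the fixed-effects model
#' \eqn{Y = \mu + L + T + L \times T + Rep(L \times T) + \varepsilon},
#' where `L` contrasts mutant vs control and `T` lead vs regular food. A
#' significant line-by-treatment interaction (p < 0.05) indicates an effect
#' of the mutation on lead sensitivity. With one observation per replicate
#' the replicate stratum and the residual merge (the default); set
#' `rep_stratum = TRUE` to test the interaction against the
#' replicate-within-cell mean square when replicates are vials containing
#' several measured flies.
#'
#' The sensitivity statistic is the difference-of-differences of cell means,
#' `(lead[mutant - control]) - (regular[mutant - control])`, and its
#' combined SEM is \eqn{\sqrt{SE_l^2 + SE_r^2}} where \eqn{SE_l, SE_r} are
#' the standard errors of the mutant-minus-control difference on lead and
#' regular food.
#'
#' @param assay Tibble from [simulate_mutant_assay()] or with the same
#'   schema (`line`, `treatment` in `regular`/`lead`, `replicate`, `value`,
#'   optionally `sex`).
#' @param mutant Mutant line id to test against `control`.
#' @param sex Optional sex filter (sexes are analyzed separately).
#' @param control Control line label, default `"control"`.
#' @param rep_stratum Test the interaction against the Rep(LxT) stratum.
#' @return One-row tibble: `mutant`, `sex`, `statistic` (interaction F),
#'   `df1`, `df2`, `p_value`, `significant` (p < 0.05), `sensitivity`,
#'   `se_lead`, `se_regular`, `sem_combined`.
#' @export
fit_mutant_anova <- function(assay, mutant, sex = NULL, control = "control",
                             rep_stratum = FALSE) {
  d <- dplyr::filter(assay, .data$line %in% c(mutant, control))
  if (!is.null(sex)) d <- dplyr::filter(d, .data$sex == !!sex)
  d <- dplyr::filter(d, !is.na(.data$value))

  cells <- d %>% dplyr::count(.data$line, .data$treatment)
  want <- tidyr::expand_grid(line = c(control, mutant),
                             treatment = c("regular", "lead"))
  missing_cells <- dplyr::anti_join(want, cells, by = c("line", "treatment"))
  low <- cells$n < 2
  if (nrow(missing_cells) > 0 || any(low)) {
    bad <- dplyr::bind_rows(missing_cells,
                            cells[low, c("line", "treatment")])
    abort(sprintf("cell(s) missing or with < 2 replicates: %s",
                  paste(paste(bad$line, bad$treatment, sep = "/"), collapse = ", ")))
  }

  d <- d %>% dplyr::mutate(line = factor(.data$line, levels = c(control, mutant)),
                           treatment = factor(.data$treatment,
                                              levels = c("regular", "lead")))
  if (rep_stratum) {
    # replicate vials nested in line x treatment form the error stratum
    d$rep_id <- factor(d$replicate)
    a <- summary(aov(value ~ line * treatment + line:treatment:rep_id,
                     data = d))[[1]]
    rn <- trimws(rownames(a))
    f <- a[rn == "line:treatment", "Mean Sq"] /
      a[rn == "line:treatment:rep_id", "Mean Sq"]
    df1 <- a$Df[rn == "line:treatment"]
    df2 <- a$Df[rn == "line:treatment:rep_id"]
  } else {
    a <- summary(aov(value ~ line * treatment, data = d))[[1]]
    rn <- trimws(rownames(a))
    f <- a[rn == "line:treatment", "Mean Sq"] / a[rn == "Residuals", "Mean Sq"]
    df1 <- a$Df[rn == "line:treatment"]
    df2 <- a$Df[rn == "Residuals"]
  }
  p <- pf(f, df1, df2, lower.tail = FALSE)

  cm <- d %>%
    dplyr::group_by(.data$line, .data$treatment) %>%
    dplyr::summarise(mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()), .groups = "drop")
  pick <- function(l, t, col) cm[[col]][cm$line == l & cm$treatment == t]
  sens <- (pick(mutant, "lead", "mean") - pick(control, "lead", "mean")) -
    (pick(mutant, "regular", "mean") - pick(control, "regular", "mean"))
  se_l <- sqrt(pick(mutant, "lead", "se")^2 + pick(control, "lead", "se")^2)
  se_r <- sqrt(pick(mutant, "regular", "se")^2 + pick(control, "regular", "se")^2)

  tibble::tibble(
    mutant = mutant, sex = if (is.null(sex)) NA_character_ else sex,
    statistic = f, df1 = df1, df2 = df2, p_value = p,
    significant = p < 0.05,
    sensitivity = sens, se_lead = se_l, se_regular = se_r,
    sem_combined = sqrt(se_l^2 + se_r^2)
  )
}

#' Functional validation rate across sexes
#'
#' Averages the per-sex success fractions of mutant validation and reports
#' the result as a percentage:
#' `((n_female/n) + (n_male/n)) / 2 * 100`.
#'
#' @param n_female,n_male Number of mutants with a significant
#'   line-by-treatment interaction in females and males.
#' @param n_tested Number of mutants tested (>= 1).
#' @return One-row tibble: `n_tested`, `n_significant_female`,
#'   `n_significant_male`, `rate_percent`.
#' @examples
#' validation_rate(11, 13, 16)  # 75
#' validation_rate(4, 2, 4)     # 75
#' @export
validation_rate <- function(n_female, n_male, n_tested) {
  if (n_tested < 1) abort("`n_tested` must be >= 1")
  stopifnot(n_female >= 0, n_male >= 0, n_female <= n_tested, n_male <= n_tested)
  tibble::tibble(
    n_tested = n_tested,
    n_significant_female = n_female,
    n_significant_male = n_male,
    rate_percent = ((n_female / n_tested) + (n_male / n_tested)) / 2 * 100
  )
}
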