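#' Simulation parameters for replicate-level phenotypes
#'
#' Holds the generative model for one trait measured on a line panel under a
#' control/lead treatment contrast:
#' \deqn{Y = \mu + L + S + T + L{\times}S + L{\times}T + S{\times}T +
#'       L{\times}S{\times}T + \varepsilon,}
#' with line terms drawn once per line (and per interaction cell) from
#' zero-mean Gaussians with the stated variances, fixed treatment/sex shifts,
#' and optional causal variant effects acting on either the trait level or on
#' the control-minus-lead sensitivity contrast. Viability is generated on a
#' latent logit scale and realized as a binomial draw of survivors out of 50
#' larvae per replicate vial.
#'
#' @param mu Grand mean, in trait units (logit scale for viability).
#' @param var_L,var_LxS,var_LxT,var_LxSxT Variance components (trait units^2)
#'   of the line main effect and its interactions with sex and treatment.
#' @param var_resid Residual (within-cell, between-replicate) variance.
#' @param fixed_T Fixed shift added to lead-treatment observations.
#' @param fixed_S Fixed shift added to male observations.
#' @param fixed_SxT Additional fixed shift for male x lead observations.
#' @param causal_effects `NULL`, or a tibble/data.frame with columns
#'   `variant_id`, `effect`, `acts_on` (`"level"` or `"sensitivity"`). A
#'   `"level"` effect shifts every observation of carrier lines by
#'   `effect` per coded allele; a `"sensitivity"` effect shifts the
#'   control-minus-lead contrast by `effect` (implemented as a `-effect`
#'   shift of lead observations), creating true sensitivity signal for
#'   association power studies.
#' @param reps_per_cell Replicates per line x sex x treatment cell
#'   (vials for development time and viability, individual flies for
#'   activity).
#' @param lethal_line_fraction Fraction of lines expected to be non-viable on
#'   lead medium; consumed by callers choosing lines for
#'   [inject_lethality()], not by the generator itself.
#'
#' @return A list of class `"sim_params"`.
#' @seealso [default_sim_params()], [simulate_phenotypes()]
#' @export
sim_params <- function(mu = 0, var_L = 0, var_LxS = 0, var_LxT = 0,
                       var_LxSxT = 0, var_resid = 1,
                       fixed_T = 0, fixed_S = 0, fixed_SxT = 0,
                       causal_effects = NULL, reps_per_cell = 5,
                       lethal_line_fraction = 0) {
  vars <- c(var_L = var_L, var_LxS = var_LxS, var_LxT = var_LxT,
            var_LxSxT = var_LxSxT, var_resid = var_resid)
  if (any(vars < 0)) abort("variance components must be >= 0")
  if (reps_per_cell < 1) abort("`reps_per_cell` must be >= 1")
  if (!is.null(causal_effects)) {
    causal_effects <- tibble::as_tibble(causal_effects)
    stopifnot(all(c("variant_id", "effect", "acts_on") %in% names(causal_effects)))
    if (!all(causal_effects$acts_on %in% c("level", "sensitivity"))) {
      abort("`acts_on` must be 'level' or 'sensitivity'")
    }
  }
  structure(
    list(mu = mu, var_L = var_L, var_LxS = var_LxS, var_LxT = var_LxT,
         var_LxSxT = var_LxSxT, var_resid = var_resid,
         fixed_T = fixed_T, fixed_S = fixed_S, fixed_SxT = fixed_SxT,
         causal_effects = causal_effects, reps_per_cell = as.integer(reps_per_cell),
         lethal_line_fraction = lethal_line_fraction),
    class = "sim_params"
  )
}

#' Study-condition defaults per trait
#'
#' Default generative parameters matching the design of the lead-exposure
#' DGRP screen: development time in days (grand mean 10.7 d on control food,
#' +3.0 d fixed lead effect, replicate vials of 50 larvae, variance
#' components from the published full-model ANOVA of development time);
#' activity as beam-crossing counts over 2 days (20 flies per sex, published
#' activity variance components); viability as survivors out of 50 larvae on
#' a latent logit scale (60\% control survival, 35\% on lead).
#'
#' @param trait One of `"dev_time"`, `"viability"`, `"activity"`.
#' @return A [sim_params()] object.
#' @export
default_sim_params <- function(trait = c("dev_time", "viability", "activity")) {
  trait <- match.arg(trait)
  switch(trait,
    dev_time = sim_params(
      mu = 10.7, fixed_T = 3.0, fixed_S = 0.1, fixed_SxT = 0.1,
      var_L = 1.728, var_LxS = 0.003, var_LxT = 1.913, var_LxSxT = 0,
      var_resid = 0.920, reps_per_cell = 5, lethal_line_fraction = 0.06
    ),
    viability = sim_params(
      mu = qlogis(0.60), fixed_T = qlogis(0.35) - qlogis(0.60),
      var_L = 0.5, var_LxT = 0.4, var_resid = 0, reps_per_cell = 5,
      lethal_line_fraction = 0.06
    ),
    activity = sim_params(
      mu = 1500, fixed_T = 0, fixed_S = 0, fixed_SxT = 0,
      var_L = 121983.4, var_LxS = 18092.6, var_LxT = 5230.5,
      var_LxSxT = 9218.6, var_resid = 273941.6, reps_per_cell = 20
    )
  )
}

n_larvae_per_vial <- 50L

#' Simulate a replicate-level phenotype table
#'
#' Generates long-format observations (one row per replicate vial or fly)
#' for one trait under the Gaussian-ANOVA model of [sim_params()].
#' Development time and activity are measured per sex; viability is a single
#' proportion per vial (larval sex is not determined, so `sex` is `NA`) and
#' is realized as a binomial number of survivors out of 50 larvae on a
#' latent logit-Gaussian per-line survival probability.
#'
#' @param panel A [simulate_panel()] result.
#' @param params A [sim_params()] object.
#' @param trait `"dev_time"`, `"viability"` or `"activity"`.
#' @param seed Integer seed; fully determines the table.
#' @return A tibble with columns `line`, `sex` (`"F"`/`"M"`, `NA` for
#'   viability), `treatment` (`"control"`/`"lead"`), `replicate`, `trait`,
#'   `value`, `missing` (logical). Viability values lie in \[0, 1\] and are
#'   integer multiples of 1/50.
#' @examples
#' pan <- simulate_panel(panel_config(n_lines = 10, n_variants = 0, seed = 1))
#' ph <- simulate_phenotypes(pan, default_sim_params("dev_time"), "dev_time", seed = 2)
#' head(ph)
#' @export
simulate_phenotypes <- function(panel, params, trait, seed = 1) {
  stopifnot(inherits(panel, "line_panel"), inherits(params, "sim_params"))
  if (!trait %in% c("dev_time", "viability", "activity")) {
    abort(sprintf("unknown trait '%s'", trait))
  }
  ce <- params$causal_effects
  if (!is.null(ce) && nrow(ce) > 0 &&
      !all(ce$variant_id %in% colnames(panel$genotypes))) {
    missing_v <- setdiff(ce$variant_id, colnames(panel$genotypes))
    abort(sprintf("causal variant(s) not in panel: %s",
                  paste(missing_v, collapse = ", ")))
  }

  with_seed(seed, {
    lines <- panel$line_ids
    n <- length(lines)
    sexes <- if (trait == "viability") NA_character_ else c("F", "M")
    trts <- c("control", "lead")
    r <- params$reps_per_cell

    # random line terms, one draw per line / per interaction cell
    eff_L <- setNames(rnorm(n, 0, sqrt(params$var_L)), lines)
    cell_key <- function(...) paste(..., sep = ".")
    eff_LxT <- setNames(rnorm(n * 2, 0, sqrt(params$var_LxT)),
                        cell_key(rep(lines, each = 2), rep(trts, n)))
    if (trait != "viability") {
      eff_LxS <- setNames(rnorm(n * 2, 0, sqrt(params$var_LxS)),
                          cell_key(rep(lines, each = 2), rep(sexes, n)))
      eff_LxSxT <- setNames(
        rnorm(n * 4, 0, sqrt(params$var_LxSxT)),
        cell_key(rep(lines, each = 4), rep(rep(sexes, each = 2), n), rep(trts, 2 * n))
      )
    }

    # per-line causal shifts: level acts everywhere, sensitivity shifts lead
    shift_level <- setNames(numeric(n), lines)
    shift_lead <- setNames(numeric(n), lines)
    if (!is.null(ce) && nrow(ce) > 0) {
      for (i in seq_len(nrow(ce))) {
        g <- panel$genotypes[, ce$variant_id[i]]
        if (ce$acts_on[i] == "level") {
          shift_level <- shift_level + ce$effect[i] * g
        } else {
          shift_lead <- shift_lead - ce$effect[i] * g
        }
      }
    }

    grid <- tidyr::expand_grid(
      line = lines, sex = sexes, treatment = trts,
      replicate = seq_len(r)
    )
    eta <- params$mu +
      eff_L[grid$line] +
      eff_LxT[cell_key(grid$line, grid$treatment)] +
      ifelse(grid$treatment == "lead", params$fixed_T, 0) +
      shift_level[grid$line] +
      ifelse(grid$treatment == "lead", shift_lead[grid$line], 0)
    if (trait != "viability") {
      eta <- eta +
        eff_LxS[cell_key(grid$line, grid$sex)] +
        eff_LxSxT[cell_key(grid$line, grid$sex, grid$treatment)] +
        ifelse(grid$sex == "M", params$fixed_S, 0) +
        ifelse(grid$sex == "M" & grid$treatment == "lead", params$fixed_SxT, 0)
    }

    value <- if (trait == "viability") {
      p <- plogis(eta + rnorm(nrow(grid), 0, sqrt(params$var_resid)))
      rbinom(nrow(grid), n_larvae_per_vial, p) / n_larvae_per_vial
    } else {
      out <- eta + rnorm(nrow(grid), 0, sqrt(params$var_resid))
      if (trait == "activity") pmax(out, 0) else out
    }

    tibble::tibble(
      line = grid$line, sex = grid$sex, treatment = grid$treatment,
      replicate = grid$replicate, trait = trait,
      value = unname(value), missing = FALSE
    )
  })
}

#' Mark lines as non-viable on lead medium
#'
#' Emulates lethality of sensitive lines at the screening dose: affected
#' lines contribute no development-time or activity observations on lead
#' medium (records flagged missing with `NA` value), and their lead-medium
#' viability is an observed zero. With `mode = "females_only"` (lines that
#' produced only male offspring on lead) only female records of sexed traits
#' are affected; viability, which is unsexed, is left unchanged.
#'
#' @param table A phenotype tibble from [simulate_phenotypes()] (any traits,
#'   possibly row-bound).
#' @param lines Character vector of line ids to affect.
#' @param mode `"both_sexes"` (line fully non-viable on lead) or
#'   `"females_only"`.
#' @return The table with the affected records updated.
#' @export
inject_lethality <- function(table, lines,
                             mode = c("both_sexes", "females_only")) {
  mode <- match.arg(mode)
  if (length(lines) == 0) return(table)
  unknown <- setdiff(lines, unique(table$line))
  if (length(unknown) > 0) {
    abort(sprintf("unknown line id(s): %s", paste(unknown, collapse = ", ")))
  }
  hit <- table$line %in% lines & table$treatment == "lead"
  sexed <- table$trait %in% c("dev_time", "activity")
  if (mode == "females_only") {
    hit_sexed <- hit & sexed & table$sex %in% "F"
    hit_via <- rep(FALSE, nrow(table))
  } else {
    hit_sexed <- hit & sexed
    hit_via <- hit & table$trait == "viability"
  }
  table$value[hit_sexed] <- NA_real_
  table$missing[hit_sexed] <- TRUE
  table$value[hit_via] <- 0
  table
}
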