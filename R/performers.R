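#' Classify lines as good or poor performers on lead medium
#'
#' Runs a per-line Welch two-sample t-test between lead-exposed and control
#' replicates. A line is a `"poor"` performer when it is significantly worse
#' on lead at the nominal level (slower development, lower viability or
#' activity); every other line — including lines significantly *better* on
#' lead — is a `"good"` performer. No correction across lines is applied.
#'
#' @param table Phenotype tibble.
#' @param trait Trait to classify on.
#' @param sex Optional sex filter (`"F"`/`"M"`); required direction of
#'   "worse" is higher values on lead for `dev_time`, lower for `viability`
#'   and `activity`.
#' @param alpha Nominal per-line significance level, default 0.05.
#' @return Tibble with `line`, `trait`, `sex`, `statistic` (Welch t),
#'   `p_value`, `class`; lines with fewer than 2 usable replicates per
#'   treatment are skipped (a warning reports how many).
#' @export
classify_lines <- function(table, trait, sex = NULL, alpha = 0.05) {
  worse_is_higher <- trait == "dev_time"
  d <- dplyr::filter(table, .data$trait == !!trait, !.data$missing,
                     !is.na(.data$value))
  if (!is.null(sex)) d <- dplyr::filter(d, .data$sex == !!sex)
  if (nrow(d) == 0) abort(sprintf("no usable records for trait '%s'", trait))

  skipped <- 0L
  out <- d %>%
    dplyr::group_by(.data$line) %>%
    dplyr::group_map(function(g, key) {
      ctl <- g$value[g$treatment == "control"]
      pb <- g$value[g$treatment == "lead"]
      if (length(ctl) < 2 || length(pb) < 2 ||
          (sd(ctl) == 0 && sd(pb) == 0)) {
        skipped <<- skipped + 1L
        return(NULL)
      }
      tt <- t.test(pb, ctl, var.equal = FALSE)
      worse <- if (worse_is_higher) mean(pb) > mean(ctl) else mean(pb) < mean(ctl)
      tibble::tibble(
        line = key$line, trait = trait,
        sex = if (is.null(sex)) NA_character_ else sex,
        statistic = unname(tt$statistic), p_value = tt$p.value,
        class = if (tt$p.value < alpha && worse) "poor" else "good"
      )
    }) %>%
    dplyr::bind_rows()
  if (skipped > 0) {
    warn(sprintf("%d line(s) skipped: fewer than 2 informative replicates per treatment",
                 skipped))
  }
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error level in (0, 1), default 0.05.
#' @param m Number of tests in the family (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 42)   # 1.19e-3
#' bonferroni_threshold(0.05, 113)  # 4.42e-4
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) abort("`m` must be >= 1")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  alpha / m
}

# Firth-penalized logistic regression (Jeffreys-prior score correction);
# used as the separation fallback, where plain ML diverges
firth_logistic <- function(y, X, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    XtWX <- crossprod(X * w, X)
    inv <- solve(XtWX)
    # hat diagonal of the weighted design
    h <- rowSums((X %*% inv) * X) * w
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- inv %*% U
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(inv))
  list(coef = beta, se = se)
}

#' Allele enrichment among good performers by logistic regression
#'
#' For each supplied variant, regresses performer class (good = 1) on the
#' 0/1 line genotype code and tests the genotype coefficient with a
#' likelihood-ratio test. The family of tests is Bonferroni-corrected with
#' `m` = number of variants tested. Complete or quasi-complete separation
#' (a pure genotype-by-class cell) is detected and handled with a
#' Firth-penalized fit, always flagged; genotypes constant across the
#' classified lines are flagged `"no_variation"` with no estimate.
#'
#' @param calls Performer calls from [classify_lines()].
#' @param panel A `line_panel` providing genotypes.
#' @param variants Character vector of variant ids to test (typically the
#'   GWA top hits).
#' @param alpha Family-wise level before correction, default 0.05.
#' @return Tibble with `variant_id`, `estimate` (log-odds of being a good
#'   performer per coded allele), `se`, `p_value`, `m`, `alpha`,
#'   `bonferroni_alpha`, `significant`, `flag`.
#' @export
logistic_enrichment <- function(calls, panel, variants, alpha = 0.05) {
  stopifnot(all(variants %in% colnames(panel$genotypes)))
  lines_used <- intersect(calls$line, panel$line_ids)
  calls <- calls[match(lines_used, calls$line), ]
  y <- as.integer(calls$class == "good")
  if (length(unique(y)) < 2) abort("need at least one good and one poor line")
  m <- length(variants)
  thr <- bonferroni_threshold(alpha, m)

  purrr::map_dfr(variants, function(v) {
    g <- panel$genotypes[lines_used, v]
    if (length(unique(g)) < 2) {
      return(tibble::tibble(variant_id = v, estimate = NA_real_, se = NA_real_,
                            p_value = NA_real_, m = m, alpha = alpha,
                            bonferroni_alpha = thr, significant = FALSE,
                            flag = "no_variation"))
    }
    sep <- any(table(factor(y, levels = 0:1), factor(g)) == 0)
    if (!sep) {
      fit <- stats::glm(y ~ g, family = stats::binomial())
      null_dev <- fit$null.deviance
      lr <- null_dev - fit$deviance
      p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
      sm <- summary(fit)$coefficients
      tibble::tibble(variant_id = v, estimate = sm["g", 1], se = sm["g", 2],
                     p_value = p, m = m, alpha = alpha, bonferroni_alpha = thr,
                     significant = p < thr, flag = NA_character_)
    } else {
      ff <- firth_logistic(y, cbind(1, g))
      z <- ff$coef[2] / ff$se[2]
      p <- 2 * stats::pnorm(-abs(z))
      tibble::tibble(variant_id = v, estimate = ff$coef[2], se = ff$se[2],
                     p_value = p, m = m, alpha = alpha, bonferroni_alpha = thr,
                     significant = p < thr, flag = "separation")
    }
  })
}
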