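#' Minor-allele-frequency filter
#'
#' Keeps variants whose folded minor allele frequency, computed over lines
#' with non-missing genotypes, is at least `maf_min` (boundary inclusive:
#' a variant carried by exactly `maf_min` of the lines is kept).
#' Monomorphic variants are always excluded.
#'
#' @param panel A [simulate_panel()] result (or any `line_panel`).
#' @param maf_min Minimum minor allele frequency in (0, 0.5], default 0.05.
#' @return Character vector of retained variant ids.
#' @export
maf_filter <- function(panel, maf_min = 0.05) {
  stopifnot(maf_min > 0, maf_min <= 0.5)
  if (ncol(panel$genotypes) == 0) return(character(0))
  f <- colMeans(panel$genotypes, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  colnames(panel$genotypes)[maf >= maf_min]
}

#' Single-marker association test
#'
#' Ordinary least-squares regression of a per-line phenotype on one
#' genotype column (0/1 allele code for homozygous inbred lines) plus
#' optional covariate columns, with a two-sided t-test on the genotype
#' coefficient. Rank-deficient designs (genotype collinear with a
#' covariate) and zero-residual perfect fits are returned flagged rather
#' than with a fabricated p-value.
#'
#' @param y Numeric per-line phenotype.
#' @param g Numeric per-line genotype code.
#' @param covariates Optional data.frame of per-line covariates (numeric or
#'   factor); expanded via [stats::model.matrix()].
#' @return One-row tibble: `effect`, `se`, `statistic`, `p_value`, `n`,
#'   `flag` (`NA`, `"collinear"` or `"perfect_fit"`).
#' @export
single_marker_test <- function(y, g, covariates = NULL) {
  stopifnot(length(y) == length(g))
  dat <- data.frame(.y = y, .g = g)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(y))
    dat <- cbind(dat, as.data.frame(covariates))
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  cov_cols <- setdiff(names(dat), c(".y", ".g"))
  Xc <- if (length(cov_cols) == 0) {
    matrix(1, nrow = n, ncol = 1)
  } else {
    stats::model.matrix(~., data = dat[, cov_cols, drop = FALSE])
  }
  p_cov <- qr(Xc)$rank
  if (n < p_cov + 2) abort("too few complete lines for the model")
  res <- marker_scan(dat$.y, matrix(dat$.g, ncol = 1), Xc)
  tibble::tibble(effect = res$effect, se = res$se, statistic = res$statistic,
                 p_value = res$p_value, n = n, flag = res$flag)
}

# vectorized OLS scan: residualize y and every genotype column on the
# covariate design, then test each genotype coefficient by its t statistic
marker_scan <- function(y, G, Xc) {
  qrX <- qr(Xc)
  p <- qrX$rank
  n <- length(y)
  y_r <- qr.resid(qrX, y)
  G_r <- qr.resid(qrX, G)
  gg <- colSums(G_r^2)
  gy <- as.vector(crossprod(G_r, y_r))
  yy <- sum(y_r^2)
  df <- n - p - 1
  beta <- gy / gg
  rss <- yy - beta^2 * gg
  scale_tol <- max(yy, 1) * 1e-12
  collinear <- gg < n * 1e-12
  sigma2 <- rss / df
  se <- sqrt(pmax(sigma2, 0) / gg)
  stat <- beta / se
  pval <- 2 * pt(-abs(stat), df)
  # a zero-residual fit with real signal is an exact fit; a zero-residual
  # fit with a null coefficient just means there was nothing to explain
  perfect <- !collinear & rss < scale_tol & beta^2 * gg > scale_tol
  null_fit <- !collinear & rss < scale_tol & !perfect
  pval[perfect] <- 0
  stat[perfect] <- Inf * sign(beta[perfect])
  pval[null_fit] <- 1
  stat[null_fit] <- 0
  beta[collinear] <- NA_real_
  se[collinear] <- NA_real_
  stat[collinear] <- NA_real_
  pval[collinear] <- NA_real_
  flag <- rep(NA_character_, length(beta))
  flag[perfect] <- "perfect_fit"
  flag[collinear] <- "collinear"
  list(effect = beta, se = se, statistic = stat, p_value = pval, flag = flag)
}

collapse_sex <- function(phenotype, sex_mode) {
  val_col <- intersect(c("sensitivity", "mean", "value"), names(phenotype))[1]
  if (is.na(val_col)) abort("phenotype table needs a sensitivity/mean/value column")
  ph <- dplyr::select(phenotype, dplyr::any_of(c("line", "sex")),
                      value = dplyr::all_of(val_col))
  if (sex_mode == "none" || !"sex" %in% names(ph)) {
    return(dplyr::summarise(dplyr::group_by(ph, .data$line),
                            value = mean(.data$value), .groups = "drop"))
  }
  if (sex_mode %in% c("F", "M")) {
    return(ph %>% dplyr::filter(.data$sex == sex_mode) %>%
             dplyr::select("line", "value"))
  }
  wide <- ph %>%
    dplyr::filter(.data$sex %in% c("F", "M")) %>%
    tidyr::pivot_wider(names_from = "sex", values_from = "value")
  if (!all(c("F", "M") %in% names(wide))) abort("both sexes required for this sex_mode")
  if (sex_mode == "average") {
    dplyr::transmute(wide, line = .data$line, value = (.data$F + .data$M) / 2)
  } else { # difference
    dplyr::transmute(wide, line = .data$line, value = .data$F - .data$M)
  }
}

#' Genome-wide single-marker association scan
#'
#' Tests every MAF-filtered variant for additive association with a
#' per-line phenotype (typically a lead-sensitivity table from
#' [sensitivity()]), adjusting for Wolbachia infection and inversion
#' covariates, and reports top hits below a fixed p-value threshold chosen
#' from quantile-quantile diagnostics. For sexed traits the phenotype can be
#' scanned for each sex separately (`"F"`, `"M"`), for the unweighted
#' average of the sexes (`"average"`), or for the female-minus-male
#' difference (`"difference"`); unsexed traits use `"none"`. Lines with a
#' missing phenotype (e.g. lines non-viable on lead medium) are excluded.
#'
#' No multiple-testing correction is applied here: the reporting threshold
#' (default `1e-5`) plays that role, as in the source study design.
#'
#' @param phenotype Tibble with `line`, optionally `sex`, and one of
#'   `sensitivity`/`mean`/`value`.
#' @param panel A `line_panel`.
#' @param sex_mode `"F"`, `"M"`, `"average"`, `"difference"`, or `"none"`.
#' @param maf_min Minor-allele-frequency threshold (see [maf_filter()]).
#' @param covariates Character subset of `c("wolbachia", "inversions")`.
#' @param report_threshold Top-hit p-value threshold, default `1e-5`.
#' @return Object of class `"gwa_result"`; `tidy()` returns the per-variant
#'   records, `glance()` a one-row summary, `autoplot()` the QQ plot.
#' @export
run_gwa <- function(phenotype, panel,
                    sex_mode = c("none", "F", "M", "average", "difference"),
                    maf_min = 0.05,
                    covariates = c("wolbachia", "inversions"),
                    report_threshold = 1e-5) {
  sex_mode <- match.arg(sex_mode)
  stopifnot(report_threshold > 0, report_threshold < 1)
  ph <- collapse_sex(phenotype, sex_mode)
  ph <- dplyr::filter(ph, !is.na(.data$value))
  lines_used <- intersect(ph$line, panel$line_ids)
  if (length(lines_used) == 0) abort("no lines shared between phenotype and panel")
  ph <- ph[match(lines_used, ph$line), ]

  keep <- maf_filter(panel, maf_min)
  if (length(keep) == 0) {
    records <- tibble::tibble(
      variant_id = character(0), chrom = character(0), pos = integer(0),
      sex_mode = character(0), effect = numeric(0), se = numeric(0),
      statistic = numeric(0), p_value = numeric(0), n = integer(0),
      maf = numeric(0), flag = character(0)
    )
    return(new_gwa_result(records, sex_mode, maf_min, report_threshold,
                          length(lines_used)))
  }
  G <- panel$genotypes[lines_used, keep, drop = FALSE]

  cov_df <- NULL
  covariates <- intersect(covariates, c("wolbachia", "inversions"))
  if (length(covariates) > 0) {
    cv <- panel$covariates[match(lines_used, panel$covariates$line), ]
    cols <- character(0)
    if ("wolbachia" %in% covariates) cols <- c(cols, "wolbachia")
    if ("inversions" %in% covariates) {
      cols <- c(cols, setdiff(names(cv), c("line", "wolbachia")))
    }
    if (length(cols) > 0) {
      cov_df <- as.data.frame(cv[, cols, drop = FALSE])
      # drop constant covariates (e.g. an inversion fixed in the used lines)
      keep_cov <- vapply(cov_df, function(x) length(unique(x)) > 1, logical(1))
      cov_df <- cov_df[, keep_cov, drop = FALSE]
      if (ncol(cov_df) == 0) cov_df <- NULL
    }
  }
  Xc <- if (is.null(cov_df)) {
    matrix(1, nrow = length(lines_used), ncol = 1)
  } else {
    stats::model.matrix(~., data = cov_df)
  }

  res <- marker_scan(ph$value, G, Xc)
  vmeta <- panel$variants[match(keep, panel$variants$variant_id), ]
  records <- tibble::tibble(
    variant_id = keep, chrom = vmeta$chrom, pos = vmeta$pos,
    sex_mode = sex_mode,
    effect = res$effect, se = res$se, statistic = res$statistic,
    p_value = res$p_value, n = length(lines_used),
    maf = vmeta$maf, flag = res$flag
  )
  new_gwa_result(records, sex_mode, maf_min, report_threshold, length(lines_used))
}

new_gwa_result <- function(records, sex_mode, maf_min, report_threshold, n_lines) {
  top <- dplyr::filter(records, is.na(.data$flag) | .data$flag == "perfect_fit",
                       .data$p_value < report_threshold)
  structure(
    list(records = records, top_hits = dplyr::arrange(top, .data$p_value),
         sex_mode = sex_mode, maf_min = maf_min,
         report_threshold = report_threshold, n_lines = n_lines),
    class = "gwa_result"
  )
}

#' @export
print.gwa_result <- function(x, ...) {
  cat(sprintf("<gwa_result> %d variants tested on %d lines (sex mode '%s')\n",
              nrow(x$records), x$n_lines, x$sex_mode))
  cat(sprintf("  top hits at p < %g: %d\n", x$report_threshold, nrow(x$top_hits)))
  invisible(x)
}

#' @describeIn run_gwa Per-variant association records.
#' @param x A `gwa_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gwa_result <- function(x, ...) x$records

#' @describeIn run_gwa One-row scan summary.
#' @exportS3Method generics::glance
glance.gwa_result <- function(x, ...) {
  p <- x$records$p_value[is.na(x$records$flag)]
  tibble::tibble(
    n_variants = nrow(x$records), n_lines = x$n_lines,
    n_top_hits = nrow(x$top_hits),
    min_p = if (length(p) > 0) min(p) else NA_real_,
    median_p = if (length(p) > 0) stats::median(p) else NA_real_,
    sex_mode = x$sex_mode, report_threshold = x$report_threshold
  )
}

#' Quantile-quantile data for an association scan
#'
#' Pairs the observed \eqn{-\log_{10} p} values, sorted from most to least
#' significant, with the corresponding uniform order-statistic expectations
#' \eqn{-\log_{10}(i/(m+1))}.
#'
#' @param records A `gwa_result` or its `tidy()` record tibble.
#' @return Tibble with `expected` and `observed` columns.
#' @export
qq_data <- function(records) {
  if (inherits(records, "gwa_result")) records <- records$records
  p <- records$p_value[!is.na(records$p_value)]
  if (length(p) == 0) abort("no p-values to plot")
  m <- length(p)
  tibble::tibble(
    expected = -log10(seq_len(m) / (m + 1)),
    observed = -log10(sort(p))
  )
}

#' Pairwise linkage disequilibrium (r-squared)
#'
#' For fully inbred homozygous lines, haplotype frequencies equal joint line
#' frequencies, so \eqn{r^2 = D^2 / (f_A f_a f_B f_b)} with
#' \eqn{D = f_{AB} - f_A f_B} computed directly from the 0/1 line codes.
#'
#' @param panel A `line_panel`.
#' @param pairs Two-column data.frame/matrix of variant ids, or a length-2
#'   character vector for a single pair.
#' @return Tibble with `variant_a`, `variant_b`, `r2` (in \[0, 1\]).
#' @export
ld_r2 <- function(panel, pairs) {
  if (is.character(pairs) && length(pairs) == 2) {
    pairs <- matrix(pairs, ncol = 2)
  }
  pairs <- as.data.frame(pairs)
  names(pairs) <- c("variant_a", "variant_b")
  G <- panel$genotypes
  purrr::pmap_dfr(pairs, function(variant_a, variant_b) {
    ga <- G[, variant_a]
    gb <- G[, variant_b]
    fa <- mean(ga)
    fb <- mean(gb)
    if (fa %in% c(0, 1) || fb %in% c(0, 1)) {
      abort(sprintf("r2 undefined for monomorphic variant (%s, %s)",
                    variant_a, variant_b))
    }
    D <- mean(ga * gb) - fa * fb
    tibble::tibble(variant_a = variant_a, variant_b = variant_b,
                   r2 = D^2 / (fa * (1 - fa) * fb * (1 - fb)))
  })
}
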