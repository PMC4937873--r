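#' Configuration for a synthetic inbred-line panel
#'
#' Bundles the design constants of a simulated mapping panel of fully inbred
#' (homozygous) lines, modelled on the Drosophila Genetic Reference Panel:
#' roughly 200 lines, a set of biallelic variants, a Wolbachia infection
#' covariate carried by about half the lines, and a small number of
#' segregating cosmopolitan inversions.
#'
#' @param n_lines Number of inbred lines (>= 2).
#' @param n_variants Number of biallelic variants to simulate (may be 0).
#' @param maf_range Length-2 numeric in (0, 0.5]; per-variant minor allele
#'   frequencies are drawn uniformly from this interval.
#' @param wolbachia_rate Proportion of lines carrying Wolbachia infection.
#' @param n_inversions Number of segregating inversions (each line is
#'   homozygous standard `"ST"` or inverted `"INV"`).
#' @param inversion_rate Frequency of the inverted arrangement per inversion.
#' @param seed Integer seed; fully determines `simulate_panel()` output.
#'
#' @return A list of class `"panel_config"`.
#' @seealso [simulate_panel()]
#' @export
panel_config <- function(n_lines = 200, n_variants = 1000,
                         maf_range = c(0.05, 0.5), wolbachia_rate = 0.53,
                         n_inversions = 2, inversion_rate = 0.15, seed = 1) {
  if (n_lines < 2) abort("`n_lines` must be >= 2 (a panel needs lines to contrast).")
  if (n_variants < 0) abort("`n_variants` must be >= 0.")
  stopifnot(length(maf_range) == 2)
  if (maf_range[1] > maf_range[2]) maf_range <- rev(maf_range)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
    abort("`maf_range` must lie within (0, 0.5].")
  }
  if (wolbachia_rate < 0 || wolbachia_rate > 1) abort("`wolbachia_rate` must be in [0, 1].")
  structure(
    list(n_lines = as.integer(n_lines), n_variants = as.integer(n_variants),
         maf_range = as.numeric(maf_range), wolbachia_rate = wolbachia_rate,
         n_inversions = as.integer(n_inversions),
         inversion_rate = inversion_rate, seed = as.integer(seed)),
    class = "panel_config"
  )
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

inversion_names <- function(k) {
  std <- c("In_2L_t", "In_2R_NS", "In_3R_P", "In_3R_K", "In_3R_Mo")
  if (k <= length(std)) std[seq_len(k)] else c(std, paste0("In_x_", seq_len(k - length(std))))[seq_len(k)]
}

#' Simulate a panel of fully inbred lines
#'
#' Draws a homozygous biallelic genotype matrix (coded 0/1, where 1 is the
#' minor-allele homozygote), per-variant metadata, and line covariates
#' (Wolbachia infection status and inversion arrangements). Each variant's
#' population frequency is drawn from `config$maf_range`; columns are coded
#' so the counted allele is the empirical minor allele, and the stored
#' `maf` equals the mean of the coded column.
#'
#' @param config A [panel_config()].
#' @return A list of class `"line_panel"` with elements
#'   `line_ids` (character), `genotypes` (lines x variants 0/1 integer matrix
#'   with dimnames), `variants` (tibble: variant_id, chrom, pos, ref, alt,
#'   maf), and `covariates` (tibble: line, wolbachia, one column per
#'   inversion with levels ST/INV).
#' @examples
#' pan <- simulate_panel(panel_config(n_lines = 20, n_variants = 50, seed = 1))
#' dim(pan$genotypes)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  with_seed(config$seed, {
    n <- config$n_lines
    m <- config$n_variants
    line_ids <- sprintf("line_%03d", seq_len(n))

    chroms <- c("2L", "2R", "3L", "3R", "X")
    bases <- c("A", "C", "G", "T")
    if (m > 0) {
      f <- runif(m, config$maf_range[1], config$maf_range[2])
      G <- matrix(rbinom(n * m, 1L, rep(f, each = n)), nrow = n, ncol = m)
      # fold so the coded allele is the empirical minor allele
      flip <- colMeans(G) > 0.5
      G[, flip] <- 1L - G[, flip]
      chrom <- sample(chroms, m, replace = TRUE)
      pos <- integer(m)
      for (ch in chroms) {
        idx <- which(chrom == ch)
        pos[idx] <- sort(sample.int(2.3e7, length(idx)))
      }
      ref <- sample(bases, m, replace = TRUE)
      alt <- unname(vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1)))
      ord <- order(match(chrom, chroms), pos)
      G <- G[, ord, drop = FALSE]
      variants <- tibble::tibble(
        variant_id = sprintf("%s_%d", chrom[ord], pos[ord]),
        chrom = chrom[ord], pos = pos[ord],
        ref = ref[ord], alt = alt[ord],
        maf = colMeans(G)
      )
      dimnames(G) <- list(line_ids, variants$variant_id)
      storage.mode(G) <- "integer"
    } else {
      G <- matrix(integer(0), nrow = n, ncol = 0, dimnames = list(line_ids, NULL))
      variants <- tibble::tibble(
        variant_id = character(0), chrom = character(0), pos = integer(0),
        ref = character(0), alt = character(0), maf = numeric(0)
      )
    }

    covariates <- tibble::tibble(
      line = line_ids,
      wolbachia = rbinom(n, 1L, config$wolbachia_rate)
    )
    if (config$n_inversions > 0) {
      for (nm in inversion_names(config$n_inversions)) {
        covariates[[nm]] <- factor(
          ifelse(rbinom(n, 1L, config$inversion_rate) == 1L, "INV", "ST"),
          levels = c("ST", "INV")
        )
      }
    }

    new_line_panel(line_ids, G, variants, covariates)
  })
}

new_line_panel <- function(line_ids, genotypes, variants, covariates) {
  stopifnot(
    identical(rownames(genotypes), line_ids),
    ncol(genotypes) == nrow(variants),
    all(genotypes %in% c(0L, 1L))
  )
  structure(
    list(line_ids = line_ids, genotypes = genotypes,
         variants = variants, covariates = covariates),
    class = "line_panel"
  )
}

#' @export
print.line_panel <- function(x, ...) {
  cat(sprintf("<line_panel> %d inbred lines x %d biallelic variants\n",
              length(x$line_ids), ncol(x$genotypes)))
  n_inv <- sum(!names(x$covariates) %in% c("line", "wolbachia"))
  cat(sprintf("  Wolbachia-positive lines: %d (%.0f%%); inversions tracked: %d\n",
              sum(x$covariates$wolbachia), 100 * mean(x$covariates$wolbachia), n_inv))
  invisible(x)
}
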