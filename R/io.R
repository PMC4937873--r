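#' Write and read a line panel as plain-text tables
#'
#' `write_panel()` serializes a `line_panel` into three headered TSVs in
#' `dir`: `genotypes.tsv` (lines x variants, 0/1, first column `line`),
#' `variants.tsv` (variant metadata) and `covariates.tsv`. `read_panel()`
#' reverses this losslessly.
#'
#' @param panel A `line_panel`.
#' @param dir Directory (created if needed).
#' @return `write_panel()` the directory invisibly; `read_panel()` a
#'   `line_panel`.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- tibble::as_tibble(panel$genotypes, .name_repair = "minimal")
  gt <- dplyr::bind_cols(tibble::tibble(line = panel$line_ids), gt)
  readr::write_tsv(gt, file.path(dir, "genotypes.tsv"))
  readr::write_tsv(panel$variants, file.path(dir, "variants.tsv"))
  write_covariates(panel$covariates, file.path(dir, "covariates.tsv"))
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  gt <- readr::read_tsv(file.path(dir, "genotypes.tsv"),
                        show_col_types = FALSE)
  variants <- readr::read_tsv(
    file.path(dir, "variants.tsv"), show_col_types = FALSE,
    col_types = readr::cols(variant_id = "c", chrom = "c", pos = "i",
                            ref = "c", alt = "c", maf = "d")
  )
  covariates <- read_covariates(file.path(dir, "covariates.tsv"))
  line_ids <- gt$line
  G <- as.matrix(gt[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- line_ids
  check_genotype_matrix(G)
  new_line_panel(line_ids, G, variants, covariates)
}

check_genotype_matrix <- function(G) {
  bad <- which(!(G %in% c(0L, 1L)) & !is.na(G))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(G))
    abort(sprintf("genotype matrix must be 0/1: offending entry at line row %d, variant column %d",
                  rc[1], rc[2]))
  }
}

#' Read a genotype TSV into a line panel
#'
#' Reads a lines x variants 0/1 table (first column `line`, header row of
#' variant ids). Variant ids of the form `chrom_pos` are parsed back into
#' chromosome and position; `ref`/`alt` are unknown from this format and
#' left `NA`, and `maf` is recomputed from the coded columns.
#'
#' @param path Genotype TSV path.
#' @param covariates Optional covariate table or path to one
#'   (see [read_covariates()]). Defaults to a covariate-free panel
#'   (all lines uninfected, no inversions).
#' @return A `line_panel`.
#' @export
read_genotypes_tsv <- function(path, covariates = NULL) {
  gt <- readr::read_tsv(path, show_col_types = FALSE)
  line_ids <- as.character(gt[[1]])
  G <- as.matrix(gt[, -1, drop = FALSE])
  storage.mode(G) <- "integer"
  rownames(G) <- line_ids
  check_genotype_matrix(G)
  ids <- colnames(G)
  parsed <- regmatches(ids, regexec("^(.+)_([0-9]+)$", ids))
  chrom <- vapply(parsed, function(p) if (length(p) == 3) p[2] else NA_character_, "")
  pos <- vapply(parsed, function(p) if (length(p) == 3) as.integer(p[3]) else NA_integer_, 1L)
  variants <- tibble::tibble(
    variant_id = ids, chrom = chrom, pos = pos,
    ref = NA_character_, alt = NA_character_,
    maf = if (ncol(G) > 0) unname(pmin(colMeans(G), 1 - colMeans(G))) else numeric(0)
  )
  covariates <- resolve_covariates(covariates, line_ids)
  new_line_panel(line_ids, G, variants, covariates)
}

resolve_covariates <- function(covariates, line_ids) {
  if (is.null(covariates)) {
    tibble::tibble(line = line_ids, wolbachia = 0L)
  } else if (is.character(covariates)) {
    read_covariates(covariates)
  } else {
    tibble::as_tibble(covariates)
  }
}

#' Write a line panel as a minimal VCF
#'
#' Emits an uncompressed VCF 4.2 with one sample column per line and
#' homozygous diploid genotypes only (`0/0` reference, `1/1` coded
#' minor-allele homozygote), honoring CHROM/POS/ID/REF/ALT with 1-based
#' positions. Unknown ref/alt bases are written as `N`.
#'
#' @param panel A `line_panel`.
#' @param path Output `.vcf` path.
#' @export
write_vcf <- function(panel, path) {
  v <- panel$variants
  ref <- ifelse(is.na(v$ref), "N", v$ref)
  alt <- ifelse(is.na(v$alt), "N", v$alt)
  gt <- t(panel$genotypes)  # variants x lines
  gt_str <- matrix(ifelse(gt == 1L, "1/1", "0/0"), nrow = nrow(gt))
  body <- cbind(v$chrom, v$pos, v$variant_id, ref, alt, ".", "PASS", ".",
                "GT", gt_str)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=leadsens",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$line_ids), collapse = "\t")
  )
  writeLines(c(header, apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a minimal VCF into a line panel
#'
#' Accepts the dialect written by [write_vcf()]: biallelic records with
#' homozygous diploid GT fields (`0/0` or `1/1`). Heterozygous or missing
#' genotypes are rejected — the panel model assumes fully inbred lines.
#'
#' @param path VCF path.
#' @param covariates As in [read_genotypes_tsv()].
#' @return A `line_panel`.
#' @export
read_genotypes_vcf <- function(path, covariates = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (any(!gt_raw %in% c("0/0", "1/1", "0|0", "1|1"))) {
    abort("minimal-VCF dialect allows only homozygous GT fields (0/0 or 1/1)")
  }
  G <- t(ifelse(gt_raw %in% c("1/1", "1|1"), 1L, 0L) |>
           matrix(nrow = nrow(gt_raw), dimnames = dimnames(gt_raw)))
  line_ids <- rownames(G)
  colnames(G) <- fix$ID
  variants <- tibble::tibble(
    variant_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = unname(ifelse(fix$REF == "N", NA_character_, fix$REF)),
    alt = unname(ifelse(fix$ALT == "N", NA_character_, fix$ALT)),
    maf = if (ncol(G) > 0) unname(pmin(colMeans(G), 1 - colMeans(G))) else numeric(0)
  )
  covariates <- resolve_covariates(covariates, line_ids)
  new_line_panel(line_ids, G, variants, covariates)
}

#' Write/read the long-format phenotype table
#'
#' CSV with columns `line,sex,treatment,replicate,trait,value,missing`.
#' `read_phenotypes()` validates the schema and value ranges (viability in
#' \[0, 1\], positive development times, non-negative activity, known
#' treatment and sex codes) and reports the first offending row.
#'
#' @param table Phenotype tibble.
#' @param path CSV path.
#' @export
write_phenotypes <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  tbl <- readr::read_csv(
    path, show_col_types = FALSE,
    col_types = readr::cols(line = "c", sex = "c", treatment = "c",
                            replicate = "i", trait = "c", value = "d",
                            missing = "l")
  )
  need <- c("line", "sex", "treatment", "replicate", "trait", "value", "missing")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(sprintf("phenotype file lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  fail_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      abort(sprintf("phenotype schema violation (%s) at row %d of %s",
                    what, idx[1], path))
    }
  }
  fail_row(!tbl$treatment %in% c("control", "lead"), "treatment not control/lead")
  fail_row(!(tbl$sex %in% c("F", "M") | is.na(tbl$sex)), "sex not F/M/NA")
  fail_row(!tbl$trait %in% c("dev_time", "viability", "activity"), "unknown trait")
  ok_val <- !is.na(tbl$value)
  fail_row(tbl$trait == "viability" & ok_val & (tbl$value < 0 | tbl$value > 1),
           "viability outside [0, 1]")
  fail_row(tbl$trait == "dev_time" & ok_val & tbl$value <= 0, "dev_time <= 0")
  fail_row(tbl$trait == "activity" & ok_val & tbl$value < 0, "activity < 0")
  fail_row(tbl$missing & !is.na(tbl$value) & tbl$trait != "viability",
           "missing record carries a value")
  tbl
}

#' Write/read the line covariate table
#'
#' Headered TSV with `line`, binary `wolbachia`, and one column per
#' inversion with arrangements `ST`/`INV`.
#'
#' @param covariates Covariate tibble.
#' @param path TSV path.
#' @export
write_covariates <- function(covariates, path) {
  readr::write_tsv(covariates, path)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  cv <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(line = "c", wolbachia = "i",
                                                .default = "c"))
  for (nm in setdiff(names(cv), c("line", "wolbachia"))) {
    bad <- !cv[[nm]] %in% c("ST", "INV")
    if (any(bad)) {
      abort(sprintf("covariate column '%s' has arrangement other than ST/INV at row %d",
                    nm, which(bad)[1]))
    }
    cv[[nm]] <- factor(cv[[nm]], levels = c("ST", "INV"))
  }
  cv
}

#' Read gene windows from BED or GFF3
#'
#' Returns gene intervals in the package's internal convention: 1-based,
#' inclusive on both ends. BED input (0-based, half-open) is converted;
#' GFF3 is already 1-based inclusive. Parsing goes through
#' \pkg{rtracklayer} when installed.
#'
#' @param path `.bed`, `.gff`/`.gff3` file.
#' @param format Override autodetection by extension.
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_windows <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
    df <- as.data.frame(gr)
    id <- if (format == "bed") {
      df$name
    } else {
      df$ID %||% df$Name %||% df$gene_id
    }
    tb <- tibble::tibble(
      gene_id = as.character(id), chrom = as.character(df$seqnames),
      start = df$start, end = df$end, strand = as.character(df$strand)
    )
  } else if (format == "bed") {
    df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                          comment = "#")
    tb <- tibble::tibble(
      gene_id = as.character(df[[4]]), chrom = as.character(df[[1]]),
      start = df[[2]] + 1L, end = df[[3]],  # 0-based half-open -> 1-based inclusive
      strand = if (ncol(df) >= 6) as.character(df[[6]]) else "*"
    )
  } else {
    df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                          comment = "#")
    attr_id <- sub(".*(?:ID|Name|gene_id)=([^;]+).*", "\\1", df[[9]])
    tb <- tibble::tibble(
      gene_id = attr_id, chrom = as.character(df[[1]]),
      start = df[[4]], end = df[[5]], strand = as.character(df[[7]])
    )
  }
  if (any(tb$start > tb$end)) abort("malformed gene interval (start > end)")
  tb
}

#' Read a two-column ortholog mapping TSV
#'
#' One row per gene-ortholog pair (one-to-many allowed); a header row is
#' detected and skipped when its first field is `gene` or `gene_id`.
#'
#' @param path TSV path.
#' @return Tibble: `gene`, `ortholog`.
#' @export
read_orthologs <- function(path) {
  first <- tolower(strsplit(readLines(path, n = 1), "\t")[[1]][1])
  has_header <- first %in% c("gene", "gene_id")
  df <- readr::read_tsv(path, col_names = has_header, show_col_types = FALSE)
  if (!has_header) names(df)[1:2] <- c("gene", "ortholog")
  names(df)[1:2] <- c("gene", "ortholog")
  tibble::as_tibble(df[, 1:2])
}

#' Default pipeline run configuration
#'
#' @return Named list of default paths and parameters; see
#'   [read_run_config()].
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    n_lines = 200, n_variants = 5000, maf_range = c(0.05, 0.5),
    wolbachia_rate = 0.53, n_inversions = 2,
    maf_min = 0.05, report_threshold = 1e-5, alpha = 0.05,
    window = 1000, n_randomizations = 1000, tail = "strict",
    paths = list(),
    output_dir = "leadsens_out"
  )
}

#' Read/write the pipeline run configuration (YAML)
#'
#' The configuration holds file paths, module parameters (`maf_min`,
#' `report_threshold`, `alpha`, `window`, `n_randomizations`, `tail`) and
#' an explicit `seed` for every stochastic stage; missing fields are filled
#' with defaults. Configurations round-trip unchanged through
#' serialization.
#'
#' @param path YAML file.
#' @return A named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- utils::modifyList(default_run_config(), cfg)
  if (is.null(out$seed)) abort("run config must set an explicit `seed`")
  structure(out, class = "run_config")
}

#' @rdname read_run_config
#' @param config A run-config list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write stage outputs with a machine-readable manifest
#'
#' Writes every tibble in `outputs` as a headered TSV under `dir` and a
#' `manifest.json` recording inputs, parameters, seeds and the package
#' version.
#'
#' @param outputs Named list of tibbles/data.frames.
#' @param dir Output directory.
#' @param config Optional run configuration to record.
#' @export
write_results <- function(outputs, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(outputs)) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(tibble::as_tibble(outputs[[nm]]), f)
    files[nm] <- basename(f)
  }
  manifest <- list(
    package = "leadsens",
    version = as.character(utils::packageVersion("leadsens")),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = as.list(files),
    config = if (is.null(config)) NULL else unclass(config)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
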