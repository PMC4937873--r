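#' Simulate gene windows along the panel's chromosomes
#'
#' Synthetic gene annotation for end-to-end runs: non-overlapping windows of
#' realistic gene size tiled per chromosome arm, in 1-based inclusive
#' coordinates.
#'
#' @param panel A `line_panel` (chromosome names are taken from its
#'   variants; falls back to the standard arms).
#' @param genes_per_chrom Number of genes per chromosome.
#' @param seed Integer seed.
#' @return Tibble: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
simulate_gene_windows <- function(panel, genes_per_chrom = 200, seed = 1) {
  chroms <- unique(panel$variants$chrom)
  if (length(chroms) == 0) chroms <- c("2L", "2R", "3L", "3R", "X")
  with_seed(seed, {
    purrr::map_dfr(chroms, function(ch) {
      starts <- sort(sample.int(2.25e7, genes_per_chrom))
      len <- pmax(200L, stats::rgeom(genes_per_chrom, 1 / 4000) + 200L)
      tibble::tibble(
        gene_id = sprintf("gene_%s_%03d", ch, seq_len(genes_per_chrom)),
        chrom = ch, start = starts,
        end = starts + len,
        strand = sample(c("+", "-"), genes_per_chrom, replace = TRUE)
      )
    })
  })
}

#' Simulate a genetic-interaction edge list over a gene set
#'
#' Erdős–Rényi-style random pairs over the supplied gene ids, deduplicated
#' and without self-loops, standing in for a curated interaction database.
#'
#' @param gene_ids Character vector of gene ids.
#' @param n_edges Number of interaction edges to draw.
#' @param seed Integer seed.
#' @return Tibble: `gene_a`, `gene_b`.
#' @export
simulate_interactions <- function(gene_ids, n_edges = 2000, seed = 1) {
  n <- length(gene_ids)
  stopifnot(n >= 2)
  with_seed(seed, {
    a <- sample.int(n, n_edges * 2, replace = TRUE)
    b <- sample.int(n, n_edges * 2, replace = TRUE)
    keep <- a != b
    lo <- pmin(a[keep], b[keep])
    hi <- pmax(a[keep], b[keep])
    uq <- !duplicated(paste(lo, hi))
    idx <- which(uq)[seq_len(min(n_edges, sum(uq)))]
    tibble::tibble(gene_a = gene_ids[lo[idx]], gene_b = gene_ids[hi[idx]])
  })
}

#' Run the full synthetic analysis pipeline
#'
#' Drives every stage end to end on a simulated panel: phenotype
#' generation with lethal-line injection, variance partitioning and
#' broad-sense heritability, sensitivity phenotypes and their cross-trait
#' correlation, the association scan with covariate adjustment, performer
#' classification with logistic allele enrichment, variant-to-gene
#' annotation, one-bridge subnetwork extraction with the largest-cluster
#' randomization test, and the mutant-validation ANOVA. Per-stage counts
#' (lines dropped, variants filtered, candidates unmapped) are logged via
#' `message()`.
#'
#' @param config A run configuration (list from [read_run_config()] or
#'   [default_run_config] fields); `seed` drives every stochastic stage.
#' @param write Write stage outputs and a manifest to `config$output_dir`.
#' @return Named list with the stage results.
#' @export
run_pipeline <- function(config = NULL, write = FALSE) {
  cfg <- utils::modifyList(default_run_config(), as.list(config %||% list()))
  seed <- cfg$seed
  log_stage <- function(...) message(sprintf(...))

  log_stage("[simulate] panel: %d lines, %d variants (seed %d)",
            cfg$n_lines, cfg$n_variants, seed)
  panel <- simulate_panel(panel_config(
    n_lines = cfg$n_lines, n_variants = cfg$n_variants,
    maf_range = cfg$maf_range, wolbachia_rate = cfg$wolbachia_rate,
    n_inversions = cfg$n_inversions, seed = seed
  ))

  # causal sensitivity variants give the scan true signal to find
  common <- maf_filter(panel, 0.2)
  causal <- with_seed(seed + 101, sample(common, min(3, length(common))))
  par_dev <- default_sim_params("dev_time")
  par_dev$causal_effects <- tibble::tibble(
    variant_id = causal, effect = 2.0, acts_on = "sensitivity"
  )
  ph_dev <- simulate_phenotypes(panel, par_dev, "dev_time", seed = seed + 1)
  ph_via <- simulate_phenotypes(panel, default_sim_params("viability"),
                                "viability", seed = seed + 2)

  n_lethal <- round(par_dev$lethal_line_fraction * cfg$n_lines)
  lethal <- with_seed(seed + 3, sample(panel$line_ids, n_lethal))
  male_only <- with_seed(seed + 4,
                         sample(setdiff(panel$line_ids, lethal),
                                min(4, cfg$n_lines - n_lethal)))
  ph <- dplyr::bind_rows(ph_dev, ph_via) %>%
    inject_lethality(lethal, "both_sexes") %>%
    inject_lethality(male_only, "females_only")
  log_stage("[simulate] lethal on lead: %d lines (both sexes) + %d (females only)",
            length(lethal), length(male_only))

  vc_dev <- fit_anova(ph, "dev_time", model = "full")
  vc_via <- fit_anova(ph, "viability", model = "no_sex")
  h2_dev <- broad_sense_h2(vc_dev)
  h2_via <- broad_sense_h2(vc_via)
  log_stage("[varcomp] dev_time H2 = %.3f (dropped %d lines); viability H2 = %.3f",
            h2_dev$H2, length(vc_dev$dropped_lines), h2_via$H2)

  sens_dev <- sensitivity(line_means(dplyr::filter(ph, .data$trait == "dev_time")))
  sens_via <- sensitivity(line_means(dplyr::filter(ph, .data$trait == "viability"),
                                     by = c("line", "treatment")))
  corr <- trait_correlation(sens_dev, sens_via)
  log_stage("[sensitivity] dev~viability line correlation R = %.3f (n = %d)",
            corr$estimate, corr$n)

  gwa_avg <- run_gwa(sens_dev, panel, sex_mode = "average",
                     maf_min = cfg$maf_min,
                     report_threshold = cfg$report_threshold)
  log_stage("[gwa] %d variants pass MAF >= %.2f on %d lines; %d top hits at p < %g",
            nrow(gwa_avg$records), cfg$maf_min, gwa_avg$n_lines,
            nrow(gwa_avg$top_hits), cfg$report_threshold)

  calls <- classify_lines(ph, "dev_time", sex = "F", alpha = cfg$alpha)
  # the candidate set carried forward: the 100 strongest associations
  top_vars <- head(dplyr::arrange(gwa_avg$records, .data$p_value)$variant_id, 100)
  enrich <- logistic_enrichment(calls, panel, top_vars, alpha = cfg$alpha)
  log_stage("[performers] %d poor / %d good lines; %d enriched after Bonferroni (m = %d)",
            sum(calls$class == "poor"), sum(calls$class == "good"),
            sum(enrich$significant, na.rm = TRUE), nrow(enrich))

  genes <- if (!is.null(cfg$paths$annotation)) {
    read_gene_windows(cfg$paths$annotation)
  } else {
    simulate_gene_windows(panel, genes_per_chrom = 400, seed = seed + 5)
  }
  ann <- map_variants(
    panel$variants[panel$variants$variant_id %in% top_vars, ],
    genes, window = cfg$window
  )
  cand_genes <- unique(stats::na.omit(ann$gene_id))
  log_stage("[annotate] %d/%d top variants genic or near-genic; %d candidate genes",
            dplyr::n_distinct(ann$variant_id[ann$class == "genic_or_near"]),
            length(top_vars), length(cand_genes))

  edges <- if (!is.null(cfg$paths$edges)) {
    load_edges(cfg$paths$edges)
  } else {
    edges_to_graph(as.matrix(simulate_interactions(
      genes$gene_id, n_edges = 5 * length(genes$gene_id), seed = seed + 6)))
  }
  net <- randomization_test(edges, cand_genes,
                            n_randomizations = cfg$n_randomizations,
                            seed = seed + 7, tail = cfg$tail)
  log_stage("[network] %d candidates mapped (%d unmapped), largest cluster %d, p_strict = %.4g",
            length(net$candidates), length(net$unmapped),
            net$largest_cluster_size, net$permutation$p_strict)

  # replicate unit = vial mean of ~50 larvae, hence the small residual sd
  assay <- simulate_mutant_assay(n_mutants = 8,
                                 interaction = c(rep(1.5, 6), 0, 0),
                                 sd = 0.5, seed = seed + 8)
  mut <- purrr::map_dfr(paste0("mutant_", 1:8), function(m) {
    dplyr::bind_rows(fit_mutant_anova(assay, m, sex = "F"),
                     fit_mutant_anova(assay, m, sex = "M"))
  })
  vr <- validation_rate(sum(mut$significant[mut$sex == "F"]),
                        sum(mut$significant[mut$sex == "M"]), 8)
  log_stage("[mutants] validation rate %.1f%% (F %d/8, M %d/8)",
            vr$rate_percent, vr$n_significant_female, vr$n_significant_male)

  out <- list(
    panel = panel, phenotypes = ph,
    varcomp_dev = vc_dev, varcomp_via = vc_via,
    h2_dev = h2_dev, h2_via = h2_via,
    sensitivity_dev = sens_dev, sensitivity_via = sens_via,
    correlation = corr, gwa = gwa_avg, performer_calls = calls,
    enrichment = enrich, annotation = ann, network = net,
    mutants = mut, validation = vr, config = cfg
  )
  if (write) {
    write_results(list(
      variance_components_dev = vc_dev$varcomp,
      variance_components_via = vc_via$varcomp,
      heritability = dplyr::bind_rows(dev_time = h2_dev, viability = h2_via,
                                      .id = "trait"),
      sensitivity_dev = sens_dev, sensitivity_viability = sens_via,
      gwa_records = gwa_avg$records, gwa_top_hits = gwa_avg$top_hits,
      performer_calls = calls, enrichment = enrich,
      annotation = ann, network_nodes = net$nodes,
      network_summary = glance(net), mutants = mut, validation = vr
    ), cfg$output_dir, config = cfg)
    log_stage("[write] results under %s", cfg$output_dir)
  }
  invisible(out)
}
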