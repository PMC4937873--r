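#' Map variants to genes within a distance window
#'
#' Assigns each positioned variant to every gene whose interval lies within
#' `window` base pairs (distance 0 inside the gene; otherwise the distance
#' to the nearest interval edge, `start - pos` upstream or `pos - end`
#' downstream). A variant can therefore be associated with several genes —
#' overlapping or merely nearby — and a gene with several variants. Strand
#' is ignored: only the distance rule applies. Coordinates are 1-based
#' inclusive (GFF convention).
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos`.
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end` (1-based,
#'   inclusive; `start <= end` or an error is raised).
#' @param window Maximum distance in bp, default 1000.
#' @return Tibble with one row per variant-gene assignment (`variant_id`,
#'   `gene_id`, `distance`, `class = "genic_or_near"`) plus one row per
#'   unassigned variant (`gene_id` `NA`, `class = "intergenic"`).
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", chrom = "2L", start = 1000, end = 2000)
#' v <- tibble::tibble(variant_id = c("a", "b"), chrom = "2L", pos = c(2500, 3500))
#' map_variants(v, genes)  # a is within 1 kb, b is intergenic
#' @export
map_variants <- function(variants, genes, window = 1000) {
  stopifnot(all(c("variant_id", "chrom", "pos") %in% names(variants)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (any(genes$start > genes$end)) {
    bad <- genes$gene_id[genes$start > genes$end]
    abort(sprintf("malformed gene interval(s) (start > end): %s",
                  paste(bad, collapse = ", ")))
  }
  hits <- variants %>%
    dplyr::select("variant_id", "chrom", "pos") %>%
    dplyr::inner_join(
      dplyr::select(genes, "gene_id", "chrom", "start", "end"),
      by = "chrom", relationship = "many-to-many"
    ) %>%
    dplyr::mutate(distance = pmax(0, .data$start - .data$pos,
                                  .data$pos - .data$end)) %>%
    dplyr::filter(.data$distance <= window) %>%
    dplyr::transmute(.data$variant_id, .data$gene_id, .data$distance,
                     class = "genic_or_near")
  lonely <- variants %>%
    dplyr::filter(!.data$variant_id %in% hits$variant_id) %>%
    dplyr::transmute(.data$variant_id, gene_id = NA_character_,
                     distance = NA_real_, class = "intergenic")
  dplyr::bind_rows(hits, lonely) %>%
    dplyr::arrange(match(.data$variant_id, variants$variant_id))
}
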