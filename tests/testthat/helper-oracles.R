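# shared helpers: hand-built panels and independent oracles

# panel with an explicitly chosen genotype matrix
make_panel <- function(G, wolbachia = NULL, inversions = NULL) {
  n <- nrow(G)
  m <- ncol(G)
  line_ids <- sprintf("line_%03d", seq_len(n))
  rownames(G) <- line_ids
  if (is.null(colnames(G))) colnames(G) <- sprintf("2L_%d", seq_len(m) * 1000L)
  storage.mode(G) <- "integer"
  ids <- colnames(G)
  pos <- as.integer(sub("^2L_", "", ids))
  variants <- tibble::tibble(
    variant_id = ids, chrom = "2L", pos = pos,
    ref = "A", alt = "T",
    maf = if (m > 0) pmin(colMeans(G), 1 - colMeans(G)) else numeric(0)
  )
  cov <- tibble::tibble(line = line_ids,
                        wolbachia = wolbachia %||% rep(0L, n))
  if (!is.null(inversions)) cov <- dplyr::bind_cols(cov, inversions)
  leadsens:::new_line_panel(line_ids, G, variants, cov)
}

# long-format phenotype rows from a per-line list of replicate vectors
make_pheno <- function(values, trait = "dev_time", sex = "F") {
  purrr::imap_dfr(values, function(trts, line) {
    purrr::imap_dfr(trts, function(v, trt) {
      tibble::tibble(line = line, sex = sex, treatment = trt,
                     replicate = seq_along(v), trait = trait,
                     value = v, missing = FALSE)
    })
  })
}

# textbook Welch two-sample t-test
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# brute-force one-bridge extraction: enumerate candidate pairs, keep direct
# edges and both legs of every single-bridge two-path
brute_subnetwork <- function(edges, candidates) {
  # edges: two-column character matrix
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  if (nrow(edges) == 0) {
    return(list(edges = character(0), intermediates = character(0)))
  }
  has_edge <- function(a, b) key(a, b) %in% key(edges[, 1], edges[, 2])
  nbrs <- function(v) unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  all_nodes <- unique(c(edges))
  cand <- intersect(candidates, all_nodes)
  kept <- character(0)
  inter <- character(0)
  if (length(cand) >= 2) {
    prs <- utils::combn(cand, 2)
    for (i in seq_len(ncol(prs))) {
      c1 <- prs[1, i]; c2 <- prs[2, i]
      if (has_edge(c1, c2)) kept <- c(kept, key(c1, c2))
      for (x in setdiff(intersect(nbrs(c1), nbrs(c2)), cand)) {
        kept <- c(kept, key(c1, x), key(c2, x))
        inter <- c(inter, x)
      }
    }
  }
  list(edges = sort(unique(kept)), intermediates = sort(unique(inter)))
}

edge_keys <- function(edge_tbl) {
  if (nrow(edge_tbl) == 0) return(character(0))
  sort(paste(pmin(edge_tbl$from, edge_tbl$to), pmax(edge_tbl$from, edge_tbl$to)))
}
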