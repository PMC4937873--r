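#' Load a genetic-interaction edge list
#'
#' Reads a two-column gene-pair file (TSV) into a simple undirected
#' \pkg{igraph} graph: self-loops and duplicate edges (including symmetric
#' duplicates) are removed and their counts logged as attributes; malformed
#' rows are skipped with a message naming the line number.
#'
#' @param path Path to a two-column tab-separated file (a header line is
#'   detected and skipped if its first field is `gene_a`, `from` or
#'   `source`).
#' @return An undirected simple `igraph` graph with graph attributes
#'   `n_dropped_rows`, `n_collapsed` (duplicate edges + self-loops removed).
#' @export
load_edges <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 0 &&
      tolower(strsplit(lines[1], "\t")[[1]][1]) %in% c("gene_a", "from", "source")) {
    lines <- lines[-1]
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, function(p) length(p) >= 2 && all(nzchar(p[1:2])), logical(1))
  bad <- which(!ok)
  if (length(bad) > 0) {
    message(sprintf("skipped %d malformed row(s) at line(s): %s",
                    length(bad), paste(head(bad, 10), collapse = ", ")))
  }
  el <- do.call(rbind, lapply(parts[ok], function(p) p[1:2]))
  edges_to_graph(el, n_dropped_rows = length(bad))
}

#' Build a simple interaction graph from a gene-pair table
#'
#' @param edges Two-column matrix/data.frame of gene pairs.
#' @param n_dropped_rows Bookkeeping count carried onto the graph.
#' @return Simple undirected `igraph` graph.
#' @export
edges_to_graph <- function(edges, n_dropped_rows = 0) {
  if (is.null(edges) || nrow(edges) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    raw_m <- igraph::ecount(g)
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    g <- igraph::set_graph_attr(g, "n_collapsed", raw_m - igraph::ecount(g))
  }
  igraph::set_graph_attr(g, "n_dropped_rows", n_dropped_rows)
}

# core one-bridge extraction on an integer edge list; z = candidate indicator.
# retained edges: candidate-candidate edges, plus both edges of every
# candidate - intermediate - candidate 2-path (an intermediate is a
# non-candidate with >= 2 candidate neighbors).
bridge_edges <- function(E, z) {
  za <- z[E[, 1]]
  zb <- z[E[, 2]]
  candcand <- which(za & zb)
  one <- xor(za, zb)
  x <- as.integer(ifelse(za[one], E[one, 2], E[one, 1]))  # non-candidate endpoint
  cnt <- tabulate(x, nbins = length(z))
  inter <- cnt >= 2
  bridge <- which(one)[inter[x]]
  list(edges = c(candcand, bridge), intermediates = which(inter & !z))
}

#' Extract the one-bridge candidate-gene subnetwork
#'
#' From a genetic-interaction graph and a candidate gene set, retains every
#' edge that is either a direct connection between two candidate genes or
#' one of the two edges of a path `c1 - x - c2` where `x` is a single
#' non-candidate "bridge" gene connecting two distinct candidates. Bridge
#' genes recruited this way are the network's intermediate genes. Connected
#' components are computed on the retained edge set; candidate genes with no
#' retained edge do not appear in any component.
#'
#' @param graph An `igraph` interaction graph (see [load_edges()]).
#' @param candidates Character vector of candidate gene ids; ids absent from
#'   the graph are recorded as unmapped.
#' @return Object of class `"subnetwork_result"` with fields `candidates`
#'   (mapped, with a retained edge or not), `unmapped`, `intermediates`,
#'   `edges` (tibble `from`/`to`), `nodes` (tibble `node`, `role`,
#'   `component`), `largest_cluster_size`.
#' @export
extract_subnetwork <- function(graph, candidates) {
  vnames <- igraph::V(graph)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(igraph::vcount(graph)))
  mapped <- intersect(unique(candidates), vnames)
  unmapped <- setdiff(unique(candidates), vnames)
  E <- igraph::as_edgelist(graph, names = FALSE)
  z <- vnames %in% mapped
  core <- if (nrow(E) > 0) bridge_edges(E, z) else list(edges = integer(0), intermediates = integer(0))

  edge_tbl <- tibble::tibble(
    from = vnames[E[core$edges, 1]],
    to = vnames[E[core$edges, 2]]
  )
  inter <- vnames[core$intermediates]

  if (nrow(edge_tbl) > 0) {
    sub <- igraph::graph_from_data_frame(edge_tbl, directed = FALSE)
    comp <- igraph::components(sub)
    nodes <- tibble::tibble(
      node = igraph::V(sub)$name,
      role = ifelse(igraph::V(sub)$name %in% inter, "intermediate", "candidate"),
      component = unname(comp$membership)
    )
    largest <- max(comp$csize)
  } else {
    nodes <- tibble::tibble(node = character(0), role = character(0),
                            component = integer(0))
    largest <- 0L
  }

  structure(
    list(candidates = mapped, unmapped = unmapped, intermediates = inter,
         edges = edge_tbl, nodes = nodes,
         largest_cluster_size = as.integer(largest),
         permutation = NULL, orthologs = NULL),
    class = "subnetwork_result"
  )
}

# largest retained cluster size only, for the randomization inner loop
largest_cluster_size_fast <- function(E, z, n) {
  core <- bridge_edges(E, z)
  if (length(core$edges) == 0) return(0L)
  sub <- igraph::graph_from_edgelist(E[core$edges, , drop = FALSE],
                                     directed = FALSE)
  as.integer(max(igraph::components(sub)$csize))
}

#' Randomization test for the largest subnetwork cluster
#'
#' Assesses whether the largest connected cluster of the one-bridge
#' candidate subnetwork is larger than expected by chance: each of
#' `n_randomizations` draws samples, without replacement from the graph's
#' node universe, a random gene set the same size as the mapped candidate
#' set, extracts its subnetwork and records its largest cluster size. The
#' literal estimator divides the number of random draws whose largest
#' cluster *exceeds* the observed size by the number of randomizations
#' (`tail = "strict"`); the conventional `>=` version is always co-reported
#' (`p_inclusive >= p_strict`). The add-one estimator `(k+1)/(B+1)` is
#' available via `add_one`.
#'
#' @param graph `igraph` interaction graph.
#' @param candidates Candidate gene ids (unmapped ids are excluded before
#'   sizing the random sets).
#' @param n_randomizations Number of random draws, default 1000.
#' @param seed Mandatory integer seed.
#' @param tail Which estimator fills `permutation_p`: `"strict"` (default)
#'   or `"inclusive"`.
#' @param add_one Use the `(k+1)/(B+1)` estimator, default `FALSE`.
#' @return The [extract_subnetwork()] result with a `permutation` list
#'   added: `p` (selected tail), `p_strict`, `p_inclusive`,
#'   `n_randomizations`, `seed`, `tail`, `null_sizes`.
#' @export
randomization_test <- function(graph, candidates, n_randomizations = 1000,
                               seed, tail = c("strict", "inclusive"),
                               add_one = FALSE) {
  tail <- match.arg(tail)
  if (n_randomizations < 1) abort("`n_randomizations` must be >= 1")
  if (missing(seed)) abort("`seed` is mandatory for the randomization test")
  obs <- extract_subnetwork(graph, candidates)
  n <- igraph::vcount(graph)
  k <- length(obs$candidates)
  if (k > n) abort("candidate set larger than the graph's node universe")
  E <- igraph::as_edgelist(graph, names = FALSE)

  null_sizes <- with_seed(seed, {
    vapply(seq_len(n_randomizations), function(i) {
      z <- logical(n)
      z[sample.int(n, k)] <- TRUE
      largest_cluster_size_fast(E, z, n)
    }, integer(1))
  })

  B <- n_randomizations
  denom <- if (add_one) B + 1 else B
  bump <- if (add_one) 1 else 0
  p_strict <- (sum(null_sizes > obs$largest_cluster_size) + bump) / denom
  p_inclusive <- (sum(null_sizes >= obs$largest_cluster_size) + bump) / denom
  obs$permutation <- list(
    p = if (tail == "strict") p_strict else p_inclusive,
    p_strict = p_strict, p_inclusive = p_inclusive,
    n_randomizations = B, seed = seed, tail = tail,
    add_one = add_one, null_sizes = null_sizes
  )
  obs
}

#' Overlay an ortholog mapping on a subnetwork
#'
#' Tags every node of the extracted network with its orthologs from a
#' (possibly one-to-many) mapping table and reports the fraction of nodes
#' with at least one ortholog.
#'
#' @param result A `subnetwork_result`.
#' @param mapping Tibble/data.frame whose first two columns are gene id and
#'   ortholog id.
#' @return `result` with `orthologs` (tibble `node`, `orthologs`
#'   (comma-collapsed), `has_ortholog`) and `ortholog_fraction` (proportion
#'   in \[0, 1\]) added.
#' @export
overlay_orthologs <- function(result, mapping) {
  stopifnot(inherits(result, "subnetwork_result"))
  mapping <- as.data.frame(mapping)[, 1:2]
  names(mapping) <- c("node", "ortholog")
  nodes <- result$nodes$node
  tagged <- tibble::tibble(node = nodes) %>%
    dplyr::left_join(mapping, by = "node") %>%
    dplyr::group_by(.data$node) %>%
    dplyr::summarise(
      orthologs = paste(stats::na.omit(.data$ortholog), collapse = ","),
      has_ortholog = any(!is.na(.data$ortholog)),
      .groups = "drop"
    )
  result$orthologs <- tagged
  result$ortholog_fraction <- if (nrow(tagged) > 0) mean(tagged$has_ortholog) else 0
  result
}

#' @export
print.subnetwork_result <- function(x, ...) {
  cat(sprintf("<subnetwork_result> %d candidate + %d intermediate genes, %d edges\n",
              sum(x$nodes$role == "candidate"),
              length(x$intermediates), nrow(x$edges)))
  cat(sprintf("  largest cluster: %d nodes\n", x$largest_cluster_size))
  if (!is.null(x$permutation)) {
    cat(sprintf("  randomization p (%s tail, B = %d): %.4g\n",
                x$permutation$tail, x$permutation$n_randomizations,
                x$permutation$p))
  }
  if (!is.null(x$ortholog_fraction)) {
    cat(sprintf("  nodes with orthologs: %.0f%%\n", 100 * x$ortholog_fraction))
  }
  invisible(x)
}

#' @describeIn extract_subnetwork Node table of the extracted network.
#' @param x A `subnetwork_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.subnetwork_result <- function(x, ...) x$nodes

#' @describeIn extract_subnetwork One-row summary (sizes and permutation p).
#' @exportS3Method generics::glance
glance.subnetwork_result <- function(x, ...) {
  tibble::tibble(
    n_candidates_mapped = length(x$candidates),
    n_candidates_retained = sum(x$nodes$role == "candidate"),
    n_intermediates = length(x$intermediates),
    n_edges = nrow(x$edges),
    largest_cluster_size = x$largest_cluster_size,
    p_strict = if (is.null(x$permutation)) NA_real_ else x$permutation$p_strict,
    p_inclusive = if (is.null(x$permutation)) NA_real_ else x$permutation$p_inclusive,
    ortholog_fraction = x$ortholog_fraction %||% NA_real_
  )
}
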