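#' Per-edge link similarity score
#'
#' The score used to cluster same-sign links: the sum of the two same-sign
#' link-clustering subtypes, S_e = PLC_e + NLC_e. Under the default
#' `min_total` denominator convention this equals SLC_e.
#'
#' @param coeffs a `link_coef_table` (see [link_clustering_coefficients()])
#' @param sign +1 (default) or -1: which edges to score
#' @return named numeric vector of scores, names are canonical `from|to`
#'   edge keys
#' @export
link_similarity_scores <- function(coeffs, sign = 1) {
  stopifnot(inherits(coeffs, "link_coef_table"), sign %in% c(-1, 1))
  sel <- coeffs$sign == sign
  stats::setNames(coeffs$PLC[sel] + coeffs$NLC[sel], rownames(coeffs)[sel])
}

#' Partition density of a set of link communities
#'
#' The link-community quality function of Ahn et al.: a link-count-weighted
#' mean of per-community link densities, normalised so a tree scores 0 and a
#' clique scores 1:
#' D = (2/M) * sum_c m_c (m_c - (n_c - 1)) / ((n_c - 2)(n_c - 1)),
#' where m_c and n_c are the link and node counts of community c and M is the
#' total number of links. Communities with n_c = 2 contribute 0.
#'
#' @param m_c integer vector of per-community link counts
#' @param n_c integer vector of per-community node counts
#' @param M total link count used for the weighting (defaults to `sum(m_c)`)
#' @return the partition density D
#' @export
partition_density <- function(m_c, n_c, M = sum(m_c)) {
  stopifnot(length(m_c) == length(n_c))
  if (length(m_c) == 0L || M == 0L) return(0)
  if (any(m_c < n_c - 1L)) {
    stop("community with fewer links than a spanning tree (m_c < n_c - 1)")
  }
  dc <- ifelse(n_c > 2L,
               m_c * (m_c - (n_c - 1)) / ((n_c - 2) * (n_c - 1)),
               0)
  (2 / M) * sum(dc)
}

# connected components of the subgraph formed by the given edge rows;
# returns list(m_c, n_c, membership = integer per edge row)
link_communities_at <- function(edges) {
  if (nrow(edges) == 0L) {
    return(list(m_c = integer(), n_c = integer(), membership = integer()))
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership
  edge_comp <- unname(memb[edges$from])
  list(m_c = as.integer(tabulate(edge_comp, comp$no)),
       n_c = as.integer(tabulate(memb, comp$no)),
       membership = as.integer(edge_comp))
}

#' Sweep the similarity-score cutoff and record the partition density
#'
#' Single-linkage clustering of same-sign links: ranking links by score in
#' descending order and cutting the implied dendrogram at score s retains
#' every link with S_e >= s and merges retained links into one community
#' whenever they share a node. The sweep visits every distinct score value
#' (the lowest level retains all links of the sign) and records the
#' partition density at each cutoff, computed over the retained links
#' (M = number of links with score at or above the cutoff), so a partition
#' of the retained links into cliques scores exactly 1.
#'
#' @param net a [signed_network]
#' @param scores named score vector from [link_similarity_scores()]; must
#'   cover every edge of the requested sign
#' @param sign +1 (default) or -1
#' @return data.frame `cutoff`, `D`, `n_communities`, `n_edges` with one row
#'   per distinct score, cutoffs descending
#' @export
sweep_partition_density <- function(net, scores = NULL, sign = 1) {
  stopifnot(inherits(net, "signed_network"))
  e <- net$edges[net$edges$sign == sign, , drop = FALSE]
  if (nrow(e) == 0L) stop("network has no edges of sign ", sign)
  if (is.null(scores)) {
    scores <- link_similarity_scores(link_clustering_coefficients(net), sign)
  }
  key <- edge_key(e$from, e$to)
  if (!all(key %in% names(scores))) {
    stop("scores missing for ", sum(!key %in% names(scores)), " edge(s)")
  }
  s <- unname(scores[key])
  cutoffs <- sort(unique(s), decreasing = TRUE)
  out <- data.frame(cutoff = cutoffs, D = NA_real_,
                    n_communities = NA_integer_, n_edges = NA_integer_)
  for (r in seq_along(cutoffs)) {
    keep <- s >= cutoffs[r]
    lc <- link_communities_at(e[keep, , drop = FALSE])
    out$D[r] <- partition_density(lc$m_c, lc$n_c)
    out$n_communities[r] <- length(lc$m_c)
    out$n_edges[r] <- sum(keep)
  }
  out
}

#' Extract link-community modules at the density-maximising cutoff
#'
#' Runs the descending score sweep, picks the cutoff maximising the
#' partition density (ties resolved by `tie_rule`), and returns the link
#' communities at that cutoff together with the modules: communities whose
#' induced gene set (union of link endpoints) has at least `min_genes`
#' genes.
#'
#' @param net a [signed_network]
#' @param scores optional named score vector (computed from the default
#'   coefficients when `NULL`)
#' @param sign +1 (default) or -1
#' @param min_genes minimum module gene-set size (default 3, i.e. size >= 3)
#' @param tie_rule `"stringent"` (default: largest cutoff among ties, most
#'   stringent, minimal modules) or `"inclusive"` (smallest cutoff)
#' @return object of class `link_partition`: list with `sign`, `cutoff`,
#'   `D`, `sweep` (the full curve), `communities` (list of data.frames of
#'   edges), `modules` (named list of character gene vectors, only
#'   communities with >= `min_genes` genes), `M`
#' @export
extract_modules <- function(net, scores = NULL, sign = 1, min_genes = 3L,
                            tie_rule = c("stringent", "inclusive")) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(inherits(net, "signed_network"))
  if (is.null(scores)) {
    scores <- link_similarity_scores(link_clustering_coefficients(net), sign)
  }
  curve <- sweep_partition_density(net, scores, sign)
  best <- which(curve$D == max(curve$D))
  pick <- if (tie_rule == "stringent") min(best) else max(best)
  cutoff <- curve$cutoff[pick]
  e <- net$edges[net$edges$sign == sign, , drop = FALSE]
  s <- unname(scores[edge_key(e$from, e$to)])
  keep <- e[s >= cutoff, , drop = FALSE]
  lc <- link_communities_at(keep)
  communities <- split(keep, lc$membership)
  names(communities) <- NULL
  genes <- lapply(communities, function(ed) sort(unique(c(ed$from, ed$to))))
  # deterministic order: by size descending, then first gene
  ord <- order(-lengths(genes),
               vapply(genes, `[`, character(1), 1L), method = "radix")
  communities <- communities[ord]
  genes <- genes[ord]
  is_mod <- lengths(genes) >= min_genes
  modules <- genes[is_mod]
  if (length(modules)) names(modules) <- paste0("M", seq_along(modules))
  structure(list(sign = sign, cutoff = cutoff, D = curve$D[pick],
                 sweep = curve, communities = communities,
                 modules = modules, min_genes = min_genes, M = nrow(e)),
            class = "link_partition")
}

#' @export
print.link_partition <- function(x, ...) {
  cat(sprintf(paste0("link_partition (sign %+d): cutoff %.4g, ",
                     "partition density D = %.4g\n"),
              x$sign, x$cutoff, x$D))
  cat(sprintf("  %d link communities over %d links; %d modules (>= %d genes)\n",
              length(x$communities), sum(vapply(x$communities, nrow, 1L)),
              length(x$modules), x$min_genes))
  invisible(x)
}

#' Module-map meta-network
#'
#' Summarises a set of gene modules over a signed network: per module, the
#' intra-module positive and negative link densities (edges with both
#' endpoints inside the module over choose(gene count, 2)); per module pair,
#' a meta-edge recording the number of network links spanning the two
#' modules and the fraction of those links that are negative. Modules may
#' share genes (link communities overlap on nodes); an edge internal to
#' either module of a pair is not counted as spanning.
#'
#' @param net a [signed_network]
#' @param modules named list of character gene vectors (e.g.
#'   `extract_modules(...)$modules`)
#' @return object of class `module_map`: list with `nodes` (data.frame
#'   `module`, `n_genes`, `pos_density`, `neg_density`) and `edges`
#'   (data.frame `module_a`, `module_b`, `n_links`, `prop_negative`)
#' @export
module_map <- function(net, modules) {
  stopifnot(inherits(net, "signed_network"), length(modules) >= 1L)
  if (is.null(names(modules))) names(modules) <- paste0("M", seq_along(modules))
  e <- net$edges
  nodes <- data.frame(module = names(modules),
                      n_genes = lengths(modules),
                      pos_density = NA_real_, neg_density = NA_real_,
                      stringsAsFactors = FALSE)
  inside <- lapply(modules, function(g) e$from %in% g & e$to %in% g)
  for (k in seq_along(modules)) {
    npairs <- choose(length(modules[[k]]), 2)
    nodes$pos_density[k] <- if (npairs > 0) sum(inside[[k]] & e$sign > 0) / npairs else 0
    nodes$neg_density[k] <- if (npairs > 0) sum(inside[[k]] & e$sign < 0) / npairs else 0
  }
  pairs <- utils::combn(seq_along(modules), 2)
  rows <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    ga <- modules[[a]]; gb <- modules[[b]]
    span <- ((e$from %in% ga & e$to %in% gb) |
               (e$from %in% gb & e$to %in% ga)) &
      !inside[[a]] & !inside[[b]]
    if (any(span)) {
      rows[[p]] <- data.frame(module_a = names(modules)[a],
                              module_b = names(modules)[b],
                              n_links = sum(span),
                              prop_negative = sum(span & e$sign < 0) / sum(span),
                              stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(edges)) {
    edges <- data.frame(module_a = character(), module_b = character(),
                        n_links = integer(), prop_negative = numeric(),
                        stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "module_map")
}

#' @export
print.module_map <- function(x, ...) {
  cat(sprintf("module_map: %d modules, %d meta-edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(x$nodes, row.names = FALSE, digits = 3)
  if (nrow(x$edges)) print(x$edges, row.names = FALSE, digits = 3)
  invisible(x)
}
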