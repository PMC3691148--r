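#' Construct a signed undirected network
#'
#' A `signed_network` is a simple undirected graph whose edges carry a sign in
#' \{+1, -1\}: +1 for, e.g., coexpression or alleviating (positive) genetic
#' interactions, -1 for anti-coexpression or synthetic-lethal (negative)
#' interactions. Node identifiers are case-sensitive opaque strings. Self-loops
#' and parallel edges are not representable: each unordered node pair carries
#' at most one sign.
#'
#' Edges are stored with the lexicographically smaller endpoint first and rows
#' sorted by that canonical key, so iteration order (and therefore any output
#' derived from it) is deterministic.
#'
#' @param edges data.frame with columns `from`, `to`, `sign` (sign coercible
#'   to +1/-1; `"+"`/`"-"` accepted). May have zero rows.
#' @param nodes optional character vector of node identifiers; must contain
#'   every edge endpoint. Isolated nodes are kept. Defaults to the endpoints.
#' @return An object of class `signed_network`: a list with elements `nodes`
#'   (sorted character vector) and `edges` (data.frame `from`, `to`, `sign`).
#' @examples
#' net <- signed_network(data.frame(from = c("a", "a"), to = c("b", "c"),
#'                                  sign = c(1, -1)))
#' summary(net)
#' @export
signed_network <- function(edges, nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        sign = parse_sign(edges$sign),
                        stringsAsFactors = FALSE)
  }
  if (any(edges$from == edges$to)) {
    stop("self-loops are not allowed in a signed_network")
  }
  # canonical orientation: from < to
  swap <- edges$from > edges$to
  if (any(swap)) {
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    dupk <- unique(key[duplicated(key)])
    sgn <- split(edges$sign, key)
    conflict <- dupk[vapply(sgn[dupk], function(s) length(unique(s)) > 1L, logical(1))]
    if (length(conflict)) {
      stop("conflicting signs for pair(s): ",
           paste(gsub("\r", "--", conflict), collapse = ", "))
    }
    edges <- edges[!duplicated(key), , drop = FALSE]
    key <- key[!duplicated(key)]
  }
  ord <- order(edges$from, edges$to, method = "radix")
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  endpoints <- unique(c(edges$from, edges$to))
  if (is.null(nodes)) {
    nodes <- endpoints
  } else {
    nodes <- unique(as.character(nodes))
    missing <- setdiff(endpoints, nodes)
    if (length(missing)) {
      stop("edge endpoints not in node set: ", paste(missing, collapse = ", "))
    }
  }
  structure(list(nodes = sort(nodes, method = "radix"), edges = edges),
            class = "signed_network")
}

parse_sign <- function(x) {
  if (is.numeric(x)) {
    s <- as.integer(x)
  } else {
    x <- trimws(as.character(x))
    s <- ifelse(x %in% c("+", "+1", "1"), 1L,
                ifelse(x %in% c("-", "-1"), -1L, NA_integer_))
  }
  if (any(is.na(s) | !(s %in% c(-1L, 1L)))) {
    bad <- which(is.na(s) | !(s %in% c(-1L, 1L)))[1]
    stop("unparseable sign at position ", bad, ": ",
         deparse(as.character(x)[bad]))
  }
  s
}

#' @export
print.signed_network <- function(x, ...) {
  m <- nrow(x$edges)
  mp <- sum(x$edges$sign > 0)
  cat(sprintf("signed_network: %d nodes, %d edges (%d positive, %d negative)\n",
              length(x$nodes), m, mp, m - mp))
  invisible(x)
}

#' @export
summary.signed_network <- function(object, ...) {
  e <- object$edges
  out <- list(n_nodes = length(object$nodes), n_edges = nrow(e),
              n_positive = sum(e$sign > 0), n_negative = sum(e$sign < 0))
  class(out) <- "summary.signed_network"
  out
}

#' @export
print.summary.signed_network <- function(x, ...) {
  cat(sprintf(paste0("Signed undirected network\n",
                     "  nodes:          %d\n",
                     "  edges:          %d\n",
                     "  positive edges: %d\n",
                     "  negative edges: %d\n"),
              x$n_nodes, x$n_edges, x$n_positive, x$n_negative))
  invisible(x)
}

#' Number of edges of a signed network
#' @param net a `signed_network`
#' @param sign optional +1 or -1 to count one sign only
#' @return integer edge count
#' @export
n_edges <- function(net, sign = NULL) {
  stopifnot(inherits(net, "signed_network"))
  if (is.null(sign)) nrow(net$edges) else sum(net$edges$sign == sign)
}

# canonical "a|b" edge key, smaller endpoint first
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# adjacency: named list node -> integer vector of signs named by neighbor
adjacency_list <- function(net) {
  adj <- vector("list", length(net$nodes))
  names(adj) <- net$nodes
  for (i in seq_along(adj)) adj[[i]] <- integer(0)
  e <- net$edges
  if (nrow(e)) {
    for (r in seq_len(nrow(e))) {
      a <- e$from[r]; b <- e$to[r]; s <- e$sign[r]
      adj[[a]][[b]] <- s
      adj[[b]][[a]] <- s
    }
  }
  adj
}

#' Excess neighbors of a node, split by link sign
#'
#' The "excess" neighborhood of node `i` relative to `exclude` is the set of
#' neighbors of `i` with `exclude` removed — the quantity n(i) used in the
#' denominators of the link-clustering coefficients, where `exclude` is the
#' partner node on the edge under evaluation.
#'
#' @param net a `signed_network`
#' @param i node identifier
#' @param exclude node identifier to drop from the neighborhood (need not be
#'   adjacent to `i`)
#' @return named numeric vector `c(n, n_pos, n_neg)` with `n = n_pos + n_neg`
#' @export
signed_excess_neighbors <- function(net, i, exclude) {
  stopifnot(inherits(net, "signed_network"))
  if (!(i %in% net$nodes)) stop("unknown node: ", i)
  if (!(exclude %in% net$nodes)) stop("unknown node: ", exclude)
  e <- net$edges
  hit <- e$from == i | e$to == i
  nb <- ifelse(e$from[hit] == i, e$to[hit], e$from[hit])
  s <- e$sign[hit]
  keep <- nb != exclude
  c(n = sum(keep), n_pos = sum(keep & s > 0), n_neg = sum(keep & s < 0))
}

#' Read a signed edge list from a TSV file
#'
#' Expected rows are `node_a <TAB> node_b <TAB> sign` with sign one of
#' `+1`, `-1`, `+`, `-`. A header row and `#`-prefixed comment lines are
#' allowed. Duplicate rows with identical sign are deduplicated; self-loop
#' rows are skipped with a warning.
#'
#' @param path file path or connection
#' @param conflict_policy `"error"` (default) stops when the same unordered
#'   pair appears with both signs, naming the pair; `"drop"` silently removes
#'   such pairs entirely (the ambiguous-interaction policy used for
#'   genetic-interaction data).
#' @return a [signed_network]
#' @export
read_signed_edge_list <- function(path, conflict_policy = c("error", "drop")) {
  conflict_policy <- match.arg(conflict_policy)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(signed_network(NULL))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop("malformed row (need 3 tab-separated fields) at line ", lineno[which(bad)[1]])
  }
  a <- vapply(parts, `[[`, character(1), 1L)
  b <- vapply(parts, `[[`, character(1), 2L)
  s <- trimws(vapply(parts, `[[`, character(1), 3L))
  # optional header: first row whose sign field is not parseable as a sign
  if (!(s[1] %in% c("+", "-", "+1", "-1", "1"))) {
    a <- a[-1]; b <- b[-1]; s <- s[-1]; lineno <- lineno[-1]
    if (!length(a)) return(signed_network(NULL))
  }
  ok <- s %in% c("+", "-", "+1", "-1", "1")
  if (any(!ok)) {
    stop("unparseable sign ", deparse(s[which(!ok)[1]]),
         " at line ", lineno[which(!ok)[1]])
  }
  sign <- ifelse(s %in% c("-", "-1"), -1L, 1L)
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop row(s) skipped")
    a <- a[!loops]; b <- b[!loops]; sign <- sign[!loops]
  }
  df <- data.frame(from = a, to = b, sign = sign, stringsAsFactors = FALSE)
  if (conflict_policy == "drop") {
    key <- edge_key(df$from, df$to)
    nsign <- vapply(split(df$sign, key), function(x) length(unique(x)),
                    integer(1))
    ambiguous <- names(nsign)[nsign > 1L]
    df <- df[!(key %in% ambiguous), , drop = FALSE]
  }
  signed_network(df)
}

#' Write a signed edge list to a TSV file
#'
#' Writes the canonical representation (`source target sign` with sign as
#' `+1`/`-1`); [read_signed_edge_list] on the output reproduces the network
#' exactly. Isolated nodes are not representable in an edge list and are not
#' written.
#'
#' @param net a [signed_network]
#' @param path file path or connection
#' @return invisibly, `net`
#' @export
write_signed_edge_list <- function(net, path) {
  stopifnot(inherits(net, "signed_network"))
  e <- net$edges
  lines <- c("source\ttarget\tsign",
             if (nrow(e)) paste(e$from, e$to,
                                ifelse(e$sign > 0, "+1", "-1"), sep = "\t"))
  writeLines(lines, path)
  invisible(net)
}

#' Induced signed subnetwork on one edge sign
#' @param net a `signed_network`
#' @param sign +1 or -1
#' @param keep_nodes keep all original nodes (default FALSE: only endpoints)
#' @return a `signed_network` containing only edges of the requested sign
#' @export
subnetwork_by_sign <- function(net, sign, keep_nodes = FALSE) {
  stopifnot(inherits(net, "signed_network"), sign %in% c(-1, 1))
  e <- net$edges[net$edges$sign == sign, , drop = FALSE]
  signed_network(e, nodes = if (keep_nodes) net$nodes else NULL)
}
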