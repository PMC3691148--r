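# Rank edges by coefficient descending; ties broken by the canonical
# edge key so the order is stable and documented.
rank_order <- function(coeff, keys) {
  order(-coeff, keys, method = "radix")
}

#' Cumulative annotation proportion along ranked coefficients
#'
#' Sorts edges by coefficient in descending order (rank 0% = highest) and, at
#' each percentage of the grid, reports the fraction of the top-x% edges whose
#' binary annotation is true. At 100% the value equals the overall annotation
#' base rate. The curve depends on the coefficient only through ranks, so it
#' is invariant under strictly monotone transforms.
#'
#' @param coeff numeric vector of per-edge coefficient values
#' @param annotation logical (or 0/1) vector, same length
#' @param grid percentages at which to evaluate (default 1..100)
#' @param keys optional character tie-break keys (canonical edge keys);
#'   defaults to the element index
#' @return data.frame `percent`, `n_top`, `proportion`
#' @export
ranked_cumulative_proportion <- function(coeff, annotation, grid = 1:100,
                                         keys = NULL) {
  if (length(grid) == 0L) stop("grid must not be empty")
  stopifnot(length(coeff) == length(annotation), length(coeff) >= 1L)
  annotation <- as.logical(annotation)
  if (is.null(keys)) keys <- sprintf("%09d", seq_along(coeff))
  ann <- annotation[rank_order(coeff, keys)]
  k <- pmax(1L, ceiling(length(ann) * grid / 100))
  csum <- cumsum(ann)
  data.frame(percent = grid, n_top = k, proportion = csum[k] / k)
}

#' Per-bin medians of an edge attribute along ranked coefficients
#'
#' Edges are ranked by coefficient descending (rank 0% = highest) and split
#' into `n_bins` equal-count bins; the median of the real-valued attribute is
#' reported per bin.
#'
#' @param coeff numeric per-edge coefficient values
#' @param attribute numeric per-edge attribute, same length
#' @param n_bins number of rank bins (default 100, capped at the number of
#'   edges)
#' @param keys optional character tie-break keys
#' @return data.frame `bin`, `rank_lo`, `rank_hi` (percent bounds), `n`,
#'   `median`
#' @export
ranked_bin_median <- function(coeff, attribute, n_bins = 100L, keys = NULL) {
  stopifnot(length(coeff) == length(attribute), n_bins >= 1L)
  n <- length(coeff)
  n_bins <- min(as.integer(n_bins), n)
  if (is.null(keys)) keys <- sprintf("%09d", seq_along(coeff))
  att <- attribute[rank_order(coeff, keys)]
  bounds <- round(seq(0L, n, length.out = n_bins + 1L))
  med <- numeric(n_bins)
  cnt <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    idx <- (bounds[b] + 1L):bounds[b + 1L]
    med[b] <- stats::median(att[idx])
    cnt[b] <- length(idx)
  }
  data.frame(bin = seq_len(n_bins),
             rank_lo = 100 * bounds[-(n_bins + 1L)] / n,
             rank_hi = 100 * bounds[-1L] / n,
             n = cnt, median = med)
}

#' Annotation enrichment in the top fraction of ranked edges
#'
#' Builds the 2x2 table (top-fraction vs rest) x (annotated vs not) and runs
#' Fisher's exact test. The reported odds ratio is the sample odds ratio with
#' the Haldane half-count correction applied when any cell is zero. When the
#' table is degenerate (every edge annotated, or none), no test is possible:
#' the result is flagged and p-values are 1.
#'
#' @param coeff numeric per-edge coefficient values
#' @param annotation logical (or 0/1) per-edge annotation
#' @param top_fraction fraction of edges in the "top" group, in (0, 1)
#' @param keys optional character tie-break keys
#' @return list with `table` (2x2 matrix), `odds_ratio`, `p_two_sided`,
#'   `p_greater` (enrichment in the top), `p_less`, `degenerate`
#' @export
enrichment_in_top_fraction <- function(coeff, annotation, top_fraction,
                                       keys = NULL) {
  stopifnot(top_fraction > 0, top_fraction < 1,
            length(coeff) == length(annotation))
  annotation <- as.logical(annotation)
  n <- length(coeff)
  if (is.null(keys)) keys <- sprintf("%09d", seq_along(coeff))
  ann <- annotation[rank_order(coeff, keys)]
  k <- max(1L, min(n - 1L, ceiling(n * top_fraction)))
  top_ann <- sum(ann[seq_len(k)])
  rest_ann <- sum(ann) - top_ann
  tab <- matrix(c(top_ann, k - top_ann,
                  rest_ann, (n - k) - rest_ann),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("top", "rest"),
                                c("annotated", "not_annotated")))
  if (sum(ann) == 0L || sum(ann) == n) {
    or <- haldane_or(tab)
    return(list(table = tab, odds_ratio = or, p_two_sided = 1,
                p_greater = 1, p_less = 1, degenerate = TRUE))
  }
  ft2 <- stats::fisher.test(tab, alternative = "two.sided")
  fg <- stats::fisher.test(tab, alternative = "greater")
  fl <- stats::fisher.test(tab, alternative = "less")
  list(table = tab, odds_ratio = haldane_or(tab),
       p_two_sided = ft2$p.value, p_greater = fg$p.value,
       p_less = fl$p.value, degenerate = FALSE)
}

haldane_or <- function(tab) {
  if (any(tab == 0L)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Read a per-edge annotation table
#'
#' TSV with columns `source`, `target`, `attribute`, `value`. Edge keys are
#' canonicalised; every edge must exist in `net` when it is supplied.
#'
#' @param path file path
#' @param net optional [signed_network] to validate edge keys against
#' @return data.frame `key`, `attribute`, `value` (value kept as character;
#'   coerce per attribute as appropriate)
#' @export
read_edge_annotations <- function(path, net = NULL) {
  tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("annotation file needs 4 columns: source target attribute value")
  key <- edge_key(tab[[1L]], tab[[2L]])
  if (!is.null(net)) {
    known <- edge_key(net$edges$from, net$edges$to)
    bad <- setdiff(key, known)
    if (length(bad)) {
      stop("annotation rows for edges not in the network: ",
           paste(utils::head(bad, 3L), collapse = ", "))
    }
  }
  data.frame(key = key, attribute = tab[[3L]], value = tab[[4L]],
             stringsAsFactors = FALSE)
}
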