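#' Partition the common neighbors of an edge by link-sign pattern
#'
#' For an edge e = (i, j), every common excess neighbor k (adjacent to both i
#' and j) is classified by the sign pair of the two links reaching it:
#' (+,+) and (-,-) are "same-sign" contributions (further split into
#' positive-positive and negative-negative), while (+,-) and (-,+) are
#' "hybrid".
#'
#' @param net a [signed_network]
#' @param i,j endpoints of an edge of `net`
#' @return named integer vector `c(c_pp, c_nn, c_hy)`
#' @export
common_neighbor_partition <- function(net, i, j) {
  stopifnot(inherits(net, "signed_network"))
  e <- net$edges
  if (!any(e$from == pmin(i, j) & e$to == pmax(i, j))) {
    stop("edge (", i, ", ", j, ") is not in the network")
  }
  adj <- adjacency_list(net)
  cnp_from_adj(adj[[i]], adj[[j]], i, j)
}

# classify common neighbors given the two adjacency sign vectors
cnp_from_adj <- function(Ni, Nj, i, j) {
  Ni <- Ni[names(Ni) != j]
  Nj <- Nj[names(Nj) != i]
  common <- intersect(names(Ni), names(Nj))
  si <- Ni[common]; sj <- Nj[common]
  c_pp <- sum(si > 0 & sj > 0)
  c_nn <- sum(si < 0 & sj < 0)
  c(c_pp = c_pp, c_nn = c_nn, c_hy = length(common) - c_pp - c_nn)
}

#' Signed link-clustering coefficients for every edge
#'
#' The link-clustering coefficient (LC) of an edge e = (i, j) is the
#' proportion of shared neighbors between its endpoints, using the excess
#' neighbor counts n(i), n(j) (partner excluded). Taking the signs of the two
#' links reaching each common neighbor into account splits LC into a
#' same-sign part (SLC, sign patterns +/+ or -/-) and a hybrid part (HLC,
#' +/- or -/+); SLC splits further into a positive (PLC, +/+) and a negative
#' (NLC, -/-) subtype.
#'
#' Under the default `min_total` denominator convention all five coefficients
#' share the denominator d = min(n(i), n(j)), so the decompositions
#' LC = SLC + HLC and SLC = PLC + NLC hold exactly per edge. The alternative
#' `min_signed` convention normalises each subtype by the matching
#' sign-specific excess-neighbor counts — PLC by min(n+(i), n+(j)), NLC by
#' min(n-(i), n-(j)), HLC by min(n+(i), n-(j)) + min(n-(i), n+(j)) — for
#' sensitivity analysis; LC and SLC keep d and the decomposition identities
#' need not hold. A zero denominator yields coefficient 0 (pendant edges
#' score 0 throughout).
#'
#' @param net a [signed_network]
#' @param denominator `"min_total"` (default) or `"min_signed"`
#' @return a data.frame of class `link_coef_table`, one row per edge:
#'   `from`, `to`, `sign`, `LC`, `SLC`, `HLC`, `PLC`, `NLC`, the common
#'   neighbor counts `c_pp`, `c_nn`, `c_hy`, and the excess counts `n_i`,
#'   `n_j`, `n_pos_i`, `n_neg_i`, `n_pos_j`, `n_neg_j`. Row names are
#'   canonical `from|to` edge keys.
#' @examples
#' net <- signed_network(data.frame(
#'   from = c("1", "1", "2", "1", "2", "1", "2"),
#'   to   = c("2", "3", "3", "4", "4", "5", "5"),
#'   sign = c(1, 1, 1, 1, -1, -1, -1)))
#' link_clustering_coefficients(net)
#' @export
link_clustering_coefficients <- function(net,
                                         denominator = c("min_total",
                                                         "min_signed")) {
  stopifnot(inherits(net, "signed_network"))
  denominator <- match.arg(denominator)
  e <- net$edges
  m <- nrow(e)
  adj <- adjacency_list(net)
  cpp <- cnn <- chy <- integer(m)
  ni <- nj <- npi <- nni <- npj <- nnj <- integer(m)
  for (r in seq_len(m)) {
    i <- e$from[r]; j <- e$to[r]
    Ni <- adj[[i]]; Ni <- Ni[names(Ni) != j]
    Nj <- adj[[j]]; Nj <- Nj[names(Nj) != i]
    common <- intersect(names(Ni), names(Nj))
    si <- Ni[common]; sj <- Nj[common]
    cpp[r] <- sum(si > 0 & sj > 0)
    cnn[r] <- sum(si < 0 & sj < 0)
    chy[r] <- length(common) - cpp[r] - cnn[r]
    ni[r] <- length(Ni); nj[r] <- length(Nj)
    npi[r] <- sum(Ni > 0); nni[r] <- ni[r] - npi[r]
    npj[r] <- sum(Nj > 0); nnj[r] <- nj[r] - npj[r]
  }
  d <- pmin(ni, nj)
  safe_div <- function(num, den) ifelse(den > 0, num / pmax(den, 1L), 0)
  if (denominator == "min_total") {
    # building LC and SLC from the subtypes keeps the decomposition
    # identities exact in floating point, not just mathematically
    HLC <- safe_div(chy, d)
    PLC <- safe_div(cpp, d)
    NLC <- safe_div(cnn, d)
    SLC <- PLC + NLC
    LC <- SLC + HLC
  } else {
    LC <- safe_div(cpp + cnn + chy, d)
    SLC <- safe_div(cpp + cnn, d)
    PLC <- safe_div(cpp, pmin(npi, npj))
    NLC <- safe_div(cnn, pmin(nni, nnj))
    HLC <- safe_div(chy, pmin(npi, nnj) + pmin(nni, npj))
  }
  out <- data.frame(from = e$from, to = e$to, sign = e$sign,
                    LC = LC, SLC = SLC, HLC = HLC, PLC = PLC, NLC = NLC,
                    c_pp = cpp, c_nn = cnn, c_hy = chy,
                    n_i = ni, n_j = nj,
                    n_pos_i = npi, n_neg_i = nni,
                    n_pos_j = npj, n_neg_j = nnj,
                    stringsAsFactors = FALSE)
  rownames(out) <- edge_key(e$from, e$to)
  attr(out, "denominator") <- denominator
  class(out) <- c("link_coef_table", "data.frame")
  out
}

#' @export
print.link_coef_table <- function(x, ...) {
  cat(sprintf("link_coef_table: %d edges (denominator convention: %s)\n",
              nrow(x), attr(x, "denominator")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more edges)\n", sep = "")
  invisible(x)
}

#' Common-neighbor (CNB) profile of negative edges
#'
#' For each negative edge e = (i, j), every hybrid common neighbor k (linked
#' to one endpoint positively and to the other negatively) contributes the
#' PLC of the positive member and the HLC of the negative member of the link
#' pair \{(i,k), (j,k)\}. Per edge, the medians of those two sets summarise
#' how cohesive the positive clusters reached through e's hybrid neighbors
#' are; across negative edges, the Pearson correlations of each median with
#' HLC(e) quantify whether negative links with stronger hybrid clustering
#' bridge denser positive clusters.
#'
#' @param net a [signed_network]
#' @param coeffs a `link_coef_table` computed on `net` (defaults to computing
#'   one with the default convention)
#' @return list of class `cnb_profile` with `profile` (data.frame `from`,
#'   `to`, `HLC`, `med_PLC_pos`, `med_HLC_neg`, `n_hybrid`, one row per
#'   negative edge with at least one hybrid common neighbor), `cor_PLC`
#'   and `cor_HLC` (Pearson correlations of `med_PLC_pos` resp. `med_HLC_neg`
#'   with `HLC`; `NA` when fewer than 3 rows exist or a variable is
#'   constant), and the two correlation-test p-values `p_PLC`, `p_HLC`.
#' @export
cnb_profile <- function(net, coeffs = link_clustering_coefficients(net)) {
  stopifnot(inherits(net, "signed_network"))
  adj <- adjacency_list(net)
  neg <- coeffs[coeffs$sign < 0, , drop = FALSE]
  rows <- vector("list", nrow(neg))
  for (r in seq_len(nrow(neg))) {
    i <- neg$from[r]; j <- neg$to[r]
    Ni <- adj[[i]]; Ni <- Ni[names(Ni) != j]
    Nj <- adj[[j]]; Nj <- Nj[names(Nj) != i]
    common <- intersect(names(Ni), names(Nj))
    hy <- common[(Ni[common] > 0) != (Nj[common] > 0)]
    if (!length(hy)) next
    plc_pos <- numeric(length(hy))
    hlc_neg <- numeric(length(hy))
    for (h in seq_along(hy)) {
      k <- hy[h]
      # of the pair {(i,k), (j,k)}, one link is positive, one negative
      if (Ni[[k]] > 0) { pos <- edge_key(i, k); negk <- edge_key(j, k) }
      else             { pos <- edge_key(j, k); negk <- edge_key(i, k) }
      plc_pos[h] <- coeffs[pos, "PLC"]
      hlc_neg[h] <- coeffs[negk, "HLC"]
    }
    rows[[r]] <- data.frame(from = i, to = j, HLC = neg$HLC[r],
                            med_PLC_pos = stats::median(plc_pos),
                            med_HLC_neg = stats::median(hlc_neg),
                            n_hybrid = length(hy), stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  prof <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(from = character(), to = character(), HLC = numeric(),
               med_PLC_pos = numeric(), med_HLC_neg = numeric(),
               n_hybrid = integer(), stringsAsFactors = FALSE)
  }
  safe_cor <- function(x, y) {
    if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(c(r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  cp <- safe_cor(prof$med_PLC_pos, prof$HLC)
  ch <- safe_cor(prof$med_HLC_neg, prof$HLC)
  structure(list(profile = prof,
                 cor_PLC = cp[["r"]], p_PLC = cp[["p"]],
                 cor_HLC = ch[["r"]], p_HLC = ch[["p"]]),
            class = "cnb_profile")
}

#' @export
print.cnb_profile <- function(x, ...) {
  cat(sprintf("cnb_profile: %d negative edges with hybrid common neighbors\n",
              nrow(x$profile)))
  cat(sprintf("  cor(median PLC of positive CNB links, HLC-) = %s\n",
              format(x$cor_PLC, digits = 3)))
  cat(sprintf("  cor(median HLC of negative CNB links, HLC-) = %s\n",
              format(x$cor_HLC, digits = 3)))
  invisible(x)
}
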