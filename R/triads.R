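# Enumerate all triangles once; returns an integer matrix (t x 3) of
# edge-row indices into net$edges. Iterates edges and scans common
# neighbors with a higher node index so each triangle appears exactly once.
triangle_edge_index <- function(net) {
  e <- net$edges
  nodes <- net$nodes
  id <- seq_along(nodes)
  names(id) <- nodes
  ef <- id[e$from]; et <- id[e$to]
  lo <- pmin(ef, et); hi <- pmax(ef, et)
  eidx <- seq_len(nrow(e))
  # adjacency by integer id
  nb <- split(c(hi, lo), c(lo, hi))
  key <- paste(lo, hi)
  elook <- eidx
  names(elook) <- key
  tri <- vector("list", nrow(e))
  for (r in seq_len(nrow(e))) {
    i <- lo[r]; j <- hi[r]
    common <- intersect(nb[[as.character(i)]], nb[[as.character(j)]])
    common <- common[common > j]
    if (length(common)) {
      tri[[r]] <- cbind(r,
                        unname(elook[paste(i, common)]),
                        unname(elook[paste(j, common)]))
    }
  }
  tri <- tri[!vapply(tri, is.null, logical(1))]
  if (!length(tri)) return(matrix(integer(), ncol = 3L))
  do.call(rbind, tri)
}

# classify triangles by the sum of their three signs:
# +3 -> T1 (+++), +1 -> T3 (++-), -1 -> T2 (+--), -3 -> T4 (---)
triad_counts_from_signs <- function(tri, signs) {
  if (nrow(tri) == 0L) return(c(T1 = 0L, T2 = 0L, T3 = 0L, T4 = 0L))
  s <- signs[tri[, 1L]] + signs[tri[, 2L]] + signs[tri[, 3L]]
  c(T1 = sum(s == 3L), T2 = sum(s == -1L),
    T3 = sum(s == 1L), T4 = sum(s == -3L))
}

#' Census of signed triads
#'
#' Counts every triangle (closed node triple) of the network exactly once and
#' classifies it by the multiset of its three edge signs: T1 = +++,
#' T2 = +--, T3 = ++-, T4 = ---. T1 and T2 are the balanced triad types of
#' structural balance theory; T3 and T4 are unbalanced.
#'
#' @param net a [signed_network]
#' @return object of class `triad_census`: list with `counts` (named integer
#'   vector T1..T4), `total` triangles, and `patterns`
#' @export
count_signed_triads <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  tri <- triangle_edge_index(net)
  counts <- triad_counts_from_signs(tri, net$edges$sign)
  structure(list(counts = counts, total = sum(counts),
                 patterns = c(T1 = "+++", T2 = "+--", T3 = "++-", T4 = "---")),
            class = "triad_census")
}

#' @export
print.triad_census <- function(x, ...) {
  cat("Signed triad census (", x$total, " triangles)\n", sep = "")
  df <- data.frame(type = names(x$counts), pattern = unname(x$patterns),
                   observed = unname(x$counts))
  if (!is.null(x$null_mean)) {
    df$null_mean <- unname(x$null_mean)
    df$null_sd <- unname(x$null_sd)
    df$fold <- unname(x$fold)
    df$p_over <- unname(x$p_over)
    df$p_under <- unname(x$p_under)
  }
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Shuffle edge signs, preserving topology and sign counts
#'
#' Returns a network with the same node pairs but the multiset of signs
#' permuted uniformly at random: the numbers of positive and negative edges
#' (and hence every topological property, including the triangle count) are
#' preserved exactly.
#'
#' @param net a [signed_network]
#' @return a [signed_network]
#' @export
shuffle_signs <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  e <- net$edges
  if (nrow(e) > 1L) e$sign <- sample(e$sign)
  signed_network(e, nodes = net$nodes)
}

#' Triad-type enrichment against the sign-shuffle null
#'
#' Compares the observed count of each signed triad type with its
#' distribution under random shuffling of the edge signs (topology and the
#' numbers of positive/negative edges fixed). Fold is observed over null
#' mean (`Inf` when the null mean is 0 but the type is observed; `NA` when
#' both are 0). Empirical p-values use the add-one convention
#' p = (1 + number of shuffles at least as extreme) / (n_shuffles + 1); the
#' upper tail (`p_over`) tests over-representation, the lower tail
#' (`p_under`) depletion.
#'
#' Each shuffle draws from its own deterministically derived seed
#' (`seed + shuffle index`), so per-shuffle results do not depend on
#' evaluation order.
#'
#' @param net a [signed_network]
#' @param n_shuffles number of sign permutations (default 1000)
#' @param seed integer seed driving all shuffles
#' @return a `triad_census` with null summaries (`null_mean`, `null_sd`,
#'   `fold`, `p_over`, `p_under`, `n_shuffles`, `seed`) attached
#' @export
triad_enrichment <- function(net, n_shuffles = 1000L, seed = 1L) {
  stopifnot(inherits(net, "signed_network"), n_shuffles >= 1L)
  tri <- triangle_edge_index(net)
  signs <- net$edges$sign
  obs <- triad_counts_from_signs(tri, signs)
  nullc <- matrix(0L, nrow = n_shuffles, ncol = 4L,
                  dimnames = list(NULL, names(obs)))
  for (b in seq_len(n_shuffles)) {
    set.seed((seed + b) %% .Machine$integer.max)
    nullc[b, ] <- triad_counts_from_signs(tri, sample(signs))
  }
  null_mean <- colMeans(nullc)
  null_sd <- apply(nullc, 2L, stats::sd)
  fold <- ifelse(null_mean > 0, obs / null_mean,
                 ifelse(obs > 0, Inf, NA_real_))
  p_over <- (1 + colSums(nullc >= rep(obs, each = n_shuffles))) / (n_shuffles + 1)
  p_under <- (1 + colSums(nullc <= rep(obs, each = n_shuffles))) / (n_shuffles + 1)
  structure(list(counts = obs, total = sum(obs),
                 patterns = c(T1 = "+++", T2 = "+--", T3 = "++-", T4 = "---"),
                 null_mean = null_mean, null_sd = null_sd, fold = fold,
                 p_over = p_over, p_under = p_under,
                 n_shuffles = n_shuffles, seed = seed),
            class = "triad_census")
}

#' Expected triad counts under uniform sign permutation (closed form)
#'
#' Under a uniform permutation of the sign multiset, the three edges of any
#' fixed triangle receive k positive signs with multivariate hypergeometric
#' probability choose(M+, k) choose(M-, 3-k) / choose(M, 3). By linearity the
#' expected count of each triad type is the total triangle count times that
#' probability (k = 3, 1, 2, 0 for T1, T2, T3, T4).
#'
#' @param net a [signed_network]
#' @return named numeric vector of expected counts for T1..T4
#' @export
expected_triad_counts <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  m <- nrow(net$edges)
  mp <- sum(net$edges$sign > 0)
  total <- count_signed_triads(net)$total
  if (m < 3L) return(c(T1 = 0, T2 = 0, T3 = 0, T4 = 0))
  pk <- function(k) choose(mp, k) * choose(m - mp, 3 - k) / choose(m, 3)
  total * c(T1 = pk(3), T2 = pk(1), T3 = pk(2), T4 = pk(0))
}
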