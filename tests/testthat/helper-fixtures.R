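# Shared fixtures and independent oracles for the test suite.

# 5-node worked example used throughout: triangle 1-2-3 all positive,
# node 4 mixed, node 5 negative pendant pair
e1_network <- function() {
  signed_network(data.frame(
    from = c("1", "1", "2", "1", "2", "1", "2"),
    to   = c("2", "3", "3", "4", "4", "5", "5"),
    sign = c(1, 1, 1, 1, -1, -1, -1)))
}

# complete balanced two-block network on {a,b,c} / {d,e,f}
balanced_two_block <- function() {
  balanced_block_network(c(3, 3), p_in = 1, p_out = 1, epsilon = 0,
                         seed = 1L)$network
}

# dense node-indexed sign matrix (0 = no edge) for the oracles
sign_matrix <- function(net) {
  n <- length(net$nodes)
  S <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  e <- net$edges
  for (r in seq_len(nrow(e))) {
    S[e$from[r], e$to[r]] <- e$sign[r]
    S[e$to[r], e$from[r]] <- e$sign[r]
  }
  S
}

# Brute-force coefficient oracle: for every edge, enumerate ALL nodes k and
# classify the triple (i, j, k) directly from the sign matrix. Independent
# of the package's adjacency-based implementation.
oracle_coeffs <- function(net) {
  S <- sign_matrix(net)
  e <- net$edges
  out <- data.frame(from = e$from, to = e$to, sign = e$sign,
                    LC = 0, SLC = 0, HLC = 0, PLC = 0, NLC = 0,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(e))) {
    i <- e$from[r]; j <- e$to[r]
    others <- setdiff(net$nodes, c(i, j))
    si <- S[i, others]; sj <- S[j, others]
    n_i <- sum(si != 0L); n_j <- sum(sj != 0L)
    both <- si != 0L & sj != 0L
    cpp <- sum(both & si > 0L & sj > 0L)
    cnn <- sum(both & si < 0L & sj < 0L)
    chy <- sum(both) - cpp - cnn
    d <- min(n_i, n_j)
    if (d > 0) {
      out$LC[r] <- (cpp + cnn + chy) / d
      out$SLC[r] <- (cpp + cnn) / d
      out$HLC[r] <- chy / d
      out$PLC[r] <- cpp / d
      out$NLC[r] <- cnn / d
    }
  }
  rownames(out) <- paste(e$from, e$to, sep = "|")
  out
}

# Brute-force triad census: scan all node triples
oracle_triads <- function(net) {
  S <- sign_matrix(net)
  counts <- c(T1 = 0L, T2 = 0L, T3 = 0L, T4 = 0L)
  n <- length(net$nodes)
  if (n < 3L) return(counts)
  triples <- utils::combn(net$nodes, 3)
  for (t in seq_len(ncol(triples))) {
    a <- triples[1, t]; b <- triples[2, t]; c <- triples[3, t]
    s <- c(S[a, b], S[a, c], S[b, c])
    if (all(s != 0L)) {
      npos <- sum(s > 0L)
      # 0 positives -> T4, 1 -> T2, 2 -> T3, 3 -> T1
      type <- c("T4", "T2", "T3", "T1")[npos + 1L]
      counts[type] <- counts[type] + 1L
    }
  }
  counts
}

# hypergeometric closed form for expected triad counts under sign shuffling
oracle_expected_triads <- function(net, total_triangles) {
  m <- nrow(net$edges)
  mp <- sum(net$edges$sign > 0)
  pk <- function(k) stats::dhyper(k, mp, m - mp, 3)
  total_triangles * c(T1 = pk(3), T2 = pk(1), T3 = pk(2), T4 = pk(0))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
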