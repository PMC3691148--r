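# all generators take an explicit integer seed and restore the caller's
# RNG state on exit; no global state leaks between calls
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Structurally balanced block network with sign noise
#'
#' Generates the canonical balanced construction: nodes fall into k blocks,
#' each intra-block pair receives a positive edge with probability `p_in`,
#' each inter-block pair a negative edge with probability `p_out`, and every
#' edge's sign is then flipped independently with probability `epsilon`.
#' With `epsilon = 0` the result is exactly structurally balanced: every
#' triangle is +++ or +--, every negative edge has SLC 0 and every positive
#' edge has HLC 0.
#'
#' @param sizes integer vector of block sizes (length = number of blocks)
#' @param p_in intra-block (positive) edge probability
#' @param p_out inter-block (negative) edge probability
#' @param epsilon sign-flip probability (default 0)
#' @param seed integer seed
#' @return list with `network` (a [signed_network] whose node set includes
#'   all generated nodes), `blocks` (data.frame `node`, `block`), and
#'   `true_sign` (the pre-noise sign per edge, named by canonical edge key)
#' @export
balanced_block_network <- function(sizes, p_in = 1, p_out = 1, epsilon = 0,
                                   seed = 1L) {
  stopifnot(all(sizes >= 1L), p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            epsilon >= 0, epsilon <= 1)
  k <- length(sizes)
  n <- sum(sizes)
  block <- rep(seq_len(k), sizes)
  node <- sprintf("n%03d_b%d", seq_len(n), block)
  with_seed(seed, {
    pr <- utils::combn(n, 2)
    same <- block[pr[1, ]] == block[pr[2, ]]
    p <- ifelse(same, p_in, p_out)
    present <- stats::runif(ncol(pr)) < p
    true_sign <- ifelse(same[present], 1L, -1L)
    flip <- stats::runif(sum(present)) < epsilon
    sign <- ifelse(flip, -true_sign, true_sign)
    from <- node[pr[1, present]]
    to <- node[pr[2, present]]
    net <- signed_network(data.frame(from = from, to = to, sign = sign,
                                     stringsAsFactors = FALSE), nodes = node)
    list(network = net,
         blocks = data.frame(node = node, block = block,
                             stringsAsFactors = FALSE),
         true_sign = stats::setNames(true_sign, edge_key(from, to)))
  })
}

#' Random signed Erdos-Renyi network
#'
#' G(n, p) with each edge independently positive with probability
#' `positive_fraction`; signs are independent of topology, so the
#' sign-shuffle null reproduces the observed triad frequencies up to
#' sampling error.
#'
#' @param n number of nodes
#' @param p edge probability
#' @param positive_fraction probability an edge is positive (default 0.5)
#' @param seed integer seed
#' @return a [signed_network] whose node set includes all `n` nodes
#' @export
random_signed_network <- function(n, p, positive_fraction = 0.5, seed = 1L) {
  stopifnot(n >= 1L, p >= 0, p <= 1,
            positive_fraction >= 0, positive_fraction <= 1)
  node <- sprintf("v%04d", seq_len(n))
  if (n < 2L) return(signed_network(NULL, nodes = node))
  with_seed(seed, {
    pr <- utils::combn(n, 2)
    present <- stats::runif(ncol(pr)) < p
    sign <- ifelse(stats::runif(sum(present)) < positive_fraction, 1L, -1L)
    signed_network(data.frame(from = node[pr[1, present]],
                              to = node[pr[2, present]],
                              sign = sign, stringsAsFactors = FALSE),
                   nodes = node)
  })
}

#' Expression matrix with planted correlated / anti-correlated modules
#'
#' Emulates condition-driven coexpression structure: modules come in
#' anti-phase pairs. Each pair q carries a latent sample profile
#' z_q = (d_q + w_q) / sqrt(2), where d_q is a two-level condition contrast
#' (+1 over the first `condition_split` fraction of samples, -1 over the
#' rest, alternating orientation between pairs) and w_q is independent
#' standard normal per sample. A gene in the first module of the pair is
#' z_q plus independent N(0, tau^2) noise; a gene in the partner module is
#' built on -(gamma * z_q + sqrt(1 - gamma^2) * w'), so its correlation with
#' the first module is attenuated by gamma.
#'
#' Calibration: the expected within-module correlation is
#' 1 / (1 + tau^2 / var(z)) and the anti-phase between-module correlation is
#' -gamma times that. `tau` is chosen as sqrt(var(z) * (1/within_r - 1)) so
#' the within-module target is `within_r`, and
#' gamma = |between_r| / within_r (requiring between_r <= 0 and
#' |between_r| <= within_r). Supplying `noise_sd` overrides the derived tau.
#'
#' @param n_modules number of modules (paired as (1,2), (3,4), ...)
#' @param genes_per_module genes in each module
#' @param n_samples number of samples (>= 4)
#' @param condition_split fraction of samples in the first condition block
#' @param within_r target within-module Pearson correlation (default 0.95)
#' @param between_r target anti-phase between-module correlation (default
#'   `-within_r`)
#' @param noise_sd optional explicit per-gene noise standard deviation;
#'   `noise_sd = 0` gives exactly +1 within modules and `-gamma` across
#'   anti-phase pairs
#' @param seed integer seed
#' @return list with `expr` (genes x samples matrix), `truth` (data.frame
#'   `gene`, `module`, `pair`, `polarity`), and `params` (resolved tau and
#'   gamma)
#' @export
planted_module_expression <- function(n_modules = 2L, genes_per_module = 10L,
                                      n_samples = 50L, condition_split = 0.5,
                                      within_r = 0.95, between_r = -within_r,
                                      noise_sd = NULL, seed = 1L) {
  stopifnot(n_samples >= 4L, n_modules >= 1L, genes_per_module >= 1L,
            condition_split > 0, condition_split < 1)
  if (within_r <= 0 || within_r > 1) {
    stop("infeasible correlation target: need 0 < within_r <= 1")
  }
  if (between_r > 0 || abs(between_r) > within_r) {
    stop("infeasible correlation target: need between_r <= 0 and |between_r| <= within_r")
  }
  gamma <- abs(between_r) / within_r
  n_pairs <- ceiling(n_modules / 2)
  d_base <- rep(c(1, -1),
                c(ceiling(condition_split * n_samples),
                  n_samples - ceiling(condition_split * n_samples)))
  with_seed(seed, {
    genes <- character(0)
    module <- integer(0)
    rows <- vector("list", n_modules)
    for (q in seq_len(n_pairs)) {
      d <- d_base * (-1)^(q - 1)
      w <- stats::rnorm(n_samples)
      z <- (d + w) / sqrt(2)
      vz <- stats::var(z)  # realized variance of the latent profile
      tau <- if (is.null(noise_sd)) sqrt(vz * (1 / within_r - 1)) else noise_sd
      wprime <- stats::rnorm(n_samples, sd = sqrt(vz))
      z_partner <- -(gamma * z + sqrt(1 - gamma^2) * wprime)
      for (half in 1:2) {
        m <- 2L * (q - 1L) + half
        if (m > n_modules) next
        base <- if (half == 1L) z else z_partner
        g <- matrix(rep(base, each = genes_per_module),
                    nrow = genes_per_module) +
          matrix(stats::rnorm(genes_per_module * n_samples, sd = tau),
                 nrow = genes_per_module)
        rownames(g) <- sprintf("g%03d_m%d",
                               (m - 1L) * genes_per_module +
                                 seq_len(genes_per_module), m)
        rows[[m]] <- g
        genes <- c(genes, rownames(g))
        module <- c(module, rep(m, genes_per_module))
      }
    }
    expr <- do.call(rbind, rows)
    colnames(expr) <- sprintf("s%03d", seq_len(n_samples))
    tau_used <- if (is.null(noise_sd)) NA_real_ else noise_sd
    list(expr = expr,
         truth = data.frame(gene = genes, module = module,
                            pair = ceiling(module / 2),
                            polarity = ifelse(module %% 2L == 1L, 1L, -1L),
                            stringsAsFactors = FALSE),
         params = list(gamma = gamma, noise_sd = tau_used,
                       within_r = within_r, between_r = between_r))
  })
}
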