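test_that("pairwise correlations match exact and independent two-pass values", {
  expr <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8),
                g3 = c(4, 3, 2, 1), g4 = c(1, 0, 1, 0))
  tab <- pairwise_pcc(expr, min_samples = 3)
  get <- function(a, b) tab$pcc[tab$gene_a == a & tab$gene_b == b]
  expect_equal(get("g1", "g2"), 1)
  expect_equal(get("g1", "g3"), -1)

  # independent two-pass oracle: center then normalise explicitly
  two_pass <- function(x, y) {
    xc <- x - mean(x); yc <- y - mean(y)
    sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  }
  expect_equal(get("g1", "g4"), two_pass(expr["g1", ], expr["g4", ]))
  expect_equal(get("g2", "g4"), two_pass(expr["g2", ], expr["g4", ]))

  expect_error(pairwise_pcc(expr[1, , drop = FALSE]), "2 genes")
})

test_that("undefined pairs (few observations, zero variance) are excluded", {
  expr <- rbind(g1 = c(1, 2, 3, 4, 5),
                g2 = c(2, 1, NA, NA, NA),
                g3 = c(7, 7, 7, 7, 7))
  tab <- pairwise_pcc(expr, min_samples = 3)
  # g1-g2 has only 2 complete pairs; g3 is constant
  expect_equal(nrow(tab), 0L)
  tab <- pairwise_pcc(expr[1:2, ], min_samples = 2)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_obs, 2L)
})

test_that("thresholding retains ties and produces the expected signed edges", {
  expr <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8),
                g3 = c(4, 3, 2, 1))
  net <- build_cen(expr, min_samples = 3)
  expect_equal(net$edges,
               data.frame(from = c("g1", "g1", "g2"),
                          to = c("g2", "g3", "g3"),
                          sign = c(1L, -1L, -1L)))

  # tie at the threshold is included (PCC exactly +-1 here at threshold 1)
  net <- build_cen(expr, pos_threshold = 1, neg_threshold = -1,
                   min_samples = 3)
  expect_equal(nrow(net$edges), 3L)

  expect_error(build_cen(expr, pos_threshold = -0.5), "neg_threshold < 0")
  expect_error(build_cen(expr, pos_threshold = 1.2), "\\[-1, 1\\]")
})

test_that("independent noise genes yield approximately no edges at |r|>=0.9", {
  # analytic null tail: P(|PCC| >= 0.9) at n = 50 via the t transform
  n <- 50
  t_crit <- 0.9 * sqrt((n - 2) / (1 - 0.9^2))
  p_tail <- 2 * stats::pt(t_crit, df = n - 2, lower.tail = FALSE)
  n_genes <- 50
  n_pairs <- choose(n_genes, 2)
  expected <- n_pairs * p_tail  # ~ 1e-9: essentially zero
  set.seed(99)
  expr <- matrix(stats::rnorm(n_genes * n), nrow = n_genes,
                 dimnames = list(sprintf("g%02d", 1:n_genes), NULL))
  net <- build_cen(expr)
  expect_lt(expected, 0.001)
  expect_equal(nrow(net$edges), 0L)
})

test_that("planted two-block expression gives within-positive, between-negative", {
  sim <- planted_module_expression(n_modules = 2, genes_per_module = 6,
                                   n_samples = 30, noise_sd = 0.1, seed = 3)
  net <- build_cen(sim$expr)
  # brute-force check against plain cor()
  cc <- stats::cor(t(sim$expr))
  for (r in seq_len(nrow(net$edges))) {
    v <- cc[net$edges$from[r], net$edges$to[r]]
    expect_true(if (net$edges$sign[r] > 0) v >= 0.9 else v <= -0.9)
  }
  mod <- stats::setNames(sim$truth$module, sim$truth$gene)
  same <- mod[net$edges$from] == mod[net$edges$to]
  expect_true(all(net$edges$sign[same] == 1L))
  expect_true(all(net$edges$sign[!same] == -1L))
})

test_that("build_cen is monotone in its thresholds", {
  sim <- planted_module_expression(n_modules = 2, genes_per_module = 5,
                                   n_samples = 20, noise_sd = 0.6, seed = 8)
  keys <- function(net, s) {
    e <- net$edges[net$edges$sign == s, ]
    paste(e$from, e$to)
  }
  thresholds <- c(0.5, 0.7, 0.9)
  for (k in seq_len(length(thresholds) - 1)) {
    lo <- build_cen(sim$expr, thresholds[k], -thresholds[k])
    hi <- build_cen(sim$expr, thresholds[k + 1], -thresholds[k + 1])
    expect_true(all(keys(hi, 1) %in% keys(lo, 1)))
    expect_true(all(keys(hi, -1) %in% keys(lo, -1)))
  }
})

test_that("sign symmetry: negating profiles transforms the network predictably", {
  sim <- planted_module_expression(n_modules = 2, genes_per_module = 5,
                                   n_samples = 25, noise_sd = 0.2, seed = 12)
  net <- build_cen(sim$expr)
  # global negation leaves the network unchanged
  expect_equal(build_cen(-sim$expr)$edges, net$edges)
  # negating half the genes flips exactly the edges crossing the split
  flip <- rownames(sim$expr)[seq_len(nrow(sim$expr) / 2)]
  expr2 <- sim$expr
  expr2[flip, ] <- -expr2[flip, ]
  net2 <- build_cen(expr2)
  crossing <- xor(net$edges$from %in% flip, net$edges$to %in% flip)
  expected <- net$edges
  expected$sign <- ifelse(crossing, -expected$sign, expected$sign)
  expected <- expected[order(expected$from, expected$to), ]
  rownames(expected) <- NULL
  expect_equal(net2$edges, expected)
})

test_that("blockwise sweep matches the naive all-pairs computation", {
  sim <- planted_module_expression(n_modules = 4, genes_per_module = 4,
                                   n_samples = 20, noise_sd = 0.3, seed = 21)
  naive <- build_cen(sim$expr, block_size = 1000L)
  blocked <- build_cen(sim$expr, block_size = 3L)
  expect_equal(blocked$edges, naive$edges)
})

test_that("series-matrix style expression files read correctly", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("!Series_title\tsomething", "ID\ts1\ts2\ts3",
               "gA\t1\t2\t3", "gB\t3\t2\tnull"), tf)
  m <- read_expression_matrix(tf)
  expect_equal(dim(m), c(2L, 3L))
  expect_true(is.na(m["gB", "s3"]))
  expect_equal(m["gA", ], c(s1 = 1, s2 = 2, s3 = 3))
})
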