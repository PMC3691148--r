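test_that("common neighbors partition by sign pattern on worked examples", {
  e1 <- e1_network()
  expect_equal(common_neighbor_partition(e1, "1", "2"),
               c(c_pp = 1, c_nn = 1, c_hy = 1))

  tri <- signed_network(data.frame(from = c("a", "a", "b"),
                                   to = c("b", "c", "c"), sign = 1))
  expect_equal(common_neighbor_partition(tri, "a", "b"),
               c(c_pp = 1, c_nn = 0, c_hy = 0))

  # balance forces every cross-block common neighbor to be hybrid
  bb <- balanced_two_block()
  a <- grep("_b1$", bb$nodes, value = TRUE)[1]
  d <- grep("_b2$", bb$nodes, value = TRUE)[1]
  expect_equal(common_neighbor_partition(bb, a, d),
               c(c_pp = 0, c_nn = 0, c_hy = 4))

  expect_error(common_neighbor_partition(e1, "3", "5"), "not in the network")
})

test_that("coefficients reproduce the worked example and degenerate cases", {
  co <- link_clustering_coefficients(e1_network())
  expect_equal(unlist(co["1|2", c("LC", "SLC", "HLC", "PLC", "NLC")]),
               c(LC = 1, SLC = 2/3, HLC = 1/3, PLC = 1/3, NLC = 1/3))
  expect_equal(unlist(co["2|4", c("LC", "SLC", "HLC", "PLC", "NLC")]),
               c(LC = 1, SLC = 1, HLC = 0, PLC = 1, NLC = 0))

  # pendant edge: zero denominator gives all-zero coefficients
  pend <- signed_network(data.frame(from = "a", to = "b", sign = -1))
  cp <- link_clustering_coefficients(pend)
  expect_equal(unname(unlist(cp[1, c("LC", "SLC", "HLC", "PLC", "NLC")])),
               rep(0, 5))
})

test_that("coefficients match the brute-force all-triples oracle", {
  for (seed in 1:25) {
    net <- random_signed_network(n = 5 + (seed %% 26), p = 0.35,
                                 positive_fraction = 0.5, seed = seed)
    if (nrow(net$edges) == 0L) next
    co <- link_clustering_coefficients(net)
    or <- oracle_coeffs(net)
    expect_equal(as.data.frame(co)[, c("LC", "SLC", "HLC", "PLC", "NLC")],
                 or[, c("LC", "SLC", "HLC", "PLC", "NLC")],
                 ignore_attr = TRUE)
  }
})

test_that("decomposition identities hold exactly under min_total", {
  for (seed in 1:10) {
    net <- random_signed_network(n = 20, p = 0.3, seed = 100 + seed)
    co <- link_clustering_coefficients(net)
    expect_equal(co$LC, co$SLC + co$HLC)
    expect_equal(co$SLC, co$PLC + co$NLC)
    expect_true(all(co$c_pp + co$c_nn + co$c_hy <= pmin(co$n_i, co$n_j)))
    expect_true(all(co$LC >= 0 & co$LC <= 1))
  }
})

test_that("sign-flip duality swaps PLC and NLC, fixing LC, SLC, HLC", {
  net <- random_signed_network(n = 18, p = 0.35, seed = 77)
  flipped <- signed_network(transform(net$edges, sign = -sign),
                            nodes = net$nodes)
  co <- link_clustering_coefficients(net)
  cf <- link_clustering_coefficients(flipped)
  expect_equal(cf$LC, co$LC)
  expect_equal(cf$SLC, co$SLC)
  expect_equal(cf$HLC, co$HLC)
  expect_equal(cf$PLC, co$NLC)
  expect_equal(cf$NLC, co$PLC)
})

test_that("coefficients are invariant under node relabeling", {
  net <- random_signed_network(n = 12, p = 0.4, seed = 55)
  set.seed(56)
  perm <- stats::setNames(sprintf("x%02d", sample(seq_along(net$nodes))),
                          net$nodes)
  rel <- signed_network(data.frame(from = perm[net$edges$from],
                                   to = perm[net$edges$to],
                                   sign = net$edges$sign),
                        nodes = unname(perm))
  co <- link_clustering_coefficients(net)
  cr <- link_clustering_coefficients(rel)
  keymap <- paste(pmin(perm[co$from], perm[co$to]),
                  pmax(perm[co$from], perm[co$to]), sep = "|")
  for (col in c("LC", "SLC", "HLC", "PLC", "NLC")) {
    expect_equal(cr[keymap, col], co[[col]])
  }
})

test_that("two-block balanced networks zero out SLC(-) and HLC(+)", {
  for (seed in 1:5) {
    sim <- balanced_block_network(c(6, 5), p_in = 0.9, p_out = 0.8,
                                  epsilon = 0, seed = seed)
    co <- link_clustering_coefficients(sim$network)
    expect_true(all(co$SLC[co$sign < 0] == 0))
    expect_true(all(co$HLC[co$sign > 0] == 0))
  }
})

test_that("multi-block (weakly balanced) networks still zero out HLC(+)", {
  # with three or more blocks a negative edge can share negative-negative
  # neighbors in a third block (SLC(-) > 0 allowed), but positive edges
  # never acquire hybrid common neighbors
  sim <- balanced_block_network(c(6, 5, 4), p_in = 0.9, p_out = 0.8,
                                epsilon = 0, seed = 2)
  co <- link_clustering_coefficients(sim$network)
  expect_true(all(co$HLC[co$sign > 0] == 0))
  expect_equal(unname(count_signed_triads(sim$network)$counts["T3"]), 0L)
})

test_that("the min_signed convention stays within [0,1] and matches counts", {
  net <- random_signed_network(n = 20, p = 0.4, seed = 13)
  cs <- link_clustering_coefficients(net, denominator = "min_signed")
  for (col in c("LC", "SLC", "HLC", "PLC", "NLC")) {
    expect_true(all(cs[[col]] >= 0 & cs[[col]] <= 1))
  }
  # PLC denominator is the smaller positive excess-neighbor count
  d <- pmin(cs$n_pos_i, cs$n_pos_j)
  expect_equal(cs$PLC, ifelse(d > 0, cs$c_pp / d, 0))
})

test_that("CNB profile reproduces the worked example and degenerate cases", {
  e1 <- e1_network()
  prof <- cnb_profile(e1)
  row <- prof$profile[prof$profile$from == "1" & prof$profile$to == "5", ]
  expect_equal(row$HLC, 1)
  expect_equal(row$med_PLC_pos, 1/3)
  expect_equal(row$med_HLC_neg, 1)
  # rows exist only for negative edges with a hybrid common neighbor
  expect_true(all(prof$profile$n_hybrid >= 1))
  keys <- paste(prof$profile$from, prof$profile$to, sep = "|")
  co <- link_clustering_coefficients(e1)
  expect_true(all(co[keys, "sign"] < 0))

  # balanced two-block network: every negative-member HLC saturates at 1
  # and every positive-member PLC takes the same symmetric value (1/4:
  # one same-block and three cross-block common neighbors), so both
  # medians are constant and the correlations are undefined
  bb <- balanced_two_block()
  pb <- cnb_profile(bb)
  expect_true(all(pb$profile$med_HLC_neg == 1))
  expect_true(all(pb$profile$med_PLC_pos == 1 / 4))
  expect_true(is.na(pb$cor_PLC) && is.na(pb$cor_HLC))

  # no negative edges -> empty profile
  pos <- signed_network(data.frame(from = c("a", "a", "b"),
                                   to = c("b", "c", "c"), sign = 1))
  expect_equal(nrow(cnb_profile(pos)$profile), 0L)
})

test_that("CNB correlations are defined on noisy balanced block networks", {
  sim <- balanced_block_network(c(12, 12, 12), p_in = 0.7, p_out = 0.5,
                                epsilon = 0.1, seed = 202)
  prof <- cnb_profile(sim$network)
  expect_gte(nrow(prof$profile), 3L)
  expect_false(is.na(prof$cor_PLC))
  expect_false(is.na(prof$cor_HLC))
})
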