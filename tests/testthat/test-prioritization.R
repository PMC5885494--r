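test_that("overlap counting intersects both sets with the universe", {
  uni <- c("A", "B", "C", "D", "E")
  expect_identical(overlap_count(c("A", "B"), c("C", "D"), uni), 0L)
  expect_identical(overlap_count(uni, uni, uni), 5L)
  expect_identical(overlap_count(c("A", "B", "C"), c("B", "C", "D"), uni), 2L)
  # genes outside the universe never count
  expect_identical(overlap_count(c("A", "X"), c("A", "X"), uni), 1L)
  expect_identical(overlap_count(c("a"), c("A"), uni), 1L)  # case-normalized
})

test_that("the hypergeometric oracle matches exhaustive enumeration", {
  counts <- enumerate_overlap_null(10, 4, 3)  # all 120 subsets
  o <- hypergeometric_oracle(4, 3, 2, 10)
  expect_equal(o$tail, mean(counts > 2))
  expect_equal(o$tail, 1 / 30)
  expect_equal(o$mean, mean(counts))
  expect_equal(o$mean, 1.2)
  expect_equal(o$sd, sqrt(mean((counts - mean(counts))^2)))
  expect_equal(o$sd, sqrt(0.56))
  # support bound and empty-target degenerate cases
  expect_equal(hypergeometric_oracle(4, 3, 3, 10)$tail, 0)
  expect_equal(unlist(hypergeometric_oracle(0, 3, 0, 10)),
               c(tail = 0, mean = 0, sd = 0))
})

test_that("a degenerate null (targets cover the universe) gives p = 0, sigma = 0", {
  pt <- permutation_test(K = 10, n = 4, g_obs = 4, universe = 10,
                         n_perm = 500, seed = 1)
  expect_equal(pt$p, 0)
  expect_equal(pt$sigma, 0)
  expect_equal(pt$mu, 4)
  expect_true(is.na(z_score(pt$g_obs, pt$mu, pt$sigma)))
})

test_that("permutation estimates converge to the closed forms", {
  n_perm <- 20000
  cases <- list(c(N = 10, K = 4, n = 3, g = 2),
                c(N = 50, K = 20, n = 10, g = 5),
                c(N = 200, K = 30, n = 40, g = 8))
  for (cs in cases) {
    o <- hypergeometric_oracle(cs["K"], cs["n"], cs["g"], cs["N"])
    pt <- permutation_test(cs["K"], cs["n"], cs["g"], cs["N"],
                           n_perm = n_perm, seed = 99)
    se <- sqrt(o$tail * (1 - o$tail) / n_perm)
    expect_lt(abs(pt$p - o$tail), 3 * se + 1e-12)
    expect_lt(abs(pt$mu - o$mean) / o$mean, 0.02)
    expect_lt(abs(pt$sigma - o$sd) / o$sd, 0.02)
  }
})

test_that("permutation p is within 3 MC standard errors in >= 99% of 100 repeats", {
  N <- 60; K <- 15; n <- 12; g <- 4; n_perm <- 2000
  o <- hypergeometric_oracle(K, n, g, N)
  se <- sqrt(o$tail * (1 - o$tail) / n_perm)
  ok <- vapply(1:100, function(s) {
    abs(permutation_test(K, n, g, N, n_perm = n_perm, seed = s)$p - o$tail) <=
      3 * se
  }, logical(1))
  expect_gte(sum(ok), 99)
})

test_that("p is non-increasing in the observed overlap for a fixed seed", {
  ps <- vapply(0:8, function(g)
    permutation_test(20, 10, g, 100, n_perm = 3000, seed = 7)$p, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("the same seed reproduces the null; pseudocount keeps p positive", {
  a <- permutation_test(20, 10, 3, 100, n_perm = 1000, seed = 5)
  b <- permutation_test(20, 10, 3, 100, n_perm = 1000, seed = 5)
  expect_identical(a, b)
  pc <- permutation_test(20, 10, 10, 100, n_perm = 1000, seed = 5,
                         pseudocount = TRUE)
  expect_equal(pc$p, (pc$n_exceed + 1) / 1001)
  expect_gt(pc$p, 0)
})

test_that("parameter validation rejects impossible draws", {
  expect_error(permutation_test(200, 10, 3, 100), "K")
  expect_error(permutation_test(20, 200, 3, 100), "n")
  expect_error(permutation_test(20, 10, 15, 100), "g_obs")
  expect_error(hypergeometric_oracle(20, 10, 15, 100), "g_obs")
})

test_that("z-scores standardize against the null and guard sigma = 0", {
  expect_equal(z_score(1.2, 1.2, 0.5), 0)
  expect_equal(z_score(2, 1.2, sqrt(0.56)), (2 - 1.2) / sqrt(0.56))
  expect_equal(z_score(2, 1.2, sqrt(0.56)), 1.069, tolerance = 1e-3)
  expect_true(is.na(z_score(3, 3, 0)))
  expect_error(z_score(1, 1, -1), "sigma")
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.002)),
               c(0.02, 0.04, 0.04, 0.008))
  expect_equal(bh_adjust(rep(0.05, 3)), rep(0.05, 3))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH q-values dominate p and are monotone along the p order", {
  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-15))
  }
})

test_that("prioritize_all is deterministic and order-independent", {
  cfg <- tiny_config(noise_sd = 0.1)
  truth <- ground_truth(cfg)
  expr <- generate_expression(cfg, truth)
  ss <- build_signature_set(expr$expression, expr$probe_map, expr$annotation)
  net <- structure(list(genes = truth$disease_sets,
                        provenance = lapply(truth$disease_sets,
                                            function(g) rep("catalog", length(g))),
                        labels = setNames(names(truth$disease_sets),
                                          names(truth$disease_sets))),
                   class = "disease_network")
  r1 <- prioritize_all(ss, net, n_perm = 500, seed = 21)
  r2 <- prioritize_all(ss, net, n_perm = 500, seed = 21)
  expect_identical(r1, r2)
  # reversing compound iteration order leaves every pair's result unchanged
  ss_rev <- ss
  ss_rev$signatures <- rev(ss$signatures)
  r3 <- prioritize_all(ss_rev, net, n_perm = 500, seed = 21)
  key <- function(r) paste(r$compound, r$disease_id)
  expect_equal(r1[order(key(r1)), c("p", "z", "q", "overlap")],
               r3[order(key(r3)), c("p", "z", "q", "overlap")],
               ignore_attr = TRUE)
  expect_equal(r1$q, bh_adjust(r1$p))
  expect_true(all(r1$significant == (r1$q < 0.2 & !is.na(r1$z))))
})

test_that("planted pairs dominate the ranking on a noiseless fixture", {
  cfg <- tiny_config(noise_sd = 0)
  truth <- ground_truth(cfg)
  expr <- generate_expression(cfg, truth)
  ss <- build_signature_set(expr$expression, expr$probe_map, expr$annotation)
  net <- structure(list(genes = truth$disease_sets,
                        provenance = lapply(truth$disease_sets,
                                            function(g) rep("catalog", length(g))),
                        labels = setNames(names(truth$disease_sets),
                                          names(truth$disease_sets))),
                   class = "disease_network")
  res <- prioritize_all(ss, net, n_perm = 2000, seed = 13)
  top <- res[seq_len(nrow(truth$planted_pairs)), ]
  expect_setequal(paste(top$compound, top$disease_id),
                  paste(truth$planted_pairs$compound,
                        truth$planted_pairs$disease_id))
  # observed overlap equals the planted overlap end-to-end
  m <- merge(res, truth$planted_pairs,
             by.x = c("compound", "disease_id"),
             by.y = c("compound", "disease_id"))
  expect_equal(m$overlap.x, m$overlap.y)
})

test_that("empty signatures yield zero overlaps and no significant pair", {
  ss <- structure(list(signatures = list(c1 = list(up = character(0),
                                                   down = character(0))),
                       universe = sprintf("G%03d", 1:50), threshold = 1.5),
                  class = "signature_set")
  net <- structure(list(genes = list(`C01.001.001` = sprintf("G%03d", 1:10)),
                        provenance = list(`C01.001.001` = rep("catalog", 10)),
                        labels = c(`C01.001.001` = "d")),
                   class = "disease_network")
  res <- prioritize_all(ss, net, n_perm = 200, seed = 1)
  expect_true(all(res$overlap == 0))
  expect_true(all(!res$significant))
  expect_true(all(is.na(res$z)))
})
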