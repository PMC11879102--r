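sig_from <- function(id, genes, values) {
  expression_signature(id, genes, values, perturbagen_id = paste0("p_", id),
                       target_id = "T1")
}

test_that("consensus weights follow the clipped Spearman row sums", {
  g <- paste0("g", 1:6)
  s1 <- sig_from("a", g, c(3.0, 1.5, -0.5, 2.0, -2.0, 0.1))
  s2 <- sig_from("b", g, c(2.5, 1.0, -1.0, 2.2, -1.5, 0.3))
  s3 <- sig_from("c", g, c(-1.0, 2.0, 1.5, -0.5, 0.8, -2.2))

  # independent oracle: rank each profile by hand, then Pearson on ranks
  # via the covariance formula
  rank_cor <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  vals <- list(s1$values, s2$values, s3$values)
  rho <- diag(3)
  for (i in 1:3) for (j in 1:3) rho[i, j] <- rank_cor(vals[[i]], vals[[j]])
  rho <- pmax(rho, 0.01)
  diag(rho) <- 0
  expected <- rowSums(rho) / sum(rowSums(rho))

  expect_equal(consensus_weights(list(s1, s2, s3)), expected,
               tolerance = 1e-12)
  # trivial cases
  expect_identical(consensus_weights(list(s1)), 1)
  expect_equal(consensus_weights(list(s1, s3)), c(0.5, 0.5))
  expect_error(consensus_weights(list()), "no signatures")
  s_small1 <- sig_from("x", c("g1", "g2"), c(1, 2))
  s_small2 <- sig_from("y", c("g1", "g2"), c(2, 1))
  expect_error(consensus_weights(list(s_small1, s_small2)),
               "insufficient overlap")
})

test_that("consensus is the element-wise weighted average on the common universe", {
  g <- paste0("g", 1:6)
  s1 <- sig_from("a", g, c(3.0, 1.5, -0.5, 2.0, -2.0, 0.1))
  s2 <- sig_from("b", g, c(2.5, 1.0, -1.0, 2.2, -1.5, 0.3))
  s3 <- sig_from("c", g, c(-1.0, 2.0, 1.5, -0.5, 0.8, -2.2))
  w <- consensus_weights(list(s1, s2, s3))
  expected <- w[1] * s1$values + w[2] * s2$values + w[3] * s3$values
  cons <- build_consensus(list(s1, s2, s3), target_id = "T1")
  expect_equal(as.numeric(cons), unname(expected), tolerance = 1e-12)

  # identical replicates reproduce the replicate
  expect_equal(as.numeric(build_consensus(list(s1, s1, s1))),
               unname(s1$values), tolerance = 1e-12)
  # single signature is the identity
  expect_equal(as.numeric(build_consensus(list(s2))), unname(s2$values))
})

test_that("consensus commutes with gene and signature reordering", {
  set.seed(42)
  g <- paste0("g", 1:20)
  sigs <- lapply(1:4, function(i) sig_from(paste0("s", i), g, rnorm(20)))
  base <- build_consensus(sigs)
  perm_sig <- build_consensus(sigs[c(3, 1, 4, 2)])
  expect_equal(as.numeric(perm_sig[names(base)]),
               as.numeric(base[names(base)]), tolerance = 1e-12)
  reord <- lapply(sigs, function(s) {
    idx <- sample(20)
    sig_from(s$signature_id, s$genes[idx], unname(s$values[idx]))
  })
  perm_gene <- build_consensus(reord)
  expect_equal(sort(names(perm_gene)), sort(names(base)))
  expect_equal(as.numeric(perm_gene[names(base)]), as.numeric(base),
               tolerance = 1e-12)
})

test_that("duplicating a replicate barely moves a concordant consensus", {
  # identical replicates: the consensus is exactly unchanged
  g <- paste0("g", 1:30)
  set.seed(7)
  s <- expression_signature("s1", g, rnorm(30))
  expect_equal(as.numeric(build_consensus(list(s, s))),
               as.numeric(build_consensus(list(s, s, s))))
  # replicate-like (shared signal) profiles: duplication tilts the
  # weights toward the duplicated replicate but leaves the ranking intact
  signal <- rnorm(30)
  sigs <- lapply(1:3, function(i)
    expression_signature(paste0("s", i), g, signal + 0.3 * rnorm(30)))
  base <- rank(as.numeric(build_consensus(sigs)))
  dup <- rank(as.numeric(build_consensus(c(sigs, sigs[1]))))
  expect_gt(cor(base, dup, method = "spearman"), 0.99)
})

test_that("signature extraction takes the value extremes, stably", {
  g <- paste0("g", 1:10)
  prof <- stats::setNames(as.numeric(10:1), g)
  sig <- extract_signature(prof, 3, target_id = "T1")
  expect_identical(sig$t_up, c("g1", "g2", "g3"))
  expect_identical(sig$t_down, c("g8", "g9", "g10"))
  expect_length(intersect(sig$t_up, sig$t_down), 0)

  one <- extract_signature(prof, 1)
  expect_identical(one$t_up, "g1")
  expect_identical(one$t_down, "g10")
  expect_error(extract_signature(prof, 6), "exceeds universe")

  # separation property on tie-free profiles
  set.seed(9)
  for (i in 1:20) {
    vals <- stats::setNames(sample(rnorm(40)), paste0("g", 1:40))
    s <- extract_signature(vals, 10)
    expect_gte(min(vals[s$t_up]), max(vals[s$t_down]))
  }
})

test_that("decrease rate is the absolute relative step change", {
  expect_equal(unname(decrease_rate(stats::setNames(c(0.5, 0.5, 0.5),
                                                    c(100, 150, 200)))),
               c(0, 0))
  expect_equal(unname(decrease_rate(stats::setNames(c(0.5, 0.4),
                                                    c(100, 150)))), 0.2)
  expect_error(decrease_rate(stats::setNames(0.5, 100)), "at least 2")
  expect_error(decrease_rate(stats::setNames(c(0.5, 0.4, 0.3),
                                             c(100, 150, 250))),
               "constant step")
})

test_that("size selection picks the first plateau size, falling back with a warning", {
  dr <- stats::setNames(c(0.05, 0.02, 0.009, 0.008), c(100, 150, 200, 250))
  expect_identical(as.integer(choose_size(dr)), 200L)
  all_small <- stats::setNames(c(0.005, 0.004), c(100, 150))
  expect_identical(as.integer(choose_size(all_small)), 100L)
  none <- stats::setNames(c(0.5, 0.4), c(100, 150))
  expect_warning(picked <- choose_size(none), "largest evaluated")
  expect_identical(as.integer(picked), 150L)
  expect_true(attr(picked, "fallback"))
  expect_error(choose_size(numeric(0)), "empty")
})

test_that("library construction groups replicates by target", {
  cfg <- simulation_config(n_genes = 200, n_targets = 4,
                           signature_size = 10, seed = 5)
  sim <- generate_signature_library(cfg)
  lib <- build_signature_library(sim$profiles, sim$meta, n = 10)
  expect_named(lib$signatures, paste0("T00", 1:4))
  expect_equal(dim(lib$consensus), c(200L, 4L))
  for (tg in names(lib$signatures)) {
    truth <- sim$ground_truth$blocks[[tg]]
    expect_gte(length(intersect(lib$signatures[[tg]]$t_up, truth$up)) / 10,
               0.95)
    expect_gte(length(intersect(lib$signatures[[tg]]$t_down, truth$down)) / 10,
               0.95)
  }
})
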