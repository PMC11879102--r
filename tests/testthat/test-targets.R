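test_that("effect-target calling uses an inclusive FDR cutoff", {
  res <- toy_results(c("a", "b", "c"), c(5, 4, 3), c(0.01, 0.05, 0.06))
  expect_identical(call_effect_targets(res), c("a", "b"))
  all_null <- toy_results(c("a", "b"), c(1, 2), c(1, 1))
  expect_length(call_effect_targets(all_null), 0)
})

test_that("reversal targets require two-sided significance and opposite signs", {
  drug <- toy_results(paste0("t", 1:6),
                      nets = c(3, -2, 4, 1, -5, 0),
                      fdr = c(0.01, 0.02, 0.20, 0.01, 0.03, 0.01))
  disease <- toy_results(paste0("t", 1:6),
                         nets = c(-2, -3, -4, 2, 6, 1),
                         fdr = c(0.04, 0.01, 0.01, 0.30, 0.02, 0.01))
  # enumerated: t1 (opposite, both significant), t5 (opposite, both
  # significant); t2 same sign, t3 drug not significant, t4 disease not
  # significant, t6 zero drug NETS
  expect_setequal(reversal_targets(drug, disease), c("t1", "t5"))
  # symmetry
  expect_setequal(reversal_targets(disease, drug),
                  reversal_targets(drug, disease))
  # identical tables have no opposing signs
  expect_length(reversal_targets(drug, drug), 0)
  # perfect reversal returns the full shared significant set
  flipped <- drug
  flipped$nets <- -drug$nets
  expect_setequal(reversal_targets(drug, flipped),
                  drug$target_id[drug$fdr <= 0.05 & drug$nets != 0])
  stranger <- toy_results("zz", 1, 0.01)
  expect_error(reversal_targets(drug, stranger), "share no targets")
})

test_that("direct and indirect targets partition the effect set", {
  cls <- classify_targets(c("a", "b", "c"), c("b", "c", "d"))
  expect_setequal(cls$direct, c("b", "c"))
  expect_identical(cls$indirect, "a")
  # the reported arithmetic: 734 effect, 421 binding-confirmed
  effect <- sprintf("t%04d", 1:734)
  binding <- c(sprintf("t%04d", 1:421), sprintf("x%04d", 1:50))
  cls2 <- classify_targets(effect, binding)
  expect_length(cls2$direct, 421)
  expect_length(cls2$indirect, 313)
  # partition law over random inputs
  set.seed(13)
  for (i in 1:20) {
    e <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(0:20, 1))
    cl <- classify_targets(e, b)
    expect_setequal(c(cl$direct, cl$indirect), unique(e))
    expect_length(intersect(cl$direct, cl$indirect), 0)
  }
  # empty binding set: everything indirect
  cl0 <- classify_targets(c("a", "b"), character(0))
  expect_length(cl0$direct, 0)
  expect_setequal(cl0$indirect, c("a", "b"))
})

test_that("query comparison is a plain Pearson correlation over shared targets", {
  a <- stats::setNames(c(1, 2, 3, 4), c("t1", "t2", "t3", "t4"))
  expect_equal(compare_queries(a, a), 1)
  expect_equal(compare_queries(a, -a), -1)
  expect_equal(compare_queries(a, 2 * a), 1)
  b <- stats::setNames(c(3, 1, 2), c("t1", "t2", "t3"))
  # closed-form covariance oracle on the shared triple (1,2,3) vs (3,1,2)
  x <- c(1, 2, 3); y <- c(3, 1, 2)
  expected <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(compare_queries(a, b), expected)
  expect_error(compare_queries(a, stats::setNames(rep(1, 4), names(a))),
               "zero variance")
  expect_error(compare_queries(a, b, restrict = c("t1", "t2")),
               "at least 3")
})

test_that("the component network restricts to direct targets and counts degrees", {
  calls <- data.frame(
    compound_id = c("c1", "c1", "c2", "c2", "c3", "c3"),
    protein_id = c("p1", "p2", "p1", "p2", "p1", "p3"),
    stringsAsFactors = FALSE)
  net <- build_component_network(calls, direct = c("p1", "p2"))
  expect_identical(nrow(net$edges), 5L)
  expect_identical(net$compound_degree[["c1"]], 2L)
  expect_identical(net$compound_degree[["c3"]], 1L)
  expect_identical(net$target_degree[["p1"]], 3L)
  # shrinking the direct set never grows the edge set
  smaller <- build_component_network(calls, direct = "p1")
  expect_lte(nrow(smaller$edges), nrow(net$edges))
  empty <- build_component_network(calls[0, ], direct = "p1")
  expect_identical(nrow(empty$edges), 0L)
})

test_that("degree ranking breaks ties lexicographically; |NETS| filter is inclusive", {
  calls <- data.frame(
    compound_id = c("c2", "c2", "c2", "c1", "c1", "c1", "c3"),
    protein_id = c("p1", "p2", "p3", "p1", "p2", "p3", "p1"),
    stringsAsFactors = FALSE)
  net <- build_component_network(calls, direct = c("p1", "p2", "p3"))
  expect_identical(top_components(net, 2), c("c1", "c2"))
  expect_identical(top_components(net, 10), c("c1", "c2", "c3"))
  res <- toy_results(c("a", "b", "c"), c(4.0, -4.5, 3.9), c(0.01, 0.01, 0.01))
  expect_setequal(top_targets(res), c("a", "b"))
})

test_that("target role tables stay internally consistent", {
  drug <- toy_results(paste0("t", 1:4), c(5, -3, 2, 0.5),
                      c(0.01, 0.02, 0.04, 0.50))
  disease <- toy_results(paste0("t", 1:4), c(-4, -2, 1, 1),
                         c(0.01, 0.01, 0.90, 0.01))
  tc <- target_calls(drug, disease, binding = c("t1", "t3"))
  expect_true(all(tc$direct == (tc$effect & tc$binding)))
  expect_true(all(tc$indirect == (tc$effect & !tc$direct)))
  expect_identical(tc$target_id[tc$therapeutic], "t1")
  # no binding input: every effect target indirect
  tc0 <- target_calls(drug, disease)
  expect_false(any(tc0$direct))
  expect_setequal(tc0$target_id[tc0$indirect], tc0$target_id[tc0$effect])
})
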