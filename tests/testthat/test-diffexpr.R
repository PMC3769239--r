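test_that("welchT matches the reference implementation", {
  # frozen hand case
  w <- welchT(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$t, -3.6742346, tolerance = 1e-6)
  expect_equal(w$df, 4)
  expect_equal(w$p, 0.0213116, tolerance = 1e-4)
  # randomized cases against stats::t.test
  set.seed(123)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    ref <- t.test(a, b)
    w <- welchT(a, b)
    expect_equal(w$t, unname(ref$statistic))
    expect_equal(w$df, unname(ref$parameter))
    expect_equal(w$p, ref$p.value)
  }
})

test_that("welchT handles identical and degenerate groups", {
  w <- welchT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  # swapping groups negates t, preserves p
  a <- c(1.2, 3.4, 2.2, 5); b <- c(0.3, 1.1, 0.9)
  expect_equal(welchT(a, b)$t, -welchT(b, a)$t)
  expect_equal(welchT(a, b)$p, welchT(b, a)$p)
  # under two observations: untestable
  expect_true(welchT(c(1), c(1, 2, 3))$untestable)
  # both groups constant: equal means testable, unequal means not
  w <- welchT(c(5, 5, 5), c(5, 5))
  expect_equal(w$t, 0); expect_equal(w$p, 1)
  expect_true(welchT(c(5, 5, 5), c(6, 6))$untestable)
})

test_that("log2 fold change is a difference of means with inclusive boundary", {
  expect_equal(log2FoldChange(c(8, 8), c(7, 7)), 1)   # exactly 2-fold
  expect_equal(log2FoldChange(c(3, 5), c(3, 5)), 0)
  expect_equal(log2FoldChange(7, 8.5), -1.5)
  expect_true(is.na(log2FoldChange(numeric(), c(1, 2))))
})

test_that("robust FDR reproduces the frozen worked example", {
  r <- robustFdr(c(0.01, 0.02, 0.5, 0.9))
  expect_equal(r$pi0, 0.715)
  expect_equal(r$q, c(0.0286, 0.0286, 0.476667, 0.6435), tolerance = 1e-4)
  # saturated null
  r1 <- robustFdr(rep(1, 5))
  expect_equal(r1$pi0, 1)
  expect_equal(r1$q, rep(1, 5))
  expect_error(robustFdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(robustFdr(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("q-values are monotone in p and lie in [0,1]", {
  set.seed(7)
  for (i in 1:10) {
    p <- runif(sample(5:300, 1))^sample(1:3, 1)
    q <- robustFdr(p)$q
    expect_true(all(q >= 0 & q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    # ties in p share a q
    expect_identical(length(unique(q[p == p[1]])), 1L)
  }
})

test_that("the BH option matches stats::p.adjust", {
  set.seed(11)
  p <- runif(50)^2
  expect_equal(robustFdr(p, method = "bh")$q, p.adjust(p, "BH"))
})

test_that("pi0 is near 1 and q-calls are rare under a uniform null", {
  set.seed(2024)
  p <- runif(1e4)
  r <- robustFdr(p)
  se <- 2 * sd(p) / sqrt(1e4)  # standard error of 2 * mean(p)
  expect_gt(r$pi0, 1 - 3 * se)
  expect_lte(mean(r$q <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 1e4))
})

test_that("differentialTable calls a planted effect with correct direction", {
  set.seed(5)
  n_a <- 14; n_b <- 10
  m <- matrix(rnorm(200 * (n_a + n_b), 8, 0.5), 200,
              dimnames = list(sprintf("g%03d", 1:200),
                              sprintf("s%02d", 1:(n_a + n_b))))
  m["g001", 1:n_a] <- m["g001", 1:n_a] + 2        # up in class A
  m["g002", n_a + 1:n_b] <- m["g002", n_a + 1:n_b] + 2  # up in class B
  ann <- data.frame(sample_id = colnames(m), platform = "GPL570",
                    cell_class = rep(c("BEC", "LEC"), c(n_a, n_b)),
                    dataset_membership = I(rep(list("B"), n_a + n_b)),
                    study_id = "sim")
  tab <- differentialTable(m, ann)
  expect_true(tab["g001", "significant"])
  expect_identical(tab["g001", "direction"], "A_UP")
  expect_true(tab["g002", "significant"])
  expect_identical(tab["g002", "direction"], "B_UP")
  expect_equal(unname(tab["g001", "log2fc"]), 2, tolerance = 0.5)
  expect_identical(markerGenes(tab, "A_UP"), "g001")
  expect_identical(markerGenes(tab, "B_UP"), "g002")
  expect_s4_class(tab, "DataFrame")
  expect_lt(abs(S4Vectors::metadata(tab)$pi0 - 1), 0.1)
})

test_that("significance is exactly the conjunction of both thresholds", {
  set.seed(6)
  m <- matrix(rnorm(100 * 20, 8, 1), 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:20)))
  m[1:20, 1:10] <- m[1:20, 1:10] + rep(runif(20, 0.3, 3), 10)
  ann <- data.frame(sample_id = colnames(m), platform = "GPL570",
                    cell_class = rep(c("BEC", "LEC"), each = 10),
                    dataset_membership = I(rep(list("B"), 20)),
                    study_id = "sim")
  tab <- differentialTable(m, ann, fcThreshold = 2, qThreshold = 0.05)
  manual <- !tab$untestable & abs(tab$log2fc) >= 1 & tab$q <= 0.05
  expect_identical(unname(tab$significant), unname(manual))
  expect_identical(unname(tab$direction == "A_UP"),
                   unname(tab$significant & tab$log2fc > 0))
})

test_that("genes observed in one class only are flagged untestable", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
             g2 = c(1, 2, 3, NA, NA, NA))
  colnames(m) <- paste0("s", 1:6)
  ann <- data.frame(sample_id = colnames(m), platform = "GPL570",
                    cell_class = rep(c("BEC", "LEC"), each = 3),
                    dataset_membership = I(rep(list("B"), 6)),
                    study_id = "sim")
  tab <- differentialTable(m, ann)
  expect_true(tab["g2", "untestable"])
  expect_true(is.na(tab["g2", "p"]))
  expect_false(tab["g2", "significant"])
  expect_error(differentialTable(m, ann, classA = "HMEC1"), "HMEC1")
})

test_that("label permutations within a class change nothing", {
  sim <- simulateExpression(smallConfig(seed = 17))
  es <- filterMissingness(mergePlatforms(sim$matrices,
                                         annotations = sim$annotations))
  tab1 <- differentialTable(es)
  ann <- sim$annotations
  bec <- which(ann$cell_class == "BEC")
  ann2 <- ann
  ann2$sample_id[bec] <- ann$sample_id[sample(bec)]
  tab2 <- differentialTable(exprsMatrix(es), ann2)
  expect_equal(as.data.frame(tab1), as.data.frame(tab2))
})
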