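test_that("separated point clouds are recovered as the two clusters", {
  x <- rbind(matrix(0, 5, 2), matrix(10, 5, 2)) +
    matrix(stats::rnorm(20, sd = 0.01), 10, 2)
  cl <- kmeansTwo(x, seed = 1)
  expect_equal(length(unique(cl[1:5])), 1)
  expect_equal(length(unique(cl[6:10])), 1)
  expect_true(cl[1] != cl[10])
})

test_that("the k-means objective beats random partitions", {
  set.seed(3)
  x <- matrix(stats::rnorm(60 * 3), 60, 3)
  cl <- kmeansTwo(x, seed = 2)
  obj <- attr(cl, "tot.withinss")
  wss <- function(assign) {
    sum(vapply(unique(assign), function(g) {
      xs <- x[assign == g, , drop = FALSE]
      sum(sweep(xs, 2, colMeans(xs))^2)
    }, numeric(1)))
  }
  rand <- vapply(1:1000, function(i) {
    a <- sample(0:1, 60, replace = TRUE)
    if (length(unique(a)) < 2) return(Inf)
    wss(a)
  }, numeric(1))
  expect_true(all(obj <= rand + 1e-9))
})

test_that("clustering is deterministic and permutation-equivariant", {
  set.seed(8)
  x <- rbind(matrix(stats::rnorm(40, 0), 20, 2),
             matrix(stats::rnorm(40, 4), 20, 2))
  cl1 <- kmeansTwo(x, seed = 7)
  cl2 <- kmeansTwo(x, seed = 7)
  expect_identical(as.integer(cl1), as.integer(cl2))
  perm <- sample(nrow(x))
  clp <- kmeansTwo(x[perm, ], seed = 7)
  # same partition, up to the 0/1 labeling
  agree <- mean(as.integer(clp) == as.integer(cl1)[perm])
  expect_true(agree == 1 || agree == 0)
})

test_that("degenerate feature matrices are rejected", {
  expect_error(kmeansTwo(matrix(1, 5, 2), seed = 1), "identical")
  expect_error(kmeansTwo(matrix(c(1, NA, 2, 3), 2, 2), seed = 1), "missing")
})

test_that("the lower-mean cluster is called native", {
  feats <- matrix(c(rep(-1, 5), rep(1, 5)), ncol = 1)
  cl <- c(rep(0L, 5), rep(1L, 5))
  expect_equal(labelClusters(cl, feats),
               c(rep("native", 5), rep("mirror", 5)))
  # negating every feature inverts the labels
  expect_equal(labelClusters(cl, -feats),
               c(rep("mirror", 5), rep("native", 5)))
  # exact tie: deterministic with a warning
  expect_warning(lab <- labelClusters(cl, matrix(0 * feats, ncol = 1)),
                 "tie")
  expect_equal(lab, c(rep("native", 5), rep("mirror", 5)))
})

test_that("metrics match the direct-arithmetic oracle on printed cases", {
  perfect <- evaluateMetrics(50, 50, 0, 0)
  expect_equal(unlist(perfect[c("acc", "sn", "spc", "mcc", "f1")]),
               c(acc = 1, sn = 1, spc = 1, mcc = 1, f1 = 1))
  inverted <- evaluateMetrics(0, 0, 50, 50)
  expect_equal(inverted$acc, 0)
  expect_equal(inverted$mcc, -1)
  mixd <- evaluateMetrics(30, 20, 10, 40)
  o <- metricOracle(30, 20, 10, 40)
  expect_equal(mixd$acc, 0.5)
  expect_equal(mixd$mcc, o$mcc, tolerance = 1e-12)
  expect_equal(mixd$f1, o$f1, tolerance = 1e-12)
  expect_error(evaluateMetrics(0, 0, 0, 0), "empty")
})

test_that("swapping cluster labels transposes the confusion table", {
  e1 <- evaluateMetrics(30, 20, 10, 40)
  e2 <- evaluateMetrics(40, 10, 20, 30)  # (tp,tn,fp,fn) -> (fn,fp,tn,tp)
  expect_equal(e2$acc, 1 - e1$acc)
})

test_that("the as-printed flag swaps sensitivity and specificity", {
  a <- evaluateMetrics(30, 20, 10, 40)
  b <- evaluateMetrics(30, 20, 10, 40, asPrinted = TRUE)
  expect_equal(b$sn, a$spc)
  expect_equal(b$spc, a$sn)
  expect_equal(b$acc, a$acc)
  expect_equal(b$f1, a$f1)
})

test_that("strong separation yields perfect domain clustering", {
  accs <- vapply(1:20, function(s) {
    sim <- simulateEtFeatures(30, 30, delta = c(a = 8, b = 8), sigma = 1,
                              seed = 500 + s)
    pr <- data.frame(model_id = paste0("m", 1:60), domain_id = "d",
                     sim$features)
    clusterDomain(pr, c("a", "b"), truth = sim$truth,
                  seed = s)$evaluation$acc
  }, numeric(1))
  expect_equal(mean(accs), 1)
})

test_that("assignments are invariant to affine feature rescaling", {
  sim <- simulateEtFeatures(25, 25, delta = c(a = 3, b = 3), sigma = 1,
                            seed = 77)
  pr <- data.frame(model_id = paste0("m", 1:50), domain_id = "d",
                   sim$features)
  r1 <- clusterDomain(pr, c("a", "b"), truth = sim$truth, seed = 5)
  pr2 <- pr; pr2$a <- pr2$a * 1000 + 5; pr2$b <- pr2$b / 50 - 2
  r2 <- clusterDomain(pr2, c("a", "b"), truth = sim$truth, seed = 5)
  expect_equal(r2$predictedLabels, r1$predictedLabels)
})

test_that("ineligible or degenerate domains are skipped with a reason", {
  sim <- simulateEtFeatures(2, 38, delta = c(a = 4), sigma = 1, seed = 9)
  pr <- data.frame(model_id = paste0("m", 1:40), domain_id = "d",
                   sim$features)
  r <- clusterDomain(pr, "a", truth = sim$truth, seed = 1)
  expect_true(r$skipped)
  expect_match(r$reason, "fewer than 3")
  prc <- data.frame(model_id = paste0("m", 1:10), domain_id = "d",
                    a = rep(1, 10))
  truth <- rep(c("native", "mirror"), 5)
  r2 <- clusterDomain(prc, "a", truth = truth, seed = 1)
  expect_true(r2$skipped)
})

test_that("group summaries average the evaluated domains", {
  mk <- function(id, acc) list(domainId = id, strategy = "s",
                               selectedTerms = "a", skipped = FALSE,
                               evaluation = data.frame(
                                 tp = 1, tn = 1, fp = 1, fn = 1, acc = acc,
                                 spc = acc, sn = acc, mcc = 0, f1 = acc))
  reps <- list(mk("d1", 0.6), mk("d2", 0.8), mk("d3", 1.0))
  s1 <- summarizeByGroup(reps[1])
  expect_equal(s1$acc, 0.6)
  s <- summarizeByGroup(reps, grouping = c(d1 = "g1", d2 = "g1", d3 = "g2"))
  expect_equal(s$acc[s$group == "g1"], 0.7)
  expect_equal(s$acc[s$group == "g2"], 1.0)
  expect_warning(summarizeByGroup(reps[1:2],
                                  grouping = c(d1 = "g1", d2 = "g1",
                                               d9 = "gX")),
                 "omitted")
})
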