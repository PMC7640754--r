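test_that("Kruskal-Wallis H matches the hand-computed textbook value", {
  # ranks 1..6 split as {1,2,3} vs {4,5,6}:
  # H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 3.857...
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 12 / 42 * (36 / 3 + 225 / 3) - 21)
  expect_equal(kw$df, 1)
  # identical groups collapse to H = 0, p = 1 after tie handling
  kw0 <- kruskal_wallis(rep(c(1, 2), 4), rep(c("a", "b"), each = 4))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p.value, 1)
  expect_error(kruskal_wallis(1:3, rep("a", 3)), "two groups")
})

test_that("Kruskal-Wallis holds its nominal type-I error rate", {
  set.seed(77)
  n_sim <- 10000
  rej <- logical(n_sim)
  for (i in 1:n_sim) {
    x <- rnorm(60)
    rej[i] <- kruskal_wallis(x, rep(1:3, each = 20))$p.value < 0.05
  }
  rate <- mean(rej)
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("Dunn z tests use tie-corrected pooled-rank variance", {
  set.seed(21)
  x <- c(rnorm(10), rnorm(10, 3))
  g <- rep(c("a", "b"), each = 10)
  d <- dunn_posthoc(x, g)
  # two groups: Bonferroni factor 1, z^2 equals tie-corrected H
  expect_equal(d$z^2, kruskal_wallis(x, g)$H)
  expect_equal(d$p.adjusted, d$p.value)
  # with ties the variance shrinks but the identity H = z^2 must survive
  xt <- c(1, 1, 2, 2, 2, 3, 3, 4, 4, 4)
  gt <- rep(c("a", "b"), each = 5)
  dt <- dunn_posthoc(xt, gt)
  expect_equal(dt$z^2, kruskal_wallis(xt, gt)$H)
})

test_that("letter displays encode exactly the adjusted-p sharing relation", {
  set.seed(31)
  # three well-separated groups -> a, b, c
  x <- c(rnorm(15), rnorm(15, 50), rnorm(15, 100))
  g <- rep(c("g1", "g2", "g3"), each = 15)
  pl <- pairwise_letters(x, g)
  expect_equal(sort(pl$letters), c("a", "b", "c"))
  # all groups identical -> one shared letter
  pl0 <- pairwise_letters(rep(1:15, 3), rep(c("g1", "g2", "g3"), each = 15))
  expect_equal(pl0$letters, rep("a", 3))
  # overlapping chain A~B, B~C, A != C -> a, ab, b (staggered integer runs)
  xc <- c(1:20, 5:24, 9:28)
  gc <- rep(c("A", "B", "C"), each = 20)
  plc <- pairwise_letters(xc, gc)
  dc <- attr(plc, "dunn")
  expect_equal(plc$letters[plc$group == "C"], "a")
  expect_equal(plc$letters[plc$group == "B"], "ab")
  expect_equal(plc$letters[plc$group == "A"], "b")
  expect_lt(dc$p.adjusted[dc$group1 == "A" & dc$group2 == "C"], 0.05)
})

test_that("letters match the sharing relation on random group structures", {
  set.seed(41)
  for (i in 1:40) {
    k <- sample(3:7, 1)
    n <- sample(8:15, 1)
    shift <- sample(0:3, k, replace = TRUE) * 1.5
    x <- rnorm(k * n) + rep(shift, each = n)
    g <- rep(paste0("g", 1:k), each = n)
    pl <- pairwise_letters(x, g)
    d <- attr(pl, "dunn")
    for (r in seq_len(nrow(d))) {
      l1 <- strsplit(pl$letters[pl$group == d$group1[r]], "")[[1]]
      l2 <- strsplit(pl$letters[pl$group == d$group2[r]], "")[[1]]
      shares <- length(intersect(l1, l2)) > 0
      expect_equal(shares, d$p.adjusted[r] >= 0.05,
                   info = sprintf("iter %d pair %s-%s", i, d$group1[r],
                                  d$group2[r]))
    }
  }
})

test_that("(n-1) chi-square scales Pearson by (N-1)/N", {
  res <- n_minus_1_chi2(30, 50, 20, 50)
  expect_equal(res$pearson, 4.0)
  expect_equal(res$statistic, 99 / 100 * 4.0)
  # equal proportions give 0; swapping rows changes nothing
  expect_equal(n_minus_1_chi2(10, 20, 15, 30)$statistic, 0)
  expect_equal(n_minus_1_chi2(7, 19, 3, 11)$statistic,
               n_minus_1_chi2(3, 11, 7, 19)$statistic)
  # degenerate margins
  expect_equal(n_minus_1_chi2(0, 10, 0, 12)$p.value, 1)
  expect_equal(n_minus_1_chi2(10, 10, 12, 12)$statistic, 0)
})

test_that("(n-1) chi-square equals (N-1)/N x independent Pearson on exhaustive small tables", {
  for (n1 in 2:12) for (n2 in 2:12) for (a in 0:n1) for (b in 0:n2) {
    s <- a + b
    if (s == 0 || s == n1 + n2) next
    got <- n_minus_1_chi2(a, n1, b, n2)
    want <- (n1 + n2 - 1) / (n1 + n2) * oracle_pearson_2x2(a, n1, b, n2)
    expect_equal(got$statistic, want,
                 info = sprintf("a=%d n1=%d b=%d n2=%d", a, n1, b, n2))
  }
})

test_that("Kendall's W spans its range and carries the chi-square identity", {
  # identical rankings -> perfect concordance
  r <- matrix(rep(1:6, 4), 4, byrow = TRUE)
  kw <- kendall_w(r)
  expect_equal(kw$W, 1)
  expect_equal(kw$chi2, kw$m * (kw$n - 1) * kw$W)
  # two fully reversed rankings: rank sums all equal -> S = 0 -> W = 0
  expect_equal(kendall_w(rbind(1:5, 5:1))$W, 0)
  expect_error(kendall_w(matrix(1:3, 1)), "two judges")
  expect_error(kendall_w(rbind(c(1, 1, 1), c(1, 2, 3))),
               "must be a ranking")
})

test_that("Kendall's W agrees with vegan's concordance on random rank matrices", {
  set.seed(51)
  for (i in 1:20) {
    m <- sample(3:8, 1)
    n <- sample(4:9, 1)
    scores <- matrix(rnorm(m * n), m, n)
    if (i %% 2 == 0) scores[, 1] <- scores[, 2]  # induce some ties
    ranks <- t(apply(scores, 1, function(z) rank(-z)))
    got <- kendall_w(ranks)
    ref <- vegan::kendall.global(t(ranks))
    expect_equal(got$W, unname(ref$Concordance_analysis["W", 1]))
    expect_equal(got$chi2, unname(ref$Concordance_analysis["Chi2", 1]))
  }
})

test_that("Kendall's W is invariant to relabelling objects and permuting judges", {
  set.seed(61)
  ranks <- t(apply(matrix(rnorm(5 * 7), 5, 7), 1, rank))
  w0 <- kendall_w(ranks)$W
  expect_equal(kendall_w(ranks[sample(5), ])$W, w0)
  expect_equal(kendall_w(ranks[, sample(7)])$W, w0)
})
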