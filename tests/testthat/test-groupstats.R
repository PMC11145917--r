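test_that("pooled t-test matches hand values and stats::t.test", {
  # identical nonconstant samples: t = 0, p = 1
  r0 <- student_ttest(c(1, 5, 9), c(1, 5, 9))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # hand-computed pooled t on (1,2,3) vs (2,3,4)
  r <- student_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -sqrt(3 / 2), tolerance = 1e-6)
  expect_equal(r$t, -1.2247, tolerance = 1e-4)
  expect_equal(r$df, 4)
  expect_equal(r$p, 0.2879, tolerance = 1e-3)
  # antisymmetry
  rs <- student_ttest(c(2, 3, 4), c(1, 2, 3))
  expect_equal(rs$t, -r$t)
  expect_equal(rs$p, r$p)
  # independent route: stats::t.test with pooled variance
  set.seed(1)
  for (rep in 1:10) {
    a <- rnorm(5, 10, 2); b <- rnorm(7, 12, 3)
    mine <- student_ttest(a, b)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    mw <- student_ttest(a, b, welch = TRUE)
    rw <- t.test(a, b)
    expect_equal(mw$t, unname(rw$statistic), tolerance = 1e-12)
    expect_equal(mw$p, rw$p.value, tolerance = 1e-12)
  }
  expect_error(student_ttest(c(1, 1, 1), c(2, 2, 2)), "degenerate variance")
  expect_error(student_ttest(1, c(1, 2)), "at least 2")
})

test_that("BH q-values follow the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)                # m = 1
  expect_equal(bh_fdr(rep(0.3, 5)), rep(0.3, 5)) # all equal collapse at j = m
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # monotone in p and equal to the brute-force oracle
  set.seed(3)
  for (rep in 1:25) {
    p <- runif(sample(2:40, 1))
    q <- bh_fdr(p)
    expect_lt(max(abs(q - brute_bh(p))), 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q >= p * rank(p) / length(p) - 1e-15))
  }
})

test_that("signed fold change uses the symmetric +-1 convention", {
  expect_equal(signed_fold_change(2, 1, epsilon = 1e-9), 2, tolerance = 1e-6)
  expect_equal(signed_fold_change(1, 2, epsilon = 1e-9), -2, tolerance = 1e-6)
  expect_equal(signed_fold_change(5, 5), 1)
  expect_equal(signed_fold_change(0, 0, epsilon = 0.5), 1)
})

test_that("volcano classification gates on strict fc and q cutoffs", {
  tab <- data.frame(fold_change = c(1.5, 1.4, -2.0, -1.5, 3.0),
                    q = c(0.01, 0.01, 0.2, 0.03, 0.05))
  out <- volcano_classify(tab, fc_cut = 1.4, q_cut = 0.05)
  expect_equal(as.character(out$significance_class),
               c("up", "ns", "ns", "down", "ns"))
})

test_that("relative z-scores are column-standardized over the pooled animals", {
  z <- relative_zscore(cbind(r1 = c(1, 2, 3)))
  expect_equal(unname(z[, 1]), c(-1, 0, 1))
  zc <- relative_zscore(cbind(a = c(4, 4, 4), b = c(1, 2, 4)))
  expect_true(all(zc[, "a"] == 0))
  expect_identical(unname(attr(zc, "degenerate")), c(TRUE, FALSE))
  set.seed(2)
  m <- matrix(rpois(60, 50), 10, 6)
  z2 <- relative_zscore(m)
  expect_equal(unname(colMeans(z2)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(z2, 2, sd)), rep(1, 6), tolerance = 1e-12)
  # control baseline standardizes against the control rows only
  z3 <- relative_zscore(m, baseline = "control", control_rows = 1:5)
  expect_equal(unname(colMeans(z3[1:5, ])), rep(0, 6), tolerance = 1e-12)
})

test_that("CV is sd/mean and scale invariant", {
  expect_equal(coefficient_of_variation(c(2, 4, 6)), 0.5)
  expect_equal(coefficient_of_variation(c(3, 3, 3)), 0)
  x <- c(5, 9, 14, 3)
  expect_equal(coefficient_of_variation(x * 17), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("Spearman correlation equals the tie-averaged rank-Pearson oracle", {
  expect_equal(spearman(1:5, c(2, 4, 6, 7, 10))$rho, 1)
  expect_equal(spearman(1:5, 5:1)$rho, -1)
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  got <- spearman(x, y)
  # brute-force oracle: mean ranks then the Pearson formula written out
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$rho, num / den, tolerance = 1e-12)
  set.seed(4)
  for (rep in 1:10) {
    a <- sample(1:6, 8, replace = TRUE)  # ties likely
    b <- rnorm(8)
    mine <- spearman(a, b)
    ref <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
  expect_error(spearman(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("correlation maps find mutual best partners and stay symmetric", {
  set.seed(6)
  base <- rnorm(6)
  counts <- cbind(r1 = base, r2 = base * 2 + 1,        # perfectly correlated
                  r3 = rnorm(6), r4 = -base + rnorm(6, 0, 1e-3))
  cm <- correlation_map(counts)
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 4))
  bp <- cm$best_partner
  expect_identical(bp$partner[bp$region == "r1"], "r2")
  expect_identical(bp$partner[bp$region == "r2"], "r1")
  expect_equal(bp$rho[bp$region == "r1"], 1)
  # planted negative correlation recovered
  expect_lt(cm$rho["r1", "r4"], 0)
  expect_identical(bp$partner[bp$region == "r4"], "r1")
})

test_that("region group statistics partition into up/down/ns and sort by q", {
  des <- group_design(groups = c("ctrl", "stress"), n_per_group = 6L,
                      regions = 1:30, baseline_mean = 100,
                      effects = list(stress = c("1" = 3, "2" = 3, "3" = 0.3)),
                      sigma = 0.2, seed = 10)
  counts <- generate_group_counts(des)
  tab <- region_group_stats(counts, "stress", "ctrl")
  expect_identical(nrow(tab), 30L)
  expect_equal(sum(table(tab$significance_class)), 30L)
  expect_false(is.unsorted(tab$q))
  expect_true(all(tab$region[tab$significance_class == "up"] %in% 1:2))
  expect_true(all(tab$region[tab$significance_class == "down"] %in% 3))
  expect_true(all(tab$q >= tab$p, na.rm = TRUE))
})
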