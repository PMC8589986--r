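# Multivariate statistics: distances, perMANOVA, PERMDISP, broken-stick
# PCA.  Small instances are verified against brute-force permutation
# enumeration and against vegan as an independent oracle.

make_groups <- function(n1 = 4, n2 = 4, shift = 2, seed = 1, p = 3) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n1 * p), n1, p),
             matrix(rnorm(n2 * p, mean = shift), n2, p))
  list(x = x, g = rep(c("a", "b"), c(n1, n2)), d = dist(x))
}

test_that("zscore_and_distance standardises and measures correctly", {
  tab <- data.frame(peak = c(60, 60, 70), BW_3dB = c(5, 5, 9))
  d <- zscore_and_distance(tab, variables = c("peak", "BW_3dB"))
  m <- as.matrix(d)
  expect_equal(m[1, 2], 0)                       # identical rows
  z <- attr(d, "zscores")
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-12)
  # 3-point toy set verified by hand: standardised columns are
  # (-0.577,-0.577,1.155) in both variables, so d13 = sqrt(2*(1.732)^2)
  expect_equal(m[1, 3], sqrt(2) * (1.1547005 + 0.5773503), tolerance = 1e-6)
  expect_error(zscore_and_distance(data.frame(peak = c(1, 1, 1),
                                              BW_3dB = 1:3),
                                   c("peak", "BW_3dB")), "zero-variance")
})

test_that("permanova F matches vegan::adonis2 and enumeration", {
  skip_if_not_installed("vegan")
  gr <- make_groups()
  res <- permanova(gr$d, gr$g, n_perm = 999)
  ad <- vegan::adonis2(gr$d ~ g, data = data.frame(g = gr$g),
                       permutations = 99)
  expect_equal(res$statistic, ad$F[1], tolerance = 1e-10)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 6)

  # exhaustive enumeration over all 8!/(4!4!) = 70 label assignments
  d2 <- as.matrix(gr$d)^2
  combs <- combn(8, 4)
  f_all <- apply(combs, 2, function(idx) {
    lab <- rep("b", 8)
    lab[idx] <- "a"
    echoclass:::.permanova_f(d2, lab, 8)
  })
  p_exact <- mean(f_all >= res$statistic - 1e-12)
  expect_lt(abs(res$p_value - p_exact), 0.05)
})

test_that("permanova degenerate and invariance properties", {
  # identical point multisets in both groups: F = 0, p ~ 1
  x <- matrix(rnorm(10), 5, 2)
  d <- dist(rbind(x, x))
  res <- permanova(d, rep(c("a", "b"), each = 5), n_perm = 199)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_gt(res$p_value, 0.5)
  expect_error(permanova(d, rep("a", 10)), "two groups")

  # invariant to row order and to rigid translation
  gr <- make_groups(seed = 3)
  f1 <- permanova(gr$d, gr$g, n_perm = 9)$statistic
  perm <- sample(8)
  f2 <- permanova(dist(gr$x[perm, ]), gr$g[perm], n_perm = 9)$statistic
  f3 <- permanova(dist(gr$x + 100), gr$g, n_perm = 9)$statistic
  expect_equal(f1, f2, tolerance = 1e-10)
  expect_equal(f1, f3, tolerance = 1e-10)
})

test_that("permdisp matches vegan::betadisper and detects scale", {
  skip_if_not_installed("vegan")
  gr <- make_groups(n1 = 5, n2 = 5, shift = 1, seed = 9)
  res <- permdisp(gr$d, gr$g, n_perm = 499)
  bd <- vegan::betadisper(gr$d, gr$g, type = "centroid")
  expect_equal(res$statistic, anova(bd)$`F value`[1], tolerance = 1e-8)

  # mirror-image groups have equal dispersion: F ~ 0
  x <- matrix(rnorm(12), 6, 2)
  xm <- rbind(x, -x)
  resm <- permdisp(dist(xm), rep(c("a", "b"), each = 6), n_perm = 199)
  expect_lt(resm$statistic, 1e-10)
  expect_gt(resm$p_value, 0.5)

  # inflating one group's spread strictly increases F
  x2 <- x
  x2[1:3, ] <- 3 * x2[1:3, ]
  g <- rep(c("a", "b"), each = 3)
  f_base <- permdisp(dist(x), g, n_perm = 9)$statistic
  f_infl <- permdisp(dist(x2), g, n_perm = 9)$statistic
  expect_gt(f_infl, f_base)

  expect_error(permdisp(dist(x), c("a", rep("b", 5))), "size 1")
})

test_that("permutation p-values are valid under the null", {
  set.seed(101)
  reps <- 200
  p_vals <- vapply(seq_len(reps), function(i) {
    x <- matrix(rnorm(16), 8, 2)
    permanova(dist(x), rep(c("a", "b"), 4), n_perm = 49)$p_value
  }, numeric(1))
  # type-I error at nominal 5%: binomial(200, .05) 99.9% bound ~ .105
  expect_lte(mean(p_vals <= 0.05), 0.105)
  expect_gte(min(p_vals), 1 / 50)
})

test_that("broken-stick PCA flags the right components", {
  expect_equal(broken_stick(3), c(11, 5, 2) / 18, tolerance = 1e-12)
  expect_equal(sum(broken_stick(15)), 1)

  # two perfectly correlated variables: proportions (1, 0), PC1 significant
  v <- rnorm(30)
  tab <- data.frame(a = v, b = 2 * v + 5)
  pc <- pca_broken_stick(tab, variables = c("a", "b"))
  expect_equal(pc$proportion, c(1, 0), tolerance = 1e-12)
  expect_true(pc$significant[1])
  expect_false(pc$significant[2])

  # independent variables at large n: no component beats the broken stick
  set.seed(2)
  big <- as.data.frame(matrix(rnorm(4000 * 5), 4000, 5))
  pc2 <- pca_broken_stick(big, variables = names(big))
  expect_false(any(pc2$significant))
  expect_true(all(diff(pc2$eigenvalues) <= 1e-12))
  expect_equal(sum(pc2$proportion), 1)

  expect_error(pca_broken_stick(data.frame(a = rep(1, 5), b = rnorm(5)),
                                variables = c("a", "b")), "constant")
})

test_that("permutation p has the documented floor", {
  # groups large enough that a permutation duplicating the observed
  # partition is essentially impossible
  gr <- make_groups(n1 = 10, n2 = 10, shift = 50)
  set.seed(5)
  res <- permanova(gr$d, gr$g, n_perm = 999)
  expect_equal(res$p_value, 0.001)   # minimum attainable with 999 perms
})
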