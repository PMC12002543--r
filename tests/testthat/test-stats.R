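test_that("Lin's CCC matches hand-evaluated cases", {
  x <- c(3.2, 4.1, 5.0, 6.3)
  expect_equal(lins_ccc(x, x)$value, 1)

  # direct evaluation of the defining formula
  expect_equal(lins_ccc(c(1, 2, 3), c(2, 3, 4))$value, 4 / 7)

  z <- c(-1, 0, 1)
  expect_equal(lins_ccc(z, -z)$value, -1)

  expect_error(lins_ccc(rep(1, 4), rep(2, 4)), "constant")
  expect_error(lins_ccc(1:3, 1:4), "equal length")

  # bias-corrected variant uses n/(n-1) moments
  bc <- lins_ccc(c(1, 2, 3), c(2, 3, 4), bias_corrected = TRUE)
  expect_equal(bc$value, 2 * 1 / (1 + 1 + 1))
})

test_that("paired t matches the textbook formula and rejects degeneracy", {
  x <- c(1, 2, 3, 4)
  y <- x + c(1, 0, 1, 0)
  res <- paired_t(x, y)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$value, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 3)
  expect_equal(res$p_value,
               2 * pt(abs(t_hand), 3, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(paired_t(x, x), "zero variance")
})

test_that("paired t p-values are uniform under the null", {
  set.seed(99)
  ps <- replicate(300, {
    a <- rnorm(20); b <- rnorm(20)
    paired_t(a, b)$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.001)
})

test_that("correlation PCA matches an SVD oracle and handles edge cases", {
  # two perfectly correlated columns: PC1 explains everything
  tab <- data.frame(a = 1:10, b = 2 * (1:10) + 3)
  pc <- pca_scores(tab, c("a", "b"))
  expect_equal(pc$explained_variance[1], 1, tolerance = 1e-12)

  # 5 x 3 hand table against an independent SVD of the z-scored matrix
  tab <- data.frame(a = c(2.1, 3.3, 1.8, 5.2, 4.4),
                    b = c(10, 12, 9, 17, 13),
                    c = c(0.3, 0.1, 0.4, 0.2, 0.25))
  pc <- pca_scores(tab, c("a", "b", "c"))
  Z <- scale(as.matrix(tab))
  sv <- svd(Z)
  scores_o <- sv$u %*% diag(sv$d)
  load_o <- sv$v
  for (j in 1:3) {     # apply the package's sign convention to the oracle
    k <- which.max(abs(load_o[, j]))
    if (load_o[k, j] < 0) {
      load_o[, j] <- -load_o[, j]; scores_o[, j] <- -scores_o[, j]
    }
  }
  expect_equal(unname(pc$scores), scores_o, tolerance = 1e-9)
  expect_equal(unname(pc$loadings), load_o, tolerance = 1e-9)
  expect_equal(pc$explained_variance, sv$d^2 / sum(sv$d^2),
               tolerance = 1e-12)

  tab$d <- 5
  expect_error(pca_scores(tab, c("a", "d")), "constant")
})

test_that("Pillai's trace reduces to the ANOVA identity for one response", {
  tab <- data.frame(g = rep(c("A", "B", "C"), each = 4),
                    y = c(1.2, 1.9, 1.4, 1.7, 3.3, 2.8, 3.6, 2.9,
                          5.1, 4.7, 5.5, 4.9))
  res <- manova_pillai(tab, "g", "y")
  # independent route: sums of squares by direct accumulation
  grand <- mean(tab$y)
  ssb <- sum(tapply(tab$y, tab$g, function(v) length(v) * (mean(v) - grand)^2))
  sse <- sum(tapply(tab$y, tab$g, function(v) sum((v - mean(v))^2)))
  expect_equal(res$value, ssb / (ssb + sse), tolerance = 1e-14)
})

test_that("Pillai's trace matches stats::manova and degenerates to zero", {
  set.seed(7)
  tab <- data.frame(g = rep(c("u", "d", "c"), each = 5),
                    y1 = rnorm(15, rep(c(0, 1, 2), each = 5)),
                    y2 = rnorm(15, rep(c(2, 0, 1), each = 5)))
  res <- manova_pillai(tab, "g", c("y1", "y2"))
  fit <- summary(stats::manova(cbind(y1, y2) ~ g, data = tab),
                 test = "Pillai")
  expect_equal(res$value, fit$stats["g", "Pillai"], tolerance = 1e-10)
  expect_equal(res$F, fit$stats["g", "approx F"], tolerance = 1e-10)
  expect_equal(res$p_value, fit$stats["g", "Pr(>F)"], tolerance = 1e-10)

  # identical group means -> V = 0
  tab0 <- data.frame(g = rep(c("a", "b"), each = 3),
                     y1 = rep(c(1, 2, 3), 2), y2 = rep(c(4, 6, 5), 2))
  expect_equal(manova_pillai(tab0, "g", c("y1", "y2"))$value, 0,
               tolerance = 1e-12)

  expect_error(manova_pillai(data.frame(g = c("a", "b"), y = 1:2), "g", "y"),
               "at least 2 rows")
})

test_that("regression matches the normal-equations oracle", {
  tab <- data.frame(x1 = c(1, 2, 3, 4, 5, 6, 7, 8),
                    x2 = c(2, 1, 4, 3, 6, 5, 8, 7),
                    y = c(3.1, 3.9, 7.2, 6.8, 11.1, 10.7, 15.2, 14.6))
  res <- linear_model(tab, "y", c("x1", "x2"))
  X <- cbind(1, tab$x1, tab$x2)
  beta <- solve(t(X) %*% X, t(X) %*% tab$y)
  expect_equal(unname(res$coefficients), as.vector(beta), tolerance = 1e-9)
  yhat <- X %*% beta
  r2 <- 1 - sum((tab$y - yhat)^2) / sum((tab$y - mean(tab$y))^2)
  expect_equal(res$value, r2, tolerance = 1e-12)

  # exact fit and orthogonal predictor
  lin <- data.frame(x = 1:6, y = 2 * (1:6) - 1)
  expect_equal(suppressWarnings(linear_model(lin, "y", "x"))$value, 1,
               tolerance = 1e-12)   # lm warns on an exact fit
  orth <- data.frame(x = c(-1, 1, -1, 1), y = c(-1, -1, 1, 1))
  expect_equal(linear_model(orth, "y", "x")$value, 0, tolerance = 1e-12)

  # R^2 is invariant under affine rescaling of predictors
  tab2 <- tab
  tab2$x1 <- tab$x1 * 100 - 7
  tab2$x2 <- tab$x2 / 3 + 2
  expect_equal(linear_model(tab2, "y", c("x1", "x2"))$value, res$value,
               tolerance = 1e-10)
})

test_that("ANCOVA group effects agree with car::Anova", {
  set.seed(12)
  tab <- data.frame(g = rep(c("ctl", "run"), each = 8),
                    mass = rnorm(16, 5000, 300))
  tab$y <- 2 + 0.001 * tab$mass + ifelse(tab$g == "run", 1.5, 0) + rnorm(16, 0, 0.5)
  res <- linear_model(tab, "y", "g", covariate = "mass")
  fit <- stats::lm(y ~ mass + g, data = tab)
  ca <- car::Anova(fit, type = 2)
  expect_equal(res$F, ca["g", "F value"], tolerance = 1e-9)
  expect_equal(res$p_value, ca["g", "Pr(>F)"], tolerance = 1e-9)
  eta_o <- ca["g", "Sum Sq"] / (ca["g", "Sum Sq"] + ca["Residuals", "Sum Sq"])
  expect_equal(res$value, eta_o, tolerance = 1e-9)
  expect_true(is.finite(res$homogeneity_of_slopes_p))
})

test_that("Spearman handles monotone inputs and matches exhaustive enumeration", {
  x <- c(1.2, 3.4, 3.9, 5.5, 7.1, 8)
  expect_equal(spearman_test(x, x^3)$value, 1)
  expect_equal(spearman_test(x, -sqrt(x))$value, -1)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")

  # n = 6 hand pairs: rho against cor(); p against an independent
  # exhaustive enumeration using iterative lexicographic permutations
  y <- c(2.3, 1.1, 4.2, 3.3, 6.6, 5.0)
  res <- spearman_test(x, y)
  expect_equal(res$value, cor(x, y, method = "spearman"), tolerance = 1e-12)

  rx <- rank(x); ry <- rank(y)
  next_perm <- function(p) {
    n <- length(p); i <- n - 1
    while (i >= 1 && p[i] >= p[i + 1]) i <- i - 1
    if (i < 1) return(NULL)
    j <- n
    while (p[j] <= p[i]) j <- j - 1
    tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
    p[(i + 1):n] <- rev(p[(i + 1):n])
    p
  }
  p <- 1:6; count <- 0; hits <- 0
  obs <- abs(cor(rx, ry))
  repeat {
    count <- count + 1
    if (abs(cor(rx, ry[p])) >= obs - 1e-12) hits <- hits + 1
    p <- next_perm(p)
    if (is.null(p)) break
  }
  expect_equal(count, factorial(6))
  expect_equal(res$p_value, hits / count, tolerance = 1e-12)
})

test_that("statistics are invariant under row permutation", {
  set.seed(21)
  tab <- data.frame(g = rep(c("a", "b", "c"), each = 5),
                    y1 = rnorm(15), y2 = rnorm(15))
  perm <- sample(15)
  tabp <- tab[perm, ]
  expect_equal(manova_pillai(tabp, "g", c("y1", "y2"))$value,
               manova_pillai(tab, "g", c("y1", "y2"))$value,
               tolerance = 1e-12)
  expect_equal(linear_model(tabp, "y1", "y2")$value,
               linear_model(tab, "y1", "y2")$value, tolerance = 1e-12)
  expect_equal(lins_ccc(tab$y1[perm], tab$y2[perm])$value,
               lins_ccc(tab$y1, tab$y2)$value, tolerance = 1e-12)
})

test_that("assumption diagnostics report the three standard checks", {
  set.seed(30)
  tab <- data.frame(g = rep(c("a", "b"), each = 10), x = rnorm(20))
  tab$y <- tab$x + rnorm(20, 0, 0.3)
  d <- assumption_diagnostics(tab, "y", "x", group = "g")
  expect_setequal(d$check, c("residual_normality_shapiro",
                             "homoscedasticity_bp",
                             "group_dispersion_levene"))
  expect_true(all(d$p_value >= 0 & d$p_value <= 1))
})
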