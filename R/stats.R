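# Validation statistics for entheseal-change measurement tables:
# repeatability (Lin's concordance correlation, paired t), multivariate
# group comparison (MANOVA with Pillai's trace), ordination (correlation
# PCA), regression/ANCOVA with effect sizes, and Spearman screening
# against age and body-size proxies.  Standard model fits go through
# stats::lm / stats::t.test; the effect-size statistics reported in this
# field (Pillai's trace, CCC, partial eta squared) are computed here from
# their defining cross-product formulas.

vera_stat <- function(statistic_name, value, df = NULL, p_value = NA_real_,
                      extra = list()) {
  structure(c(list(statistic_name = statistic_name, value = value,
                   df = df, p_value = p_value), extra),
            class = "vera_stat")
}

#' @export
print.vera_stat <- function(x, ...) {
  cat(sprintf("<%s> value = %.6g", x$statistic_name, x$value))
  if (!is.null(x$df)) cat(sprintf(", df = (%s)", paste(x$df, collapse = ", ")))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement between paired measurements (precision times accuracy):
#' rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2), with
#' population (1/n) moments - the original estimator. Repeatability of a
#' measurement protocol is conventionally accepted at rho_c >= 0.95.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @param bias_corrected use (1/(n-1)) moments instead.
#' @return A `vera_stat` with `statistic_name = "ccc"`.
#' @export
lins_ccc <- function(x, y, bias_corrected = FALSE) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (!all(is.finite(c(x, y)))) stop("non-finite values")
  n <- length(x)
  fac <- if (bias_corrected) n / (n - 1) else 1
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my)) * fac
  sx2 <- mean((x - mx)^2) * fac
  sy2 <- mean((y - my)^2) * fac
  if (sx2 == 0 && sy2 == 0)
    stop("both vectors are constant; concordance is undefined")
  denom <- sx2 + sy2 + (mx - my)^2
  vera_stat("ccc", 2 * sxy / denom,
            extra = list(n = n, bias_corrected = bias_corrected))
}

#' Paired t test
#'
#' Thin wrapper over [stats::t.test()] returning the package's common
#' result shape; errors (rather than returning NaN) when the differences
#' have zero variance, which for repeatability data means the two runs
#' are bit-identical and a t test is meaningless.
#'
#' @param x,y paired numeric vectors.
#' @return A `vera_stat` with `statistic_name = "t"`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    stop("differences have zero variance; paired t is undefined")
  tt <- stats::t.test(x, y, paired = TRUE)
  vera_stat("t", unname(tt$statistic), df = unname(tt$parameter),
            p_value = tt$p.value,
            extra = list(mean_difference = unname(tt$estimate)))
}

#' Principal component analysis of a measurement table
#'
#' Correlation PCA: the columns are z-scored before the eigendecomposition
#' so that mm^2 areas and covariates on other scales (stride counts, body
#' mass) can enter one ordination. Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is
#' positive.
#'
#' @param table data.frame.
#' @param columns character vector of >= 2 numeric column names.
#' @return A list: `scores`, `loadings`, `explained_variance` (proportion
#'   per component), `sdev`.
#' @export
pca_scores <- function(table, columns) {
  if (length(columns) < 2L) stop("need at least 2 columns")
  X <- as.matrix(table[, columns, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3L) stop("need at least 3 complete rows")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(columns[sds == 0], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pc$rotation))) {
    k <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[k, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = pc$sdev^2 / sum(pc$sdev^2), sdev = pc$sdev)
}

#' MANOVA with Pillai's trace
#'
#' Between-group (H) and within-group (E) cross-product matrices are
#' formed from the response matrix; Pillai's trace is
#' V = tr(H (H + E)^-1), reported with its standard F approximation.
#' With a single response this reduces exactly to the one-way ANOVA
#' variance-explained ratio SSB / (SSB + SSE).
#'
#' @param table data.frame.
#' @param group name of the grouping column (>= 2 levels, each with >= 2
#'   rows).
#' @param responses character vector of numeric response columns.
#' @return A `vera_stat` with `statistic_name = "pillai"`, the approximate
#'   F, df pair and p-value in `extra`.
#' @export
manova_pillai <- function(table, group, responses) {
  g <- factor(table[[group]])
  Y <- as.matrix(table[, responses, drop = FALSE])
  keep <- stats::complete.cases(Y) & !is.na(g)
  Y <- Y[keep, , drop = FALSE]; g <- droplevels(g[keep])
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 rows")
  n <- nrow(Y); p <- ncol(Y); k <- nlevels(g)
  if (n - k < p)
    stop("within-group cross-product matrix is singular with n - groups < ",
         "responses; use fewer responses")
  grand <- colMeans(Y)
  H <- matrix(0, p, p); E <- matrix(0, p, p)
  for (lev in levels(g)) {
    Yg <- Y[g == lev, , drop = FALSE]
    mg <- colMeans(Yg)
    H <- H + nrow(Yg) * tcrossprod(mg - grand)
    C <- sweep(Yg, 2L, mg)
    E <- E + crossprod(C)
  }
  V <- sum(diag(H %*% solve(H + E)))
  s <- min(p, k - 1)
  m <- (abs(p - k + 1) - 1) / 2
  nn <- (n - k - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  Fstat <- (df2 / df1) * (V / (s - V))
  pval <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  vera_stat("pillai", V, df = c(df1, df2), p_value = pval,
            extra = list(F = Fstat, n = n, p = p, groups = k))
}

#' Linear regression and ANCOVA with effect sizes
#'
#' Without `covariate`: ordinary least squares of `response` on
#' `predictors`, reporting R^2 and the overall F. With `covariate`:
#' analysis of covariance - `predictors[1]` must be a grouping factor; the
#' model `response ~ covariate + group` is fitted, the group effect is
#' tested after the covariate, partial eta^2 =
#' SS_group / (SS_group + SS_resid) is reported, and the
#' homogeneity-of-slopes assumption (no covariate x group interaction) is
#' checked and reported as a diagnostic, not a gate.
#'
#' @param table data.frame.
#' @param response response column name.
#' @param predictors character vector of predictor column names.
#' @param covariate optional covariate column name (switches to ANCOVA).
#' @return A `vera_stat`: `statistic_name = "R2"` for regression or
#'   `"partial_eta2"` for ANCOVA; coefficients and diagnostics in `extra`.
#' @export
linear_model <- function(table, response, predictors, covariate = NULL) {
  if (is.null(covariate)) {
    dat <- table[, c(response, predictors), drop = FALSE]
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    if (nrow(dat) < length(predictors) + 2L)
      stop("need at least predictors + 2 complete rows")
    X <- as.matrix(dat[, predictors, drop = FALSE])
    if (ncol(X) > 1L && kappa(stats::cor(X)) > 1e10)
      stop("predictors are collinear")
    fml <- stats::reformulate(predictors, response)
    fit <- stats::lm(fml, data = dat)
    sm <- summary(fit)
    fs <- sm$fstatistic
    vera_stat("R2", unname(sm$r.squared),
              df = if (!is.null(fs)) unname(fs[2:3]),
              p_value = if (!is.null(fs))
                stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
              else NA_real_,
              extra = list(F = if (!is.null(fs)) unname(fs[1]),
                           coefficients = stats::coef(fit),
                           residual_normality_p =
                             tryCatch(stats::shapiro.test(stats::residuals(fit))$p.value,
                                      error = function(e) NA_real_)))
  } else {
    group <- predictors[1]
    dat <- table[, c(response, group, covariate), drop = FALSE]
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    dat[[group]] <- factor(dat[[group]])
    fit <- stats::lm(stats::reformulate(c(covariate, group), response),
                     data = dat)
    an <- stats::anova(fit)
    ss_group <- an[group, "Sum Sq"]
    ss_resid <- an["Residuals", "Sum Sq"]
    inter <- stats::lm(stats::reformulate(paste(covariate, "*", group),
                                          response), data = dat)
    slopes_p <- stats::anova(inter)[paste0(covariate, ":", group), "Pr(>F)"]
    vera_stat("partial_eta2", ss_group / (ss_group + ss_resid),
              df = c(an[group, "Df"], an["Residuals", "Df"]),
              p_value = an[group, "Pr(>F)"],
              extra = list(F = an[group, "F value"],
                           homogeneity_of_slopes_p = slopes_p))
  }
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. P-values: exhaustive permutation for
#' n <= 8, deterministic Monte Carlo permutation (19999 draws) for
#' 9 <= n < 30 - validation samples in this field are small - and the
#' asymptotic t approximation otherwise.
#'
#' @param x,y numeric vectors of length >= 4.
#' @return A `vera_stat` with `statistic_name = "rho"`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 4L) stop("need at least 4 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input; rank correlation is undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    pval <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exhaustive permutation"
  } else if (n < 30L) {
    nperm <- 19999L
    rhos <- with_preserved_rng(20260101L, vapply(seq_len(nperm), function(i)
      stats::cor(rx, sample(ry)), 0.0))
    pval <- (sum(abs(rhos) >= abs(rho) - 1e-12) + 1) / (nperm + 1)
    method <- "Monte Carlo permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    pval <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
    method <- "asymptotic t"
  }
  vera_stat("rho", rho, p_value = pval,
            extra = list(n = n, p_method = method))
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Assumption diagnostics for a measurement table model
#'
#' Emits (never gates on) the checks conventionally reported alongside
#' these analyses: Shapiro-Wilk on residuals, Breusch-Pagan-style
#' heteroscedasticity (squared residuals on fitted values), and, when a
#' grouping factor is given, Levene-style dispersion homogeneity (ANOVA on
#' absolute deviations from group medians).
#'
#' @param table data.frame.
#' @param response response column.
#' @param predictors predictor columns.
#' @param group optional grouping column.
#' @return A data.frame of diagnostics with columns `check`, `statistic`,
#'   `p_value`.
#' @export
assumption_diagnostics <- function(table, response, predictors,
                                   group = NULL) {
  dat <- table[, unique(c(response, predictors, group)), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  fit <- stats::lm(stats::reformulate(predictors, response), data = dat)
  res <- stats::residuals(fit)
  out <- list()
  sw <- stats::shapiro.test(res)
  out[[1]] <- data.frame(check = "residual_normality_shapiro",
                         statistic = unname(sw$statistic),
                         p_value = sw$p.value)
  aux <- stats::lm(res^2 ~ stats::fitted(fit))
  f <- summary(aux)$fstatistic
  out[[2]] <- data.frame(check = "homoscedasticity_bp",
                         statistic = unname(f[1]),
                         p_value = stats::pf(f[1], f[2], f[3],
                                             lower.tail = FALSE))
  if (!is.null(group)) {
    gf <- factor(dat[[group]])
    med <- stats::ave(dat[[response]], gf, FUN = stats::median)
    lev <- stats::oneway.test(abs(dat[[response]] - med) ~ gf,
                              var.equal = TRUE)
    out[[3]] <- data.frame(check = "group_dispersion_levene",
                           statistic = unname(lev$statistic),
                           p_value = lev$p.value)
  }
  do.call(rbind, out)
}
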