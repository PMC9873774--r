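#' Pearson correlation matrix among divergent-thinking indices
#'
#' Pairwise Pearson correlations with two-sided p-values over the supplied
#' score columns, using pairwise-complete observations.
#'
#' @param scores data.frame of participant scores.
#' @param columns character vector of score columns to correlate (default:
#'   the four AUT indices present in `scores`).
#' @return an object of class `correlation_matrix`: list(r, p, n) of
#'   symmetric matrices. A zero-variance column yields NA entries with a
#'   warning.
#' @export
correlation_matrix <- function(scores,
                               columns = intersect(
                                 c("rb_originality", "fb_originality",
                                   "fluency", "flexibility"),
                                 names(scores))) {
  stopifnot(length(columns) >= 2)
  d <- scores[, columns, drop = FALSE]
  k <- length(columns)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      ok <- stats::complete.cases(d[[i]], d[[j]])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3) next
      if (stats::sd(d[[i]][ok]) == 0 || stats::sd(d[[j]][ok]) == 0) {
        warning("zero variance in ", columns[i], " or ", columns[j],
                "; correlation undefined")
        next
      }
      ct <- stats::cor.test(d[[i]][ok], d[[j]][ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n, handling = "pairwise-complete"),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat("Pearson correlations (", x$handling, "):\n", sep = "")
  print(round(x$r, digits))
  invisible(x)
}

coef_table <- function(est, se, df) {
  t <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             t = unname(t),
             p = 2 * stats::pt(-abs(unname(t)), df),
             row.names = NULL)
}

#' Hierarchical linear-then-quadratic regression on sEBR
#'
#' Step 1 regresses the index on sEBR; step 2 adds the squared term.
#' Reports raw and standardized coefficients, standard errors, t and
#' two-sided p per step, R-squared per step and the R-squared increment,
#' and flags observations with absolute standardized residuals above 3
#' (step-2 model).
#'
#' @param x predictor (sEBR, blinks/min).
#' @param y outcome (one AUT index).
#' @return object of class `hierarchical_fit`: list(step1, step2
#'   coefficient tables, r2 = c(step1, step2), delta_r2, n, estimator,
#'   outliers = indices flagged, std_coef = standardized step-2 slopes).
#' @export
hierarchical_quadratic_fit <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n > 4)
  if (stats::sd(x) == 0) stop("constant predictor: model is collinear")
  f1 <- stats::lm(y ~ x)
  f2 <- stats::lm(y ~ x + I(x^2))
  s1 <- summary(f1); s2 <- summary(f2)
  std_res <- stats::rstandard(f2)
  zx <- (x - mean(x)) / stats::sd(x)
  zy <- if (stats::sd(y) > 0) (y - mean(y)) / stats::sd(y) else y * 0
  fstd <- stats::lm(zy ~ zx + I(zx^2))
  structure(list(
    step1 = coef_table(stats::coef(f1), s1$coefficients[, 2], f1$df.residual),
    step2 = coef_table(stats::coef(f2), s2$coefficients[, 2], f2$df.residual),
    r2 = c(step1 = s1$r.squared, step2 = s2$r.squared),
    delta_r2 = s2$r.squared - s1$r.squared,
    n = n,
    estimator = "OLS",
    outliers = which(abs(std_res) > 3),
    std_coef = stats::coef(fstd)[-1]),
    class = "hierarchical_fit")
}

# weighted R^2 analogue reported for robust fits
robust_r2 <- function(fit, y) {
  w <- fit$w
  yw <- sum(w * y) / sum(w)
  1 - sum(w * stats::residuals(fit)^2) / sum(w * (y - yw)^2)
}

#' Robust (MM-type) hierarchical quadratic regression
#'
#' Same two-step structure as [hierarchical_quadratic_fit()] but using
#' MM-estimation (S-estimate of scale followed by a redescending bisquare
#' M-step at 95% Gaussian efficiency), which down-weights gross outliers.
#' The reported R-squared analogue is the weight-based one and is labeled
#' as such. The S-stage subsampling RNG is pinned internally so repeated
#' calls are deterministic; the caller's RNG state is restored.
#'
#' @param x predictor; @param y outcome; n must exceed 10.
#' @return object of class `hierarchical_fit` with estimator "robust-MM";
#'   outlier flags come from robust standardized residuals
#'   (residual / scale estimate) above 3.
#' @export
robust_quadratic_fit <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n > 10)
  if (stats::sd(x) == 0) stop("constant predictor: model is collinear")
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(20260101L)
  if (stats::sd(y) == 0) {
    # degenerate flat outcome: slopes are exactly zero
    est1 <- c("(Intercept)" = y[1], x = 0)
    est2 <- c("(Intercept)" = y[1], x = 0, "I(x^2)" = 0)
    return(structure(list(
      step1 = coef_table(est1, rep(NA_real_, 2), n - 2),
      step2 = coef_table(est2, rep(NA_real_, 3), n - 3),
      r2 = c(step1 = NA_real_, step2 = NA_real_),
      delta_r2 = NA_real_, n = n, estimator = "robust-MM",
      outliers = integer(0), std_coef = c(zx = 0, `I(zx^2)` = 0)),
      class = "hierarchical_fit"))
  }
  f1 <- MASS::rlm(y ~ x, method = "MM", maxit = 200)
  f2 <- MASS::rlm(y ~ x + I(x^2), method = "MM", maxit = 200)
  if (!f1$converged || !f2$converged) {
    stop("robust MM fit failed to converge (n = ", n, ", scale = ",
         signif(f2$s, 4), ")")
  }
  s1 <- summary(f1, method = "XtWX"); s2 <- summary(f2, method = "XtWX")
  std_res <- stats::residuals(f2) / f2$s
  zx <- (x - mean(x)) / stats::sd(x)
  zy <- (y - mean(y)) / stats::sd(y)
  fstd <- MASS::rlm(zy ~ zx + I(zx^2), method = "MM", maxit = 200)
  structure(list(
    step1 = coef_table(stats::coef(f1), s1$coefficients[, 2], n - 2),
    step2 = coef_table(stats::coef(f2), s2$coefficients[, 2], n - 3),
    r2 = c(step1 = robust_r2(f1, y), step2 = robust_r2(f2, y)),
    delta_r2 = robust_r2(f2, y) - robust_r2(f1, y),
    n = n,
    estimator = "robust-MM",
    outliers = which(abs(std_res) > 3),
    std_coef = stats::coef(fstd)[-1]),
    class = "hierarchical_fit")
}

#' @export
print.hierarchical_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Hierarchical fit (%s), n = %d\n", x$estimator, x$n))
  cat("Step 1 (linear):\n"); print(x$step1, digits = digits)
  cat("Step 2 (quadratic):\n"); print(x$step2, digits = digits)
  cat(sprintf("R2: step1 = %.4f, step2 = %.4f, delta = %.4f\n",
              x$r2[1], x$r2[2], x$delta_r2))
  if (length(x$outliers)) {
    cat("outliers (|std resid| > 3):", paste(x$outliers, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Power of the noncentral-F test of one (or more) regression coefficients
#'
#' Fixed-model multiple regression power: with effect size f-squared, the
#' noncentrality is lambda = f-squared x N; the test has `numerator_df`
#' numerator and N - n_predictors - 1 denominator degrees of freedom.
#'
#' @param n total sample size.
#' @param f2 Cohen's f-squared effect size (> 0).
#' @param alpha type-I error rate.
#' @param n_predictors number of predictors in the full model.
#' @param numerator_df degrees of freedom of the tested effect (1 for a
#'   single coefficient; n_predictors for the whole model R-squared).
#' @return power in (0, 1).
#' @export
regression_power <- function(n, f2, alpha = 0.05, n_predictors = 3,
                             numerator_df = 1) {
  df2 <- n - n_predictors - 1
  stopifnot(df2 >= 1, f2 > 0, alpha > 0, alpha < 1)
  crit <- stats::qf(1 - alpha, numerator_df, df2)
  1 - stats::pf(crit, numerator_df, df2, ncp = f2 * n)
}

#' Minimal sample size for a target regression power
#'
#' Smallest integer N whose noncentral-F power (see
#' [regression_power()]) reaches the target. With the conventional medium
#' effect (f-squared 0.15), alpha 0.05, three predictors and a
#' single-coefficient test this yields N = 55.
#'
#' @param f2 effect size f-squared.
#' @param alpha significance level.
#' @param power target power in (0, 1).
#' @param n_predictors predictors in the full model.
#' @param numerator_df numerator degrees of freedom of the tested effect.
#' @param n_max search ceiling (error if the target is not reached by it).
#' @return minimal N (integer).
#' @export
required_sample_size <- function(f2, alpha = 0.05, power = 0.80,
                                 n_predictors = 3, numerator_df = 1,
                                 n_max = 100000L) {
  stopifnot(f2 > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  for (n in seq(n_predictors + 2L, n_max)) {
    if (regression_power(n, f2, alpha, n_predictors, numerator_df) >=
        power) {
      return(as.integer(n))
    }
  }
  stop("target power ", power, " not attainable with N <= ", n_max)
}
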