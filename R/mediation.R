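#' Specification of a curvilinear mediation model
#'
#' The predictor-to-mediator (a) path and the direct predictor-to-outcome
#' path can each be linear or quadratic; the mediator-to-outcome (b) path
#' is linear. The instantaneous indirect effect is evaluated at low,
#' moderate and high predictor values (mean - SD, mean, mean + SD by
#' default) and its confidence interval obtained by case-resampling
#' percentile bootstrap.
#'
#' @param x_to_m "quadratic" (default) or "linear" a-path.
#' @param direct_x_to_y "quadratic" (default) or "linear" direct path.
#' @param n_boot number of bootstrap resamples (default 5000; at least
#'   1000 for reported intervals).
#' @param ci_level confidence level in (0, 1), default 0.95.
#' @param seed integer seed driving the resampling.
#' @param eval_points optional explicit numeric vector of predictor values
#'   at which to evaluate the indirect effect; `NULL` uses mean +/- 1 SD.
#' @param center_x logical; center the predictor before squaring. The
#'   instantaneous indirect effect at a given raw predictor value is
#'   invariant under this reparametrisation.
#' @return an object of class `mediation_spec`.
#' @export
mediation_spec <- function(x_to_m = c("quadratic", "linear"),
                           direct_x_to_y = c("quadratic", "linear"),
                           n_boot = 5000, ci_level = 0.95, seed = 1L,
                           eval_points = NULL, center_x = FALSE) {
  x_to_m <- match.arg(x_to_m)
  direct_x_to_y <- match.arg(direct_x_to_y)
  stopifnot(n_boot >= 1, ci_level > 0, ci_level < 1)
  if (n_boot < 1000) {
    warning("n_boot < 1000: confidence intervals will be unstable")
  }
  structure(list(x_to_m = x_to_m, m_to_y = "linear",
                 direct_x_to_y = direct_x_to_y,
                 n_boot = as.integer(n_boot), ci_level = ci_level,
                 seed = as.integer(seed), eval_points = eval_points,
                 center_x = isTRUE(center_x)),
            class = "mediation_spec")
}

# design matrices for the two path models, built once per data set
mediation_design <- function(x, m, spec) {
  xc <- if (spec$center_x) x - mean(x) else x
  xm <- if (spec$x_to_m == "quadratic") cbind(1, xc, xc^2) else cbind(1, xc)
  xy_direct <- if (spec$direct_x_to_y == "quadratic") {
    cbind(xc, xc^2)
  } else {
    cbind(xc)
  }
  list(xm = xm, xy = cbind(1, m, xy_direct), offset = mean(x))
}

# raw coefficient extraction from the two least-squares fits
paths_from_fits <- function(cm, cy, spec) {
  a1 <- cm[2]
  a2 <- if (spec$x_to_m == "quadratic") cm[3] else 0
  c1 <- cy[3]
  c2 <- if (spec$direct_x_to_y == "quadratic") cy[4] else 0
  # with centred x the raw-scale derivative at x is a1 + 2 a2 (x - mean),
  # i.e. a1 on the raw scale becomes a1 - 2 a2 mean(x)
  list(a1 = unname(a1), a2 = unname(a2), b = unname(cy[2]),
       c1 = unname(c1), c2 = unname(c2),
       i_m = unname(cm[1]), i_y = unname(cy[1]))
}

#' Fit the mediation path models
#'
#' Ordinary least squares: M on (X [, X^2]); Y on (M, X [, X^2]) as
#' dictated by the spec. Under a linear a-path the quadratic coefficient
#' a2 is exactly 0 by construction.
#'
#' @param data data.frame with columns `x`, `m`, `y` (see
#'   [as_mediation_data()] to map arbitrary column names).
#' @param spec a [mediation_spec()].
#' @return object of class `path_coefficients`: list(a1, a2, b, c1, c2,
#'   i_m, i_y, se (named vector of standard errors), spec, x_mean).
#' @export
fit_paths <- function(data, spec = mediation_spec()) {
  stopifnot(all(c("x", "m", "y") %in% names(data)))
  d <- data[stats::complete.cases(data[, c("x", "m", "y")]), ]
  n <- nrow(d)
  n_par <- 3 + (spec$x_to_m == "quadratic") +
    (spec$direct_x_to_y == "quadratic")
  if (n <= n_par + 2) stop("too few complete cases (n = ", n, ")")
  des <- mediation_design(d$x, d$m, spec)
  fm <- stats::lm.fit(des$xm, d$m)
  fy <- stats::lm.fit(des$xy, d$y)
  if (fm$rank < ncol(des$xm) || fy$rank < ncol(des$xy)) {
    stop("rank-deficient design: predictor values are degenerate")
  }
  se_of <- function(fit, X) {
    sigma2 <- sum(fit$residuals^2) / (length(fit$residuals) - ncol(X))
    sqrt(diag(chol2inv(chol(crossprod(X))) * sigma2))
  }
  co <- paths_from_fits(fm$coefficients, fy$coefficients, spec)
  se_m <- se_of(fm, des$xm); se_y <- se_of(fy, des$xy)
  co$se <- c(a1 = se_m[2],
             a2 = if (spec$x_to_m == "quadratic") se_m[3] else 0,
             b = se_y[2], c1 = se_y[3],
             c2 = if (spec$direct_x_to_y == "quadratic") se_y[4] else 0)
  co$spec <- spec
  co$x_mean <- mean(d$x)
  co$n <- n
  class(co) <- "path_coefficients"
  co
}

#' Map arbitrary column names onto the mediation (x, m, y) layout
#'
#' @param data a data.frame.
#' @param x,m,y names of the predictor, mediator and outcome columns.
#' @return data.frame with columns x, m, y.
#' @export
as_mediation_data <- function(data, x = "sebr", m = "flexibility",
                              y = "rb_originality") {
  stopifnot(all(c(x, m, y) %in% names(data)))
  data.frame(x = data[[x]], m = data[[m]], y = data[[y]])
}

#' Instantaneous indirect effect
#'
#' theta(x) = (a1 + 2 a2 x) b: the rate at which a change in the
#' predictor changes the outcome through the mediator, at predictor value
#' x. With a quadratic a-path theta varies linearly in x (slope 2 a2 b);
#' with a linear a-path it is the constant a1 b. When the model was fitted
#' with a centred predictor the supplied x values are centred with the
#' stored mean, so theta refers to raw predictor units either way.
#'
#' @param coefs a `path_coefficients` object (or list with a1, a2, b).
#' @param x_value numeric vector of predictor values.
#' @return numeric vector of theta values.
#' @export
instantaneous_indirect_effect <- function(coefs, x_value) {
  x <- x_value
  if (!is.null(coefs$spec) && isTRUE(coefs$spec$center_x)) {
    x <- x - coefs$x_mean
  }
  (coefs$a1 + 2 * coefs$a2 * x) * coefs$b
}

#' Low / moderate / high evaluation points of the predictor
#'
#' Under the default rule, returns (mean - SD, mean, mean + SD) of the
#' sample, with the n-1 denominator SD. An explicit numeric vector is
#' passed through unchanged.
#'
#' @param x_sample numeric predictor sample (n >= 2).
#' @param rule "mean_sd" or a numeric vector of explicit points.
#' @return named numeric vector c(low, moderate, high).
#' @export
evaluation_points <- function(x_sample, rule = "mean_sd") {
  if (is.numeric(rule)) {
    pts <- rule
    if (length(pts) == 3 && is.null(names(pts))) {
      names(pts) <- c("low", "moderate", "high")
    }
    return(pts)
  }
  stopifnot(identical(rule, "mean_sd"), length(x_sample) >= 2)
  mu <- mean(x_sample); sdev <- stats::sd(x_sample)
  if (sdev == 0) {
    warning("zero variance in predictor: evaluation points are degenerate")
  }
  c(low = mu - sdev, moderate = mu, high = mu + sdev)
}

#' Bootstrap the instantaneous indirect effect
#'
#' Case-resampling bootstrap: participants are resampled with replacement
#' `n_boot` times, the path models refitted, and theta evaluated at the
#' original sample's evaluation points; percentile intervals at the
#' requested level are returned. Resamples with a rank-deficient design
#' are redrawn (their count is reported). Fully deterministic under the
#' spec's seed.
#'
#' @param data data.frame with columns x, m, y (n >= 20).
#' @param spec a [mediation_spec()].
#' @return object of class `mediation_result`: list(coefficients,
#'   eval_points, theta, ci (2 x 3 matrix of lower/upper), n_boot, seed,
#'   n_redrawn, ci_level).
#' @export
bootstrap_mediation <- function(data, spec = mediation_spec()) {
  d <- data[stats::complete.cases(data[, c("x", "m", "y")]), ]
  n <- nrow(d)
  stopifnot(n >= 20)
  coefs <- fit_paths(d, spec)
  pts <- if (is.null(spec$eval_points)) {
    evaluation_points(d$x)
  } else {
    evaluation_points(d$x, spec$eval_points)
  }
  theta_hat <- instantaneous_indirect_effect(coefs, pts)

  des <- mediation_design(d$x, d$m, spec)
  xm <- des$xm
  pm <- ncol(xm)
  m_vec <- d$m; y_vec <- d$y
  x_dir <- des$xy[, -(1:2), drop = FALSE]  # direct-path columns
  pts_fit <- if (spec$center_x) pts - mean(d$x) else pts

  set.seed(spec$seed)
  theta_boot <- matrix(NA_real_, spec$n_boot, length(pts))
  n_redrawn <- 0L
  for (bb in seq_len(spec$n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      xm_b <- xm[idx, , drop = FALSE]
      fm <- stats::lm.fit(xm_b, m_vec[idx])
      xy_b <- cbind(1, m_vec[idx], x_dir[idx, , drop = FALSE])
      fy <- stats::lm.fit(xy_b, y_vec[idx])
      if (fm$rank == ncol(xm_b) && fy$rank == ncol(xy_b)) break
      n_redrawn <- n_redrawn + 1L
    }
    a1 <- fm$coefficients[2]
    a2 <- if (pm == 3) fm$coefficients[3] else 0
    theta_boot[bb, ] <- (a1 + 2 * a2 * pts_fit) * fy$coefficients[2]
  }
  alpha <- 1 - spec$ci_level
  ci <- apply(theta_boot, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2))
  colnames(ci) <- names(pts)
  structure(list(coefficients = coefs, eval_points = pts,
                 theta = theta_hat, ci = ci,
                 n_boot = spec$n_boot, seed = spec$seed,
                 ci_level = spec$ci_level, n = n,
                 n_redrawn = n_redrawn),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, digits = 4, ...) {
  co <- x$coefficients
  cat(sprintf(
    "Curvilinear mediation (n = %d, %d bootstrap resamples)\n", x$n,
    x$n_boot))
  cat(sprintf("paths: a1 = %.4f, a2 = %.5f, b = %.4f, c1 = %.4f, c2 = %.5f\n",
              co$a1, co$a2, co$b, co$c1, co$c2))
  tab <- data.frame(x = x$eval_points, theta = x$theta,
                    ci_lower = x$ci[1, ], ci_upper = x$ci[2, ])
  print(round(tab, digits))
  invisible(x)
}
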