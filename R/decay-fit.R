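#' Fit a correlation–distance decay curve
#'
#' Models the Pearson correlation between a focal gene and its neighbors as
#' a function of absolute genomic distance,
#' \deqn{\rho(d) = c + a \, e^{-|d|/\lambda},}
#' by multistart nonlinear least squares ([minpack.lm::nlsLM()]), with the
#' decay length initialized at 1, 5 and 25 kb and bounded to
#' `[100 bp, 10 Mb]`. A power-law alternative
#' \eqn{\rho(d) = c + a (1 + |d|/1\,\mathrm{kb})^{-b}} is available via
#' `model = "power"`.
#'
#' When the 95% confidence interval of the fitted amplitude covers zero, or
#' the decay model does not improve on the flat model, the fit is declared
#' flat: `a = 0`, `c = mean(pcc)`, `flat_flag = TRUE`.
#'
#' @param points a data frame with columns `distance` (bp, sign ignored;
#'   the column `signed_distance` of a [locus_profile()] is also accepted)
#'   and `pcc`. Rows with undefined PCC are dropped.
#' @param model `"exponential"` (default) or `"power"`.
#' @param conf_level confidence level for the flat-amplitude check.
#' @return An object of class `decay_fit` with elements `a`, `lambda`
#'   (bp; `NA` when flat; for the power model the shape exponent is stored
#'   in `b`), `c`, `rss`, `n_points`, `flat_flag`, `model`, `fit` (the nls
#'   object or `NULL`), `data`.
#' @export
#' @examples
#' d <- seq(1000, 10000, by = 1000)
#' fit_decay(data.frame(distance = d, pcc = 0.8 * exp(-d / 5000)))
fit_decay <- function(points, model = c("exponential", "power"),
                      conf_level = 0.95) {
  model <- match.arg(model)
  points <- tibble::as_tibble(points)
  if (!"distance" %in% names(points) && "signed_distance" %in% names(points)) {
    points$distance <- points$signed_distance
  }
  if (!all(c("distance", "pcc") %in% names(points))) {
    abort_locusecho("`points` needs columns `distance` and `pcc`")
  }
  pts <- dplyr::filter(points, !is.na(.data$pcc), !is.na(.data$distance))
  pts$d <- abs(pts$distance)
  if (nrow(pts) < 4 || length(unique(pts$d)) < 3) {
    abort_locusecho("need >= 4 points with >= 3 distinct |distance| values")
  }
  flat_c <- mean(pts$pcc)
  flat_rss <- sum((pts$pcc - flat_c)^2)
  make_flat <- function() {
    structure(list(a = 0, lambda = NA_real_, b = NA_real_, c = flat_c,
                   rss = flat_rss, n_points = nrow(pts), flat_flag = TRUE,
                   model = model, fit = NULL, data = pts),
              class = "decay_fit")
  }
  if (flat_rss < 1e-24) return(make_flat())

  a_start <- max(pts$pcc) - min(pts$pcc)
  c_start <- min(pts$pcc)
  fits <- list()
  if (model == "exponential") {
    for (lam0 in c(1e3, 5e3, 2.5e4)) {
      f <- tryCatch(
        minpack.lm::nlsLM(
          pcc ~ c + a * exp(-d / lambda), data = pts,
          start = list(a = max(a_start, 0.05), lambda = lam0, c = c_start),
          lower = c(a = -2, lambda = 100, c = -1),
          upper = c(a = 2, lambda = 1e7, c = 1),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(f)) fits[[length(fits) + 1]] <- f
    }
  } else {
    for (b0 in c(0.5, 1, 2)) {
      f <- tryCatch(
        minpack.lm::nlsLM(
          pcc ~ c + a * (1 + d / 1000)^(-b), data = pts,
          start = list(a = max(a_start, 0.05), b = b0, c = c_start),
          lower = c(a = -2, b = 0.01, c = -1),
          upper = c(a = 2, b = 20, c = 1),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(f)) fits[[length(fits) + 1]] <- f
    }
  }
  if (length(fits) == 0) {
    warning("decay fit did not converge from any start; returning flat fit")
    return(make_flat())
  }
  rsss <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  best <- fits[[which.min(rsss)]]
  est <- stats::coef(best)
  rss <- min(rsss)
  # flat-amplitude check: 95% CI of a covers 0, or no improvement over flat
  a_se <- tryCatch(sqrt(stats::vcov(best)["a", "a"]), error = function(e) Inf)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (rss >= flat_rss || (is.finite(a_se) && abs(est[["a"]]) <= zq * a_se)) {
    return(make_flat())
  }
  structure(list(a = unname(est[["a"]]),
                 lambda = if (model == "exponential") unname(est[["lambda"]]) else NA_real_,
                 b = if (model == "power") unname(est[["b"]]) else NA_real_,
                 c = unname(est[["c"]]),
                 rss = rss, n_points = nrow(pts), flat_flag = FALSE,
                 model = model, fit = best, data = pts),
            class = "decay_fit")
}

#' Evaluate a fitted decay curve
#'
#' @param object a `decay_fit`.
#' @param newdata optional data frame with a `distance` column; defaults to
#'   the fitted points.
#' @param ... unused.
#' @return Numeric vector of fitted PCC values.
#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  d <- abs(if (is.null(newdata)) object$data$distance else newdata$distance)
  if (object$flat_flag) return(rep(object$c, length(d)))
  if (object$model == "exponential") {
    object$c + object$a * exp(-d / object$lambda)
  } else {
    object$c + object$a * (1 + d / 1000)^(-object$b)
  }
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$flat_flag) {
    cat("<decay_fit> flat: a = 0, c =", signif(x$c, 4),
        "(", x$n_points, "points )\n")
  } else if (x$model == "exponential") {
    cat("<decay_fit> pcc = ", signif(x$c, 4), " + ", signif(x$a, 4),
        " * exp(-|d| / ", signif(x$lambda, 5), " bp), rss = ",
        signif(x$rss, 4), ", n = ", x$n_points, "\n", sep = "")
  } else {
    cat("<decay_fit> pcc = ", signif(x$c, 4), " + ", signif(x$a, 4),
        " * (1 + |d|/1kb)^-", signif(x$b, 4), ", rss = ",
        signif(x$rss, 4), ", n = ", x$n_points, "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a decay fit into one row per parameter
#'
#' @param x a `decay_fit`.
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  if (x$flat_flag || is.null(x$fit)) {
    return(tibble::tibble(term = c("a", "c"),
                          estimate = c(0, x$c),
                          std.error = NA_real_))
  }
  est <- stats::coef(x$fit)
  se <- sqrt(diag(stats::vcov(x$fit)))
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se[names(est)]))
}

#' One-row summary of a decay fit
#'
#' @param x a `decay_fit`.
#' @param ... unused.
#' @return A tibble: `a`, `lambda`, `c`, `rss`, `n_points`, `flat_flag`,
#'   `model`.
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(a = x$a, lambda = x$lambda, c = x$c, rss = x$rss,
                 n_points = x$n_points, flat_flag = x$flat_flag,
                 model = x$model)
}

#' Plot decay-fit points and curve
#'
#' @param object a `decay_fit`.
#' @param ... unused.
#' @return A ggplot object: PCC vs |distance| with the fitted curve.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  pts <- object$data
  grid <- tibble::tibble(distance = seq(0, max(pts$d), length.out = 200))
  grid$pcc <- predict(object, grid)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$d, y = .data$pcc)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$distance, y = .data$pcc),
                       color = "#B2182B") +
    ggplot2::labs(x = "genomic distance (bp)", y = "PCC",
                  title = if (object$flat_flag) "flat fit" else
                    sprintf("a = %.2f, lambda = %.0f bp, c = %.2f",
                            object$a, object$lambda, object$c)) +
    ggplot2::theme_minimal()
}
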