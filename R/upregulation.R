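#' Per-patient differential expression profile
#'
#' Subtracts the control expression vector from the paired tumor vector,
#' gene by gene. Negative values (higher expression in the control) are
#' retained; only the upper tail is ever called up-regulated downstream.
#'
#' @param pair A `patient_pair` from [read_sample_pairs()] or
#'   [patient_pair()].
#' @return A tibble with columns `gene` and `diff` (tumor minus control,
#'   RSEM units), carrying the patient id as attribute `patient_id`.
#' @export
differential_profile <- function(pair) {
  stopifnot(inherits(pair, "patient_pair"))
  d <- pair$tumor - pair$control
  if (any(!is.finite(d))) ne_abort("non-finite differential value", "validation_error")
  structure(tibble(gene = names(d), diff = unname(d)),
            patient_id = pair$patient_id,
            class = c("diff_profile", class(tibble())))
}

#' Frequency histogram of differential expression
#'
#' Bins a differential profile into `n_bins` equal-width bins spanning
#' `[min, max]`, computes relative frequencies \eqn{y_i} and the transform
#' \eqn{y'_i = \log_{10}(y_i + 1)} that compresses the sharp central peak
#' before Gaussian fitting. Empty bins transform to exactly 0.
#'
#' @param profile A `diff_profile` tibble from [differential_profile()].
#' @param n_bins Number of equal-width bins (default 100, minimum 10).
#' @return A tibble with columns `bin_center`, `rel_freq`, `transformed`,
#'   carrying the raw differential values as attribute `values` (used for
#'   the non-convergence fallback) and the patient id.
#' @export
build_histogram <- function(profile, n_bins = 100) {
  vals <- profile$diff
  if (n_bins < 10) ne_abort("n_bins must be at least 10", "precondition_error")
  rng <- range(vals)
  if (length(unique(vals)) < 2 || diff(rng) == 0) {
    ne_abort("degenerate distribution: fewer than 2 distinct differential values",
             "degenerate_error")
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(vals, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE),
                     nbins = n_bins)
  rel <- counts / length(vals)
  structure(
    tibble(bin_center = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
           rel_freq = rel,
           transformed = log10(rel + 1)),
    values = vals,
    patient_id = attr(profile, "patient_id"),
    class = c("de_histogram", class(tibble()))
  )
}

#' Fit a Gaussian bulk and derive the one-tail up-regulation threshold
#'
#' Least-squares fit of \eqn{A \exp(-(x-\mu)^2 / 2\sigma^2)} to the
#' transformed frequencies of a differential-expression histogram
#' (Levenberg-Marquardt). The up-regulation cut is the upper one-tail
#' quantile of the fitted bulk on the differential-expression axis,
#' \eqn{\mu + \sigma\,z_{1-\alpha}}, so that genes above it have bulk
#' tail mass (one-tail p) at most `alpha`. If the optimizer fails the
#' threshold falls back to the empirical `1 - alpha` quantile of the raw
#' differential values and the fit is flagged unconverged.
#'
#' @param hist A `de_histogram` from [build_histogram()].
#' @param alpha One-tail significance level in (0, 0.5); default 0.05.
#' @return A `gaussian_fit` object: list with `mu`, `sigma`, `amplitude`,
#'   `threshold`, `alpha`, `converged`.
#' @export
fit_gaussian_threshold <- function(hist, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 0.5)) {
    ne_abort("alpha must lie strictly between 0 and 0.5", "precondition_error")
  }
  if (sum(hist$rel_freq > 0) < 4) {
    ne_abort("fewer than 4 non-empty bins: cannot fit a Gaussian bulk", "fit_error")
  }
  vals <- attr(hist, "values")
  x <- hist$bin_center
  y <- hist$transformed
  mu0 <- x[which.max(y)]
  sigma0 <- max(stats::IQR(vals) / 2, diff(range(x)) / length(x))
  a0 <- max(y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a * exp(-(x - mu)^2 / (2 * s^2)),
      start = list(a = a0, mu = mu0, s = sigma0),
      control = minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                           maxfev = 10000, maxiter = 1000)
    ),
    error = function(e) NULL
  )
  ok <- !is.null(fit) && isTRUE(coef(fit)[["s"]] > 0) && isTRUE(coef(fit)[["a"]] > 0)
  if (ok) {
    cf <- coef(fit)
    sigma <- abs(cf[["s"]])
    out <- list(mu = cf[["mu"]], sigma = sigma, amplitude = cf[["a"]],
                threshold = cf[["mu"]] + sigma * qnorm(1 - alpha),
                alpha = alpha, converged = TRUE)
  } else {
    out <- list(mu = NA_real_, sigma = NA_real_, amplitude = NA_real_,
                threshold = unname(quantile(vals, 1 - alpha, type = 7)),
                alpha = alpha, converged = FALSE)
  }
  structure(out, patient_id = attr(hist, "patient_id"), class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mu=%.4g sigma=%.4g threshold=%.4g (alpha=%g, %s)\n",
              x$mu, x$sigma, x$threshold, x$alpha,
              if (x$converged) "converged" else "fallback quantile"))
  invisible(x)
}

#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble(term = c("mu", "sigma", "amplitude", "threshold"),
         estimate = c(x$mu, x$sigma, x$amplitude, x$threshold))
}

#' Select up-regulated genes above the fitted one-tail threshold
#'
#' A gene is called up-regulated when its differential expression strictly
#' exceeds the fit threshold. Called genes are mapped to protein accessions
#' through the symbol-accession map; genes without a mapping are dropped
#' with an informative count (they cannot take part in the PPI subnetwork).
#'
#' @param profile The `diff_profile` the fit was built from.
#' @param fit A `gaussian_fit` from [fit_gaussian_threshold()].
#' @param map A mapping tibble (`symbol`, `accession`) from
#'   [read_id_mapping()], or `NULL` to skip protein mapping.
#' @return An `upregulated_set`: list with `patient_id`, `genes` (character)
#'   and `proteins` (character, possibly shorter than `genes`).
#' @export
select_upregulated <- function(profile, fit, map = NULL) {
  stopifnot(inherits(fit, "gaussian_fit"))
  genes <- profile$gene[profile$diff > fit$threshold]
  proteins <- character(0)
  if (!is.null(map) && length(genes) > 0) {
    acc <- map$accession[match(genes, map$symbol)]
    n_unmapped <- sum(is.na(acc))
    if (n_unmapped > 0) {
      inform(sprintf("select_upregulated: %d up-regulated gene(s) without accession dropped",
                     n_unmapped))
    }
    proteins <- unique(acc[!is.na(acc)])
  }
  structure(list(patient_id = attr(profile, "patient_id"),
                 genes = genes, proteins = proteins),
            class = "upregulated_set")
}

#' @export
print.upregulated_set <- function(x, ...) {
  cat(sprintf("<upregulated_set> %s: %d genes, %d mapped proteins\n",
              x$patient_id %||% "?", length(x$genes), length(x$proteins)))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.de_histogram <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_center, y = .data$transformed)) +
    ggplot2::geom_col(width = diff(object$bin_center[1:2]), fill = "grey70") +
    ggplot2::labs(x = "differential expression (tumor - control)",
                  y = expression(log[10](y[i] + 1))) +
    ggplot2::theme_minimal()
  if (!is.null(fit) && isTRUE(fit$converged)) {
    xs <- seq(min(object$bin_center), max(object$bin_center), length.out = 200)
    curve <- tibble(x = xs, y = fit$amplitude * exp(-(xs - fit$mu)^2 / (2 * fit$sigma^2)))
    p <- p +
      ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$x, y = .data$y),
                         color = "firebrick") +
      ggplot2::geom_vline(xintercept = fit$threshold, linetype = 2)
  }
  p
}
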