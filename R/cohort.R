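#' Healthy reference model of normalized peak expiratory flow
#'
#' Fits a least-squares polynomial of `pef_norm` on `tv_norm` to pooled
#' endpoints from healthy subjects, together with the lower limit of the
#' pointwise two-sided prediction interval at the requested confidence
#' level (default 99 percent). Endpoints of any subject falling below this
#' lower bound are classified as functioning below the healthy reference.
#'
#' @param healthy_metrics pooled endpoint metrics of healthy subjects (rows
#'   with non-finite `pef_norm` or `tv_norm` are dropped)
#' @param degree polynomial degree (default 2)
#' @param level confidence level of the two-sided prediction interval
#' @return an object of class `cohort_model`: coefficients, residual scale
#'   `sigma`, coefficient covariance, residual df, `level`, `degree`, `n`
#' @export
fit_reference <- function(healthy_metrics, degree = 2, level = 0.99) {
  d <- healthy_metrics[is.finite(healthy_metrics$pef_norm) &
                         is.finite(healthy_metrics$tv_norm), ]
  if (nrow(d) < degree + 2) stop("not enough healthy endpoints to fit")
  if (diff(range(d$tv_norm)) < .Machine$double.eps^0.5)
    stop("degenerate design: all tv_norm equal")
  fit <- stats::lm(pef_norm ~ poly(tv_norm, degree, raw = TRUE), data = d)
  structure(list(coefficients = unname(stats::coef(fit)),
                 sigma = summary(fit)$sigma,
                 vcov = unname(stats::vcov(fit)),
                 df = fit$df.residual,
                 level = level, degree = degree, n = nrow(d)),
            class = "cohort_model")
}

#' @export
print.cohort_model <- function(x, ...) {
  cat(sprintf("Healthy reference: degree-%d polynomial on %d endpoints (%.0f%% prediction band)\n",
              x$degree, x$n, 100 * x$level))
  cat("coefficients:", signif(x$coefficients, 4), "\n")
  invisible(x)
}

model_design <- function(model, tv_norm) {
  vapply(0:model$degree, function(p) tv_norm^p, numeric(length(tv_norm)))
}

#' Predict the healthy reference and its lower bound
#'
#' @param object a `cohort_model`
#' @param tv_norm normalized tidal volume values
#' @param ... unused
#' @return data frame with `fit` and `lower` (lower prediction limit)
#' @export
predict.cohort_model <- function(object, tv_norm, ...) {
  X <- matrix(model_design(object, tv_norm), ncol = object$degree + 1)
  fit <- drop(X %*% object$coefficients)
  se_pred <- sqrt(object$sigma^2 + rowSums((X %*% object$vcov) * X))
  tq <- stats::qt(1 - (1 - object$level) / 2, object$df)
  data.frame(fit = fit, lower = fit - tq * se_pred)
}

#' Lung Disease Index
#'
#' The percentage of total lung volume supplied by endpoints whose
#' normalized peak expiratory flow falls below the healthy reference's
#' lower prediction bound at their normalized tidal volume. Non-ventilated
#' endpoints (zero tidal volume, e.g. fully obstructed regions) count as
#' below the bound - a blocked region is maximally dysfunctional.
#'
#' @param metrics endpoint metrics table of one subject (needs `pef_norm`,
#'   `tv_norm`, `v_ee`, `nonventilated`)
#' @param model a `cohort_model` from [fit_reference()]
#' @return LDI in percent (0 to 100)
#' @export
lung_disease_index <- function(metrics, model) {
  v <- metrics$v_ee
  if (!sum(v) || !is.finite(sum(v))) stop("total supplied volume is zero")
  below <- metrics$nonventilated | metrics$missing
  has <- !below & is.finite(metrics$pef_norm) & is.finite(metrics$tv_norm)
  if (any(has)) {
    pr <- predict(model, metrics$tv_norm[has])
    below[has] <- metrics$pef_norm[has] < pr$lower
  }
  100 * sum(v[below]) / sum(v)
}

#' Distribution statistics of endpoint expiratory time constants
#'
#' Sample median, standard deviation (n-1), mean, and a histogram on fixed
#' bins covering `(0, t_exp]`.
#'
#' @param tau_values endpoint time constants (s); non-finite values dropped
#' @param bin_width histogram bin width (s)
#' @param t_exp upper end of the binning range (s)
#' @return list with `median`, `sd`, `mean`, `n`, `breaks`, `counts`
#' @export
distribution_stats <- function(tau_values, bin_width = 0.02, t_exp = 0.3) {
  x <- tau_values[is.finite(tau_values)]
  if (length(x) < 2) stop("need at least 2 finite time constants")
  breaks <- seq(0, t_exp + bin_width * 0.999, by = bin_width)
  if (breaks[length(breaks)] < t_exp) breaks <- c(breaks, t_exp)
  counts <- tabulate(findInterval(pmin(x, t_exp), breaks,
                                  left.open = TRUE, rightmost.closed = TRUE),
                     length(breaks) - 1)
  list(median = stats::median(x), sd = stats::sd(x), mean = mean(x),
       n = length(x), breaks = breaks, counts = counts)
}

#' Phenotype clustering of subjects by time-constant distribution
#'
#' Subjects are represented by the (median, sd) of their endpoint
#' expiratory time constants. Point P is the population mean of the
#' medians and of the sds; each subject's phenotype angle is the
#' four-quadrant arctangent of its offset from P. Subjects are partitioned
#' by k-means (default k = 4, 20 seeded restarts, best inertia kept) in
#' the (median, sd) plane.
#'
#' @param summaries data frame with columns `median_tau` and `sd_tau`
#'   (one row per subject)
#' @param k number of clusters
#' @param seed integer seed for the k-means restarts
#' @return an object of class `cluster_result`: `p` (point P), `angles`
#'   (radians, in (-pi, pi]), `labels` (1..k), `centers`, `k`, `seed`,
#'   `inertia`
#' @export
cluster_phenotypes <- function(summaries, k = 4, seed = 1L) {
  xy <- cbind(summaries$median_tau, summaries$sd_tau)
  if (nrow(xy) < k) stop("need at least k subjects to form k clusters")
  p <- colMeans(xy)
  angles <- atan2(xy[, 2] - p[2], xy[, 1] - p[1])
  km <- with_seed(seed, stats::kmeans(xy, centers = k, nstart = 20,
                                      iter.max = 100))
  structure(list(p = p, angles = angles, labels = km$cluster,
                 centers = km$centers, k = k, seed = as.integer(seed),
                 inertia = km$tot.withinss),
            class = "cluster_result")
}

#' Compare two groups with an unpaired two-tailed t-test
#'
#' Pooled-variance Student t-test by default (Welch as option), as used for
#' comparing airway resistance, average expiratory time constants and
#' disease indices between groups; significance is conventionally assessed
#' at p < 0.05.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2)
#' @param var_equal pooled variance (TRUE, default) or Welch
#' @return list with `t`, `df`, `p`
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  stopifnot(length(values_a) >= 2, length(values_b) >= 2)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b))
      return(list(t = 0, df = length(values_a) + length(values_b) - 2, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Serialize / read a cohort model as structured text
#'
#' @param model a `cohort_model`
#' @param path file path
#' @return `read_cohort_model` returns a `cohort_model`
#' @export
write_cohort_model <- function(model, path) {
  yaml::write_yaml(list(degree = model$degree,
                        coefficients = model$coefficients,
                        sigma = model$sigma,
                        vcov = as.vector(model$vcov),
                        df = model$df,
                        level = model$level,
                        n = model$n), path)
  invisible(path)
}

#' @rdname write_cohort_model
#' @export
read_cohort_model <- function(path) {
  y <- yaml::read_yaml(path)
  structure(list(coefficients = as.numeric(y$coefficients),
                 sigma = y$sigma,
                 vcov = matrix(as.numeric(y$vcov), y$degree + 1, y$degree + 1),
                 df = y$df, level = y$level, degree = y$degree, n = y$n),
            class = "cohort_model")
}
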