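#' Field observations of soil loss in the Kubuqi Desert
#'
#' The ten measured-versus-predicted soil-loss pairs (kg/m^2) collected at
#' four mobile-dune and six farmland sites in the Kubuqi Desert (April-May
#' field campaign), shipped as a plain CSV and used to exercise the model
#' validation workflow.
#'
#' @return Data frame with columns `site_id`, `site_type`
#'   (`mobile_dune`/`farmland`), `lon`, `lat`, `measured`, `predicted`.
#' @export
kubuqi_observations <- function() {
  path <- system.file("extdata", "kubuqi_field_observations.csv",
                      package = "windeps", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Classify predictions against a relative accuracy band
#'
#' A prediction is accurate when it lies within `tol` (default +/-50%) of
#' the measurement, inclusive at the band edges; above the band it is an
#' overestimate, below an underestimate. Measurements of exactly zero have
#' no relative band; they are classified by absolute equality and flagged
#' with a warning.
#'
#' @param pairs Data frame with columns `measured` and `predicted`
#'   (both >= 0).
#' @param tol Band half-width as a fraction of the measurement.
#' @return List with counts `n_accurate`, `n_over`, `n_under` and a
#'   `class` vector (`"accurate"`/`"over"`/`"under"`) aligned with `pairs`.
#' @export
accuracy_classify <- function(pairs, tol = 0.5) {
  stopifnot(is.data.frame(pairs),
            all(c("measured", "predicted") %in% names(pairs)))
  m <- pairs$measured; p <- pairs$predicted
  if (any(m < 0) || any(p < 0)) stop("soil losses must be >= 0")
  cls <- character(length(m))
  zero <- m == 0
  if (any(zero)) {
    warning("measured value of 0 has no relative band; classified by equality")
    cls[zero] <- ifelse(p[zero] == 0, "accurate",
                        ifelse(p[zero] > 0, "over", "under"))
  }
  nz <- !zero
  lowr <- m[nz] * (1 - tol); uppr <- m[nz] * (1 + tol)
  cls[nz] <- ifelse(p[nz] > uppr, "over",
                    ifelse(p[nz] < lowr, "under", "accurate"))
  list(n_accurate = sum(cls == "accurate"),
       n_over = sum(cls == "over"),
       n_under = sum(cls == "under"),
       class = cls)
}

#' Ordinary least-squares calibration line
#'
#' Fits predicted soil loss on measured soil loss (y on x) with
#' `stats::lm`, the orientation used for the per-site-type calibration
#' lines.
#'
#' @param x,y Numeric vectors of equal length >= 2; `x` must vary.
#' @return List with `slope` and `intercept`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 2) stop("need at least 2 points")
  if (stats::sd(x) == 0) stop("singular fit: x is constant")
  co <- stats::coef(stats::lm(y ~ x))
  list(slope = unname(co[2]), intercept = unname(co[1]))
}

#' Coefficient of determination
#'
#' Squared Pearson correlation between `x` and `y`, equal to the OLS
#' coefficient of determination for a simple linear fit.
#'
#' @param x,y Numeric vectors with nonzero variance.
#' @return R^2 in \[0, 1\].
#' @export
r_squared <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined R^2: zero variance")
  stats::cor(x, y)^2
}

#' Root-mean-square error
#'
#' @param a,b Numeric vectors of equal length >= 1.
#' @return sqrt(mean((a - b)^2)), in the units of the inputs.
#' @export
rmse <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) == 0) stop("empty vectors")
  sqrt(mean((a - b)^2))
}

#' Model-validation report over an observation table
#'
#' Classifies all pairs against the relative accuracy band, then fits the
#' calibration line and computes R^2 and RMSE within each site type. Groups
#' with too few points (or constant measurements) skip the fit with a
#' warning.
#'
#' @param pairs Observation data frame as from [kubuqi_observations()]:
#'   columns `site_type`, `measured`, `predicted` (others carried through).
#' @param tol Accuracy band half-width (fraction), default 0.5.
#' @return List of class `validation_summary`: `counts`
#'   (n_accurate/n_over/n_under over the pooled set), `groups` (data frame
#'   per site type: n, slope, intercept, r2, rmse), `class` per-pair labels.
#' @export
validation_report <- function(pairs, tol = 0.5) {
  stopifnot("site_type" %in% names(pairs))
  cls <- accuracy_classify(pairs, tol = tol)
  groups <- do.call(rbind, lapply(split(pairs, pairs$site_type), function(g) {
    fit <- tryCatch(ols_fit(g$measured, g$predicted), error = function(e) NULL)
    if (is.null(fit)) {
      warning("skipping fit for group '", g$site_type[1],
              "' (too few points or constant x)")
      data.frame(site_type = g$site_type[1], n = nrow(g),
                 slope = NA_real_, intercept = NA_real_,
                 r2 = NA_real_, rmse = rmse(g$measured, g$predicted))
    } else {
      data.frame(site_type = g$site_type[1], n = nrow(g),
                 slope = fit$slope, intercept = fit$intercept,
                 r2 = r_squared(g$measured, g$predicted),
                 rmse = rmse(g$measured, g$predicted))
    }
  }))
  rownames(groups) <- NULL
  structure(list(counts = cls[c("n_accurate", "n_over", "n_under")],
                 groups = groups, class = cls$class, tol = tol),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat(sprintf("validation: %d accurate, %d overestimated, %d underestimated (+/-%.0f%% band)\n",
              x$counts$n_accurate, x$counts$n_over, x$counts$n_under,
              100 * x$tol))
  print(x$groups, digits = 4)
  invisible(x)
}
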