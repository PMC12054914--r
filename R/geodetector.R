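#' Discretize a continuous layer into strata
#'
#' Geographical-detector factors must be categorical, so continuous driver
#' layers are cut into `k` classes first. Quantile cuts (default) give
#' near-equal class sizes; equal-interval cuts split the range evenly;
#' natural breaks minimises within-class variance with a deterministic 1-D
#' k-means (centres initialised at evenly spaced quantiles) — the usual
#' Jenks-style approximation. Already-categorical layers pass through
#' unchanged via [as_strata()].
#'
#' @param layer Numeric vector or matrix.
#' @param method `"quantile"`, `"equal_interval"` or `"natural_breaks"`.
#' @param k Number of classes (>= 2).
#' @param source Driver name recorded on the strata.
#' @return A list of class `strata_map`: `labels` (integer classes, same
#'   shape as `layer`, dense codes 1..k), `k`, `breaks`, `method`, `source`.
#' @export
discretize <- function(layer, method = c("quantile", "equal_interval",
                                         "natural_breaks"), k = 10,
                       source = "layer") {
  method <- match.arg(method)
  if (k < 2) stop("k must be >= 2")
  v <- as.vector(layer)
  obs <- v[!is.na(v)]
  if (length(unique(obs)) < 2) stop("degenerate strata: layer is constant")
  if (length(unique(obs)) < k) {
    warning(sprintf("only %d distinct values; reducing k from %d",
                    length(unique(obs)), k))
    k <- length(unique(obs))
  }
  breaks <- switch(method,
    quantile = {
      b <- unique(stats::quantile(obs, probs = seq(0, 1, length.out = k + 1),
                                  names = FALSE))
      if (length(b) < 3) stop("degenerate strata: quantile breaks collapse")
      b
    },
    equal_interval = seq(min(obs), max(obs), length.out = k + 1),
    natural_breaks = jenks_breaks(obs, k)
  )
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  cut_codes <- as.integer(cut(v, breaks = breaks, labels = FALSE,
                              include.lowest = TRUE))
  labels <- layer
  labels[] <- cut_codes
  # re-densify in case a class came out empty
  used <- sort(unique(cut_codes[!is.na(cut_codes)]))
  labels[] <- match(cut_codes, used)
  structure(list(labels = labels, k = length(used), breaks = breaks,
                 method = method, source = source),
            class = "strata_map")
}

# deterministic 1-D k-means (Lloyd) initialised at evenly spaced quantiles;
# returns k+1 breakpoints at the midpoints between adjacent class extremes
jenks_breaks <- function(x, k) {
  x <- sort(x)
  centers <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  for (it in 1:100) {
    assign <- apply(abs(outer(x, centers, "-")), 1, which.min)
    new_centers <- vapply(seq_len(k), function(j) {
      xi <- x[assign == j]
      if (length(xi)) mean(xi) else centers[j]
    }, numeric(1))
    if (max(abs(new_centers - centers)) < 1e-12) break
    centers <- new_centers
  }
  edges <- vapply(seq_len(k - 1), function(j) {
    hi <- max(x[assign == j]); lo <- min(x[assign > j])
    (hi + lo) / 2
  }, numeric(1))
  c(min(x), edges, max(x))
}

#' Wrap a categorical layer as strata without re-cutting
#'
#' @param layer Integer class-code vector or matrix.
#' @param source Driver name recorded on the strata.
#' @return A `strata_map` with the codes remapped to dense 1..k.
#' @export
as_strata <- function(layer, source = "categorical") {
  v <- as.vector(layer)
  codes <- sort(unique(v[!is.na(v)]))
  labels <- layer
  labels[] <- match(v, codes)
  structure(list(labels = labels, k = length(codes), breaks = NULL,
                 method = "categorical", source = source),
            class = "strata_map")
}

strata_vector <- function(strata) {
  if (inherits(strata, "strata_map")) as.vector(strata$labels)
  else as.vector(strata)
}

#' Geodetector q statistic
#'
#' q = 1 - SSW/SST = 1 - sum_h N_h sigma_h^2 / (N sigma^2): the share of the
#' response's spatial variance explained by a stratification. Population
#' (divide-by-N) variances are used so SSW/SST telescopes exactly and
#' q stays in \[0, 1\] even for tiny strata.
#'
#' @param Y Numeric response vector (or matrix, flattened).
#' @param strata A `strata_map` or an integer/factor class vector aligned
#'   with `Y`. Cells where either is `NA` are dropped.
#' @return q in \[0, 1\].
#' @export
q_statistic <- function(Y, strata) {
  y <- as.vector(Y)
  s <- strata_vector(strata)
  if (length(y) != length(s)) stop("Y and strata lengths differ")
  ok <- !is.na(y) & !is.na(s)
  y <- y[ok]; s <- s[ok]
  if (length(y) < 2) stop("need at least 2 samples")
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("undefined q: total variance is zero")
  ssw <- sum(vapply(split(y, s), function(v) sum((v - mean(v))^2), numeric(1)))
  1 - ssw / sst
}

# within-strata sum of squares (population scale x N), shared by q and the
# ecological detector
ssw_sst <- function(y, s) {
  sst <- sum((y - mean(y))^2)
  ssw <- sum(vapply(split(y, s), function(v) sum((v - mean(v))^2), numeric(1)))
  list(ssw = ssw, sst = sst, n = length(y))
}

#' Interaction detector
#'
#' q of the cross-classification of two stratifications, with the joint
#' effect categorised against the marginal q values: below both weakens
#' nonlinearly, between them weakens one factor, above both but below their
#' sum enhances bivariately, equal to the sum (within tolerance) is
#' independence, and above the sum is nonlinear enhancement.
#'
#' @param Y Response vector.
#' @param strataA,strataB Stratifications aligned with `Y`.
#' @param tol Equality tolerance for the independence category.
#' @return List with `q1`, `q2`, `q12` and `category`.
#' @export
interaction_detector <- function(Y, strataA, strataB, tol = 1e-9) {
  a <- strata_vector(strataA); b <- strata_vector(strataB)
  y <- as.vector(Y)
  if (length(a) != length(y) || length(b) != length(y))
    stop("Y and strata must be aligned")
  cross <- interaction(factor(a), factor(b), drop = TRUE)
  q1 <- q_statistic(y, a)
  q2 <- q_statistic(y, b)
  q12 <- q_statistic(y, as.integer(cross))
  lo <- min(q1, q2); hi <- max(q1, q2); s <- q1 + q2
  category <-
    if (abs(q12 - s) < tol) "independent"
    else if (q12 > s) "nonlinear-enhance"
    else if (q12 > hi) "bivariate-enhance"
    else if (q12 >= lo) "univariate-weaken"
    else "nonlinear-weaken"
  list(q1 = q1, q2 = q2, q12 = q12, category = category)
}

#' Risk detector
#'
#' Stratum means of the response plus pairwise Welch two-sample t tests
#' (unequal variances, Welch-Satterthwaite degrees of freedom) of whether
#' two strata differ in mean. Strata with fewer than 2 samples are excluded
#' with a warning; pairs where both strata are exactly constant are decided
#' by mean equality.
#'
#' @param Y Response vector.
#' @param strata Stratification aligned with `Y`.
#' @param alpha Significance level, default 0.05.
#' @return List with `means` (data frame: stratum, n, mean) and `pairs`
#'   (data frame: stratum_a, stratum_b, t, p, significant).
#' @export
risk_detector <- function(Y, strata, alpha = 0.05) {
  y <- as.vector(Y); s <- strata_vector(strata)
  ok <- !is.na(y) & !is.na(s)
  y <- y[ok]; s <- s[ok]
  groups <- split(y, s)
  small <- names(groups)[vapply(groups, length, integer(1)) < 2]
  if (length(small)) {
    warning("excluding strata with < 2 samples: ", paste(small, collapse = ", "))
    groups <- groups[!names(groups) %in% small]
  }
  if (length(groups) < 2) stop("need >= 2 usable strata")
  means <- data.frame(
    stratum = names(groups),
    n = vapply(groups, length, integer(1)),
    mean = vapply(groups, mean, numeric(1)),
    row.names = NULL
  )
  cmb <- utils::combn(names(groups), 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
    ga <- groups[[cmb[1, i]]]; gb <- groups[[cmb[2, i]]]
    res <- tryCatch(stats::t.test(ga, gb, var.equal = FALSE),
                    error = function(e) NULL)
    if (is.null(res)) {
      # both essentially constant: significant iff the means differ
      sig <- !isTRUE(all.equal(mean(ga), mean(gb)))
      data.frame(stratum_a = cmb[1, i], stratum_b = cmb[2, i],
                 t = if (sig) Inf else 0, p = if (sig) 0 else 1,
                 significant = sig)
    } else {
      data.frame(stratum_a = cmb[1, i], stratum_b = cmb[2, i],
                 t = unname(res$statistic), p = res$p.value,
                 significant = res$p.value < alpha)
    }
  }))
  list(means = means, pairs = pairs, alpha = alpha)
}

#' Ecological detector
#'
#' F-ratio comparison of the within-strata variance sums of two factors:
#' F = \[N1 (N2 - 1) SSW1\] / \[N2 (N1 - 1) SSW2\], referred to the F
#' distribution with (N1 - 1, N2 - 1) degrees of freedom. The test is
#' two-sided at level `alpha`: either factor absorbing significantly more
#' variance than the other (F far from 1 in either direction) counts as a
#' significant difference.
#'
#' @param Y Response vector.
#' @param strataA,strataB Stratifications aligned with `Y`.
#' @param alpha Significance level, default 0.05.
#' @return List with `F`, `df`, `significant` (TRUE = the two factors
#'   differ, the "Y" cell of a significance table).
#' @export
ecological_detector <- function(Y, strataA, strataB, alpha = 0.05) {
  y <- as.vector(Y)
  a <- strata_vector(strataA); b <- strata_vector(strataB)
  ok <- !is.na(y) & !is.na(a) & !is.na(b)
  da <- ssw_sst(y[ok], a[ok])
  db <- ssw_sst(y[ok], b[ok])
  if (db$ssw <= 0 && da$ssw <= 0)
    stop("undefined ecological F: both within-strata variance sums are zero")
  n1 <- da$n; n2 <- db$n
  Fval <- if (db$ssw <= 0) Inf
          else (n1 * (n2 - 1) * da$ssw) / (n2 * (n1 - 1) * db$ssw)
  crit_lo <- stats::qf(alpha / 2, n1 - 1, n2 - 1)
  crit_hi <- stats::qf(1 - alpha / 2, n1 - 1, n2 - 1)
  list(F = Fval, df = c(n1 - 1, n2 - 1),
       significant = (Fval < crit_lo) || (Fval > crit_hi))
}

#' Rank drivers by explanatory power
#'
#' @param q_by_factor Named numeric vector or data frame with columns
#'   `factor` and `q`.
#' @return Data frame (`factor`, `q`, `rank`) sorted by descending q with
#'   dense ranks; tied q values share a rank.
#' @export
rank_factors <- function(q_by_factor) {
  if (is.data.frame(q_by_factor)) {
    fac <- q_by_factor$factor; q <- q_by_factor$q
  } else {
    fac <- names(q_by_factor); q <- unname(q_by_factor)
  }
  if (length(q) < 1) stop("need at least one factor")
  ord <- order(-q)
  qo <- q[ord]
  rk <- match(qo, sort(unique(qo), decreasing = TRUE))  # dense, ties share
  data.frame(factor = fac[ord], q = qo, rank = rk, row.names = NULL)
}

#' Run the full detector suite over a set of driver layers
#'
#' Factor detector (q per driver, ranked), interaction detector on every
#' driver pair, ecological detector significance table and per-driver risk
#' tables, mirroring the usual geodetector report layout.
#'
#' @param Y Response vector or matrix (e.g. an actual-erosion raster).
#' @param drivers Named list of `strata_map` objects (or class vectors)
#'   aligned with `Y`.
#' @param alpha Significance level for the risk and ecological detectors.
#' @return List of class `detector_report`: `q_table`, `interaction`
#'   (data frame of pairs), `interaction_q` (symmetric matrix),
#'   `ecological` (logical matrix), `risk` (list of per-driver tables).
#' @export
detector_report <- function(Y, drivers, alpha = 0.05) {
  stopifnot(length(drivers) >= 1, !is.null(names(drivers)))
  qs <- vapply(drivers, function(s) q_statistic(Y, s), numeric(1))
  q_table <- rank_factors(qs)
  nm <- names(drivers)
  n <- length(nm)
  qmat <- matrix(NA_real_, n, n, dimnames = list(nm, nm))
  diag(qmat) <- qs[nm]
  eco <- matrix(NA, n, n, dimnames = list(nm, nm))
  inter <- list()
  if (n >= 2) {
    cmb <- utils::combn(n, 2)
    inter <- lapply(seq_len(ncol(cmb)), function(i) {
      a <- cmb[1, i]; b <- cmb[2, i]
      it <- interaction_detector(Y, drivers[[a]], drivers[[b]])
      ec <- ecological_detector(Y, drivers[[a]], drivers[[b]], alpha = alpha)
      qmat[a, b] <<- it$q12; qmat[b, a] <<- it$q12
      eco[a, b] <<- ec$significant; eco[b, a] <<- ec$significant
      data.frame(factor_a = nm[a], factor_b = nm[b],
                 q1 = it$q1, q2 = it$q2, q12 = it$q12,
                 category = it$category,
                 ecological_significant = ec$significant)
    })
    inter <- do.call(rbind, inter)
  } else {
    inter <- data.frame()
  }
  risk <- lapply(drivers, function(s)
    tryCatch(risk_detector(Y, s, alpha = alpha), warning = function(w)
      suppressWarnings(risk_detector(Y, s, alpha = alpha))))
  structure(list(q_table = q_table, interaction = inter,
                 interaction_q = qmat, ecological = eco, risk = risk,
                 alpha = alpha),
            class = "detector_report")
}
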