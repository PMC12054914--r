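#' Critical field length
#'
#' s = 150.71 (WF EF SCF K' C)^-0.3711, the downwind distance over which
#' transport approaches its capacity. With `C = 1` (bare surface) the same
#' expression gives the potential-case length `sr`. The exponent applies to
#' the whole factor product: applying it to the last factor alone would
#' decouple the field length from climate, contradicting the transport
#' equation it feeds.
#'
#' @param WF Weather factor (kg/m).
#' @param EF,SCF,Kprime,C Dimensionless factors; `C = 1` for the potential
#'   (vegetation-free) case.
#' @return Critical field length (m); `NA` where the factor product is not
#'   positive.
#' @export
critical_field_length <- function(WF, EF, SCF, Kprime, C = 1) {
  p <- WF * EF * SCF * Kprime * C
  out <- ifelse(!is.na(p) & p > 0, 150.71 * p^(-0.3711), NA_real_)
  if (length(p) == 1 && !is.na(p) && p <= 0)
    stop("factor product must be > 0 for a finite critical field length")
  out
}

#' Maximum sand transport capacity
#'
#' Qmax = 109.8 WF EF SCF K' C (kg/m of field width), linear in every
#' factor; `C = 1` gives the potential-case capacity.
#'
#' @inheritParams critical_field_length
#' @return Transport capacity (kg/m, >= 0).
#' @export
max_transport <- function(WF, EF, SCF, Kprime, C = 1) {
  for (v in list(WF, EF, SCF, Kprime, C))
    if (any(v < 0, na.rm = TRUE)) stop("factors must be >= 0")
  109.8 * WF * EF * SCF * Kprime * C
}

#' Soil loss from transport capacity and field length
#'
#' flux = (2 z / s^2) Qmax exp(-(z/s)^2), the per-unit-area soil loss at
#' downwind distance `z` given capacity `Qmax` and critical field length
#' `s`. Evaluated with the potential-case (Qrmax, sr) it gives SLR, with the
#' actual-case (Qmax, S) it gives SL.
#'
#' @param Qmax Transport capacity (kg/m, >= 0).
#' @param s Critical field length (m, > 0).
#' @param z Downwind distance of maximum erosion (m, > 0).
#' @return Soil loss (kg/m^2).
#' @export
erosion_flux <- function(Qmax, s, z = 50) {
  if (any(z <= 0)) stop("z must be > 0")
  if (any(s <= 0, na.rm = TRUE) && length(s) == 1) stop("s must be > 0")
  out <- (2 * z / s^2) * Qmax * exp(-(z / s)^2)
  out[!is.na(s) & s <= 0] <- NA_real_
  out
}

#' Potential and actual erosion, WEPS and retention for a factor stack
#'
#' Chains the RWEQ: potential erosion SLR with the vegetation factor absent
#' (C = 1), actual erosion SL with the stack's C, the prevention service
#' WEPS = SLR - SL and the retention rate F = WEPS/SLR * 100. Cells with a
#' zero factor product (no erosive climate) have zero capacity and zero
#' flux; F is nodata where SLR = 0.
#'
#' @param stack A `factor_stack` from [build_factor_stack()].
#' @param z Downwind distance of maximum erosion (m), default 50.
#' @param year Optional label carried on the result.
#' @return List of class `erosion_fields` with matrices `SLR`, `SL`, `WEPS`,
#'   `F` and the `grid`.
#' @export
erosion_fields <- function(stack, z = 50, year = NA) {
  g <- stack$grid
  prod_r <- stack$WF * stack$EF * stack$SCF * stack$Kprime
  prod_a <- prod_r * stack$C
  slr <- matrix(0, g$nrows, g$ncols)
  sl <- matrix(0, g$nrows, g$ncols)
  pos_r <- !is.na(prod_r) & prod_r > 0
  pos_a <- !is.na(prod_a) & prod_a > 0
  slr[pos_r] <- erosion_flux(109.8 * prod_r[pos_r],
                             150.71 * prod_r[pos_r]^(-0.3711), z)
  sl[pos_a] <- erosion_flux(109.8 * prod_a[pos_a],
                            150.71 * prod_a[pos_a]^(-0.3711), z)
  slr[is.na(prod_r)] <- NA_real_
  sl[is.na(prod_a)] <- NA_real_
  w <- weps(slr, sl)
  structure(list(SLR = slr, SL = sl, WEPS = w,
                 F = retention_rate(w, slr),
                 grid = g, year = year),
            class = "erosion_fields")
}

#' Wind-erosion prevention service
#'
#' WEPS = SLR - SL per cell: the soil retained because vegetation is
#' present.
#'
#' @param SLR,SL Potential and actual erosion matrices (kg/m^2).
#' @param grid_slr,grid_sl Their `grid_spec`s (checked for alignment when
#'   supplied).
#' @return Matrix of WEPS (kg/m^2).
#' @export
weps <- function(SLR, SL, grid_slr = NULL, grid_sl = NULL) {
  if (!is.null(grid_slr) && !is.null(grid_sl))
    check_aligned(grid_slr, grid_sl, "SLR and SL")
  if (!all(dim(SLR) == dim(SL))) stop("SLR and SL dimensions differ")
  SLR - SL
}

#' Retention rate of the prevention service
#'
#' F = WEPS / SLR * 100 (%) where SLR > 0; nodata (NA) where SLR = 0, since
#' a cell with no potential erosion offers nothing to retain.
#'
#' @param WEPS,SLR Matrices (kg/m^2).
#' @param grid_weps,grid_slr Their `grid_spec`s (checked when supplied).
#' @return Matrix of retention rate (%, in \[0, 100\] where defined).
#' @export
retention_rate <- function(WEPS, SLR, grid_weps = NULL, grid_slr = NULL) {
  if (!is.null(grid_weps) && !is.null(grid_slr))
    check_aligned(grid_weps, grid_slr, "WEPS and SLR")
  if (!all(dim(WEPS) == dim(SLR))) stop("WEPS and SLR dimensions differ")
  out <- ifelse(!is.na(SLR) & SLR > 0, WEPS / SLR * 100, NA_real_)
  out
}

#' Regional total of a per-area field
#'
#' Sum of cell value x cell area over all non-nodata cells, converted from
#' kg to tonnes. An all-nodata field totals 0 with a warning.
#'
#' @param field Matrix (kg/m^2).
#' @param grid `grid_spec` providing the cell area.
#' @return Total mass (t).
#' @export
regional_total <- function(field, grid) {
  if (is.null(grid$cellsize) || grid$cellsize <= 0)
    stop("grid has no valid cell size")
  vals <- field[!is.na(field)]
  if (length(vals) == 0) {
    warning("all cells are nodata; regional total is 0")
    return(0)
  }
  sum(vals) * cell_area_m2(grid) / 1000
}

#' Per-cell change between two epochs
#'
#' @param field_t0,field_t1 Aligned matrices.
#' @param grid_t0,grid_t1 Their `grid_spec`s (checked when supplied).
#' @return List with `delta` (t1 - t0 matrix) and `summary` (data frame:
#'   mean change, percent of cells increasing / decreasing / unchanged over
#'   cells defined in both epochs).
#' @export
temporal_change <- function(field_t0, field_t1, grid_t0 = NULL, grid_t1 = NULL) {
  if (!is.null(grid_t0) && !is.null(grid_t1))
    check_aligned(grid_t0, grid_t1, "epoch rasters")
  if (!all(dim(field_t0) == dim(field_t1))) stop("epoch raster dimensions differ")
  delta <- field_t1 - field_t0
  d <- delta[!is.na(delta)]
  n <- length(d)
  summary <- data.frame(
    mean_change = if (n) mean(d) else NA_real_,
    pct_increasing = if (n) 100 * mean(d > 0) else NA_real_,
    pct_decreasing = if (n) 100 * mean(d < 0) else NA_real_,
    pct_unchanged = if (n) 100 * mean(d == 0) else NA_real_
  )
  list(delta = delta, summary = summary)
}

#' Land-cover transition matrix between two epochs
#'
#' Cross-tabulates class membership at t0 against t1 and converts cell
#' counts to areas. Row sums equal the class areas at t0; the grand total is
#' the area defined in both epochs.
#'
#' @param lc_t0,lc_t1 Aligned integer class-code matrices.
#' @param grid `grid_spec` providing the cell area.
#' @param classes Optional vector of allowed class codes; codes outside it
#'   raise an error naming the offenders.
#' @return Square matrix of areas (km^2), rows = t0 class, cols = t1 class.
#' @export
landcover_transition_matrix <- function(lc_t0, lc_t1, grid, classes = NULL) {
  if (!all(dim(lc_t0) == dim(lc_t1))) stop("land-cover raster dimensions differ")
  ok <- !is.na(lc_t0) & !is.na(lc_t1)
  a <- lc_t0[ok]; b <- lc_t1[ok]
  if (!is.null(classes)) {
    bad <- setdiff(unique(c(a, b)), classes)
    if (length(bad))
      stop("unknown land-cover class code(s): ", paste(sort(bad), collapse = ", "))
  } else {
    classes <- sort(unique(c(a, b)))
  }
  fa <- factor(a, levels = classes)
  fb <- factor(b, levels = classes)
  counts <- table(from = fa, to = fb)
  km2 <- cell_area_m2(grid) / 1e6
  m <- unclass(counts) * km2
  attr(m, "units") <- "km2"
  m
}
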