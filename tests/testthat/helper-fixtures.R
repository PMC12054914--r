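# shared fixtures and independent oracles for the suite

# small scene used by most raster tests (kept modest so the suite is quick)
tiny_scene <- function(seed = 1, nrows = 20, ncols = 24, n_stations = 3) {
  generate_scene(nrows, ncols, cellsize_m = 1000, n_stations = n_stations,
                 years = 1, seed = seed)
}

# brute-force q: explicit loop over strata, population variance sums;
# deliberately written without tapply/split so it shares nothing with the
# implementation
q_brute <- function(Y, strata) {
  y <- as.vector(Y); s <- as.vector(strata)
  ok <- !is.na(y) & !is.na(s)
  y <- y[ok]; s <- s[ok]
  n <- length(y)
  gm <- sum(y) / n
  sst <- 0
  for (i in seq_len(n)) sst <- sst + (y[i] - gm)^2
  ssw <- 0
  for (cl in unique(s)) {
    yi <- y[s == cl]
    mi <- sum(yi) / length(yi)
    for (v in yi) ssw <- ssw + (v - mi)^2
  }
  1 - ssw / sst
}

# closed-form simple-regression normal equations
ols_normal_equations <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  list(slope = slope, intercept = (sy - slope * sx) / n)
}

# per-cell scalar-loop erosion chain, the oracle for vectorised raster math
erosion_loop_oracle <- function(stack, z = 50) {
  g <- stack$grid
  slr <- sl <- matrix(NA_real_, g$nrows, g$ncols)
  for (i in seq_len(g$nrows)) for (j in seq_len(g$ncols)) {
    pr <- stack$WF[i, j] * stack$EF[i, j] * stack$SCF[i, j] * stack$Kprime[i, j]
    pa <- pr * stack$C[i, j]
    slr[i, j] <- if (is.na(pr)) NA_real_ else if (pr <= 0) 0 else
      (2 * z / (150.71 * pr^(-0.3711))^2) * (109.8 * pr) *
        exp(-(z / (150.71 * pr^(-0.3711)))^2)
    sl[i, j] <- if (is.na(pa)) NA_real_ else if (pa <= 0) 0 else
      (2 * z / (150.71 * pa^(-0.3711))^2) * (109.8 * pa) *
        exp(-(z / (150.71 * pa^(-0.3711)))^2)
  }
  list(SLR = slr, SL = sl)
}
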