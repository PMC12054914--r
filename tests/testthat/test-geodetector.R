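test_that("quantile discretization yields balanced classes, equal-interval splits the range", {
  s <- discretize(1:10, "quantile", k = 5)
  expect_equal(s$k, 5)
  expect_true(all(table(s$labels) == 2))
  e <- discretize(1:10, "equal_interval", k = 2)
  expect_equal(as.vector(table(e$labels)), c(5, 5))
  expect_equal(e$breaks[2], 5.5)
  expect_error(discretize(rep(1, 10), "quantile", k = 3), "constant")
  expect_warning(discretize(c(1, 1, 2, 2, 3, 3), "quantile", k = 5), "reducing k")
})

test_that("natural-breaks discretization separates well-separated clusters exactly", {
  x <- c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1), rnorm(50, 20, 0.1))
  s <- discretize(x, "natural_breaks", k = 3)
  expect_equal(s$k, 3)
  expect_true(all(table(s$labels, rep(1:3, each = 50)) %in% c(0, 50)))
})

test_that("categorical layers pass through with dense class codes", {
  lc <- matrix(sample(c(3L, 7L, 20L), 40, replace = TRUE), 5, 8)
  s <- as_strata(lc)
  expect_equal(s$k, 3)
  expect_true(all(sort(unique(as.vector(s$labels))) == 1:3))
  # same partition as the original codes
  y <- rnorm(40)
  expect_equal(q_statistic(y, s), q_brute(y, as.vector(lc)), tolerance = 1e-12)
})

test_that("q statistic matches hand-computed variance decompositions", {
  expect_equal(q_statistic(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(q_statistic(c(1, 2, 1, 2), c("a", "a", "b", "b")), 0)
  expect_equal(q_statistic(c(1, 2, 3, 4), rep("a", 4)), 0)
  expect_error(q_statistic(rep(5, 4), c("a", "a", "b", "b")), "total variance")
})

test_that("q equals the brute-force decomposition on random fixtures to 1e-12", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    y <- rnorm(n)
    s <- sample(1:sample(2:5, 1), n, replace = TRUE)
    if (length(unique(s)) < 2) s[1:2] <- 1:2
    expect_equal(q_statistic(y, s), q_brute(y, s), tolerance = 1e-12)
  }
})

test_that("q is invariant to class relabeling and affine response transforms", {
  set.seed(5)
  y <- rnorm(200)
  s <- sample(1:4, 200, replace = TRUE)
  q0 <- q_statistic(y, s)
  perm <- c(3, 1, 4, 2)
  expect_equal(q_statistic(y, perm[s]), q0, tolerance = 1e-12)
  expect_equal(q_statistic(3.7 * y - 12, s), q0, tolerance = 1e-12)
  expect_equal(q_statistic(-0.2 * y + 4, s), q0, tolerance = 1e-12)
})

test_that("refining a partition never lowers q", {
  set.seed(6)
  y <- rnorm(300)
  coarse <- sample(1:3, 300, replace = TRUE)
  fine <- coarse * 10 + sample(1:2, 300, replace = TRUE)  # nested refinement
  expect_gte(q_statistic(y, fine), q_statistic(y, coarse) - 1e-12)
})

test_that("interaction detector reproduces the hand-worked decomposition and categories", {
  Y <- c(0, 1, 1, 3)
  A <- c("a", "a", "b", "b"); B <- c("c", "d", "c", "d")
  it <- interaction_detector(Y, A, B)
  expect_equal(it$q1, 0.47368, tolerance = 1e-4)
  expect_equal(it$q2, 0.47368, tolerance = 1e-4)
  expect_equal(it$q12, 1)
  expect_equal(it$category, "nonlinear-enhance")
  # identical stratifications collapse to the marginal q
  set.seed(2)
  y <- rnorm(100); s <- sample(1:4, 100, replace = TRUE)
  same <- interaction_detector(y, s, s)
  expect_equal(same$q12, same$q1, tolerance = 1e-12)
  # degenerate single-class partner leaves q12 = q1
  one <- rep(1, 100)
  deg <- interaction_detector(y, s, one)
  expect_equal(deg$q12, deg$q1, tolerance = 1e-12)
})

test_that("cross-classification q dominates both marginals on synthetic strata", {
  set.seed(9)
  for (i in 1:10) {
    y <- rnorm(400)
    a <- sample(1:3, 400, replace = TRUE)
    b <- sample(1:4, 400, replace = TRUE)
    it <- interaction_detector(y, a, b)
    expect_gte(it$q12, max(it$q1, it$q2) - 1e-12)
  }
})

test_that("risk detector separates distinct strata and not identical ones", {
  # identical-sample strata: construct explicitly
  y <- rep(c(1, 2, 3), 4)
  rd <- risk_detector(c(y, y), rep(1:2, each = 12))
  expect_false(rd$pairs$significant[1])
  expect_equal(rd$pairs$t[1], 0, tolerance = 1e-12)
  # near-zero variance separation
  y2 <- c(0, 0, 0, 0, 10, 10, 10, 10.0001)
  rd2 <- risk_detector(y2, rep(1:2, each = 4))
  expect_true(rd2$pairs$significant[1])
  # reported max-mean stratum is the argmax of raw means
  set.seed(3)
  y3 <- rnorm(90) + rep(c(0, 2, 5), each = 30)
  rd3 <- risk_detector(y3, rep(1:3, each = 30))
  expect_equal(rd3$means$stratum[which.max(rd3$means$mean)], "3")
  expect_warning(risk_detector(c(1, 2, 3, 4, 9), c(1, 1, 2, 2, 3)), "excluding")
})

test_that("risk detector t matches the standard Welch computation", {
  set.seed(11)
  a <- rnorm(25, 1, 2); b <- rnorm(30, 0, 1)
  rd <- risk_detector(c(a, b), rep(1:2, c(25, 30)))
  ref <- t.test(a, b, var.equal = FALSE)
  expect_equal(rd$pairs$t[1], unname(ref$statistic), tolerance = 1e-12)
  expect_equal(rd$pairs$p[1], ref$p.value, tolerance = 1e-12)
})

test_that("ecological detector flags only genuinely different factors", {
  set.seed(4)
  y <- rnorm(200)
  s <- sample(1:4, 200, replace = TRUE)
  same <- ecological_detector(y, s, s)
  expect_equal(same$F, 1, tolerance = 1e-12)
  expect_false(same$significant)
  # a perfectly explaining factor against a useless one
  strat <- rep(1:4, each = 50)
  y2 <- strat + 0  # zero within-stratum variance under strat
  eco <- ecological_detector(y2, strat, rep(1, 200))
  expect_equal(eco$F, 0)
  expect_true(eco$significant)
})

test_that("planted dominant driver is declared significant against noise strata", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed + 500)
    strat <- sample(1:5, 2000, replace = TRUE)
    y <- plant_driver_response(strat, between_var = 0.37, noise_var = 0.63,
                               seed = seed)
    noise <- sample(1:5, 2000, replace = TRUE)
    eco <- ecological_detector(y, strat, noise)
    if (eco$significant) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("factor ranking is dense-descending with shared ranks on ties", {
  r <- rank_factors(c(A = 0.3, B = 0.1))
  expect_equal(r$factor, c("A", "B"))
  expect_equal(r$rank, c(1, 2))
  r2 <- rank_factors(c(soil = 0.369, fvc = 0.180, pop = 0.019, gdp = 0.019))
  expect_equal(r2$rank, c(1, 2, 3, 3))
  expect_error(rank_factors(numeric(0)), "at least one")
})

test_that("detector report assembles symmetric interaction and ecological tables", {
  set.seed(21)
  y <- rnorm(300)
  drivers <- list(a = sample(1:3, 300, TRUE), b = sample(1:4, 300, TRUE),
                  c = sample(1:2, 300, TRUE))
  rep <- detector_report(y, drivers)
  expect_equal(rep$q_table$factor[order(rep$q_table$rank)], rep$q_table$factor)
  expect_equal(rep$interaction_q, t(rep$interaction_q))
  expect_equal(rep$ecological[upper.tri(rep$ecological)],
               t(rep$ecological)[upper.tri(rep$ecological)])
  expect_equal(nrow(rep$interaction), 3)
})
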