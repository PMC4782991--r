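test_that("plug-in TE equals the brute-force count-table oracle", {
  set.seed(101)
  for (r in 1:40) {
    len <- sample(20:50, 1L)
    m <- sample(1:3, 1L)
    n <- sample(1:3, 1L)
    x <- sample(c(-1L, 0L, 1L), len, replace = TRUE)
    y <- sample(c(-1L, 0L, 1L), len, replace = TRUE)
    if (r %% 5L == 0L) x[sample(len, 2L)] <- NA  # missing bins excluded
    cfg <- te_config(order_m = m, order_n = n, min_samples = 5L)
    expect_equal(as.numeric(transfer_entropy(x, y, cfg)),
                 oracle_te(x, y, m, n), tolerance = 1e-12)
  }
})

test_that("lag-1 deterministic copy of a uniform source gives log2(3) bits", {
  set.seed(7)
  y <- sample(c(-1L, 0L, 1L), 20000, replace = TRUE)
  x <- c(0L, y[-length(y)])
  te <- transfer_entropy(x, y, te_config(order_m = 1L, order_n = 1L))
  expect_lt(abs(te - log2(3)), 0.02)
})

test_that("TE is invariant under relabeling the state alphabet", {
  set.seed(8)
  x <- sample(c(-1L, 0L, 1L), 400, replace = TRUE)
  y <- sample(c(-1L, 0L, 1L), 400, replace = TRUE)
  base <- transfer_entropy(x, y, te_config())
  perm <- c(`-1` = 1L, `0` = -1L, `1` = 0L)   # a permutation of the alphabet
  xp <- unname(perm[as.character(x)])
  yp <- unname(perm[as.character(y)])
  expect_equal(as.numeric(transfer_entropy(xp, yp, te_config())),
               as.numeric(base), tolerance = 1e-12)
})

test_that("insufficient data and alphabet violations are rejected", {
  expect_error(transfer_entropy(c(-1L, 0L, 1L), c(1L, 0L, 1L), te_config()),
               "insufficient data")
  x <- sample(c(-1L, 0L, 1L), 100, replace = TRUE)
  expect_error(transfer_entropy(replace(x, 3L, 7L), x, te_config()),
               "states must be")
})

test_that("etr points in the adopter direction on planted Single dyads", {
  wins <- 0L
  for (r in 1:20) {
    pd <- make_planted_dyads(0L, 1L, 0L, kappa = 0.8, n_steps = 3000L,
                             seed = 100 + r)
    src <- pd$community$series[["1"]]
    fol <- pd$community$series[["2"]]
    if (etr(fol, src) > etr(src, fol)) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("circular-shift null brackets uncoupled strengths", {
  pd <- make_planted_dyads(0L, 0L, 1L, kappa = 0, n_steps = 3000L, seed = 42)
  a <- pd$community$series[[1L]]
  b <- pd$community$series[[2L]]
  obs <- etr(a, b)
  set.seed(1)
  null <- te_circular_null(a, b, n_draws = 100L)
  expect_lt(obs, stats::quantile(null, 0.99))
})

test_that("Simpson quadrature is exact for cubics and meets the e^x bound", {
  for (n in c(2L, 4L, 10L, 50L)) {
    xs <- seq(0, 2, length.out = n + 1L)
    expect_equal(simpson_quadrature(xs^3, 0, 2), 4, tolerance = 1e-13)
  }
  xs <- seq(0, 1, length.out = 11L)
  err <- abs(simpson_quadrature(exp(xs), 0, 1) - (exp(1) - 1))
  bound <- 1 * 0.1^4 / 180 * exp(1)
  expect_lt(err, bound)
  expect_equal(simpson_quadrature(rep(2.5, 7L), 0, 1), 2.5)
  expect_error(simpson_quadrature(1:4, 0, 1), "even")
})

test_that("the Simpson TE estimator tracks the plug-in estimate", {
  pd <- make_planted_dyads(0L, 1L, 0L, kappa = 0.8, n_steps = 4000L,
                           seed = 13)
  fol <- pd$community$series[["2"]]
  src <- pd$community$series[["1"]]
  plug <- etr(fol, src, te_config())
  smth <- etr(fol, src, te_config(estimator = "simpson"))
  expect_gte(smth, 0)
  expect_lt(abs(smth - plug), 0.25 * plug)
})

test_that("cross-entropy identities hold", {
  u <- rep(1 / 3, 3)
  expect_equal(cross_entropy(u, u), log2(3))
  expect_equal(cross_entropy(c(1, 0, 0), c(0.5, 0.25, 0.25)), 1)
  # Gibbs: CE(p, q) >= H(p), equality iff p = q
  set.seed(2)
  for (r in 1:20) {
    p <- as.numeric(stats::rgamma(3, 1)); p <- p / sum(p)
    q <- as.numeric(stats::rgamma(3, 1)); q <- q / sum(q)
    expect_gte(cross_entropy(p, q) - cross_entropy(p, p), -1e-12)
  }
  expect_error(cross_entropy(c(0.7, 0.4, 0.1), u), "summing to 1")
})

test_that("mean pairwise CE matches hand computation and the homogeneous identity", {
  # three users with hand-set state histories
  s1 <- rep(c(1L, 1L, 0L), 10L)     # mostly positive
  s2 <- rep(c(-1L, -1L, 0L), 10L)   # mostly negative
  s3 <- rep(c(1L, -1L, 0L), 10L)    # balanced
  comm <- list(series = list(emotion_series(1, s1), emotion_series(2, s2),
                             emotion_series(3, s3)))
  got <- mean_pairwise_ce(comm, t = 30L)
  d1 <- emotion_distribution(s1)
  d2 <- emotion_distribution(s2)
  d3 <- emotion_distribution(s3)
  hand <- (cross_entropy(d1, d2) + cross_entropy(d2, d1) +
             cross_entropy(d1, d3) + cross_entropy(d3, d1) +
             cross_entropy(d2, d3) + cross_entropy(d3, d2)) / 9
  expect_equal(as.numeric(got), hand, tolerance = 1e-12)
  # homogeneous community: <CE>_t = H(p) (N^2 - N) / N^2
  same <- list(series = lapply(1:4, function(i) emotion_series(i, s1)))
  gh <- mean_pairwise_ce(same, t = 30L)
  expect_equal(as.numeric(gh), cross_entropy(d1, d1) * 12 / 16,
               tolerance = 1e-9)
})

test_that("EnDis definition, bounds and symmetry", {
  expect_equal(en_dis(0.3, 0.3), 0)
  expect_equal(en_dis(0.5, 0), 1)
  expect_equal(en_dis(0.3, 0.1), 2 / 3, tolerance = 1e-12)
  expect_true(is.na(en_dis(0, 0)))
  set.seed(3)
  a <- stats::runif(50)
  b <- stats::runif(50)
  expect_true(all(en_dis(a, b) >= 0 & en_dis(a, b) <= 1))
  expect_equal(en_dis(a, b), en_dis(b, a))
  expect_error(en_dis(-0.1, 0.2), "non-negative")
})

test_that("dyad classification uses an inclusive threshold", {
  th <- 0.2
  expect_equal(classify_dyad(th, th, th), "Dual")
  expect_equal(classify_dyad(th, th - 1e-9, th), "Single")
  expect_equal(classify_dyad(th - 1e-9, th - 1e-9, th), "None")
  expect_equal(classify_dyad(c(0.5, 0.1), c(0.5, 0.5), 0.3),
               c("Dual", "Single"))
})

test_that("a two-user network has two directed edges and theta is their mean", {
  pd <- make_planted_dyads(0L, 1L, 0L, kappa = 0.6, n_steps = 1500L, seed = 21)
  net <- build_network(pd$community)
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$theta_t, mean(net$edges$etr))
  expect_s3_class(net, "entrainment_network")
  dy <- net$dyads
  expect_equal(dy$pattern,
               classify_dyad(dy$etr_ij, dy$etr_ji, net$theta_t))
})

test_that("pairs with insufficient data are listed, not dropped silently", {
  s_short <- emotion_series(1, c(rep(NA_integer_, 95L), rep(0L, 5L)))
  s_a <- emotion_series(2, sample(c(-1L, 0L, 1L), 100L, replace = TRUE))
  s_b <- emotion_series(3, sample(c(-1L, 0L, 1L), 100L, replace = TRUE))
  net <- build_network(list(series = list(`1` = s_short, `2` = s_a,
                                          `3` = s_b)))
  expect_true(any(grepl("^1-", net$excluded)))
  expect_true(all(is.na(net$dyads$pattern[net$dyads$i == "1"])))
  expect_false(anyNA(net$dyads$pattern[net$dyads$i == "2"]))
})
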