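test_that("reciprocal correlation is exact on perfectly reciprocal dyads", {
  set.seed(1)
  s <- stats::runif(20, 0.1, 1)
  d <- data.frame(etr_ij = s, etr_ji = s)
  rc <- reciprocal_correlation(d)
  expect_equal(rc$estimate, 1)
  expect_lt(rc$p_value, 1e-10)
  expect_error(reciprocal_correlation(data.frame(etr_ij = rep(1, 20),
                                                 etr_ji = s)),
               "constant")
  expect_error(reciprocal_correlation(d[1:5, ]), ">= 10 dyads")
})

test_that("independent strengths give near-zero correlation", {
  set.seed(2)
  n <- 400L
  d <- data.frame(etr_ij = stats::runif(n), etr_ji = stats::runif(n))
  rc <- reciprocal_correlation(d)
  expect_lt(abs(rc$estimate), 2 / sqrt(n))
})

test_that("symmetric coupling produces significantly positive reciprocity", {
  # dyads with shared strength scale plus noise emulate equal-kappa coupling
  set.seed(3)
  base <- stats::runif(200, 0.05, 0.6)
  d <- data.frame(etr_ij = base + stats::rnorm(200, 0, 0.05),
                  etr_ji = base + stats::rnorm(200, 0, 0.05))
  d[] <- lapply(d, pmax, 0)
  rc <- reciprocal_correlation(d)
  expect_gt(rc$estimate, 0)
  expect_lt(rc$p_value, 0.01)
})

test_that("group-wise distances match hand averages", {
  d <- data.frame(bin = 1L, i = letters[1:4], j = LETTERS[1:4],
                  etr_ij = 1, etr_ji = 1,
                  pattern = c("Dual", "Dual", "Single", "None"),
                  ce = c(0.2, 0.4, 0.6, 1.0))
  g <- groupwise_distance(d)
  expect_equal(unname(g$means["Dual"]), 0.3)
  expect_equal(unname(g$means["Single"]), 0.6)
  expect_equal(unname(g$means["None"]), 1.0)
  expect_equal(as.integer(g$counts), c(2L, 1L, 1L))
})

test_that("homogeneous distances are not significant; separated groups are", {
  set.seed(104)
  same <- data.frame(pattern = rep(c("None", "Dual"), each = 30L),
                     ce = stats::rnorm(60, 1, 0.1), bin = 1L)
  g0 <- groupwise_distance(same)
  expect_gt(g0$p_value, 0.05)
  apart <- data.frame(pattern = rep(c("None", "Dual"), each = 30L),
                      ce = c(stats::rnorm(30, 2, 0.1),
                             stats::rnorm(30, 1, 0.1)), bin = 1L)
  g1 <- groupwise_distance(apart)
  expect_lt(g1$p_value, 1e-6)
  expect_gt(g1$means["None"], g1$means["Dual"])
})

test_that("R_t series, peak and stages behave as defined", {
  mk <- function(bin, pats) data.frame(bin = bin, i = seq_along(pats),
                                       j = -seq_along(pats), pattern = pats,
                                       ce = NA_real_)
  d <- rbind(mk(1L, c("Dual", "Single", "Single", "Single")),
             mk(2L, c("Dual", "Dual", "Dual", "Single")),
             mk(3L, c("Dual", "Single", "Single", "None")))
  ss <- dual_single_ratio(d)
  expect_equal(ss$r_t$r_t, c(1 / 3, 3, 1 / 2))
  expect_equal(ss$peak_bin, 2L)
  expect_equal(ss$develop_bins, c(1L, 2L))
  expect_equal(ss$maintain_bins, 3L)
  # no Dual at a bin -> ratio zero; no Single -> missing, not Inf
  d2 <- rbind(mk(1L, c("Single", "None")), mk(2L, c("Dual", "Dual")))
  ss2 <- dual_single_ratio(d2)
  expect_equal(ss2$r_t$r_t[1L], 0)
  expect_true(is.na(ss2$r_t$r_t[2L]))
  expect_error(dual_single_ratio(mk(1L, c("Dual", "None"))), "undefined")
})

test_that("lead times follow the onset definition and censoring rules", {
  mk <- function(i, bin, pat) data.frame(bin = bin, i = i, j = paste0(i, "x"),
                                         pattern = pat, ce = NA_real_)
  d <- rbind(mk("a", 3L, "Single"), mk("a", 7L, "Dual"),
             mk("b", 2L, "Dual"), mk("b", 5L, "Dual"),
             mk("c", 1L, "None"), mk("c", 4L, "None"))
  lt <- lead_time_distribution(d)
  expect_equal(lt$lead_times$lead, 4L)          # first Dual 7 - first Single 3
  expect_equal(lt$p_single_first, 1)
  expect_equal(lt$n_dual_only, 1L)
  expect_equal(lt$n_never, 1L)
})

test_that("relabeling Dual and Single negates every signed lead time", {
  set.seed(5)
  pats <- c("Dual", "Single", "None")
  d <- data.frame(bin = rep(1:20, times = 10L),
                  i = rep(paste0("u", 1:10), each = 20L),
                  j = rep(paste0("v", 1:10), each = 20L),
                  pattern = sample(pats, 200L, replace = TRUE),
                  ce = NA_real_)
  lt <- lead_time_distribution(d)
  swapped <- d
  swapped$pattern[d$pattern == "Dual"] <- "Single"
  swapped$pattern[d$pattern == "Single"] <- "Dual"
  lt2 <- lead_time_distribution(swapped)
  key <- function(z) paste(z$lead_times$i, z$lead_times$j)
  expect_setequal(key(lt), key(lt2))
  m <- match(key(lt), key(lt2))
  expect_equal(lt2$lead_times$lead[m], -lt$lead_times$lead)
})

test_that("distance regression recovers a planted slope and handles edge cases", {
  set.seed(6)
  x <- stats::runif(100, 0, 0.5)
  y <- 1.5 - 2 * x + stats::rnorm(100, 0, 0.05)
  d <- data.frame(etr_ij = x, etr_ji = x + 0.2, ce = y)  # min is x
  fit <- strength_distance_regression(d)
  expect_lt(abs(fit$slope - (-2)), 2 * fit$slope_se)
  flat <- data.frame(etr_ij = x, etr_ji = x + 0.2, ce = rep(1, 100))
  # a perfectly flat response triggers lm's perfect-fit warning; slope is 0
  fit0 <- suppressWarnings(strength_distance_regression(flat))
  expect_lt(abs(fit0$slope), 1e-10)
  degen <- data.frame(etr_ij = rep(0.3, 10), etr_ji = rep(0.4, 10),
                      ce = stats::runif(10))
  expect_error(strength_distance_regression(degen), "degenerate")
})

test_that("trajectories over a planted community separate entrained dyads", {
  pd <- make_planted_dyads(2L, 2L, 2L, kappa = 0.9, n_steps = 1200L,
                           seed = 31)
  # estimator order matched to the generator's first-order dynamics
  tr <- dyad_trajectories(pd$community, bins = 1200L,
                          cfg = te_config(order_m = 1L, order_n = 1L),
                          dyads = pd$dyads[, c("i", "j")])
  expect_s3_class(tr, "dyad_trajectories")
  expect_equal(nrow(tr), 6L)
  # coupled dyads carry more reciprocal strength than controls
  planted <- merge(tr, pd$dyads, by = c("i", "j"))
  coupled <- planted$pattern.y != "None"
  expect_gt(min(pmax(planted$etr_ij, planted$etr_ji)[coupled]),
            max(pmin(planted$etr_ij, planted$etr_ji)[!coupled]))
})
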