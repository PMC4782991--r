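test_that("modality features encode states, bigrams and activity thresholds", {
  f <- modality_features(c(1L, 1L))
  expect_setequal(f, c("emo:u:-2:POS", "emo:u:-1:POS", "emo:b:-2:-1:POSPOS"))
  # posting exactly the community mean is 'medium' (>= 1x and < 2x)
  f2 <- modality_features(c(0L, -1L), n_posts = c(5L, 5L), mean_posts = 5)
  expect_true(all(c("act:u:-2:med", "act:u:-1:med", "act:b:-2:-1:medmed")
                  %in% f2))
  f3 <- modality_features(c(0L, 0L), n_posts = c(4L, 10L), mean_posts = 5)
  expect_true(all(c("act:u:-2:low", "act:u:-1:high") %in% f3))
  expect_equal(modality_features(integer(0)), character(0))
  # missing bins contribute no emotion features
  f4 <- modality_features(c(NA, 1L))
  expect_equal(f4, "emo:u:-1:POS")
})

test_that("the factor score matches hand computations", {
  feats <- list(a = "f1", b = character(0))
  m0 <- enfg_build(feats, edges = data.frame(i = "a", j = "b", assoc = 1,
                                             pattern = "Dual"))
  # all weights zero: every assignment scores 0, marginals uniform
  expect_equal(enfg_score(m0, c(a = "POS", b = "NEG")), 0)
  inf0 <- enfg_marginals(m0)
  expect_equal(unname(inf0$marginals),
               matrix(1 / 3, 2, 3), tolerance = 1e-12)
  # single active modality feature with alpha = 1.5: log-odds 1.5
  m1 <- enfg_build(list(a = "f1"))
  m1$alpha["f1", "POS"] <- 1.5
  s_match <- enfg_score(m1, c(a = "POS"))
  s_other <- enfg_score(m1, c(a = "NEU"))
  expect_equal(s_match - s_other, 1.5)
  # literal variant: a Dual edge with gamma = 0.7 adds 1.4 to every score
  m2 <- enfg_build(feats, edges = data.frame(i = "a", j = "b", assoc = 0,
                                             pattern = "Dual"),
                   variant = "literal")
  m2$gamma <- 0.7
  expect_equal(enfg_score(m2, c(a = "POS", b = "NEG")), 1.4)
  expect_equal(enfg_score(m2, c(a = "POS", b = "POS")), 1.4)
  # the literal pairwise factor cancels in inference
  inf2 <- enfg_marginals(m2)
  expect_equal(unname(inf2$marginals), matrix(1 / 3, 2, 3),
               tolerance = 1e-12)
})

test_that("a disconnected node's marginal is the softmax of its scores", {
  m <- enfg_build(list(a = c("f1", "f2")))
  m$alpha["f1", ] <- c(0.2, -0.1, 0.4)
  m$alpha["f2", ] <- c(-0.3, 0.5, 0.1)
  sc <- colSums(m$alpha)
  inf <- enfg_marginals(m)
  expect_equal(unname(inf$marginals[1L, ]),
               unname(exp(sc) / sum(exp(sc))), tolerance = 1e-12)
})

test_that("exact probabilities normalize over all assignments", {
  m <- make_random_enfg(5L, extra_edges = 2L, seed = 44)
  inf <- enfg_marginals(m, engine = "exact")
  states <- m$states
  total <- 0
  grid <- expand.grid(rep(list(states), 5L), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    y <- stats::setNames(as.character(grid[r, ]), m$users)
    total <- total + exp(enfg_score(m, y) - inf$logZ)
  }
  expect_equal(total, 1, tolerance = 1e-9)
})

test_that("message passing matches enumeration on trees and loopy graphs", {
  for (s in 1:6) {
    tree <- make_random_enfg(6L, extra_edges = 0L, seed = 400 + s)
    ex <- enfg_marginals(tree, engine = "exact")
    bp <- enfg_marginals(tree, engine = "bp", tol = 1e-12, max_iter = 500L)
    expect_lt(max(abs(ex$marginals - bp$marginals)), 1e-9)
  }
  for (s in 1:6) {
    loopy <- make_random_enfg(8L, extra_edges = 3L, seed = 500 + s,
                              edge_scale = 0.05)
    ex <- enfg_marginals(loopy, engine = "exact")
    bp <- enfg_marginals(loopy, engine = "bp")
    tv <- max(rowSums(abs(ex$marginals - bp$marginals)) / 2)
    expect_lt(tv, 1e-3)
  }
})

test_that("clamping conditions the marginals", {
  m <- make_random_enfg(5L, extra_edges = 1L, seed = 46)
  m$beta <- 0.8
  inf <- enfg_marginals(m, clamped = c(u1 = "POS"))
  expect_equal(unname(inf$marginals["u1", ]), c(0, 0, 1))
  expect_equal(rowSums(inf$marginals), rep(1, 5L), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the analytic gradient matches central finite differences", {
  m <- make_random_enfg(5L, extra_edges = 2L, seed = 47)
  set.seed(48)
  labs <- enfg_sample(m, 6L)
  g <- enfg_gradient(m, labs, lambda = 0.1, engine = "exact")
  eps <- 1e-5
  bump <- function(model, field, idx, d) {
    if (field == "alpha") model$alpha[idx] <- model$alpha[idx] + d
    else model[[field]] <- model[[field]] + d
    model
  }
  for (k in sample(length(m$alpha), 8L)) {
    num <- (enfg_loglik(bump(m, "alpha", k, eps), labs, lambda = 0.1) -
              enfg_loglik(bump(m, "alpha", k, -eps), labs, lambda = 0.1)) /
      (2 * eps)
    expect_lt(abs(num - g$alpha[k]), 1e-5)
  }
  for (field in c("beta", "gamma")) {
    num <- (enfg_loglik(bump(m, field, NULL, eps), labs, lambda = 0.1) -
              enfg_loglik(bump(m, field, NULL, -eps), labs, lambda = 0.1)) /
      (2 * eps)
    expect_lt(abs(num - g[[field]]), 1e-5)
  }
})

test_that("a single-node model reduces to multinomial logistic regression", {
  # gradient of the single-node likelihood = empirical - softmax probabilities
  m <- enfg_build(list(a = c("f1", "f2")))
  m$alpha[] <- c(0.3, -0.2, 0.1, 0.4, 0.0, -0.5)
  labs <- matrix(c("POS", "NEG", "POS", "NEU"), ncol = 1L)
  g <- enfg_gradient(m, labs, lambda = 0)
  sc <- colSums(m$alpha)
  p <- exp(sc) / sum(exp(sc))
  emp <- c(NEG = 1, NEU = 1, POS = 2) / 4
  hand <- rbind(emp - p, emp - p)   # both features always active
  expect_equal(unname(g$alpha), unname(hand), tolerance = 1e-8)
})

test_that("heavy regularization shrinks all weights toward zero", {
  m <- make_random_enfg(5L, extra_edges = 1L, seed = 49)
  set.seed(50)
  labs <- enfg_sample(m, 50L)
  fit <- enfg_fit(enfg_build(stats::setNames(m$features, m$users),
                             NULL), labs, lambda = 1e4, max_iter = 200L)
  expect_lt(max(abs(fit$alpha)), 1e-3)
})

test_that("learned parameters dominate perturbed ones on held-out data", {
  truth <- make_random_enfg(6L, extra_edges = 2L, seed = 51, weight_sd = 0.6,
                            edge_scale = 0.6)
  set.seed(52)
  train <- enfg_sample(truth, 800L)
  heldout <- enfg_sample(truth, 400L)
  blank <- truth
  blank$alpha[] <- 0
  blank$beta <- 0
  blank$gamma <- 0
  fit <- enfg_fit(blank, train, lambda = 0.05)
  ll_fit <- enfg_loglik(fit, heldout)
  set.seed(53)
  for (r in 1:10) {
    pert <- fit
    pert$alpha <- pert$alpha + sample(c(-0.5, 0.5), length(pert$alpha),
                                      replace = TRUE)
    pert$beta <- pert$beta + sample(c(-0.5, 0.5), 1L)
    pert$gamma <- pert$gamma + sample(c(-0.5, 0.5), 1L)
    expect_gt(ll_fit, enfg_loglik(pert, heldout))
  }
})

test_that("deterministic copy-your-own-state cohorts are predicted perfectly", {
  set.seed(54)
  n_users <- 24L
  states <- sample(c(-1L, 0L, 1L), n_users, replace = TRUE)
  hist <- lapply(states, function(s) c(sample(c(-1L, 0L, 1L), 1L), s))
  feats <- lapply(hist, modality_features)
  names(feats) <- paste0("u", seq_len(n_users))
  labels <- stats::setNames(c("NEG", "NEU", "POS")[states + 2L], names(feats))
  res <- enfg_cv(feats, NULL, labels, folds = 4L, seed = 55,
                 max_iter = 300L, tol = 1e-4)
  expect_equal(res$accuracy, 1.0)
})

test_that("label-shuffled cohorts predict at chance", {
  set.seed(56)
  n_users <- 36L
  feats <- lapply(seq_len(n_users), function(i) {
    modality_features(sample(c(-1L, 0L, 1L), 3L, replace = TRUE))
  })
  names(feats) <- paste0("u", seq_len(n_users))
  labels <- stats::setNames(sample(c("NEG", "NEU", "POS"), n_users,
                                   replace = TRUE), names(feats))
  res <- enfg_cv(feats, NULL, labels, folds = 4L, seed = 57,
                 max_iter = 100L, tol = 1e-3)
  se <- sqrt(1 / 3 * 2 / 3 / n_users)
  expect_lt(abs(res$accuracy - 1 / 3), 3 * se + 0.1)
})

test_that("entrainment factors help when the final state copies a neighbour", {
  cc <- make_copycat_cohort(14L, n_steps = 300L, kappa = 0.8, seed = 58)
  folds <- make_folds(names(cc$features), k = 4L, seed = 59)
  with_edges <- enfg_cv(cc$features, cc$edges, cc$labels, folds = folds,
                        variant = "coupled", max_iter = 150L, tol = 1e-3)
  no_edges <- enfg_cv(cc$features, NULL, cc$labels, folds = folds,
                      max_iter = 150L, tol = 1e-3)
  expect_gt(with_edges$accuracy, no_edges$accuracy)
})
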