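test_that("penalty values match their closed forms", {
  n <- 3
  z <- mhn_model(matrix(0, n + 1, n))
  for (k in c("l1", "l2", "symmetric"))
    expect_equal(mhn_penalty(z, penalty_spec(k))$value, 0)

  th <- matrix(0, n + 1, n)
  th[1, 2] <- 2
  expect_equal(mhn_penalty(th, penalty_spec("l2"))$value, 4)

  th2 <- matrix(0, n + 1, n)
  th2[1, 2] <- 3; th2[2, 1] <- 4
  expect_equal(mhn_penalty(th2, penalty_spec("symmetric", smoothing = 1e-9))$value,
               5, tolerance = 1e-8)
  # diagonals are never penalized
  thd <- matrix(0, n + 1, n)
  thd[cbind(1:n, 1:n)] <- 10
  for (k in c("l1", "l2", "symmetric"))
    expect_equal(mhn_penalty(thd, penalty_spec(k))$value, 0)
  # observation row can be exempted
  tho <- matrix(0, n + 1, n)
  tho[n + 1, ] <- 2
  expect_equal(mhn_penalty(tho, penalty_spec("l1", penalize_observation = FALSE))$value, 0)
  expect_gt(mhn_penalty(tho, penalty_spec("l1"))$value, 0)
})

test_that("penalty gradients match finite differences", {
  set.seed(9)
  n <- 4
  th <- matrix(rnorm((n + 1) * n), n + 1, n)
  h <- 1e-6
  for (k in c("l1", "l2", "symmetric")) {
    spec <- penalty_spec(k, smoothing = 1e-3)
    g <- mhn_penalty(th, spec)$gradient
    fd <- matrix(0, n + 1, n)
    for (a in seq_len(n + 1)) for (b in seq_len(n)) {
      tp <- th; tp[a, b] <- tp[a, b] + h
      tm <- th; tm[a, b] <- tm[a, b] - h
      fd[a, b] <- (mhn_penalty(tp, spec)$value - mhn_penalty(tm, spec)$value) / (2 * h)
    }
    expect_lt(max(abs(g - fd) / pmax(1, abs(g))), 1e-8)
  }
})

test_that("custom penalty hooks are called and validated", {
  n <- 2
  hook <- function(th) list(value = sum(th^2), gradient = 2 * th)
  spec <- penalty_spec("custom", hook = hook)
  th <- matrix(1, n + 1, n)
  res <- mhn_penalty(th, spec)
  expect_equal(res$value, 6)
  expect_equal(res$gradient, 2 * th)
  bad <- penalty_spec("custom", hook = function(th) list(value = 0, gradient = matrix(0, 2, 2)))
  expect_error(mhn_penalty(th, bad), "custom penalty hook")
  expect_error(penalty_spec("custom"), "hook")
  expect_error(penalty_spec("l1", hook = hook), "custom")
  expect_error(penalty_spec("l1", strength = -1), "non-negative")
})

test_that("fitting improves the objective and is deterministic", {
  m0 <- random_model(3, 55, sd = 0.8)
  d <- sample_mhn(m0, 400, seed = 55)
  fit <- fit_mhn(d, penalty_spec("l1", 0.01))
  init <- mhn_initial(d)
  obj0 <- log_likelihood(init, d) / nrow(d) -
    0.01 * mhn_penalty(init$log_theta, penalty_spec("l1", 0.01))$value
  expect_gte(fit$value, obj0)
  expect_equal(fit$value, fit$objective_trace[length(fit$objective_trace)],
               tolerance = 1e-12)
  expect_true(fit$converged)
  # deterministic: refitting gives the identical matrix
  fit2 <- fit_mhn(d, penalty_spec("l1", 0.01))
  expect_identical(fit$model$log_theta, fit2$model$log_theta)
  # invariant to row order of the dataset
  fit3 <- fit_mhn(d[rev(seq_len(nrow(d))), ], penalty_spec("l1", 0.01))
  expect_identical(fit$model$log_theta, fit3$model$log_theta)
})

test_that("classic fits have a zero observation row", {
  m0 <- random_model(3, 56, sd = 0.6)
  d <- sample_mhn(m0, 200, seed = 56)
  fit <- fit_mhn(d, penalty_spec("l1", 0.01), kind = "classic")
  expect_true(all(fit$model$log_theta[4, ] == 0))
  expect_identical(fit$model$kind, "classic")
})

test_that("a dominant penalty shrinks all penalized entries", {
  m0 <- random_model(3, 57, sd = 1)
  d <- sample_mhn(m0, 300, seed = 57)
  fit <- fit_mhn(d, penalty_spec("l1", 10))
  th <- fit$model$log_theta
  off <- th
  off[cbind(1:3, 1:3)] <- 0
  expect_lt(max(abs(off)), 1e-2)
})

test_that("frozen observation row reproduces the classic fit", {
  m0 <- random_model(3, 58, sd = 0.6)
  d <- sample_mhn(m0, 250, seed = 58)
  f_classic <- fit_mhn(d, penalty_spec("l1", 0.05), kind = "classic")
  f_frozen <- fit_mhn(d, penalty_spec("l1", 0.05), freeze_observation = TRUE)
  expect_equal(f_frozen$model$log_theta[1:3, ],
               f_classic$model$log_theta[1:3, ], tolerance = 1e-10)
  expect_equal(f_frozen$logLik, f_classic$logLik, tolerance = 1e-10)
})

test_that("cross-validation is seeded, reproducible, and breaks ties downward", {
  m0 <- random_model(3, 59, sd = 0.8)
  d <- sample_mhn(m0, 120, seed = 59)
  grid <- c(0.001, 0.1)
  cv1 <- cv_mhn(d, grid = grid, folds = 3, seed = 4)
  cv2 <- cv_mhn(d, grid = grid, folds = 3, seed = 4)
  expect_identical(cv1$fold_scores, cv2$fold_scores)
  expect_identical(cv1$selected_strength, cv2$selected_strength)
  expect_identical(cv1$final_fit$model$log_theta, cv2$final_fit$model$log_theta)
  cand <- which(cv1$mean_scores == max(cv1$mean_scores))
  expect_equal(cv1$selected_strength, grid[cand[which.min(grid[cand])]])

  # with no penalized entries (one event, observation row exempt) every
  # strength yields the identical fit: an exact tie, resolved to the
  # smallest strength
  dd <- matrix(rep(c(0L, 1L), 10), ncol = 1, dimnames = list(NULL, "E1"))
  cvt <- cv_mhn(dd, grid = c(0.5, 0.05), folds = 2, seed = 1,
                penalize_observation = FALSE)
  expect_true(all(cvt$fold_scores[1, ] == cvt$fold_scores[2, ]))
  expect_equal(cvt$selected_strength, 0.05)

  expect_error(cv_mhn(d, folds = 1), "at least 2")
  expect_error(cv_mhn(d[1:2, ], folds = 3, seed = 1), "empty")
  expect_error(cv_mhn(d, grid = numeric(0)), "non-empty")
})
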