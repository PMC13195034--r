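test_that("replicate averaging and split-model merging work as stated", {
  expr <- rbind(gA = c(4, 1, 2, 3), gB1 = c(6, 1, 2, 3), gB2 = c(0, 0, 1, 0))
  tc <- expression_timecourse(expr, time = c(0, 0, 1, 2), molts = 2)
  out <- collapse_replicates_and_merge(tc, merge_groups = list(gB = c("gB1", "gB2")))
  expect_equal(out$time, c(0, 1, 2))
  expect_equal(unname(out$expr["gA", ]), c(2.5, 2, 3))    # (4+1)/2 at t=0
  expect_equal(unname(out$expr["gB", ]), c(3.5, 3, 3))    # summed models
  expect_error(collapse_replicates_and_merge(tc, list(g = "nope")), "unknown ID")

  # no replicates, no merges: identity
  tc2 <- expression_timecourse(expr[, 1:3], time = 0:2, molts = 2)
  out2 <- collapse_replicates_and_merge(tc2)
  expect_equal(out2$expr, tc2$expr, ignore_attr = TRUE)

  # split models summed: [1,2,3] + [0,1,0] -> [1,3,3]
  tc3 <- expression_timecourse(rbind(m1 = c(1, 2, 3), m2 = c(0, 1, 0)),
                               time = 0:2, molts = 2)
  out3 <- collapse_replicates_and_merge(tc3, list(m = c("m1", "m2")))
  expect_equal(unname(out3$expr["m", ]), c(1, 3, 3))
})

test_that("3-point window smoothing anchors interior time points", {
  tc <- expression_timecourse(matrix(c(3, 6, 9), 1, dimnames = list("g", NULL)),
                              time = c(0, 1, 3), molts = 3)
  sm <- smooth_windows(tc)
  expect_equal(sm$time, 1)
  expect_equal(unname(sm$expr[1, 1]), 6)   # mean of the 0/1/3 h window

  const <- expression_timecourse(matrix(5, 2, 6), time = 0:5, molts = 5)
  smc <- smooth_windows(const)
  expect_equal(ncol(smc$expr), 4L)
  expect_true(all(smc$expr == 5))

  set.seed(2)
  X <- matrix(runif(7 * 9), 7, 9)
  tcr <- expression_timecourse(X, time = 0:8, molts = 8)
  smr <- smooth_windows(tcr)
  direct <- sapply(2:8, function(i) rowMeans(X[, (i - 1):(i + 1)]))
  expect_equal(unname(smr$expr), unname(direct), tolerance = 1e-12)

  # commutes with affine rescaling of values (non-negative scale/offset)
  tca <- expression_timecourse(3 * X + 2, time = 0:8, molts = 8)
  expect_equal(unname(smooth_windows(tca)$expr), unname(3 * smr$expr + 2),
               tolerance = 1e-12)

  expect_error(smooth_windows(expression_timecourse(X[, 1:2], 0:1, molts = 1)),
               "at least 3")
})

test_that("fuzzy c-means obeys its membership and objective contracts", {
  # a point equidistant from two well-determined clusters gets 0.5/0.5
  X <- rbind(matrix(rep(c(0, 0), each = 20), 20, 2),
             matrix(rep(c(10, 0), each = 20), 20, 2),
             c(5, 0))
  fit <- fuzzy_cmeans(X, c = 2, seed = 3)
  expect_equal(rowSums(fit$membership), rep(1, nrow(X)), tolerance = 1e-9)
  expect_equal(unname(fit$membership[nrow(X), ]), c(0.5, 0.5), tolerance = 1e-3)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))

  # a point coincident with a center has membership 1 there
  d2 <- matrix(c(0, 4, 3, 5), 2, 2)
  U <- moltloss:::.fcm_membership(d2, 2)
  expect_equal(U[1, ], c(1, 0))

  expect_error(fuzzy_cmeans(X, c = 1), "at least 2")
  expect_error(fuzzy_cmeans(X[1:3, ], c = 4), "below the number")
  expect_error(fuzzy_cmeans(X * NA, c = 2), "non-finite")
})

test_that("well-separated blobs are recovered and match an independent FCM", {
  set.seed(10)
  truth <- rep(1:2, each = 40)
  X <- rbind(matrix(rnorm(80, 0, 1), 40, 2), matrix(rnorm(80, 10, 1), 40, 2))
  for (seed in 1:20) {
    fit <- fuzzy_cmeans(X, c = 2, seed = seed)
    expect_gte(adjusted_rand(fit$cluster, truth), 0.99)
  }
  fit <- fuzzy_cmeans(X, c = 2, seed = 1)
  ref <- e1071::cmeans(X, centers = fit$centers, m = 2, iter.max = 200)
  expect_gte(adjusted_rand(fit$cluster, ref$cluster), 0.99)
  ord <- order(fit$centers[, 1])
  expect_equal(unname(fit$centers[ord, ]), unname(ref$centers[order(ref$centers[, 1]), ]),
               tolerance = 1e-3)
})

test_that("small fuzzifiers approach the crisp nearest-center partition", {
  set.seed(8)
  X <- rbind(matrix(rnorm(60, 0, 0.5), 30, 2), matrix(rnorm(60, 8, 0.5), 30, 2))
  fit <- fuzzy_cmeans(X, c = 2, m = 1.05, seed = 2)
  d <- as.matrix(dist(rbind(fit$centers, X)))[-(1:2), 1:2]
  nearest <- apply(d, 1, which.min)
  expect_equal(unname(fit$cluster), unname(nearest))
  expect_true(all(apply(fit$membership, 1, max) > 0.99))
})

test_that("pre-molt clusters are selected by peak position, not noise", {
  time <- seq(0, 40, by = 1); molts <- c(10, 20, 30, 40)
  sim <- gen_expression_timecourse(200, time, molts, noise_sd = 0, seed = 6)
  # with no noise, every planted gene peaks exactly at molt - offset
  planted <- sim$truth$planted
  peaks <- time[apply(sim$tc$expr[planted, ], 1, which.max)]
  expect_true(all(peaks %in% (molts - sim$truth$peak_offset)))

  fit <- fuzzy_cmeans(standardize_rows(sim$tc$expr), c = 5, seed = 6)
  sel <- select_premolt_clusters(fit, sim$tc)
  expect_true(all(planted %in% sel$candidates))

  # a flat center is never selected
  flat_fit <- fit
  flat_fit$centers[1, ] <- 0
  flat_fit$data <- NULL
  sel_flat <- select_premolt_clusters(flat_fit, sim$tc)
  expect_false(1L %in% sel_flat$selected)

  expect_error(select_premolt_clusters(fit, expression_timecourse(
    sim$tc$expr, sim$tc$time, molts = numeric(0))), "no molt events")
})

test_that("the clustering stage is deterministic end to end", {
  time <- seq(0, 30, by = 1); molts <- c(10, 20, 30)
  run <- function() {
    sim <- gen_expression_timecourse(120, time, molts, seed = 9)
    fit <- fuzzy_cmeans(standardize_rows(sim$tc$expr), c = 5, seed = 9)
    select_premolt_clusters(fit, sim$tc)$candidates
  }
  expect_identical(run(), run())
})
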