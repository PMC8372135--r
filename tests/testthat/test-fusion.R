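test_that("thresholding votes out only strictly above the cut", {
  expect_equal(apply_threshold(1.0, 1.0), "in")    # boundary is in-class
  expect_equal(apply_threshold(0, 5), "in")
  expect_equal(apply_threshold(c(0.5, 1.5), 1.0), c("in", "out"))
})

test_that("replicate combination policies", {
  expect_equal(combine_replicates(3.3), 3.3)
  expect_equal(combine_replicates(c(1, 1, 4)), 2.0)
  expect_equal(combine_replicates(c(1, 1, 4), "median"), 1.0)
  withr::with_seed(34, {
    d <- runif(9)
    expect_equal(combine_replicates(d),
                 unname(aggregate_sample_distance(d, rep("s", 9))))
  })
  expect_error(combine_replicates(numeric(0)), class = "input_error")
})

test_that("vote fusion applies the >=2-of-10 rule", {
  v <- function(k) c(rep("out", k), rep("in", 10 - k))
  expect_equal(fuse_votes(v(0))$flag, "EVOO")
  expect_equal(fuse_votes(v(1))$flag, "EVOO")
  expect_equal(fuse_votes(v(2))$flag, "NON_EVOO")
  expect_equal(fuse_votes(v(2))$votes_out, 2L)
  expect_equal(fuse_votes(rep(TRUE, 3), min_votes = 1)$flag, "NON_EVOO")
  expect_error(fuse_votes(character(0)), class = "input_error")
})

test_that("raising thresholds or min_votes never increases flags", {
  withr::with_seed(35, {
    dist <- matrix(runif(200, 0, 3), 20, 10,
                   dimnames = list(sprintf("s%02d", 1:20), letters[1:10]))
  })
  th <- setNames(runif(10, 0.5, 2.5), letters[1:10])
  base <- decide_samples(dist, th, 2)
  for (j in 1:10) {
    th2 <- th; th2[j] <- th2[j] + 1
    bumped <- decide_samples(dist, th2, 2)
    expect_true(all(bumped$votes_out <= base$votes_out))
  }
  n_flagged <- vapply(1:5, function(mv)
    sum(decide_samples(dist, th, mv)$flag == "NON_EVOO"), 0L)
  expect_true(all(diff(n_flagged) <= 0))
})

test_that("scenario 1 thresholds guarantee 100% calibration EVOO rate", {
  expect_equal(
    unname(tune_thresholds(
      matrix(c(1, 2, 3), 3, 1, dimnames = list(c("a", "b", "c"), "m")),
      c(a = "EVOO", b = "EVOO", c = "EVOO"),
      scenario_config("S1_NO_FALSE_NEGATIVE"))),
    3 * (1 + 1e-6))
  withr::with_seed(36, {
    dist <- matrix(rexp(35 * 6), 35, 6,
                   dimnames = list(sprintf("s%02d", 1:35), letters[1:6]))
  })
  labels <- setNames(c(rep("EVOO", 15), rep("ADULT_OLIVE", 10),
                       rep("ADULT_OTHER", 10)), rownames(dist))
  th <- tune_thresholds(dist, labels, scenario_config("S1_NO_FALSE_NEGATIVE"))
  dec <- decide_samples(dist, th, 2)
  expect_true(all(dec$flag[labels[dec$sample_id] == "EVOO"] == "EVOO"))
})

test_that("scenario 2 finds a separating threshold on bimodal distances", {
  withr::with_seed(37, {
    evoo_d <- matrix(rnorm(20 * 3, 1, 0.1), 20, 3)
    adult_d <- matrix(rnorm(12 * 3, 3, 0.1), 12, 3)
  })
  dist <- rbind(evoo_d, adult_d)
  rownames(dist) <- sprintf("s%02d", 1:32)
  colnames(dist) <- c("m1", "m2", "m3")
  labels <- setNames(c(rep("EVOO", 20), rep("ADULT_OTHER", 12)),
                     rownames(dist))
  cf <- scenario_config("S2_FRAUD_SCREEN", evoo_rate_floor = 0.75)
  th <- tune_thresholds(dist, labels, cf)
  dec <- decide_samples(dist, th, cf$min_votes)
  flag <- setNames(dec$flag, dec$sample_id)
  expect_equal(mean(flag[labels == "ADULT_OTHER"] == "NON_EVOO"), 1)
  expect_equal(mean(flag[labels == "EVOO"] == "EVOO"), 1)
  expect_true(all(th > max(evoo_d) - 0.5 & th < 3))

  # exhaustive-grid oracle: no quantile on the grid beats the chosen one
  grid_rates <- vapply(cf$threshold_grid, function(q) {
    thq <- pmax(apply(evoo_d, 2, quantile, probs = q) * (1 + cf$eps), cf$eps)
    d <- decide_samples(dist, setNames(thq, colnames(dist)), cf$min_votes)
    f <- setNames(d$flag, d$sample_id)
    er <- mean(f[labels == "EVOO"] == "EVOO")
    c(det = mean(f[labels != "EVOO"] == "NON_EVOO"), evoo = er)
  }, c(0, 0))
  feasible <- grid_rates["evoo", ] >= cf$evoo_rate_floor
  expect_equal(mean(flag[labels != "EVOO"] == "NON_EVOO"),
               max(grid_rates["det", feasible]))
})

test_that("scenario 2 falls back to scenario 1 when the floor is infeasible", {
  dist <- matrix(c(1, 2, 3, 4), 4, 1,
                 dimnames = list(c("a", "b", "c", "d"), "m"))
  labels <- c(a = "EVOO", b = "EVOO", c = "ADULT_OLIVE", d = "ADULT_OTHER")
  cf <- scenario_config("S2_FRAUD_SCREEN", min_votes = 1,
                        evoo_rate_floor = 1, threshold_grid = c(0.0, 0.25))
  expect_warning(th <- tune_thresholds(dist, labels, cf), "infeasible")
  expect_equal(unname(th), 2 * (1 + 1e-6))
  expect_error(tune_thresholds(dist, c(a = "RVOO", b = "RVOO", c = "RVOO",
                                       d = "RVOO"), cf),
               class = "scenario_error")
  expect_error(tune_thresholds(dist[1:2, , drop = FALSE],
                               labels[1:2], cf), class = "scenario_error")
})

test_that("scenario 1 detection never exceeds scenario 2 with a <100% floor", {
  withr::with_seed(38, {
    dist <- rbind(matrix(rgamma(18 * 4, 2, 2), 18, 4),
                  matrix(rgamma(14 * 4, 6, 2), 14, 4))
  })
  rownames(dist) <- sprintf("s%02d", 1:32)
  colnames(dist) <- paste0("m", 1:4)
  labels <- setNames(c(rep("EVOO", 18), rep("ADULT_OLIVE", 14)),
                     rownames(dist))
  det_rate <- function(th) {
    dec <- decide_samples(dist, th, 2)
    f <- setNames(dec$flag, dec$sample_id)
    mean(f[labels == "ADULT_OLIVE"] == "NON_EVOO")
  }
  th1 <- tune_thresholds(dist, labels, scenario_config("S1_NO_FALSE_NEGATIVE"))
  th2 <- tune_thresholds(dist, labels,
                         scenario_config("S2_FRAUD_SCREEN",
                                         evoo_rate_floor = 0.75))
  expect_lte(det_rate(th1), det_rate(th2))
})
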