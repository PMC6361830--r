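test_that("scalar_stats handles degenerate and synthetic inputs", {
  # identical trials: SD = CV = 0
  rec <- data.frame(trial = rep(1:3, each = 2), cell = rep(1:2, 3),
                    time = rep(c(100, 200), 3))
  st <- scalar_stats(rec)
  expect_equal(st$sd, c(0, 0))
  expect_equal(st$cv, c(0, 0))
  expect_equal(st$mean, c(100, 200))
  # CV = SD / mean by construction
  set.seed(1)
  rec2 <- data.frame(trial = rep(1:20, 2), cell = rep(1:2, each = 20),
                     time = abs(rnorm(40, 500, 50)))
  st2 <- scalar_stats(rec2)
  expect_equal(st2$cv, st2$sd / st2$mean)
  # full rasters are reduced to first spikes
  rec3 <- rbind(rec, transform(rec, time = time + 50))
  expect_equal(scalar_stats(rec3)$mean, c(100, 200))
})

test_that("a scalar family yields a flat fitted CV near its generating value", {
  # generator: spike time of cell k ~ Normal(100 k, 10 k) -> CV = 0.1
  set.seed(123)
  K <- 40; n <- 200
  rec <- data.frame(trial = rep(seq_len(n), K),
                    cell = rep(seq_len(K), each = n),
                    time = rnorm(n * K, mean = rep(100 * seq_len(K), each = n),
                                 sd = rep(10 * seq_len(K), each = n)))
  st <- scalar_stats(rec)
  expect_true(all(abs(st$cv - 0.1) < 0.03))
  expect_equal(attr(st, "slope"), 0.1, tolerance = 0.05)
  expect_gt(attr(st, "r_squared"), 0.95)
  expect_equal(attr(st, "cv_asymptotic"), 0.1, tolerance = 0.02)
})

test_that("cells with too few trials are omitted and counted", {
  rec <- data.frame(trial = c(1, 2, 1), cell = c(1, 1, 2),
                    time = c(10, 12, 30))
  st <- scalar_stats(rec)
  expect_equal(st$cell, 1)
  expect_equal(attr(st, "n_omitted"), 1)
})

test_that("normalized histograms are proper distributions and KS behaves", {
  set.seed(7)
  rec <- data.frame(trial = rep(1:100, 2), cell = rep(c(30, 40), each = 100),
                    time = c(rnorm(100, 3000, 300), rnorm(100, 4000, 400)))
  nh <- normalized_histograms(rec, cells = c(30, 40))
  for (h in nh$histograms) {
    expect_equal(sum(h$mass), 1, tolerance = 1e-12)
    expect_true(all(h$mass >= 0))
  }
  # a sample against itself: D = 0
  same <- suppressWarnings(ks.test(nh$samples[[1]], nh$samples[[1]]))
  expect_equal(unname(same$statistic), 0)
  expect_error(normalized_histograms(rec, cells = 99), "no spikes")
})

test_that("samples from one scalar family superpose after normalization", {
  # Monte-Carlo oracle: Normal(mu, 0.1 mu) at mu = 3000 vs 4000, n = 200,
  # mean-normalized; KS should fail to reject at alpha = .05 in >= 90% of
  # seeded repetitions
  set.seed(2024)
  reps <- 100
  p_vals <- replicate(reps, {
    a <- rnorm(200, 3000, 300); b <- rnorm(200, 4000, 400)
    suppressWarnings(ks.test(a / mean(a), b / mean(b)))$p.value
  })
  expect_gte(mean(p_vals > 0.05), 0.9)
})

test_that("sum-of-normals null matches its closed form and a simulation", {
  expect_equal(sum_of_normals_null(1, 1000, 100),
               list(mean = 1000, sd = 100, cv = 0.1))
  null4 <- sum_of_normals_null(4, 1000, 100)
  expect_equal(null4$mean, 4000)
  expect_equal(null4$sd, 200)
  expect_equal(null4$cv, 0.05)
  # simulation oracle: 1e5 summed draws
  set.seed(9)
  sims <- rowSums(matrix(rnorm(4e5, 1000, 100), ncol = 4))
  expect_lt(abs(sd(sims) - 200) / 200, 0.01)
  expect_error(sum_of_normals_null(0, 1000, 100))
})

test_that("independent lengthening intervals still compress the CV", {
  set.seed(31)
  # constant means reduce to the identical-normals null
  out_const <- increasing_isi_null(rep(1000, 4), 0.1, n_draws = 20000)
  expect_equal(out_const$cv[4], 0.05, tolerance = 0.02)
  expect_equal(out_const$cv_analytic[4], 0.05)
  # linearly growing means: cumulative CV falls below the per-interval CV
  out <- increasing_isi_null(100 * (1:40), 0.1, n_draws = 10000)
  expect_lt(out$cv[40], 0.1)
  expect_equal(out$cv[40], out$cv_analytic[40], tolerance = 0.05)
  expect_equal(out$cv_analytic[40],
               0.1 * sqrt(sum((100 * (1:40))^2)) / sum(100 * (1:40)))
  # the fall is monotone after the first few terms
  expect_true(all(diff(out$cv_analytic[5:40]) < 0))
})
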