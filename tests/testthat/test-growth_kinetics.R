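test_that("noiseless curves are recovered exactly on-grid", {
  for (p in list(c(43, 20, 29), c(148, 15, 25), c(54, 28, 34))) {
    cv <- simulate_growth_curve(latent = p[2], burst_time = p[3],
                                burst_size = p[1], dt = 1, noise_sd = 0)
    est <- estimate_growth_params(cv)
    expect_equal(est$latent_min, p[2])
    expect_equal(est$burst_time_min, p[3])
    expect_equal(est$burst_size, p[1])
    expect_lt(est$fit_rss, 1e-18)
  }
})

test_that("flat curves raise an error", {
  cv <- growth_curve(seq(0, 30, 3), rep(1e5, 11))
  expect_error(estimate_growth_params(cv), "flat")
})

test_that("the grid-search optimum equals an independent exhaustive enumeration", {
  cv <- simulate_growth_curve(latent = 6, burst_time = 15, burst_size = 40,
                              dt = 3, t_max = 24, noise_sd = 0.1, seed = 99)
  est <- estimate_growth_params(cv)
  # independent re-implementation of the breakpoint scan
  t <- cv$times; ly <- log10(cv$titers)
  best <- list(rss = Inf)
  for (ti in t) for (tj in t) {
    if (tj <= ti) next
    pre <- t < ti; plat <- t >= tj; rise <- !pre & !plat
    if (sum(pre) < 2 || sum(plat) < 2) next
    m <- numeric(length(t))
    m[pre] <- mean(ly[pre]); m[plat] <- mean(ly[plat])
    m[rise] <- mean(ly[pre]) +
      (mean(ly[plat]) - mean(ly[pre])) * (t[rise] - ti) / (tj - ti)
    rss <- sum((ly - m)^2)
    if (rss < best$rss - 1e-12) best <- list(rss = rss, ti = ti, tj = tj)
  }
  expect_equal(est$latent_min, best$ti)
  expect_equal(est$burst_time_min, best$tj)
  expect_equal(est$fit_rss, best$rss)
})

test_that("estimates are scale-invariant and monotone in burst size", {
  cv <- simulate_growth_curve(20, 29, 95, dt = 3, noise_sd = 0.05, seed = 7)
  est1 <- estimate_growth_params(cv)
  cv2 <- growth_curve(cv$times, cv$titers * 37)
  est2 <- estimate_growth_params(cv2)
  expect_equal(est2$latent_min, est1$latent_min)
  expect_equal(est2$burst_time_min, est1$burst_time_min)
  expect_equal(est2$burst_size, est1$burst_size)
  sizes <- vapply(c(5, 20, 80, 320), function(b) {
    estimate_growth_params(simulate_growth_curve(12, 24, b, dt = 1,
                                                 noise_sd = 0))$burst_size
  }, 0)
  expect_true(all(diff(sizes) > 0))
})

test_that("the simulator honours its closed forms", {
  cv <- simulate_growth_curve(10, 20, 1, n0 = 2e5, dt = 3, t_max = 30,
                              noise_sd = 0)
  expect_true(all(cv$titers == 2e5))           # burst size 1: constant
  cv2 <- simulate_growth_curve(10, 20, 50, n0 = 1e5, dt = 3, t_max = 36,
                               noise_sd = 0)
  expect_equal(max(cv2$titers), 5e6)            # plateau n0 x B
  expect_equal(cv2$times, seq(0, 36, 3))        # 3-min sampling grid
  expect_true(all(diff(cv2$titers) >= 0))       # non-decreasing, no noise
  expect_error(simulate_growth_curve(10, 20, -1), "positive")
  expect_error(simulate_growth_curve(25, 20, 10), "latent")
})

test_that("replicate summaries give mean +/- sd", {
  mk <- function(b, l, bt) structure(list(latent_min = l, burst_time_min = bt,
                                          burst_size = b, fit_rss = 0),
                                     class = "growth_params")
  s <- summarize_replicates(list(mk(43, 20, 29), mk(43, 20, 29),
                                 mk(43, 20, 29)))
  expect_equal(s$formatted[s$parameter == "burst_size"], "43 ± 0")
  s2 <- summarize_replicates(list(mk(148, 15, 25), mk(142, 16, 26),
                                  mk(154, 14, 24)))
  expect_equal(s2$mean[s2$parameter == "burst_size"], 148)
  expect_equal(s2$sd[s2$parameter == "burst_size"], 6)
  expect_error(summarize_replicates(list(mk(1, 2, 3))), "2 replicates")
})

test_that("growth CSV round-trips through the reader", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  cv <- simulate_growth_curve(15, 25, 148, dt = 3, noise_sd = 0.05, seed = 2)
  df <- data.frame(time_min = cv$times, pfu_per_ml = cv$titers,
                   replicate = 1L)
  utils::write.csv(df, tmp, row.names = FALSE)
  back <- read_growth_csv(tmp)
  expect_length(back, 1L)
  expect_equal(back[[1]]$titers, cv$titers)
})
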