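test_that("lag/exponential fit recovers noiseless parameters exactly", {
  d <- generate_growth_curve(b = 10, tau = 13, k = 1 / 121, E = 5000,
                             t_max = 400, n = 200)
  g <- glance(fit_lag_exponential(d))
  expect_equal(g$b, 10, tolerance = 1e-6)
  expect_equal(g$tau, 13, tolerance = 1e-6)
  expect_equal(g$k, 1 / 121, tolerance = 1e-6)
  expect_equal(g$E, 5000, tolerance = 1e-6)
  expect_equal(g$kE, 5000 / 121, tolerance = 1e-5)
  td <- tidy(fit_lag_exponential(d))
  expect_setequal(td$term, c("b", "tau", "k", "E"))
})

test_that("median recovered lag is within 5% under 2% noise", {
  taus <- vapply(1:50, function(i) {
    d <- generate_growth_curve(b = 10, tau = 13, k = 1 / 121, E = 5000,
                               t_max = 400, n = 200, noise_frac = 0.02,
                               seed = 100 + i)
    glance(fit_lag_exponential(d))$tau
  }, 0)
  expect_lt(abs(stats::median(taus) - 13) / 13, 0.05)
})

test_that("degenerate inputs are flagged, not fitted", {
  # flat noise: no growth phase
  set.seed(1)
  d <- tibble::tibble(time_s = seq(0, 100, length.out = 50),
                      value = rnorm(50))
  f <- fit_lag_exponential(d)
  expect_true(glance(f)$flagged || glance(f)$kE < 1)
  expect_error(rescale_experiment(d, scale = 0), "nonzero")
})

test_that("affine rescaling leaves tau and k invariant and scales E", {
  d <- generate_growth_curve(b = 400, tau = 20, k = 0.02, E = 3000,
                             t_max = 300, n = 120)
  g0 <- glance(fit_lag_exponential(d))
  g1 <- glance(fit_lag_exponential(rescale_experiment(d, offset = 300,
                                                      scale = 1.7)))
  expect_equal(g1$tau, g0$tau, tolerance = 1e-6)
  expect_equal(g1$k, g0$k, tolerance = 1e-6)
  expect_equal(g1$E, 1.7 * g0$E, tolerance = 1e-6)
  # identity transform
  g2 <- glance(fit_lag_exponential(rescale_experiment(d, 0, 1)))
  expect_equal(g2$E, g0$E, tolerance = 1e-9)
})

test_that("size landscape is a normalized number-weighted census", {
  # all monomers
  l0 <- size_landscape(list(rep(1L, 20), rep(1L, 15)))
  expect_equal(l0$p, 1)
  expect_equal(l0$minus_log_p, 0)
  # alternating frames: one 10-mer + 90 monomers -> P(10) = 1/91
  census <- rep(list(c(rep(1L, 90), 10L)), 5)
  l <- size_landscape(census)
  expect_equal(sum(l$p), 1)
  expect_equal(l$p[l$n == 10], 1 / 91)
  expect_equal(l$minus_log_p[l$n == 10], log(91))
  # mass weighting shifts weight to the large cluster
  lm_ <- size_landscape(census, weighting = "mass")
  expect_equal(lm_$p[lm_$n == 10], 10 / 100)
  # empty window errors
  expect_error(size_landscape(list()), "empty")
})

test_that("plateau intercepts recover constructed landscapes", {
  # exact piecewise curve: rise to n=25, flat to 60, fall beyond
  g <- c(seq(0, 4, length.out = 25), rep(4, 35),
         4 - seq(0.1, 3, length.out = 30))
  land <- tibble::tibble(n = seq_along(g), minus_log_p = g)
  m <- plateau_intercepts(land)
  expect_false(m$no_barrier)
  expect_false(m$no_well)
  expect_equal(m$n1, 25, tolerance = 0.6)
  expect_equal(m$n2, 60, tolerance = 1.5)
  # strictly increasing curve: no plateau at all
  mono <- tibble::tibble(n = 1:50, minus_log_p = seq(0, 10, length.out = 50))
  m2 <- plateau_intercepts(mono)
  expect_true(m2$no_barrier)
  expect_true(m2$no_well)
  # monotone decreasing: no barrier
  m3 <- plateau_intercepts(
    tibble::tibble(n = 1:50, minus_log_p = seq(5, 0, length.out = 50)))
  expect_true(m3$no_barrier)
})

test_that("intercepts from sampled censuses are within 2 trimers (median)", {
  res <- t(vapply(1:20, function(i) {
    lc <- generate_landscape_census(25, 60, barrier_kBT = 4, well_kBT = 3,
                                    n_frames = 400, frame_clusters = 60,
                                    seed = 40 + i)
    m <- plateau_intercepts(size_landscape(lc$census))
    c(m$n1, m$n2)
  }, c(0, 0)))
  expect_lt(abs(stats::median(res[, 1]) - 25), 2)
  expect_lt(abs(stats::median(res[, 2]) - 60), 3)
})

test_that("first passage is monotone in the threshold and handles censoring", {
  # deterministic growth largest(t) = t
  fr <- tibble::tibble(time_s = 0:100, largest = 0:100)
  expect_equal(first_passage_to(fr, 25)$tau_obs, 25)
  t1 <- first_passage_to(fr, 10)$tau_obs
  t2 <- first_passage_to(fr, 80)$tau_obs
  expect_lt(t1, t2)
  cens <- first_passage_to(fr, 1000)
  expect_true(cens$censored)
  expect_true(is.na(cens$tau_obs))
  # renewal-process oracle: exponential waiting times between +1 steps
  set.seed(7)
  rate <- 4
  taus <- vapply(1:200, function(i) {
    w <- cumsum(stats::rexp(30, rate))
    fr <- tibble::tibble(time_s = c(0, w), largest = 0:30)
    first_passage_to(fr, 20)$tau_obs
  }, 0)
  expect_equal(mean(taus), 20 / rate, tolerance = 0.1)
})

test_that("stoichiometry series flags undefined frames", {
  tr <- structure(list(frames = tibble::tibble(
    time_s = 1:3, mem_clathrin = c(40, 40, 10),
    mem_adaptor = c(20, 40, 0))), class = "rd_trajectory")
  s <- stoichiometry_series(tr)
  expect_equal(s$ratio[1:2], c(2, 1))   # low-adaptor regime: 2 clathrin:1
  expect_true(s$undefined[3])
  expect_true(is.na(s$ratio[3]))
})
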