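test_that("burn-in removes floor(fraction * N) leading samples and flags the trace", {
  ex <- phototroph_example()
  mk <- function(n) {
    t <- simulate_posterior_trace(ex$truth, sd = 5, n = n, seed = 1)$trace
    t$burnin_applied <- FALSE
    t
  }

  t100 <- mk(100)
  out <- apply_burn_in(t100, 0.2)
  expect_equal(n_samples(out), 80L)
  expect_true(out$burnin_applied)
  expect_equal(out$burnin_fraction, 0.2)
  # the first 20 samples are the ones dropped
  expect_equal(out$samples[[1L]]$ages, t100$samples[[21L]]$ages)

  expect_equal(n_samples(apply_burn_in(mk(100), 0)), 100L)
  expect_equal(n_samples(apply_burn_in(mk(7), 0.2)), 6L)   # floor(1.4) = 1 dropped

  expect_error(apply_burn_in(out, 0.2), class = "hgtclock_value_error")
  expect_equal(n_samples(apply_burn_in(out, 0.5, force = TRUE)), 40L)
  expect_error(apply_burn_in(mk(10), 1), class = "hgtclock_value_error")
  expect_error(apply_burn_in(mk(10), -0.1), class = "hgtclock_value_error")
})

test_that("HPD is the shortest window of consecutive order statistics, earliest on ties", {
  expect_equal(hpd_interval(rep(100, 10)), c(lower = 100, upper = 100))
  expect_equal(hpd_interval(1:100, 0.95), c(lower = 1, upper = 95))
  expect_error(hpd_interval(5), class = "hgtclock_insufficient_samples")
  expect_error(hpd_interval(1:10, level = 1), class = "hgtclock_value_error")

  for (seed in 1:60) {
    set.seed(seed)
    n <- sample(2:200, 1)
    x <- switch(1 + seed %% 3,
                rnorm(n, 2000, 300),
                rexp(n, 1 / 500),
                runif(n, 0, 4000))
    lv <- sample(c(0.5, 0.8, 0.95, 0.99), 1)
    got <- hpd_interval(x, lv)
    expect_equal(unname(got), brute_hpd(x, lv))
  }
})

test_that("large-sample HPD of a standard normal approaches the analytic interval", {
  set.seed(20260401)
  x <- rnorm(1e5)
  h <- hpd_interval(x, 0.95)
  expect_lt(abs(h[["lower"]] - (-1.959964)), 0.03)
  expect_lt(abs(h[["upper"]] - 1.959964), 0.03)
})

test_that("raising the level never shrinks the HPD width", {
  set.seed(5)
  for (i in 1:10) {
    x <- rgamma(150, 3, 1 / 800)
    w <- vapply(c(0.5, 0.7, 0.9, 0.95, 0.99), function(lv) {
      h <- hpd_interval(x, lv); h[["upper"]] - h[["lower"]]
    }, numeric(1))
    expect_true(all(diff(w) >= 0))
  }
})

test_that("median uses the even-n mean-of-central convention", {
  expect_equal(median_age(c(1, 2, 3)), 2)
  expect_equal(median_age(c(1, 2, 3, 4)), 2.5)
  expect_error(median_age(numeric(0)), class = "hgtclock_insufficient_samples")
  set.seed(8)
  for (i in 1:20) {
    x <- runif(sample(1:50, 1), 0, 3000)
    s <- sort(x); n <- length(s)
    oracle <- if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    expect_equal(median_age(x), oracle)
  }
})

test_that("prob_older counts strict exceedances and reports ties separately", {
  expect_equal(prob_older(c(3, 4, 5), c(1, 2, 3))$probability, 1.0)

  a <- c(rep(2, 92), rep(1, 8))
  b <- rep(1.5, 100)
  h <- prob_older(a, b)
  expect_equal(h$probability, 0.92)
  expect_equal(h$n, 100L)

  hb <- prob_older(b, a)
  expect_equal(h$probability + hb$probability + h$ties / h$n, 1)

  tied <- prob_older(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tied$probability, 0)
  expect_equal(tied$ties, 3L)

  expect_error(prob_older(1:3, 1:4), class = "hgtclock_pairing_error")

  # unpaired mode: exhaustive cross-product oracle on small vectors
  set.seed(3)
  for (i in 1:10) {
    a <- sample(1:40, 25, replace = TRUE)
    b <- sample(1:40, 19, replace = TRUE)
    h <- prob_older(a, b, paired = FALSE)
    grid <- outer(a, b, `>`)
    expect_equal(h$probability, mean(grid))
    expect_equal(h$ties, sum(outer(a, b, `==`)))
    expect_equal(h$n, 25L * 19L)
  }
})

test_that("paired generator honors its marginals, correlation, and degenerate cases", {
  g <- paired_age_generator(2800, 100, 2500, 150, correlation = 0,
                            n = 10000, seed = 77)
  expect_lt(abs(cor(g$a$ages, g$b$ages)), 3 / sqrt(10000))
  expect_lt(abs(mean(g$a$ages) - 2800), 3 * 100 / sqrt(10000))

  gid <- paired_age_generator(2000, 50, 2000, 50, correlation = 1,
                              n = 500, seed = 1)
  h <- prob_older(gid$a, gid$b)
  expect_equal(h$probability, 0)
  expect_equal(h$ties, 500L)

  expect_error(paired_age_generator(1, 1, 1, 1, correlation = 2, n = 10),
               class = "hgtclock_value_error")
})

test_that("model summaries recover simulated truth and keep lower <= median <= upper", {
  ex <- phototroph_example()
  sim <- simulate_posterior_trace(ex$truth, sd = 10, n = 2000, seed = 15)
  crowns <- ex$clades[c("Crown Cyanobacteria", "Crown GNS", "Crown GSB",
                        "Stem GNS")]
  s <- summarize_model(sim$trace, crowns)
  expect_equal(s$node, names(crowns))
  se3 <- 3 * 1.2533 * 10 / sqrt(2000)   # 3 asymptotic SEs of a normal median
  for (i in seq_len(nrow(s))) {
    truth_age <- ex$truth$ages[resolve_node(ex$truth, crowns[[i]])]
    expect_lt(abs(s$median_ma[i] - truth_age), se3 + 0.5)
    expect_true(s$hpd_lower_ma[i] <= s$median_ma[i] &&
                  s$median_ma[i] <= s$hpd_upper_ma[i])
  }

  err <- tryCatch(
    summarize_model(sim$trace, list(clade_definition("bad", "NotATaxon"))),
    hgtclock_summary_error = identity)
  expect_match(conditionMessage(err), "NotATaxon")
})

test_that("summaries after filtering equal summaries of the manually subset trace", {
  ex <- phototroph_example()
  sim <- simulate_posterior_trace(ex$truth, sd = 300, n = 150, seed = 21)
  f <- filter_trace(sim$trace, ex$constraints)
  manual <- hgtclock:::subset_trace(sim$trace, f$result$accepted)
  cl <- ex$clades[c("Crown Cyanobacteria", "Crown GSB")]
  expect_equal(summarize_model(f$trace, cl), summarize_model(manual, cl))
})

test_that("95% HPD intervals carry about 95% of the generating mass", {
  set.seed(99)
  mass <- replicate(200, {
    x <- rnorm(400, 2500, 120)
    h <- hpd_interval(x, 0.95)
    pnorm(h[["upper"]], 2500, 120) - pnorm(h[["lower"]], 2500, 120)
  })
  expect_gt(mean(mass), 0.92)
  expect_lt(mean(mass), 0.97)
})

test_that("HPD width reduction arithmetic", {
  expect_equal(hpd_width_reduction(c(1584, 2674), c(2498, 3004)),
               100 * (1 - 506 / 1090))
  expect_equal(hpd_width_reduction(c(100, 200), c(100, 200)), 0)
  expect_equal(hpd_width_reduction(c(100, 200), c(150, 150)), 100)
  expect_lt(hpd_width_reduction(c(100, 200), c(50, 300)), 0)
  expect_error(hpd_width_reduction(c(100, 100), c(50, 60)),
               class = "hgtclock_value_error")
})
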