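test_that("brain-to-plasma ratios reproduce the published per-rat values", {
  pk <- cbd_pk()
  expect_equal(nrow(pk), 10)
  ratios <- brain_plasma_ratio(pk$plasma_ng_ml, pk$brain_ng_g)
  # 1 h animals
  expect_equal(round(ratios[pk$rat == 1], 3), 4.072)
  expect_equal(round(ratios[pk$rat == 5], 3), 1.070)
  # excluded brain sample: undefined ratio
  expect_true(is.na(ratios[pk$rat == 9]))
  expect_equal(sum(is.na(ratios)), 1)
  # equal concentrations give exactly 1
  expect_equal(brain_plasma_ratio(100, 100), 1)
  expect_error(brain_plasma_ratio(0, 10), "positive")
})

test_that("mean/SEM reproduce the published 1 h summary row", {
  pk <- cbd_pk()
  p1 <- pk$plasma_ng_ml[pk$timepoint_h == 1]
  ms <- mean_sem(p1)
  expect_equal(round(ms$mean, 2), 1976.12)
  expect_equal(round(ms$sem, 2), 1151.41)
  r1 <- brain_plasma_ratio(p1, pk$brain_ng_g[pk$timepoint_h == 1])
  msr <- mean_sem(r1)
  expect_equal(round(msr$mean, 3), 2.577)
  expect_equal(round(msr$sem, 3), 0.524)
  # the printed 24 h dispersion rows follow the sample-SD convention
  p24 <- pk$plasma_ng_ml[pk$timepoint_h == 24]
  expect_equal(round(mean_sem(p24, convention = "sd")$sem, 2), 3.25)
  expect_equal(round(mean_sem(p24)$mean, 2), 24.19)
  # constant series: zero SEM; short series error
  expect_equal(mean_sem(rep(7, 4))$sem, 0)
  expect_error(mean_sem(5), "at least 2")
})

test_that("pk_summary aggregates by timepoint with exclusions honoured", {
  s <- pk_summary(cbd_pk())
  brain24 <- s[s$timepoint_h == 24 & s$quantity == "brain_ng_g", ]
  expect_equal(brain24$n, 4)   # one excluded brain sample
  expect_equal(round(brain24$mean, 1), 91.4)
  ratio24 <- s[s$timepoint_h == 24 & s$quantity == "ratio", ]
  expect_equal(round(ratio24$mean, 3), 3.728)
})

test_that("discrimination index is bounded, antisymmetric, and guarded", {
  expect_equal(discrimination_index(10, 10), 0)
  expect_equal(discrimination_index(10, 0), 1)
  expect_equal(discrimination_index(0, 10), -1)
  set.seed(401)
  tn <- runif(200, 0, 60); tf <- runif(200, 0, 60)
  keep <- tn + tf > 0
  di <- discrimination_index(tn[keep], tf[keep])
  expect_true(all(di >= -1 & di <= 1))
  expect_equal(di, (tn[keep] - tf[keep]) / (tn[keep] + tf[keep]))
  expect_equal(discrimination_index(tf[keep], tn[keep]), -di)
  expect_error(discrimination_index(0, 0), "total")
  expect_error(discrimination_index(-1, 5), ">= 0")

  nor <- tibble::tibble(tn_s = c(20, 15, 30), tf_s = c(10, 15, 5),
                        fam1_s = c(5, 2, 10), fam2_s = c(4, 8, 1))
  out <- nor_di(nor)
  expect_equal(out$included, c(TRUE, FALSE, FALSE))
  expect_equal(out$di[1], 1 / 3)
  expect_true(all(is.na(out$di[2:3])))
})

test_that("kindling bookkeeping follows the two-consecutive rule", {
  expect_equal(kindled_at(c(2, 3, 4, 4, 5)), 4)
  expect_true(is.na(kindled_at(c(4, 3, 4, 3, 4))))
  expect_equal(kindled_at(c(5, 5)), 2)
  expect_true(is.na(kindled_at(c(0, 1, 2))))
  expect_error(kindled_at(integer(0)), "empty")
  expect_error(kindled_at(c(2, 7)), "0-5")
  # brute-force scan oracle on random logs
  oracle <- function(s) {
    hits <- which(s >= 4)
    for (k in hits) if (k > 1 && s[k - 1] >= 4) return(k)
    NA_integer_
  }
  set.seed(402)
  for (i in 1:1000) {
    s <- sample(0:5, sample(1:25, 1), replace = TRUE)
    expect_identical(kindled_at(s), oracle(s))
  }
  # monotone: raising any score never delays kindling
  set.seed(403)
  for (i in 1:50) {
    s <- sample(0:5, 12, replace = TRUE)
    j <- sample(12, 1)
    s2 <- s; s2[j] <- min(5, s2[j] + sample(0:3, 1))
    k1 <- kindled_at(s); k2 <- kindled_at(s2)
    expect_true(is.na(k1) || (!is.na(k2) && k2 <= k1))
  }
  # early-sensitivity screen
  expect_true(ptz_screen_excluded(c(5, 5, 1)))
  expect_false(ptz_screen_excluded(c(5, 4, 5)))
})

test_that("seizure summaries tabulate mortality and kindling descriptives", {
  mk_group <- function(group, n, n_dead, seed) {
    set.seed(seed)
    purrr::map_dfr(seq_len(n), function(r) {
      scores <- pmin(5, pmax(0, round(seq(1, 4.6, length.out = 10) +
                                        rnorm(10, 0, 0.6))))
      tibble::tibble(rat = paste0(group, r), group = group,
                     injection = 1:10, score = scores,
                     latency_s = ifelse(scores >= 4, runif(10, 300, 900), NA),
                     duration_s = ifelse(scores >= 4, runif(10, 30, 120), NA),
                     survived = r > n_dead)
    })
  }
  logs <- dplyr::bind_rows(mk_group("control", 12, 5, 1),
                           mk_group("treated", 12, 1, 2))
  ss <- seizure_summary(logs)
  expect_equal(ss$groups$n, c(12, 12))
  expect_equal(ss$groups$mortality[ss$groups$group == "control"], 5 / 12)
  expect_equal(ss$groups$mortality[ss$groups$group == "treated"], 1 / 12)
  expect_true(all(ss$per_injection$n_generalized >= 0))
  # all-identical logs: zero-variance latency summaries
  same <- dplyr::bind_rows(lapply(1:4, function(r) {
    tibble::tibble(rat = paste0("s", r), group = "g", injection = 1:6,
                   score = c(1, 2, 3, 4, 4, 5),
                   latency_s = c(NA, NA, NA, 600, 600, 600),
                   duration_s = c(NA, NA, NA, 60, 60, 60), survived = TRUE)
  }))
  sss <- seizure_summary(same)
  expect_equal(sss$groups$latency_sem_s, 0, tolerance = 1e-9)
  expect_equal(sss$groups$median_injections_to_kindled, 5)
  expect_error(seizure_summary(same[0, ]), "empty")
})

test_that("simulated logs recover their generating parameters", {
  # score-progression model: P(stage >= 4 at injection i) rises linearly;
  # latency drawn from a fixed normal. Summaries should match the
  # generating parameters within Monte-Carlo error.
  set.seed(404)
  true_lat <- 600
  logs <- purrr::map_dfr(1:40, function(r) {
    p <- pmin(0.95, 0.05 + 0.09 * (1:12))
    scores <- ifelse(runif(12) < p, 4, 2)
    tibble::tibble(rat = r, group = "sim", injection = 1:12, score = scores,
                   latency_s = ifelse(scores >= 4, rnorm(12, true_lat, 50), NA),
                   duration_s = ifelse(scores >= 4, rnorm(12, 75, 10), NA),
                   survived = TRUE)
  })
  ss <- seizure_summary(logs)
  expect_equal(ss$groups$latency_mean_s, true_lat, tolerance = 0.02)
  expect_equal(ss$groups$duration_mean_s, 75, tolerance = 0.05)
  # per-injection generalized counts increase with the generating ramp
  pi_ <- ss$per_injection
  expect_gt(mean(pi_$n_generalized[pi_$injection > 6]),
            mean(pi_$n_generalized[pi_$injection <= 6]))
})
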