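test_that("generative parameters are validated", {
  expect_error(gen_params(p_store = 1.2), "\\[0, 1\\]")
  expect_error(gen_params(lapse = -0.1), "\\[0, 1\\]")
  expect_error(gen_params(survival_T2 = 0.8, tested_boost = 1.5), "tested_boost")
  expect_error(gen_params(n_participants = 0), "n_participants")
  p <- gen_params(seed = 1)
  expect_s3_class(p, "gen_params")
  expect_equal(p$p_guess, 1 / 6)
})

test_that("degenerate parameters force the boundary outcomes", {
  co <- simulate_cohort(
    gen_params(p_store = 1, lapse = 0, survival_T2 = 1,
               n_participants = 2, seed = 2),
    experiment_config(2, "closed"))
  expect_true(all(co$trials$response == "correct"))

  co0 <- simulate_cohort(gen_params(p_store = 0, n_participants = 8, seed = 3),
                         experiment_config(2, "closed"))
  acc <- tapply(co0$trials$response == "correct", co0$trials$session, mean)
  n_per <- table(co0$trials$session)
  for (s in c("T1", "T2")) {
    se <- sqrt((1 / 6) * (5 / 6) / n_per[[s]])
    expect_lt(abs(acc[[s]] - 1 / 6), 4 * se)
  }
})

test_that("marginal accuracy matches the closed form at T1", {
  params <- gen_params(p_store = 0.72, lapse = 0.03, survival_T2 = 0.5,
                       n_participants = 40, seed = 4)
  co <- simulate_cohort(params, experiment_config(2, "closed"))
  t1 <- co$trials[co$trials$session == "T1", ]
  expected <- params$p_store * (1 - params$lapse) +
    (1 - params$p_store) * params$p_guess
  # clustering through shared event storage dominates the error; bound it by
  # the storage-proportion sd across 40 x 30 events plus the binomial part
  n_events <- 40 * 30
  se <- sqrt(params$p_store * (1 - params$p_store) / n_events) *
    (1 - params$lapse - params$p_guess) + sqrt(0.25 / nrow(t1))
  expect_lt(abs(mean(t1$response == "correct") - expected), 4 * se)
})

test_that("cohorts are deterministic and participants independent", {
  p <- gen_params(n_participants = 3, seed = 7)
  co1 <- simulate_cohort(p, experiment_config(2, "closed"))
  co2 <- simulate_cohort(p, experiment_config(2, "closed"))
  expect_identical(co1$trials, co2$trials)
  expect_equal(length(unique(co1$trials$participant)), 3L)
  # different participants get different triplet assignments and responses
  t1 <- co1$trials[co1$trials$participant == "P001", ]
  t2 <- co1$trials[co1$trials$participant == "P002", ]
  expect_false(identical(t1$response, t2$response))
})

test_that("holistic T2 dependency matches the exact latent-state expectation", {
  # exhaustive enumeration over the latent states of a closed-loop event at
  # T2 (surviving trace vs none), including the finite-N covariance term the
  # plug-in independence model introduces
  ps <- 0.7; lapse <- 0.05; sv <- 0.6; pg <- 1 / 6; n_ev <- 30
  w <- ps * sv
  q1 <- 1 - lapse; q0 <- pg
  p <- w * q1 + (1 - w) * q0
  joint_data <- w * (q1^2 + (1 - q1)^2) + (1 - w) * (q0^2 + (1 - q0)^2)
  cov_xy <- (w * q1^2 + (1 - w) * q0^2) - p^2
  expected_dep <- joint_data - (p^2 + (1 - p)^2) - 2 * cov_xy / n_ev

  co <- simulate_cohort(
    gen_params(p_store = ps, lapse = lapse, survival_T2 = sv,
               n_participants = 200, seed = 5),
    experiment_config(2, "closed"))
  fit <- retdep(co)
  dep2 <- fit$results$dependency[fit$results$session == "T2"]
  expect_equal(length(dep2), 200L)
  expect_equal(unique(fit$results$n_events[fit$results$session == "T2"]), n_ev)
  se <- sd(dep2) / sqrt(length(dep2))
  expect_lt(abs(mean(dep2) - expected_dep), 4 * se)
})

test_that("independent associations yield no dependency; holistic regimes diverge", {
  # independent encoding: population dependency ~ 0
  co_ind <- simulate_cohort(
    gen_params(encoding_mode = "independent_associations",
               n_participants = 120, seed = 6),
    experiment_config(2, "closed"))
  fit_ind <- retdep(co_ind)
  for (s in c("T1", "T2")) {
    v <- fit_ind$results$dependency[fit_ind$results$session == s]
    expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(length(v)))
  }

  # holistic + all-or-none: dependency clearly positive at both sessions and
  # not diluted by forgetting
  co_hol <- simulate_cohort(gen_params(n_participants = 60, seed = 7),
                            experiment_config(2, "closed"))
  fit_hol <- retdep(co_hol)
  r <- fit_hol$results
  d1 <- r$dependency[r$session == "T1"]
  d2 <- r$dependency[r$session == "T2"]
  expect_gt(one_sample_t(d1)$t, 2)
  expect_gt(one_sample_t(d2)$t, 2)
  expect_gt(mean(d2), mean(d1) - 2 * sd(d2 - d1) / sqrt(length(d1)))

  # holistic + association-independent forgetting: fragmentation lowers T2
  # dependency below T1
  co_fr <- simulate_cohort(
    gen_params(forgetting_mode = "association_independent",
               n_participants = 60, seed = 8),
    experiment_config(2, "closed"))
  fit_fr <- retdep(co_fr)
  rf <- fit_fr$results
  f1 <- rf$dependency[rf$session == "T1"]
  f2 <- rf$dependency[rf$session == "T2"]
  expect_lt(one_sample_t(f2 - f1)$t, -2)
})

test_that("open-loops carry four administered directions and little dependency", {
  co <- simulate_cohort(gen_params(n_participants = 40, seed = 9),
                        experiment_config(2, "open"))
  fit <- retdep(co)
  expect_true(all(fit$results$loop_type == "open"))
  m <- fit$matrices[[1]]
  expect_true(all(colSums(!is.na(m$resp)) == 4))
  # holistic storage never applies to open-loops, so no dependency emerges
  v <- fit$results$dependency[fit$results$session == "T1"]
  expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(length(v)))
})
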