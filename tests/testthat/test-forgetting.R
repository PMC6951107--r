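# a 6 x 30 closed-loop matrix with exactly `k` correct cells, positive
# dependency (correct cells concentrated in whole events first)
structured_matrix <- function(k, n_ev = 30) {
  resp <- matrix(0L, 6, n_ev)
  full <- k %/% 6
  resp[, seq_len(full)] <- 1L
  rem <- k %% 6
  if (rem > 0) resp[seq_len(rem), full + 1] <- 1L
  make_closed_matrix(resp)
}

test_that("flip counts follow the accuracy-matching rule", {
  m <- structured_matrix(126)  # accuracy .70 over 180 cells
  s <- simulate_t2_matrix(m, target_accuracy = 0.43, seed = 1)
  expect_equal(attr(s, "flips"), round((0.70 - 0.43) * 180))  # 49
  expect_equal(sum(s$resp), 126 - 49)
  expect_lte(abs(accuracy(s) - 0.43), 1 / 180)
  # only correct cells were touched
  expect_true(all(s$resp[m$resp == 0L] == 0L))

  # identity when the target equals current accuracy
  s0 <- simulate_t2_matrix(m, target_accuracy = 126 / 180, seed = 2)
  expect_identical(s0$resp, m$resp)
  # boundary: target 0 clears every correct cell
  sall <- simulate_t2_matrix(m, target_accuracy = 0, seed = 3)
  expect_true(all(sall$resp == 0L))
  # the model cannot add memories
  expect_warning(sup <- simulate_t2_matrix(m, target_accuracy = 0.9, seed = 4),
                 "only removes")
  expect_identical(sup$resp, m$resp)
  expect_error(simulate_t2_matrix(m, target_accuracy = 1.2), "\\[0, 1\\]")
})

test_that("open-loop matrices are rejected by the forgetting model", {
  co <- small_cohort(n = 1, seed = 41, loop = "open")
  fit <- retdep(co)
  m_open <- fit$matrices[["P001.T1.open"]]
  expect_error(simulate_t2_matrix(m_open, 0.4), "closed-loop")
  expect_error(forgetting_model_dependency(m_open, 0.4, n_sims = 2), "closed-loop")
})

test_that("zero forgetting reproduces observed dependency exactly", {
  co <- small_cohort(n = 1, seed = 42)
  fit <- retdep(co)
  m1 <- fit$matrices[["P001.T1.closed"]]
  obs <- dependency_for_participant(m1)
  sim <- forgetting_model_dependency(m1, accuracy(m1), n_sims = 5, seed = 6)
  expect_equal(sim$mean_dependency, obs$dependency)
  expect_equal(unique(sim$sims$dependency), obs$dependency)
  expect_error(forgetting_model_dependency(m1, 0.4, n_sims = 0), "n_sims")
})

test_that("every simulated matrix hits the target accuracy within 1/(6N)", {
  co <- small_cohort(n = 1, seed = 43)
  fit <- retdep(co)
  m1 <- fit$matrices[["P001.T1.closed"]]
  n_cells <- length(m1$resp)
  for (target in c(0.2, 0.35, 0.5, accuracy(m1))) {
    sim <- forgetting_model_dependency(m1, target, n_sims = 30, seed = 7)
    expect_true(all(abs(sim$sims$accuracy - target) <= 1 / n_cells + 1e-12))
  }
})

test_that("independent deletion preserves independence", {
  # matrices generated without any event-level binding keep ~0 dependency
  # after simulated forgetting
  co <- simulate_cohort(
    gen_params(encoding_mode = "independent_associations",
               n_participants = 40, seed = 44),
    experiment_config(2, "closed"))
  fit <- retdep(co)
  sims <- vapply(unique(fit$results$participant), function(p) {
    m1 <- fit$matrices[[paste0(p, ".T1.closed")]]
    forgetting_model_dependency(m1, max(0, accuracy(m1) - 0.25),
                                n_sims = 40, seed = 45)$mean_dependency
  }, numeric(1))
  expect_lt(abs(mean(sims)), 3 * sd(sims) / sqrt(length(sims)))
})

test_that("dependency dilutes monotonically with the number of flips", {
  co <- small_cohort(n = 1, seed = 46)
  fit <- retdep(co)
  m1 <- fit$matrices[["P001.T1.closed"]]
  expect_gt(dependency_for_participant(m1)$dependency, 0.05)
  targets <- accuracy(m1) - c(0.05, 0.15, 0.25, 0.35)
  means <- vapply(seq_along(targets), function(i) {
    forgetting_model_dependency(m1, targets[i], n_sims = 1000,
                                seed = 47 + i)$mean_dependency
  }, numeric(1))
  expect_true(all(diff(means) <= 0.02))  # non-increasing up to Monte-Carlo noise
})

test_that("Monte-Carlo means are stable across seed streams", {
  co <- small_cohort(n = 1, seed = 48)
  fit <- retdep(co)
  m1 <- fit$matrices[["P001.T1.closed"]]
  a <- forgetting_model_dependency(m1, 0.45, n_sims = 400, seed = 100)
  b <- forgetting_model_dependency(m1, 0.45, n_sims = 400, seed = 200)
  se <- sqrt(sd(a$sims$dependency)^2 / 400 + sd(b$sims$dependency)^2 / 400)
  expect_lt(abs(a$mean_dependency - b$mean_dependency), 3 * se)
  # same seed, same stream
  c2 <- forgetting_model_dependency(m1, 0.45, n_sims = 400, seed = 100)
  expect_identical(a$sims, c2$sims)
})

test_that("the Bernoulli flip scheme approximates the target on average", {
  m <- structured_matrix(126)
  accs <- vapply(1:50, function(i) {
    accuracy(simulate_t2_matrix(m, 0.4, seed = i, method = "bernoulli"))
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.4), 0.02)
  expect_gt(sd(accs), 0)  # unlike the exact scheme, achieved accuracy varies
})
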