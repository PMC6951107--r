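test_that("triplet generation respects counts, balance and determinism", {
  tr <- generate_triplets(60, "open", seed = 1)
  expect_equal(nrow(tr), 60)
  expect_true(all(tr$loop_type == "open"))
  # open-loops balanced over the three possible common elements
  expect_equal(as.integer(sort(table(tr$common_category))), c(20, 20, 20))

  trw <- generate_triplets(2, "within", seed = 3)
  expect_equal(sort(trw$loop_type), c("closed", "open"))

  expect_identical(generate_triplets(60, "within", seed = 9),
                   generate_triplets(60, "within", seed = 9))
  expect_error(generate_triplets(3, "within"), "even")
  expect_error(generate_triplets(10, "closed", pool_size = 5), "pool")

  # no element shared between triplets, one per category
  expect_false(anyDuplicated(tr$location) > 0)
  expect_false(anyDuplicated(tr$person) > 0)
  expect_false(anyDuplicated(tr$object) > 0)
})

test_that("encoding schedules have the published structure", {
  cl <- generate_triplets(60, "closed", seed = 2)
  op <- generate_triplets(60, "open", seed = 2)
  wi <- generate_triplets(60, "within", seed = 2)

  e_cl <- build_encoding_schedule(cl, experiment_config(1, "closed"), seed = 4)
  expect_equal(nrow(e_cl), 180)
  expect_equal(as.integer(table(e_cl$block)), rep(60L, 3))
  # one pair from each triplet per block
  for (b in 1:3)
    expect_equal(sort(e_cl$triplet_id[e_cl$block == b]), 1:60)
  # each closed triplet contributes each pair exactly once
  expect_true(all(table(e_cl$triplet_id, e_cl$pair) == 1))

  e_op <- build_encoding_schedule(op, experiment_config(1, "open"), seed = 4)
  expect_equal(nrow(e_op), 120)
  expect_equal(as.integer(table(e_op$block)), rep(60L, 2))
  # the non-encoded pair of an open-loop never appears
  for (i in seq_len(nrow(op))) {
    enc <- e_op$pair[e_op$triplet_id == op$triplet_id[i]]
    expect_equal(length(enc), 2L)
    expect_true(all(grepl(op$common_category[i], enc)))
  }

  e_wi <- build_encoding_schedule(wi, experiment_config(3), seed = 4)
  expect_equal(nrow(e_wi), 150)
  expect_equal(as.integer(table(e_wi$block)), c(30L, 60L, 60L))
  # first block is closed-loops only
  expect_true(all(e_wi$loop_type[e_wi$block == 1] == "closed"))

  # counting identity: 3 trials per closed, 2 per open
  expect_equal(nrow(e_wi), 3 * sum(wi$loop_type == "closed") +
                             2 * sum(wi$loop_type == "open"))
  expect_error(experiment_config(7), "unknown experiment")
})

test_that("test schedules cover every encoded direction exactly once", {
  cl <- generate_triplets(60, "closed", seed = 5)
  op <- generate_triplets(60, "open", seed = 5)
  wi <- generate_triplets(60, "within", seed = 5)

  t_cl2 <- build_test_schedule(cl, "T2", experiment_config(1, "closed"), seed = 6)
  expect_equal(nrow(t_cl2), 360)
  expect_false(any(duplicated(t_cl2[c("triplet_id", "cue_role", "target_role")])))
  expect_equal(as.integer(table(t_cl2$block)), rep(60L, 6))

  t_cl1 <- build_test_schedule(cl, "T1", experiment_config(1, "closed"), seed = 6)
  expect_equal(nrow(t_cl1), 180)
  expect_true(all(t_cl1$tested_at_T1))

  t_op2 <- build_test_schedule(op, "T2", experiment_config(1, "open"), seed = 6)
  expect_equal(sum(t_op2$trial_kind == "direct"), 240)
  expect_equal(sum(t_op2$trial_kind == "inference"), 120)
  # inference trials test the never-encoded pair in both directions
  inf <- t_op2[t_op2$trial_kind == "inference", ]
  for (i in seq_len(nrow(op))) {
    rows <- inf[inf$triplet_id == op$triplet_id[i], ]
    expect_equal(nrow(rows), 2L)
    expect_false(any(c(rows$cue_role, rows$target_role) == op$common_category[i]))
  }

  t_wi <- build_test_schedule(wi, "T2", experiment_config(3), seed = 6)
  expect_equal(nrow(t_wi), 300)
  # open-loops: only the 4 directions involving the common element, over 4 blocks
  for (i in which(wi$loop_type == "open")) {
    rows <- t_wi[t_wi$triplet_id == wi$triplet_id[i], ]
    expect_equal(nrow(rows), 4L)
    expect_true(all(rows$cue_role == wi$common_category[i] |
                      rows$target_role == wi$common_category[i]))
    expect_equal(length(unique(rows$block)), 4L)
  }
  expect_error(build_test_schedule(wi, "T1", experiment_config(3)), "no immediate test")
  expect_error(loopdep:::build_inference_trials(cl, 6L), "open-loops")

  # determinism
  expect_identical(build_test_schedule(wi, "T2", experiment_config(3), seed = 6), t_wi)
})

test_that("experiment 4 immediate test has 150 trials over six blocks", {
  wi <- generate_triplets(60, "within", seed = 8)
  t1 <- build_test_schedule(wi, "T1", experiment_config(4), seed = 9)
  expect_equal(nrow(t1), 150)  # 15 closed x 6 + 15 open x 4
  expect_equal(sum(wi$tested_at_T1 & wi$loop_type == "closed"), 15)
  expect_lte(max(t1$block), 6)
  expect_equal(experiment_config(4)$break_every[["T1"]], 25L)
})

test_that("foil sets contain the target once among five same-category foils", {
  tr <- generate_triplets(60, "closed", seed = 10)
  sch <- build_test_schedule(tr, "T2", experiment_config(1, "closed"), seed = 11)
  positions <- integer(0)
  for (i in 1:60) {
    fs <- foil_set(sch[i, ], tr, seed = 100 + i)
    expect_equal(length(fs$options), 6L)
    expect_false(any(duplicated(fs$options)))
    expect_equal(fs$options[fs$target_position], fs$target)
    role <- sch$target_role[i]
    expect_equal(fs$target, tr[[role]][tr$triplet_id == sch$triplet_id[i]])
    # foils come from other triplets' elements of the same category
    expect_true(all(fs$options %in% tr[[role]]))
    positions <- c(positions, fs$target_position)
  }
  expect_gte(length(unique(positions)), 4)  # spread over the six slots
  expect_identical(foil_set(sch[1, ], tr, seed = 1),
                   foil_set(sch[1, ], tr, seed = 1))
  tiny <- generate_triplets(6, "closed", seed = 1)
  sch6 <- build_test_schedule(tiny, "T2", experiment_config(2, "closed"), seed = 2)
  fs <- foil_set(sch6[1, ], tiny, seed = 3)
  expect_equal(sort(fs$options), sort(tiny[[sch6$target_role[1]]]))
  expect_error(foil_set(sch6[1, ], tiny[1:4, ]), "foils")
})
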