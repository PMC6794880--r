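test_that("G1 weights match closed forms in small cases", {
  # n = 2: w = (r/(1+r), 1/(1+r))
  j <- expert_judgement("E", c("A", "B"), 1.8)
  expect_equal(g1_weight_vector(j), c(A = 1.8 / 2.8, B = 1 / 2.8),
               tolerance = 1e-12)

  # all ratios 1.0 forces exact uniformity
  j11 <- expert_judgement("E", sprintf("F%02d", 1:11), rep(1.0, 10))
  expect_equal(unname(g1_weight_vector(j11)), rep(1 / 11, 11),
               tolerance = 1e-15)
})

test_that("first case-study expert's weights match the recursion oracle", {
  cs <- pain_case_study()
  j <- cs$panel[[1]]
  w <- g1_weight_vector(j, cs$hierarchy)
  # frozen from the independent recursion oracle
  expect_equal(unname(w["C11"]), 0.2087083923, tolerance = 1e-9)
  expect_equal(unname(w["C51"]), 0.0104204904, tolerance = 1e-9)
  # full agreement with the straight recursion, re-indexed
  expect_equal(w, g1_oracle(j$order, j$ratios)[names(w)], tolerance = 1e-12)
})

test_that("weights normalize, decrease along the order, and rebuild the ratios", {
  for (s in 1:40) {
    panel <- gen_panel(n_criteria = sample(3:8, 1), n_experts = 1,
                       ratio_mode = "grid", seed = s)
    j <- panel[[1]]
    w <- g1_weight_vector(j)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    ww <- w[j$order]
    expect_true(all(diff(ww) <= 1e-12))
    expect_equal(unname(ww[-length(ww)] / ww[-1]), j$ratios,
                 tolerance = 1e-9)
    # and the vectorized evaluation equals the step-by-step recursion
    expect_equal(w, g1_oracle(j$order, j$ratios)[names(w)],
                 tolerance = 1e-12)
  }
})

test_that("raising one ratio shifts weight to all higher-ranked positions", {
  ids <- sprintf("F%02d", 1:6)
  r0 <- rep(1.2, 5)
  w0 <- g1_weight_vector(expert_judgement("E", ids, r0))[ids]
  for (k in 2:6) {
    r1 <- r0
    r1[k - 1] <- r0[k - 1] + 0.3
    w1 <- g1_weight_vector(expert_judgement("E", ids, r1))[ids]
    above <- 1:(k - 1)
    below <- k:6
    expect_true(all(w1[above] > w0[above]))
    expect_true(all(w1[below] < w0[below]))
  }
})

test_that("invalid judgements are rejected; off-grid ratios warn or error", {
  h <- toy_hierarchy()
  ids <- leaf_criteria(h)$id

  expect_error(expert_judgement("E", ids, c(1.2, 1.3)), "ratios")
  bad <- expert_judgement("E", ids, c(1.2, 0.9, 1.1))
  expect_match(validate_judgement(bad, h)$check, "ratio_bound", all = FALSE)
  expect_error(g1_weight_vector(bad, h), "ratio < 1")

  not_perm <- expert_judgement("E", c("L1", "L2", "L3", "L3"), rep(1.1, 3))
  expect_match(validate_judgement(not_perm, h)$check, "permutation",
               all = FALSE)

  off <- expert_judgement("E", ids, c(1.25, 1.1, 1.1))
  expect_equal(nrow(validate_judgement(off, h)), 0L)  # legal when not strict
  expect_match(validate_judgement(off, h, strict_grid = TRUE)$check,
               "ratio_grid", all = FALSE)
  expect_warning(g1_weight_vector(off, h), "grid")
  expect_error(g1_weight_vector(off, h, strict_grid = TRUE), "grid")
  expect_silent(g1_weight_vector(off, h, warn_off_grid = FALSE))

  # a clean case-study judgement passes strict validation
  cs <- pain_case_study()
  expect_equal(nrow(validate_judgement(cs$panel[[2]], cs$hierarchy,
                                       strict_grid = TRUE)), 0L)
})

test_that("panel aggregation is the component-wise mean over a shared leaf set", {
  expect_equal(
    aggregate_weight_vectors(list(c(a = 0.7, b = 0.3), c(a = 0.3, b = 0.7))),
    c(a = 0.5, b = 0.5))
  one <- c(a = 0.2, b = 0.5, c = 0.3)
  expect_equal(aggregate_weight_vectors(list(one)), one)
  # order-insensitive: vectors may index the leaves in any order
  expect_equal(
    aggregate_weight_vectors(list(c(a = 0.6, b = 0.4), c(b = 0.4, a = 0.6))),
    c(a = 0.6, b = 0.4))
  expect_error(
    aggregate_weight_vectors(list(c(a = 0.5, b = 0.5), c(a = 0.5, z = 0.5))),
    "symmetric difference.*[bz]")
  expect_error(aggregate_weight_vectors(list()), "non-empty")
})
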