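test_that("column vector normalization matches the hand-checked column", {
  # first criterion column of the case-study matrix: (3, 2, 1, 1.5),
  # norm sqrt(16.25)
  cs <- pain_case_study()
  N <- normalize_matrix(cs$scores)
  expect_equal(unname(N[, "C11"]), c(3, 2, 1, 1.5) / sqrt(16.25),
               tolerance = 1e-12)
  expect_equal(round(unname(N[, "C11"]), 4), c(0.7442, 0.4961, 0.2481, 0.3721))
  # every column has unit Euclidean norm
  expect_equal(unname(sqrt(colSums(N^2))), rep(1, ncol(N)), tolerance = 1e-9)
  # row variant normalizes rows instead
  Nr <- normalize_matrix(cs$scores, "vector_row")
  expect_equal(unname(sqrt(rowSums(Nr^2))), rep(1, nrow(Nr)),
               tolerance = 1e-9)
})

test_that("degenerate matrices are rejected by construction or normalization", {
  expect_error(decision_matrix(matrix(1, 1, 3)), "two alternatives")
  expect_error(decision_matrix(matrix(c(1, NA, 2, 3), 2)), "missing")
  expect_error(decision_matrix(matrix(c(1, -1, 2, 3), 2)), ">= 0")
  Dz <- decision_matrix(cbind(a = c(0, 0), b = c(1, 2)))
  expect_error(normalize_matrix(Dz), "zero-norm column.*a")
})

test_that("weighting scales columns and validates coverage", {
  N <- normalize_matrix(decision_matrix(rbind(c(3, 1), c(1, 3))))
  V <- apply_weights(N, c(F2 = 0.25, F1 = 0.75))
  expect_equal(unname(`attributes<-`(V / N, NULL)),
               c(0.75, 0.75, 0.25, 0.25))
  expect_error(apply_weights(N, c(F1 = 1)), "F2")
  # zero weight blanks a column
  expect_equal(unname(apply_weights(N, c(F1 = 0, F2 = 1))[, 1]), c(0, 0))
})

test_that("ideal solutions respect per-column directions", {
  W <- cbind(x = c(0.1, 0.4), y = c(0.2, 0.2))
  ben <- ideal_solutions(W, "benefit")
  expect_equal(ben$positive[["x"]], 0.4)
  expect_equal(ben$negative[["x"]], 0.1)
  # constant column: both ideals coincide, contributes nothing to distances
  expect_equal(ben$positive[["y"]], ben$negative[["y"]])
  mix <- ideal_solutions(W, c(x = "cost", y = "benefit"))
  expect_equal(mix$positive[["x"]], 0.1)
  expect_equal(mix$negative[["x"]], 0.4)
})

test_that("separations are Euclidean distances to the ideal pair", {
  W <- rbind(A = c(0, 0), B = c(3, 4))
  ids <- ideal_solutions(W, "benefit")
  S <- separations(W, ids)
  expect_equal(S$d_pos, c(5, 0))  # 3-4-5 triangle
  expect_equal(S$d_neg, c(0, 5))
  cc <- closeness_and_rank(S)
  expect_equal(cc$closeness, c(0, 1))
  expect_equal(cc$rank, c(2L, 1L))
})

test_that("closeness handles ties and the all-identical degenerate case", {
  S <- data.frame(alternative = c("A", "B"), d_pos = c(1, 1), d_neg = c(1, 1))
  cc <- closeness_and_rank(S)
  expect_equal(cc$closeness, c(0.5, 0.5))
  expect_equal(cc$rank, c(1L, 1L))  # competition ranking: shared rank 1

  # m identical alternatives: 0/0 convention gives 0.5 everywhere
  D <- decision_matrix(matrix(2, 3, 4))
  res <- run_topsis(D)
  expect_equal(res$scores$closeness, rep(0.5, 3))
  expect_equal(res$scores$rank, rep(1L, 3))

  # near-ties beyond 1e-12 are distinct ranks; "1224" pattern
  S4 <- data.frame(alternative = letters[1:4],
                   d_pos = c(1, 2, 2, 3), d_neg = c(3, 2, 2, 1))
  expect_equal(closeness_and_rank(S4)$rank, c(1L, 2L, 2L, 4L))
})

test_that("run_topsis equals the straight-line oracle on random matrices", {
  for (s in 1:60) {
    m <- sample(2:5, 1); n <- sample(2:6, 1)
    D <- gen_score_matrix(m, n, seed = s)
    w <- withr::with_seed(s, stats::runif(n, 0.1, 1))
    w <- w / sum(w)
    dirs <- withr::with_seed(s + 1000L,
                             sample(c("benefit", "cost"), n, replace = TRUE))
    res <- run_topsis(D, w, directions = dirs)
    expect_equal(res$scores$closeness, topsis_oracle(D, w, dirs),
                 tolerance = 1e-12)
    expect_true(all(res$scores$closeness >= 0 & res$scores$closeness <= 1))
  }
})

test_that("closeness is invariant to weight scaling and equivariant to row permutation", {
  D <- gen_score_matrix(4, 6, seed = 42)
  w <- withr::with_seed(42, stats::runif(6, 0.1, 1))
  base <- run_topsis(D, w)$scores$closeness
  expect_equal(run_topsis(D, w * 37.5)$scores$closeness, base,
               tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  Dp <- decision_matrix(unclass(D)[perm, ])
  expect_equal(run_topsis(Dp, w)$scores$closeness, base[perm],
               tolerance = 1e-12)
})

test_that("a columnwise-dominant alternative attains closeness 1 and rank 1", {
  D <- decision_matrix(rbind(c(3, 3, 3), c(1, 2, 1), c(2, 1, 2)))
  res <- run_topsis(D)
  expect_equal(res$scores$closeness[1], 1)
  expect_equal(res$scores$rank[1], 1L)
  # under cost direction everywhere, dominance flips
  resc <- run_topsis(D, directions = "cost")
  expect_equal(resc$scores$closeness[1], 0)
})

test_that("direction flip on one column swaps its contribution between ideals", {
  D <- gen_score_matrix(4, 5, seed = 9)
  w <- rep(1 / 5, 5)
  ben <- run_topsis(D, w)
  flip <- run_topsis(D, w, directions = c("cost", rep("benefit", 4)))
  V <- flip$weighted
  expect_equal(ben$ideals$positive[[1]], flip$ideals$negative[[1]])
  expect_equal(ben$ideals$negative[[1]], flip$ideals$positive[[1]])
})

test_that("removing a constant column never changes closeness", {
  D <- gen_score_matrix(4, 5, seed = 11)
  Dc <- decision_matrix(cbind(unclass(D), K = rep(2, 4)))
  w5 <- rep(1, 5); w6 <- c(w5, 1)
  expect_equal(run_topsis(Dc, w6)$scores$closeness,
               run_topsis(D, w5)$scores$closeness, tolerance = 1e-12)
})
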