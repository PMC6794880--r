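# Independent straight-line oracles, deliberately written loop-by-loop and
# kept free of any package internals, so implementation and oracle can only
# agree by computing the same mathematics.

# G1 weights by explicit recursion w_(j-1) = r_j * w_(j): unnormalized tail
# weight 1, walk upwards, divide by the sum.
g1_oracle <- function(order, ratios) {
  n <- length(order)
  u <- numeric(n)
  u[n] <- 1
  for (j in n:2) u[j - 1L] <- ratios[j - 1L] * u[j]
  w <- u / sum(u)
  names(w) <- order
  w
}

# TOPSIS steps 2-6, spreadsheet style: one cell at a time.
topsis_oracle <- function(D, w, directions = rep("benefit", ncol(D))) {
  D <- as.matrix(D)
  m <- nrow(D); n <- ncol(D)
  R <- matrix(0, m, n)
  for (j in 1:n) {
    s <- 0
    for (i in 1:m) s <- s + D[i, j]^2
    for (i in 1:m) R[i, j] <- D[i, j] / sqrt(s)
  }
  V <- matrix(0, m, n)
  for (i in 1:m) for (j in 1:n) V[i, j] <- w[j] * R[i, j]
  vp <- numeric(n); vn <- numeric(n)
  for (j in 1:n) {
    if (directions[j] == "benefit") {
      vp[j] <- max(V[, j]); vn[j] <- min(V[, j])
    } else {
      vp[j] <- min(V[, j]); vn[j] <- max(V[, j])
    }
  }
  cc <- numeric(m)
  for (i in 1:m) {
    dp <- 0; dn <- 0
    for (j in 1:n) {
      dp <- dp + (V[i, j] - vp[j])^2
      dn <- dn + (V[i, j] - vn[j])^2
    }
    dp <- sqrt(dp); dn <- sqrt(dn)
    cc[i] <- if (dp + dn == 0) 0.5 else dn / (dp + dn)
  }
  cc
}

# a tiny two-main, four-leaf hierarchy used across tests
toy_hierarchy <- function() {
  build_hierarchy(list(
    main = list(list(id = "M1"), list(id = "M2")),
    leaves = list(
      list(id = "L1", parent = "M1"),
      list(id = "L2", parent = "M1"),
      list(id = "L3", parent = "M2"),
      list(id = "L4", parent = "M2"))))
}
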