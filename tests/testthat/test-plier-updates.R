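test_that("row standardization matches direct recomputation and flags constants", {
  expect_equal(as.numeric(standardize_rows(matrix(c(1, 2, 3), 1))),
               c(-1, 0, 1))
  m <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("f", 1:5), NULL))
  m[3, ] <- 0.7
  s <- standardize_rows(m)
  # oracle: direct (x - mean)/sd per row
  for (i in c(1, 2, 4, 5)) {
    expect_equal(s[i, ], (m[i, ] - mean(m[i, ])) / sd(m[i, ]), tolerance = 1e-12)
  }
  expect_equal(s[3, ], rep(0, 4), ignore_attr = TRUE)
  expect_equal(attr(s, "constant_rows"), "f3")
})

test_that("the objective evaluates the four displayed terms", {
  D <- matrix(c(1, 3, 2, 4), 2)
  Z <- diag(2)
  B <- matrix(1, 2, 2)
  C <- matrix(1, 2, 1)
  U <- matrix(c(1, 2), 1)
  obj <- plier_objective(D, C, Z, U, B, 1, 1, 1)
  # scalar arithmetic oracle: 14 + 6 + 4 + 3
  expect_equal(as.numeric(obj), 27)
  expect_equal(unname(attr(obj, "terms")), c(14, 6, 4, 3))

  # perfect reconstruction with no penalties is zero
  expect_equal(as.numeric(plier_objective(Z %*% B, C, Z, U, B, 0, 0, 0)), 0)

  # homogeneity on D = 0: c^4 reconstruction + c^2 ridge
  set.seed(1)
  Z2 <- matrix(abs(rnorm(6)), 2, 3); B2 <- matrix(rnorm(9), 3, 3)
  D0 <- matrix(0, 2, 3)
  U0 <- matrix(0, 1, 3)
  base_recon <- sum((Z2 %*% B2)^2); base_b <- sum(B2^2)
  for (cc in c(0.5, 2)) {
    o <- plier_objective(D0, C, cc * Z2, U0, cc * B2, 0, 1.7, 0)
    expect_equal(as.numeric(o), cc^4 * base_recon + cc^2 * 1.7 * base_b)
  }

  expect_error(plier_objective(D, C, Z, U, matrix(1, 3, 2), 1, 1, 1),
               "shape mismatch")
})

test_that("SVD initialization reproduces rank-1 data and respects the SVD bound", {
  z <- abs(rnorm(8)); b <- abs(rnorm(5))
  D <- z %*% t(b)
  C <- matrix(1, 8, 1)
  init <- plier_init(D, C, k = 1, seed = 1)
  expect_equal(init$Z0 %*% init$B0, D, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(init$U0, matrix(0, 1, 1), ignore_attr = TRUE)

  # determinism
  set.seed(42)
  D2 <- matrix(rnorm(200), 20, 10)
  i1 <- plier_init(D2, matrix(1, 20, 2), 3, seed = 9)
  i2 <- plier_init(D2, matrix(1, 20, 2), 3, seed = 9)
  expect_identical(i1, i2)

  # truncated-SVD oracle: clipped init cannot beat the rank-3 optimum,
  # and must stay within the slack lost to clipping
  sv <- svd(D2)
  D3 <- sv$u[, 1:3] %*% diag(sv$d[1:3]) %*% t(sv$v[, 1:3])
  best <- sqrt(sum((D2 - D3)^2))
  got <- sqrt(sum((D2 - i1$Z0 %*% i1$B0)^2))
  clip_slack <- sqrt(sum((i1$Z0 - sv$u[, 1:3] %*% diag(sv$d[1:3]))^2))
  expect_gte(got, best - 1e-10)
  expect_lte(got, best + clip_slack + 1e-10)

  expect_error(plier_init(D2, matrix(1, 20, 2), 11), "k exceeds")
})

test_that("update_b is the exact ridge minimizer", {
  set.seed(5)
  # orthonormal Z with no penalty is plain projection
  Z <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  D <- matrix(rnorm(24), 6, 4)
  expect_equal(update_b(D, Z, 0), t(Z) %*% D, tolerance = 1e-12)

  # ridge limit: enormous penalty shrinks B to zero
  expect_lt(max(abs(update_b(D, Z, 1e12))), 1e-10)

  # independent oracle: augmented least squares solved by QR, 20 instances
  for (i in 1:20) {
    set.seed(100 + i)
    n <- sample(4:9, 1); k <- sample(2:4, 1); m <- sample(2:6, 1)
    Z <- matrix(rnorm(n * k), n, k)
    D <- matrix(rnorm(n * m), n, m)
    l2 <- runif(1, 0.05, 2)
    B <- update_b(D, Z, l2)
    aug <- rbind(Z, sqrt(l2) * diag(k))
    oracle <- qr.solve(aug, rbind(D, matrix(0, k, m)))
    expect_lt(max(abs(B - oracle)), 1e-6)
  }
})

test_that("update_z solves the prior-regularized ridge and clips at zero", {
  set.seed(6)
  # orthonormal-row B, lambda1 = 0, non-negative truth: exact recovery
  B <- t(qr.Q(qr(matrix(rnorm(30), 10, 3))))
  Ztrue <- matrix(abs(rnorm(18)), 6, 3)
  D <- Ztrue %*% B
  C <- matrix(1, 6, 2); U <- matrix(0, 2, 3)
  expect_equal(update_z(D, B, C, U, 0), Ztrue, tolerance = 1e-10,
               ignore_attr = TRUE)

  # prior-dominated limit: Z tends to the positive part of CU
  U2 <- matrix(abs(rnorm(6)), 2, 3)
  Zinf <- update_z(D, B, C, U2, 1e12)
  expect_equal(Zinf, pmax(C %*% U2, 0), tolerance = 1e-4, ignore_attr = TRUE)

  # normal-equation oracle on a random instance (row-wise augmented QR)
  set.seed(7)
  B3 <- matrix(rnorm(12), 3, 4); D3 <- matrix(rnorm(24), 6, 4)
  C3 <- matrix(rbinom(12, 1, 0.5), 6, 2); U3 <- matrix(abs(rnorm(6)), 2, 3)
  l1 <- 0.7
  Z3 <- update_z(D3, B3, C3, U3, l1)
  P <- C3 %*% U3
  aug <- rbind(t(B3), sqrt(l1) * diag(3))
  oracle <- t(apply(cbind(D3, sqrt(l1) * P), 1, function(r)
    qr.solve(aug, r)))
  expect_lt(max(abs(Z3 - pmax(oracle, 0))), 1e-8)
  expect_gte(min(Z3), 0)

  expect_error(update_z(D3, matrix(0, 3, 4), C3, U3, 0), "singular")
})

test_that("update_u matches a projected-gradient oracle and obeys its limits", {
  set.seed(8)
  C <- random_knowledge(8, 3, density = 0.5, seed = 8)

  # self-match: z equal to one set's indicator selects that set
  z <- matrix(C[, 2], ncol = 1)
  u <- update_u(z, C, lambda3 = 1e-6)
  expect_equal(unname(which(u > 1e-6)), 2L)
  expect_equal(unname(u[2, 1]), 1, tolerance = 1e-3)

  # full shrinkage at huge lambda3
  expect_equal(max(update_u(z, C, lambda3 = 1e9)), 0)

  # projected-gradient descent oracle run to tight tolerance
  Z <- matrix(abs(rnorm(16)), 8, 2)
  l3 <- 0.8; alpha <- 0.9
  U <- update_u(Z, C, l3, l1_fraction = alpha, max_path = 3)
  pgd <- function(z) {
    u <- rep(0, ncol(C))
    L <- 2 * max(eigen(crossprod(C))$values) + l3 * (1 - alpha)
    for (i in 1:200000) {
      g <- -2 * crossprod(C, z - C %*% u) + l3 * alpha + l3 * (1 - alpha) * u
      un <- pmax(u - g / L, 0)
      if (max(abs(un - u)) < 1e-12) { u <- un; break }
      u <- un
    }
    u
  }
  for (j in 1:2) {
    oracle <- pgd(Z[, j])
    if (sum(oracle > 0) <= 3) {
      expect_equal(unname(U[, j]), as.numeric(oracle), tolerance = 1e-5)
    }
  }
  expect_error(update_u(Z, C * 0.5, 1), "binary")
})

test_that("max_path truncates support with a non-negative refit", {
  set.seed(9)
  C <- random_knowledge(20, 8, density = 0.4, seed = 9)
  z <- matrix(C %*% runif(8, 0.5, 1), ncol = 1)   # dense truth
  u_free <- update_u(z, C, lambda3 = 1e-4, max_path = 100)
  expect_gt(sum(u_free > 0), 2)                   # genuinely dense problem
  u_cap <- update_u(z, C, lambda3 = 1e-4, max_path = 2)
  expect_lte(sum(u_cap > 0), 2)
  expect_gte(min(u_cap), 0)
})

test_that("the L1 norm of U is monotone non-increasing in lambda3", {
  set.seed(10)
  C <- random_knowledge(15, 5, seed = 10)
  Z <- matrix(abs(rnorm(45)), 15, 3)
  norms <- vapply(c(0.01, 0.1, 0.5, 2, 10, 50),
                  function(l3) sum(abs(update_u(Z, C, l3))), numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})
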