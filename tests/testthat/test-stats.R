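test_that("BH adjustment reproduces hand-enumerated step-up values", {
  # manual step-up: m=5, q_(i) = min_{j>=i} m p_(j) / j
  expect_equal(bh_adjust(c(0.005, 0.011, 0.02, 0.04, 0.5)),
               c(0.025, 0.0275, 0.1 / 3, 0.05, 0.5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.8)),
               c(0.04, 0.04, 0.04, 0.8))
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("BH is invariant to input permutation", {
  set.seed(30)
  p <- runif(25)
  q <- bh_adjust(p)
  perm <- sample(25)
  expect_equal(bh_adjust(p[perm]), q[perm])
})

test_that("differential LV tests behave at the null and under strong effects", {
  set.seed(31)
  B <- matrix(rnorm(5 * 12), 5, 12, dimnames = list(paste0("LV", 1:5), NULL))
  g <- rep(c("a", "b"), 6)
  # identical groups: duplicate the same six columns
  B_id <- cbind(B[, 1:6], B[, 1:6])
  d0 <- differential_lv(B_id, rep(c("a", "b"), each = 6))
  expect_equal(d0$t, rep(0, 5), ignore_attr = TRUE)
  expect_equal(d0$p_value, rep(1, 5), ignore_attr = TRUE)

  # overwhelming effect on LV1 only
  B2 <- matrix(rnorm(3 * 40), 3, 40, dimnames = list(paste0("LV", 1:3), NULL))
  grp <- rep(c("x", "y"), each = 20)
  B2[1, grp == "y"] <- B2[1, grp == "y"] + 5
  d1 <- differential_lv(B2, grp)
  expect_lt(d1$q_value[d1$lv == "LV1"], 0.05)
  expect_equal(d1$lv[1], "LV1")                      # ordered by q then |t|
  expect_false(is.unsorted(d1$q_value))
  expect_equal(sort(d1$q_value), sort(bh_adjust(d1$p_value)))
})

test_that("zero-variance n=2 groups are guarded, not fatal", {
  B <- matrix(c(1, 1, 2, 3), 1, 4)
  d <- differential_lv(B, c("a", "a", "b", "b"))
  expect_true(is.finite(d$p_value) || d$p_value %in% c(0, 1))
  B2 <- matrix(c(1, 1, 1, 1), 1, 4)
  d2 <- differential_lv(B2, c("a", "a", "b", "b"))
  expect_equal(d2$p_value, 1)
})

test_that("log-rank matches the hand O/E/V table on a 6-subject example", {
  # groups fully separated in time, all events
  res <- logrank_test(times = 1:6, events = rep(1, 6),
                      groups = rep(c("A", "B"), each = 3))
  # hand summation: O=3, E=0.5+0.4+0.25=1.15,
  # V=0.25+0.24+0.1875=0.6775 -> (3-1.15)^2/0.6775
  expect_equal(res$observed1, 3)
  expect_equal(res$expected1, 1.15)
  expect_equal(res$statistic, (3 - 1.15)^2 / 0.6775, tolerance = 1e-12)

  # single risk table: everyone censored at t=1 except one event
  res2 <- logrank_test(c(1, 1, 1, 1), c(1, 0, 0, 0), c("A", "A", "B", "B"))
  expect_equal(res2$statistic, 1)      # (1-0.5)^2 / 0.25
})

test_that("log-rank equals survdiff on all small two-group datasets", {
  skip_if_not_installed("survival")
  for (n in 3:6) {
    times <- seq_len(n)
    for (mask in 1:(2^n - 2)) {
      grp <- as.integer(intToBits(mask))[1:n]
      if (length(unique(grp)) < 2) next
      for (events in list(rep(1L, n), c(1L, rep(c(1L, 0L), length.out = n - 1)))) {
        res <- logrank_test(times, events, grp)
        sd <- survival::survdiff(survival::Surv(times, events) ~ grp, rho = 0)
        expect_equal(res$statistic, sd$chisq, tolerance = 1e-8)
      }
    }
  }
})

test_that("log-rank is invariant to label swap, identical groups give p = 1", {
  t <- c(2, 4, 4, 7, 9, 12); e <- c(1, 1, 0, 1, 0, 1)
  g <- c(1, 2, 1, 2, 1, 2)
  r1 <- logrank_test(t, e, g)
  r2 <- logrank_test(t, e, 3 - g)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)

  same <- logrank_test(rep(t, 2), rep(e, 2), rep(c("A", "B"), each = 6))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(logrank_test(t, rep(0, 6), g), "at least one event")
})

test_that("DMP calls assign direction relative to the reference group", {
  set.seed(32)
  beta <- rbind(
    cgA = c(rnorm(10, 0.1, 0.02), rnorm(10, 0.9, 0.02)),
    cgB = c(rnorm(10, 0.5, 0.05), rnorm(10, 0.5, 0.05))
  )
  beta <- pmin(pmax(beta, 0), 1)
  colnames(beta) <- paste0("s", 1:20)
  grp <- rep(c("ref", "case"), each = 10)
  res <- dmp_test(beta, c("cgA", "cgB"), grp, reference_group = "ref")
  a <- res[res$probe_id == "cgA", ]
  expect_equal(a$direction, "hyper")
  expect_lt(a$q_value, 1e-6)

  # exactly equal means: undefined direction, p ~ 1
  beta2 <- rbind(cgC = rep(c(0.2, 0.8), 10))
  colnames(beta2) <- paste0("s", 1:20)
  res2 <- dmp_test(beta2, "cgC", grp, reference_group = "ref")
  expect_true(is.na(res2$direction))
  expect_gt(res2$p_value, 0.99)
})

test_that("planted beta shifts are recovered with controlled false discoveries", {
  # 0.3 shifts at sd 0.05, n = 15/15: every planted probe must be found in
  # every replicate; BH at 0.05 keeps spurious calls rare but not impossible
  n_exact <- 0; n_false <- 0; all_found <- TRUE
  for (rep in 1:100) {
    set.seed(1000 + rep)
    beta <- matrix(rnorm(20 * 30, 0.4, 0.05), 20, 30,
                   dimnames = list(sprintf("cg%02d", 1:20), paste0("s", 1:30)))
    grp <- rep(c("g1", "g2"), each = 15)
    planted <- c("cg03", "cg09", "cg17")
    beta[planted, grp == "g2"] <- beta[planted, grp == "g2"] + 0.3
    beta <- pmin(pmax(beta, 0), 1)
    res <- dmp_test(beta, rownames(beta), grp, reference_group = "g1")
    called <- res$probe_id[res$q_value < 0.05]
    if (!all(planted %in% called)) all_found <- FALSE
    extra <- setdiff(called, planted)
    n_false <- n_false + length(extra)
    if (length(extra) == 0) n_exact <- n_exact + 1
    if (rep == 1) {
      expect_true(all(res$direction[res$probe_id %in% planted] == "hyper"))
    }
  }
  expect_true(all_found)
  expect_gte(n_exact, 75)
  expect_lt(n_false / 100, 0.3)
})

test_that("probes unusable in one group are excluded and counted", {
  beta <- matrix(runif(3 * 8), 3, 8,
                 dimnames = list(c("a", "b", "c"), paste0("s", 1:8)))
  grp <- rep(c("g1", "g2"), each = 4)
  beta["b", grp == "g2"] <- NA
  res <- dmp_test(beta, rownames(beta), grp, reference_group = "g1")
  expect_false("b" %in% res$probe_id)
  expect_equal(attr(res, "n_excluded"), 1L)
})
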