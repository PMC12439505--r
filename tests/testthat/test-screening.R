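# Energy, entropy, their ratio, the bootstrap, and the wavelet screen.

test_that("energy and entropy reproduce their closed forms", {
  expect_identical(energy(c(0, 0, 0)), 0)
  expect_identical(energy(c(3, 4)), 25)
  expect_equal(shannon_entropy(c(0, 0, 7, 0)), 0)
  for (N in c(2, 4, 8, 16)) {
    expect_equal(shannon_entropy(rep(2.5, N)), log(N), tolerance = 1e-12)
    expect_equal(shannon_entropy(rep(-1.3, N)), log(N), tolerance = 1e-12)
  }
  expect_equal(shannon_entropy(c(3, 4)),
               -(0.36 * log(0.36) + 0.64 * log(0.64)), tolerance = 1e-12)
  expect_error(shannon_entropy(numeric(3)), "all-zero")
})

test_that("energy-to-entropy ratio composes, scales and scopes correctly", {
  withr::with_seed(5, {
    x <- random_trace()
    # quadratic homogeneity: E quadruples, H invariant
    expect_equal(energy_entropy_ratio(2 * x, "sym2"),
                 4 * energy_entropy_ratio(x, "sym2"), tolerance = 1e-10)
    # scope oracle: separate energy and entropy calls on the D6 block
    d <- decompose(x, "sym2")
    expect_equal(energy_entropy_ratio(x, "sym2", scope = "D6"),
                 energy(d$details$D6) / shannon_entropy(d$details$D6),
                 tolerance = 1e-12)
    # overall scope uses all 256 coefficients
    co <- c(unlist(d$details), d$approximation)
    expect_equal(energy_entropy_ratio(x, "sym2", scope = "overall"),
                 energy(co) / shannon_entropy(co), tolerance = 1e-12)
    # permutation/sign invariance of the ratio
    expect_equal(energy(co) / shannon_entropy(co),
                 energy(-rev(co)) / shannon_entropy(-rev(co)),
                 tolerance = 1e-12)
    # scope beyond the wavelet's depth is flagged, not computed
    expect_true(is.na(energy_entropy_ratio(x, "coif2", scope = "D6")))
  })
})

test_that("bootstrap intervals are reproducible, degenerate-safe, honest", {
  expect_equal(bootstrap_ci(rep(7, 10), n_boot = 200, seed = 1),
               c(lo = 7, hi = 7))
  withr::with_seed(8, v <- rnorm(30, 10))
  a <- bootstrap_ci(v, n_boot = 500, seed = 99)
  b <- bootstrap_ci(v, n_boot = 500, seed = 99)
  expect_identical(a, b)
  expect_lt(a[["lo"]], a[["hi"]])
  # coverage of the true mean around 95% over Monte-Carlo replications
  withr::with_seed(13, {
    hits <- vapply(1:300, function(i) {
      x <- rnorm(100, 10, 1)
      ci <- bootstrap_ci(x, n_boot = 400)
      ci[["lo"]] <= 10 && 10 <= ci[["hi"]]
    }, logical(1))
  })
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})

test_that("participant-first averaging differs from recording pooling", {
  # unbalanced fixture: participant A has 1 recording, B has 3
  ratios <- c(A = 10, B1 = 1, B2 = 2, B3 = 3)
  pid <- c("A", "B", "B", "B")
  two_stage <- mean(tapply(ratios, pid, mean))   # (10 + 2) / 2 = 6
  pooled <- mean(ratios)                         # 4
  expect_equal(two_stage, 6)
  expect_false(isTRUE(all.equal(two_stage, pooled)))
})

test_that("the screen retains per-scope winners plus forced wavelets", {
  co <- small_cohort(n_normal = 6, n_mpird = 0, seed = 31, recordings = 2)
  co <- preprocess_cohort(co)
  # single candidate is retained regardless of its ratio
  one <- screen_wavelets(co, wavelets = "db5", scopes = "D4", n_boot = 0,
                         forced = character(0))
  expect_identical(one$retained, "db5")

  sc <- screen_wavelets(co, wavelets = c("sym2", "db6", "coif2", "haar"),
                        scopes = c("D5", "D6"), n_boot = 50, seed = 2,
                        forced = "coif2")
  expect_true("coif2" %in% sc$retained)
  expect_identical(nrow(sc$results), 8L)
  # coif2 (depth 4) and db6 (depth 4) have no D6 band at all, so only
  # compact low-order filters can compete there -- their D6 ratios are
  # flagged absent rather than fabricated
  for (wv in c("coif2", "db6")) {
    expect_true(is.na(
      sc$results$mean_ratio[sc$results$wavelet == wv &
                              sc$results$scope == "D6"]))
  }
  d6 <- sc$results[sc$results$scope == "D6" &
                     is.finite(sc$results$mean_ratio), ]
  expect_setequal(d6$wavelet, c("sym2", "haar"))
  # winners have the scope's maximal mean ratio
  for (scope in c("D5", "D6")) {
    sub <- sc$results[sc$results$scope == scope &
                        is.finite(sc$results$mean_ratio), ]
    win <- sub$wavelet[sub$mean_ratio == max(sub$mean_ratio)][1]
    expect_true(win %in% sc$retained)
  }
})

test_that("dominance: a uniformly better wavelet is the sole winner", {
  co <- small_cohort(n_normal = 4, n_mpird = 0, seed = 17)
  co <- preprocess_cohort(co)
  sc <- screen_wavelets(co, wavelets = c("sym2", "sym8"),
                        scopes = "D4", n_boot = 0,
                        forced = character(0))
  per <- sapply("D4", function(s) {
    r <- sc$results[sc$results$scope == s, ]
    r$wavelet[which.max(r$mean_ratio)]
  })
  dominant <- vapply("D4", function(s) {
    rs2 <- vapply(seq_len(nrow(co$samples)), function(i)
      energy_entropy_ratio(co$samples[i, ], "sym2", s), numeric(1))
    rs8 <- vapply(seq_len(nrow(co$samples)), function(i)
      energy_entropy_ratio(co$samples[i, ], "sym8", s), numeric(1))
    all(rs2 > rs8)
  }, logical(1))
  # wherever sym2 dominates recording-wise it must win the scope
  expect_true(all(per[dominant] == "sym2"))
})
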