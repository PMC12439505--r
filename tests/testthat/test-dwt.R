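# Periodized DWT: filter-bank properties, reference coefficients,
# energy preservation, reconstruction, and the index -> window mapping.

test_that("filter banks are orthonormal quadrature-mirror pairs", {
  for (w in wavelet_names()) {
    f <- wavelet_filter(w)
    expect_equal(sum(f$lo), sqrt(2), tolerance = 1e-10, label = w)
    expect_equal(sum(f$lo^2), 1, tolerance = 1e-10, label = w)
    expect_equal(sum(f$hi), 0, tolerance = 1e-7, label = w)
    for (s in seq_len(f$length - 2)[seq_len(f$length - 2) %% 2 == 0]) {
      expect_lt(abs(sum(f$lo[seq_len(f$length - s)] * f$lo[-seq_len(s)])),
                1e-10)
    }
  }
})

test_that("max_level follows the filter-support rule with the haar cap", {
  expect_identical(max_level("haar"), 7L)
  expect_identical(max_level("sym4"), 5L)
  expect_identical(max_level("coif2"), 4L)
  expect_identical(max_level("sym2"), 6L)
  expect_identical(max_level("db8"), 4L)
  expect_error(max_level("morlet"), "unknown wavelet")
})

test_that("decomposition matches independently computed reference values", {
  # Frozen from PyWavelets wavedec(mode = "periodization") on the
  # deterministic two-tone trace.
  x <- two_tone_trace()
  d <- decompose(x, "sym2")
  expect_equal(d$details$D6,
               c(6.48165568317513, -0.367655147722066,
                 -6.65822157346988, -0.392091426322337),
               tolerance = 1e-12)
  expect_equal(d$approximation,
               c(-0.794741371776914, -1.35426811455036,
                 1.40517137155669, 1.08750397168329),
               tolerance = 1e-12)
  expect_equal(d$details$D5,
               c(3.39544200580738, 2.26528000551221, -2.37972865867341,
                 0.684560051668787, -3.63380592228855, -0.820941476552727,
                 3.74508034292863, -0.786553912289904),
               tolerance = 1e-12)
  dh <- decompose(x, "haar")
  expect_equal(dh$approximation, c(2.84440650702496, -2.6013980491397),
               tolerance = 1e-12)
  expect_equal(dh$details$D7, c(0.344245823273169, -0.605287483855485),
               tolerance = 1e-12)
})

test_that("coefficient counts are exactly dyadic for every wavelet", {
  x <- two_tone_trace()
  for (w in wavelet_names()) {
    d <- decompose(x, w)
    for (lev in seq_len(d$level)) {
      expect_length(d$details[[lev]], 256 / 2^lev)
    }
    expect_length(d$approximation, 256 / 2^d$level)
    expect_length(c(unlist(d$details), d$approximation), 256)
  }
})

test_that("constants land in the approximation and impulses keep energy", {
  d <- decompose(rep(3, 256), "haar")
  expect_true(all(abs(unlist(d$details)) < 1e-12))
  expect_equal(sum(d$approximation^2), sum(rep(3, 256)^2), tolerance = 1e-12)
  imp <- c(1, numeric(255))
  di <- decompose(imp, "db4")
  expect_equal(sum(unlist(di$details)^2) + sum(di$approximation^2), 1,
               tolerance = 1e-12)
})

test_that("a 20 Hz tone concentrates in the D6 band (13.3-26.6 Hz)", {
  x <- sin(2 * pi * 20 * perg_time_grid() / 1000)
  d <- decompose(x, "sym2")
  e <- vapply(d$details, function(v) sum(v^2), numeric(1))
  e <- c(e, A6 = sum(d$approximation^2))
  expect_identical(names(which.max(e)), "D6")
})

test_that("decompose rejects non-finite and non-dyadic input", {
  expect_error(decompose(c(rep(0, 255), NA), "haar"), "non-finite")
  expect_error(decompose(rnorm(100), "haar"), "dyadic")
})

test_that("subset reconstruction is exact, empty-safe and linear", {
  withr::with_seed(7, {
    x <- random_trace()
    d <- decompose(x, "sym2")
    addrs <- all_addresses(d)
    expect_equal(reconstruct_subset(d, addrs), x, tolerance = 1e-10)
    expect_equal(reconstruct_subset(d, character(0)), numeric(256))
    # linearity: single-index reconstructions sum to the trace
    parts <- vapply(addrs, function(a) reconstruct_subset(d, a),
                    numeric(256))
    expect_equal(rowSums(parts), x, tolerance = 1e-8)
    # disjoint additivity
    s1 <- addrs[1:10]; s2 <- addrs[11:30]
    expect_equal(reconstruct_subset(d, c(s1, s2)),
                 reconstruct_subset(d, s1) + reconstruct_subset(d, s2),
                 tolerance = 1e-12)
    expect_error(reconstruct_subset(d, "D9-1"), "invalid|address")
    expect_error(reconstruct_subset(d, "A5-1"), "deepest")
  })
})

test_that("energy maps enumerate all coefficients and preserve energy", {
  withr::with_seed(11, {
    x <- random_trace()
    em <- energy_map(decompose(x, "sym2"))
    expect_identical(nrow(em), 256L)
    expect_identical(sum(em$band == "D" & em$level == 6), 4L)
    expect_identical(sum(em$band == "A"), 4L)
    expect_equal(sum(em$energy), sum(x^2), tolerance = 1e-10)
    em0 <- energy_map(decompose(numeric(256) + 0, "haar"))
    expect_true(all(em0$energy == 0))
  })
})

test_that("index windows reproduce the printed time-frequency cells", {
  # sym2-D6-2: 38-75 ms, 13-27 Hz
  w <- index_window("D", 6, 2)
  expect_identical(c(w$t_lo, w$t_hi, w$f_lo, w$f_hi), c(38, 75, 13, 27))
  # coif1-D5-3: 38-56 ms, 27-53 Hz
  w <- index_window("D", 5, 3)
  expect_identical(c(w$t_lo, w$t_hi, w$f_lo, w$f_hi), c(38, 56, 27, 53))
  # sym2-D6-3: 75-112 ms
  w <- index_window("D", 6, 3)
  expect_identical(c(w$t_lo, w$t_hi), c(75, 112))
  # haar level 7 halves: P50 cell 0-75 ms, N95 cell 75-150 ms
  w <- index_window(c("D", "D"), c(7, 7), c(1, 2))
  expect_identical(w$t_lo, c(0, 75))
  expect_identical(w$t_hi, c(75, 150))
  # approximation band starts at DC
  w <- index_window("A", 6, 1)
  expect_identical(c(w$f_lo, w$f_hi), c(0, 13))
  expect_error(index_window("D", 6, 5), "out of range")
})

test_that("window time tilings are exact partitions of 0-150 ms", {
  for (lev in 1:7) {
    n_cells <- 256 / 2^lev
    w <- index_window(rep("D", n_cells), rep(lev, n_cells),
                      seq_len(n_cells))
    expect_equal(w$t_lo_exact[1], 0)
    expect_equal(w$t_hi_exact[n_cells], 150)
    if (n_cells > 1) {
      expect_equal(w$t_lo_exact[-1], w$t_hi_exact[-n_cells])
    }
  }
})
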