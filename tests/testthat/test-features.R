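# Feature table construction and the group statistics.

brute_force_u <- function(x, y) {
  d <- outer(x, y, "-")
  sum(d > 0) + 0.5 * sum(d == 0)
}

test_that("feature counts follow the band-retention structure", {
  co <- preprocess_cohort(small_cohort(2, 2, seed = 1, recordings = 2))
  # haar alone: D4(16) + D5(8) + D6(4) + D7(2) + A7(2) = 32 columns
  th <- build_feature_table(co, "haar")
  expect_identical(ncol(th) - 2L, 32L)
  # the six retained wavelets: 32 each, 192 candidate features in total
  t6 <- build_feature_table(co, c("haar", "sym2", "sym4", "db4", "coif1",
                                  "fk4"))
  expect_identical(ncol(t6) - 2L, 192L)
  expect_identical(nrow(t6), 4L)
  expect_true("sym2-D6-2" %in% names(t6))
  expect_false(any(grepl("-D[123]-", names(t6))))
  expect_false("sym2-A5-1" %in% names(t6))  # only the deepest approximation
  info <- attr(t6, "feature_info")
  expect_identical(nrow(info), 192L)
})

test_that("participant rows are the mean of their recordings' energies", {
  co <- preprocess_cohort(small_cohort(2, 1, seed = 2, recordings = 4))
  tab <- build_feature_table(co, "sym2")
  pid <- co$meta$participant_id
  target <- tab$participant_id[1]
  recs <- which(pid == target)
  per_rec <- vapply(recs, function(i) {
    decompose(co$samples[i, ], "sym2")$details$D6[2]^2
  }, numeric(1))
  expect_equal(tab[tab$participant_id == target, "sym2-D6-2"],
               mean(per_rec), tolerance = 1e-12)
})

test_that("Mann-Whitney agrees with brute-force pair counting", {
  expect_identical(mann_whitney(c(3, 4), c(1, 2))$U, 4)
  expect_identical(mann_whitney(1, 1)$U, 0.5)
  expect_identical(mann_whitney(c(1, 3, 5), c(2, 4))$U, 3)
  withr::with_seed(10, {
    for (i in 1:50) {
      n1 <- sample(2:12, 1); n2 <- sample(2:12, 1)
      x <- sample(1:8, n1, replace = TRUE)  # many ties
      y <- sample(1:8, n2, replace = TRUE)
      mw <- mann_whitney(x, y)
      expect_equal(mw$U, brute_force_u(x, y))
      # p agrees with the standard normal-approximation test
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
      expect_equal(mw$p, wt$p.value, tolerance = 1e-10)
    }
  })
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("effect sizes follow their definitions", {
  es <- effect_sizes(U = 12, z = 2.5, n1 = 4, n2 = 3)
  expect_equal(es$cles, 1.0)
  expect_equal(effect_sizes(10, 2.5, 8, 8)$r_es, 0.625)
  # CLES from U equals the pair-counting probability
  withr::with_seed(20, {
    x <- rnorm(9); y <- rnorm(7)
    mw <- mann_whitney(x, y)
    expect_equal(effect_sizes(mw$U, mw$z, 9, 7)$cles,
                 brute_force_u(x, y) / 63, tolerance = 1e-15)
  })
})

test_that("effect sizes are invariant under monotone transforms", {
  withr::with_seed(25, {
    x <- rlnorm(10); y <- rlnorm(12, 0.5)
    f <- function(v) log(v) * 3 + 1
    a <- mann_whitney(x, y); b <- mann_whitney(f(x), f(y))
    expect_equal(a$U, b$U)
    expect_equal(a$z, b$z, tolerance = 1e-12)
  })
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.5)$p_adj, 0.5)
  r <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(r$reject))
  expect_equal(bh_adjust(rep(0.04, 3))$p_adj, rep(0.04, 3))
  expect_error(bh_adjust(c(0.2, 1.3)), "0, 1")
  # monotone in the raw p-values
  withr::with_seed(30, {
    p <- runif(20)
    adj <- bh_adjust(p)$p_adj
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  })
})

test_that("correlation pruning removes the weaker of redundant pairs", {
  # build a table with controlled correlation structure:
  # F1 ~ F2 (rho > 0.9), F3 independent-ish, r_es F1 > F2 > F3
  withr::with_seed(40, {
    n <- 30
    f1 <- rnorm(n)
    f2 <- f1 + rnorm(n, 0, 0.05)       # |rho| ~ 0.99
    f3 <- rnorm(n)
    tab <- data.frame(participant_id = sprintf("p%02d", 1:n),
                      group = rep(c("normal", "mpird"), each = 15),
                      F1 = f1, F2 = f2, F3 = f3, check.names = FALSE)
    attr(tab, "feature_info") <- data.frame(feature = c("F1", "F2", "F3"))
    class(tab) <- c("perg_feature_table", "data.frame")
    st <- data.frame(feature = c("F1", "F2", "F3"),
                     r_es = c(0.6, 0.5, 0.3), cles = c(0.8, 0.7, 0.6))
    expect_identical(prune_correlated(tab, st), c("F1", "F3"))
    # a pair just below the cutoff is kept whole
    st2 <- st
    rho <- cor(rank(f1), rank(f2))
    expect_identical(prune_correlated(tab, st2, threshold = rho),
                     c("F1", "F2", "F3"))
    # pruned sets are pairwise below threshold post hoc
    kept <- prune_correlated(tab, st)
    rk <- apply(as.matrix(tab[, kept]), 2, rank)
    rho_mat <- abs(cor(rk))
    expect_true(all(rho_mat[upper.tri(rho_mat)] <= 0.9))
  })
})

test_that("greedy pruning keeps chain endpoints that are not correlated", {
  # rho(F1,F2) and rho(F2,F3) high, rho(F1,F3) low, r_es F1 > F2 > F3:
  # the walk keeps F1, drops F2, then keeps F3
  withr::with_seed(41, {
    n <- 200
    g <- rnorm(n)
    f1 <- g + rnorm(n, 0, sqrt(0.15))
    f2 <- g
    f3 <- g + rnorm(n, 0, sqrt(0.15))
    tab <- data.frame(participant_id = sprintf("p%03d", 1:n),
                      group = "normal", F1 = f1, F2 = f2, F3 = f3,
                      check.names = FALSE)
    class(tab) <- c("perg_feature_table", "data.frame")
    st <- data.frame(feature = c("F1", "F2", "F3"),
                     r_es = c(0.9, 0.8, 0.7), cles = c(0.9, 0.8, 0.7))
    rk <- apply(cbind(f1, f2, f3), 2, rank)
    # verify the intended correlation geometry actually holds
    expect_gt(abs(cor(rk[, 1], rk[, 2])), 0.9)
    expect_gt(abs(cor(rk[, 2], rk[, 3])), 0.9)
    expect_lte(abs(cor(rk[, 1], rk[, 3])), 0.9)
    # F1 kept, F2 dropped against F1, F3 kept against F1 alone
    expect_identical(prune_correlated(tab, st), c("F1", "F3"))
  })
})

test_that("feature statistics rank by effect size and flag rejections", {
  co <- preprocess_cohort(small_cohort(8, 8, seed = 55, recordings = 2))
  tab <- build_feature_table(co, "sym2")
  st <- feature_stats(tab)
  expect_identical(nrow(st), 32L)
  expect_true(all(st$p_adj >= st$p - 1e-15))
  expect_true(all(st$cles >= 0 & st$cles <= 1))
  rk <- rank_features(st)
  expect_true(all(diff(rk$r_es) <= 1e-15))
  expect_identical(rank_features(st[7, ]), st[7, ])
  # orientation: attenuated P50 means normal energies are larger,
  # so the top feature's CLES is above one half
  expect_gt(rk$cles[1], 0.5)
})
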