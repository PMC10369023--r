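test_that("range normalization maps min/max to 0/1 and preserves order", {
  expect_equal(range_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.3, 0.7, 1)
  expect_equal(range_normalize(x), x)
  set.seed(2)
  y <- rnorm(50)
  expect_equal(order(range_normalize(y)), order(y))
  expect_error(range_normalize(rep(3, 5)), "constant")
})

test_that("Kruskal-Wallis H matches the hand example and independent oracles", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  expect_equal(kw$statistic, 2.4)
  expect_equal(kw$df, 1L)
  expect_equal(kruskal_wallis(list(c(5, 1, 3), c(3, 1, 5)))$statistic, 0)
  set.seed(31)
  for (k in 1:100) {
    ng <- sample(2:4, 1)
    groups <- lapply(seq_len(ng), function(i)
      sample(1:8, sample(3:9, 1), replace = TRUE)) # heavy ties
    if (length(unique(unlist(groups))) < 2) next
    kw <- kruskal_wallis(groups)
    expect_equal(kw$statistic, oracle_kruskal_h(groups), tolerance = 1e-12)
    # and against the reference implementation in stats
    ref <- stats::kruskal.test(unlist(groups),
                               rep(seq_along(groups), lengths(groups)))
    expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(kw$p_value, ref$p.value, tolerance = 1e-9)
  }
  # within-group ordering is irrelevant
  g <- list(c(3, 1, 7), c(2, 9, 4))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, rev))$statistic)
  expect_error(kruskal_wallis(list(1:3)), "2 non-empty")
  expect_error(kruskal_wallis(list(c(2, 2), c(2, 2))), "identical")
})

test_that("Dunn z and Bonferroni adjustment match the brute-force oracle", {
  set.seed(17)
  for (k in 1:100) {
    ng <- sample(3:5, 1)
    groups <- lapply(seq_len(ng), function(i)
      sample(1:10, sample(3:8, 1), replace = TRUE))
    if (length(unique(unlist(groups))) < 2) next
    names(groups) <- paste0("g", seq_len(ng))
    dn <- dunn_posthoc(groups)
    n_pairs <- choose(ng, 2)
    expect_equal(nrow(dn), n_pairs)
    for (r in seq_len(nrow(dn))) {
      i <- match(dn$group1[r], names(groups))
      j <- match(dn$group2[r], names(groups))
      expect_equal(dn$z[r], oracle_dunn_z(groups, i, j), tolerance = 1e-12)
    }
    expect_true(all(dn$p_adj >= dn$p))
    expect_true(all(dn$p_adj <= 1))
    expect_equal(dn$p_adj, pmin(1, dn$p * n_pairs))
  }
})

test_that("well-separated groups are all significant after Bonferroni", {
  set.seed(99)
  groups <- list(a = rnorm(10, 0, 0.1), b = rnorm(10, 5, 0.1),
                 c = rnorm(10, 10, 0.1))
  dn <- dunn_posthoc(groups)
  # rank statistics saturate once groups separate fully: adjacent pairs of
  # n = 10 reach z = 2.54, p_adj = 0.033, no matter how far apart the means
  expect_true(all(dn$p_adj < 0.05))
  expect_lt(dn$p_adj[dn$group1 == "a" & dn$group2 == "c"], 1e-4)
  # z is antisymmetric in the pair order
  z_ab <- dn$z[dn$group1 == "a" & dn$group2 == "b"]
  dn2 <- dunn_posthoc(groups[c("b", "a", "c")])
  expect_equal(dn2$z[dn2$group1 == "b" & dn2$group2 == "a"], -z_ab)
})

test_that("ordered quantile normalization produces normal scores", {
  set.seed(4)
  x <- rexp(1000) # strongly right-skewed input
  z <- ordered_quantile_normalize(x)
  g1 <- mean((z - mean(z))^3) / sd(z)^3
  expect_lt(abs(g1), 0.05)
  expect_equal(order(z), order(x))
  # symmetric ranks map to +/- paired scores
  z5 <- ordered_quantile_normalize(c(10, 20, 30, 40, 50))
  expect_equal(z5, -rev(z5))
  expect_equal(z5[3], 0)
  expect_error(ordered_quantile_normalize(c(1, 2)), "at least 3")
})

test_that("per-distance correlations and the R-vs-distance regression are exact on constructed data", {
  # engineer records whose species medians are known
  species <- paste0("s", 1:5)
  u <- c(0, 0.2, 0.5, 0.8, 1)
  distances <- c(2, 5, 10, 30)
  rows <- list()
  set.seed(6)
  for (d in distances) {
    for (s in seq_along(species)) {
      # three individuals; median = middle value
      vals <- c(0.1, 0.2, 0.3) + s * (1 / d)
      for (v in vals)
        rows[[length(rows) + 1]] <- data.frame(
          individual_id = paste(s, d, v), species = species[s],
          defence_class = "NR", unpalatability = u[s], distance_cm = d,
          lum_boldness = v, col_boldness = v, lum_detectability = v,
          col_detectability = v)
    }
  }
  rec <- do.call(rbind, rows)
  out <- distance_correlation_regression(rec, metrics = "lum_detectability")
  # medians are strictly increasing in s at every distance, so the OQN
  # scores are the same 5 normal scores and R is the same at all distances
  r_expect <- cor(qnorm((1:5 - 0.5) / 5), u)
  expect_equal(out$correlations$R, rep(r_expect, 4), tolerance = 1e-12)
  # closed-form OLS through 4 identical R values: slope 0
  expect_equal(out$regressions$slope, 0, tolerance = 1e-12)
})

test_that("the regression matches closed-form OLS on synthetic R profiles", {
  # feed hand-built correlations through the same OLS arithmetic
  R <- c(0.3, 0.2, 0.1, 0.0)
  d <- c(2, 5, 10, 30)
  fit <- lm(R ~ d)
  slope_hand <- sum((d - mean(d)) * (R - mean(R))) / sum((d - mean(d))^2)
  expect_equal(unname(coef(fit)[2]), slope_hand, tolerance = 1e-12)
  expect_lt(slope_hand, 0)
  r2_hand <- 1 - sum(resid(fit)^2) / sum((R - mean(R))^2)
  expect_equal(summary(fit)$r.squared, r2_hand, tolerance = 1e-12)
})

test_that("permuted unpalatability gives correlations inside the null band", {
  set.seed(23)
  x <- rnorm(13)
  y <- rnorm(13)
  band <- pearson_permutation_band(x, y, n_perm = 999, seed = 5)
  expect_lt(band["lower"], 0)
  expect_gt(band["upper"], 0)
  # the observed R of independent data falls inside the band most of the time
  hits <- 0
  for (k in 1:40) {
    xx <- rnorm(13); yy <- rnorm(13)
    b <- pearson_permutation_band(xx, yy, n_perm = 499, seed = k)
    r <- cor(xx, yy)
    hits <- hits + (r >= b["lower"] && r <= b["upper"])
  }
  expect_gte(hits, 32) # 95% nominal; allow generous Monte-Carlo slack
})

test_that("degenerate inputs to the correlation stage are refused or dropped", {
  rec <- data.frame(species = rep(c("a", "b", "c"), each = 4),
                    unpalatability = rep(c(0, 0.5, 1), each = 4),
                    distance_cm = rep(c(2, 5, 10, 30), 3),
                    lum_boldness = 1, col_boldness = 1,
                    lum_detectability = 1, col_detectability = 1)
  expect_error(distance_correlation_regression(rec), "4 species")
})
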