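make_table <- function(n = 200, seed = 1) {
  withr::with_seed(seed, {
    df <- rbind(
      data.frame(group = "-PMA", area_um2 = stats::rnorm(n, 271, 29),
                 eccentricity = stats::rnorm(n, 0.405, 0.14),
                 ri = stats::rnorm(n, 1.383, 0.03),
                 rate_amol_min = stats::rlnorm(n, 5.4, 0.8)),
      data.frame(group = "+PMA", area_um2 = stats::rnorm(n, 263, 24),
                 eccentricity = stats::rnorm(n, 0.363, 0.13),
                 ri = stats::rnorm(n, 1.377, 0.03),
                 rate_amol_min = stats::rlnorm(n, 6.1, 0.75)))
    population_table(df)
  })
}

test_that("population tables validate labels and flag incomplete rows", {
  tab <- make_table()
  expect_s3_class(tab, "population_table")
  bad <- as.data.frame(tab); bad$ri[3] <- NA
  tab2 <- population_table(bad)
  expect_equal(sum(tab2$qc != ""), 1)
  odd <- as.data.frame(tab); odd$group[1] <- "ctrl"
  expect_error(population_table(odd), "labels")
  expect_error(population_table(tab[, -2]), "missing columns")
})

test_that("group summaries report the standard statistics", {
  tab <- make_table(400)
  s <- summarize_population(tab)
  pma <- s[s$group == "+PMA" & s$variable == "area_um2", ]
  expect_equal(pma$n, 400)
  expect_equal(pma$mean, 263, tolerance = 3 * 24 / 20 / 263)
  expect_equal(pma$sd, 24, tolerance = 0.15)
  he <- attr(s, "high_efflux")
  expect_true(all(he >= 0 & he <= 1))
  # a duplicated single value has zero sd and mode at the value
  dup <- population_table(data.frame(group = "+PMA", area_um2 = 100,
                                     eccentricity = 0.3, ri = 1.38,
                                     rate_amol_min = 50)[c(1, 1), ])
  sdup <- summarize_population(dup)
  expect_true(all(sdup$sd == 0))
  expect_equal(sdup$mode[sdup$variable == "rate_amol_min"], 50)
  # threshold above the maximum rate gives a zero high fraction
  s2 <- summarize_population(tab, high_threshold = 1e9)
  expect_true(all(attr(s2, "high_efflux") == 0))
  expect_error(summarize_population(tab[0, ]), "no unflagged")
})

test_that("summaries are invariant to row order", {
  tab <- make_table(150)
  s1 <- summarize_population(tab)
  perm <- tab[sample(nrow(tab)), ]
  s2 <- summarize_population(population_table(as.data.frame(perm)))
  s2 <- s2[order(s2$group, s2$variable), ]
  s1 <- s1[order(s1$group, s1$variable), ]
  expect_equal(s1$mean, s2$mean, tolerance = 1e-12)
  expect_equal(s1$mode, s2$mode, tolerance = 1e-9)
})

test_that("group comparison reports percent changes with bootstrap CIs", {
  tab <- make_table(300)
  cmp <- compare_groups(tab, n_boot = 200, seed = 5)
  # identical groups change by exactly zero
  half <- as.data.frame(tab[tab$group == "-PMA", ])
  dup <- rbind(half, transform(half, group = "+PMA"))
  cmp0 <- compare_groups(population_table(dup), n_boot = 50, seed = 1)
  expect_true(all(abs(cmp0$change_pct) < 1e-9))
  # the printed rounded means imply an 89.1% elevation
  expect_equal((624 - 330) / 330 * 100, 89.09, tolerance = 1e-3)
  # variance change sign equals the sign of the sd difference
  rates <- cmp[cmp$variable == "rate_amol_min", ]
  sds <- tapply(tab$rate_amol_min, tab$group, stats::sd)
  expect_equal(sign(rates$change_pct[rates$metric == "var"]),
               sign(sds[["+PMA"]] - sds[["-PMA"]]))
  # deterministic under the same seed
  cmp2 <- compare_groups(tab, n_boot = 200, seed = 5)
  expect_equal(cmp$ci_lo, cmp2$ci_lo, tolerance = 1e-12)
})

test_that("bimodality detection separates mixtures from single modes", {
  withr::with_seed(31, {
    clear <- c(stats::rnorm(200, 0, 1), stats::rnorm(200, 5, 1))
    expect_true(detect_bimodality(clear)$is_bimodal)
    single <- stats::rnorm(400)
    expect_false(detect_bimodality(single)$is_bimodal)
  })
  expect_error(detect_bimodality(stats::rnorm(20)), "50")
  res <- detect_bimodality(c(stats::rnorm(200, 0, 1),
                             stats::rnorm(200, 5, 1)))
  expect_length(res$means, 2)
  expect_length(res$weights, 2)
})

test_that("2D kernel density integrates to one and respects structure", {
  withr::with_seed(17, {
    x <- stats::rnorm(500); y <- stats::rnorm(500)
    d <- kde2d_grid(x, y)
    integral <- sum(d$z) * diff(d$x[1:2]) * diff(d$y[1:2])
    expect_equal(integral, 1, tolerance = 0.01)
    # symmetric data give a symmetric density
    xs <- c(x, -x); ys <- c(y, -y)
    ds <- kde2d_grid(xs, ys)
    expect_lt(max(abs(ds$z - ds$z[rev(seq_len(nrow(ds$z))),
                                  rev(seq_len(ncol(ds$z)))])) /
              max(ds$z), 0.02)
    # two separated clusters -> two local maxima along the ridge
    xc <- c(stats::rnorm(300, -4, 0.7), stats::rnorm(300, 4, 0.7))
    yc <- c(stats::rnorm(300, -4, 0.7), stats::rnorm(300, 4, 0.7))
    dc <- kde2d_grid(xc, yc, n = 64)
    ridge <- diag(dc$z)
    peaks <- sum(diff(sign(diff(ridge))) == -2)
    expect_gte(peaks, 2)
  })
  expect_error(kde2d_grid(1:5, 1:5), "10")
})
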