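published_r <- c("40.L" = 0.899, "40.R" = 0.891, "50.L" = 0.949, "50.R" = 0.908,
                 "60.L" = 0.939, "60.R" = 0.947, "70.L" = 0.604, "70.R" = 0.783,
                 "80.L" = 0.498, "80.R" = 0.912)

test_that("fixture tables reproduce every published correlation to 3 decimals", {
  rep <- validation_report(load_lung_pressures(), load_smith_scores())
  expect_identical(nrow(rep), 10L)
  for (k in names(published_r)) {
    gs <- strsplit(k, ".", fixed = TRUE)[[1]]
    row <- rep[rep$group == gs[1] & rep$side == gs[2], ]
    expect_equal(round(row$pearson_r, 3), published_r[[k]],
                 info = k, tolerance = 1e-12)
  }
  # strong/weak split as reported: everything at 40-60 cm strong, 70-80 weak
  # except the right lung at 80 cm
  expect_true(all(rep$strong[rep$group %in% c("40", "50", "60")]))
  expect_identical(rep$strong[rep$group == "80" & rep$side == "R"], TRUE)
  expect_false(any(rep$strong[rep$group == "70"]))
})

test_that("published Pearson significances are recovered", {
  expect_equal(round(as.numeric(pearson_pvalue(0.899, 6)), 3), 0.015)
  expect_equal(round(as.numeric(pearson_pvalue(0.949, 6)), 3), 0.004)
  rep <- validation_report(load_lung_pressures(), load_smith_scores())
  expect_equal(round(rep$pearson_p[rep$group == "60" & rep$side == "L"], 3), 0.005)
  expect_equal(round(rep$pearson_p[rep$group == "70" & rep$side == "L"], 3), 0.204)
  expect_equal(round(rep$pearson_p[rep$group == "80" & rep$side == "L"], 3), 0.314)
})

test_that("paired t-tests against the untreated group match the report", {
  sc <- load_smith_scores()
  pick <- function(g, s) {
    x <- sc[sc$group == g & sc$side == s, ]
    x$score[match(blastrat:::monitor_point_names, x$point_name)]
  }
  expect_equal(round(paired_t(pick("80", "L"), pick("untreated", "L"))$p, 3), 0.111)
  expect_equal(round(paired_t(pick("80", "R"), pick("untreated", "R"))$p, 3), 0.809)
  expect_equal(round(paired_t(pick("40", "L"), pick("untreated", "L"))$p, 3), 0.001)
  expect_equal(round(paired_t(pick("50", "R"), pick("untreated", "R"))$p, 3), 0.007)
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "zero-variance")
  expect_error(paired_t(1:4, 1:3), "equal length")
})

test_that("pearson has the exact-linearity and degenerate behaviours", {
  x <- c(3, 1, 4, 1, 5, 9)
  expect_equal(pearson(x, 2 * x + 1), 1.0)
  expect_error(pearson(rep(2, 6), x), "constant")
  expect_error(pearson(x, rep(0, 6)), "constant")
  expect_error(pearson(1:2, 2:3), "at least 3")
})

test_that("pearson agrees with a brute-force covariance oracle", {
  brute <- function(x, y) {
    mx <- sum(x) / length(x); my <- sum(y) / length(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  set.seed(3)
  for (i in 1:25) {
    x <- rnorm(6); y <- rnorm(6)
    expect_equal(pearson(x, y), brute(x, y), tolerance = 1e-12)
    # affine invariance and antisymmetry
    expect_equal(pearson(3.2 * x + 7, y), pearson(x, y), tolerance = 1e-12)
    expect_equal(pearson(x, -y), -pearson(x, y), tolerance = 1e-12)
  }
})

test_that("pearson p-values follow the exact t transform", {
  expect_equal(as.numeric(pearson_pvalue(0, 6)), 1.0)
  p1 <- pearson_pvalue(1, 6)
  expect_identical(as.numeric(p1), 0)
  expect_true(attr(p1, "exact_fit"))
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    ct <- cor.test(x, y)
    expect_equal(as.numeric(pearson_pvalue(pearson(x, y), 8)), ct$p.value,
                 tolerance = 1e-10)
  }
  expect_error(pearson_pvalue(1.4, 6), "exceed")
})

test_that("Smith totals stack the three components", {
  expect_identical(smith_total(0, 0, 0), 0)
  expect_identical(smith_total(4, 4, 4), 12)
  expect_equal(smith_total(1, 2, 0.667), 3.667)
  expect_error(smith_total(5, 0, 0), "\\[0, 4\\]")
  expect_error(smith_total(1, -0.1, 0), "\\[0, 4\\]")
})

test_that("validation report fails loudly on missing points", {
  pr <- load_lung_pressures()
  sc <- load_smith_scores()
  broken <- pr[!(pr$group == "40" & pr$side == "L" &
                 pr$point_name == "interior"), ]
  expect_error(validation_report(broken, sc), "interior")
})
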