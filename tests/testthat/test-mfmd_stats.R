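test_that("the mutation frequency is deviations per transmitted allele", {
  expect_equal(mf_md(1487, 702304), 1487 / (2 * 702304))
  expect_equal(signif(mf_md(1487, 702304), 3), 1.06e-3)
  expect_equal(mf_md(0, 700000), 0)
  expect_error(mf_md(10, 0), "positive")
  expect_error(mf_md(-1, 100), "nonnegative")
  # linearity in both arguments
  expect_equal(mf_md(200, 1e5), 2 * mf_md(100, 1e5))
  expect_equal(mf_md(100, 2e5), mf_md(100, 1e5) / 2)
})

test_that("trio summaries partition deviations by origin", {
  manifest <- data.frame(family_id = c("F1", "F2"), group = "control",
                         exposed_parent = "none", dose_gy = 0,
                         stringsAsFactors = FALSE)
  mds <- data.frame(
    family_id = c("F1", "F1", "F1", "F2"),
    origin = c("father", "mother", "unknown", "father"),
    stringsAsFactors = FALSE)
  ts <- summarize_trios(mds, manifest, c(F1 = 1000, F2 = 2000))
  expect_equal(ts$md_total, c(3, 1))
  expect_equal(ts$md_total, ts$md_father + ts$md_mother + ts$md_unknown)
  expect_equal(ts$mf_md, c(3 / 2000, 1 / 4000))
  expect_error(summarize_trios(mds, manifest, c(F1 = 1000)), "missing")
})

test_that("two identical groups give t = 0, p = 1, F = 1", {
  ts <- data.frame(
    family_id = sprintf("T%d", 1:8),
    group = rep(c("exposed", "control"), each = 4),
    md_total = rep(c(100, 120, 140, 160), 2),
    mf_md = rep(c(1, 1.2, 1.4, 1.6) * 1e-3, 2),
    stringsAsFactors = FALSE)
  gc <- group_comparison(ts)
  expect_equal(gc$t_statistic, 0)
  expect_equal(gc$t_p, 1)
  expect_equal(gc$f_statistic, 1)
  expect_equal(gc$percent_increase, 0)
})

test_that("t and F agree with closed-form computation on random inputs", {
  set.seed(9)
  for (i in 1:5) {
    n1 <- sample(5:12, 1); n2 <- sample(5:12, 1)
    x <- rnorm(n1, 1.3e-3, 3e-4); y <- rnorm(n2, 0.9e-3, 2e-4)
    cx <- rpois(n1, 2000); cy <- rpois(n2, 1400)
    ts <- data.frame(
      family_id = sprintf("T%d", seq_len(n1 + n2)),
      group = rep(c("exposed", "control"), c(n1, n2)),
      md_total = c(cx, cy), mf_md = c(x, y), stringsAsFactors = FALSE)
    gc <- group_comparison(ts)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    expect_equal(gc$t_statistic, t_hand, tolerance = 1e-6)
    expect_equal(gc$t_df, n1 + n2 - 2)
    expect_equal(gc$t_p, 2 * pt(-abs(t_hand), n1 + n2 - 2), tolerance = 1e-6)
    f_hand <- var(cx) / var(cy)
    expect_equal(gc$f_statistic, f_hand, tolerance = 1e-6)
    p_hand <- pf(f_hand, n1 - 1, n2 - 1)
    expect_equal(gc$f_p, 2 * min(p_hand, 1 - p_hand), tolerance = 1e-6)
  }
})

test_that("percent increase is relative to the control mean", {
  expect_equal(percent_increase(2, 1), 100)
  expect_equal(percent_increase(1, 1), 0)
  expect_error(percent_increase(1, 0), "positive")
})

test_that("a perfectly linear dose response has R squared one", {
  ts <- data.frame(mf_md = 1e-3 + 1e-3 * c(0, 0.1, 0.2, 0.3, 0.5),
                   dose_gy = c(0, 0.1, 0.2, 0.3, 0.5))
  dr <- suppressWarnings(dose_regression(ts))  # lm warns on a perfect fit
  expect_equal(dr$r_squared, 1)
  expect_equal(dr$slope, 1e-3)
  expect_equal(dr$intercept, 1e-3)
  expect_error(dose_regression(data.frame(mf_md = c(1, 2, 3) * 1e-3,
                                          dose_gy = c(0.2, 0.2, 0.2))),
               "no variance")
})

test_that("exposed-parent subgroups are summarized and compared", {
  ts <- data.frame(
    group = "exposed",
    exposed_parent = rep(c("father", "mother"), each = 3),
    mf_md = c(1.0, 1.2, 1.4, 1.0, 1.2, 1.4) * 1e-3,
    stringsAsFactors = FALSE)
  sg <- subgroup_by_exposed_parent(ts)
  expect_equal(sg$father$mean, 1.2e-3)
  expect_equal(sg$mother$mean, 1.2e-3)
  expect_equal(sg$t_p, 1)  # identical subgroups
  # single subgroup: comparison skipped, sd undefined below two trios
  ts1 <- ts[c(1, 4:6), ]; ts1$exposed_parent[1] <- "father"
  sg1 <- subgroup_by_exposed_parent(ts1)
  expect_true(is.na(sg1$father$sd))
  expect_true(is.na(sg1$t_p))
})

test_that("paternal fractions and age regressions behave as defined", {
  ts <- data.frame(
    family_id = c("A", "B", "C", "D"),
    group = "control",
    md_father = c(50, 783, 100, 0),
    md_mother = c(50, 694, 50, 0),
    paternal_age = c(20, 30, 40, 50),
    maternal_age = c(19, 28, 36, 45),
    stringsAsFactors = FALSE)
  pf <- paternal_fraction_analysis(ts)
  fr <- pf$per_trio$paternal_fraction
  expect_equal(fr[1], 0.5)
  expect_equal(round(fr[2], 3), 0.530)
  expect_true(is.na(fr[4]))  # zero resolved deviations: undefined
  # scaling both counts leaves the fraction unchanged
  ts2 <- ts; ts2$md_father <- ts$md_father * 7; ts2$md_mother <- ts$md_mother * 7
  expect_equal(paternal_fraction_analysis(ts2)$per_trio$paternal_fraction, fr)
  regs <- pf$regressions
  expect_true(all(c("paternal_fraction", "md_father", "md_mother") %in%
                    regs$response))
  expect_true(all(is.finite(regs$p_slope[regs$n >= 3])))
})

test_that("the packaged cohort reproduces its published marginals", {
  d <- goiania_cohort()
  expect_equal(nrow(d), 30)
  expect_equal(sum(d$group == "exposed"), 15)
  expect_equal(d$md_total, d$md_father + d$md_mother + d$md_unknown)
  expect_true(all(d$n_valid >= 674320 & d$n_valid <= 714892))
  expect_true(all(d$dose_gy[d$group == "control"] == 0))
  expect_equal(d$mf_md, d$md_total / (2 * d$n_valid))
})
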