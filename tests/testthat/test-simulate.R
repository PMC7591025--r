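test_that("a fixed seed makes the simulator byte-identical", {
  cfg <- sim_config(n_markers = 2000, mu = 1e-3, epsilon = 1e-3,
                    nocall_rate = 1e-3, seed = 5)
  a <- simulate_trios(cfg, n_trios = 2)
  b <- simulate_trios(cfg, n_trios = 2)
  expect_identical(a$trios, b$trios)
  expect_identical(a$truth, b$truth)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  simulate_trios(cfg, n_trios = 1, dir = dir1)
  simulate_trios(cfg, n_trios = 1, dir = dir2)
  f1 <- file.path(dir1, "Sim01_child.tsv"); f2 <- file.path(dir2, "Sim01_child.tsv")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("clean simulations produce zero deviations", {
  cfg <- sim_config(n_markers = 5000, mu = 0, epsilon = 0, nocall_rate = 0,
                    seed = 2)
  sc <- simulate_trios(cfg, n_trios = 2)
  for (fam in names(sc$trios)) {
    tr <- sc$trios[[fam]]
    res <- analyze_trio(tr$father, tr$mother, tr$child, family_id = fam)
    expect_equal(nrow(res$mds), 0)
    expect_equal(res$n_valid, 5000)
  }
  expect_equal(nrow(sc$truth), 0)
})

test_that("simulated files round-trip through the genotype reader", {
  cfg <- sim_config(n_markers = 500, mu = 5e-3, nocall_rate = 0.01, seed = 8)
  dir <- withr::local_tempdir()
  sc <- simulate_trios(cfg, n_trios = 1, dir = dir)
  back <- read_genotype_table(sc$manifest$father_file[1])
  expect_equal(nrow(back), 500)
  expect_true(all(back$genotype %in% c("AA", "AB", "BB", "NoCall")))
  expect_equal(back$confidence[back$genotype == "NoCall"],
               rep(1, sum(back$genotype == "NoCall")))
})

test_that("detectability is exact in the rare-allele limit and below one at 0.5", {
  expect_gt(detectability_probability(1e-4), 0.999)
  p_half <- detectability_probability(0.5)
  expect_lt(p_half, 1)
  expect_gt(p_half, 0)
  # monotone decreasing: more heterozygous parents mask more flips
  grid <- detectability_probability(c(0.05, 0.2, 0.35, 0.5))
  expect_true(all(diff(grid) < 0))
})

test_that("detectability matches the empirical detectable fraction", {
  maf <- 0.3
  cfg <- sim_config(n_markers = 30000, maf_range = c(maf, maf + 1e-9),
                    mu = 5e-3, epsilon = 0, nocall_rate = 0, seed = 13)
  sc <- simulate_trios(cfg, n_trios = 1)
  dn <- sc$truth[sc$truth$event == "de_novo", ]
  p_hat <- mean(dn$detectable)
  p <- detectability_probability(maf)
  se <- sqrt(p * (1 - p) / nrow(dn))
  expect_lt(abs(p_hat - p), 4 * se)
})

test_that("detected deviations recover the injected mutation rate", {
  mu <- 1e-3
  cfg <- sim_config(n_markers = 50000, mu = mu, epsilon = 0, nocall_rate = 0,
                    seed = 17)
  sc <- simulate_trios(cfg, n_trios = 1)
  tr <- sc$trios[[1]]
  res <- analyze_trio(tr$father, tr$mother, tr$child,
                      family_id = names(sc$trios)[1])
  p_det <- mean_detectability(cfg$maf_range)
  expected <- 2 * cfg$n_markers * mu * p_det
  sd_bin <- sqrt(2 * cfg$n_markers * mu * p_det * (1 - mu * p_det))
  expect_lt(abs(nrow(res$mds) - expected), 3 * sd_bin)
  ev <- evaluate_detection(sc$truth, res$mds, res$n_valid)
  expect_equal(ev$sensitivity, 1)       # every detectable injection found
  expect_equal(ev$false_md_rate, 0)     # epsilon = 0: no false deviations
  expect_equal(ev$origin_accuracy, 1)   # mendelian-resolved origins exact
})

test_that("genotyping error inflates the mutation frequency monotonically", {
  eps <- c(0, 1e-3, 4e-3)
  mf <- vapply(seq_along(eps), function(i) {
    cfg <- sim_config(n_markers = 20000, mu = 5e-4, epsilon = eps[i],
                      nocall_rate = 0, seed = 31)
    sc <- simulate_trios(cfg, n_trios = 1)
    tr <- sc$trios[[1]]
    res <- analyze_trio(tr$father, tr$mother, tr$child)
    mf_md(nrow(res$mds), res$n_valid)
  }, numeric(1))
  expect_true(all(diff(mf) > 0))
})

test_that("mismatched run identifiers are a hard error", {
  cfg <- sim_config(n_markers = 200, mu = 0.01, seed = 4)
  a <- simulate_trios(cfg, n_trios = 1)
  mds <- data.frame(family_id = "Sim01", probe_id = "S-0000001",
                    origin = "father", origin_method = "mendelian",
                    stringsAsFactors = FALSE)
  attr(mds, "run_id") <- "other-run"
  expect_error(evaluate_detection(a$truth, mds, 200), "different runs")
})

test_that("implausible event rates trigger the degenerate-regime warning", {
  expect_warning(sim_config(mu = 0.08, epsilon = 0.05), "degenerate")
})

test_that("the cohort-faithful design targets the published dose response", {
  cfg <- sim_config(n_markers = 1000)
  design <- cohort_design(cfg)
  expect_equal(nrow(design), 30)
  expect_equal(design$target_mf[design$group == "control"],
               rep(0.9e-3, 15))
  expect_equal(design$target_mf, 0.9e-3 + 1.0e-3 * design$dose_gy)
  p_det <- mean_detectability(cfg$maf_range)
  expect_equal(design$mu, design$target_mf / p_det)
})
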