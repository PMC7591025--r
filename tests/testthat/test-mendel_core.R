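test_that("classification agrees with the brute-force oracle on all 27 combos", {
  g <- ab_combos()
  v <- classify_transmission(g$f, g$m, g$k)
  for (i in seq_len(nrow(g))) {
    o <- oracle_classify(g$f[i], g$m[i], g$k[i])
    expect_equal(v$status[i], o$status,
                 info = paste(g$f[i], g$m[i], g$k[i]))
    if (o$status == "deviation") {
      expect_equal(v$origin[i], o$origin,
                   info = paste(g$f[i], g$m[i], g$k[i]))
    }
  }
  expect_equal(sum(v$status == "deviation"), 12)
  expect_equal(as.vector(table(v$origin[v$status == "deviation"])[
    c("father", "mother", "unknown")]), c(4L, 4L, 4L))
})

test_that("base-space classification matches the oracle on all base-pair combos", {
  pairs <- apply(expand.grid(b1 = c("A", "C", "G", "T"),
                             b2 = c("A", "C", "G", "T")), 1,
                 function(r) paste(sort(r), collapse = "/"))
  pairs <- unique(pairs)  # the 10 unordered base calls
  expect_length(pairs, 10)
  for (f in pairs) for (m in pairs) for (k in pairs) {
    got <- classify_transmission_bases(f, m, k)
    want <- oracle_classify(f, m, k)
    expect_equal(got$status, want$status, info = paste(f, m, k))
    if (want$status == "deviation") {
      expect_equal(got$origin, want$origin, info = paste(f, m, k))
    }
  }
})

test_that("the worked third-base example resolves to the father", {
  v <- classify_transmission_bases("A/A", "C/C", "G/C")
  expect_equal(v$status, "deviation")
  expect_equal(v$origin, "father")
  expect_equal(v$ancestral, "A")
  expect_equal(v$derived, "G")
})

test_that("swapping parents mirrors the origin and preserves status", {
  g <- ab_combos()
  v1 <- classify_transmission(g$f, g$m, g$k)
  v2 <- classify_transmission(g$m, g$f, g$k)
  expect_equal(v1$status, v2$status)
  swap <- c(father = "mother", mother = "father", unknown = "unknown")
  dev <- v1$status == "deviation"
  expect_equal(unname(swap[v1$origin[dev]]), v2$origin[dev])
})

test_that("children sampled from parental gametes are never flagged", {
  set.seed(11)
  gts <- c("AA", "AB", "BB")
  pick <- function(gt) sample(c(substr(gt, 1, 1), substr(gt, 2, 2)), 1)
  for (i in 1:200) {
    f <- sample(gts, 1); m <- sample(gts, 1)
    k <- paste(sort(c(pick(f), pick(m))), collapse = "")
    expect_equal(classify_transmission(f, m, k)$status, "consistent")
  }
})

test_that("detect_deviations finds exactly the planted inconsistencies", {
  dev <- oracle_deviations()
  n_pad <- 8
  mk <- make_markers(nrow(dev) + n_pad, chrom = "1")
  fgt <- c(dev$f, rep("AB", n_pad))
  mgt <- c(dev$m, rep("AB", n_pad))
  cgt <- c(dev$k, rep("AA", n_pad))  # AB x AB -> AA is consistent
  tr <- make_trio_tables(mk, fgt, mgt, cgt)
  tm <- filter_calls(assemble_trio(tr$father, tr$mother, tr$child,
                                   family_id = "F1"))
  mds <- detect_deviations(tm)
  expect_equal(nrow(mds), 12)
  expect_setequal(mds$probe_id, mk$probe_id[seq_len(nrow(dev))])
  # origin partition matches the oracle and sums to the total
  expect_equal(sum(mds$origin == "father") + sum(mds$origin == "mother") +
                 sum(mds$origin == "unknown"), nrow(mds))
  expect_equal(mds$origin[match(mk$probe_id[seq_len(nrow(dev))],
                                mds$probe_id)], dev$origin)
  expect_equal(mds$origin_method[mds$origin == "unknown"],
               rep("unresolved", 4))
  expect_true(all(mds$origin_method[mds$origin != "unknown"] == "mendelian"))
  # sorted by position
  expect_equal(mds$pos, sort(mds$pos))
})

test_that("a clean trio yields an empty deviation table", {
  mk <- make_markers(6)
  tr <- make_trio_tables(mk, "AA", "BB", "AB")
  tm <- filter_calls(assemble_trio(tr$father, tr$mother, tr$child))
  expect_equal(nrow(detect_deviations(tm)), 0)
})

test_that("origin-unknown plants keep unknown origin at the Mendelian stage", {
  mk <- make_markers(1)
  tr <- make_trio_tables(mk, "AA", "AA", "AB")
  mds <- detect_deviations(filter_calls(assemble_trio(tr$father, tr$mother,
                                                      tr$child)))
  expect_equal(nrow(mds), 1)
  expect_equal(mds$origin, "unknown")
  # shared homozygous parents still define ancestral/derived for the spectrum
  expect_equal(mds$ancestral_allele, "A")
  expect_equal(mds$derived_allele, "B")
})

test_that("recurrence tabulation counts marker sharing across trios", {
  md_row <- function(fam, probe) data.frame(family_id = fam, probe_id = probe,
                                            stringsAsFactors = FALSE)
  disjoint <- rbind(md_row("A", c("P1", "P2")), md_row("B", c("P3", "P4")))
  r <- tabulate_recurrence(disjoint)
  expect_equal(r$fraction[r$recurrence == 1], 1)

  shared <- rbind(md_row("A", c("P1", "P2")), md_row("B", c("P1", "P2")))
  r2 <- tabulate_recurrence(shared)
  expect_equal(r2$fraction[r2$recurrence == 2], 1)

  mix <- rbind(md_row("A", c(paste0("U", 1:4), "S1", "S2", "S3")),
               md_row("B", c(paste0("V", 1:2), "S1", "S2", "S3")))
  r3 <- tabulate_recurrence(mix)  # 6 unique markers, 3 shared by two
  expect_equal(r3$fraction[r3$recurrence == 1], 6 / 9)
  expect_equal(r3$fraction[r3$recurrence == 2], 3 / 9)
  expect_error(tabulate_recurrence(md_row("A", "P1")), "two trios")
})
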