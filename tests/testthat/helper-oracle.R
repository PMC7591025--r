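# Independent brute-force transmission oracle, written against the genetics
# directly (gamete-pair enumeration + explicit single-mutation scenarios),
# kept deliberately separate from the package's lookup-table implementation.

oracle_alleles <- function(gt) {
  if (grepl("/", gt, fixed = TRUE)) strsplit(gt, "/", fixed = TRUE)[[1]]
  else c(substr(gt, 1, 1), substr(gt, 2, 2))
}

oracle_classify <- function(father, mother, child) {
  fa <- oracle_alleles(father)
  ma <- oracle_alleles(mother)
  ka <- sort(oracle_alleles(child))
  consistent <- FALSE
  for (x in fa) for (y in ma) {
    if (identical(sort(c(x, y)), ka)) consistent <- TRUE
  }
  if (consistent) {
    return(list(status = "consistent", origin = NA_character_))
  }
  # single-mutation scenarios: parent P transmitted ancestral a, which
  # mutated to derived d; the other parent transmitted o unchanged.
  scenarios <- list(father = FALSE, mother = FALSE)
  all_bases <- unique(c(fa, ma, ka, "A", "B"))
  for (p in c("father", "mother")) {
    own <- if (p == "father") fa else ma
    oth <- if (p == "father") ma else fa
    for (a in own) for (d in setdiff(all_bases, a)) for (o in oth) {
      if (identical(sort(c(d, o)), ka)) scenarios[[p]] <- TRUE
    }
  }
  origin <- if (scenarios$father && !scenarios$mother) "father"
            else if (scenarios$mother && !scenarios$father) "mother"
            else "unknown"
  list(status = "deviation", origin = origin)
}

# all 27 A/B-space combinations
ab_combos <- function() {
  gts <- c("AA", "AB", "BB")
  expand.grid(f = gts, m = gts, k = gts, stringsAsFactors = FALSE)
}

# the 12 deviating combinations and their oracle origins, computed fresh
oracle_deviations <- function() {
  g <- ab_combos()
  res <- lapply(seq_len(nrow(g)),
                function(i) oracle_classify(g$f[i], g$m[i], g$k[i]))
  g$status <- vapply(res, `[[`, "", "status")
  g$origin <- vapply(res, function(r) r$origin %||% NA_character_, "")
  g[g$status == "deviation", ]
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
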