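#' Genotype-table column dialect
#'
#' SNP-array export tools differ in column naming; a dialect maps the
#' columns this package needs onto the names found in a particular export.
#' The defaults correspond to the package's own TSV layout (one file per
#' sample, one row per probe).
#'
#' @param probe_id,dbsnp,chrom,pos,allele_a,allele_b,genotype,confidence,signal_a,signal_b
#'   Column names in the file.
#' @param nocall Token used for a failed genotype call (default `"NC"`).
#' @return A named list of class `"genotype_dialect"`.
#' @examples
#' genotype_dialect()
#' @export
genotype_dialect <- function(probe_id = "probe_id", dbsnp = "dbsnp",
                             chrom = "chrom", pos = "pos",
                             allele_a = "allele_a", allele_b = "allele_b",
                             genotype = "genotype", confidence = "confidence",
                             signal_a = "signal_a", signal_b = "signal_b",
                             nocall = "NC") {
  structure(list(probe_id = probe_id, dbsnp = dbsnp, chrom = chrom, pos = pos,
                 allele_a = allele_a, allele_b = allele_b, genotype = genotype,
                 confidence = confidence, signal_a = signal_a,
                 signal_b = signal_b, nocall = nocall),
            class = "genotype_dialect")
}

VALID_BASES <- c("A", "C", "G", "T")
GT_LEVELS <- c("AA", "AB", "BB", "NoCall")

#' Normalize chromosome labels
#'
#' Strips any `"chr"` prefix and returns bare labels ("1".."22", "X", ...).
#' @param x Character vector of chromosome labels.
#' @return Character vector of bare labels.
#' @keywords internal
normalize_chrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

#' Read a per-sample SNP-array genotype table
#'
#' Reads one sample's genotype export (TSV, one row per probe) carrying
#' marker identity (probe id, dbSNP id, chromosome, position, the two
#' probe alleles as bases) and the sample's call (AA/AB/BB genotype in
#' A/B allele space, call confidence, raw signals). Only autosomes are
#' analyzed: rows on sex chromosomes or with malformed chromosome or
#' position are dropped at read time and counted.
#'
#' @param path Path to the TSV file (or a connection).
#' @param dialect A [genotype_dialect()] describing column names and the
#'   no-call token.
#' @return A `data.frame` with columns `probe_id`, `dbsnp`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`, `genotype` (one of `"AA","AB","BB","NoCall"`),
#'   `confidence`, `signal_a`, `signal_b`, `base_call` (e.g. `"A/G"`, empty
#'   for no-calls), sorted by (chromosome, position). Attributes
#'   `n_skipped_nonautosomal` and `n_skipped_malformed` count dropped rows.
#' @details No-call rows get confidence 1 (worst) when the file leaves the
#'   confidence field empty. Duplicate probe ids within one file are a
#'   hard error, as is a missing mandatory column.
#' @export
read_genotype_table <- function(path, dialect = genotype_dialect()) {
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  needed <- unlist(dialect[c("probe_id", "chrom", "pos", "allele_a",
                             "allele_b", "genotype")])
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    stop("genotype table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  get_col <- function(key, default = NA_character_) {
    nm <- dialect[[key]]
    if (nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }
  df <- data.frame(
    probe_id = get_col("probe_id"),
    dbsnp = get_col("dbsnp", ""),
    chrom = normalize_chrom(get_col("chrom")),
    pos = suppressWarnings(as.numeric(get_col("pos"))),
    allele_a = toupper(get_col("allele_a")),
    allele_b = toupper(get_col("allele_b")),
    genotype = get_col("genotype"),
    confidence = suppressWarnings(as.numeric(get_col("confidence"))),
    signal_a = suppressWarnings(as.numeric(get_col("signal_a"))),
    signal_b = suppressWarnings(as.numeric(get_col("signal_b"))),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$probe_id)) {
    dup <- unique(df$probe_id[duplicated(df$probe_id)])
    stop("duplicate probe_id in genotype table: ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }

  autosomal <- df$chrom %in% as.character(1:22)
  well_formed <- !is.na(df$pos) & df$pos >= 1 &
    df$allele_a %in% VALID_BASES & df$allele_b %in% VALID_BASES &
    df$allele_a != df$allele_b
  n_nonauto <- sum(!autosomal)
  n_malformed <- sum(autosomal & !well_formed)
  if (n_nonauto + n_malformed > 0L) {
    message(sprintf("read_genotype_table: skipped %d non-autosomal and %d malformed row(s)",
                    n_nonauto, n_malformed))
  }
  df <- df[autosomal & well_formed, , drop = FALSE]

  gt <- df$genotype
  gt[gt == dialect$nocall] <- "NoCall"
  bad_gt <- !(gt %in% GT_LEVELS)
  if (any(bad_gt)) {
    stop("unrecognized genotype token(s): ",
         paste(unique(df$genotype[bad_gt]), collapse = ", "), call. = FALSE)
  }
  df$genotype <- gt
  # absent confidence is treated as the worst possible call quality
  df$confidence[is.na(df$confidence)] <- 1
  if (any(df$confidence < 0 | df$confidence > 1)) {
    stop("confidence values must lie in [0, 1]", call. = FALSE)
  }
  df$base_call <- base_call(df$genotype, df$allele_a, df$allele_b)

  ord <- order(as.integer(df$chrom), df$pos)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_skipped_nonautosomal") <- n_nonauto
  attr(df, "n_skipped_malformed") <- n_malformed
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' Spell out a genotype call in base space
#'
#' @param genotype Character vector in `{"AA","AB","BB","NoCall"}`.
#' @param allele_a,allele_b The marker's A and B allele bases.
#' @return Character vector like `"A/G"`; `""` for no-calls.
#' @keywords internal
base_call <- function(genotype, allele_a, allele_b) {
  out <- character(length(genotype))
  out[genotype == "AA"] <- paste0(allele_a, "/", allele_a)[genotype == "AA"]
  out[genotype == "BB"] <- paste0(allele_b, "/", allele_b)[genotype == "BB"]
  out[genotype == "AB"] <- paste0(allele_a, "/", allele_b)[genotype == "AB"]
  out
}

#' Write a genotype table in the package dialect
#'
#' Inverse of [read_genotype_table()]: a write followed by a read
#' reproduces the records exactly.
#'
#' @param df A genotype table `data.frame` (as returned by
#'   [read_genotype_table()] or the simulator).
#' @param path Output TSV path.
#' @param dialect A [genotype_dialect()].
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(df, path, dialect = genotype_dialect()) {
  out <- data.frame(
    df$probe_id, df$dbsnp, df$chrom, format(df$pos, scientific = FALSE, trim = TRUE),
    df$allele_a, df$allele_b,
    ifelse(df$genotype == "NoCall", dialect$nocall, df$genotype),
    df$confidence, df$signal_a, df$signal_b,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(out) <- unlist(dialect[c("probe_id", "dbsnp", "chrom", "pos",
                                 "allele_a", "allele_b", "genotype",
                                 "confidence", "signal_a", "signal_b")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trio manifest
#'
#' One row per family: group membership, which parent was exposed, the
#' absorbed dose in gray, parental ages at conception, child age and sex,
#' and the paths of the three per-sample genotype files (paths may be
#' empty when the manifest only carries the study design, e.g. for
#' published per-trio summaries).
#'
#' @param path TSV with columns `family_id`, `group` (exposed/control),
#'   `exposed_parent` (father/mother/none), `dose_gy`, `father_file`,
#'   `mother_file`, `child_file`, `paternal_age`, `maternal_age`,
#'   `child_age`, `child_sex`.
#' @return A validated `data.frame`, one row per family.
#' @details A control family must have `dose_gy = 0` and
#'   `exposed_parent = "none"`; violations are hard errors.
#' @export
read_trio_manifest <- function(path) {
  m <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  required <- c("family_id", "group", "exposed_parent", "dose_gy")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0L) {
    stop("trio manifest is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("father_file", "mother_file", "child_file",
                "paternal_age", "maternal_age", "child_age", "child_sex")) {
    if (!col %in% names(m)) m[[col]] <- NA
  }
  m$group <- tolower(m$group)
  m$exposed_parent <- tolower(m$exposed_parent)
  validate_trio_manifest(m)
  m
}

#' Validate trio manifest invariants
#' @param m Manifest `data.frame`.
#' @return `m`, invisibly; errors on violation.
#' @keywords internal
validate_trio_manifest <- function(m) {
  if (!all(m$group %in% c("exposed", "control"))) {
    stop("manifest group must be 'exposed' or 'control'", call. = FALSE)
  }
  if (!all(m$exposed_parent %in% c("father", "mother", "none"))) {
    stop("exposed_parent must be 'father', 'mother' or 'none'", call. = FALSE)
  }
  if (any(!is.finite(m$dose_gy) | m$dose_gy < 0)) {
    stop("dose_gy must be a nonnegative number", call. = FALSE)
  }
  ctl <- m$group == "control"
  if (any(ctl & m$dose_gy != 0)) {
    stop("control famil(ies) with nonzero dose: ",
         paste(m$family_id[ctl & m$dose_gy != 0], collapse = ", "),
         call. = FALSE)
  }
  if (any(ctl & m$exposed_parent != "none")) {
    stop("control famil(ies) must have exposed_parent = none", call. = FALSE)
  }
  if (anyDuplicated(m$family_id)) {
    stop("duplicate family_id in manifest", call. = FALSE)
  }
  invisible(m)
}

#' Read a CpG-island BED file
#'
#' BED3 (or wider) intervals, 0-based half-open. The result is a
#' `GRanges` in 1-based coordinates, so a marker at 1-based position `p`
#' lies inside an interval `[start, end)` exactly when
#' `start + 1 <= p <= end`.
#'
#' @param path Path to the BED file. `track`/`browser`/`#` lines are
#'   ignored. Chromosome labels with or without the `chr` prefix are
#'   accepted and normalized to bare numerals.
#' @return A [GenomicRanges::GRanges] holding the islands.
#' @export
read_cpg_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines[idx], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("BED line ", idx[which(nf < 3L)[1L]], ": fewer than 3 fields",
         call. = FALSE)
  }
  chrom <- normalize_chrom(vapply(fields, `[[`, "", 1L))
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start0) | is.na(end0)
  if (any(bad)) {
    stop("BED line ", idx[which(bad)[1L]], ": non-numeric start/end",
         call. = FALSE)
  }
  if (any(start0 >= end0)) {
    stop("BED line ", idx[which(start0 >= end0)[1L]],
         ": start >= end (BED is 0-based half-open)", call. = FALSE)
  }
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0)
  )
}

#' Point membership in a CpG interval set
#'
#' @param cpg A `GRanges` from [read_cpg_bed()] (or any `GRanges` in
#'   1-based closed coordinates).
#' @param chrom Character vector of chromosome labels (with or without
#'   `chr` prefix).
#' @param pos Numeric vector of 1-based positions.
#' @return Logical vector: is each (chrom, pos) inside an interval?
#' @export
cpg_contains <- function(cpg, chrom, pos) {
  if (length(cpg) == 0L || length(pos) == 0L) {
    return(rep(FALSE, length(pos)))
  }
  q <- GenomicRanges::GRanges(
    seqnames = normalize_chrom(chrom),
    ranges = IRanges::IRanges(start = pos, width = 1)
  )
  lv <- union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(cpg))
  GenomeInfoDb::seqlevels(q) <- lv
  GenomeInfoDb::seqlevels(cpg) <- lv
  GenomicRanges::countOverlaps(q, cpg) > 0L
}
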