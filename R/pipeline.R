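#' Analyze one trio end to end
#'
#' Assemble, QC-filter, detect Mendelian deviations, resolve ambiguous
#' parents of origin, and flag CpG sites for a single family.
#'
#' @param father,mother,child Genotype tables ([read_genotype_table()] or
#'   simulator output).
#' @param family_id Family label.
#' @param cpg Optional CpG `GRanges` ([read_cpg_bed()]).
#' @param confidence_threshold,keep_rule Passed to [filter_calls()].
#' @param window_bp Passed to [resolve_unknown_origins()].
#' @param deduction Run the origin deductions (default `TRUE`; `FALSE`
#'   reports raw Mendelian-stage unknowns).
#' @return A list: `mds` (deviation table), `n_valid`, `trio` (the
#'   filtered `"trio_matrix"`).
#' @export
analyze_trio <- function(father, mother, child, family_id = "trio",
                         cpg = NULL, confidence_threshold = 0.05,
                         keep_rule = "leq", window_bp = Inf,
                         deduction = TRUE) {
  tm <- assemble_trio(father, mother, child, family_id = family_id)
  tm <- filter_calls(tm, confidence_threshold, keep_rule)
  mds <- detect_deviations(tm)
  if (deduction && nrow(mds) > 0L) {
    mds <- resolve_unknown_origins(mds, window_bp = window_bp)
  }
  if (!is.null(cpg) && nrow(mds) > 0L) {
    mds <- flag_cpg(mds, cpg)
  }
  list(mds = mds, n_valid = tm$n_valid_markers, trio = tm)
}

# restrict an assembled (possibly filtered) trio matrix to a probe subset
restrict_trio <- function(tm, probe_ids) {
  keep <- tm$markers$probe_id %in% probe_ids
  tm$markers <- tm$markers[keep, , drop = FALSE]
  rownames(tm$markers) <- NULL
  for (mem in c("father", "mother", "child")) {
    tm[[mem]] <- tm[[mem]][keep, , drop = FALSE]
    rownames(tm[[mem]]) <- NULL
  }
  tm$n_valid_markers <- sum(keep)
  tm
}

#' Run the full deviation pipeline over a cohort
#'
#' Orchestrates detect, resolve, spectrum, summarize, and compare for
#' every family of a manifest: per-trio deviation tables, a per-trio
#' summary (counts by origin, valid-SNP count, \eqn{MF_{MD}}), the
#' group comparison, the dose regression, and the substitution-class
#' table. Outputs are deterministic: rerunning on the same inputs
#' reproduces identical tables.
#'
#' @param manifest Manifest `data.frame` (or path for
#'   [read_trio_manifest()]) with `father_file`/`mother_file`/`child_file`
#'   columns.
#' @param cpg_bed Optional path to a CpG-island BED file. When spectra
#'   are produced without one, CpG flags stay `FALSE` with a warning.
#' @param out_dir Optional directory; when given, `mds.tsv`,
#'   `summary.tsv`, `classes.tsv`, `comparison.txt` and `config.txt` are
#'   written there.
#' @param confidence_threshold,keep_rule QC settings ([filter_calls()]).
#' @param completeness `"trio"` (default): complete-case filtering per
#'   family, each trio keeps its own valid-SNP count. `"global"`:
#'   markers must be valid in every sample of every family.
#' @param window_bp,deduction Origin-deduction settings.
#' @param exclude_cpg Exclude flagged CpG C>T deviations from the class
#'   table (default `FALSE`).
#' @param dialect Genotype-table dialect for the input files.
#' @return A list of class `"mendeviate_run"`: `mds`, `summary`,
#'   `comparison`, `dose`, `classes`, `manifest`, `config`.
#' @export
run_pipeline <- function(manifest, cpg_bed = NULL, out_dir = NULL,
                         confidence_threshold = 0.05, keep_rule = "leq",
                         completeness = c("trio", "global"),
                         window_bp = Inf, deduction = TRUE,
                         exclude_cpg = FALSE, dialect = genotype_dialect()) {
  completeness <- match.arg(completeness)
  if (is.character(manifest)) manifest <- read_trio_manifest(manifest)
  validate_trio_manifest(manifest)
  cpg <- if (!is.null(cpg_bed)) read_cpg_bed(cpg_bed) else NULL

  trios <- lapply(seq_len(nrow(manifest)), function(i) {
    f <- read_genotype_table(manifest$father_file[i], dialect)
    m <- read_genotype_table(manifest$mother_file[i], dialect)
    k <- read_genotype_table(manifest$child_file[i], dialect)
    tm <- assemble_trio(f, m, k, family_id = manifest$family_id[i])
    filter_calls(tm, confidence_threshold, keep_rule)
  })
  if (completeness == "global") {
    shared <- Reduce(intersect, lapply(trios, function(t) t$markers$probe_id))
    trios <- lapply(trios, restrict_trio, probe_ids = shared)
  }

  mds_list <- lapply(trios, function(tm) {
    mds <- detect_deviations(tm)
    if (deduction && nrow(mds) > 0L) {
      mds <- resolve_unknown_origins(mds, window_bp = window_bp)
    }
    if (nrow(mds) > 0L) {
      if (!is.null(cpg)) mds <- flag_cpg(mds, cpg)
    }
    mds
  })
  mds <- do.call(rbind, mds_list)
  if (is.null(cpg) && nrow(mds) > 0L) {
    warning("no CpG BED supplied; in_cpg is FALSE everywhere")
  }
  n_valid <- stats::setNames(vapply(trios, `[[`, 0L, "n_valid_markers"),
                             manifest$family_id)
  summary_df <- summarize_trios(mds, manifest, n_valid)
  comparison <- if (all(c("exposed", "control") %in% summary_df$group) &&
                    min(table(summary_df$group)) >= 2L) {
    group_comparison(summary_df)
  } else NULL
  dose <- if (nrow(summary_df) >= 3L && stats::var(summary_df$dose_gy) > 0) {
    dose_regression(summary_df)
  } else NULL
  classes <- class_table(mds, manifest, exclude_cpg = exclude_cpg)
  config <- list(confidence_threshold = confidence_threshold,
                 keep_rule = keep_rule, completeness = completeness,
                 window_bp = window_bp, deduction = deduction,
                 exclude_cpg = exclude_cpg,
                 cpg_bed = if (is.null(cpg_bed)) NA_character_ else cpg_bed,
                 version = as.character(utils::packageVersion("mendeviate")))
  out <- structure(list(mds = mds, summary = summary_df,
                        comparison = comparison, dose = dose,
                        classes = classes, manifest = manifest,
                        config = config),
                   class = "mendeviate_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

#' Write a pipeline run to disk
#'
#' @param run A `"mendeviate_run"` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(run$mds, "mds.tsv")
  wt(run$summary, "summary.tsv")
  wt(run$classes, "classes.tsv")
  txt <- c(utils::capture.output({
    if (!is.null(run$comparison)) print(run$comparison)
    if (!is.null(run$dose)) print(run$dose)
  }))
  writeLines(txt, file.path(out_dir, "comparison.txt"))
  writeLines(paste(names(run$config),
                   vapply(run$config, function(v) paste(format(v), collapse = ","), ""),
                   sep = " = "),
             file.path(out_dir, "config.txt"))
  invisible(out_dir)
}
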