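#' Pyrimidine-standardized substitution class
#'
#' Maps an (ancestral, derived) base pair onto one of the six canonical
#' single-base substitution classes `C>A, C>G, C>T, T>A, T>C, T>G`. Array
#' genotypes do not reveal which strand mutated, so a purine ancestral
#' base is complemented together with its derived base before labeling
#' (`G>A` becomes `C>T`, `A>C` becomes `T>G`, ...). The mapping is a
#' strand involution: complementing both inputs never changes the class.
#'
#' @param ancestral,derived Nucleotide vectors (`A`/`C`/`G`/`T`); pairs
#'   must differ.
#' @return Character vector of class labels.
#' @examples
#' substitution_class("G", "A")  # "C>T"
#' @export
substitution_class <- function(ancestral, derived) {
  ancestral <- toupper(ancestral); derived <- toupper(derived)
  if (any(!(ancestral %in% VALID_BASES) | !(derived %in% VALID_BASES))) {
    stop("bases must be one of A, C, G, T", call. = FALSE)
  }
  if (any(ancestral == derived)) {
    stop("ancestral and derived bases must differ", call. = FALSE)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  purine <- ancestral %in% c("A", "G")
  anc <- ifelse(purine, comp[ancestral], ancestral)
  der <- ifelse(purine, comp[derived], derived)
  paste0(anc, ">", der)
}

#' The six substitution class labels
#' @return Character vector `c("C>A","C>G","C>T","T>A","T>C","T>G")`.
#' @export
substitution_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' Flag C>T deviations inside CpG islands
#'
#' CpG islands are where C>T changes are commonly deamination-driven
#' rather than mutagen-induced, so C>T (including strand-collapsed G>A)
#' deviations falling in an island are flagged. The flag is always
#' computed; whether flagged sites are excluded from spectra is a choice
#' made in [class_table()].
#'
#' @param mds Deviation table from [detect_deviations()].
#' @param cpg `GRanges` from [read_cpg_bed()], or `NULL` (all flags
#'   `FALSE`, with a warning).
#' @return `mds` with `in_cpg` updated.
#' @export
flag_cpg <- function(mds, cpg) {
  mds$in_cpg <- FALSE
  if (is.null(cpg)) {
    warning("no CpG interval set supplied; in_cpg left FALSE everywhere")
    return(mds)
  }
  ct <- !is.na(mds$substitution_class) & mds$substitution_class == "C>T"
  if (any(ct)) {
    mds$in_cpg[ct] <- cpg_contains(cpg, mds$chrom[ct], mds$pos[ct])
  }
  mds
}

#' Per-group substitution-class summary
#'
#' Tallies each trio's deviations by substitution class and summarizes
#' per group and class: minimum, maximum, mean, standard deviation
#' (n-1 denominator) of the per-trio counts, and the group total.
#' Deviations without an assignable class are excluded from the tallies
#' (they stay in overall deviation totals elsewhere).
#'
#' @param mds Deviation table covering one or more trios, with
#'   `substitution_class` assigned.
#' @param manifest Trio manifest mapping `family_id` to `group`. Trios in
#'   the manifest with zero classified deviations count as zeros.
#' @param exclude_cpg Drop C>T deviations flagged `in_cpg` before
#'   tallying (default `FALSE`: flagged sites are reported but kept).
#' @return A `data.frame` with columns `group`, `class`, `minimum`,
#'   `maximum`, `mean`, `sd`, `total`, plus attribute `per_trio` holding
#'   the trio-by-class count matrix.
#' @export
class_table <- function(mds, manifest, exclude_cpg = FALSE) {
  keep <- !is.na(mds$substitution_class)
  if (exclude_cpg) keep <- keep & !mds$in_cpg
  mds <- mds[keep, , drop = FALSE]
  fam <- factor(mds$family_id, levels = manifest$family_id)
  cls <- factor(mds$substitution_class, levels = substitution_classes())
  counts <- table(fam, cls)
  out <- do.call(rbind, lapply(unique(manifest$group), function(g) {
    rows <- counts[manifest$group == g, , drop = FALSE]
    data.frame(group = g, class = substitution_classes(),
               minimum = apply(rows, 2, min),
               maximum = apply(rows, 2, max),
               mean = apply(rows, 2, mean),
               sd = apply(rows, 2, stats::sd),
               total = apply(rows, 2, sum),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "per_trio") <- unclass(counts)
  out
}
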