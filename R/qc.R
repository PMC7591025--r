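#' Assemble a trio genotype matrix
#'
#' Aligns the three per-sample genotype tables of one family on their
#' shared probes. Markers are the intersection of the probe ids present
#' in all three samples, ordered by (chromosome, position). Marker
#' identity columns (alleles, coordinates) are taken from the father's
#' table and checked for agreement.
#'
#' @param father,mother,child Genotype tables from
#'   [read_genotype_table()] (or equivalent `data.frame`s).
#' @param family_id Family label carried through to downstream results.
#' @return A list of class `"trio_matrix"`: `markers` (probe_id, dbsnp,
#'   chrom, pos, allele_a, allele_b), `father`/`mother`/`child`
#'   (genotype, confidence, signal_a, signal_b aligned to `markers`),
#'   `family_id`, `n_valid_markers` (`NA` until [filter_calls()] runs),
#'   and `filtered` flag.
#' @export
assemble_trio <- function(father, mother, child, family_id = "trio") {
  shared <- Reduce(intersect, list(father$probe_id, mother$probe_id,
                                   child$probe_id))
  if (length(shared) == 0L) {
    stop("no probes shared by father, mother, and child", call. = FALSE)
  }
  pick <- function(df) df[match(shared, df$probe_id), , drop = FALSE]
  f <- pick(father); m <- pick(mother); k <- pick(child)
  if (!identical(f$allele_a, m$allele_a) || !identical(f$allele_a, k$allele_a) ||
      !identical(f$allele_b, m$allele_b) || !identical(f$allele_b, k$allele_b) ||
      !identical(f$pos, m$pos) || !identical(f$pos, k$pos)) {
    stop("marker annotation (alleles/coordinates) disagrees across samples",
         call. = FALSE)
  }
  ord <- order(as.integer(f$chrom), f$pos)
  markers <- f[ord, c("probe_id", "dbsnp", "chrom", "pos",
                      "allele_a", "allele_b")]
  rownames(markers) <- NULL
  member <- function(df) {
    out <- df[ord, c("genotype", "confidence", "signal_a", "signal_b")]
    rownames(out) <- NULL
    out
  }
  structure(list(markers = markers,
                 father = member(f), mother = member(m), child = member(k),
                 family_id = family_id,
                 n_valid_markers = NA_integer_,
                 filtered = FALSE),
            class = "trio_matrix")
}

#' Call-quality and complete-case filtering for a trio
#'
#' Retains exactly the markers where all three members have a non-missing
#' call passing the confidence rule. The number of retained markers is
#' the trio's valid-SNP count \eqn{n_{vp}}, the denominator (times two,
#' for the two transmitted alleles) of the germline mutation frequency.
#'
#' @param tm A `"trio_matrix"` from [assemble_trio()].
#' @param confidence_threshold Confidence cutoff (default 0.05).
#' @param keep_rule `"leq"` (default) keeps calls with confidence value
#'   \eqn{\le} the threshold — on this platform a *lower* confidence
#'   value is a *better* call; `"geq"` implements the opposite reading.
#' @return The filtered `"trio_matrix"`, with `n_valid_markers` set and a
#'   `removed` attribute-like element counting per-member removals (a
#'   marker may be counted against several members).
#' @export
filter_calls <- function(tm, confidence_threshold = 0.05,
                         keep_rule = c("leq", "geq")) {
  keep_rule <- match.arg(keep_rule)
  stopifnot(inherits(tm, "trio_matrix"))
  if (!is.finite(confidence_threshold) || confidence_threshold < 0 ||
      confidence_threshold > 1) {
    stop("confidence_threshold must lie in [0, 1]", call. = FALSE)
  }
  ok_member <- function(mem) {
    valid <- mem$genotype != "NoCall"
    pass <- if (keep_rule == "leq") mem$confidence <= confidence_threshold
            else mem$confidence >= confidence_threshold
    valid & pass
  }
  okf <- ok_member(tm$father)
  okm <- ok_member(tm$mother)
  okc <- ok_member(tm$child)
  keep <- okf & okm & okc
  subset_member <- function(mem) {
    out <- mem[keep, , drop = FALSE]; rownames(out) <- NULL; out
  }
  tm$removed <- c(father = sum(!okf), mother = sum(!okm), child = sum(!okc))
  tm$markers <- tm$markers[keep, , drop = FALSE]
  rownames(tm$markers) <- NULL
  tm$father <- subset_member(tm$father)
  tm$mother <- subset_member(tm$mother)
  tm$child <- subset_member(tm$child)
  tm$n_valid_markers <- sum(keep)
  tm$filtered <- TRUE
  tm
}

#' @export
print.trio_matrix <- function(x, ...) {
  cat(sprintf("Trio '%s': %d markers%s\n", x$family_id, nrow(x$markers),
              if (x$filtered)
                sprintf(" (filtered; n_valid = %d)", x$n_valid_markers)
              else " (unfiltered)"))
  invisible(x)
}
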