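#' Classify one trio genotype combination
#'
#' Decides whether a child's genotype at a biallelic marker is compatible
#' with Mendelian transmission from the two parental genotypes and, for a
#' deviation, infers the parent of origin when Mendelian logic determines
#' it uniquely.
#'
#' A combination is *consistent* when some pair of gametes — one allele
#' drawn from each parent — produces the child genotype. Otherwise it is
#' a *deviation*: at least one transmitted allele must have mutated. The
#' origin is attributed to a parent P when the single-mutation
#' explanation "P's gamete mutated, the other parent transmitted one of
#' the child's alleles unchanged" works for P and only for P. When the
#' single-mutation explanation works for both parents (e.g. AA x AA
#' child AB) or for neither (two mutated gametes, e.g. AA x AA child
#' BB), the origin is `"unknown"`.
#'
#' The ancestral (pre-mutation) and derived alleles are reported whenever
#' uniquely determined: for origin-resolved deviations the mutated parent
#' is homozygous, so the ancestral allele is that parent's allele and the
#' derived allele is the child allele the other parent cannot have given;
#' for origin-unknown deviations with both parents homozygous for the
#' same allele, the ancestral allele is the shared parental allele.
#'
#' @param father_gt,mother_gt,child_gt Genotypes in A/B allele space,
#'   each one of `"AA"`, `"AB"`, `"BB"` (vectors recycle to a common
#'   length). No-calls must be removed by QC first and are an error here.
#' @return A `data.frame` with one row per combination: `status`
#'   (`"consistent"`/`"deviation"`), `origin` (`"father"`, `"mother"`,
#'   `"unknown"`, or `NA` for consistent rows), `ancestral` and `derived`
#'   (allele letters `"A"`/`"B"`, or `NA` when not determinable).
#' @examples
#' classify_transmission("AA", "AB", "BB")   # deviation, father origin
#' classify_transmission("AA", "BB", "AB")   # consistent
#' @export
classify_transmission <- function(father_gt, mother_gt, child_gt) {
  n <- max(length(father_gt), length(mother_gt), length(child_gt))
  f <- rep_len(as.character(father_gt), n)
  m <- rep_len(as.character(mother_gt), n)
  k <- rep_len(as.character(child_gt), n)
  if (any(!(c(f, m, k) %in% c("AA", "AB", "BB")))) {
    stop("genotypes must be AA/AB/BB (run QC to drop no-calls first)",
         call. = FALSE)
  }
  key <- paste(f, m, k)
  idx <- match(key, .transmission_table$key)
  out <- .transmission_table[idx, c("status", "origin", "ancestral", "derived")]
  rownames(out) <- NULL
  out
}

# Precomputed verdicts for all 27 (father, mother, child) combinations in
# A/B space. Built once at load time from first principles: gamete-pair
# enumeration for consistency, single-mutation explanations for origin.
.build_transmission_table <- function() {
  alleles <- function(gt) c(substr(gt, 1, 1), substr(gt, 2, 2))
  gts <- c("AA", "AB", "BB")
  rows <- expand.grid(f = gts, m = gts, k = gts, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    fa <- alleles(rows$f[i]); ma <- alleles(rows$m[i]); ka <- alleles(rows$k[i])
    consistent <- any(vapply(fa, function(x)
      any(vapply(ma, function(y)
        setequal_multiset(c(x, y), ka), TRUE)), TRUE))
    if (consistent) {
      return(data.frame(status = "consistent", origin = NA_character_,
                        ancestral = NA_character_, derived = NA_character_,
                        stringsAsFactors = FALSE))
    }
    # single-mutation explanations: the non-mutated parent must be able to
    # transmit one of the child's alleles; the other child allele is derived.
    father_mut <- any(ka %in% ma)  # mother explains one child allele
    mother_mut <- any(ka %in% fa)
    origin <- if (father_mut && !mother_mut) "father"
              else if (mother_mut && !father_mut) "mother"
              else "unknown"
    anc <- der <- NA_character_
    if (origin == "father") {
      der <- setdiff_one(ka, ma)
      if (fa[1] == fa[2]) anc <- fa[1]
    } else if (origin == "mother") {
      der <- setdiff_one(ka, fa)
      if (ma[1] == ma[2]) anc <- ma[1]
    } else if (fa[1] == fa[2] && ma[1] == ma[2] && fa[1] == ma[1]) {
      # both parents homozygous for the same allele: every non-parental
      # child allele descends from it
      anc <- fa[1]
      der <- setdiff(ka, fa[1])[1]
    }
    data.frame(status = "deviation", origin = origin,
               ancestral = anc, derived = der, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$key <- paste(rows$f, rows$m, rows$k)
  tab
}

# multiset equality of two length-2 allele vectors
setequal_multiset <- function(x, y) {
  identical(sort(x), sort(y))
}

# the child allele not attributable to the given parent; when both child
# alleles are attributable the derived allele is ambiguous only if the
# child is heterozygous with both alleles in the parent's set, which
# cannot occur for a deviation (it would be consistent) -- pick the one
# the parent lacks, else the duplicated allele.
setdiff_one <- function(child_alleles, other_parent_alleles) {
  not_expl <- child_alleles[!(child_alleles %in% other_parent_alleles)]
  if (length(not_expl) > 0L) not_expl[1] else child_alleles[1]
}

.transmission_table <- .build_transmission_table()

#' Classify a trio base-call combination (base space)
#'
#' Equivalent of [classify_transmission()] operating directly on
#' unordered base pairs (e.g. `"A/A"`, `"C/G"`), for data where calls are
#' expressed as nucleotides rather than in a probe's A/B space. A
#' biallelic probe can only call its two design alleles, but the logic is
#' general: it supports third-base child calls for completeness.
#'
#' @param father_bc,mother_bc,child_bc Base calls as `"X/Y"` strings.
#' @return One-row `data.frame` as in [classify_transmission()], with
#'   `ancestral`/`derived` holding nucleotide letters.
#' @examples
#' classify_transmission_bases("A/A", "C/C", "G/C")  # deviation, father
#' @export
classify_transmission_bases <- function(father_bc, mother_bc, child_bc) {
  split_bc <- function(x) strsplit(toupper(x), "/", fixed = TRUE)[[1]]
  fa <- split_bc(father_bc); ma <- split_bc(mother_bc); ka <- split_bc(child_bc)
  if (length(fa) != 2L || length(ma) != 2L || length(ka) != 2L ||
      !all(c(fa, ma, ka) %in% VALID_BASES)) {
    stop("base calls must be 'X/Y' with X,Y in {A,C,G,T}", call. = FALSE)
  }
  consistent <- any(vapply(fa, function(x)
    any(vapply(ma, function(y) setequal_multiset(c(x, y), ka), TRUE)), TRUE))
  if (consistent) {
    return(data.frame(status = "consistent", origin = NA_character_,
                      ancestral = NA_character_, derived = NA_character_,
                      stringsAsFactors = FALSE))
  }
  father_mut <- any(ka %in% ma)
  mother_mut <- any(ka %in% fa)
  origin <- if (father_mut && !mother_mut) "father"
            else if (mother_mut && !father_mut) "mother"
            else "unknown"
  anc <- der <- NA_character_
  if (origin == "father") {
    der <- setdiff_one(ka, ma)
    if (fa[1] == fa[2]) anc <- fa[1]
  } else if (origin == "mother") {
    der <- setdiff_one(ka, fa)
    if (ma[1] == ma[2]) anc <- ma[1]
  } else if (fa[1] == fa[2] && ma[1] == ma[2] && fa[1] == ma[1]) {
    anc <- fa[1]
    der <- setdiff(ka, fa[1])[1]
  }
  data.frame(status = "deviation", origin = origin,
             ancestral = anc, derived = der, stringsAsFactors = FALSE)
}

#' Detect Mendelian deviations in a filtered trio
#'
#' Scans every retained marker of a QC-filtered trio and returns one row
#' per Mendelian deviation — a child genotype no pair of parental gametes
#' can produce, interpreted as a candidate de novo point mutation.
#'
#' @param tm A filtered `"trio_matrix"` (see [filter_calls()]).
#' @return A `data.frame` of deviations sorted by (chromosome, position):
#'   marker identity, the three genotypes and base calls, parental call
#'   confidences, `origin` (father/mother/unknown), `origin_method`
#'   (`"mendelian"` when transmission logic resolved it, else
#'   `"unresolved"`), ancestral/derived alleles in A/B space and as
#'   nucleotides, `substitution_class` (see [substitution_class()];
#'   `NA` when the ancestral base is undeterminable), and `in_cpg`
#'   (initialized `FALSE`; see [flag_cpg()]).
#' @export
detect_deviations <- function(tm) {
  stopifnot(inherits(tm, "trio_matrix"))
  if (!tm$filtered) {
    warning("trio matrix has not been QC-filtered; filtering with defaults")
    tm <- filter_calls(tm)
  }
  v <- classify_transmission(tm$father$genotype, tm$mother$genotype,
                             tm$child$genotype)
  dev <- which(v$status == "deviation")
  mk <- tm$markers[dev, , drop = FALSE]
  to_base <- function(ab, allele_a, allele_b) {
    ifelse(is.na(ab), NA_character_, ifelse(ab == "A", allele_a, allele_b))
  }
  anc_base <- to_base(v$ancestral[dev], mk$allele_a, mk$allele_b)
  der_base <- to_base(v$derived[dev], mk$allele_a, mk$allele_b)
  cls <- rep(NA_character_, length(dev))
  ok <- !is.na(anc_base) & !is.na(der_base)
  if (any(ok)) cls[ok] <- substitution_class(anc_base[ok], der_base[ok])
  mds <- data.frame(
    family_id = rep(tm$family_id, length(dev)),
    probe_id = mk$probe_id,
    dbsnp = mk$dbsnp,
    chrom = mk$chrom,
    pos = mk$pos,
    father_gt = tm$father$genotype[dev],
    mother_gt = tm$mother$genotype[dev],
    child_gt = tm$child$genotype[dev],
    father_bases = base_call(tm$father$genotype[dev], mk$allele_a, mk$allele_b),
    mother_bases = base_call(tm$mother$genotype[dev], mk$allele_a, mk$allele_b),
    child_bases = base_call(tm$child$genotype[dev], mk$allele_a, mk$allele_b),
    father_confidence = tm$father$confidence[dev],
    mother_confidence = tm$mother$confidence[dev],
    origin = v$origin[dev],
    origin_method = ifelse(v$origin[dev] == "unknown", "unresolved",
                           "mendelian"),
    ancestral_allele = v$ancestral[dev],
    derived_allele = v$derived[dev],
    ancestral_base = anc_base,
    derived_base = der_base,
    substitution_class = cls,
    in_cpg = rep(FALSE, length(dev)),
    stringsAsFactors = FALSE
  )
  ord <- order(as.integer(mds$chrom), mds$pos)
  mds <- mds[ord, , drop = FALSE]
  rownames(mds) <- NULL
  mds
}

#' Recurrence of deviating markers across trios
#'
#' How often is the same marker called deviant in several families?
#' Mostly-unique deviations argue for independent mutational events;
#' heavy recurrence would point at problem probes.
#'
#' @param mds A deviation table covering two or more trios (rows from
#'   [detect_deviations()] concatenated, with distinct `family_id`s), or
#'   a list of per-trio deviation tables.
#' @return A `data.frame` with `recurrence` (number of trios sharing a
#'   deviating marker), `n_markers`, and `fraction` of distinct deviating
#'   markers.
#' @export
tabulate_recurrence <- function(mds) {
  if (is.list(mds) && !is.data.frame(mds)) {
    mds <- do.call(rbind, mds)
  }
  if (length(unique(mds$family_id)) < 2L) {
    stop("recurrence needs deviations from at least two trios", call. = FALSE)
  }
  per_marker <- tapply(mds$family_id, mds$probe_id,
                       function(f) length(unique(f)))
  tab <- table(factor(per_marker, levels = seq_len(max(per_marker))))
  data.frame(recurrence = as.integer(names(tab)),
             n_markers = as.integer(tab),
             fraction = as.numeric(tab) / length(per_marker))
}
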