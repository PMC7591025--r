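#' Parent-of-origin candidate from call confidence
#'
#' For a deviation whose origin Mendelian logic leaves ambiguous, the
#' parent whose call at the marker has the *lowest* confidence value
#' (best call quality on this platform, but also the call most likely to
#' sit near a cluster boundary) is the candidate carrier of the mutated
#' gamete. An exact tie, or a missing parental confidence, is
#' uninformative.
#'
#' @param father_confidence,mother_confidence Per-call confidence values
#'   at the deviating marker (vectors recycle).
#' @return Character vector: `"father"`, `"mother"`, or `"tie"`.
#' @export
deduce_by_confidence <- function(father_confidence, mother_confidence) {
  n <- max(length(father_confidence), length(mother_confidence))
  f <- rep_len(as.numeric(father_confidence), n)
  m <- rep_len(as.numeric(mother_confidence), n)
  out <- rep("tie", n)
  ok <- !is.na(f) & !is.na(m)
  out[ok & f < m] <- "father"
  out[ok & m < f] <- "mother"
  out
}

#' Parent-of-origin candidate from the nearest resolved deviation
#'
#' The mutated gamete carried a whole chromosomal segment from one
#' parent; the nearest deviation on the same chromosome whose origin
#' Mendelian logic already resolved is used as a proxy for which parent
#' transmitted the segment. Distance is absolute base-pair distance
#' (1-D Euclidean). Equidistant neighbors are broken toward the lower
#' genomic position, deterministically.
#'
#' @param pos Position of the ambiguous deviation (1-based, scalar).
#' @param resolved A `data.frame` of Mendelian-resolved deviations on the
#'   *same chromosome in the same trio*, with columns `pos`, `origin`,
#'   `probe_id`.
#' @param window_bp Maximum neighbor distance; beyond it no candidate
#'   (default `Inf`: whole chromosome).
#' @return A one-row `data.frame`: `candidate` (`"father"`, `"mother"`,
#'   or `"none"`), `neighbor_probe_id`, `distance_bp`.
#' @export
deduce_by_neighbor <- function(pos, resolved, window_bp = Inf) {
  none <- data.frame(candidate = "none", neighbor_probe_id = NA_character_,
                     distance_bp = NA_real_, stringsAsFactors = FALSE)
  if (is.null(resolved) || nrow(resolved) == 0L) return(none)
  d <- abs(resolved$pos - pos)
  inwin <- which(d <= window_bp)
  if (length(inwin) == 0L) return(none)
  # minimal distance, ties toward the lower genomic position
  cand <- inwin[order(d[inwin], resolved$pos[inwin])][1L]
  data.frame(candidate = resolved$origin[cand],
             neighbor_probe_id = resolved$probe_id[cand],
             distance_bp = d[cand], stringsAsFactors = FALSE)
}

#' Resolve ambiguous parent-of-origin assignments
#'
#' Applies the two deductions to every origin-unknown deviation of one
#' trio and assigns an origin only when both agree: the candidate parent
#' must have the lowest call confidence at the marker *and* be the origin
#' of the nearest Mendelian-resolved deviation on the same chromosome.
#' Disagreement, a confidence tie, or no eligible neighbor leaves the
#' deviation unresolved. Mendelian-resolved origins are never touched,
#' and only they serve as neighbors (deduced origins do not feed later
#' deductions), in a single deterministic pass.
#'
#' @param mds Per-trio deviation table from [detect_deviations()].
#' @param window_bp Neighbor search window in bp (default `Inf`).
#' @return `mds` with `origin` and `origin_method` updated (method
#'   `"deduced"` where both deductions agreed) and bookkeeping columns
#'   `deduced_by_confidence`, `deduced_by_neighbor`,
#'   `neighbor_probe_id`, `neighbor_distance_bp` filled for previously
#'   unknown rows.
#' @export
resolve_unknown_origins <- function(mds, window_bp = Inf) {
  mds$deduced_by_confidence <- NA_character_
  mds$deduced_by_neighbor <- NA_character_
  mds$neighbor_probe_id <- NA_character_
  mds$neighbor_distance_bp <- NA_real_
  unk <- which(mds$origin == "unknown")
  if (length(unk) == 0L) return(mds)
  if (length(unique(mds$family_id)) > 1L) {
    stop("resolve_unknown_origins operates on one trio at a time",
         call. = FALSE)
  }
  mds$deduced_by_confidence[unk] <- deduce_by_confidence(
    mds$father_confidence[unk], mds$mother_confidence[unk])
  resolved_by_chrom <- split(
    mds[mds$origin_method == "mendelian", c("pos", "origin", "probe_id")],
    mds$chrom[mds$origin_method == "mendelian"])
  for (i in unk) {
    nb <- deduce_by_neighbor(mds$pos[i], resolved_by_chrom[[mds$chrom[i]]],
                             window_bp)
    mds$deduced_by_neighbor[i] <- nb$candidate
    mds$neighbor_probe_id[i] <- nb$neighbor_probe_id
    mds$neighbor_distance_bp[i] <- nb$distance_bp
    agree <- nb$candidate %in% c("father", "mother") &&
      identical(nb$candidate, mds$deduced_by_confidence[i])
    if (agree) {
      mds$origin[i] <- nb$candidate
      mds$origin_method[i] <- "deduced"
    }
  }
  mds
}
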