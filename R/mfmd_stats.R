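#' Germline mutation frequency per transmitted allele
#'
#' The per-trio germline mutation frequency is the total number of
#' Mendelian deviations divided by twice the number of valid SNPs —
#' each valid biallelic marker contributes two transmitted alleles:
#' \deqn{MF_{MD} = \frac{\sum T_{MD}}{2 \, n_{vp}}}
#'
#' @param md_total Total Mendelian deviations for the trio (vectorized).
#' @param n_valid Valid-SNP count \eqn{n_{vp}} after QC filtering.
#' @return `md_total / (2 * n_valid)`.
#' @examples
#' mf_md(1487, 702304)  # 1.06e-3
#' @export
mf_md <- function(md_total, n_valid) {
  if (any(!is.finite(n_valid) | n_valid <= 0)) {
    stop("n_valid must be a positive count", call. = FALSE)
  }
  if (any(md_total < 0)) stop("md_total must be nonnegative", call. = FALSE)
  md_total / (2 * n_valid)
}

#' Build per-trio summaries from deviation tables
#'
#' Collapses a deviation table (one or many trios) to one row per trio —
#' deviations by parent of origin, the unresolved remainder, totals, the
#' valid-SNP count, and \eqn{MF_{MD}} — joined with the trio manifest's
#' design columns. This is the per-family summary the group statistics
#' consume.
#'
#' @param mds Deviation table (after origin resolution, typically).
#' @param manifest Trio manifest (`family_id`, `group`, `exposed_parent`,
#'   `dose_gy`, ages, `child_sex`).
#' @param n_valid Named vector (or single value recycled) of per-trio
#'   valid-SNP counts, names = `family_id`.
#' @return A `data.frame`, one row per manifest family: `family_id`,
#'   `group`, `exposed_parent`, `dose_gy`, `paternal_age`,
#'   `maternal_age`, `child_age`, `child_sex`, `md_father`, `md_mother`,
#'   `md_unknown`, `md_total`, `n_valid`, `mf_md`.
#' @export
summarize_trios <- function(mds, manifest, n_valid) {
  if (is.null(names(n_valid)) && length(n_valid) == 1L) {
    n_valid <- stats::setNames(rep(n_valid, nrow(manifest)),
                               manifest$family_id)
  }
  fam <- factor(mds$family_id, levels = manifest$family_id)
  cnt <- function(sel) as.integer(table(fam[sel]))
  out <- manifest[, intersect(c("family_id", "group", "exposed_parent",
                                "dose_gy", "paternal_age", "maternal_age",
                                "child_age", "child_sex"), names(manifest))]
  out$md_father <- cnt(mds$origin == "father")
  out$md_mother <- cnt(mds$origin == "mother")
  out$md_unknown <- cnt(mds$origin == "unknown")
  out$md_total <- out$md_father + out$md_mother + out$md_unknown
  nv <- n_valid[match(out$family_id, names(n_valid))]
  if (any(is.na(nv))) {
    stop("n_valid missing for famil(ies): ",
         paste(out$family_id[is.na(nv)], collapse = ", "), call. = FALSE)
  }
  out$n_valid <- as.numeric(nv)
  out$mf_md <- mf_md(out$md_total, out$n_valid)
  rownames(out) <- NULL
  out
}

#' Published per-trio summaries of the Goiânia Cs-137 cohort
#'
#' The per-family results published for the Goiânia radiological-accident
#' cohort: 15 exposed trios (parental absorbed doses 0.1–0.5 Gy) and 15
#' unexposed control trios, with deviations by parent of origin, the
#' valid-SNP count of each trio's array, doses, parental ages at
#' conception, and child age/sex. Ships with the package and drives the
#' reproduction of the study's group statistics.
#'
#' @return A trio-summary `data.frame` (see [summarize_trios()] for the
#'   column contract), with `mf_md` recomputed from the printed counts.
#' @examples
#' head(goiania_cohort())
#' @export
goiania_cohort <- function() {
  path <- system.file("extdata", "goiania_cohort.tsv", package = "mendeviate",
                      mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$mf_md <- mf_md(d$md_total, d$n_valid)
  d
}

#' Percent increase of the case mean over the control mean
#'
#' @param mean_case,mean_control Group means (control must be positive).
#' @return `100 * (mean_case - mean_control) / mean_control`.
#' @export
percent_increase <- function(mean_case, mean_control) {
  if (!is.finite(mean_control) || mean_control <= 0) {
    stop("mean_control must be positive", call. = FALSE)
  }
  100 * (mean_case - mean_control) / mean_control
}

#' Group-level comparison of mutation frequencies
#'
#' Compares exposed and control trios: unweighted group means and SDs of
#' the per-trio \eqn{MF_{MD}}, the percent increase, a pooled-variance
#' two-sample t-test on the frequencies, a two-sided variance-ratio
#' F-test (by default on the per-trio deviation *counts*,
#' exposed/control), and per-group Shapiro-Wilk normality checks on the
#' counts (reported, never gated on).
#'
#' @param ts Trio-summary `data.frame` (see [summarize_trios()]) with
#'   both groups present, at least two trios each.
#' @param f_test_on `"counts"` (default) or `"mf_md"`: the variable whose
#'   group variances the F-test compares.
#' @return A list of class `"group_comparison"`: `n`, `mean_mf`, `sd_mf`
#'   (named per group), `percent_increase`, `t_statistic`, `t_df`, `t_p`,
#'   `f_statistic`, `f_df`, `f_p`, `shapiro_p` (per group and pooled).
#' @export
group_comparison <- function(ts, f_test_on = c("counts", "mf_md")) {
  f_test_on <- match.arg(f_test_on)
  ts$group <- tolower(ts$group)
  exp <- ts[ts$group == "exposed", ]
  ctl <- ts[ts$group == "control", ]
  if (nrow(exp) < 2L || nrow(ctl) < 2L) {
    stop("need at least two trios per group", call. = FALSE)
  }
  tt <- stats::t.test(exp$mf_md, ctl$mf_md, var.equal = TRUE)
  fvar <- if (f_test_on == "counts") list(e = exp$md_total, c = ctl$md_total)
          else list(e = exp$mf_md, c = ctl$mf_md)
  ft <- if (stats::var(fvar$c) > 0) stats::var.test(fvar$e, fvar$c) else NULL
  swp <- function(x) tryCatch(stats::shapiro.test(x)$p.value,
                              error = function(e) NA_real_)
  structure(list(
    n = c(exposed = nrow(exp), control = nrow(ctl)),
    mean_mf = c(exposed = mean(exp$mf_md), control = mean(ctl$mf_md)),
    sd_mf = c(exposed = stats::sd(exp$mf_md), control = stats::sd(ctl$mf_md)),
    percent_increase = percent_increase(mean(exp$mf_md), mean(ctl$mf_md)),
    t_statistic = unname(tt$statistic),
    t_df = unname(tt$parameter),
    t_p = tt$p.value,
    f_statistic = if (is.null(ft)) NA_real_ else unname(ft$statistic),
    f_df = if (is.null(ft)) c(NA_real_, NA_real_) else unname(ft$parameter),
    f_p = if (is.null(ft)) NA_real_ else ft$p.value,
    f_test_on = f_test_on,
    shapiro_p = c(exposed = swp(exp$md_total), control = swp(ctl$md_total),
                  pooled = swp(ts$md_total))
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison of germline mutation frequencies\n")
  cat(sprintf("  exposed: n = %d, mean MF_MD = %.3g (SD %.2g)\n",
              x$n["exposed"], x$mean_mf["exposed"], x$sd_mf["exposed"]))
  cat(sprintf("  control: n = %d, mean MF_MD = %.3g (SD %.2g)\n",
              x$n["control"], x$mean_mf["control"], x$sd_mf["control"]))
  cat(sprintf("  increase: %.1f%%\n", x$percent_increase))
  cat(sprintf("  pooled t = %.3f (df %d), p = %.3f\n",
              x$t_statistic, x$t_df, x$t_p))
  if (is.finite(x$f_statistic)) {
    cat(sprintf("  variance ratio F = %.3f (df %d, %d; on %s), p = %.3f\n",
                x$f_statistic, x$f_df[1], x$f_df[2], x$f_test_on, x$f_p))
  }
  cat(sprintf("  Shapiro-Wilk p (counts): exposed %.3f, control %.3f\n",
              x$shapiro_p["exposed"], x$shapiro_p["control"]))
  invisible(x)
}

#' Dose-response regression of mutation frequency
#'
#' Ordinary least squares of the per-trio \eqn{MF_{MD}} on the parental
#' absorbed dose in gray, over all trios (controls enter at dose 0).
#'
#' @param ts Trio-summary `data.frame` with `mf_md` and `dose_gy`.
#' @return A list of class `"dose_regression"`: `slope` (per Gy),
#'   `intercept`, `r_squared`, `p_slope`, `n`, and the underlying `lm`
#'   fit as `fit`.
#' @export
dose_regression <- function(ts) {
  if (nrow(ts) < 3L) stop("need at least three trios", call. = FALSE)
  if (stats::var(ts$dose_gy) == 0) {
    stop("all doses identical: no variance in the predictor", call. = FALSE)
  }
  fit <- stats::lm(mf_md ~ dose_gy, data = ts)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 p_slope = s$coefficients["dose_gy", "Pr(>|t|)"],
                 n = nrow(ts), fit = fit),
            class = "dose_regression")
}

#' @export
print.dose_regression <- function(x, ...) {
  cat(sprintf("MF_MD = %.4g + %.4g * dose (Gy); R^2 = %.3f, p(slope) = %.3f, n = %d\n",
              x$intercept, x$slope, x$r_squared, x$p_slope, x$n))
  invisible(x)
}

#' Mutation frequency by sex of the exposed parent
#'
#' Among exposed trios, splits by which parent was exposed and compares
#' the subgroup means of \eqn{MF_{MD}} with a pooled-variance t-test.
#'
#' @param ts Trio-summary `data.frame`.
#' @return A list: `father` and `mother` sublists (`n`, `mean`, `sd` —
#'   `sd` is `NA` below two trios), and `t_p` (`NA` when either subgroup
#'   has fewer than two trios).
#' @export
subgroup_by_exposed_parent <- function(ts) {
  exp <- ts[tolower(ts$group) == "exposed", ]
  sub <- function(parent) {
    x <- exp$mf_md[exp$exposed_parent == parent]
    list(n = length(x), mean = if (length(x)) mean(x) else NA_real_,
         sd = if (length(x) >= 2L) stats::sd(x) else NA_real_)
  }
  fa <- sub("father"); mo <- sub("mother")
  t_p <- if (fa$n >= 2L && mo$n >= 2L) {
    stats::t.test(exp$mf_md[exp$exposed_parent == "father"],
                  exp$mf_md[exp$exposed_parent == "mother"],
                  var.equal = TRUE)$p.value
  } else NA_real_
  list(father = fa, mother = mo, t_p = t_p)
}

#' Paternal-fraction and parental-age analyses
#'
#' For each trio, the paternal fraction is the share of origin-resolved
#' deviations attributed to the father, `md_father / (md_father +
#' md_mother)`. The fraction and the per-parent deviation counts are
#' regressed on the parental ages at conception, separately per group —
#' the classic male-mutation-bias / parental-age-effect analyses.
#'
#' @param ts Trio-summary `data.frame` with parental ages.
#' @return A list: `per_trio` (`family_id`, `group`, ages,
#'   `paternal_fraction`) and `regressions`, a `data.frame` with one row
#'   per (group, response, predictor) OLS fit: slope, intercept,
#'   r_squared, p_slope, n.
#' @export
paternal_fraction_analysis <- function(ts) {
  denom <- ts$md_father + ts$md_mother
  frac <- ifelse(denom > 0, ts$md_father / denom, NA_real_)
  per_trio <- data.frame(family_id = ts$family_id, group = ts$group,
                         paternal_age = ts$paternal_age,
                         maternal_age = ts$maternal_age,
                         md_father = ts$md_father, md_mother = ts$md_mother,
                         paternal_fraction = frac, stringsAsFactors = FALSE)
  specs <- expand.grid(
    group = unique(ts$group),
    response = c("paternal_fraction", "md_father", "md_mother"),
    predictor = c("paternal_age", "maternal_age"),
    stringsAsFactors = FALSE)
  fits <- lapply(seq_len(nrow(specs)), function(i) {
    d <- per_trio[per_trio$group == specs$group[i], ]
    y <- d[[specs$response[i]]]; x <- d[[specs$predictor[i]]]
    ok <- is.finite(y) & is.finite(x)
    if (sum(ok) < 3L || stats::var(x[ok]) == 0) {
      return(data.frame(specs[i, ], slope = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_, p_slope = NA_real_,
                        n = sum(ok)))
    }
    fit <- stats::lm(y[ok] ~ x[ok])
    s <- summary(fit)
    data.frame(specs[i, ], slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = s$r.squared,
               p_slope = s$coefficients[2, "Pr(>|t|)"], n = sum(ok))
  })
  regs <- do.call(rbind, fits)
  rownames(regs) <- NULL
  list(per_trio = per_trio, regressions = regs)
}
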