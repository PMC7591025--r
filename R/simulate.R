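#' Simulation configuration
#'
#' Parameters of the synthetic trio generator. Markers are biallelic
#' autosomal SNPs with minor-allele frequencies drawn uniformly from
#' `maf_range`; parents are drawn under Hardy-Weinberg equilibrium; the
#' child receives one allele from each parent. A transmitted allele flips
#' to the other probe allele with probability `mu` per gamete per marker
#' (the injected de novo mutation), after which per-call genotyping
#' errors (probability `epsilon`) and no-calls (`nocall_rate`) are
#' applied. Confidence values of called genotypes are uniform on
#' `confidence_range` (the platform's passing band).
#'
#' @param n_markers Markers per trio (default 50000: a deliberately
#'   scaled-down array; the real platform carries ~700k).
#' @param maf_range Minor-allele-frequency bounds (default `c(0.05, 0.5)`).
#' @param mu Per-gamete per-marker de novo probability (default `1e-3`).
#' @param epsilon Per-call genotyping-error probability (default 0).
#' @param nocall_rate Per-call no-call probability (default 0).
#' @param confidence_range Confidence band for called genotypes
#'   (default `c(0, 0.05)`, passing the default QC threshold).
#' @param n_chromosomes Chromosomes markers are spread over (default 22).
#' @param spacing_bp Base pairs between adjacent markers (default 3000).
#' @param seed Integer seed; a fixed seed makes output byte-identical.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_markers = 50000, maf_range = c(0.05, 0.5),
                       mu = 1e-3, epsilon = 0, nocall_rate = 0,
                       confidence_range = c(0, 0.05), n_chromosomes = 22,
                       spacing_bp = 3000, seed = 1) {
  stopifnot(n_markers >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            mu >= 0, mu <= 1, epsilon >= 0, epsilon <= 1,
            nocall_rate >= 0, nocall_rate <= 1,
            n_chromosomes >= 1, n_chromosomes <= 22)
  if (mu + epsilon > 0.1) {
    warning("mu + epsilon > 0.1: degenerate regime, most markers will deviate")
  }
  structure(list(n_markers = as.integer(n_markers), maf_range = maf_range,
                 mu = mu, epsilon = epsilon, nocall_rate = nocall_rate,
                 confidence_range = confidence_range,
                 n_chromosomes = as.integer(n_chromosomes),
                 spacing_bp = spacing_bp, seed = as.integer(seed)),
            class = "sim_config")
}

#' Probability that a single de novo flip is detectable
#'
#' Exact enumeration, under Hardy-Weinberg parental genotypes at
#' minor-allele frequency `maf`, of the probability that flipping one
#' transmitted allele yields a trio genotype combination that is a
#' Mendelian deviation. Flips into contexts where a heterozygous parent
#' could have transmitted the derived allele anyway are masked, so the
#' probability is below 1 except in the `maf -> 0` limit (where parents
#' are almost surely homozygous for the major allele and any flip shows).
#'
#' @param maf Minor-allele frequency (frequency of the B allele), in
#'   `(0, 0.5]`; vectorized.
#' @return Detection probability for each `maf`.
#' @export
detectability_probability <- function(maf) {
  stopifnot(all(maf > 0 & maf <= 0.5))
  vapply(maf, function(p) {
    q <- 1 - p
    gfreq <- c(AA = q^2, AB = 2 * p * q, BB = p^2)
    gts <- names(gfreq)
    alleles <- function(gt) c(substr(gt, 1, 1), substr(gt, 2, 2))
    total <- 0
    for (fg in gts) for (mg in gts) {
      pw <- gfreq[[fg]] * gfreq[[mg]]
      for (af in alleles(fg)) for (am in alleles(mg)) {
        tw <- pw * 0.25  # each parent transmits each listed allele w.p. 1/2
        for (flip in c("father", "mother")) {
          ca <- c(af, am)
          i <- if (flip == "father") 1L else 2L
          ca[i] <- if (ca[i] == "A") "B" else "A"
          cg <- paste(sort(ca), collapse = "")
          v <- classify_transmission(fg, mg, cg)
          if (v$status == "deviation") total <- total + tw * 0.5
        }
      }
    }
    total
  }, numeric(1))
}

#' Mean detectability over a minor-allele-frequency band
#'
#' Average of [detectability_probability()] over a uniform MAF
#' distribution on `maf_range`, by midpoint quadrature.
#'
#' @param maf_range Length-2 bounds.
#' @param n_grid Quadrature points (default 201).
#' @return Scalar mean detection probability.
#' @export
mean_detectability <- function(maf_range = c(0.05, 0.5), n_grid = 201) {
  grid <- seq(maf_range[1], maf_range[2], length.out = n_grid)
  mid <- (grid[-1] + grid[-n_grid]) / 2
  mean(detectability_probability(mid))
}

# shared marker map for one simulated cohort
.sim_markers <- function(config) {
  n <- config$n_markers
  chrom <- as.character(rep_len(seq_len(config$n_chromosomes), n))
  idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  bases <- c("A", "C", "G", "T")
  a <- sample(bases, n, replace = TRUE)
  b <- vapply(a, function(x) sample(setdiff(bases, x), 1L), "")
  data.frame(probe_id = sprintf("S-%07d", seq_len(n)),
             dbsnp = sprintf("rs%07d", seq_len(n)),
             chrom = chrom,
             pos = idx * config$spacing_bp,
             allele_a = a, allele_b = unname(b),
             maf = stats::runif(n, config$maf_range[1], config$maf_range[2]),
             stringsAsFactors = FALSE)
}

.hwe_genotypes <- function(maf) {
  u <- stats::runif(length(maf))
  q <- 1 - maf
  ifelse(u < q^2, "AA", ifelse(u < q^2 + 2 * maf * q, "AB", "BB"))
}

.transmit <- function(gt) {
  # one allele per genotype; heterozygotes transmit either with p = 1/2
  ifelse(gt == "AA", "A",
         ifelse(gt == "BB", "B",
                ifelse(stats::runif(length(gt)) < 0.5, "A", "B")))
}

.gt_from_alleles <- function(a1, a2) {
  ifelse(a1 == a2, paste0(a1, a2),
         "AB")
}

.member_table <- function(markers, gt, config) {
  n <- nrow(markers)
  conf <- stats::runif(n, config$confidence_range[1], config$confidence_range[2])
  nocall <- stats::runif(n) < config$nocall_rate
  gt[nocall] <- "NoCall"
  conf[nocall] <- 1
  # crude two-channel intensity model; signals are carried, not analyzed
  sa <- round(stats::rnorm(n, ifelse(gt == "AA", 2, ifelse(gt == "AB", 1.2, 0.3)), 0.1), 4)
  sb <- round(stats::rnorm(n, ifelse(gt == "BB", 2, ifelse(gt == "AB", 1.2, 0.3)), 0.1), 4)
  df <- data.frame(markers[c("probe_id", "dbsnp", "chrom", "pos",
                             "allele_a", "allele_b")],
                   genotype = gt,
                   confidence = round(conf, 6),
                   signal_a = pmax(sa, 0), signal_b = pmax(sb, 0),
                   stringsAsFactors = FALSE)
  df$base_call <- base_call(df$genotype, df$allele_a, df$allele_b)
  df
}

.apply_genotype_errors <- function(gt, epsilon) {
  hit <- which(stats::runif(length(gt)) < epsilon)
  if (length(hit) > 0L) {
    gt[hit] <- vapply(gt[hit], function(g)
      sample(setdiff(c("AA", "AB", "BB"), g), 1L), "")
  }
  list(gt = gt, hit = hit)
}

#' Simulate one family trio
#'
#' @param config A [sim_config()].
#' @param markers Marker map from the cohort-level generator (internal
#'   layout); pass `NULL` to draw a fresh map.
#' @param family_id Family label.
#' @param mu Override of `config$mu` for this trio (used by dose-linked
#'   presets).
#' @return A list: `father`, `mother`, `child` genotype tables and
#'   `truth`, a `data.frame` of injected events (`probe_id`, `family_id`,
#'   `event` in `de_novo`/`genotype_error`, `member`, `ancestral_base`,
#'   `derived_base`, `detectable`).
#' @keywords internal
simulate_trio <- function(config, markers = NULL, family_id = "sim1",
                          mu = config$mu) {
  if (is.null(markers)) markers <- .sim_markers(config)
  n <- nrow(markers)
  fgt <- .hwe_genotypes(markers$maf)
  mgt <- .hwe_genotypes(markers$maf)
  af <- .transmit(fgt)
  am <- .transmit(mgt)
  flip <- function(x) ifelse(x == "A", "B", "A")
  mut_f <- which(stats::runif(n) < mu)
  mut_m <- which(stats::runif(n) < mu)
  anc_f <- af[mut_f]; af[mut_f] <- flip(af[mut_f])
  anc_m <- am[mut_m]; am[mut_m] <- flip(am[mut_m])
  cgt <- .gt_from_alleles(af, am)

  allele_base <- function(idx, ab) {
    ifelse(ab == "A", markers$allele_a[idx], markers$allele_b[idx])
  }
  n_dn <- length(mut_f) + length(mut_m)
  truth_dn <- data.frame(
    probe_id = markers$probe_id[c(mut_f, mut_m)],
    family_id = rep(family_id, n_dn),
    event = rep("de_novo", n_dn),
    member = c(rep("father", length(mut_f)), rep("mother", length(mut_m))),
    ancestral_base = c(allele_base(mut_f, anc_f),
                       allele_base(mut_m, anc_m)),
    derived_base = c(allele_base(mut_f, flip(anc_f)),
                     allele_base(mut_m, flip(anc_m))),
    stringsAsFactors = FALSE
  )
  mut_idx <- c(mut_f, mut_m)
  truth_dn$detectable <- if (length(mut_idx) > 0L) {
    classify_transmission(fgt[mut_idx], mgt[mut_idx],
                          cgt[mut_idx])$status == "deviation"
  } else logical(0)

  ef <- .apply_genotype_errors(fgt, config$epsilon)
  em <- .apply_genotype_errors(mgt, config$epsilon)
  ec <- .apply_genotype_errors(cgt, config$epsilon)
  err_idx <- c(ef$hit, em$hit, ec$hit)
  truth_err <- data.frame(
    probe_id = markers$probe_id[err_idx],
    family_id = rep(family_id, length(err_idx)),
    event = rep("genotype_error", length(err_idx)),
    member = c(rep("father", length(ef$hit)), rep("mother", length(em$hit)),
               rep("child", length(ec$hit))),
    ancestral_base = rep(NA_character_, length(err_idx)),
    derived_base = rep(NA_character_, length(err_idx)),
    detectable = rep(NA, length(err_idx)),
    stringsAsFactors = FALSE
  )
  list(father = .member_table(markers, ef$gt, config),
       mother = .member_table(markers, em$gt, config),
       child = .member_table(markers, ec$gt, config),
       truth = rbind(truth_dn, truth_err))
}

#' Simulate a cohort of trios with known injected mutations
#'
#' Generates per-sample genotype tables for `n_trios` families (or for an
#' explicit `design`), a trio manifest, and a truth log of every injected
#' de novo mutation and genotyping error. All families share one marker
#' map. Each family uses a deterministic substream of the global seed, so
#' the full dataset and any single family are reproducible.
#'
#' @param config A [sim_config()].
#' @param n_trios Number of (control, dose-0) families to generate when
#'   no `design` is given.
#' @param design Optional `data.frame` with one row per family:
#'   `family_id`, `group`, `exposed_parent`, `dose_gy`, optionally ages,
#'   `child_sex`, and `mu` (per-family de novo probability; defaults to
#'   `config$mu`).
#' @param dir Optional output directory; when given, per-sample TSVs, a
#'   `manifest.tsv` and a `truth.tsv` are written in the package dialect
#'   and the returned object carries their paths.
#' @return A list of class `"sim_cohort"`: `trios` (named list of
#'   father/mother/child genotype tables), `manifest`, `truth`, `config`,
#'   and (when `dir` was given) `paths`.
#' @export
simulate_trios <- function(config, n_trios = NULL, design = NULL, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(design)) {
    if (is.null(n_trios)) stop("give n_trios or design", call. = FALSE)
    design <- data.frame(
      family_id = sprintf("Sim%02d", seq_len(n_trios)),
      group = "control", exposed_parent = "none", dose_gy = 0,
      paternal_age = 30, maternal_age = 28, child_age = 10,
      child_sex = rep_len(c("male", "female"), n_trios),
      stringsAsFactors = FALSE)
  }
  if (is.null(design$mu)) design$mu <- config$mu
  set.seed(config$seed)
  markers <- .sim_markers(config)
  trios <- vector("list", nrow(design))
  names(trios) <- design$family_id
  truth <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    set.seed((config$seed * 1009L + i) %% .Machine$integer.max)
    sim <- simulate_trio(config, markers, design$family_id[i],
                         mu = design$mu[i])
    trios[[i]] <- sim[c("father", "mother", "child")]
    truth[[i]] <- sim$truth
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  run_id <- sprintf("sim-%d-%d-%d", config$seed, config$n_markers,
                    nrow(design))
  attr(truth, "run_id") <- run_id
  manifest <- design[setdiff(names(design), "mu")]
  out <- structure(list(trios = trios, manifest = manifest, truth = truth,
                        config = config, run_id = run_id),
                   class = "sim_cohort")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- lapply(seq_len(nrow(design)), function(i) {
      fid <- design$family_id[i]
      p <- file.path(dir, paste0(fid, c("_father", "_mother", "_child"), ".tsv"))
      write_genotype_table(trios[[i]]$father, p[1])
      write_genotype_table(trios[[i]]$mother, p[2])
      write_genotype_table(trios[[i]]$child, p[3])
      stats::setNames(p, c("father_file", "mother_file", "child_file"))
    })
    pm <- do.call(rbind, paths)
    manifest <- cbind(manifest, as.data.frame(pm, stringsAsFactors = FALSE))
    utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$manifest <- manifest
    out$paths <- list(dir = dir, manifest = file.path(dir, "manifest.tsv"),
                      truth = file.path(dir, "truth.tsv"))
  }
  out
}

#' Cohort-faithful simulation design
#'
#' The study design of the published Goiânia cohort (15 exposed + 15
#' control families with their doses, ages and child sexes) with a
#' per-family de novo probability calibrated so the expected mutation
#' frequency follows the cohort's dose response: `MF = 0.9e-3 + 1.0e-3 *
#' dose` (controls at the 0.9e-3 baseline). Calibration divides the
#' target frequency by the mean detectability of a flip under the
#' configured MAF distribution, since only detectable flips surface as
#' deviations.
#'
#' @param config A [sim_config()] (its `maf_range` fixes the calibration).
#' @return A `design` `data.frame` for [simulate_trios()], with `mu` and
#'   `target_mf` columns.
#' @export
cohort_design <- function(config = sim_config()) {
  d <- goiania_cohort()
  design <- d[c("family_id", "group", "exposed_parent", "dose_gy",
                "paternal_age", "maternal_age", "child_age", "child_sex")]
  design$target_mf <- 0.9e-3 + 1.0e-3 * design$dose_gy
  design$mu <- design$target_mf / mean_detectability(config$maf_range)
  design
}

#' Score detection against the simulation truth log
#'
#' @param truth Truth log from [simulate_trios()].
#' @param detected Deviation table(s) from [detect_deviations()] run on
#'   the simulated data (rows across trios combined).
#' @param n_valid Total number of valid (retained) markers across trios,
#'   the denominator of the false-deviation rate.
#' @return A list: `sensitivity` (detected share of detectable injected
#'   mutations), `false_md_rate` (detected deviations matching no
#'   injected event, per valid marker), `origin_accuracy` (share of
#'   detected true mutations with Mendelian-resolved origin whose origin
#'   matches the truth), and the underlying counts.
#' @details If both inputs carry a `run_id` attribute they must match.
#' @export
evaluate_detection <- function(truth, detected, n_valid) {
  rt <- attr(truth, "run_id"); rd <- attr(detected, "run_id")
  if (!is.null(rt) && !is.null(rd) && !identical(rt, rd)) {
    stop("truth log and detections come from different runs", call. = FALSE)
  }
  key <- function(d) paste(d$family_id, d$probe_id)
  dn <- truth[truth$event == "de_novo", , drop = FALSE]
  dn_detectable <- dn[dn$detectable, , drop = FALSE]
  det_keys <- key(detected)
  hit <- key(dn_detectable) %in% det_keys
  sensitivity <- if (nrow(dn_detectable) > 0L) mean(hit) else NA_real_
  false_keys <- setdiff(det_keys, key(truth))
  false_md_rate <- length(false_keys) / n_valid
  md_true <- detected[det_keys %in% key(dn) &
                        detected$origin_method == "mendelian", , drop = FALSE]
  origin_accuracy <- if (nrow(md_true) > 0L) {
    truth_parent <- dn$member[match(key(md_true), key(dn))]
    mean(md_true$origin == truth_parent)
  } else NA_real_
  list(sensitivity = sensitivity,
       false_md_rate = false_md_rate,
       origin_accuracy = origin_accuracy,
       n_injected_detectable = nrow(dn_detectable),
       n_detected = nrow(detected),
       n_false = length(false_keys))
}
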