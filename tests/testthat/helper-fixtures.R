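# Builders for small in-memory fixtures in the package's genotype dialect.

make_markers <- function(n, chrom = "1", start_pos = 1000, spacing = 100,
                         allele_a = "A", allele_b = "G") {
  data.frame(
    probe_id = sprintf("P%03d", seq_len(n)),
    dbsnp = sprintf("rs%d", seq_len(n)),
    chrom = rep_len(chrom, n),
    pos = start_pos + (seq_len(n) - 1) * spacing,
    allele_a = rep_len(allele_a, n),
    allele_b = rep_len(allele_b, n),
    stringsAsFactors = FALSE
  )
}

make_member <- function(markers, genotype, confidence = 0.01) {
  df <- data.frame(
    markers,
    genotype = rep_len(genotype, nrow(markers)),
    confidence = rep_len(confidence, nrow(markers)),
    signal_a = 1, signal_b = 1,
    stringsAsFactors = FALSE
  )
  df$base_call <- mendeviate:::base_call(df$genotype, df$allele_a, df$allele_b)
  df
}

# a trio with explicit per-marker genotypes
make_trio_tables <- function(markers, father_gt, mother_gt, child_gt,
                             father_conf = 0.01, mother_conf = 0.01,
                             child_conf = 0.01) {
  list(father = make_member(markers, father_gt, father_conf),
       mother = make_member(markers, mother_gt, mother_conf),
       child = make_member(markers, child_gt, child_conf))
}

write_bed <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tsv_text <- function(text) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}
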