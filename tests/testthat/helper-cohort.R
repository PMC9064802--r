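# Builders for tiny in-code cohorts used across test files.

# Write a one-trio (or n-trio) PED file; probands affected by default.
write_test_ped <- function(path, n = 1, affected = rep(2, n)) {
  lines <- unlist(lapply(seq_len(n), function(i) {
    fam <- sprintf("FAM%d", i)
    c(paste(fam, sprintf("D%d", i), "0 0 1 1"),
      paste(fam, sprintf("M%d", i), "0 0 2 1"),
      paste(fam, sprintf("C%d", i), sprintf("D%d", i), sprintf("M%d", i), "1",
            affected[i]))
  }))
  writeLines(lines, path)
  path
}

# Write a VCF from a list of records. Each record:
# list(chrom, pos, ref, alt, geno = named list sample -> "GT:DP:AD:GQ" string)
write_test_vcf <- function(path, samples, records) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r) {
    fields <- vapply(samples, function(s) r$geno[[s]], character(1))
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".",
            "GT:DP:AD:GQ", fields), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

gt_field <- function(gt, dp, alt, gq) {
  paste(gt, dp, paste(dp - alt, alt, sep = ","), gq, sep = ":")
}

write_test_annotations <- function(path, df) {
  defaults <- data.frame(gene = "GENE1", variant_type = "missense",
                         splice_distance_bp = 0, af_1kg = 0, af_evs = 0,
                         cadd_phred = 25, polyphen_humdiv = NA_real_,
                         polyphen_humvar = NA_real_, curated_class = "none",
                         stringsAsFactors = FALSE)
  for (cc in names(defaults))
    if (is.null(df[[cc]])) df[[cc]] <- rep(defaults[[cc]], nrow(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# One-trio cohort with a single biallelic site and explicit trio evidence.
# Evidence vectors are c(dp, alt, gq); gt strings like "0/1".
one_site_cohort <- function(child, mother, father,
                            child_ev = c(40, 18, 99), mother_ev = c(50, 0, 99),
                            father_ev = c(50, 0, 99), chrom = "1", pos = 1000,
                            annotation = list()) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  ped <- write_test_ped(file.path(dir, "t.ped"))
  vcf <- write_test_vcf(file.path(dir, "t.vcf"), c("C1", "D1", "M1"), list(
    list(chrom = chrom, pos = pos, ref = "G", alt = "A", geno = list(
      C1 = gt_field(child, child_ev[1], child_ev[2], child_ev[3]),
      D1 = gt_field(father, father_ev[1], father_ev[2], father_ev[3]),
      M1 = gt_field(mother, mother_ev[1], mother_ev[2], mother_ev[3])))))
  ann_df <- data.frame(chrom = chrom, pos = pos, ref = "G", alt = "A",
                       stringsAsFactors = FALSE)
  for (nm in names(annotation)) ann_df[[nm]] <- annotation[[nm]]
  ann <- write_test_annotations(file.path(dir, "t.tsv"), ann_df)
  read_trio_vcf(vcf, read_pedigree(ped), read_annotations(ann))
}

# Annotation-only variant rows for site_filter tests.
site_variant <- function(variant_type = "missense", splice = 0, af1 = 0,
                         af2 = 0, cadd = 25, key = "1:1:G:A") {
  data.frame(variant_key = key, chrom = "1", pos = 1, ref = "G", alt = "A",
             gene = "GENE1", variant_type = variant_type,
             splice_distance_bp = splice, af_1kg = af1, af_evs = af2,
             cadd_phred = cadd, polyphen_humdiv = NA_real_,
             polyphen_humvar = NA_real_, curated_class = "none",
             annotated = TRUE, stringsAsFactors = FALSE)
}
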