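test_that("read_pedigree assembles trios and maps phenotypes", {
  dir <- withr::local_tempdir()
  ped <- read_pedigree(write_test_ped(file.path(dir, "one.ped")))
  expect_s3_class(ped, "trio_pedigree")
  expect_equal(nrow(ped), 1)
  expect_equal(ped$proband_id, "C1")
  expect_equal(ped$proband_affected, "epilepsy")
  expect_equal(ped$mother_pheno, "unaffected")

  big <- read_pedigree(write_test_ped(file.path(dir, "twenty.ped"), n = 20,
                                      affected = rep(c(2, 1), each = 10)))
  expect_equal(nrow(big), 20)
  expect_equal(sum(big$proband_affected == "epilepsy"), 10)
})

test_that("read_pedigree rejects incomplete and malformed families", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "bad1.ped")
  writeLines(c("F1 mom 0 0 2 1", "F1 kid 0 mom 1 2"), p1)
  expect_error(read_pedigree(p1), "incomplete trio")

  p2 <- file.path(dir, "bad2.ped")
  writeLines(c("F1 dad 0 0 1 1", "F1 mom 0 0 2 1", "F1 kid dad mom 1 2",
               "F2 dad 0 0 1 1"), p2)
  expect_error(read_pedigree(p2), "duplicate individual ID")

  p3 <- file.path(dir, "bad3.ped")
  writeLines(c("F1 mom 0 0 2 1", "F1 kid ghost mom 1 2"), p3)
  expect_error(read_pedigree(p3), "incomplete trio")
})

test_that("load_panel normalizes, deduplicates and rejects empty files", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "panel.txt")
  writeLines(c("# comment", sprintf("g%03d", 1:200)), p)
  panel <- load_panel(p, "epilepsy")
  expect_equal(length(panel$genes), 200)
  expect_true(all(panel$genes == toupper(panel$genes)))

  writeLines(c("KCNT1", "kcnt1", "SCN1A"), p)
  expect_warning(panel <- load_panel(p, "dup"), "duplicated")
  expect_equal(sort(panel$genes), c("KCNT1", "SCN1A"))

  writeLines("# only a comment", p)
  expect_error(load_panel(p, "empty"), "empty")
})

test_that("assert_non_overlap reports intersections", {
  dir <- withr::local_tempdir()
  pa <- file.path(dir, "a.txt"); writeLines(c("KCNT1", "SCN1A"), pa)
  pb <- file.path(dir, "b.txt"); writeLines(c("LDLR", "APOB"), pb)
  pc <- file.path(dir, "c.txt"); writeLines(c("KCNT1", "LDLR"), pc)
  a <- load_panel(pa, "a"); b <- load_panel(pb, "b"); cc <- load_panel(pc, "c")
  expect_true(assert_non_overlap(a, b))
  expect_warning(res <- assert_non_overlap(a, cc), "KCNT1")
  expect_false(as.logical(res))
  expect_equal(attr(res, "overlap"), "KCNT1")
  expect_warning(res2 <- assert_non_overlap(a, a))
  expect_false(as.logical(res2))
})

test_that("read_trio_vcf reads biallelic sites with full evidence", {
  co <- one_site_cohort("0/1", mother = "0/0", father = "0/0",
                        child_ev = c(40, 18, 99))
  expect_equal(nrow(co$variants), 1)
  expect_equal(nrow(co$genotypes), 3)
  g <- co$genotypes[co$genotypes$sample_id == "C1", ]
  expect_equal(g$gt, "het")
  expect_equal(g$dp, 40)
  expect_equal(g$alt_dp, 18)
  expect_equal(g$ab, 0.45)
})

test_that("multi-allelic records split one row per alternate allele", {
  dir <- withr::local_tempdir()
  ped <- read_pedigree(write_test_ped(file.path(dir, "m.ped")))
  vcf <- file.path(dir, "m.vcf")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
              "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "C1", "D1", "M1"), collapse = "\t"))
  writeLines(c(header, paste(c("1", "500", ".", "G", "A,T", ".", "PASS", ".",
                               "GT:DP:AD:GQ", "1/2:30:2,12,16:99",
                               "0/1:40:20,20,0:99", "0/2:44:22,0,22:99"),
                             collapse = "\t")), vcf)
  co <- read_trio_vcf(vcf, ped)
  expect_equal(nrow(co$variants), 2)
  expect_equal(unique(co$variants$chrom), "1")
  expect_equal(unique(co$variants$pos), 500)
  expect_setequal(co$variants$alt, c("A", "T"))
  # AD decomposed per allele; child is het for both alternates
  gA <- co$genotypes[co$genotypes$variant_key == "1:500:G:A", ]
  expect_equal(gA$alt_dp[gA$sample_id == "C1"], 12)
  expect_equal(gA$gt[gA$sample_id == "C1"], "het")
  expect_equal(gA$gt[gA$sample_id == "M1"], "hom_ref")
  gT <- co$genotypes[co$genotypes$variant_key == "1:500:G:T", ]
  expect_equal(gT$alt_dp[gT$sample_id == "M1"], 22)
  expect_equal(gT$gt[gT$sample_id == "M1"], "het")
  expect_true(all(co$genotypes$alt_dp <= co$genotypes$dp))
})

test_that("missing pedigree samples and malformed genotypes are handled", {
  dir <- withr::local_tempdir()
  ped <- read_pedigree(write_test_ped(file.path(dir, "x.ped")))
  vcf <- write_test_vcf(file.path(dir, "x.vcf"), c("C1", "D1"), list(
    list(chrom = "1", pos = 100, ref = "G", alt = "A",
         geno = list(C1 = "0/1:30:15,15:99", D1 = "0/0:30:30,0:99"))))
  expect_error(read_trio_vcf(vcf, ped), "absent from VCF header")

  vcf2 <- write_test_vcf(file.path(dir, "y.vcf"), c("C1", "D1", "M1"), list(
    list(chrom = "1", pos = 100, ref = "G", alt = "A",
         geno = list(C1 = "0/1:30:15,15:99", D1 = "0/0:30:30,0:99",
                     M1 = "./.:.:.:."))))
  co <- read_trio_vcf(vcf2, ped)
  expect_equal(nrow(co$variants), 1)  # flagged, not dropped
  expect_equal(co$genotypes$gt[co$genotypes$sample_id == "M1"], "missing")
})

test_that("allele normalization left-aligns padded indels", {
  expect_equal(normalize_allele(100, "G", "A"), list(pos = 100, ref = "G", alt = "A"))
  expect_equal(normalize_allele(100, "GGTC", "GTC"), list(pos = 100, ref = "GG", alt = "G"))
  # suffix is trimmed before prefix, so the deletion stays left-aligned
  n <- normalize_allele(100, "TGGA", "TGA")
  expect_equal(n$pos, 100)
  expect_equal(c(n$ref, n$alt), c("TG", "T"))
  n2 <- normalize_allele(100, "CCGTA", "CCA")
  expect_equal(n2$pos, 101)
  expect_equal(c(n2$ref, n2$alt), c("CGT", "C"))
})

test_that("cohorts round-trip through VCF + annotation TSV", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(simulation_config(seed = 11, n_case_trios = 2,
                                           n_control_trios = 2,
                                           n_background_variants_per_trio = 6),
                         file.path(dir, "sim"))
  ped <- read_pedigree(sim$paths$ped)
  co <- read_trio_vcf(sim$paths$vcf, ped, read_annotations(sim$paths$annotations))
  write_cohort(co, file.path(dir, "rt.vcf"), file.path(dir, "rt.tsv"))
  co2 <- read_trio_vcf(file.path(dir, "rt.vcf"), ped,
                       read_annotations(file.path(dir, "rt.tsv")))
  ord <- function(x) {
    v <- x$variants[order(x$variants$variant_key), ]
    rownames(v) <- NULL
    g <- x$genotypes[order(x$genotypes$variant_key, x$genotypes$sample_id), ]
    rownames(g) <- NULL
    list(v = v, g = g)
  }
  expect_equal(ord(co2), ord(co))
})

test_that("multi-allelic split conserves the total alternate-allele count", {
  dir <- withr::local_tempdir()
  ped <- read_pedigree(write_test_ped(file.path(dir, "c.ped")))
  alts <- c("A", "A,T", "A,T,C")
  records <- lapply(seq_along(alts), function(i) {
    nal <- i + 1
    ad <- paste(c(30, rep(5, i)), collapse = ",")
    list(chrom = "1", pos = 100 * i, ref = "G", alt = alts[i],
         geno = list(C1 = paste0("0/1:35:", ad, ":99"),
                     D1 = paste0("0/0:35:", ad, ":99"),
                     M1 = paste0("0/0:35:", ad, ":99")))
  })
  vcf <- write_test_vcf(file.path(dir, "c.vcf"), c("C1", "D1", "M1"), records)
  co <- read_trio_vcf(vcf, ped)
  expect_equal(nrow(co$variants),
               sum(lengths(strsplit(alts, ",", fixed = TRUE))))
})
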