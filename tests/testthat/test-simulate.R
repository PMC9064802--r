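test_that("a fixed seed reproduces every output byte for byte", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 7, n_case_trios = 3, n_control_trios = 3,
                           n_background_variants_per_trio = 8)
  s1 <- simulate_cohort(cfg, file.path(dir, "a"))
  s2 <- simulate_cohort(cfg, file.path(dir, "b"))
  for (f in names(s1$paths)) {
    expect_identical(readLines(s1$paths[[f]]), readLines(s2$paths[[f]]),
                     info = f)
  }
  s3 <- simulate_cohort(simulation_config(seed = 8, n_case_trios = 3,
                                          n_control_trios = 3,
                                          n_background_variants_per_trio = 8),
                        file.path(dir, "c"))
  expect_false(identical(readLines(s1$paths$vcf), readLines(s3$paths$vcf)))
})

test_that("every VCF record has exactly one truth row", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(simulation_config(seed = 2, n_case_trios = 3,
                                           n_control_trios = 3),
                         file.path(dir, "s"))
  vcf_keys <- vapply(strsplit(grep("^[^#]", readLines(sim$paths$vcf),
                                   value = TRUE), "\t"),
                     function(f) paste(f[1], f[2], f[4], f[5], sep = ":"),
                     character(1))
  expect_setequal(vcf_keys, sim$truth$variant_key)
  expect_equal(anyDuplicated(sim$truth$variant_key), 0)
  expect_equal(length(vcf_keys), nrow(sim$truth))
})

test_that("planted genotypes are Mendelian-consistent except de novo sites", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(simulation_config(seed = 12, n_case_trios = 4,
                                           n_control_trios = 4),
                         file.path(dir, "s"))
  lines <- readLines(sim$paths$vcf)
  hdr <- strsplit(grep("^#CHROM", lines, value = TRUE), "\t")[[1]]
  ped <- read_pedigree(sim$paths$ped)
  for (ln in grep("^[^#]", lines, value = TRUE)) {
    f <- strsplit(ln, "\t")[[1]]
    names(f) <- hdr
    key <- paste(f[1], f[2], f[4], f[5], sep = ":")
    cls <- sim$truth$planted_class[sim$truth$variant_key == key]
    if (cls %in% c("de_novo", "artifact")) next
    for (i in seq_len(nrow(ped))) {
      alleles <- function(s) strsplit(strsplit(f[[s]], ":")[[1]][1], "/")[[1]]
      kid <- alleles(ped$proband_id[i])
      mom <- alleles(ped$mother_id[i])
      dad <- alleles(ped$father_id[i])
      # each child allele must be available from some parent
      expect_true(kid[1] %in% c(mom, dad) && kid[2] %in% c(mom, dad),
                  info = paste(key, ped$family_id[i]))
    }
  }
})

test_that("simulated depths concentrate around the configured mean", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(simulation_config(seed = 77, n_case_trios = 1,
                                           n_control_trios = 1,
                                           n_background_variants_per_trio = 5000,
                                           denovo_rate_per_trio = 0,
                                           nontransmitted_rate = 0,
                                           artifact_rate_per_trio = 0,
                                           p_panel_pathogenic_case = 0,
                                           p_panel_pathogenic_control = 0,
                                           depth_mean = 60),
                         file.path(dir, "s"))
  lines <- grep("^[^#]", readLines(sim$paths$vcf), value = TRUE)
  hdr <- strsplit(grep("^#CHROM", readLines(sim$paths$vcf), value = TRUE),
                  "\t")[[1]]
  ped <- read_pedigree(sim$paths$ped)
  # depth of the planted carrier parent's genotype at each site
  dp <- vapply(lines, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    names(f) <- hdr
    key <- paste(f[1], f[2], f[4], f[5], sep = ":")
    fam <- sim$truth$family_id[sim$truth$variant_key == key]
    as.numeric(strsplit(f[[ped$proband_id[ped$family_id == fam]]], ":")[[1]][2])
  }, numeric(1))
  expect_equal(length(dp), 10000)
  expect_lt(abs(mean(dp) - 60) / 60, 0.05)
})

test_that("the exposure model yields the expected odds ratio at scale", {
  set.seed(555)
  t <- simulate_exposure_table(20000, 20000, 0.5, 0.1)
  expect_equal(odds_ratio(t), 9, tolerance = 0.1)
})

test_that("allelic balance planted between the mode thresholds flips calls", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(simulation_config(seed = 41, n_case_trios = 3,
                                           n_control_trios = 3,
                                           n_background_variants_per_trio = 0,
                                           nontransmitted_rate = 0,
                                           artifact_rate_per_trio = 0,
                                           p_panel_pathogenic_case = 0,
                                           p_panel_pathogenic_control = 0,
                                           denovo_rate_per_trio = 3,
                                           ab_denovo_range = c(0.1, 0.25),
                                           gq_pass_prob = 1),
                         file.path(dir, "s"))
  co <- read_trio_vcf(sim$paths$vcf, read_pedigree(sim$paths$ped),
                      read_annotations(sim$paths$annotations))
  n_dn <- sum(sim$truth$planted_class == "de_novo")
  expect_gt(n_dn, 0)
  exome <- classify_inheritance(co, "exome_wide")
  targeted <- classify_inheritance(co, "targeted_panel")
  rec_e <- score_recovery(sim$truth, exome, mode = "exome_wide")
  rec_t <- score_recovery(sim$truth, targeted, mode = "targeted_panel")
  # no planted site clears the exome-wide threshold, every one clears targeted
  expect_equal(rec_e$n_expected[rec_e$class == "de_novo"], 0)
  expect_equal(sum(exome$call == "de_novo"), 0)
  expect_equal(rec_t$n_expected[rec_t$class == "de_novo"], n_dn)
  expect_equal(rec_t$recall[rec_t$class == "de_novo"], 1)
  expect_true(all(exome$call[exome$variant_key %in% sim$truth$variant_key] ==
                    "unresolved"))
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(p_panel_pathogenic_case = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(n_case_trios = 0), "at least one")
  expect_error(simulation_config(ab_denovo_range = c(0.5, 0.2)), "increasing")
})
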