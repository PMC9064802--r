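dn_check <- function(co, mode = "exome_wide") {
  check_de_novo(co, co$variants$variant_key[1], co$pedigree[1, ],
                mode = mode_profile(mode))
}

test_that("de novo evidence thresholds are enforced with reason codes", {
  co <- one_site_cohort("0/1", "0/0", "0/0", child_ev = c(40, 18, 99))
  expect_true(dn_check(co)$ok)

  # allelic balance 0.2: fails exome-wide (>0.25), passes targeted (>0.1)
  co <- one_site_cohort("0/1", "0/0", "0/0", child_ev = c(40, 8, 99))
  r <- dn_check(co)
  expect_false(r$ok)
  expect_equal(r$reasons, "AB_LOW")
  expect_true(dn_check(co, "targeted_panel")$ok)

  # a single paternal alternate read vetoes the call
  co <- one_site_cohort("0/1", "0/0", "0/0", father_ev = c(50, 1, 60))
  r <- dn_check(co)
  expect_false(r$ok)
  expect_equal(r$reasons, "PARENT_HAS_ALT")

  co <- one_site_cohort("0/1", "0/0", "0/0", child_ev = c(9, 4, 99))
  expect_true("DP_LOW" %in% dn_check(co)$reasons)
  co <- one_site_cohort("0/1", "0/0", "0/0", child_ev = c(40, 2, 99))
  expect_true(all(c("ALT_READS_LOW", "AB_LOW") %in% dn_check(co)$reasons))
  co <- one_site_cohort("0/1", "0/0", "0/0", mother_ev = c(50, 0, 49))
  expect_equal(dn_check(co)$reasons, "PARENT_GQ_LOW")
  # parental GQ exactly 50 is acceptable ("a minimum of 50")
  co <- one_site_cohort("0/1", "0/0", "0/0", mother_ev = c(50, 0, 50))
  expect_true(dn_check(co)$ok)
  co <- one_site_cohort("0/1", "./.", "0/0")
  expect_equal(dn_check(co)$reasons, "PARENT_MISSING")
})

test_that("classification distinguishes transmission, de novo and unresolved", {
  call1 <- function(co) classify_inheritance(co)$call
  # X-linked hemizygous son of a heterozygous mother: maternal transmission
  co <- one_site_cohort("1", "0/1", "0", chrom = "X",
                        child_ev = c(55, 54, 99), mother_ev = c(50, 25, 99))
  expect_equal(call1(co), "transmitted_maternal")
  co <- one_site_cohort("0/1", "0/0", "0/0")
  expect_equal(call1(co), "de_novo")
  co <- one_site_cohort("0/1", "0/1", "0/1",
                        mother_ev = c(50, 25, 99), father_ev = c(50, 25, 99))
  expect_equal(call1(co), "transmitted_biparental")
  co <- one_site_cohort("0/1", "0/0", "0/1", father_ev = c(50, 25, 99))
  expect_equal(call1(co), "transmitted_paternal")
  # hom-ref parents but weak evidence: unresolved, never silently dropped
  co <- one_site_cohort("0/1", "0/0", "0/0", child_ev = c(8, 3, 99))
  calls <- classify_inheritance(co)
  expect_equal(calls$call, "unresolved")
  expect_true(grepl("DP_LOW", calls$fail_reasons))
  # mitochondrial and Y sites are not classifiable with biparental logic
  co <- one_site_cohort("0/1", "0/0", "0/0", chrom = "MT")
  expect_equal(call1(co), "unresolved")
  co <- one_site_cohort("1", "0/0", "0", chrom = "Y", child_ev = c(30, 29, 99))
  expect_equal(call1(co), "unresolved")
  # non-carrier probands yield no call at all
  co <- one_site_cohort("0/0", "0/1", "0/0", mother_ev = c(50, 25, 99))
  expect_equal(nrow(classify_inheritance(co)), 0)
})

test_that("non-transmitted parental variants are detected and labeled", {
  co <- one_site_cohort("0/0", "0/1", "0/0", mother_ev = c(50, 25, 99),
                        annotation = list(curated_class = "pathogenic"))
  nt <- find_non_transmitted(co)
  expect_equal(nt$call, "non_transmitted_maternal")
  # transmitted variants are excluded from the non-transmitted list
  co <- one_site_cohort("0/1", "0/1", "0/0", mother_ev = c(50, 25, 99))
  expect_equal(nrow(find_non_transmitted(co)), 0)
  # parental GQ at the boundary (strictly > 50 required)
  co <- one_site_cohort("0/0", "0/1", "0/0", mother_ev = c(50, 25, 50))
  expect_equal(nrow(find_non_transmitted(co)), 0)
})

test_that("planted non-transmitted variants are recovered exactly", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(simulation_config(seed = 19, n_case_trios = 4,
                                           n_control_trios = 4,
                                           n_background_variants_per_trio = 0,
                                           denovo_rate_per_trio = 0,
                                           artifact_rate_per_trio = 0,
                                           nontransmitted_rate = 2,
                                           p_panel_pathogenic_case = 0,
                                           p_panel_pathogenic_control = 0,
                                           gq_pass_prob = 1),
                         file.path(dir, "sim"))
  co <- read_trio_vcf(sim$paths$vcf, read_pedigree(sim$paths$ped),
                      read_annotations(sim$paths$annotations))
  nt <- find_non_transmitted(co)
  planted <- sim$truth[grepl("^non_transmitted", sim$truth$planted_class) &
                         sim$truth$should_pass_site, ]
  expect_equal(nrow(nt), nrow(planted))
  expect_setequal(paste(nt$variant_key, nt$family_id, nt$call),
                  paste(planted$variant_key, planted$family_id,
                        planted$planted_class))
})

test_that("each carrier (variant, trio) gets exactly one call, disjoint from non-transmitted", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(simulation_config(seed = 23, n_case_trios = 3,
                                           n_control_trios = 3),
                         file.path(dir, "sim"))
  co <- read_trio_vcf(sim$paths$vcf, read_pedigree(sim$paths$ped),
                      read_annotations(sim$paths$annotations))
  calls <- classify_inheritance(co)
  expect_equal(anyDuplicated(paste(calls$variant_key, calls$family_id)), 0)
  expect_true(all(calls$call %in% c("de_novo", "transmitted_maternal",
                                    "transmitted_paternal",
                                    "transmitted_biparental", "unresolved")))
  # de novo calls carry no failure reasons
  expect_true(all(calls$fail_reasons[calls$call == "de_novo"] == ""))
  nt <- find_non_transmitted(co)
  expect_equal(length(intersect(paste(calls$variant_key, calls$family_id),
                                paste(nt$variant_key, nt$family_id))), 0)
})

test_that("exome-wide de novo calls are a subset of targeted-panel calls", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(simulation_config(seed = 31, n_case_trios = 3,
                                           n_control_trios = 3,
                                           denovo_rate_per_trio = 3,
                                           ab_denovo_range = c(0.05, 0.6),
                                           gq_pass_prob = 1),
                         file.path(dir, "sim"))
  co <- read_trio_vcf(sim$paths$vcf, read_pedigree(sim$paths$ped),
                      read_annotations(sim$paths$annotations))
  dn_keys <- function(mode) {
    calls <- classify_inheritance(co, mode)
    paste(calls$variant_key, calls$family_id)[calls$call == "de_novo"]
  }
  exome <- dn_keys("exome_wide")
  targeted <- dn_keys("targeted_panel")
  expect_true(all(exome %in% targeted))
  expect_gt(length(targeted), length(exome))
})

test_that("classification agrees with a text-level brute-force oracle", {
  set.seed(42)
  for (i in 1:40) {
    dir <- withr::local_tempdir()
    files <- random_trio_cohort_files(dir)
    co <- read_trio_vcf(files$vcf, read_pedigree(files$ped),
                        read_annotations(files$ann))
    for (ab in c(0.25, 0.1)) {
      mode <- if (ab == 0.25) "exome_wide" else "targeted_panel"
      got <- classify_inheritance(co, mode)
      want <- oracle_classify_vcf(files$vcf, ab)
      got <- got[order(got$variant_key), ]
      want <- want[order(want$variant_key), ]
      expect_equal(got$variant_key, want$variant_key)
      expect_equal(got$call, want$call)
    }
  }
})
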