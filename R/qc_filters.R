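#' Variant-level filter thresholds
#'
#' Bundles the quantitative inclusion criteria applied to every variant:
#' population frequency below 0.1% in both reference panels (the maximum of
#' the two frequencies is compared), CADD Phred strictly above 20, proband
#' genotype quality strictly above 50, de novo read evidence (depth >= 10,
#' >= 3 alternate reads, allelic balance strictly above a mode-dependent
#' threshold: 0.25 exome-wide, relaxed to 0.1 within targeted panels), and
#' parental evidence for de novo calls (GQ >= 50, zero alternate reads).
#'
#' @param max_pop_freq Maximum population allele frequency (exclusive).
#' @param min_cadd CADD Phred cutoff (strict `>`).
#' @param min_gq_proband Proband genotype-quality cutoff (strict `>`).
#' @param min_depth_denovo Minimum total depth for de novo evidence (`>=`).
#' @param min_alt_reads_denovo Minimum alternate reads for de novo (`>=`).
#' @param min_ab_exome Allelic-balance cutoff, exome-wide mode (strict `>`).
#' @param min_ab_targeted Allelic-balance cutoff, targeted-panel mode
#'   (strict `>`).
#' @param min_gq_parent Parental genotype-quality cutoff for de novo (`>=`).
#' @param max_parent_alt_reads Maximum parental alternate reads for de novo.
#' @param splice_window_bp Window around splice sites (bp) within which any
#'   consequence class is retained.
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(max_pop_freq = 0.001, min_cadd = 20,
                              min_gq_proband = 50, min_depth_denovo = 10,
                              min_alt_reads_denovo = 3, min_ab_exome = 0.25,
                              min_ab_targeted = 0.1, min_gq_parent = 50,
                              max_parent_alt_reads = 0, splice_window_bp = 3) {
  t <- list(max_pop_freq = max_pop_freq, min_cadd = min_cadd,
            min_gq_proband = min_gq_proband,
            min_depth_denovo = min_depth_denovo,
            min_alt_reads_denovo = min_alt_reads_denovo,
            min_ab_exome = min_ab_exome, min_ab_targeted = min_ab_targeted,
            min_gq_parent = min_gq_parent,
            max_parent_alt_reads = max_parent_alt_reads,
            splice_window_bp = splice_window_bp)
  if (any(vapply(t, function(x) !is.numeric(x) || length(x) != 1 || x < 0,
                 logical(1))))
    stop("all thresholds must be non-negative scalars")
  if (t$min_ab_targeted > t$min_ab_exome)
    stop("min_ab_targeted must not exceed min_ab_exome")
  class(t) <- "filter_thresholds"
  t
}

#' Read filter thresholds from a YAML config file
#'
#' Keys matching [filter_thresholds()] arguments override the defaults;
#' unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `filter_thresholds` object.
#' @export
read_thresholds_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(filter_thresholds))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown threshold key(s) in config: ", paste(bad, collapse = ", "))
  do.call(filter_thresholds, cfg)
}

# consequence classes counted as coding functional variants in their own right
FUNCTIONAL_TYPES <- c("missense", "nonsense", "frameshift")

#' Site-level annotation filter
#'
#' A variant passes when it is a functional coding change (missense, nonsense
#' or frameshift) or lies within `splice_window_bp` of a splice site, its
#' maximum allele frequency over the two reference panels is below
#' `max_pop_freq`, and its CADD Phred score exceeds `min_cadd`. Variants with
#' missing annotation fields fail with reason `ANNOTATION_MISSING` rather
#' than passing silently.
#'
#' @param variants The `variants` data frame of a `trio_cohort` (or any data
#'   frame with the annotation columns).
#' @param thresholds A `filter_thresholds` object.
#' @return Data frame: `variant_key`, `passed`, `reasons` (`;`-separated
#'   codes, empty when passed).
#' @export
site_filter <- function(variants, thresholds = filter_thresholds()) {
  v <- variants
  n <- nrow(v)
  reasons <- vector("list", n)
  need_ann <- is.na(v$variant_type) |
    (is.na(v$splice_distance_bp) & !(v$variant_type %in% FUNCTIONAL_TYPES)) |
    (is.na(v$af_1kg) & is.na(v$af_evs)) | is.na(v$cadd_phred)
  af_max <- pmax(ifelse(is.na(v$af_1kg), 0, v$af_1kg),
                 ifelse(is.na(v$af_evs), 0, v$af_evs))
  functional <- v$variant_type %in% FUNCTIONAL_TYPES |
    (!is.na(v$splice_distance_bp) &
       v$splice_distance_bp <= thresholds$splice_window_bp)
  for (i in seq_len(n)) {
    r <- character(0)
    if (need_ann[i]) {
      r <- "ANNOTATION_MISSING"
    } else {
      if (!functional[i]) r <- c(r, "NOT_FUNCTIONAL_REGION")
      if (af_max[i] >= thresholds$max_pop_freq) r <- c(r, "POP_FREQ_HIGH")
      if (v$cadd_phred[i] <= thresholds$min_cadd) r <- c(r, "CADD_LOW")
    }
    reasons[[i]] <- r
  }
  data.frame(variant_key = v$variant_key,
             passed = lengths(reasons) == 0,
             reasons = vapply(reasons, paste, character(1), collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Proband genotype-quality filter
#'
#' For one trio, a variant passes when the proband carries the alternate
#' allele (het, hom_alt or hemi_alt) with genotype quality strictly above
#' `min_gq_proband`.
#'
#' @param cohort A `trio_cohort`.
#' @param trio One row of the cohort's `trio_pedigree`.
#' @param thresholds A `filter_thresholds` object.
#' @return Data frame: `variant_key`, `family_id`, `passed`, `reasons`.
#' @export
proband_quality_filter <- function(cohort, trio,
                                   thresholds = filter_thresholds()) {
  g <- cohort$genotypes[cohort$genotypes$sample_id == trio$proband_id, ]
  g <- g[match(cohort$variants$variant_key, g$variant_key), ]
  reasons <- character(nrow(g))
  missing <- is.na(g$gt) | g$gt == "missing"
  carrier <- !missing & g$gt %in% CARRIER_GENOTYPES
  gq_ok <- !is.na(g$gq) & g$gq > thresholds$min_gq_proband
  reasons[missing] <- "GENOTYPE_MISSING"
  reasons[!missing & !carrier] <- "NOT_CARRIER"
  reasons[carrier & !gq_ok] <- "PROBAND_GQ_LOW"
  data.frame(variant_key = cohort$variants$variant_key,
             family_id = rep(trio$family_id, nrow(cohort$variants)),
             passed = carrier & gq_ok,
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Apply all variant-level filters across a cohort
#'
#' Runs [site_filter()] once per variant and [proband_quality_filter()] per
#' trio; a variant survives when it passes the site filter and the proband
#' filter in at least one trio. Every evaluated (variant, trio, stage) gets a
#' row in the decision log, so `survivors + failures = input` always holds.
#'
#' @param cohort A `trio_cohort`.
#' @param thresholds A `filter_thresholds` object.
#' @return List with `survivors` (subset of the cohort's `variants` rows) and
#'   `log` (data frame: `variant_key`, `family_id`, `stage`, `passed`,
#'   `reasons`).
#' @export
apply_filters <- function(cohort, thresholds = filter_thresholds()) {
  stopifnot(inherits(cohort, "trio_cohort"))
  site <- site_filter(cohort$variants, thresholds)
  n <- nrow(site)
  site_log <- data.frame(variant_key = site$variant_key,
                         family_id = rep(NA_character_, n),
                         stage = rep("site", n), passed = site$passed,
                         reasons = site$reasons, stringsAsFactors = FALSE)
  trio_logs <- lapply(seq_len(nrow(cohort$pedigree)), function(i) {
    pf <- proband_quality_filter(cohort, cohort$pedigree[i, ], thresholds)
    data.frame(variant_key = pf$variant_key, family_id = pf$family_id,
               stage = rep("proband", nrow(pf)), passed = pf$passed,
               reasons = pf$reasons, stringsAsFactors = FALSE)
  })
  log <- rbind(site_log, do.call(rbind, trio_logs))
  proband_pass <- unique(log$variant_key[log$stage == "proband" & log$passed])
  keep <- site$passed & site$variant_key %in% proband_pass
  list(survivors = cohort$variants[keep, , drop = FALSE], log = log)
}

#' Write a filter decision log to TSV
#' @param log Decision log from [apply_filters()].
#' @param path Output path.
#' @export
write_decision_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
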