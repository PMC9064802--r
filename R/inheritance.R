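#' Analysis-mode profile for allelic-balance thresholds
#'
#' The de novo allelic-balance requirement is mode-dependent: strictly above
#' 0.25 in exome-wide analyses, relaxed to strictly above 0.1 within targeted
#' gene panels.
#'
#' @param mode `"exome_wide"` or `"targeted_panel"`.
#' @param thresholds A `filter_thresholds` object supplying the two cutoffs.
#' @return List of class `mode_profile` with `mode` and `ab_threshold`.
#' @export
mode_profile <- function(mode = c("exome_wide", "targeted_panel"),
                         thresholds = filter_thresholds()) {
  mode <- match.arg(mode)
  structure(list(mode = mode,
                 ab_threshold = if (mode == "exome_wide")
                   thresholds$min_ab_exome else thresholds$min_ab_targeted),
            class = "mode_profile")
}

trio_genotypes <- function(cohort, key, trio) {
  g <- cohort$genotypes[cohort$genotypes$variant_key == key, ]
  one <- function(id) {
    row <- g[g$sample_id == id, ]
    if (nrow(row) != 1) {
      return(list(gt = "missing", dp = NA_real_, alt_dp = NA_real_,
                  gq = NA_real_, ab = NA_real_))
    }
    as.list(row[1, c("gt", "dp", "alt_dp", "gq", "ab")])
  }
  list(proband = one(trio$proband_id), mother = one(trio$mother_id),
       father = one(trio$father_id))
}

#' De novo evidence check for one variant in one trio
#'
#' Requires proband depth >= `min_depth_denovo`, alternate reads >=
#' `min_alt_reads_denovo`, allelic balance strictly above the mode threshold,
#' and both parents homozygous reference with genotype quality >=
#' `min_gq_parent` and no more than `max_parent_alt_reads` alternate reads.
#'
#' @param cohort A `trio_cohort`.
#' @param key Variant key (`chrom:pos:ref:alt`).
#' @param trio One pedigree row.
#' @param thresholds A `filter_thresholds` object.
#' @param mode A `mode_profile`.
#' @return List with `ok` (logical) and `reasons` (character vector of codes
#'   among `DP_LOW`, `ALT_READS_LOW`, `AB_LOW`, `PARENT_GQ_LOW`,
#'   `PARENT_HAS_ALT`, `PARENT_MISSING`).
#' @export
check_de_novo <- function(cohort, key, trio, thresholds = filter_thresholds(),
                          mode = mode_profile("exome_wide", thresholds)) {
  gg <- trio_genotypes(cohort, key, trio)
  de_novo_reasons(gg, thresholds, mode)
}

de_novo_reasons <- function(gg, thresholds, mode) {
  p <- gg$proband
  reasons <- character(0)
  if (is.na(p$dp) || p$dp < thresholds$min_depth_denovo)
    reasons <- c(reasons, "DP_LOW")
  if (is.na(p$alt_dp) || p$alt_dp < thresholds$min_alt_reads_denovo)
    reasons <- c(reasons, "ALT_READS_LOW")
  if (is.na(p$ab) || p$ab <= mode$ab_threshold)
    reasons <- c(reasons, "AB_LOW")
  for (par in list(gg$mother, gg$father)) {
    if (par$gt == "missing") {
      reasons <- c(reasons, "PARENT_MISSING")
      next
    }
    if (is.na(par$gq) || par$gq < thresholds$min_gq_parent)
      reasons <- c(reasons, "PARENT_GQ_LOW")
    if (is.na(par$alt_dp) || par$alt_dp > thresholds$max_parent_alt_reads)
      reasons <- c(reasons, "PARENT_HAS_ALT")
  }
  list(ok = length(reasons) == 0, reasons = unique(reasons))
}

#' Classify inheritance of proband variants within each trio
#'
#' For every variant whose proband carries the alternate allele, assigns
#' exactly one call: `transmitted_maternal` / `transmitted_paternal` /
#' `transmitted_biparental` when a parent also carries it (a hemizygous son
#' of a heterozygous mother is `transmitted_maternal`); `de_novo` when both
#' parents are homozygous reference and the full de novo evidence check
#' passes; otherwise `unresolved` with machine-readable reasons.
#' Mitochondrial and Y-chromosome sites are left `unresolved`
#' (`UNSUPPORTED_CHROM`) because biparental carrier logic does not apply.
#'
#' @param cohort A `trio_cohort`.
#' @param mode A `mode_profile` (or mode string).
#' @param thresholds A `filter_thresholds` object.
#' @param variant_keys Optional subset of variant keys to classify (defaults
#'   to all variants in the cohort).
#' @return Data frame of class `inheritance_calls`: one row per
#'   (variant, family) with proband a carrier; columns `variant_key`,
#'   `family_id`, `call`, `mode`, evidence columns (`proband_dp`,
#'   `proband_alt`, `proband_ab`, `proband_gq`, `mother_gq`, `mother_alt`,
#'   `father_gq`, `father_alt`) and `fail_reasons`.
#' @export
classify_inheritance <- function(cohort, mode = "exome_wide",
                                 thresholds = filter_thresholds(),
                                 variant_keys = NULL) {
  stopifnot(inherits(cohort, "trio_cohort"))
  if (!inherits(mode, "mode_profile")) mode <- mode_profile(mode, thresholds)
  keys <- if (is.null(variant_keys)) cohort$variants$variant_key else variant_keys
  chroms <- cohort$variants$chrom[match(keys, cohort$variants$variant_key)]
  rows <- list()
  for (i in seq_len(nrow(cohort$pedigree))) {
    trio <- cohort$pedigree[i, ]
    for (k in seq_along(keys)) {
      key <- keys[k]
      gg <- trio_genotypes(cohort, key, trio)
      if (!(gg$proband$gt %in% CARRIER_GENOTYPES)) next
      call <- NULL
      reasons <- character(0)
      if (sub("^chr", "", chroms[k]) %in% c("Y", "M", "MT")) {
        call <- "unresolved"
        reasons <- "UNSUPPORTED_CHROM"
      } else {
        mom_carrier <- gg$mother$gt %in% CARRIER_GENOTYPES
        dad_carrier <- gg$father$gt %in% CARRIER_GENOTYPES
        if (mom_carrier && dad_carrier) {
          call <- "transmitted_biparental"
        } else if (mom_carrier) {
          call <- "transmitted_maternal"
        } else if (dad_carrier) {
          call <- "transmitted_paternal"
        } else if (gg$mother$gt == "missing" || gg$father$gt == "missing") {
          call <- "unresolved"
          reasons <- "PARENT_MISSING"
        } else {
          dn <- de_novo_reasons(gg, thresholds, mode)
          call <- if (dn$ok) "de_novo" else "unresolved"
          reasons <- dn$reasons
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        variant_key = key, family_id = trio$family_id, call = call,
        mode = mode$mode,
        proband_dp = gg$proband$dp, proband_alt = gg$proband$alt_dp,
        proband_ab = gg$proband$ab, proband_gq = gg$proband$gq,
        mother_gq = gg$mother$gq, mother_alt = gg$mother$alt_dp,
        father_gq = gg$father$gq, father_alt = gg$father$alt_dp,
        fail_reasons = paste(reasons, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0) empty_calls() else do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("inheritance_calls", "data.frame")
  out
}

empty_calls <- function() {
  data.frame(variant_key = character(), family_id = character(),
             call = character(), mode = character(), proband_dp = numeric(),
             proband_alt = numeric(), proband_ab = numeric(),
             proband_gq = numeric(), mother_gq = numeric(),
             mother_alt = numeric(), father_gq = numeric(),
             father_alt = numeric(), fail_reasons = character(),
             stringsAsFactors = FALSE)
}

#' Detect non-transmitted parental variants
#'
#' Scans a (typically panel-restricted) cohort for variants carried by a
#' parent (het or hom_alt, genotype quality strictly above `min_gq_proband`)
#' that pass the site filter but are absent from the proband (homozygous or
#' hemizygous reference). These serve as a within-family negative-control
#' burden: pathogenic alleles the proband could have inherited but did not.
#'
#' @param cohort A `trio_cohort`.
#' @param thresholds A `filter_thresholds` object.
#' @param mode A `mode_profile` or mode string (recorded in the output).
#' @param panel Optional `gene_panel`; restricts to panel genes.
#' @return An `inheritance_calls` data frame with calls
#'   `non_transmitted_maternal` / `non_transmitted_paternal`, one row per
#'   carrier parent.
#' @export
find_non_transmitted <- function(cohort, thresholds = filter_thresholds(),
                                 mode = "targeted_panel", panel = NULL) {
  stopifnot(inherits(cohort, "trio_cohort"))
  if (!inherits(mode, "mode_profile")) mode <- mode_profile(mode, thresholds)
  v <- cohort$variants
  if (!is.null(panel)) v <- v[!is.na(v$gene) & toupper(v$gene) %in% panel$genes, ]
  if (nrow(v) > 0) v <- v[site_filter(v, thresholds)$passed, ]
  rows <- list()
  for (i in seq_len(nrow(cohort$pedigree))) {
    trio <- cohort$pedigree[i, ]
    for (key in v$variant_key) {
      gg <- trio_genotypes(cohort, key, trio)
      if (!(gg$proband$gt %in% HOMREF_GENOTYPES)) next
      for (side in c("mother", "father")) {
        par <- gg[[side]]
        if (!(par$gt %in% c("het", "hom_alt"))) next
        if (is.na(par$gq) || par$gq <= thresholds$min_gq_proband) next
        rows[[length(rows) + 1]] <- data.frame(
          variant_key = key, family_id = trio$family_id,
          call = paste0("non_transmitted_",
                        if (side == "mother") "maternal" else "paternal"),
          mode = mode$mode,
          proband_dp = gg$proband$dp, proband_alt = gg$proband$alt_dp,
          proband_ab = gg$proband$ab, proband_gq = gg$proband$gq,
          mother_gq = gg$mother$gq, mother_alt = gg$mother$alt_dp,
          father_gq = gg$father$gq, father_alt = gg$father$alt_dp,
          fail_reasons = "", stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) == 0) empty_calls() else do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("inheritance_calls", "data.frame")
  out
}

#' Write inheritance calls to TSV
#' @param calls An `inheritance_calls` data frame.
#' @param path Output path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
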