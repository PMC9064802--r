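#' Run the targeted gene-panel burden analysis
#'
#' Restricts the cohort to panel genes, applies the site and proband filters
#' in targeted-panel mode (allelic-balance floor 0.1), classifies inheritance
#' within every trio, and builds two case-control tables:
#'
#' * the proband-level exposure table — a proband is exposed when it carries
#'   at least one qualifying variant (curated class pathogenic or likely
#'   pathogenic, de novo or transmitted);
#' * the family-level non-transmitted table — a family is exposed when at
#'   least one parent carries a qualifying panel variant the proband did not
#'   inherit.
#'
#' @param cohort A `trio_cohort`.
#' @param panel A `gene_panel`.
#' @param thresholds A `filter_thresholds` object.
#' @return List of class `panel_analysis`: `panel`, `qualifying` (data frame
#'   of qualifying proband variants), `exposure_table`, `burden`
#'   (a `burden_result`), `non_transmitted` (calls),
#'   `non_transmitted_table`, `non_transmitted_burden` and `calls` (all
#'   panel-variant inheritance calls).
#' @export
run_panel_analysis <- function(cohort, panel,
                               thresholds = filter_thresholds()) {
  stopifnot(inherits(cohort, "trio_cohort"), inherits(panel, "gene_panel"))
  if (length(panel$genes) == 0) stop("empty gene panel")
  sub <- restrict_to_panel(cohort, panel)
  filtered <- apply_filters(sub, thresholds)
  calls <- classify_inheritance(sub, mode = "targeted_panel",
                                thresholds = thresholds,
                                variant_keys = filtered$survivors$variant_key)
  cls <- sub$variants$curated_class[match(calls$variant_key,
                                          sub$variants$variant_key)]
  carrier_calls <- c("de_novo", "transmitted_maternal", "transmitted_paternal",
                     "transmitted_biparental")
  qual <- calls[calls$call %in% carrier_calls &
                  cls %in% c("pathogenic", "likely_pathogenic"), , drop = FALSE]
  qual$curated_class <- sub$variants$curated_class[match(qual$variant_key,
                                                         sub$variants$variant_key)]
  qual$gene <- sub$variants$gene[match(qual$variant_key, sub$variants$variant_key)]

  exposure <- build_exposure_table(
    cohort$pedigree, qual, function(df) nrow(df) > 0,
    label = paste0(panel$name, ": >=1 pathogenic/likely pathogenic variant"))

  nt <- find_non_transmitted(sub, thresholds, mode = "targeted_panel",
                             panel = panel)
  nt_cls <- sub$variants$curated_class[match(nt$variant_key,
                                             sub$variants$variant_key)]
  nt_qual <- nt[nt_cls %in% c("pathogenic", "likely_pathogenic"), , drop = FALSE]
  nt_table <- build_exposure_table(
    cohort$pedigree, nt_qual, function(df) nrow(df) > 0,
    label = paste0(panel$name,
                   ": >=1 non-transmitted pathogenic/likely pathogenic variant"))

  structure(list(panel = panel, qualifying = qual, exposure_table = exposure,
                 burden = burden_result(exposure),
                 non_transmitted = nt_qual, non_transmitted_table = nt_table,
                 non_transmitted_burden = burden_result(nt_table),
                 calls = calls),
            class = "panel_analysis")
}

#' Restrict a cohort to the genes of a panel
#'
#' Keeps variants whose annotated gene symbol is in the panel (symbols
#' compared upper-case). Restriction is idempotent and commutes with
#' filtering.
#'
#' @param cohort A `trio_cohort`.
#' @param panel A `gene_panel`.
#' @return A `trio_cohort` containing only panel-gene variants.
#' @export
restrict_to_panel <- function(cohort, panel) {
  keep <- !is.na(cohort$variants$gene) &
    toupper(cohort$variants$gene) %in% panel$genes
  variants <- cohort$variants[keep, , drop = FALSE]
  genotypes <- cohort$genotypes[cohort$genotypes$variant_key %in%
                                  variants$variant_key, , drop = FALSE]
  rownames(variants) <- rownames(genotypes) <- NULL
  structure(list(variants = variants, genotypes = genotypes,
                 pedigree = cohort$pedigree), class = "trio_cohort")
}

#' Tally curated pathogenicity classes of panel variants
#'
#' Counts and percentages per ACMG class, plus the conventional grouped
#' summary (pathogenic/likely pathogenic, benign/likely benign, VUS).
#' Percentages are over classified variants and sum to 100 within rounding.
#'
#' @param classes Character vector of curated classes (one per variant).
#' @return List with `by_class` (data frame: class, n, pct) and `grouped`
#'   (data frame: group, n, pct). Empty input yields zero-row frames.
#' @export
summarize_variant_classes <- function(classes) {
  classes <- classes[!is.na(classes) & classes != "none"]
  n <- length(classes)
  if (n == 0) {
    empty <- data.frame(class = character(), n = integer(), pct = numeric())
    return(list(by_class = empty,
                grouped = data.frame(group = character(), n = integer(),
                                     pct = numeric())))
  }
  tab <- table(factor(classes, levels = setdiff(CURATED_CLASSES, "none")))
  by_class <- data.frame(class = names(tab), n = as.integer(tab),
                         pct = round(100 * as.integer(tab) / n),
                         stringsAsFactors = FALSE)
  grp <- c(pathogenic = "path_lpath", likely_pathogenic = "path_lpath",
           benign = "ben_lben", likely_benign = "ben_lben", VUS = "vus")
  gtab <- tapply(rep(1, n), grp[classes], sum)
  gtab[is.na(gtab)] <- 0
  grouped <- data.frame(group = c("path_lpath", "ben_lben", "vus"),
                        stringsAsFactors = FALSE)
  grouped$n <- as.integer(ifelse(is.na(gtab[grouped$group]), 0,
                                 gtab[grouped$group]))
  grouped$pct <- round(100 * grouped$n / n)
  list(by_class = by_class, grouped = grouped)
}
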