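KO_HUMAN_DISEASE <- "09160"
KO_ORGANISMAL <- "09150"
KO_NERVOUS_SYSTEM <- "09156"

#' Read a gene-to-KEGG-orthology mapping table
#'
#' Tab-separated with header `gene, category_code, category_name,
#' parent_code`; codes are 5-digit strings (e.g. 09140 Cellular Processes,
#' 09156 Nervous system), `parent_code` is empty for top-level categories. A
#' gene may map to several categories.
#'
#' @param path TSV path.
#' @return Data frame with upper-cased gene symbols and validated codes.
#' @export
read_ko_mapping <- function(path) {
  if (!file.exists(path)) stop("KO mapping file not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("gene", "category_code", "category_name", "parent_code")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0)
    stop("KO mapping lacks column(s): ", paste(missing_cols, collapse = ", "))
  m$parent_code[is.na(m$parent_code)] <- ""
  bad <- !grepl("^[0-9]{5}$", m$category_code) |
    !(m$parent_code == "" | grepl("^[0-9]{5}$", m$parent_code))
  if (any(bad))
    stop("malformed KO category code in row(s): ",
         paste(which(bad), collapse = ", "))
  m$gene <- toupper(m$gene)
  m
}

#' Select exome-wide de novo variants eligible for KEGG categorization
#'
#' Keeps de novo calls whose curated class is pathogenic, likely pathogenic
#' or VUS, and tags each with its gene and the proband's group.
#'
#' @param cohort A `trio_cohort`.
#' @param calls Exome-wide `inheritance_calls`.
#' @return Data frame: `variant_key`, `family_id`, `gene`, `curated_class`,
#'   `group`.
#' @export
select_exome_wide_de_novo <- function(cohort, calls) {
  dn <- calls[calls$call == "de_novo", , drop = FALSE]
  idx <- match(dn$variant_key, cohort$variants$variant_key)
  dn$gene <- cohort$variants$gene[idx]
  dn$curated_class <- cohort$variants$curated_class[idx]
  dn <- dn[dn$curated_class %in% c("pathogenic", "likely_pathogenic", "VUS"), ,
           drop = FALSE]
  dn$group <- cohort$pedigree$proband_affected[match(dn$family_id,
                                                     cohort$pedigree$family_id)]
  rownames(dn) <- NULL
  dn[, c("variant_key", "family_id", "gene", "curated_class", "group")]
}

ko_excluded <- function(code, parent) {
  (code == KO_HUMAN_DISEASE | parent == KO_HUMAN_DISEASE) |
    ((code == KO_ORGANISMAL | parent == KO_ORGANISMAL) &
       code != KO_NERVOUS_SYSTEM)
}

#' Categorize de novo variant genes by KEGG orthology
#'
#' Joins genes to their KO categories (multi-membership: a gene contributes
#' to every category it maps to, counted once per gene and category), drops
#' the human-disease branch (09160) and the organismal-systems branch
#' (09150) except the nervous system (09156), and tabulates per-group gene
#' counts with within-group proportions over categorized genes.
#'
#' @param genes Data frame from [select_exome_wide_de_novo()] (needs `gene`
#'   and `group` columns).
#' @param mapping KO mapping from [read_ko_mapping()].
#' @return List of class `ko_enrichment`: `table` (data frame per retained
#'   category: `category_code`, `category_name`, `count_epilepsy`,
#'   `count_no_epilepsy`, `prop_epilepsy`, `prop_no_epilepsy`), `excluded`
#'   (gene-category pairs removed by the branch exclusions) and `unmapped`
#'   (genes with no KO mapping).
#' @export
categorize_ko <- function(genes, mapping) {
  g <- unique(genes[, c("gene", "group"), drop = FALSE])
  g$gene <- toupper(g$gene)
  joined <- merge(g, mapping, by = "gene")
  unmapped <- sort(setdiff(g$gene, mapping$gene))
  drop <- ko_excluded(joined$category_code, joined$parent_code)
  excluded <- joined[drop, , drop = FALSE]
  kept <- joined[!drop, , drop = FALSE]
  kept <- unique(kept[, c("gene", "group", "category_code", "category_name")])
  cats <- unique(kept[, c("category_code", "category_name")])
  cats <- cats[order(cats$category_code), , drop = FALSE]
  n_epi <- length(unique(kept$gene[kept$group == "epilepsy"]))
  n_no <- length(unique(kept$gene[kept$group == "no_epilepsy"]))
  count_in <- function(code, grp)
    sum(kept$category_code == code & kept$group == grp)
  tab <- data.frame(
    category_code = cats$category_code, category_name = cats$category_name,
    count_epilepsy = vapply(cats$category_code, count_in, numeric(1),
                            grp = "epilepsy"),
    count_no_epilepsy = vapply(cats$category_code, count_in, numeric(1),
                               grp = "no_epilepsy"),
    stringsAsFactors = FALSE)
  tab$prop_epilepsy <- if (n_epi > 0) tab$count_epilepsy / n_epi else NA_real_
  tab$prop_no_epilepsy <- if (n_no > 0) tab$count_no_epilepsy / n_no else NA_real_
  rownames(tab) <- NULL
  structure(list(table = tab, excluded = excluded, unmapped = unmapped,
                 n_genes_epilepsy = n_epi, n_genes_no_epilepsy = n_no,
                 counting = "per gene (a gene counts once per category)"),
            class = "ko_enrichment")
}

#' Write a KO enrichment table to TSV
#' @param enrichment A `ko_enrichment` object.
#' @param path Output path.
#' @export
write_enrichment <- function(enrichment, path) {
  utils::write.table(enrichment$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
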