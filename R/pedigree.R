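#' Read a pedigree of sequencing trios from a PED file
#'
#' Parses a 6-column whitespace-delimited PED file (family, individual,
#' father, mother, sex, phenotype) and assembles one trio per family:
#' a proband (the individual whose father and mother IDs are both set)
#' plus both biological parents.
#'
#' The phenotype column carries the proband's outcome (2 = epilepsy,
#' 1 = no epilepsy). For parents the same column is read as a parental
#' phenotype (2 = affected, 1 = unaffected, anything else = unknown), so
#' that inherited variants can be checked against parental disease history.
#'
#' @param path Path to a PED file.
#' @return A data frame of class `trio_pedigree` with one row per trio and
#'   columns `family_id`, `proband_id`, `father_id`, `mother_id`,
#'   `proband_sex` (`"male"`, `"female"`, `"unknown"`), `proband_affected`
#'   (`"epilepsy"` / `"no_epilepsy"`), `father_pheno`, `mother_pheno`.
#' @examples
#' ped <- tempfile(fileext = ".ped")
#' writeLines(c("F1 dad 0 0 1 1", "F1 mom 0 0 2 1", "F1 kid dad mom 1 2"), ped)
#' read_pedigree(ped)
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(ped) < 6) stop("PED file must have 6 columns, got ", ncol(ped))
  ped <- ped[, 1:6]
  names(ped) <- c("family_id", "individual_id", "father_id", "mother_id",
                  "sex", "phenotype")
  dup <- ped$individual_id[duplicated(ped$individual_id)]
  if (length(dup) > 0)
    stop("duplicate individual ID in pedigree: ", paste(unique(dup), collapse = ", "))

  trios <- lapply(split(ped, ped$family_id), function(fam) {
    is_child <- fam$father_id != "0" & fam$mother_id != "0"
    half <- xor(fam$father_id != "0", fam$mother_id != "0")
    if (any(half) || !any(is_child))
      stop("incomplete trio in family ", fam$family_id[1],
           ": proband must name both parents")
    if (sum(is_child) != 1)
      stop("family ", fam$family_id[1], " must contain exactly one proband, found ",
           sum(is_child))
    child <- fam[is_child, ]
    for (p in c(child$father_id, child$mother_id)) {
      if (!p %in% fam$individual_id)
        stop("incomplete trio in family ", fam$family_id[1],
             ": parent ", p, " has no pedigree record")
    }
    ids <- c(child$individual_id, child$father_id, child$mother_id)
    if (anyDuplicated(ids))
      stop("family ", fam$family_id[1], ": proband and parent IDs must be distinct")
    pheno_of <- function(id) {
      ph <- fam$phenotype[fam$individual_id == id]
      if (ph == "2") "affected" else if (ph == "1") "unaffected" else "unknown"
    }
    data.frame(
      family_id = child$family_id,
      proband_id = child$individual_id,
      father_id = child$father_id,
      mother_id = child$mother_id,
      proband_sex = switch(child$sex, "1" = "male", "2" = "female", "unknown"),
      proband_affected = if (child$phenotype == "2") "epilepsy" else "no_epilepsy",
      father_pheno = pheno_of(child$father_id),
      mother_pheno = pheno_of(child$mother_id),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, trios)
  rownames(out) <- NULL
  class(out) <- c("trio_pedigree", "data.frame")
  out
}

#' Load a gene panel from a plain-text gene list
#'
#' One gene symbol per line; `#` starts a comment. Symbols are upper-cased
#' and deduplicated (duplicates trigger a warning).
#'
#' @param path Path to the panel file.
#' @param name Panel name used in reports.
#' @return An object of class `gene_panel`: a list with `name` and `genes`
#'   (character vector of unique upper-case symbols).
#' @export
load_panel <- function(path, name) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  genes <- toupper(trimws(lines))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) stop("panel file is empty: ", path)
  if (anyDuplicated(genes)) {
    warning("panel '", name, "' contains ",
            sum(duplicated(genes)), " duplicated symbol(s); deduplicated")
    genes <- unique(genes)
  }
  structure(list(name = name, genes = genes), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("Gene panel '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Check that two gene panels share no genes
#'
#' A sensitivity panel (e.g. coronary-artery-disease genes) must be disjoint
#' from the primary disease panel for the comparison to be informative.
#'
#' @param a,b Objects of class `gene_panel`.
#' @return `TRUE` if the panels are disjoint, otherwise `FALSE` with the
#'   overlapping symbols in attribute `"overlap"` and a warning listing them.
#' @export
assert_non_overlap <- function(a, b) {
  stopifnot(inherits(a, "gene_panel"), inherits(b, "gene_panel"))
  ov <- intersect(a$genes, b$genes)
  if (length(ov) == 0) return(TRUE)
  warning("panels '", a$name, "' and '", b$name, "' overlap: ",
          paste(ov, collapse = ", "))
  structure(FALSE, overlap = ov)
}
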