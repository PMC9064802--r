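ANNOTATION_COLS <- c("chrom", "pos", "ref", "alt", "gene", "variant_type",
                     "splice_distance_bp", "af_1kg", "af_evs", "cadd_phred",
                     "polyphen_humdiv", "polyphen_humvar", "curated_class")

VARIANT_TYPES <- c("missense", "nonsense", "frameshift", "inframe_indel",
                   "splice", "synonymous", "other")

CURATED_CLASSES <- c("pathogenic", "likely_pathogenic", "VUS",
                     "likely_benign", "benign", "none")

#' Normalize a variant allele pair
#'
#' Trims shared trailing then leading bases from REF/ALT (keeping at least one
#' base of each) and shifts `pos` across trimmed leading bases, so that the
#' identity key `(chrom, pos, ref, alt)` is well defined for indels regardless
#' of how the caller padded them.
#'
#' @param pos 1-based position.
#' @param ref,alt Reference and single alternate allele strings.
#' @return List with normalized `pos`, `ref`, `alt`.
#' @export
normalize_allele <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Read a per-variant annotation table
#'
#' Tab-separated with header columns `chrom, pos, ref, alt, gene,
#' variant_type, splice_distance_bp, af_1kg, af_evs, cadd_phred,
#' polyphen_humdiv, polyphen_humvar, curated_class`. Alleles are normalized
#' with [normalize_allele()] before keying so annotation rows match VCF
#' records after multi-allelic splitting.
#'
#' @param path Path to the TSV.
#' @return Data frame keyed by `variant_key`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  missing_cols <- setdiff(ANNOTATION_COLS, names(ann))
  if (length(missing_cols) > 0)
    stop("annotation table lacks column(s): ", paste(missing_cols, collapse = ", "))
  bad <- !is.na(ann$variant_type) & !ann$variant_type %in% VARIANT_TYPES
  if (any(bad))
    stop("unknown variant_type value(s): ",
         paste(unique(ann$variant_type[bad]), collapse = ", "))
  ann$curated_class[is.na(ann$curated_class) | ann$curated_class == ""] <- "none"
  bad <- !ann$curated_class %in% CURATED_CLASSES
  if (any(bad))
    stop("unknown curated_class value(s): ",
         paste(unique(ann$curated_class[bad]), collapse = ", "))
  norm <- Map(normalize_allele, ann$pos, ann$ref, ann$alt)
  ann$pos <- vapply(norm, `[[`, numeric(1), "pos")
  ann$ref <- vapply(norm, `[[`, character(1), "ref")
  ann$alt <- vapply(norm, `[[`, character(1), "alt")
  ann$variant_key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(ann$variant_key))
    stop("duplicate annotation rows for: ",
         paste(unique(ann$variant_key[duplicated(ann$variant_key)]), collapse = ", "))
  ann
}

# Classify one sample's genotype with respect to alternate allele index i
# (1-based among ALT alleles). Alleles equal to a different alternate count
# as non-carrier for this record.
classify_gt <- function(gt, alt_index) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return("missing")
  al <- strsplit(gt, "[/|]")[[1]]
  if (any(al == ".") || length(al) == 0) return("missing")
  if (!all(grepl("^[0-9]+$", al))) return("missing")
  n_alt <- sum(al == as.character(alt_index))
  if (length(al) == 1) {
    return(if (n_alt == 1) "hemi_alt" else "hemi_ref")
  }
  if (n_alt >= 2) "hom_alt" else if (n_alt == 1) "het" else "hom_ref"
}

CARRIER_GENOTYPES <- c("het", "hom_alt", "hemi_alt")
HOMREF_GENOTYPES <- c("hom_ref", "hemi_ref")

#' Read a multi-sample trio VCF into an annotated cohort
#'
#' Reads a VCF 4.2 file carrying GT, DP, AD and GQ FORMAT fields for every
#' pedigree sample, splits multi-allelic records into one record per
#' alternate allele (decomposing AD accordingly), normalizes alleles, and
#' joins the per-variant annotation table. Records with no annotation row
#' keep `curated_class = "none"` and NA annotation fields.
#'
#' @param path Path to the VCF (plain text or bgzipped).
#' @param pedigree A `trio_pedigree` from [read_pedigree()].
#' @param annotations Annotation data frame from [read_annotations()], or
#'   `NULL` to read genotypes only.
#' @return A `trio_cohort`: list with `variants` (one row per
#'   chrom/pos/ref/alt with annotation columns), `genotypes` (long data frame:
#'   `variant_key`, `sample_id`, `gt`, `dp`, `alt_dp`, `gq`, `ab`) and
#'   `pedigree`.
#' @export
read_trio_vcf <- function(path, pedigree, annotations = NULL) {
  stopifnot(inherits(pedigree, "trio_pedigree"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  need <- unique(c(pedigree$proband_id, pedigree$father_id, pedigree$mother_id))
  absent <- setdiff(need, samples)
  if (length(absent) > 0)
    stop("pedigree sample(s) absent from VCF header: ",
         paste(absent, collapse = ", "))

  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    return(empty_cohort(pedigree))
  }
  gt_m <- vcfR::extract.gt(vcf, element = "GT")
  dp_m <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  gq_m <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  ad_m <- vcfR::extract.gt(vcf, element = "AD")

  var_rows <- vector("list", n_rec)
  geno_rows <- vector("list", n_rec)
  for (i in seq_len(n_rec)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    vr <- vector("list", length(alts))
    gr <- vector("list", length(alts))
    for (j in seq_along(alts)) {
      norm <- normalize_allele(as.integer(fix[i, "POS"]), fix[i, "REF"], alts[j])
      key <- variant_key(fix[i, "CHROM"], norm$pos, norm$ref, norm$alt)
      vr[[j]] <- data.frame(
        variant_key = key, chrom = fix[i, "CHROM"], pos = norm$pos,
        ref = norm$ref, alt = norm$alt, stringsAsFactors = FALSE)
      gt <- vapply(need, function(s) classify_gt(gt_m[i, s], j), character(1))
      ad <- lapply(need, function(s) {
        x <- ad_m[i, s]
        if (is.na(x)) return(c(NA_real_, NA_real_))
        v <- suppressWarnings(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]]))
        c(if (j + 1 <= length(v)) v[j + 1] else NA_real_, sum(v, na.rm = TRUE))
      })
      alt_dp <- vapply(ad, `[`, numeric(1), 1)
      ad_sum <- vapply(ad, `[`, numeric(1), 2)
      dp <- as.numeric(dp_m[i, need])
      dp[is.na(dp)] <- ad_sum[is.na(dp)]
      # keep alt_depth <= total_depth even for inconsistent caller output
      keep <- !is.na(dp) & !is.na(alt_dp)
      dp[keep] <- pmax(dp[keep], alt_dp[keep])
      ab <- ifelse(!is.na(dp) & dp > 0, alt_dp / dp, NA_real_)
      gr[[j]] <- data.frame(
        variant_key = key, sample_id = need, gt = gt,
        dp = as.numeric(dp), alt_dp = alt_dp, gq = as.numeric(gq_m[i, need]),
        ab = ab, stringsAsFactors = FALSE, row.names = NULL)
    }
    var_rows[[i]] <- do.call(rbind, vr)
    geno_rows[[i]] <- do.call(rbind, gr)
  }
  variants <- do.call(rbind, var_rows)
  genotypes <- do.call(rbind, geno_rows)
  if (anyDuplicated(variants$variant_key))
    stop("duplicate variant key after normalization: ",
         paste(unique(variants$variant_key[duplicated(variants$variant_key)]),
               collapse = ", "))

  variants <- join_annotations(variants, annotations)
  rownames(variants) <- rownames(genotypes) <- NULL
  structure(list(variants = variants, genotypes = genotypes,
                 pedigree = pedigree),
            class = "trio_cohort")
}

join_annotations <- function(variants, annotations) {
  ann_cols <- setdiff(ANNOTATION_COLS, c("chrom", "pos", "ref", "alt"))
  if (is.null(annotations)) {
    for (cc in ann_cols) variants[[cc]] <- rep(NA, nrow(variants))
    variants$curated_class <- rep("none", nrow(variants))
    variants$annotated <- rep(FALSE, nrow(variants))
    return(variants)
  }
  idx <- match(variants$variant_key, annotations$variant_key)
  for (cc in ann_cols) variants[[cc]] <- annotations[[cc]][idx]
  variants$annotated <- !is.na(idx)
  variants$curated_class[!variants$annotated] <- "none"
  variants
}

empty_cohort <- function(pedigree) {
  variants <- data.frame(variant_key = character(), chrom = character(),
                         pos = numeric(), ref = character(), alt = character(),
                         stringsAsFactors = FALSE)
  variants <- join_annotations(variants, NULL)
  genotypes <- data.frame(variant_key = character(), sample_id = character(),
                          gt = character(), dp = numeric(), alt_dp = numeric(),
                          gq = numeric(), ab = numeric(), stringsAsFactors = FALSE)
  structure(list(variants = variants, genotypes = genotypes, pedigree = pedigree),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat("Trio cohort:", nrow(x$pedigree), "trios,",
      nrow(x$variants), "variants\n")
  invisible(x)
}

#' Write a cohort back to VCF + annotation TSV
#'
#' Emits one biallelic VCF 4.2 record per variant with GT:DP:AD:GQ sample
#' fields, plus the annotation table, in the formats [read_trio_vcf()] and
#' [read_annotations()] consume. Used for report artifacts and round-trip
#' checks.
#'
#' @param cohort A `trio_cohort`.
#' @param vcf_path,annotation_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, vcf_path, annotation_path = NULL) {
  stopifnot(inherits(cohort, "trio_cohort"))
  samples <- unique(c(cohort$pedigree$proband_id, cohort$pedigree$father_id,
                      cohort$pedigree$mother_id))
  v <- cohort$variants
  ord <- order(chrom_rank(v$chrom), v$pos, v$ref, v$alt)
  v <- v[ord, , drop = FALSE]
  g <- cohort$genotypes
  gt_string <- function(key, s) {
    row <- g[g$variant_key == key & g$sample_id == s, ]
    if (nrow(row) != 1) return("./.:.:.:.")
    gt <- switch(row$gt, hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                 hemi_alt = "1", hemi_ref = "0", "./.")
    dp <- if (is.na(row$dp)) "." else format(row$dp, scientific = FALSE)
    alt <- if (is.na(row$alt_dp)) "." else format(row$alt_dp, scientific = FALSE)
    ref_dp <- if (is.na(row$dp) || is.na(row$alt_dp)) "." else
      format(row$dp - row$alt_dp, scientific = FALSE)
    gq <- if (is.na(row$gq)) "." else format(row$gq, scientific = FALSE)
    paste(gt, dp, paste(ref_dp, alt, sep = ","), gq, sep = ":")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(i) {
    fields <- vapply(samples, function(s) gt_string(v$variant_key[i], s),
                     character(1))
    paste(c(v$chrom[i], format(v$pos[i], scientific = FALSE), ".", v$ref[i],
            v$alt[i], ".", "PASS", ".", "GT:DP:AD:GQ", fields), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), vcf_path)
  if (!is.null(annotation_path)) {
    ann <- v[v$annotated, c(ANNOTATION_COLS), drop = FALSE]
    utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(vcf_path, annotation_path))
}

chrom_rank <- function(chrom) {
  x <- sub("^chr", "", chrom)
  r <- suppressWarnings(as.numeric(x))
  r[x == "X"] <- 23
  r[x == "Y"] <- 24
  r[x %in% c("M", "MT")] <- 25
  r[is.na(r)] <- 26
  r
}
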