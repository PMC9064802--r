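# Worked-example cohorts. Both encode the published per-case variant tables
# of the study the pipeline reproduces (gene, consequence, inheritance mode,
# CADD, curated class), embedded in a synthetic 10 + 10 trio cohort with
# qualifying read evidence, so the targeted-panel and exome-wide analyses
# can be run end to end without sequence data.

EXAMPLE_EPILEPSY_FAMILIES <- c(1, 2, 3, 4, 5, 7, 9, 10, 16, 17)

example_pedigree_spec <- function() {
  n <- 20
  data.frame(
    family_id = sprintf("T%02d", 1:n),
    proband_id = sprintf("P%02d", 1:n),
    father_id = sprintf("D%02d", 1:n),
    mother_id = sprintf("M%02d", 1:n),
    sex = ifelse(1:n == 1, 1, rep(c(1, 2), 10)),  # family 1 male: X-linked case
    group = ifelse(1:n %in% EXAMPLE_EPILEPSY_FAMILIES, "epilepsy",
                   "no_epilepsy"),
    stringsAsFactors = FALSE)
}

fixture_geno <- function(inh, i) {
  dp <- function(k) 40 + (i * 7 + k * 11) %% 25
  het <- function(k) {
    d <- dp(k)
    geno_spec("0/1", d, floor(d / 2), 99)
  }
  hom <- function(k) geno_spec("0/0", dp(k), 0, 99)
  switch(inh,
    dn = list(pro = het(0), dad = hom(1), mom = hom(2)),
    mat = list(pro = het(0), dad = hom(1), mom = het(2)),
    pat = list(pro = het(0), dad = het(1), mom = hom(2)),
    nt_mat = list(pro = hom(0), dad = hom(1), mom = het(2)),
    nt_pat = list(pro = hom(0), dad = het(1), mom = hom(2)),
    hemi_mat = list(pro = geno_spec("1", 55, 54, 99),
                    dad = geno_spec("0", 50, 0, 99), mom = het(2)),
    stop("unknown inheritance spec: ", inh))
}

fixture_variant <- function(chrom, pos, gene, type, cadd, curated, fam, inh,
                            splice = 0, pphd = NA, pphv = NA) {
  al <- sim_alleles(type)
  list(chrom = as.character(chrom), pos = pos, ref = al$ref, alt = al$alt,
       gene = gene, type = type, splice = splice, cadd = cadd,
       pphd = pphd, pphv = pphv, curated = curated, fam = fam, inh = inh)
}

write_fixture_files <- function(dir, variants, prefix) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ped <- example_pedigree_spec()
  samples <- as.vector(rbind(ped$proband_id, ped$father_id, ped$mother_id))
  ord <- order(chrom_rank(vapply(variants, `[[`, character(1), "chrom")),
               vapply(variants, `[[`, numeric(1), "pos"))
  variants <- variants[ord]
  body <- vapply(variants, function(v) {
    fields <- rep("0/0:50:50,0:99", length(samples))
    names(fields) <- samples
    g <- fixture_geno(v$inh, v$pos %% 13)
    fields[ped$proband_id[v$fam]] <- format_sample_field(g$pro)
    fields[ped$father_id[v$fam]] <- format_sample_field(g$dad)
    fields[ped$mother_id[v$fam]] <- format_sample_field(g$mom)
    paste(c(v$chrom, format(v$pos, scientific = FALSE), ".", v$ref, v$alt,
            ".", "PASS", ".", "GT:DP:AD:GQ", fields), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  writeLines(c(header, body), vcf_path)

  ped_path <- file.path(dir, paste0(prefix, ".ped"))
  writeLines(vapply(seq_len(nrow(ped)), function(i) {
    paste(c(paste(ped$family_id[i], ped$father_id[i], "0 0 1 1"),
            paste(ped$family_id[i], ped$mother_id[i], "0 0 2 1"),
            paste(ped$family_id[i], ped$proband_id[i], ped$father_id[i],
                  ped$mother_id[i], ped$sex[i],
                  if (ped$group[i] == "epilepsy") 2 else 1)),
          collapse = "\n")
  }, character(1)), ped_path)

  ann_path <- file.path(dir, paste0(prefix, "_annotations.tsv"))
  ann <- do.call(rbind, lapply(variants, function(v) data.frame(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt, gene = v$gene,
    variant_type = v$type, splice_distance_bp = v$splice, af_1kg = 0,
    af_evs = 0, cadd_phred = v$cadd, polyphen_humdiv = v$pphd,
    polyphen_humvar = v$pphv, curated_class = v$curated,
    stringsAsFactors = FALSE)))
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(vcf = vcf_path, ped = ped_path, annotations = ann_path)
}

#' Worked-example cohort for the targeted epilepsy-panel analysis
#'
#' Twenty trios (10 probands with post-neonatal epilepsy, 10 without)
#' carrying 29 epilepsy-panel variants: the six published pathogenic /
#' likely-pathogenic variants (maternally inherited CASK, PRRT2 and KCNT1
#' missense and CPA6 nonsense; de novo MAGI2 splice and RBFOX3 missense)
#' each planted in its published case with its published CADD and
#' inheritance mode, plus 23 inherited benign / likely-benign / VUS panel
#' variants and two de novo VUS. Also planted: one pathogenic CAD-panel
#' variant in one case and one control (the sensitivity analysis), one
#' non-transmitted pathogenic epilepsy-panel variant in a case mother and
#' one non-transmitted pathogenic CAD variant in a case father (the
#' negative-control analyses). All planted evidence clears the quality
#' thresholds.
#'
#' @param dir Output directory.
#' @return List with file paths: `vcf`, `ped`, `annotations`,
#'   `panel_epilepsy`, `panel_cad`.
#' @export
example_targeted_cohort <- function(dir) {
  published <- list(
    fixture_variant("X", 41500000, "CASK", "missense", 21.4,
                    "likely_pathogenic", 1, "hemi_mat", pphd = 1.0, pphv = 1.0),
    fixture_variant(7, 77694888, "MAGI2", "splice", 21.1,
                    "likely_pathogenic", 2, "dn", splice = 1),
    fixture_variant(16, 29825000, "PRRT2", "missense", 24.4,
                    "likely_pathogenic", 3, "mat", pphd = 0.99, pphv = 0.94),
    fixture_variant(17, 77090000, "RBFOX3", "missense", 34.0,
                    "likely_pathogenic", 4, "dn", pphd = 0.98, pphv = 0.67),
    fixture_variant(9, 138650000, "KCNT1", "missense", 27.6,
                    "likely_pathogenic", 5, "mat", pphd = 1.0, pphv = 1.0),
    fixture_variant(8, 68300000, "CPA6", "nonsense", 46.0,
                    "pathogenic", 6, "mat"))
  cad <- list(
    fixture_variant(19, 11200000, "LDLR", "missense", 29.1,
                    "pathogenic", 7, "pat"),
    fixture_variant(2, 21224000, "APOB", "missense", 25.3,
                    "likely_pathogenic", 11, "mat"))
  non_transmitted <- list(
    fixture_variant(20, 62040000, "KCNQ2", "nonsense", 38.0,
                    "pathogenic", 3, "nt_mat"),
    fixture_variant(1, 55505000, "PCSK9", "missense", 27.0,
                    "pathogenic", 5, "nt_pat"))
  # 23 further panel variants: 9 benign, 8 likely benign, 4 inherited VUS and
  # 2 de novo VUS (so the cohort carries 29 panel variants, 4 of them de novo)
  filler_genes <- c("CACNA1H", "RYR3", "SCN9A", "EFHC1", "GRIN2D", "SRPX2",
                    "ALG13", "CHD2", "DNM1", "KCNA2", "SCN8A", "STXBP1",
                    "CACNB4", sprintf("EPI%04d", 21:30))
  filler_class <- c(rep("benign", 9), rep("likely_benign", 8), rep("VUS", 6))
  filler_fam <- rep(1:20, length.out = 23)
  filler <- lapply(seq_len(23), function(i) {
    fixture_variant(1 + (i %% 22), 5e6 + i * 1000, filler_genes[i],
                    "missense", 22 + i / 10, filler_class[i], filler_fam[i],
                    inh = if (filler_class[i] == "VUS" && i >= 22) "dn" else
                      if (i %% 2 == 0) "mat" else "pat")
  })
  paths <- write_fixture_files(dir, c(published, cad, non_transmitted, filler),
                               "targeted")
  panel_epi <- file.path(dir, "panel_epilepsy.txt")
  writeLines(c("# epilepsy panel (synthetic stand-in for the commercial 200-gene panel)",
               "CASK", "MAGI2", "PRRT2", "RBFOX3", "KCNT1", "CPA6", "KCNQ2",
               filler_genes, sprintf("EPI%04d", 31:200)), panel_epi)
  panel_cad <- file.path(dir, "panel_cad.txt")
  writeLines(c("# CAD panel (synthetic stand-in, disjoint from the epilepsy panel)",
               "LDLR", "APOB", "PCSK9", sprintf("CAD%03d", 4:89)), panel_cad)
  c(paths, panel_epilepsy = panel_epi, panel_cad = panel_cad)
}

#' Worked-example cohort for the exome-wide de novo analysis
#'
#' The same 20-trio pedigree carrying the seventeen published de novo
#' variants outside known epilepsy genes: seven variants in six probands
#' with post-neonatal epilepsy (ENOX1, PTPN14, ATF6B, SNRPB, MIF4GD, GNB3,
#' CAPN7) and ten in six probands without (DHRS11, FAM186A, HECTD4, PCBP2,
#' VPS37A, ELF1, CSTF2T, UBXN11, DCHS2, OSBP), each with its published
#' consequence class, CADD score and curated ACMG class, and with read
#' evidence clearing every de novo threshold. A synthetic KEGG-orthology
#' mapping for these genes is written alongside (nervous-system and
#' signalling categories for the epilepsy-group genes; cell growth and
#' death, ubiquitin-related protein degradation and transcription for the
#' others; two rows in excluded branches and one unmapped gene, so the
#' exclusion and reporting rules are exercised).
#'
#' @param dir Output directory.
#' @return List with file paths: `vcf`, `ped`, `annotations`, `ko_mapping`.
#' @export
example_denovo_cohort <- function(dir) {
  row <- function(chrom, pos, gene, type, cadd, curated, fam, splice = 0,
                  pphd = NA, pphv = NA)
    fixture_variant(chrom, pos, gene, type, cadd, curated, fam, "dn",
                    splice = splice, pphd = pphd, pphv = pphv)
  variants <- list(
    # probands with post-neonatal epilepsy: 7 variants in families 2,3,4,7,9,10
    row(13, 45560000, "ENOX1", "missense", 31.0, "likely_pathogenic", 2,
        pphd = 1.0, pphv = 0.99),
    row(1, 214530000, "PTPN14", "missense", 23.1, "likely_pathogenic", 2,
        pphd = 0.99, pphv = 0.97),
    row(6, 32080000, "ATF6B", "missense", 25.5, "likely_pathogenic", 3,
        pphd = 0.98, pphv = 0.70),
    row(20, 2440000, "SNRPB", "missense", 23.7, "likely_pathogenic", 4,
        pphd = 0.84, pphv = 0.49),
    row(17, 73260000, "MIF4GD", "nonsense", 42.0, "pathogenic", 7),
    row(12, 6950000, "GNB3", "missense", 24.9, "likely_pathogenic", 9,
        pphd = 0.95, pphv = 0.52),
    row(3, 15250000, "CAPN7", "missense", 25.6, "likely_pathogenic", 10,
        pphd = 0.99, pphv = 0.93),
    # probands without post-neonatal epilepsy: 10 variants in 8,11,12,13,14,15
    row(17, 34940000, "DHRS11", "missense", 28.3, "likely_pathogenic", 8,
        pphd = 0.99, pphv = 0.94),
    row(12, 50740000, "FAM186A", "frameshift", 22.6, "pathogenic", 8),
    row(12, 112819897, "HECTD4", "splice", 20.2, "likely_pathogenic", 11,
        splice = 1),
    row(12, 53845910, "PCBP2", "splice", 22.4, "VUS", 11, splice = 2),
    row(8, 17230000, "VPS37A", "missense", 21.8, "likely_pathogenic", 11,
        pphd = 0.97, pphv = 0.41),
    row(13, 41500000, "ELF1", "missense", 23.3, "VUS", 12,
        pphd = 0.99, pphv = 0.99),
    row(10, 53450000, "CSTF2T", "missense", 32.0, "likely_pathogenic", 13,
        pphd = 0.99, pphv = 0.99),
    row(1, 26610000, "UBXN11", "frameshift", 22.2, "pathogenic", 13),
    row(4, 155160000, "DCHS2", "nonsense", 25.8, "pathogenic", 14),
    row(11, 59340000, "OSBP", "missense", 31.0, "likely_pathogenic", 15,
        pphd = 1.0, pphv = 0.99))
  paths <- write_fixture_files(dir, variants, "denovo")

  ko <- rbind(
    data.frame(gene = c("ENOX1", "GNB3"), category_code = "09156",
               category_name = "Nervous system", parent_code = "09150"),
    data.frame(gene = c("PTPN14", "GNB3", "DCHS2"), category_code = "09132",
               category_name = "Signal transduction", parent_code = "09130"),
    data.frame(gene = c("ATF6B", "HECTD4", "UBXN11"), category_code = "09123",
               category_name = "Folding, sorting and degradation",
               parent_code = "09120"),
    data.frame(gene = c("SNRPB", "MIF4GD"), category_code = "09122",
               category_name = "Translation", parent_code = "09120"),
    data.frame(gene = c("CAPN7", "VPS37A"), category_code = "09141",
               category_name = "Transport and catabolism",
               parent_code = "09140"),
    data.frame(gene = c("HECTD4", "UBXN11", "VPS37A"), category_code = "09143",
               category_name = "Cell growth and death", parent_code = "09140"),
    data.frame(gene = c("PCBP2", "ELF1", "CSTF2T"), category_code = "09121",
               category_name = "Transcription", parent_code = "09120"),
    data.frame(gene = c("DHRS11", "OSBP"), category_code = "09101",
               category_name = "Carbohydrate metabolism",
               parent_code = "09100"),
    # excluded branches: human disease, and immune system under 09150
    data.frame(gene = c("GNB3", "ENOX1"), category_code = "09161",
               category_name = "Cancer: overview", parent_code = "09160"),
    data.frame(gene = "PTPN14", category_code = "09151",
               category_name = "Immune system", parent_code = "09150"))
  # FAM186A deliberately left unmapped
  ko_path <- file.path(dir, "ko_mapping.tsv")
  utils::write.table(ko, ko_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(paths, ko_mapping = ko_path)
}
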