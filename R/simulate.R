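#' Configuration for the synthetic trio-cohort generator
#'
#' Defaults mirror the study design the pipeline targets: 10 case trios
#' (probands with post-neonatal epilepsy) and 10 control trios, a
#' panel-pathogenic carrier probability of 0.5 in cases versus 0.1 in
#' controls (an expected exposure odds ratio of (0.5/0.5)/(0.1/0.9) = 9), a
#' mean site depth of 60 reads and a mean heterozygous allelic balance of
#' 0.5. Annotation spectra are parameterized to straddle every filter
#' boundary (CADD mixture around 20, allele-frequency tail around 0.1%) so
#' that filter behaviour on both sides of each threshold is exercised.
#'
#' @param n_case_trios,n_control_trios Number of trios per group.
#' @param seed Integer seed; a fixed seed gives byte-identical output files.
#' @param p_panel_pathogenic_case,p_panel_pathogenic_control Probability that
#'   a proband carries a planted pathogenic/likely-pathogenic panel variant.
#' @param n_background_variants_per_trio Background (mostly inherited,
#'   mixed-annotation) variants planted per trio.
#' @param denovo_rate_per_trio Expected planted de novo variants per trio
#'   (Poisson).
#' @param nontransmitted_rate Expected planted non-transmitted parental
#'   panel variants per trio (Poisson).
#' @param artifact_rate_per_trio Expected planted artifact sites per trio:
#'   proband carrier with hom-ref parents but evidence below the de novo
#'   thresholds (low depth or parental alternate reads).
#' @param depth_mean Mean total depth (reads).
#' @param ab_het_mean Mean allelic balance of heterozygous carriers.
#' @param ab_denovo_range Optional length-2 numeric: draw planted de novo
#'   proband allelic balance uniformly inside this interval instead of
#'   around `ab_het_mean` (used to probe the mode-dependent 0.1/0.25
#'   thresholds).
#' @param gq_pass_prob Probability that a background genotype gets a high
#'   (99) rather than low (30) genotype quality.
#' @param cadd_pass_prob Mixture weight of the deleterious CADD component
#'   (scores above 20) for background variants.
#' @param af_zero_prob Probability a background variant is absent from both
#'   reference panels (frequency 0); otherwise frequencies are drawn from a
#'   rare tail spanning the 0.1% cutoff.
#' @param af_rare_max Upper end of the rare-frequency tail.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_case_trios = 10, n_control_trios = 10,
                              seed = 1,
                              p_panel_pathogenic_case = 0.5,
                              p_panel_pathogenic_control = 0.1,
                              n_background_variants_per_trio = 20,
                              denovo_rate_per_trio = 1,
                              nontransmitted_rate = 1,
                              artifact_rate_per_trio = 0.5,
                              depth_mean = 60, ab_het_mean = 0.5,
                              ab_denovo_range = NULL,
                              gq_pass_prob = 0.95, cadd_pass_prob = 0.7,
                              af_zero_prob = 0.6, af_rare_max = 0.005) {
  cfg <- as.list(environment())
  probs <- c(p_panel_pathogenic_case, p_panel_pathogenic_control,
             gq_pass_prob, cadd_pass_prob, af_zero_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_case_trios < 1 || n_control_trios < 1) stop("need at least one trio per group")
  if (!is.null(ab_denovo_range) &&
      (length(ab_denovo_range) != 2 || ab_denovo_range[1] >= ab_denovo_range[2]))
    stop("ab_denovo_range must be an increasing length-2 numeric")
  class(cfg) <- "simulation_config"
  cfg
}

sim_gene_universe <- function() {
  list(epilepsy = c("CASK", "MAGI2", "PRRT2", "RBFOX3", "KCNT1", "CPA6",
                    sprintf("EPI%04d", 7:200)),
       cad = c("LDLR", "APOB", "PCSK9", sprintf("CAD%03d", 4:89)),
       background = sprintf("BG%04d", 1:400))
}

# deterministic gene -> locus registry; per-gene variant offsets handed out
# sequentially so every simulated variant key is unique
make_locus_registry <- function(genes) {
  env <- new.env(parent = emptyenv())
  env$chrom <- setNames(as.character(1 + (seq_along(genes) - 1) %% 22), genes)
  env$base <- setNames(1e6 * (1 + (seq_along(genes) - 1) %/% 22), genes)
  env$count <- setNames(integer(length(genes)), genes)
  env
}

next_position <- function(reg, gene) {
  reg$count[gene] <- reg$count[gene] + 1L
  list(chrom = unname(reg$chrom[gene]),
       pos = unname(reg$base[gene] + reg$count[gene] * 37))
}

geno_spec <- function(gt, dp, alt, gq) list(gt = gt, dp = dp, alt = alt, gq = gq)

hom_ref_spec <- function(depth_mean, gq = 99) {
  dp <- max(10, stats::rpois(1, depth_mean))
  geno_spec("0/0", dp, 0, gq)
}

het_spec <- function(depth_mean, ab, gq = 99, min_dp = 10) {
  dp <- max(min_dp, stats::rpois(1, depth_mean))
  alt <- min(dp, max(1, stats::rbinom(1, dp, ab)))
  geno_spec("0/1", dp, alt, gq)
}

# het genotype guaranteed to clear the de novo evidence bar (dp >= 10,
# alt >= 3, ab > 0.25)
qualifying_het_spec <- function(depth_mean, ab, gq = 99) {
  dp <- max(12, stats::rpois(1, depth_mean))
  alt <- stats::rbinom(1, dp, ab)
  alt <- min(dp, max(alt, max(3, floor(0.25 * dp) + 1)))
  geno_spec("0/1", dp, alt, gq)
}

# het genotype with allelic balance strictly inside (lo, hi]
ranged_ab_het_spec <- function(lo, hi, gq = 99) {
  dp <- 40 + 4 * stats::rpois(1, 5)
  ab <- stats::runif(1, lo, hi)
  alt <- max(3, min(floor(hi * dp), max(floor(lo * dp) + 1, round(ab * dp))))
  geno_spec("0/1", dp, alt, gq)
}

sim_background_annotation <- function(cfg) {
  type <- sample(c("missense", "nonsense", "frameshift", "synonymous",
                   "splice", "inframe_indel"), 1,
                 prob = c(0.4, 0.08, 0.07, 0.3, 0.1, 0.05))
  splice_dist <- if (type == "splice") sample(0:6, 1) else
    if (type == "synonymous") sample(c(1:4, 50, 200), 1) else
      if (type == "inframe_indel") 200 else 0
  cadd <- if (stats::runif(1) < cfg$cadd_pass_prob)
    20.5 + stats::rexp(1, 1 / 8) else stats::runif(1, 1, 20)
  af1 <- if (stats::runif(1) < cfg$af_zero_prob) 0 else
    stats::runif(1, 0, cfg$af_rare_max)
  af2 <- if (stats::runif(1) < cfg$af_zero_prob) 0 else
    stats::runif(1, 0, cfg$af_rare_max)
  list(type = type, splice_dist = splice_dist,
       cadd = round(cadd, 1), af1 = signif(af1, 3), af2 = signif(af2, 3))
}

site_should_pass <- function(type, splice_dist, af1, af2, cadd, cfg_thresholds) {
  t <- cfg_thresholds
  functional <- type %in% FUNCTIONAL_TYPES | splice_dist <= t$splice_window_bp
  functional && max(af1, af2) < t$max_pop_freq && cadd > t$min_cadd
}

# alleles are emitted already left-aligned/minimal so the VCF key equals the
# normalized key used throughout the pipeline
sim_alleles <- function(type) {
  if (type == "frameshift") list(ref = "GAT", alt = "G")
  else if (type == "inframe_indel") list(ref = "CTTT", alt = "C")
  else list(ref = "G", alt = "A")
}

#' Simulate a complete synthetic trio cohort
#'
#' Writes every input the pipeline consumes — multi-sample VCF (GT:DP:AD:GQ),
#' PED, annotation TSV, epilepsy and CAD panel files, a synthetic
#' gene-to-KEGG-orthology mapping — plus a truth table recording, for every
#' emitted variant, the planted inheritance class, curated class, panel
#' membership and whether it was planted to survive the site filter and
#' (per analysis mode) the de novo evidence thresholds.
#'
#' Planted genotypes are Mendelian-consistent except at de novo sites, where
#' both parents are written homozygous reference with zero alternate reads
#' and GQ >= 50. Per-proband panel-pathogenic exposure is drawn Bernoulli
#' with the group-specific probability, planting a qualifying transmitted
#' pathogenic variant in an epilepsy-panel gene. All randomness flows from
#' `config$seed`; the same configuration yields byte-identical files.
#'
#' @param config A `simulation_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with file `paths`, the `truth` variant table,
#'   the `trios` truth table and the seed used.
#' @export
simulate_cohort <- function(config = simulation_config(), dir) {
  stopifnot(inherits(config, "simulation_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(config$seed)
  genes <- sim_gene_universe()
  if (config$nontransmitted_rate > 0 || config$p_panel_pathogenic_case > 0) {
    if (length(genes$epilepsy) < 1) stop("infeasible config: no panel genes")
  }
  reg <- make_locus_registry(c(genes$epilepsy, genes$cad, genes$background))

  n_trios <- config$n_case_trios + config$n_control_trios
  fam <- sprintf("F%03d", seq_len(n_trios))
  group <- c(rep("epilepsy", config$n_case_trios),
             rep("no_epilepsy", config$n_control_trios))
  proband <- sprintf("P%03d", seq_len(n_trios))
  father <- sprintf("D%03d", seq_len(n_trios))
  mother <- sprintf("M%03d", seq_len(n_trios))
  sex <- sample(1:2, n_trios, replace = TRUE)

  variants <- list()
  truth <- list()
  exposure_truth <- logical(n_trios)
  thresholds <- filter_thresholds()

  add_variant <- function(gene, panel, family_idx, type, splice_dist, af1, af2,
                          cadd, curated, planted_class, pro, mom, dad,
                          dn_exome = NA, dn_targeted = NA) {
    loc <- next_position(reg, gene)
    al <- sim_alleles(type)
    i <- length(variants) + 1
    variants[[i]] <<- list(
      chrom = loc$chrom, pos = loc$pos, ref = al$ref, alt = al$alt,
      gene = gene, type = type, splice_dist = splice_dist, af1 = af1,
      af2 = af2, cadd = cadd, curated = curated, family_idx = family_idx,
      pro = pro, mom = mom, dad = dad)
    truth[[i]] <<- data.frame(
      variant_key = variant_key(loc$chrom, loc$pos, al$ref, al$alt),
      family_id = fam[family_idx], gene = gene, panel = panel,
      planted_class = planted_class, planted_curated_class = curated,
      should_pass_site = site_should_pass(type, splice_dist, af1, af2, cadd,
                                          thresholds),
      denovo_evidence_exome = dn_exome,
      denovo_evidence_targeted = dn_targeted,
      stringsAsFactors = FALSE)
  }

  for (ti in seq_len(n_trios)) {
    p_exp <- if (group[ti] == "epilepsy") config$p_panel_pathogenic_case else
      config$p_panel_pathogenic_control
    exposure_truth[ti] <- stats::runif(1) < p_exp
    if (exposure_truth[ti]) {
      gene <- sample(genes$epilepsy, 1)
      from_mother <- stats::runif(1) < 0.5
      par_spec <- het_spec(config$depth_mean, config$ab_het_mean)
      add_variant(gene, "epilepsy", ti, "missense", 0, 0, 0,
                  round(22 + stats::rexp(1, 1 / 8), 1),
                  sample(c("pathogenic", "likely_pathogenic"), 1),
                  if (from_mother) "transmitted_maternal" else "transmitted_paternal",
                  pro = qualifying_het_spec(config$depth_mean, config$ab_het_mean),
                  mom = if (from_mother) par_spec else hom_ref_spec(config$depth_mean),
                  dad = if (from_mother) hom_ref_spec(config$depth_mean) else par_spec)
    }

    n_dn <- stats::rpois(1, config$denovo_rate_per_trio)
    for (k in seq_len(n_dn)) {
      gene <- sample(genes$background, 1)
      pro <- if (is.null(config$ab_denovo_range))
        qualifying_het_spec(config$depth_mean, config$ab_het_mean) else
          ranged_ab_het_spec(config$ab_denovo_range[1], config$ab_denovo_range[2])
      ab <- pro$alt / pro$dp
      add_variant(gene, "none", ti, "missense", 0, 0, 0,
                  round(22 + stats::rexp(1, 1 / 8), 1),
                  sample(c("pathogenic", "likely_pathogenic", "VUS"), 1),
                  "de_novo", pro = pro,
                  mom = hom_ref_spec(config$depth_mean),
                  dad = hom_ref_spec(config$depth_mean),
                  dn_exome = ab > thresholds$min_ab_exome,
                  dn_targeted = ab > thresholds$min_ab_targeted)
    }

    n_nt <- stats::rpois(1, config$nontransmitted_rate)
    for (k in seq_len(n_nt)) {
      gene <- sample(genes$epilepsy, 1)
      from_mother <- stats::runif(1) < 0.5
      par_spec <- het_spec(config$depth_mean, config$ab_het_mean)
      add_variant(gene, "epilepsy", ti, "missense", 0, 0, 0,
                  round(22 + stats::rexp(1, 1 / 8), 1),
                  sample(c("pathogenic", "likely_pathogenic", "benign"), 1),
                  if (from_mother) "non_transmitted_maternal" else "non_transmitted_paternal",
                  pro = hom_ref_spec(config$depth_mean),
                  mom = if (from_mother) par_spec else hom_ref_spec(config$depth_mean),
                  dad = if (from_mother) hom_ref_spec(config$depth_mean) else par_spec)
    }

    n_art <- stats::rpois(1, config$artifact_rate_per_trio)
    for (k in seq_len(n_art)) {
      gene <- sample(genes$background, 1)
      flavour <- sample(c("low_dp", "parent_alt"), 1)
      pro <- if (flavour == "low_dp") geno_spec("0/1", 6, 2, 80) else
        qualifying_het_spec(config$depth_mean, config$ab_het_mean)
      mom <- hom_ref_spec(config$depth_mean)
      if (flavour == "parent_alt") mom$alt <- 2
      add_variant(gene, "none", ti, "missense", 0, 0, 0,
                  round(22 + stats::rexp(1, 1 / 8), 1), "VUS", "artifact",
                  pro = pro, mom = mom, dad = hom_ref_spec(config$depth_mean),
                  dn_exome = FALSE, dn_targeted = FALSE)
    }

    for (k in seq_len(config$n_background_variants_per_trio)) {
      gene <- sample(genes$background, 1)
      ann <- sim_background_annotation(config)
      from_mother <- stats::runif(1) < 0.5
      transmitted <- stats::runif(1) < 0.5
      gq_bg <- function() if (stats::runif(1) < config$gq_pass_prob) 99 else 30
      par_spec <- het_spec(config$depth_mean, config$ab_het_mean, gq = gq_bg())
      pro <- if (transmitted)
        het_spec(config$depth_mean, config$ab_het_mean, gq = gq_bg()) else
          hom_ref_spec(config$depth_mean, gq = gq_bg())
      side <- if (from_mother) "maternal" else "paternal"
      add_variant(gene, "none", ti, ann$type, ann$splice_dist, ann$af1,
                  ann$af2, ann$cadd, "none",
                  paste0(if (transmitted) "transmitted_" else "non_transmitted_",
                         side),
                  pro = pro,
                  mom = if (from_mother) par_spec else hom_ref_spec(config$depth_mean, gq = gq_bg()),
                  dad = if (from_mother) hom_ref_spec(config$depth_mean, gq = gq_bg()) else par_spec)
    }
  }

  truth_df <- do.call(rbind, truth)
  paths <- write_sim_outputs(dir, variants, truth_df, fam, proband, father,
                             mother, sex, group, exposure_truth, genes, config)
  invisible(list(paths = paths, truth = truth_df,
                 trios = utils::read.delim(paths$truth_trios,
                                           stringsAsFactors = FALSE),
                 seed = config$seed))
}

format_sample_field <- function(spec) {
  paste(spec$gt, spec$dp, paste(spec$dp - spec$alt, spec$alt, sep = ","),
        spec$gq, sep = ":")
}

write_sim_outputs <- function(dir, variants, truth_df, fam, proband, father,
                              mother, sex, group, exposure_truth, genes,
                              config) {
  n_trios <- length(fam)
  samples <- as.vector(rbind(proband, father, mother))
  ord <- order(chrom_rank(vapply(variants, `[[`, character(1), "chrom")),
               vapply(variants, `[[`, numeric(1), "pos"))
  variants <- variants[ord]

  depth_bg <- max(10, round(config$depth_mean))
  body <- vapply(variants, function(v) {
    fields <- rep(paste0("0/0:", depth_bg, ":", depth_bg, ",0:99"),
                  length(samples))
    names(fields) <- samples
    ti <- v$family_idx
    fields[proband[ti]] <- format_sample_field(v$pro)
    fields[father[ti]] <- format_sample_field(v$dad)
    fields[mother[ti]] <- format_sample_field(v$mom)
    paste(c(v$chrom, format(v$pos, scientific = FALSE), ".", v$ref, v$alt,
            ".", "PASS", ".", "GT:DP:AD:GQ", fields), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=trioburden simulate_cohort seed=", config$seed),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  vcf_path <- file.path(dir, "cohort.vcf")
  writeLines(c(header, body), vcf_path)

  ped_path <- file.path(dir, "cohort.ped")
  ped <- c(vapply(seq_len(n_trios), function(i) {
    paste(c(paste(fam[i], father[i], "0 0 1 1"),
            paste(fam[i], mother[i], "0 0 2 1"),
            paste(fam[i], proband[i], father[i], mother[i], sex[i],
                  if (group[i] == "epilepsy") 2 else 1)), collapse = "\n")
  }, character(1)))
  writeLines(ped, ped_path)

  ann_path <- file.path(dir, "annotations.tsv")
  ann <- do.call(rbind, lapply(variants, function(v) data.frame(
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt, gene = v$gene,
    variant_type = v$type, splice_distance_bp = v$splice_dist,
    af_1kg = v$af1, af_evs = v$af2, cadd_phred = v$cadd,
    polyphen_humdiv = NA_real_, polyphen_humvar = NA_real_,
    curated_class = v$curated, stringsAsFactors = FALSE)))
  utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  panel_epi_path <- file.path(dir, "panel_epilepsy.txt")
  writeLines(c("# synthetic epilepsy gene panel", genes$epilepsy),
             panel_epi_path)
  panel_cad_path <- file.path(dir, "panel_cad.txt")
  writeLines(c("# synthetic CAD gene panel", genes$cad), panel_cad_path)

  ko_path <- file.path(dir, "ko_mapping.tsv")
  utils::write.table(synthetic_ko_mapping(c(genes$epilepsy, genes$cad,
                                            genes$background)),
                     ko_path, sep = "\t", quote = FALSE, row.names = FALSE)

  truth_path <- file.path(dir, "truth_variants.tsv")
  utils::write.table(truth_df[order(match(truth_df$variant_key,
                                          vapply(variants, function(v)
                                            variant_key(v$chrom, v$pos, v$ref, v$alt),
                                            character(1)))), ],
                     truth_path, sep = "\t", quote = FALSE, row.names = FALSE)

  trios_path <- file.path(dir, "truth_trios.tsv")
  utils::write.table(data.frame(family_id = fam, group = group,
                                exposure_truth = exposure_truth,
                                stringsAsFactors = FALSE),
                     trios_path, sep = "\t", quote = FALSE, row.names = FALSE)

  list(vcf = vcf_path, ped = ped_path, annotations = ann_path,
       panel_epilepsy = panel_epi_path, panel_cad = panel_cad_path,
       ko_mapping = ko_path, truth_variants = truth_path,
       truth_trios = trios_path)
}

#' Synthetic gene-to-KEGG-orthology mapping
#'
#' Deterministically assigns each gene one or two categories from a small
#' fixed catalogue spanning retained branches (metabolism, genetic
#' information processing, signal transduction, cell growth and death,
#' nervous system) and excluded ones (human disease 09160 and its children,
#' immune system 09151 under organismal systems 09150), so exclusion logic
#' is exercised. Purely synthetic: it is a stand-in mapping for tests and
#' simulations, not a KEGG snapshot.
#'
#' @param genes Character vector of gene symbols.
#' @return Data frame with columns `gene`, `category_code`, `category_name`,
#'   `parent_code`.
#' @export
synthetic_ko_mapping <- function(genes) {
  catalogue <- data.frame(
    category_code = c("09101", "09121", "09122", "09123", "09132", "09141",
                      "09143", "09156", "09151", "09161"),
    category_name = c("Carbohydrate metabolism", "Transcription",
                      "Translation", "Folding, sorting and degradation",
                      "Signal transduction", "Transport and catabolism",
                      "Cell growth and death", "Nervous system",
                      "Immune system", "Cancer: overview"),
    parent_code = c("09100", "09120", "09120", "09120", "09130", "09140",
                    "09140", "09150", "09150", "09160"),
    stringsAsFactors = FALSE)
  rows <- lapply(seq_along(genes), function(i) {
    # stable hash of the symbol so the mapping is reproducible without RNG
    h <- sum(utf8ToInt(genes[i]) * seq_along(utf8ToInt(genes[i])))
    idx <- 1 + (h %% nrow(catalogue))
    second <- 1 + ((h %/% 7) %% nrow(catalogue))
    take <- unique(c(idx, if (h %% 3 == 0) second))
    data.frame(gene = toupper(genes[i]),
               category_code = catalogue$category_code[take],
               category_name = catalogue$category_name[take],
               parent_code = catalogue$parent_code[take],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Draw a single case-control exposure table from the simulator's model
#'
#' The exposure sub-model of [simulate_cohort()] in isolation: each case
#' proband is exposed with probability `p_case`, each control with `p_control`.
#' Useful for studying the sampling behaviour of the burden statistics at
#' arbitrary cohort sizes without generating genotype data.
#'
#' @param n_case,n_control Probands per group.
#' @param p_case,p_control Exposure probabilities.
#' @param label Table label.
#' @return A `contingency_table`.
#' @export
simulate_exposure_table <- function(n_case, n_control, p_case, p_control,
                                    label = "simulated exposure") {
  a <- stats::rbinom(1, n_case, p_case)
  c_ <- stats::rbinom(1, n_control, p_control)
  contingency_table(a, n_case - a, c_, n_control - c_, label = label)
}

#' Score pipeline recovery of planted simulation truth
#'
#' Compares inheritance calls against the simulator's truth table. For each
#' planted class, recall is computed over planted (variant, family) pairs
#' expected to be recoverable in the given mode — i.e. planted to survive
#' the site filter and, for de novo, with evidence above the mode's
#' thresholds — and precision over the pipeline's calls of that class
#' restricted to planted non-background variants.
#'
#' @param truth Truth data frame from [simulate_cohort()].
#' @param calls `inheritance_calls` for proband variants.
#' @param nt_calls Optional `inheritance_calls` from [find_non_transmitted()].
#' @param mode `"exome_wide"` or `"targeted_panel"`; which de novo evidence
#'   flag applies.
#' @return Data frame: `class`, `n_expected`, `n_called`, `recall`,
#'   `precision`.
#' @export
score_recovery <- function(truth, calls, nt_calls = NULL,
                           mode = c("exome_wide", "targeted_panel")) {
  mode <- match.arg(mode)
  ev <- if (mode == "exome_wide") truth$denovo_evidence_exome else
    truth$denovo_evidence_targeted
  pair <- function(df) paste(df$variant_key, df$family_id)
  all_calls <- rbind(calls[, c("variant_key", "family_id", "call")],
                     if (!is.null(nt_calls))
                       nt_calls[, c("variant_key", "family_id", "call")])
  classes <- c("de_novo", "transmitted_maternal", "transmitted_paternal",
               "non_transmitted_maternal", "non_transmitted_paternal")
  rows <- lapply(classes, function(cls) {
    expected <- truth$planted_class == cls & truth$should_pass_site
    if (cls == "de_novo") expected <- expected & !is.na(ev) & ev
    exp_pairs <- pair(truth[expected, , drop = FALSE])
    called <- all_calls[all_calls$call == cls, , drop = FALSE]
    called_pairs <- pair(called)
    tp <- sum(exp_pairs %in% called_pairs)
    data.frame(class = cls, n_expected = length(exp_pairs),
               n_called = length(called_pairs),
               recall = if (length(exp_pairs) > 0) tp / length(exp_pairs) else NA_real_,
               precision = if (length(called_pairs) > 0) {
                 planted_pairs <- pair(truth[truth$planted_class == cls, ,
                                             drop = FALSE])
                 sum(called_pairs %in% planted_pairs) / length(called_pairs)
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
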