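#' Assemble the full cohort analysis report
#'
#' Runs the whole pipeline on one cohort: reads pedigree, VCF and
#' annotations; applies the variant filters; classifies exome-wide
#' inheritance and selects de novo pathogenic / likely-pathogenic / VUS
#' variants; runs each targeted panel analysis (burden and non-transmitted
#' tables with exact-CI odds ratios); categorizes de novo genes by KEGG
#' orthology; and writes a JSON report plus TSV artifacts.
#'
#' @param vcf,ped,annotations Input file paths.
#' @param panels Named list of gene-panel file paths (names become panel
#'   names).
#' @param ko_mapping Optional KO mapping TSV path.
#' @param thresholds A `filter_thresholds` object.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @return List of class `cohort_report`.
#' @export
run_cohort_report <- function(vcf, ped, annotations, panels = list(),
                              ko_mapping = NULL,
                              thresholds = filter_thresholds(),
                              out_dir = NULL) {
  pedigree <- read_pedigree(ped)
  ann <- read_annotations(annotations)
  cohort <- read_trio_vcf(vcf, pedigree, ann)
  filtered <- apply_filters(cohort, thresholds)
  exome_calls <- classify_inheritance(cohort, "exome_wide", thresholds,
                                      variant_keys = filtered$survivors$variant_key)
  dn <- select_exome_wide_de_novo(cohort, exome_calls)
  dn_exposure <- build_exposure_table(
    pedigree, dn, function(df) nrow(df) > 0,
    label = "exome-wide: >=1 de novo pathogenic/likely pathogenic/VUS variant")

  panel_results <- lapply(names(panels), function(nm) {
    run_panel_analysis(cohort, load_panel(panels[[nm]], nm), thresholds)
  })
  names(panel_results) <- names(panels)

  enrichment <- if (!is.null(ko_mapping))
    categorize_ko(dn, read_ko_mapping(ko_mapping)) else NULL

  report <- structure(list(
    cohort = list(
      n_trios = nrow(pedigree),
      n_epilepsy = sum(pedigree$proband_affected == "epilepsy"),
      n_no_epilepsy = sum(pedigree$proband_affected == "no_epilepsy"),
      n_variants = nrow(cohort$variants),
      n_filter_survivors = nrow(filtered$survivors)),
    panels = panel_results,
    de_novo = list(
      variants = dn,
      n_variants = nrow(dn),
      n_probands_epilepsy = length(unique(dn$family_id[dn$group == "epilepsy"])),
      n_probands_no_epilepsy = length(unique(dn$family_id[dn$group == "no_epilepsy"])),
      exposure_table = dn_exposure,
      burden = burden_result(dn_exposure)),
    enrichment = enrichment,
    provenance = list(
      tool = paste0("trioburden ",
                    as.character(utils::packageVersion("trioburden"))),
      thresholds = unclass(thresholds),
      inputs = list(vcf = vcf, ped = ped, annotations = annotations,
                    panels = panels, ko_mapping = ko_mapping))),
    class = "cohort_report")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_decision_log(filtered$log, file.path(out_dir, "filter_log.tsv"))
    write_calls(exome_calls, file.path(out_dir, "exome_calls.tsv"))
    if (!is.null(enrichment))
      write_enrichment(enrichment, file.path(out_dir, "ko_enrichment.tsv"))
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         na = "null")
  }
  report
}

burden_to_json <- function(b) {
  list(table = list(a = b$table$a, b = b$table$b, c = b$table$c,
                    d = b$table$d, label = b$table$label),
       odds_ratio = b$odds_ratio, ci_low = b$ci_low, ci_high = b$ci_high,
       ci_level = b$ci_level, chi2_stat = b$chi2_stat, chi2_p = b$chi2_p,
       fisher_p = b$fisher_p, method_notes = b$method_notes)
}

report_to_json <- function(report) {
  list(
    cohort = report$cohort,
    panels = lapply(report$panels, function(p) list(
      panel = p$panel$name, n_panel_genes = length(p$panel$genes),
      n_qualifying_variants = nrow(p$qualifying),
      qualifying = p$qualifying[, c("variant_key", "family_id", "gene",
                                    "call", "curated_class")],
      burden = burden_to_json(p$burden),
      non_transmitted_burden = burden_to_json(p$non_transmitted_burden))),
    de_novo = list(
      n_variants = report$de_novo$n_variants,
      n_probands_epilepsy = report$de_novo$n_probands_epilepsy,
      n_probands_no_epilepsy = report$de_novo$n_probands_no_epilepsy,
      burden = burden_to_json(report$de_novo$burden)),
    enrichment = if (!is.null(report$enrichment))
      list(table = report$enrichment$table,
           unmapped = report$enrichment$unmapped,
           counting = report$enrichment$counting),
    provenance = report$provenance)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort:", x$cohort$n_trios, "trios (", x$cohort$n_epilepsy,
      "epilepsy /", x$cohort$n_no_epilepsy, "no epilepsy ),",
      x$cohort$n_variants, "variants,", x$cohort$n_filter_survivors,
      "filter survivors\n")
  for (nm in names(x$panels)) {
    cat("\n== Panel:", nm, "==\n")
    print(x$panels[[nm]]$burden)
  }
  cat("\n== Exome-wide de novo ==\n")
  cat(x$de_novo$n_variants, "de novo P/LP/VUS variants (",
      x$de_novo$n_probands_epilepsy, "epilepsy probands vs",
      x$de_novo$n_probands_no_epilepsy, "no-epilepsy probands )\n")
  print(x$de_novo$burden)
  invisible(x)
}

parse_cli_args <- function(args) {
  flags <- list()
  positional <- character(0)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1], "--"))
        stop("flag --", key, " needs a value")
      val <- args[i + 1]
      if (key == "panel") {
        kv <- strsplit(val, "=", fixed = TRUE)[[1]]
        if (length(kv) != 2) stop("--panel expects NAME=PATH")
        flags$panel <- c(flags$panel, stats::setNames(kv[2], kv[1]))
      } else {
        flags[[key]] <- val
      }
      i <- i + 2
    } else {
      positional <- c(positional, a)
      i <- i + 1
    }
  }
  list(cmd = if (length(positional) > 0) positional[1] else NA_character_,
       flags = flags)
}

#' Command-line entry point
#'
#' Thin driver over the package functions, suitable for
#' `Rscript -e 'trioburden::trioburden_cli()' <subcommand> ...` or the
#' wrapper script shipped under `inst/scripts/`. Subcommands:
#' `simulate` (`--out-dir`, `--seed`), `classify` (`--vcf --ped
#' --annotations --mode --out-dir`), `burden` (adds repeatable `--panel
#' NAME=PATH`), `enrich` (adds `--ko-mapping`), `report` / `all` (full
#' report; `all` first simulates when given `--seed` and no `--vcf`).
#'
#' @param args Character vector of arguments (defaults to the command line).
#' @return Integer exit status, invisibly (0 on success).
#' @export
trioburden_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    p <- parse_cli_args(args)
    if (is.na(p$cmd) ||
        !p$cmd %in% c("simulate", "classify", "burden", "enrich", "report", "all"))
      stop("usage: trioburden {simulate|classify|burden|enrich|report|all} [--flags]")
    f <- p$flags
    out_dir <- if (!is.null(f$`out-dir`)) f$`out-dir` else "."
    thresholds <- if (!is.null(f$config)) read_thresholds_config(f$config) else
      filter_thresholds()

    if (p$cmd == "simulate" || (p$cmd == "all" && is.null(f$vcf))) {
      seed <- if (!is.null(f$seed)) as.integer(f$seed) else 1L
      sim <- simulate_cohort(simulation_config(seed = seed), out_dir)
      message("simulated cohort written to ", out_dir)
      if (p$cmd == "simulate") return(invisible(0L))
      f$vcf <- sim$paths$vcf
      f$ped <- sim$paths$ped
      f$annotations <- sim$paths$annotations
      f$panel <- c(epilepsy = sim$paths$panel_epilepsy,
                   cad = sim$paths$panel_cad)
      f$`ko-mapping` <- sim$paths$ko_mapping
    }
    for (need in c("vcf", "ped", "annotations"))
      if (is.null(f[[need]])) stop("missing required flag --", need)
    for (path in c(f$vcf, f$ped, f$annotations, f$panel, f$`ko-mapping`))
      if (!file.exists(path)) stop("input file not found: ", path)

    if (p$cmd == "classify") {
      pedigree <- read_pedigree(f$ped)
      cohort <- read_trio_vcf(f$vcf, pedigree, read_annotations(f$annotations))
      filtered <- apply_filters(cohort, thresholds)
      mode <- if (!is.null(f$mode)) f$mode else "exome_wide"
      calls <- classify_inheritance(cohort, mode, thresholds,
                                    variant_keys = filtered$survivors$variant_key)
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_decision_log(filtered$log, file.path(out_dir, "filter_log.tsv"))
      write_calls(calls, file.path(out_dir, "calls.tsv"))
      message("wrote ", file.path(out_dir, "calls.tsv"))
    } else {
      panels <- as.list(f$panel)
      report <- run_cohort_report(f$vcf, f$ped, f$annotations, panels,
                                  ko_mapping = f$`ko-mapping`,
                                  thresholds = thresholds, out_dir = out_dir)
      print(report)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
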