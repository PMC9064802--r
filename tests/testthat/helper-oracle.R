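# Independent brute-force inheritance oracle: re-derives the classification
# for every proband-carrier site straight from the VCF text, sharing no code
# with the package internals.

# Random one-trio cohort: 3 sites with genotypes, depths and qualities drawn
# to land on both sides of every classification threshold.
random_trio_cohort_files <- function(dir, n_sites = 3) {
  samples <- c("C1", "D1", "M1")
  gts <- c("0/0", "0/1", "1/1", "./.")
  records <- lapply(seq_len(n_sites), function(i) {
    geno <- lapply(samples, function(s) {
      gt <- sample(gts, 1, prob = c(0.35, 0.35, 0.2, 0.1))
      dp <- sample(5:80, 1)
      alt <- switch(gt,
                    "0/0" = sample(0:2, 1, prob = c(0.7, 0.2, 0.1)),
                    "0/1" = sample(seq(0, dp), 1),
                    "1/1" = dp,
                    "./." = 0)
      gq <- sample(c(20, 45, 49, 50, 51, 99), 1)
      gt_field(gt, dp, alt, gq)
    })
    names(geno) <- samples
    list(chrom = sample(c("1", "2", "X"), 1), pos = 1000 * i, ref = "G",
         alt = "A", geno = geno)
  })
  vcf <- write_test_vcf(file.path(dir, "r.vcf"), samples, records)
  ped <- write_test_ped(file.path(dir, "r.ped"))
  ann <- write_test_annotations(file.path(dir, "r.tsv"), do.call(rbind, lapply(
    records, function(r) data.frame(chrom = r$chrom, pos = r$pos, ref = r$ref,
                                    alt = r$alt, stringsAsFactors = FALSE))))
  list(vcf = vcf, ped = ped, ann = ann)
}

# mode_ab: 0.25 (exome) or 0.1 (targeted)
oracle_classify_vcf <- function(vcf_path, mode_ab) {
  lines <- readLines(vcf_path)
  hdr <- strsplit(lines[startsWith(lines, "#CHROM")], "\t")[[1]]
  body <- lines[!startsWith(lines, "#")]
  calls <- list()
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    names(f) <- hdr
    parse <- function(s) {
      x <- strsplit(f[[s]], ":")[[1]]
      ad <- as.numeric(strsplit(x[3], ",")[[1]])
      list(gt = x[1], dp = as.numeric(x[2]), alt = ad[2], gq = as.numeric(x[4]))
    }
    c_ <- parse("C1"); d_ <- parse("D1"); m_ <- parse("M1")
    carries <- function(g) g$gt %in% c("0/1", "1/1", "1/0", "1")
    if (!carries(c_)) next
    call <- if (m_$gt == "./." || d_$gt == "./.") {
      if (carries(m_) && carries(d_)) "transmitted_biparental"
      else if (carries(m_)) "transmitted_maternal"
      else if (carries(d_)) "transmitted_paternal"
      else "unresolved"
    } else if (carries(m_) && carries(d_)) "transmitted_biparental"
    else if (carries(m_)) "transmitted_maternal"
    else if (carries(d_)) "transmitted_paternal"
    else {
      ok <- c_$dp >= 10 && c_$alt >= 3 && (c_$alt / c_$dp) > mode_ab &&
        m_$gq >= 50 && d_$gq >= 50 && m_$alt == 0 && d_$alt == 0
      if (ok) "de_novo" else "unresolved"
    }
    calls[[length(calls) + 1]] <- data.frame(
      variant_key = paste(f[["#CHROM"]], f[["POS"]], f[["REF"]], f[["ALT"]],
                          sep = ":"),
      call = call, stringsAsFactors = FALSE)
  }
  if (length(calls) == 0)
    return(data.frame(variant_key = character(), call = character()))
  do.call(rbind, calls)
}
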