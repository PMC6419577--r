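#' Read a multi-sample VCF into a genotype matrix
#'
#' Biallelic SNP records are transcribed to 0/1/2 codes; multiallelic
#' records are skipped and counted (attribute `n_multiallelic`, plus a
#' message). Missing calls (`./.` or `.|.`) become `NA`. When every call is
#' phased the haplotypes are preserved and attached as a `hap_matrix`.
#'
#' @param path VCF 4.x file (plain text).
#' @param pass_only keep only records with FILTER PASS/"." (default FALSE).
#' @param genome optional [genome_map()].
#' @return a `geno_matrix`; phased haplotypes (if complete) in `$phased`.
#' @export
read_genotypes <- function(path, pass_only = FALSE, genome = NULL) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("VCF parse error: ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt[, -1, drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  keep <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "." &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  if (pass_only) keep <- keep & fix[, "FILTER"] %in% c("PASS", ".")
  n_multi <- sum(grepl(",", fix[, "ALT"]))
  if (n_multi > 0) message("skipped ", n_multi, " multiallelic record(s)")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  gtf <- sub(":.*", "", gt)
  a1 <- substr(gtf, 1, 1); sep <- substr(gtf, 2, 2); a2 <- substr(gtf, 3, 3)
  geno <- matrix(NA_integer_, nrow(gtf), ncol(gtf))
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  geno[ok] <- as.integer(a1[ok]) + as.integer(a2[ok])
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  phased <- NULL
  if (nrow(gtf) > 0 && all(sep == "|" | !ok)) {
    hap <- matrix(NA_integer_, nrow(gtf), 2 * ncol(gtf))
    hap[, 2 * seq_len(ncol(gtf)) - 1] <- ifelse(ok, as.integer(a1), NA)
    hap[, 2 * seq_len(ncol(gtf))] <- ifelse(ok, as.integer(a2), NA)
    if (!anyNA(hap)) phased <- hap_matrix(hap, sites, samples, genome)
  }
  out <- geno_matrix(geno, sites, samples, genome, phased = phased)
  attr(out, "n_multiallelic") <- n_multi
  out
}

#' Write a genotype matrix as VCF
#'
#' Emits a minimal plain-text VCF 4.2 with GT-only calls. Phased output uses
#' the attached haplotypes when available, falling back to unphased codes.
#'
#' @param gm a `geno_matrix`.
#' @param path output file.
#' @param phased write `0|1`-style calls from `gm$phased` when present.
#' @export
write_genotypes <- function(gm, path, phased = !is.null(gm$phased)) {
  n <- nrow(gm$sites)
  if (phased && !is.null(gm$phased)) {
    h <- gm$phased$hap
    calls <- matrix(paste0(h[, seq(1, ncol(h), 2), drop = FALSE], "|",
                           h[, seq(2, ncol(h), 2), drop = FALSE]),
                    nrow = n)
  } else {
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    calls <- matrix("./.", n, length(gm$samples))
    ok <- !is.na(gm$geno)
    calls[ok] <- code[as.character(gm$geno[ok])]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pedflow",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  body <- paste(gm$sites$chrom, format(gm$sites$pos, scientific = FALSE, trim = TRUE),
                paste0("SNP_", gm$sites$chrom, "_",
                       format(gm$sites$pos, scientific = FALSE, trim = TRUE)),
                gm$sites$ref, gm$sites$alt, ".", "PASS", ".", "GT",
                apply(calls, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Per-site allele statistics
#'
#' @param gm a `geno_matrix`.
#' @return data.frame with per-site non-missing allele count `n`, alternate
#'   allele frequency `p`, minor allele frequency `maf` and missing call
#'   fraction `missing`.
#' @export
site_stats <- function(gm) {
  nm <- rowSums(!is.na(gm$geno))
  alt <- rowSums(gm$geno, na.rm = TRUE)
  p <- ifelse(nm > 0, alt / (2 * nm), NA)
  data.frame(n = 2 * nm, p = p, maf = pmin(p, 1 - p),
             missing = 1 - nm / length(gm$samples))
}

#' Filter sites on minor allele frequency and missingness
#'
#' Retains sites with MAF strictly above `maf_min` (computed from
#' non-missing allele counts) and missing-call fraction strictly below
#' `missing_max`; site order is preserved and the filter is idempotent.
#'
#' @param gm a `geno_matrix`.
#' @param maf_min MAF threshold in \[0, 0.5\] (default 0.05).
#' @param missing_max missingness threshold in \[0, 1\] (default 0.2).
#' @return filtered `geno_matrix` with attribute `n_removed`.
#' @export
filter_sites <- function(gm, maf_min = 0.05, missing_max = 0.2) {
  if (nrow(gm$sites) == 0) stop("empty genotype matrix")
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must lie in [0, 0.5]")
  if (missing_max < 0 || missing_max > 1) stop("missing_max must lie in [0, 1]")
  st <- site_stats(gm)
  keep <- !is.na(st$maf) & (maf_min == 0 | st$maf > maf_min) &
    (missing_max == 1 | st$missing < missing_max)
  keep[is.na(keep)] <- FALSE
  if (maf_min == 0 && missing_max == 1) keep <- rep(TRUE, nrow(gm$sites))
  out <- subset_samples(gm, sites = which(keep))
  attr(out, "n_removed") <- sum(!keep)
  out
}
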