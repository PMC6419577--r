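#' Haplotype matrix
#'
#' Phased haplotypes as a sites x (2 * samples) 0/1 matrix. Columns are
#' paired per sample (`<id>_1`, `<id>_2`); site metadata gives chromosome,
#' position and alleles. Positions are strictly increasing within each
#' chromosome.
#'
#' @param hap integer matrix (sites in rows, haplotypes in columns, values
#'   0/1).
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param samples character vector of sample ids (half the column count).
#' @param genome optional [genome_map()].
#' @return a `hap_matrix` object.
#' @export
hap_matrix <- function(hap, sites, samples, genome = NULL) {
  hap <- as.matrix(hap)
  if (ncol(hap) != 2 * length(samples)) {
    stop("haplotype columns must be twice the sample count")
  }
  if (nrow(hap) != nrow(sites)) stop("site metadata does not match matrix")
  sites$chrom <- norm_chrom(sites$chrom)
  o <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (!identical(o, seq_len(nrow(sites)))) { sites <- sites[o, ]; hap <- hap[o, , drop = FALSE] }
  if (any(stats::ave(sites$pos, sites$chrom, FUN = function(p) c(1, diff(p))) <= 0)) {
    stop("positions must be strictly increasing within chromosome")
  }
  colnames(hap) <- paste(rep(samples, each = 2), 1:2, sep = "_")
  rownames(sites) <- NULL
  structure(list(hap = hap, sites = sites, samples = samples, genome = genome),
            class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat("hap_matrix:", nrow(x$sites), "sites x", length(x$samples),
      "samples (", ncol(x$hap), "haplotypes ) on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Genotype matrix
#'
#' Biallelic genotypes coded 0 (hom ref), 1 (het), 2 (hom alt), `NA`
#' (missing), sites in rows and samples in columns; the substrate of every
#' scan in the package.
#'
#' @param geno integer matrix, sites x samples.
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param samples character sample ids (column order).
#' @param genome optional [genome_map()].
#' @param phased optional `hap_matrix` the codes derive from.
#' @return a `geno_matrix` object.
#' @export
geno_matrix <- function(geno, sites, samples, genome = NULL, phased = NULL) {
  geno <- as.matrix(geno)
  if (ncol(geno) != length(samples)) stop("sample ids do not match columns")
  if (nrow(geno) != nrow(sites)) stop("site metadata does not match matrix")
  if (!all(geno %in% c(0L, 1L, 2L, NA))) stop("genotype codes must be 0/1/2/NA")
  sites$chrom <- norm_chrom(sites$chrom)
  o <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (!identical(o, seq_len(nrow(sites)))) { sites <- sites[o, ]; geno <- geno[o, , drop = FALSE] }
  colnames(geno) <- samples
  rownames(sites) <- NULL
  structure(list(geno = geno, sites = sites, samples = samples,
                 genome = genome, phased = phased), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$sites), "sites x", length(x$samples),
      "samples on", length(unique(x$sites$chrom)), "chromosome(s);",
      format(100 * mean(is.na(x$geno)), digits = 3), "% missing\n")
  invisible(x)
}

#' Collapse phased haplotypes to genotype codes
#'
#' Optionally layers on per-call genotyping error (a wrong code drawn
#' uniformly from the two alternatives) and missingness, both i.i.d. per
#' site x sample, to emulate imperfect variant calls.
#'
#' @param hm a `hap_matrix`.
#' @param error_rate per-call error probability.
#' @param missing_rate per-call missing probability.
#' @return a `geno_matrix` (with `phased` back-reference when error-free).
#' @export
hap_to_geno <- function(hm, error_rate = 0, missing_rate = 0) {
  stopifnot(inherits(hm, "hap_matrix"))
  n <- length(hm$samples)
  g <- hm$hap[, 2 * seq_len(n) - 1, drop = FALSE] +
    hm$hap[, 2 * seq_len(n), drop = FALSE]
  if (error_rate > 0) {
    err <- which(stats::runif(length(g)) < error_rate)
    if (length(err)) {
      shift <- sample(1:2, length(err), replace = TRUE)
      g[err] <- (g[err] + shift) %% 3L
    }
  }
  if (missing_rate > 0) g[stats::runif(length(g)) < missing_rate] <- NA
  geno_matrix(g, hm$sites, hm$samples, hm$genome,
              phased = if (error_rate == 0) hm else NULL)
}

#' Subset a genotype or haplotype matrix
#'
#' @param x a `geno_matrix` or `hap_matrix`.
#' @param samples sample ids to keep (default all).
#' @param sites logical or integer site index (default all).
#' @return object of the same class.
#' @export
subset_samples <- function(x, samples = NULL, sites = NULL) {
  if (is.null(samples)) samples <- x$samples
  miss <- setdiff(samples, x$samples)
  if (length(miss)) stop("unknown sample: ", miss[1])
  if (is.null(sites)) sites <- seq_len(nrow(x$sites))
  if (inherits(x, "geno_matrix")) {
    geno_matrix(x$geno[sites, samples, drop = FALSE],
                x$sites[sites, , drop = FALSE], samples, x$genome)
  } else if (inherits(x, "hap_matrix")) {
    cols <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))
    hap_matrix(x$hap[sites, cols, drop = FALSE],
               x$sites[sites, , drop = FALSE], samples, x$genome)
  } else stop("unsupported class")
}

# internal: site index vector for one chromosome, in position order
sites_on <- function(x, chrom) which(x$sites$chrom == norm_chrom(chrom))
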