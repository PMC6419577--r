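#' Sliding-window grid over a genome
#'
#' Windows are anchored at position 1 on every chromosome and advance by
#' `step`; the terminal windows are clipped at the chromosome end and their
#' statistics are normalised by the actual covered bp.
#'
#' @param genome a [genome_map()].
#' @param window,step window and step size in bp (`window >= step > 0`).
#' @return interval data.frame with a `bp` column of true covered width.
#' @export
window_grid <- function(genome, window, step = window) {
  if (!(window >= step && step > 0)) stop("need window >= step > 0")
  out <- do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    L <- genome$length[i]
    s <- seq(1, L, by = step)
    e <- pmin(s + window - 1, L)
    data.frame(chrom = genome$chrom[i], start = s, end = e,
               stringsAsFactors = FALSE)
  }))
  out$bp <- out$end - out$start + 1
  out
}

# internal: per-window sums of a per-site quantity, via cumulative sums
window_sums <- function(sites, value, grid) {
  out <- numeric(nrow(grid)); cnt <- integer(nrow(grid))
  for (ch in unique(grid$chrom)) {
    gi <- which(grid$chrom == ch)
    si <- which(sites$chrom == ch)
    pos <- sites$pos[si]
    cs <- c(0, cumsum(value[si]))
    lo <- findInterval(grid$start[gi] - 1, pos)   # sites strictly before start
    hi <- findInterval(grid$end[gi], pos)         # sites up to end
    out[gi] <- cs[hi + 1] - cs[lo + 1]
    cnt[gi] <- hi - lo
  }
  list(sum = out, n = cnt)
}

#' Windowed SNP density scan
#'
#' Counts sites polymorphic within the panel per window and divides by the
#' true window width, i.e. segregating sites per bp.
#'
#' @param gm a `geno_matrix`.
#' @param genome a [genome_map()] (default `gm$genome`).
#' @param window,step window/step in bp (default 100 kb non-overlapping).
#' @return data.frame `chrom`, `start`, `end`, `bp`, `n_snps`, `value`.
#' @export
snp_density_scan <- function(gm, genome = gm$genome, window = 1e5,
                             step = window) {
  grid <- window_grid(genome, window, step)
  st <- site_stats(gm)
  poly <- as.numeric(!is.na(st$p) & st$p > 0 & st$p < 1)
  ws <- window_sums(gm$sites, poly, grid)
  grid$n_snps <- ws$sum
  grid$value <- ws$sum / grid$bp
  grid
}

#' Zero-diversity segments
#'
#' Maximal runs of consecutive zero-polymorphism bins, merged into segments
#' of at least `min_len` bp. Input bins must be non-overlapping (e.g.
#' [snp_density_scan()] with `step = window`).
#'
#' @param density data.frame from [snp_density_scan()].
#' @param min_len minimum reported segment length in bp (default 100 kb).
#' @return interval data.frame of segments, with per-sub-genome total bp in
#'   attribute `subgenome_bp` when chromosome names carry a letter prefix.
#' @export
zero_diversity_segments <- function(density, min_len = 1e5) {
  o <- order(density$chrom, density$start)
  density <- density[o, ]
  by_chr <- split(density, density$chrom)
  for (d in by_chr) {
    if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)])) {
      stop("density bins overlap; use non-overlapping bins")
    }
  }
  zero <- density[density$n_snps == 0, c("chrom", "start", "end")]
  if (nrow(zero) == 0) {
    return(intervals(character(), numeric(), numeric()))
  }
  seg <- merge_intervals(zero, max_gap = 0)
  seg <- seg[seg$end - seg$start + 1 >= min_len, , drop = FALSE]
  rownames(seg) <- NULL
  sub <- sub("^([A-Za-z]+).*$", "\\1", seg$chrom)
  attr(seg, "subgenome_bp") <- tapply(seg$end - seg$start + 1, sub, sum)
  seg
}

# internal: per-site nucleotide diversity from allele counts
per_site_pi <- function(x, samples = NULL) {
  if (inherits(x, "hap_matrix")) {
    h <- x$hap
    if (!is.null(samples)) {
      h <- h[, as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2"))),
             drop = FALSE]
    }
    n <- rowSums(!is.na(h)); alt <- rowSums(h, na.rm = TRUE)
  } else {
    g <- x$geno
    if (!is.null(samples)) g <- g[, samples, drop = FALSE]
    n <- 2 * rowSums(!is.na(g)); alt <- rowSums(g, na.rm = TRUE)
  }
  pi <- numeric(length(n))
  ok <- n >= 2
  pi[ok] <- (n[ok] - alt[ok]) * alt[ok] / (n[ok] * (n[ok] - 1) / 2)
  list(pi = pi, used = ok)
}

#' Windowed nucleotide diversity (pi) scan
#'
#' Per site, pi is the pairwise-difference probability
#' `c_ref * c_alt / choose(n, 2)` over the `n` non-missing allele calls;
#' the window value is the per-site sum divided by the true window width
#' (pi per bp). Accepts genotypes or phased haplotypes.
#'
#' @param x a `geno_matrix` or `hap_matrix`.
#' @param genome a [genome_map()] (default from `x`).
#' @param window,step bp (defaults 100 kb sliding 20 kb).
#' @param samples optional sample subset defining the group.
#' @return data.frame `chrom`, `start`, `end`, `bp`, `n_snps`, `value`, with
#'   the mean window value as attribute `mean_value`.
#' @export
pi_scan <- function(x, genome = x$genome, window = 1e5, step = 2e4,
                    samples = NULL) {
  grid <- window_grid(genome, window, step)
  ps <- per_site_pi(x, samples)
  ws <- window_sums(x$sites, ps$pi, grid)
  grid$n_snps <- window_sums(x$sites, as.numeric(ps$used), grid)$sum
  grid$value <- ws$sum / grid$bp
  attr(grid, "mean_value") <- mean(grid$value, na.rm = TRUE)
  grid
}

#' Windowed Weir-Cockerham Fst scan
#'
#' Per-site variance components a (between populations), b (between
#' individuals within populations) and c (within individuals) under the
#' two-population Weir-Cockerham estimator; the window value is the
#' ratio of sums `sum(a) / sum(a + b + c)`. Sites where either group has no
#' non-missing calls are skipped; windows with no usable sites (or an
#' entirely missing group) are flagged `NA`.
#'
#' @param gm a `geno_matrix`.
#' @param group_a,group_b character vectors of sample ids (>= 2 each).
#' @param genome a [genome_map()].
#' @param window,step bp (defaults 100 kb sliding 20 kb).
#' @return data.frame `chrom`, `start`, `end`, `bp`, `n_snps`, `value`.
#' @export
fst_scan <- function(gm, group_a, group_b, genome = gm$genome,
                     window = 1e5, step = 2e4) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("both groups need >= 2 samples")
  }
  comp <- fst_site_components(gm, group_a, group_b)
  grid <- window_grid(genome, window, step)
  ok <- as.numeric(comp$defined)
  sa <- window_sums(gm$sites, ifelse(comp$defined, comp$a, 0), grid)
  sd_ <- window_sums(gm$sites, ifelse(comp$defined, comp$a + comp$b + comp$c, 0),
                     grid)
  nok <- window_sums(gm$sites, ok, grid)$sum
  grid$n_snps <- nok
  grid$value <- ifelse(nok > 0 & sd_$sum > 0, sa$sum / sd_$sum, NA)
  grid
}

#' @rdname fst_scan
#' @return `fst_site_components`: data.frame of per-site `a`, `b`, `c` and a
#'   `defined` flag (exposed for verification).
#' @export
fst_site_components <- function(gm, group_a, group_b) {
  ga <- gm$geno[, group_a, drop = FALSE]
  gb <- gm$geno[, group_b, drop = FALSE]
  n1 <- rowSums(!is.na(ga)); n2 <- rowSums(!is.na(gb))
  p1 <- rowSums(ga, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(gb, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(ga == 1, na.rm = TRUE) / n1
  h2 <- rowSums(gb == 1, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  defined <- n1 > 0 & n2 > 0 & nbar > 1 & nc > 0
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!defined] <- b[!defined] <- cc[!defined] <- NA
  data.frame(a = a, b = b, c = cc, defined = defined)
}

#' Linkage-disequilibrium decay
#'
#' r-squared for every intra-chromosomal site pair within `max_dist` bp:
#' from haplotype frequencies (`D^2 / (pA pa pB pb)`, equal to the squared
#' Pearson correlation of haplotype allele indicators) when given phased
#' haplotypes, or the squared genotype correlation as the unphased fallback.
#' Pairs involving a monomorphic site are skipped.
#'
#' @param x a `hap_matrix` (phased route) or `geno_matrix` (fallback).
#' @param max_dist maximum pair distance in bp (default 1 Mb).
#' @param bin_width decay-curve distance bin width in bp.
#' @return list with `pairs` (chrom, pos1, pos2, dist, r2) and `curve`
#'   (bin midpoint, mean r2, n pairs).
#' @export
ld_decay <- function(x, max_dist = 1e6, bin_width = 2e4) {
  phased <- inherits(x, "hap_matrix") && !anyNA(x$hap)
  mat <- if (phased) x$hap else x$geno
  pairs <- list()
  for (ch in unique(x$sites$chrom)) {
    idx <- which(x$sites$chrom == ch)
    if (length(idx) < 2) next
    m <- t(mat[idx, , drop = FALSE])   # samples/haplotypes x sites
    if (phased) {
      p <- colMeans(m)
      keep <- which(p > 0 & p < 1)
      if (length(keep) < 2) next
      m <- m[, keep, drop = FALSE]; p <- p[keep]
      pab <- crossprod(m) / nrow(m)    # two-locus haplotype frequency p_AB
      D <- pab - outer(p, p)
      v <- p * (1 - p)
      r2 <- D^2 / outer(v, v)
    } else {
      sds <- apply(m, 2, stats::sd, na.rm = TRUE)
      keep <- which(!is.na(sds) & sds > 0)
      if (length(keep) < 2) next
      m <- m[, keep, drop = FALSE]
      r2 <- suppressWarnings(
        stats::cor(m, use = "pairwise.complete.obs"))^2
    }
    pos <- x$sites$pos[idx][keep]
    ut <- which(upper.tri(r2), arr.ind = TRUE)
    d <- pos[ut[, 2]] - pos[ut[, 1]]
    sel <- d <= max_dist & !is.na(r2[ut])
    pairs[[ch]] <- data.frame(chrom = ch, pos1 = pos[ut[sel, 1]],
                              pos2 = pos[ut[sel, 2]], dist = d[sel],
                              r2 = r2[ut][sel], stringsAsFactors = FALSE)
  }
  pairs <- if (length(pairs)) do.call(rbind, c(pairs, make.row.names = FALSE))
    else data.frame(chrom = character(), pos1 = numeric(), pos2 = numeric(),
                    dist = numeric(), r2 = numeric())
  if (nrow(pairs)) {
    bin <- pmin(floor((pairs$dist - 1) / bin_width), 1e9)
    curve <- do.call(rbind, lapply(split(pairs$r2, bin), function(v)
      data.frame(mean_r2 = mean(v), n_pairs = length(v))))
    curve$dist_mid <- (as.numeric(rownames(curve)) + 0.5) * bin_width
    curve <- curve[order(curve$dist_mid), c("dist_mid", "mean_r2", "n_pairs")]
    rownames(curve) <- NULL
  } else {
    curve <- data.frame(dist_mid = numeric(), mean_r2 = numeric(),
                        n_pairs = numeric())
  }
  list(pairs = pairs, curve = curve)
}

#' Allele-sharing genetic distance matrix
#'
#' `d(i, j) = 1 -` mean shared-allele fraction over sites non-missing in
#' both samples (per site: 1 - |gi - gj| / 2). Pairs with no jointly
#' observed site are `NA` (flagged).
#'
#' @param gm a `geno_matrix`.
#' @param samples optional subset.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
genetic_distance_matrix <- function(gm, samples = NULL) {
  if (is.null(samples)) samples <- gm$samples
  if (length(samples) < 2) stop("need >= 2 samples")
  g <- gm$geno[, samples, drop = FALSE]
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(g[, i]) & !is.na(g[, j])
      d[i, j] <- d[j, i] <-
        if (any(ok)) mean(abs(g[ok, i] - g[ok, j])) / 2 else NA
    }
  }
  d
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration (via the standard implementation in
#' \pkg{ape}); negative branch lengths are clamped to zero with the deficit
#' moved to the sibling branch, and the unrooted tree is returned as newick
#' text.
#'
#' @param dm symmetric distance matrix with >= 3 taxa, all entries defined.
#' @return newick string; the `phylo` object is attached as attribute
#'   `phylo`.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbour joining needs >= 3 taxa")
  if (anyNA(dm)) stop("distance matrix has undefined entries")
  tr <- ape::nj(dm)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sib)) {
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  nwk <- ape::write.tree(tr)
  attr(nwk, "phylo") <- tr
  nwk
}

#' Write a windowed statistic table as TSV (1-based inclusive intervals)
#' @param ws data.frame from a scan function.
#' @param path output file.
#' @export
write_window_stats <- function(ws, path) {
  utils::write.table(ws, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
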