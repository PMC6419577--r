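# shared fixtures and independent oracles, built in code at test time

toy_genome <- function(len = 1e5, chrom = "A01") genome_map(chrom, len)

# genotype matrix from a plain sites x samples matrix
toy_gm <- function(m, pos = NULL, chrom = "A01", len = NULL,
                   samples = paste0("s", seq_len(ncol(m)))) {
  if (is.null(pos)) pos <- seq_len(nrow(m)) * 10
  if (is.null(len)) len <- max(pos) + 10
  geno_matrix(m, data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G"),
              samples, genome_map(chrom, len))
}

toy_hap <- function(h, pos = NULL, chrom = "A01", len = NULL,
                    samples = paste0("s", seq_len(ncol(h) / 2))) {
  if (is.null(pos)) pos <- seq_len(nrow(h)) * 10
  if (is.null(len)) len <- max(pos) + 10
  hap_matrix(h, data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G"),
             samples, genome_map(chrom, len))
}

trio_pedigree <- function() {
  pedigree_graph(
    nodes = data.frame(id = c("P1", "P2", "C"),
                       role = c("exotic_founder", "exotic_founder",
                                "backbone")),
    edges = data.frame(parent = c("P1", "P2"), child = c("C", "C")))
}

threegen_pedigree <- function() {
  pedigree_graph(
    nodes = data.frame(
      id = c(paste0("GP", 1:4), "P1", "P2", "T"),
      role = c(rep("exotic_founder", 4), "backbone", "backbone", "elite")),
    edges = data.frame(parent = c("GP1", "GP2", "GP3", "GP4", "P1", "P2"),
                       child = c("P1", "P1", "P2", "P2", "T", "T")))
}

# oracle: union of intervals via a per-base boolean mask (single chromosome)
mask_union <- function(iv, len, max_gap = 0) {
  mask <- logical(len)
  for (i in seq_len(nrow(iv))) mask[iv$start[i]:iv$end[i]] <- TRUE
  if (max_gap > 0) {
    r <- rle(mask)
    gap <- which(!r$values & r$lengths <= max_gap)
    gap <- gap[gap > 1 & gap < length(r$values)]
    r$values[gap] <- TRUE
    mask <- inverse.rle(r)
  }
  r <- rle(mask)
  e <- cumsum(r$lengths); s <- e - r$lengths + 1
  data.frame(start = s[r$values], end = e[r$values])
}

# oracle: EHH by explicit pair enumeration over markers (core, x]
brute_ehh <- function(hap, core, x) {
  H <- ncol(hap)
  rng <- if (x > core) (core + 1):x else x:(core - 1)
  cnt <- 0
  for (i in 1:(H - 1)) for (j in (i + 1):H) {
    if (all(hap[rng, i] == hap[rng, j])) cnt <- cnt + 1
  }
  cnt / choose(H, 2)
}

brute_ihh <- function(hap, pos, core, min_ehh = 0.05, max_extend = 1e9) {
  tot <- 0
  for (dir in c(-1, 1)) {
    ep <- 1; dp <- 0; s <- core + dir
    while (s >= 1 && s <= nrow(hap)) {
      d <- abs(pos[s] - pos[core])
      if (d > max_extend) break
      e <- brute_ehh(hap, core, s)
      tot <- tot + 0.5 * (ep + e) * (d - dp)
      ep <- e; dp <- d
      if (e < min_ehh) break
      s <- s + dir
    }
  }
  tot
}

# total bp of the pairwise overlap between two interval sets (same chrom set)
overlap_sets_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0)
  tot <- 0
  for (i in seq_len(nrow(a))) {
    tot <- tot + sum(overlap_bp(a[rep(i, nrow(b)), , drop = FALSE], b))
  }
  tot
}

# precision/recall of detected vs truth interval sets, pooled
interval_pr <- function(detected, truth) {
  ov <- overlap_sets_bp(detected, truth)
  c(precision = if (interval_bp(detected) > 0) ov / interval_bp(detected)
    else NA_real_,
    recall = if (interval_bp(truth) > 0) ov / interval_bp(truth)
    else NA_real_)
}

# write a small VCF body from scratch (hand-built text, used by io tests)
write_test_vcf <- function(path, records,
                           samples = c("s1", "s2", "s3")) {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
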