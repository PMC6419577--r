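#' Simulation configuration
#'
#' Bundles every knob of the pedigree genotype simulator. The defaults are
#' the package's standing study conditions: a two-chromosome 20 Mb genome
#' (one chromosome per sub-genome) scaled down from the ~2.3 Gb cotton
#' genome, SNP density and a neutral 1/i site-frequency law calibrated so a
#' 100 kb-window diversity scan of an outbred wild-type panel sits near
#' pi = 1.32e-3 per bp, haplotype-block structure in the founder pool so
#' linkage-based statistics see realistic local LD, and a per-Mb
#' recombination rate raised tenfold so the crossover count per (shortened)
#' chromosome stays near one per meiosis.
#'
#' @param genome a [genome_map()].
#' @param snp_per_chrom SNPs simulated per chromosome.
#' @param founder_count pedigree founder accessions when no pedigree given.
#' @param n_wild accessions in the outbred wild-type comparison panel.
#' @param freq_law `"neutral"` (P(i) proportional to 1/i over `sfs_classes`
#'   haplotype count classes) or `"fixed"` (all sites at `freq_p`).
#' @param freq_p alternate-allele frequency under the fixed law.
#' @param sfs_classes haplotype count H of the neutral SFS (classes 1..H-1).
#' @param block_snps founder haplotypes are drawn per block of this many
#'   consecutive sites from a pool of `block_pool` prototype haplotypes,
#'   inducing local LD; 0 draws every site independently.
#' @param block_pool prototype haplotypes per block.
#' @param recomb_rate crossover rate, cM/Mb.
#' @param pedigree a `pedigree` object; default [example_pedigree()].
#' @param mode `"inbred"` (default): every accession is a fully homozygous
#'   line; a cross is collapsed single-seed descent, i.e. one gamete per
#'   parent plus one derivation recombination, doubled. `"outbred"`: a child
#'   is the diploid union of one gamete per parent.
#' @param missing_rate,error_rate per-call missing and wrong-code
#'   probabilities layered on the genotype matrix.
#' @param sweep_specs data.frame (`chrom`, `start`, `end`, `intensity`) of
#'   sweeps to plant.
#' @param qtl_specs data.frame (`site`, `effect`) of trait loci.
#' @param h2 narrow-sense heritability for simulated phenotypes.
#' @param seed integer master seed; every stage draws from its own derived
#'   stream so adding sites does not perturb pedigree transmission.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome = genome_map(c("A01", "D01"), c(1e7, 1e7)),
                       snp_per_chrom = 61000,
                       founder_count = 5,
                       n_wild = 20,
                       freq_law = c("neutral", "fixed"),
                       freq_p = 0.5,
                       sfs_classes = 40,
                       block_snps = 50,
                       block_pool = 16,
                       recomb_rate = 10,
                       pedigree = NULL,
                       mode = c("inbred", "outbred"),
                       missing_rate = 0.02,
                       error_rate = 0.001,
                       sweep_specs = NULL,
                       qtl_specs = NULL,
                       h2 = 0.6,
                       seed = 1L) {
  freq_law <- match.arg(freq_law)
  mode <- match.arg(mode)
  if (snp_per_chrom <= 0) stop("snp_per_chrom must be positive")
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (recomb_rate < 0) stop("recomb_rate must be >= 0")
  if (!is.null(sweep_specs) &&
      (any(sweep_specs$intensity < 0) || any(sweep_specs$intensity > 1))) {
    stop("sweep intensity must lie in [0, 1]")
  }
  structure(list(genome = genome, snp_per_chrom = snp_per_chrom,
                 founder_count = founder_count, n_wild = n_wild,
                 freq_law = freq_law, freq_p = freq_p,
                 sfs_classes = sfs_classes, block_snps = block_snps,
                 block_pool = block_pool, recomb_rate = recomb_rate,
                 pedigree = pedigree, mode = mode,
                 missing_rate = missing_rate, error_rate = error_rate,
                 sweep_specs = sweep_specs, qtl_specs = qtl_specs,
                 h2 = h2, seed = as.integer(seed)),
            class = "sim_config")
}

# internal: seed one of the named RNG substreams of a config
substream <- function(seed, k) {
  set.seed(as.integer((as.numeric(seed) * 1103L + 7919 * k) %% 2147483629))
}

#' Simulated SNP sites
#'
#' Draws the shared site map of a configuration: sorted distinct positions
#' per chromosome and a per-site alternate-allele frequency from the
#' configured law. Every panel simulated from the same config shares this
#' map, so between-group statistics line up site by site.
#'
#' @param config a [sim_config()].
#' @return data.frame `chrom`, `pos`, `ref`, `alt`, `freq`.
#' @export
simulate_sites <- function(config) {
  substream(config$seed, 1)
  out <- do.call(rbind, lapply(seq_len(nrow(config$genome)), function(i) {
    L <- config$genome$length[i]
    n <- min(config$snp_per_chrom, L)
    pos <- sort(sample.int(L, n))
    data.frame(chrom = config$genome$chrom[i], pos = pos,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(out)
  bases <- c("A", "C", "G", "T")
  out$ref <- sample(bases, n, replace = TRUE)
  out$alt <- vapply(out$ref, function(r) sample(setdiff(bases, r), 1), "")
  if (config$freq_law == "fixed") {
    out$freq <- rep(config$freq_p, n)
  } else {
    H <- config$sfs_classes
    i <- sample.int(H - 1, n, replace = TRUE, prob = 1 / seq_len(H - 1))
    out$freq <- i / H
  }
  rownames(out) <- NULL
  out
}

# internal: draw n_hap haplotypes over the given sites; block_snps > 0
# copies one of block_pool prototype haplotypes per block per haplotype
draw_haps <- function(sites, n_hap, config) {
  n <- nrow(sites)
  if (config$block_snps <= 0) {
    return(matrix(stats::rbinom(n * n_hap, 1, rep(sites$freq, n_hap)),
                  nrow = n))
  }
  hap <- matrix(0L, n, n_hap)
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    blocks <- split(idx, ceiling(seq_along(idx) / config$block_snps))
    for (b in blocks) {
      proto <- matrix(stats::rbinom(length(b) * config$block_pool, 1,
                                    rep(sites$freq[b], config$block_pool)),
                      nrow = length(b))
      pick <- sample.int(config$block_pool, n_hap, replace = TRUE)
      hap[b, ] <- proto[, pick, drop = FALSE]
    }
  }
  hap
}

#' Simulate founder haplotypes
#'
#' Draws unrelated accessions over the configuration's shared site map.
#' Inbred accessions carry two identical haplotypes (a fully homozygous
#' line); outbred accessions carry two independent draws. Deterministic
#' under the config seed: the site map comes from the site stream and the
#' haplotypes from the stream named by `stream`.
#'
#' @param config a [sim_config()].
#' @param n number of accessions (default `config$founder_count`).
#' @param ids accession ids (default `F1..Fn`).
#' @param inbred logical; default follows `config$mode`.
#' @param sites precomputed [simulate_sites()] output (optional).
#' @param stream substream index (founder panel 2, wild panel 5).
#' @return a `hap_matrix`.
#' @export
simulate_founder_haplotypes <- function(config, n = config$founder_count,
                                        ids = paste0("F", seq_len(n)),
                                        inbred = config$mode == "inbred",
                                        sites = NULL, stream = 2) {
  if (n <= 0) stop("need at least one accession")
  if (is.null(sites)) sites <- simulate_sites(config)
  substream(config$seed, stream)
  if (inbred) {
    one <- draw_haps(sites, n, config)
    hap <- one[, rep(seq_len(n), each = 2), drop = FALSE]
  } else {
    hap <- draw_haps(sites, 2 * n, config)
  }
  hap_matrix(hap, sites, ids, config$genome)
}

#' Simulate an outbred wild-type comparison panel
#'
#' Convenience wrapper drawing `config$n_wild` outbred accessions (ids
#' `W1..Wn`) on the same site map as the pedigree, from an independent
#' haplotype stream.
#'
#' @param config a [sim_config()].
#' @param sites optional precomputed site map.
#' @return a `hap_matrix`.
#' @export
simulate_wild_panel <- function(config, sites = NULL) {
  simulate_founder_haplotypes(config, n = config$n_wild,
                              ids = paste0("W", seq_len(config$n_wild)),
                              inbred = FALSE, sites = sites, stream = 5)
}

#' Simulate one gamete by meiosis
#'
#' The crossover count per chromosome is Poisson(length_Mb * recomb_rate /
#' 100), breakpoint positions are uniform and strictly inside the
#' chromosome, and the gamete alternates between the two input haplotypes at
#' the breakpoints starting from a random one. Uses the current RNG state;
#' callers owning a config seed their stream first.
#'
#' @param pair two-column 0/1 matrix: the parent's haplotype pair.
#' @param sites site map aligned with `pair` rows.
#' @param genome a [genome_map()].
#' @param recomb_rate cM/Mb.
#' @return list with `hap` (integer vector), `breaks` (data.frame `chrom`,
#'   `pos`) and `segments` (data.frame `chrom`, `start`, `end`, `source`
#'   with source 1 or 2 = input column).
#' @export
simulate_gamete <- function(pair, sites, genome, recomb_rate) {
  hap <- integer(nrow(sites))
  breaks <- list(); segments <- list()
  for (i in seq_len(nrow(genome))) {
    ch <- genome$chrom[i]; L <- genome$length[i]
    idx <- which(sites$chrom == ch)
    k <- stats::rpois(1, L / 1e6 * recomb_rate / 100)
    bp <- if (k > 0) sort(sample.int(L - 1L, min(k, L - 1L))) else integer(0)
    start <- sample(1:2, 1)
    src <- rep(c(start, 3L - start), length.out = length(bp) + 1)
    lo <- c(1, bp + 1); hi <- c(bp, L)
    segments[[ch]] <- data.frame(chrom = ch, start = lo, end = hi,
                                 source = src, stringsAsFactors = FALSE)
    if (length(bp)) breaks[[ch]] <- data.frame(chrom = ch, pos = bp)
    if (length(idx)) {
      seg_of_site <- findInterval(sites$pos[idx], lo)
      take <- src[seg_of_site]
      hap[idx] <- ifelse(take == 1L, pair[idx, 1], pair[idx, 2])
    }
  }
  list(hap = hap,
       breaks = if (length(breaks)) do.call(rbind, c(breaks, make.row.names = FALSE))
                else data.frame(chrom = character(), pos = numeric()),
       segments = do.call(rbind, c(segments, make.row.names = FALSE)))
}

# internal: collapse consecutive same-source segments
squash_segments <- function(seg) {
  if (nrow(seg) <= 1) return(seg)
  keep <- list(); cur <- seg[1, ]
  for (i in 2:nrow(seg)) {
    s <- seg[i, ]
    if (s$chrom == cur$chrom && s$source == cur$source &&
        s$start == cur$end + 1) {
      cur$end <- s$end
    } else {
      keep[[length(keep) + 1]] <- cur; cur <- s
    }
  }
  keep[[length(keep) + 1]] <- cur
  do.call(rbind, c(keep, make.row.names = FALSE))
}

#' Simulate genotypes for a whole breeding pedigree
#'
#' Founders (nodes without recorded parents, which must carry the
#' `exotic_founder` role) are drawn fresh; every other accession is built
#' from one gamete per recorded parent in topological order. In `"inbred"`
#' mode the two gametes are recombined once more (collapsed single-seed
#' descent) and the result doubled, so every accession is a homozygous
#' mosaic of its parents; in `"outbred"` mode the child is the diploid union
#' of the two gametes. The returned truth records, per child, the intervals
#' truly transmitted from each parent (a tiling of every chromosome), all
#' crossover breakpoints, and the simulation mode.
#'
#' @param config a [sim_config()]; `config$pedigree` defaults to
#'   [example_pedigree()].
#' @return list with `genotypes` (`geno_matrix`, error/missingness applied),
#'   `haplotypes` (`hap_matrix`, error-free), and `truth` (list:
#'   `transmitted`, `crossovers`, `mode`).
#' @export
simulate_pedigree_genotypes <- function(config) {
  ped <- config$pedigree
  if (is.null(ped)) ped <- example_pedigree()
  ord <- validate_pedigree(ped)
  par <- parents_of(ped)
  roles <- stats::setNames(ped$nodes$role, ped$nodes$id)
  founders <- ord[vapply(ord, function(i) length(par[[i]]) == 0, TRUE)]
  bad <- founders[roles[founders] != "exotic_founder"]
  if (length(bad)) {
    stop("accession without recorded parents lacks founder role: ", bad[1])
  }
  sites <- simulate_sites(config)
  fh <- simulate_founder_haplotypes(config, n = length(founders),
                                    ids = founders, sites = sites, stream = 2)
  n_sites <- nrow(sites)
  hap <- matrix(0L, n_sites, 2 * length(ord))
  colnames(hap) <- paste(rep(ord, each = 2), 1:2, sep = "_")
  hap[, paste(rep(founders, each = 2), 1:2, sep = "_")] <- fh$hap
  transmitted <- list(); crossovers <- list()
  substream(config$seed, 3)
  genome_iv <- intervals(config$genome$chrom, 1, config$genome$length)
  for (id in setdiff(ord, founders)) {
    p <- par[[id]]
    if (length(p) == 1) p <- c(p, p)
    pairA <- hap[, paste(p[1], 1:2, sep = "_"), drop = FALSE]
    pairB <- hap[, paste(p[2], 1:2, sep = "_"), drop = FALSE]
    gA <- simulate_gamete(pairA, sites, config$genome, config$recomb_rate)
    gB <- simulate_gamete(pairB, sites, config$genome, config$recomb_rate)
    cxrow <- function(tag, br) if (nrow(br)) cbind(meiosis = tag, br) else NULL
    cx <- rbind(cxrow("parent1", gA$breaks), cxrow("parent2", gB$breaks))
    if (config$mode == "inbred") {
      gD <- simulate_gamete(cbind(gA$hap, gB$hap), sites, config$genome,
                            config$recomb_rate)
      hap[, paste(id, 1:2, sep = "_")] <- cbind(gD$hap, gD$hap)
      seg <- gD$segments
      seg$source <- p[seg$source]
      seg <- squash_segments(seg)
      seg <- cbind(child = id, copy = NA_integer_, seg)
      cx <- rbind(cx, cxrow("derivation", gD$breaks))
    } else {
      hap[, paste(id, 1:2, sep = "_")] <- cbind(gA$hap, gB$hap)
      seg <- rbind(cbind(child = id, copy = 1L, genome_iv, source = p[1]),
                   cbind(child = id, copy = 2L, genome_iv, source = p[2]))
    }
    transmitted[[id]] <- seg
    if (!is.null(cx) && nrow(cx)) crossovers[[id]] <- cbind(child = id, cx)
  }
  hm <- hap_matrix(hap, sites, ord, config$genome)
  substream(config$seed, 4)
  gm <- hap_to_geno(hm, config$error_rate, config$missing_rate)
  truth <- list(
    transmitted = do.call(rbind, c(transmitted, make.row.names = FALSE)),
    crossovers = if (length(crossovers))
      do.call(rbind, c(crossovers, make.row.names = FALSE))
    else data.frame(child = character(), meiosis = character(),
                    chrom = character(), pos = numeric()),
    mode = config$mode)
  list(genotypes = gm, haplotypes = hm, truth = truth)
}

#' Ancestor segments implied by the simulation truth
#'
#' Composes the per-meiosis transmitted intervals down the pedigree: a
#' region of `child` descends from `ancestor` iff it was transmitted at
#' every link of some pedigree path. Defined for `"inbred"` simulations,
#' where each accession has a single genome tiling.
#'
#' @param sim result of [simulate_pedigree_genotypes()].
#' @param ped the `pedigree` used.
#' @param child,ancestor accession ids.
#' @return interval data.frame of truly ancestor-derived regions.
#' @export
truth_ancestor_segments <- function(sim, ped, child, ancestor) {
  if (sim$truth$mode != "inbred") {
    stop("ancestry composition is defined for inbred-mode simulations")
  }
  tr <- sim$truth$transmitted
  genome <- sim$haplotypes$genome
  whole <- intervals(genome$chrom, 1, genome$length)
  par <- parents_of(ped)
  memo <- new.env()
  rec <- function(node) {
    if (node == ancestor) return(whole)
    if (!is.null(memo[[node]])) return(memo[[node]])
    out <- intervals(character(), numeric(), numeric())
    for (p in unique(par[[node]])) {
      if (!(ancestor == p || ancestor %in% pedigree_ancestors(ped, p))) next
      from_p <- tr[tr$child == node & tr$source == p,
                   c("chrom", "start", "end")]
      if (nrow(from_p) == 0) next
      up <- rec(p)
      if (nrow(up) == 0) next
      ov <- GenomicRanges::intersect(as_gr(from_p), as_gr(up))
      out <- rbind(out, gr_to_iv(ov))
    }
    out <- merge_intervals(out, 0)
    memo[[node]] <- out
    out
  }
  rec(child)
}

#' @rdname truth_ancestor_segments
#' @return `truth_ancestor_fraction`: fraction of the genome (0..1).
#' @export
truth_ancestor_fraction <- function(sim, ped, child, ancestor) {
  interval_bp(truth_ancestor_segments(sim, ped, child, ancestor)) /
    sum(sim$haplotypes$genome$length)
}

#' Plant a selective sweep into a haplotype panel
#'
#' Inside `region`, each haplotype is replaced by the designated swept donor
#' haplotype (column `donor`) with probability `intensity`; sites outside
#' the region are untouched. At intensity 1 the region becomes monomorphic.
#'
#' @param hm a `hap_matrix`.
#' @param region single-row interval data.frame.
#' @param intensity replacement probability in \[0, 1\].
#' @param donor donor haplotype column index (default 1).
#' @param seed optional seed; otherwise the current RNG state is used.
#' @return modified `hap_matrix`.
#' @export
plant_sweep_region <- function(hm, region, intensity, donor = 1, seed = NULL) {
  if (intensity < 0 || intensity > 1) stop("intensity must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  idx <- which(hm$sites$chrom == norm_chrom(region$chrom[1]) &
               hm$sites$pos >= region$start[1] & hm$sites$pos <= region$end[1])
  if (length(idx) == 0 || intensity == 0) return(hm)
  swept <- hm$hap[idx, donor]
  take <- stats::runif(ncol(hm$hap)) < intensity
  hm$hap[idx, take] <- swept
  hm
}

#' Simulate phenotypes from planted trait loci
#'
#' The genetic value of an accession is the sum of QTL allele effects over
#' its genotype codes plus an optional polygenic term from `n_polygenic`
#' random background sites. Per environment, independent normal noise is
#' added with variance var(g) * (1 - h2) / h2, so the within-environment
#' heritability is `h2` up to sampling error; all environments share the
#' genetic value. `h2 = 0` yields pure noise; `h2 = 1` yields the genetic
#' value exactly.
#'
#' @param gm a `geno_matrix` (missing codes are mean-imputed).
#' @param qtl data.frame with columns `site` (row index into `gm$sites`) and
#'   `effect` (trait units per alternate allele).
#' @param h2 heritability in \[0, 1\].
#' @param n_env number of environments.
#' @param trait trait name for the output table.
#' @param n_polygenic background sites with N(0, polygenic_sd) effects.
#' @param polygenic_sd per-site background effect SD.
#' @param noise_sd noise SD used when `h2 = 0` (otherwise derived).
#' @param seed optional seed.
#' @return long-format data.frame `accession`, `trait`, `environment`,
#'   `value`, with the noise SD as attribute `noise_sd`.
#' @export
simulate_phenotypes <- function(gm, qtl = NULL, h2 = 0.6, n_env = 1,
                                trait = "trait", n_polygenic = 0,
                                polygenic_sd = 0.1, noise_sd = 1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  g <- matrix(gm$geno, nrow(gm$sites))
  mu <- rowMeans(g, na.rm = TRUE)
  g[is.na(g)] <- mu[row(g)[is.na(g)]]
  gv <- numeric(length(gm$samples))
  if (!is.null(qtl) && nrow(qtl)) {
    if (any(qtl$site < 1 | qtl$site > nrow(gm$sites))) {
      stop("QTL site index outside the genotype matrix")
    }
    gv <- gv + as.vector(crossprod(g[qtl$site, , drop = FALSE], qtl$effect))
  }
  if (n_polygenic > 0) {
    bs <- sample.int(nrow(gm$sites), min(n_polygenic, nrow(gm$sites)))
    gv <- gv + as.vector(crossprod(g[bs, , drop = FALSE],
                                   stats::rnorm(length(bs), 0, polygenic_sd)))
  }
  if (h2 == 0) {
    gv <- numeric(length(gv)); sd_e <- noise_sd
  } else {
    vg <- stats::var(gv)
    if (vg == 0) stop("zero genetic variance with h2 > 0")
    sd_e <- sqrt(vg * (1 - h2) / h2)
  }
  envs <- paste0("E", seq_len(n_env))
  out <- do.call(rbind, lapply(envs, function(e) {
    data.frame(accession = gm$samples, trait = trait, environment = e,
               value = gv + stats::rnorm(length(gv), 0, sd_e),
               stringsAsFactors = FALSE)
  }))
  attr(out, "noise_sd") <- sd_e
  out
}

#' Read/write long-format phenotype tables
#' @param path TSV with columns `accession`, `trait`, `environment`, `value`.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("accession", "trait", "environment", "value")
  if (!all(need %in% names(df))) {
    stop("phenotype file needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df[c("accession", "trait", "environment")])) {
    stop("duplicate (accession, trait, environment) rows")
  }
  df
}

#' @rdname read_phenotypes
#' @param phen phenotype data.frame.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.table(phen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
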