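small_cfg <- function(snp_per_chrom = 2000, ...) {
  sim_config(genome = genome_map("A01", 1e6), snp_per_chrom = snp_per_chrom,
             pedigree = trio_pedigree(), ...)
}

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- small_cfg(seed = 11)
  a <- simulate_pedigree_genotypes(cfg)
  b <- simulate_pedigree_genotypes(cfg)
  expect_identical(a$haplotypes$hap, b$haplotypes$hap)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$truth$transmitted, b$truth$transmitted)
  w1 <- simulate_wild_panel(cfg); w2 <- simulate_wild_panel(cfg)
  expect_identical(w1$hap, w2$hap)
  # wild and pedigree panels share the site map
  expect_identical(w1$sites[c("chrom", "pos")],
                   a$haplotypes$sites[c("chrom", "pos")])
})

test_that("the fixed-frequency law hits its binomial expectation", {
  cfg <- sim_config(genome = genome_map("A01", 1e6), snp_per_chrom = 1e4,
                    freq_law = "fixed", freq_p = 0.5, block_snps = 0,
                    seed = 2)
  h <- simulate_founder_haplotypes(cfg, n = 5, inbred = FALSE)
  n_draw <- nrow(h$hap) * ncol(h$hap)
  expect_lt(abs(mean(h$hap) - 0.5), 3 * sqrt(0.25 / n_draw))
})

test_that("founder-panel diversity sits at the wild calibration target", {
  cfg <- sim_config(genome = genome_map("A01", 1e7), seed = 4)
  w <- simulate_wild_panel(cfg)
  pi_bar <- attr(pi_scan(w, window = 1e5, step = 1e5), "mean_value")
  expect_lt(abs(pi_bar - 1.32e-3) / 1.32e-3, 0.2)
})

test_that("gametes follow the Poisson crossover model", {
  cfg <- small_cfg(seed = 3)
  sites <- simulate_sites(cfg)
  pair <- cbind(rep(0L, nrow(sites)), rep(1L, nrow(sites)))
  # no recombination: gamete equals one parent haplotype, no breakpoints
  set.seed(1)
  g0 <- simulate_gamete(pair, sites, cfg$genome, recomb_rate = 0)
  expect_equal(nrow(g0$breaks), 0)
  expect_true(all(g0$hap == 0) || all(g0$hap == 1))
  expect_equal(nrow(g0$segments), 1)
  # 100 Mb at 1 cM/Mb: crossover count is Poisson(1)
  big <- genome_map("A01", 1e8)
  s2 <- data.frame(chrom = "A01", pos = c(1, 1e8), ref = "A", alt = "G")
  set.seed(9)
  k <- replicate(4000, {
    g <- simulate_gamete(cbind(0L, 1L)[c(1, 1), ], s2, big, recomb_rate = 1)
    nrow(g$breaks)
  })
  expect_lt(abs(mean(k) - 1), 3 * sqrt(1 / 4000))
  # breakpoints sorted and strictly inside the chromosome
  set.seed(5)
  g <- simulate_gamete(pair, sites, cfg$genome, recomb_rate = 300)
  expect_true(all(diff(g$breaks$pos) > 0))
  expect_true(all(g$breaks$pos >= 1 & g$breaks$pos < 1e6))
})

test_that("outbred crosses transmit one whole chromosome per parent at rate 0", {
  cfg <- small_cfg(mode = "outbred", recomb_rate = 0, seed = 6,
                   error_rate = 0, missing_rate = 0)
  sim <- simulate_pedigree_genotypes(cfg)
  tr <- sim$truth$transmitted[sim$truth$transmitted$child == "C", ]
  expect_equal(nrow(tr), 2)
  expect_setequal(tr$source, c("P1", "P2"))
  expect_true(all(tr$start == 1 & tr$end == 1e6))
})

test_that("inbred-mode truth tiles every descendant chromosome exactly", {
  cfg <- sim_config(genome = genome_map(c("A01", "D01"), c(1e6, 8e5)),
                    snp_per_chrom = 1500, seed = 8)
  sim <- simulate_pedigree_genotypes(cfg)
  tr <- sim$truth$transmitted
  kids <- unique(tr$child)
  expect_gt(length(kids), 15)
  for (ch in kids) {
    for (cr in c("A01", "D01")) {
      s <- tr[tr$child == ch & tr$chrom == cr, ]
      s <- s[order(s$start), ]
      expect_equal(s$start[1], 1)
      expect_equal(s$end[nrow(s)], if (cr == "A01") 1e6 else 8e5)
      if (nrow(s) > 1) expect_equal(s$start[-1], s$end[-nrow(s)] + 1)
    }
  }
  # every accession is homozygous in inbred mode
  expect_true(all(sim$haplotypes$hap[, seq(1, 10, 2)] ==
                    sim$haplotypes$hap[, seq(2, 10, 2)]))
})

test_that("transmitted regions carry near-perfect genotype identity", {
  cfg <- small_cfg(seed = 12, snp_per_chrom = 4000)
  sim <- simulate_pedigree_genotypes(cfg)
  tr <- sim$truth$transmitted
  g <- sim$genotypes
  for (p in c("P1", "P2")) {
    seg <- tr[tr$child == "C" & tr$source == p, ]
    if (nrow(seg) == 0) next
    in_seg <- rep(FALSE, nrow(g$sites))
    for (i in seq_len(nrow(seg))) {
      in_seg <- in_seg | (g$sites$pos >= seg$start[i] &
                            g$sites$pos <= seg$end[i])
    }
    ok <- in_seg & !is.na(g$geno[, "C"]) & !is.na(g$geno[, p])
    # direct per-site recount: identity inside truth segments is limited
    # only by the planted genotyping error (0.001 per call, either sample)
    ident <- mean(g$geno[ok, "C"] == g$geno[ok, p])
    expect_gt(ident, 0.99)
    out_ok <- !in_seg & !is.na(g$geno[, "C"]) & !is.na(g$geno[, p])
    if (sum(out_ok) > 200) {
      expect_lt(mean(g$geno[out_ok, "C"] == g$geno[out_ok, p]), 0.95)
    }
  }
})

test_that("planted sweeps thin diversity in proportion to intensity", {
  cfg <- sim_config(genome = genome_map("A01", 1e6), snp_per_chrom = 3000,
                    seed = 21)
  w <- simulate_wild_panel(cfg)
  region <- intervals("A01", 400001, 600000)
  expect_error(plant_sweep_region(w, region, 1.5), "intensity")
  # intensity 0 is the identity
  expect_identical(plant_sweep_region(w, region, 0)$hap, w$hap)
  # intensity 1: monomorphic region, windowed pi = 0 inside
  h1 <- plant_sweep_region(w, region, 1, seed = 1)
  p1 <- pi_scan(h1, window = 1e5, step = 1e5)
  inside <- p1$start >= region$start & p1$end <= region$end
  expect_true(all(p1$value[inside] == 0))
  expect_true(all(p1$value[!inside] > 0))
  # intensity 0.9 crushes pi inside relative to outside
  ratios <- sapply(1:20, function(s) {
    h <- plant_sweep_region(w, region, 0.9, seed = s)
    p <- pi_scan(h, window = 1e5, step = 1e5)
    mean(p$value[inside]) / mean(p$value[!inside])
  })
  expect_lt(mean(ratios), 0.2)
})

test_that("ancestor composition respects pedigree expectation", {
  ped <- threegen_pedigree()
  fr <- sapply(1:8, function(s) {
    cfg <- sim_config(genome = genome_map("A01", 5e6), snp_per_chrom = 1000,
                      pedigree = ped, seed = s)
    sim <- simulate_pedigree_genotypes(cfg)
    sapply(paste0("GP", 1:4), function(g)
      truth_ancestor_fraction(sim, ped, "T", g))
  })
  # each child-chromosome tiles; four grandparents partition the genome
  expect_equal(colSums(fr), rep(1, 8), tolerance = 1e-12)
  expect_lt(abs(mean(fr) - 0.25), 0.15)
})

test_that("phenotype simulation partitions variance as requested", {
  set.seed(30)
  g <- matrix(rbinom(500 * 20, 2, 0.4), 20, 500)
  gm <- toy_gm(g, samples = paste0("a", 1:500))
  qtl <- data.frame(site = 3, effect = 1)
  # no noise: phenotype equals the genotype code
  ph1 <- simulate_phenotypes(gm, qtl, h2 = 1, seed = 1)
  expect_equal(ph1$value, unname(g[3, ]))
  # h2 = 0: phenotype uncorrelated with the QTL genotype
  ph0 <- simulate_phenotypes(gm, qtl, h2 = 0, seed = 2)
  expect_lt(abs(cor(ph0$value, g[3, ])), 0.1)
  # errors
  expect_error(simulate_phenotypes(gm, data.frame(site = 1e6, effect = 1),
                                   h2 = 0.5), "site index")
  gm0 <- toy_gm(matrix(1L, 4, 10), samples = paste0("a", 1:10))
  expect_error(simulate_phenotypes(gm0, data.frame(site = 1, effect = 1),
                                   h2 = 1), "zero genetic variance")
  # environments share the genetic value
  ph <- simulate_phenotypes(gm, qtl, h2 = 0.8, n_env = 3, seed = 3)
  expect_equal(nrow(ph), 1500)
  expect_false(anyDuplicated(ph[c("accession", "trait", "environment")]) > 0)
})

test_that("pedigree diversity is reduced relative to the wild pool", {
  ok <- sapply(1:6, function(s) {
    cfg <- sim_config(genome = genome_map("A01", 2e6), snp_per_chrom = 8000,
                      seed = s)
    sim <- simulate_pedigree_genotypes(cfg)
    w <- simulate_wild_panel(cfg)
    attr(pi_scan(sim$genotypes, window = 1e5, step = 1e5), "mean_value") <
      attr(pi_scan(w, window = 1e5, step = 1e5), "mean_value")
  })
  expect_true(all(ok))
})
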