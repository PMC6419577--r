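test_that("windowed pi equals the all-pairs difference average", {
  # monomorphic window
  h0 <- toy_hap(matrix(0L, 10, 4))
  expect_true(all(pi_scan(h0, window = 100, step = 100)$value == 0))
  # two haplotypes, one differing site, 100 kb window: exactly 1e-5
  h1 <- toy_hap(matrix(c(0L, 1L), 1, 2), pos = 50, len = 1e5,
                samples = "s1")
  expect_equal(pi_scan(h1, window = 1e5, step = 1e5)$value, 1e-5)
  # random 10-haplotype, 50-site windows against the 45-pair oracle
  set.seed(101)
  for (rep in 1:20) {
    h <- matrix(rbinom(50 * 10, 1, runif(1, 0.1, 0.9)), 50, 10)
    hm <- toy_hap(h, pos = sort(sample.int(9999, 50)), len = 1e4,
                  samples = paste0("s", 1:5))
    got <- pi_scan(hm, window = 1e4, step = 1e4)$value
    pairs <- combn(10, 2)
    brute <- mean(apply(pairs, 2, function(p) sum(h[, p[1]] != h[, p[2]]))) / 1e4
    expect_equal(got, brute, tolerance = 1e-12)
  }
})

test_that("pi is invariant to sample order and zero for identical pairs", {
  set.seed(5)
  m <- matrix(sample(c(0L, 1L, 2L), 80, replace = TRUE), 20, 4)
  gm <- toy_gm(m)
  perm <- subset_samples(gm, samples = rev(gm$samples))
  expect_equal(pi_scan(gm, window = 100, step = 100)$value,
               pi_scan(perm, window = 100, step = 100)$value)
  dup <- toy_hap(cbind(m[, 1], m[, 1]) %% 2L, samples = "x")
  expect_true(all(pi_scan(dup, window = 1000, step = 1000)$value == 0))
})

test_that("SNP density counts polymorphic sites per true window width", {
  g <- genome_map("A01", 2.5e5)
  m <- rbind(matrix(c(0L, 2L), 100, 2, byrow = TRUE),   # polymorphic
             matrix(0L, 30, 2))                         # monomorphic
  pos <- c(sort(sample(1:1e5, 100)), sort(sample(100001:2e5, 30)))
  gm <- geno_matrix(m, data.frame(chrom = "A01", pos = pos, ref = "A",
                                  alt = "G"), c("a", "b"), g)
  d <- snp_density_scan(gm, window = 1e5)
  expect_equal(d$value[1], 0.001)     # 100 polymorphic SNPs / 100 kb
  expect_equal(d$value[2], 0)         # monomorphic sites do not count
  expect_equal(d$bp[3], 5e4)          # terminal window uses true width
  # random placement equals a brute-force per-window count
  set.seed(9)
  pos2 <- sort(sample.int(2.5e5, 400))
  gm2 <- geno_matrix(matrix(c(0L, 2L), 400, 2, byrow = TRUE),
                     data.frame(chrom = "A01", pos = pos2, ref = "A",
                                alt = "G"), c("a", "b"), g)
  d2 <- snp_density_scan(gm2, window = 3e4, step = 1e4)
  brute <- sapply(seq_len(nrow(d2)), function(i)
    sum(pos2 >= d2$start[i] & pos2 <= d2$end[i]))
  expect_equal(d2$n_snps, brute)
})

test_that("zero-diversity segments are maximal merged zero-bin runs", {
  g <- genome_map("A01", 1e6)
  mono <- geno_matrix(matrix(0L, 50, 3),
                      data.frame(chrom = "A01", pos = sort(sample.int(1e6, 50)),
                                 ref = "A", alt = "G"),
                      c("a", "b", "c"), g)
  d <- snp_density_scan(mono, window = 1e5)
  seg <- zero_diversity_segments(d)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 1); expect_equal(seg$end, 1e6)  # all 10 bins
  # no zero bins -> empty
  poly <- geno_matrix(matrix(c(0L, 2L, 1L), 100, 3),
                      data.frame(chrom = "A01",
                                 pos = sort(sample.int(1e6, 100)),
                                 ref = "A", alt = "G"), c("a", "b", "c"), g)
  dp <- snp_density_scan(poly, window = 1e4)
  dp$n_snps <- pmax(dp$n_snps, 1)
  expect_equal(nrow(zero_diversity_segments(dp, min_len = 1e4)), 0)
  # overlapping bins are ambiguous
  dov <- snp_density_scan(poly, window = 1e5, step = 5e4)
  expect_error(zero_diversity_segments(dov), "overlap")
})

test_that("Weir-Cockerham Fst honours its limiting cases", {
  # alternate allele fixed in A, absent in B: exactly 1
  gm <- toy_gm(matrix(c(rep(2L, 5), rep(0L, 5)), 1), samples = paste0("s", 1:10))
  f <- fst_scan(gm, paste0("s", 1:5), paste0("s", 6:10),
                window = 100, step = 100)
  expect_equal(f$value[1], 1)
  # identical allele frequencies in balanced groups: ~0
  set.seed(33)
  block <- matrix(rep(sample(c(0L, 1L, 2L), 300, replace = TRUE), 2), 300, 2)
  m <- do.call(cbind, rep(list(block), 20))[, order(rep(1:2, 20))]
  m <- matrix(as.integer(m), 300)
  gm2 <- toy_gm(m, samples = paste0("s", 1:40))
  f2 <- fst_scan(gm2, paste0("s", seq(1, 40, 2)), paste0("s", seq(2, 40, 2)),
                 window = 3000, step = 3000)
  expect_lt(abs(f2$value[1]), 0.02)
  expect_error(fst_scan(gm, "s1", paste0("s", 6:10)), ">= 2 samples")
})

test_that("per-site Fst components match hand-computed algebra", {
  set.seed(12)
  m <- matrix(sample(c(0L, 1L, 2L, NA), 40, replace = TRUE,
                     prob = c(.4, .25, .25, .1)), 5, 8)
  gm <- toy_gm(m)
  comp <- fst_site_components(gm, paste0("s", 1:4), paste0("s", 5:8))
  for (i in 1:5) {
    ga <- m[i, 1:4]; gb <- m[i, 5:8]
    n1 <- sum(!is.na(ga)); n2 <- sum(!is.na(gb))
    if (n1 == 0 || n2 == 0 || (n1 + n2) / 2 <= 1) {
      expect_false(comp$defined[i]); next
    }
    p1 <- sum(ga, na.rm = TRUE) / (2 * n1); p2 <- sum(gb, na.rm = TRUE) / (2 * n2)
    h1 <- sum(ga == 1, na.rm = TRUE) / n1; h2 <- sum(gb == 1, na.rm = TRUE) / n2
    nbar <- (n1 + n2) / 2
    nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
    pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
    hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
    expect_equal(comp$a[i], a)
    expect_equal(comp$b[i], b)
    expect_equal(comp$c[i], hbar / 2)
  }
})

test_that("phased r2 equals the squared haplotype-indicator correlation", {
  # perfect coupling
  h <- rbind(c(0L, 1L, 0L, 1L), c(0L, 1L, 0L, 1L))
  ld <- ld_decay(toy_hap(h))
  expect_equal(ld$pairs$r2, 1)
  # all four gametes at equal frequency: equilibrium
  h2 <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  expect_equal(ld_decay(toy_hap(h2))$pairs$r2, 0)
  # random phased panel against the correlation oracle
  set.seed(55)
  h3 <- matrix(rbinom(15 * 20, 1, 0.4), 15, 20)
  hm <- toy_hap(h3, samples = paste0("s", 1:10))
  ld3 <- ld_decay(hm)
  for (k in sample(nrow(ld3$pairs), 30)) {
    i <- match(ld3$pairs$pos1[k], hm$sites$pos)
    j <- match(ld3$pairs$pos2[k], hm$sites$pos)
    expect_equal(ld3$pairs$r2[k], cor(h3[i, ], h3[j, ])^2, tolerance = 1e-10)
  }
  # curve aggregates every retained pair
  expect_equal(sum(ld3$curve$n_pairs), nrow(ld3$pairs))
})

test_that("allele-sharing distances count per-site agreement", {
  m <- cbind(a = c(0L, 2L, 1L), b = c(0L, 2L, 1L), c = c(2L, 0L, 1L))
  d <- genetic_distance_matrix(toy_gm(m, samples = c("a", "b", "c")))
  expect_equal(d["a", "b"], 0)          # identical samples
  expect_equal(unname(diag(d)), c(0, 0, 0))
  opp <- cbind(a = c(0L, 0L), b = c(2L, 2L))
  expect_equal(genetic_distance_matrix(toy_gm(opp, samples = c("a", "b")))["a", "b"], 1)
  # random pair equals the direct per-site count
  set.seed(8)
  m2 <- matrix(sample(c(0L, 1L, 2L, NA), 60, replace = TRUE), 30, 2)
  d2 <- genetic_distance_matrix(toy_gm(m2, samples = c("x", "y")))
  ok <- !is.na(m2[, 1]) & !is.na(m2[, 2])
  expect_equal(d2["x", "y"], mean(abs(m2[ok, 1] - m2[ok, 2])) / 2)
})

test_that("neighbour joining recovers additive topologies", {
  # 3 taxa: closed-form branch lengths
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- attr(neighbor_joining(d3), "phylo")
  bl <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 4))
  # 4 taxa favouring the split {A,B} | {C,D}
  tip <- c(A = 1, B = 2, C = 3, D = 4)
  d4 <- matrix(0, 4, 4, dimnames = list(names(tip), names(tip)))
  d4["A", "B"] <- d4["B", "A"] <- 3
  d4["C", "D"] <- d4["D", "C"] <- 3
  for (x in c("A", "B")) for (y in c("C", "D")) {
    d4[x, y] <- d4[y, x] <- 8
  }
  tr4 <- attr(neighbor_joining(d4), "phylo")
  expect_true(ape::is.monophyletic(tr4, c("A", "B")))
  # 5 taxa from a known tree with additive branch lengths
  nwk <- "((A:1,B:2):3,(C:1.5,D:2.5):2,E:4);"
  ref <- ape::read.tree(text = nwk)
  d5 <- ape::cophenetic.phylo(ref)
  tr5 <- attr(neighbor_joining(d5), "phylo")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(ref), ape::unroot(tr5))),
               0)
  expect_true(all(tr5$edge.length >= 0))
  expect_error(neighbor_joining(d3[1:2, 1:2]), ">= 3 taxa")
})

test_that("wild and pedigree groups separate into two tree clades", {
  cfg <- sim_config(genome = genome_map("A01", 1e6), snp_per_chrom = 3000,
                    seed = 19)
  sim <- simulate_pedigree_genotypes(cfg)
  wild <- hap_to_geno(simulate_wild_panel(cfg))
  ped_ids <- sim$genotypes$samples[1:8]
  combined <- geno_matrix(cbind(sim$genotypes$geno[, ped_ids],
                                wild$geno + 0L),
                          sim$genotypes$sites,
                          c(ped_ids, wild$samples), cfg$genome)
  d <- genetic_distance_matrix(combined)
  tr <- attr(neighbor_joining(d), "phylo")
  expect_true(ape::is.monophyletic(tr, wild$samples))
})
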