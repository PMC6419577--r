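sites_df <- function(n, chrom = "A01", spacing = 50) {
  data.frame(chrom = chrom, pos = seq_len(n) * spacing, ref = "A", alt = "G")
}

test_that("SNP windows advance by step and handle tails", {
  w <- snp_windows(sites_df(500), size = 200, step = 20)
  full <- w[!w$truncated, ]
  expect_equal(nrow(full), 16)                 # floor((500-200)/20)+1
  expect_equal(full$first, seq(1, 301, 20))
  expect_equal(full$last, full$first + 199)
  expect_equal(nrow(snp_windows(sites_df(200))), 1)
  w199 <- snp_windows(sites_df(199))
  expect_equal(nrow(w199), 1)
  expect_true(w199$truncated)
  expect_equal(w199$n_sites, 199)
  # the sub-step tail beyond the last full window adds no extra window
  w210 <- snp_windows(sites_df(210))
  expect_equal(nrow(w210), 1)
  expect_false(w210$truncated)
  # chromosomes shorter than one step yield no window at all
  expect_equal(nrow(snp_windows(sites_df(15))), 0)
  expect_error(snp_windows(sites_df(100), size = 10, step = 20), "size")
  # windows never cross a chromosome boundary
  s2 <- rbind(sites_df(250), sites_df(250, chrom = "D01"))
  w2 <- snp_windows(s2)
  expect_true(all(w2$first >= 1))
  expect_true(all(s2$chrom[w2$first] == s2$chrom[w2$last]))
})

test_that("the 99% identity-ratio rule qualifies windows", {
  base <- rep(0L, 200)
  mk <- function(desc) {
    toy_gm(cbind(d = desc, p = base, o = rep(2L, 200)),
           samples = c("d", "p", "o"))
  }
  w <- function(gm) snp_windows(gm$sites, 200, 20)[1, ]
  # 198/200 identical: ratio 0.99, qualifies
  d1 <- base; d1[c(5, 105)] <- 1L
  s1 <- identity_ratio_scan(mk(d1), "d", "p", w(mk(d1)))
  expect_equal(s1$ratio, 0.99)
  expect_true(s1$qualifies)
  # 197/200: 0.985, does not qualify
  d2 <- base; d2[c(5, 105, 155)] <- 1L
  s2 <- identity_ratio_scan(mk(d2), "d", "p", w(mk(d2)))
  expect_equal(s2$ratio, 0.985)
  expect_false(s2$qualifies)
  # 99/99 compared with min_informative 100: insufficient data
  d3 <- base; d3[1:101] <- NA
  gm3 <- mk(d3)
  s3 <- identity_ratio_scan(gm3, "d", "p", w(gm3))
  expect_equal(s3$n_compared, 99)
  expect_equal(s3$ratio, 1)
  expect_false(s3$qualifies)
  # no compared sites at all: uninformative
  d4 <- rep(NA_integer_, 200)
  s4 <- identity_ratio_scan(mk(d4), "d", "p", w(mk(d4)))
  expect_true(s4$uninformative)
  expect_false(s4$qualifies)
})

test_that("window counts equal a brute-force per-site recount", {
  set.seed(61)
  m <- matrix(sample(c(0L, 1L, 2L, NA), 2000 * 2, replace = TRUE,
                     prob = c(.45, .25, .25, .05)), 2000, 2)
  gm <- toy_gm(m, samples = c("d", "p"))
  w <- snp_windows(gm$sites, 200, 20)
  sc <- identity_ratio_scan(gm, "d", "p", w)
  pick <- sample(nrow(w), min(100, nrow(w)))
  for (k in pick) {
    rng <- w$first[k]:w$last[k]
    ok <- !is.na(m[rng, 1]) & !is.na(m[rng, 2])
    expect_equal(sc$n_compared[k], sum(ok))
    expect_equal(sc$n_identical[k], sum(m[rng, 1][ok] == m[rng, 2][ok]))
  }
})

test_that("indistinguishable founder pairs mask windows", {
  set.seed(71)
  f1 <- sample(c(0L, 2L), 600, replace = TRUE)
  f2 <- f1; f2[401:600] <- sample(c(0L, 2L), 200, replace = TRUE)
  f3 <- sample(c(0L, 2L), 600, replace = TRUE)
  gm <- toy_gm(cbind(f1 = f1, f2 = f2, f3 = f3),
               samples = c("f1", "f2", "f3"))
  w <- snp_windows(gm$sites, 200, 200)
  mask <- uninformative_window_mask(gm, c("f1", "f2", "f3"), w)
  expect_true(all(mask[1:2]))     # f1 == f2 over the first 400 sites
  expect_false(mask[3])
  expect_error(uninformative_window_mask(gm, "f1", w), ">= 2 founder")
})

test_that("segment detection attributes verbatim copies uniquely", {
  set.seed(81)
  pa <- sample(c(0L, 2L), 1000, replace = TRUE)
  pb <- sample(c(0L, 2L), 1000, replace = TRUE)
  gm <- toy_gm(cbind(d = pa, A = pa, B = pb), samples = c("d", "A", "B"))
  w <- snp_windows(gm$sites, 200, 20)
  seg <- detect_ibd_segments(gm, "d", c("A", "B"), w)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$sources, "A")
  expect_true(seg$unique)
  expect_equal(seg$start, gm$sites$pos[1])
  expect_equal(seg$end, gm$sites$pos[1000])
  # matching neither parent: empty
  dz <- sample(c(0L, 2L), 1000, replace = TRUE)
  gm2 <- toy_gm(cbind(d = dz, A = pa, B = pb), samples = c("d", "A", "B"))
  expect_equal(nrow(detect_ibd_segments(gm2, "d", c("A", "B"), w)), 0)
  expect_error(detect_ibd_segments(gm, "d", c("d", "A")), "descendant")
})

test_that("raising the ratio threshold never increases IBD bp", {
  cfg <- sim_config(genome = genome_map("A01", 2e6), snp_per_chrom = 3000,
                    pedigree = trio_pedigree(), seed = 91)
  sim <- simulate_pedigree_genotypes(cfg)
  gm <- sim$genotypes
  w <- snp_windows(gm$sites)
  bp <- sapply(c(0.90, 0.95, 0.99, 0.999), function(r) {
    seg <- detect_ibd_segments(gm, "C", c("P1", "P2"), w, ratio_min = r)
    if (nrow(seg)) interval_bp(seg[c("chrom", "start", "end")]) else 0
  })
  expect_true(all(diff(bp) <= 0))
  # overlay output is non-overlapping
  seg <- detect_ibd_segments(gm, "C", c("P1", "P2"), w)
  if (nrow(seg) > 1) {
    o <- order(seg$chrom, seg$start)
    s <- seg[o, ]
    expect_true(all(s$start[-1] > s$end[-nrow(s)] |
                      s$chrom[-1] != s$chrom[-nrow(s)]))
  }
})

test_that("contribution tracing accounts for every base pair", {
  # target cloned from the ancestor through two generations, no recombination
  ped <- pedigree_graph(
    nodes = data.frame(id = c("F", "M1", "M2"),
                       role = c("exotic_founder", "backbone", "elite")),
    edges = data.frame(parent = c("F", "M1"), child = c("M1", "M2")))
  cfg <- sim_config(genome = genome_map("A01", 1e6), snp_per_chrom = 2000,
                    pedigree = ped, recomb_rate = 0, error_rate = 0,
                    missing_rate = 0, seed = 7)
  sim <- simulate_pedigree_genotypes(cfg)
  gm <- sim$genotypes
  for (md in c("direct", "chained")) {
    tc <- trace_contributions(ped, gm, "M2", "F", mode = md)
    pct <- tc$report$pct[tc$report$ancestor == "F"]
    expect_gt(pct, 99)
    expect_equal(sum(tc$report$pct), 100, tolerance = 0.01)
  }
  expect_error(trace_contributions(ped, gm, "M1", "M2"), "ancestor")
})

test_that("chained-mode traced bp is a subset of direct-mode bp", {
  ped <- threegen_pedigree()
  cfg <- sim_config(genome = genome_map("A01", 5e6), snp_per_chrom = 5000,
                    pedigree = ped, seed = 13)
  sim <- simulate_pedigree_genotypes(cfg)
  gm <- sim$genotypes
  w <- snp_windows(gm$sites)
  for (g in c("GP1", "GP3")) {
    dir <- trace_contributions(ped, gm, "T", g, mode = "direct", windows = w)
    chn <- trace_contributions(ped, gm, "T", g, mode = "chained", windows = w)
    di <- dir$per_ancestor[[g]]; ci <- chn$per_ancestor[[g]]
    expect_lte(interval_bp(ci), interval_bp(di) + 1e-9)
    if (nrow(ci) && nrow(di)) {
      # every chained interval is contained in the direct set
      expect_equal(overlap_sets_bp(ci, di), interval_bp(ci))
    }
  }
})

test_that("direct IBD from a founder decays down the generations", {
  ped <- pedigree_graph(
    nodes = data.frame(id = c("F", "X1", "X2", "G1", "G2"),
                       role = c("exotic_founder", "exotic_founder",
                                "exotic_founder", "backbone", "elite")),
    edges = data.frame(parent = c("F", "X1", "G1", "X2"),
                       child = c("G1", "G1", "G2", "G2")))
  bp <- sapply(1:6, function(s) {
    cfg <- sim_config(genome = genome_map("A01", 5e6), snp_per_chrom = 5000,
                      pedigree = ped, seed = 100 + s)
    gm <- simulate_pedigree_genotypes(cfg)$genotypes
    w <- snp_windows(gm$sites)
    sapply(c("G1", "G2"), function(tg) {
      iv <- pedflow:::qualifying_intervals(gm, tg, "F", w)
      interval_bp(iv)
    })
  })
  expect_lte(mean(bp["G2", ]), mean(bp["G1", ]))
})

test_that("common-IBD intersection respects emptiness and identity", {
  a <- intervals("A01", c(1, 5e4), c(2e4, 9e4))
  expect_error(common_ibd_intersection(list()), "no segment sets")
  expect_equal(nrow(common_ibd_intersection(
    list(a, intervals(character(), numeric(), numeric())))), 0)
  same <- common_ibd_intersection(list(a, a, a), min_len = 1e4)
  expect_equal(same$start, a$start)
  expect_equal(same$end, a$end)
  # min_len filter drops short fragments
  b <- intervals("A01", c(1, 5e4), c(12000, 9e4))
  got <- common_ibd_intersection(list(a, b), min_len = 1e4)
  expect_equal(nrow(got), 2)
  got2 <- common_ibd_intersection(list(a, b), min_len = 2e4)
  expect_equal(nrow(got2), 1)
  expect_equal(got2$start, 5e4)
})
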