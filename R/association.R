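#' Genomic relationship (kinship) matrix
#'
#' VanRaden form: genotype codes are mean-imputed per site, centred at
#' `2p`, and the sample cross-product is scaled by `sum(2 p (1 - p))` over
#' the sites used; sites fixed after filtering are excluded.
#'
#' @param gm a `geno_matrix` (apply [filter_sites()] first).
#' @return symmetric n x n numeric matrix with sample dimnames.
#' @export
kinship_matrix <- function(gm) {
  g <- t(gm$geno)                       # samples x sites
  mu <- colMeans(g, na.rm = TRUE)
  g[is.na(g)] <- mu[col(g)[is.na(g)]]
  p <- mu / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic sites for kinship")
  Z <- sweep(g[, keep, drop = FALSE], 2, 2 * p[keep])
  K <- tcrossprod(Z) / sum(2 * p[keep] * (1 - p[keep]))
  dimnames(K) <- list(gm$samples, gm$samples)
  K
}

#' Genotype principal components
#'
#' Eigendecomposition of the mean-imputed, centred genotype covariance.
#' Components are ordered by descending eigenvalue and each component's
#' sign is fixed so its largest-magnitude site loading is positive.
#'
#' @param gm a `geno_matrix`.
#' @param k number of components (0 < k < n samples).
#' @return list with `scores` (n x k), `sdev`, `loadings`.
#' @export
genotype_pca <- function(gm, k = 3) {
  if (k <= 0) stop("k must be positive")
  n <- length(gm$samples)
  if (n <= k) stop("need more samples than components")
  g <- t(gm$geno)
  mu <- colMeans(g, na.rm = TRUE)
  g[is.na(g)] <- mu[col(g)[is.na(g)]]
  pc <- stats::prcomp(g, center = TRUE, scale. = FALSE, rank. = k)
  for (j in seq_len(k)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  rownames(pc$x) <- gm$samples
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       sdev = pc$sdev[seq_len(k)],
       loadings = pc$rotation[, seq_len(k), drop = FALSE])
}

# internal: profile log-likelihood of delta = sigma_e^2 / sigma_g^2 on
# eigen-rotated data (single variance component plus residual)
mlm_null_delta <- function(ys, Xs, d) {
  n <- length(ys)
  ll <- function(logd) {
    delta <- exp(logd)
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xs, Xs * w)
    beta <- solve(XtWX, crossprod(Xs, ys * w))
    r <- ys - Xs %*% beta
    s2 <- sum(w * r^2) / n
    -0.5 * (n * log(2 * pi * s2) + sum(log(d + delta)) + n)
  }
  opt <- stats::optimize(ll, c(-10, 10), maximum = TRUE)
  exp(opt$maximum)
}

#' Mixed-model candidate-SNP association scan
#'
#' Fits `y = mu + PCs b + marker a + u + e` with `cov(u) = sg^2 K` (the
#' PCA + K model). The variance ratio is estimated once under the null via
#' the eigendecomposition of K and reused for every marker (P3D);
#' per-marker effects are then generalized least squares with a Wald t test
#' on `n - p` residual degrees of freedom. With `K = NULL` (identity) and
#' no PCs the scan collapses exactly to ordinary least-squares marker
#' regression. `exact = TRUE` re-optimises the variance ratio per marker
#' instead.
#'
#' @param y numeric phenotype vector aligned with `gm$samples` (or named by
#'   accession).
#' @param gm a `geno_matrix`.
#' @param sites candidate site row indices (default: all sites).
#' @param pcs optional n x q matrix of covariates (e.g.
#'   `genotype_pca(gm)$scores`).
#' @param K optional kinship matrix from [kinship_matrix()].
#' @param exact per-marker variance-ratio re-estimation (slower).
#' @return data.frame `site`, `id`, `effect`, `se`, `p`, `neg_log10_p`;
#'   monomorphic markers are skipped with a message.
#' @export
mlm_scan <- function(y, gm, sites = seq_len(nrow(gm$sites)), pcs = NULL,
                     K = NULL, exact = FALSE) {
  n <- length(gm$samples)
  if (!is.null(names(y))) y <- y[gm$samples]
  if (length(y) != n || anyNA(y)) {
    stop("phenotype must align with the genotype samples, no missing values")
  }
  X0 <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(pcs)) X0 <- cbind(X0, as.matrix(pcs))
  if (qr(X0)$rank < ncol(X0)) stop("singular fixed-effect design")
  if (is.null(K)) {
    U <- NULL; d <- rep(1, n)          # identity relationship: no rotation
  } else {
    e <- eigen((K + t(K)) / 2, symmetric = TRUE)
    U <- e$vectors; d <- pmax(e$values, 0)
  }
  rot <- function(v) if (is.null(U)) v else crossprod(U, v)
  ys <- rot(y)
  X0s <- rot(X0)
  delta0 <- mlm_null_delta(ys, X0s, d)
  g <- gm$geno
  mu_site <- rowMeans(g, na.rm = TRUE)
  out <- list()
  for (s in sites) {
    x <- g[s, ]
    x[is.na(x)] <- mu_site[s]
    if (stats::var(x) == 0) {
      message("skipped monomorphic marker at row ", s)
      next
    }
    Xs <- cbind(X0s, marker = as.vector(rot(x)))
    delta <- if (exact) mlm_null_delta(ys, Xs, d) else delta0
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    ok <- tryCatch({ beta <- solve(XtWX, XtWy); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("singular fixed-effect design at marker row ", s)
    r <- ys - Xs %*% beta
    df <- n - ncol(Xs)
    s2 <- sum(w * r^2) / df
    covb <- s2 * solve(XtWX)
    j <- ncol(Xs)
    tval <- beta[j] / sqrt(covb[j, j])
    p <- 2 * stats::pt(-abs(tval), df)
    out[[length(out) + 1]] <- data.frame(
      site = s,
      id = paste0("SNP_", gm$sites$chrom[s], "_", gm$sites$pos[s]),
      effect = beta[j], se = sqrt(covb[j, j]), p = p,
      neg_log10_p = -log10(p), stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(site = integer(), id = character(), effect = numeric(),
                      se = numeric(), p = numeric(), neg_log10_p = numeric()))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Two-group phenotype comparison
#'
#' An F test for variance equality at the 0.05 level chooses between the
#' pooled-variance and Welch two-sample t tests; the two-sided p value is
#' returned with significance stars at 0.05 (`*`) and 0.01 (`**`).
#'
#' @param values numeric phenotype values.
#' @param groups factor/character of the same length with exactly two
#'   levels (both non-empty, >= 2 values each).
#' @return list: `t`, `p`, `means` (named), `method`, `stars`.
#' @export
group_phenotype_test <- function(values, groups) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("need exactly two groups")
  a <- values[groups == lev[1]]; b <- values[groups == lev[2]]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  means <- stats::setNames(c(mean(a), mean(b)), lev)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- means[1] == means[2]
    return(list(t = if (eq) 0 else Inf * sign(means[1] - means[2]),
                p = if (eq) 1 else 0, means = means,
                method = "degenerate", stars = if (eq) "" else "**"))
  }
  fp <- tryCatch(stats::var.test(a, b)$p.value, error = function(e) 0)
  pooled <- !is.na(fp) && fp >= 0.05
  tt <- stats::t.test(a, b, var.equal = pooled)
  stars <- if (tt$p.value < 0.01) "**" else if (tt$p.value < 0.05) "*" else ""
  list(t = unname(tt$statistic), p = tt$p.value, means = means,
       method = if (pooled) "pooled" else "welch", stars = stars)
}

#' Derive cotton yield traits
#'
#' Lint percentage is lint weight over seed-cotton weight x 100; the lint
#' index is the lint obtained from 100 seeds and the seed index the weight
#' of 100 seeds (seed weight = seed cotton minus lint). The identity
#' `lint_pct = 100 * LI / (LI + SI)` follows from the definitions.
#'
#' @param lint_weight lint weight, g (>= 0).
#' @param seed_cotton_weight seed-cotton weight, g (> 0, >= lint).
#' @param n_seeds seed count the sample corresponds to (> 0).
#' @return data.frame `lint_pct`, `lint_index`, `seed_index`.
#' @export
derive_yield_traits <- function(lint_weight, seed_cotton_weight, n_seeds) {
  if (any(seed_cotton_weight <= 0)) stop("seed-cotton weight must be > 0")
  if (any(lint_weight < 0)) stop("lint weight must be >= 0")
  if (any(lint_weight > seed_cotton_weight)) {
    stop("lint weight cannot exceed seed-cotton weight")
  }
  if (any(n_seeds <= 0)) stop("seed count must be > 0")
  data.frame(lint_pct = 100 * lint_weight / seed_cotton_weight,
             lint_index = 100 * lint_weight / n_seeds,
             seed_index = 100 * (seed_cotton_weight - lint_weight) / n_seeds)
}

#' Split accessions by genotype at a named SNP
#'
#' Returns the homozygous reference and homozygous alternate accession
#' sets at a site (id convention `SNP_<chrom>_<pos>`); heterozygotes are
#' excluded, matching genotype-group trait comparisons that contrast the
#' two homozygous classes.
#'
#' @param gm a `geno_matrix`.
#' @param snp_id site id string.
#' @return list with `hom_ref`, `hom_alt`, `het` accession id vectors.
#' @export
genotype_groups <- function(gm, snp_id) {
  ids <- paste0("SNP_", gm$sites$chrom, "_", gm$sites$pos)
  s <- match(snp_id, ids)
  if (is.na(s)) stop("unknown SNP id: ", snp_id)
  g <- gm$geno[s, ]
  list(hom_ref = gm$samples[!is.na(g) & g == 0],
       hom_alt = gm$samples[!is.na(g) & g == 2],
       het = gm$samples[!is.na(g) & g == 1])
}
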