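#' SNP-count sliding windows
#'
#' Windows of `size` consecutive SNPs advancing by `step` SNPs, never
#' crossing a chromosome boundary. Because starts advance by `step`, the
#' tail beyond the last full window is always shorter than one step and is
#' never emitted separately; a chromosome with fewer sites than one full
#' window yields a single truncated window (flagged) iff it has at least
#' `step` sites, and nothing otherwise.
#'
#' @param sites site data.frame (`chrom`, `pos`), position-sorted.
#' @param size,step window and step in SNPs (`size >= step >= 1`).
#' @return data.frame `chrom`, `win`, `first`, `last` (global site row
#'   indices), `start`, `end` (bp of first/last site), `n_sites`,
#'   `truncated`.
#' @export
snp_windows <- function(sites, size = 200, step = 20) {
  if (size < step) stop("window size must be >= step")
  if (step < 1) stop("step must be >= 1")
  out <- list()
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    n <- length(idx)
    if (n >= size) {
      # full windows only: the tail beyond the last full window is always
      # shorter than one step (starts advance by step)
      first <- seq(1, n - size + 1, by = step)
      last <- first + size - 1
      trunc <- rep(FALSE, length(first))
    } else if (n >= step) {
      first <- 1; last <- n; trunc <- TRUE   # short chromosome: one
    } else next                              # truncated window, or none
    out[[ch]] <- data.frame(
      chrom = ch, win = seq_along(first),
      first = idx[first], last = idx[last],
      start = sites$pos[idx[first]], end = sites$pos[idx[last]],
      n_sites = last - first + 1, truncated = trunc,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), win = integer(), first = integer(),
                      last = integer(), start = numeric(), end = numeric(),
                      n_sites = integer(), truncated = logical()))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# internal: windowed identical/compared counts between two samples via
# cumulative sums over the global site order (windows never cross chroms)
pair_window_counts <- function(gm, a, b, windows) {
  ga <- gm$geno[, a]; gb <- gm$geno[, b]
  ok <- !is.na(ga) & !is.na(gb)
  same <- ok & ga == gb
  cs_ok <- c(0, cumsum(ok)); cs_same <- c(0, cumsum(same))
  n_compared <- cs_ok[windows$last + 1] - cs_ok[windows$first]
  n_identical <- cs_same[windows$last + 1] - cs_same[windows$first]
  list(compared = n_compared, identical = n_identical)
}

#' Sliding-window SNP identity ratio between two accessions
#'
#' Per window, the compared sites are those non-missing in both accessions
#' and the ratio is the fraction with the same unordered genotype code. A
#' window qualifies as an IBD candidate iff the ratio is at least
#' `ratio_min` (default 0.99) and at least `min_informative` sites were
#' compared; windows with no compared sites are flagged uninformative.
#'
#' @param gm a `geno_matrix`.
#' @param descendant,parent sample ids.
#' @param windows from [snp_windows()] (default 200/20 over `gm$sites`).
#' @param ratio_min qualification threshold on the identity ratio.
#' @param min_informative minimum compared sites (default half the window).
#' @return `windows` extended with `n_compared`, `n_identical`, `ratio`,
#'   `qualifies`, `uninformative`.
#' @export
identity_ratio_scan <- function(gm, descendant, parent,
                                windows = snp_windows(gm$sites),
                                ratio_min = 0.99, min_informative = 100) {
  stopifnot(descendant %in% gm$samples, parent %in% gm$samples)
  cnt <- pair_window_counts(gm, descendant, parent, windows)
  windows$n_compared <- cnt$compared
  windows$n_identical <- cnt$identical
  windows$ratio <- ifelse(cnt$compared > 0, cnt$identical / cnt$compared, NA)
  windows$uninformative <- cnt$compared == 0
  windows$qualifies <- !windows$uninformative &
    windows$ratio >= ratio_min & cnt$compared >= min_informative
  windows
}

#' Mask windows uninformative for origin tracing
#'
#' A window is masked iff any pair of the designated founder accessions is
#' mutually near-identical there (within-window identity at or above
#' `identity_cutoff`): where candidate sources are indistinguishable, a
#' match to a descendant cannot be attributed.
#'
#' @param gm a `geno_matrix`.
#' @param founders at least two founder sample ids.
#' @param windows from [snp_windows()].
#' @param identity_cutoff founder-pair identity threshold (default 0.99,
#'   mirroring the IBD qualification threshold).
#' @return logical mask, `TRUE` = uninformative.
#' @export
uninformative_window_mask <- function(gm, founders,
                                      windows = snp_windows(gm$sites),
                                      identity_cutoff = 0.99) {
  if (length(founders) < 2) stop("need >= 2 founder accessions")
  mask <- rep(FALSE, nrow(windows))
  for (i in seq_len(length(founders) - 1)) {
    for (j in (i + 1):length(founders)) {
      cnt <- pair_window_counts(gm, founders[i], founders[j], windows)
      r <- ifelse(cnt$compared > 0, cnt$identical / cnt$compared, NA)
      mask <- mask | (!is.na(r) & r >= identity_cutoff)
    }
  }
  mask
}

# internal: merged bp intervals of qualifying unmasked windows for one
# descendant-parent pair; windows merge when their site spans overlap/abut
qualifying_intervals <- function(gm, descendant, parent, windows, mask = NULL,
                                 ratio_min = 0.99, min_informative = 100,
                                 min_run = 1) {
  sc <- identity_ratio_scan(gm, descendant, parent, windows,
                            ratio_min, min_informative)
  q <- sc$qualifies
  if (!is.null(mask)) q <- q & !mask
  keep <- which(q)
  if (!length(keep)) return(intervals(character(), numeric(), numeric()))
  w <- sc[keep, ]
  w <- w[order(w$chrom, w$first), ]
  runs <- list(); cur <- w[1, ]; run_n <- 1
  flush <- function(cur, run_n) if (run_n >= min_run)
    data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
               stringsAsFactors = FALSE) else NULL
  out <- list()
  if (nrow(w) > 1) for (i in 2:nrow(w)) {
    nx <- w[i, ]
    if (nx$chrom == cur$chrom && nx$first <= cur$last + 1) {
      cur$last <- max(cur$last, nx$last); cur$end <- max(cur$end, nx$end)
      run_n <- run_n + 1
    } else {
      out[[length(out) + 1]] <- flush(cur, run_n); cur <- nx; run_n <- 1
    }
  }
  out[[length(out) + 1]] <- flush(cur, run_n)
  out <- do.call(rbind, out)
  if (is.null(out)) intervals(character(), numeric(), numeric()) else out
}

# internal: overlay per-source interval sets into disjoint segments with
# source attribution; returns descendant IBD segment table
overlay_sources <- function(iv_by_source, gm, descendant) {
  empty <- data.frame(descendant = character(), chrom = character(),
                      start = numeric(), end = numeric(), n_snps = integer(),
                      sources = character(), n_sources = integer(),
                      unique = logical(), stringsAsFactors = FALSE)
  iv_by_source <- Filter(function(x) nrow(x) > 0, iv_by_source)
  if (!length(iv_by_source)) return(empty)
  grs <- lapply(iv_by_source, as_gr)
  all_gr <- GenomicRanges::disjoin(do.call(c, unname(grs)))
  if (!length(all_gr)) return(empty)
  cover <- vapply(grs, function(g)
    IRanges::overlapsAny(all_gr, g), logical(length(all_gr)))
  cover <- matrix(cover, nrow = length(all_gr))
  piece <- gr_to_iv(all_gr)
  src <- apply(cover, 1, function(z) paste(names(iv_by_source)[z],
                                           collapse = ","))
  nsrc <- rowSums(cover)
  n_snps <- vapply(seq_len(nrow(piece)), function(i)
    sum(gm$sites$chrom == piece$chrom[i] & gm$sites$pos >= piece$start[i] &
          gm$sites$pos <= piece$end[i]), 0)
  out <- data.frame(descendant = descendant, chrom = piece$chrom,
                    start = piece$start, end = piece$end, n_snps = n_snps,
                    sources = src, n_sources = nsrc, unique = nsrc == 1,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), ]
}

#' Detect IBD segments between a descendant and candidate parents
#'
#' Per candidate parent, qualifying unmasked identity-ratio windows are
#' merged into runs (site spans overlapping or abutting) whose segment
#' spans the first through last SNP position. Per-parent segments are then
#' overlaid: base-pair regions qualifying for exactly one parent are
#' `unique`, regions qualifying for several carry the full source set.
#'
#' @param gm a `geno_matrix`.
#' @param descendant sample id.
#' @param parents candidate source sample ids (must not include the
#'   descendant).
#' @param windows from [snp_windows()]; defaults to 200/20 windows.
#' @param mask optional logical mask from [uninformative_window_mask()].
#' @param ratio_min,min_informative,min_run window qualification parameters.
#' @return data.frame of IBD segments: `descendant`, `chrom`, `start`,
#'   `end`, `n_snps`, `sources`, `n_sources`, `unique`.
#' @export
detect_ibd_segments <- function(gm, descendant, parents,
                                windows = snp_windows(gm$sites),
                                mask = NULL, ratio_min = 0.99,
                                min_informative = 100, min_run = 1) {
  if (descendant %in% parents) {
    stop("descendant cannot be among the candidate parents")
  }
  iv <- lapply(stats::setNames(parents, parents), function(p)
    qualifying_intervals(gm, descendant, p, windows, mask,
                         ratio_min, min_informative, min_run))
  overlay_sources(iv, gm, descendant)
}

#' Trace genomic contributions of ancestors to a target accession
#'
#' In `direct` mode, IBD segments are detected between the target and each
#' ancestor independently. In `chained` mode, a region counts for an
#' ancestor only if a qualifying segment covers it at every parent-child
#' link of some pedigree path from the ancestor down to the target (stable
#' transmission) and it is also directly IBD between target and ancestor;
#' the second condition makes chained tracing a refinement of direct
#' tracing at window resolution. Contributions are the unique (single-source) bp per
#' ancestor as a percentage of the total genome; multi-source bp is
#' reported as shared and the remainder as unknown.
#'
#' @param ped the `pedigree`.
#' @param gm a `geno_matrix` containing target and ancestors.
#' @param target sample id.
#' @param ancestors ancestor ids (must be pedigree ancestors of `target`).
#' @param mode `"direct"` or `"chained"`.
#' @param windows,mask,ratio_min,min_informative,min_run see
#'   [detect_ibd_segments()].
#' @return list with `segments` (overlaid segment table), `per_ancestor`
#'   (interval list) and `report` (data.frame of unique/shared bp and
#'   percentages plus the unknown remainder).
#' @export
trace_contributions <- function(ped, gm, target, ancestors,
                                mode = c("direct", "chained"),
                                windows = snp_windows(gm$sites), mask = NULL,
                                ratio_min = 0.99, min_informative = 100,
                                min_run = 1) {
  mode <- match.arg(mode)
  anc_all <- pedigree_ancestors(ped, target)
  bad <- setdiff(ancestors, anc_all)
  if (length(bad)) {
    stop("not a pedigree ancestor of ", target, ": ", bad[1])
  }
  per_anc <- stats::setNames(vector("list", length(ancestors)), ancestors)
  for (anc in ancestors) {
    if (mode == "direct") {
      per_anc[[anc]] <- qualifying_intervals(gm, target, anc, windows, mask,
                                             ratio_min, min_informative,
                                             min_run)
    } else {
      paths <- pedigree_paths(ped, anc, target)
      acc <- NULL
      for (pth in paths) {
        cur <- NULL
        ok <- TRUE
        for (k in seq_len(length(pth) - 1)) {
          link <- qualifying_intervals(gm, pth[k + 1], pth[k], windows, mask,
                                       ratio_min, min_informative, min_run)
          if (nrow(link) == 0) { ok <- FALSE; break }
          cur <- if (is.null(cur)) link else
            gr_to_iv(GenomicRanges::intersect(as_gr(cur), as_gr(link)))
          if (nrow(cur) == 0) { ok <- FALSE; break }
        }
        if (ok && !is.null(cur) && nrow(cur)) {
          acc <- if (is.null(acc)) cur else rbind(acc, cur)
        }
      }
      if (is.null(acc)) {
        per_anc[[anc]] <- intervals(character(), numeric(), numeric())
      } else {
        # stable transmission refines direct detection: intersecting with
        # the direct target-ancestor set keeps chained bp a subset of
        # direct bp despite window-resolution over-extension at segment
        # boundaries
        direct <- qualifying_intervals(gm, target, anc, windows, mask,
                                       ratio_min, min_informative, min_run)
        acc <- merge_intervals(acc, 0)
        per_anc[[anc]] <- if (nrow(direct) == 0) direct else
          gr_to_iv(GenomicRanges::intersect(as_gr(acc), as_gr(direct)))
      }
    }
  }
  seg <- overlay_sources(per_anc, gm, target)
  genome_bp <- sum(gm$genome$length)
  uni_bp <- vapply(ancestors, function(a)
    sum(seg$end[seg$unique & seg$sources == a] -
          seg$start[seg$unique & seg$sources == a] + 1), 0)
  shared_bp <- sum(seg$end[!seg$unique] - seg$start[!seg$unique] + 1)
  report <- data.frame(ancestor = ancestors, unique_bp = uni_bp,
                       pct = 100 * uni_bp / genome_bp,
                       stringsAsFactors = FALSE)
  report <- rbind(report,
                  data.frame(ancestor = "shared", unique_bp = shared_bp,
                             pct = 100 * shared_bp / genome_bp),
                  data.frame(ancestor = "unknown",
                             unique_bp = genome_bp - sum(uni_bp) - shared_bp,
                             pct = 100 - 100 * (sum(uni_bp) + shared_bp) /
                               genome_bp))
  rownames(report) <- NULL
  list(segments = seg, per_ancestor = per_anc, report = report)
}

#' Intersect IBD segments across descendants
#'
#' Base-pair intersection of the segment sets of several descendants (all
#' traced from the same ancestor); fragments of at least `min_len` bp are
#' retained. If any descendant's set is empty the intersection is empty.
#'
#' @param segment_sets list of interval data.frames, one per descendant.
#' @param min_len minimum fragment length in bp (default 10 kb).
#' @return interval data.frame of common IBD fragments.
#' @export
common_ibd_intersection <- function(segment_sets, min_len = 1e4) {
  if (!length(segment_sets)) stop("no segment sets supplied")
  empty <- intervals(character(), numeric(), numeric())
  if (any(vapply(segment_sets, nrow, 0L) == 0)) return(empty)
  gr <- as_gr(segment_sets[[1]])
  for (s in segment_sets[-1]) {
    gr <- GenomicRanges::intersect(gr, as_gr(s))
    if (!length(gr)) return(empty)
  }
  out <- gr_to_iv(gr)
  out <- out[out$end - out$start + 1 >= min_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export IBD segments
#'
#' Writes the rich 1-based TSV and, optionally, a BED (0-based half-open)
#' of the segment intervals.
#'
#' @param segments table from [detect_ibd_segments()].
#' @param path TSV output path.
#' @param bed_path optional BED output path.
#' @export
write_ibd_segments <- function(segments, path, bed_path = NULL) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed_path)) {
    iv <- segments[c("chrom", "start", "end")]
    iv$name <- segments$sources
    write_bed(iv, bed_path)
  }
  invisible(path)
}
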