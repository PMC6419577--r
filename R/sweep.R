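#' Pi-ratio selective sweep scan
#'
#' Flags windows in the upper tail of `log10(pi_wild / pi_ped)`. The
#' threshold is the empirical `1 - quantile` quantile of the finite
#' log-ratios; windows at or above it are flagged (ties inclusive). A window
#' with `pi_ped = 0` and `pi_wild > 0` has ratio `+Inf` and is always
#' flagged; windows where both groups are invariant are excluded from the
#' quantile and never flagged.
#'
#' @param pi_wild,pi_ped aligned window tables from [pi_scan()] (identical
#'   intervals).
#' @param quantile upper-tail fraction (default 0.05).
#' @return data.frame with the window interval, `pi_wild`, `pi_ped`,
#'   `log10_ratio` and `pi_flagged`; threshold in attribute `threshold`.
#' @export
pi_ratio_scan <- function(pi_wild, pi_ped, quantile = 0.05) {
  if (!identical(pi_wild[c("chrom", "start", "end")],
                 pi_ped[c("chrom", "start", "end")])) {
    stop("window lists are not aligned on identical intervals")
  }
  out <- pi_wild[c("chrom", "start", "end")]
  out$pi_wild <- pi_wild$value
  out$pi_ped <- pi_ped$value
  out$log10_ratio <- log10(out$pi_wild / out$pi_ped)
  out$log10_ratio[out$pi_ped == 0 & out$pi_wild > 0] <- Inf
  out$log10_ratio[out$pi_ped == 0 & out$pi_wild == 0] <- NaN
  fin <- is.finite(out$log10_ratio)
  thr <- if (any(fin)) stats::quantile(out$log10_ratio[fin], 1 - quantile,
                                       names = FALSE) else Inf
  out$pi_flagged <- (fin & out$log10_ratio >= thr) |
    (is.infinite(out$log10_ratio) & out$log10_ratio > 0)
  attr(out, "threshold") <- thr
  out
}

#' Extended haplotype homozygosity curve from one core site
#'
#' EHH at a marker x is the fraction of haplotype pairs identical at every
#' marker between the core and x (x included, the core excluded), so
#' EHH(0) = 1 and the curve is non-increasing outward. Evaluation proceeds
#' in one direction until EHH < `min_ehh`, the chromosome's site set ends,
#' or `max_extend` bp is reached; the truncation reason is recorded.
#'
#' @param hm a `hap_matrix` (phased; >= 2 haplotypes).
#' @param core site row index of the core.
#' @param direction `"right"` (increasing position) or `"left"`.
#' @param min_ehh truncation threshold (default 0.05).
#' @param max_extend maximum extension in bp (default 200 kb).
#' @return data.frame `pos`, `distance`, `ehh` (first row the core itself),
#'   with attribute `truncation` in `threshold`, `chrom_end`, `window_end`.
#' @export
ehh_curve <- function(hm, core, direction = c("right", "left"),
                      min_ehh = 0.05, max_extend = 2e5) {
  if (!inherits(hm, "hap_matrix")) {
    stop("EHH needs phased haplotypes; simulate or supply a phased panel")
  }
  direction <- match.arg(direction)
  dir <- if (direction == "right") 1L else -1L
  idx <- which(hm$sites$chrom == hm$sites$chrom[core])
  lo <- min(idx); hi <- max(idx)
  H <- ncol(hm$hap)
  if (H < 2) stop("need >= 2 haplotypes")
  pairs_all <- H * (H - 1) / 2
  grp <- rep(1L, H)
  pos0 <- hm$sites$pos[core]
  out <- data.frame(pos = pos0, distance = 0, ehh = 1)
  reason <- "chrom_end"
  s <- core + dir
  while (s >= lo && s <= hi) {
    d <- abs(hm$sites$pos[s] - pos0)
    if (d > max_extend) { reason <- "window_end"; break }
    grp <- match(paste(grp, hm$hap[s, ]), unique(paste(grp, hm$hap[s, ])))
    cnt <- tabulate(grp)
    ehh <- sum(cnt * (cnt - 1) / 2) / pairs_all
    out <- rbind(out, data.frame(pos = hm$sites$pos[s], distance = d,
                                 ehh = ehh))
    if (ehh < min_ehh) { reason <- "threshold"; break }
    s <- s + dir
  }
  attr(out, "truncation") <- reason
  out
}

#' Cross-population EHH (XP-EHH) scan
#'
#' Per site, iHH is the trapezoidal integral of the whole-panel EHH curve
#' over physical distance, both directions summed; the raw score is
#' `ln(iHH_ped / iHH_wild)` and is standardised to zero mean and unit SD
#' genome-wide. Window scores are the maximum standardised score among the
#' window's sites (mean available via `aggregate = "mean"`), and windows in
#' the top `quantile` are flagged (ties inclusive). Sites with
#' `iHH_wild = 0` or a non-finite raw score are skipped and counted.
#'
#' @param hap_ped,hap_wild `hap_matrix` panels over identical site sets.
#' @param genome a [genome_map()].
#' @param window,step window grid in bp (default 100 kb tiling).
#' @param quantile upper-tail fraction for flagging (default 0.05).
#' @param min_ehh,max_extend EHH truncation (see [ehh_curve()]).
#' @param aggregate `"max"` (default) or `"mean"` window aggregation.
#' @return list with `sites` (per-site iHHs, `raw`, `std`) and `windows`
#'   (grid with `score`, `xpehh_flagged`); skipped-site count in attribute
#'   `n_skipped` of `sites`.
#' @export
xpehh_scan <- function(hap_ped, hap_wild, genome = hap_ped$genome,
                       window = 1e5, step = window, quantile = 0.05,
                       min_ehh = 0.05, max_extend = 2e5,
                       aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!identical(hap_ped$sites[c("chrom", "pos")],
                 hap_wild$sites[c("chrom", "pos")])) {
    stop("panels must share an identical site set")
  }
  chrom_id <- as.integer(factor(hap_ped$sites$chrom,
                                levels = unique(hap_ped$sites$chrom)))
  ihh_p <- .ihh_scan_cpp(hap_ped$hap, hap_ped$sites$pos, chrom_id,
                         min_ehh, max_extend)
  ihh_w <- .ihh_scan_cpp(hap_wild$hap, hap_wild$sites$pos, chrom_id,
                         min_ehh, max_extend)
  raw <- rep(NA_real_, length(ihh_p))
  usable <- ihh_w > 0 & ihh_p > 0
  raw[usable] <- log(ihh_p[usable] / ihh_w[usable])
  n_skip <- sum(!usable)
  if (n_skip > 0) message("skipped ", n_skip, " site(s) with zero iHH")
  mu <- mean(raw, na.rm = TRUE)
  sdv <- stats::sd(raw, na.rm = TRUE)
  std <- if (isTRUE(sdv > 0)) (raw - mu) / sdv else raw - mu
  sites <- data.frame(chrom = hap_ped$sites$chrom, pos = hap_ped$sites$pos,
                      ihh_ped = ihh_p, ihh_wild = ihh_w, raw = raw,
                      std = std, stringsAsFactors = FALSE)
  attr(sites, "n_skipped") <- n_skip
  grid <- window_grid(genome, window, step)
  agg <- if (aggregate == "max") function(v) if (all(is.na(v))) NA_real_
    else max(v, na.rm = TRUE)
    else function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  score <- rep(NA_real_, nrow(grid))
  for (ch in unique(grid$chrom)) {
    gi <- which(grid$chrom == ch)
    si <- which(sites$chrom == ch)
    pos <- sites$pos[si]; v <- std[si]
    lo <- findInterval(grid$start[gi] - 1, pos)
    hi <- findInterval(grid$end[gi], pos)
    score[gi] <- vapply(seq_along(gi), function(k) {
      if (hi[k] <= lo[k]) NA_real_ else agg(v[(lo[k] + 1):hi[k]])
    }, 0)
  }
  grid$score <- score
  thr <- stats::quantile(score, 1 - quantile, na.rm = TRUE, names = FALSE)
  grid$xpehh_flagged <- !is.na(score) & score >= thr
  attr(grid, "threshold") <- thr
  list(sites = sites, windows = grid)
}

#' Confirm pi-ratio sweeps with XP-EHH
#'
#' A window is a confirmed sweep iff it is flagged by both the pi-ratio
#' scan and the XP-EHH scan on the same window grid; adjacent confirmed
#' windows are merged into sweep segments (bridging one step).
#'
#' @param pi_windows output of [pi_ratio_scan()].
#' @param xpehh_windows `$windows` of [xpehh_scan()] on the same grid.
#' @param step the grid step in bp (merge gap).
#' @return list with `windows` (flags and `confirmed`) and `segments`
#'   (merged confirmed intervals).
#' @export
confirm_sweeps <- function(pi_windows, xpehh_windows, step = 2e4) {
  if (!identical(pi_windows[c("chrom", "start", "end")],
                 xpehh_windows[c("chrom", "start", "end")])) {
    stop("window grids are not aligned")
  }
  w <- pi_windows
  w$xpehh_flagged <- xpehh_windows$xpehh_flagged
  w$confirmed <- w$pi_flagged & w$xpehh_flagged
  seg <- if (any(w$confirmed)) {
    merge_intervals(w[w$confirmed, c("chrom", "start", "end")],
                    max_gap = step)
  } else intervals(character(), numeric(), numeric())
  list(windows = w, segments = seg)
}
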