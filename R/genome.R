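#' Genome coordinate map
#'
#' Defines the chromosome naming and length context shared by every scan in
#' the package. Chromosome names in the "A1"/"D13" dialect common for
#' allotetraploid cotton are normalized to zero-padded form ("A01"), and the
#' sub-genome label (the leading letter block) is derived from the name.
#'
#' @param chrom character vector of chromosome names (unique).
#' @param length integer vector of chromosome lengths in base pairs (> 0).
#' @return A `genome_map` data.frame with columns `chrom`, `length`,
#'   `subgenome`.
#' @examples
#' genome_map(c("A1", "D2"), c(1e6, 2e6))
#' @export
genome_map <- function(chrom, length) {
  chrom <- norm_chrom(as.character(chrom))
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  sub <- sub("^([A-Za-z]+).*$", "\\1", chrom)
  sub[!grepl("^[A-Za-z]", chrom)] <- NA_character_
  out <- data.frame(chrom = chrom, length = length, subgenome = sub,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_map", "data.frame")
  out
}

#' Normalize chromosome names
#'
#' Accepts both "A1" and "A01" spellings and returns the zero-padded form.
#' Names that do not end in a bare number are returned unchanged.
#'
#' @param x character vector.
#' @return character vector of normalized names.
#' @export
norm_chrom <- function(x) {
  x <- as.character(x)
  m <- grepl("^([A-Za-z]+)([0-9]+)$", x)
  pre <- sub("^([A-Za-z]+)([0-9]+)$", "\\1", x[m])
  num <- as.integer(sub("^([A-Za-z]+)([0-9]+)$", "\\2", x[m]))
  x[m] <- paste0(pre, sprintf("%02d", num))
  x
}

#' Construct a set of genomic intervals
#'
#' Intervals are 1-based and end-inclusive throughout the package; BED export
#' converts to 0-based half-open at the boundary only.
#'
#' @param chrom,start,end vectors of equal length.
#' @param genome optional [genome_map()] to validate against.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
intervals <- function(chrom, start, end, genome = NULL) {
  out <- data.frame(chrom = norm_chrom(chrom), start = as.numeric(start),
                    end = as.numeric(end), stringsAsFactors = FALSE)
  if (nrow(out) && any(out$start > out$end)) stop("interval start > end")
  if (nrow(out) && any(out$start < 1)) stop("coordinates are 1-based")
  if (!is.null(genome)) {
    i <- match(out$chrom, genome$chrom)
    if (anyNA(i)) stop("unknown chromosome: ", out$chrom[which(is.na(i))[1]])
    if (any(out$end > genome$length[i])) stop("interval beyond chromosome end")
  }
  out
}

# internal: 1-based inclusive data.frame <-> GRanges
as_gr <- function(iv) {
  GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start, iv$end))
}
gr_to_iv <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Base pairs shared by two intervals
#'
#' Vectorised over rows (shorter argument recycled). Returns 0 when the
#' chromosomes differ or the intervals are disjoint; coordinates are 1-based
#' inclusive, so `overlap_bp` of `[1,100]` and `[100,200]` is 1.
#'
#' @param a,b interval data.frames (see [intervals()]).
#' @return numeric vector of overlap lengths in bp.
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  same <- norm_chrom(a$chrom[ia]) == norm_chrom(b$chrom[ib])
  ov <- pmin(a$end[ia], b$end[ib]) - pmax(a$start[ia], b$start[ib]) + 1
  ifelse(same, pmax(ov, 0), 0)
}

#' Total base pairs covered by a set of intervals
#' @param iv interval data.frame.
#' @return numeric scalar (bp), overlaps counted once per row.
#' @export
interval_bp <- function(iv) if (nrow(iv) == 0) 0 else sum(iv$end - iv$start + 1)

#' Merge intervals closer than a gap
#'
#' Produces a sorted, pairwise non-overlapping set in which two input
#' intervals are joined iff the gap between them is at most `max_gap` bp
#' (`max_gap = 0` joins touching/overlapping intervals only).
#'
#' @param iv interval data.frame.
#' @param max_gap maximum bridged gap in bp (>= 0).
#' @return merged interval data.frame, sorted by chromosome then start.
#' @export
merge_intervals <- function(iv, max_gap = 0) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (nrow(iv) == 0) return(intervals(character(), numeric(), numeric()))
  gr <- GenomicRanges::reduce(as_gr(iv), min.gapwidth = max_gap + 1)
  out <- gr_to_iv(GenomicRanges::sort(gr))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Feature annotation set
#'
#' Reads a BED-like TSV of genomic features (genes, QTL intervals, GWAS
#' sites) with columns `chrom`, `start0` (0-based), `end`, `kind`, `name`,
#' `trait` (optional, blank allowed). Coordinates are converted to the
#' package-internal 1-based inclusive convention.
#'
#' @param path TSV file path.
#' @param genome optional [genome_map()] for validation.
#' @return data.frame with columns `chrom`, `start`, `end`, `kind`, `name`,
#'   `trait`.
#' @export
read_features <- function(path, genome = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  need <- c("chrom", "start0", "end", "kind", "name")
  if (!all(need %in% names(df))) {
    stop("feature file needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$trait)) df$trait <- NA_character_
  iv <- intervals(df$chrom, df$start0 + 1, df$end, genome)
  cbind(iv, df[c("kind", "name", "trait")])
}

#' @rdname read_features
#' @param features feature data.frame as returned by `read_features`.
#' @export
write_features <- function(features, path) {
  out <- data.frame(chrom = features$chrom, start0 = features$start - 1,
                    end = features$end, kind = features$kind,
                    name = features$name, trait = features$trait)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Overlap segments with annotated features
#'
#' Reports every (segment, feature) pair sharing at least `min_bp` base
#' pairs; used to ask which genes or QTLs fall inside detected IBD or sweep
#' segments.
#'
#' @param segments interval data.frame.
#' @param features feature data.frame (see [read_features()]).
#' @param min_bp minimum overlap to report (default 1).
#' @return data.frame with the segment coordinates, feature name/kind/trait
#'   and the shared bp, one row per qualifying pair.
#' @export
overlap_features <- function(segments, features, min_bp = 1) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      feature = character(), kind = character(),
                      trait = character(), overlap_bp = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(segments) == 0 || nrow(features) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(as_gr(segments), as_gr(features),
                                      minoverlap = min_bp)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  data.frame(chrom = segments$chrom[qi], start = segments$start[qi],
             end = segments$end[qi], feature = features$name[si],
             kind = features$kind[si], trait = features$trait[si],
             overlap_bp = overlap_bp(segments[qi, , drop = FALSE],
                                     features[si, , drop = FALSE]),
             stringsAsFactors = FALSE)
}

#' Export intervals as BED
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param iv interval data.frame; extra columns beyond chrom/start/end are
#'   written as BED name column if a `name` column exists.
#' @param path output file.
#' @export
write_bed <- function(iv, path) {
  name <- if (!is.null(iv$name)) iv$name else rep(".", nrow(iv))
  out <- data.frame(iv$chrom, format(iv$start - 1, scientific = FALSE, trim = TRUE),
                    format(iv$end, scientific = FALSE, trim = TRUE), name)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
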