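#' Classify SNP effects against a coding annotation
#'
#' Each site gets exactly one region class — `exon`, `intron`, `upstream`,
#' `downstream` or `intergenic` (priority in that order; up/downstream are
#' strand-aware within a fixed flank of the gene bounds). For sites inside a
#' CDS the reference and alternate codons are translated under the standard
#' genetic code: `stop_gained` when only the alternate codon is a stop,
#' `stop_lost` when only the reference is, otherwise `synonymous` iff the
#' amino acids agree and `nonsynonymous` if they differ.
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt` (e.g.
#'   `gm$sites`).
#' @param gff GFF3 file path (gene/mRNA/CDS/exon records with strand and
#'   phase) or a `GRanges` as returned by `rtracklayer::import()`.
#' @param fasta reference FASTA path or a [Biostrings::DNAStringSet].
#' @param flank upstream/downstream flank in bp (default 2000).
#' @return data.frame with columns `chrom`, `pos`, `region`, `effect`,
#'   `gene`.
#' @export
annotate_snp_effects <- function(sites, gff, fasta, flank = 2000) {
  if (is.character(gff)) gff <- rtracklayer::import(gff)
  if (is.character(fasta)) fasta <- Biostrings::readDNAStringSet(fasta)
  names(fasta) <- sub("\\s.*", "", names(fasta))
  type <- as.character(gff$type)
  ids <- if (!is.null(gff$ID)) as.character(gff$ID) else rep(NA, length(gff))
  parent <- if (!is.null(gff$Parent)) {
    vapply(gff$Parent, function(p) if (length(p)) as.character(p)[1]
           else NA_character_, "")
  } else rep(NA_character_, length(gff))
  # climb Parent links until a gene record is reached
  gene_of <- function(i) {
    while (!is.na(i) && type[i] != "gene") {
      p <- parent[i]
      i <- if (is.na(p)) NA_integer_ else match(p, ids)
    }
    if (is.na(i)) NA_character_ else ids[i]
  }
  feat_gene <- vapply(seq_along(gff), gene_of, "")
  genes <- gff[type == "gene"]
  gene_ids <- ids[type == "gene"]
  cds <- gff[type == "CDS"]
  cds_gene <- feat_gene[type == "CDS"]
  exons <- if (any(type == "exon")) gff[type == "exon"] else cds
  exon_gene <- if (any(type == "exon")) feat_gene[type == "exon"] else cds_gene

  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, sites$pos))
  n <- nrow(sites)
  region <- rep("intergenic", n)
  effect <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)

  first_hit <- function(gr) {
    h <- GenomicRanges::findOverlaps(sgr, gr, select = "first",
                                     ignore.strand = TRUE)
    h
  }
  # flanks, strand-aware
  up <- GenomicRanges::flank(genes, flank, start = TRUE)
  dn <- GenomicRanges::flank(genes, flank, start = FALSE)
  hu <- first_hit(up); hd <- first_hit(dn)
  region[!is.na(hd)] <- "downstream"; gene[!is.na(hd)] <- gene_ids[hd[!is.na(hd)]]
  region[!is.na(hu)] <- "upstream";  gene[!is.na(hu)] <- gene_ids[hu[!is.na(hu)]]
  hg <- first_hit(genes)
  region[!is.na(hg)] <- "intron";    gene[!is.na(hg)] <- gene_ids[hg[!is.na(hg)]]
  he <- first_hit(exons)
  region[!is.na(he)] <- "exon";      gene[!is.na(he)] <- exon_gene[he[!is.na(he)]]

  hc <- first_hit(cds)
  for (i in which(!is.na(hc))) {
    g <- cds_gene[hc[i]]
    pieces <- cds[cds_gene == g]
    pieces <- pieces[order(GenomicRanges::start(pieces))]
    minus <- as.character(GenomicRanges::strand(pieces))[1] == "-"
    pos_map <- unlist(lapply(seq_along(pieces), function(k)
      seq(GenomicRanges::start(pieces)[k], GenomicRanges::end(pieces)[k])))
    chr <- as.character(GenomicRanges::seqnames(pieces))[1]
    seq_fwd <- paste(vapply(seq_along(pieces), function(k)
      as.character(Biostrings::subseq(fasta[[chr]],
                                      GenomicRanges::start(pieces)[k],
                                      GenomicRanges::end(pieces)[k])), ""),
      collapse = "")
    if (minus) {
      pos_map <- rev(pos_map)
      seq_cds <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(seq_fwd)))
      ph <- pieces@elementMetadata$phase[length(pieces)]
    } else {
      seq_cds <- seq_fwd
      ph <- pieces@elementMetadata$phase[1]
    }
    if (is.null(ph) || is.na(ph)) ph <- 0L
    if (ph > 0) { pos_map <- pos_map[-seq_len(ph)]
                  seq_cds <- substring(seq_cds, ph + 1) }
    cp <- match(sites$pos[i], pos_map)
    if (is.na(cp)) next
    ci <- (cp - 1) %/% 3
    if (3 * ci + 3 > nchar(seq_cds)) {
      stop("SNP codon extends past CDS annotation for gene ", g)
    }
    codon_ref <- substring(seq_cds, 3 * ci + 1, 3 * ci + 3)
    base_alt <- sites$alt[i]
    if (minus) base_alt <- chartr("ACGT", "TGCA", base_alt)
    codon_alt <- codon_ref
    substring(codon_alt, (cp - 1) %% 3 + 1, (cp - 1) %% 3 + 1) <- base_alt
    aa_ref <- Biostrings::GENETIC_CODE[[toupper(codon_ref)]]
    aa_alt <- Biostrings::GENETIC_CODE[[toupper(codon_alt)]]
    effect[i] <- if (aa_alt == "*" && aa_ref != "*") "stop_gained"
      else if (aa_ref == "*" && aa_alt != "*") "stop_lost"
      else if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
    region[i] <- "exon"; gene[i] <- g
  }
  data.frame(chrom = sites$chrom, pos = sites$pos, region = region,
             effect = effect, gene = gene, stringsAsFactors = FALSE)
}

#' dN/dS ratio from SNP effect counts
#'
#' The raw count ratio of non-synonymous (including stop-gained and
#' stop-lost, the "large-effect" classes, which are also reported
#' separately) to synonymous SNPs; values above 1 are read as directional
#' selection. A site-proportional variant normalising each count by the
#' expected number of non-synonymous/synonymous sites is available with
#' `normalized = TRUE` (2/3 vs 1/3 of coding sites, the crude average over
#' the standard code).
#'
#' @param annotation output of [annotate_snp_effects()].
#' @param normalized apply the 2:1 site-count normalisation.
#' @return list with `dnds`, `n_nonsyn`, `n_syn`, `n_stop_gained`,
#'   `n_stop_lost`.
#' @export
dnds_ratio <- function(annotation, normalized = FALSE) {
  eff <- annotation$effect
  n_syn <- sum(eff == "synonymous", na.rm = TRUE)
  n_sg <- sum(eff == "stop_gained", na.rm = TRUE)
  n_sl <- sum(eff == "stop_lost", na.rm = TRUE)
  n_non <- sum(eff == "nonsynonymous", na.rm = TRUE) + n_sg + n_sl
  if (n_syn == 0) stop("undefined dN/dS: no synonymous SNPs")
  ratio <- n_non / n_syn
  if (normalized) ratio <- (n_non / 2) / (n_syn / 1)
  list(dnds = ratio, n_nonsyn = n_non, n_syn = n_syn,
       n_stop_gained = n_sg, n_stop_lost = n_sl)
}
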