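#' @keywords internal
#' @importFrom Rcpp sourceCpp
#' @useDynLib pedflow, .registration = TRUE
"_PACKAGE"

# stage dependency table: each stage lists the stages it needs
.stage_deps <- list(simulate = character(), filter = character(),
                    diversity = c("filter"), sweep = c("diversity"),
                    ibd = c("filter"), trace = c("ibd"),
                    assoc = c("filter"))

# internal: validate thresholds before any compute
validate_run_config <- function(config) {
  chk <- function(x, lo, hi, what) {
    if (!is.null(x) && (x < lo || x > hi)) {
      stop("invalid ", what, ": ", x, " outside [", lo, ", ", hi, "]")
    }
  }
  chk(config$filter$maf_min, 0, 0.5, "maf_min")
  chk(config$filter$missing_max, 0, 1, "missing_max")
  chk(config$sweep$quantile, 0, 0.5, "sweep quantile")
  chk(config$ibd$ratio_min, 0, 1, "ratio_min")
  chk(config$simulate$h2, 0, 1, "h2")
  invisible(TRUE)
}

#' Run the genome-flow analysis pipeline
#'
#' Orchestrates the stages `simulate`, `filter`, `diversity`, `sweep`,
#' `ibd`, `trace` and `assoc` from one hierarchical configuration (a list
#' or a YAML file path; every stage keyed by its name). Each stage writes
#' its tables into `out_dir` and a machine-readable `manifest.json`
#' (parameters, stage counters, input file hashes, package version) is
#' written at the end; reruns with an identical configuration are
#' bit-identical for deterministic stages. Thresholds are validated before
#' any computation and missing stage dependencies are reported by name.
#'
#' @param config list or YAML path. Recognised blocks: `simulate`
#'   (arguments of [sim_config()]), `input` (`vcf`, `pedigree`), `filter`
#'   (`maf_min`, `missing_max`), `diversity` (`window`, `step`,
#'   `density_window`), `sweep` (`quantile`, `max_extend`, `sweep_region` +
#'   `intensity` to plant one), `ibd` (`size`, `step`, `ratio_min`,
#'   `min_informative`, `founders`), `trace` (`target`, `ancestors`,
#'   `mode`), `assoc` (`qtl_site`, `qtl_effect`, `h2`, `n_pcs`), `seed`.
#' @param stages character subset of the stage names (order is fixed
#'   internally).
#' @param out_dir output directory (created).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, stages = c("simulate", "filter"),
                         out_dir = tempfile("pedflow_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_run_config(config)
  all_stages <- names(.stage_deps)
  stages <- unique(match.arg(stages, all_stages, several.ok = TRUE))
  stages <- all_stages[all_stages %in% stages]
  for (s in stages) {
    miss <- setdiff(.stage_deps[[s]], stages)
    miss <- miss[!(miss == "filter" & !is.null(config$input$vcf))]
    if (length(miss)) {
      stop("stage '", s, "' requires predecessor stage(s): ",
           paste(miss, collapse = ", "))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  st <- new.env(parent = emptyenv())
  counters <- list()
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if ("simulate" %in% stages) {
    sc_args <- config$simulate
    sc_args$seed <- seed
    if (is.null(sc_args$pedigree)) sc_args$pedigree <- example_pedigree()
    cfg <- do.call(sim_config, sc_args)
    sim <- simulate_pedigree_genotypes(cfg)
    st$sim <- sim; st$config_sim <- cfg
    st$wild <- simulate_wild_panel(cfg)
    st$gm <- sim$genotypes
    write_genotypes(sim$genotypes, file.path(out_dir, "pedigree.vcf"))
    write_pedigree(cfg$pedigree, file.path(out_dir, "pedigree.tsv"))
    tr <- sim$truth$transmitted
    tsv(tr, "truth_transmitted.tsv")
    counters$simulate <- list(n_sites = nrow(sim$genotypes$sites),
                              n_accessions = length(sim$genotypes$samples))
  }

  if ("filter" %in% stages || any(c("diversity", "ibd", "assoc") %in% stages)) {
    if (is.null(st$gm)) {
      if (is.null(config$input$vcf)) stop("no VCF input and no simulate stage")
      st$gm <- read_genotypes(config$input$vcf)
      if (!is.null(config$input$pedigree)) {
        st$ped <- read_pedigree(config$input$pedigree)
      }
    }
    maf <- config$filter$maf_min; if (is.null(maf)) maf <- 0.05
    mis <- config$filter$missing_max; if (is.null(mis)) mis <- 0.2
    n0 <- nrow(st$gm$sites)
    st$gmf <- filter_sites(st$gm, maf, mis)
    counters$filter <- list(sites_read = n0,
                            sites_removed = attr(st$gmf, "n_removed"),
                            sites_kept = nrow(st$gmf$sites))
    tsv(st$gmf$sites, "sites_filtered.tsv")
  }

  if ("diversity" %in% stages) {
    dv <- config$diversity
    win <- if (is.null(dv$window)) 1e5 else dv$window
    stp <- if (is.null(dv$step)) 2e4 else dv$step
    dwin <- if (is.null(dv$density_window)) 1e5 else dv$density_window
    ped_samples <- if (!is.null(st$sim)) st$sim$genotypes$samples
      else st$gmf$samples
    st$pi_ped <- pi_scan(st$gmf, window = win, step = stp,
                         samples = intersect(ped_samples, st$gmf$samples))
    tsv(st$pi_ped, "pi_pedigree.tsv")
    if (!is.null(st$wild)) {
      st$pi_wild <- pi_scan(st$wild, window = win, step = stp)
      tsv(st$pi_wild, "pi_wild.tsv")
    }
    dens <- snp_density_scan(st$gmf, window = dwin)
    st$density <- dens
    tsv(dens, "snp_density.tsv")
    st$zero_div <- zero_diversity_segments(dens, min_len = dwin)
    tsv(st$zero_div, "zero_diversity_segments.tsv")
    counters$diversity <- list(n_windows = nrow(st$pi_ped),
                               n_zero_div_segments = nrow(st$zero_div))
  }

  if ("sweep" %in% stages) {
    if (is.null(st$pi_wild)) stop("sweep stage needs the wild-panel scan")
    sw <- config$sweep
    q <- if (is.null(sw$quantile)) 0.05 else sw$quantile
    mext <- if (is.null(sw$max_extend)) 2e5 else sw$max_extend
    hap_ped <- st$sim$haplotypes
    win <- if (is.null(config$diversity$window)) 1e5 else config$diversity$window
    stp <- if (is.null(config$diversity$step)) 2e4 else config$diversity$step
    pr <- pi_ratio_scan(st$pi_wild, st$pi_ped, quantile = q)
    xp <- xpehh_scan(hap_ped, st$wild, window = win, step = stp,
                     quantile = q, max_extend = mext)
    cf <- confirm_sweeps(pr, xp$windows, step = stp)
    st$sweeps <- cf
    tsv(cf$windows, "sweep_windows.tsv")
    tsv(cf$segments, "sweep_segments.tsv")
    counters$sweep <- list(n_pi_flagged = sum(pr$pi_flagged, na.rm = TRUE),
                           n_confirmed = sum(cf$windows$confirmed,
                                             na.rm = TRUE),
                           n_segments = nrow(cf$segments))
  }

  if ("ibd" %in% stages || "trace" %in% stages) {
    ib <- config$ibd
    size <- if (is.null(ib$size)) 200 else ib$size
    stp <- if (is.null(ib$step)) 20 else ib$step
    rmin <- if (is.null(ib$ratio_min)) 0.99 else ib$ratio_min
    mininf <- if (is.null(ib$min_informative)) size / 2 else ib$min_informative
    ped <- if (!is.null(st$config_sim)) st$config_sim$pedigree else st$ped
    if (is.null(ped)) stop("ibd tracing needs a pedigree")
    st$windows <- snp_windows(st$gmf$sites, size, stp)
    founders <- ib$founders
    if (is.null(founders)) {
      founders <- ped$nodes$id[ped$nodes$role == "exotic_founder"]
    }
    founders <- intersect(founders, st$gmf$samples)
    st$mask <- if (length(founders) >= 2)
      uninformative_window_mask(st$gmf, founders, st$windows, rmin) else NULL
    counters$ibd <- list(n_windows = nrow(st$windows),
                         n_masked = sum(st$mask))
    st$ibd_params <- list(windows = st$windows, mask = st$mask,
                          ratio_min = rmin, min_informative = mininf)
    tg <- config$trace$target
    if (is.null(tg)) tg <- "Ekangmian 9"
    par <- parents_of(ped)[[tg]]
    par <- intersect(unlist(lapply(par, function(p)
      if (ped$nodes$role[ped$nodes$id == p] == "hybrid")
        parents_of(ped)[[p]] else p)), st$gmf$samples)
    if (length(par)) {
      st$ibd_segments <- detect_ibd_segments(
        st$gmf, tg, par, st$windows, st$mask, rmin, mininf)
      write_ibd_segments(st$ibd_segments,
                         file.path(out_dir, "ibd_segments.tsv"),
                         file.path(out_dir, "ibd_segments.bed"))
      counters$ibd$n_segments <- nrow(st$ibd_segments)
    }
  }

  if ("trace" %in% stages) {
    ped <- if (!is.null(st$config_sim)) st$config_sim$pedigree else st$ped
    tg <- config$trace$target
    if (is.null(tg)) tg <- "Ekangmian 9"
    anc <- config$trace$ancestors
    if (is.null(anc)) {
      anc <- intersect(pedigree_ancestors(ped, tg), st$gmf$samples)
      anc <- anc[ped$nodes$role[match(anc, ped$nodes$id)] != "hybrid"]
    }
    md <- if (is.null(config$trace$mode)) "direct" else config$trace$mode
    pr <- st$ibd_params
    st$trace <- trace_contributions(ped, st$gmf, tg, anc, mode = md,
                                    windows = pr$windows, mask = pr$mask,
                                    ratio_min = pr$ratio_min,
                                    min_informative = pr$min_informative)
    tsv(st$trace$report, "contribution_report.tsv")
    tsv(st$trace$segments, "traced_segments.tsv")
    counters$trace <- list(
      pct_traceable = sum(st$trace$report$pct[
        !(st$trace$report$ancestor %in% c("unknown"))]))
  }

  if ("assoc" %in% stages) {
    as_cfg <- config$assoc
    npc <- if (is.null(as_cfg$n_pcs)) 3 else as_cfg$n_pcs
    qsite <- as_cfg$qtl_site
    if (is.null(qsite)) qsite <- which.max(site_stats(st$gmf)$maf)
    qeff <- if (is.null(as_cfg$qtl_effect)) 1 else as_cfg$qtl_effect
    h2 <- if (is.null(as_cfg$h2)) 0.5 else as_cfg$h2
    set.seed(seed + 17)
    phen <- simulate_phenotypes(st$gmf,
                                qtl = data.frame(site = qsite, effect = qeff),
                                h2 = h2, n_env = 1, trait = "lint_pct")
    write_phenotypes(phen, file.path(out_dir, "phenotypes.tsv"))
    y <- stats::setNames(phen$value[phen$environment == "E1"],
                         phen$accession[phen$environment == "E1"])
    K <- kinship_matrix(st$gmf)
    pcs <- genotype_pca(st$gmf, k = min(npc, length(st$gmf$samples) - 2))
    cand <- as_cfg$candidate_sites
    if (is.null(cand)) cand <- unique(c(qsite, sample.int(nrow(st$gmf$sites),
                                                          min(9, nrow(st$gmf$sites)))))
    st$assoc <- mlm_scan(y, st$gmf, sites = cand, pcs = pcs$scores, K = K)
    tsv(st$assoc, "association.tsv")
    counters$assoc <- list(n_markers = nrow(st$assoc),
                           top_id = st$assoc$id[which.min(st$assoc$p)])
  }

  hashes <- list()
  for (f in c(config$input$vcf, config$input$pedigree)) {
    if (!is.null(f) && file.exists(f)) hashes[[basename(f)]] <-
        unname(tools::md5sum(f))
  }
  manifest <- list(package = "pedflow",
                   version = as.character(utils::packageVersion("pedflow")),
                   seed = seed, stages = stages, parameters = config[
                     setdiff(names(config), "simulate")],
                   counters = counters, input_hashes = hashes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(state = as.list(st), manifest = manifest,
                 out_dir = out_dir))
}
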