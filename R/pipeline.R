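# End-to-end orchestration: QC -> thinning -> PCA/DAPC -> FST/di ->
# iHS -> Rsb -> region calling -> intersection -> annotation.

#' Pipeline configuration
#'
#' Bundles every tunable constant of the scan pipeline. Defaults are the
#' standard SNP-array settings: per-SNP and per-sample call rate 0.95,
#' MAF 0.03, sheep autosomes 1-26, 1-in-10 LD thinning, 20-SNP windows,
#' top 1% of window means, di threshold 4.0 (3.0 as the relaxed option),
#' EHH cutoff 0.05, piHS/pRsB threshold 4.0 (P < 0.0001), +/- 500 bp
#' region padding, minimum run of 2 significant SNPs.
#'
#' @param min_snp_call,min_sample_call,min_maf QC thresholds.
#' @param autosomes autosomal chromosome labels.
#' @param thin_k LD thinning block size.
#' @param window_w window size in SNPs.
#' @param top_frac flagged fraction of window means.
#' @param di_threshold per-SNP di significance threshold.
#' @param ehh_cutoff EHH/EHHS truncation threshold.
#' @param sig_threshold piHS/pRsB significance threshold.
#' @param freq_bounds iHS derived-frequency bounds.
#' @param bin_width iHS standardization bin width.
#' @param pad_bp region padding in bp.
#' @param min_run minimum adjacent significant SNPs per region.
#' @param min_windows minimum qualifying windows per region.
#' @param n_pcs,n_axes DAPC dimensioning (NULL = defaults).
#' @param seed RNG seed for stochastic stages.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_snp_call = 0.95, min_sample_call = 0.95,
                            min_maf = 0.03,
                            autosomes = as.character(1:26),
                            thin_k = 10L, window_w = 20L, top_frac = 0.01,
                            di_threshold = 4.0, ehh_cutoff = 0.05,
                            sig_threshold = 4.0,
                            freq_bounds = c(0.05, 0.95), bin_width = 0.05,
                            pad_bp = 500L, min_run = 2L, min_windows = 2L,
                            n_pcs = NULL, n_axes = NULL, seed = 1L) {
  stopifnot(min_snp_call >= 0, min_snp_call <= 1,
            min_sample_call >= 0, min_sample_call <= 1,
            min_maf >= 0, min_maf <= 0.5,
            thin_k >= 1, window_w >= 1,
            top_frac > 0, top_frac <= 1,
            ehh_cutoff > 0, ehh_cutoff < 1,
            pad_bp >= 0, min_run >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full selection-scan pipeline
#'
#' Executes, in order: sample and SNP QC on the unphased genotypes; LD
#' thinning + PCA + DAPC; per-SNP FST between the focal group and each
#' other group, summarised as di, flagged both per SNP (threshold) and by
#' window (top fraction); the iHS scan within the focal group and the Rsb
#' scan of focal vs all non-focal haplotypes (phased input restricted to
#' QC-surviving SNPs); run-based and window-based region calling;
#' cross-method intersection; optional gene-interval annotation. All
#' stages are pure functions of (inputs, config, seed).
#'
#' @param genotypes dosage matrix, or `NULL` to derive from `haplotypes`.
#' @param haplotypes phased haplotype matrix (for iHS/Rsb); may be `NULL`
#'   to skip the EHH scans.
#' @param markers the shared [marker_map()].
#' @param samples the [sample_table()] (groups define the contrast).
#' @param focal_group group label scanned for selection (default: first
#'   group in the sample table).
#' @param genes optional gene intervals ([read_gene_intervals()] output).
#' @param config a [pipeline_config()].
#' @param out_dir if non-NULL, artifacts are written there as
#'   TSV/BED/VCF with a `run_log.tsv` recording stage counts and the
#'   seed.
#' @return a list of class `sweepscan_result` with elements `qc`
#'   (reports), `pca`, `dapc`, `tracks` (di / piHS / pRsB scan tracks),
#'   `windows`, `regions` (named list of `sweep_regions`), `overlaps`,
#'   `annotation`, and `config`.
#' @export
run_pipeline <- function(genotypes = NULL, haplotypes = NULL, markers,
                         samples, focal_group = NULL, genes = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  log <- list()
  note <- function(stage, what) log[[length(log) + 1L]] <<-
    data.frame(stage = stage, note = what, stringsAsFactors = FALSE)
  if (is.null(genotypes)) {
    if (is.null(haplotypes)) stop("stage input: need genotypes or haplotypes")
    odd <- seq(1L, nrow(haplotypes), by = 2L)
    genotypes <- haplotypes[odd, , drop = FALSE] +
      haplotypes[odd + 1L, , drop = FALSE]
    rownames(genotypes) <- samples$sample_id
  }
  focal_group <- focal_group %||% samples$group[1L]
  if (!focal_group %in% samples$group)
    stop("stage input: focal group '", focal_group, "' not in sample table")

  ## --- QC ---------------------------------------------------------------
  sq <- sample_qc_filter(genotypes, samples, config$min_sample_call)
  mq <- snp_qc_filter(sq$genotypes, markers, config$min_snp_call,
                      config$min_maf, config$autosomes)
  G <- mq$genotypes; mm <- mq$markers; st <- sq$samples
  keep_snps <- mm$snp_id
  note("qc", sprintf("%d samples, %d SNPs retained", nrow(st), nrow(mm)))

  ## --- structure --------------------------------------------------------
  thin_idx <- thin_every_kth(mm, config$thin_k)
  pca <- snp_pca(G[, thin_idx, drop = FALSE])
  dapc <- if (length(unique(st$group)) >= 2L)
    snp_dapc(G[, thin_idx, drop = FALSE], st$group,
             n_pcs = config$n_pcs, n_axes = config$n_axes) else NULL
  note("structure", sprintf("%d thinned SNPs, PC1 %.2f%%",
                            length(thin_idx), pca$pct_variance[1L]))

  ## --- differentiation --------------------------------------------------
  others <- setdiff(unique(st$group), focal_group)
  fst_tracks <- lapply(others, function(g)
    wc_fst_per_snp(G, mm, st$group, focal_group, g))
  names(fst_tracks) <- paste0(focal_group, "_vs_", others)
  di <- di_track(fst_tracks)
  di <- flag_threshold(di, config$di_threshold)
  wt <- window_means(di, config$window_w)
  wt <- flag_top_fraction(wt, config$top_frac)
  note("fst-di", sprintf("%d SNPs flagged at di >= %.1f, %d/%d windows",
                         sum(di$flag), config$di_threshold,
                         sum(wt$flag), nrow(wt)))

  ## --- EHH scans --------------------------------------------------------
  ihs <- rsb <- NULL
  if (!is.null(haplotypes)) {
    hap_keep <- match(keep_snps, colnames(haplotypes) %||% keep_snps)
    if (anyNA(hap_keep))
      stop("stage input: haplotypes lack QC-retained SNPs")
    Hq <- haplotypes[, hap_keep, drop = FALSE]
    hap_groups <- rep(samples$group, each = 2L)
    Hf <- Hq[hap_groups == focal_group, , drop = FALSE]
    Ho <- Hq[hap_groups != focal_group, , drop = FALSE]
    ihs <- ihs_scan(Hf, mm, freq_bounds = config$freq_bounds,
                    bin_width = config$bin_width,
                    cutoff = config$ehh_cutoff,
                    threshold = config$sig_threshold)
    rsb <- rsb_scan(Hf, Ho, mm, cutoff = config$ehh_cutoff,
                    threshold = config$sig_threshold)
    note("ehh", sprintf("%d iHS / %d Rsb SNPs flagged",
                        sum(ihs$flag), sum(rsb$flag)))
  }

  ## --- regions ----------------------------------------------------------
  regions <- list(di = call_runs(di, config$min_run, config$pad_bp, "di"))
  regions$di_windows <- call_window_regions(wt, config$min_windows,
                                            method = "di_windows")
  if (!is.null(ihs))
    regions$ihs <- call_runs(ihs, config$min_run, config$pad_bp, "ihs")
  if (!is.null(rsb))
    regions$rsb <- call_runs(rsb, config$min_run, config$pad_bp, "rsb")
  main <- regions[intersect(c("di", "ihs", "rsb"), names(regions))]
  overlaps <- if (length(main) >= 2L) intersect_region_sets(main) else NULL
  annotation <- if (!is.null(genes))
    annotate_regions(do.call(rbind, unname(main)), genes) else NULL
  note("regions", sprintf("%d candidate regions",
                          sum(vapply(regions, nrow, 0L))))

  res <- list(qc = list(sample = sq$report, snp = mq$report),
              pca = pca, dapc = dapc,
              tracks = c(list(di = di, ihs = ihs, rsb = rsb), fst_tracks),
              windows = wt, regions = regions, overlaps = overlaps,
              annotation = annotation,
              markers = mm, samples = st,
              log = do.call(rbind, log), config = config)
  class(res) <- "sweepscan_result"
  if (!is.null(out_dir)) write_result(res, out_dir)
  res
}

write_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_qc_report(res$qc$sample, file.path(out_dir, "qc_samples.tsv"))
  write_qc_report(res$qc$snp, file.path(out_dir, "qc_snps.tsv"))
  write_coordinates(res$pca, file.path(out_dir, "pca_coordinates.tsv"))
  if (!is.null(res$dapc))
    write_coordinates(res$dapc, file.path(out_dir, "dapc_coordinates.tsv"))
  for (nm in names(res$tracks))
    if (!is.null(res$tracks[[nm]]))
      write_scan_track(res$tracks[[nm]],
                       file.path(out_dir, paste0("track_", nm, ".tsv")))
  write_window_track(res$windows, file.path(out_dir, "windows_di.tsv"))
  for (nm in names(res$regions))
    write_regions(res$regions[[nm]],
                  bed_path = file.path(out_dir, paste0("regions_", nm, ".bed")),
                  tsv_path = file.path(out_dir, paste0("regions_", nm, ".tsv")))
  if (!is.null(res$overlaps))
    write.table(res$overlaps, file.path(out_dir, "overlaps.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$annotation))
    write.table(res$annotation, file.path(out_dir, "annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$log, file.path(out_dir, "run_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.sweepscan_result <- function(x, ...) {
  cat("sweepscan result\n")
  if (!is.null(x$log)) {
    for (i in seq_len(nrow(x$log)))
      cat(sprintf("  [%s] %s\n", x$log$stage[i], x$log$note[i]))
  }
  invisible(x)
}

#' Run the pipeline from files on disk
#'
#' Convenience wrapper: reads a PED/MAP pair (genotypes), an optional
#' phased VCF (haplotypes), the sample table TSV and an optional gene
#' interval file, then calls [run_pipeline()].
#'
#' @param ped,map PLINK text paths.
#' @param vcf optional phased VCF path.
#' @param samples_tsv sample table path.
#' @param genes_path optional BED/GFF3 path.
#' @param focal_group,config,out_dir passed to [run_pipeline()].
#' @return a `sweepscan_result`.
#' @export
run_pipeline_files <- function(ped, map, vcf = NULL, samples_tsv,
                               genes_path = NULL, focal_group = NULL,
                               config = pipeline_config(), out_dir = NULL) {
  gset <- read_plink_textset(ped, map)
  labels <- read_sample_table(samples_tsv)
  st <- apply_sample_labels(gset$samples, labels)
  H <- NULL
  if (!is.null(vcf)) H <- read_phased_vcf(vcf, samples = labels)$haplotypes
  run_pipeline(gset$genotypes, H, gset$markers, st,
               focal_group = focal_group, config = config,
               genes = if (!is.null(genes_path)) read_gene_intervals(genes_path),
               out_dir = out_dir)
}
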