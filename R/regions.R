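# Candidate-region calling and interval arithmetic. Coordinates are
# 1-based inclusive bp internally (matching printed genomic intervals);
# BED export converts to 0-based half-open.

sweep_regions <- function(chrom = character(), start = integer(),
                          end = integer(), method = character(),
                          n_snps = integer(), snp_ids = character()) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), method = as.character(method),
                   n_snps = as.integer(n_snps),
                   snp_ids = as.character(snp_ids),
                   stringsAsFactors = FALSE)
  class(df) <- c("sweep_regions", "data.frame")
  df
}

#' Call candidate regions from runs of significant SNPs
#'
#' A candidate region is a maximal run of at least `min_run` consecutive
#' flagged SNPs (consecutive rows of the marker-ordered track on one
#' chromosome; no bp-gap limit), extended by `pad_bp` up- and downstream
#' of the extreme significant SNPs and floored at position 1. Padded
#' regions that overlap (share at least 1 bp) are merged.
#'
#' @param track a flagged [scan_track()].
#' @param min_run minimum run length (default 2).
#' @param pad_bp padding in bp on each side (default 500, i.e. 0.5 Kb).
#' @param method method label stored with the regions (default: the
#'   track's statistic name).
#' @return a `sweep_regions` data.frame: `chrom, start, end, method,
#'   n_snps, snp_ids`, sorted and pairwise disjoint.
#' @export
call_runs <- function(track, min_run = 2L, pad_bp = 500L, method = NULL) {
  method <- method %||% attr(track, "statistic") %||% "scan"
  out <- sweep_regions()
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    f <- track$flag[idx]
    r <- rle(f)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_run)) {
      rows <- idx[starts[k]:ends[k]]
      out <- rbind(out, sweep_regions(
        ch, max(1L, min(track$pos[rows]) - pad_bp),
        max(track$pos[rows]) + pad_bp, method,
        length(rows), paste(track$snp_id[rows], collapse = ",")))
    }
  }
  merge_regions(out)
}

#' Call candidate regions from runs of significant windows
#'
#' Under the default `"adjacent"` reading, at least `min_windows`
#' consecutive flagged windows on a chromosome form a region spanning the
#' first window's start bp to the last window's end bp. Under `"any"`,
#' every maximal run of flagged windows becomes a region provided the
#' chromosome carries at least `min_windows` flagged windows in total.
#'
#' @param wt a flagged [window_means()] track.
#' @param min_windows minimum qualifying windows (default 2).
#' @param mode `"adjacent"` (default) or `"any"`.
#' @param method method label (default: statistic name + "_windows").
#' @return a `sweep_regions` data.frame.
#' @export
call_window_regions <- function(wt, min_windows = 2L,
                                mode = c("adjacent", "any"),
                                method = NULL) {
  mode <- match.arg(mode)
  method <- method %||%
    paste0(attr(wt, "statistic") %||% "scan", "_windows")
  out <- sweep_regions()
  for (ch in unique(wt$chrom)) {
    idx <- which(wt$chrom == ch)
    f <- wt$flag[idx]
    min_len <- if (mode == "adjacent") min_windows else 1L
    if (mode == "any" && sum(f) < min_windows) next
    r <- rle(f)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      rows <- idx[starts[k]:ends[k]]
      out <- rbind(out, sweep_regions(
        ch, wt$start_bp[rows[1L]], wt$end_bp[rows[length(rows)]], method,
        sum(wt$n_snps[rows]), ""))
    }
  }
  merge_regions(out)
}

# sort by (chrom, start) and merge overlapping (>= 1 shared bp) regions
merge_regions <- function(rg) {
  if (nrow(rg) == 0L) return(rg)
  rg <- rg[order(chrom_rank(rg$chrom), rg$start, rg$end), , drop = FALSE]
  keep <- rg[1L, , drop = FALSE]
  for (i in seq_len(nrow(rg))[-1L]) {
    j <- nrow(keep)
    if (rg$chrom[i] == keep$chrom[j] && rg$start[i] <= keep$end[j]) {
      keep$end[j] <- max(keep$end[j], rg$end[i])
      keep$n_snps[j] <- keep$n_snps[j] + rg$n_snps[i]
      keep$snp_ids[j] <- paste(c(keep$snp_ids[j], rg$snp_ids[i])[
        nzchar(c(keep$snp_ids[j], rg$snp_ids[i]))], collapse = ",")
    } else {
      keep <- rbind(keep, rg[i, , drop = FALSE])
    }
  }
  rownames(keep) <- NULL
  class(keep) <- c("sweep_regions", "data.frame")
  keep
}

regions_to_granges <- function(rg) {
  GenomicRanges::GRanges(rg$chrom,
                         IRanges::IRanges(rg$start, rg$end))
}

#' Intersect candidate-region sets from several methods
#'
#' For every combination of two or more methods, emits the maximal
#' intervals contained in one region of each method (the set intersection
#' of the merged region sets). Symmetric in its arguments; intersecting
#' identical sets returns the regions themselves.
#'
#' @param sets a named list of `sweep_regions` (names = method labels).
#' @return a data.frame `methods, chrom, start, end` with one row per
#'   intersected interval; zero rows when the sets are disjoint.
#' @export
intersect_region_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L, !is.null(names(sets)))
  out <- data.frame(methods = character(), chrom = character(),
                    start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  gr <- lapply(sets, function(rg)
    GenomicRanges::reduce(regions_to_granges(rg)))
  for (m in 2:length(sets)) {
    for (cmb in asplit(combn(names(sets), m), 2L)) {
      inter <- suppressWarnings(Reduce(GenomicRanges::intersect, gr[cmb]))
      if (length(inter) == 0L) next
      out <- rbind(out, data.frame(
        methods = paste(cmb, collapse = "+"),
        chrom = as.character(GenomicRanges::seqnames(inter)),
        start = GenomicRanges::start(inter),
        end = GenomicRanges::end(inter),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Read gene intervals from BED or GFF3
#'
#' BED (0-based half-open) and GFF3 (1-based inclusive) are normalized to
#' 1-based inclusive internally via `rtracklayer`. For GFF3, rows of type
#' `"gene"` are kept when present; gene identifiers come from the BED
#' name column or the GFF3 `Name`/`ID`/`gene_id` attribute.
#'
#' @param path path to a `.bed`, `.gff`/`.gff3`/`.gtf` file.
#' @return a data.frame `chrom, start, end, gene_id`.
#' @export
read_gene_intervals <- function(path) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc) && any(mc$type == "gene"))
    gr <- gr[mc$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  id <- NULL
  for (f in c("name", "Name", "ID", "gene_id"))
    if (is.null(id) && f %in% names(mc)) id <- as.character(mc[[f]])
  if (is.null(id) || all(is.na(id))) id <- paste0("feature", seq_along(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             gene_id = id, stringsAsFactors = FALSE)
}

#' Annotate candidate regions with overlapping gene intervals
#'
#' Emits every (region, gene) pair sharing at least 1 bp; a gene abutting
#' a region without overlap is not reported. The number of distinct genes
#' hit is attached as attribute `n_genes`.
#'
#' @param regions a `sweep_regions` data.frame.
#' @param genes a data.frame `chrom, start, end, gene_id` (1-based
#'   inclusive), e.g. from [read_gene_intervals()].
#' @return a data.frame `chrom, start, end, method, gene_id` with
#'   attribute `n_genes`.
#' @export
annotate_regions <- function(regions, genes) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), method = character(),
                      gene_id = character(), stringsAsFactors = FALSE)
  if (nrow(regions) == 0L || nrow(genes) == 0L) {
    attr(empty, "n_genes") <- 0L
    return(empty)
  }
  gr_r <- regions_to_granges(regions)
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_g, minoverlap = 1L)
  out <- data.frame(
    chrom = regions$chrom[S4Vectors::queryHits(hits)],
    start = regions$start[S4Vectors::queryHits(hits)],
    end = regions$end[S4Vectors::queryHits(hits)],
    method = regions$method[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  attr(out, "n_genes") <- length(unique(out$gene_id))
  out
}

#' Write regions as BED (0-based half-open) and TSV
#'
#' @param regions a `sweep_regions` data.frame.
#' @param bed_path,tsv_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_regions <- function(regions, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(regions$chrom, regions$start - 1L, regions$end,
                      regions$method, regions$n_snps)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path))
    write.table(as.data.frame(regions), tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}
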