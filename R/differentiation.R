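# Differentiation-based scan: per-SNP Weir & Cockerham (1984) FST between
# two populations, the di statistic (sum of genome-wide z-standardized
# pairwise FST for a focal group), 20-SNP window averaging and the two
# significance modes (per-SNP threshold; top-fraction of window means).

#' Per-SNP Weir-Cockerham FST between two populations
#'
#' The two-population unbiased estimator theta-hat = a / (a + b + c) of
#' Weir & Cockerham (1984), computed per SNP from genotype counts with the
#' observed heterozygosity correction. Undefined (`NA`) where a population
#' has fewer than 2 non-missing individuals or the SNP is monomorphic
#' across both populations.
#'
#' @param G dosage matrix.
#' @param mm the matching [marker_map()].
#' @param labels population (or group) label per individual.
#' @param pop_a,pop_b the two labels to contrast.
#' @return a [scan_track()] (statistic `"fst"`).
#' @export
wc_fst_per_snp <- function(G, mm, labels, pop_a, pop_b) {
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(G))
  if (!pop_a %in% labels) stop("unknown population label: ", pop_a)
  if (!pop_b %in% labels) stop("unknown population label: ", pop_b)
  comp <- function(pop) {
    sub <- G[labels == pop, , drop = FALSE]
    n <- colSums(!is.na(sub))
    list(n = n,
         p = colSums(sub, na.rm = TRUE) / (2 * n),
         h = colSums(sub == 1L, na.rm = TRUE) / n)
  }
  A <- comp(pop_a); B <- comp(pop_b)
  r <- 2
  ok <- A$n >= 2L & B$n >= 2L
  nbar <- (A$n + B$n) / r
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(ok & abs(denom) > .Machine$double.eps, a / denom, NA_real_)
  mono <- pbar %in% c(0, 1) & s2 == 0           # monomorphic across both
  theta[mono] <- NA_real_
  scan_track(mm, theta, "fst")
}

#' The di differentiation statistic
#'
#' For a focal group i, di at each SNP is the sum over the other groups j
#' of the z-standardized pairwise FST: `(FST_ij - E[FST_ij]) / sd(FST_ij)`,
#' where the expectation and standard deviation are the genome-wide
#' empirical moments of that pair's defined FST values. With exactly two
#' groups, di reduces to the per-SNP FST z-score. Undefined SNPs are
#' excluded from the moments; a SNP undefined in any pair is undefined in
#' di.
#'
#' @param fst_tracks a (optionally named) list of [wc_fst_per_snp()]
#'   tracks, one per comparison of the focal group against another group.
#' @param sd_type `"population"` (denominator n, default) or `"sample"`
#'   (n - 1).
#' @return a [scan_track()] (statistic `"di"`).
#' @export
di_track <- function(fst_tracks, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (inherits(fst_tracks, "scan_track")) fst_tracks <- list(fst_tracks)
  stopifnot(length(fst_tracks) >= 1L)
  z <- lapply(fst_tracks, function(tr) {
    v <- tr$value
    def <- v[!is.na(v)]
    if (length(def) < 2L) stop("a pairwise FST track has < 2 defined values")
    m <- mean(def)
    s <- if (sd_type == "population")
      sqrt(mean((def - m)^2)) else sd(def)
    if (s == 0) stop("degenerate FST distribution (zero standard deviation)")
    (v - m) / s
  })
  di <- Reduce(`+`, z)
  mm0 <- fst_tracks[[1L]]
  scan_track(marker_map(mm0$snp_id, mm0$chrom, mm0$pos), di, "di")
}

#' Non-overlapping window means of a scan track
#'
#' Per chromosome, consecutive blocks of exactly `w` SNPs (in map order);
#' a trailing block of fewer than `w` SNPs is dropped, and a chromosome
#' with fewer than `w` SNPs contributes no window (with a warning). The
#' window value is the mean over the defined statistics in the block.
#'
#' @param track a [scan_track()].
#' @param w window size in SNPs (default 20).
#' @return a `data.frame` of class `window_track`: `chrom, start_idx,
#'   end_idx, start_bp, end_bp, n_snps, value, flag` (indices are rows of
#'   the track).
#' @export
window_means <- function(track, w = 20L) {
  w <- as.integer(w)
  if (is.na(w) || w < 1L) stop("w must be a positive integer")
  out <- list()
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    nw <- length(idx) %/% w
    if (nw == 0L) {
      warning("chromosome ", ch, " has fewer than ", w, " SNPs: no windows")
      next
    }
    for (b in seq_len(nw)) {
      rows <- idx[((b - 1L) * w + 1L):(b * w)]
      v <- track$value[rows]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start_idx = rows[1L], end_idx = rows[w],
        start_bp = track$pos[rows[1L]], end_bp = track$pos[rows[w]],
        n_snps = w,
        value = if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  wt <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start_idx = integer(),
               end_idx = integer(), start_bp = integer(),
               end_bp = integer(), n_snps = integer(), value = numeric())
  wt$flag <- logical(nrow(wt))
  attr(wt, "statistic") <- attr(track, "statistic")
  class(wt) <- c("window_track", "data.frame")
  wt
}

#' Flag the top fraction of window means
#'
#' Flags windows whose mean is at least the `ceiling(frac * m)`-th largest
#' defined window mean (the empirical top-`frac` order statistic); ties at
#' the cutoff are all flagged. Windows with an undefined mean are never
#' flagged.
#'
#' @param wt a [window_means()] track.
#' @param frac fraction to flag, in (0, 1] (default 0.01).
#' @return the window track with updated `flag`.
#' @export
flag_top_fraction <- function(wt, frac = 0.01) {
  if (!is.numeric(frac) || frac <= 0 || frac > 1)
    stop("frac must lie in (0, 1]")
  if (nrow(wt) < 1L) stop("no windows to flag")
  v <- wt$value
  def <- sort(v[!is.na(v)], decreasing = TRUE)
  if (length(def) == 0L) {
    wt$flag <- FALSE
    return(wt)
  }
  cutoff <- def[min(length(def), max(1L, ceiling(frac * length(def))))]
  wt$flag <- !is.na(v) & v >= cutoff
  wt
}

#' Flag SNPs at or above a fixed threshold
#'
#' @param track a [scan_track()].
#' @param thr finite threshold; SNPs with defined `value >= thr` are
#'   flagged (inclusive, matching a "statistic >= 4.0" significance rule).
#' @return the track with updated `flag`.
#' @export
flag_threshold <- function(track, thr) {
  if (!is.finite(thr)) stop("threshold must be finite")
  track$flag <- !is.na(track$value) & track$value >= thr
  track
}

#' Write a window track as TSV
#' @param wt a [window_means()] track.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_window_track <- function(wt, path) {
  write.table(as.data.frame(wt), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
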