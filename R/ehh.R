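# Extended haplotype homozygosity statistics on phased haplotypes.
#
# EHH for carriers of a core allele is the probability that two randomly
# chosen carrier chromosomes are identical over the interval from the core
# to a test marker; it is computed outward marker-by-marker by partition
# refinement (each step splits haplotype classes by the next allele), so
# it is non-increasing with distance. iHH integrates EHH over physical
# distance; iHS = ln(iHH_ancestral / iHH_derived), standardized within
# derived-allele-frequency bins. EHHS is the site-specific analogue over
# all chromosomes, normalized to 1 at the core; Rsb = standardized
# ln(iES_groupA / iES_groupB).

#' Ancestral-allele assignment by the major rule
#'
#' The higher-frequency allele at each SNP is taken to be ancestral; an
#' exact 50/50 tie is broken toward allele 0 (documented convention).
#'
#' @param freqs frequency of allele 1 per SNP.
#' @return an `ancestral_assignment`: list with `ancestral` (0/1 per SNP)
#'   and `provenance`.
#' @export
assign_ancestral_major <- function(freqs) {
  if (anyNA(freqs)) stop("allele frequencies must be defined at every SNP")
  out <- list(ancestral = ifelse(freqs > 0.5, 1L, 0L),
              provenance = "major", seed = NA_integer_)
  class(out) <- "ancestral_assignment"
  out
}

#' Random ancestral-allele assignment
#'
#' Independent fair coin per SNP, reproducible from `seed`; used to check
#' that scan results are robust to the ancestral-state convention (see
#' [consistency_check()]).
#'
#' @param n_snps number of SNPs.
#' @param seed RNG seed.
#' @return an `ancestral_assignment`.
#' @export
assign_ancestral_random <- function(n_snps, seed) {
  anc <- with_seed(seed, sample(c(0L, 1L), n_snps, replace = TRUE))
  out <- list(ancestral = anc, provenance = "random", seed = as.integer(seed))
  class(out) <- "ancestral_assignment"
  out
}

# One direction of an EHH/EHHS walk. `rows` indexes the chromosomes
# considered; `cls0` is their class partition at the core. Returns a
# data.frame(idx, h) of markers visited while the (optionally normalized)
# statistic stays >= cutoff, starting at the core.
ehh_walk <- function(H, rows, core, step, cutoff, cls0, h0) {
  n <- length(rows)
  denom <- choose(n, 2)
  cls <- cls0
  idx <- core
  hh <- h0
  t <- core + step
  S <- ncol(H)
  while (t >= 1L && t <= S) {
    key <- cls * 2L + H[rows, t]
    cls <- match(key, unique(key))
    h <- sum(choose(tabulate(cls), 2)) / denom
    if (h / h0 < cutoff) break
    idx <- c(idx, t)
    hh <- c(hh, h)
    if (h == 0) break
    t <- t + step
  }
  data.frame(idx = idx, h = hh)
}

#' EHH curve around a core SNP for one allele
#'
#' At marker t, carriers of `allele` at `core` are partitioned by their
#' allele string from core to t inclusive; EHH(t) is the fraction of
#' carrier pairs falling in the same class, `sum(choose(k_h, 2)) /
#' choose(n, 2)`. The walk proceeds outward in each direction and stops
#' after the last marker with EHH >= `cutoff` (or the chromosome end;
#' walks never cross a chromosome boundary).
#'
#' @param H haplotype matrix ((2 x individuals) x SNPs, {0,1}).
#' @param mm the matching [marker_map()].
#' @param core column index of the core SNP.
#' @param allele core allele (0 or 1) whose carriers are followed.
#' @param cutoff EHH truncation threshold (default 0.05).
#' @return an object of class `ehh_curve` (lists `left`/`right` of
#'   data.frames `idx, ehh` starting at the core, where EHH = 1), or
#'   `NULL` if fewer than 2 chromosomes carry the allele (undefined).
#' @export
ehh_curve <- function(H, mm, core, allele, cutoff = 0.05) {
  rows <- which(H[, core] == allele)
  if (length(rows) < 2L) return(NULL)
  bounds <- chrom_bounds(mm, core)
  Hc <- H[, bounds[1L]:bounds[2L], drop = FALSE]
  core_l <- core - bounds[1L] + 1L
  cls0 <- rep(1L, length(rows))
  left <- ehh_walk(Hc, rows, core_l, -1L, cutoff, cls0, 1)
  right <- ehh_walk(Hc, rows, core_l, +1L, cutoff, cls0, 1)
  left$idx <- left$idx + bounds[1L] - 1L
  right$idx <- right$idx + bounds[1L] - 1L
  names(left)[2L] <- names(right)[2L] <- "ehh"
  out <- list(core = core, allele_class = as.character(allele),
              n = length(rows), left = left, right = right)
  class(out) <- "ehh_curve"
  out
}

#' Site-specific EHH (EHHS) curve around a core SNP
#'
#' As [ehh_curve()] but over all chromosomes regardless of core allele:
#' H(t) is the pairwise homozygosity of core-to-t allele strings and
#' EHHS(t) = H(t) / H(core), so EHHS(core) = 1 by normalization. The same
#' cutoff rule truncates the walk (applied to the normalized value).
#'
#' @inheritParams ehh_curve
#' @return an `ehh_curve` (allele class `"all"`, columns `idx, ehh`
#'   holding EHHS), or `NULL` if fewer than 2 chromosomes.
#' @export
ehhs_curve <- function(H, mm, core, cutoff = 0.05) {
  n <- nrow(H)
  if (n < 2L) return(NULL)
  cls0 <- match(H[, core], unique(H[, core]))
  h0 <- sum(choose(tabulate(cls0), 2)) / choose(n, 2)
  if (h0 == 0) return(NULL)
  bounds <- chrom_bounds(mm, core)
  Hc <- H[, bounds[1L]:bounds[2L], drop = FALSE]
  core_l <- core - bounds[1L] + 1L
  rows <- seq_len(n)
  left <- ehh_walk(Hc, rows, core_l, -1L, cutoff, cls0, h0)
  right <- ehh_walk(Hc, rows, core_l, +1L, cutoff, cls0, h0)
  left$idx <- left$idx + bounds[1L] - 1L
  right$idx <- right$idx + bounds[1L] - 1L
  left$h <- left$h / h0
  right$h <- right$h / h0
  names(left)[2L] <- names(right)[2L] <- "ehh"
  out <- list(core = core, allele_class = "all", n = n,
              left = left, right = right)
  class(out) <- "ehh_curve"
  out
}

# first/last marker row index of the chromosome containing `core`
chrom_bounds <- function(mm, core) {
  ch <- mm$chrom[core]
  idx <- which(mm$chrom == ch)
  c(min(idx), max(idx))
}

#' Integrate an EHH curve over physical distance
#'
#' Trapezoidal integral of EHH against bp position, summed over the two
#' directions; truncation follows the curve's stopping rule (no
#' integration beyond the last above-cutoff marker, no interpolation of
#' the crossing point). Units: bp x EHH, which cancel in the ln ratios.
#'
#' @param curve an [ehh_curve()] (or `NULL`).
#' @param mm the matching [marker_map()].
#' @return the integral in bp, or `NA` for a `NULL` curve.
#' @export
integrate_ihh <- function(curve, mm) {
  if (is.null(curve)) return(NA_real_)
  trap <- function(df) {
    if (nrow(df) < 2L) return(0)
    x <- abs(diff(mm$pos[df$idx]))
    v <- df$ehh
    sum(x * (v[-length(v)] + v[-1L]) / 2)
  }
  trap(curve$left) + trap(curve$right)
}

#' Gaussian tail-probability significance transform
#'
#' Maps a standardized, approximately normal statistic v to
#' `-log10(1 - 2 * |Phi(v) - 0.5|)`, the negative log10 of the two-sided
#' Gaussian tail probability; a transformed value of 4.0 corresponds to a
#' two-sided P of 0.0001. The transform is symmetric (`p(v) = p(-v)`) and
#' monotone increasing in |v| so both sweep polarities are detectable;
#' `side = "literal"` applies the one-sided form `-log10(2 * (1 -
#' Phi(v)))` exactly as printed in some sources, under which negative
#' statistics can never be significant.
#'
#' @param values numeric vector of standardized statistics.
#' @param side `"two.sided"` (default) or `"literal"`.
#' @return transformed values (same length; `NA` preserved).
#' @export
p_transform <- function(values, side = c("two.sided", "literal")) {
  side <- match.arg(side)
  v <- if (side == "two.sided") abs(values) else values
  # -log10(2 * (1 - Phi(v))), computed on the log scale for stability
  -(log(2) + pnorm(v, lower.tail = FALSE, log.p = TRUE)) / log(10)
}

#' iHS scan within a group of populations
#'
#' For every SNP whose derived-allele frequency lies inside `freq_bounds`,
#' the raw statistic is `ln(iHH_A / iHH_D)` (integrated EHH of the
#' ancestral over the derived allele). Raw values are standardized within
#' derived-allele-frequency bins of width `bin_width` (subtract the bin
#' mean, divide by the bin sd), transformed with [p_transform()] into
#' piHS, and flagged where piHS >= `threshold`.
#'
#' @param H phased haplotypes of the scanned group.
#' @param mm the matching [marker_map()].
#' @param anc an ancestral assignment ([assign_ancestral_major()] /
#'   [assign_ancestral_random()]); default: major rule from `H`.
#' @param freq_bounds admissible derived-allele frequency range (default
#'   c(0.05, 0.95)).
#' @param bin_width standardization bin width on derived frequency
#'   (default 0.05).
#' @param cutoff EHH truncation threshold (default 0.05).
#' @param threshold piHS significance threshold (default 4.0, i.e.
#'   P < 0.0001).
#' @param side transform convention, see [p_transform()].
#' @return a [scan_track()] (statistic `"piHS"`) with `value` = piHS and
#'   extra columns `raw` (ln ratio), `std` (standardized iHS) and
#'   `derived_freq`.
#' @export
ihs_scan <- function(H, mm, anc = NULL,
                     freq_bounds = c(0.05, 0.95), bin_width = 0.05,
                     cutoff = 0.05, threshold = 4.0,
                     side = "two.sided") {
  check_haplotypes(H, mm)
  S <- ncol(H)
  if (is.null(anc)) anc <- assign_ancestral_major(colMeans(H))
  stopifnot(length(anc$ancestral) == S)
  raw <- rep(NA_real_, S)
  dfreq <- rep(NA_real_, S)
  for (s in seq_len(S)) {
    der <- 1L - anc$ancestral[s]
    pd <- mean(H[, s] == der)
    dfreq[s] <- pd
    if (pd < freq_bounds[1L] || pd > freq_bounds[2L]) next
    ihh_a <- integrate_ihh(ehh_curve(H, mm, s, anc$ancestral[s], cutoff), mm)
    ihh_d <- integrate_ihh(ehh_curve(H, mm, s, der, cutoff), mm)
    if (is.na(ihh_a) || is.na(ihh_d) || ihh_a == 0 || ihh_d == 0) next
    raw[s] <- log(ihh_a / ihh_d)
  }
  std <- standardize_by_bin(raw, dfreq, freq_bounds, bin_width)
  logp <- p_transform(std, side)
  scan_track(mm, logp, "piHS", flag = !is.na(logp) & logp >= threshold,
             extra = list(raw = raw, std = std, derived_freq = dfreq))
}

standardize_by_bin <- function(raw, freq, freq_bounds, bin_width) {
  breaks <- seq(freq_bounds[1L], freq_bounds[2L], by = bin_width)
  if (max(breaks) < freq_bounds[2L]) breaks <- c(breaks, freq_bounds[2L])
  bin <- cut(freq, breaks, include.lowest = TRUE)
  std <- rep(NA_real_, length(raw))
  for (b in levels(bin)) {
    i <- which(bin == b & !is.na(raw))
    if (length(i) == 0L) next
    if (length(i) < 2L || sd(raw[i]) == 0) {
      warning("frequency bin ", b, " has too few SNPs to standardize")
      next
    }
    std[i] <- (raw[i] - mean(raw[i])) / sd(raw[i])
  }
  std
}

#' Rsb scan between two groups
#'
#' For every SNP, the raw statistic is `ln(iES_A / iES_B)` (integrals of
#' the site-specific EHHS in each group); it is standardized by
#' subtracting the genome-wide median and dividing by the standard
#' deviation (median-centering is robust to the sweep outliers being
#' sought), transformed with [p_transform()] into pRsB and flagged at
#' `threshold`. Positive standardized values indicate longer haplotype
#' homozygosity in group A.
#'
#' @param H_a,H_b phased haplotypes of the two groups, on the same marker
#'   map.
#' @param mm the shared [marker_map()].
#' @param cutoff EHHS truncation threshold (default 0.05).
#' @param threshold pRsB significance threshold (default 4.0).
#' @param side transform convention, see [p_transform()].
#' @return a [scan_track()] (statistic `"pRsB"`) with `value` = pRsB and
#'   extra columns `raw` and `std`.
#' @export
rsb_scan <- function(H_a, H_b, mm, cutoff = 0.05, threshold = 4.0,
                     side = "two.sided") {
  check_haplotypes(H_a, mm)
  check_haplotypes(H_b, mm)
  S <- ncol(H_a)
  raw <- rep(NA_real_, S)
  for (s in seq_len(S)) {
    ies_a <- integrate_ihh(ehhs_curve(H_a, mm, s, cutoff), mm)
    ies_b <- integrate_ihh(ehhs_curve(H_b, mm, s, cutoff), mm)
    if (is.na(ies_a) || is.na(ies_b) || ies_a == 0 || ies_b == 0) next
    raw[s] <- log(ies_a / ies_b)
  }
  def <- raw[!is.na(raw)]
  if (length(def) < 2L) stop("fewer than 2 defined Rsb values")
  s0 <- sd(def)
  if (s0 == 0) {  # e.g. identical haplotype sets: raw constant (usually 0)
    warning("degenerate Rsb distribution (zero sd); standardized set to 0")
    std <- ifelse(is.na(raw), NA_real_, 0)
  } else {
    std <- (raw - median(def)) / s0
  }
  logp <- p_transform(std, side)
  scan_track(mm, logp, "pRsB", flag = !is.na(logp) & logp >= threshold,
             extra = list(raw = raw, std = std))
}

#' Consistency of the iHS scan under random ancestral assignments
#'
#' Reruns [ihs_scan()] under `n_perm` random ancestral assignments and
#' compares each run to the major-allele run: Spearman rank correlation of
#' |standardized iHS| (over SNPs defined in both) and Jaccard overlap of
#' the significant sets.
#'
#' @param H,mm,... as in [ihs_scan()].
#' @param n_perm number of random assignments (default 100).
#' @param seed RNG seed; permutation k uses `seed + k`.
#' @param assignments optional list of `ancestral_assignment` objects to
#'   use instead of random draws (overrides `n_perm`).
#' @return a list of class `ihs_consistency` with the per-run data.frame
#'   (`run, cor_abs_std, jaccard`) and summary means.
#' @export
consistency_check <- function(H, mm, n_perm = 100L, seed = 1L,
                              assignments = NULL, ...) {
  base <- ihs_scan(H, mm, anc = NULL, ...)
  if (!is.null(assignments)) n_perm <- length(assignments)
  runs <- data.frame(run = seq_len(n_perm), cor_abs_std = NA_real_,
                     jaccard = NA_real_)
  for (k in seq_len(n_perm)) {
    anc <- if (!is.null(assignments)) assignments[[k]] else
      assign_ancestral_random(ncol(H), seed = seed + k)
    tr <- ihs_scan(H, mm, anc = anc, ...)
    ok <- !is.na(base$std) & !is.na(tr$std)
    if (sum(ok) >= 3L)
      runs$cor_abs_std[k] <- suppressWarnings(
        cor(abs(base$std[ok]), abs(tr$std[ok]), method = "spearman"))
    u <- sum(base$flag | tr$flag)
    runs$jaccard[k] <- if (u == 0L) 1 else sum(base$flag & tr$flag) / u
  }
  out <- list(runs = runs,
              mean_cor = mean(runs$cor_abs_std, na.rm = TRUE),
              mean_jaccard = mean(runs$jaccard, na.rm = TRUE),
              seed = seed)
  class(out) <- "ihs_consistency"
  out
}

#' @export
print.ihs_consistency <- function(x, ...) {
  cat("iHS ancestral-assignment consistency over", nrow(x$runs), "runs\n")
  cat(sprintf("  mean rank cor of |std iHS|: %.3f\n", x$mean_cor))
  cat(sprintf("  mean Jaccard of significant sets: %.3f\n", x$mean_jaccard))
  invisible(x)
}
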