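# Synthetic study generator: a linkage-free Balding-Nichols neutral
# background (so the EHH statistics have a fast-decaying null) with
# localized selective sweeps injected by copying a template haplotype
# over geometric-length segments around a core SNP, plus a truth table
# for recovery testing.

#' Default simulation configuration
#'
#' The default scenario mirrors, at desk scale, a two-group SNP-array
#' study: 2 groups x 100 diploids, 2,000 mapped autosomal SNPs on one
#' chromosome with SNP50-like ~2.5 kb mean spacing, between-group
#' Balding-Nichols differentiation F = 0.05, and one sweep in group A
#' (carrier fraction 0.8, mean haplotype half-length 50 SNPs) centred on
#' the middle SNP.
#'
#' @param n_snps number of SNPs (default 2000).
#' @param n_chrom number of chromosomes (default 1; SNPs split evenly).
#' @param pop_sizes named integer vector, diploids per population.
#' @param pop_groups named character vector, population -> group.
#' @param F between-group Balding-Nichols differentiation, in \[0, 0.5\].
#' @param spacing bp step range between adjacent SNPs (uniform draw).
#' @param sweeps list of sweep specs: each a list
#'   `(group, core_idx, f, mean_half_len)`; `NULL` for the default single
#'   sweep, `list()` for none.
#' @param seed RNG seed (default 1).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 2000L, n_chrom = 1L,
                       pop_sizes = c(popA = 100L, popB = 100L),
                       pop_groups = c(popA = "A", popB = "B"),
                       F = 0.05,
                       spacing = c(500L, 5000L),
                       sweeps = NULL,
                       seed = 1L) {
  stopifnot(n_snps >= 1L, all(pop_sizes >= 2L), F >= 0, F <= 0.5,
            all(names(pop_sizes) %in% names(pop_groups)))
  if (is.null(sweeps))
    sweeps <- list(list(group = unname(pop_groups[[1L]]),
                        core_idx = max(1L, n_snps %/% 2L),
                        f = 0.8, mean_half_len = 50))
  for (sw in sweeps)
    stopifnot(sw$f > 0, sw$f <= 1,
              sw$core_idx >= 1L, sw$core_idx <= n_snps)
  cfg <- list(n_snps = as.integer(n_snps), n_chrom = as.integer(n_chrom),
              pop_sizes = pop_sizes, pop_groups = pop_groups, F = F,
              spacing = spacing, sweeps = sweeps, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a SNP-array marker map
#'
#' bp positions are cumulative Uniform(`spacing[1]`, `spacing[2]`) steps
#' per chromosome (~2.5 kb mean spacing by default, emulating a 50K array
#' on a scaled genome); SNPs are split evenly across chromosomes.
#'
#' @param n_snps number of SNPs.
#' @param n_chrom number of chromosomes.
#' @param spacing bp step range.
#' @param seed RNG seed.
#' @return a [marker_map()].
#' @export
sim_marker_map <- function(n_snps, n_chrom = 1L, spacing = c(500L, 5000L),
                           seed = NULL) {
  chrom <- as.character(rep(seq_len(n_chrom), length.out = n_snps))
  chrom <- sort(chrom)  # contiguous blocks per chromosome
  pos <- with_seed(seed, {
    unlist(lapply(split(seq_len(n_snps), chrom), function(i)
      cumsum(round(runif(length(i), spacing[1L], spacing[2L])))))
  })
  marker_map(sprintf("snp%05d", seq_len(n_snps)), chrom, as.integer(pos),
             allele1 = "G", allele2 = "A")
}

#' Balding-Nichols per-group allele frequencies
#'
#' Ancestral frequency p ~ Uniform(0.05, 0.95) per SNP; each group's
#' frequency is an independent draw from
#' Beta(p (1 - F) / F, (1 - p)(1 - F) / F), whose mean is p and variance
#' F p (1 - p). F = 0 degenerates to every group sharing p exactly.
#'
#' @param n_snps number of SNPs.
#' @param groups character vector of group names.
#' @param F differentiation parameter in \[0, 0.5\].
#' @param seed RNG seed.
#' @return matrix SNPs x groups of allele-1 frequencies, with the
#'   ancestral frequencies as attribute `ancestral`.
#' @export
bn_frequencies <- function(n_snps, groups, F, seed = NULL) {
  with_seed(seed, {
    p <- runif(n_snps, 0.05, 0.95)
    freq <- matrix(NA_real_, n_snps, length(groups),
                   dimnames = list(NULL, groups))
    for (g in seq_along(groups)) {
      freq[, g] <- if (F == 0) p else
        rbeta(n_snps, p * (1 - F) / F, (1 - p) * (1 - F) / F)
    }
    attr(freq, "ancestral") <- p
    freq
  })
}

#' Sample phased haplotypes from group allele frequencies
#'
#' Each chromosome copy's allele at each SNP is an independent
#' Bernoulli(group frequency) draw -- a linkage-free drift baseline --
#' and diploids pair consecutive copies, so genotypes are Hardy-Weinberg
#' by construction.
#'
#' @param freqs SNPs x groups frequency matrix ([bn_frequencies()]).
#' @param pop_sizes named integer vector, diploids per population.
#' @param pop_groups named character vector, population -> group.
#' @param seed RNG seed.
#' @return list(haplotypes, samples).
#' @export
sample_haplotypes <- function(freqs, pop_sizes, pop_groups, seed = NULL) {
  n_snps <- nrow(freqs)
  with_seed(seed, {
    blocks <- list()
    ids <- pops <- character(0)
    for (pop in names(pop_sizes)) {
      g <- pop_groups[[pop]]
      if (!g %in% colnames(freqs)) stop("no frequencies for group ", g)
      n <- pop_sizes[[pop]]
      h <- matrix(rbinom(2L * n * n_snps, 1L, rep(freqs[, g], each = 2L * n)),
                  nrow = 2L * n)
      blocks[[pop]] <- h
      ids <- c(ids, sprintf("%s_%03d", pop, seq_len(n)))
      pops <- c(pops, rep(pop, n))
    }
    H <- do.call(rbind, blocks)
    storage.mode(H) <- "integer"
    st <- sample_table(ids, pops, group = unname(pop_groups[pops]))
    rownames(H) <- paste0(rep(st$sample_id, each = 2L), c("_1", "_2"))
    list(haplotypes = H, samples = st)
  })
}

#' Inject a selective sweep into a haplotype set
#'
#' Designates a template haplotype (the alleles of one randomly chosen
#' chromosome copy of the swept group, forced to allele 1 at the core)
#' and overwrites, for a fraction `f` of the swept group's copies, the
#' interval `[core - L, core + R]` with the template, where L and R are
#' independent Geometric(1 / mean_half_len) draws per copy (clamped to
#' the core's chromosome). Other groups are untouched. This mimics the
#' recombination-eroded shared haplotype around a selected core.
#'
#' @param H haplotype matrix.
#' @param mm the matching [marker_map()].
#' @param st the matching [sample_table()].
#' @param spec a list `(group, core_idx, f, mean_half_len)`.
#' @param seed RNG seed.
#' @return list(haplotypes, truth) where truth is a one-row data.frame
#'   `chrom, core_idx, core_bp, group, f, mean_half_len, n_carriers`.
#' @export
inject_sweep <- function(H, mm, st, spec, seed = NULL) {
  check_haplotypes(H, mm, st)
  rows <- which(rep(st$group, each = 2L) == spec$group)
  if (length(rows) == 0L) stop("no haplotypes in group ", spec$group)
  n_car <- as.integer(round(spec$f * length(rows)))
  if (n_car < 2L)
    stop("sweep would have fewer than 2 carrier chromosomes")
  bounds <- chrom_bounds(mm, spec$core_idx)
  with_seed(seed, {
    template <- H[sample(rows, 1L), ]
    template[spec$core_idx] <- 1L
    carriers <- sample(rows, n_car)
    for (cp in carriers) {
      L <- rgeom(1L, 1 / spec$mean_half_len)
      R <- rgeom(1L, 1 / spec$mean_half_len)
      lo <- max(bounds[1L], spec$core_idx - L)
      hi <- min(bounds[2L], spec$core_idx + R)
      H[cp, lo:hi] <- template[lo:hi]
    }
    truth <- data.frame(chrom = mm$chrom[spec$core_idx],
                        core_idx = spec$core_idx,
                        core_bp = mm$pos[spec$core_idx],
                        group = spec$group, f = spec$f,
                        mean_half_len = spec$mean_half_len,
                        n_carriers = n_car, stringsAsFactors = FALSE)
    list(haplotypes = H, truth = truth)
  })
}

#' Simulate a complete synthetic study
#'
#' Composes [sim_marker_map()], [bn_frequencies()], [sample_haplotypes()]
#' and [inject_sweep()] under one seed, and collapses haplotypes to
#' unphased genotype dosages (`G = H[2j-1, ] + H[2j, ]`, counting
#' allele 1).
#'
#' @param cfg a [sim_config()].
#' @return a list of class `sim_dataset`: `haplotypes, genotypes, markers,
#'   samples, truth, freqs, config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  mm <- sim_marker_map(cfg$n_snps, cfg$n_chrom, cfg$spacing, seed = cfg$seed)
  groups <- unique(unname(cfg$pop_groups[names(cfg$pop_sizes)]))
  freqs <- bn_frequencies(cfg$n_snps, groups, cfg$F, seed = cfg$seed + 1L)
  hs <- sample_haplotypes(freqs, cfg$pop_sizes, cfg$pop_groups,
                          seed = cfg$seed + 2L)
  H <- hs$haplotypes
  truth <- NULL
  for (k in seq_along(cfg$sweeps)) {
    sw <- inject_sweep(H, mm, hs$samples, cfg$sweeps[[k]],
                       seed = cfg$seed + 2L + k)
    H <- sw$haplotypes
    truth <- rbind(truth, sw$truth)
  }
  odd <- seq(1L, nrow(H), by = 2L)
  G <- H[odd, , drop = FALSE] + H[odd + 1L, , drop = FALSE]
  rownames(G) <- hs$samples$sample_id
  colnames(G) <- mm$snp_id
  out <- list(haplotypes = H, genotypes = G, markers = mm,
              samples = hs$samples,
              truth = truth %||% data.frame(),
              freqs = freqs, config = cfg)
  class(out) <- "sim_dataset"
  out
}

#' Write a simulated dataset to disk
#'
#' Emits a phased VCF, a PLINK PED/MAP pair (unphased collapse), the
#' sample table TSV and the sweep truth TSV. Note the PED/MAP dosage
#' round-trip caveat of [write_plink_textset()].
#'
#' @param sim a [simulate_dataset()] result.
#' @param out_dir output directory (created if needed).
#' @param formats subset of `c("vcf", "plink", "samples", "truth")`.
#' @return named character vector of paths written.
#' @export
write_dataset <- function(sim, out_dir,
                          formats = c("vcf", "plink", "samples", "truth")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if ("vcf" %in% formats) {
    p <- file.path(out_dir, "haplotypes.vcf")
    write_phased_vcf(sim$haplotypes, sim$markers, sim$samples, p)
    paths["vcf"] <- p
  }
  if ("plink" %in% formats) {
    ped <- file.path(out_dir, "genotypes.ped")
    map <- file.path(out_dir, "genotypes.map")
    write_plink_textset(sim$genotypes, sim$markers, sim$samples, ped, map)
    paths["ped"] <- ped
    paths["map"] <- map
  }
  if ("samples" %in% formats) {
    p <- file.path(out_dir, "samples.tsv")
    write_sample_table(sim$samples, p)
    paths["samples"] <- p
  }
  if ("truth" %in% formats) {
    p <- file.path(out_dir, "sweep_truth.tsv")
    write.table(sim$truth, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["truth"] <- p
  }
  paths
}
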