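# Genotype / haplotype input-output and quality control.
#
# Genotypes are held as an individuals x SNPs integer matrix of
# minor-allele dosages {0, 1, 2, NA}; phased haplotypes as a
# (2 x individuals) x SNPs {0, 1} matrix with the two chromosome copies of
# sample j in rows 2j-1 and 2j.

#' Read a PLINK text fileset (PED/MAP)
#'
#' Parses whitespace-delimited PED/MAP files, recodes each genotype to the
#' dosage of the file-wide minor allele of that SNP, and re-sorts markers
#' by (chromosome, position), permuting genotype columns accordingly.
#' `"0"` alleles mark missing genotypes: a genotype with either allele
#' missing becomes `NA`. The minor allele is the rarer of the two observed
#' allele labels; an exact 50/50 tie is broken by taking the
#' lexicographically larger label as minor (so that [write_plink_textset()]
#' round-trips). The PED family identifier (column 1) is used as the
#' population label.
#'
#' @param ped_path path to the PED file (6 metadata columns + 2 alleles per
#'   SNP).
#' @param map_path path to the MAP file (4 columns: chrom, snp_id, cM, bp).
#' @return a list with elements `genotypes` (integer matrix, rownames =
#'   sample ids, colnames = snp ids), `markers` (a [marker_map()]) and
#'   `samples` (a [sample_table()]).
#' @export
read_plink_textset <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- read.table(map_path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
  if (ncol(map) != 4L)
    stop("MAP file must have 4 columns (chrom, snp_id, cM, bp), found ",
         ncol(map))
  names(map) <- c("chrom", "snp_id", "cm", "pos")
  if (any(!grepl("^-?[0-9]+$", map$pos)))
    stop("non-integer bp position in MAP file: ",
         map$snp_id[!grepl("^-?[0-9]+$", map$pos)][1L])
  if (anyDuplicated(map$snp_id))
    stop("duplicate snp_id in MAP file: ",
         map$snp_id[duplicated(map$snp_id)][1L])
  n_snp <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * n_snp
  bad <- which(lengths(toks) != want)
  if (length(bad))
    stop("ragged PED row: line ", bad[1L], " has ", lengths(toks)[bad[1L]],
         " fields, expected ", want)
  n_ind <- length(toks)
  ped <- matrix(unlist(toks), nrow = n_ind, byrow = TRUE)

  a1 <- ped[, 6L + 2L * seq_len(n_snp) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(n_snp), drop = FALSE]
  G <- matrix(NA_integer_, n_ind, n_snp)
  minor <- major <- character(n_snp)
  for (j in seq_len(n_snp)) {
    al <- c(a1[, j], a2[, j])
    obs <- al[al != "0"]
    labs <- sort(unique(obs))
    if (length(labs) > 2L)
      stop("more than two alleles at SNP ", map$snp_id[j], ": ",
           paste(labs, collapse = "/"))
    miss <- a1[, j] == "0" | a2[, j] == "0"
    if (length(labs) <= 1L) {
      # monomorphic (or all-missing): the minor allele is unobserved
      minor[j] <- NA_character_
      major[j] <- if (length(labs)) labs else NA_character_
      d <- rep(0L, n_ind)
    } else {
      cnt <- c(sum(obs == labs[1L]), sum(obs == labs[2L]))
      # minor = rarer label; tie -> lexicographically larger label
      mi <- if (cnt[2L] <= cnt[1L]) 2L else 1L
      minor[j] <- labs[mi]
      major[j] <- labs[3L - mi]
      d <- (a1[, j] == minor[j]) + (a2[, j] == minor[j])
    }
    d[miss] <- NA_integer_
    G[, j] <- as.integer(d)
  }

  mm <- marker_map(map$snp_id, map$chrom, as.integer(map$pos),
                   allele1 = minor, allele2 = major)
  perm <- attr(mm, "sort_order")
  G <- G[, perm, drop = FALSE]
  st <- sample_table(ped[, 2L], population = ped[, 1L])
  dimnames(G) <- list(st$sample_id, mm$snp_id)
  list(genotypes = G, markers = mm, samples = st)
}

#' Write a PLINK text fileset (PED/MAP)
#'
#' Inverse of [read_plink_textset()]. Each SNP's counted allele is written
#' with its `allele1` label from the marker map (falling back to `"B"`,
#' with `"A"` for the other allele); `NA` genotypes become `"0 0"`. A
#' matrix whose dosages count the file-wide minor allele at every SNP
#' round-trips exactly through [read_plink_textset()]; other SNPs are
#' recovered up to allele orientation (dosage `2 - d`).
#'
#' @param G integer dosage matrix (individuals x SNPs).
#' @param mm the matching [marker_map()].
#' @param st the matching [sample_table()].
#' @param ped_path,map_path output paths.
#' @return `ped_path`, invisibly.
#' @export
write_plink_textset <- function(G, mm, st, ped_path, map_path) {
  check_genotypes(G, mm, st)
  a1 <- ifelse(is.na(mm$allele1), "B", mm$allele1)
  a2 <- ifelse(is.na(mm$allele2), "A", mm$allele2)
  map <- data.frame(mm$chrom, mm$snp_id, 0, mm$pos)
  write.table(map, map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n <- nrow(G)
  rows <- character(n)
  for (i in seq_len(n)) {
    d <- G[i, ]
    x <- ifelse(is.na(d), "0 0",
         ifelse(d == 0L, paste(a2, a2),
         ifelse(d == 1L, paste(a1, a2), paste(a1, a1))))
    rows[i] <- paste(st$population[i], st$sample_id[i], 0, 0, 0, -9,
                     paste(x, collapse = " "))
  }
  writeLines(rows, ped_path)
  invisible(ped_path)
}

#' Read phased haplotypes from a VCF
#'
#' Reads a biallelic, fully phased VCF (every GT uses the `|` separator)
#' and returns a {0,1} haplotype matrix with REF mapped to 0 and ALT to 1.
#' Sites are re-sorted by (chromosome, position). Unphased or missing GT
#' fields and multi-allelic records are errors (phasing is an upstream
#' responsibility).
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF.
#' @param samples optional [sample_table()] supplying population/group
#'   labels for the VCF samples.
#' @return a list with `haplotypes` ((2 x individuals) x SNPs matrix),
#'   `markers` (a [marker_map()]) and `samples` (a [sample_table()]).
#' @export
read_phased_vcf <- function(vcf_path, samples = NULL) {
  stopifnot(file.exists(vcf_path))
  vcf <- suppressWarnings(VariantAnnotation::readVcf(vcf_path))
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  if (any(S4Vectors::elementNROWS(alt) != 1L)) {
    bad <- which(S4Vectors::elementNROWS(alt) != 1L)[1L]
    stop("multi-allelic site at ", as.character(GenomicRanges::seqnames(rr))[bad],
         ":", GenomicRanges::start(rr)[bad])
  }
  gt <- VariantAnnotation::geno(vcf)$GT  # sites x samples
  if (is.null(gt)) stop("VCF has no GT field")
  ok <- array(grepl("^[01]\\|[01]$", gt), dim = dim(gt))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop("unphased or missing genotype '", gt[bad[1L], bad[2L]],
         "' at record ", rownames(gt)[bad[1L]],
         " sample ", colnames(gt)[bad[2L]],
         " (all GT fields must be phased biallelic '|')")
  }
  ids <- names(rr)
  if (is.null(ids) || anyDuplicated(ids))
    ids <- paste0("var", seq_along(rr))
  mm <- marker_map(ids,
                   as.character(GenomicRanges::seqnames(rr)),
                   GenomicRanges::start(rr),
                   allele1 = as.character(unlist(alt)),
                   allele2 = as.character(VariantAnnotation::ref(vcf)))
  perm <- attr(mm, "sort_order")
  gt <- gt[perm, , drop = FALSE]

  n_ind <- ncol(gt)
  H <- matrix(NA_integer_, 2L * n_ind, nrow(mm))
  h1 <- matrix(as.integer(substr(t(gt), 1L, 1L)), nrow = n_ind)
  h2 <- matrix(as.integer(substr(t(gt), 3L, 3L)), nrow = n_ind)
  H[seq(1L, 2L * n_ind, by = 2L), ] <- h1
  H[seq(2L, 2L * n_ind, by = 2L), ] <- h2

  sid <- colnames(gt)
  st <- if (is.null(samples)) sample_table(sid, population = "unknown")
        else apply_sample_labels(sample_table(sid, "unknown"), samples)
  rownames(H) <- paste0(rep(sid, each = 2L), c("_1", "_2"))
  colnames(H) <- mm$snp_id
  list(haplotypes = H, markers = mm, samples = st)
}

#' Write phased haplotypes to a VCF
#'
#' Emits a minimal VCF v4.2 with phased GT fields; allele labels come from
#' the marker map (`allele2` = REF = 0, `allele1` = ALT = 1, defaulting to
#' A/G). Round-trips exactly through [read_phased_vcf()].
#'
#' @param H (2 x individuals) x SNPs {0,1} matrix.
#' @param mm the matching [marker_map()].
#' @param st the matching [sample_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(H, mm, st, path) {
  check_haplotypes(H, mm, st)
  ref <- ifelse(is.na(mm$allele2), "A", mm$allele2)
  alt <- ifelse(is.na(mm$allele1), "G", mm$allele1)
  n_ind <- nrow(H) %/% 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", unique(mm$chrom), ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", st$sample_id), collapse = "\t")),
             con)
  h1 <- H[seq(1L, 2L * n_ind, by = 2L), , drop = FALSE]
  h2 <- H[seq(2L, 2L * n_ind, by = 2L), , drop = FALSE]
  for (j in seq_len(nrow(mm))) {
    gts <- paste0(h1[, j], "|", h2[, j])
    writeLines(paste(c(mm$chrom[j], mm$pos[j], mm$snp_id[j], ref[j], alt[j],
                       ".", "PASS", ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}

check_genotypes <- function(G, mm, st) {
  stopifnot(is.matrix(G))
  if (ncol(G) != nrow(mm))
    stop("genotype matrix has ", ncol(G), " SNPs but marker map has ", nrow(mm))
  if (nrow(G) != nrow(st))
    stop("genotype matrix has ", nrow(G), " samples but sample table has ",
         nrow(st))
  if (!all(G %in% c(0L, 1L, 2L, NA)))
    stop("genotype dosages must be in {0, 1, 2, NA}")
  invisible(TRUE)
}

check_haplotypes <- function(H, mm, st = NULL) {
  stopifnot(is.matrix(H))
  if (nrow(H) %% 2L != 0L) stop("haplotype matrix must have an even row count")
  if (ncol(H) != nrow(mm))
    stop("haplotype matrix has ", ncol(H), " SNPs but marker map has ", nrow(mm))
  if (!is.null(st) && nrow(H) != 2L * nrow(st))
    stop("haplotype matrix rows must be 2 x samples")
  if (anyNA(H) || !all(H %in% c(0L, 1L)))
    stop("haplotypes must be complete {0,1}")
  invisible(TRUE)
}

qc_report <- function(axis, input, removed, thresholds) {
  rep <- list(axis = axis, input = input, removed = removed,
              retained = input - sum(unlist(removed)), thresholds = thresholds)
  class(rep) <- "qc_report"
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (", x$axis, "): ", x$input, " in, ", x$retained,
      " retained\n", sep = "")
  for (nm in names(x$removed))
    cat("  removed by ", nm, ": ", x$removed[[nm]], "\n", sep = "")
  invisible(x)
}

#' Write a QC report as TSV
#' @param rep a QC report from [snp_qc_filter()] / [sample_qc_filter()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(rep, path) {
  df <- data.frame(axis = rep$axis,
                   filter = c("input", names(rep$removed), "retained"),
                   count = c(rep$input, unlist(rep$removed), rep$retained))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-SNP quality control
#'
#' Retains SNPs with call rate >= `min_snp_call`, minor allele frequency
#' (on non-missing genotypes) >= `min_maf`, and a chromosome in the
#' `autosomes` set; marker order is preserved. A SNP failing several
#' filters is counted against the first (call rate, then MAF, then
#' autosome), so removal counts sum to `input - retained`.
#'
#' @param G dosage matrix.
#' @param mm the matching [marker_map()].
#' @param min_snp_call minimum per-SNP call rate (default 0.95).
#' @param min_maf minimum minor allele frequency (default 0.03).
#' @param autosomes character vector of autosomal chromosome labels
#'   (e.g. `as.character(1:26)` for sheep); a required, species-specific
#'   choice.
#' @return list(genotypes, markers, report).
#' @export
snp_qc_filter <- function(G, mm, min_snp_call = 0.95, min_maf = 0.03,
                          autosomes) {
  if (ncol(G) != nrow(mm))
    stop("genotype matrix has ", ncol(G), " SNPs but marker map has ",
         nrow(mm))
  n <- nrow(G)
  nonmiss <- colSums(!is.na(G))
  call_rate <- nonmiss / n
  p <- colSums(G, na.rm = TRUE) / (2 * nonmiss)
  maf <- pmin(p, 1 - p)
  maf[nonmiss == 0] <- 0
  fail_call <- call_rate < min_snp_call
  fail_maf <- !fail_call & maf < min_maf
  fail_auto <- !fail_call & !fail_maf & !(mm$chrom %in% as.character(autosomes))
  keep <- !(fail_call | fail_maf | fail_auto)
  if (!any(keep)) stop("no SNPs survive QC")
  rep <- qc_report("snp", nrow(mm),
                   list(call_rate = sum(fail_call), maf = sum(fail_maf),
                        non_autosomal = sum(fail_auto)),
                   list(min_snp_call = min_snp_call, min_maf = min_maf,
                        autosomes = paste(autosomes, collapse = ",")))
  mm2 <- mm[keep, , drop = FALSE]
  rownames(mm2) <- NULL
  attr(mm2, "sort_order") <- seq_len(nrow(mm2))
  class(mm2) <- class(mm)
  list(genotypes = G[, keep, drop = FALSE], markers = mm2, report = rep)
}

#' Per-sample quality control
#'
#' Retains individuals genotyped for at least `min_sample_call` of the
#' SNPs.
#'
#' @param G dosage matrix.
#' @param st the matching [sample_table()].
#' @param min_sample_call minimum per-sample call rate (default 0.95).
#' @return list(genotypes, samples, report).
#' @export
sample_qc_filter <- function(G, st, min_sample_call = 0.95) {
  if (nrow(G) != nrow(st)) stop("genotypes and sample table disagree")
  call_rate <- rowSums(!is.na(G)) / ncol(G)
  keep <- call_rate >= min_sample_call
  if (!any(keep)) stop("no samples survive QC")
  rep <- qc_report("sample", nrow(st),
                   list(call_rate = sum(!keep)),
                   list(min_sample_call = min_sample_call))
  st2 <- st[keep, , drop = FALSE]
  rownames(st2) <- NULL
  class(st2) <- class(st)
  list(genotypes = G[keep, , drop = FALSE], samples = st2, report = rep)
}

#' LD thinning: keep one SNP in every block of k
#'
#' Partitions the (chrom, pos)-sorted marker list into consecutive blocks
#' of `k` and keeps the last SNP of each complete block; an incomplete
#' trailing block is dropped, so `floor(n / k)` SNPs are retained. With
#' the SNP-array marker density this emulates sampling one in every k
#' SNPs to obtain an approximately unlinked subset.
#'
#' @param mm a [marker_map()] (already sorted by construction).
#' @param k block size (default 10).
#' @return integer vector of retained marker row indices.
#' @export
thin_every_kth <- function(mm, k = 10L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  n <- if (is.data.frame(mm)) nrow(mm) else as.integer(mm)
  if (n < k) return(integer(0))
  seq_len(n %/% k) * k
}

`%||%` <- function(a, b) if (is.null(a)) b else a
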