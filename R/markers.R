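# Core tabular types shared by every stage: the marker map (coordinate
# backbone), the sample table (population / group structure) and the
# per-SNP scan track (common currency of the three selection scans).

#' Order chromosomes naturally
#'
#' Numeric-looking chromosome labels sort numerically (1, 2, ..., 26),
#' the rest (X, MT, scaffolds) alphabetically after them.
#'
#' @param chrom character vector of chromosome labels.
#' @return integer ranks usable in `order()`.
#' @keywords internal
chrom_rank <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.numeric(chrom))
  lev <- unique(chrom[order(is.na(num), num, chrom)])
  match(chrom, lev)
}

#' Construct a marker map
#'
#' The marker map is the shared coordinate backbone: one row per SNP with a
#' unique identifier, a chromosome label and a 1-based bp position. Rows are
#' always stored sorted by (chromosome, position). Optional allele labels
#' record which allele the genotype dosage counts (`allele1`) and its
#' complement (`allele2`).
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom chromosome labels (coerced to character).
#' @param pos integer bp positions, 1-based, strictly positive.
#' @param allele1,allele2 optional allele labels (counted / other).
#' @return a `data.frame` of class `marker_map`, sorted by (chrom, pos).
#' @examples
#' marker_map(c("s1", "s2"), c("1", "1"), c(500L, 100L))
#' @export
marker_map <- function(snp_id, chrom, pos, allele1 = NULL, allele2 = NULL) {
  snp_id <- as.character(snp_id)
  chrom <- as.character(chrom)
  if (anyNA(suppressWarnings(as.numeric(pos))) || any(as.numeric(pos) %% 1 != 0))
    stop("marker positions must be integer bp")
  pos <- as.integer(pos)
  n <- length(snp_id)
  stopifnot(length(chrom) == n, length(pos) == n)
  if (any(pos <= 0)) stop("marker positions must be positive (1-based bp)")
  if (anyDuplicated(snp_id)) {
    dup <- snp_id[duplicated(snp_id)][1L]
    stop("duplicate snp_id: ", dup)
  }
  if (anyDuplicated(paste(chrom, pos)))
    stop("two SNPs share the same (chrom, pos)")
  mm <- data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos,
    allele1 = if (is.null(allele1)) NA_character_ else as.character(allele1),
    allele2 = if (is.null(allele2)) NA_character_ else as.character(allele2),
    stringsAsFactors = FALSE
  )
  ord <- order(chrom_rank(mm$chrom), mm$pos)
  mm <- mm[ord, , drop = FALSE]
  rownames(mm) <- NULL
  attr(mm, "sort_order") <- ord  # permutation applied to the input order
  class(mm) <- c("marker_map", "data.frame")
  mm
}

#' Construct a sample table
#'
#' Maps each sample to a population and each population to exactly one
#' group (the unit of the selection contrast, e.g. focal vs reference).
#'
#' @param sample_id unique sample identifiers.
#' @param population population (breed) label per sample.
#' @param group group label per sample; defaults to the population.
#' @return a `data.frame` of class `sample_table`.
#' @export
sample_table <- function(sample_id, population, group = population) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  population <- rep_len(as.character(population), n)
  group <- rep_len(as.character(group), n)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id: ", sample_id[duplicated(sample_id)][1L])
  if (anyNA(population) || any(!nzchar(population)))
    stop("every sample needs a population label")
  p2g <- unique(data.frame(population, group))
  if (anyDuplicated(p2g$population))
    stop("a population maps to more than one group")
  st <- data.frame(sample_id = sample_id, population = population,
                   group = group, stringsAsFactors = FALSE)
  class(st) <- c("sample_table", "data.frame")
  st
}

#' Read a sample table from a 3-column TSV
#'
#' Expected columns (with header): `sample_id`, `population`, `group`.
#'
#' @param path path to the TSV file.
#' @return a [sample_table()].
#' @export
read_sample_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", stringsAsFactors = FALSE)
  need <- c("sample_id", "population", "group")
  if (!all(need %in% names(df)))
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  sample_table(df$sample_id, df$population, df$group)
}

#' Write a sample table as TSV
#' @param st a [sample_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(st, path) {
  write.table(as.data.frame(st), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Attach population/group labels from a sample table to another
#'
#' Replaces the population and group columns of `st` by those found in
#' `labels` (matched on `sample_id`); errors on samples absent from
#' `labels`.
#'
#' @param st,labels sample tables.
#' @return a [sample_table()] in `st`'s row order.
#' @export
apply_sample_labels <- function(st, labels) {
  i <- match(st$sample_id, labels$sample_id)
  if (anyNA(i))
    stop("samples missing from label table: ",
         paste(head(st$sample_id[is.na(i)], 5L), collapse = ", "))
  sample_table(st$sample_id, labels$population[i], labels$group[i])
}

#' Construct a per-SNP scan track
#'
#' A scan track aligns one statistic to the marker map: one row per SNP
#' with the statistic value (`NA` where undefined) and a significance
#' flag. Extra per-SNP columns (raw / standardized values of the EHH
#' statistics) may be supplied via `extra`.
#'
#' @param mm a [marker_map()].
#' @param value numeric vector aligned to `mm` (NA = undefined).
#' @param statistic name of the statistic (e.g. "fst", "di", "piHS").
#' @param flag logical significance flags (only on defined values).
#' @param extra optional named list of aligned columns.
#' @return a `data.frame` of class `scan_track` with columns
#'   `snp_id, chrom, pos, value, flag` (+ extras).
#' @export
scan_track <- function(mm, value, statistic, flag = FALSE, extra = NULL) {
  n <- nrow(mm)
  value <- rep_len(as.numeric(value), n)
  flag <- rep_len(as.logical(flag), n)
  flag[is.na(flag)] <- FALSE
  flag[is.na(value)] <- FALSE  # flags only on defined values
  tr <- data.frame(snp_id = mm$snp_id, chrom = mm$chrom, pos = mm$pos,
                   value = value, flag = flag, stringsAsFactors = FALSE)
  for (nm in names(extra)) tr[[nm]] <- extra[[nm]]
  attr(tr, "statistic") <- statistic
  class(tr) <- c("scan_track", "data.frame")
  tr
}

#' Write a scan track as TSV
#' @param track a [scan_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_track <- function(track, path) {
  write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so library functions stay side-effect free.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
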