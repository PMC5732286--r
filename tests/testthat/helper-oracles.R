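# Independent oracles and in-code fixtures shared across test files.
# Oracles deliberately use different formulations from the package code.

# Weir & Cockerham (1984) theta-hat for two populations, coded from the
# general multi-allele variance-component form: sum the a, b, c components
# over both alleles of the biallelic SNP. The package uses the biallelic
# shortcut; agreement is a genuine dual-route check.
oracle_wc_fst <- function(da, db) {
  da <- da[!is.na(da)]
  db <- db[!is.na(db)]
  if (length(da) < 2L || length(db) < 2L) return(NA_real_)
  r <- 2
  n <- c(length(da), length(db))
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  asum <- bsum <- csum <- 0
  for (allele in c("alt", "ref")) {
    p <- if (allele == "alt") c(mean(da) / 2, mean(db) / 2)
         else 1 - c(mean(da) / 2, mean(db) / 2)
    h <- c(mean(da == 1L), mean(db == 1L))  # hets carry one copy of each
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- nbar / nc *
      (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    asum <- asum + a
    bsum <- bsum + b
    csum <- csum + hbar / 2
  }
  denom <- asum + bsum + csum
  if (abs(denom) < .Machine$double.eps) NA_real_ else asum / denom
}

# Brute-force EHH: fraction of carrier pairs with identical allele strings
# over the inclusive interval from core to marker t.
oracle_ehh <- function(H, rows, core, t) {
  n <- length(rows)
  if (n < 2L) return(NA_real_)
  seg <- H[rows, core:t, drop = FALSE]
  str <- apply(seg, 1L, paste, collapse = "")
  sum(choose(table(str), 2)) / choose(n, 2)
}

# Brute-force EHHS: pairwise string homozygosity over all rows, normalized
# by the core-site homozygosity.
oracle_ehhs <- function(H, core, t) {
  n <- nrow(H)
  h0 <- sum(choose(table(H[, core]), 2)) / choose(n, 2)
  if (h0 == 0) return(NA_real_)
  oracle_ehh(H, seq_len(n), core, t) / h0
}

# Brute-force candidate-region caller: walks the flag vector row by row,
# no rle, no vectorization (independent of the package implementation).
oracle_call_runs <- function(chrom, pos, flag, min_run = 2L, pad_bp = 500L) {
  out <- NULL
  i <- 1L
  n <- length(flag)
  while (i <= n) {
    if (flag[i]) {
      j <- i
      while (j < n && flag[j + 1L] && chrom[j + 1L] == chrom[i]) j <- j + 1L
      if (j - i + 1L >= min_run)
        out <- rbind(out, data.frame(chrom = chrom[i],
                                     start = max(1L, pos[i] - pad_bp),
                                     end = pos[j] + pad_bp))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) return(out)
  # merge overlaps
  merged <- out[1L, ]
  for (k in seq_len(nrow(out))[-1L]) {
    m <- nrow(merged)
    if (out$chrom[k] == merged$chrom[m] && out$start[k] <= merged$end[m])
      merged$end[m] <- max(merged$end[m], out$end[k])
    else merged <- rbind(merged, out[k, ])
  }
  merged
}

# random phased haplotype fixture with a marker map
random_hapset <- function(n_hap, n_snp, seed, p = NULL) {
  withr::with_seed(seed, {
    if (is.null(p)) p <- runif(n_snp, 0.1, 0.9)
    H <- matrix(rbinom(n_hap * n_snp, 1L, rep(p, each = n_hap)), n_hap)
    storage.mode(H) <- "integer"
    mm <- marker_map(sprintf("s%03d", seq_len(n_snp)), rep("1", n_snp),
                     cumsum(sample(500:5000, n_snp, TRUE)))
    list(H = H, mm = mm)
  })
}

# tiny PED/MAP fixture written to tempdir; returns paths + hand expectations
write_tiny_pedmap <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  map <- c("1\tsnpA\t0\t100",
           "1\tsnpB\t0\t200",
           "2\tsnpC\t0\t50")
  # sample1: A A | A G | C C ; sample2: A G | G G | C T
  # snpA alleles {A:3, G:1} -> minor G; snpB {A:1, G:3} -> minor A;
  # snpC {C:3, T:1} -> minor T
  ped <- c("fam1 sample1 0 0 0 -9 A A A G C C",
           "fam1 sample2 0 0 0 -9 A G G G C T")
  ped_path <- file.path(dir, "toy.ped")
  map_path <- file.path(dir, "toy.map")
  writeLines(ped, ped_path)
  writeLines(map, map_path)
  list(ped = ped_path, map = map_path,
       # marker order sorted: snpA(1:100), snpB(1:200), snpC(2:50)
       expected = matrix(c(0L, 1L,   # snpA: dosage of G
                           1L, 0L,   # snpB: dosage of A
                           0L, 1L),  # snpC: dosage of T
                         nrow = 2L, dimnames = list(c("sample1", "sample2"),
                                                    c("snpA", "snpB", "snpC"))))
}

# small phased VCF fixture: 3 samples x 4 sites, hand-transcribed truth
write_tiny_vcf <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                           gts = NULL) {
  if (is.null(gts))
    gts <- rbind(c("0|1", "1|1", "0|0"),
                 c("1|0", "0|0", "1|1"),
                 c("0|0", "0|1", "1|0"),
                 c("1|1", "1|0", "0|1"))
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "ind1", "ind2", "ind3"), collapse = "\t"))
  body <- vapply(seq_len(nrow(gts)), function(i)
    paste(c("1", i * 1000L, paste0("v", i), "A", "G", ".", "PASS", ".", "GT",
            gts[i, ]), collapse = "\t"), "")
  path <- file.path(dir, "toy.vcf")
  writeLines(c(hdr, body), path)
  path
}
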