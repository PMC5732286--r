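# PLINK/VCF parsing, QC filters and LD thinning.

test_that("PED/MAP parsing recodes to minor-allele dosage and handles missing", {
  fx <- write_tiny_pedmap()
  got <- read_plink_textset(fx$ped, fx$map)
  expect_identical(unname(got$genotypes), unname(fx$expected))
  expect_identical(got$markers$snp_id, c("snpA", "snpB", "snpC"))
  expect_identical(got$samples$sample_id, c("sample1", "sample2"))
  expect_identical(got$samples$population, c("fam1", "fam1"))

  # "0 0" at one genotype -> that cell missing, others unaffected
  dir <- withr::local_tempdir()
  writeLines(c("fam1 s1 0 0 0 -9 A A 0 0 C C",
               "fam1 s2 0 0 0 -9 A G G G C T"),
             file.path(dir, "m.ped"))
  writeLines(readLines(fx$map), file.path(dir, "m.map"))
  gm <- read_plink_textset(file.path(dir, "m.ped"), file.path(dir, "m.map"))
  expect_true(is.na(gm$genotypes["s1", "snpB"]))
  expect_identical(sum(is.na(gm$genotypes)), 1L)
})

test_that("unsorted MAP positions are re-sorted with columns permuted", {
  dir <- withr::local_tempdir()
  writeLines(c("1\tsnpB\t0\t200", "1\tsnpA\t0\t100"), file.path(dir, "u.map"))
  writeLines(c("f s1 0 0 0 -9 G G A A",
               "f s2 0 0 0 -9 G T A T"), file.path(dir, "u.ped"))
  got <- read_plink_textset(file.path(dir, "u.ped"), file.path(dir, "u.map"))
  expect_identical(got$markers$snp_id, c("snpA", "snpB"))
  expect_identical(got$markers$pos, c(100L, 200L))
  # snpA col (T minor): dosages 0,1 ; snpB col (T minor): 0,1
  expect_identical(unname(got$genotypes[, "snpA"]), c(0L, 1L))
  expect_identical(unname(got$genotypes[, "snpB"]), c(0L, 1L))
})

test_that("malformed PED/MAP inputs raise named errors", {
  fx <- write_tiny_pedmap()
  dir <- withr::local_tempdir()
  writeLines(c("f s1 0 0 0 -9 A A G G C C",
               "f s2 0 0 0 -9 A A G G"), file.path(dir, "r.ped"))
  writeLines(readLines(fx$map), file.path(dir, "r.map"))
  expect_error(read_plink_textset(file.path(dir, "r.ped"),
                                  file.path(dir, "r.map")),
               "ragged PED row: line 2")
  writeLines(c("1\tdup\t0\t100", "1\tdup\t0\t200"), file.path(dir, "d.map"))
  expect_error(read_plink_textset(file.path(dir, "r.ped"),
                                  file.path(dir, "d.map")), "duplicate snp_id")
  writeLines(c("1\ta\t0\t1e5", "1\tb\t0\t200"), file.path(dir, "n.map"))
  expect_error(read_plink_textset(file.path(dir, "r.ped"),
                                  file.path(dir, "n.map")), "non-integer bp")
})

test_that("phased VCF parsing maps REF/ALT to 0/1 haplotype rows", {
  path <- write_tiny_vcf()
  got <- read_phased_vcf(path)
  # hand transcription: sample j rows 2j-1, 2j; sites in position order
  expect_identical(dim(got$haplotypes), c(6L, 4L))
  expect_identical(unname(got$haplotypes[, 1L]), c(0L, 1L, 1L, 1L, 0L, 0L))
  expect_identical(unname(got$haplotypes[, 2L]), c(1L, 0L, 0L, 0L, 1L, 1L))
  expect_identical(unname(got$haplotypes[, 4L]), c(1L, 1L, 1L, 0L, 0L, 1L))
  expect_identical(got$markers$pos, c(1000L, 2000L, 3000L, 4000L))
})

test_that("single-sample GT 0|1 gives rows [0],[1]", {
  gts <- matrix(c("0|1"), nrow = 1L)
  dir <- withr::local_tempdir()
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="x">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "only"), collapse = "\t"),
               paste(c("1", "100", "v1", "A", "G", ".", "PASS", ".", "GT",
                       "0|1"), collapse = "\t")),
             file.path(dir, "one.vcf"))
  got <- read_phased_vcf(file.path(dir, "one.vcf"))
  expect_identical(unname(got$haplotypes[, 1L]), c(0L, 1L))
})

test_that("unphased or missing GT and multi-allelic sites are rejected", {
  gts <- rbind(c("0|1", "1|1", "0|0"),
               c("1|0", "./.", "1|1"))
  path <- write_tiny_vcf(gts = gts[, , drop = FALSE])
  expect_error(read_phased_vcf(path), "unphased or missing")
  gts2 <- rbind(c("0|1", "1|1", "0|0"), c("1|0", "0/0", "1|1"))
  expect_error(read_phased_vcf(write_tiny_vcf(gts = gts2)),
               "unphased or missing")
  dir <- withr::local_tempdir()
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="x">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s"), collapse = "\t"),
               paste(c("1", "100", "v1", "A", "G,T", ".", "PASS", ".", "GT",
                       "0|1"), collapse = "\t")),
             file.path(dir, "multi.vcf"))
  expect_error(read_phased_vcf(file.path(dir, "multi.vcf")), "multi-allelic")
})

test_that("VCF and PED/MAP writers round-trip through their readers", {
  sim <- simulate_dataset(sim_config(n_snps = 60L,
                                     pop_sizes = c(popA = 5L, popB = 5L),
                                     sweeps = list(), seed = 11L))
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "rt.vcf")
  write_phased_vcf(sim$haplotypes, sim$markers, sim$samples, vcf)
  back <- read_phased_vcf(vcf)
  expect_identical(unname(back$haplotypes), unname(sim$haplotypes))
  expect_identical(back$markers$pos, sim$markers$pos)

  # PED/MAP: dosages recovered exactly where the matrix counts the minor
  # allele, and up to orientation (2 - d) elsewhere
  write_plink_textset(sim$genotypes, sim$markers, sim$samples,
                      file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  gt <- read_plink_textset(file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  p <- colMeans(sim$genotypes) / 2
  minor_coded <- p < 0.5 | (p == 0.5)  # tie rule favours the counted "B"
  same <- gt$genotypes == sim$genotypes
  flipped <- gt$genotypes == 2L - sim$genotypes
  expect_true(all(same[, minor_coded]))
  expect_true(all(same | flipped))
})

test_that("snp_qc_filter applies call-rate, MAF and autosome filters", {
  # 5-SNP toy: call rates 1.0/0.90/1.0/1.0/1.0; MAFs .10/.10/.02/.10/.10;
  # chroms 1/1/1/X/1 -> removed: 1 call-rate, 1 MAF, 1 non-autosome
  n <- 50L
  make_col <- function(maf, miss = 0L) {
    d <- c(rep(1L, round(2 * n * maf)), rep(0L, n - round(2 * n * maf)))
    if (miss > 0L) d[seq_len(miss)] <- NA_integer_
    d
  }
  G <- cbind(make_col(0.10), make_col(0.10, miss = 5L), make_col(0.02),
             make_col(0.10), make_col(0.10))
  mm <- marker_map(paste0("s", 1:5), c("1", "1", "1", "X", "1"),
                   c(100L, 200L, 300L, 100L, 400L))
  # marker_map sorts: s1,s2,s3,s5 then X:s4 -> reorder G accordingly
  G <- G[, match(mm$snp_id, paste0("s", 1:5))]
  out <- snp_qc_filter(G, mm, autosomes = as.character(1:26))
  expect_identical(out$report$removed,
                   list(call_rate = 1L, maf = 1L, non_autosomal = 1L))
  expect_identical(out$report$retained, 2L)
  expect_setequal(out$markers$snp_id, c("s1", "s5"))
  # monomorphic SNP removed (MAF 0)
  G2 <- cbind(rep(0L, n), make_col(0.1))
  mm2 <- marker_map(c("a", "b"), c("1", "1"), c(1L, 2L))
  out2 <- snp_qc_filter(G2, mm2, autosomes = "1")
  expect_identical(out2$markers$snp_id, "b")
  # empty retained set errors
  expect_error(snp_qc_filter(cbind(rep(0L, n)), mm2[1, ], autosomes = "1"),
               "no SNPs survive QC")
})

test_that("snp_qc_filter is idempotent and order-preserving", {
  sim <- simulate_dataset(sim_config(n_snps = 200L,
                                     pop_sizes = c(popA = 20L, popB = 20L),
                                     sweeps = list(), seed = 3L))
  G <- sim$genotypes
  G[sample(length(G), 200L)] <- NA_integer_
  once <- snp_qc_filter(G, sim$markers, autosomes = as.character(1:26))
  twice <- snp_qc_filter(once$genotypes, once$markers,
                         autosomes = as.character(1:26))
  expect_identical(twice$genotypes, once$genotypes)
  expect_identical(twice$markers$snp_id, once$markers$snp_id)
  expect_false(is.unsorted(match(once$markers$snp_id, sim$markers$snp_id)))
})

test_that("sample_qc_filter retains samples by call rate", {
  G <- matrix(1L, 3L, 10L)
  G[2L, 1L] <- NA_integer_   # 90% call rate
  st <- sample_table(c("a", "b", "c"), "p")
  out <- sample_qc_filter(G, st, 0.95)
  expect_identical(out$samples$sample_id, c("a", "c"))
  expect_identical(out$report$removed$call_rate, 1L)
  # threshold 0 is the identity
  out0 <- sample_qc_filter(G, st, 0)
  expect_identical(out0$samples$sample_id, st$sample_id)
  expect_error(sample_qc_filter(matrix(NA_integer_, 2L, 4L),
                                sample_table(c("x", "y"), "p"), 0.95),
               "no samples survive")
})

test_that("thin_every_kth keeps floor(n/k) last-of-block SNPs", {
  mm <- marker_map(paste0("s", 1:10), rep("1", 10), 1:10 * 100L)
  expect_identical(thin_every_kth(mm, 10L), 10L)
  expect_identical(thin_every_kth(mm[1:9, ], 10L), integer(0))
  expect_identical(thin_every_kth(mm, 3L), c(3L, 6L, 9L))
  expect_error(thin_every_kth(mm, 0L), "positive")
  # property: retained count == floor(n/k) over random n, k
  withr::with_seed(1, {
    for (i in 1:50) {
      n <- sample(1:5000, 1L)
      k <- sample(1:50, 1L)
      idx <- thin_every_kth(n, k)
      expect_length(idx, n %/% k)
      if (length(idx)) expect_true(all(diff(idx) == k) && idx[1L] == k)
    }
  })
})

test_that("QC filters commute with column permutation followed by re-sorting", {
  sim <- simulate_dataset(sim_config(n_snps = 120L,
                                     pop_sizes = c(popA = 15L, popB = 15L),
                                     sweeps = list(), seed = 5L))
  G <- sim$genotypes
  G[sample(length(G), 100L)] <- NA_integer_
  base <- snp_qc_filter(G, sim$markers, autosomes = as.character(1:26))
  perm <- withr::with_seed(2, sample(ncol(G)))
  mmp <- marker_map(sim$markers$snp_id[perm], sim$markers$chrom[perm],
                    sim$markers$pos[perm])
  Gp <- G[, perm][, attr(mmp, "sort_order")]
  out <- snp_qc_filter(Gp, mmp, autosomes = as.character(1:26))
  expect_identical(out$markers$snp_id, base$markers$snp_id)
  expect_identical(unname(out$genotypes), unname(base$genotypes))
})
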