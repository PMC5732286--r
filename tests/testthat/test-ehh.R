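# EHH family: curves, integrals, iHS, Rsb, significance transform.

test_that("ancestral assignment rules", {
  a <- assign_ancestral_major(c(0.2, 0.8, 0.5))
  expect_identical(a$ancestral, c(0L, 1L, 0L))  # tie -> allele 0
  r1 <- assign_ancestral_random(1000L, seed = 5L)
  expect_identical(r1$ancestral, assign_ancestral_random(1000L, 5L)$ancestral)
  r2 <- assign_ancestral_random(1000L, seed = 6L)
  d <- mean(r1$ancestral != r2$ancestral)
  expect_gt(d, 0.5 - 3 * sqrt(0.25 / 1000))  # binomial 3-sigma band
  expect_lt(d, 0.5 + 3 * sqrt(0.25 / 1000))
  expect_length(assign_ancestral_random(0L, 1L)$ancestral, 0L)
})

test_that("ehh_curve partition arithmetic on hand cases", {
  mm <- marker_map(paste0("s", 1:3), rep("1", 3), c(1000L, 2000L, 3000L))
  # 4 carriers of allele 1 at core (SNP2) splitting 2/2 at SNP3
  H <- rbind(c(0L, 1L, 0L), c(0L, 1L, 0L), c(1L, 1L, 1L), c(0L, 1L, 1L),
             c(1L, 0L, 0L))
  cv <- ehh_curve(H, mm, 2L, 1L, cutoff = 0)
  expect_equal(cv$right$ehh, c(1, 1 / 3))       # C(2,2)*2 / C(4,2)
  expect_equal(cv$left$ehh[1L], 1)              # EHH at the core = 1
  # identical carriers -> EHH 1 everywhere
  Hid <- matrix(rep(c(0L, 1L, 1L), each = 3), 3)
  cvid <- ehh_curve(Hid, mm, 2L, 1L)
  expect_true(all(cvid$left$ehh == 1) && all(cvid$right$ehh == 1))
  # < 2 carriers -> undefined (NULL), signalled not thrown
  H1 <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 1L, 1L))
  expect_null(ehh_curve(H1, mm, 1L, 1L))
})

test_that("ehhs_curve normalizes by core homozygosity", {
  mm <- marker_map(paste0("s", 1:2), rep("1", 2), c(1000L, 2000L))
  # core counts 3/1 (n=4), adjacent marker splits the 3-class into 2/1
  H <- rbind(c(1L, 0L), c(1L, 0L), c(1L, 1L), c(0L, 0L))
  cv <- ehhs_curve(H, mm, 1L, cutoff = 0)
  expect_equal(cv$right$ehh, c(1, (1 / 6) / (3 / 6)))   # EHHS = 1/3
  # monomorphic window -> EHHS 1 everywhere
  Hm <- matrix(1L, 4L, 2L)
  cvm <- ehhs_curve(Hm, mm, 1L)
  expect_true(all(cvm$right$ehh == 1))
})

test_that("EHH and EHHS match brute-force pair enumeration exactly", {
  for (seed in 1:30) {
    fx <- random_hapset(sample(4:8, 1L), sample(3:6, 1L), seed = seed)
    H <- fx$H; mm <- fx$mm
    core <- withr::with_seed(seed * 7L, sample(ncol(H), 1L))
    for (allele in 0:1) {
      cv <- ehh_curve(H, mm, core, allele, cutoff = 0)
      if (is.null(cv)) {
        expect_lt(sum(H[, core] == allele), 2L)
        next
      }
      rows <- which(H[, core] == allele)
      for (df in list(cv$left, cv$right))
        for (i in seq_len(nrow(df)))
          expect_equal(df$ehh[i], oracle_ehh(H, rows, core, df$idx[i]))
      # monotone non-increasing outward
      expect_true(all(diff(cv$left$ehh) <= 1e-12))
      expect_true(all(diff(cv$right$ehh) <= 1e-12))
    }
    cs <- ehhs_curve(H, mm, core, cutoff = 0)
    if (!is.null(cs)) {
      for (df in list(cs$left, cs$right))
        for (i in seq_len(nrow(df)))
          expect_equal(df$ehh[i], oracle_ehhs(H, core, df$idx[i]))
      expect_true(all(diff(cs$left$ehh) <= 1e-12))
      expect_true(all(diff(cs$right$ehh) <= 1e-12))
    }
  }
})

test_that("integrate_ihh is a bp-space trapezoid with truncation", {
  # EHH == 1 over markers spanning 10,000 bp each side -> iHH = 20,000
  mm <- marker_map(paste0("s", 1:5), rep("1", 5),
                   c(10000L, 15000L, 20000L, 25000L, 30000L))
  H <- matrix(rep(c(1L, 1L, 1L, 1L, 1L), each = 4), 4)
  cv <- ehh_curve(H, mm, 3L, 1L)
  expect_equal(integrate_ihh(cv, mm), 20000)
  # two-point curve {1.0 at 0 bp, 0.5 at 1,000 bp}, one side only -> 750
  curve <- structure(list(core = 1L, allele_class = "1", n = 4L,
                          left = data.frame(idx = 1L, ehh = 1),
                          right = data.frame(idx = 1:2, ehh = c(1, 0.5))),
                     class = "ehh_curve")
  mm2 <- marker_map(c("a", "b"), c("1", "1"), c(1L, 1001L))
  expect_equal(integrate_ihh(curve, mm2), 750)
  expect_true(is.na(integrate_ihh(NULL, mm2)))
})

test_that("p_transform calibration, symmetry, monotonicity", {
  expect_equal(p_transform(0), 0)
  # transformed 4.0 <-> two-sided tail probability 1e-4
  v <- uniroot(function(x) p_transform(x) - 4, c(1, 10), tol = 1e-12)$root
  expect_equal(2 * pnorm(v, lower.tail = FALSE), 1e-4, tolerance = 1e-10)
  expect_equal(v, qnorm(1 - 5e-5), tolerance = 1e-6)
  x <- c(0.3, 1.5, 2, 4.2)
  expect_equal(p_transform(x), p_transform(-x))
  expect_true(all(diff(p_transform(seq(0, 6, 0.25))) > 0))
  expect_true(all(p_transform(seq(-5, 5, 0.5)) >= 0))
  # literal one-sided variant never flags negative statistics
  expect_lt(p_transform(-3, side = "literal"), 0)
  expect_equal(p_transform(3, side = "literal"),
               -log10(2 * pnorm(-3)), tolerance = 1e-12)
})

test_that("ihs raw value negates when the core ancestral state flips", {
  fx <- random_hapset(24L, 12L, seed = 42L, p = rep(0.4, 12L))
  anc <- assign_ancestral_major(colMeans(fx$H))
  tr <- suppressWarnings(ihs_scan(fx$H, fx$mm, anc))
  flip <- anc
  flip$ancestral <- 1L - anc$ancestral
  tr2 <- suppressWarnings(ihs_scan(fx$H, fx$mm, flip))
  ok <- !is.na(tr$raw) & !is.na(tr2$raw)
  expect_gt(sum(ok), 0L)
  expect_equal(tr2$raw[ok], -tr$raw[ok], tolerance = 1e-12)
})

test_that("standardized iHS has per-bin mean 0 and sd 1", {
  sim <- simulate_dataset(sim_config(n_snps = 300L,
                                     pop_sizes = c(popA = 40L, popB = 10L),
                                     sweeps = list(), seed = 13L))
  H <- sim$haplotypes[rep(sim$samples$group, each = 2L) == "A", ]
  tr <- suppressWarnings(ihs_scan(H, sim$markers))
  bin <- cut(tr$derived_freq, seq(0.05, 0.95, 0.05), include.lowest = TRUE)
  for (b in levels(bin)) {
    i <- which(bin == b & !is.na(tr$std))
    if (length(i) >= 2L) {
      expect_equal(mean(tr$std[i]), 0, tolerance = 1e-8)
      expect_equal(sd(tr$std[i]), 1, tolerance = 1e-8)
    }
  }
  # piHS flags match the threshold contract
  expect_identical(tr$flag, !is.na(tr$value) & tr$value >= 4.0)
})

test_that("rsb on identical haplotype sets gives raw 0 and on a sweep ranks the core", {
  fx <- random_hapset(20L, 15L, seed = 3L)
  expect_warning(tr <- rsb_scan(fx$H, fx$H, fx$mm), "degenerate")
  expect_true(all(tr$raw[!is.na(tr$raw)] == 0))
  # sweep injected only in group A -> core standardized Rsb positive, top 1%
  sim <- simulate_dataset(sim_config(seed = 1L))
  gr <- rep(sim$samples$group, each = 2L)
  rsb <- rsb_scan(sim$haplotypes[gr == "A", ], sim$haplotypes[gr == "B", ],
                  sim$markers)
  core <- sim$truth$core_idx
  expect_gt(rsb$std[core], 0)
  expect_lte(rank(-rsb$std, na.last = "keep")[core],
             0.01 * sum(!is.na(rsb$std)))
  # standardized track has median 0
  expect_equal(median(rsb$std, na.rm = TRUE), 0, tolerance = 1e-10)
})

test_that("consistency_check reports perfect agreement for the major assignment", {
  fx <- random_hapset(16L, 10L, seed = 77L)
  anc <- assign_ancestral_major(colMeans(fx$H))
  rep1 <- suppressWarnings(
    consistency_check(fx$H, fx$mm, assignments = list(anc)))
  expect_equal(rep1$runs$cor_abs_std[1L], 1)
  expect_equal(rep1$runs$jaccard[1L], 1)
  # fixed seed -> identical report across reruns
  rep2 <- suppressWarnings(consistency_check(fx$H, fx$mm, n_perm = 3L, seed = 9L))
  rep3 <- suppressWarnings(consistency_check(fx$H, fx$mm, n_perm = 3L, seed = 9L))
  expect_identical(rep2$runs, rep3$runs)
})
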