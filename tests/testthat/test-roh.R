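# A convenient fixture: n homozygous SNPs evenly spaced on one chromosome.
hom_run_map <- function(n, spacing_bp = 1e4) {
  marker_map(chrom = rep("1", n), bp = seq(1, by = spacing_bp,
                                           length.out = n),
             morgans = seq(0, by = spacing_bp * 1e-8, length.out = n))
}

test_that("uninterrupted homozygous stretches are fully eligible", {
  map <- hom_run_map(60)
  codes <- rep(2L, 60)
  flags <- scan_homozygous_windows(codes, map, roh_preset("HD"))
  expect_true(all(flags))
})

test_that("one heterozygote removes hit support within window reach", {
  map <- hom_run_map(60)
  codes <- rep(0L, 60)
  codes[30] <- 1L
  params <- roh_preset("HD")   # 50-SNP windows, no het allowed
  flags <- scan_homozygous_windows(codes, map, params)
  expect_false(flags[30])
  # hand-rolled window count: windows start at 1..11; a window starting at
  # s covers SNPs s..s+49 and is a hit iff it avoids SNP 30, i.e. s > 30.
  # SNP i is covered by windows max(1, i-49)..min(i, 11).
  hits <- (1:11) > 30   # all FALSE: every window contains the het
  expect_false(any(hits))
  expect_false(any(flags))
})

test_that("the missing-genotype allowance has a sharp boundary", {
  map <- hom_run_map(50)
  codes5 <- rep(2L, 50); codes5[seq(5, 45, by = 10)] <- NA  # 5 missing
  codes6 <- codes5; codes6[26] <- NA                        # 6 missing
  params <- roh_preset("HD")
  expect_true(all(scan_homozygous_windows(codes5, map, params)))
  expect_false(any(scan_homozygous_windows(codes6, map, params)))
})

test_that("short chromosomes fall back to a single whole-chromosome window", {
  map <- hom_run_map(20)
  flags <- scan_homozygous_windows(rep(2L, 20), map, roh_preset("HD"))
  expect_true(all(flags))
  flags_het <- scan_homozygous_windows(c(rep(2L, 10), 1L, rep(2L, 9)),
                                       map, roh_preset("HD"))
  expect_false(any(flags_het))
})

test_that("20 homozygous SNPs spaced 10 kb give one 190-kb ROH on HD rules", {
  map <- hom_run_map(20, 1e4)
  codes <- rep(2L, 20)
  params <- roh_preset("HD")
  segs <- call_roh(scan_homozygous_windows(codes, map, params), codes,
                   map, params)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 20L)
  expect_equal(segs$length_bp, 19 * 1e4 + 1)   # inclusive bp length
  # every rule is satisfied with margin: >= 15 SNPs, >= 100 kb,
  # <= 10 kb per SNP
  expect_gte(segs$n_snps, params$min_snps)
  expect_gte(segs$length_bp, params$min_length_bp)
  expect_lte(segs$length_bp / segs$n_snps, params$min_density_bp_per_snp)
})

test_that("a 250-kb internal gap splits the run and kills both halves", {
  bp <- c(seq(1, by = 1e4, length.out = 10),
          seq(1 + 9e4 + 2.5e5, by = 1e4, length.out = 10))
  map <- marker_map(chrom = rep("1", 20), bp = bp, morgans = bp * 1e-8)
  codes <- rep(2L, 20)
  params <- roh_preset("HD")   # max gap 200 kb, min 15 SNPs
  segs <- call_roh(scan_homozygous_windows(codes, map, params), codes,
                   map, params)
  expect_equal(nrow(segs), 0L)
})

test_that("runs below the SNP-count floor never qualify", {
  map <- hom_run_map(14, 1e5)   # generous span, only 14 SNPs
  codes <- rep(0L, 14)
  params <- roh_preset("HD")
  segs <- call_roh(scan_homozygous_windows(codes, map, params), codes,
                   map, params)
  expect_equal(nrow(segs), 0L)
})

test_that("ROH calls depend only on het/hom status, not allele labels", {
  set.seed(61)
  map <- hom_run_map(80)
  codes <- sample(c(0L, 2L), 80, TRUE)
  codes[40] <- 1L
  params <- roh_preset("HD")
  swapped <- 2L - codes + 0L   # relabel strands: 0 <-> 2, het fixed
  expect_identical(
    scan_homozygous_windows(codes, map, params),
    scan_homozygous_windows(swapped, map, params))
  expect_identical(
    call_roh(scan_homozygous_windows(codes, map, params), codes, map,
             params),
    call_roh(scan_homozygous_windows(swapped, map, params), swapped, map,
             params))
})

test_that("relaxing the minimum length never decreases F_ROH", {
  set.seed(62)
  truth <- hbd_model("1R", epsilon = 0.002)
  truth$rates <- c(20, 20); truth$mixing <- c(0.3, 0.7)
  panel <- toy_panel(2, 1, 1e-4, seed = 62)
  sim <- simulate_mosaic(truth, panel$map, panel$freqs, 3, seed = 62)
  lengths_bp <- c(2e6, 1e6, 5e5, 1e5)
  fr <- sapply(lengths_bp, function(L) {
    p <- roh_params(min_length_bp = L, max_gap_bp = 2e5,
                    min_density_bp_per_snp = 1e4)
    mean(roh_scan(sim$geno, panel$map, p)$f_roh)
  })
  expect_true(all(diff(fr) >= 0))
})

test_that("F_ROH tracks true autozygosity on mosaic genomes", {
  truth <- hbd_model("1R", epsilon = 0.002)
  truth$rates <- c(20, 20); truth$mixing <- c(0.25, 0.75)
  panel <- toy_panel(4, 1, 1e-4, seed = 63)   # HD-like density
  sim <- simulate_mosaic(truth, panel$map, panel$freqs, 15, seed = 63)
  scan <- roh_scan(sim$geno, panel$map, roh_preset("HD"))
  true_f <- sim$truth$fractions[, 1]
  expect_gt(stats::cor(scan$f_roh, true_f), 0.9)

  # recall: true HBD segments longer than 4x the minimum ROH length are
  # nearly always hit by a call from the density-matched preset
  min_len_m <- 1e5 * 1e-8                 # 100 kb on the 1 cM/Mb map
  segs <- sim$truth$segments
  segs <- segs[segs$class == 1L &
                 (segs$end_m - segs$start_m) > 4 * min_len_m, ]
  hit <- mapply(function(id, ch, s_m, e_m) {
    calls <- scan$segments[scan$segments$id == id &
                             scan$segments$chrom == ch, ]
    if (!nrow(calls)) return(FALSE)
    s_bp <- s_m * 1e8 + 1; e_bp <- e_m * 1e8 + 1
    any(pmin(calls$end_bp, e_bp) - pmax(calls$start_bp, s_bp) > 0)
  }, segs$id, segs$chrom, segs$start_m, segs$end_m)
  expect_gt(mean(hit), 0.9)
})
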