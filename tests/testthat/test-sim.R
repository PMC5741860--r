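test_that("simulated frequencies follow the Beta law, floor and seed", {
  f <- simulate_frequencies(1e5, a = 1, b = 1, maf_floor = 0, seed = 2)
  # uniform mean 0.5, SE = sqrt(1/12/n)
  expect_lt(abs(mean(f) - 0.5), 3 * sqrt(1 / 12 / 1e5))
  f2 <- simulate_frequencies(5e4, a = 1, b = 1, maf_floor = 0.01, seed = 3)
  expect_true(all(pmin(f2, 1 - f2) >= 0.01))
  expect_identical(simulate_frequencies(100, 2, 5, 0.01, seed = 9),
                   simulate_frequencies(100, 2, 5, 0.01, seed = 9))
  expect_error(simulate_frequencies(10, a = -1), "positive")
  expect_error(simulate_frequencies(10, maf_floor = 0.5), "maf_floor")
})

test_that("the simulated map is an even grid under the 1 cM/Mb convention", {
  map <- simulate_map(1, 1, 0.01)
  expect_equal(nrow(map), 101L)
  expect_equal(map$morgans, seq(0, 1, by = 0.01))
  # 0.01 Morgan between markers = 1,000,000 bp
  expect_equal(unique(diff(map$bp)), 1e6)
  map2 <- simulate_map(2, 0.5, 0.01)
  expect_equal(sort(unique(map2$chrom)), c("1", "2"))
  expect_equal(sum(map2$chrom == "1"), 51L)
  expect_error(simulate_map(0, 1, 0.01), "positive")
})

test_that("a pure non-HBD mixture yields zero autozygosity", {
  model <- hbd_model("KR", K = 2, epsilon = 0.002)
  model$rates <- c(20, 20)
  model$mixing <- c(0, 1)
  panel <- toy_panel(1, 1, 0.01)
  sim <- simulate_mosaic(model, panel$map, panel$freqs, 5, seed = 4)
  expect_equal(unname(sim$truth$fractions[, 1]), rep(0, 5))
  expect_true(all(sim$truth$segments$class == 2L))
})

test_that("segment lengths are exponential with the class rate", {
  model <- hbd_model("KR", K = 2, epsilon = 0.002)
  model$rates <- c(20, 20)
  model$mixing <- c(0.5, 0.5)
  panel <- toy_panel(1, 10, 0.1)    # markers irrelevant to segment draws
  sim <- simulate_mosaic(model, panel$map, panel$freqs, 30, seed = 5)
  segs <- sim$truth$segments
  # exclude segments truncated by the chromosome end
  hbd <- segs[segs$class == 1L & segs$end_m < 10, ]
  expect_gt(nrow(hbd), 2000)
  len <- hbd$end_m - hbd$start_m
  expect_lt(abs(mean(len) - 1 / 20), 3 * (1 / 20) / sqrt(nrow(hbd)))
})

test_that("genome fractions match the renewal stationary distribution", {
  model <- hbd_model("KR", K = 3, epsilon = 0.002)
  model$rates <- c(10, 100, 50)
  model$mixing <- c(0.1, 0.5, 0.4)
  panel <- toy_panel(1, 10, 0.5)
  sim <- simulate_mosaic(model, panel$map, panel$freqs, 200, seed = 6)
  expected <- (model$mixing / model$rates) /
    sum(model$mixing / model$rates)
  got <- colMeans(sim$truth$fractions)
  # 3-SE band from the observed spread of per-individual fractions
  se <- apply(sim$truth$fractions, 2, stats::sd) / sqrt(200)
  expect_true(all(abs(got - expected) < 3 * se + 1e-3))
})

test_that("segments tile each chromosome exactly", {
  model <- hbd_model("KR", K = 3, epsilon = 0.002)
  model$rates <- c(10, 1000, 100)
  model$mixing <- c(0.05, 0.8, 0.15)
  panel <- toy_panel(3, 1, 0.01)
  sim <- simulate_mosaic(model, panel$map, panel$freqs, 5, seed = 7)
  segs <- sim$truth$segments
  for (id in unique(segs$id)) for (ch in unique(segs$chrom)) {
    s <- segs[segs$id == id & segs$chrom == ch, ]
    expect_lt(abs(s$start_m[1] - 0), 1e-12)
    expect_lt(abs(s$end_m[nrow(s)] - 1), 1e-12)
    if (nrow(s) > 1)
      expect_lt(max(abs(s$start_m[-1] - s$end_m[-nrow(s)])), 1e-12)
  }
  # per-individual class fractions sum to 1 over all classes
  expect_equal(unname(rowSums(sim$truth$fractions)), rep(1, 5),
               tolerance = 1e-9)
})

test_that("heterozygote rate inside true HBD segments approaches epsilon", {
  model <- hbd_model("KR", K = 2, epsilon = 0.01)
  model$rates <- c(4, 4)
  model$mixing <- c(0.6, 0.4)
  panel <- toy_panel(2, 1, 2e-4, seed = 8)
  sim <- simulate_mosaic(model, panel$map, panel$freqs, 3, seed = 8)
  inside <- sim$truth$marker_class == 1L
  het <- sim$geno$codes == 1L
  n <- sum(inside)
  expect_gt(n, 5000)
  rate <- sum(het[inside]) / n
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / n))
})

test_that("identical config and seed reproduce the simulation bit for bit", {
  model <- hbd_model("MixKR", K = 4, epsilon = 0.005)
  panel <- toy_panel(2, 0.5, 0.005)
  s1 <- simulate_mosaic(model, panel$map, panel$freqs, 3, seed = 123)
  s2 <- simulate_mosaic(model, panel$map, panel$freqs, 3, seed = 123)
  expect_identical(s1$geno$codes, s2$geno$codes)
  expect_identical(s1$truth$segments, s2$truth$segments)
})

test_that("panel thinning keeps every k-th marker unchanged", {
  panel <- toy_panel(1, 1, 0.01)
  g <- geno_data(matrix(sample(0:2, 2 * 101, TRUE), 2, 101),
                 freqs = panel$freqs)
  same <- downsample_panel(g, panel$map, 1)
  expect_identical(same$geno$codes, g$codes)
  thin <- downsample_panel(g, panel$map, 20)
  expect_equal(nrow(thin$map), 6L)
  expect_equal(thin$map$morgans, seq(0, 1, by = 0.2))
  expect_identical(thin$geno$codes,
                   g$codes[, seq(1, 101, by = 20), drop = FALSE])
  # the thinned panel really is a different marker set
  expect_false(isTRUE(all.equal(f_hom(thin$geno), f_hom(g))))
  expect_error(downsample_panel(g, panel$map, 0), "at least 1")
})

test_that("gene dropping reproduces classical expectations", {
  panel <- toy_panel(2, 1, 0.02, seed = 12)
  founders <- data.frame(id = sprintf("f%02d", 1:40),
                         sire = NA, dam = NA)
  gd <- gene_drop(founders, panel$map, panel$freqs, seed = 13)
  # founder heterozygosity per marker is 2f(1-f)
  het <- colMeans(gd$geno$codes == 1L)
  expected <- 2 * panel$freqs * (1 - panel$freqs)
  expect_lt(abs(mean(het) - mean(expected)), 3 * sqrt(0.5 * 0.5 / 40 /
                                                        nrow(panel$map)) +
              0.01)
  expect_true(all(gd$autozygosity[1:40] == 0))

  # offspring of a parent-offspring mating: expected autozygosity 1/4
  ped <- data.frame(id = c("a", "b", "c", "x"),
                    sire = c(NA, NA, "a", "c"),
                    dam = c(NA, NA, "b", "b"))
  set.seed(14)
  auto <- replicate(400, gene_drop(ped, panel$map, panel$freqs)$autozygosity[["x"]])
  se <- stats::sd(auto) / sqrt(length(auto))
  expect_lt(abs(mean(auto) - 0.25), 3 * se)
})

test_that("a single-marker map degenerates to plain allele sampling", {
  map <- marker_map("1", 1, 0)
  ped <- data.frame(id = c("m", "o"), sire = c(NA, "m"), dam = c(NA, NA))
  gd <- gene_drop(ped, map, 0.5, seed = 15)
  expect_equal(dim(gd$geno$codes), c(2L, 1L))
  expect_true(all(gd$geno$codes %in% 0:2))
})

test_that("out-of-order pedigrees are reordered and cycles rejected", {
  panel <- toy_panel(1, 0.1, 0.05)
  ped <- data.frame(id = c("x", "a", "b"), sire = c("a", NA, NA),
                    dam = c("b", NA, NA))
  expect_warning(gd <- gene_drop(ped, panel$map, panel$freqs, seed = 16),
                 "reordered")
  expect_setequal(gd$geno$ids, c("x", "a", "b"))
  cyc <- data.frame(id = c("p", "q"), sire = c("q", "p"), dam = c(NA, NA))
  expect_error(suppressWarnings(gene_drop(cyc, panel$map, panel$freqs)),
               "cycle")
})
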