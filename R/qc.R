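#' Allele frequencies on a reference subset
#'
#' `f_A = (2 n_AA + n_AB) / (2 n_called)` per marker, computed on the
#' given individuals only (a typical choice is a founder cohort, e.g.
#' bulls born before a cutoff year, so that estimators refer to a defined
#' base population).  Markers with no called genotype in the subset get
#' `NA` and are flagged in the `"undefined"` attribute.
#'
#' @param geno A [geno_data()].
#' @param subset Individual IDs (default: all).
#' @return Numeric vector of allele-A frequencies with attribute
#'   `"undefined"` (logical per marker).
#' @export
allele_frequencies <- function(geno, subset = NULL) {
  ids <- if (is.null(subset)) geno$ids else intersect(subset, geno$ids)
  if (!length(ids)) stop("no individuals left after intersecting 'subset'")
  codes <- geno$codes[match(ids, geno$ids), , drop = FALSE]
  f <- colMeans(codes, na.rm = TRUE) / 2
  undefined <- colSums(!is.na(codes)) == 0L
  f[undefined] <- NA_real_
  structure(f, undefined = undefined)
}

#' Quality-control filters for genotype data
#'
#' Applies, in order: (1) drop individuals with call rate below
#' `ind_callrate_min`; then drop SNPs that (2) have a call rate below
#' `snp_callrate_min`, (3) have a minor allele frequency below `maf_min`,
#' (4) deviate from Hardy-Weinberg proportions (1-df chi-square on
#' observed vs expected genotype counts, p below `hwe_p_min`), or (5) show
#' opposite-homozygote conflicts in more than one distinct parent-offspring
#' pair (only when a pedigree is supplied; skipped, and reported as
#' skipped, otherwise).
#'
#' @param geno A [geno_data()].
#' @param map The aligned [marker_map()].
#' @param ind_callrate_min,snp_callrate_min,maf_min,hwe_p_min Thresholds.
#' @param pedigree Optional pedigree `data.frame` (`id`, `sire`, `dam`)
#'   for the Mendelian rule.
#' @return A list with filtered `geno`, `map` and a `report` data.frame of
#'   per-rule removal counts.
#' @export
qc_filter <- function(geno, map, ind_callrate_min = 0.90,
                      snp_callrate_min = 0.95, maf_min = 0.01,
                      hwe_p_min = 0.001, pedigree = NULL) {
  stopifnot(ncol(geno$codes) == nrow(map))
  for (th in c(ind_callrate_min, snp_callrate_min, maf_min, hwe_p_min))
    if (th < 0 || th > 1) stop("thresholds must lie in [0, 1]")

  cr_ind <- rowMeans(!is.na(geno$codes))
  keep_ind <- cr_ind >= ind_callrate_min
  codes <- geno$codes[keep_ind, , drop = FALSE]
  ids <- geno$ids[keep_ind]

  n_called <- colSums(!is.na(codes))
  cr_snp <- n_called / nrow(codes)
  fail_cr <- cr_snp < snp_callrate_min

  f <- colMeans(codes, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  fail_maf <- is.na(maf) | maf < maf_min

  fail_hwe <- hwe_chisq_p(codes) < hwe_p_min
  fail_hwe[is.na(fail_hwe)] <- FALSE

  mendel_skipped <- is.null(pedigree)
  fail_mendel <- rep(FALSE, ncol(codes))
  if (!mendel_skipped) {
    ped <- normalize_pedigree(pedigree)
    pairs <- rbind(
      cbind(ped$id, ped$sire)[!is.na(ped$sire), , drop = FALSE],
      cbind(ped$id, ped$dam)[!is.na(ped$dam), , drop = FALSE])
    pairs <- pairs[pairs[, 1L] %in% ids & pairs[, 2L] %in% ids, ,
                   drop = FALSE]
    if (nrow(pairs)) {
      conflicts <- matrix(0L, nrow(pairs), ncol(codes))
      for (r in seq_len(nrow(pairs))) {
        a <- codes[match(pairs[r, 1L], ids), ]
        b <- codes[match(pairs[r, 2L], ids), ]
        conflicts[r, ] <- !is.na(a) & !is.na(b) &
          ((a == 0L & b == 2L) | (a == 2L & b == 0L))
      }
      fail_mendel <- colSums(conflicts) > 1L
    }
  }

  drop_snp <- fail_cr | fail_maf | fail_hwe | fail_mendel
  if (all(drop_snp)) stop("all markers removed by QC")

  report <- data.frame(
    rule = c("individual_callrate", "snp_callrate", "maf", "hwe",
             "mendelian"),
    removed = c(sum(!keep_ind), sum(fail_cr), sum(fail_maf),
                sum(fail_hwe), if (mendel_skipped) NA else
                  sum(fail_mendel)),
    note = c("", "", "", "1-df chi-square",
             if (mendel_skipped) "skipped: no pedigree supplied" else
               "opposite homozygotes in >1 parent-offspring pair"),
    stringsAsFactors = FALSE)

  keep <- !drop_snp
  new_map <- map[keep, , drop = FALSE]
  rownames(new_map) <- NULL
  list(geno = geno_data(codes[, keep, drop = FALSE], ids = ids,
                        genoprobs = lapply_keep(
                          if (is.null(geno$genoprobs)) NULL else
                            geno$genoprobs[intersect(names(geno$genoprobs),
                                                     ids)], which(keep)),
                        freqs = geno$freqs[keep]),
       map = new_map, report = report)
}

# Hardy-Weinberg 1-df chi-square p-value per marker from genotype counts.
hwe_chisq_p <- function(codes) {
  nAA <- colSums(codes == 2L, na.rm = TRUE)
  nAB <- colSums(codes == 1L, na.rm = TRUE)
  nBB <- colSums(codes == 0L, na.rm = TRUE)
  n <- nAA + nAB + nBB
  f <- (2 * nAA + nAB) / (2 * n)
  eAA <- n * f^2; eAB <- n * 2 * f * (1 - f); eBB <- n * (1 - f)^2
  x2 <- (nAA - eAA)^2 / eAA + (nAB - eAB)^2 / eAB + (nBB - eBB)^2 / eBB
  # monomorphic markers have expected zeros; no HWE evidence either way
  x2[!is.finite(x2)] <- 0
  stats::pchisq(x2, df = 1L, lower.tail = FALSE)
}
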