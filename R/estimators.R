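#' Marker-based inbreeding coefficient estimators
#'
#' The classical global estimators computed per individual over its
#' non-missing markers, with `x` the genotype code (copies of allele A)
#' and `f` the allele-A frequency from an explicit reference set (no
#' silent in-sample frequencies):
#'
#' * `f_hom()`: proportion of homozygous SNPs.
#' * `f_exhom()`: excess homozygosity,
#'   `(O_hom - E_hom) / (N - E_hom)` with
#'   `E_hom = sum_i (1 - 2 f_i (1 - f_i))`.
#' * `f_grm1()`: genomic-relationship diagonal with a common denominator,
#'   `sum_i (x_i - 2 f_i)^2 / sum_i 2 f_i (1 - f_i) - 1`.
#' * `f_grm2()`: per-SNP weighting,
#'   `(1/N) sum_i (x_i - 2 f_i)^2 / (2 f_i (1 - f_i)) - 1`
#'   (markers with `f` 0 or 1 are excluded and `N` decremented).
#' * `f_uni()`: correlation between uniting gametes,
#'   `(1/N) sum_i (x_i^2 - (1 + 2 f_i) x_i + 2 f_i^2) / (2 f_i (1 - f_i))`.
#'
#' @param geno A [geno_data()] or a genotype-code matrix.
#' @param freqs Allele-A frequencies of the reference population.
#' @return Named numeric vector, one value per individual.
#' @examples
#' g <- geno_data(rbind(a = c(0L, 1L, 2L, 0L)))
#' f_hom(g)   # 0.75
#' @name classical_estimators
NULL

est_codes <- function(geno) {
  if (inherits(geno, "geno_data")) geno$codes else as.matrix(geno)
}

#' @rdname classical_estimators
#' @export
f_hom <- function(geno) {
  codes <- est_codes(geno)
  n <- rowSums(!is.na(codes))
  if (any(n == 0L)) stop("individual with no non-missing genotype")
  rowSums(codes != 1L, na.rm = TRUE) / n
}

#' @rdname classical_estimators
#' @export
f_exhom <- function(geno, freqs) {
  codes <- est_codes(geno)
  stopifnot(length(freqs) == ncol(codes))
  ehom_i <- 1 - 2 * freqs * (1 - freqs)
  apply_rows(codes, function(x, ok) {
    O <- sum(x[ok] != 1L)
    E <- sum(ehom_i[ok])
    N <- sum(ok)
    (O - E) / (N - E)
  })
}

#' @rdname classical_estimators
#' @export
f_grm1 <- function(geno, freqs) {
  codes <- est_codes(geno)
  stopifnot(length(freqs) == ncol(codes))
  w <- 2 * freqs * (1 - freqs)
  apply_rows(codes, function(x, ok) {
    sum((x[ok] - 2 * freqs[ok])^2) / sum(w[ok]) - 1
  })
}

#' @rdname classical_estimators
#' @export
f_grm2 <- function(geno, freqs) {
  codes <- est_codes(geno)
  stopifnot(length(freqs) == ncol(codes))
  w <- 2 * freqs * (1 - freqs)
  apply_rows(codes, function(x, ok) {
    ok <- ok & w > 0
    mean((x[ok] - 2 * freqs[ok])^2 / w[ok]) - 1
  })
}

#' @rdname classical_estimators
#' @export
f_uni <- function(geno, freqs) {
  codes <- est_codes(geno)
  stopifnot(length(freqs) == ncol(codes))
  w <- 2 * freqs * (1 - freqs)
  apply_rows(codes, function(x, ok) {
    ok <- ok & w > 0
    xo <- x[ok]; fo <- freqs[ok]
    mean((xo^2 - (1 + 2 * fo) * xo + 2 * fo^2) / w[ok])
  })
}

apply_rows <- function(codes, fun) {
  out <- vapply(seq_len(nrow(codes)), function(i) {
    x <- codes[i, ]
    fun(x, !is.na(x))
  }, 0)
  names(out) <- rownames(codes)
  out
}

#' Pedigree inbreeding coefficients
#'
#' Exact inbreeding coefficients from a pedigree: `F` of an individual is
#' the kinship between its parents, computed with the tabular kinship
#' recursion (`phi(i, i) = (1 + F_i) / 2`;
#' `phi(i, j) = (phi(s_i, j) + phi(d_i, j)) / 2` for `j` not a descendant
#' of `i`), which is exact for any pedigree.  Unknown parents are treated
#' as unrelated non-inbred founders.
#'
#' @param pedigree A `data.frame` with columns `id`, `sire`, `dam`.
#' @return Named numeric vector of inbreeding coefficients, in pedigree
#'   order.
#' @examples
#' ped <- data.frame(id = c("s", "d", "x"), sire = c(NA, NA, "s"),
#'                   dam = c(NA, NA, "d"))
#' f_ped(ped)  # founders 0, x 0
#' @export
f_ped <- function(pedigree) {
  ped <- normalize_pedigree(pedigree)
  n <- nrow(ped)
  pos <- seq_len(n)
  names(pos) <- ped$id
  si <- pos[ped$sire]; di <- pos[ped$dam]  # NA for unknown
  phi <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    for (j in seq_len(i - 1L)) {
      v <- 0
      if (!is.na(s)) v <- v + phi[s, j] / 2
      if (!is.na(d)) v <- v + phi[d, j] / 2
      phi[i, j] <- phi[j, i] <- v
    }
    fi <- if (!is.na(s) && !is.na(d)) phi[s, d] else 0
    phi[i, i] <- (1 + fi) / 2
  }
  Fi <- ifelse(is.na(si) | is.na(di), 0, phi[cbind(si, di)])
  names(Fi) <- ped$id
  Fi
}

#' All classical estimators in one table
#'
#' @param geno A [geno_data()].
#' @param freqs Reference allele frequencies.
#' @param pedigree Optional pedigree for `F_PED` (matched on individual
#'   ID; `NA` where absent).
#' @return A `data.frame` with one row per individual and columns
#'   `F_HOM`, `F_ExHOM`, `F_GRM1`, `F_GRM2`, `F_UNI` and (if a pedigree is
#'   given) `F_PED`.
#' @export
f_estimates <- function(geno, freqs, pedigree = NULL) {
  out <- data.frame(id = geno$ids,
                    F_HOM = f_hom(geno),
                    F_ExHOM = f_exhom(geno, freqs),
                    F_GRM1 = f_grm1(geno, freqs),
                    F_GRM2 = f_grm2(geno, freqs),
                    F_UNI = f_uni(geno, freqs),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(pedigree)) {
    fp <- f_ped(pedigree)
    out$F_PED <- fp[match(geno$ids, names(fp))]
  }
  out
}
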