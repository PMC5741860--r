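#' Sliding-window ROH parameters and per-panel presets
#'
#' The window rule: 50-SNP windows, no heterozygote allowed, up to five
#' missing genotypes per window; a SNP is eligible when at least
#' `window_hit_threshold` of the windows covering it are hits.  Candidate
#' runs of eligible SNPs are split at inter-SNP gaps above `max_gap_bp`
#' and kept when they contain at least `min_snps` SNPs, span at least
#' `min_length_bp` (inclusive bp length), and have at most
#' `min_density_bp_per_snp` bp per SNP.
#'
#' Presets bind the per-panel parameters (by increasing density): LD - one
#' SNP per 500 kb, 5 Mb minimum length, 1 Mb maximum gap; 50K - one SNP
#' per 100 kb, 1 Mb, 500 kb; HD - one SNP per 10 kb, 100 kb, 200 kb.  A
#' `"relaxed"` preset (20-SNP windows, at least 10 SNPs per ROH) is
#' provided as an alternative, not a default.
#'
#' @param window_snps,window_max_het,window_max_missing Window rule.
#' @param window_hit_threshold Minimum fraction of covering windows that
#'   must be hits (the source tool's default 0.05).
#' @param min_snps,min_length_bp,max_gap_bp,min_density_bp_per_snp Run
#'   filters.
#' @return A list of class `"roh_params"`.
#' @export
roh_params <- function(window_snps = 50L, window_max_het = 0L,
                       window_max_missing = 5L,
                       window_hit_threshold = 0.05, min_snps = 15L,
                       min_length_bp = 1e6, max_gap_bp = 5e5,
                       min_density_bp_per_snp = 1e5) {
  stopifnot(window_snps >= 1L, window_max_het >= 0L,
            window_max_missing >= 0L, min_snps >= 0L,
            window_hit_threshold > 0, window_hit_threshold <= 1)
  structure(list(window_snps = as.integer(window_snps),
                 window_max_het = as.integer(window_max_het),
                 window_max_missing = as.integer(window_max_missing),
                 window_hit_threshold = window_hit_threshold,
                 min_snps = as.integer(min_snps),
                 min_length_bp = min_length_bp, max_gap_bp = max_gap_bp,
                 min_density_bp_per_snp = min_density_bp_per_snp),
            class = "roh_params")
}

#' @rdname roh_params
#' @param panel `"LD"`, `"50K"`, `"HD"` or `"relaxed"`.
#' @export
roh_preset <- function(panel = c("HD", "50K", "LD", "relaxed")) {
  panel <- match.arg(panel)
  switch(panel,
    LD = roh_params(min_length_bp = 5e6, max_gap_bp = 1e6,
                    min_density_bp_per_snp = 5e5),
    `50K` = roh_params(min_length_bp = 1e6, max_gap_bp = 5e5,
                       min_density_bp_per_snp = 1e5),
    HD = roh_params(min_length_bp = 1e5, max_gap_bp = 2e5,
                    min_density_bp_per_snp = 1e4),
    relaxed = roh_params(window_snps = 20L, min_snps = 10L,
                         min_length_bp = 1e5, max_gap_bp = 2e5,
                         min_density_bp_per_snp = 1e4))
}

#' Per-SNP ROH eligibility from sliding homozygous windows
#'
#' Slides windows of `window_snps` consecutive SNPs along each chromosome;
#' a window is a hit when its heterozygote count is at most
#' `window_max_het` and its missing count at most `window_max_missing`.
#' A SNP is eligible when the fraction of covering windows that are hits
#' reaches `window_hit_threshold`.  A chromosome shorter than the window
#' is scanned as a single whole-chromosome window.
#'
#' @param codes Genotype codes for one individual (0/1/2, `NA` missing).
#' @param map The aligned [marker_map()].
#' @param params A [roh_params()].
#' @return Logical vector of per-SNP eligibility.
#' @export
scan_homozygous_windows <- function(codes, map, params = roh_preset("HD")) {
  stopifnot(length(codes) == nrow(map))
  out <- logical(length(codes))
  for (idx in split(seq_along(codes), map$chrom)) {
    het <- as.integer(!is.na(codes[idx]) & codes[idx] == 1L)
    mis <- as.integer(is.na(codes[idx]))
    n <- length(idx)
    w <- min(params$window_snps, n)
    nw <- n - w + 1L
    ch <- cumsum(c(0L, het)); cm <- cumsum(c(0L, mis))
    hit <- (ch[(w + 1L):(n + 1L)] - ch[1:nw]) <= params$window_max_het &
      (cm[(w + 1L):(n + 1L)] - cm[1:nw]) <= params$window_max_missing
    # windows covering SNP i: starts max(1, i-w+1) .. min(i, nw)
    chit <- cumsum(c(0L, as.integer(hit)))
    i <- seq_len(n)
    lo <- pmax(1L, i - w + 1L)
    hi <- pmin(i, nw)
    n_cov <- pmax(hi - lo + 1L, 0L)
    n_hit <- ifelse(n_cov > 0L, chit[pmax(hi, lo) + 1L] - chit[lo], 0L)
    out[idx] <- n_cov > 0L & n_hit / pmax(n_cov, 1L) >=
      params$window_hit_threshold
  }
  out
}

#' Call ROH and the genomic inbreeding coefficient F_ROH
#'
#' `call_roh()` turns per-SNP eligibility flags into run-level ROH calls;
#' `f_roh()` is the summed ROH length divided by the autosome length.
#'
#' @param flags Eligibility from [scan_homozygous_windows()].
#' @param codes The same individual's genotype codes.
#' @param map The aligned [marker_map()].
#' @param params A [roh_params()].
#' @return `call_roh()`: `data.frame` with `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_bp`.
#' @export
call_roh <- function(flags, codes, map, params = roh_preset("HD")) {
  stopifnot(length(flags) == nrow(map))
  segs <- list()
  for (idx in split(seq_along(flags), map$chrom)) {
    fl <- flags[idx]
    # maximal eligible runs, split where the inter-SNP gap is too large
    gap_break <- c(FALSE, diff(map$bp[idx]) > params$max_gap_bp)
    run_id <- cumsum(!fl | gap_break)
    for (r in split(idx[fl], run_id[fl])) {
      if (!length(r)) next
      n_snps <- length(r)
      len <- map$bp[r[n_snps]] - map$bp[r[1L]] + 1
      if (n_snps >= params$min_snps && len >= params$min_length_bp &&
          len / n_snps <= params$min_density_bp_per_snp)
        segs[[length(segs) + 1L]] <-
          data.frame(chrom = map$chrom[r[1L]], start_bp = map$bp[r[1L]],
                     end_bp = map$bp[r[n_snps]], n_snps = n_snps,
                     length_bp = len, stringsAsFactors = FALSE)
    }
  }
  if (!length(segs))
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0),
                      length_bp = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, segs)
}

#' @rdname call_roh
#' @param segments Output of `call_roh()`.
#' @param autosome_length_bp Total autosome length in bp.
#' @return `f_roh()`: a single proportion.
#' @export
f_roh <- function(segments, autosome_length_bp) {
  sum(segments$length_bp) / autosome_length_bp
}

#' ROH calls for every individual
#'
#' Convenience wrapper running the window scan and run caller per
#' individual and computing `F_ROH` against the map's physical span.
#'
#' @param geno A [geno_data()].
#' @param map The aligned [marker_map()].
#' @param params A [roh_params()].
#' @return A list with `segments` (one `data.frame`, PLINK-.hom-like
#'   columns `id`, `chrom`, `start_bp`, `end_bp`, `n_snps`, `length_bp`)
#'   and `f_roh` (named vector).
#' @export
roh_scan <- function(geno, map, params = roh_preset("HD")) {
  auto_len <- sum(tapply(map$bp, map$chrom, function(b) max(b) - min(b) + 1))
  segs <- lapply(geno$ids, function(id) {
    codes <- individual_codes(geno, id)
    s <- call_roh(scan_homozygous_windows(codes, map, params), codes, map,
                  params)
    if (nrow(s)) cbind(id = id, s, stringsAsFactors = FALSE) else NULL
  })
  segments <- do.call(rbind, segs)
  fr <- vapply(geno$ids, function(id) {
    if (is.null(segments)) 0
    else f_roh(segments[segments$id == id, , drop = FALSE], auto_len)
  }, 0)
  if (is.null(segments))
    segments <- data.frame(id = character(0), chrom = character(0),
                           start_bp = numeric(0), end_bp = numeric(0),
                           n_snps = integer(0), length_bp = numeric(0))
  list(segments = segments, f_roh = fr)
}
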