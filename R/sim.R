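#' Simulate allele frequencies
#'
#' Draws per-marker frequencies of allele A from a Beta(a, b) distribution.
#' A minor-allele-frequency floor is applied by resampling (not
#' truncation), which preserves the Beta shape without creating an atom at
#' the floor.
#'
#' @param n_markers Number of markers.
#' @param a,b Beta shape parameters (both > 0).
#' @param maf_floor Minimum minor allele frequency in `[0, 0.5)`.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_markers`.
#' @examples
#' f <- simulate_frequencies(100, a = 1, b = 1, maf_floor = 0.01, seed = 1)
#' @export
simulate_frequencies <- function(n_markers, a = 1, b = 1, maf_floor = 0,
                                 seed = NULL) {
  if (!is.numeric(a) || !is.numeric(b) || a <= 0 || b <= 0)
    stop("Beta shape parameters must be positive")
  if (n_markers < 1) stop("'n_markers' must be at least 1")
  if (maf_floor < 0 || maf_floor >= 0.5)
    stop("'maf_floor' must lie in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  f <- stats::rbeta(n_markers, a, b)
  repeat {
    bad <- pmin(f, 1 - f) < maf_floor
    if (!any(bad)) break
    f[bad] <- stats::rbeta(sum(bad), a, b)
  }
  f
}

#' Panel marker spacings emulating common cattle SNP arrays
#'
#' Even grids whose genome-wide marker counts (for a ~25 Morgan genome)
#' match the low-density (~7K), 50K (~31K) and high-density (~600K)
#' genotyping panels.  The HD grid thinned 20x gives the 50K grid and
#' thinned 85x the LD grid.
#'
#' @param panel `"LD"`, `"50K"` or `"HD"`.
#' @return Marker spacing in Morgans.
#' @export
panel_spacing <- function(panel = c("HD", "50K", "LD")) {
  panel <- match.arg(panel)
  c(HD = 4e-5, `50K` = 8e-4, LD = 3.4e-3)[[panel]]
}

#' Simulate an evenly spaced marker map
#'
#' Markers are placed at `0, spacing, 2 spacing, ...` up to the chromosome
#' length.  Physical positions follow the fixed 1 cM/Mb conversion
#' (1e-8 Morgan per bp), offset by 1 so positions are 1-based.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in Morgans.
#' @param marker_spacing Inter-marker distance in Morgans (see
#'   [panel_spacing()]).
#' @return A [marker_map()].
#' @examples
#' simulate_map(1, 1, 0.01)   # 101 markers on a 1-Morgan chromosome
#' @export
simulate_map <- function(n_chromosomes, chrom_length, marker_spacing) {
  if (n_chromosomes < 1 || chrom_length <= 0 || marker_spacing <= 0)
    stop("chromosome count, length and spacing must be positive")
  pos <- seq(0, chrom_length, by = marker_spacing)
  if (!length(pos)) stop("no markers fit on the chromosome")
  chrom <- rep(as.character(seq_len(n_chromosomes)), each = length(pos))
  morgans <- rep(pos, n_chromosomes)
  marker_map(chrom = chrom, bp = round(morgans * 1e8) + 1,
             morgans = morgans)
}

#' Simulate mosaic genomes with known age-stratified autozygosity
#'
#' Each chromosome is tiled by a renewal process: a class is drawn with
#' probability equal to its mixing proportion, its length drawn from an
#' exponential with the class rate, and the process repeats until the
#' chromosome is covered (the first segment's class is drawn from the
#' mixing proportions, matching the HMM's chromosome-reset convention).
#' Inside an HBD segment a marker is homozygous A with probability
#' `f_A (1 - epsilon)`, homozygous B with probability
#' `(1 - f_A)(1 - epsilon)` and heterozygous with probability `epsilon`;
#' inside non-HBD segments genotypes follow Hardy-Weinberg proportions.
#'
#' @param model An [hbd_model()] used as the generative truth (its
#'   `epsilon` is the heterozygote-in-HBD error).
#' @param map A [marker_map()].
#' @param freqs Allele-A frequencies, one per marker.
#' @param n_individuals Number of individuals.
#' @param seed Optional integer seed.
#' @return A list with
#'   `geno`: a [geno_data()] (frequencies attached);
#'   `truth`: a list with `segments` (`data.frame`: `id`, `chrom`,
#'   `start_m`, `end_m`, `class`), `fractions` (individuals x K matrix of
#'   true class fractions of the map length) and `marker_class`
#'   (individuals x markers matrix of true class indices).
#' @export
simulate_mosaic <- function(model, map, freqs, n_individuals, seed = NULL) {
  stopifnot(inherits(model, "hbd_model"))
  if (abs(sum(model$mixing) - 1) > 1e-8)
    stop("model mixing proportions must sum to 1")
  if (model$K < 2L) stop("at least one HBD and one non-HBD class required")
  stopifnot(length(freqs) == nrow(map))
  if (!is.null(seed)) set.seed(seed)
  K <- model$K
  ids <- sprintf("ind%03d", seq_len(n_individuals))
  chroms <- unique(map$chrom)
  chrom_idx <- split(seq_len(nrow(map)), factor(map$chrom, levels = chroms))
  total_len <- total_map_length(map)

  codes <- matrix(NA_integer_, n_individuals, nrow(map))
  marker_class <- matrix(NA_integer_, n_individuals, nrow(map))
  seg_list <- vector("list", n_individuals)

  for (i in seq_len(n_individuals)) {
    segs <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      idx <- chrom_idx[[ci]]
      lo <- min(map$morgans[idx]); hi <- max(map$morgans[idx])
      L <- hi - lo
      starts <- numeric(0); classes <- integer(0)
      at <- 0
      while (at < L || length(starts) == 0L) {
        k <- sample.int(K, 1L, prob = model$mixing)
        starts <- c(starts, at); classes <- c(classes, k)
        at <- at + stats::rexp(1L, rate = model$rates[k])
      }
      ends <- c(starts[-1L], L)
      segs[[ci]] <- data.frame(id = ids[i], chrom = chroms[ci],
                               start_m = lo + starts, end_m = lo + ends,
                               class = classes, stringsAsFactors = FALSE)
      mc <- classes[findInterval(map$morgans[idx] - lo, starts,
                                 rightmost.closed = FALSE)]
      marker_class[i, idx] <- mc
    }
    seg_list[[i]] <- do.call(rbind, segs)
  }

  # emit genotypes given the true class at each marker
  f_rep <- rep(freqs, each = n_individuals)
  is_hbd <- marker_class != K
  n <- length(codes)
  u_err <- stats::runif(n); u_all <- stats::runif(n); u2 <- stats::runif(n)
  hbd_code <- ifelse(u_err < model$epsilon, 1L,
                     ifelse(u_all < f_rep, 2L, 0L))
  nhb_code <- (u_all < f_rep) + (u2 < f_rep)
  codes[] <- ifelse(is_hbd, hbd_code, as.integer(nhb_code))

  segments <- do.call(rbind, seg_list)
  lens <- segments$end_m - segments$start_m
  fractions <- matrix(0, n_individuals, K, dimnames = list(ids, NULL))
  agg <- tapply(lens, list(factor(segments$id, levels = ids),
                           factor(segments$class, levels = seq_len(K))),
                sum, default = 0)
  fractions[] <- agg / total_len

  geno <- geno_data(codes, ids = ids, freqs = freqs)
  list(geno = geno,
       truth = list(segments = segments, fractions = fractions,
                    marker_class = marker_class))
}

#' Thin a marker panel
#'
#' Keeps every `keep_every`-th marker per chromosome (starting at the
#' first), preserving order and genotype alignment.
#'
#' @param geno A [geno_data()].
#' @param map The aligned [marker_map()].
#' @param keep_every Positive integer stride; 1 returns the input.
#' @return A list with thinned `geno` and `map`.
#' @export
downsample_panel <- function(geno, map, keep_every) {
  if (keep_every < 1) stop("'keep_every' must be at least 1")
  keep <- unlist(lapply(split(seq_len(nrow(map)), map$chrom),
                        function(i) i[seq(1L, length(i), by = keep_every)]),
                 use.names = FALSE)
  keep <- sort(keep)
  if (!length(keep)) stop("downsampling removed every marker")
  new_map <- map[keep, , drop = FALSE]
  rownames(new_map) <- NULL
  new_geno <- geno_data(geno$codes[, keep, drop = FALSE], ids = geno$ids,
                        genoprobs = lapply_keep(geno$genoprobs, keep),
                        freqs = geno$freqs[keep])
  list(geno = new_geno, map = new_map)
}

lapply_keep <- function(gp, keep) {
  if (is.null(gp)) return(NULL)
  lapply(gp, function(m) m[keep, , drop = FALSE])
}

#' Gene dropping along a pedigree
#'
#' Founder haplotypes are drawn independently per marker from the allele
#' frequencies; non-founders inherit parental gametes with recombination
#' as a Poisson process on the genetic map (Haldane model, no
#' interference).  Each founder haplotype carries a unique label so true
#' autozygosity (both labels identical at a marker) is recoverable.
#'
#' @param pedigree A `data.frame` with columns `id`, `sire`, `dam`
#'   (`NA`, `"0"` or `0` = unknown parent) and optionally `birth_year`.
#' @param map A [marker_map()].
#' @param freqs Allele-A frequencies.
#' @param seed Optional integer seed.
#' @return A list with `geno` (a [geno_data()]), `autozygosity` (per
#'   individual, the fraction of markers where the two inherited founder
#'   haplotype labels coincide) and `labels` (list per individual of a
#'   2 x markers label matrix).
#' @export
gene_drop <- function(pedigree, map, freqs, seed = NULL) {
  ped <- normalize_pedigree(pedigree)
  stopifnot(length(freqs) == nrow(map))
  if (!is.null(seed)) set.seed(seed)
  n_mark <- nrow(map)
  chroms <- split(seq_len(n_mark), map$chrom)
  hap <- list(); lab <- list()
  next_label <- 1L
  for (r in seq_len(nrow(ped))) {
    id <- ped$id[r]
    h <- matrix(0L, 2L, n_mark); l <- matrix(0L, 2L, n_mark)
    for (g in 1:2) {
      par <- ped[[c("sire", "dam")[g]]][r]
      if (is.na(par)) {
        h[g, ] <- as.integer(stats::runif(n_mark) < freqs)
        l[g, ] <- next_label
        next_label <- next_label + 1L
      } else {
        gam <- meiosis(hap[[par]], lab[[par]], map, chroms)
        h[g, ] <- gam$h; l[g, ] <- gam$l
      }
    }
    hap[[id]] <- h; lab[[id]] <- l
  }
  codes <- do.call(rbind, lapply(ped$id, function(id)
    as.integer(colSums(hap[[id]]))))
  geno <- geno_data(codes, ids = ped$id, freqs = freqs)
  auto <- vapply(ped$id, function(id) mean(lab[[id]][1L, ] == lab[[id]][2L, ]),
                 0)
  list(geno = geno, autozygosity = auto, labels = lab)
}

# One gamete from a parent: crossovers per chromosome are Poisson on the
# genetic length; the transmitted haplotype at a marker is the starting one
# flipped once per crossover to its left.
meiosis <- function(h, l, map, chroms) {
  out_h <- integer(ncol(h)); out_l <- integer(ncol(h))
  for (idx in chroms) {
    m <- map$morgans[idx]
    L <- max(m) - min(m)
    nx <- stats::rpois(1L, L)
    xpos <- sort(stats::runif(nx, min(m), max(m)))
    start <- sample.int(2L, 1L)
    phase <- (start - 1L + findInterval(m, xpos)) %% 2L + 1L
    out_h[idx] <- h[cbind(phase, idx)]
    out_l[idx] <- l[cbind(phase, idx)]
  }
  list(h = out_h, l = out_l)
}

normalize_pedigree <- function(pedigree) {
  ped <- as.data.frame(pedigree, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  for (col in c("id", "sire", "dam")) {
    ped[[col]] <- as.character(ped[[col]])
    ped[[col]][ped[[col]] %in% c("0", "", "NA")] <- NA
  }
  if (anyDuplicated(ped$id)) stop("duplicate individual IDs in pedigree")
  for (col in c("sire", "dam")) {
    unknown <- !is.na(ped[[col]]) & !(ped[[col]] %in% ped$id)
    if (any(unknown))
      stop("parent not listed as an individual: ",
           paste(ped[[col]][unknown], collapse = ", "))
  }
  # topological sort; reorder with a warning if children precede parents
  order_ok <- function(p) {
    pos <- seq_len(nrow(p))
    names(pos) <- p$id
    all(is.na(p$sire) | pos[p$sire] < pos, na.rm = TRUE) &&
      all(is.na(p$dam) | pos[p$dam] < pos, na.rm = TRUE)
  }
  if (!order_ok(ped)) {
    placed <- character(0)
    rest <- ped
    out <- ped[0, ]
    while (nrow(rest)) {
      ready <- (is.na(rest$sire) | rest$sire %in% placed) &
        (is.na(rest$dam) | rest$dam %in% placed)
      if (!any(ready))
        stop("pedigree contains a cycle involving: ",
             paste(rest$id, collapse = ", "))
      out <- rbind(out, rest[ready, , drop = FALSE])
      placed <- c(placed, rest$id[ready])
      rest <- rest[!ready, , drop = FALSE]
    }
    warning("pedigree reordered so parents precede offspring")
    ped <- out
  }
  rownames(ped) <- NULL
  ped
}
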