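#' Marker map constructor
#'
#' An ordered table of autosomal SNPs.  Physical positions are 1-based;
#' genetic positions are in Morgans and must be non-decreasing within a
#' chromosome.  The package-wide physical/genetic conversion is fixed at
#' 1 cM/Mb (1e-8 Morgan per bp), the usual proxy when only a physical map
#' is available.
#'
#' @param chrom Chromosome labels.
#' @param bp 1-based physical positions (unique within chromosome).
#' @param morgans Genetic positions in Morgans.
#' @param id Marker names (defaults to `chrom_bp`).
#' @param allele1,allele2 Allele labels; `allele1` is allele "A", the
#'   allele that genotype codes count and frequencies refer to.
#' @return A `data.frame` of class `"marker_map"` with columns `chrom`,
#'   `id`, `bp`, `morgans`, `allele1`, `allele2`.
#' @export
marker_map <- function(chrom, bp, morgans, id = NULL,
                       allele1 = "A", allele2 = "B") {
  n <- length(bp)
  if (is.null(id)) id <- paste(chrom, bp, sep = "_")
  m <- data.frame(chrom = as.character(chrom), id = as.character(id),
                  bp = as.numeric(bp), morgans = as.numeric(morgans),
                  allele1 = rep_len(as.character(allele1), n),
                  allele2 = rep_len(as.character(allele2), n),
                  stringsAsFactors = FALSE)
  validate_marker_map(m)
  class(m) <- c("marker_map", "data.frame")
  m
}

validate_marker_map <- function(m) {
  stopifnot(all(c("chrom", "id", "bp", "morgans") %in% names(m)))
  for (ch in unique(m$chrom)) {
    i <- m$chrom == ch
    if (anyDuplicated(m$bp[i]))
      stop("duplicate physical positions on chromosome ", ch)
    if (is.unsorted(m$bp[i]))
      stop("markers not sorted by position on chromosome ", ch)
    if (is.unsorted(m$morgans[i]))
      stop("genetic positions decrease on chromosome ", ch)
  }
  invisible(m)
}

#' Genotype container
#'
#' Holds genotype codes (0/1/2 copies of allele A, `NA` = missing) for a
#' set of individuals aligned to a [marker_map()], optionally per-marker
#' genotype probability triples (hom-A, het, hom-B) for sequence data, and
#' optionally per-marker frequencies of allele A.
#'
#' @param codes Individuals x markers integer matrix; row names are taken
#'   as individual IDs when `ids` is missing.
#' @param ids Individual identifiers.
#' @param genoprobs Optional list, named by individual, of markers x 3
#'   probability matrices (rows summing to 1).
#' @param freqs Optional numeric vector of allele-A frequencies.
#' @return A list of class `"geno_data"`.
#' @export
geno_data <- function(codes, ids = rownames(codes), genoprobs = NULL,
                      freqs = NULL) {
  codes <- as.matrix(codes)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(codes)))
  stopifnot(length(ids) == nrow(codes))
  if (!all(codes %in% c(0L, 1L, 2L) | is.na(codes)))
    stop("genotype codes must be 0, 1, 2 or NA")
  rownames(codes) <- ids
  if (!is.null(freqs)) {
    stopifnot(length(freqs) == ncol(codes))
    if (any(freqs < 0 | freqs > 1, na.rm = TRUE))
      stop("frequencies must lie in [0, 1]")
  }
  if (!is.null(genoprobs)) {
    stopifnot(is.list(genoprobs), all(names(genoprobs) %in% ids))
    for (gp in genoprobs) {
      stopifnot(ncol(gp) == 3L, nrow(gp) == ncol(codes))
      if (any(abs(rowSums(gp) - 1) > 1e-6))
        stop("genotype probability rows must sum to 1")
    }
  }
  structure(list(ids = as.character(ids), codes = codes,
                 genoprobs = genoprobs, freqs = freqs),
            class = "geno_data")
}

#' @exportS3Method base::print
print.geno_data <- function(x, ...) {
  cat(sprintf("geno_data: %d individuals x %d markers (%s genotype%s)\n",
              nrow(x$codes), ncol(x$codes),
              if (is.null(x$genoprobs)) "hard" else "probabilistic",
              if (is.null(x$freqs)) ", no frequencies" else
                ", frequencies attached"))
  invisible(x)
}

#' @exportS3Method base::print
print.marker_map <- function(x, ...) {
  cat(sprintf("marker_map: %d markers on %d chromosome(s), %.3f Morgans\n",
              nrow(x), length(unique(x$chrom)), total_map_length(x)))
  invisible(x)
}

#' Total genetic length of a map
#'
#' Sum over chromosomes of the span between first and last marker, in
#' Morgans.
#' @param map A [marker_map()].
#' @return Length in Morgans.
#' @export
total_map_length <- function(map) {
  sum(tapply(map$morgans, map$chrom, function(m) max(m) - min(m)))
}

# helper: row of codes / genoprobs for one individual
individual_codes <- function(geno, id) {
  i <- match(id, geno$ids)
  if (is.na(i)) stop("unknown individual: ", id)
  geno$codes[i, ]
}

individual_genoprobs <- function(geno, id) {
  if (is.null(geno$genoprobs)) return(NULL)
  geno$genoprobs[[id]]
}
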