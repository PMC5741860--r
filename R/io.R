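#' Read and write PLINK text genotype files
#'
#' `read_plink_text()` reads a whitespace-separated `.ped`/`.map` pair into
#' a [geno_data()] and [marker_map()].  Genotype codes count copies of
#' allele A; per marker, allele A is taken from `alleles` when supplied
#' and otherwise set to the alphabetically first allele observed at that
#' marker (so a round trip through [write_plink_text()] is an identity for
#' alphabetically ordered labels, and for any labels when the original
#' `allele1` is passed back).  The missing genotype is the `0 0` pair.
#'
#' The `.map` file has columns chromosome, marker id, genetic position
#' (Morgans) and physical position (bp).
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @param alleles Optional character vector of allele-A labels, one per
#'   marker.
#' @return A list with `geno` and `map`.
#' @export
read_plink_text <- function(ped_path, map_path, alleles = NULL) {
  if (!file.exists(ped_path)) stop("no such file: ", ped_path)
  if (!file.exists(map_path)) stop("no such file: ", map_path)
  mp <- utils::read.table(map_path, header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(mp) < 4L) stop("map file must have 4 columns")
  n_mark <- nrow(mp)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * n_mark
  for (i in seq_along(toks))
    if (length(toks[[i]]) != want)
      stop(sprintf("line %d of %s has %d fields, expected %d", i,
                   ped_path, length(toks[[i]]), want))
  ids <- vapply(toks, `[[`, "", 2L)
  a1 <- matrix(unlist(lapply(toks, function(x) x[seq(7L, want, by = 2L)])),
               ncol = n_mark, byrow = TRUE)
  a2 <- matrix(unlist(lapply(toks, function(x) x[seq(8L, want, by = 2L)])),
               ncol = n_mark, byrow = TRUE)

  codes <- matrix(NA_integer_, length(ids), n_mark)
  ref <- character(n_mark); alt <- character(n_mark)
  for (j in seq_len(n_mark)) {
    obs <- c(a1[, j], a2[, j])
    seen <- sort(unique(obs[obs != "0"]))
    if (length(seen) > 2L)
      stop(sprintf("marker %d has more than two alleles: %s", j,
                   paste(seen, collapse = "/")))
    A <- if (!is.null(alleles)) alleles[j]
         else if (length(seen)) seen[1L] else NA_character_
    B <- setdiff(seen, A)
    ref[j] <- if (is.na(A)) "A" else A
    alt[j] <- if (length(B)) B[1L] else "B"
    miss <- a1[, j] == "0" | a2[, j] == "0"
    codes[, j] <- (a1[, j] == A) + (a2[, j] == A)
    codes[miss, j] <- NA_integer_
  }
  map <- marker_map(chrom = mp[[1L]], bp = mp[[4L]], morgans = mp[[3L]],
                    id = mp[[2L]], allele1 = ref, allele2 = alt)
  list(geno = geno_data(codes, ids = ids), map = map)
}

#' @rdname read_plink_text
#' @param geno A [geno_data()].
#' @param map The aligned [marker_map()].
#' @param prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @export
write_plink_text <- function(geno, map, prefix) {
  stopifnot(ncol(geno$codes) == nrow(map))
  utils::write.table(
    data.frame(map$chrom, map$id, map$morgans, map$bp),
    paste0(prefix, ".map"), quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE)
  n_mark <- nrow(map)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(geno$codes))) {
    g <- geno$codes[i, ]
    al1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, map$allele1, map$allele2))
    al2 <- ifelse(is.na(g), "0", ifelse(g == 2L, map$allele1, map$allele2))
    writeLines(paste(c(geno$ids[i], geno$ids[i], "0", "0", "0", "-9",
                       rbind(al1, al2)), collapse = " "), con)
  }
  invisible(prefix)
}

#' Read genotypes from a VCF
#'
#' Reads biallelic SNP records (others are skipped with a message).  With
#' `use_likelihoods = TRUE` and a `PL` (Phred-scaled) or `GL` (log10)
#' genotype-likelihood field present, per-genotype probabilities are
#' normalized into `genoprobs` triples (hom-REF, het, hom-ALT); hard codes
#' from `GT` are always filled in.  Allele A is the REF allele.
#'
#' @param path VCF file (may be bgzipped).
#' @param use_likelihoods Fill genotype probabilities from PL/GL.
#' @return A list with `geno` and `map`.
#' @export
read_vcf <- function(path, use_likelihoods = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  keep <- vcfR::is.biallelic(v)
  snp <- !grepl(",", vcfR::getALT(v)) &
    nchar(vcfR::getREF(v)) == 1L & nchar(vcfR::getALT(v)) == 1L
  keep <- keep & snp
  if (any(!keep))
    message(sum(!keep), " non-biallelic/non-SNP record(s) skipped")
  v <- v[keep, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code_of <- c("0/0" = 2L, "0/1" = 1L, "1/0" = 1L, "1/1" = 0L)
  codes <- matrix(code_of[gt], nrow = nrow(gt))
  codes <- t(codes)  # individuals x markers
  ids <- colnames(gt)
  rownames(codes) <- ids

  map <- marker_map(chrom = vcfR::getCHROM(v), bp = vcfR::getPOS(v),
                    morgans = (vcfR::getPOS(v) - 1) * 1e-8,
                    id = vcfR::getID(v),
                    allele1 = vcfR::getREF(v), allele2 = vcfR::getALT(v))

  genoprobs <- NULL
  if (use_likelihoods) {
    has_pl <- any(grepl("PL", v@gt[, "FORMAT"]))
    has_gl <- any(grepl("GL", v@gt[, "FORMAT"]))
    field <- if (has_pl) "PL" else if (has_gl) "GL" else NULL
    if (!is.null(field)) {
      raw <- vcfR::extract.gt(v, element = field)
      genoprobs <- lapply(seq_along(ids), function(i) {
        trip <- matrix(NA_real_, nrow(raw), 3L)
        vals <- strsplit(raw[, i], ",")
        ok <- lengths(vals) == 3L
        m <- matrix(as.numeric(unlist(vals[ok])), ncol = 3L, byrow = TRUE)
        lik <- if (field == "PL") 10^(-m / 10) else 10^m
        trip[ok, ] <- lik / rowSums(lik)
        # (hom-REF, het, hom-ALT) = (hom-A, het, hom-B): VCF order kept;
        # records without a likelihood triple carry no information
        if (any(!ok)) trip[!ok, ] <- 1 / 3
        trip
      })
      names(genoprobs) <- ids
    } else {
      # hard genotypes as degenerate probabilities
      genoprobs <- lapply(seq_along(ids), function(i) {
        trip <- matrix(1 / 3, ncol(codes), 3L)
        g <- codes[i, ]
        ok <- !is.na(g)
        trip[ok, ] <- 0
        trip[cbind(which(ok), 3L - g[ok])] <- 1
        trip
      })
      names(genoprobs) <- ids
    }
  }
  list(geno = geno_data(codes, ids = ids, genoprobs = genoprobs),
       map = map)
}

#' Read a pedigree file
#'
#' Whitespace-separated columns: individual, sire, dam and optionally
#' birth year.  `0`, `NA` or an empty field mark an unknown parent.
#'
#' @param path File path.
#' @return A `data.frame` with columns `id`, `sire`, `dam` and
#'   `birth_year` (NA when absent), parents preceding offspring.
#' @export
read_pedigree <- function(path) {
  p <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         fill = TRUE)
  if (ncol(p) < 3L) stop("pedigree file needs at least 3 columns")
  ped <- data.frame(id = as.character(p[[1L]]),
                    sire = as.character(p[[2L]]),
                    dam = as.character(p[[3L]]),
                    birth_year = if (ncol(p) >= 4L) as.numeric(p[[4L]])
                                 else NA_real_,
                    stringsAsFactors = FALSE)
  normalize_pedigree(ped)
}

#' Write HBD or simulated-truth segments as tab-separated text
#'
#' Columns: individual, chromosome, physical start/end, class index and
#' the class rate (a generation-equivalent: the rate is about twice the
#' number of generations to the common ancestor).
#'
#' @param segments A segment `data.frame` (from [predict.hbd_fit()] with
#'   `type = "segments"`, or simulated truth converted to bp).
#' @param path Output file.
#' @export
write_segments <- function(segments, path) {
  utils::write.table(segments, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' Write a minimal VCF (GT only)
#'
#' @param geno A [geno_data()].
#' @param map The aligned [marker_map()].
#' @param path Output file.
#' @export
write_vcf <- function(geno, map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", geno$ids),
                     collapse = "\t")), con)
  gt_of <- c("1/1", "0/1", "0/0")  # codes 0,1,2 -> copies of REF
  for (j in seq_len(nrow(map))) {
    g <- geno$codes[, j]
    gt <- ifelse(is.na(g), "./.", gt_of[g + 1L])
    writeLines(paste(c(map$chrom[j], map$bp[j], map$id[j], map$allele1[j],
                       map$allele2[j], ".", ".", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Serialize fitted models and decodings as structured text
#'
#' `write_fit_text()` writes one block per individual: a parameter table
#' (class, rate, mixing, free-rate flag) plus log-likelihood, BIC and the
#' non-missing marker count.  `write_decoding()` writes a per-marker
#' table (chrom, bp, one posterior column per class).
#'
#' @param fit An [hbd_fit()].
#' @param path Output file.
#' @export
write_fit_text <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  K <- fit$model$K
  for (id in fit$ids) {
    f <- fit$fits[[id]]
    writeLines(sprintf("#individual\t%s\tkind\t%s\tloglik\t%.6f\tbic\t%.6f\tn_obs\t%d",
                       id, fit$model$kind, f$loglik, f$bic, f$n_obs), con)
    writeLines("class\ttype\trate\tmixing\tfree_rate", con)
    writeLines(sprintf("%d\t%s\t%.6g\t%.6g\t%s", seq_len(K),
                       c(rep("HBD", K - 1L), "non-HBD"), f$rates,
                       f$mixing, fit$model$free_rates), con)
  }
  invisible(path)
}

#' @rdname write_fit_text
#' @param decoding An `"hbd_decoding"` from [forward_backward()].
#' @param map The aligned [marker_map()].
#' @export
write_decoding <- function(decoding, map, path) {
  post <- decoding$posteriors
  colnames(post) <- paste0("class", seq_len(ncol(post)))
  utils::write.table(data.frame(chrom = map$chrom, bp = map$bp, post),
                     path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
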