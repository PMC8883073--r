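#' Construct a genetic map
#'
#' A genetic map places an ordered set of loci on chromosomes with both a
#' physical (bp, 1-based) and a genetic (cM) coordinate, together with the
#' physical length of every chromosome. It is the coordinate system shared
#' by the crossing-scheme simulator, marker selection, and projection.
#'
#' @param loci data.frame with columns `chrom`, `bp`, `cM` and optionally
#'   `locus` (locus identifier). If `locus` is absent ids are generated in
#'   `chrom_index` style where the index is the 100-kb bin of the position
#'   (e.g. a locus at 36.4 Mb on A01 becomes `A01_364`).
#' @param chrom_lengths data.frame with columns `chrom`, `length_bp`.
#' @return An object of class `genetic_map`: a list with elements `loci`
#'   (ordered by chromosome then bp) and `lengths`.
#' @details Within each chromosome bp and cM must be strictly increasing,
#'   cM non-negative, and every locus must lie within the chromosome
#'   length. Chromosome order follows `chrom_lengths`.
#' @examples
#' gm <- genetic_map(
#'   data.frame(chrom = "A01", bp = c(1e6, 2e6), cM = c(0, 5)),
#'   data.frame(chrom = "A01", length_bp = 3e6)
#' )
#' map_chroms(gm)
#' @export
genetic_map <- function(loci, chrom_lengths) {
  stopifnot(is.data.frame(loci), is.data.frame(chrom_lengths))
  need <- c("chrom", "bp", "cM")
  if (!all(need %in% names(loci)))
    stop("loci must have columns: ", paste(need, collapse = ", "))
  if (!all(c("chrom", "length_bp") %in% names(chrom_lengths)))
    stop("chrom_lengths must have columns: chrom, length_bp")
  loci$chrom <- as.character(loci$chrom)
  chrom_lengths$chrom <- as.character(chrom_lengths$chrom)
  if (anyDuplicated(chrom_lengths$chrom))
    stop("duplicated chromosome in chrom_lengths")
  unknown <- setdiff(loci$chrom, chrom_lengths$chrom)
  if (length(unknown))
    stop("loci on chromosomes without a length: ", paste(unknown, collapse = ", "))

  ord <- order(match(loci$chrom, chrom_lengths$chrom), loci$bp)
  loci <- loci[ord, , drop = FALSE]
  if (is.null(loci$locus))
    loci$locus <- sprintf("%s_%d", loci$chrom, floor(loci$bp / 1e5))
  if (anyDuplicated(loci$locus))
    stop("duplicated locus ids in map")

  for (ch in unique(loci$chrom)) {
    l <- loci[loci$chrom == ch, ]
    if (any(diff(l$bp) <= 0)) stop("bp positions not strictly increasing on ", ch)
    if (any(diff(l$cM) <= 0)) stop("cM positions not strictly increasing on ", ch)
    if (any(l$cM < 0)) stop("negative cM position on ", ch)
    len <- chrom_lengths$length_bp[chrom_lengths$chrom == ch]
    if (any(l$bp < 1 | l$bp > len)) stop("locus outside chromosome length on ", ch)
  }
  rownames(loci) <- NULL
  structure(list(loci = loci, lengths = chrom_lengths), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic_map:", nrow(x$loci), "loci on", nrow(x$lengths), "chromosomes\n")
  invisible(x)
}

#' Chromosomes of a genetic map
#' @param map a `genetic_map`
#' @return character vector of chromosome names, in map order
#' @export
map_chroms <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  unique(map$loci$chrom)
}

#' Read a genetic map from tab-separated files
#'
#' @param map_file TSV with header and columns `chrom`, `bp`, `cM`.
#' @param lengths_file TSV with header and columns `chrom`, `length_bp`.
#' @return a `genetic_map`
#' @export
read_genetic_map <- function(map_file, lengths_file) {
  loci <- utils::read.delim(map_file, stringsAsFactors = FALSE)
  lens <- utils::read.delim(lengths_file, stringsAsFactors = FALSE)
  genetic_map(loci, lens)
}

#' Write a genetic map to tab-separated files
#' @param map a `genetic_map`
#' @param map_file,lengths_file output paths
#' @return invisibly, the map
#' @export
write_genetic_map <- function(map, map_file, lengths_file) {
  stopifnot(inherits(map, "genetic_map"))
  utils::write.table(map$loci, map_file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(map$lengths, lengths_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(map)
}

## Linear cM lookup at arbitrary bp, extrapolating flat beyond the mapped
## ends (the mapped span is all the genetic information we have).
interp_cm <- function(map, chrom, bp) {
  l <- map$loci[map$loci$chrom == chrom, ]
  if (nrow(l) == 0) stop("no map loci on chromosome ", chrom)
  if (nrow(l) == 1) return(rep(l$cM, length(bp)))
  stats::approx(l$bp, l$cM, xout = bp, rule = 2)$y
}

chrom_length <- function(map, chrom) {
  len <- map$lengths$length_bp[map$lengths$chrom == chrom]
  if (!length(len)) stop("unknown chromosome ", chrom)
  len
}
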