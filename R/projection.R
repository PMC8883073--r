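## Sparse-marker to genome-wide projection: build a dense panel of SNPs
## homozygous in every parent/accession, then substitute each line's
## marker-interval genotype classes with the corresponding parental
## alleles at the dense SNPs. Genotypes are carried as alt-allele dosage
## (0, 1, 2), which represents any diploid pair of the parental alleles.

#' Build a dense genome-wide SNP panel
#'
#' Partitions the genome into `n_regions` windows of equal width (total
#' genome length / n_regions, windows tiled within each chromosome),
#' keeps the variants homozygous in every sample as candidates, and
#' retains per window the candidate nearest the window midpoint (ties to
#' the smaller bp). Windows without candidates contribute no SNP, so the
#' panel size is at most `n_regions`.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` and one
#'   VCF-style GT column per sample (see [simulate_accession_variants]).
#' @param n_regions number of windows (>= 1).
#' @param chrom_lengths data.frame `chrom`, `length_bp`.
#' @param samples sample column names; defaults to the table's `samples`
#'   attribute or all columns after the four fixed ones.
#' @return object of class `dense_panel`: list with `snps` (data.frame
#'   `chrom`, `pos`, `ref`, `alt`, `region`), `geno` (samples x SNPs
#'   alt-dosage matrix with values 0/2), `n_regions` and `window_bp`.
#' @export
build_dense_panel <- function(variants, n_regions, chrom_lengths,
                              samples = NULL) {
  stopifnot(is.data.frame(variants))
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (is.null(samples)) samples <- attr(variants, "samples")
  if (is.null(samples))
    samples <- setdiff(names(variants), c("chrom", "pos", "ref", "alt"))
  gt <- as.matrix(variants[, samples, drop = FALSE])
  hom <- apply(gt == "0/0" | gt == "1/1", 1, all)
  cand <- variants[hom, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  cand_gt <- gt[hom, , drop = FALSE]

  w <- sum(chrom_lengths$length_bp) / n_regions
  keep <- integer(0); region <- integer(0)
  region_offset <- 0L
  for (i in seq_len(nrow(chrom_lengths))) {
    ch <- chrom_lengths$chrom[i]
    len <- chrom_lengths$length_bp[i]
    starts <- seq(1, len, by = w)
    ends <- pmin(starts + w - 1, len)
    rows <- which(cand$chrom == ch)
    if (length(rows)) {
      win <- findInterval(cand$pos[rows], starts)
      for (k in unique(win)) {
        in_win <- rows[win == k]
        mid <- (starts[k] + ends[k]) / 2
        ## in_win ascending in pos, so which.min keeps the smaller bp on a
        ## distance tie
        best <- in_win[which.min(abs(cand$pos[in_win] - mid))]
        keep <- c(keep, best)
        region <- c(region, region_offset + k)
      }
    }
    region_offset <- region_offset + length(starts)
  }
  ord <- order(keep)
  keep <- keep[ord]; region <- region[ord]
  snps <- cand[keep, , drop = FALSE]
  snps$region <- region
  rownames(snps) <- NULL
  geno <- t(ifelse(cand_gt[keep, , drop = FALSE] == "1/1", 2, 0))
  dimnames(geno) <- list(samples, paste0(snps$chrom, "_", snps$pos))
  structure(list(snps = snps, geno = geno, n_regions = as.integer(n_regions),
                 window_bp = w),
            class = "dense_panel")
}

#' @export
print.dense_panel <- function(x, ...) {
  cat(sprintf("dense_panel: %d SNPs in %d regions (window %.0f bp), %d samples\n",
              nrow(x$snps), x$n_regions, x$window_bp, nrow(x$geno)))
  invisible(x)
}

#' Project marker genotype classes onto a dense SNP panel
#'
#' For every line and every panel SNP, the SNP takes the genotype class of
#' the nearest marker in bp on the same chromosome (ties to the left
#' marker), and the class is instantiated with parental alleles: class A
#' becomes the donor's homozygous panel genotype, class B the line's
#' recipient parent's genotype, and class H the heterozygous donor /
#' recipient pair (when donor and recipient carry the same allele the cell
#' is that homozygote regardless of class). Panel samples (parents and
#' accessions) are carried through unchanged, so the result can feed a
#' joint diversity analysis.
#'
#' @param mat a [marker_matrix] with no missing calls (run [fill_missing]
#'   first); line recipient labels must name panel samples.
#' @param panel a [dense_panel].
#' @param donor name of the donor sample in the panel.
#' @return object of class `projected_matrix`: list with `dosage`
#'   ((panel samples + lines) x SNPs alt-dosage matrix), `snps`, and
#'   `samples` (data.frame `id`, `role` = reference/line, `recipient`).
#'   Panel SNPs on chromosomes without any marker are `NA` for lines and
#'   listed in the `unassignable` attribute.
#' @export
project_genotypes <- function(mat, panel, donor) {
  stopifnot(inherits(mat, "marker_matrix"), inherits(panel, "dense_panel"))
  if (!donor %in% rownames(panel$geno))
    stop("donor sample not in panel: ", donor)
  miss_rec <- setdiff(unique(mat$lines$recipient), rownames(panel$geno))
  if (length(miss_rec))
    stop("recipient samples not in panel: ", paste(miss_rec, collapse = ", "))

  n_snp <- nrow(panel$snps)
  lines_dos <- matrix(NA_real_, nrow(mat$calls), n_snp,
                      dimnames = list(rownames(mat$calls),
                                      colnames(panel$geno)))
  don_dos <- panel$geno[donor, ]
  unassignable <- integer(0)
  for (ch in unique(panel$snps$chrom)) {
    sidx <- which(panel$snps$chrom == ch)
    midx <- which(mat$markers$chrom == ch)
    if (!length(midx)) { unassignable <- c(unassignable, sidx); next }
    mp <- mat$markers$bp[midx]
    nearest <- if (length(midx) == 1) rep(1L, length(sidx)) else {
      mid <- (mp[-1] + mp[-length(mp)]) / 2
      ## left.open puts a SNP exactly at a midpoint with the left marker
      findInterval(panel$snps$pos[sidx], mid, left.open = TRUE) + 1L
    }
    for (i in seq_len(nrow(mat$calls))) {
      cls <- mat$calls[i, midx[nearest]]
      rec_dos <- panel$geno[mat$lines$recipient[i], sidx]
      dd <- don_dos[sidx]
      v <- ifelse(cls == "A", dd,
                  ifelse(cls == "B", rec_dos,
                         ifelse(cls == "H", (dd + rec_dos) / 2, NA_real_)))
      lines_dos[i, sidx] <- v
    }
  }
  dosage <- rbind(panel$geno, lines_dos)
  samples <- data.frame(
    id = c(rownames(panel$geno), mat$lines$id),
    role = c(rep("reference", nrow(panel$geno)),
             rep("line", nrow(mat$calls))),
    recipient = c(rep(NA_character_, nrow(panel$geno)),
                  mat$lines$recipient),
    stringsAsFactors = FALSE
  )
  structure(list(dosage = dosage, snps = panel$snps, samples = samples),
            class = "projected_matrix",
            unassignable = unassignable)
}

#' @export
print.projected_matrix <- function(x, ...) {
  cat(sprintf("projected_matrix: %d samples (%d lines) x %d SNPs\n",
              nrow(x$dosage), sum(x$samples$role == "line"), ncol(x$dosage)))
  invisible(x)
}

#' Write a projected genotype matrix as CSV (samples x SNPs alt dosage)
#' @param x a `projected_matrix`.
#' @param file output path.
#' @return invisibly, `x`.
#' @export
write_projected_matrix <- function(x, file) {
  stopifnot(inherits(x, "projected_matrix"))
  d <- data.frame(sample = rownames(x$dosage), role = x$samples$role,
                  x$dosage, check.names = FALSE)
  colnames(d)[-(1:2)] <- paste0(x$snps$chrom, "_", x$snps$pos)
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  invisible(x)
}
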