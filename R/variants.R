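## Synthetic parental/accession variant tables. Genotypes are VCF-style GT
## strings ("0/0", "1/1", "0/1", "./.") against a donor-side A-genome
## reference; filter-relevant evidence that comes from alignments in real
## data (flanking variation, homoeologous hits, reference mismatch of the
## donor) is carried as logical flag columns.

.BASES <- c("A", "C", "G", "T")

.rand_pos <- function(n, chrom_lengths) {
  ch <- chrom_lengths$chrom[sample.int(nrow(chrom_lengths), n, replace = TRUE,
                                       prob = chrom_lengths$length_bp)]
  pos <- vapply(ch, function(c1) {
    len <- chrom_lengths$length_bp[chrom_lengths$chrom == c1]
    sample.int(len, 1L)
  }, 1L)
  d <- data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  d <- unique(d[order(match(d$chrom, chrom_lengths$chrom), d$pos), , drop = FALSE])
  while (nrow(d) < n) {   # top up after de-duplication
    extra <- .rand_pos(n - nrow(d), chrom_lengths)
    d <- unique(rbind(d, extra))
    d <- d[order(match(d$chrom, chrom_lengths$chrom), d$pos), , drop = FALSE]
  }
  rownames(d) <- NULL
  d
}

#' Simulate an annotated parental variant table
#'
#' Generates a variant table of the kind used for diagnostic-marker design:
#' donor (`BraA`) and recipient (`BjuA_*`) genotype calls plus the flag
#' columns the filters consume, with per-locus ground-truth annotations of
#' which selection criterion each locus violates. Violations are drawn
#' independently per criterion with the given rates, so the surviving set
#' of any downstream filter can be checked exactly against the annotations.
#'
#' For `panel = "a_genome"` (markers discriminating the donor A genome from
#' the recipient's A subgenome) the violation rate names are `het_parent`
#' (a parent call heterozygous), `ref_mismatch` (donor disagrees with the
#' reference), `monomorphic` (recipients carry the donor allele),
#' `recipient_nonuniform` (one recipient differs from the rest),
#' `flanking_variation` (variation within 100 bp), `homoeolog_hit`
#' (homologous region in the B-progenitor genome). A locus drawn as
#' `monomorphic` suppresses a co-drawn `recipient_nonuniform` (the two
#' patterns are structurally exclusive).
#'
#' For `panel = "b_genome"` (markers detecting the B subgenome through an
#' A/B homoeologous contrast) the names are `a_polymorphic` (recipient A
#' calls differ from the donor), `no_ab_contrast` (B-homoeolog call equals
#' the A allele), and `recipient_polymorphic` (recipients segregate in
#' either subgenome).
#'
#' @param n_loci number of loci.
#' @param violation_rates named numeric vector of per-criterion violation
#'   probabilities in \[0, 1\]; unnamed criteria default to 0.
#' @param seed optional integer seed.
#' @param panel `"a_genome"` or `"b_genome"`.
#' @param n_recipients number of recipient parental lines.
#' @param chrom_lengths chromosome length table (`chrom`, `length_bp`);
#'   defaults to the package's ten-chromosome study genome
#'   ([a_genome_chrom_lengths]).
#' @return data.frame of class `parental_variants` with genotype columns,
#'   flag columns, ground-truth `truth_violates_*` columns and a
#'   `truth_pass` column.
#' @export
simulate_parental_variants <- function(n_loci, violation_rates = NULL,
                                       seed = NULL,
                                       panel = c("a_genome", "b_genome"),
                                       n_recipients = 6,
                                       chrom_lengths = a_genome_chrom_lengths()) {
  panel <- match.arg(panel)
  if (!is.null(seed)) set.seed(seed)
  crits <- if (panel == "a_genome") {
    c("het_parent", "ref_mismatch", "monomorphic", "recipient_nonuniform",
      "flanking_variation", "homoeolog_hit")
  } else {
    c("a_polymorphic", "no_ab_contrast", "recipient_polymorphic")
  }
  rates <- stats::setNames(rep(0, length(crits)), crits)
  if (!is.null(violation_rates)) {
    bad <- setdiff(names(violation_rates), crits)
    if (length(bad)) stop("unknown criteria: ", paste(bad, collapse = ", "))
    if (any(violation_rates < 0 | violation_rates > 1))
      stop("violation rates must be in [0, 1]")
    rates[names(violation_rates)] <- violation_rates
  }

  d <- .rand_pos(n_loci, chrom_lengths)
  d$ref <- sample(.BASES, n_loci, replace = TRUE)
  d$alt <- vapply(d$ref, function(r) sample(setdiff(.BASES, r), 1L), "")

  viol <- vapply(crits, function(cr) stats::runif(n_loci) < rates[cr],
                 logical(n_loci))
  viol <- matrix(viol, nrow = n_loci, dimnames = list(NULL, crits))

  rec_cols <- sprintf("BjuA_%d", seq_len(n_recipients))
  if (panel == "a_genome") {
    viol[viol[, "monomorphic"], "recipient_nonuniform"] <- FALSE
    d$BraA <- "0/0"
    rec <- matrix("1/1", n_loci, n_recipients, dimnames = list(NULL, rec_cols))
    for (i in which(viol[, "monomorphic"])) rec[i, ] <- "0/0"
    for (i in which(viol[, "recipient_nonuniform"]))
      rec[i, sample.int(n_recipients, 1L)] <- "0/0"
    for (i in which(viol[, "het_parent"])) {
      k <- sample.int(n_recipients + 1L, 1L)
      if (k == 1L) d$BraA[i] <- "0/1" else rec[i, k - 1L] <- "0/1"
    }
    d <- cbind(d, as.data.frame(rec, stringsAsFactors = FALSE))
    d$BjuB <- "./."
    d$reference_mismatch_BraA <- viol[, "ref_mismatch"]
    d$flanking_variation_within_100bp <- viol[, "flanking_variation"]
    d$homoeolog_hit_in_B_genome <- viol[, "homoeolog_hit"]
  } else {
    d$BraA <- "0/0"
    rec <- matrix("0/0", n_loci, n_recipients, dimnames = list(NULL, rec_cols))
    for (i in which(viol[, "a_polymorphic"])) rec[i, ] <- "1/1"
    d <- cbind(d, as.data.frame(rec, stringsAsFactors = FALSE))
    d$BjuB <- ifelse(viol[, "no_ab_contrast"], "0/0", "1/1")
    d$recipients_B_polymorphic <- viol[, "recipient_polymorphic"]
  }

  for (cr in crits) d[[paste0("truth_violates_", cr)]] <- viol[, cr]
  d$truth_pass <- rowSums(viol) == 0
  attr(d, "panel") <- panel
  attr(d, "recipient_cols") <- rec_cols
  class(d) <- c("parental_variants", "data.frame")
  d
}

#' Simulate a parent + accession variant table for dense-panel building
#'
#' Produces genome-wide biallelic variants with one VCF-style GT column per
#' sample. Most calls are homozygous (`0/0` or `1/1`, drawn per sample from
#' a per-locus alt-allele frequency); a small fraction are heterozygous or
#' missing, which makes a locus ineligible for a dense panel restricted to
#' loci homozygous in every sample.
#'
#' @param n_loci number of variant loci.
#' @param samples character vector of sample (column) names.
#' @param p_het,p_missing per-call probabilities of a heterozygous or
#'   missing genotype.
#' @param seed optional integer seed.
#' @param chrom_lengths chromosome length table; defaults to the study
#'   genome.
#' @return data.frame of class `accession_variants` with columns `chrom`,
#'   `pos`, `ref`, `alt` and one GT column per sample.
#' @export
simulate_accession_variants <- function(n_loci, samples, p_het = 0.02,
                                        p_missing = 0.02, seed = NULL,
                                        chrom_lengths = a_genome_chrom_lengths()) {
  if (!is.null(seed)) set.seed(seed)
  d <- .rand_pos(n_loci, chrom_lengths)
  d$ref <- sample(.BASES, n_loci, replace = TRUE)
  d$alt <- vapply(d$ref, function(r) sample(setdiff(.BASES, r), 1L), "")
  f_alt <- stats::runif(n_loci, 0.1, 0.9)
  for (s in samples) {
    gt <- ifelse(stats::runif(n_loci) < f_alt, "1/1", "0/0")
    u <- stats::runif(n_loci)
    gt[u < p_het] <- "0/1"
    gt[u >= p_het & u < p_het + p_missing] <- "./."
    d[[s]] <- gt
  }
  attr(d, "samples") <- samples
  class(d) <- c("accession_variants", "data.frame")
  d
}

#' Write a variant table as minimal VCF plus sidecar annotations
#'
#' The genotype columns go into a minimal VCFv4.2 body (GT-only FORMAT);
#' flag and ground-truth annotation columns go into a tab-separated sidecar
#' keyed by `chrom:pos`.
#'
#' @param x a `parental_variants` or `accession_variants` table.
#' @param vcf_file output VCF path.
#' @param annot_file output sidecar TSV path (omitted if `NULL` or if there
#'   are no annotation columns).
#' @return invisibly, `x`.
#' @export
write_variants_vcf <- function(x, vcf_file, annot_file = NULL) {
  stopifnot(is.data.frame(x))
  fixed <- c("chrom", "pos", "ref", "alt")
  stopifnot(all(fixed %in% names(x)))
  gt_cols <- names(x)[vapply(x, function(col)
    is.character(col) && all(col %in% c("0/0", "0/1", "1/0", "1/1", "./.")),
    TRUE)]
  gt_cols <- setdiff(gt_cols, fixed)
  if (!length(gt_cols)) stop("no genotype columns found")
  hdr <- c("##fileformat=VCFv4.2",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  paste(gt_cols, collapse = "\t")))
  body <- paste(x$chrom, x$pos, ".", x$ref, x$alt, ".", ".", ".", "GT",
                sep = "\t")
  for (s in gt_cols) body <- paste(body, x[[s]], sep = "\t")
  writeLines(c(hdr, body), vcf_file)
  annot_cols <- setdiff(names(x), c(fixed, gt_cols))
  if (!is.null(annot_file) && length(annot_cols)) {
    a <- data.frame(key = paste0(x$chrom, ":", x$pos),
                    x[, annot_cols, drop = FALSE],
                    check.names = FALSE)
    utils::write.table(a, annot_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' Read a minimal VCF plus sidecar annotations back into a variant table
#'
#' @param vcf_file VCF path (GT-only FORMAT, as written by
#'   [write_variants_vcf]).
#' @param annot_file optional sidecar TSV keyed by `chrom:pos`.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, one GT column per
#'   sample, and any sidecar columns joined back on.
#' @export
read_variants_vcf <- function(vcf_file, annot_file = NULL) {
  lines <- readLines(vcf_file)
  hline <- grep("^#CHROM", lines)
  if (!length(hline)) stop("missing #CHROM header line")
  cols <- strsplit(sub("^#", "", lines[hline[1]]), "\t")[[1]]
  body <- lines[-seq_len(hline[1])]
  m <- do.call(rbind, strsplit(body, "\t"))
  colnames(m) <- cols
  samples <- cols[-(1:9)]
  d <- data.frame(chrom = m[, "CHROM"], pos = as.integer(m[, "POS"]),
                  ref = m[, "REF"], alt = m[, "ALT"],
                  stringsAsFactors = FALSE)
  gt_only <- function(v) sub(":.*$", "", v)
  for (s in samples) d[[s]] <- gt_only(m[, s])
  if (!is.null(annot_file)) {
    a <- utils::read.delim(annot_file, stringsAsFactors = FALSE)
    key <- paste0(d$chrom, ":", d$pos)
    idx <- match(key, a$key)
    for (col in setdiff(names(a), "key")) d[[col]] <- a[[col]][idx]
  }
  attr(d, "samples") <- samples
  d
}
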