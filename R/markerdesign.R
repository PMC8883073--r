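## Selection of subgenome-diagnostic SNP markers from annotated parental
## variant tables, plus distribution statistics of a selected panel.

.recipient_cols <- function(table) {
  rc <- attr(table, "recipient_cols")
  if (is.null(rc)) rc <- grep("^BjuA_", names(table), value = TRUE)
  if (!length(rc)) stop("no recipient genotype columns (BjuA_*) found")
  rc
}

.is_hom <- function(gt) gt == "0/0" | gt == "1/1"
.hom_allele <- function(gt, ref, alt)
  ifelse(gt == "0/0", ref, ifelse(gt == "1/1", alt, NA_character_))

#' Filter loci diagnostic for the donor A genome
#'
#' Applies the marker-design criteria for SNPs that discriminate the donor
#' genome from the recipient's A subgenome: (i) homozygous in the donor and
#' every recipient; (ii) donor concordant with the reference (flag
#' `reference_mismatch_BraA` false); (iii) polymorphic between recipient
#' and donor A genomes; (iv) uniform across all recipient lines; (v) no
#' sequence variation within the 100-bp flanking region (flag); (vi) no
#' homologous region in the B-progenitor genome (flag). Even spacing along
#' chromosomes is a separate step ([select_evenly_spaced]).
#'
#' @param table a parental variant table (see
#'   [simulate_parental_variants]) with donor column `BraA`, recipient
#'   columns `BjuA_*` and the three flag columns.
#' @return the subset of rows passing all criteria, with a logical
#'   attribute matrix `"criteria"` (loci x criterion).
#' @export
filter_a_genome_diagnostic <- function(table) {
  stopifnot(is.data.frame(table))
  rc <- .recipient_cols(table)
  flags <- c("reference_mismatch_BraA", "flanking_variation_within_100bp",
             "homoeolog_hit_in_B_genome")
  missing_cols <- setdiff(c("BraA", "ref", "alt", flags), names(table))
  if (length(missing_cols))
    stop("missing required annotation columns: ",
         paste(missing_cols, collapse = ", "))
  rec_gt <- as.matrix(table[, rc, drop = FALSE])
  hom <- .is_hom(table$BraA) & apply(.is_hom(rec_gt), 1, all)
  donor_allele <- .hom_allele(table$BraA, table$ref, table$alt)
  rec_allele <- matrix(.hom_allele(rec_gt, table$ref, table$alt),
                       nrow = nrow(table))
  polymorphic <- rowSums(rec_allele != donor_allele, na.rm = TRUE) > 0
  uniform <- apply(rec_gt, 1, function(g) length(unique(g)) == 1)
  crit <- cbind(
    hom_parents   = hom,
    ref_match     = !table$reference_mismatch_BraA,
    polymorphic   = polymorphic & !is.na(donor_allele),
    uniform       = uniform,
    clean_flank   = !table$flanking_variation_within_100bp,
    no_homoeolog  = !table$homoeolog_hit_in_B_genome
  )
  keep <- rowSums(!crit) == 0
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "criteria") <- crit
  attr(out, "recipient_cols") <- rc
  out
}

#' Filter loci detecting the B subgenome via homoeologous contrast
#'
#' Retains loci uniform between the donor and recipient A genomes but
#' polymorphic between the A allele and the recipient's B-subgenome
#' homoeolog, with recipients non-polymorphic in both subgenomes. Such
#' loci amplify from both subgenomes and report B-genome presence.
#'
#' @param table a parental variant table with a `BjuB` homoeolog genotype
#'   column (see [simulate_parental_variants] with `panel = "b_genome"`).
#' @return the subset of rows passing, with attribute `"criteria"`.
#' @export
filter_b_genome_detection <- function(table) {
  stopifnot(is.data.frame(table))
  if (is.null(table$BjuB) || all(table$BjuB == "./."))
    stop("table has no BjuB homoeolog calls")
  rc <- .recipient_cols(table)
  rec_gt <- as.matrix(table[, rc, drop = FALSE])
  hom <- .is_hom(table$BraA) & apply(.is_hom(rec_gt), 1, all) &
    .is_hom(table$BjuB)
  donor_allele <- .hom_allele(table$BraA, table$ref, table$alt)
  rec_allele <- matrix(.hom_allele(rec_gt, table$ref, table$alt),
                       nrow = nrow(table))
  b_allele <- .hom_allele(table$BjuB, table$ref, table$alt)
  uniform_a <- rowSums(rec_allele != donor_allele, na.rm = TRUE) == 0
  ab_contrast <- !is.na(b_allele) & !is.na(donor_allele) &
    b_allele != donor_allele
  rec_nonpoly <- if (is.null(table$recipients_B_polymorphic)) TRUE else
    !table$recipients_B_polymorphic
  crit <- cbind(hom_parents = hom, uniform_a = uniform_a,
                ab_contrast = ab_contrast, recipients_nonpoly = rec_nonpoly)
  keep <- rowSums(!crit) == 0
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "criteria") <- crit
  attr(out, "recipient_cols") <- rc
  out
}

.maximin_select <- function(pos, k, chrom_len) {
  n <- length(pos)
  if (k > n) return(NULL)
  if (k == n) return(seq_len(n))
  if (k == 1) return(which.min(abs(pos - chrom_len / 2)))
  chosen <- c(which.min(pos), which.max(pos))
  while (length(chosen) < k) {
    remaining <- setdiff(seq_len(n), chosen)
    mind <- vapply(remaining, function(i) min(abs(pos[i] - pos[chosen])), 0)
    best <- remaining[mind == max(mind)]
    chosen <- c(chosen, best[which.min(pos[best])])
  }
  sort(chosen)
}

#' Select evenly spaced markers per chromosome
#'
#' Greedy maximin spacing: per chromosome the selection is seeded with the
#' candidates closest to the two chromosome ends, then candidates are added
#' one at a time, each maximizing its minimum bp distance to the markers
#' already chosen, until the target count is reached. Ties go to the
#' smaller bp position; a target of 1 picks the candidate nearest the
#' chromosome midpoint. The procedure is deterministic.
#'
#' @param candidates data.frame of candidate loci with columns `chrom`,
#'   `pos`, `ref`, `alt` and genotype columns `BraA`, `BjuA_*` (typically
#'   the output of [filter_a_genome_diagnostic]).
#' @param targets named integer vector of marker counts per chromosome
#'   (chromosomes not named are skipped), or a single unnamed count applied
#'   to every chromosome present.
#' @param map a [genetic_map] supplying chromosome lengths and the cM
#'   interpolation for the selected markers.
#' @return data.frame of class `diagnostic_markers` with columns `id`,
#'   `chrom`, `bp`, `cM`, `donor_allele`, `recipient_allele`.
#' @export
select_evenly_spaced <- function(candidates, targets, map) {
  stopifnot(is.data.frame(candidates), inherits(map, "genetic_map"))
  chroms <- unique(candidates$chrom)
  if (is.null(names(targets))) {
    if (length(targets) != 1) stop("targets must be named by chromosome")
    targets <- stats::setNames(rep(targets, length(chroms)), chroms)
  }
  rc <- .recipient_cols(candidates)
  out <- list()
  for (ch in names(targets)) {
    cand <- candidates[candidates$chrom == ch, , drop = FALSE]
    cand <- cand[order(cand$pos), , drop = FALSE]
    k <- targets[[ch]]
    if (k > nrow(cand))
      stop(sprintf("target %d exceeds %d candidates on chromosome %s",
                   k, nrow(cand), ch))
    if (k == 0) next
    sel <- cand[.maximin_select(cand$pos, k, chrom_length(map, ch)), ,
                drop = FALSE]
    out[[ch]] <- data.frame(
      id = sprintf("%s_%d", ch, floor(sel$pos / 1e5)),
      chrom = ch, bp = sel$pos,
      cM = interp_cm(map, ch, sel$pos),
      donor_allele = .hom_allele(sel$BraA, sel$ref, sel$alt),
      recipient_allele = .hom_allele(sel[[rc[1]]], sel$ref, sel$alt),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$id <- make.unique(res$id, sep = "_")
  class(res) <- c("diagnostic_markers", "data.frame")
  res
}

#' Physical and genetic distribution statistics of a marker panel
#'
#' Per chromosome: marker count, chromosome length, two physical density
#' variants — length-based (chromosome length / count) and span-based
#' (marker bp span / (count - 1)) — and the mean genetic interval (cM span
#' of the markers / (count - 1)). The genome-wide summary is the
#' arithmetic mean of the per-chromosome values. Alternatively, supply
#' externally computed per-chromosome values via `per_chrom` (e.g. a
#' published marker summary) and only the genome-wide means of its numeric
#' columns are computed.
#'
#' @param markers data.frame with `chrom`, `bp` and optionally `cM`
#'   (interpolated from `map` if absent); ignored when `per_chrom` given.
#' @param chrom_lengths data.frame `chrom`, `length_bp`.
#' @param map optional [genetic_map] for cM interpolation.
#' @param per_chrom optional data.frame of per-chromosome values with a
#'   `chrom` column; its numeric columns are averaged genome-wide.
#' @return list with `per_chrom` (data.frame) and `genome_wide` (named
#'   numeric means of the per-chromosome columns). Span-based values are
#'   `NA` on chromosomes with fewer than two markers and genome-wide means
#'   skip them.
#' @export
distribution_stats <- function(markers = NULL, chrom_lengths = NULL,
                               map = NULL, per_chrom = NULL) {
  if (!is.null(per_chrom)) {
    stopifnot(is.data.frame(per_chrom), "chrom" %in% names(per_chrom))
    num <- vapply(per_chrom, is.numeric, TRUE) & names(per_chrom) != "chrom"
    gw <- vapply(per_chrom[, num, drop = FALSE], mean, 0, na.rm = TRUE)
    return(list(per_chrom = per_chrom, genome_wide = gw))
  }
  stopifnot(is.data.frame(markers), is.data.frame(chrom_lengths))
  if (is.null(markers$cM)) {
    if (is.null(map)) stop("need marker cM positions or a map")
    markers$cM <- NA_real_
    for (ch in unique(markers$chrom)) {
      i <- markers$chrom == ch
      markers$cM[i] <- interp_cm(map, ch, markers$bp[i])
    }
  }
  rows <- lapply(unique(markers$chrom), function(ch) {
    g <- markers[markers$chrom == ch, ]
    len <- chrom_lengths$length_bp[chrom_lengths$chrom == ch]
    if (!length(len)) stop("no chromosome length for ", ch)
    n <- nrow(g)
    data.frame(
      chrom = ch, n_markers = n, length_bp = len,
      density_length_mb = len / n / 1e6,
      density_span_mb = if (n >= 2) diff(range(g$bp)) / (n - 1) / 1e6 else NA_real_,
      interval_cm = if (n >= 2) diff(range(g$cM)) / (n - 1) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  pc <- do.call(rbind, rows)
  num <- vapply(pc, is.numeric, TRUE) & !names(pc) %in% c("chrom")
  gw <- vapply(pc[, num, drop = FALSE], mean, 0, na.rm = TRUE)
  list(per_chrom = pc, genome_wide = gw)
}

#' Find large genetic gaps in a marker panel
#'
#' Scans each chromosome for intervals without markers longer than a cM
#' threshold, including the leading interval from the chromosome's mapped
#' start to the first marker and the trailing interval from the last marker
#' to the mapped end.
#'
#' @param markers data.frame with `chrom` and `cM` (or `bp` plus `map`).
#' @param map a [genetic_map] giving each chromosome's mapped cM extent.
#' @param threshold_cM minimum gap size reported (default 20).
#' @return data.frame with `chrom`, `from_cM`, `to_cM`, `size_cM`, `type`
#'   (leading/internal/trailing); zero rows if no gap exceeds the
#'   threshold.
#' @export
find_gaps <- function(markers, map, threshold_cM = 20) {
  stopifnot(is.data.frame(markers), inherits(map, "genetic_map"))
  if (is.null(markers$cM)) {
    markers$cM <- NA_real_
    for (ch in unique(markers$chrom)) {
      i <- markers$chrom == ch
      markers$cM[i] <- interp_cm(map, ch, markers$bp[i])
    }
  }
  out <- list()
  for (ch in unique(markers$chrom)) {
    cm <- sort(markers$cM[markers$chrom == ch])
    ml <- map$loci$cM[map$loci$chrom == ch]
    if (!length(ml)) stop("chromosome ", ch, " absent from map")
    lo <- min(ml); hi <- max(ml)
    from <- c(lo, cm)
    to <- c(cm, hi)
    type <- c("leading", rep("internal", length(cm) - 1), "trailing")
    g <- data.frame(chrom = ch, from_cM = from, to_cM = to,
                    size_cM = to - from, type = type,
                    stringsAsFactors = FALSE)
    out[[ch]] <- g[g$size_cM > threshold_cM, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a diagnostic marker table as TSV
#' @param markers a `diagnostic_markers` data.frame.
#' @param file output path.
#' @return invisibly, `markers`.
#' @export
write_marker_table <- function(markers, file) {
  utils::write.table(markers, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(markers)
}
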