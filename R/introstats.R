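## Segregation expectations from the crossing scheme and tests of observed
## deviation. Genotype classes: A = donor homozygote, B = recipient
## homozygote, H = heterozygote; the donor-allele ("A^r") genotype
## frequency is f = (2 n_A + n_H) / (2 (n_A + n_B + n_H)).

#' Exact single-locus segregation expectation of a crossing scheme
#'
#' Propagates the genotype probability vector over (A, H, B) through the
#' scheme's steps: `make_f1` gives pure H; `backcross_to_recipient` turns
#' a parent with donor-gamete probability g = p_A + p_H/2 into (0, g,
#' 1 - g); `self` applies the Mendelian transition (A stays A; H gives
#' 1/4 A + 1/2 H + 1/4 B; B stays B). All probabilities are dyadic
#' rationals and exact in double precision. For the backcross-self scheme
#' this yields A:B:H = 1:5:2 and a donor genotype frequency of 25%.
#'
#' @param spec a [cross_spec] without selection entries (expectations
#'   under selection are not computed).
#' @return list with `p_A`, `p_B`, `p_H` and `f_star`
#'   (= p_A + p_H / 2, the expected donor genotype frequency).
#' @examples
#' expected_segregation(cross_spec(
#'   c("make_f1", "backcross_to_recipient", "self"), n = 1))
#' @export
expected_segregation <- function(spec) {
  stopifnot(inherits(spec, "cross_spec"))
  if (!is.null(spec$selection))
    stop("expectation under selection is not supported")
  p <- c(A = 0, H = 1, B = 0)          # after make_f1
  for (step in spec$steps[-1]) {
    if (step == "backcross_to_recipient") {
      g <- p["A"] + p["H"] / 2         # donor-allele gamete probability
      p <- c(A = 0, H = unname(g), B = unname(1 - g))
    } else {                           # self
      p <- c(A = unname(p["A"] + p["H"] / 4),
             H = unname(p["H"] / 2),
             B = unname(p["B"] + p["H"] / 4))
    }
  }
  list(p_A = unname(p["A"]), p_B = unname(p["B"]), p_H = unname(p["H"]),
       f_star = unname(p["A"] + p["H"] / 2))
}

#' Count genotype calls
#'
#' @param x a [marker_matrix], or a character vector/matrix of A/B/H/D
#'   codes.
#' @return list with `n_A`, `n_B`, `n_H`, `n_D` and `n_total`.
#' @export
genotype_counts <- function(x) {
  calls <- if (inherits(x, "marker_matrix")) x$calls else x
  tab <- table(factor(calls, levels = c("A", "B", "H", "D")))
  list(n_A = unname(tab[["A"]]), n_B = unname(tab[["B"]]),
       n_H = unname(tab[["H"]]), n_D = unname(tab[["D"]]),
       n_total = length(calls))
}

#' Observed donor-allele genotype frequency
#'
#' f = (2 n_A + n_H) / (2 (n_A + n_B + n_H)): the frequency of the donor
#' allele among non-missing diploid calls. Equals 1 when all calls are
#' donor homozygotes and the theoretical f* of the crossing scheme in
#' expectation.
#'
#' @param counts list with `n_A`, `n_B`, `n_H` (e.g. from
#'   [genotype_counts]); missing calls are excluded by construction.
#' @return frequency in \[0, 1\].
#' @export
ar_frequency <- function(counts) {
  n <- counts$n_A + counts$n_B + counts$n_H
  if (n == 0) stop("no non-missing calls")
  (2 * counts$n_A + counts$n_H) / (2 * n)
}

#' Chi-square goodness-of-fit test of a segregation ratio
#'
#' Pearson chi-square of the observed A/B/H counts against the expected
#' proportions of a crossing scheme, df = 2.
#'
#' @param counts list with `n_A`, `n_B`, `n_H`.
#' @param exp expectation from [expected_segregation] (or any list with
#'   `p_A`, `p_B`, `p_H`).
#' @return list with `statistic`, `df`, `p_value`, `expected` (expected
#'   counts named A, B, H). Warns when an expected count is below 5,
#'   errors below 1 or at zero total.
#' @export
segregation_test <- function(counts, exp) {
  obs <- c(A = counts$n_A, B = counts$n_B, H = counts$n_H)
  n <- sum(obs)
  if (n == 0) stop("no non-missing calls")
  p <- c(A = exp$p_A, B = exp$p_B, H = exp$p_H)
  e <- n * p
  if (any(e < 1)) stop("expected count below 1 in some class")
  if (any(e < 5)) warning("expected count below 5; chi-square approximate")
  stat <- sum((obs - e)^2 / e)
  list(statistic = stat, df = 2L,
       p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
       expected = e)
}

#' Donor genome coverage
#'
#' Fraction of non-missing loci carrying at least one donor allele,
#' (n_A + n_H) / (n_A + n_B + n_H) — the proportion of the assayed genome
#' replaced (fully or heterozygously) by donor segments. For a
#' [marker_matrix] also reports the per-line mean and per-recipient-group
#' means, the summaries used to describe introgression panels.
#'
#' @param x a [marker_matrix] or a counts list (`n_A`, `n_B`, `n_H`).
#' @return for counts, a single proportion; for a matrix, a list with
#'   `aggregate` (pooled counts), `per_line` (data.frame), `mean_per_line`
#'   and `by_recipient` (named means).
#' @export
donor_coverage <- function(x) {
  cov1 <- function(cn) {
    n <- cn$n_A + cn$n_B + cn$n_H
    if (n == 0) stop("no non-missing calls")
    (cn$n_A + cn$n_H) / n
  }
  if (!inherits(x, "marker_matrix")) return(cov1(x))
  s <- per_line_summary(x)$lines
  list(aggregate = cov1(genotype_counts(x)),
       per_line = s[, c("id", "recipient", "donor_coverage")],
       mean_per_line = mean(s$donor_coverage, na.rm = TRUE),
       by_recipient = tapply(s$donor_coverage, s$recipient, mean,
                             na.rm = TRUE))
}

#' Flag markers with distorted segregation
#'
#' Per marker: observed donor genotype frequency, its direction relative
#' to the scheme's theoretical value f*, and a two-sided exact binomial
#' test of the 2N non-missing allele draws against f*, Bonferroni-corrected
#' across markers. Markers significantly below f* indicate selection for
#' the recipient genotype (e.g. self-incompatibility regions); the summary
#' reports how many markers sit above f* ("positively selected") and how
#' many are significantly recipient-skewed.
#'
#' @param x a [marker_matrix].
#' @param exp expectation with `f_star` (see [expected_segregation]).
#' @param alpha familywise significance level after Bonferroni (default
#'   0.05).
#' @return list with `per_marker` (data.frame: id, chrom, bp, counts,
#'   `f`, `direction`, `p_raw`, `p_adj`, `significant`) and `summary`
#'   (n_markers, n_above, prop_above, n_sig_below, n_sig_above).
#' @export
flag_distorted_markers <- function(x, exp, alpha = 0.05) {
  stopifnot(inherits(x, "marker_matrix"))
  f_star <- exp$f_star
  m <- x$markers
  res <- lapply(seq_len(ncol(x$calls)), function(j) {
    cn <- genotype_counts(x$calls[, j])
    n <- cn$n_A + cn$n_B + cn$n_H
    if (n == 0) stop("marker ", m$id[j], " has no non-missing calls")
    f <- ar_frequency(cn)
    pt <- stats::binom.test(2 * cn$n_A + cn$n_H, 2 * n, p = f_star)
    data.frame(id = m$id[j], chrom = m$chrom[j], bp = m$bp[j],
               n_A = cn$n_A, n_B = cn$n_B, n_H = cn$n_H, n_D = cn$n_D,
               f = f,
               direction = if (f > f_star) "above" else
                 if (f < f_star) "below" else "at",
               p_raw = pt$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- stats::p.adjust(res$p_raw, method = "bonferroni")
  res$significant <- res$p_adj < alpha
  summary <- list(
    n_markers = nrow(res),
    n_above = sum(res$direction == "above"),
    prop_above = mean(res$direction == "above"),
    n_sig_below = sum(res$significant & res$direction == "below"),
    n_sig_above = sum(res$significant & res$direction == "above")
  )
  list(per_marker = res, summary = summary)
}

#' Write a per-marker distortion report as TSV
#'
#' @param report result of [flag_distorted_markers].
#' @param file output path; the per-marker table is written with one
#'   trailing comment line holding the global summary.
#' @return invisibly, `report`.
#' @export
write_distortion_report <- function(report, file) {
  utils::write.table(report$per_marker, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- report$summary
  cat(sprintf("# markers=%d above=%d prop_above=%.4f sig_below=%d sig_above=%d\n",
              s$n_markers, s$n_above, s$prop_above, s$n_sig_below,
              s$n_sig_above),
      file = file, append = TRUE)
  invisible(report)
}
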