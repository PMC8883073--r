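## Default study conditions: the Brassica juncea x B. rapa introgression
## panel the package was developed around. Ten A-genome chromosomes, a
## 132-marker diagnostic panel, six recipient parents and 107 BC1S1 plants.

#' Chromosome lengths of the ten-chromosome A genome
#'
#' @return data.frame with `chrom` (A01..A10) and `length_bp`.
#' @export
a_genome_chrom_lengths <- function() {
  data.frame(
    chrom = sprintf("A%02d", 1:10),
    length_bp = c(29595527L, 31442979L, 38154160L, 21928416L, 28493056L,
                  29167992L, 28928902L, 22981702L, 45156810L, 20725693L),
    stringsAsFactors = FALSE
  )
}

#' Per-chromosome summary of the diagnostic A-genome marker panel
#'
#' The distribution of the 132 subgenome-diagnostic SNP markers used as the
#' package's default simulation conditions: marker count, published average
#' physical density (Mb per marker) and average genetic interval (cM)
#' per chromosome.
#'
#' @return data.frame with columns `chrom`, `length_bp`, `n_markers`,
#'   `density_mb`, `interval_cm`.
#' @export
a_genome_marker_summary <- function() {
  d <- a_genome_chrom_lengths()
  d$n_markers <- c(15L, 12L, 17L, 10L, 10L, 14L, 15L, 10L, 15L, 14L)
  d$density_mb <- c(1.649, 2.643, 1.710, 2.062, 2.958, 2.004, 1.862, 2.160,
                    2.885, 1.481)
  d$interval_cm <- c(4.113, 7.878, 6.535, 6.590, 10.658, 6.807, 5.328,
                     7.367, 6.523, 5.440)
  d
}

#' Recipient parents and progeny counts of the study design
#'
#' Six recipient accessions in three morphotypes, with the number of
#' backcross-self (BC1S1) lines and selected plants per recipient
#' (107 plants in total).
#'
#' @return data.frame with `id`, `morphotype`, `n_lines`, `n_plants`.
#' @export
study_recipients <- function() {
  data.frame(
    id = c("20JS1535", "20JS1539", "20JS1537", "20JS1536", "20JS1538",
           "20JS1540"),
    morphotype = c("semi-heading I", "semi-heading I", "semi-heading II",
                   "heading", "heading", "heading"),
    n_lines = c(13L, 19L, 41L, 3L, 16L, 9L),
    n_plants = c(14L, 20L, 44L, 3L, 17L, 9L),
    stringsAsFactors = FALSE
  )
}

#' Genetic map matching the default marker panel
#'
#' Builds a map with the panel's per-chromosome marker counts, markers
#' evenly spaced in bp, and per-chromosome genetic spans equal to
#' (count - 1) x the published mean marker interval, so simulated
#' recombination reproduces the panel's genetic marker spacing.
#'
#' @return a [genetic_map] with 132 loci on 10 chromosomes.
#' @export
study_map <- function() {
  s <- a_genome_marker_summary()
  loci <- do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
    k <- s$n_markers[i]
    data.frame(chrom = s$chrom[i],
               bp = round(s$length_bp[i] * (seq_len(k) - 0.5) / k),
               cM = (seq_len(k) - 1) * s$interval_cm[i],
               stringsAsFactors = FALSE)
  }))
  genetic_map(loci, s[, c("chrom", "length_bp")])
}

#' Simulate the study's marker genotype matrix
#'
#' Runs the backcross-self (BC1S1) crossing scheme once per recipient
#' parent with that recipient's plant count, genotypes the combined
#' population at all 132 panel markers, and returns one observed matrix of
#' 107 lines x 132 markers. The default missing rate is the study's
#' observed value (322 missing of 14 124 calls).
#'
#' @param seed integer seed; recipient sub-populations use consecutive
#'   derived seeds.
#' @param missing_rate,error_rate per-call rates passed to
#'   [genotype_population].
#' @param selection optional selection data.frame (see [cross_spec])
#'   applied in every recipient's cross.
#' @param n_per_recipient optional integer vector overriding the plant
#'   counts (recycled across the six recipients).
#' @return a [marker_matrix] with per-line recipient labels.
#' @export
simulate_study_matrix <- function(seed = 1L, missing_rate = 322 / 14124,
                                  error_rate = 0, selection = NULL,
                                  n_per_recipient = NULL) {
  gm <- study_map()
  rec_tab <- study_recipients()
  if (!is.null(n_per_recipient))
    rec_tab$n_plants <- rep_len(n_per_recipient, nrow(rec_tab))
  donor <- founder_genome("B9008", "R", gm)
  mats <- vector("list", nrow(rec_tab))
  for (i in seq_len(nrow(rec_tab))) {
    rec <- founder_genome(rec_tab$id[i], "J", gm)
    spec <- cross_spec(c("make_f1", "backcross_to_recipient", "self"),
                       n = rec_tab$n_plants[i],
                       seed = seed + i - 1L,
                       selection = selection)
    pop <- run_cross(spec, donor, rec, gm)
    mats[[i]] <- genotype_population(pop, missing_rate = missing_rate,
                                     error_rate = error_rate,
                                     seed = seed + 100L + i,
                                     line_prefix = sprintf("R%d_", i))
  }
  do.call(rbind_marker_matrix, mats)
}
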