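# hand-built variant table: donor BraA plus two recipients, all flags clean
hand_table <- function() {
  d <- data.frame(
    chrom = "A01", pos = c(1e6, 2e6, 3e6, 4e6),
    ref = "A", alt = "G",
    BraA = c("0/0", "0/0", "0/0", "0/0"),
    BjuA_1 = c("1/1", "0/1", "0/0", "1/1"),
    BjuA_2 = c("1/1", "1/1", "0/0", "0/0"),
    BjuB = "./.",
    reference_mismatch_BraA = FALSE,
    flanking_variation_within_100bp = FALSE,
    homoeolog_hit_in_B_genome = FALSE,
    stringsAsFactors = FALSE
  )
  d
}

test_that("diagnostic filter applies the design criteria", {
  d <- hand_table()
  surv <- filter_a_genome_diagnostic(d)
  # locus 2: heterozygous recipient; locus 3: identical to donor;
  # locus 4: recipients not uniform
  expect_equal(surv$pos, 1e6)
  # flags exclude otherwise-clean loci
  d2 <- hand_table()
  d2$flanking_variation_within_100bp[1] <- TRUE
  expect_equal(nrow(filter_a_genome_diagnostic(d2)), 0)
  d3 <- hand_table()
  d3$reference_mismatch_BraA[1] <- TRUE
  expect_equal(nrow(filter_a_genome_diagnostic(d3)), 0)
})

test_that("diagnostic filter rejects tables missing annotations", {
  d <- hand_table()
  d$homoeolog_hit_in_B_genome <- NULL
  expect_error(filter_a_genome_diagnostic(d), "homoeolog_hit_in_B_genome")
})

test_that("filters are idempotent", {
  t2 <- simulate_parental_variants(400, c(het_parent = 0.2,
                                          monomorphic = 0.3), seed = 8)
  s1 <- filter_a_genome_diagnostic(t2)
  s2 <- filter_a_genome_diagnostic(s1)
  expect_equal(s2$pos, s1$pos)
})

test_that("B-genome detection filter needs an A/B homoeologous contrast", {
  d <- data.frame(
    chrom = "A01", pos = c(1e6, 2e6, 3e6),
    ref = "A", alt = "G",
    BraA = "0/0",
    BjuA_1 = c("0/0", "1/1", "0/0"),
    BjuB = c("1/1", "1/1", "0/0"),
    recipients_B_polymorphic = FALSE,
    stringsAsFactors = FALSE
  )
  surv <- filter_b_genome_detection(d)
  # locus 2 polymorphic between the A genomes, locus 3 has no A/B contrast
  expect_equal(surv$pos, 1e6)
  d$BjuB <- "./."
  expect_error(filter_b_genome_detection(d), "BjuB")
})

test_that("annotated B-genome fixture reproduces its ground truth", {
  tb <- simulate_parental_variants(
    500, c(a_polymorphic = 0.25, no_ab_contrast = 0.2,
           recipient_polymorphic = 0.1), seed = 9, panel = "b_genome")
  surv <- filter_b_genome_detection(tb)
  expect_identical(paste(surv$chrom, surv$pos),
                   paste(tb$chrom, tb$pos)[tb$truth_pass])
})

cand_table <- function(pos, chrom = "A01") {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
             BraA = "0/0", BjuA_1 = "1/1",
             stringsAsFactors = FALSE)
}

test_that("maximin selection keeps forced configurations", {
  gm <- genetic_map(data.frame(chrom = "A01", bp = c(1e6, 100e6),
                               cM = c(0, 100)),
                    data.frame(chrom = "A01", length_bp = 110e6))
  # all candidates requested: all selected
  p10 <- seq(1e6, 100e6, length.out = 10)
  sel <- select_evenly_spaced(cand_table(p10), c(A01 = 10L), gm)
  expect_equal(sel$bp, p10)
  # maximin forced: {1, 2, 100} Mb with target 2 keeps the extremes
  sel2 <- select_evenly_spaced(cand_table(c(1e6, 2e6, 100e6)),
                               c(A01 = 2L), gm)
  expect_equal(sel2$bp, c(1e6, 100e6))
  expect_error(select_evenly_spaced(cand_table(c(1e6, 2e6)), c(A01 = 3L), gm),
               "A01")
})

test_that("maximin selection spaces markers at least as well as random subsets", {
  gm <- genetic_map(data.frame(chrom = "A01", bp = c(1e6, 100e6),
                               cM = c(0, 100)),
                    data.frame(chrom = "A01", length_bp = 110e6))
  set.seed(21)
  pos <- sort(sample(seq(1e6, 100e6, by = 1e4), 60))
  k <- 8L
  sel <- select_evenly_spaced(cand_table(pos), c(A01 = k), gm)
  expect_length(sel$bp, k)
  expect_true(all(sel$bp %in% pos))
  min_gap <- function(p) min(diff(sort(p)))
  got <- min_gap(sel$bp)
  rand <- replicate(1000, min_gap(sample(pos, k)))
  expect_gte(got, max(rand))
})

test_that("panel distribution statistics summarize both coordinate systems", {
  # two markers spanning 10 Mb on a 20 Mb chromosome
  gm <- genetic_map(data.frame(chrom = "A01", bp = c(1, 1e7), cM = c(0, 30)),
                    data.frame(chrom = "A01", length_bp = 2e7))
  st <- distribution_stats(data.frame(chrom = "A01", bp = c(1, 1e7)),
                           data.frame(chrom = "A01", length_bp = 2e7),
                           map = gm)
  expect_equal(st$per_chrom$density_length_mb, 10)
  expect_equal(st$per_chrom$density_span_mb, 10, tolerance = 1e-6)
  expect_equal(st$per_chrom$interval_cm, 30)
  # genome-wide means are arithmetic means of per-chromosome values and do
  # not depend on chromosome order
  pc <- a_genome_marker_summary()
  gw1 <- distribution_stats(per_chrom = pc)$genome_wide
  gw2 <- distribution_stats(per_chrom = pc[sample(nrow(pc)), ])$genome_wide
  expect_equal(gw1, gw2)
})

test_that("single-marker chromosomes report span statistics as absent", {
  gm <- toy_map()
  st <- distribution_stats(data.frame(chrom = c("A01", "A02"),
                                      bp = c(1e6, 1e6)),
                           gm$lengths, map = gm)
  expect_true(all(is.na(st$per_chrom$density_span_mb)))
  expect_true(all(is.na(st$per_chrom$interval_cm)))
})

test_that("gap finder reports intervals above threshold including chromosome ends", {
  gm <- genetic_map(data.frame(chrom = "A01", bp = c(1, 60e6), cM = c(0, 60)),
                    data.frame(chrom = "A01", length_bp = 61e6))
  # markers every 5 cM: no gap above 20
  dense <- data.frame(chrom = "A01", cM = seq(0, 60, by = 5))
  expect_equal(nrow(find_gaps(dense, gm, 20)), 0)
  # first marker at 25 cM: leading gap
  g <- find_gaps(data.frame(chrom = "A01", cM = c(25, 30, 35, 40, 45, 50, 55, 60)),
                 gm, 20)
  expect_equal(g$type, "leading")
  expect_equal(g$size_cM, 25)
})

test_that("gap finder agrees with a brute-force scan on random panels", {
  gm <- genetic_map(data.frame(chrom = "A01", bp = c(1, 80e6), cM = c(0, 80)),
                    data.frame(chrom = "A01", length_bp = 81e6))
  set.seed(33)
  for (rep in 1:20) {
    cm <- sort(runif(sample(3:12, 1), 0, 80))
    got <- find_gaps(data.frame(chrom = "A01", cM = cm), gm, 15)
    diffs <- diff(c(0, cm, 80))
    expect_equal(got$size_cM, diffs[diffs > 15])
  }
})
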