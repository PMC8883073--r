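test_that("genetic_map validates coordinates and ordering", {
  expect_s3_class(toy_map(), "genetic_map")
  gm_unsorted <- genetic_map(data.frame(chrom = "A01", bp = c(2e6, 1e6),
                                        cM = c(5, 0)),
                             data.frame(chrom = "A01", length_bp = 3e6))
  expect_equal(gm_unsorted$loci$bp, c(1e6, 2e6))  # sorted by position
  expect_error(genetic_map(data.frame(chrom = "A01", bp = c(1e6, 2e6),
                                      cM = c(5, 5)),
                           data.frame(chrom = "A01", length_bp = 3e6)),
               "strictly increasing")
  expect_error(genetic_map(data.frame(chrom = "A01", bp = 5e6, cM = 0),
                           data.frame(chrom = "A01", length_bp = 3e6)),
               "outside chromosome length")
  gm <- toy_map()
  tf <- tempfile(); tf2 <- tempfile()
  write_genetic_map(gm, tf, tf2)
  expect_equal(read_genetic_map(tf, tf2)$loci, gm$loci)
})

test_that("gamete from a homozygous parent is that haplotype", {
  gm <- toy_map()
  n <- nrow(gm$loci)
  parent <- matrix("J", n, 2, dimnames = list(gm$loci$locus, NULL))
  set.seed(1)
  for (k in 1:10)
    expect_identical(unname(simulate_meiosis(parent, gm)), rep("J", n))
})

test_that("meiosis rejects loci absent from the map", {
  gm <- toy_map()
  parent <- matrix("J", 3, 2, dimnames = list(c("x", "y", "z"), NULL))
  expect_error(simulate_meiosis(parent, gm), "absent from map")
})

test_that("zero map distance means zero recombinants", {
  gm <- genetic_map(data.frame(chrom = "A01", bp = c(1e6, 2e6),
                               cM = c(0, 1e-9)),
                    data.frame(chrom = "A01", length_bp = 3e6))
  parent <- matrix(c("a", "a", "b", "b"), 2, 2,
                   dimnames = list(gm$loci$locus, NULL))
  set.seed(2)
  gams <- replicate(2000, simulate_meiosis(parent, gm))
  expect_true(all(gams[1, ] == gams[2, ]))
})

test_that("recombination fraction at 50 cM matches the Haldane closed form", {
  gm <- genetic_map(data.frame(chrom = "A01", bp = c(1e6, 2e6), cM = c(0, 50)),
                    data.frame(chrom = "A01", length_bp = 3e6))
  parent <- matrix(c("a", "a", "b", "b"), 2, 2,
                   dimnames = list(gm$loci$locus, NULL))
  set.seed(3)
  n <- 100000
  gams <- replicate(n, simulate_meiosis(parent, gm))
  rf_obs <- mean(gams[1, ] != gams[2, ])
  rf_exp <- (1 - exp(-2 * 50 / 100)) / 2   # 0.3161 from the map function
  se <- sqrt(rf_exp * (1 - rf_exp) / n)
  expect_lt(abs(rf_obs - rf_exp), 3 * se)
})

test_that("F1 of two homozygous founders is uniformly heterozygous", {
  gm <- toy_map()
  f <- toy_founders(gm)
  pop <- run_cross(cross_spec("make_f1", n = 20, seed = 5),
                   f$donor, f$recipient, gm)
  cls <- genotype_classes(pop)
  expect_true(all(cls == "H"))
})

test_that("BC1S1 genotype proportions at an unlinked locus approach 1:5:2", {
  gm <- one_locus_map()
  f <- toy_founders(gm)
  n <- 100000
  pop <- run_cross(cross_spec(bc1s1_steps, n = n, seed = 11),
                   f$donor, f$recipient, gm)
  cls <- genotype_classes(pop)[, 1]
  p <- c(A = 1 / 8, B = 5 / 8, H = 2 / 8)
  for (g in names(p)) {
    se <- sqrt(p[g] * (1 - p[g]) / n)
    expect_lt(abs(mean(cls == g) - p[g]), 3 * se)
  }
})

test_that("crossing is reproducible and population-size stable", {
  gm <- toy_map()
  f <- toy_founders(gm)
  sp <- cross_spec(bc1s1_steps, n = 30, seed = 9)
  p1 <- run_cross(sp, f$donor, f$recipient, gm)
  p2 <- run_cross(sp, f$donor, f$recipient, gm)
  expect_identical(p1$origins, p2$origins)
  expect_length(p1$origins, 30)
})

test_that("every simulated allele traces to a founder", {
  gm <- toy_map()
  f <- toy_founders(gm)
  pop <- run_cross(cross_spec(bc1s1_steps, n = 50, seed = 13),
                   f$donor, f$recipient, gm)
  all_orig <- unlist(pop$origins)
  expect_true(all(all_orig %in% c(1L, 2L)))
  # per-locus allele counts over the population sum to 2N
  counts <- Reduce(`+`, lapply(pop$origins, function(o)
    (o[, 1] %in% 1:2) + (o[, 2] %in% 1:2)))
  expect_true(all(counts == 2 * 50))
})

test_that("lethal zygotic selection removes the targeted genotype", {
  gm <- toy_map()
  f <- toy_founders(gm)
  sel <- data.frame(locus = gm$loci$locus[1], w_A = 0, w_H = 1, w_B = 1)
  pop <- run_cross(cross_spec(bc1s1_steps, n = 300, seed = 17,
                              selection = sel),
                   f$donor, f$recipient, gm)
  cls <- genotype_classes(pop)
  expect_false(any(cls[, 1] == "A"))
  expect_true(any(cls[, 2] == "A"))  # other loci still segregate freely
})

test_that("selection at an untracked locus or with zero fitness is rejected", {
  gm <- toy_map()
  f <- toy_founders(gm)
  sel <- data.frame(locus = "nope", w_A = 1, w_H = 1, w_B = 1)
  expect_error(run_cross(cross_spec(bc1s1_steps, n = 5, seed = 1,
                                    selection = sel),
                         f$donor, f$recipient, gm), "not tracked")
  expect_error(cross_spec(bc1s1_steps, n = 5,
                          selection = data.frame(locus = "x", w_A = 0,
                                                 w_H = 0, w_B = 0)),
               "all zero")
  # F1 is uniformly heterozygous: zero H fitness leaves nothing to sample
  sel0 <- data.frame(locus = gm$loci$locus[1], w_A = 1, w_H = 0, w_B = 1)
  expect_error(run_cross(cross_spec("make_f1", n = 5, seed = 1,
                                    selection = sel0),
                         f$donor, f$recipient, gm), "rejected by selection")
})

test_that("genotyping with zero noise reproduces the truth exactly", {
  gm <- toy_map()
  f <- toy_founders(gm)
  pop <- run_cross(cross_spec(bc1s1_steps, n = 25, seed = 19),
                   f$donor, f$recipient, gm)
  m <- genotype_population(pop, missing_rate = 0, error_rate = 0)
  expect_identical(unname(m$calls), unname(genotype_classes(pop)))
})

test_that("missing_rate 1 blanks every call", {
  gm <- toy_map()
  f <- toy_founders(gm)
  pop <- run_cross(cross_spec(bc1s1_steps, n = 10, seed = 19),
                   f$donor, f$recipient, gm)
  m <- genotype_population(pop, missing_rate = 1, seed = 1)
  expect_true(all(m$calls == "D"))
})

test_that("missing-call count matches the binomial expectation", {
  # study-scale matrix: 107 x 132 calls at the observed missing rate
  rate <- 322 / 14124
  m <- simulate_study_matrix(seed = 4, missing_rate = rate)
  n_calls <- length(m$calls)
  expect_equal(n_calls, 14124)
  n_miss <- sum(m$calls == "D")
  se <- sqrt(n_calls * rate * (1 - rate))
  expect_lt(abs(n_miss - 322), 3 * se)
})

test_that("genotyping errors hit the requested fraction of calls", {
  gm <- toy_map()
  f <- toy_founders(gm)
  pop <- run_cross(cross_spec(bc1s1_steps, n = 400, seed = 23),
                   f$donor, f$recipient, gm)
  truth <- genotype_classes(pop)
  m <- genotype_population(pop, error_rate = 0.1, seed = 2)
  err <- mean(m$calls != truth)
  se <- sqrt(0.1 * 0.9 / length(truth))
  expect_lt(abs(err - 0.1), 4 * se)
})

test_that("parental-variant annotations are exact ground truth", {
  # all violation rates zero: everything passes
  t0 <- simulate_parental_variants(100, seed = 1)
  expect_true(all(t0$truth_pass))
  # heterozygous-parent rate 1: nothing survives the homozygosity criterion
  t1 <- simulate_parental_variants(100, c(het_parent = 1), seed = 2)
  expect_false(any(t1$truth_pass))
  expect_equal(nrow(filter_a_genome_diagnostic(t1)), 0)
  # mixed rates: survivor set equals the annotated pass set
  t2 <- simulate_parental_variants(
    800, c(het_parent = 0.15, ref_mismatch = 0.1, monomorphic = 0.25,
           recipient_nonuniform = 0.1, flanking_variation = 0.3,
           homoeolog_hit = 0.2), seed = 3)
  surv <- filter_a_genome_diagnostic(t2)
  expect_identical(paste(surv$chrom, surv$pos),
                   paste(t2$chrom, t2$pos)[t2$truth_pass])
})

test_that("variant tables round-trip through VCF plus sidecar", {
  tab <- simulate_parental_variants(60, c(het_parent = 0.2), seed = 5)
  vcf <- tempfile(fileext = ".vcf"); ann <- tempfile(fileext = ".tsv")
  write_variants_vcf(tab, vcf, ann)
  back <- read_variants_vcf(vcf, ann)
  expect_equal(back$pos, tab$pos)
  expect_equal(back$BraA, tab$BraA)
  expect_equal(back$truth_pass, tab$truth_pass)
  surv_a <- filter_a_genome_diagnostic(back)
  expect_equal(nrow(surv_a), sum(tab$truth_pass))
})
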