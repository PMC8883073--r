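# small variant table with controllable genotypes
var_table <- function(pos, gts, chrom = "A01") {
  d <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  for (s in names(gts)) d[[s]] <- gts[[s]]
  attr(d, "samples") <- names(gts)
  d
}

test_that("dense panel keeps one homozygous SNP per window, nearest the midpoint", {
  lens <- data.frame(chrom = "A01", length_bp = 100)
  # 4 windows of 25 bp; candidates in every window
  pos <- c(5, 12, 30, 60, 70, 90)
  v <- var_table(pos, list(S1 = "0/0", S2 = "1/1"))
  p <- build_dense_panel(v, 4, lens)
  # midpoints 13, 38, 63, 88
  expect_equal(p$snps$pos, c(12, 30, 60, 90))
  expect_equal(p$snps$region, 1:4)
  # a heterozygous call in any sample disqualifies the locus
  v2 <- v; v2$S1[2] <- "0/1"
  p2 <- build_dense_panel(v2, 4, lens)
  expect_equal(p2$snps$pos, c(5, 30, 60, 90))
  expect_error(build_dense_panel(v, 0, lens), "n_regions")
})

test_that("windows without candidates contribute nothing; full coverage hits n_regions", {
  lens <- data.frame(chrom = "A01", length_bp = 100)
  v <- var_table(c(10, 60), list(S1 = "0/0"))
  p <- build_dense_panel(v, 4, lens)
  expect_equal(nrow(p$snps), 2)
  v2 <- var_table(seq(2, 98, by = 3), list(S1 = "0/0"))
  p2 <- build_dense_panel(v2, 4, lens)
  expect_equal(nrow(p2$snps), 4)
})

test_that("panel choice equals a brute-force midpoint rule on random tables", {
  set.seed(61)
  lens <- data.frame(chrom = c("A01", "A02"), length_bp = c(500, 300))
  for (rep in 1:10) {
    n <- 40
    ch <- sample(lens$chrom, n, replace = TRUE)
    pos <- integer(n)
    for (c1 in lens$chrom) {
      i <- ch == c1
      pos[i] <- sample(seq_len(lens$length_bp[lens$chrom == c1]), sum(i))
    }
    d <- unique(data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE))
    d <- d[order(match(d$chrom, lens$chrom), d$pos), ]
    v <- var_table(d$pos, list(S1 = sample(c("0/0", "1/1", "0/1"),
                                           nrow(d), replace = TRUE,
                                           prob = c(.45, .45, .1))),
                   chrom = d$chrom)
    nr <- sample(3:8, 1)
    p <- build_dense_panel(v, nr, lens)
    # brute force: per chromosome, windows of width total/nr
    w <- sum(lens$length_bp) / nr
    want <- NULL
    for (ci in seq_len(nrow(lens))) {
      c1 <- lens$chrom[ci]; len <- lens$length_bp[ci]
      starts <- seq(1, len, by = w)
      hom <- v[v$chrom == c1 & v$S1 != "0/1", ]
      for (k in seq_along(starts)) {
        endk <- min(starts[k] + w - 1, len)
        inw <- hom[hom$pos >= starts[k] & hom$pos <= endk, ]
        if (!nrow(inw)) next
        mid <- (starts[k] + endk) / 2
        dd <- abs(inw$pos - mid)
        best <- inw[dd == min(dd), ]
        want <- rbind(want, best[which.min(best$pos),
                                 c("chrom", "pos")])
      }
    }
    expect_equal(p$snps[, c("chrom", "pos")],
                 want[order(match(want$chrom, lens$chrom), want$pos), ],
                 ignore_attr = TRUE)
  }
})

proj_fixture <- function() {
  lens <- data.frame(chrom = "A01", length_bp = 1000)
  set.seed(62)
  pos <- sort(sample(1:1000, 20))
  gts <- list(DON = sample(c("0/0", "1/1"), 20, replace = TRUE),
              REC = sample(c("0/0", "1/1"), 20, replace = TRUE))
  v <- var_table(pos, gts)
  panel <- build_dense_panel(v, 10, lens)
  list(panel = panel, lens = lens)
}

test_that("uniform lines project onto their parent's panel row", {
  fx <- proj_fixture()
  calls <- rbind(rep("B", 4), rep("A", 4), rep("H", 4))
  m <- mk_matrix(calls, bp = c(100, 400, 700, 950), recipient = "REC")
  pr <- project_genotypes(m, fx$panel, donor = "DON")
  don_row <- pr$dosage["DON", ]
  rec_row <- pr$dosage["REC", ]
  expect_equal(pr$dosage["L001", ], rec_row)  # all-B: recipient identity
  expect_equal(pr$dosage["L002", ], don_row)  # all-A: donor identity
  expect_equal(pr$dosage["L003", ], (don_row + rec_row) / 2)
  # cells mix only parental dosages
  expect_true(all(pr$dosage %in% c(0, 1, 2)))
})

test_that("projection follows the nearest marker with a left tie-break", {
  fx <- proj_fixture()
  mbp <- c(100, 400, 700, 950)
  calls <- matrix(sample(c("A", "B", "H"), 4, replace = TRUE), 1, 4)
  m <- mk_matrix(calls, bp = mbp, recipient = "REC")
  pr <- project_genotypes(m, fx$panel, donor = "DON")
  don_row <- pr$dosage["DON", ]
  rec_row <- pr$dosage["REC", ]
  for (s in seq_len(nrow(fx$panel$snps))) {
    dd <- abs(fx$panel$snps$pos[s] - mbp)
    nearest <- which(dd == min(dd))[1]   # smaller bp on ties
    want <- switch(calls[1, nearest],
                   A = don_row[s], B = rec_row[s],
                   H = (don_row[s] + rec_row[s]) / 2)
    expect_equal(pr$dosage["L001", s], unname(want))
  }
  # idempotent and deterministic
  pr2 <- project_genotypes(m, fx$panel, donor = "DON")
  expect_identical(pr$dosage, pr2$dosage)
})

test_that("a chromosome without markers is flagged unassignable", {
  lens <- data.frame(chrom = c("A01", "A02"), length_bp = c(500, 500))
  v <- var_table(c(100, 300), list(DON = c("0/0", "1/1"),
                                   REC = c("1/1", "0/0")))
  v2 <- var_table(c(150, 350), list(DON = c("0/0", "0/0"),
                                    REC = c("1/1", "1/1")), chrom = "A02")
  vv <- rbind(v, v2)
  attr(vv, "samples") <- c("DON", "REC")
  panel <- build_dense_panel(vv, 4, lens)
  m <- mk_matrix(matrix(c("A", "B"), 1, 2), chrom = c("A01", "A01"),
                 bp = c(100, 300), recipient = "REC")
  pr <- project_genotypes(m, panel, donor = "DON")
  un <- attr(pr, "unassignable")
  expect_true(all(panel$snps$chrom[un] == "A02"))
  expect_true(all(is.na(pr$dosage["L001", un])))
})

test_that("panel donor-dosage fraction approximates marker-level donor coverage", {
  # simulate lines with known truth on a dense map, genotype at all loci
  gm <- toy_map(8, 8, cm_step = 15)
  f <- toy_founders(gm)
  pop <- run_cross(cross_spec(bc1s1_steps, n = 20, seed = 63),
                   f$donor, f$recipient, gm)
  m <- genotype_population(pop)
  lens <- gm$lengths
  set.seed(64)
  nv <- 200
  ch <- sample(lens$chrom, nv, replace = TRUE, prob = lens$length_bp)
  pos <- vapply(ch, function(c1)
    sample.int(lens$length_bp[lens$chrom == c1], 1), 1L)
  d <- unique(data.frame(chrom = ch, pos = pos))
  d <- d[order(match(d$chrom, lens$chrom), d$pos), ]
  # opposite homozygotes everywhere: donor dosage 2, recipient 0
  v <- var_table(d$pos, list(DON = rep("1/1", nrow(d)),
                             REC = rep("0/0", nrow(d))), chrom = d$chrom)
  panel <- build_dense_panel(v, 60, lens)
  pr <- project_genotypes(m, panel, donor = "DON")
  cov <- donor_coverage(m)$per_line
  for (i in seq_len(nrow(m$calls))) {
    frac <- mean(pr$dosage[m$lines$id[i], ] > 0)
    expect_lt(abs(frac - cov$donor_coverage[i]), 0.25)
  }
})
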