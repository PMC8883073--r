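# Small in-code fixtures shared across test files.

# a 2-chromosome toy map with evenly spaced loci
toy_map <- function(n1 = 5, n2 = 4, cm_step = 10) {
  loci <- rbind(
    data.frame(chrom = "A01", bp = seq(1e6, by = 2e6, length.out = n1),
               cM = seq(0, by = cm_step, length.out = n1)),
    data.frame(chrom = "A02", bp = seq(1e6, by = 2e6, length.out = n2),
               cM = seq(0, by = cm_step, length.out = n2))
  )
  genetic_map(loci, data.frame(chrom = c("A01", "A02"),
                               length_bp = c(2e6 * n1 + 1e6, 2e6 * n2 + 1e6)))
}

toy_founders <- function(map) {
  list(donor = founder_genome("DON", "R", map),
       recipient = founder_genome("REC", "J", map))
}

bc1s1_steps <- c("make_f1", "backcross_to_recipient", "self")

# single-locus map: the simplest possible unlinked-locus setting
one_locus_map <- function() {
  genetic_map(data.frame(chrom = "A01", bp = 1e6, cM = 0),
              data.frame(chrom = "A01", length_bp = 2e6))
}

# build a marker_matrix directly from a character matrix of calls
mk_matrix <- function(calls, chrom = NULL, bp = NULL, recipient = "REC") {
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("A01", m)
  if (is.null(bp)) bp <- seq(1e6, by = 1e6, length.out = m)
  marker_matrix(
    calls,
    lines = data.frame(id = sprintf("L%03d", seq_len(n)),
                       recipient = rep_len(recipient, n)),
    markers = data.frame(id = sprintf("%s_%d", chrom, bp),
                         chrom = chrom, bp = bp)
  )
}

# brute-force nearest non-missing fill, used as an independent oracle
brute_fill <- function(calls, chrom, bp) {
  out <- calls
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    for (i in seq_len(nrow(calls))) {
      for (j in idx) {
        if (calls[i, j] != "D") next
        obs <- idx[calls[i, idx] != "D"]
        if (!length(obs)) next
        dd <- abs(bp[obs] - bp[j])
        cand <- obs[dd == min(dd)]
        out[i, j] <- calls[i, cand[which.min(bp[cand])]]
      }
    }
  }
  out
}
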