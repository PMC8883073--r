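## Crossing-scheme simulator. Haplotypes are stored as founder-origin
## vectors (1 = donor, 2 = recipient); allele codes are resolved from the
## founders only when genotypes are emitted. Recombination follows a
## no-interference (Haldane) model: the crossover count per chromosome is
## Poisson with mean equal to the chromosome map length in Morgans, and
## crossover positions are uniform on the cM axis.

## Fast internal gamete sampler over pre-extracted chromosome structure.
## chrom_idx: list of integer locus indices per chromosome; chrom_cm: list
## of locus cM positions per chromosome. parent: n_loci x 2 matrix.
.meiosis_internal <- function(parent, chrom_idx, chrom_cm) {
  gamete <- parent[, 1]
  for (k in seq_along(chrom_idx)) {
    idx <- chrom_idx[[k]]
    cm <- chrom_cm[[k]]
    span <- cm[length(cm)] - cm[1]
    nxo <- stats::rpois(1L, span / 100)
    start <- sample.int(2L, 1L)
    if (nxo == 0L) {
      phase <- rep.int(start, length(idx))
    } else {
      xo <- sort(stats::runif(nxo, cm[1], cm[length(cm)]))
      phase <- (start - 1L + findInterval(cm, xo)) %% 2L + 1L
    }
    swap <- phase == 2L
    if (any(swap)) gamete[idx[swap]] <- parent[idx[swap], 2L]
  }
  gamete
}

.chrom_structure <- function(map) {
  chroms <- unique(map$loci$chrom)
  idx <- lapply(chroms, function(ch) which(map$loci$chrom == ch))
  cm <- lapply(idx, function(i) map$loci$cM[i])
  list(idx = idx, cm = cm)
}

#' Simulate one meiosis (gamete formation)
#'
#' Draws a single gamete from a diploid parent under a no-interference
#' crossover model: per chromosome the number of crossovers is Poisson with
#' mean equal to the chromosome's map length in Morgans, and crossover
#' positions are uniform in cM. Between two loci d cM apart the expected
#' recombination fraction is the Haldane value (1 - exp(-2d/100))/2.
#'
#' @param parent a matrix with one row per locus (rownames = locus ids) and
#'   two columns, one per haplotype; entries are allele codes.
#' @param map the `genetic_map`; the parent must be defined at exactly the
#'   map loci.
#' @return named vector of allele codes, one per map locus (the gamete).
#' @export
simulate_meiosis <- function(parent, map) {
  stopifnot(inherits(map, "genetic_map"))
  parent <- as.matrix(parent)
  if (ncol(parent) != 2) stop("parent must have two haplotype columns")
  loci <- map$loci$locus
  if (is.null(rownames(parent)))
    stop("parent rows must be named by locus id")
  extra <- setdiff(rownames(parent), loci)
  if (length(extra))
    stop("locus absent from map: ", paste(utils::head(extra, 3), collapse = ", "))
  if (!all(loci %in% rownames(parent)))
    stop("parent must be defined at all map loci")
  parent <- parent[loci, , drop = FALSE]
  cs <- .chrom_structure(map)
  g <- .meiosis_internal(parent, cs$idx, cs$cm)
  names(g) <- loci
  g
}

## Acceptance probability of an offspring (origin matrix) under zygotic
## selection; sel_idx maps selection rows to locus indices.
.sel_accept_prob <- function(off, sel_idx, sel_w) {
  p <- 1
  for (r in seq_along(sel_idx)) {
    o <- off[sel_idx[r], ]
    g <- if (o[1] == 1L && o[2] == 1L) 1L else if (o[1] == 2L && o[2] == 2L) 3L else 2L
    w <- sel_w[r, ]
    p <- p * w[g] / max(w)
  }
  p
}

#' Run a crossing scheme and simulate a population
#'
#' Realizes a `cross_spec` starting from two homozygous founders, producing
#' `n` independent lines. Each backcross or selfing step replaces every
#' line by one offspring of that line (lines are independent pedigrees, as
#' when one plant per line is carried forward). With selection entries,
#' offspring are retained by rejection sampling with acceptance probability
#' proportional to the genotype fitness weight at each selected locus.
#'
#' @param spec a `cross_spec`.
#' @param donor,recipient `founder_genome` objects (donor first).
#' @param map the shared `genetic_map`.
#' @return object of class `sim_population`: a list with `origins` (list of
#'   n loci x 2 founder-origin matrices, 1 = donor, 2 = recipient), `map`,
#'   `donor`, `recipient`, `generation`, and `spec`.
#' @examples
#' gm <- genetic_map(data.frame(chrom = "A01", bp = 1e6, cM = 0),
#'                   data.frame(chrom = "A01", length_bp = 2e6))
#' don <- founder_genome("donor", "G", gm)
#' rec <- founder_genome("recipient", "T", gm)
#' pop <- run_cross(cross_spec(c("make_f1", "backcross_to_recipient", "self"),
#'                             n = 50, seed = 1), don, rec, gm)
#' table(genotype_classes(pop)[, 1])
#' @export
run_cross <- function(spec, donor, recipient, map) {
  stopifnot(inherits(spec, "cross_spec"),
            inherits(donor, "founder_genome"),
            inherits(recipient, "founder_genome"),
            inherits(map, "genetic_map"))
  loci <- map$loci$locus
  if (!setequal(names(donor$alleles), loci) ||
      !setequal(names(recipient$alleles), loci))
    stop("founders must be defined at the map loci")
  if (!any(donor$alleles[loci] != recipient$alleles[loci]))
    stop("founders must differ at >= 1 locus")

  sel <- spec$selection
  sel_idx <- NULL; sel_w <- NULL
  if (!is.null(sel)) {
    sel_idx <- match(sel$locus, loci)
    if (anyNA(sel_idx))
      stop("selection locus not tracked by the map: ",
           paste(sel$locus[is.na(sel_idx)], collapse = ", "))
    sel_w <- as.matrix(sel[, c("w_A", "w_H", "w_B")])
  }

  set.seed(spec$seed)
  cs <- .chrom_structure(map)
  n_loci <- length(loci)
  rec_hap <- rep.int(2L, n_loci)
  f1 <- cbind(rep.int(1L, n_loci), rec_hap)

  ## offspring generator per step, given the current individual
  draw_offspring <- function(ind, step) {
    if (step == "backcross_to_recipient")
      cbind(.meiosis_internal(ind, cs$idx, cs$cm), rec_hap)
    else  # self
      cbind(.meiosis_internal(ind, cs$idx, cs$cm),
            .meiosis_internal(ind, cs$idx, cs$cm))
  }

  produce <- function(ind, step) {
    if (is.null(sel)) return(draw_offspring(ind, step))
    for (try in 1:10000) {
      off <- draw_offspring(ind, step)
      p <- .sel_accept_prob(off, sel_idx, sel_w)
      if (p >= 1 || stats::runif(1) < p) return(off)
    }
    stop("all offspring rejected by selection (effective fitness zero)")
  }

  pop <- vector("list", spec$n)
  for (i in seq_len(spec$n)) pop[[i]] <- f1
  if (!is.null(sel)) {
    ## F1 genotype is fixed; selection with zero weight on H at a
    ## polymorphic locus leaves nothing to sample
    p_f1 <- .sel_accept_prob(f1, sel_idx, sel_w)
    if (p_f1 == 0) stop("all offspring rejected by selection (effective fitness zero)")
  }
  for (step in spec$steps[-1])
    for (i in seq_len(spec$n)) pop[[i]] <- produce(pop[[i]], step)

  gen <- paste(c("F1", vapply(spec$steps[-1], function(s)
    switch(s, backcross_to_recipient = "BC", self = "S"), "")), collapse = "")
  structure(list(origins = pop, map = map, donor = donor,
                 recipient = recipient, generation = gen, spec = spec),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("sim_population: %d individuals x %d loci (%s; donor %s, recipient %s)\n",
              length(x$origins), nrow(x$map$loci), x$generation,
              x$donor$label, x$recipient$label))
  invisible(x)
}

#' True genotype classes of a simulated population
#'
#' Classifies each (individual, locus) pair by founder origin: `A` both
#' haplotypes donor-derived, `B` both recipient-derived, `H` one of each.
#'
#' @param pop a `sim_population`.
#' @param loci locus ids to report (default all map loci).
#' @return character matrix, individuals x loci, codes A/B/H.
#' @export
genotype_classes <- function(pop, loci = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  all_loci <- pop$map$loci$locus
  if (is.null(loci)) loci <- all_loci
  idx <- match(loci, all_loci)
  if (anyNA(idx)) stop("unknown loci: ", paste(loci[is.na(idx)], collapse = ", "))
  out <- matrix(NA_character_, length(pop$origins), length(idx),
                dimnames = list(NULL, loci))
  for (i in seq_along(pop$origins)) {
    o <- pop$origins[[i]][idx, , drop = FALSE]
    s <- o[, 1] + o[, 2]                 # 2 = AA(donor), 4 = BB, 3 = het
    out[i, ] <- c("A", "H", "B")[s - 1L]
  }
  out
}

#' Emulate marker genotyping of a simulated population
#'
#' Converts true genotype classes at marker loci into an observed marker
#' genotype matrix, with independent per-call genotyping error (a uniformly
#' chosen wrong code among the other two of A/B/H) and missingness
#' (code D).
#'
#' @param pop a `sim_population`.
#' @param marker_loci locus ids assayed (default all tracked loci).
#' @param missing_rate per-call missingness probability in \[0, 1\].
#' @param error_rate per-call genotyping-error probability in \[0, 1).
#' @param seed optional integer seed.
#' @param line_prefix prefix for generated line ids.
#' @return a [marker_matrix] of observed calls.
#' @export
genotype_population <- function(pop, marker_loci = NULL, missing_rate = 0,
                                error_rate = 0, seed = NULL,
                                line_prefix = "L") {
  stopifnot(inherits(pop, "sim_population"))
  if (missing_rate < 0 || missing_rate > 1 || error_rate < 0 || error_rate >= 1)
    stop("missing_rate must be in [0, 1] and error_rate in [0, 1)")
  if (is.null(marker_loci)) marker_loci <- pop$map$loci$locus
  if (!is.null(seed)) set.seed(seed)
  truth <- genotype_classes(pop, marker_loci)
  calls <- truth
  n <- length(calls)
  if (error_rate > 0) {
    err <- which(stats::runif(n) < error_rate)
    for (j in err) {
      others <- setdiff(c("A", "B", "H"), calls[j])
      calls[j] <- others[sample.int(2L, 1L)]
    }
  }
  if (missing_rate > 0)
    calls[stats::runif(n) < missing_rate] <- "D"

  ids <- sprintf("%s%03d", line_prefix, seq_len(nrow(calls)))
  rownames(calls) <- ids
  minfo <- pop$map$loci[match(marker_loci, pop$map$loci$locus),
                        c("locus", "chrom", "bp", "cM")]
  names(minfo)[1] <- "id"
  marker_matrix(calls,
                lines = data.frame(id = ids,
                                   recipient = pop$recipient$label,
                                   stringsAsFactors = FALSE),
                markers = minfo)
}
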