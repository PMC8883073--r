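#' Define a fully homozygous founder genome
#'
#' Founders are inbred parents: a single allele per tracked map locus
#' describes both haplotypes. The crossing simulator tracks founder origin,
#' so allele codes only need to be distinct between donor and recipient at
#' the loci that should be informative.
#'
#' @param label founder name (e.g. `"B9008"` for a donor line).
#' @param alleles character vector of allele codes, one per map locus, named
#'   by locus id; a length-1 vector is recycled to all loci.
#' @param map the `genetic_map` the founder is defined on.
#' @return object of class `founder_genome`.
#' @export
founder_genome <- function(label, alleles, map) {
  stopifnot(inherits(map, "genetic_map"), is.character(label), length(label) == 1)
  loci <- map$loci$locus
  if (length(alleles) == 1) {
    alleles <- rep(alleles, length(loci))
    names(alleles) <- loci
  }
  if (is.null(names(alleles)) || !setequal(names(alleles), loci))
    stop("alleles must be named by map locus ids and cover every locus")
  alleles <- alleles[loci]
  structure(list(label = label, alleles = alleles), class = "founder_genome")
}

#' @export
print.founder_genome <- function(x, ...) {
  cat("founder_genome", x$label, "-", length(x$alleles), "loci (homozygous)\n")
  invisible(x)
}

#' Declare a crossing scheme
#'
#' A crossing scheme is an ordered list of steps applied to a starting pair
#' of founders. `make_f1` (always first) crosses donor x recipient;
#' `backcross_to_recipient` crosses every individual to the recipient
#' parent; `self` self-pollinates every individual. The classical
#' backcross-self (BC1S1) scheme is
#' `c("make_f1", "backcross_to_recipient", "self")`.
#'
#' Optional zygotic selection reweights offspring genotype frequencies at
#' named loci: an offspring with genotype class g at a selected locus is
#' retained with probability proportional to the fitness weight of g.
#'
#' @param steps character vector of steps; the first must be `"make_f1"`.
#' @param n population size (number of independent lines carried through
#'   the scheme).
#' @param seed integer seed making the simulated population reproducible.
#' @param selection optional data.frame with columns `locus`, `w_A`, `w_H`,
#'   `w_B` (non-negative fitness weights, not all zero per locus).
#' @return object of class `cross_spec`.
#' @examples
#' cross_spec(c("make_f1", "backcross_to_recipient", "self"), n = 100, seed = 1)
#' @export
cross_spec <- function(steps, n, seed = 1L,
                       selection = NULL) {
  valid <- c("make_f1", "backcross_to_recipient", "self")
  if (!length(steps) || !all(steps %in% valid))
    stop("steps must be drawn from: ", paste(valid, collapse = ", "))
  if (steps[1] != "make_f1") stop("first step must be make_f1")
  if (any(steps[-1] == "make_f1")) stop("make_f1 can only be the first step")
  if (!is.numeric(n) || n < 1) stop("population size must be >= 1")
  if (!is.null(selection)) {
    need <- c("locus", "w_A", "w_H", "w_B")
    if (!is.data.frame(selection) || !all(need %in% names(selection)))
      stop("selection needs columns: ", paste(need, collapse = ", "))
    w <- as.matrix(selection[, c("w_A", "w_H", "w_B")])
    if (any(w < 0)) stop("fitness weights must be >= 0")
    if (any(rowSums(w) == 0)) stop("fitness weights at a locus are all zero")
  }
  structure(list(steps = steps, n = as.integer(n), seed = as.integer(seed),
                 selection = selection),
            class = "cross_spec")
}

#' @export
print.cross_spec <- function(x, ...) {
  cat("cross_spec:", paste(x$steps, collapse = " -> "),
      sprintf("(n = %d, seed = %d%s)\n", x$n, x$seed,
              if (is.null(x$selection)) "" else ", with selection"))
  invisible(x)
}
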