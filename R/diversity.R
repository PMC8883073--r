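## Genetic diversity of projected lines and reference accessions:
## allele-sharing (identity-by-state) distance, neighbor-joining tree,
## per-group distance summaries.

#' Identity-by-state genetic distance
#'
#' d(i, j) = 1 - mean allele sharing over pairwise-complete loci, where two
#' diploid genotypes share 2 alleles when identical homozygotes, 1 when a
#' heterozygote meets either homozygote, and 0 for opposite homozygotes.
#' On alt-allele dosages this is mean(|dos_i - dos_j|) / 2. Distances are
#' in \[0, 1\]: 0 for identical samples, 1 for opposite homozygotes at
#' every locus.
#'
#' @param x a `projected_matrix`, or a numeric samples x loci matrix of
#'   alt-allele dosages (0/1/2, `NA` = missing).
#' @return object of class `ibs_dist`: list with `d` (symmetric distance
#'   matrix), `n_loci` (pairwise-complete locus counts) and
#'   `incomplete_pairs` (pairs with zero complete loci, distance `NA`).
#' @export
ibs_distance <- function(x) {
  dos <- if (inherits(x, "projected_matrix")) x$dosage else as.matrix(x)
  if (nrow(dos) < 2) stop("need >= 2 samples")
  if (ncol(dos) < 1) stop("need >= 1 locus")
  ids <- rownames(dos)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(dos)))
  n <- nrow(dos)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  nl <- matrix(ncol(dos), n, n, dimnames = list(ids, ids))
  incomplete <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diffs <- abs(dos[i, ] - dos[j, ])
      ok <- !is.na(diffs)
      nl[i, j] <- nl[j, i] <- sum(ok)
      if (!any(ok)) {
        d[i, j] <- d[j, i] <- NA_real_
        incomplete <- c(incomplete, paste(ids[i], ids[j], sep = ":"))
      } else {
        d[i, j] <- d[j, i] <- mean(diffs[ok]) / 2
      }
    }
  }
  diag(nl) <- rowSums(!is.na(dos))
  structure(list(d = d, n_loci = nl, incomplete_pairs = incomplete),
            class = "ibs_dist")
}

#' @export
print.ibs_dist <- function(x, ...) {
  cat(sprintf("ibs_dist: %d samples, distances %.4f..%.4f\n",
              nrow(x$d), min(x$d[upper.tri(x$d)], na.rm = TRUE),
              max(x$d[upper.tri(x$d)], na.rm = TRUE)))
  invisible(x)
}

#' Write a distance matrix as square CSV
#' @param d an `ibs_dist` or square matrix.
#' @param file output path.
#' @return invisibly, `d`.
#' @export
write_distance_matrix <- function(d, file) {
  m <- if (inherits(d, "ibs_dist")) d$d else as.matrix(d)
  utils::write.csv(data.frame(sample = rownames(m), m, check.names = FALSE),
                   file, row.names = FALSE, quote = FALSE)
  invisible(d)
}

#' Neighbor-joining tree
#'
#' Classical agglomerative neighbor joining: at each step the pair
#' minimizing the Q criterion Q(i,j) = (n-2) d(i,j) - r_i - r_j is joined,
#' with the standard branch-length and distance-update formulas; Q ties are
#' broken toward the lexicographically smallest pair of cluster ids
#' (smallest contained leaf name). Negative branch lengths are clamped to
#' zero and the total clamped deficit recorded. The result is the usual
#' unrooted tree with a basal trifurcation.
#'
#' @param d an `ibs_dist` or a symmetric distance matrix with dimnames.
#' @return an `ape` `phylo` tree with attributes `newick` (the emitted
#'   newick text) and `clamped` (total negative branch length set to 0).
#' @export
neighbor_join <- function(d) {
  D <- if (inherits(d, "ibs_dist")) d$d else as.matrix(d)
  if (nrow(D) < 3) stop("need >= 3 samples")
  if (anyNA(D)) stop("distance matrix has undefined entries")
  if (is.null(rownames(D))) stop("distance matrix needs sample names")
  labels <- rownames(D)          # newick fragment per active cluster
  reps <- rownames(D)            # smallest leaf id per cluster (tie-break)
  clamp_total <- 0
  clamp <- function(v) {
    if (v < 0) { clamp_total <<- clamp_total - v; 0 } else v
  }
  fmt <- function(v) sprintf("%.10g", v)

  while (nrow(D) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    key <- apply(cand, 1, function(ij) {
      p <- sort(c(reps[ij[1]], reps[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    vj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))))
    new_lab <- paste0("(", labels[i], ":", fmt(vi), ",",
                      labels[j], ":", fmt(vj), ")")
    new_rep <- min(reps[i], reps[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dk <- dk[-c(i, j)]
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    D <- rbind(cbind(D, dk), c(dk, 0))
    labels <- c(labels[-c(i, j)], new_lab)
    reps <- c(reps[-c(i, j)], new_rep)
    rownames(D) <- colnames(D) <- reps
  }
  ## final three clusters: closed-form three-point branch lengths
  va <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  vb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  vc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  newick <- paste0("(", labels[1], ":", fmt(va), ",",
                   labels[2], ":", fmt(vb), ",",
                   labels[3], ":", fmt(vc), ");")
  tree <- ape::read.tree(text = newick)
  attr(tree, "newick") <- newick
  attr(tree, "clamped") <- clamp_total
  tree
}

#' Per-group distance summary
#'
#' Within-group minimum, mean and maximum pairwise distance per group (over
#' unordered pairs; undefined and flagged for singleton groups) and the
#' matrix of between-group mean distances. Output ordering is
#' alphabetical in the group label, so summaries do not depend on sample
#' order.
#'
#' @param d an `ibs_dist` or symmetric distance matrix with dimnames.
#' @param groups named character vector mapping sample id to group label,
#'   or a data.frame with columns `id` and `group`.
#' @return list with `within` (data.frame `group`, `n`, `min_d`, `mean_d`,
#'   `max_d`, `singleton`) and `between` (symmetric matrix of mean
#'   between-group distances; diagonal = within-group means).
#' @export
group_distance_summary <- function(d, groups) {
  m <- if (inherits(d, "ibs_dist")) d$d else as.matrix(d)
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group), groups$id)
  miss <- setdiff(rownames(m), names(groups))
  if (length(miss))
    stop("samples without group label: ", paste(miss, collapse = ", "))
  g <- groups[rownames(m)]
  levs <- sort(unique(g))
  within <- do.call(rbind, lapply(levs, function(lv) {
    idx <- which(g == lv)
    if (length(idx) < 2)
      return(data.frame(group = lv, n = length(idx), min_d = NA_real_,
                        mean_d = NA_real_, max_d = NA_real_,
                        singleton = TRUE, stringsAsFactors = FALSE))
    v <- m[idx, idx][upper.tri(m[idx, idx])]
    data.frame(group = lv, n = length(idx), min_d = min(v), mean_d = mean(v),
               max_d = max(v), singleton = FALSE, stringsAsFactors = FALSE)
  }))
  between <- matrix(NA_real_, length(levs), length(levs),
                    dimnames = list(levs, levs))
  for (a in seq_along(levs)) for (b in seq_along(levs)) {
    ia <- which(g == levs[a]); ib <- which(g == levs[b])
    if (a == b) {
      between[a, b] <- within$mean_d[a]
    } else {
      between[a, b] <- mean(m[ia, ib, drop = FALSE])
    }
  }
  list(within = within, between = between)
}
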