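## The marker genotype matrix: the central observational object. Calls are
## one of four codes: A (donor homozygote), B (recipient homozygote),
## H (heterozygote), D (missing).

.CODES <- c("A", "B", "H", "D")

#' Construct a marker genotype matrix
#'
#' @param calls character matrix (lines x markers) with codes A/B/H/D.
#' @param lines data.frame with columns `id` and `recipient` (the line's
#'   recipient/recurrent parent), one row per matrix row.
#' @param markers data.frame with columns `id`, `chrom`, `bp` (and
#'   optionally `cM`), one row per matrix column. Markers are kept sorted
#'   by chromosome then bp; an unsorted input is sorted with a warning.
#' @return object of class `marker_matrix`.
#' @export
marker_matrix <- function(calls, lines, markers) {
  calls <- as.matrix(calls)
  stopifnot(is.character(calls), is.data.frame(lines), is.data.frame(markers))
  if (!all(c("id", "recipient") %in% names(lines)))
    stop("lines needs columns id, recipient")
  if (!all(c("id", "chrom", "bp") %in% names(markers)))
    stop("markers needs columns id, chrom, bp")
  if (nrow(calls) != nrow(lines) || ncol(calls) != nrow(markers))
    stop("calls dimensions do not match lines/markers")
  if (anyDuplicated(lines$id)) stop("duplicate line ids")
  if (anyDuplicated(markers$id)) stop("duplicate marker ids")
  bad <- which(!calls %in% .CODES)
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(calls))
    stop(sprintf("invalid genotype code '%s' at line %s, marker %s",
                 calls[bad[1]], lines$id[rc[1]], markers$id[rc[2]]))
  }
  ord <- order(match(markers$chrom, unique(markers$chrom)), markers$bp)
  if (!identical(ord, seq_len(nrow(markers)))) {
    warning("markers not sorted by chromosome and position; sorting")
    markers <- markers[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  for (ch in unique(markers$chrom))
    if (any(diff(markers$bp[markers$chrom == ch]) <= 0))
      stop("duplicate marker positions on ", ch)
  dimnames(calls) <- list(lines$id, markers$id)
  rownames(lines) <- NULL
  rownames(markers) <- NULL
  structure(list(calls = calls, lines = lines, markers = markers),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  tab <- table(factor(x$calls, levels = .CODES))
  cat(sprintf("marker_matrix: %d lines x %d markers (%s)\n",
              nrow(x$calls), ncol(x$calls),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$calls)

#' Combine marker matrices over the same marker panel
#'
#' Stacks the lines of several matrices genotyped at an identical marker
#' set (e.g. per-recipient simulated sub-populations).
#'
#' @param ... `marker_matrix` objects sharing the same markers.
#' @return a single `marker_matrix`.
#' @export
rbind_marker_matrix <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1, all(vapply(xs, inherits, TRUE, "marker_matrix")))
  m0 <- xs[[1]]$markers
  for (x in xs[-1])
    if (!identical(x$markers$id, m0$id)) stop("marker panels differ")
  marker_matrix(do.call(rbind, lapply(xs, `[[`, "calls")),
                do.call(rbind, lapply(xs, `[[`, "lines")),
                m0)
}

#' Read a marker genotype matrix from CSV
#'
#' Expected layout: first column line id, second column recipient label,
#' remaining columns one per marker with codes A/B/H/D. Marker chromosome
#' and position are taken from `markers` when supplied, otherwise parsed
#' from `chrom_index` ids (index = 100-kb bin, so `A01_364` maps to
#' 36.4 Mb on A01).
#'
#' @param file CSV path.
#' @param markers optional data.frame (`id`, `chrom`, `bp`) overriding the
#'   id-derived marker coordinates.
#' @return a [marker_matrix].
#' @export
load_matrix <- function(file, markers = NULL) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 3) stop("expected line id, recipient and >= 1 marker column")
  lines <- data.frame(id = as.character(d[[1]]),
                      recipient = as.character(d[[2]]),
                      stringsAsFactors = FALSE)
  calls <- as.matrix(d[, -(1:2), drop = FALSE])
  storage.mode(calls) <- "character"
  if (is.null(markers)) {
    ids <- colnames(calls)
    parts <- regmatches(ids, regexec("^(.+)_([0-9]+)$", ids))
    ok <- lengths(parts) == 3
    if (!all(ok))
      stop("marker ids not in chrom_index form: ",
           paste(ids[!ok], collapse = ", "), " (supply `markers`)")
    markers <- data.frame(id = ids,
                          chrom = vapply(parts, `[`, "", 2),
                          bp = as.numeric(vapply(parts, `[`, "", 3)) * 1e5,
                          stringsAsFactors = FALSE)
  }
  marker_matrix(calls, lines, markers)
}

#' Write a marker genotype matrix to CSV
#'
#' @param x a [marker_matrix].
#' @param file output CSV path.
#' @return invisibly, `x`.
#' @export
save_matrix <- function(x, file) {
  stopifnot(inherits(x, "marker_matrix"))
  d <- data.frame(line = x$lines$id, recipient = x$lines$recipient,
                  x$calls, stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(d, file, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Fill missing genotype calls from the nearest marker
#'
#' Replaces each missing call (D) by the call of the nearest non-missing
#' marker in bp on the same chromosome for that line; when two non-missing
#' neighbors are equidistant the left (smaller bp) one is used. A
#' chromosome with no non-missing call for a line is left missing. The
#' input is not modified.
#'
#' @param x a [marker_matrix].
#' @return a new [marker_matrix] with missing calls filled.
#' @export
fill_missing <- function(x) {
  stopifnot(inherits(x, "marker_matrix"))
  calls <- x$calls
  for (ch in unique(x$markers$chrom)) {
    idx <- which(x$markers$chrom == ch)
    bp <- x$markers$bp[idx]
    for (i in seq_len(nrow(calls))) {
      m <- calls[i, idx]
      miss <- which(m == "D")
      if (!length(miss)) next
      obs <- which(m != "D")
      if (!length(obs)) next
      for (j in miss) {
        ## obs is in ascending bp order, so which.min takes the left
        ## neighbor on a distance tie
        m[j] <- m[obs[which.min(abs(bp[obs] - bp[j]))]]
      }
      calls[i, idx] <- m
    }
  }
  marker_matrix(calls, x$lines, x$markers)
}

#' Per-line genotype proportions
#'
#' For every line, the proportions of A, B and H calls over its non-missing
#' calls, plus group means by recipient parent. Lines with no non-missing
#' call get `NA` proportions and are flagged.
#'
#' @param x a [marker_matrix].
#' @return list with `lines` (per-line counts, proportions, a
#'   `donor_coverage` column ((A + H) / non-missing) and `all_missing`
#'   flag) and `groups` (mean proportions and coverage by recipient).
#' @export
per_line_summary <- function(x) {
  stopifnot(inherits(x, "marker_matrix"))
  cnt <- function(code) rowSums(x$calls == code)
  d <- data.frame(id = x$lines$id, recipient = x$lines$recipient,
                  n_A = cnt("A"), n_B = cnt("B"), n_H = cnt("H"),
                  n_D = cnt("D"), stringsAsFactors = FALSE)
  tot <- d$n_A + d$n_B + d$n_H
  d$p_A <- ifelse(tot > 0, d$n_A / tot, NA_real_)
  d$p_B <- ifelse(tot > 0, d$n_B / tot, NA_real_)
  d$p_H <- ifelse(tot > 0, d$n_H / tot, NA_real_)
  d$donor_coverage <- ifelse(tot > 0, (d$n_A + d$n_H) / tot, NA_real_)
  d$all_missing <- tot == 0
  rownames(d) <- NULL
  groups <- stats::aggregate(
    d[, c("p_A", "p_B", "p_H", "donor_coverage")],
    by = list(recipient = d$recipient),
    FUN = function(v) mean(v, na.rm = TRUE))
  list(lines = d, groups = groups[order(groups$recipient), , drop = FALSE])
}

#' Graphical genotype plot
#'
#' Lines x markers tile plot of the four genotype codes, markers arranged
#' by physical position within chromosome, lines grouped by recipient
#' parent.
#'
#' @param x a [marker_matrix].
#' @param palette named colors for codes A, B, H, D.
#' @param file optional path; when given the plot is also saved with
#'   `ggplot2::ggsave()`.
#' @param width,height device size in inches when saving.
#' @return the ggplot object, invisibly when `file` is given.
#' @export
export_graphical_genotypes <- function(x,
                                       palette = c(A = "#E69F00",
                                                   B = "#4472C4",
                                                   H = "#2E9E44",
                                                   D = "grey75"),
                                       file = NULL, width = 10, height = 7) {
  stopifnot(inherits(x, "marker_matrix"))
  stopifnot(all(.CODES %in% names(palette)))
  line_ord <- x$lines$id[order(x$lines$recipient, x$lines$id)]
  d <- data.frame(
    line = factor(rep(rownames(x$calls), ncol(x$calls)),
                  levels = rev(line_ord)),
    marker = factor(rep(colnames(x$calls), each = nrow(x$calls)),
                    levels = x$markers$id),
    call = factor(as.vector(x$calls), levels = .CODES)
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$marker, y = .data$line,
                                       fill = .data$call)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = palette, drop = FALSE,
                               name = "genotype") +
    ggplot2::labs(x = "marker (physical order)", y = "line") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 4),
                   axis.text.y = ggplot2::element_text(size = 4))
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}
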