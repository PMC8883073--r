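## End-to-end orchestration: simulate -> markerdesign -> genotypes ->
## introstats -> projection -> diversity, driven by one config (R list or
## YAML file) and one seed. Stage randomness uses fixed offsets from the
## config seed so stages are independently reproducible, and every tabular
## output carries a comment header with the config hash.

.STAGES <- c("simulate", "design", "genotypes", "stats", "projection",
             "diversity")

## polynomial rolling hash over the deparsed config, for output
## provenance headers (a tag, not a cryptographic digest)
.config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.write_tabular <- function(df, path, hash, seed, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Default pipeline configuration
#'
#' Returns the full configuration list with the package's study-condition
#' defaults; override any entry before passing to [run_pipeline]. Entries:
#' `seed`, `out_dir`, `stages` (subset of simulate, design, genotypes,
#' stats, projection, diversity), `matrix_file` / `variants_file` (inputs
#' when the simulate stage is disabled), `n_design_loci` and
#' `violation_rates` (marker-design fixture), `targets` (markers per
#' chromosome; default the study panel counts), `n_panel_loci` and
#' `n_accessions` (dense-panel input), `n_regions`, `alpha`,
#' `missing_rate`, `error_rate`, `selection`.
#'
#' @param out_dir output directory.
#' @param seed integer master seed.
#' @return named list.
#' @export
default_config <- function(out_dir, seed = 1L) {
  s <- a_genome_marker_summary()
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = .STAGES,
    matrix_file = NULL,
    variants_file = NULL,
    n_design_loci = 2000L,
    violation_rates = c(het_parent = 0.1, ref_mismatch = 0.05,
                        monomorphic = 0.3, recipient_nonuniform = 0.1,
                        flanking_variation = 0.3, homoeolog_hit = 0.2),
    targets = stats::setNames(s$n_markers, s$chrom),
    n_panel_loci = 4000L,
    n_accessions = 12L,
    n_regions = 2000L,
    alpha = 0.05,
    missing_rate = 322 / 14124,
    error_rate = 0,
    selection = NULL
  )
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$out_dir), !is.null(config$seed))
  base <- default_config(config$out_dir, config$seed)
  base[names(config)] <- config
  ## YAML deserializes named vectors as lists; flatten the scalar-map fields
  for (f in c("stages", "targets", "violation_rates"))
    if (is.list(base[[f]])) base[[f]] <- unlist(base[[f]])
  for (f in c("seed", "n_design_loci", "n_panel_loci", "n_accessions",
              "n_regions"))
    base[[f]] <- as.integer(base[[f]])
  base
}

#' Run the full introgression-analysis pipeline
#'
#' Executes the enabled stages in order: `simulate` (marker matrix,
#' annotated design variants, panel variants), `design` (diagnostic-marker
#' filtering, even spacing, distribution stats, gap report), `genotypes`
#' (load/validate, missing fill, per-line summary), `stats` (segregation
#' expectation and test, donor coverage, distortion flags), `projection`
#' (dense panel and genome-wide genotype projection) and `diversity`
#' (distance matrix, neighbor-joining tree, group summary). Stage inputs
#' are checked before execution; a stage whose input artifact is neither
#' produced by an enabled earlier stage nor supplied as a file fails the
#' pre-flight check by name. Rerunning with an identical config rewrites
#' byte-identical tabular outputs.
#'
#' @param config a config list (see [default_config]) or the path of a
#'   YAML file holding one.
#' @return invisibly, the run manifest (also written as
#'   `manifest.json`): config hash, seed, package version, per-stage
#'   record counts and output files.
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  stages <- cfg$stages
  bad <- setdiff(stages, .STAGES)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))

  ## pre-flight dependency check
  if ("genotypes" %in% stages && !"simulate" %in% stages &&
      is.null(cfg$matrix_file))
    stop("pre-flight: genotypes stage needs a marker genotype matrix ",
         "(markers): enable simulate or set matrix_file")
  for (st in c("stats", "projection"))
    if (st %in% stages && !any(c("genotypes") %in% stages))
      stop("pre-flight: ", st, " stage needs the genotypes stage ",
           "(marker genotype matrix with markers)")
  if ("projection" %in% stages && !"simulate" %in% stages &&
      is.null(cfg$variants_file))
    stop("pre-flight: projection stage needs panel variants: enable ",
         "simulate or set variants_file")
  if ("design" %in% stages && !"simulate" %in% stages)
    stop("pre-flight: design stage needs simulated parental variants: ",
         "enable simulate")
  if ("diversity" %in% stages && !"projection" %in% stages)
    stop("pre-flight: diversity stage needs the projection stage")

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(cfg[setdiff(names(cfg), "out_dir")])
  seed <- cfg$seed
  out <- function(f) file.path(cfg$out_dir, f)
  wt <- function(df, f, sep = "\t") .write_tabular(df, out(f), hash, seed, sep)
  manifest <- list(config_hash = hash, seed = seed,
                   package = as.character(utils::packageVersion("introgressr")),
                   stages = list())
  counts <- function(...) list(...)

  mat <- NULL; design_tab <- NULL; panel_variants <- NULL
  sel <- cfg$selection
  if (!is.null(sel) && !is.data.frame(sel))
    sel <- as.data.frame(sel, stringsAsFactors = FALSE)

  if ("simulate" %in% stages) {
    mat <- simulate_study_matrix(seed = seed, missing_rate = cfg$missing_rate,
                                 error_rate = cfg$error_rate, selection = sel)
    save_matrix(mat, out("marker_matrix.csv"))
    design_tab <- simulate_parental_variants(cfg$n_design_loci,
                                             cfg$violation_rates,
                                             seed = seed + 1000L)
    write_variants_vcf(design_tab, out("design_variants.vcf"),
                       out("design_variants_annotations.tsv"))
    samples <- c("B9008", study_recipients()$id,
                 sprintf("ACC%02d", seq_len(cfg$n_accessions)))
    panel_variants <- simulate_accession_variants(cfg$n_panel_loci, samples,
                                                  seed = seed + 2000L)
    write_variants_vcf(panel_variants, out("panel_variants.vcf"))
    manifest$stages$simulate <- counts(
      lines = nrow(mat$calls), markers = ncol(mat$calls),
      design_loci = nrow(design_tab), panel_loci = nrow(panel_variants))
  }

  markers <- NULL
  if ("design" %in% stages) {
    if (is.null(design_tab))
      stop("pre-flight: design stage needs simulated parental variants")
    cand <- filter_a_genome_diagnostic(design_tab)
    targets <- pmin(cfg$targets,
                    table(factor(cand$chrom, levels = names(cfg$targets))))
    markers <- select_evenly_spaced(cand, stats::setNames(as.integer(targets),
                                                          names(cfg$targets)),
                                    study_map())
    wt(markers, "markers.tsv")
    ds <- distribution_stats(markers, a_genome_chrom_lengths(),
                             map = study_map())
    wt(ds$per_chrom, "marker_distribution.tsv")
    gaps <- find_gaps(markers, study_map(), threshold_cM = 20)
    wt(gaps, "marker_gaps.tsv")
    manifest$stages$design <- counts(candidates = nrow(cand),
                                     markers = nrow(markers),
                                     gaps = nrow(gaps))
  }

  filled <- NULL
  if ("genotypes" %in% stages) {
    if (is.null(mat)) mat <- load_matrix(cfg$matrix_file)
    filled <- fill_missing(mat)
    save_matrix(filled, out("marker_matrix_filled.csv"))
    s <- per_line_summary(mat)
    wt(s$lines, "per_line_summary.tsv")
    wt(s$groups, "group_summary.tsv")
    manifest$stages$genotypes <- counts(
      lines = nrow(mat$calls), markers = ncol(mat$calls),
      calls = length(mat$calls), filled = sum(mat$calls == "D") -
        sum(filled$calls == "D"))
  }

  if ("stats" %in% stages) {
    exp <- expected_segregation(cross_spec(
      c("make_f1", "backcross_to_recipient", "self"), n = 1))
    cn <- genotype_counts(mat)
    st <- segregation_test(cn, exp)
    glob <- data.frame(n_A = cn$n_A, n_B = cn$n_B, n_H = cn$n_H,
                       n_D = cn$n_D, ar_frequency = ar_frequency(cn),
                       donor_coverage = donor_coverage(cn),
                       chisq = st$statistic, df = st$df,
                       p_value = st$p_value)
    wt(glob, "segregation_global.tsv")
    rep <- flag_distorted_markers(mat, exp, alpha = cfg$alpha)
    wt(rep$per_marker, "marker_distortion.tsv")
    manifest$stages$stats <- counts(markers = nrow(rep$per_marker),
                                    sig_below = rep$summary$n_sig_below)
  }

  proj <- NULL
  if ("projection" %in% stages) {
    if (is.null(panel_variants))
      panel_variants <- read_variants_vcf(cfg$variants_file)
    panel <- build_dense_panel(panel_variants, cfg$n_regions,
                               a_genome_chrom_lengths())
    proj <- project_genotypes(filled, panel, donor = "B9008")
    write_projected_matrix(proj, out("projected_genotypes.csv"))
    manifest$stages$projection <- counts(panel_snps = nrow(panel$snps),
                                         samples = nrow(proj$dosage))
  }

  if ("diversity" %in% stages) {
    dd <- ibs_distance(proj)
    write_distance_matrix(dd, out("distances.csv"))
    tree <- neighbor_join(dd)
    ape::write.tree(tree, out("nj_tree.nwk"))
    groups <- ifelse(proj$samples$role == "reference", "reference",
                     proj$samples$recipient)
    names(groups) <- proj$samples$id
    gs <- group_distance_summary(dd, groups)
    wt(gs$within, "diversity_groups.tsv")
    manifest$stages$diversity <- counts(samples = nrow(dd$d),
                                        groups = nrow(gs$within))
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
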