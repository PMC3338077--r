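#' Pipeline configuration
#'
#' Collects the input paths and every tunable threshold of the pipeline.
#' The defaults are the analysis constants of the study design: detection
#' at signal/error >= 3, negative-control floor at mean + 1.5 sd,
#' Bonferroni alpha 0.05, a gain-side association threshold of 1 sample
#' and a loss-side threshold of 2.
#'
#' @param feature_table Path to a feature-table TSV (optional; expression
#'   stages are skipped when absent).
#' @param samples,cnv_calls,mirna_loci Paths to the sample sheet, CNV call
#'   and miRNA locus TSVs; default to the packaged study tables.
#' @param ct_table Optional path to a qPCR Ct TSV.
#' @param cytoband Path to the cytoband reference table.
#' @param out_dir Output directory for stage TSVs and the manifest.
#' @param detection_threshold,offset,negctrl_sd_multiplier,alpha,min_gain,min_loss
#'   Stage thresholds (see the stage functions).
#' @param seed Integer seed for any stochastic step.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(feature_table = NULL,
                            samples = NULL,
                            cnv_calls = NULL,
                            mirna_loci = NULL,
                            ct_table = NULL,
                            cytoband = NULL,
                            out_dir = "mircnv_out",
                            detection_threshold = 3,
                            offset = 1,
                            negctrl_sd_multiplier = 1.5,
                            alpha = 0.05,
                            min_gain = 1L,
                            min_loss = 2L,
                            seed = 1L) {
  cfg <- list(feature_table = feature_table, samples = samples,
              cnv_calls = cnv_calls, mirna_loci = mirna_loci,
              ct_table = ct_table, cytoband = cytoband, out_dir = out_dir,
              detection_threshold = detection_threshold, offset = offset,
              negctrl_sd_multiplier = negctrl_sd_multiplier, alpha = alpha,
              min_gain = as.integer(min_gain), min_loss = as.integer(min_loss),
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' `write_pipeline_config()` followed by `read_pipeline_config()` is the
#' identity.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

write_stage_tsv <- function(x, out_dir, name) {
  utils::write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the integrated pipeline
#'
#' Executes the stages in order: preprocessing (when a feature table is
#' configured), differential expression, presence sets, CNV call parsing,
#' integration, and qPCR quantification (when a Ct table is configured).
#' Writes per-stage TSVs and a JSON manifest (package version, config,
#' seed) into `out_dir`. Deterministic given the configured seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the stage results (`samples`,
#'   `cnv_calls`, `integration`, and when expression input is present
#'   `preprocessed`, `de`, `categories`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  extdata <- function(f) system.file("extdata", f, package = "mircnv")
  path_or_default <- function(p, f) if (is.null(p)) extdata(f) else p

  for (field in c("samples", "cnv_calls", "mirna_loci")) {
    p <- config[[field]]
    if (!is.null(p) && !file.exists(p)) {
      stop("config field '", field, "': file not found: ", p)
    }
  }

  ref <- if (is.null(config$cytoband)) load_cytoband_reference() else
    load_cytoband_reference(config$cytoband)
  fixtures_dir <- dirname(path_or_default(config$samples, "samples.tsv"))

  read_tsv <- function(p) utils::read.table(p, sep = "\t", header = TRUE,
                                            stringsAsFactors = FALSE, quote = "")
  samples <- read_tsv(path_or_default(config$samples, "samples.tsv"))
  calls_tab <- read_tsv(path_or_default(config$cnv_calls, "cnv_calls.tsv"))
  loci <- read_tsv(path_or_default(config$mirna_loci, "mirna_loci.tsv"))
  loci <- loci[!duplicated(loci$mirna_id), ]

  calls <- lapply(stats::setNames(nm = samples$sample_id), function(sid) {
    parse_call_set(calls_tab$call[calls_tab$sample_id == sid], ref = ref)
  })

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(samples = samples, cnv_calls = calls)

  xeno <- samples$sample_id[samples$origin != "control" &
                              as.logical(samples$mirna_profiled)]
  ctrl <- samples$sample_id[samples$origin == "control"]
  categories <- NULL

  if (!is.null(config$feature_table)) {
    if (!file.exists(config$feature_table)) {
      stop("config field 'feature_table': file not found: ",
           config$feature_table)
    }
    ft <- read_tsv(config$feature_table)
    pre <- preprocess_mirna(ft,
                            detection_threshold = config$detection_threshold,
                            offset = config$offset,
                            multiplier = config$negctrl_sd_multiplier)
    expr_samples <- colnames(pre$expression)
    xeno_e <- intersect(xeno, expr_samples)
    ctrl_e <- intersect(ctrl, expr_samples)
    groups <- stats::setNames(ifelse(expr_samples %in% ctrl_e, "control",
                                     "case"), expr_samples)
    de <- moderated_t_test(pre$expression, groups, alpha = config$alpha)
    categories <- expression_categories(pre$detection, de, xeno_e, ctrl_e,
                                        alpha = config$alpha)
    results$preprocessed <- pre
    results$de <- de
    results$categories <- categories
    write_stage_tsv(de, config$out_dir, "differential_expression.tsv")
    write_stage_tsv(data.frame(mirna_id = names(categories),
                               category = unname(categories)),
                    config$out_dir, "expression_categories.tsv")
    expr_out <- data.frame(mirna_id = rownames(pre$expression),
                           pre$expression, check.names = FALSE)
    write_stage_tsv(expr_out, config$out_dir, "expression_matrix.tsv")
  }

  integration <- build_integration_table(
    loci, calls, profiled = xeno, categories = categories, ref = ref,
    min_gain = config$min_gain, min_loss = config$min_loss)
  results$integration <- integration
  write_stage_tsv(integration, config$out_dir, "integration.tsv")
  write_stage_tsv(calls_to_bed(calls, ref), config$out_dir, "cnv_calls.bed")

  if (!is.null(config$ct_table)) {
    cts <- read_tsv(config$ct_table)
    targets <- setdiff(unique(cts$target), "U6")
    rq <- do.call(rbind, lapply(targets, function(tg) {
      r <- relative_quantification(cts, tg, sample_group = xeno,
                                   calibrator_group = ctrl)
      data.frame(target = tg, delta_delta_ct = r$delta_delta_ct, rq = r$rq,
                 stringsAsFactors = FALSE)
    }))
    results$qpcr <- rq
    write_stage_tsv(rq, config$out_dir, "qpcr_rq.tsv")
  }

  manifest <- list(package = "mircnv",
                   version = as.character(utils::packageVersion("mircnv")),
                   seed = config$seed,
                   config = unclass(config),
                   fixtures_dir = fixtures_dir,
                   n_samples = nrow(samples),
                   n_integration_records = nrow(integration))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(results)
}

#' Hierarchical clustering of sample profiles with Newick export
#'
#' Clusters the columns of a matrix with the chosen distance
#' (1 - Pearson correlation, the conventional expression-profile distance,
#' or Euclidean) and linkage, with deterministic tie-breaking by ordering
#' columns by name. Constant columns have undefined correlation; their
#' correlation distance is set to the maximum (1) with a warning.
#'
#' @param mat Numeric matrix with >= 2 named columns.
#' @param distance "one_minus_pearson" (default) or "euclidean".
#' @param linkage "average" (default) or "complete".
#' @return List with `hclust` (the tree) and `newick` (the dendrogram as a
#'   Newick string with branch lengths).
#' @export
hierarchical_cluster <- function(mat,
                                 distance = c("one_minus_pearson", "euclidean"),
                                 linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(mat), ncol(mat) >= 2L, !is.null(colnames(mat)))
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  d <- if (distance == "euclidean") {
    stats::dist(t(mat))
  } else {
    constant <- apply(mat, 2L, stats::sd) == 0
    cc <- suppressWarnings(stats::cor(mat))
    if (any(constant)) {
      warning("constant profile column(s): correlation distance set to 1 for ",
              paste(colnames(mat)[constant], collapse = ", "))
      cc[constant, ] <- 0
      cc[, constant] <- 0
      diag(cc) <- 1
    }
    stats::as.dist(1 - cc)
  }
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)))
}
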