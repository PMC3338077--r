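#' Detection call from total gene signal and error
#'
#' A probe is called detected on an array when its total gene signal divided
#' by its total gene error reaches the detection threshold; ratios under the
#' threshold are undetected. The conventional threshold is 3, and the
#' boundary ratio of exactly 3 counts as detected.
#'
#' @param signal Non-negative numeric vector of total gene signals.
#' @param error Positive numeric vector of total gene errors.
#' @param threshold Detection threshold on the signal/error ratio.
#' @return Logical vector.
#' @export
detection_call <- function(signal, error, threshold = 3) {
  if (any(error <= 0)) {
    bad <- which(error <= 0)[1L]
    stop("invalid measurement: non-positive total gene error at position ", bad)
  }
  signal / error >= threshold
}

ft_matrix <- function(feature_table, value_col) {
  probes <- sort(unique(feature_table$probe_id))
  samples <- sort(unique(feature_table$sample_id))
  m <- matrix(NA_real_, nrow = length(probes), ncol = length(samples),
              dimnames = list(probes, samples))
  m[cbind(match(feature_table$probe_id, probes),
          match(feature_table$sample_id, samples))] <- feature_table[[value_col]]
  if (anyNA(m)) stop("feature table is not complete: every sample must ",
                     "measure every probe exactly once")
  m
}

check_feature_table <- function(feature_table) {
  need <- c("sample_id", "probe_id", "total_gene_signal", "total_gene_error",
            "is_control_probe", "is_negative_control")
  if (!all(need %in% names(feature_table))) {
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(feature_table[c("sample_id", "probe_id")])) {
    stop("duplicated (sample_id, probe_id) pairs in feature table")
  }
  invisible(feature_table)
}

#' Detection matrix for a feature table
#'
#' @param feature_table Long-format feature table (see
#'   [simulate_mirna_arrays()] for the column contract).
#' @param threshold Detection threshold on signal/error.
#' @return Logical probe x sample matrix with attribute
#'   `detection_threshold`.
#' @export
detection_matrix <- function(feature_table, threshold = 3) {
  check_feature_table(feature_table)
  sig <- ft_matrix(feature_table, "total_gene_signal")
  err <- ft_matrix(feature_table, "total_gene_error")
  if (any(err <= 0)) {
    i <- which(err <= 0, arr.ind = TRUE)[1L, ]
    stop("invalid measurement: non-positive total gene error for probe ",
         rownames(err)[i[1L]], " in sample ", colnames(err)[i[2L]])
  }
  d <- sig / err >= threshold
  attr(d, "detection_threshold") <- threshold
  d
}

#' Quantile-normalize a value matrix across arrays
#'
#' Replaces each array's sorted values by the mean of the sorted values over
#' all arrays; tied values receive the mean of the reference values at their
#' ranks. After normalization the sorted value vectors of all arrays are
#' identical.
#'
#' @param mat Numeric matrix, rows = probes, columns = arrays.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 1L)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Offset, log2-transform, and quantile-normalize signals
#'
#' Computes `log2(total_gene_signal + offset)` per probe and array, then
#' quantile-normalizes between all arrays. All probes present in the
#' feature table (including control probes) enter normalization, so that
#' negative-control summary statistics are available on the normalized
#' scale for expression filtering.
#'
#' @param feature_table Long-format feature table.
#' @param offset Positive offset added to signals before log2; stabilizes
#'   zeros.
#' @return Numeric probe x sample matrix of normalized log2 expression with
#'   attribute `offset`.
#' @export
normalize_expression <- function(feature_table, offset = 1) {
  check_feature_table(feature_table)
  sig <- ft_matrix(feature_table, "total_gene_signal")
  if (offset <= 0 && any(sig <= 0)) {
    stop("offset must be positive when zero signals are present")
  }
  expr <- quantile_normalize(log2(sig + offset))
  attr(expr, "offset") <- offset
  expr
}

#' Negative-control summary statistics per array
#'
#' @param expr Normalized log2 expression matrix (all probes).
#' @param negctrl_probes Character vector of negative-control probe ids.
#' @param center `"mean"` (default) or `"median"` summary of the
#'   negative-control distribution.
#' @param multiplier SD multiplier for the expression floor.
#' @return Data frame per array: `sample_id`, `center`, `sd`, `floor`
#'   (= center + multiplier * sd).
#' @export
negctrl_stats <- function(expr, negctrl_probes, center = c("mean", "median"),
                          multiplier = 1.5) {
  center <- match.arg(center)
  negctrl_probes <- intersect(negctrl_probes, rownames(expr))
  if (!length(negctrl_probes)) {
    stop("no negative-control probes present; cannot compute expression floor")
  }
  neg <- expr[negctrl_probes, , drop = FALSE]
  ctr <- apply(neg, 2L, if (center == "mean") mean else stats::median)
  sds <- apply(neg, 2L, stats::sd)
  data.frame(sample_id = colnames(expr), center = ctr, sd = sds,
             floor = ctr + multiplier * sds, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Filter probes to the analyzable miRNA set
#'
#' Removes, in order: (i) control probes (including negative controls),
#' (ii) miRNAs not detected in any sample, and (iii) miRNAs whose
#' normalized expression never exceeds the per-array negative-control floor
#' (center + multiplier * sd of negative-control expression) on any array.
#'
#' @param feature_table Long-format feature table (source of the control
#'   flags).
#' @param detections Logical detection matrix over all probes (from
#'   [detection_matrix()] on the same table).
#' @param expr Normalized log2 expression over all probes (from
#'   [normalize_expression()] on the same table).
#' @param multiplier Negative-control SD multiplier (default 1.5).
#' @param center Negative-control summary statistic ("mean" or "median").
#' @return Character vector of kept probe ids (a subset of the input
#'   probes; applying the filter to an already-filtered universe is
#'   idempotent).
#' @export
filter_probes <- function(feature_table, detections, expr,
                          multiplier = 1.5, center = c("mean", "median")) {
  center <- match.arg(center)
  check_feature_table(feature_table)
  flags <- unique(feature_table[c("probe_id", "is_control_probe",
                                  "is_negative_control")])
  is_ctrl <- flags$is_control_probe | flags$is_negative_control
  negctrl_probes <- flags$probe_id[flags$is_negative_control]
  ns <- negctrl_stats(expr, negctrl_probes, center = center,
                      multiplier = multiplier)
  floor_by_sample <- ns$floor[match(colnames(expr), ns$sample_id)]

  candidates <- flags$probe_id[!is_ctrl]
  candidates <- intersect(rownames(expr), candidates)
  detected_any <- rowSums(detections[candidates, , drop = FALSE]) > 0L
  above_floor <- rowSums(sweep(expr[candidates, , drop = FALSE], 2L,
                               floor_by_sample, `>`)) > 0L
  candidates[detected_any & above_floor]
}

#' Full preprocessing of a raw feature table
#'
#' Runs the preprocessing stack in its canonical order: detection calls on
#' raw signal/error ratios, offset + log2 + quantile normalization, then
#' probe filtering (control removal, never-detected removal,
#' negative-control expression floor).
#'
#' @inheritParams filter_probes
#' @param detection_threshold Signal/error detection threshold.
#' @param offset Positive offset added before log2.
#' @return List with `expression` (filtered normalized matrix), `detection`
#'   (filtered detection matrix), `kept_probes`, `negctrl` (per-array
#'   negative-control statistics), and the thresholds used.
#' @export
preprocess_mirna <- function(feature_table, detection_threshold = 3,
                             offset = 1, multiplier = 1.5,
                             center = c("mean", "median")) {
  center <- match.arg(center)
  det <- detection_matrix(feature_table, threshold = detection_threshold)
  expr <- normalize_expression(feature_table, offset = offset)
  kept <- filter_probes(feature_table, det, expr, multiplier = multiplier,
                        center = center)
  flags <- unique(feature_table[c("probe_id", "is_negative_control")])
  ns <- negctrl_stats(expr, flags$probe_id[flags$is_negative_control],
                      center = center, multiplier = multiplier)
  list(expression = expr[kept, , drop = FALSE],
       detection = det[kept, , drop = FALSE],
       kept_probes = kept,
       negctrl = ns,
       detection_threshold = detection_threshold,
       offset = offset,
       multiplier = multiplier)
}
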