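#' Count gain/loss/neutral samples at a miRNA locus
#'
#' For every profiled sample, the locus band is `gain` when any gain
#' interval in the sample's call set covers it, `loss` when any loss
#' interval covers it, and `neutral` otherwise (including samples with no
#' calls at all: copy-number status is defined relative to the call set, an
#' uncalled region is "no change"). A sample whose gain and loss calls both
#' cover the locus is counted neutral with a warning (the locus is
#' unresolved there). A profiled sample missing from the call map is
#' treated as neutral with a warning.
#'
#' @param locus_band Band query such as "9p21.3".
#' @param calls Named list: sample_id -> list of `cnv_interval`.
#' @param profiled Character vector of profiled sample ids to count over.
#' @param ref A `cytoband_ref`.
#' @return Named integer vector `c(gain_count=, loss_count=, neutral_count=)`
#'   summing to `length(profiled)`.
#' @export
count_status <- function(locus_band, calls, profiled,
                         ref = load_cytoband_reference()) {
  if (!length(profiled)) stop("profiled sample list must be non-empty")
  gain <- loss <- 0L
  missing <- setdiff(profiled, names(calls))
  if (length(missing)) {
    warning("no call set for sample(s) ", paste(missing, collapse = ", "),
            "; treated as neutral")
  }
  for (s in profiled) {
    cs <- calls[[s]]
    if (is.null(cs) || !length(cs)) next
    covering <- vapply(cs, contains_band, logical(1), band = locus_band,
                       ref = ref)
    dirs <- unique(vapply(cs[covering], `[[`, character(1), "direction"))
    if (length(dirs) == 2L) {
      warning("sample ", s, ": gain and loss both cover ", locus_band,
              "; counted neutral")
    } else if (identical(dirs, "gain")) {
      gain <- gain + 1L
    } else if (identical(dirs, "loss")) {
      loss <- loss + 1L
    }
  }
  c(gain_count = gain, loss_count = loss,
    neutral_count = length(profiled) - gain - loss)
}

#' Classify the expression/copy-number association of one record
#'
#' `overexpressed_in_gain` when the miRNA is exclusively expressed in
#' xenografts or significantly over-expressed and its locus is gained in at
#' least `min_gain` profiled samples; `underexpressed_in_loss` when it is
#' exclusive to controls or significantly under-expressed and its locus is
#' lost in at least `min_loss` samples; `none` otherwise. The defaults
#' mirror the narrative thresholds of the study design: a single gained
#' passage suffices on the gain side, at least two lost passages on the
#' loss side.
#'
#' @param record One-row data frame or list with `expression_category`,
#'   `gain_count`, `loss_count`.
#' @param min_gain Minimum gained samples for the gain-side association.
#' @param min_loss Minimum lost samples for the loss-side association.
#' @return One of "overexpressed_in_gain", "underexpressed_in_loss",
#'   "none".
#' @export
classify_association <- function(record, min_gain = 1L, min_loss = 2L) {
  cat_up <- record$expression_category %in% c("exclusive_xeno", "over")
  cat_down <- record$expression_category %in% c("exclusive_control", "under")
  if (cat_up && record$gain_count >= min_gain) return("overexpressed_in_gain")
  if (cat_down && record$loss_count >= min_loss) return("underexpressed_in_loss")
  "none"
}

#' Build the per-locus integration table
#'
#' The core joint analysis: one record per miRNA locus giving the number of
#' profiled samples whose copy-number call set shows a gain, a loss, or no
#' change at the locus band, the miRNA's expression category, the resulting
#' association call, and (when a control detection matrix is supplied) the
#' number of control samples in which the miRNA is detected.
#'
#' @param loci Data frame with columns `mirna_id`, `cytoband` (unique
#'   `mirna_id`); an optional `expression_category` column is used when
#'   `categories` is `NULL`.
#' @param calls Named list: sample_id -> list of `cnv_interval`.
#' @param profiled Character vector of profiled sample ids.
#' @param categories Optional named character vector miRNA ->
#'   expression category (`exclusive_xeno`, `exclusive_control`, `over`,
#'   `under`, `other`); loci absent from it get `other`.
#' @param control_detections Optional logical detection matrix restricted
#'   to the control samples, used for `control_detected_count` (NA when
#'   absent).
#' @param ref A `cytoband_ref`.
#' @param min_gain,min_loss Association thresholds, see
#'   [classify_association()].
#' @return Data frame sorted by chromosome then band: `mirna_id`,
#'   `cytoband`, `gain_count`, `loss_count`, `neutral_count`, `n_profiled`,
#'   `expression_category`, `association`, `control_detected_count`.
#' @export
build_integration_table <- function(loci, calls, profiled, categories = NULL,
                                    control_detections = NULL,
                                    ref = load_cytoband_reference(),
                                    min_gain = 1L, min_loss = 2L) {
  stopifnot(is.data.frame(loci),
            all(c("mirna_id", "cytoband") %in% names(loci)))
  if (anyDuplicated(loci$mirna_id)) {
    stop("duplicate mirna_id in loci table")
  }
  if (!nrow(loci)) {
    return(data.frame(mirna_id = character(0), cytoband = character(0),
                      gain_count = integer(0), loss_count = integer(0),
                      neutral_count = integer(0), n_profiled = integer(0),
                      expression_category = character(0),
                      association = character(0),
                      control_detected_count = integer(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(categories) && "expression_category" %in% names(loci)) {
    categories <- stats::setNames(loci$expression_category, loci$mirna_id)
  }

  recs <- lapply(seq_len(nrow(loci)), function(i) {
    counts <- count_status(loci$cytoband[i], calls, profiled, ref = ref)
    cat_i <- if (!is.null(categories) && loci$mirna_id[i] %in% names(categories)) {
      unname(categories[loci$mirna_id[i]])
    } else "other"
    ctl <- NA_integer_
    if (!is.null(control_detections) &&
        loci$mirna_id[i] %in% rownames(control_detections)) {
      ctl <- sum(control_detections[loci$mirna_id[i], ])
    }
    rec <- data.frame(mirna_id = loci$mirna_id[i],
                      cytoband = loci$cytoband[i],
                      gain_count = counts[["gain_count"]],
                      loss_count = counts[["loss_count"]],
                      neutral_count = counts[["neutral_count"]],
                      n_profiled = length(profiled),
                      expression_category = cat_i,
                      control_detected_count = ctl,
                      stringsAsFactors = FALSE)
    rec$association <- classify_association(rec, min_gain = min_gain,
                                            min_loss = min_loss)
    rec
  })
  out <- do.call(rbind, recs)

  # sort by chromosome, then band position on the reference
  pos <- vapply(seq_len(nrow(out)), function(i) {
    m <- regmatches(out$cytoband[i],
                    regexec("^([0-9]+|[XYxy])([pq].*)$", out$cytoband[i]))[[1L]]
    band_span(ref, m[2L], m[3L])[1L]
  }, numeric(1))
  chrom <- vapply(out$cytoband, function(b) {
    normalize_chrom(regmatches(b, regexec("^([0-9]+|[XYxy])", b))[[1L]][2L])
  }, character(1))
  out <- out[order(match(chrom, attr(ref, "chrom_levels")), pos), ]
  rownames(out) <- NULL
  out[c("mirna_id", "cytoband", "gain_count", "loss_count", "neutral_count",
        "n_profiled", "expression_category", "association",
        "control_detected_count")]
}

#' Derive expression categories from presence sets and DE results
#'
#' Combines the exclusivity calls (detection in all samples of one group,
#' none of the other) with the significant over/under calls of the
#' moderated-t stage. Exclusivity takes precedence: a miRNA exclusive to
#' one group cannot simultaneously be classified over- or under-expressed.
#'
#' @param detections Filtered logical detection matrix.
#' @param de_results Data frame from [moderated_t_test()] (cases =
#'   xenografts, controls = controls).
#' @param xenografts,controls Sample-id vectors.
#' @param alpha Significance level on the q-value.
#' @return Named character vector miRNA -> category (`exclusive_xeno`,
#'   `exclusive_control`, `over`, `under`, `other`).
#' @export
expression_categories <- function(detections, de_results, xenografts,
                                  controls, alpha = 0.05) {
  cats <- stats::setNames(rep("other", nrow(detections)), rownames(detections))
  dir <- classify_direction(de_results, alpha = alpha)
  cats[intersect(dir$over, names(cats))] <- "over"
  cats[intersect(dir$under, names(cats))] <- "under"
  cats[exclusive_set(detections, xenografts, controls)] <- "exclusive_xeno"
  cats[exclusive_set(detections, controls, xenografts)] <- "exclusive_control"
  cats
}
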