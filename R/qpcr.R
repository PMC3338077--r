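#' Relative quantification from a Ct table (2^-ddCt)
#'
#' Computes the relative expression of a target against an endogenous
#' reference (U6 by default): per sample, `dCt = mean(Ct_target) -
#' mean(Ct_reference)` over replicates; per group, the mean of per-sample
#' dCt; then `ddCt = dCt_sample_group - dCt_calibrator_group` and
#' `RQ = 2^-ddCt`.
#'
#' @param cts Data frame with columns `sample_id`, `target`, `replicate`,
#'   `ct` (finite). Duplicated wells appear as distinct replicate rows.
#' @param target Target assay name (e.g. an miRNA id).
#' @param sample_group Character vector of sample ids of the group being
#'   quantified.
#' @param calibrator_group Character vector of calibrator sample ids.
#' @param reference Endogenous control assay name (default "U6").
#' @param ntc_floor Negative-template-control contamination floor: any
#'   sample id in `cts` matching "NTC" with a Ct below this value triggers
#'   a contamination warning.
#' @return List with `target`, `delta_ct_sample`, `delta_ct_calibrator`,
#'   `delta_delta_ct`, and `rq` (= 2^-ddCt exactly).
#' @export
relative_quantification <- function(cts, target, sample_group,
                                    calibrator_group, reference = "U6",
                                    ntc_floor = 35) {
  stopifnot(is.data.frame(cts),
            all(c("sample_id", "target", "ct") %in% names(cts)))
  if (any(!is.finite(cts$ct))) stop("non-finite Ct values in table")

  ntc <- grepl("NTC", cts$sample_id, ignore.case = TRUE)
  if (any(ntc & cts$ct < ntc_floor)) {
    warning("negative-template control amplified below Ct ", ntc_floor,
            "; possible contamination")
  }

  mean_ct <- function(sample, assay) {
    x <- cts$ct[cts$sample_id == sample & cts$target == assay]
    if (!length(x)) {
      stop("no Ct measurements for assay '", assay, "' in sample '",
           sample, "'")
    }
    mean(x)
  }
  delta_ct <- function(group) {
    mean(vapply(group, function(s) mean_ct(s, target) - mean_ct(s, reference),
                numeric(1)))
  }
  d_s <- delta_ct(sample_group)
  d_c <- delta_ct(calibrator_group)
  ddct <- d_s - d_c
  list(target = target, delta_ct_sample = d_s, delta_ct_calibrator = d_c,
       delta_delta_ct = ddct, rq = rq_from_ddct(ddct))
}

#' Closed-form 2^-ddCt conversions
#'
#' @param ddct Delta-delta-Ct value(s).
#' @return `rq_from_ddct`: relative quantity `2^-ddCt`.
#' @export
rq_from_ddct <- function(ddct) 2^(-ddct)

#' @rdname rq_from_ddct
#' @param rq Positive relative quantity.
#' @return `ddct_from_rq`: the delta-delta-Ct `-log2(RQ)`.
#' @export
ddct_from_rq <- function(rq) {
  stopifnot(all(rq > 0))
  -log2(rq)
}
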