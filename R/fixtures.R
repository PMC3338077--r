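#' Load the packaged xenograft study tables
#'
#' Loads the study's sample sheet (six xenograft series from five patients,
#' 34 passages of which 14 were miRNA-profiled, plus two mesenchymal-stem-cell
#' controls), the per-sample aCGH copy-number call sets (series-wide calls
#' expanded to every passage, passage-restricted calls only to theirs), the
#' miRNA locus table used by the integration stage, and the list of 46
#' miRNAs detected in every xenograft sample but in neither control.
#'
#' @param dir Directory containing the fixture TSVs; defaults to the
#'   files installed with the package.
#' @param ref A `cytoband_ref` used to parse the call strings.
#' @return List with components:
#'   \describe{
#'     \item{samples}{data frame: `sample_id`, `series_id`, `patient_id`,
#'       `passage`, `origin`, `mirna_profiled`, `acgh_profiled`.}
#'     \item{cnv_calls}{named list: sample_id -> list of `cnv_interval`
#'       (samples with no calls map to an empty list).}
#'     \item{mirna_loci}{data frame: `mirna_id`, `cytoband`, `direction`,
#'       `reported_count`, `expression_category`, deduplicated on
#'       `mirna_id`.}
#'     \item{xeno_exclusive}{character vector of the 46 xenograft-exclusive
#'       miRNA ids.}
#'   }
#' @export
load_study_fixtures <- function(dir = system.file("extdata", package = "mircnv"),
                                ref = load_cytoband_reference()) {
  need <- c("samples.tsv", "cnv_calls.tsv", "mirna_loci.tsv",
            "xenograft_exclusive_mirnas.tsv")
  paths <- file.path(dir, need)
  missing <- need[!file.exists(paths)]
  if (length(missing)) {
    stop("missing fixture file(s): ", paste(missing, collapse = ", "))
  }
  read_tsv <- function(p) utils::read.table(p, sep = "\t", header = TRUE,
                                            stringsAsFactors = FALSE,
                                            check.names = FALSE, quote = "")
  samples <- read_tsv(paths[1L])
  req_cols <- c("sample_id", "series_id", "passage", "origin", "mirna_profiled")
  if (!all(req_cols %in% names(samples))) {
    stop("corrupt samples fixture: expected columns ",
         paste(req_cols, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in fixtures")
  samples$mirna_profiled <- as.logical(samples$mirna_profiled)
  samples$acgh_profiled <- as.logical(samples$acgh_profiled)

  calls_tab <- read_tsv(paths[2L])
  if (!all(c("sample_id", "call") %in% names(calls_tab))) {
    stop("corrupt cnv_calls fixture")
  }
  unknown <- setdiff(calls_tab$sample_id, samples$sample_id)
  if (length(unknown)) stop("cnv calls for unknown sample(s): ",
                            paste(unknown, collapse = ", "))
  cnv_calls <- lapply(stats::setNames(nm = samples$sample_id), function(sid) {
    parse_call_set(calls_tab$call[calls_tab$sample_id == sid], ref = ref)
  })

  loci <- read_tsv(paths[3L])
  loci <- loci[!duplicated(loci$mirna_id), ]
  rownames(loci) <- NULL

  excl <- read_tsv(paths[4L])$mirna_id

  list(samples = samples, cnv_calls = cnv_calls, mirna_loci = loci,
       xeno_exclusive = excl)
}

#' Sample ids of the miRNA-profiled xenograft passages
#'
#' @param fixtures Output of [load_study_fixtures()].
#' @return Character vector (length 14 on the packaged tables).
#' @export
mirna_profiled_samples <- function(fixtures) {
  s <- fixtures$samples
  s$sample_id[s$mirna_profiled & s$origin != "control"]
}
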