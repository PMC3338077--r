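#' Simulation configuration for synthetic miRNA arrays
#'
#' Describes a synthetic miRNA microarray experiment emulating an
#' Agilent-style feature table: per-probe total gene signal and total gene
#' error for a set of xenograft and control arrays, log-normal signals with
#' group mean shifts for planted differentially expressed miRNAs, a
#' low-signal negative-control probe population, and optional coupling of
#' miRNA expression to copy-number calls.
#'
#' Signals are generated on the log2 scale as
#' `baseline_log2_mean + miRNA-specific baseline + group shift + noise`,
#' where the miRNA-specific baseline has standard deviation
#' `baseline_log2_sd` (spread of expression levels across miRNAs) and the
#' per-measurement noise has standard deviation `noise_log2_sd` (replicate
#' variability of one probe across arrays). Total gene error is
#' `error_cv * signal * e`, `e` log-normal with sdlog 0.2, so expressed
#' probes have signal/error ratios well above the detection threshold of 3
#' at the default `error_cv`. "Off" states (unexpressed miRNAs, planted
#' exclusivity, negative controls) are drawn from a dim distribution with
#' signal/error ratio below 3 on every array.
#'
#' @param n_mirnas Number of miRNA probes (default 866, the size of the
#'   human complement of the emulated array).
#' @param n_negative_controls Number of negative-control probes.
#' @param n_control_probes Number of non-negative control (spike-in style)
#'   probes, removed by filtering.
#' @param group_sizes Named integer vector of array counts per origin;
#'   names from `primary_xenograft`, `metastasis_xenograft`, `control`.
#'   Defaults mirror the study design: 11 primary + 3 metastasis xenograft
#'   passages and 2 stem-cell controls.
#' @param baseline_log2_mean Mean log2 signal of expressed probes.
#' @param baseline_log2_sd SD of per-miRNA baseline levels (log2).
#' @param noise_log2_sd SD of per-measurement noise (log2).
#' @param error_cv Ratio of total gene error to total gene signal for
#'   expressed probes.
#' @param frac_unexpressed Fraction of unplanted miRNAs that are off on
#'   every array (never detected), as on real arrays.
#' @param planted_effects `NULL` or data frame with columns `mirna_id`,
#'   `category` (one of `exclusive_xeno`, `exclusive_control`, `over`,
#'   `under`, `cnv_coupled`), `log2_shift`.
#' @param cnv_coupling `NULL` or data frame with columns `mirna_id`, `call`
#'   (signed cytoband call string; its sign gives the direction),
#'   `n_carriers` (number of xenograft arrays carrying the call), and
#'   `log2_shift` (magnitude of the expression shift in carriers).
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_mirnas = 866,
                       n_negative_controls = 50,
                       n_control_probes = 10,
                       group_sizes = c(primary_xenograft = 11,
                                       metastasis_xenograft = 3,
                                       control = 2),
                       baseline_log2_mean = 8,
                       baseline_log2_sd = 1.5,
                       noise_log2_sd = 0.35,
                       error_cv = 0.1,
                       frac_unexpressed = 0.1,
                       planted_effects = NULL,
                       cnv_coupling = NULL,
                       seed = 1L) {
  cfg <- list(n_mirnas = as.integer(n_mirnas),
              n_negative_controls = as.integer(n_negative_controls),
              n_control_probes = as.integer(n_control_probes),
              group_sizes = group_sizes,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              noise_log2_sd = noise_log2_sd,
              error_cv = error_cv,
              frac_unexpressed = frac_unexpressed,
              planted_effects = planted_effects,
              cnv_coupling = cnv_coupling,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_mirnas < 1L || cfg$n_negative_controls < 1L) {
    stop("n_mirnas and n_negative_controls must be positive")
  }
  if (is.null(names(cfg$group_sizes)) ||
      !all(names(cfg$group_sizes) %in%
           c("primary_xenograft", "metastasis_xenograft", "control"))) {
    stop("group_sizes must be named with valid origins")
  }
  if (any(cfg$group_sizes <= 0)) stop("group_sizes must be positive")
  if (cfg$error_cv <= 0) stop("error_cv must be positive")
  pe <- cfg$planted_effects
  if (!is.null(pe)) {
    stopifnot(is.data.frame(pe),
              all(c("mirna_id", "category", "log2_shift") %in% names(pe)))
    bad <- setdiff(pe$category, c("exclusive_xeno", "exclusive_control",
                                  "over", "under", "cnv_coupled"))
    if (length(bad)) stop("unknown planted categories: ", paste(bad, collapse = ", "))
    if (any(!is.finite(pe$log2_shift))) stop("log2_shift must be finite")
    if (anyDuplicated(pe$mirna_id)) stop("duplicate mirna_id in planted_effects")
  }
  cc <- cfg$cnv_coupling
  if (!is.null(cc)) {
    stopifnot(is.data.frame(cc),
              all(c("mirna_id", "call", "n_carriers", "log2_shift") %in% names(cc)))
  }
  invisible(cfg)
}

#' Simulated miRNA probe ids
#'
#' @param n Number of probes.
#' @return Character vector `mirna_0001` ...
#' @export
sim_mirna_ids <- function(n) sprintf("mirna_%04d", seq_len(n))

sim_sample_ids <- function(group_sizes) {
  unlist(lapply(names(group_sizes), function(g) {
    prefix <- switch(g, primary_xenograft = "xeno_pri",
                     metastasis_xenograft = "xeno_met", control = "control")
    sprintf("%s_%02d", prefix, seq_len(group_sizes[[g]]))
  }))
}

sim_sample_origins <- function(group_sizes) {
  rep(names(group_sizes), times = group_sizes)
}

# One draw of the dim "off" state: low signal with signal/error ratio < 3.
draw_off_state <- function(n) {
  signal <- 2^stats::rnorm(n, mean = 2, sd = 0.5)
  error <- signal / (1 + stats::runif(n, 0, 1))   # ratio in (1, 2), always < 3
  list(signal = signal, error = error)
}

#' Simulate an miRNA array feature table with planted ground truth
#'
#' Emits a long-format Agilent-style feature table (one row per sample and
#' probe: total gene signal, total gene error, control-probe flags) plus the
#' ground truth of every planted effect, for recovery testing of the
#' preprocessing, differential-expression, and presence-set stages.
#' Identical configurations produce identical tables.
#'
#' @param config A [sim_config()].
#' @return List with `feature_table` (data frame: `sample_id`, `probe_id`,
#'   `total_gene_signal`, `total_gene_error`, `is_control_probe`,
#'   `is_negative_control`), `ground_truth` (data frame: `mirna_id`,
#'   `category`, `log2_shift`; unplanted miRNAs carry category `expressed`
#'   or `unexpressed` with shift 0), `samples` (data frame: `sample_id`,
#'   `origin`), and the `config`.
#' @export
simulate_mirna_arrays <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  sample_ids <- sim_sample_ids(config$group_sizes)
  origins <- sim_sample_origins(config$group_sizes)
  is_xeno <- origins != "control"
  n_samp <- length(sample_ids)
  mirna_ids <- sim_mirna_ids(config$n_mirnas)

  pe <- config$planted_effects
  if (!is.null(pe)) {
    unknown <- setdiff(pe$mirna_id, mirna_ids)
    if (length(unknown)) {
      stop("planted_effects references unknown miRNA(s): ",
           paste(unknown, collapse = ", "))
    }
  }

  category <- stats::setNames(rep("expressed", config$n_mirnas), mirna_ids)
  shift <- stats::setNames(rep(0, config$n_mirnas), mirna_ids)
  if (!is.null(pe)) {
    category[pe$mirna_id] <- pe$category
    shift[pe$mirna_id] <- pe$log2_shift
  }
  # a deterministic (seeded) subset of unplanted miRNAs is off everywhere
  free <- mirna_ids[category == "expressed"]
  n_off <- round(config$frac_unexpressed * length(free))
  if (n_off > 0L) category[sample(free, n_off)] <- "unexpressed"

  baseline <- stats::setNames(
    config$baseline_log2_mean +
      stats::rnorm(config$n_mirnas, 0, config$baseline_log2_sd), mirna_ids)

  # per-probe, per-sample "on" indicator
  on <- matrix(TRUE, nrow = config$n_mirnas, ncol = n_samp,
               dimnames = list(mirna_ids, sample_ids))
  on[category == "unexpressed", ] <- FALSE
  on[category == "exclusive_xeno", !is_xeno] <- FALSE
  on[category == "exclusive_control", is_xeno] <- FALSE

  # log2 group shift applied to xenograft samples (case group)
  shift_mat <- matrix(0, nrow = config$n_mirnas, ncol = n_samp,
                      dimnames = list(mirna_ids, sample_ids))
  de <- category %in% c("over", "under", "cnv_coupled")
  shift_mat[de, is_xeno] <- shift[de]

  mu <- baseline + shift_mat
  log2_signal <- mu + matrix(stats::rnorm(config$n_mirnas * n_samp, 0,
                                          config$noise_log2_sd),
                             nrow = config$n_mirnas)
  signal <- 2^log2_signal
  error <- config$error_cv * signal *
    exp(matrix(stats::rnorm(config$n_mirnas * n_samp, 0, 0.2),
               nrow = config$n_mirnas))
  off <- draw_off_state(sum(!on))
  signal[!on] <- off$signal
  error[!on] <- off$error

  ft_mirna <- data.frame(
    sample_id = rep(sample_ids, each = config$n_mirnas),
    probe_id = rep(mirna_ids, times = n_samp),
    total_gene_signal = as.vector(signal),
    total_gene_error = as.vector(error),
    is_control_probe = FALSE,
    is_negative_control = FALSE,
    stringsAsFactors = FALSE)

  neg_ids <- sprintf("negctrl_%03d", seq_len(config$n_negative_controls))
  neg_off <- draw_off_state(config$n_negative_controls * n_samp)
  ft_neg <- data.frame(
    sample_id = rep(sample_ids, each = config$n_negative_controls),
    probe_id = rep(neg_ids, times = n_samp),
    total_gene_signal = neg_off$signal,
    total_gene_error = neg_off$error,
    is_control_probe = TRUE,
    is_negative_control = TRUE,
    stringsAsFactors = FALSE)

  ctl_ids <- sprintf("spikectrl_%03d", seq_len(config$n_control_probes))
  n_ctl <- config$n_control_probes * n_samp
  ctl_signal <- 2^stats::rnorm(n_ctl, mean = 12, sd = 0.3)
  ft_ctl <- data.frame(
    sample_id = rep(sample_ids, each = config$n_control_probes),
    probe_id = rep(ctl_ids, times = n_samp),
    total_gene_signal = ctl_signal,
    total_gene_error = config$error_cv * ctl_signal,
    is_control_probe = TRUE,
    is_negative_control = FALSE,
    stringsAsFactors = FALSE)

  feature_table <- rbind(ft_mirna, ft_neg, ft_ctl)
  feature_table <- feature_table[order(feature_table$sample_id,
                                       feature_table$probe_id), ]
  rownames(feature_table) <- NULL

  ground_truth <- data.frame(mirna_id = mirna_ids,
                             category = unname(category),
                             log2_shift = unname(shift),
                             stringsAsFactors = FALSE)
  ground_truth$log2_shift[!ground_truth$category %in%
                            c("over", "under", "cnv_coupled")] <- 0

  list(feature_table = feature_table,
       ground_truth = ground_truth,
       samples = data.frame(sample_id = sample_ids, origin = origins,
                            stringsAsFactors = FALSE),
       config = config)
}

#' Simulate expression coupled to copy-number calls
#'
#' Extends [simulate_mirna_arrays()]: for every row of the configuration's
#' `cnv_coupling` table, a seeded random subset of `n_carriers` xenograft
#' samples is assigned the stated copy-number call, and the coupled miRNA's
#' signal is shifted by `log2_shift` in the call's direction (up for a gain,
#' down for a loss) in exactly those samples. All other miRNAs are
#' unaffected. The emitted call sets feed the integration stage, which
#' should recover the planted carrier counts exactly.
#'
#' @param config A [sim_config()] with non-empty `cnv_coupling`.
#' @param ref A `cytoband_ref` used to parse the coupled call strings.
#' @return As [simulate_mirna_arrays()], plus `cnv_calls` (named list:
#'   sample_id -> list of `cnv_interval`) and a `coupling` data frame
#'   recording carrier sample ids per coupled miRNA.
#' @export
simulate_cnv_coupled <- function(config, ref = load_cytoband_reference()) {
  stopifnot(inherits(config, "sim_config"))
  cc <- config$cnv_coupling
  if (is.null(cc) || !nrow(cc)) stop("cnv_coupling must be non-empty")
  mirna_ids <- sim_mirna_ids(config$n_mirnas)
  unknown <- setdiff(cc$mirna_id, mirna_ids)
  if (length(unknown)) {
    stop("cnv_coupling references unknown miRNA(s): ",
         paste(unknown, collapse = ", "))
  }

  base <- simulate_mirna_arrays(config)
  sample_ids <- base$samples$sample_id
  xeno_ids <- sample_ids[base$samples$origin != "control"]
  calls <- lapply(stats::setNames(nm = sample_ids), function(s) list())
  coupling <- vector("list", nrow(cc))

  # carrier assignment and signal shifts continue the seeded RNG stream
  for (i in seq_len(nrow(cc))) {
    iv <- parse_call(cc$call[i], ref = ref)
    if (cc$n_carriers[i] > length(xeno_ids)) {
      stop("n_carriers exceeds the number of xenograft samples")
    }
    carriers <- sort(sample(xeno_ids, cc$n_carriers[i]))
    for (s in carriers) calls[[s]] <- c(calls[[s]], list(iv))
    sgn <- if (iv$direction == "gain") 1 else -1
    rows <- base$feature_table$probe_id == cc$mirna_id[i] &
      base$feature_table$sample_id %in% carriers
    fac <- 2^(sgn * abs(cc$log2_shift[i]))
    base$feature_table$total_gene_signal[rows] <-
      base$feature_table$total_gene_signal[rows] * fac
    base$feature_table$total_gene_error[rows] <-
      base$feature_table$total_gene_error[rows] * fac
    coupling[[i]] <- data.frame(mirna_id = cc$mirna_id[i],
                                call = format(iv),
                                carriers = paste(carriers, collapse = ","),
                                stringsAsFactors = FALSE)
    base$ground_truth$category[base$ground_truth$mirna_id == cc$mirna_id[i]] <-
      "cnv_coupled"
    base$ground_truth$log2_shift[base$ground_truth$mirna_id == cc$mirna_id[i]] <-
      sgn * abs(cc$log2_shift[i])
  }

  base$cnv_calls <- calls
  base$coupling <- do.call(rbind, coupling)
  base
}
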