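#' Inverse of the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration on the
#' asymptotically linearized problem, as needed by the moment-matching
#' estimator of the variance prior.
#'
#' @param y Positive numeric vector.
#' @return Numeric vector `x` with `trigamma(x) = y` to near machine
#'   precision.
#' @export
trigamma_inverse <- function(y) {
  stopifnot(all(is.finite(y)))
  x <- ifelse(y > 1e7, 1 / sqrt(y), 0.5 + 1 / y)
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

#' Estimate the hierarchical variance prior
#'
#' Fits the empirical-Bayes model in which each miRNA's true variance is
#' drawn from a scaled inverse chi-square prior with `d0` degrees of
#' freedom and scale `s0_sq`, by moment-matching the log sample variances:
#' the excess spread of `log(s^2)` beyond its expected chi-square sampling
#' variability determines `d0` (via the trigamma inverse), and the centered
#' mean determines `s0_sq`. If the observed spread does not exceed the
#' sampling expectation, the prior is degenerate: `d0 = Inf` and `s0_sq`
#' equals the mean sample variance (complete shrinkage).
#'
#' @param sample_variances Positive numeric vector of per-miRNA pooled
#'   sample variances (length >= 2). Non-positive values are floored at
#'   1e-12 with a warning.
#' @param residual_dfs Residual degrees of freedom, length 1 or matching
#'   `sample_variances`, all >= 1.
#' @return List with `d0` (prior degrees of freedom, possibly `Inf`) and
#'   `s0_sq` (prior variance).
#' @export
estimate_prior <- function(sample_variances, residual_dfs) {
  stopifnot(length(sample_variances) >= 2L, all(residual_dfs >= 1))
  if (length(residual_dfs) == 1L) {
    residual_dfs <- rep(residual_dfs, length(sample_variances))
  }
  stopifnot(length(residual_dfs) == length(sample_variances))
  if (any(sample_variances <= 0)) {
    warning("non-positive sample variance(s) floored at 1e-12")
    sample_variances <- pmax(sample_variances, 1e-12)
  }
  z <- log(sample_variances)
  e <- z - digamma(residual_dfs / 2) + log(residual_dfs / 2)
  evar <- stats::var(e) - mean(trigamma(residual_dfs / 2))
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s0_sq = mean(sample_variances)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-sample t-tests per miRNA
#'
#' For every row of the expression matrix, computes the pooled two-sample
#' variance, shrinks it toward the hierarchical prior
#' (`s_tilde^2 = (d0 s0^2 + dg sg^2) / (d0 + dg)`), and forms the moderated
#' t-statistic `(mean_case - mean_control) / sqrt(s_tilde^2 (1/n1 + 1/n2))`
#' with two-sided p-values from the t distribution on `d0 + dg` degrees of
#' freedom (standard normal when `d0 = Inf`). With `d0 = 0` (no shrinkage)
#' the statistic is the ordinary pooled two-sample t. Multiplicity is
#' corrected by Bonferroni: `q = min(1, p * m)` over the `m` tested miRNAs.
#'
#' @param expr Numeric miRNA x sample matrix of normalized log2 expression.
#' @param groups Named character vector (or factor) mapping every column of
#'   `expr` to `"case"` or `"control"`; both groups need >= 2 samples.
#' @param params `"estimate"` (default) to estimate the prior from the data
#'   via [estimate_prior()], or a list with components `d0` and `s0_sq`.
#' @param alpha Significance level for direction classification.
#' @return Data frame with one row per miRNA: `mirna_id`,
#'   `log2_fold_change` (case mean minus control mean), `residual_df`,
#'   `sample_variance`, `shrunken_variance`, `moderated_t`, `p_value`,
#'   `q_value`, `direction` ("over"/"under"/"ns"), with attributes `d0` and
#'   `s0_sq`.
#' @export
moderated_t_test <- function(expr, groups, params = "estimate", alpha = 0.05) {
  stopifnot(is.matrix(expr))
  groups <- as.character(groups[colnames(expr)])
  if (anyNA(groups) || !all(groups %in% c("case", "control"))) {
    stop("groups must label every expression column as 'case' or 'control'")
  }
  n1 <- sum(groups == "case")
  n2 <- sum(groups == "control")
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")

  case <- expr[, groups == "case", drop = FALSE]
  ctrl <- expr[, groups == "control", drop = FALSE]
  m1 <- rowMeans(case)
  m2 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1L)
  v2 <- rowSums((ctrl - m2)^2) / (n2 - 1L)
  dg <- n1 + n2 - 2L
  sg_sq <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / dg

  if (identical(params, "estimate")) {
    params <- estimate_prior(sg_sq, dg)
  }
  stopifnot(is.list(params), !is.null(params$d0), !is.null(params$s0_sq))
  d0 <- params$d0
  s0_sq <- params$s0_sq

  s_tilde_sq <- if (is.infinite(d0)) {
    rep(s0_sq, length(sg_sq))
  } else if (d0 == 0) {
    sg_sq
  } else {
    (d0 * s0_sq + dg * sg_sq) / (d0 + dg)
  }

  se <- sqrt(s_tilde_sq * (1 / n1 + 1 / n2))
  lfc <- m1 - m2
  tstat <- lfc / se
  degenerate <- s_tilde_sq <= 0
  if (any(degenerate)) {
    warning(sum(degenerate), " miRNA(s) constant in both groups; t set to 0")
    tstat[degenerate] <- 0
  }
  df_total <- d0 + dg
  p <- if (is.infinite(df_total)) {
    2 * stats::pnorm(-abs(tstat))
  } else {
    2 * stats::pt(-abs(tstat), df = df_total)
  }
  p[degenerate] <- 1
  q <- stats::p.adjust(p, method = "bonferroni")

  direction <- rep("ns", length(p))
  direction[q < alpha & lfc > 0] <- "over"
  direction[q < alpha & lfc < 0] <- "under"

  out <- data.frame(mirna_id = rownames(expr),
                    log2_fold_change = lfc,
                    residual_df = dg,
                    sample_variance = sg_sq,
                    shrunken_variance = s_tilde_sq,
                    moderated_t = tstat,
                    p_value = p,
                    q_value = q,
                    direction = direction,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Partition differential-expression results by direction
#'
#' @param results Data frame from [moderated_t_test()].
#' @param alpha Significance level on the Bonferroni q-value.
#' @return List with character vectors `over`, `under`, `ns` of miRNA ids.
#' @export
classify_direction <- function(results, alpha = 0.05) {
  sig <- results$q_value < alpha
  list(over = results$mirna_id[sig & results$log2_fold_change > 0],
       under = results$mirna_id[sig & results$log2_fold_change < 0],
       ns = results$mirna_id[!(sig & results$log2_fold_change != 0)])
}
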