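#' Group-level presence status of each miRNA
#'
#' A miRNA is `present_in_all` when detected in every sample of the group,
#' `absent_in_all` when detected in none, and `mixed` otherwise.
#'
#' @param detections Logical miRNA x sample detection matrix.
#' @param group Character vector of sample ids (columns of `detections`).
#' @return Named character vector (miRNA -> status).
#' @export
group_status <- function(detections, group) {
  if (!length(group)) stop("group must be non-empty")
  missing <- setdiff(group, colnames(detections))
  if (length(missing)) {
    stop("unknown sample(s) in group: ", paste(missing, collapse = ", "))
  }
  d <- detections[, group, drop = FALSE]
  n_det <- rowSums(d)
  status <- rep("mixed", nrow(d))
  status[n_det == ncol(d)] <- "present_in_all"
  status[n_det == 0L] <- "absent_in_all"
  stats::setNames(status, rownames(d))
}

#' miRNAs exclusive to one sample group
#'
#' Returns the miRNAs detected in every sample of `group_a` and in no
#' sample of `group_b`.
#'
#' @param detections Logical detection matrix.
#' @param group_a,group_b Disjoint character vectors of sample ids.
#' @return Character vector of miRNA ids.
#' @export
exclusive_set <- function(detections, group_a, group_b) {
  if (length(intersect(group_a, group_b))) {
    stop("groups must be disjoint")
  }
  sa <- group_status(detections, group_a)
  sb <- group_status(detections, group_b)
  names(sa)[sa == "present_in_all" & sb == "absent_in_all"]
}

#' Three-group presence/absence partition
#'
#' Assigns every miRNA that is `present_in_all` in at least one of three
#' disjoint sample groups to one of the seven regions of the corresponding
#' Venn diagram, according to its per-group status (`present_in_all` = in,
#' `absent_in_all` = out). miRNAs with a `mixed` status in any group are
#' excluded from region assignment and reported separately.
#'
#' @param detections Logical detection matrix.
#' @param groups Named list of exactly three disjoint sample-id vectors.
#' @return Object of class `venn_partition`: list with `regions` (named
#'   list of membership vectors, names like "a", "a+b", "a+b+c" built from
#'   the sorted group names), `counts` (named integer vector), and
#'   `ambiguous` (miRNAs excluded for mixed status).
#' @export
venn_partition <- function(detections, groups) {
  if (length(groups) != 3L || is.null(names(groups)) ||
      anyDuplicated(names(groups))) {
    stop("groups must be a named list of exactly three sample sets")
  }
  ids <- unlist(groups)
  if (anyDuplicated(ids)) stop("groups must be disjoint")

  status <- vapply(groups, function(g) group_status(detections, g),
                   character(nrow(detections)))
  if (!is.matrix(status)) {            # single-miRNA matrices drop dimensions
    status <- matrix(status, nrow = 1L,
                     dimnames = list(rownames(detections), names(groups)))
  }
  present <- status == "present_in_all"
  mixed_any <- apply(status == "mixed", 1L, any)
  eligible <- !mixed_any & rowSums(present) > 0L

  gnames <- sort(names(groups))
  region_names <- unlist(lapply(1:3, function(k)
    utils::combn(gnames, k, paste, collapse = "+", simplify = FALSE)))
  regions <- stats::setNames(vector("list", length(region_names)), region_names)
  for (rn in region_names) regions[[rn]] <- character(0)

  mirnas <- rownames(detections)
  for (i in which(eligible)) {
    key <- paste(sort(names(groups)[present[i, ]]), collapse = "+")
    regions[[key]] <- c(regions[[key]], mirnas[i])
  }
  out <- list(regions = regions,
              counts = vapply(regions, length, integer(1)),
              ambiguous = mirnas[mixed_any & rowSums(present) > 0L])
  class(out) <- "venn_partition"
  out
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("presence/absence partition:\n")
  for (rn in names(x$counts)) cat("  ", rn, ": ", x$counts[[rn]], "\n", sep = "")
  cat("  ambiguous (mixed in some group):", length(x$ambiguous), "\n")
  invisible(x)
}
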