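#' Load an ordered cytoband reference
#'
#' Reads a UCSC-style cytoband table (chrom, start, end, band, stain) and
#' builds an ordered per-chromosome band index used for parsing and
#' containment queries on signed cytoband-interval copy-number calls.
#' The package ships the standard UCSC hg19 `cytoBand` table.
#'
#' @param path Path to a tab-separated cytoband table without header,
#'   columns chrom ("chr1".."chrY"), start, end (0-based half-open), band
#'   name (e.g. "p36.33"), stain. Defaults to the packaged hg19 table.
#' @return An object of class `cytoband_ref`: a data frame with columns
#'   `chrom`, `start`, `end`, `band`, `arm`, sorted by chromosome and
#'   coordinate, plus attribute `chrom_levels`.
#' @export
load_cytoband_reference <- function(path = system.file("extdata", "cytoband_hg19.tsv",
                                                       package = "mircnv")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("cytoband reference file not found: ", path)
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "band", "stain"),
                           stringsAsFactors = FALSE)
  tab$chrom <- sub("^chr", "", tab$chrom)
  tab$arm <- substr(tab$band, 1L, 1L)
  if (!all(tab$arm %in% c("p", "q"))) {
    stop("malformed band names in cytoband reference")
  }
  chrom_levels <- c(as.character(1:22), "X", "Y")
  tab <- tab[tab$chrom %in% chrom_levels, c("chrom", "start", "end", "band", "arm")]
  tab <- tab[order(match(tab$chrom, chrom_levels), tab$start), ]
  rownames(tab) <- NULL
  # sanity: bands tile each chromosome without overlap
  for (chr in unique(tab$chrom)) {
    b <- tab[tab$chrom == chr, ]
    if (any(b$start[-1L] != b$end[-nrow(b)])) {
      stop("cytoband reference bands do not tile chromosome ", chr)
    }
    if (anyDuplicated(b$band)) stop("duplicate band names on chromosome ", chr)
  }
  attr(tab, "chrom_levels") <- chrom_levels
  class(tab) <- c("cytoband_ref", "data.frame")
  tab
}

#' @export
print.cytoband_ref <- function(x, ...) {
  cat("cytoband reference:", length(unique(x$chrom)), "chromosomes,",
      nrow(x), "bands\n")
  invisible(x)
}

normalize_chrom <- function(chrom) {
  chrom <- toupper(trimws(chrom))
  sub("^CHR", "", chrom)
}

#' Resolve a cytoband name to its coordinate span
#'
#' Finds the reference rows covered by `band` on `chrom`. An exact band name
#' matches itself; a band split into sub-bands in the reference (e.g. "17q21")
#' matches all its sub-bands; a band stated at finer precision than the
#' reference falls back to its nearest named ancestor (e.g. "9p21.3" resolves
#' to "9p21" on a 400-band reference).
#'
#' @param ref A `cytoband_ref`.
#' @param chrom Chromosome name ("1".."22", "X", "Y"; "chr" prefix and lower
#'   case tolerated).
#' @param band Band name, e.g. "p21.3".
#' @return Integer vector of row indices into `ref`.
#' @export
resolve_band <- function(ref, chrom, band) {
  chrom <- normalize_chrom(chrom)
  band <- trimws(band)
  rows <- which(ref$chrom == chrom)
  if (!length(rows)) stop("unknown chromosome: ", chrom)
  cand <- band
  repeat {
    hit <- rows[ref$band[rows] == cand]
    if (length(hit)) return(hit)
    # children: reference bands nested under the query band
    hit <- rows[startsWith(ref$band[rows], paste0(cand, "."))]
    if (length(hit)) return(hit)
    # ancestor fallback: strip one level of sub-band precision
    parent <- if (grepl("\\.\\d\\d+$", cand)) {
      substr(cand, 1L, nchar(cand) - 1L)          # q21.32 -> q21.3
    } else if (grepl("\\.\\d$", cand)) {
      substr(cand, 1L, nchar(cand) - 2L)          # q21.3 -> q21
    } else {
      NA_character_
    }
    if (is.na(parent)) {
      stop("band '", band, "' not resolvable on chromosome ", chrom)
    }
    cand <- parent
  }
}

band_span <- function(ref, chrom, band) {
  rows <- resolve_band(ref, chrom, band)
  c(min(ref$start[rows]), max(ref$end[rows]))
}

#' Parse one signed cytoband-interval call
#'
#' Parses call strings as printed in aCGH result tables: a leading `+`/`-`
#' sets the direction, followed by a bare chromosome (`+8`, whole
#' chromosome), a chromosome arm (`-17p`), a single band (`-9p21.3`), or a
#' band range whose endpoints are bands or the arm termini `pter`/`qter`
#' (`+1q21.1-qter`, `-1p13.3-p31.1`). A trailing `(uncontinuous)` marks a
#' discontinuous interval. Ranges are canonicalized to reference
#' (pter-to-qter) order. The ASCII hyphen, Unicode minus, and internal
#' whitespace are tolerated.
#'
#' @param call Call string.
#' @param ref A `cytoband_ref` used to validate band names.
#' @return An object of class `cnv_interval`: list with `direction`
#'   ("gain"/"loss"), `chrom`, `start_band`, `end_band` (band names or
#'   "pter"/"qter"; `NA` for whole chromosome/arm), `arm` (for whole-arm
#'   calls), `scope` ("whole_chromosome", "whole_arm", "single_band",
#'   "band_range"), `discontinuous`, and the original `call` string.
#' @export
parse_call <- function(call, ref = load_cytoband_reference()) {
  stopifnot(is.character(call), length(call) == 1L)
  raw <- call
  s <- gsub("−", "-", trimws(call))   # Unicode minus
  discontinuous <- grepl("\\(uncontinuous\\)", s)
  s <- trimws(sub("\\(uncontinuous\\)", "", s))
  sign <- substr(s, 1L, 1L)
  if (!sign %in% c("+", "-")) {
    stop("call '", raw, "' lacks a leading +/- sign")
  }
  direction <- if (sign == "+") "gain" else "loss"
  body <- gsub("[[:space:]]", "", substring(s, 2L))
  if (!nzchar(body)) stop("empty call body in '", raw, "'")

  m <- regmatches(body, regexec("^([0-9]+|[XYxy])(.*)$", body))[[1L]]
  if (!length(m)) stop("cannot parse chromosome in call '", raw, "'")
  chrom <- normalize_chrom(m[2L])
  rest <- m[3L]
  if (!chrom %in% attr(ref, "chrom_levels")) {
    stop("unknown chromosome '", chrom, "' in call '", raw, "'")
  }

  iv <- list(direction = direction, chrom = chrom, start_band = NA_character_,
             end_band = NA_character_, arm = NA_character_,
             scope = NA_character_, discontinuous = discontinuous, call = raw)
  if (rest == "") {
    iv$scope <- "whole_chromosome"
  } else if (rest %in% c("p", "q")) {
    iv$scope <- "whole_arm"
    iv$arm <- rest
  } else if (grepl("-", rest, fixed = TRUE)) {
    ends <- strsplit(rest, "-", fixed = TRUE)[[1L]]
    if (length(ends) != 2L || !all(nzchar(ends))) {
      stop("cannot parse band range '", rest, "' in call '", raw, "'")
    }
    pos <- vapply(ends, function(tok) {
      if (tok == "pter") return(-Inf)
      if (tok == "qter") return(Inf)
      mean(band_span(ref, chrom, tok))   # validates the band name
    }, numeric(1))
    ord <- order(pos)
    iv$scope <- "band_range"
    iv$start_band <- ends[ord[1L]]
    iv$end_band <- ends[ord[2L]]
  } else {
    band_span(ref, chrom, rest)          # validates
    iv$scope <- "single_band"
    iv$start_band <- rest
    iv$end_band <- rest
  }
  class(iv) <- "cnv_interval"
  iv
}

#' @export
format.cnv_interval <- function(x, ...) {
  sign <- if (x$direction == "gain") "+" else "-"
  body <- switch(x$scope,
    whole_chromosome = x$chrom,
    whole_arm = paste0(x$chrom, x$arm),
    single_band = paste0(x$chrom, x$start_band),
    band_range = paste0(x$chrom, x$start_band, "-", x$end_band)
  )
  paste0(sign, body, if (x$discontinuous) " (uncontinuous)" else "")
}

#' @export
print.cnv_interval <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

interval_span <- function(interval, ref) {
  rows <- which(ref$chrom == interval$chrom)
  chrom_start <- min(ref$start[rows])
  chrom_end <- max(ref$end[rows])
  switch(interval$scope,
    whole_chromosome = c(chrom_start, chrom_end),
    whole_arm = {
      arm_rows <- rows[ref$arm[rows] == interval$arm]
      c(min(ref$start[arm_rows]), max(ref$end[arm_rows]))
    },
    single_band = band_span(ref, interval$chrom, interval$start_band),
    band_range = {
      lo <- if (interval$start_band == "pter") chrom_start else
        band_span(ref, interval$chrom, interval$start_band)[1L]
      hi <- if (interval$end_band == "qter") chrom_end else
        band_span(ref, interval$chrom, interval$end_band)[2L]
      c(lo, hi)
    }
  )
}

#' Test whether a copy-number interval covers a cytoband
#'
#' Returns `TRUE` iff the full coordinate span of `band` lies within the
#' interval's span on the same chromosome. A whole-chromosome call covers
#' every band of the chromosome; a whole-arm call every band of that arm.
#' Discontinuous intervals are treated as covering their full span (the
#' internal gaps are not published in call tables). A band on a different
#' chromosome yields `FALSE`.
#'
#' @param interval A `cnv_interval` (from [parse_call()]).
#' @param band Band query such as "9p21.3" (chromosome + band name).
#' @param ref A `cytoband_ref`.
#' @return Logical scalar.
#' @export
contains_band <- function(interval, band, ref = load_cytoband_reference()) {
  stopifnot(inherits(interval, "cnv_interval"))
  m <- regmatches(band, regexec("^([0-9]+|[XYxy])([pq].*)$", trimws(band)))[[1L]]
  if (!length(m)) stop("cannot parse band query '", band, "'")
  chrom <- normalize_chrom(m[2L])
  if (chrom != interval$chrom) return(FALSE)
  qspan <- band_span(ref, chrom, m[3L])
  ispan <- interval_span(interval, ref)
  qspan[1L] >= ispan[1L] && qspan[2L] <= ispan[2L]
}

#' Parse a set of calls for one sample
#'
#' @param calls Character vector of call strings.
#' @param ref A `cytoband_ref`.
#' @return List of `cnv_interval` objects.
#' @export
parse_call_set <- function(calls, ref = load_cytoband_reference()) {
  lapply(calls, parse_call, ref = ref)
}

#' Flag opposite-direction overlaps within one call set
#'
#' A gain and a loss on the same sample whose spans share a common band are
#' biologically contradictory at the band level; such pairs are flagged so
#' integration counting can treat the locus as unresolved.
#'
#' @param call_set List of `cnv_interval` objects for one sample.
#' @param ref A `cytoband_ref`.
#' @return Data frame with one row per conflicting pair (columns `first`,
#'   `second`, the canonical call strings); zero rows if conflict-free.
#' @export
find_conflicts <- function(call_set, ref = load_cytoband_reference()) {
  out <- data.frame(first = character(0), second = character(0),
                    stringsAsFactors = FALSE)
  n <- length(call_set)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      a <- call_set[[i]]; b <- call_set[[j]]
      if (a$chrom != b$chrom || a$direction == b$direction) next
      sa <- interval_span(a, ref); sb <- interval_span(b, ref)
      if (sa[1L] < sb[2L] && sb[1L] < sa[2L]) {
        out <- rbind(out, data.frame(first = format(a), second = format(b),
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Split a series' calls into always-present and passage-restricted
#'
#' Given the call sets of every profiled passage of one xenograft series,
#' classifies each distinct call (identity = canonical direction + span
#' string) as present in all passages ("always") or only in some
#' ("partial", with the carrying passages attached).
#'
#' @param series_calls Named list: passage label -> list of `cnv_interval`.
#' @return List with `always` (character vector of canonical calls) and
#'   `partial` (data frame `call`, `passages` with comma-separated passage
#'   labels).
#' @export
classify_recurrence <- function(series_calls) {
  stopifnot(length(series_calls) >= 1L)
  per_passage <- lapply(series_calls, function(cs)
    unique(vapply(cs, format, character(1))))
  all_calls <- unique(unlist(per_passage))
  if (!length(all_calls)) {
    return(list(always = character(0),
                partial = data.frame(call = character(0), passages = character(0),
                                     stringsAsFactors = FALSE)))
  }
  in_all <- vapply(all_calls, function(cl)
    all(vapply(per_passage, function(p) cl %in% p, logical(1))), logical(1))
  partial_calls <- all_calls[!in_all]
  partial <- data.frame(
    call = partial_calls,
    passages = vapply(partial_calls, function(cl)
      paste(names(per_passage)[vapply(per_passage, function(p) cl %in% p,
                                      logical(1))], collapse = ","),
      character(1)),
    stringsAsFactors = FALSE)
  rownames(partial) <- NULL
  list(always = unname(all_calls[in_all]), partial = partial)
}

#' Export parsed calls as BED intervals
#'
#' @param calls Named list: sample_id -> list of `cnv_interval`.
#' @param ref A `cytoband_ref`.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `direction` (one row per call), suitable for writing as BED.
#' @export
calls_to_bed <- function(calls, ref = load_cytoband_reference()) {
  rows <- lapply(names(calls), function(sid) {
    ivs <- calls[[sid]]
    if (!length(ivs)) return(NULL)
    do.call(rbind, lapply(ivs, function(iv) {
      sp <- interval_span(iv, ref)
      data.frame(chrom = paste0("chr", iv$chrom), start = sp[1L], end = sp[2L],
                 name = paste0(sid, ":", format(iv)), direction = iv$direction,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      name = character(0), direction = character(0))
  }
  rownames(out) <- NULL
  out
}
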