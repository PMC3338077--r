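ref <- cached_ref()

test_that("call strings of every scope parse to the expected interval", {
  iv <- parse_call("+8", ref)
  expect_equal(iv$direction, "gain")
  expect_equal(iv$chrom, "8")
  expect_equal(iv$scope, "whole_chromosome")

  iv <- parse_call("-17p", ref)
  expect_equal(iv$scope, "whole_arm")
  expect_equal(iv$arm, "p")
  expect_equal(iv$direction, "loss")

  iv <- parse_call("-9p21.3", ref)
  expect_equal(iv$scope, "single_band")
  expect_equal(iv$start_band, "p21.3")

  iv <- parse_call("-2q35-q37.3 (uncontinuous)", ref)
  expect_equal(iv$scope, "band_range")
  expect_true(iv$discontinuous)
  expect_equal(iv$start_band, "q35")
  expect_equal(iv$end_band, "q37.3")

  # p-arm range canonicalized to pter -> qter order
  iv <- parse_call("-1p13.3-p31.1", ref)
  expect_equal(iv$start_band, "p31.1")
  expect_equal(iv$end_band, "p13.3")

  # ter anchors ordered correctly on either arm
  iv <- parse_call("-1p36.12-pter", ref)
  expect_equal(iv$start_band, "pter")
  expect_equal(iv$end_band, "p36.12")
  iv <- parse_call("+1q21.1-qter", ref)
  expect_equal(iv$start_band, "q21.1")
  expect_equal(iv$end_band, "qter")
})

test_that("parser tolerates whitespace, Unicode minus, and lower-case chromosomes", {
  # note the canonical form orders p-arm endpoints pter -> qter
  expect_equal(format(parse_call("- 3p12.3-p24.3", ref)), "-3p24.3-p12.3")
  expect_equal(format(parse_call("−9p21.3", ref)), "-9p21.3")
  expect_equal(parse_call("-xq12-q26.3", ref)$chrom, "X")
})

test_that("malformed calls raise errors naming the offending token", {
  expect_error(parse_call("8q24", ref), "sign")
  expect_error(parse_call("+1q99.9", ref), "q99.9")
  expect_error(parse_call("-25q11", ref), "chromosome")
})

test_that("parse -> format -> parse is stable over every fixture call string", {
  fx <- load_study_fixtures(ref = ref)
  calls <- unique(unlist(lapply(fx$cnv_calls, function(cs)
    vapply(cs, `[[`, character(1), "call"))))
  expect_gt(length(calls), 20)
  for (cl in calls) {
    iv <- parse_call(cl, ref)             # must not error
    canon <- format(iv)
    iv2 <- parse_call(canon, ref)
    expect_equal(format(iv2), canon)
  }
})

test_that("containment answers the band queries the integration stage needs", {
  expect_true(contains_band(parse_call("-9p21.3", ref), "9p21.3", ref))
  expect_true(contains_band(parse_call("-17p", ref), "17p13.3", ref))
  expect_true(contains_band(parse_call("-1p13.3-p31.1", ref), "1p21.3", ref))
  expect_false(contains_band(parse_call("-16q", ref), "9p21.3", ref))
  expect_true(contains_band(parse_call("-Xq12-q26.3", ref), "Xq26.3", ref))
  expect_false(contains_band(parse_call("-17q12-q21.32", ref), "17q11.2", ref))
  expect_true(contains_band(parse_call("+17q21.32-qter", ref), "17q22", ref))
})

test_that("a whole-chromosome call covers every band of that chromosome", {
  iv <- parse_call("+17", ref)
  bands <- ref$band[ref$chrom == "17"]
  for (b in bands) expect_true(contains_band(iv, paste0("17", b), ref))
  expect_false(contains_band(iv, "9p21.3", ref))
})

test_that("containment is monotone under interval widening", {
  nested <- list(parse_call("-9p21.3", ref), parse_call("-9p21.1-p24.3", ref),
                 parse_call("-9p", ref), parse_call("-9", ref))
  queries <- paste0("9", ref$band[ref$chrom == "9"])
  for (q in queries) {
    hits <- vapply(nested, contains_band, logical(1), band = q, ref = ref)
    # once a narrower interval contains the band, all wider ones must too
    expect_true(all(diff(hits) >= 0))
  }
})

test_that("sub-band queries fall back to their nearest named ancestor", {
  # 5q32 is unsplit in the reference; a finer query resolves to it
  expect_identical(resolve_band(ref, "5", "q32.1"), resolve_band(ref, "5", "q32"))
  # a parent query spans all its sub-bands
  rows <- resolve_band(ref, "17", "q21")
  expect_setequal(ref$band[rows], c("q21.1", "q21.2", "q21.31", "q21.32", "q21.33"))
  expect_error(resolve_band(ref, "17", "z9"), "not resolvable")
})

test_that("recurrence classification splits always-present from passage-restricted calls", {
  fx <- load_study_fixtures(ref = ref)
  s455 <- fx$samples$sample_id[fx$samples$series_id == "455"]
  series_calls <- fx$cnv_calls[s455]
  names(series_calls) <- sub("^455-p", "", s455)
  rec <- classify_recurrence(series_calls)
  expect_setequal(rec$always, c("+1q", "-16q", "-9p21.3"))
  expect_setequal(rec$partial$call, c("-13", "-Xq21.1"))
  expect_equal(sort(strsplit(rec$partial$passages[rec$partial$call == "-13"],
                             ",")[[1]]), sort(c("5", "11", "17", "25")))
  expect_equal(rec$partial$passages[rec$partial$call == "-Xq21.1"], "25")

  single <- classify_recurrence(series_calls[1])
  expect_equal(length(single$partial$call), 0L)
  expect_setequal(single$always,
                  vapply(series_calls[[1]], format, character(1)))

  empty <- classify_recurrence(list(p1 = list(), p2 = list()))
  expect_equal(empty$always, character(0))
  expect_equal(nrow(empty$partial), 0L)
})

test_that("opposite-direction overlaps are flagged and fixtures carry none", {
  cs <- parse_call_set(c("+17", "-17q12-q21.32"), ref)
  conf <- find_conflicts(cs, ref)
  expect_equal(nrow(conf), 1L)

  cs2 <- parse_call_set(c("+17", "-16q"), ref)
  expect_equal(nrow(find_conflicts(cs2, ref)), 0L)

  fx <- load_study_fixtures(ref = ref)
  n_conf <- vapply(fx$cnv_calls, function(cs) nrow(find_conflicts(cs, ref)),
                   integer(1))
  expect_true(all(n_conf == 0L))
})

test_that("BED export maps calls to reference coordinates", {
  calls <- list(s1 = parse_call_set(c("-9p21.3", "+8"), ref), s2 = list())
  bed <- calls_to_bed(calls, ref)
  expect_equal(nrow(bed), 2L)
  band9 <- ref[ref$chrom == "9" & ref$band == "p21.3", ]
  expect_equal(bed$start[1], band9$start)
  expect_equal(bed$end[1], band9$end)
  expect_equal(bed$direction, c("loss", "gain"))
})
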