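ref <- cached_ref()

test_that("locus counting over the profiled samples matches the study tables", {
  fx <- load_study_fixtures(ref = ref)
  prof <- mirna_profiled_samples(fx)
  expect_equal(count_status("9p21.3", fx$cnv_calls, prof, ref)[["loss_count"]], 10L)
  expect_equal(count_status("1q24.2", fx$cnv_calls, prof, ref)[["gain_count"]], 6L)
  # chromosome 22 carries no calls at all: everything neutral
  expect_equal(unname(count_status("22q11.21", fx$cnv_calls, prof, ref)),
               c(0L, 0L, 14L))
})

test_that("counts always partition the profiled samples", {
  set.seed(33)
  pool <- c("+8", "-9p21.3", "+1q", "-17p", "-Xq12-q26.3", "+17q21.32-qter")
  samples <- sprintf("s%02d", 1:10)
  for (rep in 1:5) {
    calls <- lapply(stats::setNames(nm = samples), function(s)
      parse_call_set(sample(pool, sample(0:3, 1)), ref))
    for (band in c("9p21.3", "8q24.21", "17q25.3", "Xq26.3")) {
      counts <- count_status(band, calls, samples, ref)
      expect_equal(sum(counts), 10L)
    }
  }
})

test_that("samples missing from the call map count as neutral with a warning", {
  calls <- list(s1 = parse_call_set("-9p21.3", ref))
  expect_warning(counts <- count_status("9p21.3", calls, c("s1", "s2"), ref),
                 "treated as neutral")
  expect_equal(unname(counts), c(0L, 1L, 1L))
})

test_that("a gain/loss conflict at the locus is counted neutral with a warning", {
  calls <- list(s1 = parse_call_set(c("+17", "-17p"), ref))
  expect_warning(counts <- count_status("17p13.3", calls, "s1", ref),
                 "counted neutral")
  expect_equal(sum(counts), 1L)
  expect_equal(counts[["neutral_count"]], 1L)
})

test_that("association classification follows category and count thresholds", {
  rec <- list(expression_category = "exclusive_control", gain_count = 0L,
              loss_count = 10L)
  expect_equal(classify_association(rec), "underexpressed_in_loss")
  rec <- list(expression_category = "exclusive_xeno", gain_count = 1L,
              loss_count = 0L)
  expect_equal(classify_association(rec, min_gain = 1), "overexpressed_in_gain")
  rec <- list(expression_category = "over", gain_count = 0L, loss_count = 0L)
  expect_equal(classify_association(rec), "none")
  # loss side defaults to a two-sample threshold
  rec <- list(expression_category = "under", gain_count = 0L, loss_count = 1L)
  expect_equal(classify_association(rec), "none")
  expect_equal(classify_association(rec, min_loss = 1), "underexpressed_in_loss")
})

test_that("integration table is sorted, complete, and guards duplicates", {
  fx <- load_study_fixtures(ref = ref)
  prof <- mirna_profiled_samples(fx)
  tab <- build_integration_table(fx$mirna_loci, fx$cnv_calls, prof, ref = ref)
  expect_equal(nrow(tab), nrow(fx$mirna_loci))
  expect_true(all(tab$gain_count + tab$loss_count + tab$neutral_count ==
                    tab$n_profiled))
  # sorted by chromosome then band position
  expect_equal(tab$cytoband[1], "1p21.3")
  expect_equal(tab$mirna_id[nrow(tab)], "miR-503")

  dup <- rbind(fx$mirna_loci, fx$mirna_loci[1, ])
  expect_error(build_integration_table(dup, fx$cnv_calls, prof, ref = ref),
               "duplicate")
  empty <- build_integration_table(fx$mirna_loci[0, ], fx$cnv_calls, prof,
                                   ref = ref)
  expect_equal(nrow(empty), 0L)
})

test_that("calls on chromosomes unrelated to every locus change no record", {
  fx <- load_study_fixtures(ref = ref)
  prof <- mirna_profiled_samples(fx)
  before <- build_integration_table(fx$mirna_loci, fx$cnv_calls, prof, ref = ref)
  calls2 <- fx$cnv_calls
  for (s in prof) calls2[[s]] <- c(calls2[[s]], parse_call_set("+21", ref))
  after <- build_integration_table(fx$mirna_loci, calls2, prof, ref = ref)
  expect_equal(before, after)
})

test_that("control detection counts join onto the integration records", {
  fx <- load_study_fixtures(ref = ref)
  prof <- mirna_profiled_samples(fx)
  ctl_det <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2,
                    dimnames = list(c("miR-31", "miR-557"),
                                    c("control_1", "control_2")))
  tab <- build_integration_table(fx$mirna_loci, fx$cnv_calls, prof,
                                 control_detections = ctl_det, ref = ref)
  expect_equal(tab$control_detected_count[tab$mirna_id == "miR-31"], 1L)
  expect_equal(tab$control_detected_count[tab$mirna_id == "miR-557"], 2L)
  expect_true(is.na(tab$control_detected_count[tab$mirna_id == "miR-137"]))
})

test_that("expression categories combine exclusivity and moderated-t calls", {
  det <- make_detections(rbind(
    ex_xeno = c(1, 1, 1, 0, 0),
    ex_ctrl = c(0, 0, 0, 1, 1),
    both = c(1, 1, 1, 1, 1),
    also_both = c(1, 1, 1, 1, 1)))
  colnames(det) <- c("x1", "x2", "x3", "c1", "c2")
  de <- data.frame(mirna_id = rownames(det),
                   log2_fold_change = c(2, -2, 3, -0.1),
                   q_value = c(0.001, 0.001, 0.01, 0.9))
  cats <- expression_categories(det, de, xenografts = c("x1", "x2", "x3"),
                                controls = c("c1", "c2"))
  # exclusivity overrides the significant over/under calls
  expect_equal(unname(cats["ex_xeno"]), "exclusive_xeno")
  expect_equal(unname(cats["ex_ctrl"]), "exclusive_control")
  expect_equal(unname(cats["both"]), "over")
  expect_equal(unname(cats["also_both"]), "other")
})

test_that("planted copy-number coupling is recovered end to end", {
  cc <- data.frame(mirna_id = "mirna_0010", call = "-9p21.3",
                   n_carriers = 10, log2_shift = 2)
  cfg <- sim_config(n_mirnas = 40, cnv_coupling = cc, seed = 77)
  sim <- simulate_cnv_coupled(cfg, ref = ref)
  xeno <- sim$samples$sample_id[sim$samples$origin != "control"]
  counts <- count_status("9p21.3", sim$cnv_calls, xeno, ref)
  expect_equal(counts[["loss_count"]], 10L)
  expect_equal(counts[["gain_count"]], 0L)
})
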