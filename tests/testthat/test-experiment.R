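test_that("condition counts are exact within each epoch", {
  tr <- variant_run("pdp_refined", n_epochs = 2, trials = 999, seed = 61)
  counts <- table(tr$epoch, tr$condition)
  expect_true(all(counts == 333))
})

test_that("the pipeline is a deterministic function of the seed", {
  a <- variant_run("pdp_wm", n_epochs = 2, trials = 300, seed = 62)
  cfg <- experiment_config(model = "pdp_wm", n_epochs = 2,
                           trials_per_epoch = 300, seed = 62)
  b <- run_experiment(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "epoch_mse"), attr(b, "epoch_mse"))
  c2 <- variant_run("pdp_wm", n_epochs = 2, trials = 300, seed = 63)
  expect_false(identical(a$rt, c2$rt))
})

test_that("all three variants produce the Stroop RT ordering", {
  for (m in c("pdp", "pdp_refined", "pdp_wm")) {
    tr <- filter_trials(variant_run(m, n_epochs = 10, trials = 1000,
                                    seed = 1))
    m_rt <- tapply(tr$rt, tr$condition, mean)
    expect_lt(m_rt[["congruent"]], m_rt[["neutral"]])
    expect_lt(m_rt[["congruent"]], m_rt[["incongruent"]])
    # interference (neutral < incongruent) is a near-null contrast in the
    # memoryless variants (the heavily trained neutral-word unit leaks as
    # strongly as a distractor color word); only the delay layer separates it
    if (m == "pdp_wm") expect_lt(m_rt[["neutral"]], m_rt[["incongruent"]])
  }
})

test_that("trial tables carry coherent labels and responses", {
  tr <- variant_run("pdp_wm", n_epochs = 2, trials = 300, seed = 62)
  expect_true(all(tr$condition == stroop_condition(tr$word, tr$ink)))
  ok <- !is.na(tr$rt)
  expect_true(all(tr$correct[ok] == (tr$response[ok] == tr$ink[ok])))
  expect_true(all(tr$pair_label[tr$trial_index == 1 & tr$epoch == 1] ==
                    "other"))
  relab <- pair_label(tr$word[-nrow(tr)], tr$ink[-nrow(tr)],
                      tr$word[-1], tr$ink[-1])
  within_epoch <- tr$epoch[-1] == tr$epoch[-nrow(tr)]
  expect_equal(tr$pair_label[-1][within_epoch], relab[within_epoch])
})

test_that("designed-pair mode yields powered NP cells", {
  tr <- variant_run("pdp_wm", n_epochs = 2, trials = 1200, seed = 64,
                    designed = TRUE)
  counts <- table(tr$pair_label)
  for (l in c("NP-I", "NP-N", "NP-C", "contra-NP-I", "contra-NP-N",
              "contra-NP-C"))
    expect_gt(counts[[l]], 150)
})

test_that("positive priming speeds responses in the PDP-WM model", {
  tr <- variant_run("pdp_wm", n_epochs = 6, trials = 1000, seed = 1)
  rep <- pp_report(tr)
  expect_true(all(rep$pp_mean < rep$base_mean))
  expect_true(all(rep$p < 0.01))
})

test_that("a no-repetition sequence leaves the PP cell empty with a warning", {
  tr <- variant_run("pdp_wm", n_epochs = 2, trials = 1200, seed = 64,
                    designed = TRUE)
  # drop the PP-labeled probes to emulate a design without ink repetitions
  tr2 <- tr[tr$pair_label != "PP", ]
  expect_warning(rep <- pp_report(tr2), "no PP trials")
  expect_true(any(is.na(rep$pp_mean)))
})

test_that("wm_sweep reuses networks across levels and reports contrasts", {
  cfg <- experiment_config(model = "pdp_wm", n_epochs = 1,
                           trials_per_epoch = 600, seed = 65,
                           designed_pairs = TRUE)
  sw <- wm_sweep(cfg, w_delays = c(0, 0.8))
  expect_equal(nrow(sw), 2)
  expect_true(all(c("np_effect", "npi_effect", "npi_p") %in% names(sw)))
  # the same epoch seeds mean the w_delay = 0 level equals a refined run
  cfg0 <- cfg; cfg0$model <- "pdp_refined"
  ref <- run_experiment(cfg0)
  wm0 <- attr(sw, "reports")[[1]]
  ref_np <- summarize_np(ref)
  expect_equal(wm0$subtype$I$groups$mean, ref_np$subtype$I$groups$mean)
})

test_that("wm_sweep rejects non-WM configurations", {
  cfg <- experiment_config(model = "pdp", n_epochs = 1, trials_per_epoch = 10)
  expect_error(wm_sweep(cfg), "pdp_wm")
})
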