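pair_fixture <- function(pred, truth, gene = "A") {
  bench <- truth_as_benchmark(tibble::tibble(
    sample = "S1", gene = gene, allele1 = truth[1], allele2 = truth[2]))
  calls <- tibble::tibble(sample = "S1", tool = "T", gene = gene,
                          allele1 = pred[1], allele2 = pred[2])
  classify_calls(calls, bench, tool = "T")
}

test_that("per-pair classification covers the right/wrong/uncalled cases", {
  id <- pair_fixture(c("A*25:01", "A*02:01"), c("A*25:01", "A*02:01"))
  expect_equal(c(id$right, id$wrong, id$uncalled), c(2L, 0L, 0L))

  mis <- pair_fixture(c("A*26:01", "A*02:01"), c("A*25:01", "A*02:01"))
  expect_equal(c(mis$right, mis$wrong, mis$uncalled), c(1L, 1L, 0L))
  expect_equal(mis$miscalls$truth_allele, "A*25:01")
  expect_equal(mis$miscalls$pred_allele, "A*26:01")

  unc <- pair_fixture(c(NA, NA), c("A*25:01", "A*02:01"))
  expect_equal(c(unc$right, unc$wrong, unc$uncalled), c(0L, 0L, 2L))
  expect_equal(nrow(unc$miscalls), 0L)
})

test_that("swapped order and homozygous calls match as multisets", {
  sw <- pair_fixture(c("A*02:01", "A*25:01"), c("A*25:01", "A*02:01"))
  expect_equal(sw$right, 2L)

  # homozygous prediction against heterozygous truth: one copy right
  hom <- pair_fixture(c("A*02:01", "A*02:01"), c("A*25:01", "A*02:01"))
  expect_equal(c(hom$right, hom$wrong), c(1L, 1L))
  expect_equal(hom$miscalls$truth_allele, "A*25:01")

  # heterozygous prediction against homozygous truth
  het <- pair_fixture(c("A*02:01", "A*03:01"), c("A*02:01", "A*02:01"))
  expect_equal(c(het$right, het$wrong), c(1L, 1L))
})

test_that("a single emitted allele leaves an unpairable miss", {
  one <- pair_fixture(c("A*26:01", NA), c("A*25:01", "A*02:01"))
  expect_equal(c(one$right, one$wrong, one$uncalled), c(0L, 1L, 1L))
  expect_equal(nrow(one$miscalls), 2L)
  # the wrong call pairs with one truth allele, the other miss is unpaired
  expect_equal(sum(!is.na(one$miscalls$pred_allele)), 1L)
})

test_that("low-resolution predictions are wrong, never right or uncalled", {
  lr <- pair_fixture(c("B*58", "B*07:02"), c("B*58:01", "B*07:02"),
                     gene = "B")
  expect_equal(c(lr$right, lr$wrong, lr$uncalled), c(1L, 1L, 0L))
  expect_equal(lr$miscalls$truth_allele, "B*58:01")
  expect_equal(lr$miscalls$pred_allele, "B*58")
})

test_that("miscall pairing prefers shared first fields", {
  d <- pair_fixture(c("C*03:04", "C*07:02"), c("C*03:03", "C*07:01"),
                    gene = "C")
  expect_equal(c(d$right, d$wrong), c(0L, 2L))
  pairs <- d$miscalls
  expect_equal(pairs$pred_allele[pairs$truth_allele == "C*03:03"], "C*03:04")
  expect_equal(pairs$pred_allele[pairs$truth_allele == "C*07:01"], "C*07:02")
  expect_false(any(pairs$ambiguous))
})

test_that("recall and accuracy implement their defining ratios", {
  expect_equal(recall(3, 1), 0.75)
  expect_equal(recall(343, 0), 1)
  expect_equal(recall(343, 57), 0.8575)
  expect_equal(accuracy(3, 1, 1), 0.6)
  expect_equal(accuracy(3, 1, 0), recall(3, 1))
  expect_warning(expect_true(is.na(recall(0, 0))), "undefined")
  expect_warning(expect_true(is.na(accuracy(0, 0, 0))), "undefined")
})

test_that("a tool skipping one of four genes loses accuracy, not recall", {
  genes2 <- c("DRB1", "DPB1", "DQA1", "DQB1")
  n <- 25
  truth <- dplyr::bind_rows(lapply(genes2, function(g) {
    tibble::tibble(sample = sprintf("S%02d", 1:n), gene = g,
                   allele1 = paste0(g, "*01:01"),
                   allele2 = paste0(g, "*04:01"))
  }))
  bench <- truth_as_benchmark(truth)
  calls <- dplyr::mutate(truth[truth$gene != "DQA1", ], tool = "T")
  ev <- evaluate_tool(calls, bench, tool = "T")
  expect_equal(ev$metrics$recall, 1)
  expect_equal(ev$metrics$accuracy, 0.75)
  # restricting the scope to the supported genes restores accuracy
  ev3 <- evaluate_tool(calls, bench, tool = "T",
                       genes = c("DRB1", "DPB1", "DQB1"))
  expect_equal(ev3$metrics$accuracy, 1)
})

test_that("general and specific error rates reproduce a planted fixture", {
  fx <- planted_error_calls("A*25:01", "A*11:01", n_total = 40,
                            wrong_as = c(rep("A*26:01", 30),
                                         rep("A*30:01", 2)),
                            gene = "A")
  ev <- evaluate_tool(fx$pred, truth_as_benchmark(fx$truth), tool = "toolX")
  expect_equal(general_error_rate(ev, "A25:01"), 32 / 40)
  expect_equal(specific_error_rate(ev, "A25:01", "A26:01"), 30 / 32)
  expect_equal(specific_error_rate(ev, "A25:01", "A30:01"), 2 / 32)
  expect_equal(specific_error_rate(ev, "A25:01", "A99:01"), 0)
  expect_equal(general_error_rate(ev, "A11:01"), 0)
  expect_warning(expect_true(is.na(general_error_rate(ev, "B07:02"))),
                 "absent")
  expect_warning(expect_true(is.na(specific_error_rate(ev, "A11:01",
                                                       "A26:01"))),
                 "no miscalls")
})

test_that("percent rendering rounds half-up to two decimals", {
  expect_equal(as_percent(371 / 435), 85.29)
  expect_equal(as_percent(343 / 371), 92.45)
  expect_equal(as_percent(0.5), 50)
  expect_equal(as_percent(0.12345), 12.35)
})

test_that("classification counts equal the brute-force oracle", {
  set.seed(23)
  pool <- sprintf("A*%02d:01", 1:6)
  for (rep in 1:300) {
    truth <- sort(sample(pool, 2, replace = TRUE))
    pred <- random_pred_pair(truth, pool)
    got <- pair_fixture(pred, truth)
    want <- oracle_classify(pred, truth)
    expect_equal(got$right, want$right)
    expect_equal(got$wrong, want$wrong)
    expect_equal(got$uncalled, want$uncalled)
    expect_equal(sort(got$miscalls$truth_allele), sort(want$miscall))
  }
})

test_that("evaluation satisfies its conservation identities on a cohort", {
  cfg <- sim_config(seed = 401, n_samples = 120)
  coh <- simulate_cohort(cfg)
  bench <- build_benchmark(coh$calls)
  n_complete <- sum(bench$benchmark$status == "complete")
  for (tl in c("tool1", "tool5", "tool7")) {
    ev <- evaluate_tool(coh$calls[coh$calls$tool == tl, ], bench, tool = tl)
    cls <- ev$classification
    expect_equal(cls$right + cls$wrong + cls$uncalled, 2L * n_complete)
    expect_gte(min(ev$metrics$recall - ev$metrics$accuracy), 0)
    # general rates in [0,1]; specific rates sum to 1 per miscalled allele
    expect_true(all(ev$general_errors$rate >= 0 &
                      ev$general_errors$rate <= 1))
    sums <- ev$specific_errors |>
      dplyr::group_by(truth_allele) |>
      dplyr::summarise(s = sum(rate), n = sum(count), .groups = "drop")
    paired_totals <- sums$n / sums$s
    miscalls <- ev$general_errors$miscalls[
      match(sums$truth_allele, ev$general_errors$allele)]
    expect_true(all(sums$s <= 1 + 1e-12))
    expect_true(all(paired_totals <= miscalls + 1e-9))
    # total miscalls equal wrong-paired truth slots
    expect_equal(sum(ev$general_errors$miscalls), nrow(cls$miscalls))
  }
})

test_that("evaluating a tool against its own calls is perfect", {
  truth <- random_truth(10)
  calls <- dplyr::mutate(truth, tool = "T")
  ev <- evaluate_tool(calls, truth_as_benchmark(truth), tool = "T")
  expect_equal(ev$metrics$recall, rep(1, nrow(ev$metrics)))
  expect_equal(ev$metrics$accuracy, rep(1, nrow(ev$metrics)))
  expect_equal(sum(ev$general_errors$miscalls), 0L)
})
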