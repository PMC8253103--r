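test_that("CYT is the offset geometric mean of GZMA and PRF1", {
  expect_equal(cyt_score(0, 0), 0.01)
  expect_equal(cyt_score(100, 25), sqrt(100.01 * 25.01))
  expect_equal(cyt_score(100, 25), 50.0125, tolerance = 1e-4)
  expect_equal(cyt_score(7, 7), 7.01)
  expect_equal(cyt_score(3, 80), cyt_score(80, 3))
  expect_error(cyt_score(-1, 5), "nonnegative")
  # strictly monotone in each argument
  expect_true(cyt_score(10, 5) < cyt_score(11, 5))
  expect_true(cyt_score(10, 5) < cyt_score(10, 6))
})

test_that("TMB counts only the nonsynonymous keyword set", {
  expect_equal(tmb_score(c("missense_variant", "synonymous_variant",
                           "stop_gained"), coding_mb = 38), 2 / 38)
  expect_equal(tmb_score(character(0)), 0)
  expect_equal(tmb_score(rep("missense_variant", 76), coding_mb = 38), 2)
  expect_error(tmb_score("missense_variant", coding_mb = 0), "positive")
  expect_length(tmb_keywords(), 13L)
  # linear in the qualifying count
  expect_equal(tmb_score(rep("stop_gained", 10)),
               10 * tmb_score("stop_gained"))
})

test_that("per-sample TMB from a MAF table fills absent samples with zero", {
  maf <- tibble::tibble(
    Tumor_Sample_Barcode = c("P1", "P1", "P1", "P2"),
    One_Consequence = c("missense_variant", "synonymous_variant",
                        "stop_gained", "intron_variant"))
  tm <- tmb_from_maf(maf, coding_mb = 38, samples = c("P1", "P2", "P3"))
  expect_equal(tm$tmb[tm$sample == "P1"], 2 / 38)
  expect_equal(tm$tmb[tm$sample == "P2"], 0)
  expect_equal(tm$tmb[tm$sample == "P3"], 0)
  expect_error(tmb_from_maf(tibble::tibble(Tumor_Sample_Barcode = "P1")),
               "One_Consequence")
})

test_that("median split uses a strict-greater rule with ties going low", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(median_split(c(1, 2, 3))),
               c("low", "low", "high"))
  expect_warning(s <- median_split(c(2, 2, 2)), "degenerate")
  expect_equal(as.character(s), rep("low", 3))
  expect_warning(s2 <- median_split(c(1, 2, 5), c("a", "a", "b")),
                 "fewer than 2")
  expect_true(is.na(s2[3]))
})

test_that("median split is computed within each condition", {
  v <- c(1, 2, 3, 4, 100, 200, 300, 400)
  cond <- rep(c("x", "y"), each = 4)
  s <- median_split(v, cond)
  expect_equal(as.character(s),
               rep(c("low", "low", "high", "high"), 2))
})

test_that("supertype presence follows the map and LOH only demotes", {
  map <- default_supertype_map()
  bench <- truth_as_benchmark(tibble::tibble(
    sample = c("P1", "P1", "P2", "P2", "P3", "P3"),
    gene = rep(c("A", "B"), 3),
    allele1 = c("A*02:01", "B*44:02", "A*01:01", "B*07:02",
                "A*02:01", "B*44:03"),
    allele2 = c("A*03:01", "B*08:01", "A*24:02", "B*35:01",
                "A*02:01", "B*44:02")))
  pres <- supertype_presence(bench, "B44", map)
  expect_equal(as.character(pres$presence[pres$sample == "P1"]), "present")
  expect_equal(as.character(pres$presence[pres$sample == "P2"]), "absent")

  loh <- tibble::tibble(sample = "P1", allele = "B*44:02")
  pres_loh <- supertype_presence(bench, "B44", map, loh = loh)
  expect_equal(as.character(pres_loh$presence[pres_loh$sample == "P1"]),
               "absent")
  # P3 carries two B44 alleles; losing one still leaves presence
  loh3 <- tibble::tibble(sample = "P3", allele = "B*44:03")
  pres3 <- supertype_presence(bench, "B44", map, loh = loh3)
  expect_equal(as.character(pres3$presence[pres3$sample == "P3"]), "present")
  # LOH never promotes an absent sample
  all_loh <- tidyr::crossing(sample = c("P1", "P2", "P3"),
                             allele = unique(c(bench$benchmark$allele1,
                                               bench$benchmark$allele2)))
  pres_all <- supertype_presence(bench, "B44", map, loh = all_loh)
  plain <- supertype_presence(bench, "B44", map)
  expect_true(all(!(pres_all$presence == "present" &
                      plain$presence == "absent")))
  expect_true(all(pres_all$presence == "absent"))
})

test_that("Gun-Bullet labels cross presence with the TMB group", {
  g <- gun_bullet_groups(c("present", "absent", "present", NA),
                         c("high", "low", "low", "high"))
  expect_equal(as.character(g),
               c("present&high", "absent&low", "present&low", NA))
  cts <- gun_bullet_contrasts()
  expect_named(cts, c("presence", "concordant", "discordant"))
  expect_equal(cts$concordant, c("present&high", "absent&low"))
})

test_that("a planted supertype-by-TMB interaction raises CYT where expected", {
  cfg <- sim_config(seed = 601, n_samples = 800)
  coh <- simulate_cohort(cfg)
  lat <- coh$phenotypes$latent
  cell <- gun_bullet_groups(ifelse(lat$strong_present, "present", "absent"),
                            ifelse(lat$tmb_high, "high", "low"))
  hi <- log(lat$cyt[cell == "present&high"])
  lo <- log(lat$cyt[cell == "absent&low"])
  tt <- stats::t.test(hi, lo, alternative = "greater")
  expect_lt(tt$p.value, 0.05)
  expect_gt(mean(hi) - mean(lo), 0.5)
})

test_that("immuno_table assembles consistent per-sample records", {
  cfg <- sim_config(seed = 602, n_samples = 150)
  coh <- simulate_cohort(cfg)
  ph <- coh$phenotypes
  rec <- immuno_table(truth_as_benchmark(coh$truth), ph$expression, ph$maf,
                      ph$clinical, cfg$supertype_map, "B44")
  expect_true(all(rec$cyt >= 0.01))
  expect_true(all(rec$tmb >= 0))
  # group labels are consistent with their inputs
  ok <- !is.na(rec$gun_bullet)
  expect_equal(as.character(rec$gun_bullet[ok]),
               paste0(rec$presence[ok], "&", rec$tmb_group[ok]))
  # recomputed CYT matches the expression matrix
  expect_equal(rec$cyt[match(colnames(ph$expression), rec$sample)],
               unname(cyt_score(ph$expression["GZMA", ],
                                ph$expression["PRF1", ])))
})
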