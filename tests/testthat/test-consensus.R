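one_gene_calls <- function(...) {
  pairs <- list(...)
  tibble::tibble(sample = "S1", tool = paste0("T", seq_along(pairs)),
                 gene = "A",
                 allele1 = vapply(pairs, `[`, character(1), 1),
                 allele2 = vapply(pairs, `[`, character(1), 2))
}

test_that("voting fills both slots from concordant alleles", {
  b <- vote_gene(one_gene_calls(c("A*01:01", "A*02:01"),
                                c("A*01:01", "A*02:01"),
                                c("A*01:01", "A*03:01")))
  expect_equal(b$allele1, "A*01:01")
  expect_equal(b$votes1, 3L)
  expect_equal(b$allele2, "A*02:01")
  expect_equal(b$votes2, 2L)
  expect_equal(b$status, "complete")
  expect_false(b$ambiguous)
})

test_that("homozygous consensus needs two homozygous callers", {
  b <- vote_gene(one_gene_calls(c("A*01:01", "A*01:01"),
                                c("A*01:01", "A*01:01"),
                                c("A*01:01", "A*02:01")))
  expect_equal(b$allele1, "A*01:01")
  expect_equal(b$allele2, "A*01:01")
  expect_equal(b$votes1, 5L)
  expect_equal(b$status, "complete")

  # one homozygous caller plus one heterozygous vote must not fabricate
  # homozygosity: slot 2 stays open
  b2 <- vote_gene(one_gene_calls(c("A*01:01", "A*01:01"),
                                 c("A*01:01", "A*02:01"),
                                 c("A*03:01", "A*04:01")))
  expect_equal(b2$allele1, "A*01:01")
  expect_equal(b2$status, "partial")
})

test_that("no allele reaching two votes leaves the pair unresolved", {
  b <- vote_gene(one_gene_calls(c("A*01:01", "A*02:01"),
                                c("A*03:01", "A*04:01")))
  expect_equal(b$status, "unresolved")
  expect_true(is.na(b$allele1))
})

test_that("a single tool cannot create consensus, even via homozygosity", {
  b <- vote_gene(one_gene_calls(c("A*01:01", "A*01:01")))
  expect_equal(b$status, "unresolved")
})

test_that("exact vote ties are broken lexicographically and flagged", {
  # A*01:01 has 3 votes; A*02:01 and A*03:01 tie at 2 for the last slot
  calls <- tibble::tibble(
    sample = "S1", tool = c("T1", "T2", "T3"), gene = "A",
    allele1 = c("A*01:01", "A*01:01", "A*01:01"),
    allele2 = c("A*02:01", "A*03:01", NA))
  calls2 <- dplyr::bind_rows(calls, tibble::tibble(
    sample = "S1", tool = "T4", gene = "A",
    allele1 = "A*02:01", allele2 = "A*03:01"))
  b <- vote_gene(calls2)
  expect_equal(b$allele2, "A*02:01")
  expect_true(b$ambiguous)
})

test_that("benchmark construction reports per-gene status and rejects duplicates", {
  truth <- random_truth(5, genes = c("A", "B"))
  calls <- agreeing_calls(truth, n_tools = 3)
  bench <- build_benchmark(calls)
  expect_s3_class(bench, "hla_benchmark")
  expect_true(all(bench$benchmark$status == "complete"))
  # heterozygous consensus carries 3 votes per slot, homozygous 6
  expect_true(all(bench$benchmark$votes1 %in% c(3L, 6L)))
  expect_equal(sum(bench$report$complete), 10)

  expect_error(build_benchmark(dplyr::bind_rows(calls, calls[1, ])),
               "duplicate")
})

test_that("a gene reported by a single tool stays unresolved cohort-wide", {
  truth <- random_truth(4, genes = c("A", "B"))
  calls <- agreeing_calls(truth, n_tools = 3)
  calls <- calls[!(calls$gene == "B" & calls$tool != "C1"), ]
  bench <- build_benchmark(calls)
  bdf <- bench$benchmark
  expect_true(all(bdf$status[bdf$gene == "B"] == "unresolved"))
  expect_true(all(bdf$status[bdf$gene == "A"] == "complete"))
})

test_that("allelic vs population counts follow per-copy semantics", {
  bench <- truth_as_benchmark(tibble::tibble(
    sample = c("P1", "P2", "P3", "P4"), gene = "A",
    allele1 = c("A*25:01", "A*25:01", "A*25:01", "A*02:01"),
    allele2 = c("A*26:01", "A*11:01", "A*25:01", "A*03:01")))
  # P1, P2 heterozygous carriers; P3 homozygous
  expect_equal(allele_counts(bench, "A25:01"),
               c(allelic = 4L, population = 3L))
  expect_equal(allele_counts(bench, "A26:01"),
               c(allelic = 1L, population = 1L))
  expect_equal(allele_counts(bench, "A99:01"),
               c(allelic = 0L, population = 0L))
})

test_that("population frequency uses class-level sample denominators", {
  bench <- truth_as_benchmark(tibble::tibble(
    sample = rep(sprintf("P%02d", 1:10), 2),
    gene = rep(c("A", "DRB1"), each = 10),
    allele1 = c(rep("A*02:01", 4), rep("A*01:01", 6), rep("DRB1*01:01", 10)),
    allele2 = c(rep("A*03:01", 10), rep("DRB1*04:01", 5),
                rep("DRB1*01:01", 5))))
  expect_equal(population_frequency(bench, "A02:01"), 0.4)
  expect_equal(population_frequency(bench, "DRB1*04:01"), 0.5)
  expect_equal(population_frequency(bench, "A11:01"), 0)
  # gene absent but class resolved: frequency is 0, not undefined
  expect_equal(population_frequency(bench, "B07:02"), 0)
  # class with no resolved samples at all: undefined
  classI_only <- truth_as_benchmark(tibble::tibble(
    sample = "P1", gene = "A", allele1 = "A*01:01", allele2 = "A*02:01"))
  expect_warning(
    expect_true(is.na(population_frequency(classI_only, "DRB1*01:01"))),
    "undefined")
})

test_that("frequency table exposes both allelic denominators and count bounds", {
  set.seed(7)
  truth <- random_truth(60, genes = c("A", "B"))
  bench <- truth_as_benchmark(truth)
  tab <- allele_frequency_table(bench)
  expect_true(all(tab$population_count <= tab$allelic_count))
  expect_true(all(tab$allelic_count <= 2 * tab$population_count))
  expect_true(all(tab$population_frequency >= 0 &
                    tab$population_frequency <= 1))
  # class-level allelic frequencies sum to 1 over all alleles of a class
  expect_equal(sum(tab$allelic_frequency_class[hla_class(tab$gene) == "I"]),
               1, tolerance = 1e-12)
  expect_equal(sum(tab$allelic_frequency_gene[tab$gene == "A"]), 1,
               tolerance = 1e-12)
})

test_that("voting is invariant to call-row order", {
  cfg <- sim_config(seed = 301, n_samples = 40)
  coh <- simulate_cohort(cfg)
  b1 <- build_benchmark(coh$calls)
  set.seed(1)
  shuffled <- coh$calls[sample(nrow(coh$calls)), ]
  b2 <- build_benchmark(shuffled)
  expect_equal(b1$benchmark, b2$benchmark)
})

test_that("slot vote totals are bounded by the reporting-tool count", {
  cfg <- sim_config(seed = 302, n_samples = 60)
  coh <- simulate_cohort(cfg)
  bench <- build_benchmark(coh$calls)$benchmark
  reporting <- hlabench:::calls_to_long(coh$calls) |>
    dplyr::distinct(sample, gene, tool) |>
    dplyr::count(sample, gene, name = "n_tools")
  merged <- dplyr::left_join(bench, reporting, by = c("sample", "gene"))
  het <- !is.na(merged$allele1) & !is.na(merged$allele2) &
    merged$allele1 != merged$allele2
  expect_true(all(merged$votes1[het] + merged$votes2[het] <=
                    2 * merged$n_tools[het]))
})

test_that("majority voting beats every tool's individual error rate", {
  # 8 independent tools with uniform 10% per-copy error
  pool <- sprintf("A*%02d:01", 1:8)
  tools <- lapply(1:8, function(i) {
    sim_tool(paste0("U", i), error = 0.10, dominant_mass = 0)
  })
  names(tools) <- paste0("U", 1:8)
  freqs <- tibble::tibble(gene = "A", allele = pool, freq = rep(1 / 8, 8))
  cfg <- sim_config(seed = 303, n_samples = 300, genes = "A",
                    allele_freqs = freqs, tools = tools)
  truth <- simulate_truth(cfg)
  calls <- simulate_tool_calls(truth, cfg)
  bench <- build_benchmark(calls)$benchmark
  bench_calls <- tibble::tibble(sample = bench$sample, tool = "benchmark",
                                gene = bench$gene, allele1 = bench$allele1,
                                allele2 = bench$allele2)
  ev <- evaluate_tool(bench_calls, truth_as_benchmark(truth),
                      tool = "benchmark")
  bench_err <- 1 - ev$metrics$accuracy
  expect_lt(bench_err, 0.10)
})
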