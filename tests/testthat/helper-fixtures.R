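# Programmatic fixtures shared across test files.

# A call table in which `n_tools` tools agree exactly with the given truth
# genotypes, so the voted benchmark reproduces the truth.
agreeing_calls <- function(truth, n_tools = 3, prefix = "C") {
  dplyr::bind_rows(lapply(seq_len(n_tools), function(i) {
    dplyr::mutate(truth, tool = paste0(prefix, i), .after = "sample")
  }))
}

# Random two-field genotypes for property tests.
random_truth <- function(n, genes = c("A", "B"), alleles_per_gene = 6) {
  pool <- lapply(genes, function(g) {
    sprintf("%s*%02d:01", g, seq_len(alleles_per_gene))
  })
  names(pool) <- genes
  dplyr::bind_rows(lapply(genes, function(g) {
    tibble::tibble(sample = sprintf("S%04d", seq_len(n)), gene = g,
                   allele1 = sample(pool[[g]], n, replace = TRUE),
                   allele2 = sample(pool[[g]], n, replace = TRUE))
  }))
}

# Random predicted pair for one truth pair: with the given probabilities,
# mutate copies, drop copies, or drop the whole call.
random_pred_pair <- function(truth_pair, pool,
                             p_wrong = 0.3, p_drop_copy = 0.15,
                             p_drop_all = 0.1) {
  if (stats::runif(1) < p_drop_all) return(c(NA_character_, NA_character_))
  out <- truth_pair
  for (i in 1:2) {
    u <- stats::runif(1)
    if (u < p_wrong) {
      out[i] <- sample(setdiff(pool, truth_pair[i]), 1)
    } else if (u < p_wrong + p_drop_copy) {
      out[i] <- NA_character_
    }
  }
  out
}

# Deterministic planted-error fixture behind the worked error-rate
# examples: `n_total` benchmark copies of `allele` (heterozygous with
# `partner`), of which the evaluated tool miscalls the copies listed in
# `wrong_as` (a character vector, one entry per miscalled copy).
planted_error_calls <- function(allele, partner, n_total, wrong_as,
                                gene, sample_prefix = "P") {
  stopifnot(length(wrong_as) <= n_total)
  truth <- tibble::tibble(
    sample = sprintf("%s%05d", sample_prefix, seq_len(n_total)),
    gene = gene, allele1 = allele, allele2 = partner)
  pred <- truth
  pred$allele1[seq_along(wrong_as)] <- wrong_as
  pred$tool <- "toolX"
  list(truth = truth, pred = pred)
}
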