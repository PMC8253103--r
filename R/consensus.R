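#' @importFrom dplyr %>% arrange bind_rows count desc distinct filter group_by
#'   left_join mutate n rename row_number select slice summarise ungroup
#'   coalesce if_else anti_join inner_join full_join first pull relocate
#' @importFrom rlang .data
NULL

# ---- call-table plumbing ----------------------------------------------------

# Validate a multi-tool call table (sample, tool, gene, allele1, allele2) and
# normalize allele names to two-field resolution. Empty strings are read as
# NA (uncalled copies).
validate_calls <- function(calls, genes = hla_genes()) {
  need <- c("sample", "tool", "gene", "allele1", "allele2")
  miss <- setdiff(need, names(calls))
  if (length(miss)) {
    stop("call table is missing column(s): ", paste(miss, collapse = ", "))
  }
  calls <- tibble::as_tibble(calls)[need]
  calls$sample <- as.character(calls$sample)
  calls$tool <- as.character(calls$tool)
  calls$gene <- as.character(calls$gene)
  bad_gene <- !(calls$gene %in% genes)
  if (any(bad_gene)) {
    stop("unknown gene token in call table: '", calls$gene[bad_gene][1], "'")
  }
  for (col in c("allele1", "allele2")) {
    v <- as.character(calls[[col]])
    v[!is.na(v) & trimws(v) == ""] <- NA_character_
    calls[[col]] <- hla_normalize(v, genes = genes)
  }
  # an allele must belong to the gene of its row
  for (col in c("allele1", "allele2")) {
    g <- hla_gene(calls[[col]])
    mism <- !is.na(g) & g != calls$gene
    if (any(mism)) {
      stop("allele '", calls[[col]][mism][1], "' does not match gene '",
           calls$gene[mism][1], "' in call table")
    }
  }
  # a call cannot have a second allele without a first
  swap <- is.na(calls$allele1) & !is.na(calls$allele2)
  if (any(swap)) {
    a2 <- calls$allele2[swap]
    calls$allele1[swap] <- a2
    calls$allele2[swap] <- NA_character_
  }
  calls
}

# Long form: one row per called allele copy.
calls_to_long <- function(calls) {
  long <- tidyr::pivot_longer(calls, c("allele1", "allele2"),
                              names_to = "copy", values_to = "allele")
  long[!is.na(long$allele), c("sample", "tool", "gene", "allele")]
}

# ---- voting -----------------------------------------------------------------

#' Consensus genotype for one sample and gene by allelic voting
#'
#' Every called allele copy is one vote, so a homozygous call contributes
#' two votes (per-copy voting keeps benchmark allelic counts consistent
#' with the allelic-count denominator of the general error rate). A slot is
#' filled by the highest-voted allele that has at least two votes from at
#' least two distinct tools; the second slot takes the next-highest
#' distinct such allele. A homozygous consensus (same allele in both slots)
#' requires at least two tools calling that allele homozygous and no
#' distinct allele reaching two votes. Exact vote ties are broken
#' lexicographically and flagged `ambiguous`.
#'
#' @param calls A call table (columns `sample`, `tool`, `gene`, `allele1`,
#'   `allele2`) restricted to one sample and one gene.
#' @param genes Allowed gene tokens.
#' @return A one-row tibble with `sample`, `gene`, `allele1`, `allele2`,
#'   `votes1`, `votes2`, `status` (`complete`/`partial`/`unresolved`) and
#'   `ambiguous`.
#' @examples
#' calls <- tibble::tibble(
#'   sample = "S1", tool = c("T1", "T2", "T3"), gene = "A",
#'   allele1 = c("A*01:01", "A*01:01", "A*01:01"),
#'   allele2 = c("A*02:01", "A*02:01", "A*03:01"))
#' vote_gene(calls)
#' @export
vote_gene <- function(calls, genes = hla_genes()) {
  calls <- validate_calls(calls, genes)
  if (nrow(calls) == 0 ||
      length(unique(calls$sample)) != 1 || length(unique(calls$gene)) != 1) {
    stop("vote_gene() expects calls for exactly one sample and one gene")
  }
  vote_all(calls)
}

# Vectorized voting over every (sample, gene) present in a validated call
# table. Returns the benchmark tibble.
vote_all <- function(calls) {
  base <- dplyr::distinct(calls, .data$sample, .data$gene)
  long <- calls_to_long(calls)

  empty <- tibble::tibble(
    sample = character(), gene = character(),
    allele1 = character(), allele2 = character(),
    votes1 = integer(), votes2 = integer(),
    status = character(), ambiguous = logical())
  if (nrow(long) == 0) {
    slots <- empty
  } else {
    per_tool <- dplyr::count(long, .data$sample, .data$gene, .data$allele,
                             .data$tool, name = "copies")
    tab <- per_tool %>%
      group_by(.data$sample, .data$gene, .data$allele) %>%
      summarise(votes = sum(.data$copies),
                n_tools = dplyr::n(),
                n_hom_tools = sum(.data$copies == 2L),
                .groups = "drop")

    elig <- tab %>%
      filter(.data$votes >= 2L, .data$n_tools >= 2L) %>%
      arrange(.data$sample, .data$gene, desc(.data$votes), .data$allele) %>%
      group_by(.data$sample, .data$gene) %>%
      mutate(rk = row_number(),
             n_elig = dplyr::n(),
             votes3 = dplyr::nth(.data$votes, 3L)) %>%
      ungroup() %>%
      filter(.data$rk <= 2L)

    slots <- elig %>%
      group_by(.data$sample, .data$gene) %>%
      summarise(
        allele1 = .data$allele[1L],
        votes1 = .data$votes[1L],
        allele2 = dplyr::nth(.data$allele, 2L),
        votes2 = dplyr::nth(.data$votes, 2L),
        # tie broken iff an excluded eligible allele had the same votes as
        # the last included one
        ambiguous = dplyr::first(.data$n_elig) > 2L &&
          !is.na(dplyr::first(.data$votes3)) &&
          dplyr::first(.data$votes3) == dplyr::nth(.data$votes, 2L),
        hom_ok = .data$n_hom_tools[1L] >= 2L,
        .groups = "drop")

    # homozygous consensus: no distinct second allele, >=2 tools homozygous
    hom <- is.na(slots$allele2) & slots$hom_ok
    slots$allele2[hom] <- slots$allele1[hom]
    slots$votes2[hom] <- slots$votes1[hom]
    slots$hom_ok <- NULL
    slots$ambiguous[is.na(slots$ambiguous)] <- FALSE
  }

  out <- dplyr::left_join(base, slots, by = c("sample", "gene"))
  out$status <- dplyr::case_when(
    !is.na(out$allele1) & !is.na(out$allele2) ~ "complete",
    !is.na(out$allele1) ~ "partial",
    TRUE ~ "unresolved")
  out$ambiguous[is.na(out$ambiguous)] <- FALSE
  out$votes1 <- as.integer(out$votes1)
  out$votes2 <- as.integer(out$votes2)
  dplyr::arrange(out, .data$sample, .data$gene)
}

# ---- benchmark --------------------------------------------------------------

#' Build the consensus benchmark genotype set from a multi-tool call table
#'
#' Runs allelic voting (see [vote_gene()]) over every (sample, gene) pair
#' that at least one tool reported, and attaches a per-gene build report
#' counting complete, partial and unresolved benchmarks. Unresolved pairs
#' stay in the table but are excluded from evaluation denominators.
#'
#' @param calls Call table with columns `sample`, `tool`, `gene`,
#'   `allele1`, `allele2`; duplicate (sample, tool, gene) rows are an
#'   input error.
#' @param genes Allowed gene tokens.
#' @return An object of class `hla_benchmark`: a list with `benchmark`
#'   (tibble `sample`, `gene`, `allele1`, `allele2`, `votes1`, `votes2`,
#'   `status`, `ambiguous`) and `report` (per-gene status counts).
#' @export
build_benchmark <- function(calls, genes = hla_genes()) {
  calls <- validate_calls(calls, genes)
  if (nrow(calls) == 0) stop("call table is empty")
  dup <- duplicated(calls[c("sample", "tool", "gene")])
  if (any(dup)) {
    d <- calls[dup, ][1, ]
    stop("duplicate call rows for sample '", d$sample, "', tool '", d$tool,
         "', gene '", d$gene, "'")
  }
  bench <- vote_all(calls)
  report <- bench %>%
    count(.data$gene, .data$status, name = "n") %>%
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  for (col in c("complete", "partial", "unresolved")) {
    if (!col %in% names(report)) report[[col]] <- 0L
  }
  structure(list(benchmark = bench,
                 report = report[c("gene", "complete", "partial", "unresolved")]),
            class = "hla_benchmark")
}

#' @export
print.hla_benchmark <- function(x, ...) {
  df <- x$benchmark
  cat("HLA consensus benchmark: ", length(unique(df$sample)), " samples, ",
      length(unique(df$gene)), " genes, ", nrow(df), " genotypes\n", sep = "")
  print(x$report)
  invisible(x)
}

# Accept either an hla_benchmark or its benchmark tibble.
as_benchmark_df <- function(bench) {
  if (inherits(bench, "hla_benchmark")) return(bench$benchmark)
  need <- c("sample", "gene", "allele1", "allele2", "status")
  if (is.data.frame(bench) && all(need %in% names(bench))) {
    return(tibble::as_tibble(bench))
  }
  stop("expected an 'hla_benchmark' object or a benchmark tibble")
}

#' Treat simulated true genotypes as a benchmark
#'
#' Wraps a table of known true genotypes (e.g. from [simulate_truth()]) in
#' the benchmark container so that tools and ensembles can be scored
#' against simulation truth instead of a voted consensus. Vote counts are
#' `NA` because no voting took place.
#'
#' @param truth Tibble with columns `sample`, `gene`, `allele1`, `allele2`.
#' @param genes Allowed gene tokens.
#' @return An `hla_benchmark` object with all genotypes `complete`.
#' @export
truth_as_benchmark <- function(truth, genes = hla_genes()) {
  need <- c("sample", "gene", "allele1", "allele2")
  miss <- setdiff(need, names(truth))
  if (length(miss)) stop("truth table is missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- tibble::as_tibble(truth)[need]
  df$allele1 <- hla_normalize(df$allele1, genes)
  df$allele2 <- hla_normalize(df$allele2, genes)
  if (any(is.na(df$allele1) | is.na(df$allele2))) {
    stop("truth genotypes must have both allele copies")
  }
  df$votes1 <- NA_integer_
  df$votes2 <- NA_integer_
  df$status <- "complete"
  df$ambiguous <- FALSE
  report <- df %>% count(.data$gene, name = "complete") %>%
    mutate(partial = 0L, unresolved = 0L)
  structure(list(benchmark = df, report = report), class = "hla_benchmark")
}

# ---- frequency summaries ----------------------------------------------------

#' Allelic and population counts of an allele in the benchmark
#'
#' The allelic count is the number of benchmark slots equal to the allele
#' (a homozygous carrier counts 2); the population count is the number of
#' samples carrying it at least once (a homozygous carrier counts 1).
#'
#' @param bench An `hla_benchmark` or benchmark tibble.
#' @param allele Allele name in any supported dialect.
#' @return Named integer vector with elements `allelic` and `population`.
#' @export
allele_counts <- function(bench, allele) {
  df <- as_benchmark_df(bench)
  a <- hla_normalize(allele)
  if (length(a) != 1) stop("allele_counts() takes a single allele")
  hits1 <- !is.na(df$allele1) & df$allele1 == a
  hits2 <- !is.na(df$allele2) & df$allele2 == a
  c(allelic = sum(hits1) + sum(hits2),
    population = length(unique(df$sample[hits1 | hits2])))
}

#' Population frequency of an allele in the benchmark
#'
#' The fraction of benchmark samples carrying the allele at least once,
#' with the denominator taken as the number of samples that have at least
#' one resolved (complete or partial) benchmark genotype for any gene of
#' the allele's HLA class (class I = A/B/C, class II = DRB1/DPB1/DQA1/DQB1;
#' the two classes have separate sample denominators because not every
#' sample resolves in both).
#'
#' @inheritParams allele_counts
#' @return Fraction in `[0, 1]`, or `NA` with a warning when no sample has
#'   a resolved genotype in the allele's class.
#' @export
population_frequency <- function(bench, allele) {
  df <- as_benchmark_df(bench)
  a <- hla_normalize(allele)
  if (length(a) != 1) stop("population_frequency() takes a single allele")
  cls <- hla_class(hla_gene(a))
  in_class <- hla_class(df$gene) == cls & df$status != "unresolved"
  denom <- length(unique(df$sample[in_class]))
  if (denom == 0) {
    warning("no resolved benchmark samples in class ", cls,
            "; population frequency undefined")
    return(NA_real_)
  }
  unname(allele_counts(df, a)["population"]) / denom
}

#' Frequency table of every allele in the benchmark
#'
#' One row per distinct allele with its allelic count, population count and
#' population frequency. Both possible "allelic frequency" denominators are
#' exposed rather than guessed: `allelic_frequency_class` divides by all
#' filled benchmark slots of the allele's HLA class, and
#' `allelic_frequency_gene` by the filled slots of its gene.
#'
#' @param bench An `hla_benchmark` or benchmark tibble.
#' @return A tibble sorted by decreasing population frequency.
#' @export
allele_frequency_table <- function(bench) {
  df <- as_benchmark_df(bench)
  long <- tidyr::pivot_longer(df, c("allele1", "allele2"),
                              names_to = "slot", values_to = "allele")
  long <- long[!is.na(long$allele), ]
  long$class <- hla_class(long$gene)

  class_samples <- long %>% distinct(.data$class, .data$sample) %>%
    count(.data$class, name = "n_class_samples")
  class_slots <- long %>% count(.data$class, name = "n_class_slots")
  gene_slots <- long %>% count(.data$gene, name = "n_gene_slots")

  long %>%
    group_by(.data$class, .data$gene, .data$allele) %>%
    summarise(allelic_count = dplyr::n(),
              population_count = length(unique(.data$sample)),
              .groups = "drop") %>%
    left_join(class_samples, by = "class") %>%
    left_join(class_slots, by = "class") %>%
    left_join(gene_slots, by = "gene") %>%
    mutate(population_frequency = .data$population_count / .data$n_class_samples,
           allelic_frequency_class = .data$allelic_count / .data$n_class_slots,
           allelic_frequency_gene = .data$allelic_count / .data$n_gene_slots) %>%
    select(-"n_class_samples", -"n_class_slots", -"n_gene_slots") %>%
    arrange(desc(.data$population_frequency))
}
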