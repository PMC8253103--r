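# Readers and writers for the pipeline's table dialects. All tables are
# UTF-8, tab-separated, with a header row; '#' comment lines are allowed.
# Data files carry fractions at full precision; percentages appear only in
# rendered reports.

read_tsv_checked <- function(path, required, what) {
  df <- readr::read_tsv(path, comment = "#",
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE, na = c("", "NA"))
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(what, " file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df
}

#' Read a multi-tool HLA call table
#'
#' TSV with header `sample`, `tool`, `gene`, `allele1`, `allele2`; empty
#' allele cells mean the copy was uncalled. Allele names may use any
#' supported dialect and are normalized to two-field resolution.
#'
#' @param path Path to the TSV file.
#' @param genes Allowed gene tokens.
#' @return Validated call tibble.
#' @export
read_hla_calls <- function(path, genes = hla_genes()) {
  df <- read_tsv_checked(path, c("sample", "tool", "gene",
                                 "allele1", "allele2"), "call table")
  validate_calls(df, genes = genes)
}

#' Write a call table
#' @param calls Call tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hla_calls <- function(calls, path) {
  readr::write_tsv(calls, path, na = "")
  invisible(path)
}

#' Write / read a benchmark table
#'
#' The benchmark dialect is `sample`, `gene`, `allele1`, `allele2`,
#' `votes1`, `votes2`, `status`, `ambiguous`.
#'
#' @param bench An `hla_benchmark` or benchmark tibble.
#' @param path File path.
#' @return `write_benchmark()` returns the path invisibly;
#'   `read_benchmark()` returns an `hla_benchmark`.
#' @export
write_benchmark <- function(bench, path) {
  readr::write_tsv(as_benchmark_df(bench), path, na = "")
  invisible(path)
}

#' @rdname write_benchmark
#' @export
read_benchmark <- function(path) {
  df <- read_tsv_checked(path, c("sample", "gene", "allele1", "allele2",
                                 "votes1", "votes2", "status", "ambiguous"),
                         "benchmark")
  df$votes1 <- as.integer(df$votes1)
  df$votes2 <- as.integer(df$votes2)
  df$ambiguous <- as.logical(df$ambiguous)
  report <- df %>%
    dplyr::count(.data$gene, .data$status, name = "n") %>%
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  for (col in c("complete", "partial", "unresolved")) {
    if (!col %in% names(report)) report[[col]] <- 0L
  }
  structure(list(benchmark = tibble::as_tibble(df),
                 report = report[c("gene", "complete", "partial",
                                   "unresolved")]),
            class = "hla_benchmark")
}

#' Read a MAF-dialect somatic mutation table
#'
#' Requires at least `Tumor_Sample_Barcode` and `One_Consequence`; any
#' extra MAF columns are kept but ignored downstream.
#'
#' @param path Path to the TSV file.
#' @return Tibble of mutation records.
#' @export
read_maf <- function(path) {
  read_tsv_checked(path, c("Tumor_Sample_Barcode", "One_Consequence"), "MAF")
}

#' Read an expression matrix
#'
#' TSV with a `gene` column and one column per sample, values in TPM.
#'
#' @param path Path to the TSV file.
#' @param required_genes Genes that must be present (default GZMA and
#'   PRF1, the CYT inputs).
#' @return Numeric matrix with genes as row names.
#' @export
read_expression <- function(path, required_genes = c("GZMA", "PRF1")) {
  df <- read_tsv_checked(path, "gene", "expression")
  m <- as_expression_matrix(df)
  miss <- setdiff(required_genes, rownames(m))
  if (length(miss)) {
    stop("expression file '", path, "' lacks required gene row(s): ",
         paste(miss, collapse = ", "))
  }
  m
}

#' Write an expression matrix
#' @param expr Matrix with gene row names.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- tibble::as_tibble(expr, rownames = "gene")
  readr::write_tsv(df, path, na = "")
  invisible(path)
}

#' Read a clinical table
#'
#' TSV with columns `sample`, `vital_status`, `days_to_death`,
#' `days_to_last_follow_up`, `tumor_stage` (plus optional `age`,
#' `cancer_type`, kept when present). Day and age fields are coerced to
#' numeric.
#'
#' @param path Path to the TSV file.
#' @return Clinical tibble.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_checked(path, c("sample", "vital_status", "days_to_death",
                                 "days_to_last_follow_up", "tumor_stage"),
                         "clinical")
  for (col in intersect(c("days_to_death", "days_to_last_follow_up", "age"),
                        names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df
}

#' Read allele-level LOH calls
#'
#' TSV with columns `sample`, `allele`, `loh_pvalue`. An allele is
#' declared lost when its coverage-imbalance p-value is at or below
#' `alpha` (default 0.05). Returns only the lost alleles.
#'
#' @param path Path to the TSV file.
#' @param alpha Significance threshold for declaring LOH.
#' @return Tibble with `sample` and normalized `allele` of LOH events.
#' @export
read_loh <- function(path, alpha = 0.05) {
  df <- read_tsv_checked(path, c("sample", "allele", "loh_pvalue"), "LOH")
  df$loh_pvalue <- as.numeric(df$loh_pvalue)
  df <- df[!is.na(df$loh_pvalue) & df$loh_pvalue <= alpha, ]
  tibble::tibble(sample = df$sample, allele = hla_normalize(df$allele))
}

#' Write the per-tool evaluation reports
#'
#' Emits three TSVs next to `prefix`: `<prefix>_metrics.tsv` (per class
#' right/wrong/uncalled/recall/accuracy), `<prefix>_general_errors.tsv`
#' and `<prefix>_specific_errors.tsv`.
#'
#' @param eval An `hla_evaluation` from [evaluate_tool()].
#' @param prefix Path prefix for the three files.
#' @return Character vector of the three paths, invisibly.
#' @export
write_evaluation <- function(eval, prefix) {
  paths <- paste0(prefix, c("_metrics.tsv", "_general_errors.tsv",
                            "_specific_errors.tsv"))
  readr::write_tsv(dplyr::mutate(eval$metrics, tool = eval$tool, .before = 1),
                   paths[1], na = "")
  readr::write_tsv(dplyr::mutate(eval$general_errors, tool = eval$tool,
                                 .before = 1), paths[2], na = "")
  readr::write_tsv(dplyr::mutate(eval$specific_errors, tool = eval$tool,
                                 .before = 1), paths[3], na = "")
  invisible(paths)
}
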