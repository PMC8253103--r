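# Per-sample immune covariates: cytolytic activity (CYT), tumor mutation
# burden (TMB), supertype presence with optional LOH adjustment, and the
# supertype-by-TMB ("Gun-Bullet") cross-classification.

#' Immune cytolytic activity score
#'
#' CYT is the geometric mean of GZMA and PRF1 expression in TPM with a
#' 0.01 offset: `sqrt((gzma + 0.01) * (prf1 + 0.01))`. The offset keeps
#' the score defined (0.01) when both genes are silent. The formula is
#' applied to TPM directly, with no log transform or re-normalization.
#'
#' @param gzma,prf1 Nonnegative TPM expression values (vectorized).
#' @param offset Pseudo-expression added to both genes (default 0.01 TPM).
#' @return Numeric CYT scores, always `>= offset` for nonnegative inputs.
#' @examples
#' cyt_score(100, 25)
#' @export
cyt_score <- function(gzma, prf1, offset = 0.01) {
  if (any(gzma < 0, na.rm = TRUE) || any(prf1 < 0, na.rm = TRUE)) {
    stop("expression values must be nonnegative")
  }
  sqrt((gzma + offset) * (prf1 + offset))
}

#' Per-sample CYT from an expression matrix
#'
#' @param expr Expression table with genes in rows and samples in columns
#'   (a matrix or data frame with gene names as row names, or a first
#'   column `gene`). Rows `GZMA` and `PRF1` are required.
#' @return A tibble with columns `sample` and `cyt`.
#' @export
cyt_from_expression <- function(expr) {
  expr <- as_expression_matrix(expr)
  need <- c("GZMA", "PRF1")
  miss <- setdiff(need, rownames(expr))
  if (length(miss)) {
    stop("expression matrix is missing required gene row(s): ",
         paste(miss, collapse = ", "))
  }
  tibble::tibble(sample = colnames(expr),
                 cyt = cyt_score(as.numeric(expr["GZMA", ]),
                                 as.numeric(expr["PRF1", ])))
}

# Coerce the accepted expression dialects to a numeric matrix.
as_expression_matrix <- function(expr) {
  if (is.data.frame(expr) && "gene" %in% names(expr)) {
    g <- expr$gene
    expr <- as.matrix(expr[setdiff(names(expr), "gene")])
    rownames(expr) <- g
  } else {
    expr <- as.matrix(expr)
  }
  storage.mode(expr) <- "double"
  expr
}

#' Consequence keywords counted as nonsynonymous for TMB
#'
#' The 13 MAF `One_Consequence` values treated as nonsynonymous somatic
#' mutations.
#'
#' @return Character vector of keywords.
#' @export
tmb_keywords <- function() {
  c("missense_variant", "frameshift_variant", "stop_gained",
    "inframe_insertion", "splice_region_variant", "splice_donor_variant",
    "inframe_deletion", "splice_acceptor_variant",
    "protein_altering_variant", "stop_lost", "start_lost",
    "stop_retained_variant", "coding_sequence_variant")
}

#' Tumor mutation burden from consequence tokens
#'
#' Counts the consequences belonging to the nonsynonymous keyword set and
#' divides by the coding-region length in megabases. The coding length is
#' a parameter (default 38 Mb, a conventional whole-exome coding
#' footprint) and is recorded by downstream tables.
#'
#' @param consequences Character vector of `One_Consequence` tokens for
#'   one sample.
#' @param coding_mb Coding-region length in Mb; must be positive.
#' @param keywords Keyword set (default [tmb_keywords()]).
#' @return Mutations per Mb.
#' @export
tmb_score <- function(consequences, coding_mb = 38, keywords = tmb_keywords()) {
  if (!is.numeric(coding_mb) || length(coding_mb) != 1 || coding_mb <= 0) {
    stop("coding_mb must be a single positive number")
  }
  sum(consequences %in% keywords) / coding_mb
}

#' Per-sample TMB from a MAF-dialect mutation table
#'
#' @param maf Tibble with at least `Tumor_Sample_Barcode` and
#'   `One_Consequence`; extra columns are ignored.
#' @param coding_mb Coding-region length in Mb.
#' @param keywords Nonsynonymous keyword set.
#' @param samples Optional character vector of samples that must appear in
#'   the output (samples without mutation rows get TMB 0).
#' @return Tibble with `sample`, `n_nonsyn`, `tmb` and the `coding_mb`
#'   used.
#' @export
tmb_from_maf <- function(maf, coding_mb = 38, keywords = tmb_keywords(),
                         samples = NULL) {
  need <- c("Tumor_Sample_Barcode", "One_Consequence")
  miss <- setdiff(need, names(maf))
  if (length(miss)) {
    stop("MAF table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(coding_mb) || coding_mb <= 0) {
    stop("coding_mb must be a single positive number")
  }
  counts <- maf %>%
    dplyr::filter(.data$One_Consequence %in% keywords) %>%
    dplyr::count(sample = .data$Tumor_Sample_Barcode, name = "n_nonsyn")
  all_samples <- union(samples, unique(maf$Tumor_Sample_Barcode))
  tibble::tibble(sample = all_samples) %>%
    dplyr::left_join(counts, by = "sample") %>%
    dplyr::mutate(n_nonsyn = dplyr::coalesce(.data$n_nonsyn, 0L),
                  tmb = .data$n_nonsyn / coding_mb,
                  coding_mb = coding_mb)
}

#' Split samples into high/low groups at the within-condition median
#'
#' Values strictly greater than their condition's median are `"high"`;
#' values at or below the median are `"low"`. Conditions with fewer than
#' two non-missing values are skipped (`NA` labels) with a warning, and a
#' condition whose values are all tied yields an all-`"low"` degenerate
#' split (also warned).
#'
#' @param values Numeric scores, one per sample.
#' @param condition Grouping labels (e.g. cancer type by stage); a single
#'   condition when `NULL`.
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(values, condition = NULL) {
  if (is.null(condition)) condition <- rep("all", length(values))
  out <- rep(NA_character_, length(values))
  for (cc in unique(condition)) {
    i <- which(condition == cc & !is.na(values))
    if (length(i) < 2) {
      warning("condition '", cc, "' has fewer than 2 values; split skipped")
      next
    }
    med <- stats::median(values[i])
    out[i] <- ifelse(values[i] > med, "high", "low")
    if (all(out[i] == "low")) {
      warning("degenerate split in condition '", cc, "': all values tied")
    }
  }
  factor(out, levels = c("low", "high"))
}

#' Supertype presence per sample, with optional LOH demotion
#'
#' A sample is `present` for a supertype when at least one of its class I
#' benchmark alleles maps to it. With an LOH table, an allele hit by a
#' loss-of-heterozygosity event no longer confers presence, so LOH can
#' only demote `present` to `absent`, never the reverse. Samples are
#' scored from all their resolved class I benchmark slots (partial
#' genotypes contribute the slots they have).
#'
#' @param bench An `hla_benchmark` or benchmark tibble.
#' @param supertype Supertype label to query (e.g. `"B44"`).
#' @param map Supertype map tibble ([read_supertype_map()]).
#' @param loh Optional tibble of LOH events with columns `sample` and
#'   `allele` (see [read_loh()]).
#' @return Tibble with `sample` and factor `presence`
#'   (`absent`/`present`).
#' @export
supertype_presence <- function(bench, supertype, map, loh = NULL) {
  df <- as_benchmark_df(bench)
  df <- df[hla_class(df$gene) == "I", ]
  long <- tidyr::pivot_longer(df, c("allele1", "allele2"),
                              names_to = "slot", values_to = "allele")
  long <- long[!is.na(long$allele), c("sample", "allele")]
  long$st <- assign_supertype(long$allele, map)
  hit <- long[long$st == supertype, ]
  if (!is.null(loh)) {
    if (!all(c("sample", "allele") %in% names(loh))) {
      stop("LOH table needs columns sample and allele")
    }
    loh$allele <- hla_normalize(loh$allele)
    hit <- dplyr::anti_join(hit, loh, by = c("sample", "allele"))
  }
  tibble::tibble(sample = unique(df$sample)) %>%
    dplyr::mutate(presence = factor(
      ifelse(.data$sample %in% hit$sample, "present", "absent"),
      levels = c("absent", "present")))
}

#' Gun-Bullet cross-classification of presence and TMB group
#'
#' Crosses supertype presence ("gun") with the TMB median-split group
#' ("bullets") into the four cells `present&high`, `present&low`,
#' `absent&high`, `absent&low`.
#'
#' @param presence Factor/character `present`/`absent` per sample.
#' @param tmb_group Factor/character `high`/`low` per sample.
#' @return Factor with the four cell labels.
#' @export
gun_bullet_groups <- function(presence, tmb_group) {
  lab <- ifelse(is.na(presence) | is.na(tmb_group), NA_character_,
                paste0(as.character(presence), "&", as.character(tmb_group)))
  factor(lab, levels = c("present&high", "present&low",
                         "absent&high", "absent&low"))
}

#' The three Gun-Bullet contrasts
#'
#' The group pairings compared for a queried supertype: plain presence vs
#' absence, the concordant extreme cells (`present&high` vs `absent&low`)
#' and the discordant cells (`present&low` vs `absent&high`).
#'
#' @return A named list of length-2 character vectors.
#' @export
gun_bullet_contrasts <- function() {
  list(presence = c("present", "absent"),
       concordant = c("present&high", "absent&low"),
       discordant = c("present&low", "absent&high"))
}

#' Assemble the per-sample immune record table
#'
#' Joins CYT, TMB, survival-ready clinical fields, supertype presence and
#' the Gun-Bullet label into one table, computing the CYT and TMB
#' median splits within each cancer condition (cancer type crossed with
#' early/advanced stage).
#'
#' @param bench An `hla_benchmark` or benchmark tibble.
#' @param expr Expression table (see [cyt_from_expression()]).
#' @param maf MAF-dialect mutation table (see [tmb_from_maf()]).
#' @param clinical Clinical tibble with `sample`, `vital_status`,
#'   `days_to_death`, `days_to_last_follow_up`, `tumor_stage`,
#'   `cancer_type` (and optionally `age`).
#' @param map Supertype map.
#' @param supertype Supertype label to query.
#' @param loh Optional LOH table.
#' @param coding_mb Coding-region length for TMB.
#' @return Tibble with one row per sample carrying `condition`, `cyt`,
#'   `tmb`, `cyt_group`, `tmb_group`, `presence`, `gun_bullet`, `time`,
#'   `event` (and `age` when provided).
#' @export
immuno_table <- function(bench, expr, maf, clinical, map,
                         supertype, loh = NULL, coding_mb = 38) {
  cyt <- cyt_from_expression(expr)
  os <- derive_os(clinical)
  stage <- classify_stage(clinical$tumor_stage)
  cond <- tibble::tibble(
    sample = as.character(clinical$sample),
    cancer_type = as.character(clinical$cancer_type),
    condition = paste(clinical$cancer_type, as.character(stage), sep = "_"))
  if ("age" %in% names(clinical)) cond$age <- clinical$age
  cond$condition[is.na(stage)] <- NA_character_

  tmb <- tmb_from_maf(maf, coding_mb = coding_mb, samples = cond$sample)
  pres <- supertype_presence(bench, supertype, map, loh = loh)

  rec <- cond %>%
    dplyr::inner_join(cyt, by = "sample") %>%
    dplyr::left_join(tmb[c("sample", "tmb")], by = "sample") %>%
    dplyr::left_join(pres, by = "sample") %>%
    dplyr::left_join(os, by = "sample") %>%
    dplyr::filter(!is.na(.data$condition))
  rec$cyt_group <- median_split(rec$cyt, rec$condition)
  rec$tmb_group <- median_split(rec$tmb, rec$condition)
  rec$gun_bullet <- gun_bullet_groups(rec$presence, rec$tmb_group)
  rec$supertype <- supertype
  rec$coding_mb <- coding_mb
  rec
}
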