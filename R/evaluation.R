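# Scoring a tool's calls against the consensus benchmark.
#
# Every evaluated (sample, gene) pair contributes exactly two allele slots:
# predicted alleles matched by the benchmark (as multisets) are "right",
# predicted alleles not in the benchmark are "wrong", and predicted slots
# the tool did not emit are "uncalled". Unmatched benchmark slots are the
# miscalls that feed the per-allele general error rate, and the pairing of
# unmatched benchmark alleles with wrong predictions feeds the pairwise
# specific error rate.

#' Recall of a call classification
#'
#' `recall = right / (right + wrong)`: the fraction of emitted allele calls
#' that agree with the benchmark. Uncalled slots do not enter.
#'
#' @param right,wrong Nonnegative counts.
#' @return Rate in `[0, 1]`, or `NA` with a warning when `right + wrong`
#'   is zero.
#' @export
recall <- function(right, wrong) {
  den <- right + wrong
  if (any(den == 0)) warning("recall undefined when right + wrong = 0")
  ifelse(den == 0, NA_real_, right / den)
}

#' Accuracy of a call classification
#'
#' `accuracy = right / (right + wrong + uncalled)`: like [recall()] but
#' charging the tool for slots it failed to call, so a tool that skips a
#' gene loses accuracy without losing recall.
#'
#' @param right,wrong,uncalled Nonnegative counts.
#' @return Rate in `[0, 1]`, or `NA` with a warning on a zero denominator.
#' @export
accuracy <- function(right, wrong, uncalled) {
  den <- right + wrong + uncalled
  if (any(den == 0)) warning("accuracy undefined on empty classification")
  ifelse(den == 0, NA_real_, right / den)
}

# ---- per-pair classification ------------------------------------------------

# Multiset mismatch detail for one (sample, gene) pair with k >= 1 predicted
# alleles and a complete two-slot truth. Returns the unmatched truth alleles
# (the miscalls), the truth->prediction pairs, and an ambiguity flag for
# pairings decided lexicographically.
mismatch_detail <- function(pred, truth) {
  tt <- truth
  matched <- logical(length(pred))
  for (i in seq_along(pred)) {
    j <- match(pred[i], tt)
    if (!is.na(j)) {
      tt <- tt[-j]
      matched[i] <- TRUE
    }
  }
  wrongp <- pred[!matched]
  miscall <- tt
  amb <- FALSE
  pair_t <- character(0)
  pair_p <- character(0)

  if (length(miscall) == 1 && length(wrongp) >= 1) {
    # one unmatched truth slot; at most one wrong prediction is possible here
    pair_t <- miscall
    pair_p <- wrongp[1]
  } else if (length(miscall) == 2 && length(wrongp) == 1) {
    # tool emitted a single wrong allele: pair it with the nearer truth
    # allele (shared first field), remaining tie broken lexicographically;
    # the second truth slot is an unpairable miss
    cand <- miscall[order(hla_field1(miscall) != hla_field1(wrongp), miscall)]
    if (cand[1] != cand[2] &&
        (hla_field1(cand[1]) == hla_field1(wrongp)) ==
        (hla_field1(cand[2]) == hla_field1(wrongp))) {
      amb <- TRUE
    }
    pair_t <- cand[1]
    pair_p <- wrongp
  } else if (length(miscall) == 2 && length(wrongp) == 2) {
    # both truth slots missed: choose the assignment maximizing shared
    # first fields, then lexicographic order
    s_keep <- (hla_field1(miscall[1]) == hla_field1(wrongp[1])) +
      (hla_field1(miscall[2]) == hla_field1(wrongp[2]))
    s_swap <- (hla_field1(miscall[1]) == hla_field1(wrongp[2])) +
      (hla_field1(miscall[2]) == hla_field1(wrongp[1]))
    if (s_swap > s_keep) {
      wrongp <- rev(wrongp)
    } else if (s_swap == s_keep) {
      o <- order(miscall)
      miscall_s <- miscall[o]
      wrongp <- sort(wrongp)
      if (miscall[o][1] != miscall[o][2] && wrongp[1] != wrongp[2]) {
        amb <- TRUE
      }
      miscall <- miscall_s
    }
    pair_t <- miscall
    pair_p <- wrongp
  }

  list(miscall = miscall,
       pairs = if (length(pair_t)) {
         data.frame(truth_allele = pair_t, pred_allele = pair_p,
                    stringsAsFactors = FALSE)
       } else NULL,
       ambiguous = amb)
}

#' Classify one tool's calls against complete benchmark genotypes
#'
#' Joins the tool's call table with the benchmark on (sample, gene) and
#' classifies each of the two allele slots per pair as right, wrong or
#' uncalled by multiset matching. A gene a tool never reported for a
#' sample counts as two uncalled slots. Benchmark pairs that are not
#' `complete` are skipped (they carry no usable truth).
#'
#' @param calls Call table for a single tool (other tools are dropped with
#'   a message if present; use `tool` to pick one).
#' @param bench An `hla_benchmark` or benchmark tibble.
#' @param tool Tool identifier to score; defaults to the only tool present.
#' @param genes Gene scope of the evaluation (default all genes present in
#'   the benchmark).
#' @return A list of class `hla_classification`: `pairs` (per sample-gene
#'   counts), `miscalls` (truth allele, paired prediction or `NA`,
#'   ambiguity flag), and the `right`/`wrong`/`uncalled` totals.
#' @export
classify_calls <- function(calls, bench, tool = NULL, genes = NULL) {
  bdf <- as_benchmark_df(bench)
  if (is.null(genes)) genes <- unique(bdf$gene)
  calls <- validate_calls(calls, genes = union(genes, unique(calls$gene)))
  tools <- unique(calls$tool)
  if (is.null(tool)) {
    if (length(tools) != 1) {
      stop("call table contains tools ", paste(tools, collapse = ", "),
           "; pick one with `tool`")
    }
    tool <- tools
  } else if (!tool %in% tools) {
    stop("tool '", tool, "' not present in call table (available: ",
         paste(tools, collapse = ", "), ")")
  }
  calls <- calls[calls$tool == tool & calls$gene %in% genes, ]

  truth <- bdf[bdf$status == "complete" & bdf$gene %in% genes,
               c("sample", "gene", "allele1", "allele2")]
  names(truth)[3:4] <- c("t1", "t2")
  if (nrow(truth) == 0) stop("benchmark has no complete genotypes in scope")
  if (!any(truth$sample %in% calls$sample)) {
    stop("no samples shared between tool calls and benchmark")
  }

  pred <- calls[c("sample", "gene", "allele1", "allele2")]
  names(pred)[3:4] <- c("p1", "p2")
  df <- dplyr::left_join(truth, pred, by = c("sample", "gene"))

  # put a single prediction in p1
  swap <- is.na(df$p1) & !is.na(df$p2)
  df$p1[swap] <- df$p2[swap]
  df$p2[swap] <- NA_character_

  k <- (!is.na(df$p1)) + (!is.na(df$p2))
  right <- integer(nrow(df))
  one <- k == 1L
  right[one] <- (df$p1[one] == df$t1[one]) | (df$p1[one] == df$t2[one])
  hom2 <- k == 2L & df$p1 == df$p2
  right[hom2] <- pmin(2L, (df$p1 == df$t1) + (df$p1 == df$t2))[hom2]
  het2 <- k == 2L & df$p1 != df$p2
  right[het2] <- ((df$p1 == df$t1) | (df$p1 == df$t2))[het2] +
    ((df$p2 == df$t1) | (df$p2 == df$t2))[het2]

  df$right <- right
  df$wrong <- k - right
  df$uncalled <- 2L - k

  # miscall detail only needed where a call was made but truth not fully hit
  idx <- which(k >= 1L & right < 2L)
  mis <- vector("list", length(idx))
  amb <- logical(length(idx))
  for (ii in seq_along(idx)) {
    i <- idx[ii]
    p <- c(df$p1[i], df$p2[i])
    d <- mismatch_detail(p[!is.na(p)], c(df$t1[i], df$t2[i]))
    pairs <- d$pairs
    truth_alleles <- d$miscall
    pred_for <- rep(NA_character_, length(truth_alleles))
    if (!is.null(pairs)) {
      pred_for[match(pairs$truth_allele, truth_alleles)] <- pairs$pred_allele
      # match() maps the first occurrence only; fix duplicated truth alleles
      if (length(truth_alleles) == 2 && truth_alleles[1] == truth_alleles[2] &&
          nrow(pairs) == 2) {
        pred_for <- pairs$pred_allele
      }
    }
    mis[[ii]] <- data.frame(sample = df$sample[i], gene = df$gene[i],
                            truth_allele = truth_alleles,
                            pred_allele = pred_for,
                            stringsAsFactors = FALSE)
    amb[ii] <- d$ambiguous
  }
  miscalls <- if (length(mis)) {
    out <- dplyr::bind_rows(mis)
    out$ambiguous <- rep(amb, vapply(mis, nrow, integer(1)))
    tibble::as_tibble(out)
  } else {
    tibble::tibble(sample = character(), gene = character(),
                   truth_allele = character(), pred_allele = character(),
                   ambiguous = logical())
  }

  structure(list(
    tool = tool,
    pairs = tibble::as_tibble(df[c("sample", "gene", "t1", "t2", "p1", "p2",
                                   "right", "wrong", "uncalled")]),
    miscalls = miscalls,
    right = sum(df$right), wrong = sum(df$wrong), uncalled = sum(df$uncalled)),
    class = "hla_classification")
}

#' @export
print.hla_classification <- function(x, ...) {
  cat("Classification of tool '", x$tool, "' on ", nrow(x$pairs),
      " sample-gene pairs\n", sep = "")
  cat(sprintf("  right %d  wrong %d  uncalled %d  recall %.4f  accuracy %.4f\n",
              x$right, x$wrong, x$uncalled,
              recall(x$right, x$wrong),
              accuracy(x$right, x$wrong, x$uncalled)))
  invisible(x)
}

# ---- error profile ----------------------------------------------------------

# Benchmark allelic counts within an evaluated scope.
benchmark_allelic_counts <- function(bdf, genes) {
  sub <- bdf[bdf$status == "complete" & bdf$gene %in% genes, ]
  long <- c(sub$allele1, sub$allele2)
  tab <- table(long)
  tibble::tibble(allele = names(tab), benchmark_allelic_count = as.integer(tab))
}

#' Evaluate one tool against the benchmark
#'
#' Aggregates [classify_calls()] over all complete benchmark genotypes in
#' the gene scope and derives, per HLA class, recall and accuracy, and per
#' benchmark allele the general error rate (miscalled copies divided by
#' benchmark allelic count) and the specific error rates (distribution of
#' those miscalls over the wrongly predicted partner alleles). Truth slots
#' a tool missed without emitting a pairable wrong allele count toward the
#' general error rate but contribute no specific pair.
#'
#' @inheritParams classify_calls
#' @return An object of class `hla_evaluation`: `tool`, `metrics` (per
#'   class right/wrong/uncalled/recall/accuracy), `classification`,
#'   `general_errors` (allele, benchmark_allelic_count, miscalls, rate) and
#'   `specific_errors` (truth allele, predicted allele, count, rate).
#' @export
evaluate_tool <- function(calls, bench, tool = NULL, genes = NULL) {
  bdf <- as_benchmark_df(bench)
  if (is.null(genes)) genes <- unique(bdf$gene)
  cls <- classify_calls(calls, bench, tool = tool, genes = genes)

  metrics <- cls$pairs %>%
    dplyr::mutate(class = hla_class(.data$gene)) %>%
    dplyr::group_by(.data$class) %>%
    dplyr::summarise(genes = paste(sort(unique(.data$gene)), collapse = ","),
                     right = sum(.data$right), wrong = sum(.data$wrong),
                     uncalled = sum(.data$uncalled), .groups = "drop") %>%
    dplyr::mutate(recall = recall(.data$right, .data$wrong),
                  accuracy = accuracy(.data$right, .data$wrong, .data$uncalled))

  bcounts <- benchmark_allelic_counts(bdf, genes)
  mc <- dplyr::count(cls$miscalls, .data$truth_allele, name = "miscalls")
  general <- bcounts %>%
    dplyr::left_join(mc, by = c(allele = "truth_allele")) %>%
    dplyr::mutate(miscalls = dplyr::coalesce(.data$miscalls, 0L),
                  rate = .data$miscalls / .data$benchmark_allelic_count) %>%
    dplyr::arrange(dplyr::desc(.data$rate), .data$allele)

  paired <- cls$miscalls[!is.na(cls$miscalls$pred_allele), ]
  specific <- paired %>%
    dplyr::count(.data$truth_allele, .data$pred_allele, name = "count") %>%
    dplyr::left_join(mc, by = "truth_allele") %>%
    dplyr::mutate(rate = .data$count / .data$miscalls) %>%
    dplyr::select("truth_allele", "pred_allele", "count", "rate") %>%
    dplyr::arrange(.data$truth_allele, dplyr::desc(.data$count))

  structure(list(tool = cls$tool, genes = sort(unique(genes)),
                 metrics = metrics, classification = cls,
                 general_errors = general, specific_errors = specific),
            class = "hla_evaluation")
}

#' @export
print.hla_evaluation <- function(x, ...) {
  cat("Evaluation of tool '", x$tool, "' (genes: ",
      paste(x$genes, collapse = ", "), ")\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' General error rate of an allele for an evaluated tool
#'
#' The fraction of the allele's benchmark copies the tool failed to call
#' exactly.
#'
#' @param eval An `hla_evaluation` from [evaluate_tool()].
#' @param allele Allele name (any dialect).
#' @return Rate in `[0, 1]`; `NA` with a warning when the allele is absent
#'   from the benchmark scope.
#' @export
general_error_rate <- function(eval, allele) {
  a <- hla_normalize(allele)
  i <- match(a, eval$general_errors$allele)
  if (is.na(i)) {
    warning("allele ", a, " absent from the evaluated benchmark")
    return(NA_real_)
  }
  eval$general_errors$rate[i]
}

#' Specific error rate of an allele pair for an evaluated tool
#'
#' The fraction of allele `i`'s miscalls that were emitted as allele `j`.
#'
#' @param eval An `hla_evaluation` from [evaluate_tool()].
#' @param i Benchmark (truth) allele.
#' @param j Predicted (wrong) allele.
#' @return Rate in `[0, 1]`; `NA` with a warning when `i` has no miscalls.
#' @export
specific_error_rate <- function(eval, i, j) {
  ai <- hla_normalize(i)
  aj <- hla_normalize(j)
  mc <- eval$general_errors$miscalls[match(ai, eval$general_errors$allele)]
  if (is.na(mc) || mc == 0) {
    warning("allele ", ai, " has no miscalls; specific error rate undefined")
    return(NA_real_)
  }
  k <- which(eval$specific_errors$truth_allele == ai &
               eval$specific_errors$pred_allele == aj)
  if (!length(k)) return(0)
  eval$specific_errors$rate[k]
}

#' Render a rate as a percentage rounded half-up to two decimals
#'
#' Reports mirror the field convention of printing percentages with two
#' decimals (e.g. `371/435` renders as `85.29`). Rates themselves are kept
#' at full precision everywhere else.
#'
#' @param rate Numeric vector of rates in `[0, 1]`.
#' @return Numeric percentage rounded half-up to 2 decimals.
#' @export
as_percent <- function(rate) {
  floor(rate * 10000 + 0.5) / 100
}
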