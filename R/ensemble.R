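# Integrated ("ensemble") genotype calls from a small roster of top-ranked
# tools: alleles reported concordantly (at least two per-copy votes from at
# least two tools) are accepted outright; any remaining slot falls back to
# the call of the highest-ranked tool that reported the gene.

#' Configuration for ensemble calling
#'
#' @param ranked_tools Character vector of at least two distinct tool
#'   identifiers, ordered by decreasing standalone accuracy (rank 1 first).
#' @param genes Gene scope the ensemble applies to.
#' @return A list of class `ensemble_config`.
#' @export
ensemble_config <- function(ranked_tools, genes = hla_genes()) {
  ranked_tools <- as.character(ranked_tools)
  if (length(ranked_tools) < 2) stop("need at least two ranked tools")
  if (anyDuplicated(ranked_tools)) stop("ranked tools must be distinct")
  structure(list(ranked_tools = ranked_tools, genes = genes),
            class = "ensemble_config")
}

# Ensemble decision for one (sample, gene): small-vector logic, called per
# group. `tool_calls` is a list mapping tool -> character vector of 0-2
# called allele copies, in roster order.
ensemble_one <- function(tool_calls, ranked_tools) {
  copies <- unlist(tool_calls, use.names = FALSE)
  if (!length(copies)) return(c(NA_character_, NA_character_))

  votes <- table(copies)
  n_tools <- table(unlist(lapply(tool_calls, unique), use.names = FALSE))
  alleles <- names(votes)
  concordant <- alleles[votes >= 2 & n_tools[alleles] >= 2]

  if (length(concordant) > 1) {
    # overflow guard: keep the two strongest, preferring the rank-1 tool's
    # own alleles on vote ties, then lexicographic order
    r1 <- tool_calls[[ranked_tools[1]]]
    pref <- concordant %in% r1
    o <- order(-as.integer(votes[concordant]), !pref, concordant)
    concordant <- concordant[o][seq_len(min(2L, length(concordant)))]
  }

  slots <- concordant
  if (length(slots) < 2) {
    # fall back to the best-ranked tool that reported the gene, consuming
    # its allele copies not already used by the concordant slots
    for (tl in ranked_tools) {
      avail <- tool_calls[[tl]]
      if (is.null(avail) || !length(avail)) next
      for (s in slots) {
        j <- match(s, avail)
        if (!is.na(j)) avail <- avail[-j]
      }
      while (length(slots) < 2 && length(avail)) {
        slots <- c(slots, avail[1])
        avail <- avail[-1]
      }
      break
    }
  }
  length(slots) <- 2L
  slots
}

#' Integrated genotype calls from ranked tools
#'
#' For each (sample, gene) reported by any roster tool, alleles reaching
#' two per-copy votes from two distinct tools fill the genotype slots
#' first (highest votes first); remaining slots are filled from the
#' highest-ranked reporting tool's call, treated as a multiset so a
#' homozygous fallback can fill both slots. If no roster tool reported the
#' gene the ensemble is uncalled.
#'
#' @param calls Multi-tool call table.
#' @param config An [ensemble_config()].
#' @return A call table with `tool = "ensemble"`, same dialect as the
#'   input.
#' @export
ensemble_calls <- function(calls, config) {
  stopifnot(inherits(config, "ensemble_config"))
  calls <- validate_calls(calls, genes = union(config$genes,
                                               unique(calls$gene)))
  calls <- calls[calls$tool %in% config$ranked_tools &
                   calls$gene %in% config$genes, ]
  if (nrow(calls) == 0) stop("no calls from the configured tools in scope")

  key <- paste(calls$sample, calls$gene, sep = "\r")
  out <- lapply(split(seq_len(nrow(calls)), key), function(ix) {
    sub <- calls[ix, ]
    tc <- lapply(stats::setNames(config$ranked_tools, config$ranked_tools),
                 function(tl) {
                   r <- which(sub$tool == tl)
                   if (!length(r)) return(NULL)
                   a <- c(sub$allele1[r[1]], sub$allele2[r[1]])
                   a[!is.na(a)]
                 })
    slots <- ensemble_one(tc, config$ranked_tools)
    tibble::tibble(sample = sub$sample[1], tool = "ensemble",
                   gene = sub$gene[1],
                   allele1 = slots[1], allele2 = slots[2])
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$sample, .data$gene)
}

#' Score an ensemble and its constituent tools against a benchmark
#'
#' Runs [ensemble_calls()] and evaluates the ensemble and every roster
#' tool with [evaluate_tool()] on the same gene scope, for side-by-side
#' comparison.
#'
#' @inheritParams ensemble_calls
#' @param bench An `hla_benchmark` or benchmark tibble.
#' @return A list of class `hla_ensemble_eval`: `metrics` (one row per
#'   tool and for the ensemble, per HLA class) and `evaluations` (the
#'   underlying `hla_evaluation` objects).
#' @export
evaluate_ensemble <- function(calls, bench, config) {
  ens <- ensemble_calls(calls, config)
  evals <- lapply(config$ranked_tools, function(tl) {
    evaluate_tool(calls[calls$tool == tl, ], bench, tool = tl,
                  genes = config$genes)
  })
  names(evals) <- config$ranked_tools
  evals$ensemble <- evaluate_tool(ens, bench, tool = "ensemble",
                                  genes = config$genes)
  metrics <- dplyr::bind_rows(lapply(names(evals), function(nm) {
    dplyr::mutate(evals[[nm]]$metrics, tool = nm, .before = 1)
  }))
  structure(list(metrics = metrics, evaluations = evals, config = config),
            class = "hla_ensemble_eval")
}

#' @export
print.hla_ensemble_eval <- function(x, ...) {
  cat("Ensemble evaluation (", paste(x$config$ranked_tools, collapse = " > "),
      ")\n", sep = "")
  print(x$metrics)
  invisible(x)
}
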