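# Seeded synthetic cohorts with the statistical structure the analysis
# assumes: Hardy-Weinberg genotypes per gene, tool calls with per-allele
# error rates, dominant confusion partners and per-gene dropout, expression
# coupled to a strong-supertype-by-high-TMB interaction, and
# proportional-hazards survival driven by CYT.

#' Default per-gene allele frequency tables for simulation
#'
#' A compact pool of common class I alleles per gene with frequencies
#' summing to one, loosely shaped like European-ancestry cohort
#' frequencies (one dominant A allele, a broad tail).
#'
#' @return Tibble with columns `gene`, `allele`, `freq`.
#' @export
default_allele_freqs <- function() {
  tibble::tibble(
    gene = c(rep("A", 12), rep("B", 14), rep("C", 11)),
    allele = c(
      "A*01:01", "A*02:01", "A*03:01", "A*24:02", "A*11:01", "A*25:01",
      "A*26:01", "A*32:01", "A*68:01", "A*29:02", "A*30:01", "A*23:01",
      "B*07:02", "B*08:01", "B*44:02", "B*44:03", "B*35:01", "B*15:01",
      "B*40:01", "B*57:01", "B*58:01", "B*18:01", "B*27:05", "B*51:01",
      "B*14:02", "B*13:02",
      "C*07:01", "C*07:02", "C*04:01", "C*03:04", "C*06:02", "C*03:03",
      "C*05:01", "C*12:03", "C*01:02", "C*02:02", "C*08:02"),
    freq = c(
      0.16, 0.27, 0.13, 0.11, 0.06, 0.04, 0.04, 0.04, 0.04, 0.04, 0.03, 0.04,
      0.14, 0.12, 0.10, 0.08, 0.08, 0.07, 0.07, 0.05, 0.05, 0.06, 0.05, 0.07,
      0.03, 0.03,
      0.18, 0.16, 0.13, 0.10, 0.09, 0.07, 0.08, 0.06, 0.05, 0.05, 0.03))
}

#' Describe one simulated genotyping tool
#'
#' @param name Tool identifier.
#' @param error Baseline per-copy miscall probability for alleles without
#'   an override.
#' @param allele_error Named numeric vector of per-allele miscall
#'   probabilities overriding the baseline (names are allele strings).
#' @param confusion Named character vector mapping an allele to its
#'   dominant wrong-call partner; the partner may be any allele name,
#'   including a one-field truncation such as `"B58"`.
#' @param dominant_mass Probability that a miscall of a confused allele
#'   lands on its dominant partner (the rest is uniform over the other
#'   pool alleles of the gene).
#' @param dropout Named numeric vector of per-gene probabilities that the
#'   tool fails to call the gene for a sample (unnamed scalar = all
#'   genes).
#' @return List of class `sim_tool`.
#' @export
sim_tool <- function(name, error = 0.05, allele_error = NULL,
                     confusion = NULL, dominant_mass = 0.9, dropout = 0) {
  stopifnot(error >= 0, error <= 1, dominant_mass >= 0, dominant_mass <= 1,
            all(dropout >= 0), all(dropout <= 1))
  if (!is.null(allele_error)) {
    names(allele_error) <- hla_normalize(names(allele_error))
    stopifnot(all(allele_error >= 0), all(allele_error <= 1))
  }
  if (!is.null(confusion)) {
    names(confusion) <- hla_normalize(names(confusion))
    confusion[] <- hla_normalize(unname(confusion))
    if (any(names(confusion) == confusion)) {
      stop("confusion partner equals the true allele for ",
           names(confusion)[names(confusion) == confusion][1])
    }
  }
  structure(list(name = name, error = error, allele_error = allele_error,
                 confusion = confusion, dominant_mass = dominant_mass,
                 dropout = dropout),
            class = "sim_tool")
}

#' Default roster of eight simulated tools
#'
#' Eight tools with distinct error profiles echoing the patterns real HLA
#' genotypers display: mostly low baseline error, each with one or two
#' signature confusion pairs (including a low-resolution `B58` emitter),
#' and one tool that never calls gene C.
#'
#' @return Named list of [sim_tool()] descriptions.
#' @export
default_tool_roster <- function() {
  tools <- list(
    sim_tool("tool1", error = 0.03,
             allele_error = c("A*25:01" = 0.85),
             confusion = c("A*25:01" = "A*26:01")),
    sim_tool("tool2", error = 0.04,
             allele_error = c("A*02:01" = 0.12),
             confusion = c("A*02:01" = "A*02:13")),
    sim_tool("tool3", error = 0.05,
             allele_error = c("C*06:02" = 0.26),
             confusion = c("C*06:02" = "C*06:103")),
    sim_tool("tool4", error = 0.06,
             allele_error = c("C*07:01" = 0.23),
             confusion = c("C*07:01" = "C*07:02")),
    sim_tool("tool5", error = 0.08,
             allele_error = c("C*03:03" = 0.69),
             confusion = c("C*03:03" = "C*03:04")),
    sim_tool("tool6", error = 0.07,
             allele_error = c("B*58:01" = 0.50),
             confusion = c("B*58:01" = "B*58")),
    sim_tool("tool7", error = 0.12,
             allele_error = c("C*12:03" = 0.30),
             confusion = c("C*12:03" = "C*12:02"),
             dropout = c(A = 1)),
    sim_tool("tool8", error = 0.10,
             allele_error = c("B*44:02" = 0.30),
             confusion = c("B*44:02" = "B*83:01")))
  stats::setNames(tools, vapply(tools, `[[`, character(1), "name"))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort. The defaults describe the
#' conditions the pipeline is meant to be exercised under: a single
#' early-stage melanoma-like condition, eight tools with signature
#' confusion pairs, TMB log-normal around a median of 9.5 mutations/Mb,
#' a 2.5-fold CYT interaction multiplier when a strong supertype meets a
#' high TMB, and a protective CYT log-hazard of -0.8 per within-condition
#' standard deviation.
#'
#' @param seed Mandatory integer seed (< 2^31 - 3; sub-generators use
#'   `seed + 1` and `seed + 2`).
#' @param n_samples Cohort size.
#' @param genes Genes to simulate.
#' @param allele_freqs Per-gene allele frequency tibble
#'   ([default_allele_freqs()]); frequencies must sum to 1 per gene.
#' @param tools Named list of [sim_tool()] descriptions.
#' @param supertype_map Supertype map used to mark strong/weak carriers.
#' @param strong_supertype,weak_supertype Supertype labels treated as
#'   strong ("gun") and weak in the phenotype model.
#' @param conditions Character vector of cancer conditions
#'   (`"TYPE_early"` / `"TYPE_advanced"`); samples are spread evenly.
#' @param tmb_meanlog,tmb_sdlog Log-normal TMB parameters (mutations/Mb).
#' @param coding_mb Coding footprint used to convert TMB to mutation
#'   counts.
#' @param expr_meanlog,expr_sdlog Baseline log-scale GZMA/PRF1 TPM.
#' @param interaction_multiplier Multiplier applied to GZMA/PRF1 means
#'   when the strong supertype is present and TMB is above the condition
#'   median; 1 disables the planted interaction.
#' @param baseline_hazard Baseline death hazard per day.
#' @param beta_cyt Log-hazard per standard deviation of within-condition
#'   CYT (negative = protective).
#' @param censor_max Upper bound of the independent uniform censoring
#'   time in days.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_samples = 500,
                       genes = c("A", "B", "C"),
                       allele_freqs = default_allele_freqs(),
                       tools = default_tool_roster(),
                       supertype_map = default_supertype_map(),
                       strong_supertype = "B44",
                       weak_supertype = "A02",
                       conditions = "SKCM_early",
                       tmb_meanlog = log(9.5),
                       tmb_sdlog = 0.8,
                       coding_mb = 38,
                       expr_meanlog = log(20),
                       expr_sdlog = 0.5,
                       interaction_multiplier = 2.5,
                       baseline_hazard = 1 / 1500,
                       beta_cyt = -0.8,
                       censor_max = 3000) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is mandatory for simulation")
  }
  seed <- as.integer(seed)
  allele_freqs <- allele_freqs[allele_freqs$gene %in% genes, ]
  if (nrow(allele_freqs) == 0) stop("empty allele frequency table")
  sums <- tapply(allele_freqs$freq, allele_freqs$gene, sum)
  if (any(abs(sums - 1) > 1e-8)) {
    stop("allele frequencies must sum to 1 per gene (off for: ",
         paste(names(sums)[abs(sums - 1) > 1e-8], collapse = ", "), ")")
  }
  if (baseline_hazard <= 0 || censor_max <= 0) {
    stop("hazard parameters must be positive")
  }
  stopifnot(all(vapply(tools, inherits, logical(1), "sim_tool")))
  structure(list(
    seed = seed, n_samples = n_samples, genes = genes,
    allele_freqs = allele_freqs, tools = tools,
    supertype_map = supertype_map,
    strong_supertype = strong_supertype, weak_supertype = weak_supertype,
    conditions = conditions, tmb_meanlog = tmb_meanlog,
    tmb_sdlog = tmb_sdlog, coding_mb = coding_mb,
    expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
    interaction_multiplier = interaction_multiplier,
    baseline_hazard = baseline_hazard, beta_cyt = beta_cyt,
    censor_max = censor_max), class = "sim_config")
}

#' Simulate true genotypes
#'
#' Draws two allele copies per gene independently from the gene's
#' frequency table (Hardy-Weinberg sampling). Fully reproducible under
#' the configured seed.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with `sample`, `gene`, `allele1`, `allele2`.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed)
  samples <- sprintf("S%05d", seq_len(cfg$n_samples))
  out <- lapply(cfg$genes, function(g) {
    pool <- cfg$allele_freqs[cfg$allele_freqs$gene == g, ]
    a1 <- sample(pool$allele, cfg$n_samples, replace = TRUE, prob = pool$freq)
    a2 <- sample(pool$allele, cfg$n_samples, replace = TRUE, prob = pool$freq)
    tibble::tibble(sample = samples, gene = g, allele1 = a1, allele2 = a2)
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$sample, .data$gene)
}

# Miscall one vector of true allele copies for one tool (vectorized per
# gene pool).
miscall_copies <- function(alleles, gene, tool, pool) {
  n <- length(alleles)
  rate <- rep(tool$error, n)
  if (!is.null(tool$allele_error)) {
    ov <- tool$allele_error[alleles]
    rate[!is.na(ov)] <- ov[!is.na(ov)]
  }
  err <- stats::runif(n) < rate
  out <- alleles
  if (!any(err)) return(out)
  idx <- which(err)
  partner <- rep(NA_character_, length(idx))
  if (!is.null(tool$confusion)) partner <- tool$confusion[alleles[idx]]
  use_dom <- !is.na(partner) & stats::runif(length(idx)) < tool$dominant_mass
  out[idx[use_dom]] <- partner[use_dom]
  rest <- idx[!use_dom]
  if (length(rest)) {
    out[rest] <- vapply(alleles[rest], function(a) {
      others <- setdiff(pool, a)
      if (!length(others)) stop("gene pool too small to draw a wrong allele")
      others[sample.int(length(others), 1)]
    }, character(1))
  }
  out
}

#' Simulate multi-tool genotype calls
#'
#' Each true allele copy is miscalled independently with the tool's
#' per-allele error rate; a miscall lands on the tool's dominant
#' confusion partner with the configured mass and otherwise uniformly on
#' another pool allele of the gene. Whole (tool, gene, sample) calls are
#' dropped with the tool's per-gene dropout probability (emitted as
#' uncalled rows).
#'
#' @param truth Output of [simulate_truth()].
#' @param cfg A [sim_config()].
#' @return Multi-tool call table (`sample`, `tool`, `gene`, `allele1`,
#'   `allele2`).
#' @export
simulate_tool_calls <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed + 1L)
  pools <- split(cfg$allele_freqs$allele, cfg$allele_freqs$gene)
  out <- lapply(cfg$tools, function(tool) {
    res <- truth
    res$tool <- tool$name
    for (g in unique(res$gene)) {
      i <- which(res$gene == g)
      res$allele1[i] <- miscall_copies(res$allele1[i], g, tool, pools[[g]])
      res$allele2[i] <- miscall_copies(res$allele2[i], g, tool, pools[[g]])
      dr <- if (length(tool$dropout) == 1 && is.null(names(tool$dropout))) {
        tool$dropout
      } else if (g %in% names(tool$dropout)) tool$dropout[[g]] else 0
      if (dr > 0) {
        gone <- stats::runif(length(i)) < dr
        res$allele1[i[gone]] <- NA_character_
        res$allele2[i[gone]] <- NA_character_
      }
    }
    res
  })
  out <- dplyr::bind_rows(out)[c("sample", "tool", "gene",
                                 "allele1", "allele2")]
  dplyr::arrange(out, .data$sample, .data$tool, .data$gene)
}

#' Simulate expression, mutations, and clinical follow-up
#'
#' TMB is log-normal per condition and realized as MAF-style mutation
#' rows (nonsynonymous keywords plus synonymous decoys). GZMA and PRF1
#' are log-normal with the interaction multiplier applied when the strong
#' supertype is present and TMB is above the condition median. Survival
#' times are exponential with hazard
#' `baseline_hazard * exp(beta_cyt * z(CYT))` (z-scored within
#' condition), censored by an independent uniform time.
#'
#' @param truth Output of [simulate_truth()].
#' @param cfg A [sim_config()].
#' @return List with `expression` (2 x n matrix, rows GZMA/PRF1), `maf`,
#'   `clinical`, and `latent` (per-sample true TMB, presence flags, CYT
#'   and hazard, for closing-the-loop tests).
#' @export
simulate_phenotypes <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::local_seed(cfg$seed + 2L)
  samples <- unique(truth$sample)
  n <- length(samples)
  condition <- rep(cfg$conditions, length.out = n)

  # strong/weak supertype carriers from the true class I genotype
  classI <- truth[hla_class(truth$gene) == "I", ]
  long <- tidyr::pivot_longer(classI, c("allele1", "allele2"),
                              names_to = "slot", values_to = "allele")
  long$st <- assign_supertype(long$allele, cfg$supertype_map)
  strong <- samples %in% long$sample[long$st == cfg$strong_supertype]
  weak <- samples %in% long$sample[long$st == cfg$weak_supertype]

  n_nonsyn <- pmax(0L, as.integer(round(
    stats::rlnorm(n, cfg$tmb_meanlog, cfg$tmb_sdlog) * cfg$coding_mb)))
  tmb <- n_nonsyn / cfg$coding_mb
  tmb_high <- as.logical(stats::ave(tmb, condition, FUN = function(v) {
    v > stats::median(v)
  }))

  boost <- ifelse(strong & tmb_high, log(cfg$interaction_multiplier), 0)
  gzma <- stats::rlnorm(n, cfg$expr_meanlog + boost, cfg$expr_sdlog)
  prf1 <- stats::rlnorm(n, cfg$expr_meanlog + boost, cfg$expr_sdlog)
  cyt <- cyt_score(gzma, prf1)

  z <- stats::ave(log(cyt), condition, FUN = function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  hazard <- cfg$baseline_hazard * exp(cfg$beta_cyt * z)
  t_death <- stats::rexp(n, rate = hazard)
  t_cens <- stats::runif(n, 0, cfg$censor_max)
  time <- round(pmin(t_death, t_cens), 1)
  event <- t_death <= t_cens

  # MAF rows: nonsynonymous keywords plus ~40% synonymous decoys
  kw <- tmb_keywords()
  n_syn <- as.integer(round(0.4 * n_nonsyn))
  maf <- tibble::tibble(
    Tumor_Sample_Barcode = c(rep(samples, n_nonsyn), rep(samples, n_syn)),
    One_Consequence = c(sample(kw, sum(n_nonsyn), replace = TRUE),
                        rep("synonymous_variant", sum(n_syn))))

  stage_pool <- list(early = c("stage i", "stage ii"),
                     advanced = c("stage iii", "stage iv"))
  stage_cls <- ifelse(grepl("_advanced$", condition), "advanced", "early")
  tumor_stage <- vapply(stage_cls, function(s) sample(stage_pool[[s]], 1),
                        character(1))
  clinical <- tibble::tibble(
    sample = samples,
    vital_status = ifelse(event, "Dead", "Alive"),
    days_to_death = ifelse(event, time, NA_real_),
    days_to_last_follow_up = ifelse(event, NA_real_, time),
    tumor_stage = tumor_stage,
    age = pmin(90, pmax(25, round(stats::rnorm(n, 60, 10)))),
    cancer_type = sub("_(early|advanced)$", "", condition))

  expression <- rbind(GZMA = gzma, PRF1 = prf1)
  colnames(expression) <- samples

  list(expression = expression, maf = maf, clinical = clinical,
       latent = tibble::tibble(sample = samples, condition = condition,
                               strong_present = strong, weak_present = weak,
                               tmb = tmb, tmb_high = unname(tmb_high),
                               gzma = gzma, prf1 = prf1, cyt = cyt, z = z,
                               hazard = hazard, time = time, event = event))
}

#' Simulate a full cohort
#'
#' Runs [simulate_truth()], [simulate_tool_calls()] and
#' [simulate_phenotypes()] under one configuration.
#'
#' @param cfg A [sim_config()].
#' @return List with `truth`, `calls`, `phenotypes` and the `config`.
#' @export
simulate_cohort <- function(cfg) {
  truth <- simulate_truth(cfg)
  calls <- simulate_tool_calls(truth, cfg)
  phenotypes <- simulate_phenotypes(truth, cfg)
  list(truth = truth, calls = calls, phenotypes = phenotypes, config = cfg)
}
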