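# Overall-survival derivation from clinical fields and group comparison:
# Kaplan-Meier curves, log-rank tests and Cox proportional-hazards models
# (fits delegated to the survival package, Breslow tie handling).

#' Derive overall survival from clinical fields
#'
#' Patients alive at last contact are censored at
#' `days_to_last_follow_up`; deceased patients contribute an event at
#' `days_to_death`. Records whose required day field is missing or
#' negative, or whose vital status is not alive/dead (case-insensitive),
#' are rejected with a warning; the rejected rows and reasons are attached
#' as the `rejected` attribute.
#'
#' @param clinical Tibble with columns `sample`, `vital_status`,
#'   `days_to_death`, `days_to_last_follow_up`.
#' @return Tibble with `sample`, `time` (days) and `event` (TRUE = death
#'   observed).
#' @export
derive_os <- function(clinical) {
  need <- c("sample", "vital_status", "days_to_death",
            "days_to_last_follow_up")
  miss <- setdiff(need, names(clinical))
  if (length(miss)) {
    stop("clinical table is missing column(s): ", paste(miss, collapse = ", "))
  }
  vs <- tolower(trimws(as.character(clinical$vital_status)))
  dtd <- suppressWarnings(as.numeric(clinical$days_to_death))
  dtf <- suppressWarnings(as.numeric(clinical$days_to_last_follow_up))

  time <- ifelse(vs == "dead", dtd, ifelse(vs == "alive", dtf, NA_real_))
  event <- vs == "dead"
  reason <- dplyr::case_when(
    !vs %in% c("alive", "dead") ~ "unrecognized vital_status",
    is.na(time) ~ "required day field missing",
    time < 0 ~ "negative survival time",
    TRUE ~ NA_character_)
  ok <- is.na(reason)
  if (!all(ok)) {
    warning(sum(!ok), " clinical record(s) rejected (",
            paste(unique(reason[!ok]), collapse = "; "), ")")
  }
  out <- tibble::tibble(sample = as.character(clinical$sample)[ok],
                        time = time[ok], event = event[ok])
  attr(out, "rejected") <- tibble::tibble(
    sample = as.character(clinical$sample)[!ok], reason = reason[!ok])
  out
}

#' Classify free-text tumor stage into early/advanced
#'
#' Normalizes case and sub-stage suffixes (`"Stage IIIA"` reduces to
#' `iii`) and maps stages 0, i and ii to `early` and iii, iv and x to
#' `advanced`. Unrecognized tokens become `NA` with a warning.
#'
#' @param tumor_stage Character vector of stage annotations.
#' @return Factor with levels `early`, `advanced`.
#' @export
classify_stage <- function(tumor_stage) {
  tok <- tolower(trimws(as.character(tumor_stage)))
  tok <- sub("^stage\\s*", "", tok)
  m <- regmatches(tok, regexpr("^(iv|iii|ii|i|0|x)", tok))
  base <- rep(NA_character_, length(tok))
  base[regexpr("^(iv|iii|ii|i|0|x)", tok) > 0] <- m
  out <- dplyr::case_when(
    base %in% c("0", "i", "ii") ~ "early",
    base %in% c("iii", "iv", "x") ~ "advanced",
    TRUE ~ NA_character_)
  bad <- is.na(out) & !is.na(tumor_stage)
  if (any(bad)) {
    warning("unrecognized tumor_stage value(s), e.g. '",
            tumor_stage[bad][1], "'; left unclassified")
  }
  factor(out, levels = c("early", "advanced"))
}

#' Kaplan-Meier product-limit curve
#'
#' @param time Nonnegative follow-up times.
#' @param event Logical (or 0/1) event indicator.
#' @return List of class `km_curve` with `curve` (tibble `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`) and `median`, the smallest
#'   time at which survival drops to 0.5 or below (`NA` when the curve
#'   never reaches 0.5).
#' @export
km_curve <- function(time, event) {
  if (!length(time)) stop("no survival records")
  if (any(is.na(time)) || any(time < 0)) stop("times must be nonnegative")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  curve <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                          n_event = fit$n.event, n_censor = fit$n.censor,
                          surv = fit$surv)
  drop <- curve$time[curve$surv <= 0.5 + 1e-12]
  structure(list(curve = curve,
                 median = if (length(drop)) min(drop) else NA_real_,
                 n = length(time), events = sum(as.integer(event))),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: ", x$n, " records, ", x$events, " events, median ",
      if (is.na(x$median)) "not reached" else x$median, "\n", sep = "")
  invisible(x)
}

#' Survival probability at given times
#'
#' Evaluates the right-continuous step function of a [km_curve()].
#'
#' @param km A `km_curve` object.
#' @param t Times at which to evaluate survival.
#' @return Numeric survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  steps <- km$curve[km$curve$n_event > 0, ]
  vapply(t, function(tt) {
    i <- which(steps$time <= tt)
    if (!length(i)) 1 else steps$surv[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square with one degree of freedom. When one
#' group has no events the statistic is still returned but flagged
#' low-information.
#'
#' @param time,event Survival times and event indicators.
#' @param group Two-level grouping vector.
#' @return List with `statistic`, `df`, `p_value`, `low_information` and
#'   the per-group observed/expected table.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) != 2) stop("log-rank test needs exactly two groups")
  if (any(table(group) == 0)) stop("both groups must be non-empty")
  event <- as.integer(event)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd$chisq
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  low <- any(tapply(event, group, sum) == 0)
  list(statistic = unname(stat), df = 1L, p_value = unname(p),
       low_information = low,
       table = tibble::tibble(group = levels(group), n = as.integer(sd$n),
                              observed = sd$obs, expected = sd$exp))
}

#' Cox proportional-hazards regression (Breslow ties)
#'
#' Fits a proportional-hazards model by partial-likelihood maximization
#' with the Breslow approximation for ties and reports hazard ratios with
#' Wald confidence intervals and p-values. Covariates constant across
#' samples are reported with coefficient 0 / hazard ratio 1 and flagged
#' `degenerate` instead of entering the fit; suspected monotone likelihood
#' (perfect separation) is flagged `separation`.
#'
#' @param time,event Survival times and event indicators.
#' @param covariates Data frame of covariates (numeric, or two-level
#'   factors/characters which are dummy-coded).
#' @param conf_level Confidence level for the hazard-ratio interval.
#' @return Tibble with `term`, `coef`, `hr`, `se`, `z`, `p_value`,
#'   `ci_lower`, `ci_upper`, `flag`.
#' @export
cox_hr <- function(time, event, covariates, conf_level = 0.95) {
  covariates <- as.data.frame(covariates)
  if (!nrow(covariates) || nrow(covariates) != length(time)) {
    stop("covariates must have one row per survival record")
  }
  if (sum(as.integer(event)) < 1) stop("at least one event is required")

  X <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) return(v)
    f <- droplevels(as.factor(v))
    if (nlevels(f) > 2) {
      stop("covariate '", nm, "' has more than two levels; dummy-code it")
    }
    as.integer(f == levels(f)[nlevels(f)])
  })
  names(X) <- names(covariates)
  X <- as.data.frame(X)
  if (any(!stats::complete.cases(X))) stop("covariates must be finite")

  constant <- unname(vapply(X, function(v) length(unique(v)) == 1,
                            logical(1)))
  res <- tibble::tibble(term = names(X), coef = 0, hr = 1, se = NA_real_,
                        z = NA_real_, p_value = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        flag = ifelse(constant, "degenerate", ""))
  fit_terms <- names(X)[!constant]
  if (length(fit_terms)) {
    dat <- cbind(data.frame(.time = time, .event = as.integer(event)),
                 X[fit_terms])
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~",
      paste(sprintf("`%s`", fit_terms), collapse = " + ")))
    fit <- survival::coxph(fml, data = dat, ties = "breslow")
    sm <- summary(fit, conf.int = conf_level)
    i <- match(fit_terms, res$term)
    res$coef[i] <- unname(stats::coef(fit))
    res$hr[i] <- exp(res$coef[i])
    res$se[i] <- unname(sm$coefficients[, "se(coef)"])
    res$z[i] <- unname(sm$coefficients[, "z"])
    res$p_value[i] <- unname(sm$coefficients[, "Pr(>|z|)"])
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    res$ci_lower[i] <- exp(res$coef[i] - zq * res$se[i])
    res$ci_upper[i] <- exp(res$coef[i] + zq * res$se[i])
    sep <- abs(res$coef[i]) > 15 | res$se[i] > 100
    res$flag[i][sep] <- "separation"
  }
  res
}

#' Compare survival between two labelled groups
#'
#' Convenience wrapper producing the per-contrast summary used by the
#' Gun-Bullet analysis: group sizes, deaths, KM medians, the log-rank
#' test and the univariate Cox hazard ratio of group A vs group B.
#'
#' @param records Tibble with `time`, `event` and a `group` column.
#' @param groups Length-2 character vector naming the two groups to
#'   compare (group A first; the hazard ratio is A vs B).
#' @return One-row tibble with the comparison summary.
#' @export
compare_survival <- function(records, groups) {
  stopifnot(length(groups) == 2)
  sub <- records[records$group %in% groups & !is.na(records$group) &
                   !is.na(records$time), ]
  if (!nrow(sub)) stop("no records in the requested groups")
  a <- sub[sub$group == groups[1], ]
  b <- sub[sub$group == groups[2], ]
  if (!nrow(a) || !nrow(b)) stop("both groups must be non-empty")
  lr <- logrank_test(sub$time, sub$event, sub$group == groups[1])
  cx <- cox_hr(sub$time, sub$event,
               data.frame(groupA = as.integer(sub$group == groups[1])))
  tibble::tibble(
    group_a = groups[1], group_b = groups[2],
    n_a = nrow(a), n_b = nrow(b),
    deaths_a = sum(a$event), deaths_b = sum(b$event),
    median_a = km_curve(a$time, a$event)$median,
    median_b = km_curve(b$time, b$event)$median,
    logrank_stat = lr$statistic, logrank_p = lr$p_value,
    hr = cx$hr[1], hr_ci_lower = cx$ci_lower[1], hr_ci_upper = cx$ci_upper[1],
    hr_p = cx$p_value[1])
}
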