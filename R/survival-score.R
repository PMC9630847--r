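# Per-gene univariate Cox hazard estimation, hazard-weighted per-patient
# score, maximally-selected cut-point stratification, and KM/log-rank
# comparison.

validate_survival <- function(survival) {
  stopifnot(is.data.frame(survival),
            all(c("sample", "time", "event") %in% names(survival)))
  if (any(survival$time <= 0)) abort("Survival times must be > 0.")
  if (!all(survival$event %in% c(0, 1))) abort("`event` must be 0/1.")
  invisible(survival)
}

#' Univariate Cox proportional-hazards estimate for one gene
#'
#' Fits `Surv(time, event) ~ expression` by partial likelihood with Breslow
#' tie handling (Efron available via `ties`) and reports the hazard ratio
#' `HR = exp(coef)` with its two-sided Wald p-value. A cohort with no events
#' is an error; a constant expression vector or a non-converged fit is
#' returned flagged rather than failing.
#'
#' @param gene_expr Named numeric vector (names = sample ids), typically
#'   z-normalized log2 expression.
#' @param survival Survival tibble (`sample`, `time`, `event`).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param gene Gene label carried into the output.
#' @return One-row tibble: `gene`, `hr`, `coef`, `wald_p`, `n`, `n_events`,
#'   `status` (`"ok"`, `"constant"`, or `"not_converged"`).
#' @export
cox_univariate <- function(gene_expr, survival, ties = "breslow",
                           gene = "gene") {
  validate_survival(survival)
  if (!is.null(names(gene_expr))) {
    shared <- intersect(names(gene_expr), survival$sample)
    survival <- survival[match(shared, survival$sample), ]
    gene_expr <- gene_expr[shared]
  }
  if (length(gene_expr) != nrow(survival)) {
    abort("Expression and survival samples do not align.")
  }
  n_events <- sum(survival$event)
  if (n_events == 0L) abort("No events in the cohort; Cox fit undefined.")
  if (n_events < 2L) abort("Need at least 2 events.")
  if (sd(gene_expr) == 0) {
    return(tibble(gene = gene, hr = NA_real_, coef = NA_real_,
                  wald_p = NA_real_, n = length(gene_expr),
                  n_events = n_events, status = "constant"))
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(survival$time, survival$event) ~ gene_expr,
                    ties = ties),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(
        survival::coxph(
          survival::Surv(survival$time, survival$event) ~ gene_expr,
          ties = ties))
    })
  if (is.null(fit) || !is.finite(coef(fit))) {
    return(tibble(gene = gene, hr = NA_real_, coef = NA_real_,
                  wald_p = NA_real_, n = length(gene_expr),
                  n_events = n_events, status = "not_converged"))
  }
  sm <- summary(fit)
  tibble(gene = gene, hr = unname(exp(coef(fit))), coef = unname(coef(fit)),
         wald_p = unname(sm$coefficients[1, "Pr(>|z|)"]),
         n = length(gene_expr), n_events = n_events, status = "ok")
}

#' Per-gene Cox screen over an expression table
#'
#' Runs [cox_univariate()] for every gene row. Expression should be log2 and
#' z-normalized ([z_normalize()]) so hazard ratios are per standard
#' deviation.
#'
#' @param expr Expression tibble (genes x samples).
#' @param survival Survival tibble.
#' @param ties Tie handling, as in [cox_univariate()].
#' @return Tibble with one [cox_univariate()] row per gene.
#' @export
cox_screen <- function(expr, survival, ties = "breslow") {
  m <- expr_as_matrix(expr)
  purrr::map_dfr(rownames(m), function(gn) {
    cox_univariate(m[gn, ], survival, ties = ties, gene = gn)
  })
}

#' Select genes with significant hazard ratios
#'
#' @param estimates Tibble from [cox_screen()].
#' @param alpha Wald-p threshold (default 0.05).
#' @return Character vector of gene names; an empty roster raises a warning
#'   of class `triadnet_empty_roster` (never silent).
#' @export
select_significant <- function(estimates, alpha = 0.05) {
  stopifnot(all(c("gene", "wald_p") %in% names(estimates)))
  roster <- estimates |>
    filter(!is.na(.data$wald_p), .data$wald_p < alpha) |>
    pull("gene")
  if (length(roster) == 0L) {
    warn("No gene reached the hazard-ratio significance threshold.",
         class = "triadnet_empty_roster")
  }
  roster
}

#' Hazard-weighted per-patient score
#'
#' The score of patient s is the mean over the significant-gene roster of the
#' patient's z-normalized expression weighted by the gene's hazard ratio:
#' `score(s) = (1 / n_genes) * sum_g e[g, s] * HR[g]`. Input must already be
#' z-normalized per gene (checked; un-normalized input is an error), and the
#' roster must be non-empty.
#'
#' @param z_expr Z-normalized expression tibble restricted (or restrictable)
#'   to the roster.
#' @param estimates Tibble from [cox_screen()] providing `gene` and `hr`.
#' @param roster Optional gene roster (defaults to all genes shared between
#'   `z_expr` and `estimates`).
#' @return Object of class `ptp_score_result`: tibble `sample`, `score`, with
#'   attributes `roster` and `weights` (named HR vector).
#' @export
ptp_score <- function(z_expr, estimates, roster = NULL) {
  m <- expr_as_matrix(z_expr)
  if (!is_z_normalized(z_expr)) {
    abort("`z_expr` must be z-normalized per gene (see z_normalize()).")
  }
  roster <- roster %||% intersect(rownames(m), estimates$gene)
  if (length(roster) == 0L) abort("Empty gene roster; no score defined.")
  if (!all(roster %in% rownames(m))) {
    abort("Roster genes missing from the expression table.")
  }
  w <- estimates$hr[match(roster, estimates$gene)]
  if (anyNA(w)) abort("Missing hazard ratio for some roster genes.")
  sc <- colSums(m[roster, , drop = FALSE] * w) / length(roster)
  out <- tibble(sample = colnames(m), score = unname(sc))
  class(out) <- c("ptp_score_result", class(out))
  attr(out, "roster") <- roster
  attr(out, "weights") <- setNames(w, roster)
  out
}

#' @method tidy ptp_score_result
#' @export
tidy.ptp_score_result <- function(x, ...) {
  tibble(sample = x$sample, score = x$score)
}

#' @method glance ptp_score_result
#' @export
glance.ptp_score_result <- function(x, ...) {
  tibble(n_samples = nrow(x), n_genes = length(attr(x, "roster")),
         mean_score = mean(x$score), sd_score = sd(x$score))
}

# Log-rank scores (observed event minus Nelson-Aalen cumulative hazard at the
# observation time): the building block of the maximally selected statistic.
logrank_scores <- function(time, event) {
  o <- order(time)
  t_o <- time[o]
  e_o <- event[o]
  n <- length(t_o)
  at_risk <- n - seq_len(n) + 1
  # Nelson-Aalen increments at distinct times, in increasing time order.
  tf <- factor(t_o, levels = unique(t_o))
  d <- tapply(e_o, tf, sum)              # events per distinct time
  r <- tapply(at_risk, tf, max)          # risk set size at each distinct time
  haz <- cumsum(d / r)
  cumhaz <- haz[as.integer(tf)]
  sc <- numeric(n)
  sc[o] <- e_o - cumhaz
  sc
}

#' Optimal cut-point by the maximally selected log-rank statistic
#'
#' Scans every observed score value whose induced split respects the minimum
#' group proportion, standardizes the log-rank statistic of each split with
#' the permutation variance (Lausen-Schumacher form), and returns the
#' cut-point maximizing the absolute standardized statistic; ties take the
#' lower cut-point. The split assigns `score > cutpoint` to the high group.
#' The associated log-rank p-value is selection-biased (maximum over many
#' candidate splits) and is reported as such.
#'
#' @param score Numeric score vector.
#' @param survival Survival tibble aligned with `score` (by `sample` names of
#'   `score` when present, otherwise by position).
#' @param minprop Minimum proportion of samples in either group
#'   (default 0.1).
#' @return One-row tibble: `cutpoint`, `statistic` (|standardized log-rank|),
#'   `n_high`, `n_low`.
#' @export
optimal_cutpoint <- function(score, survival, minprop = 0.1) {
  validate_survival(survival)
  if (inherits(score, "ptp_score_result")) {
    score <- setNames(score$score, score$sample)
  }
  if (!is.null(names(score))) {
    survival <- survival[match(names(score), survival$sample), ]
  }
  stopifnot(length(score) == nrow(survival))
  if (length(unique(score)) < 2L) {
    abort("All scores equal; no cut-point exists.")
  }
  n <- length(score)
  a <- logrank_scores(survival$time, survival$event)
  ssq <- sum((a - mean(a))^2)
  o <- order(score)
  s_sorted <- score[o]
  a_sorted <- a[o]
  csum <- cumsum(a_sorted)
  # candidate cut after position i: low group = first i sorted samples
  is_cand <- seq_len(n - 1L) >= ceiling(minprop * n) &
    seq_len(n - 1L) <= floor((1 - minprop) * n) &
    s_sorted[-n] != s_sorted[-1L]       # cut only between distinct values
  if (!any(is_cand)) {
    abort("No admissible cut-point under the minimum group proportion.")
  }
  idx <- which(is_cand)
  m_low <- idx
  u <- csum[idx] - m_low * mean(a)
  v <- m_low * (n - m_low) / (n * (n - 1)) * ssq
  z <- abs(u) / sqrt(v)
  best <- idx[which.max(z)]             # which.max takes the first maximum
  tibble(cutpoint = unname(s_sorted[best]), statistic = unname(max(z)),
         n_high = as.integer(n - best), n_low = as.integer(best))
}

#' Two-group log-rank test with KM curves
#'
#' Standard two-group log-rank chi-square (1 df) via the Mantel-Haenszel
#' form, with per-group Kaplan-Meier estimates attached for plotting.
#' Identical groups give chi-square 0 and p = 1.
#'
#' @param groups Binary/two-level label vector aligned with `survival` (by
#'   names when present).
#' @param survival Survival tibble.
#' @return One-row tibble `chisq`, `df`, `p_value`, `n_groups`, with the
#'   [survival::survfit] object in attribute `km_fit`.
#' @export
km_logrank <- function(groups, survival) {
  validate_survival(survival)
  if (!is.null(names(groups))) {
    survival <- survival[match(names(groups), survival$sample), ]
  }
  stopifnot(length(groups) == nrow(survival))
  groups <- factor(groups)
  if (nlevels(groups) != 2L) abort("Exactly two groups are required.")
  surv_obj <- survival::Surv(survival$time, survival$event)
  sd_fit <- survival::survdiff(surv_obj ~ groups)
  chisq <- unname(sd_fit$chisq)
  p <- pchisq(chisq, df = 1L, lower.tail = FALSE)
  km <- survival::survfit(surv_obj ~ groups)
  out <- tibble(chisq = chisq, df = 1L, p_value = p, n_groups = 2L)
  attr(out, "km_fit") <- km
  out
}

#' End-to-end survival stratification by hazard-weighted score
#'
#' Convenience pipeline: z-normalize, per-gene Cox screen, significant-gene
#' roster, hazard-weighted score, optimal cut-point, and the (selection-
#' biased) high-vs-low log-rank comparison.
#'
#' @param expr Log2 expression tibble (genes x samples).
#' @param survival Survival tibble.
#' @param alpha Roster significance threshold.
#' @param minprop Minimum group proportion for the cut-point.
#' @return List: `estimates`, `roster`, `score` (`ptp_score_result`),
#'   `cutpoint` (tibble), `logrank` (tibble), `groups` (named character
#'   vector, "high"/"low").
#' @export
score_stratify <- function(expr, survival, alpha = 0.05, minprop = 0.1) {
  z <- suppressWarnings(z_normalize(expr))
  est <- cox_screen(z, survival)
  roster <- select_significant(est, alpha = alpha)
  if (length(roster) == 0L) {
    return(list(estimates = est, roster = roster, score = NULL,
                cutpoint = NULL, logrank = NULL, groups = NULL))
  }
  sc <- ptp_score(z, est, roster = roster)
  cp <- optimal_cutpoint(sc, survival, minprop = minprop)
  grp <- setNames(ifelse(sc$score > cp$cutpoint, "high", "low"), sc$sample)
  lr <- km_logrank(grp, survival)
  list(estimates = est, roster = roster, score = sc, cutpoint = cp,
       logrank = lr, groups = grp)
}
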