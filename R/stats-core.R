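# Shared statistical primitives used by every screen in the package.

#' Spearman rank correlation with a two-sided p-value
#'
#' Computes Spearman's Rs as the Pearson correlation of mid-ranks (average
#' ranks for ties) with a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom, the
#' convention used at cohort sample sizes. On tie-free vectors Rs equals the
#' classical `1 - 6 * sum(d^2) / (n * (n^2 - 1))`.
#'
#' A constant input vector leaves the correlation undefined; rather than
#' silently returning 0, the result carries `rho = NA` and
#' `status = "constant"`.
#'
#' @param x,y Numeric vectors of equal length (at least 3), finite values.
#' @return A one-row tibble with columns `rho`, `p_value`, `n`, `status`
#'   (`"ok"` or `"constant"`).
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("Need at least 3 paired observations.")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("`x` and `y` must be finite.")
  }
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n,
                  status = "constant"))
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE, continuity = FALSE)
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = n, status = "ok")
}

# Vectorised Spearman over the columns of `xm` against the columns of `ym`,
# assuming complete data; used by the drug screens where the pair count is
# large. Returns rho and t-approximation p matrices. Mid-ranks per column,
# then Pearson via crossprod of standardised ranks -- identical numbers to
# spearman_cor() on each pair.
spearman_matrix <- function(xm, ym) {
  n <- nrow(xm)
  stopifnot(nrow(ym) == n, n >= 3L)
  rx <- apply(xm, 2L, rank)
  ry <- apply(ym, 2L, rank)
  rx <- scale(rx)
  ry <- scale(ry)
  rho <- crossprod(rx, ry) / (n - 1)
  rho[!is.finite(rho)] <- NA_real_
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[rho == 1 | rho == -1] <- 0
  list(rho = rho, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment. Output order matches input order; adjusted values
#' are never smaller than the raw values and are capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return A tibble with columns `p` (input) and `fdr` (BH-adjusted),
#'   index-aligned with the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  tibble(p = p, fdr = p.adjust(p, method = "BH"))
}

#' Per-gene z-normalization of an expression table
#'
#' Centers and scales each gene row to mean 0 and unit standard deviation
#' (sample convention, `n - 1` denominator). Constant rows become all-zero
#' and are flagged via the `constant_genes` attribute and a warning.
#'
#' @param expr Expression tibble: first column gene identifiers, remaining
#'   columns one per sample, log2 scale.
#' @return A tibble of the same shape with attributes `z_normalized = TRUE`
#'   and `constant_genes` (character vector, possibly empty).
#' @export
z_normalize <- function(expr) {
  m <- expr_as_matrix(expr)
  if (nrow(m) == 0L || ncol(m) == 0L) abort("Expression table is empty.")
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  const <- rownames(m)[s == 0]
  if (length(const) > 0) {
    warn(paste0("Constant gene rows set to zero after z-normalization: ",
                paste(const, collapse = ", ")))
  }
  s[s == 0] <- 1
  z <- (m - mu) / s
  out <- matrix_as_expr(z, id_col = names(expr)[1])
  attr(out, "z_normalized") <- TRUE
  attr(out, "constant_genes") <- const
  out
}

is_z_normalized <- function(expr, tol = 1e-8) {
  if (isTRUE(attr(expr, "z_normalized"))) return(TRUE)
  m <- expr_as_matrix(expr)
  s <- apply(m, 1L, sd)
  all(abs(rowMeans(m)) < tol) && all(abs(s - 1) < tol | s < tol)
}

#' Per-group alteration frequency
#'
#' Frequency of altered samples (proportion of samples in a group carrying a
#' mutation / copy-number event) for every gene and group.
#'
#' @param alterations Tibble: first column sample identifiers, remaining
#'   columns one binary (0/1) indicator per gene.
#' @param groups Tibble with columns `sample` and `group`.
#' @return Tibble with columns `group`, `gene`, `n_altered`, `n`, `frequency`.
#' @export
alteration_frequency <- function(alterations, groups) {
  stopifnot(is.data.frame(alterations), is.data.frame(groups))
  if (!all(c("sample", "group") %in% names(groups))) {
    abort("`groups` needs columns `sample` and `group`.")
  }
  vals <- as.matrix(alterations[-1])
  if (!all(vals %in% c(0, 1))) abort("Alteration matrix must be binary 0/1.")
  long <- alterations |>
    rename(sample = 1) |>
    tidyr::pivot_longer(-"sample", names_to = "gene", values_to = "altered") |>
    inner_join(groups, by = "sample")
  long |>
    group_by(.data$group, .data$gene) |>
    summarise(n_altered = sum(.data$altered), n = n(),
              frequency = sum(.data$altered) / n(), .groups = "drop")
}

#' Wilcoxon rank-sum test with log fold-change
#'
#' Two-sided Wilcoxon rank-sum p-value together with the log fold-change,
#' defined as `mean(a) - mean(b)` on log2-scale inputs (difference of group
#' means; the scale choice is documented in the methods vignette).
#'
#' @param a,b Numeric vectors (each of length at least 2), log2 scale.
#' @return One-row tibble with columns `p_value`, `logfc`, `n_a`, `n_b`.
#' @export
rank_sum_logfc <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("Each group needs at least 2 observations.")
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  tibble(p_value = wt$p.value, logfc = mean(a) - mean(b),
         n_a = length(a), n_b = length(b))
}

# ---- expression-table helpers -----------------------------------------------

#' Convert an expression tibble to a numeric matrix
#'
#' The package's tabular convention is genes (or miRNAs) in rows with the
#' identifier in the first column and one column per sample. These helpers
#' convert between that shape and a plain numeric matrix with rownames.
#'
#' @param expr Expression tibble (first column identifiers).
#' @return Numeric matrix, features x samples.
#' @export
expr_as_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 2L)
  m <- as.matrix(expr[-1])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(expr[[1]])
  m
}

#' @rdname expr_as_matrix
#' @param m Numeric matrix with rownames.
#' @param id_col Name for the identifier column.
#' @export
matrix_as_expr <- function(m, id_col = "gene") {
  if (is.null(colnames(m))) colnames(m) <- sprintf("V%d", seq_len(ncol(m)))
  out <- as_tibble(m, .name_repair = "minimal")
  out <- tibble(!!id_col := rownames(m)) |> dplyr::bind_cols(out)
  out
}
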