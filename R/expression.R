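#' Create an expression matrix with tissue grouping
#'
#' @param values Numeric probes x samples matrix (non-negative intensities,
#'   no missing values) with probe rownames and sample colnames.
#' @param groups Either a named character vector (sample -> tissue) or a
#'   data frame with columns `sample`, `tissue` covering every sample.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` needs probe rownames and sample colnames")
  }
  if (anyNA(values)) abort("expression matrix contains missing values")
  if (any(values < 0)) abort("expression intensities must be non-negative")
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$tissue), groups$sample)
  }
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing) > 0L) {
    abort(paste0("sample(s) without a tissue group: ",
                 paste(missing, collapse = ", ")))
  }
  structure(
    list(values = values, groups = groups[colnames(values)]),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " probes x ", ncol(x$values),
      " samples; tissues: ",
      paste(sort(unique(x$groups)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read an expression matrix and its tissue grouping from TSV
#'
#' The matrix file has probe ids in the first column and sample ids as
#' header; the groups file has columns `sample` and `tissue`.
#'
#' @param matrix_path,groups_path File paths.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(matrix_path, groups_path) {
  df <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df[[1]])
  groups <- readr::read_tsv(groups_path, show_col_types = FALSE)
  expression_matrix(values, groups)
}

#' Quantile-normalize an expression matrix
#'
#' Classic quantile normalization: each sample's r-th order statistic is
#' replaced by the mean of the r-th order statistics across samples, so all
#' samples share an identical sorted value vector afterwards; tied values
#' receive the mean of their ranks' reference values. A single-sample
#' matrix is returned unchanged with a warning.
#'
#' @param em An [expression_matrix()].
#' @return A quantile-normalized [expression_matrix()].
#' @export
quantile_normalize <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (ncol(em$values) < 2L) {
    warn("single-sample matrix: quantile normalization is the identity")
    return(em)
  }
  norm <- limma::normalizeQuantiles(em$values, ties = TRUE)
  dimnames(norm) <- dimnames(em$values)
  expression_matrix(norm, em$groups)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact p by full enumeration of the rank-sum null distribution (with
#' midranks for ties) when requested or, in `auto` mode, when the pooled
#' sample size is at most 12 and tie-free; otherwise a tie-corrected normal
#' approximation (with continuity correction). Two-sided throughout.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal-approx"`.
#' @return A p-value in `(0, 1]`.
#' @export
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "normal-approx")) {
  mode <- match.arg(mode)
  if (length(a) < 1L || length(b) < 1L) abort("both groups must be non-empty")
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0L
  if (mode == "auto") {
    mode <- if (length(pooled) <= 12L && !ties) "exact" else "normal-approx"
  }
  if (mode == "exact") {
    return(wilcoxon_exact_p(a, b))
  }
  if (stats::sd(pooled) == 0) return(1)  # degenerate: all values identical
  stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
}

# Exact two-sided p: enumerate all C(n, na) assignments of the pooled
# midranks to group a; p = min(1, 2 * min(P(W <= w), P(W >= w))).
wilcoxon_exact_p <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))  # midranks
  w_obs <- sum(r[seq_len(na)])
  sets <- utils::combn(length(r), na)
  w_all <- colSums(matrix(r[sets], nrow = na))
  eps <- 1e-9
  p_le <- mean(w_all <= w_obs + eps)
  p_ge <- mean(w_all >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

#' Compare expression between two tissues
#'
#' For every probe: per-tissue mean intensities, fold change
#' (target / reference), log2 ratio, two-sided Wilcoxon rank-sum p-value
#' across the two sample groups, a Benjamini-Hochberg adjusted p-value, and
#' the over-expression flag `fold_change >= fold_threshold` (inclusive at
#' the threshold). The flag follows fold change only; p-values are reported
#' alongside for inspection. A zero reference mean leaves `fold_change`
#' `NA` with `fold_undefined = TRUE`. With a probe -> gene map, results are
#' aggregated per gene: means are averaged across the gene's probes, the
#' gene fold change is the average of the probe-level ratios, and the
#' p-value is recomputed on per-sample expression averaged across the
#' gene's probes.
#'
#' @param em An [expression_matrix()].
#' @param target,reference Tissue labels (both present in the grouping).
#' @param fold_threshold Over-expression threshold on the fold change
#'   (default 1.5, inclusive).
#' @param probe_gene_map Optional data frame with columns `probe`, `gene`.
#' @param p_mode Passed to [wilcoxon_rank_sum()] (default `"auto"`).
#' @return A tibble of class `tissue_comparison`: `id`, `mean_target`,
#'   `mean_reference`, `fold_change`, `log2_ratio`, `p_value`, `p_adjusted`
#'   (BH), `overexpressed`, `fold_undefined`.
#' @export
compare_tissues <- function(em, target, reference, fold_threshold = 1.5,
                            probe_gene_map = NULL, p_mode = "auto") {
  stopifnot(inherits(em, "expression_matrix"))
  for (t in c(target, reference)) {
    if (t %!in% em$groups) abort(paste0("tissue '", t, "' not in grouping"))
  }
  ta <- em$values[, em$groups == target, drop = FALSE]
  rf <- em$values[, em$groups == reference, drop = FALSE]

  per_row <- function(ta, rf, ids) {
    mean_t <- rowMeans(ta)
    mean_r <- rowMeans(rf)
    fold <- ifelse(mean_r == 0, NA_real_, mean_t / mean_r)
    p <- vapply(seq_along(ids), function(i) {
      wilcoxon_rank_sum(ta[i, ], rf[i, ], mode = p_mode)
    }, numeric(1))
    tibble(
      id = ids,
      mean_target = unname(mean_t),
      mean_reference = unname(mean_r),
      fold_change = unname(fold),
      log2_ratio = unname(log2(fold)),
      p_value = p,
      p_adjusted = p.adjust(p, method = "BH"),
      overexpressed = !is.na(fold) & fold >= fold_threshold,
      fold_undefined = is.na(fold)
    )
  }

  res <- per_row(ta, rf, rownames(em$values))

  if (!is.null(probe_gene_map)) {
    pm <- as_tibble(probe_gene_map)
    res <- left_join(res, pm, by = c(id = "probe")) |>
      filter(!is.na(.data$gene))
    agg <- res |>
      group_by(.data$gene) |>
      summarise(
        mean_target = mean(.data$mean_target),
        mean_reference = mean(.data$mean_reference),
        fold_change = mean(.data$fold_change),  # average of probe ratios
        n_probes = n(), .groups = "drop"
      )
    # p-value on per-sample expression averaged over the gene's probes
    p <- vapply(agg$gene, function(g) {
      probes <- pm$probe[pm$gene == g & pm$probe %in% rownames(em$values)]
      at <- colMeans(ta[probes, , drop = FALSE])
      ar <- colMeans(rf[probes, , drop = FALSE])
      wilcoxon_rank_sum(at, ar, mode = p_mode)
    }, numeric(1))
    res <- agg |>
      mutate(
        id = .data$gene,
        log2_ratio = log2(.data$fold_change),
        p_value = p,
        p_adjusted = p.adjust(p, method = "BH"),
        overexpressed = !is.na(.data$fold_change) &
          .data$fold_change >= fold_threshold,
        fold_undefined = is.na(.data$fold_change)
      ) |>
      select("id", "mean_target", "mean_reference", "fold_change",
             "log2_ratio", "p_value", "p_adjusted", "overexpressed",
             "fold_undefined")
  }

  structure(res, class = c("tissue_comparison", class(res)),
            target = target, reference = reference,
            fold_threshold = fold_threshold)
}

#' @exportS3Method generics::glance
glance.tissue_comparison <- function(x, ...) {
  tibble(
    target = attr(x, "target"), reference = attr(x, "reference"),
    n = nrow(x), n_overexpressed = sum(x$overexpressed),
    fold_threshold = attr(x, "fold_threshold")
  )
}

#' Scatter plot of a tissue comparison
#'
#' Mean reference intensity against mean target intensity on log scales;
#' over-expressed probes/genes (fold change at or above the threshold) are
#' highlighted as red diamonds.
#'
#' @param object A [compare_tissues()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tissue_comparison <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_reference,
                                   y = .data$mean_target)) +
    ggplot2::geom_point(data = df[!df$overexpressed, ],
                        colour = "grey40", shape = 16, size = 1.5) +
    ggplot2::geom_point(data = df[df$overexpressed, ],
                        colour = "red", shape = 18, size = 2.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey70") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = paste0("mean intensity (", attr(object, "reference"), ")"),
      y = paste0("mean intensity (", attr(object, "target"), ")")
    ) +
    ggplot2::theme_minimal()
}
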