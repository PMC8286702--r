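# Expression matrices, qPCR fold changes, water content, the
# expression-water regression and group comparisons.

#' Log2-transform an FPKM matrix
#'
#' @param mat Numeric matrix of FPKM values (genes x samples), all >= 0.
#' @param pseudocount Added before taking log2 (zeros are common in FPKM
#'   matrices, so a pseudocount is unavoidable; the value used is recorded
#'   as an attribute).
#' @return Matrix of `log2(x + pseudocount)` with attribute `pseudocount`.
#' @export
log2_transform <- function(mat, pseudocount = 1) {
  mat <- as.matrix(mat)
  if (any(mat < 0, na.rm = TRUE)) stop("negative FPKM value")
  out <- log2(mat + pseudocount)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Tissue water content from fresh and dry weight
#'
#' `(FW - DW) / FW * 100`.
#'
#' @param FW Fresh weight (g), > 0.
#' @param DW Dry weight (g), `0 <= DW <= FW`. Vectorized.
#' @return Water content in percent.
#' @export
water_content <- function(FW, DW) {
  if (any(FW <= 0)) stop("FW must be positive")
  if (any(DW < 0) || any(DW > FW)) stop("need 0 <= DW <= FW")
  (FW - DW) / FW * 100
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = Ct_target - Ct_reference`; per condition,
#' `ddCt = mean dCt(condition) - mean dCt(control)`; fold change is
#' `2^-ddCt`. The standard error over biological replicates of
#' `2^-(dCt - mean dCt(control))` is reported per condition.
#'
#' @param ct data.frame with columns `gene`, `condition`, `replicate`,
#'   `ct`.
#' @param reference_gene Id of the normalizer gene (must have a Ct in every
#'   condition x replicate cell used).
#' @param control_condition The baseline condition label.
#' @param per_replicate If `TRUE`, ddCt is computed per replicate and then
#'   summarized, instead of on replicate-mean dCt.
#' @return data.frame: `gene`, `condition`, `fold`, `se`, `n`.
#' @export
ddct_fold_change <- function(ct, reference_gene, control_condition,
                             per_replicate = FALSE) {
  need <- c("gene", "condition", "replicate", "ct")
  stopifnot(all(need %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  ref <- ct[ct$gene == reference_gene, ]
  if (nrow(ref) == 0L) stop("reference gene ", reference_gene, " not found")
  refkey <- paste(ref$condition, ref$replicate)
  refct <- setNames(ref$ct, refkey)
  targets <- setdiff(unique(ct$gene), reference_gene)
  out <- list()
  for (g in targets) {
    tg <- ct[ct$gene == g, ]
    key <- paste(tg$condition, tg$replicate)
    if (anyNA(refct[key])) {
      stop("missing reference Ct for gene ", g, " in ",
           paste(unique(key[is.na(refct[key])]), collapse = ", "))
    }
    dct <- tg$ct - refct[key]
    if (!control_condition %in% tg$condition) {
      stop("control condition ", control_condition, " absent for ", g)
    }
    ctrl_mean <- mean(dct[tg$condition == control_condition])
    for (cond in unique(tg$condition)) {
      dd <- dct[tg$condition == cond] - ctrl_mean
      folds <- 2^(-dd)
      fold <- if (per_replicate) mean(folds) else 2^(-mean(dd))
      out[[length(out) + 1L]] <- data.frame(
        gene = g, condition = cond, fold = fold,
        se = if (length(folds) > 1L) sd(folds) / sqrt(length(folds)) else NA_real_,
        n = length(folds), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Linear regression of water content on gene expression
#'
#' Ordinary least squares of `water ~ expression` with the Pearson
#' correlation and its two-sided t-test,
#' `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param expr_series Numeric expression values.
#' @param water_series Paired water-content values (same length, n >= 3).
#' @param alpha Significance level.
#' @return List of class `CorrelationResult`: `n`, `pearson_r`, `slope`,
#'   `intercept`, `p_value`, `significant`, `defined` (FALSE when either
#'   series has zero variance, in which case r is undefined).
#' @export
expression_water_regression <- function(expr_series, water_series,
                                        alpha = 0.05) {
  ok <- stats::complete.cases(expr_series, water_series)
  x <- expr_series[ok]; y <- water_series[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (var(x) == 0 || var(y) == 0) {
    return(structure(list(n = n, pearson_r = NA_real_, slope = NA_real_,
                          intercept = NA_real_, p_value = NA_real_,
                          significant = FALSE, defined = FALSE),
                     class = "CorrelationResult"))
  }
  r <- stats::cor(x, y)
  fit <- stats::coef(lm(y ~ x))
  tt <- r * sqrt((n - 2) / max(1e-300, 1 - r^2))
  p <- 2 * pt(-abs(tt), df = n - 2)
  structure(list(n = n, pearson_r = r, slope = unname(fit[2L]),
                 intercept = unname(fit[1L]), p_value = p,
                 significant = p < alpha, defined = TRUE),
            class = "CorrelationResult")
}

#' @export
print.CorrelationResult <- function(x, ...) {
  if (!x$defined) {
    cat("<CorrelationResult> undefined (zero variance)\n")
  } else {
    cat(sprintf("<CorrelationResult> n=%d r=%.3f slope=%.3g p=%.3g%s\n",
                x$n, x$pearson_r, x$slope, x$p_value,
                if (x$significant) " *" else ""))
  }
  invisible(x)
}

#' One-way ANOVA with Tukey HSD and a compact letter display
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @param alpha Significance level for the Tukey comparisons.
#' @return List: `F`, `p`, `tukey` (data.frame of pairwise comparisons
#'   with adjusted p-values), `letters` (named character vector; groups
#'   sharing a letter are not significantly different).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(vapply(groups, length, 1L) < 2L)) stop("each group needs n >= 2")
  if (all(vapply(groups, var, 0) == 0)) {
    stop("zero within-group variance in every group")
  }
  df <- data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  fit <- aov(y ~ g, data = df)
  an <- anova(fit)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  comp <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                     p_adj = tk[, "p adj"], row.names = NULL,
                     stringsAsFactors = FALSE)
  letters <- .letter_display(names(groups), comp, alpha)
  list(F = an[["F value"]][1L], p = an[["Pr(>F)"]][1L],
       tukey = comp, letters = letters)
}

# compact letter display by insert-and-absorb over the significance matrix
.letter_display <- function(levels, comp, alpha) {
  k <- length(levels)
  sig <- matrix(FALSE, k, k, dimnames = list(levels, levels))
  for (i in seq_len(nrow(comp))) {
    pr <- strsplit(comp$comparison[i], "-", fixed = TRUE)[[1L]]
    if (comp$p_adj[i] < alpha) {
      sig[pr[1L], pr[2L]] <- sig[pr[2L], pr[1L]] <- TRUE
    }
  }
  sets <- list(levels)      # candidate letter groups
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (!sig[i, j]) next
      for (s in seq_along(sets)) {
        if (all(c(levels[i], levels[j]) %in% sets[[s]])) {
          a <- setdiff(sets[[s]], levels[i])
          b <- setdiff(sets[[s]], levels[j])
          sets[[s]] <- a
          if (!any(vapply(sets, function(x) all(b %in% x), TRUE))) {
            sets[[length(sets) + 1L]] <- b
          }
        }
      }
    }
  }
  sets <- sets[!vapply(sets, function(s) any(vapply(
    sets, function(t) !identical(s, t) && all(s %in% t), TRUE)), TRUE)]
  out <- setNames(rep("", k), levels)
  for (s in seq_along(sets)) {
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  }
  out
}

#' Select candidate genes linking expression to water accumulation
#'
#' Genes with a significant positive expression-water regression AND mean
#' expression above `fpkm_min` in the late-stage target-tissue samples are
#' returned ranked by descending Pearson r.
#'
#' @param correlations Named list of `CorrelationResult` objects (per gene).
#' @param expr FPKM matrix (genes x samples).
#' @param target_samples Column names of the late-stage target-tissue
#'   samples (e.g. outer seed coat at the last stages).
#' @param fpkm_min Expression threshold (FPKM).
#' @return data.frame: `gene_id`, `pearson_r`, `p_value`,
#'   `target_mean_fpkm`, ranked by r; zero rows when nothing qualifies.
#' @export
candidate_selection <- function(correlations, expr, target_samples,
                                fpkm_min = 1) {
  stopifnot(all(target_samples %in% colnames(expr)))
  rows <- list()
  for (g in names(correlations)) {
    cr <- correlations[[g]]
    if (!isTRUE(cr$defined) || !cr$significant || cr$pearson_r <= 0) next
    if (!g %in% rownames(expr)) next
    m <- mean(expr[g, target_samples])
    if (m < fpkm_min) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, pearson_r = cr$pearson_r, p_value = cr$p_value,
      target_mean_fpkm = m, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), pearson_r = numeric(0),
                      p_value = numeric(0), target_mean_fpkm = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(-out$pearson_r), , drop = FALSE]
}
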