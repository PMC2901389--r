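#' Display a fold change in the "1/x" down-regulation notation
#' @param fold Numeric vector of positive fold changes.
#' @return Character vector: `"2.00"` for fold 2, `"1/2.00"` for fold 0.5.
#' @export
format_fold <- function(fold) {
  ifelse(fold < 1, sprintf("1/%.2f", 1 / fold), sprintf("%.2f", fold))
}

#' Relative quantification by the 2^-ddCt method
#'
#' Technical replicate Cts are averaged per sample and gene; per sample
#' `dCt = Ct_target - Ct_reference`; `ddCt` is the treated-minus-control
#' difference of group mean dCts; the fold change is `2^-ddCt`. The 95%
#' confidence interval is the two-sample t-interval on ddCt (pooled
#' Student by default), exponentiated — a monotone transform, so the
#' "interval excludes 1" significance rule is preserved. With a single
#' sample in either arm the point estimate is returned and the interval
#' flagged unavailable.
#'
#' @param records Data.frame with columns `sample`, `condition`
#'   (`"treated"`/`"control"`), `gene`, `ct`; one row per technical
#'   replicate well.
#' @param target Target gene symbol (default: the unique non-reference
#'   gene in `records`).
#' @param reference_gene Normaliser gene (default `"18S"`).
#' @param conf_level Confidence level (default 0.95).
#' @param flavor `"pooled"` (default) or `"welch"` interval on ddCt.
#' @return Object of class `ddct_result`: list with `fold`, `ci_lower`,
#'   `ci_upper`, `significant`, `ddct`, `se`, `df`, `display`,
#'   `n_treated`, `n_control`.
#' @export
ddct_fold_change <- function(records, target = NULL,
                             reference_gene = "18S", conf_level = 0.95,
                             flavor = c("pooled", "welch")) {
  flavor <- match.arg(flavor)
  need <- c("sample", "condition", "gene", "ct")
  if (!all(need %in% names(records)))
    stop("`records` needs columns sample, condition, gene, ct", call. = FALSE)
  if (any(!is.finite(records$ct)) || any(records$ct <= 0))
    stop("all Ct values must be finite and positive", call. = FALSE)
  if (!all(records$condition %in% c("treated", "control")))
    stop("condition must be 'treated' or 'control'", call. = FALSE)
  if (is.null(target)) {
    target <- setdiff(unique(records$gene), reference_gene)
    if (length(target) != 1)
      stop("specify `target`: records hold several non-reference genes",
           call. = FALSE)
  }
  # replicate average per sample x gene
  avg <- aggregate(ct ~ sample + condition + gene, records, mean)
  dct_of <- function(cond) {
    sub <- avg[avg$condition == cond, ]
    tgt <- sub[sub$gene == target, ]
    ref <- sub[sub$gene == reference_gene, ]
    if (nrow(ref) == 0 || !all(tgt$sample %in% ref$sample))
      stop(sprintf("reference gene '%s' missing for a %s sample",
                   reference_gene, cond), call. = FALSE)
    if (nrow(tgt) == 0)
      stop(sprintf("no %s Ct for target '%s'", cond, target), call. = FALSE)
    tgt$ct - ref$ct[match(tgt$sample, ref$sample)]
  }
  d_t <- dct_of("treated"); d_c <- dct_of("control")
  ddct <- mean(d_t) - mean(d_c)
  fold <- 2^(-ddct)
  n1 <- length(d_t); n2 <- length(d_c)
  if (n1 < 2 || n2 < 2) {
    res <- list(fold = fold, ci_lower = NA_real_, ci_upper = NA_real_,
                significant = NA, ddct = ddct, se = NA_real_,
                df = NA_real_, display = format_fold(fold),
                n_treated = n1, n_control = n2)
    return(structure(res, class = "ddct_result"))
  }
  v1 <- var(d_t); v2 <- var(d_c)
  if (flavor == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tq <- qt(1 - (1 - conf_level) / 2, df)
  ci <- 2^(-(ddct + c(1, -1) * tq * se))   # lower, upper
  structure(list(fold = fold, ci_lower = ci[1], ci_upper = ci[2],
                 significant = ci[1] > 1 || ci[2] < 1, ddct = ddct,
                 se = se, df = df, display = format_fold(fold),
                 n_treated = n1, n_control = n2),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("ddct_result: fold %s (95%% CI %.3g-%.3g), %s\n", x$display,
              x$ci_lower, x$ci_upper,
              if (isTRUE(x$significant)) "significant (CI excludes 1)"
              else if (isFALSE(x$significant)) "not significant"
              else "CI unavailable"))
  invisible(x)
}

#' Unpaired t-test from printed group summaries
#'
#' Reconstructs an unpaired two-sample Student t-test from per-group
#' mean, standard error of the mean, and n (the form in which published
#' figure legends report count data): `sd = sem * sqrt(n)`, pooled
#' variance by default, Welch available.
#'
#' @param mean1,sem1,n1 First group's mean, SEM and size (`n >= 2`,
#'   `sem > 0`).
#' @param mean2,sem2,n2 Second group.
#' @param flavor `"pooled"` (default) or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
ttest_from_summary <- function(mean1, sem1, n1, mean2, sem2, n2,
                               flavor = c("pooled", "welch")) {
  flavor <- match.arg(flavor)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sem1 < 0 || sem2 < 0) stop("SEMs must be non-negative", call. = FALSE)
  v1 <- (sem1 * sqrt(n1))^2; v2 <- (sem2 * sqrt(n2))^2
  if (flavor == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se2 == 0)
    return(list(t = 0, df = df, p = if (mean1 == mean2) 1 else 0))
  tt <- (mean1 - mean2) / sqrt(se2)
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

#' Unpaired t-test from raw per-observation counts
#'
#' Computes each group's mean/SEM/n and delegates to
#' [ttest_from_summary()], so the raw-data path and the
#' summary-statistics path agree exactly whenever both are computable.
#'
#' @param group1,group2 Numeric vectors (>= 2 observations each).
#' @inheritParams ttest_from_summary
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
ttest_from_counts <- function(group1, group2,
                              flavor = c("pooled", "welch")) {
  flavor <- match.arg(flavor)
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs >= 2 observations", call. = FALSE)
  ttest_from_summary(mean(group1), sd(group1) / sqrt(length(group1)),
                     length(group1),
                     mean(group2), sd(group2) / sqrt(length(group2)),
                     length(group2), flavor = flavor)
}
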