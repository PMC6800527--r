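#' Split-plot repeated-measures ANOVA
#'
#' Fits the univariate split-plot decomposition used for novel-tank
#' measures and component scores: between-subject factors (e.g. condition,
#' sex) are tested against the subjects-within-cells error stratum; each
#' within-subject factor (e.g. time bin, scoring view) and its
#' interactions with between factors are tested against the corresponding
#' factor-by-subject stratum. Sums of squares are sequential, as produced
#' by `aov` with an `Error()` term.
#'
#' Subjects with incomplete within-factor cells are dropped listwise with
#' a warning; an empty between cell is an error.
#'
#' @param data Long-format data.frame.
#' @param response Name of the response column.
#' @param subject Name of the subject identifier column.
#' @param between Character vector of between-subject factor names.
#' @param within Character vector of within-subject factor names.
#' @return An object of class `splitplot_fit`: `table` (data.frame with
#'   effect, stratum, ss, df_num, df_den, statistic, p), `strata`
#'   (residual MS/df per stratum), the cleaned `data`, and the underlying
#'   `aov` fit.
#' @examples
#' d <- expand.grid(subject = factor(1:12), bin = factor(1:3))
#' d$grp <- factor(rep(rep(c("a", "b"), each = 6), 3))
#' set.seed(1); d$y <- rnorm(nrow(d))
#' fit <- splitplot_anova(d, "y", "subject", "grp", "bin")
#' fit$table[, c("effect", "df_num", "df_den")]
#' @export
splitplot_anova <- function(data, response, subject, between, within) {
  data <- as.data.frame(data)
  for (v in c(subject, between, within)) {
    if (!v %in% names(data)) stop("missing column: ", v)
    data[[v]] <- factor(data[[v]])
  }
  if (!response %in% names(data)) stop("missing column: ", response)
  data <- data[!is.na(data[[response]]), , drop = FALSE]

  # listwise deletion of subjects with incomplete within cells
  wcells <- interaction(data[within], drop = FALSE)
  full <- nlevels(wcells)
  cnt <- table(data[[subject]], wcells)
  complete <- rownames(cnt)[apply(cnt, 1, function(r) all(r >= 1))]
  if (length(complete) < nlevels(data[[subject]])) {
    warning(nlevels(data[[subject]]) - length(complete),
            " subject(s) dropped for incomplete within-factor cells")
    data <- data[data[[subject]] %in% complete, , drop = FALSE]
  }
  data[[subject]] <- droplevels(data[[subject]])
  for (v in c(between, within)) data[[v]] <- droplevels(data[[v]])
  if (length(between) > 0) {
    bcells <- interaction(data[between], drop = FALSE)
    if (any(table(bcells) == 0)) stop("empty between-subject cell")
  }

  fixed <- paste(c(between, within), collapse = " * ")
  errterm <- sprintf("Error(%s/(%s))", subject,
                     paste(within, collapse = " * "))
  fml <- stats::as.formula(paste(response, "~", fixed, "+", errterm))
  fit <- stats::aov(fml, data = data)

  smry <- summary(fit)
  rows <- list()
  strata <- list()
  for (snm in names(smry)) {
    tab <- smry[[snm]][[1]]
    enms <- trimws(rownames(tab))
    resid_i <- which(enms == "Residuals")
    if (length(resid_i) == 0) next
    df_den <- tab$Df[resid_i]
    ms_den <- tab$`Mean Sq`[resid_i]
    stratum <- sub("^Error: ", "", snm)
    strata[[stratum]] <- list(ms = ms_den, df = df_den)
    for (i in seq_len(nrow(tab))) {
      if (i == resid_i) next
      rows[[length(rows) + 1]] <- data.frame(
        effect = enms[i], stratum = stratum, ss = tab$`Sum Sq`[i],
        df_num = tab$Df[i], df_den = df_den,
        statistic = tab$`F value`[i], p = tab$`Pr(>F)`[i],
        stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, strata = strata, data = data, fit = fit,
                 response = response, subject = subject,
                 between = between, within = within),
            class = "splitplot_fit")
}

#' @export
print.splitplot_fit <- function(x, ...) {
  cat("Split-plot repeated-measures ANOVA:", x$response, "\n")
  tab <- x$table
  tab$statistic <- round(tab$statistic, 2)
  tab$p <- signif(tab$p, 3)
  tab$ss <- signif(tab$ss, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Extract one effect's row from a split-plot fit
#' @param fit A `splitplot_fit`.
#' @param effect Effect name as it appears in the table (e.g.
#'   `"condition"`, `"bin:view"`); factor order within interaction names
#'   is normalized.
#' @return One-row data.frame.
#' @export
anova_effect <- function(fit, effect) {
  norm <- function(e) paste(sort(strsplit(e, ":")[[1]]), collapse = ":")
  hit <- vapply(fit$table$effect, norm, "") == norm(effect)
  if (!any(hit)) stop("effect not found: ", effect)
  fit$table[hit, , drop = FALSE]
}

#' Residual diagnostics for a split-plot fit
#'
#' Computes per-stratum residual summaries supporting the visual normality
#' check: skewness, excess kurtosis, and theoretical-vs-sample quantile
#' pairs for a normal Q-Q plot. No automatic rejection is performed; the
#' `kurtosis_flag`/`skewness_flag` fields only mark strata whose moments
#' are far from normal (|skewness| > 1 or excess kurtosis > 2).
#'
#' @param fit A `splitplot_fit`.
#' @return List of class `residual_diagnostics`, one element per error
#'   stratum with `skewness`, `kurtosis` (excess), flags and `qq`
#'   (data.frame of theoretical/sample quantiles).
#' @export
residual_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "splitplot_fit"))
  pr <- stats::proj(fit$fit)
  out <- list()
  for (snm in names(pr)) {
    mat <- pr[[snm]]
    if (!"Residuals" %in% colnames(mat)) next
    r <- mat[, "Residuals"]
    r <- r[is.finite(r)]
    if (length(r) < 4 || stats::sd(r) == 0) next
    stratum <- sub("^Error: ", "", snm)
    sk <- moment_skewness(r)
    ku <- moment_kurtosis(r)
    qq <- data.frame(theoretical = stats::qnorm(stats::ppoints(length(r))),
                     sample = sort((r - mean(r)) / stats::sd(r)))
    out[[stratum]] <- list(n = length(r), skewness = sk, kurtosis = ku,
                           skewness_flag = abs(sk) > 1,
                           kurtosis_flag = ku > 2, qq = qq)
  }
  structure(out, class = "residual_diagnostics")
}

moment_skewness <- function(x) {
  x <- x - mean(x)
  mean(x^3) / mean(x^2)^1.5
}

moment_kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2 - 3
}

#' @export
print.residual_diagnostics <- function(x, ...) {
  for (s in names(x)) {
    cat(sprintf("%s: n=%d skewness=%.2f%s excess kurtosis=%.2f%s\n",
                s, x[[s]]$n, x[[s]]$skewness,
                if (x[[s]]$skewness_flag) " [flag]" else "",
                x[[s]]$kurtosis, if (x[[s]]$kurtosis_flag) " [flag]" else ""))
  }
  invisible(x)
}
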