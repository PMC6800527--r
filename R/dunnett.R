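#' Dunnett many-to-one contrasts
#'
#' Two-sided comparisons of every level against a single reference level,
#' with the familywise adjustment computed from the equicoordinate
#' multivariate t distribution under the contrasts' correlation matrix
#' (equicorrelation 1/2 for balanced designs sharing a control). With a
#' single comparison the adjusted p reduces to the ordinary two-sided
#' t-test p.
#'
#' @param means Named vector of cell means; names are the level labels.
#' @param n Per-level count backing each mean (scalar or named vector):
#'   subjects per group for a between factor, subjects per within level
#'   for a within factor.
#' @param ms_error Error mean square on the scale of the cell means (see
#'   Details).
#' @param df_error Error degrees of freedom.
#' @param control Reference level label (e.g. the vehicle group, or
#'   `"1"` for the first time bin).
#' @param design `"between"`: independent groups, the variance of a cell
#'   mean is `ms_error / n_level` and contrasts correlate through the
#'   shared control; `"within"`: paired levels over the same subjects, the
#'   variance of a difference is `2 * ms_error / n` and contrasts are
#'   equicorrelated at 1/2.
#' @param alpha Familywise significance level.
#' @param family Label carried into the output (e.g.
#'   `"condition vs control"`).
#' @return Data frame of class `contrast_result`: family, contrast,
#'   estimate, se, statistic, df, p (Dunnett-adjusted), p_unadj,
#'   significant.
#' @examples
#' m <- c(control = 0, a = 0.5, b = 1.1, c = 0.2)
#' dunnett_contrasts(m, n = 12, ms_error = 1, df_error = 44,
#'                   control = "control")
#' @export
dunnett_contrasts <- function(means, n, ms_error, df_error, control,
                              design = c("between", "within"),
                              alpha = 0.05, family = "dunnett") {
  design <- match.arg(design)
  stopifnot(length(means) >= 2, df_error > 0, ms_error >= 0)
  labs <- names(means)
  if (is.null(labs)) stop("means must be named by level")
  if (!control %in% labs) stop("control label absent: ", control)
  if (length(n) == 1) n <- stats::setNames(rep(n, length(means)), labs)
  trt <- setdiff(labs, control)
  k <- length(trt)
  est <- means[trt] - means[control]
  if (design == "between") {
    se <- sqrt(ms_error * (1 / n[trt] + 1 / n[control]))
    corr <- outer(trt, trt, function(a, b) {
      sqrt((n[a] / (n[a] + n[control])) * (n[b] / (n[b] + n[control])))
    })
    diag(corr) <- 1
  } else {
    se <- sqrt(2 * ms_error / n[trt])
    corr <- matrix(0.5, k, k)
    diag(corr) <- 1
  }
  tstat <- est / se
  p_unadj <- 2 * stats::pt(-abs(tstat), df_error)
  p_adj <- vapply(tstat, function(tt) {
    dunnett_p(abs(tt), corr, df_error)
  }, 0)
  p_adj <- pmax(p_adj, p_unadj)  # adjusted p can never undercut unadjusted
  out <- data.frame(family = family,
                    contrast = paste(trt, "-", control),
                    estimate = as.numeric(est), se = as.numeric(se),
                    statistic = as.numeric(tstat), df = df_error,
                    p = as.numeric(p_adj), p_unadj = as.numeric(p_unadj),
                    significant = as.numeric(p_adj) < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("contrast_result", "data.frame")
  out
}

# P(max_i |T_i| >= t) for equicoordinate multivariate t with correlation
# matrix corr and df degrees of freedom; deterministic given the fixed
# internal seed of the integration routine
dunnett_p <- function(t, corr, df) {
  k <- nrow(corr)
  if (k == 1) return(2 * stats::pt(-t, df))
  pr <- with_fixed_seed(20240901L, {
    mvtnorm::pmvt(lower = rep(-t, k), upper = rep(t, k), df = round(df),
                  corr = corr, algorithm = mvtnorm::GenzBretz(
                    abseps = 1e-5, maxpts = 50000))
  })
  max(1 - as.numeric(pr), 0)
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_fixed_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Dunnett post hocs from a split-plot fit
#'
#' Convenience wrapper running the contrast families of the novel-tank
#' analysis directly from a [splitplot_anova()] fit: every level of a
#' factor against its reference level, optionally within each level of a
#' conditioning factor. Between factors use the subject-stratum error on
#' subject means; within factors use the factor-by-subject stratum.
#'
#' @param fit A `splitplot_fit`.
#' @param factor_name Factor whose levels are compared.
#' @param control Reference level; defaults to the factor's first level.
#' @param by Optional conditioning factor: contrasts are run within each
#'   of its levels (e.g. bin vs bin 1 within each condition).
#' @param alpha Familywise significance level per family.
#' @return A `contrast_result` data frame (one family per `by` level).
#' @export
posthoc_dunnett <- function(fit, factor_name, control = NULL, by = NULL,
                            alpha = 0.05) {
  stopifnot(inherits(fit, "splitplot_fit"))
  dat <- fit$data
  resp <- dat[[fit$response]]
  f <- dat[[factor_name]]
  if (is.null(control)) control <- levels(f)[1]
  is_between <- factor_name %in% fit$between
  subsets <- if (is.null(by)) list(all = rep(TRUE, nrow(dat)))
             else split(seq_len(nrow(dat)), dat[[by]])
  out <- list()
  for (snm in names(subsets)) {
    idx <- subsets[[snm]]
    if (is.logical(idx)) idx <- which(idx)
    d <- dat[idx, , drop = FALSE]
    r <- resp[idx]
    fam <- if (is.null(by)) sprintf("%s vs %s", factor_name, control)
           else sprintf("%s vs %s | %s=%s", factor_name, control, by, snm)
    if (is_between) {
      cm <- contrast_inputs_between(fit, d, r, factor_name)
    } else {
      cm <- contrast_inputs_within(fit, d, r, factor_name)
    }
    out[[snm]] <- dunnett_contrasts(cm$means, cm$n, cm$ms, cm$df, control,
                                    design = cm$design, alpha = alpha,
                                    family = fam)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("contrast_result", "data.frame")
  res
}

# between factor: work on subject means; error = subjects within
# between cells (ms on the subject-mean scale, df = N - #cells)
contrast_inputs_between <- function(fit, d, r, factor_name) {
  subj <- d[[fit$subject]]
  sm <- tapply(r, subj, mean)
  sm <- sm[!is.na(sm)]
  smeta <- d[!duplicated(d[[fit$subject]]), , drop = FALSE]
  smeta <- smeta[match(names(sm), as.character(smeta[[fit$subject]])), ]
  cells <- interaction(smeta[fit$between], drop = TRUE)
  cellmean <- tapply(sm, cells, mean)
  resid <- sm - cellmean[as.character(cells)]
  df <- length(sm) - nlevels(cells)
  ms <- sum(resid^2) / df
  fl <- droplevels(smeta[[factor_name]])
  means <- tapply(sm, fl, mean)
  n <- as.numeric(table(fl))
  names(n) <- levels(fl)
  list(means = means, n = n, ms = ms, df = df, design = "between")
}

# within factor: level means over subjects; error = factor x subject
# stratum of the full fit, rescaled to the per-(subject, level) mean
contrast_inputs_within <- function(fit, d, r, factor_name) {
  stratum <- stratum_name(fit, factor_name)
  err <- fit$strata[[stratum]]
  if (is.null(err)) stop("no error stratum for within factor ", factor_name)
  fl <- droplevels(d[[factor_name]])
  # observations per (subject, level) cell (other within factors averaged)
  subj <- droplevels(d[[fit$subject]])
  percell <- nrow(d) / (nlevels(subj) * nlevels(fl))
  means <- tapply(r, fl, mean, na.rm = TRUE)
  n <- as.numeric(table(fl)) / percell     # subjects represented per level
  names(n) <- levels(fl)
  list(means = means, n = n, ms = err$ms / percell, df = err$df,
       design = "within")
}

stratum_name <- function(fit, factor_name) {
  cand <- names(fit$strata)
  hit <- cand[vapply(cand, function(s) {
    parts <- strsplit(s, ":")[[1]]
    setequal(parts, c(fit$subject, factor_name))
  }, TRUE)]
  if (length(hit) != 1) stop("cannot locate error stratum for ", factor_name)
  hit
}
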