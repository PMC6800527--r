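#' Align per-view contrast results into a significance matrix
#'
#' Joins contrast tables computed separately from 3D, top-view and
#' front-view data into one long matrix keyed by (measure, family,
#' contrast). Every view must carry the identical contrast universe;
#' cells for measures that cannot be scored in a view (time in the top
#' half from the top view) are marked not-applicable.
#'
#' @param contrasts_by_view Named list (names among `"3D"`, `"top"`,
#'   `"front"`) of data.frames with columns `measure`, `family`,
#'   `contrast`, `significant` (logical, `NA` = not applicable).
#' @return Data frame of class `significance_matrix`: measure, family,
#'   contrast, view, status (`"significant"`, `"ns"`, `"na"`).
#' @export
matched_contrasts <- function(contrasts_by_view) {
  stopifnot(is.list(contrasts_by_view), length(contrasts_by_view) >= 2)
  views <- names(contrasts_by_view)
  key <- function(d) paste(d$measure, d$family, d$contrast, sep = "\r")
  keys <- lapply(contrasts_by_view, key)
  universe <- sort(unique(unlist(keys)))
  for (v in views) {
    missing <- setdiff(universe, keys[[v]])
    if (length(missing) > 0) {
      stop("view '", v, "' is missing contrast(s): ",
           paste(gsub("\r", " / ", missing[seq_len(min(3, length(missing)))]),
                 collapse = "; "))
    }
    if (anyDuplicated(keys[[v]])) {
      stop("view '", v, "' has duplicated contrasts")
    }
  }
  out <- list()
  for (v in views) {
    d <- contrasts_by_view[[v]]
    d <- d[match(universe, keys[[v]]), , drop = FALSE]
    status <- ifelse(is.na(d$significant), "na",
                     ifelse(d$significant, "significant", "ns"))
    out[[v]] <- data.frame(measure = d$measure, family = d$family,
                           contrast = d$contrast, view = v,
                           status = status, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("significance_matrix", "data.frame")
  res
}

#' Classify 2D-vs-3D disagreements into false positives and negatives
#'
#' Treats the 3D layer as ground truth. For every applicable (measure,
#' contrast) cell and each 2D view: a contrast significant in the 2D view
#' but not in 3D is a false positive; a contrast not significant in the
#' 2D view but significant in 3D is a false negative. Counts are
#' aggregated per measure and per view.
#'
#' @param m A `significance_matrix` from [matched_contrasts()] containing
#'   a `"3D"` layer and at least one 2D layer.
#' @param truth_view The ground-truth layer (default `"3D"`).
#' @return Data frame of class `findings_ledger`: measure, view,
#'   false_positives, false_negatives, total, n_contrasts (applicable
#'   cells).
#' @export
classify_findings <- function(m, truth_view = "3D") {
  stopifnot(inherits(m, "significance_matrix"))
  views <- unique(m$view)
  if (!truth_view %in% views) stop("missing ground-truth view: ", truth_view)
  key <- paste(m$measure, m$family, m$contrast, sep = "\r")
  truth <- m[m$view == truth_view, ]
  tkey <- paste(truth$measure, truth$family, truth$contrast, sep = "\r")
  out <- list()
  for (v in setdiff(views, truth_view)) {
    d <- m[m$view == v, ]
    dkey <- paste(d$measure, d$family, d$contrast, sep = "\r")
    t3 <- truth$status[match(dkey, tkey)]
    ok <- d$status != "na" & t3 != "na"
    fp <- ok & d$status == "significant" & t3 == "ns"
    fn <- ok & d$status == "ns" & t3 == "significant"
    for (ms in unique(d$measure)) {
      i <- d$measure == ms
      out[[length(out) + 1]] <- data.frame(
        measure = ms, view = v,
        false_positives = sum(fp[i]), false_negatives = sum(fn[i]),
        total = sum(fp[i]) + sum(fn[i]), n_contrasts = sum(ok[i]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("findings_ledger", "data.frame")
  res
}

#' Format a findings ledger in the conventional report layout
#'
#' One row per measure plus a Total row; one column block per 2D view
#' with false positives, false negatives and their sum. Cells for
#' measure/view combinations with no applicable contrasts are dashed.
#'
#' @param ledger A `findings_ledger` from [classify_findings()].
#' @param measures Row order; defaults to [ethogram_measures()] restricted
#'   to the measures present.
#' @return Character matrix ready for printing/writing.
#' @export
ledger_table <- function(ledger, measures = NULL) {
  stopifnot(inherits(ledger, "findings_ledger"))
  if (is.null(measures)) {
    measures <- intersect(ethogram_measures(), unique(ledger$measure))
    measures <- union(measures, unique(ledger$measure))
  }
  views <- unique(ledger$view)
  cols <- unlist(lapply(views, function(v) {
    paste(v, c("false positives", "false negatives", "total"))
  }))
  out <- matrix("-", length(measures) + 1, length(cols),
                dimnames = list(c(measures, "Total"), cols))
  for (v in views) {
    d <- ledger[ledger$view == v, ]
    for (ms in measures) {
      r <- d[d$measure == ms, ]
      if (nrow(r) == 0 || r$n_contrasts == 0) next
      out[ms, paste(v, c("false positives", "false negatives", "total"))] <-
        as.character(c(r$false_positives, r$false_negatives, r$total))
    }
    applicable <- d$n_contrasts > 0
    out["Total", paste(v, c("false positives", "false negatives",
                            "total"))] <-
      as.character(c(sum(d$false_positives[applicable]),
                     sum(d$false_negatives[applicable]),
                     sum(d$total[applicable])))
  }
  out
}

#' Per-view contrast battery over all nine measures
#'
#' Runs, for each ethogram measure and each scoring view, the split-plot
#' ANOVA (between: condition, sex; within: time bin) followed by the
#' Dunnett families of the novel-tank analysis: each condition against
#' the control, each time bin against the first minute (overall), and the
#' bin contrasts within each condition. Families can be gatekept on the
#' corresponding omnibus term being significant in at least one view
#' (`gate = "omnibus"`), or always run (`gate = "always"`).
#'
#' @param etho Ethogram table from [ethogram_cohort()] (long over
#'   subject, view, bin, with metadata columns `group` and `sex`).
#' @param control Control group label.
#' @param alpha Significance level.
#' @param gate `"omnibus"` or `"always"`.
#' @param measures Measures to analyze (default all nine).
#' @param views Views to analyze.
#' @return Named list of per-view contrast data.frames (columns measure,
#'   family, contrast, significant), ready for [matched_contrasts()].
#' @export
view_contrast_battery <- function(etho, control = "vehicle", alpha = 0.05,
                                  gate = c("omnibus", "always"),
                                  measures = ethogram_measures(),
                                  views = c("3D", "top", "front")) {
  gate <- match.arg(gate)
  per_view <- list()
  omnibus <- list()
  fits <- list()
  for (v in views) {
    dv <- etho[etho$view == v & !etho$flagged, , drop = FALSE]
    for (ms in measures) {
      d <- dv[, c("subject_id", "group", "sex", "bin", ms)]
      names(d)[5] <- "y"
      if (all(is.na(d$y))) {
        fits[[paste(v, ms)]] <- NULL
        next
      }
      fit <- splitplot_anova(d, "y", "subject_id", c("group", "sex"), "bin")
      fits[[paste(v, ms)]] <- fit
      for (eff in c("group", "bin", "group:bin")) {
        p <- anova_effect(fit, eff)$p
        kk <- paste(ms, eff)
        omnibus[[kk]] <- isTRUE(omnibus[[kk]]) || (is.finite(p) && p < alpha)
      }
    }
  }
  run_family <- function(ms, eff) {
    gate == "always" || isTRUE(omnibus[[paste(ms, eff)]])
  }
  for (v in views) {
    rows <- list()
    for (ms in measures) {
      fit <- fits[[paste(v, ms)]]
      fams <- list()
      if (run_family(ms, "group")) {
        fams$cond <- function(f) posthoc_dunnett(f, "group",
                                                 control = control,
                                                 alpha = alpha)
      }
      if (run_family(ms, "bin")) {
        fams$bin <- function(f) posthoc_dunnett(f, "bin", control = "1",
                                                alpha = alpha)
      }
      if (run_family(ms, "group:bin")) {
        fams$binbygroup <- function(f) posthoc_dunnett(f, "bin",
                                                       control = "1",
                                                       by = "group",
                                                       alpha = alpha)
      }
      for (fam in fams) {
        template <- NULL
        if (!is.null(fit)) {
          cr <- fam(fit)
          rows[[length(rows) + 1]] <- data.frame(
            measure = ms, family = cr$family, contrast = cr$contrast,
            significant = cr$significant, stringsAsFactors = FALSE)
        } else {
          # measure unscorable in this view: emit the same contrast
          # universe as not-applicable, using any scorable view's fit
          ref <- Filter(Negate(is.null),
                        lapply(views, function(w) fits[[paste(w, ms)]]))
          if (length(ref) == 0) next
          cr <- fam(ref[[1]])
          rows[[length(rows) + 1]] <- data.frame(
            measure = ms, family = cr$family, contrast = cr$contrast,
            significant = NA, stringsAsFactors = FALSE)
        }
      }
    }
    per_view[[v]] <- do.call(rbind, rows)
  }
  per_view
}
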