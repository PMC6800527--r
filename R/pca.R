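#' Correlation-matrix PCA with eigenvalue retention and varimax rotation
#'
#' The dimension-reduction step applied to the nine ethogram measures:
#' columns are standardized to zero mean and unit variance, the
#' correlation matrix is eigendecomposed, components with eigenvalue
#' greater than one are retained, and the retained loadings are
#' varimax-rotated (with Kaiser normalization). Component scores are
#' computed by the regression method and loading-column signs are fixed so
#' the largest-magnitude loading of each component is positive. Rotated
#' components are ordered by explained variance.
#'
#' @param x Numeric matrix or data.frame of observations (typically one
#'   row per subject x time bin) by measures; rows with missing cells are
#'   not allowed.
#' @param eigen_cutoff Retention threshold on eigenvalues (default 1).
#' @param tol Varimax convergence tolerance on the rotation criterion.
#' @param max_iter Maximum varimax sweeps; on non-convergence the
#'   unrotated solution is returned with a warning.
#' @return An object of class `pca_model`: measure names, column
#'   means/SDs, all eigenvalues, `retained_k`, rotated `loadings`
#'   (measures x k), orthonormal `rotmat`, explained and cumulative
#'   variance (percent) per retained component, `scores`, and `converged`.
#' @export
pca_varimax <- function(x, eigen_cutoff = 1, tol = 1e-6, max_iter = 1000) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing cells: supply row-complete observations only")
  p <- ncol(x)
  if (nrow(x) < 2 * p) stop("need at least twice as many rows as columns")
  sds <- apply(x, 2, stats::sd)
  if (any(sds < .Machine$double.eps * 100)) {
    stop("constant column(s): ", paste(colnames(x)[sds < 1e-12],
                                       collapse = ", "))
  }
  mus <- colMeans(x)
  z <- scale(x, center = mus, scale = sds)
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  ev <- eig$values
  k <- sum(ev > eigen_cutoff)
  if (k < 1) stop("no component exceeds the eigenvalue cutoff")
  A <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  rot <- varimax_rotate(A, normalize = TRUE, tol = tol, max_iter = max_iter)
  if (!rot$converged) {
    warning("varimax did not converge in ", max_iter,
            " sweeps; returning unrotated loadings")
    L <- A
    rotmat <- diag(k)
  } else {
    L <- rot$loadings
    rotmat <- rot$rotmat
  }
  # sign convention: largest-magnitude loading per component positive
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) {
      L[, j] <- -L[, j]
      rotmat[, j] <- -rotmat[, j]
    }
  }
  expl <- colSums(L^2) / p * 100
  ord <- order(expl, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  rotmat <- rotmat[, ord, drop = FALSE]
  expl <- expl[ord]
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("m", seq_len(p))
  rownames(L) <- nm
  colnames(L) <- paste0("PC", seq_len(k))
  scores <- z %*% solve(R, L)            # regression-method scores
  colnames(scores) <- colnames(L)
  structure(list(measure_names = nm, center = mus, scale = sds,
                 eigenvalues = ev, retained_k = k, loadings = L,
                 rotmat = rotmat, explained_var = expl,
                 cumulative_var = cumsum(expl), scores = scores,
                 converged = rot$converged, criterion = rot$criterion),
            class = "pca_model")
}

#' Varimax rotation by pairwise Jacobi sweeps
#'
#' Maximizes the varimax simplicity criterion (the summed variance of
#' squared loadings per factor, on Kaiser-normalized rows) by repeatedly
#' applying the closed-form optimal planar rotation to each pair of
#' factors. The criterion is non-decreasing across sweeps.
#'
#' @param A Loading matrix (variables x factors).
#' @param normalize Kaiser-normalize rows before rotating (and undo
#'   afterwards).
#' @param tol Convergence tolerance on the criterion increase per sweep.
#' @param max_iter Maximum number of sweeps.
#' @return List: rotated `loadings`, orthonormal `rotmat`
#'   (`A %*% rotmat = loadings`), `criterion` value per sweep,
#'   `converged`, `iterations`.
#' @export
varimax_rotate <- function(A, normalize = TRUE, tol = 1e-6,
                           max_iter = 1000) {
  A <- as.matrix(A)
  p <- nrow(A); k <- ncol(A)
  if (k < 2) {
    return(list(loadings = A, rotmat = diag(k),
                criterion = varimax_criterion(A, normalize),
                converged = TRUE, iterations = 0L))
  }
  h <- if (normalize) sqrt(rowSums(A^2)) else rep(1, p)
  h[h == 0] <- 1
  B <- A / h
  rotmat <- diag(k)
  crit <- varimax_criterion_raw(B)
  path <- crit
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (pp in 1:(k - 1)) {
      for (qq in (pp + 1):k) {
        xj <- B[, pp]; yj <- B[, qq]
        u <- xj^2 - yj^2
        v <- 2 * xj * yj
        num <- 2 * (p * sum(u * v) - sum(u) * sum(v))
        den <- p * sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2)
        if (abs(num) < 1e-15 && abs(den) < 1e-15) next
        phi <- atan2(num, den) / 4
        cs <- cos(phi); sn <- sin(phi)
        B[, pp] <- cs * xj + sn * yj
        B[, qq] <- -sn * xj + cs * yj
        rp <- rotmat[, pp]; rq <- rotmat[, qq]
        rotmat[, pp] <- cs * rp + sn * rq
        rotmat[, qq] <- -sn * rp + cs * rq
      }
    }
    newcrit <- varimax_criterion_raw(B)
    path <- c(path, newcrit)
    if (newcrit - crit < tol) {
      crit <- newcrit
      converged <- TRUE
      break
    }
    crit <- newcrit
  }
  list(loadings = B * h, rotmat = rotmat, criterion = path,
       converged = converged, iterations = it)
}

# varimax simplicity criterion on an already-normalized loading matrix
varimax_criterion_raw <- function(B) {
  p <- nrow(B)
  sum(apply(B^2, 2, function(s) sum(s^2) / p - (mean(s))^2))
}

#' Varimax simplicity criterion of a loading matrix
#' @param A Loading matrix.
#' @param normalize Kaiser-normalize rows first.
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(A, normalize = TRUE) {
  h <- if (normalize) sqrt(rowSums(A^2)) else rep(1, nrow(A))
  h[h == 0] <- 1
  varimax_criterion_raw(A / h)
}

#' @export
print.pca_model <- function(x, digits = 3, ...) {
  cat(sprintf("Correlation PCA: %d measures, %d retained components (eigenvalue > 1)\n",
              length(x$measure_names), x$retained_k))
  cat("Eigenvalues:", paste(round(x$eigenvalues, digits), collapse = " "),
      "\n")
  cat("Explained variance (%):",
      paste(round(x$explained_var, 1), collapse = " "), "\n")
  cat("Varimax-rotated loadings:\n")
  print(round(x$loadings, digits))
  invisible(x)
}

#' Summary table of a PCA model in the conventional report layout
#'
#' Formats eigenvalues, explained and cumulative variance and the rotated
#' loadings, with loadings below a display threshold suppressed and large
#' loadings marked.
#'
#' @param model A `pca_model`.
#' @param hide_below Suppress loadings smaller than this magnitude.
#' @param bold_above Mark loadings at or above this magnitude with `*`.
#' @return Character matrix ready for printing/writing.
#' @export
pca_table <- function(model, hide_below = 0.1, bold_above = 0.7) {
  k <- model$retained_k
  L <- model$loadings
  fmt <- matrix("", nrow(L), k, dimnames = dimnames(L))
  for (j in seq_len(k)) {
    for (i in seq_len(nrow(L))) {
      v <- L[i, j]
      if (abs(v) < hide_below) next
      fmt[i, j] <- if (abs(v) >= bold_above) sprintf("*%.3f*", v)
                   else sprintf("%.3f", v)
    }
  }
  hdr <- rbind(Eigenvalues = sprintf("%.2f", model$eigenvalues[seq_len(k)]),
               `Explained variance (%)` = sprintf("%.1f", model$explained_var),
               `Cumulative variance (%)` = sprintf("%.1f",
                                                   model$cumulative_var))
  colnames(hdr) <- colnames(L)
  rbind(hdr, fmt)
}
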