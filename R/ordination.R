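# Ordination: principal coordinates analysis (metric embedding via
# eigendecomposition of the Gower double-centred squared-distance matrix)
# and non-metric multidimensional scaling (Kruskal stress-1 minimised by
# iterative majorisation with monotone regression).

#' Principal coordinates analysis
#'
#' Gower double-centring of `-d^2 / 2`, symmetric eigendecomposition,
#' coordinates `eigenvector * sqrt(eigenvalue)` for positive eigenvalues.
#' The percent variance of an axis is `100 * lambda / sum(positive
#' lambdas)` (negative eigenvalues, which arise for non-Euclidean
#' dissimilarities such as Bray-Curtis, are excluded from the denominator
#' by default). Axes are ordered by decreasing eigenvalue; the sign of each
#' axis is fixed so its first nonzero loading is non-negative.
#'
#' @param d a [as_dist_matrix()] (or square matrix), n >= 3.
#' @param negative_lambda how to form the variance denominator:
#'   `"exclude"` (positive eigenvalues only, default) or `"absolute"`
#'   (sum of absolute values of all eigenvalues).
#' @return object of class `ordination`: list with `points` (n x k matrix,
#'   k = number of positive eigenvalues), `eigenvalues` (all n),
#'   `percent_variance` (per positive axis), `method = "pcoa"`.
#' @export
pcoa <- function(d, negative_lambda = c("exclude", "absolute")) {
  negative_lambda <- match.arg(negative_lambda)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("pcoa needs n >= 3")
  a <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- ctr %*% a %*% ctr
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  tol <- 1e-9 * max(abs(e$values), 1)
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), nrow = length(pos))
  # sign convention: first nonzero loading of each axis non-negative
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > tol)
    if (length(nz) > 0 && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  denom <- switch(negative_lambda,
                  exclude = sum(e$values[pos]),
                  absolute = sum(abs(e$values)))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(points = coords, eigenvalues = e$values,
                 percent_variance = 100 * e$values[pos] / denom,
                 method = "pcoa"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  if (x$method == "pcoa") {
    cat("PCoA: ", nrow(x$points), " points, ", ncol(x$points),
        " positive axes; first axes explain ",
        paste(sprintf("%.1f%%", head(x$percent_variance, 2)),
              collapse = " + "), "\n", sep = "")
  } else {
    cat("NMDS: ", nrow(x$points), " points in ", ncol(x$points),
        " dimensions, stress = ", format(x$stress, digits = 4),
        if (!x$converged) " (not converged; best so far)", "\n", sep = "")
  }
  invisible(x)
}

.stress1 <- function(dconf, dhat) {
  sqrt(sum((dconf - dhat)^2) / sum(dconf^2))
}

#' Non-metric multidimensional scaling
#'
#' Minimises Kruskal stress-1 (badness of fit between configuration
#' distances and the rank order of the input dissimilarities) by iterative
#' majorisation (Guttman transform) alternated with monotone (isotonic)
#' regression of configuration distances on the dissimilarity ranks. The
#' first restart starts from the PCoA configuration, the rest from random
#' configurations; the best final stress wins. The reported stress
#' sequence is non-increasing within a restart (iteration stops, keeping
#' the best configuration so far, if a numerical uptick occurs).
#'
#' @param d a [as_dist_matrix()] (or square matrix), n >= k + 1.
#' @param k embedding dimension (default 2).
#' @param n_restarts random restarts (default 4, first one PCoA-seeded).
#' @param max_iter maximum iterations per restart (default 200).
#' @param seed optional integer seed for the random starts.
#' @param tol relative stress-improvement convergence tolerance.
#' @return object of class `ordination`: list with `points`, `stress`,
#'   `stress_sequence` (winning restart), `converged`, `method = "nmds"`.
#' @export
nmds <- function(d, k = 2L, n_restarts = 4L, max_iter = 200L, seed = NULL,
                 tol = 1e-7) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < k + 1) stop("nmds needs n >= k + 1")
  if (!is.null(seed)) {
    old <- .local_seed(as.integer(seed))
    on.exit(.restore_seed(old))
  }
  ut <- upper.tri(d)
  delta <- d[ut]
  ord <- order(delta)

  run_restart <- function(x0) {
    x <- x0
    dconf <- as.matrix(dist(x))[ut]
    fit <- isoreg(dconf[ord])
    dhat <- numeric(length(dconf))
    dhat[ord] <- fit$yf
    stress <- .stress1(dconf, dhat)
    seqs <- stress
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # Guttman transform with current disparities
      dh <- matrix(0, n, n)
      dh[ut] <- dhat
      dh <- dh + t(dh)
      dc <- as.matrix(dist(x))
      ratio <- ifelse(dc > 0, dh / dc, 0)
      b <- -ratio
      diag(b) <- rowSums(ratio)
      x_new <- b %*% x / n
      dconf_new <- as.matrix(dist(x_new))[ut]
      fit <- isoreg(dconf_new[ord])
      dhat_new <- numeric(length(dconf_new))
      dhat_new[ord] <- fit$yf
      stress_new <- .stress1(dconf_new, dhat_new)
      if (stress_new > stress + 1e-12) break  # keep best so far
      improved <- stress - stress_new
      x <- x_new
      dconf <- dconf_new
      dhat <- dhat_new
      stress <- stress_new
      seqs <- c(seqs, stress)
      if (improved < tol * max(stress, 1e-12)) {
        converged <- TRUE
        break
      }
    }
    list(points = x, stress = stress, stress_sequence = seqs,
         converged = converged)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    x0 <- if (r == 1) {
      p <- pcoa(d)$points
      if (ncol(p) >= k) p[, seq_len(k), drop = FALSE] else
        cbind(p, matrix(rnorm(n * (k - ncol(p)), sd = 1e-4), n))
    } else {
      matrix(rnorm(n * k), n, k)
    }
    res <- run_restart(x0)
    if (is.null(best) || res$stress < best$stress) best <- res
  }
  rownames(best$points) <- rownames(d)
  colnames(best$points) <- paste0("NMDS", seq_len(k))
  structure(c(best, list(method = "nmds")), class = "ordination")
}
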