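# Distance matrices and permutational multivariate ANOVA, implemented from
# first principles (sums of squared inter-point distances, label
# permutation). Established packages are deliberately not called here: the
# permutation machinery itself is the point, and vegan serves as an
# independent cross-check in the test suite only.

#' Distance matrix container
#'
#' @param m square symmetric numeric matrix with zero diagonal.
#' @param metric metric label (`"bray_curtis"`, `"euclidean"`, ...).
#' @return matrix of class `dist_matrix` with attribute `metric`.
#' @export
as_dist_matrix <- function(m, metric = "unknown") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (any(abs(m - t(m)) > 1e-12)) stop("distance matrix must be symmetric")
  if (any(diag(m) != 0)) stop("distance matrix must have zero diagonal")
  if (any(m < 0)) stop("distances must be non-negative")
  structure(m, metric = metric, class = c("dist_matrix", "matrix", "array"))
}

#' Bray-Curtis dissimilarity
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` on non-negative abundance
#' rows (samples x features).
#'
#' @param mat numeric matrix, rows = samples, columns = features; no
#'   negative values.
#' @return a [as_dist_matrix()] with metric `"bray_curtis"`.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("Bray-Curtis requires non-negative abundances")
  rs <- rowSums(mat)
  num <- as.matrix(dist(mat, method = "manhattan"))
  den <- outer(rs, rs, "+")
  zero_pair <- which(den == 0 & upper.tri(den), arr.ind = TRUE)
  if (nrow(zero_pair) > 0) {
    rn <- rownames(mat)
    if (is.null(rn)) rn <- as.character(seq_len(nrow(mat)))
    stop("Bray-Curtis undefined for all-zero sample pair (",
         rn[zero_pair[1, 1]], ", ", rn[zero_pair[1, 2]], ")")
  }
  d <- num / den
  diag(d) <- 0
  as_dist_matrix(d, "bray_curtis")
}

#' Euclidean distance, optionally on z-scored columns
#'
#' Standardising (z-scoring each column) makes the distance invariant to
#' the measurement units of individual variables, which is the standard
#' treatment for physicochemical property matrices.
#'
#' @param mat numeric matrix, rows = samples.
#' @param standardize z-score columns first (default TRUE). Zero-variance
#'   columns contribute 0 after centering.
#' @return a [as_dist_matrix()] with metric `"euclidean"`.
#' @export
euclidean_dist <- function(mat, standardize = TRUE) {
  mat <- as.matrix(mat)
  if (standardize) {
    mu <- colMeans(mat)
    s <- apply(mat, 2, sd)
    s[s == 0] <- 1
    mat <- sweep(sweep(mat, 2, mu), 2, s, "/")
  }
  as_dist_matrix(as.matrix(dist(mat)), "euclidean")
}

# ---- PERMANOVA internals ---------------------------------------------------

.permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in levels(groups)) {
    ix <- which(groups == g)
    if (length(ix) > 1) {
      ss_within <- ss_within + sum(d2[ix, ix]) / (2 * length(ix))
    }
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

.pseudo_f <- function(d2, idx_by_group, df_among, df_within) {
  # idx_by_group: list of index vectors; d2 fixed. Fast inner loop for
  # permutations: only SS_within depends on the relabeling.
  n <- nrow(d2)
  ss_total <- attr(d2, "ss_total")
  ss_within <- 0
  for (ix in idx_by_group) {
    if (length(ix) > 1) ss_within <- ss_within + sum(d2[ix, ix]) /
        (2 * length(ix))
  }
  ss_among <- ss_total - ss_within
  if (ss_within <= 0) return(Inf)
  (ss_among / df_among) / (ss_within / df_within)
}

# number of distinct relabelings, with groups of equal size interchangeable
.n_relabelings <- function(sizes) {
  lg <- lfactorial(sum(sizes)) - sum(lfactorial(sizes)) -
    sum(lfactorial(table(sizes)))
  round(exp(lg))
}

# enumerate all distinct assignments of n items to groups of the given
# sizes, counting unordered swaps of equal-size groups once
.enumerate_relabelings <- function(sizes) {
  n <- sum(sizes)
  k <- length(sizes)
  res <- list()
  # canonical form: among a run of equal-size groups, block minima must
  # increase, so each unordered label swap is generated exactly once
  rec2 <- function(avail, gi, assign, min_first) {
    if (gi > k) {
      if (length(avail) == 0L) res[[length(res) + 1L]] <<- assign
      return(invisible(NULL))
    }
    s <- sizes[gi]
    anchor_needed <- gi > 1 && sizes[gi - 1] == s
    lower <- if (anchor_needed) min_first[gi - 1] else -Inf
    pool <- avail[avail > lower]
    if (length(pool) < s) return(invisible(NULL))
    # choose the block minimum f, then s-1 further elements above f
    for (fi in seq_len(length(pool) - s + 1L)) {
      f <- pool[fi]
      rest <- avail[avail > f]
      combs <- if (s == 1) list(integer(0)) else
        utils::combn(rest, s - 1, simplify = FALSE)
      for (cb in combs) {
        block <- c(f, cb)
        a2 <- assign
        a2[block] <- gi
        mf <- min_first
        mf[gi] <- f
        rec2(setdiff(avail, block), gi + 1L, a2, mf)
      }
    }
    invisible(NULL)
  }
  rec2(seq_len(n), 1L, integer(n), rep(-Inf, k))
  res
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Partitions the total sum of squared inter-point distances into among-
#' and within-group components and tests the pseudo-F ratio
#' `(SS_among / (g-1)) / (SS_within / (n-g))` by random relabeling of the
#' group memberships. When the number of distinct relabelings (unordered
#' swaps of equal-size groups counted once) does not exceed `n_perm`, the
#' full set is enumerated and the p-value is exact
#' (`#\{F_perm >= F_obs\} / N`, observed relabeling included); otherwise
#' `n_perm` random relabelings are drawn and
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`, which never reports 0.
#' Ties count as `>=` (conservative). Groups must be sorted out by the
#' caller; the reference analysis uses 999 permutations and alpha 0.05.
#'
#' @param d a [as_dist_matrix()] (or plain square matrix).
#' @param groups factor or character of group labels, one per row of `d`.
#' @param n_perm permutations for the sampled branch (default 999).
#' @param seed optional integer seed for the sampled branch.
#' @return object of class `permanova_result`: list with `pseudo_F`,
#'   `p_perm`, `method` (`"exact"` or `"sampled"`),
#'   `n_permutations_used`, `df_among`, `df_within`, `ss` (total, within,
#'   among), `degenerate`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = NULL) {
  d <- as.matrix(d)
  groups <- factor(groups)
  n <- nrow(d)
  g <- nlevels(groups)
  if (g < 2) stop("permanova needs at least 2 groups")
  if (n < 3) stop("permanova needs n >= 3")
  if (length(groups) != n) stop("groups length must match distance matrix")
  d2 <- d^2
  ss <- .permanova_ss(d2, groups)
  df_among <- g - 1L
  df_within <- n - g
  attr(d2, "ss_total") <- ss[["total"]]
  if (ss[["total"]] <= 0) {
    return(structure(list(pseudo_F = NA_real_, p_perm = NA_real_,
                          method = "degenerate", n_permutations_used = 0L,
                          df_among = df_among, df_within = df_within,
                          ss = ss, degenerate = TRUE),
                     class = "permanova_result"))
  }
  obs <- .pseudo_f(d2, split(seq_len(n), groups), df_among, df_within)
  eps <- 1e-12 * max(1, abs(if (is.finite(obs)) obs else 0))
  sizes <- as.integer(table(groups))
  n_distinct <- .n_relabelings(sizes)
  if (n_distinct <= n_perm + 0.5) {
    # order sizes as the enumerator expects arbitrary order; it anchors
    # equal-size runs, so sort to make runs contiguous
    ord_sizes <- sort(sizes, decreasing = TRUE)
    labelings <- .enumerate_relabelings(ord_sizes)
    f_all <- vapply(labelings, function(a) {
      .pseudo_f(d2, split(seq_len(n), a), df_among, df_within)
    }, numeric(1))
    p <- sum(f_all >= obs - eps) / length(f_all)
    method <- "exact"
    used <- length(labelings)
  } else {
    if (!is.null(seed)) {
      old <- .local_seed(as.integer(seed))
      on.exit(.restore_seed(old))
    }
    b <- 0L
    for (i in seq_len(n_perm)) {
      perm <- sample.int(n)
      f_p <- .pseudo_f(d2, split(perm, groups), df_among, df_within)
      if (f_p >= obs - eps) b <- b + 1L
    }
    p <- (1 + b) / (1 + n_perm)
    method <- "sampled"
    used <- as.integer(n_perm)
  }
  structure(list(pseudo_F = obs, p_perm = p, method = method,
                 n_permutations_used = used, df_among = df_among,
                 df_within = df_within, ss = ss, degenerate = FALSE),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA: pseudo-F = ", format(x$pseudo_F, digits = 5),
      " (df ", x$df_among, ", ", x$df_within, "), p = ",
      format(x$p_perm, digits = 4), " [", x$method, ", ",
      x$n_permutations_used, " relabelings]\n", sep = "")
  invisible(x)
}

#' Pairwise PERMANOVA comparisons
#'
#' Runs a two-group test for every unordered group pair on the pair's
#' sub-matrix and reports the multivariate analogue of the t statistic,
#' `pseudo_t = sqrt(pseudo_F)`. Small designs (e.g. 3 vs 3 replicates)
#' admit very few distinct relabelings, so whenever that number falls
#' below `montecarlo_min_perms` a Monte-Carlo p-value is additionally
#' computed from a large resample (with replacement) of the permutation
#' statistic; both p-values are always reported when computed.
#'
#' @param d a [as_dist_matrix()].
#' @param groups group labels, one per row of `d`.
#' @param n_perm permutations for the sampled branch (default 999).
#' @param montecarlo_min_perms threshold on distinct relabelings below
#'   which the Monte-Carlo p is added (default 100).
#' @param montecarlo_draws resample size (default 10000).
#' @param seed optional integer seed.
#' @return data.frame with one row per pair: `group1`, `group2`,
#'   `pseudo_t`, `p_perm`, `n_distinct`, `p_montecarlo` (NA when not
#'   computed).
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999L,
                               montecarlo_min_perms = 100L,
                               montecarlo_draws = 10000L, seed = NULL) {
  d <- as.matrix(d)
  groups <- factor(groups)
  lv <- levels(groups)
  if (!is.null(seed)) {
    old <- .local_seed(as.integer(seed))
    on.exit(.restore_seed(old))
  }
  rows <- list()
  for (i in seq_len(length(lv) - 1)) {
    for (j in seq((i + 1), length(lv))) {
      ix <- which(groups %in% c(lv[i], lv[j]))
      if (length(ix) < 3 || length(unique(groups[ix])) < 2 ||
          min(table(droplevels(groups[ix]))) < 1) {
        warning("pair (", lv[i], ", ", lv[j], ") skipped: too few members")
        next
      }
      sub <- d[ix, ix]
      sub_groups <- droplevels(groups[ix])
      res <- permanova(sub, sub_groups, n_perm = n_perm)
      sizes <- as.integer(table(sub_groups))
      n_distinct <- .n_relabelings(sizes)
      p_mc <- NA_real_
      if (n_distinct < montecarlo_min_perms) {
        d2 <- sub^2
        attr(d2, "ss_total") <- .permanova_ss(d2, sub_groups)[["total"]]
        obs <- res$pseudo_F
        eps <- 1e-12 * max(1, abs(if (is.finite(obs)) obs else 0))
        nsub <- length(ix)
        b <- 0L
        for (r in seq_len(montecarlo_draws)) {
          perm <- sample.int(nsub)
          f_p <- .pseudo_f(d2, split(perm, sub_groups), res$df_among,
                           res$df_within)
          if (f_p >= obs - eps) b <- b + 1L
        }
        p_mc <- (1 + b) / (1 + montecarlo_draws)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = lv[i], group2 = lv[j],
        pseudo_t = sqrt(res$pseudo_F), p_perm = res$p_perm,
        n_distinct = n_distinct, p_montecarlo = p_mc,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
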