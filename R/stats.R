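# Multivariate differentiation: z-scored Euclidean distances, perMANOVA
# and PERMDISP permutation tests (999 permutations), and PCA on the
# correlation matrix with broken-stick component significance.

#' Z-score a feature table and build a Euclidean distance matrix
#'
#' Each selected column is standardised to mean 0, sd 1 across events and
#' pairwise Euclidean distances are computed.  The default variable subset
#' is the fifteen starred parameters (-3 dB variants only).
#'
#' @param table event feature table ([build_event_table()] output or any
#'   data.frame containing the feature columns).
#' @param variables character vector of columns to use.
#' @return a `dist` object with a `"zscores"` attribute holding the
#'   standardised matrix.
#' @export
zscore_and_distance <- function(table,
                                variables = feature_names(starred = TRUE)) {
  x <- as.matrix(table[, variables, drop = FALSE])
  if (any(!is.finite(x))) stop("feature table contains non-finite values")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(variables[sds == 0], collapse = ", "))
  z <- scale(x)
  d <- dist(z)
  attr(d, "zscores") <- z
  d
}

.permutation_result <- function(stat, perm_stats, n_perm, df_between,
                                df_within) {
  p <- (sum(perm_stats >= stat - 1e-12) + 1) / (n_perm + 1)
  structure(list(statistic = stat, p_value = p, n_permutations = n_perm,
                 df_between = df_between, df_within = df_within,
                 perm_stats = perm_stats),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("pseudo-F(%d, %d) = %.3f, p = %.4g (%d permutations)\n",
              x$df_between, x$df_within, x$statistic, x$p_value,
              x$n_permutations))
  invisible(x)
}

# pseudo-F from squared distances for a label vector
.permanova_f <- function(d2, labels, n) {
  groups <- unique(labels)
  g <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (grp in groups) {
    idx <- which(labels == grp)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  (ss_between / (g - 1)) / (ss_within / (n - g))
}

#' Permutational multivariate analysis of variance (perMANOVA)
#'
#' Pseudo-F computed from between/within sums of squared inter-point
#' distances; the p-value is the proportion of label permutations (plus the
#' observed one) whose F meets or exceeds the observed F, so the smallest
#' attainable p with 999 permutations is 0.001.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param labels group labels (>= 2 groups).
#' @param n_perm number of permutations.
#' @return object of class `permutation_test`.
#' @export
permanova <- function(d, labels, n_perm = 999) {
  m <- as.matrix(d)
  n <- nrow(m)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  g <- length(unique(labels))
  if (g < 2) stop("need at least two groups")
  d2 <- m^2
  f_obs <- .permanova_f(d2, labels, n)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    .permanova_f(d2, sample(labels), n)
  }, numeric(1))
  .permutation_result(f_obs, f_perm, n_perm, g - 1, n - g)
}

# principal-coordinate embedding of a distance matrix, keeping real and
# imaginary axes separately (negative eigenvalues)
.pcoa_axes <- function(m) {
  n <- nrow(m)
  a <- -0.5 * m^2
  centering <- diag(n) - matrix(1 / n, n, n)
  b <- centering %*% a %*% centering
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  neg <- e$values < -tol
  list(real = e$vectors[, pos, drop = FALSE] %*%
         diag(sqrt(e$values[pos]), sum(pos)),
       imag = e$vectors[, neg, drop = FALSE] %*%
         diag(sqrt(-e$values[neg]), sum(neg)))
}

# distances to group centroids in PCoA space (imaginary axes subtract)
.centroid_distances <- function(axes, labels) {
  z <- numeric(length(labels))
  for (grp in unique(labels)) {
    idx <- which(labels == grp)
    cr <- colMeans(axes$real[idx, , drop = FALSE])
    dr <- sweep(axes$real[idx, , drop = FALSE], 2, cr)
    d2 <- rowSums(dr^2)
    if (ncol(axes$imag) > 0) {
      ci <- colMeans(axes$imag[idx, , drop = FALSE])
      di <- sweep(axes$imag[idx, , drop = FALSE], 2, ci)
      d2 <- d2 - rowSums(di^2)
    }
    z[idx] <- sqrt(pmax(d2, 0))
  }
  z
}

.anova_f <- function(z, labels) {
  n <- length(z)
  groups <- unique(labels)
  g <- length(groups)
  grand <- mean(z)
  ssb <- 0
  ssw <- 0
  for (grp in groups) {
    zi <- z[labels == grp]
    ssb <- ssb + length(zi) * (mean(zi) - grand)^2
    ssw <- ssw + sum((zi - mean(zi))^2)
  }
  (ssb / (g - 1)) / (ssw / (n - g))
}

#' Permutation test of multivariate dispersion homogeneity (PERMDISP)
#'
#' Each point's distance to its group centroid is computed in
#' principal-coordinate space (negative eigenvalue axes subtract, following
#' the standard correction), a one-way ANOVA F is formed on those
#' distances, and significance is assessed by permuting the distances
#' across groups.
#'
#' @inheritParams permanova
#' @return `permutation_test` with an extra `group_dispersion` field (mean
#'   centroid distance per group).
#' @export
permdisp <- function(d, labels, n_perm = 999) {
  m <- as.matrix(d)
  n <- nrow(m)
  labels <- as.character(labels)
  stopifnot(length(labels) == n)
  groups <- unique(labels)
  g <- length(groups)
  if (g < 2) stop("need at least two groups")
  if (any(table(labels) < 2))
    stop("dispersion undefined for groups of size 1")
  axes <- .pcoa_axes(m)
  z <- .centroid_distances(axes, labels)
  f_obs <- .anova_f(z, labels)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    .anova_f(z, sample(labels))
  }, numeric(1))
  out <- .permutation_result(f_obs, f_perm, n_perm, g - 1, n - g)
  out$group_dispersion <- vapply(groups, function(grp) {
    mean(z[labels == grp])
  }, numeric(1))
  names(out$group_dispersion) <- groups
  out
}

#' Broken-stick expected eigenvalue proportions
#'
#' @param p number of components.
#' @return numeric vector `b_k = (1/p) * sum_{i=k}^{p} 1/i`, summing to 1.
#' @export
broken_stick <- function(p) {
  vapply(seq_len(p), function(k) sum(1 / (k:p)) / p, numeric(1))
}

#' PCA on the correlation matrix with broken-stick significance
#'
#' Events are standardised (PCA on the correlation matrix); a component is
#' deemed significant when its proportion of variance exceeds the
#' broken-stick expectation for its rank.
#'
#' @inheritParams zscore_and_distance
#' @return object of class `pca_broken_stick`: eigenvalues, proportions,
#'   loadings, scores, broken-stick proportions, significance flags.
#' @export
pca_broken_stick <- function(table,
                             variables = feature_names(starred = TRUE)) {
  x <- as.matrix(table[, variables, drop = FALSE])
  if (nrow(x) < 3 || ncol(x) < 2) stop("need >= 3 rows and >= 2 variables")
  if (any(apply(x, 2, sd) == 0)) stop("constant column in PCA input")
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  prop <- eig / sum(eig)
  bs <- broken_stick(length(eig))
  # sequential rule: a component is significant only while every component
  # up to and including it exceeds its broken-stick expectation (trailing
  # components trivially exceed their tiny expectations otherwise)
  sig <- cumprod(prop > bs) > 0
  structure(list(eigenvalues = eig, proportion = prop,
                 loadings = pc$rotation, scores = pc$x,
                 broken_stick = bs, significant = sig),
            class = "pca_broken_stick")
}

#' @export
print.pca_broken_stick <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat("PCA on correlation matrix; first", k, "components:\n")
  print(round(rbind(proportion = x$proportion[1:k],
                    broken_stick = x$broken_stick[1:k]), 4))
  cat("significant: ", paste(which(x$significant), collapse = ", "), "\n")
  invisible(x)
}
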