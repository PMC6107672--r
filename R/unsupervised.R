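resolve_rows <- function(rows, n) {
  if (is.null(rows)) return(seq_len(n))
  if (is.logical(rows)) return(which(rows))
  as.integer(rows)
}

# Unsupervised analyses on the aligned feature matrix: greedy orthogonal
# matching pursuit over the peak columns, hierarchical bisecting k-means
# segmentation, PCA with unit-variance scaling, and a PLSA aspect model fit by
# EM with deterministic (nonnegative-SVD) initialization.

#' Select peak columns by simultaneous orthogonal matching pursuit
#'
#' Greedy sparse selection of the peak columns that best reconstruct the
#' mean-centered, unit-variance-scaled intensity matrix. At each step the
#' column (unit-normalized) whose residual energy is largest is added, and the
#' residual is the projection of the scaled matrix onto the orthogonal
#' complement of the selected columns' span. Columns are standardized so the
#' selection reflects spatial covariation rather than absolute abundance;
#' segmentation distances are computed on the same scaling. Deterministic.
#'
#' @param fm a `feature_matrix`, or a plain numeric matrix
#' @param n_atoms number of columns to select (default `min(200, ncol)`)
#' @return integer vector of column indices in selection order
#' @export
select_peaks_omp <- function(fm, n_atoms = NULL) {
  x <- if (inherits(fm, "feature_matrix")) fm$values else fm
  p <- ncol(x)
  n_atoms <- n_atoms %||% min(200L, p)
  stopifnot(n_atoms >= 1, n_atoms <= p)
  xc <- scale(x, center = TRUE, scale = FALSE)
  norms <- sqrt(colSums(xc^2))
  degenerate <- norms < 1e-12
  if (all(degenerate)) {
    warning("select_peaks_omp: all columns constant; selecting column 1")
    return(1L)
  }
  # centered, unit-norm columns: dictionary and reconstruction target alike
  d <- sweep(xc, 2, pmax(norms, 1e-12), "/")
  xc <- d
  if (p >= 2 && all(abs(stats::cor(x[, !degenerate, drop = FALSE])[
    upper.tri(diag(sum(!degenerate)))] - 1) < 1e-12)) {
    warning("select_peaks_omp: all columns identical; selecting one")
    return(which(!degenerate)[1])
  }
  selected <- integer(0)
  resid <- xc
  for (k in seq_len(n_atoms)) {
    score <- colSums(crossprod(d, resid)^2)    # residual energy per atom
    score[selected] <- -Inf
    score[degenerate] <- -Inf
    if (all(!is.finite(score))) break
    j <- unname(which.max(score))
    selected <- c(selected, j)
    ds <- d[, selected, drop = FALSE]
    # project xc onto span(ds) and subtract
    g <- crossprod(ds)
    coef <- solve(g + diag(1e-10, ncol(ds)), crossprod(ds, xc))
    resid <- xc - ds %*% coef
  }
  selected
}

#' Hierarchical segmentation by bisecting k-means
#'
#' Top-down splitting of spectra by similarity: starting from one segment, the
#' segment with the largest within-segment sum of squared distances is split
#' by 2-means at every level, on unit-variance standardized, OMP-selected
#' columns. Level k of the tree has k segments, and level k+1 refines level k.
#' A fixed seed yields an identical tree.
#'
#' @param fm a `feature_matrix` or numeric matrix
#' @param n_segments maximum number of segments (tree depth), >= 2
#' @param seed integer seed for the 2-means initializations
#' @param rows optional logical/integer row subset (e.g. tissue pixels only)
#' @param n_atoms columns to pre-select with [select_peaks_omp()];
#'   `NULL` selects `min(200, ncol)`
#' @param nstart random starts per 2-means split
#' @return a `segmentation_tree`: `labels` (matrix, one column per level,
#'   level k in column k), `split_lineage` (which segment split at each
#'   level), `segment_means` (per final segment, on the original columns),
#'   `rows` (row indices used)
#' @export
bisect_kmeans <- function(fm, n_segments, seed = 1, rows = NULL,
                          n_atoms = NULL, nstart = 10) {
  x_full <- if (inherits(fm, "feature_matrix")) fm$values else fm
  rows <- resolve_rows(rows, nrow(x_full))
  x <- x_full[rows, , drop = FALSE]
  stopifnot(n_segments >= 2)
  if (nrow(x) < n_segments) stop("bisect_kmeans: fewer spectra than segments")
  sel <- select_peaks_omp(x, n_atoms = n_atoms)
  xs <- x[, sel, drop = FALSE]
  sds <- apply(xs, 2, stats::sd)
  xs <- sweep(xs, 2, pmax(sds, 1e-12), "/")
  if (nrow(unique(xs)) < n_segments) {
    stop("bisect_kmeans: fewer distinct spectra than segments")
  }

  labels <- matrix(1L, nrow = nrow(xs), ncol = n_segments)
  lineage <- integer(n_segments - 1)
  wss <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(scale(xs[idx, , drop = FALSE], scale = FALSE)^2)
  }
  seg_wss <- c(wss(seq_len(nrow(xs))))
  for (level in 2:n_segments) {
    labels[, level] <- labels[, level - 1]
    splittable <- which(vapply(seq_len(level - 1),
                               function(s) sum(labels[, level] == s) >= 2, TRUE))
    if (length(splittable) == 0) stop("bisect_kmeans: no segment large enough to split")
    target <- splittable[which.max(seg_wss[splittable])]
    lineage[level - 1] <- target
    idx <- which(labels[, level] == target)
    km <- with_seed(derive_seed(seed, paste0("bisect_level_", level)),
                    stats::kmeans(xs[idx, , drop = FALSE], centers = 2,
                                  nstart = nstart, iter.max = 100))
    labels[idx[km$cluster == 2], level] <- level
    seg_wss[target] <- wss(which(labels[, level] == target))
    seg_wss[level] <- wss(which(labels[, level] == level))
  }
  seg_means <- do.call(rbind, lapply(seq_len(n_segments), function(s) {
    colMeans(x[labels[, n_segments] == s, , drop = FALSE])
  }))
  structure(list(labels = labels, split_lineage = lineage,
                 segment_means = seg_means, rows = rows,
                 selected_columns = sel),
            class = "segmentation_tree")
}

#' @export
print.segmentation_tree <- function(x, ...) {
  cat(sprintf("segmentation_tree: %d spectra, %d levels; split lineage: %s\n",
              nrow(x$labels), ncol(x$labels),
              paste(x$split_lineage, collapse = " -> ")))
  invisible(x)
}

#' PCA of the feature matrix with unit-variance scaling
#'
#' Columns are standardized to unit variance before the eigendecomposition,
#' components are ordered by explained variance, and each loading vector is
#' sign-fixed so its largest-magnitude entry is positive (score-image polarity
#' is otherwise arbitrary). Constant columns are dropped with a warning.
#'
#' @param fm a `feature_matrix` or numeric matrix
#' @param n_components number of components (default 5)
#' @param rows optional row subset
#' @return a `latent_decomposition`: `method = "PCA"`, `loadings`
#'   (columns x components), `scores` (rows x components), `explained`
#'   (per-component explained-variance %), `centers_used` (column m/z if
#'   available), `rows`
#' @export
pca_decompose <- function(fm, n_components = 5, rows = NULL) {
  x <- if (inherits(fm, "feature_matrix")) fm$values else fm
  centers <- if (inherits(fm, "feature_matrix")) fm$centers else seq_len(ncol(x))
  rows <- resolve_rows(rows, nrow(x))
  x <- x[rows, , drop = FALSE]
  keep <- apply(x, 2, stats::sd) > 0
  if (!all(keep)) {
    warning("pca_decompose: dropping ", sum(!keep), " constant column(s)")
    x <- x[, keep, drop = FALSE]
    centers <- centers[keep]
  }
  if (ncol(x) < n_components) stop("pca_decompose: fewer non-constant columns than components")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  k <- seq_len(n_components)
  load <- pc$rotation[, k, drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, "*")
  scores <- sweep(pc$x[, k, drop = FALSE], 2, flip, "*")
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(method = "PCA", n_components = n_components,
                 loadings = load, scores = scores, explained = expl[k],
                 centers_used = centers, rows = rows),
            class = "latent_decomposition")
}

# deterministic nonnegative seeding from the SVD (NNDSVD-style): for each
# component take the dominant sign variant of the rank-1 pair, clip at zero.
# A dense floor (5% of the mean) replaces the clipped zeros: exact zeros are
# absorbing states of the EM updates and strand the fit in poor local optima.
nndsvd_init <- function(x, k) {
  s <- svd(x, nu = k, nv = k)
  w <- matrix(0, nrow(x), k)   # per-row mixture seeds
  h <- matrix(0, k, ncol(x))   # per-component distribution seeds
  for (j in seq_len(k)) {
    u <- s$u[, j]; v <- s$v[, j]
    # fix SVD sign ambiguity deterministically
    if (sum(v^3) < 0) { u <- -u; v <- -v }
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    if (sqrt(sum(up^2)) * sqrt(sum(vp^2)) >= sqrt(sum(un^2)) * sqrt(sum(vn^2))) {
      w[, j] <- up; h[j, ] <- vp
    } else {
      w[, j] <- un; h[j, ] <- vn
    }
  }
  w <- w + 0.05 * mean(w)
  h <- h + 0.05 * mean(h)
  list(pzd = w / rowSums(w),                    # P(z|d)
       pwz = sweep(h, 1, rowSums(h), "/"))      # P(w|z)
}

#' PLSA aspect model of the spectrum-by-peak matrix
#'
#' Factorizes the nonnegative feature matrix as
#' `P(w|d) = sum_z P(z|d) P(w|z)` by EM. Initialization is deterministic:
#' a nonnegative SVD seeding, so repeated runs are identical. Iteration stops
#' when the relative log-likelihood change falls below `tol` or after
#' `max_iter` iterations. Component loadings `P(w|z)` and per-spectrum
#' mixtures `P(z|d)` live on probability simplices; the log-likelihood is
#' non-decreasing over EM iterations.
#'
#' @param fm a `feature_matrix` or nonnegative numeric matrix
#' @param n_components number of aspects (>= 2, default 5)
#' @param tol relative log-likelihood convergence tolerance
#' @param max_iter maximum EM iterations
#' @param rows optional row subset
#' @return a `latent_decomposition`: `method = "PLSA"`, `loadings`
#'   (components x columns, each row summing to 1), `scores` (rows x
#'   components, each row summing to 1), `log_likelihood` (trace), `rows`
#' @export
plsa_decompose <- function(fm, n_components = 5, tol = 1e-6, max_iter = 500,
                           rows = NULL) {
  x <- if (inherits(fm, "feature_matrix")) fm$values else fm
  rows <- resolve_rows(rows, nrow(x))
  x <- x[rows, , drop = FALSE]
  if (any(x < 0)) stop("plsa_decompose: negative input; PLSA requires nonnegative data")
  stopifnot(n_components >= 2)
  nz_rows <- rowSums(x) > 0
  if (!all(nz_rows)) x <- x + 1e-12  # keep empty spectra on the simplex
  k <- n_components
  init <- nndsvd_init(x, k)
  pzd <- init$pzd          # n x k
  pwz <- init$pwz          # k x p
  nd <- rowSums(x)
  loglik <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    mix <- pzd %*% pwz                       # n x p, P(w|d)
    mix <- pmax(mix, 1e-300)
    ll <- sum(x * log(mix))
    loglik <- c(loglik, ll)
    if (is.finite(prev) && abs(ll - prev) <= tol * abs(prev)) break
    prev <- ll
    ratio <- x / mix                         # n x p
    pzd_new <- matrix(0, nrow(x), k)
    pwz_new <- matrix(0, k, ncol(x))
    for (z in seq_len(k)) {
      # q_z(d,w) * n(d,w) = pzd[d,z] * pwz[z,w] * ratio[d,w]
      t_dw_row <- pzd[, z] * sweep(ratio, 2, pwz[z, ], "*")
      pzd_new[, z] <- rowSums(t_dw_row)
      pwz_new[z, ] <- colSums(t_dw_row)
    }
    pzd <- pzd_new / pmax(rowSums(pzd_new), 1e-300)
    pwz <- sweep(pwz_new, 1, pmax(rowSums(pwz_new), 1e-300), "/")
  }
  structure(list(method = "PLSA", n_components = k,
                 loadings = pwz, scores = pzd, log_likelihood = loglik,
                 n_iter = length(loglik), rows = rows),
            class = "latent_decomposition")
}

#' @export
print.latent_decomposition <- function(x, ...) {
  cat(sprintf("latent_decomposition (%s): %d components, %d spectra\n",
              x$method, x$n_components, nrow(x$scores)))
  if (x$method == "PCA") {
    cat("  explained %:", paste(sprintf("%.2f", x$explained), collapse = ", "), "\n")
  } else {
    cat(sprintf("  EM iterations: %d, final log-likelihood: %.4f\n",
                x$n_iter, utils::tail(x$log_likelihood, 1)))
  }
  invisible(x)
}
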