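# Cluster-level metrics: packing fraction, composition ratios, ellipse
# eccentricity, and PCA + Gaussian-mixture typing of the 8-feature table.

#' Molecular cross-section areas (nm^2)
#'
#' Default single-molecule cross-section areas used by
#' [packing_fraction()]: ~38 nm^2 for the tetramer (GlpF) and ~43 nm^2
#' for the pentamer (FocA).
#' @export
cross_section_areas <- function() c(glpf = 38, foca = 43)

#' 2D packing fraction of a protein cluster
#'
#' \deqn{f = \frac{n_{GlpF} A_{GlpF} + n_{FocA} A_{FocA}}{A_{cluster}}}
#' Values above 1 are permitted and flagged: an apparent packing fraction
#' f > 1 indicates nonplanar (tilted/domed) cluster architecture rather
#' than an error.
#'
#' @param n_glpf,n_foca molecule counts (>= 0).
#' @param a_cluster cluster area, nm^2 (> 0).
#' @param areas named vector with elements `glpf`, `foca` (nm^2).
#' @return The packing fraction, with attribute `nonplanar` (`TRUE` when
#'   f > 1).
#' @export
packing_fraction <- function(n_glpf, n_foca, a_cluster,
                             areas = cross_section_areas()) {
  if (n_glpf < 0 || n_foca < 0) stop("counts must be >= 0")
  if (a_cluster <= 0) stop("a_cluster must be > 0")
  f <- (n_glpf * areas[["glpf"]] + n_foca * areas[["foca"]]) / a_cluster
  attr(f, "nonplanar") <- f > 1
  f
}

#' Pentamer composition ratios of a classified particle set
#'
#' Fraction of pentamers among edge particles and among all particles, and
#' the normalized edge-over-total ratio that quantifies edge enrichment of
#' the pentameric species.
#'
#' @param particles list of particles carrying `nf` and `location_class`,
#'   or a data frame with columns `nf` and `location_class`.
#' @param pentamer_nf symmetry order counted as "pentamer" (default 5).
#' @return A list: `edge_fraction`, `total_fraction`, `normalized_ratio`
#'   (NA with a flag when there are no edge particles), `n_edge`,
#'   `n_total`.
#' @export
composition_ratios <- function(particles, pentamer_nf = 5L) {
  df <- if (is.data.frame(particles)) particles else
    data.frame(nf = vapply(particles, function(p) p$nf, integer(1)),
               location_class = vapply(particles, function(p)
                 as.character(p$location_class), character(1)))
  n_total <- nrow(df)
  if (n_total == 0) stop("no particles")
  is_edge <- df$location_class == "edge"
  n_edge <- sum(is_edge)
  total_fraction <- mean(df$nf == pentamer_nf)
  if (n_edge == 0) {
    warning("no edge particles: normalized ratio undefined")
    return(list(edge_fraction = NA_real_, total_fraction = total_fraction,
                normalized_ratio = NA_real_, n_edge = 0L, n_total = n_total))
  }
  edge_fraction <- mean(df$nf[is_edge] == pentamer_nf)
  list(edge_fraction = edge_fraction, total_fraction = total_fraction,
       normalized_ratio = if (total_fraction > 0)
         edge_fraction / total_fraction else NA_real_,
       n_edge = as.integer(n_edge), n_total = as.integer(n_total))
}

#' Eccentricity of a cluster contour
#'
#' Second-moment ellipse fit to the contour points; eccentricity
#' e = sqrt(1 - (b/a)^2) in [0, 1).
#'
#' @param contour list with `theta` (radians) and `radius` (nm), or an
#'   n x 2 matrix of boundary points (nm).
#' @return Eccentricity in [0, 1).
#' @export
contour_eccentricity <- function(contour) {
  pts <- if (is.matrix(contour)) contour else
    cbind(contour$radius * cos(contour$theta),
          contour$radius * sin(contour$theta))
  pts <- scale(pts, scale = FALSE)
  ev <- eigen(stats::cov(pts), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  if (ev[1] == 0) return(0)
  sqrt(1 - ev[2] / ev[1])
}

# --- Gaussian mixture (EM, full covariance) -------------------------------

# log density of multivariate normal
#' @keywords internal
#' @noRd
dmvnorm_log <- function(x, mu, sigma) {
  p <- length(mu)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(rep(-Inf, nrow(x)))
  dev <- sweep(x, 2, mu)
  z <- forwardsolve(t(ch), t(dev))
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

#' Gaussian mixture model by EM
#'
#' Full-covariance Gaussian mixture fitted by expectation-maximization
#' with several seeded random restarts; deterministic for a fixed seed.
#'
#' @param x numeric matrix (n x p).
#' @param k number of components (default 2).
#' @param n_restarts random restarts (default 10).
#' @param max_iter EM iterations per restart.
#' @param tol log-likelihood convergence tolerance.
#' @param seed RNG seed.
#' @return A list: `labels` (hard assignment), `posterior` (n x k),
#'   `means`, `covariances`, `weights`, `loglik`.
#' @export
gmm_em <- function(x, k = 2L, n_restarts = 10L, max_iter = 200L,
                   tol = 1e-8, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  stopifnot(n > k)
  set.seed(seed)
  reg <- 1e-6 * mean(diag(stats::cov(x)))
  best <- list(loglik = -Inf)
  for (rs in seq_len(n_restarts)) {
    mu <- x[sample.int(n, k), , drop = FALSE]
    sig <- replicate(k, stats::cov(x) + reg * diag(p), simplify = FALSE)
    w <- rep(1 / k, k)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      lp <- vapply(seq_len(k), function(j)
        log(w[j]) + dmvnorm_log(x, mu[j, ], sig[[j]]), numeric(n))
      m <- apply(lp, 1, max)
      post <- exp(lp - m)
      sm <- rowSums(post)
      ll <- sum(log(sm) + m)
      post <- post / sm
      if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
      ll_old <- ll
      nk <- colSums(post)
      if (any(nk < 1e-8)) break    # empty component: abandon restart
      w <- nk / n
      for (j in seq_len(k)) {
        mu[j, ] <- colSums(post[, j] * x) / nk[j]
        dev <- sweep(x, 2, mu[j, ])
        sig[[j]] <- crossprod(dev * sqrt(post[, j])) / nk[j] + reg * diag(p)
      }
    }
    if (is.finite(ll) && ll > best$loglik) {
      best <- list(labels = max.col(post), posterior = post, means = mu,
                   covariances = sig, weights = w, loglik = ll)
    }
  }
  if (!is.finite(best$loglik)) stop("GMM did not converge in any restart")
  best
}

#' PCA and Gaussian-mixture typing of a cluster feature table
#'
#' Standardizes the feature table (zero mean, unit variance per column —
#' the features have incommensurable units), runs a principal component
#' analysis, and fits a 2-component Gaussian mixture in (pc1, pc2) space
#' to split the clusters into two major groups. Constant feature columns
#' are dropped with a warning. Deterministic for a fixed seed.
#'
#' @param features data frame or matrix of cluster features (rows =
#'   clusters; canonically 8 columns: n_total, edge_ratio, total_ratio,
#'   chi, packing_fraction, eccentricity, line_tension,
#'   leading_velocity).
#' @param n_groups mixture components (default 2).
#' @param seed RNG seed for the GMM restarts.
#'
#' @return A list of class `pca_gmm`: `pc_scores`, `explained_variance`
#'   (percent, decreasing, sums to 100), `loadings`, `group_labels`,
#'   `gmm`, `dropped_columns`, `seed`.
#' @export
pca_gmm <- function(features, n_groups = 2L, seed = 1L) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (nrow(x) < 10) stop("need >= 10 rows")
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sds == 0]
  if (length(dropped)) {
    warning("dropping constant feature column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x
  gm <- gmm_em(scores[, 1:2, drop = FALSE], k = n_groups, seed = seed)
  structure(list(pc_scores = scores, explained_variance = ev,
                 loadings = pc$rotation, group_labels = gm$labels,
                 gmm = gm, dropped_columns = dropped, seed = seed),
            class = "pca_gmm")
}

#' @export
print.pca_gmm <- function(x, ...) {
  cat(sprintf("pca_gmm: %d clusters, pc1 %.1f%%, pc2 %.1f%% (groups: %s)\n",
              nrow(x$pc_scores), x$explained_variance[1],
              x$explained_variance[2],
              paste(table(x$group_labels), collapse = "/")))
  invisible(x)
}
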