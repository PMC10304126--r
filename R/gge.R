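#' GGE decomposition of a cell-mean table
#'
#' Centers the genotype-by-environment mean table by environment means
#' (removing the environment main effect, so genotype main effect plus
#' interaction — "G + GE" — remain), and decomposes the centered table by
#' SVD with genotype-focused singular-value partitioning: genotype
#' coordinates carry the singular values, environment coordinates are the
#' unit-norm right singular vectors.  No column scaling is applied.
#'
#' @param means g x e matrix of cell means (g >= 3).
#' @return Object of class `gge_fit`: `centered` (the environment-centered
#'   matrix), `lambda` (singular values), `gen_coord` (g x p, singular
#'   values absorbed), `env_coord` (e x p, unit scale), `var_explained`
#'   (per-axis fraction).
#' @export
fit_gge <- function(means) {
  m <- as.matrix(means)
  g <- nrow(m); e <- ncol(m)
  if (g < 3L || e < 1L) stop("need >= 3 genotypes", call. = FALSE)
  centered <- sweep(m, 2L, colMeans(m))
  if (all(abs(centered) < 1e-12)) {
    stop("no genotypic signal: all genotypes identical in every environment",
         call. = FALSE)
  }
  p <- min(g - 1L, e)
  sv <- svd(centered, nu = p, nv = p)
  lambda <- sv$d[seq_len(p)]
  u <- sv$u; v <- sv$v
  for (k in seq_len(p)) {               # reproducible axis signs
    i <- which.max(abs(u[, k]))
    if (u[i, k] < 0) { u[, k] <- -u[, k]; v[, k] <- -v[, k] }
  }
  gen_coord <- sweep(u, 2L, lambda, `*`)
  env_coord <- v
  rownames(gen_coord) <- rownames(m); rownames(env_coord) <- colnames(m)
  structure(list(centered = centered, lambda = lambda,
                 gen_coord = gen_coord, env_coord = env_coord,
                 var_explained = lambda^2 / sum(lambda^2)),
            class = "gge_fit")
}

#' @export
print.gge_fit <- function(x, ...) {
  cat(sprintf("GGE fit: %d genotypes x %d environments\n",
              nrow(x$gen_coord), nrow(x$env_coord)))
  cat("Axis 1-2 variance explained (%):",
      paste(sprintf("%.1f", 100 * utils::head(x$var_explained, 2)),
            collapse = " + "), "\n")
  invisible(x)
}

#' Rank genotypes against the ideal genotype
#'
#' The "genotype ranking" view of the GGE biplot: the average-environment
#' coordinate (AEC) direction is the unit vector toward the mean of the
#' environment coordinates in the first two axes; the *ideal genotype* sits
#' on that direction at the largest genotype projection (maximal mean
#' performance, zero instability).  Genotypes are ranked by Euclidean
#' distance of their axis-1/axis-2 coordinates to the ideal point —
#' closest first.
#'
#' @param fit A `gge_fit`.  When only one axis exists (e.g. a single
#'   environment), geometry collapses to that axis and the ranking equals
#'   the mean-yield ranking.
#' @return Tibble ordered by distance: `GEN`, `distance`, `projection`
#'   (signed length along the AEC direction), `rank`; the ideal point is
#'   attached as attribute `ideal`.
#' @export
ideal_genotype_ranking <- function(fit) {
  stopifnot(inherits(fit, "gge_fit"))
  n_ax <- min(2L, ncol(fit$gen_coord))
  gc <- fit$gen_coord[, seq_len(n_ax), drop = FALSE]
  ec <- fit$env_coord[, seq_len(n_ax), drop = FALSE]
  aec <- colMeans(ec)
  len <- sqrt(sum(aec^2))
  if (len < 1e-12) stop("degenerate average-environment direction",
                        call. = FALSE)
  aec <- aec / len
  proj <- drop(gc %*% aec)
  ideal <- aec * max(proj)
  dist <- sqrt(rowSums(sweep(gc, 2L, ideal)^2))
  out <- tibble::tibble(GEN = rownames(gc), distance = unname(dist),
                        projection = unname(proj))
  out <- out[order(out$distance), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "ideal") <- ideal
  out
}

#' One-call GGE ranking from plot data or a mean table
#'
#' @param x A balanced [met_data] object or a g x e matrix of cell means.
#' @return List with `fit` (`gge_fit`) and `ranking` (see
#'   [ideal_genotype_ranking()]).
#' @export
gge <- function(x) {
  m <- if (inherits(x, "met_data")) cell_means(x) else as.matrix(x)
  fit <- fit_gge(m)
  list(fit = fit, ranking = ideal_genotype_ranking(fit))
}
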