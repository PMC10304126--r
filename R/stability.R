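#' Weighted average of absolute IPCA scores
#'
#' The scalar stability index behind WAASB: for entity i (a genotype or an
#' environment) with scores `IPCA[i, k]` on p interaction axes and
#' nonnegative axis weights `EP[k]` (the variance explained by each axis),
#' `WAAS_i = sum_k |IPCA[i,k]| * EP[k] / sum_k EP[k]`.  Zero iff every
#' score of the entity is zero; lower is more stable.
#'
#' @param scores Numeric matrix, rows = entities, columns = axes.
#' @param ep Nonnegative axis weights, length = number of columns.
#' @return Named numeric vector of index values, one per row.
#' @seealso [waasb()] for the full pipeline from plot data.
#' @export
waasb_index <- function(scores, ep) {
  scores <- as.matrix(scores)
  stopifnot(length(ep) == ncol(scores), all(ep >= 0))
  if (sum(ep) == 0) {
    return(stats::setNames(rep(0, nrow(scores)), rownames(scores)))
  }
  drop(abs(scores) %*% ep) / sum(ep)
}

#' WAASB stability analysis of a balanced MET
#'
#' Computes the WAASB index — the weighted average of absolute scores from
#' the singular value decomposition of the BLUP-shrunken
#' genotype-by-environment matrix — for every genotype and every
#' environment, together with mean yields and the yield-by-stability
#' quadrant classification.
#'
#' All `p = min(g-1, e-1)` axes enter the index, weighted by their share of
#' the interaction variance.  Scores use the symmetric scaling
#' (singular vectors times the square root of the singular value), so
#' genotypes and environments share one biplot scale.
#'
#' @param x A balanced [met_data] object.
#' @param vc Variance components (computed if omitted).
#' @return Object of class `waasb_fit`: list with `scores` (tibble: `id`,
#'   `type` ("GEN"/"ENV"), `yield` — genotype mean or environment mean —
#'   `waasb`, `quadrant`), `gen_scores` and `env_scores` (score matrices),
#'   `ep`, `lambda`, and the shrinkage factor `s`.
#' @export
waasb <- function(x, vc = variance_components(x)) {
  stopifnot(inherits(x, "met_data"))
  bm <- blup_ge_matrix(x, vc)
  g <- nrow(bm); e <- ncol(bm)
  p <- min(g - 1L, e - 1L)
  sv <- svd(bm, nu = p, nv = p)
  lambda <- sv$d[seq_len(p)]
  u <- sv$u; v <- sv$v
  for (k in seq_len(p)) {               # sign convention as in fit_ammi
    i <- which.max(abs(u[, k]))
    if (u[i, k] < 0) { u[, k] <- -u[, k]; v[, k] <- -v[, k] }
  }
  scal <- sqrt(lambda)
  gen_scores <- sweep(u, 2L, scal, `*`)
  env_scores <- sweep(v, 2L, scal, `*`)
  rownames(gen_scores) <- rownames(bm)
  rownames(env_scores) <- colnames(bm)
  ep <- if (sum(lambda^2) > 0) lambda^2 / sum(lambda^2) else rep(0, p)

  m <- cell_means(x)
  gen_yield <- rowMeans(m); env_yield <- colMeans(m)
  w_gen <- waasb_index(gen_scores, ep)
  w_env <- waasb_index(env_scores, ep)
  scores <- tibble::tibble(
    id = c(rownames(bm), colnames(bm)),
    type = rep(c("GEN", "ENV"), c(g, e)),
    yield = unname(c(gen_yield, env_yield)),
    waasb = unname(c(w_gen, w_env)),
    quadrant = unname(c(quadrant_classify(gen_yield, w_gen),
                        quadrant_classify(env_yield, w_env)))
  )
  structure(list(scores = scores, gen_scores = gen_scores,
                 env_scores = env_scores, ep = ep, lambda = lambda,
                 s = attr(bm, "s"), vc = vc),
            class = "waasb_fit")
}

#' @export
print.waasb_fit <- function(x, ...) {
  cat("WAASB stability analysis\n")
  gen <- x$scores[x$scores$type == "GEN", ]
  print(gen[order(gen$waasb), ], n = 6)
  invisible(x)
}

#' Classify entities into yield-by-stability quadrants
#'
#' Quadrants of the WAASB-by-yield plot, with cut-off lines at the mean
#' yield and mean WAASB of the classified entities.  For genotypes:
#' I = low yield, unstable; II = high yield, unstable; III = low yield,
#' stable; IV = high yield, stable (broad adaptability — the selection
#' quadrant).  Ties on a cut-off count as high-yielding (`>=`) and stable
#' (`<=`), so an entity exactly on both lines lands in quadrant IV.
#'
#' @param yields,waasb Aligned numeric vectors (>= 2 entities).
#' @return Character vector of labels `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
quadrant_classify <- function(yields, waasb) {
  stopifnot(length(yields) == length(waasb))
  if (length(yields) < 2L) {
    stop("quadrant classification needs >= 2 entities", call. = FALSE)
  }
  high <- yields >= mean(yields)
  stable <- waasb <= mean(waasb)
  out <- ifelse(high,
                ifelse(stable, "IV", "II"),
                ifelse(stable, "III", "I"))
  stats::setNames(out, names(yields))
}

#' Blend mean performance and stability into a single selection score
#'
#' Rescales yields to [0, 100] (highest yield scores 100) and WAASB to
#' [0, 100] (lowest WAASB — most stable — scores 100), then forms the
#' weighted blend `(weight_y * Y' + (100 - weight_y) * W') / 100`.
#' `weight_y = 100` ranks purely on yield, `0` purely on stability.
#'
#' @param yields,waasb Aligned numeric vectors, each with spread (constant
#'   vectors cannot be rescaled and raise an error).
#' @param weight_y Weight on mean performance, in [0, 100] (default 50).
#' @return Named numeric vector of blended scores in [0, 100].
#' @export
waasby <- function(yields, waasb, weight_y = 50) {
  stopifnot(length(yields) == length(waasb),
            weight_y >= 0, weight_y <= 100)
  if (diff(range(yields)) == 0 || diff(range(waasb)) == 0) {
    stop("cannot rescale a constant vector", call. = FALSE)
  }
  y_res <- 100 * (yields - min(yields)) / diff(range(yields))
  w_res <- 100 * (max(waasb) - waasb) / diff(range(waasb))
  out <- (weight_y * y_res + (100 - weight_y) * w_res) / 100
  stats::setNames(out, names(yields))
}
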