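#' Moran's I spatial autocorrelation statistic
#'
#' Classical Moran's I,
#' `I = (n/W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`,
#' with either inverse-distance weights (optionally truncated at
#' `max_dist`) or rook adjacency on a lattice of spacing `lattice_step`.
#' Expectation under no autocorrelation is `-1/(n-1)`.
#'
#' @param values numeric vector (non-constant, length >= 3).
#' @param coords n x 2 coordinate matrix.
#' @param weights `"idw"` (default) or `"rook"`.
#' @param max_dist truncation distance for idw weights (`NULL` = none).
#' @param lattice_step neighbour spacing for rook weights (default 1).
#' @return the Moran's I statistic (single number).
#' @export
moranI <- function(values, coords, weights = c("idw", "rook"),
                   max_dist = NULL, lattice_step = 1) {
  weights <- match.arg(weights)
  n <- length(values)
  if (n < 3) stop("Moran's I needs at least 3 points", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("Moran's I is undefined for constant values", call. = FALSE)
  D <- as.matrix(stats::dist(coords))
  W <- if (weights == "idw") {
    w <- 1 / D
    w[!is.finite(w)] <- 0
    if (!is.null(max_dist)) w[D > max_dist] <- 0
    w
  } else {
    dx <- abs(outer(coords[, 1], coords[, 1], "-"))
    dy <- abs(outer(coords[, 2], coords[, 2], "-"))
    tol <- 1e-9 * lattice_step
    1 * ((abs(dx - lattice_step) < tol & dy < tol) |
         (abs(dy - lattice_step) < tol & dx < tol))
  }
  diag(W) <- 0
  sw <- sum(W)
  if (sw == 0) stop("all spatial weights are zero", call. = FALSE)
  z <- values - mean(values)
  (n / sw) * sum(W * tcrossprod(z)) / sum(z^2)
}

#' Checkerboard fold assignment
#'
#' Points are assigned to one of two folds by the parity of their block
#' indices: `fold = (floor((x-ox)/b) + floor((y-oy)/b)) mod 2`, giving the
#' alternating spatial blocks of a checkerboard. Both folds serve
#' alternately as training and test data.
#'
#' @param points a [LabeledPoints-class].
#' @param block_size block side length (map units), > 0.
#' @param origin checkerboard origin, default `c(0, 0)`.
#' @return integer vector of fold labels in `{0, 1}`.
#' @export
checkerboardAssign <- function(points, block_size, origin = c(0, 0)) {
  stopifnot(block_size > 0)
  bx <- floor((points@coords[, 1] - origin[1]) / block_size)
  by <- floor((points@coords[, 2] - origin[2]) / block_size)
  as.integer((bx + by) %% 2)
}

#' Candidate block sizes for checkerboard optimization
#'
#' Log-spaced sizes from twice the predictor resolution up to `max_size`
#' map units (10 degrees in the geographic setting).
#'
#' @param resolution predictor cell size.
#' @param max_size largest candidate (default 10).
#' @param n number of candidates.
#' @export
blockSizeCandidates <- function(resolution, max_size = 10, n = 8) {
  exp(seq(log(2 * resolution), log(max_size), length.out = n))
}

#' Choose the checkerboard block size
#'
#' Evaluates each candidate block size on three criteria and picks the one
#' with the best (smallest) unweighted rank sum:
#' \itemize{
#'   \item spatial autocorrelation between folds, as Moran's I of the
#'     presence/pseudo-absence label with inverse-distance weights
#'     truncated at five block sizes (smaller is better);
#'   \item environmental similarity of the folds, as the Euclidean distance
#'     between fold centroids in standardized predictor space (smaller is
#'     better);
#'   \item balance, as the standard deviation of per-fold record counts
#'     (smaller is better).
#' }
#' Candidates that leave a fold empty are invalid. Rank-sum ties break to
#' the smallest block size.
#'
#' @param points a [LabeledPoints-class] with env values and both labels.
#' @param candidates numeric vector of block sizes
#'   (see [blockSizeCandidates()]).
#' @param origin checkerboard origin.
#' @return list with `block_size` (chosen), `fold` (labels at the chosen
#'   size) and `diagnostics` (one row per candidate: block_size, valid,
#'   moran_i, env_distance, count_sd, rank_sum).
#' @export
optimizeBlockSize <- function(points, candidates, origin = c(0, 0)) {
  if (length(candidates) < 1) stop("no candidate block sizes", call. = FALSE)
  env <- pointEnv(points)
  if (ncol(env) == 0) stop("points carry no env values", call. = FALSE)
  Z <- scale(env)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  lab <- as.numeric(pointLabels(points) == "presence")
  rows <- lapply(candidates, function(b) {
    fold <- checkerboardAssign(points, b, origin)
    if (length(unique(fold)) < 2L)
      return(data.frame(block_size = b, valid = FALSE, moran_i = NA,
                        env_distance = NA, count_sd = NA))
    mi <- tryCatch(moranI(lab, points@coords, "idw", max_dist = 5 * b),
                   error = function(e) NA_real_)
    cent <- rowsum(Z, fold) / as.vector(table(fold))
    ed <- sqrt(sum((cent[1, ] - cent[2, ])^2))
    data.frame(block_size = b, valid = TRUE, moran_i = mi,
               env_distance = ed, count_sd = stats::sd(table(fold)))
  })
  diag <- do.call(rbind, rows)
  if (!any(diag$valid))
    stop("every candidate block size leaves a fold empty; ",
         "use kfoldAssign() instead", call. = FALSE)
  ok <- which(diag$valid)
  rk <- function(v) rank(v, ties.method = "min", na.last = "keep")
  rankSum <- rk(diag$moran_i[ok]) + rk(diag$env_distance[ok]) +
    rk(diag$count_sd[ok])
  diag$rank_sum <- NA_real_
  diag$rank_sum[ok] <- rankSum
  best <- ok[which(rankSum == min(rankSum, na.rm = TRUE))]
  chosen <- diag$block_size[best[which.min(diag$block_size[best])]]
  list(block_size = chosen,
       fold = checkerboardAssign(points, chosen, origin),
       diagnostics = diag)
}

#' Random k-fold assignment
#'
#' Random folds of near-equal size (`floor(n/k)` or `ceiling(n/k)`); used
#' for species with too few records for a spatial block design.
#'
#' @param points a [LabeledPoints-class].
#' @param k number of folds (default 3).
#' @param seed integer seed.
#' @return integer fold labels in `1..k`.
#' @export
kfoldAssign <- function(points, k = 3, seed = 1) {
  n <- nPoints(points)
  if (n < k) stop("fewer points (", n, ") than folds (", k, ")", call. = FALSE)
  withSeed(seed, sample(rep_len(seq_len(k), n)))
}

#' Assign cross-validation folds
#'
#' Species with at least `min_records` presence records get the
#' checkerboard design with data-driven block size
#' ([optimizeBlockSize()]); species with fewer get random k-fold
#' ([kfoldAssign()], `k = 3`).
#'
#' @param points presence + pseudo-absence [LabeledPoints-class] with env.
#' @param resolution predictor cell size (sets the candidate range).
#' @param min_records presence-count threshold for the checkerboard path
#'   (default 15).
#' @param k folds for the random design.
#' @param max_block largest candidate block size.
#' @param seed integer seed (k-fold path).
#' @return `points` with the `fold` slot filled; attribute `"method"` is
#'   `"checkerboard"` or `"kfold"`, and `"block_size"` is set on the
#'   checkerboard path.
#' @export
assignFolds <- function(points, resolution, min_records = 15, k = 3,
                        max_block = 10, seed = 1) {
  nPres <- sum(pointLabels(points) == "presence")
  if (nPres >= min_records) {
    opt <- optimizeBlockSize(points,
                             blockSizeCandidates(resolution, max_block))
    out <- initialize(points, fold = as.integer(opt$fold))
    attr(out, "method") <- "checkerboard"
    attr(out, "block_size") <- opt$block_size
  } else {
    out <- initialize(points, fold = as.integer(kfoldAssign(points, k, seed)))
    attr(out, "method") <- "kfold"
  }
  out
}
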