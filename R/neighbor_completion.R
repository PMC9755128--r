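# Core of the double multi-weighted nearest-neighbor (DMWNN) completion:
# neighbor indices, linearly decreasing weights, row/column filling,
# fusion, and multilayer stacking with auto-stop.

#' Linearly decreasing neighbor weights
#'
#' The t-th closest neighbor (t = 0, ..., k-1) receives weight
#' \deqn{\omega_t = \frac{2(k - t)}{k(k + 1)}}
#' so the weights decrease linearly with rank and sum exactly to 1
#' (telescoping over the triangular number k(k+1)/2).
#'
#' @param k Neighbor count, a positive integer.
#' @return Numeric vector of length `k`.
#' @examples
#' linear_weights(3)  # 1/2, 1/3, 1/6
#' @export
linear_weights <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1) stop("k must be a positive integer")
  k <- as.integer(k)
  t <- seq_len(k) - 1L
  2 * (k - t) / (k * (k + 1))
}

#' Per-row top-k neighbor index
#'
#' For each row `i` of a square similarity matrix, lists the `k` other rows
#' with the highest similarity to `i`, in descending similarity; ties are
#' broken by ascending row index so the ordering is deterministic across
#' platforms. The self-row is excluded by default: under the fill rule a
#' self-neighbor contributes nothing at zero cells yet would consume the
#' largest weight, so excluding it spends the weight budget on informative
#' neighbors. `include_self = TRUE` restores the literal top-k of the whole
#' row for comparison.
#'
#' A `k` exceeding the number of eligible neighbors is clamped with a
#' warning.
#'
#' @param sim Square `similarity_matrix` (or plain matrix).
#' @param k Neighbor count.
#' @param include_self Keep row `i` as its own candidate neighbor?
#' @return An `n x k` integer matrix of neighbor row indices with attributes
#'   `k` and `include_self`.
#' @export
build_neighbor_index <- function(sim, k, include_self = FALSE) {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  if (n != ncol(sim)) stop("similarity matrix must be square")
  if (length(k) != 1L || is.na(k) || k < 1) stop("k must be >= 1")
  kmax <- if (include_self) n else n - 1L
  if (kmax < 1L) stop("no eligible neighbors: matrix has a single row")
  if (k > kmax) {
    warning(sprintf("k = %d clamped to %d (only %d eligible neighbors)",
                    as.integer(k), kmax, kmax))
    k <- kmax
  }
  k <- as.integer(k)
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    cand <- if (include_self) seq_len(n) else setdiff(seq_len(n), i)
    # order() is stable, so ascending-index tie-break falls out of sorting
    # candidates (already ascending) by decreasing similarity
    ord <- cand[order(sim[i, cand], decreasing = TRUE)]
    idx[i, ] <- ord[seq_len(k)]
  }
  structure(idx, k = k, include_self = include_self)
}

# Sparse row-combination operator: W[i, idx[i,t]] = sim[i, idx[i,t]] * w[t].
# Filling row i is then (W %*% m)[i, ].
neighbor_weight_matrix <- function(idx, sim, w) {
  n <- nrow(sim)
  k <- ncol(idx)
  if (length(w) != k) stop("weight vector length differs from neighbor count")
  W <- matrix(0, n, n)
  rows <- rep(seq_len(n), times = k)
  cols <- as.vector(idx)
  W[cbind(rows, cols)] <- sim[cbind(rows, cols)] * rep(w, each = n)
  W
}

#' Fill the zero entries of a matrix from row neighbors
#'
#' Each zero cell `(i, j)` receives
#' \eqn{\sum_{t=0}^{k-1} m[K_{i,t}, j] \cdot S[i, K_{i,t}] \cdot \omega_t},
#' the weighted vote of row `i`'s nearest neighbors at column `j`; nonzero
#' cells are left untouched (`literal_ones = TRUE` instead overwrites them
#' with the constant 1, the reading that binarizes earlier-layer scores --
#' the two coincide on a binary input).
#'
#' @param m Numeric matrix with entries in `[0, 1]`.
#' @param idx Row-side neighbor index from [build_neighbor_index()].
#' @param sim Row-side similarity matrix.
#' @param w Weights from [linear_weights()], length `ncol(idx)`.
#' @param literal_ones Overwrite nonzero cells with 1 instead of keeping
#'   their value.
#' @return Matrix of the same shape; values stay in `[0, 1]` whenever
#'   `sim` and `m` do, since the weights sum to 1.
#' @export
fill_rows <- function(m, idx, sim, w, literal_ones = FALSE) {
  m <- as.matrix(m)
  sim <- as.matrix(sim)
  if (nrow(sim) != nrow(m) || ncol(sim) != nrow(m)) {
    stop("row-side similarity must be nrow(m) x nrow(m)")
  }
  if (nrow(idx) != nrow(m)) stop("neighbor index rows differ from nrow(m)")
  filled <- neighbor_weight_matrix(idx, sim, w) %*% m
  out <- ifelse(m == 0, filled, if (literal_ones) 1 else m)
  dimnames(out) <- dimnames(m)
  out
}

#' Fill the zero entries of a matrix from column neighbors
#'
#' The column-side counterpart of [fill_rows()]: operates on the transpose
#' with the disease-side neighbor index and similarity, then transposes
#' back.
#'
#' @param m Numeric matrix.
#' @param idx Column-side neighbor index (over `ncol(m)` entities).
#' @param sim Column-side similarity, `ncol(m) x ncol(m)`.
#' @param w Weights, length `ncol(idx)`.
#' @param literal_ones See [fill_rows()].
#' @return Matrix of the same shape as `m`.
#' @export
fill_columns <- function(m, idx, sim, w, literal_ones = FALSE) {
  t(fill_rows(t(as.matrix(m)), idx, sim, w, literal_ones = literal_ones))
}

#' Fuse two completed matrices
#'
#' Element-wise convex combination `eta1 * a + eta2 * b`. With
#' `eta1 + eta2 = 1` and both inputs preserving known positives at 1, the
#' fusion preserves them too.
#'
#' @param a,b Matrices of identical shape.
#' @param eta1,eta2 Fusion weights (default 0.5 each).
#' @return The fused matrix.
#' @export
fuse_scores <- function(a, b, eta1 = 0.5, eta2 = 0.5) {
  if (!all(dim(a) == dim(b))) stop("fuse: shapes differ")
  eta1 * a + eta2 * b
}

#' Completion model configuration
#'
#' Bundles the tunables of the DMWNN predictor. Defaults are the
#' configuration found best on the curated lncRNA-disease benchmark:
#' `lambda = 0.1`, `k = 217`, two layers, equal fusion weights.
#'
#' @param k Neighbor count (clamped per side to the available neighbors).
#' @param lambda Fused-similarity weight in `[0, 1]`.
#' @param layers Stacking depth `L`, between 1 and 5. Stacking more than
#'   five layers is not supported: each layer re-predicts from the previous
#'   layer's predictions, and depth drives the scores away from the data.
#' @param eta1,eta2 Fusion weights for the row- and column-filled matrices.
#' @param metric Similarity metric, `"fused"` or a baseline.
#' @param include_self Allow an entity as its own neighbor (literal top-k).
#' @param literal_ones Use the constant-1 overwrite for nonzero cells at
#'   every layer (audit mode; binarizes intermediate scores).
#' @return A list of class `dmwnn_config`.
#' @export
dmwnn_config <- function(k = 217, lambda = 0.1, layers = 2,
                         eta1 = 0.5, eta2 = 0.5,
                         metric = c("fused", "cosine", "pearson", "jaccard"),
                         include_self = FALSE, literal_ones = FALSE) {
  metric <- match.arg(metric)
  if (k < 1) stop("k must be >= 1")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (layers < 1 || layers > 5) stop("layers must lie in 1..5")
  if (eta1 < 0 || eta2 < 0) stop("fusion weights must be non-negative")
  structure(list(k = as.integer(k), lambda = lambda,
                 layers = as.integer(layers), eta1 = eta1, eta2 = eta2,
                 metric = metric, include_self = isTRUE(include_self),
                 literal_ones = isTRUE(literal_ones)),
            class = "dmwnn_config")
}

#' Predict lncRNA-disease association scores by multilayer neighbor filling
#'
#' Runs up to `cfg$layers` passes over the target matrix. Each pass fills
#' the remaining zero cells twice -- once from lncRNA-side neighbors
#' (rows), once from disease-side neighbors (columns) -- and fuses the two
#' results with weights `eta1`/`eta2`. Later passes start from the previous
#' fused matrix, so cells whose entire neighborhoods were zero in one pass
#' can acquire scores in the next. A pass is skipped (auto-stop) when no
#' zero cells remain. Known positives keep the score 1 throughout.
#'
#' @param y Binary lncRNA x disease adjacency (target matrix).
#' @param sl Row-side (lncRNA) similarity, `nrow(y)` square.
#' @param sd Column-side (disease) similarity, `ncol(y)` square.
#' @param cfg A [dmwnn_config()].
#' @return A `dmwnn_prediction`: list with `scores` (completed matrix in
#'   `[0, 1]`), `known` (binary mask of the input positives), `zero_counts`
#'   (zeros remaining before each executed layer), `layers_run`, and the
#'   `config`.
#' @export
predict_associations <- function(y, sl, sd, cfg = dmwnn_config()) {
  y <- as.matrix(y)
  sl <- as.matrix(sl)
  sd <- as.matrix(sd)
  check_binary(y, "target matrix")
  if (nrow(sl) != nrow(y)) stop("row-side similarity does not match target rows")
  if (nrow(sd) != ncol(y)) stop("column-side similarity does not match target columns")
  kl <- build_neighbor_index(sl, cfg$k, include_self = cfg$include_self)
  kd <- build_neighbor_index(sd, cfg$k, include_self = cfg$include_self)
  wl <- linear_weights(attr(kl, "k"))
  wd <- linear_weights(attr(kd, "k"))
  Wl <- neighbor_weight_matrix(kl, sl, wl)
  Wd <- neighbor_weight_matrix(kd, sd, wd)

  cur <- y
  zero_counts <- integer(0)
  layers_run <- 0L
  for (l in seq_len(cfg$layers)) {
    nz <- sum(cur == 0)
    if (nz == 0L) break
    zero_counts <- c(zero_counts, nz)
    a <- ifelse(cur == 0, Wl %*% cur,
                if (cfg$literal_ones && l > 1L) 1 else cur)
    b <- t(ifelse(t(cur) == 0, Wd %*% t(cur),
                  if (cfg$literal_ones && l > 1L) 1 else t(cur)))
    cur <- fuse_scores(a, b, cfg$eta1, cfg$eta2)
    layers_run <- l
  }
  dimnames(cur) <- dimnames(y)
  structure(list(scores = cur, known = y, zero_counts = zero_counts,
                 layers_run = layers_run, config = cfg),
            class = "dmwnn_prediction")
}

#' @export
print.dmwnn_prediction <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("DMWNN prediction: %d lncRNAs x %d diseases\n",
              nrow(x$scores), ncol(x$scores)))
  cat(sprintf("  metric=%s lambda=%.3g k=%d layers=%d (ran %d)\n",
              cfg$metric, cfg$lambda, cfg$k, cfg$layers, x$layers_run))
  cat(sprintf("  known positives: %d; zeros before each layer: %s\n",
              sum(x$known), paste(x$zero_counts, collapse = ", ")))
  invisible(x)
}

#' End-to-end prediction from three edge-list adjacencies
#'
#' Convenience pipeline: align vocabularies, build the concatenated
#' interaction profiles, compute both similarity matrices under the
#' configured metric, and run [predict_associations()].
#'
#' @param ld,ml,md Adjacencies (any orientation) holding the
#'   lncRNA-disease, lncRNA-miRNA and miRNA-disease edges.
#' @param cfg A [dmwnn_config()].
#' @return A `dmwnn_prediction`.
#' @export
dmwnn_predict <- function(ld, ml, md, cfg = dmwnn_config()) {
  al <- align_vocabularies(ld, ml, md)
  pr <- build_profiles(al$ld, al$ml, al$md)
  sl <- similarity_matrix(pr$lmd, cfg$metric, cfg$lambda)
  sd <- similarity_matrix(pr$dml, cfg$metric, cfg$lambda)
  predict_associations(al$ld, sl, sd, cfg)
}
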