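# Fused potential-association similarity and the classical baselines,
# all computed over binary interaction-profile rows.

new_similarity <- function(values, metric, lambda = NA_real_) {
  structure(values, metric = metric, lambda = lambda,
            class = c("similarity_matrix", "matrix", "array"))
}

check_binary <- function(m, what = "profile matrix") {
  if (!all(m == 0 | m == 1)) stop(what, " must be binary (0/1)")
  invisible(m)
}

#' Fused potential-association similarity of two binary profiles
#'
#' For binary vectors `x`, `y` of length `n`, returns
#' \deqn{sim(x,y) = \frac{\lambda\,\lVert x \circ y\rVert_2 +
#'   (1-\lambda)\,\lVert x - y\rVert_2}{\sqrt{n}}}
#' where \eqn{x \circ y} is the element-wise product. For binary input
#' \eqn{\lVert x \circ y\rVert_2 = \sqrt{c}} with `c` the number of shared
#' 1-positions, and \eqn{\lVert x-y\rVert_2 = \sqrt{d}} with `d` the number
#' of differing positions, so the score rises both with shared confirmed
#' associations (weight `lambda`) and with positions where exactly one
#' profile has a confirmed association (weight `1 - lambda`) -- the latter
#' term is what credits "potential" associations that a plain overlap count
#' treats as evidence of dissimilarity. Both norms are at most
#' \eqn{\sqrt{n}}, so the score lies in `[0, 1]`.
#'
#' @param x,y Binary vectors of equal positive length.
#' @param lambda Weight in `[0, 1]` on the shared-association term.
#' @return A similarity score in `[0, 1]`.
#' @examples
#' fused_pair_similarity(c(1, 0, 1, 0), c(1, 1, 0, 0), 0.5)  # (1 + sqrt(2))/4
#' @export
fused_pair_similarity <- function(x, y, lambda) {
  if (length(x) != length(y)) stop("profile lengths differ")
  if (length(x) == 0L) stop("zero-length profiles")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  check_binary(x, "x")
  check_binary(y, "y")
  cc <- sum(x * y)
  d <- sum(x != y)
  (lambda * sqrt(cc) + (1 - lambda) * sqrt(d)) / sqrt(length(x))
}

#' Fused similarity matrix over profile rows
#'
#' Applies [fused_pair_similarity()] to every pair of rows of a binary
#' profile matrix, diagonal included (self-similarity is
#' \eqn{\lambda\sqrt{c}/\sqrt{n}}, not forced to 1; neighbor selection
#' excludes the self-row separately). Vectorized through the Gram matrix:
#' shared counts are `P P'` and differing counts `r_i + r_j - 2 (P P')_{ij}`
#' with `r` the row sums.
#'
#' @param profiles Binary matrix whose rows are interaction profiles
#'   (e.g. the `lmd` or `dml` element of [build_profiles()]).
#' @param lambda Weight in `[0, 1]` on the shared-association term.
#' @return A symmetric `similarity_matrix` with entries in `[0, 1]`.
#' @export
fused_similarity_matrix <- function(profiles, lambda) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) == 0L) stop("zero-length profiles")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  check_binary(profiles)
  g <- tcrossprod(profiles)           # shared 1-position counts
  r <- rowSums(profiles)
  d <- outer(r, r, `+`) - 2 * g       # differing-position counts
  d[d < 0] <- 0                       # guard rounding on large counts
  s <- (lambda * sqrt(g) + (1 - lambda) * sqrt(d)) / sqrt(ncol(profiles))
  s <- (s + t(s)) / 2
  dimnames(s) <- if (is.null(rownames(profiles))) NULL else
    list(rownames(profiles), rownames(profiles))
  new_similarity(s, "fused", lambda)
}

#' Baseline similarity matrices (cosine, Pearson, Jaccard)
#'
#' Classical row-wise similarities used as comparators for the fused
#' metric: cosine = dot/(|x||y|), Pearson = centred cosine, Jaccard =
#' shared / (union of supports). Any pair involving an all-zero profile
#' (or, for Pearson, a zero-variance profile) scores 0 rather than NaN so
#' degenerate entities never poison downstream ranking.
#'
#' @param profiles Binary profile matrix.
#' @param metric One of `"cosine"`, `"pearson"`, `"jaccard"`.
#' @return A symmetric `similarity_matrix`.
#' @export
baseline_similarity_matrix <- function(profiles,
                                       metric = c("cosine", "pearson", "jaccard")) {
  metric <- match.arg(metric)
  profiles <- as.matrix(profiles)
  if (ncol(profiles) == 0L) stop("zero-length profiles")
  check_binary(profiles)
  n <- nrow(profiles)
  g <- tcrossprod(profiles)
  r <- rowSums(profiles)
  s <- switch(metric,
    cosine = {
      den <- outer(sqrt(r), sqrt(r))
      out <- ifelse(den > 0, g / den, 0)
      out
    },
    pearson = {
      ctr <- profiles - r / ncol(profiles)
      gc <- tcrossprod(ctr)
      v <- sqrt(diag(gc))
      den <- outer(v, v)
      ifelse(den > 0, gc / den, 0)
    },
    jaccard = {
      un <- outer(r, r, `+`) - g
      ifelse(un > 0, g / un, 0)
    }
  )
  s <- (s + t(s)) / 2
  dimnames(s) <- if (is.null(rownames(profiles))) NULL else
    list(rownames(profiles), rownames(profiles))
  new_similarity(s, metric)
}

#' Similarity matrix dispatcher
#'
#' Routes to [fused_similarity_matrix()] or [baseline_similarity_matrix()]
#' by metric name; convenience for the cross-validation drivers and the
#' command-line interface.
#'
#' @param profiles Binary profile matrix.
#' @param metric `"fused"`, `"cosine"`, `"pearson"` or `"jaccard"`.
#' @param lambda Fused-metric weight; ignored by the baselines.
#' @return A `similarity_matrix`.
#' @export
similarity_matrix <- function(profiles, metric = "fused", lambda = 0.1) {
  metric <- match.arg(metric, c("fused", "cosine", "pearson", "jaccard"))
  if (metric == "fused") fused_similarity_matrix(profiles, lambda)
  else baseline_similarity_matrix(profiles, metric)
}
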