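# Cross-validation drivers, ranking metrics and confusion-matrix metrics.
#
# Conventions (the benchmark literature's dominant ones for this task):
# positives = held-out known associations; negatives = every cell that is 0
# in the full target matrix (unverified pairs); training positives are
# excluded from scoring. Similarities are recomputed per fold from the
# masked target so a held-out pair never leaks into the profiles that score
# it.

#' Partition known positives into cross-validation folds
#'
#' Randomly assigns the positive cells to `folds` near-equal groups
#' (sizes differ by at most one), deterministically for a given seed.
#'
#' @param positives Two-column matrix of (row, col) indices of known
#'   positives, as from `which(y == 1, arr.ind = TRUE)`.
#' @param folds Number of folds, at least 2 and at most the positive count.
#' @param seed Integer seed governing the shuffle.
#' @return Integer vector of fold labels (1..folds), one per positive.
#' @export
kfold_split <- function(positives, folds = 5, seed = 1) {
  np <- nrow(positives)
  if (folds < 2) stop("folds must be >= 2")
  if (folds > np) stop(sprintf("folds (%d) exceeds positive count (%d)", folds, np))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  sample(rep_len(seq_len(folds), np))
}

# Save/restore the global RNG state so package internals never perturb a
# user's random stream beyond the documented seeded draws.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Score one cross-validation fold
#'
#' Masks the held-out positives to 0 in the target matrix, rebuilds the
#' concatenated profiles and both similarity matrices from the masked
#' target (the miRNA adjacencies are unaffected by masking), runs the
#' completion model, and returns the scores of the evaluation cells:
#' held-out positives (label 1) and all cells that are 0 in the full
#' target (label 0). Training positives are excluded.
#'
#' @param ld,ml,md Aligned adjacencies ([align_vocabularies()]).
#' @param held_out Two-column index matrix of positives to mask; must all
#'   be 1 in `ld`.
#' @param cfg A [dmwnn_config()].
#' @return List with `scores`, `labels` (parallel vectors) and the fold's
#'   `prediction`.
#' @export
run_fold <- function(ld, ml, md, held_out, cfg = dmwnn_config()) {
  y <- as.matrix(ld)
  held_out <- as.matrix(held_out)
  if (nrow(held_out) > 0 && any(y[held_out] != 1)) {
    stop("held_out contains cells that are not known positives")
  }
  y_masked <- y
  y_masked[held_out] <- 0
  pr <- build_profiles(new_adjacency(y_masked, "lncRNA", "disease"), ml, md)
  sl <- similarity_matrix(pr$lmd, cfg$metric, cfg$lambda)
  sd <- similarity_matrix(pr$dml, cfg$metric, cfg$lambda)
  pred <- predict_associations(y_masked, sl, sd, cfg)
  zero_cells <- which(y == 0)
  scores <- c(pred$scores[held_out], pred$scores[zero_cells])
  labels <- c(rep(1L, nrow(held_out)), rep(0L, length(zero_cells)))
  list(scores = scores, labels = labels, prediction = pred)
}

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney formulation with midrank tie handling: the probability
#' that a random positive outranks a random negative, counting ties as
#' one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("roc_auc needs both classes")
  r <- rank(scores)           # midranks by default
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation over the distinct score thresholds: walking the
#' thresholds from high to low, each increment in recall contributes a
#' rectangle at the precision attained at that threshold. Ties share a
#' threshold (all tied scores enter together).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels with at least one positive.
#' @return AUPR in `(0, 1]`.
#' @export
pr_aupr <- function(scores, labels) {
  labels <- as.integer(labels != 0)
  np <- sum(labels)
  if (np == 0L) stop("pr_aupr needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp <- cumsum(!duplicated(s))          # threshold groups (ties pooled)
  tp <- cumsum(l)
  n_at <- seq_along(l)
  last <- which(grp != c(grp[-1L], -1))  # last element of each group
  prec <- tp[last] / n_at[last]
  rec <- tp[last] / np
  sum(diff(c(0, rec)) * prec)
}

#' Confusion-matrix metrics at a threshold policy
#'
#' Binarizes scores and reports accuracy, sensitivity (TPR), specificity
#' (1 - FPR), precision and the Matthews correlation coefficient.
#' `threshold = "youden"` (default) picks the score cutoff maximizing
#' Youden's J = TPR - FPR over the distinct scores; a number in `[0, 1]`
#' fixes the cutoff (predict positive when score >= cutoff). Metrics with
#' a zero denominator are reported as 0 with a warning.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels, both classes present.
#' @param threshold `"youden"` or a fixed numeric cutoff.
#' @return Named list: `threshold`, `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `mcc`.
#' @export
classification_metrics <- function(scores, labels, threshold = "youden") {
  labels <- as.integer(labels != 0)
  if (sum(labels) == 0L || sum(labels) == length(labels)) {
    stop("classification_metrics needs both classes")
  }
  if (identical(threshold, "youden")) {
    # one descending sweep: cumulative TP/FP at each distinct-score boundary
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]
    l <- labels[ord]
    boundary <- which(s != c(s[-1L], -Inf))  # last index of each tie group
    tp_c <- cumsum(l)[boundary]
    fp_c <- boundary - tp_c
    j <- tp_c / sum(labels == 1L) - fp_c / sum(labels == 0L)
    threshold <- s[boundary[which.max(j)]]
  }
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  tn <- sum(!pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, ": zero denominator, reporting 0")
      0
    } else num / den
  }
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / (tp + fp + tn + fn),
       sensitivity = safe(tp, tp + fn, "sensitivity"),
       specificity = safe(tn, tn + fp, "specificity"),
       precision = safe(tp, tp + fp, "precision"),
       mcc = if (mcc_den == 0) {
         warning("mcc: zero denominator, reporting 0")
         0
       } else (tp * tn - fp * fn) / mcc_den)
}

fold_report_row <- function(fold, scores, labels, threshold) {
  cm <- classification_metrics(scores, labels, threshold)
  data.frame(fold = fold,
             auc = roc_auc(scores, labels),
             aupr = pr_aupr(scores, labels),
             accuracy = cm$accuracy, sensitivity = cm$sensitivity,
             specificity = cm$specificity, precision = cm$precision,
             mcc = cm$mcc)
}

#' k-fold cross-validation of the completion model
#'
#' Splits the known positives into folds, and for each fold masks it,
#' recomputes profiles and similarities from the masked target, predicts,
#' and scores the held-out positives against all unverified (zero) cells.
#' Reports per-fold AUC, AUPR and confusion metrics plus their mean and
#' sample standard deviation.
#'
#' @param ld,ml,md Adjacencies (any orientation); aligned internally.
#' @param cfg A [dmwnn_config()].
#' @param folds Fold count (default 5).
#' @param seed Seed for the fold split.
#' @param threshold Threshold policy for the confusion metrics
#'   (see [classification_metrics()]).
#' @return A `dmwnn_eval`: list with `per_fold` (data.frame), `mean`, `sd`
#'   (named vectors), `folds`, `seed` and `config`.
#' @export
kfold_cv <- function(ld, ml, md, cfg = dmwnn_config(), folds = 5, seed = 1,
                     threshold = "youden") {
  al <- align_vocabularies(ld, ml, md)
  y <- as.matrix(al$ld)
  pos <- which(y == 1, arr.ind = TRUE)
  fold <- kfold_split(pos, folds, seed)
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    r <- run_fold(al$ld, al$ml, al$md, pos[fold == f, , drop = FALSE], cfg)
    rows[[f]] <- fold_report_row(f, r$scores, r$labels, threshold)
  }
  per_fold <- do.call(rbind, rows)
  met <- per_fold[, setdiff(names(per_fold), "fold"), drop = FALSE]
  structure(list(per_fold = per_fold,
                 mean = colMeans(met),
                 sd = apply(met, 2, stats::sd),
                 folds = folds, seed = seed, config = cfg),
            class = "dmwnn_eval")
}

#' Leave-one-out cross-validation
#'
#' One fold per known positive: each iteration masks a single association,
#' rebuilds similarities, predicts, and ranks the masked pair against all
#' unverified cells. `aggregate = "mean"` (default) averages per-iteration
#' AUCs; `aggregate = "pooled"` concatenates all iterations' (score, label)
#' pairs into one ranking before computing a single AUC.
#'
#' @param ld,ml,md Adjacencies (any orientation).
#' @param cfg A [dmwnn_config()].
#' @param aggregate `"mean"` or `"pooled"`.
#' @return A `dmwnn_eval` with a single aggregate `auc` (and `aupr` for the
#'   pooled mode), the per-iteration AUC vector, and no sd fields.
#' @export
loocv <- function(ld, ml, md, cfg = dmwnn_config(),
                  aggregate = c("mean", "pooled")) {
  aggregate <- match.arg(aggregate)
  al <- align_vocabularies(ld, ml, md)
  y <- as.matrix(al$ld)
  pos <- which(y == 1, arr.ind = TRUE)
  np <- nrow(pos)
  if (np < 2) stop("LOOCV needs at least 2 known positives")
  aucs <- numeric(np)
  pooled_scores <- if (aggregate == "pooled") vector("list", np) else NULL
  pooled_labels <- if (aggregate == "pooled") vector("list", np) else NULL
  for (i in seq_len(np)) {
    r <- run_fold(al$ld, al$ml, al$md, pos[i, , drop = FALSE], cfg)
    aucs[i] <- roc_auc(r$scores, r$labels)
    if (aggregate == "pooled") {
      pooled_scores[[i]] <- r$scores
      pooled_labels[[i]] <- r$labels
    }
  }
  res <- list(per_iteration_auc = aucs, aggregate = aggregate,
              n_positives = np, config = cfg)
  if (aggregate == "mean") {
    res$auc <- mean(aucs)
  } else {
    s <- unlist(pooled_scores)
    l <- unlist(pooled_labels)
    res$auc <- roc_auc(s, l)
    res$aupr <- pr_aupr(s, l)
  }
  structure(res, class = "dmwnn_eval")
}

#' @export
print.dmwnn_eval <- function(x, ...) {
  if (!is.null(x$per_fold)) {
    cat(sprintf("DMWNN %d-fold cross-validation (seed %s)\n", x$folds, x$seed))
    print(x$per_fold, row.names = FALSE, digits = 4)
    cat(sprintf("mean AUC %.4f +/- %.4f; mean AUPR %.4f +/- %.4f\n",
                x$mean[["auc"]], x$sd[["auc"]],
                x$mean[["aupr"]], x$sd[["aupr"]]))
  } else {
    cat(sprintf("DMWNN LOOCV over %d positives (%s aggregation): AUC %.4f\n",
                x$n_positives, x$aggregate, x$auc))
  }
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes a `dmwnn_eval` as JSON (parameters, per-fold table, summary) or
#' as a flat TSV of the per-fold table.
#'
#' @param x A `dmwnn_eval`.
#' @param path Output file.
#' @param format `"json"` or `"tsv"`.
#' @export
write_eval_report <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- if (!is.null(x$per_fold)) x$per_fold
           else data.frame(iteration = seq_along(x$per_iteration_auc),
                           auc = x$per_iteration_auc)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    obj <- unclass(x)
    obj$config <- unclass(obj$config)
    if (!is.null(obj$mean)) obj$mean <- as.list(obj$mean)
    if (!is.null(obj$sd)) obj$sd <- as.list(obj$sd)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(x)
}

#' Rank candidate lncRNAs for one disease
#'
#' Sorts the lncRNAs not already known to be associated with the given
#' disease by descending predicted score (ties by ascending identifier)
#' and returns the top of the list -- the candidate set a wet-lab screen
#' would start from.
#'
#' @param pred A `dmwnn_prediction`.
#' @param disease Disease identifier (normalized like the input ids).
#' @param top_n Maximum number of candidates (default 20).
#' @return `data.frame` with `lncRNA`, `score`, in rank order.
#' @export
rank_candidates <- function(pred, disease, top_n = 20) {
  stopifnot(inherits(pred, "dmwnn_prediction"))
  disease <- normalize_id(disease)
  dis <- colnames(pred$scores)
  if (!disease %in% dis) {
    near <- utils::head(dis[order(utils::adist(disease, dis))], 3)
    stop(sprintf("unknown disease '%s'; nearest matches: %s",
                 disease, paste(near, collapse = ", ")))
  }
  s <- pred$scores[, disease]
  known <- pred$known[, disease] != 0
  cand <- data.frame(lncRNA = rownames(pred$scores)[!known],
                     score = s[!known], stringsAsFactors = FALSE)
  cand <- cand[order(-cand$score, cand$lncRNA), , drop = FALSE]
  rownames(cand) <- NULL
  utils::head(cand, top_n)
}
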