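#' Mean absolute error
#'
#' @param pred,target Equal-length numeric vectors.
#' @return `mean(abs(pred - target))`.
#' @export
mae <- function(pred, target) {
  if (length(pred) == 0) stop("empty input", call. = FALSE)
  if (length(pred) != length(target))
    stop("pred and target must have equal length", call. = FALSE)
  mean(abs(pred - target))
}

#' Threshold classification metrics
#'
#' Confusion counts at the given probability threshold, then
#' Accuracy = (TP+TN)/n, Recall = TP/(TP+FN), Precision = TP/(TP+FP),
#' F = 2PR/(P+R) (F1). Ratios with a zero denominator are reported as 0
#' and flagged in the `"undefined"` attribute, with a warning.
#'
#' @param prob Probabilities in `[0, 1]`.
#' @param label 0/1 labels.
#' @param threshold Decision threshold (default 0.5).
#' @return Named list with `accuracy`, `recall`, `precision`, `f_score`;
#'   attributes `"counts"` (TP, FP, FN, TN) and `"undefined"`.
#' @export
classification_metrics <- function(prob, label, threshold = 0.5) {
  if (length(prob) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(prob) == length(label))
  if (!all(label %in% c(0, 1)))
    stop("labels must be 0 or 1", call. = FALSE)
  if (any(prob < 0 | prob > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  pos <- prob >= threshold
  tp <- sum(pos & label == 1)
  fp <- sum(pos & label == 0)
  fn <- sum(!pos & label == 1)
  tn <- sum(!pos & label == 0)
  undefined <- character()
  ratio <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      return(0)
    }
    num / den
  }
  recall <- ratio(tp, tp + fn, "recall")
  precision <- ratio(tp, tp + fp, "precision")
  f_score <- ratio(2 * precision * recall, precision + recall, "f_score")
  if (length(undefined))
    warning(sprintf("undefined (0/0) metric(s) reported as 0: %s",
                    paste(undefined, collapse = ", ")))
  structure(list(accuracy = (tp + tn) / length(prob), recall = recall,
                 precision = precision, f_score = f_score),
            counts = c(TP = tp, FP = fp, FN = fn, TN = tn),
            undefined = undefined)
}

#' ROC curve points and AUC
#'
#' Points are produced by thresholding at each distinct score (ties share a
#' threshold), ordered from the origin to (1, 1); the AUC is the
#' trapezoidal area under the points.
#'
#' @param prob Scores (higher means more positive).
#' @param label 0/1 labels; both classes must be present.
#' @return List with `points` (`data.frame` of `fpr`, `tpr`, `threshold`)
#'   and `auc`.
#' @export
roc_points <- function(prob, label) {
  stopifnot(length(prob) == length(label))
  if (!all(label %in% c(0, 1)))
    stop("labels must be 0 or 1", call. = FALSE)
  n_pos <- sum(label == 1)
  n_neg <- sum(label == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC requires at least one positive and one negative label",
         call. = FALSE)
  thr <- sort(unique(prob), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(prob >= t & label == 1) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(prob >= t & label == 0) / n_neg, 0)
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Mean ROC over trials on a common grid
#'
#' Vertical averaging: each trial's curve is interpolated onto a fixed
#' false-positive-rate grid and the true positive rates are averaged.
#'
#' @param rocs List of [roc_points()] results.
#' @param grid FPR grid (default 101 points on `[0, 1]`).
#' @return `data.frame` with `fpr` and mean `tpr`.
#' @export
mean_roc <- function(rocs, grid = seq(0, 1, length.out = 101)) {
  stopifnot(length(rocs) >= 1)
  tprs <- vapply(rocs, function(r)
    stats::approx(r$points$fpr, r$points$tpr, xout = grid, ties = max,
                  rule = 2)$y, numeric(length(grid)))
  data.frame(fpr = grid, tpr = rowMeans(matrix(tprs, nrow = length(grid))))
}

#' Average metrics over trials
#'
#' @param results List of per-trial results (each with a named `metrics`
#'   vector, as produced by [run_trials()]).
#' @return List with named vectors `mean` and `sd` (sd is 0 for a single
#'   trial).
#' @export
aggregate_trials <- function(results) {
  if (!length(results)) stop("no trial results", call. = FALSE)
  keys <- names(results[[1]]$metrics)
  for (r in results)
    if (!identical(names(r$metrics), keys))
      stop("inconsistent metric keys across trials", call. = FALSE)
  M <- do.call(rbind, lapply(results, `[[`, "metrics"))
  mean_ <- colMeans(M)
  sd_ <- if (nrow(M) > 1) apply(M, 2, stats::sd) else stats::setNames(
    numeric(length(keys)), keys)
  list(mean = mean_, sd = sd_)
}

#' Export per-atom attention weights
#'
#' One record per atom per molecule: the attention weight of each enabled
#' path (weights over enabled paths sum to 1). Disabled paths are reported
#' as `NA` and written as empty fields in the CSV.
#'
#' @param model An `mpgcn_model` using attention aggregation over more
#'   than one path.
#' @param graphs List of [molecular_graph()] objects.
#' @param file Optional CSV path; when given, the table is also written
#'   with columns `mol_id`, `atom_idx`, `alpha_node`, `alpha_edge`,
#'   `alpha_3d`.
#' @return `data.frame` of attention records.
#' @export
export_attention <- function(model, graphs, file = NULL) {
  stopifnot(inherits(model, "mpgcn_model"))
  if (length(model$config$paths) < 2 ||
      model$config$aggregation != "attention")
    stop("attention export requires a model with attention aggregation ",
         "over at least two paths", call. = FALSE)
  rows <- lapply(graphs, function(g) {
    out <- forward(model, g)
    alpha <- attr(out, "alpha")
    df <- data.frame(mol_id = g$id, atom_idx = seq_len(g$n_atoms),
                     alpha_node = NA_real_, alpha_edge = NA_real_,
                     alpha_3d = NA_real_)
    for (p in colnames(alpha))
      df[[paste0("alpha_", if (p == "3d") "3d" else p)]] <- alpha[, p]
    df
  })
  res <- do.call(rbind, rows)
  if (!is.null(file))
    utils::write.csv(res, file, row.names = FALSE, na = "")
  res
}

#' Write a metrics JSON report
#'
#' `{"task": ..., "per_trial": [...], "mean": {...}, "std": {...}}`.
#'
#' @param trials An `mpgcn_trials` object from [run_trials()].
#' @param path Output file.
#' @export
write_metrics_json <- function(trials, path) {
  stopifnot(inherits(trials, "mpgcn_trials"))
  obj <- list(
    task = trials$results[[1]]$task,
    per_trial = lapply(trials$results, function(r)
      c(list(trial = r$trial, n_test = r$n_test), as.list(r$metrics))),
    mean = as.list(trials$mean),
    std = as.list(trials$sd)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
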