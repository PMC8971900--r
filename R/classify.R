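#' Stratified train/test split of samples
#'
#' Splits sample ids into a training and a test set at `train_fraction`,
#' stratified by habitat so both classes appear on both sides. With
#' `individual_aware = TRUE` the split is grouped by individual instead, so
#' one subject's paired samples never straddle the split.
#'
#' @param metadata Sample metadata.
#' @param train_fraction Fraction of samples assigned to training.
#' @param seed Integer seed.
#' @param individual_aware Split whole individuals rather than samples.
#' @return A list with character vectors `train` and `test`.
#' @export
split_samples <- function(metadata, train_fraction = 0.7, seed = 1L,
                          individual_aware = FALSE) {
  metadata <- validate_metadata(metadata)
  set.seed(substream_seed(seed, "split"))
  for (attempt in seq_len(100)) {
    if (individual_aware) {
      inds <- unique(metadata$individual_id)
      n_tr <- round(train_fraction * length(inds))
      tr_ind <- sample(inds, n_tr)
      train <- metadata$sample_id[metadata$individual_id %in% tr_ind]
    } else {
      train <- unlist(lapply(split(metadata$sample_id, metadata$habitat),
                             function(ids) {
                               sample(ids, round(train_fraction * length(ids)))
                             }), use.names = FALSE)
    }
    test <- setdiff(metadata$sample_id, train)
    ok <- length(unique(metadata$habitat[metadata$sample_id %in% train])) == 2 &&
      length(unique(metadata$habitat[metadata$sample_id %in% test])) == 2
    if (ok) return(list(train = sort(train), test = sort(test)))
    warning("a class was absent from one side of the split; redrawing")
  }
  stop("could not produce a split with both classes on both sides", call. = FALSE)
}

#' Rank features by random-forest importance
#'
#' Fits a random forest on the training samples only (all features, relative
#' abundances) and ranks features by mean decrease in Gini impurity,
#' descending, ties broken by feature id.
#'
#' @param rel Relative-abundance matrix restricted to training samples.
#' @param labels Factor (or character) habitat label per training sample.
#' @param seed Integer seed.
#' @param ntree Number of trees.
#' @return A tibble `feature_id`, `importance`, `rank`.
#' @export
rank_importance <- function(rel, labels, seed = 1L, ntree = 500) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("training data has a single class", call. = FALSE)
  if (ncol(rel) < 2) stop("need at least 2 features", call. = FALSE)
  set.seed(substream_seed(seed, "importance"))
  rf <- randomForest::randomForest(x = as.data.frame(rel), y = labels,
                                   ntree = ntree)
  imp <- rf$importance[, "MeanDecreaseGini"]
  ord <- order(-imp, names(imp))
  tibble::tibble(feature_id = names(imp)[ord],
                 importance = unname(imp[ord]),
                 rank = seq_along(imp))
}

#' Refit on the top-k features and evaluate
#'
#' Refits the random forest on the `top_k` most important features and
#' reports resubstitution (train) and held-out (test) accuracy with
#' per-class confusion counts.
#'
#' @param rel Relative-abundance matrix covering train and test samples.
#' @param metadata Sample metadata.
#' @param split A `train`/`test` list from [split_samples()].
#' @param ranking Importance ranking from [rank_importance()].
#' @param top_k Number of top features to keep (clipped, with a warning, to
#'   the number available).
#' @param seed Integer seed.
#' @param ntree Number of trees.
#' @return An object of class `classifier_report`: list with
#'   `train_accuracy` and `test_accuracy` (percent), `confusion` (tibble),
#'   `importance` (the retained top-k ranking), `top_k`, `seed`.
#' @export
train_and_evaluate <- function(rel, metadata, split, ranking, top_k = 30,
                               seed = 1L, ntree = 500) {
  metadata <- validate_metadata(metadata)
  if (length(split$test) == 0) stop("empty test set", call. = FALSE)
  if (top_k > nrow(ranking)) {
    warning("top_k = ", top_k, " exceeds the ", nrow(ranking),
            " available features; clipping")
    top_k <- nrow(ranking)
  }
  feats <- ranking$feature_id[seq_len(top_k)]
  lab <- function(ids) factor(metadata$habitat[match(ids, metadata$sample_id)],
                              levels = habitat_levels())
  xtr <- as.data.frame(rel[split$train, feats, drop = FALSE])
  xte <- as.data.frame(rel[split$test, feats, drop = FALSE])

  set.seed(substream_seed(seed, "refit"))
  rf <- randomForest::randomForest(x = xtr, y = lab(split$train), ntree = ntree)
  pr_tr <- stats::predict(rf, xtr)
  pr_te <- stats::predict(rf, xte)

  conf <- function(truth, pred, which) {
    tb <- as.data.frame(table(truth = truth, predicted = pred))
    tibble::tibble(split = which, truth = as.character(tb$truth),
                   predicted = as.character(tb$predicted),
                   n = as.integer(tb$Freq))
  }
  acc <- function(truth, pred) 100 * mean(truth == pred)

  structure(list(
    train_accuracy = acc(lab(split$train), pr_tr),
    test_accuracy = acc(lab(split$test), pr_te),
    confusion = dplyr::bind_rows(conf(lab(split$train), pr_tr, "train"),
                                 conf(lab(split$test), pr_te, "test")),
    importance = ranking[seq_len(top_k), ],
    top_k = top_k, seed = seed,
    n_train = length(split$train), n_test = length(split$test)),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("Habitat-of-origin random-forest report\n")
  cat(sprintf("  top %d features; train %.2f%%, test %.2f%% accuracy (%d/%d samples)\n",
              x$top_k, x$train_accuracy, x$test_accuracy, x$n_train, x$n_test))
  invisible(x)
}

#' One-call habitat classification pipeline
#'
#' Split (stratified 70/30 by default), rank importances on the training
#' side only, refit on the top-k features, evaluate.
#'
#' @param table A feature-table matrix (counts; converted to relative
#'   abundances internally).
#' @param metadata Sample metadata.
#' @param train_fraction,top_k,seed,ntree,individual_aware Passed through to
#'   the stage functions.
#' @return A `classifier_report`.
#' @export
#' @examples
#' prof <- default_profiles(n_tail = 40)
#' sim <- generate_paired_study(simulation_config(n_individuals = 12, seed = 3,
#'                                                depth_range = c(2000, 3000)),
#'                              prof$saliva, prof$mucosa)
#' classify_habitat(sim$table, sim$metadata, top_k = 10, ntree = 100)
classify_habitat <- function(table, metadata, train_fraction = 0.7,
                             top_k = 30, seed = 1L, ntree = 500,
                             individual_aware = FALSE) {
  metadata <- validate_metadata(metadata)
  rel <- to_relative(table)
  split <- split_samples(metadata, train_fraction = train_fraction,
                         seed = seed, individual_aware = individual_aware)
  lab_tr <- metadata$habitat[match(split$train, metadata$sample_id)]
  ranking <- rank_importance(rel[split$train, , drop = FALSE], lab_tr,
                             seed = seed, ntree = ntree)
  train_and_evaluate(rel, metadata, split, ranking, top_k = top_k,
                     seed = seed, ntree = ntree)
}
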