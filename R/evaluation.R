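# Evaluation protocols: 10-fold cross-validation (CF-test), fixed 85.7%
# holdout with per-iteration evaluation (DD-test), and the metric set
# accuracy / sensitivity / FP per exam / F-measure.

#' Assign examples to k cross-validation folds
#'
#' Seeded random partition. With `grouping = "none"` fold sizes differ by at
#' most one; with `"by_exam"` all patches of one exam land in the same fold
#' (exams balanced across folds, so patch counts may differ more), which
#' avoids leaking exam-level appearance between train and test.
#'
#' @param n number of examples.
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @param grouping `"none"` or `"by_exam"`.
#' @param exam_ids required for `"by_exam"`: exam id per example.
#' @return integer fold index (1..k) per example.
#' @export
kfold_split <- function(n, k = 10L, seed = 1L,
                        grouping = c("none", "by_exam"), exam_ids = NULL) {
  grouping <- match.arg(grouping)
  if (n < k) stop(sprintf("cannot make %d folds from %d examples", k, n))
  set.seed(seed)
  if (grouping == "none")
    return(sample(rep(seq_len(k), length.out = n)))
  stopifnot(!is.null(exam_ids), length(exam_ids) == n)
  exams <- sample(unique(exam_ids))
  if (length(exams) < k)
    stop("by_exam grouping needs at least k distinct exams")
  exam_fold <- stats::setNames(rep(seq_len(k), length.out = length(exams)),
                               exams)
  unname(exam_fold[exam_ids])
}

#' Split a dataset into fixed training and testing parts
#'
#' The training side receives `round(train_fraction * n)` examples (half-up
#' rounding); the test side is the complement and stays fixed for the whole
#' training run.
#'
#' @param dataset a [patch_dataset()].
#' @param train_fraction fraction of examples used for training
#'   (default 0.857).
#' @param seed RNG seed.
#' @param grouping as in [kfold_split()]; `"by_exam"` keeps exams intact.
#' @return list with `train` and `test` datasets and the chosen `test_idx`.
#' @export
holdout_split <- function(dataset, train_fraction = 0.857, seed = 1L,
                          grouping = c("none", "by_exam")) {
  grouping <- match.arg(grouping)
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- length(dataset)
  n_train <- as.integer(floor(train_fraction * n + 0.5))
  if (n_train == 0L || n_train == n)
    stop("holdout_split: one side of the split is empty")
  set.seed(seed)
  if (grouping == "none") {
    train_idx <- sample.int(n, n_train)
  } else {
    exams <- sample(unique(dataset$exam_ids))
    sizes <- cumsum(table(dataset$exam_ids)[exams])
    n_ex <- which.min(abs(sizes - n_train))
    train_idx <- which(dataset$exam_ids %in% exams[seq_len(n_ex)])
  }
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = dataset_subset(dataset, train_idx),
       test = dataset_subset(dataset, test_idx),
       test_idx = test_idx)
}

#' Confusion counts for binary nodule classification
#'
#' Positive class is nodule (= 1).
#'
#' @param predicted,truth equal-length 0/1 label vectors.
#' @return named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and true label vectors differ in length")
  stopifnot(all(predicted %in% 0:1), all(truth %in% 0:1))
  c(TP = sum(predicted == 1L & truth == 1L),
    FP = sum(predicted == 1L & truth == 0L),
    TN = sum(predicted == 0L & truth == 0L),
    FN = sum(predicted == 0L & truth == 1L))
}

#' Evaluation metrics from confusion counts
#'
#' accuracy = (TP+TN)/n; sensitivity = TP/(TP+FN);
#' precision = TP/(TP+FP); F-measure = F1, the harmonic mean of precision
#' and sensitivity; FP/exam = FP divided by the number of distinct exams
#' contributing patches to the evaluated set. Undefined ratios (zero
#' denominators) are reported as 0 with `degenerate = TRUE`.
#'
#' @param confusion counts from [confusion_counts()].
#' @param exam_ids exam ids of the evaluated patches (distinct values are
#'   counted).
#' @return an `evaluation_report` list with accuracy, sensitivity,
#'   f_measure, fp_per_exam, precision, the four counts, `n`, `exam_count`
#'   and `degenerate`.
#' @export
compute_metrics <- function(confusion, exam_ids) {
  stopifnot(length(exam_ids) >= 1)
  tp <- confusion[["TP"]]; fp <- confusion[["FP"]]
  tn <- confusion[["TN"]]; fn <- confusion[["FN"]]
  n <- tp + fp + tn + fn
  exam_count <- length(unique(exam_ids))
  degenerate <- FALSE
  ratio <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  sens <- ratio(tp, tp + fn)
  prec <- ratio(tp, tp + fp)
  f1 <- if (prec + sens == 0) { degenerate <- TRUE; 0 } else
    2 * prec * sens / (prec + sens)
  structure(list(accuracy = ratio(tp + tn, n), sensitivity = sens,
                 f_measure = f1, fp_per_exam = fp / exam_count,
                 precision = prec, TP = tp, FP = fp, TN = tn, FN = fn,
                 n = n, exam_count = exam_count, degenerate = degenerate),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("evaluation over %d patches / %d exams\n",
                     "  accuracy    %.4f\n  sensitivity %.4f\n",
                     "  FP/exam     %.4f\n  F-measure   %.4f\n"),
              x$n, x$exam_count, x$accuracy, x$sensitivity,
              x$fp_per_exam, x$f_measure))
  if (x$degenerate) cat("  (degenerate: some ratios had zero denominators)\n")
  invisible(x)
}

#' k-fold cross-validated evaluation (CF-test)
#'
#' Trains k models, each on k-1 folds, and evaluates each on its held-out
#' fold. The headline report pools the confusion counts across folds
#' (micro-average); per-fold reports are returned for transparency.
#'
#' @param dataset a [patch_dataset()].
#' @param net_config a [network_config()].
#' @param config a [training_config()]; per-fold seeds are derived from
#'   `seed`.
#' @param k number of folds.
#' @param seed seed for the fold assignment and the per-fold training.
#' @param grouping fold grouping, see [kfold_split()].
#' @return list with `pooled` (an `evaluation_report`), `per_fold` (list of
#'   reports) and `folds` (the assignment).
#' @export
run_cf_test <- function(dataset, net_config, config, k = 10L, seed = 1L,
                        grouping = c("none", "by_exam")) {
  grouping <- match.arg(grouping)
  folds <- kfold_split(length(dataset), k = k, seed = seed,
                       grouping = grouping, exam_ids = dataset$exam_ids)
  pooled <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  per_fold <- vector("list", k)
  for (fold in seq_len(k)) {
    tr <- dataset_subset(dataset, folds != fold)
    te <- dataset_subset(dataset, folds == fold)
    cfg <- config
    cfg$seed <- seed * 131L + fold
    fit <- train(tr, net_config, cfg)
    cm <- confusion_counts(predict_dataset(net_config, fit$params, te),
                           te$labels)
    per_fold[[fold]] <- compute_metrics(cm, te$exam_ids)
    pooled <- pooled + cm
  }
  list(pooled = compute_metrics(pooled, dataset$exam_ids),
       per_fold = per_fold, folds = folds)
}

#' Fixed-holdout evaluation with per-iteration testing (DD-test)
#'
#' Splits once (the test side never changes), then trains on the training
#' side while evaluating the fixed test set after every epoch, yielding a
#' metric trajectory across iterations.
#'
#' @param dataset a [patch_dataset()].
#' @param net_config a [network_config()].
#' @param config a [training_config()]; the decaying schedule is the
#'   conventional choice here.
#' @param seed seed for the split (training uses `config$seed`).
#' @param train_fraction forwarded to [holdout_split()].
#' @param grouping forwarded to [holdout_split()].
#' @return list with `trajectory` (data.frame: epoch, loss, precision, lr
#'   and test accuracy/sensitivity/fp_per_exam/f_measure), `final` (the last
#'   epoch's `evaluation_report`), `params` and `split`.
#' @export
run_dd_test <- function(dataset, net_config, config, seed = 1L,
                        train_fraction = 0.857,
                        grouping = c("none", "by_exam")) {
  grouping <- match.arg(grouping)
  split <- holdout_split(dataset, train_fraction = train_fraction,
                         seed = seed, grouping = grouping)
  rows <- list(); final <- NULL
  hook <- function(params, state) {
    cm <- confusion_counts(predict_dataset(net_config, params, split$test),
                           split$test$labels)
    rep <- compute_metrics(cm, split$test$exam_ids)
    final <<- rep
    h <- state$history[nrow(state$history), ]
    rows[[length(rows) + 1L]] <<- data.frame(
      epoch = h$epoch, loss = h$loss, precision = h$precision, lr = h$lr,
      test_accuracy = rep$accuracy, test_sensitivity = rep$sensitivity,
      test_fp_per_exam = rep$fp_per_exam, test_f_measure = rep$f_measure)
  }
  fit <- train(split$train, net_config, config, epoch_hook = hook)
  list(trajectory = do.call(rbind, rows), final = final,
       params = fit$params, split = split)
}
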