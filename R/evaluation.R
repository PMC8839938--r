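# Evaluation: the database/query class-center protocol, metric computation
# (accuracy, precision, recall, F1, AUC, specificity, sensitivity), classifier
# heads on embeddings, k-fold cross-validation aggregation, and the
# test-subset ablation.

#' Split labeled embeddings into database and query halves
#'
#' Per class, members are shuffled and the first `floor(n_c / 2)` go to the
#' database, the rest to the query set; database classes are then truncated
#' to the size of the smallest class so prototypes are estimated from equal
#' per-class counts. The query half keeps its natural imbalance.
#'
#' @param embeddings 20 x n matrix of record embeddings (columns = records).
#' @param labels length-n class labels.
#' @param seed integer seed for the per-class shuffles.
#' @return list with `database` and `query`, each a list holding
#'   `embeddings` and `labels`.
#' @export
split_database_query <- function(embeddings, labels, seed = 1L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2L))
    stop("every class needs >= 2 members, got: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  db_idx <- list(); qu_idx <- integer(0)
  for (cl in names(tab)) {
    members <- which(labels == cl)
    members <- members[sample.int(length(members))]
    h <- length(members) %/% 2L
    db_idx[[cl]] <- members[seq_len(h)]
    qu_idx <- c(qu_idx, members[(h + 1L):length(members)])
  }
  # truncation to the smallest class balances the database; the excess
  # members rejoin the query set rather than being discarded
  cap <- min(lengths(db_idx))
  db <- unlist(lapply(db_idx, function(ix) ix[seq_len(cap)]),
               use.names = FALSE)
  qu_idx <- c(qu_idx, unlist(lapply(db_idx, function(ix)
    ix[-seq_len(cap)]), use.names = FALSE))
  qu_idx <- sort(qu_idx)
  list(database = list(embeddings = embeddings[, db, drop = FALSE],
                       labels = labels[db]),
       query = list(embeddings = embeddings[, qu_idx, drop = FALSE],
                    labels = labels[qu_idx]))
}

#' Per-class mean embeddings (class center vectors)
#'
#' @param embeddings 20 x n matrix.
#' @param labels length-n class labels.
#' @return an object of class `class_centers`: list with `centers` (20 x C
#'   matrix, one column per class, catalog order = sorted label order unless
#'   `classes` given), `classes`, `n_per_class`.
#' @param classes optional explicit class order.
#' @export
class_centers <- function(embeddings, labels, classes = NULL) {
  labels <- as.character(labels)
  if (is.null(classes)) classes <- sort(unique(labels))
  if (!all(classes %in% labels))
    stop("class absent from database: ",
         paste(setdiff(classes, labels), collapse = ", "))
  centers <- vapply(classes, function(cl)
    rowMeans(embeddings[, labels == cl, drop = FALSE]),
    numeric(nrow(embeddings)))
  structure(list(centers = centers, classes = classes,
                 n_per_class = as.integer(table(labels)[classes])),
            class = "class_centers")
}

#' Classify a query embedding by its nearest class center
#'
#' Label = argmin Euclidean distance to the centers; ties break to the
#' earlier class in catalog order. Scores (for ROC sweeps) are negated
#' distances, monotone in the decision rule.
#'
#' @param query embedding vector.
#' @param centers a [class_centers()].
#' @return list with `label` and `scores` (named, negated distances).
#' @export
nearest_center_classify <- function(query, centers) {
  d <- apply(centers$centers, 2L, euclidean_distance, y = query)
  list(label = centers$classes[which.min(d)],
       scores = stats::setNames(-d, centers$classes))
}

# trapezoidal AUC over the score-threshold sweep (TPR vs FPR)
auc_trapezoid <- function(scores, is_pos) {
  if (!any(is_pos) || all(is_pos)) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[is_pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!is_pos] >= t), numeric(1))
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

binary_from_counts <- function(tp, fp, tn, fn) {
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  c(accuracy = (tp + tn) / (tp + fp + tn + fn),
    precision = prec, recall = rec,
    f1 = if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    sensitivity = rec)
}

#' Compute the evaluation metric panel
#'
#' Accuracy, precision, recall, F1, specificity, sensitivity and trapezoidal
#' AUC. With two classes the metrics are reported for the designated
#' positive class; with more, every metric except overall accuracy is
#' macro-averaged one-vs-rest.
#'
#' @param truth true labels.
#' @param predicted predicted labels (same length).
#' @param scores optional n x C score matrix (columns in `classes` order;
#'   higher = more confident) for the AUC sweep.
#' @param classes class order; default sorted union of labels.
#' @param positive positive class for the binary case; default the second
#'   entry of `classes`.
#' @return an object of class `evaluation_report`: list with `confusion`
#'   (true x predicted counts), `metrics` (named numeric vector), `n`.
#' @export
compute_metrics <- function(truth, predicted, scores = NULL, classes = NULL,
                            positive = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  if (!all(c(truth, predicted) %in% classes)) stop("label outside catalog")
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (nrow(scores) != length(truth) || ncol(scores) != length(classes))
      stop("`scores` must be n x C, aligned with `truth` and `classes`")
  }
  conf <- table(factor(truth, classes), factor(predicted, classes))
  acc <- sum(diag(conf)) / sum(conf)
  per_class <- function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    tn <- sum(truth != cl & predicted != cl)
    binary_from_counts(tp, fp, tn, fn)
  }
  if (length(classes) == 2L) {
    if (is.null(positive)) positive <- classes[2L]
    m <- per_class(positive)
    auc <- if (!is.null(scores))
      auc_trapezoid(scores[, match(positive, classes)], truth == positive)
    else NA_real_
  } else {
    pm <- vapply(classes, per_class, numeric(6))
    m <- rowMeans(pm, na.rm = TRUE)
    auc <- if (!is.null(scores)) {
      aucs <- vapply(seq_along(classes), function(j)
        auc_trapezoid(scores[, j], truth == classes[j]), numeric(1))
      mean(aucs, na.rm = TRUE)
    } else NA_real_
  }
  metrics <- c(accuracy = unname(acc), m[c("precision", "recall", "f1")],
               auc = auc, m[c("specificity", "sensitivity")])
  structure(list(confusion = conf, metrics = metrics, n = length(truth)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("<evaluation_report on", x$n, "queries>\n")
  print(round(x$metrics, digits))
  invisible(x)
}

#' Evaluate a few-shot model with the database/query protocol
#'
#' Embeds the test records, splits them into database and query halves,
#' computes class centers from the database, classifies every query by its
#' nearest center, and reports the metric panel.
#'
#' @param fit an `ecg_encoder_fit` (or bare `encoder_weights`).
#' @param test_records list of labeled `qrs_set`.
#' @param seed seed for the database/query split.
#' @param label_field label field name (default from the fit's config).
#' @return an `evaluation_report`.
#' @export
fsl_evaluate <- function(fit, test_records, seed = 1L,
                         label_field = NULL) {
  weights <- if (inherits(fit, "ecg_encoder_fit")) fit$weights else fit
  if (is.null(label_field))
    label_field <- if (inherits(fit, "ecg_encoder_fit"))
      fit$config$label_field else "superclass"
  labs <- labels_of(test_records, label_field)
  emb <- embed_many(test_records, weights)
  sq <- split_database_query(emb, labs, seed = seed)
  centers <- class_centers(sq$database$embeddings, sq$database$labels)
  res <- apply(sq$query$embeddings, 2L, nearest_center_classify,
               centers = centers)
  pred <- vapply(res, `[[`, character(1), "label")
  scores <- t(vapply(res, `[[`, numeric(length(centers$classes)), "scores"))
  compute_metrics(sq$query$labels, pred, scores, classes = centers$classes)
}

#' Fit a classifier head on embeddings and evaluate it
#'
#' @param train_embeddings 20 x n matrix; `train_labels` its labels.
#' @param test_embeddings 20 x m matrix; `test_labels` its labels.
#' @param model one of `"xgboost"`, `"random-forest"`, `"decision-tree"`,
#'   `"knn-5"`, `"knn-20"`, `"svm-linear"`, `"svm-poly"`, `"svm-rbf"`,
#'   `"svm-sigmoid"`.
#' @param train_labels,test_labels class labels.
#' @param seed integer seed (tree ensembles are stochastic).
#' @return an `evaluation_report`.
#' @export
downstream_classify <- function(train_embeddings, train_labels,
                                test_embeddings, test_labels,
                                model = "random-forest", seed = 1L) {
  known <- c("xgboost", "random-forest", "decision-tree", "knn-5", "knn-20",
             "svm-linear", "svm-poly", "svm-rbf", "svm-sigmoid")
  if (!model %in% known)
    stop("unknown model name: ", model, " (expected one of ",
         paste(known, collapse = ", "), ")")
  classes <- sort(unique(as.character(train_labels)))
  xtr <- t(train_embeddings)
  xte <- t(test_embeddings)
  ytr <- factor(as.character(train_labels), levels = classes)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  scores <- NULL
  if (model == "xgboost") {
    dtr <- xgboost::xgb.DMatrix(xtr, label = as.integer(ytr) - 1L)
    bst <- xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = length(classes), nthread = 1L,
                    verbosity = 0L, seed = seed),
      data = dtr, nrounds = 50L)
    pr <- predict(bst, xgboost::xgb.DMatrix(xte))
    scores <- if (is.matrix(pr)) pr
              else matrix(pr, ncol = length(classes), byrow = TRUE)
  } else if (model == "random-forest") {
    rf <- randomForest::randomForest(xtr, ytr)
    scores <- predict(rf, xte, type = "prob")[, classes, drop = FALSE]
  } else if (model == "decision-tree") {
    df <- data.frame(y = ytr, xtr)
    tr <- rpart::rpart(y ~ ., data = df, method = "class")
    scores <- predict(tr, data.frame(xte), type = "prob")[, classes,
                                                          drop = FALSE]
  } else if (model %in% c("knn-5", "knn-20")) {
    kk <- if (model == "knn-5") 5L else 20L
    kk <- min(kk, nrow(xtr))
    pr <- class::knn(xtr, xte, ytr, k = kk, prob = TRUE)
    p <- attr(pr, "prob")
    scores <- matrix((1 - p) / max(1L, length(classes) - 1L),
                     nrow(xte), length(classes))
    scores[cbind(seq_len(nrow(xte)), match(pr, classes))] <- p
  } else {
    kern <- c("svm-linear" = "linear", "svm-poly" = "polynomial",
              "svm-rbf" = "radial", "svm-sigmoid" = "sigmoid")[[model]]
    sv <- e1071::svm(xtr, ytr, kernel = kern, probability = TRUE)
    pr <- predict(sv, xte, probability = TRUE)
    scores <- attr(pr, "probabilities")[, classes, drop = FALSE]
  }
  pred <- classes[max.col(scores, ties.method = "first")]
  compute_metrics(as.character(test_labels), pred, scores, classes = classes)
}

#' k-fold repeated-split evaluation
#'
#' Trains and evaluates `k` independent repetitions from scratch, each on a
#' freshly drawn 70/15/15 split (seeded from the repetition index), and
#' aggregates each metric's average, minimum, maximum and standard deviation.
#'
#' @param dataset list of labeled `qrs_set`.
#' @param method `"fsl"` (proximity evaluation), `"softmax"`, or
#'   `"head:<model>"` with a [downstream_classify()] model name.
#' @param config a [training_config()]; its seed anchors the per-fold seeds.
#' @param k repetitions (default 5).
#' @return an object of class `cv_report`: list with `per_fold` (data.frame),
#'   `summary` (avg/min/max/std per metric), `seeds`, `method`, `k`.
#' @export
crossvalidate <- function(dataset, method = "fsl",
                          config = training_config(), k = 5L) {
  seeds <- vapply(seq_len(k), function(i) derive_seed(config$seed, 100L + i),
                  integer(1))
  rows <- vector("list", k)
  for (fold in seq_len(k)) {
    cfg <- config
    cfg$seed <- seeds[fold]
    rep <- evaluate_once(dataset, method, cfg)
    rows[[fold]] <- c(fold = fold, seed = seeds[fold], rep$metrics)
  }
  per_fold <- as.data.frame(do.call(rbind, rows))
  mcols <- setdiff(names(per_fold), c("fold", "seed"))
  summary <- t(vapply(mcols, function(mc) {
    v <- per_fold[[mc]]
    c(avg = mean(v, na.rm = TRUE), min = suppressWarnings(min(v, na.rm = TRUE)),
      max = suppressWarnings(max(v, na.rm = TRUE)),
      std = stats::sd(v, na.rm = TRUE))
  }, numeric(4)))
  structure(list(per_fold = per_fold, summary = summary, seeds = seeds,
                 method = method, k = k),
            class = "cv_report")
}

evaluate_once <- function(dataset, method, cfg) {
  if (method == "softmax") {
    fit <- train_softmax(dataset, config = cfg)
    test <- fit$splits$test
    emb <- embed_many(test, fit$weights)
    probs <- t(apply(emb, 2L, softmax_head, weights = fit$weights))
    pred <- fit$classes[max.col(probs, ties.method = "first")]
    compute_metrics(labels_of(test, cfg$label_field), pred, probs,
                    classes = fit$classes)
  } else if (method == "fsl") {
    fit <- train_fsl(dataset, config = cfg)
    fsl_evaluate(fit, fit$splits$test, seed = derive_seed(cfg$seed, 7L))
  } else if (grepl("^head:", method)) {
    fit <- train_fsl(dataset, config = cfg)
    tr <- c(fit$splits$train, fit$splits$validation)
    te <- fit$splits$test
    downstream_classify(embed_many(tr, fit$weights),
                        labels_of(tr, cfg$label_field),
                        embed_many(te, fit$weights),
                        labels_of(te, cfg$label_field),
                        model = sub("^head:", "", method),
                        seed = derive_seed(cfg$seed, 8L))
  } else stop("unknown evaluation method: ", method)
}

#' @export
print.cv_report <- function(x, digits = 3, ...) {
  cat(sprintf("<cv_report: %s, %d repetitions>\n", x$method, x$k))
  print(round(x$summary, digits))
  invisible(x)
}

#' Test-subset size ablation
#'
#' Fits the named classifier once on the training embeddings, then for each
#' fraction draws a seeded random subset of the test set of that relative
#' size and records the classifier's accuracy on it. Errors if the smallest
#' subset cannot contain every class.
#'
#' @param fit an `ecg_encoder_fit`.
#' @param train_records,test_records labeled `qrs_set` lists.
#' @param fractions subset sizes relative to the test set, in (0, 1].
#' @param model [downstream_classify()] model name (default
#'   `"random-forest"`).
#' @param seed integer seed for the subset draws.
#' @return data.frame with columns `fraction`, `n`, `accuracy`.
#' @export
subset_ablation <- function(fit, train_records, test_records,
                            fractions = c(0.01, 0.05, 0.10, 0.50, 1.00),
                            model = "random-forest", seed = 1L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  lf <- fit$config$label_field
  tr_emb <- embed_many(train_records, fit$weights)
  te_emb <- embed_many(test_records, fit$weights)
  tr_lab <- labels_of(train_records, lf)
  te_lab <- labels_of(test_records, lf)
  classes <- sort(unique(tr_lab))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  out <- data.frame(fraction = fractions, n = NA_integer_,
                    accuracy = NA_real_)
  for (i in seq_along(fractions)) {
    n_sub <- max(1L, as.integer(round(fractions[i] * length(te_lab))))
    idx <- if (n_sub == length(te_lab)) seq_along(te_lab)
           else sample.int(length(te_lab), n_sub)
    if (!all(classes %in% te_lab[idx]))
      stop(sprintf("subset at fraction %.2f misses a class", fractions[i]))
    rep <- downstream_classify(tr_emb, tr_lab,
                               te_emb[, idx, drop = FALSE], te_lab[idx],
                               model = model, seed = derive_seed(seed, i))
    out$n[i] <- n_sub
    out$accuracy[i] <- rep$metrics[["accuracy"]]
  }
  out
}
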