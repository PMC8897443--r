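#' Population trial set for decoding
#'
#' Single-trial population responses for one mouse/session: trials in rows,
#' neurons in columns, with CS+/CS- trial labels.
#'
#' @param x Numeric matrix `[n_trials, n_neurons]`.
#' @param y Labels, coercible to a 2-level factor (e.g. `"CS+"` / `"CS-"`).
#' @param mouse_id,session_id Optional identifiers.
#' @return An object of class `population_trials`.
#' @export
population_trials <- function(x, y, mouse_id = NA, session_id = NA) {
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(nrow(x) == length(y), !anyNA(x))
  if (nlevels(y) != 2L) stop("population_trials() requires exactly 2 classes")
  structure(list(x = x, y = y, mouse_id = mouse_id, session_id = session_id),
            class = "population_trials")
}

# Stratified fold assignment: shuffles within each class, then deals trials
# round-robin so every fold holds both classes.
stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

fit_linear_svm <- function(x, y, cost = 1) {
  e1071::svm(x = x, y = y, kernel = "linear", cost = cost, scale = FALSE)
}

standardize_train_test <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(x_train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(x_test, 2, mu), 2, sdv, "/"))
}

#' Cross-validated linear-SVM decoding accuracy
#'
#' Mean held-out accuracy of a linear-kernel support vector classifier
#' under stratified k-fold cross-validation (default 10-fold).
#' Features are standardized using statistics of the training folds only.
#'
#' @param pop A `population_trials` object.
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Optional integer seed controlling the fold assignment.
#' @param cost SVM regularization constant (libsvm default, 1).
#' @return Mean held-out accuracy in `[0, 1]`.
#' @export
svm_cv_performance <- function(pop, folds = 10, seed = NULL, cost = 1) {
  stopifnot(inherits(pop, "population_trials"))
  if (min(table(pop$y)) < folds) {
    stop("svm_cv_performance() needs at least `folds` trials per class")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  fold_of <- stratified_folds(pop$y, folds)
  acc <- vapply(seq_len(folds), function(k) {
    tr <- fold_of != k
    std <- standardize_train_test(pop$x[tr, , drop = FALSE],
                                  pop$x[!tr, , drop = FALSE])
    fit <- fit_linear_svm(std$train, pop$y[tr], cost = cost)
    mean(stats::predict(fit, std$test) == pop$y[!tr])
  }, numeric(1))
  mean(acc)
}

#' Neuron-count-matched resampling of a per-mouse metric
#'
#' Different mice contribute different numbers of neurons, so per-mouse
#' metrics are computed on resampled populations of equal size: for every
#' mouse, `n_resamples` draws (with replacement) of `n_star` neurons, where
#' `n_star` is the lowest neuron count across mice, with the metric applied
#' to each draw and averaged.
#'
#' @param populations Named list of `population_trials`, one per mouse.
#' @param metric Function taking a `population_trials` and returning a
#'   scalar (e.g. [svm_cv_performance()] or a mean-Z_diff wrapper).
#' @param n_resamples Number of neuron resamples per mouse (default 100).
#' @param seed Optional integer seed.
#' @param ... Passed on to `metric`.
#' @return A tibble with `mouse_id`, `mean`, `sd`, `n_neurons_used`.
#' @export
resampled_metric <- function(populations, metric, n_resamples = 100,
                             seed = NULL, ...) {
  stopifnot(length(populations) >= 1L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n_star <- min(vapply(populations, function(p) ncol(p$x), integer(1)))
  ids <- names(populations)
  if (is.null(ids)) ids <- as.character(seq_along(populations))
  rows <- lapply(seq_along(populations), function(i) {
    pop <- populations[[i]]
    vals <- vapply(seq_len(n_resamples), function(r) {
      cols <- sample.int(ncol(pop$x), n_star, replace = TRUE)
      sub <- population_trials(pop$x[, cols, drop = FALSE], pop$y,
                               pop$mouse_id, pop$session_id)
      metric(sub, ...)
    }, numeric(1))
    tibble::tibble(mouse_id = ids[i], mean = mean(vals), sd = stats::sd(vals),
                   n_neurons_used = n_star)
  })
  do.call(rbind, rows)
}

#' Cross-session decoder transfer
#'
#' Fits the linear SVM on one session's trials (restricted to neurons
#' tracked into the test session), estimates a baseline accuracy on data
#' held out from the training session, then evaluates the frozen decoder
#' on the same neurons' trials from the test session. The transfer
#' deficit is `train_perf - test_perf`; under representational drift it
#' grows with the gap between sessions.
#'
#' @param train,test `population_trials` whose columns are aligned to the
#'   same neuron identities (column names are neuron ids).
#' @param tracked_ids Character/integer vector of neuron ids present in
#'   both sessions.
#' @param folds Folds for the internal held-out estimate (default 10).
#' @param seed Optional integer seed.
#' @return A list with `train_perf`, `test_perf`, `deficit`.
#' @export
cross_session_svm <- function(train, test, tracked_ids, folds = 10, seed = NULL) {
  stopifnot(inherits(train, "population_trials"),
            inherits(test, "population_trials"))
  tracked_ids <- as.character(tracked_ids)
  if (!all(tracked_ids %in% colnames(train$x)) ||
      !all(tracked_ids %in% colnames(test$x))) {
    stop("tracked_ids must be present in both sessions")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  xtr <- train$x[, tracked_ids, drop = FALSE]
  xte <- test$x[, tracked_ids, drop = FALSE]
  pop_tr <- population_trials(xtr, train$y, train$mouse_id, train$session_id)
  train_perf <- svm_cv_performance(pop_tr, folds = folds)
  std <- standardize_train_test(xtr, xte)
  fit <- fit_linear_svm(std$train, train$y)
  test_perf <- mean(stats::predict(fit, std$test) == test$y)
  list(train_perf = train_perf, test_perf = test_perf,
       deficit = train_perf - test_perf)
}

#' Similarity of single-neuron discriminability between two sessions
#'
#' Pearson correlation of per-neuron Z_diff scores across a pair of
#' sessions, over the neurons tracked between them. Declining similarity
#' with increasing session gap is the signature of representational drift.
#'
#' @param zdiff_a,zdiff_b Named numeric vectors of per-neuron Z_diff
#'   scores (names are neuron ids).
#' @param tracked_ids Neuron ids present in both sessions.
#' @return Pearson r.
#' @export
zdiff_similarity <- function(zdiff_a, zdiff_b, tracked_ids = NULL) {
  if (is.null(tracked_ids)) {
    tracked_ids <- intersect(names(zdiff_a), names(zdiff_b))
  }
  tracked_ids <- as.character(tracked_ids)
  a <- zdiff_a[tracked_ids]
  b <- zdiff_b[tracked_ids]
  keep <- is.finite(a) & is.finite(b)
  if (sum(keep) < 3L) {
    stop("zdiff_similarity() needs >= 3 tracked neurons with valid Z_diff")
  }
  stats::cor(a[keep], b[keep], method = "pearson")
}
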