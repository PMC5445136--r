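#' Stratified train/test split
#'
#' Randomly assigns `train_fraction` of the rows of every class to the
#' training set, preserving class proportions; the split is disjoint and
#' exhaustive.
#'
#' @param data Tibble with a label column.
#' @param train_fraction Fraction per class assigned to training.
#' @param seed Optional integer seed; identical seeds give identical splits.
#' @param label_col Name of the label column.
#' @param group_col Optional grouping column (e.g. `"trial_index"`): whole
#'   groups are assigned to one side, stratified by the group's label.
#'   Window-level splitting (`NULL`, the default) follows the original
#'   random-sample design; trial-level splitting keeps windows of one trial
#'   together, which removes the shared trial-level random effects between
#'   training and test and is what the chance-level leakage guard uses.
#' @param strata_col Optional extra stratification column (e.g.
#'   `"subject_id"`): the split then preserves the class proportions within
#'   every stratum. For pooled multi-subject data this avoids a subtle
#'   anti-learning artifact: each subject's class totals are fixed by the
#'   protocol, so a plain class-stratified split makes a subject's training
#'   and test class compositions negatively correlated, biasing accuracy
#'   below chance for label-free data.
#' @return List with tibbles `train` and `test`.
#' @examples
#' df <- tibble::tibble(level = rep(c("L0", "L1"), each = 8), v = 1:16)
#' sp <- stratified_split(df, seed = 1)
#' nrow(sp$train)
#' @export
stratified_split <- function(data, train_fraction = 0.75, seed = NULL,
                             label_col = "level", group_col = NULL,
                             strata_col = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  y <- data[[label_col]]
  if (is.null(y)) abort(sprintf("missing label column '%s'", label_col))
  if (!is.null(strata_col)) {
    if (is.null(data[[strata_col]])) {
      abort(sprintf("missing stratification column '%s'", strata_col))
    }
    y <- paste(y, data[[strata_col]], sep = "\r")
  }
  if (!is.null(group_col)) {
    g <- data[[group_col]]
    if (is.null(g)) abort(sprintf("missing group column '%s'", group_col))
    units <- !duplicated(g)
    gy <- y[units]
    gid <- g[units]
  } else {
    gy <- y
    gid <- seq_along(y)
    g <- gid
  }
  counts <- table(gy)
  if (any(counts < 2)) {
    abort(sprintf("class '%s' has fewer than 2 samples",
                  sub("\r.*", "", names(counts)[which.min(counts)])))
  }
  pick <- function() {
    unlist(lapply(split(seq_along(gy), gy), function(idx) {
      n_tr <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
      sample(idx)[seq_len(n_tr)]
    }), use.names = FALSE)
  }
  tr_units <- if (is.null(seed)) pick() else with_seed(seed, pick())
  tr <- g %in% gid[tr_units]
  list(train = data[tr, , drop = FALSE], test = data[!tr, , drop = FALSE])
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each row a fold id in `1..k` such that every class is spread as
#' evenly as possible across folds. Consumes the current RNG stream.
#'
#' @param y Label vector.
#' @param k Number of folds.
#' @return Integer vector of fold ids, same length as `y`.
#' @export
stratified_folds <- function(y, k) {
  counts <- table(y)
  if (any(counts < k)) {
    abort(sprintf("class '%s' has fewer samples (%d) than folds (%d)",
                  names(counts)[which.min(counts)], min(counts), k))
  }
  folds <- integer(length(y))
  for (cl in names(counts)) {
    idx <- which(y == cl)
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

confusion_matrix <- function(truth, pred, classes) {
  table(truth = factor(truth, levels = classes),
        pred = factor(pred, levels = classes))
}

# Fit-and-score one train/test fold: min-max normalisation, optional GA
# selection, optional PCA reduction, then each classifier. Every fitted
# object uses training rows only.
evaluate_fold <- function(train, test, classifiers, feature_cols,
                          ga = NULL, pca_threshold = NULL, seed = 1L,
                          label_col = "level") {
  y_tr <- train[[label_col]]
  y_te <- test[[label_col]]
  classes <- sort(unique(c(y_tr, y_te)))
  np <- minmax_fit(train, feature_cols)
  x_tr <- minmax_apply(feature_block(train, feature_cols), np)
  x_te <- minmax_apply(feature_block(test, feature_cols), np)
  selected <- seq_along(feature_cols)
  if (!is.null(ga)) {
    ga$seed <- sub_seed(seed, 71L)
    res <- run_ga(x_tr, y_tr, ga)
    if (length(res$selected)) selected <- res$selected
    x_tr <- x_tr[, selected, drop = FALSE]
    x_te <- x_te[, selected, drop = FALSE]
  }
  if (!is.null(pca_threshold)) {
    pm <- fit_pca(x_tr)
    k <- choose_k(pm, pca_threshold)
    x_tr <- project_pca(pm, x_tr, k)
    x_te <- project_pca(pm, x_te, k)
  }
  purrr::map_dfr(classifiers, function(kind) {
    pred <- if (kind == "oracle") {
      y_te
    } else {
      model <- train_classifier(x_tr, y_tr,
                                classifier_config(kind, seed = sub_seed(seed, 72L)))
      predict(model, x_te)
    }
    cm <- confusion_matrix(y_te, pred, classes)
    tibble::tibble(classifier = kind,
                   accuracy = mean(pred == y_te),
                   n_test = length(y_te),
                   n_features_selected = length(selected),
                   confusion = list(cm))
  })
}

scenario_kinds <- c("single_signal", "multi_signal_raw",
                    "multi_signal_processed", "multi_subject",
                    "between_subject_loso", "multi_day_lodo")

scenario_defaults <- function(kind) {
  switch(kind,
    single_signal = list(repeats = 10L, classifiers = "lda", ga = FALSE,
                         pca = FALSE),
    multi_signal_raw = list(repeats = 10L, classifiers = "lda", ga = FALSE,
                            pca = FALSE),
    multi_signal_processed = list(repeats = 5L,
                                  classifiers = c("lda", "knn", "svm"),
                                  ga = TRUE, pca = TRUE),
    multi_subject = list(repeats = 10L, classifiers = c("lda", "knn", "svm"),
                         ga = TRUE, pca = TRUE),
    between_subject_loso = list(repeats = 20L,
                                classifiers = c("lda", "knn", "svm"),
                                ga = TRUE, pca = TRUE),
    multi_day_lodo = list(repeats = 1L, classifiers = c("lda", "knn", "svm"),
                          ga = TRUE, pca = TRUE)
  )
}

#' Run one evaluation scenario
#'
#' Executes a full recognition experiment on an extracted feature tibble:
#'
#' * `"single_signal"` -- one LDA per channel on that channel's 12
#'   features, repeated random 75/25 splits.
#' * `"multi_signal_raw"` -- LDA on all 36 features, repeated splits, no
#'   selection or reduction.
#' * `"multi_signal_processed"` / `"multi_subject"` -- GA feature selection
#'   then PCA reduction inside each training split, then every configured
#'   classifier.
#' * `"between_subject_loso"` -- leave-one-subject-out rotation (one fold
#'   per subject), the processed pipeline fitted inside each training fold,
#'   repeated `n_repeats` times.
#' * `"multi_day_lodo"` -- leave-one-day-out rotation over the distinct
#'   recording days.
#'
#' Min-max normalisation, GA, PCA and classifier standardisation are all
#' fitted strictly on the training rows of each split/fold.
#'
#' @param features Feature tibble from [extract_features()].
#' @param kind One of the scenario kinds above.
#' @param classifiers Classifier kinds to evaluate (`"lda"`, `"knn"`,
#'   `"svm"`, or `"oracle"` which returns the true labels, for testing);
#'   `NULL` uses the scenario's default.
#' @param n_repeats Number of seeded repetitions; `NULL` uses the
#'   scenario's default (10 for split scenarios, 20 for LOSO, 1 for LODO).
#' @param ga A [ga_config()] to enable wrapper selection, `FALSE` to
#'   disable, or `NULL` for the scenario default (the full budget
#'   `ga_config()` on processed scenarios).
#' @param pca_threshold Explained-variance threshold for the PCA rank,
#'   `FALSE` to disable, `NULL` for the scenario default (0.95 on processed
#'   scenarios).
#' @param train_fraction Training fraction for split scenarios.
#' @param split_groups Optional grouping column for the splits (see
#'   [stratified_split()]); `NULL` splits at window level as in the
#'   original design.
#' @param seed Master seed; the whole scenario is deterministic given it.
#' @return A `scenario_report`: `kind`, `classes`, tibble `runs` with one
#'   row per (repeat, fold, channel, classifier) holding `accuracy` and the
#'   confusion matrix, and the resolved settings.
#' @export
run_scenario <- function(features, kind = scenario_kinds,
                         classifiers = NULL, n_repeats = NULL, ga = NULL,
                         pca_threshold = NULL, train_fraction = 0.75,
                         split_groups = NULL, seed = 1L) {
  kind <- match.arg(kind)
  def <- scenario_defaults(kind)
  classifiers <- classifiers %||% def$classifiers
  n_repeats <- as.integer(n_repeats %||% def$repeats)
  ga_cfg <- if (is.null(ga)) {
    if (def$ga) ga_config() else NULL
  } else if (isFALSE(ga)) NULL else ga
  pca_thr <- if (is.null(pca_threshold)) {
    if (def$pca) 0.95 else NULL
  } else if (isFALSE(pca_threshold)) NULL else pca_threshold

  all_cols <- feature_names()
  missing <- setdiff(all_cols, names(features))
  if (length(missing)) {
    abort(sprintf("feature tibble lacks columns: %s",
                  paste(head(missing, 4), collapse = ", ")))
  }

  runs <- list()
  add_run <- function(rep_i, fold, channel, tab) {
    runs[[length(runs) + 1L]] <<- dplyr::mutate(
      tab, `repeat` = rep_i, fold = fold, channel = channel,
      .before = 1)
  }

  if (kind %in% c("single_signal", "multi_signal_raw",
                  "multi_signal_processed", "multi_subject")) {
    channel_sets <- if (kind == "single_signal") {
      list(bvp = feature_names("bvp"), ecg = feature_names("ecg"),
           scl = feature_names("scl"))
    } else {
      list(all = all_cols)
    }
    strata <- if (!is.null(features$subject_id) &&
                  length(unique(features$subject_id)) > 1) "subject_id"
    for (r in seq_len(n_repeats)) {
      sp <- stratified_split(features, train_fraction,
                             seed = sub_seed(seed, 31L, r),
                             group_col = split_groups,
                             strata_col = strata)
      for (ch in names(channel_sets)) {
        add_run(r, NA_character_, ch,
                evaluate_fold(sp$train, sp$test, classifiers,
                              channel_sets[[ch]], ga_cfg, pca_thr,
                              seed = sub_seed(seed, 32L, r)))
      }
    }
  } else {
    unit_col <- if (kind == "between_subject_loso") "subject_id" else "day_index"
    if (is.null(features[[unit_col]])) {
      abort(sprintf("scenario '%s' needs metadata column '%s'", kind, unit_col))
    }
    if (kind == "multi_day_lodo" && !is.null(features$subject_id)) {
      # the multi-day design concerns the subject(s) recorded on > 1 day
      multi <- features |>
        dplyr::distinct(.data$subject_id, .data$day_index) |>
        dplyr::count(.data$subject_id) |>
        dplyr::filter(.data$n > 1)
      if (nrow(multi) > 0) {
        features <- dplyr::filter(features,
                                  .data$subject_id %in% multi$subject_id)
      }
    }
    units <- sort(unique(features[[unit_col]]))
    if (length(units) < 2) {
      abort(sprintf("scenario '%s' needs >= 2 distinct values of '%s'",
                    kind, unit_col))
    }
    for (r in seq_len(n_repeats)) {
      for (u in units) {
        hold <- features[[unit_col]] == u
        add_run(r, as.character(u), "all",
                evaluate_fold(features[!hold, , drop = FALSE],
                              features[hold, , drop = FALSE],
                              classifiers, all_cols, ga_cfg, pca_thr,
                              seed = sub_seed(seed, 33L, r, match(u, units))))
      }
    }
  }

  structure(list(kind = kind,
                 classes = sort(unique(features$level)),
                 runs = dplyr::bind_rows(runs),
                 classifiers = classifiers,
                 n_repeats = n_repeats,
                 ga = ga_cfg, pca_threshold = pca_thr,
                 train_fraction = train_fraction, seed = seed),
            class = "scenario_report")
}

#' Summarise a scenario report
#'
#' Mean and standard deviation of the overall accuracy over runs, plus the
#' per-class accuracies recovered from the confusion matrices, per
#' channel/classifier. The chance level `1/#classes` is included for
#' reference.
#'
#' @param report A `scenario_report` from [run_scenario()].
#' @return Tibble with columns `scenario`, `channel`, `classifier`,
#'   `class` (`"overall"` or a level label), `mean_accuracy`,
#'   `sd_accuracy`, `n_runs`, `chance`.
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "scenario_report"))
  chance <- 1 / length(report$classes)
  per_run <- report$runs |>
    dplyr::mutate(per_class = purrr::map(.data$confusion, function(cm) {
      rs <- rowSums(cm)
      acc <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
      tibble::tibble(class = rownames(cm), accuracy = acc)
    }))
  overall <- per_run |>
    dplyr::group_by(.data$channel, .data$classifier) |>
    dplyr::summarise(class = "overall",
                     mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = if (dplyr::n() > 1) sd(.data$accuracy) else 0,
                     n_runs = dplyr::n(), .groups = "drop")
  by_class <- per_run |>
    dplyr::select("channel", "classifier", "per_class") |>
    tidyr::unnest("per_class") |>
    dplyr::group_by(.data$channel, .data$classifier, .data$class) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy, na.rm = TRUE),
                     sd_accuracy = if (dplyr::n() > 1)
                       sd(.data$accuracy, na.rm = TRUE) else 0,
                     n_runs = dplyr::n(), .groups = "drop")
  dplyr::bind_rows(overall, by_class) |>
    dplyr::mutate(scenario = report$kind, chance = chance, .before = 1) |>
    dplyr::arrange(.data$channel, .data$classifier,
                   .data$class != "overall", .data$class)
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report: %s, %d runs>\n", x$kind, nrow(x$runs)))
  s <- summarize_report(x)
  print(dplyr::filter(s, .data$class == "overall"), n = 20)
  invisible(x)
}

#' @export
tidy.scenario_report <- function(x, ...) {
  dplyr::select(x$runs, -"confusion")
}

#' @export
glance.scenario_report <- function(x, ...) {
  best <- summarize_report(x) |>
    dplyr::filter(.data$class == "overall") |>
    dplyr::slice_max(.data$mean_accuracy, n = 1, with_ties = FALSE)
  tibble::tibble(scenario = x$kind, n_runs = nrow(x$runs),
                 best_classifier = best$classifier,
                 best_mean_accuracy = best$mean_accuracy,
                 chance = 1 / length(x$classes))
}

#' @export
autoplot.scenario_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$classifier, y = .data$accuracy,
                                   fill = .data$channel)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 1 / length(object$classes),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(title = object$kind, y = "overall accuracy per run") +
    ggplot2::theme_minimal()
}
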