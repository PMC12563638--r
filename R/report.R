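channel_set_id <- function(channels) paste(channels, collapse = "-")

#' Evaluate classifiers over channel sets and CV schemes
#'
#' Runs the full evaluation protocol on a dataset: per subject and channel
#' set, the fused entropy features are extracted once, then every requested
#' classifier is evaluated under every requested scheme — subject-dependent
#' LOOCV and stratified 10-fold within each subject, and cross-subject
#' LOSOCV across subjects. Per-channel feature blocks are computed once per
#' subject and reused across channel sets.
#'
#' @param dataset An `eeg_dataset` (named list of [trial_set()], e.g. from
#'   [generate_dataset()] or [load_dataset()]).
#' @param channel_sets List of character vectors; default: each channel
#'   alone.
#' @param classifiers Classifier ids or codes (default all six).
#' @param schemes Subset of `c("loocv", "kfold10", "losocv")`.
#' @param seed Seed for the stratified k-fold shuffles.
#' @param cfg An [entropy_config()].
#' @param progress Print per-subject progress to stderr.
#' @return A tibble of class `eval_report`: one row per
#'   (subject, channel_set, classifier, scheme) with `accuracy` in
#'   `[0, 100]` and `n_test`. The montage order is kept in
#'   `attr(, "montage")`.
#' @export
evaluate_dataset <- function(dataset,
                             channel_sets = NULL,
                             classifiers = classifier_specs()$id,
                             schemes = c("loocv", "kfold10", "losocv"),
                             seed = 1, cfg = entropy_config(),
                             progress = FALSE) {
  stopifnot(length(dataset) >= 1)
  schemes <- match.arg(schemes, several.ok = TRUE)
  classifiers <- vapply(classifiers, normalize_classifier_id, character(1))
  channels <- dataset[[1]]$channels
  if (is.null(channel_sets)) channel_sets <- as.list(channels)

  # per-subject, per-channel feature blocks, extracted once
  needed <- unique(unlist(channel_sets))
  fms <- lapply(names(dataset), function(id) {
    ts <- dataset[[id]]
    if (progress) message("features: subject ", id)
    blocks <- lapply(needed, function(ch) extract_channel_block(ts, ch, cfg))
    names(blocks) <- needed
    lapply(channel_sets, function(cs) {
      X <- do.call(cbind, blocks[cs])
      assemble_feature_matrix(X, ts$labels, ts$subject_id, cs, cfg)
    })
  })
  names(fms) <- names(dataset)

  rows <- list()
  for (ci in seq_along(channel_sets)) {
    cs_id <- channel_set_id(channel_sets[[ci]])
    for (clf in classifiers) {
      if (progress) message("evaluate: ", cs_id, " / ", clf)
      for (sch in intersect(schemes, c("loocv", "kfold10"))) {
        for (id in names(dataset)) {
          res <- if (sch == "loocv") {
            run_loocv(fms[[id]][[ci]], clf)
          } else {
            run_kfold(fms[[id]][[ci]], clf, k = 10, seed = seed)
          }
          rows[[length(rows) + 1]] <- tibble::tibble(
            subject_id = id, channel_set = cs_id, classifier = clf,
            scheme = sch, accuracy = res$accuracy,
            n_test = nrow(res$predictions))
        }
      }
      if ("losocv" %in% schemes && length(dataset) >= 2) {
        los <- run_losocv(lapply(fms, `[[`, ci), clf)
        rows[[length(rows) + 1]] <- dplyr::transmute(
          los$per_subject,
          subject_id = .data$subject_id, channel_set = cs_id,
          classifier = clf, scheme = "losocv",
          accuracy = .data$accuracy, n_test = .data$n_test)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("eval_report", class(tibble::tibble())),
            montage = channels)
}

#' Mean and SD aggregates of an evaluation report
#'
#' Arithmetic mean and sample standard deviation of the per-subject
#' accuracies for every (channel_set, classifier, scheme) column — the
#' "Mean" and "SD" rows of the report tables. Full precision is retained;
#' round only for display.
#'
#' @param report An `eval_report` tibble, or any tibble with an `accuracy`
#'   column and grouping columns among `channel_set`, `classifier`,
#'   `scheme`.
#' @return Tibble with `mean`, `sd` and `n` per group.
#' @export
aggregate_report <- function(report) {
  stopifnot(is.data.frame(report), "accuracy" %in% colnames(report))
  if (nrow(report) == 0) stop("aggregate_report: empty report")
  by <- intersect(c("channel_set", "channel_pair", "classifier", "scheme"),
                  colnames(report))
  dplyr::summarise(
    dplyr::group_by(report, dplyr::across(dplyr::all_of(by))),
    mean = mean(.data$accuracy),
    sd = sd(.data$accuracy),
    n = dplyr::n(),
    .groups = "drop")
}

#' Wide per-subject accuracy table for one scheme
#'
#' Lays a report out like the printed result tables: one row per subject,
#' one column per classifier (C1..C6), then `Mean` and `SD` rows, values
#' rounded to 2 decimals for display.
#'
#' @param report An `eval_report`.
#' @param scheme One scheme to tabulate.
#' @param channel_set Channel-set id to tabulate (default the first).
#' @return A tibble with a `subject` column followed by classifier-code
#'   columns.
#' @export
report_wide <- function(report, scheme, channel_set = NULL) {
  df <- dplyr::filter(report, .data$scheme == !!scheme)
  if (!is.null(channel_set)) {
    df <- dplyr::filter(df, .data$channel_set == !!channel_set)
  } else if ("channel_set" %in% colnames(df)) {
    first <- df$channel_set[1]
    df <- dplyr::filter(df, .data$channel_set == first)
  }
  if (nrow(df) == 0) stop("report_wide: no rows for scheme ", scheme)
  df$code <- classifier_code(df$classifier)
  wide <- tidyr::pivot_wider(
    df[, c("subject_id", "code", "accuracy")],
    names_from = "code", values_from = "accuracy")
  codes <- setdiff(colnames(wide), "subject_id")
  agg <- rbind(
    c(subject = "Mean", round(colMeans(wide[codes]), 2)),
    c(subject = "SD", round(apply(wide[codes], 2, sd), 2)))
  body <- dplyr::mutate(wide, dplyr::across(dplyr::all_of(codes),
                                            ~ round(.x, 2)))
  names(body)[names(body) == "subject_id"] <- "subject"
  dplyr::bind_rows(body, tibble::as_tibble(agg) |>
                     dplyr::mutate(dplyr::across(dplyr::all_of(codes),
                                                 as.numeric)))
}

#' Representative channel per subject
#'
#' For each subject, picks the single channel whose features give the
#' highest accuracy for the stated classifier and scheme — the subject's
#' representative channel — and tallies how often each channel is chosen
#' across subjects. Ties are broken by fixed montage order (first of
#' AF3, T7, PZ, T8, AF4 by default) and all tied channels are kept in a
#' list column.
#'
#' @param report An `eval_report` (or any tibble with `subject_id`,
#'   `channel_set`, `classifier`, `scheme`, `accuracy`) containing every
#'   single-channel cell.
#' @param classifier Classifier id or code to inspect.
#' @param scheme CV scheme to inspect.
#' @param montage Channel order for tie-breaking.
#' @return An object of class `channel_report`: `best` tibble
#'   (`subject_id`, `channel`, `accuracy`, `ties` list column),
#'   `occurrence` tibble (`channel`, `n`, zero-filled over the montage),
#'   plus `classifier` and `scheme`.
#' @export
best_channel_per_subject <- function(report, classifier = "lda",
                                     scheme = "loocv",
                                     montage = NULL) {
  classifier <- normalize_classifier_id(classifier)
  if (is.null(montage)) {
    montage <- attr(report, "montage")
    if (is.null(montage)) montage <- DEFAULT_MONTAGE
  }
  df <- dplyr::filter(report,
                      .data$classifier == !!classifier,
                      .data$scheme == !!scheme,
                      .data$channel_set %in% montage)
  if (nrow(df) == 0) {
    stop("best_channel_per_subject: no single-channel rows for ",
         classifier, " / ", scheme)
  }
  missing <- dplyr::filter(
    dplyr::count(df, .data$subject_id), .data$n < length(montage))
  if (nrow(missing) > 0) {
    have <- df[df$subject_id == missing$subject_id[1], "channel_set",
               drop = TRUE]
    stop("best_channel_per_subject: subject ", missing$subject_id[1],
         " is missing single-channel cells for ",
         paste(setdiff(montage, have), collapse = ", "))
  }
  best <- df |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(g, key) {
      top <- max(g$accuracy)
      tied <- g$channel_set[g$accuracy == top]
      tied <- montage[montage %in% tied]
      tibble::tibble(channel = tied[1], accuracy = top, ties = list(tied))
    }) |>
    dplyr::ungroup()
  occurrence <- tibble::tibble(channel = montage) |>
    dplyr::left_join(dplyr::count(best, .data$channel), by = "channel") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  structure(
    list(best = best, occurrence = occurrence, classifier = classifier,
         scheme = scheme),
    class = "channel_report")
}

#' @export
print.channel_report <- function(x, ...) {
  cat(sprintf("<channel_report> %s / %s\n", x$classifier, x$scheme))
  occ <- x$occurrence
  cat("  occurrences:",
      paste(sprintf("%s:%d", occ$channel, occ$n), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname best_channel_per_subject
#' @param x A `channel_report`.
#' @param ... Unused.
#' @export
tidy.channel_report <- function(x, ...) {
  dplyr::mutate(x$best, classifier = x$classifier, scheme = x$scheme,
                n_ties = lengths(.data$ties))
}

#' Tally channel occurrences from a best-channel listing
#'
#' Counts how often each channel appears in a vector of per-subject
#' representative channels (e.g. a transcribed best-channel table column).
#'
#' @param channels Character vector of channel labels, one per subject.
#' @param montage Channel order for the output (zero-filled).
#' @return Tibble with `channel` and `n`; `n` sums to `length(channels)`.
#' @examples
#' channel_occurrences(c("PZ", "T7", "PZ"))
#' @export
channel_occurrences <- function(channels, montage = DEFAULT_MONTAGE) {
  tb <- table(factor(channels, levels = montage))
  tibble::tibble(channel = montage, n = as.integer(tb))
}

#' @rdname best_channel_per_subject
#' @param object A `channel_report`.
#' @export
autoplot.channel_report <- function(object, ...) {
  occ <- object$occurrence
  occ$channel <- factor(occ$channel, levels = occ$channel)
  ggplot2::ggplot(occ, ggplot2::aes(x = .data$channel, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "channel", y = "times selected as representative",
                  title = sprintf("Representative-channel occurrences (%s, %s)",
                                  object$classifier, object$scheme)) +
    ggplot2::theme_minimal()
}

#' @rdname evaluate_dataset
#' @param object An `eval_report`.
#' @param ... Unused.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$code <- classifier_code(df$classifier)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$code, y = .data$accuracy)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::labs(x = "classifier", y = "accuracy (%)",
                  title = "Per-subject accuracy by classifier and CV scheme") +
    ggplot2::theme_minimal()
}

#' @rdname evaluate_dataset
#' @param x An `eval_report`.
#' @export
glance.eval_report <- function(x, ...) {
  df <- tibble::as_tibble(x)
  agg <- aggregate_report(df)
  dplyr::summarise(
    dplyr::group_by(agg, .data$scheme),
    best_classifier = .data$classifier[which.max(.data$mean)],
    best_mean_accuracy = max(.data$mean),
    n_cells = sum(.data$n), .groups = "drop")
}

#' Per-subject best-single-channel accuracy
#'
#' For each subject, the maximum accuracy over the single-channel cells of
#' one classifier and scheme — the subject-level summary used by the
#' printed result tables, where each subject is scored on their
#' representative channel.
#'
#' @inheritParams best_channel_per_subject
#' @return Tibble with `subject_id`, `channel` (argmax, montage-order
#'   tie-break) and `accuracy`.
#' @export
subject_best_accuracy <- function(report, classifier, scheme,
                                  montage = NULL) {
  cr <- best_channel_per_subject(report, classifier = classifier,
                                 scheme = scheme, montage = montage)
  dplyr::select(cr$best, "subject_id", "channel", "accuracy")
}

#' Bundled reference accuracy tables
#'
#' Per-subject results transcribed from a published five-channel,
#' 27-subject EEG lie-detection benchmark, shipped as plain CSV under
#' `inst/extdata/`. They exercise the report-aggregation and
#' channel-occurrence operations at full scale without any recomputation:
#' `ref_subject_accuracy()` holds the single-channel accuracies of six
#' classifiers under LOOCV, stratified 10-fold and LOSOCV;
#' `ref_best_channels()` the per-subject representative channels;
#' `ref_pairwise_accuracy()` the two-channel (T7-PZ, T7-T8, PZ-T8)
#' accuracies.
#'
#' @return A tibble.
#' @examples
#' agg <- aggregate_report(ref_subject_accuracy())
#' agg[agg$scheme == "loocv" & agg$classifier == "lda", ]
#' @export
ref_subject_accuracy <- function() {
  read_ref_csv("reference_subject_accuracy.csv") |>
    tidyr::pivot_longer(-c("subject", "scheme"), names_to = "classifier",
                        values_to = "accuracy") |>
    dplyr::rename(subject_id = "subject")
}

#' @rdname ref_subject_accuracy
#' @export
ref_best_channels <- function() {
  dplyr::rename(read_ref_csv("reference_best_channels.csv"),
                subject_id = "subject")
}

#' @rdname ref_subject_accuracy
#' @export
ref_pairwise_accuracy <- function() {
  dplyr::rename(read_ref_csv("reference_pairwise_accuracy.csv"),
                subject_id = "subject")
}

read_ref_csv <- function(name) {
  path <- system.file("extdata", name, package = "msentropy")
  if (path == "") stop("bundled table not found: ", name)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
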