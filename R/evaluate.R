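#' Cross-validated evaluation grid
#'
#' Reproduces the full model-evaluation design: for every combination of
#' model variant, train/test split scheme, feature count k and AO task
#' duration, repeat `repeats` times a subject-level random partition, rank
#' features on the training subjects (unless `selection_mode =
#' "paper_faithful"`, which ranks once on all subjects before splitting — the
#' original single-cohort protocol, kept for comparison runs), fit the
#' k-feature prefix model by the normal equation, and record on the held-out
#' subjects the root mean square error of the predicted FAS totals and the
#' percentage whose predicted total falls in the correct fatigue class.
#'
#' Variants: `"EEG"` ranks all significant EEG features (P300 + normalized
#' powers + ratios, p < alpha); `"NR-EEG"` additionally removes the worse
#' member of each reciprocal ratio pair ([drop_redundant()]); `"E4"` ranks
#' the six wristband features (st, lf, tp, hf, lfnu, lf_hf) by p-value
#' without a significance gate.
#'
#' Split schemes at m subjects: `"70:30"` trains on `round(0.7 m)` random
#' subjects, `"80:20"` on `round(0.8 m)`, and `"LOO"` holds out one subject,
#' drawn without replacement across repeats until all have served (then with
#' replacement). Train and test subjects are disjoint in every repeat; the
#' same partitions are reused across variants, durations and k so cells are
#' comparable.
#'
#' @param features Feature tibble from [cohort_features()] (any number of
#'   durations).
#' @param variants,splits Character subsets of the defaults.
#' @param k_max Largest feature-count prefix evaluated (default 15).
#' @param repeats Cross-validation repeats (default 10).
#' @param alpha Selection significance level.
#' @param seed Integer seed for the partitions.
#' @param selection_mode `"per_fold"` (leakage-free, default) or
#'   `"paper_faithful"`.
#' @param durations Optional subset of the durations present in `features`.
#' @return An `nf_eval_grid` tibble, one row per cell: `variant`, `split`,
#'   `duration_s`, `k`, `accuracy` (mean % correct), `accuracy_se`, `rmse`
#'   (mean), `rmse_se`, `n_reps` (repeats where the cell was available: a
#'   fold can select fewer than k features).
#' @export
evaluate_grid <- function(features,
                          variants = c("EEG", "NR-EEG", "E4"),
                          splits = c("70:30", "80:20", "LOO"),
                          k_max = 15, repeats = 10, alpha = 0.05, seed = 1,
                          selection_mode = c("per_fold", "paper_faithful"),
                          durations = NULL) {
  selection_mode <- match.arg(selection_mode)
  variants <- match.arg(variants, c("EEG", "NR-EEG", "E4"), several.ok = TRUE)
  splits <- match.arg(splits, c("70:30", "80:20", "LOO"), several.ok = TRUE)
  durations <- durations %||% sort(unique(features$duration_s), decreasing = TRUE)

  ## complete subjects only, identical across durations
  fms <- lapply(durations, function(d) {
    assemble_feature_matrix(features[features$duration_s == d, , drop = FALSE])
  })
  names(fms) <- as.character(durations)
  subjects <- fms[[1]]$subject_id
  m <- length(subjects)

  partitions <- draw_partitions(subjects, splits, repeats, seed)

  cells <- list()
  for (d in as.character(durations)) {
    fm <- fms[[d]]
    for (variant in variants) {
      global_sel <- if (selection_mode == "paper_faithful") {
        variant_selection(fm, variant, alpha)
      }
      for (split in splits) {
        per_rep <- vector("list", repeats)
        for (rep_i in seq_len(repeats)) {
          part <- partitions[[split]][[rep_i]]
          train <- fm[fm$subject_id %in% part$train, , drop = FALSE]
          test <- fm[fm$subject_id %in% part$test, , drop = FALSE]
          sel <- if (selection_mode == "paper_faithful") global_sel
                 else variant_selection(train, variant, alpha)
          per_rep[[rep_i]] <- eval_prefixes(sel, train, test, k_max)
        }
        res <- dplyr::bind_rows(per_rep)
        summ <- res |>
          dplyr::filter(!is.na(.data$rmse)) |>
          dplyr::group_by(.data$k) |>
          dplyr::summarise(
            acc_mean = mean(.data$accuracy),
            acc_se = sd(.data$accuracy) / sqrt(dplyr::n()),
            rmse_mean = mean(.data$rmse),
            rmse_sem = sd(.data$rmse) / sqrt(dplyr::n()),
            n_reps = dplyr::n(),
            .groups = "drop"
          ) |>
          dplyr::rename(accuracy = "acc_mean", accuracy_se = "acc_se",
                        rmse = "rmse_mean", rmse_se = "rmse_sem")
        summ <- dplyr::left_join(tibble(k = seq_len(k_max)), summ, by = "k")
        cells[[length(cells) + 1L]] <- dplyr::bind_cols(
          tibble(variant = variant, split = split, duration_s = as.numeric(d)),
          summ[, c("k", "accuracy", "accuracy_se", "rmse", "rmse_se", "n_reps")]
        )
      }
    }
  }
  out <- dplyr::bind_rows(cells)
  out$n_reps[is.na(out$n_reps)] <- 0L
  structure(out, class = c("nf_eval_grid", class(out)),
            m = m, repeats = repeats, alpha = alpha, seed = seed,
            selection_mode = selection_mode)
}

variant_selection <- function(fm, variant, alpha) {
  feat_cols <- attr(fm, "feature_cols") %||%
    setdiff(names(fm), c("subject_id", "fas"))
  if (variant == "E4") {
    cols <- intersect(e4_model_features(), feat_cols)
    sub <- fm[, c("subject_id", "fas", cols)]
    attr(sub, "feature_cols") <- cols
    return(select_features(sub, alpha = Inf))
  }
  eeg_cols <- feat_cols[grepl("^(p300_|np_|ratio_)", feat_cols)]
  sub <- fm[, c("subject_id", "fas", eeg_cols)]
  attr(sub, "feature_cols") <- eeg_cols
  sel <- select_features(sub, alpha = alpha)
  if (variant == "NR-EEG") sel <- drop_redundant(sel)
  sel
}

eval_prefixes <- function(sel, train, test, k_max) {
  y_tr <- train$fas
  y_te <- test$fas
  true_class <- fas_class(y_te)
  rows <- lapply(seq_len(k_max), function(k) {
    if (k > nrow(sel)) {
      return(tibble(k = k, accuracy = NA_real_, rmse = NA_real_))
    }
    feats <- sel$feature[seq_len(k)]
    fit <- suppressMessages(fit_mlr(train[, feats, drop = FALSE], y_tr))
    pred <- predict(fit, test)
    tibble(
      k = k,
      accuracy = 100 * mean(fas_class_pred(pred) == true_class),
      rmse = rmse_value(y_te, pred)
    )
  })
  dplyr::bind_rows(rows)
}

## subject-level partitions per split scheme, shared across grid cells
draw_partitions <- function(subjects, splits, repeats, seed) {
  m <- length(subjects)
  out <- list()
  for (split in splits) {
    s <- derive_seed(seed, match(split, c("70:30", "80:20", "LOO")))
    out[[split]] <- withr::with_seed(s, {
      if (split == "LOO") {
        ord <- sample(subjects)
        lapply(seq_len(repeats), function(r) {
          held <- if (r <= m) ord[r] else sample(subjects, 1)
          list(train = setdiff(subjects, held), test = held)
        })
      } else {
        n_train <- round(ifelse(split == "70:30", 0.7, 0.8) * m)
        lapply(seq_len(repeats), function(r) {
          tr <- sample(subjects, n_train)
          list(train = tr, test = setdiff(subjects, tr))
        })
      }
    })
  }
  out
}

#' Best cell of an evaluation grid
#'
#' @param grid An `nf_eval_grid`.
#' @return One-row tibble: the available cell with the highest accuracy,
#'   ties broken by lower RMSE then smaller k.
#' @export
best_cell <- function(grid) {
  avail <- grid[grid$n_reps > 0, , drop = FALSE]
  avail[order(-avail$accuracy, avail$rmse, avail$k), ][1, ]
}
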