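#' Run the full measurement-and-analysis chain on a simulated study
#'
#' Executes the complete pipeline on a [simulate_study()] object:
#'
#' 1. simulate each reference-protocol session and train an individual
#'    classifier per participating child, plus the general (pooled) model;
#' 2. for every child-day, materialize the raw trace, segment it into
#'    2.5 s frames, compute the 12 key-values and classify every frame with
#'    the child's selected model;
#' 3. consolidate non-wear time, restrict to the diary wake window and keep
#'    valid days (>= 6 h wear);
#' 4. collapse valid days into daily activity measures and join them with
#'    the daily affect composites.
#'
#' @param study An [simulate_study()] result.
#' @param cost,gamma Classifier hyperparameters (see [train_model()]).
#' @param verbose Print per-child progress.
#' @return List with `day_table` (one row per valid child-day: activity
#'   measures and affect scores), `wear` (per child-day wear summary),
#'   `individual_models`, `general_model`, and `epoch_accuracy` (share of
#'   wake-window epochs classified identically to the simulation's
#'   ground-truth labels, per child-day).
#' @export
run_pipeline <- function(study, cost = 1, gamma = 1 / 12, verbose = FALSE) {
  stopifnot(inherits(study, "actiflux_study"))
  ref_children <- study$children$child_id[study$children$has_reference]

  refsets <- list()
  individual_models <- list()
  for (cid in ref_children) {
    seed <- study$children$ref_seed[study$children$child_id == cid]
    ses <- simulate_reference_session(
      cid, seed = seed, params_per_kind = study$params$params_per_kind,
      rate = study$params$rate, frame_length = study$params$frame_length)
    feats <- compute_features(segment_frames(ses$trace,
                                             study$params$frame_length))
    refsets[[cid]] <- reference_set(feats, ses$epochs$label, cid)
    individual_models[[cid]] <- suppressMessages(
      train_model(refsets[[cid]], cost = cost, gamma = gamma,
                  scope = "individual"))
  }
  general_model <- suppressMessages(
    train_model(pool_reference_sets(refsets), cost = cost, gamma = gamma,
                scope = "general"))

  wear <- list(); days <- list(); acc <- list()
  for (cid in study$children$child_id) {
    model <- select_model(cid, individual_models, general_model)
    dates <- sort(unique(study$truth_days$date[study$truth_days$child_id == cid]))
    cleaned_days <- list()
    for (d in as.list(dates)) {
      tr <- realize_trace(study, cid, d)
      feats <- compute_features(segment_frames(tr, study$params$frame_length))
      labs <- predict_epochs(model, feats, child_id = cid)
      truth <- true_epochs(study, cid, d)
      cleaned <- consolidate_nonwear(labs)
      cleaned <- restrict_to_wake_window(cleaned, study$sleep)
      n <- min(nrow(labs), nrow(truth))
      acc[[length(acc) + 1L]] <- data.frame(
        child_id = cid, date = d,
        accuracy = mean((labs$label == truth$label)[seq_len(n)][
          cleaned$retained[seq_len(n)]]))
      cleaned_days[[format(d)]] <- cleaned
      rm(tr, feats)
    }
    all_cleaned <- do.call(rbind, cleaned_days)
    attr(all_cleaned, "epoch_seconds") <- study$params$frame_length
    class(all_cleaned) <- class(cleaned_days[[1]])
    ws <- summarize_wear(all_cleaned)
    wear[[cid]] <- ws
    for (d in as.list(ws$date[ws$valid])) {
      day_ep <- cleaned_days[[format(d)]]
      days[[length(days) + 1L]] <- summarize_day(day_ep)
    }
    if (verbose) {
      message(sprintf("%s: %d/%d valid days", cid, sum(ws$valid), nrow(ws)))
    }
  }
  wear <- do.call(rbind, c(wear, list(make.row.names = FALSE)))
  day_table <- do.call(rbind, days)
  affect <- affect_day_scores(study$affect_items, study$params$item_map)
  day_table <- merge(day_table, affect, by = c("child_id", "date"),
                     all.x = TRUE)
  day_table <- day_table[order(day_table$child_id, day_table$date), ]
  rownames(day_table) <- NULL
  list(day_table = day_table, wear = wear,
       individual_models = individual_models, general_model = general_model,
       epoch_accuracy = do.call(rbind, acc))
}
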