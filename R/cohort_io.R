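#' Load a cohort from manifest, echo and clinical CSV files
#'
#' Joins per-recording annotations, per-participant echocardiography results
#' and clinical covariates into one cohort object. Participants whose four
#' recordings are all flagged noisy are marked excluded; participants with a
#' corrupt or unreadable WAV are dropped with a log entry; identifiers present
#' in the manifest but absent from the echo file are listed in the
#' reconciliation report and excluded from disease analyses.
#'
#' @param dir Directory holding `manifest.csv`, `echo.csv`, `clinical.csv`
#'   and the WAV files referenced by the manifest.
#' @param read_audio Read waveforms (set `FALSE` for label-only work).
#' @return List of class `pcg_cohort` with `participants`, `recordings`,
#'   `audio`, and a `reconciliation` data frame logging every exclusion with
#'   participant id and reason.
#' @export
load_cohort <- function(dir, read_audio = TRUE) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  echo <- utils::read.csv(file.path(dir, "echo.csv"), stringsAsFactors = FALSE)
  clinical_path <- file.path(dir, "clinical.csv")
  clinical <- if (file.exists(clinical_path))
    utils::read.csv(clinical_path, stringsAsFactors = FALSE) else NULL
  manifest <- manifest[order(manifest$participant_id, manifest$position), ]
  rownames(manifest) <- NULL
  echo <- echo[order(echo$participant_id), ]
  rownames(echo) <- NULL

  need <- c("participant_id", "position", "annotator1_grade",
            "annotator2_grade", "annotator1_noise", "annotator2_noise",
            "wav_path")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols))
    stop("manifest missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(manifest[, c("participant_id", "position")]))
    stop("duplicate (participant, position) rows in manifest")
  g <- c(manifest$annotator1_grade, manifest$annotator2_grade)
  if (any(g < 0 | g > 6)) stop("annotator grades outside 0-6")
  manifest$murmur_grade <- (manifest$annotator1_grade + manifest$annotator2_grade) / 2

  log_rows <- list()
  note <- function(id, reason)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      participant_id = id, reason = reason, stringsAsFactors = FALSE)

  audio <- NULL
  dropped <- character(0)
  if (read_audio) {
    audio <- list()
    for (k in seq_len(nrow(manifest))) {
      w <- tryCatch(read_wav(file.path(dir, manifest$wav_path[k])),
                    error = function(e) e)
      if (inherits(w, "error")) {
        note(manifest$participant_id[k],
             paste0("corrupt audio (", conditionMessage(w), ")"))
        dropped <- c(dropped, manifest$participant_id[k])
      } else {
        audio[[paste0(manifest$participant_id[k], "_", manifest$position[k])]] <-
          list(waveform = w$samples, sample_rate_hz = w$sample_rate_hz)
      }
    }
  }
  if (length(dropped)) {
    keep <- !manifest$participant_id %in% dropped
    manifest <- manifest[keep, ]
    rownames(manifest) <- NULL
  }

  no_echo <- setdiff(manifest$participant_id, echo$participant_id)
  for (id in no_echo) note(id, "no echocardiography record")

  noisy <- manifest$annotator1_noise | manifest$annotator2_noise
  all_noisy <- tapply(noisy, manifest$participant_id, function(z) all(z) & length(z) == 4)
  excluded_ids <- names(all_noisy)[all_noisy %in% TRUE]
  for (id in excluded_ids) note(id, "all four recordings noisy")

  participants <- echo[echo$participant_id %in% manifest$participant_id, ,
                       drop = FALSE]
  rownames(participants) <- NULL
  if (!is.null(clinical))
    participants <- merge(participants, clinical, by = "participant_id",
                          all.x = TRUE, sort = TRUE)
  participants$excluded_all_noisy <-
    participants$participant_id %in% excluded_ids

  reconciliation <- if (length(log_rows)) do.call(rbind, log_rows)
    else data.frame(participant_id = character(0), reason = character(0))
  structure(list(participants = participants, recordings = manifest,
                 audio = audio, reconciliation = reconciliation,
                 config = NULL),
            class = "pcg_cohort")
}
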