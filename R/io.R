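# CSV/JSON interchange. Hypnogram CSV: subject_id,study,condition,
# epoch_index,stage. Physio CSV: subject_id,study,condition,variable,
# sensor_id,time_s,value. Times are seconds since lights-off, 0-based.

#' Write a cohort to CSV plus a JSON manifest
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hyp <- do.call(rbind, lapply(cohort, function(s) {
    do.call(rbind, lapply(list(s$hm, s$lm), function(n) {
      data.frame(subject_id = n$subject_id, study = n$study,
                 condition = n$condition,
                 epoch_index = seq_along(n$hypnogram) - 1L,
                 stage = n$hypnogram)
    }))
  }))
  hyp_path <- file.path(dir, "hypnogram.csv")
  utils::write.csv(hyp, hyp_path, row.names = FALSE, quote = FALSE)

  phys_path <- NULL
  if (!is.null(cohort[[1]]$hm$physio)) {
    phys <- do.call(rbind, lapply(cohort, function(s) {
      do.call(rbind, lapply(list(s$hm, s$lm), function(n) {
        cbind(data.frame(subject_id = n$subject_id, study = n$study,
                         condition = n$condition), n$physio)
      }))
    }))
    phys_path <- file.path(dir, "physio.csv")
    utils::write.csv(phys, phys_path, row.names = FALSE, quote = FALSE)
  }

  spec <- attr(cohort, "spec")
  manifest <- list(
    n_subjects = length(cohort),
    study_sizes = spec$study_sizes, seed = spec$seed,
    subjects = vapply(cohort, function(s) s$profile$subject_id, ""),
    spec = spec[setdiff(names(spec), NULL)])
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(hyp_path, phys_path, man_path))
}

#' Read a hypnogram CSV
#'
#' Validates stage labels (W/N1/N2/N3/REM), conditions (HM/LM), epoch
#' contiguity and duplicates; errors name the offending row.
#'
#' @param path CSV with columns subject_id,study,condition,epoch_index,stage.
#' @return Named list (\code{"subject|condition"}) of stage sequences, each
#'   with attributes \code{subject_id}, \code{study}, \code{condition}.
#' @export
read_hypnogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "study", "condition", "epoch_index", "stage")
  if (!all(need %in% names(df)))
    stop("hypnogram CSV must have columns: ", paste(need, collapse = ","))
  bad <- which(!df$stage %in% STAGES)
  if (length(bad))
    stop(sprintf("row %d: unknown stage label '%s'", bad[1] + 1L, df$stage[bad[1]]))
  bad <- which(!df$condition %in% c("HM", "LM"))
  if (length(bad))
    stop(sprintf("row %d: unknown condition '%s'", bad[1] + 1L, df$condition[bad[1]]))
  key <- paste(df$subject_id, df$condition, sep = "|")
  out <- list()
  for (k in unique(key)) {
    sub <- df[key == k, ]
    o <- order(sub$epoch_index)
    sub <- sub[o, ]
    if (anyDuplicated(sub$epoch_index)) {
      d <- sub$epoch_index[duplicated(sub$epoch_index)][1]
      stop(sprintf("duplicate epoch %d for %s", d, k))
    }
    if (!identical(as.integer(sub$epoch_index), seq_len(nrow(sub)) - 1L))
      stop(sprintf("missing or non-contiguous epochs for %s", k))
    seqs <- sub$stage
    attr(seqs, "subject_id") <- sub$subject_id[1]
    attr(seqs, "study") <- sub$study[1]
    attr(seqs, "condition") <- sub$condition[1]
    out[[k]] <- seqs
  }
  out
}

#' Read a physiology CSV
#'
#' @param path CSV with columns
#'   subject_id,study,condition,variable,sensor_id,time_s,value.
#' @return Named list (\code{"subject|condition"}) of data frames with
#'   columns variable, sensor_id, time_s, value.
#' @export
read_physio_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "study", "condition", "variable", "sensor_id",
            "time_s", "value")
  if (!all(need %in% names(df)))
    stop("physio CSV must have columns: ", paste(need, collapse = ","))
  bad <- which(df$time_s < 0 | df$time_s >= 27000)
  if (length(bad))
    stop(sprintf("row %d: time_s %s outside [0, 27000)", bad[1] + 1L,
                 format(df$time_s[bad[1]])))
  key <- paste(df$subject_id, df$condition, sep = "|")
  lapply(split(df, key), function(sub) {
    out <- sub[, c("variable", "sensor_id", "time_s", "value")]
    attr(out, "subject_id") <- sub$subject_id[1]
    attr(out, "study") <- sub$study[1]
    attr(out, "condition") <- sub$condition[1]
    out
  })
}
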