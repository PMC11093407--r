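#' Build a session table from report traces and sequences
#'
#' The session table is the long-format exchange schema (one row per
#' observation and subject): columns `task`, `subject_id`, `sequence_id`,
#' `t` (1-based), `x`, `v` (the report after observing `x`), and, when the
#' generating sequences are supplied, `h` and `cp`. Real experimental
#' sessions exported in this schema can be fed to every analysis in place of
#' simulated cohorts.
#'
#' @param traces List of `estimate_trace` objects.
#' @param seqs Optional list of `obs_sequence` objects (matched by
#'   `sequence_id`) supplying `x`, `h` and `cp`.
#' @return A data frame in the session schema.
#' @export
sessions_table <- function(traces, seqs) {
  seq_map <- stats::setNames(seqs, vapply(seqs, `[[`, "", "sequence_id"))
  rows <- lapply(traces, function(tr) {
    sq <- seq_map[[tr$sequence_id]]
    if (is.null(sq)) stop("data error: no sequence ", tr$sequence_id, call. = FALSE)
    data.frame(task = tr$task, subject_id = tr$agent_id,
               sequence_id = tr$sequence_id, t = seq_len(tr$n_obs),
               x = sq$x, v = tr$v[-1], h = sq$h, cp = sq$cp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a session table to CSV
#'
#' UTF-8, comma-separated, `.` decimal, header included.
#'
#' @param table Data frame in the session schema (see [sessions_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a session table
#'
#' Validates the schema and value ranges; all violations are collected and
#' reported together with their row numbers.
#'
#' @param path CSV path.
#' @return The validated session table.
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sessions(tbl)
  tbl
}

validate_sessions <- function(tbl) {
  problems <- character(0)
  required <- c("task", "subject_id", "sequence_id", "t", "x", "v")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    stop("validation error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- function(rows, what) {
    if (length(rows)) {
      problems <<- c(problems, sprintf("row %d: %s", rows, what))
    }
  }
  bad(which(!tbl$task %in% c("magnitude", "probability")), "unknown task")
  bad(which(tbl$x < 0 | tbl$x > 1), "x outside [0, 1]")
  bad(which(tbl$v < 0 | tbl$v > 1), "v outside [0, 1]")
  bad(which(tbl$task == "probability" & !tbl$x %in% c(0, 1)),
      "non-binary observation in probability task")
  for (key in unique(paste(tbl$subject_id, tbl$sequence_id))) {
    rows <- which(paste(tbl$subject_id, tbl$sequence_id) == key)
    if (!identical(as.integer(tbl$t[rows]), seq_along(rows))) {
      bad(rows[1], sprintf("t not contiguous from 1 for %s", key))
    }
  }
  if (length(problems)) {
    stop("validation error:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(tbl)
}

#' Convert a session table back into estimate traces
#'
#' The pre-observation report `v_0` is set to 0.5 (slider midpoint), as in
#' the task.
#'
#' @param table A validated session table.
#' @return List of `estimate_trace` objects.
#' @export
sessions_to_traces <- function(table) {
  keys <- unique(table[, c("subject_id", "sequence_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    rows <- table$subject_id == keys$subject_id[i] &
      table$sequence_id == keys$sequence_id[i]
    d <- table[rows, ]
    new_estimate_trace(d$task[1], c(0.5, d$v), keys$sequence_id[i],
                       keys$subject_id[i], kind = "imported")
  })
}

#' Write a sequence set to CSV with a JSON sidecar
#'
#' The CSV holds one row per observation (`task`, `sequence_id`, `t`, `x`,
#' `h`, `cp`); the sidecar records the generating configuration and the
#' per-sequence seeds so the set is fully reproducible.
#'
#' @param seqs List of `obs_sequence` objects.
#' @param path Output CSV path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path) {
  df <- do.call(rbind, lapply(seqs, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  cfg <- seqs[[1]]$config
  sidecar <- list(
    config = cfg[setdiff(names(cfg), "task")],
    task = cfg$task,
    seeds = stats::setNames(
      lapply(seqs, `[[`, "seed"),
      vapply(seqs, `[[`, "", "sequence_id")
    )
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sequence set written by [write_sequences()]
#'
#' @param path CSV path (the `.json` sidecar is read from
#'   `paste0(path, ".json")` if present).
#' @return List of `obs_sequence` objects.
#' @export
read_sequences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else {
    NULL
  }
  lapply(unique(df$sequence_id), function(sid) {
    d <- df[df$sequence_id == sid, ]
    cfg <- if (!is.null(sidecar)) {
      args <- sidecar$config
      if (d$task[1] == "magnitude") do.call(magnitude_config, args)
      else do.call(probability_config, args)
    } else {
      NULL
    }
    seed <- if (!is.null(sidecar)) sidecar$seeds[[sid]] else NA_integer_
    new_obs_sequence(d$task[1], d$x, d$h, as.logical(d$cp), cfg, seed,
                     sequence_id = sid)
  })
}

#' Tabulate normative traces
#'
#' @param traces List of `normative_trace` objects.
#' @return Data frame with columns `task`, `sequence_id`, `t`, `v`, `u`,
#'   `omega`, `alpha`.
#' @export
traces_table <- function(traces) {
  do.call(rbind, lapply(traces, function(tr) {
    data.frame(task = tr$task, sequence_id = tr$sequence_id,
               t = seq_len(tr$n_obs), v = tr$v, u = tr$u,
               omega = tr$omega, alpha = tr$alpha, stringsAsFactors = FALSE)
  }))
}
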