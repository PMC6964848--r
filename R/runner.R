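# ---------------------------------------------------------------------------
# Local task queue: deterministic task ids (FNV-1a over a canonical payload
# string), a worker pool via the parallel package, and CSV checkpointing so
# interrupted scans resume without recomputing finished tasks. The queue
# semantics (idempotent tasks, per-task failure isolation) mirror a remote
# queue backend without depending on one.
# ---------------------------------------------------------------------------

# canonical, locale-independent string form of a payload
stable_string <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (is.null(nm)) nm <- rep("", length(x))
    ord <- order(nm)
    inner <- vapply(ord, function(i)
      paste0(nm[i], "=", stable_string(x[[i]])), character(1))
    return(paste0("{", paste(inner, collapse = ";"), "}"))
  }
  if (is.numeric(x)) return(paste(formatC(x, digits = 15, format = "g"),
                                  collapse = ","))
  if (is.logical(x)) return(paste(as.integer(x), collapse = ","))
  paste(as.character(x), collapse = ",")
}

# FNV-1a 32-bit, in double arithmetic (exact: all intermediates < 2^41)
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
    h <- h %% 4294967296
  }
  h
}

bitwXor_dbl <- function(a, b) {
  # a < 2^32, b < 256: xor on the low 8 bits only
  lo <- a %% 256
  a - lo + bitwXor(as.integer(lo), as.integer(b))
}

#' Deterministic task id of a payload
#' @param payload a list of scalar fields describing the task.
#' @return an 8-hex-digit id; identical payloads always hash identically.
#' @export
task_id <- function(payload) {
  h <- fnv1a32(stable_string(payload))
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

#' Build a task list from payloads
#' @param payloads list of payload lists.
#' @return list of tasks `list(task_id, payload, status = "pending")`.
#' @export
make_tasks <- function(payloads) {
  lapply(payloads, function(p)
    list(task_id = task_id(p), payload = p, status = "pending"))
}

#' Execute tasks on a local worker pool
#'
#' Applies `fn(payload)` to every pending task; `fn` must return a named
#' list of scalar fields. Failures mark the row "failed" with the error
#' message and never abort the run. With a checkpoint path, finished task
#' ids are skipped on restart and new results appended.
#'
#' @param tasks task list from [make_tasks()].
#' @param fn worker function, `payload -> named list`.
#' @param workers number of parallel workers (forked; 1 = serial).
#' @param checkpoint optional CSV path for resume support.
#' @return list with `results` (data.frame sorted by task_id, with columns
#'   task_id, status, error and the fields returned by `fn`) and `report`
#'   (an `fm_run_report`).
#' @export
run_tasks <- function(tasks, fn, workers = 1L, checkpoint = NULL) {
  stopifnot(workers >= 1)
  t0 <- Sys.time()
  ids <- vapply(tasks, `[[`, character(1), "task_id")
  if (anyDuplicated(ids)) stop("duplicate task ids (identical payloads)")
  done <- if (!is.null(checkpoint) && file.exists(checkpoint)) {
    utils::read.csv(checkpoint, stringsAsFactors = FALSE,
                    colClasses = "character")
  } else NULL
  todo <- tasks[!ids %in% done$task_id]
  exec1 <- function(task) {
    out <- tryCatch(
      list(status = "done", error = "", fields = fn(task$payload)),
      error = function(e)
        list(status = "failed", error = conditionMessage(e), fields = NULL))
    row <- c(list(task_id = task$task_id, status = out$status,
                  error = out$error), out$fields)
    lapply(row, as.character)
  }
  new_rows <- if (length(todo)) {
    if (workers > 1) {
      parallel::mclapply(todo, exec1, mc.cores = workers)
    } else {
      lapply(todo, exec1)
    }
  } else list()
  all_rows <- new_rows
  if (!is.null(done) && nrow(done)) {
    all_rows <- c(all_rows, lapply(seq_len(nrow(done)), function(i)
      as.list(done[i, , drop = FALSE])))
  }
  cols <- unique(unlist(lapply(all_rows, names)))
  df <- as.data.frame(
    stats::setNames(lapply(cols, function(cn)
      vapply(all_rows, function(r)
        if (is.null(r[[cn]])) NA_character_ else as.character(r[[cn]]),
        character(1))), cols),
    stringsAsFactors = FALSE)
  df <- df[order(df$task_id), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(checkpoint)) {
    utils::write.csv(df, checkpoint, row.names = FALSE, quote = FALSE)
  }
  n_done <- sum(df$status == "done")
  n_failed <- sum(df$status == "failed")
  report <- structure(list(
    total = length(tasks), done = n_done, failed = n_failed,
    pending = length(tasks) - n_done - n_failed,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    checkpoint = checkpoint), class = "fm_run_report")
  list(results = df, report = report)
}

#' @export
print.fm_run_report <- function(x, ...) {
  cat(sprintf("Run report: %d tasks, %d done, %d failed, %d pending (%.2fs)\n",
              x$total, x$done, x$failed, x$pending, x$wall_time_s))
  invisible(x)
}
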