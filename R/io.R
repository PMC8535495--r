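#' Read and write TDS task files
#'
#' Two interchange formats are supported and inferred from the file
#' extension (or forced with `format`):
#'
#' * **CSV (long form)** — columns `task_id`, `start_time`, `stop_time`,
#'   `event_time`, `descriptor`; one row per selection event, UTF-8, header
#'   required. Tasks are grouped by `task_id`; `start_time`/`stop_time` must
#'   be constant within a task.
#' * **JSON** — an array of objects
#'   `{task_id, start, stop, events: [{t, descriptor}, ...]}`.
#'
#' Validation failures (unsorted events, events outside `[start, stop)`,
#' missing columns, empty files) raise errors naming the offending task.
#'
#' @param path File path.
#' @param format `"csv"`, `"json"`, or `NULL` to infer from the extension.
#' @return `read_tasks` returns a list of [tds_task()] records;
#'   `write_tasks` returns `path` invisibly.
#' @export
read_tasks <- function(path, format = NULL) {
  format <- infer_format(path, format)
  if (format == "csv") read_tasks_csv(path) else read_tasks_json(path)
}

#' @rdname read_tasks
#' @param tasks A list of [tds_task()] records.
#' @export
write_tasks <- function(tasks, path, format = NULL) {
  stopifnot(length(tasks) > 0, all(vapply(tasks, inherits, TRUE, "tds_task")))
  format <- infer_format(path, format)
  if (format == "csv") write_tasks_csv(tasks, path) else write_tasks_json(tasks, path)
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "json")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) return(ext)
  stop("cannot infer task file format from extension '", ext,
       "'; pass format = \"csv\" or \"json\"", call. = FALSE)
}

read_tasks_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("empty or unreadable task file: ", path,
                             call. = FALSE)
  )
  need <- c("task_id", "start_time", "stop_time", "event_time", "descriptor")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("task CSV is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("task file contains no events: ", path, call. = FALSE)
  ids <- unique(df$task_id)
  lapply(ids, function(id) {
    rows <- df[df$task_id == id, , drop = FALSE]
    if (length(unique(rows$start_time)) > 1 || length(unique(rows$stop_time)) > 1) {
      stop("task ", id, ": inconsistent start/stop times across rows",
           call. = FALSE)
    }
    tds_task(id, rows$start_time[1], rows$stop_time[1],
             data.frame(time = rows$event_time, descriptor = rows$descriptor))
  })
}

write_tasks_csv <- function(tasks, path) {
  rows <- lapply(tasks, function(x) {
    if (nrow(x$events) == 0) {
      stop("task ", x$task_id, " has no events; the long-form CSV cannot ",
           "represent event-free tasks, use JSON", call. = FALSE)
    }
    data.frame(
      task_id = x$task_id,
      start_time = num17(x$start_time),
      stop_time = num17(x$stop_time),
      event_time = num17(x$events$time),
      descriptor = x$events$descriptor,
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
}

# full-precision decimal text so CSV round-trips are exact
num17 <- function(x) sprintf("%.17g", x)

read_tasks_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(raw) == 0) stop("task file contains no tasks: ", path, call. = FALSE)
  lapply(raw, function(obj) {
    need <- c("task_id", "start", "stop", "events")
    miss <- setdiff(need, names(obj))
    if (length(miss) > 0) {
      stop("task object missing field(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    ev <- if (length(obj$events) == 0) {
      data.frame(time = numeric(0), descriptor = character(0))
    } else {
      data.frame(
        time = vapply(obj$events, function(e) as.numeric(e$t), 0),
        descriptor = vapply(obj$events, function(e) as.character(e$descriptor), ""),
        stringsAsFactors = FALSE
      )
    }
    tds_task(obj$task_id, obj$start, obj$stop, ev)
  })
}

write_tasks_json <- function(tasks, path) {
  objs <- lapply(tasks, function(x) {
    list(
      task_id = x$task_id,
      start = x$start_time,
      stop = x$stop_time,
      events = if (nrow(x$events) == 0) list() else
        lapply(seq_len(nrow(x$events)), function(r) {
          list(t = x$events$time[r], descriptor = x$events$descriptor[r])
        })
    )
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
}
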