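#' Open a controller backend
#'
#' A backend is the source of control events. Two backends are registered:
#'
#' \describe{
#'   \item{`virtual`}{Replays a scripted event list deterministically. The
#'     descriptor is `"virtual:<script.csv>"`, where the script has one event
#'     per line, `seq,element_id,raw_value` (integer fields, header optional);
#'     or pass a data frame of events directly. An empty descriptor
#'     (`"virtual:"`) opens a backend that never delivers events.}
#'   \item{`midi`}{A live device, descriptor `"midi:<port-name>"`. Control
#'     change messages (status 0xB0-0xBF) would map 1:1 to events (controller
#'     number = element id, data byte = raw value). No R MIDI binding is
#'     bundled, so opening this backend signals a
#'     `hhtune_backend_unavailable` error; the virtual backend is the
#'     supported, fully tested path and accepts recorded sessions.}
#' }
#'
#' Scripts are validated at load time: raw values outside 0-127 or
#' non-integer fields are rejected before the session starts.
#'
#' @param spec Backend descriptor string, or a data frame with columns
#'   `seq`, `element_id`, `raw_value` (treated as a virtual script).
#' @return A backend handle (class `hh_backend`), to be used with [poll()]
#'   and [close_backend()].
#' @examples
#' b <- open_backend(data.frame(seq = 1, element_id = 7, raw_value = 64))
#' poll(b)
#' @export
open_backend <- function(spec) {
  if (is.data.frame(spec)) return(virtual_backend(spec))
  if (!is.character(spec) || length(spec) != 1)
    stop("backend spec must be a string or an event data frame", call. = FALSE)
  if (startsWith(spec, "virtual:")) {
    path <- sub("^virtual:", "", spec)
    if (path == "") return(virtual_backend(empty_events()))
    if (!file.exists(path))
      stop("virtual backend: script not found: ", path, call. = FALSE)
    return(virtual_backend(read_event_script(path)))
  }
  if (startsWith(spec, "midi:")) {
    stop(structure(class = c("hhtune_backend_unavailable", "error", "condition"),
                   list(message = paste0(
                     "live MIDI backend not available in this build; ",
                     "use \"virtual:<script.csv>\" (see ?open_backend)"),
                     call = NULL)))
  }
  stop("unknown backend '", spec,
       "'; valid backends: \"virtual:<script.csv>\", \"midi:<port>\"",
       call. = FALSE)
}

empty_events <- function() {
  data.frame(seq = integer(0), element_id = integer(0), raw_value = integer(0))
}

#' Read and write virtual-controller event scripts
#'
#' CSV with integer columns `seq,element_id,raw_value`; `seq` must be
#' strictly increasing and raw values must lie in 0-127.
#'
#' @param path CSV path.
#' @param events Data frame of events.
#' @return `read_event_script()`: the validated event data frame.
#' @export
read_event_script <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("seq", first, fixed = TRUE)
  df <- read.csv(path, header = has_header,
                 col.names = c("seq", "element_id", "raw_value"))
  validate_events(df)
}

#' @rdname read_event_script
#' @export
write_event_script <- function(events, path) {
  validate_events(events)
  write.csv(events[c("seq", "element_id", "raw_value")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_events <- function(df) {
  need <- c("seq", "element_id", "raw_value")
  if (!all(need %in% names(df)))
    stop("event script needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  for (col in need) {
    v <- df[[col]]
    if (nrow(df) && (any(!is.finite(v)) || any(v != as.integer(v))))
      stop("event script column '", col, "' must be integer", call. = FALSE)
    df[[col]] <- as.integer(v)
  }
  if (any(df$raw_value < 0 | df$raw_value > 127))
    stop("event script contains raw values outside [0, 127]", call. = FALSE)
  if (nrow(df) > 1 && any(diff(df$seq) <= 0))
    stop("event script 'seq' must be strictly increasing", call. = FALSE)
  df[need]
}

virtual_backend <- function(events) {
  events <- validate_events(events)
  env <- new.env(parent = emptyenv())
  env$pending <- events
  env$open <- TRUE
  env$kind <- "virtual"
  class(env) <- c("hh_backend_virtual", "hh_backend")
  env
}

#' Poll a backend for control events
#'
#' Returns every event accumulated since the previous poll, in arrival order,
#' and clears the backend's queue. By default no coalescing is applied
#' (every raw event is delivered, so per-event simulation reruns see the full
#' trajectory); with `coalesce = TRUE` only the latest value per element
#' survives, which keeps slow simulations responsive.
#'
#' For the virtual backend one poll drains the whole remaining script (the
#' scripted events are all "already accumulated"); [backend_exhausted()]
#' reports when nothing is left.
#'
#' @param backend A handle from [open_backend()].
#' @param coalesce Keep only the latest event per element within this batch.
#' @return Data frame of events (`seq`, `element_id`, `raw_value`), possibly
#'   zero-row.
#' @export
poll <- function(backend, coalesce = FALSE) UseMethod("poll")

#' @export
poll.hh_backend_virtual <- function(backend, coalesce = FALSE) {
  if (!backend$open)
    stop(structure(class = c("hhtune_backend_closed", "error", "condition"),
                   list(message = "backend is closed", call = NULL)))
  ev <- backend$pending
  backend$pending <- empty_events()
  if (coalesce && nrow(ev) > 1) {
    keep <- !duplicated(ev$element_id, fromLast = TRUE)
    ev <- ev[keep, , drop = FALSE]
    rownames(ev) <- NULL
  }
  ev
}

#' @rdname poll
#' @export
backend_exhausted <- function(backend) UseMethod("backend_exhausted")

#' @export
backend_exhausted.hh_backend_virtual <- function(backend) {
  !backend$open || nrow(backend$pending) == 0
}

#' @rdname poll
#' @export
close_backend <- function(backend) UseMethod("close_backend")

#' @export
close_backend.hh_backend_virtual <- function(backend) {
  backend$open <- FALSE
  invisible(backend)
}

#' @export
print.hh_backend <- function(x, ...) {
  cat(sprintf("<hh_backend:%s> %s, %d pending event(s)\n", x$kind,
              if (x$open) "open" else "closed", nrow(x$pending)))
  invisible(x)
}
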