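#' Configure a hands-on tuning session
#'
#' Bundles everything a closed-loop session needs: the device layout, the
#' active parameter bindings (optionally organised in switchable banks), the
#' starting model parameters and stimulus protocol, and the event backend.
#'
#' Validation enforces the session invariants up front: every binding's
#' element must exist in the layout and be a continuous element (buttons
#' cannot carry a parameter), every bound name must be a real tunable
#' parameter, and no element may be bound twice within a bank (meta roles
#' excepted).
#'
#' @param layout A [device_layout()]; default [uc33_layout()].
#' @param bindings List of [parameter_binding()]s; default
#'   [default_bindings()].
#' @param parameters Starting [hh_parameters()].
#' @param protocol Starting [stimulus_protocol()].
#' @param backend Backend descriptor or event data frame (see
#'   [open_backend()]).
#' @param banks Optional named list of additional binding lists; a button
#'   press on an id in `bank_buttons` swaps the active table.
#' @param bank_buttons Named integer vector mapping button element ids to
#'   bank names (the starting table is bank `"default"` = `bindings`).
#' @param spike_threshold Spike detection threshold handed to the simulator,
#'   mV.
#' @return An object of class `session_config`.
#' @export
session_config <- function(layout = uc33_layout(),
                           bindings = default_bindings(),
                           parameters = hh_parameters(),
                           protocol = stimulus_protocol(),
                           backend = "virtual:",
                           banks = list(),
                           bank_buttons = integer(0),
                           spike_threshold = 0) {
  validate_hh_parameters(parameters)
  validate_protocol(protocol)
  stopifnot(inherits(layout, "device_layout"))
  all_banks <- c(list(default = bindings), banks)
  for (bank_name in names(all_banks)) {
    bk <- all_banks[[bank_name]]
    ids <- vapply(bk, function(b) b$element_id, integer(1))
    if (anyDuplicated(ids))
      stop("bank '", bank_name, "': element bound twice: ",
           paste(ids[duplicated(ids)], collapse = ", "), call. = FALSE)
    for (b in bk) {
      stopifnot(inherits(b, "parameter_binding"))
      row <- layout$elements[layout$elements$element_id == b$element_id, ]
      if (nrow(row) == 0)
        stop("bank '", bank_name, "': element ", b$element_id,
             " not in layout '", layout$name, "'", call. = FALSE)
      if (row$kind == "button")
        stop("bank '", bank_name, "': element ", b$element_id,
             " is a button and cannot carry a parameter", call. = FALSE)
    }
  }
  if (length(bank_buttons)) {
    if (is.null(names(bank_buttons)) || !all(names(bank_buttons) %in% names(all_banks)))
      stop("bank_buttons must be a named vector naming configured banks",
           call. = FALSE)
    kinds <- layout$elements$kind[match(bank_buttons, layout$elements$element_id)]
    if (any(is.na(kinds)) || any(kinds != "button"))
      stop("bank_buttons must reference button elements of the layout",
           call. = FALSE)
  }
  structure(list(layout = layout, bindings = bindings,
                 parameters = parameters, protocol = protocol,
                 backend = backend, banks = banks,
                 bank_buttons = bank_buttons,
                 spike_threshold = as.numeric(spike_threshold)),
            class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("<session_config> layout '%s', %d binding(s), %d extra bank(s), backend %s\n",
              x$layout$name, length(x$bindings), length(x$banks),
              if (is.character(x$backend)) x$backend else "<event frame>"))
  invisible(x)
}

# fingerprint of the binding tables, used to reject replay under a
# different configuration
bindings_digest <- function(config) {
  all_banks <- c(list(default = config$bindings), config$banks)
  lapply(all_banks, function(bk) lapply(bk, function(b)
    list(element_id = b$element_id, parameter = b$parameter,
         map_kind = b$map_kind, low = b$low0, high = b$high0,
         meta_low_id = b$meta_low_id, meta_high_id = b$meta_high_id)))
}

empty_records <- function() {
  data.frame(sim_index = integer(0), seq = integer(0), element_id = integer(0),
             raw_value = integer(0), parameter = character(0),
             mapped_value = numeric(0), role = character(0),
             timestamp = character(0), stringsAsFactors = FALSE)
}

snapshot_state <- function(parameters, protocol, bindings, bank) {
  raw <- lapply(bindings, function(b) b$last_raw)
  names(raw) <- vapply(bindings, function(b) as.character(b$element_id), "")
  list(parameters = unclass(parameters), protocol = unclass(protocol),
       raw = raw, bank = bank)
}

# The event-application engine shared by live sessions and replay.
# `events` rows are applied in order against mutable binding state; each
# applied event triggers one simulation.
apply_events <- function(events, state, config, max_sims = Inf,
                         coalesce_batch = FALSE, record_time = TRUE,
                         quiet = FALSE) {
  records <- list()
  for (k in seq_len(nrow(events))) {
    if (state$sim_index >= max_sims) break
    ev <- events[k, ]
    id <- ev$element_id

    # bank switching: a button press (raw 127) swaps the active table
    if (length(config$bank_buttons) && id %in% config$bank_buttons) {
      if (ev$raw_value == 127L) {
        target <- names(config$bank_buttons)[match(id, config$bank_buttons)]
        state$bank <- target
        state$bindings <- state$bank_tables[[target]]
        if (!quiet)
          message(sprintf("event seq %d: switched to binding bank '%s'",
                          ev$seq, target))
      }
      next
    }

    idx <- which(vapply(state$bindings, function(b) b$element_id, integer(1)) == id)
    role <- "primary"
    if (!length(idx)) {
      idx <- which(vapply(state$bindings, function(b) {
        isTRUE(b$meta_low_id == id) || isTRUE(b$meta_high_id == id)
      }, logical(1)))
      role <- "meta"
    }
    if (!length(idx)) {
      if (!quiet)
        message(sprintf("event seq %d: element %d is unbound; skipped",
                        ev$seq, id))
      next
    }
    idx <- idx[1]
    b <- state$bindings[[idx]]

    if (role == "primary") {
      b$last_raw <- check_raw(ev$raw_value)
      value <- map_raw(b$last_raw, b)
    } else {
      b <- apply_meta(b, ev$raw_value)
      if (is.na(b$last_raw))
        b$last_raw <- unmap_raw(get_tunable(state$parameters, state$protocol,
                                            b$parameter), b)
      value <- map_raw(b$last_raw, b)
    }
    state$bindings[[idx]] <- b
    upd <- set_tunable(state$parameters, state$protocol, b$parameter, value)
    state$parameters <- upd$parameters
    state$protocol <- upd$protocol

    state$sim_index <- state$sim_index + 1L
    state$trace <- tryCatch(
      hh_simulate(state$parameters, state$protocol),
      error = function(e) {
        stop("simulation ", state$sim_index, " failed (event seq ", ev$seq,
             ", element ", id, "): ", conditionMessage(e), call. = FALSE)
      })
    records[[length(records) + 1]] <- data.frame(
      sim_index = state$sim_index, seq = ev$seq, element_id = id,
      raw_value = ev$raw_value, parameter = b$parameter,
      mapped_value = value, role = role,
      timestamp = if (record_time) format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")
                  else "",
      stringsAsFactors = FALSE)
  }
  state$records <- rbind(state$records,
                         do.call(rbind, c(list(empty_records()), records)))
  state
}

init_session_state <- function(config) {
  bank_tables <- c(list(default = config$bindings), config$banks)
  # seed every binding's last_raw from the starting parameter value, so the
  # controller and model agree before the first event
  bank_tables <- lapply(bank_tables, function(bk) lapply(bk, function(b) {
    v <- get_tunable(config$parameters, config$protocol, b$parameter)
    b$last_raw <- as.integer(unmap_raw(v, b))
    b
  }))
  state <- new.env(parent = emptyenv())
  state$parameters <- config$parameters
  state$protocol <- config$protocol
  state$bank_tables <- bank_tables
  state$bank <- "default"
  state$bindings <- bank_tables[["default"]]
  state$sim_index <- 0L
  state$records <- empty_records()
  state$trace <- NULL
  state
}

#' Run a closed-loop tuning session
#'
#' The core loop: poll the backend, apply each event through the active
#' bindings (primary elements set their parameter; meta elements reshape the
#' primary's range and re-derive its value; bank buttons swap the binding
#' table; unbound elements are logged and skipped), and re-run the simulation
#' once per applied event — the simulation index counts these reruns. A
#' baseline simulation runs before any event so a current trace always
#' exists.
#'
#' @param config A [session_config()].
#' @param max_sims Stop after this many post-baseline simulations
#'   (default unbounded; a virtual backend also stops on script exhaustion).
#' @param coalesce Per-poll coalescing: only the latest event per element in
#'   each polled batch triggers a simulation (for slow models); default off,
#'   one simulation per event.
#' @param sink Optional function called as `sink(trace, sim_index)` after
#'   every simulation (e.g. a file writer or live plotter).
#' @param quiet Suppress per-event messages.
#' @return An object of class `session_log`: list with `version`,
#'   `initial` and `final` full parameter snapshots, the `records` data
#'   frame (one row per applied event: `sim_index`, `seq`, `element_id`,
#'   `raw_value`, `parameter`, `mapped_value`, `role`, `timestamp`), the
#'   bindings fingerprint, and the final `trace`.
#' @examples
#' ev <- data.frame(seq = 1:2, element_id = c(0, 6), raw_value = c(40, 90))
#' log <- run_session(session_config(backend = ev), quiet = TRUE)
#' log$records[, c("sim_index", "parameter", "mapped_value")]
#' @export
run_session <- function(config, max_sims = Inf, coalesce = FALSE,
                        sink = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "session_config"))
  backend <- if (inherits(config$backend, "hh_backend")) config$backend
             else open_backend(config$backend)
  state <- init_session_state(config)
  initial <- snapshot_state(state$parameters, state$protocol,
                            state$bindings, state$bank)

  state$trace <- hh_simulate(state$parameters, state$protocol)  # baseline
  if (!is.null(sink)) sink(state$trace, 0L)

  repeat {
    ev <- poll(backend, coalesce = coalesce)
    if (nrow(ev)) {
      before <- state$sim_index
      state <- apply_events(ev, state, config, max_sims = max_sims,
                            quiet = quiet)
      if (!is.null(sink) && state$sim_index > before)
        sink(state$trace, state$sim_index)
    }
    if (state$sim_index >= max_sims) break
    if (backend_exhausted(backend)) break
  }
  close_backend(backend)

  structure(list(version = "1",
                 initial = initial,
                 records = state$records,
                 final = snapshot_state(state$parameters, state$protocol,
                                        state$bindings, state$bank),
                 bindings = bindings_digest(config),
                 n_simulations = state$sim_index,
                 trace = state$trace),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %d applied event(s), %d simulation(s) after baseline\n",
              nrow(x$records), x$n_simulations))
  if (nrow(x$records))
    cat("  parameters touched:",
        paste(unique(x$records$parameter), collapse = ", "), "\n")
  invisible(x)
}

#' Replay a recorded session deterministically
#'
#' Rebuilds the session from the log's initial snapshot and re-applies every
#' recorded raw event through the configuration's bindings. Because the
#' model, the mappings and the event order are all deterministic, the final
#' parameter vector matches the log's final snapshot exactly and the final
#' voltage trace is bit-identical to the live session's. A config whose
#' binding tables differ from the ones the log was recorded under is
#' rejected before any simulation runs.
#'
#' @param log A `session_log` from [run_session()] or [read_session_log()].
#' @param config The [session_config()] to replay under (its backend field is
#'   ignored; events come from the log).
#' @return The final `hh_trace`. Attributes: `final_parameters`,
#'   `final_protocol`, `records` (the replayed record table, timestamps
#'   excluded).
#' @export
replay_session <- function(log, config) {
  stopifnot(inherits(log, "session_log"), inherits(config, "session_config"))
  if (!identical(bindings_digest(config), log$bindings))
    stop("replay rejected: config bindings differ from the recorded session",
         call. = FALSE)
  unknown <- setdiff(unique(log$records$parameter), tunable_parameters())
  if (length(unknown))
    stop("replay rejected: log references unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  config$parameters <- do.call(hh_parameters, as.list(log$initial$parameters))
  config$protocol <- do.call(stimulus_protocol, as.list(log$initial$protocol))
  state <- init_session_state(config)
  state$trace <- hh_simulate(state$parameters, state$protocol)

  ev <- log$records[, c("seq", "element_id", "raw_value")]
  state <- apply_events(ev, state, config, record_time = FALSE, quiet = TRUE)

  # tolerance covers the last-ulp wobble of decimal serialisation in logs
  # that went through JSON; live logs replay exactly
  final_par <- unclass(state$parameters)
  if (!isTRUE(all.equal(final_par, log$final$parameters, tolerance = 1e-12)))
    warning("replayed final parameters differ from the recorded snapshot")
  trace <- state$trace
  attr(trace, "final_parameters") <- state$parameters
  attr(trace, "final_protocol") <- state$protocol
  attr(trace, "records") <- state$records
  trace
}

#' Write and read session logs
#'
#' JSON on disk: version field, initial and final snapshots, the record
#' list and the bindings fingerprint. Traces are not stored — [replay_session()]
#' regenerates them exactly.
#'
#' @param log A `session_log`.
#' @param path JSON file path.
#' @return `read_session_log()`: a `session_log` (with `trace = NULL`).
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  out <- list(version = log$version, initial = log$initial,
              records = log$records, final = log$final,
              bindings = log$bindings, n_simulations = log$n_simulations)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  if (!file.exists(path))
    stop("session log not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(raw$version))
    stop("not a session log (missing version field): ", path, call. = FALSE)
  records <- if (length(raw$records)) {
    r <- do.call(rbind, lapply(raw$records, function(row)
      data.frame(sim_index = as.integer(row$sim_index),
                 seq = as.integer(row$seq),
                 element_id = as.integer(row$element_id),
                 raw_value = as.integer(row$raw_value),
                 parameter = as.character(row$parameter),
                 mapped_value = as.numeric(row$mapped_value),
                 role = as.character(row$role),
                 timestamp = as.character(row$timestamp %||% ""),
                 stringsAsFactors = FALSE)))
    rownames(r) <- NULL
    r
  } else empty_records()
  fix_snapshot <- function(s) {
    list(parameters = lapply(s$parameters, as.numeric),
         protocol = lapply(s$protocol, as.numeric),
         raw = lapply(s$raw, function(x)
           if (is.null(x)) NA_integer_ else as.integer(x)),
         bank = as.character(s$bank))
  }
  # JSON round-trips drop NA meta ids to null and narrow doubles to
  # integers; restore the canonical types so digests compare identical()
  fix_bank <- function(bk) lapply(bk, function(b) {
    list(element_id = as.integer(b$element_id),
         parameter = as.character(b$parameter),
         map_kind = as.character(b$map_kind),
         low = as.numeric(b$low), high = as.numeric(b$high),
         meta_low_id = if (is.null(b$meta_low_id)) NA_integer_
                       else as.integer(b$meta_low_id),
         meta_high_id = if (is.null(b$meta_high_id)) NA_integer_
                        else as.integer(b$meta_high_id))
  })
  structure(list(version = as.character(raw$version),
                 initial = fix_snapshot(raw$initial),
                 records = records,
                 final = fix_snapshot(raw$final),
                 bindings = lapply(raw$bindings, fix_bank),
                 n_simulations = as.integer(raw$n_simulations),
                 trace = NULL),
            class = "session_log")
}
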