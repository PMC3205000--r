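#' Generate a random scripted session (test fixture)
#'
#' Produces a deterministic pseudo-random event script over the bound
#' continuous elements of a binding table: element ids drawn uniformly from
#' the bound primaries, raw values uniform on 0-127, `seq` 1..n. The same
#' arguments always yield a byte-identical file; the caller's RNG state is
#' left untouched.
#'
#' @param seed Integer seed.
#' @param n_events Number of events (>= 0).
#' @param layout A [device_layout()] (elements are checked against it).
#' @param bindings Binding table whose primary element ids are sampled.
#' @param path Optional CSV output path; omit to get the data frame only.
#' @param include_meta Also sample the bindings' meta element ids.
#' @return The event data frame (invisibly, if `path` is given).
#' @export
make_fixture <- function(seed, n_events, layout = uc33_layout(),
                         bindings = default_bindings(), path = NULL,
                         include_meta = FALSE) {
  if (!is.numeric(n_events) || length(n_events) != 1 || n_events < 0 ||
      n_events != as.integer(n_events))
    stop("n_events must be a non-negative integer", call. = FALSE)
  n_events <- as.integer(n_events)
  ids <- vapply(bindings, function(b) b$element_id, integer(1))
  if (include_meta) {
    meta <- unlist(lapply(bindings, function(b)
      c(b$meta_low_id, b$meta_high_id)))
    ids <- unique(c(ids, meta[!is.na(meta)]))
  }
  if (!all(ids %in% layout$elements$element_id))
    stop("bindings reference elements outside the layout", call. = FALSE)

  events <- with_local_seed(seed, {
    if (n_events == 0) empty_events()
    else data.frame(seq = seq_len(n_events),
                    element_id = sample(ids, n_events, replace = TRUE),
                    raw_value = sample(0:127, n_events, replace = TRUE))
  })
  events <- validate_events(events)
  if (!is.null(path)) {
    write_event_script(events, path)
    return(invisible(events))
  }
  events
}

# run `expr` under set.seed(seed) and restore the caller's RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
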