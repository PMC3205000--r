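#' Control elements and device layouts
#'
#' A `control_element` is one physical knob, slider or button on a control
#' surface, identified by an integer `element_id` (the controller number a
#' control-change message carries). A `device_layout` is the set of elements a
#' device exposes; element ids must be unique within a layout.
#'
#' @param element_id Integer identifier, unique within a layout.
#' @param kind One of `"knob"`, `"slider"`, `"button"`.
#' @param label Display label.
#' @return `control_element()`: a one-row data frame; `device_layout()`: an
#'   object of class `device_layout`.
#' @export
control_element <- function(element_id, kind = c("knob", "slider", "button"),
                            label = NULL) {
  kind <- match.arg(kind)
  element_id <- as.integer(element_id)
  if (is.na(element_id) || element_id < 0)
    stop("element_id must be a non-negative integer", call. = FALSE)
  if (is.null(label)) label <- sprintf("%s %d", kind, element_id)
  data.frame(element_id = element_id, kind = kind, label = label,
             stringsAsFactors = FALSE)
}

#' @rdname control_element
#' @param name Layout name.
#' @param elements A data frame of elements, e.g. built by `rbind()`-ing
#'   [control_element()] rows.
#' @export
device_layout <- function(name, elements) {
  stopifnot(is.data.frame(elements),
            all(c("element_id", "kind", "label") %in% names(elements)))
  if (anyDuplicated(elements$element_id))
    stop("element_id values must be unique within a layout", call. = FALSE)
  if (!all(elements$kind %in% c("knob", "slider", "button")))
    stop("element kind must be knob, slider or button", call. = FALSE)
  structure(list(name = name, elements = elements), class = "device_layout")
}

#' @export
print.device_layout <- function(x, ...) {
  k <- table(factor(x$elements$kind, c("knob", "slider", "button")))
  cat(sprintf("<device_layout> '%s': %d knobs, %d sliders, %d buttons\n",
              x$name, k[["knob"]], k[["slider"]], k[["button"]]))
  invisible(x)
}

#' Emulated layout of a 33-continuous-element, 14-button control surface
#'
#' The bundled default layout mirrors a common compact MIDI control surface
#' (24 rotary knobs plus 9 sliders -- 33 continuous elements -- and 14
#' buttons). Continuous elements take ids 0-32 (knobs 0-23, sliders 24-32)
#' and buttons ids 33-46; the id assignment is this package's convention.
#'
#' @return A [device_layout()].
#' @examples
#' uc33_layout()
#' @export
uc33_layout <- function() {
  knobs <- do.call(rbind, lapply(0:23, function(i)
    control_element(i, "knob", sprintf("knob %d", i + 1))))
  sliders <- do.call(rbind, lapply(24:32, function(i)
    control_element(i, "slider", sprintf("slider %d", i - 23))))
  buttons <- do.call(rbind, lapply(33:46, function(i)
    control_element(i, "button", sprintf("button %d", i - 32))))
  device_layout("UC-33 emulation", rbind(knobs, sliders, buttons))
}
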