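#' Define a stimulus object
#'
#' A named display/sound object holding everything the presenter needs to
#' draw it: kind, asset paths, position and size in degrees, background
#' color. Objects are called by command token via the registry's alias
#' table.
#'
#' @param name object name (valid token word).
#' @param kind one of `"DOT"`, `"IMAGE"`, `"SOUND"`, `"IMAGE_SOUND"`,
#'   `"BLACK"`.
#' @param image,sound asset paths (IMAGE_SOUND requires both; checked
#'   against disk at registration when `check_assets = TRUE` there).
#' @param pos `c(x, y)` position in degrees.
#' @param size `c(w, h)` in degrees; DOT must have positive size.
#' @param background background color.
#' @param sound_dur_s,sound_level_db sound metadata: default 1 s tone-burst
#'   duration at a nominal 80 dB SPL level (metadata only; the simulation
#'   has no acoustics).
#' @return object of class `stimulus_object`.
#' @export
stimulus_object <- function(name,
                            kind = c("DOT", "IMAGE", "SOUND", "IMAGE_SOUND",
                                     "BLACK"),
                            image = NULL, sound = NULL,
                            pos = c(0, 0), size = c(0.5, 0.5),
                            background = "black",
                            sound_dur_s = 1, sound_level_db = 80) {
  kind <- match.arg(kind)
  check_token_word(name)
  if (kind == "IMAGE_SOUND" && (is.null(image) || is.null(sound)))
    stop("IMAGE_SOUND objects need both an image and a sound asset")
  if (kind == "IMAGE" && is.null(image)) stop("IMAGE objects need an image")
  if (kind == "SOUND" && is.null(sound)) stop("SOUND objects need a sound")
  if (kind == "DOT" && any(size <= 0)) stop("DOT size must be > 0")
  structure(list(name = name, kind = kind, image = image, sound = sound,
                 pos = pos, size = size, background = background,
                 sound_dur_s = sound_dur_s, sound_level_db = sound_level_db),
            class = "stimulus_object")
}

#' Create a presenter endpoint
#'
#' The stimulus endpoint of the rig: it predefines all the objects that may
#' be called during the experiment, listens for command tokens, draws the
#' named object at the next frame boundary, replies on the serial path and
#' emits a 1 ms TTL on the parallel sideband at stimulus onset. The alias
#' table maps token words to object names (for example the 7-character word
#' `"grendot"` to the object `'greendot'`), so the word on the wire need not
#' equal the object name.
#'
#' @param geom a [display_geometry()]; its refresh rate sets the frame
#'   quantization.
#' @param audio_latency_ms fixed audio latency added to sound onsets
#'   (default 0: sound is not frame-quantized).
#' @return a `presenter` environment.
#' @export
presenter_create <- function(geom, audio_latency_ms = 0) {
  stopifnot(inherits(geom, "display_geometry"))
  p <- new.env(parent = emptyenv())
  p$geom <- geom
  p$objects <- list()
  p$alias <- character(0)          # token word -> object name
  p$events <- list()               # presentation events
  p$current <- NULL                # name of object on screen
  p$audio_latency_ms <- audio_latency_ms
  class(p) <- "presenter"
  p
}

#' Register a stimulus object with the presenter
#'
#' @param p a [presenter_create()] endpoint.
#' @param obj a [stimulus_object()].
#' @param token token word that calls this object (defaults to the object
#'   name); recorded in the alias table.
#' @param check_assets verify that referenced asset files exist.
#' @return the presenter, invisibly.
#' @export
register_object <- function(p, obj, token = obj$name, check_assets = FALSE) {
  stopifnot(inherits(p, "presenter"), inherits(obj, "stimulus_object"))
  if (!is.null(p$objects[[obj$name]]))
    stop(sprintf("registration error: object '%s' already registered",
                 obj$name))
  if (check_assets) {
    for (a in c(obj$image, obj$sound))
      if (!is.null(a) && !file.exists(a))
        stop(sprintf("asset error: missing asset file '%s'", a))
  }
  check_token_word(token)
  p$objects[[obj$name]] <- obj
  p$alias[token] <- obj$name
  invisible(p)
}

#' Quantize a requested onset time to the next frame boundary
#'
#' Stimulus changes take effect at vertical refresh: the onset is the
#' smallest frame-boundary time at or after the request, with boundaries at
#' multiples of `1e6 / refresh_hz` microseconds from session start. At
#' 60 Hz the worst-case delay is one frame, i.e. an inherent error of 16 ms
#' (truncated frame period) in visual stimulus onset.
#'
#' @param geom a [display_geometry()].
#' @param t_request_us requested time (microseconds).
#' @return onset time in microseconds (frame boundary, `>= t_request_us`).
#' @export
frame_quantize <- function(geom, t_request_us) {
  stopifnot(inherits(geom, "display_geometry"))
  period <- 1e6 / geom$refresh_hz
  ceiling(t_request_us / period) * period
}

#' Worst-case stimulus-onset error of a display
#'
#' The largest possible delay between a presentation request and the next
#' vertical refresh, truncated to whole milliseconds: 16 ms for a 60 Hz
#' display.
#'
#' @param geom a [display_geometry()].
#' @return whole milliseconds (numeric).
#' @export
worst_case_onset_error_ms <- function(geom) {
  stopifnot(inherits(geom, "display_geometry"))
  floor((1e6 / geom$refresh_hz) / 1000)
}

#' Handle one command token
#'
#' The presenter's experimental loop body: decode the word, look up the
#' object through the alias table, update the display at the next frame
#' boundary, reply on the serial path and emit a 1 ms TTL on
#' `parallel.bit8` at stimulus onset. Unknown words are refused: no display
#' change, no reply, no TTL.
#'
#' For IMAGE_SOUND objects the sound starts at the request time plus the
#' configured audio latency -- audio is not frame-quantized -- while the
#' image waits for the frame boundary; [audit_av_sync()] measures the
#' resulting offsets.
#'
#' @param p a [presenter_create()] endpoint.
#' @param word command token word.
#' @param t_request_us request time (microseconds).
#' @param bus optional [bus_create()] to emit the TTL on.
#' @return a `presentation_event`: `t_request_us`, `t_onset_us`, `object`,
#'   `reply`, `ttl`, `sound_onset_us` (NA unless the object has sound).
#' @export
handle_token <- function(p, word, t_request_us, bus = NULL) {
  stopifnot(inherits(p, "presenter"))
  name <- unname(p$alias[word])
  if (is.na(name))
    stop(sprintf("protocol error: unknown token word '%s'", word))
  obj <- p$objects[[name]]
  t_onset <- frame_quantize(p$geom, t_request_us)
  sound_onset <- if (obj$kind %in% c("SOUND", "IMAGE_SOUND"))
    t_request_us + p$audio_latency_ms * 1000 else NA_real_
  ttl <- list(t_us = t_onset, line = "parallel.bit8", duration_ms = 1)
  if (!is.null(bus)) emit_ttl(bus, "parallel.bit8", t_onset, 1)
  ev <- structure(list(t_request_us = t_request_us, t_onset_us = t_onset,
                       object = name, reply = paste0("ack:", word),
                       ttl = ttl, sound_onset_us = sound_onset,
                       kind = obj$kind),
                  class = "presentation_event")
  p$current <- name
  p$events[[length(p$events) + 1L]] <- ev
  ev
}

#' Presentation events as a data frame
#'
#' @param p a [presenter_create()] endpoint.
#' @return data.frame with one row per handled token.
#' @export
presentation_log <- function(p) {
  stopifnot(inherits(p, "presenter"))
  if (!length(p$events))
    return(data.frame(t_request_us = numeric(0), t_onset_us = numeric(0),
                      object = character(0), kind = character(0),
                      sound_onset_us = numeric(0)))
  do.call(rbind, lapply(p$events, function(e)
    data.frame(t_request_us = e$t_request_us, t_onset_us = e$t_onset_us,
               object = e$object, kind = e$kind,
               sound_onset_us = e$sound_onset_us)))
}

#' Audit audio-visual synchrony
#'
#' For every event with both image and sound, the offset between the
#' (frame-quantized) image onset and the (unquantized) sound onset. Bounded
#' by one frame period minus the audio latency.
#'
#' @param events data.frame from [presentation_log()] (or a presenter).
#' @return data.frame with `t_request_us` and `offset_us`
#'   (`image onset - sound onset`).
#' @export
audit_av_sync <- function(events) {
  if (inherits(events, "presenter")) events <- presentation_log(events)
  av <- events[events$kind == "IMAGE_SOUND", , drop = FALSE]
  data.frame(t_request_us = av$t_request_us,
             offset_us = av$t_onset_us - av$sound_onset_us)
}

#' Build the standard object registry for the association tasks
#'
#' Registers the black screen, the green fixation dot (called by the token
#' word `"grendot"`), the image+sound test stimulus (`"SndPICn"`) and an
#' image-only distracter.
#'
#' @param p a [presenter_create()] endpoint.
#' @param image,sound asset paths for the test stimulus (optional in
#'   simulation).
#' @param target_pos test-stimulus position `c(x, y)` degrees.
#' @param image_size_deg test-image size `c(w, h)` degrees; this size also
#'   defines the test-phase forgiveness window.
#' @return the presenter, invisibly.
#' @export
register_default_objects <- function(p, image = NULL, sound = NULL,
                                     target_pos = c(0, 0),
                                     image_size_deg = c(4, 4)) {
  register_object(p, stimulus_object("blackscreen", "BLACK"),
                  token = "blank")
  register_object(p, stimulus_object("greendot", "DOT", pos = c(0, 0),
                                     size = c(0.5, 0.5)),
                  token = "grendot")
  register_object(p, stimulus_object("soundpic", "IMAGE_SOUND",
                                     image = if (is.null(image)) "img.png"
                                             else image,
                                     sound = if (is.null(sound)) "snd.wav"
                                             else sound,
                                     pos = target_pos,
                                     size = image_size_deg),
                  token = "SndPICn")
  register_object(p, stimulus_object("distracterpic", "IMAGE",
                                     image = "distracter.png",
                                     pos = -target_pos,
                                     size = image_size_deg),
                  token = "distracter")
  invisible(p)
}
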