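#' Encode a command token
#'
#' Commands between the control script and the presenter travel as short
#' ASCII words with a single terminator character, e.g. `"grendot\n"`. The
#' word must be nonempty printable ASCII without the terminator embedded;
#' a defensive maximum length of 32 characters is enforced.
#'
#' @param word token word (character scalar).
#' @param terminator single terminator character, default `"\n"`.
#' @return raw vector: word bytes followed by the terminator byte.
#' @seealso [decode_token()]
#' @export
encode_token <- function(word, terminator = "\n") {
  check_token_word(word, terminator)
  c(charToRaw(word), charToRaw(terminator))
}

#' Decode a command token
#'
#' Exact inverse of [encode_token()]: strips the trailing terminator and
#' returns the word.
#'
#' @param bytes raw vector as produced by [encode_token()].
#' @param terminator expected terminator character.
#' @return the token word (character scalar).
#' @export
decode_token <- function(bytes, terminator = "\n") {
  if (!is.raw(bytes) || length(bytes) < 2)
    stop("token must be at least one word byte plus terminator")
  if (bytes[length(bytes)] != charToRaw(terminator))
    stop("token does not end with the expected terminator")
  word <- rawToChar(bytes[-length(bytes)])
  check_token_word(word, terminator)
  word
}

check_token_word <- function(word, terminator = "\n") {
  if (!is.character(word) || length(word) != 1 || is.na(word) || !nzchar(word))
    stop("token word must be a nonempty character scalar")
  if (nchar(word) > 32) stop("token word exceeds the 32-character limit")
  if (grepl(terminator, word, fixed = TRUE))
    stop("token word must not contain the terminator character")
  if (!all(utf8ToInt(word) >= 32L & utf8ToInt(word) <= 126L))
    stop("token word must be printable ASCII")
  invisible(word)
}

#' Create a message bus
#'
#' The bus replicates the rig's two message fabrics in one deterministic,
#' in-memory object: the serial word+terminator channel (command/reply
#' tokens) and the parallel TTL sideband (1 ms logic pulses used as event
#' timestamps). Endpoints register token handlers; [send_command()] runs the
#' lockstep handshake; every exchange is appended to an ordered log.
#'
#' @return a `bus` object (an environment; mutable by design, like a device).
#' @export
bus_create <- function() {
  b <- new.env(parent = emptyenv())
  b$log <- list()                     # ordered records
  b$handlers <- list()                # endpoint -> list(word -> function)
  b$pending <- character(0)           # endpoints with an outstanding command
  b$line_end <- numeric(0)            # line id -> end time of last pulse (us)
  class(b) <- "bus"
  b
}

bus_append <- function(bus, rec) {
  n <- length(bus$log)
  if (n > 0 && rec$t_us < bus$log[[n]]$t_us)
    stop("bus log timestamps must be nondecreasing")
  bus$log[[n + 1L]] <- rec
  invisible(bus)
}

#' Register a token handler on a bus endpoint
#'
#' @param bus a [bus_create()] object.
#' @param endpoint endpoint name (e.g. `"presenter"`).
#' @param word token word the handler answers.
#' @param fn `function(word, t_us)` returning the reply word (character) to
#'   send back; called when the token arrives.
#' @export
bus_register_handler <- function(bus, endpoint, word, fn) {
  stopifnot(inherits(bus, "bus"), is.function(fn))
  check_token_word(word)
  if (is.null(bus$handlers[[endpoint]])) bus$handlers[[endpoint]] <- list()
  bus$handlers[[endpoint]][[word]] <- fn
  invisible(bus)
}

#' Send a command token and wait (logically) for its reply
#'
#' The lockstep handshake: one endpoint sends a word, the receiving
#' endpoint's handler runs, and a reply naming the command comes back before
#' anything else happens. Overlapping outstanding commands from one endpoint
#' are a protocol error, as is a word the receiver has no handler for.
#' Reply words echo the command prefixed `"ack:"`.
#'
#' @param bus a [bus_create()] object.
#' @param from,to endpoint names.
#' @param word command token word.
#' @param t_us send time on the session clock (microseconds).
#' @return the reply token word (invisibly also logged).
#' @export
send_command <- function(bus, from, to, word, t_us) {
  stopifnot(inherits(bus, "bus"))
  check_token_word(word)
  if (from %in% bus$pending)
    stop(sprintf("protocol error: endpoint '%s' already awaits a reply", from))
  h <- bus$handlers[[to]][[word]]
  if (is.null(h))
    stop(sprintf("protocol error: endpoint '%s' has no handler for word '%s'",
                 to, word))
  bus$pending <- c(bus$pending, from)
  bus_append(bus, list(t_us = t_us, endpoint = from, dir = "tx",
                       kind = "token", payload = word))
  reply <- h(word, t_us)
  if (!is.character(reply) || length(reply) != 1)
    stop("handler must return a reply word")
  # reply time: handlers may advance the clock via attribute "t_us"
  t_reply <- attr(reply, "t_us")
  if (is.null(t_reply)) t_reply <- t_us
  bus$pending <- setdiff(bus$pending, from)
  bus_append(bus, list(t_us = t_reply, endpoint = from, dir = "rx",
                       kind = "token", payload = as.character(reply)))
  as.character(reply)
}

#' Emit a TTL pulse on a logic line
#'
#' A low-high-low logic pulse (default width 1 ms) whose rising edge is the
#' event timestamp seen by the analysis side. Pulses on one line must not
#' overlap.
#'
#' @param bus a [bus_create()] object.
#' @param line logical line id, e.g. `"parallel.bit8"`, `"reward.dio0"`.
#' @param t_us rising-edge time (microseconds).
#' @param duration_ms pulse width in ms, default 1.
#' @return the pulse record `list(t_us, line, duration_ms)` invisibly.
#' @export
emit_ttl <- function(bus, line, t_us, duration_ms = 1) {
  stopifnot(inherits(bus, "bus"))
  if (duration_ms <= 0) stop("TTL duration must be > 0 ms")
  prev_end <- bus$line_end[line]
  if (!is.na(prev_end) && length(prev_end) && t_us < prev_end)
    stop(sprintf("overlapping TTL pulse on line '%s'", line))
  bus$line_end[line] <- t_us + duration_ms * 1000
  pulse <- list(t_us = t_us, line = line, duration_ms = duration_ms)
  bus_append(bus, list(t_us = t_us, endpoint = line, dir = "tx",
                       kind = "ttl", payload = duration_ms))
  invisible(pulse)
}

#' Bus log as a data frame
#'
#' @param bus a [bus_create()] object.
#' @return data.frame with columns t_us, endpoint, dir, kind, payload.
#' @export
bus_log <- function(bus) {
  stopifnot(inherits(bus, "bus"))
  if (!length(bus$log))
    return(data.frame(t_us = numeric(0), endpoint = character(0),
                      dir = character(0), kind = character(0),
                      payload = character(0)))
  do.call(rbind, lapply(bus$log, function(r)
    data.frame(t_us = r$t_us, endpoint = r$endpoint, dir = r$dir,
               kind = r$kind, payload = as.character(r$payload))))
}

#' Write a bus log to JSON-lines
#'
#' One record per line: `{"t_us":..., "endpoint":..., "dir":"tx|rx",
#' "kind":"token|ttl", "payload":...}`.
#'
#' @param bus a [bus_create()] object.
#' @param path output file path.
#' @export
write_buslog_jsonl <- function(bus, path) {
  lines <- vapply(bus$log, function(r)
    jsonlite::toJSON(r, auto_unbox = TRUE), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines bus log
#'
#' @param path file written by [write_buslog_jsonl()].
#' @return data.frame as from [bus_log()].
#' @export
read_buslog_jsonl <- function(path) {
  recs <- lapply(readLines(path), jsonlite::fromJSON)
  do.call(rbind, lapply(recs, function(r)
    data.frame(t_us = r$t_us, endpoint = r$endpoint, dir = r$dir,
               kind = r$kind, payload = as.character(r$payload))))
}

#' Replay-check the lockstep invariant on a bus log
#'
#' Verifies, by replaying the ordered log, that every transmitted command
#' token is answered by exactly one reply before the same endpoint transmits
#' again (one-command-one-reply alternation), and -- when
#' `require_ttl = TRUE` -- that each command/reply pair is accompanied by
#' exactly one TTL pulse on `ttl_line` whose rising edge is at or after the
#' command time (the triple-synchronization property: command token, reply
#' token, timestamp pulse per stimulus change).
#'
#' @param log data.frame from [bus_log()] or [read_buslog_jsonl()].
#' @param require_ttl also check one TTL per exchange on `ttl_line`.
#' @param ttl_line line carrying stimulus-onset pulses.
#' @return list with `ok` (logical) and `violations` (character vector).
#' @export
check_lockstep <- function(log, require_ttl = FALSE,
                           ttl_line = "parallel.bit8") {
  violations <- character(0)
  tok <- log[log$kind == "token", , drop = FALSE]
  for (ep in unique(tok$endpoint)) {
    d <- tok$dir[tok$endpoint == ep]
    # must alternate tx, rx, tx, rx, ... starting with tx
    expect <- rep(c("tx", "rx"), length.out = length(d))
    if (length(d) %% 2 != 0 || !all(d == expect))
      violations <- c(violations, sprintf(
        "endpoint '%s': command/reply alternation broken", ep))
  }
  if (require_ttl) {
    n_cmd <- sum(tok$dir == "tx")
    ttl <- log[log$kind == "ttl" & log$endpoint == ttl_line, , drop = FALSE]
    if (nrow(ttl) != n_cmd)
      violations <- c(violations, sprintf(
        "%d commands but %d TTL pulses on %s", n_cmd, nrow(ttl), ttl_line))
    cmd_t <- tok$t_us[tok$dir == "tx"]
    if (nrow(ttl) == n_cmd && any(ttl$t_us < cmd_t))
      violations <- c(violations,
                      "TTL rising edge precedes its command time")
  }
  list(ok = length(violations) == 0, violations = violations)
}
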