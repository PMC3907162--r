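#' Specify a behavioral task
#'
#' The four association-family task variants plus a single configurable
#' calibration walk:
#' \describe{
#'   \item{ASSOCIATION}{a sound is played and the associated target image is
#'     simultaneously presented at the center of the screen.}
#'   \item{LEFT_RIGHT}{the target image appears at `offset_deg` either left
#'     or right, the side drawn uniformly at run time.}
#'   \item{SINGLE_DISTRACTER}{a central green dot, then target and one
#'     distracter image on opposite sides, sides drawn at run time.}
#'   \item{MULTI_DISTRACTER}{target plus distracters at positions kept
#'     deliberately fixed across trials.}
#'   \item{CALIBRATION_WALK}{the fixation dot steps through a fixed sequence
#'     of positions for eye-signal calibration.}
#' }
#'
#' @param kind one of the task kinds above.
#' @param pairs list of `c(sound, image)` asset pairs (nonempty for the
#'   association-family tasks).
#' @param offset_deg horizontal eccentricity (degrees) for lateral targets.
#' @param distracter_positions list of `c(x, y)` degree positions; required
#'   for MULTI_DISTRACTER, and the walk waypoints for CALIBRATION_WALK.
#' @param timing_ms named list with `t_acquire`, `t_initial_fix`,
#'   `t_reward_fix` in milliseconds (the three dialog-box timing criteria).
#' @return object of class `task_spec`.
#' @export
task_spec <- function(kind = c("ASSOCIATION", "LEFT_RIGHT",
                               "SINGLE_DISTRACTER", "MULTI_DISTRACTER",
                               "CALIBRATION_WALK"),
                      pairs = list(c("call1.wav", "img1.png")),
                      offset_deg = 8,
                      distracter_positions = NULL,
                      timing_ms = list(t_acquire = 500, t_initial_fix = 300,
                                       t_reward_fix = 500)) {
  kind <- match.arg(kind)
  assoc_family <- kind %in% c("ASSOCIATION", "LEFT_RIGHT",
                              "SINGLE_DISTRACTER", "MULTI_DISTRACTER")
  if (assoc_family && length(pairs) == 0)
    stop("association-family tasks need at least one sound/image pair")
  if (kind == "MULTI_DISTRACTER" && length(distracter_positions) == 0)
    stop("config error: MULTI_DISTRACTER requires fixed distracter positions")
  structure(list(kind = kind, pairs = pairs, offset_deg = offset_deg,
                 distracter_positions = distracter_positions,
                 timing_ms = timing_ms),
            class = "task_spec")
}

#' Plan one trial of a task
#'
#' Resolves the run-time randomization for one trial: which sound/image pair
#' is used, on which side or at which fixed positions the stimuli appear.
#' All draws consume the supplied session RNG, so a seeded session replans
#' identically. Draw order: pair first, then side, then distracter identity.
#'
#' @param task a [task_spec()].
#' @param rng ignored placeholder for explicitness; draws use R's global
#'   RNG stream (seed the session with `set.seed()`).
#' @return object of class `trial_plan`: `fixation_token`, `test_token`,
#'   `target_pos` (degrees), `distracters` (list of
#'   `list(token, pos)`), `side` (LEFT/RIGHT/CENTER), `pair`, `timing_ms`.
#' @export
plan_trial <- function(task, rng = NULL) {
  stopifnot(inherits(task, "task_spec"))
  k <- task$kind
  pair <- task$pairs[[if (length(task$pairs) > 1)
    sample.int(length(task$pairs), 1) else 1L]]
  plan <- list(fixation_token = "grendot", test_token = "SndPICn",
               pair = pair, distracters = list(), timing_ms = task$timing_ms)
  if (k == "ASSOCIATION") {
    plan$target_pos <- c(0, 0); plan$side <- "CENTER"
  } else if (k == "LEFT_RIGHT") {
    side <- if (stats::runif(1) < 0.5) "LEFT" else "RIGHT"
    plan$target_pos <- c(if (side == "LEFT") -task$offset_deg
                         else task$offset_deg, 0)
    plan$side <- side
  } else if (k == "SINGLE_DISTRACTER") {
    side <- if (stats::runif(1) < 0.5) "LEFT" else "RIGHT"
    sgn <- if (side == "LEFT") -1 else 1
    plan$target_pos <- c(sgn * task$offset_deg, 0)
    plan$side <- side
    others <- setdiff(vapply(task$pairs, `[`, "", 2), pair[2])
    dtok <- if (length(others))
      others[sample.int(length(others), 1)] else "distracter"
    plan$distracters <- list(list(token = dtok,
                                  pos = c(-sgn * task$offset_deg, 0)))
  } else if (k == "MULTI_DISTRACTER") {
    plan$target_pos <- c(0, 0); plan$side <- "CENTER"
    plan$distracters <- lapply(task$distracter_positions, function(p)
      list(token = "distracter", pos = as.numeric(p)))
  } else {                       # CALIBRATION_WALK
    pos <- task$distracter_positions
    if (is.null(pos)) pos <- list(c(0, 0), c(-8, 0), c(8, 0), c(0, -8),
                                  c(0, 8))
    plan$target_pos <- as.numeric(pos[[1]])
    plan$walk <- pos
    plan$side <- "CENTER"
  }
  structure(plan, class = "trial_plan")
}

#' The six-case do-case dispatch table
#'
#' Maps (trial phase, fixation state) to the next presentation command, as
#' the control script's looping do-case: three fixation-failure situations
#' and three success situations.
#' \itemize{
#'   \item F1 -- (PRE, FAILURE): black screen, no target to fixate; present
#'     the fixation target.
#'   \item F2 -- (FIX, FAILURE): failure during fixation; present the black
#'     screen.
#'   \item F3 -- (TEST, FAILURE): failure during the test stimulus; present
#'     the black screen.
#'   \item S1 -- (PRE, SUCCESS): gaze already at the target location with no
#'     target present; present the fixation target, exactly as F1.
#'   \item S2 -- (FIX, SUCCESS): present the test stimulus.
#'   \item S3 -- (TEST, SUCCESS): reset to the black screen for the refresh
#'     period.
#' }
#'
#' @param phase one of `"PRE"`, `"FIX"`, `"TEST"`.
#' @param state `"SUCCESS"` or `"FAILURE"`.
#' @param fixation_token,test_token,blank_token token words to issue.
#' @return the command token word (character scalar) with attribute `"case"`
#'   naming the do-case branch (`"F1"` ... `"S3"`).
#' @export
dispatch <- function(phase, state, fixation_token = "grendot",
                     test_token = "SndPICn", blank_token = "blank") {
  key <- paste(phase, state, sep = ":")
  out <- switch(key,
    "PRE:FAILURE"  = structure(fixation_token, case = "F1"),
    "FIX:FAILURE"  = structure(blank_token,    case = "F2"),
    "TEST:FAILURE" = structure(blank_token,    case = "F3"),
    "PRE:SUCCESS"  = structure(fixation_token, case = "S1"),
    "FIX:SUCCESS"  = structure(test_token,     case = "S2"),
    "TEST:SUCCESS" = structure(blank_token,    case = "S3"),
    stop(sprintf("logic error: undefined dispatch case (%s, %s)",
                 phase, state)))
  out
}

#' Enumerate the dispatch table
#'
#' @return data.frame of all defined (phase, state) cases with their
#'   do-case labels and command tokens.
#' @export
dispatch_table <- function() {
  grid <- expand.grid(phase = c("PRE", "FIX", "TEST"),
                      state = c("FAILURE", "SUCCESS"),
                      stringsAsFactors = FALSE)
  grid$case <- NA_character_
  grid$token <- NA_character_
  for (i in seq_len(nrow(grid))) {
    tok <- dispatch(grid$phase[i], grid$state[i])
    grid$case[i] <- attr(tok, "case")
    grid$token[i] <- as.character(tok)
  }
  grid[order(grid$case), ]
}

#' Open a recording session
#'
#' Session state holds the current scenario, the open per-trial data file
#' and the trial counter. At most one data file is open at a time; the
#' counter is monotone within a file.
#'
#' @param subject subject name.
#' @param scenario initial scenario name.
#' @param out_dir directory for data files.
#' @param params named list of session parameters (window size in degrees,
#'   reward duration in ms, ...), stored for the record.
#' @return a `session_state` environment.
#' @export
session_open <- function(subject, scenario, out_dir = tempdir(),
                         params = list()) {
  s <- new.env(parent = emptyenv())
  s$subject <- subject
  s$scenario <- scenario
  s$out_dir <- out_dir
  s$params <- params
  s$trial_counter <- 0L
  s$files <- character(0)
  s$con <- NULL
  class(s) <- "session_state"
  session_new_file(s)
  s
}

session_new_file <- function(s) {
  stamp <- format(Sys.time(), "%Y%m%dT%H%M%S")
  path <- file.path(s$out_dir, sprintf("%s_%s_%s_%03d.csv", s$subject,
                                       s$scenario, stamp,
                                       length(s$files) + 1L))
  con <- file(path, open = "wt")
  writeLines("trial_id,outcome,t_acquire_event,t_fail,reward_t", con)
  flush(con)
  s$con <- con
  s$data_file <- path
  s$files <- c(s$files, path)
  invisible(s)
}

#' Record one trial into the session data file
#'
#' @param s a `session_state` from [session_open()].
#' @param result a `trial_result`.
#' @return the trial id assigned, invisibly.
#' @export
session_record_trial <- function(s, result) {
  stopifnot(inherits(s, "session_state"))
  if (is.null(s$con)) stop("session has no open data file")
  s$trial_counter <- s$trial_counter + 1L
  row <- trial_result_row(result, s$trial_counter)
  writeLines(paste(row$trial_id, row$outcome, row$t_acquire_event,
                   row$t_fail, row$reward_t, sep = ","), s$con)
  flush(s$con)
  invisible(s$trial_counter)
}

#' Switch the experimental scenario
#'
#' Selecting another scenario automatically names and saves the current data
#' file while initiating collection into a fresh file; the trial counter
#' resets. Already-flushed trials are never lost.
#'
#' @param s a `session_state`.
#' @param new_scenario scenario name to switch to.
#' @return the session state, invisibly.
#' @export
switch_scenario <- function(s, new_scenario) {
  stopifnot(inherits(s, "session_state"))
  if (is.null(s$con)) stop("session is not active")
  close(s$con); s$con <- NULL
  s$scenario <- new_scenario
  s$trial_counter <- 0L
  session_new_file(s)
  invisible(s)
}

#' Close a session
#'
#' Saves the current data file and ends the session; the ongoing stimulus is
#' the caller's to terminate (the closed-loop runner presents the black
#' screen first).
#'
#' @param s a `session_state`.
#' @return character vector of all data files written.
#' @export
session_quit <- function(s) {
  stopifnot(inherits(s, "session_state"))
  if (!is.null(s$con)) { close(s$con); s$con <- NULL }
  s$files
}
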