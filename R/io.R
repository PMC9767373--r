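#' Read and write schedules, sessions and parameter sets
#'
#' Plain-text interchange formats: schedules and per-trial session records as
#' CSV (columns `trial,stimulus_id,stimulus_class,block_type,probe_block_id`
#' plus, for sessions, `participant,response,outcome`), parameter sets as
#' JSON.
#'
#' @param x Object to write.
#' @param path File path.
#' @return Readers return tibbles (or a [param_set()]); writers return the
#'   input invisibly.
#' @name gng_io
NULL

#' @rdname gng_io
#' @export
write_schedule <- function(x, path) {
  readr::write_csv(
    x[, c("trial", "stimulus_id", "stimulus_class", "block_type", "probe_block_id")],
    path, na = ""
  )
  invisible(x)
}

#' @rdname gng_io
#' @export
read_schedule <- function(path) {
  sched <- readr::read_csv(
    path,
    col_types = readr::cols(
      trial = readr::col_integer(),
      stimulus_id = readr::col_integer(),
      stimulus_class = readr::col_character(),
      block_type = readr::col_character(),
      probe_block_id = readr::col_integer()
    )
  )
  attr(sched, "n_stimuli") <- length(unique(sched$stimulus_id))
  class(sched) <- c("gng_schedule", class(sched))
  sched
}

#' @rdname gng_io
#' @export
write_sessions <- function(x, path) {
  readr::write_csv(
    x[, c("participant", "trial", "stimulus_id", "stimulus_class",
          "block_type", "probe_block_id", "response", "outcome")],
    path, na = ""
  )
  invisible(x)
}

#' @rdname gng_io
#' @export
read_sessions <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      participant = readr::col_integer(),
      trial = readr::col_integer(),
      stimulus_id = readr::col_integer(),
      stimulus_class = readr::col_character(),
      block_type = readr::col_character(),
      probe_block_id = readr::col_integer(),
      response = readr::col_character(),
      outcome = readr::col_double()
    )
  )
}

#' @rdname gng_io
#' @export
write_params <- function(x, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("write_params() requires the jsonlite package.")
  }
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' @rdname gng_io
#' @export
read_params <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("read_params() requires the jsonlite package.")
  }
  do.call(param_set, jsonlite::read_json(path, simplifyVector = TRUE))
}
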