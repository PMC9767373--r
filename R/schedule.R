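#' Generate a go/no-go task schedule with interleaved probe blocks
#'
#' Builds the fixed trial sequence of a deterministic go/no-go learning task:
#' `n_stimuli * presentations` trials in pseudo-random order, subject to two
#' ordering constraints — each stimulus appears exactly once in every
#' consecutive bin of `n_stimuli` trials, and no two consecutive trials share a
#' stimulus — with `n_probe_blocks` contiguous runs of non-reinforced probe
#' trials overlaid on the sequence. The default configuration is a 588-trial
#' session: 12 stimuli (6 go, 6 no-go) shown 49 times each, with five 36-trial
#' probe blocks.
#'
#' Stimulus ordering is generated bin-wise: each bin of `n_stimuli` trials is a
#' random permutation of the stimulus set, resampled whenever its first element
#' would repeat the previous bin's last element. Probe onsets default to equal
#' spacing with the first onset at `2 * probe_block_length` trials, so every
#' probe block has a full reinforced pre-probe and post-probe window of the
#' same length.
#'
#' @param n_stimuli Number of distinct stimuli; the first half are go stimuli,
#'   the second half no-go stimuli.
#' @param presentations Presentations per stimulus; total trials are
#'   `n_stimuli * presentations`.
#' @param n_probe_blocks Number of contiguous non-reinforced probe blocks.
#' @param probe_block_length Trials per probe block.
#' @param probe_onsets Optional integer vector of 0-based trial indices at
#'   which each probe block starts. `NULL` uses the equal-spacing default.
#' @param seed Integer seed; identical seed and configuration give a
#'   bit-identical schedule.
#'
#' @return A tibble of class `gng_schedule` with one row per trial and columns
#'   `trial` (0-based), `stimulus_id` (0-based), `stimulus_class`
#'   (`"go"`/`"nogo"`), `block_type` (`"reinforced"`/`"probe"`), and
#'   `probe_block_id` (1-based block number, `NA` on reinforced trials).
#'   Configuration is stored in attributes `n_stimuli`, `presentations`,
#'   `n_probe_blocks`, `probe_block_length`, `probe_onsets`.
#'
#' @examples
#' sched <- gng_schedule(seed = 1)
#' nrow(sched)                      # 588
#' table(sched$block_type)          # 408 reinforced, 180 probe
#' @export
gng_schedule <- function(n_stimuli = 12, presentations = 49,
                         n_probe_blocks = 5, probe_block_length = 36,
                         probe_onsets = NULL, seed = 1L) {
  n_stimuli <- check_count(n_stimuli, "n_stimuli")
  presentations <- check_count(presentations, "presentations")
  n_probe_blocks <- check_count(n_probe_blocks, "n_probe_blocks", min = 0)
  probe_block_length <- check_count(probe_block_length, "probe_block_length", min = 0)
  n_trials <- n_stimuli * presentations

  if (n_probe_blocks * probe_block_length > n_trials) {
    abort(paste0(
      "Infeasible configuration: probe trials (",
      n_probe_blocks * probe_block_length, ") exceed total trials (",
      n_trials, ")."
    ), class = "gng_config_error")
  }
  if (n_stimuli == 1 && presentations > 1) {
    abort("Infeasible configuration: a single stimulus cannot satisfy the no-consecutive-repeat constraint.",
          class = "gng_config_error")
  }

  if (is.null(probe_onsets)) {
    probe_onsets <- default_probe_onsets(n_trials, n_probe_blocks, probe_block_length)
  }
  probe_onsets <- as.integer(probe_onsets)
  check_probe_onsets(probe_onsets, n_probe_blocks, probe_block_length, n_trials)

  stim <- with_seed(seed, {
    out <- integer(n_trials)
    last <- -1L
    for (b in seq_len(presentations)) {
      repeat {
        perm <- sample.int(n_stimuli) - 1L
        if (n_stimuli == 1 || perm[1] != last) break
      }
      out[((b - 1L) * n_stimuli + 1L):(b * n_stimuli)] <- perm
      last <- perm[n_stimuli]
    }
    out
  })

  probe_id <- rep(NA_integer_, n_trials)
  for (k in seq_along(probe_onsets)) {
    idx <- probe_onsets[k] + seq_len(probe_block_length)  # 1-based rows
    probe_id[idx] <- k
  }

  sched <- tibble::tibble(
    trial = seq_len(n_trials) - 1L,
    stimulus_id = stim,
    stimulus_class = ifelse(stim < n_stimuli %/% 2, "go", "nogo"),
    block_type = ifelse(is.na(probe_id), "reinforced", "probe"),
    probe_block_id = probe_id
  )
  attr(sched, "n_stimuli") <- n_stimuli
  attr(sched, "presentations") <- presentations
  attr(sched, "n_probe_blocks") <- n_probe_blocks
  attr(sched, "probe_block_length") <- probe_block_length
  attr(sched, "probe_onsets") <- probe_onsets
  class(sched) <- c("gng_schedule", class(sched))
  sched
}

# Equal spacing between probe onsets; first onset leaves a full pre-probe
# window, last block leaves a full post-probe window.
default_probe_onsets <- function(n_trials, n_probe_blocks, probe_block_length) {
  if (n_probe_blocks == 0) return(integer(0))
  first <- 2L * probe_block_length
  if (n_probe_blocks == 1) return(first)
  span <- n_trials - 2L * probe_block_length - first
  if (span < 0) {
    abort("Infeasible configuration: no room for probe blocks with full flanking windows.",
          class = "gng_config_error")
  }
  spacing <- span %/% (n_probe_blocks - 1L)
  if (spacing < 2L * probe_block_length) {
    abort("Infeasible configuration: probe blocks would overlap their flanking windows.",
          class = "gng_config_error")
  }
  first + (seq_len(n_probe_blocks) - 1L) * spacing
}

check_probe_onsets <- function(onsets, n_probe_blocks, len, n_trials) {
  if (length(onsets) != n_probe_blocks) {
    abort("Infeasible configuration: `probe_onsets` must have one onset per probe block.",
          class = "gng_config_error")
  }
  if (n_probe_blocks == 0) return(invisible(onsets))
  if (any(onsets < 0) || any(onsets + len > n_trials)) {
    abort("Infeasible configuration: probe block extends outside the session.",
          class = "gng_config_error")
  }
  o <- sort(onsets)
  if (any(diff(o) < len)) {
    abort("Infeasible configuration: probe blocks overlap.",
          class = "gng_config_error")
  }
  invisible(onsets)
}

#' Check a task schedule against its structural invariants
#'
#' Diagnostic companion to [gng_schedule()]: re-derives every structural rule
#' a schedule must satisfy and reports violations instead of erroring, so
#' externally supplied or hand-edited schedules can be audited.
#'
#' Rules checked: equal presentation counts across stimuli; each consecutive
#' bin of `n_stimuli` trials is a permutation of the stimulus set; no two
#' consecutive trials share a stimulus; probe trials form contiguous runs of
#' equal length, consistent with `n_probe_blocks`/`probe_block_length` when
#' those attributes are present.
#'
#' @param schedule A `gng_schedule` or any data frame with the schedule
#'   columns (see [gng_schedule()]).
#' @return A tibble with columns `rule` (identifier of the violated
#'   invariant), `trial` (first offending 0-based trial index, `NA` for global
#'   rules) and `detail`. Zero rows when the schedule is valid.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(nrow(schedule) > 0)
  bad <- list()
  note <- function(rule, trial, detail) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(
      rule = rule, trial = as.integer(trial), detail = detail
    )
  }

  n_trials <- nrow(schedule)
  stim <- schedule$stimulus_id
  n_stimuli <- attr(schedule, "n_stimuli") %||% length(unique(stim))

  counts <- table(factor(stim, levels = sort(unique(stim))))
  if (length(unique(as.integer(counts))) > 1 || n_trials %% n_stimuli != 0) {
    note("presentation-count", NA,
         "per-stimulus presentation counts are not all equal")
  }

  rep_idx <- which(stim[-1] == stim[-n_trials])
  if (length(rep_idx) > 0) {
    note("no-consecutive-repeat", rep_idx[1],
         "two consecutive trials share a stimulus")
  }

  if (n_trials %% n_stimuli == 0) {
    for (b in seq_len(n_trials %/% n_stimuli)) {
      rows <- ((b - 1L) * n_stimuli + 1L):(b * n_stimuli)
      if (anyDuplicated(stim[rows]) > 0) {
        note("bin-permutation", rows[1] - 1L,
             sprintf("bin %d is not a permutation of the stimulus set", b))
        break
      }
    }
  }

  is_probe <- schedule$block_type == "probe"
  if (any(is_probe)) {
    r <- rle(is_probe)
    lens <- r$lengths[r$values]
    expected_len <- attr(schedule, "probe_block_length") %||% lens[1]
    expected_n <- attr(schedule, "n_probe_blocks") %||% length(lens)
    if (length(lens) != expected_n) {
      note("probe-block-count", NA,
           sprintf("%d probe runs found, %d expected", length(lens), expected_n))
    }
    off <- which(lens != expected_len)
    if (length(off) > 0) {
      starts <- (cumsum(c(0L, r$lengths))[-(length(r$lengths) + 1L)])[r$values]
      note("probe-block-length", starts[off[1]],
           sprintf("probe run of %d trials, %d expected", lens[off[1]], expected_len))
    }
  }

  if (length(bad) == 0) {
    tibble::tibble(rule = character(), trial = integer(), detail = character())
  } else {
    dplyr::bind_rows(bad)
  }
}
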