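#' Response rate with ceiling/floor correction
#'
#' `k / n`, except that perfect counts are pulled strictly inside (0, 1) so the
#' rate can be probit-transformed: a count of `n` becomes `1 - 1/(2n)` and a
#' count of 0 becomes `1/(2n)`. Interior counts are returned untouched.
#' Vectorized over `k` and `n`.
#'
#' @param k Number of go responses (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @return Rate strictly in (0, 1).
#' @examples
#' corrected_rate(18, 36)  # 0.5
#' corrected_rate(36, 36)  # 1 - 1/72
#' @export
corrected_rate <- function(k, n) {
  if (any(n < 1)) abort("`n` must be >= 1.", class = "gng_rate_error")
  if (any(k < 0 | k > n)) abort("`k` must lie in [0, n].", class = "gng_rate_error")
  r <- k / n
  nn <- rep(n, length.out = length(r))
  hi <- k == nn
  lo <- k == 0
  r[hi] <- 1 - 1 / (2 * nn[hi])
  r[lo] <- 1 / (2 * nn[lo])
  r
}

check_rate <- function(x, name) {
  if (any(x <= 0 | x >= 1)) {
    abort(sprintf("`%s` must lie strictly in (0, 1); apply corrected_rate() first.", name),
          class = "gng_rate_error")
  }
  x
}

#' Sensitivity index d-prime
#'
#' `d' = z(HR) - z(FAR)` with `z` the standard-normal quantile: separation
#' between the go-stimulus and no-go-stimulus response distributions.
#'
#' @param HR,FAR Hit and false-alarm rates strictly in (0, 1)
#'   (see [corrected_rate()]).
#' @return d-prime; antisymmetric under swapping `HR` and `FAR`.
#' @export
dprime <- function(HR, FAR) {
  qnorm(check_rate(HR, "HR")) - qnorm(check_rate(FAR, "FAR"))
}

#' Response-bias criterion c
#'
#' `c = (z(HR) + z(FAR)) / 2`. Under this sign convention a larger overall
#' propensity to respond (both rates high) gives a larger `c`, and a reduction
#' in go-responding lowers it.
#'
#' @inheritParams dprime
#' @return Criterion; symmetric in its arguments and 0 when `FAR = 1 - HR`.
#' @export
criterion <- function(HR, FAR) {
  (qnorm(check_rate(HR, "HR")) + qnorm(check_rate(FAR, "FAR"))) / 2
}

# SDT summary of a set of session rows: counts, corrected rates, d', c.
# Returns a one-row tibble; rate fields are NA when a class is absent.
sdt_window <- function(rows) {
  go <- rows$stimulus_class == "go"
  resp_go <- rows$response == "go"
  n_go <- sum(go)
  n_nogo <- sum(!go)
  if (n_go == 0 || n_nogo == 0) {
    return(tibble::tibble(n_go_trials = n_go, n_nogo_trials = n_nogo,
                          HR = NA_real_, FAR = NA_real_,
                          d_prime = NA_real_, criterion_c = NA_real_))
  }
  HR <- corrected_rate(sum(resp_go & go), n_go)
  FAR <- corrected_rate(sum(resp_go & !go), n_nogo)
  tibble::tibble(
    n_go_trials = n_go, n_nogo_trials = n_nogo, HR = HR, FAR = FAR,
    d_prime = dprime(HR, FAR), criterion_c = criterion(HR, FAR)
  )
}

#' Sliding-window learning curve
#'
#' Computes a behavioural metric in a centred sliding window over trials:
#' `"dprime"` and `"criterion"` from corrected hit/false-alarm rates within
#' the window, or the windowed go-response probability conditioned on stimulus
#' class (`"p_go_go"` for go stimuli, `"p_go_nogo"` for no-go stimuli).
#' Positions whose window extends past the session edge, or lacks the trial
#' types the metric needs, are reported as `NA`.
#'
#' @param session A session tibble from [simulate_session()] (one participant).
#' @param metric One of `"dprime"`, `"criterion"`, `"p_go_go"`, `"p_go_nogo"`.
#' @param window Odd window width in trials (21 is the conventional width for
#'   d-prime curves, 5 for go-probability curves).
#' @return A tibble with columns `trial` and `value`, one row per session
#'   trial.
#' @export
sliding_curve <- function(session,
                          metric = c("dprime", "criterion", "p_go_go", "p_go_nogo"),
                          window = 21) {
  metric <- match.arg(metric)
  window <- check_count(window, "window")
  n <- nrow(session)
  if (window %% 2 == 0) {
    abort("`window` must be odd (centred windows).", class = "gng_config_error")
  }
  if (window > n) {
    abort("`window` exceeds the session length.", class = "gng_config_error")
  }
  h <- (window - 1L) %/% 2L

  go_stim <- session$stimulus_class == "go"
  resp_go <- session$response == "go"
  # windowed counts via cumulative sums
  csum <- function(x) cumsum(c(0, x))
  wsum <- function(x, t) {  # t: 1-based centre positions with full windows
    cs <- csum(x)
    cs[t + h + 1L] - cs[t - h]
  }
  t_ok <- (h + 1L):(n - h)
  n_go <- wsum(go_stim, t_ok)
  n_nogo <- wsum(!go_stim, t_ok)
  k_hit <- wsum(go_stim & resp_go, t_ok)
  k_fa <- wsum(!go_stim & resp_go, t_ok)

  val <- rep(NA_real_, n)
  v <- rep(NA_real_, length(t_ok))
  if (metric %in% c("dprime", "criterion")) {
    ok <- n_go > 0 & n_nogo > 0
    HR <- corrected_rate(k_hit[ok], n_go[ok])
    FAR <- corrected_rate(k_fa[ok], n_nogo[ok])
    v[ok] <- if (metric == "dprime") dprime(HR, FAR) else criterion(HR, FAR)
  } else if (metric == "p_go_go") {
    ok <- n_go > 0
    v[ok] <- k_hit[ok] / n_go[ok]
  } else {
    ok <- n_nogo > 0
    v[ok] <- k_fa[ok] / n_nogo[ok]
  }
  val[t_ok] <- v
  tibble::tibble(trial = session$trial, value = val)
}

#' Probe-block contrasts of SDT measures
#'
#' For each probe block, computes hit rate, false-alarm rate, d-prime and
#' criterion on the block's probe trials, on the same number of reinforced
#' trials immediately before it (pre-probe window), and immediately after it
#' (post-probe window), together with the probe-minus-pre and probe-minus-post
#' deltas.
#'
#' @param session A single participant's session tibble.
#' @param schedule Optional; ignored (block structure is carried by the
#'   session columns). Retained so calls can pass the generating schedule.
#' @param window Flanking-window length in trials; defaults to the probe-block
#'   length (36).
#' @return A tibble with one row per probe block: `probe_block_id`, the four
#'   measures in each window (suffixes `_pre`, `_probe`, `_post`) and the
#'   deltas `delta_*` (probe minus pre-probe) and `delta_*_post` (probe minus
#'   post-probe) for `d_prime`, `criterion_c`, `HR`, `FAR`.
#' @export
block_contrast <- function(session, schedule = NULL, window = 36) {
  window <- check_count(window, "window")
  probe_ids <- sort(unique(session$probe_block_id[!is.na(session$probe_block_id)]))
  if (length(probe_ids) == 0) {
    abort("Session contains no probe trials.", class = "gng_config_error")
  }
  n <- nrow(session)
  rows <- purrr::map(probe_ids, function(k) {
    idx <- which(session$probe_block_id == k)
    pre_idx <- (min(idx) - window):(min(idx) - 1L)
    post_idx <- (max(idx) + 1L):(max(idx) + window)
    for (w in list(pre = pre_idx, post = post_idx)) {
      if (min(w) < 1 || max(w) > n ||
          any(session$block_type[w] != "reinforced")) {
        abort(sprintf(
          "Probe block %d lacks a full reinforced flanking window of %d trials.",
          k, window
        ), class = "gng_window_error")
      }
    }
    s_pre <- sdt_window(session[pre_idx, ])
    s_probe <- sdt_window(session[idx, ])
    s_post <- sdt_window(session[post_idx, ])
    stats <- c("HR", "FAR", "d_prime", "criterion_c")
    out <- tibble::tibble(probe_block_id = k)
    for (st in stats) {
      out[[paste0(st, "_pre")]] <- s_pre[[st]]
      out[[paste0(st, "_probe")]] <- s_probe[[st]]
      out[[paste0(st, "_post")]] <- s_post[[st]]
      out[[paste0("delta_", st)]] <- s_probe[[st]] - s_pre[[st]]
      out[[paste0("delta_", st, "_post")]] <- s_probe[[st]] - s_post[[st]]
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Per-participant probe contrasts for a cohort of sessions
#'
#' Maps [block_contrast()] over participants in a long sessions table.
#'
#' @param sessions A long tibble of sessions (multiple participants).
#' @param window Flanking-window length, as in [block_contrast()].
#' @return Per-participant, per-probe-block contrast tibble.
#' @export
cohort_contrast <- function(sessions, window = 36) {
  sessions |>
    dplyr::group_by(.data$participant) |>
    dplyr::group_modify(~ block_contrast(.x, window = window)) |>
    dplyr::ungroup()
}

#' Average probe contrasts within participant
#'
#' Collapses a [cohort_contrast()] table to one row per participant by
#' averaging each delta across probe blocks, the form entered into group-level
#' one-sample tests.
#'
#' @param contrasts Output of [cohort_contrast()].
#' @return One row per participant with the across-block mean deltas.
#' @export
contrast_summary <- function(contrasts) {
  contrasts |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("delta_"),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
}

#' One-sample t-test of per-participant deltas against zero
#'
#' @param deltas Numeric vector, one delta per participant (non-finite values
#'   dropped).
#' @return A one-row tibble: `estimate` (mean), `t_statistic`, `dof`,
#'   `p_value` (two-sided), `cohens_d` (mean / SD), `n`.
#' @export
group_test <- function(deltas) {
  deltas <- deltas[is.finite(deltas)]
  n <- length(deltas)
  if (n < 2) abort("Need at least 2 finite deltas.", class = "gng_test_error")
  s <- sd(deltas)
  if (s == 0) {
    abort("Zero variance across participants: t-test degenerate.",
          class = "gng_test_error")
  }
  ht <- stats::t.test(deltas, mu = 0)
  tibble::tibble(
    estimate = mean(deltas),
    t_statistic = unname(ht$statistic),
    dof = unname(ht$parameter),
    p_value = ht$p.value,
    cohens_d = mean(deltas) / s,
    n = n
  )
}
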