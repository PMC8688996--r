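# Reference-trace goal metrics.
#
# Eight goal metrics are computed from a tethered-speedometer velocity /
# displacement trace within the annotated phases: Push maximum velocity,
# Glid end velocity, StPr average velocity, Swim average velocity per cycle,
# Swim phase average velocity, T5m, T15m and lap average velocity.

#' Create a reference velocity/displacement trace
#'
#' @param t Time vector (s), uniform at rate `fr`.
#' @param v Velocity (m/s): line-of-cable velocity before parallax
#'   correction, forward velocity after.
#' @param d Cumulative displacement (m); integrated from `v` when missing.
#' @param fr Sampling rate (Hz), default 100.
#' @param corrected Whether the parallax correction has been applied.
#' @return A tibble of class `reference_trace`.
#' @export
reference_trace <- function(t, v, d = NULL, fr = 100, corrected = FALSE) {
  if (is.null(d)) d <- pracma::cumtrapz(t, v)[, 1]
  stopifnot(length(t) == length(v), length(t) == length(d))
  structure(tibble::tibble(t = as.numeric(t), v = as.numeric(v), d = as.numeric(d)),
            fr = fr, corrected = corrected,
            class = c("reference_trace", class(tibble::tibble())))
}

#' @rdname reference_trace
#' @param trace A `reference_trace`.
#' @export
is_corrected <- function(trace) isTRUE(attr(trace, "corrected"))

#' Read and write reference-trace CSV files (`t,v,d`)
#'
#' @param path CSV path.
#' @param trace A `reference_trace` (for writing).
#' @param fr,corrected Metadata for reading (stored in a sidecar YAML when
#'   written by [write_reference_csv()]).
#' @export
read_reference_csv <- function(path, fr = NULL, corrected = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta_path <- paste0(path, ".yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    fr <- fr %||% meta$fr
    corrected <- corrected %||% meta$corrected
  }
  reference_trace(df$t, df$v, df$d, fr = fr %||% 100,
                  corrected = corrected %||% FALSE)
}

#' @rdname read_reference_csv
#' @export
write_reference_csv <- function(trace, path) {
  readr::write_csv(tibble::as_tibble(trace)[c("t", "v", "d")], path,
                   progress = FALSE)
  yaml::write_yaml(list(fr = attr(trace, "fr"),
                        corrected = is_corrected(trace)), paste0(path, ".yaml"))
  invisible(path)
}

#' Correct speedometer parallax
#'
#' The speedometer sits `h` metres above the water line, so its cable length
#' L and payout velocity measure the hypotenuse of a right triangle whose
#' horizontal leg x is the swimmer's forward position. With `d0` the initial
#' horizontal distance from the device anchor:
#' \deqn{L(t) = \sqrt{d_0^2 + h^2} + d_{cable}(t), \quad x = \sqrt{L^2 - h^2}}
#' \deqn{v_f = v_{cable} \cdot L / x = v_{cable} / \cos\alpha}
#' Forward displacement is re-based to zero at the start (`x - d0`).
#'
#' @param raw Uncorrected `reference_trace` (cable-frame `v`, `d`).
#' @param h Device height above water (m); the correction is the identity at
#'   `h = 0`.
#' @param d0 Initial horizontal distance from the anchor (m), > 0.
#' @return A corrected `reference_trace`.
#' @export
correct_parallax <- function(raw, h, d0) {
  if (is_corrected(raw)) {
    warning("trace is already corrected; returning unchanged")
    return(raw)
  }
  stopifnot(h >= 0, d0 > 0)
  ell <- sqrt(d0^2 + h^2) + raw$d
  if (any(ell < h)) stop("impossible geometry: cable length shorter than device height")
  x <- sqrt(ell^2 - h^2)
  v_f <- raw$v * ell / x
  reference_trace(raw$t, v_f, d = x - x[1], fr = attr(raw, "fr"),
                  corrected = TRUE)
}

interp_at <- function(t, y, t0) stats::approx(t, y, xout = t0, rule = 2)$y

first_crossing <- function(t, d, level) {
  i <- which(d >= level)
  if (length(i) == 0L) return(NA_real_)
  i <- i[1]
  if (i == 1L) return(t[1])
  # linear interpolation between the bracketing samples
  t[i - 1] + (level - d[i - 1]) / (d[i] - d[i - 1]) * (t[i] - t[i - 1])
}

mean_v <- function(trace, interval) {
  i <- trace$t >= interval[1] & trace$t < interval[2]
  if (sum(i) < 2L) stop("interval too short for the reference trace")
  pracma::trapz(trace$t[i], trace$v[i]) / (trace$t[i][sum(i)] - trace$t[i][1])
}

#' Compute the eight goal metrics from a corrected reference trace
#'
#' * `push_vmax`: maximum velocity within the Push phase;
#' * `glid_vend`: velocity at the end of the Glid phase;
#' * `stpr_vavg`: time-average velocity over StPr;
#' * `swim_vavg_cycle`: average velocity over each stroke cycle (list column);
#' * `swim_vavg_phase`: time-average velocity over the whole Swim phase;
#' * `t5m`, `t15m`: first times (from lap start) at which the displacement
#'   from the wall crosses 5 m and 15 m, linearly interpolated;
#' * `lap_vavg`: `pool_length / lap duration`.
#'
#' @param trace Corrected `reference_trace` covering the lap, with `d = 0` at
#'   the wall at lap start.
#' @param ann A `phase_annotation`.
#' @param cycles A `cycle_set`, or `NULL` (per-cycle list empty, warning).
#' @param pool_length Pool length (m), default 25.
#' @param sync_offset Time (s) added to the trace clock to align it with the
#'   annotation clock, default 0.
#' @return A one-row tibble of class `goal_metric_set`; `swim_vavg_cycle` is
#'   a list column holding a tibble `cycle`, `v_avg`.
#' @export
compute_goal_metrics <- function(trace, ann, cycles = NULL, pool_length = 25,
                                 sync_offset = 0) {
  if (!is_corrected(trace)) stop("reference trace must be parallax-corrected first")
  tr <- trace
  tr$t <- tr$t + sync_offset
  lap <- ann$lap
  d0 <- interp_at(tr$t, tr$d, lap[1])
  d_from_wall <- tr$d - d0
  push <- ann$phases$Push
  i_push <- tr$t >= push[1] & tr$t < push[2]
  if (!any(i_push)) stop("reference trace does not cover the Push phase")
  push_vmax <- max(tr$v[i_push])
  glid_vend <- interp_at(tr$t, tr$v, ann$phases$Glid[2])
  stpr_vavg <- mean_v(tr, ann$phases$StPr)
  swim_vavg_phase <- mean_v(tr, ann$phases$Swim)
  if (is.null(cycles)) {
    warning("no cycles supplied; per-cycle velocity list is empty")
    cyc_v <- tibble::tibble(cycle = integer(), v_avg = numeric())
  } else {
    ci <- cycle_intervals(cycles)
    cyc_v <- tibble::tibble(
      cycle = ci$cycle,
      v_avg = vapply(seq_len(nrow(ci)),
                     function(k) mean_v(tr, c(ci$on[k], ci$off[k])), numeric(1))
    )
  }
  t5 <- first_crossing(tr$t, d_from_wall, 5) - lap[1]
  t15 <- first_crossing(tr$t, d_from_wall, 15) - lap[1]
  if (is.na(t15)) stop("displacement never reaches 15 m; T15m undefined")
  out <- tibble::tibble(
    push_vmax = push_vmax, glid_vend = glid_vend, stpr_vavg = stpr_vavg,
    swim_vavg_phase = swim_vavg_phase, t5m = t5, t15m = t15,
    lap_vavg = pool_length / (lap[2] - lap[1]),
    swim_vavg_cycle = list(cyc_v)
  )
  class(out) <- c("goal_metric_set", class(out))
  out
}

GOAL_TARGETS <- c("push_vmax", "glid_vend", "stpr_vavg", "swim_vavg_cycle",
                  "swim_vavg_phase", "t5m", "t15m", "lap_vavg")

#' Write goal metrics to JSON
#'
#' @param metrics A `goal_metric_set` (one lap).
#' @param path JSON path.
#' @export
write_goal_metrics_json <- function(metrics, path) {
  obj <- as.list(tibble::as_tibble(metrics)[1, setdiff(names(metrics), "swim_vavg_cycle")])
  obj$swim_vavg_cycle <- metrics$swim_vavg_cycle[[1]]$v_avg
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
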