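#' Tidy a pulling run into its force-extension record
#'
#' @param x an `sop_pulling`.
#' @param ... unused.
#' @return tibble with `time` (ps), `extension` (A), `force_pN`.
#' @export
tidy.sop_pulling <- function(x, ...) x$trace

#' One-row summary of a pulling run
#'
#' @param x an `sop_pulling`.
#' @param smooth_window,min_drop passed to [detect_breaking_forces()].
#' @param ... unused.
#' @return tibble with fbf/cbf (pN), max extension, pulling speed and run
#'   length.
#' @export
glance.sop_pulling <- function(x, smooth_window = 25, min_drop = 50, ...) {
  bf <- detect_breaking_forces(x$trace, smooth_window, min_drop)
  v <- pulling_speed(x$protocol, x$params$dt)
  tibble::tibble(fbf_pN = bf$fbf, cbf_pN = bf$cbf, n_events = nrow(bf$events),
                 max_extension_A = max(x$trace$extension),
                 v_um_s = v$um_per_s, n_frames = nrow(x$trace),
                 time_ps = max(x$trace$time))
}

#' Tidy a translocation run into its per-cycle log
#'
#' @param x an `sop_translocation`.
#' @param ... unused.
#' @return the per-cycle tibble (cycle, start_protomer, n_selected,
#'   total_force_pN, x, I, time_ps).
#' @export
tidy.sop_translocation <- function(x, ...) x$log

#' One-row summary of a translocation run
#'
#' @param x an `sop_translocation`.
#' @param ... unused.
#' @return tibble with final translocated fraction and line, mean applied
#'   force and cycle count.
#' @export
glance.sop_translocation <- function(x, ...) {
  lg <- x$log
  tibble::tibble(x_final = lg$x[nrow(lg)], I_final = lg$I[nrow(lg)],
                 mean_force_pN = mean(lg$total_force_pN),
                 mean_selected = mean(lg$n_selected), n_cycles = nrow(lg))
}

#' Tidy an event report into its fragment table
#'
#' @param x an `event_report`.
#' @param ... unused.
#' @return the fragments tibble.
#' @export
tidy.event_report <- function(x, ...) x$fragments

#' One-row summary of an event report
#'
#' @param x an `event_report`.
#' @param ... unused.
#' @return tibble with fbf/cbf, pathway label and oligomer decomposition.
#' @export
glance.event_report <- function(x, ...) {
  tibble::tibble(fbf_pN = x$fbf, cbf_pN = x$cbf, pathway = x$pathway,
                 oligomers = x$oligomers, n_fragments = nrow(x$fragments))
}

#' Serialize an event report to JSON
#'
#' @param report an `event_report`.
#' @param path output path.
#' @export
write_event_report <- function(report, path) {
  jsonlite::write_json(
    list(fbf_pN = report$fbf, cbf_pN = report$cbf, pathway = report$pathway,
         oligomers = report$oligomers, fragments = report$fragments),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
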