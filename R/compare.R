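#' Summarize a breathing profile over a TSS window
#'
#' Reduces one threshold slice of a profile to window-vs-background
#' statistics around the transcription start site: mean occupancy inside
#' the window, the largest bubble length observed there, the
#' event-weighted mean bubble lifetime, the same three quantities over
#' the background (all retained positions outside the window), and the
#' focus ratio (window / background occupancy). A focus ratio well above
#' 1 is the signature of a promoter whose breathing is concentrated at
#' the TSS.
#'
#' Means are taken over all defined (length, position) cells;
#' lifetime means are weighted by event count so that rarely-opening
#' cells do not dominate.
#'
#' @param profile A `breathing_profile`.
#' @param window Integer `c(lo, hi)` of TSS-relative positions
#'   (inclusive; position 0 does not exist). Default `c(-50, 50)`.
#' @param threshold One of the profile's thresholds, Angstrom.
#' @return A `tss_window_summary` list; `focus_ratio` is `NA` (flagged
#'   by `focus_defined = FALSE`) when the background mean occupancy is 0
#'   or the background is empty.
#' @export
summarize_tss_window <- function(profile, window = c(-50, 50), threshold = 1.0) {
  stopifnot(inherits(profile, "breathing_profile"))
  ti <- match(threshold, profile$thresholds)
  if (is.na(ti)) {
    stop("threshold ", threshold, " not in profile grid {",
         paste(profile$thresholds, collapse = ", "), "}")
  }
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] > window[2L]) stop("window must be c(lo, hi)")
  in_win <- profile$positions >= window[1L] & profile$positions <= window[2L]
  if (!any(in_win)) stop("window contains no profile positions")

  slice_stats <- function(sel) {
    occ <- profile$occupancy[ti, , sel, drop = FALSE]
    life <- profile$mean_lifetime[ti, , sel, drop = FALSE]
    nev <- profile$event_count[ti, , sel, drop = FALSE]
    has_events <- !is.na(nev) & nev > 0L
    list(
      mean_occupancy = mean(occ, na.rm = TRUE),
      max_length = if (any(has_events)) {
        max(profile$lengths[apply(has_events, 2L, any)])
      } else 0L,
      mean_lifetime = if (any(has_events)) {
        sum(life[has_events] * nev[has_events]) / sum(nev[has_events])
      } else NA_real_,
      n_events = sum(nev[has_events])
    )
  }

  win <- slice_stats(in_win)
  bg <- if (any(!in_win)) slice_stats(!in_win) else
    list(mean_occupancy = NA_real_, max_length = NA_integer_,
         mean_lifetime = NA_real_, n_events = 0L)
  focus_defined <- any(!in_win) && is.finite(bg$mean_occupancy) && bg$mean_occupancy > 0
  structure(
    list(sequence_name = profile$provenance$sequence_name,
         window = window, threshold = threshold,
         window_mean_occupancy = win$mean_occupancy,
         window_max_length = win$max_length,
         window_mean_lifetime = win$mean_lifetime,
         window_n_events = win$n_events,
         background_mean_occupancy = bg$mean_occupancy,
         background_max_length = bg$max_length,
         background_mean_lifetime = bg$mean_lifetime,
         background_n_events = bg$n_events,
         focus_ratio = if (focus_defined) win$mean_occupancy / bg$mean_occupancy else NA_real_,
         focus_defined = focus_defined),
    class = "tss_window_summary"
  )
}

#' @export
print.tss_window_summary <- function(x, ...) {
  cat(sprintf("TSS window summary '%s' (window [%+d, %+d], threshold %g A)\n",
              x$sequence_name, x$window[1L], x$window[2L], x$threshold))
  cat(sprintf("  window:     occupancy %.4g, max bubble %s bp, mean lifetime %s ps (%d events)\n",
              x$window_mean_occupancy, x$window_max_length,
              format(x$window_mean_lifetime, digits = 4), x$window_n_events))
  cat(sprintf("  background: occupancy %.4g, max bubble %s bp, mean lifetime %s ps (%d events)\n",
              x$background_mean_occupancy, x$background_max_length,
              format(x$background_mean_lifetime, digits = 4), x$background_n_events))
  cat(sprintf("  focus ratio: %s\n",
              if (x$focus_defined) sprintf("%.4g", x$focus_ratio) else "undefined (background occupancy 0)"))
  invisible(x)
}

#' Contrast the TSS breathing focus of two promoters
#'
#' Operational form of the question "is promoter A's breathing more
#' TSS-focused than promoter B's?": both profiles are reduced by
#' [summarize_tss_window()], the A/B ratios of window occupancy, window
#' mean lifetime and window max bubble length are reported, and the
#' categorical verdict is positive iff `focus_ratio(A) > focus_ratio(B)`
#' AND `window mean lifetime(A) > window mean lifetime(B)`. The verdict
#' is deliberately a conjunction of inequalities, not a statistical test;
#' uncertainty is conveyed by repeating the comparison over master seeds.
#'
#' @param profile_a,profile_b `breathing_profile`s sharing the threshold.
#' @param window TSS-relative window `c(lo, hi)`.
#' @param threshold Opening threshold present in both profiles.
#' @return A `profile_contrast` list with both summaries, the ratios and
#'   the verdict (`NA` when either side's statistics are undefined).
#' @export
compare_profiles <- function(profile_a, profile_b, window = c(-50, 50),
                             threshold = 1.0) {
  if (!threshold %in% profile_a$thresholds || !threshold %in% profile_b$thresholds) {
    stop("threshold ", threshold, " must be present in both profiles' grids")
  }
  sa <- summarize_tss_window(profile_a, window, threshold)
  sb <- summarize_tss_window(profile_b, window, threshold)
  ratio <- function(x, y) if (is.finite(x) && is.finite(y) && y != 0) x / y else NA_real_
  verdict <- if (sa$focus_defined && sb$focus_defined &&
                 is.finite(sa$window_mean_lifetime) && is.finite(sb$window_mean_lifetime)) {
    sa$focus_ratio > sb$focus_ratio && sa$window_mean_lifetime > sb$window_mean_lifetime
  } else NA
  structure(
    list(summary_a = sa, summary_b = sb,
         occupancy_ratio = ratio(sa$window_mean_occupancy, sb$window_mean_occupancy),
         lifetime_ratio = ratio(sa$window_mean_lifetime, sb$window_mean_lifetime),
         max_length_ratio = ratio(sa$window_max_length, sb$window_max_length),
         a_more_tss_focused = verdict),
    class = "profile_contrast"
  )
}

#' @export
print.profile_contrast <- function(x, ...) {
  cat(sprintf("profile contrast: '%s' (A) vs '%s' (B)\n",
              x$summary_a$sequence_name, x$summary_b$sequence_name))
  cat(sprintf("  A/B window occupancy ratio:   %.4g\n", x$occupancy_ratio))
  cat(sprintf("  A/B window lifetime ratio:    %.4g\n", x$lifetime_ratio))
  cat(sprintf("  A/B window max-length ratio:  %.4g\n", x$max_length_ratio))
  cat(sprintf("  verdict: A more TSS-focused than B: %s\n", x$a_more_tss_focused))
  invisible(x)
}

#' Write a contrast report
#'
#' Plain-text summary plus a structured JSON twin next to it.
#'
#' @param contrast A `profile_contrast`.
#' @param path Output `.txt` path (`.json` written alongside).
#' @return `path`, invisibly.
#' @export
write_contrast_report <- function(contrast, path) {
  stopifnot(inherits(contrast, "profile_contrast"))
  txt <- utils::capture.output({
    print(contrast)
    cat("\n"); print(contrast$summary_a)
    cat("\n"); print(contrast$summary_b)
  })
  writeLines(txt, path)
  jsonlite::write_json(
    list(summary_a = unclass(contrast$summary_a),
         summary_b = unclass(contrast$summary_b),
         occupancy_ratio = contrast$occupancy_ratio,
         lifetime_ratio = contrast$lifetime_ratio,
         max_length_ratio = contrast$max_length_ratio,
         a_more_tss_focused = contrast$a_more_tss_focused),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
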