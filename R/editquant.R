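#' Reporter editing efficiency from flow-cytometry events
#'
#' Efficiency is the fraction of red-positive (transfected) cells that are
#' also green-positive (edited): the EGFP+/tdTomato+ ratio of the
#' tdTomato-to-EGFP switch reporter, with rectangular gates. The 95% CI is
#' the Wilson score interval.
#'
#' @param events Tibble with numeric columns `green` and `red` (one row
#'   per cell), e.g. from [simulate_reporter_events()].
#' @param green_threshold,red_threshold Positive gate thresholds.
#' @return One-row tibble: `n_red`, `n_green_red`, `efficiency`,
#'   `conf_low`, `conf_high`.
#' @export
#' @examples
#' ev <- simulate_reporter_events(2000, edit_prob = 0.25, seed = 1)
#' reporter_efficiency(ev)
reporter_efficiency <- function(events, green_threshold = 500,
                                red_threshold = 1000) {
  if (green_threshold <= 0 || red_threshold <= 0) {
    abort("gate thresholds must be > 0")
  }
  if (!all(is.finite(events$green)) || !all(is.finite(events$red))) {
    abort("intensities must be finite")
  }
  red_pos <- events$red >= red_threshold
  n_red <- sum(red_pos)
  if (n_red == 0) {
    abort("no red-positive events; efficiency undefined")
  }
  n_gr <- sum(red_pos & events$green >= green_threshold)
  ci <- wilson_ci(n_gr, n_red)
  tibble(
    n_red = n_red, n_green_red = n_gr,
    efficiency = n_gr / n_red,
    conf_low = ci[1], conf_high = ci[2]
  )
}

# Wilson score interval via prop.test without continuity correction
wilson_ci <- function(x, n, conf_level = 0.95) {
  as.numeric(
    prop.test(x, n, conf.level = conf_level, correct = FALSE)$conf.int
  )
}

#' Base-editing site frequency: the editing-window maximum
#'
#' The site-level base-editing frequency is the highest per-position
#' conversion frequency within the editing window; ties go to the smallest
#' position. Spacer positions are numbered from the 5' (PAM-distal) end.
#'
#' @param profile Tibble with column `position` and either `freq` or
#'   `converted` + `depth` (as from [simulate_base_edit_pileup()]).
#' @param window Length-2 integer vector `c(start, end)`, 1-based
#'   inclusive; default spans the whole profile.
#' @return One-row tibble: `site_frequency`, `position`.
#' @export
#' @examples
#' prof <- tibble::tibble(position = 1:10, freq = 0)
#' prof$freq[c(3, 5, 7)] <- c(0.10, 0.467, 0.20)
#' base_edit_site_frequency(prof, window = c(1, 10))
base_edit_site_frequency <- function(profile, window = NULL) {
  if (nrow(profile) == 0) abort("empty base-edit profile")
  if (!"freq" %in% names(profile)) {
    profile <- mutate(profile, freq = .data$converted / .data$depth)
  }
  S <- max(profile$position)
  window <- window %||% c(1L, S)
  if (length(window) != 2 || window[1] < 1 || window[2] > S ||
      window[1] > window[2]) {
    abort("window must be c(start, end) with 1 <= start <= end <= spacer length")
  }
  inw <- profile[profile$position >= window[1] &
                 profile$position <= window[2], ]
  inw <- arrange(inw, .data$position)
  best <- which.max(inw$freq)  # first index on ties
  tibble(site_frequency = inw$freq[best], position = inw$position[best])
}

#' Summarize replicate site frequencies
#'
#' Mean and s.e.m. of per-replicate site frequencies, grouped by `site`.
#'
#' @param freqs Tibble with columns `site` and `site_frequency` (one row
#'   per replicate).
#' @return Tibble `site`, `n`, `mean_frequency`, `sem`.
#' @export
summarize_site_frequencies <- function(freqs) {
  freqs |>
    group_by(.data$site) |>
    summarise(
      n = dplyr::n(),
      mean_frequency = mean(.data$site_frequency),
      sem = stats::sd(.data$site_frequency) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Summarize editing outcomes across injected embryos
#'
#' Counts edited blastocysts (per-embryo editing frequency above
#' `threshold`), the percent edited, and the frequency range over edited
#' embryos only.
#'
#' @param per_embryo_freqs Numeric vector of per-embryo editing
#'   frequencies in percent, one per genotyped blastocyst.
#' @param n_zygotes Number of injected zygotes.
#' @param site Site label.
#' @param pam_class Optional PAM class label (e.g. "N4GTAT").
#' @param threshold Edited-call threshold in percent; an embryo is edited
#'   when its frequency is strictly above this (default 1, a Sanger-level
#'   detection floor).
#' @return One-row tibble of class `embryo_summary`: `site`, `pam_class`,
#'   `n_zygotes`, `n_blastocysts`, `n_edited`, `percent_edited`,
#'   `freq_min`, `freq_max` (NA when nothing is edited).
#' @export
#' @examples
#' embryo_summary(c(26.1, 30.7, 0, 0, 0, 0, 0, 0),
#'   n_zygotes = 20, site = "Tyr-1")
embryo_summary <- function(per_embryo_freqs, n_zygotes, site,
                           pam_class = NA_character_, threshold = 1) {
  if (length(per_embryo_freqs) == 0) {
    abort("need at least one genotyped blastocyst")
  }
  n_blast <- length(per_embryo_freqs)
  edited <- per_embryo_freqs > threshold
  n_edited <- sum(edited)
  out <- tibble(
    site = site,
    pam_class = pam_class,
    n_zygotes = as.integer(n_zygotes),
    n_blastocysts = n_blast,
    n_edited = n_edited,
    percent_edited = 100 * n_edited / n_blast,
    freq_min = if (n_edited > 0) min(per_embryo_freqs[edited]) else NA_real_,
    freq_max = if (n_edited > 0) max(per_embryo_freqs[edited]) else NA_real_
  )
  class(out) <- c("embryo_summary", class(out))
  out
}
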