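#' Enumerate the sensing montage of a lead
#'
#' For a 1-3-3-1 directional lead this is the canonical 15-pair montage:
#' distal ring to each E1 segment (3), within-level angular pairs (6),
#' corresponding segments across levels (3), and each E2 segment to the
#' proximal ring (3). The 15 pairs schedule as three 5-pair groups recorded
#' 40 s each (2 min total). For 4-contact leads all 6 unordered pairs are
#' returned.
#'
#' @param lead a \code{lead_geometry}.
#' @return list of \code{bipolar_pair}.
#' @export
enumerate_montage <- function(lead) {
  stopifnot(inherits(lead, "lead_geometry"))
  if (length(lead$contacts) == 4L) {
    cmb <- utils::combn(lead$contacts, 2)
    return(lapply(seq_len(ncol(cmb)),
                  function(j) bipolar_pair(lead, cmb[1, j], cmb[2, j])))
  }
  if (length(lead$contacts) != 8L)
    stop("unsupported lead geometry: ", lead$lead_code, call. = FALSE)
  pairs <- list(
    c("E0", "E1a"), c("E0", "E1b"), c("E0", "E1c"),
    c("E1a", "E1b"), c("E1a", "E1c"), c("E1b", "E1c"),
    c("E2a", "E2b"), c("E2a", "E2c"), c("E2b", "E2c"),
    c("E1a", "E2a"), c("E1b", "E2b"), c("E1c", "E2c"),
    c("E2a", "E3"), c("E2b", "E3"), c("E2c", "E3"))
  lapply(pairs, function(p) bipolar_pair(lead, p[1], p[2]))
}

#' Split a montage into recording groups
#'
#' @param pairs montage list from \code{\link{enumerate_montage}}.
#' @param n_groups number of sequentially recorded groups (default 3).
#' @param group_s seconds recorded per group (default 40).
#' @return list with \code{groups} (list of pair lists) and
#'   \code{total_s}.
#' @export
montage_groups <- function(pairs, n_groups = 3, group_s = 40) {
  idx <- split(seq_along(pairs),
               ceiling(seq_along(pairs) / (length(pairs) / n_groups)))
  list(groups = lapply(idx, function(i) pairs[i]),
       total_s = n_groups * group_s)
}

#' Per-direction radial spectra from corresponding-segment pairs
#'
#' One PSD per radial direction (a, b, c) computed from that direction's
#' corresponding-segment pair (E1a-E2a, E1b-E2b, E1c-E2c). Directions whose
#' pair is flagged invalid (e.g. broken contact) are omitted.
#'
#' @param rec a \code{recording} containing the corresponding-segment pairs
#'   of \code{lead_id}.
#' @param lead_id lead id prefix of the channel labels.
#' @param ... passed to \code{\link{power_spectral_density}}.
#' @return named list direction -> \code{spectral_estimate}.
#' @export
radial_spectra <- function(rec, lead_id = "HC", ...) {
  out <- list()
  for (d in c("a", "b", "c")) {
    lab <- paste0(lead_id, "_E1", d, "-E2", d)
    i <- match(lab, rec$channels$label)
    if (is.na(i))
      stop("missing corresponding-segment pair: ", lab, call. = FALSE)
    if (!rec$channels$valid[i]) next
    out[[d]] <- power_spectral_density(rec, lab, ...)
  }
  out
}

#' Rank segmented contacts by LFP band power
#'
#' Per recording, the power attributed to each segmented contact is the mean
#' band power over all montage pairs containing that contact (the referencing
#' scheme is declared, the field reports no canonical attribution). Ranks are
#' descending (1 = highest power); exact ties break by contact name order and
#' are flagged.
#'
#' @param recs a \code{recording} or list of recordings.
#' @param lead a 1-3-3-1 \code{lead_geometry}.
#' @param band Hz band (default 3-8 Hz, capturing the 4-5 Hz theta peak).
#' @param lead_id lead id prefix in channel labels.
#' @return data.frame with session, contact, power, rank, tied.
#' @export
rank_segments <- function(recs, lead, band = c(3, 8), lead_id = "HC") {
  if (inherits(recs, "recording")) recs <- list(recs)
  segs <- segmented_contacts(lead)
  montage <- enumerate_montage(lead)
  out <- lapply(seq_along(recs), function(si) {
    rec <- recs[[si]]
    pair_pow <- new.env()
    pwr <- vapply(segs, function(ct) {
      covering <- Filter(function(p) ct %in% c(p$anode, p$cathode), montage)
      vals <- c()
      for (p in covering) {
        lab <- paste0(lead_id, "_", p$label)
        i <- match(lab, rec$channels$label)
        if (is.na(i) || !rec$channels$valid[i]) next
        v <- get0(lab, envir = pair_pow)
        if (is.null(v)) {
          v <- band_power(power_spectral_density(rec, lab), band)
          assign(lab, v, envir = pair_pow)
        }
        vals <- c(vals, v)
      }
      if (!length(vals))
        stop("segment ", ct, " has no covering montage pair in recording",
             call. = FALSE)
      mean(vals)
    }, numeric(1))
    ord <- order(-pwr, segs)       # descending power, name order on ties
    rk <- integer(length(segs)); rk[ord] <- seq_along(segs)
    data.frame(session = si, contact = segs, power = pwr, rank = rk,
               tied = duplicated(pwr) | duplicated(pwr, fromLast = TRUE),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Post-stimulation suppression profile
#'
#' Baseline is the median band power over 2 s sub-windows of the 20 s
#' pre-stimulus window; each post-stimulation minute is the median over its
#' 2 s sub-windows; normalized values are minute/baseline and dispersion is
#' the s.d. across sub-windows (the across-sub-window reading of the
#' median/avg/s.d. convention).
#'
#' @param rec a \code{recording}.
#' @param event the \code{stim_event} profiled.
#' @param band Hz band.
#' @param channel channel label; defaults to the first montage channel
#'   containing the stimulated contact.
#' @param baseline_s required pre-stimulus baseline length, s (20).
#' @param max_minutes profile at most this many post minutes (10).
#' @param sub_s sub-window length, s (2, so a minute yields 30 estimates).
#' @return a \code{suppression_profile}: stimulated_contact, baseline_power,
#'   minute_power, normalized, dispersion.
#' @export
suppression_response <- function(rec, event, band = c(3, 8), channel = NULL,
                                 baseline_s = 20, max_minutes = 10,
                                 sub_s = 2) {
  if (baseline_s < 20)
    stop("baseline window must be >= 20 s pre-stimulus", call. = FALSE)
  if (event$onset < baseline_s)
    stop("need >= ", baseline_s, " s of pre-stimulus data", call. = FALSE)
  contact <- event$setting$cathode
  if (is.null(channel)) {
    hit <- which(rec$channels$anode == contact | rec$channels$cathode == contact)
    if (!length(hit)) stop("no channel contains stimulated contact ", contact,
                           call. = FALSE)
    channel <- rec$channels$label[hit[1]]
  }
  x <- rec_channel(rec, channel)
  fs <- rec$fs
  sub_power <- function(a, b) {
    starts <- seq(a, b - sub_s, by = sub_s)
    vapply(starts, function(s) {
      seg <- x[(as.integer(s * fs) + 1L):(as.integer((s + sub_s) * fs))]
      band_power(power_spectral_density(seg, fs = fs, segment_s = sub_s,
                                        overlap = 0), band)
    }, numeric(1))
  }
  base_sub <- sub_power(event$onset - baseline_s, event$onset)
  baseline <- stats::median(base_sub)
  n_min <- min(max_minutes,
               floor((rec_duration(rec) - event$offset) / 60))
  if (n_min < 1) stop("need at least one complete post-stimulation minute",
                      call. = FALSE)
  mins <- lapply(seq_len(n_min), function(m) {
    sub_power(event$offset + (m - 1) * 60, event$offset + m * 60)
  })
  minute_power <- vapply(mins, stats::median, numeric(1))
  structure(list(stimulated_contact = contact, channel = channel,
                 baseline_power = baseline,
                 baseline_sd = stats::sd(base_sub),
                 minute_power = minute_power,
                 normalized = minute_power / baseline,
                 dispersion = vapply(mins, stats::sd, numeric(1))),
            class = "suppression_profile")
}

#' @export
print.suppression_profile <- function(x, ...) {
  cat(sprintf("<suppression_profile> stim %s on %s: normalized minutes %s\n",
              x$stimulated_contact, x$channel,
              paste(sprintf("%.2f", x$normalized), collapse = " ")))
  invisible(x)
}

#' Concordance between two contact rankings
#'
#' Coefficient of determination R^2 = squared Pearson correlation between
#' the two rank vectors over the same contacts (equal to squared Spearman
#' when there are no ties). R^2 is direction-blind, so the signed rank
#' correlation is reported alongside.
#'
#' @param rank_a,rank_b named integer rank vectors over identical contact
#'   sets, n >= 3.
#' @return list \code{r_squared}, \code{r} (signed).
#' @export
rank_concordance <- function(rank_a, rank_b) {
  if (is.null(names(rank_a)) || is.null(names(rank_b)) ||
      !setequal(names(rank_a), names(rank_b)))
    stop("rankings must cover identical named contact sets", call. = FALSE)
  if (length(rank_a) < 3) stop("need >= 3 contacts", call. = FALSE)
  b <- rank_b[names(rank_a)]
  r <- stats::cor(as.numeric(rank_a), as.numeric(b))
  list(r_squared = r^2, r = r)
}
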