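#' Impedance from a constant-current test stimulus
#'
#' The implanted device delivers a constant-current pulse (100 Hz, 80 us)
#' and measures the resulting voltage; the reported impedance magnitude is
#' |Z| = |V/I|.
#'
#' @param current_ma delivered current, mA (non-zero).
#' @param voltage_v measured voltage, V.
#' @return impedance magnitude in Ohm.
#' @examples
#' impedance_from_waveform(1, 1)     # 1000 Ohm
#' impedance_from_waveform(0.5, 0.6) # 1200 Ohm
#' @export
impedance_from_waveform <- function(current_ma, voltage_v) {
  if (any(current_ma == 0)) stop("current must be non-zero", call. = FALSE)
  abs(voltage_v / (current_ma / 1000))
}

#' Longitudinal impedance trend and breakage detection
#'
#' Per contact: the stabilization month (first month after which every
#' rolling relative change stays below \code{stab_tol}), the long-term level
#' (median impedance from stabilization on, broken months excluded), and
#' breakage flags (impedance above the open-circuit ceiling or a
#' month-to-month step change beyond \code{step_factor}). When a usage map
#' is given, the sense-only / stimulated long-term level ratio is reported
#' (chronically stimulated contacts run lower by a factor of 2-3).
#'
#' @param series data.frame with columns \code{contact}, \code{month},
#'   \code{ohms} (>= 3 months per contact, strictly increasing within
#'   contact).
#' @param usage optional named vector contact -> \code{"stimulated"} or
#'   \code{"sense_only"}; taken from a \code{usage} column if present.
#' @param ceiling_ohm open-circuit ceiling, Ohm (50 kOhm).
#' @param step_factor month-over-month ratio flagged as a step change (5).
#' @param stab_tol rolling relative-change criterion (0.1).
#' @return list with \code{per_contact} data.frame (contact,
#'   stabilization_month, level, broken, breakage_month) and
#'   \code{sense_stim_ratio} (NA without usage info).
#' @export
impedance_trend <- function(series, usage = NULL, ceiling_ohm = 5e4,
                            step_factor = 5, stab_tol = 0.1) {
  stopifnot(all(c("contact", "month", "ohms") %in% names(series)))
  # contacts are only unique within a lead; key by lead_contact when a lead
  # column is present
  key <- if (!is.null(series$lead)) paste(series$lead, series$contact, sep = "_")
         else series$contact
  series <- series; series$contact <- key
  if (is.null(usage) && !is.null(series$usage))
    usage <- with(unique(series[, c("contact", "usage")]),
                  stats::setNames(usage, contact))
  rows <- lapply(split(series, series$contact), function(s) {
    if (is.unsorted(s$month, strictly = TRUE))
      stop("timestamps must be strictly increasing within contact ",
           s$contact[1], call. = FALSE)
    if (nrow(s) < 3)
      stop("need >= 3 time points for contact ", s$contact[1], call. = FALSE)
    z <- s$ohms
    step <- c(FALSE, pmax(z[-1] / z[-length(z)],
                          z[-length(z)] / z[-1]) > step_factor)
    broken_at <- which(z > ceiling_ohm | step)
    breakage_month <- if (length(broken_at)) s$month[min(broken_at)] else NA_real_
    ok <- if (length(broken_at)) seq_len(min(broken_at) - 1L) else seq_along(z)
    stab <- NA_real_; level <- NA_real_
    if (length(ok) >= 3) {
      zz <- z[ok]
      # rolling change on a 3-point median so one noisy month cannot mask
      # an otherwise settled trajectory
      zs <- zz
      if (length(zz) >= 3)
        zs[2:(length(zz) - 1)] <- vapply(2:(length(zz) - 1), function(i)
          stats::median(zz[(i - 1):(i + 1)]), numeric(1))
      rc <- abs(diff(zs)) / zs[-length(zs)]
      calm <- rev(cumprod(rev(rc < stab_tol))) == 1   # all later changes calm
      j <- which(calm)[1]
      if (!is.na(j) && j < length(zz)) {
        stab <- s$month[ok][j]
        level <- stats::median(zz[j:length(zz)])
      }
    }
    data.frame(contact = s$contact[1], stabilization_month = stab,
               level = level, broken = !is.na(breakage_month),
               breakage_month = breakage_month, stringsAsFactors = FALSE)
  })
  per_contact <- do.call(rbind, rows)
  rownames(per_contact) <- NULL
  ratio <- NA_real_
  if (!is.null(usage)) {
    u <- usage[per_contact$contact]
    sl <- per_contact$level[u == "sense_only" & !per_contact$broken]
    st <- per_contact$level[u == "stimulated" & !per_contact$broken]
    if (length(sl) && length(st))
      ratio <- stats::median(sl, na.rm = TRUE) / stats::median(st, na.rm = TRUE)
  }
  list(per_contact = per_contact, sense_stim_ratio = ratio)
}
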