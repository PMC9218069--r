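#' Build a DBS lead geometry
#'
#' Supported lead types are the 4-contact cylindrical leads (codes
#' \code{"3387"}, \code{"3389"}) with contacts \code{E0..E3} all at ring
#' positions, and the 8-contact directional lead (code \code{"1-3-3-1"}) with
#' ring contacts at the distal (\code{E0}) and proximal (\code{E3}) ends and
#' two levels of three angular segments (\code{E1a,E1b,E1c},
#' \code{E2a,E2b,E2c}) in between. Level index 0 is most distal.
#'
#' @param lead_code one of \code{"3387"}, \code{"3389"}, \code{"1-3-3-1"}.
#' @return an object of class \code{lead_geometry} with fields
#'   \code{lead_code}, \code{contacts}, \code{levels} (named integer vector,
#'   contact to axial level) and \code{segment_angle} (named vector, angular
#'   sector index \code{0,1,2} or \code{"ring"}).
#' @examples
#' build_lead("1-3-3-1")$contacts
#' @export
build_lead <- function(lead_code) {
  stopifnot(is.character(lead_code), length(lead_code) == 1L)
  if (lead_code %in% c("3387", "3389")) {
    contacts <- paste0("E", 0:3)
    levels <- stats::setNames(0:3, contacts)
    angle <- stats::setNames(rep("ring", 4L), contacts)
  } else if (lead_code == "1-3-3-1") {
    contacts <- c("E0", "E1a", "E1b", "E1c", "E2a", "E2b", "E2c", "E3")
    levels <- stats::setNames(c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L), contacts)
    angle <- stats::setNames(c("ring", "0", "1", "2", "0", "1", "2", "ring"),
                             contacts)
  } else {
    stop("unsupported lead code: '", lead_code, "'", call. = FALSE)
  }
  structure(list(lead_code = lead_code, contacts = contacts,
                 levels = levels, segment_angle = angle),
            class = "lead_geometry")
}

#' Serialize / deserialize a lead geometry as JSON
#'
#' Named maps (levels, segment angles) are stored as JSON objects so the
#' round trip is exact.
#'
#' @param lead a \code{lead_geometry}.
#' @param path file path.
#' @return \code{read_lead_json} returns a \code{lead_geometry} identical to
#'   the one written.
#' @export
write_lead_json <- function(lead, path) {
  stopifnot(inherits(lead, "lead_geometry"))
  obj <- list(lead_code = lead$lead_code, contacts = lead$contacts,
              levels = as.list(lead$levels),
              segment_angle = as.list(lead$segment_angle))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lead_json
#' @export
read_lead_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(lead_code = obj$lead_code, contacts = obj$contacts,
                 levels = vapply(obj$levels, as.integer, 0L),
                 segment_angle = vapply(obj$segment_angle, as.character, "")),
            class = "lead_geometry")
}

#' @export
print.lead_geometry <- function(x, ...) {
  cat("<lead_geometry>", x$lead_code, "with", length(x$contacts),
      "contacts:", paste(x$contacts, collapse = " "), "\n")
  invisible(x)
}

# Segmented (non-ring) contacts of a lead.
segmented_contacts <- function(lead) {
  lead$contacts[lead$segment_angle[lead$contacts] != "ring"]
}

#' Construct a bipolar sensing/stimulation pair
#'
#' @param lead a \code{lead_geometry}.
#' @param anode,cathode contact names on the lead; must differ.
#' @return a \code{bipolar_pair} with a \code{"E1a-E2a"}-style label.
#' @export
bipolar_pair <- function(lead, anode, cathode) {
  stopifnot(inherits(lead, "lead_geometry"))
  if (!all(c(anode, cathode) %in% lead$contacts))
    stop("contacts not on lead ", lead$lead_code, ": ",
         paste(setdiff(c(anode, cathode), lead$contacts), collapse = ", "),
         call. = FALSE)
  if (anode == cathode) stop("anode and cathode must differ", call. = FALSE)
  structure(list(anode = anode, cathode = cathode,
                 label = paste0(anode, "-", cathode)),
            class = "bipolar_pair")
}

#' Stimulation setting
#'
#' Amplitude mode (\code{"V"} constant-voltage or \code{"mA"} constant-current)
#' is carried explicitly and never converted.
#'
#' @param amplitude stimulation amplitude, > 0.
#' @param mode \code{"V"} or \code{"mA"}.
#' @param rate pulse rate in Hz.
#' @param pulse_width_us pulse width in microseconds.
#' @param duration_s train/burst duration in seconds.
#' @param cathode stimulating cathode contact name.
#' @param anode returning anode: a contact name or \code{"case"} (monopolar).
#' @export
stim_setting <- function(amplitude, mode = c("V", "mA"), rate, pulse_width_us,
                         duration_s, cathode = "E1", anode = "case") {
  mode <- match.arg(mode)
  # amplitude 0 is permitted as an explicit sham (no pulses delivered)
  stopifnot(amplitude >= 0, rate > 0, duration_s > 0, pulse_width_us > 0)
  structure(list(amplitude = amplitude, mode = mode, rate = rate,
                 pulse_width_us = pulse_width_us, duration_s = duration_s,
                 cathode = cathode, anode = anode),
            class = "stim_setting")
}

# A stimulation event placed inside a recording [onset, offset) in seconds.
stim_event <- function(setting, onset, offset) {
  stopifnot(onset >= 0, offset > onset)
  structure(list(setting = setting, onset = onset, offset = offset),
            class = "stim_event")
}

#' Assemble a multichannel recording
#'
#' Channel labels follow the \code{"LEAD_Ex-Ey"} dialect, e.g.
#' \code{"HC_E0-E3"}. Samples are microvolts, channels in rows.
#'
#' @param samples numeric matrix, channels x time, in uV.
#' @param fs sampling rate in Hz (default configuration uses 200-800 Hz).
#' @param channels data.frame with columns \code{label}, \code{lead},
#'   \code{anode}, \code{cathode} and logical \code{valid}.
#' @param hp_cutoff,lp_cutoff hardware filter corner frequencies in Hz.
#' @param condition \code{"sling"} or \code{"free_roaming"}.
#' @param t0 session start time (seconds since an arbitrary epoch).
#' @export
new_recording <- function(samples, fs, channels, hp_cutoff = 0.5,
                          lp_cutoff = 100, condition = c("sling", "free_roaming"),
                          t0 = 0) {
  condition <- match.arg(condition)
  samples <- as.matrix(samples)
  stopifnot(is.numeric(fs), fs > 0, hp_cutoff < lp_cutoff,
            nrow(samples) == nrow(channels))
  if (!all(c("label", "lead", "anode", "cathode") %in% names(channels)))
    stop("channels table needs label/lead/anode/cathode columns", call. = FALSE)
  if (is.null(channels$valid)) channels$valid <- TRUE
  bad <- !grepl("^[A-Za-z]+(_[LR])?_E[0-9][abc]?-E[0-9][abc]?$", channels$label)
  if (any(bad))
    stop("channel label(s) not in LEAD_Ex-Ey dialect: ",
         paste(channels$label[bad], collapse = ", "), call. = FALSE)
  rownames(samples) <- channels$label
  structure(list(samples = samples, fs = fs, channels = channels,
                 hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
                 condition = condition, t0 = t0),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %.1f s @ %g Hz (%s)\n",
              nrow(x$samples), ncol(x$samples) / x$fs, x$fs, x$condition))
  cat("  channels:", paste(utils::head(x$channels$label, 8), collapse = " "),
      if (nrow(x$channels) > 8) "..." else "", "\n")
  invisible(x)
}

# Duration of a recording in seconds.
rec_duration <- function(rec) ncol(rec$samples) / rec$fs

# Extract one channel's sample vector by label.
rec_channel <- function(rec, channel) {
  i <- match(channel, rec$channels$label)
  if (is.na(i)) stop("no such channel: '", channel, "'", call. = FALSE)
  rec$samples[i, ]
}
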