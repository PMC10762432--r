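# Analytic dipole volume-conduction forward model.
#
# An infinite homogeneous medium replaces a tissue-resolved torso/head model:
# it preserves the qualitative structure of interest (attenuation ordering
# neck > ear > scalp, cross-ear > single-ear, near-parallel projection planes)
# without finite-element machinery. Units: positions mm, dipole moments mA*m,
# conductivity S/m, potentials mV. The conversion is handled once in
# point_lead_vector(): with distances in metres, d / (4*pi*sigma*|d|^3)
# is numerically the lead vector in mV per mA*m.

#' Electrode layout
#'
#' @param electrodes Numeric matrix (n x 3) of electrode positions in mm,
#'   rownames = electrode names, in a body frame with the dipole near the
#'   origin.
#' @param channels Named list; each element is `list(pos = , neg = )` naming
#'   the positive and negative terminal electrodes of one bipolar channel.
#' @return An object of class `electrode_layout`.
#' @export
electrode_layout <- function(electrodes, channels) {
  electrodes <- as.matrix(electrodes)
  if (ncol(electrodes) != 3L || is.null(rownames(electrodes))) {
    stop("`electrodes` must be an n x 3 matrix with rownames", call. = FALSE)
  }
  for (ch in names(channels)) {
    terms <- unlist(channels[[ch]][c("pos", "neg")])
    missing <- setdiff(terms, rownames(electrodes))
    if (length(missing) > 0) {
      stop("channel '", ch, "' references unknown electrode(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(electrodes = electrodes, channels = channels),
            class = "electrode_layout")
}

#' Default electrode layout
#'
#' Places the dipole at the origin of a body frame (x left-right, y
#' front-back, z below-above) with an ear cluster roughly 350 mm above and
#' 100 mm posterior of the heart, and wrist electrodes far to each side.
#' Scalp electrodes sit at helix + L/2 and helix + 3L/2 vertically; neck
#' electrodes at concha - L/2 and concha - 3L/2, so electrode-dipole
#' distances order neck < ear < scalp. The coordinates are declared desk-scale
#' fixtures, not anatomical reconstructions.
#'
#' @param L Vertical electrode spacing parameter in mm (the helix-concha
#'   separation).
#' @return An [electrode_layout()] with channels `wrist`, `scalp`, `ear`,
#'   `neck` plus the two-ear set `left_ear`, `right_ear`, `cross_ear`.
#' @export
default_electrode_layout <- function(L = 25) {
  hz <- 330 + L                      # left helix height (directly above concha)
  el <- rbind(
    "left wrist"   = c(400, 0, -300),
    "right wrist"  = c(-400, 0, -300),
    "left concha"  = c(80, 100, 330),
    "left helix"   = c(80, 100, hz),
    "right concha" = c(-80, 100, 330),
    "right helix"  = c(-80, 100, hz),
    "lower scalp"  = c(80, 100, hz + L / 2),
    "upper scalp"  = c(80, 100, hz + 3 * L / 2),
    "upper neck"   = c(80, 100, 330 - L / 2),
    "lower neck"   = c(80, 100, 330 - 3 * L / 2)
  )
  colnames(el) <- c("x", "y", "z")
  electrode_layout(el, list(
    wrist     = list(pos = "left wrist", neg = "right wrist"),
    scalp     = list(pos = "lower scalp", neg = "upper scalp"),
    ear       = list(pos = "left concha", neg = "left helix"),
    neck      = list(pos = "lower neck", neg = "upper neck"),
    left_ear  = list(pos = "left concha", neg = "left helix"),
    right_ear = list(pos = "right helix", neg = "right concha"),
    cross_ear = list(pos = "left helix", neg = "right concha")
  ))
}

#' Potential of a current dipole in an infinite homogeneous medium
#'
#' `phi = p . (r_obs - r_dip) / (4 pi sigma |r_obs - r_dip|^3)`.
#'
#' @param p Dipole moment, length-3, mA*m.
#' @param r_dip Dipole position, mm.
#' @param r_obs Observation point, mm; must be > 1 mm from the dipole.
#' @param sigma Medium conductivity, S/m.
#' @return Potential in mV.
#' @examples
#' dipole_potential(c(0, 0, 1), c(0, 0, 0), c(0, 0, 100), 0.2)  # ~39.8 mV
#' @export
dipole_potential <- function(p, r_dip, r_obs, sigma) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  d <- (r_obs - r_dip) / 1000       # metres
  dist <- sqrt(sum(d^2))
  if (dist <= 1e-3) stop("observation point within 1 mm of the dipole", call. = FALSE)
  sum(p * d) / (4 * pi * sigma * dist^3)
}

# Point lead function g(r_obs): phi(mV) = p(mA*m) . g.
point_lead_vector <- function(r_obs, r_dip, sigma) {
  d <- (r_obs - r_dip) / 1000
  dist <- sqrt(sum(d^2))
  if (dist <= 1e-3) stop("electrode within 1 mm of the dipole", call. = FALSE)
  d / (4 * pi * sigma * dist^3)
}

#' Lead field from an electrode layout
#'
#' One lead vector per bipolar channel: `l = g(pos) - g(neg)` where `g` is
#' the point lead function of the dipole medium. Swapping terminals negates
#' the lead vector.
#'
#' @param layout An [electrode_layout()].
#' @param sigma Medium conductivity in S/m.
#' @param dipole_pos Dipole position in mm.
#' @return An object of class `lead_field`: list with `leads` (channels x 3
#'   matrix, mV per mA*m), `sigma`, `dipole_pos`, `channels`.
#' @export
lead_field_from_layout <- function(layout, sigma = 0.2, dipole_pos = c(0, 0, 0)) {
  stopifnot(inherits(layout, "electrode_layout"))
  chans <- names(layout$channels)
  leads <- matrix(0, nrow = length(chans), ncol = 3L,
                  dimnames = list(chans, c("x", "y", "z")))
  for (ch in chans) {
    pr <- layout$channels[[ch]]
    leads[ch, ] <- point_lead_vector(layout$electrodes[pr$pos, ], dipole_pos, sigma) -
      point_lead_vector(layout$electrodes[pr$neg, ], dipole_pos, sigma)
  }
  structure(list(leads = leads, sigma = sigma, dipole_pos = dipole_pos,
                 channels = chans),
            class = "lead_field")
}

#' Gain-specified lead field
#'
#' Constructs channels whose lead vectors are explicit gains along given
#' directions, bypassing the dipole geometry. With the default heart-vector
#' parameters the dominant component is x, so a channel with gain `g` along
#' `(1, 0, 0)` has an R amplitude of about `g` mV. Used to set up controlled
#' channel-attenuation experiments (e.g. neck:ear:scalp = 4:2:1).
#'
#' @param gains Named numeric vector, one gain per channel (mV per mA*m along
#'   the channel direction).
#' @param directions Optional channels x 3 matrix of lead directions
#'   (normalized internally); defaults to `(1, 0, 0)` for every channel.
#' @return A `lead_field`.
#' @export
lead_field_gains <- function(gains, directions = NULL) {
  chans <- names(gains)
  if (is.null(chans) || anyDuplicated(chans)) {
    stop("`gains` must be uniquely named", call. = FALSE)
  }
  if (is.null(directions)) {
    directions <- matrix(rep(c(1, 0, 0), each = length(chans)),
                         nrow = length(chans),
                         dimnames = list(chans, c("x", "y", "z")))
  }
  directions <- as.matrix(directions)[chans, , drop = FALSE]
  norms <- sqrt(rowSums(directions^2))
  if (any(norms == 0)) stop("zero-length lead direction", call. = FALSE)
  leads <- directions / norms * gains
  structure(list(leads = leads, sigma = NA_real_, dipole_pos = c(0, 0, 0),
                 channels = chans),
            class = "lead_field")
}

#' Simulated cardiac rhythm of one channel
#'
#' The noiseless projection `l(channel) . p(t)` on the canonical cycle axis.
#'
#' @param hv A `heart_vector`.
#' @param lf A `lead_field`.
#' @param channel Channel name present in `lf`.
#' @return Numeric trace in mV, same length and axis as `hv`.
#' @export
simulate_channel_rhythm <- function(hv, lf, channel) {
  stopifnot(inherits(hv, "heart_vector"), inherits(lf, "lead_field"))
  if (!channel %in% lf$channels) {
    stop("unknown channel '", channel, "'", call. = FALSE)
  }
  as.vector(lf$leads[channel, ] %*% hv$p)
}
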