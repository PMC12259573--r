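#' Standard 10-20 / 10-10 scalp coordinate table
#'
#' Two-dimensional electrode positions on the unit head disc, derived from
#' the standard 10-20 spherical grid by azimuthal-equidistant projection
#' (vertex Cz at the origin, nose along +y, right ear along +x, outer 10-20
#' ring at radius 0.5). Positions are used for nearest-neighbour geometry in
#' bad-channel detection; channel names not present in this table are
#' rejected by the data model.
#'
#' @return data.frame with columns `name`, `x`, `y`.
#' @export
#' @examples
#' pos <- ten_twenty_positions()
#' pos[pos$name %in% c("Cz", "Pz", "FCz"), ]
ten_twenty_positions <- function() {
  # (name, inclination from vertex in degrees, azimuth from nose in degrees;
  # negative azimuth = left hemisphere)
  spec <- rbind(
    c("Fpz", 72, 0), c("AFz", 54, 0), c("Fz", 36, 0), c("FCz", 18, 0),
    c("Cz", 0, 0), c("CPz", 18, 180), c("Pz", 36, 180), c("POz", 54, 180),
    c("Oz", 72, 180),
    # outer 10-20 ring (36 degree steps)
    c("Fp1", 72, -18), c("Fp2", 72, 18), c("AF7", 72, -36), c("AF8", 72, 36),
    c("F7", 72, -54), c("F8", 72, 54), c("FT7", 72, -72), c("FT8", 72, 72),
    c("T7", 72, -90), c("T8", 72, 90), c("TP7", 72, -108), c("TP8", 72, 108),
    c("P7", 72, -126), c("P8", 72, 126), c("PO7", 72, -144), c("PO8", 72, 144),
    c("O1", 72, -162), c("O2", 72, 162),
    # frontal arc Fz -> F7/F8
    c("F1", 45, -13.5), c("F3", 54, -27), c("F5", 63, -40.5),
    c("F2", 45, 13.5), c("F4", 54, 27), c("F6", 63, 40.5),
    # fronto-central arc FCz -> FT7/FT8
    c("FC1", 31.5, -18), c("FC3", 45, -36), c("FC5", 58.5, -54),
    c("FC2", 31.5, 18), c("FC4", 45, 36), c("FC6", 58.5, 54),
    # central coronal line
    c("C1", 18, -90), c("C3", 36, -90), c("C5", 54, -90),
    c("C2", 18, 90), c("C4", 36, 90), c("C6", 54, 90),
    # centro-parietal arc CPz -> TP7/TP8
    c("CP1", 31.5, -162), c("CP3", 45, -144), c("CP5", 58.5, -126),
    c("CP2", 31.5, 162), c("CP4", 45, 144), c("CP6", 58.5, 126),
    # parietal arc Pz -> P7/P8
    c("P1", 45, -166.5), c("P3", 54, -153), c("P5", 63, -139.5),
    c("P2", 45, 166.5), c("P4", 54, 153), c("P6", 63, 139.5),
    c("PO3", 63, -162), c("PO4", 63, 162)
  )
  incl <- as.numeric(spec[, 2])
  az <- as.numeric(spec[, 3]) * pi / 180
  r <- incl / 144 # outer ring (72 deg) maps to radius 0.5
  data.frame(name = spec[, 1], x = r * sin(az), y = r * cos(az),
             stringsAsFactors = FALSE)
}

#' Default 28-channel montage
#'
#' The harmonized montage used by the synthetic generator: a 28-channel
#' 10-20 subset covering the whole scalp, including the midline electrodes
#' Fz, Cz, Pz and Oz (Pz serves as the common offline reference downstream).
#'
#' @return character vector of 28 channel names.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
    "O1", "Oz", "O2")
}

# Position lookup for a vector of channel names; errors on unknown names.
channel_positions <- function(names) {
  tab <- ten_twenty_positions()
  idx <- match(names, tab$name)
  if (anyNA(idx)) {
    stop("unknown channel name(s): ", paste(names[is.na(idx)], collapse = ", "),
         " (not in the bundled 10-20 position table)")
  }
  out <- tab[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
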