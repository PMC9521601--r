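# Channel montages: named source-detector channels with 2-D scalp layout
# coordinates.  Channels are named by their two nearest 10-10 electrodes
# ("FP1-AF7"); a channel's layout position is the midpoint of the two
# electrode positions.

# Flattened azimuthal-equidistant 10-10 layout: Cz at the origin, the outer
# 10 % ring (through FP1/FP2, AF7/AF8, TP8, P8) is the unit circle, nose up
# (+y), right ear +x.  Interior rows are interpolated between the midline
# and the outer ring.  Frozen static table: layout feeds plots only, never
# statistics.
.ELECTRODE_XY <- local({
  deg <- pi / 180
  ring <- function(az) c(sin(az * deg), cos(az * deg))
  lerp <- function(a, b, f) a + f * (b - a)
  fp1 <- ring(-18); fp2 <- ring(18)
  af7 <- ring(-54); af8 <- ring(54)
  f7  <- ring(-72); f8  <- ring(72)
  tp8 <- ring(126); p8  <- ring(144)
  afz <- c(0, 0.75); fz <- c(0, 0.5); cpz <- c(0, -0.25); pz <- c(0, -0.5)
  tab <- rbind(
    FP1 = fp1, FP2 = fp2, AF7 = af7, AF8 = af8,
    AF3 = lerp(afz, af7, 0.5), AF4 = lerp(afz, af8, 0.5),
    F5  = lerp(fz, f7, 0.75),  F6  = lerp(fz, f8, 0.75),
    C4  = c(0.5, 0), C6 = c(0.75, 0),
    CP4 = lerp(cpz, tp8, 0.5), CP6 = lerp(cpz, tp8, 0.75),
    P4  = lerp(pz, p8, 0.5),   P6  = lerp(pz, p8, 0.75),
    TP8 = tp8, P8 = p8)
  colnames(tab) <- c("x", "y")
  round(tab, 4)
})

# 18 channels per subject, in montage order V1..V18.
.DEFAULT_CHANNELS <- c(
  "FP1-AF7", "AF7-F5", "FP1-AF3", "AF3-F5", "FP2-AF8", "AF8-F6",
  "FP2-AF4", "AF4-F6", "C4-C6", "C4-CP4", "C6-CP6", "CP4-CP6",
  "CP6-TP8", "CP6-P6", "CP4-P4", "P4-P6", "TP8-P8", "P8-P6")

#' Construct a channel montage
#'
#' A montage is an ordered set of uniquely named channels with one 2-D
#' layout coordinate each, tagged with the subject role it belongs to.
#'
#' @param channels character vector of channel names (unique).
#' @param positions numeric matrix with one row per channel and columns
#'   `x`, `y` (unitless scalp-projection plane).
#' @param subject_role `"teacher"` or `"child"`.
#' @return An object of class `channel_montage`.
#' @seealso [default_montage()], [read_montage()]
#' @export
channel_montage <- function(channels, positions, subject_role) {
  subject_role <- match.arg(subject_role, c("teacher", "child"))
  channels <- as.character(channels)
  if (anyDuplicated(channels))
    stop("duplicate channel names in montage: ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "))
  positions <- as.matrix(positions)
  if (nrow(positions) != length(channels) || ncol(positions) != 2)
    stop("positions must be a ", length(channels), "x2 matrix (one x,y row ",
         "per channel)")
  if (anyNA(positions)) stop("montage positions contain missing values")
  dimnames(positions) <- list(channels, c("x", "y"))
  structure(list(channels = channels, positions = positions,
                 subject_role = subject_role),
            class = "channel_montage")
}

#' Default 18-channel prefrontal / right-temporoparietal montage
#'
#' The embedded montage covers the prefrontal cortex (PFC) and right
#' temporoparietal junction (rTPJ) with 18 source-detector channels named
#' by their flanking 10-10 electrodes.  Each channel position is the
#' midpoint of its two electrode coordinates in an embedded flattened
#' 10-10 scalp projection.  Teacher and child use the same channel set.
#'
#' @param role `"teacher"` or `"child"`.
#' @return A [channel_montage] with 18 channels, first channel `"FP1-AF7"`.
#' @examples
#' m <- default_montage("teacher")
#' m$channels[1]
#' @export
default_montage <- function(role = c("teacher", "child")) {
  role <- match.arg(role)
  pos <- t(vapply(.DEFAULT_CHANNELS, function(ch) {
    el <- strsplit(ch, "-", fixed = TRUE)[[1]]
    colMeans(.ELECTRODE_XY[el, , drop = FALSE])
  }, numeric(2)))
  channel_montage(.DEFAULT_CHANNELS, pos, role)
}

#' Embedded 10-10 electrode coordinates
#'
#' The static 2-D electrode coordinate table used by [default_montage()].
#'
#' @return A matrix with electrode rows and `x`, `y` columns.
#' @export
electrode_positions <- function() .ELECTRODE_XY

#' Read / write a montage TSV
#'
#' Tab-separated file with header `channel`, `x`, `y`.
#'
#' @param path file path.
#' @param subject_role `"teacher"` or `"child"`.
#' @return `read_montage()` a [channel_montage]; `write_montage()` the path,
#'   invisibly.
#' @export
read_montage <- function(path, subject_role = "teacher") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("channel", "x", "y")
  if (!all(need %in% names(df)))
    stop("montage file must have columns channel, x, y")
  channel_montage(df$channel, as.matrix(df[, c("x", "y")]), subject_role)
}

#' @rdname read_montage
#' @param montage a [channel_montage].
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(channel = montage$channels,
                   x = montage$positions[, "x"],
                   y = montage$positions[, "y"])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.channel_montage <- function(x, ...) {
  cat("<channel_montage> ", length(x$channels), " channels, role=",
      x$subject_role, "\n", sep = "")
  cat("  ", paste(utils::head(x$channels, 6), collapse = ", "),
      if (length(x$channels) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}
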