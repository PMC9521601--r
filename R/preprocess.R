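# Raw-intensity -> concentration preprocessing: band-pass filtering,
# despiking and the modified Beer-Lambert law (MBLL).

# Molar extinction coefficients of hemoglobin (mM^-1 cm^-1), standard
# compiled in-vitro spectra, at the two measurement wavelengths.
.EXTINCTION <- matrix(
  c(0.586, 1.5485,   # 760 nm: HbO2, HHb
    1.058, 0.6913),  # 850 nm: HbO2, HHb
  nrow = 2, byrow = TRUE,
  dimnames = list(c("760", "850"), c("HbO2", "HHb")))

#' Preprocessing configuration
#'
#' @param band_low,band_high band-pass edges in Hz (defaults 0.01 and 0.2:
#'   below the band lie slow global drifts, above it respiratory and
#'   cardiac physiology).
#' @param dpf_by_wavelength differential pathlength factors, named by
#'   wavelength in nm (defaults 7.25 at 760 nm, 6.38 at 850 nm).
#' @param source_detector_distance optode separation in cm (default 3.0,
#'   typical adult fNIRS).
#' @param despike_threshold robust-z threshold for spike detection
#'   (default 5).
#' @param despike_window rolling-median window length in samples (odd,
#'   default 11).
#' @param filter_order Butterworth order for each of the high- and low-pass
#'   stages (default 3).
#' @param filter_enabled,despike_enabled stage switches for the pipeline.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(band_low = 0.01, band_high = 0.2,
                              dpf_by_wavelength = c("760" = 7.25,
                                                    "850" = 6.38),
                              source_detector_distance = 3.0,
                              despike_threshold = 5,
                              despike_window = 11,
                              filter_order = 3,
                              filter_enabled = TRUE,
                              despike_enabled = TRUE) {
  if (!(band_low > 0 && band_low < band_high))
    stop("need 0 < band_low < band_high")
  if (any(dpf_by_wavelength <= 0)) stop("all DPF values must be > 0")
  if (source_detector_distance <= 0)
    stop("source_detector_distance must be > 0")
  if (despike_window < 3 || despike_window %% 2 == 0)
    stop("despike_window must be odd and >= 3")
  structure(list(band_low = band_low, band_high = band_high,
                 dpf_by_wavelength = dpf_by_wavelength,
                 source_detector_distance = source_detector_distance,
                 despike_threshold = despike_threshold,
                 despike_window = despike_window,
                 filter_order = filter_order,
                 filter_enabled = filter_enabled,
                 despike_enabled = despike_enabled),
            class = "preprocess_config")
}

#' Zero-phase band-pass filter
#'
#' Cascade of an order-`filter_order` Butterworth high-pass at `band_low`
#' and low-pass at `band_high`, each applied forward-backward
#' ([signal::filtfilt()]) so the net phase response is zero — essential
#' when the downstream statistic is a cross-subject correlation.  The
#' channel mean is removed before filtering and is NOT restored: the
#' high-pass removes DC by design.
#'
#' @param samples numeric T x C matrix.
#' @param sampling_rate Hz.
#' @param config a [preprocess_config].
#' @return Filtered matrix of the same shape.
#' @export
bandpass <- function(samples, sampling_rate, config = preprocess_config()) {
  samples <- as.matrix(samples)
  ny <- sampling_rate / 2
  if (!(config$band_low > 0 && config$band_high < ny))
    stop("band edges must lie strictly inside (0, Nyquist = ", ny, " Hz)")
  if (nrow(samples) <= 3 * config$filter_order * 3)
    stop("series too short for order-", config$filter_order, " filtering")
  hp <- signal::butter(config$filter_order, config$band_low / ny,
                       type = "high")
  lp <- signal::butter(config$filter_order, config$band_high / ny,
                       type = "low")
  out <- apply(samples, 2, function(x) {
    x <- x - mean(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  })
  dimnames(out) <- dimnames(samples)
  out
}

#' Remove spike artifacts
#'
#' Samples whose deviation from a rolling median exceeds
#' `despike_threshold` robust-z units (MAD-scaled over the whole channel)
#' are replaced by linear interpolation of the neighboring clean samples;
#' everything else passes through unchanged.
#'
#' @inheritParams bandpass
#' @return Despiked matrix of the same shape.
#' @export
despike <- function(samples, config = preprocess_config()) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 10) stop("despike needs at least 10 samples")
  k <- min(config$despike_window,
           if (nrow(samples) %% 2 == 1) nrow(samples) else nrow(samples) - 1)
  out <- apply(samples, 2, function(x) {
    med <- zoo::rollmedian(x, k, fill = NA, align = "center")
    # pad edges with the nearest interior rolling median
    med <- zoo::na.locf(zoo::na.locf(med, na.rm = FALSE), fromLast = TRUE)
    resid <- x - med
    s <- stats::mad(resid)
    # locally monotone smooth series have mostly zero residuals; fall back
    # to a mean-absolute scale so isolated spikes are still detectable
    if (s == 0) s <- 1.4826 * mean(abs(resid))
    if (s == 0) return(x)                  # constant / noise-free channel
    bad <- abs(resid) > config$despike_threshold * s
    if (!any(bad)) return(x)
    x[bad] <- NA
    as.numeric(zoo::na.approx(x, na.rm = FALSE, rule = 2))
  })
  dimnames(out) <- dimnames(samples)
  out
}

#' Modified Beer-Lambert conversion
#'
#' Converts dual-wavelength raw intensities to chromophore concentration
#' changes.  Optical density change is taken against the whole-series mean
#' intensity per channel, `dOD(t) = -log10(I(t) / mean(I))`, the 2x2
#' extinction system is solved per channel with effective path length
#' `distance * DPF(wavelength)`, and the baseline step subtracts each
#' concentration channel's whole-timeline mean (so the choice of intensity
#' reference only shifts a constant that the baseline removes, and the
#' conversion is exactly invertible for mean-zero concentrations, see
#' [forward_raw()]).  Concentration units follow the extinction table (mM
#' here); only consistency matters downstream (the pipeline's statistics
#' are rank-based).
#'
#' @param intensity_760,intensity_850 strictly positive T x C intensity
#'   matrices, same shape.
#' @param config a [preprocess_config].
#' @return List with elements `hbo2` and `hhb`, each T x C.
#' @export
mbll <- function(intensity_760, intensity_850,
                 config = preprocess_config()) {
  i760 <- as.matrix(intensity_760); i850 <- as.matrix(intensity_850)
  if (!all(dim(i760) == dim(i850)))
    stop("the two wavelength series must have identical shape")
  for (nm in c("760", "850")) {
    m <- if (nm == "760") i760 else i850
    if (any(m <= 0)) {
      bad <- which(m <= 0, arr.ind = TRUE)[1, ]
      ch <- if (!is.null(colnames(m))) colnames(m)[bad[2]] else bad[2]
      stop("non-positive intensity at ", nm, " nm, channel ", ch,
           ", sample ", bad[1])
    }
  }
  dpf <- config$dpf_by_wavelength
  if (!all(c("760", "850") %in% names(dpf)))
    stop("dpf_by_wavelength must name wavelengths 760 and 850")
  d <- config$source_detector_distance
  E <- .EXTINCTION
  if (abs(det(E)) < 1e-12) stop("singular extinction matrix")
  Einv <- solve(E)
  od760 <- -log10(sweep(i760, 2, colMeans(i760), "/")) / (d * dpf[["760"]])
  od850 <- -log10(sweep(i850, 2, colMeans(i850), "/")) / (d * dpf[["850"]])
  hbo2 <- Einv[1, 1] * od760 + Einv[1, 2] * od850
  hhb  <- Einv[2, 1] * od760 + Einv[2, 2] * od850
  hbo2 <- sweep(hbo2, 2, colMeans(hbo2))   # baseline: mean of timeline
  hhb <- sweep(hhb, 2, colMeans(hhb))
  dimnames(hbo2) <- dimnames(i760); dimnames(hhb) <- dimnames(i760)
  list(hbo2 = hbo2, hhb = hhb)
}

#' Full raw-to-concentration pipeline
#'
#' Stages in order: band-pass filter, despike, MBLL (which applies the
#' whole-series-mean baseline).  Because the MBLL log-ratio needs a
#' positive baseline, the filter stage operates on the intensity
#' fluctuation and adds each channel's mean intensity back afterwards.
#' Stages can be disabled via the config switches, in which case the
#' result equals plain [mbll()] output.
#'
#' @param intensity_760,intensity_850 raw intensity matrices.
#' @param montage a [channel_montage] for the output recording.
#' @param sampling_rate Hz.
#' @param config a [preprocess_config].
#' @param chromophore which chromophore to return in the recording.
#' @return A [subject_recording] of the selected chromophore.
#' @export
preprocess_pipeline <- function(intensity_760, intensity_850, montage,
                                sampling_rate = 7.81,
                                config = preprocess_config(),
                                chromophore = c("HbO2", "HHb")) {
  chromophore <- match.arg(chromophore)
  i760 <- as.matrix(intensity_760); i850 <- as.matrix(intensity_850)
  if (config$filter_enabled) {
    i760 <- sweep(bandpass(i760, sampling_rate, config), 2,
                  colMeans(i760), "+")
    i850 <- sweep(bandpass(i850, sampling_rate, config), 2,
                  colMeans(i850), "+")
  }
  if (config$despike_enabled) {
    i760 <- despike(i760, config)
    i850 <- despike(i850, config)
  }
  conc <- mbll(i760, i850, config)
  samples <- if (chromophore == "HbO2") conc$hbo2 else conc$hhb
  subject_recording(samples, montage, sampling_rate, chromophore)
}

#' Embedded hemoglobin extinction coefficients
#'
#' @return 2x2 matrix (rows 760/850 nm, columns HbO2/HHb), mM^-1 cm^-1.
#' @export
extinction_coefficients <- function() .EXTINCTION
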