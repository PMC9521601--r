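# Synthetic dyad generator: a shared low-pass latent drive between chosen
# teacher and child channel subsets, white idiosyncratic noise, and
# additive physiological components (1/f drift plus Mayer-wave,
# respiratory and cardiac sinusoids).  This is the validation test bed for
# the whole pipeline: the planted coupling and hub channels are known, so
# detection power and hub recovery can be measured.

#' Synthetic dyad configuration
#'
#' Coupled channels are `a * s(t) + sqrt(1 - a^2) * eps` with `s` a shared
#' low-pass Gaussian latent, `a` the coupling, and `eps` unit white
#' Gaussian noise; uncoupled channels are noise only.  All channels
#' additionally carry a 1/f drift and the configured physiological
#' sinusoids with random phases.  With physiological variance `v`, the
#' Pearson correlation between two coupled channels is `a^2 / (1 + v)`.
#'
#' @param n_samples recording length T (default 300, about 38 s at
#'   7.81 Hz).
#' @param sampling_rate Hz (default 7.81).
#' @param teacher_coupled teacher channels carrying the latent (default
#'   the three prefrontal channels `FP2-AF8`, `FP1-AF7`, `AF3-F5`).
#' @param child_coupled child channels carrying the latent (default the
#'   three right-temporoparietal channels `CP4-CP6`, `C4-C6`, `CP6-TP8`).
#' @param coupling latent weight `a` in `[0, 1)`; the default 0.78 yields
#'   a coupled-pair Spearman correlation of about 0.5 under the default
#'   noise.
#' @param lag child latent delay in samples (default 0).
#' @param one_over_f_sd standard deviation of the 1/f drift (default 0.3).
#' @param one_over_f_exponent spectral exponent beta of the drift
#'   (default 1).
#' @param sinusoid_freqs,sinusoid_amps physiological sinusoid frequencies
#'   (Hz) and amplitudes: defaults 0.1 Hz (Mayer waves, amp 0.3), 0.3 Hz
#'   (respiration, amp 0.2), 1.2 Hz (cardiac, amp 0.2).
#' @param seed integer RNG seed.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_samples = 300, sampling_rate = 7.81,
                         teacher_coupled = c("FP2-AF8", "FP1-AF7",
                                             "AF3-F5"),
                         child_coupled = c("CP4-CP6", "C4-C6", "CP6-TP8"),
                         coupling = 0.78, lag = 0,
                         one_over_f_sd = 0.3, one_over_f_exponent = 1,
                         sinusoid_freqs = c(0.1, 0.3, 1.2),
                         sinusoid_amps = c(0.3, 0.2, 0.2),
                         seed = 1L) {
  if (coupling < 0 || coupling >= 1)
    stop("coupling must lie in [0, 1)")
  if (length(sinusoid_freqs) != length(sinusoid_amps))
    stop("sinusoid_freqs and sinusoid_amps must have equal length")
  if (lag < 0 || lag >= n_samples) stop("lag must be in [0, n_samples)")
  structure(list(n_samples = as.integer(n_samples),
                 sampling_rate = sampling_rate,
                 teacher_coupled = teacher_coupled,
                 child_coupled = child_coupled,
                 coupling = coupling, lag = as.integer(lag),
                 one_over_f_sd = one_over_f_sd,
                 one_over_f_exponent = one_over_f_exponent,
                 sinusoid_freqs = sinusoid_freqs,
                 sinusoid_amps = sinusoid_amps,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Physiological noise variance of a configuration
#'
#' Total variance of the additive 1/f and sinusoidal components (a
#' sinusoid of amplitude A contributes A^2/2).
#'
#' @param config a [synth_config].
#' @return Scalar variance.
#' @export
phys_noise_variance <- function(config)
  config$one_over_f_sd^2 + sum(config$sinusoid_amps^2) / 2

#' Coupling calibration helpers
#'
#' `spearman_from_pearson()` converts a Pearson correlation of a bivariate
#' Gaussian to the corresponding Spearman correlation,
#' `rho_S = (6/pi) asin(rho_P / 2)`; `pearson_from_spearman()` inverts it.
#' `calibrate_coupling()` returns the latent weight `a` for which two
#' coupled channels reach a target Spearman correlation under the
#' configured physiological noise: `a^2 = rho_P * (1 + v)`.
#'
#' @param rho_p,rho_s Pearson / Spearman correlation.
#' @param target_spearman desired coupled-pair Spearman correlation.
#' @param config a [synth_config] (for its noise variance).
#' @return Correlation or coupling scalar.
#' @export
spearman_from_pearson <- function(rho_p) (6 / pi) * asin(rho_p / 2)

#' @rdname spearman_from_pearson
#' @export
pearson_from_spearman <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' @rdname spearman_from_pearson
#' @export
calibrate_coupling <- function(target_spearman, config = synth_config()) {
  rho_p <- pearson_from_spearman(target_spearman)
  a2 <- rho_p * (1 + phys_noise_variance(config))
  if (a2 >= 1)
    stop("target correlation unreachable under the configured noise ",
         "(required coupling >= 1)")
  sqrt(a2)
}

# low-pass (0.2 Hz) unit-variance Gaussian process; extra warmup samples
# are generated and discarded to avoid filter edge effects
.lowpass_latent <- function(n, sampling_rate) {
  warm <- 200L
  lp <- signal::butter(3, 0.2 / (sampling_rate / 2), type = "low")
  x <- signal::filtfilt(lp, stats::rnorm(n + 2 * warm))
  x <- x[(warm + 1):(warm + n)]
  x / stats::sd(x)
}

# 1/f^beta noise by spectral shaping, scaled to the requested sd
.one_over_f <- function(n, sd_target, beta) {
  if (sd_target <= 0) return(numeric(n))
  freqs <- seq_len(floor(n / 2))
  amp <- freqs^(-beta / 2)
  phase <- stats::runif(length(freqs), 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(length(freqs) + 1)] <- spec
  full[n:(n - length(freqs) + 2)] <- Conj(spec[seq_len(length(freqs) - 1)])
  x <- Re(stats::fft(full, inverse = TRUE))
  sd_target * x / stats::sd(x)
}

.phys_noise <- function(n, config) {
  t_sec <- (seq_len(n) - 1) / config$sampling_rate
  x <- .one_over_f(n, config$one_over_f_sd, config$one_over_f_exponent)
  for (k in seq_along(config$sinusoid_freqs))
    x <- x + config$sinusoid_amps[k] *
      sin(2 * pi * config$sinusoid_freqs[k] * t_sec +
            stats::runif(1, 0, 2 * pi))
  x
}

#' Generate a synthetic dyad
#'
#' Deterministic given `config$seed`.  Teacher channels in
#' `teacher_coupled` and child channels in `child_coupled` share the
#' low-pass latent (the child's copy delayed by `lag` samples); all other
#' channels are independent noise.
#'
#' @param config a [synth_config].
#' @param dyad_id label for the dyad.
#' @return A [dyad_recording].
#' @export
generate_dyad <- function(config = synth_config(), dyad_id = "synth") {
  set.seed(config$seed)
  tm <- default_montage("teacher"); cm <- default_montage("child")
  bad <- c(setdiff(config$teacher_coupled, tm$channels),
           setdiff(config$child_coupled, cm$channels))
  if (length(bad))
    stop("coupled channel(s) not in montage: ", paste(bad, collapse = ", "))
  n <- config$n_samples; a <- config$coupling
  s_full <- .lowpass_latent(n + config$lag, config$sampling_rate)
  s_teacher <- s_full[(config$lag + 1):(config$lag + n)]
  s_child <- s_full[seq_len(n)]
  build <- function(montage, coupled, s) {
    m <- vapply(montage$channels, function(ch) {
      eps <- stats::rnorm(n)
      base <- if (ch %in% coupled) a * s + sqrt(1 - a^2) * eps else eps
      base + .phys_noise(n, config)
    }, numeric(n))
    subject_recording(m, montage, config$sampling_rate, "HbO2")
  }
  teacher <- build(tm, config$teacher_coupled, s_teacher)
  child <- build(cm, config$child_coupled, s_child)
  validate_dyad(teacher, child, dyad_id)
}

#' Generate a cohort of mutually independent dyads
#'
#' Coupling is forced to 0 and each dyad gets its own seed
#' (`seed + i - 1`), so all channels are independent within and across
#' dyads — the negative control for type-I-error studies and for
#' cross-pairing probes.
#'
#' @param n_dyads number of dyads.
#' @param config a [synth_config]; its `coupling` is ignored (set to 0).
#' @return List of [dyad_recording]s named `null1`, `null2`, ...
#' @export
generate_null_cohort <- function(n_dyads, config = synth_config()) {
  lapply(seq_len(n_dyads), function(i) {
    cfg <- config
    cfg$coupling <- 0
    cfg$seed <- config$seed + i - 1L
    generate_dyad(cfg, dyad_id = paste0("null", i))
  })
}

#' Forward optical model (inverse of the MBLL conversion)
#'
#' Synthesizes dual-wavelength intensities from chromophore concentration
#' changes through the embedded extinction table:
#' `I = baseline * 10^(-dOD)` with
#' `dOD = (eps_HbO2 * hbo2 + eps_HHb * hhb) * distance * DPF`.  Because
#' [mbll()] references intensities to their own mean and mean-centers the
#' recovered concentrations, the round trip `mbll(forward_raw(x))`
#' recovers `x` exactly when the planted concentrations are mean-zero per
#' channel (and `x` minus its channel means otherwise).
#'
#' @param hbo2 T x C matrix of oxygenated-hemoglobin concentration
#'   changes, or a [subject_recording] holding them.
#' @param hhb matching deoxygenated-hemoglobin matrix; defaults to
#'   `-hbo2 / 3` (a typical inverse hemodynamic ratio).
#' @param config a [preprocess_config] (distance, DPF).
#' @param baseline_intensity positive baseline light intensity.
#' @return List with matrices `i760` and `i850`.
#' @export
forward_raw <- function(hbo2, hhb = NULL, config = preprocess_config(),
                        baseline_intensity = 1) {
  if (inherits(hbo2, "subject_recording")) hbo2 <- hbo2$samples
  hbo2 <- as.matrix(hbo2)
  if (is.null(hhb)) hhb <- -hbo2 / 3
  hhb <- as.matrix(hhb)
  if (!all(dim(hbo2) == dim(hhb)))
    stop("hbo2 and hhb must have identical shape")
  E <- .EXTINCTION; d <- config$source_detector_distance
  dpf <- config$dpf_by_wavelength
  od760 <- (E["760", "HbO2"] * hbo2 + E["760", "HHb"] * hhb) *
    d * dpf[["760"]]
  od850 <- (E["850", "HbO2"] * hbo2 + E["850", "HHb"] * hhb) *
    d * dpf[["850"]]
  i760 <- baseline_intensity * 10^(-od760)
  i850 <- baseline_intensity * 10^(-od850)
  if (any(!is.finite(i760)) || any(!is.finite(i850)) ||
      any(i760 <= 0) || any(i850 <= 0))
    stop("generated non-positive or non-finite intensity; rescale the ",
         "concentration amplitudes")
  list(i760 = i760, i850 = i850)
}
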