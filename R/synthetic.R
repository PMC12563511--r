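# Synthetic signals with known reversibility structure, and a two-group
# MEG-like cohort generator with a controllable irreversibility contrast.
#
# Reversible references: stationary linear Gaussian processes (white noise,
# Gaussian AR) and phase-randomized surrogates, which are time-symmetric in
# distribution. Irreversible references: the logistic map at r = 4 and the
# cohort generator's logistic-map-driven slow component.

#' Stationary Gaussian autoregressive series (time-reversible reference)
#'
#' Simulates `x_t = sum_i coeffs[i] * x_{t-i} + e_t` with Gaussian
#' innovations. Stationary linear Gaussian processes are statistically
#' time-reversible, so these serve as the null for irreversibility
#' statistics. `coeffs = numeric(0)` gives i.i.d. Gaussian noise.
#'
#' @param n Length of the returned series.
#' @param coeffs AR coefficients; the AR polynomial must have all roots
#'   outside the unit circle (stationarity).
#' @param sd Innovation standard deviation.
#' @param seed Optional integer seed for reproducibility.
#' @param burn Burn-in samples discarded (default 1000).
#' @return Numeric vector of length `n`.
#' @export
gen_gaussian_ar <- function(n, coeffs = numeric(0), sd = 1, seed = NULL,
                            burn = 1000L) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be a positive integer")
  if (length(coeffs)) {
    roots <- polyroot(c(1, -coeffs))
    if (any(Mod(roots) <= 1 + 1e-10))
      stop("nonstationary AR coefficients: roots of 1 - sum(a_i z^i) must lie outside the unit circle")
  }
  e <- stats::rnorm(n + burn, sd = sd)
  x <- if (length(coeffs)) as.numeric(stats::filter(e, coeffs, method = "recursive"))
       else e
  x[(burn + 1L):(burn + n)]
}

#' Logistic-map series (irreversible positive control)
#'
#' Iterates `x_{t+1} = r x_t (1 - x_t)`, discarding an initial transient.
#' At `r = 4` the orbit is chaotic on `[0, 1]` and strongly time-
#' irreversible, making it the standard positive control for asymmetry
#' statistics.
#'
#' @param n Length of the returned series.
#' @param r Map parameter in `(0, 4]` (default 4).
#' @param x0 Initial condition in `(0, 1)`.
#' @param transient Iterations discarded before recording (default 1000).
#' @return Numeric vector of length `n`.
#' @examples
#' gen_logistic_map(2, x0 = 0.2, transient = 0)  # 0.64 0.9216
#' @export
gen_logistic_map <- function(n, r = 4, x0 = 0.2, transient = 1000L) {
  n <- as.integer(n); transient <- as.integer(transient)
  if (n < 1L) stop("`n` must be a positive integer")
  if (!(x0 > 0 && x0 < 1)) stop("`x0` must lie strictly inside (0, 1)")
  if (!(r > 0 && r <= 4)) stop("`r` must lie in (0, 4]")
  x <- numeric(n + transient)
  cur <- x0
  for (t in seq_len(n + transient)) {
    cur <- r * cur * (1 - cur)
    x[t] <- cur
  }
  x[(transient + 1L):(transient + n)]
}

#' Phase-randomized surrogate (linear-Gaussian null)
#'
#' Preserves the amplitude spectrum of the input exactly while randomizing
#' Fourier phases under Hermitian symmetry, destroying any nonlinear
#' temporal asymmetry. The output is real-valued with the same power
#' spectrum as the input.
#'
#' @param x Numeric vector of length at least 64.
#' @param seed Optional integer seed.
#' @return Numeric vector, same length as `x`.
#' @export
phase_randomized_surrogate <- function(x, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 64L) stop("surrogate construction needs at least 64 samples")
  X <- stats::fft(x)
  amp <- Mod(X)
  ph <- Arg(X)
  half <- if (n %% 2L == 0L) n / 2L - 1L else (n - 1L) / 2L
  new_ph <- stats::runif(half, 0, 2 * pi)
  ph[2L:(half + 1L)] <- new_ph
  ph[n:(n - half + 1L)] <- -new_ph          # Hermitian symmetry
  # DC (and Nyquist, if present) keep their original (real) phases
  Re(stats::fft(amp * exp(1i * ph), inverse = TRUE)) / n
}

#' 1/f-like noise by spectral shaping
#'
#' Gaussian white noise reshaped in the frequency domain so the power
#' spectrum falls off as `1/f^exponent`, then standardized to unit
#' variance.
#'
#' @param n Length of the series.
#' @param exponent Spectral exponent (default 1, i.e. pink noise).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n` with mean ~0 and sd 1.
#' @export
pink_noise <- function(n, exponent = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be at least 2")
  X <- stats::fft(stats::rnorm(n))
  k <- seq_len(n) - 1L
  k <- pmin(k, n - k)                        # folded frequency index
  scale <- c(0, k[-1]^(-exponent / 2))       # kill DC
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

#' Burst-train irreversible process
#'
#' A strongly time-irreversible reference process: a Poisson train of
#' events with exponentially distributed amplitudes, convolved with a
#' causal kernel that rises instantaneously and decays as a sum of
#' exponentials with several time constants. Every burst therefore has a
#' sharp onset and a slow multi-timescale relaxation -- the sawtooth
#' asymmetry characteristic of nonequilibrium avalanche-like dynamics --
#' so ordinal asymmetry is present at sample resolution and survives
#' coarse-graining up to scales of order the largest decay constant.
#'
#' @param n Length of the series.
#' @param decay Decay time constants of the kernel, in samples
#'   (default `c(3, 12, 48)`, spanning the usual coarse-graining range).
#' @param event_rate Expected events per sample (default 1/30).
#' @param seed Optional integer seed.
#' @return Standardized numeric vector of length `n` (mean 0, sd 1).
#' @export
gen_burst_train <- function(n, decay = c(3, 12, 48), event_rate = 1 / 30,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be at least 2")
  if (any(decay <= 0) || event_rate <= 0 || event_rate > 1)
    stop("`decay` must be positive and `event_rate` in (0, 1]")
  events <- stats::rbinom(n, 1L, event_rate) * stats::rexp(n)
  lags <- 0:ceiling(6 * max(decay))
  kernel <- rowSums(vapply(decay, function(td) exp(-lags / td),
                           numeric(length(lags))))
  z <- as.numeric(stats::filter(events, kernel, method = "convolution",
                                sides = 1))
  z[is.na(z)] <- 0
  (z - mean(z)) / stats::sd(z)
}

# Band-limited Gaussian background: white noise passed through the
# zero-phase band gain used by the preprocessing module.
.band_noise <- function(n, low_hz, high_hz, sample_rate_hz) {
  w <- stats::rnorm(n)
  y <- .fft_filter(w, function(f)
    .g_highpass(f, low_hz, 4) * .g_lowpass(f, high_hz, 4), sample_rate_hz)
  s <- stats::sd(y)
  if (s == 0) y else (y - mean(y)) / s
}

.ctf_like_labels <- function(n_channels) {
  cells <- expand.grid(region = c("C", "F", "O", "P", "T"),
                       hemi = c("L", "R"), stringsAsFactors = FALSE)
  i <- seq_len(n_channels) - 1L
  sprintf("M%s%s%02d", cells$hemi[i %% 10L + 1L], cells$region[i %% 10L + 1L],
          i %/% 10L + 11L)
}

#' Generate a two-group MEG-like synthetic cohort
#'
#' Builds per-subject multichannel recordings in which each channel mixes
#' a reversible background with an irreversible ingredient by variance
#' fraction:
#' `sqrt(1 - mix) * background + sqrt(mix) * irreversible`,
#' where the background is a weighted sum of band-limited Gaussian
#' oscillations (per `band_powers`) plus 1/f noise -- time-reversible by
#' construction -- and the irreversible ingredient is the burst-train
#' process of [gen_burst_train()]. The two groups share every parameter
#' except their `irreversibility_mix`, so any group difference in MsPTIRR
#' is attributable to the mix contrast alone. Channel labels follow the
#' CTF convention so [map_regions()] applies directly.
#'
#' Defaults mirror the study geometry this generator emulates: 15 + 19
#' subjects, 275 channels, two minutes at 1200 Hz. Tests and examples
#' scale these down explicitly. The default mixes (0.3 for the control-like
#' group, 0.1 for the patient-like group) encode the qualitative finding
#' that the patient group's irreversibility is lower.
#'
#' @param n_per_group Named integer pair: subjects per group. Names are the
#'   group labels (default `c(HC = 15, SZ = 19)`).
#' @param n_channels Channels per subject (default 275).
#' @param n_samples Samples per channel (default 144000).
#' @param sample_rate_hz Sampling rate (default 1200).
#' @param irreversibility_mix Numeric pair in `[0, 1]`: the fraction of
#'   each channel's variance contributed by the irreversible component,
#'   one value per group in the order of `n_per_group`
#'   (default `c(HC = 0.3, SZ = 0.1)`).
#' @param band_powers Named nonnegative weights of the band-limited
#'   background components; names must appear in [meg_bands()].
#' @param noise_sd Weight of the 1/f noise component (default 1).
#' @param seed Optional integer seed; fixing it makes the cohort
#'   bit-reproducible.
#' @param dir Optional directory: when given, each recording is written as
#'   a delimited file ([write_recording()]) instead of being kept in
#'   memory, and the manifest's `file` column points at it.
#' @return List with `subjects` (list of `list(subject_id, group, data,
#'   sample_rate_hz)`; `data` is `NULL` when `dir` is used) and `manifest`
#'   (data frame: `subject_id`, `group`, `mix`, `file`).
#' @export
gen_cohort <- function(n_per_group = c(HC = 15, SZ = 19),
                       n_channels = 275,
                       n_samples = 144000,
                       sample_rate_hz = 1200,
                       irreversibility_mix = c(HC = 0.3, SZ = 0.1),
                       band_powers = c(delta = 1, theta = 0.7, alpha = 1.5,
                                       beta = 0.6, gamma = 0.3),
                       noise_sd = 1,
                       seed = NULL,
                       dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(n_per_group) != 2L || any(n_per_group < 1L))
    stop("`n_per_group` must be two positive counts, one per group")
  if (is.null(names(n_per_group)))
    names(n_per_group) <- c("HC", "SZ")
  if (length(irreversibility_mix) != 2L ||
      any(irreversibility_mix < 0) || any(irreversibility_mix > 1))
    stop("`irreversibility_mix` must be two weights in [0, 1]")
  if (any(band_powers < 0)) stop("`band_powers` must be nonnegative")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  n_channels <- as.integer(n_channels); n_samples <- as.integer(n_samples)
  if (n_channels < 1L || n_samples < 64L)
    stop("need at least 1 channel and 64 samples")
  bands <- meg_bands()
  bands <- bands[bands$name %in% names(band_powers) &
                 bands$high_hz < sample_rate_hz / 2, , drop = FALSE]
  labels <- .ctf_like_labels(n_channels)
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)

  groups <- rep(names(n_per_group), times = n_per_group)
  mixes <- rep(as.numeric(irreversibility_mix), times = n_per_group)
  subjects <- vector("list", length(groups))
  files <- character(length(groups))
  for (i in seq_along(groups)) {
    sid <- sprintf("S%03d", i)
    mix <- mixes[i]
    rec <- matrix(0, nrow = n_channels, ncol = n_samples,
                  dimnames = list(labels, NULL))
    for (ch in seq_len(n_channels)) {
      bg <- noise_sd * pink_noise(n_samples)
      for (b in seq_len(nrow(bands))) {
        w <- band_powers[[bands$name[b]]]
        if (w > 0)
          bg <- bg + sqrt(w) * .band_noise(n_samples, bands$low_hz[b],
                                           bands$high_hz[b], sample_rate_hz)
      }
      bg <- (bg - mean(bg)) / stats::sd(bg)
      ch_sig <- sqrt(1 - mix) * bg
      if (mix > 0)
        ch_sig <- ch_sig + sqrt(mix) * gen_burst_train(n_samples)
      rec[ch, ] <- ch_sig
    }
    if (!is.null(dir)) {
      files[i] <- file.path(dir, paste0(sid, ".tsv"))
      write_recording(rec, files[i], sample_rate_hz)
      rec <- NULL
    } else files[i] <- NA_character_
    subjects[[i]] <- list(subject_id = sid, group = groups[i], data = rec,
                          sample_rate_hz = sample_rate_hz)
  }
  manifest <- data.frame(subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
                         group = groups, mix = mixes, file = files,
                         stringsAsFactors = FALSE)
  list(subjects = subjects, manifest = manifest)
}
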