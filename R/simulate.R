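# Synthetic multielectrode recordings with cue-locked structure.
#
# Each channel carries three superimposed processes:
#   * a "foreground" unit: large-amplitude spikes (inhomogeneous Poisson,
#     cue-modulated, refractory) that threshold detection can isolate;
#   * a sub-threshold multi-unit background: many small-amplitude spikes
#     whose summed band power modulates with the cue but whose individual
#     events sit below the detection threshold -- the component that MUA and
#     mid-frequency wavelet power integrate and threshold crossings miss;
#   * spatially correlated low-frequency oscillations plus white noise.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

.derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 131 + 7919 * k) %% 2147483629
}

#' Simulation parameters
#'
#' Collects every knob of the recording simulator. Defaults describe a
#' 96-channel array sampled at 30 kHz with 10 Hz baseline firing that
#' quadruples on fully tuned channels during cues, 80 uV foreground spikes,
#' a 25 uV sub-threshold multi-unit background at 60 Hz, two spatially
#' correlated low-frequency oscillations and 10 uV RMS white noise.
#'
#' @param n_channels Number of channels (default 96).
#' @param fs Sampling rate in Hz (default 30000).
#' @param tuning `n_channels x n_movements` matrix of gains in `[0, 1]`;
#'   `NULL` assigns each channel one preferred movement round-robin with
#'   gain `tuning_strength`.
#' @param tuning_strength Gain used when `tuning` is auto-built (default 1).
#' @param baseline_rate Foreground-unit rest firing rate, Hz (default 10).
#' @param cue_rate_multiplier Rate multiplier on a fully tuned channel during
#'   its preferred cue (default 4).
#' @param spike_amp_uv Foreground spike negative-peak amplitude per channel,
#'   uV; scalar recycled (default 80).
#' @param unit_tuning_scale Fraction of the channel tuning that the
#'   foreground unit expresses (default 0.25); the multi-unit background
#'   expresses the full tuning, so most cue information lives in
#'   sub-threshold band power rather than in isolatable spikes.
#' @param mua_rate Multi-unit background event rate at rest, Hz (default 60).
#' @param mua_amp_uv Background spike amplitude, uV (default 25, below a
#'   -4.5 x RMS threshold at the default noise floor).
#' @param lfp_components List of oscillation components, each
#'   `list(freq, amp, lambda)`: frequency (Hz), amplitude (uV) and spatial
#'   correlation length (mm); optional `mod_freq` (Hz, default 0.3) and
#'   `mod_depth` (default 0.5) set the slow amplitude modulation that gives
#'   the oscillation a fluctuating, spatially shared envelope. Default:
#'   8 Hz / 40 uV and 20 Hz / 20 uV, both with `lambda` 2 mm.
#' @param noise_rms White-noise RMS in uV (default 10).
#' @param day_index Day of a chronic series (default 0).
#' @param amplitude_decay Per-day multiplicative decay of all spike
#'   amplitudes, in `(0, 1]` (default 1 = stable).
#' @param refractory_s Absolute refractory period between spikes of one
#'   train, s (default 0.0015).
#' @param lag_s Neural latency between cue onset and rate change (default 0).
#' @param seed Integer seed; every stochastic draw derives from it.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_channels = 96, fs = 30000,
                              tuning = NULL, tuning_strength = 1,
                              baseline_rate = 10, cue_rate_multiplier = 4,
                              spike_amp_uv = 80, unit_tuning_scale = 0.25,
                              mua_rate = 60, mua_amp_uv = 25,
                              lfp_components = list(
                                list(freq = 8, amp = 40, lambda = 2),
                                list(freq = 20, amp = 20, lambda = 2)),
                              noise_rms = 10, day_index = 0,
                              amplitude_decay = 1, refractory_s = 0.0015,
                              lag_s = 0, seed = NULL) {
  stopifnot(n_channels >= 1, fs > 0, baseline_rate >= 0, mua_rate >= 0,
            cue_rate_multiplier >= 1, noise_rms > 0,
            amplitude_decay > 0, amplitude_decay <= 1, refractory_s >= 0)
  structure(list(n_channels = n_channels, fs = fs, tuning = tuning,
                 tuning_strength = tuning_strength,
                 baseline_rate = baseline_rate,
                 cue_rate_multiplier = cue_rate_multiplier,
                 spike_amp_uv = rep_len(spike_amp_uv, n_channels),
                 unit_tuning_scale = unit_tuning_scale,
                 mua_rate = mua_rate, mua_amp_uv = mua_amp_uv,
                 lfp_components = lfp_components, noise_rms = noise_rms,
                 day_index = day_index, amplitude_decay = amplitude_decay,
                 refractory_s = refractory_s, lag_s = lag_s, seed = seed),
            class = "simulation_params")
}

#' Round-robin movement tuning matrix
#'
#' Assigns each channel one preferred movement in rotation; the channel
#' expresses gain `strength` for that movement and 0 for the others.
#'
#' @param n_channels Number of channels.
#' @param movements Character vector of movement labels.
#' @param strength Gain of the preferred movement (default 1).
#' @return `n_channels x length(movements)` matrix with movement columns.
#' @export
make_tuning <- function(n_channels, movements, strength = 1) {
  m <- matrix(0, n_channels, length(movements),
              dimnames = list(NULL, movements))
  pref <- ((seq_len(n_channels) - 1) %% length(movements)) + 1
  m[cbind(seq_len(n_channels), pref)] <- strength
  m
}

#' Generate a cue schedule for one task block
#'
#' Task1 blocks start with 6.5 s of rest followed by 10 cues (5 random
#' repetitions of hand open and hand close), each 2.5 s long and followed by
#' 6.5 s of rest. Task2 blocks start with 4.5 s of rest followed by 16 cues
#' (4 repetitions of each of 4 wrist/index movements), 2.5 s cues and 4 s
#' inter-cue rests. The cue order is a seeded random permutation.
#'
#' @param task_id `"Task1"` or `"Task2"`.
#' @param block_index Block index (default 0).
#' @param seed Integer seed for the cue order.
#' @return A [cue_schedule()].
#' @export
make_cue_schedule <- function(task_id, block_index = 0, seed = NULL) {
  task_id <- match.arg(task_id, names(.task_movements))
  movements <- .task_movements[[task_id]]
  reps <- if (task_id == "Task1") 5 else 4
  initial_rest <- if (task_id == "Task1") 6.5 else 4.5
  inter_rest <- if (task_id == "Task1") 6.5 else 4.0
  cue_dur <- 2.5
  order <- .with_seed(seed, sample(rep(movements, each = reps)))
  n <- length(order)
  onsets <- initial_rest + (seq_len(n) - 1) * (cue_dur + inter_rest)
  cue_schedule(task_id, block_index,
               events = data.frame(movement = order, onset_s = onsets,
                                   duration_s = cue_dur),
               initial_rest = initial_rest, inter_cue_rest = inter_rest,
               block_duration = initial_rest + n * (cue_dur + inter_rest))
}

# biphasic, negative-leading spike waveform; unit negative peak, 1.2 ms
# total: sharp 0.3 ms negative phase, slow area-balancing positive phase
.spike_template <- function(fs) {
  t <- seq(0, 1.2e-3, by = 1 / fs)
  w <- ifelse(t <= 0.3e-3, -sin(pi * t / 0.3e-3),
              (1 / 3) * sin(pi * (t - 0.3e-3) / 0.9e-3))
  list(w = w, peak_at = which.min(w), p2p = max(w) - min(w))
}

# inhomogeneous Poisson train by thinning, with absolute refractory period
.spike_train <- function(duration, base_rate, gain_by_event, events, lag,
                         multiplier, refractory) {
  if (base_rate <= 0 || duration <= 0) return(numeric(0))
  gmax <- if (length(gain_by_event)) max(gain_by_event) else 0
  rmax <- base_rate * (1 + (multiplier - 1) * gmax)
  n <- rpois(1, rmax * duration)
  if (n == 0) return(numeric(0))
  t <- sort(runif(n, 0, duration))
  rate <- rep(base_rate, n)
  if (nrow(events) > 0) {
    iv <- findInterval(t, events$onset_s + lag)
    hit <- iv >= 1 & t < events$onset_s[pmax(iv, 1)] + lag +
      events$duration_s[pmax(iv, 1)]
    g <- ifelse(hit, gain_by_event[pmax(iv, 1)], 0)
    rate <- base_rate * (1 + (multiplier - 1) * g)
  }
  t <- t[runif(n) < rate / rmax]
  if (refractory > 0 && length(t) > 1) {
    keep <- logical(length(t)); last <- -Inf
    for (i in seq_along(t)) {
      if (t[i] - last >= refractory) { keep[i] <- TRUE; last <- t[i] }
    }
    t <- t[keep]
  }
  t
}

#' Simulate a raw recording for one cue-schedule block
#'
#' Builds a [raw_recording()] of the block's duration: per channel,
#' cue-modulated foreground spikes and sub-threshold multi-unit background
#' spikes (both inhomogeneous Poisson with refractory period, amplitudes
#' scaled by `amplitude_decay^day_index`), plus spatially correlated
#' sinusoidal low-frequency components and white Gaussian noise. The
#' ground-truth spike times are attached as attribute `"spikes"` (a list
#' with per-channel `foreground` and `background` event-time vectors).
#'
#' @param schedule A [cue_schedule()].
#' @param geometry An [array_geometry()]; defaults to a square-ish grid for
#'   `params$n_channels` channels.
#' @param params A [simulation_params()].
#' @return A [raw_recording()], fully determined by `params$seed`.
#' @export
simulate_recording <- function(schedule, geometry = NULL,
                               params = simulation_params()) {
  stopifnot(inherits(schedule, "cue_schedule"),
            inherits(params, "simulation_params"))
  nch <- params$n_channels
  if (is.null(geometry))
    geometry <- grid_geometry(nch, n_cols = ceiling(sqrt(nch)))
  if (nrow(geometry$positions) < nch)
    stop("geometry has fewer channels than params$n_channels")
  duration <- schedule$block_duration
  n_samp <- round(duration * params$fs)
  if (n_samp < 1) stop("schedule has zero duration")
  if (n_samp * nch > 2^31)
    stop("block too long to represent in one in-memory recording")
  movements <- .task_movements[[schedule$task_id]]
  tuning <- params$tuning
  if (is.null(tuning))
    tuning <- make_tuning(nch, movements, params$tuning_strength)
  if (nrow(tuning) != nch || ncol(tuning) != length(movements))
    stop("tuning must be n_channels x n_movements for this task")
  colnames(tuning) <- movements
  ev <- schedule$events
  decay <- params$amplitude_decay^params$day_index
  tmpl <- .spike_template(params$fs)

  .with_seed(params$seed, {
    samples <- matrix(rnorm(nch * n_samp, sd = params$noise_rms),
                      nrow = n_samp)
    # spatially correlated oscillations: per component, a handful of latent
    # sinusoids anchored at random sites, mixed into channels with
    # exp(-distance / lambda) weights
    if (length(params$lfp_components)) {
      pos <- geometry$positions[seq_len(nch), , drop = FALSE]
      tt <- seq_len(n_samp) / params$fs
      mix <- NULL; carriers <- NULL
      for (comp in params$lfp_components) {
        K <- max(4L, min(8L, nch))
        anchors <- pos[sample.int(nch, K, replace = K > nch), , drop = FALSE]
        W <- exp(-sqrt(outer(pos[, 1], anchors[, 1], "-")^2 +
                         outer(pos[, 2], anchors[, 2], "-")^2) / comp$lambda)
        phases <- runif(K, 0, 2 * pi)
        mod_freq <- if (is.null(comp$mod_freq)) 0.3 else comp$mod_freq
        mod_depth <- if (is.null(comp$mod_depth)) 0.5 else comp$mod_depth
        psi <- runif(K, 0, 2 * pi)
        # latent k = (1 + depth*sin(2*pi*fm*t + psi_k)) * sin(2*pi*f*t +
        # phi_k); expanding both phases makes every latent a fixed linear
        # combination of six shared carriers, so synthesis stays one
        # matrix product
        scale <- comp$amp / pmax(sqrt(rowSums(W^2)), 1e-12)
        Ws <- sweep(W, 1, scale, "*")
        cphi <- cos(phases); sphi <- sin(phases)
        cpsi <- cos(psi); spsi <- sin(psi)
        A <- Ws %*% cbind(cphi, sphi,
                          mod_depth * spsi * cphi, mod_depth * spsi * sphi,
                          mod_depth * cpsi * cphi, mod_depth * cpsi * sphi)
        sx <- sin(2 * pi * comp$freq * tt); cx <- cos(2 * pi * comp$freq * tt)
        sm <- sin(2 * pi * mod_freq * tt); cm <- cos(2 * pi * mod_freq * tt)
        mix <- cbind(mix, A)
        carriers <- cbind(carriers, sx, cx, cm * sx, cm * cx, sm * sx, sm * cx)
      }
      samples <- samples + carriers %*% t(mix)
    }
    fg <- vector("list", nch); bg <- vector("list", nch)
    for (ch in seq_len(nch)) {
      gains <- if (nrow(ev)) tuning[ch, ev$movement] else numeric(0)
      fg[[ch]] <- .spike_train(duration, params$baseline_rate,
                               gains * params$unit_tuning_scale, ev,
                               params$lag_s, params$cue_rate_multiplier,
                               params$refractory_s)
      bg[[ch]] <- .spike_train(duration, params$mua_rate, gains, ev,
                               params$lag_s, params$cue_rate_multiplier,
                               params$refractory_s)
      .add_spikes_cpp(samples, ch, as.integer(round(fg[[ch]] * params$fs)) + 1L,
                      tmpl$w, tmpl$peak_at, params$spike_amp_uv[ch] * decay)
      .add_spikes_cpp(samples, ch, as.integer(round(bg[[ch]] * params$fs)) + 1L,
                      tmpl$w, tmpl$peak_at, params$mua_amp_uv * decay)
    }
    rec <- raw_recording(samples, fs = params$fs,
                         channel_ids = rownames(geometry$positions)[seq_len(nch)])
    attr(rec, "spikes") <- list(foreground = fg, background = bg,
                                template_p2p = tmpl$p2p)
    rec
  })
}

#' Simulate a session of task blocks
#'
#' Generates `n_blocks` consecutive blocks of one task on one day. Blocks
#' share `params` but use distinct seeds derived from `(params$seed,
#' block index)`, so a session is reproducible as a whole.
#'
#' @param task_id `"Task1"` or `"Task2"`.
#' @param n_blocks Number of blocks (default 2, train + test).
#' @param day_index Day index applied to all blocks.
#' @param params A [simulation_params()].
#' @param geometry Optional [array_geometry()].
#' @return List of `n_blocks` elements, each `list(schedule, recording)`.
#' @export
simulate_session <- function(task_id, n_blocks = 2, day_index = 0,
                             params = simulation_params(), geometry = NULL) {
  stopifnot(n_blocks >= 1)
  lapply(seq_len(n_blocks), function(b) {
    sched <- make_cue_schedule(task_id, block_index = b - 1,
                               seed = .derive_seed(params$seed, 2 * b - 1))
    p <- params
    p$day_index <- day_index
    p$seed <- .derive_seed(params$seed, 2 * b)
    list(schedule = sched, recording = simulate_recording(sched, geometry, p))
  })
}
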