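# Shared small fixtures, built in code. The task study is generated once per
# test run and cached (deterministic under its seed).

.fixture_env <- new.env(parent = emptyenv())

# small but complete synthetic study used by several test files
cached_study <- function() {
  if (is.null(.fixture_env$study)) {
    .fixture_env$params <- sim_params(seed = 42)   # default study conditions
    .fixture_env$study <- make_task_dataset(.fixture_env$params)
  }
  list(study = .fixture_env$study, params = .fixture_env$params)
}

# epochs object with iid normal noise
noise_epochs <- function(n_tr = 6, n_ch = 4, fs = 200, window = c(-0.5, 1),
                         sd = 1, seed = 1, roles = NULL) {
  set.seed(seed)
  times <- seq(window[1L], window[2L], by = 1 / fs)
  dat <- array(rnorm(n_tr * n_ch * length(times), sd = sd),
               c(n_tr, n_ch, length(times)))
  epochs(dat, times, fs,
         labels = data.frame(class = rep_len(c("left", "right"), n_tr)),
         roles = roles)
}

# single-channel recording with pink (1/f) noise
pink_recording <- function(duration_s = 10, fs = 1000, seed = 1, n_ch = 1,
                           roles = "mtl") {
  p <- sim_params(fs = fs, n_channels = n_ch,
                  channel_roles = rep(roles, n_ch),
                  duration_s = duration_s, seed = seed)
  make_background(p)
}

# Gaussian-windowed oscillatory burst added to a recording
with_burst <- function(rec, ch = 1, center_s, freq, dur, amp) {
  n <- round(dur * rec$fs)
  if (n %% 2L == 0L) n <- n + 1L
  t <- (seq_len(n) - (n + 1) / 2) / rec$fs
  wave <- -amp * exp(-0.5 * (t / (dur / 6))^2) * cos(2 * pi * freq * t)
  c_idx <- round(center_s * rec$fs) + 1L
  idx <- (c_idx - (n - 1L) %/% 2L):(c_idx + (n - 1L) %/% 2L)
  rec$data[ch, idx] <- rec$data[ch, idx] + wave
  rec
}

# brute-force concordant-pair AUC oracle
auc_oracle <- function(scores, y, positive) {
  pos <- scores[y == positive]
  neg <- scores[y != positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# brute-force Modulation Index oracle: explicit binning + KL formula
mi_oracle <- function(phase, amp, n_bins = 18) {
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  ph <- (phase + pi) %% (2 * pi) - pi
  ph[ph == -pi] <- pi
  m <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    inb <- ph > edges[b] & ph <= edges[b + 1]
    m[b] <- if (any(inb)) mean(amp[inb]) else 0
  }
  p <- m / sum(m)
  h <- -sum(p[p > 0] * log(p[p > 0]))
  (log(n_bins) - h) / log(n_bins)
}
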