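# Shared fixtures: tone clips, hand-built micro spectrograms, white-noise
# blocks, and a clustering solution wrapper for planted ground truth.

tone_clip <- function(freq, duration = 1, rate = 48000, amp = 0.5,
                      site = "tone") {
  audio_clip(amp * sin(2 * pi * freq * seq_len(round(duration * rate)) / rate),
             rate, site)
}

# Spectrogram object from a bare magnitude matrix (bin k at k*fr Hz).
micro_spec <- function(A, fr = 46.875) {
  A <- as.matrix(A)
  structure(list(A = A,
                 freqs = (seq_len(nrow(A)) - 1) * fr,
                 times = (seq_len(ncol(A)) - 1) / fr,
                 params = list(rate = 2 * fr * (nrow(A) - 1),
                               window_len = 2L * (nrow(A) - 1L),
                               hop = 2L * (nrow(A) - 1L),
                               fr = fr, tr = 1 / fr)),
            class = "spectrogram")
}

# One masked 1-second integration block of white noise.
wn_block <- function(seed, rate = 48000, amp = 0.2) {
  clip <- with_seed(seed, audio_clip(stats::rnorm(rate) * amp, rate, "wn"))
  tile_windows(mask_band(compute_spectrogram(clip)), 1)[[1]]
}

truth_solution <- function(truth, site_ids) {
  g <- truth$true_group[match(site_ids, truth$site_id)]
  structure(list(algorithm = "truth", k = length(unique(g)),
                 labels = as.integer(factor(g, levels = unique(g))),
                 seed = NA, site_ids = site_ids),
            class = "ssm_clustering")
}

# Independent brute-force ACI: explicit double loop over bins and frames.
aci_bruteforce <- function(A) {
  total <- 0
  for (f in seq_len(nrow(A))) {
    num <- 0; den <- 0
    for (t in seq_len(ncol(A) - 1)) num <- num + abs(A[f, t + 1] - A[f, t])
    for (t in seq_len(ncol(A))) den <- den + A[f, t]
    if (den > 0) total <- total + num / den
  }
  total
}

# Independent brute-force Gini over all ordered pairs.
gini_bruteforce <- function(p) {
  n <- length(p)
  if (mean(p) == 0) return(0)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(p[i] - p[j])
  s / (2 * n^2 * mean(p))
}

# Exact two-sided WMW p-value by full enumeration of group assignments.
wmw_enumerate <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); nx <- length(x)
  u_of <- function(idx) {
    r <- rank(all_v)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  combos <- utils::combn(n, nx)
  u_all <- apply(combos, 2, function(idx) {
    r <- rank(all_v)
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  mu <- nx * (n - nx) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
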