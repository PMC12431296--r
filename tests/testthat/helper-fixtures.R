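# Small in-code fixtures shared across test files.

# epochs with iid Gaussian channels: n_per_class trials per class
toy_epochs <- function(n_per_class = 5, n_ch = 4, n_samp = 100, fs = 250,
                       sd_by_class = rep(1, 4), seed = 1,
                       channel_names = NULL) {
  set.seed(seed)
  n <- 4 * n_per_class
  labels <- rep(0:3, each = n_per_class)
  data <- array(0, dim = c(n, n_ch, n_samp))
  for (tr in seq_len(n))
    data[tr, , ] <- matrix(rnorm(n_ch * n_samp, sd = sd_by_class[labels[tr] + 1]),
                           n_ch, n_samp)
  eeg_epochs(data, labels, fs,
             channel_names %||% paste0("ch", seq_len(n_ch)), t_start = 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# detection set with explicit records
toy_detections <- function(records, width = 600, height = 300, id = "img1") {
  detection_set(id, width, height, records)
}

# random SPD matrix
rand_spd <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) + diag(n) * 0.1
}

# naive O(N^2) sample-entropy oracle (independent of the package kernel)
sampen_naive <- function(x, m, r) {
  n <- length(x)
  A <- 0; B <- 0
  for (i in 1:(n - m - 1)) {
    for (j in (i + 1):(n - m)) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  -log(A / B)
}

# generator spec with ERD planted on 5 known non-core channels, used by
# the channel-recovery checks. Every planted channel carries the same
# contrast (attenuation 0.6 in two classes) so their band-power ANOVA
# scores cluster tightly at the top of the candidate ranking.
recovery_sim_spec <- function() {
  list(spec = eeg_sim_spec(erd = list(
         "left hand"  = c(CP4 = 0.6, C6 = 0.6, CPz = 0.6),
         "right hand" = c(CP3 = 0.6, C5 = 0.6),
         "legs"       = c(CPz = 0.6, C5 = 0.6, C6 = 0.6),
         "tongue"     = c(CP4 = 0.6, CP3 = 0.6))),
       planted = c("CP3", "CP4", "C5", "C6", "CPz"))
}

# a fast low-resolution CSFF configuration for smoke-level tests
fast_csff_config <- function() {
  csff_config(wp = window_par(2, 0.5, 1, 4),
              selection = selection_config(k_total = 8))
}
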