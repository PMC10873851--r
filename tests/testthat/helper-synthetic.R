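# shared small fixtures, built once per test run
normalize_maps_test <- function(x) {
  x <- x - rowMeans(x)
  x / sqrt(rowSums(x^2))
}

tiny_montage <- make_montage(16)
std_montage <- make_montage(32)
std_gt <- ground_truth(std_montage, k = 4, seed = 100)

# a segmentation object without running backfit (for rule-level tests)
manual_segmentation <- function(labels, fs = 200, mask = NULL, k = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, length(labels))
  if (is.null(k)) k <- max(labels, na.rm = TRUE)
  labels[mask] <- NA_integer_
  structure(list(labels = labels, fit_corr = ifelse(is.na(labels), NA_real_, 1),
                 fs = fs, mask = mask, k = k),
            class = "ms_segmentation")
}

# sinusoidal multichannel test recording
tone_recording <- function(freq, fs = 1000, dur = 4, nch = 8) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  data <- t(sapply(seq_len(nch), function(i) sin(2 * pi * freq * t + i)))
  recording(data, fs)
}

# steady-state amplitude of channel 1, measured away from the edges
steady_amp <- function(rec) {
  n <- ncol(rec$data)
  max(abs(rec$data[1, floor(n * 0.4):floor(n * 0.6)]))
}
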