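## Shared fixtures, built once per test run.

.fixtures <- new.env()

## small noise-free phantom set (one per class)
clean_phantoms <- function() {
  if (is.null(.fixtures$clean)) {
    .fixtures$clean <- generate_phantoms(
      phantom_spec(image_size = 64, n_per_class = 2, noise_sd = 0,
                   impulse_frac = 0, seed = 42))
  }
  .fixtures$clean
}

noisy_phantoms <- function() {
  if (is.null(.fixtures$noisy)) {
    .fixtures$noisy <- generate_phantoms(
      phantom_spec(image_size = 64, n_per_class = 3, seed = 7))
  }
  .fixtures$noisy
}

## a bright Gaussian blob on a dark field
blob_image <- function(n = 64, cx = n / 2, cy = n / 2, s2 = 9, amp = 0.8) {
  pmin(pmax(0.1 + amp * outer(seq_len(n), seq_len(n), function(i, j)
    exp(-((i - cy)^2 + (j - cx)^2) / (2 * s2))), 0), 1)
}

## filled disk / ellipse masks
disk_mask <- function(n = 64, r = 20, cx = n / 2, cy = n / 2) {
  outer(seq_len(n), seq_len(n), function(i, j)
    (i - cy)^2 + (j - cx)^2 <= r^2) * 1
}
ellipse_mask_fx <- function(n = 64, a = 20, b = 10, cx = n / 2, cy = n / 2) {
  outer(seq_len(n), seq_len(n), function(i, j)
    ((i - cy) / b)^2 + ((j - cx) / a)^2 <= 1) * 1
}
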