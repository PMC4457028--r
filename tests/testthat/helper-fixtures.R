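# Shared fixtures: small/fast generator models and hand-built objects.

# Compact nucleus for fast unit tests: small sphere, moderate separations,
# no size jitter unless asked.
small_model <- function(separation_mean = 1.6, separation_sd = 0.4, ...) {
  nucleus_model("meristematic", semi_axes = c(x = 1.6, y = 1.6, z = 1.6),
                nucleolus_radius = 0.6, separation_mean = separation_mean,
                separation_sd = separation_sd, margin = 0.8,
                size_jitter_sd = 0, ...)
}

# A locus_pair built directly from coordinates (um).
fake_pair <- function(p1, p2, threshold = 0.4) {
  foci <- data.frame(x_um = c(p1[1], p2[1]), y_um = c(p1[2], p2[2]),
                     z_um = c(p1[3], p2[3]), peak = c(100, 90),
                     score = c(30, 25), amplitude = c(2000, 1800),
                     residual = c(1, 1), converged = TRUE)
  class(foci) <- c("focus_detections", "data.frame")
  measure_pair(foci, pairing_threshold = threshold)
}

# A pair with a stated distance along z from the origin.
pair_with_distance <- function(d, threshold = 0.4)
  fake_pair(c(0, 0, 0), c(0, 0, d), threshold = threshold)
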