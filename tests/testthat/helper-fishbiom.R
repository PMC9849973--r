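# Shared fixtures, built in code.

# A tiny hand-checkable sample.
tiny_sample <- function() {
  biometric_sample(total_length = c(3.0, 5.0, 7.0),
                   standard_length = c(2.4, 4.1, 5.7),
                   body_weight = c(0.25, 1.20, 3.40),
                   label = "tiny")
}

# Noise-free power-law sample W = a * L^b on a length grid.
power_law_sample <- function(a, b, lengths = seq(2, 9, by = 0.5)) {
  biometric_sample(total_length = lengths,
                   body_weight = a * lengths^b,
                   label = sprintf("exact a=%g b=%g", a, b))
}

# Fabricated LFD whose ln(Nt/dt) is exactly linear in relative age with
# slope -z: an analytic oracle for the catch-curve regression.
linear_catch_lfd <- function(z = 1, linf = 20, k = 0.3,
                             lowers = seq(1, 8, by = 1), width = 1) {
  t_of <- function(l) -log(1 - l / linf) / k
  mids <- lowers + width / 2
  dt <- t_of(lowers + width) - t_of(lowers)
  count <- dt * exp(4 - z * t_of(mids))
  lfd <- data.frame(lower = lowers, upper = lowers + width,
                    midpoint = mids, count = count)
  structure(lfd, width = width, anchor = 0,
            modal_bin = which.max(count), n = sum(count),
            class = c("length_frequency", "data.frame"))
}
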