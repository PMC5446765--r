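# Noise-free single-temperature kinetic curve from known (lambda, n) truth.
make_weibull_curve <- function(lambda, n, n_times = 8,
                               lo = 0.05, hi = 2) {
  time_s <- exp(seq(log(lo * lambda), log(hi * lambda), length.out = n_times))
  data.frame(time_s = time_s, fraction = exp(-(time_s / lambda)^n))
}

# Constant-temperature series sampled every `by` seconds.
constant_series <- function(temp_C, duration_s, by = 1) {
  data.frame(time_s = seq(0, duration_s, by = by), temp_C = temp_C)
}

erythrosine <- params_erythrosine()
activity <- params_activity()
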