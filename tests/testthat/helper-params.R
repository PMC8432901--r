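# canonical parameter sets used throughout the suite
p_crit <- function(h = 1e-6, N = 1e5)
  wc_params(alpha = 0.1, beta = 1, w0 = 0.1, w_sum = 13.8, h = h, N = N)
p_super <- function(h = 1e-3, N = 1e4)
  wc_params(alpha = 0.1, beta = 1, w0 = 0.2, w_sum = 13.8, h = h, N = N)

# effective standard error of a time average with correlation time tau:
# var of the mean ~ 2 * tau * var / T
time_avg_se <- function(v, tau, T) sqrt(2 * tau * v / T)
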