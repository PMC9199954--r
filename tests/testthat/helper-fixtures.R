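# Shared virtual-instrument fixtures. All stochastic fixtures take explicit
# seeds so individual tests stay reproducible in isolation.

# clean instrument with an effectively instantaneous (single-channel) IRF
ideal_instrument <- function(channel_width_ps = 10, n_channels = 1024) {
  instrument_model(irf = irf_model(fwhm_ps = channel_width_ps, t0_ps = 500),
                   channel_width_ps = channel_width_ps,
                   n_channels = n_channels, dark_rate_cps = 0)
}

# clean instrument with a realistic 300-ps Gaussian IRF
typical_instrument <- function(dark_rate_cps = 0) {
  instrument_model(irf = irf_model(fwhm_ps = 300), dark_rate_cps = dark_rate_cps)
}

standard_props <- function() optical_props(0.1, 10)

# independent OLS oracle: closed-form slope/intercept from first moments
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  list(intercept = a, slope = b, fitted = a + b * x)
}

# synthetic kit measurement where retrieval is an exact affine map plus
# optional injected coupling; the null case for linearity/crosstalk
synthetic_kit <- function(mua_gain = 1, mua_offset = 0,
                          mus_gain = 1, mus_offset = 0,
                          couple_mua_from_mus = 0, couple_mus_from_mua = 0) {
  kit <- medphot_kit()
  data.frame(label = kit$label,
             nominal_mua = kit$mua, nominal_musp = kit$musp,
             mua = mua_offset + mua_gain * kit$mua +
               couple_mua_from_mus * (kit$musp - 10),
             musp = mus_offset + mus_gain * kit$musp +
               couple_mus_from_mua * (kit$mua - 0.1))
}
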