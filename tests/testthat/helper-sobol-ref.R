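# first 16 unscrambled Sobol points in 6 dimensions (independent reference)
sobol_ref_6d <- matrix(c(
0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.75, 0.25, 0.25, 0.25, 0.75, 0.75, 0.25, 0.75, 0.75, 0.75, 0.25, 0.25, 0.375, 0.375, 0.625, 0.875, 0.375, 0.125, 0.875, 0.875, 0.125, 0.375, 0.875, 0.625, 0.625, 0.125, 0.875, 0.625, 0.625, 0.875, 0.125, 0.625, 0.375, 0.125, 0.125, 0.375, 0.1875, 0.3125, 0.9375, 0.4375, 0.5625, 0.3125, 0.6875, 0.8125, 0.4375, 0.9375, 0.0625, 0.8125, 0.9375, 0.0625, 0.6875, 0.1875, 0.3125, 0.5625, 0.4375, 0.5625, 0.1875, 0.6875, 0.8125, 0.0625, 0.3125, 0.1875, 0.3125, 0.5625, 0.9375, 0.4375, 0.8125, 0.6875, 0.8125, 0.0625, 0.4375, 0.9375, 0.5625, 0.4375, 0.0625, 0.8125, 0.1875, 0.6875, 0.0625, 0.9375, 0.5625, 0.3125, 0.6875, 0.1875
), ncol = 6, byrow = TRUE)
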