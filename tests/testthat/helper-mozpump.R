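# Shared fixtures: the reference configuration/timing and a smaller grid
# for the cheaper property tests.

ref_config <- default_config()
ref_timing <- default_timing()

sim_cont <- simulate_mode("continuous", ref_config, ref_timing, 2000)
sim_burst <- simulate_mode("burst", ref_config, ref_timing, 2000)

# relative difference helper
rel_diff <- function(a, b) abs(a - b) / abs(b)
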