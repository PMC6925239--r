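# Run the full simulate -> align -> profile -> call chain on a synthetic
# reference with known ground truth.
simulate_and_call <- function(spacer = 100L, seed = 1L,
                              break_present = TRUE, depth = 50,
                              error_rate = 0.01, arm_len = 2000L,
                              intact_fraction = 0) {
  ref <- make_test_reference(spacer, arm_len, seed = seed)
  region <- locate_break_region(ref)
  cfg <- sim_config(seed = seed + 1L, depth = depth,
                    error_rate = error_rate,
                    break_present = break_present,
                    intact_fraction = intact_fraction)
  sim <- simulate_reads(ref, cfg)
  index <- build_index(ref)
  pairs <- align_pairs(sim$pairs, index)
  profiles <- compute_profiles(pairs, ref, region = region)
  list(ref = ref, region = region, sim = sim, pairs = pairs,
       profiles = profiles, call = call_break(profiles, region),
       excised = attr(ref, "region"))
}
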