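# Small study configuration used across tests: one ~3 min session with
# right-hand reaches only, non-acting (left) arm -> acting (right) arm and
# acting arm -> both legs coupling at lag 1.
overflow_coupling <- function(strength = 0.4) {
  A <- matrix(0, 4, 4)
  A[2, 1] <- strength            # left_arm (non-acting) -> right_arm (acting)
  A[3, 2] <- strength            # right_arm -> left_leg
  A[4, 2] <- strength            # right_arm -> right_leg
  A
}

small_sim_config <- function(seed = 1, strength = 0.4, ...) {
  sim_config(duration = 200,
             coupling = overflow_coupling(strength),
             reach_counts = matrix(c(0, 8, 0, 7, 0, 5), nrow = 3, byrow = TRUE),
             seed = seed, ...)
}
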