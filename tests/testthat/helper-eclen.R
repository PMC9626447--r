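# Shared fixtures for the test suite.  The three canonical parameter sets are
# cheap to derive (closed form + one bisection), so they are rebuilt here once
# per test run.
p_REC <- ec_phenotype_params("REC")
p_UEC <- ec_phenotype_params("UEC")
p_TEC <- ec_phenotype_params("TEC")

# Production-resolution deterministic configuration used throughout: 12 h at
# dt = 1e-2 s, one recorded state per second of model time.
cfg_12h <- ec_sim_config(dt = 1e-2, hours = 12)

# Episode onset times (s) of the tumbling oscillation after the transient
# discard; used by the dt-convergence checks.
episode_onsets <- function(traj, threshold = 20, discard = 7200) {
  post <- traj[traj$t_s >= discard, , drop = FALSE]
  r <- rle(post$L_um < threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  post$t_s[starts[which(r$values)]]
}
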