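# Shared fixtures: tiny deterministic objects used across test files.

default_params <- epbd_parameters()

# a short mixed-composition promoter with the TSS mid-sequence
tiny_promoter <- function() {
  promoter_sequence("ATGCATGCATGC", tss_index = 6L, name = "tiny")
}

# wrap bare trajectory matrices as a trajectory_ensemble so profile code
# can be exercised on constructed (non-simulated) data
manual_ensemble <- function(replicas, seq, sample_dt = 1,
                            config = test_scale_config(), params = default_params) {
  structure(
    list(replicas = replicas, velocities = NULL, sample_dt = sample_dt,
         seq = seq, config = config, params = params,
         replica_seeds = seq_along(replicas)),
    class = "trajectory_ensemble"
  )
}

# brute-force bubble scan: per-cell frame loop, no run-length shortcuts
brute_force_bubbles <- function(trajectory, threshold, len, sample_dt = 1) {
  n <- ncol(trajectory); n_frames <- nrow(trajectory)
  out <- list()
  for (p in seq_len(n - len + 1L)) {
    open <- logical(n_frames)
    for (f in seq_len(n_frames)) {
      open[f] <- all(trajectory[f, p:(p + len - 1L)] >= threshold)
    }
    f <- 1L
    while (f <= n_frames) {
      if (open[f]) {
        g <- f
        while (g <= n_frames && open[g]) g <- g + 1L
        out[[length(out) + 1L]] <- data.frame(
          start = p, birth_frame = f, death_frame = g,
          lifetime = (g - f) * sample_dt,
          censored = f == 1L || g == n_frames + 1L)
        f <- g
      } else f <- f + 1L
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), birth_frame = integer(0),
                      death_frame = integer(0), lifetime = numeric(0),
                      censored = logical(0)))
  }
  do.call(rbind, out)
}
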