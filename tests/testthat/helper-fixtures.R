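# Shared fixture builders. Everything is generated in code with fixed
# seeds; no data files.

# typical 1-hour dynamic framing: short early frames, 5-min late frames
hour_schedule <- function() {
  frame_schedule(c(seq(0, 120, 15), seq(150, 570, 30), seq(600, 3300, 300)),
                 c(seq(15, 135, 15), seq(180, 600, 30), seq(900, 3600, 300)))
}

# densely sampled plasma input over the hour (Feng-style bolus)
dense_input <- function(t_end = 3600, dt = 5) {
  synth_input("feng",
              schedule = frame_schedule(seq(0, t_end - dt, dt),
                                        seq(dt, t_end, dt)))
}

# short 10-min schedule for fast perfusion-style tests
short_schedule <- function() frame_schedule(seq(0, 570, 30), seq(30, 600, 30))

# smooth "blobby" anatomy volume for registration tests; pure function of
# (dim, seed)
blob_image <- function(d = c(48, 48, 48), voxel = 2, seed = 5, nblob = 5) {
  set.seed(seed)
  ijk <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  base <- array(0, d)
  for (b in seq_len(nblob)) {
    c0 <- runif(3, d[1] * 0.25, d[1] * 0.75)
    s <- runif(1, 3, 7)
    a <- runif(1, 50, 100)
    base <- base + array(a * exp(-rowSums(sweep(ijk, 2, c0)^2) / (2 * s^2)),
                         d)
  }
  dynamic_image(base, voxel_size = rep(voxel, 3))
}

expect_rel_error <- function(value, truth, tol) {
  expect_lt(abs(value - truth) / abs(truth), tol)
}
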