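# shared fixtures: default geometry/medium and hand-built raw streams

default_geom <- channel_geometry()
default_medium <- medium_model()

# trajectory with a clean jump -> exponential creep -> plateau structure
make_clean_trajectory <- function(L_i = 9, L_t = 18, L_e = 28, tau = 0.05,
                                  pre_s = 0.5, creep_s = 0.3, travel_s = 1,
                                  frame_rate = 200, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_pre <- round(pre_s * frame_rate)
  n_creep <- round(creep_s * frame_rate)
  n_travel <- round(travel_s * frame_rate)
  tt <- (seq_len(n_creep) - 1L) / frame_rate
  len <- c(rep(0, n_pre), L_t - (L_t - L_i) * exp(-tt / tau), rep(L_e, n_travel))
  if (noise > 0) len <- pmax(len + rnorm(length(len), 0, noise), 0)
  aspiration_trajectory((seq_along(len) - 1L) / frame_rate, len)
}

# impedance trace with constant baseline and a constant event plateau
make_clean_trace <- function(A1 = 3.41, A2 = 1.17, phase1 = -0.05,
                             phase2 = -0.5, baseline = 1e6,
                             n_base = 50, n_event = 35, n_post = 25,
                             rate = 25, amp_noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  amp <- function(a) baseline * c(rep(1, n_base), rep(a, n_event), rep(1, n_post))
  ph <- function(p) c(rep(0, n_base), rep(p, n_event), rep(0, n_post))
  a1 <- amp(A1); a2 <- amp(A2)
  if (amp_noise > 0) {
    n <- length(a1)
    a1 <- a1 * (1 + rnorm(n, 0, amp_noise))
    a2 <- a2 * (1 + rnorm(n, 0, amp_noise))
  }
  impedance_trace((seq_along(a1) - 1L) / rate, a1, ph(phase1), a2, ph(phase2))
}
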