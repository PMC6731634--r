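# Shared fixtures. Everything is generated in code; the two "study systems"
# below define the synthetic conditions used by the recovery experiments.

# Coupling-recovery system: 20 regions in 2 modules, module-linked intrinsic
# frequencies (0.04 / 0.065 Hz), operated at G = 0.5 with noise SD 0.02.
fitting_system <- function() {
  conn <- generate_connectome(20, n_modules = 2, homotopic_strength = 1,
                              seed = 11)
  pair_f <- rep(c(0.04, 0.065), length.out = 10)
  omega <- 2 * pi * pair_f[c(1:10, 1:10)]
  params <- hopf_params(a = 0, omega = omega, G = 0.5, beta = 0.02,
                        dt_s = 0.1, tr_s = 2, transient_s = 60)
  list(conn = conn, params = params, g_true = 0.5)
}

# Perturbation-recovery system: 16 regions (8 homotopic pairs), uniform
# background connectivity, weak working-point coupling G = 0.02, and
# pair-tagged frequencies - pairs 2, 5, 7 share 0.055 Hz and are the planted
# stimulation sites.
perturb_system <- function() {
  conn <- generate_connectome(16, n_modules = 1, homotopic_strength = 1,
                              seed = 13)
  planted <- c(2L, 5L, 7L)
  freqs <- generate_pair_frequencies(8, tagged = planted)
  params <- hopf_params(a = 0, omega = freqs$omega, G = 0.02, beta = 0.02,
                        dt_s = 0.1, tr_s = 2, transient_s = 60)
  list(conn = conn, params = params, planted = planted, delta_a = 0.3)
}

# Pure sinusoid series, one frequency per region.
sinusoid_ts <- function(freqs_hz, tr_s = 2, n_t = 200, phase = 0) {
  tt <- (seq_len(n_t) - 1) * tr_s
  vals <- t(vapply(freqs_hz, function(f) cos(2 * pi * f * tt + phase),
                   numeric(n_t)))
  regional_ts(vals, tr_s)
}

# Best label agreement over all permutations of k cluster identities.
label_agreement <- function(pred, true, k) {
  perms <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == k), ,
                 drop = FALSE]
  max(apply(perms, 1, function(p) mean(p[pred] == true)))
}
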