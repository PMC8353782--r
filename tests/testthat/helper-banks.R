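# Shared fixtures: small banks and simulation shortcuts used across tests.

# two well-separated 5-category items (mirror-symmetric intercepts)
mirror_bank <- function() {
  grm_bank(list(
    grm_item(a = 1.6, d = c(2.5, 1, -1, -2.5), label = "p"),
    grm_item(a = 1.6, d = c(2.5, 1, -1, -2.5), label = "q")))
}

zero_slope_bank <- function(J = 4) {
  grm_bank(lapply(seq_len(J), function(j) {
    grm_item(a = 0, d = c(2, 0.5, -0.5, -2), label = paste0("z", j))
  }))
}

# subset of the published bank, selected by TAS-20 item label
sub_bank <- function(labels) {
  grm_bank(unname(gafs8_bank()[as.character(labels)]))
}

# one-group simulation shortcut
sim_one_group <- function(bank, n, seed, dist = latent_dist(0, 1)) {
  simulate_responses(sim_config(
    bank = bank, groups = list(g = list(dist = dist, n = n)), seed = seed))
}

# two-group simulation shortcut (published group moments)
sim_two_groups <- function(bank, n_per, seed, dif = NULL,
                           foc = latent_dist(1.01, 1.17)) {
  simulate_responses(sim_config(
    bank = bank,
    groups = list(ref = list(dist = latent_dist(0, 1), n = n_per),
                  foc = list(dist = foc, n = n_per)),
    dif = dif, seed = seed))
}
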