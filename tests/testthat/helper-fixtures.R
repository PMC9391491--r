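# Shared small fixtures, built in code (nothing binary ships with the tests).

# two-amino-acid chain with a reverse loss on the leaf
tiny_chain <- function() {
  net <- aa_network(c("a1", "a2"),
                    edges = data.frame(from = "a1", to = "a2"),
                    root = "a1",
                    loss_kind = c(a1 = "none", a2 = "reverse"))
  kin <- aa_kinetics(net,
                     kcat_f = c(a1 = 2, a2 = 1),
                     kcat_loss = c(a1 = 0, a2 = 0.5),
                     K_I = c(a1 = 100, a2 = 50),
                     K_M_up = list(a1 = NULL, a2 = c(a1 = 100)),
                     K_M_loss = c(a1 = 1000, a2 = 500))
  list(net = net, kin = kin)
}

# single-species charging setup used by several tests
one_species_state <- function(tc = 5, tu = 1, syn = 0.5, rib = 10,
                              aa = 150, k_S = 100) {
  list(params = charging_params("s1", k_S = k_S, K_D_tRNAc = 1,
                                K_D_tRNAu = 2, k_rib_max = 20),
       state = charging_state("s1", c(s1 = tc), c(s1 = tu), c(s1 = syn),
                              rib, c(s1 = aa), c(s1 = 1)))
}
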