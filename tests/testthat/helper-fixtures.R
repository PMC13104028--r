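# Shared fixture builders. All randomness is seeded by the caller.

# Exact logistic series on a 2-fold dilution grid.
make_logistic_series <- function(r_max, r_min, x0, p, top = 1666.7,
                                 n = 16, sd = 0, n_rep = 1) {
  x <- top / 2^(seq_len(n) - 1)
  params <- logistic_params(r_max = r_max, r_min = r_min, x0 = x0, p = p)
  titration_series(x, logistic_value(x, params), r_sd = sd, n_rep = n_rep)
}

# Small SMILES set: 8 clearly distinct structures plus a near-duplicate
# pair of long-chain alcohols (high path-fingerprint similarity).
prune_test_smiles <- function() {
  c(d1 = "O=Cc1ccccc1", d2 = "O=Cc1ccncc1", d3 = "O=CC1CCCCC1",
    d4 = "O=Cc1ccco1", d5 = "O=Cc1cccs1", d6 = "O=Cc1ccc(O)cc1",
    d7 = "OC(=O)c1ccccc1", d8 = "O=Cc1ccc(Cl)cc1",
    near_a = "CCCCCCCCCO", near_b = "CCCCCCCCCCO")
}

standard_itc_protocol <- function() {
  itc_protocol(cell_conc = 25, syringe_conc = 500, cell_volume = 275,
               injection_volumes = c(0.2, rep(3, 19)))
}
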