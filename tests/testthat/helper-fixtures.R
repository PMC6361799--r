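# Shared fixture builders: tiny point-charge topologies and dimers built in
# code at test time.

# minimal topology from parallel per-atom vectors; chain "A" atoms are
# partner1, chain "B" partner2
make_point_topology <- function(charge, chain,
                                rmin_half = 0, epsilon = 0,
                                atom_name = NULL, element = "C",
                                residue_number = NULL,
                                donor_heavy = FALSE, acceptor = FALSE,
                                polar_hydrogen = FALSE, bonded_heavy = NA_integer_,
                                temperature = 300) {
  n <- length(charge)
  if (is.null(atom_name)) atom_name <- paste0("X", seq_len(n))
  if (is.null(residue_number)) residue_number <- seq_len(n)
  atoms <- data.frame(
    atom_name = atom_name, element = rep_len(element, n),
    residue_number = residue_number,
    residue_name = rep("RES", n), chain_id = chain,
    charge = charge, rmin_half = rep_len(rmin_half, n),
    epsilon = rep_len(epsilon, n),
    donor_heavy = rep_len(donor_heavy, n),
    acceptor = rep_len(acceptor, n),
    polar_hydrogen = rep_len(polar_hydrogen, n),
    bonded_heavy = rep_len(bonded_heavy, n),
    stringsAsFactors = FALSE)
  topology(atoms, "A", "B", temperature = temperature)
}

# a standard small dimer reused across tests
toy_dimer <- function(n_hb = 2, n_sb = 1, seed = 7, n_res = 3) {
  build_toy_dimer(dimer_spec(n_res, n_res, n_designed_hbonds = n_hb,
                             n_salt_bridges = n_sb, seed = seed))
}

kT300 <- 0.0019872041 * 300
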