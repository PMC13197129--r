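# shared fixture builders (everything generated in code, nothing stored)

# one synthetic fragment of length k with given or random torsions
make_fragment <- function(sequence = "GAC", torsions = aform_torsions(),
                          entry_id = "SYN0001", year = 2000L,
                          pucker = "C3'-endo", start_index = 1L) {
  chain_to_fragment(
    build_ideal_chain(sequence, torsions, pucker = pucker,
                      start_index = start_index),
    entry_id, year)
}

# a set of n well-separated random conformer fragments (deterministic)
make_conformer_set <- function(n, k = 3, frame = "FULL15", seed = 1,
                               min_separation = 1.2) {
  pl <- plant_fragment_clusters(n, 1, k = k, frame = frame, intra_noise = 0,
                                min_separation = min_separation, seed = seed)
  pl$fragments
}

expect_fragment_invariants <- function(fragments) {
  for (r in seq_len(nrow(fragments))) {
    nts <- fragments$nucleotides[[r]]
    expect_identical(nrow(nts), as.integer(fragments$k[[r]]))
    expect_identical(nchar(fragments$sequence[[r]]), as.integer(fragments$k[[r]]))
    expect_true(all(nts$res_name %in% c("A", "C", "G", "U")))
    expect_identical(diff(nts$seq_index), rep(1L, nrow(nts) - 1L))
    expect_true(all(vapply(nts$atoms, function(m) all(is.finite(m)), logical(1))))
    expect_false(any(vapply(nts$atoms, function(m) anyDuplicated(rownames(m)) > 0,
                            logical(1))))
  }
}
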