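# Shared small fixtures, built in code at test time.

tiny_params <- function(n_chains = 2L, n_monomers = 6L, seed = 101L,
                        sequences = NULL) {
  generator_params(n_chains = n_chains, n_monomers = n_monomers,
                   sequences = sequences,
                   duration = 5 * 200, save_interval = 200, seed = seed)
}

tiny_ensemble <- function(n_frames = 3L, n_chains = 2L, n_monomers = 6L,
                          seed = 101L, composition = "homopolymer",
                          sequences = NULL) {
  p <- tiny_params(n_chains, n_monomers, seed, sequences)
  pack_frames(p, composition, n_frames = n_frames)
}

# single sampled chain plus its encoded sample
tiny_encoded <- function(sequence = c("L", "L", "D", "L"), seed = 7L) {
  p <- tiny_params(1L, length(sequence), seed,
                   sequences = list(sequence))
  set.seed(seed)
  coords <- sample_chain(p, sequence)
  chain <- build_chain(sequence)
  cfg <- atomistic_config(coords, p$box, chain)
  cg <- map_to_cg(cfg)
  sc <- codec_scales(s = length(sequence))
  ty <- assign_types(chain, "homopolymer")
  enc <- encode_chain(chain, coords, cg$Q, ty$types, ty$k, sc)
  list(params = p, chain = chain, coords = coords, cfg = cfg, cg = cg,
       scales = sc, types = ty, enc = enc)
}
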