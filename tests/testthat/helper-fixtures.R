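# shared fixtures: the Suwon reference site and small hand-built objects

ref_comp <- function() {
  validate_composition(c("Zelkova serrata" = 112, "Prunus yedoensis" = 70,
                         "Pinus densiflora" = 0, "other" = 26))
}

# three-species toy used where the fourth (zero-count) species is noise
zpo_comp <- function() validate_composition(c(Z = 112, P = 70, O = 26))

toy_params <- function(n = 3, annual = c(60, 40, 20),
                       phenology = c("deciduous", "deciduous", "evergreen")) {
  species_params(paste0("s", seq_len(n)), annual[seq_len(n)],
                 phenology[seq_len(n)])
}
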