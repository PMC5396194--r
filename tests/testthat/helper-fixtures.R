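# shared builders for synthetic fixtures; everything is generated in code

# short pulse train for cheap unit tests; acceptance-scale work uses the
# full 100-pulse default
short_protocol <- function(n_pulses = 10) voltage_protocol(n_pulses = n_pulses)

# the resistant-strain design: 6 synonymous sites plus V410L and F1534C,
# panel of 10 individuals (3 hom-mutant / 4 het / 3 hom-wild at 410,
# all hom-mutant at 1534)
kdr_pair_spec <- function(seed = 11L,
                          zyg410 = rep(c("hom_mutant", "het", "hom_wild"),
                                       c(3, 4, 3))) {
  sequence_sim_spec(
    synthetic_channel_cds(),
    syn_positions = c(100L, 200L, 300L, 700L, 900L, 1200L),
    nonsyn_changes = data.frame(codon = c(410L, 1534L),
                                wild_codon = c("GTA", "TTC"),
                                mutant_codon = c("TTA", "TGC"),
                                stringsAsFactors = FALSE),
    n_individuals = 10,
    genotype_config = rbind(
      data.frame(individual = 1:10, residue = 410L, zygosity = zyg410),
      data.frame(individual = 1:10, residue = 1534L,
                 zygosity = "hom_mutant")),
    seed = seed)
}

# the adult susceptible deltamethrin bioassay design: slope 5.3,
# LC50 7.6e-6, five concentrations spanning 5-95% mortality, ~134 per jar
adult_delta_spec <- function(seed, n_per_conc = 134L) {
  lc50 <- 7.6e-6; slope <- 5.3
  mortality_sim_spec(lc50, slope, design_concentrations(lc50, slope),
                     n_per_conc = n_per_conc, n_control = 0, seed = seed)
}

# independent codon lookup built from the classic 64-codon table in
# T/C/A/G order (used as a second-opinion oracle for translation)
oracle_translate <- function(codon) {
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  bases <- c(T = 0L, C = 1L, A = 2L, G = 3L)
  b <- bases[strsplit(toupper(codon), "")[[1]]]
  aas[16L * b[1] + 4L * b[2] + b[3] + 1L]
}
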