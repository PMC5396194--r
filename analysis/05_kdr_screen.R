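#!/usr/bin/env Rscript
# Sequence-level kdr analysis: compare the synthetic susceptible and
# resistant strain CDSs (6 planted synonymous changes + V410L + F1534C),
# call diploid genotypes over the 10-individual resistant panel, compute
# allele frequencies, and screen the field-population codon table.

library(kdrtox)
dir.create("results", showWarnings = FALSE)

spec <- sequence_sim_spec(
  synthetic_channel_cds(),
  syn_positions = c(100L, 200L, 300L, 700L, 900L, 1200L),
  nonsyn_changes = data.frame(codon = c(410L, 1534L),
                              wild_codon = c("GTA", "TTC"),
                              mutant_codon = c("TTA", "TGC")),
  n_individuals = 10,
  genotype_config = rbind(
    data.frame(individual = 1:10, residue = 410L,
               zygosity = rep(c("hom_mutant", "het", "hom_wild"),
                              c(3, 4, 3))),
    data.frame(individual = 1:10, residue = 1534L,
               zygosity = "hom_mutant")),
  seed = 11L)

pair <- generate_strain_pair(spec)
write_fasta(c(susceptible = pair$susceptible, resistant = pair$resistant),
            "results/strain_pair.fasta")
vc <- compare_cds(pair$susceptible, pair$resistant)
message("Strain comparison: ", nrow(vc), " nucleotide difference(s), ",
        attr(vc, "n_nonsynonymous"), " nonsynonymous:")
print(as.data.frame(vc))

panel <- generate_genotype_panel(spec)
f410 <- allele_frequency(panel, 410)
f1534 <- allele_frequency(panel, 1534)
message(sprintf("\nResistant panel allele frequencies: V410L %.0f%%, F1534C %.0f%%",
                f410, f1534))

scr <- screen_populations(read_screen_table(
  system.file("extdata", "pernambuco_kdr_screen.tsv", package = "kdrtox")))
print(scr)

write_summary_json(list(
  strain_differences = as.data.frame(vc),
  allele_frequency_410 = as.numeric(f410),
  allele_frequency_1534 = as.numeric(f1534),
  screen_carriers = as.list(scr$carriers)), "results/kdr_screen.json")
message("\nwrote results/kdr_screen.json")
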