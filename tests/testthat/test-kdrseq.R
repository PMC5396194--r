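test_that("translation follows the codon key and the standard code", {
  expect_equal(as.character(translate_cds("GTA")), "V")
  expect_equal(as.character(translate_cds("TTA")), "L")
  expect_equal(as.character(translate_cds("TTC")), "F")
  expect_equal(as.character(translate_cds("TGC")), "C")
  expect_equal(as.character(translate_cds("")), "")
  set.seed(13)
  bases <- c("A", "C", "G", "T")
  codons <- replicate(1000, paste0(sample(bases, 3, TRUE), collapse = ""))
  got <- vapply(codons, function(cd)
    as.character(suppressWarnings(translate_cds(cd))), character(1))
  want <- vapply(codons, oracle_translate, character(1))
  expect_identical(unname(got), unname(want))
})

test_that("translation rejects ambiguity and flags internal stops", {
  expect_error(translate_cds("ATGKCA"), "ambiguity")
  expect_error(translate_cds("ATGC"), "divisible")
  expect_warning(aa <- translate_cds("ATGTAAGGG"), "internal stop")
  expect_equal(attr(aa, "internal_stops"), 2L)
})

test_that("the planted strain pair shows 8 differences, 2 nonsynonymous", {
  pair <- generate_strain_pair(kdr_pair_spec())
  vc <- compare_cds(pair$susceptible, pair$resistant)
  expect_equal(nrow(vc), 8)
  expect_equal(attr(vc, "n_nonsynonymous"), 2)
  expect_equal(attr(vc, "n_synonymous"), 6)
  ns <- vc[vc$class == "nonsynonymous", ]
  expect_setequal(ns$codon, c(410L, 1534L))
  expect_setequal(paste0(ns$aa_a, ns$aa_b), c("VL", "FC"))
})

test_that("identical sequences compare empty; empty change lists are identity", {
  cds <- synthetic_channel_cds(1540)
  expect_equal(nrow(compare_cds(cds, cds)), 0)
  pair <- generate_strain_pair(sequence_sim_spec(cds))
  expect_identical(pair$susceptible, pair$resistant)
})

test_that("comparison is symmetric up to allele swapping and checks inputs", {
  pair <- generate_strain_pair(kdr_pair_spec())
  ab <- compare_cds(pair$susceptible, pair$resistant)
  ba <- compare_cds(pair$resistant, pair$susceptible)
  expect_equal(ab$position, ba$position)
  expect_equal(ab$base_a, ba$base_b)
  expect_equal(ab$aa_a, ba$aa_b)
  expect_equal(ab$class, ba$class)
  expect_error(compare_cds("ATGATG", "ATG"), "pre-align")
  expect_error(compare_cds("ATK", "ATG"), "unambiguous")
})

test_that("random planted mutation sets are recovered exactly", {
  cds <- synthetic_channel_cds(1540)
  # only codons with a single-base synonymous alternative are eligible
  has_syn_neighbor <- vapply(20:1500, function(cd) {
    codon <- substr(cds, 3 * cd - 2, 3 * cd)
    any(vapply(1:3, function(pos) {
      alts <- setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))
      any(vapply(alts, function(b) {
        alt <- codon; substr(alt, pos, pos) <- b
        oracle_translate(alt) == oracle_translate(codon)
      }, logical(1)))
    }, logical(1)))
  }, logical(1))
  eligible <- (20:1500)[has_syn_neighbor]
  for (seed in 1:10) {
    set.seed(seed)
    syn <- sort(sample(eligible, sample(2:8, 1)))
    spec <- sequence_sim_spec(cds, syn_positions = syn, seed = seed)
    pair <- generate_strain_pair(spec)
    vc <- compare_cds(pair$susceptible, pair$resistant)
    expect_equal(nrow(vc), length(syn))
    expect_setequal(vc$codon, syn)
    expect_true(all(vc$class == "synonymous"))
    expect_identical(as.character(translate_cds(pair$resistant)),
                     as.character(translate_cds(pair$susceptible)))
    # the generator's own plant list matches the re-analysis
    expect_equal(vc$position, pair$planted$position)
  }
})

test_that("misdeclared changes are rejected", {
  cds <- synthetic_channel_cds(1540)
  # a nonsynonymous request that does not change the amino acid
  expect_error(sequence_sim_spec(
    cds, nonsyn_changes = data.frame(codon = 410, wild_codon = "GTA",
                                     mutant_codon = "GTC")),
    "synonymous")
  # wild codon not matching the template
  expect_error(sequence_sim_spec(
    cds, nonsyn_changes = data.frame(codon = 410, wild_codon = "AAA",
                                     mutant_codon = "CAA")),
    "wild")
  # a codon with no single-base synonymous alternative (ATG at codon 1)
  expect_error(
    generate_strain_pair(sequence_sim_spec(cds, syn_positions = 1L)),
    "synonymous alternative")
})

test_that("codon calls expand IUPAC codes into diploid genotypes", {
  cds <- synthetic_channel_cds()
  call <- call_codon(cds, 410)
  expect_equal(call$codon, "GTA")
  expect_equal(call$zygosity, "hom_wild")
  expect_equal(call$amino_acids, "V")
  het <- sub("TTC$", "", cds)  # not used further; build a het amplicon:
  amp <- cds
  substr(amp, 3 * 1534 - 2, 3 * 1534) <- "TKC"
  hc <- call_codon(amp, 1534)
  expect_equal(hc$zygosity, "het")
  expect_setequal(hc$amino_acids, c("F", "C"))
  substr(amp, 3 * 1534 - 2, 3 * 1534) <- "NNN"
  expect_equal(call_codon(amp, 1534)$zygosity, "ambiguous")
  expect_error(call_codon("ATGGTA", 410), "outside")
  # offset mapping: residue 410 at sequence codon 2
  short <- paste0("ATG", "GTA")
  expect_equal(call_codon(short, 410, offset = 408)$codon, "GTA")
})

test_that("allele frequencies follow the diploid accounting", {
  spec <- kdr_pair_spec()
  panel <- generate_genotype_panel(spec)
  expect_equal(as.numeric(allele_frequency(panel, 1534)), 100)
  expect_equal(as.numeric(allele_frequency(panel, 410)), 50)
  all_wild <- kdr_pair_spec(zyg410 = rep("hom_wild", 10))
  expect_equal(as.numeric(allele_frequency(generate_genotype_panel(all_wild),
                                           410)), 0)
})

test_that("panel round trips reproduce every planted zygosity configuration", {
  set.seed(14)
  zygs <- c("hom_wild", "het", "hom_mutant")
  for (i in 1:8) {
    z410 <- sample(zygs, 10, replace = TRUE)
    spec <- kdr_pair_spec(zyg410 = z410)
    panel <- generate_genotype_panel(spec)
    calls <- lapply(panel$sequences, call_codon, residue = 410)
    expect_identical(unname(vapply(calls, `[[`, character(1), "zygosity")),
                     z410)
    planted <- 100 * (2 * sum(z410 == "hom_mutant") + sum(z410 == "het")) / 20
    expect_equal(as.numeric(allele_frequency(panel, 410)), planted)
  }
})

test_that("ambiguous individuals are excluded from frequencies with warning", {
  spec <- kdr_pair_spec()
  panel <- generate_genotype_panel(spec)
  bad <- panel$sequences[[1]]
  substr(bad, 3 * 410 - 2, 3 * 410) <- "NNN"
  panel$sequences[[1]] <- bad
  expect_warning(f <- allele_frequency(panel, 410), "ambiguous")
  expect_equal(attr(f, "n_individuals"), 9)
  expect_equal(attr(f, "n_excluded"), 1)
})

test_that("population screening counts carriers per printed codon strings", {
  path <- system.file("extdata", "pernambuco_kdr_screen.tsv",
                      package = "kdrtox")
  scr <- screen_populations(read_screen_table(path))
  expect_equal(scr$carriers[["residue_1534"]], 5L)
  expect_equal(scr$carriers[["residue_410"]], 0L)
  empty <- data.frame(population = character(), codon_410 = character(),
                      codon_1534 = character())
  scr0 <- screen_populations(empty)
  expect_true(all(scr0$carriers == 0) || length(scr0$carriers) == 0)
})

test_that("random screening tables match a brute-force scan oracle", {
  set.seed(15)
  codons410 <- c("GTA", "TTA", "KTA")  # wild, mutant, het V/L
  codons1534 <- c("TTC", "TGC", "TKC")
  for (i in 1:10) {
    tb <- data.frame(population = paste0("pop", 1:12),
                     codon_410 = sample(codons410, 12, TRUE),
                     codon_1534 = sample(codons1534, 12, TRUE),
                     stringsAsFactors = FALSE)
    scr <- screen_populations(tb)
    # brute force: a population carries the mutant when its codon string is
    # the mutant codon or the heterozygous merge
    expect_equal(scr$carriers[["residue_410"]],
                 sum(tb$codon_410 %in% c("TTA", "KTA")))
    expect_equal(scr$carriers[["residue_1534"]],
                 sum(tb$codon_1534 %in% c("TGC", "TKC")))
  }
})

test_that("invalid codon strings exclude a population from totals", {
  tb <- data.frame(population = c("a", "b"),
                   codon_410 = c("GTA", "XYZ"),
                   codon_1534 = c("TGC", "TGC"), stringsAsFactors = FALSE)
  scr <- screen_populations(tb)
  expect_equal(scr$n_excluded, 1)
  expect_equal(scr$carriers[["residue_1534"]], 1L)
})
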