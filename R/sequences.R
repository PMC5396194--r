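#' Known kdr sites of the mosquito sodium channel
#'
#' Codon key for the two knockdown-resistance positions handled throughout:
#' V410L in domain I S6 and F1534C in domain III S6 (V: GTA; L: TTA;
#' F: TTC; C: TGC). Residue numbers follow the conventional reference
#' protein numbering; sequences with a different frame supply an offset.
#'
#' @return Data frame with `residue`, `wild_codon`, `mutant_codon`,
#'   `wild_aa`, `mutant_aa`.
#' @export
kdr_sites <- function() {
  data.frame(residue = c(410L, 1534L),
             wild_codon = c("GTA", "TTC"),
             mutant_codon = c("TTA", "TGC"),
             wild_aa = c("V", "F"),
             mutant_aa = c("L", "C"),
             stringsAsFactors = FALSE)
}

#' Synthetic sodium-channel open reading frame
#'
#' A deterministic, seeded 1600-codon synthetic CDS carrying the wild-type
#' kdr codons (GTA at codon 410, TTC at codon 1534; numbering offset 0) and
#' no internal stop codons. It stands in for a real channel CDS in
#' simulations and tests; it is not a biological sequence.
#'
#' @param n_codons Length in codons (>= 1534).
#' @param seed Integer seed.
#' @return Upper-case nucleotide string of length `3 * n_codons`.
#' @export
synthetic_channel_cds <- function(n_codons = 1600, seed = 410153L) {
  stopifnot(n_codons >= 1534)
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                              c("T", "C", "A", "G")), 1, paste0,
                  collapse = "")
  coding <- setdiff(codons, stops)
  seqc <- sample(coding, n_codons, replace = TRUE)
  seqc[1] <- "ATG"
  sites <- kdr_sites()
  seqc[sites$residue] <- sites$wild_codon
  paste0(seqc, collapse = "")
}

#' Specification of a simulated strain pair / genotype panel
#'
#' Plants a configurable set of synonymous and nonsynonymous differences on
#' a template CDS (the "susceptible" strain) to produce a "resistant"
#' strain, and describes the per-individual zygosity of a diploid amplicon
#' panel at the nonsynonymous sites.
#'
#' @param template_cds Nucleotide string, length divisible by 3, long enough
#'   to contain every queried codon.
#' @param syn_positions Codon indices (1-based) receiving a single-base
#'   synonymous substitution each.
#' @param nonsyn_changes Data frame with `codon`, `wild_codon`,
#'   `mutant_codon`; every change must alter the translated amino acid and
#'   match the template at `codon`.
#' @param n_individuals Panel size.
#' @param genotype_config Data frame with `individual` (1..n), `residue`
#'   (codon number, offset 0) and `zygosity` in
#'   `c("hom_wild", "het", "hom_mutant")`, covering every individual at
#'   every nonsynonymous site.
#' @param seed Integer seed (selects the synonymous substitution bases).
#' @return A `sequence_sim_spec`.
#' @export
sequence_sim_spec <- function(template_cds, syn_positions = integer(),
                              nonsyn_changes = NULL, n_individuals = 0,
                              genotype_config = NULL, seed = 1L) {
  template_cds <- toupper(template_cds)
  if (nchar(template_cds) %% 3 != 0)
    stop("template CDS length must be divisible by 3")
  if (grepl("[^ACGT]", template_cds))
    stop("template CDS must contain only A/C/G/T")
  n_codons <- nchar(template_cds) / 3
  if (length(syn_positions) && any(syn_positions < 1 | syn_positions > n_codons))
    stop("synonymous codon indices outside the template")
  if (!is.null(nonsyn_changes)) {
    stopifnot(all(c("codon", "wild_codon", "mutant_codon") %in%
                    names(nonsyn_changes)))
    if (any(nonsyn_changes$codon > n_codons))
      stop("nonsynonymous codon indices outside the template")
    for (r in seq_len(nrow(nonsyn_changes))) {
      cd <- nonsyn_changes$codon[r]
      have <- substr(template_cds, 3 * cd - 2, 3 * cd)
      if (have != nonsyn_changes$wild_codon[r])
        stop("template codon ", cd, " is ", have, ", not the stated wild ",
             "codon ", nonsyn_changes$wild_codon[r])
      if (translate_codon(nonsyn_changes$wild_codon[r]) ==
          translate_codon(nonsyn_changes$mutant_codon[r]))
        stop("change at codon ", cd, " does not alter the amino acid; ",
             "declare it as a synonymous position instead")
    }
    if (any(nonsyn_changes$codon %in% syn_positions))
      stop("a codon cannot be both synonymous and nonsynonymous")
  }
  if (n_individuals > 0) {
    if (is.null(genotype_config))
      stop("`genotype_config` required when n_individuals > 0")
    stopifnot(all(c("individual", "residue", "zygosity") %in%
                    names(genotype_config)))
    bad <- setdiff(genotype_config$zygosity,
                   c("hom_wild", "het", "hom_mutant"))
    if (length(bad)) stop("unknown zygosity label(s): ",
                          paste(bad, collapse = ", "))
    need <- expand.grid(individual = seq_len(n_individuals),
                        residue = nonsyn_changes$codon)
    key <- function(d) paste(d$individual, d$residue)
    if (!all(key(need) %in% key(genotype_config)))
      stop("`genotype_config` must cover every individual at every ",
           "nonsynonymous site")
  }
  structure(list(template_cds = template_cds, syn_positions = syn_positions,
                 nonsyn_changes = nonsyn_changes,
                 n_individuals = as.integer(n_individuals),
                 genotype_config = genotype_config, seed = as.integer(seed)),
            class = "sequence_sim_spec")
}

# single-base synonymous alternatives of a codon
synonymous_neighbors <- function(codon) {
  aa <- translate_codon(codon)
  out <- character()
  for (pos in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == substr(codon, pos, pos)) next
    alt <- codon
    substr(alt, pos, pos) <- b
    if (translate_codon(alt) == aa) out <- c(out, alt)
  }
  out
}

#' Generate a susceptible/resistant strain CDS pair with planted changes
#'
#' The susceptible CDS is the template; the resistant CDS carries one
#' seeded single-base synonymous substitution at each `syn_positions` codon
#' and the stated codon replacements at each nonsynonymous site. The planted
#' truth (every altered nucleotide position with its codon context and
#' class) is returned for downstream recovery checks.
#'
#' @param spec A [sequence_sim_spec()].
#' @return List with `susceptible`, `resistant` (nucleotide strings) and
#'   `planted` (data frame: `position`, `base_susceptible`,
#'   `base_resistant`, `codon`, `aa_susceptible`, `aa_resistant`, `class`).
#' @export
generate_strain_pair <- function(spec) {
  stopifnot(inherits(spec, "sequence_sim_spec"))
  set.seed(spec$seed)
  sus <- spec$template_cds
  res <- sus
  for (cd in spec$syn_positions) {
    codon <- substr(res, 3 * cd - 2, 3 * cd)
    alts <- synonymous_neighbors(codon)
    if (!length(alts))
      stop("codon ", cd, " (", codon, ") has no single-base synonymous ",
           "alternative; choose a different synonymous position")
    substr(res, 3 * cd - 2, 3 * cd) <- sample(alts, 1)
  }
  if (!is.null(spec$nonsyn_changes)) {
    for (r in seq_len(nrow(spec$nonsyn_changes))) {
      cd <- spec$nonsyn_changes$codon[r]
      substr(res, 3 * cd - 2, 3 * cd) <- spec$nonsyn_changes$mutant_codon[r]
    }
  }
  planted <- diff_table(sus, res)
  list(susceptible = sus, resistant = res, planted = planted)
}

diff_table <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  pos <- which(av != bv)
  if (!length(pos))
    return(data.frame(position = integer(), base_susceptible = character(),
                      base_resistant = character(), codon = integer(),
                      aa_susceptible = character(),
                      aa_resistant = character(), class = character(),
                      stringsAsFactors = FALSE))
  codon <- (pos - 1L) %/% 3L + 1L
  aa_a <- vapply(codon, function(cd)
    translate_codon(substr(a, 3 * cd - 2, 3 * cd)), character(1))
  aa_b <- vapply(codon, function(cd)
    translate_codon(substr(b, 3 * cd - 2, 3 * cd)), character(1))
  data.frame(position = pos, base_susceptible = av[pos],
             base_resistant = bv[pos], codon = codon,
             aa_susceptible = aa_a, aa_resistant = aa_b,
             class = ifelse(aa_a == aa_b, "synonymous", "nonsynonymous"),
             stringsAsFactors = FALSE)
}

iupac_merge <- function(bases) {
  bases <- sort(unique(bases))
  if (length(bases) == 1) return(bases)
  map <- Biostrings::IUPAC_CODE_MAP
  key <- paste0(bases, collapse = "")
  hit <- names(map)[vapply(map, function(x)
    paste0(sort(strsplit(x, "")[[1]]), collapse = "") == key, logical(1))]
  if (!length(hit)) stop("no IUPAC code for base set ", key)
  hit[1]
}

#' Generate a diploid amplicon panel with IUPAC heterozygote codes
#'
#' Produces one Sanger-style consensus sequence per individual on the
#' susceptible background: homozygous sites emit the plain codon
#' (wild or mutant), heterozygous sites merge the wild and mutant codons
#' base-wise into IUPAC ambiguity codes. The per-individual truth table is
#' retained so genotype calls and allele frequencies can be checked against
#' the planted configuration.
#'
#' @param spec A [sequence_sim_spec()] with `n_individuals > 0`.
#' @return A `genotype_panel`: list with `sequences` (named character
#'   vector), `truth` (the genotype configuration), `sites` (the
#'   nonsynonymous change table) and `offset` (0).
#' @export
generate_genotype_panel <- function(spec) {
  stopifnot(inherits(spec, "sequence_sim_spec"))
  if (spec$n_individuals < 1) stop("spec has no individuals")
  sites <- spec$nonsyn_changes
  seqs <- vapply(seq_len(spec$n_individuals), function(ind) {
    s <- spec$template_cds
    cfg <- spec$genotype_config[spec$genotype_config$individual == ind, ]
    for (r in seq_len(nrow(cfg))) {
      site <- sites[sites$codon == cfg$residue[r], ]
      codon <- switch(cfg$zygosity[r],
        hom_wild = site$wild_codon,
        hom_mutant = site$mutant_codon,
        het = {
          w <- strsplit(site$wild_codon, "")[[1]]
          m <- strsplit(site$mutant_codon, "")[[1]]
          paste0(vapply(1:3, function(i) iupac_merge(c(w[i], m[i])),
                        character(1)), collapse = "")
        },
        stop("unknown zygosity label: ", cfg$zygosity[r]))
      substr(s, 3 * cfg$residue[r] - 2, 3 * cfg$residue[r]) <- codon
    }
    s
  }, character(1))
  names(seqs) <- sprintf("individual_%02d", seq_len(spec$n_individuals))
  structure(list(sequences = seqs, truth = spec$genotype_config,
                 sites = sites, offset = 0L),
            class = "genotype_panel")
}
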