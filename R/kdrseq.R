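# single-codon translation through the standard genetic code
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

#' Translate an unambiguous coding sequence
#'
#' Standard genetic-code translation of a full CDS. Ambiguity codes are
#' rejected: full-CDS translation is meaningful only for an unambiguous
#' consensus. Internal stop codons are flagged with a warning and recorded
#' in the `internal_stops` attribute.
#'
#' @param cds Nucleotide string (A/C/G/T), length divisible by 3.
#' @return Amino-acid string (stop as `*`), with attribute
#'   `internal_stops` giving codon indices of any premature stops.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) == 0) return(structure("", internal_stops = integer()))
  if (grepl("[^ACGT]", cds))
    stop("ambiguity codes present; translation requires an unambiguous CDS")
  if (nchar(cds) %% 3 != 0) stop("CDS length must be divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  aav <- strsplit(aa, "")[[1]]
  stops <- which(aav == "*")
  stops <- stops[stops < length(aav)]
  if (length(stops))
    warning("internal stop codon(s) at codon ",
            paste(stops, collapse = ", "))
  structure(aa, internal_stops = as.integer(stops))
}

#' Compare two aligned coding sequences
#'
#' Reports every mismatching nucleotide position with its codon context and
#' synonymous/nonsynonymous classification. Sequences must be positionally
#' comparable (equal length, same codon-numbering offset); alignment is out
#' of scope — pre-align unequal sequences before comparing.
#'
#' @param a,b Nucleotide strings (A/C/G/T), equal length divisible by 3.
#' @return A `variant_comparison`: data frame with `position`, `base_a`,
#'   `base_b`, `codon`, `aa_a`, `aa_b`, `class`, plus attributes
#'   `n_synonymous` and `n_nonsynonymous`.
#' @export
compare_cds <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b))
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b),
         "); pre-align them before comparison")
  if (nchar(a) %% 3 != 0) stop("CDS length must be divisible by 3")
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b))
    stop("comparison requires unambiguous A/C/G/T sequences")
  d <- diff_table(a, b)
  names(d) <- c("position", "base_a", "base_b", "codon", "aa_a", "aa_b",
                "class")
  structure(d, n_synonymous = sum(d$class == "synonymous"),
            n_nonsynonymous = sum(d$class == "nonsynonymous"),
            class = c("variant_comparison", "data.frame"))
}

expand_iupac_codon <- function(codon) {
  bases <- strsplit(toupper(codon), "")[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  if (!all(bases %in% names(map)))
    stop("invalid IUPAC letter(s) in codon '", codon, "'")
  sets <- lapply(bases, function(b) strsplit(map[[b]], "")[[1]])
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  apply(grid, 1, paste0, collapse = "")
}

#' Diploid codon call at a residue through IUPAC expansion
#'
#' Extracts the codon for `residue` (mapped through `offset`: sequence codon
#' index = residue - offset), expands any IUPAC ambiguity codes, and calls
#' the genotype. A single expansion is homozygous (wild or mutant by
#' comparison with `wild_aa`); two expansions translating to distinct amino
#' acids are heterozygous; more than two expansions cannot come from one
#' diploid site and are called ambiguous, never silently resolved.
#'
#' @param amplicon Nucleotide string, possibly containing IUPAC ambiguity
#'   codes.
#' @param residue Reported residue number (1-based).
#' @param offset Codon-numbering offset (sequence codon = residue - offset).
#' @param wild_aa Wild-type amino acid at the residue; defaults to the
#'   [kdr_sites()] entry when the residue is a known kdr position.
#' @param individual Optional individual id carried in the call.
#' @return A `codon_call`: list with `individual`, `residue`, `codon`,
#'   `amino_acids` (character vector) and `zygosity` in
#'   `c("hom_wild", "het", "hom_mutant", "ambiguous")`.
#' @export
call_codon <- function(amplicon, residue, offset = 0, wild_aa = NULL,
                       individual = NA_character_) {
  idx <- residue - offset
  if (idx < 1 || 3 * idx > nchar(amplicon))
    stop("residue ", residue, " (sequence codon ", idx,
         ") lies outside the amplicon")
  if (is.null(wild_aa)) {
    sites <- kdr_sites()
    hit <- match(residue, sites$residue)
    wild_aa <- if (!is.na(hit)) sites$wild_aa[hit] else NA_character_
  }
  codon <- toupper(substr(amplicon, 3 * idx - 2, 3 * idx))
  expansions <- expand_iupac_codon(codon)
  aas <- unique(vapply(expansions, translate_codon, character(1)))
  zyg <- if (length(expansions) > 2) "ambiguous"
    else if (length(expansions) == 2 && length(aas) == 2) "het"
    else if (!is.na(wild_aa) && all(aas == wild_aa)) "hom_wild"
    else if (!is.na(wild_aa)) "hom_mutant"
    else "hom_wild"  # no reference: single amino acid, assume reference-like
  structure(list(individual = individual, residue = residue, codon = codon,
                 amino_acids = aas, zygosity = zyg),
            class = "codon_call")
}

#' Mutant allele frequency at a residue
#'
#' Counts mutant alleles over a genotype panel: homozygous mutant
#' individuals contribute 2 alleles, heterozygotes 1, homozygous wild 0;
#' the frequency is `mutant alleles / (2 * n individuals) * 100`.
#' Individuals with ambiguous calls are excluded with a warning and the
#' denominator reduced accordingly.
#'
#' @param panel A `genotype_panel` (from [generate_genotype_panel()]) or a
#'   list of `codon_call` objects.
#' @param residue Residue number.
#' @param mutant_aa Mutant amino acid; defaults to the [kdr_sites()] entry.
#' @param offset Codon-numbering offset (used when calling from a panel).
#' @return Frequency in percent, with attributes `n_individuals` (used) and
#'   `n_excluded`.
#' @export
allele_frequency <- function(panel, residue, mutant_aa = NULL, offset = NULL) {
  sites <- kdr_sites()
  if (is.null(mutant_aa)) {
    hit <- match(residue, sites$residue)
    if (!is.na(hit)) mutant_aa <- sites$mutant_aa[hit]
  }
  calls <- if (inherits(panel, "genotype_panel")) {
    if (is.null(mutant_aa)) {
      site <- panel$sites[panel$sites$codon == residue - panel$offset, ]
      if (nrow(site) == 1)
        mutant_aa <- translate_codon(site$mutant_codon)
    }
    lapply(names(panel$sequences), function(id)
      call_codon(panel$sequences[[id]], residue,
                 offset = offset %||% panel$offset, individual = id))
  } else panel
  if (is.null(mutant_aa))
    stop("`mutant_aa` is required for residues outside the kdr site table")
  zyg <- vapply(calls, function(cc) cc$zygosity, character(1))
  amb <- zyg == "ambiguous"
  if (any(amb))
    warning(sum(amb), " individual(s) with ambiguous calls excluded; n = ",
            sum(!amb))
  calls <- calls[!amb]
  n_mut <- vapply(calls, function(cc) {
    has_mut <- mutant_aa %in% cc$amino_acids
    if (cc$zygosity == "het") as.integer(has_mut)
    else if (has_mut) 2L else 0L
  }, integer(1))
  structure(100 * sum(n_mut) / (2 * length(calls)),
            n_individuals = length(calls), n_excluded = sum(amb))
}

#' Screen populations for kdr mutations from codon strings
#'
#' Counts, per kdr site, how many populations carry the mutant allele: any
#' codon string whose IUPAC expansion contains the mutant amino acid counts
#' the population as a carrier (population rows are consensus calls, so
#' carrier status — not zygosity — is what is tabulated). Populations with
#' an invalid codon string are flagged and excluded from the totals.
#'
#' @param table Data frame with a `population` column and one codon-string
#'   column per site named `codon_<residue>` (e.g. `codon_410`,
#'   `codon_1534`).
#' @param sites Site table, defaulting to [kdr_sites()].
#' @return A `screen_summary`: list with `calls` (per population and site:
#'   codon, carrier flag, valid flag) and `carriers` (named count of carrier
#'   populations per site) and `n_excluded`.
#' @export
screen_populations <- function(table, sites = kdr_sites()) {
  stopifnot("population" %in% names(table))
  calls <- list()
  excluded <- character()
  for (r in seq_len(nrow(sites))) {
    col <- paste0("codon_", sites$residue[r])
    if (!col %in% names(table)) stop("missing column ", col)
    for (i in seq_len(nrow(table))) {
      codon <- toupper(table[[col]][i])
      rec <- list(population = table$population[i],
                  residue = sites$residue[r], codon = codon)
      rec$valid <- !is.na(codon) && nchar(codon) == 3 &&
        !grepl(sprintf("[^%s]", paste(names(Biostrings::IUPAC_CODE_MAP),
                                      collapse = "")), codon)
      rec$carrier <- if (rec$valid) {
        aas <- vapply(expand_iupac_codon(codon), translate_codon,
                      character(1))
        sites$mutant_aa[r] %in% aas
      } else NA
      if (!rec$valid) excluded <- union(excluded, table$population[i])
      calls[[length(calls) + 1L]] <- rec
    }
  }
  calls <- do.call(rbind, lapply(calls, as.data.frame))
  keep <- !is.null(calls) && nrow(calls) > 0
  use <- if (keep) calls$valid & !(calls$population %in% excluded) else logical()
  carriers <- if (keep) tapply(calls$carrier[use], calls$residue[use], sum)
              else setNames(integer(nrow(sites)),
                            as.character(sites$residue))
  structure(list(calls = calls,
                 carriers = setNames(as.integer(carriers),
                                     paste0("residue_", names(carriers))),
                 n_excluded = length(excluded)),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("kdr population screen:\n")
  for (nm in names(x$carriers))
    cat(sprintf("  %s: %d carrier population(s)\n", nm, x$carriers[[nm]]))
  if (x$n_excluded)
    cat("  ", x$n_excluded, "population(s) excluded (invalid codon)\n")
  invisible(x)
}

#' @export
print.codon_call <- function(x, ...) {
  cat(sprintf("codon %s at residue %d: %s (%s)\n", x$codon, x$residue,
              paste(x$amino_acids, collapse = "/"), x$zygosity))
  invisible(x)
}
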