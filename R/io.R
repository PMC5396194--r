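#' Read and write concentration-mortality tables
#'
#' Tab-delimited text with columns `concentration`, `n_exposed`, `n_dead`,
#' `strain`, `stage`, `insecticide`, `synergist`; the concentration unit is
#' carried in a `# unit:` header comment line.
#'
#' @param table A `conc_mort_table`.
#' @param path File path.
#' @return `read_mortality_table` returns a `conc_mort_table`;
#'   `write_mortality_table` returns `path` invisibly.
#' @export
write_mortality_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unit: ", attr(table, "unit") %||% ""), con)
  write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_mortality_table
#' @export
read_mortality_table <- function(path) {
  first <- readLines(path, n = 1)
  unit <- if (startsWith(first, "# unit:")) trimws(sub("# unit:", "", first))
          else NULL
  out <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(out, "unit") <- unit
  class(out) <- c("conc_mort_table", "data.frame")
  out
}

#' Read and write voltage-clamp traces
#'
#' Two-column delimited text (`time_ms`, `current_uA`) preceded by a
#' structured header block (`# key: value` lines) carrying the protocol,
#' sampling interval and trace metadata.
#'
#' @param trace A `current_trace`.
#' @param path File path.
#' @return `read_trace` returns a `current_trace`; `write_trace` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  pr <- trace$protocol
  hdr <- c(v_hold = pr$v_hold, v_step = pr$v_step, n_pulses = pr$n_pulses,
           pulse_ms = pr$pulse_ms, inter_ms = pr$inter_ms,
           sample_interval = trace$sample_interval, pre_ms = trace$pre_ms,
           tail_ms = trace$tail_ms)
  meta <- trace$meta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(hdr), format(hdr, trim = TRUE)), con)
  for (nm in names(meta))
    writeLines(sprintf("# meta_%s: %s", nm, meta[[nm]]), con)
  writeLines("time_ms\tcurrent_uA", con)
  write.table(data.frame(time_ms = trace$time, current_uA = trace$current),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  hdr_lines <- grep("^# ", lines, value = TRUE)
  kv <- strsplit(sub("^# ", "", hdr_lines), ": ")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  h <- setNames(as.list(vals), keys)
  num <- function(k) as.numeric(h[[k]])
  meta_keys <- grep("^meta_", keys, value = TRUE)
  meta <- setNames(as.list(vals[match(meta_keys, keys)]),
                   sub("^meta_", "", meta_keys))
  dat <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(
    list(time = dat$time_ms, current = dat$current_uA,
         sample_interval = num("sample_interval"),
         protocol = voltage_protocol(num("v_hold"), num("v_step"),
                                     num("n_pulses"), num("pulse_ms"),
                                     num("inter_ms")),
         pre_ms = num("pre_ms"), tail_ms = num("tail_ms"), meta = meta),
    class = "current_trace")
}

#' Read and write FASTA sequence sets
#'
#' Thin wrappers over Biostrings' FASTA support, keeping sequences as plain
#' named character vectors in the rest of the package.
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path File path.
#' @return `read_fasta` returns a named character vector; `write_fasta`
#'   returns `path` invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Read a population screening table
#'
#' Tab-delimited text with a `population` column and codon-string columns
#' `codon_410`, `codon_1534` (one per screened site).
#'
#' @param path File path.
#' @return Data frame suitable for [screen_populations()].
#' @export
read_screen_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write an analysis summary as JSON
#'
#' @param x A list or data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
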