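# File interfaces: FASTA genomes via Biostrings, tab-separated tables
# with headers for everything else, YAML simulation configs.

#' Write a genome to FASTA (60-column wrapped)
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case contig sequences.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write a pipeline table as TSV with header
#'
#' @param df data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline TSV with header
#'
#' @param path File path.
#' @return data.frame (strings kept as characters).
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' Read a simulation config from YAML
#'
#' Scalar fields map directly onto [sim_config()] arguments; unknown
#' fields are an error.
#'
#' @param path YAML file path.
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(sim_config, y)
}

#' Write a simulation config to YAML
#'
#' @param config A [sim_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
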