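# FASTA and expression-table input/output plus assembly summary statistics.

.DNA_CHARS <- c("A", "C", "G", "T", "U", "N")

#' Guess the alphabet of a set of residue strings
#'
#' Sequences consisting only of IUPAC nucleotide characters (ACGTUN) are
#' called \code{"dna"}; anything else is \code{"protein"}.
#'
#' @param seqs character vector of residue strings.
#' @return \code{"dna"} or \code{"protein"}.
#' @keywords internal
guess_alphabet <- function(seqs) {
  chars <- unique(strsplit(paste(toupper(seqs), collapse = ""), "")[[1]])
  if (length(chars) == 0 || all(chars %in% .DNA_CHARS)) "dna" else "protein"
}

#' Read a FASTA file
#'
#' Reads nucleotide or amino-acid FASTA into a `Biostrings` string set
#' (`DNAStringSet` or `AAStringSet`). The set name carries the full header;
#' use [seq_ids()] for the identifier (first whitespace-separated token).
#' Malformed input (sequence data before the first header, an empty header,
#' or a header with no sequence) raises an error naming the offending line.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"auto"` (default), `"dna"` or `"protein"`. With
#'   `"auto"` the alphabet is inferred from the residue characters.
#' @param min_length optional minimum sequence length; shorter records are
#'   dropped after parsing (assemblies are sometimes published with a
#'   100 bp or 201 bp floor). Default `NULL` keeps everything.
#' @return a `DNAStringSet` or `AAStringSet`; empty set for an empty file.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">tx1 demo", "ACGTACGT"), fa)
#' read_fasta(fa)
read_fasta <- function(path, alphabet = c("auto", "dna", "protein"),
                       min_length = NULL) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  .validate_fasta_lines(lines, path)
  if (!any(nzchar(trimws(lines)))) {
    return(if (alphabet == "protein") Biostrings::AAStringSet() else
             Biostrings::DNAStringSet())
  }
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in ", path, ": ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  seqs <- as.character(raw)
  if (alphabet == "auto") alphabet <- guess_alphabet(seqs)
  out <- if (alphabet == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- names(raw)
  if (!is.null(min_length)) out <- out[Biostrings::width(out) >= min_length]
  out
}

.validate_fasta_lines <- function(lines, path) {
  in_record <- FALSE
  have_residues <- FALSE
  header_line <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      if (in_record && !have_residues) {
        stop("FASTA parse error in ", path, ": record at line ",
             header_line, " has an empty sequence", call. = FALSE)
      }
      if (!nzchar(trimws(substring(ln, 2)))) {
        stop("FASTA parse error in ", path, ": empty header at line ", i,
             call. = FALSE)
      }
      in_record <- TRUE
      have_residues <- FALSE
      header_line <- i
    } else {
      if (!in_record) {
        stop("FASTA parse error in ", path,
             ": sequence data before any header at line ", i, call. = FALSE)
      }
      have_residues <- TRUE
    }
  }
  if (in_record && !have_residues) {
    stop("FASTA parse error in ", path, ": record at line ", header_line,
         " has an empty sequence", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write sequences to FASTA
#'
#' @param x a `DNAStringSet`/`AAStringSet` (or named character vector).
#' @param path output path.
#' @param wrap line width for wrapping residues (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, wrap = 60) {
  if (is.character(x)) {
    alphabet <- guess_alphabet(x)
    x <- if (alphabet == "dna") Biostrings::DNAStringSet(x)
         else Biostrings::AAStringSet(x)
  }
  Biostrings::writeXStringSet(x, path, width = wrap)
  invisible(path)
}

#' Sequence identifiers of a string set
#'
#' @param x an `XStringSet` read by [read_fasta()].
#' @return character vector of ids (first token of each header).
#' @export
seq_ids <- function(x) sub("\\s.*$", "", names(x))

#' Assembly summary statistics
#'
#' Computes the statistics conventionally reported for de novo
#' transcriptome assemblies: number of sequences, longest contig, N50,
#' mean and median length. N50 is the length of the contig at which the
#' cumulative length of contigs, sorted in descending order, first reaches
#' half the total assembly length.
#'
#' @param x an `XStringSet`, or a numeric vector of sequence lengths.
#' @return an object of class `assembly_stats`: a list with elements
#'   `n_sequences`, `longest`, `n50`, `mean`, `median`.
#' @export
#' @examples
#' assembly_stats(c(2, 3, 4, 5, 6))  # n50 = 5
assembly_stats <- function(x) {
  lens <- if (is.numeric(x)) x else Biostrings::width(x)
  if (length(lens) == 0) stop("assembly_stats: empty sequence set",
                              call. = FALSE)
  if (any(lens <= 0)) stop("assembly_stats: non-positive length",
                           call. = FALSE)
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= sum(sorted) / 2)[1L]]
  out <- list(
    n_sequences = length(lens),
    longest     = max(lens),
    n50         = n50,
    mean        = mean(lens),
    median      = stats::median(lens)
  )
  class(out) <- "assembly_stats"
  out
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly statistics\n")
  cat(sprintf("  sequences: %d\n  longest:   %d bp\n  N50:       %d bp\n",
              x$n_sequences, as.integer(x$longest), as.integer(x$n50)))
  cat(sprintf("  mean:      %.1f bp\n  median:    %.1f bp\n",
              x$mean, x$median))
  invisible(x)
}

#' Serialize assembly statistics as JSON
#'
#' @param stats an `assembly_stats` object.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
assembly_stats_json <- function(stats, path = NULL) {
  stopifnot(inherits(stats, "assembly_stats"))
  js <- jsonlite::toJSON(unclass(stats), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Transcripts-per-million from counts
#'
#' Standard length-normalized TPM: per-transcript read counts are divided
#' by transcript length, and the resulting rates rescaled to sum to 1e6.
#'
#' @param counts named numeric vector of read counts (>= 0).
#' @param lengths numeric vector of transcript lengths in bp (> 0), in the
#'   same order (or with the same names) as `counts`.
#' @return numeric vector of TPM values summing to 1e6 (all-zero counts
#'   give an all-zero column with a warning).
#' @export
tpm_from_counts <- function(counts, lengths) {
  if (length(counts) != length(lengths)) {
    stop("counts and lengths differ in length", call. = FALSE)
  }
  if (!is.null(names(counts)) && !is.null(names(lengths))) {
    lengths <- lengths[names(counts)]
  }
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (any(lengths <= 0)) stop("non-positive lengths", call. = FALSE)
  rate <- counts / lengths
  total <- sum(rate)
  if (total == 0) {
    warning("all counts are zero; returning all-zero TPM column")
    return(setNames(numeric(length(counts)), names(counts)))
  }
  rate / total * 1e6
}

#' Construct an expression matrix
#'
#' Container for per-tissue transcript abundances of one assembly.
#'
#' @param values numeric matrix, transcripts in rows (rownames = ids),
#'   tissues in columns (colnames = tissue labels); values >= 0.
#' @param assembly_id assembly label.
#' @param unit `"TPM"`, `"RPM"` or `"relative"`. For `"TPM"` each column
#'   must sum to 1e6 within 0.1%.
#' @return object of class `expr_matrix` with fields `assembly_id`,
#'   `tissues`, `values`, `unit`.
#' @export
expression_matrix <- function(values, assembly_id,
                              unit = c("relative", "TPM", "RPM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(colnames(values)) ||
      (nrow(values) > 0 && is.null(rownames(values)))) {
    stop("values must have transcript rownames and tissue colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate transcript ids", call. = FALSE)
  }
  if (any(values < 0) || any(!is.finite(values))) {
    stop("expression values must be finite and non-negative", call. = FALSE)
  }
  if (unit == "TPM" && nrow(values) > 0) {
    sums <- colSums(values)
    if (any(abs(sums - 1e6) > 1e3)) {
      stop("TPM columns must sum to 1e6 within 0.1%", call. = FALSE)
    }
  }
  structure(
    list(assembly_id = assembly_id, tissues = colnames(values),
         values = values, unit = unit),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix '%s': %d transcripts x %d tissues (%s)\n",
              x$assembly_id, nrow(x$values), length(x$tissues), x$unit))
  invisible(x)
}

#' Read an expression table
#'
#' Plain TSV with one header line: first column transcript id, remaining
#' columns one per tissue.
#'
#' @param path TSV file path.
#' @inheritParams expression_matrix
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, assembly_id = basename(path),
                            unit = c("relative", "TPM", "RPM")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs id column plus >= 1 tissue",
                         call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    stop("non-numeric (or ragged) expression values in ", path, call. = FALSE)
  }
  if (any(is.na(vals))) stop("missing/ragged values in ", path, call. = FALSE)
  if (any(vals < 0)) stop("negative expression values in ", path,
                          call. = FALSE)
  rownames(vals) <- as.character(df[[1]])
  expression_matrix(vals, assembly_id = assembly_id, unit = unit)
}

#' Write an expression table
#'
#' Values are written with 15 significant digits, so a write/read round
#' trip preserves the matrix well past 6 significant digits.
#'
#' @param mat an `expr_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  stopifnot(inherits(mat, "expr_matrix"))
  df <- data.frame(transcript_id = rownames(mat$values),
                   signif(mat$values, 15), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
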