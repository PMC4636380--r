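#' Read an energy matrix from TSV or JSON
#'
#' TSV format: 4 rows labeled A, C, G, T (first column) by `n` columns of
#' energies in kB*T. JSON format: an object
#' `{"alphabet": "ACGT", "matrix": [[...], ...]}` with 4 rows in alphabet
#' order.
#'
#' @param path File path; format inferred from the `.json` extension,
#'   otherwise TSV.
#' @return A 4 x n numeric matrix with rows named A, C, G, T.
#' @export
read_energy_matrix <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$matrix)) stop("JSON energy matrix needs a 'matrix' field")
    xi <- as.matrix(obj$matrix)
    ab <- strsplit(toupper(obj$alphabet %||% "ACGT"), "")[[1L]]
    rownames(xi) <- ab
    xi <- xi[DNA_BASES, , drop = FALSE]
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            row.names = 1L, comment.char = "#")
    xi <- as.matrix(df)
    rownames(xi) <- toupper(rownames(xi))
    xi <- xi[DNA_BASES, , drop = FALSE]
  }
  colnames(xi) <- NULL
  validate_energy_matrix(xi, ncol(xi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an energy matrix
#'
#' @param xi A 4 x n energy matrix (rows A, C, G, T).
#' @param path Output path; `.json` writes the JSON representation, anything
#'   else tab-separated text.
#' @return `path`, invisibly.
#' @export
write_energy_matrix <- function(xi, path) {
  xi <- validate_energy_matrix(xi, ncol(xi))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- lapply(seq_len(4L), function(i) unname(xi[i, ]))
    jsonlite::write_json(list(alphabet = "ACGT", matrix = rows),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(cbind(base = rownames(xi), as.data.frame(xi)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()`; sequences are returned
#' as uppercase ACGT strings.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package")
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  if (any(grepl("[^ACGT]", out)))
    stop("FASTA contains non-ACGT characters")
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Character vector of ACGT sequences (names become headers).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("writing FASTA requires the Biostrings package")
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
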