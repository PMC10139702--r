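#' Read an aligned protein FASTA file
#'
#' Reads an aligned amino acid FASTA into a character matrix (rows = named
#' sequences, columns = alignment sites). Residues are upper-cased; the 20
#' standard one-letter codes plus the gap `-` and ambiguity `X` (also `?`,
#' `*`, `.`, all treated as missing data) are permitted.
#'
#' @param path Path to an aligned FASTA file.
#' @return Character matrix with one row per sequence.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  aa <- tryCatch(ape::read.FASTA(path, type = "AA"),
                 error = function(e) stop("failed to parse FASTA '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  if (length(aa) == 0L) stop("alignment '", path, "' contains no sequences",
                             call. = FALSE)
  lens <- lengths(aa)
  if (length(unique(lens)) != 1L)
    stop("alignment '", path, "': sequences have unequal lengths (",
         paste(range(lens), collapse = "-"), "); input must be aligned",
         call. = FALSE)
  mat <- toupper(do.call(rbind, as.character(aa)))
  rownames(mat) <- names(aa)
  validate_alignment(mat, context = path)
  mat
}

#' Validate a protein alignment matrix
#'
#' Checks the alignment contract: a character matrix with unique row names,
#' at least one column, and only permitted residue/missing symbols.
#'
#' @param alignment Character matrix.
#' @param context Label used in error messages (e.g. a file path).
#' @return The alignment, invisibly, after validation.
#' @export
validate_alignment <- function(alignment, context = "alignment") {
  if (!is.matrix(alignment) || !is.character(alignment))
    stop(context, ": alignment must be a character matrix", call. = FALSE)
  if (ncol(alignment) < 1L)
    stop(context, ": alignment has no columns", call. = FALSE)
  nm <- rownames(alignment)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    stop(context, ": sequences must have unique non-empty names",
         call. = FALSE)
  ok <- alignment %in% c(AA_CODES, AA_MISSING)
  if (!all(ok)) {
    bad <- unique(alignment[!ok])
    stop(context, ": unknown residue symbol(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(alignment)
}

#' Write a protein alignment to FASTA
#'
#' @param alignment Character matrix of aligned residues.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment))) {
    writeLines(c(paste0(">", rownames(alignment)[i]),
                 paste(alignment[i, ], collapse = "")), con)
  }
  invisible(path)
}

# Integer-encoded alignment (20 states, 0 = missing), rows as in input.
encode_alignment <- function(alignment) {
  m <- matrix(aa_index(alignment), nrow = nrow(alignment),
              dimnames = dimnames(alignment))
  m
}
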