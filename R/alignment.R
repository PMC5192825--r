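#' Construct a protein alignment
#'
#' A gap-aware aligned amino-acid matrix anchored on a designated reference
#' taxon (the species whose protein defines the gene, e.g. human). Residues
#' are the 20 standard amino acids; `-` is a gap and `X` (unknown) is treated
#' as a gap throughout, since an unknown state carries no substitution
#' information.
#'
#' @param sequences named character vector of aligned sequences (equal
#'   lengths), or a character matrix with one row per taxon and one aligned
#'   column per matrix column.
#' @param reference name of the reference taxon; must be among the rows.
#' @return an object of class `protein_alignment`: a character matrix
#'   (taxa x columns) with attribute `reference`.
#' @export
protein_alignment <- function(sequences, reference) {
  if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
      stop("sequences must be named by taxon", call. = FALSE)
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L)
      stop("aligned sequences must have equal length", call. = FALSE)
    mat <- do.call(rbind, strsplit(toupper(unname(sequences)), ""))
    rownames(mat) <- names(sequences)
  }
  if (anyDuplicated(rownames(mat)))
    stop("duplicate taxon names in alignment", call. = FALSE)
  if (!reference %in% rownames(mat))
    stop("reference taxon '", reference, "' not in alignment", call. = FALSE)
  bad <- setdiff(unique(as.vector(mat)), c(AA20, "-", "X", "*"))
  if (length(bad))
    stop("unexpected residue characters: ", paste(bad, collapse = " "),
         call. = FALSE)
  structure(mat, reference = reference, class = c("protein_alignment", "matrix"))
}

#' Read an aligned FASTA file of protein orthologs
#'
#' @param path path to an aligned FASTA file (one gene, one row per taxon).
#' @param reference name of the reference taxon.
#' @param alias optional named character vector mapping FASTA record names
#'   (e.g. assembly names) to tree leaf names; applied before validation.
#' @return a `protein_alignment`.
#' @export
read_protein_alignment <- function(path, reference, alias = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!is.null(alias)) {
    hit <- names(seqs) %in% names(alias)
    names(seqs)[hit] <- unname(alias[names(seqs)[hit]])
  }
  protein_alignment(seqs, reference)
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("protein_alignment: %d taxa x %d columns (reference: %s)\n",
              nrow(x), ncol(x), attr(x, "reference")))
  invisible(x)
}

#' @keywords internal
alignment_reference <- function(alignment) attr(alignment, "reference")
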