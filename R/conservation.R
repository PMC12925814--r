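# Multiple-sequence-alignment conservation analysis: entropy-based
# per-column scores with similarity classification, consensus and logo
# matrices, and mapping between alignment columns and residue numbers of
# a chosen reference sequence.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Default residue similarity classes
#'
#' Groups used to call a column "similar" when all its residues fall in
#' one physicochemical class: basic \{K,R,H\}, acidic \{D,E\}, polar
#' \{S,T,N,Q\}, aromatic \{F,W,Y\}, aliphatic \{L,I,V,M\}, small
#' \{A,G\}, \{C\}, \{P\}.
#'
#' @return list of character vectors
#' @export
default_similarity_classes <- function() {
  list(basic = c("K", "R", "H"), acidic = c("D", "E"),
       polar = c("S", "T", "N", "Q"), aromatic = c("F", "W", "Y"),
       aliphatic = c("L", "I", "V", "M"), small = c("A", "G"),
       cys = "C", pro = "P")
}

#' Read (or wrap) a multiple sequence alignment
#'
#' Reads aligned FASTA via Biostrings, uppercases, and validates the
#' alphabet (20 amino acids, gap `-`, unknown `X`). Ragged alignments
#' raise an error naming the offending sequences.
#'
#' @param path FASTA file path
#' @param aligned require equal lengths (default TRUE)
#' @return object of class `msa`: list with `ids` and `seqs` (character
#'   matrix, one row per sequence)
#' @export
read_msa <- function(path, aligned = TRUE) {
  set <- Biostrings::readBStringSet(path)
  msa_from_strings(toupper(as.character(set)), names(set),
                   aligned = aligned)
}

#' @rdname read_msa
#' @param strings named character vector of (aligned) sequences
#' @param ids sequence identifiers
#' @export
msa_from_strings <- function(strings, ids = names(strings),
                             aligned = TRUE) {
  strings <- toupper(strings)
  if (is.null(ids)) ids <- paste0("seq", seq_along(strings))
  lens <- nchar(strings)
  if (aligned && length(unique(lens)) != 1L)
    stop("ragged alignment; offending sequences: ",
         paste(ids[lens != stats::median(lens)], collapse = ", "))
  seqs <- do.call(rbind, strsplit(strings, ""))
  bad <- setdiff(unique(as.vector(seqs)), c(AA20, "-", "X"))
  if (length(bad))
    stop("alphabet violation: ", paste(bad, collapse = ", "))
  rownames(seqs) <- ids
  structure(list(ids = ids, seqs = seqs, n_columns = ncol(seqs)),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$ids), "sequences x", x$n_columns, "columns\n")
  invisible(x)
}

#' Write an alignment to FASTA
#'
#' @param msa an `msa`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_msa <- function(msa, path) {
  seqs <- apply(msa$seqs, 1, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- msa$ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

column_entropy <- function(col) {
  res <- col[col %in% AA20]
  if (!length(res)) return(NA_real_)
  f <- table(res) / length(res)
  -sum(f * log(f))
}

#' Per-column conservation profile
#'
#' Score is `1 - H / ln(20)` with `H` the Shannon entropy of the
#' non-gap residue frequencies ('X' is treated like a gap). Columns are
#' classed `identical` when one residue type fills all non-gap rows,
#' `similar` when all non-gap residues share one similarity class,
#' `masked` when the gap fraction exceeds the threshold, else
#' `variable`.
#'
#' @param msa an `msa` with >= 2 sequences
#' @param gap_mask_threshold columns with a larger gap fraction are
#'   masked
#' @param similarity_classes list of residue groups (see
#'   [default_similarity_classes()])
#' @return data.frame of class `conservation_profile`: columns `column`,
#'   `score`, `majority`, `majority_fraction`, `gap_fraction`, `class`
#' @export
conservation_profile <- function(msa, gap_mask_threshold = 0.5,
                                 similarity_classes =
                                   default_similarity_classes()) {
  if (length(msa$ids) < 2L)
    stop("conservation needs at least 2 sequences")
  n <- ncol(msa$seqs)
  out <- data.frame(column = seq_len(n), score = NA_real_,
                    majority = NA_character_,
                    majority_fraction = NA_real_,
                    gap_fraction = NA_real_, class = NA_character_)
  for (j in seq_len(n)) {
    col <- msa$seqs[, j]
    res <- col[col %in% AA20]
    gapfrac <- mean(!col %in% AA20)
    out$gap_fraction[j] <- gapfrac
    if (length(res)) {
      f <- sort(table(res), decreasing = TRUE)
      out$majority[j] <- names(f)[1]
      out$majority_fraction[j] <- f[[1]] / length(res)
      out$score[j] <- 1 - column_entropy(col) / log(20)
    }
    cls <- if (gapfrac > gap_mask_threshold) "masked"
      else if (!length(res)) "masked"
      else if (length(unique(res)) == 1L) "identical"
      else if (any(vapply(similarity_classes,
                          function(g) all(res %in% g), logical(1))))
        "similar"
      else "variable"
    out$class[j] <- cls
  }
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Consensus sequence of an alignment
#'
#' Per column: the plurality non-gap residue, or `-` when the gap
#' fraction exceeds 0.5. Ties are broken lexicographically and recorded
#' in the `"ties"` attribute.
#'
#' @param msa an `msa` with >= 2 sequences
#' @return consensus string with attribute `"ties"` (logical per column)
#' @export
consensus_sequence <- function(msa) {
  if (length(msa$ids) < 2L) stop("consensus needs at least 2 sequences")
  n <- ncol(msa$seqs)
  cons <- character(n); ties <- logical(n)
  for (j in seq_len(n)) {
    col <- msa$seqs[, j]
    res <- col[col %in% AA20]
    if (!length(res) || mean(!col %in% AA20) > 0.5) {
      cons[j] <- "-"
      next
    }
    f <- table(res)
    top <- names(f)[f == max(f)]
    ties[j] <- length(top) > 1L
    cons[j] <- sort(top)[1]
  }
  structure(paste(cons, collapse = ""), ties = ties)
}

#' Position-frequency and information-content (logo) matrix
#'
#' @param msa an `msa`
#' @return list with `frequencies` (20 x n matrix over non-gap
#'   residues, columns sum to 1 where any residue is present) and
#'   `information` (bits per column, in `[0, log2(20)]`)
#' @export
logo_matrix <- function(msa) {
  n <- ncol(msa$seqs)
  freq <- matrix(0, nrow = length(AA20), ncol = n,
                 dimnames = list(AA20, NULL))
  info <- numeric(n)
  for (j in seq_len(n)) {
    col <- msa$seqs[, j]
    res <- col[col %in% AA20]
    if (!length(res)) { info[j] <- 0; next }
    f <- table(factor(res, levels = AA20)) / length(res)
    freq[, j] <- as.numeric(f)
    nz <- f[f > 0]
    info[j] <- log2(20) + sum(nz * log2(nz))
  }
  list(frequencies = freq, information = info)
}

#' Map a reference residue number to its alignment column
#'
#' The reference numbering is the 1-based ungapped position within the
#' chosen reference row (numbering is a property of that row and is
#' never re-derived).
#'
#' @param msa an `msa`
#' @param reference_id id of the reference row
#' @param residue_number 1-based ungapped residue number
#' @return alignment column index
#' @export
map_reference_position <- function(msa, reference_id, residue_number) {
  row <- msa_reference_row(msa, reference_id)
  nongap <- which(row %in% c(AA20, "X"))
  if (residue_number < 1L || residue_number > length(nongap))
    stop("residue number ", residue_number,
         " outside ungapped reference length ", length(nongap))
  nongap[residue_number]
}

#' @rdname map_reference_position
#' @param column alignment column index (must be non-gap in the
#'   reference)
#' @return `column_to_residue`: the reference residue number at that
#'   column
#' @export
column_to_residue <- function(msa, reference_id, column) {
  row <- msa_reference_row(msa, reference_id)
  if (column < 1L || column > length(row)) stop("column out of range")
  if (!row[column] %in% c(AA20, "X"))
    stop("reference has a gap at column ", column)
  sum(row[seq_len(column)] %in% c(AA20, "X"))
}

msa_reference_row <- function(msa, reference_id) {
  k <- match(reference_id, msa$ids)
  if (is.na(k)) stop("reference id not found: ", reference_id)
  msa$seqs[k, ]
}

#' Residue occupancy at a mapped reference position
#'
#' Maps a reference residue number to its alignment column and tabulates
#' the residue of every sequence there, reporting the fraction of
#' sequences identical to the reference residue and the column's
#' conservation class.
#'
#' @inheritParams map_reference_position
#' @param gap_mask_threshold passed to [conservation_profile()]
#' @return list with `column`, `reference_residue`, `residues` (named
#'   character vector per sequence), `fraction_identical`, `class`
#' @export
check_position_conservation <- function(msa, reference_id, residue_number,
                                        gap_mask_threshold = 0.5) {
  col <- map_reference_position(msa, reference_id, residue_number)
  occupants <- msa$seqs[, col]
  names(occupants) <- msa$ids
  ref_res <- occupants[[reference_id]]
  prof <- conservation_profile(msa, gap_mask_threshold)
  list(column = col,
       reference_residue = ref_res,
       residues = occupants,
       fraction_identical = mean(occupants == ref_res),
       class = prof$class[col])
}
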