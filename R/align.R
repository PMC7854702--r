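#' Read protein sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase amino-acid sequences.
#' @export
read_fasta_protein <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- names(ss)
  out
}

# BLOSUM62 from Biostrings, cached per session
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

encode_protein <- function(seqs, matrix_letters) {
  lapply(seqs, function(s) {
    s <- toupper(gsub("\\s", "", s))
    ch <- strsplit(s, "")[[1]]
    unknown <- !(ch %in% matrix_letters)
    if (any(unknown)) {
      repl <- if ("X" %in% matrix_letters) "X" else matrix_letters[1]
      rlang::warn(sprintf("residues %s not in the substitution matrix: scored as %s",
                          paste(unique(ch[unknown]), collapse = ","), repl))
      ch[unknown] <- repl
    }
    match(ch, matrix_letters) - 1L
  })
}

#' Smith-Waterman local alignment with EMBOSS Water conventions
#'
#' Affine-gap three-state local dynamic programming with traceback from the
#' maximum cell. Penalties follow EMBOSS Water: a gap of length L costs
#' `gap_open + (L - 1) * gap_extend` (the opening penalty covers the first
#' gap position). Percent identity is the fraction of identical columns
#' over the alignment length (gap columns included in the denominator);
#' percent similarity additionally counts residue pairs with a positive
#' substitution score. Ties in the DP prefer the diagonal move, then a gap
#' in `b`, then a gap in `a`; among equal-scoring maxima the smallest end
#' coordinates win.
#'
#' @param a,b Protein sequences (plain strings, or single-element values
#'   from [read_fasta_protein()]).
#' @param matrix Substitution matrix: `"BLOSUM62"` (default, from
#'   Biostrings) or a numeric matrix with residue dimnames.
#' @param gap_open,gap_extend Gap penalties (EMBOSS defaults 10 and 0.5).
#' @return Object of class `local_alignment`: `score`, `aligned_a`,
#'   `aligned_b`, `identity_pct`, `similarity_pct`, `length`,
#'   `start_a`, `end_a`, `start_b`, `end_b`, `n_identical`, `n_similar`,
#'   `n_gaps`.
#' @export
smith_waterman <- function(a, b, matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 0.5) {
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  subst <- if (is.matrix(matrix)) matrix else switch(matrix,
    BLOSUM62 = blosum62_matrix(),
    stop("unknown substitution matrix: ", matrix))
  letters_ <- rownames(subst)
  sa <- unname(if (is.character(a) && length(a) == 1) a else as.character(a)[1])
  sb <- unname(if (is.character(b) && length(b) == 1) b else as.character(b)[1])
  if (nchar(sa) == 0 || nchar(sb) == 0) stop("empty sequence")
  enc <- encode_protein(c(sa, sb), letters_)
  res <- cpp_smith_waterman(enc[[1]], enc[[2]], unname(subst),
                            gap_open, gap_extend)
  ai <- res$a_idx; bi <- res$b_idx
  ca <- strsplit(toupper(sa), "")[[1]]; cb <- strsplit(toupper(sb), "")[[1]]
  col_a <- ifelse(ai >= 0, ca[pmax(ai, 0) + 1], "-")
  col_b <- ifelse(bi >= 0, cb[pmax(bi, 0) + 1], "-")
  len <- length(col_a)
  both <- ai >= 0 & bi >= 0
  n_id <- sum(both & col_a == col_b)
  pos <- rep(FALSE, len)
  if (any(both))
    pos[both] <- subst[cbind(enc[[1]][ai[both] + 1] + 1L,
                             enc[[2]][bi[both] + 1] + 1L)] > 0
  n_sim <- sum(pos)
  structure(list(
    score = res$score,
    aligned_a = paste(col_a, collapse = ""),
    aligned_b = paste(col_b, collapse = ""),
    identity_pct = 100 * n_id / len,
    similarity_pct = 100 * n_sim / len,
    length = len,
    start_a = if (any(ai >= 0)) min(ai[ai >= 0]) + 1L else NA_integer_,
    end_a = res$end_a,
    start_b = if (any(bi >= 0)) min(bi[bi >= 0]) + 1L else NA_integer_,
    end_b = res$end_b,
    n_identical = n_id, n_similar = n_sim, n_gaps = sum(!both)
  ), class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("<local_alignment> score %.1f, length %d\n", x$score, x$length))
  cat(sprintf("  identity %d/%d (%.1f%%), similarity %d/%d (%.1f%%), gaps %d\n",
              x$n_identical, x$length, round(x$identity_pct, 1),
              x$n_similar, x$length, round(x$similarity_pct, 1), x$n_gaps))
  cat(sprintf("  a: %d-%d, b: %d-%d\n", x$start_a, x$end_a, x$start_b, x$end_b))
  invisible(x)
}

#' @export
glance.local_alignment <- function(x, ...) {
  tibble::tibble(score = x$score, identity_pct = x$identity_pct,
                 similarity_pct = x$similarity_pct, length = x$length,
                 n_gaps = x$n_gaps)
}
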