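#' Bisulfite-aware alignment of cloned BSP reads
#'
#' Aligns each clone read globally to the reference amplicon on the
#' bisulfite-collapsed alphabet (every C replaced by T in both sequences), so a
#' converted cytosine (read T over reference C) scores as a match and CpG-site
#' columns accept both C and T; the methylation call is made later from the
#' original read base. Both orientations are tried and the better score kept
#' (ties prefer forward, with a warning). Reads of the same length as the
#' reference whose best collapsed Hamming distance is at most 3 take an
#' ungapped fast path: with affine gap cost `open + ext` per run (default
#' 4 + 1), any gapped global alignment of equal-length sequences pays at least
#' 10, more than the 2 x 3 score a rescue of three mismatches could recoup, so
#' the ungapped alignment is provably optimal there.
#'
#' @param reads named character vector of clone sequences (original base
#'   calls, FASTA orientation arbitrary).
#' @param ref original (unconverted) amplicon sequence; a
#'   [reference_region()] or character scalar.
#' @param gap_opening,gap_extension affine gap penalties; a gap of length k
#'   costs `gap_opening + k * gap_extension`.
#' @param score_floor alignments scoring below this are flagged unalignable.
#' @return An object of class `clone_alignments`: list with `table` (one row
#'   per clone: `clone_id`, `orientation`, `score`, `identity`, `unalignable`)
#'   and `refmap`, a character matrix (reference positions x clones) giving
#'   the read base aligned over each reference position (NA at gaps).
#' @export
align_clones <- function(reads, ref, gap_opening = 4, gap_extension = 1,
                         score_floor = 0) {
  ref_seq <- .as_seq(ref)
  if (is.null(names(reads)) || anyDuplicated(names(reads)))
    stop("reads must have unique names")
  L <- nchar(ref_seq)
  ref_collapsed <- gsub("C", "T", ref_seq, fixed = TRUE)
  refc <- .seq_chars(ref_collapsed)
  ref_orig <- .seq_chars(ref_seq)
  non_c <- which(ref_orig != "C")

  n <- length(reads)
  refmap <- matrix(NA_character_, nrow = L, ncol = n,
                   dimnames = list(NULL, names(reads)))
  orientation <- character(n); score <- numeric(n)
  slow <- integer(0)
  ties <- character(0)

  oriented <- vector("list", n)
  for (i in seq_len(n)) {
    fwd <- toupper(reads[[i]])
    rev <- revcomp(fwd)
    if (nchar(fwd) == L) {
      kf <- sum(.seq_chars(gsub("C", "T", fwd, fixed = TRUE)) != refc)
      kr <- sum(.seq_chars(gsub("C", "T", rev, fixed = TRUE)) != refc)
      k <- min(kf, kr)
      if (k <= 3L) {
        if (kf == kr) ties <- c(ties, names(reads)[i])
        use_rev <- kr < kf
        orientation[i] <- if (use_rev) "reverse_complement" else "forward"
        oriented[[i]] <- if (use_rev) rev else fwd
        score[i] <- L - 2 * k
        refmap[, i] <- .seq_chars(oriented[[i]])
        next
      }
    }
    slow <- c(slow, i)
    oriented[[i]] <- c(fwd, rev)
  }

  if (length(slow) > 0L) {
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                   baseOnly = FALSE)
    subj <- Biostrings::DNAString(ref_collapsed)
    for (i in slow) {
      cand <- vapply(oriented[[i]],
                     function(x) gsub("C", "T", x, fixed = TRUE), "")
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(cand), subj, type = "global",
        substitutionMatrix = sm, gapOpening = gap_opening,
        gapExtension = gap_extension)
      sc <- Biostrings::score(aln)
      if (sc[1L] == sc[2L]) ties <- c(ties, names(reads)[i])
      pick <- if (sc[2L] > sc[1L]) 2L else 1L
      orientation[i] <- c("forward", "reverse_complement")[pick]
      score[i] <- sc[pick]
      pc <- .seq_chars(as.character(Biostrings::alignedPattern(aln)[pick]))
      sc_ch <- .seq_chars(as.character(Biostrings::alignedSubject(aln)[pick]))
      orig <- .seq_chars(oriented[[i]][pick])
      ir <- cumsum(pc != "-"); iref <- cumsum(sc_ch != "-")
      both <- pc != "-" & sc_ch != "-"
      refmap[iref[both], i] <- orig[ir[both]]
      oriented[[i]] <- oriented[[i]][pick]
    }
  }
  if (length(ties) > 0L)
    warning("orientation score tie (forward kept) for: ",
            paste(ties, collapse = ", "))

  # identity over aligned columns (read base over reference base), excluding
  # bisulfite-ambiguous (reference C) columns; gap columns are not aligned
  # columns and are penalized through the score, not the identity
  rm_nc <- refmap[non_c, , drop = FALSE]
  n_aligned <- colSums(!is.na(rm_nc))
  identity <- ifelse(n_aligned == 0, 0,
                     colSums(rm_nc == matrix(ref_orig[non_c],
                                             length(non_c), n),
                             na.rm = TRUE) / pmax(n_aligned, 1L))
  tab <- data.frame(clone_id = names(reads), orientation = orientation,
                    score = score, identity = identity,
                    unalignable = score < score_floor,
                    row.names = NULL)
  structure(list(table = tab, refmap = refmap, ref = ref_seq),
            class = "clone_alignments")
}

#' @export
print.clone_alignments <- function(x, ...) {
  cat("<clone_alignments> ", nrow(x$table), " clones vs ", nchar(x$ref),
      " bp reference; ", sum(x$table$unalignable), " unalignable\n", sep = "")
  invisible(x)
}

#' Align a single clone read
#'
#' Convenience wrapper around [align_clones()] for one read.
#'
#' @inheritParams align_clones
#' @param read clone sequence (character scalar).
#' @param clone_id identifier for the read.
#' @return list with `orientation`, `score`, `identity`, `unalignable` and
#'   `refmap` (character vector over reference positions).
#' @export
align_clone <- function(read, ref, clone_id = "clone", ...) {
  reads <- stats::setNames(read, clone_id)
  a <- align_clones(reads, ref, ...)
  c(as.list(a$table[1L, ]), list(refmap = a$refmap[, 1L]))
}
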