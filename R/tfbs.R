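#' Built-in transcription factor motif set
#'
#' Editable approximations of the binding consensi reported for the promoter:
#' the Sp1 GC box, the Oct-1 octamer and the C/EBP palindrome. These are
#' standard literature consensi, not the output of any particular prediction
#' server; users can supply their own motif table.
#'
#' @return data.frame with columns `name`, `consensus` (IUPAC), and
#'   `max_mismatches`.
#' @export
default_motifs <- function() {
  data.frame(
    name = c("Sp1", "Oct-1A", "C/EBPalp"),
    consensus = c("GGGGCGGGGC", "ATGCAAAT", "TTGCGCAA"),
    max_mismatches = c(1L, 1L, 1L))
}

#' Load a motif table from TSV
#'
#' @param path TSV with header `name`, `consensus`, `max_mismatches`.
#' @return validated motif data.frame.
#' @export
read_motifs <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "consensus", "max_mismatches") %in% names(m)))
  m$consensus <- toupper(m$consensus)
  bad <- gsub("[ACGTRYSWKMBDHVN]", "", m$consensus)
  if (any(nchar(bad) > 0L))
    stop("unknown IUPAC code in motif(s): ",
         paste(m$name[nchar(bad) > 0L], collapse = ", "))
  m
}

# IUPAC code -> base set
.iupac <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

#' Scan a reference for transcription factor binding motifs
#'
#' Consensus motifs are matched with an IUPAC-aware mismatch budget (every
#' window within budget is reported; overlapping hits allowed). A motif may
#' alternatively be given as a position weight matrix, scored as log-odds
#' against a uniform background with a threshold expressed as a fraction of
#' the maximum attainable score.
#'
#' @param ref [reference_region()] or character sequence.
#' @param motifs data.frame as from [default_motifs()], or a named list of
#'   4 x w probability matrices (rows A, C, G, T) for PWM scanning.
#' @param both_strands also scan the reverse strand (default forward only,
#'   promoter orientation known).
#' @param pwm_threshold fraction of the maximum PWM score required.
#' @return data.frame `motif`, `start`, `end` (0-based half-open), `strand`,
#'   `score` (matches for consensus motifs, log-odds for PWMs), sorted by
#'   position.
#' @export
scan_motifs <- function(ref, motifs = default_motifs(), both_strands = FALSE,
                        pwm_threshold = 0.85) {
  s <- .as_seq(ref)
  strands <- if (both_strands) c("+", "-") else "+"
  hits <- list()
  for (strand in strands) {
    seqs <- if (strand == "+") s else revcomp(s)
    L <- nchar(seqs)
    subj <- Biostrings::DNAString(seqs)
    if (is.data.frame(motifs)) {
      for (k in seq_len(nrow(motifs))) {
        cons <- toupper(motifs$consensus[k])
        if (!all(.seq_chars(cons) %in% names(.iupac)))
          stop("unknown IUPAC code in motif ", motifs$name[k])
        if (nchar(cons) > L) next
        mm <- motifs$max_mismatches[k]
        m <- Biostrings::matchPattern(cons, subj, max.mismatch = mm,
                                      fixed = "subject")
        if (length(m) == 0L) next
        st <- Biostrings::start(m) - 1L
        inb <- st >= 0L & st + nchar(cons) <= L
        st <- st[inb]
        if (length(st) == 0L) next
        nmm <- vapply(seq_along(st), function(j)
          .count_mismatch(cons, substr(seqs, st[j] + 1L, st[j] + nchar(cons))),
          1L)
        hits[[length(hits) + 1L]] <- data.frame(
          motif = motifs$name[k], start = st, end = st + nchar(cons),
          strand = strand, score = nchar(cons) - nmm)
      }
    } else {
      for (nm in names(motifs)) {
        pwm <- motifs[[nm]]
        stopifnot(is.matrix(pwm), nrow(pwm) == 4L)
        lo <- log2(pmax(pwm, 1e-6) / 0.25)
        best <- sum(apply(lo, 2L, max))
        worst <- sum(apply(lo, 2L, min))
        thr <- worst + pwm_threshold * (best - worst)
        w <- ncol(pwm)
        if (w > L) next
        chs <- .seq_chars(seqs)
        idx <- match(chs, c("A", "C", "G", "T"))
        sc <- vapply(seq_len(L - w + 1L), function(p) {
          ii <- idx[p:(p + w - 1L)]
          if (anyNA(ii)) return(-Inf)
          sum(lo[cbind(ii, seq_len(w))])
        }, 1)
        ok <- which(sc >= thr)
        if (length(ok) == 0L) next
        hits[[length(hits) + 1L]] <- data.frame(
          motif = nm, start = ok - 1L, end = ok - 1L + w,
          strand = strand, score = sc[ok])
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      score = numeric(0)))
  out <- do.call(rbind, hits)
  # map reverse-strand hits back to forward coordinates
  if (any(out$strand == "-")) {
    L <- nchar(s)
    i <- out$strand == "-"
    new_start <- L - out$end[i]
    out$end[i] <- L - out$start[i]
    out$start[i] <- new_start
  }
  out <- out[order(out$start, out$end, out$motif), ]
  rownames(out) <- NULL
  out
}

.count_mismatch <- function(consensus, window) {
  cc <- .seq_chars(consensus); wc <- .seq_chars(window)
  sum(!mapply(function(a, b) b %in% .iupac[[a]], cc, wc))
}

#' CpG sites covered by predicted TF binding sites
#'
#' A site is covered by a hit when both bases of its CG dinucleotide lie
#' inside the hit interval (`c_position` and `c_position + 1` within
#' `[start, end)`).
#'
#' @param hits hit table from [scan_motifs()].
#' @param sites CpG site table from [enumerate_cpg_sites()].
#' @return data.frame `site`, `c_position`, `covered`, `motifs`
#'   (comma-separated covering motif names, "" if none).
#' @export
overlap_cpg <- function(hits, sites) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    cp <- sites$c_position[i]
    cov <- hits$start <= cp & (cp + 1L) < hits$end
    data.frame(site = sites$index[i], c_position = cp,
               covered = any(cov),
               motifs = paste(unique(hits$motif[cov]), collapse = ","))
  })
  do.call(rbind, rows)
}
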