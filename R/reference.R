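#' Promoter reference region
#'
#' Light container for a single reference sequence. Sequences are stored as
#' uppercase character strings over the alphabet A, C, G, T, N; `N` bases are
#' never counted as C or G by any downstream statistic.
#'
#' @param sequence character scalar, the DNA sequence.
#' @param id record identifier.
#' @param origin_offset position of base 0 in an external coordinate system
#'   (reporting only; all internal coordinates are 0-based half-open).
#' @return An object of class `reference_region`.
#' @export
reference_region <- function(sequence, id = "ref", origin_offset = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("reference sequence is empty")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L) {
    stop("invalid bases in reference '", id, "': ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  }
  structure(list(id = id, sequence = sequence,
                 origin_offset = as.integer(origin_offset)),
            class = "reference_region")
}

#' @export
print.reference_region <- function(x, ...) {
  cat("<reference_region> ", x$id, ": ", nchar(x$sequence), " bp\n", sep = "")
  invisible(x)
}

.seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.as_seq <- function(x) {
  if (inherits(x, "reference_region")) x$sequence else toupper(as.character(x))
}

#' Observed/expected CpG ratio of a window
#'
#' The Gardiner-Garden & Frommer statistic: `n_CG * L / (n_C * n_G)` where
#' `L` is the window length. Returns 0 when the window contains no C or no G.
#'
#' @param sequence DNA window (character scalar).
#' @return Numeric ratio (>= 0).
#' @export
obs_exp_cpg <- function(sequence) {
  s <- .as_seq(sequence)
  L <- nchar(s)
  if (L < 1L) stop("empty window")
  if (L < 2L) stop("window must be at least 2 bases")
  ch <- .seq_chars(s)
  nC <- sum(ch == "C"); nG <- sum(ch == "G")
  if (nC == 0L || nG == 0L) return(0)
  nCG <- sum(ch[-L] == "C" & ch[-1L] == "G")
  (nCG * L) / (nC * nG)
}

#' CpG island detection parameters
#'
#' @param min_length minimum island length in bases.
#' @param min_gc minimum G+C fraction.
#' @param min_obs_exp minimum observed/expected CpG ratio.
#' @param window scan window size in bases (must not exceed `min_length`).
#' @param step scan step in bases.
#' @param max_n_frac windows with more than this fraction of `N` are skipped.
#' @return A list of class `island_params`.
#' @export
island_params <- function(min_length = 200L, min_gc = 0.50,
                          min_obs_exp = 0.60, window = 100L, step = 1L,
                          max_n_frac = 0.10) {
  stopifnot(window <= min_length, step >= 1L, min_gc >= 0, min_gc <= 1,
            min_obs_exp >= 0)
  structure(list(min_length = as.integer(min_length), min_gc = min_gc,
                 min_obs_exp = min_obs_exp, window = as.integer(window),
                 step = as.integer(step), max_n_frac = max_n_frac),
            class = "island_params")
}

# criteria over [start, end) given precomputed indicator cumsums (0-based coords)
.interval_stats <- function(cumC, cumG, cumCG, cumN, start, end) {
  L <- end - start
  nC <- cumC[end + 1L] - cumC[start + 1L]
  nG <- cumG[end + 1L] - cumG[start + 1L]
  # CG pair counted at the C position; pair at end-1 would straddle the boundary
  nCG <- cumCG[end] - cumCG[start + 1L]
  nN <- cumN[end + 1L] - cumN[start + 1L]
  gc <- (nC + nG) / L
  oe <- if (nC == 0 || nG == 0) 0 else (nCG * L) / (nC * nG)
  list(gc = gc, obs_exp = oe, n_frac = nN / L)
}

#' Detect CpG islands by sliding-window scan
#'
#' Scans `window`-sized windows every `step` bases; windows passing the GC and
#' observed/expected criteria (and the N filter) are unioned into runs, and each
#' run is reported as its longest sub-interval of length >= `min_length` that
#' itself satisfies all three criteria (leftmost such interval on ties). Runs
#' with no qualifying sub-interval are dropped. Forward strand only.
#'
#' @param ref a [reference_region()] or character sequence.
#' @param params an [island_params()] object.
#' @return data.frame with columns `start`, `end` (0-based half-open), `gc`,
#'   `obs_exp`, sorted and non-overlapping.
#' @export
detect_cpg_islands <- function(ref, params = island_params()) {
  s <- .as_seq(ref)
  L <- nchar(s)
  empty <- data.frame(start = integer(0), end = integer(0),
                      gc = numeric(0), obs_exp = numeric(0))
  if (L < params$window) {
    warning("sequence shorter than scan window; no islands reported")
    return(empty)
  }
  ch <- .seq_chars(s)
  cumC <- c(0L, cumsum(ch == "C"))
  cumG <- c(0L, cumsum(ch == "G"))
  cumN <- c(0L, cumsum(ch == "N"))
  isCG <- c(ch[-L] == "C" & ch[-1L] == "G", FALSE)
  cumCG <- c(0L, cumsum(isCG))

  starts <- seq.int(0L, L - params$window, by = params$step)
  w <- params$window
  nC <- cumC[starts + w + 1L] - cumC[starts + 1L]
  nG <- cumG[starts + w + 1L] - cumG[starts + 1L]
  nCG <- cumCG[starts + w] - cumCG[starts + 1L]
  nN <- cumN[starts + w + 1L] - cumN[starts + 1L]
  gc <- (nC + nG) / w
  oe <- ifelse(nC == 0 | nG == 0, 0, (nCG * w) / (nC * nG))
  ok <- gc >= params$min_gc & oe >= params$min_obs_exp &
    (nN / w) <= params$max_n_frac
  if (!any(ok)) return(empty)

  # union of qualifying windows -> maximal runs
  qs <- starts[ok]
  runs <- list()
  run_start <- qs[1L]; run_end <- qs[1L] + w
  if (length(qs) > 1L) {
    for (p in qs[-1L]) {
      if (p <= run_end) run_end <- p + w
      else { runs[[length(runs) + 1L]] <- c(run_start, run_end)
             run_start <- p; run_end <- p + w }
    }
  }
  runs[[length(runs) + 1L]] <- c(run_start, run_end)

  out <- empty
  for (r in runs) {
    iv <- .trim_island(cumC, cumG, cumCG, cumN, r[1L], r[2L], params)
    if (!is.null(iv)) {
      st <- .interval_stats(cumC, cumG, cumCG, cumN, iv[1L], iv[2L])
      out <- rbind(out, data.frame(start = iv[1L], end = iv[2L],
                                   gc = st$gc, obs_exp = st$obs_exp))
    }
  }
  rownames(out) <- NULL
  out
}

# longest sub-interval of [a, b) with length >= min_length meeting all criteria;
# leftmost on ties; NULL if none
.trim_island <- function(cumC, cumG, cumCG, cumN, a, b, params) {
  if (b - a < params$min_length) return(NULL)
  for (len in seq.int(b - a, params$min_length, by = -1L)) {
    for (st in seq.int(a, b - len)) {
      x <- .interval_stats(cumC, cumG, cumCG, cumN, st, st + len)
      if (x$gc >= params$min_gc && x$obs_exp >= params$min_obs_exp)
        return(c(st, st + len))
    }
  }
  NULL
}

#' Enumerate CpG sites within an interval
#'
#' One site per CG dinucleotide whose C lies in the interval; ordinals are
#' assigned 1..n in coordinate order (CpG1, CpG2, ...).
#'
#' @param ref a [reference_region()] or character sequence.
#' @param interval `c(start, end)` 0-based half-open; default whole sequence.
#' @return data.frame with columns `index` (1-based ordinal) and `c_position`
#'   (0-based position of the C).
#' @export
enumerate_cpg_sites <- function(ref, interval = NULL) {
  s <- .as_seq(ref)
  L <- nchar(s)
  if (is.null(interval)) interval <- c(0L, L)
  stopifnot(interval[1L] >= 0L, interval[2L] <= L)
  ch <- .seq_chars(s)
  pos0 <- which(ch[-L] == "C" & ch[-1L] == "G") - 1L  # 0-based C positions
  pos0 <- pos0[pos0 >= interval[1L] & pos0 < interval[2L]]
  data.frame(index = seq_along(pos0), c_position = pos0)
}

#' In-silico bisulfite conversion
#'
#' `mode = "full"` replaces every C with T (an unmethylated molecule);
#' `mode = "cpg_protected"` replaces every C with T except a C immediately
#' followed by G (a fully methylated molecule). Length is preserved.
#'
#' @param sequence DNA character scalar.
#' @param mode `"cpg_protected"` or `"full"`.
#' @return Converted sequence (character scalar).
#' @export
bisulfite_convert <- function(sequence, mode = c("cpg_protected", "full")) {
  mode <- match.arg(mode)
  s <- .as_seq(sequence)
  if (mode == "full") return(gsub("C", "T", s, fixed = TRUE))
  ch <- .seq_chars(s)
  L <- length(ch)
  if (L == 0L) return(s)
  protect <- ch == "C" & c(ch[-1L], "") == "G"
  ch[ch == "C" & !protect] <- "T"
  paste(ch, collapse = "")
}

#' Reverse complement
#' @param sequence DNA character scalar (A/C/G/T/N).
#' @return Reverse-complemented sequence.
#' @export
revcomp <- function(sequence) {
  s <- .as_seq(sequence)
  paste(rev(.seq_chars(chartr("ACGTN", "TGCAN", s))), collapse = "")
}
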