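# Independent brute-force oracles. These deliberately share no code with the
# package internals: counting is done with gregexpr/substring, alignment with
# a plain three-matrix Gotoh recursion.

oracle_count <- function(s, what) {
  m <- gregexpr(what, s, fixed = TRUE)[[1]]
  if (m[1] == -1) 0L else length(m)
}

oracle_obs_exp <- function(s) {
  L <- nchar(s)
  nC <- oracle_count(s, "C"); nG <- oracle_count(s, "G")
  if (nC == 0 || nG == 0) return(0)
  (oracle_count(s, "CG") * L) / (nC * nG)
}

oracle_gc <- function(s) (oracle_count(s, "C") + oracle_count(s, "G")) / nchar(s)

oracle_n_frac <- function(s) oracle_count(s, "N") / nchar(s)

# naive re-implementation of the island definition: qualifying windows ->
# union runs -> longest qualifying sub-interval (leftmost on ties)
oracle_islands <- function(s, params = island_params()) {
  L <- nchar(s)
  if (L < params$window) return(data.frame(start = integer(0), end = integer(0)))
  w <- params$window
  starts0 <- seq(0, L - w, by = params$step)
  qual <- vapply(starts0, function(st) {
    win <- substring(s, st + 1, st + w)
    oracle_gc(win) >= params$min_gc &&
      oracle_obs_exp(win) >= params$min_obs_exp &&
      oracle_n_frac(win) <= params$max_n_frac
  }, TRUE)
  qs <- starts0[qual]
  if (length(qs) == 0) return(data.frame(start = integer(0), end = integer(0)))
  covered <- rep(FALSE, L)
  for (st in qs) covered[(st + 1):(st + w)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1
  out <- data.frame(start = integer(0), end = integer(0))
  for (k in which(r$values)) {
    a <- begs[k] - 1; b <- ends[k]      # 0-based half-open run
    found <- NULL
    if (b - a >= params$min_length) {
      for (len in seq(b - a, params$min_length, by = -1)) {
        for (st in seq(a, b - len)) {
          sub <- substring(s, st + 1, st + len)
          if (oracle_gc(sub) >= params$min_gc &&
              oracle_obs_exp(sub) >= params$min_obs_exp) {
            found <- c(st, st + len); break
          }
        }
        if (!is.null(found)) break
      }
    }
    if (!is.null(found))
      out <- rbind(out, data.frame(start = found[1], end = found[2]))
  }
  out
}

# global affine-gap alignment score; gap of length k costs open + k * ext
oracle_gotoh <- function(a, b, match = 1, mismatch = -1, open = 4, ext = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in y (x consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in x (y consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

oracle_collapse <- function(s) gsub("C", "T", s, fixed = TRUE)

IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# every window start (0-based) within the mismatch budget
oracle_scan <- function(s, consensus, max_mm) {
  w <- nchar(consensus)
  L <- nchar(s)
  if (w > L) return(integer(0))
  cc <- strsplit(consensus, "")[[1]]
  hits <- integer(0)
  for (st in 0:(L - w)) {
    win <- strsplit(substring(s, st + 1, st + w), "")[[1]]
    mm <- sum(!vapply(seq_len(w), function(k)
      win[k] %in% IUPAC_SETS[[cc[k]]], TRUE))
    if (mm <= max_mm) hits <- c(hits, st)
  }
  hits
}

# random DNA sequence with controllable GC content
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# mutate a sequence: substitutions and optional indels
mutate_seq <- function(s, n_sub = 0, n_ins = 0, n_del = 0) {
  ch <- strsplit(s, "")[[1]]
  if (n_sub > 0) {
    pos <- sample(length(ch), n_sub)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  if (n_del > 0) ch <- ch[-sample(length(ch), n_del)]
  if (n_ins > 0) for (k in seq_len(n_ins)) {
    p <- sample(length(ch), 1)
    ch <- append(ch, sample(c("A", "C", "G", "T"), 1), after = p)
  }
  paste(ch, collapse = "")
}
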