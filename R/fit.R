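#' Clone quality control
#'
#' Computes the bisulfite conversion efficiency of one aligned clone — the
#' fraction of non-CpG reference cytosine positions read as T (a retained C
#' there is an unconverted cytosine) — together with its alignment identity
#' and the number of ambiguous CpG columns, and decides pass/fail.
#'
#' @param refmap character vector of read bases over reference positions (as
#'   produced by [align_clones()]).
#' @param ref original (unconverted) reference amplicon.
#' @param sites CpG site table from [enumerate_cpg_sites()].
#' @param identity alignment identity of the clone.
#' @param unalignable logical flag from alignment.
#' @param min_conversion,min_identity pass thresholds.
#' @return list with `conversion_rate`, `identity`, `n_ambiguous_cpg`,
#'   `pass`, `reason` ("" when passing).
#' @export
clone_qc <- function(refmap, ref, sites, identity,
                     unalignable = FALSE,
                     min_conversion = 0.95, min_identity = 0.90) {
  ref_ch <- .seq_chars(.as_seq(ref))
  L <- length(ref_ch)
  # non-CpG cytosines: a C not immediately followed by G
  cpos <- which(ref_ch == "C" & c(ref_ch[-1L], "") != "G")
  obs <- refmap[cpos]
  informative <- obs %in% c("C", "T")
  site_obs <- refmap[sites$c_position + 1L]
  n_amb <- sum(!(site_obs %in% c("C", "T")))
  if (unalignable)
    return(list(conversion_rate = NA_real_, identity = identity,
                n_ambiguous_cpg = n_amb, pass = FALSE,
                reason = "unalignable"))
  if (length(cpos) == 0L || !any(informative))
    return(list(conversion_rate = NA_real_, identity = identity,
                n_ambiguous_cpg = n_amb, pass = FALSE,
                reason = "no informative non-CpG C positions"))
  conv <- sum(obs[informative] == "T") / sum(informative)
  pass <- conv >= min_conversion && identity >= min_identity
  reason <- if (pass) "" else if (conv < min_conversion)
    "incomplete bisulfite conversion" else "low alignment identity"
  list(conversion_rate = conv, identity = identity,
       n_ambiguous_cpg = n_amb, pass = pass, reason = reason)
}

#' Call per-site methylation states for one clone
#'
#' At each CpG site's C column: read C means methylated, read T unmethylated,
#' anything else (gap, A, G, N) missing.
#'
#' @inheritParams clone_qc
#' @return integer vector (1 = methylated, 0 = unmethylated, NA = missing),
#'   one element per site.
#' @export
call_clone <- function(refmap, sites) {
  b <- refmap[sites$c_position + 1L]
  ifelse(b == "C", 1L, ifelse(b == "T", 0L, NA_integer_))
}

#' Per-site methylation rates of a call matrix
#'
#' @param m call matrix (clones x sites; 1/0/NA).
#' @return numeric vector: methylated / (methylated + unmethylated) per site;
#'   NA (with a warning) for all-missing sites.
#' @export
per_site_rates <- function(m) {
  m <- as.matrix(m)
  valid <- colSums(!is.na(m))
  if (any(valid == 0L)) warning("site(s) with no valid calls: rate undefined")
  meth <- colSums(m == 1L, na.rm = TRUE)
  ifelse(valid == 0L, NA_real_, meth / valid)
}

#' Integral methylation rate of a call matrix
#'
#' The group-level statistic: methylated CpG calls as a fraction of all
#' non-missing calls over every sequenced clone and site.
#'
#' @param m call matrix (clones x sites; 1/0/NA).
#' @return fraction in \[0, 1\].
#' @export
integral_rate <- function(m) {
  m <- as.matrix(m)
  valid <- sum(!is.na(m))
  if (length(m) == 0L || valid == 0L) stop("no non-missing calls in matrix")
  sum(m == 1L, na.rm = TRUE) / valid
}

#' Fit a clone-based BSP methylation model
#'
#' The central fitting function: aligns cloned bisulfite-PCR reads to the
#' reference amplicon, applies conversion/identity quality control, calls
#' per-clone per-site methylation, and estimates per-site and integral
#' methylation rates per group (e.g. per laying week).
#'
#' @param clones named character vector of clone read sequences.
#' @param reference the amplicon [reference_region()] or character sequence
#'   (original, unconverted bases).
#' @param groups character vector assigning each clone to a group, parallel to
#'   `clones`; if NULL, clone names of the form `group|clone` are parsed.
#' @param sites CpG site table; default enumerates all CG dinucleotides in
#'   the reference.
#' @param min_conversion,min_identity quality-control thresholds.
#' @param ... passed to [align_clones()].
#' @return An object of class `bsp_fit` with components `matrices` (one call
#'   matrix per group), `qc` (per-clone QC table), `rates` (groups x sites
#'   matrix of per-site rates), `integral` (per-group integral rates),
#'   `sites`, `groups`, `n_excluded`.
#' @seealso [coef.bsp_fit()], [summary.bsp_fit()], [plot.bsp_fit()],
#'   [simulate.bsp_fit()]
#' @export
bsp_fit <- function(clones, reference, groups = NULL, sites = NULL,
                    min_conversion = 0.95, min_identity = 0.90, ...) {
  ref_seq <- .as_seq(reference)
  if (is.null(names(clones))) stop("clones must be named")
  if (is.null(groups)) {
    if (!all(grepl("|", names(clones), fixed = TRUE)))
      stop("groups not given and clone names are not of the form 'group|clone'")
    groups <- sub("\\|.*$", "", names(clones))
  }
  stopifnot(length(groups) == length(clones))
  if (is.null(sites)) sites <- enumerate_cpg_sites(ref_seq)
  if (nrow(sites) == 0L) stop("reference contains no CpG sites")

  aln <- align_clones(clones, ref_seq, ...)
  qc_rows <- vector("list", length(clones))
  calls <- matrix(NA_integer_, nrow = length(clones), ncol = nrow(sites),
                  dimnames = list(names(clones),
                                  paste0("CpG", sites$index)))
  for (i in seq_along(clones)) {
    q <- clone_qc(aln$refmap[, i], ref_seq, sites,
                  identity = aln$table$identity[i],
                  unalignable = aln$table$unalignable[i],
                  min_conversion = min_conversion,
                  min_identity = min_identity)
    qc_rows[[i]] <- data.frame(clone_id = names(clones)[i],
                               group = groups[i],
                               orientation = aln$table$orientation[i],
                               conversion_rate = q$conversion_rate,
                               identity = q$identity,
                               n_ambiguous_cpg = q$n_ambiguous_cpg,
                               pass = q$pass, reason = q$reason)
    if (q$pass) calls[i, ] <- call_clone(aln$refmap[, i], sites)
  }
  qc <- do.call(rbind, qc_rows)
  failed <- qc[!qc$pass, , drop = FALSE]
  if (nrow(failed) > 0L)
    message(nrow(failed), " clone(s) excluded by QC: ",
            paste(failed$clone_id, " (", failed$reason, ")",
                  sep = "", collapse = "; "))

  glev <- unique(groups)
  matrices <- lapply(glev, function(g) {
    keep <- groups == g & qc$pass
    calls[keep, , drop = FALSE]
  })
  names(matrices) <- glev
  rates <- t(vapply(matrices, function(m)
    suppressWarnings(per_site_rates(m)), numeric(nrow(sites))))
  integral <- vapply(matrices, function(m)
    if (sum(!is.na(m)) == 0L) NA_real_ else integral_rate(m), numeric(1))

  structure(list(matrices = matrices, qc = qc, rates = rates,
                 integral = integral, sites = sites, groups = glev,
                 n_excluded = nrow(failed),
                 thresholds = c(min_conversion = min_conversion,
                                min_identity = min_identity)),
            class = "bsp_fit")
}

#' @export
print.bsp_fit <- function(x, ...) {
  cat("BSP methylation fit: ", length(x$groups), " group(s), ",
      nrow(x$sites), " CpG sites, ",
      sum(vapply(x$matrices, nrow, 1L)), " clones retained (",
      x$n_excluded, " excluded by QC)\n", sep = "")
  cat("Integral methylation rate by group:\n")
  print(round(x$integral, 4))
  invisible(x)
}

#' Per-site methylation rate estimates
#' @param object a `bsp_fit`.
#' @param ... unused.
#' @return groups x sites matrix of per-site methylation rates.
#' @export
coef.bsp_fit <- function(object, ...) object$rates

#' @export
summary.bsp_fit <- function(object, ...) {
  tabs <- lapply(object$groups, function(g) {
    m <- object$matrices[[g]]
    data.frame(group = g, site = object$sites$index,
               c_position = object$sites$c_position,
               n_meth = colSums(m == 1L, na.rm = TRUE),
               n_valid = colSums(!is.na(m)),
               rate = object$rates[g, ], row.names = NULL)
  })
  structure(list(site_table = do.call(rbind, tabs),
                 integral = object$integral, qc = object$qc),
            class = "summary.bsp_fit")
}

#' @export
print.summary.bsp_fit <- function(x, ...) {
  cat("Integral methylation rate by group:\n")
  print(round(x$integral, 4))
  cat("\nPer-site rates:\n")
  print(x$site_table, digits = 4)
  invisible(x)
}

#' Simulate call matrices from a fitted model
#'
#' Parametric simulation: draws new clone call matrices of the same dimensions
#' as the fitted ones, with independent Bernoulli states at the estimated
#' per-group per-site rates (missing cells stay missing).
#'
#' @param object a `bsp_fit`.
#' @param nsim number of replicate simulations.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of length `nsim`; each element a named list of call matrices.
#' @export
simulate.bsp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(k) {
    sims <- vector("list", length(object$matrices))
    names(sims) <- names(object$matrices)
    for (g in names(object$matrices)) {
      m <- object$matrices[[g]]
      p <- object$rates[g, ]
      sim <- matrix(stats::rbinom(length(m), 1L,
                                  rep(p, each = nrow(m))),
                    nrow = nrow(m), dimnames = dimnames(m))
      sim[is.na(m)] <- NA_integer_
      sims[[g]] <- sim
    }
    sims
  })
}
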