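#' Eggshell color value of one egg
#'
#' The colorimeter is read at the obtuse, medium and acute ends along the
#' longitudinal axis; the egg's color value is the arithmetic mean of the
#' three readings (the greener/darker the shell, the smaller the value).
#'
#' @param readings numeric vector of exactly three positive readings.
#' @return the mean reading.
#' @export
egg_color_value <- function(readings) {
  if (length(readings) != 3L) stop("exactly three position readings required")
  if (any(!is.finite(readings)) || any(readings <= 0))
    stop("readings must be positive")
  mean(readings)
}

#' Per-egg color values from a measurement table
#'
#' @param color data.frame with columns `week`, `egg_id`, `r1`, `r2`, `r3`
#'   and optionally `exclude` (flagged abnormal eggs are dropped).
#' @return data.frame `week`, `egg_id`, `value`.
#' @export
egg_color_values <- function(color) {
  stopifnot(all(c("week", "egg_id", "r1", "r2", "r3") %in% names(color)))
  if ("exclude" %in% names(color)) color <- color[!color$exclude, ]
  data.frame(week = color$week, egg_id = color$egg_id,
             value = rowMeans(color[, c("r1", "r2", "r3")]))
}

#' Weekly summary statistics of a phenotype
#'
#' Sample mean, sample SD (n-1), coefficient of variation (sd/mean), minimum,
#' maximum and count per week.
#'
#' @param values numeric vector of per-egg values.
#' @param weeks parallel vector of week labels.
#' @return data.frame `week`, `n`, `mean`, `sd`, `cv`, `min`, `max`, ordered
#'   by week.
#' @export
summarize_weeks <- function(values, weeks) {
  stopifnot(length(values) == length(weeks))
  wk <- sort(unique(weeks))
  rows <- lapply(wk, function(w) {
    v <- values[weeks == w]
    if (length(v) < 2L) stop("week ", w, ": need n >= 2 for SD")
    data.frame(week = w, n = length(v), mean = mean(v), sd = stats::sd(v),
               cv = stats::sd(v) / mean(v), min = min(v), max = max(v))
  })
  do.call(rbind, rows)
}

#' Classical one-way ANOVA
#'
#' @param values numeric response.
#' @param groups parallel group labels (>= 2 groups, each n >= 2).
#' @return list with `F`, `p` and the underlying `aov` fit (`NULL` in the
#'   degenerate zero-variance case, where F = 0 and p = 1 with a warning).
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("each group needs n >= 2")
  if (stats::var(values) == 0) {
    warning("zero total variance; F reported as 0, p as 1")
    return(list(F = 0, p = 1, fit = NULL))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  list(F = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L], fit = fit)
}

#' Tukey HSD pairwise p-value matrix
#'
#' @param values numeric response.
#' @param groups parallel group labels.
#' @return symmetric matrix of adjusted pairwise p-values (diagonal 1).
#' @export
tukey_pmatrix <- function(values, groups) {
  groups <- factor(groups)
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  lev <- levels(groups)
  p <- matrix(1, nlevels(groups), nlevels(groups),
              dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (k in seq_along(pairs)) {
    a <- pairs[[k]][1L]; b <- pairs[[k]][2L]
    p[a, b] <- p[b, a] <- tk[k, "p adj"]
  }
  p
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb algorithm: groups sharing a letter do not differ at
#' `alpha`; groups whose letter sets are disjoint do.
#'
#' @param pmat symmetric matrix of pairwise p-values with group dimnames.
#' @param alpha significance level.
#' @return named character vector of letter strings, one per group.
#' @export
compact_letters <- function(pmat, alpha = 0.05) {
  stopifnot(is.matrix(pmat), nrow(pmat) == ncol(pmat))
  g <- nrow(pmat)
  labels <- rownames(pmat)
  if (is.null(labels)) labels <- as.character(seq_len(g))
  # columns: list of membership logical vectors
  cols <- list(rep(TRUE, g))
  sig <- which(pmat < alpha & upper.tri(pmat), arr.ind = TRUE)
  if (nrow(sig) > 0L) {
    for (k in seq_len(nrow(sig))) {
      i <- sig[k, 1L]; j <- sig[k, 2L]
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          cols[[ci]] <- a
          cols[[length(cols) + 1L]] <- b
        }
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
        if (ci != cj && keep[ci] && keep[cj] &&
            all(!cols[[ci]] | cols[[cj]]) &&
            !identical(cols[[ci]], cols[[cj]]))
          keep[ci] <- FALSE
      }
      cols <- cols[keep]
      # drop exact duplicates
      cols <- cols[!duplicated(vapply(cols, paste, "", collapse = ""))]
    }
  }
  # order columns by their first member for stable letters
  ord <- order(vapply(cols, function(x) which(x)[1L], 1L))
  cols <- cols[ord]
  out <- vapply(seq_len(g), function(i)
    paste(letters[which(vapply(cols, `[`, TRUE, i))], collapse = ""), "")
  stats::setNames(out, labels)
}

#' Segment ordered weeks into laying stages
#'
#' Greedy segmentation: a stage is a maximal run of consecutive weeks whose
#' letter sets share a common letter (running intersection non-empty). Stages
#' are labelled by the rank of their mean value (1 = smallest/darkest).
#'
#' @param weeks ordered week labels.
#' @param letter_sets character vector of compact letters per week (same
#'   order).
#' @param means per-week mean values (same order).
#' @return data.frame `stage`, `start_week`, `end_week`, `mean`, `rank`.
#' @export
assign_stages <- function(weeks, letter_sets, means) {
  stopifnot(length(weeks) == length(letter_sets),
            length(weeks) == length(means))
  sets <- strsplit(letter_sets, "")
  stage_id <- integer(length(weeks))
  cur <- 1L; common <- sets[[1L]]
  stage_id[1L] <- cur
  for (i in seq_along(weeks)[-1L]) {
    nxt <- intersect(common, sets[[i]])
    if (length(nxt) > 0L) { common <- nxt } else { cur <- cur + 1L
                                                  common <- sets[[i]] }
    stage_id[i] <- cur
  }
  st <- lapply(unique(stage_id), function(s) {
    idx <- which(stage_id == s)
    data.frame(stage = s, start_week = weeks[min(idx)],
               end_week = weeks[max(idx)], mean = mean(means[idx]))
  })
  out <- do.call(rbind, st)
  out$rank <- rank(out$mean, ties.method = "first")
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample: dCt = mean(target Ct replicates) - mean(reference Ct
#' replicates); ddCt = dCt - mean dCt of the calibrator group;
#' rq = 2^-ddCt. Samples lacking reference Ct values are dropped with a
#' warning.
#'
#' @param ct long-format data.frame with columns `sample_id`, `week`,
#'   `gene_role` (`"target"`/`"reference"`), `ct`, `replicate`.
#' @param calibrator_group week/group used as calibrator.
#' @return data.frame `sample_id`, `week`, `delta_ct`, `delta_delta_ct`, `rq`.
#' @export
ddct <- function(ct, calibrator_group) {
  stopifnot(all(c("sample_id", "week", "gene_role", "ct") %in% names(ct)))
  ids <- unique(ct$sample_id)
  rows <- lapply(ids, function(id) {
    d <- ct[ct$sample_id == id, ]
    tg <- d$ct[d$gene_role == "target"]
    rf <- d$ct[d$gene_role == "reference"]
    if (length(rf) == 0L || all(is.na(rf))) {
      warning("sample ", id, " dropped: no reference Ct")
      return(NULL)
    }
    if (length(tg) == 0L || all(is.na(tg))) {
      warning("sample ", id, " dropped: no target Ct")
      return(NULL)
    }
    data.frame(sample_id = id, week = d$week[1L],
               delta_ct = mean(tg, na.rm = TRUE) - mean(rf, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  cal <- out$delta_ct[out$week == calibrator_group]
  if (length(cal) == 0L) stop("calibrator group ", calibrator_group,
                              " has no samples")
  out$delta_delta_ct <- out$delta_ct - mean(cal)
  out$rq <- 2^(-out$delta_delta_ct)
  out
}
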