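#' Read a FASTA file
#'
#' Wrapped lines are joined, case is normalized to upper. Duplicate record
#' ids, empty files and RNA bases (U) are errors.
#'
#' @param path FASTA file (single or multi-record).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not a FASTA file (no leading '>'): ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), "")
  if (length(seqs) != length(ids) || any(!nzchar(seqs)))
    stop("FASTA record without sequence in ", path)
  names(seqs) <- ids
  hasU <- grepl("U", seqs, fixed = TRUE)
  if (any(hasU)) stop("RNA base U in record(s): ",
                      paste(ids[hasU], collapse = ", "))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write CpG islands as BED
#'
#' BED is 0-based half-open, matching the internal coordinates.
#'
#' @param islands island table from [detect_cpg_islands()].
#' @param path output file.
#' @param chrom chromosome/sequence name for column 1.
#' @return `path`, invisibly.
#' @export
write_bed <- function(islands, path, chrom = "ref") {
  df <- data.frame(chrom = chrom, start = islands$start, end = islands$end,
                   name = sprintf("CpG_island_%d", seq_len(nrow(islands))),
                   score = round(1000 * islands$obs_exp))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = ".")
  invisible(path)
}

#' Run the full BSP methylation pipeline
#'
#' Orchestrates island detection, bisulfite conversion, clone
#' alignment/QC/calling, phenotype and expression summaries, correlation and
#' TF-motif overlap, writing every intermediate as TSV/BED/JSON into
#' `out_dir`.
#'
#' @param ref_fasta reference FASTA (first record used).
#' @param clones_fasta clone FASTA.
#' @param manifest_tsv TSV with columns `clone_id`, `group`; if NULL, clone
#'   ids of the form `group|clone` are parsed.
#' @param color_tsv optional eggshell color TSV (`week`, `egg_id`, `r1`,
#'   `r2`, `r3`, `exclude`).
#' @param ct_tsv optional qPCR Ct TSV (`sample_id`, `week`, `gene_role`,
#'   `ct`, `replicate`).
#' @param out_dir output directory (created if needed).
#' @param params island detection parameters ([island_params()]).
#' @param motifs motif table ([default_motifs()]).
#' @param min_conversion,min_identity clone QC thresholds.
#' @param amplicon_pad bases added either side of the chosen island to form
#'   the alignment amplicon.
#' @param calibrator_group calibrator for 2^-ddCt; default the first week.
#' @param alpha significance level for correlations and letters.
#' @param adjust multiplicity adjustment for the site correlation table.
#' @return invisibly, a run report (class `bsp_run`): record counts per
#'   stage, exclusions with reasons, and the fitted `bsp_fit` object.
#' @export
run_pipeline <- function(ref_fasta, clones_fasta, manifest_tsv = NULL,
                         color_tsv = NULL, ct_tsv = NULL, out_dir,
                         params = island_params(),
                         motifs = default_motifs(),
                         min_conversion = 0.95, min_identity = 0.90,
                         amplicon_pad = 25L, calibrator_group = NULL,
                         alpha = 0.05, adjust = "none") {
  for (f in c(ref_fasta, clones_fasta, manifest_tsv, color_tsv, ct_tsv))
    if (!is.null(f) && !file.exists(f)) stop("missing input: ", f)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ref_all <- read_fasta(ref_fasta)
  ref <- reference_region(ref_all[[1L]], id = names(ref_all)[1L])
  islands <- detect_cpg_islands(ref, params)
  write_bed(islands, file.path(out_dir, "islands.bed"), chrom = ref$id)
  if (nrow(islands) == 0L) stop("no CpG island detected in reference")
  # island with the most CpG sites defines the amplicon
  n_cg <- vapply(seq_len(nrow(islands)), function(i)
    nrow(enumerate_cpg_sites(ref, c(islands$start[i], islands$end[i]))), 1L)
  isl <- islands[which.max(n_cg), ]
  sites_ref <- enumerate_cpg_sites(ref, c(isl$start, isl$end))
  .write_tsv(data.frame(ordinal = sites_ref$index,
                        position_1based = sites_ref$c_position + 1L),
             file.path(out_dir, "sites.tsv"))

  amp <- c(max(0L, isl$start - amplicon_pad),
           min(nchar(ref$sequence), isl$end + amplicon_pad))
  amp_seq <- substr(ref$sequence, amp[1L] + 1L, amp[2L])
  sites <- data.frame(index = sites_ref$index,
                      c_position = sites_ref$c_position - amp[1L])

  clones <- read_fasta(clones_fasta)
  groups <- if (is.null(manifest_tsv)) NULL else {
    man <- utils::read.delim(manifest_tsv, stringsAsFactors = FALSE)
    stopifnot(all(c("clone_id", "group") %in% names(man)))
    idx <- match(names(clones), man$clone_id)
    if (anyNA(idx)) stop("clones missing from manifest: ",
                         paste(names(clones)[is.na(idx)], collapse = ", "))
    as.character(man$group[idx])
  }
  fit <- bsp_fit(clones, amp_seq, groups = groups, sites = sites,
                 min_conversion = min_conversion,
                 min_identity = min_identity)
  .write_tsv(fit$qc, file.path(out_dir, "clone_qc.tsv"))
  calls_long <- do.call(rbind, lapply(names(fit$matrices), function(g) {
    m <- fit$matrices[[g]]
    if (nrow(m) == 0L) return(NULL)
    data.frame(clone_id = rownames(m), group = g,
               t(apply(m, 1L, function(r)
                 ifelse(is.na(r), ".", ifelse(r == 1L, "M", "U")))),
               check.names = FALSE)
  }))
  .write_tsv(calls_long, file.path(out_dir, "calls.tsv"))
  sm <- summary(fit)
  .write_tsv(sm$site_table, file.path(out_dir, "site_rates.tsv"))
  .write_tsv(data.frame(group = names(fit$integral),
                        integral_rate = fit$integral),
             file.path(out_dir, "integral_rates.tsv"))
  for (g in names(fit$matrices))
    if (nrow(fit$matrices[[g]]) > 0L)
      writeLines(format_lollipop(fit$matrices[[g]]),
                 file.path(out_dir, paste0("lollipop_", g, ".txt")))

  weeks_fit <- suppressWarnings(as.numeric(names(fit$integral)))

  color_summary <- NULL; stages <- NULL
  if (!is.null(color_tsv)) {
    color <- utils::read.delim(color_tsv, stringsAsFactors = FALSE)
    vals <- egg_color_values(color)
    color_summary <- summarize_weeks(vals$value, vals$week)
    .write_tsv(.round_summary(color_summary),
               file.path(out_dir, "week_color_summary.tsv"))
    pm <- tukey_pmatrix(vals$value, vals$week)
    lets <- compact_letters(pm, alpha)
    stages <- assign_stages(color_summary$week,
                            lets[as.character(color_summary$week)],
                            color_summary$mean)
    jsonlite::write_json(list(letters = as.list(lets), stages = stages),
                         file.path(out_dir, "stages.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  rq <- NULL; rq_week <- NULL
  if (!is.null(ct_tsv)) {
    ct <- utils::read.delim(ct_tsv, stringsAsFactors = FALSE)
    if (is.null(calibrator_group)) calibrator_group <- min(ct$week)
    rq <- ddct(ct, calibrator_group)
    .write_tsv(rq, file.path(out_dir, "rq.tsv"))
    rq_week <- tapply(rq$rq, rq$week, mean)
  }

  corr <- list()
  if (!is.null(rq_week)) {
    common <- intersect(weeks_fit, as.numeric(names(rq_week)))
    r1 <- pearson_assoc(fit$integral[as.character(common)],
                        rq_week[as.character(common)])
    corr[["methylation_vs_expression"]] <- r1
    st <- site_correlation_table(coef(fit)[as.character(common), ,
                                           drop = FALSE],
                                 rq_week[as.character(common)],
                                 adjust = adjust)
    .write_tsv(st, file.path(out_dir, "site_correlations.tsv"))
  }
  if (!is.null(color_summary)) {
    common <- intersect(weeks_fit, color_summary$week)
    cw <- stats::setNames(color_summary$mean, color_summary$week)
    corr[["methylation_vs_color"]] <-
      pearson_assoc(fit$integral[as.character(common)],
                    cw[as.character(common)])
    if (!is.null(rq_week)) {
      common2 <- intersect(as.numeric(names(rq_week)), color_summary$week)
      corr[["expression_vs_color"]] <-
        pearson_assoc(rq_week[as.character(common2)],
                      cw[as.character(common2)])
    }
  }
  if (length(corr) > 0L) {
    ct_tab <- do.call(rbind, Map(function(nm, x)
      data.frame(series = nm, r = x$r, p = x$p, n = x$n,
                 stars = .stars(x$p)), names(corr), corr))
    .write_tsv(ct_tab, file.path(out_dir, "correlations.tsv"))
  }

  hits <- scan_motifs(ref, motifs)
  .write_tsv(hits, file.path(out_dir, "tf_hits.tsv"))
  cov <- overlap_cpg(hits, sites_ref)
  .write_tsv(cov, file.path(out_dir, "site_tf_coverage.tsv"))
  key <- integer(0)
  if (!is.null(rq_week)) {
    key <- flag_key_sites(st, cov$site[cov$covered], alpha,
                          use_adjusted = (adjust == "bh"))
    .write_tsv(data.frame(key_site = key),
               file.path(out_dir, "key_sites.tsv"))
  }

  report <- list(
    n_reference_records = length(ref_all),
    n_islands = nrow(islands),
    n_sites = nrow(sites),
    clones_read = length(clones),
    clones_passed = sum(fit$qc$pass),
    clones_failed = sum(!fit$qc$pass),
    failed_reasons = table(fit$qc$reason[!fit$qc$pass]),
    integral_rates = fit$integral,
    correlations = corr,
    key_sites = key,
    thresholds = list(min_conversion = min_conversion,
                      min_identity = min_identity, alpha = alpha,
                      adjust = adjust, island_params = unclass(params)),
    fit = fit, stages = stages)
  class(report) <- "bsp_run"
  jsonlite::write_json(report[c("n_reference_records", "n_islands",
                                "n_sites", "clones_read", "clones_passed",
                                "clones_failed", "integral_rates",
                                "key_sites", "thresholds")],
                       file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

# human-facing rounding convention: 2 decimals for means/SDs, 4 for CV
.round_summary <- function(s) {
  s$mean <- round(s$mean, 2); s$sd <- round(s$sd, 2)
  s$cv <- round(s$cv, 4)
  s$min <- round(s$min, 2); s$max <- round(s$max, 2)
  s
}

#' @export
print.bsp_run <- function(x, ...) {
  cat("BSP pipeline run: ", x$clones_read, " clones read, ",
      x$clones_passed, " passed QC, ", x$clones_failed, " failed\n", sep = "")
  cat("Islands: ", x$n_islands, "; CpG sites: ", x$n_sites, "\n", sep = "")
  if (length(x$key_sites)) cat("Key sites: CpG",
                               paste(x$key_sites, collapse = ", CpG"),
                               "\n", sep = "")
  invisible(x)
}
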