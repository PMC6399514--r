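#' Configuration for a synthetic BSP study
#'
#' Defaults emulate the study design the package targets: a ~1 kb promoter
#' whose CpG-island core carries 14 CpG sites; 45 clones per week (15 clones
#' from each of 3 shell-gland samples) over 8 laying weeks with overall
#' methylation rising from about 0.84 to 0.91; realistic bisulfite conversion
#' failures and sequencing errors; weekly eggshell-color distributions with
#' the published weekly means/SDs/sample sizes; and qPCR Ct tables whose
#' fold-changes fall across weeks.
#'
#' @param seed integer seed driving every draw (files use seed, seed+1, ...).
#' @param n_sites number of planted CpG sites.
#' @param ref_length total reference length (bases).
#' @param amplicon_pad bases of primer padding either side of the island core.
#' @param weeks_meth weeks with methylation/expression data.
#' @param overall_rates planted overall methylation rate per week.
#' @param site_offsets per-site additive offsets around the weekly rate
#'   (defaults reproduce a realistic spread with one weakly methylated site).
#' @param per_week_site_prob optional weeks x sites probability matrix; when
#'   given it overrides `overall_rates` + `site_offsets`.
#' @param clones_per_week sequenced clones per week.
#' @param reverse_frac fraction of clones reported in reverse-complement
#'   orientation.
#' @param conversion_failure per-cytosine probability that an unmethylated C
#'   escapes conversion (read as C).
#' @param seq_error per-base substitution error rate.
#' @param indel_rate per-base indel rate (0 by default; substitutions only).
#' @param beta_kappa if non-NULL, per-clone site probabilities are drawn from
#'   Beta(kappa*p, kappa*(1-p)) to mimic clone-level mosaicism.
#' @param weeks_color weeks with eggshell color measurements.
#' @param color_means,color_sds,color_n weekly color mean, SD and egg count.
#' @param position_sd SD of the three per-egg position readings around the
#'   egg's latent value (colorimeter repeatability).
#' @param folds planted expression fold-change per week (vs calibrator).
#' @param samples_per_week qPCR samples per week.
#' @param ct_replicates technical replicates per Ct.
#' @param ct_noise_sd replicate Ct noise SD (cycles).
#' @param reference_ct mean reference-gene Ct.
#' @param baseline_delta target minus reference Ct at fold 1.
#' @param calibrator_week calibrator group for 2^-ddCt.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_sites = 14L,
                         ref_length = 1000L,
                         amplicon_pad = 25L,
                         weeks_meth = c(25L, 30L, 35L, 40L, 45L, 50L, 55L, 60L),
                         overall_rates = c(0.8393, 0.8437, 0.8527, 0.8776,
                                           0.9082, 0.9167, 0.9107, 0.9133),
                         site_offsets = NULL,
                         per_week_site_prob = NULL,
                         clones_per_week = 45L,
                         reverse_frac = 0.5,
                         conversion_failure = 0.01,
                         seq_error = 0.002,
                         indel_rate = 0,
                         beta_kappa = NULL,
                         weeks_color = c(20L, 25L, 30L, 35L, 40L, 45L,
                                         50L, 55L, 60L),
                         color_means = c(53.53, 53.86, 56.14, 56.59, 56.95,
                                         56.88, 58.57, 57.79, 58.40),
                         color_sds = c(2.80, 2.58, 3.14, 2.93, 3.33, 4.07,
                                       2.97, 3.48, 3.19),
                         color_n = c(264L, 337L, 313L, 290L, 285L, 319L,
                                     348L, 313L, 184L),
                         position_sd = 0.8,
                         folds = c(1.00, 0.95, 0.60, 0.55, 0.50,
                                   0.30, 0.28, 0.25),
                         samples_per_week = 5L,
                         ct_replicates = 3L,
                         ct_noise_sd = 0.15,
                         reference_ct = 20,
                         baseline_delta = 5,
                         calibrator_week = 25L) {
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (is.null(site_offsets)) {
    # realistic per-site spread: one weak site, several near-saturated,
    # centred on zero so the weekly mean stays at overall_rates
    sr <- c(71.93, 91.23, 85.96, 88.60, 92.11, 94.74, 56.14,
            92.11, 92.11, 96.49, 86.84, 91.23, 89.47, 96.49) / 100
    off <- sr - mean(sr)
    site_offsets <- if (n_sites == 14L) off else
      stats::approx(seq_along(off), off, n = n_sites)$y
    site_offsets <- site_offsets - mean(site_offsets)
  }
  stopifnot(length(site_offsets) == n_sites,
            length(overall_rates) == length(weeks_meth),
            length(folds) == length(weeks_meth),
            length(color_means) == length(weeks_color),
            length(color_sds) == length(weeks_color),
            length(color_n) == length(weeks_color),
            all(overall_rates >= 0 & overall_rates <= 1))
  if (is.null(per_week_site_prob)) {
    prob <- outer(overall_rates, site_offsets, `+`)
    prob <- pmin(pmax(prob, 0.02), 0.995)
  } else {
    prob <- per_week_site_prob
    stopifnot(is.matrix(prob), nrow(prob) == length(weeks_meth),
              ncol(prob) == n_sites, all(prob >= 0 & prob <= 1))
  }
  dimnames(prob) <- list(as.character(weeks_meth), paste0("CpG", 1:n_sites))
  cfg <- list(seed = as.integer(seed), n_sites = as.integer(n_sites),
              ref_length = as.integer(ref_length),
              amplicon_pad = as.integer(amplicon_pad),
              weeks_meth = weeks_meth, overall_rates = overall_rates,
              site_offsets = site_offsets, per_week_site_prob = prob,
              clones_per_week = as.integer(clones_per_week),
              reverse_frac = reverse_frac,
              conversion_failure = conversion_failure,
              seq_error = seq_error, indel_rate = indel_rate,
              beta_kappa = beta_kappa,
              weeks_color = weeks_color, color_means = color_means,
              color_sds = color_sds, color_n = color_n,
              position_sd = position_sd,
              folds = folds, samples_per_week = as.integer(samples_per_week),
              ct_replicates = as.integer(ct_replicates),
              ct_noise_sd = ct_noise_sd, reference_ct = reference_ct,
              baseline_delta = baseline_delta,
              calibrator_week = calibrator_week)
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a synthetic promoter reference with a planted CpG island
#'
#' Builds a reference of `ref_length` bases: AT-rich flanks with no CG
#' dinucleotides around a GC-balanced core of `n_sites` 20-bp blocks, each
#' carrying exactly one CG dinucleotide at a recorded position, so that the
#' core satisfies the standard island criteria and the planted sites are the
#' only CpG sites in the sequence. Deterministic given the seed.
#'
#' @param config a [synth_config()].
#' @return list with `ref` (a [reference_region()]) and `truth` (planted
#'   `site_positions` 0-based, `amplicon` interval, `per_week_site_prob`).
#' @export
generate_reference <- function(config = synth_config()) {
  n_sites <- config$n_sites
  if (n_sites < 1L) stop("n_sites must be >= 1")
  block <- 20L
  core_len <- n_sites * block
  flank <- (config$ref_length - core_len) %/% 2L
  if (flank < config$amplicon_pad + 5L)
    stop("too many sites for reference length")
  set.seed(config$seed)
  flank_chars <- function(n) sample(c("A", "T", "C", "G"), n, replace = TRUE,
                                    prob = c(0.36, 0.36, 0.14, 0.14))
  left <- flank_chars(flank)
  right <- flank_chars(config$ref_length - flank - core_len)
  # each 20-bp block: the planted CG, then 9 C/G letters interleaved with 9
  # A/T letters -- a C is never immediately followed by a G, so the planted
  # sites are the only CpGs, and G+C content stays even along the island
  core <- unlist(lapply(seq_len(n_sites), function(k) {
    s <- sample(c(rep("C", 4L), rep("G", 5L)))
    w <- sample(c("A", "T"), 9L, replace = TRUE)
    c("C", "G", as.vector(rbind(s, w)))
  }))
  ch <- c(left, core, right)
  planted <- flank + (seq_len(n_sites) - 1L) * block  # 0-based C positions
  # remove any CG created by chance outside the planted sites
  repeat {
    cg <- which(ch[-length(ch)] == "C" & ch[-1L] == "G") - 1L
    stray <- setdiff(cg, planted)
    if (length(stray) == 0L) break
    ch[stray + 2L] <- "A"
  }
  seqs <- paste(ch, collapse = "")
  found <- enumerate_cpg_sites(seqs)
  stopifnot(identical(found$c_position, as.integer(planted)))
  amplicon <- c(flank - config$amplicon_pad,
                flank + core_len + config$amplicon_pad)
  list(ref = reference_region(seqs, id = "synthetic_promoter"),
       truth = list(site_positions = planted, amplicon = amplicon,
                    per_week_site_prob = config$per_week_site_prob))
}

#' Generate synthetic BSP clone reads
#'
#' For every week and clone, draws per-site methylation states
#' Bernoulli(p\[week, site\]), applies bisulfite conversion with per-cytosine
#' failure, adds substitution (and optionally indel) sequencing errors, and
#' reports a fraction of clones in reverse-complement orientation.
#' Deterministic given the seed (stream `seed + 1`).
#'
#' @param reference output of [generate_reference()].
#' @param config a [synth_config()].
#' @return list with `reads` (named character vector), `manifest`
#'   (data.frame `clone_id`, `group`), and `truth` (per-clone planted
#'   `states` matrix, `realized_conversion`, `orientation`,
#'   `planted_overall` per week).
#' @export
generate_clones <- function(reference, config = synth_config()) {
  set.seed(config$seed + 1L)
  amp <- reference$truth$amplicon
  amp_seq <- substr(reference$ref$sequence, amp[1L] + 1L, amp[2L])
  amp_ch <- .seq_chars(amp_seq)
  L <- length(amp_ch)
  site_pos <- reference$truth$site_positions - amp[1L] + 1L  # 1-based in amplicon
  c_all <- which(amp_ch == "C")
  c_nonsite <- setdiff(c_all, site_pos)
  prob <- config$per_week_site_prob
  weeks <- config$weeks_meth
  bases <- c("A", "C", "G", "T")

  reads <- character(0); groups <- character(0)
  states_all <- list(); conv_real <- numeric(0); orient <- character(0)
  for (wi in seq_along(weeks)) {
    p <- prob[wi, ]
    for (j in seq_len(config$clones_per_week)) {
      pj <- p
      if (!is.null(config$beta_kappa))
        pj <- stats::rbeta(length(p), config$beta_kappa * p,
                           config$beta_kappa * (1 - p))
      states <- stats::rbinom(length(p), 1L, pj)
      ch <- amp_ch
      # CpG-site cytosines: methylated stay C; unmethylated convert unless failed
      un <- site_pos[states == 0L]
      fail_site <- stats::runif(length(un)) < config$conversion_failure
      ch[un[!fail_site]] <- "T"
      ch[site_pos[states == 1L]] <- "C"
      # non-CpG cytosines convert unless failed
      fail_non <- stats::runif(length(c_nonsite)) < config$conversion_failure
      ch[c_nonsite[!fail_non]] <- "T"
      conv <- if (length(c_nonsite)) mean(!fail_non) else NA_real_
      # substitution errors
      if (config$seq_error > 0) {
        err <- which(stats::runif(L) < config$seq_error)
        for (e in err)
          ch[e] <- sample(setdiff(bases, ch[e]), 1L)
      }
      # optional indels
      if (config$indel_rate > 0) {
        dels <- stats::runif(length(ch)) < config$indel_rate / 2
        ins <- stats::runif(length(ch)) < config$indel_rate / 2
        out <- character(0)
        for (k in seq_along(ch)) {
          if (!dels[k]) out <- c(out, ch[k])
          if (ins[k]) out <- c(out, sample(bases, 1L))
        }
        ch <- out
      }
      read <- paste(ch, collapse = "")
      is_rev <- stats::runif(1L) < config$reverse_frac
      if (is_rev) read <- revcomp(read)
      id <- sprintf("w%d_c%02d", weeks[wi], j)
      reads[id] <- read
      groups <- c(groups, as.character(weeks[wi]))
      states_all[[id]] <- states
      conv_real <- c(conv_real, conv)
      orient <- c(orient, if (is_rev) "reverse_complement" else "forward")
    }
  }
  states <- do.call(rbind, states_all)
  colnames(states) <- colnames(prob)
  wk_of <- rep(as.character(weeks), each = config$clones_per_week)
  planted_overall <- vapply(as.character(weeks), function(w)
    mean(states[wk_of == w, ]), numeric(1))
  list(reads = reads,
       manifest = data.frame(clone_id = names(reads), group = groups),
       truth = list(states = states,
                    realized_conversion = stats::setNames(conv_real,
                                                          names(reads)),
                    orientation = stats::setNames(orient, names(reads)),
                    planted_overall = planted_overall,
                    planted_matrix_mean = rowMeans(prob)))
}

#' Generate synthetic eggshell color measurements
#'
#' Per egg, a latent color value ~ Normal(week mean, week SD); the three
#' position readings are the latent value plus Normal(0, `position_sd`)
#' colorimeter noise. Deterministic given the seed (stream `seed + 2`).
#'
#' @param config a [synth_config()].
#' @return list with `color` (data.frame `week`, `egg_id`, `r1`, `r2`, `r3`,
#'   `exclude`) and `truth` (planted weekly means/SDs).
#' @export
generate_color <- function(config = synth_config()) {
  set.seed(config$seed + 2L)
  rows <- lapply(seq_along(config$weeks_color), function(wi) {
    w <- config$weeks_color[wi]; n <- config$color_n[wi]
    latent <- stats::rnorm(n, config$color_means[wi], config$color_sds[wi])
    data.frame(week = w,
               egg_id = sprintf("w%d_e%03d", w, seq_len(n)),
               r1 = latent + stats::rnorm(n, 0, config$position_sd),
               r2 = latent + stats::rnorm(n, 0, config$position_sd),
               r3 = latent + stats::rnorm(n, 0, config$position_sd),
               exclude = FALSE)
  })
  list(color = do.call(rbind, rows),
       truth = list(means = stats::setNames(config$color_means,
                                            config$weeks_color),
                    sds = stats::setNames(config$color_sds,
                                          config$weeks_color)))
}

#' Generate a synthetic qPCR Ct table
#'
#' Reference-gene replicate Cts ~ Normal(`reference_ct`, `ct_noise_sd`);
#' target Cts are offset by `baseline_delta - log2(fold)` for the week's
#' planted fold-change. Deterministic given the seed (stream `seed + 3`).
#'
#' @param config a [synth_config()].
#' @return list with `ct` (long data.frame `sample_id`, `week`, `gene_role`,
#'   `ct`, `replicate`) and `truth` (planted folds).
#' @export
generate_ct <- function(config = synth_config()) {
  set.seed(config$seed + 3L)
  rows <- list()
  for (wi in seq_along(config$weeks_meth)) {
    w <- config$weeks_meth[wi]
    mu_t <- config$reference_ct + config$baseline_delta -
      log2(config$folds[wi])
    for (s in seq_len(config$samples_per_week)) {
      id <- sprintf("w%d_s%d", w, s)
      for (r in seq_len(config$ct_replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = id, week = w, gene_role = "reference",
          ct = stats::rnorm(1L, config$reference_ct, config$ct_noise_sd),
          replicate = r)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = id, week = w, gene_role = "target",
          ct = stats::rnorm(1L, mu_t, config$ct_noise_sd), replicate = r)
      }
    }
  }
  list(ct = do.call(rbind, rows),
       truth = list(folds = stats::setNames(config$folds,
                                            config$weeks_meth)))
}

#' Generate a complete synthetic study bundle on disk
#'
#' Writes every file the pipeline consumes — reference FASTA, clone FASTA,
#' group manifest, color TSV, Ct TSV — plus a ground-truth JSON and a config
#' echo. The write is atomic: on any failure the partial bundle directory is
#' removed.
#'
#' @param config a [synth_config()].
#' @param dir output directory (created; must not already exist).
#' @return invisibly, a list with the file `paths`, the `truth` list and the
#'   `config`.
#' @export
generate_bundle <- function(config = synth_config(), dir) {
  if (dir.exists(dir)) stop("bundle directory already exists: ", dir)
  dir.create(dir, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(dir, recursive = TRUE), add = TRUE)

  refg <- generate_reference(config)
  cl <- generate_clones(refg, config)
  co <- generate_color(config)
  ctg <- generate_ct(config)

  paths <- list(
    reference = file.path(dir, "reference.fasta"),
    clones = file.path(dir, "clones.fasta"),
    manifest = file.path(dir, "manifest.tsv"),
    color = file.path(dir, "color.tsv"),
    ct = file.path(dir, "ct.tsv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.json"))

  write_fasta(stats::setNames(refg$ref$sequence, refg$ref$id),
              paths$reference)
  write_fasta(cl$reads, paths$clones)
  utils::write.table(cl$manifest, paths$manifest, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(co$color, paths$color, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(ctg$ct, paths$ct, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  truth <- list(seed = config$seed,
                site_positions = refg$truth$site_positions,
                amplicon = refg$truth$amplicon,
                per_week_site_prob = config$per_week_site_prob,
                states = cl$truth$states,
                realized_conversion = cl$truth$realized_conversion,
                orientation = cl$truth$orientation,
                planted_overall = cl$truth$planted_overall,
                color_means = co$truth$means,
                folds = ctg$truth$folds)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       digits = NA)
  ok <- TRUE
  invisible(list(paths = paths, truth = truth, config = config))
}
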