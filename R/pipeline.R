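#' Write an epoch_set to a plain-text container
#'
#' Stores the amplitude block as a wide TSV (one row per trial x channel,
#' time samples as columns) next to a JSON sidecar holding the time axis,
#' sampling rate, alignment, channel labels, baseline and trial metadata.
#'
#' @param epochs an `epoch_set`.
#' @param path basename; writes `<path>.tsv` and `<path>.json`.
#' @return invisibly, the two file paths.
#' @export
write_epochs <- function(epochs, path) {
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), ncol = d[3], byrow = TRUE)
  tab <- data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                    channel = rep(epochs$channels, d[1]),
                    signif(flat, 8))
  names(tab)[-(1:2)] <- sprintf("t%d", seq_len(d[3]))
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  utils::write.table(tab, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(time_ms = epochs$time_ms, sfreq = epochs$sfreq,
         alignment = epochs$alignment, channels = epochs$channels,
         baseline = epochs$baseline, meta = epochs$meta),
    js, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(c(tsv, js))
}

#' Read an epoch_set written by [write_epochs()]
#'
#' @param path basename used at write time.
#' @return an `epoch_set`.
#' @export
read_epochs <- function(path) {
  tab <- utils::read.delim(paste0(path, ".tsv"), check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n_tr <- max(tab$trial); chans <- side$channels
  n_t <- length(side$time_ms)
  dat <- array(NA_real_, c(n_tr, length(chans), n_t))
  amp <- as.matrix(tab[, -(1:2)])
  for (k in seq_len(nrow(tab))) {
    dat[tab$trial[k], match(tab$channel[k], chans), ] <- amp[k, ]
  }
  meta <- as.data.frame(side$meta)
  epoch_set(dat, side$time_ms, side$sfreq, side$alignment, chans, meta,
            baseline = side$baseline)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Behaviour table writers/readers
#'
#' One row per trial with a subject column; the inverse reconstructs the
#' `subject_behavior` list.
#' @param behaviors named list of `subject_behavior`.
#' @param path TSV path.
#' @return invisibly, `path` (writer) or the list (reader).
#' @export
write_behavior <- function(behaviors, path) {
  rows <- do.call(rbind, lapply(names(behaviors), function(nm) {
    data.frame(subject_id = nm, behaviors[[nm]]$trials)
  }))
  write_tsv(rows, path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  tab <- utils::read.delim(path)
  out <- lapply(split(tab, tab$subject_id), function(d) {
    structure(list(trials = d[setdiff(names(d), "subject_id")],
                   accuracy = mean(d$responded),
                   n_valid = sum(d$responded),
                   subject_id = d$subject_id[1]),
              class = "subject_behavior")
  })
  out[unique(tab$subject_id)]
}

#' Run the full analysis pipeline on a configuration
#'
#' Stages (in order, each optional via `stages`): `simulate` (cohort
#' generation), `preprocess` (trial exclusion), `metrics` (eight neural
#' scalars per subject), `ddm` (G-square fits), `stats` (group comparison,
#' moderation, mediation). All tabular outputs are TSV, summaries JSON;
#' every file is stamped with the MD5 of the written config so downstream
#' artifacts are traceable to their settings.
#'
#' @param config a [cohort_config()] (or list of its arguments, or a path
#'   to a JSON file of them).
#' @param out_dir output directory (created).
#' @param stages character subset of
#'   `c("simulate", "preprocess", "metrics", "ddm", "stats")`.
#' @return list with the in-memory results of each stage and `files`.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "preprocess", "metrics",
                                    "ddm", "stats")) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  if (is.null(config$seed)) stop("config must carry an explicit seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  log <- list(config_md5 = cfg_hash)
  res <- list(config = config, files = character(0))

  if ("simulate" %in% stages) {
    sim <- simulate_cohort(config, epochs = TRUE)
    res$subjects <- sim$subjects; res$behaviors <- sim$behaviors
    res$epochs <- sim$epochs
    p <- file.path(out_dir, "subjects.tsv")
    write_tsv(data.frame(sim$subjects, config_md5 = cfg_hash), p)
    res$files <- c(res$files, p)
    p <- file.path(out_dir, "behavior.tsv")
    write_behavior(sim$behaviors, p)
    res$files <- c(res$files, p)
    log$n_subjects <- nrow(sim$subjects)
  }
  if ("preprocess" %in% stages) {
    stopifnot(!is.null(res$epochs))
    res$epochs <- lapply(res$epochs, exclude_trials)
    log$exclusions <- lapply(res$epochs, function(e) attr(e, "exclusion_log"))
  }
  if ("metrics" %in% stages) {
    stopifnot(!is.null(res$epochs))
    waves <- lapply(res$epochs, n2c_waveform)
    gp <- grand_n2c_peak(waves)
    metrics <- do.call(rbind, lapply(res$epochs, neural_metrics,
                                     grand_peak = gp))
    rownames(metrics) <- NULL
    res$metrics <- metrics; res$grand_n2c_peak <- gp
    p <- file.path(out_dir, "metrics.tsv")
    write_tsv(data.frame(subject_id = res$subjects$subject_id, metrics,
                         config_md5 = cfg_hash), p)
    res$files <- c(res$files, p)
  }
  if ("ddm" %in% stages) {
    stopifnot(!is.null(res$behaviors))
    res$ddm <- lapply(res$behaviors, fit_ddm, deadline = config$deadline)
    p <- file.path(out_dir, "ddm.tsv")
    write_tsv(data.frame(
      subject_id = names(res$ddm),
      a = vapply(res$ddm, `[[`, numeric(1), "a"),
      v = vapply(res$ddm, `[[`, numeric(1), "v"),
      t0 = vapply(res$ddm, `[[`, numeric(1), "t0"),
      g2 = vapply(res$ddm, `[[`, numeric(1), "g2"),
      converged = vapply(res$ddm, `[[`, logical(1), "converged"),
      config_md5 = cfg_hash, row.names = NULL), p)
    res$files <- c(res$files, p)
  }
  if ("stats" %in% stages) {
    tab <- build_cohort_table(res$subjects, res$behaviors, res$metrics,
                              res$ddm)
    res$table <- tab
    p <- file.path(out_dir, "cohort.tsv")
    write_tsv(data.frame(tab, config_md5 = cfg_hash), p)
    res$files <- c(res$files, p)
    gc_rt <- group_compare(tab$mean_rt, tab$group)
    mod <- moderation(tab, "mean_rt", "cri_leisure", "cpp_slope")
    med <- if (nrow(tab) >= 10) {
      mediation_bootstrap(tab, "cpp_slope", "cpp_amplitude", "mean_rt",
                          n_boot = 1000, seed = config$seed)
    } else {
      NULL # bootstrap mediation needs >= 10 subjects
    }
    res$stats <- list(rt_group = gc_rt, moderation = mod, mediation = med)
    p <- file.path(out_dir, "stats.json")
    jsonlite::write_json(list(
      config_md5 = cfg_hash,
      rt_group = list(f = gc_rt$f, df = gc_rt$df, p = gc_rt$p,
                      partial_eta2 = gc_rt$partial_eta2),
      moderation = list(coefficients = mod$coefficients,
                        conditional = mod$conditional, r2 = mod$r2,
                        mse = mod$mse),
      mediation = list(indirect = med$indirect, boot_se = med$boot_se,
                       ci = med$ci, n_boot = med$n_boot, seed = med$seed)
    ), p, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    res$files <- c(res$files, p)
  }
  log_path <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, log_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  res$files <- c(res$files, cfg_path, log_path)
  res
}
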