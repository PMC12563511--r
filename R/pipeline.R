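# Pipeline orchestration: configuration, simulate -> compute -> compare.
# These functions are also the backend of the command-line wrapper in
# inst/cli/msptirr.

#' Assemble a run configuration
#'
#' Collects the parameters that drive the pipeline commands, with the
#' analysis defaults: `m = 3`, `tau = 2`, scales 1..100, alpha 0.05, the
#' standard five-band table, both index kinds.
#'
#' @param out_dir Output directory for all written artifacts.
#' @param manifest Path to a cohort manifest (required by
#'   [cmd_compute()]; written by [cmd_simulate()]).
#' @param m,tau Embedding dimension and delay.
#' @param scales Integer vector of scale factors.
#' @param kinds Index kinds to compute (subset of `c("PTIRR", "PE")`).
#' @param bands If `TRUE`, also compute per-band subject profiles
#'   (band-decomposed with [meg_bands()]).
#' @param regions If `TRUE`, [cmd_compare()] adds per-region contrasts.
#' @param alpha Significance level.
#' @param seed Integer seed governing every stochastic step.
#' @param cohort Named list of overrides passed to [gen_cohort()] by
#'   [cmd_simulate()] (e.g. `list(n_channels = 20, n_samples = 6000)`).
#' @param quiet Suppress progress messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = "msptirr_out", manifest = NULL,
                       m = 3L, tau = 2L, scales = 1:100,
                       kinds = c("PTIRR", "PE"), bands = FALSE,
                       regions = TRUE, alpha = 0.05, seed = 1L,
                       cohort = list(), quiet = FALSE) {
  cfg <- list(out_dir = out_dir, manifest = manifest,
              m = as.integer(m), tau = as.integer(tau),
              scales = as.integer(scales),
              kinds = match.arg(kinds, c("PTIRR", "PE"), several.ok = TRUE),
              bands = isTRUE(bands), regions = isTRUE(regions),
              alpha = alpha, seed = as.integer(seed),
              cohort = cohort, quiet = isTRUE(quiet))
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' Fields found in the file override the [run_config()] defaults; unknown
#' fields are rejected with their names.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param ... Further overrides applied on top of the file.
#' @return A `run_config`.
#' @export
load_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if (!is.null(raw$scales) && length(raw$scales) == 2L && is.null(names(raw$scales)))
    raw$scales <- seq(raw$scales[1], raw$scales[2])  # allow [from, to] shorthand
  do.call(run_config, raw)
}

.log_msg <- function(cfg, ...) {
  if (!cfg$quiet) message(sprintf(...))
}

.write_run_meta <- function(cfg, step) {
  meta <- list(step = step, seed = cfg$seed, m = cfg$m, tau = cfg$tau,
               scales = range(cfg$scales), alpha = cfg$alpha,
               bands = cfg$bands, regions = cfg$regions,
               package_version = as.character(utils::packageVersion("msptirr")))
  jsonlite::write_json(meta, file.path(cfg$out_dir, paste0(step, "_meta.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Simulate a synthetic cohort to disk
#'
#' Runs [gen_cohort()] with the config's seed and cohort overrides and
#' writes one recording per subject plus `manifest.tsv` under
#' `out_dir/recordings/`.
#'
#' @param config A [run_config()].
#' @return The manifest data frame, invisibly. The manifest path is stored
#'   in the returned config attribute `manifest`.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rec_dir <- file.path(config$out_dir, "recordings")
  if (!dir.exists(rec_dir)) dir.create(rec_dir, recursive = TRUE)
  args <- config$cohort
  args$seed <- config$seed
  args$dir <- rec_dir
  cohort <- do.call(gen_cohort, args)
  manifest_path <- file.path(rec_dir, "manifest.tsv")
  man <- cohort$manifest
  man$file <- basename(man$file)
  write_manifest(man, manifest_path)
  .write_run_meta(config, "simulate")
  .log_msg(config, "simulated %d subjects (seed %d) -> %s",
           nrow(man), config$seed, manifest_path)
  invisible(structure(man, manifest_path = manifest_path))
}

#' Compute multiscale profiles for every subject in a manifest
#'
#' Reads each recording, computes per-channel and channel-averaged
#' MsPTIRR/MsPE profiles (per `config$kinds`), optionally repeats the
#' channel-averaged profiles on each frequency band, and writes one tidy
#' table `profiles.tsv` with columns `subject_id`, `group`, `band`
#' (`broadband` or a band name), `channel` (label or `MEAN`), `scale`,
#' `index_kind`, `value`.
#'
#' @param config A [run_config()] with `manifest` set.
#' @return The profiles data frame, invisibly.
#' @export
cmd_compute <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$manifest)) stop("config$manifest is required for cmd_compute")
  man <- read_manifest(config$manifest)
  rec_dir <- attr(man, "dir")
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  pieces <- list()
  for (i in seq_len(nrow(man))) {
    f <- man$file[i]
    if (!file.exists(f)) f <- file.path(rec_dir, man$file[i])
    if (!file.exists(f))
      stop("recording file not found for subject ", man$subject_id[i], ": ",
           man$file[i])
    rec <- read_recording(f)
    fs <- attr(rec, "sample_rate_hz")
    for (kind in config$kinds) {
      sp <- subject_profile(rec, scales = config$scales, m = config$m,
                            tau = config$tau, kind = kind,
                            subject_id = man$subject_id[i],
                            group = man$group[i])
      df <- as.data.frame(sp)
      df$band <- "broadband"
      pieces[[length(pieces) + 1L]] <- df
    }
    if (config$bands) {
      if (is.na(fs)) stop("band analysis requires a sample-rate declaration in ", f)
      by_band <- band_decompose(rec, sample_rate_hz = fs)
      for (bn in names(by_band)) {
        for (kind in config$kinds) {
          sp <- subject_profile(by_band[[bn]], scales = config$scales,
                                m = config$m, tau = config$tau, kind = kind,
                                subject_id = man$subject_id[i],
                                group = man$group[i])
          df <- as.data.frame(sp)
          df <- df[df$channel == "MEAN", , drop = FALSE]  # subject mean only
          df$band <- bn
          pieces[[length(pieces) + 1L]] <- df
        }
      }
    }
    .log_msg(config, "computed profiles for %s (%s)", man$subject_id[i],
             man$group[i])
  }
  profiles <- do.call(rbind, pieces)
  profiles <- profiles[, c("subject_id", "group", "band", "channel", "scale",
                           "index_kind", "value")]
  write_table_tsv(profiles, file.path(config$out_dir, "profiles.tsv"))
  .write_run_meta(config, "compute")
  invisible(profiles)
}

# subjects x scales matrix for one group from tidy profile rows
.group_matrix <- function(rows, group) {
  g <- rows[rows$group == group, ]
  subj <- sort(unique(g$subject_id))
  scales <- sort(unique(g$scale))
  mat <- matrix(NA_real_, nrow = length(subj), ncol = length(scales),
                dimnames = list(subj, scales))
  mat[cbind(match(g$subject_id, subj), match(g$scale, scales))] <- g$value
  mat
}

.compare_stratum <- function(rows, alpha) {
  groups <- sort(unique(rows$group))
  if (length(groups) != 2L)
    stop("per-scale comparison needs exactly 2 groups; found: ",
         paste(groups, collapse = ", "))
  a <- .group_matrix(rows, groups[1])
  b <- .group_matrix(rows, groups[2])
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("fewer than 2 subjects in a group")
  res <- per_scale_ttest(a, b, alpha = alpha)
  attr(res, "groups") <- groups
  res
}

#' Compare the two groups per scale, by stratum
#'
#' Reads `profiles.tsv` from `out_dir` and runs per-scale two-group
#' t tests on the subject-level (MEAN-channel) MsPTIRR profiles: whole-head
#' broadband, per (hemisphere, region) cell when `config$regions` is set
#' and channel labels parse as CTF names, and per frequency band when
#' per-band profiles are present. Writes `stats.tsv` (per-scale tests,
#' long format with a `stratum` column) and `intervals.tsv` (one row per
#' stratum with its significant scale intervals).
#'
#' @param config A [run_config()] whose `out_dir` holds a `profiles.tsv`.
#' @return List with `stats` and `intervals` data frames, invisibly.
#' @export
cmd_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ppath <- file.path(config$out_dir, "profiles.tsv")
  profiles <- read_table_tsv(ppath)
  profiles <- profiles[profiles$index_kind == "PTIRR", , drop = FALSE]
  if (nrow(profiles) == 0L)
    stop("no PTIRR rows in ", ppath, "; run cmd_compute with kinds including PTIRR")
  strata <- list()

  mean_rows <- profiles[profiles$channel == "MEAN" &
                        profiles$band == "broadband", ]
  strata[["whole_head"]] <- mean_rows

  if (config$regions) {
    ch_rows <- profiles[profiles$channel != "MEAN" &
                        profiles$band == "broadband", ]
    if (nrow(ch_rows)) {
      rmap <- map_regions(unique(ch_rows$channel))
      for (h in c("L", "R")) for (r in c("C", "F", "O", "P", "T")) {
        chans <- region_channels(rmap, h, r)
        if (!length(chans)) next
        sub <- ch_rows[ch_rows$channel %in% chans, ]
        # subject-level region mean at each scale
        agg <- stats::aggregate(value ~ subject_id + group + scale, data = sub,
                                FUN = mean)
        strata[[paste0(h, r)]] <- agg
      }
    }
  }

  for (bn in setdiff(unique(profiles$band), "broadband")) {
    strata[[paste0("band_", bn)]] <-
      profiles[profiles$band == bn & profiles$channel == "MEAN", ]
  }

  stat_pieces <- list()
  int_pieces <- list()
  for (nm in names(strata)) {
    res <- .compare_stratum(strata[[nm]], config$alpha)
    groups <- attr(res, "groups")
    res$stratum <- nm
    stat_pieces[[nm]] <- res
    ints <- significance_intervals(res, alpha = config$alpha)
    int_pieces[[nm]] <- data.frame(stratum = nm,
                                   intervals = format_intervals(ints),
                                   n_significant_scales = sum(res$p_value < config$alpha),
                                   stringsAsFactors = FALSE)
    .log_msg(config, "stratum %-12s (%s vs %s): %s", nm, groups[1], groups[2],
             format_intervals(ints))
  }
  stats_tab <- do.call(rbind, stat_pieces)
  rownames(stats_tab) <- NULL
  stats_tab <- stats_tab[, c("stratum", setdiff(names(stats_tab), "stratum"))]
  intervals_tab <- do.call(rbind, int_pieces)
  rownames(intervals_tab) <- NULL
  write_table_tsv(stats_tab, file.path(config$out_dir, "stats.tsv"))
  write_table_tsv(intervals_tab, file.path(config$out_dir, "intervals.tsv"))
  .write_run_meta(config, "compare")
  invisible(list(stats = stats_tab, intervals = intervals_tab))
}

#' Per-channel embedding-parameter selection table
#'
#' Runs [fnn_dimension()] and [cc_delay()] on every channel of a recording
#' and aggregates the choices by mode -- the procedure behind the analysis
#' defaults `m = 3`, `tau = 2`.
#'
#' @param recording Channels x samples matrix.
#' @param max_m,max_tau Search ranges.
#' @param ... Passed through to the selectors.
#' @return List with `table` (data frame: `channel`, `chosen_m`,
#'   `chosen_tau`) and `mode_m`, `mode_tau`.
#' @export
select_embedding <- function(recording, max_m = 6L, max_tau = 15L, ...) {
  stopifnot(is.matrix(recording))
  if (is.null(rownames(recording)))
    rownames(recording) <- sprintf("ch%03d", seq_len(nrow(recording)))
  rows <- lapply(rownames(recording), function(ch) {
    x <- recording[ch, ]
    tau <- cc_delay(x, max_tau = max_tau, ...)$chosen_tau
    m <- fnn_dimension(x, tau = tau, max_m = max_m, ...)$chosen_m
    data.frame(channel = ch, chosen_m = m, chosen_tau = tau,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       mode_m = aggregate_by_mode(tab$chosen_m),
       mode_tau = aggregate_by_mode(tab$chosen_tau))
}
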