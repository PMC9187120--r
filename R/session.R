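#' Spike waveform
#'
#' A baseline-referenced average spike waveform recorded on one probe site.
#'
#' @param samples numeric vector of voltage values (arbitrary units).
#' @param sampling_rate sampling rate in Hz.
#' @param site_index integer index of the recording site of origin.
#' @return object of class `waveform`.
#' @export
waveform <- function(samples, sampling_rate, site_index = 1L) {
  if (length(samples) == 0) stop("waveform samples must be non-empty")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 site_index = as.integer(site_index)),
            class = "waveform")
}

.OUTCOMES <- c("hit", "miss", "CR", "FA", "early_lick")
.DEFAULT_AREAS <- c("wS1", "wS2", "wM1", "wM2", "ALM", "tjM1")
.DEFAULT_LAYERS <- c("L2/3", "L5", "L6a", "unknown")

#' Session container
#'
#' Bundles the sorted units of one recording session with their spike times,
#' the trial table and (for opto sessions) the light-pulse onsets.
#'
#' @param units data.frame with columns `unit_id`, `area`, `layer`,
#'   `assigned_site`, `spike_width_ms`, `cell_class` (`baseline_rate_hz`
#'   optional).
#' @param spikes named list of strictly increasing spike-time vectors
#'   (seconds), keyed by `unit_id`.
#' @param trials data.frame with columns `trial_id`, `visual_onset_s`,
#'   `whisker_onset_s` (NA on no-stimulus trials), `auditory_onset_s`,
#'   `outcome`, `first_lick_s`, `light_on`.
#' @param waveforms optional named list (by `unit_id`) of lists of
#'   [waveform()] objects, one per recording site.
#' @param light_pulses optional sorted vector of light-train onset times (s).
#' @param session_id character id.
#' @param group `"Novice"` or `"Expert"`.
#' @param areas,layers allowed vocabulary for unit locations.
#' @return object of class `spike_session`.
#' @export
session <- function(units, spikes, trials, waveforms = NULL,
                    light_pulses = NULL, session_id = "session",
                    group = c("Expert", "Novice"),
                    areas = .DEFAULT_AREAS, layers = .DEFAULT_LAYERS) {
  group <- match.arg(group)
  s <- structure(list(units = units, spikes = spikes, trials = trials,
                      waveforms = waveforms, light_pulses = light_pulses,
                      session_id = session_id, group = group),
                 class = "spike_session")
  validate_session(s, areas = areas, layers = layers)
  s
}

#' Validate a session
#'
#' Checks referential integrity and the invariants of the session data model:
#' unique unit ids, strictly increasing spike times, trial-event ordering
#' (visual < whisker < auditory where the whisker stimulus is present),
#' outcome/stimulus consistency (hit/miss need a whisker onset, CR/FA must
#' lack one), non-overlapping increasing trials, and cell-class consistency
#' with the spike-width thresholds.
#'
#' @param s a `spike_session`.
#' @param areas,layers allowed vocabulary.
#' @return `s`, invisibly; signals a validation error otherwise.
#' @export
validate_session <- function(s, areas = .DEFAULT_AREAS,
                             layers = .DEFAULT_LAYERS) {
  u <- s$units
  need <- c("unit_id", "area", "layer", "assigned_site",
            "spike_width_ms", "cell_class")
  if (!all(need %in% names(u)))
    stop("validation error: units table missing column(s): ",
         paste(setdiff(need, names(u)), collapse = ", "))
  if (anyDuplicated(u$unit_id))
    stop("validation error: duplicate unit_id in units table")
  bad <- setdiff(u$area, areas)
  if (length(bad)) stop("validation error: unknown area(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(u$layer, layers)
  if (length(bad)) stop("validation error: unknown layer(s): ",
                        paste(bad, collapse = ", "))
  bad <- setdiff(u$cell_class, c("RS", "FS", "excluded"))
  if (length(bad)) stop("validation error: unknown cell_class: ",
                        paste(bad, collapse = ", "))
  ok <- !is.na(u$spike_width_ms) & !is.na(u$cell_class)
  if (any(ok)) {
    expect <- classify_rs_fs(u$spike_width_ms[ok])
    mism <- u$cell_class[ok] != expect
    if (any(mism))
      stop("validation error: cell_class inconsistent with spike_width_ms ",
           "for unit ", u$unit_id[ok][which(mism)[1]])
  }
  extra <- setdiff(names(s$spikes), as.character(u$unit_id))
  if (length(extra))
    stop("validation error: spikes reference unknown unit_id: ",
         paste(extra, collapse = ", "))
  for (id in names(s$spikes)) {
    st <- s$spikes[[id]]
    if (length(st) > 1 && any(diff(st) <= 0))
      stop("validation error: spike times not strictly increasing for unit ",
           id)
  }
  tr <- s$trials
  if (nrow(tr)) {
    if (any(tr$auditory_onset_s <= tr$visual_onset_s))
      stop("validation error: auditory onset precedes visual onset in trial ",
           tr$trial_id[which(tr$auditory_onset_s <= tr$visual_onset_s)[1]])
    wp <- !is.na(tr$whisker_onset_s)
    if (any(wp & (tr$whisker_onset_s <= tr$visual_onset_s |
                  tr$whisker_onset_s >= tr$auditory_onset_s)))
      stop("validation error: whisker onset outside (visual, auditory) window")
    bad <- setdiff(tr$outcome, .OUTCOMES)
    if (length(bad)) stop("validation error: unknown outcome(s): ",
                          paste(bad, collapse = ", "))
    if (any(tr$outcome %in% c("hit", "miss") & !wp))
      stop("validation error: hit/miss trial without whisker onset")
    if (any(tr$outcome %in% c("CR", "FA") & wp))
      stop("validation error: CR/FA trial with whisker onset")
    if (nrow(tr) > 1) {
      o <- order(tr$visual_onset_s)
      if (any(tr$visual_onset_s[o][-1] <= tr$auditory_onset_s[o][-nrow(tr)]))
        stop("validation error: overlapping or non-increasing trials")
    }
  }
  if (!is.null(s$light_pulses) && length(s$light_pulses) > 1 &&
      is.unsorted(s$light_pulses, strictly = TRUE))
    stop("validation error: light pulse onsets must be strictly increasing")
  invisible(s)
}

#' Select usable trials
#'
#' Returns the trial rows matching the requested outcomes. Early-lick trials
#' are aborted during the task and are excluded from all analyses by default.
#'
#' @param trials trial data.frame.
#' @param outcomes character vector of outcomes to keep, or NULL for all
#'   non-early-lick trials.
#' @param whisker one of `"any"`, `"present"`, `"absent"` to additionally
#'   filter on the whisker stimulus.
#' @return filtered data.frame.
#' @export
select_trials <- function(trials, outcomes = NULL,
                          whisker = c("any", "present", "absent")) {
  whisker <- match.arg(whisker)
  keep <- if (is.null(outcomes)) trials$outcome != "early_lick"
          else trials$outcome %in% outcomes
  if (whisker == "present") keep <- keep & !is.na(trials$whisker_onset_s)
  if (whisker == "absent") keep <- keep & is.na(trials$whisker_onset_s)
  trials[keep, , drop = FALSE]
}

.fmt_time <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))

#' Write a session to a directory of plain-text tables
#'
#' Writes `units.csv`, `spikes.csv`, `trials.csv`, `waveforms.csv` and, when
#' light pulses are present, `light_pulses.csv` (comma-separated, header
#' row). Times are written as decimal seconds at microsecond precision, so
#' [load_session()] inverts the round trip exactly at that precision.
#'
#' @param s a `spike_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_session <- function(s, dir) {
  validate_session(s)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("I/O error: cannot create directory ", dir)
  u <- s$units
  u$spike_width_ms <- ifelse(is.na(u$spike_width_ms), "",
                             sprintf("%.6f", u$spike_width_ms))
  utils::write.csv(u, file.path(dir, "units.csv"), row.names = FALSE)
  ids <- as.character(s$units$unit_id)
  sp <- data.frame(
    unit_id = rep(ids, vapply(s$spikes[ids], length, 1L)),
    time_s = .fmt_time(unlist(s$spikes[ids], use.names = FALSE)))
  utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
  tr <- s$trials
  for (col in c("visual_onset_s", "whisker_onset_s", "auditory_onset_s",
                "first_lick_s"))
    tr[[col]] <- .fmt_time(tr[[col]])
  utils::write.csv(tr, file.path(dir, "trials.csv"), row.names = FALSE)
  wf <- data.frame(unit_id = character(), site_index = integer(),
                   sample_index = integer(), value = numeric(),
                   sampling_rate = numeric())
  if (!is.null(s$waveforms)) {
    wf <- do.call(rbind, lapply(names(s$waveforms), function(id) {
      do.call(rbind, lapply(s$waveforms[[id]], function(w)
        data.frame(unit_id = id, site_index = w$site_index,
                   sample_index = seq_along(w$samples) - 1L,
                   value = w$samples, sampling_rate = w$sampling_rate)))
    }))
  }
  utils::write.csv(wf, file.path(dir, "waveforms.csv"), row.names = FALSE)
  if (!is.null(s$light_pulses))
    utils::write.csv(data.frame(onset_s = .fmt_time(s$light_pulses)),
                     file.path(dir, "light_pulses.csv"), row.names = FALSE)
  meta <- data.frame(session_id = s$session_id, group = s$group)
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  invisible(dir)
}

.num_or_na <- function(x) {
  x <- as.character(x)
  x[x == ""] <- NA_character_
  as.numeric(x)
}

#' Load a session from a directory written by [save_session()]
#'
#' @param dir directory containing the session tables.
#' @return a validated `spike_session`.
#' @export
load_session <- function(dir) {
  need <- c("units.csv", "spikes.csv", "trials.csv")
  miss <- need[!file.exists(file.path(dir, need))]
  if (length(miss))
    stop("format error: missing file(s): ", paste(miss, collapse = ", "))
  rd <- function(f) utils::read.csv(file.path(dir, f),
                                    colClasses = "character")
  u <- rd("units.csv")
  u$assigned_site <- as.integer(u$assigned_site)
  u$spike_width_ms <- .num_or_na(u$spike_width_ms)
  if ("baseline_rate_hz" %in% names(u))
    u$baseline_rate_hz <- .num_or_na(u$baseline_rate_hz)
  sp <- rd("spikes.csv")
  sp$time_s <- as.numeric(sp$time_s)
  spikes <- lapply(stats::setNames(nm = as.character(u$unit_id)),
                   function(id) sp$time_s[sp$unit_id == id])
  extra <- setdiff(unique(sp$unit_id), as.character(u$unit_id))
  if (length(extra))
    stop("validation error: spikes reference unknown unit_id: ",
         paste(extra, collapse = ", "))
  tr <- rd("trials.csv")
  for (col in c("visual_onset_s", "whisker_onset_s", "auditory_onset_s",
                "first_lick_s"))
    tr[[col]] <- .num_or_na(tr[[col]])
  tr$light_on <- as.logical(tr$light_on)
  waveforms <- NULL
  if (file.exists(file.path(dir, "waveforms.csv"))) {
    wf <- rd("waveforms.csv")
    if (nrow(wf)) {
      wf$site_index <- as.integer(wf$site_index)
      wf$sample_index <- as.integer(wf$sample_index)
      wf$value <- as.numeric(wf$value)
      wf$sampling_rate <- as.numeric(wf$sampling_rate)
      waveforms <- lapply(split(wf, wf$unit_id), function(d)
        lapply(split(d, d$site_index), function(g)
          waveform(g$value[order(g$sample_index)], g$sampling_rate[1],
                   g$site_index[1])))
    }
  }
  light <- NULL
  if (file.exists(file.path(dir, "light_pulses.csv"))) {
    lp <- rd("light_pulses.csv")
    light <- as.numeric(lp$onset_s)
  }
  sid <- "session"; grp <- "Expert"
  if (file.exists(file.path(dir, "meta.csv"))) {
    m <- rd("meta.csv")
    sid <- m$session_id[1]; grp <- m$group[1]
  }
  session(u, spikes, tr, waveforms = waveforms, light_pulses = light,
          session_id = sid, group = grp)
}
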