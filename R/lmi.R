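#' Learning modulation index
#'
#' Normalized difference of the grand-average whisker-evoked rate change
#' between Expert and Novice cohorts:
#' `LMI = (dAP_Expert - dAP_Novice) / (|dAP_Expert| + |dAP_Novice|)`,
#' bounded in \[-1, 1\]. Positive values indicate increased evoked activity
#' after learning; |LMI| = 1 when the two deltas have opposite signs or one
#' is zero.
#'
#' @param delta_ap_expert,delta_ap_novice grand-average evoked rate changes
#'   (Hz) in the Expert and Novice groups.
#' @return the index; `NA` with a warning when both deltas are zero.
#' @export
learning_modulation_index <- function(delta_ap_expert, delta_ap_novice) {
  denom <- abs(delta_ap_expert) + abs(delta_ap_novice)
  out <- (delta_ap_expert - delta_ap_novice) / denom
  if (any(denom == 0)) {
    warning("LMI undefined: both deltas are zero")
    out[denom == 0] <- NA_real_
  }
  out
}

#' Excitation-inhibition balance index
#'
#' Difference between the RS and FS learning modulation indices of an area;
#' negative values indicate a shift toward inhibition across learning.
#'
#' @param lmi_rs,lmi_fs learning modulation indices.
#' @return `lmi_rs - lmi_fs` (in \[-2, 2\]); `NA` when either is undefined.
#' @export
ei_balance <- function(lmi_rs, lmi_fs) lmi_rs - lmi_fs

#' LMI and E-I balance table from two evoked-response cohorts
#'
#' Grand-average evoked delta per area and cell class in each group (units
#' pooled over sessions/mice), then the learning modulation index and the
#' per-area E-I balance. Area-class groups present in only one cohort are
#' skipped with a warning.
#'
#' @param novice_responses,expert_responses data.frames from
#'   [session_evoked_responses()] (columns `area`, `cell_class`,
#'   `delta_rate_hz`), possibly row-bound over sessions.
#' @return list with `lmi` (data.frame: `area`, `cell_class`,
#'   `delta_ap_novice`, `delta_ap_expert`, `n_novice`, `n_expert`, `lmi`)
#'   and `ei` (data.frame: `area`, `ei_lmi`).
#' @export
lmi_table <- function(novice_responses, expert_responses) {
  keyify <- function(d) paste(d$area, d$cell_class, sep = ".")
  kn <- keyify(novice_responses); ke <- keyify(expert_responses)
  keys <- sort(unique(c(kn, ke)))
  rows <- list()
  for (k in keys) {
    if (!(k %in% kn) || !(k %in% ke)) {
      warning("area x class ", k, " missing in one group; skipped")
      next
    }
    dn <- novice_responses$delta_rate_hz[kn == k]
    de <- expert_responses$delta_rate_hz[ke == k]
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    rows[[k]] <- data.frame(
      area = parts[1], cell_class = parts[2],
      delta_ap_novice = mean(dn), delta_ap_expert = mean(de),
      n_novice = length(dn), n_expert = length(de),
      lmi = suppressWarnings(
        learning_modulation_index(mean(de), mean(dn))))
  }
  lmi <- do.call(rbind, rows)
  rownames(lmi) <- NULL
  ei <- NULL
  if (!is.null(lmi)) {
    areas <- unique(lmi$area)
    ei <- do.call(rbind, lapply(areas, function(a) {
      rs <- lmi$lmi[lmi$area == a & lmi$cell_class == "RS"]
      fs <- lmi$lmi[lmi$area == a & lmi$cell_class == "FS"]
      if (length(rs) != 1 || length(fs) != 1) return(NULL)
      data.frame(area = a, lmi_rs = rs, lmi_fs = fs,
                 ei_lmi = ei_balance(rs, fs))
    }))
  }
  list(lmi = lmi, ei = ei)
}

#' Per-mouse-weighted LMI variant
#'
#' Like [lmi_table()] but averaging unit deltas within each session/mouse
#' first and then across mice, for reporting styles that weight mice
#' equally.
#'
#' @param novice_responses,expert_responses as in [lmi_table()], with an
#'   additional `session_id` column.
#' @return as [lmi_table()].
#' @export
lmi_table_by_mouse <- function(novice_responses, expert_responses) {
  collapse <- function(d) {
    key <- interaction(d$area, d$cell_class, d$session_id, drop = TRUE)
    agg <- lapply(split(d, key), function(g)
      data.frame(area = g$area[1], cell_class = g$cell_class[1],
                 delta_rate_hz = mean(g$delta_rate_hz)))
    do.call(rbind, agg)
  }
  lmi_table(collapse(novice_responses), collapse(expert_responses))
}
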