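## Synchronous affected/healthy epoch pairing and per-phase summaries.

#' Pair affected- and healthy-side epochs recorded synchronously
#'
#' Greedy nearest-timestamp matching between the two feature streams: the
#' globally closest remaining pair (same surgical phase, interval at most
#' `max_interval` seconds) is accepted repeatedly until no admissible pair
#' remains. Each epoch is used at most once; unmatched epochs are dropped.
#' The 3-minute synchrony criterion is inclusive: an interval of exactly
#' `max_interval` is paired.
#'
#' @param affected,healthy Data frames of epochs for one patient and side
#'   (columns `timestamp_s`, `phase`, and the indicators of
#'   [baep_indicators()]), each sorted by `timestamp_s`.
#' @param max_interval Maximum affected-healthy recording interval, seconds
#'   (default 180 = 3 min).
#' @return Data frame with one row per pair: `phase`, `interval_s`,
#'   `aff_timestamp_s`, `hea_timestamp_s`, and each indicator twice with
#'   `aff_`/`hea_` prefixes. Zero rows if no pair is admissible.
#' @examples
#' a <- data.frame(timestamp_s = 600, phase = "pre_resection", la_v = 6.27)
#' h <- data.frame(timestamp_s = 779, phase = "pre_resection", la_v = 5.70)
#' pair_streams(a, h)  # interval 179 s -> paired
#' @export
pair_streams <- function(affected, healthy, max_interval = 180) {
  for (nm in c("affected", "healthy")) {
    df <- get(nm)
    if (!is.data.frame(df) || is.null(df$timestamp_s))
      stop_config("%s must be a data frame with a timestamp_s column", nm)
    if (is.unsorted(df$timestamp_s, strictly = FALSE))
      stop_config("%s stream is not sorted by timestamp", nm)
  }
  ind <- intersect(baep_indicators(), intersect(names(affected), names(healthy)))
  empty <- function() {
    out <- data.frame(phase = character(), interval_s = numeric(),
                      aff_timestamp_s = numeric(), hea_timestamp_s = numeric())
    for (v in ind) {
      out[[paste0("aff_", v)]] <- numeric()
      out[[paste0("hea_", v)]] <- numeric()
    }
    out
  }
  if (!nrow(affected) || !nrow(healthy)) return(empty())

  dt <- abs(outer(affected$timestamp_s, healthy$timestamp_s, "-"))
  same_phase <- outer(affected$phase, healthy$phase, "==")
  dt[!same_phase | dt > max_interval] <- Inf

  m <- nrow(affected)
  take_i <- integer(0)
  take_j <- integer(0)
  repeat {
    k <- which.min(dt)  # deterministic tie-break: first in epoch order
    if (!is.finite(dt[k])) break
    i <- (k - 1L) %% m + 1L
    j <- (k - 1L) %/% m + 1L
    take_i <- c(take_i, i)
    take_j <- c(take_j, j)
    dt[i, ] <- Inf
    dt[, j] <- Inf
  }
  if (!length(take_i)) return(empty())
  ord <- order(affected$timestamp_s[take_i])
  take_i <- take_i[ord]
  take_j <- take_j[ord]
  out <- data.frame(phase = affected$phase[take_i],
                    interval_s = abs(affected$timestamp_s[take_i] -
                                       healthy$timestamp_s[take_j]),
                    aff_timestamp_s = affected$timestamp_s[take_i],
                    hea_timestamp_s = healthy$timestamp_s[take_j])
  for (v in ind) {
    out[[paste0("aff_", v)]] <- affected[[v]][take_i]
    out[[paste0("hea_", v)]] <- healthy[[v]][take_j]
  }
  out
}

#' Summarize the paired epochs of one surgical phase
#'
#' Collapses the pairs of one phase to a single representative indicator
#' vector per side. The default representative is the per-indicator median
#' over epochs where the indicator is present, which is robust to the outlier
#' epochs that intraoperative interference produces; the mean is available.
#' An indicator absent in more than half of the phase's pairs is absent from
#' the summary.
#'
#' @param pairs Output of [pair_streams()].
#' @param phase `"pre_resection"` or `"post_resection"` (epochs acquired
#'   during active resection are never summarized).
#' @param method `"median"` (default) or `"mean"`.
#' @return Object of class `baep_phase_summary`: list with `phase`,
#'   `n_pairs`, and named indicator vectors `affected` and `healthy` — or
#'   `NULL` if the phase has no pairs (absence, not an error).
#' @export
summarize_phase <- function(pairs, phase = c("pre_resection", "post_resection"),
                            method = c("median", "mean")) {
  phase <- match.arg(phase)
  method <- match.arg(method)
  rows <- pairs[pairs$phase == phase, , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  fun <- if (method == "median") stats::median else mean
  summarize_side <- function(prefix) {
    ind <- baep_indicators()
    vals <- vapply(ind, function(v) {
      col <- rows[[paste0(prefix, v)]]
      if (is.null(col)) return(NA_real_)
      if (mean(is.na(col)) > 0.5) return(NA_real_)  # majority-absence rule
      fun(col, na.rm = TRUE)
    }, 0)
    stats::setNames(vals, ind)
  }
  structure(list(phase = phase, n_pairs = nrow(rows),
                 affected = summarize_side("aff_"),
                 healthy = summarize_side("hea_")),
            class = "baep_phase_summary")
}

#' @export
print.baep_phase_summary <- function(x, ...) {
  cat(sprintf("Phase summary (%s, %d pairs)\n", x$phase, x$n_pairs))
  print(round(rbind(affected = x$affected, healthy = x$healthy), 3))
  invisible(x)
}
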