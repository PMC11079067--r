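## Standardized indexes: referencing the affected side against the
## synchronously recorded healthy side cancels multiplicative interference
## common to both ears — the core quantity of the package.

#' Standardized index of the affected side (STI)
#'
#' For each indicator, `STI = affected / healthy - 1` (dimensionless). Any
#' interference factor applied multiplicatively to both ears cancels exactly:
#' `STI(c*a, c*h) = STI(a, h)` for every `c > 0`. An indicator absent on
#' either side is absent from the result.
#'
#' @param summary A `baep_phase_summary` from [summarize_phase()].
#' @return Object of class `baep_sti`: list with `phase`, `n_pairs`, and
#'   `sti`, a named vector over [baep_indicators()].
#' @examples
#' s <- structure(list(phase = "pre_resection", n_pairs = 1,
#'                     affected = c(la_v = 6.27), healthy = c(la_v = 5.70)),
#'                class = "baep_phase_summary")
#' compute_sti(s)$sti[["la_v"]]  # 0.1
#' @export
compute_sti <- function(summary) {
  stopifnot(inherits(summary, "baep_phase_summary"))
  ind <- intersect(baep_indicators(), names(summary$affected))
  a <- summary$affected[ind]
  h <- summary$healthy[ind]
  bad <- !is.na(h) & h == 0 & !is.na(a)
  if (any(bad))
    stop_config("healthy-side value is zero for indicator(s): %s",
                paste(ind[bad], collapse = ", "))
  sti <- a / h - 1
  sti[is.na(a) | is.na(h)] <- NA_real_
  structure(list(phase = summary$phase, n_pairs = summary$n_pairs,
                 sti = stats::setNames(as.numeric(sti), ind)),
            class = "baep_sti")
}

#' @export
print.baep_sti <- function(x, ...) {
  cat(sprintf("Standardized indexes (STI, %s)\n", x$phase))
  print(round(x$sti, 4))
  invisible(x)
}

#' Intraoperative difference (D) and standardized difference (STD)
#'
#' `D = affected_post - affected_pre` in the indicator's own units;
#' `STD = D - (healthy_post - healthy_pre)`, which removes any drift added
#' equally to both ears between the phases. Absence in any operand
#' propagates.
#'
#' @param pre,post `baep_phase_summary` objects for the pre-resection and
#'   post-resection phases of the same patient.
#' @return Object of class `baep_diff`: list with named vectors `d` and
#'   `std` over [baep_indicators()].
#' @export
compute_differences <- function(pre, post) {
  stopifnot(inherits(pre, "baep_phase_summary"),
            inherits(post, "baep_phase_summary"))
  if (pre$phase != "pre_resection" || post$phase != "post_resection")
    stop_config("compute_differences() needs a pre_resection and a post_resection summary")
  ind <- baep_indicators()
  d <- post$affected[ind] - pre$affected[ind]
  std <- d - (post$healthy[ind] - pre$healthy[ind])
  structure(list(d = stats::setNames(as.numeric(d), ind),
                 std = stats::setNames(as.numeric(std), ind)),
            class = "baep_diff")
}

#' @export
print.baep_diff <- function(x, ...) {
  cat("Intraoperative differences (D) and standardized differences (STD)\n")
  print(round(rbind(d = x$d, std = x$std), 4))
  invisible(x)
}

#' Diagnostic standardized values against a constant normal reference
#'
#' Reports the intermediate quantities behind the STI: the standardized value
#' `(affected / healthy) * reference` and the standardized difference value
#' `reference * STI`, both in the indicator's units. These depend on the
#' chosen constant reference only through a scale factor, which is why the
#' dimensionless STI is the index used downstream.
#'
#' @param summary A `baep_phase_summary`.
#' @param normal_reference Named vector of positive reference values per
#'   indicator.
#' @return Data frame: `indicator`, `standardized_value`,
#'   `standardized_difference`, `sti`.
#' @export
standardized_values <- function(summary, normal_reference) {
  if (any(normal_reference <= 0, na.rm = TRUE))
    stop_config("normal_reference values must be positive")
  sti <- compute_sti(summary)$sti
  ind <- intersect(names(sti), names(normal_reference))
  ref <- normal_reference[ind]
  data.frame(indicator = ind,
             standardized_value = as.numeric((sti[ind] + 1) * ref),
             standardized_difference = as.numeric(ref * sti[ind]),
             sti = as.numeric(sti[ind]),
             row.names = NULL)
}

#' Per-patient standardized indexes from a feature stream
#'
#' Convenience wrapper running the full standardization chain for one
#' patient: split sides, pair synchronous epochs ([pair_streams()]),
#' summarize the pre- and post-resection phases ([summarize_phase()]),
#' compute STI per phase ([compute_sti()]) and D/STD across phases
#' ([compute_differences()]).
#'
#' @param features Data frame of one patient's epochs in the
#'   [cohort_features()] layout (both sides).
#' @param max_interval Pairing tolerance, seconds.
#' @param method Phase representative, `"median"` or `"mean"`.
#' @return One-row data frame: `n_pairs_pre`, `n_pairs_post`, `n_epochs`,
#'   and per indicator `raw_pre_*`, `raw_post_*` (affected-side medians),
#'   `hea_pre_*`, `hea_post_*`, `sti_pre_*`, `sti_post_*`, `d_*`, `std_*`.
#'   Indicators unavailable for a phase are `NA`.
#' @export
standardize_patient <- function(features, max_interval = 180,
                                method = "median") {
  aff <- features[features$side == "affected", , drop = FALSE]
  hea <- features[features$side == "healthy", , drop = FALSE]
  pairs <- pair_streams(aff, hea, max_interval = max_interval)
  pre <- summarize_phase(pairs, "pre_resection", method)
  post <- summarize_phase(pairs, "post_resection", method)

  ind <- baep_indicators()
  na_vec <- stats::setNames(rep(NA_real_, length(ind)), ind)
  grab <- function(x, what) if (is.null(x)) na_vec else x[[what]][ind]
  out <- data.frame(n_pairs_pre = if (is.null(pre)) 0L else pre$n_pairs,
                    n_pairs_post = if (is.null(post)) 0L else post$n_pairs,
                    n_epochs = nrow(features))
  put <- function(out, prefix, v) {
    names(v) <- paste0(prefix, ind)
    cbind(out, as.data.frame(as.list(v)))
  }
  out <- put(out, "raw_pre_", grab(pre, "affected"))
  out <- put(out, "raw_post_", grab(post, "affected"))
  out <- put(out, "hea_pre_", grab(pre, "healthy"))
  out <- put(out, "hea_post_", grab(post, "healthy"))
  out <- put(out, "sti_pre_", if (is.null(pre)) na_vec else compute_sti(pre)$sti)
  out <- put(out, "sti_post_", if (is.null(post)) na_vec else compute_sti(post)$sti)
  if (!is.null(pre) && !is.null(post)) {
    dd <- compute_differences(pre, post)
    out <- put(out, "d_", dd$d)
    out <- put(out, "std_", dd$std)
  } else {
    out <- put(out, "d_", na_vec)
    out <- put(out, "std_", na_vec)
  }
  out
}

#' Standardize every patient of a cohort or feature table
#'
#' @param x A `baep_cohort` or a flat feature table ([cohort_features()]
#'   layout, possibly read with [read_features()]).
#' @param max_interval,method Passed to [standardize_patient()].
#' @return Data frame with one row per patient (`patient_id` first), columns
#'   as in [standardize_patient()].
#' @export
standardize_cohort <- function(x, max_interval = 180, method = "median") {
  features <- if (inherits(x, "baep_cohort")) cohort_features(x) else x
  ids <- unique(features$patient_id)
  rows <- lapply(ids, function(id) {
    one <- standardize_patient(
      features[features$patient_id == id, , drop = FALSE],
      max_interval = max_interval, method = method)
    cbind(patient_id = id, one)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Long-format index table (one row per patient, phase and indicator)
#'
#' @param indices Wide table from [standardize_cohort()].
#' @return Data frame: `patient_id`, `phase`, `indicator`, `raw_affected`,
#'   `raw_healthy`, `sti`, `d`, `std` (`d`/`std` repeated on both phase
#'   rows for convenience).
#' @export
indices_long <- function(indices) {
  ind <- baep_indicators()
  out <- list()
  for (ph in c("pre", "post")) {
    for (v in ind) {
      out[[paste(ph, v)]] <- data.frame(
        patient_id = indices$patient_id,
        phase = paste0(ph, "_resection"),
        indicator = v,
        raw_affected = indices[[paste0("raw_", ph, "_", v)]],
        raw_healthy = indices[[paste0("hea_", ph, "_", v)]],
        sti = indices[[paste0("sti_", ph, "_", v)]],
        d = indices[[paste0("d_", v)]],
        std = indices[[paste0("std_", v)]])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$patient_id, res$phase, res$indicator), ]
}
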