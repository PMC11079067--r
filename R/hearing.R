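## AAO-HNS hearing classification and hearing-preservation (HP) labelling.

#' Classify audiometry into AAO-HNS classes A-D
#'
#' Standard AAO-HNS (1995) thresholds: class A if PTA <= 30 dB and
#' WRS >= 70%; class B if PTA <= 50 dB and WRS >= 50% (and not A); class C if
#' PTA > 50 dB and WRS >= 50%; class D if WRS < 50%. Hearing preservation
#' (HP) is class A-C, which under these thresholds is equivalent to
#' WRS >= 50%. The classes partition the valid (PTA, WRS) space.
#'
#' @param pta Pure tone average, dB (vector; must be in \[0, 150\]).
#' @param wrs Word recognition score, percent (vector in \[0, 100\]).
#' @return Data frame with `aao_class` (factor A-D) and `hp` (logical).
#' @examples
#' classify_aao_hns(c(20, 33.9, 60, 40), c(80, 66, 55, 40))
#' @export
classify_aao_hns <- function(pta, wrs) {
  if (length(pta) != length(wrs))
    stop_config("pta and wrs must have the same length")
  if (any(!is.finite(pta)) || any(pta < 0) || any(pta > 150))
    stop_config("pta values must lie in [0, 150] dB")
  if (any(!is.finite(wrs)) || any(wrs < 0) || any(wrs > 100))
    stop_config("wrs values must lie in [0, 100] %%")
  cls <- ifelse(wrs < 50, "D",
                ifelse(pta > 50, "C",
                       ifelse(pta <= 30 & wrs >= 70, "A", "B")))
  data.frame(aao_class = factor(cls, levels = c("A", "B", "C", "D")),
             hp = wrs >= 50)
}

#' Hearing-outcome table for a cohort
#'
#' Tabulates AAO-HNS class counts and HP rates before and after surgery for
#' the affected ear. Preoperative percentages use all patients as
#' denominator; postoperative percentages use the preoperatively
#' hearing-preserved patients, the subset in whom postoperative hearing is at
#' stake. Percentages are rounded half-up to one decimal.
#'
#' @param hearing Data frame in the [cohort_hearing()] layout (`patient_id`,
#'   `stage`, `pta_db`, `wrs_pct`, optional `side` — only `affected` rows are
#'   used).
#' @return List with `pre` and `post` data frames (`aao_class`, `n`, `pct`),
#'   `n_patients`, `n_preop_hp`, `preop_hp_rate_pct`, `n_postop_hp`,
#'   `postop_hp_rate_pct` (denominator: preop-HP patients) and
#'   `postop_hp_rate_overall_pct` (denominator: all patients).
#' @export
outcome_table <- function(hearing) {
  if (!is.null(hearing$side))
    hearing <- hearing[hearing$side == "affected", , drop = FALSE]
  pre <- hearing[hearing$stage == "pre", , drop = FALSE]
  post <- hearing[hearing$stage == "post", , drop = FALSE]
  if (!nrow(pre)) stop_config("every patient needs preoperative audiometry")

  cls_pre <- classify_aao_hns(pre$pta_db, pre$wrs_pct)
  n <- nrow(pre)
  hp_ids <- pre$patient_id[cls_pre$hp]
  post <- post[post$patient_id %in% hp_ids, , drop = FALSE]
  cls_post <- classify_aao_hns(post$pta_db, post$wrs_pct)
  n_hp_pre <- length(hp_ids)

  tab <- function(cls, denom) {
    cnt <- table(cls$aao_class)
    data.frame(aao_class = names(cnt), n = as.integer(cnt),
               pct = round_half_up(100 * as.integer(cnt) / denom, 1))
  }
  n_hp_post <- sum(cls_post$hp)
  list(pre = tab(cls_pre, n),
       post = tab(cls_post, max(n_hp_pre, 1L)),
       n_patients = n,
       n_preop_hp = n_hp_pre,
       preop_hp_rate_pct = round_half_up(100 * n_hp_pre / n, 1),
       n_postop_hp = n_hp_post,
       postop_hp_rate_pct = round_half_up(100 * n_hp_post / max(n_hp_pre, 1L), 1),
       postop_hp_rate_overall_pct = round_half_up(100 * n_hp_post / n, 1))
}

#' Per-patient HP labels for the affected ear
#'
#' @param hearing Data frame in the [cohort_hearing()] layout.
#' @return Data frame: `patient_id`, `hp_pre`, `hp_post`, `class_pre`,
#'   `class_post`.
#' @export
hp_labels <- function(hearing) {
  if (!is.null(hearing$side))
    hearing <- hearing[hearing$side == "affected", , drop = FALSE]
  pre <- hearing[hearing$stage == "pre", , drop = FALSE]
  post <- hearing[hearing$stage == "post", , drop = FALSE]
  cp <- classify_aao_hns(pre$pta_db, pre$wrs_pct)
  co <- classify_aao_hns(post$pta_db, post$wrs_pct)
  pre_lab <- data.frame(patient_id = pre$patient_id,
                        hp_pre = cp$hp, class_pre = cp$aao_class)
  post_lab <- data.frame(patient_id = post$patient_id,
                         hp_post = co$hp, class_post = co$aao_class)
  merge(pre_lab, post_lab, by = "patient_id", all.x = TRUE)
}
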