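# The two bench formulas of the experimental arm, in vectorized form.

#' Sucrose preference percentage from bottle weights
#'
#' `100 * (w1 - w3) / ((w1 - w3) + (w2 - w4))`: sucrose consumed as a
#' percentage of total fluid consumed, where `w1`/`w2` are the sucrose and
#' water bottle weights before the test and `w3`/`w4` after. All arguments
#' recycle; consumption must be non-negative with a positive total.
#'
#' @param w1,w3 sucrose bottle weight before/after (g).
#' @param w2,w4 water bottle weight before/after (g).
#' @return preference percentage in [0, 100].
#' @export
sucrose_preference <- function(w1, w2, w3, w4) {
  sucrose_preference_consumed(w1 - w3, w2 - w4)
}

#' Sucrose preference percentage from consumed amounts
#'
#' Consumption form of [sucrose_preference()]:
#' `100 * sucrose / (sucrose + water)`.
#'
#' @param sucrose sucrose solution consumed (g), `>= 0`.
#' @param water water consumed (g), `>= 0`.
#' @return preference percentage in [0, 100].
#' @export
sucrose_preference_consumed <- function(sucrose, water) {
  if (any(!is.finite(sucrose)) || any(!is.finite(water))) {
    stop("consumption values must be finite")
  }
  if (any(sucrose < 0) || any(water < 0)) {
    stop("negative consumption: bottle weight after exceeds weight before")
  }
  total <- sucrose + water
  if (any(total <= 0)) stop("zero total consumption: preference is undefined")
  100 * sucrose / total
}

#' Relative expression by the 2^-ddCt method
#'
#' `dCt_treated = ct_target_treated - ct_ref_treated`;
#' `dCt_control = ct_target_control - ct_ref_control`;
#' `ddCt = dCt_treated - dCt_control`; returns `2^(-ddCt)`.
#' The reference gene is whatever Ct series is supplied; the function takes
#' no position on its identity. All arguments recycle.
#'
#' @param ct_target_treated,ct_ref_treated Ct of target and reference gene
#'   in the treated sample.
#' @param ct_target_control,ct_ref_control Ct of target and reference gene
#'   in the control sample.
#' @return fold change, `> 0`; 1 when expression is unchanged.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Batch sucrose-preference computation
#'
#' Adds an `spt` column to a table of replicate bottle weights and, when a
#' `group` column is present, attaches a per-group summary (mean and SEM)
#' as attribute `"summary"`. Group-level significance testing is left to
#' standard ANOVA/posthoc routines.
#'
#' @param df data frame with columns `w1`, `w2`, `w3`, `w4` and optionally
#'   `group`.
#' @return the input tibble with an `spt` column.
#' @export
spt_batch <- function(df) {
  miss <- setdiff(c("w1", "w2", "w3", "w4"), names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- tibble::as_tibble(df)
  out$spt <- sucrose_preference(df$w1, df$w2, df$w3, df$w4)
  if ("group" %in% names(out)) {
    attr(out, "summary") <- group_summary(out, "spt")
  }
  out
}

#' Batch 2^-ddCt computation
#'
#' @param df data frame with columns `ct_target_treated`, `ct_ref_treated`,
#'   `ct_target_control`, `ct_ref_control` and optionally `group`.
#' @return the input tibble with a `fold_change` column; per-group mean/SEM
#'   in attribute `"summary"` when a `group` column is present.
#' @export
ddct_batch <- function(df) {
  need <- c("ct_target_treated", "ct_ref_treated",
            "ct_target_control", "ct_ref_control")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- tibble::as_tibble(df)
  out$fold_change <- ddct_fold_change(df$ct_target_treated, df$ct_ref_treated,
                                      df$ct_target_control, df$ct_ref_control)
  if ("group" %in% names(out)) {
    attr(out, "summary") <- group_summary(out, "fold_change")
  }
  out
}

# Internal: per-group mean and standard error of one column.
group_summary <- function(df, col) {
  groups <- split(df[[col]], df$group)
  tibble::tibble(
    group = names(groups),
    n = unname(vapply(groups, length, integer(1))),
    mean = unname(vapply(groups, mean, numeric(1))),
    sem = unname(vapply(groups, function(x) {
      if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
    }, numeric(1)))
  )
}
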