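## Chemical descriptors. Descriptors are ingested from a table (they come
## from dedicated cheminformatics software); only the neutral fraction
## N(pKa) and an optional logD estimate are derived here.

#' Neutral fraction of a base at a given pH
#'
#' Henderson-Hasselbalch rearrangement for a monoprotic base:
#' `N(pKa) = 10^pH / (10^pH + 10^pKa)`. At `pKa = pH` half the molecules
#' are neutral; the fraction falls with pKa and rises with pH. The
#' formula does not apply to acids, whose charged form appears at low
#' pKa instead.
#'
#' @param pKa acidic dissociation constant of the conjugate acid.
#' @param pH medium pH (default 7.3, the recording-solution pH).
#' @return Neutral fraction in (0, 1); vectorized.
#' @export
#' @examples
#' neutral_fraction(7.3)       # 0.5
#' neutral_fraction(9.3)       # ~0.0099: mostly protonated
neutral_fraction <- function(pKa, pH = 7.3) {
  stopifnot(all(is.finite(pKa)), all(is.finite(pH)))
  10^pH / (10^pH + 10^pKa)
}

#' Base-10 log of the neutral fraction
#'
#' Computed on the log scale directly for numerical stability at high
#' pKa, where `N(pKa)` underflows.
#'
#' @inheritParams neutral_fraction
#' @return `log10(N(pKa))`; vectorized.
#' @export
log_neutral_fraction <- function(pKa, pH = 7.3) {
  stopifnot(all(is.finite(pKa)), all(is.finite(pH)))
  ## log10(10^pH / (10^pH + 10^pKa)) = -log10(1 + 10^(pKa - pH));
  ## for large pKa - pH the term 10^x overflows but the limit is -x
  x <- pKa - pH
  ifelse(x > 30, -x, -log1p(10^pmin(x, 30)) / log(10))
}

#' Estimate logD from logP and pKa (base behaviour)
#'
#' For a monoprotic base only the neutral fraction partitions into
#' octanol, so `logD = logP + log10 N(pKa)`; the estimate approaches
#' logP from below as the molecule becomes predominantly neutral. Meant
#' as a fallback when a measured logD is absent from the descriptor
#' table, and flagged as an estimate by the ingestion step.
#'
#' @param logP octanol-water partition coefficient of the neutral form.
#' @param pKa dissociation constant of the conjugate acid.
#' @param pH medium pH.
#' @return Estimated logD at `pH`.
#' @export
estimate_logD <- function(logP, pKa, pH = 7.3) {
  logP + log_neutral_fraction(pKa, pH)
}

#' Validate and complete a chemical descriptor table
#'
#' Recomputes the neutral fraction from pKa and cross-checks it against a
#' supplied `n_pka` column (warning beyond 1e-3 relative disagreement).
#' Fills `n_pka` where absent. Drugs flagged as acids (optional logical
#' `acid` column) are outside the scope of the base-form
#' Henderson-Hasselbalch rearrangement: their table values are kept
#' untouched and `acid_flagged` is set. A missing `logD7_3` is filled
#' with [estimate_logD()] and flagged in `logD_estimated`.
#'
#' @param table data.frame in [read_descriptors()] layout.
#' @param pH pH for the neutral-fraction computation.
#' @return The table with `n_pka`, `log_n_pka`, `acid_flagged` and
#'   `logD_estimated` columns completed.
#' @export
validate_descriptors <- function(table, pH = 7.3) {
  stopifnot(is.data.frame(table))
  df <- table
  df$acid_flagged <- if ("acid" %in% names(df)) df$acid %in% c(TRUE, "TRUE", 1)
                     else rep(FALSE, nrow(df))
  base <- !df$acid_flagged & !is.na(df$pKa)
  n_calc <- ifelse(base, neutral_fraction(df$pKa, pH), NA_real_)
  if ("n_pka" %in% names(df)) {
    have <- base & !is.na(df$n_pka)
    off <- have & abs(df$n_pka - n_calc) > 1e-3 * pmax(n_calc, .Machine$double.eps)
    if (any(off))
      .warnf("n_pka inconsistent with pKa for: %s",
             paste(df$drug_code[off], collapse = ", "))
    df$n_pka[base & is.na(df$n_pka)] <- n_calc[base & is.na(df$n_pka)]
  } else {
    df$n_pka <- n_calc
  }
  df$log_n_pka <- ifelse(base, log_neutral_fraction(df$pKa, pH), log10(df$n_pka))
  if (!"logD7_3" %in% names(df)) df$logD7_3 <- NA_real_
  fill <- base & is.na(df$logD7_3) & !is.na(df$logP)
  df$logD_estimated <- fill
  df$logD7_3[fill] <- estimate_logD(df$logP[fill], df$pKa[fill], pH)
  df
}
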