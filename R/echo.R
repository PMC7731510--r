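#' Derived echocardiographic volumes and function
#'
#' From M-mode left-ventricle internal dimensions at diastole (`lvidd`, mm)
#' and systole (`lvids`, mm) and heart rate (`hr`, beats/min), derives:
#' \itemize{
#'   \item EDV, ESV (microlitres) by the Teichholz cube-corrected formula
#'     \eqn{V = 7.0\,D^3 / (2.4 + D)};
#'   \item ejection fraction \eqn{EF = (LVIDd^3 - LVIDs^3) \times 100 / LVIDd^3} (percent);
#'   \item cardiac output \eqn{CO = (EDV - ESV) \times HR} (microlitres/min).
#' }
#' `formula = "printed"` switches the volume formula to the literal variant
#' \eqn{(7.0 + D^3)/(2.4 + D)} sometimes seen in print, kept for
#' auditability; EF and CO structure are unchanged.
#'
#' @param lvidd,lvids diastolic and systolic LV internal diameter, mm;
#'   vectors are recycled element-wise. Requires `0 <= lvids <= lvidd`,
#'   `lvidd > 0`.
#' @param hr heart rate, beats/min, `> 0`.
#' @param formula `"teichholz"` (default) or `"printed"`.
#' @return data.frame with `lvidd`, `lvids`, `hr`, `edv`, `esv`, `ef`, `co`.
#' @export
echo_derive <- function(lvidd, lvids, hr, formula = c("teichholz", "printed")) {
  formula <- match.arg(formula)
  n <- max(length(lvidd), length(lvids), length(hr))
  lvidd <- rep_len(as.numeric(lvidd), n)
  lvids <- rep_len(as.numeric(lvids), n)
  hr <- rep_len(as.numeric(hr), n)
  if (anyNA(lvidd) || anyNA(lvids) || anyNA(hr)) stop("inputs must be finite")
  if (any(lvidd <= 0)) stop("lvidd must be positive")
  if (any(lvids < 0)) stop("lvids must be nonnegative")
  if (any(lvids > lvidd)) stop("lvids must not exceed lvidd")
  if (any(hr <= 0)) stop("hr must be positive")
  vol <- if (formula == "teichholz") function(d) 7.0 * d^3 / (2.4 + d)
         else function(d) (7.0 + d^3) / (2.4 + d)
  edv <- vol(lvidd)
  esv <- vol(lvids)
  ef <- (lvidd^3 - lvids^3) * 100 / lvidd^3
  data.frame(lvidd = lvidd, lvids = lvids, hr = hr,
             edv = edv, esv = esv, ef = ef, co = (edv - esv) * hr)
}

#' Aggregate blinded immunohistochemistry rater scores into a grade
#'
#' Each rater scores a marker 0 (no/low expression), 1 (moderate) or
#' 2 (high). The mean score maps to an ordinal grade:
#' `-` iff the mean is exactly 0; `+` for means in `(0, 2/3]`;
#' `++` for `(2/3, 4/3]`; `+++` above `4/3`. Boundaries are compared as
#' exact rationals (`3*sum` vs `2*n` and `4*n`), so a mean of exactly
#' two-thirds never misgrades through floating point.
#'
#' @param scores integer vector of rater scores, each in `{0, 1, 2}`.
#' @param n_raters expected number of raters (default 3).
#' @return list with `scores`, `mean` (numeric), `grade`
#'   (ordered factor with levels `-`, `+`, `++`, `+++`).
#' @export
aggregate_scores <- function(scores, n_raters = 3L) {
  if (length(scores) != n_raters)
    stop("expected ", n_raters, " rater scores, got ", length(scores))
  if (anyNA(scores) || !all(scores %in% c(0L, 1L, 2L)))
    stop("each rater score must be 0, 1 or 2")
  s <- sum(as.integer(scores))
  n <- as.integer(n_raters)
  grade <- if (s == 0L) "-"
           else if (3L * s <= 2L * n) "+"
           else if (3L * s <= 4L * n) "++"
           else "+++"
  list(scores = as.integer(scores), mean = s / n,
       grade = factor(grade, levels = c("-", "+", "++", "+++"), ordered = TRUE))
}
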