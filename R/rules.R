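# Clinical decision primitives used by the laboratory trigger module.

#' Drug-induced liver injury pattern (R ratio)
#'
#' Computes the R ratio `(ALT/ALT_ULN) / (ALP/ALP_ULN)` and classifies the
#' injury pattern: hepatocellular when ALT >= 3 ULN and R >= 5; cholestatic
#' when ALP >= 2 ULN and R <= 2; mixed when both enzyme criteria hold and
#' 2 < R < 5; otherwise none. The hepatic laboratory trigger fires whenever
#' the pattern is not `"none"`.
#'
#' @param alt,alp Measured ALT and ALP, U/L.
#' @param alt_uln,alp_uln Upper limits of normal, U/L (defaults 40 and 150).
#' @return A list with `r_value` and `pattern`.
#' @examples
#' liver_injury_rule(150, 80, 40, 150) # hepatocellular, R = 7.03
#' @export
liver_injury_rule <- function(alt, alp, alt_uln = 40, alp_uln = 150) {
  vals <- c(alt = alt, alp = alp, alt_uln = alt_uln, alp_uln = alp_uln)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("liver_injury_rule: all inputs must be positive and finite",
         call. = FALSE)
  }
  r <- (alt / alt_uln) / (alp / alp_uln)
  hep <- alt >= 3 * alt_uln
  chol <- alp >= 2 * alp_uln
  pattern <- if (hep && r >= 5) {
    "hepatocellular"
  } else if (chol && r <= 2) {
    "cholestatic"
  } else if (hep && chol && r > 2 && r < 5) {
    "mixed"
  } else {
    "none"
  }
  list(r_value = r, pattern = pattern)
}

#' Acute kidney injury rule
#'
#' Evaluates the three-part AKI screen over a creatinine series and a urine
#' output series: (a) serum creatinine rise >= 0.3 mg/dL within 48 h
#' (compared against the minimum value in the preceding 48 h window);
#' (b) creatinine >= 1.5 x baseline within seven days of baseline (baseline
#' is the earliest value flagged as baseline, else the earliest value);
#' (c) urine output below 0.5 mL/kg/h sustained for more than 6 h. Returns
#' every time at which any branch first becomes true.
#'
#' @param scr_series Data frame (or tibble) with columns `time` (hours) and
#'   `value` (mg/dL), optionally `is_baseline`; may be empty or `NULL`.
#' @param urine_series Data frame with columns `time` (hours) and `value`
#'   (mL/kg/h); interpreted as a step function between consecutive points.
#' @return Sorted numeric vector of qualifying times (hours); empty when
#'   neither series qualifies.
#' @export
aki_rule <- function(scr_series = NULL, urine_series = NULL) {
  times <- numeric()
  if (!is.null(scr_series) && nrow(as.data.frame(scr_series)) > 0) {
    s <- as.data.frame(scr_series)
    s <- s[order(s$time), , drop = FALSE]
    if (is.null(s$is_baseline)) s$is_baseline <- FALSE
    base_idx <- which(s$is_baseline)[1]
    if (is.na(base_idx)) base_idx <- 1L
    baseline <- s$value[base_idx]
    base_time <- s$time[base_idx]
    for (i in seq_len(nrow(s))) {
      t <- s$time[i]; v <- s$value[i]
      prior <- s$value[s$time >= t - 48 & s$time < t]
      if (length(prior) && v - min(prior) >= 0.3) {
        times <- c(times, t)
        next
      }
      if (t >= base_time && t <= base_time + 7 * 24 && baseline > 0 &&
          v >= 1.5 * baseline && i != base_idx) {
        times <- c(times, t)
      }
    }
  }
  if (!is.null(urine_series) && nrow(as.data.frame(urine_series)) > 0) {
    u <- as.data.frame(urine_series)
    u <- u[order(u$time), , drop = FALSE]
    run_start <- NA_real_
    for (i in seq_len(nrow(u))) {
      if (u$value[i] < 0.5) {
        if (is.na(run_start)) run_start <- u$time[i]
        run_end <- if (i < nrow(u)) u$time[i + 1] else u$time[i]
        if (run_end - run_start > 6) {
          times <- c(times, run_start + 6)
          break
        }
      } else {
        run_start <- NA_real_
      }
    }
  }
  sort(unique(times))
}
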