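#' Read a long-format plate table
#'
#' Tab-separated columns: `well`, `id`, `role`, `replicate`, `time_s`,
#' `absorbance`. Roles: `sample`, `negative_control`, `no_substrate`,
#' `no_xo`, `no_sod`, `blank`, `wildtype`.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
readPlate <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("well", "id", "role", "replicate", "time_s", "absorbance")
  if (!all(need %in% names(df)))
    stop("plate table must have columns: ", paste(need, collapse = ", "))
  roles <- c("sample", "negative_control", "no_substrate", "no_xo", "no_sod",
             "blank", "wildtype")
  bad <- setdiff(unique(df$role), roles)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  for (w in unique(df$well)) {
    t <- df$time_s[df$well == w]
    if (is.unsorted(t, strictly = TRUE))
      stop("timepoints not strictly increasing in well ", w)
  }
  df
}

#' NADH concentration from absorbance at 340 nm
#'
#' Beer-Lambert conversion `c = A / (d * epsilon)` with the NADH extinction
#' coefficient 6.22 per mM per cm and the 0.29 cm path length of 100 ul in a
#' 96-well plate.
#'
#' @param absorbance non-negative absorbance value(s) at 340 nm.
#' @param epsilon extinction coefficient, default 6.22 mM^-1 cm^-1.
#' @param pathLength optical path in cm, default 0.29.
#' @return concentration in mM.
#' @examples
#' nadhConcentration(1.80)  # ~0.998 mM
#' @export
nadhConcentration <- function(absorbance, epsilon = 6.22, pathLength = 0.29) {
  if (any(absorbance < 0)) stop("absorbance must be non-negative")
  absorbance / (pathLength * epsilon)
}

#' MDH activity call from endpoint absorbances
#'
#' A sample is called active when its endpoint absorbance (NADH remaining)
#' is significantly lower than the negative control's: one-sided Welch
#' t-test, sample < control, at level `alpha`.
#'
#' @param sampleEndpoints,negativeEndpoints endpoint absorbances,
#'   >= 2 replicates each.
#' @param alpha significance level, default 0.05.
#' @return list with `active`, `p`, `t`.
#' @export
mdhActivityCall <- function(sampleEndpoints, negativeEndpoints, alpha = 0.05) {
  if (length(sampleEndpoints) < 2L || length(negativeEndpoints) < 2L)
    stop("need at least 2 replicates per group")
  fit <- welchTTest(sampleEndpoints, negativeEndpoints, alternative = "less")
  list(active = fit$p <= alpha, p = fit$p, t = fit$t)
}

#' SOD inhibition rate
#'
#' `((A - B) - (C - D)) / (A - B) * 100`, where A is the no-SOD control, B
#' the blank, C the sample and D the no-xanthine-oxidase control (absorbance
#' at 450 nm, conventionally at the 20 min timepoint). Values outside
#' \[0, 100\] are reported as-is with `out_of_range = TRUE`.
#'
#' @param A_noSOD,B_blank,C_sample,D_noXO absorbance values.
#' @return list with `percent` and `out_of_range`.
#' @examples
#' sodInhibition(1.0, 0.1, 0.4, 0.1)$percent  # 66.67
#' @export
sodInhibition <- function(A_noSOD, B_blank, C_sample, D_noXO) {
  if (A_noSOD <= B_blank)
    stop("degenerate assay: no-SOD signal not above blank (A <= B)")
  pct <- ((A_noSOD - B_blank) - (C_sample - D_noXO)) / (A_noSOD - B_blank) * 100
  list(percent = pct, out_of_range = pct < 0 || pct > 100)
}

#' SOD activity call from inhibition rates
#'
#' Active when the per-replicate inhibition rate is significantly higher
#' than the negative control's (one-sided Welch t-test at `alpha`).
#'
#' @param sampleRates,negativeRates inhibition rates (%), >= 2 replicates.
#' @param alpha significance level, default 0.05.
#' @return list with `active`, `p`, `t`.
#' @export
sodActivityCall <- function(sampleRates, negativeRates, alpha = 0.05) {
  if (length(sampleRates) < 2L || length(negativeRates) < 2L)
    stop("need at least 2 replicates per group")
  fit <- welchTTest(sampleRates, negativeRates, alternative = "greater")
  list(active = fit$p <= alpha, p = fit$p, t = fit$t)
}

# per-replicate concentration drop (uM) between t = 0 and t = 90 s,
# after no-substrate subtraction and the 275 uM floor substitution
mdhDeltaConc <- function(series, negativeSeries = NULL, noSubstrateSeries = NULL,
                         floor_uM = 275) {
  need <- c("replicate", "time_s", "absorbance")
  stopifnot(all(need %in% names(series)))
  if (!all(c(0, 90) %in% series$time_s))
    stop("MDH mode requires absorbance at the 0 s and 90 s timepoints")
  adj <- series
  if (!is.null(noSubstrateSeries)) {
    # unspecific NADH oxidation: subtract the no-substrate control mean,
    # per timepoint, before anything else
    ns <- tapply(noSubstrateSeries$absorbance, noSubstrateSeries$time_s, mean)
    adj$absorbance <- adj$absorbance -
      as.numeric(ns[as.character(adj$time_s)])
  }
  conc <- nadhConcentration(pmax(adj$absorbance, 0)) * 1000  # mM -> uM
  reps <- sort(unique(adj$replicate))
  neg0 <- NA_real_
  if (!is.null(negativeSeries)) {
    n0 <- negativeSeries$absorbance[negativeSeries$time_s == 0]
    neg0 <- mean(nadhConcentration(n0) * 1000)
  }
  vapply(reps, function(r) {
    i0 <- which(adj$replicate == r & adj$time_s == 0)
    i90 <- which(adj$replicate == r & adj$time_s == 90)
    c0 <- conc[i0]
    # fast enzymes exhaust NADH before the first read; substitute the
    # negative-control mean so the drop is not underestimated
    if (c0 < floor_uM) {
      if (is.na(neg0))
        stop("t0 concentration below ", floor_uM,
             " uM but no negative-control series supplied")
      c0 <- neg0
    }
    c0 - conc[i90]
  }, numeric(1))
}

#' Wild-type-normalised specific activity
#'
#' MDH mode: per replicate, the NADH concentration drop between the 0 and
#' 90 s timepoints (after subtracting the no-substrate control per timepoint
#' and substituting the negative-control mean for t0 values below the
#' `floor_uM` floor), averaged over replicates and divided by the wild-type
#' mean computed the same way. SOD mode: the replicate-mean inhibition rate
#' at the 20 min timepoint divided by the wild-type mean.
#'
#' @param series long data.frame for the sample (columns `replicate`,
#'   `time_s`, `absorbance`; SOD mode instead needs per-replicate
#'   `inhibition` values, see Details).
#' @param wildtypeSeries same shape, for the wild-type control(s).
#' @param mode `"mdh"` or `"sod"`.
#' @param negativeSeries negative-control series (required for the MDH floor
#'   rule to fire).
#' @param noSubstrateSeries optional no-substrate control series (MDH mode).
#' @param floor_uM t0 substitution floor in uM, default 275.
#' @details In SOD mode `series` and `wildtypeSeries` are data.frames with a
#'   column `inhibition` (one row per replicate), as produced by
#'   [sodInhibition()] applied per replicate at 20 min.
#' @return list with `activity` (normalised, wild type = 1), `raw`
#'   (replicate mean before normalisation), `per_replicate`.
#' @export
specificActivity <- function(series, wildtypeSeries, mode = c("mdh", "sod"),
                             negativeSeries = NULL, noSubstrateSeries = NULL,
                             floor_uM = 275) {
  mode <- match.arg(mode)
  if (mode == "mdh") {
    d <- mdhDeltaConc(series, negativeSeries, noSubstrateSeries, floor_uM)
    w <- mdhDeltaConc(wildtypeSeries, negativeSeries, noSubstrateSeries,
                      floor_uM)
  } else {
    stopifnot("inhibition" %in% names(series),
              "inhibition" %in% names(wildtypeSeries))
    d <- series$inhibition
    w <- wildtypeSeries$inhibition
  }
  wt <- mean(w)
  if (wt == 0) stop("wild-type mean activity is zero; cannot normalise")
  list(activity = mean(d) / wt, raw = mean(d), per_replicate = d)
}
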