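#' Age-band z-score standardization of an exposure
#'
#' Standardizes a raw exposure internally within 5-year age bands: within each
#' band `[20,25), [25,30), ..., [75,80), [80,Inf)` the z-score is
#' `(x - band mean) / band SD`, with the sample SD (divisor n-1). Effects
#' estimated on the standardized exposure are then per SD of exposure.
#'
#' Bands with fewer than `min_band` members, or with zero spread, cannot be
#' standardized; by default they are merged into the nearest populated band
#' (by band index; adjacent larger band preferred) with a warning. The merge
#' repeats until every remaining band is usable.
#'
#' @param values numeric raw exposure (e.g. serum uric acid, umol/L).
#' @param ages numeric ages in years; must all be `>= band_start`.
#' @param band_width width of the age bands in years (default 5).
#' @param band_start left edge of the first band (default 20); ages at or
#'   above `band_top` are pooled into one top band.
#' @param band_top lower edge of the open-ended top band (default 80).
#' @param min_band minimum band size (default 2).
#' @param policy what to do with degenerate bands: `"merge"` (default) or
#'   `"error"`.
#' @return numeric vector of z-scores, with the final band assignment in
#'   attribute `"band"`.
#' @export
standardize_exposure <- function(values, ages, band_width = 5, band_start = 20,
                                 band_top = 80, min_band = 2L,
                                 policy = c("merge", "error")) {
  policy <- match.arg(policy)
  stopifnot(length(values) == length(ages))
  if (anyNA(values) || anyNA(ages)) stop("standardize_exposure(): NA in values or ages")
  if (any(ages < band_start)) {
    stop(sprintf("standardize_exposure(): age below band start (%g)", band_start))
  }
  breaks <- c(seq(band_start, band_top, by = band_width), Inf)
  band <- findInterval(ages, breaks, rightmost.closed = FALSE)

  repeat {
    sizes <- tapply(values, band, length)
    spreads <- tapply(values, band, stats::sd)
    ids <- as.integer(names(sizes))
    bad <- ids[sizes < min_band | spreads == 0 | is.na(spreads)]
    if (!length(bad)) break
    if (length(ids) <= 1L) {
      stop("standardize_exposure(): all values collapse to a single degenerate band")
    }
    if (policy == "error") {
      stop(sprintf("standardize_exposure(): degenerate age band(s): %s",
                   paste(bad, collapse = ", ")))
    }
    b <- bad[1L]
    good <- setdiff(ids, b)
    d <- abs(good - b)
    cand <- good[d == min(d)]
    # prefer the larger neighbouring band on ties
    tgt <- cand[which.max(sizes[as.character(cand)])]
    warning(sprintf("standardize_exposure(): merging degenerate age band %d into band %d",
                    b, tgt))
    band[band == b] <- tgt
  }

  z <- numeric(length(values))
  for (b in unique(band)) {
    idx <- band == b
    m <- mean(values[idx])
    s <- stats::sd(values[idx])
    z[idx] <- (values[idx] - m) / s
  }
  attr(z, "band") <- band
  z
}

#' Incidence density per 1000 person-years
#'
#' @param events number of incident events.
#' @param person_years total person-time at risk, in years.
#' @return events per 1000 person-years.
#' @examples
#' incidence_density(10, 500) # 20
#' @export
incidence_density <- function(events, person_years) {
  if (!is.numeric(person_years) || person_years <= 0) {
    stop("incidence_density(): person_years must be > 0")
  }
  if (events < 0) stop("incidence_density(): events must be >= 0")
  1000 * events / person_years
}
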