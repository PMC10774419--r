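#' Engine-power equivalence of the unmotorized fleet
#'
#' Effort is expressed in engine power, so unmotorized vessels need a kW
#' equivalent for oar and sail. During early motorization the catch per kW
#' of the whole artisanal fleet is assumed stable, making total artisanal
#' catch proportional to `NV_unmotorized * PPV_eq + P_motorized`. The
#' proportionality is resolved as the no-intercept least-squares fit
#' `Catch_y = a NV_y + b P_y`, and `PPV_eq = a / b` cancels the unknown
#' catchability. Only years in which the unmotorized fleet makes up 20-80\%
#' (closed interval) of the artisanal vessel count are used: newly motorized
#' vessels are over-used early on, and unmotorized craft under-used late.
#'
#' @param catch Tibble `year`, `catch`: total artisanal catch (landings +
#'   discards + IUU), tonnes.
#' @param nv_unmotor Tibble `year`, `n_vessels` for the unmotorized fleet.
#' @param nv_motor Tibble `year`, `n_vessels` for the motorized artisanal
#'   fleet (needed to form the motorization share the selection window is
#'   defined on).
#' @param p_motor Tibble `year`, `p_total`: total motorized artisanal engine
#'   power, kW.
#' @param window Closed share window, default `c(0.2, 0.8)`.
#' @return A `motor_equivalence` list: `ppv_eq` (kW per unmotorized vessel),
#'   `years_used`, `window`, and the raw coefficients `a`, `b`.
#' @export
solve_motor_equivalence <- function(catch, nv_unmotor, nv_motor, p_motor,
                                    window = c(0.2, 0.8)) {
  years <- Reduce(intersect, list(catch$year, nv_unmotor$year,
                                  nv_motor$year, p_motor$year))
  nvu <- nv_unmotor$n_vessels[match(years, nv_unmotor$year)]
  nvm <- nv_motor$n_vessels[match(years, nv_motor$year)]
  p <- p_motor$p_total[match(years, p_motor$year)]
  ca <- catch$catch[match(years, catch$year)]
  share <- nvu / (nvu + nvm)
  sel <- is.finite(share) & share >= window[1] & share <= window[2] &
    nvu > 0 & p > 0
  if (sum(sel) < 2) {
    stop("insufficient motorization overlap: fewer than 2 years with ",
         "unmotorized share inside [", window[1], ", ", window[2], "]")
  }
  f <- lm(ca[sel] ~ 0 + nvu[sel] + p[sel])
  a <- unname(coef(f)[1]); b <- unname(coef(f)[2])
  ppv <- a / b
  if (!is.finite(ppv) || ppv <= 0) {
    stop("negative or undefined fitted power equivalence (a = ",
         signif(a, 4), ", b = ", signif(b, 4),
         "); consider widening the share window")
  }
  structure(list(ppv_eq = ppv, years_used = years[sel], window = window,
                 a = a, b = b),
            class = "motor_equivalence")
}

#' Nominal fishing effort of a fleet segment
#'
#' `Eff_Nom = P * DAS * R_act`, in kW x days at sea: total engine power of
#' the segment, times days at sea per year, times the ratio of active
#' vessels to total capacity.
#'
#' @param p Total engine power, kW (>= 0).
#' @param das Days at sea per year (>= 0).
#' @param r_act Activity ratio in `[0, 1]`; the fleet-wide mean 0.72 is used
#'   for countries with no activity data (see [default_activity_ratio()]).
#' @return Nominal effort in kW x days; vectorized.
#' @export
nominal_effort <- function(p, das, r_act = default_activity_ratio()) {
  if (any(p < 0) || any(das < 0) || any(r_act < 0)) {
    stop("effort factors must be non-negative")
  }
  if (any(r_act > 1)) stop("activity ratio greater than 1")
  p * das * r_act
}

#' Look up days at sea with similar-segment fallback
#'
#' An exact (country, sector, gear, year) match is preferred; otherwise the
#' key is relaxed in a fixed order - drop year, then drop gear, then drop
#' country (regional/global mean) - and the mean of the surviving rows is
#' used. The provenance of the value records which fallback fired.
#'
#' @param saup,sector,gear,year Segment key.
#' @param das_table Tibble `saup`, `sector`, `gear`, `year`, `das`, and
#'   optionally `r_act`.
#' @return List `das`, `r_act` (`NA` if absent everywhere), `provenance`
#'   (one of `"exact"`, `"segment"`, `"country"`, `"region"`).
#' @export
fill_days_at_sea <- function(saup, sector, gear, year, das_table) {
  if (nrow(das_table) == 0) stop("empty days-at-sea table")
  take <- function(d, prov) {
    list(das = mean(d$das),
         r_act = if ("r_act" %in% names(d) && any(!is.na(d$r_act))) {
           mean(d$r_act, na.rm = TRUE)
         } else NA_real_,
         provenance = prov)
  }
  d <- das_table[das_table$saup == saup & das_table$sector == sector &
                   das_table$gear == gear & das_table$year == year, ]
  if (nrow(d) > 0) return(take(d, "exact"))
  d <- das_table[das_table$saup == saup & das_table$sector == sector &
                   das_table$gear == gear, ]
  if (nrow(d) > 0) return(take(d, "segment"))
  d <- das_table[das_table$saup == saup & das_table$sector == sector, ]
  if (nrow(d) > 0) return(take(d, "country"))
  d <- das_table[das_table$sector == sector, ]
  if (nrow(d) > 0) return(take(d, "region"))
  take(das_table, "region")
}

#' Estimate technological creep from a CPUE series
#'
#' Technological creep is the biomass-independent annual increase in catch
#' per unit effort. It is estimated as `c = exp(slope) - 1` from the
#' least-squares regression of log CPUE on year; when a biomass index is
#' supplied, log biomass enters the regression as a covariate so the year
#' trend is purged of stock effects (without one, the raw log-CPUE trend is
#' used and labelled as such). Sector defaults of 1.4\%/yr (industrial) and
#' 5\%/yr (artisanal) from [default_creep_rates()] apply when estimation is
#' impossible.
#'
#' @param year Years.
#' @param cpue Catch per kW; non-positive values are dropped with a warning.
#' @param biomass_index Optional positive biomass index per year.
#' @return A `creep_model` list: `rate` (fraction/yr), `baseline_year`
#'   (1949), `n_years`, `biomass_adjusted`.
#' @export
estimate_creep <- function(year, cpue, biomass_index = NULL) {
  keep <- is.finite(cpue) & cpue > 0
  if (any(!keep)) {
    warning(sum(!keep), " non-positive CPUE value(s) dropped")
  }
  if (sum(keep) < 5) stop("fewer than 5 positive CPUE years")
  y <- year[keep]; lc <- log(cpue[keep])
  if (!is.null(biomass_index)) {
    b <- biomass_index[keep]
    if (any(b <= 0)) stop("biomass index must be positive")
    f <- lm(lc ~ y + log(b))
  } else {
    f <- lm(lc ~ y)
  }
  creep_model(exp(unname(coef(f)["y"])) - 1,
              n_years = sum(keep),
              biomass_adjusted = !is.null(biomass_index))
}

#' Construct a creep model
#'
#' @param rate Annual creep rate (fraction/yr, > -1); may be a single rate
#'   or a per-year vector named by year.
#' @param baseline_year Year at which the effective/nominal ratio is 1
#'   (default 1949).
#' @param n_years,biomass_adjusted Optional estimation metadata.
#' @return A `creep_model` list.
#' @export
creep_model <- function(rate, baseline_year = 1949, n_years = NA_integer_,
                        biomass_adjusted = FALSE) {
  if (any(rate <= -1)) stop("creep rate must be > -1")
  structure(list(rate = rate, baseline_year = baseline_year,
                 n_years = n_years, biomass_adjusted = biomass_adjusted),
            class = "creep_model")
}

#' Effective effort from nominal effort and technological creep
#'
#' Effective effort compounds the creep geometrically from the 1949
#' baseline: `Eff_y = Nom_y * prod_(k = 1950..y) (1 + c_k)`, so effective
#' effort in 1949 equals nominal effort in 1949 exactly.
#'
#' @param year Years (>= baseline; the baseline year itself is allowed).
#' @param nominal Nominal effort per year (>= 0).
#' @param creep A [creep_model()], or a single rate.
#' @return Numeric vector of effective effort.
#' @export
effective_effort <- function(year, nominal, creep) {
  if (!inherits(creep, "creep_model")) creep <- creep_model(creep)
  base <- creep$baseline_year
  if (any(year < base)) stop("years before the ", base, " baseline")
  if (any(nominal < 0)) stop("nominal effort must be non-negative")
  span <- seq(base, max(year))
  rate <- creep$rate
  rate_by_year <- if (length(rate) == 1) rep(rate, length(span)) else {
    r <- rate[as.character(span)]
    if (anyNA(r)) stop("per-year creep rates must cover ", base, "..", max(year))
    unname(r)
  }
  rate_by_year[1] <- 0  # baseline: multiplier 1 at `base`
  mult <- cumprod(1 + rate_by_year)
  nominal * mult[match(year, span)]
}
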