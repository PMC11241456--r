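#' Pricing-model parameters
#'
#' The symbols of the zero-loss revenue model: `Pf` is the treatment or
#' examination fee per patient, `cm` the material cost per show-up patient,
#' `cp` the fixed personnel cost of the period, `nt` the number of
#' appointed patients, `ns` the show-ups among them, and `beta` the
#' show-up rate of the classifier's show-up predictions (its positive
#' predictive value, from [column_rates()]).
#'
#' @param Pf Fee per patient (currency units); must exceed `cm`.
#' @param cm Material cost per show-up patient (currency units).
#' @param cp Fixed personnel cost for the period (currency units).
#' @param nt Appointed patients (count).
#' @param ns Show-up patients (count), `0 <= ns <= nt`.
#' @param beta Show-up rate in `(0, 1)` (boundaries allowed for revenue
#'   accounting but not for penalty solving).
#' @return An object of class `pricing_params`.
#' @export
pricing_params <- function(Pf, cm, cp, nt, ns, beta) {
  if (Pf <= cm || cm < 0) rlang::abort("require Pf > cm >= 0")
  if (cp < 0) rlang::abort("cp must be >= 0")
  if (ns < 0 || ns > nt) rlang::abort("require 0 <= ns <= nt")
  if (beta < 0 || beta > 1) rlang::abort("beta must lie in [0, 1]")
  structure(list(Pf = Pf, cm = cm, cp = cp, nt = nt, ns = ns, beta = beta),
            class = "pricing_params")
}

#' Number of no-show patients
#'
#' @param nt Appointed patients.
#' @param ns Show-up patients, `0 <= ns <= nt`.
#' @return `nt - ns`.
#' @export
no_show_count <- function(nt, ns) {
  if (any(ns > nt) || any(ns < 0)) rlang::abort("require 0 <= ns <= nt")
  nt - ns
}

#' Expected refill of vacated appointment slots
#'
#' Of `nn` vacated slots, the expected number refilled by prior no-shows
#' who reappoint and attend is `nnr = nn * (1 - beta) * beta`, and by new
#' patients `nsn = nn * beta^2`. Their sum is `nn * beta <= nn`, so the
#' refill never exceeds the vacancies.
#'
#' @param nn Number of no-shows (count, >= 0).
#' @param beta Show-up rate in `[0, 1]`.
#' @return List with `nnr`, `nsn` (expected counts, possibly fractional)
#'   and `nn`.
#' @export
#' @examples
#' slot_fill(nn = 40, beta = 0.9)  # nnr = 3.6, nsn = 32.4
slot_fill <- function(nn, beta) {
  if (any(nn < 0)) rlang::abort("nn must be >= 0")
  if (any(beta < 0 | beta > 1)) rlang::abort("beta must lie in [0, 1]")
  list(nnr = nn * (1 - beta) * beta, nsn = nn * beta^2, nn = nn)
}

#' Expected revenue with full attendance
#'
#' `Er = nt * (Pf - cm) - cp`: every appointed patient attends, pays the
#' fee and incurs the material cost; personnel cost is fixed.
#'
#' @param params A [pricing_params()].
#' @return Expected revenue (currency units).
#' @export
expected_revenue <- function(params) {
  params$nt * (params$Pf - params$cm) - params$cp
}

#' Revised revenue under no-shows, slot refill and a penalty fee
#'
#' Show-ups and new refill patients pay the standard fee; reappointed
#' no-shows pay the penalty fee `phi` instead:
#' `Rr = ns*(Pf-cm) + beta^2*(nt-ns)*(Pf-cm) + (beta-beta^2)*(nt-ns)*(phi-cm) - cp`.
#' This equals `(ns + nsn)*(Pf - cm) + nnr*(phi - cm) - cp` with `nnr`,
#' `nsn` from [slot_fill()].
#'
#' @param params A [pricing_params()].
#' @param phi Penalty fee charged to reappointed no-shows (currency units).
#' @return Revised revenue (currency units).
#' @export
revised_revenue <- function(params, phi) {
  with(params, {
    nn <- nt - ns
    ns * (Pf - cm) + beta^2 * nn * (Pf - cm) +
      (beta - beta^2) * nn * (phi - cm) - cp
  })
}

#' Zero-loss penalty fee
#'
#' Solves `revised_revenue(params, phi) = 0` for `phi`, the surcharge on
#' reappointed no-show patients that makes the non-profit period exactly
#' break even:
#' `phi = cm + (cp - (ns + beta^2*(nt-ns)) * (Pf - cm)) / (beta*(1-beta)*(nt-ns))`.
#' The value is reported unclamped: `below_material_cost` flags a subsidy
#' regime (`phi < cm`) and `above_standard_fee` a super-fee regime
#' (`phi > Pf`).
#'
#' @param params A [pricing_params()] with `beta` in the open interval
#'   `(0, 1)` and at least one no-show (`ns < nt`); otherwise the phi
#'   coefficient in the zero-loss equation vanishes and the fee is
#'   undefined.
#' @return List with `phi`, `penalty_rate` (percent of `Pf`), and the two
#'   regime flags.
#' @export
#' @examples
#' # shortfall of 100 spread over 2.5 expected reappointments:
#' penalty_cost(pricing_params(Pf = 100, cm = 20, cp = 1100,
#'                             nt = 20, ns = 10, beta = 0.5))$phi  # 60
penalty_cost <- function(params) {
  with(params, {
    nn <- nt - ns
    if (beta <= 0 || beta >= 1 || nn == 0) {
      rlang::abort(paste0("penalty fee undefined: beta in (0,1) and at least ",
                          "one no-show required"),
                   class = "undefined_penalty_error")
    }
    phi <- cm + (cp - (ns + beta^2 * nn) * (Pf - cm)) / (beta * (1 - beta) * nn)
    list(phi = phi,
         penalty_rate = penalty_rate(phi, Pf),
         below_material_cost = phi < cm,
         above_standard_fee = phi > Pf)
  })
}

#' Penalty fee as a percentage of the standard fee
#'
#' @param phi Penalty fee (currency units).
#' @param Pf Standard fee (currency units, > 0).
#' @return `100 * phi / Pf`.
#' @export
penalty_rate <- function(phi, Pf) {
  if (any(Pf <= 0)) rlang::abort("Pf must be > 0")
  100 * phi / Pf
}

#' Escalated penalty for repeat offenders
#'
#' Applies a per-offence multiplier sequence to the base fee; offences
#' beyond the sequence reuse its last multiplier.
#'
#' @param phi Base penalty fee.
#' @param offence Offence index (1 = first missed-then-rescheduled visit).
#' @param multipliers Escalation sequence (default 1, 1.5, 2).
#' @return Escalated fee.
#' @export
escalate_penalty <- function(phi, offence, multipliers = c(1, 1.5, 2)) {
  if (any(offence < 1)) rlang::abort("offence must be >= 1")
  phi * multipliers[pmin(offence, length(multipliers))]
}

#' Horizon-simulation settings
#'
#' @param horizon_days Number of simulated days (default 100).
#' @param demand_mean Poisson mean of daily appointed patients
#'   (default 11, about 1073 patients per 100 days).
#' @param Pf,cm,cp Cost parameters as in [pricing_params()]; `cp` defaults
#'   to the break-even personnel cost at mean demand,
#'   `demand_mean * (Pf - cm)`.
#' @return An object of class `horizon_config`.
#' @export
horizon_config <- function(horizon_days = 100L, demand_mean = 11,
                           Pf = 100, cm = 20, cp = demand_mean * (Pf - cm)) {
  if (horizon_days < 1) rlang::abort("horizon_days must be >= 1")
  if (demand_mean <= 0) rlang::abort("demand_mean must be > 0")
  structure(list(horizon_days = as.integer(horizon_days),
                 demand_mean = demand_mean, Pf = Pf, cm = cm, cp = cp),
            class = "horizon_config")
}

#' Simulate daily penalty fees over a horizon
#'
#' For each day, appointed patients `nt_d` are drawn Poisson; the daily
#' no-show fraction `u_d` is drawn uniformly on `(0, r_max]` where
#' `r_max = 1 - beta` is the algorithm's no-show ceiling; show-ups are
#' `ns_d = floor(nt_d * (1 - u_d))`, so every day with demand has at least
#' one no-show. The zero-loss fee and rate are computed per day via
#' [penalty_cost()]; days without demand contribute no rate. The series is
#' fully reproducible from `seed`, and algorithms simulated with the same
#' seed share identical demand and no-show-quantile draws, so differences
#' across algorithms isolate their `beta`.
#'
#' @param rates Named numeric vector of per-algorithm show-up rates
#'   `beta`, e.g. `c(RF = 0.975, GB = 0.975, AB = 0.950)`.
#' @param config A [horizon_config()].
#' @param seed Integer seed.
#' @return List of class `penalty_series`: `daily` (tibble with columns
#'   `algorithm`, `day`, `nt`, `ns`, `phi`, `rate`) and `average_rate`
#'   (named vector, mean percent rate over contributing days).
#' @export
simulate_horizon <- function(rates, config = horizon_config(), seed = 1L) {
  if (is.null(names(rates)) || any(!nzchar(names(rates)))) {
    rlang::abort("rates must be a named vector of per-algorithm betas")
  }
  if (any(rates <= 0 | rates >= 1)) {
    rlang::abort("per-algorithm beta must lie in (0, 1)")
  }
  draws <- withr::with_seed(seed, {
    list(nt = stats::rpois(config$horizon_days, config$demand_mean),
         q = stats::runif(config$horizon_days))
  })
  daily <- dplyr::bind_rows(lapply(names(rates), function(alg) {
    beta <- rates[[alg]]
    r_max <- 1 - beta
    u <- draws$q * r_max           # shared quantiles across algorithms
    u[u == 0] <- r_max * 1e-12     # open at 0
    nt <- draws$nt
    ns <- floor(nt * (1 - u))
    phi <- rate <- rep(NA_real_, length(nt))
    live <- nt > ns
    for (d in which(live)) {
      pc <- penalty_cost(pricing_params(Pf = config$Pf, cm = config$cm,
                                        cp = config$cp, nt = nt[d],
                                        ns = ns[d], beta = beta))
      phi[d] <- pc$phi
      rate[d] <- pc$penalty_rate
    }
    tibble::tibble(algorithm = alg, day = seq_along(nt), nt = nt, ns = ns,
                   phi = phi, rate = rate)
  }))
  avg <- vapply(names(rates), function(alg) {
    r <- daily$rate[daily$algorithm == alg]
    r <- r[!is.na(r)]
    if (length(r) == 0) {
      rlang::abort(paste0("no contributing days for algorithm ", alg))
    }
    mean(r)
  }, numeric(1))
  structure(list(daily = daily, average_rate = avg,
                 config = config, seed = seed),
            class = "penalty_series")
}
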