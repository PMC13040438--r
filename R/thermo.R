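# Redox thermodynamics of the Wood-Ljungdahl pathway's electron transfers:
# standard free energies from half-couple midpoint potentials, concentration
# corrections, and the Nernst dependence of the H+/H2 couple on hydrogen
# partial pressure.

#' Physical and bioenergetic constants
#'
#' Bundles the constants used throughout the thermodynamic and ledger
#' calculations.  Potentials are handled in mV and energies in kJ/mol; the
#' mV-to-V conversion happens in one place, inside [delta_g_standard()].
#'
#' @param temperature Temperature in kelvin.  The default 298.15 K (25 °C)
#'   is the standard-state convention under which the classic midpoint
#'   potentials are tabulated; the organism's growth temperature (328.15 K,
#'   55 °C) can be supplied instead.
#' @param faraday Faraday constant in kJ V^-1 mol^-1.
#' @param gas_constant Gas constant in kJ mol^-1 K^-1.
#' @param proton_per_atp Protons translocated per ATP synthesised by the
#'   ATP synthase (default 4).
#' @return A `thermo_params` list.
#' @export
thermo_params <- function(temperature = 298.15, faraday = 96.485,
                          gas_constant = 8.314e-3, proton_per_atp = 4) {
  stopifnot(
    is.numeric(temperature), temperature > 0,
    is.numeric(faraday), faraday > 0,
    is.numeric(gas_constant), gas_constant > 0,
    proton_per_atp > 0
  )
  structure(
    list(
      temperature = temperature, faraday = faraday,
      gas_constant = gas_constant, proton_per_atp = proton_per_atp
    ),
    class = "thermo_params"
  )
}

#' Define a redox half-couple
#'
#' @param name Identifier, e.g. `"co2_formate"`.
#' @param e0_prime Standard midpoint potential at pH 7 in mV.
#' @param e_prime_cellular Optional physiological potential in mV (e.g.
#'   -370 mV for NADPH/NADP+ in vivo, versus -320 mV standard).
#' @param n_electrons Number of electrons transferred by the couple.
#' @param source Either `"PAPER"` or `"LITERATURE"`, recording whether the
#'   potential is taken from the study this model encodes or from the
#'   general literature.
#' @return A `redox_couple` object.
#' @export
redox_couple <- function(name, e0_prime, e_prime_cellular = NA_real_,
                         n_electrons = 2L, source = "LITERATURE") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(e0_prime) || length(e0_prime) != 1L || !is.finite(e0_prime)) {
    stop("couple '", name, "': e0_prime must be a finite potential in mV")
  }
  if (!is.na(e_prime_cellular) && !is.finite(e_prime_cellular)) {
    stop("couple '", name, "': e_prime_cellular must be finite if given")
  }
  n_electrons <- as.integer(n_electrons)
  if (is.na(n_electrons) || n_electrons < 1L) {
    stop("couple '", name, "': n_electrons must be a positive integer")
  }
  structure(
    list(
      name = name, e0_prime = e0_prime,
      e_prime_cellular = as.double(e_prime_cellular),
      n_electrons = n_electrons, source = source
    ),
    class = "redox_couple"
  )
}

#' @export
print.redox_couple <- function(x, ...) {
  cat(sprintf(
    "<redox couple> %s: E0' = %g mV%s, n = %d [%s]\n",
    x$name, x$e0_prime,
    if (is.na(x$e_prime_cellular)) "" else sprintf(", E' = %g mV", x$e_prime_cellular),
    x$n_electrons, x$source
  ))
  invisible(x)
}

#' Built-in registry of redox couples
#'
#' Reads the versioned TSV shipped with the package.  Couples tagged
#' `PAPER` carry potentials printed in the study this model encodes
#' (CO2/formate -432 mV, NAD -320/-270 mV, NADP cellular -370 mV,
#' ferredoxin -450 mV, menaquinone -74 mV); couples tagged `LITERATURE`
#' (H+/H2 -414 mV, methylene-THF/methyl-THF -200 mV) are standard textbook
#' values consistent with the study's printed free-energy changes.
#'
#' @param file Path to a registry TSV; defaults to the shipped one.
#' @return A data frame with one row per couple.
#' @export
redox_couples <- function(file = system.file("extdata", "redox_couples.tsv",
                                             package = "acetoledger")) {
  reg <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("name", "e0_prime_mV", "e_prime_mV", "n_electrons", "source")
  if (!all(needed %in% names(reg))) {
    stop("registry file lacks columns: ", paste(setdiff(needed, names(reg)), collapse = ", "))
  }
  reg
}

#' Look up a couple from the registry
#'
#' @param name Couple name as in the registry's `name` column.
#' @param registry Registry data frame from [redox_couples()].
#' @return A [redox_couple()] object.
#' @export
get_couple <- function(name, registry = redox_couples()) {
  i <- match(name, registry$name)
  if (is.na(i)) {
    stop(
      "unknown redox couple '", name, "'; available: ",
      paste(registry$name, collapse = ", ")
    )
  }
  redox_couple(
    registry$name[i], registry$e0_prime_mV[i],
    registry$e_prime_mV[i], registry$n_electrons[i], registry$source[i]
  )
}

#' Standard free-energy change of an electron transfer
#'
#' Computes dG0' = -n * F * (E0'_acceptor - E0'_donor) for transfer of `n`
#' electrons from the donor couple to the acceptor couple, with midpoint
#' potentials in mV and the result in kJ/mol.  Negative values mean the
#' transfer donor -> acceptor is exergonic.
#'
#' With the shipped registry this reproduces the two anchor values of the
#' model: formate -> H+/H2 (n = 2) gives -3.5 kJ/mol (the "close to
#' equilibrium" Fdh-Ech reaction, -3 kJ/mol after integer rounding), and
#' menaquinol -> methylene-THF (n = 2) gives +24.3 kJ/mol (the endergonic
#' leg of the confurcating methylene-THF reductase).
#'
#' @param donor,acceptor [redox_couple()] objects (electron source and sink).
#' @param n Electrons transferred (>= 1).
#' @param params [thermo_params()].
#' @param potential Which potential to read off each couple: `"standard"`
#'   (E0', default) or `"cellular"` (E', falling back to E0' when no
#'   cellular value is recorded).
#' @return Free-energy change in kJ/mol.
#' @export
delta_g_standard <- function(donor, acceptor, n = 2L, params = thermo_params(),
                             potential = c("standard", "cellular")) {
  potential <- match.arg(potential)
  stopifnot(inherits(donor, "redox_couple"), inherits(acceptor, "redox_couple"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive electron count")
  e_of <- function(cpl) {
    e <- if (potential == "cellular" && !is.na(cpl$e_prime_cellular)) {
      cpl$e_prime_cellular
    } else {
      cpl$e0_prime
    }
    if (!is.finite(e)) stop("couple '", cpl$name, "' has no usable potential")
    e
  }
  -n * params$faraday * (e_of(acceptor) - e_of(donor)) / 1000
}

#' Concentration-corrected free-energy change
#'
#' dG' = dG0' + R * T * ln(Q) for a reaction quotient Q.  A 10-fold excess
#' of products over educts (Q = 10 per participating species) raises dG'
#' by R*T*ln(10) = 5.7 kJ/mol per decade at 298.15 K, which is how the
#' slightly exergonic formate oxidation can be pushed endergonic (or vice
#' versa) by metabolite concentrations.
#'
#' @param dg0 Standard free-energy change in kJ/mol.
#' @param reaction_quotient Dimensionless Q > 0.
#' @param params [thermo_params()].
#' @return dG' in kJ/mol.
#' @export
delta_g_prime <- function(dg0, reaction_quotient, params = thermo_params()) {
  if (!is.numeric(reaction_quotient) || any(reaction_quotient <= 0)) {
    stop("reaction quotient must be > 0")
  }
  dg0 + params$gas_constant * params$temperature * log(reaction_quotient)
}

#' Hydrogen electrode potential at a given partial pressure
#'
#' Nernst correction of the H+/H2 couple at pH 7:
#' E = E0' - (R*T / 2F) * ln(pH2).  At 298.15 K the slope is 29.58 mV per
#' decade of pressure; lowering pH2 makes the couple a weaker reductant
#' (less negative potential), raising it below 1 atm standard state makes
#' it stronger.
#'
#' @param partial_pressure_h2 H2 partial pressure in atm (> 0).
#' @param params [thermo_params()].
#' @param e0_h2 Standard potential of H+/H2 at pH 7 in mV.
#' @return Potential in mV.
#' @export
h2_potential <- function(partial_pressure_h2, params = thermo_params(),
                         e0_h2 = -414) {
  if (!is.numeric(partial_pressure_h2) || any(partial_pressure_h2 <= 0)) {
    stop("H2 partial pressure must be > 0 atm")
  }
  rt_2f_mv <- params$gas_constant * params$temperature / (2 * params$faraday) * 1000
  e0_h2 - rt_2f_mv * log(partial_pressure_h2)
}

#' Nernst slope of the H2 couple in mV per decade of pressure
#'
#' @param params [thermo_params()].
#' @return Slope magnitude in mV/decade (29.58 at 298.15 K).
#' @export
h2_nernst_slope <- function(params = thermo_params()) {
  params$gas_constant * params$temperature * log(10) / (2 * params$faraday) * 1000
}

#' H2-dependence feasibility sweep for CO2 reduction to formate
#'
#' Evaluates, over a list of H2 partial pressures, the free-energy change of
#' reducing the CO2/formate couple with a given reductant, and locates the
#' pressure at which the reaction crosses dG' = 0.
#'
#' Two reductant conventions are supported.  With
#' `reductant = "h2_equilibrated"` (default) the reductant pool (e.g.
#' NADPH maintained by an NADP+-reducing hydrogenase) is assumed to
#' equilibrate with gaseous H2, so its effective potential is
#' [h2_potential()] at each pressure; dG' then rises as pH2 falls and the
#' crossover marks the minimum pressure at which CO2 reduction remains
#' exergonic.  With `reductant = "fixed"` the couple's own potential
#' (cellular value if recorded, else standard) is used at every pressure,
#' which isolates the couple-vs-couple comparison from the gas phase.
#'
#' When the reductant couple records a cellular potential, the sweep also
#' reports the *equilibration pressure*: the pH2 at which the H2 couple
#' potential equals that cellular value, i.e. the pressure below which H2
#' can no longer hold the pool at its usual reduction state (about
#' 0.03 atm for NADPH at -370 mV).
#'
#' @param couple Reductant [redox_couple()].
#' @param pressures Non-empty vector of H2 partial pressures in atm.
#' @param params [thermo_params()].
#' @param acceptor Couple being reduced; defaults to CO2/formate from the
#'   registry.
#' @param reductant `"h2_equilibrated"` or `"fixed"` (see Details).
#' @param tol_decades Bisection tolerance for the crossover, in log10-atm.
#' @return A data frame with columns `p_h2`, `e_reductant_mV`,
#'   `dg_prime_kj`, and attributes `crossover_p_h2` (NA when dG' does not
#'   change sign over the swept range) and `equilibration_p_h2`.
#' @export
feasibility_sweep <- function(couple, pressures, params = thermo_params(),
                              acceptor = get_couple("co2_formate"),
                              reductant = c("h2_equilibrated", "fixed"),
                              tol_decades = 1e-6) {
  reductant <- match.arg(reductant)
  stopifnot(inherits(couple, "redox_couple"))
  if (length(pressures) == 0) stop("pressure list must be non-empty")
  if (any(pressures <= 0)) stop("all pressures must be > 0 atm")

  e_red_at <- function(p) {
    if (reductant == "h2_equilibrated") {
      h2_potential(p, params)
    } else {
      rep(
        if (!is.na(couple$e_prime_cellular)) couple$e_prime_cellular else couple$e0_prime,
        length(p)
      )
    }
  }
  dg_at <- function(p) {
    e_red <- e_red_at(p)
    -2 * params$faraday * (acceptor$e0_prime - e_red) / 1000
  }

  ord <- order(pressures)
  p <- pressures[ord]
  out <- data.frame(
    p_h2 = p,
    e_reductant_mV = e_red_at(p),
    dg_prime_kj = dg_at(p)
  )

  crossover <- NA_real_
  if (reductant == "h2_equilibrated") {
    # dG'(p) is monotone in log10 p; bisect if the sign changes in range.
    lo <- log10(min(p))
    hi <- log10(max(p))
    f <- function(d) dg_at(10^d)
    if (lo < hi && f(lo) * f(hi) < 0) {
      while (hi - lo > tol_decades) {
        mid <- (lo + hi) / 2
        if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
      }
      crossover <- 10^((lo + hi) / 2)
    } else if (any(dg_at(p) == 0)) {
      crossover <- p[which(dg_at(p) == 0)[1]]
    }
  }

  equilibration <- NA_real_
  if (!is.na(couple$e_prime_cellular)) {
    # Closed form: E0'(H2) - slope * log10(p) = E'_cellular.
    slope <- h2_nernst_slope(params)
    e0_h2 <- h2_potential(1, params)
    equilibration <- 10^((e0_h2 - couple$e_prime_cellular) / slope)
  }

  attr(out, "crossover_p_h2") <- crossover
  attr(out, "equilibration_p_h2") <- equilibration
  attr(out, "reductant_mode") <- reductant
  out
}

#' Round half away from zero
#'
#' The rounding convention used when comparing computed energies or fold
#' changes to integers quoted in prose (so -3.5 rounds to -4 and 5.769 to
#' 6), as opposed to R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded values.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
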