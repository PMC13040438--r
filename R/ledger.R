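# Stoichiometric bookkeeping for metabolic scenarios: validates that
# electron carriers and internal metabolites close exactly, derives the net
# reaction of a scenario, and totals vectorial protons into a chemiosmotic
# ATP yield.  All balances are computed in exact rational arithmetic.

# Electron-pair carriers of the model.  Each unit of a carrier holds one
# electron PAIR: Fd2- is deliberately counted as a two-electron carrier,
# which is the only convention under which the CO ledger's printed
# coefficients (0.75 MQH2 + 0.75 Fd2- -> 1.5 NADH) balance.
LEDGER_CARRIERS <- c("NADPH", "NADH", "Fd2-", "MQH2")

# Species vocabulary.  THF-bound C1 intermediates are internal; H2O is
# tracked only where the chemistry demands it (CO oxidation, the
# cyclohydrolase dehydration) -- scalar protons are not balanced, matching
# the loose water/proton convention of metabolic ledger diagrams.
LEDGER_SPECIES <- c(
  "H2", "CO2", "CO", "formate", "formate_periplasm", "acetate", "H2O",
  "THF", "formyl-THF", "methenyl-THF", "methylene-THF", "methyl-THF"
)

# Electron-pair content of external species relative to the CO2/H2O
# reference state; used for the whole-scenario electron audit (an acetate
# carries 8 electrons = 4 pairs).
SPECIES_PAIR_CONTENT <- c(
  H2 = 1, CO = 1, formate = 1, acetate = 4,
  CO2 = 0, H2O = 0, formate_periplasm = 1
)

#' Define one enzyme-level reaction step
#'
#' A step records, per unit flux: the signed metabolite stoichiometry
#' (negative = consumed), the signed electron-pair coefficients of the
#' redox carriers (positive = reduced form produced), vectorial proton
#' counts, substrate-level ATP, and a `pairs_transferred` audit field --
#' the net electron pairs *released* by the metabolite redox changes (e.g.
#' +1 for oxidising one H2, -1 for reducing CO2 to formate).  The validator
#' recomputes the audit: pairs released by metabolites plus pairs released
#' by oxidised carriers must equal the pairs captured in reduced carriers.
#'
#' @param id Short identifier, unique within a scenario.
#' @param enzyme Enzyme or complex name (e.g. `"Nfn"`, `"Fdh-Ech"`).
#' @param metabolites Named coefficients ([rational()] or exact decimals).
#' @param carriers Named electron-pair coefficients over
#'   `NADPH, NADH, Fd2-, MQH2`.
#' @param protons_out Protons translocated to the periplasm per unit flux.
#' @param protons_in Protons consumed from the gradient per unit flux.
#' @param atp_substrate Signed substrate-level ATP per unit flux.
#' @param pairs_transferred Audit field, see Description.
#' @return A `reaction_step` object.
#' @export
reaction_step <- function(id, enzyme, metabolites = NULL, carriers = NULL,
                          protons_out = 0, protons_in = 0,
                          atp_substrate = 0, pairs_transferred = 0) {
  as_named_rational <- function(x, what) {
    if (is.null(x) || length(x) == 0) return(NULL)
    if (is.null(names(x)) || any(names(x) == "")) {
      stop("step '", id, "': all ", what, " coefficients must be named")
    }
    as_rational(x)
  }
  step <- structure(
    list(
      id = id, enzyme = enzyme,
      metabolites = as_named_rational(metabolites, "metabolite"),
      carriers = as_named_rational(carriers, "carrier"),
      protons_out = as_rational(protons_out),
      protons_in = as_rational(protons_in),
      atp_substrate = as_rational(atp_substrate),
      pairs_transferred = as_rational(pairs_transferred)
    ),
    class = "reaction_step"
  )
  if (step$protons_out < 0 || step$protons_in < 0) {
    stop("step '", id, "': vectorial proton counts must be non-negative")
  }
  step
}

# Reverse a step: negate stoichiometry and swap the vectorial proton sides.
# Used for enzymes the model runs in either direction (Nfn, Fdh-Ech, Etf).
reverse_step <- function(step, id = paste0(step$id, "_rev")) {
  neg <- function(x) if (is.null(x)) NULL else -x
  reaction_step(
    id = id, enzyme = step$enzyme,
    metabolites = neg(step$metabolites),
    carriers = neg(step$carriers),
    protons_out = step$protons_in,
    protons_in = step$protons_out,
    atp_substrate = -step$atp_substrate,
    pairs_transferred = -step$pairs_transferred
  )
}

#' Assemble a metabolic scenario
#'
#' A scenario is an ordered list of steps with exact rational flux
#' multipliers, normalised to one acetate produced.  Species not listed in
#' `external_species` (and every carrier) must net to zero over the whole
#' scenario.
#'
#' @param name Scenario name.
#' @param steps List of `list(step = reaction_step, flux = ...)` entries;
#'   fluxes are coerced with [as_rational()] and must be >= 0.
#' @param external_species Species allowed a nonzero net balance.
#' @param params [thermo_params()]; supplies the H+/ATP quotient.
#' @return A `scenario` object.
#' @export
scenario <- function(name, steps, external_species, params = thermo_params()) {
  stopifnot(length(steps) >= 1)
  steps <- lapply(steps, function(entry) {
    stopifnot(inherits(entry$step, "reaction_step"))
    entry$flux <- as_rational(entry$flux)
    if (entry$flux < 0) {
      stop("scenario '", name, "': flux for step '", entry$step$id, "' is negative; ",
           "encode the reverse direction as its own step")
    }
    entry
  })
  unknown_sp <- setdiff(
    unlist(lapply(steps, function(e) names(e$step$metabolites))),
    LEDGER_SPECIES
  )
  unknown_ca <- setdiff(
    unlist(lapply(steps, function(e) names(e$step$carriers))),
    LEDGER_CARRIERS
  )
  if (length(unknown_sp) || length(unknown_ca)) {
    stop(
      "scenario '", name, "': unknown names: ",
      paste(c(unknown_sp, unknown_ca), collapse = ", ")
    )
  }
  if (length(bad <- setdiff(external_species, LEDGER_SPECIES))) {
    stop("scenario '", name, "': unknown external species: ", paste(bad, collapse = ", "))
  }
  structure(
    list(name = name, steps = steps, external_species = external_species, params = params),
    class = "scenario"
  )
}

# Net of one coefficient slot (metabolites or carriers) over all steps,
# weighted by flux.  Returns a named rational.
scenario_net <- function(s, slot) {
  nm <- character(0)
  vals <- list()
  for (entry in s$steps) {
    coefs <- entry$step[[slot]]
    if (is.null(coefs)) next
    for (i in seq_along(coefs)) {
      nm <- c(nm, names(coefs)[i])
      vals <- c(vals, list(coefs[i] * entry$flux))
    }
  }
  if (length(nm) == 0) return(rational(numeric(0)))
  rat_accumulate(nm, do.call(c.rational, vals))
}

# Per-step electron-pair audit: pairs released by metabolite redox change
# plus pairs released by oxidised carriers must equal pairs captured in
# reduced carriers.
step_pair_audit_ok <- function(step) {
  released <- step$pairs_transferred
  captured <- rational(0)
  if (!is.null(step$carriers)) {
    for (i in seq_along(step$carriers)) {
      ci <- step$carriers[i]
      if (ci < 0) released <- released + abs(ci) else captured <- captured + ci
    }
  }
  released == captured
}

#' Validate a scenario's conservation laws
#'
#' Checks (a) every carrier nets to exactly zero, (b) every species outside
#' the external set nets to exactly zero, and (c) every step passes its
#' electron-pair audit.  Balances are exact rational sums, so "zero" means
#' identically zero.
#'
#' @param s A [scenario()].
#' @return A character vector of violation messages; empty when valid.
#' @export
validate_scenario <- function(s) {
  stopifnot(inherits(s, "scenario"))
  violations <- character(0)

  carriers <- scenario_net(s, "carriers")
  for (i in seq_along(carriers)) {
    if (!(carriers[i] == 0)) {
      violations <- c(violations, sprintf(
        "carrier '%s' does not close: net %s", names(carriers)[i], format(carriers[i])
      ))
    }
  }

  species <- scenario_net(s, "metabolites")
  for (i in seq_along(species)) {
    nm <- names(species)[i]
    if (!(nm %in% s$external_species) && !(species[i] == 0)) {
      violations <- c(violations, sprintf(
        "internal species '%s' does not close: net %s", nm, format(species[i])
      ))
    }
  }

  for (entry in s$steps) {
    if (!step_pair_audit_ok(entry$step)) {
      violations <- c(violations, sprintf(
        "step '%s' fails its electron-pair audit", entry$step$id
      ))
    }
  }
  violations
}

#' Net reaction of a scenario
#'
#' Flux-weighted sum of all metabolite coefficients, restricted to the
#' external species.  Errors (carrying the violation list) if the scenario
#' does not validate.
#'
#' @param s A [scenario()].
#' @return A named [rational()] vector of net coefficients (negative =
#'   consumed).
#' @export
net_reaction <- function(s) {
  v <- validate_scenario(s)
  if (length(v)) {
    stop("scenario '", s$name, "' is invalid:\n  ", paste(v, collapse = "\n  "))
  }
  species <- scenario_net(s, "metabolites")
  keep <- names(species) %in% s$external_species & as.double(species) != 0
  species[keep]
}

#' Proton and ATP balance sheet of a scenario
#'
#' Totals the vectorial protons (out minus in) over all steps, converts
#' them to chemiosmotic ATP through the H+/ATP quotient, adds the
#' substrate-level ATP (formyl-THF synthetase -1, acetate kinase +1), and
#' returns the full ledger report.  All fields are exact rationals.
#'
#' @param s A [scenario()].
#' @return A `ledger_report` with fields `net_reaction`, `carrier_balance`,
#'   `protons_translocated`, `atp_chemiosmotic`, `atp_substrate_level`,
#'   `atp_total`.
#' @export
atp_yield <- function(s) {
  net <- net_reaction(s) # validates
  protons <- rational(0)
  atp_sub <- rational(0)
  for (entry in s$steps) {
    protons <- protons + entry$flux * (entry$step$protons_out - entry$step$protons_in)
    atp_sub <- atp_sub + entry$flux * entry$step$atp_substrate
  }
  quotient <- as_rational(s$params$proton_per_atp)
  atp_chem <- protons / quotient
  structure(
    list(
      scenario = s$name,
      net_reaction = net,
      carrier_balance = scenario_net(s, "carriers"),
      protons_translocated = protons,
      proton_per_atp = quotient,
      atp_chemiosmotic = atp_chem,
      atp_substrate_level = atp_sub,
      atp_total = atp_chem + atp_sub
    ),
    class = "ledger_report"
  )
}

#' @export
print.ledger_report <- function(x, ...) {
  fmt_side <- function(coefs, sign) {
    keep <- if (sign < 0) as.double(coefs) < 0 else as.double(coefs) > 0
    if (!any(keep)) return("")
    parts <- sprintf("%s %s", format(abs(coefs[keep])), names(coefs)[keep])
    paste(parts, collapse = " + ")
  }
  cat("Ledger report --", x$scenario, "\n")
  cat("  net reaction: ", fmt_side(x$net_reaction, -1), " -> ",
      fmt_side(x$net_reaction, +1), "\n", sep = "")
  cat("  carriers close:", all(as.double(x$carrier_balance) == 0), "\n")
  cat("  H+ translocated (net):", format(x$protons_translocated), "\n")
  cat("  ATP chemiosmotic:", format(x$atp_chemiosmotic),
      sprintf("(H+/ATP = %s)", format(x$proton_per_atp)), "\n")
  cat("  ATP substrate-level:", format(x$atp_substrate_level), "\n")
  cat("  ATP total:", format(x$atp_total), "\n")
  invisible(x)
}

#' Convert a ledger report to plain lists for JSON output
#'
#' @param report A `ledger_report` from [atp_yield()].
#' @return A list of numeric fields (rationals as decimal values, with the
#'   exact fraction strings alongside).
#' @export
ledger_report_as_list <- function(report) {
  named_num <- function(r) as.list(as.double(r))
  list(
    scenario = report$scenario,
    net_reaction = named_num(report$net_reaction),
    net_reaction_exact = as.list(format(report$net_reaction)),
    carrier_balance = named_num(report$carrier_balance),
    protons_translocated = as.double(report$protons_translocated),
    proton_per_atp = as.double(report$proton_per_atp),
    atp_chemiosmotic = as.double(report$atp_chemiosmotic),
    atp_substrate_level = as.double(report$atp_substrate_level),
    atp_total = as.double(report$atp_total)
  )
}

#' Whole-scenario electron-pair audit
#'
#' Counts the electron pairs entering the scenario from external substrates
#' (H2, CO, formate: one pair each relative to the CO2/H2O reference) and
#' the pairs leaving in products (acetate: four pairs).  For every balanced
#' acetogenic ledger both totals equal 4 pairs (8 electrons) per acetate.
#'
#' @param s A [scenario()].
#' @return A list with `pairs_in`, `pairs_out` (rationals, per acetate).
#' @export
electron_pair_total <- function(s) {
  net <- net_reaction(s)
  pairs_in <- rational(0)
  pairs_out <- rational(0)
  for (i in seq_along(net)) {
    nm <- names(net)[i]
    content <- SPECIES_PAIR_CONTENT[[nm]]
    if (is.null(content) || content == 0) next
    if (net[i] < 0) {
      pairs_in <- pairs_in + abs(net[i]) * rational(content)
    } else {
      pairs_out <- pairs_out + net[i] * rational(content)
    }
  }
  acetate <- if ("acetate" %in% names(net)) net["acetate"] else rational(0)
  list(
    pairs_in = pairs_in, pairs_out = pairs_out,
    acetate_produced = acetate
  )
}
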