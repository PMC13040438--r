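# The three built-in bioenergetic scenarios of autotrophic acetogenesis in
# M. thermoacetica -- growth on H2 + CO2 at high or low H2 partial pressure,
# and growth on CO -- plus the optional periplasmic formate cycle.  Each
# scenario is an exact ledger normalised to one acetate produced.

#' Options controlling the built-in scenarios
#'
#' @param ech_protons Vectorial protons per formate turned over by the
#'   Fdh-Ech complex (the unknown `x` of the model; default 0, since no
#'   explicit number can be given).  Counted outward when Fdh-Ech runs
#'   forward (formate oxidation) and as a cost against the gradient when it
#'   runs in reverse.
#' @param proton_per_atp H+/ATP quotient of the ATP synthase (default 4).
#' @param temperature Kelvin, forwarded to [thermo_params()].
#' @param formate_cycle Whether to append the periplasmic formate cycle
#'   (only meaningful for the high-H2 and CO scenarios).
#' @param formate_cycle_protons Extra vectorial protons per formate cycled;
#'   the model does not quantify this, so the default is 0.
#' @param formate_cycle_flux Formate cycled per acetate (default 1).
#' @return A list of options for the scenario builders.
#' @export
scenario_options <- function(ech_protons = 0, proton_per_atp = 4,
                             temperature = 298.15, formate_cycle = FALSE,
                             formate_cycle_protons = 0, formate_cycle_flux = 1) {
  list(
    ech_protons = as_rational(ech_protons),
    proton_per_atp = proton_per_atp,
    temperature = temperature,
    formate_cycle = isTRUE(formate_cycle),
    formate_cycle_protons = as_rational(formate_cycle_protons),
    formate_cycle_flux = as_rational(formate_cycle_flux)
  )
}

# --- unit step definitions (coefficients per unit flux) -------------------

step_nadp_hydrogenase <- function() reaction_step(
  "nadp_hyd", "NADP+-reducing hydrogenase",
  metabolites = c(H2 = -1),
  carriers = c(NADPH = 1),
  pairs_transferred = 1
)

step_nadph_fdh <- function() reaction_step(
  "nadph_fdh", "NADPH-dependent formate dehydrogenase",
  metabolites = c(CO2 = -1, formate = 1),
  carriers = c(NADPH = -1),
  pairs_transferred = -1
)

step_fdh_ech_forward <- function(x = rational(0)) reaction_step(
  "fdh_ech", "Fdh-Ech",
  metabolites = c(formate = -1, CO2 = 1, H2 = 1),
  protons_out = x
)

step_fdh_ech_reverse <- function(x = rational(0)) {
  reverse_step(step_fdh_ech_forward(x), id = "fdh_ech_rev")
}

step_formyl_thf_synthetase <- function() reaction_step(
  "fthfs", "formyl-THF synthetase",
  metabolites = c(formate = -1, THF = -1, `formyl-THF` = 1),
  atp_substrate = -1
)

step_cyclohydrolase <- function() reaction_step(
  "mthfc", "methenyl-THF cyclohydrolase",
  metabolites = c(`formyl-THF` = -1, `methenyl-THF` = 1, H2O = 1)
)

step_methylene_thf_dh <- function() reaction_step(
  "mthfd", "methylene-THF dehydrogenase",
  metabolites = c(`methenyl-THF` = -1, `methylene-THF` = 1),
  carriers = c(NADPH = -1),
  pairs_transferred = -1
)

step_nfn_forward <- function() reaction_step(
  "nfn", "Nfn transhydrogenase",
  carriers = c(NADPH = -2, NADH = 1, `Fd2-` = 1)
)

step_nfn_reverse <- function() reverse_step(step_nfn_forward(), id = "nfn_rev")

# Per unit NADH bifurcated: 1 NADH -> 0.5 MQH2 + 0.5 Fd2-.
step_etf_bifurcation <- function() reaction_step(
  "etf", "EtfABCX",
  carriers = c(NADH = "-1", MQH2 = "1/2", `Fd2-` = "1/2")
)

# Confurcation direction (CO scenario): 0.5 MQH2 + 0.5 Fd2- -> 1 NADH.
step_etf_confurcation <- function() reverse_step(step_etf_bifurcation(), id = "etf_conf")

# Ferredoxin-dependent NADH-dehydrogenase-like complex, per MQ reduced:
# 4 H+ translocated (1.25 MQ <-> 5 H+ in the CO ledger).
step_nadh_dehydrogenase <- function() reaction_step(
  "nadh_dh", "Fd-dependent NADH dehydrogenase",
  carriers = c(`Fd2-` = -1, MQH2 = 1),
  protons_out = 4
)

# Confurcating Type IV MTHFR fed by 0.5 NADH + 0.5 MQH2; oxidising the
# 0.5 MQH2 on the periplasmic face translocates one proton (redox loop).
step_mthfr <- function() reaction_step(
  "mthfr", "MTHFR (Type IV, confurcating)",
  metabolites = c(`methylene-THF` = -1, `methyl-THF` = 1),
  carriers = c(NADH = "-1/2", MQH2 = "-1/2"),
  protons_out = 1,
  pairs_transferred = -1
)

step_codh_co2_to_co <- function() reaction_step(
  "codh", "CODH/ACS (carbonyl branch, CO2 -> CO)",
  metabolites = c(CO2 = -1, CO = 1, H2O = 1),
  carriers = c(`Fd2-` = -1),
  pairs_transferred = -1
)

step_co_oxidation <- function() reaction_step(
  "co_ox", "CODH (CO oxidation)",
  metabolites = c(CO = -1, H2O = -1, CO2 = 1),
  carriers = c(`Fd2-` = 1),
  pairs_transferred = 1
)

step_acs_acetate <- function() reaction_step(
  "acs_ack", "ACS condensation + Pta/Ack",
  metabolites = c(`methyl-THF` = -1, CO = -1, THF = 1, acetate = 1),
  atp_substrate = 1
)

entry <- function(step, flux) list(step = step, flux = as_rational(flux))

scenario_params <- function(options) {
  thermo_params(
    temperature = options$temperature,
    proton_per_atp = options$proton_per_atp
  )
}

#' Build the high-H2 scenario
#'
#' Acetogenesis from H2 + CO2 at high H2 partial pressure: five H2 are
#' oxidised to NADPH, two CO2 are reduced to formate with NADPH, one
#' formate is re-oxidised by the forward Fdh-Ech (releasing H2 that the
#' hydrogenase recaptures), and the methyl and carbonyl branches condense
#' the remaining C1 units into acetate.  Net: 4 H2 + 2 CO2 -> acetate
#' (+ 2 H2O); 2 vectorial H+ (NADH dehydrogenase + redox loop) plus the
#' unknown Fdh-Ech contribution, i.e. 0.5 ATP at H+/ATP = 4 and x = 0.
#'
#' @param options [scenario_options()].
#' @return A validated [scenario()].
#' @export
build_high_h2 <- function(options = scenario_options()) {
  s <- scenario(
    "high_h2",
    steps = list(
      entry(step_nadp_hydrogenase(), 5),
      entry(step_nadph_fdh(), 2),
      entry(step_fdh_ech_forward(options$ech_protons), 1),
      entry(step_formyl_thf_synthetase(), 1),
      entry(step_cyclohydrolase(), 1),
      entry(step_methylene_thf_dh(), 1),
      entry(step_nfn_forward(), 1),
      entry(step_etf_bifurcation(), "1/2"),
      entry(step_nadh_dehydrogenase(), "1/4"),
      entry(step_mthfr(), 1),
      entry(step_codh_co2_to_co(), 1),
      entry(step_acs_acetate(), 1)
    ),
    external_species = c("H2", "CO2", "acetate", "H2O"),
    params = scenario_params(options)
  )
  if (options$formate_cycle) {
    s <- apply_formate_cycle(
      s, as.double(options$formate_cycle_protons),
      flux = options$formate_cycle_flux
    )
  }
  s
}

#' Build the low-H2 scenario
#'
#' At low H2 partial pressure NADPH-dependent CO2 reduction is no longer
#' favourable, so the Fdh-Ech complex runs in reverse: H2 + CO2 -> formate,
#' driven by the proton gradient (consuming `x` protons per formate).
#' Three H2 feed the NADP+-reducing hydrogenase; carrier balancing through
#' Nfn, EtfABCX and the NADH dehydrogenase is identical to the high-H2
#' case, so the NADH-dehydrogenase + redox-loop proton count stays at 2,
#' but the Fdh-Ech coupling site is lost (and reversed), lowering the ATP
#' yield.  The formate cycle is not active under these conditions.
#'
#' @param options [scenario_options()].
#' @return A validated [scenario()].
#' @export
build_low_h2 <- function(options = scenario_options()) {
  if (options$formate_cycle) {
    stop("the formate cycle is not active under low H2; build with formate_cycle = FALSE")
  }
  scenario(
    "low_h2",
    steps = list(
      entry(step_nadp_hydrogenase(), 3),
      entry(step_fdh_ech_reverse(options$ech_protons), 1),
      entry(step_formyl_thf_synthetase(), 1),
      entry(step_cyclohydrolase(), 1),
      entry(step_methylene_thf_dh(), 1),
      entry(step_nfn_forward(), 1),
      entry(step_etf_bifurcation(), "1/2"),
      entry(step_nadh_dehydrogenase(), "1/4"),
      entry(step_mthfr(), 1),
      entry(step_codh_co2_to_co(), 1),
      entry(step_acs_acetate(), 1)
    ),
    external_species = c("H2", "CO2", "acetate", "H2O"),
    params = scenario_params(options)
  )
}

#' Build the CO scenario
#'
#' Acetogenesis from CO: three of four CO are oxidised to CO2 with
#' ferredoxin reduction; 1.25 Fd2- feed the NADH dehydrogenase (reducing
#' 1.25 MQ and translocating five protons), 0.75 MQH2 + 0.75 Fd2- confurcate
#' to 1.5 NADH at EtfABCX, Nfn regenerates 2 NADPH, and the methyl branch
#' runs as on H2 + CO2 with the fourth CO entering acetyl-CoA directly.
#' Net: 4 CO + 2 H2O -> acetate + 2 CO2; 6 vectorial H+ -> 1.5 ATP at
#' H+/ATP = 4 and x = 0.
#'
#' @param options [scenario_options()].
#' @return A validated [scenario()].
#' @export
build_co <- function(options = scenario_options()) {
  s <- scenario(
    "co",
    steps = list(
      entry(step_co_oxidation(), 3),
      entry(step_nadh_dehydrogenase(), "5/4"),
      entry(step_etf_confurcation(), "3/2"),
      entry(step_nfn_reverse(), 1),
      entry(step_nadph_fdh(), 2),
      entry(step_fdh_ech_forward(options$ech_protons), 1),
      entry(step_nadp_hydrogenase(), 1),
      entry(step_formyl_thf_synthetase(), 1),
      entry(step_cyclohydrolase(), 1),
      entry(step_methylene_thf_dh(), 1),
      entry(step_mthfr(), 1),
      entry(step_acs_acetate(), 1)
    ),
    external_species = c("CO", "CO2", "acetate", "H2O"),
    params = scenario_params(options)
  )
  if (options$formate_cycle) {
    s <- apply_formate_cycle(
      s, as.double(options$formate_cycle_protons),
      flux = options$formate_cycle_flux
    )
  }
  s
}

#' Append the periplasmic formate cycle to a scenario
#'
#' Adds the suggested energy-conserving formate cycle: FocA exports
#' formate, the periplasmic cytochrome b-dependent formate dehydrogenase
#' oxidises it to CO2 feeding menaquinone, and a matching cytoplasmic
#' re-reduction closes the cycle so that formate, CO2 and the quinone pool
#' all net to zero.  Only the configurable vectorial proton count changes
#' the ledger; the model does not quantify it, so the default adds none.
#'
#' The cycle is declared inactive at low H2, so applying it to the low-H2
#' scenario is an error.
#'
#' @param s A [scenario()] containing an MTHFR step.
#' @param loop_protons_per_formate Extra vectorial protons per formate
#'   cycled (>= 0).
#' @param flux Formate cycled per acetate.
#' @return The extended, still-valid [scenario()].
#' @export
apply_formate_cycle <- function(s, loop_protons_per_formate = 0, flux = 1) {
  stopifnot(inherits(s, "scenario"))
  if (identical(s$name, "low_h2")) {
    stop("the formate cycle is not active under low H2")
  }
  has_mthfr <- any(vapply(s$steps, function(e) e$step$id == "mthfr", logical(1)))
  if (!has_mthfr) {
    stop("scenario '", s$name, "' has no MTHFR step; the formate cycle requires one")
  }
  loop <- as_rational(loop_protons_per_formate)
  if (loop < 0) stop("loop protons must be non-negative")
  foca <- reaction_step(
    "foca", "FocA formate export",
    metabolites = c(formate = -1, formate_periplasm = 1)
  )
  cytb_fdh <- reaction_step(
    "cytb_fdh", "periplasmic cytochrome b-dependent Fdh",
    metabolites = c(formate_periplasm = -1, CO2 = 1),
    carriers = c(MQH2 = 1),
    protons_out = loop,
    pairs_transferred = 1
  )
  fdh_return <- reaction_step(
    "fdh_return", "cytoplasmic CO2 re-reduction (cycle closure)",
    metabolites = c(CO2 = -1, formate = 1),
    carriers = c(MQH2 = -1),
    pairs_transferred = -1
  )
  s$steps <- c(s$steps, list(
    entry(foca, flux), entry(cytb_fdh, flux), entry(fdh_return, flux)
  ))
  v <- validate_scenario(s)
  if (length(v)) stop("formate cycle broke the ledger:\n  ", paste(v, collapse = "\n  "))
  s
}

#' Catalog of built-in scenarios
#'
#' @return Named list of builder functions (`high_h2`, `low_h2`, `co`),
#'   each taking [scenario_options()].
#' @export
scenario_catalog <- function() {
  list(high_h2 = build_high_h2, low_h2 = build_low_h2, co = build_co)
}

#' Build a named scenario from the catalog
#'
#' @param name One of `"high_h2"`, `"low_h2"`, `"co"`.
#' @param options [scenario_options()].
#' @return A validated [scenario()].
#' @export
build_scenario <- function(name, options = scenario_options()) {
  cat <- scenario_catalog()
  if (!name %in% names(cat)) {
    stop("unknown scenario '", name, "'; available: ", paste(names(cat), collapse = ", "))
  }
  cat[[name]](options)
}

#' Write a scenario to an editable YAML file
#'
#' Fluxes and coefficients are serialised as exact fraction strings
#' (`"5/4"`), so a round trip through [read_scenario_yaml()] preserves the
#' ledger bit for bit.
#'
#' @param s A [scenario()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario_yaml <- function(s, path) {
  ser_coefs <- function(x) if (is.null(x)) NULL else as.list(format(x))
  doc <- list(
    name = s$name,
    external_species = as.list(s$external_species),
    proton_per_atp = s$params$proton_per_atp,
    temperature = s$params$temperature,
    steps = lapply(s$steps, function(e) {
      st <- e$step
      out <- list(
        id = st$id, enzyme = st$enzyme, flux = format(e$flux),
        metabolites = ser_coefs(st$metabolites),
        carriers = ser_coefs(st$carriers),
        protons_out = format(st$protons_out),
        protons_in = format(st$protons_in),
        atp_substrate = format(st$atp_substrate),
        pairs_transferred = format(st$pairs_transferred)
      )
      out[!vapply(out, is.null, logical(1))]
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read a scenario from a YAML file written by [write_scenario_yaml()]
#'
#' @param path YAML file path.
#' @return A [scenario()].
#' @export
read_scenario_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  de_coefs <- function(x) {
    if (is.null(x)) return(NULL)
    out <- as_rational(unlist(x, use.names = FALSE))
    names(out) <- names(x)
    out
  }
  steps <- lapply(doc$steps, function(st) {
    entry(
      reaction_step(
        id = st$id, enzyme = st$enzyme,
        metabolites = de_coefs(st$metabolites),
        carriers = de_coefs(st$carriers),
        protons_out = as_rational(st$protons_out),
        protons_in = as_rational(st$protons_in),
        atp_substrate = as_rational(st$atp_substrate),
        pairs_transferred = as_rational(st$pairs_transferred)
      ),
      st$flux
    )
  })
  scenario(
    doc$name, steps,
    external_species = unlist(doc$external_species),
    params = thermo_params(
      temperature = doc$temperature,
      proton_per_atp = doc$proton_per_atp
    )
  )
}
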