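# Independent oracles used across the suite.

# Brute-force net reaction: accumulate a plain double-precision
# species x step incidence matrix and multiply by the flux vector,
# independently of the rational ledger machinery.
oracle_net_species <- function(s) {
  species <- unique(unlist(lapply(s$steps, function(e) names(e$step$metabolites))))
  if (length(species) == 0) return(numeric(0))
  inc <- matrix(0, nrow = length(species), ncol = length(s$steps),
                dimnames = list(species, NULL))
  for (j in seq_along(s$steps)) {
    coefs <- s$steps[[j]]$step$metabolites
    if (is.null(coefs)) next
    inc[names(coefs), j] <- as.double(coefs)
  }
  flux <- vapply(s$steps, function(e) as.double(e$flux), 0)
  drop(inc %*% flux)
}

# Same accumulation for carriers.
oracle_net_carriers <- function(s) {
  carriers <- unique(unlist(lapply(s$steps, function(e) names(e$step$carriers))))
  if (length(carriers) == 0) return(numeric(0))
  inc <- matrix(0, nrow = length(carriers), ncol = length(s$steps),
                dimnames = list(carriers, NULL))
  for (j in seq_along(s$steps)) {
    coefs <- s$steps[[j]]$step$carriers
    if (is.null(coefs)) next
    inc[names(coefs), j] <- as.double(coefs)
  }
  flux <- vapply(s$steps, function(e) as.double(e$flux), 0)
  drop(inc %*% flux)
}

# Named-double view of a rational net reaction for comparisons.
net_as_double <- function(net) {
  out <- as.double(net)
  names(out) <- names(net)
  out[order(names(out))]
}

make_couple <- function(e0, name = sprintf("c%+.0f", e0), cellular = NA_real_) {
  redox_couple(name, e0, cellular)
}
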