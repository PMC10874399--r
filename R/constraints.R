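#' @keywords internal
.flux_names <- function(variant) {
  if (variant == "extended")
    c("v_IC", "v_EAA", "v_ENT", "v_RNAP", "v_RNase", "v_AF",
      "w_IC", "w_EAA", "w_ENT", "w_RNAP", "w_RNase", "w_AF", "w_rP")
  else
    c("v_IC", "v_EAA", "v_ENT", "v_RNAP", "v_AF",
      "w_IC", "w_EAA", "w_ENT", "w_RNAP", "w_AF", "w_rP")
}

#' @keywords internal
.row_names <- function(variant) {
  if (variant == "extended")
    c("C", "AA", "NT", "rRNA", "rP",
      "cap IC", "cap EAA", "cap ENT", "cap RNAP", "cap RNase", "cap AF",
      "cap R", "min deg", "mass")
  else
    c("C", "AA", "NT", "rRNA", "rP",
      "cap IC", "cap EAA", "cap ENT", "cap RNAP", "cap AF", "cap R", "mass")
}

#' @keywords internal
.species_names <- function(variant) {
  if (variant == "extended")
    c("C", "AA", "NT", "rRNA", "rP",
      "IC", "EAA", "ENT", "RNAP", "RNase", "AF", "R")
  else
    c("C", "AA", "NT", "rRNA", "rP", "IC", "EAA", "ENT", "RNAP", "AF", "R")
}

# protein lengths charged to translation, in flux order of the w-columns;
# rP is discounted by the imported fraction (imported residues are free)
.protein_lengths <- function(params, comp, variant) {
  n_rP_eff <- (1 - params$rp_import_fraction) * comp$n_rP
  if (variant == "extended")
    c(w_IC = params$n_IC, w_EAA = params$n_EAA, w_ENT = params$n_ENT,
      w_RNAP = params$n_RNAP, w_RNase = params$n_RNase, w_AF = params$n_AF,
      w_rP = n_rP_eff)
  else
    c(w_IC = params$n_IC, w_EAA = params$n_EAA, w_ENT = params$n_ENT,
      w_RNAP = params$n_RNAP, w_AF = params$n_AF, w_rP = n_rP_eff)
}

#' Stoichiometric matrix of the self-fabricating cell
#'
#' Species-by-reaction matrix N of the model: carbon import, amino-acid and
#' nucleotide synthesis, transcription, (optionally) rRNA degradation,
#' ribosome assembly, and one translation reaction per protein. The
#' amino-acid charge of ribosomal protein synthesis is discounted by
#' `rp_import_fraction` (imported residues are free).
#'
#' @param params an `rba_params` object.
#' @param comp an `rba_composition` (see [derive_composition()]).
#' @param variant `"base"` or `"extended"`.
#' @return numeric matrix with species rows and flux columns.
#' @export
stoich_matrix <- function(params, comp, variant = c("base", "extended")) {
  variant <- match.arg(variant)
  fx <- .flux_names(variant)
  sp <- .species_names(variant)
  N <- matrix(0, length(sp), length(fx), dimnames = list(sp, fx))
  N["C", "v_IC"] <- 1
  N["C", "v_EAA"] <- -params$n_AA
  N["C", "v_ENT"] <- -params$n_NT
  N["AA", "v_EAA"] <- 1
  N["AA", "v_ENT"] <- -1
  nlen <- .protein_lengths(params, comp, variant)
  for (w in names(nlen)) N["AA", w] <- -nlen[[w]]
  N["NT", "v_ENT"] <- 1
  N["NT", "v_RNAP"] <- -comp$n_rRNA
  N["rRNA", "v_RNAP"] <- 1
  N["rRNA", "v_AF"] <- -1
  N["rP", "v_AF"] <- -1
  N["rP", "w_rP"] <- 1
  N["R", "v_AF"] <- 1
  for (i in c("IC", "EAA", "ENT", "RNAP", if (variant == "extended") "RNase",
              "AF"))
    N[i, paste0("w_", i)] <- 1
  if (variant == "extended") {
    N["NT", "v_RNase"] <- comp$n_rRNA
    N["rRNA", "v_RNase"] <- -1
  }
  N
}

#' Molar masses of the model species
#'
#' Species-aligned molar mass vector: the carbon unit, free amino acids and
#' nucleotides, free rRNA and rP (at the current composition), each protein,
#' and the ribosome.
#'
#' @inheritParams stoich_matrix
#' @return named numeric vector, g/mmol.
#' @export
omega_species <- function(params, comp, variant = c("base", "extended")) {
  variant <- match.arg(variant)
  w <- c(C = params$omega_C, AA = params$omega_AA, NT = params$omega_NT,
         rRNA = comp$n_rRNA * params$omega_NT,
         rP = comp$n_rP * params$omega_AA,
         IC = params$n_IC * params$omega_AA,
         EAA = params$n_EAA * params$omega_AA,
         ENT = params$n_ENT * params$omega_AA,
         RNAP = params$n_RNAP * params$omega_AA,
         RNase = params$n_RNase * params$omega_AA,
         AF = params$n_AF * params$omega_AA,
         R = params$omega_R)
  w[.species_names(variant)]
}

#' Growth-rate-parameterized constraint system
#'
#' Assembles the linear constraint system of the model at a fixed growth
#' rate `mu`: stoichiometric rows (C, AA, NT, rRNA, rP), capacity rows for
#' every catalyst (with concentrations eliminated via `c_i = w_i / mu` and
#' `c_R = v_AF / mu`), the minimum-degradation row (extended variant), and
#' the dry-mass row `omega_C * v_IC = mu`. The base system is 12 rows by 11
#' fluxes; the extended system adds the RNase flux/synthesis columns and the
#' RNase capacity and minimum-degradation rows (14 by 13).
#'
#' `accumulation_mode = "forbid"` turns the rRNA, cap R (and min deg) rows
#' from inequalities into equalities, i.e. forbids accumulation of free rRNA
#' and idle ribosome capacity (the no-accumulation solution branch).
#'
#' For `rp_import_fraction > 0`, the AA and cap R rows charge only the
#' synthesized fraction of the ribosomal protein, and the dry-mass row gains
#' the imported mass `rp_import_fraction * n_rP * omega_AA` at `w_rP` as an
#' exchange contribution, keeping total dry mass normalized.
#'
#' @param params an `rba_params` object.
#' @param comp an `rba_composition` object.
#' @param mu growth rate, per hour (> 0).
#' @param variant `"base"` or `"extended"`. The extended variant requires a
#'   degradation scenario other than `"none"`.
#' @param accumulation_mode `"allow"` (inequalities, default) or `"forbid"`.
#' @return an object of class `rba_constraints`: list with coefficient
#'   matrix `A` (labeled rows/columns), `sign` (`"eq"`/`"ge"` per row),
#'   `rhs`, `mu`, `variant`, `accumulation_mode`, plus the `params` and
#'   `comp` used.
#' @export
build_constraints <- function(params, comp, mu,
                              variant = c("base", "extended"),
                              accumulation_mode = c("allow", "forbid")) {
  variant <- match.arg(variant)
  accumulation_mode <- match.arg(accumulation_mode)
  stopifnot(inherits(params, "rba_params"), inherits(comp, "rba_composition"))
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0)
    stop("build_constraints: mu must be a single positive number")
  if (variant == "extended" && params$degradation$scenario == "none")
    stop("build_constraints: extended variant requires a degradation ",
         "scenario ('constant' or 'hill')")
  fx <- .flux_names(variant)
  rows <- .row_names(variant)
  A <- matrix(0, length(rows), length(fx), dimnames = list(rows, fx))
  nlen <- .protein_lengths(params, comp, variant)

  A["C", c("v_IC", "v_EAA", "v_ENT")] <- c(1, -params$n_AA, -params$n_NT)
  A["AA", c("v_EAA", "v_ENT")] <- c(1, -1)
  A["AA", names(nlen)] <- -nlen
  A["NT", c("v_ENT", "v_RNAP")] <- c(1, -comp$n_rRNA)
  A["rRNA", c("v_RNAP", "v_AF")] <- c(1, -1)
  A["rP", c("v_AF", "w_rP")] <- c(-1, 1)
  A["cap IC", c("v_IC", "w_IC")] <- c(-mu, params$kcat_IC)
  A["cap EAA", c("v_EAA", "w_EAA")] <- c(-mu, params$kcat_EAA)
  A["cap ENT", c("v_ENT", "w_ENT")] <- c(-mu, params$kcat_ENT)
  A["cap RNAP", c("v_RNAP", "w_RNAP")] <-
    c(-mu * comp$n_rRNA, kel_bar_RNAP(params))
  A["cap AF", c("v_AF", "w_AF")] <- c(-mu, params$kcat_AF)
  A["cap R", "v_AF"] <- kel_bar_R(params)
  A["cap R", names(nlen)] <- -mu * nlen
  A["mass", "v_IC"] <- params$omega_C
  if (params$rp_import_fraction > 0)
    A["mass", "w_rP"] <- params$rp_import_fraction * comp$n_rP * params$omega_AA
  if (variant == "extended") {
    A["NT", "v_RNase"] <- comp$n_rRNA
    A["rRNA", "v_RNase"] <- -1
    A["cap RNase", c("v_RNase", "w_RNase")] <-
      c(-mu * comp$n_rRNA, params$kdeg_RNase)
    A["min deg", c("v_RNase", "v_AF")] <-
      c(mu, -kdeg_value(params$degradation, comp$x_rP) * (1 - comp$x_rP))
  }

  sgn <- stats::setNames(rep("ge", length(rows)), rows)
  sgn[c("C", "AA", "NT", "mass")] <- "eq"
  if (accumulation_mode == "forbid") {
    sgn[c("rRNA", "cap R")] <- "eq"
    if (variant == "extended") sgn["min deg"] <- "eq"
  }
  rhs <- stats::setNames(rep(0, length(rows)), rows)
  rhs["mass"] <- mu

  structure(
    list(A = A, sign = sgn, rhs = rhs, mu = mu, variant = variant,
         accumulation_mode = accumulation_mode,
         params = params, comp = comp),
    class = "rba_constraints"
  )
}

#' @export
print.rba_constraints <- function(x, ...) {
  cat(sprintf("<rba_constraints> %s model at mu = %.6g/h (%d rows x %d fluxes, accumulation %sed)\n",
              x$variant, x$mu, nrow(x$A), ncol(x$A), x$accumulation_mode))
  invisible(x)
}

#' Export a constraint system as a labeled data frame / CSV
#'
#' One row per constraint with its coefficients, sign and right-hand side;
#' suitable for inspection or round-tripping through CSV.
#'
#' @param sys an `rba_constraints` object.
#' @param path optional file path; if given, written as CSV (RFC 4180,
#'   header row, '.' decimal).
#' @return the data frame, invisibly if `path` is given.
#' @export
constraints_as_table <- function(sys, path = NULL) {
  stopifnot(inherits(sys, "rba_constraints"))
  df <- data.frame(row = rownames(sys$A), sys$A,
                   sign = unname(sys$sign), rhs = unname(sys$rhs),
                   check.names = FALSE)
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Concentrations implied by a flux vector
#'
#' At steady state, concentrations follow from fluxes as
#' `c = N v_tot / mu`: each enzyme's concentration is `w_i / mu`, the
#' ribosome's is `v_AF / mu`, and species allowed to accumulate (free rRNA,
#' free rP) carry their net production divided by `mu`. Metabolite rows held
#' at equality give zero concentrations.
#'
#' @param sys an `rba_constraints` object.
#' @param fluxes named flux vector satisfying `sys` (within tolerance).
#' @param mu growth rate, per hour; defaults to `sys$mu`.
#' @return named concentration vector (mmol/g) over the model species.
#' @export
concentrations_from_fluxes <- function(sys, fluxes, mu = sys$mu) {
  stopifnot(inherits(sys, "rba_constraints"))
  if (mu <= 0) stop("concentrations_from_fluxes: mu must be positive")
  N <- stoich_matrix(sys$params, sys$comp, sys$variant)
  fluxes <- fluxes[colnames(N)]
  cvec <- drop(N %*% fluxes) / mu
  # clip negative round-off within the solver's feasibility tolerance
  cvec[cvec < 0 & cvec > -1e-9] <- 0
  cvec
}

#' Ribosome allocations of a flux vector
#'
#' Fraction of the total effective ribosome elongation capacity devoted to
#' each protein: `phi_i = mu * n_i * w_i / (kel_bar_R * v_AF)`. Their sum is
#' at most 1 (the ribosome capacity constraint).
#'
#' @param fluxes named flux vector (must include `v_AF` > 0 and the
#'   `w_` fluxes).
#' @param mu growth rate, per hour.
#' @param params an `rba_params` object.
#' @param comp an `rba_composition` object.
#' @param variant `"base"` or `"extended"`.
#' @return named allocation vector over proteins.
#' @export
allocations <- function(fluxes, mu, params, comp,
                        variant = c("base", "extended")) {
  variant <- match.arg(variant)
  if (!("v_AF" %in% names(fluxes)) || fluxes[["v_AF"]] <= 0)
    stop("allocations: undefined, v_AF must be positive ",
         "(no ribosome synthesis)")
  nlen <- .protein_lengths(params, comp, variant)
  phi <- mu * nlen * fluxes[names(nlen)] / (kel_bar_R(params) * fluxes[["v_AF"]])
  stats::setNames(as.numeric(phi), sub("^w_", "", names(nlen)))
}

#' Mass-conservation audit of the stoichiometry
#'
#' Computes `t(omega) %*% N` over the reaction columns. For a closed set of
#' internal reactions this is zero everywhere except the exchange columns:
#' carbon import (`v_IC`, contributing `omega_C`) and, when
#' `rp_import_fraction > 0`, ribosomal protein import riding on `w_rP`.
#'
#' @inheritParams stoich_matrix
#' @return named numeric vector over flux columns, g/mmol.
#' @export
mass_balance_audit <- function(params, comp, variant = c("base", "extended")) {
  variant <- match.arg(variant)
  N <- stoich_matrix(params, comp, variant)
  drop(omega_species(params, comp, variant) %*% N)
}
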