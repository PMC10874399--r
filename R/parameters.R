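#' Degradation model for ribosomal RNA
#'
#' Describes how the minimum rRNA degradation rate constant \eqn{k^{deg}}
#' depends on the ribosomal protein mass fraction \eqn{x_{rP}}. Three
#' scenarios are supported: `"none"` (no degradation, the base model),
#' `"constant"` (\eqn{k^{deg} \equiv k^{deg}_{max}}), and `"hill"`, where
#' ribosomal proteins cooperatively protect rRNA,
#' \deqn{k^{deg}(x) = k^{deg}_{max} (1 - x^n / (K^n + x^n)),}
#' with half-saturation constant \eqn{K} and Hill factor \eqn{n}.
#'
#' @param scenario one of `"none"`, `"constant"`, `"hill"`.
#' @param kdeg_max maximal degradation rate constant, per hour (ignored for
#'   `"none"`).
#' @param K half-saturation constant on the \eqn{x_{rP}} scale, in (0, 1).
#' @param n_hill Hill factor (cooperativity), >= 1.
#' @return an object of class `rba_degradation`.
#' @export
#' @examples
#' degradation_model("hill", kdeg_max = 2, K = 0.2, n_hill = 6)
degradation_model <- function(scenario = c("none", "constant", "hill"),
                              kdeg_max = 0, K = 0.2, n_hill = 1) {
  scenario <- match.arg(scenario)
  if (!is.numeric(kdeg_max) || length(kdeg_max) != 1L || kdeg_max < 0)
    stop("degradation: kdeg_max must be a single non-negative number")
  if (!is.numeric(K) || length(K) != 1L || K <= 0 || K >= 1)
    stop("degradation: K must lie in (0, 1)")
  if (!is.numeric(n_hill) || length(n_hill) != 1L || n_hill < 1)
    stop("degradation: n_hill must be >= 1")
  structure(
    list(scenario = scenario, kdeg_max = kdeg_max, K = K, n_hill = n_hill),
    class = "rba_degradation"
  )
}

# field groups used by the validator and the serializer
.rba_mass_fields <- c("omega_C", "omega_AA", "omega_NT", "omega_R")
.rba_length_fields <- c("n_AA", "n_NT", "n_IC", "n_EAA", "n_ENT",
                        "n_RNAP", "n_RNase", "n_AF")
.rba_rate_fields <- c("kcat_IC", "kcat_EAA", "kcat_ENT", "kcat_AF",
                      "kel_RNAP", "kel_R", "kdeg_RNase")
.rba_fraction_fields <- c("f_act_RNAP", "phi_rRNA_RNAP", "f_act_R")

#' Parameter set for one growth condition
#'
#' Bundles all kinetic and mass constants of the coarse-grained
#' self-fabricating-cell model for a single growth condition. All rates are
#' stored per hour; [load_parameters()] converts per-second file entries on
#' load. Molar masses are in g/mmol, protein lengths in amino acids,
#' elongation rates in residues (AA or NT) per hour.
#'
#' The carbon stoichiometries `n_AA` (carbon units per amino acid) and
#' `n_NT` (extra carbon units per nucleotide) are derived from the molar
#' masses (`n_AA = omega_AA/omega_C`, `n_NT = (omega_NT - omega_AA)/omega_C`)
#' unless supplied; if supplied they must agree with the masses, since
#' internal reactions of the model conserve mass exactly.
#'
#' @param omega_C,omega_AA,omega_NT,omega_R molar masses of the carbon unit,
#'   amino acid residue, nucleotide residue, and whole ribosome (g/mmol).
#' @param n_IC,n_EAA,n_ENT,n_RNAP,n_RNase,n_AF protein lengths (AA) of the
#'   importer, the two lumped metabolic enzymes, RNA polymerase, RNase, and
#'   the ribosome assembly factors.
#' @param kcat_IC,kcat_EAA,kcat_ENT,kcat_AF enzyme turnover numbers, per hour.
#' @param kel_RNAP transcription elongation rate, NT per hour.
#' @param f_act_RNAP fraction of actively transcribing RNA polymerases.
#' @param phi_rRNA_RNAP fraction of RNAP allocated to rRNA synthesis.
#' @param kel_R translation elongation rate, AA per hour.
#' @param f_act_R fraction of actively translating ribosomes.
#' @param kdeg_RNase RNase turnover number, NT per hour.
#' @param degradation an [degradation_model()] object.
#' @param rp_import_fraction fraction of ribosomal protein imported free of
#'   synthesis cost, in [0, 1) (mitochondrial scenario; default 0).
#' @param n_AA,n_NT optional carbon stoichiometries; derived from masses if
#'   `NULL`.
#' @param condition_label free-text label for the growth condition.
#' @param meta optional named list of metadata (e.g. fixture provenance).
#' @return a validated object of class `rba_params`.
#' @seealso [ecoli_fixture()], [load_parameters()], [random_parameters()]
#' @export
parameter_set <- function(omega_C, omega_AA, omega_NT, omega_R,
                          n_IC, n_EAA, n_ENT, n_RNAP, n_RNase, n_AF,
                          kcat_IC, kcat_EAA, kcat_ENT, kcat_AF,
                          kel_RNAP, f_act_RNAP = 1, phi_rRNA_RNAP = 1,
                          kel_R, f_act_R = 1,
                          kdeg_RNase,
                          degradation = degradation_model("none"),
                          rp_import_fraction = 0,
                          n_AA = NULL, n_NT = NULL,
                          condition_label = "",
                          meta = list()) {
  if (is.null(n_AA)) n_AA <- omega_AA / omega_C
  if (is.null(n_NT)) n_NT <- (omega_NT - omega_AA) / omega_C
  p <- structure(
    list(
      omega_C = omega_C, omega_AA = omega_AA, omega_NT = omega_NT,
      omega_R = omega_R,
      n_AA = n_AA, n_NT = n_NT,
      n_IC = n_IC, n_EAA = n_EAA, n_ENT = n_ENT,
      n_RNAP = n_RNAP, n_RNase = n_RNase, n_AF = n_AF,
      kcat_IC = kcat_IC, kcat_EAA = kcat_EAA, kcat_ENT = kcat_ENT,
      kcat_AF = kcat_AF,
      kel_RNAP = kel_RNAP, f_act_RNAP = f_act_RNAP,
      phi_rRNA_RNAP = phi_rRNA_RNAP,
      kel_R = kel_R, f_act_R = f_act_R,
      kdeg_RNase = kdeg_RNase,
      degradation = degradation,
      rp_import_fraction = rp_import_fraction,
      condition_label = condition_label,
      meta = meta
    ),
    class = "rba_params"
  )
  validate_parameters(p)
}

#' Validate a parameter set
#'
#' Checks positivity of masses, lengths and rates, range constraints on the
#' active fractions, consistency of the carbon stoichiometries with the
#' molar masses (mass conservation of the internal reactions), and the
#' degradation sub-model. Errors name the offending field.
#'
#' @param p an `rba_params` object (or a bare list with the same fields).
#' @return `p`, invisibly classed as `rba_params`, if valid.
#' @export
validate_parameters <- function(p) {
  need <- c(.rba_mass_fields, .rba_length_fields, .rba_rate_fields,
            .rba_fraction_fields, "n_AA", "n_NT", "degradation",
            "rp_import_fraction")
  for (f in need) {
    if (is.null(p[[f]]))
      stop("parameter set: missing field '", f, "'")
  }
  for (f in c(.rba_mass_fields, .rba_length_fields, .rba_rate_fields)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter set: field '", f, "' must be a single positive number")
  }
  for (f in .rba_fraction_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      stop("parameter set: field '", f, "' must lie in (0, 1]")
  }
  v <- p$rp_import_fraction
  if (!is.numeric(v) || length(v) != 1L || v < 0 || v >= 1)
    stop("parameter set: field 'rp_import_fraction' must lie in [0, 1)")
  if (!inherits(p$degradation, "rba_degradation"))
    p$degradation <- do.call(degradation_model, p$degradation)
  # mass conservation: AA and NT synthesis must balance on the carbon unit
  if (abs(p$n_AA * p$omega_C - p$omega_AA) > 1e-9 * p$omega_AA)
    stop("parameter set: field 'n_AA' inconsistent with omega_AA/omega_C ",
         "(internal reactions must conserve mass)")
  if (abs(p$n_NT * p$omega_C + p$omega_AA - p$omega_NT) > 1e-9 * p$omega_NT)
    stop("parameter set: field 'n_NT' inconsistent with ",
         "(omega_NT - omega_AA)/omega_C")
  if (p$omega_R <= p$omega_AA)
    stop("parameter set: field 'omega_R' must exceed omega_AA")
  class(p) <- "rba_params"
  invisible(p)
}

#' Effective transcription elongation rate
#'
#' `kel_RNAP * f_act_RNAP * phi_rRNA_RNAP`, NT per hour.
#' @param p an `rba_params` object.
#' @return scalar rate, per hour.
#' @export
kel_bar_RNAP <- function(p) p$kel_RNAP * p$f_act_RNAP * p$phi_rRNA_RNAP

#' Effective translation elongation rate
#'
#' `kel_R * f_act_R`, AA per hour.
#' @param p an `rba_params` object.
#' @return scalar rate, per hour.
#' @export
kel_bar_R <- function(p) p$kel_R * p$f_act_R

#' @export
print.rba_params <- function(x, ...) {
  cat("<rba_params>",
      if (nzchar(x$condition_label)) paste0(" condition: ", x$condition_label),
      "\n", sep = "")
  cat(sprintf("  masses (g/mmol): C %.4g, AA %.4g, NT %.4g, R %.5g\n",
              x$omega_C, x$omega_AA, x$omega_NT, x$omega_R))
  cat(sprintf("  elongation (per h): translation %.4g (f_act %.2f), transcription %.4g (f_act %.2f)\n",
              x$kel_R, x$f_act_R, x$kel_RNAP, x$f_act_RNAP))
  cat(sprintf("  kcat (per h): IC %.4g, EAA %.4g, ENT %.4g, AF %.4g; RNase %.4g NT/h\n",
              x$kcat_IC, x$kcat_EAA, x$kcat_ENT, x$kcat_AF, x$kdeg_RNase))
  d <- x$degradation
  cat(sprintf("  degradation: %s", d$scenario))
  if (d$scenario != "none")
    cat(sprintf(" (kdeg_max %.4g/h, K %.2f, n %g)", d$kdeg_max, d$K, d$n_hill))
  if (x$rp_import_fraction > 0)
    cat(sprintf("; rP import fraction %.3g", x$rp_import_fraction))
  cat("\n")
  invisible(x)
}

#' Archaeal scenario variant
#'
#' Returns a copy of `base` with the maximal rRNA degradation rate constant
#' multiplied by `deg_factor`, emulating the higher RNA misfolding and
#' degradation pressure of extreme environments (high temperature, low pH).
#'
#' @param base an `rba_params` object with a `"constant"` or `"hill"`
#'   degradation scenario.
#' @param deg_factor positive multiplier for `kdeg_max` (2 for the standard
#'   archaeal scenario).
#' @return a validated `rba_params` copy.
#' @export
variant_archaea <- function(base, deg_factor = 2) {
  stopifnot(inherits(base, "rba_params"))
  if (base$degradation$scenario == "none")
    stop("variant_archaea: base set has no degradation to scale ",
         "(scenario 'none')")
  if (!is.numeric(deg_factor) || length(deg_factor) != 1L || deg_factor <= 0)
    stop("variant_archaea: deg_factor must be a positive scalar")
  p <- base
  p$degradation$kdeg_max <- p$degradation$kdeg_max * deg_factor
  p$condition_label <- paste0(base$condition_label, " [archaea x",
                              format(deg_factor), "]")
  validate_parameters(p)
  p
}

#' Mitochondrial scenario variant
#'
#' Returns a copy of `base` in which a fraction of the ribosomal protein is
#' imported free of synthesis cost (as cytosolically translated proteins are
#' for mitochondrial ribosomes). Downstream, the amino-acid balance and the
#' ribosome capacity constraint charge only `(1 - import_fraction) * n_rP`
#' residues per ribosomal protein complex, and the imported mass enters the
#' dry-mass balance as an exchange term.
#'
#' @param base an `rba_params` object.
#' @param import_fraction fraction of rP imported for free, in [0, 1).
#' @return a validated `rba_params` copy.
#' @export
variant_mitochondria <- function(base, import_fraction = 1 / 3) {
  stopifnot(inherits(base, "rba_params"))
  if (!is.numeric(import_fraction) || length(import_fraction) != 1L ||
      import_fraction < 0 || import_fraction >= 1)
    stop("variant_mitochondria: import_fraction must lie in [0, 1)")
  p <- base
  p$rp_import_fraction <- import_fraction
  p$condition_label <- paste0(base$condition_label, " [mito import ",
                              format(import_fraction), "]")
  validate_parameters(p)
  p
}

#' Random parameter set (property-test generator)
#'
#' Draws a valid parameter set uniformly (log-uniformly for rates) within
#' per-field bounds. Deterministic for a fixed seed. The carbon
#' stoichiometries are derived from the drawn masses so that every draw
#' passes [validate_parameters()].
#'
#' @param seed integer seed.
#' @param ranges named list of `c(lo, hi)` bounds overriding the defaults
#'   (fields: the mass, length and rate fields of [parameter_set()], plus
#'   `f_act_RNAP`, `f_act_R`).
#' @return a validated `rba_params` object.
#' @export
random_parameters <- function(seed, ranges = list()) {
  defaults <- list(
    omega_C = c(0.02, 0.06), omega_AA = c(0.08, 0.14),
    omega_NT = c(0.25, 0.40), omega_R = c(1500, 3500),
    n_IC = c(300, 1500), n_EAA = c(1000, 5000), n_ENT = c(1000, 5000),
    n_RNAP = c(2000, 5000), n_RNase = c(400, 1500), n_AF = c(500, 3000),
    kcat_IC = c(1e4, 1e6), kcat_EAA = c(5e2, 5e4), kcat_ENT = c(5e2, 5e4),
    kcat_AF = c(1e3, 1e5),
    kel_RNAP = c(1e5, 1e6), kel_R = c(2e4, 2e5),
    kdeg_RNase = c(1e5, 1e6),
    f_act_RNAP = c(0.1, 1), f_act_R = c(0.5, 1)
  )
  for (f in names(ranges)) {
    r <- ranges[[f]]
    if (is.null(defaults[[f]]))
      stop("random_parameters: unknown field '", f, "' in ranges")
    if (length(r) != 2L || r[1] > r[2] || r[1] <= 0)
      stop("random_parameters: infeasible range for '", f, "'")
    defaults[[f]] <- r
  }
  runif_field <- function(f, log_scale = FALSE) {
    r <- defaults[[f]]
    if (log_scale) exp(stats::runif(1, log(r[1]), log(r[2])))
    else stats::runif(1, r[1], r[2])
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  draw <- list()
  for (f in c("omega_C", "omega_AA", "omega_NT", "omega_R",
              "n_IC", "n_EAA", "n_ENT", "n_RNAP", "n_RNase", "n_AF",
              "f_act_RNAP", "f_act_R"))
    draw[[f]] <- runif_field(f)
  for (f in c("kcat_IC", "kcat_EAA", "kcat_ENT", "kcat_AF",
              "kel_RNAP", "kel_R", "kdeg_RNase"))
    draw[[f]] <- runif_field(f, log_scale = TRUE)
  # keep the nucleotide heavier than the amino acid so n_NT > 0
  if (draw$omega_NT <= draw$omega_AA)
    draw$omega_NT <- draw$omega_AA + draw$omega_C
  do.call(parameter_set, c(draw, list(
    condition_label = paste0("random seed ", seed),
    meta = list(source = "random_parameters", seed = seed)
  )))
}

# save/restore the global RNG state so generators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
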